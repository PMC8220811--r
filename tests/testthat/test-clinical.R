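write_clinical_fixture <- function(tbl, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(tbl, path, na = "NA", progress = FALSE)
  path
}

# parse records through the reader so NA normalization is applied uniformly
read_records <- function(tbl) {
  read_clinical_table(write_clinical_fixture(tbl))
}

base_record <- function(case_id, tumor_status = NA, event = NA, site = NA,
                        pfi = 100, cancer = "BRCA") {
  tibble::tibble(
    case_id = case_id, cancer_type = cancer,
    tumor_status = tumor_status, new_tumor_event_type = event,
    new_tumor_event_site = site, `PFI.time` = pfi
  )
}

test_that("clinical parsing normalizes NA tokens and enforces the schema", {
  tbl <- dplyr::bind_rows(
    base_record("c1", "WITH TUMOR", "Recurrence", "Lung", 120),
    base_record("c2", "[Not Available]", "Metastasis", NA, 300),
    base_record("c3", "tumor free", NA, "", NA)
  )
  path <- write_clinical_fixture(tbl)
  rec <- read_clinical_table(path)
  expect_equal(nrow(rec), 3)
  expect_true(is.na(rec$tumor_status[2]))          # [Not Available] -> NA
  expect_true(is.na(rec$new_tumor_event_site[3]))  # empty cell -> NA
  expect_true(is.na(rec$pfi_time[3]))
  expect_equal(rec$tumor_status[3], "tumor free")  # value kept, matching is case-insensitive later

  # missing required column
  broken <- dplyr::select(tbl, -`PFI.time`)
  expect_error(read_clinical_table(write_clinical_fixture(broken)), "PFI.time")

  # duplicate case ids
  dup <- dplyr::bind_rows(base_record("c1"), base_record("c1"))
  expect_error(read_clinical_table(write_clinical_fixture(dup)), "duplicate")

  # column aliases
  aliased <- dplyr::rename(tbl, bcr_patient_barcode = case_id)
  rec2 <- read_clinical_table(write_clinical_fixture(aliased),
                              aliases = c(case_id = "bcr_patient_barcode"))
  expect_equal(rec2$case_id, rec$case_id)
})

test_that("the three positive rules, the negative rule, and exclusions fire correctly", {
  records <- dplyr::bind_rows(
    base_record("m1", tumor_status = "METASTASIS"),                  # r1 vocabulary
    base_record("m2", tumor_status = NA, event = "Metastasis"),      # r2
    base_record("m3", tumor_status = "NOT CLEAR", site = "Liver"),   # r3
    base_record("n1", tumor_status = "TUMOR FREE"),                  # negative
    base_record("x1", tumor_status = "NOT CLEAR", event = "Recurrence"),
    base_record("x2", tumor_status = NA),                            # removed: NA status
    base_record("x3", tumor_status = "WITH TUMOR", event = "Recurrence")
  )
  # lower-case variants must match too
  records$tumor_status[4] <- "tumor free"
  cohort <- assign_metastasis_labels(read_records(records))
  entries <- tidy(cohort)
  expect_equal(entries$label[match(c("m1", "m2", "m3"), entries$case_id)],
               c(1L, 1L, 1L))
  expect_equal(entries$label[entries$case_id == "n1"], 0L)
  expect_false(any(c("x1", "x2", "x3") %in% entries$case_id))
  expect_equal(
    cohort$excluded$reason[match(c("x1", "x2", "x3"), cohort$excluded$case_id)],
    c("unclear_tumor_status", "unclear_tumor_status", "ambiguous_non_metastasis")
  )
  # partition invariant
  expect_equal(nrow(entries) + nrow(cohort$excluded), nrow(records))
})

test_that("retention keeps all metastasis cases and the longest-followed negatives", {
  neg <- dplyr::bind_rows(lapply(1:10, function(i) {
    base_record(sprintf("n%02d", i), tumor_status = "TUMOR FREE", pfi = i)
  }))
  pos <- base_record("m1", tumor_status = NA, event = "Metastasis", pfi = 2)
  cohort <- assign_metastasis_labels(read_records(dplyr::bind_rows(neg, pos)))

  kept <- retain_longest_nonmet(cohort, fraction = 0.7)
  entries <- tidy(kept)
  # floor(0.7 * 10) = 7 negatives, PFI 10..4, plus the positive
  expect_setequal(entries$case_id[entries$label == 0],
                  sprintf("n%02d", 4:10))
  expect_true("m1" %in% entries$case_id)
  expect_equal(nrow(entries) + nrow(kept$excluded), 11)

  # fraction 1.0 keeps everything
  expect_equal(sum(tidy(retain_longest_nonmet(cohort, 1.0))$label == 0), 10)

  # floor() edge: a single negative with fraction 0.7 keeps none
  single <- assign_metastasis_labels(read_records(dplyr::bind_rows(
    base_record("n1", tumor_status = "TUMOR FREE", pfi = 5), pos
  )))
  expect_equal(sum(tidy(retain_longest_nonmet(single, 0.7))$label == 0), 0)

  expect_error(retain_longest_nonmet(cohort, 0), "fraction")
  expect_error(retain_longest_nonmet(cohort, 1.2), "fraction")
})

test_that("negatives with missing PFI are excluded before retention", {
  records <- dplyr::bind_rows(
    base_record("n1", tumor_status = "TUMOR FREE", pfi = NA),
    base_record("n2", tumor_status = "TUMOR FREE", pfi = 50),
    base_record("m1", tumor_status = NA, event = "Metastasis", pfi = NA)
  )
  cohort <- retain_longest_nonmet(
    assign_metastasis_labels(read_records(records)), fraction = 1.0
  )
  expect_equal(cohort$excluded$reason[cohort$excluded$case_id == "n1"], "missing_pfi")
  expect_true(all(c("n2", "m1") %in% tidy(cohort)$case_id))  # positives keep NA pfi
})

test_that("raising the retention fraction never drops a previously retained case", {
  neg <- dplyr::bind_rows(lapply(1:17, function(i) {
    base_record(sprintf("n%02d", i), tumor_status = "TUMOR FREE", pfi = (i * 37) %% 19)
  }))
  cohort <- assign_metastasis_labels(read_records(dplyr::bind_rows(
    neg, base_record("m1", tumor_status = NA, event = "Metastasis")
  )))
  kept_prev <- character(0)
  for (f in c(0.1, 0.3, 0.5, 0.7, 0.9, 1.0)) {
    kept_now <- tidy(retain_longest_nonmet(cohort, f))$case_id
    expect_true(all(kept_prev %in% kept_now))
    kept_prev <- kept_now
  }
})

test_that("labeling output is identical regardless of input row order", {
  tbl <- gen_clinical_table(n_per_branch = 3, seed = 9)
  clin <- dplyr::select(tbl, -truth_label, -truth_reason) |>
    dplyr::rename(`PFI.time` = pfi_time)
  shuffled <- withr::with_seed(1, clin[sample(nrow(clin)), ])

  label_from <- function(d) {
    cohort <- label_cohort(read_records(d), fraction = 0.7)
    out <- withr::local_tempfile(fileext = ".tsv")
    write_labeled_cohort(cohort, out)
    readLines(out)
  }
  expect_identical(label_from(clin), label_from(shuffled))
})
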