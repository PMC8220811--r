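na_tokens <- c("na", "[not available]", "[not applicable]", "#n/a", "")

normalize_clinical_value <- function(x) {
  x <- trimws(as.character(x))
  x[tolower(x) %in% na_tokens] <- NA_character_
  x
}

clinical_required <- c("case_id", "cancer_type", "tumor_status",
                       "new_tumor_event_type", "new_tumor_event_site",
                       "PFI.time")

#' Read and normalize a TCGA-CDR-style clinical table
#'
#' Expects a TSV with at least the columns `case_id`, `cancer_type`,
#' `tumor_status`, `new_tumor_event_type`, `new_tumor_event_site`, and
#' `PFI.time` (names configurable through `aliases`). Literal `NA`,
#' `[Not Available]`, and empty cells are normalized to `NA`; value matching
#' downstream is case-insensitive after whitespace trimming.
#'
#' @param path Path to the clinical TSV.
#' @param aliases Named character vector mapping required column names to the
#'   names actually present in the file, e.g.
#'   `c(case_id = "bcr_patient_barcode")`.
#' @return A tibble of clinical records with columns `case_id`, `cancer_type`,
#'   `tumor_status`, `new_tumor_event_type`, `new_tumor_event_site`,
#'   `pfi_time`.
#' @export
read_clinical_table <- function(path, aliases = character()) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, na = character())
  for (std in names(aliases)) {
    if (aliases[[std]] %in% names(tbl)) {
      names(tbl)[names(tbl) == aliases[[std]]] <- std
    }
  }
  missing <- setdiff(clinical_required, names(tbl))
  if (length(missing) > 0) {
    rlang::abort(sprintf(
      "clinical table %s is missing required column(s): %s",
      path, paste(missing, collapse = ", ")
    ))
  }
  out <- tibble::tibble(
    case_id = trimws(tbl$case_id),
    cancer_type = normalize_clinical_value(tbl$cancer_type),
    tumor_status = normalize_clinical_value(tbl$tumor_status),
    new_tumor_event_type = normalize_clinical_value(tbl$new_tumor_event_type),
    new_tumor_event_site = normalize_clinical_value(tbl$new_tumor_event_site),
    pfi_time = suppressWarnings(as.numeric(normalize_clinical_value(tbl$`PFI.time`)))
  )
  if (any(out$case_id == "" | is.na(out$case_id))) {
    rlang::abort("clinical table has empty case_id values")
  }
  if (anyDuplicated(out$case_id) > 0) {
    rlang::abort(sprintf(
      "duplicate case_id in clinical table: %s",
      out$case_id[anyDuplicated(out$case_id)]
    ))
  }
  if (any(out$pfi_time < 0, na.rm = TRUE)) {
    rlang::abort("PFI.time must be non-negative")
  }
  out
}

value_eq <- function(x, value) {
  !is.na(x) & toupper(x) == toupper(value)
}

#' Assign binary metastasis labels to clinical records
#'
#' Derives the metastasis outcome from clinical fields with three positive
#' rules applied in order:
#' 1. `tumor_status` itself names a metastatic state (the matching value set
#'    is configurable; TCGA-CDR vocabulary has no such value, so with the
#'    default set this rule applies only to extended vocabularies);
#' 2. `tumor_status` uninformative (`NOT CLEAR` or `NA`) but
#'    `new_tumor_event_type` is `Metastasis`;
#' 3. neither `tumor_status` nor `new_tumor_event_type` informative, but a
#'    `new_tumor_event_site` is recorded.
#'
#' Of the remaining cases, those with uninformative `tumor_status` are
#' excluded; label 0 is given only to cases with `tumor_status = TUMOR FREE`
#' and no new tumor event; everything else is excluded as ambiguous.
#'
#' @param records Tibble of clinical records from [read_clinical_table()].
#' @param met_status_values Character vector of `tumor_status` values counted
#'   as rule-1 metastasis (matched case-insensitively).
#' @return A `labeled_cohort`: list with `entries` (tibble: `case_id`,
#'   `cancer_type`, `label`, `pfi_time`) and `excluded` (tibble: `case_id`,
#'   `reason`). Entries and exclusions partition the input records.
#' @export
assign_metastasis_labels <- function(records,
                                     met_status_values = c("METASTASIS", "METASTATIC")) {
  records <- tibble::as_tibble(records)
  status <- toupper(records$tumor_status)
  event <- records$new_tumor_event_type
  site <- records$new_tumor_event_site

  status_unclear <- is.na(status) | status == "NOT CLEAR"
  r1 <- !is.na(status) & status %in% toupper(met_status_values)
  r2 <- !r1 & status_unclear & value_eq(event, "Metastasis")
  r3 <- !r1 & !r2 & status_unclear & is.na(event) & !is.na(site)
  positive <- r1 | r2 | r3

  removed_unclear <- !positive & status_unclear
  negative <- !positive & !removed_unclear &
    is.na(event) & status == "TUMOR FREE"
  ambiguous <- !positive & !removed_unclear & !negative

  entries <- tibble::tibble(
    case_id = records$case_id,
    cancer_type = records$cancer_type,
    label = ifelse(positive, 1L, 0L),
    pfi_time = records$pfi_time
  )[positive | negative, ]

  excluded <- dplyr::bind_rows(
    tibble::tibble(case_id = records$case_id[removed_unclear],
                   reason = "unclear_tumor_status"),
    tibble::tibble(case_id = records$case_id[ambiguous],
                   reason = "ambiguous_non_metastasis")
  )
  new_labeled_cohort(entries, excluded, n_input = nrow(records))
}

new_labeled_cohort <- function(entries, excluded, n_input) {
  stopifnot(nrow(entries) + nrow(excluded) == n_input)
  structure(list(entries = tibble::as_tibble(entries),
                 excluded = tibble::as_tibble(excluded)),
            class = "labeled_cohort")
}

#' @export
print.labeled_cohort <- function(x, ...) {
  cat(sprintf(
    "<labeled_cohort> %d labeled (%d metastasis, %d non-metastasis), %d excluded\n",
    nrow(x$entries), sum(x$entries$label == 1), sum(x$entries$label == 0),
    nrow(x$excluded)
  ))
  invisible(x)
}

#' Tidy a labeled cohort into its entry table
#'
#' @param x A `labeled_cohort`.
#' @param ... Unused.
#' @return The `entries` tibble (`case_id`, `cancer_type`, `label`,
#'   `pfi_time`).
#' @method tidy labeled_cohort
#' @export
tidy.labeled_cohort <- function(x, ...) x$entries

#' Summarize a labeled cohort
#'
#' @param x A `labeled_cohort`.
#' @param ... Unused.
#' @return One-row tibble with labeled/positive/negative/excluded counts.
#' @method glance labeled_cohort
#' @export
glance.labeled_cohort <- function(x, ...) {
  tibble::tibble(
    n_labeled = nrow(x$entries),
    n_metastasis = sum(x$entries$label == 1),
    n_non_metastasis = sum(x$entries$label == 0),
    n_excluded = nrow(x$excluded)
  )
}

#' Keep only the longest-followed non-metastasis cases
#'
#' Short progression-free intervals can make a "non-metastasis" label
#' temporary (the next visit might reveal progression), so only the fraction
#' of label-0 cases with the longest PFI times is retained; all label-1 cases
#' are kept unconditionally. Label-0 cases with missing PFI time are excluded
#' first (`missing_pfi`). Sorting is by `pfi_time` descending with ties broken
#' by `case_id` ascending, and `floor(fraction * n0)` cases are kept, so the
#' result is deterministic.
#'
#' @param cohort A `labeled_cohort` from [assign_metastasis_labels()].
#' @param fraction Fraction of label-0 cases to retain, in (0, 1]; default
#'   0.70.
#' @param per_cancer Apply the filter within each cancer type instead of
#'   globally (default `FALSE`, the global filter).
#' @return A `labeled_cohort` with filtered entries; dropped cases move to
#'   `excluded` with reasons `missing_pfi` or `pfi_retention_filtered`.
#' @export
retain_longest_nonmet <- function(cohort, fraction = 0.70, per_cancer = FALSE) {
  stopifnot(inherits(cohort, "labeled_cohort"))
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      is.na(fraction) || fraction <= 0 || fraction > 1) {
    rlang::abort("`fraction` must be a single number in (0, 1]")
  }
  n_input <- nrow(cohort$entries) + nrow(cohort$excluded)
  pos <- dplyr::filter(cohort$entries, .data$label == 1L)
  neg <- dplyr::filter(cohort$entries, .data$label == 0L)

  missing <- is.na(neg$pfi_time)
  excl_missing <- tibble::tibble(case_id = neg$case_id[missing],
                                 reason = "missing_pfi")
  neg <- neg[!missing, ]

  keep_top <- function(d) {
    d <- dplyr::arrange(d, dplyr::desc(.data$pfi_time), .data$case_id)
    utils::head(d, floor(fraction * nrow(d)))
  }
  kept <- if (per_cancer) {
    neg |>
      dplyr::group_by(.data$cancer_type) |>
      dplyr::group_modify(~ keep_top(.x)) |>
      dplyr::ungroup() |>
      dplyr::select(dplyr::all_of(names(cohort$entries)))
  } else {
    keep_top(neg)
  }
  dropped <- dplyr::anti_join(neg, kept, by = "case_id")
  excl_dropped <- tibble::tibble(case_id = dropped$case_id,
                                 reason = "pfi_retention_filtered")
  entries <- dplyr::bind_rows(pos, kept) |>
    dplyr::arrange(.data$case_id)
  excluded <- dplyr::bind_rows(cohort$excluded, excl_missing, excl_dropped)
  new_labeled_cohort(entries, excluded, n_input)
}

#' Label a cohort end to end
#'
#' Convenience wrapper: [assign_metastasis_labels()] followed by
#' [retain_longest_nonmet()].
#'
#' @inheritParams assign_metastasis_labels
#' @inheritParams retain_longest_nonmet
#' @return A `labeled_cohort`.
#' @export
label_cohort <- function(records, fraction = 0.70,
                         met_status_values = c("METASTASIS", "METASTATIC"),
                         per_cancer = FALSE) {
  cohort <- assign_metastasis_labels(records, met_status_values)
  retain_longest_nonmet(cohort, fraction = fraction, per_cancer = per_cancer)
}

#' Write a labeled cohort and its exclusion report
#'
#' @param cohort A `labeled_cohort`.
#' @param path Output TSV for labeled entries (`case_id`, `cancer_type`,
#'   `label`, `pfi_time`).
#' @param report_path Optional TSV path for the exclusion report (`case_id`,
#'   `reason`).
#' @return `path`, invisibly.
#' @export
write_labeled_cohort <- function(cohort, path, report_path = NULL) {
  stopifnot(inherits(cohort, "labeled_cohort"))
  readr::write_tsv(cohort$entries, path, progress = FALSE)
  if (!is.null(report_path)) {
    readr::write_tsv(cohort$excluded, report_path, progress = FALSE)
  }
  invisible(path)
}
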