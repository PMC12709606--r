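TRUTH_CATEGORIES <- c("simple_cyst", "complicated_cyst", "solid_benign",
                      "solid_malignant", "mixed")
EXCLUSION_REASONS <- c("hyperechoic", "unknown_content", "incomplete_followup",
                       "no_screenshots", "superficial", "not_in_fov")
REFERENCE_STANDARDS <- c("bmode_features", "aspiration", "biopsy", "excision",
                         "followup")

as_cohort_table <- function(df, reader_scores = NULL) {
  stopifnot(is.data.frame(df))
  required <- c("mass_id", "patient_id", "truth_category", "reference_standard",
                "exclusion_reason", "depth_mm", "size_mm")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("cohort table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$mass_id)) stop("mass ids must be unique")
  bad <- !df$truth_category %in% TRUTH_CATEGORIES
  if (any(bad)) stop("unknown truth categories: ",
                     paste(unique(df$truth_category[bad]), collapse = ", "))
  bad_reason <- !is.na(df$exclusion_reason) &
    !df$exclusion_reason %in% EXCLUSION_REASONS
  if (any(bad_reason)) {
    stop("unknown exclusion reason(s): ",
         paste(unique(df$exclusion_reason[bad_reason]), collapse = ", "))
  }
  out <- df
  class(out) <- c("cohort_table", "data.frame")
  attr(out, "reader_scores") <- reader_scores
  out
}

#' Per-reader gCNR scores of a cohort
#'
#' @param cohort a cohort table.
#' @return long data frame with columns `mass_id`, `reader_id`,
#'   `gcnr_bmode`, `gcnr_slsc`, or `NULL` if the cohort carries no scores.
#' @export
reader_scores <- function(cohort) attr(cohort, "reader_scores")

subset_cohort <- function(cohort, keep) {
  scores <- reader_scores(cohort)
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(scores)) scores <- scores[scores$mass_id %in% out$mass_id, , drop = FALSE]
  as_cohort_table(as.data.frame(out), scores)
}

#' Eligibility filtering (study flowchart accounting)
#'
#' Removes every record that carries an exclusion reason (hyperechoic
#' content, unknown contents, incomplete follow-up, missing screenshots,
#' superficial location, or mass not fully inside the field of view) and
#' reports per-reason counts. Exclusion reasons are record attributes set
#' by the generator; this operation implements the accounting.
#'
#' @param cohort a cohort table.
#' @return the eligible cohort, with attribute `"filter_report"` (named
#'   count per reason plus `n_input` and `n_eligible`).
#' @export
apply_eligibility_filters <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  reason <- cohort$exclusion_reason
  bad <- !is.na(reason) & !reason %in% EXCLUSION_REASONS
  if (any(bad)) {
    stop("unknown exclusion reason(s): ", paste(unique(reason[bad]), collapse = ", "))
  }
  counts <- table(factor(reason[!is.na(reason)], levels = EXCLUSION_REASONS))
  out <- subset_cohort(cohort, is.na(reason))
  report <- c(as.list(counts),
              list(n_input = nrow(cohort), n_eligible = nrow(out)))
  attr(out, "filter_report") <- report
  out
}

#' Statistical-subgroup selection
#'
#' Keeps only the categories entering the diagnostic-accuracy analysis:
#' complicated cysts (the fluid positives) and benign/malignant solid
#' masses (the negatives). Mixed-content masses are excluded because they
#' contain both true-positive and true-negative material; simple cysts are
#' excluded because B-mode features alone classify them.
#'
#' @param eligible an eligibility-filtered cohort table.
#' @return the analysis subgroup, with attribute `"subgroup_counts"`.
#' @export
select_statistical_subgroup <- function(eligible) {
  stopifnot(inherits(eligible, "cohort_table"))
  if (any(!is.na(eligible$exclusion_reason))) {
    stop("input must already be eligibility-filtered")
  }
  keep_cats <- c("complicated_cyst", "solid_benign", "solid_malignant")
  out <- subset_cohort(eligible, eligible$truth_category %in% keep_cats)
  counts <- table(factor(out$truth_category, levels = keep_cats))
  attr(out, "subgroup_counts") <- c(
    as.list(counts),
    list(n_total = nrow(out),
         n_positive = sum(out$truth_category == "complicated_cyst"),
         n_negative = sum(out$truth_category %in% c("solid_benign", "solid_malignant")))
  )
  out
}

#' Binary truth labels for the analysis subgroup
#'
#' Complicated cysts are the fluid positives; solid masses (benign or
#' malignant) are the negatives.
#'
#' @param subgroup a [select_statistical_subgroup()] output.
#' @return named character vector (`"positive"` / `"negative"`), one entry
#'   per mass.
#' @export
binary_truth_labels <- function(subgroup) {
  stopifnot(inherits(subgroup, "cohort_table"))
  bad <- !subgroup$truth_category %in%
    c("complicated_cyst", "solid_benign", "solid_malignant")
  if (any(bad)) {
    stop("subgroup contains mixed or simple-cyst records; run select_statistical_subgroup first")
  }
  labels <- ifelse(subgroup$truth_category == "complicated_cyst",
                   "positive", "negative")
  stats::setNames(labels, subgroup$mass_id)
}
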