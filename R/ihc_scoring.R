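# Semi-quantitative immunohistochemistry scoring: H-score arithmetic,
# cut-off derivation (cohort-median vs expert policy) and dichotomisation.

#' Compute an H-score from intensity fractions
#'
#' The H-score summarises immunohistochemical staining of a tumour core as
#' \eqn{\sum_i i \times p_i} where \eqn{i \in \{0,1,2,3\}} is staining
#' intensity and \eqn{p_i} the percentage of cells staining at that
#' intensity; the score ranges from 0 (no staining) to 300 (all cells at
#' maximal intensity).
#'
#' @param intensity_fractions Named numeric vector mapping intensity
#'   (`"0"`, `"1"`, `"2"`, `"3"`) to the percentage of cells at that
#'   intensity. Intensities not mentioned are taken as 0 percent.
#' @param tolerance Absolute tolerance on the percentage sum; the
#'   percentages must sum to 100 within this tolerance (default 0.5,
#'   tolerating rounded percentages).
#'
#' @return A single H-score in \[0, 300\].
#' @export
#' @examples
#' compute_hscore(c("3" = 100))          # 300
#' compute_hscore(c("1" = 50, "2" = 25, "3" = 25))  # 175
compute_hscore <- function(intensity_fractions, tolerance = 0.5) {
  if (length(intensity_fractions) == 0 || is.null(names(intensity_fractions))) {
    abort("`intensity_fractions` must be a named vector with names in 0..3.")
  }
  nm <- names(intensity_fractions)
  if (!all(nm %in% as.character(0:3))) {
    abort(paste0("Unknown staining intensity: ",
                 paste(setdiff(nm, as.character(0:3)), collapse = ", "),
                 " (must be 0, 1, 2 or 3)."))
  }
  if (anyDuplicated(nm)) abort("Each intensity may appear at most once.")
  if (any(intensity_fractions < 0)) abort("Percentages must be non-negative.")
  total <- sum(intensity_fractions)
  if (abs(total - 100) > tolerance) {
    abort(sprintf("Percentages sum to %.3f; expected 100 (tolerance %.3g).",
                  total, tolerance))
  }
  sum(as.numeric(nm) * intensity_fractions)
}

#' Derive cohort-median cut-offs for a set of markers
#'
#' Computes the per-marker sample median of non-missing H-scores over a
#' cohort. Under the default NPI+ policy this is the cut-off rule for ER,
#' PgR, CK7/8, HER3, HER4 and MUC1; markers whose median is degenerate
#' (zero, or a constant column) are flagged because they call for an
#' expert-supplied value instead.
#'
#' @param cohort A cohort data frame with H-score columns (`er_h`, `pgr_h`,
#'   ... — see [read_cohort()] for the schema).
#' @param markers Character vector of panel marker names to derive
#'   (default: the six median-policy markers).
#'
#' @return A tibble with columns `marker`, `cutoff`, `policy`
#'   (`"cohort_median"`).
#' @export
compute_median_cutoffs <- function(cohort,
                                   markers = c("ER", "PgR", "CK7/8",
                                               "HER3", "HER4", "MUC1")) {
  cols <- marker_columns()
  bad <- setdiff(markers, names(cols))
  if (length(bad) > 0) {
    abort(paste0("Unknown marker(s): ", paste(bad, collapse = ", ")))
  }
  rows <- purrr::map(markers, function(m) {
    x <- cohort[[cols[[m]]]]
    x <- x[!is.na(x)]
    if (length(x) == 0) {
      abort(paste0("Marker ", m, " has no non-missing H-scores; ",
                   "cannot take a cohort median."))
    }
    med <- median(x)
    if (med == 0) {
      warn(paste0("Median H-score for ", m, " is 0; the cut-off policy ",
                  "calls for an expert value for such markers."))
    }
    if (length(unique(x)) == 1) {
      warn(paste0("All non-missing H-scores for ", m, " are identical (",
                  x[1], "); the median cut-off is degenerate."))
    }
    tibble(marker = m, cutoff = med, policy = "cohort_median")
  })
  bind_rows(rows)
}

#' Expert cut-offs shipped as package defaults
#'
#' CK5/6, EGFR, p53 and HER2 take expert cut-offs in the NPI+ scheme (their
#' cohort medians are typically zero). The numeric values shipped here are
#' package defaults chosen at plausible positivity thresholds — they are
#' not published values — and are intended to be edited for a given
#' laboratory. HER2 carries no H-score cut-off: its status is resolved from
#' the IHC category (and in-situ hybridisation) by [resolve_her2()], so its
#' `cutoff` is `NA`.
#'
#' @return A tibble with columns `marker`, `cutoff`, `policy` (`"expert"`).
#' @export
default_expert_cutoffs <- function() {
  tibble(
    marker = c("CK5/6", "EGFR", "p53", "HER2"),
    cutoff = c(10, 10, 20, NA_real_),
    policy = "expert"
  )
}

#' Assemble a complete cut-off table
#'
#' Combines median-policy cut-offs (derived from a training cohort, or
#' supplied directly) with expert cut-offs into the full ten-marker table
#' used by [dichotomize()] and [classify_cohort()]. Cut-offs are derived
#' once on a training series and then applied as fixed configuration to
#' validation series.
#'
#' @param cohort Optional training cohort from which median-policy cut-offs
#'   are derived via [compute_median_cutoffs()]. Ignored when `median_cutoffs`
#'   is given.
#' @param median_cutoffs Optional tibble (`marker`, `cutoff`, `policy`) for
#'   the median-policy markers.
#' @param expert_cutoffs Tibble of expert cut-offs
#'   (default [default_expert_cutoffs()]).
#'
#' @return A tibble of class `npi_cutoffs` covering all ten panel markers.
#' @export
npi_cutoffs <- function(cohort = NULL, median_cutoffs = NULL,
                        expert_cutoffs = default_expert_cutoffs()) {
  if (is.null(median_cutoffs)) {
    if (is.null(cohort)) {
      abort("Supply either a training `cohort` or `median_cutoffs`.")
    }
    median_cutoffs <- compute_median_cutoffs(cohort)
  }
  out <- bind_rows(median_cutoffs, expert_cutoffs) |>
    arrange(match(.data$marker, npi_markers()))
  validate_cutoffs(out)
  structure(out, class = c("npi_cutoffs", class(out)))
}

validate_cutoffs <- function(cutoffs) {
  missing_m <- setdiff(npi_markers(), cutoffs$marker)
  if (length(missing_m) > 0) {
    abort(paste0("Cut-off table is missing marker(s): ",
                 paste(missing_m, collapse = ", ")))
  }
  if (anyDuplicated(cutoffs$marker)) {
    abort("Cut-off table has duplicated markers.")
  }
  num <- cutoffs[cutoffs$marker != "HER2", ]
  if (any(is.na(num$cutoff)) ||
      any(num$cutoff < 0 | num$cutoff > 300)) {
    abort("Cut-offs must lie in [0, 300] (HER2 excepted: resolved categorically).")
  }
  if (!all(cutoffs$policy %in% c("cohort_median", "expert"))) {
    abort("Cut-off policy must be 'cohort_median' or 'expert'.")
  }
  invisible(cutoffs)
}

#' Cut-off table used by the default synthetic study conditions
#'
#' The fixed cut-off table applied to validation cohorts in this package's
#' worked examples: median-policy values stipulated as the synthetic
#' training-series medians (the valleys between the generator's low and
#' high expression modes), plus the default expert values. All values are
#' synthetic package defaults, not published cut-offs.
#'
#' @return A tibble of class `npi_cutoffs`.
#' @export
default_cutoffs <- function() {
  med <- tibble(
    marker = c("ER", "PgR", "CK7/8", "HER3", "HER4", "MUC1"),
    cutoff = c(100, 100, 150, 100, 100, 120),
    policy = "cohort_median"
  )
  npi_cutoffs(median_cutoffs = med)
}

#' Resolve HER2 status from IHC category (and in-situ hybridisation)
#'
#' HER2 scoring follows the ASCO/CAP IHC categories: `3+` is positive,
#' `0`/`1+` negative, and `2+` equivocal. Equivocal cases are either
#' excluded from analysis (`mode = "exclude_equivocal"`, mirroring a
#' validation series without reflex testing) or resolved by in-situ
#' hybridisation (`mode = "ish_resolve"`: positive iff amplified, excluded
#' when ISH was not done).
#'
#' @param her2_ihc Character vector of IHC categories in
#'   `{"0","1+","2+","3+"}`.
#' @param her2_ish Optional character vector in
#'   `{"amplified","not_amplified","not_done"}` (recycled `"not_done"` when
#'   `NULL`).
#' @param mode Equivocal-case policy; see Details.
#'
#' @return Character vector in `{"positive","negative","excluded"}`.
#' @export
#' @examples
#' resolve_her2(c("0", "1+", "2+", "3+"))
resolve_her2 <- function(her2_ihc, her2_ish = NULL,
                         mode = c("exclude_equivocal", "ish_resolve")) {
  mode <- match.arg(mode)
  if (is.null(her2_ish)) her2_ish <- rep("not_done", length(her2_ihc))
  her2_ish[is.na(her2_ish)] <- "not_done"
  if (any(is.na(her2_ihc)) ||
      !all(her2_ihc %in% c("0", "1+", "2+", "3+"))) {
    abort("HER2 IHC category must be one of 0, 1+, 2+, 3+ (not unknown).")
  }
  if (!all(her2_ish %in% c("amplified", "not_amplified", "not_done"))) {
    abort("HER2 ISH must be amplified, not_amplified or not_done.")
  }
  dplyr::case_when(
    her2_ihc == "3+" ~ "positive",
    her2_ihc %in% c("0", "1+") ~ "negative",
    mode == "exclude_equivocal" ~ "excluded",
    her2_ish == "amplified" ~ "positive",
    her2_ish == "not_amplified" ~ "negative",
    .default = "excluded"
  )
}

#' Dichotomise marker H-scores against a cut-off table
#'
#' Converts each H-score column of a cohort to `"low"`/`"high"` against the
#' marker's cut-off. A value exactly at the cut-off counts as `"high"` under
#' the default inclusive-positivity convention (`boundary = "ge"`); missing
#' H-scores propagate as `NA`.
#'
#' @param cohort Cohort data frame with H-score columns.
#' @param cutoffs An `npi_cutoffs` table.
#' @param boundary `"ge"` (value at the cut-off is high; default) or `"gt"`.
#'
#' @return A tibble with `patient_id` (if present) and one `low`/`high`
#'   column per non-HER2 panel marker, named as the H-score columns.
#' @export
dichotomize <- function(cohort, cutoffs, boundary = c("ge", "gt")) {
  boundary <- match.arg(boundary)
  validate_cutoffs(cutoffs)
  cols <- marker_columns()
  cut <- setNames(cutoffs$cutoff, cutoffs$marker)
  out <- purrr::imap(cols, function(col, m) {
    x <- cohort[[col]]
    hi <- if (boundary == "ge") x >= cut[[m]] else x > cut[[m]]
    if_else(hi, "high", "low")
  })
  names(out) <- unname(cols)
  res <- as_tibble(out)
  if ("patient_id" %in% names(cohort)) {
    res <- dplyr::bind_cols(tibble(patient_id = cohort$patient_id), res)
  }
  res
}
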