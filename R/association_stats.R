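# Contingency-table association machinery: Pearson chi-square and the
# classical (uncorrected) Cramer's V used to compare class and group
# distributions between cohorts and across clinicopathological variables.

as_contingency <- function(table) {
  m <- as.matrix(table)
  if (!is.numeric(m)) abort("Contingency table must be numeric counts.")
  if (any(is.na(m)) || any(m < 0) || any(m != round(m))) {
    abort("Cell counts must be non-negative integers.")
  }
  if (nrow(m) < 2 || ncol(m) < 2) {
    abort("A contingency table needs at least 2 rows and 2 columns.")
  }
  if (sum(m) < 1) abort("Total count must be at least 1.")
  m
}

drop_empty_lines <- function(m) {
  zr <- rowSums(m) == 0
  zc <- colSums(m) == 0
  if (any(zr) || any(zc)) {
    warn(sprintf("Dropping %d all-zero row(s) and %d all-zero column(s).",
                 sum(zr), sum(zc)))
    m <- m[!zr, !zc, drop = FALSE]
  }
  if (nrow(m) < 2 || ncol(m) < 2) {
    abort("Table is degenerate after dropping empty rows/columns.")
  }
  m
}

#' Pearson chi-square test of independence
#'
#' Plain Pearson chi-square with expected counts from the margins and
#' `(r-1)(c-1)` degrees of freedom. No continuity correction is applied
#' (including for 2x2 tables) so that Cramer's V is consistent across
#' table sizes. All-zero rows or columns are dropped with a warning;
#' expected counts below 5 trigger a warning but no automatic switch to an
#' exact test.
#'
#' @param table Matrix-like object of non-negative integer counts with at
#'   least 2 rows and 2 columns.
#'
#' @return A list with `chi2`, `dof`, `p`, `n`.
#' @export
chi_square <- function(table) {
  m <- drop_empty_lines(as_contingency(table))
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 5)) {
    warn(sprintf("%d cell(s) have expected count below 5; the chi-square approximation may be inaccurate.",
                 sum(expected < 5)))
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(chi2 = unname(ct$statistic), dof = unname(ct$parameter),
       p = ct$p.value, n = sum(m))
}

#' Cramer's V
#'
#' Classical association strength for an r x c contingency table:
#' \eqn{V = \sqrt{\chi^2 / (n \, (\min(r, c) - 1))}}, lying in \[0, 1\]
#' with 1 attained only under perfect association. No bias correction is
#' applied.
#'
#' @inheritParams chi_square
#' @return Cramer's V as a single number.
#' @export
#' @examples
#' cramers_v(rbind(c(10, 0), c(0, 10)))  # 1
cramers_v <- function(table) {
  m <- suppressWarnings(drop_empty_lines(as_contingency(table)))
  cs <- chi_square(m)
  sqrt(cs$chi2 / (cs$n * (min(dim(m)) - 1)))
}

#' Full association result for a table
#'
#' @inheritParams chi_square
#' @return An object of class `npi_assoc` with `chi2`, `dof`, `p`, `v`,
#'   `n` and the (cleaned) table. Has [tidy()] and [glance()] methods.
#' @export
association <- function(table) {
  m <- drop_empty_lines(as_contingency(table))
  cs <- suppressWarnings(chi_square(m))
  structure(c(cs, list(v = sqrt(cs$chi2 / (cs$n * (min(dim(m)) - 1))),
                       table = m)),
            class = "npi_assoc")
}

#' Compare two labelled count distributions
#'
#' Builds the 2 x k table of two cohorts' category counts (for instance
#' two series' biological-class distributions) and reports the chi-square
#' test and Cramer's V.
#'
#' @param dist_a,dist_b Named non-negative integer count vectors over the
#'   same label set.
#'
#' @return An `npi_assoc` (see [association()]).
#' @export
compare_distributions <- function(dist_a, dist_b) {
  if (is.null(names(dist_a)) || is.null(names(dist_b))) {
    abort("Both distributions must be named count vectors.")
  }
  only_a <- setdiff(names(dist_a), names(dist_b))
  only_b <- setdiff(names(dist_b), names(dist_a))
  if (length(only_a) > 0 || length(only_b) > 0) {
    abort(paste0(
      "Label sets differ.",
      if (length(only_a) > 0) paste0(" Only in first: ",
                                     paste(only_a, collapse = ", "), "."),
      if (length(only_b) > 0) paste0(" Only in second: ",
                                     paste(only_b, collapse = ", "), ".")))
  }
  m <- rbind(a = dist_a, b = dist_b[names(dist_a)])
  association(m)
}
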