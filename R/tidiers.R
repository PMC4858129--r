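# broom-style tidy()/glance() methods for the package's result objects.

#' @describeIn km_estimate Tidy the curve as a tibble.
#' @param x Object to tidy.
#' @param ... Unused.
#' @export
tidy.npi_km <- function(x, ...) x$curve

#' @describeIn km_estimate One-row summary (patients, events, last
#'   follow-up).
#' @export
glance.npi_km <- function(x, ...) {
  tibble(n = x$n, n_events = sum(x$curve$n_event),
         n_groups = length(unique(x$curve$group)), max_time = x$max_time)
}

#' @describeIn logrank_test Per-group observed/expected table.
#' @param x Object to tidy.
#' @param ... Unused.
#' @export
tidy.npi_logrank <- function(x, ...) x$groups

#' @describeIn logrank_test One-row test summary.
#' @export
glance.npi_logrank <- function(x, ...) {
  tibble(statistic = x$statistic, dof = x$dof, p.value = x$p, n = x$n)
}

#' @describeIn cox_fit Coefficient table (term, estimate, se, p).
#' @param x Object to tidy.
#' @param ... Unused.
#' @export
tidy.npi_cox <- function(x, ...) x$coefficients

#' @describeIn cox_fit One-row fit summary.
#' @export
glance.npi_cox <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events, loglik = x$loglik, iter = x$iter)
}

#' @describeIn association Table cells in long form with expected counts.
#' @param x Object to tidy.
#' @param ... Unused.
#' @export
tidy.npi_assoc <- function(x, ...) {
  m <- x$table
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  rn <- rownames(m) %||% as.character(seq_len(nrow(m)))
  cn <- colnames(m) %||% as.character(seq_len(ncol(m)))
  tibble(row = rep(rn, times = ncol(m)),
         col = rep(cn, each = nrow(m)),
         observed = as.vector(m), expected = as.vector(expected))
}

#' @describeIn association One-row summary (chi2, dof, p, Cramer's V, n).
#' @export
glance.npi_assoc <- function(x, ...) {
  tibble(statistic = x$chi2, dof = x$dof, p.value = x$p,
         cramers_v = x$v, n = x$n)
}

#' @describeIn derive_formula Rounded index terms with raw estimates.
#' @param x Object to tidy.
#' @param ... Unused.
#' @export
tidy.npi_formula_fit <- function(x, ...) x$terms

#' @describeIn derive_formula One-row derivation summary.
#' @export
glance.npi_formula_fit <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events,
         n_candidates = nrow(x$full), n_retained = length(x$retained),
         alpha = x$alpha)
}

#' @export
print.npi_rulebase <- function(x, ...) {
  cat("NPI+ fuzzy rule base:", length(x$rules), "rules; threshold",
      x$activation_threshold, "\n")
  for (r in x$rules) {
    cat(sprintf("  %-18s <- %s (w=%g)\n", r$consequent,
                paste0(names(r$antecedents), ":", r$antecedents,
                       collapse = ", "), r$weight))
  }
  invisible(x)
}

#' @export
print.npi_formula <- function(x, ...) {
  sg <- function(b) if (b < 0) " - " else " + "
  terms <- paste0(sprintf("(%.1f x %s)", abs(x$terms), names(x$terms)),
                  collapse = "")
  pieces <- sprintf("(%.1f x %s)", abs(x$terms), names(x$terms))
  signs <- c("", vapply(x$terms[-1], sg, character(1)))
  if (x$terms[1] < 0) pieces[1] <- paste0("-", pieces[1])
  cat(x$class, ":", paste0(signs, pieces, collapse = ""), "\n")
  if (length(x$cutpoints) > 0) {
    cat("  cutpoints:", paste(x$cutpoints, collapse = ", "),
        " groups:", paste(x$group_labels, collapse = ", "), "\n")
  }
  invisible(x)
}
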