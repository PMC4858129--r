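# Breast-cancer-specific survival machinery. Kaplan-Meier, log-rank and
# Cox partial-likelihood fitting stand on the survival package; this file
# supplies the encoding conventions, validation and tidy surfaces the
# pipeline relies on.

#' Encode breast-cancer-specific survival
#'
#' BCSS counts death from breast cancer as the event; deaths from other
#' causes and patients still alive are censored at last follow-up.
#'
#' @param data Tibble with a follow-up time column (years) and an event
#'   column coded `"bc_death"`, `"other_death"` or `"alive"`.
#' @param time_col,event_col Column names (defaults `"time"`, `"event"`).
#'
#' @return `data` with an appended integer `status` column (1 = breast
#'   cancer death, 0 = censored).
#' @export
#' @examples
#' bcss_encode(tibble::tibble(time = c(5, 12.3), event = c("bc_death", "alive")))
bcss_encode <- function(data, time_col = "time", event_col = "event") {
  data <- as_tibble(data)
  tm <- data[[time_col]]
  ev <- data[[event_col]]
  if (is.null(tm) || is.null(ev)) {
    abort(paste0("Columns `", time_col, "` and `", event_col, "` are required."))
  }
  if (any(is.na(tm)) || any(!is.finite(tm)) || any(tm <= 0)) {
    abort("Follow-up times must be positive and finite.")
  }
  if (!all(ev %in% c("bc_death", "other_death", "alive"))) {
    abort("Event must be one of bc_death, other_death, alive.")
  }
  mutate(data, status = as.integer(ev == "bc_death"))
}

#' Kaplan-Meier product-limit estimate
#'
#' @param data Tibble with `time` and `status` columns (see
#'   [bcss_encode()]), optionally a grouping column.
#' @param group Optional name of a grouping column; one curve per level.
#'
#' @return An object of class `npi_km` whose `curve` element is a tibble
#'   (`group`, `time`, `n_risk`, `n_event`, `n_censor`, `survival`);
#'   survival starts at 1 before the first event and is non-increasing
#'   within each group. [tidy()] returns the curve tibble.
#' @export
km_estimate <- function(data, group = NULL) {
  data <- as_tibble(data)
  if (nrow(data) == 0) abort("Need at least one record.")
  if (!all(c("time", "status") %in% names(data))) {
    abort("`data` needs `time` and `status` columns.")
  }
  if (is.null(group)) {
    fit <- survival::survfit(survival::Surv(time, status) ~ 1, data = data)
    grp <- rep("all", length(fit$time))
  } else {
    data$.grp <- as.character(data[[group]])
    fit <- survival::survfit(survival::Surv(time, status) ~ .grp, data = data)
    grp <- if (is.null(fit$strata)) {
      rep(unique(data$.grp), length(fit$time))
    } else {
      rep(sub("^\\.grp=", "", names(fit$strata)), fit$strata)
    }
  }
  curve <- tibble(group = grp, time = fit$time, n_risk = fit$n.risk,
                  n_event = fit$n.event, n_censor = fit$n.censor,
                  survival = fit$surv)
  structure(list(curve = curve, n = nrow(data), max_time = max(data$time)),
            class = "npi_km")
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' Right-continuous step evaluation: the survival probability just after
#' `t`, so evaluation at an event time returns the post-drop value; before
#' the first event it is 1. Times beyond the last follow-up return the
#' last estimate with an extrapolation warning.
#'
#' @param km An `npi_km` from [km_estimate()].
#' @param t Time(s) in years, non-negative.
#' @param group Curve to evaluate when the estimate is grouped.
#'
#' @return Numeric survival probabilities, one per `t`.
#' @export
survival_at <- function(km, t, group = NULL) {
  if (!inherits(km, "npi_km")) abort("`km` must come from km_estimate().")
  if (any(t < 0)) abort("Evaluation times must be non-negative.")
  curve <- km$curve
  if (!is.null(group)) {
    curve <- filter(curve, .data$group == !!group)
    if (nrow(curve) == 0) abort(paste0("No curve for group ", group))
  } else if (length(unique(curve$group)) > 1) {
    abort("The estimate is grouped; specify `group`.")
  }
  last_fu <- max(curve$time)
  if (any(t > last_fu)) {
    warn(sprintf("Evaluation beyond the last follow-up time (%.3g); returning the last estimate.",
                 last_fu))
  }
  vapply(t, function(tt) {
    idx <- which(curve$time <= tt)
    if (length(idx) == 0) 1 else curve$survival[max(idx)]
  }, numeric(1))
}

#' Log-rank test between survival groups
#'
#' Standard (unweighted) log-rank chi-square across two or more groups,
#' with degrees of freedom one less than the number of groups; the p-value
#' is the chi-square upper tail.
#'
#' @param data Tibble with `time`, `status` and a grouping column.
#' @param group Name of the grouping column.
#'
#' @return An object of class `npi_logrank` with `statistic`, `dof`, `p`,
#'   `n` and a per-group summary tibble. Has a [tidy()] method.
#' @export
logrank_test <- function(data, group) {
  data <- as_tibble(data)
  data$.grp <- as.character(data[[group]])
  lv <- unique(data$.grp)
  if (length(lv) < 2) abort("Need at least two non-empty groups.")
  if (sum(data$status) == 0) {
    abort("All records are censored; the log-rank statistic is undefined.")
  }
  sd <- survival::survdiff(survival::Surv(time, status) ~ .grp, data = data)
  dof <- length(sd$n) - 1L
  stat <- unname(sd$chisq)
  structure(list(statistic = stat, dof = dof,
                 p = pchisq(stat, dof, lower.tail = FALSE),
                 n = sum(sd$n),
                 groups = tibble(group = sub("^\\.grp=", "", names(sd$n)),
                                 n = as.integer(sd$n),
                                 observed = as.numeric(sd$obs),
                                 expected = as.numeric(sd$exp))),
            class = "npi_logrank")
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximiser for BCSS on a set of covariate columns,
#' with Efron handling of tied event times. Used by [derive_formula()] and
#' available directly.
#'
#' @param data Tibble with `time`, `status` and the covariate columns.
#' @param covariates Character vector of covariate column names.
#' @param min_events Minimum events required, defaulting to the number of
#'   covariates.
#'
#' @return An object of class `npi_cox`: `coefficients` (tibble `term`,
#'   `estimate`, `se`, `p`), `n`, `n_events`, `loglik`, `iter` and the
#'   underlying `coxph` fit. Has [tidy()] and [glance()] methods.
#' @export
cox_fit <- function(data, covariates, min_events = length(covariates)) {
  data <- as_tibble(data)
  absent <- setdiff(c("time", "status", covariates), names(data))
  if (length(absent) > 0) {
    abort(paste0("Missing column(s): ", paste(absent, collapse = ", ")))
  }
  for (v in covariates) {
    if (length(unique(data[[v]])) < 2) {
      abort(paste0("Covariate ", v, " is constant; drop it before fitting."))
    }
  }
  n_events <- sum(data$status)
  if (n_events < max(1, min_events)) {
    abort(sprintf("Only %d event(s) for %d covariate(s).",
                  n_events, length(covariates)))
  }
  fml <- stats::as.formula(paste("survival::Surv(time, status) ~",
                                 paste(sprintf("`%s`", covariates),
                                       collapse = " + ")))
  warnings_seen <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = "efron"),
    warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  if (anyNA(co[, "coef"]) || any(!is.finite(co[, "coef"])) ||
      any(grepl("converge|infinit|out of iterations", warnings_seen,
                ignore.case = TRUE))) {
    abort(paste0("Cox fit failed to converge after ", fit$iter,
                 " iterations (possible separation). Diagnostics: ",
                 paste(unique(warnings_seen), collapse = "; ")))
  }
  structure(list(
    coefficients = tibble(term = covariates,
                          estimate = unname(co[, "coef"]),
                          se = unname(co[, "se(coef)"]),
                          p = unname(co[, "Pr(>|z|)"])),
    n = fit$n, n_events = n_events, loglik = fit$loglik[2],
    iter = fit$iter, fit = fit), class = "npi_cox")
}

#' Bonferroni significance flags
#'
#' Flags test `i` as significant iff `p[i] < alpha / m` where `m` is the
#' number of tests; the family-wise level defaults to the conventional
#' 0.01 used when comparing many survival curves.
#'
#' @param pvalues Numeric p-values in \[0, 1\].
#' @param alpha Family-wise significance level (default 0.01).
#'
#' @return Logical vector of flags (empty input gives empty flags).
#' @export
bonferroni_adjust <- function(pvalues, alpha = 0.01) {
  if (length(pvalues) == 0) return(logical(0))
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  pvalues < alpha / length(pvalues)
}
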