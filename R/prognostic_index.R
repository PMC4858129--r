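# Class-specific prognostic index: bespoke weighted formulae of
# clinicopathological variables, prognostic-group assignment via fixed
# cutpoints, and the Cox-regression procedure that derives both.

index_variable_names <- function() {
  c("nodes_positive", "nodal_ratio", "size", "stage",
    "tubules", "pleomorphism", "mitosis")
}

#' Nodal ratio
#'
#' Number of positive lymph nodes divided by the total number of nodes
#' examined.
#'
#' @param nodes_positive Non-negative integer count(s).
#' @param nodes_total Positive integer count(s).
#' @return Numeric ratio(s) in \[0, 1\].
#' @export
#' @examples
#' nodal_ratio(2, 4)  # 0.5
nodal_ratio <- function(nodes_positive, nodes_total) {
  if (any(is.na(nodes_positive)) || any(is.na(nodes_total))) {
    abort("Nodal counts must not be missing.")
  }
  if (any(nodes_total < 1)) abort("`nodes_total` must be at least 1.")
  if (any(nodes_positive < 0)) abort("`nodes_positive` must be non-negative.")
  if (any(nodes_positive > nodes_total)) {
    abort("`nodes_positive` cannot exceed `nodes_total`.")
  }
  nodes_positive / nodes_total
}

#' Histological grade from its component scores
#'
#' Combines tubule formation, nuclear pleomorphism and mitotic count
#' scores (each 1-3) by the usual sum convention: 3-5 is grade 1, 6-7
#' grade 2, 8-9 grade 3.
#'
#' @param tubules,pleomorphism,mitosis Integer scores in 1-3.
#' @return Integer grade(s) in 1-3.
#' @export
npi_grade <- function(tubules, pleomorphism, mitosis) {
  for (x in list(tubules, pleomorphism, mitosis)) {
    if (any(!x %in% 1:3)) abort("Grade component scores must be 1, 2 or 3.")
  }
  s <- tubules + pleomorphism + mitosis
  if_else(s <= 5, 1L, if_else(s <= 7, 2L, 3L))
}

#' Construct a prognostic-index formula
#'
#' A weighted linear combination of clinicopathological variables for one
#' biological class, with ascending cutpoints splitting the index into
#' prognostic groups.
#'
#' @param class Biological class label (never `"Unclassified"`).
#' @param terms Named numeric vector of coefficients; names drawn from
#'   `nodes_positive`, `nodal_ratio`, `size`, `stage`, `tubules`,
#'   `pleomorphism`, `mitosis`.
#' @param cutpoints Strictly ascending numeric cutpoints (may be empty if
#'   groups are not yet configured).
#' @param group_labels Character labels, one more than there are
#'   cutpoints (e.g. `c("1.1", "1.2", "1.3")`).
#'
#' @return A list of class `npi_formula`.
#' @export
npi_formula <- function(class, terms, cutpoints = numeric(0),
                        group_labels = NULL) {
  if (!class %in% npi_classes()) {
    abort(paste0("Unknown biological class: ", class))
  }
  if (length(terms) == 0 || is.null(names(terms)) ||
      !all(names(terms) %in% index_variable_names())) {
    abort(paste0("Formula terms must be named coefficients over: ",
                 paste(index_variable_names(), collapse = ", ")))
  }
  if (length(cutpoints) > 0 && any(diff(cutpoints) <= 0)) {
    abort("Cutpoints must be strictly ascending.")
  }
  if (!is.null(group_labels) &&
      length(group_labels) != length(cutpoints) + 1) {
    abort("Need exactly one more group label than cutpoints.")
  }
  structure(list(class = class, terms = terms, cutpoints = cutpoints,
                 group_labels = group_labels),
            class = "npi_formula")
}

#' Default NPI+ index formulae
#'
#' The bespoke per-class formulae combining mitosis, tubule formation,
#' pleomorphism (1-3 scores), size category (1 if < 1.5 cm, 2 otherwise),
#' lymph-node stage (1-3) and the continuous nodal ratio. The HER2+/ER-
#' formula carries the panel's only negative coefficient (nodal ratio).
#' Group cutpoints are package defaults calibrated on the default
#' synthetic cohort so that within-class group proportions resemble the
#' development series; they are synthetic placeholders, not published
#' cutpoints, and [derive_cutpoints()] can replace them.
#'
#' @return Named list of [npi_formula()] objects, one per class.
#' @export
default_formulas <- function() {
  list(
    "Luminal A" = npi_formula(
      "Luminal A",
      c(mitosis = 0.8, size = 0.5, nodal_ratio = 1.8),
      cutpoints = c(2.15, 3.25),
      group_labels = c("1.1", "1.2", "1.3")),
    "Luminal N" = npi_formula(
      "Luminal N",
      c(tubules = 0.8, stage = 0.6),
      cutpoints = c(3.65),
      group_labels = c("2.1", "2.2")),
    "Luminal B" = npi_formula(
      "Luminal B",
      c(mitosis = 0.7, nodal_ratio = 1.0),
      cutpoints = c(1.45),
      group_labels = c("3.1", "3.2")),
    "Basal p53 altered" = npi_formula(
      "Basal p53 altered",
      c(nodal_ratio = 1.4, size = 0.4),
      cutpoints = c(1.28),
      group_labels = c("4.1", "4.2")),
    "Basal p53 normal" = npi_formula(
      "Basal p53 normal",
      c(stage = 0.6, pleomorphism = 1.8),
      cutpoints = c(6.05),
      group_labels = c("5.1", "5.2")),
    "HER2+/ER+" = npi_formula(
      "HER2+/ER+",
      c(size = 0.5, stage = 0.9),
      cutpoints = c(2.35),
      group_labels = c("6.1", "6.2")),
    "HER2+/ER-" = npi_formula(
      "HER2+/ER-",
      c(stage = 0.9, nodal_ratio = -0.6),
      cutpoints = c(2.45),
      group_labels = c("7.1", "7.2"))
  )
}

# Materialise the index variables a formula may reference from the cohort
# columns, deriving size category and nodal ratio where needed.
index_variables <- function(data, size_coding = c("binary", "continuous")) {
  size_coding <- match.arg(size_coding)
  out <- as_tibble(data)
  if (!"size_cat" %in% names(out) && "size_cm" %in% names(out)) {
    out$size_cat <- if_else(out$size_cm < 1.5, 1L, 2L)
  }
  if (!"size" %in% names(out)) {
    src <- if (size_coding == "binary") "size_cat" else "size_cm"
    if (src %in% names(out)) out$size <- out[[src]]
  }
  if (!"nodal_ratio" %in% names(out) &&
      all(c("nodes_positive", "nodes_total") %in% names(out))) {
    out$nodal_ratio <- nodal_ratio(out$nodes_positive, out$nodes_total)
  }
  out
}

#' Compute the class-specific prognostic index
#'
#' Evaluates each patient's biological class formula on the
#' clinicopathological variables: grade component scores as 1-3, size as
#' the binary category (1 if < 1.5 cm, 2 otherwise; switchable to
#' continuous centimetres), stage as 1-3 and nodal ratio as the exact
#' quotient.
#'
#' @param data Cohort tibble with a `class` column (no `"Unclassified"` or
#'   `"Excluded"` rows) and the clinicopathological columns each class's
#'   formula requires.
#' @param formulas Named list of [npi_formula()] objects
#'   (default [default_formulas()]).
#' @param size_coding `"binary"` (default) or `"continuous"`.
#'
#' @return `data` with an appended `npi_index` column.
#' @export
compute_index <- function(data, formulas = default_formulas(),
                          size_coding = c("binary", "continuous")) {
  data <- as_tibble(data)
  if (!"class" %in% names(data)) abort("`data` needs a `class` column.")
  if (any(data$class %in% c("Unclassified", "Excluded"))) {
    abort("Cannot compute an index for Unclassified or Excluded tumours.")
  }
  unknown <- setdiff(unique(data$class), names(formulas))
  if (length(unknown) > 0) {
    abort(paste0("No formula configured for class(es): ",
                 paste(unknown, collapse = ", ")))
  }
  vars <- index_variables(data, size_coding)
  idx <- rep(NA_real_, nrow(data))
  for (cl in unique(data$class)) {
    f <- formulas[[cl]]
    rows <- which(data$class == cl)
    need <- names(f$terms)
    absent <- setdiff(need, names(vars))
    if (length(absent) > 0) {
      abort(paste0("Class ", cl, " formula needs missing variable(s): ",
                   paste(absent, collapse = ", ")))
    }
    X <- as.matrix(vars[rows, need, drop = FALSE])
    if (anyNA(X)) {
      bad <- need[colSums(is.na(X)) > 0]
      abort(paste0("Missing values in variable(s) ",
                   paste(bad, collapse = ", "), " for class ", cl, "."))
    }
    idx[rows] <- drop(X %*% f$terms)
  }
  mutate(data, npi_index = idx)
}

assign_group_one <- function(index, formula) {
  if (length(formula$cutpoints) == 0 || is.null(formula$group_labels)) {
    abort(paste0("No cutpoints configured for class ", formula$class,
                 "; supply them or run derive_cutpoints()."))
  }
  # boundary at a cutpoint falls in the higher (worse) group
  k <- 1L + vapply(index, function(v) sum(v >= formula$cutpoints), integer(1))
  formula$group_labels[k]
}

#' Assign NPI+ prognostic groups
#'
#' Cuts each patient's index at the class's fixed cutpoints. A value
#' exactly at a cutpoint goes to the higher (worse) group — conservative
#' risk assignment.
#'
#' @param data Tibble with `class` and `npi_index` columns (from
#'   [compute_index()]).
#' @param formulas Named list of [npi_formula()] objects with cutpoints.
#'
#' @return `data` with an appended `prognostic_group` column (labels such
#'   as `"1.1"` ... `"7.2"`).
#' @export
assign_group <- function(data, formulas = default_formulas()) {
  data <- as_tibble(data)
  if (!all(c("class", "npi_index") %in% names(data))) {
    abort("`data` needs `class` and `npi_index` columns; run compute_index().")
  }
  grp <- rep(NA_character_, nrow(data))
  for (cl in unique(data$class)) {
    rows <- which(data$class == cl)
    grp[rows] <- assign_group_one(data$npi_index[rows], formulas[[cl]])
  }
  mutate(data, prognostic_group = grp)
}

#' Derive an index formula from survival data by Cox regression
#'
#' Implements the formula-derivation procedure: fit a proportional-hazards
#' model of breast-cancer-specific survival on the candidate
#' clinicopathological variables within one biological class, retain the
#' variables significant at `alpha` (per-variable Wald test), refit on the
#' retained set, and round the coefficients to one decimal to form the
#' index terms.
#'
#' @param data Class subset with `time` and `status` columns (see
#'   [bcss_encode()]) and the clinicopathological columns.
#' @param candidates Candidate variable names (default: all seven index
#'   variables).
#' @param alpha Wald significance level for retention (default 0.05).
#' @param min_events Minimum number of events required (default 10).
#' @param size_coding Passed to the variable builder.
#'
#' @return An object of class `npi_formula_fit` with elements `terms`
#'   (tibble: variable, coefficient rounded to 1 dp, raw estimate, se, p),
#'   `full` (the all-candidates fit), `retained`, `n`, `n_events`. Has
#'   [tidy()] and [glance()] methods; `as_formula()` converts it to an
#'   [npi_formula()].
#' @export
derive_formula <- function(data, candidates = index_variable_names(),
                           alpha = 0.05, min_events = 10,
                           size_coding = c("binary", "continuous")) {
  data <- as_tibble(data)
  bad <- setdiff(candidates, index_variable_names())
  if (length(bad) > 0) {
    abort(paste0("Unknown candidate variable(s): ", paste(bad, collapse = ", ")))
  }
  vars <- index_variables(data, size_coding)
  absent <- setdiff(candidates, names(vars))
  if (length(absent) > 0) {
    abort(paste0("Cohort lacks candidate variable(s): ",
                 paste(absent, collapse = ", ")))
  }
  n_events <- sum(vars$status)
  if (n_events == 0) abort("No events in the subset; cannot fit.")
  if (n_events < min_events) {
    abort(sprintf("Only %d events; need at least %d.", n_events, min_events))
  }
  full <- cox_fit(vars, candidates)
  keep <- full$coefficients$term[full$coefficients$p < alpha]
  if (length(keep) == 0) {
    abort(paste0("No candidate variable is significant at alpha = ", alpha, "."))
  }
  refit <- cox_fit(vars, keep)
  terms <- refit$coefficients |>
    mutate(coefficient = round(.data$estimate, 1)) |>
    select(variable = "term", "coefficient", raw_coefficient = "estimate",
           "se", "p")
  structure(list(terms = terms, full = full$coefficients, retained = keep,
                 n = nrow(vars), n_events = n_events, alpha = alpha),
            class = "npi_formula_fit")
}

#' Convert a derived fit to an index formula
#'
#' @param fit An `npi_formula_fit` from [derive_formula()].
#' @param class Biological class label for the formula.
#' @param cutpoints,group_labels Passed to [npi_formula()].
#' @return An [npi_formula()].
#' @export
as_formula <- function(fit, class, cutpoints = numeric(0),
                       group_labels = NULL) {
  if (!inherits(fit, "npi_formula_fit")) {
    abort("`fit` must come from derive_formula().")
  }
  npi_formula(class, setNames(fit$terms$coefficient, fit$terms$variable),
              cutpoints, group_labels)
}

#' Derive prognostic-group cutpoints by log-rank grid search
#'
#' Searches candidate cutpoints (quantiles of the index distribution) for
#' the set of `n_groups - 1` cutpoints maximising the log-rank chi-square
#' between the resulting groups, subject to every group holding at least
#' `min_frac` of the patients. Exact ties (e.g. homogeneous survival,
#' where every admissible split scores alike) are broken deterministically
#' by taking the median candidate set.
#'
#' @param index Numeric index values.
#' @param time,status Survival columns encoded as by [bcss_encode()].
#' @param n_groups Number of prognostic groups (>= 2, default 2).
#' @param min_frac Minimum fraction of patients per group (default 0.1).
#' @param probs Quantile grid for candidate cutpoints.
#'
#' @return Strictly ascending numeric cutpoints of length `n_groups - 1`.
#' @export
derive_cutpoints <- function(index, time, status, n_groups = 2,
                             min_frac = 0.1,
                             probs = seq(0.1, 0.9, by = 0.05)) {
  if (n_groups < 2) abort("`n_groups` must be at least 2.")
  if (length(unique(index)) < n_groups) {
    abort("Fewer distinct index values than groups.")
  }
  if (sum(status) == 0) abort("No events; the log-rank objective is undefined.")
  cand <- sort(unique(as.numeric(quantile(index, probs, type = 7))))
  sets <- utils::combn(cand, n_groups - 1, simplify = FALSE)
  n <- length(index)
  score_one <- function(cuts) {
    grp <- 1L + vapply(index, function(v) sum(v >= cuts), integer(1))
    tab <- tabulate(grp, nbins = n_groups)
    if (any(tab < min_frac * n)) return(NA_real_)
    if (length(unique(grp)) < 2) return(NA_real_)
    ev <- tapply(status, grp, sum)
    if (sum(ev > 0) == 0) return(NA_real_)
    # identical curves in every group make the statistic degenerate
    # (0/0 or a singular variance); score such splits as no separation so
    # the deterministic tie rule applies
    sd <- tryCatch(survival::survdiff(survival::Surv(time, status) ~ grp),
                   error = function(e) NULL)
    if (is.null(sd)) return(0)
    chi <- unname(sd$chisq)
    if (!is.finite(chi)) 0 else chi
  }
  scores <- purrr::map_dbl(sets, score_one)
  if (all(is.na(scores))) {
    abort("No admissible cutpoint set under the minimum group size.")
  }
  best <- max(scores, na.rm = TRUE)
  winners <- which(!is.na(scores) & abs(scores - best) < 1e-12)
  pick <- winners[ceiling(length(winners) / 2)]
  sets[[pick]]
}
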