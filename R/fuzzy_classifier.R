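# Fuzzy rule-based assignment of the seven biological classes.
#
# Mamdani-style semantics: trapezoidal-shoulder memberships around each
# marker's cut-off, min-conjunction within a rule, max-disjunction across
# rules sharing a consequent class.

#' Fuzzy low/high membership of an H-score around a cut-off
#'
#' Piecewise-linear shoulder membership: `mu_high` is 0 at or below
#' `cutoff - width`, 1 at or above `cutoff + width`, linear in between;
#' `mu_low = 1 - mu_high`. At the cut-off itself both memberships are 0.5.
#'
#' @param value Numeric vector of H-scores.
#' @param cutoff Cut-off (H-score units).
#' @param width Half-width of the fuzzy transition band (H-score units,
#'   must be positive).
#'
#' @return A tibble with columns `mu_low`, `mu_high`, one row per value.
#' @export
#' @examples
#' membership(c(80, 100, 120), cutoff = 100, width = 20)
membership <- function(value, cutoff, width) {
  if (!is.numeric(width) || length(width) != 1 || is.na(width) || width <= 0) {
    abort("`width` must be a single positive number.")
  }
  mu_high <- pmin(1, pmax(0, (value - (cutoff - width)) / (2 * width)))
  tibble(mu_low = 1 - mu_high, mu_high = mu_high)
}

#' Construct a fuzzy rule
#'
#' @param consequent A biological class label (never `"Unclassified"`).
#' @param antecedents Named character vector mapping markers to the side
#'   they must lie on, e.g. `c("ER" = "high", "HER2" = "low")`. For HER2
#'   the sides mean resolved-positive / resolved-negative.
#' @param weight Non-negative rule weight (default 1).
#'
#' @return A list of class `npi_rule`.
#' @export
fuzzy_rule <- function(consequent, antecedents, weight = 1) {
  if (!consequent %in% npi_classes()) {
    abort(paste0("Rule consequent must be one of the seven classes, got: ",
                 consequent))
  }
  if (length(antecedents) == 0 || is.null(names(antecedents))) {
    abort("A rule needs at least one named antecedent.")
  }
  if (anyDuplicated(names(antecedents))) {
    abort("Each marker may appear at most once per rule.")
  }
  if (!all(names(antecedents) %in% npi_markers())) {
    abort(paste0("Unknown antecedent marker(s): ",
                 paste(setdiff(names(antecedents), npi_markers()),
                       collapse = ", ")))
  }
  if (!all(antecedents %in% c("low", "high"))) {
    abort("Antecedent sides must be 'low' or 'high'.")
  }
  if (!is.numeric(weight) || length(weight) != 1 || weight < 0) {
    abort("`weight` must be a single non-negative number.")
  }
  structure(list(consequent = consequent,
                 antecedents = antecedents,
                 weight = weight),
            class = "npi_rule")
}

#' Construct a rule base
#'
#' @param rules List of [fuzzy_rule()] objects; every one of the seven
#'   classes must be the consequent of at least one rule.
#' @param activation_threshold Minimum winning activation below which a
#'   tumour is left `"Unclassified"` (in \[0, 1\], default 0.5).
#' @param membership_width Fuzzy transition half-width in H-score units:
#'   either a single number applied to all markers or a named per-marker
#'   vector (default 20).
#'
#' @return A list of class `npi_rulebase`.
#' @export
rulebase <- function(rules, activation_threshold = 0.5, membership_width = 20) {
  if (length(rules) == 0) abort("Rule base must contain at least one rule.")
  if (!all(purrr::map_lgl(rules, inherits, "npi_rule"))) {
    abort("All rules must be created with fuzzy_rule().")
  }
  consequents <- purrr::map_chr(rules, "consequent")
  uncovered <- setdiff(npi_classes(), consequents)
  if (length(uncovered) > 0) {
    abort(paste0("Class(es) without any rule: ",
                 paste(uncovered, collapse = ", ")))
  }
  if (activation_threshold < 0 || activation_threshold > 1) {
    abort("`activation_threshold` must lie in [0, 1].")
  }
  if (any(membership_width <= 0)) abort("`membership_width` must be positive.")
  structure(list(rules = rules,
                 activation_threshold = activation_threshold,
                 membership_width = membership_width),
            class = "npi_rulebase")
}

#' Default NPI+ rule base
#'
#' An editable approximation of the biomarker logic behind the seven
#' classes (the originally induced rules are not published): luminal
#' classes require CK7/8 high, ER high and HER2 negative, split by the
#' PgR/HER3/HER4 pattern (A: PgR high; N: PgR, HER3 and HER4 low; B: PgR
#' low with HER3 or HER4 high); basal classes require CK5/6 or EGFR high
#' with ER low and HER2 negative, split by p53 (altered: high); HER2+
#' classes require resolved HER2 positivity, split by ER.
#'
#' @inheritParams rulebase
#' @return An `npi_rulebase`.
#' @export
default_rulebase <- function(activation_threshold = 0.5, membership_width = 20) {
  lum <- c("CK7/8" = "high", "ER" = "high", "HER2" = "low")
  rules <- list(
    fuzzy_rule("Luminal A", c(lum, "PgR" = "high")),
    fuzzy_rule("Luminal N", c(lum, "PgR" = "low", "HER3" = "low", "HER4" = "low")),
    fuzzy_rule("Luminal B", c(lum, "PgR" = "low", "HER3" = "high")),
    fuzzy_rule("Luminal B", c(lum, "PgR" = "low", "HER4" = "high")),
    fuzzy_rule("Basal p53 altered",
               c("CK5/6" = "high", "ER" = "low", "HER2" = "low", "p53" = "high")),
    fuzzy_rule("Basal p53 altered",
               c("EGFR" = "high", "ER" = "low", "HER2" = "low", "p53" = "high")),
    fuzzy_rule("Basal p53 normal",
               c("CK5/6" = "high", "ER" = "low", "HER2" = "low", "p53" = "low")),
    fuzzy_rule("Basal p53 normal",
               c("EGFR" = "high", "ER" = "low", "HER2" = "low", "p53" = "low")),
    fuzzy_rule("HER2+/ER+", c("HER2" = "high", "ER" = "high")),
    fuzzy_rule("HER2+/ER-", c("HER2" = "high", "ER" = "low"))
  )
  rulebase(rules, activation_threshold, membership_width)
}

marker_width <- function(rb, marker) {
  w <- rb$membership_width
  if (length(w) == 1 && is.null(names(w))) return(unname(w))
  if (!marker %in% names(w)) {
    abort(paste0("No membership width configured for marker ", marker))
  }
  unname(w[[marker]])
}

# Memberships for one profile: named H-score vector plus resolved HER2
# status. HER2 membership is crisp (status is categorical, not an H-score).
profile_memberships <- function(hscores, her2_status, cutoffs, rb) {
  cut <- setNames(cutoffs$cutoff, cutoffs$marker)
  ms <- purrr::map(setdiff(npi_markers(), "HER2"), function(m) {
    v <- hscores[[m]] %||% NA_real_
    if (is.na(v)) return(c(mu_low = NA_real_, mu_high = NA_real_))
    mu <- membership(v, cut[[m]], marker_width(rb, m))
    c(mu_low = mu$mu_low, mu_high = mu$mu_high)
  })
  names(ms) <- setdiff(npi_markers(), "HER2")
  ms$HER2 <- switch(her2_status,
                    positive = c(mu_low = 0, mu_high = 1),
                    negative = c(mu_low = 1, mu_high = 0),
                    c(mu_low = NA_real_, mu_high = NA_real_))
  ms
}

#' Activation of a single fuzzy rule
#'
#' Min-conjunction over the rule's antecedents of the matching membership
#' side, scaled by the rule weight. A profile missing any marker the rule
#' requires contributes zero activation (conservative missing-marker
#' policy: missing evidence never supports a class).
#'
#' @param memberships Named list mapping each marker to
#'   `c(mu_low = , mu_high = )`, as built internally by [classify()].
#' @param rule An [fuzzy_rule()].
#'
#' @return Activation in \[0, weight\].
#' @export
rule_activation <- function(memberships, rule) {
  mus <- purrr::map2_dbl(names(rule$antecedents), rule$antecedents,
                         function(m, side) {
    mu <- memberships[[m]]
    if (is.null(mu)) return(NA_real_)
    unname(mu[[paste0("mu_", side)]])
  })
  if (any(is.na(mus))) return(0)
  rule$weight * min(mus)
}

#' Classify one tumour profile
#'
#' Scores every class as the maximum activation over its rules and returns
#' the argmax class with that score as the confidence. When the best score
#' falls below the rule base's activation threshold the tumour is
#' `"Unclassified"` (confidence = the best score). Exact ties between
#' classes are broken deterministically by the fixed class order of
#' [npi_classes()], with a warning.
#'
#' @param hscores Named numeric vector of H-scores (panel marker names;
#'   missing markers may be absent or `NA`).
#' @param her2_status `"positive"`, `"negative"` or `"excluded"`/`NA` (from
#'   [resolve_her2()]).
#' @param cutoffs An `npi_cutoffs` table.
#' @param rb An `npi_rulebase` (default [default_rulebase()]).
#'
#' @return A one-row tibble with columns `class`, `confidence`.
#' @export
classify <- function(hscores, her2_status, cutoffs, rb = default_rulebase()) {
  if (!inherits(rb, "npi_rulebase")) abort("`rb` must be an npi_rulebase.")
  validate_cutoffs(cutoffs)
  ms <- profile_memberships(hscores, her2_status, cutoffs, rb)
  act <- purrr::map_dbl(rb$rules, rule_activation, memberships = ms)
  cls_scores <- vapply(npi_classes(), function(cl) {
    idx <- purrr::map_chr(rb$rules, "consequent") == cl
    if (!any(idx)) 0 else max(act[idx])
  }, numeric(1))
  best <- max(cls_scores)
  if (best < rb$activation_threshold) {
    return(tibble(class = "Unclassified", confidence = best))
  }
  winners <- which(cls_scores == best)
  if (length(winners) > 1) {
    warn(paste0("Activation tie between classes ",
                paste(npi_classes()[winners], collapse = ", "),
                "; resolved by fixed class order."))
  }
  tibble(class = npi_classes()[winners[1]], confidence = best)
}

#' Classify a whole cohort
#'
#' Resolves HER2 status per patient, classifies every non-excluded tumour
#' and returns the cohort with `her2_status`, `class` and `confidence`
#' columns appended. Patients excluded for equivocal HER2 carry
#' `class = "Excluded"` so they are surfaced, never silently dropped.
#'
#' @param cohort Cohort data frame with H-score columns and `her2_ihc`
#'   (optionally `her2_ish`).
#' @param cutoffs An `npi_cutoffs` table.
#' @param rb An `npi_rulebase`.
#' @param her2_mode Equivocal-case policy passed to [resolve_her2()].
#'
#' @return The cohort tibble with appended columns, of class
#'   `npi_classification`. Use [class_distribution()] for the tabulated
#'   distribution.
#' @export
classify_cohort <- function(cohort, cutoffs, rb = default_rulebase(),
                            her2_mode = c("exclude_equivocal", "ish_resolve")) {
  her2_mode <- match.arg(her2_mode)
  cols <- marker_columns()
  n <- nrow(cohort)
  if (n == 0) {
    out <- mutate(as_tibble(cohort), her2_status = character(0),
                  class = character(0), confidence = numeric(0))
    return(structure(out, class = c("npi_classification", class(out))))
  }
  status <- resolve_her2(cohort$her2_ihc,
                         if ("her2_ish" %in% names(cohort)) cohort$her2_ish,
                         mode = her2_mode)
  res <- purrr::map(seq_len(n), function(i) {
    if (status[i] == "excluded") {
      return(tibble(class = "Excluded", confidence = NA_real_))
    }
    hs <- purrr::map_dbl(cols, function(cn) {
      v <- cohort[[cn]][i]
      if (is.null(v)) NA_real_ else v
    })
    names(hs) <- names(cols)
    classify(hs, status[i], cutoffs, rb)
  }) |> bind_rows()
  out <- as_tibble(cohort) |>
    mutate(her2_status = status, class = res$class, confidence = res$confidence)
  structure(out, class = c("npi_classification", class(out)))
}

#' Tabulate a classified cohort's class distribution
#'
#' @param classified An `npi_classification` (from [classify_cohort()]).
#' @return A tibble `class`, `n`, `fraction` over the seven classes plus
#'   `"Unclassified"` and `"Excluded"` (zero-count levels retained), in the
#'   fixed class order. Fractions are of the full input cohort, so they sum
#'   to 1 and counts reconcile with the input size.
#' @export
class_distribution <- function(classified) {
  lv <- c(npi_classes(include_unclassified = TRUE), "Excluded")
  cnt <- table(factor(classified$class, levels = lv))
  tibble(class = lv, n = as.integer(cnt),
         fraction = as.integer(cnt) / max(1L, nrow(classified)))
}
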