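# Reproducible synthetic cohorts with the statistical structure the
# pipeline assumes: class-conditional bimodal H-score mixtures around the
# configured cut-offs, class-conditional clinicopathology, and
# exponential breast-cancer-specific survival driven by each class's
# index formula, with other-cause death and administrative follow-up
# encoded as censoring.

default_marker_params <- function() {
  cls <- npi_classes(include_unclassified = TRUE)
  # mean/sd per (class, marker) on the H-score scale; rows are classes in
  # the order of npi_classes(TRUE)
  p <- list(
    #        LumA    LumN    LumB    BasA    BasN    H+E+    H+E-    Unc
    ER    = list(c(210, 45), c(210, 45), c(210, 45), c(15, 15), c(15, 15),
                 c(200, 45), c(15, 15), c(100, 60)),
    PgR   = list(c(200, 45), c(25, 20), c(25, 20), c(20, 20), c(20, 20),
                 c(80, 60), c(15, 15), c(100, 60)),
    "CK5/6" = list(c(2, 4), c(2, 4), c(2, 4), c(120, 50), c(120, 50),
                   c(3, 5), c(5, 8), c(3, 5)),
    "CK7/8" = list(c(250, 30), c(250, 30), c(250, 30), c(190, 50), c(190, 50),
                   c(230, 40), c(230, 40), c(120, 40)),
    EGFR  = list(c(3, 5), c(3, 5), c(3, 5), c(90, 50), c(90, 50),
                 c(5, 8), c(8, 12), c(3, 5)),
    HER3  = list(c(40, 30), c(35, 25), c(180, 45), c(40, 30), c(40, 30),
                 c(50, 35), c(50, 35), c(100, 60)),
    HER4  = list(c(40, 30), c(35, 25), c(170, 50), c(40, 30), c(40, 30),
                 c(50, 35), c(50, 35), c(100, 60)),
    p53   = list(c(12, 12), c(12, 12), c(12, 12), c(150, 55), c(5, 6),
                 c(15, 15), c(15, 15), c(20, 20)),
    MUC1  = list(c(200, 50), c(200, 50), c(200, 50), c(90, 50), c(90, 50),
                 c(160, 60), c(160, 60), c(120, 60))
  )
  purrr::imap(p, function(rows, marker) {
    tibble(class = cls, marker = marker,
           mean = purrr::map_dbl(rows, 1), sd = purrr::map_dbl(rows, 2))
  }) |> bind_rows()
}

default_clinpath_params <- function() {
  tibble(
    class = npi_classes(include_unclassified = TRUE),
    # categorical probabilities for the grade components (scores 1..3)
    tubules = list(c(.10, .40, .50), c(.08, .35, .57), c(.08, .32, .60),
                   c(.02, .13, .85), c(.03, .22, .75), c(.04, .25, .71),
                   c(.03, .20, .77), c(.06, .30, .64)),
    pleomorphism = list(c(.05, .55, .40), c(.03, .50, .47), c(.02, .50, .48),
                        c(.01, .14, .85), c(.01, .30, .69), c(.01, .30, .69),
                        c(.01, .35, .64), c(.02, .40, .58)),
    mitosis = list(c(.70, .20, .10), c(.60, .25, .15), c(.50, .25, .25),
                   c(.10, .20, .70), c(.20, .25, .55), c(.20, .25, .55),
                   c(.15, .25, .60), c(.40, .30, .30)),
    # log-mean of tumour size in cm (common log-sd 0.45)
    size_meanlog = c(.53, .53, .58, .79, .65, .70, .72, .60),
    # probability of any nodal involvement
    p_node_involved = c(.30, .30, .30, .27, .29, .53, .44, .30)
  )
}

default_hazard_params <- function() {
  tibble(
    class = npi_classes(include_unclassified = TRUE),
    baseline = c(1.6e-3, 7.8e-4, 3.4e-3, 1.03e-2, 8.3e-5, 4.8e-3,
                 1.26e-2, 1.5e-2)
  )
}

#' Synthetic-cohort generator configuration
#'
#' Default study conditions: 1073 patients with class proportions matching
#' the development-series distribution, bimodal class-conditional H-score
#' mixtures straddling the default cut-offs, clinicopathology whose
#' grade/size/stage margins resemble a development-series cohort, and
#' exponential BCSS with each class's hazard scaled by
#' `exp(index formula)` so higher-index patients die sooner and the HER2+
#' classes fare worst.
#'
#' @param n_patients Cohort size (default 1073).
#' @param seed Integer seed; `generate()` is deterministic given it.
#' @param class_proportions Named fractions over the seven classes plus
#'   `"Unclassified"`, summing to 1.
#' @param marker_params Tibble `class`, `marker`, `mean`, `sd` of the
#'   truncated-normal H-score draws (truncated to \[0, 300\]).
#' @param clinpath_params Tibble of per-class categorical probabilities for
#'   the grade components, log-size mean, and nodal-involvement
#'   probability.
#' @param hazard_params Tibble `class`, `baseline` exponential BCSS rates
#'   (per year).
#' @param other_cause_rate Exponential rate of death from other causes.
#' @param accrual_years,followup_years Uniform accrual window and
#'   administrative close-out: a patient's administrative censoring time is
#'   `followup_years - U(0, accrual_years)`.
#' @param equivocal_fraction Probability a tumour is scored HER2 IHC 2+
#'   (its ISH result then reflects the true class).
#' @param formulas Index formulae used for the survival linear predictor
#'   and the true prognostic group.
#' @param cutoffs Nominal cut-off table the H-score mixtures straddle.
#'
#' @return A list of class `npi_generator_config`.
#' @export
generator_config <- function(n_patients = 1073,
                             seed = 1L,
                             class_proportions = NULL,
                             marker_params = default_marker_params(),
                             clinpath_params = default_clinpath_params(),
                             hazard_params = default_hazard_params(),
                             other_cause_rate = 0.012,
                             accrual_years = 12,
                             followup_years = 25,
                             equivocal_fraction = 0.07,
                             formulas = default_formulas(),
                             cutoffs = default_cutoffs()) {
  if (is.null(class_proportions)) {
    # development-series distribution: 288/205/186/113/96/62/85/38 of 1073
    class_proportions <- setNames(
      c(288, 205, 186, 113, 96, 62, 85, 38) / 1073,
      npi_classes(include_unclassified = TRUE))
  }
  cfg <- structure(list(
    n_patients = n_patients, seed = seed,
    class_proportions = class_proportions, marker_params = marker_params,
    clinpath_params = clinpath_params, hazard_params = hazard_params,
    other_cause_rate = other_cause_rate, accrual_years = accrual_years,
    followup_years = followup_years,
    equivocal_fraction = equivocal_fraction,
    formulas = formulas, cutoffs = cutoffs), class = "npi_generator_config")
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  problems <- character(0)
  if (!is.numeric(cfg$n_patients) || cfg$n_patients < 1) {
    problems <- c(problems, "n_patients must be a positive count")
  }
  lv <- npi_classes(include_unclassified = TRUE)
  if (!setequal(names(cfg$class_proportions), lv)) {
    problems <- c(problems,
                  "class_proportions must be named over the eight class labels")
  } else if (abs(sum(cfg$class_proportions) - 1) > 1e-9 ||
             any(cfg$class_proportions < 0)) {
    problems <- c(problems, "class_proportions must be non-negative and sum to 1")
  }
  if (any(cfg$marker_params$sd <= 0)) {
    problems <- c(problems, "marker_params sd values must be positive")
  }
  if (any(cfg$hazard_params$baseline <= 0) || cfg$other_cause_rate <= 0) {
    problems <- c(problems, "all hazard rates must be positive")
  }
  if (cfg$followup_years <= 0 || cfg$accrual_years < 0 ||
      cfg$followup_years <= cfg$accrual_years) {
    problems <- c(problems,
                  "followup_years must be positive and exceed accrual_years")
  }
  if (cfg$equivocal_fraction < 0 || cfg$equivocal_fraction > 1) {
    problems <- c(problems, "equivocal_fraction must lie in [0, 1]")
  }
  if (length(problems) > 0) {
    abort(paste0("Invalid generator config: ",
                 paste(problems, collapse = "; "), "."))
  }
  invisible(cfg)
}

# Inverse-CDF truncated normal on [lo, hi]; deterministic given the RNG
# stream.
rtruncnorm_inv <- function(n, mean, sd, lo = 0, hi = 300) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

sample_score <- function(n, probs) sample.int(3L, n, replace = TRUE, prob = probs)

#' Generate a synthetic cohort
#'
#' Draws a cohort under the configured study conditions. Observable
#' columns follow the cohort CSV schema (marker H-scores, HER2 IHC/ISH,
#' clinicopathology, follow-up time and event type); hidden truth columns
#' (`true_class`, `true_index`, `true_group`, `true_lp`) let downstream
#' tests score recovery. Deterministic given `config$seed`.
#'
#' @param config An [generator_config()].
#' @return A tibble of class `npi_cohort` with the configuration attached
#'   as the `"config"` attribute.
#' @export
generate <- function(config = generator_config()) {
  validate_generator_config(config)
  set.seed(config$seed)
  n <- as.integer(config$n_patients)
  lv <- npi_classes(include_unclassified = TRUE)
  true_class <- sample(lv, n, replace = TRUE,
                       prob = config$class_proportions[lv])

  cohort <- tibble(patient_id = sprintf("P%05d", seq_len(n)),
                   true_class = true_class)

  # --- markers -----------------------------------------------------------
  mp <- config$marker_params
  cols <- marker_columns()
  for (m in names(cols)) {
    par <- mp[mp$marker == m, ]
    mean_i <- par$mean[match(true_class, par$class)]
    sd_i <- par$sd[match(true_class, par$class)]
    cohort[[cols[[m]]]] <- round(rtruncnorm_inv(n, mean_i, sd_i), 1)
  }

  is_her2 <- true_class %in% c("HER2+/ER+", "HER2+/ER-")
  equivocal <- stats::runif(n) < config$equivocal_fraction
  cohort$her2_ihc <- dplyr::case_when(
    equivocal ~ "2+",
    is_her2 ~ "3+",
    stats::runif(n) < 0.5 ~ "0",
    .default = "1+")
  cohort$her2_ish <- if_else(equivocal,
                             if_else(is_her2, "amplified", "not_amplified"),
                             "not_done")

  # --- clinicopathology --------------------------------------------------
  cp <- config$clinpath_params
  ci <- match(true_class, cp$class)
  draw_score <- function(field) {
    vapply(seq_len(n),
           function(i) sample_score(1L, cp[[field]][[ci[i]]]), integer(1))
  }
  cohort$tubules <- draw_score("tubules")
  cohort$pleomorphism <- draw_score("pleomorphism")
  cohort$mitosis <- draw_score("mitosis")
  cohort$size_cm <- round(stats::rlnorm(n, cp$size_meanlog[ci], 0.45), 2)
  cohort$size_cm <- pmin(pmax(cohort$size_cm, 0.2), 7)
  cohort$nodes_total <- 4L + stats::rpois(n, 6)
  involved <- stats::runif(n) < cp$p_node_involved[ci]
  extra <- stats::rbinom(n, pmax(cohort$nodes_total - 1L, 0L), 0.25)
  cohort$nodes_positive <- if_else(involved, 1L + extra, 0L)
  cohort$stage <- if_else(cohort$nodes_positive == 0L, 1L,
                          if_else(cohort$nodes_positive <= 3L, 2L, 3L))

  # --- survival ----------------------------------------------------------
  classed <- cohort$true_class != "Unclassified"
  idx <- rep(NA_real_, n)
  if (any(classed)) {
    sub <- cohort[classed, ] |> mutate(class = .data$true_class)
    idx[classed] <- compute_index(sub, config$formulas)$npi_index
  }
  lp <- if_else(is.na(idx), 0, idx)
  base <- config$hazard_params$baseline[
    match(true_class, config$hazard_params$class)]
  t_bc <- stats::rexp(n, rate = base * exp(lp))
  t_other <- stats::rexp(n, rate = config$other_cause_rate)
  t_admin <- config$followup_years - stats::runif(n, 0, config$accrual_years)
  cohort$time <- round(pmin(t_bc, t_other, t_admin), 3)
  cohort$time <- pmax(cohort$time, 0.01)
  cohort$event <- dplyr::case_when(
    t_bc <= t_other & t_bc <= t_admin ~ "bc_death",
    t_other <= t_admin ~ "other_death",
    .default = "alive")

  cohort$true_index <- idx
  cohort$true_lp <- lp
  grp <- rep(NA_character_, n)
  if (any(classed)) {
    sub <- cohort[classed, ] |>
      mutate(class = .data$true_class, npi_index = idx[classed])
    grp[classed] <- assign_group(sub, config$formulas)$prognostic_group
  }
  cohort$true_group <- grp

  obs_first <- c("patient_id", unname(cols), "her2_ihc", "her2_ish",
                 clinpath_columns(), "time", "event")
  cohort <- cohort[, c(obs_first, "true_class", "true_index", "true_lp",
                       "true_group")]
  structure(cohort, class = c("npi_cohort", class(cohort)),
            config = config)
}

# Markers whose membership a class's default rules depend on (HER2 is
# categorical and handled via the equivocal flag instead).
rule_markers <- function(rb, class) {
  ms <- purrr::map(rb$rules, function(r) {
    if (r$consequent == class) names(r$antecedents) else character(0)
  })
  setdiff(unique(unlist(ms)), "HER2")
}

#' Score pipeline recovery of generator truth
#'
#' Compares pipeline outputs with the hidden truth columns of a synthetic
#' cohort: biological-class agreement (overall and restricted to
#' non-borderline profiles, i.e. those whose class-relevant markers all
#' lie at least `margin` H-score units from the cut-off), prognostic-group
#' agreement, and — when derived fits are supplied — the largest absolute
#' deviation of the recovered Cox coefficients from the generating ones.
#'
#' @param cohort An `npi_cohort` (must carry truth columns).
#' @param classified The [classify_cohort()] result for the same patients.
#' @param grouped Optional [assign_group()] output (rows matching the
#'   classified, correctly classified subset is scored).
#' @param beta_fits Optional named list of [derive_formula()] fits keyed by
#'   class, compared against the generating formula coefficients.
#' @param cutoffs,rb Cut-off table and rule base defining marker relevance
#'   and the borderline margin (defaults as the pipeline defaults).
#' @param margin Borderline half-width in H-score units (defaults to the
#'   rule base's membership width).
#'
#' @return A tibble `metric`, `value`.
#' @export
truth_recovery_report <- function(cohort, classified, grouped = NULL,
                                  beta_fits = NULL,
                                  cutoffs = default_cutoffs(),
                                  rb = default_rulebase(),
                                  margin = NULL) {
  need <- c("true_class", "true_index", "true_group")
  if (!all(need %in% names(cohort))) {
    abort("Cohort lacks truth columns; was it produced by generate()?")
  }
  if (nrow(cohort) != nrow(classified)) {
    abort("`cohort` and `classified` must cover the same patients.")
  }
  if (is.null(margin)) {
    w <- rb$membership_width
    margin <- if (length(w) == 1) unname(w) else max(w)
  }
  cut <- setNames(cutoffs$cutoff, cutoffs$marker)
  cols <- marker_columns()
  borderline <- purrr::map_lgl(seq_len(nrow(cohort)), function(i) {
    cl <- cohort$true_class[i]
    if (cl == "Unclassified") return(TRUE)
    ms <- rule_markers(rb, cl)
    any(purrr::map_lgl(ms, function(m) {
      v <- cohort[[cols[[m]]]][i]
      is.na(v) || abs(v - cut[[m]]) < margin
    }))
  })
  scored <- classified$class != "Excluded"
  agree <- classified$class == cohort$true_class
  metrics <- tibble(
    metric = c("n", "n_excluded", "class_agreement",
               "class_agreement_nonborderline", "fraction_borderline"),
    value = c(nrow(cohort), sum(!scored),
              mean(agree[scored]),
              mean(agree[scored & !borderline]),
              mean(borderline)))
  if (!is.null(grouped)) {
    ok <- scored & agree & !is.na(cohort$true_group)
    gmatch <- grouped$prognostic_group[match(cohort$patient_id[ok],
                                             grouped$patient_id)] ==
      cohort$true_group[ok]
    metrics <- bind_rows(metrics,
                         tibble(metric = "group_agreement",
                                value = mean(gmatch, na.rm = TRUE)))
  }
  if (!is.null(beta_fits)) {
    fml <- attr(cohort, "config")$formulas %||% default_formulas()
    dev <- purrr::imap_dbl(beta_fits, function(fit, cl) {
      truth <- fml[[cl]]$terms
      est <- setNames(fit$terms$raw_coefficient, fit$terms$variable)
      shared <- intersect(names(truth), names(est))
      if (length(shared) == 0) return(NA_real_)
      max(abs(est[shared] - truth[shared]))
    })
    metrics <- bind_rows(metrics,
                         tibble(metric = "max_abs_beta_error",
                                value = max(dev, na.rm = TRUE)))
  }
  metrics
}
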