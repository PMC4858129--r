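# Independent oracles and small fixture builders shared across tests.
# The oracles are deliberately naive re-derivations (sort midpoints,
# direct product-limit products, observed-minus-expected tabulations,
# expected-count summations) kept separate from the package code paths
# they check.

# Sample median as the sorted-midpoint rule.
median_oracle <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# Product-limit estimator by direct product over distinct event times.
km_oracle <- function(time, status) {
  ev <- sort(unique(time[status == 1]))
  surv <- numeric(length(ev))
  s <- 1
  for (i in seq_along(ev)) {
    t <- ev[i]
    n_risk <- sum(time >= t)
    d <- sum(time == t & status == 1)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  tibble::tibble(time = ev, survival = surv)
}

# Two-group log-rank chi-square by observed-minus-expected tabulation.
logrank_oracle <- function(time, status, group) {
  g <- as.integer(factor(group))
  stopifnot(length(unique(g)) == 2)
  ev <- sort(unique(time[status == 1]))
  O1 <- E1 <- V <- 0
  for (t in ev) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(time == t & status == 1)
    d1 <- sum(time == t & status == 1 & g == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# Pearson chi-square by explicit expected-count summation.
chisq_oracle <- function(m) {
  n <- sum(m)
  e <- outer(rowSums(m), colSums(m)) / n
  sum((m - e)^2 / e)
}

# Prototypical marker profiles far from every default cut-off.
proto_profile <- function(class) {
  base <- c(ER = 10, PgR = 10, `CK5/6` = 0, `CK7/8` = 250, EGFR = 0,
            HER3 = 20, HER4 = 20, p53 = 0, MUC1 = 200)
  switch(class,
    "Luminal A" = replace(base, c("ER", "PgR"), c(250, 250)),
    "Luminal N" = replace(base, "ER", 250),
    "Luminal B" = replace(base, c("ER", "HER3"), c(250, 250)),
    "Basal p53 altered" = replace(base, c("CK7/8", "CK5/6", "p53"),
                                  c(250, 200, 200)),
    "Basal p53 normal" = replace(base, c("CK7/8", "CK5/6"), c(250, 200)),
    "HER2+/ER+" = replace(base, "ER", 250),
    "HER2+/ER-" = base)
}

proto_her2 <- function(class) {
  if (class %in% c("HER2+/ER+", "HER2+/ER-")) "positive" else "negative"
}

# A tiny cohort row in the CSV schema from a named profile.
profile_row <- function(id, profile, her2_ihc = "0", her2_ish = NA_character_) {
  cols <- c(ER = "er_h", PgR = "pgr_h", `CK5/6` = "ck56_h", `CK7/8` = "ck78_h",
            EGFR = "egfr_h", HER3 = "her3_h", HER4 = "her4_h", p53 = "p53_h",
            MUC1 = "muc1_h")
  out <- tibble::tibble(patient_id = id, her2_ihc = her2_ihc,
                        her2_ish = her2_ish)
  for (m in names(cols)) out[[cols[[m]]]] <- unname(profile[m])
  out
}

random_surv_data <- function(n, seed, p_censor = 0.3) {
  set.seed(seed)
  tibble::tibble(time = round(rexp(n, 0.2), 3) + 0.01,
                 status = as.integer(runif(n) > p_censor))
}
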