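test_that("BCSS encoding scores breast-cancer death and censors the rest", {
  d <- tibble::tibble(time = c(5, 12.3, 25.5),
                      event = c("bc_death", "other_death", "alive"))
  enc <- bcss_encode(d)
  expect_equal(enc$status, c(1L, 0L, 0L))
  expect_error(bcss_encode(tibble::tibble(time = 0, event = "alive")),
               "positive")
  expect_error(bcss_encode(tibble::tibble(time = 1, event = "dead")),
               "bc_death")
})

test_that("Kaplan-Meier estimate matches the direct product-limit oracle", {
  # all censored: survival stays at 1
  allc <- tibble::tibble(time = 1:5, status = 0L)
  km <- km_estimate(allc)
  expect_true(all(km$curve$survival == 1))

  # n = 4, single event at t = 2
  one <- tibble::tibble(time = c(2, 3, 4, 5), status = c(1L, 0L, 0L, 0L))
  expect_equal(survival_at(km_estimate(one), 2), 0.75)

  # 50 random records against the independent product oracle
  for (seed in c(1, 2, 3)) {
    d <- random_surv_data(50, seed)
    km <- km_estimate(d)
    oracle <- km_oracle(d$time, d$status)
    got <- km$curve |> dplyr::filter(n_event > 0)
    expect_equal(got$time, oracle$time)
    expect_equal(got$survival, oracle$survival)
  }
  expect_error(km_estimate(tibble::tibble(time = numeric(0),
                                          status = integer(0))), "at least one")
})

test_that("uncensored KM equals the empirical survival function", {
  set.seed(9)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    t <- round(rexp(n, 0.3), 2) + 0.01
    km <- km_estimate(tibble::tibble(time = t, status = 1L))
    for (tt in sample(t, min(5, n))) {
      expect_equal(survival_at(km, tt), mean(t > tt))
    }
  }
})

test_that("curve evaluation is right-continuous with extrapolation warning", {
  d <- tibble::tibble(time = c(1, 2, 3, 4), status = c(0L, 1L, 0L, 1L))
  km <- km_estimate(d)
  expect_equal(survival_at(km, 0), 1)
  expect_equal(survival_at(km, 1.999), 1)
  expect_equal(survival_at(km, 2), 2 / 3)   # post-drop value at the event
  expect_warning(v <- survival_at(km, 10), "follow-up")
  expect_equal(v, 0)
  expect_error(survival_at(km, -1), "non-negative")
})

test_that("log-rank matches the observed-minus-expected oracle and the chi-square tail", {
  # identical groups: statistic 0, p 1
  d <- random_surv_data(20, 5)
  dup <- dplyr::bind_rows(dplyr::mutate(d, g = "a"), dplyr::mutate(d, g = "b"))
  res <- logrank_test(dup, "g")
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  expect_equal(res$dof, 1L)

  # small worked two-group example against the hand tabulation
  set.seed(77)
  for (i in 1:20) {
    a <- random_surv_data(15, 100 + i)
    b <- random_surv_data(15, 200 + i, p_censor = 0.15)
    b$time <- b$time * 1.6
    dd <- dplyr::bind_rows(dplyr::mutate(a, g = "a"), dplyr::mutate(b, g = "b"))
    res <- logrank_test(dd, "g")
    expect_equal(res$statistic, logrank_oracle(dd$time, dd$status, dd$g),
                 tolerance = 1e-8)
    expect_equal(res$p, pchisq(res$statistic, res$dof, lower.tail = FALSE))

    # invariance under group relabelling and common time rescaling
    swapped <- dplyr::mutate(dd, g = ifelse(g == "a", "b", "a"))
    expect_equal(logrank_test(swapped, "g")$statistic, res$statistic)
    scaled <- dplyr::mutate(dd, time = time * 3.7)
    expect_equal(logrank_test(scaled, "g")$statistic, res$statistic)
  }

  expect_error(logrank_test(dplyr::mutate(d, g = "a"), "g"), "two")
  allc <- tibble::tibble(time = 1:6, status = 0L, g = rep(c("a", "b"), 3))
  expect_error(logrank_test(allc, "g"), "censored")
})

test_that("Cox fitting recovers a known hazard ratio and scales under duplication", {
  set.seed(12)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.05 * exp(log(2) * x))
  cens <- rexp(n, 0.01)
  d <- tibble::tibble(x = x, time = pmin(t, cens),
                      status = as.integer(t <= cens))
  fit <- cox_fit(d, "x")
  expect_lt(abs(fit$coefficients$estimate - log(2)), 0.1)

  # duplicating every row leaves the estimate, halves the variance
  fit2 <- cox_fit(dplyr::bind_rows(d, d), "x")
  expect_equal(fit2$coefficients$estimate, fit$coefficients$estimate,
               tolerance = 0.01)
  expect_equal((fit$coefficients$se / fit2$coefficients$se)^2, 2,
               tolerance = 0.05)

  expect_error(cox_fit(dplyr::mutate(d, k = 1), "k"), "constant")
  expect_error(cox_fit(d[d$status == 0, ][1:5, ], "x"), "event")
})

test_that("a pure-noise covariate gives small coefficients and uniform p-values", {
  set.seed(60)
  ps <- replicate(60, {
    d <- tibble::tibble(x = rnorm(120), time = rexp(120, 0.1),
                        status = rbinom(120, 1, 0.8))
    cox_fit(d, "x")$coefficients$p
  })
  expect_lt(mean(ps < 0.05), 0.15)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("Cox confidence coverage is near nominal across replicates", {
  set.seed(314)
  hits <- 0
  reps <- 200
  for (i in seq_len(reps)) {
    x <- rbinom(150, 1, 0.5)
    t <- rexp(150, 0.1 * exp(0.7 * x))
    fit <- cox_fit(tibble::tibble(x = x, time = t, status = 1L), "x")
    est <- fit$coefficients$estimate
    se <- fit$coefficients$se
    hits <- hits + (abs(est - 0.7) <= 2 * se)
  }
  expect_gte(hits / reps, 0.93)
})

test_that("Bonferroni flags use the per-test threshold alpha / m", {
  expect_equal(bonferroni_adjust(0.009, alpha = 0.01), TRUE)
  expect_equal(bonferroni_adjust(c(0.009, 0.5, 0.3, 0.2, 0.1), alpha = 0.01),
               c(FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(bonferroni_adjust(c(0.001, 0.009, 0.5, 0.3, 0.2), alpha = 0.01),
               c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(bonferroni_adjust(numeric(0)), logical(0))
  expect_error(bonferroni_adjust(c(0.5, 1.2)), "0, 1")
})
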