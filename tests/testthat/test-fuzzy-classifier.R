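test_that("membership is a normalised trapezoidal shoulder", {
  mu <- membership(100, cutoff = 100, width = 20)
  expect_equal(c(mu$mu_low, mu$mu_high), c(0.5, 0.5))
  expect_equal(membership(120, 100, 20)$mu_high, 1)
  expect_equal(membership(80, 100, 20)$mu_high, 0)
  expect_equal(membership(110, 100, 20)$mu_high, 0.75)
  expect_error(membership(50, 100, 0), "positive")

  # mu_low + mu_high = 1 everywhere; shift invariance in (value, cutoff)
  set.seed(5)
  v <- runif(200, -50, 350)
  mu <- membership(v, 100, 20)
  expect_equal(mu$mu_low + mu$mu_high, rep(1, 200))
  shifted <- membership(v + 37, 137, 20)
  expect_equal(shifted$mu_high, mu$mu_high)
})

test_that("rule activation is min-conjunction scaled by weight", {
  ms <- list(ER = c(mu_low = 0.2, mu_high = 0.8),
             PgR = c(mu_low = 0.4, mu_high = 0.6),
             HER2 = c(mu_low = 1, mu_high = 0))
  r <- fuzzy_rule("Luminal A", c(ER = "high", PgR = "high", HER2 = "low"))
  expect_equal(rule_activation(ms, r), 0.6)
  r2 <- fuzzy_rule("Luminal A", c(ER = "high", PgR = "high"), weight = 0.5)
  expect_equal(rule_activation(ms, r2), 0.3)
  # any zero antecedent kills the rule; missing markers contribute zero
  r3 <- fuzzy_rule("Luminal A", c(ER = "high", HER2 = "high"))
  expect_equal(rule_activation(ms, r3), 0)
  r4 <- fuzzy_rule("Luminal A", c(MUC1 = "high"))
  expect_equal(rule_activation(ms, r4), 0)
})

test_that("rule and rulebase constructors validate their invariants", {
  expect_error(fuzzy_rule("Unclassified", c(ER = "high")), "seven classes")
  expect_error(fuzzy_rule("Luminal A", c(ER = "high", ER = "low")),
               "at most once")
  expect_error(fuzzy_rule("Luminal A", c(ER = "medium")), "low")
  expect_error(rulebase(list(fuzzy_rule("Luminal A", c(ER = "high")))),
               "without any rule")
})

test_that("prototypical profiles classify to their class with confidence 1", {
  cuts <- default_cutoffs()
  for (cl in npi_classes()) {
    res <- classify(proto_profile(cl), proto_her2(cl), cuts)
    expect_equal(res$class, cl)
    expect_equal(res$confidence, 1)
  }
})

test_that("profiles with no usable evidence are Unclassified with zero confidence", {
  cuts <- default_cutoffs()
  empty <- setNames(rep(NA_real_, 9), setdiff(npi_markers(), "HER2"))
  res <- classify(empty, "negative", cuts)
  expect_equal(res$class, "Unclassified")
  expect_equal(res$confidence, 0)
})

test_that("raising the activation threshold never rescues an Unclassified profile", {
  cuts <- default_cutoffs()
  set.seed(13)
  for (i in 1:40) {
    hs <- setNames(runif(9, 0, 300), setdiff(npi_markers(), "HER2"))
    her2 <- sample(c("positive", "negative"), 1)
    prev <- NULL
    for (thr in c(0.2, 0.5, 0.8)) {
      res <- classify(hs, her2, cuts, default_rulebase(activation_threshold = thr))
      if (!is.null(prev) && prev == "Unclassified") {
        expect_equal(res$class, "Unclassified")
      }
      prev <- res$class
    }
  }
})

test_that("the classifier degenerates to crisp boolean rule evaluation as width shrinks", {
  cuts <- default_cutoffs()
  rb_crisp <- default_rulebase(membership_width = 1e-9)
  rb <- default_rulebase()
  set.seed(29)
  for (i in 1:100) {
    hs <- setNames(runif(9, 0, 300), setdiff(npi_markers(), "HER2"))
    # keep away from exact cut-offs where the crisp limit is ambiguous
    hs <- ifelse(abs(hs - 100) < 1e-6, hs + 1, hs)
    her2 <- sample(c("positive", "negative"), 1)
    got <- suppressWarnings(classify(hs, her2, cuts, rb_crisp))

    # oracle: dichotomize + boolean evaluation of the same rules
    side <- ifelse(hs >= setNames(cuts$cutoff, cuts$marker)[names(hs)],
                   "high", "low")
    side <- c(side, HER2 = if (her2 == "positive") "high" else "low")
    sat <- purrr::map_lgl(rb$rules, function(r) {
      all(side[names(r$antecedents)] == r$antecedents)
    })
    expected <- if (!any(sat)) "Unclassified" else {
      cons <- purrr::map_chr(rb$rules, "consequent")
      npi_classes()[min(match(cons[sat], npi_classes()))]
    }
    expect_equal(got$class, expected)
  }
})

test_that("HER2-positive profiles split on ER regardless of luminal markers", {
  cuts <- default_cutoffs()
  hs <- proto_profile("HER2+/ER+")
  expect_equal(classify(hs, "positive", cuts)$class, "HER2+/ER+")
  hs["ER"] <- 5
  expect_equal(classify(hs, "positive", cuts)$class, "HER2+/ER-")
})

test_that("cohort classification reconciles counts and reports exclusions", {
  cuts <- default_cutoffs()
  empty <- classify_cohort(tibble::tibble(er_h = numeric(0),
                                          her2_ihc = character(0)), cuts)
  expect_equal(nrow(class_distribution(empty) |> dplyr::filter(n > 0)), 0)

  one <- profile_row("p1", proto_profile("Luminal A"), her2_ihc = "0")
  cl1 <- classify_cohort(one, cuts)
  expect_equal(class_distribution(cl1)$n[1], 1L)

  rows <- dplyr::bind_rows(
    profile_row("a", proto_profile("Luminal A"), "0"),
    profile_row("b", proto_profile("Basal p53 altered"), "1+"),
    profile_row("c", proto_profile("HER2+/ER+"), "3+"),
    profile_row("d", proto_profile("Luminal A"), "2+"))
  cl <- classify_cohort(rows, cuts, her2_mode = "exclude_equivocal")
  expect_equal(cl$class, c("Luminal A", "Basal p53 altered", "HER2+/ER+",
                           "Excluded"))
  dist <- class_distribution(cl)
  expect_equal(sum(dist$n), nrow(rows))
  cl2 <- classify_cohort(dplyr::mutate(rows, her2_ish = c(NA, NA, NA,
                                                          "amplified")),
                         cuts, her2_mode = "ish_resolve")
  expect_equal(cl2$class[4], "HER2+/ER+")
})

test_that("rule bases round-trip losslessly through YAML", {
  rb <- default_rulebase(activation_threshold = 0.4,
                         membership_width = 25)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_rulebase(rb, path)
  back <- read_rulebase(path)
  expect_equal(back$activation_threshold, rb$activation_threshold)
  expect_equal(back$membership_width, rb$membership_width)
  expect_equal(length(back$rules), length(rb$rules))
  for (i in seq_along(rb$rules)) {
    expect_equal(back$rules[[i]]$consequent, rb$rules[[i]]$consequent)
    expect_equal(back$rules[[i]]$antecedents, rb$rules[[i]]$antecedents)
    expect_equal(back$rules[[i]]$weight, rb$rules[[i]]$weight)
  }
})
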