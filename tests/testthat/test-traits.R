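test_that("trait summaries average culms within plots before SE", {
  # four plot means {3.3, 3.5, 3.4, 3.4}: mean 3.4, se = sd/sqrt(4)
  d <- tibble::tibble(
    variety = "V", treatment = "FFP", internode = 1,
    replicate = rep(1:4, each = 2), culm = rep(1:2, 4),
    length_cm = c(3.2, 3.4, 3.4, 3.6, 3.3, 3.5, 3.35, 3.45)
  )
  s <- summarize_traits(d, "length_cm")
  expect_equal(s$mean, 3.4)
  expect_equal(s$se, sd(c(3.3, 3.5, 3.4, 3.4)) / 2, tolerance = 1e-12)
  expect_equal(s$se, 0.041, tolerance = 2e-2)
  expect_equal(s$n, 4)

  # single plot: se reported as 0 with n = 1
  s1 <- summarize_traits(dplyr::filter(d, replicate == 1), "length_cm")
  expect_equal(s1$n, 1)
  expect_equal(s1$se, 0)

  # constant values: se 0
  s0 <- summarize_traits(dplyr::mutate(d, length_cm = 5), "length_cm")
  expect_equal(s0$se, 0)

  # all-missing group dropped with a warning
  d$length_cm[d$variety == "V"] <- NA_real_
  expect_warning(out <- summarize_traits(d, "length_cm"), "omitted")
  expect_equal(nrow(out), 0)
})

test_that("percent change reproduces the two-treatment table convention", {
  expect_equal(percent_change(22.7, 28.4), -20.1)
  expect_equal(percent_change(852, 773), 10.2)
  expect_equal(percent_change(5, 5), 0)
  expect_error(percent_change(1, 0), "nonzero")
  # scale invariance
  for (k in c(0.01, 1, 250)) {
    expect_equal(percent_change(k * 13.2, k * 16.9, digits = Inf),
                 percent_change(13.2, 16.9, digits = Inf), tolerance = 1e-9)
  }
})

test_that("average percent change is the mean of ratios, not ratio of sums", {
  expect_equal(average_percent_change(c(1490.3, 1186.5), c(1155.3, 760.0)), 42.6)
  expect_equal(average_percent_change(c(25.2, 16.8, 11.3), c(19.5, 11.9, 7.6)), 39.7)
  # identical pairs reduce to a single percent change
  expect_equal(average_percent_change(c(12, 12), c(10, 10)), percent_change(12, 10))
  # distinguishable from the ratio-of-sums pooling
  expect_false(isTRUE(all.equal(
    average_percent_change(c(1490.3, 1186.5), c(1155.3, 760.0), digits = Inf),
    (sum(c(1490.3, 1186.5)) / sum(c(1155.3, 760.0)) - 1) * 100
  )))
  expect_error(average_percent_change(1, numeric(0)), "equal-length")
})

test_that("split-plot ANOVA matches brute-force SS and aov strata", {
  set.seed(101)
  for (i in 1:5) {
    d <- make_plot_table(mu = c(FFP.A = 10, OPT.A = 8, FFP.B = 11, OPT.B = 10.5))
    fit <- split_plot_anova(d, "value")
    eff <- tidy(fit)
    brute <- split_plot_ss_brute(d$value, factor(d$replicate),
                                 factor(d$treatment), factor(d$variety))
    expect_equal(eff$sumsq,
                 unname(brute[c("replicate", "whole", "whole_error",
                                "sub", "interaction", "residual")]),
                 tolerance = 1e-9)
    # decomposition: effect SS sum to total SS
    expect_equal(sum(eff$sumsq), unname(brute["total"]), tolerance = 1e-9)
    expect_equal(sum(eff$df), nrow(d) - 1)

    # independent implementation: aov() with an Error() stratum
    ao <- summary(suppressWarnings(aov(
      value ~ factor(replicate) + treatment * variety +
        Error(factor(replicate):treatment), data = d)))
    wp <- ao[["Error: factor(replicate):treatment"]][[1]]
    sp <- ao[["Error: Within"]][[1]]
    expect_equal(eff$statistic[2], wp["treatment", "F value"], tolerance = 1e-9)
    expect_equal(eff$p.value[2], wp["treatment", "Pr(>F)"], tolerance = 1e-9)
    expect_equal(eff$p.value[4], sp["variety", "Pr(>F)"], tolerance = 1e-9)
    expect_equal(eff$p.value[5], sp["treatment:variety", "Pr(>F)"], tolerance = 1e-9)
  }
})

test_that("split-plot ANOVA handles degenerate and invalid layouts explicitly", {
  d <- make_plot_table(sd = 0)   # all responses equal
  fit <- split_plot_anova(d, "value")
  eff <- tidy(fit)
  expect_equal(eff$sumsq, rep(0, 6), tolerance = 1e-20)
  expect_true(all(is.na(eff$statistic) | !is.finite(eff$statistic)))

  expect_error(split_plot_anova(d[-1, ], "value"), "balanced")
  d2 <- d; d2$value[1] <- NA
  expect_error(split_plot_anova(d2, "value"), "missing")
})

test_that("N-effect test holds its nominal type-I error under the null", {
  set.seed(20260930)
  n_sim <- 2000
  p <- replicate(n_sim, {
    d <- make_plot_table()  # pure noise, no effects
    tidy(split_plot_anova(d, "value"))$p.value[2]
  })
  rate <- mean(p <= 0.05)
  expect_gt(rate, 0.05 - 0.015)
  expect_lt(rate, 0.05 + 0.015)
})

test_that("LSD letter groups mark separated, tied and chained means", {
  # two groups far apart
  lg <- letter_groups(c(FFP = 20, OPT = 10), n = 4, error_ms = 0.5, df = 6)
  expect_equal(lg$letter, c("a", "b"))
  # identical means share a letter
  lg2 <- letter_groups(c(FFP = 10, OPT = 10), n = 4, error_ms = 0.5, df = 6)
  expect_equal(lg2$letter, c("a", "a"))

  # chained overlap {a, ab, b}: LSD ~ 1.0 with ms = 0.334, n = 4, df = 6
  ms <- 2 * (1 / qt(0.975, 6))^2
  lg3 <- letter_groups(c(g1 = 10, g2 = 9.2, g3 = 8.4), n = 4,
                       error_ms = ms, df = 6)
  expect_equal(lg3$letter, c("a", "ab", "b"))
  # brute-force pairwise LSD verdicts agree with shared letters
  m <- c(10, 9.2, 8.4)
  lsd <- qt(0.975, 6) * sqrt(ms * (1 / 4 + 1 / 4))
  share <- function(i, j) {
    any(strsplit(lg3$letter[i], "")[[1]] %in% strsplit(lg3$letter[j], "")[[1]])
  }
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(share(i, j), abs(m[i] - m[j]) <= lsd)
  }
  expect_error(letter_groups(c(a = 1), n = 4, error_ms = 1, df = 6), "two groups")
  expect_error(letter_groups(c(a = 1, b = 2), n = 4, error_ms = 1, df = 0), "df")
})

test_that("harvest index is grain over biomass", {
  expect_equal(harvest_index(500, 1000), 0.5)
  expect_equal(harvest_index(0, 800), 0)
  expect_equal(harvest_index(724, 1219), 0.594, tolerance = 1e-3)
  expect_error(harvest_index(500, 0), "positive")
})

test_that("percent-change table joins treatments and matches the scalar form", {
  trial <- gen_field_trial(seed = 11)
  s <- summarize_traits(trial, "length_cm")
  pct <- percent_change_table(s)
  expect_true(all(c("mean_ffp", "mean_opt", "pct_change") %in% names(pct)))
  row <- dplyr::filter(pct, variety == "YJRZ", internode == 3)
  expect_equal(row$pct_change, percent_change(row$mean_opt, row$mean_ffp))
  # renderer produces "mean +/- se" strings
  disp <- render_trait_table(s)
  expect_match(disp$display[1], "^[0-9.]+ ± [0-9.]+")
})

test_that("a configured -20% length effect is recovered across simulations", {
  set.seed(515)
  cfg <- mini_trial_config()
  n_sim <- 500
  rec <- replicate(n_sim, {
    trial <- gen_field_trial(cfg, culms_per_plot = 4,
                             seed = sample.int(2^31 - 1, 1))
    pm <- summarize_plot_means(trial, "length_cm", internodes = 1:3,
                               sum_internodes = TRUE)
    g <- tapply(pm$value, pm$treatment, mean)
    (g[["OPT"]] - g[["FFP"]]) / g[["FFP"]] * 100
  })
  expect_equal(mean(rec), -20.1, tolerance = 1.5 / 20.1)
})
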