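test_that("GLM odds ratio equals the closed-form 2x2 odds ratio", {
  df <- data.frame(
    success = c(rep(1, 30), rep(0, 70), rep(1, 60), rep(0, 40)),
    group = rep(c("a", "b"), each = 100)
  )
  fit <- fit_success_glm(df, success ~ group)
  or_closed <- (30 / 70) / (60 / 40)
  or_glm <- fit$odds_ratios$odds_ratio[fit$odds_ratios$term == "groupa"]
  # reference level is "a"; invert to compare a vs b
  if (!length(or_glm)) {
    or_glm <- 1 / fit$odds_ratios$odds_ratio[fit$odds_ratios$term == "groupb"]
  }
  expect_equal(unname(or_glm), or_closed, tolerance = 1e-6)
  # CI bounds ordered, odds ratio = exp(coefficient)
  with(fit$odds_ratios, expect_true(all(ci_lower <= ci_upper)))
  expect_equal(fit$odds_ratios$odds_ratio, exp(fit$odds_ratios$estimate))
})

test_that("an all-equal response carries no slope information", {
  df <- data.frame(success = rep(1, 40), x = rnorm(40))
  fit <- suppressWarnings(fit_success_glm(df, success ~ x))
  expect_true(fit$separation || abs(fit$coefficients["x", "Estimate"]) < 1e-6)
})

test_that("likelihood-ratio test matches the chi-squared tail", {
  set.seed(8)
  df <- data.frame(success = rbinom(300, 1, 0.5), x = rnorm(300),
                   z = rnorm(300))
  f0 <- fit_success_glm(df, success ~ x)
  f1 <- fit_success_glm(df, success ~ x + z)
  res <- lrt(f0, f1)
  expect_equal(res$df, 1)
  expect_equal(res$statistic,
               2 * (f1$logLik - f0$logLik))
  expect_equal(res$p_value, lrt_pvalue(res$statistic, 1))
  # identical models: statistic 0, p 1
  res0 <- lrt(f0, f0)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  expect_error(lrt(f1, f0), "not nested")
})

test_that("chi-squared tail values match an independent integration oracle", {
  expect_equal(lrt_pvalue(9.13, 3), chisq_tail_integrate(9.13, 3),
               tolerance = 1e-9)
  expect_equal(lrt_pvalue(9.13, 3), 0.0276, tolerance = 5e-4)
  expect_equal(lrt_pvalue(3.841, 1), 0.05, tolerance = 1e-3)
  expect_equal(lrt_pvalue(31.414, 1), chisq_tail_integrate(31.414, 1),
               tolerance = 1e-9)
})

test_that("chisq_success reproduces hand-computed Pearson statistics", {
  res <- chisq_success(rbind(c(10, 90), c(90, 10)))
  expect_equal(res$statistic, 128)  # n (ad - bc)^2 / (r1 r2 c1 c2)
  expect_equal(res$df, 1)
  # identical proportions: statistic 0
  res0 <- chisq_success(rbind(c(30, 70), c(60, 140)))
  expect_equal(res0$statistic, 0)
  # 3-group table vs the Pearson formula, recomputed independently
  m <- rbind(c(120, 80), c(110, 90), c(40, 160))
  res3 <- chisq_success(m)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  expect_equal(res3$statistic, sum((m - expected)^2 / expected),
               tolerance = 1e-9)
  expect_equal(res3$df, 2)
  expect_error(chisq_success(rbind(c(0, 0), c(1, 2))), "degenerate")
  expect_error(chisq_success(rbind(c(5, 5))), "two groups")
})

test_that("kruskal_dunn: degenerate equality, Holm ordering, and power", {
  same <- rep(c(1, 2, 3), times = 3)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- kruskal_dunn(same, g)
  expect_equal(res$kruskal$statistic, 0)
  expect_true(all(abs(res$pairwise$z) < 1e-12))
  # Holm-adjusted p never below raw p, and capped at 1
  set.seed(3)
  x <- c(rnorm(30), rnorm(30, 0.5), rnorm(30, 1))
  gg <- rep(c("a", "b", "c"), each = 30)
  res2 <- kruskal_dunn(x, gg)
  expect_true(all(res2$pairwise$adjusted_p >= res2$pairwise$p_value - 1e-15))
  expect_true(all(res2$pairwise$adjusted_p <= 1))
  # a group shifted by 10x IQR is detected at adjusted p < 0.001
  set.seed(4)
  y <- c(rnorm(50), rnorm(50), rnorm(50) + 10 * IQR(rnorm(1000)))
  res3 <- kruskal_dunn(y, rep(c("a", "b", "shift"), each = 50))
  shifted <- res3$pairwise[res3$pairwise$group1 == "shift" |
                             res3$pairwise$group2 == "shift", ]
  expect_true(all(shifted$adjusted_p < 0.001))
  expect_error(kruskal_dunn(1:5, rep("a", 5)), "two groups")
})

test_that("Holm step-down definition on a known pair", {
  # adjusted p for raw (0.01, 0.04) with m = 2 is (0.02, 0.04): the smallest
  # p is scaled by m, the next by m - 1, with running maxima
  raw <- c(0.01, 0.04)
  m <- length(raw)
  o <- order(raw)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * raw[o]))[order(o)]
  expect_equal(adj, c(0.02, 0.04))
  expect_equal(stats::p.adjust(raw, "holm"), adj)
})

test_that("sigma effect direction is recovered from a simulated grid", {
  d <- hypothetical_design(n_per_cell = 30L, seed = 77,
                           basins = make_hypothetical_basins()[c("circular",
                                                                 "elliptical")])
  g <- run_grid(d)
  fit <- fit_success_glm(g$records, success ~ basin + step_length + turn_sd)
  or_sigma <- fit$odds_ratios$odds_ratio[fit$odds_ratios$term == "turn_sd"]
  expect_lt(or_sigma, 1)  # higher turning dispersion lowers the success odds
})

test_that("backward selection drops pure-noise terms", {
  set.seed(21)
  df <- data.frame(success = rbinom(400, 1, 0.5), noise = rnorm(400))
  df$success <- rbinom(400, 1, stats::plogis(-0.5 + 0.0 * df$noise))
  sel <- select_success_glm(df, success ~ noise)
  expect_true("noise" %in% sel$steps$dropped)
  expect_equal(attr(stats::terms(sel$fit$fit), "term.labels"), character(0))
})

test_that("compare_to_telemetry flags interval coverage sensibly", {
  d <- real_lakes_design(n_per_cell = 40L, seed = 5, lakes = "Bassenthwaite")
  g <- run_grid(d)
  tel <- lake_telemetry("Bassenthwaite", n_fish = 200, seed = 6)
  cmp <- compare_to_telemetry(g, tel)
  expect_equal(nrow(cmp), 9)
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))
  # a cell at 100% success cannot cover a 46% empirical rate
  full <- cmp[cmp$success_rate == 100, ]
  if (nrow(full)) expect_true(all(!full$rate_within_ci))
  # degenerate empirical match: empirical rate equal to cell rate is covered
  cell1 <- g$cells[1, ]
  fake <- data.frame(lake = "Bassenthwaite",
                     success = rep(c(TRUE, FALSE),
                                   c(cell1$n_success,
                                     cell1$n_sims - cell1$n_success)),
                     passage_days = NA_real_)
  fake$passage_days[fake$success] <- cell1$mean_passage_days
  cmp1 <- compare_to_telemetry(g, fake)
  expect_true(cmp1$rate_within_ci[1])
  expect_error(compare_to_telemetry(g, fake[0, ]), "no telemetry")
})
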