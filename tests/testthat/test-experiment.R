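test_that("comparison harness produces one row per web, method, replicate", {
  webs <- list(chain = fixture_web("chain3"), tp = fixture_web("two_prey"))
  cfg <- tabu_config(t_max = 10, n_can = 3, tabu_length = 2)
  cmp <- run_comparison(webs, methods = c("ID", "OD", "TS"), reps = 3,
                        config = cfg, base_seed = 5)
  rows <- tidy(cmp)
  expect_equal(nrow(rows), 2L * 3L * 3L)
  expect_equal(dplyr::n_distinct(rows[c("web", "method", "rep")]), 18L)

  # deterministic methods have zero variance across replicates
  det <- dplyr::filter(rows, .data$method != "TS")
  v <- dplyr::summarise(dplyr::group_by(det, .data$web, .data$method),
                        s = stats::sd(.data$sea), .groups = "drop")
  expect_true(all(v$s == 0))

  # identical seeds reproduce identical tables
  cmp2 <- run_comparison(webs, methods = c("ID", "OD", "TS"), reps = 3,
                         config = cfg, base_seed = 5)
  expect_identical(rows, tidy(cmp2))

  wl <- web_level_means(rows)
  expect_equal(nrow(wl), 6L)
  s <- summary(cmp)
  expect_setequal(s$metric, c("sea", "r50"))
  expect_s3_class(autoplot(cmp), "ggplot")
  expect_error(run_comparison(list("missing.json"), methods = "ID"),
               "missing.json")
  expect_error(run_comparison(webs, methods = "ZZ"), "subset")
})

test_that("one-way ANOVA matches the hand decomposition", {
  df <- data.frame(g = rep(c("a", "b"), each = 2), y = c(0, 1, 2, 3))
  res <- one_way_anova(df, "y", "g")
  expect_equal(res$statistic, 8)          # SSB = 4, SSW = 1, df = (1, 2)
  expect_equal(res$df, 1L)
  expect_equal(res$df_residual, 2L)
  expect_equal(res$statistic, anova_f_oracle(df$y, df$g))

  # identical groups: F = 0 with positive within-variance
  df0 <- data.frame(g = rep(c("a", "b"), each = 3), y = rep(c(1, 2, 3), 2))
  expect_equal(one_way_anova(df0, "y", "g")$statistic, 0)

  # all values constant: degenerate, p undefined
  dfc <- data.frame(g = rep(c("a", "b"), each = 2), y = rep(1, 4))
  resc <- one_way_anova(dfc, "y", "g")
  expect_true(resc$degenerate)
  expect_true(is.na(resc$p_value))

  expect_error(one_way_anova(data.frame(g = "a", y = 1), "y", "g"),
               "two groups")
})

test_that("benchmark table statistics reproduce the published comparison", {
  bench <- sea_benchmark()
  expect_equal(nrow(bench), 72L)
  means <- dplyr::summarise(dplyr::group_by(bench, .data$method),
                            m = mean(.data$sea), .groups = "drop")
  mt <- setNames(means$m, means$method)
  expect_equal(round(unname(mt["TS"]), 3), 0.385)
  expect_equal(round(unname(mt["ID"]), 3), 0.274)

  # dispersion of the TS column: SD 0.030 (the value printed as +/- 0.030),
  # SEM 0.009
  ts <- bench$sea[bench$method == "TS"]
  expect_equal(round(stats::sd(ts), 3), 0.030)
  expect_equal(round(stats::sd(ts) / sqrt(12), 4), 0.0087)

  # ANOVA over 6 methods x 12 webs: df = (5, 66); F agrees with the
  # independent hand decomposition
  res <- one_way_anova(bench, "sea", "method")
  expect_equal(res$df, 5L)
  expect_equal(res$df_residual, 66L)
  expect_equal(res$statistic, anova_f_oracle(bench$sea, bench$method))
  expect_equal(res$statistic, 12.71748, tolerance = 1e-6)
  expect_lt(res$p_value, 0.001)
})

test_that("Dunnett contrasts against the tabu control", {
  bench <- sea_benchmark()
  dn <- dunnett_vs_control(bench, "sea", "method", control = "TS")
  expect_equal(nrow(dn), 5L)
  est <- setNames(dn$estimate, dn$method)
  expect_equal(round(unname(est["OD"]), 3), -0.095)
  expect_equal(round(unname(est["EIG"]), 3), -0.162)
  expect_true(all(dn$significance == "<0.01"))
  # balanced design: all simultaneous intervals share one half-width
  hw <- (dn$conf_high - dn$conf_low) / 2
  expect_lt(diff(range(hw)), 1e-10)
  # reproducible despite the Monte-Carlo quantile
  dn2 <- dunnett_vs_control(bench, "sea", "method", control = "TS")
  expect_identical(dn$conf_low, dn2$conf_low)

  # a group identical to the control: zero difference, non-significant
  df <- data.frame(m = rep(c("TS", "X", "Y"), each = 4),
                   y = c(1, 2, 3, 4, 1, 2, 3, 4, 5, 6, 7, 8))
  d0 <- dunnett_vs_control(df, "y", "m", control = "TS")
  expect_equal(d0$estimate[d0$method == "X"], 0)
  expect_gt(d0$p_adjusted[d0$method == "X"], 0.9)
  expect_error(dunnett_vs_control(df, "y", "m", control = "ZZ"),
               "not present")
})

test_that("published connectance table is internally consistent", {
  cb <- connectance_benchmark()
  expect_equal(round(cb$links / cb$s^2, 3), cb$connectance)
  expect_true(all(cb$weighted_connectance <= cb$connectance))
})
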