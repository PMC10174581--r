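test_that("random initial solutions satisfy the budget constraint", {
  x <- random_initial_solution(6, 2, seed = 42)
  expect_equal(sum(x), 4L)                       # sum x_i = N - n
  expect_length(attr(x, "removed"), 2L)
  expect_identical(x, random_initial_solution(6, 2, seed = 42))
  expect_false(identical(attr(x, "removed"),
                         attr(random_initial_solution(6, 2, seed = 43),
                              "removed")) &&
               identical(attr(x, "removed"),
                         attr(random_initial_solution(6, 2, seed = 44),
                              "removed")))
  expect_equal(sum(random_initial_solution(5, 5, seed = 1)), 0L)
  expect_error(random_initial_solution(4, 5), "1..4")
  expect_error(tabu_config(t_max = 0), "t_max")
  expect_error(tabu_config(retry_cap = 1, n_can = 10), "retry_cap")
})

test_that("candidate solutions are single swaps avoiding the tabu list", {
  cfg <- tabu_config(n_can = 4, tabu_length = 3, seed = 1)
  cur <- c(4L, 6L)
  cand <- tabu_candidates(cur, 6, config = cfg, seed = 7)
  expect_length(cand$sets, 4L)
  for (i in seq_along(cand$sets)) {
    set <- cand$sets[[i]]
    expect_length(set, 2L)                        # budget preserved
    # exactly one restore and one removal: Hamming distance 2
    expect_equal(length(setdiff(set, cur)) + length(setdiff(cur, set)), 2L)
  }
  expect_equal(anyDuplicated(cand$swaps), 0L)

  # never more candidates than distinct swaps n * (N - n)
  big <- tabu_candidates(1L, 3, config = tabu_config(n_can = 50), seed = 1)
  expect_lte(length(big$sets), 1L * 2L)

  # a tabu swap is never drawn
  tabu <- "1~3"
  for (seed in 1:10) {
    cnd <- tabu_candidates(1L, 3, tabu = tabu,
                           config = tabu_config(n_can = 10), seed = seed)
    expect_false(any(cnd$swaps == "1~3"))
  }

  # every swap forbidden: the oldest entry is evicted, >= 1 candidate returned
  all_tabu <- c("1~3", "1~4", "2~3", "2~4")
  forced <- tabu_candidates(c(1L, 2L), 4, tabu = all_tabu,
                            config = tabu_config(n_can = 2, retry_cap = 5),
                            seed = 3)
  expect_gte(length(forced$sets), 1L)
  expect_lt(length(forced$tabu), length(all_tabu))
  expect_false("1~3" %in% forced$tabu)            # oldest entry went first
})

test_that("tabu search bookkeeping: non-decreasing best-F trace, determinism", {
  w <- generate_niche_web(10, 0.25, seed = 5)
  cfg <- tabu_config(t_max = 30, n_can = 5, tabu_length = 3, seed = 9)
  res <- tabu_search(w, n = 2, t = 0.5, config = cfg)
  expect_true(all(diff(res$trace$f_best) >= 0))
  expect_gte(res$disintegration, res$trace$f_best[1])   # >= F(X_0)
  expect_equal(res$disintegration, max(res$trace$f_best))
  expect_length(res$removed_idx, 2L)
  expect_equal(nrow(res$trace), cfg$t_max + 1L)

  res2 <- tabu_search(w, n = 2, t = 0.5, config = cfg)
  expect_identical(res$removed_idx, res2$removed_idx)
  expect_identical(res$trace, res2$trace)

  # degenerate budget: everything removed at once
  res_all <- tabu_search(w, n = 10, t = 0.5, config = cfg)
  expect_equal(res_all$disintegration, 10L)
  expect_error(tabu_search(w, n = 11, t = 0.5, config = cfg), "1..10")
})

test_that("tabu search reaches the exhaustive optimum on small webs", {
  hits <- 0L
  runs <- 10L
  for (i in seq_len(runs)) {
    set.seed(i)
    s <- sample(8:10, 1)
    n <- sample(2:3, 1)
    w <- generate_niche_web(s, 0.25, seed = 1000 + i)
    oracle <- brute_force_optimal_removal(w, n, t = 0.5)
    cfg <- tabu_config(t_max = 200, n_can = 10, tabu_length = 3, seed = i)
    res <- tabu_search(w, n, t = 0.5, config = cfg)
    expect_lte(res$disintegration, oracle$disintegration)  # never exceeds
    hits <- hits + (res$disintegration == oracle$disintegration)
  }
  expect_gte(hits, ceiling(0.95 * runs))
})

test_that("the tabu removal curve collapses the chain at the first budget", {
  cfg <- tabu_config(t_max = 10, n_can = 3, tabu_length = 2, seed = 1)
  cv <- tabu_removal_curve(fixture_web("chain3"), t = 0.5, config = cfg)
  expect_equal(cv$counts, c(3L, 3L, 3L))
  expect_equal(cv$method, "TS")

  # isolated import-only web: F = p exactly
  cv_iso <- tabu_removal_curve(fixture_web("isolated"), t = 0.5, config = cfg)
  expect_equal(cv_iso$counts, 1:4)
})

test_that("with a generous budget the optimizer dominates greedy baselines", {
  cfg <- tabu_config(t_max = 100, n_can = 10, tabu_length = 3, seed = 2)
  for (s in 1:3) {
    w <- generate_niche_web(8, 0.25, seed = 300 + s)
    ts_cv <- tabu_removal_curve(w, t = 0.5, config = cfg)
    for (m in c("OD", "ID")) {
      base_cv <- sequential_removal(w, m, t = 0.5)
      expect_true(all(ts_cv$counts >= base_cv$counts))
    }
  }
})
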