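#' Tabu search configuration
#'
#' Tuning parameters of the tabu search optimizer.  `t_max` bounds the number
#' of iterations, `n_can` the candidate solutions drawn per iteration,
#' `tabu_length` (the tabu step length L) the FIFO memory of recently accepted
#' swaps that may not be re-drawn, and `retry_cap` the number of rejected
#' draws tolerated before the generator falls back (returning the candidates
#' found so far or, if none, evicting the oldest tabu entry).
#'
#' @param t_max maximum iterations (>= 1).
#' @param n_can candidate solutions per iteration (>= 1).
#' @param tabu_length tabu list length L (>= 0).
#' @param seed integer RNG seed; every stochastic path derives from it.
#' @param retry_cap maximum failed swap draws before fallback
#'   (>= `n_can`).
#' @return A `tabu_config` list.
#' @export
tabu_config <- function(t_max = 100L, n_can = 20L, tabu_length = 7L,
                        seed = 1L, retry_cap = 50L * n_can) {
  t_max <- as.integer(t_max); n_can <- as.integer(n_can)
  tabu_length <- as.integer(tabu_length); retry_cap <- as.integer(retry_cap)
  if (t_max < 1L) abort("`t_max` must be >= 1.")
  if (n_can < 1L) abort("`n_can` must be >= 1.")
  if (tabu_length < 0L) abort("`tabu_length` must be >= 0.")
  if (retry_cap < n_can) abort("`retry_cap` must be >= `n_can`.")
  structure(list(t_max = t_max, n_can = n_can, tabu_length = tabu_length,
                 seed = as.integer(seed), retry_cap = retry_cap),
            class = "tabu_config")
}

#' Random initial removal solution
#'
#' Draws a uniform random n-subset of the N species as the initial primary
#' removal set, encoded as the binary state vector x with `x[i] = 0` for
#' removed and `x[i] = 1` for kept species (so `sum(x) = N - n`).  The
#' removed indices are attached as attribute `"removed"`.  The environment
#' node is not part of the vector and is never removable.
#'
#' @param n_species number of species N.
#' @param n removal budget, `1 <= n <= N`.
#' @param seed integer RNG seed.
#' @return Integer 0/1 vector of length `n_species` with attribute
#'   `"removed"`.
#' @export
random_initial_solution <- function(n_species, n, seed = 1L) {
  if (n < 1L || n > n_species) {
    abort(sprintf("`n` must be in 1..%d.", n_species))
  }
  removed <- withr::with_seed(seed, sort(sample.int(n_species, n)))
  states <- rep(1L, n_species)
  states[removed] <- 0L
  structure(states, removed = removed)
}

swap_key <- function(a, b) paste(sort(c(a, b)), collapse = "~")

# Draw up to n_can candidate removal sets, each one swap away from `current`.
# A swap {y0 restored, y1 removed} is rejected if already drawn this
# iteration or present in the tabu list.  After retry_cap consecutive
# rejections the generator returns what it has; with no candidate at all it
# evicts the oldest tabu entry and keeps drawing, so at least one candidate
# is always produced.  Caller controls the RNG state.
draw_candidates <- function(current, n_species, tabu, config) {
  kept <- setdiff(seq_len(n_species), current)
  stopifnot(length(current) >= 1L, length(kept) >= 1L)
  max_swaps <- length(current) * length(kept)
  sets <- list()
  swaps <- character(0)
  tries <- 0L
  while (length(sets) < config$n_can && length(sets) < max_swaps) {
    y0 <- current[sample.int(length(current), 1L)]
    y1 <- kept[sample.int(length(kept), 1L)]
    key <- swap_key(y0, y1)
    if (key %in% swaps || key %in% tabu) {
      tries <- tries + 1L
      if (tries >= config$retry_cap) {
        if (length(sets) >= 1L) break
        tabu <- tabu[-1L]   # deadlock: relax the oldest prohibition
        tries <- 0L
      }
      next
    }
    swaps <- c(swaps, key)
    sets[[length(sets) + 1L]] <- sort(c(setdiff(current, y0), y1))
  }
  list(sets = sets, swaps = swaps, tabu = tabu)
}

#' Exported wrapper for candidate generation (testing and inspection)
#'
#' Generates the candidate neighbourhood of a removal set as used inside one
#' tabu search iteration: up to `n_can` solutions, each differing from
#' `current` by one restore/remove swap, none of whose swaps is in the tabu
#' list or drawn twice.  See [tabu_config()] for the deadlock fallback.
#'
#' @param current integer vector of currently removed species indices.
#' @param n_species number of species N.
#' @param tabu character vector of tabu swap keys (oldest first).
#' @param config a [tabu_config()].
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @return A list with `sets` (list of removed-index vectors), `swaps`
#'   (their swap keys) and the possibly relaxed `tabu` list.
#' @export
tabu_candidates <- function(current, n_species, tabu = character(0),
                            config = tabu_config(), seed = NULL) {
  if (is.null(seed)) {
    draw_candidates(current, n_species, tabu, config)
  } else {
    withr::with_seed(seed, draw_candidates(current, n_species, tabu, config))
  }
}

#' Find the most destructive n-species removal set by tabu search
#'
#' Maximises the disintegration `F(X) = f(G0) - f(G)` over all removal sets
#' of exactly `n` species, where `f` counts the species surviving the
#' extinction cascade at threshold `t`.  The search starts from a uniform
#' random n-subset, and per iteration draws up to `n_can` neighbours of the
#' current solution (single restore/remove swaps avoiding the tabu list),
#' moves to the best of them, and either records a new global best -- in
#' which case the tabu list is cleared (aspiration) -- or adds the accepted
#' swap to the FIFO tabu list of length L.  Terminates after `t_max`
#' iterations and returns the historical best.
#'
#' The run is fully reproducible from `config$seed`.
#'
#' @param web a `foodweb` or augmented web.
#' @param n removal budget, `1 <= n <= N`.
#' @param t extinction threshold in `[0, 1]`.
#' @param config a [tabu_config()].
#' @param strict_less passed to [simulate_cascade()].
#' @return An object of class `tabu_result`: `removed` (species labels),
#'   `removed_idx`, `disintegration` (best F), `n`, `threshold`, `config`,
#'   and `trace`, a tibble with per-iteration `f_current` and the
#'   non-decreasing `f_best`.
#' @examples
#' tabu_search(fixture_web("chain3"), n = 1, t = 0.5,
#'             config = tabu_config(t_max = 5, n_can = 2, seed = 1))
#' @export
tabu_search <- function(web, n, t, config = tabu_config(),
                        strict_less = FALSE) {
  aug <- as_augmented(web)
  n_sp <- n_species(aug)
  if (n < 1L || n > n_sp) abort(sprintf("`n` must be in 1..%d.", n_sp))
  n <- as.integer(n)
  objective <- function(set) {
    disintegration(aug, aug$web$species[set], t, strict_less)
  }

  if (n == n_sp) {   # everything removed: nothing to optimise
    trace <- tibble(iteration = 0L, f_current = n_sp, f_best = n_sp)
    return(new_tabu_result(aug, seq_len(n_sp), n_sp, n, t, config, trace))
  }

  withr::with_seed(config$seed, {
    cur <- sort(sample.int(n_sp, n))
    f_cur <- objective(cur)
    opt <- cur
    f_opt <- f_cur
    tabu <- character(0)
    trace_cur <- numeric(config$t_max + 1L)
    trace_opt <- numeric(config$t_max + 1L)
    trace_cur[1L] <- f_cur
    trace_opt[1L] <- f_opt
    for (iter in seq_len(config$t_max)) {
      cand <- draw_candidates(cur, n_sp, tabu, config)
      tabu <- cand$tabu
      f_vals <- vapply(cand$sets, objective, numeric(1))
      k <- which.max(f_vals)   # ties: first drawn candidate wins
      cur <- cand$sets[[k]]
      f_cur <- f_vals[k]
      if (f_cur > f_opt) {     # aspiration: new global best resets the list
        opt <- cur
        f_opt <- f_cur
        tabu <- character(0)
      } else {
        tabu <- c(tabu, cand$swaps[k])
        if (length(tabu) > config$tabu_length) {
          tabu <- tabu[-seq_len(length(tabu) - config$tabu_length)]
        }
      }
      trace_cur[iter + 1L] <- f_cur
      trace_opt[iter + 1L] <- f_opt
    }
  })
  trace <- tibble(iteration = 0:config$t_max,
                  f_current = trace_cur, f_best = trace_opt)
  new_tabu_result(aug, opt, f_opt, n, t, config, trace)
}

new_tabu_result <- function(aug, idx, f_opt, n, t, config, trace) {
  structure(
    list(removed = aug$web$species[idx], removed_idx = idx,
         disintegration = f_opt, n = n, threshold = t,
         config = config, trace = trace),
    class = "tabu_result"
  )
}

#' @export
print.tabu_result <- function(x, ...) {
  cat(sprintf("<tabu search> n = %d, t = %g: F = %d, removing {%s}\n",
              x$n, x$threshold, x$disintegration, toString(x$removed)))
  invisible(x)
}

#' @rdname tabu_search
#' @param x a `tabu_result`.
#' @param ... unused.
#' @export
tidy.tabu_result <- function(x, ...) x$trace

#' @rdname tabu_search
#' @export
glance.tabu_result <- function(x, ...) {
  tibble(n = x$n, threshold = x$threshold,
         disintegration = x$disintegration,
         iterations = max(x$trace$iteration),
         seed = x$config$seed)
}

#' Removal curve of the tabu strategy
#'
#' For each removal budget `p = 1..N`, independently optimises the p-species
#' removal set with [tabu_search()] (budget-p seed `xor(seed, p)`) and records
#' the resulting disintegration as `N_p`.  Because the budgets are optimised
#' independently under a finite iteration budget, the raw series is forced
#' monotone by a cumulative maximum (adding a species to the budget can never
#' make the true optimum worse).  Computation stops at the first budget
#' reaching total collapse; the remaining entries are padded with N.
#'
#' @param web a `foodweb` or augmented web.
#' @param t extinction threshold.
#' @param config a [tabu_config()].
#' @param strict_less passed to [simulate_cascade()].
#' @return An [extinction_curve()] with `method = "TS"`.
#' @export
tabu_removal_curve <- function(web, t, config = tabu_config(),
                               strict_less = FALSE) {
  aug <- as_augmented(web)
  n <- n_species(aug)
  counts <- rep(NA_integer_, n)
  best <- 0L
  for (p in seq_len(n)) {
    cfg <- config
    cfg$seed <- bitwXor(config$seed, p)
    res <- tabu_search(aug, p, t, cfg, strict_less)
    best <- max(best, res$disintegration)
    counts[p] <- best
    if (best == n) break
  }
  counts[is.na(counts)] <- n
  extinction_curve(counts, threshold = t, method = "TS")
}
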