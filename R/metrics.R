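#' Secondary-extinction curve
#'
#' Container for the removal-protocol outcome on a web of N species: for each
#' number of primary removals `p = 1..N`, `counts[p]` is the cumulative number
#' of extinct species N_p (primary plus secondary).  Producers pad the series
#' with N after total collapse, so it always has length N with
#' `counts[N] = N`, `counts[p] >= p` and non-decreasing counts.
#'
#' @param counts integer vector of cumulative extinctions, length N.
#' @param threshold extinction threshold the curve was computed at.
#' @param method removal strategy label (e.g. `"ID"`, `"TS"`).
#' @param removed optional character vector of the primarily removed species
#'   in removal order (`NA` once the web has collapsed, or for set-based
#'   protocols).
#' @return An object of class `extinction_curve`.  `tidy()` returns the
#'   per-step tibble, `glance()` a one-row summary including [sea()] and
#'   [r50()].
#' @examples
#' cv <- sequential_removal(fixture_web("chain3"), "ID", t = 0.5)
#' glance(cv)
#' @export
extinction_curve <- function(counts, threshold, method = NA_character_,
                             removed = NULL) {
  counts <- as.integer(counts)
  n <- length(counts)
  if (n < 1L) abort("`counts` must be non-empty.")
  if (anyNA(counts)) abort("`counts` contains NA.")
  if (any(diff(counts) < 0L)) abort("`counts` must be non-decreasing.")
  if (any(counts < seq_len(n)) || any(counts > n)) {
    abort("`counts` must satisfy p <= counts[p] <= N.")
  }
  if (counts[n] != n) {
    abort("`counts` must end at N (pad after total collapse).")
  }
  removed <- removed %||% rep(NA_character_, n)
  structure(
    list(n_species = n, counts = counts, threshold = threshold,
         method = method, removed = removed),
    class = "extinction_curve"
  )
}

#' @export
print.extinction_curve <- function(x, ...) {
  cat(sprintf("<extinction curve> %s, t = %g, N = %d: SEA = %.3f, R50 = %.3f\n",
              x$method, x$threshold, x$n_species, sea(x), r50(x)))
  invisible(x)
}

#' @rdname extinction_curve
#' @param x an `extinction_curve`.
#' @param ... unused.
#' @export
tidy.extinction_curve <- function(x, ...) {
  tibble(p = seq_len(x$n_species), removed = x$removed,
         n_extinct = x$counts,
         prop_primary = seq_len(x$n_species) / x$n_species,
         prop_extinct = x$counts / x$n_species)
}

#' @rdname extinction_curve
#' @export
glance.extinction_curve <- function(x, ...) {
  tibble(method = x$method, threshold = x$threshold,
         n_species = x$n_species, sea = sea(x), r50 = r50(x))
}

#' Secondary extinction area
#'
#' Area between the cumulative secondary-extinction curve and the 1:1 line,
#' \deqn{SEA = \sum_{p=1}^{N} N_p / N^2 - 0.5.}
#' SEA equals 0.5 when every species is extinct after the first primary
#' removal and takes its minimum, `1/(2N)` under this discrete sum, when no
#' secondary extinction ever occurs (the minimum approaches 0 as N grows).
#' Larger SEA means a more destructive removal protocol.
#'
#' @param curve an [extinction_curve()], or a numeric N_p series of length N.
#' @return SEA, a number in `[1/(2N), 0.5]`.
#' @examples
#' sea(extinction_curve(c(3, 3, 3), threshold = 0.5))
#' @export
sea <- function(curve) {
  counts <- curve_counts(curve)
  sum(counts) / length(counts)^2 - 0.5
}

#' R50 robustness index
#'
#' The minimum proportion of primary removals needed to drive the total
#' number of extinct species to at least half the web:
#' `R50 = min{p : N_p >= N/2} / N`.  A count hitting exactly N/2 qualifies.
#' Lower R50 means a less robust web (or a more destructive protocol); the
#' bounds are `1/N` (immediate collapse) and, for even N without secondary
#' extinctions, `0.5`.
#'
#' @inheritParams sea
#' @return R50, a number in `[1/N, 1]`.
#' @export
r50 <- function(curve) {
  counts <- curve_counts(curve)
  n <- length(counts)
  min(which(counts >= n / 2)) / n
}

curve_counts <- function(curve) {
  if (inherits(curve, "extinction_curve")) return(curve$counts)
  if (!is.numeric(curve) || length(curve) < 1L || anyNA(curve)) {
    abort("`curve` must be an extinction_curve or a complete numeric N_p series.")
  }
  n <- length(curve)
  if (curve[n] != n) {
    abort(sprintf(
      "N_p series must be complete: length N with counts[N] = N (got final %g over length %d).",
      curve[n], n))
  }
  curve
}

#' Build the removal curve for any strategy
#'
#' Dispatches to [sequential_removal()] for the centrality strategies and to
#' [tabu_removal_curve()] for `"TS"`.
#'
#' @param web a `foodweb` or augmented web.
#' @param method one of `"OD"`, `"ID"`, `"SD"`, `"PD"`, `"EIG"`, `"TS"`.
#' @param t extinction threshold.
#' @param config [tabu_config()] used when `method = "TS"`.
#' @param ... passed on to [sequential_removal()].
#' @return An [extinction_curve()].
#' @export
removal_curve <- function(web, method, t, config = tabu_config(), ...) {
  if (method == "TS") {
    tabu_removal_curve(web, t, config)
  } else {
    sequential_removal(web, method, t, ...)
  }
}

#' Sweep the extinction threshold
#'
#' Recomputes the removal curve of a strategy over a grid of extinction
#' thresholds (default 5% to 95% by 5%, the 19-point grid) and reports SEA and
#' R50 per threshold and replicate.  Deterministic strategies are computed
#' once per threshold and the value replicated; the stochastic tabu strategy
#' is re-optimised per replicate with seed `base_seed + rep`.
#'
#' @param web a `foodweb` or augmented web.
#' @param method one of `"OD"`, `"ID"`, `"SD"`, `"PD"`, `"EIG"`, `"TS"`.
#' @param t_grid numeric vector of thresholds in (0, 1).
#' @param reps replicates per threshold (only meaningful for `"TS"`).
#' @param config [tabu_config()] for the tabu strategy.
#' @param base_seed integer; per-replicate seeds are `base_seed + rep`.
#' @param ... passed to [sequential_removal()].
#' @return A tibble with columns `method`, `t`, `rep`, `sea`, `r50`.
#' @examples
#' threshold_sweep(fixture_web("chain3"), "ID", t_grid = c(0.25, 0.75))
#' @export
threshold_sweep <- function(web, method, t_grid = seq(0.05, 0.95, by = 0.05),
                            reps = 1L, config = tabu_config(),
                            base_seed = 1L, ...) {
  aug <- as_augmented(web)
  if (any(t_grid <= 0 | t_grid >= 1)) abort("`t_grid` must lie in (0, 1).")
  stochastic <- identical(method, "TS")
  purrr::map_dfr(t_grid, function(tt) {
    if (stochastic) {
      purrr::map_dfr(seq_len(reps), function(r) {
        cfg <- config
        cfg$seed <- base_seed + r
        cv <- tabu_removal_curve(aug, tt, cfg)
        tibble(method = method, t = tt, rep = r, sea = sea(cv), r50 = r50(cv))
      })
    } else {
      cv <- sequential_removal(aug, method, tt, ...)
      tibble(method = method, t = tt, rep = seq_len(reps),
             sea = sea(cv), r50 = r50(cv))
    }
  })
}
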