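#' Generate a synthetic quantitative food web (niche model)
#'
#' Topology from the classical niche model: each species gets a niche value
#' n_i ~ U(0,1) and consumes every species whose niche value falls in an
#' interval of width `r_i = n_i * Beta(1, 1/(2C) - 1)` centred below its own
#' niche value; the species with the smallest niche value is forced basal.
#' The whole web is resampled until the realized binary connectance is within
#' `tol` of `target_c` (the usual practice when generating webs at a fixed
#' connectance).  Cycles and cannibalistic self-links can occur, as in real
#' webs; acyclicity is not enforced.
#'
#' Positive flux weights are drawn from a lognormal law (right-skewed, as
#' empirical carbon-flow distributions are).  Imports go to every basal
#' species and, with probability `import_fraction`, to consumers as well;
#' exports and respiration are positive for every species.
#'
#' @param s species count (>= 2).
#' @param target_c target binary directed connectance in (0, 1); must allow a
#'   connected web (`target_c * s^2 >= s - 1`).
#' @param seed integer RNG seed; the web is a deterministic function of the
#'   parameters and seed.
#' @param weight_meanlog,weight_sdlog lognormal parameters of the flux
#'   weights.
#' @param import_fraction probability that a non-basal species also receives
#'   an import.
#' @param tol acceptable |realized - target| connectance gap.
#' @param max_tries resampling attempts before giving up.
#' @return A [foodweb()].
#' @examples
#' w <- generate_niche_web(20, 0.15, seed = 7)
#' web_summary(w)
#' @export
generate_niche_web <- function(s, target_c, seed = 1L,
                               weight_meanlog = 0, weight_sdlog = 1,
                               import_fraction = 0.1, tol = 0.03,
                               max_tries = 500L) {
  if (s < 2L) abort("`s` must be >= 2.")
  if (target_c <= 0 || target_c >= 1) abort("`target_c` must be in (0, 1).")
  if (target_c * s^2 < s - 1) {
    abort(sprintf(
      "target connectance %.3f is too sparse for %d species (needs C*S^2 >= S-1).",
      target_c, s))
  }
  withr::with_seed(seed, {
    for (try in seq_len(max_tries)) {
      adj <- niche_topology(s, target_c)
      realized <- sum(adj) / s^2
      if (abs(realized - target_c) <= tol) {
        n_links <- sum(adj)
        flows <- matrix(0, s, s)
        flows[adj] <- rlnorm(n_links, weight_meanlog, weight_sdlog)
        basal <- colSums(adj) == 0          # no prey: fed by the environment
        gets_import <- basal | (runif(s) < import_fraction)
        imports <- ifelse(gets_import, rlnorm(s, weight_meanlog, weight_sdlog), 0)
        exports <- rlnorm(s, weight_meanlog - 2, weight_sdlog / 2)
        respiration <- rlnorm(s, weight_meanlog - 2, weight_sdlog / 2)
        return(foodweb(flows, imports = imports, exports = exports,
                       respiration = respiration,
                       name = sprintf("niche_S%d_C%.2f_seed%d", s, target_c, seed)))
      }
    }
    abort(sprintf(
      "could not hit connectance %.3f +/- %.3f within %d tries.",
      target_c, tol, max_tries))
  })
}

# adjacency of one niche-model draw: adj[j, i] TRUE when i consumes j
niche_topology <- function(s, target_c) {
  beta <- 1 / (2 * target_c) - 1
  nv <- runif(s)
  r <- nv * rbeta(s, 1, beta)
  r[which.min(nv)] <- 0                 # guarantee at least one basal species
  centre <- runif(s, r / 2, pmin(nv, 1 - r / 2))
  adj <- matrix(FALSE, s, s)
  for (i in seq_len(s)) {
    if (r[i] > 0) {
      adj[, i] <- nv >= centre[i] - r[i] / 2 & nv <= centre[i] + r[i] / 2
    }
  }
  adj
}

#' Hand-computable fixture webs
#'
#' Tiny webs whose cascade outcomes can be derived by hand; used throughout
#' the test suite and the documentation examples.
#'
#' * `chain3` -- linear chain A -> B -> C (flows 5 and 2), imports
#'   (10, 0, 0), exports (5, 3, 2): baseline inflows (10, 5, 2); removing A at
#'   t = 0.5 collapses the whole chain.
#' * `two_prey` -- consumer D eats A (flow 3) and B (flow 1), imports
#'   (4, 2, 0): removing B at t = 0.5 leaves D at P = 3/4 and kills nobody
#'   else; removing A drops D to P = 1/4 and kills it.
#' * `isolated` -- four species with imports only and no inter-species flow:
#'   no secondary extinction is possible at any t < 1.
#' * `rank_swap` -- imports (12, 2, 7) and one flow A -> B of 8: the
#'   in-degree ranking of B and D swaps once A is removed, separating dynamic
#'   from static scoring.
#'
#' @param name one of `"chain3"`, `"two_prey"`, `"isolated"`, `"rank_swap"`.
#' @return A [foodweb()].
#' @export
fixture_web <- function(name = c("chain3", "two_prey", "isolated",
                                 "rank_swap")) {
  name <- match.arg(name)
  switch(name,
    chain3 = {
      flows <- matrix(0, 3, 3)
      flows[1, 2] <- 5; flows[2, 3] <- 2
      foodweb(flows, imports = c(10, 0, 0), exports = c(5, 3, 2),
              species = c("A", "B", "C"), name = "chain3")
    },
    two_prey = {
      flows <- matrix(0, 3, 3)
      flows[1, 3] <- 3; flows[2, 3] <- 1
      foodweb(flows, imports = c(4, 2, 0), exports = c(1, 1, 4),
              species = c("A", "B", "D"), name = "two_prey")
    },
    isolated = foodweb(matrix(0, 4, 4), imports = c(1, 1, 1, 1),
                       exports = c(1, 1, 1, 1),
                       species = c("A", "B", "C", "D"), name = "isolated"),
    rank_swap = {
      flows <- matrix(0, 3, 3)
      flows[1, 2] <- 8
      foodweb(flows, imports = c(12, 2, 7), exports = c(4, 10, 7),
              species = c("A", "B", "D"), name = "rank_swap")
    }
  )
}

#' Exhaustive optimal removal set (small-web oracle)
#'
#' Enumerates all `choose(N, n)` removal sets and returns one maximising the
#' disintegration F.  The enumeration cost explodes combinatorially, which is
#' exactly why the tabu search exists; this routine is the ground-truth
#' oracle for small webs.  Ties are broken in favour of the lexicographically
#' smallest index set (the enumeration order of `utils::combn`).
#'
#' @param web a `foodweb` or augmented web.
#' @param n removal budget.
#' @param t extinction threshold.
#' @param cap refuse to enumerate more than this many subsets.
#' @param strict_less passed to [simulate_cascade()].
#' @return A list with `removed` (species labels), `removed_idx` and
#'   `disintegration` (the optimum F*).
#' @examples
#' brute_force_optimal_removal(fixture_web("chain3"), n = 1, t = 0.5)
#' @export
brute_force_optimal_removal <- function(web, n, t, cap = 1e6,
                                        strict_less = FALSE) {
  aug <- as_augmented(web)
  n_sp <- n_species(aug)
  if (n < 1L || n > n_sp) abort(sprintf("`n` must be in 1..%d.", n_sp))
  if (choose(n_sp, n) > cap) {
    abort(sprintf(
      "choose(%d, %d) = %g subsets exceeds the cap (%g); use tabu_search().",
      n_sp, n, choose(n_sp, n), cap))
  }
  sets <- combn(n_sp, n)
  f_vals <- apply(sets, 2L, function(idx) {
    disintegration(aug, idx, t, strict_less)
  })
  best <- which.max(f_vals)   # first max = lexicographically smallest set
  idx <- sets[, best]
  list(removed = aug$web$species[idx], removed_idx = idx,
       disintegration = f_vals[best])
}
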