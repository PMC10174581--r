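strategy_names <- c("OD", "ID", "SD", "PD", "EIG", "TS")

#' Weighted degree scores of surviving species
#'
#' Weighted in-degree is the total energy a species receives, weighted
#' out-degree the total energy it passes on, both evaluated on the current
#' surviving sub-web.  By default the environment edges count: imports add to
#' the in-degree and exports plus respiration to the out-degree, since they
#' are part of the augmented graph.  Set `include_env = FALSE` to score the
#' inter-species flows only.
#'
#' @param web a `foodweb` or augmented web.
#' @param alive logical mask of surviving species (default: all alive).
#' @param include_env count environment edges in the degrees.
#' @return A tibble with one row per surviving species: `species`,
#'   `in_degree`, `out_degree`, `sum_degree`, `product_degree`.
#' @examples
#' weighted_degrees(fixture_web("chain3"))
#' @export
weighted_degrees <- function(web, alive = NULL, include_env = TRUE) {
  aug <- as_augmented(web)
  n <- n_species(aug)
  alive <- alive %||% rep(TRUE, n)
  stopifnot(is.logical(alive), length(alive) == n)
  flows <- aug$web$flows
  flows[!alive, ] <- 0
  flows[, !alive] <- 0
  ind <- colSums(flows) + if (include_env) aug$env_out else 0
  outd <- rowSums(flows) + if (include_env) aug$env_in else 0
  tibble(species = aug$web$species[alive],
         in_degree = ind[alive], out_degree = outd[alive],
         sum_degree = (ind + outd)[alive],
         product_degree = (ind * outd)[alive])
}

#' Eigenvector centrality of the surviving flow matrix
#'
#' Dominant-eigenvector scores of the alive sub-web's weighted inter-species
#' flow matrix, computed by power iteration on the transpose of the flow
#' matrix so that a species scores highly when it receives energy from
#' highly scoring species.  Iterates are L1-normalised; convergence tolerance
#' is 1e-10 with at most 1e4 iterations.  On an acyclic (nilpotent) sub-web
#' the iteration can reach the zero vector; the last non-zero normalised
#' iterate is returned.  An all-zero sub-web yields uniform scores.
#'
#' @inheritParams weighted_degrees
#' @return A tibble with `species` and non-negative `score` summing to 1 over
#'   surviving species.
#' @export
eigenvector_scores <- function(web, alive = NULL) {
  aug <- as_augmented(web)
  n <- n_species(aug)
  alive <- alive %||% rep(TRUE, n)
  stopifnot(is.logical(alive), length(alive) == n)
  m <- aug$web$flows[alive, alive, drop = FALSE]
  k <- nrow(m)
  if (k == 0L) abort("no surviving species to score.")
  a <- t(m)
  x <- rep(1 / k, k)
  if (any(a > 0)) {
    for (iter in seq_len(1e4)) {
      x_new <- as.vector(a %*% x)
      s <- sum(x_new)
      if (s == 0) break    # nilpotent sub-web: keep last non-zero iterate
      x_new <- x_new / s
      delta <- max(abs(x_new - x))
      x <- x_new
      if (delta < 1e-10) break
    }
  }
  tibble(species = aug$web$species[alive], score = x)
}

strategy_scores <- function(aug, strategy, alive, include_env) {
  if (strategy == "EIG") {
    sc <- eigenvector_scores(aug, alive)$score
  } else {
    deg <- weighted_degrees(aug, alive, include_env = include_env)
    sc <- switch(strategy, OD = deg$out_degree, ID = deg$in_degree,
                 SD = deg$sum_degree, PD = deg$product_degree)
  }
  # expand back to full length with -Inf for dead species
  full <- rep(-Inf, length(alive))
  full[alive] <- sc
  full
}

#' Sequential removal protocol for a centrality strategy
#'
#' Removes one species per step in decreasing order of a centrality score --
#' weighted out-degree (`OD`), in-degree (`ID`), their sum (`SD`) or product
#' (`PD`), or eigenvector centrality (`EIG`) -- running the extinction cascade
#' at threshold `t` after every removal and recording the cumulative number
#' of extinct species `N_p`.  In the default `dynamic` mode scores are
#' recomputed on the current surviving web at each step; in `static` mode the
#' ranking is fixed on the intact web.  Species already secondarily extinct
#' are never chosen as primary removals; ties go to the lowest species index.
#' Once every species is extinct the count series is padded with N so it
#' always has length N.
#'
#' The tabu-search protocol is provided separately by
#' [tabu_removal_curve()].
#'
#' @param web a `foodweb` or augmented web.
#' @param strategy one of `"OD"`, `"ID"`, `"SD"`, `"PD"`, `"EIG"`.
#' @param t extinction threshold in `[0, 1]`.
#' @param mode `"dynamic"` (rescore each step) or `"static"` (rank once on
#'   the intact web).
#' @param include_env count environment edges in degree scores.
#' @param strict_less passed to [simulate_cascade()].
#' @return An [extinction_curve()] object.
#' @examples
#' sequential_removal(fixture_web("chain3"), "ID", t = 0.5)
#' @export
sequential_removal <- function(web, strategy, t,
                               mode = c("dynamic", "static"),
                               include_env = TRUE, strict_less = FALSE) {
  aug <- as_augmented(web)
  mode <- match.arg(mode)
  if (!strategy %in% setdiff(strategy_names, "TS")) {
    abort(sprintf("unknown strategy '%s'; use one of %s (TS: see tabu_removal_curve).",
                  strategy, toString(setdiff(strategy_names, "TS"))))
  }
  n <- n_species(aug)
  static_scores <- if (mode == "static") {
    strategy_scores(aug, strategy, rep(TRUE, n), include_env)
  }
  alive <- rep(TRUE, n)
  removed <- integer(0)
  counts <- integer(0)
  while (any(alive)) {
    scores <- if (mode == "dynamic") {
      strategy_scores(aug, strategy, alive, include_env)
    } else {
      s <- static_scores
      s[!alive] <- -Inf
      s
    }
    pick <- which.max(scores)   # ties -> lowest index
    removed <- c(removed, pick)
    res <- simulate_cascade(aug, removed, t, strict_less)
    alive <- unname(res$alive)
    counts <- c(counts, res$disintegration)
  }
  p_used <- length(counts)
  extinction_curve(
    counts = c(counts, rep(n, n - p_used)),
    threshold = t, method = strategy,
    removed = c(aug$web$species[removed], rep(NA_character_, n - p_used))
  )
}
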