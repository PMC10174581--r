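#' Simulate a thresholded secondary-extinction cascade
#'
#' Removes the species in `remove` (primary extinctions) and propagates
#' secondary extinctions to the unique fixed point.  A dead species --
#' primarily removed or secondarily extinct -- loses all incident edges.  In
#' each synchronous round the inflow fraction of every surviving species is
#' recomputed as
#' \deqn{P(i) = (imports_i + \sum_{j\,alive} flows_{ji}) / b_i}
#' where `b_i` is the baseline inflow in the intact augmented web, and every
#' species with `P(i) <= t` goes extinct (with `strict_less = TRUE`, only
#' `P(i) < t`).  Because the cascade is monotone the fixed point does not
#' depend on update order; synchronous rounds are used for determinism and
#' speed.  Imports come from the environment node, which never dies, so a
#' species with `imports >= (1 - t) * b` can never go secondarily extinct.
#' Species with zero baseline inflow have `P(i)` defined as 0 and die as soon
#' as a cascade is evaluated.
#'
#' The survivor count `f` counts live species (the environment node is not a
#' species); the disintegration is `F = N - f`, the total number of primary
#' plus secondary extinctions.
#'
#' @param web a `foodweb` or augmented web (plain webs are augmented on the
#'   fly).
#' @param remove species labels or indices to remove primarily (may be
#'   empty).
#' @param t extinction threshold in `[0, 1]`: the minimum fraction of original
#'   energy inflow a species needs to survive.
#' @param strict_less use the strict rule `P(i) < t` instead of the default
#'   `P(i) <= t` (sensitivity checks only).
#' @return An object of class `cascade_result`: a list with `threshold`,
#'   `alive` (named logical), `fractions` (final inflow fractions, 0 for dead
#'   species), `f` (survivors), `disintegration` (F), `n_removed`,
#'   `secondary` (F - n), `rounds` and `removed`.
#' @examples
#' res <- simulate_cascade(fixture_web("chain3"), remove = "A", t = 0.5)
#' glance(res)
#' @export
simulate_cascade <- function(web, remove = character(0), t,
                             strict_less = FALSE) {
  aug <- as_augmented(web)
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0 || t > 1) {
    abort("`t` must be a single number in [0, 1].")
  }
  idx <- resolve_species(aug, remove)
  n <- n_species(aug)
  flows <- aug$web$flows
  imports <- aug$env_out
  b <- aug$baseline_inflow
  alive <- rep(TRUE, n)
  alive[idx] <- FALSE
  fractions <- numeric(n)
  rounds <- 0L
  repeat {
    inflow <- imports + colSums(flows[alive, , drop = FALSE])
    p_frac <- ifelse(b > 0, inflow / b, 0)
    dying <- alive & if (strict_less) p_frac < t else p_frac <= t
    if (!any(dying)) {
      fractions[alive] <- p_frac[alive]
      break
    }
    alive[dying] <- FALSE
    rounds <- rounds + 1L
  }
  f <- sum(alive)
  structure(
    list(threshold = t,
         alive = setNames(alive, aug$web$species),
         fractions = setNames(fractions, aug$web$species),
         f = f,
         disintegration = n - f,
         n_removed = length(idx),
         secondary = n - f - length(idx),
         rounds = rounds,
         removed = aug$web$species[idx]),
    class = "cascade_result"
  )
}

#' Disintegration caused by a removal set
#'
#' Convenience wrapper around [simulate_cascade()] returning only the
#' disintegration `F = f(G0) - f(G)`: the number of species lost, primary
#' removals plus secondary extinctions.  `F >= n` always, with equality when
#' the removal triggers no secondary extinction.  This is the objective
#' maximised by [tabu_search()].
#'
#' @inheritParams simulate_cascade
#' @return integer disintegration count.
#' @examples
#' disintegration(fixture_web("chain3"), remove = "A", t = 0.5)
#' @export
disintegration <- function(web, remove = character(0), t,
                           strict_less = FALSE) {
  simulate_cascade(web, remove, t, strict_less)$disintegration
}

#' @export
print.cascade_result <- function(x, ...) {
  cat(sprintf(
    "<cascade> t = %g: %d removed, %d secondary, %d survive (F = %d, %d rounds)\n",
    x$threshold, x$n_removed, x$secondary, x$f, x$disintegration, x$rounds
  ))
  invisible(x)
}

#' @rdname simulate_cascade
#' @param x a `cascade_result`.
#' @param ... unused.
#' @export
tidy.cascade_result <- function(x, ...) {
  species <- names(x$alive)
  status <- ifelse(species %in% x$removed, "removed",
                   ifelse(x$alive, "alive", "secondary"))
  tibble(species = species, status = status,
         alive = unname(x$alive), fraction = unname(x$fractions))
}

#' @rdname simulate_cascade
#' @export
glance.cascade_result <- function(x, ...) {
  tibble(threshold = x$threshold, n_removed = x$n_removed,
         secondary = x$secondary, survivors = x$f,
         disintegration = x$disintegration, rounds = x$rounds)
}
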