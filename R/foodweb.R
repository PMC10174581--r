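#' Construct a quantitative food web
#'
#' A quantitative food web is a directed network whose nodes are species
#' (or trophic compartments) and whose links carry energy fluxes, typically
#' carbon flows in gC m^-2 day^-1.  `flows[i, j]` is the flux from species
#' `i` (prey) to species `j` (consumer).  Each species additionally exchanges
#' energy with the external environment through imports (environment to
#' species), exports and respiration (species to environment).
#'
#' Cannibalistic self-links (a non-zero diagonal) occur in real webs and are
#' retained; they count as links in the summary statistics.
#'
#' @param flows square numeric matrix of non-negative inter-species fluxes;
#'   rows are sources, columns are targets.
#' @param imports,exports,respiration non-negative numeric vectors, one entry
#'   per species.  Default to zero.
#' @param species character vector of unique species labels; defaults to the
#'   dimnames of `flows` or `sp01`, `sp02`, ...
#' @param name label for the web.
#' @return An object of class `foodweb`.
#' @examples
#' w <- foodweb(
#'   flows = matrix(c(0, 5, 0, 0, 0, 2, 0, 0, 0), 3, 3, byrow = TRUE),
#'   imports = c(10, 0, 0), exports = c(5, 3, 2),
#'   species = c("A", "B", "C"), name = "chain"
#' )
#' w
#' @export
foodweb <- function(flows, imports = NULL, exports = NULL, respiration = NULL,
                    species = NULL, name = "foodweb") {
  flows <- as.matrix(flows)
  if (nrow(flows) != ncol(flows)) {
    abort("`flows` must be a square matrix (one row and column per species).")
  }
  n <- nrow(flows)
  species <- species %||% rownames(flows) %||% sprintf("sp%02d", seq_len(n))
  imports <- expand_env_vector(imports, n, "imports")
  exports <- expand_env_vector(exports, n, "exports")
  respiration <- expand_env_vector(respiration, n, "respiration")
  dimnames(flows) <- list(species, species)
  web <- structure(
    list(name = as.character(name)[1], species = as.character(species),
         flows = unname(flows) , imports = unname(imports),
         exports = unname(exports), respiration = unname(respiration)),
    class = "foodweb"
  )
  validate_foodweb(web)
}

expand_env_vector <- function(x, n, what) {
  if (is.null(x)) x <- 0
  x <- as.numeric(x)
  if (length(x) == 1L) x <- rep(x, n)
  if (length(x) != n) {
    abort(sprintf("`%s` must have one value per species (%d), got %d.",
                  what, n, length(x)))
  }
  x
}

#' Validate a food web object
#'
#' Checks the invariants of the `foodweb` class: a square non-negative finite
#' flow matrix, matching non-negative environment vectors, and unique species
#' labels.  Returns the object invisibly unchanged so it can be used in
#' pipelines.
#'
#' @param web a `foodweb`.
#' @return `web`, invisibly.
#' @export
validate_foodweb <- function(web) {
  if (!inherits(web, "foodweb")) abort("not a `foodweb` object.")
  n <- length(web$species)
  if (n < 1L) abort("a food web needs at least one species.")
  if (anyDuplicated(web$species)) {
    dup <- unique(web$species[duplicated(web$species)])
    abort(sprintf("duplicate species labels: %s.", toString(dup)))
  }
  if (!is.numeric(web$flows) || !identical(dim(web$flows), c(n, n))) {
    abort(sprintf("`flows` must be a numeric %d x %d matrix.", n, n))
  }
  check_nonneg(web$flows, "flows")
  for (f in c("imports", "exports", "respiration")) {
    v <- web[[f]]
    if (!is.numeric(v) || length(v) != n) {
      abort(sprintf("`%s` must be a numeric vector of length %d.", f, n))
    }
    check_nonneg(v, f)
  }
  invisible(web)
}

check_nonneg <- function(x, what) {
  if (anyNA(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` contains missing or non-finite values.", what))
  }
  if (any(x < 0)) abort(sprintf("`%s` contains negative values.", what))
  invisible(x)
}

#' @export
print.foodweb <- function(x, ...) {
  s <- web_summary(x)
  cat(sprintf(
    "<foodweb> %s: %d species, %d links (C = %.3f), total interspecies flow %.4g\n",
    x$name, s$s, s$links, s$connectance, sum(x$flows)
  ))
  invisible(x)
}

#' Number of species in a web
#'
#' @param web a `foodweb` or `foodweb_aug`.
#' @return integer species count (the virtual environment node, when present,
#'   is not counted).
#' @export
n_species <- function(web) {
  if (inherits(web, "foodweb_aug")) web <- web$web
  length(web$species)
}

#' Attach the virtual environment node
#'
#' Augments a food web with a virtual node representing the external
#' environment: edges from the environment to every species carrying the
#' imports, and edges from every species back to the environment carrying
#' exports plus respiration.  The augmented web caches each species' baseline
#' inflow in the intact web, `imports[i] + sum_j flows[j, i]` -- the
#' denominator of the inflow fraction P(i) used by the extinction cascade.
#' The environment node is never removable and never goes extinct.
#'
#' Augmentation is idempotent: augmenting an already augmented web returns it
#' unchanged.  Species whose baseline inflow is zero are flagged with a
#' warning; in cascades their inflow fraction is defined as 0, so they are
#' non-viable as soon as a cascade is evaluated.
#'
#' @param web a `foodweb` (or an already augmented web).
#' @return An object of class `foodweb_aug` with fields `web`, `env_out`
#'   (environment to species weights), `env_in` (species to environment
#'   weights) and `baseline_inflow`.
#' @examples
#' aug <- augment_web(fixture_web("chain3"))
#' aug$baseline_inflow
#' @export
augment_web <- function(web) {
  if (inherits(web, "foodweb_aug")) return(web)
  validate_foodweb(web)
  baseline <- web$imports + colSums(web$flows)
  if (any(baseline == 0)) {
    warn(sprintf(
      "species with zero baseline inflow (non-viable in any cascade): %s",
      toString(web$species[baseline == 0])
    ))
  }
  structure(
    list(web = web, env_out = web$imports,
         env_in = web$exports + web$respiration,
         baseline_inflow = baseline),
    class = "foodweb_aug"
  )
}

#' @export
print.foodweb_aug <- function(x, ...) {
  cat(sprintf("<augmented foodweb> %s: %d species + environment node\n",
              x$web$name, n_species(x)))
  invisible(x)
}

as_augmented <- function(web) {
  if (inherits(web, "foodweb_aug")) web else augment_web(web)
}

# map user-supplied species (labels or indices) to validated integer indices
resolve_species <- function(web, which) {
  if (inherits(web, "foodweb_aug")) web <- web$web
  n <- length(web$species)
  if (is.null(which) || length(which) == 0L) return(integer(0))
  if (is.character(which)) {
    idx <- match(which, web$species)
    if (anyNA(idx)) {
      abort(sprintf("unknown species: %s.", toString(which[is.na(idx)])))
    }
  } else {
    idx <- as.integer(which)
    if (any(idx < 1L | idx > n)) {
      abort(sprintf("species index out of range 1..%d.", n))
    }
  }
  if (anyDuplicated(idx)) abort("duplicated species in removal set.")
  idx
}
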