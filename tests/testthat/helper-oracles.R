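# Independent oracles and fixture builders used across the suite.

# Asynchronous one-at-a-time cascade: kills a single random eligible species
# per step.  Independent of simulate_cascade()'s synchronous rounds; used to
# check that the monotone cascade has an order-independent fixed point.
async_alive <- function(aug, remove, t, seed) {
  aug <- augment_web(aug)
  n <- n_species(aug)
  flows <- aug$web$flows
  imports <- aug$env_out
  b <- aug$baseline_inflow
  alive <- rep(TRUE, n)
  alive[remove] <- FALSE
  set.seed(seed)
  repeat {
    inflow <- imports + colSums(flows[alive, , drop = FALSE])
    p <- ifelse(b > 0, inflow / b, 0)
    victims <- which(alive & p <= t)
    if (!length(victims)) break
    alive[victims[sample.int(length(victims), 1L)]] <- FALSE
  }
  alive
}

# Random web with an exact number of positive inter-species links (used to
# check the connectance arithmetic against published S / link counts).
make_web_with_links <- function(s, links, seed = 1) {
  stopifnot(links <= s^2)
  set.seed(seed)
  flows <- matrix(0, s, s)
  flows[sample.int(s^2, links)] <- runif(links, 0.1, 5)
  foodweb(flows, imports = rep(1, s), exports = rep(0.1, s),
          name = sprintf("rand_%d_%d", s, links))
}

# Linear-scan R50 oracle, independent of r50()'s implementation.
r50_scan <- function(counts) {
  n <- length(counts)
  for (p in seq_len(n)) {
    if (counts[p] >= n / 2) return(p / n)
  }
  stop("curve never reaches N/2")
}

# Hand-computed one-way ANOVA F from the classical decomposition.
anova_f_oracle <- function(values, groups) {
  groups <- as.factor(groups)
  grand <- mean(values)
  k <- nlevels(groups)
  ssb <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  n <- length(values)
  (ssb / (k - 1)) / (ssw / (n - k))
}

expect_foodweb_equal <- function(a, b) {
  expect_identical(a$species, b$species)
  expect_equal(a$flows, b$flows)
  expect_equal(a$imports, b$imports)
  expect_equal(a$exports, b$exports)
  expect_equal(a$respiration, b$respiration)
}
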