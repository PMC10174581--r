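#' Descriptive summary of a food web
#'
#' Returns the species richness S, the number of realized inter-species links
#' C_n (strictly positive flows, cannibalistic self-links included, virtual
#' environment edges excluded), the binary directed connectance C = C_n / S^2,
#' and the weighted directed connectance C_w (see
#' [weighted_connectance()]).
#'
#' @param web a `foodweb` or augmented web.
#' @return A one-row tibble with columns `name`, `s`, `links`, `connectance`,
#'   `weighted_connectance`.
#' @examples
#' web_summary(fixture_web("chain3"))
#' @export
web_summary <- function(web) {
  if (inherits(web, "foodweb_aug")) web <- web$web
  validate_foodweb(web)
  s <- length(web$species)
  links <- sum(web$flows > 0)
  tibble(
    name = web$name,
    s = s,
    links = links,
    connectance = links / s^2,
    weighted_connectance = weighted_connectance(web)
  )
}

#' Weighted directed connectance
#'
#' Quantitative analogue of the binary connectance, based on the effective
#' number of links in the flow distribution: for each species the Shannon
#' entropy (base 2) of its inter-species inflows and of its outflows is
#' converted to an effective link count 2^H (0 for a species with no flows),
#' the quantitative link density is the mean of these effective counts over
#' 2S entries, and C_w is that density divided by S.  When all realized links
#' carry identical weight the effective counts equal the raw counts and
#' C_w reduces to C; in skewed flow distributions C_w < C.
#'
#' Environment edges (imports, exports, respiration) are excluded; the
#' statistic is descriptive only and plays no role in cascades or removal
#' strategies.
#'
#' @param web a `foodweb` or augmented web.
#' @return C_w, a number in `[0, C]`.
#' @export
weighted_connectance <- function(web) {
  if (inherits(web, "foodweb_aug")) web <- web$web
  validate_foodweb(web)
  s <- length(web$species)
  eff_in <- apply(web$flows, 2L, effective_links)
  eff_out <- apply(web$flows, 1L, effective_links)
  sum(eff_in + eff_out) / (2 * s) / s
}

# effective number of links of one flow vector: 2^(Shannon entropy, bits)
effective_links <- function(w) {
  w <- w[w > 0]
  if (!length(w)) return(0)
  p <- w / sum(w)
  2^(-sum(p * log2(p)))
}
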