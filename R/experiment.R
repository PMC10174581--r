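#' Run the strategy-comparison experiment
#'
#' For every combination of web, removal strategy and replicate, builds the
#' removal curve at threshold `t` and records SEA and R50.  Deterministic
#' strategies yield identical rows across replicates (kept so the design is
#' balanced); the tabu strategy is re-optimised per replicate, with replicate
#' seed `base_seed + rep` and per-budget seeds derived inside
#' [tabu_removal_curve()].  Results are only returned if every web loads and
#' validates.
#'
#' @param webs a named list of `foodweb` objects and/or paths to canonical
#'   JSON files.
#' @param methods subset of `c("OD","ID","SD","PD","EIG","TS")`.
#' @param t extinction threshold (default 0.5).
#' @param reps replicates per web and method (default 10).
#' @param config [tabu_config()] for the tabu strategy.
#' @param base_seed integer base seed.
#' @param ... passed to [sequential_removal()].
#' @return An object of class `web_comparison`; `tidy()` gives the per-run
#'   rows `(web, method, rep, sea, r50)`, `summary()` the per-method means
#'   with SD and SEM.
#' @examples
#' cmp <- run_comparison(list(chain = fixture_web("chain3")),
#'                       methods = c("ID", "OD"), reps = 2)
#' summary(cmp)
#' @export
run_comparison <- function(webs, methods = strategy_names, t = 0.5,
                           reps = 10L, config = tabu_config(),
                           base_seed = 1L, ...) {
  if (!length(webs)) abort("`webs` must be a non-empty list.")
  if (!length(methods) || !all(methods %in% strategy_names)) {
    abort(sprintf("`methods` must be a non-empty subset of %s.",
                  toString(strategy_names)))
  }
  if (reps < 1L) abort("`reps` must be >= 1.")
  webs <- load_webs(webs)
  augs <- lapply(webs, augment_web)
  rows <- purrr::imap_dfr(augs, function(aug, web_name) {
    purrr::map_dfr(methods, function(m) {
      if (m == "TS") {
        purrr::map_dfr(seq_len(reps), function(r) {
          cfg <- config
          cfg$seed <- base_seed + r
          cv <- tabu_removal_curve(aug, t, cfg)
          tibble(web = web_name, method = m, rep = r,
                 sea = sea(cv), r50 = r50(cv))
        })
      } else {
        cv <- sequential_removal(aug, m, t, ...)
        tibble(web = web_name, method = m, rep = seq_len(reps),
               sea = sea(cv), r50 = r50(cv))
      }
    })
  })
  structure(list(rows = rows, threshold = t, reps = reps,
                 base_seed = base_seed, config = config),
            class = "web_comparison")
}

load_webs <- function(webs) {
  out <- purrr::imap(webs, function(w, nm) {
    if (inherits(w, "foodweb")) return(w)
    if (is.character(w)) {
      if (!file.exists(w)) abort(sprintf("web file not found: %s", w))
      return(read_foodweb_json(w))
    }
    abort(sprintf("web '%s' is neither a foodweb nor a file path.", nm))
  })
  nms <- names(out) %||% vapply(out, function(w) w$name, character(1))
  nms[!nzchar(nms)] <- vapply(out[!nzchar(nms)], function(w) w$name,
                              character(1))
  setNames(out, nms)
}

#' @export
print.web_comparison <- function(x, ...) {
  cat(sprintf("<web comparison> %d webs x %d methods x %d reps at t = %g\n",
              length(unique(x$rows$web)), length(unique(x$rows$method)),
              x$reps, x$threshold))
  print(summary(x))
  invisible(x)
}

#' @rdname run_comparison
#' @param x,object a `web_comparison`.
#' @export
tidy.web_comparison <- function(x, ...) x$rows

#' @rdname run_comparison
#' @export
glance.web_comparison <- function(x, ...) {
  tibble(n_webs = length(unique(x$rows$web)),
         n_methods = length(unique(x$rows$method)),
         reps = x$reps, threshold = x$threshold)
}

#' @rdname run_comparison
#' @export
summary.web_comparison <- function(object, ...) {
  web_level_means(object$rows) |>
    tidyr::pivot_longer(c("sea", "r50"), names_to = "metric") |>
    group_by(.data$method, .data$metric) |>
    summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
              sem = stats::sd(.data$value) / sqrt(dplyr::n()),
              .groups = "drop")
}

#' Collapse replicate rows to web-level means
#'
#' Averages the per-replicate SEA and R50 over replicates, giving one value
#' per web and method -- the unit of analysis for [one_way_anova()] and
#' [dunnett_vs_control()].
#'
#' @param rows a tibble with columns `web`, `method`, `sea`, `r50` (e.g.
#'   `tidy()` of a [run_comparison()] result).
#' @return A tibble with one row per `(web, method)`.
#' @export
web_level_means <- function(rows) {
  rows |>
    group_by(.data$web, .data$method) |>
    summarise(sea = mean(.data$sea), r50 = mean(.data$r50),
              .groups = "drop")
}

#' One-way ANOVA across removal strategies
#'
#' Classical one-way analysis of variance (between/within decomposition,
#' `F = MSB/MSW`) of a metric across strategy groups, fitted with
#' [stats::aov()].  The intended input is one value per web and method --
#' replicate averages, as produced by `summary()`/[web_level_means] of a
#' comparison -- so k methods over m webs give `df = (k - 1, k m - k)`.
#' When every group is constant the F statistic is undefined and the result
#' is flagged degenerate.
#'
#' @param data a data frame.
#' @param value name of the numeric response column.
#' @param group name of the grouping column.
#' @return One-row tibble: `statistic` (F), `df`, `df_residual`, `p_value`,
#'   `degenerate`.
#' @examples
#' df <- data.frame(g = rep(c("a", "b"), each = 2), y = c(0, 1, 2, 3))
#' one_way_anova(df, "y", "g")
#' @export
one_way_anova <- function(data, value = "sea", group = "method") {
  y <- data[[value]]
  g <- factor(data[[group]])
  if (nlevels(g) < 2L) abort("need at least two groups.")
  if (any(table(g) < 2L)) abort("every group needs at least two values.")
  fit <- aov(y ~ g)
  tab <- summary(fit)[[1L]]
  f_stat <- tab$`F value`[1L]
  degenerate <- !is.finite(f_stat)
  tibble(statistic = f_stat, df = tab$Df[1L], df_residual = tab$Df[2L],
         p_value = if (degenerate) NA_real_ else tab$`Pr(>F)`[1L],
         degenerate = degenerate)
}

#' Dunnett many-to-one contrasts against a control strategy
#'
#' Compares every strategy's mean metric to the control strategy (TS by
#' default) with Dunnett's simultaneous many-to-one procedure: mean
#' differences `mean(group) - mean(control)` with two-sided simultaneous
#' confidence intervals and single-step adjusted p values, via
#' [multcomp::glht()] on a one-way [stats::aov()] fit.  The underlying
#' multivariate-t quantile is evaluated by seeded Monte Carlo integration, so
#' results are reproducible; in a balanced design all intervals share one
#' half-width.
#'
#' @inheritParams one_way_anova
#' @param control level of `group` used as the control.
#' @param conf_level simultaneous confidence level.
#' @param seed seed for the quantile integration.
#' @return A tibble with one row per non-control group: `method`, `estimate`
#'   (mean difference to control), `conf_low`, `conf_high`, `p_adjusted`, and
#'   a display `significance` band (`"<0.01"`, `"<0.05"` or the rounded p).
#' @examples
#' df <- data.frame(m = rep(c("TS", "OD"), each = 3),
#'                  y = c(5, 6, 7, 1, 2, 3))
#' dunnett_vs_control(df, "y", "m", control = "TS")
#' @export
dunnett_vs_control <- function(data, value = "sea", group = "method",
                               control = "TS", conf_level = 0.95,
                               seed = 1L) {
  y <- data[[value]]
  g <- factor(data[[group]])
  if (!control %in% levels(g)) {
    abort(sprintf("control group '%s' not present.", control))
  }
  if (nlevels(g) < 2L) abort("need at least two groups.")
  g <- stats::relevel(g, ref = control)
  fit <- aov(y ~ g)
  glht_fit <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
  withr::with_seed(seed, {
    ci <- stats::confint(glht_fit, level = conf_level)$confint
    p_adj <- summary(glht_fit)$test$pvalues
  })
  comparisons <- sub(" - .*$", "", rownames(ci))
  tibble(
    method = comparisons,
    control = control,
    estimate = unname(ci[, "Estimate"]),
    conf_low = unname(ci[, "lwr"]),
    conf_high = unname(ci[, "upr"]),
    p_adjusted = as.numeric(p_adj),
    significance = dplyr::case_when(
      p_adj < 0.01 ~ "<0.01",
      p_adj < 0.05 ~ "<0.05",
      .default = sprintf("%.2f", p_adj)
    )
  )
}

#' Published benchmark SEA table
#'
#' Secondary-extinction areas (t = 0.5, replicate averages) reported for
#' twelve empirical estuarine, marine and wetland carbon-flow webs under the
#' six removal strategies.  Shipped as a regression fixture for the
#' comparison statistics.
#'
#' @return A tibble with columns `web`, `method`, `sea` (72 rows).
#' @examples
#' sea_benchmark() |> dplyr::group_by(method) |>
#'   dplyr::summarise(mean_sea = mean(sea))
#' @export
sea_benchmark <- function() {
  webs <- c("Crystal River", "Swartkops Estuary", "Okefenokee Swamp",
            "Neuse Estuary", "Gulf of Maine", "Middle Atlantic Bight",
            "Chesapeake Bay", "Graminoids", "Cypress", "Lake Oneida",
            "Mangroves", "Florida Bay")
  vals <- list(
    OD  = c(0.374, 0.267, 0.246, 0.149, 0.281, 0.283, 0.279, 0.378, 0.297,
            0.294, 0.326, 0.307),
    ID  = c(0.322, 0.283, 0.274, 0.200, 0.249, 0.243, 0.265, 0.301, 0.304,
            0.248, 0.317, 0.287),
    SD  = c(0.315, 0.272, 0.281, 0.190, 0.272, 0.260, 0.300, 0.364, 0.301,
            0.294, 0.336, 0.309),
    PD  = c(0.376, 0.291, 0.262, 0.171, 0.281, 0.267, 0.272, 0.327, 0.315,
            0.263, 0.327, 0.306),
    EIG = c(0.302, 0.130, 0.179, 0.082, 0.217, 0.193, 0.233, 0.348, 0.281,
            0.217, 0.274, 0.223),
    TS  = c(0.415, 0.363, 0.361, 0.320, 0.373, 0.359, 0.398, 0.420, 0.410,
            0.393, 0.415, 0.391)
  )
  purrr::imap_dfr(vals, function(v, m) tibble(web = webs, method = m, sea = v))
}

#' Published benchmark web characteristics
#'
#' Species richness, link counts and (weighted) connectance reported for the
#' same twelve empirical webs as [sea_benchmark()].
#'
#' @return A tibble with columns `web`, `s`, `links`, `connectance`,
#'   `weighted_connectance`.
#' @export
connectance_benchmark <- function() {
  tibble(
    web = c("Crystal River", "Swartkops Estuary", "Okefenokee Swamp",
            "Neuse Estuary", "Gulf of Maine", "Middle Atlantic Bight",
            "Chesapeake Bay", "Graminoids", "Cypress", "Lake Oneida",
            "Mangroves", "Florida Bay"),
    s = c(21L, 25L, 26L, 30L, 31L, 32L, 36L, 66L, 68L, 74L, 94L, 125L),
    links = c(61L, 104L, 132L, 77L, 332L, 375L, 122L, 793L, 554L, 1220L,
              1339L, 1969L),
    connectance = c(0.138, 0.166, 0.195, 0.086, 0.345, 0.366, 0.094, 0.182,
                    0.120, 0.223, 0.152, 0.126),
    weighted_connectance = c(0.074, 0.090, 0.077, 0.057, 0.148, 0.156,
                             0.068, 0.033, 0.058, 0.073, 0.036, 0.032)
  )
}
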