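#' Labour-demand schedule
#'
#' Total labour demand (all jobs, occupied plus vacant) is a fixed
#' country-specific ratio of population size, optionally scaled by a
#' time-varying multiplier (sensitivity and automation hook). Its split over
#' the three skill groups follows a fitted logit-linear trend
#' (see [fit_share_trend()]).
#'
#' @param ratios Tibble `region, ratio` of jobs per person.
#' @param trend A `share_trend` fit from [fit_share_trend()].
#' @param ratio_shift Function of year returning the demand multiplier
#'   (default constantly 1).
#' @return A `demand_schedule`.
#' @export
demand_schedule <- function(ratios, trend, ratio_shift = function(year) 1) {
  if (any(ratios$ratio <= 0)) abort("demand/population ratios must be positive")
  structure(list(ratios = as_tibble(ratios), trend = trend,
                 ratio_shift = ratio_shift),
            class = "demand_schedule")
}

#' Total labour demand for a region-year
#'
#' @param population_size Population (agents or persons; demand is returned in
#'   the same unit).
#' @param schedule A [demand_schedule()].
#' @param region Region identifier.
#' @param year Calendar year.
#' @return Total jobs demanded.
#' @export
total_demand <- function(population_size, schedule, region, year) {
  stopifnot(population_size >= 0)
  r <- schedule$ratios$ratio[schedule$ratios$region == region]
  if (length(r) != 1L) abort(paste0("no demand ratio for region ", region))
  population_size * r * schedule$ratio_shift(year)
}

#' Fit the skill-share trend of labour demand
#'
#' Fits two log-ratio linear regressions against the medium-skill reference,
#' `log(share_high/share_medium)` and `log(share_low/share_medium)`, each
#' linear in year with additive region offsets when several regions are
#' supplied (a generalized-logit trend for compositional data). Projections
#' invert the fit and renormalize onto the simplex.
#'
#' @param history Tibble `region, year, share_high, share_medium, share_low`
#'   with at least 3 years of simplex-valued shares.
#' @param clamp Shares are clamped to `[clamp, 1 - clamp]` before the log
#'   transform.
#' @return A `share_trend` object with components `fit_high`, `fit_low`
#'   (lm fits), and `residuals` for diagnostics.
#' @export
fit_share_trend <- function(history, clamp = 1e-6) {
  h <- as_tibble(history)
  if (length(unique(h$year)) < 3L) abort("need at least 3 years of shares")
  s <- as.matrix(h[, c("share_high", "share_medium", "share_low")])
  if (any(s == 0)) abort("zero shares in history: log-ratio undefined")
  if (any(abs(rowSums(s) - 1) > 1e-6)) abort("history shares must sum to 1")
  s <- pmin(pmax(s, clamp), 1 - clamp)
  d <- tibble(region = factor(h$region), year = h$year,
              lr_high = log(s[, 1] / s[, 2]),
              lr_low = log(s[, 3] / s[, 2]))
  fml <- if (nlevels(d$region) > 1L) {
    list(h = lr_high ~ year + region, l = lr_low ~ year + region)
  } else {
    list(h = lr_high ~ year, l = lr_low ~ year)
  }
  fit_high <- stats::lm(fml$h, data = d)
  fit_low <- stats::lm(fml$l, data = d)
  structure(list(fit_high = fit_high, fit_low = fit_low,
                 regions = levels(d$region),
                 years = range(h$year),
                 residuals = tibble(region = h$region, year = h$year,
                                    resid_high = stats::resid(fit_high),
                                    resid_low = stats::resid(fit_low))),
            class = "share_trend")
}

#' Project demand shares from a fitted trend
#'
#' @param trend A `share_trend` fit.
#' @param region Region identifier.
#' @param year Year (vectorized).
#' @return Tibble `region, year, share_high, share_medium, share_low`
#'   (each row on the simplex).
#' @export
project_shares <- function(trend, region, year) {
  nd <- tibble(year = year,
               region = factor(rep(region, length.out = length(year)),
                               levels = trend$regions))
  eh <- unname(exp(stats::predict(trend$fit_high, nd)))
  el <- unname(exp(stats::predict(trend$fit_low, nd)))
  tot <- 1 + eh + el
  tibble(region = as.character(nd$region), year = year,
         share_high = eh / tot, share_medium = 1 / tot, share_low = el / tot)
}

#' Project skill-specific labour demand
#'
#' Multiplies the projected share split by total demand.
#'
#' @inheritParams total_demand
#' @return One-row tibble `region, year, total, dem_high, dem_medium,
#'   dem_low`.
#' @export
project_demand <- function(population_size, schedule, region, year) {
  tot <- total_demand(population_size, schedule, region, year)
  sh <- project_shares(schedule$trend, region, year)
  tibble(region = region, year = year, total = tot,
         dem_high = tot * sh$share_high,
         dem_medium = tot * sh$share_medium,
         dem_low = tot * sh$share_low)
}

#' @describeIn fit_share_trend Tidy both log-ratio fits.
#' @param x,object A `share_trend`.
#' @param ... Unused.
#' @export
tidy.share_trend <- function(x, ...) {
  one <- function(fit, which) {
    cf <- summary(fit)$coefficients
    tibble(ratio = which, term = rownames(cf), estimate = cf[, 1],
           std.error = cf[, 2])
  }
  bind_rows(one(x$fit_high, "high_vs_medium"), one(x$fit_low, "low_vs_medium"))
}

#' @describeIn fit_share_trend One-row summary with in-sample fit.
#' @export
glance.share_trend <- function(x, ...) {
  tibble(r.squared_high = summary(x$fit_high)$r.squared,
         r.squared_low = summary(x$fit_low)$r.squared,
         n_years = diff(x$years) + 1,
         sigma_high = summary(x$fit_high)$sigma,
         sigma_low = summary(x$fit_low)$sigma)
}
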