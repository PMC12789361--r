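#' Stylized-EU parameter bundle
#'
#' Generates a fully self-contained parameter bundle for a three-region
#' stylized European population, calibrated so that the module-level
#' aggregates reproduce the headline projection assumptions:
#' a total fertility rate path of 1.51 / 1.58 / 1.64 (2020-24 / 2035-39 /
#' 2055-59), female/male life expectancy of 83.5/77.6 rising to 91.2/85.6,
#' education shares at ages 30-34 of 12.96/47.88/39.15 (2020) trending toward
#' 7.74/39.75/52.50 (2060), labour-force participation of 38.6/85.3/36.3 per
#' broad age group (2020), 5-year external immigration of 15,272,419 and
#' emigration of 7,279,140 persons (2020-24), and demand/population ratios
#' in \[0.4, 0.6\] with an optional configurable outlier. Occupation-model
#' coefficients are chosen to reproduce the documented sign structure
#' (education and age gradients, immigrant penalties narrowing with duration,
#' demand effects reducing unemployment); they are synthetic values, not
#' estimates from survey data.
#'
#' Calibrations are deterministic: life-table level search for mortality,
#' exact scaling for fertility, threshold root-finding for education, and
#' baseline root-finding for participation against a large synthetic
#' calibration population drawn at the bundle seed.
#'
#' @param agents Number of agents in the base population.
#' @param seed Bundle seed (base-population synthesis and calibration).
#' @param total_persons Persons represented (sets the agent scale factor).
#' @param outlier_region Optional region receiving `outlier_ratio` as its
#'   demand/population ratio (emulating a cross-border labour market).
#' @param outlier_ratio Ratio for the outlier region.
#' @param calib_size Size of the synthetic calibration population used to
#'   pin the participation baselines (larger is more precise).
#' @return A `skillsim_bundle` list understood by [run_projection()].
#' @export
stylized_bundle <- function(agents = 200000L, seed = 1234L,
                            total_persons = 446.8e6,
                            outlier_region = NULL, outlier_ratio = 0.77,
                            calib_size = 500000L) {
  regions <- c("north", "central", "south")
  region_share <- c(north = 0.45, central = 0.33, south = 0.22)
  scale_factor <- total_persons / agents
  year0 <- 2020L
  periods <- seq(2020L, 2060L, by = 5L)

  ## --- education model: anchor 2020 shares at 30-34, trend to 2060 ---
  tgt20 <- c(low = 0.1296, medium = 0.4788, high = 0.3915)
  tgt60 <- c(low = 0.0774, medium = 0.3975, high = 0.5250)
  slope <- mean(c(qlogis(tgt20["low"]) - qlogis(tgt60["low"]),
                  qlogis(tgt20["low"] + tgt20["medium"]) -
                    qlogis(tgt60["low"] + tgt60["medium"]))) / 40
  region_edu_off <- c(north = 0.15, central = 0, south = -0.15)
  beta_sex_female <- 0.10
  # mixture cells used for threshold calibration: region x sex at the
  # reference cohort (mother unknown)
  mix_lp <- as.vector(outer(region_edu_off[regions],
                            c(female = beta_sex_female, male = 0), `+`))
  mix_w <- as.vector(outer(region_share[regions], c(0.5, 0.5), `*`))
  t1 <- uniroot(function(t) sum(mix_w * plogis(t - mix_lp)) - tgt20["low"],
                c(-10, 10), tol = 1e-12)$root
  t2 <- uniroot(function(t) sum(mix_w * plogis(t - mix_lp)) -
                  (tgt20["low"] + tgt20["medium"]),
                c(-10, 10), tol = 1e-12)$root
  education <- education_params(
    thresholds = c(t1, t2), beta_cohort = slope, cohort_ref = 1988,
    cohort_plateau = 2035, beta_sex_female = beta_sex_female,
    beta_mother = c(low = -0.25, medium = 0, high = 0.25, unknown = 0),
    region_offsets = region_edu_off)

  ## --- base-population marginals ---
  age_groups <- paste0(seq(0, 95, 5), "-", seq(4, 99, 5))
  age_w <- c(4.8, 5.1, 5.2, 5.3, 5.4, 5.7, 6.0, 6.5, 6.9, 7.2, 7.4, 7.0,
             6.4, 5.6, 5.0, 4.0, 3.0, 1.8, 0.8, 0.2)
  age_w <- age_w / sum(age_w)
  origin_adult <- c(native = 0.84, other_region = 0.04,
                    ext_A = 0.03, ext_B = 0.09)
  origin_child <- c(native = 0.95, other_region = 0.01,
                    ext_A = 0.01, ext_B = 0.03)
  marg <- purrr::map_dfr(seq_along(age_groups), function(gi) {
    mid <- 5 * (gi - 1) + 2
    child <- mid < 15
    orig <- if (child) origin_child else origin_adult
    purrr::map_dfr(regions, function(r) {
      purrr::map_dfr(c("female", "male"), function(s) {
        if (child) {
          edu_share <- c(none = 1)
        } else {
          pr <- education_probabilities(year0 - mid, s, "unknown", r,
                                        education)
          edu_share <- drop(pr)
        }
        tidyr::expand_grid(education = names(edu_share),
                           origin = names(orig)) %>%
          mutate(region = r, sex = s, age_group = age_groups[gi],
                 share = region_share[r] * 0.5 * age_w[gi] *
                   edu_share[.data$education] * orig[.data$origin])
      })
    })
  }) %>%
    select("region", "age_group", "sex", "education", "origin", "share")
  marg$share <- marg$share / sum(marg$share)
  base_spec <- base_population_spec(agents, scale_factor, marg, seed = seed,
                                    year = year0)

  ## --- mortality: Gompertz-Makeham level calibrated to the e0 path ---
  e0_target <- list(
    female = interp_path(c(2020, 2035, 2055), c(83.5, 87.0, 91.2), periods),
    male = interp_path(c(2020, 2035, 2055), c(77.6, 81.4, 85.6), periods))
  edu_rr <- c(low = 1.25, medium = 1, high = 0.82)
  ages <- 0:AGE_CAP
  makeham_q <- function(level, sex) {
    b0 <- if (sex == "female") 2.0e-5 else 3.5e-5
    h <- 2e-4 + level * b0 * exp(0.105 * ages)
    h[1] <- h[1] + 0.0025
    q <- 1 - exp(-h)
    q[length(q)] <- 1
    q
  }
  q_rows <- purrr::map_dfr(seq_along(periods), function(pi) {
    purrr::map_dfr(c("female", "male"), function(s) {
      lev <- uniroot(function(lg) {
        life_table_e0(makeham_q(exp(lg), s)) - e0_target[[s]][pi]
      }, c(-6, 6), tol = 1e-10)$root
      purrr::map_dfr(names(edu_rr), function(e) {
        h <- -log(1 - makeham_q(exp(lev), s))
        q <- 1 - exp(-h * edu_rr[e])
        q[length(q)] <- 1
        tibble(period_start = periods[pi], age = ages, sex = s,
               education = e, q = q)
      })
    })
  })
  mortality <- mortality_schedule(q_rows)

  ## --- fertility: gamma age pattern scaled to the TFR path ---
  tfr_path <- interp_path(c(2020, 2035, 2055), c(1.51, 1.58, 1.64), periods)
  fert_ages <- 15:49
  w <- dgamma(fert_ages - 14, shape = 6, rate = 0.35)
  w <- w / sum(w)
  fert_rr <- c(low = 1.12, medium = 1, high = 0.92)
  f_rows <- purrr::map_dfr(seq_along(periods), function(pi) {
    purrr::map_dfr(names(fert_rr), function(e) {
      tibble(period_start = periods[pi], age = fert_ages, education = e,
             f = pmin(1, w * tfr_path[pi] * fert_rr[e]))
    })
  })
  fertility <- fertility_schedule(f_rows, sex_ratio = 105)

  ## --- migration ---
  imm_5y <- c(15272419, 12726958, 12395784)
  annual_inflow <- interp_path(c(2020, 2035, 2055), imm_5y / 5, periods)
  ext_split <- c(ext_A = 0.25, ext_B = 0.75)
  inflow <- tidyr::expand_grid(year = 2020:2061, region = regions,
                               origin = names(ext_split)) %>%
    mutate(persons = annual_inflow[match(period_of(periods, .data$year),
                                         periods)] *
             region_share[.data$region] * ext_split[.data$origin])
  inflow_age <- tibble(
    age_group = c("0-14", "15-19", "20-24", "25-29", "30-34", "35-39",
                  "40-49", "50-64", "65-79"),
    share = c(0.15, 0.08, 0.15, 0.18, 0.14, 0.10, 0.12, 0.06, 0.02))
  inflow_education <- bind_rows(
    tibble(origin = "ext_A", education = c("low", "medium", "high"),
           share = c(0.10, 0.35, 0.55)),
    tibble(origin = "ext_B", education = c("low", "medium", "high"),
           share = c(0.35, 0.40, 0.25)))
  em_base <- tidyr::expand_grid(
    origin_class = c("native", "other_region", "external"),
    age_group = c("0-14", "15-39", "40-64", "65+")) %>%
    mutate(rate = c(0.0010, 0.0030, 0.0015, 0.0005,
                    0.0100, 0.0200, 0.0120, 0.0050,
                    0.0080, 0.0150, 0.0100, 0.0040))
  # scale emigration so the expected 2020 outflow matches the 5-year figure
  mcls <- ifelse(marg$origin %in% c("native", "other_region"),
                 marg$origin, "external")
  mage <- emigration_age_band(as.integer(sub("-.*", "", marg$age_group)) + 2L)
  mrate <- em_base$rate[match(paste(mcls, mage),
                              paste(em_base$origin_class, em_base$age_group))]
  expected_out <- sum(marg$share * mrate) * total_persons
  em_base$rate <- em_base$rate * (7279140 / 5) / expected_out
  od_rates <- tidyr::expand_grid(from_region = regions, to_region = regions,
                                 origin_class = c("native", "other_region",
                                                  "external")) %>%
    filter(.data$from_region != .data$to_region) %>%
    mutate(rate_start = c(native = 0.0012, other_region = 0.0150,
                          external = 0.0040)[.data$origin_class] / 2,
           rate_target = c(native = 0.0020, other_region = 0.0150,
                           external = 0.0040)[.data$origin_class] / 2)
  migration <- migration_schedule(inflow, inflow_age, inflow_education,
                                  em_base, od_rates,
                                  convergence_year = 2050, start_year = 2020)

  ## --- labour-force participation, baselines calibrated on a synthetic
  ##     calibration population ---
  lfp0 <- lfp_params(
    age_baseline = c("15-19" = -1.3, "20-24" = 0.7, "25-29" = 1.6,
                     "30-34" = 1.7, "35-39" = 1.75, "40-44" = 1.8,
                     "45-49" = 1.75, "50-54" = 1.6, "55-59" = 1.2,
                     "60-64" = 0.2, "65-69" = -1.6, "70-74" = -2.6),
    beta_edu = c(low = -0.6, medium = 0, high = 0.45),
    beta_sex_female = -0.25,
    beta_origin = c(native = 0, other_region = -0.05,
                    ext_A = -0.10, ext_B = -0.50),
    beta_recent = -0.8, beta_child_arrival = 0.35,
    beta_cohort = 0, cohort_ref = 1980)
  lfp <- calibrate_lfp_baselines(
    lfp0, base_spec,
    targets = c("15-24" = 0.386, "25-54" = 0.853, "55-74" = 0.363),
    calib_size = calib_size)

  ## --- occupation model: documented synthetic sign structure ---
  terms <- c("(Intercept)", "sex_female", "edu", "sex_female:edu",
             "agegr", "agegr2", "dem_high", "dem_lowmed",
             "other_region", "ext_A_recent", "ext_A_settled",
             "ext_B_recent", "ext_B_settled", "ext_child",
             "ext_B_recent:edu", "ext_B_settled:edu",
             "ext_B_recent:sex_female")
  beta <- rbind(
    `(Intercept)` = c(-1.00, 0.60, -1.50),
    sex_female = c(0.10, -0.05, -0.15),
    edu = c(-0.45, 0.25, 1.30),
    `sex_female:edu` = c(-0.05, 0.00, 0.05),
    agegr = c(0.28, 0.32, 0.50),
    agegr2 = c(-0.020, -0.022, -0.028),
    dem_high = c(0.50, 0.80, 2.60),
    dem_lowmed = c(1.90, 2.30, 0.70),
    other_region = c(-0.05, -0.10, -0.15),
    ext_A_recent = c(-0.25, -0.35, -0.60),
    ext_A_settled = c(-0.08, -0.12, -0.20),
    ext_B_recent = c(-0.45, -0.85, -1.50),
    ext_B_settled = c(-0.20, -0.35, -0.60),
    ext_child = c(-0.03, -0.05, -0.08),
    `ext_B_recent:edu` = c(0.00, -0.05, -0.25),
    `ext_B_settled:edu` = c(0.00, -0.02, -0.10),
    `ext_B_recent:sex_female` = c(-0.10, -0.15, -0.25))
  colnames(beta) <- c("L", "M", "H")
  occupation <- occupation_coefficients(beta[terms, ])
  occupation_targets <- bind_rows(
    tibble(region = "north", outcome = OCC_LEVELS,
           share = c(0.060, 0.075, 0.445, 0.420)),
    tibble(region = "central", outcome = OCC_LEVELS,
           share = c(0.067, 0.085, 0.465, 0.383)),
    tibble(region = "south", outcome = OCC_LEVELS,
           share = c(0.075, 0.095, 0.485, 0.345)))

  ## --- labour demand: fixed ratios and a logit-linear share trend fitted
  ##     to a synthetic 2010-2019 history ---
  # region ratios average (population-weighted) to ~0.46 jobs per person,
  # the aggregate demand-to-population level implied by ~206.5M jobs for
  # ~446.8M persons in the base year
  ratios <- tibble(region = regions,
                   ratio = unname(c(north = 0.50, central = 0.45,
                                    south = 0.41)[regions]))
  if (!is.null(outlier_region)) {
    ratios$ratio[ratios$region == outlier_region] <- outlier_ratio
  }
  sh20 <- c(high = 0.4194, medium = 0.4881, low = 0.0925)
  sh60 <- c(high = 0.5491, medium = 0.3650, low = 0.0859)
  bH <- (log(sh60["high"] / sh60["medium"]) -
           log(sh20["high"] / sh20["medium"])) / 40
  bL <- (log(sh60["low"] / sh60["medium"]) -
           log(sh20["low"] / sh20["medium"])) / 40
  aH <- log(sh20["high"] / sh20["medium"]) - bH * 2020
  aL <- log(sh20["low"] / sh20["medium"]) - bL * 2020
  offH <- c(north = 0.08, central = 0, south = -0.08)
  offL <- c(north = -0.05, central = 0, south = 0.05)
  demand_history <- tidyr::expand_grid(region = regions, year = 2010:2019) %>%
    mutate(eh = exp(aH + bH * .data$year + offH[.data$region]),
           el = exp(aL + bL * .data$year + offL[.data$region]),
           share_high = .data$eh / (1 + .data$eh + .data$el),
           share_medium = 1 / (1 + .data$eh + .data$el),
           share_low = .data$el / (1 + .data$eh + .data$el)) %>%
    select("region", "year", "share_high", "share_medium", "share_low")
  trend <- fit_share_trend(demand_history)
  demand <- demand_schedule(ratios, trend)

  structure(list(
    regions = regions, region_share = region_share, year0 = year0,
    agents = agents, seed = seed, scale_factor = scale_factor,
    base_spec = base_spec, mortality = mortality, fertility = fertility,
    migration = migration, education = education, lfp = lfp,
    occupation = occupation, occupation_targets = occupation_targets,
    demand = demand, demand_history = demand_history,
    benchmark_50plus = benchmark_lfp_50plus()),
    class = "skillsim_bundle")
}

#' @export
print.skillsim_bundle <- function(x, ...) {
  cat("<skillsim_bundle> stylized 3-region bundle:",
      x$agents, "agents (x", format(round(x$scale_factor)), "persons), base year",
      x$year0, "\n")
  invisible(x)
}

# solve a per-broad-age-group shift of the LFP baselines so that expected
# participation on a synthetic calibration population matches the targets
calibrate_lfp_baselines <- function(params, base_spec, targets,
                                    calib_size = 500000L) {
  spec <- base_spec
  spec$size <- as.integer(calib_size)
  spec$seed <- base_spec$seed + 7L
  pop <- synthesize_base_population(spec)$individuals
  pop$broad <- broad_age_group(pop$age)
  groups <- list("15-24" = c("15-19", "20-24"),
                 "25-54" = c("25-29", "30-34", "35-39", "40-44", "45-49",
                             "50-54"),
                 "55-74" = c("55-59", "60-64", "65-69", "70-74"))
  for (g in names(groups)) {
    inb <- !is.na(pop$broad) & pop$broad == g
    elig <- inb & !pop$in_school
    sub <- pop[elig, ]
    n_all <- sum(inb)
    shift <- uniroot(function(d) {
      p2 <- params
      p2$age_baseline[groups[[g]]] <- p2$age_baseline[groups[[g]]] + d
      sum(lfp_probability(sub, p2)) / n_all - targets[g]
    }, c(-8, 8), tol = 1e-10)$root
    params$age_baseline[groups[[g]]] <-
      params$age_baseline[groups[[g]]] + shift
  }
  params
}

#' Verify a bundle against its calibration targets
#'
#' Recomputes each headline aggregate with the module-level operations
#' (implied TFR, life-table e0, marginal education shares at 30-34, expected
#' participation, scheduled migration volumes, demand ratio range) and
#' tabulates it against the target.
#'
#' @param bundle A [stylized_bundle()].
#' @return Tibble `quantity, target, value`.
#' @export
fixture_verification <- function(bundle) {
  m <- bundle$base_spec$marginals
  at3034 <- m[m$age_group == "30-34", ]
  edu_sh <- tapply(at3034$share, at3034$education, sum) / sum(at3034$share)
  inflow5 <- sum(bundle$migration$inflow$persons[
    bundle$migration$inflow$year %in% 2020:2024])
  spec <- bundle$base_spec
  spec$size <- 200000L
  pop <- synthesize_base_population(spec)$individuals
  pop$broad <- broad_age_group(pop$age)
  lfp_exp <- vapply(c("15-24", "25-54", "55-74"), function(g) {
    inb <- !is.na(pop$broad) & pop$broad == g
    sum(lfp_probability(pop[inb & !pop$in_school, ], bundle$lfp)) / sum(inb)
  }, 0)
  tibble(
    quantity = c("tfr_2020_24", "e0_female_2020_24", "e0_male_2020_24",
                 "edu_low_30_34_2020", "edu_medium_30_34_2020",
                 "edu_high_30_34_2020", "lfp_15_24_2020", "lfp_25_54_2020",
                 "lfp_55_74_2020", "immigrants_5y_2020_24",
                 "demand_ratio_min", "demand_ratio_max"),
    target = c(1.51, 83.5, 77.6, 12.96, 47.88, 39.15, 38.6, 85.3, 36.3,
               15272419, 0.4, 0.6),
    value = c(implied_tfr(bundle$fertility, period = 2020),
              life_expectancy_of(bundle$mortality, "female", period = 2020),
              life_expectancy_of(bundle$mortality, "male", period = 2020),
              100 * edu_sh[["low"]], 100 * edu_sh[["medium"]],
              100 * edu_sh[["high"]],
              100 * lfp_exp[["15-24"]], 100 * lfp_exp[["25-54"]],
              100 * lfp_exp[["55-74"]],
              inflow5, min(bundle$demand$ratios$ratio),
              max(bundle$demand$ratios$ratio)))
}
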