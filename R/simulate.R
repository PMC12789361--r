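#' Run a projection
#'
#' Advances the population year by year from the bundle's base year:
#' demographic events (mortality, emigration, between-region migration,
#' external immigration, fertility), education revelation, labour-force
#' participation, labour-demand projection, and occupation allocation under
#' the scenario's operators. Occupation calibration factors are computed once
#' in the base year against the bundle's observed occupation distribution and
#' held constant thereafter. Every draw comes from a named stream spawned
#' from the master seed, so a run is a pure function of
#' (bundle, scenario, seed).
#'
#' @param bundle A [stylized_bundle()] (or a bundle read back with
#'   [read_bundle()]).
#' @param scenario A [scenario_spec()]; defaults to the reference (no-op)
#'   scenario.
#' @param seed Master seed for all Monte Carlo events.
#' @param years Simulated calendar years; the first must be the bundle's
#'   base year.
#' @param progress Print a line per simulated year.
#' @return A `skillsim_run` with elements `report` (list of per-statistic
#'   tibbles across years), `demand`, `events` (per-year demographic flows),
#'   `calibration`, `final_state`, `scenario`, `seed`, `scale_factor`.
#' @export
run_projection <- function(bundle, scenario = build_scenario("reference"),
                           seed = 1L, years = 2020:2060, progress = FALSE) {
  stopifnot(inherits(bundle, "skillsim_bundle"),
            inherits(scenario, "scenario_spec"))
  if (years[1] != bundle$year0) {
    abort("the first simulated year must be the bundle's base year")
  }
  rng <- rng_streams(seed)
  state <- synthesize_base_population(bundle$base_spec)
  calib <- NULL
  acc <- vector("list", length(years))
  demand_rows <- vector("list", length(years))
  events <- vector("list", length(years))

  for (i in seq_along(years)) {
    t <- years[i]
    n0 <- sum(present_idx(state$individuals))
    deaths <- emig <- immig <- births <- 0L
    if (i > 1L) {
      state <- advance_clock(state)
      state <- apply_mortality(state, bundle$mortality, rng)
      n1 <- sum(present_idx(state$individuals)); deaths <- n0 - n1
      state <- apply_emigration(state, bundle$migration, rng)
      n2 <- sum(present_idx(state$individuals)); emig <- n1 - n2
      state <- apply_internal_migration(state, bundle$migration, rng)
      infl <- scenario_operator(scenario, "inflow_multiplier", t)
      ovr <- scenario_operator(scenario, "immigrant_attribute_override", t)
      state <- apply_immigration(state, bundle$migration, rng,
                                 multiplier = infl$multiplier %||% 1,
                                 origin_override = ovr$source_group)
      n3 <- sum(present_idx(state$individuals)); immig <- n3 - n2
      state <- apply_fertility(state, bundle$fertility, rng)
      births <- sum(present_idx(state$individuals)) - n3
    }
    edu_op <- scenario_operator(scenario, "education_odds_multiplier", t)
    state <- apply_education(state, bundle$education, rng,
                             threshold_shift = if (is.null(edu_op)) 0 else
                               log(edu_op$odds),
                             shift_min_cohort = edu_op$min_cohort %||% -Inf)
    lfp_op <- scenario_operator(scenario, "lfp_override_50plus", t)
    override <- if (is.null(lfp_op)) NULL else {
      if (is.character(lfp_op$schedule)) bundle[[lfp_op$schedule]]
      else lfp_op$schedule
    }
    state <- apply_lfp(state, bundle$lfp, rng, override_50plus = override)

    ind <- state$individuals
    present <- present_idx(ind)
    dm <- demand_multiplier_at(scenario, t)
    dem_t <- purrr::map_dfr(bundle$regions, function(r) {
      pop_r <- sum(present & ind$region == r)
      d <- project_demand(pop_r, bundle$demand, r, t)
      mutate(d, total = .data$total * dm, dem_high = .data$dem_high * dm,
             dem_medium = .data$dem_medium * dm, dem_low = .data$dem_low * dm)
    })
    lf <- tibble(region = bundle$regions,
                 lf = vapply(bundle$regions, function(r) {
                   sum(present & ind$lfp & ind$region == r)
                 }, 0))
    ratios_t <- dem_t %>%
      left_join(lf, by = "region") %>%
      mutate(dem_high = .data$dem_high / pmax(.data$lf, 1),
             dem_lowmed = (.data$dem_medium + .data$dem_low) /
               pmax(.data$lf, 1)) %>%
      select("region", "dem_high", "dem_lowmed")

    if (i == 1L) {
      calib <- purrr::map_dfr(bundle$regions, function(r) {
        rows <- which(present & ind$lfp & ind$region == r)
        rt <- ratios_t[ratios_t$region == r, ]
        p <- occupation_probabilities(ind[rows, ], rt$dem_high,
                                      rt$dem_lowmed, bundle$occupation)
        tg <- bundle$occupation_targets[
          bundle$occupation_targets$region == r, ]
        lam <- compute_calibration_factors(
          p, setNames(tg$share, tg$outcome)[OCC_LEVELS])
        tibble(region = r, outcome = OCC_LEVELS, lambda = unname(lam))
      })
    }
    hb <- scenario_operator(scenario, "hiring_odds_multiplier", t)
    state <- allocate_occupations(state, bundle$occupation, calib, ratios_t,
                                  rng, hiring_boost = hb)
    tr <- scenario_operator(scenario, "occupation_transition", t)
    if (!is.null(tr)) {
      p1 <- annualize_probability(tr$p5)
      ind2 <- state$individuals
      mv <- which(present_idx(ind2) & !is.na(ind2$occupation) &
                    ind2$occupation %in% c("L", "M"))
      if (length(mv)) {
        u <- with_stream(rng, "scenario", runif(length(mv)))
        up <- u < p1
        ind2$occupation[mv[up]] <-
          ifelse(ind2$occupation[mv[up]] == "M", "H", "M")
        state <- population_state(ind2, state$year, state$scale_factor)
      }
    }
    acc[[i]] <- account_year(state, dem_t)
    demand_rows[[i]] <- dem_t
    events[[i]] <- tibble(year = t, population = sum(present_idx(
      state$individuals)), births = births, deaths = deaths,
      emigrants = emig, immigrants = immig)
    if (progress) {
      message(sprintf("year %d: %d agents present", t, events[[i]]$population))
    }
  }

  report <- list(
    workers = purrr::map_dfr(acc, "workers"),
    unemployed = purrr::map_dfr(acc, "unemployed"),
    vacancies = purrr::map_dfr(acc, "vacancies"),
    underutilization = purrr::map_dfr(acc, "underutilization"),
    occupation_by_education = purrr::map_dfr(acc, "occupation_by_education"),
    education_by_job = purrr::map_dfr(acc, "education_by_job"))
  structure(list(report = report, demand = bind_rows(demand_rows),
                 events = bind_rows(events), calibration = calib,
                 final_state = state, scenario = scenario, seed = seed,
                 years = years, scale_factor = bundle$scale_factor),
            class = "skillsim_run")
}

#' @export
print.skillsim_run <- function(x, ...) {
  last <- x$report$vacancies[x$report$vacancies$year == max(x$years) &
                               x$report$vacancies$skill == "total", ]
  cat("<skillsim_run> scenario '", x$scenario$name, "', ",
      x$years[1], "-", max(x$years), ", seed ", x$seed, "\n",
      "  final-year total vacancy rate: ",
      sprintf("%.1f%%", 100 * last$vacancy_rate), "\n", sep = "")
  invisible(x)
}

#' @describeIn run_projection Vacancy accounting in long form, counts both in
#'   agents and persons.
#' @param x,object A `skillsim_run`.
#' @param ... Unused.
#' @export
tidy.skillsim_run <- function(x, ...) {
  x$report$vacancies %>%
    mutate(scenario = x$scenario$name,
           demand_persons = .data$demand * x$scale_factor,
           occupied_persons = .data$occupied * x$scale_factor,
           vacancies_persons = .data$vacancies * x$scale_factor)
}

#' @describeIn run_projection One-row final-year summary.
#' @export
glance.skillsim_run <- function(x, ...) {
  yr <- max(x$years)
  v <- x$report$vacancies
  uu <- x$report$underutilization
  tibble(scenario = x$scenario$name, final_year = yr,
         population = x$events$population[x$events$year == yr],
         total_vacancy_rate = v$vacancy_rate[v$year == yr &
                                               v$skill == "total"],
         underutilized_share = uu$share[uu$year == yr],
         seed = x$seed)
}
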