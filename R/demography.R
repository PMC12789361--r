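#' Mortality schedule
#'
#' Annual death probabilities by single age, sex, education and 5-year period.
#' Probabilities must lie in \[0, 1\] and equal 1 at the age cap, so no
#' individual outlives the life table.
#'
#' @param q_table Tibble with columns `period_start`, `age` (0..100), `sex`,
#'   `education` and `q`.
#' @return A `mortality_schedule`.
#' @export
mortality_schedule <- function(q_table) {
  q_table <- as_tibble(q_table)
  if (any(q_table$q < 0 | q_table$q > 1)) {
    abort("death probabilities must lie in [0, 1]")
  }
  cap <- q_table$q[q_table$age == AGE_CAP]
  if (length(cap) == 0L || any(cap != 1)) {
    abort("q at the age cap must be 1")
  }
  structure(list(q = q_table,
                 periods = sort(unique(q_table$period_start))),
            class = "mortality_schedule")
}

period_of <- function(periods, year) {
  periods[findInterval(year, periods, rightmost.closed = FALSE)]
}

# children (education not yet assigned) use the medium-education column
edu_for_rates <- function(education) {
  ifelse(is.na(education), "medium", education)
}

#' Apply mortality for one year
#'
#' Each alive individual dies with the schedule probability for their age, sex
#' and education; the dead are flagged and never resurrected.
#'
#' @param state A [population_state()].
#' @param schedule A [mortality_schedule()].
#' @param rng A [rng_streams()] object (uses the `mortality` stream).
#' @return The updated state.
#' @export
apply_mortality <- function(state, schedule, rng) {
  ind <- state$individuals
  p <- which(present_idx(ind))
  if (length(p) == 0L) return(state)
  per <- period_of(schedule$periods, state$year)
  qt <- schedule$q[schedule$q$period_start == per, ]
  key <- paste(pmin(ind$age[p], AGE_CAP), ind$sex[p],
               edu_for_rates(ind$education[p]))
  q <- qt$q[match(key, paste(qt$age, qt$sex, qt$education))]
  if (anyNA(q)) {
    abort(paste0("mortality schedule is missing cells, e.g. ",
                 key[which(is.na(q))[1]]))
  }
  dies <- with_stream(rng, "mortality", runif(length(p))) < q
  ind$alive[p[dies]] <- FALSE
  population_state(ind, state$year, state$scale_factor)
}

#' Period life expectancy at birth
#'
#' Standard life-table accumulation with the mid-year death convention:
#' `l(x+1) = l(x) (1 - q(x))`, `L(x) = l(x+1) + d(x)/2`,
#' `e0 = sum(L) / l(0)`.
#'
#' @param schedule A [mortality_schedule()].
#' @param sex,education,period Cell selectors; `period` is any year inside the
#'   wanted 5-year period.
#' @return Life expectancy at birth in years.
#' @export
life_expectancy_of <- function(schedule, sex, education = "medium", period = 2020) {
  per <- period_of(schedule$periods, period)
  qt <- schedule$q[schedule$q$period_start == per &
                     schedule$q$sex == sex &
                     schedule$q$education == education, ]
  qt <- qt[order(qt$age), ]
  if (!identical(as.integer(qt$age), 0:AGE_CAP)) {
    abort("schedule must cover every single age 0..cap for the cell")
  }
  life_table_e0(qt$q)
}

life_table_e0 <- function(q) {
  if (any(q < 0 | q > 1)) abort("death probabilities must lie in [0, 1]")
  l <- cumprod(c(1, 1 - q))
  d <- l[-length(l)] - l[-1]
  L <- l[-1] + d / 2
  sum(L)
}

#' Fertility schedule
#'
#' Annual birth probabilities for women by single age (15-49), education and
#' period, plus the sex ratio at birth.
#'
#' @param f_table Tibble with columns `period_start`, `age`, `education`, `f`.
#' @param sex_ratio Males per 100 females at birth.
#' @return A `fertility_schedule`.
#' @export
fertility_schedule <- function(f_table, sex_ratio = 105) {
  f_table <- as_tibble(f_table)
  if (any(f_table$f < 0 | f_table$f > 1)) abort("birth probabilities must lie in [0, 1]")
  if (any(f_table$f[f_table$age < 15 | f_table$age > 49] > 0)) {
    abort("fertility must be zero outside ages 15-49")
  }
  structure(list(f = f_table, sex_ratio = sex_ratio,
                 periods = sort(unique(f_table$period_start))),
            class = "fertility_schedule")
}

#' Total fertility rate implied by a schedule
#'
#' Sum of the single-age annual rates, i.e. the average number of births a
#' woman would have under the period rates.
#'
#' @param schedule A [fertility_schedule()].
#' @param education Education column to sum over.
#' @param period Any year inside the wanted period.
#' @return The implied TFR.
#' @export
implied_tfr <- function(schedule, education = "medium", period = 2020) {
  per <- period_of(schedule$periods, period)
  ft <- schedule$f[schedule$f$period_start == per &
                     schedule$f$education == education, ]
  sum(ft$f)
}

#' Apply fertility for one year
#'
#' Alive women aged 15-49 give birth with the schedule probability for their
#' age and education. Newborns enter at age 0 in the mother's region with the
#' mother's education recorded (intergenerational transmission feeds the
#' education model at age 15), and sex drawn by the sex ratio at birth.
#'
#' @inheritParams apply_mortality
#' @param schedule A [fertility_schedule()].
#' @return The updated state.
#' @export
apply_fertility <- function(state, schedule, rng) {
  ind <- state$individuals
  w <- which(present_idx(ind) & ind$sex == "female" &
               ind$age >= 15L & ind$age <= 49L)
  if (length(w) == 0L) return(state)
  per <- period_of(schedule$periods, state$year)
  ft <- schedule$f[schedule$f$period_start == per, ]
  key <- paste(ind$age[w], edu_for_rates(ind$education[w]))
  f <- ft$f[match(key, paste(ft$age, ft$education))]
  if (anyNA(f)) abort("fertility schedule is missing cells")
  draws <- with_stream(rng, "fertility",
                       list(u = runif(length(w)),
                            s = runif(length(w))))
  mothers <- w[draws$u < f]
  if (length(mothers) == 0L) return(state)
  p_male <- schedule$sex_ratio / (100 + schedule$sex_ratio)
  baby_sex <- ifelse(draws$s[draws$u < f] < p_male, "male", "female")
  babies <- tibble(
    id = max(ind$id) + seq_along(mothers),
    birth_year = state$year, age = 0L,
    sex = baby_sex,
    region = ind$region[mothers], birth_region = ind$region[mothers],
    origin = "native",
    edu_final = NA_character_, education = NA_character_, in_school = TRUE,
    mother_edu = ifelse(is.na(ind$education[mothers]), "unknown",
                        ind$education[mothers]),
    age_at_imm = NA_integer_, duration = NA_integer_,
    lfp = FALSE, occupation = NA_character_,
    alive = TRUE, emigrated = FALSE
  )
  population_state(bind_rows(ind, babies), state$year, state$scale_factor)
}

#' Migration schedule
#'
#' External immigration inflows (persons per year, by destination region and
#' external origin group, with age/sex/education attribute distributions),
#' emigration rates by origin class and broad age, and an origin-destination
#' matrix of annual between-region migration rates converging linearly to a
#' common target by `convergence_year`.
#'
#' @param inflow Tibble `year, region, origin, persons`.
#' @param inflow_age Tibble `age_group, share` (arrival age distribution).
#' @param inflow_education Tibble `origin, education, share` (attainment of
#'   arrivals aged 15+).
#' @param emigration_rates Tibble `origin_class, age_group, rate` with broad
#'   age groups `0-14`, `15-39`, `40-64`, `65+`.
#' @param od_rates Tibble `from_region, to_region, origin_class,
#'   rate_start, rate_target` with origin classes `native`, `other_region`,
#'   `external`.
#' @param convergence_year Year by which OD rates reach `rate_target`.
#' @param start_year First year of the schedules.
#' @return A `migration_schedule`.
#' @export
migration_schedule <- function(inflow, inflow_age, inflow_education,
                               emigration_rates, od_rates,
                               convergence_year = 2050, start_year = 2020) {
  if (any(inflow$persons < 0)) abort("immigration inflow must be non-negative")
  if (abs(sum(inflow_age$share) - 1) > 1e-9) {
    abort("inflow age distribution must sum to 1")
  }
  chk <- tapply(inflow_education$share, inflow_education$origin, sum)
  if (any(abs(chk - 1) > 1e-9)) {
    abort("inflow education distribution must sum to 1 per origin group")
  }
  if (any(emigration_rates$rate < 0 | emigration_rates$rate > 1) ||
      any(od_rates$rate_start < 0 | od_rates$rate_start > 1)) {
    abort("migration rates must lie in [0, 1]")
  }
  structure(list(inflow = as_tibble(inflow),
                 inflow_age = as_tibble(inflow_age),
                 inflow_education = as_tibble(inflow_education),
                 emigration_rates = as_tibble(emigration_rates),
                 od_rates = as_tibble(od_rates),
                 convergence_year = convergence_year,
                 start_year = start_year),
            class = "migration_schedule")
}

emigration_age_band <- function(age) {
  ifelse(age <= 14, "0-14",
         ifelse(age <= 39, "15-39", ifelse(age <= 64, "40-64", "65+")))
}

#' Apply emigration (departures from the modelled area) for one year
#'
#' @inheritParams apply_mortality
#' @param schedule A [migration_schedule()].
#' @return The updated state; emigrants are flagged, not killed.
#' @export
apply_emigration <- function(state, schedule, rng) {
  ind <- state$individuals
  p <- which(present_idx(ind))
  if (length(p) == 0L) return(state)
  er <- schedule$emigration_rates
  cls <- ifelse(ind$origin[p] %in% c("native", "other_region"),
                ind$origin[p], "external")
  key <- paste(cls, emigration_age_band(ind$age[p]))
  rate <- er$rate[match(key, paste(er$origin_class, er$age_group))]
  if (anyNA(rate)) abort("emigration rate table is missing cells")
  leaves <- with_stream(rng, "migration", runif(length(p))) < rate
  ind$emigrated[p[leaves]] <- TRUE
  population_state(ind, state$year, state$scale_factor)
}

od_rate_at <- function(schedule, year) {
  w <- pmin(1, pmax(0, (year - schedule$start_year) /
                      (schedule$convergence_year - schedule$start_year)))
  r <- schedule$od_rates
  r$rate <- (1 - w) * r$rate_start + w * r$rate_target
  r
}

#' Apply migration between modelled regions for one year
#'
#' Each present individual moves to another modelled region with the (possibly
#' converging) OD rate; movers keep their birth region, so their `origin`
#' classification is re-derived at the destination.
#'
#' @inheritParams apply_emigration
#' @return The updated state.
#' @export
apply_internal_migration <- function(state, schedule, rng) {
  ind <- state$individuals
  p <- which(present_idx(ind))
  if (length(p) == 0L) return(state)
  od <- od_rate_at(schedule, state$year)
  regions <- sort(unique(c(od$from_region, od$to_region)))
  cls <- ifelse(ind$origin[p] %in% c("native", "other_region"),
                ind$origin[p], "external")
  # total out-rate and conditional destination per (region, origin class)
  grp <- paste(od$from_region, od$origin_class)
  out_rate <- tapply(od$rate, grp, sum)
  r_i <- out_rate[paste(ind$region[p], cls)]
  r_i[is.na(r_i)] <- 0
  draws <- with_stream(rng, "migration",
                       list(u = runif(length(p)), d = runif(length(p))))
  moves <- draws$u < r_i
  if (any(moves)) {
    mi <- p[moves]
    gkey <- paste(ind$region[mi], cls[moves])
    for (g in unique(gkey)) {
      rows <- mi[gkey == g]
      dest <- od[grp == g, ]
      if (nrow(dest) == 0L) next
      cum <- cumsum(dest$rate) / sum(dest$rate)
      pick <- findInterval(draws$d[match(rows, p)], cum) + 1L
      ind$region[rows] <- dest$to_region[pick]
    }
    ind$origin[mi] <- origin_of(ind$birth_region[mi], ind$region[mi], regions)
    # arrival in a new modelled region restarts the duration clock
    ind$duration[mi] <- ifelse(ind$origin[mi] == "native", NA_integer_, 0L)
    ind$age_at_imm[mi] <- ifelse(ind$origin[mi] == "native", NA_integer_,
                                 ind$age[mi])
  }
  population_state(ind, state$year, state$scale_factor)
}

#' Apply external immigration for one year
#'
#' Creates new individuals according to the inflow schedule (persons divided
#' by the agent scale factor, stochastically rounded so expectations are
#' preserved), with age, sex and education drawn from the schedule's
#' distributions, `duration = 0` and `age_at_imm = age`.
#'
#' @inheritParams apply_emigration
#' @param multiplier Scenario multiplier on the external inflow.
#' @param origin_override If set, arrivals take the attribute parameter block
#'   (education distribution, and downstream participation/occupation
#'   behaviour) of this origin group instead of their own.
#' @return The updated state.
#' @export
apply_immigration <- function(state, schedule, rng, multiplier = 1,
                              origin_override = NULL) {
  ind <- state$individuals
  fl <- schedule$inflow[schedule$inflow$year == state$year, ]
  if (nrow(fl) == 0L || sum(fl$persons) == 0) return(state)
  arrivals <- with_stream(rng, "migration", {
    n_cell <- stochastic_round(fl$persons * multiplier / state$scale_factor)
    n <- sum(n_cell)
    if (n == 0L) NULL else {
      region <- rep(fl$region, n_cell)
      origin <- rep(fl$origin, n_cell)
      if (!is.null(origin_override)) origin <- rep(origin_override, n)
      ia <- schedule$inflow_age
      grp <- sample.int(nrow(ia), n, replace = TRUE, prob = ia$share)
      lo <- as.integer(sub("-.*", "", ia$age_group[grp]))
      hi <- as.integer(sub(".*-", "", ia$age_group[grp]))
      age <- lo + as.integer(floor(runif(n) * (hi - lo + 1L)))
      sex <- ifelse(runif(n) < 0.5, "female", "male")
      edu <- rep(NA_character_, n)
      for (og in unique(origin)) {
        ie <- schedule$inflow_education[schedule$inflow_education$origin == og, ]
        if (nrow(ie) == 0L) {
          abort(paste0("no inflow education distribution for origin group '",
                       og, "'"))
        }
        sel <- which(origin == og & age >= 15L)
        if (length(sel)) {
          edu[sel] <- ie$education[sample.int(nrow(ie), length(sel),
                                              replace = TRUE, prob = ie$share)]
        }
      }
      list(region = region, origin = origin, age = age, sex = sex, edu = edu)
    }
  })
  if (is.null(arrivals)) return(state)
  n <- length(arrivals$age)
  revealed <- revealed_education(arrivals$edu, arrivals$age)
  newcomers <- tibble(
    id = max(ind$id, 0L) + seq_len(n),
    birth_year = state$year - arrivals$age, age = arrivals$age,
    sex = arrivals$sex, region = arrivals$region,
    birth_region = arrivals$origin, origin = arrivals$origin,
    edu_final = arrivals$edu, education = revealed,
    in_school = arrivals$age < 15L |
      (!is.na(arrivals$edu) &
         (is.na(revealed) | revealed != arrivals$edu)),
    mother_edu = "unknown",
    age_at_imm = arrivals$age, duration = 0L,
    lfp = FALSE, occupation = NA_character_,
    alive = TRUE, emigrated = FALSE
  )
  population_state(bind_rows(ind, newcomers), state$year, state$scale_factor)
}
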