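# Shared small fixtures, built once per test run.
.cache <- new.env(parent = emptyenv())

# small stylized bundle for unit tests (heavier default bundle lives in the
# acceptance file)
small_bundle <- function() {
  if (is.null(.cache$small)) {
    .cache$small <- stylized_bundle(agents = 20000L, seed = 99L,
                                    calib_size = 100000L)
  }
  .cache$small
}

# a flat mortality schedule: constant q at all ages below the cap
flat_mortality <- function(q, periods = 2020L) {
  grid <- tidyr::expand_grid(period_start = periods, age = 0:100,
                             sex = c("female", "male"),
                             education = c("low", "medium", "high"))
  grid$q <- ifelse(grid$age == 100L, 1, q)
  mortality_schedule(grid)
}

flat_fertility <- function(f, periods = 2020L) {
  grid <- tidyr::expand_grid(period_start = periods, age = 15:49,
                             education = c("low", "medium", "high"))
  grid$f <- f
  fertility_schedule(grid)
}

# a minimal migration schedule with uniform emigration rate and no OD moves
simple_migration <- function(emigration_rate = 0, inflow_persons = 0,
                             region = "central", years = 2020:2030) {
  migration_schedule(
    inflow = tibble::tibble(year = years, region = region, origin = "ext_B",
                            persons = inflow_persons),
    inflow_age = tibble::tibble(age_group = c("20-24", "25-29"),
                                share = c(0.5, 0.5)),
    inflow_education = tibble::tibble(origin = "ext_B",
                                      education = c("low", "medium", "high"),
                                      share = c(0.3, 0.4, 0.3)),
    emigration_rates = tidyr::expand_grid(
      origin_class = c("native", "other_region", "external"),
      age_group = c("0-14", "15-39", "40-64", "65+")) |>
      dplyr::mutate(rate = emigration_rate),
    od_rates = tibble::tibble(from_region = character(),
                              to_region = character(),
                              origin_class = character(),
                              rate_start = numeric(), rate_target = numeric())
  )
}

# hand-built population of working-age adults with given attribute columns
toy_population <- function(n, year = 2020, age = 40, sex = "male",
                           education = "medium", region = "central",
                           origin = "native", lfp = TRUE,
                           occupation = NA_character_) {
  tibble::tibble(
    id = seq_len(n), birth_year = year - age, age = age, sex = sex,
    region = region,
    birth_region = ifelse(origin == "native", region, origin),
    origin = origin, edu_final = education, education = education,
    in_school = FALSE, mother_edu = "unknown",
    age_at_imm = ifelse(origin == "native", NA_integer_, as.integer(age - 10L)),
    duration = ifelse(origin == "native", NA_integer_, 10L),
    lfp = lfp, occupation = occupation, alive = TRUE, emigrated = FALSE
  )
}

toy_state <- function(n, year = 2020, scale_factor = 1, ...) {
  population_state(toy_population(n, year = year, ...), year, scale_factor)
}

# random coefficient matrix for the occupation model (core terms only)
random_occ_coeffs <- function() {
  terms <- c("(Intercept)", "sex_female", "edu", "sex_female:edu",
             "agegr", "agegr2", "dem_high", "dem_lowmed")
  beta <- matrix(rnorm(length(terms) * 3, sd = 0.3), length(terms), 3,
                 dimnames = list(terms, c("L", "M", "H")))
  occupation_coefficients(beta)
}

# random individual covariate tibble for the occupation model
random_occ_data <- function(n) {
  tibble::tibble(
    sex = sample(c("female", "male"), n, TRUE),
    education = sample(c("low", "medium", "high"), n, TRUE),
    age = sample(15:74, n, TRUE),
    origin = "native", duration = NA_integer_, age_at_imm = NA_integer_
  )
}
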