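#' Population state
#'
#' The simulated population is an ordinary tibble with one row per individual,
#' wrapped together with the current calendar year and the agent scale factor
#' (persons represented per agent). All module verbs
#' (`apply_mortality()`, `apply_lfp()`, ...) take a state first and return a
#' state, so a simulation step is a pipe.
#'
#' Individual columns:
#' \describe{
#'   \item{id}{unique integer}
#'   \item{birth_year, age}{`age = year - birth_year` for alive individuals}
#'   \item{sex}{"female" or "male"}
#'   \item{region}{region of residence}
#'   \item{birth_region}{region (or external origin group) of birth}
#'   \item{origin}{derived: "native", "other_region", or the external group
#'     label ("ext_A", "ext_B")}
#'   \item{edu_final}{latent final educational attainment ("low", "medium",
#'     "high"); `NA` until drawn at age 15}
#'   \item{education}{attainment revealed so far (low at 15, medium at 18,
#'     high at 22); `NA` for children}
#'   \item{in_school}{TRUE while revealed attainment is below the latent final
#'     level (or below age 15); in-school individuals are outside the labour
#'     force}
#'   \item{mother_edu}{education of the mother ("low"/"medium"/"high"/
#'     "unknown")}
#'   \item{age_at_imm, duration}{age at immigration and completed years of
#'     stay (0 in the arrival year); `NA` for individuals living in their
#'     birth region}
#'   \item{lfp}{TRUE if active (employed or unemployed)}
#'   \item{occupation}{"U" (unemployed), "L", "M", "H" (job skill level), or
#'     `NA` if inactive/unassigned}
#'   \item{alive, emigrated}{status flags; events never resurrect or re-admit}
#' }
#'
#' @param individuals Tibble of individuals with the columns above.
#' @param year Calendar year of the state.
#' @param scale_factor Persons represented per agent.
#' @return An object of class `population_state`.
#' @export
population_state <- function(individuals, year, scale_factor = 1) {
  stopifnot(is.data.frame(individuals))
  structure(
    list(individuals = as_tibble(individuals),
         year = as.integer(year),
         scale_factor = scale_factor),
    class = "population_state"
  )
}

#' @export
print.population_state <- function(x, ...) {
  alive <- present_idx(x$individuals)
  cat("<population_state> year ", x$year, ": ",
      sum(alive), " present agents (x", format(x$scale_factor),
      " persons each), ", nrow(x$individuals), " rows total\n", sep = "")
  invisible(x)
}

# logical index of individuals currently in the simulated population
present_idx <- function(ind) ind$alive & !ind$emigrated

#' @export
as_tibble.population_state <- function(x, ...) x$individuals

# age cap: survivors beyond this age face certain death at the next step
AGE_CAP <- 100L

origin_of <- function(birth_region, region, regions) {
  ifelse(birth_region == region, "native",
         ifelse(birth_region %in% regions, "other_region", birth_region))
}

# revealed attainment given latent final level and current age
revealed_education <- function(edu_final, age) {
  lvl <- match(edu_final, c("low", "medium", "high"))
  cap <- ifelse(age >= 22, 3L, ifelse(age >= 18, 2L, ifelse(age >= 15, 1L, 0L)))
  shown <- pmin(lvl, cap)
  out <- c("low", "medium", "high")[ifelse(shown == 0L, NA_integer_, shown)]
  out[is.na(edu_final)] <- NA_character_
  out
}

#' Specify a base population
#'
#' @param size Number of agents to synthesize.
#' @param scale_factor Persons represented per agent.
#' @param marginals Tibble of target joint shares with columns
#'   `region`, `age_group` (5-year label), `sex`, `education`
#'   ("none" for ages below 15), `origin` ("native", "other_region", or an
#'   external group label) and `share`; shares must sum to 1.
#' @param seed Integer seed making the synthesis reproducible.
#' @param year Base calendar year.
#' @param recent_share Probability that a foreign-born base individual arrived
#'   within the last five years.
#' @return A `base_population_spec` list.
#' @export
base_population_spec <- function(size, scale_factor, marginals, seed,
                                 year = 2020L, recent_share = 0.2) {
  if (size < 0) abort("base population size must be non-negative")
  tot <- sum(marginals$share)
  if (abs(tot - 1) > 1e-9) {
    abort(sprintf("marginal shares must sum to 1 (got %.12f)", tot))
  }
  if (any(marginals$share < 0)) abort("marginal shares must be non-negative")
  structure(
    list(size = as.integer(size), scale_factor = scale_factor,
         marginals = as_tibble(marginals), seed = as.integer(seed),
         year = as.integer(year), recent_share = recent_share),
    class = "base_population_spec"
  )
}

#' Synthesize the base population
#'
#' Draws `size` individuals from the joint marginal distribution of the spec
#' (region x age group x sex x education x origin), assigns a uniform single
#' age within the age group, applies the schooling revelation rule to current
#' students, and draws duration of stay for the foreign-born. Deterministic
#' for a fixed spec seed.
#'
#' @param spec A [base_population_spec()].
#' @return A [population_state()] at the spec's base year.
#' @export
synthesize_base_population <- function(spec) {
  stopifnot(inherits(spec, "base_population_spec"))
  m <- spec$marginals
  regions <- unique(m$region)
  empty <- tibble(
    id = integer(), birth_year = integer(), age = integer(),
    sex = character(), region = character(), birth_region = character(),
    origin = character(), edu_final = character(), education = character(),
    in_school = logical(), mother_edu = character(),
    age_at_imm = integer(), duration = integer(),
    lfp = logical(), occupation = character(),
    alive = logical(), emigrated = logical()
  )
  if (spec$size == 0L) {
    return(population_state(empty, spec$year, spec$scale_factor))
  }

  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(spec$seed)

  cell <- sample.int(nrow(m), spec$size, replace = TRUE, prob = m$share)
  age_lo <- as.integer(sub("-.*", "", m$age_group[cell]))
  age_hi <- as.integer(sub(".*-", "", m$age_group[cell]))
  age <- age_lo + as.integer(floor(runif(spec$size) * (age_hi - age_lo + 1L)))
  edu <- m$education[cell]
  edu[edu == "none"] <- NA_character_
  region <- m$region[cell]
  origin <- m$origin[cell]
  birth_region <- ifelse(origin == "native", region,
    ifelse(origin == "other_region",
           # born in another modelled region: pick one uniformly
           vapply(region, function(r) sample(setdiff(regions, r), 1L), ""),
           origin))

  foreign <- origin != "native"
  duration <- rep(NA_integer_, spec$size)
  if (any(foreign)) {
    fa <- age[foreign]
    recent <- runif(sum(foreign)) < spec$recent_share
    d_recent <- as.integer(floor(runif(sum(foreign)) * 5))
    d_long <- 5L + as.integer(floor(runif(sum(foreign)) * pmax(1L, fa - 4L)))
    d <- ifelse(recent, d_recent, d_long)
    duration[foreign] <- pmin(d, fa)
  }
  age_at_imm <- ifelse(foreign, age - duration, NA_integer_)

  revealed <- revealed_education(edu, age)
  in_school <- age < 15L |
    (!is.na(edu) & !is.na(revealed) & revealed != edu) |
    (!is.na(edu) & is.na(revealed))

  ind <- tibble(
    id = seq_len(spec$size),
    birth_year = spec$year - age,
    age = age, sex = m$sex[cell], region = region,
    birth_region = birth_region, origin = origin,
    edu_final = edu, education = revealed, in_school = in_school,
    mother_edu = "unknown",
    age_at_imm = as.integer(age_at_imm), duration = as.integer(duration),
    lfp = FALSE, occupation = NA_character_,
    alive = TRUE, emigrated = FALSE
  )
  population_state(ind, spec$year, spec$scale_factor)
}

#' Advance the simulation clock by one year
#'
#' Increments the calendar year and the age (and duration of stay) of every
#' alive, non-emigrated individual. Nothing else changes.
#'
#' @param state A [population_state()].
#' @return The state one year later.
#' @export
advance_clock <- function(state) {
  stopifnot(inherits(state, "population_state"))
  ind <- state$individuals
  p <- present_idx(ind)
  ind$age[p] <- ind$age[p] + 1L
  has_dur <- p & !is.na(ind$duration)
  ind$duration[has_dur] <- ind$duration[has_dur] + 1L
  population_state(ind, state$year + 1L, state$scale_factor)
}

#' Validate population invariants
#'
#' Checks id uniqueness, the age/birth-year identity, the age cap, and that
#' only active individuals hold an occupation. Aborts on violation.
#'
#' @param state A [population_state()].
#' @return `state`, invisibly.
#' @export
validate_population <- function(state) {
  ind <- state$individuals
  p <- present_idx(ind)
  if (anyDuplicated(ind$id)) abort("individual ids are not unique")
  if (any(ind$age[p] + ind$birth_year[p] != state$year)) {
    abort("age != year - birth_year for some alive individual")
  }
  if (any(ind$age[p] < 0L | ind$age[p] > AGE_CAP)) {
    abort("alive individual outside [0, age cap]")
  }
  occ <- !is.na(ind$occupation[p])
  if (any(occ & !ind$lfp[p])) {
    abort("occupation assigned to an inactive individual")
  }
  invisible(state)
}
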