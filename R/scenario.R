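#' Scenario specification
#'
#' A scenario is a named list of operators hooked into the simulation loop,
#' all inactive before `start_year`. Known hooks:
#' \describe{
#'   \item{inflow_multiplier}{`list(multiplier)` - scales external
#'     immigration.}
#'   \item{immigrant_attribute_override}{`list(source_group)` - new arrivals
#'     take the education/participation/occupation parameter blocks of the
#'     named (best-performing) origin group.}
#'   \item{education_odds_multiplier}{`list(odds, min_cohort)` - multiplies
#'     the odds of attaining medium-and-above and of attaining high education
#'     for cohorts born at or after `min_cohort` whose attainment is not yet
#'     revealed.}
#'   \item{occupation_transition}{`list(p5)` - each 5-year increment moves
#'     `p5` of medium-skill workers up to high-skill and `p5` of low-skill
#'     workers up to medium-skill, applied as an annualized post-draw
#'     reassignment with `p1 = 1 - (1 - p5)^(1/5)`.}
#'   \item{lfp_override_50plus}{`list(schedule)` - named participation-rate
#'     vector replacing the model for ages 50+ (benchmark late-career
#'     schedule).}
#'   \item{demand_multiplier_path}{`list(end_value, end_year)` - demand
#'     multiplier moving linearly from 1 at `start_year` to `end_value` at
#'     `end_year`.}
#'   \item{hiring_odds_multiplier}{`list(odds)` - odds of being hired one
#'     skill level above the education-matched job are multiplied by `odds`.}
#' }
#'
#' @param name Scenario name.
#' @param start_year First year the operators act.
#' @param operators Named list of operator parameter lists (hooks above).
#' @return A `scenario_spec`.
#' @export
scenario_spec <- function(name, start_year = 2025L, operators = list()) {
  known <- c("inflow_multiplier", "immigrant_attribute_override",
             "education_odds_multiplier", "occupation_transition",
             "lfp_override_50plus", "demand_multiplier_path",
             "hiring_odds_multiplier")
  bad <- setdiff(names(operators), known)
  if (length(bad)) {
    abort(paste0("unknown operator hook(s): ", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(names(operators))) abort("operator hooks must be unique")
  structure(list(name = name, start_year = as.integer(start_year),
                 operators = operators),
            class = "scenario_spec")
}

#' Built-in policy scenarios
#'
#' Returns the parameterization of the reference run and the seven what-if
#' policy responses: a 50% larger external immigration inflow; selection of
#' immigrants with the attribute profile of the best-performing origin group;
#' 25% higher odds of secondary and post-secondary attainment for cohorts
#' born 1990+; mid-career retraining moving 5% of medium- and of low-skill
#' workers one level up per 5-year increment; participation of the 50+
#' population at a high late-career benchmark; labour demand gradually
#' reduced 15% by 2060 through automation; and employer upskilling raising
#' the odds of above-education hiring by 25%.
#'
#' @param name One of `"reference"`, `"high_immigration"`,
#'   `"better_selection"`, `"better_education"`, `"retraining"`,
#'   `"later_retirement"`, `"automation"`, `"upskilling"`.
#' @return A [scenario_spec()].
#' @export
build_scenario <- function(name) {
  switch(name,
    reference = scenario_spec("reference", operators = list()),
    high_immigration = scenario_spec("high_immigration", operators = list(
      inflow_multiplier = list(multiplier = 1.5))),
    better_selection = scenario_spec("better_selection", operators = list(
      immigrant_attribute_override = list(source_group = "ext_A"))),
    better_education = scenario_spec("better_education", operators = list(
      education_odds_multiplier = list(odds = 1.25, min_cohort = 1990))),
    retraining = scenario_spec("retraining", operators = list(
      occupation_transition = list(p5 = 0.05))),
    later_retirement = scenario_spec("later_retirement", operators = list(
      lfp_override_50plus = list(schedule = "benchmark_50plus"))),
    automation = scenario_spec("automation", operators = list(
      demand_multiplier_path = list(end_value = 0.85, end_year = 2060))),
    upskilling = scenario_spec("upskilling", operators = list(
      hiring_odds_multiplier = list(odds = 1.25))),
    abort(paste0(
      "unknown scenario '", name, "'; known scenarios: reference, ",
      "high_immigration, better_selection, better_education, retraining, ",
      "later_retirement, automation, upskilling"))
  )
}

#' Operator parameters active in a given year
#'
#' @param spec A [scenario_spec()].
#' @param hook Operator hook name.
#' @param year Simulation year.
#' @return The operator's parameter list, or `NULL` if absent or not yet
#'   active.
#' @export
scenario_operator <- function(spec, hook, year) {
  if (year < spec$start_year) return(NULL)
  spec$operators[[hook]]
}

#' Demand multiplier implied by a scenario for a year
#'
#' Linear from 1 at the scenario start year to the operator's end value at
#' its end year; 1 before the start and outside the operator.
#'
#' @inheritParams scenario_operator
#' @return A scalar multiplier.
#' @export
demand_multiplier_at <- function(spec, year) {
  op <- scenario_operator(spec, "demand_multiplier_path", year)
  if (is.null(op)) return(1)
  w <- pmin(1, pmax(0, (year - spec$start_year) /
                      (op$end_year - spec$start_year)))
  1 + w * (op$end_value - 1)
}

#' Annualize a 5-year transition probability
#'
#' `p1 = 1 - (1 - p5)^(1/5)`: applying `p1` five times reproduces the 5-year
#' probability.
#'
#' @param p5 Transition probability per 5-year increment.
#' @return Per-year probability.
#' @export
annualize_probability <- function(p5) {
  stopifnot(all(p5 >= 0 & p5 <= 1))
  1 - (1 - p5)^(1 / 5)
}

#' Benchmark late-career participation schedule
#'
#' Stylized participation rates of the 50+ population in a high
#' late-career-participation country (Swedish-level magnitudes), used by the
#' later-retirement scenario. Values are synthetic benchmark levels, not an
#' official series.
#'
#' @return Named vector of rates per 5-year age group.
#' @export
benchmark_lfp_50plus <- function() {
  c("50-54" = 0.90, "55-59" = 0.86, "60-64" = 0.73,
    "65-69" = 0.33, "70-74" = 0.15)
}
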