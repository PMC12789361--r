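#' Labour-force participation model parameters
#'
#' Logistic model of being active (employed or unemployed) for individuals
#' aged 15-74 who are out of school. The linear predictor combines a baseline
#' per 5-year age group with offsets for education, sex, origin group,
#' recent arrival (duration of stay below 5 years), arrival during childhood
#' (below age 15), and a linear birth-cohort term.
#'
#' @param age_baseline Named vector of baselines per 5-year group
#'   ("15-19" ... "70-74"), on the logit scale.
#' @param beta_edu Named offsets for education (low/medium/high).
#' @param beta_sex_female Offset for women.
#' @param beta_origin Named offsets per origin group ("native" must be 0).
#' @param beta_recent Offset for foreign-born with duration of stay < 5.
#' @param beta_child_arrival Offset for foreign-born who arrived before 15
#'   (their integration profile resembles natives').
#' @param beta_cohort Slope per birth-cohort year.
#' @param cohort_ref Reference birth cohort.
#' @return An `lfp_params` list.
#' @export
lfp_params <- function(age_baseline,
                       beta_edu = c(low = 0, medium = 0, high = 0),
                       beta_sex_female = 0,
                       beta_origin = c(native = 0),
                       beta_recent = 0, beta_child_arrival = 0,
                       beta_cohort = 0, cohort_ref = 1980) {
  stopifnot(all(is.finite(age_baseline)), all(is.finite(beta_edu)))
  structure(list(age_baseline = age_baseline, beta_edu = beta_edu,
                 beta_sex_female = beta_sex_female, beta_origin = beta_origin,
                 beta_recent = beta_recent,
                 beta_child_arrival = beta_child_arrival,
                 beta_cohort = beta_cohort, cohort_ref = cohort_ref),
            class = "lfp_params")
}

#' Participation probability
#'
#' @param data Tibble with columns `age`, `sex`, `education`, `origin`,
#'   `duration`, `age_at_imm`, `birth_year`.
#' @param params An [lfp_params()].
#' @return Numeric vector of probabilities in (0, 1).
#' @export
lfp_probability <- function(data, params) {
  base <- params$age_baseline[age_band(data$age)]
  if (anyNA(base)) abort("age outside the participation age range 15-74")
  orig <- params$beta_origin[data$origin]
  orig[is.na(orig)] <- 0
  recent <- !is.na(data$duration) & data$duration < 5L
  child <- !is.na(data$age_at_imm) & data$age_at_imm < 15L
  lp <- unname(base) +
    unname(params$beta_edu[data$education]) +
    params$beta_sex_female * (data$sex == "female") +
    unname(orig) +
    params$beta_recent * recent +
    params$beta_child_arrival * child +
    params$beta_cohort * (data$birth_year - params$cohort_ref)
  plogis(lp)
}

#' Draw labour-force participation for one year
#'
#' Out-of-school individuals aged 15-74 are active with their model
#' probability; everyone else is inactive. Occupation is reset for the newly
#' inactive (occupation is re-imputed cross-sectionally each year anyway).
#'
#' @param state A [population_state()].
#' @param params An [lfp_params()].
#' @param rng A [rng_streams()] (uses the `lfp` stream).
#' @param override_50plus Optional named vector of participation *rates* per
#'   5-year group ("50-54" ... "70-74") replacing the model probability for
#'   ages 50+ (the later-retirement scenario hook).
#' @return The updated state.
#' @export
apply_lfp <- function(state, params, rng, override_50plus = NULL) {
  ind <- state$individuals
  ind$lfp <- FALSE
  elig <- which(present_idx(ind) & !ind$in_school &
                  ind$age >= 15L & ind$age <= 74L)
  if (length(elig)) {
    pr <- lfp_probability(ind[elig, ], params)
    if (!is.null(override_50plus)) {
      old <- ind$age[elig] >= 50L
      pr[old] <- unname(override_50plus[age_band(ind$age[elig][old])])
      if (anyNA(pr)) abort("override schedule is missing an age group")
    }
    ind$lfp[elig] <- with_stream(rng, "lfp", runif(length(elig))) < pr
  }
  ind$occupation[!ind$lfp] <- NA_character_
  population_state(ind, state$year, state$scale_factor)
}
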