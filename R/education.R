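#' Education model parameters
#'
#' Cumulative (proportional-odds) logit over \{low, medium, high\} final
#' attainment: `P(level <= j) = plogis(threshold_j - lp)`, with a linear
#' predictor built from the birth cohort (secular trend with a plateau), sex,
#' mother's education (intergenerational transmission) and region of birth.
#' Raising the predictor shifts probability mass monotonically toward higher
#' attainment.
#'
#' @param thresholds Two strictly increasing cut-points (low|medium,
#'   medium|high).
#' @param beta_cohort Slope per birth-cohort year.
#' @param cohort_ref Reference birth cohort (predictor 0).
#' @param cohort_plateau Birth cohort after which the trend stops (avoids
#'   extrapolating to degenerate shares).
#' @param beta_sex_female Offset for women.
#' @param beta_mother Named offsets for mother's education
#'   (low/medium/high/unknown); unknown must be 0.
#' @param region_offsets Named offsets per region of birth.
#' @return An `education_params` list.
#' @export
education_params <- function(thresholds, beta_cohort = 0,
                             cohort_ref = 1988, cohort_plateau = 2035,
                             beta_sex_female = 0,
                             beta_mother = c(low = 0, medium = 0, high = 0,
                                             unknown = 0),
                             region_offsets = c()) {
  if (length(thresholds) != 2L || diff(thresholds) <= 0) {
    abort("thresholds must be two strictly increasing cut-points")
  }
  structure(list(thresholds = thresholds, beta_cohort = beta_cohort,
                 cohort_ref = cohort_ref, cohort_plateau = cohort_plateau,
                 beta_sex_female = beta_sex_female, beta_mother = beta_mother,
                 region_offsets = region_offsets),
            class = "education_params")
}

education_lp <- function(cohort, sex, mother_edu, region, params) {
  co <- pmin(cohort, params$cohort_plateau) - params$cohort_ref
  lp <- params$beta_cohort * co +
    params$beta_sex_female * (sex == "female") +
    unname(params$beta_mother[mother_edu])
  if (length(params$region_offsets)) {
    off <- params$region_offsets[region]
    off[is.na(off)] <- 0
    lp <- lp + unname(off)
  }
  lp
}

#' Final-attainment probabilities
#'
#' @param cohort Birth-cohort year(s).
#' @param sex "female"/"male".
#' @param mother_edu Mother's education ("low"/"medium"/"high"/"unknown").
#' @param region Region of birth.
#' @param params An [education_params()].
#' @return A numeric matrix with one row per input and columns
#'   `low`, `medium`, `high`, each row on the simplex.
#' @export
education_probabilities <- function(cohort, sex, mother_edu, region, params) {
  lp <- education_lp(cohort, sex, mother_edu, region, params)
  c1 <- plogis(params$thresholds[1] - lp)
  c2 <- plogis(params$thresholds[2] - lp)
  cbind(low = c1, medium = c2 - c1, high = 1 - c2)
}

#' Draw final educational attainment
#'
#' One multinomial draw per individual from [education_probabilities()].
#' Intended for individuals reaching the decision age (15); the draw is latent
#' and revealed on the schooling schedule (low at 15, medium at 18, high
#' at 22).
#'
#' @inheritParams education_probabilities
#' @param u Uniform draws (one per individual); supplied by the caller so the
#'   education RNG stream is managed in one place.
#' @return Character vector of levels.
#' @export
assign_final_education <- function(cohort, sex, mother_edu, region, params, u) {
  pr <- education_probabilities(cohort, sex, mother_edu, region, params)
  lvl <- 1L + (u > pr[, 1]) + (u > pr[, 1] + pr[, 2])
  c("low", "medium", "high")[lvl]
}

#' Draw and reveal education in the population
#'
#' Individuals aged 15 and above without a latent final level draw one from
#' the cohort model; everyone's revealed level and schooling status are then
#' refreshed from the revelation schedule. Attainment is absorbing: the latent
#' level never changes once drawn.
#'
#' @param state A [population_state()].
#' @param params An [education_params()].
#' @param rng A [rng_streams()] (uses the `education` stream).
#' @param threshold_shift Subtracted from both cut-points at draw time for the
#'   affected cohorts (scenario hook: an odds multiplier `m` on attaining
#'   medium-and-above and high corresponds to a shift of `log(m)`).
#' @param shift_min_cohort First birth cohort the shift applies to.
#' @return The updated state.
#' @export
apply_education <- function(state, params, rng, threshold_shift = 0,
                            shift_min_cohort = -Inf) {
  ind <- state$individuals
  need <- which(present_idx(ind) & ind$age >= 15L & is.na(ind$edu_final))
  if (length(need)) {
    u <- with_stream(rng, "education", runif(length(need)))
    pars <- params
    if (threshold_shift != 0) {
      boosted <- ind$birth_year[need] >= shift_min_cohort
      if (any(!boosted)) {
        ind$edu_final[need[!boosted]] <- assign_final_education(
          ind$birth_year[need[!boosted]], ind$sex[need[!boosted]],
          ind$mother_edu[need[!boosted]], ind$birth_region[need[!boosted]],
          params, u[!boosted])
      }
      pars$thresholds <- pars$thresholds - threshold_shift
      need <- need[boosted]
      u <- u[boosted]
    }
    if (length(need)) {
      ind$edu_final[need] <- assign_final_education(
        ind$birth_year[need], ind$sex[need], ind$mother_edu[need],
        ind$birth_region[need], pars, u)
    }
  }
  p <- which(present_idx(ind) & !is.na(ind$edu_final))
  ind$education[p] <- revealed_education(ind$edu_final[p], ind$age[p])
  ind$in_school[p] <- is.na(ind$education[p]) |
    ind$education[p] != ind$edu_final[p]
  under <- which(present_idx(ind) & ind$age < 15L)
  ind$in_school[under] <- TRUE
  population_state(ind, state$year, state$scale_factor)
}
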