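test_that("cumulative-logit education probabilities are forced at extremes", {
  p0 <- education_params(thresholds = c(-30, 30))
  pr <- education_probabilities(1990, "male", "unknown", "central", p0)
  expect_equal(drop(pr), c(low = 0, medium = 1, high = 0), tolerance = 1e-10)
  p1 <- education_params(thresholds = c(0, 1e-9))
  pr1 <- education_probabilities(1988, "male", "unknown", "central", p1)
  expect_equal(unname(pr1[1, "low"]), 0.5, tolerance = 1e-9)
  expect_error(education_params(thresholds = c(1, 0)), "increasing")
})

test_that("raising the predictor shifts mass toward higher attainment", {
  set.seed(11)
  for (i in 1:20) {
    th <- sort(rnorm(2, sd = 2))
    th[2] <- th[1] + abs(diff(th)) + 0.1
    pars <- education_params(th, beta_cohort = abs(rnorm(1, 0, 0.05)))
    pr <- education_probabilities(c(1960, 1990, 2020), "male", "unknown",
                                  "x", pars)
    cum_low <- pr[, "low"]
    cum_med <- pr[, "low"] + pr[, "medium"]
    expect_true(all(diff(cum_low) <= 1e-12))
    expect_true(all(diff(cum_med) <= 1e-12))
    expect_true(all(abs(rowSums(pr) - 1) < 1e-12))
  }
})

test_that("simulated attainment refits to the generating parameters", {
  set.seed(21)
  n <- 20000
  pars <- education_params(c(-1.8, 0.5), beta_cohort = 0.02,
                          cohort_ref = 1990, beta_sex_female = 0.2,
                          beta_mother = c(low = -0.3, medium = 0, high = 0.3,
                                          unknown = 0))
  cohort <- sample(1960:2000, n, TRUE)
  sex <- sample(c("female", "male"), n, TRUE)
  mother <- sample(c("low", "medium", "high"), n, TRUE)
  edu <- assign_final_education(cohort, sex, mother, "x", pars, runif(n))
  df <- data.frame(
    edu = factor(edu, levels = c("low", "medium", "high"), ordered = TRUE),
    cohort_c = cohort - 1990, female = as.numeric(sex == "female"),
    m_low = as.numeric(mother == "low"), m_high = as.numeric(mother == "high"))
  fit <- MASS::polr(edu ~ cohort_c + female + m_low + m_high, data = df,
                    Hess = TRUE)
  se <- sqrt(diag(vcov(fit)))
  est <- c(coef(fit), fit$zeta)
  truth <- c(cohort_c = 0.02, female = 0.2, m_low = -0.3, m_high = 0.3,
             `low|medium` = -1.8, `medium|high` = 0.5)
  expect_true(all(abs(est[names(truth)] - truth) <
                    3 * se[names(truth)] + 1e-12))
})

test_that("the fixture trend raises high attainment monotonically", {
  b <- small_bundle()
  # expected high share of the 30-34 cohort at successive report years
  highs <- vapply(seq(2020, 2060, 10), function(yr) {
    pr <- education_probabilities(yr - 32, c("female", "male"), "unknown",
                                  b$regions[2], b$education)
    mean(pr[, "high"])
  }, 0)
  expect_true(all(diff(highs) > 0))
})

test_that("education is drawn once and revealed on schedule", {
  rng <- rng_streams(8)
  b <- small_bundle()
  st <- toy_state(300, age = 15)
  st$individuals$edu_final <- NA_character_
  st$individuals$education <- NA_character_
  st$individuals$in_school <- TRUE
  out <- apply_education(st, b$education, rng)
  expect_true(all(!is.na(out$individuals$edu_final)))
  expect_true(all(out$individuals$education == "low"))  # age 15 reveals low
  expect_true(all(out$individuals$in_school ==
                    (out$individuals$edu_final != "low")))
  again <- apply_education(out, b$education, rng)
  expect_identical(again$individuals$edu_final, out$individuals$edu_final)
  # degenerate probabilities force the level
  forced <- education_params(c(-40, -39))
  st2 <- toy_state(50, age = 22)
  st2$individuals$edu_final <- NA_character_
  out2 <- apply_education(st2, forced, rng)
  expect_true(all(out2$individuals$edu_final == "high"))
  expect_true(all(out2$individuals$education == "high"))
})

test_that("participation probabilities respect the model structure", {
  pars <- lfp_params(age_baseline = setNames(rep(0, 12),
                                             age_band(seq(15, 74, 5))),
                     beta_recent = -0.7)
  base <- toy_population(1, age = 40)
  expect_equal(lfp_probability(base, pars), 0.5)
  recent <- base
  recent$origin <- "ext_B"
  recent$duration <- 2L
  recent$age_at_imm <- 38L
  settled <- recent
  settled$duration <- 12L
  settled$age_at_imm <- 28L
  expect_lt(lfp_probability(recent, pars), lfp_probability(settled, pars))
})

test_that("simulated participation refits to the generating coefficients", {
  set.seed(31)
  n <- 20000
  pars <- lfp_params(
    age_baseline = setNames(seq(-1, 1.2, length.out = 12),
                            age_band(seq(15, 74, 5))),
    beta_edu = c(low = -0.5, medium = 0, high = 0.4),
    beta_sex_female = -0.3)
  pop <- toy_population(n, age = 0)
  pop$age <- sample(15:74, n, TRUE)
  pop$sex <- sample(c("female", "male"), n, TRUE)
  pop$education <- sample(c("low", "medium", "high"), n, TRUE)
  pr <- lfp_probability(pop, pars)
  y <- as.numeric(runif(n) < pr)
  df <- data.frame(y = y, age_idx = (pop$age - 15) %/% 5,
                   female = as.numeric(pop$sex == "female"),
                   e_low = as.numeric(pop$education == "low"),
                   e_high = as.numeric(pop$education == "high"))
  fit <- glm(y ~ female + e_low + e_high, family = binomial, data = df,
             subset = age_idx == 5)  # one age group: baseline is the intercept
  se <- sqrt(diag(vcov(fit)))
  truth <- c(`(Intercept)` = unname(pars$age_baseline["40-44"]),
             female = -0.3, e_low = -0.5, e_high = 0.4)
  expect_true(all(abs(coef(fit)[names(truth)] - truth) <
                    3 * se[names(truth)] + 1e-12))
})

test_that("apply_lfp honours eligibility, overrides, and resets", {
  rng <- rng_streams(9)
  b <- small_bundle()
  force_on <- lfp_params(age_baseline = setNames(rep(30, 12),
                                                 age_band(seq(15, 74, 5))))
  st <- toy_state(200, age = 40, occupation = "M")
  out <- apply_lfp(st, force_on, rng)
  expect_true(all(out$individuals$lfp))
  st$individuals$in_school[1:50] <- TRUE
  out2 <- apply_lfp(st, force_on, rng)
  expect_true(all(!out2$individuals$lfp[1:50]))
  expect_true(all(is.na(out2$individuals$occupation[1:50])))
  # the 50+ override pins rates to the benchmark schedule
  old <- toy_state(40000, age = 62)
  ov <- benchmark_lfp_50plus()
  out3 <- apply_lfp(old, b$lfp, rng, override_50plus = ov)
  rate <- mean(out3$individuals$lfp)
  expect_lt(abs(rate - ov[["60-64"]]), 4 * sqrt(ov[["60-64"]] *
                                                  (1 - ov[["60-64"]]) / 40000))
  # empty state passes through
  empty <- population_state(toy_population(0), 2020)
  expect_equal(nrow(apply_lfp(empty, b$lfp, rng)$individuals), 0)
})
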