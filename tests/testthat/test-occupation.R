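test_that("zero and pure-intercept coefficients give the forced softmax", {
  terms <- c("(Intercept)", "sex_female", "edu", "sex_female:edu",
             "agegr", "agegr2", "dem_high", "dem_lowmed")
  zero <- occupation_coefficients(
    matrix(0, length(terms), 3, dimnames = list(terms, c("L", "M", "H"))))
  d <- toy_population(1)
  expect_equal(drop(occupation_probabilities(d, 0, 0, zero)),
               c(U = 0.25, L = 0.25, M = 0.25, H = 0.25), tolerance = 1e-12)
  beta <- matrix(0, length(terms), 3, dimnames = list(terms, c("L", "M", "H")))
  beta["(Intercept)", ] <- log(2)
  ints <- occupation_coefficients(beta)
  expect_equal(drop(occupation_probabilities(d, 0, 0, ints)),
               c(U = 1 / 7, L = 2 / 7, M = 2 / 7, H = 2 / 7),
               tolerance = 1e-12)
})

test_that("probabilities match an independent exponentiate-and-normalize oracle", {
  set.seed(41)
  for (rep in 1:25) {
    coeffs <- random_occ_coeffs()
    d <- random_occ_data(40)
    dh <- runif(1); dl <- runif(1)
    p <- occupation_probabilities(d, dh, dl, coeffs)
    # oracle: explicit per-row linear predictors, naive exp / sum(exp)
    for (i in sample(40, 5)) {
      sexf <- d$sex[i] == "female"
      edu <- match(d$education[i], c("low", "medium", "high")) - 1
      ag <- (d$age[i] - 15) %/% 5 + 1
      x <- c(1, sexf, edu, sexf * edu, ag, ag^2, dh, dl)
      eta <- c(0, colSums(x * coeffs$beta))
      oracle <- unname(exp(eta) / sum(exp(eta)))
      expect_equal(unname(p[i, ]), oracle, tolerance = 1e-12)
    }
    expect_true(all(abs(rowSums(p) - 1) < 1e-12))
  }
})

test_that("calibration rescaling follows the closed formula", {
  p <- matrix(0.25, 3, 4, dimnames = list(NULL, c("U", "L", "M", "H")))
  expect_equal(apply_calibration(p, c(1, 1, 1, 1)), p)
  out <- apply_calibration(p[1, , drop = FALSE], c(2, 1, 1, 1))
  expect_equal(drop(out), c(U = 0.4, L = 0.2, M = 0.2, H = 0.2))
  set.seed(42)
  q <- matrix(runif(400), 100, 4)
  q <- q / rowSums(q)
  lam <- c(1, runif(3, 0.2, 3))
  expect_true(all(abs(rowSums(apply_calibration(q, lam)) - 1) < 1e-12))
  expect_error(apply_calibration(q, c(1, 0, 1, 1)), "positive")
})

test_that("calibration factors reproduce targets and known fixed points", {
  set.seed(43)
  p <- matrix(runif(4000), 1000, 4)
  p <- p / rowSums(p)
  colnames(p) <- c("U", "L", "M", "H")
  # fixed point: target equal to the uncalibrated aggregate
  lam0 <- compute_calibration_factors(p, colMeans(p))
  expect_equal(unname(lam0), rep(1, 4), tolerance = 1e-4)
  # heterogeneous population, shifted target
  tgt <- c(U = 0.10, L = 0.15, M = 0.45, H = 0.30)
  lam <- compute_calibration_factors(p, tgt)
  agg <- colMeans(apply_calibration(p, lam))
  expect_true(max(abs(agg - tgt)) < 1e-6)
  # idempotence: recalibrating the calibrated model returns factors of 1
  lam2 <- compute_calibration_factors(apply_calibration(p, lam), tgt)
  expect_equal(unname(lam2), rep(1, 4), tolerance = 1e-4)
})

test_that("calibration factors agree with a brute-force grid oracle", {
  # two individuals, hand-set probabilities, single free factor structure:
  # target achievable with lambda = (1, g, 1, 1)
  p <- rbind(c(0.4, 0.2, 0.2, 0.2), c(0.2, 0.4, 0.2, 0.2))
  colnames(p) <- c("U", "L", "M", "H")
  g_true <- 1.7
  tgt <- colMeans(apply_calibration(p, c(1, g_true, 1, 1)))
  grid <- seq(1.0, 2.5, by = 1e-4)
  err <- vapply(grid, function(g) {
    max(abs(colMeans(apply_calibration(p, c(1, g, 1, 1))) - tgt))
  }, 0)
  g_grid <- grid[which.min(err)]
  lam <- compute_calibration_factors(p, tgt)
  expect_lt(abs(lam[["L"]] / lam[["U"]] - g_grid), 1e-4 + 1e-4)
})

test_that("allocation is degenerate, unbiased, and demand-responsive", {
  rng <- rng_streams(10)
  b <- small_bundle()
  ratios <- tibble::tibble(region = "central", dem_high = 0.45,
                           dem_lowmed = 0.6)
  # degenerate: huge negative predictors for all jobs force unemployment
  forced <- b$occupation
  forced$beta["(Intercept)", ] <- -50
  st <- toy_state(500)
  out <- allocate_occupations(st, forced, NULL, ratios, rng)
  expect_true(all(out$individuals$occupation == "U"))
  # aggregate counts within 4 SD of the summed calibrated probabilities
  st2 <- toy_state(30000)
  st2$individuals$education <- sample(c("low", "medium", "high"), 30000, TRUE)
  st2$individuals$age <- sample(20:64, 30000, TRUE)
  p <- occupation_probabilities(st2$individuals, ratios$dem_high,
                                ratios$dem_lowmed, b$occupation)
  out2 <- allocate_occupations(st2, b$occupation, NULL, ratios, rng)
  for (k in c("U", "L", "M", "H")) {
    got <- sum(out2$individuals$occupation == k)
    mu <- sum(p[, k])
    sd_k <- sqrt(sum(p[, k] * (1 - p[, k])))
    expect_lt(abs(got - mu), 4 * sd_k + 1e-9)
  }
  # education gradient: high job probability rises with education
  agg <- tapply(p[, "H"], st2$individuals$education, mean)
  expect_gt(agg[["high"]], agg[["low"]])
  u_agg <- tapply(p[, "U"], st2$individuals$education, mean)
  expect_lt(u_agg[["high"]], u_agg[["low"]])
  # raising high-skill demand lowers expected unemployment
  p_hi <- occupation_probabilities(st2$individuals, ratios$dem_high + 0.2,
                                   ratios$dem_lowmed, b$occupation)
  expect_lt(mean(p_hi[, "U"]), mean(p[, "U"]))
})

test_that("inactive individuals stay unassigned", {
  rng <- rng_streams(11)
  b <- small_bundle()
  st <- toy_state(100, lfp = FALSE)
  out <- allocate_occupations(
    st, b$occupation, NULL,
    tibble::tibble(region = "central", dem_high = 0.4, dem_lowmed = 0.6), rng)
  expect_true(all(is.na(out$individuals$occupation)))
})

test_that("the Newton-Raphson fit recovers simulated coefficients", {
  set.seed(51)
  coeffs <- random_occ_coeffs()
  d <- random_occ_data(50000)
  p <- occupation_probabilities(d, 0.45, 0.6, coeffs)
  u <- runif(50000)
  y <- c("U", "L", "M", "H")[1 + (u > p[, 1]) + (u > p[, 1] + p[, 2]) +
                               (u > 1 - p[, 4])]
  # demand ratios are constant here, hence collinear with the intercept:
  # drop them from the estimation design
  terms <- setdiff(coeffs$terms, c("dem_high", "dem_lowmed"))
  X <- occupation_design(d, 0.45, 0.6, coeffs$terms)[, terms]
  fit <- fit_multinomial_logit(X, y)
  truth <- coeffs$beta[terms, ]
  truth["(Intercept)", ] <- truth["(Intercept)", ] +
    0.45 * coeffs$beta["dem_high", ] + 0.6 * coeffs$beta["dem_lowmed", ]
  expect_true(all(abs(fit$coefficients - truth) < 3 * fit$std_error))
  expect_lt(fit$gradient_norm, 1e-8)
})

test_that("a two-outcome single-covariate fit matches the 2x2 log-odds", {
  set.seed(52)
  n <- 4000
  x <- sample(0:1, n, TRUE)
  pr <- plogis(-0.4 + 0.9 * x)
  y <- ifelse(runif(n) < pr, "L", "U")
  tab <- table(x, y)
  or_hat <- log(tab["1", "L"] * tab["0", "U"] /
                  (tab["0", "L"] * tab["1", "U"]))
  X <- cbind(`(Intercept)` = 1, x = x)
  fit <- fit_multinomial_logit(X, y, levels = c("U", "L"))
  expect_equal(unname(fit$coefficients["x", "L"]), or_hat, tolerance = 1e-8)
  expect_equal(unname(fit$coefficients["(Intercept)", "L"]),
               log(tab["0", "L"] / tab["0", "U"]), tolerance = 1e-8)
})

test_that("fitting null data returns estimates near zero", {
  set.seed(53)
  d <- random_occ_data(20000)
  y <- sample(c("U", "L", "M", "H"), 20000, TRUE)
  X <- occupation_design(d, 0, 0,
                         c("(Intercept)", "sex_female", "edu", "agegr"))
  fit <- fit_multinomial_logit(X, y)
  expect_true(all(abs(fit$coefficients) < 3 * fit$std_error + 1e-12))
})

test_that("estimator precision improves with sample size", {
  set.seed(54)
  coeffs <- random_occ_coeffs()
  terms <- setdiff(coeffs$terms, c("dem_high", "dem_lowmed"))
  rmse <- vapply(c(5000, 20000, 50000), function(n) {
    d <- random_occ_data(n)
    p <- occupation_probabilities(d, 0, 0, coeffs)
    u <- runif(n)
    y <- c("U", "L", "M", "H")[1 + (u > p[, 1]) + (u > p[, 1] + p[, 2]) +
                                 (u > 1 - p[, 4])]
    X <- occupation_design(d, 0, 0, coeffs$terms)[, terms]
    fit <- fit_multinomial_logit(X, y)
    sqrt(mean((fit$coefficients - coeffs$beta[terms, ])^2))
  }, 0)
  expect_true(rmse[3] < rmse[1])
})

test_that("the fit agrees with an independent optimizer", {
  skip_if_not_installed("nnet")
  set.seed(55)
  n <- 8000
  d <- random_occ_data(n)
  coeffs <- random_occ_coeffs()
  p <- occupation_probabilities(d, 0, 0, coeffs)
  u <- runif(n)
  y <- factor(c("U", "L", "M", "H")[1 + (u > p[, 1]) + (u > p[, 1] + p[, 2]) +
                                      (u > 1 - p[, 4])],
              levels = c("U", "L", "M", "H"))
  X <- occupation_design(d, 0, 0, coeffs$terms)[, c("sex_female", "edu",
                                                    "agegr")]
  fit <- fit_multinomial_logit(cbind(`(Intercept)` = 1, X), y)
  nn <- nnet::multinom(y ~ X, trace = FALSE, reltol = 1e-14, maxit = 500)
  expect_equal(unname(t(coef(nn))), unname(fit$coefficients),
               tolerance = 1e-4)
  expect_equal(as.numeric(logLik(nn)), fit$loglik, tolerance = 1e-8)
})

test_that("degenerate designs and outcomes raise informative errors", {
  d <- random_occ_data(200)
  X <- occupation_design(d, 0, 0, c("(Intercept)", "sex_female", "edu"))
  expect_error(fit_multinomial_logit(X, rep(c("U", "L", "M"), length.out = 200)),
               "no observations for outcome")
  Xbad <- cbind(X, dup = X[, "edu"])
  y <- sample(c("U", "L", "M", "H"), 200, TRUE)
  expect_error(fit_multinomial_logit(Xbad, y), "rank deficient")
  # perfect separation: a covariate that fully determines the outcome
  set.seed(56)
  xsep <- c(rep(0, 100), rep(1, 100))
  ysep <- c(rep("U", 100), rep("L", 100))
  expect_error(
    fit_multinomial_logit(cbind(`(Intercept)` = 1, x = xsep), ysep,
                          levels = c("U", "L")),
    "separat")
})
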