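OCC_LEVELS <- c("U", "L", "M", "H")

#' Occupation model coefficients
#'
#' Multinomial-logit parameters allocating active individuals to unemployment
#' (the reference category) or a low-, medium- or high-skill job. For each
#' non-reference outcome the linear predictor combines an intercept, sex,
#' education (coded 0/1/2 for low/medium/high), their interaction, the 5-year
#' age-group index and its square, immigrant-composite dummies (origin group x
#' recent/settled x childhood arrival) with education and sex interactions,
#' and two labour-demand ratios: high-skill demand over labour force, and
#' combined low-plus-medium demand over labour force.
#'
#' @param beta Numeric matrix, one column per non-reference outcome
#'   (`L`, `M`, `H`), rownames naming terms. Required rows:
#'   `(Intercept)`, `sex_female`, `edu`, `sex_female:edu`, `agegr`, `agegr2`,
#'   `dem_high`, `dem_lowmed`; any additional rows are treated as immigrant
#'   dummies and interactions and matched to design columns by name.
#' @param reference Reference outcome (fixed to "U").
#' @return An `occupation_coefficients` object.
#' @export
occupation_coefficients <- function(beta, reference = "U") {
  stopifnot(is.matrix(beta), !is.null(rownames(beta)))
  if (!identical(colnames(beta), c("L", "M", "H"))) {
    abort("beta must have columns L, M, H")
  }
  if (any(!is.finite(beta))) abort("coefficients must be finite")
  structure(list(beta = beta, reference = reference,
                 terms = rownames(beta)),
            class = "occupation_coefficients")
}

# immigrant composite classification used by the occupation and fixture code
immvar_class <- function(origin, duration, age_at_imm) {
  child <- !is.na(age_at_imm) & age_at_imm < 15L
  recent <- !is.na(duration) & duration < 5L
  ifelse(origin == "native", "native",
    ifelse(origin == "other_region", "other_region",
      ifelse(child, "ext_child",
        paste0(origin, ifelse(recent, "_recent", "_settled")))))
}

#' Occupation design matrix
#'
#' Builds the covariate matrix for [occupation_probabilities()] from
#' individual records plus the two country-year demand ratios.
#'
#' @param data Tibble with columns `sex`, `education`, `age`, `origin`,
#'   `duration`, `age_at_imm`.
#' @param dem_high,dem_lowmed Demand-to-labour-force ratios (scalar or one
#'   per row).
#' @param terms Term names the coefficient matrix expects (defines which
#'   immigrant dummies exist).
#' @return Numeric matrix with one row per individual.
#' @export
occupation_design <- function(data, dem_high, dem_lowmed, terms) {
  n <- nrow(data)
  sexf <- as.numeric(data$sex == "female")
  edu <- match(data$education, c("low", "medium", "high")) - 1
  if (anyNA(edu)) abort("education must be assigned for all records")
  agegr <- (pmin(pmax(data$age, 15L), 74L) - 15L) %/% 5L + 1L
  X <- cbind(`(Intercept)` = rep(1, n), sex_female = sexf, edu = edu,
             `sex_female:edu` = sexf * edu, agegr = agegr, agegr2 = agegr^2,
             dem_high = rep(dem_high, length.out = n),
             dem_lowmed = rep(dem_lowmed, length.out = n))
  imm <- immvar_class(data$origin, data$duration, data$age_at_imm)
  extra <- setdiff(terms, colnames(X))
  for (tm in extra) {
    if (endsWith(tm, ":edu")) {
      g <- sub(":edu$", "", tm)
      X <- cbind(X, (imm == g) * edu)
    } else if (endsWith(tm, ":sex_female")) {
      g <- sub(":sex_female$", "", tm)
      X <- cbind(X, (imm == g) * sexf)
    } else {
      X <- cbind(X, as.numeric(imm == tm))
    }
    colnames(X)[ncol(X)] <- tm
  }
  X[, terms, drop = FALSE]
}

#' Occupation probabilities
#'
#' Softmax of the multinomial-logit linear predictors, with the reference
#' (unemployment) predictor fixed at 0. Rows sum to 1 to within 1e-12.
#'
#' @param data Individual records (see [occupation_design()]).
#' @param dem_high,dem_lowmed Demand covariates.
#' @param coeffs An [occupation_coefficients()].
#' @return Matrix `n x 4` with columns `U`, `L`, `M`, `H`.
#' @export
occupation_probabilities <- function(data, dem_high, dem_lowmed, coeffs) {
  X <- occupation_design(data, dem_high, dem_lowmed, coeffs$terms)
  eta <- cbind(0, X %*% coeffs$beta)
  if (any(!is.finite(eta))) {
    bad <- which(!is.finite(rowSums(eta)))[1]
    abort(paste0("non-finite occupation predictor for record ", bad,
                 " (age ", data$age[bad], ", education ",
                 data$education[bad], ")"))
  }
  softmax_rows(eta, OCC_LEVELS)
}

softmax_rows <- function(eta, labels) {
  m <- eta - apply(eta, 1, max)
  e <- exp(m)
  p <- e / rowSums(e)
  colnames(p) <- labels
  p
}

#' Post-hoc calibration of occupation probabilities
#'
#' Rescales each individual's probability vector by outcome-specific factors
#' and renormalizes:
#' `p_k' = lambda_k p_k / sum_j lambda_j p_j`. With all factors equal to 1
#' this is the identity.
#'
#' @param p Matrix `n x 4` of probabilities (columns `U`, `L`, `M`, `H`).
#' @param lambda Positive factors, length 4, reference (`U`) fixed at 1.
#' @return The calibrated probability matrix.
#' @export
apply_calibration <- function(p, lambda) {
  if (any(lambda <= 0)) abort("calibration factors must be strictly positive")
  q <- sweep(p, 2, lambda, `*`)
  q / rowSums(q)
}

#' Calibration factors matching target occupation shares
#'
#' Finds multiplicative factors such that the population-aggregated calibrated
#' probabilities equal the target shares, by iterative proportional updating
#' (`lambda_k <- lambda_k * target_k / model_k`, reference renormalized to 1).
#' The factors are intended to be computed once in the base year against the
#' observed occupation distribution and held constant thereafter.
#'
#' @param p Matrix `n x 4` of uncalibrated probabilities.
#' @param target Target shares (length 4, simplex, names `U`,`L`,`M`,`H`).
#' @param tol Convergence tolerance on the maximum absolute share error.
#' @param max_iter Iteration cap.
#' @param lambda_floor Floor applied when a target share is 0 (with a
#'   warning), keeping probabilities well defined.
#' @return Named vector of factors with `U = 1`.
#' @export
compute_calibration_factors <- function(p, target, tol = 1e-6,
                                        max_iter = 500L,
                                        lambda_floor = 1e-9) {
  stopifnot(ncol(p) == 4L, length(target) == 4L)
  if (abs(sum(target) - 1) > 1e-8) abort("target shares must sum to 1")
  if (nrow(p) == 0L) abort("calibration requires a nonempty population")
  zero_tgt <- target == 0
  if (any(zero_tgt & colMeans(p) > 0)) {
    warn("target share of 0 with positive model mass; factor floored")
  }
  lambda <- setNames(rep(1, 4), OCC_LEVELS)
  for (it in seq_len(max_iter)) {
    agg <- colMeans(apply_calibration(p, lambda))
    if (max(abs(agg - target)) < tol) return(lambda)
    upd <- ifelse(agg > 0, target / agg, 1)
    lambda <- lambda * upd
    lambda[zero_tgt] <- lambda_floor
    lambda <- lambda / lambda["U"]
  }
  abort(sprintf(
    "calibration did not converge in %d iterations (share error %.2e)",
    max_iter, max(abs(colMeans(apply_calibration(p, lambda)) - target))))
}

#' Allocate occupations in the population
#'
#' Every active individual receives one of \{unemployed, low-, medium-,
#' high-skill job\} by a single multinomial draw from their calibrated
#' probabilities; inactive individuals stay unassigned. Calibration factors
#' are per region.
#'
#' @param state A [population_state()].
#' @param coeffs An [occupation_coefficients()].
#' @param calib Tibble `region, outcome, lambda` (or `NULL` for no
#'   calibration).
#' @param demand_ratios Tibble `region, dem_high, dem_lowmed` of current-year
#'   demand-to-labour-force ratios.
#' @param rng A [rng_streams()] (uses the `occupation` stream).
#' @param hiring_boost Optional list `list(odds = )`: multiplies the
#'   probability weight of the outcome one skill level above the
#'   education-matched job (low-educated: M, medium-educated: H) before the
#'   draw, renormalizing (the upskilling scenario hook).
#' @return The updated state.
#' @export
allocate_occupations <- function(state, coeffs, calib, demand_ratios, rng,
                                 hiring_boost = NULL) {
  ind <- state$individuals
  act <- which(present_idx(ind) & ind$lfp)
  if (length(act) == 0L) return(state)
  u <- with_stream(rng, "occupation", runif(length(act)))
  for (r in unique(ind$region[act])) {
    sel <- ind$region[act] == r
    rows <- act[sel]
    dr <- demand_ratios[demand_ratios$region == r, ]
    if (nrow(dr) != 1L) abort(paste0("missing demand ratios for region ", r))
    p <- occupation_probabilities(ind[rows, ], dr$dem_high, dr$dem_lowmed,
                                  coeffs)
    if (!is.null(calib)) {
      lam <- calib$lambda[calib$region == r][match(OCC_LEVELS,
               calib$outcome[calib$region == r])]
      p <- apply_calibration(p, lam)
    }
    if (!is.null(hiring_boost)) {
      edu <- ind$education[rows]
      w <- matrix(1, nrow(p), 4, dimnames = list(NULL, OCC_LEVELS))
      w[edu == "low", "M"] <- hiring_boost$odds
      w[edu == "medium", "H"] <- hiring_boost$odds
      p <- p * w
      p <- p / rowSums(p)
    }
    cum1 <- p[, 1]; cum2 <- cum1 + p[, 2]; cum3 <- cum2 + p[, 3]
    ui <- u[sel]
    ind$occupation[rows] <-
      OCC_LEVELS[1L + (ui > cum1) + (ui > cum2) + (ui > cum3)]
  }
  population_state(ind, state$year, state$scale_factor)
}

#' Fit the occupation model by maximum likelihood
#'
#' Newton-Raphson on the multinomial log-likelihood with a generalized-logit
#' link (reference category first), with step-halving, a divergence detector
#' for perfect separation, and a rank check naming collinear columns.
#' Standard errors come from the inverse observed information.
#'
#' @param x Design matrix (e.g. from [occupation_design()]).
#' @param y Observed outcomes: factor or character; the first level of
#'   `levels` is the reference.
#' @param levels Outcome levels, reference first.
#' @param max_iter,tol Newton-Raphson controls; convergence requires the
#'   gradient max-norm below `tol`.
#' @return An object of class `mnl_fit` with `coefficients` (term x outcome
#'   matrix), `std_error`, `vcov`, `loglik`, `iterations`, `gradient_norm`.
#' @export
fit_multinomial_logit <- function(x, y, levels = OCC_LEVELS,
                                  max_iter = 100L, tol = 1e-8) {
  x <- as.matrix(x)
  y <- as.character(y)
  if (!all(y %in% levels)) abort("outcome values outside the stated levels")
  cnt <- table(factor(y, levels = levels))
  if (any(cnt == 0L)) {
    abort(paste0("no observations for outcome(s): ",
                 paste(names(cnt)[cnt == 0], collapse = ", ")))
  }
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    bad <- colnames(x)[qrx$pivot[(qrx$rank + 1L):ncol(x)]]
    abort(paste0("design matrix is rank deficient; offending terms: ",
                 paste(bad, collapse = ", ")))
  }
  n <- nrow(x); p <- ncol(x); K <- length(levels) - 1L
  Y <- matrix(0, n, K)
  for (k in seq_len(K)) Y[, k] <- as.numeric(y == levels[k + 1L])
  B <- matrix(0, p, K)
  ll_of <- function(B) {
    eta <- cbind(0, x %*% B)
    m <- apply(eta, 1, max)
    sum((eta[cbind(seq_len(n), match(y, levels))] - m) -
          log(rowSums(exp(eta - m))))
  }
  ll <- ll_of(B)
  gnorm <- Inf
  for (it in seq_len(max_iter)) {
    eta <- cbind(0, x %*% B)
    P <- softmax_rows(eta, levels)[, -1L, drop = FALSE]
    G <- crossprod(x, Y - P)                     # p x K gradient
    gnorm <- max(abs(G))
    if (gnorm < tol) break
    H <- matrix(0, p * K, p * K)
    for (k in seq_len(K)) for (l in k:K) {
      w <- P[, k] * ((k == l) - P[, l])
      blk <- crossprod(x, x * w)
      ik <- (k - 1L) * p + seq_len(p); il <- (l - 1L) * p + seq_len(p)
      H[ik, il] <- blk
      H[il, ik] <- t(blk)
    }
    delta <- tryCatch(solve(H, as.vector(G)),
                      error = function(e) abort(
                        "information matrix is singular (possible separation)"))
    step <- 1
    repeat {
      Bn <- B + matrix(step * delta, p, K)
      lln <- ll_of(Bn)
      if (lln >= ll - 1e-10 || step < 1e-6) break
      step <- step / 2
    }
    if (max(abs(Bn)) > 30) {
      abort("estimates diverging; outcomes may be perfectly separated")
    }
    B <- Bn; ll <- lln
  }
  if (gnorm >= tol) {
    warn(sprintf("Newton-Raphson stopped at gradient norm %.2e", gnorm))
  }
  eta <- cbind(0, x %*% B)
  P <- softmax_rows(eta, levels)[, -1L, drop = FALSE]
  H <- matrix(0, p * K, p * K)
  for (k in seq_len(K)) for (l in k:K) {
    w <- P[, k] * ((k == l) - P[, l])
    blk <- crossprod(x, x * w)
    ik <- (k - 1L) * p + seq_len(p); il <- (l - 1L) * p + seq_len(p)
    H[ik, il] <- blk
    H[il, ik] <- t(blk)
  }
  V <- solve(H)
  se <- matrix(sqrt(diag(V)), p, K)
  dimnames(B) <- dimnames(se) <- list(colnames(x), levels[-1L])
  structure(list(coefficients = B, std_error = se, vcov = V,
                 loglik = ll, iterations = it, gradient_norm = gnorm,
                 nobs = n, levels = levels),
            class = "mnl_fit")
}

#' @export
print.mnl_fit <- function(x, ...) {
  cat("<mnl_fit> multinomial logit,", x$nobs, "obs, logLik",
      format(x$loglik), "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @describeIn fit_multinomial_logit Tidy the per-outcome coefficients.
#' @param x,object An `mnl_fit`.
#' @param ... Unused.
#' @export
tidy.mnl_fit <- function(x, ...) {
  est <- x$coefficients
  tibble(
    y.level = rep(colnames(est), each = nrow(est)),
    term = rep(rownames(est), ncol(est)),
    estimate = as.vector(est),
    std.error = as.vector(x$std_error)
  ) %>%
    mutate(statistic = .data$estimate / .data$std.error,
           p.value = 2 * stats::pnorm(-abs(.data$statistic)))
}

#' @describeIn fit_multinomial_logit One-row fit summary.
#' @export
glance.mnl_fit <- function(x, ...) {
  tibble(logLik = x$loglik, nobs = x$nobs, iterations = x$iterations,
         gradient_norm = x$gradient_norm,
         df = length(x$coefficients))
}
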