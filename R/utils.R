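`%||%` <- function(x, y) if (is.null(x)) y else x

#' Named independent random-number streams
#'
#' A single master seed spawns one L'Ecuyer-CMRG stream per simulation module
#' (mortality, fertility, migration, education, labour-force participation,
#' occupation, scenario operators), so that module-level draws are reproducible
#' in isolation: changing how many random numbers one module consumes does not
#' perturb the draws of the others.
#'
#' @param seed Integer master seed.
#' @param names Character vector of stream names to spawn.
#' @return An environment of class `rng_streams` holding one stream state per
#'   name. Use [with_stream()] to evaluate an expression under a given stream.
#' @export
#' @examples
#' rng <- rng_streams(1)
#' a <- with_stream(rng, "mortality", runif(3))
#' b <- with_stream(rng, "fertility", runif(3))
rng_streams <- function(seed,
                        names = c("base_population", "mortality", "fertility",
                                  "migration", "education", "lfp",
                                  "occupation", "scenario")) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  suppressWarnings(set.seed(as.integer(seed), kind = "L'Ecuyer-CMRG"))
  s <- get(".Random.seed", envir = globalenv())
  env <- new.env(parent = emptyenv())
  for (nm in names) {
    s <- parallel::nextRNGStream(s)
    assign(nm, s, envir = env)
  }
  class(env) <- "rng_streams"
  env
}

#' Evaluate an expression under a named random stream
#'
#' Swaps the named stream state into the session RNG, evaluates `expr`, stores
#' the advanced state back, and restores whatever RNG state was active before.
#'
#' @param streams An object from [rng_streams()].
#' @param name Stream name.
#' @param expr Expression performing random draws.
#' @return The value of `expr`.
#' @export
with_stream <- function(streams, name, expr) {
  stopifnot(inherits(streams, "rng_streams"))
  if (!exists(name, envir = streams, inherits = FALSE)) {
    abort(paste0("unknown RNG stream '", name, "'"))
  }
  old <- get0(".Random.seed", envir = globalenv())
  assign(".Random.seed", get(name, envir = streams), envir = globalenv())
  on.exit({
    assign(name, get(".Random.seed", envir = globalenv()), envir = streams)
    if (is.null(old)) {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

# round a non-negative expectation to an integer count, preserving the mean
stochastic_round <- function(x) {
  lo <- floor(x)
  as.integer(lo + (runif(length(x)) < (x - lo)))
}

# 5-year age-group label ("15-19", ...), capped at 100
age_band <- function(age, width = 5L) {
  lo <- pmin(age %/% width * width, 100L)
  paste0(lo, "-", lo + width - 1L)
}

# broad labour-force age groups used in reporting
broad_age_group <- function(age) {
  dplyr::case_when(
    age >= 15 & age <= 24 ~ "15-24",
    age >= 25 & age <= 54 ~ "25-54",
    age >= 55 & age <= 74 ~ "55-74",
    TRUE ~ NA_character_
  )
}

# linear interpolation over anchor years, constant outside the anchor range
interp_path <- function(anchor_years, anchor_values, years) {
  stats::approx(anchor_years, anchor_values, xout = years, rule = 2)$y
}
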