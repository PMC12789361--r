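#' Write a parameter bundle to disk
#'
#' Serializes every schedule and coefficient table of the bundle as plain CSV
#' plus a JSON config, and emits a JSON manifest with md5 checksums and a
#' machine-readable calibration verification report
#' (see [fixture_verification()]).
#'
#' @param bundle A [stylized_bundle()].
#' @param dir Destination directory.
#' @return The directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) readr::write_csv(df, file.path(dir, name))
  wr(bundle$base_spec$marginals, "marginals.csv")
  wr(bundle$mortality$q, "mortality.csv")
  wr(bundle$fertility$f, "fertility.csv")
  mg <- bundle$migration
  wr(mg$inflow, "inflow.csv")
  wr(mg$inflow_age, "inflow_age.csv")
  wr(mg$inflow_education, "inflow_education.csv")
  wr(mg$emigration_rates, "emigration.csv")
  wr(mg$od_rates, "od_rates.csv")
  ed <- bundle$education
  wr(bind_rows(
    tibble(component = "threshold", name = c("t1", "t2"),
           value = ed$thresholds),
    tibble(component = "scalar",
           name = c("beta_cohort", "cohort_ref", "cohort_plateau",
                    "beta_sex_female"),
           value = c(ed$beta_cohort, ed$cohort_ref, ed$cohort_plateau,
                     ed$beta_sex_female)),
    tibble(component = "mother", name = names(ed$beta_mother),
           value = unname(ed$beta_mother)),
    tibble(component = "region", name = names(ed$region_offsets),
           value = unname(ed$region_offsets))), "education_params.csv")
  lf <- bundle$lfp
  wr(bind_rows(
    tibble(component = "age_baseline", name = names(lf$age_baseline),
           value = unname(lf$age_baseline)),
    tibble(component = "edu", name = names(lf$beta_edu),
           value = unname(lf$beta_edu)),
    tibble(component = "origin", name = names(lf$beta_origin),
           value = unname(lf$beta_origin)),
    tibble(component = "scalar",
           name = c("beta_sex_female", "beta_recent", "beta_child_arrival",
                    "beta_cohort", "cohort_ref"),
           value = c(lf$beta_sex_female, lf$beta_recent,
                     lf$beta_child_arrival, lf$beta_cohort,
                     lf$cohort_ref))), "lfp_params.csv")
  oc <- bundle$occupation$beta
  wr(tibble(term = rep(rownames(oc), ncol(oc)),
            outcome = rep(colnames(oc), each = nrow(oc)),
            value = as.vector(oc)), "occupation_coefficients.csv")
  wr(bundle$occupation_targets, "occupation_targets.csv")
  wr(bundle$demand$ratios, "demand_ratios.csv")
  wr(bundle$demand_history, "demand_history.csv")
  wr(tibble(age_group = names(bundle$benchmark_50plus),
            rate = unname(bundle$benchmark_50plus)), "benchmark_50plus.csv")
  cfg <- list(regions = bundle$regions,
              region_share = as.list(bundle$region_share),
              year0 = bundle$year0, agents = bundle$agents,
              seed = bundle$seed, scale_factor = bundle$scale_factor,
              sex_ratio = bundle$fertility$sex_ratio,
              convergence_year = mg$convergence_year,
              migration_start_year = mg$start_year,
              recent_share = bundle$base_spec$recent_share)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  ver <- fixture_verification(bundle)
  jsonlite::write_json(ver, file.path(dir, "verification.json"),
                       dataframe = "rows", digits = NA)
  files <- setdiff(list.files(dir), "manifest.json")
  manifest <- list(files = lapply(setNames(files, files), function(f) {
    unname(tools::md5sum(file.path(dir, f)))
  }))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Read a parameter bundle from disk
#'
#' Inverse of [write_bundle()]; the demand share trend is refitted from the
#' stored history (an exact operation for logit-linear histories).
#'
#' @param dir Directory written by [write_bundle()].
#' @return A `skillsim_bundle`.
#' @export
read_bundle <- function(dir) {
  rd <- function(name) readr::read_csv(file.path(dir, name),
                                       show_col_types = FALSE, progress = FALSE)
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  marg <- rd("marginals.csv")
  base_spec <- base_population_spec(cfg$agents, cfg$scale_factor, marg,
                                    seed = cfg$seed, year = cfg$year0,
                                    recent_share = cfg$recent_share)
  mortality <- mortality_schedule(rd("mortality.csv"))
  fertility <- fertility_schedule(rd("fertility.csv"),
                                  sex_ratio = cfg$sex_ratio)
  migration <- migration_schedule(
    rd("inflow.csv"), rd("inflow_age.csv"), rd("inflow_education.csv"),
    rd("emigration.csv"), rd("od_rates.csv"),
    convergence_year = cfg$convergence_year,
    start_year = cfg$migration_start_year)
  edp <- rd("education_params.csv")
  pick <- function(df, comp) setNames(df$value[df$component == comp],
                                      df$name[df$component == comp])
  esc <- pick(edp, "scalar")
  education <- education_params(
    thresholds = unname(pick(edp, "threshold")[c("t1", "t2")]),
    beta_cohort = esc[["beta_cohort"]], cohort_ref = esc[["cohort_ref"]],
    cohort_plateau = esc[["cohort_plateau"]],
    beta_sex_female = esc[["beta_sex_female"]],
    beta_mother = pick(edp, "mother"),
    region_offsets = pick(edp, "region"))
  lfd <- rd("lfp_params.csv")
  lsc <- pick(lfd, "scalar")
  lfp <- lfp_params(
    age_baseline = pick(lfd, "age_baseline"),
    beta_edu = pick(lfd, "edu"), beta_origin = pick(lfd, "origin"),
    beta_sex_female = lsc[["beta_sex_female"]],
    beta_recent = lsc[["beta_recent"]],
    beta_child_arrival = lsc[["beta_child_arrival"]],
    beta_cohort = lsc[["beta_cohort"]], cohort_ref = lsc[["cohort_ref"]])
  occ <- rd("occupation_coefficients.csv")
  terms <- unique(occ$term)
  beta <- matrix(occ$value[order(match(occ$outcome, c("L", "M", "H")),
                                 match(occ$term, terms))],
                 nrow = length(terms),
                 dimnames = list(terms, c("L", "M", "H")))
  occupation <- occupation_coefficients(beta)
  demand_history <- rd("demand_history.csv")
  demand <- demand_schedule(rd("demand_ratios.csv"),
                            fit_share_trend(demand_history))
  bm <- rd("benchmark_50plus.csv")
  rs <- unlist(cfg$region_share)
  structure(list(
    regions = cfg$regions, region_share = rs[cfg$regions],
    year0 = cfg$year0, agents = cfg$agents, seed = cfg$seed,
    scale_factor = cfg$scale_factor, base_spec = base_spec,
    mortality = mortality, fertility = fertility, migration = migration,
    education = education, lfp = lfp, occupation = occupation,
    occupation_targets = rd("occupation_targets.csv"),
    demand = demand, demand_history = demand_history,
    benchmark_50plus = setNames(bm$rate, bm$age_group)),
    class = "skillsim_bundle")
}
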