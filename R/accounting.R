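#' Vacancies and vacancy rates by skill
#'
#' Vacancies are skill-specific labour demand minus jobs occupied at that
#' skill; they may be negative (demand is a covariate, not a hard cap) and
#' are reported signed. Rates are vacancies over demand; a rate with zero
#' demand and positive occupation is undefined and reported as `NA` with a
#' warning.
#'
#' @param demand Named numeric vector of demand by skill
#'   (`low`, `medium`, `high`), any unit.
#' @param occupied Named numeric vector of occupied jobs by skill, same unit.
#' @return Tibble `skill, demand, occupied, vacancies, vacancy_rate`,
#'   including a `total` row.
#' @export
vacancy_table <- function(demand, occupied) {
  skills <- c("low", "medium", "high")
  stopifnot(all(skills %in% names(demand)), all(skills %in% names(occupied)))
  if (any(demand < 0)) abort("demand must be non-negative")
  d <- c(demand[skills], total = sum(demand[skills]))
  o <- c(occupied[skills], total = sum(occupied[skills]))
  v <- d - o
  rate <- ifelse(d > 0, v / d, ifelse(o > 0, NA_real_, 0))
  if (anyNA(rate)) warn("vacancy rate undefined where demand is 0")
  tibble(skill = c(skills, "total"), demand = unname(d),
         occupied = unname(o), vacancies = unname(v),
         vacancy_rate = unname(rate))
}

#' Percentage change between two periods
#'
#' @param from,to Numeric vectors of the earlier and later values.
#' @return `(to - from) / from * 100`.
#' @export
pct_change <- function(from, to) (to - from) / from * 100

#' Underutilized workers
#'
#' An active individual is underutilized if unemployed or holding a job whose
#' skill level is below the level matching their education (high-educated in
#' medium- or low-skill jobs, medium-educated in low-skill jobs). The share
#' divides by the active labour force.
#'
#' @param state A [population_state()], occupations allocated.
#' @return One-row tibble `count, active, share` (agent counts).
#' @export
underutilization <- function(state) {
  ind <- state$individuals
  a <- ind[present_idx(ind) & ind$lfp, ]
  under <- a$occupation == "U" |
    (a$education == "high" & a$occupation %in% c("M", "L")) |
    (a$education == "medium" & a$occupation == "L")
  tibble(count = sum(under), active = nrow(a),
         share = if (nrow(a) > 0) sum(under) / nrow(a) else NA_real_)
}

#' Skill-mismatch composition matrices
#'
#' Two row-normalized tables: the occupation distribution of workers within
#' each educational attainment (which includes unemployment), and the
#' educational composition of the holders of each job skill level. Rows sum
#' to 1; empty groups are omitted with a message.
#'
#' @param state A [population_state()], occupations allocated.
#' @return List of tibbles `occupation_by_education` (education, U/L/M/H
#'   shares) and `education_by_job` (job skill, low/medium/high shares).
#' @export
mismatch_matrices <- function(state) {
  ind <- state$individuals
  a <- ind[present_idx(ind) & ind$lfp & !is.na(ind$occupation), ]
  obe <- a %>%
    count(.data$education, .data$occupation) %>%
    group_by(.data$education) %>%
    mutate(share = .data$n / sum(.data$n)) %>%
    ungroup() %>%
    select(-"n") %>%
    tidyr::pivot_wider(names_from = "occupation", values_from = "share",
                       values_fill = 0)
  for (k in OCC_LEVELS) if (!k %in% names(obe)) obe[[k]] <- 0
  obe <- obe[, c("education", OCC_LEVELS)]
  miss_e <- setdiff(c("low", "medium", "high"), obe$education)
  if (length(miss_e)) {
    message("no active workers with education: ", paste(miss_e, collapse = ", "))
  }
  w <- a[a$occupation != "U", ]
  ebj <- w %>%
    count(.data$occupation, .data$education) %>%
    group_by(.data$occupation) %>%
    mutate(share = .data$n / sum(.data$n)) %>%
    ungroup() %>%
    select(-"n") %>%
    tidyr::pivot_wider(names_from = "education", values_from = "share",
                       values_fill = 0) %>%
    rename(job_skill = "occupation")
  for (e in c("low", "medium", "high")) if (!e %in% names(ebj)) ebj[[e]] <- 0
  ebj <- ebj[, c("job_skill", "low", "medium", "high")]
  list(occupation_by_education = obe, education_by_job = ebj)
}

#' Yearly mismatch accounting for a simulated state
#'
#' Aggregates one simulation year into the per-year report rows: workers by
#' education and by occupation, unemployment, demand, vacancies and rates,
#' underutilization and the composition matrices. Counts are agent counts;
#' multiply by the state's scale factor for persons.
#'
#' @param state A [population_state()] with occupations allocated.
#' @param demand_state Tibble `region, year, total, dem_high, dem_medium,
#'   dem_low` for the year (agent units).
#' @return A list of tibbles (one year of a mismatch report).
#' @export
account_year <- function(state, demand_state) {
  ind <- state$individuals
  a <- ind[present_idx(ind) & ind$lfp, ]
  by_edu <- c(low = sum(a$education == "low"),
              medium = sum(a$education == "medium"),
              high = sum(a$education == "high"))
  by_occ <- c(low = sum(a$occupation == "L", na.rm = TRUE),
              medium = sum(a$occupation == "M", na.rm = TRUE),
              high = sum(a$occupation == "H", na.rm = TRUE))
  unemp <- sum(a$occupation == "U", na.rm = TRUE)
  dem <- c(low = sum(demand_state$dem_low),
           medium = sum(demand_state$dem_medium),
           high = sum(demand_state$dem_high))
  vt <- vacancy_table(dem, by_occ)
  mm <- mismatch_matrices(state)
  uu <- underutilization(state)
  list(year = state$year,
       workers = tibble(year = state$year,
                        education = names(by_edu),
                        workers_by_education = unname(by_edu),
                        workers_by_occupation = unname(by_occ)),
       unemployed = tibble(year = state$year, unemployed = unemp),
       vacancies = mutate(vt, year = state$year, .before = 1),
       underutilization = mutate(uu, year = state$year, .before = 1),
       occupation_by_education = mutate(mm$occupation_by_education,
                                        year = state$year, .before = 1),
       education_by_job = mutate(mm$education_by_job,
                                 year = state$year, .before = 1))
}

#' Write a mismatch report to CSV files
#'
#' Long-format files, one row per (scenario, year, category):
#' `demand_occupied_vacancies.csv` (skill, demand, occupied, vacancies,
#' vacancy_rate), `workers.csv` (education, workers by education and by
#' occupation, unemployed), `underutilization.csv` (count, active, share),
#' and `mismatch_matrices.csv` (matrix, row group, shares). Counts are both
#' in agents and in persons (agents times the scale factor).
#'
#' @param run A `skillsim_run` from [run_projection()].
#' @param dir Destination directory (created if needed).
#' @return The written file paths, invisibly.
#' @export
write_report <- function(run, dir) {
  stopifnot(inherits(run, "skillsim_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(paste0("cannot create directory ", dir))
  sc <- run$scenario$name
  k <- run$scale_factor
  rep <- run$report
  vac <- rep$vacancies %>%
    mutate(scenario = sc, .before = 1) %>%
    mutate(demand_persons = .data$demand * k,
           occupied_persons = .data$occupied * k,
           vacancies_persons = .data$vacancies * k)
  workers <- rep$workers %>%
    left_join(rep$unemployed, by = "year") %>%
    mutate(scenario = sc, .before = 1)
  uu <- rep$underutilization %>%
    mutate(scenario = sc, .before = 1) %>%
    mutate(count_persons = .data$count * k)
  mm <- bind_rows(
    rep$occupation_by_education %>%
      tidyr::pivot_longer(dplyr::all_of(OCC_LEVELS), names_to = "column",
                          values_to = "share") %>%
      mutate(matrix = "occupation_by_education") %>%
      rename(row = "education"),
    rep$education_by_job %>%
      tidyr::pivot_longer(c("low", "medium", "high"), names_to = "column",
                          values_to = "share") %>%
      mutate(matrix = "education_by_job") %>%
      rename(row = "job_skill")
  ) %>%
    mutate(scenario = sc, .before = 1) %>%
    select("scenario", "year", "matrix", "row", "column", "share")
  paths <- file.path(dir, c("demand_occupied_vacancies.csv", "workers.csv",
                            "underutilization.csv", "mismatch_matrices.csv"))
  readr::write_csv(vac, paths[1])
  readr::write_csv(workers, paths[2])
  readr::write_csv(uu, paths[3])
  readr::write_csv(mm, paths[4])
  invisible(paths)
}
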