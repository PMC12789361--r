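#' Plot vacancy rates by skill over time
#'
#' @param object A `skillsim_run`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.skillsim_run <- function(object, ...) {
  v <- object$report$vacancies
  ggplot2::ggplot(v, ggplot2::aes(x = .data$year, y = .data$vacancy_rate,
                                  colour = .data$skill)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%",
                                                             100 * x)) +
    ggplot2::labs(x = NULL, y = "vacancy rate (share of demand)",
                  colour = "job skill",
                  title = paste0("Vacancy rates, scenario '",
                                 object$scenario$name, "'")) +
    ggplot2::theme_minimal()
}

#' Plot projected and occupied jobs by skill
#'
#' Demand (dashed) versus occupied jobs (solid) per skill level; the gap is
#' the vacancy count.
#'
#' @param run A `skillsim_run`.
#' @return A ggplot.
#' @export
plot_demand_occupied <- function(run) {
  v <- run$report$vacancies %>%
    filter(.data$skill != "total") %>%
    tidyr::pivot_longer(c("demand", "occupied"), names_to = "series",
                        values_to = "jobs") %>%
    mutate(jobs_persons = .data$jobs * run$scale_factor / 1e6)
  ggplot2::ggplot(v, ggplot2::aes(x = .data$year, y = .data$jobs_persons,
                                  colour = .data$skill,
                                  linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(values = c(demand = "dashed",
                                              occupied = "solid")) +
    ggplot2::labs(x = NULL, y = "jobs (millions of persons)",
                  colour = "job skill", linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the occupation mix within each educational group
#'
#' Stacked composition of unemployment and job skill levels by educational
#' attainment for selected years; the below-education share is the
#' overqualification component of underutilization.
#'
#' @param run A `skillsim_run`.
#' @param years Years to facet (default first and last simulated year).
#' @return A ggplot.
#' @export
plot_mismatch <- function(run, years = range(run$years)) {
  m <- run$report$occupation_by_education %>%
    filter(.data$year %in% years) %>%
    tidyr::pivot_longer(dplyr::all_of(OCC_LEVELS), names_to = "occupation",
                        values_to = "share") %>%
    mutate(occupation = factor(.data$occupation, levels = rev(OCC_LEVELS)),
           education = factor(.data$education,
                              levels = c("low", "medium", "high")))
  ggplot2::ggplot(m, ggplot2::aes(x = .data$education, y = .data$share,
                                  fill = .data$occupation)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~year) +
    ggplot2::labs(x = "educational attainment", y = "share of active workers",
                  fill = "occupation") +
    ggplot2::theme_minimal()
}

#' Plot projected demand shares by skill
#'
#' @param trend A `share_trend` fit.
#' @param region Region to project.
#' @param years Projection years.
#' @return A ggplot.
#' @export
plot_demand_shares <- function(trend, region, years = 2010:2060) {
  sh <- project_shares(trend, region, years) %>%
    tidyr::pivot_longer(dplyr::starts_with("share_"), names_to = "skill",
                        names_prefix = "share_", values_to = "share")
  ggplot2::ggplot(sh, ggplot2::aes(x = .data$year, y = .data$share,
                                   colour = .data$skill)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = NULL, y = "share of labour demand", colour = "skill") +
    ggplot2::theme_minimal()
}
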