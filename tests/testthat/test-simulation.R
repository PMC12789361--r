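test_that("a run is a pure function of bundle, scenario and seed", {
  b <- small_bundle()
  r1 <- run_projection(b, seed = 5, years = 2020:2024)
  r2 <- run_projection(b, seed = 5, years = 2020:2024)
  expect_identical(r1$final_state$individuals, r2$final_state$individuals)
  expect_identical(r1$report$vacancies, r2$report$vacancies)
  r3 <- run_projection(b, seed = 6, years = 2020:2024)
  expect_false(identical(r1$report$vacancies, r3$report$vacancies))
})

test_that("the reference scenario is a strict no-op layer", {
  b <- small_bundle()
  ref <- run_projection(b, build_scenario("reference"), seed = 7,
                        years = 2020:2024)
  bare <- run_projection(b, scenario_spec("none", operators = list()),
                         seed = 7, years = 2020:2024)
  expect_identical(ref$final_state$individuals, bare$final_state$individuals)
  expect_identical(ref$report$vacancies, bare$report$vacancies)
  expect_identical(ref$events, bare$events)
})

test_that("the demographic accounting identity holds agent-exactly", {
  b <- small_bundle()
  r <- run_projection(b, seed = 8, years = 2020:2026)
  ev <- r$events
  for (i in 2:nrow(ev)) {
    expect_identical(ev$population[i],
                     ev$population[i - 1] + ev$births[i] - ev$deaths[i] -
                       ev$emigrants[i] + ev$immigrants[i])
  }
})

test_that("labour supply splits exactly into employed and unemployed", {
  b <- small_bundle()
  r <- run_projection(b, seed = 9, years = 2020:2023)
  w <- r$report$workers |>
    dplyr::group_by(year) |>
    dplyr::summarise(edu = sum(workers_by_education),
                     occ = sum(workers_by_occupation))
  u <- r$report$unemployed
  expect_identical(w$edu, w$occ + u$unemployed)
  expect_silent(validate_population(r$final_state))
})

test_that("fit summaries and plots are well formed", {
  b <- small_bundle()
  r <- run_projection(b, seed = 10, years = 2020:2022)
  td <- tidy(r)
  expect_true(all(c("scenario", "demand_persons") %in% names(td)))
  g <- glance(r)
  expect_equal(g$final_year, 2022)
  expect_s3_class(autoplot(r), "ggplot")
  expect_s3_class(plot_demand_occupied(r), "ggplot")
  expect_s3_class(plot_mismatch(r), "ggplot")
  expect_s3_class(plot_demand_shares(b$demand$trend, "central"), "ggplot")
})

test_that("scenario operators act on the intended margins", {
  b <- small_bundle()
  yrs <- 2020:2027
  ref <- run_projection(b, seed = 11, years = yrs)
  # 50% higher inflow: more immigrants every active year
  hi <- run_projection(b, build_scenario("high_immigration"), seed = 11,
                       years = yrs)
  expect_identical(hi$events$immigrants[hi$events$year < 2025],
                   ref$events$immigrants[ref$events$year < 2025])
  expect_true(all(hi$events$immigrants[hi$events$year >= 2025] >
                    ref$events$immigrants[ref$events$year >= 2025]))
  # retraining only relabels drawn occupations upward
  re <- run_projection(b, build_scenario("retraining"), seed = 11,
                       years = yrs)
  expect_identical(re$events, ref$events)
  v_ref <- ref$report$workers
  v_re <- re$report$workers
  hi_ref <- v_ref$workers_by_occupation[v_ref$education == "high" &
                                          v_ref$year == 2027]
  hi_re <- v_re$workers_by_occupation[v_re$education == "high" &
                                        v_re$year == 2027]
  expect_gte(hi_re, hi_ref)
  # later retirement raises 55-74 activity from the start year on
  lr <- run_projection(b, build_scenario("later_retirement"), seed = 11,
                       years = yrs)
  old_active <- function(r) {
    ind <- r$final_state$individuals
    mean(ind$lfp[ind$alive & !ind$emigrated & ind$age >= 55 & ind$age <= 64])
  }
  expect_gt(old_active(lr), old_active(ref))
  # better selection relabels arrivals to the high-performing origin block
  rng <- rng_streams(12)
  st <- toy_state(100, scale_factor = b$scale_factor, region = "central")
  st$individuals$region <- sample(b$regions, 100, TRUE)
  sel <- apply_immigration(st, b$migration, rng, origin_override = "ext_A")
  arrivals <- sel$individuals[sel$individuals$duration == 0L &
                                !is.na(sel$individuals$duration), ]
  expect_gt(nrow(arrivals), 0)
  expect_true(all(arrivals$origin == "ext_A"))
  # and the high-performing block is indeed better educated
  ie <- b$migration$inflow_education
  expect_gt(ie$share[ie$origin == "ext_A" & ie$education == "high"],
            ie$share[ie$origin == "ext_B" & ie$education == "high"])
})
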