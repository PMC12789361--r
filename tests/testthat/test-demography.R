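test_that("mortality extremes behave as probabilities dictate", {
  rng <- rng_streams(1)
  st <- toy_state(500)
  none <- apply_mortality(st, flat_mortality(0), rng)
  expect_true(all(none$individuals$alive))
  all_die <- apply_mortality(st, flat_mortality(1), rng)
  expect_true(all(!all_die$individuals$alive))
})

test_that("death counts follow the binomial oracle", {
  rng <- rng_streams(2)
  st <- toy_state(100000)
  out <- apply_mortality(st, flat_mortality(0.01), rng)
  deaths <- sum(!out$individuals$alive)
  # binomial mean 1000, sd sqrt(n p (1-p))
  expect_lt(abs(deaths - 1000), 4 * sqrt(100000 * 0.01 * 0.99))
})

test_that("missing mortality cells raise a configuration error", {
  rng <- rng_streams(1)
  sched <- flat_mortality(0.01)
  sched$q <- sched$q[sched$q$sex != "male", ]
  expect_error(apply_mortality(toy_state(10), sched, rng), "missing cells")
})

test_that("life expectancy follows the life-table conventions", {
  expect_equal(life_expectancy_of(flat_mortality(1), "female"), 0.5)
  expect_equal(life_expectancy_of(flat_mortality(0), "female"), 100.5)
  # e0 rises monotonically when q declines uniformly
  e0s <- vapply(c(0.05, 0.02, 0.01, 0.005),
                function(q) life_expectancy_of(flat_mortality(q), "male"), 0)
  expect_true(all(diff(e0s) > 0))
  bad <- flat_mortality(0.5)
  bad$q$q[5] <- 1.2
  expect_error(mortality_schedule(bad$q), "\\[0, 1\\]")
})

test_that("fixture mortality hits the life-expectancy path", {
  b <- small_bundle()
  expect_lt(abs(life_expectancy_of(b$mortality, "female", period = 2020) - 83.5), 0.5)
  expect_lt(abs(life_expectancy_of(b$mortality, "male", period = 2020) - 77.6), 0.5)
  expect_lt(abs(life_expectancy_of(b$mortality, "female", period = 2057) - 91.2), 0.5)
  expect_lt(abs(life_expectancy_of(b$mortality, "male", period = 2057) - 85.6), 0.5)
  # education gradient: lower mortality means longer life for the high educated
  expect_gt(life_expectancy_of(b$mortality, "female", "high"),
            life_expectancy_of(b$mortality, "female", "low"))
})

test_that("fertility extremes and the binomial oracle hold", {
  rng <- rng_streams(3)
  women <- toy_state(50000, age = 27, sex = "female")
  none <- apply_fertility(women, flat_fertility(0), rng)
  expect_equal(nrow(none$individuals), 50000)
  out <- apply_fertility(women, flat_fertility(0.1), rng)
  births <- nrow(out$individuals) - 50000
  expect_lt(abs(births - 5000), 4 * sqrt(50000 * 0.1 * 0.9))
  babies <- out$individuals[out$individuals$age == 0, ]
  expect_true(all(babies$birth_year == 2020))
  expect_true(all(babies$mother_edu == "medium"))
  expect_true(all(babies$origin == "native"))
  expect_true(all(babies$in_school))
})

test_that("the fixture schedule implies the assumed fertility path", {
  b <- small_bundle()
  expect_lt(abs(implied_tfr(b$fertility, period = 2020) - 1.51), 0.01)
  expect_lt(abs(implied_tfr(b$fertility, period = 2037) - 1.58), 0.01)
  expect_lt(abs(implied_tfr(b$fertility, period = 2057) - 1.64), 0.01)
})

test_that("emigration extremes and flags behave", {
  rng <- rng_streams(4)
  st <- toy_state(1000)
  stay <- apply_emigration(st, simple_migration(0), rng)
  expect_true(all(!stay$individuals$emigrated))
  go <- apply_emigration(st, simple_migration(1), rng)
  expect_true(all(go$individuals$emigrated))
  expect_true(all(go$individuals$alive))  # emigrated, not dead
  mid <- apply_emigration(toy_state(50000), simple_migration(0.02), rng)
  gone <- sum(mid$individuals$emigrated)
  expect_lt(abs(gone - 1000), 4 * sqrt(50000 * 0.02 * 0.98))
})

test_that("immigration creates arrivals with a fresh duration clock", {
  rng <- rng_streams(5)
  st <- toy_state(100, scale_factor = 10)
  none <- apply_immigration(st, simple_migration(0, inflow_persons = 0), rng)
  expect_identical(none$individuals, st$individuals)
  out <- apply_immigration(st, simple_migration(0, inflow_persons = 5000), rng)
  arr <- out$individuals[out$individuals$origin == "ext_B", ]
  expect_equal(nrow(arr), 500)  # 5000 persons / scale 10, integral so exact
  expect_true(all(arr$duration == 0L))
  expect_true(all(arr$age_at_imm == arr$age))
  expect_true(all(!duplicated(out$individuals$id)))
})

test_that("the fixture inflow reproduces the scheduled 5-year volume", {
  b <- small_bundle()
  inflow <- b$migration$inflow
  expect_equal(sum(inflow$persons[inflow$year %in% 2020:2024]), 15272419,
               tolerance = 1e-9)
})

test_that("the population is constant when all rates are zero", {
  rng <- rng_streams(6)
  st <- toy_state(2000)
  mig <- simple_migration(0)
  for (k in 1:3) {
    st <- advance_clock(st)
    st <- apply_mortality(st, flat_mortality(0, periods = c(2020L, 2025L)), rng)
    st <- apply_emigration(st, mig, rng)
    st <- apply_immigration(st, mig, rng)
    st <- apply_fertility(st, flat_fertility(0, periods = c(2020L, 2025L)), rng)
  }
  expect_equal(sum(st$individuals$alive & !st$individuals$emigrated), 2000)
})

test_that("between-region moves reclassify origin and restart the clock", {
  rng <- rng_streams(7)
  st <- toy_state(5000, region = "central")
  sched <- simple_migration(0)
  sched$od_rates <- tibble::tibble(
    from_region = "central", to_region = "north",
    origin_class = "native", rate_start = 0.5, rate_target = 0.5)
  out <- apply_internal_migration(st, sched, rng)
  moved <- out$individuals[out$individuals$region == "north", ]
  expect_gt(nrow(moved), 0)
  expect_true(all(moved$origin == "other_region"))
  expect_true(all(moved$duration == 0L))
  expect_true(all(moved$birth_region == "central"))
})
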