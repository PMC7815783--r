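test_that("incidence hazard composes relative risks multiplicatively", {
  p <- model_params(lambda0 = 0.01, rr = c(obese = 2, smoker = 1.5, inactive = 1.3))
  # empty product: baseline hazard untouched
  expect_identical(incidence_hazard(p, "female", 5, character()), 0.01)
  # hand multiplication over all three factors
  expect_equal(incidence_hazard(p, "male", 8, c("obese", "smoker", "inactive")),
               0.01 * 2 * 1.5 * 1.3)
  # RR-neutral limit: profile-independent
  pn <- model_params(lambda0 = 0.01, rr = c(obese = 1, smoker = 1, inactive = 1))
  for (prof in list(character(), "obese", c("smoker", "inactive"))) {
    expect_equal(incidence_hazard(pn, "female", 3, prof), 0.01)
  }
  expect_error(incidence_hazard(p, "female", 25, "obese"), "age_band")
  expect_error(incidence_hazard(p, "female", 3, "vaping"), "unknown risk factor")
})

test_that("adding a factor never decreases the hazard when all rr >= 1", {
  p <- model_params(lambda0 = 0.02, rr = c(obese = 3.1, smoker = 1, inactive = 1.2))
  profiles <- list(character(), "obese", "smoker", "inactive",
                   c("obese", "smoker"), c("obese", "inactive"),
                   c("smoker", "inactive"))
  for (prof in profiles) {
    for (extra in setdiff(c("obese", "smoker", "inactive"), prof)) {
      expect_gte(incidence_hazard(p, "male", 7, c(prof, extra)),
                 incidence_hazard(p, "male", 7, prof))
    }
  }
})

test_that("null dynamics leave the state unchanged and closed populations conserve mass", {
  st <- make_state(2000, 5e4, p_obese = 0.3, p_smoker = 0.1, p_inactive = 0.4,
                   p_diabetic = 0.1)
  p0 <- model_params(aging_rate = 0) # every rate zero, no entry
  expect_equal(step_state(st, p0, 0.1)$counts, st$counts, tolerance = 0)

  # closed population (entry = mortality = 0) with every internal flow active
  p <- model_params(entry_rate = 0, mortality = 0, lambda0 = 0.02,
                    onset = list(obese = 0.05, smoker = 0.02, inactive = 0.08),
                    reversal = list(obese = 0.01, smoker = 0.03, inactive = 0.02),
                    rr = c(obese = 2.5, smoker = 1.4, inactive = 1.6))
  s <- st
  for (i in 1:100) s <- step_state(s, p, 0.1)
  expect_equal(total_population(s), total_population(st), tolerance = 1e-9)
  expect_true(all(s$counts >= 0))
})

test_that("a single cohort under constant hazard follows 1 - exp(-lambda t)", {
  lam <- 0.3; t_end <- 2
  counts <- array(0, dim = c(2L, 20L, 2L, 2L, 2L, 2L))
  counts[1, 11, 1, 1, 1, 1] <- 1000 # one cohort, factor-free, non-diabetic
  st <- compartment_state(0, counts)
  p <- model_params(aging_rate = 0, lambda0 = lam)
  frac_at <- function(dt) {
    traj <- simulate_model(st, p, t_end, dt)
    prevalence(state_at(traj, t_end), "diabetes")
  }
  truth <- 1 - exp(-lam * t_end)
  err1 <- abs(frac_at(0.1) - truth)
  err2 <- abs(frac_at(0.05) - truth)
  expect_lt(err1, 0.01)            # O(dt) discretization error
  expect_lt(err2, err1 * 0.7)      # halving dt shrinks the error
})

test_that("trajectories are scale-equivariant and have the requested length", {
  st <- make_state(2000, 1e4, p_obese = 0.3, p_diabetic = 0.1)
  p <- model_params(entry_rate = c(female = 100, male = 120), mortality = 0.01,
                    lambda0 = 0.01, onset = 0.03, reversal = 0.01,
                    rr = c(obese = 2, smoker = 1.3, inactive = 1.5))
  # t_end = t0 + dt: exactly two states
  expect_length(simulate_model(st, p, 2000.1, 0.1)$states, 2L)

  traj1 <- simulate_model(st, p, 2005, 0.25)
  st2 <- compartment_state(st$time, st$counts * 2)
  p2 <- p; p2$entry_rate <- p$entry_rate * 2
  traj2 <- simulate_model(st2, p2, 2005, 0.25)
  expect_equal(state_at(traj2, 2005)$counts, 2 * state_at(traj1, 2005)$counts,
               tolerance = 1e-12)
})

test_that("halving dt barely moves long-horizon prevalences", {
  st <- make_state(2012, 1e5, p_obese = 0.4, p_smoker = 0.16, p_inactive = 0.46,
                   p_diabetic = 0.12)
  p <- model_params(entry_rate = c(female = 900, male = 900), mortality = 0.012,
                    lambda0 = 0.006, onset = 0.02, reversal = 0.005,
                    rr = c(obese = 3, smoker = 1.3, inactive = 1.6))
  pr <- function(dt) {
    prevalence(state_at(simulate_model(st, p, 2050, dt), 2050), "diabetes",
               age_range = c(15, 79))
  }
  expect_lt(abs(pr(0.2) - pr(0.1)), 0.002)
})

test_that("the step rejects dt values that break per-step probabilities", {
  st <- make_state(0, 1000, p_obese = 0.5)
  fast <- model_params(onset = list(obese = 12, smoker = 0, inactive = 0))
  expect_error(step_state(st, fast, 0.25), "transition probability")
  expect_error(step_state(st, fast, 0.5), "dt")
  expect_error(step_state(st, fast, -0.1), "positive")
})

test_that("diabetes is absorbing: prevalence never falls in a closed cohort", {
  st <- make_state(0, 1e4, p_obese = 0.4, p_diabetic = 0.05)
  p <- model_params(mortality = 0.02, lambda0 = 0.01, onset = 0.02,
                    reversal = 0.01, rr = c(obese = 2, smoker = 1, inactive = 1))
  traj <- simulate_model(st, p, 20, 0.1)
  prevs <- vapply(traj$states, prevalence, numeric(1), quantity = "diabetes")
  expect_true(all(diff(prevs) >= -1e-12))
})

test_that("prevalence does hand arithmetic and honours filters", {
  counts <- array(0, dim = c(2L, 20L, 2L, 2L, 2L, 2L))
  counts[1, 4, 1, 1, 1, 2] <- 10   # diabetic
  counts[2, 4, 2, 1, 1, 2] <- 30   # diabetic, obese
  counts[1, 5, 1, 1, 1, 1] <- 20
  counts[2, 5, 2, 1, 1, 1] <- 40
  st <- compartment_state(0, counts)
  expect_equal(prevalence(st, "diabetes"), 0.40)
  expect_equal(prevalence(st, "obesity"), 0.70)
  # single-stratum filters are exactly 0 or 1
  expect_equal(prevalence(st, "diabetes", sex = "female", age_range = c(15, 19)), 1)
  expect_equal(prevalence(st, "diabetes", sex = "female", age_range = c(20, 24)), 0)
  # profile predicate
  expect_equal(prevalence(st, "diabetes", profile = c(obese = TRUE)), 30 / 70)
  expect_error(prevalence(st, "diabetes", sex = "male", age_range = c(90, 99)),
               "undefined|no occupancy")
})

test_that("calibration recovers known parameters and handles degenerate specs", {
  init <- make_state(0, 1e4, p_obese = 0.3)
  true <- model_params(lambda0 = 0.02, onset = list(obese = 0.05, smoker = 0, inactive = 0),
                       rr = c(obese = 3, smoker = 1, inactive = 1))
  traj <- simulate_model(init, true, 10, 0.1)
  targets <- rbind(
    prevalence_target(5, "diabetes", prevalence(state_at(traj, 5), "diabetes")),
    prevalence_target(10, "diabetes", prevalence(state_at(traj, 10), "diabetes")),
    prevalence_target(10, "obesity", prevalence(state_at(traj, 10), "obesity")))

  # zero free parameters: params and loss returned unchanged
  cal0 <- calibrate_model(init, true, targets, free = list())
  expect_identical(cal0$params, true)
  expect_lt(cal0$loss, 1e-20)

  # perturbed start, two free scales: recovered within 1 % relative error
  start <- true
  start$lambda0 <- true$lambda0 * 0.4
  start$onset$obese <- true$onset$obese * 2.5
  cal <- calibrate_model(init, start, targets,
                         free = list(lambda0 = c(0.05, 20), onset.obese = c(0.05, 20)),
                         dt = 0.1)
  expect_lt(max(abs(cal$params$lambda0 / true$lambda0 - 1)), 0.01)
  expect_lt(max(abs(cal$params$onset$obese / true$onset$obese - 1)), 0.01)
  expect_lte(cal$loss, cal$start_loss)

  # more free parameters than targets: warns, does not error
  expect_warning(
    calibrate_model(init, true, targets[1, ],
                    free = list(lambda0 = c(0.5, 2), onset.obese = c(0.5, 2))),
    "unidentifiable")
})

test_that("conflicting equal-weight targets settle between the two values", {
  init <- make_state(0, 1e4)
  start <- model_params(lambda0 = 0.02)
  targets <- rbind(prevalence_target(8, "diabetes", 0.1),
                   prevalence_target(8, "diabetes", 0.3))
  cal <- calibrate_model(init, start, targets, free = list(lambda0 = c(0.01, 50)))
  fitted_prev <- prevalence(state_at(simulate_model(init, cal$params, 8, 0.1), 8),
                            "diabetes")
  expect_gt(fitted_prev, 0.1)
  expect_lt(fitted_prev, 0.3)
  expect_equal(fitted_prev, 0.2, tolerance = 0.05) # least-squares midpoint
})

test_that("states and configs round-trip through their file formats", {
  st <- make_state(2020, 1234.5, p_obese = 0.3, p_diabetic = 0.2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_state_csv(st, f)
  st2 <- read_state_csv(f)
  expect_equal(st2$counts, st$counts, tolerance = 1e-12)
  expect_equal(st2$time, st$time)

  cfg <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "params:",
    "  entry_rate: {female: 100, male: 110}",
    "  mortality: 0.01",
    "  lambda0: 0.005",
    "  onset: {obese: 0.03, smoker: 0.01, inactive: 0.05}",
    "  reversal: {obese: 0.01, smoker: 0.02, inactive: 0.01}",
    "  rr: {obese: 3.0, smoker: 1.3, inactive: 1.6}",
    "initial:",
    "  time: 2012",
    "  total: 50000",
    "  p_obese: 0.4",
    "  p_diabetic: 0.1"), cfg)
  conf <- read_model_config(cfg)
  expect_s3_class(conf$params, "model_params")
  expect_equal(conf$params$rr[["obese"]], 3.0)
  expect_equal(conf$params$entry_rate[["male"]], 110)
  expect_equal(total_population(conf$initial), 50000)
  expect_equal(prevalence(conf$initial, "obesity"), 0.4)
})
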