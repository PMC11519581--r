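test_that("simulate_ode honours absorbing states and the identity at t0", {
  # prey birth rate 0 and no prey: prey stays extinct
  traj <- simulate_ode(lv_fix, c(a = 0), seq(1, 10), y0 = c(prey = 0,
                                                            predator = 2))
  expect_equal(unname(traj$states[, "prey"]), rep(0, 10))

  # requesting only the initial time returns y0 exactly
  y0 <- c(A = 40, B = 10, C = 1)
  tr0 <- simulate_ode(rep_fix, times = 0, y0 = y0)
  expect_equal(unname(tr0$states[1, ]), unname(y0))
})

test_that("the repressilator fixture oscillates over 72 h", {
  traj <- simulate_ode(rep_fix, times = seq(1, 72))
  for (v in c("A", "B", "C")) {
    x <- traj$states[, v]
    peaks <- which(diff(sign(diff(x))) == -2)
    expect_gt(length(peaks), 0)
    expect_gt(diff(range(x)), 10) # far from a constant trajectory
  }
})

test_that("fixture structure matches the declared models", {
  expect_length(lv_fix$state_names, 2)
  expect_length(lv_fix$parameter_names, 4)
  expect_length(rep_fix$state_names, 3)
  expect_length(rep_fix$parameter_names, 6)
  expect_length(vir_fix$state_names, 6)
  expect_length(vir_fix$parameter_names, 11)
  expect_length(vir_fix$free_parameters, 7)
})

test_that("viral fixture saturates rather than blowing up or dying out", {
  traj <- simulate_ode(vir_fix, times = seq(4, 48, 4))
  v <- traj$states[, "V"]
  expect_true(all(diff(v) > 0))          # titre accumulates
  late_growth <- (v[12] - v[11]) / v[12]
  expect_lt(late_growth, 0.05)           # and has plateaued by 48 h
})

test_that("integration converges and is consistent under sub-selection", {
  times <- seq(1, 40, 1)
  a <- simulate_ode(lv_fix, times = times, rtol = 1e-8)
  b <- simulate_ode(lv_fix, times = times, rtol = 5e-9)
  expect_lt(max(abs(a$states - b$states)), 1e-5)

  sub <- times[c(5, 17, 33)]
  direct <- simulate_ode(lv_fix, times = sub)
  expect_lt(max(abs(direct$states - a$states[c(5, 17, 33), ])), 1e-5)
})

test_that("simulate_ode signals integration failure explicitly", {
  # exponential blow-up: prey grows unboundedly with no predation
  expect_error(
    simulate_ode(lv_fix, c(a = 5, b = 0, c = 0, delta = 0),
                 times = c(10, 50)),
    "failed|blow-up")
})

test_that("invalid simulation requests are rejected", {
  expect_error(simulate_ode(lv_fix, times = c(2, 1)), "increasing")
  expect_error(simulate_ode(lv_fix, times = 1, y0 = c(-1, 1)),
               "non-negative")
  expect_error(simulate_ode(lv_fix, theta = c(bogus = 1), times = 1),
               "unknown parameter")
})

test_that("generate_dataset emulates designs record-for-record", {
  des <- new_design(enumerate_candidates(seq(12, 72, 12), c("B", "C")))
  data <- generate_dataset(rep_fix, design = des)
  # 6 simultaneous B,C measurements -> 12 records
  expect_equal(nrow(data), 12)
  expect_true(all(data$sd > 0))
  expect_false(anyDuplicated(data[, c("time", "variable")]) > 0)

  # zero-noise values are bit-identical to the simulation
  traj <- simulate_ode(rep_fix, times = sort(unique(data$time)))
  for (i in seq_len(nrow(data)))
    expect_identical(data$value[i],
                     unname(traj$states[match(data$time[i], traj$times),
                                        data$variable[i]]))

  # seeded gaussian noise is reproducible
  g1 <- generate_dataset(rep_fix, design = des,
                         noise = noise_spec("gaussian"), seed = 9L)
  g2 <- generate_dataset(rep_fix, design = des,
                         noise = noise_spec("gaussian"), seed = 9L)
  expect_identical(g1$value, g2$value)
  expect_false(identical(g1$value, data$value))

  expect_error(
    generate_dataset(rep_fix,
                     design = new_design(list(measurement_candidate(1, "Z", 3)))),
    "Z")
})

test_that("datasets round-trip through CSV", {
  des <- new_design(enumerate_candidates(c(6, 18), c("B", "C")))
  data <- generate_dataset(rep_fix, design = des)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(data, path)
  back <- read_dataset(path)
  expect_equal(back$value, data$value, tolerance = 1e-12)
  expect_equal(back$variable, data$variable)
})

test_that("SBML import reproduces the compiled LV fixture", {
  path <- system.file("extdata", "lotka_volterra_synthetic.sbml.xml",
                      package = "parsec")
  sb <- read_sbml_model(path)
  expect_setequal(sb$state_names, c("prey", "predator"))
  expect_setequal(sb$parameter_names, c("a", "b", "c", "delta"))
  times <- seq(2, 20, 2)
  ref <- simulate_ode(lv_fix, times = times)
  got <- simulate_ode(sb, sb$default_parameters, times,
                      y0 = sb$default_initial_state)
  expect_lt(max(abs(got$states[, colnames(ref$states)] - ref$states)), 1e-5)
})
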