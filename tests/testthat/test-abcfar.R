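test_that("chi_squared reproduces the weighted sum of squares", {
  pred <- manual_trajectory(c(1, 2), matrix(c(1, 2), 2, 1,
                                            dimnames = list(NULL, "y")))
  data <- manual_dataset(c(1, 2), "y", c(2, 4), c(1, 2))
  # (2-1)^2/1 + (4-2)^2/4 = 2
  expect_equal(chi_squared(data, pred), 2.0)

  exact <- manual_dataset(c(1, 2), "y", c(1, 2), c(1, 1))
  expect_identical(chi_squared(exact, pred), 0)

  bad_sd <- manual_dataset(1, "y", 1, 0)
  expect_error(chi_squared(bad_sd, pred), "positive")
  missing_pt <- manual_dataset(3, "y", 1, 1)
  expect_error(chi_squared(missing_pt, pred), "missing")
})

test_that("select_far keeps the round(FAR x N) lowest-chi2 combos", {
  combos <- matrix(seq_len(16), 8, 2)
  batch <- structure(list(combos = combos,
                          chi2 = c(5, 1, 3, 2, 9, 4, 7, 6), iteration = 1),
                     class = "sample_batch")
  sel <- select_far(batch, 0.25)
  expect_equal(sort(sel$chi2), c(1, 2))

  # FAR = 1 keeps everything
  expect_equal(length(select_far(batch, 1)$chi2), 8)
  # 60000 x 0.01 -> 600 (paper-scale arithmetic)
  expect_equal(parsec:::round_half_up(0.01 * 60000), 600)
  # floor of one and round-half-up behaviour
  expect_equal(parsec:::round_half_up(0.4), 1)
  expect_equal(parsec:::round_half_up(2.5), 3)

  # carried combos enter the pooled global ranking
  carried <- list(combos = matrix(0, 2, 2), chi2 = c(0.5, 10))
  sel2 <- select_far(batch, 0.25, carried)
  expect_equal(sort(sel2$chi2), c(0.5, 1))
  expect_error(select_far(batch, 0), "\\(0, 1\\]")
})

test_that("ABC-FAR solves a quadratic chi-squared toy to the analytic mode", {
  # y(t) = theta1 * t and one observation y(1) = 2: chi2 is an exact
  # quadratic in theta1 minimised at theta1 = 2
  data <- manual_dataset(1, "y", 2, 0.1)
  sp <- parameter_space(c("t1", "t2"), c(-1, -1), c(1, 1),
                        dummy = c(FALSE, TRUE))
  fit <- run_abc_far(linear_toy, data, sp, far = 0.05, n = 400,
                     iterations = 4, seed = 2)
  bin_w <- 2 / 100
  expect_lt(abs(marginal_mode(fit$marginals$t1) - log10(2)), 1.5 * bin_w)
})

test_that("HDUS keeps the minimum selected chi2 non-increasing", {
  for (s in c(1, 8, 33, 71, 204)) {
    fit <- run_abc_far(lv_fix, lv_data(), far = 0.2, n = 300, iterations = 4,
                       seed = s)
    mins <- vapply(fit$history, `[[`, numeric(1), "min_chi2")
    expect_true(all(diff(mins) <= 1e-12))
    expect_equal(unique(vapply(fit$history, `[[`, numeric(1), "n_selected")),
                 60)
  }
})

test_that("marginals stay normalised through a full fit", {
  fit <- run_abc_far(lv_fix, lv_data(), far = 0.1, n = 300, iterations = 3,
                     seed = 4)
  for (m in fit$marginals) {
    expect_equal(sum(m$mass), 1, tolerance = 1e-12)
    expect_true(all(m$mass >= 0))
  }
  expect_equal(fit$n_simulations, 900)
})

test_that("empty data and degenerate inputs error cleanly", {
  empty <- manual_dataset(numeric(), character(), numeric(), numeric())
  expect_error(run_abc_far(lv_fix, empty, n = 10), "no records")
})

test_that("pair_diagnostics returns self-correlation 1 and flags zero variance", {
  fit <- run_abc_far(lv_fix, lv_data(), far = 0.2, n = 300, iterations = 3,
                     seed = 6)
  self <- pair_diagnostics(fit, "a", "a")
  expect_equal(self$correlation, 1, tolerance = 1e-12)
  expect_equal(self$slope, 1, tolerance = 1e-12)

  fit0 <- fit
  fit0$selected$combos[, "b"] <- 0.3
  expect_error(pair_diagnostics(fit0, "a", "b"), "zero variance")

  # prcc variant runs and stays in [-1, 1]
  pr <- pair_diagnostics(fit, "a", "b", method = "prcc")
  expect_true(abs(pr$correlation) <= 1)
})

test_that("failed simulations score +Inf and are never selected", {
  # huge prey growth rates blow up the integration for part of the prior
  sp <- parameter_space(c("a", "b", "c", "delta"),
                        lower = c(-1, -1, -1, -1), upper = c(3, 0, 0, 0))
  des <- new_design(enumerate_candidates(c(5, 10), c("prey", "predator")))
  data <- generate_dataset(lv_fix, design = des)
  fit <- run_abc_far(lv_fix, data, sp, far = 0.1, n = 200, iterations = 2,
                     seed = 3)
  expect_gt(fit$n_failed, 0)
  expect_true(all(is.finite(fit$selected$chi2)))
})

test_that("fit artifacts serialise to JSON + CSV", {
  fit <- run_abc_far(lv_fix, lv_data(), far = 0.2, n = 200, iterations = 2,
                     seed = 5)
  dir <- withr::local_tempdir()
  write_fit(fit, dir)
  expect_true(all(file.exists(file.path(dir, c("fit.json", "selected.csv",
                                               "marginals.csv")))))
  js <- jsonlite::read_json(file.path(dir, "fit.json"))
  expect_equal(js$settings$far, 0.2)
  sel <- utils::read.csv(file.path(dir, "selected.csv"), check.names = FALSE)
  expect_equal(nrow(sel), length(fit$selected$chi2))
})
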