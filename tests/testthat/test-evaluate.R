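# independent brute-force double loop for the estimation error
brute_error <- function(truth_log10, combos) {
  tot <- 0
  for (j in seq_along(truth_log10))
    for (m in seq_len(nrow(combos)))
      tot <- tot + unname((truth_log10[j] - combos[m, j])^2)
  sqrt(tot)
}

fake_fit <- function(combos, space) {
  structure(list(space = space,
                 selected = list(combos = combos,
                                 chi2 = rep(0, nrow(combos)))),
            class = "abcfar_fit")
}

test_that("estimation_error matches direct arithmetic and the brute oracle", {
  sp <- parameter_space(c("p1", "p2", "dummy"), rep(-1, 3), rep(1, 3))
  truth <- c(p1 = 0.5, p2 = -0.2, dummy = 0)

  # exact recovery -> 0
  sel <- rbind(c(0.5, -0.2, 0.9), c(0.5, -0.2, -0.4))
  colnames(sel) <- sp$name
  expect_equal(estimation_error(truth, fake_fit(sel, sp),
                                log10_input = TRUE), 0)

  # r = 2, M = 2, deviations (0.1, 0.2) and (0.2, 0.1)
  sel2 <- rbind(c(0.6, 0, 0), c(0.7, -0.1, 0))
  colnames(sel2) <- sp$name
  expect_equal(estimation_error(truth, fake_fit(sel2, sp),
                                log10_input = TRUE),
               sqrt(0.01 + 0.04 + 0.04 + 0.01))

  # r = 1, M = 1, single deviation of 0.3
  sp1 <- parameter_space("p1", -1, 1)
  sel3 <- matrix(0.8, 1, 1, dimnames = list(NULL, "p1"))
  expect_equal(estimation_error(c(p1 = 0.5), fake_fit(sel3, sp1),
                                log10_input = TRUE), 0.3)

  # random-input agreement with the brute-force double loop to 1e-12
  set.seed(42)
  for (i in 1:20) {
    r <- sample(2:5, 1); M <- sample(1:6, 1)
    spr <- parameter_space(paste0("q", 1:r), rep(-2, r), rep(2, r))
    truth_r <- stats::setNames(stats::runif(r, -1, 1), spr$name)
    combos <- matrix(stats::runif(r * M, -1, 1), M, r,
                     dimnames = list(NULL, spr$name))
    expect_equal(estimation_error(truth_r, fake_fit(combos, spr),
                                  log10_input = TRUE),
                 brute_error(truth_r, combos), tolerance = 1e-12)
  }

  expect_error(estimation_error(c(zzz = 1), fake_fit(sel, sp)), "missing")
})

test_that("accuracy_ratio is scale-invariant with guarded degenerate cases", {
  expect_equal(accuracy_ratio(c(2, 4), c(1, 5)), 1)
  r <- accuracy_ratio(c(3, 5, 7), c(1, 2, 3))
  expect_equal(accuracy_ratio(c(3, 5, 7) * 13, c(1, 2, 3) * 13), r,
               tolerance = 1e-12)
  expect_warning(expect_equal(accuracy_ratio(c(1), c(0)), Inf), "perfect")
  expect_error(accuracy_ratio(numeric(), 1), "non-empty")
})

test_that("timepoint_entropy hits its analytic anchors and bounds", {
  # all points in one bin
  d0 <- new_design(list(measurement_candidate(1, "B", 3),
                        measurement_candidate(2, "B", 4)))
  expect_equal(timepoint_entropy(list(d0), 72), 0)

  # exactly uniform occupancy over 12 bins -> log2(12)
  du <- new_design(lapply(1:12, function(i)
    measurement_candidate(i, "B", 6 * i - 3)))
  expect_equal(timepoint_entropy(list(du), 72), log2(12), tolerance = 1e-12)

  # bounds on arbitrary ensembles
  ens <- design_ensemble(rep_psi(), rep_cands, 10, 6, "random", seed = 2)
  h <- timepoint_entropy(ens, 72)
  expect_gte(h, 0)
  expect_lte(h, log2(12))
  expect_error(timepoint_entropy(list(du), 50), "outside")
})

test_that("fuzzy_burden_ratio counts distinct candidate sets", {
  d1 <- make_random_design(rep_cands, 6, seed = 1)
  d2 <- make_random_design(rep_cands, 6, seed = 2)
  # identical repeated design on both sides -> 1
  expect_equal(fuzzy_burden_ratio(list(d1, d1), list(d1, d1, d1)), 1)
  # distinct c-subset of the k-designs -> ratio <= 1
  expect_equal(fuzzy_burden_ratio(list(d1), list(d1, d2)), 0.5)
  expect_error(fuzzy_burden_ratio(list(), list(d1)), "non-empty")
})

test_that("subsample_error_curve is exact at full size and unbiased at 1", {
  errs <- c(1, 2, 3, 4, 5, 6)
  curve <- subsample_error_curve(errs, c(1, 3, 6), n_subsamples = 400,
                                 seed = 3)
  expect_equal(curve$mean_error[curve$size == 6], mean(errs))
  expect_equal(curve$sd_error[curve$size == 6], 0)
  expect_equal(curve$mean_error[curve$size == 1], mean(errs),
               tolerance = 0.15)
})

test_that("evaluate_design is deterministic under a fixed seed", {
  d <- make_random_design(rep_cands, 4, seed = 8)
  ev1 <- evaluate_design(d, rep_fix, n = 150, iterations = 2, far = 0.1,
                         seed = 12)
  ev2 <- evaluate_design(d, rep_fix, n = 150, iterations = 2, far = 0.1,
                         seed = 12)
  expect_identical(ev1$errors, ev2$errors)
  expect_equal(ev1$mean_error, mean(ev1$errors))
  expect_true(all(ev1$errors >= 0))
})
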