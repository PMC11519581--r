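# small synthetic vector set with two well-separated clouds
make_clouds <- function(n_per = 4, gap = 10, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n_per * 3, 0, 0.1), n_per),
             matrix(stats::rnorm(n_per * 3, gap, 0.1), n_per))
  x
}

# brute-force best 2-partition under the intra-cluster distance objective
best_two_partition <- function(x) {
  n <- nrow(x)
  best <- Inf; best_assign <- NULL
  for (mask in 1:(2^(n - 1) - 1)) {
    assign <- as.integer(intToBits(mask))[1:n] + 1L
    if (length(unique(assign)) < 2) next
    cen <- rbind(colMeans(x[assign == 1, , drop = FALSE]),
                 colMeans(x[assign == 2, , drop = FALSE]))
    obj <- parsec:::intra_cluster_objective(x, assign, cen)
    if (obj < best) { best <- obj; best_assign <- assign }
  }
  list(objective = best, assignments = best_assign)
}

test_that("k-means recovers well-separated clouds for every seed", {
  x <- make_clouds()
  oracle <- best_two_partition(x)
  for (s in 1:8) {
    cm <- psi_cluster(x, 2, "kmeans", seed = s)
    # same partition as the exhaustive oracle (up to label swap)
    expect_equal(length(unique(paste(cm$assignments,
                                     oracle$assignments))), 2)
    expect_equal(cm$objective, oracle$objective, tolerance = 1e-8)
  }
})

test_that("cluster model invariants hold for both methods", {
  psi <- rep_psi()
  km <- psi_cluster(psi, 6, "kmeans", seed = 2)
  expect_equal(sort(unique(km$assignments)), 1:6)
  expect_equal(km$objective,
               parsec:::intra_cluster_objective(psi, km$assignments,
                                                km$centroids),
               tolerance = 1e-12)

  fc <- psi_cluster(psi, 6, "cmeans", seed = 2)
  expect_equal(rowSums(fc$membership), rep(1, 24), tolerance = 1e-9)
  expect_true(all(fc$membership >= 0))

  # saturation: every distinct vector its own cluster -> objective 0
  x <- make_clouds()
  cm <- psi_cluster(x, nrow(x), "kmeans", seed = 1)
  expect_equal(cm$objective, 0, tolerance = 1e-10)
  expect_error(psi_cluster(x, nrow(x) + 1, "kmeans"), "exceeds")
})

test_that("PARSEC(k) designs take exactly one candidate per cluster", {
  psi <- rep_psi()
  cm <- psi_cluster(psi, 6, "kmeans", seed = 3)
  d <- make_parsec_k_design(cm, rep_cands, seed = 10)
  expect_length(d$candidates, 6)
  picked <- vapply(d$candidates, function(cc) cc$id, integer(1))
  expect_equal(sort(unique(cm$assignments[picked])), 1:6)

  # singleton clusters force a deterministic design
  xs <- make_clouds(1, gap = 5)
  cms <- psi_cluster(xs, 2, "kmeans", seed = 1)
  ds <- make_parsec_k_design(cms, rep_cands[1:2], seed = 99)
  expect_setequal(vapply(ds$candidates, `[[`, integer(1), "id"), 1:2)
})

test_that("PARSEC(c) selection is deterministic and resolves conflicts", {
  psi <- rep_psi()
  cm <- psi_cluster(psi, 6, "cmeans", seed = 4)
  d1 <- make_parsec_c_design(cm, rep_cands)
  d2 <- make_parsec_c_design(cm, rep_cands)
  expect_identical(parsec:::design_key(d1), parsec:::design_key(d2))
  expect_length(d1$candidates, 6)
  expect_false(anyDuplicated(vapply(d1$candidates, `[[`, integer(1),
                                    "id")) > 0)

  # crisp memberships reduce to picking each cluster's single top member
  u <- diag(3)[c(1, 1, 2, 3), ]
  fake <- structure(list(method = "cmeans", n_clusters = 3,
                         membership = u, assignments = max.col(u),
                         centroids = NULL, objective = 0, seed = 1),
                    class = "cluster_model")
  dc <- make_parsec_c_design(fake, rep_cands[1:4])
  expect_setequal(vapply(dc$candidates, `[[`, integer(1), "id"),
                  c(1, 3, 4))
})

test_that("random and anti-PARSEC designs respect their contracts", {
  d <- make_random_design(rep_cands, 6, seed = 1)
  times <- parsec:::design_times(d)
  expect_length(unique(vapply(d$candidates, `[[`, integer(1), "id")), 6)
  expect_true(all(unique(times) %% 3 == 0 & times >= 3 & times <= 72))
  expect_length(make_random_design(rep_cands, 24, seed = 1)$candidates, 24)
  expect_error(make_random_design(rep_cands, 25, seed = 1), "exceeds")

  psi <- rep_psi()
  cm <- psi_cluster(psi, 6, "kmeans", seed = 2)
  sizes <- table(cm$assignments)
  nmax <- max(sizes)
  wd <- make_anti_parsec_design(cm, rep_cands, nmax, seed = 3)
  lab <- as.integer(names(sizes)[which.max(sizes)])
  expect_setequal(vapply(wd$candidates, `[[`, integer(1), "id"),
                  which(cm$assignments == lab))
  expect_error(make_anti_parsec_design(cm, rep_cands, nmax + 1),
               "smaller")

  # single cluster: anti-PARSEC degenerates to a uniform random subset
  one <- psi_cluster(psi, 1, "kmeans", seed = 1)
  d1 <- make_anti_parsec_design(one, rep_cands, 6, seed = 5)
  expect_length(d1$candidates, 6)
})

test_that("intra-cluster profile is non-increasing with a located elbow", {
  psi <- rep_psi()
  prof <- intra_cluster_profile(psi, 2:12, "kmeans", restarts = 10, seed = 1)
  expect_true(all(diff(prof$objective) <= 1e-8))
  expect_true(prof$elbow %in% 2:12)
  full <- intra_cluster_profile(psi, nrow(psi), "kmeans", seed = 1)
  expect_equal(full$objective, 0, tolerance = 1e-10)
})

test_that("PARSEC(c) distinct designs form a subset of PARSEC(k)'s reach", {
  # on crisply separated synthetic clouds both algorithms agree on the
  # partition, so every c-design must satisfy one-per-cluster for k-means
  x <- make_clouds(4, gap = 10)[rep(1:8, each = 2), ] +
    matrix(stats::rnorm(48, 0, 0.01), 16)
  cands <- enumerate_candidates(seq_len(16), "B")
  cd <- design_ensemble(x, cands, 20, 2, "parsec_c", seed = 6)
  km <- psi_cluster(x, 2, "kmeans", seed = 1)
  for (d in cd) {
    ids <- vapply(d$candidates, `[[`, integer(1), "id")
    expect_equal(sort(unique(km$assignments[ids])), 1:2)
  }
})

test_that("design ensembles are reproducible and honour provenance labels", {
  psi <- rep_psi()
  e1 <- design_ensemble(psi, rep_cands, 5, 6, "parsec_k", seed = 9,
                        label = "PD_BC")
  e2 <- design_ensemble(psi, rep_cands, 5, 6, "parsec_k", seed = 9,
                        label = "PD_BC")
  expect_identical(lapply(e1, parsec:::design_key),
                   lapply(e2, parsec:::design_key))
  expect_equal(unique(vapply(e1, `[[`, character(1), "provenance")), "PD_BC")
})
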