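#' Cluster PARSEC-PSI vectors
#'
#' Partitions measurement candidates by the Euclidean distance between
#' their PARSEC-PSI vectors, minimising total intra-cluster distance.
#' `"kmeans"` uses Lloyd-style k-means (`stats::kmeans`, best of
#' `restarts` seeded starts); `"cmeans"` is fuzzy c-means with fuzzifier
#' `fuzzifier` and convergence tolerance `tol`, returning a full membership
#' matrix. Duplicate vectors are clustered as-is. The reported `objective`
#' is the recomputed sum of Euclidean distances of each vector to its
#' (hard-)assigned centroid.
#'
#' @param vectors numeric matrix, one PARSEC-PSI vector per row.
#' @param n_clusters number of clusters (`<= nrow(vectors)`).
#' @param method `"kmeans"` or `"cmeans"`.
#' @param seed integer seed; clustering is deterministic given it.
#' @param restarts random restarts within this call (k-means).
#' @param fuzzifier fuzzy exponent `m` (c-means, default 2).
#' @param tol centroid-change convergence tolerance (c-means).
#' @return a `cluster_model`: method, `n_clusters`, hard `assignments`,
#'   `membership` (c-means only), `centroids`, `objective`, `seed`.
#' @export
psi_cluster <- function(vectors, n_clusters, method = c("kmeans", "cmeans"),
                        seed = 1L, restarts = 10, fuzzifier = 2,
                        tol = 1e-6) {
  method <- match.arg(method)
  stopifnot(is.matrix(vectors))
  n <- nrow(vectors)
  if (n_clusters > n)
    stop("n_clusters exceeds the number of candidates")
  n_distinct <- nrow(unique(vectors))
  if (method == "kmeans") {
    k_eff <- min(n_clusters, n_distinct)
    if (k_eff == n_distinct) {
      # saturated: every distinct vector is its own centroid (exact optimum;
      # stats::kmeans rejects centers == points)
      ux <- unique(vectors)
      assignments <- match(data.frame(t(vectors)), data.frame(t(ux)))
      centroids <- ux
      obj <- intra_cluster_objective(vectors, assignments, centroids)
      return(structure(list(method = method, n_clusters = n_clusters,
                            assignments = assignments, membership = NULL,
                            centroids = centroids, objective = obj,
                            seed = seed), class = "cluster_model"))
    }
    # rare empty-cluster outcomes are retried with a fresh derived seed
    km <- NULL
    for (try in 0:5) {
      km <- local_seed(derive_seed(seed, try * 7919L),
                       suppressWarnings(
                         stats::kmeans(vectors, centers = k_eff,
                                       nstart = restarts, iter.max = 100)))
      if (length(unique(km$cluster)) == k_eff) break
    }
    assignments <- km$cluster
    centroids <- km$centers
    if (k_eff < n_clusters) {
      # degenerate: fewer distinct vectors than clusters; pad with empties
      centroids <- rbind(centroids,
                         matrix(NA_real_, n_clusters - k_eff, ncol(vectors)))
    }
    membership <- NULL
  } else {
    fc <- local_seed(seed, fuzzy_cmeans(vectors, n_clusters, fuzzifier, tol))
    assignments <- fc$assignments
    centroids <- fc$centroids
    membership <- fc$membership
  }
  obj <- intra_cluster_objective(vectors, assignments, centroids)
  structure(list(method = method, n_clusters = n_clusters,
                 assignments = assignments, membership = membership,
                 centroids = centroids, objective = obj, seed = seed),
            class = "cluster_model")
}

# sum of Euclidean distances of each vector to its assigned centroid
intra_cluster_objective <- function(vectors, assignments, centroids) {
  d <- vectors - centroids[assignments, , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

# standard fuzzy c-means (Bezdek) on Euclidean distance
fuzzy_cmeans <- function(x, k, m = 2, tol = 1e-6, max_iter = 300) {
  n <- nrow(x)
  # seed centroids from distinct data points where possible
  ux <- unique(x)
  init <- ux[sample.int(nrow(ux), min(k, nrow(ux))), , drop = FALSE]
  if (nrow(init) < k)
    init <- rbind(init, init[sample.int(nrow(init), k - nrow(init),
                                        replace = TRUE), , drop = FALSE] +
                    stats::rnorm((k - nrow(init)) * ncol(x), 0, 1e-6))
  cen <- init
  expo <- 2 / (m - 1)
  for (iter in seq_len(max_iter)) {
    d2 <- outer(rowSums(x^2), rep(1, k)) - 2 * x %*% t(cen) +
      outer(rep(1, n), rowSums(cen^2))
    d2 <- pmax(d2, 0)
    d <- sqrt(d2)
    u <- matrix(0, n, k)
    zero <- d < 1e-12
    anyzero <- rowSums(zero) > 0
    if (any(anyzero))
      u[anyzero, ] <- zero[anyzero, , drop = FALSE] /
        rowSums(zero[anyzero, , drop = FALSE])
    if (any(!anyzero)) {
      dd <- d[!anyzero, , drop = FALSE]
      u[!anyzero, ] <- 1 / t(apply(dd, 1, function(r)
        colSums(outer(r, r, function(a, b) (b / a)^expo))))
    }
    um <- u^m
    cen_new <- t(um) %*% x / colSums(um)
    shift <- max(abs(cen_new - cen))
    cen <- cen_new
    if (shift < tol) break
  }
  list(membership = u, centroids = cen,
       assignments = max.col(u, ties.method = "first"))
}

#' PARSEC(k) design: one random candidate per k-means cluster
#'
#' @param cm a `cluster_model` with `method = "kmeans"`.
#' @param candidates the candidate list the clustering was computed on.
#' @param seed integer seed for the within-cluster picks.
#' @return a `parsec_design` of size `n_clusters` (provenance `"PD"`).
#' @export
make_parsec_k_design <- function(cm, candidates, seed = 1L) {
  stopifnot(inherits(cm, "cluster_model"), cm$method == "kmeans")
  labels <- sort(unique(cm$assignments))
  picks <- local_seed(seed, vapply(labels, function(cl) {
    members <- which(cm$assignments == cl)
    members[sample.int(length(members), 1)]
  }, integer(1)))
  new_design(candidates[picks], provenance = "PD", seed = seed)
}

#' PARSEC(c) design: highest-membership candidate per c-means cluster
#'
#' Deterministic given the cluster model: each cluster contributes the
#' candidate with the greatest membership in its column. When one candidate
#' tops several clusters it is kept for the cluster where its membership is
#' larger and the runner-up takes the other; remaining ties break toward
#' the lowest candidate index.
#'
#' @param cm a `cluster_model` with `method = "cmeans"`.
#' @param candidates the candidate list the clustering was computed on.
#' @return a `parsec_design` of size `n_clusters` (provenance `"PDc"`).
#' @export
make_parsec_c_design <- function(cm, candidates) {
  stopifnot(inherits(cm, "cluster_model"), cm$method == "cmeans")
  u <- cm$membership
  k <- ncol(u)
  picks <- rep(NA_integer_, k)
  taken <- logical(nrow(u))
  # clusters claim candidates in order of decreasing top membership, so a
  # candidate topping two clusters stays with the stronger claim
  repeat {
    open <- which(is.na(picks))
    if (!length(open)) break
    best_val <- -Inf; best_cl <- NA; best_cand <- NA
    for (cl in open) {
      col <- u[, cl]
      col[taken] <- -Inf
      i <- which.max(col) # which.max takes the lowest index on ties
      if (col[i] > best_val) {
        best_val <- col[i]; best_cl <- cl; best_cand <- i
      }
    }
    picks[best_cl] <- best_cand
    taken[best_cand] <- TRUE
  }
  new_design(candidates[picks], provenance = "PDc", seed = cm$seed)
}

#' Random design: distinct candidates drawn uniformly
#'
#' @param candidates candidate list.
#' @param n design size (`<= length(candidates)`).
#' @param seed integer seed.
#' @return a `parsec_design` (provenance `"RD"`).
#' @export
make_random_design <- function(candidates, n, seed = 1L) {
  if (n > length(candidates))
    stop("design size exceeds the number of candidates")
  picks <- local_seed(seed, sample.int(length(candidates), n))
  new_design(candidates[picks], provenance = "RD", seed = seed)
}

#' Anti-PARSEC design: all candidates from the most populous cluster
#'
#' The negative control for cluster-spanning designs: `n` distinct
#' candidates drawn uniformly from the single largest cluster (ties in
#' cluster size break toward the lowest cluster index).
#'
#' @param cm a `cluster_model`.
#' @param candidates the candidate list the clustering was computed on.
#' @param n design size; must not exceed the largest cluster.
#' @param seed integer seed.
#' @return a `parsec_design` (provenance `"WD"`).
#' @export
make_anti_parsec_design <- function(cm, candidates, n, seed = 1L) {
  stopifnot(inherits(cm, "cluster_model"))
  sizes <- table(cm$assignments)
  big <- as.integer(names(sizes)[which.max(sizes)])
  members <- which(cm$assignments == big)
  if (length(members) < n)
    stop("largest cluster is smaller than the requested design size")
  picks <- local_seed(seed, members[sample.int(length(members), n)])
  new_design(candidates[picks], provenance = "WD", seed = seed)
}

#' Intra-cluster distance profile over cluster counts
#'
#' Best-of-restarts clustering objective for each `k`, with an
#' elbow/inflection locator (maximum discrete second difference) that
#' suggests the experiment sample size. The suggestion is reported
#' alongside the raw profile, never silently applied.
#'
#' @param vectors PARSEC-PSI matrix.
#' @param k_range integer vector of cluster counts.
#' @param method `"kmeans"` or `"cmeans"`.
#' @param restarts restarts per clustering call.
#' @param seed integer seed.
#' @return list with `k`, `objective`, and `elbow` (suggested k, `NA` when
#'   `k_range` has fewer than 3 values).
#' @export
intra_cluster_profile <- function(vectors, k_range,
                                  method = c("kmeans", "cmeans"),
                                  restarts = 10, seed = 1L) {
  method <- match.arg(method)
  stopifnot(all(k_range >= 1), all(k_range <= nrow(vectors)))
  obj <- vapply(seq_along(k_range), function(i)
    psi_cluster(vectors, k_range[i], method,
                seed = derive_seed(seed, i), restarts = restarts)$objective,
    numeric(1))
  elbow <- NA_integer_
  if (length(k_range) >= 3) {
    d2 <- utils::head(obj, -2) - 2 * obj[c(-1, -length(obj))] +
      utils::tail(obj, -2)
    elbow <- k_range[which.max(d2) + 1]
  }
  list(k = k_range, objective = obj, elbow = elbow)
}

#' Generate a design ensemble
#'
#' Repeats clustering + selection with distinct top-level seeds, mirroring
#' the run-to-run variability the framework exploits: each realisation is a
#' fresh clustering (with its own internal restarts) followed by the
#' generator's selection rule.
#'
#' @param vectors PARSEC-PSI matrix.
#' @param candidates candidate list (row order matching `vectors`).
#' @param n_designs ensemble size.
#' @param n_clusters clusters / design size.
#' @param generator `"parsec_k"`, `"parsec_c"`, `"random"` or
#'   `"anti_parsec"`.
#' @param seed integer master seed.
#' @param restarts k-means restarts per realisation. The default of 1 keeps
#'   each realisation a single stochastic k-means run: the run-to-run
#'   clustering variability is the source of design diversity the ensemble
#'   statistics rest on, and averaging it away with multi-start clustering
#'   collapses the ensemble onto a handful of designs.
#' @param label provenance tag override (e.g. `"PD_BC"`).
#' @return list of `parsec_design`s.
#' @export
design_ensemble <- function(vectors, candidates, n_designs, n_clusters,
                            generator = c("parsec_k", "parsec_c", "random",
                                          "anti_parsec"),
                            seed = 1L, restarts = 1, label = NULL) {
  generator <- match.arg(generator)
  lapply(seq_len(n_designs), function(i) {
    s <- derive_seed(seed, i)
    d <- switch(generator,
      parsec_k = make_parsec_k_design(
        psi_cluster(vectors, n_clusters, "kmeans", seed = s,
                    restarts = restarts), candidates, seed = s),
      parsec_c = make_parsec_c_design(
        psi_cluster(vectors, n_clusters, "cmeans", seed = s), candidates),
      random = make_random_design(candidates, n_clusters, seed = s),
      anti_parsec = {
        # a clustering whose largest cluster is too small is infeasible for
        # this generator; redraw with a fresh seed up to a cap
        d <- NULL
        for (try in 0:19) {
          s2 <- derive_seed(s, try)
          d <- tryCatch(make_anti_parsec_design(
            psi_cluster(vectors, n_clusters, "kmeans", seed = s2,
                        restarts = restarts), candidates, n_clusters,
            seed = s2), error = function(e) NULL)
          if (!is.null(d)) break
        }
        if (is.null(d))
          stop("no clustering with a cluster of >= n members found")
        d
      })
    if (!is.null(label)) d$provenance <- label
    d
  })
}
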