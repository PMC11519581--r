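#' Chi-squared distance between a dataset and a model prediction
#'
#' `sum((R_D - R_P)^2 / sd_D^2)` over all data points, where `R_D` are the
#' recorded values, `R_P` the predicted values at the matching (time,
#' variable) pairs, and `sd_D` the per-record standard deviations. Zero iff
#' the prediction matches the data exactly.
#'
#' @param data a `parsec_dataset` (columns `time, variable, value, sd`).
#' @param prediction a `trajectory` from [simulate_ode()] covering every
#'   (time, variable) in `data`.
#' @return non-negative scalar.
#' @export
chi_squared <- function(data, prediction) {
  if (nrow(data) == 0) stop("dataset has no records")
  if (any(data$sd <= 0)) stop("all sd values must be positive")
  t_idx <- match(data$time, prediction$times)
  s_idx <- match(data$variable, colnames(prediction$states))
  if (anyNA(t_idx) || anyNA(s_idx))
    stop("prediction is missing a (time, variable) pair required by the data")
  pred <- prediction$states[cbind(t_idx, s_idx)]
  sum(((data$value - pred) / data$sd)^2)
}

# chi2 for a whole batch of log10 combos; failures map to +Inf
chi2_batch <- function(model, data, combos, space, y0) {
  free <- setdiff(space$name, space$name[space$dummy])
  idx <- match(free, model$parameter_names)
  if (anyNA(idx))
    stop("parameter space names not found in model: ",
         paste(free[is.na(idx)], collapse = ", "))
  n <- nrow(combos)
  thetas <- matrix(rep(model$default_parameters, each = n), nrow = n)
  thetas[, idx] <- 10^combos[, free, drop = FALSE]
  times <- sort(unique(data$time))
  sim <- simulate_ode_batch(model, thetas, times, y0 = y0)
  nt <- length(times)
  ns <- length(model$state_names)
  arrmat <- matrix(sim$states, nrow = n, ncol = nt * ns)
  col <- match(data$time, times) + nt * (match(data$variable,
                                               model$state_names) - 1)
  if (anyNA(col)) stop("data references unknown variable or time")
  pred <- arrmat[, col, drop = FALSE]
  resid <- sweep(pred, 2, data$value, "-")
  resid <- sweep(resid, 2, data$sd, "/")
  chi2 <- rowSums(resid^2)
  chi2[!sim$ok | !is.finite(chi2)] <- Inf
  chi2
}

# round-half-up with a floor of 1
round_half_up <- function(x) max(1L, as.integer(floor(x + 0.5)))

#' Fixed-acceptance-rate selection
#'
#' Ranks the sampled combinations (pooled with any carried-over combinations
#' under the history-dependent strategy) by chi-squared and keeps the
#' `round(far * N)` best, where `N` is the batch size. Ranking is global
#' over the pooled set; ties are broken by sample order (batch first, then
#' carried).
#'
#' @param batch a `sample_batch` with `chi2` filled.
#' @param far fraction in `(0, 1]`.
#' @param carried optional list with `combos` and `chi2` from the previous
#'   iteration's selection (no re-simulation).
#' @return list with `combos` (matrix) and `chi2` (vector), length
#'   `round(far * N)`.
#' @export
select_far <- function(batch, far, carried = NULL) {
  if (!is.numeric(far) || far <= 0 || far > 1)
    stop("far must lie in (0, 1]")
  if (anyNA(batch$chi2)) stop("chi2 must be filled for all combos")
  n <- nrow(batch$combos)
  combos <- batch$combos
  chi2 <- batch$chi2
  if (!is.null(carried)) {
    combos <- rbind(combos, carried$combos)
    chi2 <- c(chi2, carried$chi2)
  }
  m <- round_half_up(far * n)
  ord <- order(chi2)[seq_len(min(m, length(chi2)))]
  list(combos = combos[ord, , drop = FALSE], chi2 = chi2[ord])
}

#' ABC with a fixed acceptance rate (ABC-FAR)
#'
#' Iterative likelihood-free estimation of ODE parameters on a log10 scale.
#' Each iteration (1) mixes the current marginals with a prior-wide uniform
#' whose weight `0.25/(k+1)` decays over iterations, (2) draws `n`
#' parameter combinations by Latin hypercube sampling of the mixed
#' marginals, (3) evaluates the chi-squared statistic of each combination
#' against the data, and (4) keeps the `round(far * n)` best to update the
#' marginals. Under the history-dependent update strategy (HDUS) the
#' previous iteration's selection re-enters the ranking pool, which makes
#' the minimum selected chi-squared non-increasing; HIUS discards it.
#' Combinations whose simulation fails score `+Inf` and are logged, never
#' fatal (unless every combination fails).
#'
#' @param model an [ode_model()].
#' @param data a `parsec_dataset` with at least one record.
#' @param space a [parameter_space()] over the free parameters (log10
#'   bounds), optionally including a dummy parameter.
#' @param prior named list of marginals; defaults to uniform over `space`.
#' @param far fixed acceptance rate in `(0, 1]`.
#' @param n combinations sampled per iteration.
#' @param iterations number of refinement iterations.
#' @param strategy `"HDUS"` (history-dependent) or `"HIUS"`.
#' @param seed integer master seed; per-iteration seeds are derived from it.
#' @param y0 initial state for the simulations.
#' @param n_bins histogram bins for the updated marginals.
#' @return an `abcfar_fit`: per-iteration history (selected combos and
#'   chi-squared values), final marginals, final selection, settings and the
#'   total simulation count (the raw computational-cost measure).
#' @export
run_abc_far <- function(model, data, space = log_uniform_space(model),
                        prior = uniform_prior(space, n_bins), far = 0.01,
                        n = 60000, iterations = 5,
                        strategy = c("HDUS", "HIUS"), seed = 1L,
                        y0 = model$default_initial_state, n_bins = 100) {
  strategy <- match.arg(strategy)
  if (nrow(data) == 0) stop("dataset has no records: nothing to fit")
  if (any(data$sd <= 0)) stop("all sd values must be positive")
  p <- prior
  carried <- NULL
  history <- vector("list", iterations)
  n_sims <- 0L
  n_failed <- 0L
  for (k in seq_len(iterations)) {
    mixed <- lapply(p, mix_noisy_marginal, k = k)
    batch <- lhs_sample(mixed, n, seed = derive_seed(seed, k))
    batch$iteration <- k
    batch$chi2 <- chi2_batch(model, data, batch$combos, space, y0)
    n_sims <- n_sims + n
    n_failed <- n_failed + sum(!is.finite(batch$chi2))
    if (all(!is.finite(batch$chi2)) && is.null(carried))
      stop("every sampled combination failed to simulate")
    sel <- select_far(batch, far, if (strategy == "HDUS") carried)
    p <- update_marginals(sel$combos, space, n_bins)
    if (strategy == "HDUS") carried <- sel
    history[[k]] <- list(iteration = k, min_chi2 = min(sel$chi2),
                         mean_chi2 = mean(sel$chi2[is.finite(sel$chi2)]),
                         n_selected = length(sel$chi2),
                         n_failed = sum(!is.finite(batch$chi2)),
                         selected = sel)
  }
  structure(list(
    history = history, marginals = p, selected = sel, space = space,
    settings = list(far = far, n = n, iterations = iterations,
                    strategy = strategy, seed = seed, n_bins = n_bins),
    n_simulations = n_sims, n_failed = n_failed
  ), class = "abcfar_fit")
}

#' @export
print.abcfar_fit <- function(x, ...) {
  s <- x$settings
  cat(sprintf("<abcfar_fit> %d iterations, N=%d, FAR=%g, %s\n",
              s$iterations, s$n, s$far, s$strategy))
  cat(sprintf("  final min chi2: %.4g over %d selected combos (%d sims)\n",
              min(x$selected$chi2), length(x$selected$chi2),
              x$n_simulations))
  invisible(x)
}

#' Pairwise identifiability diagnostics on the final selection
#'
#' Correlation and least-squares slope of `log10(param_j)` on
#' `log10(param_i)` over the combinations selected in the last iteration. A
#' strong correlation flags practical non-identifiability; the slope is the
#' compensatory percent change in `j` per percent change in `i` that keeps
#' the fit quality constant. Compare against a dummy-parameter pair to
#' calibrate significance.
#'
#' @param fit an `abcfar_fit`.
#' @param param_i,param_j parameter names.
#' @param method `"pearson"` (default) or `"prcc"` (partial rank
#'   correlation, conditioning on all other parameters).
#' @return list with `correlation`, `slope`, `n` and the p-value of the
#'   correlation test.
#' @export
pair_diagnostics <- function(fit, param_i, param_j,
                             method = c("pearson", "prcc")) {
  method <- match.arg(method)
  combos <- fit$selected$combos
  if (nrow(combos) < 3) stop("need >= 3 selected combos for diagnostics")
  xi <- combos[, param_i]
  xj <- combos[, param_j]
  if (stats::sd(xi) == 0 || stats::sd(xj) == 0)
    stop("zero variance in a parameter: diagnostics undefined")
  slope <- stats::cov(xi, xj) / stats::var(xi)
  if (method == "pearson" || identical(param_i, param_j)) {
    ct <- stats::cor.test(xi, xj)
    r <- unname(ct$estimate)
    pval <- ct$p.value
  } else {
    others <- setdiff(colnames(combos), c(param_i, param_j))
    ri <- rank(xi); rj <- rank(xj)
    if (length(others)) {
      Z <- apply(combos[, others, drop = FALSE], 2, rank)
      ri <- stats::resid(stats::lm(ri ~ Z))
      rj <- stats::resid(stats::lm(rj ~ Z))
    }
    ct <- stats::cor.test(ri, rj)
    r <- unname(ct$estimate)
    pval <- ct$p.value
  }
  list(correlation = r, slope = slope, n = nrow(combos), p_value = pval)
}

#' Serialise a fit: JSON summary + CSV of selected combos and marginals
#'
#' @param fit an `abcfar_fit`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_fit <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summ <- list(
    settings = fit$settings, n_simulations = fit$n_simulations,
    n_failed = fit$n_failed,
    iterations = lapply(fit$history, function(h)
      h[c("iteration", "min_chi2", "mean_chi2", "n_selected", "n_failed")]))
  jsonlite::write_json(summ, file.path(dir, "fit.json"), auto_unbox = TRUE,
                       digits = NA)
  sel <- data.frame(fit$selected$combos, chi2 = fit$selected$chi2,
                    check.names = FALSE)
  utils::write.csv(sel, file.path(dir, "selected.csv"), row.names = FALSE)
  write_marginals(fit$marginals, file.path(dir, "marginals.csv"))
  invisible(dir)
}

# deterministic child-seed derivation (kept below 2^31)
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 1009 + as.double(k) * 99991) %% 2147483629 + 1)
}
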