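#' Estimation error of a fit against a known truth
#'
#' Root of the summed squared deviations between the true free-parameter
#' values and every combination selected in the fit's last iteration,
#' computed on the log10 scale the estimation runs on:
#' `sqrt(sum_j sum_m (theta_j - hat(theta)_j^m)^2)` over the `r` free
#' parameters and `M` selected combinations. The dummy parameter is
#' excluded.
#'
#' @param theta_truth named numeric vector of true values (natural scale) or
#'   log10 values when `log10_input = TRUE`.
#' @param fit an `abcfar_fit`.
#' @param log10_input set when `theta_truth` is already log10.
#' @return non-negative scalar.
#' @export
estimation_error <- function(theta_truth, fit, log10_input = FALSE) {
  free <- setdiff(fit$space$name, fit$space$name[fit$space$dummy])
  if (is.null(names(theta_truth)))
    stop("theta_truth must be named")
  if (!all(free %in% names(theta_truth)))
    stop("theta_truth is missing parameter(s): ",
         paste(setdiff(free, names(theta_truth)), collapse = ", "))
  truth <- theta_truth[free]
  if (!log10_input) truth <- log10(truth)
  combos <- fit$selected$combos[, free, drop = FALSE]
  if (nrow(combos) < 1) stop("fit has no selected combinations")
  dev <- sweep(combos, 2, truth, "-")
  sqrt(sum(dev^2))
}

#' Evaluate one design by ABC-FAR estimation error
#'
#' For each parameter set `Theta` in `theta_sets`: generate the dataset
#' `D(G, Theta)` the design would return, run ABC-FAR against it, and score
#' the estimation error at `Theta`. Errors are aggregated by arithmetic
#' mean. Fully deterministic given `seed`.
#'
#' @param design a `parsec_design`.
#' @param model an [ode_model()].
#' @param theta_sets matrix of parameter vectors (rows, natural scale, all
#'   model parameters) at which the design is scored; defaults to the
#'   ground truth.
#' @param space [parameter_space()] for the estimator (prior bounds).
#' @param noise a [noise_spec()].
#' @param far,n,iterations,strategy ABC-FAR settings (reduced-scale
#'   defaults: `n = 2000`, 4 iterations).
#' @param seed integer master seed.
#' @param y0 initial state.
#' @return an `evaluation_result`: per-set errors, their mean, and a
#'   settings snapshot.
#' @export
evaluate_design <- function(design, model,
                            theta_sets = matrix(model$default_parameters, 1,
                              dimnames = list(NULL, model$parameter_names)),
                            space = log_uniform_space(model),
                            noise = noise_spec(), far = 0.01, n = 2000,
                            iterations = 4, strategy = "HDUS", seed = 1L,
                            y0 = model$default_initial_state) {
  errors <- vapply(seq_len(nrow(theta_sets)), function(i) {
    th <- resolve_theta(model, theta_sets[i, ])
    names(th) <- model$parameter_names
    data <- generate_dataset(model, th, design, noise, y0 = y0,
                             seed = derive_seed(seed, 1000 + i))
    fit <- run_abc_far(model, data, space, far = far, n = n,
                       iterations = iterations, strategy = strategy,
                       seed = derive_seed(seed, i), y0 = y0)
    estimation_error(th, fit)
  }, numeric(1))
  structure(list(design = design, errors = errors, mean_error = mean(errors),
                 settings = list(far = far, n = n, iterations = iterations,
                                 strategy = strategy, seed = seed,
                                 noise = noise)),
            class = "evaluation_result")
}

#' Accuracy ratio of random over PARSEC estimation errors
#'
#' `mean(random_errors) / mean(parsec_errors)`; values above 1 mean the
#' PARSEC designs estimate parameters more accurately.
#'
#' @param random_errors,parsec_errors non-empty numeric vectors of
#'   per-design mean errors.
#' @return positive scalar; `Inf` with a warning when PARSEC recovery is
#'   perfect (zero mean error).
#' @export
accuracy_ratio <- function(random_errors, parsec_errors) {
  if (!length(random_errors) || !length(parsec_errors))
    stop("both error lists must be non-empty")
  mp <- mean(parsec_errors)
  if (mp == 0) {
    warning("perfect PARSEC recovery: accuracy ratio undefined")
    return(Inf)
  }
  mean(random_errors) / mp
}

#' Fuzzy burden ratio
#'
#' Distinct designs produced under PARSEC(c) divided by those under
#' PARSEC(k), on identically configured ensembles; distinctness is by
#' order-ignoring candidate-set equality. Small values mean fuzzy
#' clustering collapses the design search and saves evaluation cost.
#'
#' @param c_designs,k_designs design ensembles (lists of `parsec_design`).
#' @return positive scalar.
#' @export
fuzzy_burden_ratio <- function(c_designs, k_designs) {
  if (!length(c_designs) || !length(k_designs))
    stop("ensembles must be non-empty")
  n_distinct <- function(dl)
    length(unique(vapply(dl, design_key, character(1))))
  n_distinct(c_designs) / n_distinct(k_designs)
}

#' Shannon entropy of an ensemble's pooled time points
#'
#' Pools every measurement time across the ensemble, bins them into
#' `n_bins` equal-length bins over `[0, horizon]`, and returns the base-2
#' Shannon entropy (empty bins contribute 0). A uniform occupancy gives
#' `log2(n_bins)` bits; concentration on few bins drives it toward 0.
#'
#' @param ensemble list of `parsec_design`s (or a single design).
#' @param horizon experiment duration (hours).
#' @param n_bins number of bins (default 12).
#' @return entropy in bits, in `[0, log2(n_bins)]`.
#' @export
timepoint_entropy <- function(ensemble, horizon, n_bins = 12) {
  if (inherits(ensemble, "parsec_design")) ensemble <- list(ensemble)
  times <- unlist(lapply(ensemble, design_times))
  if (any(times < 0 | times > horizon))
    stop("design times fall outside [0, horizon]")
  edges <- seq(0, horizon, length.out = n_bins + 1)
  cnt <- tabulate(pmin(pmax(findInterval(times, edges,
                                         rightmost.closed = TRUE), 1L),
                       n_bins), nbins = n_bins)
  p <- cnt / sum(cnt)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Mean error versus sub-sample size
#'
#' For each requested size, draws `n_subsamples` random subsets of the
#' ensemble's per-design errors and averages the within-subset means —
#' the "how many design realisations do I need" curve.
#'
#' @param errors numeric vector of per-design mean errors.
#' @param sizes sub-sample sizes (each `<= length(errors)`).
#' @param n_subsamples sub-samplings per size (default 20).
#' @param seed integer seed.
#' @return data.frame with `size`, `mean_error`, `sd_error`.
#' @export
subsample_error_curve <- function(errors, sizes, n_subsamples = 20,
                                  seed = 1L) {
  stopifnot(all(sizes >= 1), all(sizes <= length(errors)))
  rows <- local_seed(seed, lapply(sizes, function(sz) {
    means <- vapply(seq_len(n_subsamples), function(i)
      mean(errors[sample.int(length(errors), sz)]), numeric(1))
    data.frame(size = sz, mean_error = mean(means), sd_error = stats::sd(means))
  }))
  do.call(rbind, rows)
}

#' Compare design-generator ensembles
#'
#' Evaluates each ensemble with [evaluate_design()] at shared settings and
#' assembles the comparison metrics: per-generator mean errors (both the
#' mean of per-design means and the pooled per-set mean), accuracy ratios
#' of every generator against the reference PARSEC ensemble, and pooled
#' time-point entropies.
#'
#' @param ensembles named list of design ensembles; the name `"PD"` (or the
#'   first element) is the PARSEC reference.
#' @param model,theta_sets,space,noise,far,n,iterations,strategy,seed,y0
#'   passed to [evaluate_design()].
#' @param horizon experiment duration for the entropy.
#' @return an `ensemble_comparison` list.
#' @export
compare_ensembles <- function(ensembles, model,
                              theta_sets = matrix(model$default_parameters, 1,
                                dimnames = list(NULL,
                                                model$parameter_names)),
                              space = log_uniform_space(model),
                              noise = noise_spec(), far = 0.01, n = 2000,
                              iterations = 4, strategy = "HDUS", seed = 1L,
                              y0 = model$default_initial_state,
                              horizon = NULL) {
  evals <- lapply(seq_along(ensembles), function(g)
    lapply(seq_along(ensembles[[g]]), function(i)
      evaluate_design(ensembles[[g]][[i]], model, theta_sets, space, noise,
                      far, n, iterations, strategy,
                      seed = derive_seed(seed, g * 100000 + i), y0 = y0)))
  names(evals) <- names(ensembles)
  mean_errors <- lapply(evals, function(ev)
    vapply(ev, `[[`, numeric(1), "mean_error"))
  pooled_errors <- lapply(evals, function(ev)
    unlist(lapply(ev, `[[`, "errors")))
  ref <- if ("PD" %in% names(ensembles)) "PD" else names(ensembles)[1]
  ratios <- vapply(names(ensembles), function(g)
    accuracy_ratio(mean_errors[[g]], mean_errors[[ref]]), numeric(1))
  entropy <- if (!is.null(horizon))
    vapply(ensembles, timepoint_entropy, numeric(1), horizon = horizon)
  structure(list(evaluations = evals, mean_errors = mean_errors,
                 pooled_mean = vapply(pooled_errors, mean, numeric(1)),
                 accuracy_ratios = ratios, reference = ref,
                 entropy = entropy),
            class = "ensemble_comparison")
}

#' Markdown summary of an ensemble comparison
#' @param cmp an `ensemble_comparison`.
#' @return character vector of markdown lines.
#' @export
format_comparison <- function(cmp) {
  hdr <- "| generator | designs | mean error | pooled mean | accuracy ratio |"
  sep <- "|---|---|---|---|---|"
  rows <- vapply(names(cmp$mean_errors), function(g)
    sprintf("| %s | %d | %.4g | %.4g | %.3g |", g,
            length(cmp$mean_errors[[g]]), mean(cmp$mean_errors[[g]]),
            cmp$pooled_mean[[g]], cmp$accuracy_ratios[[g]]),
    character(1))
  c(hdr, sep, rows)
}
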