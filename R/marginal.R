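#' Parameter space for estimation
#'
#' Describes the universe the estimator searches: per-parameter bounds on a
#' log10 scale, plus an optional dummy parameter. The dummy is sampled and
#' selected like any other parameter but never enters a model right-hand
#' side; its posterior staying uniform is the estimator's negative control
#' and calibrates significance thresholds for identifiability diagnostics.
#'
#' @param names character parameter identifiers.
#' @param lower,upper numeric log10 bounds (`lower < upper` elementwise).
#' @param dummy logical vector flagging dummy parameters (default: the
#'   parameter literally named `"dummy"`).
#' @return an object of class `parameter_space` (data.frame).
#' @export
parameter_space <- function(names, lower, upper, dummy = names == "dummy") {
  stopifnot(length(names) == length(lower), length(lower) == length(upper))
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    stop("bounds must be finite")
  if (any(lower >= upper)) stop("each lower bound must be below its upper")
  structure(data.frame(name = as.character(names), lower = lower,
                       upper = upper, dummy = dummy,
                       stringsAsFactors = FALSE),
            class = c("parameter_space", "data.frame"))
}

#' Log-uniform parameter space around a centre point
#'
#' Builds the estimator's default prior universe: bounds spanning
#' `half_width` decades either side of `centre` (natural scale) for the
#' model's free parameters, with a dummy parameter appended. A full span of
#' two orders of magnitude (`half_width = 1`) is the default.
#'
#' @param model an [ode_model()].
#' @param centre named numeric vector (natural scale); defaults to the
#'   model's ground truth.
#' @param half_width decades either side of the centre.
#' @param add_dummy append a dummy parameter spanning the same total width.
#' @return a [parameter_space()].
#' @export
log_uniform_space <- function(model, centre = model$default_parameters,
                              half_width = 1, add_dummy = TRUE) {
  centre <- resolve_theta(model, centre)
  free <- model$free_parameters
  idx <- match(free, model$parameter_names)
  lo <- log10(centre[idx]) - half_width
  hi <- log10(centre[idx]) + half_width
  nm <- free
  if (add_dummy) {
    # dummy spans a unit-free range of the same total width
    nm <- c(nm, "dummy")
    lo <- c(lo, -half_width)
    hi <- c(hi, half_width)
  }
  parameter_space(nm, lo, hi)
}

#' Histogram marginal distributions
#'
#' Marginals are fixed-width histograms over a parameter's prior log10
#' range: `breaks` (length `n_bins + 1`) and non-negative `mass` summing to
#' 1. This representation makes the noisy-mixing step and inverse-CDF Latin
#' hypercube sampling exact.
#'
#' @param parameter parameter identifier.
#' @param breaks increasing numeric vector of bin edges (log10 units).
#' @param mass per-bin probability mass; normalised on construction.
#' @return an object of class `parsec_marginal`.
#' @export
marginal_histogram <- function(parameter, breaks, mass) {
  stopifnot(length(mass) == length(breaks) - 1, all(diff(breaks) > 0))
  if (any(mass < 0)) stop("marginal mass must be non-negative")
  s <- sum(mass)
  if (s <= 0) stop("marginal mass must have positive total")
  structure(list(parameter = parameter, breaks = as.numeric(breaks),
                 mass = as.numeric(mass) / s),
            class = "parsec_marginal")
}

#' Uniform marginal over a parameter's prior range
#'
#' @param parameter identifier.
#' @param lower,upper log10 bounds.
#' @param n_bins number of histogram bins (default 100).
#' @export
uniform_marginal <- function(parameter, lower, upper, n_bins = 100) {
  marginal_histogram(parameter, seq(lower, upper, length.out = n_bins + 1),
                     rep(1 / n_bins, n_bins))
}

#' Uniform prior marginals for every parameter of a space
#'
#' @param space a [parameter_space()].
#' @param n_bins histogram bins per parameter.
#' @return named list of [marginal_histogram()]s.
#' @export
uniform_prior <- function(space, n_bins = 100) {
  out <- lapply(seq_len(nrow(space)), function(i)
    uniform_marginal(space$name[i], space$lower[i], space$upper[i], n_bins))
  stats::setNames(out, space$name)
}

#' Quantile function of a histogram marginal
#'
#' Piecewise-linear inverse CDF; exact for the histogram representation.
#'
#' @param m a `parsec_marginal`.
#' @param p probabilities in `[0, 1]`.
#' @export
marginal_quantile <- function(m, p) {
  stopifnot(all(p >= 0 & p <= 1))
  cum <- c(0, cumsum(m$mass))
  cum[length(cum)] <- 1 # guard rounding
  idx <- findInterval(p, cum, rightmost.closed = TRUE)
  idx[idx > length(m$mass)] <- length(m$mass)
  # within zero-mass bins the CDF is flat; findInterval lands on the last
  # bin whose cumulative start is <= p, skip forward over zero-mass bins
  zero <- m$mass[idx] == 0
  while (any(zero)) {
    idx[zero] <- idx[zero] + 1
    idx[idx > length(m$mass)] <- length(m$mass)
    zero <- m$mass[idx] == 0 & idx < length(m$mass)
  }
  frac <- (p - cum[idx]) / ifelse(m$mass[idx] > 0, m$mass[idx], 1)
  frac <- pmin(pmax(frac, 0), 1)
  m$breaks[idx] + frac * diff(m$breaks)[idx]
}

#' CDF of a histogram marginal
#' @rdname marginal_quantile
#' @param x quantiles (log10 units).
#' @export
marginal_cdf <- function(m, x) {
  cum <- c(0, cumsum(m$mass))
  idx <- findInterval(x, m$breaks, rightmost.closed = TRUE)
  out <- numeric(length(x))
  inside <- idx >= 1 & idx <= length(m$mass)
  out[x >= m$breaks[length(m$breaks)]] <- 1
  w <- diff(m$breaks)
  out[inside] <- cum[idx[inside]] +
    m$mass[idx[inside]] * (x[inside] - m$breaks[idx[inside]]) / w[idx[inside]]
  pmin(pmax(out, 0), 1)
}

#' Mode (bin midpoint of maximal mass) of a marginal
#' @param m a `parsec_marginal`.
#' @export
marginal_mode <- function(m) {
  i <- which.max(m$mass)
  (m$breaks[i] + m$breaks[i + 1]) / 2
}

#' Mix a marginal with its prior-wide uniform ("gradient noisy sampling")
#'
#' At iteration `k` the sampling distribution is
#' `0.25/(k+1) * U + (1 - 0.25/(k+1)) * p`, where `U` is uniform over the
#' prior bounds (the marginal's full break range). The uniform share decays
#' with `k`, so early iterations explore while late ones refine.
#'
#' @param m current marginal estimate `p`.
#' @param k iteration index (`>= 1`).
#' @return the mixed, normalised marginal.
#' @export
mix_noisy_marginal <- function(m, k) {
  stopifnot(inherits(m, "parsec_marginal"))
  if (!is.numeric(k) || length(k) != 1 || k < 1)
    stop("iteration index k must be >= 1")
  w <- 0.25 / (k + 1)
  widths <- diff(m$breaks)
  u <- widths / sum(widths)
  marginal_histogram(m$parameter, m$breaks, w * u + (1 - w) * m$mass)
}

#' Latin hypercube sample from per-parameter marginals
#'
#' For each parameter independently, `[0,1]` is cut into `n` equal strata;
#' one uniform draw is taken per stratum, the strata are randomly permuted,
#' and draws are pushed through the marginal's inverse CDF. No transition
#' kernel is involved: parameters are sampled independently.
#'
#' @param marginals named list of `parsec_marginal`s.
#' @param n number of samples (`>= 1`).
#' @param seed integer seed.
#' @return a `sample_batch`: list with `combos` (an `n x p` matrix of log10
#'   values, columns named) and `chi2` (unfilled, `NA`).
#' @export
lhs_sample <- function(marginals, n, seed = 1L) {
  stopifnot(n >= 1)
  combos <- local_seed(seed, {
    vapply(marginals, function(m) {
      u <- (sample.int(n) - 1 + stats::runif(n)) / n
      marginal_quantile(m, u)
    }, numeric(n))
  })
  if (n == 1) combos <- matrix(combos, nrow = 1,
                               dimnames = list(NULL, names(marginals)))
  structure(list(combos = combos, chi2 = rep(NA_real_, n), iteration = NA),
            class = "sample_batch")
}

#' Empirical histogram update of marginals from selected combinations
#'
#' Each parameter's marginal becomes the normalised binned empirical
#' distribution of its selected values over the prior-wide break grid.
#'
#' @param selected matrix of selected combos (log10), columns named.
#' @param space a [parameter_space()] supplying the bin grids.
#' @param n_bins histogram bins.
#' @return named list of marginals.
#' @export
update_marginals <- function(selected, space, n_bins = 100) {
  if (!is.matrix(selected) || nrow(selected) < 1)
    stop("need >= 1 selected combination")
  out <- lapply(seq_len(nrow(space)), function(i) {
    br <- seq(space$lower[i], space$upper[i], length.out = n_bins + 1)
    x <- selected[, space$name[i]]
    cnt <- tabulate(pmin(pmax(findInterval(x, br, rightmost.closed = TRUE),
                              1L), n_bins), nbins = n_bins)
    marginal_histogram(space$name[i], br, cnt)
  })
  stats::setNames(out, space$name)
}

#' Write marginals to CSV (`parameter, bin_lo, bin_hi, mass`)
#' @param marginals named list of marginals.
#' @param path output file.
#' @export
write_marginals <- function(marginals, path) {
  rows <- do.call(rbind, lapply(marginals, function(m)
    data.frame(parameter = m$parameter, bin_lo = utils::head(m$breaks, -1),
               bin_hi = m$breaks[-1], mass = m$mass)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
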