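#' eFAST search-curve sample in the unit hypercube
#'
#' Extended Fourier Amplitude Sensitivity Test sampling: every parameter
#' oscillates along a space-filling curve
#' `x_l(s) = 1/2 + asin(sin(omega_l s + phi_l)) / pi` over
#' `s = 2 pi j / NS`. The driver parameter gets the high frequency
#' `omega = floor((NS - 1) / (2 M))`; all complementary parameters share
#' frequencies at most `omega / (2 M)` so their harmonics do not alias into
#' the driver's first `M` harmonics.
#'
#' @param p number of parameters.
#' @param driver index of the parameter of interest.
#' @param ns points per curve (odd; default 65).
#' @param m interference factor (harmonics counted; default 4).
#' @param phases numeric vector of random phase shifts, length `p`.
#' @return `ns x p` matrix of coordinates in `[0, 1]`.
#' @keywords internal
efast_curve <- function(p, driver, ns, m, phases) {
  omega_max <- floor((ns - 1) / (2 * m))
  if (omega_max < 1) stop("ns too small for interference factor m")
  lowmax <- max(1, floor(omega_max / (2 * m)))
  omega <- rep(1, p)
  if (p > 1) {
    # distinct complementary frequencies whenever they fit below
    # omega_max / (2 m); sharing a frequency lets random phases cancel and
    # silently deflate the complementary variance
    omega[-driver] <- if (p - 1 <= lowmax) seq_len(p - 1) else
      rep_len(seq_len(lowmax), p - 1)
  }
  omega[driver] <- omega_max
  s <- 2 * pi * (seq_len(ns) - 1) / ns
  x <- vapply(seq_len(p), function(l)
    0.5 + asin(sin(omega[l] * s + phases[l])) / pi, numeric(ns))
  attr(x, "omega") <- omega
  x
}

# smallest curve length whose driver frequency keeps the first m harmonics
# clear of distinct complementary frequencies 1..(p-1): omega1 = 2 m (p-1),
# ns = 2 m omega1 + 1 (p = 2 recovers the classic 65-point minimum)
efast_default_ns <- function(p, m = 4) {
  omega1 <- max(8, 2 * m * (p - 1))
  2 * m * omega1 + 1
}

# first-order index of the driver frequency from one output curve
efast_first_order <- function(y, omega_driver, m) {
  ns <- length(y)
  q_max <- floor((ns - 1) / 2)
  s <- 2 * pi * (seq_len(ns) - 1) / ns
  q <- seq_len(q_max)
  A <- vapply(q, function(qq) sum(y * cos(qq * s)), numeric(1)) * 2 / ns
  B <- vapply(q, function(qq) sum(y * sin(qq * s)), numeric(1)) * 2 / ns
  spec <- A^2 + B^2
  total <- sum(spec)
  if (total <= .Machine$double.eps * max(1, mean(y)^2))
    return(structure(0, zero_variance = TRUE))
  hh <- omega_driver * seq_len(m)
  hh <- hh[hh <= q_max]
  min(1, sum(spec[hh]) / total)
}

#' Per-parameter variation ranges for sensitivity analysis
#'
#' PSI at a training sample is a local-in-distribution quantity: each free
#' parameter varies over `half_width` decades either side of its value in
#' `theta0` (log10 scale), clipped to `bounds` when supplied.
#'
#' @param model an [ode_model()].
#' @param theta0 parameter vector (natural scale) the ranges centre on.
#' @param half_width log10 half-width (default 0.25 decades).
#' @param bounds optional [parameter_space()] to clip against.
#' @return data.frame with `name`, `lower`, `upper` (log10) per free
#'   parameter.
#' @export
psi_ranges <- function(model, theta0 = model$default_parameters,
                       half_width = 0.25, bounds = NULL) {
  theta0 <- resolve_theta(model, theta0)
  free <- model$free_parameters
  ctr <- log10(theta0[match(free, model$parameter_names)])
  lo <- ctr - half_width
  hi <- ctr + half_width
  if (!is.null(bounds)) {
    i <- match(free, bounds$name)
    ok <- !is.na(i)
    lo[ok] <- pmax(lo[ok], bounds$lower[i[ok]])
    hi[ok] <- pmin(hi[ok], bounds$upper[i[ok]])
  }
  if (any(hi <= lo)) stop("degenerate variation range")
  data.frame(name = free, lower = lo, upper = hi, stringsAsFactors = FALSE)
}

#' eFAST first-order sensitivity indices over a whole time grid
#'
#' Workhorse shared by [efast_psi()] and [compute_parsec_psi()]: simulates
#' the eFAST sample once over the full grid and returns indices for every
#' (time, variable, parameter) triple, so the per-candidate extraction is
#' free. Indices lie in `[0, 1]`; a constant output (zero total variance)
#' yields 0 for all parameters at that point and is flagged.
#'
#' @param model an [ode_model()].
#' @param times output time grid.
#' @param variables observed state identifiers.
#' @param theta0 centre parameter vector (natural scale).
#' @param ranges from [psi_ranges()].
#' @param ns,m,n_resample eFAST settings: points per curve (default: the
#'   smallest interference-free length for the parameter count, see
#'   details), interference factor, resample curves (random phase draws
#'   averaged over).
#' @param seed integer seed for the phases.
#' @param y0 initial state.
#' @return array `[time, variable, parameter]` of first-order indices.
#' @export
efast_psi_grid <- function(model, times, variables,
                           theta0 = model$default_parameters,
                           ranges = psi_ranges(model, theta0), ns = NULL,
                           m = 4, n_resample = 1, seed = 1L,
                           y0 = model$default_initial_state) {
  theta0 <- resolve_theta(model, theta0)
  stopifnot(all(variables %in% model$state_names))
  p <- nrow(ranges)
  if (is.null(ns)) ns <- efast_default_ns(p, m)
  idx <- match(ranges$name, model$parameter_names)
  nt <- length(times)
  nv <- length(variables)
  out <- array(0, c(nt, nv, p),
               dimnames = list(NULL, variables, ranges$name))
  phases <- local_seed(seed,
                       matrix(stats::runif(n_resample * p, 0, 2 * pi),
                              n_resample, p))
  for (l in seq_len(p)) {
    acc <- matrix(0, nt, nv)
    for (r in seq_len(n_resample)) {
      x <- efast_curve(p, l, ns, m, phases[r, ])
      omega <- attr(x, "omega")
      # map unit coordinates to log10 ranges, then to natural scale
      lg <- sweep(sweep(x, 2, ranges$upper - ranges$lower, "*"), 2,
                  ranges$lower, "+")
      thetas <- matrix(rep(theta0, each = ns), nrow = ns)
      thetas[, idx] <- 10^lg
      sim <- simulate_ode_batch(model, thetas, times, y0 = y0)
      if (any(!sim$ok))
        stop("eFAST simulation failed at ", sum(!sim$ok), " sample points")
      for (j in seq_len(nt)) for (v in seq_len(nv)) {
        y <- sim$states[, j, match(variables[v], model$state_names)]
        acc[j, v] <- acc[j, v] +
          efast_first_order(y, omega[l], m) / n_resample
      }
    }
    out[, , l] <- acc
  }
  out
}

#' Parameter sensitivity index (PSI) vector of one measurement candidate
#'
#' First-order eFAST indices `psi(M_i, Theta_j, theta_l)` for each free
#' parameter and each observed variable at the candidate's time(s), with
#' parameters varied over `ranges` around `theta0`.
#'
#' @param model an [ode_model()].
#' @param candidate a [measurement_candidate()].
#' @param theta0 training sample the PSI is evaluated at (natural scale).
#' @param ranges from [psi_ranges()].
#' @param ... further settings passed to [efast_psi_grid()].
#' @return matrix `parameters x variables` of indices in `[0, 1]`.
#' @export
efast_psi <- function(model, candidate, theta0 = model$default_parameters,
                      ranges = psi_ranges(model, theta0), ...) {
  stopifnot(inherits(candidate, "measurement_candidate"))
  times <- sort(unique(candidate$times))
  grid <- efast_psi_grid(model, times, unique(candidate$variables), theta0,
                         ranges, ...)
  p <- dim(grid)[3]
  out <- matrix(NA_real_, p, length(candidate$variables),
                dimnames = list(dimnames(grid)[[3]], candidate$variables))
  for (v in seq_along(candidate$variables))
    out[, v] <- grid[match(candidate$times[v], times),
                     candidate$variables[v], ]
  out
}

#' Training samples from an uncertainty distribution
#'
#' Latin hypercube draws of full free-parameter vectors from a log-uniform
#' uncertainty specification. Parameters absent from `space` stay at the
#' model's ground truth.
#'
#' @param model an [ode_model()].
#' @param space a [parameter_space()] over the uncertain parameters (log10
#'   bounds, no dummy).
#' @param k number of samples.
#' @param seed integer seed.
#' @return matrix `k x parameters` (natural scale, all model parameters,
#'   columns named).
#' @export
training_samples <- function(model, space, k, seed = 1L) {
  marg <- uniform_prior(space)
  batch <- lhs_sample(marg, k, seed = seed)
  out <- matrix(rep(model$default_parameters, each = k), nrow = k,
                dimnames = list(NULL, model$parameter_names))
  out[, space$name] <- 10^batch$combos
  out
}

#' Log-uniform uncertainty specification over selected parameters
#'
#' A `fold`-fold uncertainty means each listed parameter ranges over
#' `[truth / sqrt(fold), truth * sqrt(fold)]`, i.e. a log-uniform band of
#' total width `log10(fold)` centred on the truth.
#'
#' @param model an [ode_model()].
#' @param params parameters carrying uncertainty (default: first two free).
#' @param fold total fold-range (default 4).
#' @param centre centre vector (natural scale).
#' @return a [parameter_space()].
#' @export
uncertainty_space <- function(model, params = model$free_parameters[1:2],
                              fold = 4, centre = model$default_parameters) {
  centre <- resolve_theta(model, centre)
  ctr <- log10(centre[match(params, model$parameter_names)])
  hw <- log10(fold) / 2
  parameter_space(params, ctr - hw, ctr + hw, dummy = rep(FALSE,
                                                          length(params)))
}

#' Concatenate PSI vectors into a PARSEC-PSI vector
#'
#' Sample-major concatenation: for each training sample in order, the
#' per-variable PSI columns are appended (parameter index varying fastest,
#' then variable, then sample). The layout is recorded in the element names
#' so distances are reproducible across runs. For staggered candidates each
#' variable's PSI is already evaluated at its own time by [efast_psi()].
#'
#' @param candidate the [measurement_candidate()] the vectors belong to.
#' @param psi_per_sample list (one entry per training sample) of
#'   `parameters x variables` PSI matrices.
#' @return a `parsec_psi` vector with `candidate` attribute.
#' @export
build_parsec_psi <- function(candidate, psi_per_sample) {
  dims <- unique(lapply(psi_per_sample, dim))
  if (length(dims) != 1) stop("mismatched PSI dimensions across samples")
  values <- unlist(lapply(seq_along(psi_per_sample), function(j) {
    m <- psi_per_sample[[j]]
    v <- as.vector(m)
    names(v) <- paste0("s", j, ".", rep(colnames(m), each = nrow(m)), ".",
                       rep(rownames(m), ncol(m)))
    v
  }))
  if (any(values < -1e-9 | values > 1 + 1e-9))
    stop("PSI entries must lie in [0, 1]")
  structure(pmin(pmax(values, 0), 1), candidate = candidate,
            class = "parsec_psi")
}

#' PARSEC-PSI matrix for a set of measurement candidates
#'
#' Runs eFAST once per training sample over the pooled candidate time grid
#' and assembles the full candidate-by-feature PARSEC-PSI matrix used for
#' clustering.
#'
#' @param model an [ode_model()].
#' @param candidates list of [measurement_candidate()]s.
#' @param training matrix of training samples (rows, natural scale) as from
#'   [training_samples()]; defaults to the single ground-truth guess.
#' @param half_width log10 half-width of the per-parameter PSI range.
#' @param bounds optional clipping [parameter_space()].
#' @param ns,m,n_resample,seed eFAST settings (see [efast_psi_grid()]).
#' @param y0 initial state.
#' @return numeric matrix, one row per candidate.
#' @export
compute_parsec_psi <- function(model, candidates,
                               training = matrix(model$default_parameters, 1,
                                 dimnames = list(NULL,
                                                 model$parameter_names)),
                               half_width = 0.25, bounds = NULL, ns = NULL,
                               m = 4, n_resample = 1, seed = 1L,
                               y0 = model$default_initial_state) {
  vars <- unique(unlist(lapply(candidates, `[[`, "variables")))
  times <- sort(unique(unlist(lapply(candidates, `[[`, "times"))))
  grids <- lapply(seq_len(nrow(training)), function(j) {
    th <- resolve_theta(model, training[j, ])
    efast_psi_grid(model, times, vars, th,
                   psi_ranges(model, th, half_width, bounds), ns, m,
                   n_resample, seed = derive_seed(seed, j), y0 = y0)
  })
  rows <- lapply(candidates, function(cc) {
    psi <- lapply(grids, function(g) {
      out <- vapply(seq_along(cc$variables), function(v)
        g[match(cc$times[v], times), cc$variables[v], ],
        numeric(dim(g)[3]))
      rownames(out) <- dimnames(g)[[3]]
      colnames(out) <- cc$variables
      out
    })
    build_parsec_psi(cc, psi)
  })
  mat <- do.call(rbind, lapply(rows, as.numeric))
  colnames(mat) <- names(rows[[1]])
  rownames(mat) <- vapply(candidates, function(cc) paste0("M", cc$id),
                          character(1))
  mat
}

#' Write a PARSEC-PSI matrix to CSV
#' @param psi matrix from [compute_parsec_psi()].
#' @param path output file.
#' @export
write_parsec_psi <- function(psi, path) {
  utils::write.csv(data.frame(candidate = rownames(psi), psi,
                              check.names = FALSE), path, row.names = FALSE)
  invisible(path)
}
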