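#' ODE model objects
#'
#' An `ode_model` bundles a deterministic right-hand side with its state and
#' parameter names, default (ground-truth) parameter values, default initial
#' state, and the subset of parameters treated as free during estimation.
#' The three fixture models used throughout the package are created by
#' [lotka_volterra_model()], [repressilator_model()] and [viral_model()];
#' arbitrary models can be built from an R function or imported from SBML
#' with [read_sbml_model()].
#'
#' @param name model identifier.
#' @param state_names character vector of state-variable identifiers.
#' @param parameter_names character vector of parameter identifiers.
#' @param rhs either an integer id of a compiled fixture right-hand side or a
#'   function `function(t, y, theta)` returning the state derivatives.
#' @param default_parameters named numeric vector, one value per parameter.
#' @param default_initial_state named numeric vector, one value per state.
#' @param free_parameters character vector naming the parameters that are
#'   estimated; the remainder are held at their defaults.
#' @param horizon default integration horizon in hours.
#' @return an object of class `ode_model`.
#' @export
ode_model <- function(name, state_names, parameter_names, rhs,
                      default_parameters, default_initial_state,
                      free_parameters = parameter_names, horizon = Inf) {
  stopifnot(length(default_parameters) == length(parameter_names),
            length(default_initial_state) == length(state_names),
            all(free_parameters %in% parameter_names))
  structure(list(
    name = name,
    state_names = state_names,
    parameter_names = parameter_names,
    rhs = rhs,
    default_parameters = stats::setNames(as.numeric(default_parameters),
                                         parameter_names),
    default_initial_state = stats::setNames(as.numeric(default_initial_state),
                                            state_names),
    free_parameters = free_parameters,
    horizon = horizon
  ), class = "ode_model")
}

#' @export
print.ode_model <- function(x, ...) {
  cat("<ode_model>", x$name, "\n")
  cat("  states:    ", paste(x$state_names, collapse = ", "), "\n")
  cat("  parameters:", paste(x$parameter_names, collapse = ", "),
      sprintf(" (%d free)", length(x$free_parameters)), "\n")
  invisible(x)
}

#' Lotka-Volterra predator-prey fixture
#'
#' Classic two-species model: prey `x` grows at rate `a` and is consumed at
#' rate `b`; predators `y` convert predation into growth at rate `c` and die
#' at rate `delta`. All four rate parameters are free.
#'
#' \deqn{dx/dt = a x - b x y, \qquad dy/dt = c x y - \delta y}
#'
#' @return an `ode_model` with states `prey`, `predator`.
#' @export
lotka_volterra_model <- function() {
  ode_model(
    name = "lotka_volterra",
    state_names = c("prey", "predator"),
    parameter_names = c("a", "b", "c", "delta"),
    rhs = 1L,
    default_parameters = c(a = 1.0, b = 0.4, c = 0.2, delta = 0.8),
    default_initial_state = c(prey = 6, predator = 2),
    horizon = 60
  )
}

#' Three-gene repressilator fixture
#'
#' Protein-only cyclic repression circuit: protein A is repressed by C, B by
#' A, and C by B, each with Hill kinetics (maximal synthesis `k1`, repression
#' threshold `K`, Hill coefficient `n`) and first-order degradation (`dA`,
#' `dB`, `dC`). The slight asymmetry in the degradation rates breaks the
#' rotational symmetry so the three proteins carry distinguishable
#' sensitivity profiles. Default degradation rates correspond to protein
#' half-lives of 5-7 h, giving sustained oscillations with a period of
#' roughly 41 h — a few cycles across a 72-120 h experiment, well resolved
#' by a 3 h sampling grid. All six parameters are free.
#'
#' @return an `ode_model` with states `A`, `B`, `C`; time unit hours.
#' @export
repressilator_model <- function() {
  ode_model(
    name = "repressilator",
    state_names = c("A", "B", "C"),
    parameter_names = c("k1", "K", "n", "dA", "dB", "dC"),
    rhs = 2L,
    default_parameters = c(k1 = 30, K = 25, n = 3, dA = 0.14, dB = 0.12,
                           dC = 0.10),
    default_initial_state = c(A = 40, B = 10, C = 1),
    horizon = 168
  )
}

#' Positive-sense RNA virus life-cycle fixture (synthetic stand-in)
#'
#' A six-species, eleven-parameter cellular virus-growth model of the
#' canonical positive-sense RNA virus structure: genomic (+)RNA `Rp` is
#' translated into non-structural (`Pn`) and structural (`Ps`) protein,
#' replicated via a (-)RNA template `Rm`, packaged into assembly
#' intermediates `Rv`, and released as virions `V` (the titre). The seven
#' parameters tied to translation, replication and packaging are free; the
#' four degradation rates are fixed host properties. Coefficients are a
#' synthetic stand-in chosen to give saturating dynamics over 48 h.
#'
#' Translation, minus-strand synthesis and packaging all saturate through a
#' shared occupancy term `Rp / (K_r + Rp)`. Parameters: `k_t` maximal
#' translation rate, `f` non-structural fraction, `d_p` protein
#' degradation, `k_m` (-)RNA synthesis, `d_m` (-)RNA degradation, `k_p`
#' (+)RNA synthesis, `d_r` (+)RNA degradation, `k_a` packaging rate, `K_r`
#' occupancy saturation constant, `k_e` export rate, `d_v` virion loss.
#'
#' @return an `ode_model` with states `Rp`, `Rm`, `Pn`, `Ps`, `Rv`, `V`.
#' @export
viral_model <- function() {
  ode_model(
    name = "viral",
    state_names = c("Rp", "Rm", "Pn", "Ps", "Rv", "V"),
    parameter_names = c("k_t", "f", "d_p", "k_m", "d_m", "k_p", "d_r",
                        "k_a", "K_r", "k_e", "d_v"),
    rhs = 3L,
    default_parameters = c(k_t = 200, f = 0.3, d_p = 0.3, k_m = 0.5,
                           d_m = 0.2, k_p = 0.05, d_r = 0.2, k_a = 0.05,
                           K_r = 5, k_e = 1, d_v = 0.1),
    default_initial_state = c(Rp = 10, Rm = 0, Pn = 0, Ps = 0, Rv = 0, V = 0),
    horizon = 96,
    free_parameters = c("k_t", "f", "k_m", "k_p", "k_a", "K_r", "k_e")
  )
}

#' Simulate an ODE model
#'
#' Integrates the model with an adaptive embedded Runge-Kutta 5(4)
#' (Dormand-Prince) scheme and returns the states at exactly the requested
#' times. Integration failure (step underflow or state blow-up) raises an
#' error rather than returning a truncated trajectory.
#'
#' @param model an [ode_model()].
#' @param theta named or positional numeric parameter vector (natural scale);
#'   defaults to the model's ground-truth values.
#' @param times strictly increasing numeric vector of output times (hours),
#'   all `>= t0`.
#' @param y0 initial state at `t0`; defaults to the model's default.
#' @param t0 initial time (default 0).
#' @param rtol,atol relative/absolute integration tolerances.
#' @return a `trajectory`: list with `times` and a `times x states` matrix
#'   `states` (columns named by state).
#' @export
simulate_ode <- function(model, theta = model$default_parameters, times,
                         y0 = model$default_initial_state, t0 = 0,
                         rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "ode_model"))
  theta <- resolve_theta(model, theta)
  times <- as.numeric(times)
  if (length(times) < 1) stop("at least one output time is required")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (times[1] < t0) stop("times must not precede t0")
  if (any(y0 < 0)) stop("y0 must be non-negative")
  if (max(times) > model$horizon)
    stop("requested times exceed the model integration horizon")
  if (is.function(model$rhs)) {
    states <- ode_solve_r(model$rhs, theta, as.numeric(y0), times, t0,
                          rtol, atol, 1000000L)
  } else {
    states <- ode_solve_fixture(model$rhs, theta, as.numeric(y0), times, t0,
                                rtol, atol, 1000000L)
  }
  colnames(states) <- model$state_names
  structure(list(times = times, states = states), class = "trajectory")
}

#' Simulate one model at many parameter vectors
#'
#' Batch companion to [simulate_ode()] used by the ABC-FAR inner loop and the
#' eFAST sampler. For compiled fixture models the whole batch runs in C++;
#' for R-function models it falls back to a loop. Failed integrations yield
#' `NA` trajectories flagged in `ok` instead of an error.
#'
#' @param thetas numeric matrix, one parameter vector per row (natural scale,
#'   full parameter count).
#' @inheritParams simulate_ode
#' @return list with `states` (array `n x times x states`) and logical `ok`.
#' @export
simulate_ode_batch <- function(model, thetas, times,
                               y0 = model$default_initial_state, t0 = 0,
                               rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "ode_model"), is.matrix(thetas))
  times <- as.numeric(times)
  if (is.function(model$rhs)) {
    n <- nrow(thetas)
    arr <- array(NA_real_, c(n, length(times), length(model$state_names)))
    ok <- logical(n)
    for (i in seq_len(n)) {
      res <- tryCatch(
        ode_solve_r(model$rhs, thetas[i, ], as.numeric(y0), times, t0,
                    rtol, atol, 1000000L),
        error = function(e) NULL)
      if (!is.null(res)) {
        arr[i, , ] <- res
        ok[i] <- TRUE
      }
    }
    return(list(states = arr, ok = ok))
  }
  res <- ode_solve_fixture_batch(model$rhs, thetas, as.numeric(y0), times, t0,
                                 rtol, atol, 1000000L)
  res
}

# fill a partial / named theta against model defaults, preserving order
resolve_theta <- function(model, theta) {
  full <- model$default_parameters
  if (!is.null(names(theta)) && any(names(theta) != "")) {
    unknown <- setdiff(names(theta), model$parameter_names)
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    full[names(theta)] <- theta
  } else {
    if (length(theta) != length(full))
      stop("theta length does not match model parameter count")
    full[] <- theta
  }
  as.numeric(full)
}
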