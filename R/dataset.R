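#' Observation noise specification
#'
#' Controls how synthetic datasets are perturbed and how the reported
#' standard deviation `sd` of each record is set. The chi-squared statistic
#' divides by `sd^2`, so noiseless data still needs a positive `sd`: it is
#' taken as `max(rel_sd * |value|, sd_floor)`, which keeps the statistic
#' finite and scale-free.
#'
#' @param type `"none"` for noiseless observations or `"gaussian"` for
#'   additive Gaussian noise with the same `sd`.
#' @param rel_sd relative standard deviation (fraction of `|value|`).
#' @param sd_floor absolute floor on `sd` (model units).
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(type = c("none", "gaussian"), rel_sd = 0.05,
                       sd_floor = 1e-6) {
  type <- match.arg(type)
  stopifnot(rel_sd >= 0, sd_floor > 0)
  structure(list(type = type, rel_sd = rel_sd, sd_floor = sd_floor),
            class = "noise_spec")
}

#' Generate a synthetic dataset emulating a design
#'
#' Simulates the model at `theta_truth` and reads off one record per
#' (variable, time) pair implied by the design's candidates, optionally
#' adding seeded Gaussian noise. This is the `D(G, Theta)` operation: the
#' dataset a designed experiment would return if the model at `theta_truth`
#' were the real system.
#'
#' @param model an [ode_model()].
#' @param theta_truth generating parameter vector (natural scale; named or
#'   full-length).
#' @param design a [new_design()].
#' @param noise a [noise_spec()].
#' @param y0 initial state.
#' @param seed integer seed for the noise draws (ignored for `type="none"`).
#' @return a `parsec_dataset`: data.frame with columns
#'   `time, variable, value, sd` plus provenance attributes.
#' @export
generate_dataset <- function(model, theta_truth = model$default_parameters,
                             design, noise = noise_spec(),
                             y0 = model$default_initial_state, seed = 1L) {
  stopifnot(inherits(model, "ode_model"), inherits(design, "parsec_design"))
  vars <- unique(unlist(lapply(design$candidates, `[[`, "variables")))
  unknown <- setdiff(vars, model$state_names)
  if (length(unknown))
    stop("design references unknown variable(s): ",
         paste(unknown, collapse = ", "))
  pairs <- do.call(rbind, lapply(design$candidates, function(cc)
    data.frame(time = cc$times, variable = cc$variables,
               stringsAsFactors = FALSE)))
  if (anyDuplicated(pairs)) stop("duplicated (time, variable) pair in design")
  times <- sort(unique(pairs$time))
  traj <- simulate_ode(model, theta_truth, times, y0 = y0)
  value <- mapply(function(tt, v)
    traj$states[match(tt, times), v], pairs$time, pairs$variable)
  sd <- pmax(noise$rel_sd * abs(value), noise$sd_floor)
  if (noise$type == "gaussian") {
    value <- local_seed(seed, value + stats::rnorm(length(value), 0, sd))
  }
  out <- data.frame(time = pairs$time, variable = pairs$variable,
                    value = value, sd = sd, stringsAsFactors = FALSE)
  out <- out[order(out$time, out$variable), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "theta_truth") <- resolve_theta(model, theta_truth)
  attr(out, "noise") <- noise
  class(out) <- c("parsec_dataset", "data.frame")
  out
}

#' Read / write datasets as delimited text
#'
#' Plain CSV with header `time,variable,value,sd`.
#'
#' @param data a `parsec_dataset` (or any data.frame with those columns).
#' @param path file path.
#' @export
write_dataset <- function(data, path) {
  utils::write.csv(data[, c("time", "variable", "value", "sd")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "variable", "value", "sd")
  if (!all(need %in% names(out)))
    stop("dataset file must have columns time,variable,value,sd")
  if (any(out$sd <= 0)) stop("dataset sd values must be positive")
  class(out) <- c("parsec_dataset", "data.frame")
  out
}

# evaluate a function under a temporary RNG state
local_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
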