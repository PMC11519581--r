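#' Measurement candidates and designs
#'
#' A measurement candidate is one feasible observation option: a non-empty
#' set of observed state variables together with the time point(s) at which
#' they are read. For simultaneous designs all variables share one time; a
#' staggered candidate carries one time per variable. A design is an ordered
#' set of distinct candidates; PARSEC designs additionally satisfy
#' one-candidate-per-cluster.
#'
#' @param id integer candidate index.
#' @param variables character vector of observed state identifiers.
#' @param time numeric; a single time (hours) shared by all variables, or one
#'   time per variable for staggered measurements.
#' @return an object of class `measurement_candidate`.
#' @export
measurement_candidate <- function(id, variables, time) {
  variables <- as.character(variables)
  if (length(variables) < 1) stop("a candidate must observe >= 1 variable")
  times <- as.numeric(time)
  if (length(times) == 1) times <- rep(times, length(variables))
  if (length(times) != length(variables))
    stop("time must be scalar or one value per variable")
  structure(list(id = as.integer(id), variables = variables, times = times),
            class = "measurement_candidate")
}

#' Enumerate simultaneous measurement candidates on a feasible time grid
#'
#' One candidate per grid time, all observing the same variable set
#' simultaneously — the discretised design universe used for the fixtures
#' (repressilator: multiples of 3 h in (0, 72]; viral model: multiples of
#' 2 h in (0, 48]).
#'
#' @param grid numeric vector of feasible times `T_F`.
#' @param variables character vector of measurable state identifiers.
#' @return list of [measurement_candidate()] objects.
#' @export
enumerate_candidates <- function(grid, variables) {
  lapply(seq_along(grid), function(i)
    measurement_candidate(i, variables, grid[i]))
}

#' Construct a design from measurement candidates
#'
#' @param candidates list of [measurement_candidate()]s (distinct).
#' @param provenance generator tag, e.g. `"PD_BC"`, `"RD_BC"`, `"WD_BC"`.
#' @param seed seed used by the generator, for the record.
#' @return an object of class `parsec_design`.
#' @export
new_design <- function(candidates, provenance = "manual", seed = NA_integer_) {
  ids <- vapply(candidates, function(cc) cc$id, integer(1))
  if (anyDuplicated(ids)) stop("design candidates must be distinct")
  structure(list(candidates = candidates, provenance = provenance,
                 seed = seed), class = "parsec_design")
}

#' @export
print.parsec_design <- function(x, ...) {
  cat("<parsec_design>", x$provenance, "size", length(x$candidates), "\n")
  for (cc in x$candidates)
    cat(sprintf("  #%d  %s @ %s h\n", cc$id,
                paste(cc$variables, collapse = ","),
                paste(format(cc$times), collapse = ",")))
  invisible(x)
}

# order-independent identity of a design: sorted candidate ids
design_key <- function(design) {
  paste(sort(vapply(design$candidates, function(cc) cc$id, integer(1))),
        collapse = "-")
}

design_times <- function(design) {
  unlist(lapply(design$candidates, function(cc) cc$times), use.names = FALSE)
}

#' Serialise designs to JSON
#'
#' @param designs a `parsec_design` or list thereof.
#' @param path output file.
#' @export
write_designs <- function(designs, path) {
  if (inherits(designs, "parsec_design")) designs <- list(designs)
  out <- lapply(designs, function(d) list(
    provenance = d$provenance, seed = d$seed,
    candidates = lapply(d$candidates, function(cc)
      list(id = cc$id, variables = cc$variables, times = cc$times))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
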