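#' Load and validate a run configuration
#'
#' Configurations are YAML mappings; [run_pipeline()] receives either a file
#' path or an already-parsed list. Validation is structural: required fields
#' must be present and well-typed, unknown model names are rejected, and
#' defaults are filled in so the resolved configuration written next to the
#' artifacts is complete.
#'
#' @param config path to a YAML file or a named list.
#' @return validated, fully resolved config list.
#' @export
load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a YAML mapping")
  defaults <- list(
    seed = 1L,
    grid = NULL, variables = NULL, sample_size = 6L,
    guess = NULL,
    training = NULL,
    psi = list(half_width = 0.25, ns = NULL, m = 4L, n_resample = 1L),
    clustering = list(method = "kmeans", restarts = 10L),
    ensembles = list(n_designs = 20L,
                     generators = c("parsec_k", "random", "anti_parsec")),
    abc = list(far = 0.01, n = 2000L, iterations = 4L, strategy = "HDUS",
               prior_half_width = 1),
    noise = list(type = "none", rel_sd = 0.05, sd_floor = 1e-6))
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) {
      config[[nm]] <- defaults[[nm]]
    } else if (is.list(defaults[[nm]])) {
      miss <- setdiff(names(defaults[[nm]]), names(config[[nm]]))
      config[[nm]][miss] <- defaults[[nm]][miss]
    }
  }
  if (is.null(config$model))
    stop("config is missing required field: model")
  known <- c("lotka_volterra", "repressilator", "viral")
  if (is.null(config$sbml) && !config$model %in% known)
    stop("unknown model '", config$model, "'; expected one of ",
         paste(known, collapse = ", "), " or an sbml path")
  if (!is.null(config$grid) &&
      !all(c("from", "to", "by") %in% names(config$grid)))
    stop("grid must have fields from, to, by")
  if (!config$clustering$method %in% c("kmeans", "cmeans"))
    stop("clustering method must be kmeans or cmeans")
  if (!config$abc$strategy %in% c("HDUS", "HIUS"))
    stop("abc strategy must be HDUS or HIUS")
  config
}

config_model <- function(config) {
  if (!is.null(config$sbml)) return(read_sbml_model(config$sbml))
  switch(config$model,
         lotka_volterra = lotka_volterra_model(),
         repressilator = repressilator_model(),
         viral = viral_model())
}

# fixture defaults for the feasible grid / measurables when unspecified
config_grid <- function(config, model) {
  if (!is.null(config$grid))
    return(seq(config$grid$from, config$grid$to, by = config$grid$by))
  switch(model$name,
         repressilator = seq(3, 72, by = 3),
         viral = seq(2, 48, by = 2),
         seq(1, 20, by = 1))
}

config_variables <- function(config, model) {
  if (!is.null(config$variables)) return(unlist(config$variables))
  switch(model$name,
         repressilator = c("B", "C"),
         viral = c("Rp", "Rm", "V"),
         model$state_names)
}

#' Run the full PARSEC pipeline
#'
#' Orchestrates candidates -> sensitivity (PARSEC-PSI) -> clustering ->
#' design ensembles -> ABC-FAR evaluation -> comparison, writing every
#' artifact plus a manifest with content hashes into `out_dir`. All
#' randomness fans out from the single top-level seed via a documented
#' counter scheme (stage index -> derived child seed), so an identical
#' config and seed reproduce byte-identical numeric artifacts. Any stage
#' failure aborts with the stage name; artifacts from completed stages
#' remain on disk.
#'
#' @param config YAML path or list (see [load_config()]).
#' @param out_dir artifact directory (created).
#' @return invisibly, a list with the key results (psi, ensembles,
#'   comparison, manifest).
#' @export
run_pipeline <- function(config, out_dir) {
  config <- load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  log_lines <- character()
  logit <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(...))
    log_lines <<- c(log_lines, line)
    message(line)
  }

  model <- stage("model", config_model(config))
  grid <- config_grid(config, model)
  vars <- config_variables(config, model)
  horizon <- max(grid)
  yaml::write_yaml(config, file.path(out_dir, "config_resolved.yaml"))

  logit("stage candidates: %d grid times x {%s}", length(grid),
        paste(vars, collapse = ","))
  candidates <- stage("candidates", enumerate_candidates(grid, vars))

  guess <- model$default_parameters
  if (!is.null(config$guess)) {
    guess[names(config$guess)] <- unlist(config$guess)
  }
  if (!is.null(config$training)) {
    tr <- config$training
    usp <- uncertainty_space(model, unlist(tr$params), tr$fold, guess)
    train <- training_samples(model, usp, tr$k, seed = derive_seed(seed, 21))
    test <- if (!is.null(tr$test_k) && tr$test_k > 0)
      training_samples(model, usp, tr$test_k, seed = derive_seed(seed, 22))
  } else {
    train <- matrix(guess, 1, dimnames = list(NULL, model$parameter_names))
    test <- NULL
  }

  logit("stage psi: %d training sample(s)", nrow(train))
  psi <- stage("psi", compute_parsec_psi(
    model, candidates, train, half_width = config$psi$half_width,
    ns = config$psi$ns, m = config$psi$m,
    n_resample = config$psi$n_resample, seed = derive_seed(seed, 1)))
  write_parsec_psi(psi, file.path(out_dir, "parsec_psi.csv"))

  logit("stage profile: intra-cluster objective over k")
  profile <- stage("profile", intra_cluster_profile(
    psi, seq(2, min(12, nrow(psi) - 1)), config$clustering$method,
    restarts = config$clustering$restarts, seed = derive_seed(seed, 2)))
  utils::write.csv(data.frame(k = profile$k, objective = profile$objective),
                   file.path(out_dir, "cluster_profile.csv"),
                   row.names = FALSE)

  gens <- unlist(config$ensembles$generators)
  labels <- c(parsec_k = "PD", parsec_c = "PDc", random = "RD",
              anti_parsec = "WD")
  logit("stage ensembles: %d designs x {%s}, k=%d",
        config$ensembles$n_designs, paste(gens, collapse = ","),
        config$sample_size)
  ensembles <- stage("ensembles", {
    out <- lapply(seq_along(gens), function(g)
      design_ensemble(psi, candidates, config$ensembles$n_designs,
                      config$sample_size, gens[g],
                      seed = derive_seed(seed, 3 + g),
                      restarts = config$clustering$restarts,
                      label = labels[[gens[g]]]))
    stats::setNames(out, labels[gens])
  })
  for (g in names(ensembles))
    write_designs(ensembles[[g]],
                  file.path(out_dir, paste0("designs_", g, ".json")))

  theta_sets <- rbind(train, test)
  space <- log_uniform_space(model, centre = guess,
                             half_width = config$abc$prior_half_width)
  noise <- noise_spec(config$noise$type, config$noise$rel_sd,
                      config$noise$sd_floor)
  logit("stage evaluate: ABC-FAR N=%d x %d iterations, %d parameter set(s)",
        config$abc$n, config$abc$iterations, nrow(theta_sets))
  cmp <- stage("evaluate", compare_ensembles(
    ensembles, model, theta_sets, space, noise, far = config$abc$far,
    n = config$abc$n, iterations = config$abc$iterations,
    strategy = config$abc$strategy, seed = derive_seed(seed, 10),
    horizon = horizon))
  n_sims <- sum(vapply(unlist(cmp$evaluations, recursive = FALSE),
                       function(ev) ev$settings$n * ev$settings$iterations *
                         length(ev$errors), numeric(1)))
  logit("evaluation cost: %d model simulations", n_sims)

  jsonlite::write_json(list(
    mean_errors = cmp$mean_errors, pooled_mean = as.list(cmp$pooled_mean),
    accuracy_ratios = as.list(cmp$accuracy_ratios),
    entropy = as.list(cmp$entropy), reference = cmp$reference,
    n_simulations = n_sims,
    elbow = profile$elbow), file.path(out_dir, "comparison.json"),
    auto_unbox = TRUE, digits = NA)
  writeLines(format_comparison(cmp), file.path(out_dir, "comparison.md"))
  writeLines(log_lines, file.path(out_dir, "pipeline.log"))

  manifest <- write_manifest(out_dir)
  invisible(list(psi = psi, profile = profile, ensembles = ensembles,
                 comparison = cmp, manifest = manifest))
}

# manifest of every artifact with a content hash; reruns with an unchanged
# config must reproduce the hashes
write_manifest <- function(out_dir) {
  # the log carries wall-clock timestamps; everything else must hash
  # identically across reruns of an unchanged config
  files <- setdiff(list.files(out_dir), c("manifest.json", "pipeline.log"))
  manifest <- lapply(files, function(f)
    list(file = f,
         sha256 = digest::digest(file.path(out_dir, f), algo = "sha256",
                                 file = TRUE)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  manifest
}
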