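#' Minimal SBML Level 3 model import
#'
#' Reads an SBML document and builds an [ode_model()] mapping species to
#' states and global parameters to model parameters. Kinetics may come from
#' rate rules (one per species) or from reactions with kinetic laws and
#' integer stoichiometry. Only the core MathML subset is understood:
#' `ci`, `cn`, `plus`, `minus`, `times`, `divide`, `power`. Events,
#' function definitions, local reaction parameters, assignment rules and
#' non-unit compartments are not supported and raise an error.
#'
#' @param path path to an SBML XML file.
#' @param free_parameters optional character vector; defaults to all.
#' @return an `ode_model` whose rhs is an R function (slow integration
#'   path).
#' @export
read_sbml_model <- function(path, free_parameters = NULL) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  mdl <- xml2::xml_find_first(doc, ".//model")
  if (inherits(mdl, "xml_missing")) stop("no <model> element found")
  for (bad in c(".//listOfEvents/*", ".//listOfFunctionDefinitions/*",
                ".//listOfLocalParameters/*", ".//assignmentRule"))
    if (length(xml2::xml_find_all(doc, bad)))
      stop("unsupported SBML construct: ", bad)

  sp <- xml2::xml_find_all(mdl, ".//listOfSpecies/species")
  state_names <- xml2::xml_attr(sp, "id")
  init <- as.numeric(ifelse(is.na(xml2::xml_attr(sp, "initialConcentration")),
                            xml2::xml_attr(sp, "initialAmount"),
                            xml2::xml_attr(sp, "initialConcentration")))
  init[is.na(init)] <- 0

  pr <- xml2::xml_find_all(mdl, ".//listOfParameters/parameter")
  par_names <- xml2::xml_attr(pr, "id")
  par_vals <- as.numeric(xml2::xml_attr(pr, "value"))
  if (!length(par_names)) stop("model declares no parameters")

  derivs <- vector("list", length(state_names))
  names(derivs) <- state_names
  for (i in seq_along(derivs)) derivs[[i]] <- quote(0)

  rules <- xml2::xml_find_all(mdl, ".//listOfRules/rateRule")
  for (r in rules) {
    var <- xml2::xml_attr(r, "variable")
    if (!var %in% state_names) stop("rate rule for unknown species: ", var)
    derivs[[var]] <- mathml_to_expr(xml2::xml_find_first(r, ".//math/*"))
  }

  rxns <- xml2::xml_find_all(mdl, ".//listOfReactions/reaction")
  for (rx in rxns) {
    law <- xml2::xml_find_first(rx, ".//kineticLaw/math/*")
    if (inherits(law, "xml_missing"))
      stop("reaction without kinetic law: ", xml2::xml_attr(rx, "id"))
    rate <- mathml_to_expr(law)
    add_term <- function(refs, sign) {
      for (ref in refs) {
        sid <- xml2::xml_attr(ref, "species")
        st <- xml2::xml_attr(ref, "stoichiometry")
        st <- if (is.na(st)) 1 else as.numeric(st)
        if (!sid %in% state_names) next # boundary species
        term <- if (st == 1) rate else call("*", st, rate)
        derivs[[sid]] <<- call(sign, derivs[[sid]], term)
      }
    }
    add_term(xml2::xml_find_all(rx, ".//listOfReactants/speciesReference"), "-")
    add_term(xml2::xml_find_all(rx, ".//listOfProducts/speciesReference"), "+")
  }

  body <- as.call(c(quote(c), derivs))
  rhs <- function(t, y, theta) {
    env <- c(as.list(stats::setNames(y, state_names)),
             as.list(stats::setNames(theta, par_names)), list(t = t))
    unname(eval(body, env))
  }
  if (is.null(free_parameters)) free_parameters <- par_names
  ode_model(name = xml2::xml_attr(mdl, "id"),
            state_names = state_names, parameter_names = par_names,
            rhs = rhs, default_parameters = par_vals,
            default_initial_state = init,
            free_parameters = free_parameters)
}

# recursive MathML -> R call translation (core subset)
mathml_to_expr <- function(node) {
  name <- xml2::xml_name(node)
  if (name == "ci") return(as.name(trimws(xml2::xml_text(node))))
  if (name == "cn") return(as.numeric(trimws(xml2::xml_text(node))))
  if (name != "apply") stop("unsupported MathML node: ", name)
  kids <- xml2::xml_children(node)
  op <- xml2::xml_name(kids[[1]])
  args <- lapply(kids[-1], mathml_to_expr)
  fn <- switch(op, plus = "+", minus = "-", times = "*", divide = "/",
               power = "^",
               stop("unsupported MathML operator: ", op))
  if (length(args) == 1 && op == "minus") return(call("-", args[[1]]))
  Reduce(function(a, b) call(fn, a, b), args)
}
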