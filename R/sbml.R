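#' Export a translation model as SBML Level 3
#'
#' Writes the model as an SBML Level 3 Version 2 core document with
#' explicit mass-action kinetic laws (MathML products of a rate parameter
#' and the reactant species). Amounts are written at full precision so a
#' round trip through [import_sbml()] reproduces the parameter record
#' exactly.
#'
#' @param p A `linear_params` or `nonlinear_params` object.
#' @param init Initial state (defaults to all pools free).
#' @param path Output file path (`.xml`).
#' @return Invisibly, `path`.
#' @examples
#' f <- tempfile(fileext = ".xml")
#' export_sbml(nonlinear_params(2, 2, 5, 1), path = f)
#' p2 <- import_sbml(f)$params
#' @export
export_sbml <- function(p, init = initial_state(p), path) {
  model <- sbml_model_spec(p)
  num <- function(x) sprintf("%.17g", x)
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version2/core",
    level = "3", version = "2")
  mdl <- xml2::xml_add_child(doc, "model", id = model$id,
                             name = model$name)
  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  xml2::xml_add_child(lc, "compartment", id = "cytoplasm", size = "1",
                      constant = "true")
  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (s in model$species) {
    xml2::xml_add_child(ls, "species", id = s, compartment = "cytoplasm",
                        initialAmount = num(init[[s]]),
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  }
  lp <- xml2::xml_add_child(mdl, "listOfParameters")
  for (nm in model$rates) {
    xml2::xml_add_child(lp, "parameter", id = nm, value = num(p[[nm]]),
                        constant = "true")
  }
  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (i in seq_along(model$reactions)) {
    rx <- model$reactions[[i]]
    rn <- xml2::xml_add_child(lr, "reaction", id = names(model$reactions)[i],
                              reversible = "false")
    lre <- xml2::xml_add_child(rn, "listOfReactants")
    for (s in rx$reactants)
      xml2::xml_add_child(lre, "speciesReference", species = s,
                          stoichiometry = "1", constant = "true")
    lpr <- xml2::xml_add_child(rn, "listOfProducts")
    for (s in rx$products)
      xml2::xml_add_child(lpr, "speciesReference", species = s,
                          stoichiometry = "1", constant = "true")
    kl <- xml2::xml_add_child(rn, "kineticLaw")
    math <- xml2::xml_add_child(
      kl, "math", xmlns = "http://www.w3.org/1998/Math/MathML")
    ap <- xml2::xml_add_child(math, "apply")
    xml2::xml_add_child(ap, "times")
    xml2::xml_add_child(ap, "ci", rx$rate)
    for (s in rx$reactants) xml2::xml_add_child(ap, "ci", s)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

sbml_model_spec <- function(p) {
  if (inherits(p, "linear_params")) {
    list(id = "linear_translation_cycle",
         name = "Linear protein translation cycle",
         species = linear_species,
         rates = c("k1", "k2", "k3"),
         totals = c(total_40S = "c40S"),
         reactions = list(
           R1 = list(rate = "k1", reactants = "c40S",
                     products = "c_mRNA40S"),
           R2 = list(rate = "k2", reactants = "c_mRNA40S",
                     products = "cAUG"),
           R3 = list(rate = "k3", reactants = "cAUG", products = "c40S")))
  } else if (inherits(p, "nonlinear_params")) {
    list(id = "nonlinear_translation_model",
         name = "Non-linear protein translation model with recycling",
         species = nonlinear_species,
         rates = c("k1", "k2", "k3", "k4"),
         reactions = list(
           R1 = list(rate = "k1", reactants = c("c40S", "c_eIF4F"),
                     products = "c_mRNA40S"),
           R2 = list(rate = "k2", reactants = "c_mRNA40S",
                     products = c("cAUG", "c_eIF4F")),
           R3 = list(rate = "k3", reactants = c("cAUG", "c60S"),
                     products = "c80S"),
           R4 = list(rate = "k4", reactants = "c80S",
                     products = c("c40S", "c60S"))))
  } else stop("unsupported model object")
}

#' @rdname export_sbml
#' @return For `import_sbml()`: list with `params` and `init`.
#' @export
import_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "s")
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(mdl, "xml_missing")) stop("not an SBML document: no model")
  sp_nodes <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns)
  sp <- stats::setNames(
    as.numeric(xml2::xml_attr(sp_nodes, "initialAmount")),
    xml2::xml_attr(sp_nodes, "id"))
  par_nodes <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter",
                                  ns)
  pars <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                          xml2::xml_attr(par_nodes, "id"))
  model_id <- xml2::xml_attr(mdl, "id")
  # verify mass-action structure: each kineticLaw must be a product of the
  # rate parameter and the reactant species
  rx_nodes <- xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns)
  for (rx in rx_nodes) {
    cis <- xml2::xml_text(xml2::xml_find_all(
      rx, ".//s:kineticLaw//*[local-name()='ci']", ns))
    reactants <- xml2::xml_attr(xml2::xml_find_all(
      rx, ".//s:listOfReactants/s:speciesReference", ns), "species")
    expected <- sort(c(intersect(cis, names(pars)), reactants))
    if (!length(intersect(cis, names(pars))) ||
        !setequal(sort(trimws(cis)), expected))
      stop("unsupported model: reaction ", xml2::xml_attr(rx, "id"),
           " does not have a plain mass-action kinetic law")
  }
  if (identical(model_id, "linear_translation_cycle")) {
    if (!setequal(names(sp), linear_species))
      stop("unsupported model: unknown species in linear model")
    params <- linear_params(pars[["k1"]], pars[["k2"]], pars[["k3"]],
                            total_40S = sum(sp[linear_species]))
    init <- sp[linear_species]
  } else if (identical(model_id, "nonlinear_translation_model")) {
    if (!setequal(names(sp), nonlinear_species))
      stop("unsupported model: unknown species in non-linear model")
    init <- sp[nonlinear_species]
    params <- nonlinear_params(
      pars[["k1"]], pars[["k2"]], pars[["k3"]], pars[["k4"]],
      total_40S = unname(init["c40S"] + init["c_mRNA40S"] + init["cAUG"] +
                           init["c80S"]),
      total_60S = unname(init["c60S"] + init["c80S"]),
      total_eIF4F = unname(init["c_eIF4F"] + init["c_mRNA40S"]))
  } else {
    stop("unsupported model: unknown SBML model id '", model_id, "'")
  }
  list(params = params, init = init)
}
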