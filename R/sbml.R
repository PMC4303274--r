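SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"

#' Export a reaction network as an SBML Level 3 document
#'
#' Serialises a [build_network()] result to SBML Level 3 (version 1,
#' core). Species identifiers are the stable ids of the species
#' enumeration (e.g. `CaM_RT_A1B0C1D0_tWFF`); free calcium is exported as
#' a boundary species (clamped), and every reaction is reversible with a
#' mass-action kinetic law `kf * reactants - kr * products` whose rate
#' ratio equals the reaction's equilibrium constant.
#'
#' @param network A [build_network()] result.
#' @param path Output file path (`.xml`).
#' @param model_id Model identifier written to the document.
#' @return `path`, invisibly.
#' @export
export_sbml <- function(network, path, model_id = "hemiconcerted_cam") {
  stopifnot(inherits(network, "cam_network"))
  doc <- xml2::xml_new_root("sbml", xmlns = SBML_NS,
                            level = "3", version = "1")
  model <- xml2::xml_add_child(doc, "model", id = model_id)
  comps <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "cell",
                      spatialDimensions = "3", size = "1", constant = "true")
  tnames <- vapply(network$targets, function(t) t$name, "")
  los <- xml2::xml_add_child(model, "listOfSpecies")
  add_species <- function(id, boundary) {
    xml2::xml_add_child(los, "species", id = id, compartment = "cell",
                        initialConcentration = "0",
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = if (boundary) "true" else "false",
                        constant = "false")
  }
  for (id in network$species$id) add_species(id, FALSE)
  add_species("Ca", TRUE)
  for (nm in tnames) add_species(nm, FALSE)
  lor <- xml2::xml_add_child(model, "listOfReactions")
  re <- network$reactions
  for (i in seq_len(nrow(re))) {
    rx <- xml2::xml_add_child(lor, "reaction", id = re$id[i],
                              reversible = "true", fast = "false")
    reactants <- c(re$reactant[i],
                   if (!is.na(re$ligand[i])) re$ligand[i])
    lre <- xml2::xml_add_child(rx, "listOfReactants")
    for (s in reactants)
      xml2::xml_add_child(lre, "speciesReference", species = s,
                          stoichiometry = "1", constant = "true")
    lpr <- xml2::xml_add_child(rx, "listOfProducts")
    xml2::xml_add_child(lpr, "speciesReference", species = re$product[i],
                        stoichiometry = "1", constant = "true")
    kl <- xml2::xml_add_child(rx, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math", xmlns = MATHML_NS)
    top <- xml2::xml_add_child(math, "apply")
    xml2::xml_add_child(top, "minus")
    fwd <- xml2::xml_add_child(top, "apply")
    xml2::xml_add_child(fwd, "times")
    xml2::xml_add_child(fwd, "ci", "kf")
    for (s in reactants) xml2::xml_add_child(fwd, "ci", s)
    bwd <- xml2::xml_add_child(top, "apply")
    xml2::xml_add_child(bwd, "times")
    xml2::xml_add_child(bwd, "ci", "kr")
    xml2::xml_add_child(bwd, "ci", re$product[i])
    lp <- xml2::xml_add_child(kl, "listOfLocalParameters")
    xml2::xml_add_child(lp, "localParameter", id = "kf",
                        value = format(re$kf[i], digits = 17))
    xml2::xml_add_child(lp, "localParameter", id = "kr",
                        value = format(re$kr[i], digits = 17))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read an SBML document written by [export_sbml()]
#'
#' Parses species and reactions (with their local `kf`/`kr` parameters)
#' back into tabular form; the equilibrium constant of each reaction is
#' recovered as `kf / kr`.
#'
#' @param path SBML file path.
#' @return A list with `species` (tibble: `id`, `boundary`) and
#'   `reactions` (tibble: `id`, `reactant`, `ligand`, `product`, `kf`,
#'   `kr`, `Keq`).
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  spn <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  species <- tibble::tibble(
    id = xml2::xml_attr(spn, "id"),
    boundary = xml2::xml_attr(spn, "boundaryCondition") == "true")
  rxn <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  reactions <- purrr::map_dfr(rxn, function(r) {
    reacts <- xml2::xml_attr(
      xml2::xml_find_all(r, "./listOfReactants/speciesReference"), "species")
    prods <- xml2::xml_attr(
      xml2::xml_find_all(r, "./listOfProducts/speciesReference"), "species")
    lp <- xml2::xml_find_all(r, "./kineticLaw/listOfLocalParameters/localParameter")
    pv <- stats::setNames(as.numeric(xml2::xml_attr(lp, "value")),
                          xml2::xml_attr(lp, "id"))
    ## the protein reactant is the non-boundary, non-target one; by the
    ## writer's convention it is listed first, any ligand second
    tibble::tibble(id = xml2::xml_attr(r, "id"),
                   reactant = reacts[1],
                   ligand = if (length(reacts) > 1) reacts[2] else NA_character_,
                   product = prods[1],
                   kf = pv[["kf"]], kr = pv[["kr"]],
                   Keq = pv[["kf"]] / pv[["kr"]])
  })
  list(species = species, reactions = reactions)
}

#' Structural validation of an SBML document
#'
#' Checks the structural well-formedness this package relies on: a Level 3
#' root in the SBML namespace, a model with compartments, unique species
#' identifiers, every species reference resolving to a declared species,
#' and a kinetic law with `kf` and `kr` local parameters on every
#' reaction.
#'
#' @param path SBML file path.
#' @return `TRUE` invisibly; stops with a message on the first violation.
#' @export
validate_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  if (!SBML_NS %in% unlist(xml2::xml_ns(doc)))
    stop("document is not in the SBML Level 3 core namespace")
  if (xml2::xml_name(doc) != "sbml")
    stop("root element is not <sbml>")
  if (!identical(xml2::xml_attr(doc, "level"), "3"))
    stop("not an SBML Level 3 document")
  xml2::xml_ns_strip(doc)
  ids <- xml2::xml_attr(xml2::xml_find_all(doc, ".//listOfSpecies/species"), "id")
  if (length(ids) == 0) stop("document declares no species")
  if (anyDuplicated(ids)) stop("duplicate species ids")
  refs <- xml2::xml_attr(xml2::xml_find_all(doc, ".//speciesReference"), "species")
  bad <- setdiff(refs, ids)
  if (length(bad)) stop("unresolved species references: ",
                        paste(utils::head(bad, 5), collapse = ", "))
  for (r in xml2::xml_find_all(doc, ".//listOfReactions/reaction")) {
    lp <- xml2::xml_attr(xml2::xml_find_all(
      r, "./kineticLaw/listOfLocalParameters/localParameter"), "id")
    if (!all(c("kf", "kr") %in% lp))
      stop("reaction ", xml2::xml_attr(r, "id"), " lacks kf/kr parameters")
  }
  invisible(TRUE)
}

#' Stoichiometry matrix from a parsed SBML document
#'
#' @param parsed Result of [read_sbml()].
#' @return Integer matrix (species x reactions).
#' @export
sbml_stoichiometry_matrix <- function(parsed) {
  rows <- parsed$species$id
  re <- parsed$reactions
  S <- matrix(0L, length(rows), nrow(re), dimnames = list(rows, re$id))
  for (i in seq_len(nrow(re))) {
    S[re$reactant[i], i] <- S[re$reactant[i], i] - 1L
    if (!is.na(re$ligand[i])) S[re$ligand[i], i] <- S[re$ligand[i], i] - 1L
    S[re$product[i], i] <- S[re$product[i], i] + 1L
  }
  S
}
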