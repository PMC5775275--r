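#' Read a reaction network from JSON
#'
#' Expects the schema
#' `{"places": [{"name", "initial", "clamped"}], "reactions": [{"name",
#' "substrates": {...}, "products": {...}, "rate_constant"}]}`.
#' Structural problems (missing fields, dangling species, negative
#' initials) are reported as errors.
#'
#' @param path Path to a JSON file.
#' @return A validated `reaction_network`.
#' @export
read_network_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (field in c("places", "reactions"))
    if (is.null(x[[field]]))
      stop("network JSON lacks required field '", field, "'", call. = FALSE)
  places <- lapply(x$places, function(p) {
    if (is.null(p$name) || is.null(p$initial))
      stop("every place needs 'name' and 'initial'", call. = FALSE)
    place(p$name, p$initial, isTRUE(p$clamped))
  })
  reactions <- lapply(x$reactions, function(r) {
    if (is.null(r$name) || is.null(r$substrates) || is.null(r$rate_constant))
      stop("every reaction needs 'name', 'substrates' and 'rate_constant'",
           call. = FALSE)
    reaction(r$name, unlist(r$substrates),
             if (length(r$products)) unlist(r$products) else numeric(),
             r$rate_constant)
  })
  reaction_network(places, reactions)
}

#' Write a reaction network to JSON
#'
#' Inverse of [read_network_json()]; round-trips exactly.
#'
#' @param net A `reaction_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(net, path) {
  x <- list(
    places = lapply(net$places, function(p)
      list(name = p$name, initial = p$initial, clamped = p$clamped)),
    reactions = lapply(net$reactions, function(r)
      list(name = r$name,
           substrates = as.list(r$substrates),
           products = as.list(r$products),
           rate_constant = r$rate_constant)))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Export a network as SBML Level 3 (mass-action kinetic laws)
#'
#' Export-only convenience for interoperability with SBML-aware
#' simulators: clamped places map to `boundaryCondition="true"` species
#' and each reaction carries an explicit mass-action `kineticLaw`.
#' Requires the `xml2` package.
#'
#' @param net A `reaction_network`.
#' @param params Named rate constants.
#' @param path Output file path (`.xml`).
#' @param model_id SBML model id.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(net, params, path, model_id = "reaction_network") {
  if (!requireNamespace("xml2", quietly = TRUE))
    stop("SBML export requires the 'xml2' package", call. = FALSE)
  params <- unlist(params)
  doc <- xml2::xml_new_root(
    "sbml", xmlns = "http://www.sbml.org/sbml/level3/version2/core",
    level = "3", version = "2")
  mdl <- xml2::xml_add_child(doc, "model", id = model_id)
  cmps <- xml2::xml_add_child(mdl, "listOfCompartments")
  xml2::xml_add_child(cmps, "compartment", id = "cell", constant = "true",
                      size = "1")
  sps <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (p in net$places)
    xml2::xml_add_child(sps, "species", id = p$name, compartment = "cell",
                        initialConcentration = format(p$initial),
                        boundaryCondition = tolower(as.character(p$clamped)),
                        hasOnlySubstanceUnits = "false", constant = "false")
  prs <- xml2::xml_add_child(mdl, "listOfParameters")
  for (k in unique(vapply(net$reactions, `[[`, character(1), "rate_constant")))
    xml2::xml_add_child(prs, "parameter", id = k, value = format(params[[k]]),
                        constant = "true")
  rxs <- xml2::xml_add_child(mdl, "listOfReactions")
  for (r in net$reactions) {
    rx <- xml2::xml_add_child(rxs, "reaction", id = r$name,
                              reversible = "false")
    lor <- xml2::xml_add_child(rx, "listOfReactants")
    for (s in names(r$substrates))
      xml2::xml_add_child(lor, "speciesReference", species = s,
                          stoichiometry = format(r$substrates[[s]]),
                          constant = "true")
    if (length(r$products)) {
      lop <- xml2::xml_add_child(rx, "listOfProducts")
      for (s in names(r$products))
        xml2::xml_add_child(lop, "speciesReference", species = s,
                            stoichiometry = format(r$products[[s]]),
                            constant = "true")
    }
    kl <- xml2::xml_add_child(rx, "kineticLaw")
    math <- xml2::xml_add_child(
      kl, "math", xmlns = "http://www.w3.org/1998/Math/MathML")
    ap <- xml2::xml_add_child(math, "apply")
    xml2::xml_add_child(ap, "times")
    xml2::xml_add_child(ap, "ci", r$rate_constant)
    for (s in names(r$substrates))
      for (i in seq_len(r$substrates[[s]]))
        xml2::xml_add_child(ap, "ci", s)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
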