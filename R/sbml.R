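# Optional SBML Level 3 export (requires the suggested package xml2).
# One SBML reaction per network reaction; the kinetic law is emitted as
# MathML built from the same flux expressions the simulator evaluates.

# infix math -> MathML (numbers, species ids, + - * /), minimal recursive
# descent over a pre-tokenised expression tree built below
mathml_apply <- function(op, args) {
  paste0("<apply><", op, "/>", paste0(args, collapse = ""), "</apply>")
}
mathml_ci <- function(x) paste0("<ci> ", x, " </ci>")
mathml_cn <- function(x) paste0("<cn> ", format(x, digits = 17), " </cn>")

law_mathml <- function(r) {
  prod_side <- function(side, kname) {
    terms <- c(mathml_cn(r$law$params[[kname]]),
               unlist(lapply(names(side), function(sp) {
                 if (side[[sp]] == 1) mathml_ci(sp)
                 else mathml_apply("power", c(mathml_ci(sp), mathml_cn(side[[sp]])))
               })))
    if (length(terms) == 1L) terms else mathml_apply("times", terms)
  }
  mm_core <- function() {
    S <- mathml_ci(names(r$reactants))
    mathml_apply("divide", c(
      mathml_apply("times", c(mathml_cn(r$law$params$kcat), mathml_ci(r$enzyme), S)),
      mathml_apply("plus", c(mathml_cn(r$law$params$Km), S))))
  }
  body <- switch(r$law$kind,
    mass_action_irreversible = prod_side(r$reactants, "k"),
    mass_action_reversible = mathml_apply("minus", c(
      prod_side(r$reactants, "kon"), prod_side(r$products, "koff"))),
    michaelis_menten = mm_core(),
    michaelis_menten_activated = {
      A <- mathml_ci(r$activator)
      boost <- mathml_apply("plus", c(
        mathml_cn(1),
        mathml_apply("times", c(
          mathml_cn(r$law$params$act_factor - 1),
          mathml_apply("divide", c(
            A, mathml_apply("plus", c(A, mathml_cn(r$law$params$act_Km)))))))))
      mathml_apply("times", c(mm_core(), boost))
    })
  paste0('<math xmlns="http://www.w3.org/1998/Math/MathML">', body, "</math>")
}

#' Export a reaction network as SBML Level 3
#'
#' Species are exported with molar initial concentrations in a single unit
#' compartment; each reaction carries its kinetic law as MathML (the same
#' flux expression the simulator integrates).  Enzymes and activators are
#' declared as modifier species.
#'
#' @param network a validated `txasim_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_sbml <- function(network, path) {
  if (!requireNamespace("xml2", quietly = TRUE)) {
    stop("SBML export requires the 'xml2' package", call. = FALSE)
  }
  stop_if_invalid(network)
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))
  sp_xml <- vapply(network$species, function(s) {
    sprintf(paste0('<species id="%s" compartment="plasma" ',
                   'initialConcentration="%s" hasOnlySubstanceUnits="false" ',
                   'boundaryCondition="false" constant="false"/>'),
            s$name, format(s$initial_concentration, digits = 17))
  }, character(1))
  rx_xml <- vapply(network$reactions, function(r) {
    side <- function(side, tag) {
      if (length(side) == 0L) return("")
      refs <- vapply(names(side), function(sp) {
        sprintf('<speciesReference species="%s" stoichiometry="%g" constant="true"/>',
                sp, side[[sp]]) }, character(1))
      sprintf("<%s>%s</%s>", tag, paste0(refs, collapse = ""), tag)
    }
    mods <- c(r$enzyme, r$activator)
    mod_xml <- if (length(mods)) {
      sprintf("<listOfModifiers>%s</listOfModifiers>",
              paste0(sprintf('<modifierSpeciesReference species="%s"/>', mods),
                     collapse = ""))
    } else ""
    rev <- identical(r$law$kind, "mass_action_reversible")
    paste0(sprintf('<reaction id="%s" reversible="%s">', r$id,
                   if (rev) "true" else "false"),
           if (nzchar(r$note)) sprintf("<notes><body xmlns=\"http://www.w3.org/1999/xhtml\"><p>%s</p></body></notes>", esc(r$note)) else "",
           side(r$reactants, "listOfReactants"),
           side(r$products, "listOfProducts"),
           mod_xml,
           "<kineticLaw>", law_mathml(r), "</kineticLaw>",
           "</reaction>")
  }, character(1))
  doc_str <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">',
    sprintf('<model id="%s" name="%s">',
            gsub("[^A-Za-z0-9_]", "_", network$metadata$name),
            esc(network$metadata$name)),
    '<listOfCompartments><compartment id="plasma" spatialDimensions="3" size="1" constant="true"/></listOfCompartments>',
    "<listOfSpecies>", paste0(sp_xml, collapse = ""), "</listOfSpecies>",
    "<listOfReactions>", paste0(rx_xml, collapse = ""), "</listOfReactions>",
    "</model></sbml>")
  doc <- xml2::read_xml(doc_str)  # validates well-formedness
  xml2::write_xml(doc, path)
  invisible(path)
}
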