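# Model-file I/O.  A network is a single JSON document:
#
#   { "schema": "txasim-model/1",
#     "name": ..., "version": ..., "provenance": ...,
#     "species":   [ {name, initial_concentration, unit, tags}, ... ],
#     "reactions": [ {id, reactants: [{species, stoich}], products: [...],
#                     enzyme?, activator?, law: {kind, params}, note}, ... ] }
#
# Concentrations in the file are expressed in each record's `unit`; internal
# state is always molar.  A machine-readable schema ships in
# inst/extdata/model_schema.json.

#' Load a reaction network from a JSON model file
#'
#' @param path path to a model JSON file.
#' @return a validated `txasim_network` with all concentrations in molar.
#' @seealso [write_network()], [default_model()]
#' @export
load_network <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (field in c("species", "reactions")) {
    if (is.null(doc[[field]])) {
      stop("model file '", path, "' lacks required '", field, "' array",
           call. = FALSE)
    }
  }
  parse_species <- function(rec, i) {
    for (field in c("name", "initial_concentration")) {
      if (is.null(rec[[field]])) {
        stop(sprintf("species record %d is missing field '%s'", i, field),
             call. = FALSE)
      }
    }
    species(rec$name, rec$initial_concentration,
            unit = if (is.null(rec$unit)) "M" else rec$unit,
            tags = unlist(rec$tags))
  }
  parse_side <- function(side, id) {
    if (is.null(side) || length(side) == 0L) return(numeric(0))
    nm <- vapply(side, function(e) {
      if (is.null(e$species)) {
        stop("reaction '", id, "': reactant/product entry lacks 'species'",
             call. = FALSE)
      }
      e$species
    }, character(1))
    st <- vapply(side, function(e) if (is.null(e$stoich)) 1 else as.numeric(e$stoich),
                 numeric(1))
    stats::setNames(st, nm)
  }
  parse_reaction <- function(rec, i) {
    if (is.null(rec$id)) stop(sprintf("reaction record %d lacks 'id'", i), call. = FALSE)
    if (is.null(rec$law) || is.null(rec$law$kind)) {
      stop("reaction '", rec$id, "' lacks a kinetic law kind", call. = FALSE)
    }
    reaction(rec$id,
             reactants = parse_side(rec$reactants, rec$id),
             products = parse_side(rec$products, rec$id),
             law = kinetic_law(rec$law$kind, lapply(rec$law$params, as.numeric)),
             enzyme = rec$enzyme,
             activator = rec$activator,
             note = if (is.null(rec$note)) "" else rec$note)
  }
  sp <- mapply(parse_species, doc$species, seq_along(doc$species),
               SIMPLIFY = FALSE)
  rx <- mapply(parse_reaction, doc$reactions, seq_along(doc$reactions),
               SIMPLIFY = FALSE)
  net <- reaction_network(sp, rx,
                          name = if (is.null(doc$name)) "unnamed" else doc$name,
                          version = if (is.null(doc$version)) "0" else doc$version,
                          provenance = if (is.null(doc$provenance)) "" else doc$provenance)
  stop_if_invalid(net)
  net
}

#' Write a reaction network to a JSON model file
#'
#' Concentrations are written in each species' display unit when the
#' unit conversion round-trips exactly in double precision; otherwise that
#' species is written in molar, so `load_network(write_network(x))` always
#' reproduces the internal state bit-for-bit.
#'
#' @param network a `txasim_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  sp_rec <- lapply(network$species, function(s) {
    u <- s$display_unit
    val <- from_molar(s$initial_concentration, u)
    if (to_molar(val, u) != s$initial_concentration) {
      u <- "M"
      val <- s$initial_concentration
    }
    list(name = s$name, initial_concentration = val, unit = u,
         tags = as.list(s$tags))
  })
  side_rec <- function(side) {
    lapply(names(side), function(nm) list(species = nm, stoich = side[[nm]]))
  }
  rx_rec <- lapply(network$reactions, function(r) {
    rec <- list(id = r$id,
                reactants = side_rec(r$reactants),
                products = side_rec(r$products))
    if (!is.null(r$enzyme)) rec$enzyme <- r$enzyme
    if (!is.null(r$activator)) rec$activator <- r$activator
    rec$law <- list(kind = r$law$kind, params = r$law$params)
    rec$note <- r$note
    rec
  })
  doc <- list(schema = "txasim-model/1",
              name = network$metadata$name,
              version = network$metadata$version,
              provenance = network$metadata$provenance,
              species = sp_rec,
              reactions = rx_rec)
  # digits = I(17): 17 significant digits round-trip doubles bit-exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}
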