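#' @useDynLib txasim, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# ---------------------------------------------------------------------------
# Reaction-network data model.
#
# A network is an ordered set of species (each with an initial concentration,
# stored internally in molar) and an ordered set of reactions, each carrying a
# kinetic law.  Four law kinds are supported:
#
#   mass_action_irreversible   params: k
#   mass_action_reversible     params: kon, koff
#   michaelis_menten           params: kcat, Km           (+ enzyme species)
#   michaelis_menten_activated params: kcat, Km, act_factor, act_Km
#                              (+ enzyme and activator species)
#
# The "activated" variant scales the Michaelis-Menten rate by
# 1 + (act_factor - 1) * [A]/([A] + act_Km), a saturating cofactor term used
# for the fibrin-templating of tPA.
# ---------------------------------------------------------------------------

.law_kinds <- c("mass_action_irreversible", "mass_action_reversible",
                "michaelis_menten", "michaelis_menten_activated")

.law_params <- list(
  mass_action_irreversible   = "k",
  mass_action_reversible     = c("kon", "koff"),
  michaelis_menten           = c("kcat", "Km"),
  michaelis_menten_activated = c("kcat", "Km", "act_factor", "act_Km")
)

#' Construct a species record
#'
#' @param name unique identifier string.
#' @param initial_concentration initial concentration, in `unit`.
#' @param unit display unit; converted to molar internally.
#' @param tags character vector of role labels (e.g. `"zymogen"`,
#'   `"protease"`, `"inhibitor"`, `"complex"`, `"ligand"`).
#' @return a `txasim_species` list with the concentration in molar.
#' @export
species <- function(name, initial_concentration, unit = "M", tags = character()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  conc <- to_molar(as.numeric(initial_concentration), unit)
  structure(list(name = name,
                 initial_concentration = conc,
                 display_unit = if (identical(unit, "μM")) "uM" else unit,
                 tags = as.character(tags)),
            class = "txasim_species")
}

#' Construct a kinetic law
#'
#' @param law_kind one of the supported law kinds (see Details of
#'   [reaction()]).  (The formal is named `law_kind`, not `kind`, so that
#'   the rate parameter `k = ...` cannot partially match it.)
#' @param ... named numeric parameters; the set must match the kind exactly.
#' @return a `txasim_law` object.
#' @export
kinetic_law <- function(law_kind, ...) {
  params <- list(...)
  if (length(params) == 1L && is.list(params[[1L]]) && is.null(names(params))) {
    params <- params[[1L]]
  }
  structure(list(kind = law_kind, params = lapply(params, as.numeric)),
            class = "txasim_law")
}

#' Construct a reaction
#'
#' Reactants and products are given as named integer vectors of positive
#' stoichiometric coefficients, e.g. `c(A = 1, B = 1)`.  Michaelis-Menten
#' reactions name their enzyme separately (it is not consumed); the
#' `michaelis_menten_activated` kind additionally names an activator species
#' whose saturating concentration multiplies the catalytic rate.
#'
#' @param id unique reaction identifier.
#' @param reactants,products named numeric vectors of positive integer
#'   stoichiometries (empty vector allowed for source/sink reactions).
#' @param law a [kinetic_law()].
#' @param enzyme optional enzyme species name (Michaelis-Menten kinds only).
#' @param activator optional activator species name
#'   (`michaelis_menten_activated` only).
#' @param note free-text provenance for the rate constants.
#' @return a `txasim_reaction` object.
#' @export
reaction <- function(id, reactants, products, law, enzyme = NULL,
                     activator = NULL, note = "") {
  stopifnot(is.character(id), length(id) == 1L, inherits(law, "txasim_law"))
  as_stoich <- function(x) {
    if (is.null(x) || length(x) == 0L) return(stats::setNames(numeric(0), character(0)))
    stopifnot(!is.null(names(x)), all(nzchar(names(x))))
    stats::setNames(as.numeric(x), names(x))
  }
  structure(list(id = id,
                 reactants = as_stoich(reactants),
                 products = as_stoich(products),
                 enzyme = enzyme,
                 activator = activator,
                 law = law,
                 note = note),
            class = "txasim_reaction")
}

#' Assemble a reaction network
#'
#' @param species list of [species()] records.
#' @param reactions list of [reaction()] records.
#' @param name,version,provenance metadata strings.
#' @return a `txasim_network` object.  Call [validate_network()] to check the
#'   type invariants; construction itself does not stop on violations so that
#'   a validator can report all of them at once.
#' @export
reaction_network <- function(species, reactions, name = "unnamed",
                             version = "0", provenance = "") {
  structure(list(species = species,
                 reactions = reactions,
                 metadata = list(name = name, version = version,
                                 provenance = provenance)),
            class = "txasim_network")
}

#' @export
print.txasim_network <- function(x, ...) {
  cat(sprintf("<txasim_network> %s (v%s): %d species, %d reactions\n",
              x$metadata$name, x$metadata$version,
              length(x$species), length(x$reactions)))
  invisible(x)
}

#' Species names of a network
#' @param network a `txasim_network`.
#' @return character vector in network order.
#' @export
species_names <- function(network) {
  vapply(network$species, function(s) s$name, character(1))
}

#' Initial state vector of a network
#' @param network a `txasim_network`.
#' @param overrides named numeric vector/list of molar initial-concentration
#'   overrides.
#' @return named numeric vector (molar), in network species order.
#' @export
initial_state <- function(network, overrides = NULL) {
  y0 <- stats::setNames(
    vapply(network$species, function(s) s$initial_concentration, numeric(1)),
    species_names(network))
  if (length(overrides)) {
    overrides <- unlist(overrides)
    unknown <- setdiff(names(overrides), names(y0))
    if (length(unknown)) {
      stop("initial-condition override names unknown species: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    if (any(overrides < 0)) stop("negative initial concentration override", call. = FALSE)
    y0[names(overrides)] <- as.numeric(overrides)
  }
  y0
}

#' Validate a reaction network
#'
#' Checks every type invariant and returns all violations as data, not
#' exceptions: unique non-empty species names, non-negative initial
#' concentrations, known law kinds with exactly the right strictly-positive
#' parameter sets, positive-integer stoichiometry, referenced species
#' declared, and Michaelis-Menten reactions having exactly one substrate
#' (stoichiometry 1) and an enzyme.
#'
#' @param network a `txasim_network`.
#' @return data.frame with columns `scope` ("species"/"reaction"/"network"),
#'   `id` and `message`; zero rows iff the network is valid.
#' @export
validate_network <- function(network) {
  bad <- list()
  add <- function(scope, id, message) {
    bad[[length(bad) + 1L]] <<- data.frame(scope = scope, id = id,
                                           message = message)
  }
  nms <- species_names(network)
  if (anyDuplicated(nms)) {
    add("network", "species", paste0("duplicated species names: ",
        paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  }
  for (s in network$species) {
    if (!is.finite(s$initial_concentration) || s$initial_concentration < 0) {
      add("species", s$name, "initial_concentration must be finite and >= 0")
    }
    if (!s$display_unit %in% .valid_units) {
      add("species", s$name, paste0("unknown display_unit '", s$display_unit, "'"))
    }
  }
  rids <- vapply(network$reactions, function(r) r$id, character(1))
  if (anyDuplicated(rids)) {
    add("network", "reactions", paste0("duplicated reaction ids: ",
        paste(unique(rids[duplicated(rids)]), collapse = ", ")))
  }
  for (r in network$reactions) {
    lk <- r$law$kind
    if (!lk %in% .law_kinds) {
      add("reaction", r$id, paste0("unknown law kind '", lk, "'"))
      next
    }
    want <- .law_params[[lk]]
    have <- names(r$law$params)
    if (!setequal(want, have)) {
      add("reaction", r$id, sprintf(
        "law '%s' requires parameters {%s}, got {%s}",
        lk, paste(want, collapse = ","), paste(have, collapse = ",")))
    } else {
      vals <- unlist(r$law$params[want])
      if (any(!is.finite(vals) | vals <= 0)) {
        add("reaction", r$id, paste0("non-positive kinetic parameter: ",
            paste(want[!is.finite(vals) | vals <= 0], collapse = ",")))
      }
    }
    st <- c(r$reactants, r$products)
    if (length(st) && (any(st <= 0) || any(st != round(st)))) {
      add("reaction", r$id, "stoichiometric coefficients must be positive integers")
    }
    refs <- c(names(r$reactants), names(r$products), r$enzyme, r$activator)
    unknown <- setdiff(refs, nms)
    if (length(unknown)) {
      add("reaction", r$id, paste0("undeclared species referenced: ",
          paste(unknown, collapse = ", ")))
    }
    if (lk %in% c("michaelis_menten", "michaelis_menten_activated")) {
      if (is.null(r$enzyme)) {
        add("reaction", r$id, "michaelis_menten reaction requires an enzyme")
      }
      if (length(r$reactants) != 1L || any(r$reactants != 1)) {
        add("reaction", r$id,
            "michaelis_menten reaction must have exactly one substrate with stoichiometry 1")
      }
      if (lk == "michaelis_menten_activated" && is.null(r$activator)) {
        add("reaction", r$id, "michaelis_menten_activated reaction requires an activator")
      }
    } else if (!is.null(r$enzyme)) {
      add("reaction", r$id, "enzyme field only allowed for michaelis_menten kinds")
    }
  }
  if (length(bad) == 0L) {
    return(data.frame(scope = character(), id = character(),
                      message = character()))
  }
  do.call(rbind, bad)
}

stop_if_invalid <- function(network) {
  v <- validate_network(network)
  if (nrow(v) > 0L) {
    stop("invalid reaction network:\n",
         paste(sprintf("  [%s %s] %s", v$scope, v$id, v$message), collapse = "\n"),
         call. = FALSE)
  }
  invisible(network)
}

#' Net stoichiometric matrix
#'
#' @param network a `txasim_network`.
#' @return integer matrix, species x reactions; entry (i, j) is the net
#'   change of species i per unit (forward) flux of reaction j.  For
#'   reversible reactions the forward direction is reactants -> products.
#' @export
stoichiometric_matrix <- function(network) {
  nms <- species_names(network)
  S <- matrix(0, nrow = length(nms), ncol = length(network$reactions),
              dimnames = list(nms, vapply(network$reactions, `[[`, character(1), "id")))
  for (j in seq_along(network$reactions)) {
    r <- network$reactions[[j]]
    for (sp in names(r$reactants)) S[sp, j] <- S[sp, j] - r$reactants[[sp]]
    for (sp in names(r$products))  S[sp, j] <- S[sp, j] + r$products[[sp]]
  }
  S
}
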