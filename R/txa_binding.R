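# Two-binding-site model of the TXA-plasmin(ogen) interaction.
#
# Plasminogen carries two TXA sites.  The low-affinity x site (Kd = 600 uM)
# switches the zymogen into a conformation that uPA activates 3-fold faster.
# The high-affinity y site (Kd = 1.1 uM) is the lysine binding site through
# which plasmin(ogen) engages fibrin: with TXA on y, plasminogen cannot be
# activated by tPA (a fibrin-templated reaction) and plasmin cannot bind or
# degrade fibrin.  Site occupancies are modelled as thermodynamically
# independent, giving four zymogen variants (Pg, Pgx, Pgy, Pgxy) and two
# plasmin variants (Pn, Pny; the x site has no stated effect after
# activation and is dropped).  All binding steps are reversible mass action
# with koff = Kd * kon per site, so TXA is never consumed.

#' TXA binding parameters
#'
#' Defaults encode the published site affinities (x: 600 uM, y: 1.1 uM) and
#' the 3-fold uPA activation enhancement of x-occupied plasminogen.  The
#' association rates are not reported; the default
#' \eqn{k_{on} = 10^6\,M^{-1}s^{-1}} (typical small-molecule binding) makes
#' binding fast relative to the lysis timescale so that outcomes are
#' equilibrium-controlled: the test suite verifies that scaling both kon
#' values by 0.1x or 10x at fixed Kd leaves every lysis time essentially
#' unchanged.
#'
#' @param Kd_x,Kd_y site dissociation constants, molar.
#' @param kon_x,kon_y association rates, per molar per second.
#' @param upa_enhancement dimensionless multiplier (> 1) on uPA-mediated
#'   activation of x-occupied plasminogen.
#' @return a `txasim_txa_params` list (koff values derived exactly as
#'   `Kd * kon`).
#' @export
txa_binding_params <- function(Kd_x = 600e-6, Kd_y = 1.1e-6,
                               kon_x = 1e6, kon_y = 1e6,
                               upa_enhancement = 3) {
  stopifnot(Kd_x > 0, Kd_y > 0, kon_x > 0, kon_y > 0, upa_enhancement > 1)
  structure(list(Kd_x = Kd_x, Kd_y = Kd_y,
                 kon_x = kon_x, kon_y = kon_y,
                 koff_x = Kd_x * kon_x, koff_y = Kd_y * kon_y,
                 upa_enhancement = upa_enhancement),
            class = "txasim_txa_params")
}

#' Capability flags of the plasmin(ogen) variant set
#'
#' @return data.frame over the six tracked variants with logical columns
#'   `zymogen`, `tpa_activatable` (true iff zymogen with y free),
#'   `upa_activatable` (true for every zymogen variant) and `fibrin_binding`
#'   (true iff y free).
#' @export
plasminogen_species_set <- function() {
  data.frame(
    name = c("Pg", "Pgx", "Pgy", "Pgxy", "Pn", "Pny"),
    zymogen = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    x_bound = c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE),
    y_bound = c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE),
    tpa_activatable = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    upa_activatable = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    fibrin_binding = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
}

#' Generate the TXA binding/unbinding reactions
#'
#' Emits the five reversible mass-action binding steps
#' `Pg+TXA <-> Pgx`, `Pg+TXA <-> Pgy`, `Pgx+TXA <-> Pgxy`,
#' `Pgy+TXA <-> Pgxy` and `Pn+TXA <-> Pny`, with `koff = Kd * kon` for the
#' site involved and identical site affinity regardless of the other site's
#' occupancy (no cooperativity).
#'
#' @param params a [txa_binding_params()].
#' @return list of 5 reversible `txasim_reaction` records.
#' @export
expand_binding_reactions <- function(params) {
  stopifnot(inherits(params, "txasim_txa_params"))
  bind <- function(id, from, to, site) {
    kon <- if (site == "x") params$kon_x else params$kon_y
    koff <- if (site == "x") params$koff_x else params$koff_y
    reaction(id, stats::setNames(c(1, 1), c(from, "TXA")),
             stats::setNames(1, to),
             kinetic_law("mass_action_reversible", kon = kon, koff = koff),
             note = sprintf("TXA %s-site binding, Kd = %g M", site, koff / kon))
  }
  list(bind("txa_bind_Pg_x", "Pg", "Pgx", "x"),
       bind("txa_bind_Pg_y", "Pg", "Pgy", "y"),
       bind("txa_bind_Pgx_y", "Pgx", "Pgxy", "y"),
       bind("txa_bind_Pgy_x", "Pgy", "Pgxy", "x"),
       bind("txa_bind_Pn_y", "Pn", "Pny", "y"))
}

#' Single-site equilibrium occupancy
#'
#' @param Kd site dissociation constant, molar (> 0).
#' @param ligand free (clamped) ligand concentration, molar (>= 0).
#' @return occupied fraction `ligand / (ligand + Kd)` in \[0, 1\].
#' @export
equilibrium_occupancy <- function(Kd, ligand) {
  if (any(Kd <= 0)) stop("Kd must be > 0", call. = FALSE)
  if (any(ligand < 0)) stop("ligand concentration must be >= 0", call. = FALSE)
  ligand / (ligand + Kd)
}

#' Equilibrium partition of plasminogen over the four TXA-bound variants
#'
#' Independent-sites product form at a clamped free-TXA concentration:
#' the fraction with both sites occupied is `occ_x * occ_y`, with one site
#' `occ * (1 - occ_other)`, and so on; the four fractions sum to one.
#'
#' @param total_pg total plasminogen, molar.
#' @param txa_free free TXA concentration, molar (treated as clamped).
#' @param params a [txa_binding_params()].
#' @return named numeric vector of concentrations `(Pg, Pgx, Pgy, Pgxy)`.
#' @export
equilibrium_partition <- function(total_pg, txa_free,
                                  params = txa_binding_params()) {
  if (total_pg < 0 || txa_free < 0) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  ox <- equilibrium_occupancy(params$Kd_x, txa_free)
  oy <- equilibrium_occupancy(params$Kd_y, txa_free)
  c(Pg   = total_pg * (1 - ox) * (1 - oy),
    Pgx  = total_pg * ox * (1 - oy),
    Pgy  = total_pg * (1 - ox) * oy,
    Pgxy = total_pg * ox * oy)
}
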