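# Fibrinolysis sub-network: plasminogen activation by tPA (fibrin-cofactor
# dependent) and uPA (solution phase), plasmin-fibrin binding and
# degradation, and the inhibitor system.
#
# Inhibitor scopes follow the biology of the lysine-binding y site.  The
# fast irreversible inhibitor antiplasmin (AP) docks through that site, so
# it reaches only y-free plasmin (free or fibrin-bound): TXA on y is
# displaced indirectly, through the reversible binding equilibrium.  The
# slower, redundant inhibitors alpha2-macroglobulin (A2M, a bait-region
# protease trap) and alpha1-antitrypsin (A1AT) act independently of the
# lysine site: they capture free and TXA-bound plasmin (releasing the TXA)
# but cannot reach the fibrin-bound pool.  uPA is inactivated by protein C
# inhibitor (PCI); both activators are also subject to (low, quickly
# consumed) PAI-1.

#' Plasminogen-activation parameters
#'
#' tPA acts through Michaelis-Menten kinetics on the y-free zymogen variants
#' (Pg, Pgx) with its catalytic rate scaled by a saturating fibrin-cofactor
#' term `1 + (F - 1) * [Fn]/([Fn] + fibrin_Km)`; at saturating fibrin the
#' catalytic efficiency (kcat/Km) is exactly `F = fibrin_efficiency_factor`
#' times the fibrin-free value.  uPA acts in solution on all four zymogen
#' variants, `upa_enhancement`-fold faster on the x-occupied ones.
#'
#' Solution-phase tPA constants are of the magnitude measured for tPA on
#' native plasminogen; uPA constants are within the measured range for
#' two-chain uPA and, with the 500-fold fibrin factor, place the
#' fibrin-templated tPA efficiency about an order of magnitude above the
#' uPA efficiency, which reproduces the reported tPA:uPA balance behaviour.
#'
#' @param tpa_kcat,tpa_Km Michaelis-Menten constants of tPA on y-free
#'   plasminogen in solution (per second; molar).
#' @param fibrin_efficiency_factor dimensionless fold-increase of tPA
#'   catalytic efficiency at saturating fibrin (default 500).
#' @param fibrin_Km half-saturation fibrin concentration of the cofactor
#'   term, molar; well below peak fibrin so the full factor is attained in a
#'   formed clot.
#' @param upa_kcat,upa_Km Michaelis-Menten constants of uPA on each
#'   plasminogen variant.
#' @return a `txasim_activation_params` list.
#' @export
activation_params <- function(tpa_kcat = 0.06, tpa_Km = 65e-6,
                              fibrin_efficiency_factor = 500,
                              fibrin_Km = 0.2e-6,
                              upa_kcat = 2.4, upa_Km = 27e-6) {
  vals <- c(tpa_kcat, tpa_Km, fibrin_efficiency_factor, fibrin_Km,
            upa_kcat, upa_Km)
  stopifnot(all(is.finite(vals)), all(vals > 0), fibrin_efficiency_factor > 1)
  structure(list(tpa_kcat = tpa_kcat, tpa_Km = tpa_Km,
                 fibrin_efficiency_factor = fibrin_efficiency_factor,
                 fibrin_Km = fibrin_Km,
                 upa_kcat = upa_kcat, upa_Km = upa_Km),
            class = "txasim_activation_params")
}

#' Plasmin/activator inhibitor parameters
#'
#' All inhibition reactions are irreversible second-order captures.  A1AT is
#' the weak, slow, redundant plasmin inhibitor (`k_a1at` much smaller than
#' `k_ap`); its physiological abundance (tens of micromolar) is what makes
#' it matter.  Scopes: AP (lysine-site dependent) reaches the y-free pools,
#' free and fibrin-bound plasmin, the latter at `ap_bound_factor` times its
#' free-plasmin rate; A2M and A1AT (lysine-site independent) reach free and
#' TXA-bound plasmin but not the fibrin-bound pool.
#'
#' @param k_ap antiplasmin + plasmin capture rate, per molar per second.
#' @param k_a1at alpha1-antitrypsin + plasmin rate (must be < `k_ap`).
#' @param k_a2m alpha2-macroglobulin + plasmin rate.
#' @param k_pci_upa PCI + uPA inactivation rate.
#' @param k_pai1_tpa,k_pai1_upa PAI-1 capture of the activators.
#' @param ap_bound_factor multiplier on `k_ap` for fibrin-bound plasmin
#'   (default 1: same rate; the bound pool is protected only from A2M/A1AT).
#' @return a `txasim_inhibitor_params` list.
#' @export
inhibitor_params <- function(k_ap = 1e7, k_a1at = 1e3, k_a2m = 1e6,
                             k_pci_upa = 2e3, k_pai1_tpa = 1e7,
                             k_pai1_upa = 1e7, ap_bound_factor = 1) {
  vals <- c(k_ap, k_a1at, k_a2m, k_pci_upa, k_pai1_tpa, k_pai1_upa,
            ap_bound_factor)
  stopifnot(all(is.finite(vals)), all(vals > 0))
  if (k_a1at >= k_ap) {
    stop("k_a1at must be smaller than k_ap (A1AT is the slow inhibitor)",
         call. = FALSE)
  }
  structure(list(k_ap = k_ap, k_a1at = k_a1at, k_a2m = k_a2m,
                 k_pci_upa = k_pci_upa, k_pai1_tpa = k_pai1_tpa,
                 k_pai1_upa = k_pai1_upa, ap_bound_factor = ap_bound_factor),
            class = "txasim_inhibitor_params")
}

#' Fibrin-phase parameters
#'
#' Plasmin binds fibrin reversibly through its (y-free) lysine binding site
#' and the bound enzyme degrades fibrin by Michaelis-Menten kinetics into
#' inert degradation products (FDP).
#'
#' @param kon_fb,koff_fb plasmin-fibrin association/dissociation rates.
#' @param lysis_kcat,lysis_Km Michaelis-Menten constants of fibrin
#'   degradation by fibrin-bound plasmin.
#' @return a `txasim_fibrin_params` list.
#' @export
fibrin_params <- function(kon_fb = 1e6, koff_fb = 1,
                          lysis_kcat = 8, lysis_Km = 2e-6) {
  vals <- c(kon_fb, koff_fb, lysis_kcat, lysis_Km)
  stopifnot(all(is.finite(vals)), all(vals > 0))
  structure(list(kon_fb = kon_fb, koff_fb = koff_fb,
                 lysis_kcat = lysis_kcat, lysis_Km = lysis_Km),
            class = "txasim_fibrin_params")
}

#' Build the fibrinolysis reactions
#'
#' Emits, in the reaction-network schema:
#' \enumerate{
#'   \item tPA Michaelis-Menten activation of the y-free zymogens (Pg, Pgx),
#'     catalytic rate scaled by the saturating fibrin-cofactor term;
#'   \item uPA Michaelis-Menten activation of all four zymogen variants,
#'     `upa_enhancement`-fold faster when x is occupied; activation drops
#'     the x site, releasing its TXA, and preserves the y-site state
#'     (Pg, Pgx -> Pn; Pgy, Pgxy -> Pny);
#'   \item reversible plasmin-fibrin binding and Michaelis-Menten fibrin
#'     degradation (fibrin-bound plasmin as the enzyme, FDP as inert sink);
#'   \item irreversible inhibitor captures with the documented scopes;
#'   \item PCI inactivation of uPA and PAI-1 capture of both activators.
#' }
#'
#' @param act an [activation_params()].
#' @param inh an [inhibitor_params()].
#' @param txa a [txa_binding_params()] (supplies the uPA enhancement and the
#'   binding reactions via [expand_binding_reactions()]).
#' @param fib a [fibrin_params()].
#' @param include_binding also append the TXA binding reactions
#'   (default `TRUE`).
#' @return list of `txasim_reaction` records.
#' @export
build_fibrinolysis_reactions <- function(act = activation_params(),
                                         inh = inhibitor_params(),
                                         txa = txa_binding_params(),
                                         fib = fibrin_params(),
                                         include_binding = TRUE) {
  stopifnot(inherits(act, "txasim_activation_params"),
            inherits(inh, "txasim_inhibitor_params"),
            inherits(txa, "txasim_txa_params"),
            inherits(fib, "txasim_fibrin_params"))
  rx <- list()
  add <- function(r) rx[[length(rx) + 1L]] <<- r

  # (a) tPA activation of y-free variants, fibrin-templated
  tpa_law <- kinetic_law("michaelis_menten_activated",
                         kcat = act$tpa_kcat, Km = act$tpa_Km,
                         act_factor = act$fibrin_efficiency_factor,
                         act_Km = act$fibrin_Km)
  add(reaction("act_tpa_Pg", c(Pg = 1), c(Pn = 1), tpa_law,
               enzyme = "tPA", activator = "Fn",
               note = "tPA activation, fibrin cofactor saturating to 500x efficiency"))
  add(reaction("act_tpa_Pgx", c(Pgx = 1), c(Pn = 1, TXA = 1), tpa_law,
               enzyme = "tPA", activator = "Fn",
               note = "as act_tpa_Pg; x-site TXA released on activation"))

  # (b) uPA activation of all zymogen variants, solution phase
  upa_law <- function(enhanced) {
    kinetic_law("michaelis_menten",
                kcat = act$upa_kcat * if (enhanced) txa$upa_enhancement else 1,
                Km = act$upa_Km)
  }
  add(reaction("act_upa_Pg", c(Pg = 1), c(Pn = 1), upa_law(FALSE),
               enzyme = "uPA", note = "uPA activation in solution"))
  add(reaction("act_upa_Pgx", c(Pgx = 1), c(Pn = 1, TXA = 1), upa_law(TRUE),
               enzyme = "uPA",
               note = "x site occupied: activation enhanced 3-fold; TXA released"))
  add(reaction("act_upa_Pgy", c(Pgy = 1), c(Pny = 1), upa_law(FALSE),
               enzyme = "uPA", note = "y-bound zymogen still uPA-activatable"))
  add(reaction("act_upa_Pgxy", c(Pgxy = 1), c(Pny = 1, TXA = 1), upa_law(TRUE),
               enzyme = "uPA",
               note = "x and y occupied: enhanced activation, x-site TXA released"))

  # (c) plasmin-fibrin binding and degradation
  add(reaction("pn_fn_bind", c(Pn = 1, Fn = 1), c(PnFn = 1),
               kinetic_law("mass_action_reversible",
                           kon = fib$kon_fb, koff = fib$koff_fb),
               note = "only y-free plasmin binds fibrin"))
  add(reaction("fn_degrade", c(Fn = 1), c(FDP = 1),
               kinetic_law("michaelis_menten",
                           kcat = fib$lysis_kcat, Km = fib$lysis_Km),
               enzyme = "PnFn",
               note = "fibrin-bound plasmin degrades fibrin to inert FDP"))

  # (d) irreversible plasmin inhibitors, scoped per pool
  add(reaction("inh_ap_pn", c(AP = 1, Pn = 1), c(AP_Pn = 1),
               kinetic_law("mass_action_irreversible", k = inh$k_ap),
               note = "antiplasmin: fast irreversible capture of free plasmin"))
  add(reaction("inh_ap_pnfn", c(AP = 1, PnFn = 1), c(AP_Pn = 1, Fn = 1),
               kinetic_law("mass_action_irreversible",
                           k = inh$k_ap * inh$ap_bound_factor),
               note = "antiplasmin also reaches fibrin-bound plasmin"))
  add(reaction("inh_a1at_pn", c(A1AT = 1, Pn = 1), c(A1AT_Pn = 1),
               kinetic_law("mass_action_irreversible", k = inh$k_a1at),
               note = "A1AT: slow, weak plasmin capture (lysine-site independent)"))
  add(reaction("inh_a1at_pny", c(A1AT = 1, Pny = 1), c(A1AT_Pn = 1, TXA = 1),
               kinetic_law("mass_action_irreversible", k = inh$k_a1at),
               note = "A1AT also captures TXA-bound plasmin, releasing the TXA"))
  add(reaction("inh_a2m_pn", c(A2M = 1, Pn = 1), c(A2M_Pn = 1),
               kinetic_law("mass_action_irreversible", k = inh$k_a2m),
               note = "A2M bait-region trap (cannot reach fibrin-bound plasmin)"))
  add(reaction("inh_a2m_pny", c(A2M = 1, Pny = 1), c(A2M_Pn = 1, TXA = 1),
               kinetic_law("mass_action_irreversible", k = inh$k_a2m),
               note = "A2M also captures TXA-bound plasmin, releasing the TXA"))

  # (e) activator inhibition
  add(reaction("inh_pci_upa", c(PCI = 1, uPA = 1), c(PCI_uPA = 1),
               kinetic_law("mass_action_irreversible", k = inh$k_pci_upa),
               note = "protein C inhibitor inactivates uPA"))
  add(reaction("inh_pai1_tpa", c(PAI1 = 1, tPA = 1), c(PAI1_tPA = 1),
               kinetic_law("mass_action_irreversible", k = inh$k_pai1_tpa),
               note = "PAI-1 capture of tPA (low physiological PAI-1)"))
  add(reaction("inh_pai1_upa", c(PAI1 = 1, uPA = 1), c(PAI1_uPA = 1),
               kinetic_law("mass_action_irreversible", k = inh$k_pai1_upa),
               note = "PAI-1 capture of uPA"))

  if (include_binding) rx <- c(rx, expand_binding_reactions(txa))
  rx
}

#' Species records of the fibrinolysis sub-network
#'
#' Physiological plasma defaults: plasminogen 2 uM and antiplasmin 1 uM (the
#' nominal 2:1 ratio that makes antiplasmin exhaustible), A1AT 40 uM,
#' A2M 3 uM, PCI 90 nM, PAI-1 0.4 nM, fibrinogen 9 uM.  tPA, uPA and TXA
#' default to zero and are set per scenario.
#'
#' @return list of [species()] records.
#' @export
fibrinolysis_species <- function() {
  list(
    species("Pg",   2,   "uM", c("zymogen")),
    species("Pgx",  0,   "uM", c("zymogen", "txa_bound")),
    species("Pgy",  0,   "uM", c("zymogen", "txa_bound")),
    species("Pgxy", 0,   "uM", c("zymogen", "txa_bound")),
    species("Pn",   0,   "uM", c("protease")),
    species("Pny",  0,   "uM", c("protease", "txa_bound")),
    species("PnFn", 0,   "uM", c("protease", "complex")),
    species("TXA",  0,   "uM", c("ligand")),
    species("tPA",  0,   "nM", c("protease", "activator")),
    species("uPA",  0,   "nM", c("protease", "activator")),
    species("Fg",   9,   "uM", c("substrate")),
    species("Fn",   0,   "uM", c("substrate", "clot")),
    species("FDP",  0,   "uM", c("sink")),
    species("AP",   1,   "uM", c("inhibitor")),
    species("A1AT", 40,  "uM", c("inhibitor")),
    species("A2M",  3,   "uM", c("inhibitor")),
    species("PCI",  90,  "nM", c("inhibitor")),
    species("PAI1", 0.4, "nM", c("inhibitor")),
    species("AP_Pn",   0, "uM", c("complex", "inert")),
    species("A1AT_Pn", 0, "uM", c("complex", "inert")),
    species("A2M_Pn",  0, "uM", c("complex", "inert")),
    species("PCI_uPA", 0, "nM", c("complex", "inert")),
    species("PAI1_tPA", 0, "nM", c("complex", "inert")),
    species("PAI1_uPA", 0, "nM", c("complex", "inert")))
}
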