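# Tissue-factor initiated thrombin generation.
#
# The cascade is data, not code: the engine consumes a model-file fragment
# (inst/extdata/coagulation_cascade.json, regenerated by
# tools/make_model.R from coagulation_cascade_network()).  The reactions and
# rate constants follow the widely reproduced TF-pathway mass-action ODE
# model of extrinsic coagulation (Hockin-Mann lineage): TF:VIIa-driven
# activation of factors IX and X, the intrinsic tenase (IXa:VIIIa) and
# prothrombinase (Xa:Va) complexes, meizothrombin (mIIa) as intermediate,
# and stoichiometric inhibition by TFPI and ATIII.  Thrombin (IIa) converts
# fibrinogen to fibrin by Michaelis-Menten kinetics, providing the clot
# substrate for fibrinolysis.

#' Construct the coagulation cascade as a standalone network
#'
#' @param TF tissue-factor initial concentration in molar (default 5 pM,
#'   the standard initiation dose of this model family).
#' @return a validated `txasim_network` containing the cascade species
#'   (zymogens at mean plasma concentrations, complexes at zero) plus
#'   fibrinogen/fibrin, and the cascade reactions.
#' @export
coagulation_cascade_network <- function(TF = 5e-12) {
  note <- "rate constant per the TF-pathway mass-action ODE model family (fallback transcription)"
  ma <- function(id, reactants, products, k) {
    reaction(id, reactants, products,
             kinetic_law("mass_action_irreversible", k = k), note = note)
  }
  sp <- list(
    species("TF",    from_molar(TF, "pM"), "pM", "initiator"),
    species("VII",   10,  "nM", "zymogen"),
    species("VIIa",  0.1, "nM", "protease"),
    species("TF_VII",  0, "nM", "complex"),
    species("TF_VIIa", 0, "nM", c("complex", "protease")),
    species("X",    160,  "nM", "zymogen"),
    species("Xa",     0,  "nM", "protease"),
    species("TF_VIIa_X",  0, "nM", "complex"),
    species("TF_VIIa_Xa", 0, "nM", "complex"),
    species("IX",    90,  "nM", "zymogen"),
    species("IXa",    0,  "nM", "protease"),
    species("TF_VIIa_IX", 0, "nM", "complex"),
    species("II",  1400,  "nM", "zymogen"),
    species("IIa",    0,  "nM", "protease"),
    species("mIIa",   0,  "nM", "protease"),
    species("VIII", 0.7,  "nM", "cofactor"),
    species("VIIIa",  0,  "nM", "cofactor"),
    species("VIIIa1L", 0, "nM", "cofactor"),
    species("VIIIa2",  0, "nM", "cofactor"),
    species("IXa_VIIIa",   0, "nM", "complex"),
    species("IXa_VIIIa_X", 0, "nM", "complex"),
    species("V",     20,  "nM", "cofactor"),
    species("Va",     0,  "nM", "cofactor"),
    species("Xa_Va",    0, "nM", "complex"),
    species("Xa_Va_II", 0, "nM", "complex"),
    species("TFPI",  2.5, "nM", "inhibitor"),
    species("Xa_TFPI", 0, "nM", c("complex", "inert")),
    species("TF_VIIa_Xa_TFPI", 0, "nM", c("complex", "inert")),
    species("ATIII", 3400, "nM", "inhibitor"),
    species("Xa_ATIII",   0, "nM", c("complex", "inert")),
    species("mIIa_ATIII", 0, "nM", c("complex", "inert")),
    species("IXa_ATIII",  0, "nM", c("complex", "inert")),
    species("IIa_ATIII",  0, "nM", c("complex", "inert")),
    species("TF_VIIa_ATIII", 0, "nM", c("complex", "inert")),
    species("Fg", 9, "uM", "substrate"),
    species("Fn", 0, "uM", c("substrate", "clot")))
  rx <- list(
    ma("c01_tf_vii_on",  c(TF = 1, VII = 1), c(TF_VII = 1), 3.2e6),
    ma("c02_tf_vii_off", c(TF_VII = 1), c(TF = 1, VII = 1), 3.1e-3),
    ma("c03_tf_viia_on",  c(TF = 1, VIIa = 1), c(TF_VIIa = 1), 2.3e7),
    ma("c04_tf_viia_off", c(TF_VIIa = 1), c(TF = 1, VIIa = 1), 3.1e-3),
    ma("c05_tfviia_act_vii", c(TF_VIIa = 1, VII = 1), c(TF_VIIa = 1, VIIa = 1), 4.4e5),
    ma("c06_xa_act_vii",  c(Xa = 1, VII = 1), c(Xa = 1, VIIa = 1), 1.3e7),
    ma("c07_iia_act_vii", c(IIa = 1, VII = 1), c(IIa = 1, VIIa = 1), 2.3e4),
    ma("c08_tfviia_x_on",  c(TF_VIIa = 1, X = 1), c(TF_VIIa_X = 1), 2.5e7),
    ma("c09_tfviia_x_off", c(TF_VIIa_X = 1), c(TF_VIIa = 1, X = 1), 1.05),
    ma("c10_tfviia_x_cat", c(TF_VIIa_X = 1), c(TF_VIIa_Xa = 1), 6),
    ma("c11_tfviia_xa_on",  c(TF_VIIa = 1, Xa = 1), c(TF_VIIa_Xa = 1), 2.2e7),
    ma("c12_tfviia_xa_off", c(TF_VIIa_Xa = 1), c(TF_VIIa = 1, Xa = 1), 19),
    ma("c13_tfviia_ix_on",  c(TF_VIIa = 1, IX = 1), c(TF_VIIa_IX = 1), 1e7),
    ma("c14_tfviia_ix_off", c(TF_VIIa_IX = 1), c(TF_VIIa = 1, IX = 1), 2.4),
    ma("c15_tfviia_ix_cat", c(TF_VIIa_IX = 1), c(TF_VIIa = 1, IXa = 1), 1.8),
    ma("c16_xa_act_ii", c(Xa = 1, II = 1), c(Xa = 1, IIa = 1), 7.5e3),
    ma("c17_iia_act_viii", c(IIa = 1, VIII = 1), c(IIa = 1, VIIIa = 1), 2e7),
    ma("c18_tenase_on",  c(VIIIa = 1, IXa = 1), c(IXa_VIIIa = 1), 1e7),
    ma("c19_tenase_off", c(IXa_VIIIa = 1), c(VIIIa = 1, IXa = 1), 5e-3),
    ma("c20_tenase_x_on",  c(IXa_VIIIa = 1, X = 1), c(IXa_VIIIa_X = 1), 1e8),
    ma("c21_tenase_x_off", c(IXa_VIIIa_X = 1), c(IXa_VIIIa = 1, X = 1), 1e-3),
    ma("c22_tenase_x_cat", c(IXa_VIIIa_X = 1), c(IXa_VIIIa = 1, Xa = 1), 8.2),
    ma("c23_viiia_decay", c(VIIIa = 1), c(VIIIa1L = 1, VIIIa2 = 1), 6e-3),
    ma("c24_viiia_reform", c(VIIIa1L = 1, VIIIa2 = 1), c(VIIIa = 1), 2.2e4),
    ma("c25_tenase_x_decay", c(IXa_VIIIa_X = 1),
       c(VIIIa1L = 1, VIIIa2 = 1, X = 1, IXa = 1), 1e-3),
    ma("c26_tenase_decay", c(IXa_VIIIa = 1),
       c(VIIIa1L = 1, VIIIa2 = 1, IXa = 1), 1e-3),
    ma("c27_iia_act_v", c(IIa = 1, V = 1), c(IIa = 1, Va = 1), 2e7),
    ma("c28_prothrombinase_on",  c(Xa = 1, Va = 1), c(Xa_Va = 1), 4e8),
    ma("c29_prothrombinase_off", c(Xa_Va = 1), c(Xa = 1, Va = 1), 0.2),
    ma("c30_prothrombinase_ii_on",  c(Xa_Va = 1, II = 1), c(Xa_Va_II = 1), 1e8),
    ma("c31_prothrombinase_ii_off", c(Xa_Va_II = 1), c(Xa_Va = 1, II = 1), 103),
    ma("c32_prothrombinase_ii_cat", c(Xa_Va_II = 1), c(Xa_Va = 1, mIIa = 1), 63.5),
    ma("c33_miia_maturation", c(mIIa = 1, Xa_Va = 1), c(IIa = 1, Xa_Va = 1), 1.5e7),
    ma("c34_xa_tfpi_on",  c(Xa = 1, TFPI = 1), c(Xa_TFPI = 1), 9e5),
    ma("c35_xa_tfpi_off", c(Xa_TFPI = 1), c(Xa = 1, TFPI = 1), 3.6e-4),
    ma("c36_tfviiaxa_tfpi_on", c(TF_VIIa_Xa = 1, TFPI = 1),
       c(TF_VIIa_Xa_TFPI = 1), 3.2e8),
    ma("c37_tfviiaxa_tfpi_off", c(TF_VIIa_Xa_TFPI = 1),
       c(TF_VIIa_Xa = 1, TFPI = 1), 1.1e-4),
    ma("c38_tfviia_xatfpi", c(TF_VIIa = 1, Xa_TFPI = 1),
       c(TF_VIIa_Xa_TFPI = 1), 5e7),
    ma("c39_atiii_xa",   c(Xa = 1, ATIII = 1), c(Xa_ATIII = 1), 1.5e3),
    ma("c40_atiii_miia", c(mIIa = 1, ATIII = 1), c(mIIa_ATIII = 1), 7.1e3),
    ma("c41_atiii_ixa",  c(IXa = 1, ATIII = 1), c(IXa_ATIII = 1), 4.9e2),
    ma("c42_atiii_iia",  c(IIa = 1, ATIII = 1), c(IIa_ATIII = 1), 7.1e3),
    ma("c43_atiii_tfviia", c(TF_VIIa = 1, ATIII = 1), c(TF_VIIa_ATIII = 1), 2.3e2),
    reaction("c44_iia_fg", c(Fg = 1), c(Fn = 1),
             kinetic_law("michaelis_menten", kcat = 84, Km = 7.2e-6),
             enzyme = "IIa",
             note = "thrombin-catalyzed fibrinogen -> fibrin (fibrinopeptide release kinetics)"))
  net <- reaction_network(sp, rx, name = "coagulation_cascade",
                          version = "1",
                          provenance = "TF-pathway cascade fragment; see note fields")
  stop_if_invalid(net)
  net
}

#' Load and validate a coagulation cascade fragment
#'
#' @param source path to a model-file fragment (defaults to the packaged
#'   cascade), or an already-loaded `txasim_network`.
#' @return list with `species` and `reactions` of the validated fragment.
#'   Errors if any of the mandatory species (TF, II, IIa, Fg) is missing.
#' @export
build_coagulation_reactions <- function(source = NULL) {
  net <- if (inherits(source, "txasim_network")) {
    source
  } else if (is.null(source)) {
    p <- system.file("extdata", "coagulation_cascade.json", package = "txasim")
    if (nzchar(p)) load_network(p) else coagulation_cascade_network()
  } else {
    load_network(source)
  }
  stop_if_invalid(net)
  missing <- setdiff(c("TF", "II", "IIa", "Fg"), species_names(net))
  if (length(missing)) {
    stop("cascade fragment lacks mandatory species: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  list(species = net$species, reactions = net$reactions)
}

#' Thrombogram summary metrics
#'
#' @param tc a `txasim_time_course` containing thrombin (`IIa`).
#' @param lag_fraction lag threshold as a fraction of peak thrombin
#'   (default 10 percent).
#' @return list with `lag_time` (s, `NA` if thrombin never rises),
#'   `peak_height` (molar), `time_to_peak` (s) and
#'   `endogenous_thrombin_potential` (molar x seconds, trapezoidal).
#' @export
thrombin_metrics <- function(tc, lag_fraction = 0.1) {
  if (!inherits(tc, "txasim_time_course") || length(tc$times) == 0L) {
    stop("empty or invalid time course", call. = FALSE)
  }
  if (!"IIa" %in% tc$species) stop("time course lacks thrombin (IIa)", call. = FALSE)
  iia <- tc$concentrations[, "IIa"]
  t <- tc$times
  peak <- max(iia)
  etp <- sum(diff(t) * (utils::head(iia, -1) + utils::tail(iia, -1)) / 2)
  if (peak <= 0) {
    return(list(lag_time = NA_real_, peak_height = 0,
                time_to_peak = NA_real_, endogenous_thrombin_potential = etp))
  }
  ipeak <- which.max(iia)
  ilag <- which(iia >= lag_fraction * peak)[1L]
  lag <- if (ilag > 1L) {
    # linear interpolation of the threshold crossing
    t0 <- t[ilag - 1L]; t1 <- t[ilag]
    y0 <- iia[ilag - 1L]; y1 <- iia[ilag]
    t0 + (lag_fraction * peak - y0) / (y1 - y0) * (t1 - t0)
  } else t[1L]
  list(lag_time = lag, peak_height = peak, time_to_peak = t[ipeak],
       endogenous_thrombin_potential = etp)
}
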