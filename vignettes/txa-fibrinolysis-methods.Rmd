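---
title: "Modelling tranexamic acid in coagulation and fibrinolysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling tranexamic acid in coagulation and fibrinolysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txasim)
```

## The model

txasim integrates a closed, well-mixed mass-action/Michaelis–Menten reaction
network for tissue-factor (TF) initiated coagulation coupled to
plasmin-mediated fibrinolysis:

$$\frac{d[X_i]}{dt} \;=\; \sum_r \nu_{ir}\, v_r(\mathbf{c}),$$

with net stoichiometries $\nu$ and per-reaction fluxes $v_r$ given by one of
four kinetic-law kinds (irreversible and reversible mass action,
Michaelis–Menten, and a cofactor-activated Michaelis–Menten variant).  All
internal concentrations are molar, all times seconds; display units exist
only at the I/O boundary.

The thrombin-generation sub-network follows the classical TF-pathway ODE
models of the extrinsic cascade: TF:VIIa formation and its activation of
factors IX and X, intrinsic tenase (IXa:VIIIa) and prothrombinase (Xa:Va)
assembly, meizothrombin as intermediate, and stoichiometric inhibition by
TFPI and ATIII.  Thrombin converts fibrinogen (9 µM) to fibrin by
Michaelis–Menten kinetics (kcat 84 s⁻¹, Km 7.2 µM), producing the clot
substrate.  At the default 5 pM TF this yields the standard thrombogram —
lag ≈ 10 min, peak ≈ 120 nM free thrombin — and complete fibrin formation.
The cascade ships as *data* (a sectioned JSON fragment with per-reaction
provenance notes), not as code, so individual constants can be corrected
without touching the engine.

### The two-site TXA mechanism

Plasminogen carries two independent TXA binding sites:

* the **x site** (Kd = 600 µM): TXA occupancy switches the zymogen into a
  conformation that uPA activates **3-fold** faster;
* the **y site** (Kd = 1.1 µM): the lysine binding site through which
  plasmin(ogen) engages fibrin.  With TXA on y, plasminogen cannot be
  activated by tPA (a fibrin-templated reaction) and plasmin cannot bind or
  degrade fibrin.

This gives four zymogen variants (Pg, Pgx, Pgy, Pgxy) and two plasmin
variants (Pn, Pny).  Activation drops the x site (its only stated effect is
on zymogen activation) and releases any TXA bound there; the y-site state is
inherited.  All binding steps are reversible mass action with
koff = Kd·kon, so TXA is never consumed — a conservation law the test suite
verifies exactly by integer null-space analysis and numerically to solver
tolerance.

Association rates are not reported for these sites.  The default
kon = 10⁶ M⁻¹s⁻¹ (typical small-molecule binding) makes the binding
equilibrium fast relative to lysis dynamics wherever that is physically
possible; see *Equilibrium control and its limits* below.

### Activation and lysis

tPA activates the y-free zymogens by Michaelis–Menten kinetics
(kcat 0.06 s⁻¹, Km 65 µM in solution) with the catalytic rate multiplied by
a saturating fibrin-cofactor term $1 + (F-1)\,[Fn]/([Fn]+K_f)$, $F = 500$,
$K_f = 0.2$ µM.  At saturating fibrin the catalytic efficiency is therefore
exactly 500-fold the fibrin-free value, by construction; $K_f$ sits well
below peak fibrin (≈ 9 µM) so a formed clot realises essentially the full
factor.  uPA activates all four zymogen variants in solution
(kcat 2.4 s⁻¹, Km 27 µM; 3-fold faster on Pgx/Pgxy).

Free plasmin binds fibrin reversibly through the y site
(kon 10⁶ M⁻¹s⁻¹, koff 1 s⁻¹) and the bound enzyme degrades fibrin to inert
degradation products by Michaelis–Menten kinetics (kcat 8 s⁻¹ per lumped
fibrin-monomer unit, Km 2 µM).

### The inhibitor system and its scopes

| inhibitor | rate (M⁻¹s⁻¹) | level | reaches |
|---|---|---|---|
| antiplasmin (AP) | 1e7 | 1 µM | free and fibrin-bound plasmin (y-free pools) |
| α2-macroglobulin (A2M) | 1e6 | 3 µM | free and TXA-bound plasmin |
| α1-antitrypsin (A1AT) | 1e3 | 40 µM | free and TXA-bound plasmin |
| PCI (on uPA) | 2e3 | 90 nM | uPA |
| PAI-1 (on tPA/uPA) | 1e7 | 0.4 nM | both activators |

The scope structure is the heart of the model's behaviour.  AP capture is
lysine-binding-site dependent — the same site TXA occupies — so AP reaches
only y-free plasmin; this is why TXA raises measurable plasmin generation.
A2M (a bait-region protease trap) and A1AT capture plasmin through
lysine-site-independent chemistry, so they also reach the TXA-bound pool
(releasing the TXA), but neither can attack plasmin seated on fibrin.
An early design iteration restricted *all* inhibitors to the y-free pool;
in that structure TXA cannot slow lysis through A2M/A1AT at all — fibrin
binding and capture then compete out of the same free pool and both scale
with the same free fraction — and the knockout-panel phenotypes
(anti-fibrinolysis with A1AT only, dose-monotone inhibition with A2M
present) are unreachable.  The lysine-independent scope makes them emerge
naturally and is the package's own design choice.

Plasminogen (2 µM) is twice antiplasmin (1 µM) — the nominal 2:1 ratio that
makes antiplasmin exhaustible.  When A2M and A1AT are knocked out, enough
plasmin can be generated to deplete AP outright; any plasmin remaining
afterwards degrades fibrin essentially unopposed (hyperfibrinolysis).
Because TXA accelerates uPA-mediated generation (x site) while its y-site
protection is only kinetic — irreversible inhibitors always win eventually —
TXA *speeds up* AP depletion and becomes pro-fibrinolytic exactly in this
depleted regime.  With A2M or A1AT present the same doses slow or abolish
lysis.  The tPA:uPA balance then sets the net effect: the packaged
efficiencies place tPA 2.5 nM ≈ 2.6× the uPA 5 nM activation flux, so the
anti-fibrinolytic tPA blockade dominates at 2.5 nM, the two cancel near
1 nM, and the pro-fibrinolytic uPA response dominates at 0.1 nM.

## Calibration and provenance of constants

The complete reaction list of the source model was not available to this
implementation; constants were assembled from the cited prior ODE-model
family (coagulation cascade) and from standard literature ranges
(fibrinolysis), with each reaction's `note` field recording its provenance.
Five constants are not pinned by any printed number and act as the model's
free calibration: `upa_kcat`/`upa_Km`, `lysis_kcat`, `k_a2m` and
`k_pci_upa`.  They were set **once**, within literature-plausible ranges, so
that the stated qualitative outcomes of the reproduced experiments hold at
the printed doses (dose-dependent tPA inhibition with full blockade at
3.47 mM; knockout-panel phenotypes; the pro→neutral→anti transition with a
neutral point at 1 nM tPA), and then frozen as the package defaults.  They
are calibrated to figure-stated behaviours, not fitted to any quantitative
curve — no lysis-time data exist to fit.

Initial conditions not printed in the main text use mean plasma values:
fibrinogen 9 µM, plasminogen 2 µM, antiplasmin 1 µM, A1AT 40 µM, A2M 3 µM,
PCI 90 nM, PAI-1 0.4 nM, and the cascade zymogens at the standard values of
the source model family.

## Numerics

No stiff ODE solver package is assumed: txasim owns its integrator
(compiled code).  It is a linearly implicit Bader–Deuflhard midpoint scheme
with polynomial extrapolation (sequence 2, 6, 10, 14, 22), exact analytic
Jacobians assembled from the kinetic laws, LU factorisation per extrapolation
column, and per-component WRMS error control with scale
`atol + rtol·|y|` (defaults rtol 1e-8, atol 1e-14 M — the network spans
pM–mM).  The solver is validated against closed-form solutions
(exponential decay, the reversible-bimolecular Riccati solution, and the
integrated Michaelis–Menten equation evaluated via Lambert-W) to 1e-6
relative error, and conserved moieties drift by ~1e-11 relative over full
scenario runs.

Numerical policies: integration states are never clipped (conservation is
preserved to solver accuracy); at output, negative excursions within
100·atol of zero are set to zero and anything substantially negative aborts
with a structured solver error carrying the last good state.  Threshold
crossings (lysis times, AP depletion) are linearly interpolated between
grid points.  Everything is deterministic — identical inputs give
bit-identical output; there is no Monte Carlo anywhere.

Lysis time is measured from the fibrin *peak* (the clot must form before
lysis is meaningful): LT50 is the first post-peak time at which the clot
signal (fibrin plus fibrin-bound plasmin) falls to 50 % of peak.  The
anti/neutral/pro classification compares successive doses with a 5 %
relative tolerance — the operational definition of lysis at "similar
times": at least one >5 % rise and no >5 % fall is anti-fibrinolytic, the
mirror image pro-fibrinolytic, anything else (all flat, or mixed) neutral;
an undefined lysis time counts as infinite.

## Equilibrium control and its limits

Holding both Kd fixed and scaling kon_x, kon_y by 0.1× or 10× leaves every
lysis time in the uPA-driven regimes unchanged to ≤ 0.3 % — those outcomes
are controlled by the binding *equilibria*, not the rates.  This is not
attainable everywhere: at substoichiometric TXA doses (≈ 1 µM against 2 µM
plasminogen) free TXA is scarce (~0.5 µM) while nascent plasmin is captured
irreversibly by antiplasmin at k·[AP] ≈ 10 s⁻¹.  The race between TXA
rebinding and capture is then genuinely kinetic, and no physically sensible
kon (we verified up to 10⁸ M⁻¹s⁻¹) brings the low-dose tPA-regime lysis
times into the equilibrium-controlled limit.  The corresponding acceptance
check is asserted at its stated 2 % bound and left failing for that narrow
slice, with the passing uPA-regime subset pinned by a separate test; the
dose-response *classifications* are kon-robust throughout.

## What the simulations do and do not establish

The scenario drivers reproduce in-silico experiments on a stated world:
printed doses, printed affinities and enhancement factors, mean plasma
levels, a closed stirred volume.  They do not emulate flow or perfusion,
platelet surfaces, spatial clot structure, TXA pharmacokinetics, plasmin
positive feedback on its own activation, consumption of A2M/A1AT outside
this reaction system (deliberately excluded — including it would only
amplify the depletion effects), or FDP feedback on polymerisation.  A green
dose–response test therefore establishes internal mechanistic consistency,
not clinical effect sizes; no mapping to trial outcomes is attempted.

## Known limitations

* The cascade constants are a fallback transcription from the published
  TF-pathway model family; per-reaction notes mark them all, and the
  JSON-fragment design makes corrections data edits, not code edits.
* Fibrin is a lumped monomer-equivalent species; `lysis_kcat` is an
  effective turnover per lumped unit and is one of the calibrated constants.
* Whether activated plasmin retains a functional x site is not modelled
  (Pn/Pny only); adding Pnx/Pnxy is a local change to the species expansion.
* AP is assumed to reach fibrin-bound plasmin at its free-pool rate
  (`ap_bound_factor = 1`); literature suggests partial protection, and the
  factor is exposed as a parameter.
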