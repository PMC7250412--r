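Package: txasim
Title: Kinetic Modelling of Coagulation, Fibrinolysis and Tranexamic Acid
Version: 0.1.0
Authors@R:
    person("txasim", "maintainers", email = "txasim@example.org", role = c("aut", "cre"))
Description: An ordinary-differential-equation simulator for tissue-factor
    initiated coagulation coupled to plasmin-mediated fibrinolysis, centred on
    a two-binding-site model of the interaction between tranexamic acid (TXA)
    and plasmin(ogen).  The package provides a validated JSON reaction-network
    format with mass-action and Michaelis-Menten kinetic laws, exact
    conserved-moiety analysis, a stiff semi-implicit extrapolation integrator
    with analytic Jacobians, clot-lysis metrics, and scenario drivers for TXA
    dose-response sweeps, plasmin-inhibitor knockout panels and
    tPA:uPA balance experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
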