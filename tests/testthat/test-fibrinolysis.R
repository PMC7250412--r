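# Builds a fibrinolysis-only network (no coagulation cascade) so these
# tests run on small systems with controlled initial conditions.
fibrinolysis_network <- function(act = activation_params(),
                                 inh = inhibitor_params(),
                                 txa = txa_binding_params(),
                                 fib = fibrin_params(),
                                 overrides = list()) {
  sp <- fibrinolysis_species()
  net <- reaction_network(
    sp, build_fibrinolysis_reactions(act, inh, txa, fib),
    name = "fibrinolysis_only")
  stopifnot(nrow(validate_network(net)) == 0L)
  net
}

test_that("uPA activates x-occupied plasminogen exactly 3-fold faster", {
  net <- fibrinolysis_network()
  st <- initial_state(net, list(Pg = 1e-6, Pgx = 1e-6, Pgy = 1e-6,
                                Pgxy = 1e-6, uPA = 5e-9))
  fx <- instantaneous_fluxes(net, st)
  expect_equal(fx[["act_upa_Pgx"]] / fx[["act_upa_Pg"]], 3, tolerance = 1e-14)
  expect_equal(fx[["act_upa_Pgxy"]] / fx[["act_upa_Pgy"]],
               fx[["act_upa_Pgx"]] / fx[["act_upa_Pg"]], tolerance = 1e-14)
})

test_that("fibrin raises tPA catalytic efficiency 500-fold at saturation", {
  act <- activation_params()
  net <- fibrinolysis_network(act = act)
  # efficiency regime: substrate far below Km
  s_lo <- 1e-9
  st0 <- initial_state(net, list(Pg = s_lo, tPA = 2.5e-9, Fn = 0))
  st1 <- initial_state(net, list(Pg = s_lo, tPA = 2.5e-9,
                                 Fn = 1e9 * act$fibrin_Km))
  v0 <- instantaneous_fluxes(net, st0)[["act_tpa_Pg"]]
  v1 <- instantaneous_fluxes(net, st1)[["act_tpa_Pg"]]
  expect_equal(v1 / v0, 500, tolerance = 1e-8)
  # the same factor holds for the ratio of fitted kcat/Km at low substrate
  expect_equal(v0, act$tpa_kcat * 2.5e-9 * s_lo / (act$tpa_Km + s_lo),
               tolerance = 1e-12)
})

test_that("tPA activation flux vanishes as TXA saturates the y site", {
  net <- fibrinolysis_network()
  # equilibrium zymogen partition at a saturating clamped TXA level
  part <- equilibrium_partition(2e-6, 0.1)  # 0.1 M >> both Kd
  st <- initial_state(net, list(Pg = part[["Pg"]], Pgx = part[["Pgx"]],
                                Pgy = part[["Pgy"]], Pgxy = part[["Pgxy"]],
                                tPA = 2.5e-9, Fn = 9e-6))
  fx <- instantaneous_fluxes(net, st)
  tpa_flux <- fx[["act_tpa_Pg"]] + fx[["act_tpa_Pgx"]]
  upa_ref <- instantaneous_fluxes(
    net, initial_state(net, list(Pg = 2e-6, tPA = 2.5e-9, Fn = 9e-6)))
  # residual flux equals the tiny y-free fraction left at 0.1 M TXA
  expect_lt(tpa_flux / upa_ref[["act_tpa_Pg"]], 1e-4)
})

test_that("instantaneous_fluxes matches the kinetic-law definitions", {
  net <- fibrinolysis_network()
  expect_identical(unname(instantaneous_fluxes(net, numeric(length(net$species)))),
                   numeric(length(net$reactions)))
  # second-order mass action: AP + Pn at 1 uM each
  st <- initial_state(net, list(AP = 1e-6, Pn = 1e-6))
  fx <- instantaneous_fluxes(net, st)
  expect_identical(fx[["inh_ap_pn"]], inhibitor_params()$k_ap * 1e-12)
  # Michaelis-Menten half-saturation identity: [S] = Km -> kcat*[E]/2
  act <- activation_params()
  st2 <- initial_state(net, list(Pg = act$upa_Km, uPA = 5e-9))
  expect_equal(instantaneous_fluxes(net, st2)[["act_upa_Pg"]],
               act$upa_kcat * 5e-9 / 2, tolerance = 1e-12)
  expect_error(instantaneous_fluxes(net, numeric(3)), "entries")
})

test_that("antiplasmin displaces TXA: closed Pn/TXA/AP subsystem ends fully inhibited", {
  # no activators, no fibrin: plasmin 0.5 uM, AP 1 uM, TXA varied
  ends <- sapply(c(0, 10e-6, 1000e-6), function(txa0) {
    net <- fibrinolysis_network()
    tc <- simulate_network(net,
      overrides = list(Pg = 0, Fg = 0, A1AT = 0, A2M = 0, PAI1 = 0, PCI = 0,
                       Pn = 0.5e-6, AP = 1e-6, TXA = txa0),
      settings = solver_settings(t_end = 50000, output_points = 30))
    fin <- tc$concentrations[nrow(tc$concentrations), ]
    c(inhibited = fin[["AP_Pn"]], free_pool = fin[["Pn"]] + fin[["Pny"]],
      txa = fin[["TXA"]])
  })
  # all plasmin ends in the irreversible AP complex regardless of dose
  expect_true(all(abs(ends["inhibited", ] - 0.5e-6) / 0.5e-6 < 1e-3))
  expect_true(all(ends["free_pool", ] / 0.5e-6 < 1e-3))
  # and TXA is fully recovered (never consumed)
  expect_equal(ends["txa", ], c(0, 10e-6, 1000e-6), tolerance = 1e-9)
})

test_that("TXA monotonically lowers instantaneous free plasmin", {
  # fixed total plasmin equilibrated against increasing TXA
  net <- fibrinolysis_network()
  free_pn <- sapply(txa_dose_ladder(), function(txa0) {
    tc <- simulate_network(net,
      overrides = list(Pg = 0, Fg = 0, AP = 0, A1AT = 0, A2M = 0,
                       Pn = 0.5e-6, TXA = txa0),
      settings = solver_settings(t_end = 1000, output_points = 10))
    tc$concentrations[nrow(tc$concentrations), "Pn"]
  })
  expect_true(all(diff(free_pn) < 0))
})

test_that("only AP reaches the fibrin-bound plasmin pool", {
  rx <- build_fibrinolysis_reactions()
  touches_pnfn <- Filter(function(r) {
    "PnFn" %in% c(names(r$reactants), names(r$products), r$enzyme)
  }, rx)
  expect_identical(sort(vapply(touches_pnfn, `[[`, character(1), "id")),
                   c("fn_degrade", "inh_ap_pnfn", "pn_fn_bind"))
  # knocking A2M/A1AT out leaves the bound-pool inhibition flux unchanged
  net <- fibrinolysis_network()
  st <- initial_state(net, list(PnFn = 1e-7, Fn = 5e-6, AP = 1e-6,
                                A2M = 3e-6, A1AT = 40e-6))
  st0 <- initial_state(net, list(PnFn = 1e-7, Fn = 5e-6, AP = 1e-6,
                                 A2M = 0, A1AT = 0))
  expect_identical(instantaneous_fluxes(net, st)[["inh_ap_pnfn"]],
                   instantaneous_fluxes(net, st0)[["inh_ap_pnfn"]])
})

test_that("fibrin moiety is conserved through formation, binding and lysis", {
  net <- fibrinolysis_network()
  tc <- simulate_network(net,
    overrides = list(Fg = 0, Fn = 5e-6, Pn = 0.2e-6, AP = 0.2e-6),
    settings = solver_settings(t_end = 3000, output_points = 40))
  fib_total <- rowSums(tc$concentrations[, c("Fg", "Fn", "PnFn", "FDP")])
  expect_lt(max(abs(fib_total - fib_total[1L])) / fib_total[1L], 1e-6)
})
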