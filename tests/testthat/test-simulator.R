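test_that("build_rhs implements net-stoichiometry times flux", {
  net <- tiny_decay_network(k = 0.1, A0 = 1e-6)
  f <- build_rhs(net)
  expect_equal(f(c(1e-6, 0)), c(-1e-7, 1e-7), tolerance = 1e-15)

  empty <- reaction_network(list(species("A", 1e-6)), list(), name = "empty")
  expect_identical(build_rhs(empty)(5e-7), 0)

  # full model at t = 0: derivative equals S %*% fluxes (oracle composition)
  full <- full_model()
  y0 <- initial_state(full, list(tPA = 2.5e-9, uPA = 5e-9, TXA = 14e-6))
  lhs <- build_rhs(full)(y0)
  rhs_oracle <- as.numeric(stoichiometric_matrix(full) %*%
                             instantaneous_fluxes(full, y0))
  expect_equal(lhs, rhs_oracle, tolerance = 1e-12)
})

test_that("the analytic Jacobian matches finite differences", {
  full <- full_model()
  y <- initial_state(full, list(tPA = 2.5e-9, uPA = 5e-9, TXA = 14e-6,
                                Pn = 1e-8, Fn = 1e-6))
  creac <- txasim:::compile_network(full)
  J <- txasim:::cpp_jacobian(creac, as.numeric(y))
  f <- function(x) as.numeric(txasim:::cpp_rhs(creac, x))
  set.seed(1)
  for (j in sample(seq_along(y), 12L)) {
    h <- max(abs(y[j]), 1e-9) * 1e-6
    yp <- as.numeric(y); ym <- as.numeric(y)
    yp[j] <- yp[j] + h; ym[j] <- ym[j] - h
    fd <- (f(yp) - f(ym)) / (2 * h)
    scale <- max(abs(J[, j]), 1e-6)
    expect_lt(max(abs(J[, j] - fd)) / scale, 1e-5)
  }
})

test_that("solver reproduces closed forms on every analytic fixture", {
  cases <- list(
    list(kind = "irreversible_decay", t_end = 500),
    list(kind = "reversible_binding", t_end = 10),
    list(kind = "mm_enzyme", t_end = 2000),
    list(kind = "open_chain", t_end = 600))
  for (cs in cases) {
    fx <- make_fixture(cs$kind)
    tt <- c(0, 10^seq(log10(cs$t_end) - 5, log10(cs$t_end), length.out = 50))
    tc <- simulate_network(fx$network,
                           settings = solver_settings(t_end = cs$t_end,
                                                      output_times = tt))
    exact <- fx$analytic(tt)
    err <- abs(tc$concentrations[, colnames(exact)] - exact) /
      (abs(exact) + 1e-12 * max(exact))
    expect_lt(max(err), 1e-6, label = cs$kind)
  }
})

test_that("a time course starts at its initial conditions and stays finite", {
  net <- full_model()
  tc <- simulate_network(net, overrides = list(uPA = 5e-9, TXA = 54e-6),
                         settings = solver_settings(t_end = 60,
                                                    output_points = 13))
  expect_identical(tc$concentrations[1L, ], initial_state(net, list(uPA = 5e-9, TXA = 54e-6)))
  expect_false(anyNA(tc$concentrations))
  expect_true(all(tc$concentrations >= -1e-14))
  expect_identical(tc$provenance$overrides$TXA, 54e-6)
})

test_that("simulation is deterministic and constant without reactions", {
  none <- reaction_network(list(species("A", 2e-6), species("B", 1e-9)),
                           list(), name = "static")
  tc <- simulate_network(none, settings = solver_settings(t_end = 100,
                                                          output_points = 5))
  expect_true(all(tc$concentrations[, "A"] == 2e-6))
  expect_true(all(tc$concentrations[, "B"] == 1e-9))

  fx <- make_fixture("reversible_binding")
  s <- solver_settings(t_end = 5, output_points = 20)
  t1 <- simulate_network(fx$network, settings = s)
  t2 <- simulate_network(fx$network, settings = s)
  expect_identical(t1$concentrations, t2$concentrations)
})

test_that("input validation and error paths work", {
  net <- tiny_decay_network()
  expect_error(simulate_network(net, overrides = list(Z = 1)), "unknown species")
  expect_error(simulate_network(net, overrides = list(A = -1)), "negative")
  expect_error(simulate_network(net,
    settings = solver_settings(output_times = c(0, 2, 1))), "increasing")
  expect_error(solver_settings(t_end = -1))
  expect_error(solver_settings(rtol = 0))
})

test_that("tolerance refinement leaves lysis metrics converged", {
  net <- full_model()
  m <- lapply(c(1, 0.5), function(f) {
    tc <- simulate_network(net, overrides = list(uPA = 5e-9, TXA = 54e-6,
                                                 A2M = 0, A1AT = 0),
                           settings = solver_settings(rtol = 1e-8 * f,
                                                      atol = 1e-14 * f,
                                                      output_points = 400))
    compute_lysis_metrics(tc)
  })
  for (field in c("fibrin_peak", "lysis_time_50",
                  "percent_fibrin_remaining_at_end", "time_of_AP_depletion")) {
    expect_lt(abs(m[[1]][[field]] - m[[2]][[field]]) / abs(m[[2]][[field]]),
              1e-3, label = field)
  }
})

test_that("metrics agree between coarse and fine output grids", {
  net <- full_model()
  m <- lapply(c(200, 2000), function(n) {
    tc <- simulate_network(net, overrides = list(uPA = 5e-9, TXA = 54e-6,
                                                 A2M = 0, A1AT = 0),
                           settings = solver_settings(output_points = n))
    compute_lysis_metrics(tc)
  })
  # interpolation error of a threshold crossing on a 36 s grid
  expect_lt(abs(m[[1]]$lysis_time_50 - m[[2]]$lysis_time_50), 36)
  expect_lt(abs(m[[1]]$fibrin_peak - m[[2]]$fibrin_peak) / m[[2]]$fibrin_peak,
            5e-3)
})

test_that("time-course export round-trips through CSV", {
  fx <- make_fixture("irreversible_decay")
  tc <- simulate_network(fx$network, settings = solver_settings(t_end = 10,
                                                                output_points = 6))
  f <- withr::local_tempfile(fileext = ".csv")
  write_time_course(tc, f, format = "tidy")
  df <- utils::read.csv(f)
  expect_identical(names(df), c("time", "species", "concentration_M"))
  expect_identical(nrow(df), 12L)
  expect_true(file.exists(paste0(f, ".provenance.json")))
  wide <- as.data.frame(tc, format = "wide")
  expect_identical(dim(wide), c(6L, 3L))
})
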