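synthetic_tc <- function(times, fibrin, ap = NULL) {
  conc <- cbind(Fn = fibrin)
  if (!is.null(ap)) conc <- cbind(conc, AP = ap)
  structure(list(times = times, concentrations = conc,
                 species = colnames(conc)),
            class = "txasim_time_course")
}

test_that("lysis metrics handle the stated synthetic cases", {
  # constant fibrin: no lysis, 100 % remaining
  m <- compute_lysis_metrics(synthetic_tc(seq(0, 1000, 100), rep(1e-6, 11)))
  expect_true(is.na(m$lysis_time_50))
  expect_identical(m$percent_fibrin_remaining_at_end, 100)

  # rise to 1 uM at t = 100, linear fall to 0 at t = 500 -> LT50 = 300 s
  tt <- c(0, 100, seq(150, 500, 50), 600)
  fib <- approx(c(0, 100, 500, 600), c(0, 1e-6, 0, 0), xout = tt)$y
  m <- compute_lysis_metrics(synthetic_tc(tt, fib))
  expect_identical(m$fibrin_peak, 1e-6)
  expect_identical(m$t_peak, 100)
  expect_equal(m$lysis_time_50, 300, tolerance = 1e-12)

  # appending post-lysis zero samples changes nothing except the end
  m2 <- compute_lysis_metrics(synthetic_tc(c(tt, 700, 800),
                                           c(fib, 0, 0)))
  expect_identical(m2$lysis_time_50, m$lysis_time_50)
  expect_identical(m2$t_peak, m$t_peak)

  # AP depletion crossing is interpolated
  m3 <- compute_lysis_metrics(synthetic_tc(
    c(0, 100, 200), rep(1e-6, 3), ap = c(1e-6, 0.5e-6, 0)))
  expect_equal(m3$time_of_AP_depletion, 198, tolerance = 1e-6)

  expect_error(compute_lysis_metrics(synthetic_tc(0:1, 0:1)[-1]), "time course")
  tc_nofib <- structure(list(times = 0:1,
                             concentrations = matrix(0, 2, 1, dimnames = list(NULL, "X")),
                             species = "X"), class = "txasim_time_course")
  expect_error(compute_lysis_metrics(tc_nofib), "fibrin")
})

test_that("classification follows the tolerance-band rules", {
  d <- txa_dose_ladder()
  expect_identical(classify_txa_effect(d, c(100, 110, 130, 200, 400, NA))$label,
                   "anti_fibrinolytic")
  expect_identical(classify_txa_effect(d, c(400, 380, 300, 200, 150, 100))$label,
                   "pro_fibrinolytic")
  # within 5 % everywhere -> neutral
  expect_identical(classify_txa_effect(d, c(100, 101, 102, 99, 100, 103))$label,
                   "neutral")
  # mixed directions -> neutral
  expect_identical(classify_txa_effect(d, c(100, 150, 90, 200, 100, 50))$label,
                   "neutral")
  cls <- classify_txa_effect(d, rep(NA_real_, 6))
  expect_true(cls$all_undefined)
  # undefined counts as +Inf: lysis appearing at high dose is "pro"
  expect_identical(classify_txa_effect(d, c(NA, NA, NA, NA, 500, 400))$label,
                   "pro_fibrinolytic")
  expect_error(classify_txa_effect(1, 1))
})

test_that("scenario objects validate and map onto overrides", {
  sc <- scenario(tPA = 2.5e-9, A2M = 0)
  ov <- txasim:::scenario_overrides(sc)
  expect_identical(ov$A2M, 0)
  expect_identical(ov$tPA, 2.5e-9)
  expect_false("AP" %in% names(ov))  # NULL = packaged default
  expect_error(scenario(TXA = -1), ">= 0")
  expect_error(run_knockout_panel(scenario(tPA = 1e-9)), "uPA > 0")
})

test_that("dose sweeps are deterministic, sorted and de-duplicated", {
  net <- full_model()
  sw <- run_dose_sweep(scenario(uPA = 5e-9, A2M = 0, A1AT = 0,
                                solver = solver_settings(t_end = 1200,
                                                         output_points = 60)),
                       c(54e-6, 0, 54e-6), net)
  expect_identical(sw$dose, c(0, 54e-6))
  expect_identical(nrow(sw), 2L)
  sw2 <- run_dose_sweep(scenario(uPA = 5e-9, A2M = 0, A1AT = 0,
                                 solver = solver_settings(t_end = 1200,
                                                          output_points = 60)),
                        c(0, 54e-6), net)
  expect_identical(sw$lysis_time_50, sw2$lysis_time_50)

  empty <- run_dose_sweep(scenario(uPA = 5e-9), numeric(0), net)
  expect_identical(nrow(empty), 0L)
  expect_error(run_dose_sweep(scenario(uPA = 5e-9), c(-1e-6), net), ">= 0")
})

test_that("local sensitivity distinguishes inert from active parameters", {
  base <- scenario(uPA = 5e-9, A2M = 0, A1AT = 0,
                   solver = solver_settings(t_end = 4000, output_points = 150))
  # kon_y at fixed Kd: equilibrium-controlled regime -> derivative near zero
  s_kon <- local_sensitivity(base, "kon_y", delta = 9)
  expect_false(s_kon$non_differentiable)
  # scale: lysis times are ~2000 s; slope per log-unit should be tiny
  expect_lt(abs(s_kon$estimate), 0.01 * s_kon$value_up)

  expect_error(local_sensitivity(base, "k_made_up"), "unknown model parameter")
  expect_error(local_sensitivity(scenario(uPA = 5e-9), "TXA"), "zero or unset")

  # TXA dose in the tPA regime slows lysis: positive log-derivative
  s_txa <- local_sensitivity(scenario(tPA = 2.5e-9, TXA = 1e-6), "TXA",
                             delta = 0.5)
  expect_false(s_txa$non_differentiable)
  expect_gt(s_txa$estimate, 0)
})

test_that("the CLI runs a scenario end to end", {
  cfg <- withr::local_tempfile(fileext = ".json")
  writeLines('{"uPA": 5e-9, "TXA": 54e-6, "A2M": 0, "A1AT": 0,
               "solver": {"t_end": 900, "output_points": 40}}', cfg)
  out <- withr::local_tempfile(fileext = ".csv")
  expect_message(txasim_main(c("simulate", "--config", cfg, "--out", out)),
                 "wrote")
  df <- utils::read.csv(out)
  expect_identical(names(df), c("time", "species", "concentration_M"))
  expect_true(max(df$time) == 900)

  mout <- withr::local_tempfile(fileext = ".json")
  expect_message(txasim_main(c("metrics", "--in", out, "--out", mout)), "wrote")
  m <- jsonlite::read_json(mout)
  expect_true(m$fibrin_peak > 0)

  expect_error(txasim_main(c("warp", "--out", "x")), "unknown subcommand")
  expect_error(txasim_main("simulate"), "--out")
})
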