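# Scenario drivers reproducing the in-silico experiments: TXA dose sweeps
# under tPA, plasmin-inhibitor knockout panels under uPA, and tPA:uPA
# balance sweeps, plus the lysis metrics and the
# anti/neutral/pro-fibrinolytic classification they feed.

#' The printed TXA dose ladder
#'
#' The six TXA doses of the dose-response experiments
#' (0, 1, 3, 14, 54 and 3470 uM), in molar.
#' @export
txa_dose_ladder <- function() c(0, 1, 3, 14, 54, 3470) * 1e-6

#' Define a simulation scenario
#'
#' A scenario is a complete, provenance-carrying description of one run:
#' initiation (TF), activator and TXA doses, inhibitor levels and solver
#' settings.  `NULL` inhibitor levels mean "use the packaged physiological
#' value"; `0` is an explicit knockout.
#'
#' @param TF tissue factor, molar (default 5 pM).
#' @param tPA,uPA,TXA initial concentrations, molar.
#' @param AP,A1AT,A2M,PCI inhibitor levels in molar, or `NULL` for the
#'   packaged defaults.
#' @param solver a [solver_settings()].
#' @return a `txasim_scenario` list.
#' @export
scenario <- function(TF = 5e-12, tPA = 0, uPA = 0, TXA = 0,
                     AP = NULL, A1AT = NULL, A2M = NULL, PCI = NULL,
                     solver = solver_settings()) {
  conc <- c(TF = TF, tPA = tPA, uPA = uPA, TXA = TXA,
            AP = AP, A1AT = A1AT, A2M = A2M, PCI = PCI)
  if (any(conc < 0)) stop("scenario concentrations must be >= 0", call. = FALSE)
  structure(list(TF = TF, tPA = tPA, uPA = uPA, TXA = TXA,
                 AP = AP, A1AT = A1AT, A2M = A2M, PCI = PCI,
                 solver = solver),
            class = "txasim_scenario")
}

scenario_overrides <- function(sc) {
  ov <- list(TF = sc$TF, tPA = sc$tPA, uPA = sc$uPA, TXA = sc$TXA,
             AP = sc$AP, A1AT = sc$A1AT, A2M = sc$A2M, PCI = sc$PCI)
  ov[!vapply(ov, is.null, logical(1))]
}

#' Run one scenario
#'
#' @param sc a [scenario()].
#' @param network the model to integrate (default: packaged full model).
#' @return a `txasim_time_course` whose provenance echoes the scenario.
#' @export
run_scenario <- function(sc, network = default_model()) {
  stopifnot(inherits(sc, "txasim_scenario"))
  tc <- simulate_network(network, overrides = scenario_overrides(sc),
                         settings = sc$solver)
  tc$provenance$scenario <- unclass(sc)[setdiff(names(sc), "solver")]
  tc
}

# total clot signal: free fibrin plus the fibrin carried in plasmin-fibrin
# complexes
fibrin_signal <- function(tc) {
  fib <- tc$concentrations[, "Fn"]
  if ("PnFn" %in% tc$species) fib <- fib + tc$concentrations[, "PnFn"]
  fib
}

# first time y crosses below `thr` after index `from`, linearly interpolated
first_crossing_below <- function(t, y, thr, from = 1L) {
  n <- length(y)
  if (from > n) return(NA_real_)
  idx <- which(y[from:n] <= thr)
  if (length(idx) == 0L) return(NA_real_)
  i <- idx[1L] + from - 1L
  if (i == 1L) return(t[1L])
  y0 <- y[i - 1L]; y1 <- y[i]
  if (y0 <= thr || y1 == y0) return(t[i])
  t[i - 1L] + (y0 - thr) / (y0 - y1) * (t[i] - t[i - 1L])
}

#' Clot-lysis metrics of a time course
#'
#' The fibrin signal is free fibrin plus fibrin-bound plasmin complex (clot
#' mass).  Lysis time is measured from the fibrin peak: the clot must first
#' form before lysis is meaningful.
#'
#' @param tc a `txasim_time_course` containing `Fn` (and `AP` for the
#'   depletion time).
#' @param threshold_fraction lysis threshold as a fraction of peak fibrin
#'   (default 0.5, i.e. LT50).
#' @param ap_depletion_fraction AP is called depleted below this fraction of
#'   its initial level (default 1 percent).
#' @return list with `fibrin_peak` (molar), `t_peak` (s), `lysis_time_50`
#'   (s, `NA` when the threshold is never reached),
#'   `percent_fibrin_remaining_at_end` (percent of peak) and
#'   `time_of_AP_depletion` (s or `NA`).  Threshold crossings are linearly
#'   interpolated between grid points.
#' @export
compute_lysis_metrics <- function(tc, threshold_fraction = 0.5,
                                  ap_depletion_fraction = 0.01) {
  if (!inherits(tc, "txasim_time_course")) stop("not a time course", call. = FALSE)
  if (!"Fn" %in% tc$species) stop("time course lacks fibrin (Fn)", call. = FALSE)
  t <- tc$times
  fib <- fibrin_signal(tc)
  ipeak <- which.max(fib)
  peak <- fib[ipeak]
  lysis <- if (peak > 0) {
    first_crossing_below(t, fib, threshold_fraction * peak, from = ipeak)
  } else NA_real_
  pct <- if (peak > 0) 100 * fib[length(fib)] / peak else 100
  ap_t <- NA_real_
  if ("AP" %in% tc$species) {
    ap <- tc$concentrations[, "AP"]
    if (ap[1L] > 0) {
      ap_t <- first_crossing_below(t, ap, ap_depletion_fraction * ap[1L])
    }
  }
  list(fibrin_peak = peak, t_peak = t[ipeak], lysis_time_50 = lysis,
       percent_fibrin_remaining_at_end = pct, time_of_AP_depletion = ap_t)
}

#' TXA dose-response sweep
#'
#' Runs one simulation per TXA dose with everything else held fixed.
#' Deterministic: identical inputs give identical tables.
#'
#' @param base a [scenario()]; its `TXA` field is ignored.
#' @param txa_doses non-negative doses in molar; duplicates are dropped and
#'   doses sorted ascending.
#' @param network model to integrate.
#' @param keep_time_courses attach the individual time courses as an
#'   attribute (`"time_courses"`) for downstream inspection.
#' @return data.frame with one row per dose: the [compute_lysis_metrics()]
#'   fields plus `dose` (molar) and `solver_error` (NA or message).
#' @export
run_dose_sweep <- function(base, txa_doses = txa_dose_ladder(),
                           network = default_model(),
                           keep_time_courses = FALSE) {
  stopifnot(inherits(base, "txasim_scenario"))
  if (any(txa_doses < 0)) stop("TXA doses must be >= 0", call. = FALSE)
  txa_doses <- sort(unique(txa_doses))
  rows <- list(); tcs <- list()
  for (d in txa_doses) {
    sc <- base
    sc$TXA <- d
    res <- tryCatch(run_scenario(sc, network), txasim_solver_error = function(e) e)
    if (inherits(res, "txasim_solver_error")) {
      rows[[length(rows) + 1L]] <- data.frame(
        dose = d, fibrin_peak = NA_real_, t_peak = NA_real_,
        lysis_time_50 = NA_real_, percent_fibrin_remaining_at_end = NA_real_,
        time_of_AP_depletion = NA_real_, solver_error = conditionMessage(res))
      tcs[[length(tcs) + 1L]] <- NULL
    } else {
      m <- compute_lysis_metrics(res)
      rows[[length(rows) + 1L]] <- data.frame(
        dose = d, fibrin_peak = m$fibrin_peak, t_peak = m$t_peak,
        lysis_time_50 = m$lysis_time_50,
        percent_fibrin_remaining_at_end = m$percent_fibrin_remaining_at_end,
        time_of_AP_depletion = m$time_of_AP_depletion,
        solver_error = NA_character_)
      tcs[[length(tcs) + 1L]] <- res
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(dose = numeric(), fibrin_peak = numeric(), t_peak = numeric(),
               lysis_time_50 = numeric(),
               percent_fibrin_remaining_at_end = numeric(),
               time_of_AP_depletion = numeric(), solver_error = character())
  if (keep_time_courses) attr(out, "time_courses") <- tcs
  out
}

#' Classify the net TXA effect from a dose-response of lysis times
#'
#' Undefined lysis times (no lysis) are treated as infinite.  Successive
#' dose steps are compared with a relative tolerance: a step is "up" if the
#' lysis time grows by more than `tol`, "down" if it shrinks by more than
#' `tol`, flat otherwise.  The effect is `anti_fibrinolytic` if at least one
#' step is up and none is down, `pro_fibrinolytic` if at least one is down
#' and none is up, and `neutral` otherwise (all flat, or mixed directions).
#'
#' @param doses dose vector, molar.
#' @param lysis_times matching lysis times in seconds (`NA` = no lysis).
#' @param tol relative tolerance for "similar times" (default 5 percent).
#' @return list with `label` (one of `anti_fibrinolytic`, `neutral`,
#'   `pro_fibrinolytic`), `all_undefined` (no dose lysed at all), and the
#'   `evidence` table of (dose, lysis_time_50).
#' @export
classify_txa_effect <- function(doses, lysis_times, tol = 0.05) {
  stopifnot(length(doses) == length(lysis_times), length(doses) >= 2L)
  o <- order(doses)
  doses <- doses[o]
  lt <- lysis_times[o]
  lt[is.na(lt)] <- Inf
  up <- down <- FALSE
  for (i in seq_len(length(lt) - 1L)) {
    a <- lt[i]; b <- lt[i + 1L]
    if (is.infinite(a) && is.infinite(b)) next
    if (is.infinite(b)) { up <- TRUE; next }
    if (is.infinite(a)) { down <- TRUE; next }
    if (b > a * (1 + tol)) up <- TRUE
    else if (b < a * (1 - tol)) down <- TRUE
  }
  label <- if (up && !down) "anti_fibrinolytic"
           else if (down && !up) "pro_fibrinolytic"
           else "neutral"
  list(label = label,
       all_undefined = all(is.infinite(lt)),
       evidence = data.frame(dose = doses, lysis_time_50 = lysis_times[o]))
}

#' Plasmin-inhibitor knockout panel
#'
#' Four TXA dose sweeps under uPA: (A) A2M and A1AT both at physiological
#' levels, (B) A2M only (A1AT knocked out), (C) A1AT only (A2M knocked
#' out), (D) neither.  Antiplasmin stays at its physiological level
#' throughout; it is the exhaustible inhibitor whose depletion the panel
#' exposes.
#'
#' @param base a [scenario()] with `uPA > 0`.
#' @param txa_doses doses in molar.
#' @param network model to integrate.
#' @return named list of panels `A`..`D`, each with elements `sweep` (the
#'   [run_dose_sweep()] table) and `classification`
#'   ([classify_txa_effect()] output).
#' @export
run_knockout_panel <- function(base, txa_doses = txa_dose_ladder(),
                               network = default_model()) {
  stopifnot(inherits(base, "txasim_scenario"))
  if (is.null(base$uPA) || base$uPA <= 0) {
    stop("knockout panel requires a scenario with uPA > 0", call. = FALSE)
  }
  panels <- list(A = c(a2m = NA, a1at = NA),  # NA = physiological
                 B = c(a2m = NA, a1at = 0),
                 C = c(a2m = 0, a1at = NA),
                 D = c(a2m = 0, a1at = 0))
  out <- list()
  for (p in names(panels)) {
    sc <- base
    if (!is.na(panels[[p]]["a2m"])) sc$A2M <- panels[[p]][["a2m"]]
    if (!is.na(panels[[p]]["a1at"])) sc$A1AT <- panels[[p]][["a1at"]]
    sw <- run_dose_sweep(sc, txa_doses, network)
    out[[p]] <- list(sweep = sw,
                     classification = classify_txa_effect(sw$dose, sw$lysis_time_50))
  }
  out
}

#' tPA:uPA balance sweep
#'
#' Holds uPA fixed, knocks out A2M and A1AT (the regime in which the uPA
#' pathway turns TXA pro-fibrinolytic), and runs a TXA dose sweep at each
#' tPA level.  As tPA rises the classification moves from pro-fibrinolytic
#' through neutral to anti-fibrinolytic.
#'
#' @param base a [scenario()]; its `uPA` is kept, `A2M`/`A1AT` are forced
#'   to zero.
#' @param tpa_levels tPA concentrations in molar (default 0.1, 1, 2.5 nM).
#' @param txa_doses doses in molar.
#' @param network model to integrate.
#' @return named list (one entry per tPA level, names in nM) of
#'   `sweep` + `classification` pairs.
#' @export
run_tpa_upa_balance <- function(base, tpa_levels = c(0.1, 1, 2.5) * 1e-9,
                                txa_doses = txa_dose_ladder(),
                                network = default_model()) {
  stopifnot(inherits(base, "txasim_scenario"))
  out <- list()
  for (tpa in tpa_levels) {
    sc <- base
    sc$tPA <- tpa
    sc$A2M <- 0
    sc$A1AT <- 0
    sw <- run_dose_sweep(sc, txa_doses, network)
    out[[sprintf("tPA_%gnM", tpa * 1e9)]] <-
      list(tPA = tpa, sweep = sw,
           classification = classify_txa_effect(sw$dose, sw$lysis_time_50))
  }
  out
}

#' Local parameter sensitivity of the lysis time
#'
#' Two-sided finite difference of `lysis_time_50` with respect to the
#' logarithm of one model parameter, holding the scenario fixed.  Rate
#' parameters are looked up in the four parameter blocks of
#' [build_full_network()]; scenario concentration fields (`TXA`, `tPA`,
#' ...) are perturbed directly.  Note that perturbing `kon_x`/`kon_y` holds
#' the corresponding Kd fixed by construction (koff = Kd * kon), which is
#' exactly the equilibrium-control robustness probe.
#'
#' @param base a [scenario()].
#' @param parameter parameter name (e.g. `"kon_y"`, `"upa_kcat"`,
#'   `"k_ap"`, `"TXA"`).
#' @param delta relative perturbation; the parameter is scaled by
#'   `(1 + delta)` and `1/(1 + delta)` (so `delta = 9` probes a factor 10).
#' @return list with `estimate` (d lysis_time_50 / d log parameter),
#'   `delta`, the two perturbed metric values, and `non_differentiable`
#'   (TRUE when the metric is undefined on either side).
#' @export
local_sensitivity <- function(base, parameter, delta = 0.5) {
  stopifnot(inherits(base, "txasim_scenario"), delta > 0)
  blocks <- list(txa_binding = names(formals(txa_binding_params)),
                 activation = names(formals(activation_params)),
                 inhibitors = names(formals(inhibitor_params)),
                 fibrin = names(formals(fibrin_params)))
  scen_fields <- c("TF", "tPA", "uPA", "TXA", "AP", "A1AT", "A2M", "PCI")
  in_block <- names(blocks)[vapply(blocks, function(b) parameter %in% b, logical(1))]
  metric_at <- function(factor) {
    if (length(in_block)) {
      # rebuild the perturbed parameter block, everything else at defaults
      args <- list()
      cons <- list(txa_binding = txa_binding_params,
                   activation = activation_params,
                   inhibitors = inhibitor_params,
                   fibrin = fibrin_params)
      blk <- in_block[1L]
      defaults <- cons[[blk]]()
      val <- defaults[[parameter]] * factor
      args[[blk]] <- do.call(cons[[blk]],
                             stats::setNames(list(val), parameter))
      net <- do.call(build_full_network, args)
    } else if (parameter %in% scen_fields) {
      net <- build_full_network()
    } else {
      stop("unknown model parameter: '", parameter, "'", call. = FALSE)
    }
    sc <- base
    if (parameter %in% scen_fields) {
      cur <- sc[[parameter]]
      if (is.null(cur) || cur <= 0) {
        stop("scenario field '", parameter,
             "' is zero or unset; log-sensitivity undefined", call. = FALSE)
      }
      sc[[parameter]] <- cur * factor
    }
    compute_lysis_metrics(run_scenario(sc, net))$lysis_time_50
  }
  f <- 1 + delta
  up <- metric_at(f)
  dn <- metric_at(1 / f)
  nd <- is.na(up) || is.na(dn)
  list(estimate = if (nd) NA_real_ else (up - dn) / (2 * log(f)),
       delta = delta, value_up = up, value_down = dn,
       non_differentiable = nd)
}
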