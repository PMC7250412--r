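# Assembling and integrating the ODE system
#
#   d[X]/dt = sum_r  nu(X, r) * v_r(state)
#
# where nu is the net stoichiometry and v_r the kinetic-law flux.  The
# integration itself happens in compiled code (see src/txasim.cpp): a
# linearly implicit extrapolation scheme with the exact analytic Jacobian,
# the class of method required for a network spanning pM..mM concentrations
# and millisecond..hour timescales.

kind_code <- c(mass_action_irreversible = 0L, mass_action_reversible = 1L,
               michaelis_menten = 2L, michaelis_menten_activated = 3L)

# Lower a validated network to the index-based form the C++ core consumes.
compile_network <- function(network) {
  nms <- species_names(network)
  idx <- function(x) {
    i <- match(x, nms)
    if (anyNA(i)) stop("unknown species: ", paste(x[is.na(i)], collapse = ", "),
                       call. = FALSE)
    i - 1L
  }
  lapply(network$reactions, function(r) {
    p <- r$law$params
    par <- c(k = 0, kon = 0, koff = 0, kcat = 0, Km = 0, actF = 1, actKm = 1)
    for (nm in c("k", "kon", "koff", "kcat", "Km")) {
      if (!is.null(p[[nm]])) par[nm] <- p[[nm]]
    }
    if (!is.null(p$act_factor)) par["actF"] <- p$act_factor
    if (!is.null(p$act_Km)) par["actKm"] <- p$act_Km
    list(kind = kind_code[[r$law$kind]],
         ridx = idx(names(r$reactants)), rst = unname(r$reactants),
         pidx = idx(names(r$products)), pst = unname(r$products),
         enz = if (is.null(r$enzyme)) -1L else idx(r$enzyme),
         act = if (is.null(r$activator)) -1L else idx(r$activator),
         par = unname(par))
  })
}

#' Instantaneous reaction fluxes
#'
#' Evaluates every kinetic law at a given state.  Reversible mass-action
#' reactions report their net forward flux, so composing the flux vector
#' with [stoichiometric_matrix()] yields the exact time derivative.
#'
#' @param network a validated `txasim_network`.
#' @param state numeric state vector in molar, in network species order
#'   (names, if present, are checked).
#' @return named numeric vector of fluxes (molar per second), one per
#'   reaction.
#' @export
instantaneous_fluxes <- function(network, state) {
  nms <- species_names(network)
  if (length(state) != length(nms)) {
    stop(sprintf("state has %d entries but network has %d species",
                 length(state), length(nms)), call. = FALSE)
  }
  if (!is.null(names(state)) && !identical(names(state), nms)) {
    state <- state[nms]
    if (anyNA(state)) stop("state names do not match network species", call. = FALSE)
  }
  fx <- cpp_fluxes(compile_network(network), as.numeric(state))
  stats::setNames(fx, vapply(network$reactions, `[[`, character(1), "id"))
}

#' Build the ODE right-hand side of a network
#'
#' @param network a validated `txasim_network`.
#' @return a deterministic, side-effect-free function `f(state, t = 0)`
#'   returning d(state)/dt in molar per second.  The system is autonomous;
#'   `t` is accepted for interface compatibility only.
#' @export
build_rhs <- function(network) {
  stop_if_invalid(network)
  creac <- compile_network(network)
  n <- length(network$species)
  function(state, t = 0) {
    stopifnot(length(state) == n)
    as.numeric(cpp_rhs(creac, as.numeric(state)))
  }
}

#' Solver settings
#'
#' @param t_end end time in seconds (start is 0).
#' @param output_points number of equally spaced output times (used when
#'   `output_times` is `NULL`).
#' @param output_times explicit strictly increasing output grid in seconds;
#'   overrides `output_points`.
#' @param rtol,atol relative / absolute (molar) integration tolerances.
#' @param max_step maximum macro step in seconds (`Inf` to disable).
#' @param h_init initial step size; `NULL` for automatic.
#' @param nonneg_policy negative concentrations within roundoff of zero are
#'   clipped at output; substantially negative values abort the run with a
#'   structured solver error (only policy currently implemented).
#' @return a `txasim_solver_settings` list.
#' @export
solver_settings <- function(t_end = 7200, output_points = 400,
                            output_times = NULL, rtol = 1e-8, atol = 1e-14,
                            max_step = Inf, h_init = NULL,
                            nonneg_policy = "clip_to_zero_below_threshold") {
  stopifnot(t_end > 0, rtol > 0, atol > 0)
  nonneg_policy <- match.arg(nonneg_policy,
                             c("clip_to_zero_below_threshold", "reject_step"))
  structure(list(t_end = t_end, output_points = output_points,
                 output_times = output_times, rtol = rtol, atol = atol,
                 max_step = max_step, h_init = h_init,
                 nonneg_policy = nonneg_policy),
            class = "txasim_solver_settings")
}

#' Integrate a reaction network
#'
#' Deterministic stiff integration of the network ODEs from its initial
#' concentrations (optionally overridden per species).  On solver failure a
#' condition of class `txasim_solver_error` is signalled carrying the last
#' good state and time.
#'
#' @param network a validated `txasim_network`.
#' @param overrides named list/vector of molar initial-concentration
#'   overrides (e.g. `list(TXA = 54e-6)`).
#' @param settings a [solver_settings()].
#' @return a `txasim_time_course`: list with `times` (seconds),
#'   `concentrations` (time x species matrix, molar), `species`, solver
#'   diagnostics, and full provenance (network metadata, overrides,
#'   settings).
#' @export
simulate_network <- function(network, overrides = NULL,
                             settings = solver_settings()) {
  stop_if_invalid(network)
  y0 <- initial_state(network, overrides)
  times <- settings$output_times
  if (is.null(times)) {
    times <- seq(0, settings$t_end, length.out = max(2L, settings$output_points))
  }
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("output times must be strictly increasing", call. = FALSE)
  }
  res <- cpp_simulate(compile_network(network), as.numeric(y0), times,
                      settings$rtol, settings$atol,
                      if (is.finite(settings$max_step)) settings$max_step else -1,
                      if (is.null(settings$h_init)) -1 else settings$h_init)
  if (!identical(res$status, "ok")) {
    cond <- structure(
      class = c("txasim_solver_error", "error", "condition"),
      list(message = paste0("solver failure: ", res$message,
                            sprintf(" (t = %.6g s)", res$t_reached)),
           call = sys.call(),
           t_reached = res$t_reached,
           last_state = stats::setNames(res$last_state, names(y0))))
    stop(cond)
  }
  conc <- res$Y
  dimnames(conc) <- list(NULL, names(y0))
  structure(list(times = times,
                 concentrations = conc,
                 species = names(y0),
                 diagnostics = res[c("n_steps", "n_fev", "n_jac", "n_reject")],
                 provenance = list(network = network$metadata,
                                   overrides = as.list(overrides),
                                   settings = unclass(settings))),
            class = "txasim_time_course")
}

#' @export
print.txasim_time_course <- function(x, ...) {
  cat(sprintf("<txasim_time_course> %d species x %d times, t in [%g, %g] s (%g steps)\n",
              length(x$species), length(x$times), min(x$times), max(x$times),
              x$diagnostics$n_steps))
  invisible(x)
}

#' @export
as.data.frame.txasim_time_course <- function(x, row.names = NULL,
                                             optional = FALSE,
                                             format = c("wide", "tidy"), ...) {
  format <- match.arg(format)
  if (format == "wide") {
    return(data.frame(time = x$times, x$concentrations, check.names = FALSE))
  }
  data.frame(time = rep(x$times, times = length(x$species)),
             species = rep(x$species, each = length(x$times)),
             concentration_M = as.vector(x$concentrations))
}

#' Export a time course to CSV
#'
#' Writes the concentrations in tidy (`time, species, concentration_M`) or
#' wide layout, plus a JSON sidecar `<path>.provenance.json` echoing the
#' scenario configuration.
#'
#' @param tc a `txasim_time_course`.
#' @param path output CSV path.
#' @param format `"tidy"` or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_time_course <- function(tc, path, format = c("tidy", "wide")) {
  format <- match.arg(format)
  utils::write.csv(as.data.frame(tc, format = format), path,
                   row.names = FALSE)
  jsonlite::write_json(tc$provenance, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
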