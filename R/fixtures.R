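# Programmatic test fixtures: tiny networks with known closed-form
# solutions.  These power the solver-oracle and property tests; nothing is
# stored on disk.

# Solve w + log(w) = a (equivalent to w*exp(w) = exp(a)) for w > 0.
# Stable for very large `a`, which arises in the zero-order MM regime.
lambert_w_log <- function(a) {
  vapply(a, function(ai) {
    w <- if (ai > 1) ai - log(ai) else exp(ai)  # starting guess per regime
    for (i in 1:100) {
      f <- w + log(w) - ai
      wn <- w - f * w / (w + 1)
      if (wn <= 0) wn <- w / 2
      if (abs(wn - w) <= 1e-15 * max(1, abs(wn))) { w <- wn; break }
      w <- wn
    }
    w
  }, numeric(1))
}

#' Generate an analytic test fixture
#'
#' Builds a small validated reaction network together with (where a closed
#' form exists) an exact solution evaluator, used throughout the test suite
#' as an independent oracle for the stiff integrator.
#'
#' Kinds:
#' \describe{
#'   \item{`irreversible_decay`}{`A -> B`, rate `k`; exponential decay.}
#'   \item{`reversible_binding`}{`A + B <-> C`; the single quadratic Riccati
#'     ODE integrates in closed form.}
#'   \item{`mm_enzyme`}{`S -> P` catalysed by `E`; the integrated
#'     Michaelis-Menten equation solved with a Lambert-W evaluation.}
#'   \item{`open_chain`}{`A -> B -> C` two-step chain; bi-exponential.}
#'   \item{`full_model_subset`}{the TXA-plasmin(ogen) binding subsystem only
#'     (no activation, no inhibitors); no closed-form time course, its
#'     equilibrium is [equilibrium_partition()].}
#' }
#'
#' @param fixture fixture kind, see Details.  (The formal is named
#'   `fixture`, not `kind`, so that rate arguments like `k = ...` cannot
#'   partially match it.)
#' @param ... kind-specific parameters with sensible defaults:
#'   `irreversible_decay(k = 0.01, A0 = 1e-6)`;
#'   `reversible_binding(kon = 1e6, koff = 1, A0 = 2e-6, B0 = 2e-6, C0 = 0)`;
#'   `mm_enzyme(kcat = 1, Km = 1e-6, E0 = 1e-8, S0 = 1e-5)`;
#'   `open_chain(k1 = 0.02, k2 = 0.005, A0 = 1e-6)`;
#'   `full_model_subset(params = txa_binding_params(), Pg0 = 2e-6,
#'     Pn0 = 0, TXA0 = 1e-6)`.
#' @return list with elements `network` (a validated `txasim_network`) and
#'   `analytic` (`function(times)` returning a times x species matrix in
#'   molar, or `NULL` when no closed form exists).
#' @export
make_fixture <- function(fixture, ...) {
  args <- list(...)
  arg <- function(name, default) {
    if (!is.null(args[[name]])) args[[name]] else default
  }
  switch(fixture,
    irreversible_decay = {
      k <- arg("k", 0.01); A0 <- arg("A0", 1e-6)
      net <- reaction_network(
        list(species("A", A0), species("B", 0)),
        list(reaction("decay", c(A = 1), c(B = 1),
                      kinetic_law("mass_action_irreversible", k = k),
                      note = "fixture: exponential decay")),
        name = "fixture_irreversible_decay")
      analytic <- function(times) {
        A <- A0 * exp(-k * times)
        cbind(A = A, B = A0 - A)
      }
      list(network = net, analytic = analytic)
    },
    reversible_binding = {
      kon <- arg("kon", 1e6); koff <- arg("koff", 1)
      A0 <- arg("A0", 2e-6); B0 <- arg("B0", 2e-6); C0 <- arg("C0", 0)
      net <- reaction_network(
        list(species("A", A0), species("B", B0), species("C", C0)),
        list(reaction("bind", c(A = 1, B = 1), c(C = 1),
                      kinetic_law("mass_action_reversible", kon = kon, koff = koff),
                      note = "fixture: reversible bimolecular binding")),
        name = "fixture_reversible_binding")
      # dc/dt = kon (c - r1)(c - r2) for totals a = A0+C0, b = B0+C0;
      # r2 <= min(a, b) is the equilibrium complex concentration.
      a <- A0 + C0; b <- B0 + C0; Kd <- koff / kon
      disc <- sqrt((a + b + Kd)^2 - 4 * a * b)
      r1 <- ((a + b + Kd) + disc) / 2
      r2 <- ((a + b + Kd) - disc) / 2
      K <- (C0 - r1) / (C0 - r2)
      theta <- kon * (r1 - r2)
      analytic <- function(times) {
        E <- exp(-theta * times) / K
        C <- (r1 * E - r2) / (E - 1)
        C[!is.finite(E)] <- C0  # t = 0 guard when K == 0 is impossible; keep safe
        cbind(A = a - C, B = b - C, C = C)
      }
      list(network = net, analytic = analytic)
    },
    mm_enzyme = {
      kcat <- arg("kcat", 1); Km <- arg("Km", 1e-6)
      E0 <- arg("E0", 1e-8); S0 <- arg("S0", 1e-5)
      net <- reaction_network(
        list(species("E", E0), species("S", S0), species("P", 0)),
        list(reaction("cat", c(S = 1), c(P = 1),
                      kinetic_law("michaelis_menten", kcat = kcat, Km = Km),
                      enzyme = "E",
                      note = "fixture: single Michaelis-Menten conversion")),
        name = "fixture_mm_enzyme")
      analytic <- function(times) {
        # integrated MM: S(t) = Km * W(S0/Km * exp((S0 - kcat E0 t)/Km)),
        # evaluated through w + log(w) = a to avoid overflow for S0 >> Km
        aa <- log(S0 / Km) + (S0 - kcat * E0 * times) / Km
        S <- Km * lambert_w_log(aa)
        cbind(E = rep(E0, length(times)), S = S, P = S0 - S)
      }
      list(network = net, analytic = analytic)
    },
    open_chain = {
      k1 <- arg("k1", 0.02); k2 <- arg("k2", 0.005); A0 <- arg("A0", 1e-6)
      net <- reaction_network(
        list(species("A", A0), species("B", 0), species("C", 0)),
        list(reaction("step1", c(A = 1), c(B = 1),
                      kinetic_law("mass_action_irreversible", k = k1)),
             reaction("step2", c(B = 1), c(C = 1),
                      kinetic_law("mass_action_irreversible", k = k2))),
        name = "fixture_open_chain")
      analytic <- function(times) {
        A <- A0 * exp(-k1 * times)
        B <- if (abs(k1 - k2) < 1e-12 * (k1 + k2)) {
          A0 * k1 * times * exp(-k1 * times)
        } else {
          A0 * k1 / (k2 - k1) * (exp(-k1 * times) - exp(-k2 * times))
        }
        cbind(A = A, B = B, C = A0 - A - B)
      }
      list(network = net, analytic = analytic)
    },
    full_model_subset = {
      params <- arg("params", txa_binding_params())
      Pg0 <- arg("Pg0", 2e-6); Pn0 <- arg("Pn0", 0); TXA0 <- arg("TXA0", 1e-6)
      sp <- list(species("Pg", Pg0), species("Pgx", 0), species("Pgy", 0),
                 species("Pgxy", 0), species("Pn", Pn0), species("Pny", 0),
                 species("TXA", TXA0))
      net <- reaction_network(sp, expand_binding_reactions(params),
                              name = "fixture_txa_binding_subsystem")
      list(network = net, analytic = NULL)
    },
    stop("unknown fixture kind: '", fixture, "'", call. = FALSE)
  )
}
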