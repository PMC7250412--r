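# Shared helpers: tiny networks built in code, plus a per-session cache so
# expensive full-model sweeps are computed once per test run.

tiny_decay_network <- function(k = 1, A0 = 1e-6) {
  reaction_network(
    list(species("A", A0), species("B", 0)),
    list(reaction("r1", c(A = 1), c(B = 1),
                  kinetic_law("mass_action_irreversible", k = k))),
    name = "tiny_decay")
}

two_state_network <- function(kf = 2, kr = 1, A0 = 1e-6, B0 = 0) {
  reaction_network(
    list(species("A", A0), species("B", B0)),
    list(reaction("fwd", c(A = 1), c(B = 1),
                  kinetic_law("mass_action_reversible", kon = kf, koff = kr))),
    name = "two_state")
}

.cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

full_model <- function() cached("full_model", build_full_network())

# numeric gradient of a scalar function (central differences)
num_deriv <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)
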