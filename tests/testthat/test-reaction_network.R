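test_that("minimal model files load, validate and round-trip", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{
    "schema": "txasim-model/1", "name": "mini",
    "species": [
      {"name": "A", "initial_concentration": 1, "unit": "uM", "tags": ["zymogen"]},
      {"name": "B", "initial_concentration": 0, "unit": "uM"}
    ],
    "reactions": [
      {"id": "r1", "reactants": [{"species": "A", "stoich": 1}],
       "products": [{"species": "B", "stoich": 1}],
       "law": {"kind": "mass_action_irreversible", "params": {"k": 1}}}
    ]}', f)
  net <- load_network(f)
  expect_s3_class(net, "txasim_network")
  expect_length(net$species, 2L)
  expect_length(net$reactions, 1L)
  # concentrations are molar internally
  expect_identical(initial_state(net)[["A"]], 1e-6)

  # full-precision round trip, including an awkward value
  net$species[[1L]]$initial_concentration <- 1.1e-6 * (1 + 2^-50)
  f2 <- withr::local_tempfile(fileext = ".json")
  write_network(net, f2)
  net2 <- load_network(f2)
  expect_identical(initial_state(net2), initial_state(net))
  expect_identical(lapply(net2$reactions, function(r) r$law$params),
                   lapply(net$reactions, function(r) r$law$params))
})

test_that("schema violations are reported with the offending record", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"species": [{"name": "A", "initial_concentration": 1}],
    "reactions": [{"id": "bad", "reactants": [{"species": "Q"}],
      "products": [], "law": {"kind": "mass_action_irreversible",
      "params": {"k": 1}}}]}', f)
  expect_error(load_network(f), "Q")
  f2 <- withr::local_tempfile(fileext = ".json")
  writeLines('{"species": []}', f2)
  expect_error(load_network(f2), "reactions")
  expect_error(load_network(file.path(tempdir(), "no_such.json")), "not found")
})

test_that("validate_network returns violations as data, not exceptions", {
  good <- two_state_network()
  expect_identical(nrow(validate_network(good)), 0L)

  bad_k <- reaction_network(
    list(species("A", 1e-6), species("B", 0)),
    list(reaction("neg", c(A = 1), c(B = 1),
                  kinetic_law("mass_action_irreversible", k = -1))))
  v <- validate_network(bad_k)
  expect_identical(nrow(v), 1L)
  expect_identical(v$id, "neg")
  expect_match(v$message, "non-positive")

  two_sub <- reaction_network(
    list(species("A", 1e-6), species("B", 1e-6), species("E", 1e-9),
         species("P", 0)),
    list(reaction("mm2", c(A = 1, B = 1), c(P = 1),
                  kinetic_law("michaelis_menten", kcat = 1, Km = 1e-6),
                  enzyme = "E")))
  v <- validate_network(two_sub)
  expect_identical(nrow(v), 1L)
  expect_match(v$message, "exactly one substrate")

  # wrong parameter set for the kind
  extra <- reaction_network(
    list(species("A", 1e-6), species("B", 0)),
    list(reaction("xp", c(A = 1), c(B = 1),
                  kinetic_law("mass_action_irreversible", k = 1, Km = 1))))
  expect_match(validate_network(extra)$message, "requires parameters")
})

test_that("packaged full model has the expected species and structure", {
  net <- default_model()
  expect_identical(nrow(validate_network(net)), 0L)
  expect_true(all(c("TF", "tPA", "uPA", "TXA", "Pg", "Pgx", "Pgy", "Pgxy",
                    "Pn", "Pny", "AP", "A1AT", "A2M", "PCI", "Fg", "Fn")
                  %in% species_names(net)))
  # nominal 2:1 plasminogen : antiplasmin
  y0 <- initial_state(net)
  expect_identical(y0[["Pg"]] / y0[["AP"]], 2)
})

test_that("conserved moieties are exact integer left null vectors", {
  # closed two-state system: the only law is A + B
  laws <- conserved_moieties(two_state_network())
  expect_length(laws, 1L)
  expect_identical(sort(names(laws[[1L]])), c("A", "B"))
  expect_identical(unname(laws[[1L]]), c(1L, 1L))

  # open chain A -> B -> C conserves A + B + C
  chain <- make_fixture("open_chain")$network
  laws <- conserved_moieties(chain)
  expect_length(laws, 1L)
  expect_identical(unname(laws[[1L]][c("A", "B", "C")]), c(1L, 1L, 1L))

  # every law of the full model is an exact integer null vector of t(S)
  net <- full_model()
  S <- stoichiometric_matrix(net)
  laws <- conserved_moieties(net)
  expect_gt(length(laws), 0L)
  for (L in laws) {
    v <- numeric(nrow(S)); names(v) <- rownames(S)
    v[names(L)] <- L
    expect_identical(max(abs(t(S) %*% v)), 0)
  }
})

test_that("full model conserves total TXA and the plasminogen moiety", {
  net <- full_model()
  laws <- conserved_moieties(net)
  # total TXA: coefficient 1 on free TXA and on every TXA-bound species
  txa_law <- Filter(function(L) "TXA" %in% names(L), laws)
  expect_gte(length(txa_law), 1L)
  L <- txa_law[[1L]]
  txa_carriers <- c(TXA = 1L, Pgx = 1L, Pgy = 1L, Pgxy = 2L, Pny = 1L)
  expect_identical(L[names(txa_carriers)], txa_carriers)

  # the canonical total-plasminogen-moiety vector (all Pg variants, plasmin
  # variants and their inhibitor complexes at coefficient 1) is an exact
  # conservation law of the packaged model
  S <- stoichiometric_matrix(net)
  v <- numeric(nrow(S)); names(v) <- rownames(S)
  v[c("Pg", "Pgx", "Pgy", "Pgxy", "Pn", "Pny", "PnFn",
      "AP_Pn", "A1AT_Pn", "A2M_Pn")] <- 1
  expect_identical(max(abs(t(S) %*% v)), 0)
  # and the returned basis spans a law touching the plasminogen pool
  expect_gte(length(Filter(function(L) "Pg" %in% names(L), laws)), 1L)
})

test_that("SBML export produces a well-formed document", {
  skip_if_not_installed("xml2")
  f <- withr::local_tempfile(fileext = ".xml")
  export_sbml(two_state_network(), f)
  doc <- xml2::read_xml(f)
  find <- function(tag) xml2::xml_find_all(doc, sprintf("//*[local-name()='%s']", tag))
  expect_identical(length(find("species")), 2L)
  expect_identical(length(find("reaction")), 1L)
  expect_identical(length(find("math")), 1L)
  expect_identical(length(find("kineticLaw")), 1L)
})
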