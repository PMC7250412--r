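# Assembly of the packaged full model: coagulation cascade fragment (data)
# + generated fibrinolysis / TXA-binding reactions (code).

.txasim_cache <- new.env(parent = emptyenv())

#' Build the full coagulation-fibrinolysis network
#'
#' Merges the coagulation cascade fragment with the fibrinolysis species and
#' the generated activation / inhibition / TXA-binding reactions.  Species
#' shared between the two sections (fibrinogen, fibrin) are kept once, with
#' the cascade's initial concentrations.
#'
#' @param txa_binding a [txa_binding_params()].
#' @param activation an [activation_params()].
#' @param inhibitors an [inhibitor_params()].
#' @param fibrin a [fibrin_params()].
#' @param cascade optional cascade fragment (path or `txasim_network`);
#'   defaults to the packaged fragment.
#' @return a validated `txasim_network`.
#' @export
build_full_network <- function(txa_binding = txa_binding_params(),
                               activation = activation_params(),
                               inhibitors = inhibitor_params(),
                               fibrin = fibrin_params(),
                               cascade = NULL) {
  coag <- build_coagulation_reactions(cascade)
  fib_sp <- fibrinolysis_species()
  have <- vapply(coag$species, function(s) s$name, character(1))
  fib_sp <- fib_sp[!vapply(fib_sp, function(s) s$name %in% have, logical(1))]
  rx <- c(coag$reactions,
          build_fibrinolysis_reactions(act = activation, inh = inhibitors,
                                       txa = txa_binding, fib = fibrin,
                                       include_binding = TRUE))
  net <- reaction_network(
    c(coag$species, fib_sp), rx,
    name = "txa_fibrinolysis_full",
    version = "1",
    provenance = "TF-initiated coagulation + fibrinolysis with two-site TXA binding")
  stop_if_invalid(net)
  net
}

#' The packaged full model
#'
#' Loads (and caches) the packaged model file
#' `inst/extdata/txa_fibrinolysis_model.json`, which is generated by
#' `tools/make_model.R` from [build_full_network()] with all-default
#' parameters.
#'
#' @param force reload from disk even if cached.
#' @return a validated `txasim_network`.
#' @export
default_model <- function(force = FALSE) {
  if (!force && !is.null(.txasim_cache$default_model)) {
    return(.txasim_cache$default_model)
  }
  p <- system.file("extdata", "txa_fibrinolysis_model.json", package = "txasim")
  net <- if (nzchar(p)) load_network(p) else build_full_network()
  .txasim_cache$default_model <- net
  net
}
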