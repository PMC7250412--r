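#' Concentration unit handling
#'
#' All internal state in txasim is molar (M) and all times are seconds.
#' Display units appear only at the I/O boundary (model files, CSV export).
#'
#' @param x numeric vector of concentrations expressed in `unit`.
#' @param unit one of `"M"`, `"mM"`, `"uM"` (alias `"μM"`), `"nM"`, `"pM"`.
#' @return `to_molar()` returns `x` in molar; `from_molar()` the reverse.
#' @examples
#' to_molar(5, "pM")      # 5e-12
#' from_molar(1.1e-6, "uM")  # 1.1
#' @export
to_molar <- function(x, unit) {
  x * unit_scale(unit)
}

#' @rdname to_molar
#' @export
from_molar <- function(x, unit) {
  x / unit_scale(unit)
}

unit_scale <- function(unit) {
  stopifnot(is.character(unit), length(unit) == 1L)
  # accept the Greek mu spelling used in print
  if (identical(unit, "μM")) unit <- "uM"
  scale <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12)[unit]
  if (is.na(scale)) {
    stop("unknown concentration unit: '", unit, "'", call. = FALSE)
  }
  unname(scale)
}

.valid_units <- c("M", "mM", "uM", "μM", "nM", "pM")
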