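# Exact conserved-moiety analysis.
#
# A conservation law is an integer vector L over species with L . DeltaS = 0
# for the net stoichiometry DeltaS of every reaction, i.e. an element of the
# left null space of the stoichiometric matrix.  The computation is done in
# exact rational arithmetic (numerator/denominator pairs of integer-valued
# doubles) so that the returned laws satisfy L %*% S == 0 exactly in integer
# arithmetic, which the test suite asserts by direct multiplication.

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0.5) {
    t <- a %% b
    a <- b
    b <- t
  }
  a
}

gcd_vec <- function(x) {
  g <- 0
  for (v in x) g <- gcd2(g, v)
  g
}

# Reduced row echelon form of an integer matrix in rational arithmetic.
# Returns num/den matrices plus the pivot column index of each nonzero row.
rat_rref <- function(M) {
  m <- nrow(M); n <- ncol(M)
  num <- M
  den <- matrix(1, m, n)
  simplify <- function(i) {
    for (j in seq_len(n)) {
      if (num[i, j] == 0) { den[i, j] <<- 1; next }
      g <- gcd2(num[i, j], den[i, j])
      if (g > 1) { num[i, j] <<- num[i, j] / g; den[i, j] <<- den[i, j] / g }
      if (den[i, j] < 0) { num[i, j] <<- -num[i, j]; den[i, j] <<- -den[i, j] }
    }
  }
  pivots <- integer(0)
  row <- 1L
  for (col in seq_len(n)) {
    if (row > m) break
    piv <- which(num[row:m, col] != 0)
    if (length(piv) == 0L) next
    piv <- piv[1L] + row - 1L
    if (piv != row) {
      tmp <- num[row, ]; num[row, ] <- num[piv, ]; num[piv, ] <- tmp
      tmp <- den[row, ]; den[row, ] <- den[piv, ]; den[piv, ] <- tmp
    }
    # scale pivot row to leading 1
    pn <- num[row, col]; pd <- den[row, col]
    for (j in seq_len(n)) {
      num[row, j] <- num[row, j] * pd
      den[row, j] <- den[row, j] * pn
    }
    simplify(row)
    # eliminate the column from every other row
    for (i in seq_len(m)) {
      if (i == row || num[i, col] == 0) next
      fn <- num[i, col]; fd <- den[i, col]
      for (j in seq_len(n)) {
        # row_i <- row_i - f * row_row
        an <- num[i, j]; ad <- den[i, j]
        bn <- num[row, j] * fn; bd <- den[row, j] * fd
        num[i, j] <- an * bd - bn * ad
        den[i, j] <- ad * bd
      }
      simplify(i)
    }
    pivots <- c(pivots, col)
    row <- row + 1L
  }
  list(num = num, den = den, pivots = pivots)
}

#' Conserved moieties of a reaction network
#'
#' Computes an integer basis of the left null space of the net stoichiometric
#' matrix using exact rational elimination.  Each returned law `L` satisfies
#' `sum(L * net_change)` equal to zero for every reaction, exactly.  For the
#' packaged full model the basis includes total TXA (free TXA plus every
#' TXA-bound species) and the total plasminogen moiety, reflecting that TXA
#' binding is reversible and TXA is never consumed.
#'
#' @param network a validated `txasim_network`.
#' @return list of conservation laws, each a named integer vector holding the
#'   nonzero species coefficients.
#' @export
conserved_moieties <- function(network) {
  stop_if_invalid(network)
  S <- stoichiometric_matrix(network)
  N <- t(S)  # reactions x species; null space of N = left null space of S
  nms <- colnames(N)
  n <- ncol(N)
  if (nrow(N) == 0L) {
    return(lapply(nms, function(s) stats::setNames(1L, s)))
  }
  rr <- rat_rref(N)
  free_cols <- setdiff(seq_len(n), rr$pivots)
  laws <- list()
  for (f in free_cols) {
    vn <- numeric(n); vd <- rep(1, n)
    vn[f] <- 1
    for (i in seq_along(rr$pivots)) {
      p <- rr$pivots[i]
      vn[p] <- -rr$num[i, f]
      vd[p] <- rr$den[i, f]
    }
    # clear denominators with the lcm -> integer vector, reduce by gcd
    scale <- 1
    for (d in unique(vd)) scale <- scale * d / gcd2(scale, d)
    L <- round(vn * (scale / vd))
    g <- gcd_vec(L)
    if (g > 1) L <- L / g
    if (sum(L) < 0 || (sum(L) == 0 && L[which(L != 0)[1L]] < 0)) L <- -L
    stopifnot(max(abs(N %*% L)) == 0)  # exact integer check
    lv <- stats::setNames(as.integer(L), nms)
    laws[[length(laws) + 1L]] <- lv[lv != 0L]
  }
  laws
}

#' Conservation drift of a simulated time course
#'
#' @param network the simulated `txasim_network`.
#' @param tc a [simulate_network()] time course.
#' @param laws optional list of laws from [conserved_moieties()].
#' @return numeric vector of maximum relative drifts, one per law
#'   (absolute drift where the conserved total is zero).
#' @export
conservation_drift <- function(network, tc, laws = conserved_moieties(network)) {
  Y <- tc$concentrations
  vapply(laws, function(L) {
    tot <- as.numeric(Y[, names(L), drop = FALSE] %*% as.numeric(L))
    ref <- tot[1L]
    if (abs(ref) > 0) max(abs(tot - ref)) / abs(ref) else max(abs(tot - ref))
  }, numeric(1))
}
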