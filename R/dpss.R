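#' Discrete prolate spheroidal sequences (Slepian tapers)
#'
#' Computes the first `k` DPSS tapers of length `n` for time-bandwidth
#' product `nw`, via the standard symmetric-tridiagonal eigenproblem
#' (Percival & Walden formulation): the tapers are the eigenvectors of the
#' tridiagonal matrix with diagonal `((n-1-2i)/2)^2 cos(2 pi W)` and
#' off-diagonal `i (n-i) / 2`, `W = nw / n`, ordered by decreasing
#' eigenvalue. Tapers are unit-energy; polarity follows the usual
#' convention (symmetric tapers have positive mean, antisymmetric tapers a
#' positive initial lobe).
#'
#' @param n Taper length in samples.
#' @param nw Time-bandwidth product (half-bandwidth W = nw/n cycles/sample).
#' @param k Number of tapers (default `floor(2 * nw - 1)`, the count with
#'   near-unit spectral concentration).
#' @return An n x k matrix, one taper per column.
#' @export
#' @examples
#' v <- dpss_tapers(500, 2)
#' crossprod(v)[1:3, 1:3] # ~ identity
dpss_tapers <- function(n, nw, k = floor(2 * nw - 1)) {
  stopifnot(n >= 2, nw > 0, k >= 1, k <= n)
  key <- sprintf("%d_%g_%d", n, nw, k)
  cached <- .dpss_cache[[key]]
  if (!is.null(cached)) return(cached)
  w <- nw / n
  i <- seq_len(n) - 1
  diag_main <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  off <- (seq_len(n - 1) * (n - seq_len(n - 1))) / 2
  tri <- matrix(0, n, n)
  diag(tri) <- diag_main
  tri[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  tri[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  es <- eigen(tri, symmetric = TRUE)
  v <- es$vectors[, seq_len(k), drop = FALSE]
  # unit energy and conventional polarity
  for (j in seq_len(k)) {
    v[, j] <- v[, j] / sqrt(sum(v[, j]^2))
    if (j %% 2 == 1) {
      if (sum(v[, j]) < 0) v[, j] <- -v[, j]
    } else {
      if (v[2, j] - v[1, j] < 0) v[, j] <- -v[, j]
    }
  }
  .dpss_cache[[key]] <- v
  v
}

.dpss_cache <- new.env(parent = emptyenv())
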