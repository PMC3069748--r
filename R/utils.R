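# Shared numerical helpers: fast Bessel approximations, log-sum-exp,
# quadrature nodes and the per-step seed derivation.

#' Fast log I0
#'
#' Logarithm of the modified Bessel function of the first kind, order zero,
#' using the Abramowitz & Stegun polynomial approximations (9.8.1 / 9.8.2).
#' Relative error is below 2e-7, which is far inside the tolerance of any
#' likelihood computed here; the exact `stats::besselI` is kept as the test
#' oracle but is several times slower on the multi-million-point grids used
#' by the phasing likelihoods.
#'
#' @param x Non-negative numeric vector.
#' @return `log(I0(x))`, same shape as `x`.
#' @keywords internal
log_i0 <- function(x) {
  x <- abs(x)
  out <- numeric(length(x))
  small <- x <= 3.75
  if (any(small)) {
    t2 <- (x[small] / 3.75)^2
    p <- 1 + t2 * (3.5156229 + t2 * (3.0899424 + t2 * (1.2067492 +
      t2 * (0.2659732 + t2 * (0.0360768 + t2 * 0.0045813)))))
    out[small] <- log(p)
  }
  if (any(!small)) {
    xb <- x[!small]
    it <- 3.75 / xb
    p <- 0.39894228 + it * (0.01328592 + it * (0.00225319 + it * (-0.00157565 +
      it * (0.00916281 + it * (-0.02057706 + it * (0.02635537 +
        it * (-0.01647633 + it * 0.00392377)))))))
    out[!small] <- xb - 0.5 * log(xb) + log(p)
  }
  dim(out) <- dim(x)
  out
}

#' Log of the Rice density
#'
#' Density of the amplitude `x` of a 2-D Gaussian with mean length `nu` and
#' per-component variance `s2` (so the underlying complex noise has total
#' variance `2*s2`).
#'
#' @param x,nu Non-negative amplitudes (observed, model).
#' @param s2 Per-component variance (sigma^2), strictly positive.
#' @keywords internal
log_rice <- function(x, nu, s2) {
  log(x) - log(s2) - (x^2 + nu^2) / (2 * s2) + log_i0(x * nu / s2)
}

#' Row-wise log-sum-exp over the columns of a matrix
#' @keywords internal
row_logsumexp <- function(m) {
  mx <- do.call(pmax, lapply(seq_len(ncol(m)), function(j) m[, j]))
  mx + log(rowSums(exp(m - mx)))
}

#' Rayleigh quantile quadrature nodes
#'
#' Midpoint quantile nodes for a Rayleigh amplitude prior with mean square
#' `sigma2` (E\[A^2\] = sigma2).  Equal weights 1/n.
#' @keywords internal
rayleigh_nodes <- function(sigma2, n) {
  u <- (seq_len(n) - 0.5) / n
  sqrt(-sigma2 * log(1 - u))
}

#' Derive a reproducible per-step seed from a root seed
#'
#' All pipeline randomness flows from one root seed; each named step gets a
#' deterministic offset derived from the hash of its name, kept inside the
#' 32-bit integer range R requires.
#'
#' @param root Integer root seed.
#' @param step Character step name.
#' @export
derive_seed <- function(root, step) {
  h <- sum(utf8ToInt(step) * seq_along(utf8ToInt(step)))
  as.integer((as.numeric(root) * 10007 + h * 97) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

wrap_frac <- function(x) x - floor(x)

#' Circular (wrapped) absolute phase difference in degrees, in [0, 180]
#' @keywords internal
phase_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}
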