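# Unit cells, space-group operator tables and reflection geometry.
#
# Coordinates are fractional throughout; Miller indices are integers; phases
# are degrees at the interfaces and radians internally.  Only the three space
# groups needed for acentric phasing with Harker sections and origin/hand
# ambiguities are supported: P1, P21 (unique axis b) and P212121.

#' Construct a unit cell
#'
#' @param a,b,c Cell edge lengths in Angstrom (> 0).
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#' @return An object of class `unit_cell` carrying the direct and reciprocal
#'   metric tensors, the fractional-to-orthogonal matrix and the cell volume.
#' @examples
#' uc <- unit_cell(34, 42, 38, 90, 90, 90)
#' d_spacing(uc, c(1, 0, 0))
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  len <- c(a, b, c)
  ang <- c(alpha, beta, gamma)
  if (any(!is.finite(len)) || any(len <= 0)) {
    stop("cell lengths must be positive and finite")
  }
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180)) {
    stop("cell angles must lie in (0, 180) degrees")
  }
  ca <- cos(ang * pi / 180)
  g <- matrix(c(
    a * a, a * b * ca[3], a * c * ca[2],
    a * b * ca[3], b * b, b * c * ca[1],
    a * c * ca[2], b * c * ca[1], c * c
  ), 3, 3, byrow = TRUE)
  ev <- eigen(g, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("cell metric tensor is not positive definite")
  g_star <- solve(g)
  # standard orthogonalization (a along x, b in xy plane)
  sa <- sin(ang * pi / 180)
  v <- sqrt(det(g))
  orth <- matrix(c(
    a, b * ca[3], c * ca[2],
    0, b * sa[3], c * (ca[1] - ca[2] * ca[3]) / sa[3],
    0, 0, v / (a * b * sa[3])
  ), 3, 3, byrow = TRUE)
  structure(list(
    a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
    metric = g, metric_star = g_star, orth = orth, volume = v
  ), class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf(
    "unit cell  %.3f %.3f %.3f A   %.2f %.2f %.2f deg   V = %.1f A^3\n",
    x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume
  ))
  invisible(x)
}

sg_table <- local({
  ident <- diag(3)
  list(
    "P1" = list(
      symbol = "P1",
      ops = list(list(R = ident, t = c(0, 0, 0))),
      origin_shifts = matrix(0, 1, 3),
      polar = c(TRUE, TRUE, TRUE)
    ),
    "P21" = list(
      symbol = "P21",
      ops = list(
        list(R = ident, t = c(0, 0, 0)),
        list(R = diag(c(-1, 1, -1)), t = c(0, 0.5, 0))
      ),
      origin_shifts = as.matrix(expand.grid(
        x = c(0, 0.5), y = 0, z = c(0, 0.5)
      )),
      polar = c(FALSE, TRUE, FALSE)
    ),
    "P212121" = list(
      symbol = "P212121",
      ops = list(
        list(R = ident, t = c(0, 0, 0)),
        list(R = diag(c(1, -1, -1)), t = c(0.5, 0.5, 0)),
        list(R = diag(c(-1, 1, -1)), t = c(0, 0.5, 0.5)),
        list(R = diag(c(-1, -1, 1)), t = c(0.5, 0, 0.5))
      ),
      origin_shifts = as.matrix(expand.grid(
        x = c(0, 0.5), y = c(0, 0.5), z = c(0, 0.5)
      )),
      polar = c(FALSE, FALSE, FALSE)
    )
  )
})

#' Construct a space group from its Hermann-Mauguin-style symbol
#'
#' Supported symbols: `"P1"`, `"P21"` (unique axis b), `"P212121"`.  The
#' operator tables are hard coded and unit tested for closure under
#' composition modulo lattice translations.  Each group records its allowed
#' origin shifts (discrete shifts plus polar axes along which the origin is
#' continuous) and the enantiomorph action, which for these groups maps
#' every site x to -x without a symbol change.
#'
#' @param symbol Space-group symbol text.
#' @return An object of class `space_group`.
#' @export
space_group <- function(symbol) {
  key <- gsub("[ ()]", "", toupper(symbol))
  key <- switch(key,
    "P1" = "P1", "P21" = "P21", "P212121" = "P212121",
    stop("unsupported space group: ", symbol,
      " (supported: P1, P21, P212121)"
    )
  )
  structure(sg_table[[key]], class = "space_group")
}

#' @export
print.space_group <- function(x, ...) {
  cat(sprintf(
    "space group %s  (%d symmetry operation%s)\n",
    x$symbol, length(x$ops), if (length(x$ops) > 1) "s" else ""
  ))
  invisible(x)
}

as_hkl_matrix <- function(hkl) {
  if (is.null(dim(hkl))) hkl <- matrix(hkl, ncol = 3)
  storage.mode(hkl) <- "double"
  hkl
}

#' Resolution (d-spacing) of reflections
#'
#' `d = 1/|s|` from the reciprocal metric tensor; symmetric in `h` and `-h`.
#'
#' @param cell A [unit_cell].
#' @param hkl Integer vector of length 3 or an n x 3 matrix of Miller indices.
#' @return d-spacings in Angstrom.
#' @export
d_spacing <- function(cell, hkl) {
  hkl <- as_hkl_matrix(hkl)
  if (any(rowSums(abs(hkl)) == 0)) {
    stop("invalid reflection (0,0,0): d-spacing undefined")
  }
  s2 <- rowSums((hkl %*% cell$metric_star) * hkl)
  1 / sqrt(s2)
}

# Apply rotation parts to Miller indices: returns list of n x 3 matrices,
# one per operator, with h' = h %*% R (row-vector convention, so that
# F(h') = F(h) exp(-2 pi i h.t)).
hkl_sym_images <- function(sg, hkl) {
  hkl <- as_hkl_matrix(hkl)
  lapply(sg$ops, function(op) hkl %*% op$R)
}

#' Reduce Miller indices to a canonical symmetry-unique representative
#'
#' Among all symmetry equivalents of each reflection (rotations and Friedel
#' mates), the lexicographically largest (h, then k, then l) triple is the
#' representative.  `flipped` records whether the representative is reached
#' through a Friedel flip, in which case the + and - members of the stored
#' pair swap roles.
#'
#' @keywords internal
reduce_hkl <- function(sg, hkl) {
  hkl <- as_hkl_matrix(hkl)
  n <- nrow(hkl)
  key <- function(m) m[, 1] * 4e6 + m[, 2] * 2e3 + m[, 3]
  best <- hkl
  best_key <- key(hkl)
  flipped <- rep(FALSE, n)
  for (img in hkl_sym_images(sg, hkl)) {
    for (sgn in c(1, -1)) {
      cand <- sgn * img
      k <- key(cand)
      sel <- k > best_key
      if (any(sel)) {
        best[sel, ] <- cand[sel, , drop = FALSE]
        best_key[sel] <- k[sel]
        flipped[sel] <- sgn < 0
      }
    }
  }
  list(hkl = best, flipped = flipped)
}

#' Centric flags and phase restrictions
#'
#' A reflection is centric when some symmetry rotation maps h to -h.  The
#' allowed phases are then `{phi0, phi0 + 180}` with `phi0 = 180 * h.t`
#' (degrees) taken from the centrizing operator: 0/180 for the h0l zone of
#' P21 and for even-parity zones of P212121, +/-90 for its odd-parity zones.
#'
#' @return A list with logical `centric` and numeric `phi0_deg`.
#' @keywords internal
centric_info <- function(sg, hkl) {
  hkl <- as_hkl_matrix(hkl)
  n <- nrow(hkl)
  centric <- rep(FALSE, n)
  phi0 <- rep(0, n)
  for (op in sg$ops[-1]) {
    img <- hkl %*% op$R
    hit <- rowSums(abs(img + hkl)) == 0
    newhit <- hit & !centric
    if (any(newhit)) {
      centric[newhit] <- TRUE
      phi0[newhit] <- (180 * (hkl[newhit, , drop = FALSE] %*% op$t)) %% 180
    }
  }
  list(centric = centric, phi0_deg = phi0)
}

#' Generate the symmetry-unique reflection list for a resolution range
#'
#' @param cell A [unit_cell].
#' @param sg A [space_group].
#' @param d_min,d_max Resolution limits in Angstrom (`d_max` may be `Inf`).
#' @return A data frame with columns `h, k, l, d, centric, phi0_deg`, sorted
#'   by decreasing d then lexicographic hkl.
#' @export
unique_hkl <- function(cell, sg, d_min, d_max = Inf) {
  stopifnot(d_min > 0)
  lim <- function(len) max(1L, floor(len / d_min))
  hr <- -lim(cell$a):lim(cell$a)
  kr <- -lim(cell$b):lim(cell$b)
  lr <- -lim(cell$c):lim(cell$c)
  grid <- as.matrix(expand.grid(h = hr, k = kr, l = lr))
  grid <- grid[rowSums(abs(grid)) > 0, , drop = FALSE]
  d <- d_spacing(cell, grid)
  keep <- d >= d_min - 1e-9 & d <= d_max
  grid <- grid[keep, , drop = FALSE]
  red <- reduce_hkl(sg, grid)$hkl
  uni <- unique(as.data.frame(red))
  names(uni) <- c("h", "k", "l")
  uni <- as.matrix(uni)
  d <- d_spacing(cell, uni)
  ci <- centric_info(sg, uni)
  out <- data.frame(
    h = uni[, 1], k = uni[, 2], l = uni[, 3], d = d,
    centric = ci$centric, phi0_deg = ci$phi0_deg
  )
  ord <- order(-out$d, out$h, out$k, out$l)
  rownames(out) <- NULL
  out[ord, , drop = FALSE]
}

#' Apply the enantiomorph action to fractional coordinates
#'
#' For the supported space groups this maps x to -x (wrapped into the unit
#' cell) with no change of symbol.
#' @keywords internal
enantiomorph_xyz <- function(sg, xyz) {
  wrap_frac(-as.matrix(xyz))
}

#' Minimum distance between two fractional positions under symmetry
#'
#' Distance in Angstrom between `x1` and the closest symmetry image of `x2`,
#' minimized over lattice translations via the cell metric.
#' @keywords internal
site_distance <- function(cell, sg, x1, x2) {
  best <- Inf
  for (op in sg$ops) {
    dx <- wrap_frac(as.numeric(x1) - (op$R %*% as.numeric(x2) + op$t))
    dx <- ifelse(dx > 0.5, dx - 1, dx)
    best <- min(best, sqrt(drop(t(dx) %*% cell$metric %*% dx)))
  }
  best
}
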