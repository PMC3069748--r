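# Anomalous-difference Patterson synthesis, multi-trial substructure search
# with early-termination rules, trial scoring and site matching against
# ground truth.

good_fft_size <- function(n) {
  n <- max(2L, as.integer(ceiling(n)))
  repeat {
    m <- n
    for (p in c(2, 3, 5)) while (m %% p == 0) m <- m / p
    if (m == 1 && n %% 2 == 0) return(n)
    n <- n + 1L
  }
}

map_grid_dims <- function(cell, d_min, factor = 3) {
  vapply(c(cell$a, cell$b, cell$c), function(len) {
    good_fft_size(factor * len / d_min)
  }, integer(1))
}

new_map_grid <- function(values, cell, d_min = NULL) {
  structure(list(dims = dim(values), cell = cell, values = values,
                 d_min = d_min), class = "map_grid")
}

#' @export
print.map_grid <- function(x, ...) {
  cat(sprintf("map grid %d x %d x %d, sd = %.4g\n",
              x$dims[1], x$dims[2], x$dims[3], stats::sd(x$values)))
  invisible(x)
}

# Place real Fourier coefficients at all rotation images and Friedel mates
# of the given unique reflections, then invert.  Coefficients must be
# invariant under the expansion (true for |F|^2-type terms).
patterson_fft <- function(hkl, coef, cell, sg, dims) {
  W <- array(0, dims)
  for (img in hkl_sym_images(sg, hkl)) {
    for (sgn in c(1, -1)) {
      m <- sgn * img
      i1 <- m[, 1] %% dims[1]; i2 <- m[, 2] %% dims[2]; i3 <- m[, 3] %% dims[3]
      W[cbind(i1 + 1, i2 + 1, i3 + 1)] <- coef
    }
  }
  Re(fft(W, inverse = TRUE))
}

#' Anomalous-difference Patterson map
#'
#' `P(u) = sum |FA|^2 cos(2 pi h.u)` over the unique reflections, with
#' sharpened, origin-removed coefficients `E^2 - 1` from the
#' quasi-normalized |FA| estimates.  The map carries the Patterson (Laue)
#' symmetry of the space group.
#'
#' @param fa An `fa_estimate`.
#' @param cell A [unit_cell].
#' @param sg A [space_group].
#' @param d_min Resolution limit defining the grid (spacing about d_min/3).
#' @return A `map_grid`.
#' @export
anomalous_patterson <- function(fa, cell, sg, d_min) {
  tab <- fa$table[!fa$table$excluded, ]
  if (nrow(tab) == 0) stop("empty |FA| estimate")
  dims <- map_grid_dims(cell, d_min, factor = 3)
  coef <- tab$e_norm^2 - mean(tab$e_norm^2)
  vals <- patterson_fft(as.matrix(tab[, c("h", "k", "l")]), coef,
                        cell, sg, dims)
  new_map_grid(vals, cell, d_min)
}

#' Evaluate a Patterson sum directly at arbitrary vectors
#'
#' Brute-force evaluation of `sum coef * cos(2 pi h.u)`; the independent
#' oracle for the FFT synthesis and for peak positions.
#' @keywords internal
patterson_direct <- function(fa, u) {
  tab <- fa$table[!fa$table$excluded, ]
  u <- matrix(u, ncol = 3)
  coef <- tab$e_norm^2 - mean(tab$e_norm^2)
  hkl <- as.matrix(tab[, c("h", "k", "l")])
  as.vector(cos(2 * pi * (u %*% t(hkl))) %*% coef)
}

# Trilinear periodic interpolation of a map at fractional coordinates.
map_interp <- function(map, u) {
  u <- matrix(u, ncol = 3)
  dims <- map$dims
  g <- sweep(wrap_frac(u), 2, dims, "*")
  i0 <- floor(g)
  f <- g - i0
  val <- numeric(nrow(u))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
      (if (dy) f[, 2] else 1 - f[, 2]) *
      (if (dz) f[, 3] else 1 - f[, 3])
    idx <- cbind((i0[, 1] + dx) %% dims[1] + 1,
                 (i0[, 2] + dy) %% dims[2] + 1,
                 (i0[, 3] + dz) %% dims[3] + 1)
    val <- val + w * map$values[idx]
  }
  val
}

# Symmetry-minimum function on self (Harker) vectors: for each candidate
# position, the minimum Patterson value over the Harker vectors x - op(x)
# of the non-identity operators.  NA when the group has none (P1).
harker_min <- function(map, sg, x) {
  x <- matrix(x, ncol = 3)
  if (length(sg$ops) < 2) return(rep(NA_real_, nrow(x)))
  vals <- NULL
  for (op in sg$ops[-1]) {
    u <- x - t(op$R %*% t(x) + op$t)
    v <- map_interp(map, u)
    vals <- if (is.null(vals)) v else pmin(vals, v)
  }
  vals
}

# Minimum Patterson value over cross vectors between a candidate and the
# symmetry images of the existing sites.
cross_min <- function(map, sg, x, existing) {
  x <- matrix(x, ncol = 3)
  vals <- rep(Inf, nrow(x))
  for (j in seq_len(nrow(existing))) {
    for (op in sg$ops) {
      img <- drop(op$R %*% as.numeric(existing[j, ]) + op$t)
      vals <- pmin(vals, map_interp(map, x - matrix(img, nrow(x), 3,
                                                    byrow = TRUE)))
    }
  }
  vals
}

# Axis-wise 3-point parabola refinement of a candidate position against an
# arbitrary map objective, step-limited to one grid division per round.
local_peak_refine <- function(objective, x, dims, rounds = 3) {
  x <- as.numeric(x)
  for (r in seq_len(rounds)) {
    for (ax in 1:3) {
      h <- 1 / dims[ax]
      probe <- rbind(x, x, x)
      probe[1, ax] <- x[ax] - h
      probe[3, ax] <- x[ax] + h
      v <- objective(probe)
      denom <- v[1] - 2 * v[2] + v[3]
      if (is.finite(denom) && denom < 0) {
        step <- 0.5 * (v[1] - v[3]) / denom
        x[ax] <- x[ax] + max(min(step, 1), -1) * h
      } else if (which.max(v) != 2) {
        x[ax] <- probe[which.max(v), ax]
      }
    }
  }
  x
}

substructure_from_xyz <- function(xyz, element = "SE", occ = NULL, b = 20,
                                  f_prime = -8, f_dprime = 4) {
  xyz <- matrix(xyz, ncol = 3)
  occ <- occ %||% rep(1, nrow(xyz))
  st <- sites(rep(element, nrow(xyz)), xyz[, 1], xyz[, 2], xyz[, 3],
              occ = pmin(occ, 1), b = b, f_prime = f_prime,
              f_dprime = f_dprime)
  # occupancies above 1 are legal during refinement; bypass the constructor
  st$occ <- occ
  substructure(st)
}

#' Correlation score of a substructure against |FA| estimates
#'
#' Pearson correlation between the quasi-normalized observed |FA| values
#' and the quasi-normalized calculated heavy-atom amplitudes.
#'
#' @param sub A [substructure].
#' @param fa An `fa_estimate`.
#' @param cell,sg Cell and symmetry.
#' @return Correlation in `[-1, 1]`.
#' @export
score_substructure <- function(sub, fa, cell, sg) {
  if (nrow(sub$sites) == 0) stop("empty substructure")
  tab <- fa$table[!fa$table$excluded, ]
  fh <- structure_factors(sub, cell, sg, as.matrix(tab[, c("h", "k", "l")]))
  fcalc <- (Mod(fh$f_plus) + Mod(fh$f_minus)) / 2
  e_calc <- fa_normalize(fcalc, tab$shell)
  stats::cor(tab$e_norm, e_calc)
}

refine_occupancies <- function(xyz, fa, cell, sg, b = 20) {
  tab <- fa$table[!fa$table$excluded, ]
  hklm <- as.matrix(tab[, c("h", "k", "l")])
  n <- nrow(matrix(xyz, ncol = 3))
  per_site <- lapply(seq_len(n), function(i) {
    s <- substructure_from_xyz(matrix(xyz, ncol = 3)[i, , drop = FALSE], b = b)
    fh <- structure_factors(s, cell, sg, hklm)
    list(p = fh$f_plus, m = fh$f_minus)
  })
  objective <- function(occ) {
    fp <- Reduce(`+`, Map(function(ps, o) o * ps$p, per_site, occ))
    fm <- Reduce(`+`, Map(function(ps, o) o * ps$m, per_site, occ))
    fcalc <- (Mod(fp) + Mod(fm)) / 2
    e_calc <- fa_normalize(fcalc, tab$shell)
    sum((tab$e_norm - e_calc)^2)
  }
  res <- stats::optim(rep(1, n), objective, method = "L-BFGS-B",
                      lower = rep(1e-3, n), upper = rep(2, n),
                      control = list(maxit = 40))
  res$par
}

#' Multi-trial Patterson substructure search
#'
#' Each trial scores random translation candidates by the symmetry-minimum
#' Patterson function on Harker vectors, accepts the best as the first
#' site, then adds sites consistent with the cross vectors to the already
#' accepted ones; occupancies are refined by least squares on the
#' normalized |FA| values and the trial is scored by the correlation
#' between observed and calculated normalized amplitudes.  Trials are
#' reproducible from `seed`.  In P1 the first site fixes the (free) origin
#' at (0,0,0).
#'
#' @param fa An `fa_estimate`.
#' @param cell,sg Cell and symmetry.
#' @param n_sites_expected Number of sites to place (>= 1).
#' @param n_trials Number of random trials (>= 1).
#' @param seed Integer seed.
#' @param n_candidates Random translation candidates per site per trial.
#' @param early_stop Optional early-termination config (see
#'   [should_terminate_early]); when given, the trial loop stops as soon as
#'   the rule fires.
#' @return List of trial records (`trial_id`, `seed`, `score`, `sites`),
#'   sorted best first.
#' @export
search_substructure <- function(fa, cell, sg, n_sites_expected, n_trials,
                                seed, n_candidates = 400,
                                early_stop = NULL) {
  stopifnot(n_sites_expected >= 1, n_trials >= 1)
  d_min <- min(fa$table$d)
  pmap <- anomalous_patterson(fa, cell, sg, d_min)
  if (any(pmap$dims < 2 * c(cell$a, cell$b, cell$c) / d_min)) {
    stop("Patterson grid too coarse for the requested resolution")
  }
  box <- asu_box(sg)
  # precompute the symmetry-minimum (self-Harker) score over the whole
  # grid once: it does not depend on the accepted sites, and the true
  # later sites must score well on it too, so cross-vector evaluation can
  # be restricted to its top points
  dims <- pmap$dims
  gpts <- as.matrix(expand.grid(
    x = (seq_len(dims[1]) - 1) / dims[1],
    y = (seq_len(dims[2]) - 1) / dims[2],
    z = (seq_len(dims[3]) - 1) / dims[3]
  ))
  smf_grid <- harker_min(pmap, sg, gpts)
  top_idx <- if (all(is.na(smf_grid))) seq_len(nrow(gpts)) else
    order(smf_grid, decreasing = TRUE)[seq_len(min(3000, nrow(gpts)))]
  trials <- list()
  for (tr in seq_len(n_trials)) {
    tseed <- derive_seed(seed, paste0("trial", tr))
    set.seed(tseed)
    xyz <- matrix(NA_real_, 0, 3)
    for (k in seq_len(n_sites_expected)) {
      too_close <- function(x) {
        x <- matrix(x, ncol = 3)
        bad <- rep(FALSE, nrow(x))
        for (j in seq_len(nrow(xyz))) {
          d <- vapply(seq_len(nrow(x)), function(i) {
            site_distance(cell, sg, x[i, ], xyz[j, ])
          }, numeric(1))
          bad <- bad | d < 2.5
        }
        bad
      }
      objective <- function(x) {
        x <- matrix(x, ncol = 3)
        sc <- harker_min(pmap, sg, x)
        if (k > 1) {
          cm <- cross_min(pmap, sg, x, xyz)
          sc <- if (all(is.na(sc))) cm else pmin(sc, cm)
          sc[too_close(x)] <- -Inf
        }
        sc
      }
      if (k == 1) {
        # random translation candidates for the first site (this is the
        # per-trial randomness); in P1 the origin is free
        if (length(sg$ops) < 2) {
          best <- c(0, 0, 0)
        } else {
          cand <- sweep(matrix(runif(3 * n_candidates), ncol = 3), 2,
                        box, "*")
          sc <- objective(cand)
          best <- local_peak_refine(objective, cand[which.max(sc), ],
                                    pmap$dims)
        }
      } else {
        # later sites: Patterson-seeded peak picking, consistent with the
        # cross vectors to the accepted sites; the amplitude correlation
        # against the |FA| data arbitrates among the top peaks
        cand_top <- gpts[top_idx, , drop = FALSE]
        sc <- objective(cand_top)
        ord <- order(sc, decreasing = TRUE)[seq_len(min(500, length(sc)))]
        picks <- list()
        for (j in ord) {
          if (!is.finite(sc[j])) next
          xj <- cand_top[j, ]
          if (all(vapply(picks, function(p) {
            site_distance(cell, sg, xj, p) > 2.5
          }, logical(1)))) {
            picks[[length(picks) + 1]] <- xj
          }
          if (length(picks) >= 6) break
        }
        best <- NULL; best_cor <- -Inf
        for (xj in picks) {
          xr <- local_peak_refine(objective, xj, pmap$dims)
          cand_sub <- substructure_from_xyz(rbind(xyz, xr))
          cc <- score_substructure(cand_sub, fa, cell, sg)
          if (cc > best_cor) { best_cor <- cc; best <- xr }
        }
        if (is.null(best)) best <- cand_top[ord[1], ]
      }
      xyz <- rbind(xyz, best)
    }
    occ <- refine_occupancies(xyz, fa, cell, sg)
    sub <- substructure_from_xyz(xyz, occ = occ)
    score <- score_substructure(sub, fa, cell, sg)
    trials[[tr]] <- list(trial_id = tr, seed = tseed, score = score,
                         sites = sub)
    if (!is.null(early_stop)) {
      if (should_terminate_early(trials, early_stop) == "stop_success") break
    }
  }
  trials[order(-vapply(trials, `[[`, numeric(1), "score"))]
}

#' Early-termination rule for multi-trial substructure detection
#'
#' Detection stops successfully when the best trial score reaches the score
#' threshold, or when at least `min_trials` trials are done and a
#' significant deviation (best minus worst at least `deviation_threshold`,
#' with best at least 0.4) separates the trials.
#'
#' @param scores List of trial records (or a numeric vector of scores).
#' @param config List with `score_threshold` (default 0.65),
#'   `deviation_threshold` (default 0.2) and `min_trials` (default 5).
#' @return `"stop_success"` or `"continue"`.
#' @export
should_terminate_early <- function(scores, config = list()) {
  thr <- config$score_threshold %||% 0.65
  dev <- config$deviation_threshold %||% 0.2
  mtr <- config$min_trials %||% 5
  s <- if (is.numeric(scores)) scores else
    vapply(scores, `[[`, numeric(1), "score")
  if (length(s) < 1) stop("need at least one completed trial")
  if (max(s) >= thr) return("stop_success")
  if (length(s) >= mtr && max(s) - min(s) >= dev && max(s) >= 0.4) {
    return("stop_success")
  }
  "continue"
}

#' Match found sites against true sites modulo symmetry, origin and hand
#'
#' Greedy bipartite matching of site lists under all symmetry operations,
#' all allowed origin shifts (discrete shifts plus continuous shifts along
#' polar axes, generated from candidate pair alignments) and both hands.
#' Distances are metric distances in Angstrom.
#'
#' @param found,truth [substructure]s.
#' @param cell,sg Cell and symmetry.
#' @param tol Match tolerance in Angstrom.
#' @return List with `n_matched`, `mapping` (data frame `found`, `truth`,
#'   `dist`), the chosen `hand` and `shift`.
#' @export
match_sites <- function(found, truth, cell, sg, tol = 0.5) {
  if (nrow(found$sites) == 0 || nrow(truth$sites) == 0) {
    stop("both site lists must be non-empty")
  }
  tx <- as.matrix(truth$sites[, c("x", "y", "z")])
  candidates_for <- function(fx) {
    shifts <- sg$origin_shifts
    if (any(sg$polar)) {
      extra <- list()
      for (i in seq_len(nrow(fx))) for (j in seq_len(nrow(tx))) {
        for (op in sg$ops) {
          img <- drop(op$R %*% fx[i, ] + op$t)
          delta <- (tx[j, ] - img) * sg$polar
          extra[[length(extra) + 1]] <- delta
        }
      }
      base <- do.call(rbind, extra)
      shifts <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(r) {
        sweep(base, 2, as.numeric(shifts[r, ]) * (!sg$polar), "+")
      }))
    }
    unique(round(wrap_frac(shifts), 6))
  }
  evaluate <- function(fx) {
    best <- list(n_matched = -1, sum_d = Inf)
    for (r in seq_len(nrow(candidates <- candidates_for(fx)))) {
      shift <- as.numeric(candidates[r, ])
      sx <- wrap_frac(sweep(fx, 2, shift, "+"))
      dm <- outer(seq_len(nrow(sx)), seq_len(nrow(tx)),
                  Vectorize(function(i, j) site_distance(cell, sg,
                                                         sx[i, ], tx[j, ])))
      mapping <- NULL
      dmat <- dm
      repeat {
        if (all(!is.finite(dmat))) break
        ij <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
        mapping <- rbind(mapping, data.frame(found = ij[1], truth = ij[2],
                                             dist = dmat[ij[1], ij[2]]))
        dmat[ij[1], ] <- Inf; dmat[, ij[2]] <- Inf
        if (nrow(mapping) == min(nrow(sx), nrow(tx))) break
      }
      nm <- sum(mapping$dist <= tol)
      sd_ <- sum(mapping$dist)
      if (nm > best$n_matched || (nm == best$n_matched && sd_ < best$sum_d)) {
        best <- list(n_matched = nm, sum_d = sd_, mapping = mapping,
                     shift = shift)
      }
    }
    best
  }
  fx0 <- as.matrix(found$sites[, c("x", "y", "z")])
  res_orig <- evaluate(fx0)
  res_inv <- evaluate(enantiomorph_xyz(sg, fx0))
  if (res_inv$n_matched > res_orig$n_matched ||
      (res_inv$n_matched == res_orig$n_matched &&
         res_inv$sum_d < res_orig$sum_d)) {
    list(n_matched = res_inv$n_matched, mapping = res_inv$mapping,
         hand = "inverted", shift = res_inv$shift)
  } else {
    list(n_matched = res_orig$n_matched, mapping = res_orig$mapping,
         hand = "original", shift = res_orig$shift)
  }
}
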