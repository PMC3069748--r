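# Solvent-flattening density modification iterated with likelihood phase
# combination: FOM-weighted map synthesis, Wang-style solvent masking,
# flattening/flipping, map-to-structure-factor inversion, MLHL and
# correlation-aware (alpha-discounted) phase combination, cross-validated
# error estimation for the combination, and hand determination.

hkl_grid_index <- function(hkl, dims) {
  cbind(hkl[, 1] %% dims[1] + 1, hkl[, 2] %% dims[2] + 1,
        hkl[, 3] %% dims[3] + 1)
}

#' FOM-weighted Fourier synthesis of an electron-density map
#'
#' `rho(x) = (1/V) sum m |F| exp(i phi_best) exp(-2 pi i h.x)`, expanded to
#' the full sphere through the space-group operations and Friedel mates.
#' Free (cross-validation) reflections can be given zero weight so that
#' their experimental phases never feed the map.
#'
#' @param phases A `phase_distribution` (carries amplitudes `f_bar`).
#' @param dims Grid dimensions; default from the resolution limit
#'   (spacing about d_min/3, even sizes).
#' @param zero_free Give free reflections zero weight in the synthesis.
#' @return A `map_grid`.
#' @export
synthesize_map <- function(phases, dims = NULL, zero_free = FALSE) {
  tab <- phases$table
  cell <- phases$cell; sg <- phases$sg
  d_min <- min(tab$d)
  dims <- dims %||% map_grid_dims(cell, d_min, factor = 3)
  hmax <- vapply(1:3, function(i) max(abs(tab[, c("h", "k", "l")[i]])),
                 numeric(1))
  if (any(dims < 2 * hmax + 2)) stop("grid below Nyquist for the data")
  w <- tab$fom * tab$f_bar * exp(1i * tab$phi_best * pi / 180)
  if (zero_free) w[tab$free] <- 0
  hkl <- as.matrix(tab[, c("h", "k", "l")])
  # systematically absent reflections (h fixed by a rotation with a
  # non-integral phase shift, e.g. odd 0k0 along a 2_1 axis) carry only
  # measurement noise; their coefficient is identically zero
  for (op in sg$ops[-seq_len(1)]) {
    same <- rowSums(abs(hkl %*% op$R - hkl)) == 0
    frac <- drop(hkl %*% op$t) %% 1
    w[same & pmin(frac, 1 - frac) > 1e-9] <- 0
  }
  W <- array(0i, dims)
  for (op in sg$ops) {
    h2 <- hkl %*% op$R
    w2 <- w * exp(-2i * pi * drop(hkl %*% op$t))
    W[hkl_grid_index(h2, dims)] <- w2
    W[hkl_grid_index(-h2, dims)] <- Conj(w2)
  }
  vals <- Re(fft(W)) / cell$volume   # forward FFT: exp(-2 pi i h.x)
  new_map_grid(vals, cell, d_min)
}

#' Inverse Fourier coefficients of a map at given reflections
#'
#' Round-tripping an unmodified synthesis returns the input `m |F|` and
#' `phi` to machine precision (the grid is above Nyquist).
#'
#' @param map A `map_grid`.
#' @param hkl n x 3 matrix of Miller indices.
#' @return Data frame of class `modified_map_sf` with `h, k, l, f_dm`
#'   (amplitude, >= 0) and `phi_dm` (degrees).
#' @export
map_to_sf <- function(map, hkl) {
  hkl <- as_hkl_matrix(hkl)
  W <- fft(map$values, inverse = TRUE) * map$cell$volume / prod(map$dims)
  co <- W[hkl_grid_index(hkl, map$dims)]
  out <- data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                    f_dm = Mod(co), phi_dm = (Arg(co) * 180 / pi) %% 360)
  class(out) <- c("modified_map_sf", "data.frame")
  out
}

# FFT convolution of a (positive) map with a normalized spherical kernel.
smooth_map_sphere <- function(map, radius) {
  dims <- map$dims; cell <- map$cell
  steps <- lapply(1:3, function(i) {
    ix <- seq_len(dims[i]) - 1
    ifelse(ix > dims[i] / 2, ix - dims[i], ix) / dims[i]
  })
  fr <- as.matrix(expand.grid(x = steps[[1]], y = steps[[2]],
                              z = steps[[3]]))
  # metric distances of grid offsets from the origin
  d2 <- rowSums((fr %*% cell$metric) * fr)
  K <- array(as.numeric(d2 <= radius^2), dims)
  K <- K / sum(K)
  Re(fft(fft(map$values) * fft(K), inverse = TRUE)) / prod(dims)
}

#' Solvent mask from local density averaging
#'
#' The local mean of |rho| over a sphere of radius `0.8 * d_min` is
#' computed per grid point; the lowest `solvent_fraction` quantile is
#' declared solvent (exactly `round(solvent_fraction * N)` points, ties
#' broken by grid index order).  The default radius sits below the
#' inter-atomic void scale of the toy crystals (which have no bulk
#' solvent: their empty volume is distributed between atoms), where a
#' Wang-style multi-Angstrom radius would average atoms and voids
#' together and the mask would destroy real density.
#'
#' @param map A `map_grid`.
#' @param solvent_fraction Fraction of the cell assigned to solvent,
#'   in (0, 1).
#' @param radius Averaging radius in Angstrom (default `0.8 * d_min`).
#' @return A `map_grid` with logical values (`TRUE` = solvent).
#' @export
solvent_mask <- function(map, solvent_fraction, radius = NULL) {
  if (solvent_fraction <= 0 || solvent_fraction >= 1) {
    stop("solvent_fraction must be in (0, 1)")
  }
  radius <- radius %||% (0.8 * (map$d_min %||% 3))
  am <- map; am$values <- abs(map$values)
  sm <- smooth_map_sphere(am, radius)
  n_solv <- round(solvent_fraction * length(sm))
  ord <- order(as.vector(sm), seq_along(sm))
  mask <- array(FALSE, map$dims)
  mask[ord[seq_len(n_solv)]] <- TRUE
  new_map_grid(mask, map$cell, map$d_min)
}

#' Flatten or flip the solvent region of a map
#'
#' `flatten` sets solvent points to the solvent mean; `flip` reflects them
#' about the mean (`rho -> mean - flip_factor (rho - mean)`).  The protein
#' region is untouched; `flip_factor = 0` reduces flipping to flattening
#' and flipping twice with factor 1 is the identity on the solvent.
#'
#' @param map A `map_grid`.
#' @param mask Logical `map_grid` (`TRUE` = solvent).
#' @param mode `"flatten"` or `"flip"`.
#' @param flip_factor Flip strength (>= 0).
#' @return The modified `map_grid`.
#' @export
modify_density <- function(map, mask, mode = c("flatten", "flip"),
                           flip_factor = 1) {
  mode <- match.arg(mode)
  if (!all(dim(mask$values) == dim(map$values))) {
    stop("mask grid does not match the map grid")
  }
  m <- mask$values
  mu <- mean(map$values[m])
  out <- map$values
  if (mode == "flatten") {
    out[m] <- mu
  } else {
    out[m] <- mu - flip_factor * (out[m] - mu)
  }
  new_map_grid(out, map$cell, map$d_min)
}

# Evaluate combined posterior summaries (fom, phi_best) for HL sets; the
# posterior is exp(HL basis) on the phase grid for acentrics and the
# restricted two-point distribution for centrics.
hl_summarize <- function(hl, centric, phi0_deg, n_phi = 72) {
  phi <- phi_grid_deg(n_phi) * pi / 180
  X <- rbind(cos(phi), sin(phi), cos(2 * phi), sin(2 * phi))
  lq <- as.matrix(hl) %*% X
  q <- exp(lq - row_logsumexp(lq))
  m1 <- as.vector(q %*% exp(1i * phi))
  fom <- Mod(m1)
  phi_best <- (Arg(m1) * 180 / pi) %% 360
  if (any(centric)) {
    a_ax <- hl[centric, 1] * cos(phi0_deg[centric] * pi / 180) +
      hl[centric, 2] * sin(phi0_deg[centric] * pi / 180)
    p1 <- 1 / (1 + exp(-2 * a_ax))
    fom[centric] <- abs(2 * p1 - 1)
    phi_best[centric] <- ifelse(p1 >= 0.5, phi0_deg[centric],
                                (phi0_deg[centric] + 180) %% 360)
  }
  list(fom = pmin(fom, 1), phi_best = phi_best)
}

# Shared core of the two phase-combination modes: add a von Mises DM term
# with concentration (1 - alpha) * K to the experimental HL posterior.
combine_with_dm <- function(exp_phases, dm, em, alpha) {
  tab <- exp_phases$table
  key_e <- paste(tab$h, tab$k, tab$l)
  key_d <- paste(dm$h, dm$k, dm$l)
  idx <- match(key_e, key_d)
  f_dm <- dm$f_dm[idx]
  phi_dm <- dm$phi_dm[idx] * pi / 180
  # per-shell parameters prepared by estimate_comb_errors_cv
  par <- em$dm_pars
  if (is.null(par)) {
    stop("error model carries no DM-channel parameters; ",
         "run estimate_comb_errors_cv first or supply d_dm")
  }
  shell <- par$shell_index
  K <- 2 * par$d_dm[shell] * par$k_scale[shell] * f_dm * tab$f_bar /
    pmax(par$sigma_e[shell], 1e-12)
  K[is.na(K)] <- 0
  K_eff <- (1 - alpha) * K
  hl_new <- cbind(
    tab$hl_a + K_eff * cos(phi_dm),
    tab$hl_b + K_eff * sin(phi_dm),
    tab$hl_c, tab$hl_d
  )
  hl_new[is.na(hl_new)] <- 0
  sm <- hl_summarize(hl_new, tab$centric, tab$phi0_deg)
  out <- exp_phases
  out$table$hl_a <- hl_new[, 1]; out$table$hl_b <- hl_new[, 2]
  out$table$phi_best <- sm$phi_best
  out$table$fom <- sm$fom
  out
}

#' MLHL phase combination
#'
#' Combines the experimental phase information, carried as an independent
#' Hendrickson-Lattman prior, with the density-modified map channel: a von
#' Mises likelihood centred on the DM phase with concentration
#' `2 d_dm k f_dm |F| / sigma_e` (the classical treatment that assumes the
#' two maps are independent).
#'
#' @param exp_phases Experimental `phase_distribution`.
#' @param dm A `modified_map_sf`.
#' @param em An [error_model] whose DM-channel parameters have been
#'   estimated (see [estimate_comb_errors_cv]).
#' @return The combined `phase_distribution`.
#' @export
combine_phases_mlhl <- function(exp_phases, dm, em) {
  combine_with_dm(exp_phases, dm, em, alpha = 0)
}

#' Correlation-aware multivariate phase combination
#'
#' Joint treatment of the observed Friedel pairs and the density-modified
#' channel: the experimental posterior is recomputed from the data and
#' substructure with the joint Friedel likelihood, and the DM channel's
#' information is discounted by the map correlation parameter alpha
#' (`alpha = 1`: the DM map is fully redundant with the experimental map
#' and the output equals the experimental posterior; `alpha = 0`:
#' independent channels, identical to MLHL combination).
#'
#' @param data A [reflection_set].
#' @param sub A [substructure].
#' @param dm A `modified_map_sf`.
#' @param em An [error_model] carrying `dm_corr` (alpha) and the
#'   DM-channel parameters.
#' @param exp_phases Optionally the precomputed experimental posterior
#'   (saves recomputation inside cycles).
#' @return The combined `phase_distribution`.
#' @export
combine_phases_multivariate <- function(data, sub, dm, em,
                                        exp_phases = NULL) {
  alpha <- em$dm_corr
  if (is.na(alpha) || alpha < 0 || alpha > 1) {
    stop("dm_corr (alpha) must lie in [0, 1]")
  }
  if (is.null(exp_phases)) {
    exp_phases <- phase_substructure_sad(data, sub, em)
  }
  combine_with_dm(exp_phases, dm, em, alpha = alpha)
}

#' Cross-validated error estimation for phase combination
#'
#' Estimates the DM-channel Luzzati parameter `d_dm` per shell from the
#' amplitude agreement between the data and the density-modified map, and
#' the map-correlation discount alpha from the predictive likelihood of
#' the DM phases under the experimental posteriors - both evaluated ONLY
#' on free reflections, whose phases never fed the map, so the estimates
#' are honest.  With `cv = FALSE` the same estimation runs on the work
#' reflections (the overfitting-prone variant the cross-validated scheme
#' exists to replace).
#'
#' @param exp_phases Experimental `phase_distribution` (carries free flags).
#' @param dm A `modified_map_sf`.
#' @param em An [error_model] to update.
#' @param n_shells Shells for the DM parameters.
#' @param cv Use only free reflections (default) or only work reflections.
#' @return The updated [error_model] (`dm_corr`, `d_dm`, `dm_pars`).
#' @export
estimate_comb_errors_cv <- function(exp_phases, dm, em, n_shells = 10,
                                    cv = TRUE) {
  tab <- exp_phases$table
  if (cv && !any(tab$free)) {
    stop("no free reflections flagged; run flag_free_set first")
  }
  key_e <- paste(tab$h, tab$k, tab$l)
  key_d <- paste(dm$h, dm$k, dm$l)
  idx <- match(key_e, key_d)
  f_dm <- dm$f_dm[idx]
  phi_dm <- dm$phi_dm[idx] * pi / 180
  shell <- assign_shells(tab, n_shells)
  est_set <- if (cv) tab$free else !tab$free
  est_set <- est_set & !is.na(f_dm)
  d_dm <- numeric(n_shells); k_scale <- numeric(n_shells)
  sigma_e <- numeric(n_shells)
  for (s in seq_len(n_shells)) {
    i <- shell == s & est_set
    if (sum(i) >= 5 && stats::sd(f_dm[i]) > 0) {
      d_dm[s] <- min(max(stats::cor(tab$f_bar[i], f_dm[i]), 0), 0.999)
      k_scale[s] <- sum(tab$f_bar[i] * f_dm[i]) / sum(f_dm[i]^2)
    } else {
      d_dm[s] <- 0; k_scale[s] <- 1
    }
    j <- shell == s
    sigma_e[s] <- max((1 - d_dm[s]^2) * mean(tab$f_bar[j]^2), 1e-12)
  }
  # alpha: predictive likelihood of the DM phases on the estimation set
  phi <- phi_grid_deg(72) * pi / 180
  X <- rbind(cos(phi), sin(phi), cos(2 * phi), sin(2 * phi))
  use <- which(est_set & !tab$centric)
  alpha_hat <- 0
  if (length(use) >= 10) {
    hl <- as.matrix(tab[use, c("hl_a", "hl_b", "hl_c", "hl_d")])
    lq <- hl %*% X
    lq <- lq - row_logsumexp(lq)
    K <- 2 * d_dm[shell[use]] * k_scale[shell[use]] * f_dm[use] *
      tab$f_bar[use] / pmax(sigma_e[shell[use]], 1e-12)
    cosm <- cos(outer(phi_dm[use], phi, "-"))
    score <- function(alpha) {
      ke <- (1 - alpha) * K
      sum(row_logsumexp(lq + ke * cosm) - log_i0(ke))
    }
    # a fine tail near alpha = 1 lets a very strong (overconcentrated)
    # channel be discounted to its predictive optimum instead of being
    # switched off entirely
    agrid <- c(seq(0, 0.9, by = 0.05), 0.95, 0.98, 0.99, 0.995, 0.998,
               0.999, 1)
    sc <- vapply(agrid, score, numeric(1))
    j <- which.max(sc)
    alpha_hat <- agrid[j]
    if (j > 1 && j < length(agrid) - 1) {
      # parabola on the log(1 - alpha) scale, where the grid is uniform
      # enough near both ends
      u <- log(1 - agrid[(j - 1):(j + 1)])
      y <- sc[(j - 1):(j + 1)]
      num <- (u[2] - u[1])^2 * (y[2] - y[3]) - (u[2] - u[3])^2 * (y[2] - y[1])
      den <- (u[2] - u[1]) * (y[2] - y[3]) - (u[2] - u[3]) * (y[2] - y[1])
      if (is.finite(den) && abs(den) > 0) {
        ustar <- u[2] - 0.5 * num / den
        if (is.finite(ustar)) {
          alpha_hat <- 1 - exp(max(min(ustar, u[1]), u[3]))
          alpha_hat <- min(max(alpha_hat, 0), 1)
        }
      }
    }
  }
  em$dm_corr <- alpha_hat
  em$d_dm <- d_dm
  em$dm_pars <- list(shell_index = shell, d_dm = d_dm, k_scale = k_scale,
                     sigma_e = sigma_e, cv = cv)
  em
}

# Predictive free-set log-likelihood of the DM channel; the hand-decision
# statistic.
dm_predictive_loglik <- function(exp_phases, dm, em, free_only = TRUE) {
  tab <- exp_phases$table
  key_d <- paste(dm$h, dm$k, dm$l)
  idx <- match(paste(tab$h, tab$k, tab$l), key_d)
  par <- em$dm_pars
  use <- which((if (free_only) tab$free else TRUE) & !tab$centric &
                 !is.na(idx))
  if (!length(use)) return(0)
  phi <- phi_grid_deg(72) * pi / 180
  X <- rbind(cos(phi), sin(phi), cos(2 * phi), sin(2 * phi))
  hl <- as.matrix(tab[use, c("hl_a", "hl_b", "hl_c", "hl_d")])
  lq <- hl %*% X
  lq <- lq - row_logsumexp(lq)
  shell <- par$shell_index[use]
  K <- (1 - em$dm_corr) * 2 * par$d_dm[shell] * par$k_scale[shell] *
    dm$f_dm[idx[use]] * tab$f_bar[use] / pmax(par$sigma_e[shell], 1e-12)
  cosm <- cos(outer(dm$phi_dm[idx[use]] * pi / 180, phi, "-"))
  sum(row_logsumexp(lq + K * cosm) - log_i0(K))
}

#' Iterated density modification with phase combination
#'
#' Runs `n_cycles` of {synthesize (free reflections zero-weighted) ->
#' solvent mask -> modify -> invert -> estimate combination errors ->
#' combine}.  The experimental phases are combined afresh with the current
#' DM channel each cycle.  Deterministic given its inputs.
#'
#' @param data A [reflection_set] (free set flagged for CV estimation).
#' @param sub The [substructure] (used by the multivariate mode).
#' @param phases0 Experimental `phase_distribution` to start from.
#' @param n_cycles Number of cycles (>= 1).
#' @param mode `"multivariate"` (alpha-discounted) or `"mlhl"`.
#' @param solvent_fraction Solvent fraction for the mask.
#' @param em [error_model] from phasing.
#' @param density_mode `"flatten"` or `"flip"`.
#' @param flip_factor Flip strength when flipping.
#' @param cv Cross-validated error estimation (default) or work-set.
#' @param truth Optional `truth_record`: per-cycle true phase metrics are
#'   then logged.
#' @return List with `phases` (final combined), `map` (last modified map),
#'   `log` (per-cycle data frame) and `em` (with final DM parameters).
#' @export
run_dm_cycles <- function(data, sub, phases0, n_cycles,
                          mode = c("multivariate", "mlhl"),
                          solvent_fraction = 0.70, em,
                          density_mode = "flatten", flip_factor = 1,
                          cv = TRUE, truth = NULL) {
  mode <- match.arg(mode)
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  current <- phases0
  hkl <- as.matrix(data$obs[, c("h", "k", "l")])
  logs <- list()
  map <- NULL
  for (cy in seq_len(n_cycles)) {
    map0 <- synthesize_map(current, zero_free = TRUE)
    mask <- solvent_mask(map0, solvent_fraction)
    map <- modify_density(map0, mask, mode = density_mode,
                          flip_factor = flip_factor)
    dm <- map_to_sf(map, hkl)
    em <- estimate_comb_errors_cv(phases0, dm, em, cv = cv)
    current <- if (mode == "multivariate") {
      combine_phases_multivariate(data, sub, dm, em, exp_phases = phases0)
    } else {
      combine_phases_mlhl(phases0, dm, em)
    }
    row <- data.frame(cycle = cy, mean_fom = mean(current$table$fom),
                      alpha = em$dm_corr, mean_d_dm = mean(em$d_dm),
                      pred_loglik_free = dm_predictive_loglik(phases0, dm,
                                                              em))
    if (!is.null(truth)) {
      q <- phase_quality_vs_truth(current, truth)
      row$mean_cos_err <- q$mean_cos_err
      row$fom_weighted_err_deg <- q$fom_weighted_err_deg
    }
    logs[[cy]] <- row
  }
  list(phases = current, map = map, log = do.call(rbind, logs), em = em)
}

#' Determine the substructure hand
#'
#' Phases and density-modifies with both the substructure and its
#' enantiomorph; the hand with the higher cross-validated free-set
#' predictive log-likelihood of the density-modified channel wins.  A
#' difference below the noise floor (1.0 per 100 free reflections) returns
#' `"undetermined"`.
#'
#' @param data A [reflection_set] with a flagged free set.
#' @param sub Candidate [substructure].
#' @param em [error_model] from phasing (shared by both hands: the
#'   amplitudes - and hence the error parameters - are hand-invariant).
#' @param n_cycles DM cycles per hand.
#' @param ... Passed to [run_dm_cycles].
#' @return List with `decision` (`"original"`, `"inverted"`,
#'   `"undetermined"`), `delta_loglik`, and per-hand statistics.
#' @export
determine_hand <- function(data, sub, em, n_cycles = 3, ...) {
  sub_inv <- invert_hand(sub, data$sg)
  run_one <- function(s) {
    ph <- phase_substructure_sad(data, s, em)
    run_dm_cycles(data, s, ph, n_cycles = n_cycles, em = em, ...)
  }
  r_orig <- run_one(sub)
  r_inv <- run_one(sub_inv)
  l_orig <- utils::tail(r_orig$log$pred_loglik_free, 1)
  l_inv <- utils::tail(r_inv$log$pred_loglik_free, 1)
  n_free <- sum(data$obs$free)
  floor_ <- 1.0 * n_free / 100
  delta <- l_orig - l_inv
  decision <- if (abs(delta) < floor_) "undetermined" else
    if (delta > 0) "original" else "inverted"
  list(decision = decision, delta_loglik = delta, noise_floor = floor_,
       original = list(loglik = l_orig, log = r_orig$log,
                       mean_fom = mean(r_orig$phases$table$fom)),
       inverted = list(loglik = l_inv, log = r_inv$log,
                       mean_fom = mean(r_inv$phases$table$fom)),
       phases = if (decision == "inverted") r_inv$phases else r_orig$phases,
       sub = if (decision == "inverted") sub_inv else sub)
}
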