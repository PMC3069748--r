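# Substructure phasing from a joint probability of the observed Friedel
# pairs: phase posteriors on a grid, Hendrickson-Lattman coefficients and
# figures of merit, Luzzati error-parameter refinement, the substructure
# completeness check, and heavy-atom site refinement.
#
# Model per acentric reflection, given a substructure with heavy structure
# factors H+ = F_H(h), H- = conj(F_H(-h)) and shell error parameters:
#   F+  =  U + D s_h H+ ,   F-  =  U + D s_h H-
# where U = R exp(i phi) is the shared non-substructure channel (protein
# plus the unexplained part of the heavy signal), R has a Rayleigh prior
# with variance Sigma_U = Sigma_P + (1 - D^2) Sigma_G, s_h normalizes the
# model heavy power to the anomalous-difference power Sigma_G estimated
# from <dF^2>/(2 kappa^2) (no noise subtraction, so D reaches 1 only on
# noise-free data with the complete substructure), and the observed
# amplitudes are Rice-distributed about the model amplitudes with variance
# sigma_obs^2 + var_extra + kappa^2 (1 - D^2) Sigma_G.  The two Friedel
# observations are treated jointly (shared U), never through a merged
# Bijvoet-difference error.

phi_grid_deg <- function(n_phi) (seq_len(n_phi) - 1) * 360 / n_phi

#' Construct an error model
#'
#' Per-shell Luzzati parameters and variance terms for phasing, plus the
#' parameters of the density-modified channel (`dm_corr` = alpha, `d_dm`).
#'
#' @param shells Data frame with at least `shell`, `luzzati_d`, `var_extra`.
#' @param dm_corr Correlation discount alpha between the initial and
#'   density-modified maps, in `[0, 1]`.
#' @param d_dm Per-shell (or scalar) Luzzati-style parameter of the
#'   density-modified channel.
#' @export
error_model <- function(shells, dm_corr = 0, d_dm = 0) {
  stopifnot(all(c("shell", "luzzati_d", "var_extra") %in% names(shells)))
  stopifnot(all(shells$luzzati_d >= 0 & shells$luzzati_d <= 1))
  avg <- sum(shells$luzzati_d * shells$n) / sum(shells$n)
  structure(list(shells = shells, avg_luzzati = avg,
                 dm_corr = dm_corr, d_dm = d_dm),
            class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat(sprintf("error model: %d shells, <D> = %.3f, alpha = %.2f\n",
              nrow(x$shells), x$avg_luzzati, x$dm_corr))
  invisible(x)
}

# Shell-level second moments shared by phasing and error refinement.
# Returns one row per shell: total power, anomalous-difference power
# Sigma_G, model normal-heavy power, the model normalization s_h, the
# model kappa, and the Rice floor.
phasing_shell_params <- function(data, sub, n_shells = 10) {
  obs <- data$obs
  shell <- assign_shells(data, n_shells)
  hklm <- as.matrix(obs[, c("h", "k", "l")])
  st <- sub$sites
  g0 <- structure_factors(
    {
      s <- st; s$f_dprime <- 0; class(s) <- c("sites", "data.frame"); s
    },
    data$cell, data$sg, hklm
  )
  gmod <- Mod(g0$f_plus)
  s_mean <- vapply(seq_len(n_shells), function(s) {
    mean(1 / obs$d[shell == s])
  }, numeric(1))
  f0_eff <- vapply(s_mean, function(sm) {
    sum(st$occ * (st$f0_z * exp(-st$f0_width * sm^2) + st$f_prime))
  }, numeric(1))
  fdp_eff <- vapply(seq_len(n_shells), function(s) sum(st$occ * st$f_dprime),
                    numeric(1))
  kappa <- pmin(pmax(fdp_eff / pmax(f0_eff, 1e-6), 0.02), 2)
  out <- data.frame(shell = seq_len(n_shells), n = NA_real_,
                    d_max = NA_real_, d_min = NA_real_,
                    sigma_t = NA_real_, sigma_g = NA_real_,
                    sigma_gmod = NA_real_, s_h = NA_real_, kappa = kappa)
  for (s in seq_len(n_shells)) {
    i <- shell == s
    ia <- i & !obs$centric
    fbar <- (obs$f_plus[ia] + obs$f_minus[ia]) / 2
    out$n[s] <- sum(i)
    out$d_max[s] <- max(obs$d[i]); out$d_min[s] <- min(obs$d[i])
    out$sigma_t[s] <- mean(fbar^2)
    df2 <- mean((obs$f_plus[ia] - obs$f_minus[ia])^2)
    out$sigma_g[s] <- max(df2 / (2 * kappa[s]^2), 1e-8 * out$sigma_t[s])
    out$sigma_gmod[s] <- max(mean(gmod[ia]^2), 1e-12)
    out$s_h[s] <- sqrt(out$sigma_g[s] / out$sigma_gmod[s])
  }
  list(shells = out, shell_index = shell,
       h_plus = NULL, gmod = gmod)
}

# Joint Friedel-pair log marginal likelihood and phase posterior for a set
# of reflections, vectorized per shell.  Returns the posterior matrix
# (rows: reflections, cols: phase grid), the per-reflection log marginal
# likelihood, and bookkeeping columns.
sad_posterior_engine <- function(data, sub, em, n_phi = 72, n_amp = 12,
                                 mode = c("joint", "gaussian_df"),
                                 native = NULL, pars = NULL) {
  mode <- match.arg(mode)
  obs <- data$obs
  n <- nrow(obs)
  n_shells <- nrow(em$shells)
  if (is.null(pars)) pars <- phasing_shell_params(data, sub, n_shells)
  shell <- pars$shell_index
  hklm <- as.matrix(obs[, c("h", "k", "l")])
  fh <- structure_factors(sub, data$cell, data$sg, hklm)
  h_plus <- fh$f_plus
  h_minus <- Conj(fh$f_minus)   # conj(F_H(-h)): same protein-phase frame
  phi <- phi_grid_deg(n_phi) * pi / 180
  eip <- exp(1i * phi)
  post <- matrix(0, n, n_phi)
  logmarg <- numeric(n)
  uninformative <- Mod(h_plus) + Mod(h_minus) < 1e-10
  nat_obs <- NULL
  if (!is.null(native)) {
    kd <- paste(obs$h, obs$k, obs$l)
    kn <- paste(native$obs$h, native$obs$k, native$obs$l)
    idx <- match(kd, kn)
    nat_obs <- data.frame(f = native$obs$f_plus[idx],
                          sig = native$obs$sig_plus[idx])
  }
  for (s in seq_len(n_shells)) {
    p <- em$shells[s, ]
    sp <- pars$shells[s, ]
    sigma_p <- max(sp$sigma_t - (1 + sp$kappa^2) * sp$sigma_g,
                   0.05 * sp$sigma_t)
    # beta scales the model heavy centers; the residual anomalous power
    # not explained by the scaled model inflates the shared channel and
    # the per-mate variances.  beta = luzzati_d * s_h when not supplied.
    beta <- if (!is.null(p$beta)) p$beta else p$luzzati_d * sp$s_h
    resid <- if (!is.null(p$v_res)) p$v_res else
      max(sp$sigma_g - beta^2 * sp$sigma_gmod, 0)
    sigma_u <- sigma_p + resid
    v_anom <- sp$kappa^2 * resid
    idx <- which(shell == s & !uninformative)
    if (!length(idx)) next
    rp <- obs$f_plus[idx]; rm_ <- obs$f_minus[idx]
    cp <- beta * h_plus[idx]
    cm <- beta * h_minus[idx]
    # variance floors: an absolute numerical floor plus the phase-grid
    # discretization error (the model amplitude moves by up to about
    # |center| * dphi/2 between grid points, which acts as model error)
    floor2 <- (2e-3 * sqrt(sp$sigma_t))^2
    fg_p <- (0.35 * (2 * pi / n_phi) * Mod(cp))^2
    fg_m <- (0.35 * (2 * pi / n_phi) * Mod(cm))^2
    s2p <- pmax(obs$sig_plus[idx]^2 + p$var_extra + v_anom, floor2, fg_p)
    s2m <- pmax(obs$sig_minus[idx]^2 + p$var_extra + v_anom, floor2, fg_m)
    cen <- obs$centric[idx]
    nl <- length(idx)
    # Laplace profile over the shared-channel amplitude R: the integrand is
    # close to quadratic in R (the Rice exponent is quadratic in the model
    # amplitude, which is nearly linear in R), so a short vectorized
    # parabola search followed by a curvature correction integrates both
    # razor-thin (noise-free) and broad likelihood ridges accurately.
    fn_nat <- NULL; sn_nat <- NULL
    if (!is.null(nat_obs)) {
      fn_nat <- nat_obs$f[idx]; sn_nat <- pmax(nat_obs$sig[idx]^2 +
                                                 p$var_extra, floor2)
    }
    f_eval <- function(R) {
      u <- R * matrix(eip, nl, n_phi, byrow = TRUE)
      mu_p <- Mod(matrix(cp, nl, n_phi) + u)
      mu_m <- Mod(matrix(cm, nl, n_phi) + u)
      if (mode == "joint") {
        ll <- log_rice(rp, mu_p, s2p) + log_rice(rm_, mu_m, s2m)
        if (any(cen)) {
          # centric pairs are one measurement: a single Rice term
          ll[cen, ] <- log_rice(rp[cen], mu_p[cen, , drop = FALSE],
                                s2p[cen])
        }
      } else {
        s2d <- s2p + s2m
        ll <- -((rp - rm_) - (mu_p - mu_m))^2 / (2 * s2d) - 0.5 * log(s2d)
        if (any(cen)) ll[cen, ] <- log_rice(rp[cen],
                                            mu_p[cen, , drop = FALSE],
                                            s2p[cen])
      }
      if (!is.null(fn_nat)) {
        ok <- !is.na(fn_nat)
        if (any(ok)) {
          ll[ok, ] <- ll[ok, ] + log_rice(fn_nat[ok], R[ok, , drop = FALSE],
                                          sn_nat[ok])
        }
      }
      ll + log(pmax(2 * R / sigma_u, 1e-290)) - R^2 / sigma_u
    }
    su <- sqrt(sigma_u)
    fbar_m <- matrix((rp + rm_) / 2, nl, n_phi)
    # start points: Rayleigh quantiles of the prior plus data-proportional
    # candidates, so strong reflections far out in the prior tail still
    # reach their likelihood ridge
    starts <- c(lapply(rayleigh_nodes(sigma_u, max(n_amp, 6)),
                       function(Rk) matrix(Rk, nl, n_phi)),
                lapply(c(0.5, 0.75, 1, 1.25), function(fac) fac * fbar_m))
    fbest <- matrix(-Inf, nl, n_phi)
    rbest <- matrix(0, nl, n_phi)
    for (Rm in starts) {
      fk <- f_eval(Rm)
      upd <- fk > fbest
      fbest[upd] <- fk[upd]; rbest[upd] <- Rm[upd]
    }
    step0 <- pmax(su, 0.5 * fbar_m)
    f0 <- fbest; fm <- NULL; fp <- NULL; dlt <- NULL
    for (dfrac in c(0.3, 0.1, 0.03)) {
      dlt <- dfrac * step0
      fm <- f_eval(pmax(rbest - dlt, 0))
      fp <- f_eval(rbest + dlt)
      den <- fm - 2 * f0 + fp
      shift <- ifelse(is.finite(den) & den < 0,
                      0.5 * dlt * (fm - fp) / den, 0)
      shift <- pmax(pmin(shift, dlt), -dlt)
      # fall back to the best probed point when the parabola is invalid
      take_m <- fm > f0 & fm > fp & !(den < 0)
      take_p <- fp > f0 & fp >= fm & !(den < 0)
      rnew <- rbest + shift
      rnew[take_m] <- pmax(rbest - dlt, 0)[take_m]
      rnew[take_p] <- (rbest + dlt)[take_p]
      rbest <- pmax(rnew, 1e-6 * su)
      f0 <- f_eval(rbest)
    }
    fm <- f_eval(pmax(rbest - dlt, 1e-7 * su))
    fp <- f_eval(rbest + dlt)
    curv <- pmax(-(fm - 2 * f0 + fp) / dlt^2, 1e-12 / sigma_u)
    acc <- f0 + 0.5 * log(2 * pi / curv)
    # restrict centric reflections to their allowed two-point set
    if (any(cen)) {
      allowed <- outer(obs$phi0_deg[idx][cen], phi_grid_deg(n_phi),
                       function(a, b) {
                         pmin(abs(a - b) %% 360, 360 - abs(a - b) %% 360) <
                           1e-6 |
                           pmin(abs(a + 180 - b) %% 360,
                                360 - abs(a + 180 - b) %% 360) < 1e-6
                       })
      accc <- acc[cen, , drop = FALSE]
      accc[!allowed] <- -Inf
      acc[cen, ] <- accc
    }
    lm_ <- row_logsumexp(acc)
    post[idx, ] <- exp(acc - lm_)
    logmarg[idx] <- lm_ - log(n_amp * n_phi)
  }
  if (any(uninformative)) {
    post[uninformative, ] <- 1 / n_phi
    logmarg[uninformative] <- 0
  }
  list(post = post, logmarg = logmarg, phi_deg = phi_grid_deg(n_phi),
       uninformative = uninformative, shell = shell, pars = pars)
}

#' Hendrickson-Lattman coefficients and figure of merit from a posterior grid
#'
#' The centroid phase and figure of merit come from the grid itself; the HL
#' coefficients (A, B, C, D) are a weighted least-squares fit of the
#' log-posterior on the basis `{cos, sin, cos 2, sin 2}` (weights equal to
#' the posterior mass, so the fit is anchored where the probability lives),
#' followed by a one-dimensional rescaling of (A, B) that matches the
#' HL-reconstructed figure of merit to the grid figure of merit.  Centric
#' reflections get the two-point restricted representation (C = D = 0, HL
#' vector along the allowed phase axis).
#'
#' @param post Posterior matrix (rows sum to 1) or a single vector.
#' @param phi_deg Phase grid in degrees.
#' @param centric Logical per reflection.
#' @param phi0_deg Allowed-phase origin for centric reflections.
#' @return Data frame `hl_a, hl_b, hl_c, hl_d, phi_best, fom`.
#' @export
hl_and_fom <- function(post, phi_deg, centric = NULL, phi0_deg = NULL) {
  if (is.null(dim(post))) post <- matrix(post, 1)
  n <- nrow(post); n_phi <- ncol(post)
  centric <- centric %||% rep(FALSE, n)
  phi0_deg <- phi0_deg %||% rep(0, n)
  phi <- phi_deg * pi / 180
  m1 <- as.vector(post %*% exp(1i * phi))
  fom <- Mod(m1)
  phi_best <- (Arg(m1) * 180 / pi) %% 360
  flat <- apply(abs(post - 1 / n_phi), 1, max) < 1e-9
  X <- cbind(1, cos(phi), sin(phi), cos(2 * phi), sin(2 * phi))
  coef <- matrix(0, n, 4)
  ac <- which(!centric & !flat)
  for (i in ac) {
    w <- post[i, ] + 1e-6
    lp <- log(pmax(post[i, ], 1e-290))
    xw <- X * w
    cf <- tryCatch(solve(crossprod(X, xw), crossprod(xw, lp)),
                   error = function(e) rep(0, 5))
    coef[i, ] <- cf[2:5]
  }
  # rescale (A, B) so the HL representation reproduces the grid FOM
  if (length(ac)) {
    fom_from <- function(cf) {
      lq <- cf %*% t(X[, 2:5])
      q <- exp(lq - row_logsumexp(lq))
      Mod(as.vector(q %*% exp(1i * phi)))
    }
    f0 <- fom_from(coef[ac, , drop = FALSE])
    need <- which(abs(f0 - fom[ac]) > 0.005)
    if (length(need)) {
      ii <- ac[need]
      lo <- rep(0, length(ii)); hi <- rep(1, length(ii))
      # expand hi until fom exceeded or cap
      for (rep_ in 1:30) {
        cf <- coef[ii, , drop = FALSE]
        cf[, 1:2] <- cf[, 1:2] * hi
        f <- fom_from(cf)
        done <- f >= fom[ii] | hi > 64
        if (all(done)) break
        hi[!done] <- hi[!done] * 2
      }
      for (rep_ in 1:40) {
        mid <- (lo + hi) / 2
        cf <- coef[ii, , drop = FALSE]
        cf[, 1:2] <- cf[, 1:2] * mid
        f <- fom_from(cf)
        up <- f < fom[ii]
        lo[up] <- mid[up]; hi[!up] <- mid[!up]
      }
      coef[ii, 1:2] <- coef[ii, 1:2, drop = FALSE] * (lo + hi) / 2
    }
  }
  # centric reflections: two-point representation
  ce <- which(centric & !flat)
  if (length(ce)) {
    for (i in ce) {
      ia <- which.min(phase_diff_deg(phi_deg, phi0_deg[i]))
      ib <- which.min(phase_diff_deg(phi_deg, phi0_deg[i] + 180))
      p1 <- post[i, ia]; p2 <- post[i, ib]
      aa <- 0.5 * (log(pmax(p1, 1e-290)) - log(pmax(p2, 1e-290)))
      aa <- max(min(aa, 30), -30)
      coef[i, ] <- c(aa * cos(phi0_deg[i] * pi / 180),
                     aa * sin(phi0_deg[i] * pi / 180), 0, 0)
      fom[i] <- abs(p1 - p2)
      phi_best[i] <- if (p1 >= p2) phi0_deg[i] else (phi0_deg[i] + 180) %% 360
    }
  }
  if (any(flat)) {
    coef[flat, ] <- 0; fom[flat] <- 0; phi_best[flat] <- 0
  }
  data.frame(hl_a = coef[, 1], hl_b = coef[, 2], hl_c = coef[, 3],
             hl_d = coef[, 4], phi_best = phi_best, fom = pmin(fom, 1))
}

new_phase_distribution <- function(data, hl, extra = NULL) {
  obs <- data$obs
  tab <- data.frame(
    h = obs$h, k = obs$k, l = obs$l, d = obs$d,
    centric = obs$centric, phi0_deg = obs$phi0_deg, free = obs$free,
    f_bar = (obs$f_plus + obs$f_minus) / 2,
    hl, stringsAsFactors = FALSE
  )
  structure(c(list(table = tab, cell = data$cell, sg = data$sg,
                   label = data$label), extra),
            class = "phase_distribution")
}

#' @export
print.phase_distribution <- function(x, ...) {
  cat(sprintf("phase distribution: %d reflections, <fom> = %.3f\n",
              nrow(x$table), mean(x$table$fom)))
  invisible(x)
}

#' Substructure phasing of a SAD dataset (joint Friedel-pair likelihood)
#'
#' Computes the phase posterior of every reflection on a uniform grid from
#' the joint likelihood of both Friedel mates given the substructure (see
#' the model sketch in this file's header), then summarizes each posterior
#' as Hendrickson-Lattman coefficients, a centroid phase and a figure of
#' merit.  `mode = "gaussian_df"` switches to the classical merged-error
#' Gaussian on Bijvoet differences (the reference treatment this package's
#' joint mode is designed to beat).
#'
#' @param data A [reflection_set].
#' @param sub A [substructure].
#' @param em An [error_model] (e.g. from [refine_error_model]).
#' @param n_phi Phase grid size (>= 72).
#' @param n_amp Amplitude quadrature nodes for the shared channel.
#' @param mode `"joint"` or `"gaussian_df"`.
#' @return A `phase_distribution`.
#' @export
phase_substructure_sad <- function(data, sub, em, n_phi = 72, n_amp = 12,
                                   mode = c("joint", "gaussian_df")) {
  if (n_phi < 72) stop("n_phi must be at least 72")
  mode <- match.arg(mode)
  if (nrow(sub$sites) == 0) stop("empty substructure")
  eng <- sad_posterior_engine(data, sub, em, n_phi, n_amp, mode)
  hl <- hl_and_fom(eng$post, eng$phi_deg, data$obs$centric,
                   data$obs$phi0_deg)
  hl$uninformative <- eng$uninformative
  new_phase_distribution(data, hl)
}

#' Phase posterior for a single reflection
#'
#' Single-observation interface to the SAD posterior: returns the
#' normalized posterior on the phase grid together with its HL summary.
#'
#' @param obs One-row data frame with the observation columns of a
#'   [reflection_set] plus `d`, `centric`, `phi0_deg`.
#' @param f_h_plus,f_h_minus Complex heavy structure factors F_H(h), F_H(-h).
#' @param em An [error_model] whose shell table carries `sigma_t, sigma_g,
#'   s_h, kappa` (as produced by [refine_error_model]).
#' @param n_phi Grid size (>= 72).
#' @return List with `phi_deg`, `posterior` (sums to 1), and `hl` (one-row
#'   data frame).
#' @export
phase_posterior_sad <- function(obs, f_h_plus, f_h_minus, em, n_phi = 72) {
  if (n_phi < 72) stop("n_phi must be at least 72")
  sh <- em$shells
  s <- findInterval(-obs$d, sort(-sh$d_max))
  s <- max(min(s, nrow(sh)), 1)
  p <- sh[s, ]
  if (Mod(f_h_plus) + Mod(f_h_minus) < 1e-10) {
    post <- rep(1 / n_phi, n_phi)
    hl <- hl_and_fom(post, phi_grid_deg(n_phi))
    return(list(phi_deg = phi_grid_deg(n_phi), posterior = post, hl = hl,
                uninformative = TRUE))
  }
  sigma_p <- max(p$sigma_t - (1 + p$kappa^2) * p$sigma_g, 0.05 * p$sigma_t)
  beta <- if (!is.null(p$beta)) p$beta else p$luzzati_d * p$s_h
  resid <- if (!is.null(p$v_res)) p$v_res else
    max(p$sigma_g - beta^2 * p$sigma_gmod, 0)
  sigma_u <- sigma_p + resid
  v_anom <- p$kappa^2 * resid
  s2p <- obs$sig_plus^2 + p$var_extra + v_anom
  s2m <- obs$sig_minus^2 + p$var_extra + v_anom
  cp <- beta * f_h_plus
  cm <- beta * Conj(f_h_minus)
  phi <- phi_grid_deg(n_phi) * pi / 180
  amp <- rayleigh_nodes(sigma_u, 16)
  lg <- vapply(amp, function(R) {
    u <- R * exp(1i * phi)
    if (obs$centric) {
      log_rice(obs$f_plus, Mod(cp + u), s2p)
    } else {
      log_rice(obs$f_plus, Mod(cp + u), s2p) +
        log_rice(obs$f_minus, Mod(cm + u), s2m)
    }
  }, numeric(n_phi))
  acc <- row_logsumexp(lg)
  if (obs$centric) {
    allowed <- phase_diff_deg(phi_grid_deg(n_phi), obs$phi0_deg) < 1e-6 |
      phase_diff_deg(phi_grid_deg(n_phi), obs$phi0_deg + 180) < 1e-6
    acc[!allowed] <- -Inf
  }
  post <- exp(acc - max(acc)); post <- post / sum(post)
  hl <- hl_and_fom(post, phi_grid_deg(n_phi), obs$centric, obs$phi0_deg)
  list(phi_deg = phi_grid_deg(n_phi), posterior = post, hl = hl,
       uninformative = FALSE)
}

#' Uncorrelated SIRAS phasing
#'
#' Adds an independent Rice term for the native amplitude (which measures
#' the shared non-substructure channel directly) to the joint SAD
#' likelihood of the derivative Friedel pair; the two error channels are
#' treated as independent.  Reflections without a native mate fall back to
#' the SAD term alone and are flagged.
#'
#' @param deriv Derivative [reflection_set] (with anomalous signal).
#' @param native Native [reflection_set].
#' @param sub A [substructure].
#' @param em An [error_model].
#' @param n_phi,n_amp Grid sizes.
#' @return A `phase_distribution` with a `native_used` column.
#' @export
phase_substructure_siras <- function(deriv, native, sub, em, n_phi = 72,
                                     n_amp = 12) {
  if (n_phi < 72) stop("n_phi must be at least 72")
  # scale native to the derivative on Friedel means per shell
  kd <- paste(deriv$obs$h, deriv$obs$k, deriv$obs$l)
  kn <- paste(native$obs$h, native$obs$k, native$obs$l)
  idx <- match(kd, kn)
  shell <- assign_shells(deriv, nrow(em$shells))
  nat <- native
  scl <- rep(1, nrow(deriv$obs))
  for (s in seq_len(nrow(em$shells))) {
    i <- which(shell == s & !is.na(idx))
    fd <- (deriv$obs$f_plus[i] + deriv$obs$f_minus[i]) / 2
    fn <- native$obs$f_plus[idx[i]]
    if (length(i) > 5 && sum(fn^2) > 0) scl[i] <- sum(fd * fn) / sum(fn^2)
  }
  nat$obs$f_plus[idx[!is.na(idx)]] <-
    native$obs$f_plus[idx[!is.na(idx)]] * scl[!is.na(idx)]
  nat$obs$sig_plus[idx[!is.na(idx)]] <-
    native$obs$sig_plus[idx[!is.na(idx)]] * scl[!is.na(idx)]
  eng <- sad_posterior_engine(deriv, sub, em, n_phi, n_amp, "joint",
                              native = nat)
  hl <- hl_and_fom(eng$post, eng$phi_deg, deriv$obs$centric,
                   deriv$obs$phi0_deg)
  hl$native_used <- !is.na(idx)
  new_phase_distribution(deriv, hl)
}

#' Phase posterior for a single reflection with a native observation
#'
#' Uncorrelated SIRAS posterior for one reflection: the joint SAD
#' likelihood of the derivative Friedel pair times an independent Rice
#' term for the (scaled) native amplitude, which measures the shared
#' non-substructure channel directly.  With a missing native observation
#' (`NA`) the result falls back to the SAD posterior and is flagged.
#'
#' @param native_obs One-row data frame with `f_plus`, `sig_plus` (the
#'   native measurement), or `NULL`/`NA` when absent.
#' @param deriv_obs One-row observation data frame (see
#'   [phase_posterior_sad]).
#' @param f_h_plus,f_h_minus Complex heavy structure factors.
#' @param em An [error_model] from [refine_error_model].
#' @param n_phi Grid size (>= 72).
#' @return As [phase_posterior_sad], plus `native_used`.
#' @export
phase_posterior_siras_uncorrelated <- function(native_obs, deriv_obs,
                                               f_h_plus, f_h_minus, em,
                                               n_phi = 72) {
  if (n_phi < 72) stop("n_phi must be at least 72")
  base <- phase_posterior_sad(deriv_obs, f_h_plus, f_h_minus, em, n_phi)
  nat_ok <- !is.null(native_obs) && nrow(native_obs) >= 1 &&
    is.finite(native_obs$f_plus[1])
  if (!nat_ok || base$uninformative) {
    base$native_used <- FALSE
    return(base)
  }
  sh <- em$shells
  s <- findInterval(-deriv_obs$d, sort(-sh$d_max))
  s <- max(min(s, nrow(sh)), 1)
  p <- sh[s, ]
  sigma_p <- max(p$sigma_t - (1 + p$kappa^2) * p$sigma_g, 0.05 * p$sigma_t)
  beta <- if (!is.null(p$beta)) p$beta else p$luzzati_d * p$s_h
  resid <- if (!is.null(p$v_res)) p$v_res else
    max(p$sigma_g - beta^2 * p$sigma_gmod, 0)
  sigma_u <- sigma_p + resid
  v_anom <- p$kappa^2 * resid
  s2p <- deriv_obs$sig_plus^2 + p$var_extra + v_anom
  s2m <- deriv_obs$sig_minus^2 + p$var_extra + v_anom
  s2n <- native_obs$sig_plus[1]^2 + p$var_extra
  cp <- beta * f_h_plus
  cm <- beta * Conj(f_h_minus)
  phi <- phi_grid_deg(n_phi) * pi / 180
  amp <- rayleigh_nodes(sigma_u, 16)
  lg <- vapply(amp, function(R) {
    u <- R * exp(1i * phi)
    ll <- if (deriv_obs$centric) {
      log_rice(deriv_obs$f_plus, Mod(cp + u), s2p)
    } else {
      log_rice(deriv_obs$f_plus, Mod(cp + u), s2p) +
        log_rice(deriv_obs$f_minus, Mod(cm + u), s2m)
    }
    ll + log_rice(native_obs$f_plus[1], R, s2n)
  }, numeric(n_phi))
  acc <- row_logsumexp(lg)
  if (deriv_obs$centric) {
    allowed <- phase_diff_deg(phi_grid_deg(n_phi), deriv_obs$phi0_deg) <
      1e-6 |
      phase_diff_deg(phi_grid_deg(n_phi), deriv_obs$phi0_deg + 180) < 1e-6
    acc[!allowed] <- -Inf
  }
  post <- exp(acc - max(acc)); post <- post / sum(post)
  hl <- hl_and_fom(post, phi_grid_deg(n_phi), deriv_obs$centric,
                   deriv_obs$phi0_deg)
  list(phi_deg = phi_grid_deg(n_phi), posterior = post, hl = hl,
       uninformative = FALSE, native_used = TRUE)
}

#' Refine per-shell Luzzati error parameters
#'
#' Two-stage deterministic refinement.  (1) The global center scale beta
#' of the model substructure (shell-independent: site occupancies and
#' B-factors already carry the resolution dependence) is calibrated from
#' the anomalous cross-moment `<|dF| |G_model|>`, whose model expectation
#' is matched by monotone bisection - an unbiased estimating equation that
#' does not inherit the overscaling tendency of profile likelihoods on
#' amplitude-only data.  (2) With the scale fixed, the residual
#' (unexplained) heavy variance per shell is refined by maximizing the
#' summed exact log marginal likelihood of the Friedel pairs over work
#' reflections (see `bivar_rician_logmarg`), optionally followed by a
#' global `var_extra`.  The reported Luzzati parameter per shell is the
#' explained fraction of the observed anomalous-difference amplitude,
#' `D = beta sqrt(Sigma_Gmodel / Sigma_Gdata)` clamped to [0, 1]; since
#' the denominator includes measurement noise, D approaches 1 only on
#' noise-free data with a complete, correct substructure and decreases
#' monotonically as noise is added.  `avg_luzzati` is the
#' reflection-count-weighted mean of the per-shell D.
#'
#' @param data A [reflection_set].
#' @param sub A [substructure].
#' @param em0 Optional starting [error_model] (supplies `var_extra`).
#' @param n_shells Number of shells.
#' @param refine_var_extra Also refine a global variance inflation.
#' @return An [error_model] whose shell table carries the fitted D, the
#'   center scale `beta`, the residual variance `v_res`, `var_extra` and
#'   the shell moments used by the phasing likelihood.
#' @export
refine_error_model <- function(data, sub, em0 = NULL, n_shells = 10,
                               refine_var_extra = FALSE) {
  if (nrow(sub$sites) == 0) stop("empty substructure")
  pars <- phasing_shell_params(data, sub, n_shells)
  work <- !data$obs$free
  ve0 <- if (is.null(em0)) 0 else em0$shells$var_extra[1]
  obs <- data$obs
  fh <- structure_factors(sub, data$cell, data$sg,
                          as.matrix(obs[, c("h", "k", "l")]))
  h_plus <- fh$f_plus; h_minus <- Conj(fh$f_minus)
  shell <- pars$shell_index
  gmod <- pars$gmod
  # stage 1: global center scale by the anomalous cross-moment
  ac <- which(!obs$centric & work)
  dfo <- abs(obs$f_plus[ac] - obs$f_minus[ac])
  gk <- gmod[ac]
  kap <- pars$shells$kappa[shell[ac]]
  s2d <- obs$sig_plus[ac]^2 + obs$sig_minus[ac]^2
  t1 <- vapply(seq_len(n_shells), function(s) {
    i <- shell[ac] == s
    max(mean(dfo[i]^2) - mean(s2d[i]), 0)
  }, numeric(1))
  target <- sum(dfo * gk)
  model_cross <- function(beta) {
    v <- pmax((t1 - 2 * pars$shells$kappa^2 * beta^2 *
                 pars$shells$sigma_gmod) / (2 * pars$shells$kappa^2), 0)
    vv <- v[shell[ac]]
    sum(sqrt(2 / pi) * sqrt(2 * kap^2 * (beta^2 * gk^2 + vv) + s2d) * gk)
  }
  lo <- 0; hi <- 2
  if (model_cross(0) >= target) {
    beta_glob <- 0
  } else if (model_cross(hi) <= target) {
    beta_glob <- hi
  } else {
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      if (model_cross(mid) < target) lo <- mid else hi <- mid
    }
    beta_glob <- (lo + hi) / 2
  }
  beta_hat <- rep(beta_glob, n_shells)
  d_hat <- beta_hat / pars$shells$s_h
  # stage 2: residual heavy variance per shell by the exact marginal
  # likelihood of the Friedel pairs
  v_mom <- pmax((t1 - 2 * pars$shells$kappa^2 * beta_glob^2 *
                   pars$shells$sigma_gmod) / (2 * pars$shells$kappa^2), 0)
  ref <- pmax(v_mom, 0.05 * pars$shells$sigma_g)
  v_grid <- c(0.005, 0.03, 0.1, 0.25, 0.5, 0.75, 1, 1.5, 2.5)
  llv <- vapply(v_grid, function(fac) {
    lm <- sad_marginal_loglik(data, sub, d_hat, ve0, pars,
                              h_plus = h_plus, h_minus = h_minus,
                              v_res = fac * ref)
    vapply(seq_len(n_shells), function(s) {
      sum(lm[shell == s & work])
    }, numeric(1))
  }, numeric(n_shells))
  if (n_shells == 1) llv <- matrix(llv, 1)
  v_hat <- numeric(n_shells)
  for (s in seq_len(n_shells)) {
    jv <- which.max(llv[s, ])
    v_hat[s] <- v_grid[jv]
    if (jv > 1 && jv < length(v_grid)) {
      x <- log(v_grid[(jv - 1):(jv + 1)]); y <- llv[s, (jv - 1):(jv + 1)]
      num <- (x[2] - x[1])^2 * (y[2] - y[3]) -
        (x[2] - x[3])^2 * (y[2] - y[1])
      den <- (x[2] - x[1]) * (y[2] - y[3]) -
        (x[2] - x[3]) * (y[2] - y[1])
      if (is.finite(den) && abs(den) > 0) {
        vx <- x[2] - 0.5 * num / den
        if (is.finite(vx)) v_hat[s] <- exp(max(min(vx, x[3]), x[1]))
      }
    }
  }
  v_hat <- v_hat * ref
  d_rep <- pmin(beta_hat * sqrt(pars$shells$sigma_gmod /
                                  pars$shells$sigma_g), 1)
  ve_hat <- ve0
  if (refine_var_extra) {
    scale2 <- mean(pars$shells$sigma_t)
    eval_ve <- function(ve) {
      lm <- sad_marginal_loglik(data, sub, d_hat, ve, pars,
                                h_plus = h_plus, h_minus = h_minus,
                                v_res = v_hat)
      sum(lm[work])
    }
    opt <- stats::optimize(function(lv) -eval_ve(exp(lv)),
                           interval = log(c(1e-8, 0.1) * scale2))
    ve_hat <- exp(opt$minimum)
  }
  shells <- cbind(
    data.frame(shell = seq_len(n_shells), n = pars$shells$n,
               d_max = pars$shells$d_max, d_min = pars$shells$d_min,
               luzzati_d = d_rep, beta = beta_hat,
               v_res = v_hat, var_extra = ve_hat),
    pars$shells[, c("sigma_t", "sigma_g", "sigma_gmod", "s_h", "kappa")]
  )
  error_model(shells,
              dm_corr = if (is.null(em0)) 0 else em0$dm_corr,
              d_dm = if (is.null(em0)) 0 else em0$d_dm)
}

#' Substructure completeness check ("check mode")
#'
#' Runs a reduced-budget Luzzati refinement and declares the substructure
#' complete when the average Luzzati parameter exceeds the threshold
#' (default 0.7).
#'
#' @param data A [reflection_set].
#' @param sub Candidate [substructure].
#' @param threshold Completeness threshold on the average Luzzati D.
#' @return List with `status` (`"complete"` / `"incomplete"`),
#'   `avg_luzzati` and the fitted [error_model].
#' @export
check_substructure_complete <- function(data, sub, threshold = 0.7) {
  em <- refine_error_model(data, sub, n_shells = 10)
  list(status = if (em$avg_luzzati > threshold) "complete" else "incomplete",
       avg_luzzati = em$avg_luzzati, error_model = em)
}

#' Refine heavy-atom sites against the joint Friedel likelihood
#'
#' Bounded quasi-Newton maximization of the same marginal likelihood used
#' by [refine_error_model] over per-site fractional coordinates,
#' occupancies (bounded to (0, 2]) and B-factors (bounded to [2, 100]).
#' Sites closer than 1 A after refinement are merged with a warning.  The
#' likelihood is evaluated on a deterministic reflection subsample for
#' speed.
#'
#' @param data A [reflection_set].
#' @param sub Starting [substructure].
#' @param em An [error_model].
#' @param max_reflections Subsample size for the objective.
#' @param maxit Iteration budget.
#' @return The refined [substructure].
#' @export
refine_sites <- function(data, sub, em, max_reflections = 2500, maxit = 30) {
  if (nrow(sub$sites) == 0) stop("empty substructure")
  obs <- data$obs
  n <- nrow(obs)
  keep <- if (n > max_reflections) {
    round(seq(1, n, length.out = max_reflections))
  } else seq_len(n)
  sml <- data
  sml$obs <- obs[keep, , drop = FALSE]
  ns <- nrow(sub$sites)
  par0 <- unlist(lapply(seq_len(ns), function(i) {
    c(sub$sites$x[i], sub$sites$y[i], sub$sites$z[i],
      sub$sites$occ[i], sub$sites$b[i])
  }))
  build <- function(par) {
    st <- sub$sites
    for (i in seq_len(ns)) {
      p <- par[(i - 1) * 5 + 1:5]
      st$x[i] <- wrap_frac(p[1]); st$y[i] <- wrap_frac(p[2])
      st$z[i] <- wrap_frac(p[3])
      st$occ[i] <- p[4]; st$b[i] <- p[5]
    }
    substructure(st, hand = sub$hand)
  }
  rms_f <- sqrt(mean(((sml$obs$f_plus + sml$obs$f_minus) / 2)^2))
  objective <- function(par, ve) {
    s2 <- build(par)
    pars <- phasing_shell_params(sml, s2, nrow(em$shells))
    # hold the physical center scale fixed while sites move
    dvec <- em$shells$beta / pars$shells$s_h
    -sum(sad_marginal_loglik(sml, s2, dvec, ve, pars,
                             v_res = em$shells$v_res))
  }
  lower <- rep(c(-Inf, -Inf, -Inf, 1e-3, 2), ns)
  upper <- rep(c(Inf, Inf, Inf, 2, 100), ns)
  # deterministic cyclic coordinate descent with parabolic line steps and
  # a shrinking step schedule; robust against the small quadrature noise
  # of the marginal likelihood that defeats finite-difference gradients
  par_cur <- par0
  ve <- (0.002 * rms_f)^2
  step0 <- rep(c(0.008, 0.008, 0.008, 0.2, 5), ns)
  f_cur <- objective(par_cur, ve)
  n_rounds <- max(3, min(8, ceiling(maxit / 4)))
  for (round_ in seq_len(n_rounds)) {
    delta <- step0 * 0.55^(round_ - 1)
    for (p in seq_along(par_cur)) {
      pm <- par_cur; pm[p] <- max(par_cur[p] - delta[p], lower[p])
      pp <- par_cur; pp[p] <- min(par_cur[p] + delta[p], upper[p])
      fm <- objective(pm, ve); fp <- objective(pp, ve)
      den <- fm - 2 * f_cur + fp
      cand <- par_cur
      if (is.finite(den) && den > 0) {
        shift <- 0.5 * delta[p] * (fm - fp) / den
        cand[p] <- min(max(par_cur[p] + max(min(shift, delta[p]),
                                            -delta[p]), lower[p]),
                       upper[p])
      }
      fc <- if (all(cand == par_cur)) f_cur else objective(cand, ve)
      best <- which.min(c(f_cur, fm, fp, fc))
      if (best == 2) { par_cur <- pm; f_cur <- fm }
      else if (best == 3) { par_cur <- pp; f_cur <- fp }
      else if (best == 4) { par_cur <- cand; f_cur <- fc }
    }
  }
  out <- build(par_cur)
  # merge near-degenerate sites
  if (ns > 1) {
    dmat <- outer(seq_len(ns), seq_len(ns), Vectorize(function(i, j) {
      if (i >= j) return(Inf)
      site_distance(data$cell, data$sg,
                    as.numeric(out$sites[i, c("x", "y", "z")]),
                    as.numeric(out$sites[j, c("x", "y", "z")]))
    }))
    close_ <- which(dmat < 1, arr.ind = TRUE)
    if (nrow(close_)) {
      warning("merging ", nrow(close_), " site pair(s) closer than 1 A")
      drop_ <- unique(close_[, 2])
      keep_ <- setdiff(seq_len(ns), drop_)
      for (r in seq_len(nrow(close_))) {
        out$sites$occ[close_[r, 1]] <- out$sites$occ[close_[r, 1]] +
          out$sites$occ[close_[r, 2]]
      }
      st <- out$sites[keep_, , drop = FALSE]
      class(st) <- c("sites", "data.frame")
      out <- substructure(st, hand = out$hand)
    }
  }
  out
}

#' Phase quality against simulator ground truth
#'
#' Mean cosine phase error and FOM-weighted mean absolute phase error over
#' acentric reflections, plus an amplitude-matched map correlation: the
#' correlation between the FOM-weighted Fourier coefficients
#' `m |F| exp(i phi_best)` and the coefficients with the true protein
#' phases `|F| exp(i phi_true)` (identical amplitudes, so the statistic
#' isolates phase agreement).  With `align_origin = TRUE` the comparison
#' is made modulo the allowed origin shifts of the space group (discrete
#' shifts plus continuous shifts along polar axes): a pipeline's
#' substructure - and hence its phase set - is only defined up to that
#' freedom, so unaligned comparison against an absolute truth would read
#' near zero for a perfectly good solution at another origin.
#'
#' @param phases A `phase_distribution`.
#' @param truth A `truth_record`.
#' @param align_origin Maximize the agreement over allowed origin shifts.
#' @return List with `mean_cos_err`, `fom_weighted_err_deg`, `map_cc`
#'   (and `origin_shift` when aligned).
#' @export
phase_quality_vs_truth <- function(phases, truth, align_origin = FALSE) {
  tab <- phases$table
  key_p <- paste(tab$h, tab$k, tab$l)
  key_t <- paste(truth$hkl$h, truth$hkl$k, truth$hkl$l)
  idx <- match(key_p, key_t)
  phi_t <- truth$phi_p_deg[idx]
  shift <- c(0, 0, 0)
  if (align_origin) {
    sg <- phases$sg
    hklm <- as.matrix(tab[, c("h", "k", "l")])
    ac <- !tab$centric & !is.na(phi_t)
    a0 <- (tab$phi_best - phi_t) * pi / 180
    score_shift <- function(dv) {
      sum(cos(a0[ac] - 2 * pi * drop(hklm[ac, , drop = FALSE] %*% dv)))
    }
    best <- -Inf
    for (r in seq_len(nrow(sg$origin_shifts))) {
      dv <- as.numeric(sg$origin_shifts[r, ])
      # continuous polar components: coordinate ascent on fine 1-D grids
      for (pass in seq_len(if (any(sg$polar)) 2 else 1)) {
        for (ax in which(sg$polar)) {
          grid <- (0:719) / 720
          vals <- vapply(grid, function(g) {
            d2 <- dv; d2[ax] <- g; score_shift(d2)
          }, numeric(1))
          dv[ax] <- grid[which.max(vals)]
        }
      }
      sc <- score_shift(dv)
      if (sc > best) { best <- sc; shift <- dv }
    }
    phi_t <- (phi_t + 360 * drop(as.matrix(tab[, c("h", "k", "l")]) %*%
                                   shift)) %% 360
  }
  ac <- !tab$centric & !is.na(phi_t)
  dphi <- (tab$phi_best - phi_t) * pi / 180
  mean_cos <- mean(cos(dphi[ac]))
  w <- tab$fom[ac]
  err <- phase_diff_deg(tab$phi_best[ac], phi_t[ac])
  fom_err <- if (sum(w) > 0) sum(w * err) / sum(w) else mean(err)
  w1 <- tab$fom * tab$f_bar * exp(1i * tab$phi_best * pi / 180)
  w2 <- tab$f_bar * exp(1i * phi_t * pi / 180)
  use <- !is.na(phi_t)
  cc <- Re(sum(w1[use] * Conj(w2[use]))) /
    sqrt(sum(Mod(w1[use])^2) * sum(Mod(w2[use])^2))
  out <- list(mean_cos_err = mean_cos, fom_weighted_err_deg = fom_err,
              map_cc = cc)
  if (align_origin) out$origin_shift <- shift
  out
}
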