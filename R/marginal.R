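# Exact marginal likelihood of an observed Friedel pair under the shared
# complex-Gaussian channel model:
#
#   Z+ = c+ + U + e+,  Z- = c- + U + e-,   observed r+ = |Z+|, r- = |Z-|
#
# with U complex Gaussian (variance sigma_u, the shared non-substructure
# channel) and e+/- independent complex Gaussian measurement/model errors
# (per-component variances s2p, s2m).  (Z+, Z-) is then a correlated
# complex Gaussian pair; the amplitude marginal integrates one observation
# phase analytically (Bessel I0) and the remaining phase numerically with
# local Laplace refinement of the integrand peaks, so the result stays
# accurate from broad (noise-dominated) to needle-sharp (noise-free)
# likelihood ridges.  This is the objective behind the Luzzati
# error-parameter refinement and the substructure completeness check.

# g(theta) evaluation for the bivariate Rician reduction; theta may be a
# matrix (n x k) of phase values, all other arguments length n.  The
# off-diagonal coefficient b may be complex (anti-correlated anomalous
# residuals make the Friedel-pair covariance complex).
bivar_rician_g <- function(theta, rp, rm, cp, cm, a, cc, b) {
  v <- rm * exp(1i * theta) - cm
  -a * rp^2 - a * Mod(cp)^2 - cc * Mod(v)^2 + 2 * Re(b * Conj(cp) * v) +
    log_i0(2 * rp * Mod(a * cp - b * v))
}

#' Log marginal likelihood of Friedel-pair amplitudes (bivariate Rician)
#'
#' @param rp,rm Observed amplitudes.
#' @param cp,cm Complex model centers (scaled heavy structure factors).
#' @param c11,c22 Total complex variances of the two observations.
#' @param c12 Complex cross-covariance between `Z+` and `conj(Z-)`.
#' @param n_theta Coarse quadrature size for the remaining phase.
#' @return Log marginal density per reflection (up to a common additive
#'   constant in the observations).
#' @keywords internal
bivar_rician_logmarg <- function(rp, rm, cp, cm, c11, c22, c12,
                                 n_theta = 64) {
  n <- length(rp)
  det_c <- c11 * c22 - Mod(c12)^2
  a <- c22 / det_c; cc <- c11 / det_c; b <- -c12 / det_c
  dth <- 2 * pi / n_theta
  th <- (seq_len(n_theta) - 1) * dth
  G <- bivar_rician_g(matrix(th, n, n_theta, byrow = TRUE),
                      rp, rm, cp, cm, a, cc, b)
  # top-2 circular local maxima per row
  left <- G[, c(n_theta, seq_len(n_theta - 1)), drop = FALSE]
  right <- G[, c(seq_len(n_theta - 1) + 1, 1), drop = FALSE]
  ismax <- G >= left & G >= right
  Gm <- G; Gm[!ismax] <- -Inf
  j1 <- max.col(Gm, ties.method = "first")
  for (off in -1:1) Gm[cbind(seq_len(n), (j1 - 1 + off) %% n_theta + 1)] <- -Inf
  j2 <- max.col(Gm, ties.method = "first")
  has2 <- is.finite(Gm[cbind(seq_len(n), j2)])
  refine <- function(jidx, active) {
    th0 <- (jidx - 1) * dth
    delta <- rep(dth, n)
    f0 <- bivar_rician_g(matrix(th0, ncol = 1), rp, rm, cp, cm, a, cc, b)[, 1]
    for (it in 1:5) {
      fm <- bivar_rician_g(matrix(th0 - delta, ncol = 1),
                           rp, rm, cp, cm, a, cc, b)[, 1]
      fp <- bivar_rician_g(matrix(th0 + delta, ncol = 1),
                           rp, rm, cp, cm, a, cc, b)[, 1]
      den <- fm - 2 * f0 + fp
      shift <- ifelse(is.finite(den) & den < 0,
                      0.5 * delta * (fm - fp) / den, 0)
      shift <- pmax(pmin(shift, delta), -delta)
      take_m <- fm > f0 & fm > fp & !(den < 0)
      take_p <- fp > f0 & fp >= fm & !(den < 0)
      shift[take_m] <- -delta[take_m]
      shift[take_p] <- delta[take_p]
      th0 <- th0 + shift
      f0 <- bivar_rician_g(matrix(th0, ncol = 1), rp, rm, cp, cm,
                           a, cc, b)[, 1]
      delta <- delta / 3
    }
    dlt <- pmax(delta * 3, 1e-9)
    fm <- bivar_rician_g(matrix(th0 - dlt, ncol = 1), rp, rm, cp, cm,
                         a, cc, b)[, 1]
    fp <- bivar_rician_g(matrix(th0 + dlt, ncol = 1), rp, rm, cp, cm,
                         a, cc, b)[, 1]
    curv <- pmax(-(fm - 2 * f0 + fp) / dlt^2, 1e-12)
    logw <- pmin(0.5 * log(2 * pi / curv), log(3 * dth))
    list(logz = ifelse(active, f0 + logw, -Inf))
  }
  p1 <- refine(j1, rep(TRUE, n))
  p2 <- refine(j2, has2)
  # far-field trapezoid: drop the cells adjacent to each refined peak
  far <- G
  for (off in -1:1) {
    far[cbind(seq_len(n), (j1 - 1 + off) %% n_theta + 1)] <- -Inf
    idx2 <- cbind(seq_len(n), (j2 - 1 + off) %% n_theta + 1)
    far[idx2[has2, , drop = FALSE]] <- -Inf
  }
  parts <- cbind(far + log(dth), p1$logz, p2$logz)
  logint <- row_logsumexp(parts)
  log(2 * rp * rm) - log(pi * det_c) + logint
}

#' Log marginal likelihood of a centric amplitude
#'
#' Centric model: `r = | c + x exp(i phi0) | + noise` with `x` real Gaussian
#' (variance sigma_u).  Integrated by Laplace expansion about the analytic
#' roots of the amplitude equation, with a numeric fallback node set.
#' @keywords internal
centric_logmarg <- function(r, cvec, s2, sigma_u, phi0_deg) {
  n <- length(r)
  e0 <- exp(-1i * phi0_deg * pi / 180)
  c_par <- Re(cvec * e0)
  c_perp <- Im(cvec * e0)
  su <- sqrt(sigma_u)
  s2 <- rep(s2, length.out = n)
  out <- numeric(n)
  base <- seq(-4.5, 4.5, length.out = 61)
  loc <- seq(-5, 5, length.out = 41)
  for (i in seq_len(n)) {
    sui <- su
    nodes <- base * sui
    disc <- r[i]^2 - c_perp[i]^2
    if (disc > 0) {
      for (sgn in c(-1, 1)) {
        root <- -c_par[i] + sgn * sqrt(disc)
        slope <- max(abs(root + c_par[i]) / r[i], 0.05)
        width <- min(sqrt(s2[i]) / slope, sui)
        nodes <- c(nodes, root + loc * width)
      }
    } else {
      # below the tangency amplitude: expand around the closest approach
      width <- min(sqrt(sqrt(s2[i]) * max(r[i], 1e-6)), sui)
      nodes <- c(nodes, -c_par[i] + loc * width)
    }
    nodes <- sort(unique(nodes))
    mu <- sqrt((nodes + c_par[i])^2 + c_perp[i]^2)
    hv <- log_rice(r[i], mu, s2[i]) - nodes^2 / (2 * sigma_u) -
      0.5 * log(2 * pi * sigma_u)
    m <- max(hv)
    w <- diff(nodes)
    f <- exp(hv - m)
    out[i] <- m + log(sum(0.5 * (f[-1] + f[-length(f)]) * w))
  }
  out
}

# Per-reflection exact log marginal for a dataset given substructure and a
# per-shell (beta, var_extra) parameterization; shared by the error-model
# refinement and the site refinement objective.
sad_marginal_loglik <- function(data, sub, dvec, ve, pars,
                                h_plus = NULL, h_minus = NULL,
                                v_res = NULL) {
  obs <- data$obs
  n <- nrow(obs)
  shell <- pars$shell_index
  n_shells <- nrow(pars$shells)
  if (is.null(h_plus)) {
    fh <- structure_factors(sub, data$cell, data$sg,
                            as.matrix(obs[, c("h", "k", "l")]))
    h_plus <- fh$f_plus
    h_minus <- Conj(fh$f_minus)
  }
  out <- numeric(n)
  for (s in seq_len(n_shells)) {
    sp <- pars$shells[s, ]
    beta <- dvec[s] * sp$s_h
    resid <- if (is.null(v_res)) {
      max(sp$sigma_g - beta^2 * sp$sigma_gmod, 0)
    } else v_res[s]
    sigma_p <- max(sp$sigma_t - (1 + sp$kappa^2) * sp$sigma_g,
                   0.05 * sp$sigma_t)
    sigma_u <- sigma_p + resid
    floor2 <- (1e-4 * sqrt(sp$sigma_t))^2
    i <- which(shell == s & !obs$centric)
    if (length(i)) {
      s2p <- pmax(obs$sig_plus[i]^2 + ve, floor2)
      s2m <- pmax(obs$sig_minus[i]^2 + ve, floor2)
      kap2 <- sp$kappa^2
      out[i] <- bivar_rician_logmarg(
        obs$f_plus[i], obs$f_minus[i],
        beta * h_plus[i], beta * h_minus[i],
        c11 = sigma_p + resid * (1 + kap2) + 2 * s2p,
        c22 = sigma_p + resid * (1 + kap2) + 2 * s2m,
        c12 = complex(real = sigma_p + resid * (1 - kap2),
                      imaginary = 2 * sp$kappa * resid)
      )
    }
    ic <- which(shell == s & obs$centric)
    if (length(ic)) {
      out[ic] <- centric_logmarg(
        obs$f_plus[ic], beta * h_plus[ic],
        pmax(obs$sig_plus[ic]^2 + ve + 0.5 * sp$kappa^2 * resid, floor2),
        sigma_u, obs$phi0_deg[ic]
      )
    }
  }
  out
}
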