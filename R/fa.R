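# Heavy-atom amplitude (|FA|) estimation and anomalous/isomorphous signal
# statistics, including the choice of the best signal channel.

fa_normalize <- function(fa, shell) {
  e <- numeric(length(fa))
  for (s in unique(shell)) {
    i <- shell == s
    ms <- mean(fa[i]^2)
    e[i] <- if (ms > 0) fa[i] / sqrt(ms) else 0
  }
  e
}

new_fa_estimate <- function(obs, fa, sig_fa, shell, method, excluded) {
  out <- data.frame(
    h = obs$h, k = obs$k, l = obs$l, d = obs$d, centric = obs$centric,
    fa = fa, sig_fa = sig_fa, shell = shell, excluded = excluded
  )
  out$e_norm <- 0
  use <- !excluded
  out$e_norm[use] <- fa_normalize(fa[use], shell[use])
  structure(list(table = out, method = method), class = "fa_estimate")
}

#' @export
print.fa_estimate <- function(x, ...) {
  cat(sprintf("|FA| estimate (%s): %d reflections (%d excluded)\n",
              x$method, nrow(x$table), sum(x$table$excluded)))
  invisible(x)
}

#' Simple |FA| estimate from absolute Bijvoet differences
#'
#' The baseline used by most detection programs: `|FA| ~ |dF|` per acentric
#' reflection; centric reflections carry no Bijvoet difference and are
#' excluded (flagged, not dropped).
#'
#' @param data A [reflection_set] with anomalous data.
#' @param n_shells Shells for quasi-normalization.
#' @return An object of class `fa_estimate` with per-reflection `fa`,
#'   `sig_fa` and quasi-normalized `e_norm` (unit mean square per shell).
#' @export
estimate_fa_simple <- function(data, n_shells = 10) {
  stopifnot(inherits(data, "reflection_set"))
  obs <- data$obs
  if (!any(!obs$centric)) stop("no acentric reflections: no anomalous signal")
  fa <- abs(obs$f_plus - obs$f_minus)
  fa[obs$centric] <- 0
  sig <- sqrt(obs$sig_plus^2 + obs$sig_minus^2)
  shell <- assign_shells(data, n_shells)
  new_fa_estimate(obs, fa, sig, shell, "simple", excluded = obs$centric)
}

# Per-shell second moments used by the multivariate model.
fa_shell_params <- function(data, shell, kappa, heavy_fraction,
                            refine_heavy_fraction) {
  obs <- data$obs
  ns <- max(shell)
  out <- data.frame(shell = seq_len(ns), sigma_t = NA_real_, q = heavy_fraction)
  for (s in seq_len(ns)) {
    i <- shell == s & !obs$centric
    fbar <- (obs$f_plus[i] + obs$f_minus[i]) / 2
    out$sigma_t[s] <- mean(fbar^2)
    if (refine_heavy_fraction) {
      df2 <- mean((obs$f_plus[i] - obs$f_minus[i])^2)
      sig2 <- mean(obs$sig_plus[i]^2 + obs$sig_minus[i]^2)
      q <- (df2 - sig2) / (2 * kappa^2) / out$sigma_t[s]
      out$q[s] <- min(max(q, 1e-3), 0.8)
    }
  }
  out
}

#' Multivariate |FA| estimate from joint Friedel-pair likelihoods
#'
#' Posterior expectation `E[|FA| | |F+|, |F-|, sigma+, sigma-]` under a
#' joint model of the Friedel pair: the normal heavy-atom structure factor
#' is complex Gaussian with shell variance `heavy_fraction * Sigma`, the
#' protein component is complex Gaussian and shared between the mates, the
#' anomalous component is `+/- i kappa` times the normal heavy component,
#' and measurement noise is complex Gaussian per mate (Rice-distributed
#' amplitudes).  One observation phase is integrated analytically (a Bessel
#' I0 term); the remaining relative phase uses one 64-point angular
#' quadrature and the heavy amplitude a Rayleigh-quantile quadrature.
#'
#' @param data A [reflection_set].
#' @param error_model Optional [error_model]; its `var_extra` per shell is
#'   added to the measurement variances.
#' @param heavy_fraction Prior ratio of heavy to total intensity per shell,
#'   in (0, 1).
#' @param kappa Ratio f''/(f0 + f') of the anomalous scatterers (dimensionless).
#' @param refine_heavy_fraction Re-estimate the heavy fraction per shell by
#'   matching the observed mean squared Bijvoet difference.
#' @param n_shells,n_phi,n_amp Quadrature sizes.
#' @return An `fa_estimate` (method `"multivariate"`).
#' @export
estimate_fa_multivariate <- function(data, error_model = NULL,
                                     heavy_fraction = 0.05, kappa = 0.25,
                                     refine_heavy_fraction = TRUE,
                                     n_shells = 10, n_phi = 64, n_amp = 24) {
  stopifnot(inherits(data, "reflection_set"))
  if (heavy_fraction <= 0 || heavy_fraction >= 1) {
    stop("heavy_fraction must be in (0, 1)")
  }
  obs <- data$obs
  if (any(obs$sig_plus <= 0) || any(obs$sig_minus <= 0)) {
    stop("non-positive measurement variances")
  }
  shell <- assign_shells(data, n_shells)
  pars <- fa_shell_params(data, shell, kappa, heavy_fraction,
                          refine_heavy_fraction)
  ve <- rep(0, n_shells)
  if (!is.null(error_model)) ve <- error_model$shells$var_extra
  acent <- which(!obs$centric)
  fa <- rep(0, nrow(obs)); sig_fa <- rep(0, nrow(obs))
  theta <- 2 * pi * (seq_len(n_phi) - 0.5) / n_phi
  eith <- exp(1i * theta)
  for (s in seq_len(n_shells)) {
    idx <- acent[shell[acent] == s]
    if (!length(idx)) next
    sigma_t <- pars$sigma_t[s]; q <- pars$q[s]
    sigma_h <- q * sigma_t
    sigma_p <- max(sigma_t - (1 + kappa^2) * sigma_h, 0.05 * sigma_t)
    rp <- obs$f_plus[idx]; rm_ <- obs$f_minus[idx]
    s2p <- obs$sig_plus[idx]^2 + ve[s]; s2m <- obs$sig_minus[idx]^2 + ve[s]
    c11 <- sigma_p + 2 * s2p; c22 <- sigma_p + 2 * s2m
    det_c <- c11 * c22 - sigma_p^2
    a <- c22 / det_c; cc <- c11 / det_c; b <- -sigma_p / det_c
    amp <- rayleigh_nodes(sigma_h, n_amp)
    nloc <- length(idx)
    logm <- matrix(NA_real_, nloc, n_amp)
    zb <- outer(rm_, eith)                      # z- over the phase grid
    for (k in seq_len(n_amp)) {
      A <- amp[k]
      mu_p <- complex(real = A, imaginary = kappa * A)
      mu_m <- complex(real = A, imaginary = -kappa * A)
      vb <- zb - mu_m                           # z- minus its mean
      # exact theta+ integral: |w| = |a mu+ - b v-|
      w <- Mod(a * mu_p - b * vb)
      lw <- -(a * rp^2 + a * Mod(mu_p)^2) -
        cc * Mod(vb)^2 + 2 * b * Re(Conj(mu_p) * vb) +
        log_i0(2 * rp * w)
      logm[, k] <- row_logsumexp(lw)
    }
    mx <- do.call(pmax, lapply(seq_len(n_amp), function(j) logm[, j]))
    wgt <- exp(logm - mx)
    z0 <- rowSums(wgt)
    m1 <- as.vector(wgt %*% amp) / z0
    m2 <- as.vector(wgt %*% amp^2) / z0
    fa[idx] <- m1
    sig_fa[idx] <- sqrt(pmax(m2 - m1^2, 0))
  }
  new_fa_estimate(obs, fa, sig_fa, shell, "multivariate",
                  excluded = obs$centric)
}

#' Brute-force quadrature oracle for the multivariate |FA| model
#'
#' Direct 3-D Riemann sum over the heavy amplitude and the two observation
#' phases of the same generative model as [estimate_fa_multivariate] -
#' no analytic reduction.  Used to validate the production estimator.
#'
#' @param rp,rm Observed |F+|, |F-|.
#' @param s2p,s2m Measurement variances (sigma^2).
#' @param sigma_p,sigma_h Shell variances of the protein and normal heavy
#'   channels.
#' @param kappa Anomalous ratio.
#' @param n Grid size per dimension.
#' @return Posterior mean of the heavy amplitude.
#' @export
fa_posterior_bruteforce <- function(rp, rm, s2p, s2m, sigma_p, sigma_h,
                                    kappa, n = 200) {
  theta <- 2 * pi * (seq_len(n) - 0.5) / n
  zp <- rp * exp(1i * theta)
  zm <- rm * exp(1i * theta)
  c11 <- sigma_p + 2 * s2p; c22 <- sigma_p + 2 * s2m
  det_c <- c11 * c22 - sigma_p^2
  a <- c22 / det_c; cc <- c11 / det_c; b <- -sigma_p / det_c
  amp <- rayleigh_nodes(sigma_h, n)
  num <- 0; den <- 0
  for (A in amp) {
    mu_p <- complex(real = A, imaginary = kappa * A)
    mu_m <- complex(real = A, imaginary = -kappa * A)
    vp <- zp - mu_p
    vm <- zm - mu_m
    q <- outer(a * Mod(vp)^2, cc * Mod(vm)^2, "+") +
      2 * b * Re(outer(vp, Conj(vm)))
    w <- sum(exp(-q))
    num <- num + A * w
    den <- den + w
  }
  num / den
}

#' Isomorphous |FA| estimate from native and derivative sets
#'
#' Friedel-averaged amplitudes are compared after per-shell least-squares
#' scaling of the native to the derivative: `fa = |<F_deriv> - k <F_nat>|`.
#' Centric reflections are retained (isomorphous differences exist there).
#'
#' @param deriv,native [reflection_set]s sharing indices.
#' @param n_shells Shells for scaling and normalization.
#' @return An `fa_estimate` (method `"isomorphous"`) on the common set, with
#'   the per-shell scale factors in `$scale`.
#' @export
estimate_fa_isomorphous <- function(deriv, native, n_shells = 10) {
  stopifnot(inherits(deriv, "reflection_set"),
            inherits(native, "reflection_set"))
  kd <- paste(deriv$obs$h, deriv$obs$k, deriv$obs$l)
  kn <- paste(native$obs$h, native$obs$k, native$obs$l)
  common <- intersect(kd, kn)
  if (length(common) < 50) {
    stop("fewer than 50 common reflections between native and derivative")
  }
  od <- deriv$obs[match(common, kd), ]
  on_ <- native$obs[match(common, kn), ]
  fd <- (od$f_plus + od$f_minus) / 2
  fn <- (on_$f_plus + on_$f_minus) / 2
  shell <- assign_shells(od, n_shells)
  scale <- numeric(n_shells)
  fa <- numeric(length(fd))
  for (s in seq_len(n_shells)) {
    i <- shell == s
    # least squares on <F^2>: k minimizing sum (fd - k fn)^2
    scale[s] <- sum(fd[i] * fn[i]) / sum(fn[i]^2)
    fa[i] <- abs(fd[i] - scale[s] * fn[i])
  }
  sig <- sqrt(od$sig_plus^2 / 2 + on_$sig_plus^2 / 2)
  est <- new_fa_estimate(od, fa, sig, shell, "isomorphous",
                         excluded = rep(FALSE, length(fa)))
  est$scale <- data.frame(shell = seq_len(n_shells), k = scale)
  est
}

anomalous_signal_score <- function(data, n_shells = 10) {
  obs <- data$obs
  shell <- assign_shells(data, n_shells)
  acent <- !obs$centric
  if (!any(acent)) return(0)
  per <- vapply(seq_len(n_shells), function(s) {
    i <- shell == s & acent
    if (!any(i)) return(NA_real_)
    df <- obs$f_plus[i] - obs$f_minus[i]
    sg2 <- obs$sig_plus[i]^2 + obs$sig_minus[i]^2
    mean(df^2 / sg2) - 1
  }, numeric(1))
  mean(per, na.rm = TRUE)
}

isomorphous_signal_score <- function(deriv, native, n_shells = 10) {
  est <- estimate_fa_isomorphous(deriv, native, n_shells)
  tab <- est$table
  per <- vapply(split(seq_len(nrow(tab)), tab$shell), function(i) {
    mean(tab$fa[i]^2 / tab$sig_fa[i]^2) - 1
  }, numeric(1))
  mean(per, na.rm = TRUE)
}

#' Choose the signal channel with the greatest expected information
#'
#' Scores each candidate by the mean over resolution shells of
#' `<(dF/sigma_dF)^2> - 1` (anomalous candidates) or its isomorphous
#' analogue, and returns the label of the maximum.  Ties break
#' deterministically in favour of the earlier label.  The score is
#' invariant to a global rescaling of amplitudes and sigmas.
#'
#' @param candidates Named list: each element either a [reflection_set]
#'   (anomalous channel) or a list `list(deriv = , native = )` (isomorphous
#'   channel).
#' @param n_shells Shells for the score.
#' @return The winning label (character).
#' @export
select_best_channel <- function(candidates, n_shells = 10) {
  if (length(candidates) == 0) stop("empty candidate list")
  labels <- names(candidates) %||% as.character(seq_along(candidates))
  scores <- vapply(candidates, function(cand) {
    if (inherits(cand, "reflection_set")) {
      anomalous_signal_score(cand, n_shells)
    } else {
      isomorphous_signal_score(cand$deriv, cand$native, n_shells)
    }
  }, numeric(1))
  labels[which.max(scores)]
}

#' Bijvoet ratio and anomalous signal-to-noise per resolution shell
#'
#' The per-shell table behind the classic signal plot: Bijvoet ratio
#' `<|dF|>/<|F|>` and `<|dF|/sigma_dF>` per equal-population shell, with an
#' overall row appended.
#'
#' @param data A [reflection_set].
#' @param n_shells Number of shells.
#' @return Data frame with columns `shell, d_max, d_min, n, bijvoet_ratio,
#'   mean_df_over_sig`; the final row (`shell = NA`) is the overall set.
#' @export
anomalous_signal_by_shell <- function(data, n_shells = 10) {
  stopifnot(n_shells >= 1)
  bs <- compute_bijvoet_stats(data, n_shells)
  pr <- bs$per_reflection
  tab <- bs$per_shell
  tab$mean_df_over_sig <- vapply(tab$shell, function(s) {
    i <- pr$shell == s
    mean(abs(pr$delta_f[i]) / pr$sig_delta_f[i])
  }, numeric(1))
  overall <- data.frame(
    shell = NA_integer_, n = nrow(pr),
    d_max = max(pr$d), d_min = min(pr$d),
    bijvoet_ratio = bs$overall_bijvoet_ratio,
    mean_df_over_sig = mean(abs(pr$delta_f) / pr$sig_delta_f)
  )
  rbind(tab, overall)
}
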