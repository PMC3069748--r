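test_that("fast log-I0 matches stats::besselI", {
  x <- c(0, 10^seq(-4, 3, length.out = 200))
  ref <- log(besselI(pmin(x, 700), 0, expon.scaled = TRUE)) + pmin(x, 700)
  expect_lt(max(abs(phasekit:::log_i0(pmin(x, 700)) - ref)), 1e-6)
})

test_that("phase posteriors are normalized with foms in range", {
  fx <- mini_sad()
  ph <- mini_phases()
  expect_true(all(ph$table$fom >= 0 & ph$table$fom <= 1))
  # the single-reflection interface integrates to one
  em <- mini_em()
  obs <- fx$data$obs
  hkl <- as.matrix(obs[, c("h", "k", "l")])
  fh <- structure_factors(fx$sub_true, fx$data$cell, fx$data$sg, hkl)
  for (i in c(10, 500, which(obs$centric)[3])) {
    pp <- phase_posterior_sad(obs[i, ], fh$f_plus[i], fh$f_minus[i], em)
    expect_equal(sum(pp$posterior), 1, tolerance = 1e-6)
    expect_true(pp$hl$fom >= 0 && pp$hl$fom <= 1)
  }
  # a zero heavy vector gives a flat, flagged posterior
  pp0 <- phase_posterior_sad(obs[10, ], 0 + 0i, 0 + 0i, em)
  expect_true(pp0$uninformative)
  expect_lt(max(abs(pp0$posterior - 1 / 72)), 1e-12)
  expect_error(phase_posterior_sad(obs[10, ], fh$f_plus[10],
                                   fh$f_minus[10], em, n_phi = 36), "72")
})

test_that("without f'' the posterior keeps the SIR-like phase ambiguity", {
  # substructure modelled with f'' = 0: P(phi) must be symmetric about the
  # heavy-atom phase, so the centroid lies along it (no sine component in
  # the heavy-phase-aligned frame)
  fx <- mini_sad()
  em <- mini_em()
  sub0 <- fx$sub_true
  sub0$sites$f_dprime <- 0
  ph0 <- phase_substructure_sad(fx$data, sub0, em)
  hkl <- as.matrix(fx$data$obs[, c("h", "k", "l")])
  fh <- structure_factors(sub0, fx$data$cell, fx$data$sg, hkl)
  phi_h <- Arg(fh$f_plus) * 180 / pi
  ac <- !fx$data$obs$centric & Mod(fh$f_plus) > 1
  # rotate HL vector into the heavy-phase frame: sine component ~ 0
  a_rot <- ph0$table$hl_a * cos(phi_h * pi / 180) +
    ph0$table$hl_b * sin(phi_h * pi / 180)
  b_rot <- -ph0$table$hl_a * sin(phi_h * pi / 180) +
    ph0$table$hl_b * cos(phi_h * pi / 180)
  expect_lt(stats::median(abs(b_rot[ac])), 0.05)
  expect_gt(stats::median(abs(a_rot[ac])), stats::median(abs(b_rot[ac])))
})

test_that("HL coefficients reproduce grid posteriors", {
  # flat posterior -> all zero coefficients
  flat <- hl_and_fom(rep(1 / 72, 72), phasekit:::phi_grid_deg(72))
  expect_equal(unlist(flat[c("hl_a", "hl_b", "hl_c", "hl_d", "fom")]),
               c(hl_a = 0, hl_b = 0, hl_c = 0, hl_d = 0, fom = 0))
  # pure A = 2 posterior: fom equals the Bessel ratio I1(2)/I0(2) from an
  # independent quadrature oracle
  phi <- phasekit:::phi_grid_deg(72) * pi / 180
  p <- exp(2 * cos(phi)); p <- p / sum(p)
  out <- hl_and_fom(p, phasekit:::phi_grid_deg(72))
  th <- seq(0, 2 * pi, length.out = 20001)[-20001]
  oracle <- abs(sum(exp(1i * th) * exp(2 * cos(th))) /
                  sum(exp(2 * cos(th))))
  expect_equal(out$fom, oracle, tolerance = 2e-3)
  expect_equal(out$hl_a, 2, tolerance = 0.05)
  expect_lt(abs(out$hl_b), 0.02)
  # property: HL-reconstructed fom within 0.02 of the grid fom over many
  # random HL draws
  set.seed(31)
  n <- 400
  hl <- cbind(stats::rnorm(n, 0, 2), stats::rnorm(n, 0, 2),
              stats::rnorm(n, 0, 0.7), stats::rnorm(n, 0, 0.7))
  X <- rbind(cos(phi), sin(phi), cos(2 * phi), sin(2 * phi))
  lq <- hl %*% X
  q <- exp(lq - phasekit:::row_logsumexp(lq))
  fit <- hl_and_fom(q, phasekit:::phi_grid_deg(72))
  fom_grid <- Mod(as.vector(q %*% exp(1i * phi)))
  lq2 <- as.matrix(fit[, c("hl_a", "hl_b", "hl_c", "hl_d")]) %*% X
  q2 <- exp(lq2 - phasekit:::row_logsumexp(lq2))
  fom_back <- Mod(as.vector(q2 %*% exp(1i * phi)))
  expect_lt(max(abs(fom_back - fom_grid)), 0.02)
})

test_that("real posteriors keep HL and grid foms consistent", {
  ph <- mini_phases()
  tab <- ph$table[!ph$table$centric, ]
  phi <- phasekit:::phi_grid_deg(72) * pi / 180
  X <- rbind(cos(phi), sin(phi), cos(2 * phi), sin(2 * phi))
  lq <- as.matrix(tab[, c("hl_a", "hl_b", "hl_c", "hl_d")]) %*% X
  q <- exp(lq - phasekit:::row_logsumexp(lq))
  fom_hl <- Mod(as.vector(q %*% exp(1i * phi)))
  expect_lt(stats::quantile(abs(fom_hl - tab$fom), 0.99), 0.02)
})

test_that("centric phasing restricts to the allowed phase pair", {
  fx <- mini_sad()
  ph <- mini_phases()
  cen <- ph$table[ph$table$centric, ]
  diff_to_axis <- pmin(
    phasekit:::phase_diff_deg(cen$phi_best, cen$phi0_deg),
    phasekit:::phase_diff_deg(cen$phi_best, cen$phi0_deg + 180)
  )
  expect_lt(max(diff_to_axis), 1e-6)
  expect_true(all(cen$hl_c == 0 & cen$hl_d == 0))
})

test_that("joint-Friedel phasing recovers phases and beats merged dF", {
  fx <- mini_sad()
  em <- mini_em()
  ph <- mini_phases()
  q <- phase_quality_vs_truth(ph, fx$truth)
  expect_gt(q$mean_cos_err, 0.4)
  expect_lt(q$fom_weighted_err_deg, 60)
  phg <- phase_substructure_sad(fx$data, fx$sub_true, em,
                                mode = "gaussian_df")
  qg <- phase_quality_vs_truth(phg, fx$truth)
  expect_gt(q$mean_cos_err, qg$mean_cos_err)
  # strong signal: most acentric phases near truth
  phi_t <- true_phi(ph, fx$truth)
  ac <- !ph$table$centric
  frac25 <- mean(phasekit:::phase_diff_deg(ph$table$phi_best[ac],
                                           phi_t[ac]) < 25)
  expect_gt(frac25, 0.35)
})

test_that("error refinement responds to noise, completeness and wrongness", {
  # monotone non-increasing avg Luzzati D with added noise, same seed
  d_at <- vapply(c(0, 0.05, 0.12), function(nf) {
    fx <- mini_sad(seed = 13, noise_frac = nf)
    refine_error_model(fx$data, fx$sub_true)$avg_luzzati
  }, numeric(1))
  expect_gte(d_at[1], 0.95)
  expect_true(all(diff(d_at) <= 0.02))
  # half substructure scores strictly lower than the full one
  fx <- mini_sad(seed = 13)
  full <- refine_error_model(fx$data, fx$sub_true)$avg_luzzati
  halves <- vapply(1:2, function(k) {
    refine_error_model(fx$data,
                       substructure(fx$sub_true$sites[k, , drop = FALSE])
    )$avg_luzzati
  }, numeric(1))
  expect_true(all(halves < full))
  # random wrong substructure scores low
  set.seed(40)
  rnd <- substructure(sites(c("SE", "SE"), stats::runif(2), stats::runif(2),
                            stats::runif(2), f_prime = -8, f_dprime = 4))
  expect_lt(refine_error_model(fx$data, rnd)$avg_luzzati, 0.4)
})

test_that("the completeness check applies the Luzzati threshold", {
  fx <- mini_sad(seed = 13)
  chk <- check_substructure_complete(fx$data, fx$sub_true)
  expect_identical(chk$status, "complete")
  expect_gt(chk$avg_luzzati, 0.7)
  # an unattainable threshold always reads incomplete
  chk2 <- check_substructure_complete(fx$data, fx$sub_true, threshold = 1.1)
  expect_identical(chk2$status, "incomplete")
})

test_that("site refinement recovers perturbed coordinates and occupancies", {
  fx0 <- mini_sad(seed = 3, noise_frac = 0)
  em <- refine_error_model(fx0$data, fx0$sub_true)
  set.seed(11)
  pert <- fx0$sub_true
  pert$sites$x <- pert$sites$x + stats::rnorm(2, 0, 0.3 / 26 / 1.7)
  pert$sites$y <- pert$sites$y + stats::rnorm(2, 0, 0.3 / 30 / 1.7)
  pert$sites$z <- pert$sites$z + stats::rnorm(2, 0, 0.3 / 28 / 1.7)
  pert$sites$occ <- c(0.5, 1)
  ref <- refine_sites(fx0$data, pert, em, max_reflections = 1500, maxit = 24)
  m <- match_sites(ref, fx0$sub_true, fx0$data$cell, fx0$data$sg, tol = 0.5)
  expect_equal(m$n_matched, 2)
  expect_lt(max(m$mapping$dist), 0.05)
  # SAD amplitudes determine site strengths only relative to each other
  # (the absolute scale is degenerate with the heavy-channel calibration,
  # and occupancy trades against B along a shallow valley): the halved
  # input occupancy must recover to parity with the other site
  s2bar <- mean(1 / fx0$data$obs$d^2)
  pow <- ref$sites$occ * exp(-ref$sites$b * s2bar / 4)
  pow_true <- fx0$sub_true$sites$occ * exp(-fx0$sub_true$sites$b * s2bar / 4)
  expect_lt(abs((pow[1] / pow[2]) / (pow_true[1] / pow_true[2]) - 1), 0.15)
  # likelihood non-degradation contract: refining an already-refined model
  # does not move it far
  ref2 <- refine_sites(fx0$data, ref, em, max_reflections = 1500, maxit = 8)
  m2 <- match_sites(ref2, fx0$sub_true, fx0$data$cell, fx0$data$sg,
                    tol = 0.5)
  expect_lt(max(m2$mapping$dist), 0.05)
})

test_that("uncorrelated SIRAS phasing adds information over SAD alone", {
  fx <- mini_siras()
  em <- refine_error_model(fx$deriv, fx$sub_true)
  ph_sad <- phase_substructure_sad(fx$deriv, fx$sub_true, em)
  ph_sir <- phase_substructure_siras(fx$deriv, fx$native, fx$sub_true, em)
  expect_gte(mean(ph_sir$table$fom), mean(ph_sad$table$fom))
  q_sad <- phase_quality_vs_truth(ph_sad, fx$truth)
  q_sir <- phase_quality_vs_truth(ph_sir, fx$truth)
  expect_gte(q_sir$mean_cos_err, q_sad$mean_cos_err)
  expect_true(all(ph_sir$table$fom >= 0 & ph_sir$table$fom <= 1))
  expect_true(all(ph_sir$table$native_used))
  # reflections without a native mate fall back to SAD and are flagged
  nat_cut <- fx$native
  nat_cut$obs <- nat_cut$obs[-(1:10), ]
  ph_cut <- phase_substructure_siras(fx$deriv, nat_cut, fx$sub_true, em)
  expect_equal(sum(!ph_cut$table$native_used), 10)
  # single-reflection interface: normalized, flagged, sharper than SAD
  hkl <- as.matrix(fx$deriv$obs[, c("h", "k", "l")])
  fh <- structure_factors(fx$sub_true, fx$deriv$cell, fx$deriv$sg, hkl)
  i <- which(!fx$deriv$obs$centric)[25]
  ni <- match(paste(fx$deriv$obs$h[i], fx$deriv$obs$k[i], fx$deriv$obs$l[i]),
              paste(fx$native$obs$h, fx$native$obs$k, fx$native$obs$l))
  pp <- phase_posterior_siras_uncorrelated(fx$native$obs[ni, ],
                                           fx$deriv$obs[i, ],
                                           fh$f_plus[i], fh$f_minus[i], em)
  expect_true(pp$native_used)
  expect_equal(sum(pp$posterior), 1, tolerance = 1e-6)
  pp0 <- phase_posterior_siras_uncorrelated(NULL, fx$deriv$obs[i, ],
                                            fh$f_plus[i], fh$f_minus[i], em)
  expect_false(pp0$native_used)
  ps <- phase_posterior_sad(fx$deriv$obs[i, ], fh$f_plus[i],
                            fh$f_minus[i], em)
  expect_equal(sum(pp0$posterior * ps$posterior > 0), 72)
})

test_that("phase quality metrics behave at their limits", {
  fx <- mini_sad()
  ph <- mini_phases()
  # phases equal to truth: perfect scores
  ideal <- ph
  ideal$table$phi_best <- true_phi(ph, fx$truth)
  ideal$table$fom <- 1
  q <- phase_quality_vs_truth(ideal, fx$truth)
  expect_equal(q$mean_cos_err, 1, tolerance = 1e-9)
  expect_equal(q$fom_weighted_err_deg, 0, tolerance = 1e-9)
  expect_equal(q$map_cc, 1, tolerance = 1e-9)
  # random phases: null result ~ 0 within a few / sqrt(N)
  set.seed(8)
  rnd <- ph
  rnd$table$phi_best <- stats::runif(nrow(ph$table), 0, 360)
  qr <- phase_quality_vs_truth(rnd, fx$truth)
  expect_lt(abs(qr$mean_cos_err), 4 / sqrt(sum(!ph$table$centric)))
})

test_that("phasing with the inverted substructure mirrors the phase set", {
  fx <- mini_sad()
  em <- mini_em()
  ph_o <- mini_phases()
  ph_i <- phase_substructure_sad(fx$data, invert_hand(fx$sub_true,
                                                      fx$data$sg), em)
  # hand symmetry of the amplitudes: equal figure-of-merit spectra
  expect_equal(mean(ph_i$table$fom), mean(ph_o$table$fom), tolerance = 0.02)
  expect_equal(stats::quantile(ph_i$table$fom, c(0.25, 0.5, 0.75)),
               stats::quantile(ph_o$table$fom, c(0.25, 0.5, 0.75)),
               tolerance = 0.05)
  # the exact mirror identity holds in the phase-ambiguous f'' = 0 limit,
  # where the posterior is symmetric about the heavy phase: inverting the
  # substructure negates the heavy phase and hence the centroid
  sub0 <- fx$sub_true
  sub0$sites$f_dprime <- 0
  ph0_o <- phase_substructure_sad(fx$data, sub0, em)
  ph0_i <- phase_substructure_sad(fx$data, invert_hand(sub0, fx$data$sg),
                                  em)
  hkl <- as.matrix(fx$data$obs[, c("h", "k", "l")])
  strong <- Mod(structure_factors(sub0, fx$data$cell, fx$data$sg,
                                  hkl)$f_plus) > 5
  ac <- !fx$data$obs$centric & strong & ph0_o$table$fom > 0.1
  mirror_diff <- phasekit:::phase_diff_deg(
    ph0_i$table$phi_best[ac], (-ph0_o$table$phi_best[ac]) %% 360
  )
  expect_lt(stats::median(mirror_diff), 10)
})
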