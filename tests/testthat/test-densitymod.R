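test_that("map synthesis produces the analytic cosine for one reflection", {
  fx <- mini_sad()
  ph <- mini_phases()
  one <- ph
  one$table <- one$table[one$table$h == 2 & one$table$k == 0 &
                           one$table$l == 0, , drop = FALSE]
  stopifnot(nrow(one$table) == 1)
  one$table$fom <- 1
  one$table$f_bar <- 10
  one$table$phi_best <- 0
  one$table$free <- FALSE
  mp <- synthesize_map(one, dims = c(24, 24, 24))
  # rho(x) = (2/V) * 10 * cos(2 pi * 2x) along a, constant along b, c
  xs <- (0:23) / 24
  expected <- 2 * 10 * cos(2 * pi * 2 * xs) / fx$data$cell$volume
  expect_equal(mp$values[, 1, 1], expected, tolerance = 1e-10)
  expect_equal(mp$values[, 5, 9], expected, tolerance = 1e-10)
})

test_that("synthesis and inversion are exact inverses", {
  ph <- mini_phases()
  mp <- synthesize_map(ph)
  sf <- map_to_sf(mp, as.matrix(ph$table[, c("h", "k", "l")]))
  w <- ph$table$fom * ph$table$f_bar
  expect_lt(max(abs(sf$f_dm - w)), 1e-6 * max(w))
  keep <- w > 1e-6 * max(w)
  expect_lt(max(phasekit:::phase_diff_deg(sf$phi_dm[keep],
                                          ph$table$phi_best[keep])), 1e-6)
  # zero weights give a flat map
  flat <- ph
  flat$table$fom <- 0
  mp0 <- synthesize_map(flat)
  expect_lt(max(abs(mp0$values)), 1e-12)
  expect_error(synthesize_map(ph, dims = c(8, 8, 8)), "Nyquist")
})

test_that("synthesized maps agree with direct summation", {
  ph <- mini_phases()
  small <- ph
  # coarse acentric subset: centric orbits self-collide on the coefficient
  # grid, which the implementation handles by single placement while a
  # naive sum would double count
  small$table <- small$table[small$table$d > 4 & !small$table$centric &
                               !(small$table$h == 0 & small$table$l == 0), ]
  mp <- synthesize_map(small, dims = c(20, 20, 20))
  # direct summation oracle at a handful of grid points
  tab <- small$table
  w <- tab$fom * tab$f_bar * exp(1i * tab$phi_best * pi / 180)
  hkl <- as.matrix(tab[, c("h", "k", "l")])
  sg <- small$sg
  pts <- rbind(c(0, 0, 0), c(0.25, 0.1, 0.6), c(0.7, 0.45, 0.3))
  for (r in seq_len(nrow(pts))) {
    x <- pts[r, ]
    acc <- 0
    for (op in sg$ops) {
      wop <- w * exp(-2i * pi * drop(hkl %*% op$t))
      hop <- hkl %*% op$R
      ph_x <- drop(hop %*% x)
      acc <- acc + sum(wop * exp(-2i * pi * ph_x)) +
        sum(Conj(wop) * exp(2i * pi * ph_x))
    }
    gi <- round(x * 20) + 1
    expect_equal(mp$values[gi[1], gi[2], gi[3]],
                 Re(acc) / small$cell$volume, tolerance = 1e-8)
  }
})

test_that("solvent masks have exact counts and deterministic ties", {
  ph <- mini_phases()
  mp <- synthesize_map(ph)
  mask <- solvent_mask(mp, 0.5)
  expect_equal(sum(mask$values), round(0.5 * prod(mp$dims)))
  # constant map: selection deterministic by index order
  cm <- mp
  cm$values[] <- 1
  m1 <- solvent_mask(cm, 0.3)
  m2 <- solvent_mask(cm, 0.3)
  expect_identical(m1$values, m2$values)
  expect_equal(sum(m1$values), round(0.3 * prod(mp$dims)))
  expect_error(solvent_mask(mp, 1.2), "solvent_fraction")
})

test_that("the solvent mask keeps atoms in the protein region", {
  fx <- mini_sad()
  ph <- mini_phases()
  mp <- synthesize_map(ph, zero_free = TRUE)
  mask <- solvent_mask(mp, 0.4)
  atoms <- rbind(as.matrix(fx$structure$light_atoms[, c("x", "y", "z")]),
                 as.matrix(fx$sub_true$sites[, c("x", "y", "z")]))
  allat <- atoms
  for (op in fx$data$sg$ops[-1]) {
    allat <- rbind(allat, phasekit:::wrap_frac(t(op$R %*% t(atoms) + op$t)))
  }
  gi <- cbind(round(allat[, 1] * mp$dims[1]) %% mp$dims[1] + 1,
              round(allat[, 2] * mp$dims[2]) %% mp$dims[2] + 1,
              round(allat[, 3] * mp$dims[3]) %% mp$dims[3] + 1)
  expect_gt(mean(!mask$values[gi]), 0.8)
  # mask symmetric under the screw operator: the image of every solvent
  # grid point is solvent
  dims <- mp$dims
  gpts <- as.matrix(expand.grid(x = (0:(dims[1] - 1)) / dims[1],
                                y = (0:(dims[2] - 1)) / dims[2],
                                z = 0.25))
  op <- fx$data$sg$ops[[2]]
  img <- phasekit:::wrap_frac(t(op$R %*% t(gpts) + op$t))
  i0 <- cbind(round(gpts[, 1] * dims[1]) %% dims[1] + 1,
              round(gpts[, 2] * dims[2]) %% dims[2] + 1,
              round(gpts[, 3] * dims[3]) %% dims[3] + 1)
  i1 <- cbind(round(img[, 1] * dims[1]) %% dims[1] + 1,
              round(img[, 2] * dims[2]) %% dims[2] + 1,
              round(img[, 3] * dims[3]) %% dims[3] + 1)
  expect_gt(mean(mask$values[i0] == mask$values[i1]), 0.995)
})

test_that("density modification has its degenerate identities", {
  ph <- mini_phases()
  mp <- synthesize_map(ph)
  mask <- solvent_mask(mp, 0.5)
  flat <- modify_density(mp, mask, "flatten")
  # already-flat solvent: flattening is idempotent
  flat2 <- modify_density(flat, mask, "flatten")
  expect_equal(flat2$values, flat$values, tolerance = 1e-12)
  # flip with factor 0 equals flattening
  flip0 <- modify_density(mp, mask, "flip", flip_factor = 0)
  expect_equal(flip0$values, flat$values, tolerance = 1e-12)
  # flipping twice with factor 1 restores the solvent
  flip1 <- modify_density(modify_density(mp, mask, "flip", 1), mask,
                          "flip", 1)
  expect_equal(flip1$values, mp$values, tolerance = 1e-10)
  bad <- mask
  bad$values <- bad$values[, , 1:2]
  expect_error(modify_density(mp, bad, "flatten"), "match")
})

test_that("phase combination limits: uninformative channel and flat prior", {
  fx <- mini_sad()
  ph <- mini_phases()
  em <- mini_em()
  mp <- synthesize_map(ph, zero_free = TRUE)
  dm <- map_to_sf(modify_density(mp, solvent_mask(mp, 0.7), "flatten"),
                  as.matrix(ph$table[, c("h", "k", "l")]))
  # d_dm = 0 everywhere: output equals input HL exactly
  em0 <- em
  em0$dm_pars <- list(shell_index = assign_shells(ph$table, 10),
                      d_dm = rep(0, 10), k_scale = rep(1, 10),
                      sigma_e = rep(1, 10), cv = TRUE)
  out0 <- combine_phases_mlhl(ph, dm, em0)
  expect_equal(out0$table$hl_a, ph$table$hl_a, tolerance = 1e-12)
  expect_equal(out0$table$hl_b, ph$table$hl_b, tolerance = 1e-12)
  # flat experimental prior + strong DM channel: phi_best -> phi_dm
  flat <- ph
  flat$table$hl_a <- 0; flat$table$hl_b <- 0
  flat$table$hl_c <- 0; flat$table$hl_d <- 0
  emS <- em
  emS$dm_pars <- list(shell_index = assign_shells(ph$table, 10),
                      d_dm = rep(0.99, 10), k_scale = rep(1, 10),
                      sigma_e = rep(1e-2, 10), cv = TRUE)
  outS <- combine_phases_mlhl(flat, dm, emS)
  ac <- !ph$table$centric & dm$f_dm > stats::median(dm$f_dm)
  # the posterior collapses onto the phase grid: agreement to half a
  # grid step (2.5 degrees)
  expect_lt(stats::median(phasekit:::phase_diff_deg(outS$table$phi_best[ac],
                                                    dm$phi_dm[ac])), 2.6)
})

test_that("alpha limits: redundant and independent channels", {
  fx <- mini_sad()
  d <- flag_free_set(fx$data, 0.05, seed = 6)
  em <- refine_error_model(d, fx$sub_true)
  ph <- phase_substructure_sad(d, fx$sub_true, em)
  mp <- synthesize_map(ph, zero_free = TRUE)
  dm <- map_to_sf(modify_density(mp, solvent_mask(mp, 0.7), "flatten"),
                  as.matrix(ph$table[, c("h", "k", "l")]))
  em <- estimate_comb_errors_cv(ph, dm, em)
  # alpha = 1: DM channel fully redundant -> experimental posterior back
  em1 <- em; em1$dm_corr <- 1
  out1 <- combine_phases_multivariate(d, fx$sub_true, dm, em1,
                                      exp_phases = ph)
  for (cn in c("hl_a", "hl_b", "hl_c", "hl_d")) {
    expect_lt(max(abs(out1$table[[cn]] - ph$table[[cn]])), 1e-6)
  }
  # alpha = 0: identical to MLHL combination
  em0 <- em; em0$dm_corr <- 0
  out0 <- combine_phases_multivariate(d, fx$sub_true, dm, em0,
                                      exp_phases = ph)
  ml <- combine_phases_mlhl(ph, dm, em0)
  for (cn in c("hl_a", "hl_b", "phi_best", "fom")) {
    expect_lt(max(abs(out0$table[[cn]] - ml$table[[cn]])), 1e-6)
  }
  em_bad <- em; em_bad$dm_corr <- 1.4
  expect_error(combine_phases_multivariate(d, fx$sub_true, dm, em_bad,
                                           exp_phases = ph), "alpha")
})

test_that("cross-validated combination errors are honest", {
  fx <- mini_sad()
  d <- flag_free_set(fx$data, 0.05, seed = 6)
  em <- refine_error_model(d, fx$sub_true)
  ph <- phase_substructure_sad(d, fx$sub_true, em)
  mp <- synthesize_map(ph, zero_free = TRUE)
  dm <- map_to_sf(modify_density(mp, solvent_mask(mp, 0.7), "flatten"),
                  as.matrix(ph$table[, c("h", "k", "l")]))
  # no free reflections: directed error
  ph_nofree <- ph
  ph_nofree$table$free <- FALSE
  expect_error(estimate_comb_errors_cv(ph_nofree, dm, em),
               "flag_free_set")
  em_cv <- estimate_comb_errors_cv(ph, dm, em, cv = TRUE)
  em_wk <- estimate_comb_errors_cv(ph, dm, em, cv = FALSE)
  # work-set estimation overfits: its d_dm is at least the free-set one
  expect_gte(mean(em_wk$d_dm), mean(em_cv$d_dm))
  expect_true(em_cv$dm_corr >= 0 && em_cv$dm_corr <= 1)
  # a pure-noise DM channel is downweighted to (almost) nothing
  set.seed(9)
  dm_noise <- dm
  dm_noise$f_dm <- sample(dm$f_dm)
  dm_noise$phi_dm <- stats::runif(nrow(dm), 0, 360)
  em_n <- estimate_comb_errors_cv(ph, dm_noise, em, cv = TRUE)
  expect_lt(mean(em_n$d_dm), 0.1)
  # a truth-built DM map gets a strong channel with small alpha
  ideal <- ph
  ideal$table$phi_best <- true_phi(ph, fx$truth)
  ideal$table$fom <- 1
  mp_t <- synthesize_map(ideal)
  dm_t <- map_to_sf(mp_t, as.matrix(ph$table[, c("h", "k", "l")]))
  em_t <- estimate_comb_errors_cv(ph, dm_t, em, cv = TRUE)
  expect_gt(mean(em_t$d_dm), 0.9)
  # the truth channel carries far more predictive information than noise
  ll_t <- phasekit:::dm_predictive_loglik(ph, dm_t, em_t)
  ll_n <- phasekit:::dm_predictive_loglik(ph, dm_noise, em_n)
  expect_gt(ll_t, ll_n + 10)
})

test_that("density-modification cycles improve phases and log honestly", {
  fx <- mini_sad()
  d <- flag_free_set(fx$data, 0.05, seed = 6)
  em <- refine_error_model(d, fx$sub_true)
  ph <- phase_substructure_sad(d, fx$sub_true, em)
  q0 <- phase_quality_vs_truth(ph, fx$truth)
  expect_error(run_dm_cycles(d, fx$sub_true, ph, n_cycles = 0, em = em),
               "n_cycles")
  res <- run_dm_cycles(d, fx$sub_true, ph, n_cycles = 3, em = em,
                       truth = fx$truth)
  expect_equal(nrow(res$log), 3)
  expect_gte(utils::tail(res$log$mean_cos_err, 1), q0$mean_cos_err - 0.01)
  # determinism
  res2 <- run_dm_cycles(d, fx$sub_true, ph, n_cycles = 3, em = em,
                        truth = fx$truth)
  expect_identical(res$log, res2$log)
  expect_identical(res$phases$table$phi_best, res2$phases$table$phi_best)
})

test_that("hand determination prefers the true hand and knows its limits", {
  fx <- mini_sad()
  d <- flag_free_set(fx$data, 0.05, seed = 6)
  em <- refine_error_model(d, fx$sub_true)
  hd <- determine_hand(d, fx$sub_true, em, n_cycles = 2)
  expect_identical(hd$decision, "original")
  # swapped input: feeding the inverted substructure mirrors the decision
  hd_inv <- determine_hand(d, invert_hand(fx$sub_true, d$sg), em,
                           n_cycles = 2)
  expect_identical(hd_inv$decision, "inverted")
  expect_equal(hd_inv$delta_loglik, -hd$delta_loglik, tolerance = 0.2 *
                 abs(hd$delta_loglik) + 1)
})
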