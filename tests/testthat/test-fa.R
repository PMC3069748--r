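truth_fh_bar <- function(fx) {
  ch <- fx$truth$channels[[1]]
  fh <- (Mod(ch$f_h_plus) + Mod(ch$f_h_minus)) / 2
  key_d <- paste(fx$data$obs$h, fx$data$obs$k, fx$data$obs$l)
  key_t <- paste(fx$truth$hkl$h, fx$truth$hkl$k, fx$truth$hkl$l)
  fh[match(key_d, key_t)]
}

test_that("simple |FA| is the absolute Bijvoet difference on acentrics", {
  fx <- mini_sad()
  d <- fx$data
  i <- which(!d$obs$centric)[5]
  d$obs$f_plus[i] <- 105; d$obs$f_minus[i] <- 95
  fa <- estimate_fa_simple(d)
  expect_equal(fa$table$fa[i], 10)
  expect_true(all(fa$table$excluded == d$obs$centric))
  expect_true(all(fa$table$fa[fa$table$excluded] == 0))
  # normalization: unit mean square per shell over included reflections
  tab <- fa$table[!fa$table$excluded, ]
  for (s in unique(tab$shell)) {
    expect_equal(mean(tab$e_norm[tab$shell == s]^2), 1, tolerance = 0.05)
  }
})

test_that("without anomalous scattering the simple estimate vanishes", {
  fx0 <- mini_sad(seed = 6, noise_frac = 0)
  # rebuild the dataset from light atoms only (f'' = 0 everywhere)
  hkl <- fx0$truth$hkl
  f0 <- structure_factors(fx0$structure$light_atoms, fx0$data$cell,
                          fx0$data$sg, as.matrix(hkl[, c("h", "k", "l")]))
  obs <- data.frame(h = hkl$h, k = hkl$k, l = hkl$l,
                    f_plus = Mod(f0$f_plus), sig_plus = 1,
                    f_minus = Mod(f0$f_plus), sig_minus = 1)
  d0 <- reflection_set(fx0$data$cell, fx0$data$sg, obs, label = "null")
  fa <- estimate_fa_simple(d0)
  expect_lt(max(fa$table$fa), 1e-8 * max(obs$f_plus))
})

test_that("multivariate |FA| matches the brute-force 3-D quadrature", {
  fx <- mini_sad()
  fm <- estimate_fa_multivariate(fx$data)
  shell <- assign_shells(fx$data, 10)
  pars <- phasekit:::fa_shell_params(fx$data, shell, 0.25, 0.05, TRUE)
  obs <- fx$data$obs
  set.seed(21)
  idx <- sample(which(!obs$centric), 25)
  rel <- vapply(idx, function(i) {
    s <- shell[i]
    sh <- pars$q[s] * pars$sigma_t[s]
    sp <- max(pars$sigma_t[s] - (1 + 0.25^2) * sh, 0.05 * pars$sigma_t[s])
    bf <- fa_posterior_bruteforce(obs$f_plus[i], obs$f_minus[i],
                                  obs$sig_plus[i]^2, obs$sig_minus[i]^2,
                                  sp, sh, 0.25, n = 150)
    (fm$table$fa[i] - bf) / bf
  }, numeric(1))
  expect_lt(sqrt(mean(rel^2)), 0.02)
})

test_that("multivariate |FA| has the stated limits and monotonicity", {
  fx <- mini_sad()
  d <- fx$data
  # no-information limit: equal mates, huge sigma -> Rayleigh prior mean
  j <- which(!d$obs$centric & assign_shells(d, 10) == 5)
  fbar <- mean((d$obs$f_plus[j] + d$obs$f_minus[j]) / 2)
  d$obs$f_plus[j[1]] <- fbar
  d$obs$f_minus[j[1]] <- fbar
  d$obs$sig_plus[j[1]] <- 60 * fbar
  d$obs$sig_minus[j[1]] <- 60 * fbar
  fm <- estimate_fa_multivariate(d, refine_heavy_fraction = FALSE,
                                 heavy_fraction = 0.05)
  shell <- assign_shells(d, 10)
  pars <- phasekit:::fa_shell_params(d, shell, 0.25, 0.05, FALSE)
  prior_mean <- sqrt(pi * 0.05 * pars$sigma_t[5]) / 2
  expect_equal(fm$table$fa[j[1]], prior_mean, tolerance = 0.05 * prior_mean)
  # monotone non-decreasing in |dF| at fixed |F+| + |F-|
  dd <- fx$data
  tot <- dd$obs$f_plus[j[2]] + dd$obs$f_minus[j[2]]
  vals <- vapply(c(0, 0.05, 0.1, 0.2), function(fr) {
    dd$obs$f_plus[j[2]] <- tot / 2 * (1 + fr)
    dd$obs$f_minus[j[2]] <- tot / 2 * (1 - fr)
    estimate_fa_multivariate(dd)$table$fa[j[2]]
  }, numeric(1))
  expect_true(all(diff(vals) > -1e-9))
  expect_true(all(fm$table$fa >= 0))
})

test_that("multivariate |FA| tracks the true heavy amplitudes better than |dF|", {
  fx <- mini_sad()
  fh <- truth_fh_bar(fx)
  ac <- !fx$data$obs$centric
  c_simple <- stats::cor(estimate_fa_simple(fx$data)$table$fa[ac], fh[ac])
  c_multi <- stats::cor(estimate_fa_multivariate(fx$data)$table$fa[ac],
                        fh[ac])
  expect_gt(c_multi, c_simple)
})

test_that("isomorphous |FA| recovers scale and vanishes on identical sets", {
  fx <- mini_siras()
  # identical sets: all differences zero
  fa0 <- estimate_fa_isomorphous(fx$deriv, fx$deriv)
  expect_lt(max(fa0$table$fa), 1e-9)
  # derivative = 2 x native: per-shell scale recovered within 1%
  dd <- fx$native
  dd$obs$f_plus <- dd$obs$f_plus * 2
  dd$obs$f_minus <- dd$obs$f_minus * 2
  fa2 <- estimate_fa_isomorphous(dd, fx$native)
  expect_true(all(abs(fa2$scale$k - 2) < 0.02))
  # too few common reflections rejected
  small <- fx$deriv
  small$obs <- small$obs[1:20, ]
  expect_error(estimate_fa_isomorphous(small, fx$native), "50")
})

test_that("SIRAS isomorphous differences track |F_H| at zero noise", {
  fx0 <- mini_siras(seed = 5, noise_frac = 0)
  fa <- estimate_fa_isomorphous(fx0$deriv, fx0$native)
  ch <- fx0$truth$channels[[1]]
  fh <- (Mod(ch$f_h_plus) + Mod(ch$f_h_minus)) / 2
  key_d <- paste(fa$table$h, fa$table$k, fa$table$l)
  key_t <- paste(fx0$truth$hkl$h, fx0$truth$hkl$k, fx0$truth$hkl$l)
  # the isomorphous difference measures |F_H| projected on the protein
  # direction (|dF_iso| ~ |F_H| |cos|), which caps the attainable
  # correlation with |F_H| near 0.7 even at zero noise
  expect_gt(stats::cor(fa$table$fa, fh[match(key_d, key_t)]), 0.65)
})

test_that("channel selection maximizes the anomalous signal score", {
  fx <- mini_sad()
  # single candidate returned unconditionally
  expect_identical(select_best_channel(list(only = fx$data)), "only")
  # two identical channels: first label by tie-break
  expect_identical(select_best_channel(list(aa = fx$data, bb = fx$data)),
                   "aa")
  # stronger f'' wins
  struct <- fx$structure
  spec <- experiment_spec("MAD",
                          data.frame(label = c("weak", "strong"),
                                     f_prime = c(-10, -8),
                                     f_dprime = c(4, 6)),
                          d_min = 2.4, noise_frac = 0.05, seed = 2)
  sim <- simulate_dataset(struct, spec)
  expect_identical(select_best_channel(sim$datasets), "strong")
  # invariance to a global rescaling
  resc <- sim$datasets$weak
  cols <- c("f_plus", "sig_plus", "f_minus", "sig_minus")
  resc$obs[cols] <- resc$obs[cols] * 13.7
  expect_identical(select_best_channel(list(weak = resc,
                                            strong = sim$datasets$strong)),
                   "strong")
  expect_error(select_best_channel(list()), "empty")
})

test_that("shell signal table recombines to the overall Bijvoet ratio", {
  fx <- mini_sad()
  tab <- anomalous_signal_by_shell(fx$data, 8)
  shell_rows <- tab[!is.na(tab$shell), ]
  overall <- tab[is.na(tab$shell), ]
  bs <- compute_bijvoet_stats(fx$data, 8)
  pr <- bs$per_reflection
  # count-weighted brute-force recombination of numerators/denominators
  num <- sum(vapply(shell_rows$shell, function(s) {
    sum(abs(pr$delta_f[pr$shell == s]))
  }, numeric(1)))
  den <- sum((fx$data$obs$f_plus + fx$data$obs$f_minus) / 2)
  expect_equal(overall$bijvoet_ratio, num / den, tolerance = 1e-12)
})

test_that("doubling f'' doubles the overall Bijvoet ratio at zero noise", {
  uc <- unit_cell(26, 30, 28)
  sg <- space_group("P21")
  struct <- generate_structure(derive_seed(3, "structure"), uc, sg, 60,
                               data.frame(element = "SE", count = 2,
                                          f_prime = -8, f_dprime = 1))
  ratio_for <- function(fdp) {
    spec <- experiment_spec("SAD",
                            data.frame(label = "x", f_prime = -8,
                                       f_dprime = fdp),
                            d_min = 2.4, noise_frac = 0, seed = 1)
    sim <- simulate_dataset(struct, spec)
    compute_bijvoet_stats(sim$datasets$x, 5)$overall_bijvoet_ratio
  }
  r1 <- ratio_for(1)
  r2 <- ratio_for(2)
  expect_equal(r2 / r1, 2, tolerance = 0.01)
})
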