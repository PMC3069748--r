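test_that("structure generation is reproducible and respects packing", {
  uc <- unit_cell(26, 30, 28)
  sg <- space_group("P21")
  hs <- data.frame(element = "SE", count = 2, f_prime = -8, f_dprime = 4)
  s1 <- generate_structure(5, uc, sg, 30, hs)
  s2 <- generate_structure(5, uc, sg, 30, hs)
  expect_identical(s1$light_atoms, s2$light_atoms)
  expect_identical(s1$heavy$sites, s2$heavy$sites)
  # degenerate structure: no light atoms, one heavy site
  s3 <- generate_structure(1, uc, sg,
                           0, data.frame(element = "SE", count = 1,
                                         f_prime = -8, f_dprime = 4))
  expect_equal(nrow(s3$light_atoms), 0)
  expect_equal(nrow(s3$heavy$sites), 1)
  # heavy sites at least 3 A apart
  expect_gt(site_distance(uc, sg,
                          as.numeric(s1$heavy$sites[1, c("x", "y", "z")]),
                          as.numeric(s1$heavy$sites[2, c("x", "y", "z")])),
            3)
  # packing failure reported
  expect_error(generate_structure(1, unit_cell(6, 6, 6), space_group("P1"),
                                  0, data.frame(element = "SE", count = 40,
                                                f_prime = 0, f_dprime = 1)),
               "packing")
})

test_that("P21 structures expand to two symmetry copies per cell", {
  uc <- unit_cell(26, 30, 28)
  sg <- space_group("P21")
  s <- generate_structure(9, uc, sg, 10,
                          data.frame(element = "SE", count = 1,
                                     f_prime = -8, f_dprime = 4))
  # apply both operators: 11 sites -> 22 distinct positions in the cell
  xyz <- rbind(as.matrix(s$light_atoms[, c("x", "y", "z")]),
               as.matrix(s$heavy$sites[, c("x", "y", "z")]))
  exp_xyz <- NULL
  for (op in sg$ops) {
    exp_xyz <- rbind(exp_xyz, phasekit:::wrap_frac(t(op$R %*% t(xyz) + op$t)))
  }
  expect_equal(nrow(unique(round(as.data.frame(exp_xyz), 8))), 22)
})

test_that("direct-summation structure factors match closed forms", {
  uc <- unit_cell(10, 10, 10)
  sg <- space_group("P1")
  hkl <- as.matrix(expand.grid(h = -2:2, k = -2:2, l = 0:2))
  hkl <- hkl[rowSums(abs(hkl)) > 0, ]
  # single atom at origin, B = 0, constant form factor: F(h) = Z for all h
  st <- sites("C", 0, 0, 0, b = 0)
  st$f0_width <- 0
  f <- structure_factors(st, uc, sg, hkl)
  expect_equal(f$f_plus, rep(complex(real = 6), nrow(hkl)), tolerance = 1e-12)
  expect_equal(f$f_minus, rep(complex(real = 6), nrow(hkl)), tolerance = 1e-12)
})

test_that("structure factors match an independent brute-force oracle", {
  uc <- unit_cell(11, 13, 12, 90, 90, 90)
  sg <- space_group("P21")
  st <- sites(c("C", "SE"), c(0.13, 0.61), c(0.27, 0.08), c(0.44, 0.77),
              occ = c(1, 0.8), b = c(12, 18),
              f_prime = c(0, -8), f_dprime = c(0, 4))
  hkl <- as.matrix(expand.grid(h = -3:3, k = -3:3, l = -2:2))
  hkl <- hkl[rowSums(abs(hkl)) > 0, ]
  f <- structure_factors(st, uc, sg, hkl)
  # oracle: naive double loop over atoms and operators
  oracle <- vapply(seq_len(nrow(hkl)), function(i) {
    h <- hkl[i, ]
    s2 <- 1 / d_spacing(uc, h)^2
    acc <- 0 + 0i
    for (j in 1:2) {
      fat <- st$f0_z[j] * exp(-st$f0_width[j] * s2) +
        complex(real = st$f_prime[j], imaginary = st$f_dprime[j])
      dw <- exp(-st$b[j] * s2 / 4)
      for (op in sg$ops) {
        xs <- op$R %*% c(st$x[j], st$y[j], st$z[j]) + op$t
        acc <- acc + st$occ[j] * fat * dw * exp(2i * pi * sum(h * xs))
      }
    }
    acc
  }, complex(1))
  expect_lt(max(Mod(f$f_plus - oracle)), 1e-10 * max(Mod(oracle)))
})

test_that("Friedel law holds exactly without anomalous scattering", {
  fx <- mini_sad()
  hkl <- as.matrix(fx$truth$hkl[, c("h", "k", "l")])
  f0 <- structure_factors(fx$structure$light_atoms, fx$data$cell,
                          fx$data$sg, hkl)
  rel <- Mod(Mod(f0$f_plus) - Mod(f0$f_minus)) / Mod(f0$f_plus)
  expect_lt(max(rel), 1e-10)
  # and F(-h) = conj(F(h)) to machine precision
  expect_lt(max(Mod(f0$f_minus - Conj(f0$f_plus))), 1e-8 * max(Mod(f0$f_plus)))
})

test_that("substructure-only single-element data carry no Bijvoet signal", {
  uc <- unit_cell(20, 22, 24)
  sg <- space_group("P21")
  struct <- generate_structure(3, uc, sg, 0,
                               data.frame(element = "SE", count = 2,
                                          f_prime = -8, f_dprime = 4))
  spec <- experiment_spec("SAD",
                          data.frame(label = "peak", f_prime = -8,
                                     f_dprime = 4),
                          d_min = 2.5, noise_frac = 0, seed = 1)
  sim <- simulate_dataset(struct, spec)
  obs <- sim$datasets$peak$obs
  expect_lt(max(abs(obs$f_plus - obs$f_minus)), 1e-8 * max(obs$f_plus))
})

test_that("zero-noise simulation reproduces the stored truth exactly", {
  fx0 <- mini_sad(seed = 6, noise_frac = 0)
  ch <- fx0$truth$channels[[1]]
  key_o <- paste(fx0$data$obs$h, fx0$data$obs$k, fx0$data$obs$l)
  key_t <- paste(fx0$truth$hkl$h, fx0$truth$hkl$k, fx0$truth$hkl$l)
  idx <- match(key_o, key_t)
  expect_equal(fx0$data$obs$f_plus, ch$f_true_plus[idx], tolerance = 1e-9)
  expect_equal(fx0$data$obs$f_minus, ch$f_true_minus[idx], tolerance = 1e-9)
})

test_that("simulated noise has the stated first and second moments", {
  fx <- mini_sad(seed = 8)
  fx0 <- mini_sad(seed = 8, noise_frac = 0)
  obs <- fx$data$obs
  z <- c((obs$f_plus - fx0$data$obs$f_plus) / obs$sig_plus,
         (obs$f_minus - fx0$data$obs$f_minus)[!obs$centric] /
           obs$sig_minus[!obs$centric])
  expect_lt(abs(mean(z)), 0.05)
  expect_gt(stats::var(z), 0.9)
  expect_lt(stats::var(z), 1.1)
})

test_that("hand inversion is an involution and preserves |F_H|", {
  fx <- mini_sad()
  sg <- fx$data$sg
  inv <- invert_hand(fx$sub_true, sg)
  expect_identical(inv$hand, "inverted")
  twice <- invert_hand(inv, sg)
  expect_equal(as.matrix(twice$sites[, c("x", "y", "z")]),
               as.matrix(fx$sub_true$sites[, c("x", "y", "z")]),
               tolerance = 1e-12, ignore_attr = TRUE)
  # single site in P1: x -> -x mod 1
  s1 <- substructure(sites("SE", 0.1, 0.2, 0.3, f_dprime = 4))
  i1 <- invert_hand(s1, space_group("P1"))
  expect_equal(as.numeric(i1$sites[1, c("x", "y", "z")]), c(0.9, 0.8, 0.7))
  # origin site is a fixed point
  s0 <- substructure(sites("SE", 0, 0, 0, f_dprime = 4))
  i0 <- invert_hand(s0, space_group("P1"))
  expect_equal(as.numeric(i0$sites[1, c("x", "y", "z")]), c(0, 0, 0))
  # both hands give identical heavy-atom amplitudes
  hkl <- as.matrix(fx$truth$hkl[, c("h", "k", "l")])
  f_o <- structure_factors(fx$sub_true, fx$data$cell, sg, hkl)
  f_i <- structure_factors(inv, fx$data$cell, sg, hkl)
  # hand inversion swaps the Friedel mates: the amplitude multiset is
  # preserved (|F'(h)| = |F(-h)|)
  expect_equal(unname(Mod(f_i$f_plus)), unname(Mod(f_o$f_minus)),
               tolerance = 1e-9)
  expect_equal(unname(Mod(f_i$f_minus)), unname(Mod(f_o$f_plus)),
               tolerance = 1e-9)
})

test_that("centric reflections have exactly equal Friedel members", {
  fx <- mini_sad()
  obs <- fx$data$obs
  cen <- obs$centric
  expect_true(any(cen))
  expect_identical(obs$f_plus[cen], obs$f_minus[cen])
  expect_identical(obs$sig_plus[cen], obs$sig_minus[cen])
})
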