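# Shared fixtures, built in code and cached for the session.  The "mini"
# crystal is a scaled-down analogue of the default toy problem: P21,
# 26 x 30 x 28 A cell, 60 light atoms, two Se-like sites, 2.4 A data.

.fixture_env <- new.env(parent = emptyenv())

mini_sad <- function(seed = 3, noise_frac = 0.05) {
  key <- sprintf("mini_%d_%g", seed, noise_frac)
  if (is.null(.fixture_env[[key]])) {
    struct <- generate_structure(
      derive_seed(seed, "structure"),
      unit_cell(26, 30, 28), space_group("P21"), n_light = 60,
      heavy_spec = data.frame(element = "SE", count = 2,
                              f_prime = -8, f_dprime = 4)
    )
    spec <- experiment_spec(
      "SAD", data.frame(label = "peak", f_prime = -8, f_dprime = 4),
      d_min = 2.4, noise_frac = noise_frac, seed = derive_seed(seed, "noise")
    )
    sim <- simulate_dataset(struct, spec)
    .fixture_env[[key]] <- list(
      data = sim$datasets$peak, truth = sim$truth, structure = struct,
      sub_true = struct$heavy
    )
  }
  .fixture_env[[key]]
}

mini_siras <- function(seed = 4, noise_frac = 0.05) {
  key <- sprintf("siras_%d_%g", seed, noise_frac)
  if (is.null(.fixture_env[[key]])) {
    struct <- generate_structure(
      derive_seed(seed, "structure"),
      unit_cell(26, 30, 28), space_group("P21"), n_light = 60,
      heavy_spec = data.frame(element = "SE", count = 2,
                              f_prime = -8, f_dprime = 4)
    )
    spec <- experiment_spec(
      "SIRAS", data.frame(label = "deriv", f_prime = -8, f_dprime = 4),
      d_min = 2.4, noise_frac = noise_frac, seed = derive_seed(seed, "noise")
    )
    sim <- simulate_dataset(struct, spec)
    .fixture_env[[key]] <- list(
      deriv = sim$datasets$deriv, native = sim$datasets$native,
      truth = sim$truth, structure = struct, sub_true = struct$heavy
    )
  }
  .fixture_env[[key]]
}

mini_em <- function(seed = 3, noise_frac = 0.05) {
  key <- sprintf("em_%d_%g", seed, noise_frac)
  if (is.null(.fixture_env[[key]])) {
    fx <- mini_sad(seed, noise_frac)
    .fixture_env[[key]] <- refine_error_model(fx$data, fx$sub_true)
  }
  .fixture_env[[key]]
}

mini_phases <- function(seed = 3, noise_frac = 0.05) {
  key <- sprintf("ph_%d_%g", seed, noise_frac)
  if (is.null(.fixture_env[[key]])) {
    fx <- mini_sad(seed, noise_frac)
    .fixture_env[[key]] <- phase_substructure_sad(fx$data, fx$sub_true,
                                                  mini_em(seed, noise_frac))
  }
  .fixture_env[[key]]
}

# An fa_estimate whose values are the true heavy-atom amplitudes: the
# idealized |FA| input used to test scoring self-consistency.
fa_from_truth <- function(fx) {
  fa <- estimate_fa_simple(fx$data)
  key_d <- paste(fa$table$h, fa$table$k, fa$table$l)
  key_t <- paste(fx$truth$hkl$h, fx$truth$hkl$k, fx$truth$hkl$l)
  ch <- fx$truth$channels[[1]]
  fh <- (Mod(ch$f_h_plus) + Mod(ch$f_h_minus)) / 2
  fa$table$fa <- fh[match(key_d, key_t)]
  fa$table$fa[fa$table$excluded] <- 0
  use <- !fa$table$excluded
  fa$table$e_norm[use] <- phasekit:::fa_normalize(fa$table$fa[use],
                                                  fa$table$shell[use])
  fa$method <- "truth"
  fa
}

true_phi <- function(phases, truth, total = FALSE) {
  tab <- phases$table
  idx <- match(paste(tab$h, tab$k, tab$l),
               paste(truth$hkl$h, truth$hkl$k, truth$hkl$l))
  if (total) truth$channels[[1]]$phi_total_deg[idx] else truth$phi_p_deg[idx]
}
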