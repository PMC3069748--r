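# Synthetic toy crystals: structure generation, direct-summation structure
# factors with wavelength-dependent f'/f'', and simulated SAD/MAD/SIRAS
# datasets with deposited ground truth.

# Single-Gaussian form factors f0(s) = Z exp(-w s^2), s = 1/d.  The widths
# are fitted by eye to the tabulated falloff of each element near 2 A
# resolution; a single Gaussian keeps the resolution dependence realistic
# without shipping full Cromer-Mann tables.
element_form_factors <- data.frame(
  element = c("C", "N", "O", "S", "FE", "SE", "BR", "HG"),
  z = c(6, 7, 8, 16, 26, 34, 35, 80),
  width = c(3.3, 3.0, 2.7, 2.2, 2.0, 1.9, 1.9, 1.5),
  stringsAsFactors = FALSE
)

lookup_element <- function(element) {
  i <- match(toupper(element), element_form_factors$element)
  if (any(is.na(i))) {
    stop("unknown element(s): ",
         paste(unique(element[is.na(i)]), collapse = ", "))
  }
  element_form_factors[i, , drop = FALSE]
}

#' Construct a table of atomic sites
#'
#' @param element Element symbols (looked up in the built-in single-Gaussian
#'   form-factor table).
#' @param x,y,z Fractional coordinates (wrapped into `[0, 1)`).
#' @param occ Occupancies in (0, 1].
#' @param b Isotropic B-factors in A^2 (>= 0).
#' @param f_prime,f_dprime Anomalous corrections f' and f'' in electrons
#'   (f'' >= 0).
#' @return Data frame of class `sites` with form-factor parameters attached.
#' @export
sites <- function(element, x, y, z, occ = 1, b = 15,
                  f_prime = 0, f_dprime = 0) {
  if (length(element) == 0) {
    out <- data.frame(
      element = character(0), x = numeric(0), y = numeric(0), z = numeric(0),
      occ = numeric(0), b = numeric(0), f0_z = numeric(0),
      f0_width = numeric(0), f_prime = numeric(0), f_dprime = numeric(0),
      stringsAsFactors = FALSE
    )
    class(out) <- c("sites", "data.frame")
    return(out)
  }
  ff <- lookup_element(element)
  out <- data.frame(
    element = toupper(element),
    x = wrap_frac(x), y = wrap_frac(y), z = wrap_frac(z),
    occ = occ, b = b,
    f0_z = ff$z, f0_width = ff$width,
    f_prime = f_prime, f_dprime = f_dprime,
    stringsAsFactors = FALSE
  )
  if (any(out$occ <= 0 | out$occ > 1 + 1e-9)) stop("occupancy must be in (0, 1]")
  if (any(out$b < 0)) stop("B-factors must be non-negative")
  if (any(out$f_dprime < 0)) stop("f'' must be non-negative")
  class(out) <- c("sites", "data.frame")
  out
}

#' Construct a substructure (anomalous scatterers)
#'
#' @param site_table A [sites] table.
#' @param hand `"original"` or `"inverted"`.
#' @export
substructure <- function(site_table, hand = c("original", "inverted")) {
  hand <- match.arg(hand)
  structure(list(sites = site_table, hand = hand), class = "substructure")
}

#' Invert the hand of a substructure
#'
#' Applies the enantiomorph action of the space group (x to -x for the
#' supported groups).  An involution modulo allowed origin shifts.
#'
#' @param sub A [substructure].
#' @param sg A [space_group].
#' @export
invert_hand <- function(sub, sg) {
  st <- sub$sites
  xyz <- enantiomorph_xyz(sg, st[, c("x", "y", "z")])
  st$x <- xyz[, 1]; st$y <- xyz[, 2]; st$z <- xyz[, 3]
  substructure(st, hand = if (sub$hand == "original") "inverted" else "original")
}

asu_box <- function(sg) {
  switch(sg$symbol,
    "P1" = c(1, 1, 1),
    "P21" = c(1, 0.5, 1),
    "P212121" = c(1, 1, 0.25)
  )
}

#' Generate a random toy structure
#'
#' Light atoms (f'' = 0) are placed uniformly in the asymmetric unit with
#' B-factors drawn uniformly in [10, 30] A^2 and a minimum inter-site
#' separation of 1.5 A (over all symmetry images); heavy sites get B in
#' [15, 25] A^2 and at least 3 A separation.  Reproducible from `seed`.
#'
#' @param seed Integer seed.
#' @param cell A [unit_cell].
#' @param sg A [space_group].
#' @param n_light Number of light (carbon surrogate) atoms.
#' @param heavy_spec Data frame with columns `element, count, f_prime,
#'   f_dprime` describing the anomalous scatterers.
#' @param light_element Element used for the protein surrogate.
#' @return A list of class `structure` with `cell`, `sg`, `light_atoms`
#'   ([sites]) and `heavy` ([substructure]).
#' @export
generate_structure <- function(seed, cell, sg, n_light, heavy_spec,
                               light_element = "C") {
  stopifnot(inherits(cell, "unit_cell"), inherits(sg, "space_group"))
  if (any(heavy_spec$count < 1)) stop("heavy-atom counts must be >= 1")
  set.seed(seed)
  box <- asu_box(sg)
  placed <- matrix(numeric(0), 0, 3)
  place <- function(n, min_sep, placed) {
    out <- matrix(NA_real_, n, 3)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (att in 1:2000) {
        cand <- runif(3) * box
        all_prev <- rbind(placed, out[seq_len(i - 1), , drop = FALSE])
        if (nrow(all_prev) == 0) { ok <- TRUE; break }
        dmin <- min(vapply(seq_len(nrow(all_prev)), function(j) {
          site_distance(cell, sg, cand, all_prev[j, ])
        }, numeric(1)))
        # also keep a site away from its own symmetry images
        dself <- if (length(sg$ops) > 1) {
          min(vapply(seq_along(sg$ops)[-1], function(k) {
            op <- sg$ops[[k]]
            dx <- wrap_frac(cand - (op$R %*% cand + op$t))
            dx <- ifelse(dx > 0.5, dx - 1, dx)
            sqrt(drop(t(dx) %*% cell$metric %*% dx))
          }, numeric(1)))
        } else Inf
        if (dmin >= min_sep && dself >= min_sep) { ok <- TRUE; break }
      }
      if (!ok) stop("packing impossible: could not place site ", i,
                    " with ", min_sep, " A separation")
      out[i, ] <- cand
    }
    out
  }
  heavy_list <- list()
  for (r in seq_len(nrow(heavy_spec))) {
    xyz <- place(heavy_spec$count[r], 3.0, placed)
    placed <- rbind(placed, xyz)
    heavy_list[[r]] <- sites(
      rep(heavy_spec$element[r], heavy_spec$count[r]),
      xyz[, 1], xyz[, 2], xyz[, 3],
      occ = 1, b = runif(heavy_spec$count[r], 15, 25),
      f_prime = heavy_spec$f_prime[r], f_dprime = heavy_spec$f_dprime[r]
    )
    class(heavy_list[[r]]) <- "data.frame"
  }
  heavy <- do.call(rbind, heavy_list)
  class(heavy) <- c("sites", "data.frame")
  light <- NULL
  if (n_light > 0) {
    xyz <- place(n_light, 1.5, placed)
    light <- sites(
      rep(light_element, n_light), xyz[, 1], xyz[, 2], xyz[, 3],
      occ = 1, b = runif(n_light, 10, 30)
    )
  } else {
    light <- sites(character(0), numeric(0), numeric(0), numeric(0))
  }
  structure(list(cell = cell, sg = sg, light_atoms = light,
                 heavy = substructure(heavy)),
            class = "structure")
}

#' @export
print.structure <- function(x, ...) {
  cat(sprintf("toy structure: %d light atoms + %d heavy sites, %s\n",
              nrow(x$light_atoms), nrow(x$heavy$sites), x$sg$symbol))
  invisible(x)
}

#' Direct-summation structure factors
#'
#' Exact summation (no FFT approximation) of
#' `F(h) = sum_sites sum_ops (f0(s) + f' + i f'') occ exp(-B s^2/4)
#'  exp(2 pi i h.(Rx + t))` with `f0(s) = Z exp(-w s^2)` and `s = 1/d`,
#' for both Friedel mates of every requested reflection.
#'
#' @param site_table A [sites] table (or a [substructure] or [structure]).
#' @param cell A [unit_cell].
#' @param sg A [space_group].
#' @param hkl n x 3 integer matrix of Miller indices.
#' @param channel Optional list with `f_prime` and `f_dprime` overriding the
#'   anomalous corrections of anomalous sites (those with f'' > 0 or named
#'   heavy elements) - used to model wavelength changes.
#' @return List with complex vectors `f_plus` (at +h) and `f_minus` (at -h).
#' @export
structure_factors <- function(site_table, cell, sg, hkl, channel = NULL) {
  if (inherits(site_table, "structure")) {
    st <- rbind(
      as.data.frame(site_table$light_atoms),
      as.data.frame(site_table$heavy$sites)
    )
  } else if (inherits(site_table, "substructure")) {
    st <- as.data.frame(site_table$sites)
  } else {
    st <- as.data.frame(site_table)
  }
  hkl <- as_hkl_matrix(hkl)
  if (!is.null(channel) && nrow(st) > 0) {
    anom <- st$f_dprime > 0 | st$element %in% channel$elements
    if (!any(anom)) anom <- rep(TRUE, nrow(st))
    if (!is.null(channel$f_prime)) st$f_prime[anom] <- channel$f_prime
    if (!is.null(channel$f_dprime)) st$f_dprime[anom] <- channel$f_dprime
  }
  n <- nrow(hkl)
  if (nrow(st) == 0) {
    return(list(f_plus = complex(n), f_minus = complex(n)))
  }
  s2 <- 1 / d_spacing(cell, hkl)^2
  sum_one <- function(H) {
    f0 <- exp(-outer(s2, st$f0_width)) *
      matrix(st$f0_z, n, nrow(st), byrow = TRUE)
    fan <- f0 + matrix(complex(real = st$f_prime, imaginary = st$f_dprime),
                       n, nrow(st), byrow = TRUE)
    dw <- exp(-outer(s2, st$b) / 4)
    wt <- fan * dw * matrix(st$occ, n, nrow(st), byrow = TRUE)
    acc <- complex(n)
    X <- t(as.matrix(st[, c("x", "y", "z")]))
    for (op in sg$ops) {
      ph <- (H %*% op$R) %*% X + matrix(drop(H %*% op$t), n, nrow(st))
      acc <- acc + rowSums(wt * exp(2i * pi * ph))
    }
    acc
  }
  list(f_plus = sum_one(hkl), f_minus = sum_one(-hkl))
}

#' Specify a simulated experiment
#'
#' @param kind `"SAD"`, `"MAD"` or `"SIRAS"`.
#' @param channels Data frame with columns `label, f_prime, f_dprime`, one
#'   row per wavelength (MAD needs >= 2; SAD and SIRAS exactly 1).
#' @param d_min High-resolution limit in Angstrom.
#' @param noise_frac Relative amplitude noise: the per-shell measurement
#'   sigma is `noise_frac` times the shell mean amplitude.
#' @param seed Integer seed for the noise draws.
#' @param native For SIRAS, whether to emit a native set (always `TRUE` when
#'   kind is SIRAS).
#' @export
experiment_spec <- function(kind = c("SAD", "MAD", "SIRAS"), channels,
                            d_min, noise_frac = 0.05, seed = 1,
                            native = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(channels), nrow(channels) >= 1, d_min > 0,
            noise_frac >= 0)
  if (kind == "MAD" && nrow(channels) < 2) stop("MAD needs >= 2 channels")
  if (kind != "MAD" && nrow(channels) != 1) {
    stop(kind, " uses exactly one anomalous channel")
  }
  native <- if (is.null(native)) kind == "SIRAS" else native
  structure(list(kind = kind, channels = channels, d_min = d_min,
                 noise_frac = noise_frac, seed = seed, native = native),
            class = "experiment_spec")
}

#' Simulate a dataset with ground truth
#'
#' Noise-free Friedel-pair amplitudes are computed by direct summation for
#' each channel, then Gaussian amplitude noise with per-shell sigma equal to
#' `noise_frac` times the shell mean amplitude is added (one shared draw for
#' the two members of a centric pair).  The returned truth record stores the
#' true protein (light-atom) phases, true total phases, the complex
#' heavy-atom structure factors per channel, the noise-free amplitudes and a
#' copy of the site list.
#'
#' @param struct A [structure] from [generate_structure].
#' @param spec An [experiment_spec].
#' @param n_shells Shells used for the noise scaling.
#' @return List with `datasets` (list of [reflection_set]: one per channel,
#'   plus `"native"` for SIRAS) and `truth` (class `truth_record`).
#' @export
simulate_dataset <- function(struct, spec, n_shells = 10) {
  stopifnot(inherits(struct, "structure"), inherits(spec, "experiment_spec"))
  cell <- struct$cell; sg <- struct$sg
  ref <- unique_hkl(cell, sg, spec$d_min)
  hkl <- as.matrix(ref[, c("h", "k", "l")])
  n <- nrow(hkl)
  fp_only <- structure_factors(struct$light_atoms, cell, sg, hkl)
  phi_p <- (Arg(fp_only$f_plus) * 180 / pi) %% 360
  set.seed(derive_seed(spec$seed, "simulate"))
  shell <- {
    ord <- order(-ref$d, ref$h, ref$k, ref$l)
    s <- integer(n); s[ord] <- pmin(as.integer(ceiling(seq_len(n) / (n / n_shells))), n_shells); s
  }
  add_noise <- function(f_plus_true, f_minus_true) {
    fbar <- (f_plus_true + f_minus_true) / 2
    sig_shell <- vapply(seq_len(n_shells), function(s) {
      spec$noise_frac * mean(fbar[shell == s])
    }, numeric(1))
    sig <- sig_shell[shell]
    eps_p <- rnorm(n); eps_m <- rnorm(n)
    eps_m[ref$centric] <- eps_p[ref$centric]
    obs_p <- pmax(f_plus_true + eps_p * sig, 1e-9)
    obs_m <- pmax(f_minus_true + eps_m * sig, 1e-9)
    sig_col <- pmax(sig, 1e-6 * max(mean(fbar), 1e-12))
    list(f_plus = obs_p, f_minus = obs_m,
         sig_plus = sig_col, sig_minus = sig_col)
  }
  datasets <- list()
  truth_channels <- list()
  for (ch in seq_len(nrow(spec$channels))) {
    lab <- spec$channels$label[ch]
    channel <- list(f_prime = spec$channels$f_prime[ch],
                    f_dprime = spec$channels$f_dprime[ch])
    ftot <- structure_factors(struct, cell, sg, hkl, channel = channel)
    fh <- structure_factors(struct$heavy, cell, sg, hkl, channel = channel)
    amp_p <- Mod(ftot$f_plus); amp_m <- Mod(ftot$f_minus)
    amp_m[ref$centric] <- amp_p[ref$centric]
    nz <- add_noise(amp_p, amp_m)
    obs <- data.frame(
      h = ref$h, k = ref$k, l = ref$l,
      f_plus = nz$f_plus, sig_plus = nz$sig_plus,
      f_minus = nz$f_minus, sig_minus = nz$sig_minus
    )
    obs$f_minus[ref$centric] <- obs$f_plus[ref$centric]
    datasets[[lab]] <- reflection_set(cell, sg, obs, label = lab,
                                      d_min = spec$d_min)
    truth_channels[[lab]] <- data.frame(
      h = ref$h, k = ref$k, l = ref$l,
      f_h_plus = fh$f_plus, f_h_minus = fh$f_minus,
      f_true_plus = amp_p, f_true_minus = amp_m,
      phi_total_deg = (Arg(ftot$f_plus) * 180 / pi) %% 360
    )
  }
  if (spec$native) {
    amp_nat <- Mod(fp_only$f_plus)
    nz <- add_noise(amp_nat, amp_nat)
    # a native set has no anomalous signal: one measurement per pair
    obs <- data.frame(
      h = ref$h, k = ref$k, l = ref$l,
      f_plus = nz$f_plus, sig_plus = nz$sig_plus,
      f_minus = nz$f_plus, sig_minus = nz$sig_plus
    )
    datasets[["native"]] <- reflection_set(cell, sg, obs, label = "native",
                                           d_min = spec$d_min)
  }
  truth <- structure(list(
    hkl = ref,
    phi_p_deg = phi_p,
    channels = truth_channels,
    sites = struct$heavy$sites,
    spec = spec
  ), class = "truth_record")
  list(datasets = datasets, truth = truth)
}

#' The default toy crystal ("toy50")
#'
#' P21 cell 34 x 42 x 38 A (beta = 90), 150 light carbon-surrogate atoms and
#' two selenium-like sites (f' = -8, f'' = 4), diffracting to 2.2 A.  All
#' package-level worked examples and acceptance-style checks reference this
#' problem.
#'
#' @param seed Integer seed for the random structure.
#' @export
toy_structure <- function(seed = 101) {
  generate_structure(
    seed,
    unit_cell(34, 42, 38, 90, 90, 90),
    space_group("P21"),
    n_light = 150,
    heavy_spec = data.frame(element = "SE", count = 2,
                            f_prime = -8, f_dprime = 4)
  )
}

#' Simulate a toy50 SAD dataset
#'
#' @param seed Seed controlling both the structure and the noise.
#' @param noise_frac Relative amplitude noise (default 5%).
#' @param d_min Resolution limit in Angstrom.
#' @param f_dprime f'' of the anomalous sites.
#' @return List with `data` (a [reflection_set]), `truth`, `structure` and
#'   `sub_true` (the true [substructure]).
#' @export
simulate_toy_sad <- function(seed = 1, noise_frac = 0.05, d_min = 2.2,
                             f_dprime = 4) {
  struct <- toy_structure(derive_seed(seed, "structure"))
  spec <- experiment_spec(
    "SAD",
    channels = data.frame(label = "peak", f_prime = -8, f_dprime = f_dprime),
    d_min = d_min, noise_frac = noise_frac,
    seed = derive_seed(seed, "noise")
  )
  sim <- simulate_dataset(struct, spec)
  list(data = sim$datasets$peak, truth = sim$truth, structure = struct,
       sub_true = struct$heavy)
}
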