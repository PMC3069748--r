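# ReflectionSet container and basic statistics on Friedel pairs.

#' Construct a reflection set
#'
#' One observation per symmetry-unique reflection, holding both members of
#' the Friedel pair (|F+|, sigma+, |F-|, sigma-), the centric flag and the
#' cross-validation (free-set) flag.
#'
#' @param cell A [unit_cell].
#' @param sg A [space_group].
#' @param obs Data frame with columns `h, k, l, f_plus, sig_plus, f_minus,
#'   sig_minus` and optionally `centric` and `free`.  The centric flag is
#'   recomputed from the symmetry if absent.
#' @param label Text label for the set (e.g. a wavelength name).
#' @param d_min,d_max Resolution limits in Angstrom; defaults are taken from
#'   the data.
#' @return An object of class `reflection_set`: the observation data frame
#'   (with derived columns `d`, `centric`, `phi0_deg`, `free`) plus the cell
#'   and symmetry.
#' @export
reflection_set <- function(cell, sg, obs, label = "data",
                           d_min = NULL, d_max = NULL) {
  stopifnot(inherits(cell, "unit_cell"), inherits(sg, "space_group"))
  need <- c("h", "k", "l", "f_plus", "sig_plus", "f_minus", "sig_minus")
  miss <- setdiff(need, names(obs))
  if (length(miss)) stop("missing observation columns: ",
                         paste(miss, collapse = ", "))
  hkl <- as.matrix(obs[, c("h", "k", "l")])
  if (any(rowSums(abs(hkl)) == 0)) stop("reflection (0,0,0) not allowed")
  red <- reduce_hkl(sg, hkl)
  if (any(red$hkl != hkl)) {
    stop("observations must be indexed on the canonical symmetry-unique set")
  }
  key <- paste(obs$h, obs$k, obs$l)
  if (anyDuplicated(key)) {
    stop("duplicate symmetry-unique reflection(s): ",
         paste(unique(key[duplicated(key)])[1:min(3, sum(duplicated(key)))],
               collapse = "; "))
  }
  if (any(obs$f_plus < 0) || any(obs$f_minus < 0)) {
    stop("amplitudes must be non-negative")
  }
  if (any(obs$sig_plus <= 0) || any(obs$sig_minus <= 0)) {
    stop("amplitude uncertainties must be positive")
  }
  ci <- centric_info(sg, hkl)
  obs$centric <- ci$centric
  obs$phi0_deg <- ci$phi0_deg
  bad <- obs$centric & (obs$f_plus != obs$f_minus |
                          obs$sig_plus != obs$sig_minus)
  if (any(bad)) {
    stop(sum(bad), " centric reflection(s) with unequal Friedel members")
  }
  obs$d <- d_spacing(cell, hkl)
  if (is.null(obs$free)) obs$free <- FALSE
  d_min <- d_min %||% min(obs$d)
  d_max <- d_max %||% max(obs$d)
  if (any(obs$d < d_min - 1e-6 | obs$d > d_max + 1e-6)) {
    stop("observations outside the stated resolution limits")
  }
  rownames(obs) <- NULL
  structure(list(
    cell = cell, sg = sg, label = label, obs = obs,
    d_min = d_min, d_max = d_max
  ), class = "reflection_set")
}

#' @export
print.reflection_set <- function(x, ...) {
  cat(sprintf(
    "reflection set '%s': %d unique reflections, %.2f-%.2f A, %s, %d centric, %d free\n",
    x$label, nrow(x$obs), x$d_max, x$d_min, x$sg$symbol,
    sum(x$obs$centric), sum(x$obs$free)
  ))
  invisible(x)
}

#' Assign equal-population resolution shells
#'
#' Reflections are ranked from low resolution (large d) to high; ties are
#' broken by lexicographic hkl order.  Shell 1 is the lowest-resolution
#' shell.
#'
#' @param data A [reflection_set] (or its `obs` data frame).
#' @param n_shells Number of shells (>= 1).
#' @return Integer shell index per reflection.
#' @export
assign_shells <- function(data, n_shells) {
  obs <- if (inherits(data, "reflection_set")) data$obs else data
  stopifnot(n_shells >= 1)
  n <- nrow(obs)
  ord <- order(-obs$d, obs$h, obs$k, obs$l)
  shell <- integer(n)
  shell[ord] <- as.integer(ceiling(seq_len(n) / (n / n_shells)))
  pmin(shell, n_shells)
}

#' Bijvoet difference statistics
#'
#' Signed Bijvoet differences `dF = |F+| - |F-|`, their merged uncertainties
#' `sigma_dF = sqrt(sigma+^2 + sigma-^2)`, and the Bijvoet ratio
#' `<|dF|>/<|F|>` (with `|F| = (|F+|+|F-|)/2`) per equal-population
#' resolution shell and overall.
#'
#' @param data A [reflection_set].
#' @param n_shells Number of equal-population shells (>= 1).
#' @return A list of class `bijvoet_stats`: per-reflection data frame
#'   (`delta_f`, `sig_delta_f`, `shell`), a per-shell table and the overall
#'   ratio.
#' @export
compute_bijvoet_stats <- function(data, n_shells) {
  stopifnot(inherits(data, "reflection_set"), n_shells >= 1)
  obs <- data$obs
  if (nrow(obs) == 0) stop("empty reflection set")
  delta_f <- obs$f_plus - obs$f_minus
  delta_f[obs$centric] <- 0
  sig_delta_f <- sqrt(obs$sig_plus^2 + obs$sig_minus^2)
  fbar <- (obs$f_plus + obs$f_minus) / 2
  shell <- assign_shells(data, n_shells)
  per_shell <- do.call(rbind, lapply(seq_len(n_shells), function(s) {
    i <- shell == s
    data.frame(
      shell = s, n = sum(i),
      d_max = max(obs$d[i]), d_min = min(obs$d[i]),
      bijvoet_ratio = if (sum(fbar[i]) > 0) {
        mean(abs(delta_f[i])) / mean(fbar[i])
      } else 0
    )
  }))
  overall <- if (sum(fbar) > 0) mean(abs(delta_f)) / mean(fbar) else 0
  structure(list(
    per_reflection = data.frame(
      h = obs$h, k = obs$k, l = obs$l, d = obs$d, centric = obs$centric,
      delta_f = delta_f, sig_delta_f = sig_delta_f, shell = shell
    ),
    per_shell = per_shell,
    overall_bijvoet_ratio = overall
  ), class = "bijvoet_stats")
}

#' Flag a stratified cross-validation (free) set
#'
#' Flags `round(fraction * N)` reflections as free, spread across
#' equal-population resolution shells (per-shell counts within one of
#' `fraction` times the shell size, largest-remainder apportionment), with a
#' reproducible selection from `seed`.
#'
#' @param data A [reflection_set].
#' @param fraction Fraction of reflections to flag, in (0, 0.5).
#' @param seed Integer seed.
#' @param n_shells Shells used for stratification.
#' @return The reflection set with its `free` column replaced.
#' @export
flag_free_set <- function(data, fraction, seed, n_shells = 10) {
  stopifnot(inherits(data, "reflection_set"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 0.5) {
    stop("fraction must lie strictly between 0 and 0.5")
  }
  obs <- data$obs
  n <- nrow(obs)
  n_shells <- min(n_shells, n)
  shell <- assign_shells(data, n_shells)
  total <- round(fraction * n)
  sizes <- tabulate(shell, n_shells)
  quota <- fraction * sizes
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  } else if (rem < 0) {
    drop <- order(quota - base)[seq_len(-rem)]
    base[drop] <- pmax(0, base[drop] - 1)
  }
  free <- rep(FALSE, n)
  set.seed(seed)
  for (s in seq_len(n_shells)) {
    idx <- which(shell == s)
    if (base[s] > 0 && length(idx) > 0) {
      free[sample(idx, min(base[s], length(idx)))] <- TRUE
    }
  }
  data$obs$free <- free
  data
}
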