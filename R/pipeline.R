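# Pipeline driver: orchestrates |FA| estimation, substructure detection
# (with early termination and the completeness check), substructure
# phasing, density modification with cross-validated error estimation,
# and hand determination, from a single validated configuration with one
# root seed.  Per-experiment defaults follow standard practice for this
# kind of pipeline: SAD uses the multivariate |FA| estimate and the
# multivariate (correlation-aware) phase combination; SIRAS chooses the
# stronger of the anomalous and isomorphous signals and combines with
# MLHL; MAD selects the wavelength with the greatest anomalous signal and
# then follows the SAD path with MLHL combination.

pipeline_steps <- c("fa", "detect", "phase", "dm", "hand")

#' Validate a pipeline configuration
#'
#' @param config A named list (or a YAML file path): `experiment` (either
#'   a synthetic specification or input file paths), `heavy` (element,
#'   expected count, f', f''), `steps` (a contiguous slice of
#'   fa-detect-phase-dm-hand), `seed`, optional `params` with per-step
#'   overrides, optional `output_dir`, `free_fraction`, `substructure`
#'   (PDB path, for slices starting at `phase`).
#' @return The validated configuration with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("experiment", "heavy", "steps", "seed", "params",
             "output_dir", "free_fraction", "substructure", "name")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  config$steps <- config$steps %||% pipeline_steps
  bad <- setdiff(config$steps, pipeline_steps)
  if (length(bad)) stop("unknown step name(s): ", paste(bad, collapse = ", "))
  idx <- match(config$steps, pipeline_steps)
  if (any(diff(idx) != 1)) {
    stop("steps must be a contiguous slice of ",
         paste(pipeline_steps, collapse = " -> "))
  }
  config$seed <- as.integer(config$seed %||% 1)
  config$free_fraction <- config$free_fraction %||% 0.05
  config$params <- config$params %||% list()
  if (is.null(config$experiment)) stop("config needs an 'experiment' block")
  config$experiment$kind <- toupper(config$experiment$kind %||% "SAD")
  config
}

config_datasets <- function(config) {
  ex <- config$experiment
  if (isTRUE(ex$synthetic)) {
    hv <- config$heavy %||% list(element = "SE", count = 2,
                                 f_prime = -8, f_dprime = 4)
    cellv <- unlist(ex$cell %||% c(34, 42, 38, 90, 90, 90))
    cell <- unit_cell(cellv[1], cellv[2], cellv[3], cellv[4], cellv[5],
                      cellv[6])
    sg <- space_group(ex$spacegroup %||% "P21")
    struct <- generate_structure(
      derive_seed(config$seed, "structure"), cell, sg,
      n_light = ex$n_light %||% 150,
      heavy_spec = data.frame(element = hv$element, count = hv$count,
                              f_prime = hv$f_prime, f_dprime = hv$f_dprime)
    )
    channels <- if (!is.null(ex$channels)) {
      do.call(rbind, lapply(ex$channels, as.data.frame))
    } else {
      data.frame(label = "peak", f_prime = hv$f_prime,
                 f_dprime = hv$f_dprime)
    }
    spec <- experiment_spec(ex$kind, channels, d_min = ex$d_min %||% 2.2,
                            noise_frac = ex$noise_frac %||% 0.05,
                            seed = derive_seed(config$seed, "noise"))
    sim <- simulate_dataset(struct, spec)
    list(datasets = sim$datasets, truth = sim$truth, structure = struct)
  } else {
    if (is.null(ex$reflections)) {
      stop("non-synthetic experiment needs 'reflections' file path(s)")
    }
    dialect <- ex$dialect %||% "tsv"
    sets <- if (dialect == "tsv") {
      ds <- read_reflections(ex$reflections, "tsv")
      stats::setNames(list(ds), ds$label)
    } else {
      read_reflections(ex$reflections, "mmcif_sf")
    }
    list(datasets = sets, truth = NULL, structure = NULL)
  }
}

#' Run the phasing pipeline
#'
#' Executes the configured step slice with early-termination and
#' completeness gating at the detection stage.  All randomness derives
#' from the root seed via named per-step seeds, so a report is
#' reproducible bit for bit from (inputs, config, seed).
#'
#' @param config Configuration list or YAML path (see [validate_config]).
#' @return A `run_report`: per-step records, chosen channel, truth metrics
#'   for synthetic runs, and the final phase set.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  inp <- config_datasets(config)
  kind <- config$experiment$kind
  report <- list(config = config, kind = kind, steps = list(),
                 synthetic = !is.null(inp$truth))
  anom_sets <- inp$datasets[names(inp$datasets) != "native"]
  native <- inp$datasets[["native"]]
  # channel choice (MAD: greatest anomalous signal; SIRAS: anomalous vs
  # isomorphous; SAD: the single channel)
  channel <- if (kind == "MAD") {
    select_best_channel(anom_sets)
  } else names(anom_sets)[1]
  data <- anom_sets[[channel]]
  siras_iso <- FALSE
  if (kind == "SIRAS" && !is.null(native)) {
    siras_iso <- isomorphous_signal_score(data, native) >
      anomalous_signal_score(data)
  }
  report$channel <- channel
  report$siras_uses_isomorphous <- siras_iso
  data <- flag_free_set(data, config$free_fraction,
                        derive_seed(config$seed, "free"))
  p <- function(step, key, default) {
    config$params[[step]][[key]] %||% default
  }
  sub <- NULL
  em <- NULL
  phases <- NULL
  truth <- inp$truth
  steps <- config$steps
  failed <- FALSE
  if ("fa" %in% steps) {
    fa <- if (kind == "SIRAS" && siras_iso) {
      estimate_fa_isomorphous(data, native)
    } else {
      estimate_fa_multivariate(
        data, heavy_fraction = p("fa", "heavy_fraction", 0.05),
        kappa = p("fa", "kappa", 0.25)
      )
    }
    report$steps$fa <- list(
      status = "ok", method = fa$method,
      signal = anomalous_signal_by_shell(data, 10)
    )
  } else {
    fa <- estimate_fa_multivariate(data)
  }
  if ("detect" %in% steps && !failed) {
    hv <- config$heavy %||% list(count = 2)
    trials <- search_substructure(
      fa, data$cell, data$sg,
      n_sites_expected = p("detect", "n_sites", hv$count %||% 2),
      n_trials = p("detect", "n_trials", 8),
      seed = derive_seed(config$seed, "detect"),
      early_stop = list(
        score_threshold = p("detect", "score_threshold", 0.65),
        deviation_threshold = p("detect", "deviation_threshold", 0.2),
        min_trials = p("detect", "min_trials", 5)
      )
    )
    best <- trials[[1]]
    if (best$score < p("detect", "score_floor", 0.1)) {
      report$steps$detect <- list(status = "failed",
                                  best_score = best$score,
                                  n_trials = length(trials))
      failed <- TRUE
    } else {
      sub <- best$sites
      chk <- check_substructure_complete(data, sub,
                                         p("detect", "luzzati_threshold",
                                           0.7))
      report$steps$detect <- list(
        status = "ok", best_score = best$score, n_trials = length(trials),
        check = chk$status, avg_luzzati = chk$avg_luzzati,
        sites = sub$sites[, c("x", "y", "z", "occ", "b")]
      )
    }
  } else if (!is.null(config$substructure)) {
    sub <- read_sites_pdb(config$substructure)$sub
  } else if (!("detect" %in% steps) && !is.null(inp$structure)) {
    sub <- inp$structure$heavy
  }
  if ("phase" %in% steps && !failed) {
    if (is.null(sub)) stop("phase step needs a substructure ",
                           "(run detect or supply one)")
    em <- refine_error_model(data, sub)
    if (isTRUE(p("phase", "refine_sites", TRUE))) {
      sub <- refine_sites(data, sub, em,
                          max_reflections = p("phase", "max_reflections",
                                              1500),
                          maxit = p("phase", "maxit", 16))
      em <- refine_error_model(data, sub)
    }
    phases <- if (kind == "SIRAS" && !is.null(native)) {
      phase_substructure_siras(data, native, sub, em)
    } else {
      phase_substructure_sad(data, sub, em)
    }
    rec <- list(status = "ok", avg_luzzati = em$avg_luzzati,
                mean_fom = mean(phases$table$fom))
    if (!is.null(truth)) {
      q <- phase_quality_vs_truth(phases, truth, align_origin = TRUE)
      rec$mean_cos_err <- q$mean_cos_err
      rec$fom_weighted_err_deg <- q$fom_weighted_err_deg
      rec$map_cc <- q$map_cc
    }
    report$steps$phase <- rec
  }
  if ("dm" %in% steps && !failed) {
    if (is.null(phases)) stop("dm step needs phases (run phase first)")
    mode <- p("dm", "mode", if (kind == "SAD") "multivariate" else "mlhl")
    dmres <- run_dm_cycles(
      data, sub, phases, n_cycles = p("dm", "n_cycles", 3), mode = mode,
      solvent_fraction = p("dm", "solvent_fraction", 0.70), em = em,
      truth = truth
    )
    phases <- dmres$phases
    em <- dmres$em
    report$steps$dm <- list(status = "ok", mode = mode,
                            log = dmres$log,
                            mean_fom = mean(phases$table$fom))
  }
  if ("hand" %in% steps && !failed) {
    if (is.null(sub) || is.null(em)) stop("hand step needs a phased ",
                                          "substructure")
    hd <- determine_hand(data, sub, em,
                         n_cycles = p("hand", "n_cycles", 2))
    report$steps$hand <- list(status = "ok", decision = hd$decision,
                              delta_loglik = hd$delta_loglik,
                              noise_floor = hd$noise_floor)
    if (hd$decision == "inverted") {
      sub <- hd$sub
      phases <- hd$phases
    }
  }
  report$status <- if (failed) "failed" else "ok"
  if (!is.null(truth) && !is.null(phases)) {
    q <- phase_quality_vs_truth(phases, truth, align_origin = TRUE)
    report$truth_metrics <- list(mean_cos_err = q$mean_cos_err,
                                 fom_weighted_err_deg = q$fom_weighted_err_deg,
                                 map_cc = q$map_cc)
  }
  report$phases <- phases
  report$substructure <- sub
  report$data <- data
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("pipeline run (%s): status %s, steps: %s\n", x$kind,
              x$status, paste(names(x$steps), collapse = ", ")))
  if (!is.null(x$truth_metrics)) {
    cat(sprintf("  truth: mean cos phase err %.3f, FOM-weighted err %.1f deg\n",
                x$truth_metrics$mean_cos_err,
                x$truth_metrics$fom_weighted_err_deg))
  }
  invisible(x)
}

#' Emit a machine-readable report plus summary tables
#'
#' Writes `report.json` (the full per-step record), `summary.tsv` (one
#' key-value row per headline statistic), `fom_cycles.tsv` (the per-cycle
#' FOM curve, when the dm step ran) and `signal_by_shell.tsv` (the
#' Bijvoet-ratio table, when the fa step ran).  Output is deterministic:
#' a rerun with identical inputs and seed produces byte-identical files.
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
emit_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  strip <- report
  strip$phases <- NULL; strip$data <- NULL
  strip$substructure <- if (!is.null(report$substructure)) {
    report$substructure$sites[, c("element", "x", "y", "z", "occ", "b")]
  }
  js <- file.path(dir, "report.json")
  jsonlite::write_json(strip, js, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, force = TRUE)
  paths <- c(paths, js)
  kv <- list(status = report$status, kind = report$kind,
             channel = report$channel)
  for (nm in names(report$steps)) {
    st <- report$steps[[nm]]
    for (f in setdiff(names(st), c("log", "signal", "sites"))) {
      if (is.atomic(st[[f]]) && length(st[[f]]) == 1) {
        kv[[paste(nm, f, sep = ".")]] <- st[[f]]
      }
    }
  }
  if (!is.null(report$truth_metrics)) {
    for (f in names(report$truth_metrics)) {
      kv[[paste("truth", f, sep = ".")]] <- report$truth_metrics[[f]]
    }
  }
  sm <- file.path(dir, "summary.tsv")
  utils::write.table(
    data.frame(key = names(kv),
               value = vapply(kv, function(v) format(v, digits = 10),
                              character(1))),
    sm, sep = "\t", quote = FALSE, row.names = FALSE
  )
  paths <- c(paths, sm)
  if (!is.null(report$steps$dm$log)) {
    fc <- file.path(dir, "fom_cycles.tsv")
    utils::write.table(format(report$steps$dm$log, digits = 10), fc,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, fc)
  }
  if (!is.null(report$steps$fa$signal)) {
    sg <- file.path(dir, "signal_by_shell.tsv")
    utils::write.table(format(report$steps$fa$signal, digits = 10), sg,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, sg)
  }
  if (!is.null(report$phases)) {
    pp <- file.path(dir, "phases.tsv")
    write_phases(report$phases, pp, "tsv")
    paths <- c(paths, pp)
  }
  if (!is.null(report$substructure) && !is.null(report$data)) {
    sp <- file.path(dir, "sites.pdb")
    write_sites_pdb(report$substructure, report$data$cell,
                    report$data$sg, sp)
    paths <- c(paths, sp)
  }
  invisible(paths)
}

#' Read back an emitted report
#' @param dir Report directory.
#' @return The parsed `report.json` as a list.
#' @export
read_report <- function(dir) {
  jsonlite::read_json(file.path(dir, "report.json"), simplifyVector = TRUE)
}
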