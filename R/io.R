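# Readers and writers: reflection data (documented TSV dialect and a
# minimal mmCIF structure-factor dialect), substructure sites as PDB
# HETATM records, phase distributions (TSV / mmCIF with HL columns),
# |FA| tables, and CCP4/MRC maps.  All text writers emit a provenance
# comment block; amplitudes round-trip at six decimal places.

fmt6 <- function(x) sprintf("%.6f", x)

provenance_lines <- function(prefix = "#") {
  paste0(prefix, " written by phasekit ",
         as.character(utils::packageVersion("phasekit")))
}

#' Write a reflection set
#'
#' Dialects: `"tsv"` - header `h k l f_plus sig_plus f_minus sig_minus
#' free`, whitespace-separated, `#` comments carrying the cell, symmetry,
#' label and resolution limits; `"mmcif_sf"` - one `data_<label>` block
#' with `_cell`, `_symmetry` and a `_refln` loop holding the
#' Friedel-separated amplitude columns and the free-set status column
#' (`f` = free, `o` = work).
#'
#' @param data A [reflection_set] (or a list of them for multi-block
#'   mmCIF output).
#' @param path Output file.
#' @param dialect `"tsv"` or `"mmcif_sf"`.
#' @export
write_reflections <- function(data, path, dialect = c("tsv", "mmcif_sf")) {
  dialect <- match.arg(dialect)
  sets <- if (inherits(data, "reflection_set")) list(data) else data
  if (dialect == "tsv") {
    if (length(sets) != 1) stop("the TSV dialect holds a single set")
    d <- sets[[1]]
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      provenance_lines(),
      sprintf("# cell %s %s %s %s %s %s", fmt6(d$cell$a), fmt6(d$cell$b),
              fmt6(d$cell$c), fmt6(d$cell$alpha), fmt6(d$cell$beta),
              fmt6(d$cell$gamma)),
      sprintf("# spacegroup %s", d$sg$symbol),
      sprintf("# label %s", d$label),
      sprintf("# resolution %s %s", fmt6(d$d_min), fmt6(d$d_max)),
      "h k l f_plus sig_plus f_minus sig_minus free"
    ), con)
    o <- d$obs
    if (nrow(o)) {
      writeLines(paste(o$h, o$k, o$l, fmt6(o$f_plus), fmt6(o$sig_plus),
                       fmt6(o$f_minus), fmt6(o$sig_minus),
                       as.integer(o$free)), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(provenance_lines(), con)
    for (d in sets) {
      writeLines(c(
        sprintf("data_%s", gsub("[^A-Za-z0-9_]", "_", d$label)),
        sprintf("_cell.length_a    %s", fmt6(d$cell$a)),
        sprintf("_cell.length_b    %s", fmt6(d$cell$b)),
        sprintf("_cell.length_c    %s", fmt6(d$cell$c)),
        sprintf("_cell.angle_alpha %s", fmt6(d$cell$alpha)),
        sprintf("_cell.angle_beta  %s", fmt6(d$cell$beta)),
        sprintf("_cell.angle_gamma %s", fmt6(d$cell$gamma)),
        sprintf("_symmetry.space_group_name_H-M '%s'", d$sg$symbol),
        "loop_",
        "_refln.index_h",
        "_refln.index_k",
        "_refln.index_l",
        "_refln.pdbx_F_plus",
        "_refln.pdbx_F_plus_sigma",
        "_refln.pdbx_F_minus",
        "_refln.pdbx_F_minus_sigma",
        "_refln.status"
      ), con)
      o <- d$obs
      if (nrow(o)) {
        writeLines(paste(o$h, o$k, o$l, fmt6(o$f_plus), fmt6(o$sig_plus),
                         fmt6(o$f_minus), fmt6(o$sig_minus),
                         ifelse(o$free, "f", "o")), con)
      }
    }
  }
  invisible(path)
}

parse_tsv_reflections <- function(lines) {
  com <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  get_com <- function(key) {
    ln <- com[grepl(paste0("^#\\s*", key, "\\b"), com)]
    if (!length(ln)) stop("TSV dialect: missing '# ", key, "' header line")
    strsplit(trimws(sub(paste0("^#\\s*", key), "", ln[1])), "\\s+")[[1]]
  }
  cellv <- as.numeric(get_com("cell"))
  sgv <- get_com("spacegroup")[1]
  lab <- paste(get_com("label"), collapse = " ")
  res <- as.numeric(get_com("resolution"))
  header <- strsplit(trimws(body[1]), "\\s+")[[1]]
  need <- c("h", "k", "l", "f_plus", "sig_plus", "f_minus", "sig_minus")
  miss <- setdiff(need, header)
  if (length(miss)) stop("TSV dialect: missing column(s): ",
                         paste(miss, collapse = ", "))
  rows <- body[-1]
  obs <- if (length(rows)) {
    m <- do.call(rbind, strsplit(trimws(rows), "\\s+"))
    df <- as.data.frame(m, stringsAsFactors = FALSE)
    names(df) <- header[seq_len(ncol(df))]
    for (cn in names(df)) df[[cn]] <- as.numeric(df[[cn]])
    df
  } else {
    df <- as.data.frame(matrix(numeric(0), 0, length(header)))
    names(df) <- header
    df
  }
  if (!is.null(obs$free)) obs$free <- obs$free > 0
  reflection_set(
    unit_cell(cellv[1], cellv[2], cellv[3], cellv[4], cellv[5], cellv[6]),
    space_group(sgv), obs, label = lab, d_min = res[1], d_max = res[2]
  )
}

parse_mmcif_reflections <- function(lines) {
  lines <- lines[!startsWith(lines, "#")]
  starts <- grep("^data_", lines)
  if (!length(starts)) stop("mmCIF: no data block found")
  out <- list()
  bounds <- c(starts, length(lines) + 1)
  for (b in seq_along(starts)) {
    blk <- lines[bounds[b]:(bounds[b + 1] - 1)]
    label <- sub("^data_", "", blk[1])
    getv <- function(tag) {
      ln <- blk[grepl(paste0("^", tag, "\\s"), blk)]
      if (!length(ln)) stop("mmCIF: missing ", tag)
      gsub("'", "", trimws(sub(paste0("^", tag), "", ln[1])))
    }
    cell <- unit_cell(
      as.numeric(getv("_cell.length_a")), as.numeric(getv("_cell.length_b")),
      as.numeric(getv("_cell.length_c")),
      as.numeric(getv("_cell.angle_alpha")),
      as.numeric(getv("_cell.angle_beta")),
      as.numeric(getv("_cell.angle_gamma"))
    )
    sg <- space_group(getv("_symmetry.space_group_name_H-M"))
    loop_at <- grep("^loop_", blk)
    if (!length(loop_at)) stop("mmCIF: no _refln loop in block ", label)
    tags <- character(0)
    i <- loop_at[1] + 1
    while (i <= length(blk) && startsWith(trimws(blk[i]), "_")) {
      tags <- c(tags, trimws(blk[i]))
      i <- i + 1
    }
    need <- c("_refln.index_h", "_refln.index_k", "_refln.index_l",
              "_refln.pdbx_F_plus", "_refln.pdbx_F_plus_sigma",
              "_refln.pdbx_F_minus", "_refln.pdbx_F_minus_sigma")
    miss <- setdiff(need, tags)
    if (length(miss)) stop("mmCIF: missing column(s): ",
                           paste(miss, collapse = ", "))
    rows <- character(0)
    while (i <= length(blk) && nzchar(trimws(blk[i])) &&
             !startsWith(blk[i], "data_") &&
             !startsWith(trimws(blk[i]), "_") &&
             !startsWith(trimws(blk[i]), "loop_")) {
      rows <- c(rows, blk[i]); i <- i + 1
    }
    obs <- if (length(rows)) {
      m <- do.call(rbind, strsplit(trimws(rows), "\\s+"))
      df <- as.data.frame(m, stringsAsFactors = FALSE)
      names(df) <- tags[seq_len(ncol(df))]
      o <- data.frame(
        h = as.numeric(df[["_refln.index_h"]]),
        k = as.numeric(df[["_refln.index_k"]]),
        l = as.numeric(df[["_refln.index_l"]]),
        f_plus = as.numeric(df[["_refln.pdbx_F_plus"]]),
        sig_plus = as.numeric(df[["_refln.pdbx_F_plus_sigma"]]),
        f_minus = as.numeric(df[["_refln.pdbx_F_minus"]]),
        sig_minus = as.numeric(df[["_refln.pdbx_F_minus_sigma"]])
      )
      if ("_refln.status" %in% tags) o$free <- df[["_refln.status"]] == "f"
      o
    } else {
      data.frame(h = numeric(0), k = numeric(0), l = numeric(0),
                 f_plus = numeric(0), sig_plus = numeric(0),
                 f_minus = numeric(0), sig_minus = numeric(0))
    }
    out[[label]] <- reflection_set(cell, sg, obs, label = label)
  }
  out
}

#' Read reflection data
#'
#' @param path Input file.
#' @param dialect `"tsv"` (single set) or `"mmcif_sf"` (one set per
#'   wavelength data block).
#' @return A [reflection_set] for TSV; a named list of them for mmCIF.
#' @export
read_reflections <- function(path, dialect = c("tsv", "mmcif_sf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "tsv") parse_tsv_reflections(lines)
  else parse_mmcif_reflections(lines)
}

#' Write substructure sites as minimal PDB
#'
#' CRYST1 plus HETATM records; occupancy and B columns carry the refined
#' values, fractional coordinates are orthogonalized.
#' @param sub A [substructure].
#' @param cell A [unit_cell].
#' @param sg A [space_group].
#' @param path Output file.
#' @export
write_sites_pdb <- function(sub, cell, sg, path) {
  st <- sub$sites
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("REMARK   3 ", provenance_lines(prefix = "")), con)
  writeLines(sprintf(
    "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s", cell$a, cell$b, cell$c,
    cell$alpha, cell$beta, cell$gamma, sg$symbol
  ), con)
  if (nrow(st)) {
    orth <- t(cell$orth %*% t(as.matrix(st[, c("x", "y", "z")])))
    for (i in seq_len(nrow(st))) {
      writeLines(sprintf(
        "HETATM%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        i, substr(st$element[i], 1, 4), substr(st$element[i], 1, 3), i,
        orth[i, 1], orth[i, 2], orth[i, 3],
        min(st$occ[i], 99.99), min(st$b[i], 999.9), st$element[i]
      ), con)
    }
  }
  writeLines("END", con)
  invisible(path)
}

#' Read substructure sites from a minimal PDB file
#' @param path PDB file with CRYST1 and HETATM records.
#' @param f_prime,f_dprime Anomalous corrections to attach.
#' @return List with `sub` ([substructure]), `cell`, `sg`.
#' @export
read_sites_pdb <- function(path, f_prime = -8, f_dprime = 4) {
  lines <- readLines(path, warn = FALSE)
  cr <- lines[startsWith(lines, "CRYST1")][1]
  if (is.na(cr)) stop("PDB: missing CRYST1 record")
  cell <- unit_cell(
    as.numeric(substr(cr, 7, 15)), as.numeric(substr(cr, 16, 24)),
    as.numeric(substr(cr, 25, 33)), as.numeric(substr(cr, 34, 40)),
    as.numeric(substr(cr, 41, 47)), as.numeric(substr(cr, 48, 54))
  )
  sg <- space_group(trimws(substr(cr, 56, 66)))
  at <- lines[startsWith(lines, "HETATM") | startsWith(lines, "ATOM")]
  if (!length(at)) stop("PDB: no atom records")
  orth <- cbind(as.numeric(substr(at, 31, 38)),
                as.numeric(substr(at, 39, 46)),
                as.numeric(substr(at, 47, 54)))
  frac <- t(solve(cell$orth) %*% t(orth))
  el <- trimws(substr(at, 77, 78))
  el[el == ""] <- trimws(substr(at, 13, 16))[el == ""]
  st <- sites(el, frac[, 1], frac[, 2], frac[, 3],
              occ = pmin(as.numeric(substr(at, 55, 60)), 1),
              b = as.numeric(substr(at, 61, 66)),
              f_prime = f_prime, f_dprime = f_dprime)
  st$occ <- as.numeric(substr(at, 55, 60))
  list(sub = substructure(st), cell = cell, sg = sg)
}

#' Write a phase distribution
#'
#' TSV dialect: `h k l a b c d phi_best fom`; mmCIF dialect: a `_refln`
#' loop with `pdbx_HL_*_iso` coefficient columns, `phase_meas` and `fom`.
#' @param phases A `phase_distribution`.
#' @param path Output file.
#' @param dialect `"tsv"` or `"mmcif"`.
#' @export
write_phases <- function(phases, path, dialect = c("tsv", "mmcif")) {
  dialect <- match.arg(dialect)
  tab <- phases$table
  con <- file(path, "w")
  on.exit(close(con))
  if (dialect == "tsv") {
    writeLines(c(provenance_lines(),
                 "h k l a b c d phi_best fom"), con)
    writeLines(paste(tab$h, tab$k, tab$l, fmt6(tab$hl_a), fmt6(tab$hl_b),
                     fmt6(tab$hl_c), fmt6(tab$hl_d), fmt6(tab$phi_best),
                     fmt6(tab$fom)), con)
  } else {
    writeLines(c(
      provenance_lines(),
      sprintf("data_%s", gsub("[^A-Za-z0-9_]", "_", phases$label)),
      "loop_",
      "_refln.index_h", "_refln.index_k", "_refln.index_l",
      "_refln.pdbx_HL_A_iso", "_refln.pdbx_HL_B_iso",
      "_refln.pdbx_HL_C_iso", "_refln.pdbx_HL_D_iso",
      "_refln.phase_meas", "_refln.fom"
    ), con)
    writeLines(paste(tab$h, tab$k, tab$l, fmt6(tab$hl_a), fmt6(tab$hl_b),
                     fmt6(tab$hl_c), fmt6(tab$hl_d), fmt6(tab$phi_best),
                     fmt6(tab$fom)), con)
  }
  invisible(path)
}

#' Write an |FA| estimate as TSV
#' @param fa An `fa_estimate`.
#' @param path Output file.
#' @export
write_fa_tsv <- function(fa, path) {
  tab <- fa$table
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(provenance_lines(),
               sprintf("# method %s", fa$method),
               "h k l fa sig_fa e_norm"), con)
  writeLines(paste(tab$h, tab$k, tab$l, fmt6(tab$fa), fmt6(tab$sig_fa),
                   fmt6(tab$e_norm)), con)
  invisible(path)
}

#' Write a map in CCP4/MRC format (mode 2, 32-bit float)
#' @param map A `map_grid`.
#' @param path Output file.
#' @export
write_ccp4_map <- function(map, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  dims <- as.integer(map$dims)
  writeBin(dims, con, size = 4)                     # NC NR NS
  writeBin(2L, con, size = 4)                       # MODE
  writeBin(c(0L, 0L, 0L), con, size = 4)            # start
  writeBin(dims, con, size = 4)                     # intervals
  writeBin(as.numeric(c(map$cell$a, map$cell$b, map$cell$c,
                        map$cell$alpha, map$cell$beta, map$cell$gamma)),
           con, size = 4)
  writeBin(c(1L, 2L, 3L), con, size = 4)            # axis order
  v <- as.numeric(map$values)
  writeBin(as.numeric(c(min(v), max(v), mean(v))), con, size = 4)
  writeBin(c(1L, 0L), con, size = 4)                # ISPG, NSYMBT
  writeBin(raw(4 * (256 - 25)), con)                # pad header to 1024
  writeBin(v, con, size = 4)
  invisible(path)
}

#' Read a CCP4/MRC map written by [write_ccp4_map]
#' @param path Map file.
#' @param cell Optional [unit_cell] (reconstructed from the header
#'   otherwise).
#' @export
read_ccp4_map <- function(path, cell = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  dims <- readBin(con, integer(), 3, size = 4)
  mode <- readBin(con, integer(), 1, size = 4)
  if (mode != 2) stop("unsupported map mode: ", mode)
  invisible(readBin(con, integer(), 3, size = 4))
  invisible(readBin(con, integer(), 3, size = 4))
  cp <- readBin(con, numeric(), 6, size = 4)
  invisible(readBin(con, integer(), 3, size = 4))
  invisible(readBin(con, numeric(), 3, size = 4))
  invisible(readBin(con, integer(), 2, size = 4))
  invisible(readBin(con, raw(), 4 * (256 - 25)))
  v <- readBin(con, numeric(), prod(dims), size = 4)
  cell <- cell %||% unit_cell(cp[1], cp[2], cp[3], cp[4], cp[5], cp[6])
  new_map_grid(array(v, dims), cell)
}

#' Write the simulator truth record as TSV
#' @param truth A `truth_record`.
#' @param path Output file.
#' @export
write_truth_tsv <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  ch1 <- truth$channels[[1]]
  writeLines(c(provenance_lines(),
               "h k l phi_p_deg phi_total_deg f_h_re f_h_im f_true_plus f_true_minus"),
             con)
  writeLines(paste(truth$hkl$h, truth$hkl$k, truth$hkl$l,
                   fmt6(truth$phi_p_deg), fmt6(ch1$phi_total_deg),
                   fmt6(Re(ch1$f_h_plus)), fmt6(Im(ch1$f_h_plus)),
                   fmt6(ch1$f_true_plus), fmt6(ch1$f_true_minus)), con)
  invisible(path)
}
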