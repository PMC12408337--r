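## Readers and writers: fixed-width HKLF-4 reflection lists, the
## instruction-file dialect (CELL/LATT/SYMM/SFAC+ION/atom records/NU/SUMP/
## SHEL/L.S./REM), CIF export. All writers are deterministic.

#' Construct a validated reflection list
#'
#' @param h,k,l Integer Miller indices.
#' @param I Observed intensities (arbitrary units).
#' @param sig Standard uncertainties, strictly positive.
#' @return Data frame of class `refl_data` with columns `h k l I sig`.
#' @export
reflection_data <- function(h, k, l, I, sig) {
  if (any(sig <= 0)) stop("sigma(I) must be positive for every reflection",
                          call. = FALSE)
  df <- data.frame(h = as.integer(h), k = as.integer(k), l = as.integer(l),
                   I = as.numeric(I), sig = as.numeric(sig))
  class(df) <- c("refl_data", class(df))
  df
}

#' Read a fixed-width HKLF-4 reflection file
#'
#' Records are `3I4 + 2F8` (h, k, l, I, sigma); the `0 0 0` terminator ends
#' parsing; trailing batch-number columns are ignored (noted in the
#' `"note"` attribute).
#'
#' @param path File path (or a character vector of lines via `text`).
#' @param text Optional literal lines instead of a file.
#' @return A [reflection_data()] data frame.
#' @export
read_hkl <- function(path, text = NULL) {
  lines <- if (is.null(text)) readLines(path) else text
  rows <- list()
  note <- NULL
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(trimws(line))) next
    if (nchar(line) < 28)
      stop("HKLF-4 width violation at line ", ln, " (need 3I4 + 2F8 = 28 columns)",
           call. = FALSE)
    fields <- c(substr(line, 1, 4), substr(line, 5, 8), substr(line, 9, 12),
                substr(line, 13, 20), substr(line, 21, 28))
    v <- suppressWarnings(as.numeric(fields))
    if (anyNA(v)) stop("HKLF-4 parse error at line ", ln, call. = FALSE)
    if (all(v[1:3] == 0)) break  # terminator
    if (nchar(line) > 28 && nzchar(trimws(substr(line, 29, nchar(line)))))
      note <- "trailing batch columns ignored"
    rows[[length(rows) + 1L]] <- v
  }
  m <- do.call(rbind, rows)
  if (is.null(m)) stop("no reflections found", call. = FALSE)
  out <- reflection_data(m[, 1], m[, 2], m[, 3], m[, 4], m[, 5])
  attr(out, "note") <- note
  out
}

#' Write a fixed-width HKLF-4 reflection file
#'
#' @param refl A [reflection_data()] data frame.
#' @param path Output file.
#' @param terminator Append the `0 0 0` end record (default `TRUE`).
#' @return Invisibly, `path`.
#' @export
write_hkl <- function(refl, path, terminator = TRUE) {
  lines <- sprintf("%4d%4d%4d%8.2f%8.2f", refl$h, refl$k, refl$l, refl$I, refl$sig)
  if (terminator) lines <- c(lines, sprintf("%4d%4d%4d%8.2f%8.2f", 0L, 0L, 0L, 0, 0))
  writeLines(lines, path)
  invisible(path)
}

## ------------------------- instruction files ------------------------------

.parse_sfac_card <- function(tokens, ln) {
  if (length(tokens) < 10L)
    stop("SFAC card needs a label and 9 coefficients (line ", ln, ")", call. = FALSE)
  vals <- suppressWarnings(as.numeric(tokens[2:10]))
  if (anyNA(vals)) stop("bad SFAC coefficients at line ", ln, call. = FALSE)
  list(label = tokens[1],
       cm = cromer_mann(vals[c(1, 3, 5, 7)], vals[c(2, 4, 6, 8)], vals[9]))
}

#' Read an instruction-file document
#'
#' Honoured records: `CELL` (wavelength + 6 cell values), `LATT`, `SYMM`,
#' `SFAC` (label + 9 Cromer--Mann coefficients + optional physical columns),
#' `ION` (label, element, dZ: ties an SFAC card to its ion identity), atom
#' records (label, sfac index, x, y, z, occupancy, U_iso or U11..U12), `NU`
#' (label, initial ionic fraction, optional `FIX`), `SUMP` (target, sigma,
#' coefficient/slot pairs; slot m refers to atom m-1 in file order, slot 1
#' being the overall scale), `SHEL` (d_max d_min), `L.S.` (cycles), `REM`
#' passthrough (including the `REM OVERRIDEF000` value), `HKLF`, `END`.
#'
#' @param path File path (or literal lines via `text`).
#' @param text Optional character vector of lines.
#' @return List with `model` ([crystal_model()]), `config`
#'   ([refine_config()]), `sfac_cards`, `rem` (passthrough lines), `f000`
#'   (from `REM OVERRIDEF000`, else `NULL`), `title`.
#' @export
read_instruction <- function(path, text = NULL) {
  lines <- if (is.null(text)) readLines(path) else text
  cell <- NULL; latt <- -1L; symm <- character()
  sfac_cards <- list(); ions <- list(); atoms <- list()
  nu_records <- list(); sump <- NULL
  rem <- character(); f000 <- NULL; title <- NULL
  dmin <- NULL; dmax <- NULL; cycles <- NULL
  for (ln in seq_along(lines)) {
    raw <- trimws(lines[ln])
    if (!nzchar(raw)) next
    tokens <- strsplit(raw, "\\s+")[[1]]
    key <- toupper(tokens[1])
    rest <- tokens[-1]
    if (key == "TITL") { title <- paste(rest, collapse = " "); next }
    if (key == "CELL") {
      v <- as.numeric(rest)
      if (length(v) < 7L || anyNA(v)) stop("bad CELL record at line ", ln, call. = FALSE)
      cell <- unit_cell(v[2], v[3], v[4], v[5], v[6], v[7])
      next
    }
    if (key == "LATT") { latt <- as.integer(rest[1]); next }
    if (key == "SYMM") { symm <- c(symm, paste(rest, collapse = " ")); next }
    if (key == "SFAC") {
      card <- .parse_sfac_card(rest, ln)
      sfac_cards[[length(sfac_cards) + 1L]] <- card
      next
    }
    if (key == "ION") {
      if (length(rest) < 3L) stop("ION record needs label element dZ (line ", ln, ")",
                                  call. = FALSE)
      ions[[rest[1]]] <- ion_spec(rest[2], as.integer(rest[3]))
      next
    }
    if (key == "NU") {
      nu_records[[rest[1]]] <- list(value = as.numeric(rest[2]),
                                    fixed = length(rest) > 2L &&
                                      toupper(rest[3]) %in% c("FIX", "FIXED"))
      next
    }
    if (key == "SUMP") {
      v <- as.numeric(gsub("\\.$", "", rest))
      if (length(v) < 4L || length(v) %% 2L != 0L || anyNA(v))
        stop("bad SUMP record at line ", ln, call. = FALSE)
      sump <- list(target = v[1], sigma = v[2],
                   coefficients = v[seq(3, length(v), 2)],
                   slots = as.integer(v[seq(4, length(v), 2)]))
      next
    }
    if (key == "SHEL") { dmax <- as.numeric(rest[1]); dmin <- as.numeric(rest[2]); next }
    if (key %in% c("L.S.", "LS")) { cycles <- as.integer(rest[1]); next }
    if (key == "REM") {
      rem <- c(rem, paste(rest, collapse = " "))
      if (length(rest) >= 2L && toupper(rest[1]) == "OVERRIDEF000")
        f000 <- as.numeric(rest[2])
      next
    }
    if (key %in% c("HKLF", "END", "UNIT", "ZERR", "FVAR", "WGHT")) next
    ## anything else with numeric fields 2..6 is an atom record
    if (length(tokens) >= 6L) {
      v <- suppressWarnings(as.numeric(tokens[2:length(tokens)]))
      if (!anyNA(v[1:5])) {
        xyz <- v[2:4]
        ## SHELX convention: a parameter shifted by +10 is held fixed
        fixed <- xyz > 5
        xyz[fixed] <- xyz[fixed] - 10
        atoms[[length(atoms) + 1L]] <- list(label = tokens[1],
                                            sfac_idx = as.integer(v[1]),
                                            xyz = xyz,
                                            xyz_fixed = all(fixed),
                                            occ = v[5],
                                            u = if (length(v) >= 11L) v[6:11]
                                                else if (length(v) >= 6L) v[6]
                                                else 0.02,
                                            line = ln)
        next
      }
    }
    rem <- c(rem, paste("(unparsed)", raw))
  }
  if (is.null(cell)) stop("missing mandatory CELL record", call. = FALSE)
  if (length(sfac_cards) == 0L) stop("missing mandatory SFAC record", call. = FALSE)
  if (length(atoms) == 0L) stop("no atom records found", call. = FALSE)

  sfac_labels <- vapply(sfac_cards, function(c) c$label, "")
  sites <- list()
  for (at in atoms) {
    if (at$sfac_idx < 1L || at$sfac_idx > length(sfac_cards))
      stop("atom ", at$label, " references dangling sfac index ", at$sfac_idx,
           " (line ", at$line, ")", call. = FALSE)
    lab <- sfac_labels[at$sfac_idx]
    ion <- ions[[lab]]
    if (is.null(ion)) {
      ## fall back: interpret the card label itself ("C", "O-1", "Si+4")
      m <- regmatches(lab, regexec("^([A-Za-z]+)([+-][0-9]+)?$", lab))[[1]]
      if (length(m) == 0L || !nzchar(m[2]))
        stop("no ION record for SFAC label '", lab, "'", call. = FALSE)
      ion <- ion_spec(m[2], if (nzchar(m[3])) as.integer(m[3]) else 0L)
    }
    nu_rec <- nu_records[[at$label]]
    sites[[length(sites) + 1L]] <- atom_site(
      at$label, ion, at$xyz, u = at$u, occ = min(at$occ, 1),
      nu = if (is.null(nu_rec)) 0 else nu_rec$value,
      nu_fixed = if (is.null(nu_rec)) FALSE else nu_rec$fixed,
      xyz_fixed = isTRUE(at$xyz_fixed))
  }
  model <- crystal_model(cell, symmetry_ops(symm, latt), sites,
                         latt = latt, symm = symm)
  if (!is.null(sump)) {
    n_at <- length(sites)
    if (any(sump$slots < 2L | sump$slots > n_at + 1L))
      stop("SUMP references a nu slot outside 2..", n_at + 1L, call. = FALSE)
  }
  config <- refine_config(
    max_cycles = if (is.null(cycles)) 200L else max(cycles, 1L),
    sump = if (is.null(sump)) NULL else list(target = sump$target, sigma = sump$sigma),
    d_min = dmin, d_max = dmax)
  list(model = model, config = config, sfac_cards = sfac_cards,
       sump = sump, rem = rem, f000 = f000, title = title)
}

#' Write a model (and settings) as an instruction-file document
#'
#' @param model A [crystal_model()].
#' @param config Optional [refine_config()] for SHEL/L.S./SUMP records.
#' @param path Output file; when `NULL` the lines are returned.
#' @param sfac Optional [build_sfac_table()]; built (fitted) when `NULL`.
#' @param f000 Optional value written as `REM OVERRIDEF000`.
#' @param rem Additional passthrough remarks.
#' @param title TITL line content.
#' @return The lines, invisibly when written to `path`.
#' @export
write_instruction <- function(model, config = NULL, path = NULL, sfac = NULL,
                              f000 = NULL, rem = character(), title = "isfac model") {
  if (is.null(sfac)) sfac <- build_sfac_table(model)
  lines <- c(paste("TITL", title),
             sprintf("CELL 0.0251 %.4f %.4f %.4f %.3f %.3f %.3f",
                     model$cell$a, model$cell$b, model$cell$c,
                     model$cell$alpha, model$cell$beta, model$cell$gamma),
             sprintf("LATT %d", model$latt))
  for (s in model$symm) lines <- c(lines, paste("SYMM", toupper(s)))
  ## one card per species actually used, in stable order
  species <- character()
  for (site in model$sites) {
    key <- if (site$is_hydrogen) "H+1" else species_label(site$ion)
    if (!key %in% species) species <- c(species, key)
  }
  for (key in species) {
    entry <- sfac[[key]]
    if (is.null(entry)) stop("sfac table lacks species ", key, call. = FALSE)
    cm <- if (is.null(entry$cm)) fit_cromer_mann(entry$ion)$cm else entry$cm
    lines <- c(lines, export_sfac_card(key, cm),
               sprintf("ION %s %s %d", key, entry$ion$element, entry$ion$dZ))
  }
  if (!is.null(f000)) lines <- c(lines, sprintf("REM OVERRIDEF000 %.4f", f000))
  for (r in rem) lines <- c(lines, paste("REM", r))
  if (!is.null(config)) {
    if (!is.null(config$d_min))
      lines <- c(lines, sprintf("SHEL %.4f %.4f",
                                if (is.null(config$d_max)) 999 else config$d_max,
                                config$d_min))
    lines <- c(lines, sprintf("L.S. %d", config$max_cycles))
    if (!is.null(config$sump)) {
      free <- which(!vapply(model$sites, function(s) s$nu_fixed, TRUE))
      pairs <- unlist(lapply(free, function(j)
        c(sprintf("%d", model$sites[[j]]$ion$dZ), sprintf("%d", j + 1L))))
      lines <- c(lines, paste("SUMP", config$sump$target, config$sump$sigma,
                              paste(pairs, collapse = " ")))
    }
  }
  for (site in model$sites) {
    key <- if (site$is_hydrogen) "H+1" else species_label(site$ion)
    idx <- match(key, species)
    ustr <- paste(sprintf("%.6f", site$u), collapse = " ")
    xyz_out <- site$xyz + if (site$xyz_fixed) 10 else 0
    lines <- c(lines, sprintf("%s %d %.6f %.6f %.6f %.4f %s",
                              site$label, idx, xyz_out[1], xyz_out[2],
                              xyz_out[3], site$occ, ustr))
    lines <- c(lines, sprintf("NU %s %.6f%s", site$label, site$nu,
                              if (site$nu_fixed) " FIX" else ""))
  }
  lines <- c(lines, "HKLF 4", "END")
  if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
  lines
}

#' Write the refined model and charges as CIF text
#'
#' Standard cell/symmetry/atom-site items plus a custom loop carrying the
#' ionic-fraction results (label, dZ, nu, dq, esu).
#'
#' @param model A refined [crystal_model()].
#' @param result Optional [refine()] result for charges and statistics.
#' @param path Output file; when `NULL` lines are returned.
#' @param data_name CIF data block name.
#' @return The lines, invisibly when written.
#' @export
write_cif <- function(model, result = NULL, path = NULL, data_name = "isfac") {
  cl <- model$cell
  lines <- c(paste0("data_", data_name),
             sprintf("_cell_length_a    %.4f", cl$a),
             sprintf("_cell_length_b    %.4f", cl$b),
             sprintf("_cell_length_c    %.4f", cl$c),
             sprintf("_cell_angle_alpha %.4f", cl$alpha),
             sprintf("_cell_angle_beta  %.4f", cl$beta),
             sprintf("_cell_angle_gamma %.4f", cl$gamma),
             sprintf("_cell_volume      %.4f", cl$volume),
             "loop_", "_space_group_symop_operation_xyz")
  for (op in model$ops)
    lines <- c(lines, paste0("  '", symop_to_string(op), "'"))
  lines <- c(lines, "loop_", "_atom_site_label", "_atom_site_type_symbol",
             "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
             "_atom_site_occupancy", "_atom_site_U_iso_or_equiv")
  for (s in model$sites) {
    ueq <- if (length(s$u) == 1L) s$u else mean(s$u[1:3])
    lines <- c(lines, sprintf("  %s %s %.6f %.6f %.6f %.4f %.6f",
                              s$label, s$ion$element, s$xyz[1], s$xyz[2],
                              s$xyz[3], s$occ, ueq))
  }
  if (!is.null(result)) {
    ch <- extract_charges(result, force = TRUE)
    lines <- c(lines,
               sprintf("_refine_ls_R_factor_all      %.4f", result$R1),
               sprintf("_refine_ls_wR_factor_ref     %.4f", result$wR2),
               "loop_", "_isfac_atom_label", "_isfac_charge_offset_dZ",
               "_isfac_ionic_fraction_nu", "_isfac_partial_charge",
               "_isfac_partial_charge_esu")
    for (i in seq_len(nrow(ch)))
      lines <- c(lines, sprintf("  %s %d %.6f %.6f %.6f", ch$label[i],
                                ch$dZ[i], ch$nu[i], ch$dq[i], ch$esu[i]))
  }
  if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
  lines
}
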