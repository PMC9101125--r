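#' Read a molecular template from a mol2 file
#'
#' SYBYL mol2 is the package's template format: it carries atom names,
#' types, partial charges, coordinates and bonds in one file.  Atom types
#' are taken verbatim from the atom-type column.  The furanose ring is
#' auto-detected as the unique 5-cycle containing exactly one oxygen
#' (override with `ring`).
#'
#' @param path file path.
#' @param ring optional explicit ring-atom indices (C1', C2', C3', C4',
#'   O4' order).
#' @param id template id; defaults to the molecule name in the file.
#' @return A `molecular_template`.
#' @export
read_template <- function(path, ring = NULL, id = NULL) {
  if (!file.exists(path)) ff_stop(paste("no such file:", path), "parse_error")
  m <- tryCatch(bio3d::read.mol2(path),
                error = function(e) ff_stop(
                  paste("mol2 parse failure:", conditionMessage(e)),
                  "parse_error"))
  at <- m$atom
  element <- toupper(sub("[^A-Za-z].*$", "", at$elety))
  element <- substr(element, 1, 1)
  # SYBYL types like C.3/O.3 keep their element; GAFF types are lowercase
  element <- toupper(substr(sub("\\..*$", "", at$elety), 1, 1))
  atoms <- data.frame(name = at$elena, element = element, type = at$elety,
                      charge = at$charge, x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  net <- round(sum(atoms$charge))
  if (abs(sum(atoms$charge) - net) > 1e-4)
    ff_stop(sprintf("partial charges sum to %.4f, not an integer net charge",
                    sum(atoms$charge)), "charge_mismatch")
  molecular_template(atoms, as.matrix(m$bond[, c("origin", "target")]),
                     net_charge = net, ring = ring,
                     id = if (is.null(id)) m$name else id)
}

#' Write a molecular template to a mol2 file
#'
#' @param template a `molecular_template`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_template <- function(template, path) {
  at <- template$atoms
  n <- nrow(at)
  m <- list(
    atom = data.frame(eleno = seq_len(n), elena = at$name,
                      x = at$x, y = at$y, z = at$z, elety = at$type,
                      resno = 1, resid = "MOL", charge = at$charge,
                      stringsAsFactors = FALSE),
    bond = data.frame(id = seq_len(nrow(template$bonds)),
                      origin = template$bonds[, 1],
                      target = template$bonds[, 2], type = "1",
                      stringsAsFactors = FALSE),
    info = c(n, nrow(template$bonds), 1, 0, 0),
    name = template$id)
  class(m) <- "mol2"
  bio3d::write.mol2(m, file = path)
  invisible(path)
}

## element from a GAFF-ish type string
type_element <- function(type) toupper(substr(sub("\\..*$", "", type), 1, 1))

#' Read an Amber frcmod parameter file
#'
#' Supports MASS/BOND/ANGLE/DIHE/NONBON sections.  DIHE lines carry
#' (IDIVF, PK, PHASE, PN); the internal barrier coefficient is Vn =
#' PK / IDIVF, PHASE maps to gamma, and a negative PN marks that further
#' terms for the same type quadruple follow.  Multi-term dihedrals are
#' aggregated under one canonical key.  Atom-type fields must be
#' dash-separated without internal whitespace.
#'
#' @param path file path.
#' @param strict_phase error on PHASE outside {0, 180} (default); when
#'   FALSE, such terms are accepted with a warning.
#' @return A `force_field` object (with masses kept in attribute
#'   `"masses"` for round-tripping).
#' @export
read_frcmod <- function(path, strict_phase = TRUE) {
  if (!file.exists(path)) ff_stop(paste("no such file:", path), "parse_error")
  lines <- readLines(path)
  section <- ""
  bonds <- list(); angles <- list(); dihedrals <- list()
  nonbonded <- list(); masses <- list()
  for (ln in seq_along(lines)) {
    raw <- trimws(lines[ln])
    if (ln == 1 || !nzchar(raw)) next
    up <- toupper(raw)
    if (up %in% c("MASS", "BOND", "ANGLE", "DIHE", "DIHEDRAL", "NONBON",
                  "NONB", "IMPROPER")) {
      section <- substr(up, 1, 4)
      next
    }
    tok <- strsplit(raw, "\\s+")[[1]]
    bad <- function(what) ff_stop(
      sprintf("line %d: cannot parse %s entry: %s", ln, what, raw),
      "parse_error")
    if (section == "MASS") {
      if (length(tok) < 2) bad("MASS")
      masses[[tok[1]]] <- as.numeric(tok[2])
    } else if (section == "BOND") {
      ty <- strsplit(tok[1], "-", fixed = TRUE)[[1]]
      if (length(ty) != 2 || length(tok) < 3) bad("BOND")
      bonds[[canonical_bond_key(ty[1], ty[2])]] <-
        c(as.numeric(tok[2]), as.numeric(tok[3]))
    } else if (section == "ANGL") {
      ty <- strsplit(tok[1], "-", fixed = TRUE)[[1]]
      if (length(ty) != 3 || length(tok) < 3) bad("ANGLE")
      angles[[canonical_angle_key(ty[1], ty[2], ty[3])]] <-
        c(as.numeric(tok[2]), as.numeric(tok[3]))
    } else if (section == "DIHE") {
      ty <- strsplit(tok[1], "-", fixed = TRUE)[[1]]
      if (length(ty) != 4 || length(tok) < 5) bad("DIHE")
      idivf <- as.numeric(tok[2]); pk <- as.numeric(tok[3])
      phase <- as.numeric(tok[4]); pn <- as.numeric(tok[5])
      if (!(phase %in% c(0, 180))) {
        if (strict_phase)
          ff_stop(sprintf("line %d: PHASE %g not in {0, 180}", ln, phase),
                  "unsupported_phase")
        ff_warn(sprintf("line %d: PHASE %g outside {0, 180} accepted", ln,
                        phase), "unsupported_phase")
      }
      key <- canonical_dihedral_key(ty)
      row <- data.frame(n = abs(pn), v = pk / idivf, gamma = phase)
      dihedrals[[key]] <- if (is.null(dihedrals[[key]])) row else
        rbind(dihedrals[[key]], row)
    } else if (section == "NONB") {
      if (length(tok) < 3) bad("NONBON")
      nonbonded[[tok[1]]] <- c(as.numeric(tok[2]), as.numeric(tok[3]))
    }
  }
  p <- force_field_parameters(bonds, angles, dihedrals, nonbonded,
                              allow_any_phase = !strict_phase)
  attr(p, "masses") <- masses
  p
}

#' Write an Amber frcmod parameter file
#'
#' Fixed-width Amber dialect; dihedrals are written with IDIVF = 1 and
#' PK = Vn, with a negative PN on every line of a multi-term series except
#' the last (the Amber continuation convention).
#'
#' @param params a `force_field` object.
#' @param path output path.
#' @param title first line of the file.
#' @return Invisibly, `path`.
#' @export
write_frcmod <- function(params, path, title = "parameter modifications") {
  out <- c(title, "MASS")
  masses <- attr(params, "masses")
  if (!is.null(masses))
    out <- c(out, sprintf("%-4s %8.3f", names(masses), unlist(masses)))
  out <- c(out, "", "BOND")
  for (k in names(params$bonds))
    out <- c(out, sprintf("%-11s %9.3f  %7.4f", k,
                          params$bonds[[k]][1], params$bonds[[k]][2]))
  out <- c(out, "", "ANGLE")
  for (k in names(params$angles))
    out <- c(out, sprintf("%-11s %9.3f  %9.3f", k,
                          params$angles[[k]][1], params$angles[[k]][2]))
  out <- c(out, "", "DIHE")
  for (k in names(params$dihedrals)) {
    d <- params$dihedrals[[k]]
    for (i in seq_len(nrow(d))) {
      pn <- if (i < nrow(d)) -d$n[i] else d$n[i]
      out <- c(out, sprintf("%-14s %3d %11.6f %9.3f %6.1f", k, 1L,
                            d$v[i], d$gamma[i], pn))
    }
  }
  out <- c(out, "", "NONBON")
  for (k in names(params$nonbonded))
    out <- c(out, sprintf("  %-4s %10.4f %10.4f", k,
                          params$nonbonded[[k]][1], params$nonbonded[[k]][2]))
  writeLines(c(out, ""), path)
  invisible(path)
}

#' Read a coordinate trajectory
#'
#' Multi-model PDB or multi-frame XYZ; the format is chosen from the file
#' extension unless given.  Frames are returned in file order with
#' provenance `"external"`.
#'
#' @param path file path.
#' @param format `"pdb"`, `"xyz"` or `"auto"`.
#' @return A `conformer_set`.
#' @export
read_trajectory <- function(path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  if (format == "pdb") {
    p <- tryCatch(bio3d::read.pdb(path, multi = TRUE),
                  error = function(e) ff_stop(
                    paste("pdb parse failure:", conditionMessage(e)),
                    "parse_error"))
    xyz <- p$xyz
    na <- ncol(xyz) / 3
    nf <- nrow(xyz)
    coords <- array(NA_real_, c(na, 3, nf))
    for (f in seq_len(nf)) coords[, , f] <- matrix(xyz[f, ], na, 3, byrow = TRUE)
    el <- substr(trimws(p$atom$elety), 1, 1)
    return(conformer_set(coords, meta = data.frame(
      provenance = rep("external", nf)), elements = el))
  }
  read_xyz_trajectory(path)
}

read_xyz_trajectory <- function(path) {
  lines <- readLines(path)
  i <- 1; frames <- list(); elements <- NULL; fidx <- 0
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    fidx <- fidx + 1
    na <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(na) || i + 1 + na > length(lines))
      ff_stop(sprintf("frame %d: malformed XYZ header", fidx),
              "inconsistent_frame")
    block <- lines[(i + 2):(i + 1 + na)]
    toks <- strsplit(trimws(block), "\\s+")
    if (any(vapply(toks, length, integer(1)) < 4))
      ff_stop(sprintf("frame %d: malformed atom line", fidx),
              "inconsistent_frame")
    el <- vapply(toks, `[`, character(1), 1)
    xyz <- suppressWarnings(
      t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3))))
    if (anyNA(xyz))
      ff_stop(sprintf("frame %d: non-numeric coordinates", fidx),
              "inconsistent_frame")
    if (is.null(elements)) elements <- el
    else if (length(el) != length(elements))
      ff_stop(sprintf("frame %d: atom count differs from frame 1", fidx),
              "inconsistent_frame")
    frames[[fidx]] <- xyz
    i <- i + 2 + na
  }
  if (!length(frames)) ff_stop("no frames in file", "inconsistent_frame")
  coords <- array(unlist(frames), c(nrow(frames[[1]]), 3, length(frames)))
  conformer_set(coords, meta = data.frame(
    provenance = rep("external", length(frames))), elements = elements)
}

#' Write a coordinate trajectory
#'
#' @param frames a `conformer_set`.
#' @param path output path.
#' @param format `"pdb"`, `"xyz"` or `"auto"` (from the extension).
#' @return Invisibly, `path`.
#' @export
write_trajectory <- function(frames, path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  na <- dim(frames$coords)[1]
  nf <- length(frames)
  el <- frames$elements
  if (is.null(el)) el <- rep("C", na)
  if (format == "xyz") {
    con <- file(path, "w")
    on.exit(close(con))
    for (f in seq_len(nf)) {
      writeLines(c(as.character(na), sprintf("frame %d", f)), con)
      writeLines(sprintf("%-2s %12.6f %12.6f %12.6f", el,
                         frames$coords[, 1, f], frames$coords[, 2, f],
                         frames$coords[, 3, f]), con)
    }
  } else {
    xyz <- matrix(NA_real_, nf, 3 * na)
    for (f in seq_len(nf)) xyz[f, ] <- as.numeric(t(frames$coords[, , f]))
    bio3d::write.pdb(file = path, xyz = bio3d::as.xyz(xyz),
                     elety = make.unique(el), resid = rep("MOL", na),
                     resno = rep(1, na))
  }
  invisible(path)
}

#' Read / write reference-energy tables
#'
#' Tab-separated table with header columns `template_id`, `frame_id`,
#' `energy` (kcal/mol) and `environment`.
#'
#' @param path file path.
#' @return `read_energy_table()` returns the data.frame.
#' @export
read_energy_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("template_id", "frame_id", "energy", "environment")
  if (!all(need %in% names(tab)))
    ff_stop(paste("energy table must have columns:",
                  paste(need, collapse = ", ")), "parse_error")
  if (any(!is.finite(tab$energy)))
    ff_stop("non-finite reference energies", "parse_error")
  tab
}

#' @rdname read_energy_table
#' @param tab data.frame as returned by [reference_energies()].
#' @export
write_energy_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write ESP grid files
#'
#' Whitespace-separated table of `x y z potential` with a one-line header
#' naming the environment (`vacuum` or `solvated`).
#'
#' @param path file path.
#' @return `read_esp_grid()` returns an `esp_grid` object.
#' @export
read_esp_grid <- function(path) {
  lines <- readLines(path)
  env <- trimws(sub("^#*\\s*", "", lines[1]))
  env <- strsplit(env, "\\s+")[[1]][1]
  toks <- strsplit(trimws(lines[-1][nzchar(trimws(lines[-1]))]), "\\s+")
  vals <- t(vapply(toks, function(t) as.numeric(t[1:4]), numeric(4)))
  esp_grid(vals[, 1:3, drop = FALSE], vals[, 4], environment = env)
}

#' @rdname read_esp_grid
#' @param grid an `esp_grid` object.
#' @export
write_esp_grid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#", grid$environment), con)
  writeLines(sprintf("%14.8f %14.8f %14.8f %16.10f",
                     grid$points[, 1], grid$points[, 2], grid$points[, 3],
                     grid$potentials), con)
  invisible(path)
}
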