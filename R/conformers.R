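#' Conformer sets
#'
#' A `conformer_set` stores an ordered collection of full-molecule
#' coordinate frames (Angstrom) as an `n_atoms x 3 x n_frames` array, plus
#' per-frame metadata: the pseudorotation window index (0-based, `NA` for
#' external frames), the target phase and amplitude, the generation seed
#' and a provenance label.
#'
#' @param coords `n_atoms x 3 x n_frames` numeric array (a single `n x 3`
#'   matrix is promoted to one frame).
#' @param template_id identifier of the source template (`NA` for external
#'   trajectories).
#' @param meta data.frame with one row per frame; missing columns among
#'   `window`, `phase_target`, `amplitude`, `seed`, `provenance` are filled
#'   with `NA`.
#' @param elements optional character vector of element symbols (needed to
#'   write XYZ trajectories).
#' @return An object of class `conformer_set`.
#' @export
conformer_set <- function(coords, template_id = NA_character_, meta = NULL,
                          elements = NULL) {
  if (is.matrix(coords)) coords <- array(coords, c(nrow(coords), 3, 1))
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  nf <- dim(coords)[3]
  base <- data.frame(window = rep(NA_integer_, nf),
                     phase_target = NA_real_, amplitude = NA_real_,
                     seed = NA_integer_, provenance = NA_character_)
  if (!is.null(meta)) {
    stopifnot(nrow(meta) == nf)
    for (cl in intersect(names(meta), names(base))) base[[cl]] <- meta[[cl]]
  }
  structure(list(coords = coords, template_id = template_id, meta = base,
                 elements = elements),
            class = "conformer_set")
}

#' @export
length.conformer_set <- function(x) dim(x$coords)[3]

#' @export
print.conformer_set <- function(x, ...) {
  cat(sprintf("<conformer_set> %d frames of %d atoms (template %s)\n",
              length(x), dim(x$coords)[1], x$template_id))
  pv <- unique(x$meta$provenance)
  cat("  provenance:", paste(pv, collapse = ", "), "\n")
  invisible(x)
}

#' @export
`[.conformer_set` <- function(x, i) {
  conformer_set(x$coords[, , i, drop = FALSE], x$template_id,
                x$meta[i, , drop = FALSE], x$elements)
}

#' Extract one frame as a coordinate matrix
#' @param frames a `conformer_set`.
#' @param i frame index.
#' @return `n x 3` matrix.
#' @export
frame_coords <- function(frames, i) frames$coords[, , i]

#' Concatenate conformer sets
#' @param ... `conformer_set` objects with matching atom counts.
#' @return A single `conformer_set`; the template id is kept only if shared.
#' @export
bind_frames <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) >= 1)
  na <- dim(sets[[1]]$coords)[1]
  for (s in sets)
    if (dim(s$coords)[1] != na)
      ff_stop("atom counts differ between conformer sets", "shape_mismatch")
  coords <- array(unlist(lapply(sets, function(s) s$coords)),
                  c(na, 3, sum(vapply(sets, length, integer(1)))))
  ids <- unique(vapply(sets, function(s) s$template_id, character(1)))
  conformer_set(coords, if (length(ids) == 1) ids else NA_character_,
                do.call(rbind, lapply(sets, function(s) s$meta)),
                sets[[1]]$elements)
}

#' Scan specification for conformer generation
#'
#' @param interval_deg phase-window width in degrees; must divide 360.
#'   Default 18, giving 20 windows.
#' @param amplitude_deg puckering amplitude used for every window (degrees).
#'   Default 35, a typical furanose amplitude.
#' @param poses_per_window number of frames generated per window.
#' @param perturb_deg half-range of the uniform random exocyclic-torsion
#'   perturbation applied by [random_poses()] (degrees).
#' @param seed integer seed for pose randomization.
#' @return An object of class `scan_spec`.
#' @export
scan_spec <- function(interval_deg = 18, amplitude_deg = 35,
                      poses_per_window = 1, perturb_deg = 30, seed = 1L) {
  if (360 %% interval_deg != 0)
    ff_stop("interval_deg must divide 360", "bad_bin_width")
  if (poses_per_window < 1)
    ff_stop("poses_per_window must be >= 1", "parse_error")
  structure(list(interval_deg = interval_deg, amplitude_deg = amplitude_deg,
                 poses_per_window = poses_per_window,
                 perturb_deg = perturb_deg, seed = as.integer(seed)),
            class = "scan_spec")
}

#' Pseudorotation scan of a template
#'
#' Embeds the template once per phase window at P = 0, interval, ...,
#' 360 - interval (window centres of the scan), producing one frame per
#' window.  Deterministic: no randomness is involved.
#'
#' @param template a `molecular_template`.
#' @param spec a [scan_spec()]; its `poses_per_window` is ignored here.
#' @return A `conformer_set` with `360 / interval_deg` frames.
#' @export
scan_pseudorotation <- function(template, spec = scan_spec()) {
  phases <- seq(0, 360 - spec$interval_deg, by = spec$interval_deg)
  n <- length(phases)
  na <- nrow(template$atoms)
  coords <- array(NA_real_, c(na, 3, n))
  for (w in seq_along(phases)) {
    coords[, , w] <- tryCatch(
      embed_ring(template, pucker_state(phases[w], spec$amplitude_deg)),
      error = function(e) ff_stop(
        sprintf("window %d (P = %g): %s", w - 1L, phases[w], conditionMessage(e)),
        "embedding_not_converged"))
  }
  conformer_set(coords, template$id,
                data.frame(window = seq_len(n) - 1L, phase_target = phases,
                           amplitude = spec$amplitude_deg, seed = NA_integer_,
                           provenance = "scan"),
                elements = template$atoms$element)
}

## Rotatable exocyclic bonds of a template: bonds (u, v) with u on the ring
## side and at least one atom strictly beyond v.  Rotating the complete
## far-side subtree about u->v changes only the torsions about that bond,
## preserving all bond lengths and angles; the ring never moves.
exocyclic_rotatable_bonds <- function(template) {
  ring <- template$ring
  adj <- template$adj
  # multi-source BFS distance to the ring
  d <- rep(Inf, length(adj))
  d[ring] <- 0
  frontier <- ring
  while (length(frontier)) {
    nxt <- integer(0)
    for (a in frontier) for (b in adj[[a]]) if (is.infinite(d[b])) {
      d[b] <- d[a] + 1
      nxt <- c(nxt, b)
    }
    frontier <- nxt
  }
  out <- list()
  for (k in seq_len(nrow(template$bonds))) {
    uv <- template$bonds[k, ]
    u <- uv[which.min(d[uv])]
    v <- uv[which.max(d[uv])]
    if (v %in% ring || d[u] == d[v]) next
    beyond <- setdiff(component_excluding(adj, v, blocked = u), v)
    if (length(beyond))
      out[[length(out) + 1]] <- list(u = u, v = v, moving = beyond)
  }
  out
}

#' Randomized pose ensembles over the pseudorotation scan
#'
#' For each phase window, generates `poses_per_window` frames by perturbing
#' the exocyclic torsions of the window's embedded geometry with seeded
#' uniform rotations in +/- `perturb_deg`; the five ring atoms are held
#' fixed at the embedded geometry, so every pose retains the window's
#' pucker exactly.  The same spec and seed always reproduce the same set.
#'
#' @param template a `molecular_template`.
#' @param spec a [scan_spec()].
#' @return A `conformer_set` with
#'   `(360 / interval_deg) * poses_per_window` frames.
#' @export
random_poses <- function(template, spec = scan_spec(poses_per_window = 8)) {
  scan <- scan_pseudorotation(template, spec)
  nw <- length(scan)
  na <- nrow(template$atoms)
  bonds <- exocyclic_rotatable_bonds(template)
  npose <- spec$poses_per_window
  coords <- array(NA_real_, c(na, 3, nw * npose))
  with_seed(spec$seed, {
    f <- 0L
    for (w in seq_len(nw)) {
      base <- scan$coords[, , w]
      for (p in seq_len(npose)) {
        xyz <- base
        for (b in bonds) {
          delta <- runif(1, -spec$perturb_deg, spec$perturb_deg) * DEG
          axis <- xyz[b$v, ] - xyz[b$u, ]
          R <- rotation_matrix(axis, delta)
          xyz[b$moving, ] <- sweep(
            sweep(xyz[b$moving, , drop = FALSE], 2, xyz[b$v, ]) %*% t(R),
            2, xyz[b$v, ], "+")
        }
        f <- f + 1L
        coords[, , f] <- xyz
      }
    }
  })
  meta <- data.frame(window = rep(scan$meta$window, each = npose),
                     phase_target = rep(scan$meta$phase_target, each = npose),
                     amplitude = spec$amplitude_deg, seed = spec$seed,
                     provenance = "random_pose")
  conformer_set(coords, template$id, meta, elements = template$atoms$element)
}

#' Minimum RMSD under rigid superposition
#'
#' Kabsch superposition (rotation + translation, proper rotations only)
#' of `a` onto `b`, returning the root-mean-square deviation in Angstrom.
#'
#' @param a,b `n x 3` coordinate matrices with consistent atom ordering.
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    ff_stop("coordinate sets differ in shape", "shape_mismatch")
  sup <- kabsch_superpose(a, b)
  fit <- a %*% sup$R + matrix(sup$t, nrow(a), 3, byrow = TRUE)
  sqrt(mean(rowSums((fit - b)^2)))
}

#' Cull near-duplicate frames by pairwise RMSD
#'
#' Greedy keep-first pass in frame order: a frame is kept iff its RMSD to
#' every previously kept frame is at least `threshold`.  The output
#' therefore has pairwise RMSD >= threshold, and culling is idempotent.
#'
#' @param frames a `conformer_set`.
#' @param threshold RMSD threshold in Angstrom (default 1.0).
#' @param heavy_only compute RMSD over non-hydrogen atoms only (default
#'   TRUE; requires element information).
#' @return The culled `conformer_set`.
#' @export
cull_by_rmsd <- function(frames, threshold = 1.0, heavy_only = TRUE) {
  n <- length(frames)
  if (n == 0) ff_stop("empty conformer set", "empty_series")
  sel <- seq_len(dim(frames$coords)[1])
  if (heavy_only && !is.null(frames$elements))
    sel <- which(frames$elements != "H")
  kept <- integer(0)
  for (i in seq_len(n)) {
    xi <- frames$coords[sel, , i]
    ok <- TRUE
    for (j in kept) {
      if (kabsch_rmsd(xi, frames$coords[sel, , j]) < threshold) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  frames[kept]
}
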