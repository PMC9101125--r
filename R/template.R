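#' Molecular templates
#'
#' A `molecular_template` bundles everything the package needs to know about
#' one small molecule: atom names, elements, GAFF-style atom-type strings,
#' partial charges (e), Cartesian coordinates (Angstrom), the bond list, the
#' net charge, and the identity of the five furanose ring atoms in the fixed
#' chemical order C1', C2', C3', C4', O4'.
#'
#' @param atoms data.frame with columns `name`, `element`, `type`, `charge`,
#'   `x`, `y`, `z`.
#' @param bonds two-column integer matrix of 1-based atom indices.
#' @param net_charge net molecular charge in e.
#' @param ring integer vector of the five ring-atom indices in the order
#'   C1', C2', C3', C4', O4'; auto-detected when `NULL`.
#' @param id template identifier string.
#' @return An object of class `molecular_template`.
#' @export
molecular_template <- function(atoms, bonds, net_charge = 0, ring = NULL,
                               id = "mol") {
  need <- c("name", "element", "type", "charge", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    ff_stop(paste("atoms must have columns:", paste(need, collapse = ", ")),
            "parse_error")
  bonds <- matrix(as.integer(bonds), ncol = 2)
  n <- nrow(atoms)
  if (abs(sum(atoms$charge) - net_charge) > 1e-6)
    ff_stop(sprintf("partial charges sum to %.6f but net charge is %g",
                    sum(atoms$charge), net_charge), "charge_mismatch")
  adj <- adjacency_list(n, bonds)
  if (n > 1 && any(is.infinite(bond_distances(adj, 1L))))
    ff_stop("bond graph is not connected", "parse_error")
  if (is.null(ring)) ring <- detect_furanose_ring(atoms, adj)
  if (length(ring) == 1 && is.na(ring)) {
    ring <- NULL  # explicitly ring-free (energy-only test molecules)
  } else {
    ring <- as.integer(ring)
    if (length(ring) != 5 || anyDuplicated(ring))
      ff_stop("ring must be five distinct atom indices", "ring_not_found")
    nxt <- c(2:5, 1)
    for (k in 1:5)
      if (!(ring[nxt[k]] %in% adj[[ring[k]]]))
        ff_stop("ring atoms are not consecutively bonded", "ring_not_found")
  }
  structure(list(atoms = atoms, bonds = bonds, net_charge = net_charge,
                 ring = ring, adj = adj, id = id),
            class = "molecular_template")
}

#' @export
print.molecular_template <- function(x, ...) {
  cat(sprintf("<molecular_template> %s: %d atoms, %d bonds, net charge %+g e\n",
              x$id, nrow(x$atoms), nrow(x$bonds), x$net_charge))
  if (!is.null(x$ring))
    cat("  ring (C1' C2' C3' C4' O4'):",
        paste(x$atoms$name[x$ring], collapse = " "), "\n")
  invisible(x)
}

#' Coordinates of a template
#' @param template a `molecular_template`.
#' @return n x 3 numeric matrix (Angstrom).
#' @export
template_coords <- function(template) {
  as.matrix(template$atoms[, c("x", "y", "z")])
}

#' Replace the coordinates of a template
#' @param template a `molecular_template`.
#' @param coords n x 3 matrix.
#' @return The template with updated coordinates.
#' @export
set_template_coords <- function(template, coords) {
  stopifnot(nrow(coords) == nrow(template$atoms))
  template$atoms[, c("x", "y", "z")] <- coords
  template
}

#' Replace the partial charges of a template
#' @param template a `molecular_template`.
#' @param charges numeric vector, one value per atom; must sum to the
#'   template's net charge.
#' @return The template with updated charges.
#' @export
set_template_charges <- function(template, charges) {
  stopifnot(length(charges) == nrow(template$atoms))
  if (abs(sum(charges) - template$net_charge) > 1e-6)
    ff_stop("charges do not sum to the net charge", "charge_mismatch")
  template$atoms$charge <- charges
  template
}

## Locate the unique 5-cycle containing exactly one oxygen.  The ring oxygen
## becomes O4'; of its two ring neighbours, C1' is the one carrying another
## oxygen substituent (the anomeric carbon), falling back to the lower index.
detect_furanose_ring <- function(atoms, adj) {
  n <- length(adj)
  cycles <- list()
  # BFS over simple paths rooted at their smallest member; close at length 5
  for (start in seq_len(n)) {
    paths <- list(start)
    while (length(paths)) {
      p <- paths[[1]]; paths <- paths[-1]
      last <- p[length(p)]
      for (b in adj[[last]]) {
        if (length(p) == 5) {
          if (b == start) cycles[[paste(sort(p), collapse = "-")]] <- p
        } else if (b > start && !(b %in% p)) {
          paths <- c(paths, list(c(p, b)))
        }
      }
    }
  }
  ok <- Filter(function(p) sum(atoms$element[p] == "O") == 1, cycles)
  if (length(ok) != 1)
    ff_stop(sprintf(
      "expected exactly one 5-ring with a single oxygen, found %d", length(ok)),
      "ring_not_found")
  cyc <- ok[[1]]
  opos <- which(atoms$element[cyc] == "O")
  # rotate so the oxygen sits last: positions C C C C O
  cyc <- cyc[((opos + seq_len(5) - 1) %% 5) + 1]
  o4 <- cyc[5]
  cand <- c(cyc[1], cyc[4])  # the two ring neighbours of O4'
  has_oxy <- vapply(cand, function(a) {
    any(atoms$element[setdiff(adj[[a]], cyc)] == "O")
  }, logical(1))
  c1 <- if (xor(has_oxy[1], has_oxy[2])) cand[which(has_oxy)] else min(cand)
  if (c1 == cyc[1]) c(cyc[1:4], o4) else c(cyc[4:1], o4)
}
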