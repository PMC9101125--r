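#' Force-field parameter sets
#'
#' Container for the constants of the additive molecular-mechanics
#' potential: harmonic bond terms (Kb in kcal/mol/A^2, b0 in A), harmonic
#' angle terms (Ktheta in kcal/mol/rad^2, theta0 in degrees), proper
#' dihedral Fourier series (periodicity n in 1..3, barrier coefficient Vn
#' in kcal/mol, phase gamma in {0, 180} degrees), per-type Lennard-Jones
#' parameters (r* in A, epsilon in kcal/mol), and the divisors applied to
#' 1-4 electrostatic and van der Waals interactions.  Dihedral keys are
#' stored canonically: the lexicographically smaller of the forward and
#' reversed type quadruple.
#'
#' @param bonds named list, key `"a-b"` -> c(k, b0).
#' @param angles named list, key `"a-b-c"` -> c(k, theta0).
#' @param dihedrals named list, key `"a-b-c-d"` -> data.frame(n, v, gamma).
#' @param nonbonded named list, key `"type"` -> c(rstar, eps).
#' @param scale_ee,scale_vdw 1-4 scaling divisors (Amber defaults 1.2, 2.0).
#' @param allow_any_phase accept dihedral phases outside {0, 180} (the
#'   frcmod reader's warn-and-accept mode); default FALSE.
#' @return An object of class `force_field`.
#' @export
force_field_parameters <- function(bonds = list(), angles = list(),
                                   dihedrals = list(), nonbonded = list(),
                                   scale_ee = 1.2, scale_vdw = 2.0,
                                   allow_any_phase = FALSE) {
  dihedrals <- canonicalize_dihedrals(dihedrals)
  if (length(bonds))
    names(bonds) <- vapply(strsplit(names(bonds), "-", fixed = TRUE),
                           function(t) canonical_bond_key(t[1], t[2]),
                           character(1))
  if (length(angles))
    names(angles) <- vapply(strsplit(names(angles), "-", fixed = TRUE),
                            function(t) canonical_angle_key(t[1], t[2], t[3]),
                            character(1))
  for (k in names(dihedrals)) {
    d <- dihedrals[[k]]
    if (!all(d$n %in% 1:3))
      ff_stop(sprintf("dihedral %s: periodicity must be 1, 2 or 3", k),
              "invalid_periodicity")
    if (!allow_any_phase && !all(d$gamma %in% c(0, 180)))
      ff_stop(sprintf("dihedral %s: gamma must be 0 or 180", k),
              "unsupported_phase")
  }
  for (k in names(bonds))
    if (bonds[[k]][1] < 0) ff_stop("Kb must be >= 0", "parse_error")
  for (k in names(angles))
    if (angles[[k]][1] < 0) ff_stop("Ktheta must be >= 0", "parse_error")
  for (k in names(nonbonded))
    if (nonbonded[[k]][2] < 0) ff_stop("epsilon must be >= 0", "parse_error")
  structure(list(bonds = bonds, angles = angles, dihedrals = dihedrals,
                 nonbonded = nonbonded, scale_ee = scale_ee,
                 scale_vdw = scale_vdw),
            class = "force_field")
}

#' @export
print.force_field <- function(x, ...) {
  cat(sprintf(paste0("<force_field> %d bond, %d angle, %d dihedral keys, ",
                     "%d atom types; 1-4 divisors ee %.2f vdw %.2f\n"),
              length(x$bonds), length(x$angles), length(x$dihedrals),
              length(x$nonbonded), x$scale_ee, x$scale_vdw))
  invisible(x)
}

#' Canonical dihedral type key
#'
#' The lexicographically smaller of `a-b-c-d` and `d-c-b-a`, so that a
#' torsion and its reverse share one key.
#'
#' @param types character vector of four atom-type strings, or a single
#'   `"a-b-c-d"` string.
#' @return Canonical key string.
#' @export
canonical_dihedral_key <- function(types) {
  if (length(types) == 1) types <- strsplit(types, "-", fixed = TRUE)[[1]]
  stopifnot(length(types) == 4)
  fwd <- paste(types, collapse = "-")
  rev_ <- paste(rev(types), collapse = "-")
  if (fwd <= rev_) fwd else rev_
}

canonical_bond_key <- function(a, b) {
  if (a <= b) paste(a, b, sep = "-") else paste(b, a, sep = "-")
}

canonical_angle_key <- function(a, b, c) {
  if (a <= c) paste(a, b, c, sep = "-") else paste(c, b, a, sep = "-")
}

canonicalize_dihedrals <- function(dihedrals) {
  if (!length(dihedrals)) return(dihedrals)
  out <- list()
  for (k in names(dihedrals)) {
    ck <- canonical_dihedral_key(k)
    d <- dihedrals[[k]]
    stopifnot(all(c("n", "v", "gamma") %in% names(d)))
    out[[ck]] <- if (is.null(out[[ck]])) d else rbind(out[[ck]], d)
  }
  out
}

## Look up a dihedral term list for a type quadruple; specific keys shadow
## X-b-c-X wildcards.  Returns NULL when nothing matches.
lookup_dihedral <- function(params, a, b, c, d) {
  k <- canonical_dihedral_key(c(a, b, c, d))
  hit <- params$dihedrals[[k]]
  if (!is.null(hit)) return(hit)
  kw <- canonical_dihedral_key(c("X", b, c, "X"))
  params$dihedrals[[kw]]
}

lookup_bond <- function(params, a, b) params$bonds[[canonical_bond_key(a, b)]]

lookup_angle <- function(params, a, b, c)
  params$angles[[canonical_angle_key(a, b, c)]]

#' The seven fitted dihedral classes
#'
#' Canonical type keys of the fluoro/hydroxy dihedral classes whose Fourier
#' coefficients the workflow refits.
#'
#' @return Character vector of seven canonical dihedral keys.
#' @export
fitted_dihedral_classes <- function() {
  vapply(list(c("c3", "c3", "c3", "oh"),
              c("c3", "c3", "c3", "f"),
              c("c3", "c3", "oh", "ho"),
              c("f",  "c3", "c3", "f"),
              c("f",  "c3", "c3", "oh"),
              c("f",  "c3", "c3", "os"),
              c("oh", "c3", "c3", "oh")),
         canonical_dihedral_key, character(1))
}

#' Default GAFF-like parameter set
#'
#' The starting parameter set shipped with the package: GAFF-flavoured
#' bond, angle and Lennard-Jones constants for the c3/os/oh/ho/h1/f types
#' used by the furanose templates, generic three-fold torsional wildcards,
#' and starting values for the seven refittable fluoro/hydroxy dihedral
#' classes.  These are the values iteration 1 of the fitting workflow
#' starts from; they are not a published parameter set.
#'
#' @return A `force_field` object.
#' @export
default_parameters <- function() {
  dihe <- function(n, v, gamma) data.frame(n = n, v = v, gamma = gamma)
  force_field_parameters(
    bonds = list(
      "c3-c3" = c(303.1, 1.535),
      "c3-os" = c(301.5, 1.439),
      "c3-oh" = c(314.1, 1.426),
      "c3-f"  = c(363.8, 1.344),
      "c3-h1" = c(335.9, 1.093),
      "ho-oh" = c(369.6, 0.974)),
    angles = list(
      "c3-c3-c3" = c(63.21, 110.63),
      "c3-c3-os" = c(67.78, 108.42),
      "c3-c3-oh" = c(67.72, 109.43),
      "c3-c3-f"  = c(66.22, 109.41),
      "c3-c3-h1" = c(46.36, 110.05),
      "c3-os-c3" = c(62.01, 111.51),
      "c3-oh-ho" = c(47.09, 108.16),
      "os-c3-os" = c(68.50, 111.55),
      "os-c3-h1" = c(50.84, 108.82),
      "oh-c3-h1" = c(50.97, 110.26),
      "f-c3-h1"  = c(50.90, 109.50),
      "f-c3-f"   = c(71.26, 107.16),
      "f-c3-oh"  = c(70.10, 108.55),
      "f-c3-os"  = c(69.80, 108.90),
      "h1-c3-h1" = c(39.18, 109.55)),
    dihedrals = list(
      "X-c3-c3-X" = dihe(3, 0.1556, 0),
      "X-c3-os-X" = dihe(3, 0.3833, 0),
      "X-c3-oh-X" = dihe(3, 0.1667, 0),
      "c3-c3-c3-oh" = dihe(3, 0.1560, 0),
      "c3-c3-c3-f"  = dihe(3, 0.1500, 0),
      "c3-c3-oh-ho" = dihe(c(1, 3), c(0.2500, 0.1600), c(0, 0)),
      "f-c3-c3-f"   = dihe(c(1, 3), c(1.2000, 0.1500), c(180, 0)),
      "f-c3-c3-oh"  = dihe(c(1, 3), c(1.0000, 0.1500), c(180, 0)),
      "f-c3-c3-os"  = dihe(c(1, 3), c(1.0000, 0.1500), c(180, 0)),
      "oh-c3-c3-oh" = dihe(c(2, 3), c(1.1750, 0.1440), c(0, 0))),
    nonbonded = list(
      "c3" = c(1.9080, 0.1094),
      "os" = c(1.6837, 0.1700),
      "oh" = c(1.7210, 0.2104),
      "ho" = c(0.3000, 0.0047),
      "h1" = c(1.3870, 0.0157),
      "f"  = c(1.7500, 0.0610)))
}
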