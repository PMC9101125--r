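#' Pseudorotation geometry of five-membered rings
#'
#' Furanose ring conformation is described by the Altona--Sundaralingam
#' pseudorotation phase angle P (which ring atoms pucker out of plane) and
#' the puckering amplitude tau_m (how far they pucker).  The five endocyclic
#' torsions nu_0..nu_4 follow the cosine wave
#' \deqn{\nu_j = \tau_m \cos(P + 144^\circ (j - 2))}
#' so that nu_2 (the torsion about the C2'--C3' bond) equals tau_m cos P.
#' This file implements the forward and inverse relations and the Cartesian
#' embedding of a ring template at a target pucker.
#'
#' @name pseudorotation
NULL

SIN36 <- sin(36 * DEG)
SIN72 <- sin(72 * DEG)

#' Pseudorotation state
#'
#' @param phase_deg phase angle P in degrees; stored normalized to [0, 360).
#' @param amplitude_deg puckering amplitude tau_m in degrees; must be >= 0.
#' @return An object of class `pucker_state`.
#' @examples
#' pucker_state(18, 35)
#' @export
pucker_state <- function(phase_deg, amplitude_deg) {
  if (!is.finite(phase_deg) || !is.finite(amplitude_deg))
    ff_stop("phase and amplitude must be finite", "invalid_pucker")
  if (amplitude_deg < 0)
    ff_stop("amplitude_deg must be non-negative", "invalid_pucker")
  structure(list(phase_deg = norm360(phase_deg), amplitude_deg = amplitude_deg),
            class = "pucker_state")
}

#' @export
print.pucker_state <- function(x, ...) {
  cat(sprintf("<pucker_state> P = %.3f deg, tau_m = %.3f deg\n",
              x$phase_deg, x$amplitude_deg))
  invisible(x)
}

#' Signed dihedral angle of four points
#'
#' IUPAC sign convention: looking from `p2` towards `p3`, a clockwise
#' rotation from the projection of `p1` to the projection of `p4` is
#' positive; a cis arrangement is 0 and trans is 180.
#'
#' @param p1,p2,p3,p4 numeric length-3 Cartesian points (Angstrom).
#' @return Signed angle in degrees in (-180, 180].
#' @examples
#' dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))   # cis, 0
#' dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))  # trans, 180
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10)
    ff_stop("three consecutive points are collinear; dihedral undefined",
            "collinear_points")
  b2h <- b2 / sqrt(sum(b2^2))
  m <- c(n1[2] * n2[3] - n1[3] * n2[2],
         n1[3] * n2[1] - n1[1] * n2[3],
         n1[1] * n2[2] - n1[2] * n2[1])
  ang <- atan2(sum(m * b2h), sum(n1 * n2)) / DEG
  norm180(ang)
}

## The atom quadruple defining nu_j, as ring positions (j-2, j-1, j, j+1)
## mod 5 in the fixed order C1', C2', C3', C4', O4'.  nu_2 is then
## C1'-C2'-C3'-C4', the torsion about the C2'-C3' bond.
nu_quadruples <- function() {
  lapply(0:4, function(j) ((j + c(-2, -1, 0, 1)) %% 5) + 1L)
}

#' Endocyclic torsions of a ring coordinate set
#'
#' @param coords 5 x 3 matrix of ring-atom coordinates in the fixed order
#'   C1', C2', C3', C4', O4'.
#' @return Numeric vector nu_0..nu_4 in degrees.
#' @export
endocyclic_torsions <- function(coords) {
  stopifnot(is.matrix(coords), nrow(coords) == 5, ncol(coords) == 3)
  vapply(nu_quadruples(), function(q) {
    dihedral_angle(coords[q[1], ], coords[q[2], ], coords[q[3], ], coords[q[4], ])
  }, numeric(1))
}

#' Phase and amplitude from endocyclic torsions
#'
#' Inverts the Altona--Sundaralingam relation using
#' tan P = ((nu4 + nu1) - (nu3 + nu0)) / (2 nu2 (sin 36 + sin 72)),
#' with the quadrant resolved by the two-argument arctangent and the
#' amplitude recovered from nu_2 = tau_m cos P and the sine combination.
#'
#' @param nu numeric vector of the five torsions nu_0..nu_4 in degrees.
#' @return A [pucker_state()].
#' @export
phase_from_torsions <- function(nu) {
  stopifnot(length(nu) == 5)
  if (max(abs(nu)) < 1e-6)
    ff_stop("all endocyclic torsions are (near) zero: phase undefined for a planar ring",
            "zero_amplitude")
  y <- (nu[5] + nu[2]) - (nu[4] + nu[1])       # nu4 + nu1 - nu3 - nu0
  x <- 2 * nu[3] * (SIN36 + SIN72)
  p <- atan2(y, x) / DEG
  tau <- sqrt(nu[3]^2 + (y / (2 * (SIN36 + SIN72)))^2)
  pucker_state(p, tau)
}

#' Endocyclic torsions from phase and amplitude
#'
#' @param state a [pucker_state()].
#' @return Numeric vector nu_0..nu_4 in degrees,
#'   nu_j = tau_m cos(P + 144 (j - 2)).
#' @export
torsions_from_phase <- function(state) {
  stopifnot(inherits(state, "pucker_state"))
  j <- 0:4
  norm180(state$amplitude_deg *
            cos((state$phase_deg + 144 * (j - 2)) * DEG) )
}

#' Phase and amplitude from ring coordinates
#'
#' @param coords 5 x 3 matrix of ring-atom coordinates (C1', C2', C3', C4',
#'   O4' order), or an n x 3 matrix of all atoms together with `order`.
#' @param order optional integer vector of the five ring-atom row indices.
#' @return A [pucker_state()].
#' @export
phase_from_ring_coords <- function(coords, order = NULL) {
  if (!is.null(order)) {
    stopifnot(length(order) == 5)
    coords <- coords[order, , drop = FALSE]
  }
  phase_from_torsions(endocyclic_torsions(coords))
}

## Residual vector for the ring-closure optimization: weighted deviations of
## endocyclic torsions, ring bond lengths and ring bond angles from targets.
ring_residuals <- function(par, nu_target, b0, theta0,
                           w_torsion = 1, w_bond = 500, w_angle = 0.02) {
  xyz <- matrix(par, 5, 3)
  nxt <- c(2:5, 1)
  prv <- c(5, 1:4)
  nu <- endocyclic_torsions(xyz)
  dt <- norm180(nu - nu_target)
  b <- sqrt(rowSums((xyz[nxt, ] - xyz)^2))
  th <- vapply(1:5, function(i) {
    u <- xyz[prv[i], ] - xyz[i, ]; v <- xyz[nxt[i], ] - xyz[i, ]
    acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) / DEG
  }, numeric(1))
  c(w_torsion * dt, w_bond * (b - b0), w_angle * (th - theta0))
}

## Initial planar-pentagon guess puckered along the ring normal.
ring_initial_guess <- function(b_mean, target, phase_shift) {
  ang <- (90 + 72 * (0:4)) * DEG
  r <- b_mean / (2 * SIN36)
  xy <- cbind(r * cos(ang), r * sin(ang))
  # out-of-plane displacement pattern with two nodes; 0.0072 A/deg maps
  # tau_m ~ 35 deg onto the ~0.25 A apex displacement of real furanoses
  z <- 0.0072 * target$amplitude_deg *
    cos((target$phase_deg + phase_shift) * DEG + 4 * pi * (0:4 - 2) / 5)
  cbind(xy, z)
}

#' Embed a molecular template at a target pucker
#'
#' Repositions the five ring atoms so their endocyclic torsions match the
#' target pseudorotation state while restraining ring bond lengths and
#' angles to the template values (damped least squares on the ring-atom
#' coordinates), then carries every exocyclic substituent rigidly in the
#' local frame of its anchor ring atom.
#'
#' @param template a `molecular_template` (see [read_template()]).
#' @param target a [pucker_state()]; amplitude must be below 60 degrees.
#' @param torsion_tol acceptance tolerance on each endocyclic torsion
#'   (degrees; default 0.5).
#' @param max_iter iteration cap for the closure optimization.
#' @return n x 3 coordinate matrix for all atoms of the template.
#' @export
embed_ring <- function(template, target, torsion_tol = 0.5, max_iter = 500) {
  stopifnot(inherits(template, "molecular_template"),
            inherits(target, "pucker_state"))
  if (target$amplitude_deg >= 60)
    ff_stop("amplitude >= 60 deg is outside the physical furanose range",
            "invalid_pucker")
  ring <- template$ring
  xyz <- template_coords(template)
  ring_old <- xyz[ring, , drop = FALSE]
  nxt <- c(2:5, 1)
  prv <- c(5, 1:4)
  b0 <- sqrt(rowSums((ring_old[nxt, ] - ring_old)^2))
  theta0 <- vapply(1:5, function(i) {
    u <- ring_old[prv[i], ] - ring_old[i, ]
    v <- ring_old[nxt[i], ] - ring_old[i, ]
    acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) / DEG
  }, numeric(1))
  nu_target <- torsions_from_phase(target)

  best <- NULL
  for (shift in c(0, -72, 72, 144, 180)) {
    start <- ring_initial_guess(mean(b0), target, shift)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = as.numeric(start), fn = ring_residuals,
                         nu_target = nu_target, b0 = b0, theta0 = theta0,
                         control = minpack.lm::nls.lm.control(
                           maxiter = min(max_iter, 1024), ptol = 1e-14,
                           ftol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
    nu_fit <- endocyclic_torsions(matrix(fit$par, 5, 3))
    if (max(abs(norm180(nu_fit - nu_target))) < 0.1) { best <- fit; break }
  }
  if (is.null(best))
    ff_stop("ring closure optimization failed to run", "embedding_not_converged")
  ring_new <- matrix(best$par, 5, 3)
  nu_new <- endocyclic_torsions_or_zero(ring_new)
  bond_dev <- max(abs(sqrt(rowSums((ring_new[nxt, ] - ring_new)^2)) - b0))
  if (max(abs(norm180(nu_new - nu_target))) > torsion_tol || bond_dev > 0.01)
    ff_stop(sprintf(
      "embedding did not converge: max torsion deviation %.3f deg, max bond deviation %.4f A",
      max(abs(norm180(nu_new - nu_target))), bond_dev),
      "embedding_not_converged")

  # keep the molecule in the template's frame
  sup <- kabsch_superpose(ring_new, ring_old)
  ring_new <- ring_new %*% sup$R + matrix(sup$t, 5, 3, byrow = TRUE)

  out <- xyz
  out[ring, ] <- ring_new
  adj <- template$adj
  for (k in 1:5) {
    a <- ring[k]
    branch_roots <- setdiff(adj[[a]], ring)
    if (!length(branch_roots)) next
    branch <- unique(unlist(lapply(branch_roots, function(r)
      component_excluding(adj, r, blocked = ring))))
    F_old <- anchor_frame(xyz[ring[prv[k]], ], xyz[a, ], xyz[ring[nxt[k]], ])
    F_new <- anchor_frame(out[ring[prv[k]], ], out[a, ], out[ring[nxt[k]], ])
    local <- sweep(xyz[branch, , drop = FALSE], 2, xyz[a, ]) %*% F_old
    out[branch, ] <- sweep(local %*% t(F_new), 2, out[a, ], "+")
  }
  out
}

## Torsions, but tolerate a perfectly planar optimized ring (amplitude 0).
endocyclic_torsions_or_zero <- function(xyz) {
  tryCatch(endocyclic_torsions(xyz), error = function(e) rep(0, 5))
}

## Right-handed orthonormal frame at ring atom `a` from its ring neighbours.
anchor_frame <- function(p, a, n) {
  ex <- n - a; ex <- ex / sqrt(sum(ex^2))
  v <- p - a
  ez <- c(ex[2] * v[3] - ex[3] * v[2],
          ex[3] * v[1] - ex[1] * v[3],
          ex[1] * v[2] - ex[2] * v[1])
  ez <- ez / sqrt(sum(ez^2))
  ey <- c(ez[2] * ex[3] - ez[3] * ex[2],
          ez[3] * ex[1] - ez[1] * ex[3],
          ez[1] * ex[2] - ez[2] * ex[1])
  cbind(ex, ey, ez)
}
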