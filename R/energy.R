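#' Additive molecular-mechanics energy
#'
#' The potential is the standard additive form: harmonic bonds
#' sum Kb (b - b0)^2, harmonic angles sum Ktheta (theta - theta0)^2,
#' Lennard-Jones Aij/r^12 - Bij/r^6 and Coulomb kC qi qj / r over all atom
#' pairs separated by three or more bonds (pairs exactly three bonds apart
#' are divided by the 1-4 scaling divisors), and proper dihedral Fourier
#' series sum_n Vn [1 + cos(n phi - gamma)] with n in 1..3 and gamma in
#' {0, 180} degrees.  Aij and Bij come from Lorentz-Berthelot combination
#' of per-type (r*, epsilon): Rij = r*_i + r*_j, eps_ij = sqrt(eps_i eps_j),
#' Aij = eps_ij Rij^12, Bij = 2 eps_ij Rij^6.  The electrostatic constant
#' is kC = 332.0522 kcal A / (mol e^2) (Amber convention).  No cutoff is
#' applied: molecules here are small.
#'
#' @name mm-energy
NULL

#' Electrostatic constant, kcal A / (mol e^2)
#' @export
COULOMB_CONSTANT <- 332.0522

## Resolve the full topology of a template against a parameter set once;
## evaluation over many frames then reuses the compiled tables.
compile_system <- function(template, params, charges = NULL) {
  at <- template$atoms
  n <- nrow(at)
  ty <- at$type
  q <- if (is.null(charges)) at$charge else charges
  adj <- template$adj

  # bonds
  bi <- template$bonds[, 1]; bj <- template$bonds[, 2]
  bk <- numeric(length(bi)); bb0 <- numeric(length(bi))
  for (k in seq_along(bi)) {
    p <- lookup_bond(params, ty[bi[k]], ty[bj[k]])
    if (is.null(p))
      ff_stop(paste("missing bond parameters for",
                    canonical_bond_key(ty[bi[k]], ty[bj[k]])),
              "missing_parameter")
    bk[k] <- p[1]; bb0[k] <- p[2]
  }

  # angles: every a-b-c with a < c among neighbours of b
  aa <- integer(0); ab <- integer(0); ac <- integer(0)
  for (b in seq_len(n)) {
    nb <- adj[[b]]
    if (length(nb) < 2) next
    for (x in seq_len(length(nb) - 1)) for (y in (x + 1):length(nb)) {
      aa <- c(aa, nb[x]); ab <- c(ab, b); ac <- c(ac, nb[y])
    }
  }
  ak <- numeric(length(aa)); ath0 <- numeric(length(aa))
  for (k in seq_along(aa)) {
    p <- lookup_angle(params, ty[aa[k]], ty[ab[k]], ty[ac[k]])
    if (is.null(p))
      ff_stop(paste("missing angle parameters for",
                    canonical_angle_key(ty[aa[k]], ty[ab[k]], ty[ac[k]])),
              "missing_parameter")
    ak[k] <- p[1]; ath0[k] <- p[2]
  }

  # proper torsions: a-b-c-d over every central bond b-c
  ta <- integer(0); tb <- integer(0); tc <- integer(0); td <- integer(0)
  for (k in seq_len(nrow(template$bonds))) {
    b <- template$bonds[k, 1]; c <- template$bonds[k, 2]
    for (a in setdiff(adj[[b]], c)) for (d in setdiff(adj[[c]], b)) {
      if (a == d) next
      ta <- c(ta, a); tb <- c(tb, b); tc <- c(tc, c); td <- c(td, d)
    }
  }
  tkey <- character(length(ta))
  term_tor <- integer(0); term_n <- numeric(0)
  term_v <- numeric(0); term_g <- numeric(0)
  for (k in seq_along(ta)) {
    tkey[k] <- canonical_dihedral_key(c(ty[ta[k]], ty[tb[k]], ty[tc[k]],
                                        ty[td[k]]))
    terms <- lookup_dihedral(params, ty[ta[k]], ty[tb[k]], ty[tc[k]], ty[td[k]])
    if (is.null(terms))
      ff_stop(paste("missing dihedral parameters for", tkey[k]),
              "missing_parameter")
    if (nrow(terms)) {
      term_tor <- c(term_tor, rep(k, nrow(terms)))
      term_n <- c(term_n, terms$n)
      term_v <- c(term_v, terms$v)
      term_g <- c(term_g, terms$gamma)
    }
  }

  # nonbonded pairs: bond-path distance >= 3 (exactly 3 -> 1-4 scaling)
  pd <- matrix(Inf, n, n)
  for (i in seq_len(n)) pd[i, ] <- bond_distances(adj, i)
  pi_ <- integer(0); pj_ <- integer(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (pd[i, j] >= 3) { pi_ <- c(pi_, i); pj_ <- c(pj_, j) }
  is14 <- pd[cbind(pi_, pj_)] == 3
  Avec <- numeric(length(pi_)); Bvec <- numeric(length(pi_))
  for (k in seq_along(pi_)) {
    p1 <- params$nonbonded[[ty[pi_[k]]]]
    p2 <- params$nonbonded[[ty[pj_[k]]]]
    if (is.null(p1) || is.null(p2))
      ff_stop(paste("missing Lennard-Jones parameters for",
                    ty[pi_[k]], "or", ty[pj_[k]]), "missing_parameter")
    Rij <- p1[1] + p2[1]
    eij <- sqrt(p1[2] * p2[2])
    Avec[k] <- eij * Rij^12
    Bvec[k] <- 2 * eij * Rij^6
  }
  qq <- q[pi_] * q[pj_]
  sc_ee <- ifelse(is14, 1 / params$scale_ee, 1)
  sc_vdw <- ifelse(is14, 1 / params$scale_vdw, 1)

  list(bi = bi, bj = bj, bk = bk, bb0 = bb0,
       aa = aa, ab = ab, ac = ac, ak = ak, ath0 = ath0 * DEG,
       ta = ta, tb = tb, tc = tc, td = td, tkey = tkey,
       term_tor = term_tor, term_n = term_n, term_v = term_v,
       term_g = term_g * DEG,
       pi_ = pi_, pj_ = pj_, A = Avec, B = Bvec, qq = qq,
       sc_ee = sc_ee, sc_vdw = sc_vdw)
}

## Vectorized signed torsion angles (radians) for index quadruples.
torsion_angles_rad <- function(coords, a, b, c, d) {
  b1 <- coords[b, , drop = FALSE] - coords[a, , drop = FALSE]
  b2 <- coords[c, , drop = FALSE] - coords[b, , drop = FALSE]
  b3 <- coords[d, , drop = FALSE] - coords[c, , drop = FALSE]
  cross <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                                u[, 3] * v[, 1] - u[, 1] * v[, 3],
                                u[, 1] * v[, 2] - u[, 2] * v[, 1])
  n1 <- cross(b1, b2)
  n2 <- cross(b2, b3)
  b2h <- b2 / sqrt(rowSums(b2^2))
  m <- cross(n1, n2)
  atan2(rowSums(m * b2h), rowSums(n1 * n2))
}

evaluate_compiled <- function(cs, coords) {
  eb <- if (length(cs$bi)) {
    b <- sqrt(rowSums((coords[cs$bi, , drop = FALSE] -
                         coords[cs$bj, , drop = FALSE])^2))
    sum(cs$bk * (b - cs$bb0)^2)
  } else 0
  ea <- if (length(cs$aa)) {
    u <- coords[cs$aa, , drop = FALSE] - coords[cs$ab, , drop = FALSE]
    v <- coords[cs$ac, , drop = FALSE] - coords[cs$ab, , drop = FALSE]
    cth <- rowSums(u * v) / sqrt(rowSums(u^2) * rowSums(v^2))
    th <- acos(pmin(1, pmax(-1, cth)))
    sum(cs$ak * (th - cs$ath0)^2)
  } else 0
  ed <- 0
  if (length(cs$term_tor)) {
    phi <- torsion_angles_rad(coords, cs$ta, cs$tb, cs$tc, cs$td)
    ed <- sum(cs$term_v * (1 + cos(cs$term_n * phi[cs$term_tor] - cs$term_g)))
  }
  ev <- 0; ec <- 0
  if (length(cs$pi_)) {
    d2 <- rowSums((coords[cs$pi_, , drop = FALSE] -
                     coords[cs$pj_, , drop = FALSE])^2)
    if (any(d2 < 1e-12))
      ff_stop("overlapping atoms in nonbonded pair", "zero_distance")
    d6 <- d2^3
    ev <- sum(cs$sc_vdw * (cs$A / (d6 * d6) - cs$B / d6))
    ec <- sum(cs$sc_ee * COULOMB_CONSTANT * cs$qq / sqrt(d2))
  }
  structure(list(bond = eb, angle = ea, vdw = ev, coulomb = ec,
                 dihedral = ed, total = eb + ea + ev + ec + ed),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf(paste0("<energy_breakdown> total %.4f kcal/mol ",
                     "(bond %.4f, angle %.4f, vdw %.4f, coulomb %.4f, ",
                     "dihedral %.4f)\n"),
              x$total, x$bond, x$angle, x$vdw, x$coulomb, x$dihedral))
  invisible(x)
}

#' Evaluate the MM energy of one conformation
#'
#' @param template a `molecular_template` (supplies types, charges, bonds).
#' @param coords `n x 3` coordinate matrix (Angstrom); defaults to the
#'   template coordinates.
#' @param params a `force_field` object.
#' @return An `energy_breakdown`: components `bond`, `angle`, `vdw`,
#'   `coulomb`, `dihedral` and their sum `total`, all kcal/mol.
#' @examples
#' t1 <- furanose_template(1)
#' mm_energy(t1, params = default_parameters())
#' @export
mm_energy <- function(template, coords = template_coords(template),
                      params = default_parameters()) {
  evaluate_compiled(compile_system(template, params), coords)
}

#' Dihedral Fourier series energy
#'
#' sum_n Vn [1 + cos(n phi - gamma)]; a gamma = 180 term equals
#' Vn [1 - cos(n phi)].
#'
#' @param phi torsion angle in degrees (vectorized).
#' @param terms data.frame with columns `n` (1..3), `v` (kcal/mol),
#'   `gamma` (0 or 180).
#' @return Energy in kcal/mol, one value per element of `phi`.
#' @export
dihedral_term_energy <- function(phi, terms) {
  if (!all(terms$n %in% 1:3))
    ff_stop("periodicity must be 1, 2 or 3", "invalid_periodicity")
  if (!all(terms$gamma %in% c(0, 180)))
    ff_stop("gamma must be 0 or 180", "unsupported_phase")
  vapply(phi, function(p)
    sum(terms$v * (1 + cos((terms$n * p - terms$gamma) * DEG))), numeric(1))
}

#' Batch energies over a conformer set
#'
#' @param template a `molecular_template`.
#' @param frames a `conformer_set` with the template's atom count.
#' @param params a `force_field` object.
#' @return data.frame with one row per frame and columns `bond`, `angle`,
#'   `vdw`, `coulomb`, `dihedral`, `total` (kcal/mol), in frame order.
#' @export
batch_energies <- function(template, frames, params = default_parameters()) {
  if (dim(frames$coords)[1] != nrow(template$atoms))
    ff_stop("frame atom count does not match template", "shape_mismatch")
  cs <- compile_system(template, params)
  n <- length(frames)
  out <- matrix(NA_real_, n, 6,
                dimnames = list(NULL, c("bond", "angle", "vdw", "coulomb",
                                        "dihedral", "total")))
  for (f in seq_len(n)) {
    e <- tryCatch(evaluate_compiled(cs, frames$coords[, , f]),
                  error = function(err) ff_stop(
                    sprintf("frame %d: %s", f, conditionMessage(err)),
                    "zero_distance"))
    out[f, ] <- c(e$bond, e$angle, e$vdw, e$coulomb, e$dihedral, e$total)
  }
  as.data.frame(out)
}
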