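#' Electrostatic-potential grids
#'
#' An `esp_grid` holds spatial points (Angstrom) with electrostatic
#' potential values in kcal/(mol e) — the same electrostatic constant as
#' the energy model, so fitted charges are directly consistent with it —
#' plus the environment tag (`vacuum` or `solvated`) and the source
#' template id.
#'
#' @param points `m x 3` matrix of positions (Angstrom).
#' @param potentials numeric vector of length m, kcal/(mol e).
#' @param environment `"vacuum"` or `"solvated"`.
#' @param template_id source template id.
#' @return An object of class `esp_grid`.
#' @export
esp_grid <- function(points, potentials, environment = "vacuum",
                     template_id = NA_character_) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3)
  if (nrow(points) != length(potentials))
    ff_stop("point and potential counts differ", "length_mismatch")
  structure(list(points = points, potentials = as.numeric(potentials),
                 environment = environment, template_id = template_id),
            class = "esp_grid")
}

#' @export
print.esp_grid <- function(x, ...) {
  cat(sprintf("<esp_grid> %d points, environment %s (template %s)\n",
              nrow(x$points), x$environment, x$template_id))
  invisible(x)
}

#' Atom-centred partial charge sets
#'
#' @param charges numeric vector, e.
#' @param net_charge net molecular charge, e.
#' @param environment `"vacuum"`, `"solvated"` or `"ipolq"`.
#' @return An object of class `charge_set` (a numeric vector with
#'   attributes).
#' @export
charge_set <- function(charges, net_charge = round(sum(charges)),
                       environment = "vacuum") {
  if (abs(sum(charges) - net_charge) > 1e-8)
    ff_stop(sprintf("charges sum to %.8f, net is %g", sum(charges),
                    net_charge), "charge_mismatch")
  structure(as.numeric(charges), net_charge = net_charge,
            environment = environment, class = "charge_set")
}

#' @export
print.charge_set <- function(x, ...) {
  cat(sprintf("<charge_set> %d atoms, net %+g e, environment %s\n",
              length(x), attr(x, "net_charge"), attr(x, "environment")))
  print(round(as.numeric(x), 4))
  invisible(x)
}

#' Quasi-random shell grid around a molecule
#'
#' Seeded uniform points kept between the van-der-Waals shells scaled by
#' `inner_scale` and `outer_scale` (and never closer than 1 Angstrom to
#' any atom), the standard construction for ESP fitting targets.
#'
#' @param template a `molecular_template`.
#' @param inner_scale,outer_scale multiples of each atom's r* defining the
#'   shell (defaults 1.4 and 2.0).
#' @param density target points per cubic Angstrom of the sampling box
#'   (default 1).
#' @param seed integer seed; the same seed yields the same points.
#' @param params parameter set supplying per-type r* radii.
#' @return `m x 3` matrix of grid positions.
#' @export
make_shell_grid <- function(template, inner_scale = 1.4, outer_scale = 2.0,
                            density = 1, seed = 1L,
                            params = default_parameters()) {
  if (density <= 0) ff_stop("density must be positive", "parse_error")
  xyz <- template_coords(template)
  rstar <- vapply(template$atoms$type, function(t) {
    p <- params$nonbonded[[t]]
    if (is.null(p)) ff_stop(paste("no r* for type", t), "missing_parameter")
    p[1]
  }, numeric(1))
  rin <- pmax(inner_scale * rstar, 1.0)
  rout <- outer_scale * rstar
  lo <- apply(xyz, 2, min) - max(rout)
  hi <- apply(xyz, 2, max) + max(rout)
  vol <- prod(hi - lo)
  n <- ceiling(density * vol)
  pts <- with_seed(seed, matrix(runif(3 * n, rep(lo, each = n),
                                      rep(hi, each = n)), n, 3))
  keep <- logical(n)
  inside <- logical(n)
  outside_ok <- rep(TRUE, n)
  for (a in seq_len(nrow(xyz))) {
    d <- sqrt(colSums((t(pts) - xyz[a, ])^2))
    outside_ok <- outside_ok & (d >= rin[a])
    inside <- inside | (d <= rout[a])
  }
  pts[outside_ok & inside, , drop = FALSE]
}

#' Fit atom-centred charges to an ESP grid
#'
#' Minimizes the squared deviation between the grid potentials and the
#' point-charge potential sum_a q_a kC / r, subject to the exact net-charge
#' constraint via a Lagrange multiplier, with an optional harmonic
#' restraint toward prior charges (used by the iterative workflow for
#' stability).
#'
#' @param grid an `esp_grid`.
#' @param coords `n x 3` atom coordinates (Angstrom).
#' @param net_charge net charge in e.
#' @param restraint_weight harmonic restraint weight toward `prior`
#'   (default 0: pure least squares).
#' @param prior optional `charge_set` (or numeric vector) of prior charges.
#' @return A `charge_set` tagged with the grid environment.
#' @export
fit_esp_charges <- function(grid, coords, net_charge = 0,
                            restraint_weight = 0, prior = NULL) {
  stopifnot(inherits(grid, "esp_grid"))
  coords <- as.matrix(coords)
  n <- nrow(coords)
  m <- nrow(grid$points)
  if (m < 1) ff_stop("empty grid", "empty_series")
  if (m < n) ff_stop("fewer grid points than atoms", "dimension_mismatch")
  M <- matrix(NA_real_, m, n)
  for (a in seq_len(n)) {
    d <- sqrt(colSums((t(grid$points) - coords[a, ])^2))
    if (any(d < 1e-6))
      ff_stop("grid point coincides with an atom", "point_on_atom")
    M[, a] <- COULOMB_CONSTANT / d
  }
  q0 <- if (is.null(prior)) numeric(n) else as.numeric(prior)
  A <- crossprod(M) + diag(restraint_weight, n)
  b <- crossprod(M, grid$potentials) + restraint_weight * q0
  K <- rbind(cbind(A, 1), c(rep(1, n), 0))
  rhs <- c(b, net_charge)
  sol <- tryCatch(solve(K, rhs),
                  error = function(e) ff_stop(
                    "singular charge-fitting system (degenerate geometry)",
                    "singular_system"))
  q <- sol[seq_len(n)]
  q <- q - (sum(q) - net_charge) / n  # exactness against round-off
  charge_set(q, net_charge, environment = grid$environment)
}

#' Implicitly polarized charges: vacuum/solvated midpoint
#'
#' The implicitly polarized charge of each atom is the midpoint of its
#' vacuum and solvated ESP fits, q = (q_vac + q_solv) / 2 — charges
#' halfway between the gas-phase and condensed-phase response.
#'
#' @param q_vac,q_solv `charge_set` objects with the same atoms and net
#'   charge.
#' @return A `charge_set` tagged `"ipolq"`.
#' @export
combine_ipolq <- function(q_vac, q_solv) {
  if (length(q_vac) != length(q_solv))
    ff_stop("charge sets have different atom counts", "length_mismatch")
  if (!isTRUE(all.equal(attr(q_vac, "net_charge"), attr(q_solv, "net_charge"))))
    ff_stop("charge sets have different net charges", "charge_mismatch")
  charge_set((as.numeric(q_vac) + as.numeric(q_solv)) / 2,
             attr(q_vac, "net_charge"), environment = "ipolq")
}

#' Five-percent convergence rule for charge sets
#'
#' @param prev,new charge sets (or numeric vectors) over the same atoms.
#' @param tol relative tolerance (default 0.05).
#' @param floor minimum denominator in e (default 0.01), guarding atoms
#'   with near-zero charge.
#' @return TRUE or FALSE.
#' @export
converged_charges <- function(prev, new, tol = 0.05, floor = 0.01) {
  if (length(prev) != length(new))
    ff_stop("charge sets have different atom counts", "length_mismatch")
  dv <- abs(as.numeric(new) - as.numeric(prev)) /
    pmax(abs(as.numeric(prev)), floor)
  all(dv < tol)
}
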