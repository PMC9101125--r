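test_that("dihedral_angle follows the IUPAC sign convention", {
  p1 <- c(0, 1, 0); p2 <- c(0, 0, 0); p3 <- c(1, 0, 0)
  expect_equal(dihedral_angle(p1, p2, p3, c(1, 1, 0)), 0)
  expect_equal(dihedral_angle(p1, p2, p3, c(1, -1, 0)), 180)
  # value frozen from the projection-plane oracle below
  expect_equal(dihedral_angle(p1, p2, p3, c(1, 0, 1)), 90)
})

test_that("dihedral_angle matches a rotation-matrix construction", {
  # independent oracle: project the outer bonds onto the plane normal to
  # the central bond and take the signed angle between the projections
  proj_oracle <- function(p1, p2, p3, p4) {
    b2 <- p3 - p2
    b2h <- b2 / sqrt(sum(b2^2))
    u <- (p1 - p2) - sum((p1 - p2) * b2h) * b2h
    v <- (p4 - p3) - sum((p4 - p3) * b2h) * b2h
    cr <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
    atan2(sum(cr * b2h), sum(u * v)) * 180 / pi
  }
  set.seed(4)
  for (k in 1:50) {
    pts <- matrix(rnorm(12, sd = 2), 4, 3)
    phi <- tryCatch(dihedral_angle(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
                    error = function(e) NA)
    if (is.na(phi)) next
    expect_equal(phi, proj_oracle(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
                 tolerance = 1e-10)
  }
  # rotating the fourth point about the central bond shifts the angle by
  # exactly the (right-handed) rotation applied
  p <- matrix(c(0, 1, 0, 0, 0, 0, 1, 0, 0, 1, 1, 0), 4, 3, byrow = TRUE)
  phi0 <- dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ])
  for (ang in c(30, 90, 145, -60)) {
    R <- furanoseFF:::rotation_matrix(p[3, ] - p[2, ], ang * pi / 180)
    p4r <- as.numeric(R %*% (p[4, ] - p[3, ])) + p[3, ]
    phi1 <- dihedral_angle(p[1, ], p[2, ], p[3, ], p4r)
    expect_equal(furanoseFF:::norm180(phi1 - phi0 - ang), 0,
                 tolerance = 1e-10)
  }
})

test_that("collinear points raise an error", {
  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               class = "ff_collinear_points")
})

test_that("phase and amplitude invert the cosine-wave construction", {
  nu <- 35 * cos(144 * pi / 180 * (0:4 - 2))
  s <- phase_from_torsions(nu)
  expect_equal(s$phase_deg, 0, tolerance = 1e-10)
  expect_equal(s$amplitude_deg, 35, tolerance = 1e-10)

  expect_error(phase_from_torsions(rep(0, 5)), class = "ff_zero_amplitude")

  s2 <- phase_from_torsions(torsions_from_phase(pucker_state(123.4, 38.2)))
  expect_equal(s2$phase_deg, 123.4, tolerance = 1e-9)
  expect_equal(s2$amplitude_deg, 38.2, tolerance = 1e-9)
})

test_that("torsion generation has the stated special values", {
  nu <- torsions_from_phase(pucker_state(90, 40))
  expect_equal(nu[3], 0, tolerance = 1e-12)  # nu_2 = tau_m cos 90
  expect_equal(torsions_from_phase(pucker_state(0, 0)), rep(0, 5))
})

test_that("phase round-trip holds over a 1000-point random grid", {
  grid <- random_pucker_states(1000, seed = 99)
  for (k in seq_len(nrow(grid))) {
    s <- phase_from_torsions(torsions_from_phase(
      pucker_state(grid$phase[k], grid$amplitude[k])))
    expect_lt(abs(s$phase_deg - grid$phase[k]), 1e-9)
    expect_lt(abs(s$amplitude_deg - grid$amplitude[k]), 1e-9)
  }
})

test_that("phase from coordinates is rigid-motion invariant", {
  tpl <- fx_template(2)
  co <- embed_ring(tpl, pucker_state(54, 35))
  s0 <- phase_from_ring_coords(co, tpl$ring)
  set.seed(7)
  for (k in 1:5) {
    ax <- rnorm(3)
    R <- furanoseFF:::rotation_matrix(ax, runif(1, 0, 2 * pi))
    co2 <- co %*% t(R) + matrix(rnorm(3, sd = 5), nrow(co), 3, byrow = TRUE)
    s1 <- phase_from_ring_coords(co2, tpl$ring)
    expect_equal(s1$phase_deg, s0$phase_deg, tolerance = 1e-8)
    expect_equal(s1$amplitude_deg, s0$amplitude_deg, tolerance = 1e-8)
  }
})

test_that("a planar regular pentagon has undefined phase", {
  ang <- (90 - 72 * (0:4)) * pi / 180
  penta <- cbind(cos(ang), sin(ang), 0)
  expect_error(phase_from_ring_coords(penta), class = "ff_zero_amplitude")
})

test_that("embed_ring reaches the target pucker and keeps bond lengths", {
  tpl <- fx_template(1)
  co <- embed_ring(tpl, pucker_state(18, 35))
  s <- phase_from_ring_coords(co, tpl$ring)
  expect_lt(abs(s$phase_deg - 18), 0.5)
  expect_lt(abs(s$amplitude_deg - 35), 1)

  ring_old <- template_coords(tpl)[tpl$ring, ]
  ring_new <- co[tpl$ring, ]
  nxt <- c(2:5, 1)
  b_old <- sqrt(rowSums((ring_old[nxt, ] - ring_old)^2))
  b_new <- sqrt(rowSums((ring_new[nxt, ] - ring_new)^2))
  expect_lt(max(abs(b_new - b_old)), 0.01)

  # flat target gives a flat ring
  co0 <- embed_ring(tpl, pucker_state(0, 0))
  nu <- vapply(furanoseFF:::nu_quadruples(), function(q) {
    r <- co0[tpl$ring, ]
    dihedral_angle(r[q[1], ], r[q[2], ], r[q[3], ], r[q[4], ])
  }, numeric(1))
  expect_lt(max(abs(nu)), 0.5)

  expect_error(embed_ring(tpl, pucker_state(0, 70)),
               class = "ff_invalid_pucker")
})

test_that("exocyclic substituents ride rigidly with their anchor atoms", {
  tpl <- fx_template(5)
  co <- embed_ring(tpl, pucker_state(144, 38))
  # every bond length of the molecule is preserved by the embedding
  d_old <- sqrt(rowSums((template_coords(tpl)[tpl$bonds[, 1], ] -
                           template_coords(tpl)[tpl$bonds[, 2], ])^2))
  d_new <- sqrt(rowSums((co[tpl$bonds[, 1], ] - co[tpl$bonds[, 2], ])^2))
  expect_lt(max(abs(d_new - d_old)), 0.02)
})
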