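# Exact oracle grid: potentials at `pts` from point charges `q` at `xyz`.
grid_from_charges <- function(pts, xyz, q, environment = "vacuum") {
  v <- numeric(nrow(pts))
  for (a in seq_len(nrow(xyz)))
    v <- v + furanoseFF::COULOMB_CONSTANT * q[a] /
      sqrt(colSums((t(pts) - xyz[a, ])^2))
  esp_grid(pts, v, environment = environment)
}

test_that("a single-atom grid is inverted exactly", {
  xyz <- matrix(0, 1, 3)
  set.seed(2)
  u <- matrix(rnorm(90), 30, 3)
  pts <- 2.5 * u / sqrt(rowSums(u^2))     # sphere of radius 2.5 A
  g <- grid_from_charges(pts, xyz, 0.5)
  q <- fit_esp_charges(g, xyz, net_charge = 0.5)
  expect_equal(as.numeric(q), 0.5, tolerance = 1e-10)
})

test_that("the net-charge constraint holds exactly on every fit", {
  tpl <- fx_template(1)
  pts <- make_shell_grid(tpl, density = 0.5, seed = 3)
  set.seed(3)
  noisy <- esp_grid(pts, rnorm(nrow(pts)))   # pure noise target
  for (net in c(0, -1, 2)) {
    q <- fit_esp_charges(noisy, template_coords(tpl), net_charge = net)
    expect_lt(abs(sum(as.numeric(q)) - net), 1e-8)
  }
})

test_that("known charges on a 5-atom system are recovered from a noiseless grid", {
  set.seed(8)
  xyz <- matrix(rnorm(15, sd = 1.2), 5, 3)
  qtrue <- c(0.31, -0.52, 0.11, -0.27, 0.37)
  u <- matrix(rnorm(600), 200, 3)
  pts <- sweep(6 * u / sqrt(rowSums(u^2)), 2, colMeans(xyz), "+")
  g <- grid_from_charges(pts, xyz, qtrue)
  q <- fit_esp_charges(g, xyz, net_charge = sum(qtrue))
  expect_lt(max(abs(as.numeric(q) - qtrue)), 1e-6)
})

test_that("fitted residual beats random constraint-satisfying perturbations", {
  tpl <- fx_template(2)
  xyz <- template_coords(tpl)
  pts <- make_shell_grid(tpl, density = 0.5, seed = 9)
  set.seed(9)
  target <- esp_grid(pts, rnorm(nrow(pts), sd = 2))
  q <- fit_esp_charges(target, xyz, net_charge = 0)
  M <- furanoseFF::COULOMB_CONSTANT /
    vapply(seq_len(nrow(xyz)), function(a)
      sqrt(colSums((t(pts) - xyz[a, ])^2)), numeric(nrow(pts)))
  base <- sum((target$potentials - M %*% as.numeric(q))^2)
  for (k in 1:1000) {
    d <- rnorm(length(q), sd = 0.01)
    d <- d - mean(d)                       # keeps the net charge
    r <- sum((target$potentials - M %*% (as.numeric(q) + d))^2)
    expect_gte(r, base - 1e-8)
  }
})

test_that("noiseless grids are reproduced to numerical precision", {
  tpl <- fx_template(5)
  xyz <- template_coords(tpl)
  pts <- make_shell_grid(tpl, density = 2, seed = 12)
  expect_gte(nrow(pts), 10 * nrow(xyz))
  g <- grid_from_charges(pts, xyz, tpl$atoms$charge)
  q <- fit_esp_charges(g, xyz, net_charge = 0)
  M <- furanoseFF::COULOMB_CONSTANT /
    vapply(seq_len(nrow(xyz)), function(a)
      sqrt(colSums((t(pts) - xyz[a, ])^2)), numeric(nrow(pts)))
  rms <- sqrt(mean((g$potentials - M %*% as.numeric(q))^2))
  expect_lt(rms, 1e-6)
})

test_that("the implicitly polarized set is the vacuum/solvated midpoint", {
  qv <- charge_set(c(0.2, -0.2))
  expect_equal(as.numeric(combine_ipolq(qv, qv)), as.numeric(qv))
  qs <- charge_set(c(0.4, -0.4))
  expect_equal(as.numeric(combine_ipolq(qv, qs)), c(0.3, -0.3))
  expect_identical(attr(combine_ipolq(qv, qs), "environment"), "ipolq")
  expect_error(combine_ipolq(qv, charge_set(c(0.5, 0.5), net_charge = 1)),
               class = "ff_charge_mismatch")
})

test_that("midpoint combination is exact on constructed polarization", {
  tpl <- fx_template(7)
  oracle <- make_oracle(5, list(tpl))
  g <- oracle_esp_grids(tpl, oracle, density = 1, seed = 4)
  qv <- fit_esp_charges(g$vacuum, template_coords(tpl), 0)
  qs <- fit_esp_charges(g$solvated, template_coords(tpl), 0)
  qi <- combine_ipolq(qv, qs)
  expect_lt(max(abs(as.numeric(qi) -
                      (tpl$atoms$charge + oracle$delta_q[[1]] / 2))), 1e-6)
})

test_that("the five-percent charge rule follows its worked examples", {
  expect_true(converged_charges(0.500, 0.515))    # 3 %
  expect_false(converged_charges(0.500, 0.530))   # 6 %
  expect_true(converged_charges(0.000, 0.0004))   # under the 0.01 e floor
  expect_error(converged_charges(c(0.1, 0.2), 0.1),
               class = "ff_length_mismatch")
})

test_that("shell grids are seeded, density-scaled and clash-free", {
  tpl <- fx_template(1)
  a <- make_shell_grid(tpl, density = 1, seed = 6)
  b <- make_shell_grid(tpl, density = 1, seed = 6)
  expect_identical(a, b)
  c_ <- make_shell_grid(tpl, density = 2, seed = 6)
  ratio <- nrow(c_) / nrow(a)
  expect_gt(ratio, 1.8); expect_lt(ratio, 2.2)

  # distance audit: every point at least inner_scale * r* (and 1 A) from
  # every atom
  params <- default_parameters()
  xyz <- template_coords(tpl)
  rstar <- vapply(tpl$atoms$type,
                  function(t) params$nonbonded[[t]][1], numeric(1))
  for (at in seq_len(nrow(xyz))) {
    d <- sqrt(colSums((t(a) - xyz[at, ])^2))
    expect_gte(min(d), max(1.4 * rstar[at], 1.0) - 1e-12)
  }
})

test_that("degenerate grids raise typed errors", {
  xyz <- matrix(rnorm(9), 3, 3)
  pts <- rbind(xyz[1, ] + c(1e-8, 0, 0), c(5, 5, 5), c(-5, 5, 5))
  expect_error(fit_esp_charges(esp_grid(pts, rep(0, 3)), xyz, 0),
               class = "ff_point_on_atom")
  expect_error(fit_esp_charges(esp_grid(matrix(5, 1, 3), 0), xyz, 0),
               class = "ff_dimension_mismatch")
})
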