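# A small but identifiable fitting setup shared by several blocks: three
# templates whose substitution patterns jointly cover all seven refittable
# classes, each with a modest pose ensemble.
fit_fixture <- function(oracle_seed = 7, noise_sd = 0, poses = 10,
                        ids = c(1, 3, 11)) {
  tpls <- lapply(ids, fx_template)
  oracle <- make_oracle(oracle_seed, tpls, noise_sd = noise_sd)
  entries <- lapply(tpls, function(t) {
    fr <- random_poses(t, scan_spec(poses_per_window = poses, seed = 2))
    list(template = t, frames = fr,
         energies = reference_energies(t, fr, oracle)$energy)
  })
  list(problem = fit_problem(entries), oracle = oracle, entries = entries)
}

test_that("design matrix columns are 1 + cos(n phi) sums with offsets", {
  tpl <- fx_template(1)
  frames <- random_poses(tpl, scan_spec(interval_deg = 120,
                                        poses_per_window = 2, seed = 5))
  prob <- fit_problem(list(list(template = tpl, frames = frames,
                                energies = rep(0, length(frames)))))
  dm <- build_design_matrix(prob)
  expect_equal(nrow(dm$X), length(frames))
  expect_equal(ncol(dm$X), nrow(dm$cols) + 1)
  expect_true(all(dm$X[, ncol(dm$X)] == 1))  # offset indicator

  # unit-coefficient probe: the column equals the dihedral energy with
  # Vn = 1, gamma = 0 summed over the torsions of that class
  p0 <- furanoseFF:::zero_adjustable(prob$params, prob$adjustable)
  cs <- furanoseFF:::compile_system(tpl, p0)
  for (f in c(1, 4)) {
    phi_all <- furanoseFF:::torsion_angles_rad(frames$coords[, , f],
                                               cs$ta, cs$tb, cs$tc, cs$td)
    for (c_ in seq_len(nrow(dm$cols))) {
      sel <- cs$tkey == dm$cols$key[c_]
      probe <- sum(dihedral_term_energy(
        phi_all[sel] * 180 / pi,
        data.frame(n = dm$cols$n[c_], v = 1, gamma = 0)))
      expect_equal(dm$X[f, c_], probe, tolerance = 1e-10)
    }
  }

  # duplicated frames give duplicated rows
  dup <- bind_frames(frames[1], frames[1])
  prob2 <- fit_problem(list(list(template = tpl, frames = dup,
                                 energies = c(0, 0))))
  dm2 <- build_design_matrix(prob2)
  expect_equal(dm2$X[1, ], dm2$X[2, ])
})

test_that("a frame with an adjustable torsion at 180 contributes zero to n = 1", {
  expect_equal(1 + cos(pi), 0)  # the column entry the design uses
  coords <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))
  tpl <- chain_template(4, coords = coords, type = "oh")
  # single torsion oh-oh-oh-oh made adjustable
  key <- canonical_dihedral_key(c("oh", "oh", "oh", "oh"))
  prob <- fit_problem(list(list(template = tpl,
                                frames = conformer_set(coords),
                                energies = 0)),
                      adjustable = key, params = null_params(type = "oh"))
  dm <- build_design_matrix(prob)
  expect_equal(dm$X[1, which(dm$cols$n == 1)], 0, tolerance = 1e-12)
})

test_that("self-consistent references are reproduced exactly", {
  # joint fit across three substitution patterns so every class is
  # identifiable (single molecules confound ring-bond classes)
  entries <- lapply(c(2, 3, 11), function(i) {
    tpl <- fx_template(i)
    frames <- random_poses(tpl, scan_spec(poses_per_window = 4, seed = 6))
    list(template = tpl, frames = frames,
         energies = batch_energies(tpl, frames)$total)
  })
  prob <- fit_problem(entries)
  fit <- fit_torsions(prob)
  expect_lt(fit$sse, 1e-10)
  # the recovered terms reproduce the default parameter values
  p <- default_parameters()
  for (k in unique(fit$terms$key)) {
    truth <- p$dihedrals[[k]]
    for (i in seq_len(nrow(truth))) {
      row <- fit$terms[fit$terms$key == k & fit$terms$n == truth$n[i], ]
      expect_equal(row$v, truth$v[i], tolerance = 1e-6)
      expect_equal(row$gamma, truth$gamma[i])
    }
  }
})

test_that("hidden oracle coefficients are recovered from noiseless data", {
  fx <- fit_fixture(oracle_seed = 7, noise_sd = 0, poses = 10)
  fit <- fit_torsions(fx$problem)
  m <- merge(fit$terms, fx$oracle$true_terms, by = c("key", "n"),
             suffixes = c("_fit", "_true"))
  expect_equal(nrow(m), 21)  # all 7 classes x 3 periodicities
  expect_lt(max(abs(m$v_fit - m$v_true)), 1e-5)
  expect_identical(m$gamma_fit, as.numeric(m$gamma_true))
  expect_lt(fit$sse, 1e-10)
})

test_that("noisy references still recover coefficients (seeded)", {
  # hidden series V1 = 0.8 (gamma 0), V3 = 0.25 (gamma 180) on the
  # hydroxyl torsion class, Gaussian noise sd 0.5 kcal/mol
  key <- "c3-c3-oh-ho"
  tpls <- lapply(c(11, 12), fx_template)
  oracle <- make_oracle(17, tpls, noise_sd = 0.5, classes = key)
  oracle$true_terms <- data.frame(key = key, n = c(1, 3), v = c(0.8, 0.25),
                                  gamma = c(0, 180),
                                  stringsAsFactors = FALSE)
  oracle$hidden_params <- furanoseFF:::update_dihedral_params(
    default_parameters(), oracle$true_terms)
  entries <- lapply(tpls, function(t) {
    fr <- random_poses(t, scan_spec(poses_per_window = 124, seed = 2))
    list(template = t, frames = fr,
         energies = reference_energies(t, fr, oracle)$energy)
  })
  fit <- fit_torsions(fit_problem(entries, adjustable = key))
  m <- merge(fit$terms, oracle$true_terms, by = c("key", "n"),
             suffixes = c("_fit", "_true"))
  expect_equal(nrow(m), 2)
  expect_lt(max(abs(m$v_fit - m$v_true) / m$v_true), 0.10)
  expect_equal(m$gamma_fit, m$gamma_true)
})

test_that("the linearized solution matches exhaustive grid search", {
  # toy problem: one adjustable class, 30 frames, signed coefficients on a
  # grid (negative = gamma 180); brute-force SSE minimization
  tpl <- fx_template(11)
  frames <- random_poses(tpl, scan_spec(interval_deg = 36,
                                        poses_per_window = 3, seed = 13))
  key <- "c3-c3-oh-ho"
  oracle <- make_oracle(23, list(tpl), noise_sd = 0, classes = key)
  eref <- reference_energies(tpl, frames, oracle)$energy
  prob <- fit_problem(list(list(template = tpl, frames = frames,
                                energies = eref)), adjustable = key)
  fit <- fit_torsions(prob)
  dm <- build_design_matrix(prob)

  grid <- seq(-2, 2, by = 0.1)
  combos <- as.matrix(expand.grid(c1 = grid, c2 = grid, c3 = grid))
  E <- combos %*% t(dm$X[, 1:3])                 # candidate dihedral sums
  R <- sweep(E, 2, dm$y)                          # minus response
  R <- R - rowMeans(R)                            # optimal offset per cand.
  sse <- rowSums(R^2)
  best <- combos[which.min(sse), ]
  ours <- fit$terms$v * ifelse(fit$terms$gamma == 180, -1, 1)
  expect_lt(max(abs(ours - best)), 0.1 + 1e-9)   # within grid resolution
})

test_that("no candidate coefficient vector beats the least-squares SSE", {
  fx <- fit_fixture(oracle_seed = 31, noise_sd = 0.3, poses = 4)
  fit <- fit_torsions(fx$problem)
  dm <- build_design_matrix(fx$problem)
  signed <- fit$terms$v * ifelse(fit$terms$gamma == 180, -1, 1)
  set.seed(14)
  for (k in 1:1000) {
    cand <- signed + rnorm(length(signed), sd = 0.02)
    E <- as.numeric(dm$X[, seq_along(signed), drop = FALSE] %*% cand)
    r <- dm$y - E
    for (i in seq_len(dm$n_offsets)) {
      rows <- dm$entry_of == i
      r[rows] <- r[rows] - mean(r[rows])
    }
    expect_gte(sum(r^2), fit$sse - 1e-8)
  }
})

test_that("the five-percent torsion rule follows its worked examples", {
  mk <- function(v, gamma = 0) structure(
    list(terms = data.frame(key = "f-c3-c3-f", n = 1, v = v, gamma = gamma)),
    class = "torsion_fit")
  expect_true(converged_torsions(mk(1.00), mk(1.04)))   # 4 % change
  expect_false(converged_torsions(mk(1.00), mk(1.06)))  # 6 % change
  expect_false(converged_torsions(mk(1.00), mk(1.00, gamma = 180)))
  expect_error(converged_torsions(mk(1), structure(
    list(terms = data.frame(key = "oh-c3-c3-oh", n = 1, v = 1, gamma = 0)),
    class = "torsion_fit")), class = "ff_key_mismatch")
})

test_that("iterating with an identity charge stage converges at iteration 2", {
  tpl <- fx_template(2)
  frames <- random_poses(tpl, scan_spec(poses_per_window = 4, seed = 4))
  eref <- batch_energies(tpl, frames)$total
  prob <- fit_problem(list(list(template = tpl, frames = frames,
                                energies = eref)))
  res <- iterate_fit(prob, charge_refitter = NULL, max_outer = 10)
  expect_true(res$converged)
  expect_equal(res$iterations, 2)
  expect_lte(res$fit$sse, res$log$sse[1] + 1e-10)
})

test_that("max_outer below one returns an unconverged empty result", {
  tpl <- fx_template(1)
  frames <- random_poses(tpl, scan_spec(interval_deg = 120,
                                        poses_per_window = 2, seed = 1))
  prob <- fit_problem(list(list(template = tpl, frames = frames,
                                energies = rep(0, length(frames)))))
  expect_warning(res <- iterate_fit(prob, max_outer = 0),
                 class = "ff_not_converged")
  expect_false(res$converged)
  expect_equal(res$iterations, 0L)
})

test_that("model methods are coherent: coef, residuals, predict, simulate", {
  fx <- fit_fixture(oracle_seed = 3, noise_sd = 0, poses = 6)
  fit <- fit_torsions(fx$problem)
  expect_length(coef(fit), nrow(fit$terms))
  expect_equal(sum(residuals(fit)^2), fit$sse, tolerance = 1e-10)
  expect_equal(fitted(fit) + residuals(fit), fit$response, tolerance = 1e-10)

  e1 <- fx$entries[[1]]
  pred <- predict(fit, e1$template, e1$frames)
  expect_equal(pred, e1$energies, tolerance = 1e-6)

  sims <- simulate(fit, nsim = 2, seed = 5)
  expect_length(sims, 2)
  expect_length(sims[[1]], fit$n_frames)
  expect_identical(simulate(fit, nsim = 2, seed = 5)[[2]], sims[[2]])
})
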