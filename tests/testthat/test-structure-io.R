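test_that("mol2 templates round-trip at format precision", {
  tpl <- fx_template(1)
  f <- withr::local_tempfile(fileext = ".mol2")
  write_template(tpl, f)
  tpl2 <- read_template(f)
  expect_identical(tpl2$atoms$type, tpl$atoms$type)
  expect_identical(tpl2$atoms$name, tpl$atoms$name)
  expect_equal(tpl2$atoms$charge, tpl$atoms$charge)  # charges are 4-dp exact
  expect_lt(max(abs(template_coords(tpl2) - template_coords(tpl))), 1e-3)
  expect_identical(tpl2$ring, tpl$ring)
  expect_equal(sort(paste(tpl2$bonds[, 1], tpl2$bonds[, 2])),
               sort(paste(tpl$bonds[, 1], tpl$bonds[, 2])))
})

test_that("the furanose ring is detected with its single oxygen last", {
  tpl <- fx_template(7)
  expect_identical(tpl$atoms$element[tpl$ring], c("C", "C", "C", "C", "O"))
  # C1' is the anomeric carbon: it carries the exocyclic methoxy oxygen
  c1_nbrs <- tpl$adj[[tpl$ring[1]]]
  expect_true(any(tpl$atoms$element[setdiff(c1_nbrs, tpl$ring)] == "O"))
})

test_that("charge columns inconsistent with an integer net are rejected", {
  f <- withr::local_tempfile(fileext = ".mol2")
  writeLines(c(
    "@<TRIPOS>MOLECULE", "bad", " 2 1 1 0 0", "SMALL", "USER_CHARGES",
    "@<TRIPOS>ATOM",
    "      1 C1          0.0000    0.0000    0.0000 c3         1 MOL       0.1500",
    "      2 C2          1.5000    0.0000    0.0000 c3         1 MOL       0.1500",
    "@<TRIPOS>BOND",
    "     1    1    2 1"), f)
  expect_error(read_template(f), class = "ff_charge_mismatch")
})

test_that("frcmod files round-trip numerically", {
  p <- default_parameters()
  f <- withr::local_tempfile(fileext = ".frcmod")
  write_frcmod(p, f)
  p2 <- read_frcmod(f)
  expect_setequal(names(p2$bonds), names(p$bonds))
  for (k in names(p$bonds)) expect_equal(p2$bonds[[k]], p$bonds[[k]])
  for (k in names(p$angles)) expect_equal(p2$angles[[k]], p$angles[[k]])
  for (k in names(p$nonbonded)) expect_equal(p2$nonbonded[[k]],
                                             p$nonbonded[[k]])
  expect_setequal(names(p2$dihedrals), names(p$dihedrals))
  for (k in names(p$dihedrals)) {
    a <- p$dihedrals[[k]]; b <- p2$dihedrals[[k]]
    rownames(b) <- NULL
    expect_equal(b$n, a$n)
    expect_equal(b$v, a$v, tolerance = 1e-6)
    expect_equal(b$gamma, a$gamma)
  }
})

test_that("negative PN marks dihedral term continuation", {
  f <- withr::local_tempfile(fileext = ".frcmod")
  writeLines(c("test", "DIHE",
               "c3-c3-c3-f  1  0.200  0.0  -3.",
               "c3-c3-c3-f  1  0.250  180.0  1."), f)
  p <- read_frcmod(f)
  d <- p$dihedrals[["c3-c3-c3-f"]]
  expect_equal(d$n, c(3, 1))
  expect_equal(d$v, c(0.200, 0.250))
  expect_equal(d$gamma, c(0, 180))
})

test_that("PK / IDIVF and unsupported phases are honoured", {
  f <- withr::local_tempfile(fileext = ".frcmod")
  writeLines(c("test", "DIHE", "c3-c3-os-c3  2  0.600  0.0  3."), f)
  expect_equal(read_frcmod(f)$dihedrals[["c3-c3-os-c3"]]$v, 0.3)
  writeLines(c("test", "DIHE", "c3-c3-os-c3  1  0.600  120.0  3."), f)
  expect_error(read_frcmod(f), class = "ff_unsupported_phase")
  expect_warning(p <- read_frcmod(f, strict_phase = FALSE),
                 class = "ff_unsupported_phase")
  expect_equal(p$dihedrals[["c3-c3-os-c3"]]$gamma, 120)
})

test_that("canonical dihedral keys identify reversed quadruples", {
  expect_equal(canonical_dihedral_key(c("f", "c3", "c3", "oh")),
               canonical_dihedral_key(c("oh", "c3", "c3", "f")))
  set.seed(11)
  types <- c("c3", "os", "oh", "ho", "f", "h1", "X")
  for (k in 1:50) {
    q <- sample(types, 4, replace = TRUE)
    expect_equal(canonical_dihedral_key(q), canonical_dihedral_key(rev(q)))
  }
})

test_that("trajectories round-trip through multi-model PDB and XYZ", {
  tpl <- fx_template(1)
  frames <- scan_pseudorotation(tpl, scan_spec(interval_deg = 120))
  for (ext in c(".pdb", ".xyz")) {
    f <- withr::local_tempfile(fileext = ext)
    write_trajectory(frames, f)
    back <- read_trajectory(f)
    expect_equal(length(back), 3)
    expect_lt(max(abs(back$coords - frames$coords)), 1e-3)
    expect_identical(unique(back$meta$provenance), "external")
  }
})

test_that("malformed XYZ frames are reported by index", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "frame 1",
               "C 0 0 0", "C 1 0 0",
               "2", "frame 2",
               "C 0 0 0", "C 1 0 bad"), f)
  expect_error(read_trajectory(f), regexp = "frame 2",
               class = "ff_inconsistent_frame")
})

test_that("energy tables and ESP grids round-trip", {
  tab <- data.frame(template_id = "T01", frame_id = 1:3,
                    energy = c(-1.25, 0.5, 3.75), environment = "reference",
                    stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_energy_table(tab, f)
  expect_equal(read_energy_table(f), tab)

  g <- esp_grid(matrix(rnorm(30), 10, 3), rnorm(10), "solvated", "T01")
  f2 <- withr::local_tempfile(fileext = ".esp")
  write_esp_grid(g, f2)
  g2 <- read_esp_grid(f2)
  expect_identical(g2$environment, "solvated")
  expect_lt(max(abs(g2$points - g$points)), 1e-7)
  expect_lt(max(abs(g2$potentials - g$potentials)), 1e-9)
})
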