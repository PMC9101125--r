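# Shared fixtures, built once per test run.

.fx <- new.env(parent = emptyenv())

fx_template <- function(i) {
  key <- paste0("t", i)
  if (is.null(.fx[[key]])) .fx[[key]] <- furanose_template(i)
  .fx[[key]]
}

# Linear chain of n atoms along x (1 A spacing unless coords given), all the
# same atom type; ring-free, for energy-term unit tests.
chain_template <- function(n, charges = rep(0, n), coords = NULL,
                           type = "c3") {
  if (is.null(coords)) coords <- cbind(seq_len(n) - 1, 0, 0)
  atoms <- data.frame(name = paste0("A", seq_len(n)), element = "C",
                      type = type, charge = charges,
                      x = coords[, 1], y = coords[, 2], z = coords[, 3],
                      stringsAsFactors = FALSE)
  bonds <- cbind(seq_len(n - 1), 2:n)
  molecular_template(atoms, bonds, net_charge = sum(charges), ring = NA,
                     id = "chain")
}

# Parameter set in which every term of the chain evaluates to zero energy
# except what the test switches on.
null_params <- function(type = "c3", dihedrals = list()) {
  force_field_parameters(
    bonds = stats::setNames(list(c(0, 1.0)), canonical_bond_key(type, type)),
    angles = stats::setNames(list(c(0, 109.5)),
                             canonical_angle_key(type, type, type)),
    dihedrals = c(stats::setNames(
      list(data.frame(n = 1, v = 0, gamma = 0)),
      canonical_dihedral_key(c("X", type, type, "X"))), dihedrals),
    nonbonded = stats::setNames(list(c(0, 0)), type))
}

# Seeded random pucker states for round-trip properties.
random_pucker_states <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(phase = runif(n, 0, 360), amplitude = runif(n, 1, 55))
}
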