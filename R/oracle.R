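#' Synthetic oracle for parameter-recovery testing
#'
#' Builds a self-consistent set of hidden "true" inputs so that every
#' fitting stage can be validated by parameter recovery without external
#' quantum-chemistry software: hidden torsion coefficients for the seven
#' refittable dihedral classes (Vn uniform in [0.05, 2] kcal/mol, gamma
#' random in {0, 180}, periodicities 1..3), hidden vacuum charges (the
#' template charges), a polarization perturbation delta-q per template
#' (uniform in +/- 0.05 e, zero-sum), a hidden constant energy offset per
#' template (uniform in +/- 5 kcal/mol, which forces the fitter's offset
#' columns to earn their keep), and a homoscedastic Gaussian noise level.
#' Everything is deterministic per master seed.
#'
#' @param seed master integer seed.
#' @param templates list of `molecular_template` objects.
#' @param params visible base parameters; hidden parameters replace the
#'   refittable classes only.
#' @param noise_sd Gaussian noise standard deviation for reference
#'   energies, kcal/mol (default 0).
#' @param classes dihedral classes to hide (default the seven fitted
#'   classes).
#' @return An object of class `oracle_spec`.
#' @export
make_oracle <- function(seed, templates, params = default_parameters(),
                        noise_sd = 0, classes = fitted_dihedral_classes()) {
  stopifnot(noise_sd >= 0)
  templates <- if (inherits(templates, "molecular_template")) list(templates)
  else templates
  oracle <- with_seed(seed, {
    hidden <- params
    true_terms <- do.call(rbind, lapply(classes, function(k)
      data.frame(key = k, n = 1:3,
                 v = round(runif(3, 0.05, 2.0), 6),
                 gamma = sample(c(0, 180), 3, replace = TRUE),
                 stringsAsFactors = FALSE)))
    hidden <- update_dihedral_params(hidden, true_terms)
    dq <- lapply(templates, function(t) {
      n <- nrow(t$atoms)
      d <- runif(n, -0.05, 0.05)
      d - mean(d)  # zero-sum: polarization conserves the net charge
    })
    offs <- stats::setNames(round(runif(length(templates), -5, 5), 6),
                            vapply(templates, `[[`, character(1), "id"))
    list(hidden_params = hidden, true_terms = true_terms, delta_q = dq,
         offsets = offs)
  })
  structure(list(seed = as.integer(seed),
                 template_ids = vapply(templates, `[[`, character(1), "id"),
                 templates = templates,
                 hidden_params = oracle$hidden_params,
                 true_terms = oracle$true_terms,
                 delta_q = oracle$delta_q,
                 offsets = oracle$offsets,
                 noise_sd = noise_sd),
            class = "oracle_spec")
}

#' @export
print.oracle_spec <- function(x, ...) {
  cat(sprintf(
    "<oracle_spec> seed %d, %d templates, noise sd %g kcal/mol\n",
    x$seed, length(x$template_ids), x$noise_sd))
  invisible(x)
}

#' Synthetic reference energies
#'
#' Emulates quantum single-point reference energies: the MM energy under
#' the hidden parameter set, plus the hidden per-template constant offset,
#' plus seeded Gaussian noise of the oracle's noise level.
#'
#' @param template a `molecular_template` known to the oracle.
#' @param frames a `conformer_set` for that template.
#' @param oracle an `oracle_spec`.
#' @return data.frame in reference-energy-table form: `template_id`,
#'   `frame_id`, `energy` (kcal/mol), `environment`.
#' @export
reference_energies <- function(template, frames, oracle) {
  stopifnot(inherits(oracle, "oracle_spec"))
  i <- match(template$id, oracle$template_ids)
  if (is.na(i))
    ff_stop(paste("template", template$id, "is unknown to the oracle"),
            "key_mismatch")
  # evaluate against the oracle's own stored template: the hidden charges
  # are frozen at oracle creation, whatever later refits do to the caller's
  # template
  e <- batch_energies(oracle$templates[[i]], frames,
                      oracle$hidden_params)$total +
    oracle$offsets[[template$id]]
  if (oracle$noise_sd > 0) {
    # sub-seed decorrelates templates while keeping everything reproducible
    e <- e + with_seed(oracle$seed + 7919L * i,
                       stats::rnorm(length(e), 0, oracle$noise_sd))
  }
  data.frame(template_id = template$id, frame_id = seq_along(e),
             energy = e, environment = "reference",
             stringsAsFactors = FALSE)
}

#' Synthetic vacuum and solvated ESP grids
#'
#' Potentials are generated from point charges on the template atoms:
#' the template charges for the vacuum grid, and the same charges plus
#' the oracle's polarization perturbation delta-q for the solvated grid.
#' Both environments share one point set.
#'
#' @param template a `molecular_template` known to the oracle.
#' @param oracle an `oracle_spec`.
#' @param density grid density, points per cubic Angstrom.
#' @param seed grid-sampling seed.
#' @return List with elements `vacuum` and `solvated`, both `esp_grid`s.
#' @export
oracle_esp_grids <- function(template, oracle, density = 2, seed = 1L) {
  i <- match(template$id, oracle$template_ids)
  if (is.na(i))
    ff_stop(paste("template", template$id, "is unknown to the oracle"),
            "key_mismatch")
  template <- oracle$templates[[i]]  # hidden charges are frozen
  pts <- make_shell_grid(template, density = density, seed = seed)
  xyz <- template_coords(template)
  pot_from <- function(q) {
    v <- numeric(nrow(pts))
    for (a in seq_len(nrow(xyz))) {
      d <- sqrt(colSums((t(pts) - xyz[a, ])^2))
      v <- v + COULOMB_CONSTANT * q[a] / d
    }
    v
  }
  q_vac <- template$atoms$charge
  q_solv <- q_vac + oracle$delta_q[[i]]
  list(vacuum = esp_grid(pts, pot_from(q_vac), "vacuum", template$id),
       solvated = esp_grid(pts, pot_from(q_solv), "solvated", template$id))
}

#' Charge-refitting stage backed by oracle ESP grids
#'
#' Returns a function suitable as the `charge_refitter` argument of
#' [iterate_fit()]: at each outer iteration it fits vacuum and solvated
#' charges to the oracle's grids.  By convention the torsion-fitting
#' stage consumes the vacuum-fit charge set (`use = "vacuum"`, the
#' workflow's convention for energy fitting); the implicitly polarized
#' midpoint (`use = "ipolq"`) is the set a simulation would take away.
#'
#' @param oracle an `oracle_spec`.
#' @param density grid density.
#' @param restraint_weight harmonic restraint toward the previous
#'   iteration's charges (default 1e-4 for stability).
#' @param use which charge set the stage returns: `"vacuum"` or
#'   `"ipolq"`.
#' @return A function `(templates, iteration) -> list of charge vectors`.
#' @export
oracle_charge_refitter <- function(oracle, density = 2,
                                   restraint_weight = 1e-4,
                                   use = c("vacuum", "ipolq")) {
  force(oracle)
  use <- match.arg(use)
  function(templates, iteration) {
    lapply(templates, function(t) {
      g <- oracle_esp_grids(t, oracle, density = density,
                            seed = oracle$seed + iteration)
      prior <- t$atoms$charge
      qv <- fit_esp_charges(g$vacuum, template_coords(t), t$net_charge,
                            restraint_weight, prior)
      if (use == "vacuum") return(as.numeric(qv))
      qs <- fit_esp_charges(g$solvated, template_coords(t), t$net_charge,
                            restraint_weight, prior)
      as.numeric(combine_ipolq(qv, qs))
    })
  }
}
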