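#' Torsion-fitting problems
#'
#' Bundles the data needed to refit dihedral Fourier coefficients: one or
#' more (template, conformer set, reference energies) triples, the set of
#' adjustable dihedral type classes, and the fixed parameter set supplying
#' every non-adjustable term.  Reference and MM energy zeros are
#' incommensurate, so a free constant offset per molecule is always part
#' of the model.
#'
#' @param entries list of lists, each with elements `template`
#'   (`molecular_template`), `frames` (`conformer_set`) and `energies`
#'   (numeric, kcal/mol, one per frame).
#' @param adjustable character vector of dihedral type keys to refit
#'   (canonicalized); defaults to the seven fluoro/hydroxy classes of
#'   [fitted_dihedral_classes()].
#' @param params fixed `force_field` parameters for all other terms.
#' @return An object of class `fit_problem`.
#' @export
fit_problem <- function(entries, adjustable = fitted_dihedral_classes(),
                        params = default_parameters()) {
  stopifnot(length(entries) >= 1)
  for (e in entries) {
    stopifnot(inherits(e$template, "molecular_template"),
              inherits(e$frames, "conformer_set"))
    if (length(e$energies) != length(e$frames))
      ff_stop(sprintf("template %s: %d energies for %d frames",
                      e$template$id, length(e$energies), length(e$frames)),
              "length_mismatch")
    if (any(!is.finite(e$energies)))
      ff_stop("non-finite reference energies", "parse_error")
  }
  adjustable <- vapply(adjustable, canonical_dihedral_key, character(1))
  structure(list(entries = entries, adjustable = unname(adjustable),
                 params = params),
            class = "fit_problem")
}

## Parameter set with the adjustable dihedral classes zeroed out (an empty
## term table still shadows any wildcard).
zero_adjustable <- function(params, adjustable) {
  for (k in adjustable)
    params$dihedrals[[k]] <- data.frame(n = numeric(0), v = numeric(0),
                                        gamma = numeric(0))
  params
}

#' Design matrix of the linearized torsion fit
#'
#' The dihedral energy is linear in the barrier coefficients Vn at fixed
#' coordinates, so the fit is ordinary least squares: one row per frame,
#' one column per (adjustable class, periodicity n) pair holding the sum
#' over matching torsions of 1 + cos(n phi), plus one indicator column per
#' molecule for the free energy offset.  The response is the reference
#' energy minus the MM energy of all non-adjustable terms.
#'
#' @param problem a [fit_problem()].
#' @return List with the design matrix `X`, response `y`, a data.frame
#'   `cols` describing the coefficient columns (key, n), the number of
#'   offset columns, per-row entry indices, and per-row target phases.
#' @export
build_design_matrix <- function(problem) {
  adjustable <- problem$adjustable
  p0 <- zero_adjustable(problem$params, adjustable)
  nent <- length(problem$entries)

  blocks <- vector("list", nent)
  present <- character(0)
  for (i in seq_len(nent)) {
    e <- problem$entries[[i]]
    cs <- compile_system(e$template, p0)
    keep <- which(cs$tkey %in% adjustable)
    present <- union(present, unique(cs$tkey[keep]))
    blocks[[i]] <- list(cs = cs, keep = keep)
  }
  if (!length(present))
    ff_stop("no adjustable dihedral class occurs in any template topology",
            "no_adjustable_terms")
  present <- adjustable[adjustable %in% present]
  cols <- expand.grid(n = 1:3, key = present, stringsAsFactors = FALSE)
  cols <- cols[, c("key", "n")]

  nrows <- sum(vapply(problem$entries, function(e) length(e$frames),
                      integer(1)))
  counts <- matrix(0L, nent, nrow(cols))
  X <- matrix(0, nrows, nrow(cols) + nent)
  y <- numeric(nrows)
  entry_of <- integer(nrows)
  phase_of <- numeric(nrows)
  row0 <- 0L
  for (i in seq_len(nent)) {
    e <- problem$entries[[i]]
    cs <- blocks[[i]]$cs
    keep <- blocks[[i]]$keep
    nf <- length(e$frames)
    rows <- row0 + seq_len(nf)
    counts[i, ] <- vapply(seq_len(nrow(cols)), function(c_)
      sum(cs$tkey[keep] == cols$key[c_]), integer(1))
    efix <- numeric(nf)
    for (f in seq_len(nf)) {
      coords <- e$frames$coords[, , f]
      efix[f] <- evaluate_compiled(cs, coords)$total
      if (length(keep)) {
        phi <- torsion_angles_rad(coords, cs$ta[keep], cs$tb[keep],
                                  cs$tc[keep], cs$td[keep])
        for (c_ in seq_len(nrow(cols))) {
          m <- cs$tkey[keep] == cols$key[c_]
          if (any(m))
            X[rows[f], c_] <- sum(1 + cos(cols$n[c_] * phi[m]))
        }
      }
    }
    X[rows, nrow(cols) + i] <- 1
    y[rows] <- e$energies - efix
    entry_of[rows] <- i
    phase_of[rows] <- e$frames$meta$phase_target
    row0 <- row0 + nf
  }
  list(X = X, y = y, cols = cols, n_offsets = nent, entry_of = entry_of,
       phase_of = phase_of, counts = counts)
}

#' Fit dihedral Fourier coefficients by least squares
#'
#' Minimizes the residual between reference energies and the MM energy
#' over the barrier coefficients Vn of the adjustable dihedral classes
#' (periodicities 1..3) and one free offset per molecule.  The phase
#' gamma is constrained to {0, 180}: a negative linear coefficient is
#' reported as (|Vn|, gamma = 180) through the identity
#' Vn [1 + cos(n phi - 180)] = Vn [1 - cos(n phi)] (the absorbed constant
#' moves into the molecule offset), which is exactly equivalent to a
#' discrete search over gamma and deterministic.
#'
#' @param problem a [fit_problem()].
#' @param ridge regularization added to the normal equations only if the
#'   design matrix is column-rank deficient (flagged in the result).
#' @return An object of class `torsion_fit` with components `terms`
#'   (data.frame key, n, v, gamma), `offsets` (kcal/mol, one per
#'   molecule), `sse`, `residuals`, `fitted`, `rank_deficient`, and the
#'   data needed by the methods ([predict.torsion_fit()],
#'   [plot.torsion_fit()], ...).
#' @examples
#' tpl <- furanose_template(1)
#' frames <- random_poses(tpl, scan_spec(interval_deg = 90,
#'                                       poses_per_window = 6, seed = 1))
#' eref <- batch_energies(tpl, frames)$total
#' fit <- fit_torsions(fit_problem(list(list(template = tpl, frames = frames,
#'                                           energies = eref))))
#' coef(fit)
#' @export
fit_torsions <- function(problem, ridge = 1e-8) {
  stopifnot(inherits(problem, "fit_problem"))
  dm <- build_design_matrix(problem)
  X <- dm$X; y <- dm$y
  if (nrow(X) < ncol(X))
    ff_stop(sprintf("%d frames cannot determine %d coefficients",
                    nrow(X), ncol(X)), "dimension_mismatch")
  qrX <- qr(X)
  rank_deficient <- qrX$rank < ncol(X)
  if (rank_deficient) {
    null_cols <- setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])
    keys <- unique(dm$cols$key[null_cols[null_cols <= nrow(dm$cols)]])
    ff_warn(paste("design matrix is rank deficient; ridge fallback used.",
                  if (length(keys)) paste("null-space classes:",
                                          paste(keys, collapse = ", "))),
            "rank_deficient")
    beta <- solve(crossprod(X) + diag(ridge, ncol(X)), crossprod(X, y))
    beta <- as.numeric(beta)
  } else {
    beta <- qr.coef(qrX, y)
  }
  cvals <- beta[seq_len(nrow(dm$cols))]
  terms <- data.frame(key = dm$cols$key, n = dm$cols$n,
                      v = abs(cvals),
                      gamma = ifelse(cvals < 0, 180, 0),
                      stringsAsFactors = FALSE)

  # dihedral energies in the reported (Vn, gamma) form: a gamma = 180 term
  # contributes Vn (2 count - sum(1 + cos n phi)); offsets are then the
  # per-molecule mean residuals, which is their least-squares value
  ncols <- nrow(dm$cols)
  adj <- matrix(0, length(y), ncols)
  for (c_ in seq_len(ncols)) {
    if (cvals[c_] >= 0) {
      adj[, c_] <- cvals[c_] * dm$X[, c_]
    } else {
      adj[, c_] <- -cvals[c_] *
        (2 * dm$counts[dm$entry_of, c_] - dm$X[, c_])
    }
  }
  adj_energy <- rowSums(adj)
  offsets <- numeric(dm$n_offsets)
  fitted <- numeric(length(y))
  for (i in seq_len(dm$n_offsets)) {
    rows <- dm$entry_of == i
    offsets[i] <- mean(y[rows] - adj_energy[rows])
    fitted[rows] <- adj_energy[rows] + offsets[i]
  }
  residuals <- y - fitted
  ids <- vapply(problem$entries, function(e) e$template$id, character(1))
  names(offsets) <- ids

  structure(list(terms = terms, offsets = offsets,
                 sse = sum(residuals^2), residuals = residuals,
                 fitted = fitted, response = y,
                 entry_of = dm$entry_of, phase_of = dm$phase_of,
                 rank_deficient = rank_deficient,
                 adjustable = problem$adjustable,
                 n_frames = length(y), template_ids = ids),
            class = "torsion_fit")
}

#' Five-percent convergence rule for torsion coefficients
#'
#' Two successive fits are converged when every barrier coefficient
#' changed by less than `tol` (relative, with a small floor guarding
#' division by near-zero values) and every gamma kept its value.
#'
#' @param prev,new `torsion_fit` objects over the same classes.
#' @param tol relative tolerance (default 0.05, the 5 percent rule).
#' @param floor minimum denominator, kcal/mol (default 0.01).
#' @return TRUE or FALSE.
#' @export
converged_torsions <- function(prev, new, tol = 0.05, floor = 0.01) {
  kp <- paste(prev$terms$key, prev$terms$n)
  kn <- paste(new$terms$key, new$terms$n)
  if (!identical(sort(kp), sort(kn)))
    ff_stop("the two fits cover different dihedral terms", "key_mismatch")
  o <- match(kp, kn)
  dv <- abs(new$terms$v[o] - prev$terms$v) /
    pmax(abs(prev$terms$v), floor)
  same_gamma <- new$terms$gamma[o] == prev$terms$gamma
  all(dv < tol) && all(same_gamma)
}

#' Alternate torsion fitting with charge refitting until convergence
#'
#' Runs the outer loop of the parameterization workflow: each iteration
#' optionally refits the partial charges (any callable stage; the
#' identity is used when `charge_refitter` is NULL), then refits the
#' torsion coefficients with the current charges, and declares
#' convergence when both five-percent rules pass against the previous
#' iteration.  The supplied starting parameters are used only on
#' iteration 1; later iterations start from the previous fit.
#'
#' @param problem a [fit_problem()].
#' @param charge_refitter NULL, or a function
#'   `function(templates, iteration)` returning a list of per-template
#'   charge vectors (summing to each net charge).
#' @param max_outer iteration cap.
#' @param tol convergence tolerance for both five-percent rules.
#' @return An object of class `ipolq_fit`: the final `torsion_fit`, the
#'   updated `force_field`, the per-iteration log, `converged`, and
#'   `iterations`.
#' @export
iterate_fit <- function(problem, charge_refitter = NULL, max_outer = 10,
                        tol = 0.05) {
  stopifnot(inherits(problem, "fit_problem"))
  if (max_outer < 1) {
    ff_warn("max_outer < 1: no iterations run", "not_converged")
    return(structure(list(fit = NULL, params = problem$params,
                          log = data.frame(), converged = FALSE,
                          iterations = 0L),
                     class = "ipolq_fit"))
  }
  params <- problem$params
  prev_fit <- NULL
  prev_charges <- lapply(problem$entries,
                         function(e) e$template$atoms$charge)
  log <- data.frame()
  converged <- FALSE
  fit <- NULL
  for (it in seq_len(max_outer)) {
    charges_ok <- TRUE
    if (!is.null(charge_refitter)) {
      templates <- lapply(problem$entries, `[[`, "template")
      new_charges <- charge_refitter(templates, it)
      charges_ok <- all(mapply(function(p, q)
        converged_charges(p, q, tol = tol), prev_charges, new_charges))
      for (i in seq_along(problem$entries))
        problem$entries[[i]]$template <-
        set_template_charges(problem$entries[[i]]$template, new_charges[[i]])
      prev_charges <- new_charges
    }
    problem$params <- params
    fit <- fit_torsions(problem)
    torsions_ok <- !is.null(prev_fit) && converged_torsions(prev_fit, fit,
                                                            tol = tol)
    max_dv <- if (is.null(prev_fit)) NA_real_ else
      max(abs(fit$terms$v - prev_fit$terms$v))
    log <- rbind(log, data.frame(iteration = it, sse = fit$sse,
                                 max_delta_v = max_dv,
                                 charges_converged = charges_ok,
                                 torsions_converged = torsions_ok))
    params <- update_dihedral_params(params, fit$terms)
    prev_fit <- fit
    if (torsions_ok && charges_ok) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    ff_warn(sprintf("no convergence after %d outer iterations", max_outer),
            "not_converged")
  structure(list(fit = fit, params = params, log = log,
                 converged = converged, iterations = nrow(log)),
            class = "ipolq_fit")
}

## Replace the fitted classes' term tables inside a parameter set.
update_dihedral_params <- function(params, terms) {
  for (k in unique(terms$key)) {
    rows <- terms[terms$key == k & terms$v > 0, c("n", "v", "gamma")]
    # an empty table still shadows wildcards and contributes zero energy
    params$dihedrals[[k]] <- data.frame(n = rows$n, v = rows$v,
                                        gamma = rows$gamma)
  }
  params
}

#' @export
print.ipolq_fit <- function(x, ...) {
  cat(sprintf("<ipolq_fit> %d iteration(s), %s\n", x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  if (!is.null(x$fit))
    cat(sprintf("  final SSE %.6g kcal^2/mol^2 over %d frames\n",
                x$fit$sse, x$fit$n_frames))
  invisible(x)
}
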