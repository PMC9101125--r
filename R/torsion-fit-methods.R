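#' @export
print.torsion_fit <- function(x, ...) {
  cat(sprintf("<torsion_fit> %d dihedral terms over %d frames, SSE %.6g\n",
              nrow(x$terms), x$n_frames, x$sse))
  if (x$rank_deficient) cat("  (rank-deficient design; ridge fallback)\n")
  invisible(x)
}

#' @export
summary.torsion_fit <- function(object, ...) {
  res <- object$residuals
  out <- list(terms = object$terms, offsets = object$offsets,
              sse = object$sse, rmse = sqrt(mean(res^2)),
              n_frames = object$n_frames,
              rank_deficient = object$rank_deficient,
              regression = origin_regression(object$response -
                                               object$offsets[object$entry_of],
                                             object$fitted -
                                               object$offsets[object$entry_of]))
  class(out) <- "summary.torsion_fit"
  out
}

#' @export
print.summary.torsion_fit <- function(x, ...) {
  cat(sprintf("Torsion coefficient fit over %d frames\n", x$n_frames))
  cat(sprintf("  SSE %.6g kcal^2/mol^2, RMSE %.4g kcal/mol\n", x$sse, x$rmse))
  cat(sprintf("  fitted-vs-reference (through origin): slope %.4f, r^2 %.4f\n",
              x$regression$slope, x$regression$r_squared))
  if (x$rank_deficient) cat("  rank-deficient design; ridge fallback used\n")
  cat("\nFitted terms (Vn kcal/mol, gamma deg):\n")
  print(x$terms, row.names = FALSE)
  cat("\nPer-molecule offsets (kcal/mol):\n")
  print(round(x$offsets, 4))
  invisible(x)
}

#' Fitted dihedral coefficients
#'
#' Returns the signed linear coefficients of the fit, named
#' `"<class>:n<periodicity>"`: the value is Vn for gamma = 0 terms and
#' -Vn for gamma = 180 terms (the two encodings are equivalent up to a
#' constant absorbed by the molecule offsets).
#'
#' @param object a `torsion_fit`.
#' @param ... unused.
#' @return Named numeric vector.
#' @export
coef.torsion_fit <- function(object, ...) {
  v <- object$terms$v * ifelse(object$terms$gamma == 180, -1, 1)
  names(v) <- sprintf("%s:n%d", object$terms$key, object$terms$n)
  v
}

#' @export
residuals.torsion_fit <- function(object, ...) object$residuals

#' @export
fitted.torsion_fit <- function(object, ...) object$fitted

#' Predict reference energies for new conformations
#'
#' Evaluates the fitted model (fixed MM terms + fitted dihedral series +
#' the molecule offset) for frames of a template that was part of the fit.
#'
#' @param object a `torsion_fit`.
#' @param template a `molecular_template` whose id appeared in the fit.
#' @param frames a `conformer_set` for that template.
#' @param params the fixed parameter set used in the fit.
#' @param ... unused.
#' @return Numeric vector of predicted reference energies (kcal/mol).
#' @export
predict.torsion_fit <- function(object, template, frames,
                                params = default_parameters(), ...) {
  i <- match(template$id, object$template_ids)
  if (is.na(i))
    ff_stop(paste("template", template$id, "was not part of the fit"),
            "key_mismatch")
  params <- update_dihedral_params(zero_adjustable(params, object$adjustable),
                                   object$terms)
  batch_energies(template, frames, params)$total + object$offsets[i]
}

#' Residuals against pseudorotation phase
#'
#' Scatter of per-frame fit residuals versus the target phase of each
#' frame's window, one panel-less base-graphics plot.
#'
#' @param x a `torsion_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.torsion_fit <- function(x, ...) {
  graphics::plot(x$phase_of, x$residuals,
                 xlab = "target pseudorotation phase (deg)",
                 ylab = "residual (kcal/mol)",
                 main = "Torsion fit residuals", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Simulate reference energies from a fitted model
#'
#' Draws new reference-energy vectors as fitted values plus Gaussian noise
#' with the residual standard deviation, one list element per simulation.
#'
#' @param object a `torsion_fit`.
#' @param nsim number of simulated vectors.
#' @param seed integer seed.
#' @param ... unused.
#' @return List of numeric vectors of length `n_frames`.
#' @export
simulate.torsion_fit <- function(object, nsim = 1, seed = 1L, ...) {
  sigma <- sqrt(object$sse / max(1, object$n_frames - nrow(object$terms) -
                                   length(object$offsets)))
  with_seed(seed, lapply(seq_len(nsim), function(k)
    object$fitted + stats::rnorm(object$n_frames, 0, sigma)))
}
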