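#' Phase-angle series of a trajectory
#'
#' Computes the pseudorotation phase and amplitude of every frame and
#' remaps phases to (-180, 180], the convention used for North/South
#' analysis (North is the hemicycle around P = 0).
#'
#' @param frames a `conformer_set`.
#' @param ring integer vector of the five ring-atom indices (C1', C2',
#'   C3', C4', O4' order), e.g. `template$ring`.
#' @return data.frame with columns `phase_deg` in (-180, 180] and
#'   `amplitude_deg`, one row per frame.
#' @export
phase_series <- function(frames, ring) {
  stopifnot(inherits(frames, "conformer_set"), length(ring) == 5)
  n <- length(frames)
  out <- data.frame(phase_deg = numeric(n), amplitude_deg = numeric(n))
  for (f in seq_len(n)) {
    s <- tryCatch(
      phase_from_ring_coords(frames$coords[, , f], ring),
      error = function(e) ff_stop(
        sprintf("frame %d: %s", f, conditionMessage(e)), "zero_amplitude"))
    out$phase_deg[f] <- norm180(s$phase_deg)
    out$amplitude_deg[f] <- s$amplitude_deg
  }
  out
}

#' Percent North
#'
#' Fraction of frames whose phase lies in the Northern hemicycle,
#' -90 <= P < 90 (the boundary frame at exactly P = 90 counts South, a
#' deterministic tie rule).  %N and %S add to exactly 100.
#'
#' @param series data.frame from [phase_series()], or a numeric vector of
#'   phases in degrees.
#' @return Percentage in [0, 100].
#' @export
percent_north <- function(series) {
  p <- if (is.data.frame(series)) series$phase_deg else as.numeric(series)
  if (!length(p)) ff_stop("empty phase series", "empty_series")
  p <- norm180(p)
  100 * sum(p >= -90 & p < 90) / length(p)
}

#' Phase probability histogram
#'
#' Left-closed, right-open bins over (-180, 180]; bin probabilities are
#' frame counts over the total and sum to one.
#'
#' @param series data.frame from [phase_series()] or numeric phases (deg).
#' @param bin_deg bin width in degrees; must divide 360 (default 18).
#' @return List of class `phase_histogram` with `breaks` (bin edges),
#'   `mid` (bin centres), `probability` (per-bin), and `percent_north`.
#' @export
phase_histogram <- function(series, bin_deg = 18) {
  if (360 %% bin_deg != 0)
    ff_stop("bin width must divide 360", "bad_bin_width")
  p <- if (is.data.frame(series)) series$phase_deg else as.numeric(series)
  if (!length(p)) ff_stop("empty phase series", "empty_series")
  p <- norm180(p)
  breaks <- seq(-180, 180, by = bin_deg)
  idx <- pmin(floor((p + 180) / bin_deg) + 1, length(breaks) - 1)
  counts <- tabulate(idx, nbins = length(breaks) - 1)
  structure(list(breaks = breaks, mid = breaks[-1] - bin_deg / 2,
                 probability = counts / length(p),
                 percent_north = percent_north(p)),
            class = "phase_histogram")
}

#' @export
print.phase_histogram <- function(x, ...) {
  cat(sprintf("<phase_histogram> %d bins of %g deg, %%N = %.2f\n",
              length(x$probability), diff(x$breaks)[1], x$percent_north))
  invisible(x)
}

#' Per-window energy-error statistics
#'
#' The energy error of a frame is EE = E_MM - E_ref.  Within each phase
#' window the mean mu and population standard deviation sigma (n divisor)
#' are reported, together with the mu +/- sigma and mu +/- 2 sigma
#' envelopes and the pooled global statistics.
#'
#' @param mm_energies,ref_energies aligned numeric vectors (kcal/mol).
#' @param windows vector of window labels, one per frame.
#' @return List with data.frame `by_window` (window, n, mu, sigma,
#'   lo1, hi1, lo2, hi2) and `global` (mu, sigma).
#' @export
window_error_stats <- function(mm_energies, ref_energies, windows) {
  if (length(mm_energies) != length(ref_energies) ||
      length(mm_energies) != length(windows))
    ff_stop("energy and window vectors differ in length", "length_mismatch")
  ee <- mm_energies - ref_energies
  sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
  lev <- unique(windows)
  by_window <- do.call(rbind, lapply(lev, function(w) {
    x <- ee[windows == w]
    data.frame(window = w, n = length(x), mu = mean(x), sigma = sd_pop(x))
  }))
  by_window$lo1 <- by_window$mu - by_window$sigma
  by_window$hi1 <- by_window$mu + by_window$sigma
  by_window$lo2 <- by_window$mu - 2 * by_window$sigma
  by_window$hi2 <- by_window$mu + 2 * by_window$sigma
  list(by_window = by_window,
       global = c(mu = mean(ee), sigma = sd_pop(ee)))
}

#' Through-origin regression of MM against reference energies
#'
#' Zero-intercept least squares: slope = sum(xy) / sum(x^2) and
#' r^2 = 1 - sum((y - slope x)^2) / sum(y^2), the uncentred (through-origin)
#' convention.  Energies should be offset-aligned per molecule first (e.g.
#' by subtracting each molecule's minimum), since reference and MM energy
#' zeros differ.
#'
#' @param x reference energies (kcal/mol).
#' @param y MM energies (kcal/mol).
#' @return List of class `origin_regression` with `slope` and `r_squared`.
#' @export
origin_regression <- function(x, y) {
  if (length(x) != length(y))
    ff_stop("x and y lengths differ", "length_mismatch")
  if (length(x) < 2 || sum(x^2) <= 0)
    ff_stop("need at least two points with non-zero x", "degenerate_x")
  slope <- sum(x * y) / sum(x^2)
  r2 <- 1 - sum((y - slope * x)^2) / sum(y^2)
  structure(list(slope = slope, r_squared = r2), class = "origin_regression")
}

#' @export
print.origin_regression <- function(x, ...) {
  cat(sprintf("<origin_regression> slope %.4f, r^2 %.4f\n",
              x$slope, x$r_squared))
  invisible(x)
}

#' Align energies per molecule by subtracting the minimum
#'
#' @param energies numeric vector (kcal/mol).
#' @param groups molecule labels, one per element (a single molecule when
#'   missing).
#' @return The aligned vector: each group's minimum maps to zero.
#' @export
align_energies <- function(energies, groups = NULL) {
  if (is.null(groups)) return(energies - min(energies))
  stats::ave(energies, groups, FUN = function(x) x - min(x))
}
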