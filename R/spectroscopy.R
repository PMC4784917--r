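#' Derivative harmonic spectrum of a magnetization trace
#'
#' The l-th Fourier coefficient of the ensemble-mean magnetization along the
#' drive is F_l = (1/T_w) integral of m_z exp(i 2 pi l t*) dt* over an
#' analysis window of T_w whole drive periods; the derivative harmonic is
#' a_l = l |F_l| (the harmonic index accounts for the time derivative picked
#' up by an inductive receive coil).  The 1/T_w normalization makes a_l
#' independent of window length; phases are discarded.  Quadrature is the FFT
#' on the uniform grid — exact for a periodic steady state windowed over whole
#' periods, so no taper is applied.
#'
#' @param trace A `mag_trace` covering an integer number of drive periods on a
#'   uniform grid (as produced by the simulators), or a numeric vector of m_z
#'   samples in which case `n_periods` must be given.
#' @param l_max Highest harmonic index to return; must stay below the Nyquist
#'   limit of the grid.
#' @param n_periods Number of drive periods spanned by a bare numeric input.
#' @return An object of class `harmonic_spectrum`: data.frame with columns
#'   `l`, `a_l`, and (when block traces are available) `a_l_se`.
#' @export
#' @examples
#' t <- seq(0, 1, length.out = 1001)[-1001]
#' harmonic_spectrum(sin(2 * pi * t), l_max = 5, n_periods = 1)
harmonic_spectrum <- function(trace, l_max = 11, n_periods = NULL) {
  if (inherits(trace, "mag_trace")) {
    mz <- trace$mz_mean
    P <- attr(trace, "n_periods_analysis")
    spp <- attr(trace, "steps_per_period")
    if (length(mz) != P * spp)
      stop("trace does not cover an integer number of periods")
    block_mz <- attr(trace, "block_mz")
  } else {
    mz <- as.numeric(trace)
    if (is.null(n_periods))
      stop("n_periods is required for a bare numeric trace")
    P <- as.integer(n_periods)
    if (length(mz) %% P != 0)
      stop("trace length is not a multiple of the stated period count")
    spp <- length(mz) %/% P
    block_mz <- NULL
  }
  if (l_max < 1) stop("l_max must be at least 1")
  N <- length(mz)
  if (l_max * P >= N / 2)
    stop(sprintf("l_max = %d exceeds the Nyquist limit of the grid (%d)",
                 l_max, floor((N / 2 - 1) / P)))

  amp_from <- function(x) {
    Fv <- stats::fft(x) / length(x)
    l <- seq_len(l_max)
    l * Mod(Fv[l * P + 1])
  }
  a_l <- amp_from(mz)
  out <- data.frame(l = seq_len(l_max), a_l = a_l)
  if (!is.null(block_mz)) {
    ab <- apply(block_mz, 2, amp_from)
    if (l_max == 1) ab <- matrix(ab, nrow = 1)
    k <- ncol(block_mz)
    out$a_l_se <- apply(ab, 1, stats::sd) / sqrt(k)
  }
  class(out) <- c("harmonic_spectrum", "data.frame")
  attr(out, "n_periods") <- P
  out
}

#' Ratio of two harmonic amplitudes
#'
#' Harmonic ratios such as r53 = a_5 / a_3 are concentration-independent
#' metrics of the nonlinearity of the magnetization response.
#'
#' @param spec A `harmonic_spectrum`.
#' @param p,q Harmonic indices of the numerator and denominator.
#' @param tol Amplitudes below `tol * max(a_l)` are treated as zero.
#' @return Dimensionless ratio a_p / a_q.
#' @export
harmonic_ratio <- function(spec, p = 5, q = 3, tol = 1e-10) {
  stopifnot(inherits(spec, "harmonic_spectrum"))
  get_a <- function(l) {
    i <- match(l, spec$l)
    if (is.na(i)) stop(sprintf("harmonic %d not present in spectrum", l))
    spec$a_l[i]
  }
  ap <- get_a(p)
  aq <- get_a(q)
  if (aq <= tol * max(spec$a_l))
    stop(sprintf("harmonic_ratio undefined: a_%d is zero (below tolerance)", q))
  ap / aq
}

#' Normalize harmonic curves by their maximum over a sweep
#'
#' Each harmonic's amplitude curve over a parameter grid is divided by its
#' maximum over that grid, so the normalized curves peak at 1 — the form in
#' which master-variable collapse is assessed.
#'
#' @param x A numeric matrix (rows = grid points, columns = harmonics) or a
#'   single numeric vector.
#' @return Object of the same shape with each column scaled to maximum 1.
#' @export
normalize_spectrum <- function(x) {
  norm1 <- function(v) {
    m <- max(v)
    if (!is.finite(m) || m <= 0)
      stop("cannot normalize an all-zero (or non-finite) harmonic curve")
    v / m
  }
  if (is.matrix(x) || is.data.frame(x)) {
    out <- as.matrix(x)
    for (j in seq_len(ncol(out))) out[, j] <- norm1(out[, j])
    out
  } else norm1(as.numeric(x))
}

#' @export
print.harmonic_spectrum <- function(x, ...) {
  cat(sprintf("harmonic_spectrum over %d period(s):\n", attr(x, "n_periods")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
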