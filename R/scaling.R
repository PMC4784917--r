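#' The Langevin function
#'
#' L(x) = coth(x) - 1/x, the equilibrium mean alignment of a classical dipole.
#' Evaluated with the series x/3 - x^3/45 for |x| < 1e-4 to avoid catastrophic
#' cancellation near the origin.
#'
#' @param x Numeric vector.
#' @return L(x), in (-1, 1).
#' @export
#' @examples
#' langevin(1)  # coth(1) - 1 = 0.3130...
langevin <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-4
  out[small] <- x[small] / 3 - x[small]^3 / 45
  xb <- x[!small]
  out[!small] <- 1 / tanh(xb) - 1 / xb
  out
}

# dL/dx = 1/x^2 - 1/sinh(x)^2, with the series 1/3 - x^2/15 near the origin.
langevin_deriv <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-3
  out[small] <- 1 / 3 - x[small]^2 / 15
  xb <- x[!small]
  out[!small] <- 1 / xb^2 - 1 / sinh(xb)^2
  out
}

# Lognormal volume multipliers with unit sample mean: the polydispersity
# channel through which a 10% radius CV enters xi0 (core volume) and Omega
# (hydrodynamic volume).
volume_multipliers <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  r <- sample_lognormal_radii(1, cv, n)
  v <- r^3
  v / mean(v)
}

#' Sweep harmonic spectra over a master-variable grid
#'
#' Runs one stochastic ensemble simulation per grid point and records the
#' derivative harmonic amplitudes.  The grid can be realized by varying the
#' mean unitless field at fixed mean unitless frequency (`vary = "xi0"`) or by
#' varying the mean unitless frequency (relaxation-time channel) at fixed mean
#' field (`vary = "tau_B"`).  Polydispersity enters through independent
#' lognormal core- and hydrodynamic-volume multipliers with radius coefficient
#' of variation `cv`; multipliers are rescaled to unit sample mean so the
#' realized ensemble master variable <xi0>/<Omega> equals the requested A
#' exactly.
#'
#' Seeding: the sweep seed deterministically derives one sub-seed per grid
#' point (radii, initial orientations, noise), so sweeps are reproducible and
#' individual points re-runnable.
#'
#' @param A Strictly increasing grid of master-variable values.
#' @param vary Which physical knob realizes the grid: "xi0" or "tau_B".
#' @param omega_mean Mean unitless frequency (fixed when `vary = "xi0"`).
#' @param xi0_mean Mean unitless field (fixed when `vary = "tau_B"`).
#' @param cv Radius coefficient of variation for both size channels
#'   (default 0.10).
#' @param harmonics Harmonic indices to record (default odd 3..11).
#' @param control A [sim_control()]; `n_blocks` > 1 enables per-point
#'   Monte-Carlo standard errors on the harmonics.
#' @return An object of class `msb_sweep`: data.frame with columns `A`,
#'   `xi0_mean`, `omega_mean`, one `a<l>` column per harmonic and matching
#'   `a<l>_se` columns when block errors are available.
#' @export
sweep_master_variable <- function(A, vary = c("xi0", "tau_B"),
                                  omega_mean = 1, xi0_mean = NULL, cv = 0.10,
                                  harmonics = c(3, 5, 7, 9, 11),
                                  control = sim_control(n_blocks = 8)) {
  vary <- match.arg(vary)
  A <- as.numeric(A)
  if (any(diff(A) <= 0)) stop("A grid must be strictly increasing")
  if (any(A <= 0)) stop("A values must be positive")
  if (vary == "tau_B" && is.null(xi0_mean))
    stop("vary = 'tau_B' requires xi0_mean")
  l_max <- max(harmonics)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(control$seed)
  point_seeds <- sample.int(.Machine$integer.max, length(A))

  rows <- vector("list", length(A))
  for (i in seq_along(A)) {
    xi_m <- if (vary == "xi0") A[i] * omega_mean else xi0_mean
    om_m <- if (vary == "xi0") omega_mean else xi0_mean / A[i]
    set.seed(point_seeds[i])
    wc <- volume_multipliers(control$n_particles, cv)
    wh <- volume_multipliers(control$n_particles, cv)
    ctl <- control
    ctl$seed <- point_seeds[i]
    tr <- tryCatch(
      simulate_dimensionless(xi_m * wc, om_m * wh, ctl),
      error = function(e)
        stop(sprintf("sweep point %d (A = %g): %s", i, A[i], conditionMessage(e)),
             call. = FALSE))
    sp <- harmonic_spectrum(tr, l_max = l_max)
    amps <- sp$a_l[match(harmonics, sp$l)]
    row <- c(A = A[i], xi0_mean = xi_m, omega_mean = om_m,
             stats::setNames(amps, paste0("a", harmonics)))
    if (!is.null(sp$a_l_se)) {
      ses <- sp$a_l_se[match(harmonics, sp$l)]
      row <- c(row, stats::setNames(ses, paste0("a", harmonics, "_se")))
    }
    rows[[i]] <- row
  }
  out <- as.data.frame(do.call(rbind, rows))
  class(out) <- c("msb_sweep", "data.frame")
  attr(out, "harmonics") <- harmonics
  attr(out, "vary") <- vary
  attr(out, "cv") <- cv
  attr(out, "n_particles") <- control$n_particles
  attr(out, "seed") <- control$seed
  out
}

#' Master-variable collapse metric between two sweeps
#'
#' Normalizes one harmonic's amplitude curve from each sweep by its maximum,
#' interpolates both linearly in log A onto the grid points falling in the
#' overlapping A range, and reports the deviation between the curves.  Two
#' sweeps that realize the same A values through different physical knobs
#' should collapse within Monte-Carlo error whenever the deterministic torque
#' dominates (xi0 > Omega).
#'
#' @param sweep1,sweep2 `msb_sweep` objects with overlapping A ranges.
#' @param harmonic Harmonic index to compare (default 3).
#' @return List with `max_dev`, `rms_dev`, `max_z` (deviation over pooled SE,
#'   when SEs are available), and the comparison grid `A`.
#' @export
collapse_test <- function(sweep1, sweep2, harmonic = 3) {
  col <- paste0("a", harmonic)
  se_col <- paste0(col, "_se")
  for (s in list(sweep1, sweep2))
    if (!col %in% names(s)) stop(sprintf("harmonic %d not in sweep", harmonic))
  lo <- max(min(sweep1$A), min(sweep2$A))
  hi <- min(max(sweep1$A), max(sweep2$A))
  if (lo >= hi) stop("sweeps cover disjoint A ranges; no overlap to compare")
  grid <- sort(unique(c(sweep1$A[sweep1$A >= lo & sweep1$A <= hi],
                        sweep2$A[sweep2$A >= lo & sweep2$A <= hi])))

  norm_interp <- function(sw, values) {
    m <- max(sw[[col]])
    stats::approx(log(sw$A), values / m, xout = log(grid))$y
  }
  y1 <- norm_interp(sweep1, sweep1[[col]])
  y2 <- norm_interp(sweep2, sweep2[[col]])
  d <- y1 - y2
  out <- list(max_dev = max(abs(d)), rms_dev = sqrt(mean(d^2)), A = grid)
  if (se_col %in% names(sweep1) && se_col %in% names(sweep2)) {
    se1 <- norm_interp(sweep1, sweep1[[se_col]])
    se2 <- norm_interp(sweep2, sweep2[[se_col]])
    pooled <- sqrt(se1^2 + se2^2)
    out$pooled_se <- pooled
    out$max_z <- max(abs(d) / pmax(pooled, .Machine$double.eps))
  }
  out
}

#' Fit a domain-scaled Langevin function to a normalized harmonic curve
#'
#' Least-squares fit of the single scale parameter b in a_l = L(b A) =
#' coth(b A) - 1/(b A) to a normalized harmonic amplitude curve over a
#' master-variable grid.  The optimum is located by a coarse log-spaced grid
#' search refined by golden-section optimization, which is robust for this
#' one-dimensional monotone-sigmoid problem.
#'
#' @param A Master-variable grid (>= 5 points).
#' @param y Normalized amplitudes in [0, 1].
#' @param b_range Search range for b (log-spanned).
#' @return An object of class `langevin_fit`: list with `b`, `r_squared`
#'   (1 - SS_res/SS_tot), `fitted`, `residuals`, `A`, `y`.
#' @export
#' @examples
#' A <- exp(seq(log(0.1), log(100), length.out = 20))
#' f <- fit_langevin_master(A, langevin(2 * A))
#' f$b          # 2
#' f$r_squared  # 1
fit_langevin_master <- function(A, y, b_range = c(1e-3, 1e3)) {
  A <- as.numeric(A); y <- as.numeric(y)
  if (length(A) < 5) stop("need at least 5 grid points to fit")
  if (length(y) != length(A)) stop("A and y lengths differ")
  if (any(y < -0.05) || any(y > 1.05))
    stop("y must be a normalized curve with values in [0, 1]")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot < 1e-12)
    stop("degenerate flat curve: no variation to fit")
  ss <- function(logb) sum((y - langevin(exp(logb) * A))^2)
  lgrid <- seq(log(b_range[1]), log(b_range[2]), length.out = 121)
  vals <- vapply(lgrid, ss, numeric(1))
  i <- which.min(vals)
  lo <- lgrid[max(1, i - 1)]
  hi <- lgrid[min(length(lgrid), i + 1)]
  opt <- stats::optimize(ss, interval = c(lo, hi), tol = 1e-10)
  b <- exp(opt$minimum)
  fitted <- langevin(b * A)
  res <- y - fitted
  out <- list(b = b, r_squared = 1 - sum(res^2) / ss_tot,
              fitted = fitted, residuals = res, A = A, y = y)
  class(out) <- "langevin_fit"
  out
}

#' @export
print.langevin_fit <- function(x, ...) {
  cat(sprintf("langevin_fit: a = L(b A), b = %.5g, R^2 = %.5f (%d points)\n",
              x$b, x$r_squared, length(x$A)))
  invisible(x)
}

#' Fit every harmonic of a sweep with the domain-scaled Langevin function
#'
#' @param sweep An `msb_sweep`.
#' @return data.frame with columns `l`, `b_l`, `R2`.
#' @export
fit_sweep_harmonics <- function(sweep) {
  stopifnot(inherits(sweep, "msb_sweep"))
  harmonics <- attr(sweep, "harmonics")
  rows <- lapply(harmonics, function(l) {
    y <- normalize_spectrum(sweep[[paste0("a", l)]])
    f <- fit_langevin_master(sweep$A, y)
    data.frame(l = l, b_l = f$b, R2 = f$r_squared)
  })
  do.call(rbind, rows)
}

#' Location of the steepest harmonic response to the master variable
#'
#' Fits L(b A) to the (normalized) harmonic curve, then reports where the
#' fitted sigmoid is steepest.  Against log A — the axis on which the curves
#' are sigmoidal — the slope d L(bA) / d log A = bA L'(bA) is maximized at a
#' universal argument x* of x L'(x), so the optimum is A* = x*/b, inversely
#' proportional to b.  Against linear A the Langevin slope L'(bA) is largest
#' as A -> 0, so the linear-axis report is simply the finite-difference argmax
#' on the grid (its lower end); both are returned.  The search is performed on
#' the fitted smooth curve rather than the raw Monte-Carlo points, whose
#' finite differences are noise-dominated.
#'
#' @param sweep An `msb_sweep` with at least 10 grid points.
#' @param harmonic Harmonic index.
#' @return List with `A_star_log` (steepest slope vs log A, from the fit),
#'   `A_star_grid_log` (finite-difference argmax of the fitted curve vs log A
#'   on the grid), `A_star_linear` (finite-difference argmax vs A), `b`, and
#'   `x_star` (universal maximizer of x L'(x), about 1.91).
#' @export
sensitivity_curve <- function(sweep, harmonic = 3) {
  stopifnot(inherits(sweep, "msb_sweep"))
  if (nrow(sweep) < 10)
    stop("sweep grid too coarse for a slope search (need >= 10 points)")
  y <- normalize_spectrum(sweep[[paste0("a", harmonic)]])
  fit <- fit_langevin_master(sweep$A, y)
  g <- function(x) x * langevin_deriv(x)
  x_star <- stats::optimize(g, interval = c(1e-6, 50), maximum = TRUE)$maximum
  Af <- sweep$A
  yf <- langevin(fit$b * Af)
  # centered finite differences of the fitted curve on the two axes
  mid <- 2:(length(Af) - 1)
  d_log <- (yf[mid + 1] - yf[mid - 1]) / (log(Af[mid + 1]) - log(Af[mid - 1]))
  d_lin <- (yf[mid + 1] - yf[mid - 1]) / (Af[mid + 1] - Af[mid - 1])
  list(A_star_log = x_star / fit$b,
       A_star_grid_log = Af[mid][which.max(d_log)],
       A_star_linear = Af[mid][which.max(d_lin)],
       b = fit$b, x_star = x_star)
}

#' Temperature-invariance study at fixed master variable
#'
#' The master variable A = <xi0>/<Omega> has no direct temperature dependence
#' (k_B T divides out of the ratio), so changing T at fixed A changes only the
#' stochastic term: for each A, the drive is rescaled as xi0(T) =
#' xi0_ref * T_ref/T and Omega(T) = Omega_ref * T_ref/T across the temperature
#' grid, and the mean traces are compared pairwise.  The report also records
#' the within-ensemble fluctuation variance of m_z, which grows as A falls
#' (weaker alignment, thermal torques relatively stronger).
#'
#' @param A_values Master-variable values to study (e.g. A, 2A, 4A).
#' @param T_grid Temperatures in kelvin (default 250 to 350 by 10).
#' @param omega_ref Mean unitless frequency at the reference temperature.
#' @param T_ref Reference temperature (K), default 293.
#' @param cv Radius coefficient of variation (default 0.10).
#' @param control A [sim_control()].
#' @return An object of class `msb_temperature_report`: data.frame with one
#'   row per A (`A`, `max_dev`, `max_z`, `fluct_var`) and the traces in
#'   attribute `traces`.
#' @export
temperature_invariance_suite <- function(A_values, T_grid = seq(250, 350, 10),
                                         omega_ref = 0.5, T_ref = 293,
                                         cv = 0.10, control = sim_control()) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(control$seed)
  run_seeds <- matrix(sample.int(.Machine$integer.max,
                                 length(A_values) * length(T_grid)),
                      nrow = length(A_values))
  # pre-draw the size multipliers so one dt* (from the global Omega minimum)
  # can serve every run: traces across the T grid must share a grid to be
  # comparable pointwise
  mult <- vector("list", length(A_values))
  omega_min <- Inf
  for (ia in seq_along(A_values)) {
    mult[[ia]] <- vector("list", length(T_grid))
    for (it in seq_along(T_grid)) {
      set.seed(run_seeds[ia, it])
      wc <- volume_multipliers(control$n_particles, cv)
      wh <- volume_multipliers(control$n_particles, cv)
      mult[[ia]][[it]] <- list(wc = wc, wh = wh)
      omega_min <- min(omega_min, omega_ref * (T_ref / T_grid[it]) * min(wh))
    }
  }
  if (is.null(control$dt_star)) {
    spp <- ceiling(1 / min(0.01 * omega_min, 1e-3))
    control$dt_star <- 1 / spp
  }
  # the comparison is of the initial response from a common initial-condition
  # policy (the regime in which the mean dynamics are master-variable
  # governed), so by default no transient is discarded
  if (is.null(control$n_periods_transient)) control$n_periods_transient <- 0L
  rows <- vector("list", length(A_values))
  all_traces <- vector("list", length(A_values))
  for (ia in seq_along(A_values)) {
    A <- A_values[ia]
    traces <- vector("list", length(T_grid))
    for (it in seq_along(T_grid)) {
      s <- T_ref / T_grid[it]
      ctl <- control
      ctl$seed <- run_seeds[ia, it]
      w <- mult[[ia]][[it]]
      traces[[it]] <- simulate_dimensionless(A * omega_ref * s * w$wc,
                                             omega_ref * s * w$wh, ctl)
    }
    max_dev <- 0; max_z <- 0
    if (length(T_grid) > 1) {
      for (i in seq_along(traces)) for (j in seq_len(i - 1)) {
        dv <- trace_deviation(traces[[i]], traces[[j]])
        max_dev <- max(max_dev, dv$max_dev)
        max_z <- max(max_z, dv$max_z)
      }
    }
    fluct <- mean(vapply(traces, function(tr)
      mean(tr$mz_sem^2) * attr(tr, "n_particles"), numeric(1)))
    rows[[ia]] <- data.frame(A = A, max_dev = max_dev, max_z = max_z,
                             fluct_var = fluct)
    all_traces[[ia]] <- traces
  }
  out <- do.call(rbind, rows)
  class(out) <- c("msb_temperature_report", "data.frame")
  attr(out, "T_grid") <- T_grid
  attr(out, "traces") <- all_traces
  out
}
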