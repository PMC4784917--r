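---
title: "Simulating Brownian magnetic nanoparticle spectroscopy: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating Brownian magnetic nanoparticle spectroscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msbsim)
```

## The physical model

Magnetic spectroscopy of nanoparticle Brownian motion (MSB) reads out the
harmonic content of the magnetization of iron-oxide nanoparticles driven by an
oscillating magnetic field. The particles of interest rotate *mechanically*
(Brownian rotation, as opposed to internal Néel rotation), so their response
encodes the rotational friction of their surroundings — viscosity,
temperature, molecular binding — which is what makes them useful as in vivo
biosensors.

`msbsim` models each particle as a point dipole of moment magnitude
$\mu = M_s \tfrac{4}{3}\pi r_\mathrm{core}^3$ rigidly attached to a sphere of
hydrodynamic volume $V = \pi d^3/6$ suspended in a Newtonian fluid. The
rotational Reynolds number under biosensing conditions is
$Re = \rho f d^2/\eta \approx 10^{-5}$ (`reynolds_number()`), so inertia is
dropped and the orientation dynamics are first order in time. In
dimensionless form, with time $t^* = t f$ measured in drive periods, the unit
orientation vector $\mathbf{m}$ obeys the stochastic Langevin equation

$$
\mathrm{d}\mathbf{m} \;=\; \frac{\xi_0}{2\Omega}\,
\mathbf{m}\times\big(\cos(2\pi t^*)\,\hat{z}\times\mathbf{m}\big)\,
\mathrm{d}t^* \;+\; \frac{1}{\sqrt{\Omega}}\,\mathbf{m}\times \mathrm{d}\mathbf{W},
$$

with the three dimensionless groups

* $\xi_0 = \mu B_0 / k_B T$ — Zeeman over thermal energy at peak field
  (`unitless_field()`); fields are stored as $B_0 = \mu_0 H_0$ in tesla, the
  convention in which MSB drive amplitudes ("5 mT") are quoted, which keeps
  the energy ratio dimensionally clean;
* $\Omega = f\tau_B$ — drive frequency over inverse Brownian relaxation time
  $\tau_B = 3\eta V / k_B T$ (`unitless_frequency()`,
  `brownian_relaxation_time()`);
* $A = \xi_0/\Omega$ — the **master variable** (`master_variable()`).

When $\xi_0 > \Omega$ the deterministic torque dominates and the mean
dynamics are governed by $A$ alone: scaling field amplitude and frequency (or
relaxation time) by the same factor leaves the mean magnetization unchanged.
Dropping the noise entirely makes this exact
(`simulate_deterministic()`), and for the axisymmetric cosine drive the
noise-free dynamics even integrate in closed form,
$m_z(t^*) = \tanh\!\big(\mathrm{atanh}(m_{z,0}) + \tfrac{A}{4\pi}\sin 2\pi
t^*\big)$, which the test suite uses as an exact reference.

Temperature enters $\xi_0$ and $\Omega$ identically (through $1/k_BT$) and
divides out of $A$, so at fixed $A$ temperature only rescales the stochastic
term — the basis of the temperature-invariance study
(`temperature_invariance_suite()`).

## Numerical integration

The SDE is integrated with the two-step Heun scheme: an Euler predictor
$\bar{\mathbf m}$ followed by a trapezoidal corrector that re-evaluates the
drift at $(\bar{\mathbf m},\,t^*+\Delta t^*)$ and applies the noise through
$\tfrac12(\mathbf m + \bar{\mathbf m})\times\mathbf N\sqrt{\Delta
t^*/\Omega}$, with the *same* Gaussian 3-vector $\mathbf N$ in both stages.
For multiplicative noise this scheme converges to the **Stratonovich**
solution, and that choice is physical rather than cosmetic: it is what makes
the static-field stationary state Boltzmann, $\langle m_z\rangle \to
L(\xi) = \coth\xi - 1/\xi$, which the suite verifies directly for
$\xi \in \{0.5, 1, 2, 5\}$.

Numerical choices worth knowing about:

* **Renormalization.** The continuous dynamics conserve $|\mathbf m| = 1$
  exactly (every torque is perpendicular to $\mathbf m$); the discrete step
  does not, drifting by $\lesssim 10^{-4}$ per step at the default step size.
  $\mathbf m$ is renormalized after every corrector step.
* **Step size.** $\Delta t^* \le \min(0.01\,\Omega_{\min},\,10^{-3})$, where
  $\Omega_{\min}$ is the smallest unitless frequency in the (polydisperse)
  ensemble. The first bound resolves the relaxation dynamics; the $10^{-3}$
  cap guarantees $\ge 1000$ steps per drive period when $\Omega$ is large.
  The chosen $\Delta t^*$ is rounded so an integer number of steps tiles one
  period, making rectangular-window Fourier analysis exact. Violations are
  rejected before any integration. In the constant-field mode (used only by
  the equilibrium oracle) time is measured in units of $\tau_B$ and only the
  $0.01\,\Omega$ rule applies — the cap exists to resolve a drive period,
  and there is none.
* **Convergence.** Deterministic traces against the closed form show the
  expected second-order behavior (error ratio $\approx 4$ under step
  halving).
* **Initial conditions and transient.** Orientations start uniform on the
  sphere (configurable to aligned); a transient of
  $\max(2, \lceil 3\,\Omega_{\max}\rceil)$ drive periods — roughly three
  relaxation times in $t^*$ units — is discarded before the analysis window.
  The underlying dynamics do not fix these choices; they are implementation
  policy, and the defaults are deliberately conservative.
* **Reproducibility.** One user seed drives everything, in a documented
  order: particle radii first, initial orientations second, then the thermal
  noise (three standard normals per particle per step, particle-major)
  consumed inside the compiled kernel through one sub-stream per block.
  Identical seed and configuration give bit-identical traces.

The kernel is C++ (via Rcpp) because a desk-scale study integrates
$\sim 10^9$ Heun steps; the R surface stays thin and the single-step update
is exposed (`heun_step()`) and cross-checked against a pure-R transcription
in the tests.

## Polydispersity

Core and hydrodynamic radii are lognormal with standard deviation 10% of the
mean by default, sampled independently (`sample_lognormal_radii()`,
`sample_ensemble()`) with the moment-matched parameterization
$\sigma_r = \sqrt{\ln(1 + s_r^2/m_r^2)}$. Independence of the two radii is
the simplest assumption consistent with the model statement; a joint
(correlated) size model would be a natural extension but is not implemented.
Dispersion enters $\xi_0$ through the core volume and $\Omega$ through the
hydrodynamic volume, and the ensemble master variable is defined on the means,
$A = \langle\xi_0\rangle/\langle\Omega\rangle$
(`ensemble_master_variable()`). A useful closed-form consequence of the
moment-matched lognormal — $\langle r^3\rangle = m_r^3(1+cv^2)^3$ — is that
the dispersion factor cancels between numerator and denominator, so the
ensemble $A$ coincides with the monodisperse value; the tests exploit this as
an oracle.

## Harmonic spectroscopy

The analysis pipeline averages over the ensemble first and then Fourier
transforms (`harmonic_spectrum()`): $F_l = \tfrac{1}{T_w}\int m_z\,
e^{i2\pi l t^*}\mathrm{d}t^*$ over a window of $T_w$ whole periods, and the
derivative harmonic is $a_l = l\,|F_l|$ — the factor $l$ accounting for the
time derivative seen by an inductive pickup. Conventions the underlying
definition leaves open, fixed here: magnitudes only (phase discarded), $1/T_w$
normalization so $a_l$ is window-length independent, FFT quadrature with no
taper (rectangular windowing is exact for a periodic steady state over whole
periods). Under this convention a unit square wave gives $a_l = 2/\pi$ for
every odd $l$, and the Debye linear response gives
$a_1 = (\xi_0/6)/\sqrt{1+(2\pi\Omega)^2}$ (`debye_first_harmonic()`), both
used as oracles.

## The Debye limits

For weak drives ($\xi_0 \ll 1$) the mean response follows the Debye form
(`debye_magnetization()`); its $\Omega > 1$ limit
$m_z \approx (A/6\pi)\sin 2\pi t^*$ (`debye_high_omega()`) depends on the
master variable alone, and its small-$\Omega$ expansion
(`debye_low_omega_expansion()`) has leading term $(\xi_0/3)\cos 2\pi t^*$
with first correction $\propto \xi_0\Omega$ — the "slew rate"
(field-amplitude-times-frequency, `slew_rate()`). One typesetting erratum in
the source material is handled deliberately: the printed low-$\Omega$
expansion carries a $(1+4\pi\Omega)$ prefactor on the cosine term that cannot
arise from the stated binomial expansion (the denominator
$1+(2\pi\Omega)^2$ has no $O(\Omega)$ term), so the implementation uses the
mathematically forced truncation
$(\xi_0/3)[\cos 2\pi t^* + 2\pi\Omega\sin 2\pi t^*]$, which agrees with the
full form to $O(\Omega^2)$ — a bound the tests check numerically. Similarly,
a printed rotational diffusion constant that is dimensionally inconsistent is
never used: the dimensionless form of the dynamics fixes everything.

## Master-variable sweeps and the one-parameter fit

`sweep_master_variable()` simulates one spectrum per grid point, realizing an
$A$ grid either through the field channel ($\xi_0$ varied at fixed $\Omega$)
or the relaxation-time channel ($\Omega$ varied at fixed $\xi_0$);
`collapse_test()` interpolates normalized harmonic curves linearly in
$\log A$ (the axis on which the curves are sigmoidal) and reports maximum and
RMS deviation with a pooled Monte-Carlo error. Monte-Carlo errors come from
splitting the ensemble into independent blocks (8 by default) and treating
block-level spectra as replicates.

Normalized harmonic curves over $A$ are well described by a one-parameter
domain-scaled Langevin function, $a_l = L(b_l A)$.
`fit_langevin_master()` fits $b_l$ by unweighted least squares (block SEs
are reported but not used as weights — the curves are approximately
homoscedastic after normalization and an unweighted fit keeps the estimator
simple), via a coarse log-grid search refined by golden-section
optimization; $L$ is evaluated with the series $x/3 - x^3/45$ below
$|x| < 10^{-4}$ to avoid cancellation. The fit is phenomenological — no
theoretical derivation is claimed — and is least accurate around the
low-$A$ inflection, as expected from the shape of $L$.

The fit quality depends on the sweep reaching harmonic saturation: every
harmonic saturates (square-wave response, $a_l \to 2/\pi$) only near
$\xi_0 \sim 10^3$, so the package's Fig-7-style studies use 18 log-spaced
$A$ values spanning $[0.1, 3000]$ at $\langle\Omega\rangle = 1$. Truncating
the grid at $A = 100$ leaves the $l \ge 7$ curves mid-rise and degrades
their $R^2$ drastically (to $\approx 0.68$ for $l = 11$ — a property of the
curve shape, not of Monte-Carlo noise; the exact noise-free closed form
gives the same failure). At the full range the fits reach $R^2 \ge 0.98$
for all odd harmonics $3$–$11$ at $n = 10^4$ particles.

`sensitivity_curve()` locates the steepest part of the fitted sigmoid — the
optimal MSB operating point, where a small change in relaxation time (hence
$A$) moves the harmonic most. "Steepest" is axis-dependent and the
definition is left open by the sigmoid language, so both are reported: versus
$\log A$ the slope $bA\,L'(bA)$ peaks at a universal argument
$x^* \approx 1.91$, giving $A^* = x^*/b_l$; versus linear $A$ the Langevin
slope is monotone decreasing, so the report is the finite-difference argmax
on the grid (its low end). The search runs on the fitted curve, not the raw
Monte-Carlo points, whose finite differences are noise-dominated.

## What the generator emulates — and what it does not

The synthetic studies reproduce the *simulation* conditions of the scaling
analysis: dilute, non-interacting, rigid-dipole (Brownian-only) particles
with 10% lognormal size dispersion, driven by a single-frequency cosine
field. Default desk scale is $n = 10^4$ particles with block-based error
bars (the original studies use $10^5$; `n_particles` is configurable up to
and beyond that). Not modelled, by design: Néel (internal) relaxation,
magnetic anisotropy energetics, interparticle interactions,
temperature-dependent viscosity, receive-coil noise floors, and real
spectrometer hardware. Passing tests therefore validate the rotational
Langevin model and its scaling law, not the full physics of any particular
experimental tracer; in particular, measured harmonic ratios of real
Micromod-type particles involve Néel contributions and apparatus transfer
functions that are out of scope here (`read_spectrum_csv()` exists so such
measured spectra can at least be pushed through the same ratio/collapse
analysis).

## Known limitations

* The Heun scheme has a small $O(\Delta t^*)$ weak bias in stationary
  statistics; at the default steps it is below the Monte-Carlo resolution of
  the suite ($\lesssim 0.3\%$ on the equilibrium mean at the coarsest static
  step, halved at the test settings).
* At very large $A$ (drive increments $\xi_0\Delta t^*/2\Omega \gtrsim 1$)
  the integrator under-resolves the fast flip itself, though renormalization
  keeps the trajectory on the sphere and the harmonic content of the
  square-wave regime is reproduced to better than 1% (checked against the
  closed form at $A = 10^3$).
* Master-variable collapse of the **mean trace** is exact only for the
  noise-free dynamics. With noise, the periodic steady state is selected by
  the thermal relaxation, and its saturation level tracks the instantaneous
  equilibrium $L(\xi_0)$ — a function of $\xi_0$, not of $A$ — so doubling
  $(\xi_0, \Omega)$ shifts the mean trace by several percent to $\sim 0.1$
  absolute (largest at the saturation flanks, where a horizontal smearing
  difference produces a large pointwise deviation). This is real physics,
  not integrator error: a Legendre-moment Fokker–Planck solution — an
  entirely independent deterministic method — reproduces the simulator's
  traces to within Monte-Carlo error and shows the same inter-parameter
  deviation. The collapse that holds to within Monte-Carlo error at desk
  scale is the one the harmonic analysis uses: normalized harmonic curves
  against $A$. Trace-level collapse should be read as the figure-level,
  qualitative statement it is; the suite asserts it quantitatively only in
  the noise-free case, plus the robust trend that collapse is distinctly
  worse when $\xi_0 \sim \Omega$.
* Temperature invariance at fixed $A$ is likewise approximate: rescaling
  $T$ moves $\xi_0(T)$ by $\pm 17\%$ across 250–350 K, and the mean trace
  retains an $O(\max_x xL'(x) \cdot \Delta\xi_0/\xi_0) \approx 0.06$
  imprint at the flank crossing regardless of parameters. The invariance is
  excellent on the scale of the response amplitude (the suite bounds it
  relatively) and the fluctuation-variance ordering in $A$ is robust.
* The worked "typical particle" numbers quoted in the biosensing literature
  involve aggressive rounding: a 20 nm core / 50 nm hydrodynamic radius
  particle at $M_s = 250$ kA/m in 5 mT gives $\xi_0 \approx 10$ by direct
  evaluation, not the conventionally quoted $\sim 6$. The package computes;
  where a check targets a quoted number, it is treated as order-of-magnitude.

## Worked example

```{r example, eval = FALSE}
spec <- msb_particle_spec(20e-9, 50e-9, Ms = 250e3)   # typical MSB tracer
env  <- msb_environment(viscosity = 1e-3, temperature = 293)
fld  <- msb_drive_field(amplitude = 5e-3, frequency = 1000)

ens <- sample_ensemble(spec, env, n = 1e4, seed = 1)
ensemble_master_variable(ens, fld, env)    # ~27: field-dominated regime

tr <- simulate_ensemble(ens, fld, env,
                        sim_control(n_particles = 1e4, seed = 1))
sp <- harmonic_spectrum(tr, l_max = 11)
harmonic_ratio(sp, 5, 3)                   # r53, the MSB nonlinearity metric
```

The problem sizes used throughout the test suite (ensembles of
$2\times10^3$–$10^4$ particles, sweeps of 8–18 grid points) are the
package's desk-scale defaults; all of them are plain arguments, and the
recipes accept `n_particles = 1e5` to run at full study scale.
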