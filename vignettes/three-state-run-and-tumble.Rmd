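---
title: "A three-state run-and-tumble model with a cell cycle: methods and design"
author: "rtcycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A three-state run-and-tumble model with a cell cycle: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rtcycle)
```

## The model

`rtcycle` implements a one-dimensional continuum model of a bacterial
population, motivated by *Caulobacter crescentus*, whose cells alternate
between two motile, non-proliferating phases and one sedentary,
proliferating phase.  Three number densities are tracked on a line:
right-movers $\rho_+(x,t)$, settled cells $\rho_0(x,t)$ and left-movers
$\rho_-(x,t)$.  Their coupled dynamics are

$$
\partial_t \boldsymbol\rho =
\mathcal{D}\,\partial_x^2 \boldsymbol\rho
+ \partial_x\!\left[(\partial_x\,\mathcal{U})\cdot\boldsymbol\rho\right]
- \mathcal{V}\cdot\partial_x \boldsymbol\rho
+ \mathcal{M}\boldsymbol\rho ,
$$

with $\mathcal{D} = \mathrm{diag}(D, 0, D)$ (settled cells do not diffuse),
$\mathcal{V} = \mathrm{diag}(v_+, 0, -v_-)$ (runs in opposite directions,
possibly at different speeds), an interaction potential matrix
$\mathcal{U} = \mathrm{diag}(-\kappa\rho_0,\; \kappa_0\rho_0,\;
-\kappa\rho_0)$ — movers are attracted to settled regions with strength
$\kappa$, settled cells repel each other with strength $\kappa_0$ — and the
kinetic matrix $\mathcal{M}$ built from four rates: settling $\lambda_s$,
doubling $\lambda_d$ (one settled cell becomes a right- and a left-mover),
tumbling $\lambda_e$ (direction exchange) and death of movers $\mu$.
Column sums of $\mathcal{M}$ are $(-\mu, +\lambda_d, -\mu)$: cell number
changes only through death of movers and doubling of settled cells.

Growth can saturate: in logistic mode the off-diagonal (growth) part of
$\mathcal{M}$ acts on $\rho_\alpha(1-\rho_\alpha/\rho_{\alpha,c})$ instead
of $\rho_\alpha$, bounding the population at carrying capacities
$\boldsymbol\rho_c$ regardless of the rates.

### Units

Internally $\lambda_e$ is the unit of time and the domain length $L$ the
unit of length; densities are dimensionless.  All presets are stored in
these units.  `params_from_si()` converts an SI parameter set; the
`cc_table1` preset carries experimentally motivated *Caulobacter* values
($\lambda_e = 0.1\,\mathrm{s^{-1}}$, $\lambda_s = 10^{-5}\,\mathrm{s^{-1}}$,
$\lambda_d = 10^{-4}\,\mathrm{s^{-1}}$, $\mu = 10^{-6}\,\mathrm{s^{-1}}$,
$v_+ = 40\,\mathrm{\mu m/s}$, $v_- = 35\,\mathrm{\mu m/s}$,
$D = 2\times10^{-9}\,\mathrm{m^2/s}$) nondimensionalized with a box of
$L = 4.5\,\mathrm{mm}$, chosen so that the dimensionless diffusivity
$D/(L^2\lambda_e) \approx 10^{-3}$ matches the regime used for the pattern
studies; the interaction strengths and carrying capacity of that preset
are not experimentally determined and are set to the values used for the
logistic wave demonstrations.

## Well-mixed dynamics

Without spatial structure the linear model is
$\dot{\boldsymbol\rho} = \mathcal{M}\boldsymbol\rho$, solved exactly by
`wm_evolve_linear()` through the matrix exponential.  The eigenvalues are
known in closed form (`wm_eigenvalues()`); two are always negative and the
third, $E_3$, has the sign of $\lambda_s - \mu$: a moving cell must settle
faster than it dies for the colony to grow.  For $\lambda_d \to \infty$,
$E_3 \to \lambda_s - \mu$.  On the balanced line $\lambda_s = \mu$ the
combination $R = \rho_+ + \rho_- + 2\rho_0$ is conserved and the densities
relax to a stationary composition determined by $R$ alone
(`wm_stationary()`); the factor 2 counts the two offspring latent in every
settled cell.  The matrix exponential uses an eigen-decomposition when the
eigenvector basis is well conditioned (reciprocal condition number above
$10^{-7}$) and falls back to scaling-and-squaring with a truncated Taylor
series otherwise (the spectrum degenerates, e.g., when
$\Lambda = 0$); both paths are deterministic.

The logistic integrator (`wm_evolve_logistic()`) is classical RK4 with a
default step of $10^{-4}/\lambda_e$, retrying a step with half the size if
it would drive a density below $-10^{-12}$.  A useful cross-check, used in
the tests: with $\rho_c = (1,1,1)$, $\lambda_s = 3\mu$,
$\mu = \lambda_d = \lambda_e$, the saturated plateau coincides (to
$10^{-3}$) with the balanced linear stationary state at
$\mu = \lambda_s = 2.848\,\lambda_e$, $\lambda_d = \lambda_e$, for the
same initial condition.

## Fourier-space moments of the free model

For free cells ($\kappa = \kappa_0 = 0$) the model is linear with constant
coefficients, so each wavenumber evolves independently:
$\tilde{\boldsymbol\rho}(k,t) = \exp[(-k^2\mathcal{D} - \mathrm{i}k\mathcal{V}
+ \mathcal{M})t]\,\tilde{\boldsymbol\rho}(k,0)$ (`spectral_propagator()`).
The intermediate scattering function and its $k$-derivatives at $k = 0$
generate the displacement moments,
$\langle (x-x_0)^n\rangle = \mathrm{i}^n N(t)^{-1}
\partial_k^n \mathcal{F}(k,t)|_{k=0}$, per population or for the total
density.  The default initial condition is a single settled cell at the
origin, $\boldsymbol\rho(x,0) = (0, \delta(x), 0)$, represented exactly in
Fourier space as $(0, 1, 0)$.

Rather than differencing in $k$ (step-size artifacts) the package
propagates the derivatives exactly: differentiating the evolution equation
$n$ times in $k$ yields a closed block-triangular linear system for
$y_m = \partial_k^m \tilde{\boldsymbol\rho}|_{k=0}$,

$$
\dot y_m = \mathcal{M} y_m - \mathrm{i}\,m\,\mathcal{V}\,y_{m-1}
 - m(m-1)\,\mathcal{D}\,y_{m-2},
$$

solved with one matrix exponential of a $3(n{+}1)$-dimensional matrix
(`displacement_moments()`).  The moments therefore carry no discretization
error; their accuracy is that of the matrix exponential itself.

Key analytic fingerprints, all covered by tests against both the closed
forms and a stochastic oracle:

* total population: MD $\simeq \lambda_d v_d t^2$ and MSD
  $\simeq 2D\lambda_d t^2$ at short times, with $v_d = (v_+-v_-)/2$;
* settled population: MD $\simeq \tfrac13\lambda_s\lambda_d v_d t^3$ and
  MSD $\simeq \tfrac23 D\lambda_s\lambda_d t^3$ — a super-ballistic $t^3$
  onset (settle–double–swim requires three elementary steps, each at least
  of order $t$), degrading to $t^4$ when $D = 0$;
* crossover times between consecutive regimes as ratios of expansion
  coefficients (`crossover_times()`);
* long-time MD slope
  $4 v_d \lambda_d\lambda_s/[\Lambda(\mu-\lambda_d+\lambda_s+\Lambda)]$;
  the long-time MSD crossover $t_l^{(2)}$ from diffusive to ballistic
  growth has no compact closed form and is estimated numerically
  (`msd_long_crossover()`) as the intersection of the fitted diffusive
  asymptote $a + bt$ (fitted where the local log-log slope is within 0.15
  of 1) with the ballistic asymptote (long-time MD slope squared).

### The particle-level oracle

`simulate_particles()` is an exact event-driven simulation of the
underlying jump-drift-diffusion process (exponential waiting times;
Gaussian increments between events; doubling replaces a settled cell by a
right- and a left-mover at its position).  It is the independent check
that the continuum moments describe the particle process: the tests
require agreement within three standard errors, with a lineage-clustered
variance estimate because descendants of one founder are correlated.  It
emulates ideal point particles with perfectly exponential transitions — it
shares all idealizations of the continuum model (no volume exclusion, no
speed variability, no chemotactic memory), so agreement validates the
mathematics, not the biology.

## Linear stability of the interacting model

Linearizing about a homogeneous stationary state
$\hat\rho_+ = \hat\rho_-$, $\hat\rho_0 = (2\mu/\lambda_d)\hat\rho_+$ gives,
per wavenumber, a $3\times3$ operator `fourier_jacobian()`: transport
contributes $-\mathrm{i}kv_\pm - Dk^2$ on the mover diagonal, attraction
couples movers to the settled perturbation with $+\kappa k^2\hat\rho_\pm$,
and repulsion adds $-\kappa_0\hat\rho_0 k^2$ to the settled diagonal.  Its
eigenvalues $s_i(k)$ (`dispersion_branches()`) are computed by numerical
eigen-decomposition — deliberately not by a closed-form cubic, which is
numerically fragile — and continued across the $k$ grid by
minimal-distance matching so that branch crossings do not scramble labels.

The leading branch satisfies $s_1(0) = E_3$ and, for $\kappa_0 = 0$,
saturates at $2\kappa\hat\rho_+\lambda_s/D - \lambda_d$ as
$k \to \infty$, giving the two endpoint stability conditions
($\mu \ge \lambda_s$ and $\lambda_d \ge 2\kappa\hat\rho_+\lambda_s/D$);
`is_stable()` checks these and can additionally scan
$\mathrm{Re}\,s_1(k)$ densely, which catches band instabilities at
intermediate $k$ that the endpoints miss.  With $\kappa_0 > 0$ the settled
branch decays as $-\kappa_0\hat\rho_0k^2$, so short wavelengths are always
damped and the instability band acquires a largest root $k_r$
(`largest_unstable_root()`; bracketing on a dense grid plus bisection):
patterns fit into a periodic box of length $L$ only if
$k_r > k_0 = 2\pi/L$.

### The separatrix and the density normalization

`separatrix_fit()` scans the reduced speed difference
$v_r = (v_+-v_-)/(v_++v_-)$ and bisects on the dimensionless maximum speed
$v_m = \max(v_+,v_-)/\sqrt{D\lambda_e}$ for the point where $k_r = k_0$,
then fits $v_m^f(v_r) = c_0 + c_1 v_r + c_2 v_r^2$.

The linearization densities matter here, because $\kappa$ and $\kappa_0$
multiply $\hat\rho_\pm$ and $\hat\rho_0$.  The package normalizes the
homogeneous state of the pattern-formation presets by unit conserved
density, $\hat R = \hat\rho_+ + \hat\rho_- + 2\hat\rho_0 = 1$, i.e.
$\hat\rho_\pm = \lambda_d/(2(2\mu+\lambda_d))$ — the natural convention
when densities are measured in units of the total initial density.  With
the preset rates ($\lambda_s = \lambda_d = \mu = 0.1\lambda_e$,
$\kappa = 0.2/\lambda_e$, $\kappa_0 = 0.05/\lambda_e$,
$D = 10^{-3}L^2\lambda_e$) this yields
$(c_0, c_1, c_2) \approx (2.76, 2.78, -1.20)$.  The alternative
normalization $\hat\rho_+ = 1$ (which reproduces the marginal-stability
configuration of the attraction-only preset `fig7`, where
$D = 2v_+^2/\lambda_e$ makes the short-wavelength condition exactly
marginal) flattens the curvature to $c_2 \approx -0.15$; the unit-$\hat R$
convention is therefore adopted as the package default for the `fig8`,
`fig9` and `fig10` presets and is an explicit, overridable argument
(`homogeneous_state_from_R()`).

## The nonlinear PDE solver

`pde_integrate()` advances the full model on a periodic grid with
classical RK4 in time and second-order central differences in space; the
interaction term is discretized in conservative flux form
$[F_{i+1/2} - F_{i-1/2}]/\Delta x$ with face-centered
$F = (\partial_x U)\rho$, so transport and interactions move mass without
creating it (the tests verify the discrete integral of those terms
vanishes to $10^{-12}$).  Central advection is appropriate at the default
grid Péclet numbers ($v\Delta x/D < 1$ for the pattern presets); the
compiled core aborts on NaN and treats densities below $-10^{-8}$ as a
step-size misconfiguration, clipping smaller undershoots to zero.  A
CFL-type bound, $\Delta t \le \min(\Delta x/v_{\max},\,
\Delta x^2/2D_{\mathrm{eff}})$ with
$D_{\mathrm{eff}} = D + (\kappa+\kappa_0)\max\rho_0$, is enforced before
every run.  Defaults follow the regime the model was studied in:
$\Delta t = 10^{-4}/\lambda_e$, $n_x = 256$ ($128$ for scans), up to
$10^6$ steps with an early exit once the state changes by less than
$10^{-8}$ per $10^3$ steps — a pointwise criterion, so uniform and static
patterns exit early while traveling waves run to completion.

Runs are initialized from the uniform stationary state (the logistic
fixed point, found by damped Newton iteration, in logistic mode) plus
seeded i.i.d. Gaussian noise of relative amplitude $10^{-3}$ — "small
fluctuations" made concrete; the amplitude is a config key, not a
constant.  All randomness flows through R's RNG, so runs are reproducible
from a single seed.

## Waves and the state diagram

`wave_speed()` measures the translation speed of a steady pattern from the
periodic cross-correlation shift between consecutive late snapshots, with
sub-grid precision from parabolic interpolation of the correlation peak,
averaged over pairs and reported in units of $\sqrt{D\lambda_e}$.  The
estimator recovers an imposed rigid translation to $10^{-3}$ relative
accuracy and is invariant under relabeling of the spatial origin.  The
cross-correlation uses the total density profile for robustness;
per-species speeds are available as a diagnostic and agree for genuine
traveling waves — in this model all three populations migrate together at
a common speed, whatever their intrinsic run speeds.

`classify_pattern()` labels a trajectory uniform / static wave / traveling
wave using a relative amplitude threshold (default $10^{-2}$) and a
dimensionless speed tolerance (default $10^{-2}$).  Neither value is
physically distinguished; they separate the noise floor from saturated
patterns at the default noise amplitude and are exposed as arguments.

`state_diagram()` locates, for each $v_r$, the transition $v_m$ by
bisection on PDE runs and fits the same quadratic as the linear theory.
Two classification protocols exist:

* `"threshold"` — the final amplitude exceeds the threshold.  Faithful to
  the idea of a saturated steady state, but it requires runs long enough
  for unstable modes to actually saturate.  At the scan scale used here
  ($2\times10^5$ steps, i.e. $t = 20/\lambda_e$) the leading growth rate
  anywhere in the unstable region is at most $\approx 0.09\,\lambda_e$, so
  a $10^{-3}$ perturbation cannot reach a $10^{-2}$ amplitude in any run
  and this protocol cannot resolve the transition.
* `"growth"` (default) — fit the exponential rate of the fundamental box
  mode $k_0$ of the total density over the second half of the run and
  call the cell unstable when the rate is positive, refining the
  transition by secant interpolation of the rate's zero across the final
  bisection bracket.  The sign change of that rate *is* the separatrix
  condition $k_r = k_0$, so this protocol is unbiased at short run times
  and essentially seed-independent.

With 5 values of $v_r$, bisection depth 5, $n_x = 128$ and
$2\times10^5$ steps per run (about 35 PDE runs, well under two minutes on
one CPU), the growth protocol gives
$(c_0, c_1, c_2) \approx (2.76, 2.81, -1.23)$, within a bisection
resolution of the theoretical separatrix at every scanned $v_r$.  These
problem sizes are the package's validation defaults; production scans can
raise the step budget and let the `"threshold"` protocol classify saturated
patterns directly.

## Known limitations

* The spectral-moment machinery applies to free cells only; interacting
  moments would require the full PDE plus averaging.
* The expansions for the moments are derived for the settled-cell initial
  condition; an initially mobile cell has simply linear short-time
  behavior and the same long-time asymptotes, and is not treated
  separately.
* The dispersion analysis linearizes about the *linear* model's
  stationary state; for the logistic model it is a good guide only far
  from carrying capacity.
* One spatial dimension, symmetric tumbling, no demographic noise during
  evolution (noise enters only the initial condition), no
  run-reverse-flick kinematics, no nematic or higher-dimensional
  extensions.
* Everything the tests validate concerns this idealized model; agreement
  between the continuum and particle descriptions says nothing about how
  faithfully either describes real *Caulobacter* populations.
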