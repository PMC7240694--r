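---
title: "Orientational relaxation and dynamic heterogeneity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orientational relaxation and dynamic heterogeneity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringhet)
```

This vignette is the package's account of its science: the observables and
models it implements, the assumptions behind them, the numerical choices
that were genuinely open, and what the synthetic-data validation does and
does not establish about real trajectories.

## The observable

Terminal orientational relaxation of a polymer is measured through a unit
vector $\mathbf{u}(t)$ directed along the molecule's longest dimension:

* **linear chains** — along the end-to-end vector, from the first to the
  last backbone bead (`end_to_end_series()`);
* **rings** — along a *diameter vector*, connecting two beads roughly half
  a contour apart (`diameter_series()`).

For a ring of $N$ beads ($N$ even) the package pairs bead $i$ with bead
$i + N/2 - 1 \pmod N$ for **every** cyclic placement $i = 0,\dots,N-1$,
giving $N$ directed tracer vectors per ring. The half-contour pairing
convention admits nearby variants ($N/2-1$, $N/2$, or a subset of
placements); we enumerate all placements at offset $N/2-1$ because each
tracer is correlated only with itself over time, so near-antipodal
duplicates are harmless and maximize statistics. The offset is exposed as
an argument for users who prefer another convention. Odd $N$ is rejected
outright: half-contour pairing is not defined there, and silently rounding
the offset would change the observable.

The decay of memory is the multi-time-origin time autocorrelation function
(TACF)

$$C(t) \;=\; \left\langle \mathbf{u}(t_0 + t)\cdot\mathbf{u}(t_0)
\right\rangle_{t_0,\ \mathrm{tracers}},$$

computed by `molecule_tacf()` as a direct sum over all admissible origins
(equilibrium dynamics depend only on time differences, so every origin is
admissible; `origin_stride` thins them if desired). Because the vectors are
unit by construction, $C(0)=1$ holds structurally — no normalization is
divided out. The lag grid is the native frame grid up to
`max_lag_fraction` (default 0.5) of the trajectory: longer lags average
over too few origins to be useful. Log-spaced thinning happens only at fit
time so the per-lag sampling counts stay interpretable.

**Assumptions.** Coordinates must be continuous (unwrapped) molecule
images; orientation vectors are meaningless across periodic-image jumps,
and the package deliberately performs no unwrapping of its own. The
multi-origin average assumes stationarity of the underlying dynamics.

## Decay models

### KWW stretched exponential

`fit_kww()` fits
$C(t) = \exp\!\left[-(t/\tau_{\mathrm{KWW}})^{\beta}\right]$ by weighted
nonlinear least squares. $\beta \le 1$ measures the breadth of the
underlying relaxation spectrum — the further below 1, the more
heterogeneous the dynamics. The terminal (integral) relaxation time follows
in closed form,

$$\tau_0 \;=\; \int_0^\infty C(t)\,dt
\;=\; \frac{\tau_{\mathrm{KWW}}}{\beta}\,\Gamma(1/\beta),$$

implemented by `tau0_from_kww()` and attached to every fit, so the identity
holds to machine precision by construction.

Numerical choices, all configurable through `kww_control()`:

* **Fit window**: lags from 0 up to the curve's first negative crossing
  (`first_negative_crossing()`), or the full window if it never crosses.
  Truncation happens before fitting; beyond the crossing the curve is
  noise.
* **Log-thinned points, equal weights**: at most 200 points uniform in
  log-lag (always keeping $t=0$). A fit on the raw linear grid would let
  the densely sampled early decade swamp the tail decades that carry the
  terminal-time information.
* **Bounds and multistart**: $\beta \in (0.05, 1]$,
  $\tau_{\mathrm{KWW}}$ searched in log space between a tenth of the grid
  spacing and $10^4\times$ the window; starts from 5 log-spaced $\tau$
  guesses $\times\ \beta \in \{0.4, 0.7, 1.0\}$ with a small seeded jitter
  (default seed 20200330, echoed in the fit). Ties resolve to the lowest
  residual. Non-convergence never raises — the best-effort parameters come
  back flagged `converged = FALSE`, and $\beta$ pinned at its bound is
  flagged separately.

### Constrained multi-exponential decomposition

`fit_multiexp()` fits
$C(t) = \sum_{i=1}^{n_m} A_i e^{-t/\tau_i}$ under $A_i \ge 0$,
$\sum_i A_i = 1$, $\tau_i > 0$ — each mode a relaxation mechanism, its
amplitude the mechanism's weight. The sum constraint is enforced by
optimizing $n_m - 1$ free amplitudes, bounded in $[0,1]$, with the last as
remainder and a quadratic penalty on negative remainders; mode times are
optimized in log space from multiple log-spaced start grids. Returned modes
are tau-ascending; numerically coincident modes are merged so the times are
strictly increasing.

`select_num_modes()` makes "the smallest number of modes that describes the
curve" reproducible: it accepts the first $n_m$ whose RMS residual is
already below `abs_tol` ($10^{-6}$, i.e. numerically exact for noiseless
curves), or whose improvement on adding one further mode falls below
`rel_improvement` (10% relative). The absolute floor matters: once a
noiseless curve is fit to $10^{-8}$, relative improvements between
essentially-zero residuals are numerical noise and must not drive the
choice.

### Per-molecule terminal times

`tau0_numeric()` integrates each molecule's own TACF by the trapezoidal
rule from $t=0$ to its first negative crossing — the standard cutoff for a
noisy terminal decay, after which the curve fluctuates about zero and would
only add variance. Molecules whose curve never crosses zero inside the
window are integrated over the full window and **flagged truncated, never
dropped**: they are precisely the slow molecules, and dropping them would
bias the slow tail that heterogeneity analysis exists to measure. Note the
estimator is slightly biased low (it cuts the positive tail beyond the
first noise-induced crossing); the bias shrinks as per-molecule noise
falls, which is why tracer count and trajectory length matter.

## Heterogeneity statistics

`build_ensemble()` collects per-molecule times and normalizes them by a
reference time — by convention the ensemble KWW $\tau_0$ of a reference
system (e.g. the pure ring melt), so blends of different composition share
an axis. Whether the reference should instead be the mean of per-molecule
integrals is a legitimate open choice; the package defaults to the
ensemble-KWW convention and takes the reference as an explicit number, so
either is available. On the ensemble:

* `ensemble_median()` — sample median (midpoint convention for even
  counts): the time by which half the molecules have fully relaxed;
* `tail_fraction(ens, x)` — fraction of molecules with normalized time
  **strictly** greater than $x$ (strictness documented and switchable);
* `relaxation_histogram()` — probability-normalized histogram, default bin
  width 0.1 in normalized time, range auto-extended to the data maximum.

## Synthetic ground truth

The generators define the study conditions for every test; all are
bit-reproducible from spec + seed.

**Rotational diffusion** (`generate_rotational_diffusion()`): each molecule
is a unit vector taking tangent-plane Gaussian steps of variance
$2 D_r\,dt$ per component, renormalized to the sphere. Its TACF is exactly
$e^{-2 D_r t}$ (the $\ell=1$ correlation of isotropic rotational
diffusion). Specs with $dt\,D_r > 0.05$ are rejected — beyond that the
discretization of the sphere walk biases the correlation.

**Free-draining bead-spring chains** (`generate_rouse_chain()`):
overdamped Euler–Maruyama dynamics of harmonic springs along a ring or
linear backbone, in units $k_BT = 1$ (lengths nm, times ns). No excluded
volume and no hydrodynamics — deliberately, because the free-draining model
is exactly solvable, which is what a fitting-stage oracle needs; chemical
fidelity is a non-goal. For a ring, the raw diameter vector
$\mathbf{d}_i = \mathbf{r}_{i+m} - \mathbf{r}_i$ relaxes as a finite mode
sum

$$\frac{\langle\mathbf{d}(t)\cdot\mathbf{d}(0)\rangle}{\langle d^2\rangle}
= \sum_{p=1}^{N-1} w_p\, e^{-t/\tau_p},\qquad
\tau_p = \frac{\zeta}{4k\sin^2(p\pi/N)},\qquad
w_p \propto \frac{\sin^2(pm\pi/N)}{\sin^2(p\pi/N)},$$

implemented in `rouse_ring_diameter_modes()` and cross-checked in the tests
against an independent eigendecomposition of the connectivity Laplacian at
$N=6$ (machine-precision agreement) and against simulation within a derived
3$\sigma$ Monte-Carlo band. Two subtleties the tests account for, found
during validation:

* the mode sum is exact for the **raw-vector** correlation; the
  **unit-vector** TACF of a Gaussian vector sits up to $\approx 0.065$
  below it at intermediate correlations (normalizing a 3-D Gaussian is not
  linear), so the unit-vector check carries that documented allowance;
* the equilibrium mean-square bond length of a **ring** is
  $3(N-1)/(Nk)$, not the open-chain $3/k$ — loop closure correlates the
  bonds — inflated $O(k\,dt/\zeta)$ by the Euler scheme.

The integrator enforces $dt < \zeta/(4k)$ and discards a warm-up of ten
times the slowest mode time by default.

**Designed mixtures** (`generate_mixture_ensemble()`): molecules are
assigned by a seeded draw to populations relaxing exponentially
($D_r = 1/(2\tau)$) or as a KWW stretched exponential. The KWW populations
use a deterministic time-dilation of a unit-rate diffusion clock,
$s(t) = (t/\tau)^\beta$ — a sampling surrogate, not a physical model, and a
**non-stationary** one: its prescribed curve is realized from the initial
time origin, and multi-origin averaging biases it upward (the tests use a
single origin there). Exponential populations are stationary and
origin-average cleanly; all heterogeneity validations use them. The
`n_tracers` option gives each molecule several independent tracer vectors,
emulating the $N$ diameter tracers of a real ring and controlling
per-molecule noise. These mixtures emulate the *phenomenology* of
threaded/unthreaded subpopulations in ring–linear blends — slow
subpopulations with designed weights — not the threading geometry itself.

## What the validation does and does not show

Problem sizes were chosen as desk-scale study conditions: ensembles of
120–800 molecules, $400$–$2000$ frames, bead-spring runs of $\sim 5\times
10^4$ steps. At these sizes the test suite establishes that: TACFs match
analytic correlations within derived Monte-Carlo bands; noiseless KWW and
multi-exponential spectra are recovered to $10^{-3}$–$10^{-2}$ relative;
the published closed-form terminal times follow from their KWW parameters;
a designed 20% slow subpopulation is recovered within the binomial 99%
interval with its median within $\pm 0.05$; and the fitted ensemble
$\beta$ decreases monotonically as the mixture spread widens.

What passing these tests does **not** show: fidelity to any real chemistry
(the generators have no excluded volume, hydrodynamics, entanglement or
actual threading geometry); correctness of per-molecule statistics under
the strong tracer–tracer correlations of a real ring (synthetic tracers
are independent); or the published heterogeneity percentages of atomistic
blend trajectories, which would require the original microsecond MD data.
The per-molecule integral's truncation bias (above) also means absolute
medians carry a systematic few-percent underestimate at realistic noise.

## Degenerate inputs and tie-breaks

Zero-length orientation vectors error with frame and tracer index rather
than being normalized. Mismatched lag grids in `ensemble_tacf()` error —
curves are never silently resampled. A TACF that never crosses zero is a
valid outcome everywhere (`NA` crossing, truncated integral, full-window
fit). Multistart ties resolve to the lowest residual, then the earliest
start; mode-count ties to fewer modes. Fits never throw on
non-convergence; they return flagged best-effort parameters.

## Pipeline

`run_pipeline()` executes simulate/load → TACF → fits → heterogeneity from
one validated YAML config (`validate_config()` collects *all* schema errors
at once and fills documented defaults). Reports echo the config and seed,
contain no timestamps, and are byte-identical across reruns; stage failures
are recorded with diagnostics and downstream stages skipped. Configs are
YAML rather than a bespoke format so that specs, system topologies and
pipeline settings share one parser.
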