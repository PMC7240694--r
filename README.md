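# ringhet

Quantifying **dynamic heterogeneity in the orientational relaxation of ring
and linear polymers** from particle-coordinate trajectories.

In a melt, terminal relaxation is usually summarized by one ensemble-average
correlation function. But when molecules experience different topological
environments — most dramatically, ring molecules threaded by linear chains in
ring–linear blends — individual molecules relax at very different rates, and
the ensemble average hides exactly the physics of interest. `ringhet`
implements the per-molecule analysis: it resolves the relaxation of every
molecule, models the decays, and measures how broad the resulting
relaxation-time distribution is. It is aimed at polymer-simulation
practitioners who have long molecular-dynamics or Brownian-dynamics
trajectories and want reproducible heterogeneity statistics.

## What it computes

For each molecule a unit orientation vector **u**(t) is tracked along the
trajectory: the end-to-end vector for a linear chain, or the family of
diameter vectors (bead pairs N/2 − 1 bonds apart, all cyclic placements) for
a ring of N beads. The package then computes the multi-time-origin time
autocorrelation function (TACF)

    C(t) = ⟨ u(t₀ + t) · u(t₀) ⟩          (averaged over origins t₀ and tracers)

and models its decay three ways:

* **KWW stretched exponential** — `fit_kww()` fits
  `C(t) = exp[−(t/τ_KWW)^β]`; the stretching exponent β ≤ 1 measures the
  breadth of the underlying relaxation spectrum (smaller β ⇒ stronger
  heterogeneity), and the terminal relaxation time follows in closed form,
  `tau0_from_kww()`:

      τ₀ = τ_KWW · Γ(1/β) / β

* **Constrained multi-exponential decomposition** — `fit_multiexp()` fits
  `C(t) = Σᵢ Aᵢ exp(−t/τᵢ)` with `Aᵢ ≥ 0`, `Σ Aᵢ = 1`, resolving the decay
  into relaxation modes (loop dynamics, molecular diffusion, threading
  release…); `select_num_modes()` picks the smallest adequate mode count.

* **Per-molecule numeric integration** — `tau0_numeric()` integrates each
  molecule's own TACF up to its first negative crossing; `build_ensemble()`,
  `ensemble_median()`, `tail_fraction()` and `relaxation_histogram()` turn
  the collected times (normalized by a reference system's relaxation time)
  into the distribution, median and slow-tail statistics that quantify
  heterogeneity.

Seeded synthetic generators with exactly known answers —
`generate_rotational_diffusion()` (single-exponential TACF),
`generate_rouse_chain()` (free-draining bead-spring chains with an analytic
mode spectrum, `rouse_ring_diameter_modes()`), and
`generate_mixture_ensemble()` (designed fast/slow populations emulating
unthreaded vs multiply-threaded rings) — provide ground truth for every
stage. `run_pipeline()` drives the whole analysis from one YAML config.

Units are nm and ns throughout. Coordinates must be unwrapped (continuous
molecule images); no periodic-box handling is performed.

## Worked example

A designed blend-like ensemble: 80% fast molecules (τ = 1 ns) and 20% slow
"threaded" molecules (τ = 10 ns), 200 molecules with 6 tracer vectors each:

```r
library(ringhet)

tau0_from_kww(7.1, 0.78)      # closed-form terminal time for tau_KWW = 7.1 ns, beta = 0.78
#> [1] 8.195637

spec <- mixture_spec(
  populations = list(
    list(weight = 0.8, kind = "exponential", tau_ns = 1),
    list(weight = 0.2, kind = "exponential", tau_ns = 10)),
  n_molecules = 200, dt = 0.05, n_frames = 1500, seed = 42, n_tracers = 6)
mix <- generate_mixture_ensemble(spec)

ens_curve <- ensemble_tacf(mix$series, max_lag_fraction = 0.3)
fit_kww(ens_curve)
#> KWW stretched-exponential fit
#>   tau_KWW = 1.555 ns,  beta = 0.6835,  tau0 = 2.015 ns
#>   rms residual 0.0328 on window [0, 22.45] ns

select_num_modes(ens_curve)$fit
#> Multi-exponential decomposition, n_m = 2
#>   mode 1: tau = 0.9679 ns, A = 0.7894
#>   mode 2: tau = 9.373 ns, A = 0.2106
#>   sum(A) = 1, rms residual 0.00105

relax <- lapply(mix$series, function(s)
  tau0_numeric(molecule_tacf(s, max_lag_fraction = 0.3)))
summary(build_ensemble(relax, reference_time = 2))
#> Relaxation-time ensemble: 200 molecules, reference time 2 ns
#>   median tau0/tau_ref = 0.518; tail fraction > 1: 0.2; truncated: 31
#>   fraction with tau0/tau_ref > 1: 20.0%
#>   fraction with tau0/tau_ref > 2: 20.0%
#>   normalized-time quartiles: 0.417  0.477  0.518  0.661  6.05
```

Reading the output: the ensemble fit has β ≈ 0.68 — well below 1, the
signature of heterogeneity — and the two-mode decomposition recovers the
designed populations almost exactly (τ ≈ 0.97 and 9.4 ns with weights
0.79/0.21 against the designed 1 and 10 ns at 0.8/0.2). The per-molecule
statistics find the designed 20% slow tail exactly, and the median sits near
0.5 because the fast population relaxes at about half the 2 ns reference
time. The 31 "truncated" molecules are slow ones whose TACF never crossed
zero inside the lag window; they are kept and flagged rather than dropped,
since dropping them would bias the slow tail.

The same analysis runs on trajectory files via
`read_xyz_trajectory()` + `diameter_series()`/`end_to_end_series()`, or end
to end from a YAML config with `run_pipeline()` (thin CLI wrapper in
`inst/cli/ringhet.R`).

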