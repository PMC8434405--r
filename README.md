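# hydrashell

Hydration-shell dynamics analysis for molecular dynamics trajectories.

Water at a protein surface is not bulk water: its diffusion is slowed, its
reorientation retarded by charged groups, and its hydrogen bonds to the
protein break and re-form on two separate time scales. These observables —
and their abrupt change at the protein dynamical transition near 200 K —
are how protein–water coupling is quantified from MD simulations.
`hydrashell` is an R package for computing them from trajectory data
(PDB / GRO / DCD), aimed at anyone analysing solvated-biomolecule
simulations who wants validated estimators rather than one-off scripts.

## What it computes

**Structure** — per-atom/per-residue RMSF with optional least-squares
superposition; RMSD time series against a reference frame (Kabsch fit);
Shrake–Rupley solvent-accessible surface area.

**Transport** — multi-time-origin mean square displacement
MSD(Δ) = ⟨|r(t₀+Δ) − r(t₀)|²⟩ with the Einstein-relation diffusion
coefficient D = slope/6; windowed per-period displacement summaries;
radial distribution functions g(r) with first-peak statistics and the
g(r)min/g(r)max de-packing ratio; two-segment breakpoint detection for
dynamical-transition scans.

**Hydration dynamics** — distance-defined shell membership (water oxygen
to nearest reference atom); the intermittent residence correlation
C_r(t) = ⟨N(t₀)⁻¹ Σ_i δ_{i,t₀+t}⟩ fitted by the biphasic stretched-
exponential model

    C_r(t) = n_s exp(−(t/τ_s)^γ) + n_1 exp(−t/τ_1)

and the water-dipole reorientation autocorrelation
C_μ(t) = ⟨μ(0)·μ(t)⟩ fitted by A_μ exp(−t/t_μ).

**Hydrogen-bond kinetics** — geometric detection (D–A < 0.35 nm and
H–D–A angle < 30°); per-frame counts; the continuous bond lifetime τ_HB
(mean unbroken bonded run, censored at the ends); the intermittent
population correlation c(t) = ⟨h(0)h(t)⟩/⟨h⟩ and its 1/e relaxation
time τ_R.

**Synthetic ground truth** — generators for Brownian walkers (known D),
rigid rotors under isotropic rotational diffusion (known t_μ = 1/(2·D_rot)),
two-state Markov on/off series (known occupancy, dwell time, and
correlation decay), geometric shell systems whose occupancy matrix is
recoverable exactly, and piecewise-linear temperature scans — so every
estimator can be validated against an analytic answer.

A YAML-driven `run_pipeline()` chains the four analysis stages with
per-stage error trapping, CSV/JSON outputs stamped with a config hash, and
a machine-readable report. A thin command-line wrapper lives in
`inst/scripts/hydrashell.R`.

## Worked example

Two-state shell kinetics around a single reference site, then diffusion
recovery — both against known ground truth:

```r
library(hydrashell)

traj <- gen_shell_system(n_waters = 300, k_on = 0.05, k_off = 0.2,
                         cutoff = 0.6, box_edge = 4, dt = 0.1,
                         n_frames = 4000, seed = 42)
mem <- shell_membership(traj, reference_selection = 1, cutoff = 0.6)
cr  <- residence_correlation(mem, window = 30, origin_stride = 5)
fit <- fit_residence(cr, fix_gamma = 1, bounds = list(tau_s = c(300, 3000)))
print(fit)
cat(sprintf("decay rate 1/tau_1 = %.3f /ps (ground truth k_on + k_off = %.2f)\n",
            1 / fit$params$tau_1, 0.25))

w <- unwrap_coordinates(gen_brownian(500, D = 1e-3, box_edge = 5, dt = 1,
                                     n_frames = 2000, seed = 42))
D <- diffusion_coefficient(msd(w, max_lag = 100, origin_stride = 10), 10, 100)
cat(sprintf("D = %.3e +/- %.1e nm^2/ps (truth 1e-3), R^2 = %.4f\n",
            D$D, D$se, D$r_squared))
```

Output:

```
fit_result [biexp_stretched] converged=TRUE
  n_s    0.206535 +/- 0.000981
  tau_s  3000 +/- 1.82e+03
  gamma  1 +/- 0
  n_1    0.792892 +/- 0.000975
  tau_1  3.99917 +/- 0.0112
  rms residual 0.00226
decay rate 1/tau_1 = 0.250 /ps (ground truth k_on + k_off = 0.25)
D = 9.988e-04 +/- 1.3e-07 nm^2/ps (truth 1e-3), R^2 = 1.0000
```

Reading the fit: the shell population decays with a single rate — the fast
component `tau_1 = 4.0 ps` recovers the generator's `k_on + k_off = 0.25/ps`
exactly — while the "slow" branch (`tau_s` pinned beyond the window,
amplitude `n_s = 0.21`) is the stationary occupancy plateau of a two-state
system, here equal to the ground-truth `k_on/(k_on+k_off) = 0.2`. The
diffusion coefficient comes back within 0.2% of the generator value.

## Layout

```
R/                  estimators, generators, readers, pipeline
tests/testthat/     unit + property tests with independent brute-force oracles
scripts/acceptance.R  ground-truth recovery report
vignettes/          methods vignette: models, conventions, design choices
inst/scripts/       command-line wrapper
```
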