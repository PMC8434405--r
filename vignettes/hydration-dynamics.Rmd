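---
title: "Quantifying hydration-shell dynamics from MD trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hydration-shell dynamics from MD trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrashell)
```

## The problem

Water in contact with a protein surface behaves differently from bulk
water: its translational diffusion slows several-fold, its reorientation is
retarded near charged side chains, and its hydrogen bonds to the protein
exchange on two distinct time scales — a sub-picosecond librational
breaking-and-reforming, and a slower relaxation tied to water leaving the
surface altogether. These observables also organize the protein dynamical
transition (PDT): below roughly 200 K both protein and hydration water show
small, harmonic mean square displacements; above it, anharmonic motion
switches on in both simultaneously, visible as a slope change in MSD versus
temperature.

`hydrashell` implements the estimator stack needed to quantify this
coupling from any trajectory of coordinate frames: structural fluctuation
metrics, transport metrics, hydration-shell residence and reorientation
correlation functions with their model fits, and hydrogen-bond population
kinetics. Internally everything is in GROMACS units — nm for length, ps for
time — and distances are always measured under the minimum-image convention
in an orthorhombic periodic box.

## Estimators and their models

### Structural fluctuation

`rmsf()` computes, per atom, the square root of the *time-averaged*
squared deviation from the time-mean position. The `1/T` normalization
matters: without it the quantity grows with trajectory length and stops
being comparable across runs, so we normalize and state so here.
`rmsd_series()` measures frame-by-frame deviation from a reference frame;
by default each frame is first superposed (`superpose()`, a Kabsch SVD fit
with the determinant correction that excludes reflections), so the series
reflects internal mobility rather than global rotation/translation.
`sasa()` is a sphere-point (Shrake–Rupley-style) solvent-accessible surface
area: quasi-uniform golden-spiral points on each extended atom sphere, a
point buried if inside any neighbour's extended sphere. Defaults — Bondi
radii, 0.14 nm water probe, 960 points — give about 1% accuracy on
sphere-cap geometry, verified against the analytic two-sphere formula.

### Transport

`msd()` is the multiple-time-origin estimator of
$\mathrm{MSD}(\Delta) = \langle |r_i(t_0+\Delta) - r_i(t_0)|^2 \rangle$,
averaged over selected atoms and all origins on a configurable stride. It
requires unwrapped coordinates (`unwrap_coordinates()` reconstructs
continuous paths from wrapped ones, valid while per-frame jumps stay below
half the box edge) and refuses input whose frame-to-frame jumps look like
box wraps. `diffusion_coefficient()` is the Einstein-relation slope over a
user-chosen lag window divided by 6, with its standard error and the fit's
R² so a ballistic (quadratic) regime is visible as a poor linear fit.
`msd_windowed()` implements the per-period variant used in temperature
scans: the trajectory is cut into non-overlapping windows (200 ps default)
and the squared displacement across each window is averaged, with the
spread over windows as the error bar.

`rdf()` histograms minimum-image center–target distances, normalized per
frame by shell volume $4\pi r^2 \Delta r$ and bulk target density $N_B/V$.
One subtlety: when a center is itself a member of the target selection it
can never count itself, so the density that center sees is $(N_B-1)/V$;
we apply that correction, which keeps the ideal-gas limit $g \equiv 1$
unbiased at finite particle number. `rdf_peak_stats()` finds the first
local maximum and the following minimum (after optional 5-bin
moving-average smoothing — raw histograms are noisy and extrema detection
on them is meaningless) and reports the de-packing ratio
$g_\min/g_\max$ of the first hydration layer; the first-minimum position
is the conventional hydration-layer thickness.

`detect_transition()` finds the temperature at which an observable changes
trend: an exhaustive scan over interior grid points, fitting an independent
least-squares line to each side (the break point belongs to both
segments). Continuity at the break is *not* enforced — on the 5–10 point
grids this is meant for, the unconstrained two-line fit is the simplest
defensible estimator, and enforcing continuity would bias the break
location on noisy data. Edge candidates are excluded because a one-point
"segment" cannot define a line; equal slopes within tolerance raise a
`degenerate` flag rather than reporting a meaningless break.

### Hydration-shell residence and reorientation

`shell_membership()` marks water *i* as occupying the shell at frame *t*
iff the minimum-image distance from its **oxygen** to the nearest
reference atom is at most the cutoff (inclusive). Distances are taken from
the oxygen, not the hydrogens, so the cutoff has the same meaning as an
oxygen-based RDF; 0.6 nm is the conventional protein-wide shell and 0.5 nm
a tighter local shell around a single residue.

`residence_correlation()` is the survival fraction of the shell
population:
$$C_r(t) = \Big\langle \tfrac{1}{N_{t_0}} \sum_{i \in \text{shell}(t_0)}
\delta_{i,t_0+t} \Big\rangle_{t_0},$$
with the **intermittent** convention — $\delta$ is evaluated at $t_0+t$
regardless of excursions in between, so re-entries count. A `continuous`
variant (a water is discounted permanently at its first exit) is provided
behind a flag because much of the literature uses it; the two answer
different questions and can differ by an order of magnitude in apparent
time scale. Origins with an empty shell are skipped and the per-lag origin
count is reported.

`fit_residence()` fits the biphasic model
$$C_r(t) = n_s\, e^{-(t/\tau_s)^\gamma} + n_1\, e^{-t/\tau_1},$$
a Kohlrausch–Williams–Watts stretched exponential for the slow, spatially
heterogeneous escape of shell waters plus a fast exponential for boundary
exchange. Bounds are $n_s, n_1 \in [0, 1.5]$, $\gamma \in (0.2, 1]$, and
$\tau \in (\mathrm{d}t,\, 10\times\mathrm{span})$; the fit is nonlinear
least squares (Levenberg–Marquardt via `minpack.lm`) with at least five
seeded multi-starts, keeping the best converged objective. The amplitudes
are not constrained to sum to one — that normalization holds only
approximately on real curves — but a deviation beyond 0.1 triggers a
warning. Uncertainties come from the local quadratic approximation at the
optimum. Times are ordered post hoc so the stretched branch is reported as
the slow one; if a converged fit lands the other way round the values are
swapped with a `reordered` flag. Two practical notes from validation:
(i) on a *two-state* system the slow branch is really the stationary
plateau, and the decomposition is only well conditioned if you pin
$\gamma = 1$ (`fix_gamma`) and push `tau_s` beyond the window through
`bounds`, letting $\tau_1$ carry the decay; (ii) a series with no decay
(constant, or all-permanent residents) returns `converged = FALSE` rather
than a fabricated fit.

`water_dipoles()` defines the dipole geometrically: the unit vector from
the oxygen along the bisector of the two O–H bonds, with hydrogen
positions re-imaged relative to the oxygen so molecules straddling the
boundary are handled. For 3-site waters (SPC/E and kin) this coincides
with the charge dipole and needs no charge metadata.
`dipole_autocorrelation()` averages $\mu(t_0)\cdot\mu(t_0+t)$ over waters
and origins, optionally restricted per origin to waters in a shell at that
origin, and `fit_reorientation()` fits $A_\mu e^{-t/t_\mu}$.

### Hydrogen-bond kinetics

`detect_hbonds()` applies the geometric criterion: donor–acceptor
distance strictly below 0.35 nm *and* the angle **at the donor** between
D→H and D→A strictly below 30°. The angle convention matters — an
H-vertex reading would change every number — so it is fixed here and
stated prominently. Boundary ties are excluded because the criterion is a
strict inequality. Donors are N/O atoms with a bonded hydrogen, acceptors
are N/O; same-molecule pairs are excluded.

From the per-pair indicator $h_i(t)$ (`hbond_existence()`), two time
scales:

* `continuous_lifetime()` — $\tau_{HB}$, the mean length of unbroken
  bonded runs. Runs touching either trajectory end are censored and
  excluded, since their full length is unknown and including them biases
  the mean.
* `intermittent_correlation()` — $c(t) = \langle h(0)h(t)\rangle /
  \langle h \rangle$, the probability that a pair bonded at a random
  origin is bonded again a lag $t$ later regardless of intermediate
  breaks; the normalization uses the same origin set per lag so
  $c(0) = 1$ exactly. `relaxation_time()` reads $\tau_R$ off the first
  crossing of $1/e$, linearly interpolated between bracketing lags — an
  estimator free of model assumptions. A curve that plateaus above $1/e$
  (large stationary bonded fraction) raises an error naming the plateau
  instead of extrapolating silently; exponential-tail extrapolation is
  available behind an explicit flag and its result is flagged.

On any intermittently re-forming system $\tau_{HB} \le \tau_R$, since
unbroken runs are subsets of intermittent persistence; the test suite
checks this as an invariant.

## The synthetic generators

Real MD output is large, slow to produce, and has no known ground truth.
The generators provide the opposite: small systems whose dynamical
parameters are exact by construction.

* `gen_brownian()` — independent Gaussian walkers, per-component step
  variance $2D\,\mathrm{d}t$, so unwrapped MSD $= 6Dt$ exactly in
  expectation. Wrapped coordinates are returned; the unwrapped truth rides
  along as an attribute.
* `gen_rotors()` — rigid 3-site waters (O–H 0.1 nm, H–O–H 109.47°, the
  SPC/E geometry) whose orientation evolves by small random rotations:
  each step a rotation vector with i.i.d. $N(0,\, 2 D_r \mathrm{d}t)$
  components per axis, the small-step sampling of isotropic rotational
  diffusion. Any body-fixed unit vector then decays as
  $\langle u(0)\cdot u(t)\rangle = e^{-2 D_r t}$, so the dipole
  reorientation time is $1/(2D_r)$. The step bound
  $D_r\,\mathrm{d}t \le 0.05$ keeps the small-rotation expansion valid.
* `gen_two_state_series()` — on/off Markov chains with first-order
  per-step probabilities $k_{on}\mathrm{d}t$ and $k_{off}\mathrm{d}t$.
  The first-order discretization mirrors frame-sampled MD data; its bias
  against the continuous-time forms is $O(\mathrm{d}t \cdot k)$ and, at
  the enforced bound $\mathrm{d}t(k_{on}+k_{off}) \le 0.1$, well inside
  every tolerance used in the tests (e.g. at
  $\mathrm{d}t\,k = 0.011$ the correlation bias is below $10^{-3}$ and the
  $1/e$-crossing bias below 1%). Stationary occupancy is
  $k_{on}/(k_{on}+k_{off})$, dwell times are exponential with mean
  $1/k_{off}$, and the indicator autocorrelation is
  $p + (1-p)e^{-(k_{on}+k_{off})t}$ — three independent closed forms, each
  checked by a separate estimator.
* `gen_shell_system()` — embeds a two-state matrix into geometry: one
  reference site at the box center, each water's oxygen placed inside
  $0.9\times$cutoff when "on" and beyond $1.1\times$cutoff when "off".
  The deliberate margin makes geometric membership recovery *exact*, so a
  full pipeline run must reproduce the generating matrix bit for bit.
* `gen_piecewise_linear()` — a continuous two-slope function with optional
  Gaussian noise, for breakpoint detection.

What the generators deliberately do **not** emulate: force-field
interactions, coupling between translation, rotation and bond states,
spatial heterogeneity of a real protein surface (one reference site, not
many), or temperature as an explicit variable — the rates *are* the
temperature surrogate. Passing tests therefore demonstrate that the
estimators are correct, not that any particular protein behaves a
particular way; on real data the scientific burden shifts to sampling and
selection choices.

## Numerical and design choices

* **Indices are 1-based** (atoms, frames), following R convention
  throughout the ecosystem this package lives in; residue numbering is
  preserved from input files, so author-numbered residues map directly.
* **Orthorhombic boxes only.** Triclinic input is rejected loudly rather
  than silently mis-measured.
* **File formats.** PDB (single/multi-model, via bio3d) and GRO
  (single/multi-frame, fixed-column parser) define topologies and frames;
  DCD is read via bio3d. XTC is not supported: its compressed XDR coding
  has no R reader, and a hand-written lossy-decompression parser is out of
  proportion here — convert to DCD or multi-frame GRO. Bonds come from
  CONECT records when present, else a covalent-radius distance heuristic
  (1.2 × radius sum) on the first frame, which is what makes PDB waters
  without CONECT records usable.
* **Tie-breaks and degenerate inputs.** Minimum-image components live in
  $[-L/2, L/2)$; shell membership is inclusive at the cutoff while the
  H-bond criterion is strict, each following its definition; empty shells
  and all-zero bond series raise analysis errors instead of returning
  NaN; superposition refuses fewer than 3 or collinear points.
* **Fit seeds.** Multi-start jitter is seeded (default or caller-supplied),
  so every fit is reproducible; pipeline outputs are a pure function of
  (inputs, config, seed), and output tables carry the config hash.

## Validation problem sizes

The test-suite fixtures are sized so each statistical tolerance sits
several standard errors away from the expected value: 500 walkers × 2000
frames for diffusion (5% band, SE ≈ 1.5%), 1000 rotors × 401 frames for
reorientation, $10^4$ chains × $10^4$ frames for the two-state closed
forms (≈ $9\times10^4$ dwell events), and 300 waters × 4000 frames for
the end-to-end shell pipeline (decay-rate SE ≈ 2–4% against a 10% band).
Estimator-versus-oracle identities are checked at $10^{-10}$ on 50–100
frame fixtures, where the double-loop references are affordable.

## Known limitations

* No triclinic boxes, velocities, forces, or binary trajectory writing.
* The RDF normalization assumes a roughly homogeneous target phase in the
  box; for a solvated protein the "bulk" density includes shell waters,
  as it does in the standard estimator.
* SASA ignores periodic images (the solute is assumed whole and
  re-imaged); `rmsf`/`rmsd` likewise operate on re-imaged molecules.
* The continuous residence variant is $O(\text{origins}\times\text{lags}
  \times\text{waters})$ and meant for moderate windows.
* Luzar–Chandler reactive-flux rate decomposition and $l=2$ reorientation
  correlators are out of scope.
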