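---
title: "Enhanced sampling and free-energy analysis on a periodic dihedral torus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enhanced sampling and free-energy analysis on a periodic dihedral torus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Photoswitching in canonical phytochromes is driven by rotation of the
chromophore's D-ring pyrrole about the bonds joining it to the C-ring: a
double-bond torsion $\Phi$ and a single-bond torsion $\Psi$. The two
photoproducts (the red-absorbing resting form and the far-red-absorbing
illuminated form) correspond to different basins of the free-energy surface
$F(\Phi, \Psi)$, separated by barriers of order $10^2$ kJ/mol that thermal
dynamics cannot cross on simulation time scales. Estimating such surfaces
therefore requires enhanced sampling; interpreting them requires
metastable-state extraction, convergence diagnostics, and barrier-to-rate
reasoning.

`torusves` implements that entire analysis chain on *synthetic surrogates*:
analytic periodic model potentials with exact gradients sampled by
overdamped Langevin dynamics, and programmable toy-protein coordinate
trajectories for the structural observables. Everything downstream of the
sampler — reweighting, clustering, diagnostics, structural analysis — is
exactly the machinery one would run on production trajectories, but here
every estimate can be scored against analytic ground truth.

## Model potentials and dynamics

A surface is a sum of product von Mises wells,
$$U(z) = -\sum_i d_i \exp\!\big[c_i(\cos(\Phi-\Phi_i) +
\cos(\Psi-\Psi_i) - 2)\big],$$
optionally plus explicit Fourier terms, shifted so $\min U = 0$. The von
Mises kernel is smooth, $2\pi$-periodic and has an analytic gradient, so
barrier heights calibrate directly: with well-separated wells the global
barrier equals the deepest well's depth, and the basin floors sit at depth
differences. The canonical four-basin layout places the middle, vertical,
horizontal and corner states $S_m, S_v, S_h, S_c$ at $(0,0)$, $(0,\pi)$,
$(\pi,0)$, $(\pi,\pi)$; the true basin coordinates of the system being
emulated are only known graphically, so these schematic centers are
configurable throughout.

Dynamics is overdamped Euler–Maruyama on the torus,
$z \leftarrow \mathrm{wrap}(z - \beta D \nabla(U+V)\Delta t +
\sqrt{2D\Delta t}\,\xi)$, with $k_B = 0.0083145$ kJ/mol/K and $T = 300$ K
($k_BT \approx 2.494$ kJ/mol). Time is measured in steps: the surrogate
deliberately carries no physical nanosecond scale. A stability guard
refuses parameter combinations whose single-step drift reaches $\pi$. The
discretization biases the stationary law by
$O(\beta D \Delta t\, U'')$; at the default $D\Delta t \le 0.005$ and the
stiffest well curvatures used here the distortion stays below
$\sim$0.5 kJ/mol, well under the tolerances of interest. All generators
take seeds and are bitwise reproducible.

Two calibrated "phantom" presets exercise the pipeline end to end: a
red-resting-like surface with global amplitude 140 kJ/mol whose deepest
basin is $S_h$ and whose $S_m$ well is 25 kJ/mol shallower, and a
far-red-like surface with amplitude 125 kJ/mol whose deepest basin is
$S_m$. They are pipeline self-consistency fixtures — calibrated to the
order of magnitude of the emulated system, never a reconstruction of its
landscapes. Note that a depth asymmetry of 25 kJ/mol reads back as a
state free-energy asymmetry of $25 - k_BT\ln(140/115) \approx 24.5$
kJ/mol: state free energies include the (here slightly depth-dependent)
basin widths.

## Variationally enhanced sampling

The bias $V_\alpha$ is a real Fourier series over the torus: products of
$\{1, \cos kx, \sin kx\}$ per coordinate, $(2N+1)^2$ basis functions, 441
at the default order $N = 10$. A convex functional of the bias is
minimized so that the biased marginal approaches a uniform target
distribution; its stochastic gradient for coefficient $k$ is
$-\langle f_k\rangle_{\text{batch}} + \langle f_k\rangle_{p_T}$, where the
batch is the stride of steps since the previous update (default stride
1000, learning rate $\mu = 0.1$). At convergence
$V \approx -U + \text{const}$ on the basis span, which is what the
variational-recovery tests assert.

Two choices here were genuinely open, and both matter at large landscape
amplitudes:

* **Curvature term.** Plain first-order updates let the instantaneous
  coefficient vector random-walk: with 441 weakly-restored modes the
  instantaneous bias wanders with an RMS residual comparable to the
  landscape itself (we measured $\sim$130 kJ/mol on the 140 kJ/mol
  preset), and the running mean inherits the drift. The averaged
  stochastic-descent family this method belongs to therefore includes a
  Hessian-vector correction,
  $\alpha \leftarrow \alpha - \mu[\nabla\Omega(\bar\alpha) +
  H(\bar\alpha)(\alpha - \bar\alpha)]$ with
  $H v \approx \beta(\langle f (f{\cdot}v)\rangle -
  \langle f\rangle\langle f{\cdot}v\rangle)$ estimated on the same batch.
  It is the default (`curvature = TRUE`); plain first-order updates remain
  selectable and are adequate for shallow surfaces.

* **When averaging starts.** The acting bias is the running mean of the
  instantaneous iterates. If averaging starts at iteration one, the mean
  must itself climb to the depth of each well before the walker escapes,
  which forces the instantaneous iterate to overshoot by up to a factor of
  two and leaves slowly-decaying artifacts (we measured +240 kJ/mol over
  the shallowest basin of the 140 kJ/mol preset). `run_ves` therefore runs
  the first `avg_start_fraction` (default 0.1) of the iterations as a fill
  stage under the instantaneous bias and starts the running mean
  afterwards. With both choices in place the averaged bias converges to an
  RMS residual below 0.1 kJ/mol on every preset used in the tests,
  deep or shallow. The `optimizer_state`/`sgd_update` helpers keep the
  plain running-mean semantics (mean over all completed iterations), so
  the averaging identity remains separately testable.

## Reweighting and landscapes

Each stored sample carries the bias energy at its sampling time; its
umbrella weight is $e^{\beta V_t}$, scaled to $[0,1]$ by the maximum over
retained samples. A leading burn-in fraction (default 0.02 of the series,
mirroring the discard of the earliest, not-yet-equilibrated weights) is
masked from every estimator. The landscape is a weighted histogram on a
periodic grid (default $50\times 50$ here; resolution is an explicit
argument everywhere), converted through
$F = -\beta^{-1}\ln \hat p$ and pinned so the deepest finite bin is
exactly 0. Empty bins are flagged `NA` and excluded from arithmetic rather
than imputed — pseudo-counts would silently bias barrier estimates.
`fes_from_potential` provides the matching bin-averaged analytic reference,
so accuracy statements compare like with like (bin-average against
bin-average; the bin average also explains why a 30 kJ/mol amplitude reads
back as $\approx 29.1$ on a 50-bin grid).

Marginal profiles integrate out the other coordinate through the Boltzmann
weights. Two barrier notions are provided: the global span of the
landscape, and the minimax path barrier — the lowest saddle connecting two
bins across all 4-connected periodic paths, computed by a widest-path
variant of Dijkstra and verified exactly against threshold-search
enumeration on small random grids. The saddle level is
direction-independent; directed barriers differ exactly by the difference
of the basin floors.

## Metastable states

Samples within `fe_cutoff` of the weight maximum on the free-energy scale
(default 45 kJ/mol; the threshold should exceed the highest basin floor of
interest by a few $k_BT$ of capture margin, and stay below the saddles)
are sieved and clustered under the toroidal metric. Clustering is
density-based with no seed and no cluster-count input; for scalability the
density is pooled on a periodic grid of cells no wider than half the
clustering radius, clusters grow through overlapping core cells, and
points inherit their cell's label. That keeps the procedure deterministic
and linear-time at millions of samples while quantizing membership
decisions by at most a quarter of the radius. Clusters connected by a
saddle lower than `merge_threshold` (default 5 kJ/mol $\approx 2 k_BT$)
above the shallower floor are merged into one superstate before labeling —
the operational form of treating rapidly-exchanging substates as one
thermodynamic state. Labels are assigned by nearest reference centroid with
closest-claimant conflict resolution and the fixed tie order
$S_m, S_v, S_h, S_c$.

A state's free energy is $-\beta^{-1}\ln$ of its members' share of the
total retained weight, with the deepest state pinned to 0 per landscape.
Cross-landscape differences $\Delta_s = F^A_s - F^B_s$ then follow the
convention that negative values mean the state is more populated in
landscape A. The sieve truncates each basin's Boltzmann integral at the
cutoff; for a 2D basin the missing fraction is $(1+\beta u)e^{-\beta u}$
at capture depth $u$, under 10% for $u \gtrsim 10$ kJ/mol and mostly
cancelling between landscapes.

## Convergence diagnostics

Landscape convergence is monitored through cumulative checkpoints: the
statistical distance between successive checkpoints is the symmetrized
(Jeffreys) Kullback–Leibler divergence between the probability vectors
$p \propto e^{-\beta F}$ over jointly finite bins (Jensen–Shannon is
selectable; plain KL is asymmetric and the symmetrization choice was
open). A plateau is declared at the earliest checkpoint from which every
sliding window (default 5 increments) keeps the mean absolute distance
slope under `slope_tol` (default 0.01 nats/checkpoint) *and* keeps the
occupied-bin fraction stable to within 5% relative. The support condition
is essential: reweighting makes the in-basin estimate of a confined,
still-filling run stabilize early, so a slope-only rule would declare
exactly the wrong runs converged. A run still expanding its explored
region is by definition not converged. Landscape variability over a
trailing window is the per-bin population standard deviation averaged over
jointly finite bins.

For circular observables (e.g. an in-plane rotation angle), the package
provides the circular mean, a seeded percentile bootstrap whose resampled
means are wrapped around the point estimate before taking quantiles (so
intervals are seam-safe; percentile rather than BCa, since only a mean
with a spread is needed), and a wrap-aware, prominence-based mode counter
for detecting bimodal angle distributions.

## Structural observables

The toy-protein generator lays residues (three atoms each) on a line 0.8 nm
apart, so non-adjacent residues never touch unless a feature is planted:
a driven dihedral quadruple realized exactly before noise, Gaussian jitter
on a mobile region, and hydrogen-bond and contact geometries satisfied in
exactly the stated fraction of frames. On top of it sit the standard
trajectory observables: proper-rotation-only Kabsch superposition, RMSD
after fitting, per-residue RMSF about the time-mean structure (isotropic
jitter of width $\sigma$ per coordinate reads back as
$\sigma\sqrt{3}$), geometric hydrogen bonds (donor–acceptor distance
$\le$ 0.35 nm and hydrogen–donor–acceptor angle $\le 30^\circ$ — the
common MD-analysis convention, both configurable, since no precise
criterion was fixed by the emulated study), and residue–residue contact
frequencies at 0.35 nm minimum heavy-atom distance with a sequence-
neighbour exclusion window. All of these are checked against brute-force
all-pairs references and for rigid-motion invariance.

## Rates and photon energies

Free-energy barriers convert to time scales through
$\tau = \tau_0 e^{\Delta F^\ddagger/k_BT}$ with a default attempt time
$\tau_0 = 1$ ps — a typical molecular prefactor, stated as an explicit
assumption rather than derived from landscape curvature. With it, a
75 kJ/mol barrier maps to $\sim 10^1$ s (seconds-scale dark reversion), a
100 kJ/mol barrier to $\sim 10^5$ s (hours-to-days), and a $\sim$33 kJ/mol
barrier to microseconds — order-of-magnitude consistency checks, not rate
predictions. Photon energies use $E = N_A h c/\lambda$ with
$N_A h c = 119\,626.57$ kJ·nm/mol, mapping the 660–700 nm red/far-red
band to about 171–181 kJ/mol.

## Problem sizes used by the tests

The variational-recovery check runs $N = 2$ on a two-term cosine surface
for $2000 \times 500$ steps; the landscape-accuracy check runs the
30 kJ/mol four-state preset at $N = 10$ for $4000 \times 1000$ steps and
compares 50-bin landscapes where the reference is below 20 kJ/mol; the
phantom read-back runs each preset for $10^7$ steps. Two-state and
mixture state-energy checks use $10^6$ exact Boltzmann draws; bootstrap
coverage uses 500 repetitions of $n = 200$, 2000 replicates each. These
sizes put sampling noise comfortably below each check's tolerance while
keeping the whole suite at the scale of minutes on one core.

## What passing tests do and do not show

The surrogate shares with real chromophore-protein systems the features
that exercise this pipeline — periodicity, multiple deep basins,
basin-dependent widths, activated barrier crossing, seam-straddling
states, and evolving (hence reweighting-sensitive) biases. It omits, by
design, everything the emulated study's atomistic stage provides: solvent
and force-field physics, inertial and thermostat effects, coupling of the
dihedrals to protein degrees of freedom, and any physical time scale.
Passing tests therefore certify the correctness and internal consistency
of the estimators at known ground truth; they say nothing about force-field
accuracy or about the biological system beyond the orders of magnitude
used for calibration.

## Worked example

```{r, eval = FALSE}
library(torusves)

cfg_a <- ves_config(potential = list(preset = "pr"), seed = 1)
cfg_b <- ves_config(potential = list(preset = "pfr"), seed = 2)
res_a <- run_pipeline(cfg_a)
res_b <- run_pipeline(cfg_b)

res_a$barrier                  # ~137 kJ/mol (built amplitude 140)
states_table(res_a$states)     # four labeled states, S_h deepest
compare_landscapes(res_a, res_b)$delta_f  # S_m asymmetry ~ +25 kJ/mol
```
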