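---
title: "Turbulent dynamics and Hopf whole-brain modelling with turbodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Turbulent dynamics and Hopf whole-brain modelling with turbodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turbodyn)
```

## The problem

Resting-state fMRI gives a few minutes of slow, noisy BOLD signal per brain
parcel. A productive way to summarise the spatiotemporal organisation of
these signals is by analogy with fluid turbulence: treat each parcel as an
oscillator with an instantaneous phase, measure how strongly phases
synchronise *locally* around each parcel at a chosen spatial scale, and
quantify the variability of that local synchronisation across space and
time. Clinical applications compare these summaries between groups — for
instance control subjects versus patients with traumatic brain injury,
where local synchronisation variability at long spatial ranges is reduced —
and then ask *mechanistic* questions with a whole-brain model fitted to the
same data: at what global coupling does the model best reproduce the data,
and how strongly does the fitted model react to simulated stimulation?

`turbodyn` implements this full pipeline: the model-free turbulence
measures, the coupled Stuart-Landau (Hopf) whole-brain model with its
distance-resolved functional-connectivity fit, in silico perturbation
measures, simulated lesion attacks on structural connectivity, the group
statistics used around these measures, and a synthetic cohort generator so
that everything is testable end-to-end without imaging data.

## Model-free measures

**Phases.** BOLD matrices (N nodes × T volumes) are demeaned per node and
band-passed with a zero-phase second-order Butterworth filter at
0.008–0.08 Hz — the conventional resting-state band; the high-pass removes
scanner drifts and the low-pass attenuates physiological noise. The filter
is run forward and backward (no phase distortion, which would corrupt the
phases) over series padded by odd reflection, which limits edge transients
at short scan lengths; the band-pass itself is the `signal` package's
Butterworth design. Instantaneous phases come from the FFT analytic-signal
(Hilbert) construction. All-zero nodes have no phase and are flagged
rather than silently zeroed.

**Local order parameter.** For node $n$ at volume $t$ and spatial scale
$\lambda$ (mm$^{-1}$),

$$R_n(t)\, e^{i\vartheta_n(t)} \;=\;
  \frac{\sum_p C_{np}\, e^{i\varphi_p(t)}}{\sum_q C_{nq}},
  \qquad C_{np} = e^{-\lambda\, r_{np}},$$

with $r_{np}$ the Euclidean distance between parcel centroids in mm and the
self term $C_{nn}=1$ included. $R \in [0,1]$ measures local
synchronisation: small $\lambda$ probes long distances
($\lambda = 0.01 \approx 100$ mm), large $\lambda$ short ones
($0.30 \approx 3$ mm). The default grid is $\lambda = 0.01$ to $0.30$ in
steps of $0.03$: ten scales, hence nine adjacent-scale transitions.

From $R$ the package derives:

* **amplitude turbulence** $D$ — the standard deviation of $R$ pooled over
  all nodes and volumes (population form: the defining brackets are plain
  averages);
* **node-level metastability** — the per-node temporal standard deviation
  of $R$ (population form again);
* **network-level turbulence** — $D$ restricted to nodes of each of the
  seven canonical resting-state networks;
* **information cascade flow** $F(\lambda)$ — the per-node lagged Pearson
  correlation between $R_\lambda(t+\Delta t)$ and
  $R_{\lambda-\Delta\lambda}(t)$, averaged over nodes, with
  $\Delta t$ = one TR (one sample — the natural unit for "successive time
  steps" at this sampling rate); the **information cascade** is the average
  of $F$ over transitions;
* **information transfer** — pairwise temporal correlations of $R$ decay
  with inter-node distance; their log–log slope inside the inertial
  subrange is the transfer exponent. Pair correlations are averaged inside
  50 equal-width distance bins (midpoints as $r$) before the fit, which
  stabilises it; non-positive correlations have no logarithm and are
  excluded with a count.

The inertial subrange — the distance window where scale-free decay is
assumed — defaults to 10–100 mm and is configurable; the bounds match the
$\lambda \leftrightarrow$ mm annotations of the scale grid, and no sharper
definition is available for BOLD data. Hemispheres are pooled throughout,
since every average above runs over all nodes.

## The Hopf whole-brain model

Each parcel is a Stuart-Landau oscillator — the normal form of a
supercritical Hopf bifurcation — with bifurcation parameter $a_n$ (noisy
fixed point below 0, self-sustained oscillation above) and intrinsic
angular frequency $\omega_n$ taken from the data as the periodogram peak in
0.008–0.08 Hz. Oscillators couple diffusively through a structural
connectome $C_{np}$ scaled by a single global coupling $G$:

$$\dot x_n = (a_n - x_n^2 - y_n^2)\,x_n - \omega_n y_n
  + G\sum_p C_{np}(x_p - x_n) + \nu\,\eta_n(t),$$

with the symmetric equation for $y_n$ and additive Gaussian noise of
standard deviation $\nu = 0.01$ on both components. The real part $x$ is
the BOLD-like observable; $y$ is the oscillator state hidden from the
scanner.

The connectome follows the exponential distance rule
$C_{np} = e^{-\lambda_c r_{np}}$ with $\lambda_c = 0.18$ mm$^{-1}$, the
decay established as best-fitting in this modelling framework (distinct
from the turbulence scale $\lambda$). An empirical structural matrix, when
available, supplies long-range exceptions: weights become
$\max(e^{-\lambda_c r}, \mathrm{SC}_{np})$ after bringing SC onto the
$[0,1]$ scale (matrices already in $[0,1]$ are used as given, so a stated
exception weight is honoured exactly).

**Numerical choices.** Integration is Euler–Maruyama at $dt = 0.1$ s with
noise scaled by $\sqrt{dt}$, a 20 s burn-in, and decimation to the TR by
stride — standard practice for this model class; the scheme, step, burn-in
and initial conditions (small Gaussian perturbations of the origin, unless
given explicitly) are design choices since no canonical values exist. The
resting baseline is $a_n = -0.02$ for every node, the value that makes the
perturbation range $[-0.02, 0]$ (below) a perturbation *from* rest *toward*
criticality. Any state exceeding $10^6$ in magnitude aborts the run with a
diverged-integration error; such runs are dropped and counted wherever
repetitions are aggregated. The integrator is compiled (Rcpp) and draws its
noise from R's RNG, so runs are bit-reproducible under a seed. Halving
$dt$ changes noiseless trajectories at first order, as expected for Euler.

## Fitting the global coupling

The distance-resolved functional connectivity $FC(r)$ is the average
Pearson correlation of z-scored node pairs within equal-width distance
bins; Kolmogorov's structure function follows as $S(r) = 2(1 - FC(r))$.
The fitting error between a simulated and an empirical profile is the
Euclidean distance of their $FC(r)$ vectors over the inertial-subrange
bins (an affine transform of $S(r)$, so the argmin is unchanged). The
error is a true metric on profiles, which the tests verify directly.

`sweep_G()` simulates the model over a grid of $G$ (the full study design
is 0 to 3 in steps of 0.01 with 100 repetitions; desk-scale analyses use a
0.1 step with 5 repetitions), averages the error over repetitions, and
returns the working point $G^\* = \arg\min$, ties broken toward smaller
$G$. Two numerical choices matter:

* the empirical target is the **group-averaged** profile of a condition
  (per-subject profiles averaged bin-wise), the more stable of the two
  possible orderings of averaging and fitting;
* repetition sub-seeds are **shared across the grid** (common random
  numbers), so simulation noise moves the whole error curve coherently
  instead of jittering adjacent grid values independently — this leaves
  each grid value's error estimate unchanged in expectation while greatly
  stabilising the argmin.

At desk scale (60 nodes, 145 volumes, 6-subject group profiles, grid step
0.1, 5 repetitions) the sweep recovers a generating coupling of 0.8 or 1.4
to within 0.2 in at least 8 of 10 seed replicates, which the acceptance
tests check; single 5-minute scans are noisy enough that tighter recovery
should not be expected at this scale.

## In silico perturbation

With the model at a fitted working point, each perturbation trial redraws
every node's bifurcation parameter uniformly in $[-0.02, 0]$ and runs the
perturbed and an unperturbed simulation; both are passed through the
empirical pipeline and the local order parameter at scale $\lambda_s$. Per
node, the trial yields the difference of time-averaged $R$. Then

* **susceptibility** $\chi$ = node average of the trial-mean difference —
  how strongly the system reacts to stimulation;
* **information-encoding capability** $I$ = node average of the
  across-trial dispersion of the difference — how distinguishably different
  stimuli are encoded.

The dispersion is reported as a standard deviation; a variance convention
also circulates for this quantity, so `capability_moment = "var"` preserves
the alternative. $\lambda_s$ defaults to 0.01, the long-distance scale
where group differences in the empirical measures concentrate; the draws
are uniform (the natural choice for a stated range, with nothing arguing
otherwise). Perturbed and unperturbed runs share their noise realisation
by default (`paired_seeds`): under a zero-width perturbation the
difference is then exactly zero, and at equal trial counts the paired
design has strictly smaller Monte-Carlo variance of $\chi$ — both checked
in the tests.

## Simulated lesion attack

Lesion masks are reduced to a patients × nodes table of overlap fractions
(lesioned volume within a parcel divided by parcel volume). The attack
threshold is $\tau = \text{mean} + k\,\mathrm{SD}$ (population SD) of the
positive overlaps pooled across patients and nodes; pooling is a documented
choice — the alternative readings (per-node means, raw mm³ volumes) are not
recoverable from the method's description — and it reproduces the expected
behaviour that the attack set shrinks sharply as $k$ grows through
1.5, 2, 3, 4. A node is attacked when its overlap reaches $\tau$
(inclusive, the documented tie rule). Attacked nodes yield a multiplicative
N × N mask: factor 0 in binary mode (complete disconnection), or
$1 - \text{lesion frequency}/\text{patients}$ in weighted mode. A pair's
entry combines its endpoint factors with the minimum by default —
disconnection is described per node, and the minimum avoids
double-penalising pairs attacked at both ends; `pair_combine = "product"`
preserves the alternative. Weighted masks with full lesion frequency
collapse exactly onto binary masks. The attacked connectome is the
elementwise product of the original with the mask.

## The synthetic cohort generator

The generator exists so that every downstream stage runs on data whose
ground truth is known. It emulates the *shape* of a longitudinal TBI
resting-state study — two groups, ~145 retained volumes at TR = 2 s,
parcellations from tens to 1,000 nodes — not real anatomy.

* **Geometry:** centroids sampled uniformly in two mirrored hemisphere
  ellipsoids (axis lengths 70 × 85 × 60 mm, centres at $x = \pm 40$ mm),
  spanning 150 mm so pairwise distances cover the 3–150 mm range the scale
  grid probes. Parcel volumes tile the ellipsoid volume into n parcels
  with right-skewed (log-normal) variability; network labels come from
  spatial k-means into seven clusters, giving spatially contiguous
  pseudo-networks.
* **Lesions:** spherical foci (default three per patient, radius 15 mm —
  the centimetre scale of focal contusions) centred on parcel centroids;
  parcel overlap is computed analytically from the sphere–sphere
  intersection, with a voxelised brute-force oracle in the tests.
* **BOLD:** the Hopf simulator itself, with per-node frequencies drawn
  uniformly in 0.03–0.07 Hz (inside the analysis band). The control-like
  group is simulated at $G = 1.4$, the injury-like group at $G = 0.8$ on a
  connectome additionally weakened by a weighted 1.5-SD attack — mirroring
  the empirical findings that the patient working point is lower and that
  focal lesions disconnect structure. Subjects at the same index share
  noise seeds across groups, pairing the contrast.

Because the generator *is* the fitted model, passing tests demonstrate
internal consistency of the pipeline — measures respond to coupling and
disconnection in the expected directions, parameters are recoverable —
not that real BOLD data behave this way. Real data add hemodynamics,
measurement noise, head motion and inter-subject variability that the
generator deliberately omits.

## Group statistics

The comparison machinery wraps the standard routines — `ks.test` for the
Kolmogorov–Smirnov distance between node-level metastability
distributions, `p.adjust` for Benjamini–Hochberg FDR, `cor.test` for
brain–behaviour Pearson correlations, `wilcox.test` for rank-sum and
signed-rank tests, and `aov` behind a thin adapter for the factorial
(group × scale) and repeated-measures ANCOVA designs, which records the
fitted formula. Each wrapper is validated in the tests against an
independently coded oracle (pooled-grid ECDFs, hand step-up arithmetic,
closed-form correlation, permutation enumeration). The top-quantile node
tally selects the $\lceil qN \rceil$ largest absolute differences (ties by
node order) so the per-network counts always sum to the selected-set size;
this rank-based rule behaves sensibly under heavy ties, where a
strict-threshold rule would select nothing.

## A worked example

```{r example, eval = FALSE}
geom <- make_geometry(60, seed = 1)
cohort <- make_cohort(geom, n_per_group = 4, seed = 2)

# model-free: turbulence at the long-distance scale
cohort_turbulence(cohort, lambda = 0.03)

# model-based: fit G for the control-like group
om <- estimate_frequencies(bandpass(bold_ts(cohort$bold[[1]], cohort$TR)))
emp <- group_fc_profile(cohort$bold[1:4], geom$distances)
sw <- sweep_G(cohort$connectomes$control, hopf_config(omega = om), emp,
              G_grid = seq(0.2, 2, 0.1), reps = 5, seed = 3)
autoplot(sw)

# reactivity at the working point
run_perturbation(cohort$connectomes$control,
                 hopf_config(omega = om, G = sw$G_star),
                 perturbation_protocol(trials = 30), seed = 4)
```

## Problem sizes and limitations

The tests and the acceptance script run at desk scale — 60–200 node
geometries, 55–145 volumes, 5 repetitions per grid value, 15–30
perturbation trials — sizes at which the statistical acceptance checks
(parameter recovery, directional group contrasts in at least 8 of 10 seed
replicates) are stable; the full study design (1,000 nodes, grid step
0.01, 100 repetitions and trials) is exposed through the same arguments
and defaults where a single number had to be chosen.

Known limitations: no hemodynamic forward model (the oscillator's real
part stands in for BOLD); no vortex or surface visualisation; lesion
overlap in the generator treats parcels as equivalent spheres; the
inertial-subrange bounds are a convention; and upstream volumetric fMRI
preprocessing (motion correction, normalisation, denoising, tractography)
is out of scope — the package starts from parcellated time series and
centroid tables.
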