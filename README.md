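# turbodyn

Multi-scale **turbulent-dynamics analysis of parcellated resting-state
BOLD signals**, with a coupled Stuart-Landau (Hopf) whole-brain model for
mechanistic follow-up. The package is written for computational
neuroscientists who have node × volume time-series tables (any
parcellation) and want to (i) quantify the spatiotemporal variability of
local synchronisation, (ii) fit a whole-brain model to the data's
distance-resolved functional connectivity, (iii) probe the fitted model
with in silico perturbations, and (iv) study how focal lesions — as
simulated structural-connectome attacks — change all of the above.

## The measures

Phases φₙ(t) are extracted from band-passed (0.008–0.08 Hz) BOLD via the
analytic signal. Around each node, phases are averaged with an exponential
spatial kernel of scale λ (mm⁻¹):

    Rₙ(t) e^{iϑₙ(t)} = Σₚ C_{np} e^{iφₚ(t)} / Σ_q C_{nq},   C_{np} = e^{−λ r_{np}}

The modulus R is the **Kuramoto local order parameter**; small λ probes
long distances (λ = 0.01 ≈ 100 mm), large λ short ones (0.30 ≈ 3 mm).
Derived measures: **amplitude turbulence** D (node–time pooled SD of R),
**node-level metastability** (temporal SD per node), **network-level
turbulence**, **information cascade flow / cascade** (lagged correlation of
R between adjacent scales / its mean), and **information transfer**
(log–log slope of pair correlations of R versus distance in the inertial
subrange).

The **Hopf model** couples Stuart-Landau oscillators
(dxₙ = [(aₙ − xₙ² − yₙ²)xₙ − ωₙyₙ + G Σₚ C_{np}(xₚ − xₙ)]dt + ν dW) on an
exponential-distance-rule connectome (λ_c = 0.18 mm⁻¹, optional long-range
exceptions). The global coupling G is fitted by grid search on the
distance-resolved FC(r) profile; the model at the working point G* is then
perturbed by redrawing the bifurcation parameters in [−0.02, 0], yielding
**susceptibility** χ and **information-encoding capability** I. Lesion
masks become node-overlap tables, SD-thresholded attack sets, and
binary/weighted disconnection masks multiplied into the connectome.

A synthetic cohort generator (brain-like two-ellipsoid geometries,
spherical lesions, Hopf-simulated BOLD) makes the whole pipeline testable
with known ground truth.

## Worked example

```r
library(turbodyn)

geom   <- make_geometry(60, seed = 1)            # 60-parcel synthetic brain
cohort <- make_cohort(geom, n_per_group = 4, seed = 2)

cohort_turbulence(cohort, lambda = 0.03)
#> # A tibble: 8 x 3
#>   subject    group   turbulence
#>   <chr>      <chr>        <dbl>
#> 1 control_01 control      0.207
#> 2 control_02 control      0.188
#> 3 control_03 control      0.182
#> 4 control_04 control      0.177
#> 5 injury_01  injury       0.173
#> 6 injury_02  injury       0.158
#> 7 injury_03  injury       0.161
#> 8 injury_04  injury       0.161
```

The injury-like group (simulated at lower coupling on a lesion-attacked
connectome) shows lower amplitude turbulence at the long-distance scale
λ = 0.03 — the direction seen empirically after traumatic brain injury.
Fitting and perturbing the model:

```r
om  <- estimate_frequencies(bandpass(bold_ts(cohort$bold[[1]], cohort$TR)))
emp <- group_fc_profile(cohort$bold[1:4], geom$distances)
sw  <- sweep_G(cohort$connectomes$control, hopf_config(omega = om), emp,
               G_grid = seq(0.2, 2, 0.1), reps = 5, seed = 3)
glance(sw)
#> # A tibble: 1 x 5
#>   G_star min_error  reps n_grid n_diverged
#>    <dbl>     <dbl> <int>  <int>      <int>
#> 1    1.1     0.488     5     19          0

pert <- run_perturbation(cohort$connectomes$control,
                         hopf_config(omega = om, G = sw$G_star),
                         perturbation_protocol(trials = 30), seed = 4)
glance(pert)
#> # A tibble: 1 x 5
#>      chi info_capability trials n_dropped lambda_s
#>    <dbl>           <dbl>  <int>     <int>    <dbl>
#> 1 0.0299          0.0195     30         0     0.01
```

The fitted working point `G_star = 1.1` sits near the cohort's generating
control coupling of 1.4 (single five-minute scans make FC profiles noisy;
the acceptance tests quantify recovery as within 0.2 in at least 8 of 10
seed replicates); χ and I quantify the model's reactivity to random
bifurcation-parameter perturbations. `autoplot(sw)` draws the fitting-error curve,
`autoplot()`/`tidy()`/`glance()` methods cover the other result types, and
`turbulence_summary()` computes every model-free measure across the full
scale grid in tidy tables.

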