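# pullgeom

Analysis of pulling-geometry experiments: single-molecule force
spectroscopy (SMFS) retraction curves and steered-MD (SMD) pulling
trajectories, of the kind used to show that a receptor's mechanical
strength depends on *which* subunit the load is applied through —
e.g. streptavidin tetramers whose biotin-binding subunits rupture near
100, 210 or 440 pN depending on the anchoring geometry, with the
binding-pocket lid (L3/4 loop) opening under load along the weak
geometries.

The package is for experimentalists and simulators who need the full
chain from raw channels to publishable statistics:

* **Trace analysis** — calibration and cantilever-bending correction,
  zero points, denoising, worm-like-chain (WLC) contour-length
  transformation, unfolding-event detection, ddFLN4 two-step fingerprint
  classification, terminal rupture force and loading rate.
* **Rupture statistics** — Bell–Evans rupture-force densities, modal
  forces, maximum-likelihood 1–3 component mixture fits (EM, BIC order
  selection), fixed-combination comparisons, and dynamic force spectra
  with barrier parameters $x^\ddagger = k_BT/\mathrm{slope}$ and $k_0$.
* **Trajectory metrics** — rupture force/frame/loading rate from SMD
  force series, lid-opening distance and angle metrics,
  unloaded-vs-loaded window histograms, replica-ensemble summaries.
* **Force-propagation networks** — contact-filtered (4.5 Å / 75%)
  correlation graphs weighted by $w_{ij} = -\log|C_{ij}|$,
  Floyd–Warshall optimal and suboptimal path ensembles (tolerance
  $-\log 0.5 = 0.69$), per-edge usage, 10-ns windows sampled every
  400 ps.
* **Synthetic data with ground truth** — SMFS retraction cycles with PEG
  elasticity, fingerprint unfolding and subunit-dependent terminal bonds;
  trajectories with programmed correlation structure and a
  load-triggered lid opening. All analysis stages are validated by
  parameter recovery against these generators.

The core rupture model: a bond under force escapes at rate
$k(F) = k_0\,e^{F x^\ddagger/k_BT}$; at constant loading rate $r$ the
rupture-force density is

$$p(F) = \frac{k_0}{r}\,e^{F x^\ddagger/k_BT}
\exp\!\left[\frac{k_0 k_BT}{x^\ddagger r}\bigl(1 - e^{F x^\ddagger/k_BT}\bigr)\right],
\qquad
F^* = \frac{k_BT}{x^\ddagger}\ln\frac{x^\ddagger r}{k_0 k_BT}.$$

Tethers follow the Marko–Siggia interpolated WLC, and force–extension
curves are inverted point-wise into contour-length space so unfolding
steps appear as discrete $\Delta L_c$ increments.

## Worked example

Simulate a trivalent (3SA) measurement spot and run the SMFS pipeline:

```r
library(pullgeom)

set <- generate_variant_dataset(
  variant_config("3SA", fingerprint_attach_rate = 0.95),
  n_traces = 150, acquisition_protocol(), seed = 122)

res <- pipeline_smfs(set)
res
#> <pg_smfs_result>
#>                stage n_in n_out
#> 1              input  150   150
#> 2       force_filter  150   136
#> 3 rupture_extraction  136   136
#> 4 fingerprint_filter  136    64
#> fits: 3SA

res$fits[["3SA"]]
#> <pg_mixture_fit> 2 component(s), n = 64, r = 2.06e+04 pN/s
#>   log-likelihood -306.36, BIC 633.51, converged: TRUE
#>         k0 x_dagger  kBT weight modal_force
#> 1 0.314243   0.4126 4.14 0.3425       88.17
#> 2 0.002608   0.2693 4.14 0.6575      202.21
```

Reading the output: of 150 retraction cycles, 136 showed interactions
above the 50 pN filter, all yielded a terminal rupture, and 64 carried
the complete two-step ddFLN4 fingerprint (ΔLc ≈ 15 and 16 nm) directly
before rupture — the certified single-tether events. BIC selects a
two-component Bell–Evans mixture for this trivalent spot, with most
probable rupture forces near 88 and 202 pN at the median loading rate of
2.1 × 10⁴ pN/s: the two weak-geometry populations (subunits A/C versus
B, generated at 100 and 210 pN modal force; a 64-event sample carries a
few-percent mode uncertainty). `tidy()`, `glance()` and `autoplot()`
work on fits, spectra, traces and metric series.

On the simulation side:

```r
pull <- generate_smd_pull_trajectory(toy_pull_model(), 200, seed = 5)
smd_rupture(pull)
#> # A tibble: 1 × 3
#>   rupture_force rupture_frame loading_rate
#>           <dbl>         <int>        <dbl>
#> 1          514.            87  5048992896.

ser <- pair_distance_series(pull, pull$metadata$lid_pair[1],
                            pull$metadata$lid_pair[2])
window_histograms(ser, 87, window_ns = 10)$shift
#> [1] 0.7768934     # nm; the generator programmed a 0.8 nm lid opening
```

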