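---
title: "Models and methods behind pullgeom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pullgeom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pullgeom)
```

pullgeom implements the analysis chain by which single-molecule force
spectroscopy (SMFS) retraction curves and steered-MD (SMD) pulling
trajectories are turned into subunit-resolved rupture statistics,
binding-pocket lid-opening metrics and force-propagation networks, for
systems such as engineered streptavidin tetramers probed through a
biotinylated fingerprint construct. Because raw AFM and MD data of that
kind are rarely deposited, the package ships synthetic-data generators
with known ground truth; every analysis stage is validated against them.
This vignette explains the models, the tunable parameters and the design
choices, and states what the synthetic tests do and do not show about
real data.

## Polymer elasticity and the contour-length transform

The tether (PEG linkers in series with folded protein) is modelled as a
serial worm-like chain using the Marko–Siggia interpolation

$$F(x) = \frac{k_BT}{L_p}\left[\frac{1}{4(1-x/L_c)^2} - \frac14 +
\frac{x}{L_c}\right],$$

the community-standard force law for PEG/protein tethers in the
10–500 pN range. `wlc_force()` and `wlc_extension()` are exact inverses
of each other (solved by a safeguarded Newton iteration on the convex
interpolation polynomial, to machine precision), which is what makes the
contour-length transform a true inversion test: `contour_length_transform()`
maps every sample of a force–extension curve to the unique contour length
consistent with its force, so unfolding steps appear as discrete jumps of
an otherwise constant series.

Points below `min_force` (default 10 pN) are masked: at low force the
fractional extension depends only weakly on $L_c$ and the inversion is
ill-conditioned. This threshold, like the persistence length default
$L_p = 0.38$ nm and the PEG contour length default 40 nm, is
configuration, not a constant — the PEG5000 linker's effective contour
and persistence lengths vary with chemistry and are rarely printed.

## Bell–Evans rupture kinetics

A loaded bond escapes its barrier at rate
$k(F) = k_0 e^{F x^\ddagger / k_BT}$. Under a constant loading rate $r$
this yields the rupture-force density

$$p(F) = \frac{k_0}{r} e^{F x^\ddagger / k_BT}
\exp\!\left[\frac{k_0 k_BT}{x^\ddagger r}
\left(1 - e^{F x^\ddagger / k_BT}\right)\right],$$

with mode $F^* = (k_BT/x^\ddagger)\ln(x^\ddagger r / k_0 k_BT)$ and the
linear $F^*$–$\ln r$ dynamic force spectrum that `dynamic_force_spectrum()`
fits. `sample_rupture_forces()` draws from this law by the exact inverse
transform, so the generator and the fitted model share no code path: the
sampler is checked against the analytic CDF by Kolmogorov–Smirnov
distance, and the fitting stack is checked by parameter recovery.

Mixture fits (`fit_mixture()`) are maximum likelihood on raw forces —
histograms are a visualization, not the estimator — via EM with
per-component weighted MLE in $(\log k_0, \log x^\ddagger)$, quantile-split
initialisation and ten jittered multi-starts under a fixed seed. Model
order (1–3 components) is chosen by BIC unless forced; per-event loading
rates are collapsed to the bin or spot median, reflecting measurements
taken at one pulling speed. Weight-only refits
(`compare_mixture_vs_fixed_combination()`) ask whether a tetravalent
sample is explained by the union of the monovalent and trivalent
processes without refitting their kinetics.

$k_0$ recovered from a dynamic force spectrum is exponentially sensitive
to the line's intercept; the package documents recovery of
$x^\ddagger$ to a few percent while $k_0$ is reliable only to within a
factor of order unity.

## The trace generator

`simulate_trace()` integrates a constant-velocity retraction (defaults:
800 nm/s, 12,000 Hz, 350 nm, cantilever 0.15 N/m) against the serial WLC
tether. At each sample the cantilever/tether force balance is solved by
vectorised Newton iteration; the next fingerprint unfolding substep and
the terminal bond carry Bell hazards integrated on the sampling grid via
exponential clocks on the cumulative hazard, so non-constant loading from
WLC nonlinearity is handled exactly. Gaussian noise (default sd 3 pN,
representative of a small 0.15 N/m lever at this bandwidth) is added to
the force channel only, and the noise-free event log — times, forces,
instantaneous and flank-averaged loading rates — rides along as ground
truth.

Defaults that the literature does not pin down were chosen once, on
physical grounds, and are exposed as configuration:

* ddFLN4 fingerprint substeps of $\Delta L_c$ = 15 and 16 nm with
  $k_0 = 0.05\,\mathrm{s^{-1}}$, $x^\ddagger = 0.45$ nm, placing typical
  unfolding forces at 60–90 pN at the loading rates this protocol
  produces;
* subunit kinetics `default_subunit_params()` chosen so the most
  probable rupture forces at the self-consistent loading rates sit near
  100 pN (subunits A and C), 210 pN (B) and 440 pN (D);
* attachment bookkeeping: 2.5% of cycles form a full specific tether,
  10% show a short nonspecific adhesion, and 1 in 10,000 background
  cycles shows a spurious fingerprint-like pattern (matching the scale
  of two events in 20,000 control attempts).

`generate_variant_dataset()` mixes these ingredients per variant spot
(0SA/1SA/3SA/4SA accessibility rules) and labels every trace with its
ground-truth subunit and whether the fingerprint actually completed
before rupture — classifier precision/recall are scored against what the
generator *did*, not what it intended, so competing-risk traces where the
bond broke first do not poison the labels.

## Trace analysis choices

* **Zero points.** The force offset is the median of the terminal
  baseline window. Because an AFM deflection offset is arbitrary, "no
  baseline" cannot be read off the force level: a trace is excluded when
  its terminal window is not flat (range above `contact_threshold`),
  i.e. it is still in contact or still loaded at the end. The distance
  offset comes from the zero crossing of a line fitted to the initial
  contact slope when the trace starts in contact, else it is zero.
* **Denoising.** Length-preserving boxcar (default 11 samples ≈ 0.9 ms);
  window 1 is the identity.
* **Event detection.** A running-maximum drop trigger: an event fires
  when the smoothed force falls 25% below the running peak (peak above
  20 pN), then the boundary descends to the local minimum with a small
  hysteresis. This keeps cascaded unfolding steps — the second substep
  firing before the force recovers past the first peak, common for
  ddFLN4 — as separate events, where naive peak pairing merges them.
  Contour lengths flanking each event are kernel-density modes of the
  transformed series; the last event with no measurable contour length
  after it is the terminal detachment.
* **Fingerprint classification.** Ordered matching of the expected
  increments (defaults 15 and 16 nm, tolerance ±2 nm), all before the
  terminal detachment.
* **Rupture extraction.** The rupture force is read from a short (5
  sample) boxcar around the terminal peak — long windows smear the drop
  and bias the force low, raw samples carry the full noise upward. The
  loading rate is a least-squares line on the final rising flank above
  75% of the peak force. On a stiffening WLC flank this is a
  window-averaged quantity that sits a little below the pointwise rate at
  the peak; the generator therefore logs both, and the estimator is
  validated against the flank-averaged truth (median error well under
  10% at default noise). This mirrors field practice, where "the" loading
  rate is whatever the linear fit immediately before rupture measures.

## Trajectory generators and metrics

`generate_correlated_trajectory()` draws per-frame node displacements
from a zero-mean multivariate Gaussian whose correlation matrix equals a
prescribed positive-semidefinite target (same scalar correlation per
Cartesian axis) — the fixture with a known answer for the correlation
and network stages. `generate_smd_pull_trajectory()` is a deliberately
minimal overdamped-Langevin harmonic chain pulled through a spring
(defaults: 0.5 Å/ns, 1.0 kcal/(mol Å²) ≈ 0.69 N/m): the recorded force
is spring extension times stiffness, a lid atom's rest offset jumps by a
programmed 8 Å when the force first exceeds `loop_open_force`, and the
pulled bond detaches above `detach_force`. Two consequences of the toy
physics are worth knowing: the chain carries a small entropic tension
(tens of pN) even unloaded, and finite mobility adds a drag component to
the measured force — both are features of the recorded ground truth, not
errors, since all events are defined on the recorded force itself.

`smd_rupture()` takes the global maximum of the force series (first
occurrence on ties — the earliest rupture-consistent event) and fits the
loading rate over the preceding 10 ns, the same span as the lid-metric
windows. `pair_distance_series()`/`angle_series()` use single-atom
selections by 1-based PDB residue number, atom name and chain; ambiguous
selections error out listing all matches, to keep off-by-one residue
mistakes loud. `window_histograms()` compares the first 10 ns (unloaded)
with the 10 ns before rupture (loaded) on shared bin edges.

## Dynamical network analysis

Nodes default to one α-carbon per residue, plus any configured ligand
atoms (for biotin, a three-atom choice is conventional but not canonical;
it is configuration here). Edges require residues to have heavy atoms
within 4.5 Å in at least 75% of analysed frames; sequence-adjacent pairs
are kept by default with a flag to drop them. Edge weights are
$w_{ij} = -\log|C_{ij}|$ (natural log, so $|C| = 0.5$ gives the
canonical tolerance 0.69), with $C$ the 3-D dot-product normalised
displacement correlation; a strict per-axis Pearson variant is available
behind a flag. Weights are nonnegative by construction, so Floyd–Warshall
is valid; suboptimal paths are enumerated by depth-first search pruned
with Floyd–Warshall distances-to-sink, capped at a configurable 10,000
paths with an explicit truncation warning (worst-case growth is
exponential). The enumeration is tested for exact set equality against
brute-force simple-path enumeration on hundreds of random small graphs.
Windowed analysis tiles the trajectory into 10-ns windows resampled every
400 ps (25 frames per window) and pools per-edge usage counts.

## What the synthetic tests do and do not show

The generators reproduce the *statistical structure* the analyses assume:
WLC-shaped loading, Bell–Evans rupture, two-step fingerprints, programmed
correlations and a load-triggered lid opening. They do not reproduce
instrument drift, baseline curvature, multiple parallel tethers,
anharmonic protein elasticity, or the full contact-map complexity of a
real tetramer. Green tests therefore certify that the chain inverts its
own assumptions correctly and recovers known parameters at realistic
noise; they do not certify the assumptions themselves for any particular
experiment.

Problem sizes used in the shipped tests were chosen to give tight Monte
Carlo bounds at desk scale: 2,000-draw KS checks, 3,000-force mixture
recovery, 10 × 200-event spectra, 500-trace classifier scoring, 10,000
frame correlation recovery, and 200-graph path-enumeration equivalence.

## Known limitations

* The EM mixture fitter assumes a common loading rate per fit; strongly
  heterogeneous rates within one spot would need the full heterogeneous
  likelihood.
* $k_0$ from spectra and mixtures is order-of-magnitude information.
* The toy pulling model is not a force field; only its recorded force
  series and programmed events are meaningful.
* The suboptimal-path cap truncates pathological near-degenerate
  ensembles; the flag reports when that happened.
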