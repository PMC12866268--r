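---
title: "Vascular morphometry with vasctort: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vascular morphometry with vasctort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasctort)
```

## What the package computes

`vasctort` quantifies the shape of landmark-delimited arterial segments and
relates that shape to binary treatment endpoints. A segment is represented
by its centerline: an ordered polyline in world millimetres with a maximal
inscribed sphere radius at every node. Three landmarks delimit the two
segments of interest — the common carotid bifurcation, the intracranial ICA
bifurcation, and the arterial end just proximal to the occlusion. The ICA
segment (first to second landmark) is summarized by its tortuosity index
alone; the MCA segment (second to third) by geodesic length, tortuosity
index, bending length, mean inscribed diameter and the mean diameter over
its distal 10 mm.

For a centerline $c(t)$ with proximal endpoint $A$ and distal endpoint $B$:

$$\mathrm{TI} = \frac{L}{\lVert B - A\rVert} - 1, \qquad
  \mathrm{BL} = \max_t \operatorname{dist}\bigl(c(t),\ \ell_{AB}\bigr),$$

where $L$ is the total geodesic (along-path) length and $\ell_{AB}$ the
*infinite* line through $A$ and $B$. TI is dimensionless, zero for a
straight segment, and invariant under rigid motion and uniform scaling; BL
carries units of length and scales linearly. We measure BL against the
infinite chord axis rather than the clipped segment: for J-shaped vessels
whose apex projects beyond an endpoint, clipping would change the value,
and the axis definition is the one that matches "orthogonal distance to the
axis through the extremal points". Lengths and BL are reported in cm at the
feature-record level, diameters in mm, matching the conventions of clinical
summary tables.

The "diameter at occlusion" averages the inscribed diameter over the nodes
whose *cumulative geodesic length* lies within 10 mm of the distal
endpoint — geodesic, not Euclidean, so the window follows the vessel around
bends. Segments shorter than 10 mm fall back to the whole-segment mean with
a warning; this occurs for very proximal occlusions and is flagged rather
than treated as an error.

## Centerline extraction

Segmentation is plain intensity thresholding followed by 26-connected
component selection (components reachable from a landmark within a 3 mm
snap radius; the largest component when no landmarks are given). This is a
deliberate simplification: it is exact on noiseless phantoms, adequate on
noisy ones, and stands where a learned vessel segmenter would sit in a
clinical system.

The distance map is an exact anisotropy-aware Euclidean distance transform
(separable lower-envelope algorithm, implemented in C++ and verified
against a brute-force oracle in the test suite). Its value at a point is
the maximal inscribed sphere radius up to voxelization error; radii at
centerline nodes are trilinearly interpolated from it.

The centerline itself is the minimal-cost path over the foreground voxel
graph with edge cost $\text{step length} / (d(v) + \varepsilon)$, where
$d(v)$ is the distance-map value at the target voxel and
$\varepsilon = 0.1$ mm regularizes the weight near the wall. The division
pulls the optimum onto the lumen's medial ridge; the algorithm is Dijkstra
with deterministic lexicographic tie-breaking, so extraction is exactly
reproducible. The raw voxel path is then anchored, smoothed and resampled:

- **Endpoint anchoring.** The graph path terminates at the voxel centers
  nearest the landmarks; the landmarks themselves are the true endpoints
  $A$ and $B$, so they are prepended/appended exactly. Without this, both
  the chord and the length lose up to half a voxel per end, which at 0.4 mm
  spacing is the dominant error term in TI.
- **Smoothing and resampling.** A moving average over a 5-node window
  (endpoints fixed) suppresses lattice staircase jitter, then the polyline
  is resampled at a uniform 0.25 mm arc-length step. Uniform resampling
  matters for the diameter features: it makes the per-node mean an
  arc-length average, so node density cannot bias it.

With these defaults the full pipeline at 0.4 mm spacing recovers a
semicircular phantom (radius 10 mm) to within 0.5% in length, 1.5% in TI
and 5% in BL, and diameters to within one voxel; errors shrink
monotonically at 0.2 mm. These figures are computed, not quoted — the
acceptance tests re-derive them on every run.

## Phantoms

A phantom is a parametric center curve (straight, circular arc, helix,
sinusoid, or a composite joined end-to-end by translation) swept by a
radius profile (constant, linear taper, piecewise linear in normalized arc
length). Rasterization uses a voxel-center point-in-tube test against a
curve sampling four times finer than the voxel size, with two deliberate
choices:

- **Flat ends.** The ball-union test alone would grow hemispherical caps
  past the endpoints; these are clipped at the planes normal to the end
  tangents, so a straight phantom is a true cylinder of volume
  $\pi r^2 L$ and volume-based oracles are exact.
- **Generic grid alignment.** The grid origin is offset from the tube
  bounding box by an irrational sub-voxel fraction (0.381966…, the golden
  ratio conjugate). Axis-aligned phantoms would otherwise sit in
  measure-zero alignment with voxel centers, making partial-volume error a
  lattice artifact instead of the generic $O(\text{spacing})$ behavior that
  refinement studies rely on.

No anti-aliasing is applied: the companion ground-truth mask is then an
exact, orderable oracle for the segmentation stage. Intensity is a constant
vessel value over constant background (default contrast 200) plus optional
Gaussian noise. The phantoms emulate the geometry of contrast-filled
arteries, not their radiometry: no contrast dynamics, beam hardening, bone,
bifurcations or neighboring vessels. Accuracy claims validated on phantoms
therefore transfer to clinical volumes only insofar as segmentation
succeeds there.

## The cohort simulator

The simulator exists to exercise the statistical engine under a known
truth, at the scale and shape of a real MDVO thrombectomy cohort
(n = 213 by default).

**Marginals.** Each feature gets a two- or three-parameter law calibrated
to a published median and IQR: log-normal for the right-skewed lengths
(MCA length 3.82 [3.02–4.78] cm, BL 0.79 [0.49–1.31] cm), scaled Beta for
the bounded tortuosity indices (MCA-TI 0.26 [0.17–0.38] on [0, 1.5];
ICA-TI 0.34 [0.30–0.38] on [0, 1]), and zero-truncated normal for the
diameters (2.99 [2.80–3.22] and 2.61 [2.24–2.90] mm). The Beta shapes are
least-squares fits to the three quantiles; only location/scale/shape at
quartile level is matched, not higher moments.

**Dependence.** A Gaussian copula imposes the published Pearson
correlations (BL–length 0.914, BL–TI 0.874, BL–diameters −0.468/−0.397,
diameter pair 0.853, ICA-TI essentially uncorrelated with everything).
Because Pearson correlation is attenuated through non-Gaussian margins, the
latent correlation for each pair is solved numerically — tensor
Gauss–Hermite quadrature (32 nodes) inside a root-finder — so the
*observed* feature correlations hit the targets; an unattainable target
raises an error rather than being silently truncated. Four pairs are not
published (length–TI and the length/TI–diameter pairs); their stand-in
values (0.85, −0.36, −0.42, −0.36, −0.43) were chosen once, jointly with
the published values, so the latent matrix is positive semi-definite
without repair — the published triangle BL–length–TI is so tight that a
careless stand-in forces a nearest-PSD projection that visibly degrades the
published pairs. A nearest-PSD repair still guards user-supplied targets,
erroring if it must move any entry by more than 0.05.

**Outcomes.** Each endpoint is Bernoulli with a logistic linear predictor
over features and covariates. Coefficients are log odds per unit (per raw
TI unit, i.e. ten times the published per-0.1 log-aOR); the published
adjusted odds ratios serve as true effects where available (e.g. BL 0.48,
MCA-TI 0.77, ICA-TI 0.59 against complete recanalization; diameter at
occlusion 4.04 for sICH; BL 2.47 for SAH). For the unpublished
feature–endpoint pairs on the primary endpoint we chose modest effects
(length 0.85/cm, mean diameter 1.25/mm, distal diameter 1.20/mm) with one
self-consistency requirement: with the imposed correlation structure, the
sign of each feature's *collapsed* per-feature-regression coefficient must
agree with its coefficient in the joint generating model. Without that
property, "direction recovery" by per-feature adjusted regressions — the
analysis the engine actually runs — would be testing an ill-posed claim.
Intercepts are solved by root-finding on a fixed 20,000-draw calibration
sample so marginal event rates match the published prevalences (59.7%,
43.7%, 81.2%, 28.6%, 6.7%, 17.8%, 4.7%). The composite severe-HT endpoint
is derived as `sah | ph2`, never drawn independently, which reproduces its
published 22.1% prevalence through the dependence induced by shared
features. Covariates are independent of features: onset-to-puncture
log-normal (median 240 [160–360] min — a typical extended-window
distribution, chosen once as no summary is published), IVT Bernoulli(0.291),
age truncated normal 81 [72–87], baseline mRS categorical with median 1 and
IQR 0–2.

**Seeding.** One master integer seed; every stochastic stage (rasterization
noise, cohort draws, each acceptance replicate) derives its own substream
seed by hashing a stage name, so stages can be re-run in isolation and
whole runs are byte-reproducible.

## The statistical engine

The unadjusted comparison runs Shapiro–Wilk at $\alpha = 0.05$ in each
group and uses the equal-variance Student's t only when neither group
rejects, otherwise the two-sided Mann–Whitney U; medians and IQRs are
reported either way. Welch's t is available behind a flag but off by
default, matching the equal-variance convention. Two identical constant
groups return p = 1 with a flag instead of erroring. The gate's type-I
error stays at the nominal 5% under both Gaussian and log-normal nulls —
the chooser is data-dependent, and the test suite verifies it does not
inflate error.

Adjusted models are per-feature logistic regressions — one anatomical
feature plus the adjusters, not a multivariable model over all six
features — fit by maximum likelihood on complete cases (n used is always
reported). Adjusters are onset-to-puncture time and IVT; age and baseline
mRS are added for the functional outcome only. TI features are multiplied
by 10 before fitting so the aOR reads per 0.1 TI; the scaling is recorded
in the result and is idempotent in the sense that pre-scaling the column by
hand gives the identical fit. Confidence intervals are Wald
($e^{\hat\beta \pm 1.96\,\mathrm{se}}$) by default — coverage is verified
at 95% ± 2% over 1,000 simulated cohorts of n = 2,000 in the acceptance
suite — with profile-likelihood intervals behind a flag.
Quasi-separation is detected by runaway coefficients or standard errors and
returned as a non-converged result rather than an exception. No
multiple-testing correction is applied anywhere: results are raw p-values
at $\alpha = 0.05$, and the 48-cell analysis grid should be read
accordingly.

## Numerical choices and degenerate inputs

- Chords below $10^{-6}$ mm make TI and BL undefined (closed or recurrent
  path) and raise errors; analytic feature evaluation uses $10^5$ dense
  samples, converging well below the $10^{-4}$ relative tolerance asserted
  in tests.
- Landmark snapping: nearest foreground voxel within 3 mm, else the nearest
  distance-map local maximum within 5 mm (hill-climbing), else an error
  naming the landmark — mirroring coarse manual placement.
- A resampling step longer than the centerline degrades to the two
  endpoints with a warning. Tubes thinner than one voxel everywhere refuse
  to rasterize.
- Per-case failures inside `run_end_to_end()` are logged and skipped, and
  the run manifest lists every output file with an MD5 checksum, so partial
  cohorts remain auditable.

Problem sizes in the test and acceptance suites (0.4 mm phantoms of ~3,000
foreground voxels; 1,000 replicate cohorts of n = 2,000 for coverage; 1,000
replicates for the chooser's type-I error; n = 10,000 for copula
calibration checks; n = 5,000 for direction recovery) were chosen as the
smallest sizes at which the Monte-Carlo tolerances quoted above are
binomially meaningful.

## Limitations

- The centerline algorithm is validated on single-channel tubes; clinical
  vasculature adds bifurcations, touching vessels and bone, which the
  threshold segmenter does not handle.
- Inscribed-sphere radii inherit a voxel-scale bias from the distance
  transform (foreground-to-background-center distances); diameters are
  accurate to about one voxel, not better, and no subvoxel wall model is
  attempted.
- The simulator matches quartile-level marginals, pairwise Pearson
  correlations and marginal event rates — not higher moments, tail
  behavior, or feature–covariate dependence. Conclusions about the
  statistical engine's operating characteristics transfer to real cohorts
  only to the extent those aspects are irrelevant to them.
- Whether published tortuosity values were computed on smoothed or raw
  centerlines is unknown; the phantom-scale tolerance bands absorb the
  difference.
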