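---
title: "Distance mapping of hallux valgus: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance mapping of hallux valgus: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halluxmap)
```

This vignette is the package's account of its own methods: what is computed,
under which conventions, which choices were genuinely open and how they were
settled, and what the synthetic validation does and does not establish.

## The measurement model

A foot is represented by 24 anatomical landmarks on a standing AP radiograph,
in pixel coordinates. The schema (`hv_schema()`) allocates 9 points to the
first metatarsal, 2 to each sesamoid, 4 to the proximal phalanx, 2 to the
distal phalanx and 5 to the second metatarsal. Published descriptions of
similar landmark sets are not perfectly self-consistent about the split
across bones; this schema follows the 9/2+2/4/2/5 allocation because the
measurement model requires, at minimum, named head and base midpoints for
every long axis and the two endpoints of the first metatarsal's distal
articular surface. Only coordinate *differences* enter any computation, so
the image convention (origin top-left, y down) never affects a result.

### Consensus and dispersion

Several annotators mark the same foot; `merge_annotations()` takes the
arithmetic mean per landmark as the consensus and reports, per landmark, the
**radial dispersion**: the square root of the mean squared Euclidean
deviation of annotator points about the consensus. The radial form is
symmetric in x and y and rotation-invariant. It is the *uncorrected*
(divide-by-k) form, which keeps the two-annotator case intuitive (two points
2 px apart have dispersion exactly 1 px). `cohort_dispersion()` averages it
over landmarks and feet into the single reproducibility figure customarily
quoted for an annotation campaign.

Two consequences of this definition are worth stating precisely. First,
"dispersion" quantifies spread about the *sample* consensus, so with k
annotators it underestimates the generating noise by the usual
finite-sample factor. Second, the simulator's jitter parameter `sigma` is
the **per-coordinate** Gaussian SD (the conventional way digitizing error is
parameterized), not the radial SD. For k = 3 annotators the per-landmark
dispersion is `sigma * sqrt(chi2_4 / 3)` in distribution, with expectation
≈ 1.085 · `sigma` — the upward pull of summing squared deviations over two
coordinates slightly exceeding the downward consensus-centering bias — so a
2.1 px jitter campaign reports ≈ 2.28 px. The recovery test asserts agreement
within 15%, which is the honest statement of how tightly this statistic
identifies the noise level at k = 3.

### Angles

All four clinical angles are computed with one primitive,
`angle_between()`: the unsigned acute angle between two lines,
`acos(|u·v| / (|u||v|))`, in [0, 90]°. The choice of origin/tip for an axis
is therefore immaterial, and no angle distinguishes medial from lateral
deviation (a signed convention is deliberately out of scope). The landmark
assignments live in one table, `hv_axes()`:

* **HVA** — MT1 long axis (head center → base midpoint) vs proximal phalanx
  long axis (head midpoint → base midpoint);
* **IMA** — MT1 vs MT2 long axes;
* **HIA** — proximal vs distal phalanx long axes (tip → base midpoint);
* **DMAA** — the complement `|90° − θ|` of the angle θ between the MT1 long
  axis and the articular line through the medial and lateral head-surface
  points, so a perpendicular articular surface reads 0°.

Clinical sources rarely state their exact axis endpoints; these follow the
standard long-axis definitions, and because they are configuration rather
than code, an alternative convention is a one-row change. A collapsed axis
(coincident endpoints) is a hard error naming the angle, not an `NA`.

### Distances and normalization

`pairwise_distances()` emits all 276 unordered pair distances in a fixed
lexicographic pair order, which also fixes the cohort-table columns and the
heatmap rows. `normalize_distances()` divides by the proximal phalanx
length — chosen as the normalizer for its consistent visibility and
stability across deformity grades — making features dimensionless and
similarity-invariant. One degeneracy is inherent: the proximal phalanx pair
itself normalizes to exactly 1 in every foot, so its correlation with
anything is undefined. The screen reports those records as `r = NA`, never
flagged, rather than silently dropping them or erroring out.

## Severity classification

The printed clinical bands (HVA mild 15–20°, moderate 21–40°, severe >40°,
and analogous rows for IMA 9–11/12–17/>17, DMAA 8–10/11–15/>15, HIA
<10/10–13/>13) are integer-bounded and leave real values like 20.3°
unassigned, as well as everything below the mild range. `hv_severity_bands()`
closes the gaps deterministically: adjacent integer bands meet at their
midpoint (20.5° for HVA mild/moderate), a *shared* printed boundary stays
with the lower band (exactly 40° is moderate; severe is strictly >40°), and
a sub-mild **normal** category absorbs values below the mild lower bound
(HIA needs none, its mild band reaching 0). Every band table — default or
user-supplied — is validated for contiguity, so classification is total on
[0, ∞). Note one documented oddity this resolves: cohorts can report a
"mild DMAA" group mean (e.g. 5.3°) *below* the printed mild band; under
these bands such feet are "normal".

## Correlation screening

`screen_correlations()` computes all 276 × 4 = 1104 Pearson correlations
(via `stats::cor` on the feature and angle matrices) and two-sided p-values
from the t-transform with n − 2 degrees of freedom — the same test
`cor.test()` performs, done in matrix form. A record is flagged when
p < α (default 0.05) **and** |r| clears the per-angle threshold (0.4 for
HVA/IMA, 0.3 for DMAA/HIA, where correlations are known to run weaker).
Two deliberate defaults mirror common exploratory practice and can both be
overridden:

* **No multiplicity correction.** 1104 tests at raw p < 0.05 expect ~55
  null false positives *on p alone*; the |r| threshold is what actually
  controls flagging (at n = 300, P(|r| ≥ 0.4) under the null is ≈ 10⁻¹³).
  `fdr = TRUE` switches flagging to Benjamini–Hochberg adjusted p-values.
* **t-transform p-values.** `method = "permutation"` provides a Monte-Carlo
  permutation p instead, preferable at small n or for heavy-tailed features.

The result is a tidy record table (class `hv_screen`) with `tidy()`,
`glance()` and `autoplot()` methods; `correlation_matrix()` reshapes it into
the 276 × 4 matrix behind the heatmap.

## The synthetic cohort generator

No public landmark dataset accompanies this methodology, so validation rests
on a parametric simulator designed for *identifiability*, not photorealism.
A foot is a chain of hinge rotations: MT2 along a reference axis; MT1
rotated by `ima` at the base; the proximal phalanx rotated by `hva` relative
to MT1 at the metatarsal head; the distal phalanx by `hia`; the articular
line tilted by `dmaa` from perpendicular. Each generative parameter is
measured by exactly one clinical angle, so
`compute_angles(simulate_foot(p))` returns `p`'s angles to floating-point
precision — the round-trip is tested over a 180-point grid at 10⁻⁶ degrees.
Remaining landmarks (shaft curves, base corners, sesamoids) are placed at
plausible offsets; the sesamoid complex drifts laterally with `hva` in
cohort mode, reflecting its clinical behavior.

Cohorts (`simulate_cohort()`) draw each angle independently from a
three-component mixture over the severity bands, with weights defaulting to
a published surgical cohort's distribution (HVA 26.6/61.5/11.3%
mild/moderate/severe; IMA 49.9/37.7/12.0; DMAA 51.3/20.3/28.4; HIA
70.4/26.0/3.0) and uniform sampling within the band (severe bands, open
above, are capped at 55/25/25/20° respectively — values chosen once as the
plausible upper range of surgical candidates). Per-foot realism knobs:
random global pose (±10° rotation, ±25 px translation, scale 0.9–1.1 —
all invisible to angles and normalized distances, and tested to be so),
~5% bone-length variation, and per-annotator Gaussian jitter (default
σ = 2.1 px, 3 annotators, matching a realistic inter-observer campaign).
Everything is a deterministic function of `seed`.

### Calibration mode and injected couplings

In a *coupled* (default) cohort, distances genuinely depend on the angles
through geometry — dozens of features correlate strongly with HVA, which is
the method's point but makes the cohort useless for false-positive
accounting. For calibration, `decouple = TRUE` row-permutes the distance
block against the angle columns after measurement: both marginals are
preserved, every distance–angle pair becomes independent, and the expected
flag count at |r| ≥ 0.4, n ≥ 300 is ~0. On this null background,
`couplings` injects known signal: a selected distance column is regenerated
as ρ·z(angle) + sqrt(1 − ρ²)·ε, rescaled to the column's observed mean and
SD (and floored at 0, a truncation that in practice never binds at the
default spreads). Injection is deliberately at the feature level — a
geometric mechanism would perturb many distances at once, making "exactly k
pairs carry signal" untestable. The screening recovery experiment (5
couplings at ρ = 0.6, n = 300, full annotator noise) must flag exactly the
injected pairs with at most one false flag; the null-calibration experiment
(50 decoupled cohorts at n = 335) must put the p < 0.05 fraction at
0.05 ± 0.02.

What passing these tests shows: the pipeline measures what the generator
encodes, the test is calibrated under independence, and signal of the
magnitude the method claims to detect is detected. What they do not show:
performance on real radiographs, where landmark error is not isotropic
Gaussian, bones are not rigid templates, severity mixtures are not uniform
within bands, and distances are mutually dependent in ways a permutation
null only partially represents.

## Numerical and degenerate-input policy

* Angles clamp the cosine into [−1, 1] before `acos` (guarding 1 + 1e−16
  cases); recovery tolerances are 10⁻⁶° for the generator round-trip and
  10⁻⁹ relative for similarity invariance.
* Coincident landmarks yield zero distances silently; errors are reserved
  for collapsed *axes* and a collapsed normalizer, which invalidate the
  measurement model.
* Pearson correlation requires n ≥ 3 and nonzero variance; within the
  screen, a constant *feature* demotes to `NA` records (see above) while a
  constant *angle* column is a hard error.
* |r| = 1 maps to p = 0 with a warning rather than an error, since exact
  collinearity legitimately occurs in constructed tests.
* Severity boundary values resolve by band closure, never by floating-point
  accident; bands are validated before every classification.

## Problem sizes

The shipped experiments run at desk scale, chosen to make Monte-Carlo
conclusions stable while keeping the full suite fast: 180 grid points for
round-trip recovery, 100 feet × 3 annotators for dispersion recovery,
n = 300 with 5 injected couplings for screening recovery, and 50 × n = 335
decoupled cohorts for null calibration. At these sizes the binding
tolerances (15% on dispersion, ±0.02 on the null fraction, ≤1 false flag)
hold with wide margin under any seed.

## Known limitations

* Unsigned angles: medial vs lateral deviation is not distinguished.
* 2D only: no pronation/rotation measures, no weightbearing-CT support.
* PNG backgrounds only for overlays (landmark tables, not images, are the
  package's primary input; DICOM pixel data is out of scope).
* The severity-band closure and the severe-band caps are conventions;
  both are overridable (`hv_severity_bands()` format, `cohort_params()`).
* Correlation screening is exploratory; flagged records are candidates for
  anatomical interpretation, not confirmatory findings.
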