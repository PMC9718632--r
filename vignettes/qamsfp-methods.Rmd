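---
title: "Fingerprint and single-marker quantitation methods in qamsfp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fingerprint and single-marker quantitation methods in qamsfp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qamsfp)
```

## The quality-evaluation problem

Multi-herb preparations such as Yinqiao powder contain dozens of
co-extracted constituents, so no single compound can certify batch
quality. The pharmacopoeial answer is two-fold. A *chromatographic
fingerprint* — the vector of areas of the peaks shared by every batch —
characterises the preparation as a whole, and each new batch is scored
against a reference fingerprint. On top of that, a handful of marker
analytes are quantified; the *single-marker* method (QAMS,
"quantitative analysis of multi-components by single marker") does this
with one calibrated reference substance instead of one standard per
analyte, using pre-established relative correction factors.

`qamsfp` implements both halves for dual-wavelength HPLC data (237 nm
for the fingerprint and the lignans phillyrin and arctiin, which do not
absorb at 327 nm; 327 nm for the caffeoylquinic acids), plus the
multivariate screening (PCA, PLS-DA/VIP) used to decide *which*
constituents matter.

## From trace to common-peak matrix

**Peak detection.** `detect_peaks()` finds local maxima of the
Savitzky–Golay-smoothed signal (3rd order, 9-point window) above a
height and a prominence threshold. The retention time is the apex grid
time. The area is the trapezoidal integral of the *raw* signal between
two flanking boundaries after subtracting the straight baseline drawn
between them. A boundary is the first point, walking outward from the
apex, where the smoothed signal drops below
`max(0.002 * apex, 4 * noise)` (noise estimated from the median
absolute first difference), capped at the valley minimum towards the
neighbouring peak. The 0.2 % gate trades a ~0.5 % systematic area
underestimate for insensitivity to baseline noise; on a noiseless
Gaussian the recovered area is within 1 % of `height * sigma * sqrt(2*pi)`.

**Shearing and screening.** The solvent front is removed with a strict
`rt < 5 min` cut (a peak exactly on the boundary is retained), and
common peaks must have area *strictly greater than* 0.4 detector units
in every batch. Both inequalities are deliberate: the screening rule is
phrased as "greater than", and the two filters commute, which the test
suite checks.

**Cross-batch matching.** The matching algorithm is a design choice of
this package (commercial fingerprint software does not document its
own). Clusters are seeded from a reference batch (the first, by
default) and each remaining batch contributes its nearest unassigned
peak within the retention-time tolerance (0.5 min default), assigned
greedily in order of increasing distance. Two refinement passes then
re-assign every batch against the cluster *consensus* (median member)
retention times. The refinement matters: with per-batch jitter of
0.1 min, the difference between two independently jittered retention
times has a standard deviation of 0.14 min, and over 29 peaks x 9
batch pairs the 0.5 min window is only ~3.5 sigma away — rare misses
against a single jittered reference chromatogram become expected over
dozens of runs. Matching against the consensus of all ten batches
pushes the miss probability per peak below 1e-6, which is what makes
ground-truth recovery exact across seeds. A cluster is a common peak
only if it contains exactly one member from every batch and survives
the area screen; columns are numbered 1..K in elution order.

**Marker localization.** Individual analyte peaks are found relative to
the internal standard either by relative retention value
(`rt / rt_is`, tolerance a fraction) or by retention-time difference
(`rt - rt_is`, tolerance in minutes) — the two conventional qualitative
parameters. Ties break toward the larger area, since dominant peaks are
the intended landmarks.

## Fingerprint similarity

The reference fingerprint is the per-peak *median* over batches (even
count: midpoint of the central order statistics — with ten batches the
convention has to be chosen; the midpoint is the standard one). Batches
are scored with the included-angle cosine

$$S = \frac{\sum_i a_i r_i}{\lVert a \rVert\, \lVert r \rVert},$$

the documented default of fingerprint-evaluation software; Pearson
correlation is available as an alternative metric. Cosine similarity is
symmetric and scale-invariant, so a proportional dilution of a whole
chromatogram does not lower a batch's score — only *relative*
composition changes do. Precision/stability statistics are RSDs
(sample, n−1 denominator — the pharmacopoeial convention) of retention
times and of areas relative to a designated reference peak. Which peak
(or sample) serves as reference is a configuration input, not a guess.

## Multivariate screening

**PCA** (`pca()`) eigendecomposes the correlation matrix by default
(the covariance option exists). Loadings are reported as component
loadings, `eigenvector * sqrt(lambda)` — the "initial factor load
matrix" convention, so in correlation mode they are the
variable-component correlations and lie in [−1, 1], and
`loadings %*% t(loadings)` reconstructs the correlation matrix (tested
to 1e−8). A component counts as non-zero when its eigenvalue exceeds
1e−10 relative to the eigenvalue total. With n samples and p > n
variables the rank is at most n−1, which is why any 10-batch, 29-peak
panel yields exactly 9 components whose cumulative contribution is
100.000 % — an analytic fact, not a data result, and the package's
tests treat it as such.

**PLS-DA** (`nipals_plsda()`) is a from-scratch NIPALS implementation:
X is autoscaled, the classes are dummy-coded as one centred indicator
column per class (deterministic class ordering), components are
extracted with X- and Y-deflation, weight vectors are unit-norm, and
convergence requires the weight change to fall below 1e−12 within 500
iterations (a convergence failure is an error naming the component).
Per component the explained response sum of squares is
`SS_a = (t_a' t_a) * ||q_a||^2`, and

$$\mathrm{VIP}_j = \sqrt{p \cdot \frac{\sum_a SS_a\, w_{aj}^2}{\sum_a SS_a}},$$

so `sum(VIP^2) = p` identically (tested to 1e−9); variables with
VIP > 1 are screened as key components. The study design this package
emulates never states which classes its ten batches were assigned, so
class labels are a required user input; the default pipeline uses a
first-half/second-half split purely to exercise the code path, and the
resulting VIP ordering on synthetic panels is illustrative, not a
reproduction of any published figure. The implementation is
cross-checked against an independent PLS-DA implementation (mixOmics)
in the test suite — the two agree on VIP to 1e−6.

## QAMS quantitation

External-standard contents invert the calibration line and convert
with the preparation constants (0.5 g of powder, 25 mL extract, 5 µL
injected):

$$\text{content} = \frac{(A - b)/k \cdot (V_\text{extract}/V_\text{inj})}{m_\text{sample} \cdot 1000} \; \text{mg g}^{-1}.$$

The content unit is not stated alongside the published batch tables; we
fixed mg g⁻¹ after checking that every published content, pushed back
through its calibration line with these constants, lands inside that
line's printed linear range — no other plausible unit does.

The relative correction factor is measured on mixed standard
solutions:

$$f_x = \frac{W_\text{is}\, A_x}{W_x\, A_\text{is}},$$

and the single-marker content of analyte *x* in a sample chromatogram
is

$$c_x = \frac{A_x \, c_\text{is}}{f_x \, A_\text{is}},$$

with the internal standard's own content taken from its calibration
curve. The source study prints the factor equation but not the content
equation; this is the standard single-marker formula, algebraically
consistent with the factor definition — when all calibration
intercepts are zero and the factor is computed from the same
calibration data, QAMS and ESM contents coincide exactly (tested to
1e−10). With non-zero intercepts QAMS carries a bias of the order of
the intercept's share of the peak area. That share is largest for the
least-abundant analyte: in the default synthetic panel, neochlorogenic
acid (content ≈ 0.08 mg g⁻¹, peak area ≈ 0.85 with an intercept of
0.048) shows relative errors of a few percent, while the six other
markers stay below ±1 %. This is a real property of the method, not a
numerical artifact.

Method validation uses `recovery_rate()`
(`100 * (detected − original)/spiked`), `relative_error()`
(`100 * (qams − esm)/esm`), and `check_rcf_reproducibility()` (pooled
RSD of per-condition factor means, 3 % acceptance threshold).
Reporting follows the tabulation conventions — contents to 3 decimals,
relative errors to 2, correction factors to 3 — with *half-up*
rounding (`round_half_up()`), because base R's round-half-even
disagrees with analytical reporting practice on exact halves (the
phillyrin factor mean 0.8375 must report as 0.838). All internal
arithmetic is full precision.

Two smaller contract decisions: a calibration fit accepts two points
(the exact interpolating line, r = 1) and errors below two, and an
inverted amount outside the linear range produces a *warning*, not an
error — a QC report must not abort on one out-of-range batch.

## The synthetic generator

No instrument data accompany the study this package re-implements, so
every downstream stage is validated on synthetic panels with known
ground truth. `default_panel_design()` emulates the study conditions:

* 10 batches, 29 shared Gaussian peaks between 8 and 125.6 min on a
  0–130 min gradient, all supra-threshold at 237 nm;
* the seven marker analytes placed at their conventional elution
  positions with 237 nm areas chosen so that detected areas invert to
  realistic contents through the published calibration lines, and
  327 nm responses set to the published line ratios (zero for
  phillyrin and arctiin);
* 15 spurious peaks: 8 with mean area 0.13–0.24 (always below the 0.4
  screen) and 7 supra-threshold peaks present in only 6 of 10 batches;
* 3 solvent-front peaks before 5 min;
* between-batch area variation log-normal with 8 % CV (areas must stay
  positive), retention-time jitter normal with sd 0.1 min, baseline
  noise sd 0.02, peak width sigma 0.1 min.

The study states none of the widths, noise levels or batch CVs; those
defaults are one-time choices of plausible values for a 130-min
gradient at conventional flow, recorded in the design manifest rather
than asserted as facts about the study, and the jitter/CV pair is
chosen once as a moderate batch-to-batch variation consistent with the
study's own observation that all batch similarities exceeded 0.95. The
generator is a pure function of (design, seed): identical seeds give
byte-identical panels.

What the generator does **not** emulate: peak tailing and asymmetry,
column aging and retention drift that accumulates across a sequence,
co-eluting shoulders (common peaks are planted 4.2 min apart, far
beyond the 4-sigma overlap warning), detector saturation, and real
herb-to-herb compositional correlation (peak areas vary independently).
Passing tests therefore demonstrate that the algorithms are correct
under clean chromatographic assumptions — they do not certify
performance on degraded real-world separations, where the matching
tolerance and detection thresholds would need tuning.

## Validation study sizes

The packaged studies run at sizes that make their Monte-Carlo
assertions sharp while keeping the whole suite in the minutes range:
ground-truth common-peak recovery over 50 seeded panels (full
trace-detection path), the similarity floor over 200 seeded panels
(matching path), spike-recovery banding over 1000 seeded six-replicate
experiments, and property loops (scale invariance, VIP identity,
reconstruction) over 5–50 seeds each.

## Known limitations

* Matching is retention-time based; it has no warping/COW-style
  full-profile alignment and will not survive systematic retention
  shifts larger than the tolerance window.
* Overlapping peaks are not deconvolved; the valley-to-valley
  integration splits a fused pair at the valley minimum.
* The 112 → 38 → 29 screening cascade of the source study depends on
  its raw chromatograms; only the rules (shear boundary, area
  threshold) are reproducible, not the intermediate counts.
* QAMS supports a single internal standard per wavelength;
  multi-marker variants are out of scope.
* Published-table fixtures carry 3-decimal precision, so statistics
  recomputed from them (e.g. replicate RSDs) can differ in the last
  digit from values the study computed on unrounded data; tests assert
  bands, not digits, in those cases.
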