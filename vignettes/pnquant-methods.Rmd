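---
title: "Quantitative pronuclear morphometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative pronuclear morphometry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pnquant)
library(dplyr)
```

## The problem

After intracytoplasmic sperm injection (ICSI), a normally fertilised human
zygote forms two pronuclei (PNs) — one carrying the maternal and one the
paternal chromosomes — that are visible in time-lapse incubator imagery from
roughly 6–8 h post-ICSI until their breakdown around 20–23 h. Their areas
grow steadily as the PNs migrate from the zygote periphery to the centre.
Qualitative pronuclear scoring systems have been inconsistent predictors of
embryo potential; `pnquant` implements a *quantitative* alternative: fit the
area trajectory of each pronucleus with a two-parameter exponential model,
reduce each embryo to its fitted coefficients, and relate the within-patient
ranking of the female coefficient to chromosomal outcomes from
preimplantation genetic testing (PGT).

The pipeline has five computational stages, each exposed as ordinary
functions over data frames:

1. **Focal selection** (`laplacian_sharpness()`, `select_clearest_plane()`)
   picks the sharpest plane of each Z-stack by variance of the Laplacian.
2. **Detection** (`detect_pronuclei()` or an ingested detection table)
   yields per-frame PN centroids and areas.
3. **Tracking** (`filter_two_pn_frames()`, `assign_sex()`,
   `enforce_label_stability()`) produces one female and one male area
   trajectory per embryo.
4. **Growth fitting** (`fit_exponential()`, `coefficient_variants()`)
   extracts the coefficients under four fitting windows.
5. **Rank statistics** (`rank_within_patient()`, `odds_ratio_woolf()`,
   `pearson_chi_square()`, `spearman_rank_corr()`,
   `cochran_heterogeneity()`) relate rankings to PGT outcomes.

A seeded simulator (`sim_config()`, `simulate_trajectories()`,
`simulate_detections()`, `simulate_outcomes()`, `render_zstack()`) generates
every input the pipeline consumes, with ground truth, so the whole chain can
be benchmarked end to end.

## The growth model

PN area is modelled as

$$f(t) = \beta_1 \, \beta_2^{\,t},$$

with $t$ in hours post-ICSI. $\beta_2$ is the hourly growth factor;
$\beta_1$ is the *fictitious area at the time of ICSI* ($f(0) = \beta_1$) —
fictitious because no pronucleus exists at $t = 0$; it is the extrapolated
intercept that summarises the whole trajectory in one number. Because
$\beta_2 \approx 1.04$ varies little between embryos, $\beta_1$ carries the
discriminative signal.

**Fitting.** The model is linear on the log scale,
$\log f(t) = \log\beta_1 + t \log\beta_2$, so we fit by closed-form least
squares of `log(area)` on time: deterministic, no initialisation, no
convergence failures. The reported $R^2$ is computed on the *original* area
scale from back-transformed predictions, because areas (not log-areas) are
the measured quantity. Whether the loss should live on the log or raw scale
is implementation-defined; the log-scale choice weights relative rather
than absolute errors, which matches multiplicative measurement noise in
segmented areas. A trajectory must have at least 4 points (2 parameters
plus 2 residual degrees of freedom).

**Variants.** Four fitting windows trade data quantity against early-stage
detection noise:

| variant    | window                        | rationale |
|------------|-------------------------------|-----------|
| `original` | all retained frames           | maximal data |
| `adjusted` | drop first and last 3 frames  | those frames carry the worst recognition error and the highest leverage |
| `h12`      | frames at ≥ 12 h              | detector overcalls essentially vanish after 12 h |
| `h14`      | frames at ≥ 14 h              | overcalls absent entirely after 14 h |

All variants report the $t = 0$ intercept, so their $\beta_1$ values are
directly comparable. A window retaining fewer than 4 points flags the
variant unavailable rather than failing the embryo.

A model-family comparison utility (`compare_model_families()`) fits linear,
logarithmic, cosine and quadratic alternatives. One caveat discovered while
building it: with $\beta_2 \approx 1.04$ over a 6–22 h span the exponential
is numerically near-linear ($e^{0.039t}$ has little curvature across 15 h),
so a straight line also achieves $R^2 > 0.99$ on clean data. The exponential
remains the best or tied-best family, which is what the package asserts; a
claim that the alternatives fall below $R^2 = 0.90$ is not attainable on
data generated under these growth statistics.

## Focal selection

Sharpness is the population variance of the 4-neighbour Laplacian response
(`[[0,1,0],[1,−4,1],[0,1,0]]`), the standard variance-of-Laplacian autofocus
statistic: defocus suppresses high spatial frequencies, and the Laplacian is
a high-pass filter, so the in-focus plane maximises the response variance.
Numerical choices: the one-pixel border where the kernel does not fit is
excluded rather than padded (padding conventions differ between libraries
and would change scores); ties break to the lowest plane index so reruns are
deterministic; colour input is collapsed to luma grayscale first. The score
is invariant to added intensity offsets and scales as $c^2$ under intensity
scaling — neither affects the argmax. Stacks of any plane count are
accepted; the default geometry is 11 focal segments 15 µm apart (−75…75 µm).

## Detection

The baseline detector — Gaussian smoothing (σ = 2 px), Otsu thresholding,
connected components, area and circularity ($4\pi A/P^2 \ge 0.7$) gates —
is a deliberately simple, deterministic stand-in for a trained
instance-segmentation network. It is adequate for the simulator's rendered
imagery and any similarly high-contrast source; clinical deployments are
expected to ingest detection tables from their own detector
(`read_detections()`), which bypasses imaging entirely. One numerical
subtlety: Otsu's threshold generally sits below the half-maximum of a
blurred disk edge and inflates areas by several percent, so each component's
area is re-measured at half-maximum between its intensity plateau and the
local surround (lower-quartile of a dilated ring) — the area-preserving
level for a symmetric edge profile.

Pixel areas convert to µm² through the square of the pixel scale; the
default 0.3275 µm/px is the calibration of the target time-lapse system and
is overridable everywhere it matters.

Recognition against annotation is summarised by three counts on a shared
frame set — correct 2PN calls, overcalls (automatic 2PN on a frame that is
not annotated 2PN) and misses (annotated 2PN not called 2PN) — with
accuracy = correct/(correct + overcalled + missed), optionally restricted
to frames after 12 h or 14 h.

## Tracking

**Abandonment.** Frames whose detection count differs from 2 are discarded
and logged with the offending count. This removes early frames where only
one PN has formed, vacuoles mislabelled as a third PN, and late frames
where partially overlapping PNs merge into one detection. An embryo with
fewer than 4 retained frames is unanalyzable.

**Identity linking.** The two detections of consecutive frames are linked
by nearest centroid. This is justified by the physical scales: PN
displacement per 10–15 min frame is far smaller than the inter-PN distance,
so the greedy match is almost always unambiguous.

**Sexing.** Two automatic rules, applied in order of precedence: the male
PN appears earlier (used when first-seen times differ by at least one frame
interval); otherwise the male PN is the one with the larger mean area over
the first 5 retained frames. Embryos failing both rules (identical
appearance and identical early areas) are excluded as indistinguishable, as
a clinic would. The classical polar-body proximity rule is deliberately not
automated — it needs a reliable polar-body detection that neither the
baseline detector nor typical learned detectors provide — but a
`sex_override` column on ingested detections is honoured, mirroring manual
embryologist correction.

**Label stability.** Per-frame labelling can still flip female and male on
isolated frames. For each consecutive retained pair the cosine between the
female→male centre vectors must be strictly positive; a failing frame has
its labels swapped (which reverses its vector and flips the sign of the
cosine) and is re-checked, and a frame failing both labelings — exactly
perpendicular vectors, the boundary of the rule — is discarded. Coincident
centres (zero-length vector) also discard the frame. Each corrected frame
becomes the reference for the next pair, so a persistent identity exchange
propagates forward and is fixed frame by frame; the alternative
(comparing every frame to the original reference) would mark every frame
after a true exchange as faulty. Corrections are recorded as `swap_events`,
and on simulated tracks with injected flips the recovered set equals the
injected set exactly in noiseless runs.

## PGT parsing and classification

PGT report strings are parsed with a whitespace- and case-tolerant grammar
covering whole-chromosome gains and losses, segmental duplications and
deletions with band ranges and megabase sizes, and mosaic annotations with
percentages; Unicode minus/times/arrow signs and both `Mb` and `m` for
megabases are accepted because clinical reports mix them. Unrecognised
terms raise an error carrying the token — silent skips would corrupt
category counts downstream.

Categories partition parsed error lists: `chromosome_normal` (no errors),
`sole_mosaic` (all errors mosaic), `sole_aneuploidy` (only non-mosaic
whole-chromosome errors), `sole_del_dup` (only non-mosaic segmental),
`euploidy_with_errors` (segmental plus mosaic, no whole-chromosome),
`aneuploidy_with_errors` (whole-chromosome plus exactly one other error
class) and `complex` (all three). A single mosaic segmental event is
classified `sole_mosaic`, not `euploidy_with_errors` — mosaicism is the
operative feature because it points to post-zygotic mitotic origin. For the
same reason `chromosome_normal` and `sole_mosaic` form one *normal group*
for outcome statistics: sole mosaicism should not be attributed to the
gametes being ranked.

Parental coincidence for structural-rearrangement carriers is resolved at
whole-chromosome level: an embryo error involving any chromosome of the
carrier's rearrangement (translocation, Robertsonian, inversion or
derivative) is `coincident`, otherwise `inconsistent`; embryos with no
errors or sole mosaicism are `not_applicable`. Band-level matching was
considered and rejected as under-specified: reported embryo segments and
carrier breakpoints rarely share resolution.

## Rank statistics

Because the area coefficient is strongly heterogeneous between patients
(Cochran Q on per-patient means; the simulator's default cohort gives
$I^2 > 90\%$), absolute $\beta_1$ values are not comparable across
patients and no normal range exists. All outcome statistics therefore work
on within-patient descending ranks (ties broken by embryo id for
deterministic reruns), pooled beyond rank K (10 for formation tables, 8 for
PGT tables).

The battery: per-rank rate tables in `numerator/denominator (percent)`
form; top-k versus bottom-k odds ratios with the Woolf log-OR interval
$\exp(\ln OR \pm 1.95996\sqrt{\Sigma 1/n_{ij}})$ and Haldane +0.5 zero-cell
correction; Pearson chi-square on R×2 formation tables (no continuity
correction); Spearman mid-rank correlation with the t approximation; and
fixed-effect Cochran Q with $I^2 = \max(0, (Q - df)/Q)$. The Woolf
construction was chosen because it reproduces published worked examples of
this analysis to printed precision; no multiple-testing correction is
applied, matching the analysis this package reimplements — users comparing
many strata should apply `p.adjust` themselves.

## The simulator

The generator emulates the study conditions end to end; its defaults are
the package's single source of truth for "realistic" scales:

* **Cohort structure**: 155 patients, 2 + Poisson(3.1) embryos each
  (≈ 5 embryos/patient, every patient at least 2 so ranking extremes
  exist).
* **Growth**: female $\beta_1 \sim$ patient effect $N(250, 75^2)$ µm² plus
  embryo deviation $N(0, 40^2)$; male $\beta_1$ shares the patient effect
  (giving the observed ≈ 0.75–0.8 female–male correlation) scaled by 1.25
  so the male PN is larger early; $\beta_2 \sim$ truncated
  $N(1.04, 0.017^2)$ on [1.01, 1.11]. The resulting PN areas at 16–22 h are
  ≈ 450–700 µm² (diameters 24–30 µm) inside a 110 µm zygote.
* **Timing**: male PN appears uniformly in 6.5–8 h, the female 0.5–1.5 h
  later; both fade at 20–23 h; frames every 15 min; PNs migrate from the
  periphery and are juxtaposed from a meeting time drawn in 12–15 h.
* **Noise**: multiplicative lognormal area noise, σ = 0.02 by default —
  chosen so that original-scale fits land in the upper-90s percent $R^2$
  range reported for real data. A closed-form relation worth knowing: over
  a 7–22 h trajectory the area curve's signal SD is ≈ 0.30 β₁ while noise σ
  contributes ≈ 1.8 σ β₁ of residual SD, so $R^2 \approx 1 - (6\sigma)^2$;
  σ = 0.05 caps $R^2$ near 0.91 regardless of the fitting method, and
  $R^2 \ge 0.98$ requires σ ≲ 0.025.
* **Detector errors**: frames with fewer than two true PNs are spuriously
  called 2PN at rate 0.25 before 12 h and 0.02 in 12–14 h (so ≈ 95% of
  overcalls are early-stage); true 2PN frames acquire a vacuole-like third
  detection at rate 0.01; overlapping late pairs (centre distance below
  0.97 of the summed radii, from 14 h) merge into one detection at rate
  0.1, putting misses near 1–2% of 2PN frames. Because both PNs exist from
  ≈ 9.5 h under these appearance windows, no overcall can fall after 12 h,
  and consequently the 12 h-window accuracy always slightly exceeds the
  14 h one (both windows share the same misses; the wider window has more
  correct frames). The all-stage accuracy sits well below both, as in real
  detector behaviour.
* **Outcomes**: $P(\text{normal group}) = \text{logistic}(\alpha + \gamma
  z)$ with $z$ the within-patient $\beta_1$ z-score; α = 0.06, γ = 0.23
  place the expected top-rank rate near 58% and the bottom-rank rate near
  45% for five-embryo patients (the expected extreme z of five draws is
  ≈ ±1.16). γ = 0 gives the null model. Non-normal embryos draw a category
  (45% sole aneuploidy, 18% sole del/dup, 15% aneuploidy-with-errors, 12%
  euploidy-with-errors, 10% complex) and a PGT string synthesised from the
  parsing grammar, so the parser is exercised on generated text, not only
  on literals; 30% of normal-group embryos are sole-mosaic.
* **Rendering**: 256×256 frames by default (scale adjusted so a 250 µm
  well spans the image), zygote disk, two PN disks with areas matching the
  trajectory, defocus blur proportional to focal distance (capped so the
  blur kernel fits the image), Gaussian sensor noise.

Everything is a deterministic function of (config, seed).

**What the simulator does not emulate** — and hence what passing tests do
not show about clinical data: Hoffman-modulation-contrast texture,
cytoplasmic granularity and nucleolus precursor bodies (the detector's task
is much easier here than in real imagery); segmentation boundary errors
beyond count errors; polar-body geometry; embryos arrested before the
pronuclear stage; PGT measurement noise (categories are drawn, not called
from reads); and any true biological link between growth kinetics and
karyotype — the outcome model is a logistic convenience, so recovering its
parameters validates the pipeline's statistics, not the biology.

## Problem sizes used in the test suite

The suite favours many small seeded cohorts over few large ones: focal
selection is validated on 200 seeded 64-px blur ladders; growth recovery on
20 seeded replicates of ≈ 10 trajectories at σ = 0.02; the β₂ summary on a
≈ 500-embryo cohort; the detector error model on 25-patient cohorts; and
the null outcome model on one 2000-patient cohort, where the top-vs-last
log-OR is asserted within 0.2 of zero (≈ 3 standard errors at that size).

## Known limitations

* The baseline detector assumes bright, roughly circular PNs on a darker
  interior; it is not a segmentation method for clinical HMC imagery.
* Nearest-centroid linking can in principle swap identities if the two PNs
  pass within a frame's displacement of each other; the cosine rule
  catches the resulting label flips but the trajectory points of the
  crossing frames may still be exchanged.
* The PGT grammar covers the notation family above, not the full ISCN
  standard.
* Appearance-time inference from detection tables uses single-detection
  frames before the first 2PN frame; if the detector never sees the male
  PN alone, sexing falls back to the early-size rule.
* With ≈ 5 embryos per patient, top-1/bottom-1 comparisons discard most of
  the cohort; the rank-rate tables use all embryos but inherit the pooling
  choice K.
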