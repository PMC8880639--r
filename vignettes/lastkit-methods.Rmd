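---
title: "From scanned series to feature vector: the lastkit pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From scanned series to feature vector: the lastkit pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lastkit)
```

lastkit turns a scanned Luria's Alternating Series Test (LAST) form into a
per-subject feature vector and a sequence-correctness score. This vignette
explains the model behind each stage, the tunable parameters and their
defaults, the numerical choices, what the synthetic generator does and does
not emulate, and the known limitations.

## 1. The signal-form representation

The drawn series is a connected pencil trace: open rectangles and
triangles joined at the writing baseline. After binarization and thinning,
the trace is collapsed to one height per image column — the **upper
envelope** of the skeleton, in up-positive page coordinates
(`to_signal_form()`). The upper envelope is the only single-valued
reduction under which the later amplitude rule works: an open rectangle
maps to a plateau near its maximum (its full-height side strokes and top
stroke dominate every column) while a triangle maps to a tent. Columns the
skeleton does not cross are linearly interpolated and flagged, and
flagged samples are excluded from arc-length measurements.

The cost of a single-valued envelope is that overlapping strokes are
invisible below the topmost one; Section 9 returns to this.

### Binarization

A LAST scan is overwhelmingly white paper, so the intensity histogram has
one dominant high-intensity mode. `estimate_background_threshold()` finds
that mode (restricted to intensities above 128; an image without such a
mode is rejected as having no paper background), walks down its
low-intensity foot while the smoothed counts keep falling, and places the
threshold 3 gray levels below the foot. The walk stops at the first
up-tick or at zero counts, so isolated dark-tail noise does not drag the
threshold down. Binarization is followed by a morphological opening with
a disk of radius `round(dpi/600)` pixels, which removes binarization
speckle; the cleaned mask is always a subset of the thresholded one.
Thinning uses the classical two-subcycle boundary-peeling scheme, which
preserves 8-connectivity and component count.

## 2. Baseline estimation (BEADS)

The signal form `y` is modelled as sparse positive peaks `x` (the
characters), a low-pass baseline `f`, and noise. `beads_solve()` minimizes

$$F(x) = \tfrac12\lVert H(y-x)\rVert_2^2 + \lambda_0\sum_n
\theta_\epsilon(x_n; r) + \sum_{i=1}^{2}\lambda_i\sum_n
\phi([D_i x]_n)$$

by majorization–minimization (MM), where `H` is the high-pass complement
of a banded zero-phase low-pass filter of order `d` with cut-off `fc`
(half-power point, cycles/sample), `D1`/`D2` are first and second
difference operators, `θϵ` is an asymmetric penalty that charges negative
amplitudes `r` times more than positive ones, and `φ` is a smoothed
absolute value (smoothing constant `ϵ = 1e-6`). The baseline estimate is
`f = L(y − x̂)` with `L = I − H`.

`adaptive_baseline()` wires this into the pipeline convention: the signal
is first shifted so its first sample is zero (the trace starts with the
pen on the writing baseline, so this anchors the baseline at zero), then
solved with the data-driven weights `λ0 = 1/σ(y)`, `λ1 = λ2 = 2λ0` and
`r = 1/σ²(y)` (population denominators). If the estimated baseline's
maximum exceeds the signal's maximum — an unambiguously pathological
outcome — `λ1` and `λ2` are doubled alternately and the decomposition is
recomputed, up to `max_doublings = 10` times, after which the last result
is returned with a warning flag.

**Numerical choices.** At very low cut-offs (the pipeline default is
`fc = 1e-4`) the MM linear system becomes nearly singular along its DC
direction and a naive iteration can oscillate. The solver therefore takes
a safeguarded step: if the candidate iterate increases the true objective,
it backtracks toward the previous iterate, and a step that cannot improve
at all terminates the iteration (the solution has stalled at numerical
precision). The objective is consequently non-increasing by construction,
and the test suite cross-checks the minimizer against a general-purpose
quasi-Newton optimizer on a small problem.

**Scale matters.** The rule `λ0 = 1/σ(y)` couples the sparsity weight to
the signal's units. On pixel-scale series signals (amplitudes of ~100 px)
it yields a very weak sparse term: the peaks absorb essentially
everything and the estimated baseline is essentially zero, so the leveling is
done by the initial shift and the baseline step only removes residual
slow structure. On amplitude-normalized signals the same rule gives a
strong-sparsity regime in which the baseline genuinely tracks slow
drift — this is the regime in which the benchmark of Section 8 operates,
and the regime in which the doubling loop has work to do.

## 3. Character separation

Adjacent characters meet at the writing baseline, so the aligned signal
dips toward zero between them. `find_separating_columns()` takes the
local minima whose value is below `valley_frac = 0.10` times the robust
maximum (95th percentile) of the aligned signal; minima within 3 columns
of each other collapse to one valley (a jagged skeleton envelope can
split a single baseline valley into near-adjacent minima).

`split_characters()` erases a vertical strip of half-width equal to half
the estimated stroke width (from the distance transform; minimum 1 px)
around each valley and labels the remaining 8-connected components. Three
clean-up rules, all part of the package's segmentation design, handle the
fragments that strip-cutting creates:

* components smaller than `min_area_frac = 0.05` of the median component
  area merge into the component whose column interval overlaps theirs
  most, or are dropped when none does;
* a component whose column span is at least 60% contained in a larger
  component's span merges into it — a strip cut through a leaning side
  stroke otherwise leaves a severed sliver that would count as a
  character;
* a component wider than `refine_wide = 1.6` times the median character
  width is re-cut at the deepest interior minimum of its signal segment
  and the split is repeated (at most three rounds). This recovers
  junctions whose valley was masked in the upper envelope by a slanted
  neighbour's overhanging stroke.

Characters are then ordered by centroid column and paired with their
aligned-signal segments.

## 4. Shape recognition

Recognition is anchored by per-scan **models** — typical characters
promoted by four rules evaluated in order (`select_models()`):

(a) if the minimum-area enclosing triangle `T` and rectangle `R` of the
character's pixels satisfy `T/(R+T) < 0.55`, it is a triangle model;
(b) if the smaller enclosing shape's symmetric ratio is below the same
0.55 threshold, the character models that shape's class;
(c) a near-horizontal line longer than 0.25 of the character width
(`hough_horizontal_fraction()`, ±5° sweep) makes it a rectangle model;
(d) more than 66% of normalized-signal samples above amplitude 0.8 makes
it a rectangle model, fewer than 33% a triangle model.

The enclosing rectangle uses rotating calipers over the convex hull. The
enclosing triangle exploits the optimality condition that at least one
side of the optimum is flush with a hull edge and the midpoint of every
side touches the hull, which leaves exactly two candidate families —
three flush sides, or two flush sides plus a third side bisected by a
hull vertex — both enumerated exhaustively (cubic in the hull size) and
verified against a support-line optimization oracle in the tests.

Characters not promoted to models are normalized to unit amplitude,
resampled to the scan's median character width, and assigned the class of
the nearest model under dynamic time warping with squared-Euclidean local
cost and a band constraint of 5% of the longer sequence; ties break
toward the rectangle class. If a class yields no model, three artificial
templates stand in: a perfect plateau plus two isosceles trapezoids (top
side 0.5 and 0.7 of the base) for rectangles; a centred tent plus two
mirrored right triangles (apex at 0.25 and 0.75 of the width) for
triangles.

## 5. Features, normalization, NW coefficient

Per character, `character_features()` measures: bounding-box width and
height; the same after **straightening** (rotation by the orientation of
the ellipse with identical normalized second central moments, bilinear
interpolation re-binarized at 0.5; isotropic masks rotate by 0); ink
area (the characters are open strokes, so "area" is the stroke pixel
count); convex hull area; equivalent-ellipse axis lengths and
orientation (degrees, in (−90, 90]); signal arc length
`Σ √(1 + Δy²)` skipping interpolated samples; the amplitude fraction;
and the DTW distance to the perfect artificial template of the
character's class. Every spatial feature is additionally divided by the
value of the examiner's first template character of the same class
(`*_n` features), making series comparable across examiners and scan
scales.

`series_features()` aggregates examinee characters per class by median
(MED) and interquartile range (IQR, type-7 quantiles), computes the
per-class width ratios — the summed class widths over the examinee
extent, in percent; 50% means both shapes got equal space — and scores
the recognized sequence with the **NW coefficient**: a Needleman–Wunsch
scoring matrix (match reward `m = 1`, mismatch and gap penalties 0,
`H(0,0) = 0`) aligns the examinee sequence against the ideal alternation
continuing the examiner's prefix, and the maximum score is normalized by
the ideal's self-alignment. With the default parameters this equals the
longest-common-subsequence length as a percentage of the sequence
length — 100% for a perfect series, decreasing with every perseveration —
a property the tests verify against an exhaustive LCS oracle. The width
ratio deliberately uses the examinee extent only: the examiner prefix is
the normalization template, not part of the subject's production.

## 6. Statistics and classification

`kruskal_dunn()` screens every feature with the tie-corrected
Kruskal–Wallis test at `α = 0.05` and, only where KW rejects, runs Dunn's
z-tests on mean ranks for all group pairs (no multiplicity correction by
default, a Holm option is exposed). `train_ecoc_svm()` reduces the
three-group problem to three pairwise Gaussian-kernel SVMs; prediction
decodes the ±1 votes by Hamming distance to the one-vs-one codewords,
ties breaking toward the larger class. The kernel coefficient follows the
"Medium Gaussian" convention `γ = 1/n_features` on standardized features;
`gamma_mode = "paper"` switches to the literal `γ = n_features`, which on
standardized data is a near-degenerate kernel and is provided for
comparability only. `cross_validate()` performs seeded, stratified k-fold
cross-validation with imputation, standardization and (by default)
KW-based feature selection all fitted inside each training fold; selection
inside the fold is the statistically safer choice and is therefore the
default, with non-nested use available by passing an explicit feature set.

## 7. The synthetic generator

`render_series()` draws the series as the pen would: a short baseline
lead-in stroke, then alternating open rectangles (up, across, down) and
triangles (up-slant, down-slant) joined by 3-px baseline connector
strokes — the test is executed without lifting the pencil, and the
connectors are exactly what makes the signal form dip to the baseline
between characters. Per-character size jitter, slant (modelled as a
horizontal shear, so leaning strokes keep their baseline endpoints, as a
leaning pen does), progressive multiplicative size decay (micrographia),
and perseveration substitutions are applied, then a slow sinusoidal
baseline drift, rasterization with a disk pen, Gaussian noise and dark
speckle. Ground truth — label sequence, per-character masks, ideal
envelope — is exact by construction, and rendering is deterministic given
the seed.

Defaults model a well-executed 600-dpi form: 120 × 100 px characters
(~5 mm), 4-px stroke, background at gray level 245 (white paper without
clipping the noise at 255), noise SD 4, speckle rate 1e-4, drift
amplitude 5 px over one page period. The drift default is deliberately
subordinate to the segmentation rule: with the pipeline's low-frequency
cut-off the aligned valleys sit at drift level, so a generator meant to
represent a *readable, well-acquired* scan keeps drift (~5% of character
height) below the 10% valley threshold. Group presets encode the
phenotypes of interest: controls draw regular, well-sized series with no
perseveration; the PD preset shrinks characters (85 × 70 px), tightens
their variability and adds progressive decay (0.985 per character) with
occasional perseveration (p = 0.06); the PSP preset keeps size but raises
perseveration (p = 0.28), size jitter (SD 14 px) and slant (SD 5°).

What the generator does **not** emulate: pencil texture and pressure
variation, stroke-order or kinematic information (unrecoverable from a
static scan in any case), curved or retraced strokes, touching characters
that overlap in depth, and page-level artifacts (rulings, folds, skew of
the whole sheet). Passing tests on synthetic data therefore demonstrate
the pipeline's correctness under the stated geometric and noise model,
not its clinical accuracy on real forms — on real patient drawings the
separation and recognition rates are expected to degrade with shape
malformation, exactly as the imperfect expert-agreement of automatic
processing on clinical material would suggest.

## 8. Benchmarks and problem sizes

The test suite checks every algorithmic core against an independent
oracle: DTW against an exhaustive lattice recursion (500 random pairs up
to length 30), the NW coefficient against brute-force LCS (10⁵ random
pairs up to length 8), enclosing shapes against support-line optimization
(200 random hulls up to 12 points, 1e-6 relative tolerance), and BEADS
against a quasi-Newton minimizer of the same objective. The BEADS
recovery benchmark uses a 2000-sample signal with a full-period sinusoid
baseline (amplitude 20), five tents of half-width 25 and height 50, and
2% noise; the solver runs on the amplitude-normalized signal with
`fc = 3e-3` (between the drift band and the peak band), `λ0 = 0.02`,
`λ1 = λ2 = 2λ0` and `r = 1/σ²` — parameters chosen once for the
benchmark's frequency content, as the solver interface intends. End-to-end
checks process ten noise-free control scans (17 characters each) and a
simulated cohort of 35 subjects per group whose features are extracted
from the ground-truth delineations (the expert-delineation analogue);
these sizes keep the default test run within a few minutes on one core
while exercising every stage at full scan resolution.

## 9. Known limitations

* The upper-envelope signal form hides anything below the topmost stroke
  in a column; severely overlapping or retraced characters cannot be
  separated by valley analysis alone (the width-refinement pass recovers
  the common single-masked-junction case).
* With the pipeline's default `fc`, the BEADS baseline is nearly flat on
  pixel-scale signals; strong low-frequency drift (comparable to the
  valley threshold) degrades separation before the baseline step can
  help.
* Per-character amplitude normalization makes a geometrically ideal
  rectangle's signal nearly flat, so its normalized amplitude features
  carry little information for perfectly drawn strokes; they become
  informative exactly when drawings deviate from ideal, which is the
  population of interest.
* The disease presets are phenomenological: they encode the direction and
  rough magnitude of published group differences (smaller, more regular
  PD characters; perseverative, irregular PSP series), not fitted
  clinical distributions, and classifier accuracies on them should not be
  read as clinical performance estimates.
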