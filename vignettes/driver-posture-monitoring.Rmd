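---
title: "Driver posture monitoring from seat pressure maps: methods and design notes"
author: "seatpose"
output: html_document
vignette: >
  %\VignetteIndexEntry{Driver posture monitoring from seat pressure maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A driver's trunk and foot postures leave a characteristic footprint in the
body pressure distribution (BPD) measured by sensor mats on the backrest and
seat pan. `seatpose` implements a feature-based recognition method for this
setting and, on top of it, an evaluation harness for the question that makes
the method practically interesting: *how far can the sensor count be reduced
before recognition degrades?* High-resolution mats (42 × 44 cells per side,
1.27 cm square cells) are reference instruments, not production hardware; the
package evaluates a family of reduced layouts with 13–145 sensors per mat
(up to a 92 % reduction) by reconstructing the full-resolution map with
inverse distance weighting and re-running the whole recognition pipeline.

The pipeline is:

1. **Label** each frame per body part from ground-truth kinematics
   (trunk classes TP0–TP4, left foot LFP0–LFP1, right foot RFP0–RFP2).
2. **Filter** near-duplicate postures per subject (3° / 2 cm rules).
3. **Extract** 200 candidate pressure features per frame pair, relative to a
   task-initial standard posture.
4. **Rank** features by random-forest out-of-bag permutation importance and
   select a subset per body part.
5. **Evaluate** per-body-part classifiers by leave-one-subject-out (LOSO)
   cross-validation (precision, recall, F1 per class; unweighted macro F1).
6. **Benchmark** reduced sensor layouts against the full-resolution result
   with per-class paired t-tests across LOSO folds.

Because no instrumented-seat recordings ship with the package, a synthetic
BPD generator (`generate_dataset()`) provides the data on which everything is
exercised and tested.

## Posture classes and labelling

Trunk posture is described by three angles relative to the task-initial
standard trunk position: rotation, inclination (forward/backward lean) and
lateral tilt, in degrees. The published class scheme gives only qualitative
definitions ("noticeable deviation" per angle), so the numeric bands are
package configuration (`posture_thresholds()`), with defaults:

| class | definition (defaults) |
|-------|------------------------|
| TP0   | all three \|angles\| ≤ 10° (dead band) |
| TP2   | inclination-dominant deviation beyond the dead band |
| TP3   | rotation-dominant deviation |
| TP1   | lateral-tilt-dominant, \|tilt\| in (10°, 25°] |
| TP4   | lateral-tilt-dominant, \|tilt\| > 25° |

When several angles exceed the dead band the largest *normalised* deviation
(\|angle\| / dead band) decides, with exact ties resolved in the fixed order
TP2 > TP3 > TP1/TP4. This precedence rule is a design decision: mixed
deviations are not defined by the published scheme, and a deterministic rule
is required for reproducibility. TP1 and TP4 differ only in the lateral-tilt
band, which is why TP4 is the class most sensitive to sensor reduction.

Foot classes are nearest-zone assignments of the foot-centre position in the
floor plane (right: accelerator / brake / floor; left: floor / clutch). Zone
reference points are configurable; defaults place the brake 12 cm left of the
accelerator and the floor zones well away from the pedals, so the default
±3 cm position scatter can never flip a zone.

### Redundancy filter

Long recordings of held postures would otherwise flood the training set with
near-duplicates of the same subject. The filter makes a greedy temporal pass
per subject and keeps a sample only if it differs from **every** previously
kept sample of that subject — by more than 3° in at least one trunk angle, or
by more than 2 cm of foot-centre distance. Comparison against all kept
samples (not only the last) is deliberate: last-only comparison lets a slow
drift re-admit near-duplicates of earlier postures. The last-only variant
remains available (`compare = "last"`). Each body part is filtered
independently; the trunk filter never sees foot data.

## The 200-candidate feature collection

Both mats are partitioned into rectangular subareas: 12 on the backrest
(4 row bands × 3 column bands, B1–B12 row-major from top-left) and 8 on the
seat pan (4 × 2, S1–S8 from front-left). Band widths are as equal as possible
with remainders pushed to the outer bands, which keeps both schemes
mirror-symmetric about the vertical midline (44 columns split 15/14/15 on
the backrest and 22/22 on the seat pan). On top of the subareas, *regional
areas* are unions of adjacent subareas: every horizontally adjacent pair,
every row band, every column band, and the upper/lower halves.

Feature kinds: center of pressure (CoP, the load-weighted centroid
\\( (x,y) = \sum_i p_i (x_i, y_i) / \sum_i p_i \\) in cell-centre cm),
contact area proportion (fraction of cells above a contact threshold),
pressure ratio between disjoint areas \\( \Sigma p_A / (\Sigma p_A +
\Sigma p_B) \\), and the area statistics mean pressure, peak pressure and
total force (pressure × cell area).

The exact published list of 200 candidates is not available, so the package
ships its own deterministic manifest, asserted to total exactly 200 at
construction:

* global area, per side: CoP x/y, contact, mean, peak, total (2 × 6 = 12);
* each of the 20 subareas: CoP x/y, contact, mean, total (100);
* each of the 29 regional areas: contact, total (58);
* 30 pressure ratios: the 12 horizontally and 15 vertically adjacent subarea
  pairs, upper vs lower halves on both sides, and left vs right halves of the
  seat pan.

The backrest has three column bands, so its "left vs right half" ratio would
ignore the middle third and duplicate information already present in the nine
per-column vertical ratios; it is omitted, which is also what lands the
total at exactly 200. Alternative segmentations can be supplied as
declarative text files (`read_segmentation()`), and the enumeration errors —
never truncates — if a scheme cannot yield 200 features.

### Relative features and degenerate inputs

Absolute pressure features vary with body mass and seat adjustment much more
than with posture. All classification therefore uses *relative* features:
the feature vector minus a per-(subject, task) reference computed as the mean
feature vector over the task's opening 0.5 s, every task starting from the
standard posture. Differences rather than ratios are used because they stay
well defined when a reference entry is zero.

Two quantities can be undefined on sparse frames: the CoP of an unloaded area
and the ratio of two unloaded areas. Both are detected exactly (zero masked
sum) and replaced before classification by neutral values — the area's
geometric centre and 0.5 respectively — keeping feature matrices dense
without injecting extreme values. The contact threshold defaults to 0 (any
positive reading counts); when the measurement has an additive noise floor,
setting the threshold equal to the floor makes contact features exactly
invariant to it, which the test suite verifies.

## Reduced sensor layouts and reconstruction

Layouts live in normalised mat coordinates \\([0,1]^2\\) and are generated by
recursive uniform sampling. Level 1 is the 3 × 3 lattice plus the four
quadrant centres (13 sensors). Each refinement adds the hypotenuse midpoints
of the right triangles formed by adjacent sensors; the family therefore
alternates between quincunx lattices (odd levels, \\(n^2 + (n-1)^2\\) points)
and full square grids (even levels), each level nesting in the next:
13, 25, 41, 81, 145 sensors for levels 1–5. The implementation uses this
closed form directly — the triangle-midpoint recursion is geometrically
equivalent but ambiguous about triangle enumeration — and the tests
cross-check the closed-form counts against exhaustive generation.

Sampling reads each sensor's value from the nearest cell of the
full-resolution frame (ties broken towards the lexicographically smallest
(row, col)). Reconstruction is inverse distance weighting: every cell becomes
a normalised \\(d^{-p}\\)-weighted mean of its `n_neighbors` nearest sensors,
with a cell within `eps` of a sensor copying its value exactly. Defaults
`power = 2`, `n_neighbors = 4`, `eps = 1e-12` are declared standard practice,
not inferred values — the source method states none. Because the weights are
convex, reconstructed values are always bounded by the sampled extrema, and a
layout sampling every cell reconstructs the identity. Reconstruction is a
fixed linear operator per (layout, geometry), precomputed once
(`idw_operator()`) so whole recordings reconstruct as one matrix product.

## Classifiers and evaluation

Five classifier families are supported with structural hyperparameters
mirroring the evaluated configurations: random forest (10 candidate variables
per split, at most 200 splits per tree — i.e. 201 terminal nodes, capped at
the sample count — 100 trees), RBF-kernel SVM on standardised inputs,
a one-hidden-layer perceptron of width 512, 3-nearest-neighbours, and naive
Bayes. Deviations forced by the open-source stack are deliberate and
documented:

* the proprietary "interaction curvature" split-selection test has no open
  equivalent; the forest uses standard impurity splits with the same capacity
  controls, and the tree count (unstated in the source) defaults to 100;
* the multiclass SVM is one-vs-one rather than ECOC;
* the perceptron trains with `nnet`'s quasi-Newton optimiser (width and
  40 passes kept) instead of adam with mini-batches;
* the "multivariate multinomial" naive Bayes applies to discrete predictors
  only; on continuous relative features the Gaussian variant is used.

Training sorts rows into a canonical lexicographic order first, so a fixed
seed yields predictions invariant to input row order.

Feature importance is the out-of-bag permutation importance: the mean
increase in a tree's OOB classification error after permuting one feature,
averaged over trees (unscaled). A constant feature scores exactly zero.
`select_features()` evaluates macro F1 over growing prefixes of the ranking
and picks the smallest prefix within a tolerance (default 0.01) of the curve
maximum — more features do not reliably help, and smaller subsets are what
make reduced layouts viable.

Evaluation is leave-one-subject-out: one fold per subject, so generalisation
is always measured on an unseen person. Per-class precision, recall and F1
come from the pooled confusion matrix; the headline number is the unweighted
(macro) mean F1 over the 10 classes, the appropriate choice under class
imbalance. Layout comparisons use two-sided paired t-tests on per-fold
per-class F1 (pairing by held-out subject), flagged at p < 0.05 and p < 0.01;
identical score vectors report t = 0, p = 1 rather than erroring, so an
identity layout compares cleanly.

## The synthetic generator

`render_frames()` models each mat's BPD as a sum of axis-aligned Gaussian
contact lobes: two ischial and two thigh lobes on the seat pan, two scapular
and one lumbar lobe on the backrest, mirror-symmetric at the standard
posture. Kinematics deform the lobes in the directions the posture classes
imply: forward inclination attenuates backrest amplitudes exponentially and
shifts the seat load forward onto the thighs; lateral tilt translates all
lobes laterally (so opposite tilts displace the CoP antisymmetrically,
exactly); rotation loads one scapula and unloads the other; moving a foot off
its standard zone translates and attenuates the same-side thigh lobe.
Per-subject anthropometry is a pressure multiplier, a lobe-spread multiplier
and a small seating offset. Measurement noise is multiplicative (default
`noise_sd = 0.15` of the local signal, clipped at zero) plus an optional
constant additive floor. Labels are derived from the drawn kinematics through
the labelling module itself, so data and labels cannot disagree by
construction, and `render_frames()` rejects inconsistent label/kinematics
pairs.

The default scenario — 10 subjects × 10 tasks × 60 frames at 25 fps, every
task opening with 13 standard-posture frames (a full 0.5 s reference window)
and closing with 5 — is desk-scale yet large enough for meaningful LOSO.
Target kinematics are drawn uniformly from each class band with a 10 %-of-
band-width margin inside the boundaries, so labels are never ambiguous at
thresholds; boundary behaviour is tested separately with hand-built cases.

What the generator does *not* emulate matters for interpreting green tests:
real inter-individual behavioural differences (the main source of foot-class
confusion on real seats), road vibration and acceleration, seat-configuration
changes within a subject, and genuinely continuous motion between postures.
Synthetic results therefore validate the *machinery* — feature definitions,
selection, LOSO protocol, layout comparison — and the qualitative ordering
(full resolution ≥ D5 ≫ D1), not the absolute F1 levels achievable on human
data, which are substantially lower especially for the right foot.

## Numerical choices and problem sizes

* All mask aggregations are sparse-matrix products over vectorised frames,
  so feature extraction of a whole recording is a handful of BLAS calls;
  oracle tests compare them against naive double loops at 1e-9.
* Snap tie-breaking, ratio/CoP sentinels, and the t = 0 degenerate paired
  test are all exact-arithmetic decisions, not tolerance-based.
* The test suite runs the default scenario once (cached across test files);
  the comparative-classifier test evaluates the perceptron at width 64
  because a width-512 `nnet` fit costs minutes on one CPU while the ordering
  claim under test is unaffected; the selection-curve and importance
  simulations use a few hundred samples. These sizes are the package's
  desk-scale choices for routine verification; all of them scale up through
  `scenario_spec()`.

## Known limitations

* Subarea boundaries and the regional-area list are reconstructions of a
  pictorial specification; both are configurable, and the shipped manifest is
  an explicit, versioned stand-in for the unavailable published list.
* Trunk class bands (Fig-3-style numeric ranges) are declared defaults, as
  are the foot zone coordinates; the synthetic generator is parameterised by
  the same configuration, so changing either keeps data and labels coherent.
* IDW parameters are declared defaults; no claim is made that they are
  optimal for BPD fields.
* The redundancy filter's "1 cm spacing" style edge cases show that
  compare-against-all-kept can retain more than one sample from a slowly
  drifting sequence once the drift exceeds the threshold relative to the
  first kept sample; this is inherent to any greedy one-pass rule.
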