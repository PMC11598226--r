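---
title: "Contactless sleep-posture monitoring: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contactless sleep-posture monitoring: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnoposture)
```

## The sensing model

Six ultrasonic range sensors hang over a bed in the fixed order
(H_R, H_L, A_R, A_L, R_L, L_L): head, abdomen and leg pairs, right and
left side. Each sensor measures the round-trip time of an echo pulse and
the range equation `distance = speed × tof / 2` turns it into metres. A
passive-infrared (PIR) sensor between the head pair flags whether the
bed is occupied at all; every downstream stage idles while it is 0.

The geometry defaults describe a ceiling mount: sensor plane 2.4 m above
the bed, trusted echo window 0.3–2.7 m (closer or farther readings are
noise-prone and flagged invalid), and roughly 0.47 m of bed covered per
sensor. A body part under a sensor raises the echo surface by the
`body_elevation` parameter, 0.25 m by default — a deliberately coarse
single number: the model needs only that an occupied channel reads
clearly shorter than the bare bed.

**Presence thresholding.** A channel's bit is 1 when its distance is
valid and at most `sensor_height − presence_margin`. The margin δ
defaults to 0.15 m, sitting between the noise scale (centimetres) and
the body elevation (0.25 m), so an occupied channel has a 0.10 m margin
against noise and a bare channel a 0.15 m one. Invalid readings become
bit 0 rather than errors: a streaming monitor must ride through
dropouts. δ must therefore always be chosen strictly below
`body_elevation`; the constructor enforces it.

## The classifier

The eight standard postures map to 6-bit words through a truth table
with don't-cares (the supine row is `XX1111`: the head bits do not
matter because the abdomen and legs already identify the pose). The
hierarchical binary classifier is the same mapping compiled into an
early-exit tree of two-bit tests:

```{r}
build_tree()
```

Leg pair `00` or `11` decides immediately (frog / supine); otherwise the
abdomen pair selects the fetal posture on `11`, and the head pair
separates yearner (`11`) from lateral. At most three comparisons decide
any word, and the compiler verifies leaf-by-leaf agreement with the
table scan on all 64 words before returning a tree, rejecting ambiguous
or non-tree-shaped tables.

Two modes matter:

* **early-exit** (`strict = FALSE`, the streaming default): bits off the
  tested path are ignored, so all 64 words get a standard label — e.g.
  `000000` exits at legs `00` as FP. This mirrors a hardware
  comparator cascade.
* **strict** (`strict = TRUE`): the tree's answer is kept only if the
  full word matches that row; anything else is `UNKNOWN`. Learning uses
  strict matching (a stored reference must be a complete pattern), and
  monitoring can use it when untyped gap frames should stay untyped.

```{r}
c(classify("111101"), classify("000000"), classify("000000", strict = TRUE))
```

## Learning

A 3-deep FIFO watches the fused word stream; three identical consecutive
words (0.5 s at the 1/6 s sampling period) declare the word stable.
Stable table words are stored under their standard label (re-learning
overwrites); stable non-table words go to the lowest free adaptive slot
`New_1…New_8` of the subject's profile. A ninth distinct novel word is a
capacity error, deliberately loud — silently dropping a posture would
bias any downstream dwell statistics. The store holds at most eight
subjects and evicts the least-recently-used profile for a ninth;
"least recently used" is our reading of replacing unused subject data,
since no explicit policy is fixed by the hardware design we model.
Subject identity is an explicit caller-supplied id: the accelerator's
subject check is a data comparison, not a recognition mechanism, and
inventing biometric matching would be out of scope. A Hamming-distance
helper (`best_match_subject`) is provided and clearly labelled a
heuristic. Adaptive slots are kept per subject (the bound is then
per-person, which is the conservative reading of a per-subject profile
store).

## Adaptive timing

The evaluator is a debounced state machine over the per-frame labels. A
frame at time `t` covers `[t, t + period)`, so a confirmed segment ends
one period after its last frame — this endpoint convention is what makes
zero-noise durations exact instead of off by one sample. A new label
must persist `count_step1` consecutive samples to be confirmed; the
default of 3 samples (0.5 s) matches the learning FIFO depth, since
neither window is separately fixed by the modelled hardware. At
confirmation the old segment closes and a TRANSITION event records the
gap between old end and new start as TD. `UNKNOWN` frames extend the gap
and reset any candidate. With `count_step1 = 1` the evaluator degenerates
to edge detection.

Counters tick per sample, not per device clock: posture data arrive
every 1/6 s, so sample ticks keep durations meaningful in software.
`clock_ticks()` converts a duration to 100 MHz clock ticks for display
parity; the hardware's 8-bit counter saturation at 255 is intentionally
not reproduced (counters here are unbounded).

```{r}
ev <- evaluate_labels(c(rep("LY", 60), rep("UNKNOWN", 30), rep("RY", 60)))
ev[, c("kind", "label", "from", "to", "duration")]
```

The invariant to remember: segment durations plus transition TDs tile
the occupied span, up to one sample period per boundary (exact on the
uniform grid, as above).

## The simulator, and what it does not claim

`generate_stream()` samples a posture schedule every 1/6 s over the
half-open span of the schedule and emits per-channel distances: the
active posture's ideal distances plus i.i.d. Gaussian noise, sd 0.02 m
by default — a realistic centimetre-scale error for low-cost ultrasonic
rangers; no empirical noise characterisation exists for the modelled
rig, so a single additive Gaussian is the honest minimal choice.
Segments are half-open `[start, end)` so boundaries are never sampled
twice. `OFF_BED` reads bare bed with PIR 0; `UNDEFINED` (mid-roll,
limbs between sensors) emits the all-zeros pattern with PIR 1 — a
stand-in convention, since how a rolling body appears at the sensors is
not specified by any source we model. Supine's don't-care head bits are
emitted as 1: the head is physically present; it is the classifier's
mask, not the scene, that ignores it.

The simulator emulates exactly the statistical structure the pipeline
assumes: piecewise-constant postures, independent per-channel Gaussian
noise, a perfect PIR. It does not model acoustic physics (beam spread,
multipath), breathing or micro-motion, partial limb coverage, or
multi-subject beds. Passing tests therefore demonstrate the pipeline's
correctness over its assumed signal model — not field accuracy on real
sleepers.

## Numerical and scale choices

* Distance noise sd 0.02 m against a 0.10 m worst-case threshold margin
  puts per-channel bit-flip probability near `2e-7`; randomized
  schedule-recovery runs are expected to recover essentially every
  segment, and the acceptance bar (at least 29 of 30) leaves room for a
  tail event.
* Random scenarios snap segment durations to whole sample periods so
  ground-truth boundaries are unambiguous; durations default to 5–15 s,
  comfortably above the 0.5 s debounce.
* Scenario files round-trip at 17 significant digits so a written and
  re-read scenario regenerates a bit-identical stream.
* Test and acceptance runs use desk-scale problem sizes — 64-word
  exhaustive classifier checks, 10–30-segment simulated nights (up to
  ~2000 frames), 150–200-step randomized store workouts — chosen to
  exercise every code path while keeping the whole suite under a minute.
* Transitions whose gap is zero on the time grid can round a hair
  negative; TD is clamped at 0.

## Known limitations

* The early-exit mode maps *every* word to a standard label, including
  the all-zeros pattern (frog, via the legs-`00` exit); use strict mode
  when off-table words must surface as `UNKNOWN`.
* One side of a published description of the tree's side branches is
  internally inconsistent with the truth table it accompanies; this
  implementation treats the table as canonical and derives the tree from
  it, verifying equivalence exhaustively.
* Accuracy is always the exact quotient `100·correct/total` — 29 of 30
  is 96.67%, and no rounding convention can make it 98.4%.
* The profile store trusts caller-supplied subject ids; there is no
  cross-session biometric re-identification, forgetting, or decay.
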