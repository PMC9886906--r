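---
title: "Methods: a triangle model of reading with manipulated oral vocabulary"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a triangle model of reading with manipulated oral vocabulary}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Skilled readers differ in how much they lean on word meaning when reading
aloud — their *semantic reliance* (SR). `triread` implements a simulation
programme that asks whether the breadth (vocabulary size, OVS) and depth
(amount of exposure, OVE) of *spoken*-language knowledge acquired before
literacy can produce such individual differences. A recurrent connectionist
"triangle" network first learns the mappings between phonology and semantics
(oral phase), then — with those weights frozen — learns to read (map
orthography onto phonology and semantics). Varying (OVS, OVE) across
simulations and measuring each trained model's SR yields a simulated
individual-differences study that can be analysed with the same statistical
battery used for human readers.

## The network

Three key layers carry slot-based codes:

* **Orthography** — 14 letter slots of `alphabet_size` units; words are
  anchored with their first vowel on slot 5 (second vowel on slot 6),
  pre-vowel consonants right-aligned into slots 1–4, later consonants
  left-aligned after the vowel(s).
* **Phonology** — 8 phoneme slots of 25 binary phonological features; slots
  1–3 hold onset consonants right-aligned against the vowel slot (4), slots
  5–8 the coda. Empty slots are the all-zero null phoneme.
* **Semantics** — sparse binary features; the number of active features per
  word doubles as an imageability proxy.

Hidden layers mediate every route: one on orthography→phonology, two on the
deeper orthography→semantics route, one each on phonology→semantics and
semantics→phonology. Phonology and semantics each have a recurrent attractor
(cleanup) layer that learns to make word patterns stable states. Four context
units, clamped as inputs on comprehension trials, disambiguate homophone
meanings. All connections are complete layer-to-layer maps. Units are
logistic; time is discrete and updates synchronous: the net input at step
*t* is the weighted sum of step *t−1* activations plus a bias.

Trial schedules follow the two-phase regime. Oral mapping trials (PS
comprehension, SP production) clamp the input for eight steps and score the
target on steps 7–8; attractor trials (PP, SS) clamp a pattern for two steps
and require the free-running network to hold it over steps 3–8 (scoring all
six free steps; a config switch restricts this to the last two); reading
trials clamp orthography for twelve steps and score both phonological and
semantic targets on steps 7–12. The four oral tasks interleave at
40/40/10/10 per cent, words drawn frequency-weighted with replacement from
the `ovs` most frequent items. Reading draws from the whole lexicon and is
identical in every condition.

Design choices the architecture description leaves open, and how this
package resolves them:

* **Per-task subnetworks.** A PS trial engages the PS route plus the semantic
  attractor; SP the SP route plus the phonological attractor; PP/SS only the
  respective attractor loop; reading engages everything. This keeps each oral
  task's gradient confined to the machinery the task exercises, in the
  tradition of this model family.
* **Frozen set.** After the oral phase every oral-trained parameter (both
  mapping routes, both attractors, and the biases of their target layers) is
  frozen, so reading training is bit-identical in what it may change across
  oral conditions.
* **Targets are injected as error only** — output layers are never forced to
  the target during a trial. A clamp-style "forcing" variant would zero the
  scored error and was deliberately not implemented.
* **Context units** feed the PS route's hidden layer and are active (clamped)
  only on PS trials for homophone meanings.

## Training: objective and learning rate

Training minimises summed per-unit **cross-entropy** over the scored window
(switchable to summed squared error); *evaluation* always uses summed squared
error, the model's analogue of response latency. Gradients come from
backpropagation through time over the unrolled trial; they are verified in
the test suite against central finite differences (relative error below
10⁻³ on all five schedules).

Updates are plain online stochastic gradient descent, one word per trial, no
momentum or weight decay, the same learning rate in both phases. The default
learning rate is **0.005**. With the summed cross-entropy objective and this
package's layer sizes, a rate of 0.05 makes online learning oscillate (word
accuracy rises and collapses non-monotonically and comprehension stays near
chance), while 0.005 converges smoothly to ceiling reading-aloud accuracy;
the larger nominal rates quoted for full-scale simulations of this model
family interact with different loss scalings and layer counts. The rate is a
config parameter (`triangle_config(learning_rate = ...)`).

Other numerical choices: initial weights uniform on (−0.1, 0.1), biases
zero; non-input layers start trials at activation 0.5 (= logistic(0)), input
layers at 0 when unclamped; activations are clipped inside the cross-entropy
at 10⁻¹⁰; nearest-neighbour decoding breaks distance ties by lowest index
and flags them.

## The synthetic language

`language_spec()` fixes the study conditions; `build_language()` generates
monosyllables as onset + rime over a designated vowel/consonant split of the
alphabet, with one-to-one letter–phoneme correspondences. Controlled
structure:

* **Rime consistency.** A target fraction of words (default 20%) pronounce
  their rime irregularly (the rime's vowel phoneme replaced), always as a
  strict minority of their rime-spelling family. Exceptions are concentrated
  family-by-family so that a complement of fully consistent families remains
  — the bimodal structure natural orthographies show, and the basis for
  consistent/inconsistent nonword sets. Consistency is type-based:
  friends / (friends + enemies), the word itself included.
* **Frequency.** Zipfian over items (exponent 1), normalised; regressions use
  log(relative frequency × 10⁶ + 1). Vocabulary-size conditions take the
  `k` most frequent words.
* **Imageability proxy.** The per-word semantic feature count, drawn
  uniformly from a spec range (default 2–8 of 50 features). It is the only
  semantic-richness dial a synthetic lexicon offers; it is monotone in what
  imageability norms measure (richness of semantic representation) but
  carries none of their affective or sensory texture.
* **Homophones.** Twin items share spelling and phonology with disjoint
  meanings and distinct context indices (two of the four context units).
* **Neighbourhood.** Coltheart's N (same length, one substitution), computed
  exhaustively.

What the generator does *not* emulate: English phonotactics and
orthographic redundancy, morphology, multi-syllabic words, age-of-acquisition
structure, and realistic feature semantics. Tests passing on this language
show the machinery is correct and the qualitative dynamics are present; they
do not license quantitative claims about English-scale simulations.

## Semantic-reliance measures

* **EoCSR** (`eoc_sr()`): split items into imageability tertiles (ties to the
  lower tertile), keep the low tertile, drop misread words and errors more
  than 2 SD from the mean, regress phonological SSE on rime consistency with
  log frequency and neighbourhood size as controls, and reverse the sign of
  the consistency coefficient. By default all variables are z-scored
  (standardized partial coefficient); `standardize = FALSE` recovers a
  planted effect on its raw scale, which is how the parameter-recovery tests
  are phrased. One caveat the tests make explicit: the ±2 SD trim removes the
  extremes of the error distribution, and when a planted consistency effect
  contributes most of that distribution's spread the trim removes the
  effect's own tails, attenuating the recovered coefficient by roughly ten
  per cent; with trimming disabled the estimator is unbiased to Monte-Carlo
  precision.
* **DoLSR** (`dol_sr()`): for each probe word (default: the whole lexicon) a
  reading trial records, at the final time step, the mean absolute net input
  the phonology layer receives through the OP route's final connection and
  the semantics layer through the OS route's final connection; averaging over
  items and forming OS / (OS + OP) gives a ratio in (0, 1). It is invariant
  to rescaling both pathways and monotone in magnifying one.

## The statistical battery

Preprocessing drops misread items, rows with missing covariates and ±2 SD
outliers on the dependent variable, then z-scores the analysis columns; it
marks its output and is a no-op on already-processed tables. Mixed models are
fit with lme4 (random intercepts for item and model version only — no random
slopes), significance read as |t| > 1.96 with Wald intervals; nested models
are compared by the likelihood-ratio chi-square after ML refits. The
OVE × OVS interaction regressions z-score the main effects and the dependent
variable and use the *product of the z-scored mains* as the interaction term,
unscaled — re-scaling a product distorts the interaction.

The structural regression is fit by a small maximum-likelihood path-model
engine written in the package (`fit_path_model()`): it minimises the
normal-theory discrepancy between the model-implied and sample covariance,
takes standard errors from the numerical Hessian, and reports CFI, TLI and
RMSEA against the independence baseline with the conventional close-fit
cutoffs (0.95 / 0.95 / 0.06). A latent SR with a single indicator is not
identified, so the loading is fixed at 1 and the indicator residual at 0 —
equivalently SR is treated as observed — making the OVE/OVS/interaction →
SR → reading-error model (with direct paths) just-identified: CFI = 1,
TLI = 1, RMSEA = 0 by construction, which is also what the full-scale study
design implies. Equation-by-equation OLS serves as the independent oracle for
the path estimates in the tests.

## Problem sizes and what the desk-scale study shows

The default grid is a 300-word language, OVS ∈ {100, 200, 300},
OVE ∈ {20 000, 80 000}, two model versions, and 100 000 reading trials per
cell (identical across cells) — twelve simulations that run in roughly ten
minutes on one CPU. Reading trials were sized so that reading-aloud accuracy
plateaus near ceiling in every cell; oral exposures of 20K–80K trials leave
the oral mappings partially learned, which is the intended source of
variation (full-scale simulations likewise span a wide oral accuracy range).

At this scale the package reproduces, qualitatively: ceiling reading-aloud
accuracy with nonwords below words; negative frequency and consistency
effects on phonological error in the pooled mixed model; a significant joint
contribution of OVE and OVS; SR variation across simulations; lower SR under
heavy oral exposure; and, for the consistency-effect measure, higher SR when
a limited exposure is spread over a larger vocabulary.

Known limitations of the scaled-down regime:

* Written-word comprehension (the orthography→semantics mapping of arbitrary
  sparse codes) stays far below full-scale accuracy at these trial counts;
  the reading-aloud results do not depend on it.
* The division-of-labour measure's *vocabulary-size* direction at low
  exposure is scale-sensitive: with only 100–300 words, how much of the
  lexicon the oral phase covered dominates the OS pathway's training
  pressure, which can reverse the direction seen in full-scale grids. The
  exposure direction (more oral exposure → lower DoLSR) is robust here.
* Twelve simulations give the between-simulation analyses (correlation,
  interaction regression, structural model) little power; their estimates
  are reported with n = 12 and should be read as demonstrations of the
  pipeline, not precise effect sizes.
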