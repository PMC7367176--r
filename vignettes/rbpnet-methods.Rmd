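---
title: "Modeling protein–RNA binding with rbpnet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling protein–RNA binding with rbpnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The modeling problem

CLIP-style experiments yield a set of short RNA sequences an RBP was
cross-linked to in vivo. `rbpnet` casts binding-site modeling as binary
classification: bound sequences are class 1, and class 0 is a matched
background — either random same-gene genomic regions of identical widths or
scrambled copies of the bound set. The model must do three things at once:
classify, localize (a per-nucleotide binding profile), and compare (score
differences between a wild-type and a variant sequence). The architecture is
built so that all three are the *same* quantity read at different
granularities: the classification score is, by construction, the sigmoid of
the profile sum.

## Architecture and the contracts it maintains

**Encoding.** Sequences are one-hot encoded over v = (A, C, G, U) in that
fixed order. A batch is padded to a common real length (shorter sequences
extend on the right of the real region) plus a symmetric margin of
m_max − 1 all-zero columns, so the widest filter can run in full-convolution
mode. A 0/1 mask marks real bases. Ambiguity codes (N, R, Y, ...) survive
I/O and encode as all-zero columns with mask 1: because no layer before the
LSTM has a bias, an all-zero column contributes nothing, which treats an
unknown base as absence of evidence rather than as a fifth symbol.

**Convolution bank.** One filter per size in 4–8 (defaults), no biases,
rectifier activation, stride of one whole base. Initial weights are the
constant 0.01. The absence of biases is load-bearing: it guarantees that
placements lying entirely in padding score exactly 0, which the
padding-invariance contract below depends on.

**WTA enhancement and track reconstruction.** Per filter and sequence, the
single maximum placement score is doubled, then the vector is squared. Ties
for the maximum break to the lowest index; this keeps the transform
deterministic and order-stable, and the enhanced argmax always equals the
raw argmax. The enhanced vector is then written back onto the sequence as a
scaled one-hot "track". How enhanced values map to bases is genuinely open
(a placement of width m covers m bases); we assign to base j the score of
the placement *starting* at j, which is total (every real base starts a
placement, thanks to the margins) and keeps tracks aligned with the raw
sequence. The alternative — the maximum over all covering placements — is
available via `build_tracks(..., assign = "max_cover")` for sensitivity
analysis; nothing downstream depends on which rule is active.

**BLSTM.** Timestep t sees the concatenation of the five track columns and
the raw one-hot column (dimension 4 × 6 = 24). The standard LSTM gate
algebra is used in both directions with the backward outputs re-reversed;
row t of H is [h→_t ; h←_t]. Hidden size is not dictated by the
architecture; the default is 20 units per direction — small enough to train
on a laptop-scale CPU in minutes, large enough that the planted-motif
fixture saturates. Initial hidden and cell states are zero. All LSTM
parameters (including biases) initialize from N(0, 0.01²).

**Masked recurrence.** At mask-0 timesteps the recurrent state passes
through unchanged. This is what makes the model's outputs exactly invariant
to the amount of zero padding: with nonzero trained biases, a plain LSTM
would integrate padding steps and the profile would depend on how much
padding a batch happened to have. The invariance is asserted in the test
suite to 10⁻⁶ and holds to machine precision.

**Output.** Per-base profile values are row sums of H with padding rows
forced to zero; the score is sigmoid(1.0 × Σ values) through a single fixed,
bias-free node that is excluded from gradient updates. The fixed unit weight
pins the sign convention: positive profile values are evidence for class 1
at that base. `score = sigmoid(sum(profile))` is asserted for every
prediction path.

## Training procedure

Mean binary cross-entropy is minimized with ADAM (α = 2·10⁻⁴, β₁ = 0.9,
β₂ = 0.999, ε = 10⁻⁸). Dropout of 10% is applied elementwise to the entries
of H after the recurrence (recurrent connections are unaffected), with
inverted scaling so inference needs no correction. Batches of 64 are
re-shuffled every epoch from the run seed; the last partial batch is kept.
After each epoch the selection metric — validation AUROC by default,
validation loss as the alternative — is computed and the best checkpoint
retained (ties keep the earlier epoch). Early stopping halts training after
`patience` epochs without improvement; the default patience is 10% of
`max_epochs`, rounded up. Note the interaction for small epoch budgets: at
`max_epochs = 10` the default patience is 1, which stops aggressively;
fixtures that need every epoch should pass `patience = max_epochs`.
Training assumes roughly balanced classes (the background generators
produce exactly balanced sets); imbalance triggers a warning, not
reweighting.

All randomness — initialization, shuffling, dropout masks — flows from a
single integer seed, and training is bit-reproducible in the single-threaded
reference mode used throughout.

**Splits and cross-validation.** The 80/10/10 split is stratified per class
with floor(n/10) in validation and test. The 10-fold plan shuffles once,
bins into 10 near-equal parts, and in fold k uses bin k as test and bin
k+1 (mod 10) as validation, so every bin serves each role once and trains
eight times. The test/validation pairing is a free choice — only the
multiset of roles is determined — and the rotation used here is the simplest
deterministic one. Pooled CV performance concatenates the held-out test
predictions of all folds before a single AUROC computation, so every
sequence is predicted exactly once. AUROC itself is the Mann–Whitney rank
form with ties counting one half; the test suite cross-checks it against an
exhaustive pair count and against pROC.

## Background generation

Given peaks (BED) and gene spans (BED6), each peak is assigned the gene with
the largest overlap (ties to the first in annotation order) and a background
interval of identical width is drawn uniformly within that gene by rejection
sampling (default 1000 tries), subject to overlapping no positive peak and
no previously placed background. Peaks are processed in input order, which
makes placement feasibility order-dependent for crowded genes — a documented
property, not a bug; peaks with no legal placement are reported and skipped
with a warning rather than silently dropped. Placement ignores strand, but
the sequence is extracted on the peak's strand. Conditional on acceptance,
the placement distribution is uniform over legal starts; the acceptance
suite verifies this within 3σ over 2000 seeds on an enumerable single-peak
case. The scrambling alternative permutes each sequence's own residues
(exact mononucleotide preservation); a dinucleotide-preserving shuffle is
available behind a flag but off by default, since plain scrambling is the
reference behaviour.

## Motif extraction

Pseudo-PFMs summarize what the convolution bank has learned, restricted to
sequence regions the model associates with binding. From the `top_n = 1000`
highest-scoring sequences (or all sequences above a score threshold), every
placement with a positive *raw* (pre-WTA) rectified convolution score whose
covered bases all have strictly positive profile values contributes its
covered k-mer, weighted by the squared convolution score. Two readings of
the weighting were possible — per placement or per sequence-maximum; the
per-placement reading is used because the weight is attributed to the
convolutional layers themselves, and the squared-score weighting then makes
the counts scale-covariant: scaling all filter weights by λ scales counts by
λ² and leaves frequencies, information content and ranking unchanged (a
property test asserts this). Strictness at 0 in the profile condition is a
deliberate boundary choice: a base summing to exactly 0 is "either class"
and does not vouch for a placement. No pseudocounts are added; columns with
no weight render as uniform in exports but are flagged, and a filter with no
contributing placements yields an explicitly empty PFM rather than a
fabricated one. PFMs are ranked by mean per-column information content
(2 + Σ f log₂ f bits against a uniform background) and exported as MEME
minimal format plus a counts TSV.

## Applied prediction modes

**Variant scoring** runs both sequences independently and reports
Δ = score(mut) − score(wt) plus a per-base profile difference when lengths
match. Substitutions within m_max of an end trigger a warning: the filters
cannot center on edge positions, so edge effects make those comparisons
unreliable.

**Long-sequence profiling** slides a window (default: the model's training
maximum, forced odd by subtracting one; step 1) and takes the central
nucleotide's profile value from each window. The first and last
⌊window/2⌋ positions copy from the first and last full windows — no
reflection, no missing values, and no pretense that edge positions carry
window-centered estimates. Scores are not reported for stitched profiles:
the classifier is calibrated for window-sized inputs only, and comparing
scores across lengths is explicitly unsupported.

**Site calling** finds all 9-nt windows with mean profile value strictly
greater than 0.3 and merges qualifying windows whose coverage is contiguous
(overlapping or abutting) into maximal sites, reporting each site's mean
over its merged extent in 0-based half-open coordinates. The merge equals
the union of qualifying windows as position sets; an independent
enumeration oracle in the test suite asserts the equivalence on random
profiles. Note that with a low threshold a window need only partially
overlap a high-scoring region to qualify, so merged sites are typically
wider than the underlying element.

**Region aggregation** extracts sub-profiles anchored at exon boundaries
(defaults: first/last 25 exonic nt, 50 nt of each flanking intron) and
reports per-offset means with a normal-approximation 95% confidence band
(±1.96 s/√n). Profiles too short for a region are skipped with a warning.

## The synthetic generator: what it does and does not emulate

`simulate_clip()` plants one motif instance — sampled column-wise from a
user PFM — at a uniformly random offset in each positive (occurrence rate
1.0 by default), overwriting the background so lengths stay fixed, and
draws composition-matched negatives. The default study conditions used by
the acceptance checks are a 7-mer point-mass motif in 1000 + 1000 sequences
of 40 nt with uniform background composition; sizes were chosen so a full
train-and-extract cycle completes in well under a minute on one CPU while
leaving the task non-trivial (the motif occupies 17.5% of each positive).
The generator emulates the *statistical* structure of a CLIP training set —
planted signal at unknown positions against matched background — but none of
the protocol biases of real CLIP data: no uridine enrichment around
cross-link sites, no truncation artifacts, no peak-width heterogeneity, no
sequence composition differences between bound and unbound regions beyond
the motif itself. Passing the planted-motif recovery checks therefore
demonstrates that the estimator and extraction machinery work, not that any
particular biological dataset will reach the same numbers.

`simulate_toy_genome()` provides chromosomes with one gene each and
non-overlapping fixed-width peaks, sized so that the background sampler's
constraints are exercised (including infeasible cases) without search-space
explosions.

## Numerical choices and degenerate inputs

- WTA ties break to the first maximum; an all-zero score vector is a fixed
  point (doubling 0 is 0).
- ReLU subgradient at exactly 0 is taken as 0.
- Binary cross-entropy is clamped at 10⁻¹² for *logging*; gradients use the
  exact sigmoid/BCE cancellation (score − label), so no clamping enters
  optimization.
- The score/profile identity is asserted at 10⁻⁶ in tests, though the
  implementation satisfies it to machine precision; the looser bound leaves
  room for alternative BLAS summation orders.
- Frequency columns must sum to 1 within 10⁻⁹ before information content is
  computed; 0·log 0 is 0.
- Empty batches, single-class validation sets, sequences exceeding the
  configured maximum, filters wider than the padded sequence, profiles
  shorter than the calling window, and truncated model bundles all raise
  immediate, named errors rather than propagating silently.

## Problem sizes used in the shipped checks

Unit tests run the forward oracle on sequences ≤ 30 nt with hidden sizes
≤ 8; the gradient check compares analytic and central-difference gradients
on a 2-filter, 3-unit model. End-to-end checks train the default
1000 + 1000 fixture for at most 30 epochs (typically stopping near epoch
10–13) and smaller 150–300-sequence fixtures elsewhere; small fixtures use
a learning rate of 10⁻³ rather than the default 2·10⁻⁴ because they take
few ADAM steps per epoch. These sizes are the package's reference
conditions; all scale linearly in sequence count and length.

## Known limitations

- Scores are comparable only between sequences of the same length; the
  profile-sum output makes longer sequences integrate more terms.
- The model sees sequence only: no secondary structure, no conservation, no
  protein concentration effects.
- One filter per size caps motif diversity at five variants; RBPs with many
  distinct binding modes may need a wider bank (the size list is a
  configuration option, the one-per-size rule is not).
- Training is CPU-bound, single-threaded reference code; it is sized for
  peak-level datasets (10³–10⁵ sequences), not for millions of reads.
- The background sampler requires peaks to lie within annotated gene spans;
  intergenic peaks are skipped with a warning.
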