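---
title: "Methods: two-dimensional gathering thresholds for short-read domain annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-dimensional gathering thresholds for short-read domain annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The annotation problem

Metagenomic and metatranscriptomic reads carry protein fragments of
20–60 aa. Against a profile library, a true 30-aa fragment of a domain
scores a fraction of the full-length match, while scanning thousands of
models over millions of reads produces abundant small chance hits in the
same score range. A single per-domain bit-score cutoff calibrated on
full-length proteins therefore either drowns fragments or floods the
output with noise. `cladescan` addresses this with two ideas:

1. **A multi-source model library.** Each domain has one sequence
   consensus model (SCM) and any number of clade-centered models (CCMs),
   each CCM built from homologs of one taxonomic niche. Diverged niches
   that the global consensus under-represents remain detectable through
   their clade's model.
2. **A two-dimensional, per-domain acceptance region.** Each hit is a
   point (bit-score `b`, mean-bit-score `b/ℓ`) with `ℓ` the hit length.
   Short true fragments have small `b` but healthy `b/ℓ`; random matches
   have both small. A discrete naive-Bayes classifier trained per domain
   assigns each point a posterior probability of being a true positive;
   acceptance additionally requires `b` to exceed the smallest bit-score
   seen among the training negatives (the hardest negatives define the
   floor, because the retained negatives are deliberately the
   highest-scoring ones).

## Training data per domain

**Positives** are fragments of the domain's SEED sequences, emulating what
a read can contain. For a sequence of length `len`, prefixes and suffixes
are generated with lengths `n·L`, `n = 1..N`, where `N` is the smallest
integer with `M ≤ N·L`, `M = min(0.30·len, 100)` aa, and the step `L` is
1 aa (`len < 15`), 5 aa (`15 ≤ len ≤ 75`) or 10 aa (`len > 75`). For large
domains (`len > 270` aa) reads may fall in the middle, so ten internal
fragments are added: start positions uniform over the region not covered
by the terminal ladders, raw lengths Normal(mean 50, sd 25) rounded, with
a floor of 1 and clipped to the span remaining in the middle region.
`M` is kept fractional and `N = ceiling(M/L)`; internal fragments may
overlap one another (no disjointness is enforced — nothing in the fragment
model requires it). Every fragment is scanned against the domain's models;
the best hit per model class yields one `(b, b/ℓ)` instance. A fragment
with no hit contributes nothing for that class.

**Negatives** are decoys that a model nevertheless matches:

- the 2-mer shuffle of each SEED sequence (non-overlapping 2-mers in
  random order, an odd trailing residue kept last — the 2-mer multiset is
  preserved, so local dipeptide composition survives while long-range
  structure is destroyed) and its reversal;
- if those yield fewer than half as many negatives as there are
  positives, samples from an order-3 Markov chain fitted to the SEED:
  every amino-acid 4-tuple receives probability
  `((n + 1)·W) / (160000 + N·W)` with `n` its count, `N` the total count
  and `W ≥ 1` a weight. As printed, this expression sums to 1 only at
  `W = 1`; since a sampler needs a distribution we renormalise over the
  160,000-tuple space, which preserves all odds ratios. Sampling treats
  the model as a stationary chain — the first three residues from the
  marginal 3-prefix distribution of the emission, then next-residue
  conditionals. (A position-specific reading of the emission would need
  per-position counts the model does not define; the stationary reading is
  recorded here as the package's interpretation.)

A decoy becomes an **SCM negative** when the SCM's best hit has a positive
bit-score, and a **CCM negative** when some CCM identifies it confidently;
with an E-value-producing engine that criterion is `E < 1`, while the
built-in scanner (which has no E-value) uses a per-model surrogate: the
99th percentile of best bit-scores over 1,000 uniform-random sequences of
the model's consensus length, calibrated once per model under the session
seed. When several CCMs accept a decoy only the best-scoring instance is
kept, mirroring the one-hit-per-region logic of the selection filters.
`calibrate_markov_weight()` implements the weight search for small
families: starting at `W = 10` and incrementing by one until a batch of
10,000 decoys yields 1–10 SCM-accepted decoys (only the SCM is used for
calibration).

The planner (`plan_negative_generation()`) targets
`required = ceiling(0.5 · n_pos)` negatives; the shortfall after simple
decoys is the Markov `deficit`, and the theoretical decoy budget is
`deficit / fp_rate` with default acceptance rates 5 / 10,000 (SCM) and
5 / 1,000 (CCM), the midpoints of the 1–10 operating ranges. Because the
built-in scanner accepts decoys far more often than a full profile engine,
`build_training_set()` additionally caps generation at `max_decoys`
(default 2,000 per domain) and stops as soon as every model class has
reached its requirement, counting only distinct `(b, b/ℓ)` pairs since
duplicates are discarded later anyway. Retained negatives are
deduplicated on exact `(b, b/ℓ)`, sorted by Euclidean distance from the
origin (most significant first) and capped at the positive count;
positives are deduplicated the same way.

## The probability space

Both axes are discretised with Fayyad–Irani MDL (recursive entropy-based
splitting with the minimum-description-length stopping rule), matching the
Weka-style discrete naive-Bayes family; when MDL accepts no cut the axis
falls back to 20 equal-width bins over the observed range (no cuts at all
for a constant axis). Boundary bins are open-ended, so any query value is
binned. Per-bin class-conditional probabilities use Laplace smoothing with
`α = 1`; priors are empirical. One space is fitted per (domain, SCM) and
one per domain pooling all CCM instances — SCM and CCM bit-scores come
from different engines and are never compared directly. The space records
`min_neg_bit`, the smallest negative bit-score, as the acceptance floor.
Spaces serialise to a versioned JSON store (`save_spaces()` /
`load_spaces()`).

Two properties worth knowing. The posterior is *approximately* invariant
under duplicating the training set: with bins held fixed, doubling all
counts attenuates the `+1` smoothing term, and the MDL threshold
(≈ `log2(N−1)/N`) loosens with `N` so bins may refine; exact invariance
holds only with vanishing smoothing and frozen bins, and the test suite
checks exactly that decomposition. Second, on well-separated synthetic
score clouds the 0.5-posterior decision boundary recovers held-out labels
at ≥95% accuracy, and the smallest bit with posterior > 0.9 lies above
`min_neg_bit` — the two filter-2 criteria are mutually consistent.

## The search backend

The core consumes hits, not engines: HMMER3 `domtblout` (envelope
coordinates, per-domain score) and PSI-BLAST 12-column tabular output are
parsed into the common hit table, and a built-in PSSM scanner makes the
pipeline self-contained. `build_pssm()` estimates per-column probabilities
`(count + pc) / (n + 20·pc)` (default pseudocount 0.5) against a uniform
1/20 background and stores log-odds in bits; the consensus is the
per-column argmax (alphabetical tie-break). `scan_pssm()` scores every
ungapped placement with at least `min_overlap = 8` aligned columns
(overhangs allowed so terminal fragments score), keeps positive-scoring
placements that are local score maxima over adjacent offsets (leftmost on
plateaus), and then trims each reported hit to its maximal-scoring
contiguous column run — the ungapped analogue of a local-alignment
envelope. Trimming matters: a fragment embedded in unrelated sequence
would otherwise carry the whole placement's overlap as its length, halving
its mean-bit-score relative to the bare training fragments and breaking
the classifier's geometry. Read characters `X` and `*` score zero
(background) and are excluded from identity denominators; `min_overlap`
= 8 keeps chance terminal matches rare while letting the 10-aa ladder
fragments score. The placement loop and the Markov sampler are implemented
in C++ (Rcpp); an exhaustive double-loop oracle in the test suite pins the
scores.

## Hit selection

Per read, three filters (`selection_params()` holds the constants):

1. **Same-domain redundancy** (`overlap_frac = 0.85`): within each model
   class and domain, hits are visited by decreasing bit-score and dropped
   when the overlap covers ≥85% of *both* hit lengths against a retained
   hit. Ties break by longer hit, then model id — determinism matters
   because downstream steps are order-sensitive. Non-overlapping repeats
   of a domain survive. Pairwise greedy suppression was chosen over
   clustering; for the ≤5 hits a 60-aa read can carry the two coincide in
   practice and greedy is canonical.
2. **Probability** (`prob_threshold = 0.90`, variant 0.85): keep iff
   `b > min_neg_bit` (strict) and posterior > threshold (strict). Hits of
   domains with no fitted space are dropped with a counted warning.
3. **Ranking** (`shared_residues = 10`): ranking score = posterior ×
   identity/100; sort descending (ties by bit, then model id) and greedily
   discard hits sharing ≥10 read positions with a retained one; output by
   start coordinate. The `[0,1]` significance factor is the filter-2
   posterior — it is monotone in the score region and already computed;
   no separate significance map is defined by the procedure.

`combine_annotations()` implements the annotation-combination rule used to
merge a second tool's output: primary annotations verbatim, secondary ones
only for reads the primary left unannotated.

## Functional profiles and evaluation

`load_pfam2go()` parses the standard external2go text; each accepted hit
counts once in every GO class of its domain (optionally restricted to a
GO-Slim set; unmapped domains pool under `"unmapped"`). Within-sample
abundance divides by the dominant class count (ties: every maximal class
gets 1.0); cross-sample abundance N^S_I is count per megabase times the
mean sample size, so samples are compared as if equally sized. Rescaling
of profile tables to [0,1] for display is left to the caller.
`evaluate_annotations()` matches at read level (a predicted domain matches
an unmatched truth hit of the same domain on the same read; coordinates
are ignored, mirroring read-level gold standards; each truth hit matches
once), with an optional clan map under which same-clan predictions count
as true positives; F = 2TP/(2TP+FP+FN). GO-DAG traversal and tree
rendering are out of scope — only flat term counting is provided.

## The synthetic study

The generator emulates the study conditions end to end. A family is a
uniform-random consensus with a SEED of homologs at substitution rate
0.10 — typical within-family SEED divergence — plus clade variants drifted
at 0.35 (well past the point where a consensus model loses the niche) each
spawning a tight sub-SEED at 0.05. The SCM is built from the
consensus-level SEED rows only, and one CCM per clade from its sub-SEED:
folding the clade rows into the SCM would let the consensus model
co-represent every niche and erase precisely the effect the multi-source
strategy targets. Sub-SEED size equals SEED size (8 rows each) so
pseudocount smoothing weighs equally on both model kinds. Training SEEDs,
in contrast, pool all homologs (consensus rows plus clade sub-rows), as a
curated family alignment would.

The default fixture is 20 families of length 80–300 aa with 3 clades,
and 2,000 reads of 60 aa (the ORF length of reads in the 180-bp regime);
half the reads carry a planted fragment of 20–50 aa — from a clade variant
with probability 0.5, otherwise from the consensus — with 2% substitution
noise, embedded in uniform-random background (uniform matches the
scanner's background model, so bit-scores are calibrated). On this
fixture, under a fixed seed, the pipeline reaches read-level recall ≥0.80
and precision ≥0.90, and among recovered clade-variant plantings the best
accepted hit is the planted clade's own CCM in ≥80% of cases. What this
does *not* show: robustness to sequencing-error models of specific
platforms, to compositional (non-uniform) background, to gapped
divergence, or to the hit-density regime of a multi-million-model library
— real SEEDs are also not i.i.d.-mutation stars around a consensus. The
test sizes (20 families / 2,000 reads; 1,000 calibration sequences and
≤2,000 Markov decoys per domain) are the package's chosen study scale;
every stage accepts larger inputs unchanged.

Whole frames containing `*` are annotated as-is rather than split into
sub-ORFs; stops score as background, so they depress rather than forbid a
placement. This is a deliberate neutral choice — splitting is an ORF-calling
policy that belongs upstream.

## Known limitations

- The built-in scanner is ungapped; indel-diverged fragments lose score
  linearly. Use an external engine's files for gapped sensitivity.
- No E-values are computed internally; E-values from external engines are
  carried as metadata only, and all selection logic runs on
  (bit, mean-bit).
- The CCM decoy-acceptance surrogate (99th-percentile random-score cut) is
  calibrated per model and seed-dependent at the ±0.5-bit level.
- `fit_space()` needs both classes; domains whose decoys never match
  (or whose fragments never score) are reported as unlearnable rather
  than silently passed (`skip_failures` downgrades this to a warning).
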