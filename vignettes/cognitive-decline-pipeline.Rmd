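---
title: "Detecting cognitive decline in clinical note sections: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cognitive decline in clinical note sections: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cognote)
```

## The problem

Early signs of cognitive decline — from subjective complaints through mild
cognitive impairment (MCI) to dementia — are often documented in free-text
clinical notes years before a formal diagnosis is coded. `cognote`
implements a complete pipeline for classifying *note sections* (the unit of
annotation and prediction) as documenting cognitive decline or not, and for
studying how three very different classifier families err:

1. an LLM classifier driven by engineered prompts (with a deterministic
   scripted backend as the default test double),
2. gradient-boosted trees on TF-IDF term features,
3. a compact attention network (embedding, 1-D convolution, bidirectional
   recurrence, additive attention pooling, sigmoid output),

combined by a majority vote and evaluated with bootstrap confidence
intervals, paired comparisons, keyword-importance extraction and a
three-set error-overlap decomposition.

A section counts as positive when it documents cognitive concerns, symptoms
(e.g. memory loss), diagnoses (e.g. MCI, Alzheimer's disease dementia),
cognitive assessments (e.g. Mini-Cog, MoCA) or cognition-directed
therapies. It counts as negative when the mention is improving, transient
(e.g. forgetfulness attributed to codeine), reversible (e.g. confusion
shortly after surgery), negated, or too vague to support a judgment. These
"hard negatives" are the scientifically interesting failure mode: they
contain the same vocabulary as positives.

## Why synthetic corpora, and what they do and do not emulate

Clinical notes of this kind cannot be shared, so the pipeline ships a
generator whose outputs have the statistical shape of the original
corpora:

* **Development corpus analogue** (`dev_corpus_config()`): 4,949 sections,
  29.4% positive, mean length 850 characters in [26, 9323]. Because such a
  corpus is assembled by expert-keyword screening, *every* negative carries
  a cognition keyword; the generator realises this with
  `hard_negative_share = 1`.
* **Test corpus analogue** (`test_corpus_config()`): 1,996 sections, 3.5%
  positive, mean length 464 characters in [26, 14740], unscreened, so only
  a small share (0.05) of negatives are hard negatives.

Section lengths follow a log-normal clamped to the configured bounds; the
log-normal was chosen because the reported ranges exceed the means many
fold, implying strong right skew. With `length_log_sd = 1`, the meanlog
that hits a target mean `m` is `log(m) - 0.5`; upper clamping shifts the
realised mean only a few characters. Patients receive geometrically
distributed numbers of consecutive sections (mean 2.5, matching a corpus
of roughly 4,949 sections over 1,969 patients). Labels are generated, not
annotated; an optional `label_flip_rate` (default 0) can emulate
annotation noise.

Texts are composed from three phrase pools (`default_phrase_bank()`):
positive cues in five categories (concern, symptom, diagnosis, assessment,
therapy), hard-negative cues in five categories (improvement, transient,
reversible, negated, uncertain), and neutral filler sentences. Two
construction invariants make the keyword screen exactly analysable: every
cue phrase, positive or hard-negative, contains at least one expert
keyword, and no filler sentence contains any. Consequently the screen
retains every positive, retains exactly the hard-negative share of
negatives, and its behaviour can be asserted exactly in tests.

What the generator does **not** emulate: real clinical syntax, negation
scope beyond fixed cue phrases, misspellings, section headers, topic
drift, or label ambiguity. Passing tests on these corpora demonstrate that
the *machinery* is correct and that the study's quantitative accounting
holds under its stated conditions; they do not certify performance on real
notes. In particular, the boosted trees can reach near-perfect scores here
because the phrase pools are finite — on real notes they plainly would
not.

## Keyword screening

The shipped lexicon (`read_lexicon()`) carries four sources: the 36
expert-curated screening terms, and the keyword lists attributed to the
boosted-trees, attention-network and LLM channels of a combined keyword
table. Matching is case-insensitive over word tokens (split on any
non-alphanumeric character; lengths are Unicode code points). Patterns
with a trailing hyphen (`cognit-`) are stems matching any token prefix;
all other patterns match whole tokens only, so `memory` does not match
"memorial". Whether bare terms like `alter` were meant as stems is
unknowable from a printed table; whole-word is the default and stems are
opt-in via the trailing hyphen. Multiword patterns match consecutive token
runs.

## Prompting machinery

A prompt template has a required task description and optional guidance,
few-shot and error-instruction blocks; `assemble_prompt()` renders them in
a fixed order with labelled headers, always appending a response-format
block that requests (a) the cognitive-decline judgment, (b) the supporting
keywords and (c) JSON output. `parse_response()` maps any response into
exactly one of three effectiveness categories: *effective and parseable*
(first balanced JSON object with a recognisable judgment field — yes/no,
true/false, 1/0, case-insensitive — and a keyword field), *effective but
not parseable* (free text that still answers both questions), and *not
effective*. The effective response rate counts the first two categories by
default (configurable), since both answer the questions asked.

Sections whose verdict is not parseable are retried once verbatim (at
temperature 0 the retry is idempotent for a deterministic backend, but the
contract allows stochastic remote backends) and then scored as negative
with a logged flag; how unparseable responses should enter the metrics is
undefined in general, and defaulting to negative on a 3.5%-positive
corpus is the conservative choice.

### The scripted backend

`scripted_backend()` is a deterministic test double for a remote LLM. Its
base judgment is a cue heuristic — positive iff the section matches a
screening keyword, overridden to negative when a hard-negative cue is
detected — which is *exact by construction* on generated corpora. Error
profiles are then imposed by seeded label flips: a global
`flip_rate_overall` plus per-category overrides on sections carrying
specific hard-negative cues. All draws are keyed by (seed, section id), so
identical prompts always produce identical responses, and differently
seeded backends err (conditionally) independently — which is what makes
the majority-vote arithmetic checkable against closed-form expectations.
`format_break_rate` and `mute_rate` emulate format-breaking and refusal
responses.

Two behaviours are worth stating plainly. First, if the prompt's
error-instruction block names a hard-negative category, the backend
disables that category's flip — a mechanistic stand-in for an LLM that
stops making an error it was explicitly warned about; this is what makes
the error-instruction stage improve accuracy strictly, mirroring the
qualitative finding that error-analysis-based instructions outperform
other prompt improvements. Second, the backend judges only the target
section, so few-shot example selection cannot change its output; the
four selection strategies are exercised end-to-end, but their accuracies
coincide on the scripted backend by design. A live-API backend would
implement the same `llm_complete()` contract; none is included, and the
test suite never performs network calls.

## Few-shot example selection

Four strategies over a pluggable embedding space, all returning exactly
`k = 5` examples (five examples being the standard compromise against
prompt-length limits): uniform random; targeted (previously misclassified
pool sections, padded with random correct ones); k-means cluster centers
(seeded `stats::kmeans`, 10 restarts, 300-iteration cap, returning each
cluster's member nearest its centroid, ties to the lowest index); and
dynamic kNN retrieval (per-query top-5 by cosine similarity, ties to the
lowest pool index). The default embedding provider is L2-normalised TF-IDF
unigram vectors fitted on the pool — deterministic, local, and preserving
the lexical-similarity geometry the strategies need; a live embedding API
could be slotted in behind the same `embed()` contract. Degenerate cases
are defined rather than left to chance: identical embeddings trigger a
degenerate-clustering warning, zero vectors get similarity 0 with a
warning, and `k` equal to the pool size returns the whole pool.

## Baselines

**Boosted trees.** TF-IDF unigrams (document-frequency floor 2,
lexicographic vocabulary, smoothed idf `log((1+N)/(1+df)) + 1`, rows
L2-normalised) feed `xgboost` with a small grid — trees {50, 200} × depth
{3, 6} × learning rate {0.1, 0.3} — selected by mean 5-fold
cross-validated F1 at the 0.5 cutoff and refit on all data. Per-feature
total split gain over the *full* vocabulary (zero for unused features) is
recorded for interpretation; keeping the zero-gain features in the
distribution matters, because the mean+2SD rule cannot select anything
from a vector of fewer than about six values.

**Attention network.** Four learned stages: token embedding (32), 1-D
convolution (64 filters, kernel 3, same padding, ReLU), a bidirectional
tanh recurrence (32 per direction), and additive attention pooling into a
sigmoid unit. Forward and backward passes are implemented directly in R,
vectorised over padded minibatches with masking in both recurrence
directions, trained with Adam on binary cross-entropy; the gradients are
verified against central finite differences in the test suite. One design
choice deserves emphasis: the additive attention scorer sees both the
recurrent state and the *local convolution feature* at each position.
With a purely recurrent scorer the attention location is
under-identified — the bidirectional summary lets the net pool anywhere
(typically sequence-final tokens) while still classifying perfectly — and
the within-section attention-interpretation rule then highlights arbitrary
anchors. Conditioning the scorer on the local feature makes attention
concentrate on locally informative tokens, which is what an
attention-based keyword report presupposes. Scores above the 0.5 cutoff
are positive; a score of exactly 0.5 is negative (the cutoff is standard,
the tie direction is a declared choice).

Training sizes are deliberately desk-scale: the default experiment trains
the net for 3 epochs at a 128-token truncation on the 4,949-section
corpus, and the test suite uses 500-section fixtures at a 32-token
truncation; at these sizes the full pipeline runs in about three minutes
and the suite in about two on one CPU core.

## Ensemble

`majority_vote()` assigns cognitive decline iff at least two of the three
models do. It generalises to any odd number of models; even counts are
rejected because no tie rule is defined anywhere in the method. Under
conditionally independent per-model error rates `e`, the ensemble error
rate is `3e²(1−e) + e³` — with `e = 0.1`, 0.028 — and the ensemble errs on
a section exactly when at least two models err there; both facts are
asserted against simulation in the acceptance suite. The practical import:
diversity, not individual strength, is what the vote converts into
precision.

## Evaluation

Six confusion-matrix metrics: precision (PPV), recall (sensitivity), F1,
specificity, NPV and accuracy. Zero-denominator metrics are reported as
undefined (`NA`), never silently zero. Percentile bootstrap intervals
(default `B = 1000`, level 0.95) resample sections with replacement;
replicates with undefined metrics are dropped per metric with a logged
count. The percentile method was chosen over BCa for transparency, and
`B = 1000` is a declared default. The resampling unit is the section,
mirroring a section-level evaluation; a `unit = "patient"` flag resamples
whole patients instead, because section-level resampling understates
variance when sections within a patient are correlated. Paired model
comparison applies the *same* resample indices to both models and runs a
paired t-test on replicate-wise metric differences; all-zero differences
give p = 1 by convention. Monte-Carlo calibration (500 simulated datasets,
n = 500, construction-true precision 0.8) puts the interval's coverage
within 3 points of nominal 95%.

## Keyword interpretation: the mean+2SD rule

All three channels reduce to one primitive, `mean2sd_select()`: select the
items whose value strictly exceeds the mean plus twice the sample (n−1)
standard deviation of the whole vector. The SD estimator and the strict
inequality are declared choices; the rule is scale-invariant, selects
nothing from constant vectors, and cannot select from vectors shorter
than about six items (the maximum z-score of n values is `(n−1)/√n`).

* **LLM channel**: case-folded, whitespace-trimmed citation counts across
  parseable verdicts (multiword keywords kept intact).
* **Attention channel**: within each section, tokens whose attention
  weight exceeds that section's mean + 2SD; aggregated by counting the
  sections in which a token was selected, flagged at a count floor of 2.
  The within-section rule is the method's; the cross-section aggregation
  (count of sections, floor 2) is this package's declared construction,
  since some aggregation is needed to turn per-section selections into a
  corpus-level list.
* **Gain channel**: mean+2SD over total split gain across the full
  vocabulary.

The merged report places model-selected keywords alongside the expert
lexicon (expert rows always present, with no importance value), sorted by
source then keyword, rendered as a four-row table.

## Error-overlap accounting

Per-model error sets (prediction ≠ gold, both classes) feed a three-set
Venn decomposition. Pairwise overlap counts are stored *inclusive* of the
triple overlap: with per-model counts (31, 23, 22), pairwise (4, 3, 8) and
triple 2, inclusion–exclusion `a+b+c−ab−ac−bc+abc` yields the published
union of 63 only under the inclusive reading, so it is adopted; the
alternative exclusive reading is arithmetically inconsistent with that
union and is documented rather than resolved. The mutual-error fraction is
`100·abc/union`, rounded half-up to one decimal (so 2/63 prints as 3.2).
Count invariants (`abc ≤ min(ab, ac, bc)`, `ab ≤ min(a, b)`, …) are
validated on construction.

## Orchestration

`run_experiment()` executes the four-part workflow — generate and screen,
select template and backend (effective response rate on a 10-section
tuning sample, then accuracy on the 200-section selection subset), compare
few-shot strategies, add error-analysis-based instructions, train the
baselines, classify the test corpus with all three models, ensemble,
evaluate with CIs and paired tests, extract keywords, and decompose error
overlap — writing every artefact plus a manifest (config hash, stage
seeds, package version) so every reported number is recomputable from the
config alone. Stage seeds are derived deterministically from one global
seed. By default patient ids are generated independently per corpus, so
the same id can appear in both the development and test analogues,
mirroring a section-level (not patient-level) split; `patient_split =
TRUE` prefixes the id spaces to make them disjoint. The numbered scripts
under `analysis/` run the same stages as a readable narrative and leave
their tables under `results/analysis/`.

## Known limitations

* The synthetic corpora are lexically easy; term-based models can saturate
  on them, so absolute performance numbers say nothing about real notes —
  only the relational claims (ensemble arithmetic, error-profile
  diversity, calibration, interpretability of a planted signal) transfer.
* The scripted backend's insensitivity to few-shot examples makes the
  strategy comparison an exercise of machinery, not a measurement.
* Attention weights are an imperfect explanation device; even with the
  conv-aware scorer, localisation on the discriminative token is the
  typical outcome, not a guarantee, at every seed.
* The hand-rolled recurrent layer uses a simple tanh recurrence rather
  than LSTM gating; at the section lengths used here the difference is
  immaterial for classification, and the composition of the four stages
  is what the architecture specifies.
* Sections are treated as exchangeable; there is no longitudinal
  modelling of a patient's trajectory, and reversible-versus-progressive
  distinctions rest entirely on within-section cues.
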