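# cognote

Detecting signs of cognitive decline in clinical note sections, and
studying *how differently* three classifier families fail at it.

## The problem

Early cognitive decline — from subjective complaints through mild
cognitive impairment (MCI) to dementia — surfaces in free-text clinical
notes long before it is coded. Classifying note sections for such signs is
a binary text-classification problem with two awkward features: positives
are rare in unscreened notes (a few percent), and the hardest negatives
use the *same vocabulary* as positives ("memory has improved markedly",
"temporary forgetfulness due to codeine", "no evidence of memory loss").

`cognote` is for NLP methodologists and clinical informaticians who want a
fully testable, self-contained implementation of this pipeline:

- a calibrated **synthetic note-corpus generator** (positive cues in five
  clinical categories, keyword-bearing hard negatives in five more,
  keyword-free filler; log-normal lengths; patient grouping), because the
  real notes cannot be shared;
- an **expert-keyword section screen** (stems like `cognit-`, whole-word
  terms like `moca`);
- prompt assembly, JSON response parsing and a deterministic **scripted
  LLM backend** with configurable error profiles;
- four **five-shot example-selection** strategies (random, targeted,
  k-means centers, dynamic kNN retrieval) over pluggable embeddings;
- two locally trained baselines: **gradient-boosted trees** on TF-IDF
  terms and a compact **attention network** (embedding → 1-D conv →
  bidirectional recurrence → additive attention → sigmoid), hand-built
  with verified gradients;
- a **majority-vote ensemble**: the final label is cognitive decline iff
  at least two of the three models say so;
- **evaluation**: precision/PPV = TP/(TP+FP), recall/sensitivity =
  TP/(TP+FN), F1 = 2PR/(P+R), specificity = TN/(TN+FP), NPV = TN/(TN+FN),
  accuracy = (TP+TN)/N, with percentile bootstrap CIs and paired t-tests
  on shared bootstrap replicates;
- **interpretation** by the mean+2SD rule — a keyword is reported when its
  importance (LLM citation count, within-section attention weight, or
  split gain) exceeds the distribution mean plus two standard deviations;
- **error-overlap accounting**: three-set Venn decomposition with
  inclusion–exclusion, `union = a+b+c−ab−ac−bc+abc`, and the mutual-error
  fraction `100·abc/union`.

The scientific point the package makes checkable: three models with
*diverse* error profiles and conditionally independent error rates `e`
combine, under majority vote, to an error rate of `3e²(1−e)+e³` — at
`e = 0.1`, 0.028 — so the vote converts diversity into precision.

## Worked example

Three scripted models with different error profiles classify an
unscreened 600-section corpus (3.5% positive); the majority vote is
evaluated against each:

```r
library(cognote)
lexicon <- read_lexicon()
bank <- default_phrase_bank(lexicon)
corpus <- generate_corpus(test_corpus_config(seed = 1, n_sections = 600L), bank)

models <- list(
  scripted_backend(lexicon, bank, flip_rate_overall = 0.05,
                   per_category_flip = list(negated = 0.5), seed = 11, name = "llm"),
  scripted_backend(lexicon, bank, flip_rate_overall = 0.06,
                   per_category_flip = list(transient = 0.5), seed = 22, name = "trees-analog"),
  scripted_backend(lexicon, bank, flip_rate_overall = 0.06,
                   per_category_flip = list(improvement = 0.5), seed = 33, name = "net-analog"))
template <- default_template_registry()$t1
preds <- lapply(models, function(m) classify_sections(m, template, corpus)$predictions)
ens <- majority_vote(preds)

reports <- c(lapply(preds, bootstrap_cis, gold = corpus, B = 1000, seed = 7),
             list(bootstrap_cis(ens, corpus, B = 1000, seed = 7)))
names(reports) <- c("llm", "trees-analog", "net-analog", "ensemble")
cat(format_metrics_table(reports), sep = "\n")
```

```
model             precision     recall         f1  specificity        npv   accuracy
llm                   36.7%      94.7%      52.9%        94.7%      99.8%      94.7%
trees-analog          30.2%     100.0%      46.3%        92.4%     100.0%      92.7%
net-analog            31.0%      94.7%      46.8%        93.1%      99.8%      93.2%
ensemble              65.5%     100.0%      79.2%        98.3%     100.0%      98.3%
```

Each individual model floods the rare positive class with false positives
(precision 30–37%); the vote removes most of them (precision 65.5%, F1
from ≤53% to 79%) without losing recall. The error sets explain why:

```r
counts <- overlap_counts(error_sets(preds, corpus))
counts
#> errors: llm=32, trees-analog=44, net-analog=41
#> pairwise (incl. triple): ab=4, ac=4, bc=2; triple=0
#> union (missed by >=1 model): 107
mutual_error_fraction(counts)
#> [1] 0
```

107 sections are missed by at least one model, but not a single one by all
three — the error profiles are almost disjoint, which is exactly the
condition under which the majority vote helps.

## The analysis workflow

The numbered scripts under `analysis/` run the full study narrative on the
synthetic analogues (development corpus: 4,949 sections, 29.4% positive;
test corpus: 1,996 sections, 3.5% positive), writing tables under
`results/analysis/`:

```sh
Rscript analysis/01_simulate.R           # corpora + dataset characteristics
Rscript analysis/02_prompting.R          # template/backend selection, five-shot, error instructions
Rscript analysis/03_baselines.R          # grid-search CV trees + attention net
Rscript analysis/04_evaluate_ensemble.R  # three models, majority vote, CIs, paired tests
Rscript analysis/05_interpret_keywords.R # mean+2SD keyword report
Rscript analysis/06_error_overlap.R      # Venn decomposition + figure
```

The same stages run as one seeded, manifest-writing call via
`run_experiment(experiment_config(seed = 1), "results/run")`. The methods
vignette (`vignettes/cognitive-decline-pipeline.Rmd`) documents the model,
every tunable default, and what the synthetic corpora do and do not show.

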