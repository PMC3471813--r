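---
title: "Literature profiling for gene functional classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Literature profiling for gene functional classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genelit)
```

## The problem and the model

`genelit` treats gene functional annotation as supervised text
classification. The object being classified is not an abstract but a
*gene*, summarized by its literature profile: the vector of
document-presence frequencies of stemmed terms over the gene's MEDLINE
corpus. Genes of one functional category (in the sense of the JCVI
Comprehensive Microbial Resource ontology — *Energy metabolism*,
*Protein fate*, and so on) tend to share a characteristic vocabulary in
their literature, and the classifier learns that vocabulary signature.

The pipeline has five stages, each exposed as package functions and as a
CLI subcommand:

1. **Corpus acquisition** (`fetch_abstracts`): genes with fewer than 5
   abstracts are ineligible; otherwise the 50 most recent abstracts are
   kept. "Most recent" is resolved by publication date descending with
   ties broken by descending PMID — recency is the natural primary key,
   and PMIDs are assigned roughly chronologically, so the tie-break is
   both deterministic and semantically consistent.
2. **Profiling** (`term_frequencies`, `baseline_profile`): presence
   frequencies per stemmed term. Presence (not multiplicity) within an
   abstract is forced by the frequency definition: the fraction *of
   abstracts* containing the term.
3. **Vocabulary disclosure** (`disclose_vocabulary`): the two filters
   described below.
4. **Redundancy reduction** (`reduce_redundancy`): average-linkage
   clustering at Pearson `r >= 0.99`, one random representative per
   cluster. In the full protocol the reduced gene list is profiled and
   disclosed *again*, so the final vocabulary is not biased by clusters
   of near-identical genes; the CLI is ordered so `dedupe` can feed a
   second `vocab` run.
5. **Classification and evaluation** (`train_classifier`,
   `predict_genes`, `replicated_holdout`).

## Tokenization and stemming

The tokenizer lower-cases text and takes maximal runs of ASCII letters:
digits, hyphens and all punctuation split tokens, and fragments shorter
than 3 characters (`min_token_len`) are dropped. This is the simplest
fully reproducible rule; it deliberately destroys entities like "p53"
(which becomes nothing) rather than inventing a partial normalization
scheme for alphanumeric identifiers. A compact English stopword list is
applied before stemming; it is configurable and can be emptied, because
the baseline promiscuity filter already removes most function words —
the list only reduces noise in very small baselines. Stemming is the
original Porter algorithm (implemented in `porter_stem()`, verified
against the canonical example words); it collapses morphological
families ("transcription", "transcriptional" → "transcript") so that
frequencies aggregate over word forms.

## The two disclosure filters

A term `w` survives into the minimum informative vocabulary iff:

* **(a)** its baseline frequency `B(w)` is at most `baseline_cutoff`
  (default 0.05). The baseline corpus is a pooled abstract set retrieved
  for a generic gene-symbol collection; terms common there ("protein",
  "expression", "gene") describe gene literature in general, not any
  category.
* **(b)** `F_g(w) − B(w) > t + k/n_g` in at least `min_genes` genes
  (defaults `t = 0.15`, `k = 1.5`, `min_genes = 2`), where `n_g` is gene
  `g`'s abstract count.

Three design points deserve justification:

* **Direction of the cut-off rule.** Read literally in isolation, one
  could take the optimized cut-off as an *exclusion* rule (drop terms
  whose excess over baseline is large). That reading would discard
  exactly the category-informative terms and retain noise, leaving the
  classifier nothing to learn from; it also contradicts the stated goal
  of a minimum *informative* vocabulary and the literature-profiling
  tradition this method descends from, where the threshold selects
  highly expressed markers. `genelit` therefore **retains** terms whose
  excess exceeds the cut-off in at least `min_genes` genes.
* **Per-gene comparison.** The excess `F_g(w) − B(w)` is evaluated per
  gene, not on pooled experimental frequencies, because the cut-off
  itself depends on the per-gene abstract count `n_g`; a pooled
  comparison would have no meaningful `n`.
* **`min_genes = 2` as the "gene-specific" filter.** A term that passes
  the cut-off in a single gene is, by construction, unusable for
  generalizing to a category (it may be that gene's own name or strain
  identifier). Setting `min_genes = 1` recovers the laxest reading and
  is supported but not default.

The baseline is pooled over all baseline abstracts rather than averaged
per baseline gene: the baseline is a single reference corpus, and
pooling keeps `B(w)` an honest document frequency with a single sample
size. Both filters are anti-monotone in their parameters (shrinking
`baseline_cutoff` or raising `min_genes` can only remove terms), which
the test suite checks property-style.

## Redundancy reduction

Pearson correlation is computed on the dense projected rows (zeros
included). Zero-variance rows — genes whose projection is constant,
typically all-zero because their literature shares nothing with the
vocabulary — have undefined correlation; they are quarantined as
singleton clusters with a warning rather than dropped or crashed on.
The dendrogram cut at height `1 − r_min` makes the partition independent
of the representative draw: the seed affects only which member
represents each cluster, never the clustering itself.

## The classifier and its confidence

The SVM uses an RBF kernel, one-vs-one decomposition, `cost = 1` and
`gamma = 1/(n_features · var(features))` by default — the standard
defaults in the absence of a tuning protocol; a seeded grid search can
be layered on top by the user within a training split. Class
probabilities come from Platt-scaled pairwise coupling (as implemented
in libsvm via `e1071`), and the confidence of a prediction is the
posterior probability of the arg-max category. This choice reproduces
the intended threshold semantics: confidences live on a `[0, 1]` scale,
per-row posteriors sum to 1, an uninformative all-zero row on a
balanced model scores near `1/K`, and raising the threshold can only
shrink the assigned set. Probability calibration in libsvm involves an
internal cross-validation shuffle; `train_classifier` seeds it
explicitly, which makes training bit-reproducible — the determinism
contract the evaluation protocol relies on. Class weights are off by
default (the training protocol preserves the source repository's
category proportions, so reweighting would distort the operating
point); a `class_weights` argument exists for skewed use cases.

Known imbalance context: in the reference training composition the
category shares range from 1.33% to 21.01% (see
`inst/extdata/category_distribution.tsv`), and a paired t-test between
the source and training distributions is the package's check that a
training subset preserves composition
(`compare_category_distributions`, degenerate identical inputs report
`p = 1` with a flag instead of erroring).

## Evaluation protocol

`replicated_holdout` implements seeded Monte-Carlo validation: each
replicate shuffles the dataset, holds out 10%, trains on 90% and scores
the precision/recall curve on the holdout; means and SDs are reported
per confidence threshold. The protocol description this follows calls
itself 10-fold cross-validation but specifies independent 90/10
shuffles per replicate; the shuffle description is operational, so
Monte-Carlo splitting is the default and a true `k`-fold partition mode
ships behind `mode = "kfold"`. A replicate whose training split loses an
entire category is redrawn (and logged) — with 100 replicates and small
categories this is a real event, and silently training on fewer
categories would corrupt the curve. Precision with zero assigned genes
is reported as missing (`NA`), never 0 or 1. Micro-averaging is the
default (one pooled number per threshold); macro-averaging is available
for category-balance-sensitive analyses. Thresholds are inclusive
(`>=`) everywhere.

Summary reporting convention: `summarize_corpus` prints mean
abstracts-per-gene truncated (not rounded) to one decimal, matching the
convention of the repository summary tables it mirrors; the exact value
is returned alongside.

## The synthetic generator

`generate_synthetic_corpus` emulates the statistical skeleton of real
per-gene corpora: per-category disjoint signature terms appearing in
each member gene's abstracts with probability `p_sig`, shared
background terms appearing anywhere with probability `p_bg`, filler
words present in every abstract (so the promiscuity filter has real
work to do), and abstracts-per-gene drawn uniformly from `[5, 50]` —
the eligibility window of the real retrieval step. The defaults (5
categories × 30 genes, 10 signature terms per category, `p_sig = 0.7`,
`p_bg = 0.05`, 200 background terms, 500 baseline abstracts) are the
reference simulation: strong but noisy signatures over a weak shared
background, sized so the full pipeline runs in seconds on one CPU. An
`overlap_fraction` parameter lets signature sets bleed into neighboring
categories, reproducing the "noisy subcategory" situation that
motivates merging confusable subcategories into a Mix category.

What the generator does **not** emulate: natural language (abstracts
are bags of tokens), gene-name ambiguity and polysemy, correlated term
co-occurrence, citation-time structure, and category-size imbalance.
Passing tests on synthetic data therefore demonstrates that the
machinery is correct — filters select the planted vocabulary,
the classifier recovers planted categories, seeds reproduce everything —
not that any particular precision is attainable on real MEDLINE
corpora, where ambiguous gene names and uneven literature depth
dominate the error budget.

## Ontology rearrangement

`rearrange`/`relabel_genes` implement the three adjustment moves used
before training: dropping a category too underrepresented to train on
(*Signal transduction* in the shipped default plan — its genes are
usually multi-category annotated, leaving too few single-category
examples), dropping noisy catch-all subcategories ("Other"), and
merging mutually confusable polysaccharide-related subcategories from
several parents into an artificial *Mix category*. Subcategories are
never moved between established categories, so the source hierarchy is
preserved; the classifier predicts categories only. The shipped
ontology file is a curated default covering the sixteen trainable
categories and the subcategories the default plan acts on, not a
verbatim copy of any repository release; users supply their own TSV for
other ontologies.

## Numerical and degenerate-input choices

* Vocabulary order is lexicographic, fixing matrix column order across
  runs; ties in `max.col` at prediction time resolve to the first
  category in sorted order (an event of measure zero with calibrated
  posteriors).
* `f_measure` refuses `p = r = 0`; `pr_curve` refuses an empty truth
  set; `term_frequencies` refuses an empty corpus.
* Stored frequencies are exact ratios of integers (`count/n`), so oracle
  identities in the tests compare with `==`-level tolerance.
* Model files are versioned; loading a foreign or truncated file is an
  explicit error, and prediction cross-checks the vocabulary hash
  recorded at training time.

## Problem sizes used by the test and acceptance runs

The reference simulation (150 genes, ≈ 27 abstracts/gene, 250 terms) is
profiled once per session and reused; the replicated holdout in the
acceptance run uses 10 replicates. Brute-force oracle comparisons run
at 100 genes × 500 terms for disclosure and 1,000 predictions for
curves. These sizes exercise every code path at full fidelity while
keeping a complete check run in well under a minute per suite.
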