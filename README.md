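# genelit

Most newly sequenced prokaryotic genes are annotated only by sequence
similarity to earlier genes that were themselves annotated the same way, and
a large fraction end up in "Unknown function" or "Unclassified" bins even
when their function is already described in the literature. `genelit`
assigns a gene to a functional category of a JCVI-CMR-style ontology
(categories such as *Energy metabolism* or *DNA metabolism*) using nothing
but the MEDLINE abstracts retrieved for its gene name.

## Method

For each gene with at least 5 abstracts in MEDLINE, up to its 50 most recent
abstracts form the gene's text corpus. The gene is represented as a
term-frequency vector over stemmed terms (Porter suffix stripping), where

> freq(w, g) = fraction of gene *g*'s abstracts containing stem *w*

— a document-presence rate, not a word count. Two filters reduce the term
space to the *minimum informative vocabulary*:

1. **Promiscuity filter.** Terms whose frequency in a baseline corpus
   (abstracts retrieved for a generic gene-symbol set) exceeds 5% are
   discarded as generic gene-literature vocabulary.
2. **Optimized cut-off filter.** For a gene with *n* abstracts the
   informativeness threshold is `opt_cutoff = t + k/n` (defaults
   `t = 0.15`, `k = 1.5`), looser for genes with few abstracts. A term is
   kept only if its frequency exceeds the baseline frequency by more than
   `opt_cutoff` in at least 2 genes; terms informative for a single gene
   cannot generalize to a category and are dropped as gene-specific.

Near-duplicate literature profiles (orthologs sharing a name) are collapsed
by average-linkage hierarchical clustering on distance `1 − Pearson r`, cut
at `r ≥ 0.99`, keeping one random representative per cluster. A multiclass
RBF-kernel SVM (one-vs-one, Platt-calibrated pairwise-coupled posteriors)
is trained on the projected vectors; the predicted category's posterior
probability is reported as the **confidence**, and predictions below a
confidence threshold (0.7 is a reasonable operating point for high-precision
annotation) are left unassigned. Evaluation follows a replicated
Monte-Carlo holdout protocol: 100 seeded 90/10 train/test shuffles, with
mean ± SD of precision and recall at each confidence level.

## Worked example

Everything below runs offline on a synthetic corpus with known ground
truth (3 categories, 10 genes each):

```r
library(genelit)

syn  <- generate_synthetic_corpus(synthetic_config(
  K = 3, genes_per_category = 10, abstracts_per_gene_range = c(5, 20),
  background_vocab_size = 60, baseline_abstracts = 150, seed = 42))
vecs  <- profile_corpora(syn$corpora)
bl    <- baseline_profile(syn$baseline)
vocab <- disclose_vocabulary(vecs, bl, cutoff_params())
vocab
#> <vocabulary> 30 informative stemmed terms

mat    <- project_matrix(vecs, vocab)
labels <- setNames(syn$genes$category, syn$genes$gene)[rownames(mat)]
model  <- train_classifier(mat, labels, svm_params(seed = 1))
predict_genes(model, mat[1:3, ])
#>      gene   category confidence low_information
#> 1 g01_001 Category01      0.858           FALSE
#> 2 g01_002 Category01      0.848           FALSE
#> 3 g01_003 Category01      0.850           FALSE

replicated_holdout(mat, labels, replicates = 5, seed = 1)
#> <cv_result> 5 replicates, 10% holdout (micro average)
#>    threshold mean_precision sd_precision mean_recall sd_recall mean_n_assigned
#> 1        0.0              1            0      1.0000    0.0000             3.0
#> ...
#> 9        0.8              1            0      0.9333    0.1491             2.8
#> 10       0.9            NaN           NA      0.0000    0.0000             0.0
```

The 30 disclosed terms are exactly the 3 × 10 planted signature stems: the
baseline filter has removed the filler words present in every abstract, and
the optimized cut-off has removed the background terms. Confidences near
0.85 reflect a calibrated 3-class posterior on cleanly separated data;
raising the threshold from 0.8 to 0.9 trades the last recall for abstention
(`NaN` precision means nothing was assigned at that level).

The same pipeline is available from a shell via the bundled CLI
(`system.file("cli", "genelit", package = "genelit")`) with subcommands
`fetch`, `baseline`, `profile`, `vocab`, `dedupe`, `rearrange`, `train`,
`evaluate`, `classify`, `synth`; every run writes a JSON manifest with
parameters, input hashes and seeds.

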