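# Shared synthetic fixtures, generated once per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# the reference simulation at the generator's default conditions,
# profiled and projected end to end
synth_pipeline <- function() {
  cached("pipeline_default", {
    syn <- generate_synthetic_corpus(synthetic_config(seed = 1))
    vecs <- profile_corpora(syn$corpora)
    bl <- baseline_profile(syn$baseline)
    vocab <- disclose_vocabulary(vecs, bl)
    mat <- project_matrix(vecs, vocab)
    labels <- stats::setNames(syn$genes$category, syn$genes$gene)[rownames(mat)]
    list(syn = syn, vecs = vecs, baseline = bl, vocab = vocab,
         mat = mat, labels = labels)
  })
}

# a small, perfectly separable 3-category simulation for classifier tests
synth_separable <- function() {
  cached("pipeline_separable", {
    cfg <- synthetic_config(K = 3L, genes_per_category = 12L,
                            abstracts_per_gene_range = c(5L, 15L),
                            signature_terms_per_category = 6L,
                            p_sig = 1, p_bg = 0,
                            background_vocab_size = 40L,
                            baseline_abstracts = 100L, seed = 1L)
    syn <- generate_synthetic_corpus(cfg)
    vecs <- profile_corpora(syn$corpora)
    bl <- baseline_profile(syn$baseline)
    vocab <- disclose_vocabulary(vecs, bl)
    mat <- project_matrix(vecs, vocab)
    labels <- stats::setNames(syn$genes$category, syn$genes$gene)[rownames(mat)]
    list(syn = syn, vocab = vocab, mat = mat, labels = labels)
  })
}

# a deterministic offline fixture store for corpus_io tests
fixture_store <- function() {
  recs <- list()
  # recA: 60 abstracts over distinct dates, two sharing the newest date
  dates <- as.Date("2005-01-01") + seq_len(59) * 30
  dates <- c(dates, dates[59])  # pmid tie-break case on the newest date
  recs$recA <- data.frame(
    gene = "recA",
    pmid = as.character(1000 + seq_len(60)),
    date = dates,
    text = sprintf("Recombinase repair text number %s", letters[(seq_len(60) %% 26) + 1]),
    stringsAsFactors = FALSE)
  recs$orfX <- data.frame(
    gene = "orfX", pmid = as.character(1:4),
    date = as.Date("2010-01-01") + 1:4,
    text = paste("hypothetical orf abstract", 1:4),
    stringsAsFactors = FALSE)
  recs$lexA <- data.frame(
    gene = "lexA", pmid = as.character(11:15),
    date = as.Date("2011-01-01") + 1:5,
    text = paste("repressor cleavage abstract", 1:5),
    stringsAsFactors = FALSE)
  do.call(rbind, recs)
}
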