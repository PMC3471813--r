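#' Synthetic corpus configuration
#'
#' Parameters of the category-structured corpus generator. Defaults
#' describe the reference simulation used throughout the test suite:
#' 5 categories of 30 genes, between 5 and 50 abstracts per gene, 10
#' signature terms per category appearing in 70% of a member gene's
#' abstracts, and 200 shared background terms appearing in 5% of any
#' abstract (including the baseline corpus).
#'
#' @param K number of categories (>= 2).
#' @param genes_per_category genes per category.
#' @param abstracts_per_gene_range inclusive integer range for per-gene
#'   abstract counts (default `c(5, 50)`).
#' @param signature_terms_per_category signature terms per category.
#' @param p_sig per-abstract probability that each signature term of the
#'   gene's category appears (default 0.7).
#' @param p_bg per-abstract probability that each background term appears
#'   (default 0.05); must satisfy `0 <= p_bg < p_sig <= 1`.
#' @param background_vocab_size number of shared background terms.
#' @param baseline_abstracts number of abstracts in the generated baseline
#'   corpus (background terms only).
#' @param overlap_fraction fraction of each category's signature terms
#'   shared with the next category (default 0), emulating mutually
#'   confusable "noisy" subcategories.
#' @param seed integer seed; all output is reproducible from it.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(K = 5L, genes_per_category = 30L,
                             abstracts_per_gene_range = c(5L, 50L),
                             signature_terms_per_category = 10L,
                             p_sig = 0.7, p_bg = 0.05,
                             background_vocab_size = 200L,
                             baseline_abstracts = 500L,
                             overlap_fraction = 0,
                             seed = 1L) {
  stopifnot(K >= 2L, genes_per_category >= 1L,
            length(abstracts_per_gene_range) == 2L,
            abstracts_per_gene_range[1L] >= 1L,
            abstracts_per_gene_range[1L] <= abstracts_per_gene_range[2L],
            signature_terms_per_category >= 1L,
            p_bg >= 0, p_bg < p_sig, p_sig <= 1,
            background_vocab_size >= 1L, baseline_abstracts >= 1L,
            overlap_fraction >= 0, overlap_fraction < 1)
  structure(list(K = as.integer(K),
                 genes_per_category = as.integer(genes_per_category),
                 abstracts_per_gene_range = as.integer(abstracts_per_gene_range),
                 signature_terms_per_category =
                   as.integer(signature_terms_per_category),
                 p_sig = p_sig, p_bg = p_bg,
                 background_vocab_size = as.integer(background_vocab_size),
                 baseline_abstracts = as.integer(baseline_abstracts),
                 overlap_fraction = overlap_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# pseudo-words built from CVC syllables; regenerated until all words are
# distinct after stemming, >= 3 letters, and not stopwords, so each word
# maps to its own feature
.make_pseudo_words <- function(n) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  words <- character(0)
  stems_seen <- character(0)
  stop_set <- litprof_stopwords()
  while (length(words) < n) {
    syll <- replicate(3L, paste0(sample(cons, 1L), sample(vow, 1L),
                                 sample(cons, 1L)))
    w <- paste(syll, collapse = "")
    if (w %in% words || w %in% stop_set) next
    st <- porter_stem(w)
    if (st %in% stems_seen) next
    words <- c(words, w)
    stems_seen <- c(stems_seen, st)
  }
  words
}

#' Generate a category-structured synthetic corpus with known truth
#'
#' Each gene in category `c` receives `n ~ Uniform[range]` abstracts; each
#' abstract independently contains each of `c`'s signature terms with
#' probability `p_sig` and each shared background term with probability
#' `p_bg`, plus fixed filler words common to all abstracts (so that the
#' baseline promiscuity filter has something to remove). Baseline abstracts
#' contain only background and filler terms. The truth manifest records
#' every category's signature set (as stemmed terms, i.e. in the pipeline's
#' own feature space).
#'
#' @param config a [synthetic_config()].
#' @param dir optional directory: when given, writes `corpus.jsonl`,
#'   `baseline.jsonl`, `genes.tsv` and `truth.json` there.
#' @return list with `corpora` (named list of `gene_corpus`), `baseline`
#'   (data.frame `pmid`, `date`, `text`), `genes` (data.frame `gene`,
#'   `category`), `truth` (list: per-category stemmed signature terms,
#'   background stems, config), and `config`.
#' @export
generate_synthetic_corpus <- function(config = synthetic_config(),
                                      dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)

  filler <- c("the", "gene", "protein", "expression", "cell", "analysis")
  n_sig_total <- config$K * config$signature_terms_per_category
  all_words <- .make_pseudo_words(n_sig_total + config$background_vocab_size)
  sig_words <- all_words[seq_len(n_sig_total)]
  bg_words <- all_words[-seq_len(n_sig_total)]
  sig_by_cat <- split(sig_words,
                      rep(seq_len(config$K),
                          each = config$signature_terms_per_category))
  # optional signature overlap: category c borrows terms from category c+1
  n_share <- floor(config$overlap_fraction *
                     config$signature_terms_per_category)
  if (n_share > 0L) {
    for (cc in seq_len(config$K)) {
      donor <- if (cc == config$K) 1L else cc + 1L
      sig_by_cat[[cc]] <- c(
        sig_by_cat[[cc]][seq_len(config$signature_terms_per_category - n_share)],
        sig_by_cat[[donor]][seq_len(n_share)])
    }
  }
  categories <- sprintf("Category%02d", seq_len(config$K))
  names(sig_by_cat) <- categories

  pmid_counter <- 100000L
  draw_abstract_text <- function(sig_terms) {
    present_sig <- sig_terms[stats::runif(length(sig_terms)) < config$p_sig]
    present_bg <- bg_words[stats::runif(length(bg_words)) < config$p_bg]
    paste(c(filler, present_sig, present_bg), collapse = " ")
  }

  genes <- data.frame(gene = character(0), category = character(0),
                      stringsAsFactors = FALSE)
  corpora <- list()
  rng <- config$abstracts_per_gene_range
  for (cc in seq_len(config$K)) {
    for (g in seq_len(config$genes_per_category)) {
      gname <- sprintf("g%02d_%03d", cc, g)
      n_abs <- sample(seq(rng[1L], rng[2L]), 1L)
      pmids <- as.character(pmid_counter + seq_len(n_abs))
      pmid_counter <- pmid_counter + n_abs
      dates <- as.Date("2000-01-01") + sample.int(7300L, n_abs)
      texts <- vapply(seq_len(n_abs), function(i) {
        draw_abstract_text(sig_by_cat[[cc]])
      }, character(1))
      corpora[[gname]] <- gene_corpus(gname, data.frame(
        pmid = pmids, date = dates, text = texts,
        stringsAsFactors = FALSE))
      genes <- rbind(genes, data.frame(gene = gname,
                                       category = categories[cc],
                                       stringsAsFactors = FALSE))
    }
  }

  baseline <- data.frame(
    pmid = as.character(900000L + seq_len(config$baseline_abstracts)),
    date = as.Date("2000-01-01") + seq_len(config$baseline_abstracts),
    text = vapply(seq_len(config$baseline_abstracts), function(i) {
      present_bg <- bg_words[stats::runif(length(bg_words)) < config$p_bg]
      paste(c(filler, present_bg), collapse = " ")
    }, character(1)),
    stringsAsFactors = FALSE)

  truth <- list(
    signature_terms = lapply(sig_by_cat,
                             function(w) sort(porter_stem(w))),
    background_terms = sort(porter_stem(bg_words)),
    filler_terms = sort(unique(porter_stem(
      setdiff(filler, litprof_stopwords())))),
    config = unclass(config))

  out <- list(corpora = corpora, baseline = baseline, genes = genes,
              truth = truth, config = config)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_corpus_file(corpora, file.path(dir, "corpus.jsonl"))
    baseline_recs <- corpora_from_baseline(baseline)
    write_corpus_file(baseline_recs, file.path(dir, "baseline.jsonl"))
    write_gene_table(genes, file.path(dir, "genes.tsv"))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

# baseline abstracts are stored in the same JSON-lines format under a
# reserved pseudo-gene name
corpora_from_baseline <- function(baseline) {
  list(baseline = gene_corpus("__baseline__", baseline))
}

#' Read a baseline corpus file
#'
#' Pools every abstract in a JSON-lines corpus file (regardless of gene
#' field) into one abstract table suitable for [baseline_profile()].
#'
#' @param path JSON-lines corpus file.
#' @return data.frame with columns `pmid`, `date`, `text`.
#' @export
read_baseline_file <- function(path) {
  .read_corpus_records(path)[, c("pmid", "date", "text")]
}
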