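#' Default English stopword list
#'
#' A compact list of common English function words removed from abstracts
#' before stemming. The baseline promiscuity filter already eliminates most
#' high-frequency generic terms, so this list is a conservative default; it
#' can be replaced or emptied via the `stopwords` argument of
#' [tokenize_and_stem()]. The list in force should be recorded in the run
#' manifest for reproducibility.
#'
#' @return character vector of lower-case stopwords.
#' @export
litprof_stopwords <- function() {
  c("the", "and", "for", "are", "but", "not", "you", "all", "any", "can",
    "had", "has", "have", "her", "his", "its", "our", "out", "she", "their",
    "them", "then", "there", "these", "they", "this", "that", "was", "were",
    "which", "while", "with", "from", "into", "been", "being", "both",
    "each", "few", "further", "here", "how", "more", "most", "other",
    "some", "such", "than", "too", "very", "what", "when", "where", "who",
    "whom", "why", "will", "would", "should", "could", "did", "does",
    "doing", "during", "before", "after", "above", "below", "between",
    "through", "about", "against", "again", "once", "only", "over",
    "under", "same", "own", "off", "nor", "also", "may", "might", "must",
    "shall", "upon", "within", "without", "among", "because", "however",
    "therefore", "thus", "although", "whether", "per", "via", "using",
    "used", "use", "based", "results", "result", "study", "studies",
    "show", "shown", "showed", "found", "observed", "suggest", "suggests",
    "suggested", "respectively", "including", "well", "due", "present",
    "two", "one", "three", "several", "many", "new", "known", "here")
}

#' Tokenize free text and stem the tokens
#'
#' Lower-cases the text, extracts maximal runs of ASCII letters (digits,
#' hyphens and all punctuation split tokens), drops tokens shorter than
#' `min_token_len` and stopwords, Porter-stems the survivors, and returns
#' the deduplicated set of stems. Presence semantics: each stem appears at
#' most once per abstract regardless of how often the word occurs.
#'
#' @param text a single character string (one abstract: title + body).
#' @param min_token_len minimum token length in characters (default 3).
#' @param stopwords character vector removed before stemming; use
#'   `character(0)` to disable.
#' @return sorted character vector of unique stems (empty for empty text).
#' @examples
#' tokenize_and_stem("Transcriptional regulation of transcription")
#' @export
tokenize_and_stem <- function(text, min_token_len = 3L,
                              stopwords = litprof_stopwords()) {
  if (length(text) != 1L || is.na(text)) {
    stop("`text` must be a single non-NA character string")
  }
  tokens <- .tokenize_raw(text, min_token_len, stopwords)
  if (length(tokens) == 0L) return(character(0))
  sort(unique(porter_stem(tokens)))
}

# lower-case, extract letter runs, length/stopword filter, dedupe (no stem)
.tokenize_raw <- function(text, min_token_len, stopwords) {
  tokens <- regmatches(tolower(text), gregexpr("[a-z]+", tolower(text)))[[1L]]
  tokens <- unique(tokens[nchar(tokens) >= min_token_len])
  setdiff(tokens, stopwords)
}

#' Term-frequency vector of a gene's abstract corpus
#'
#' The frequency of a term is the fraction of the gene's abstracts whose
#' stemmed token set contains it — a document-presence rate, not a
#' within-document count. Terms absent from every abstract are omitted, so
#' every stored frequency lies in (0, 1] and `freq * n` is an integer count
#' of abstracts.
#'
#' @param corpus a `gene_corpus` (see [gene_corpus()]).
#' @param min_token_len,stopwords passed to [tokenize_and_stem()].
#' @return an object of class `tf_vector`: list with `gene_name`, `freqs`
#'   (named numeric, sorted by term), and `n` (abstract count).
#' @export
term_frequencies <- function(corpus, min_token_len = 3L,
                             stopwords = litprof_stopwords()) {
  stopifnot(inherits(corpus, "gene_corpus"))
  if (corpus$n < 1L) stop("corpus has no abstracts")
  counts <- .presence_counts(corpus$abstracts$text, min_token_len, stopwords)
  structure(
    list(gene_name = corpus$gene_name,
         freqs = counts / corpus$n,
         n = corpus$n),
    class = "tf_vector"
  )
}

#' @export
print.tf_vector <- function(x, ...) {
  cat(sprintf("<tf_vector> gene '%s': %d terms over %d abstracts\n",
              x$gene_name, length(x$freqs), x$n))
  invisible(x)
}

# per-term counts of abstracts containing the term; each distinct token is
# stemmed once across the whole corpus
.presence_counts <- function(texts, min_token_len, stopwords) {
  raw <- lapply(texts, .tokenize_raw,
                min_token_len = min_token_len, stopwords = stopwords)
  all_tokens <- unique(unlist(raw, use.names = FALSE))
  stem_of <- stats::setNames(porter_stem(all_tokens), all_tokens)
  sets <- lapply(raw, function(tk) unique(unname(stem_of[tk])))
  all_terms <- unlist(sets, use.names = FALSE)
  if (length(all_terms) == 0L) {
    return(stats::setNames(numeric(0), character(0)))
  }
  tab <- table(all_terms)
  counts <- as.numeric(tab)
  names(counts) <- names(tab)
  counts[order(names(counts))]
}

#' Baseline term-frequency profile
#'
#' Pools a reference abstract set (the "baseline corpus") and computes, for
#' every stemmed term, the fraction of all baseline abstracts containing it.
#' Terms common in generic gene literature get high baseline frequencies and
#' are later eliminated as promiscuous. Frequencies are pooled over the whole
#' abstract set, never averaged per gene.
#'
#' @param abstracts a data.frame with a `text` column (one row per
#'   abstract), or a character vector of abstract texts.
#' @param min_token_len,stopwords passed to [tokenize_and_stem()].
#' @return an object of class `baseline_profile`: list with `freqs` (named
#'   numeric) and `n_abstracts`.
#' @export
baseline_profile <- function(abstracts, min_token_len = 3L,
                             stopwords = litprof_stopwords()) {
  texts <- if (is.data.frame(abstracts)) abstracts$text else abstracts
  if (is.null(texts) || length(texts) == 0L) {
    stop("baseline abstract set is empty")
  }
  counts <- .presence_counts(texts, min_token_len, stopwords)
  structure(
    list(freqs = counts / length(texts), n_abstracts = length(texts)),
    class = "baseline_profile"
  )
}

#' @export
print.baseline_profile <- function(x, ...) {
  cat(sprintf("<baseline_profile> %d terms over %d abstracts\n",
              length(x$freqs), x$n_abstracts))
  invisible(x)
}

#' Look up baseline frequencies, defaulting to zero
#'
#' @param baseline a `baseline_profile`.
#' @param terms character vector of stemmed terms.
#' @return numeric vector of baseline frequencies (0 for absent terms).
#' @export
baseline_freq <- function(baseline, terms) {
  stopifnot(inherits(baseline, "baseline_profile"))
  out <- baseline$freqs[terms]
  out[is.na(out)] <- 0
  names(out) <- terms
  out
}

#' Profile every corpus in a collection
#'
#' @param corpora named list of `gene_corpus` objects (e.g. from
#'   [read_corpus_file()] or [fetch_corpora()]); ineligible markers are
#'   skipped.
#' @inheritParams term_frequencies
#' @return named list of `tf_vector`, one per eligible gene.
#' @export
profile_corpora <- function(corpora, min_token_len = 3L,
                            stopwords = litprof_stopwords()) {
  eligible <- Filter(function(x) inherits(x, "gene_corpus"), corpora)
  lapply(eligible, term_frequencies,
         min_token_len = min_token_len, stopwords = stopwords)
}

#' Read and write baseline profiles
#'
#' TSV with columns `term`, `freq`, preceded by a `#` header line
#' recording the baseline abstract count.
#'
#' @param baseline a `baseline_profile`.
#' @param path file path.
#' @export
write_baseline_profile <- function(baseline, path) {
  stopifnot(inherits(baseline, "baseline_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_abstracts=%d", baseline$n_abstracts), con)
  writeLines("term\tfreq", con)
  if (length(baseline$freqs) > 0L) {
    writeLines(sprintf("%s\t%.10g", names(baseline$freqs),
                       unname(baseline$freqs)), con)
  }
  invisible(path)
}

#' @rdname write_baseline_profile
#' @return `read_baseline_profile()`: a `baseline_profile`.
#' @export
read_baseline_profile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n_abs <- as.integer(sub("^# n_abstracts=", "",
                          grep("^# n_abstracts=", lines, value = TRUE)[1L]))
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          stringsAsFactors = FALSE)
  structure(list(freqs = stats::setNames(df$freq, df$term),
                 n_abstracts = n_abs),
            class = "baseline_profile")
}

#' Write term-frequency vectors as a sparse triplet table
#'
#' One row per (gene, term) pair with a non-zero frequency; columns
#' `gene`, `term`, `freq`.
#'
#' @param vectors list of `tf_vector`.
#' @param path output TSV path.
#' @export
write_tf_triplets <- function(vectors, path) {
  rows <- do.call(rbind, lapply(vectors, function(v) {
    if (length(v$freqs) == 0L) return(NULL)
    data.frame(gene = v$gene_name, term = names(v$freqs),
               freq = unname(v$freqs), stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(gene = character(0), term = character(0),
                       freq = numeric(0))
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
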