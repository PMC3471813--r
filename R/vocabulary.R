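#' Vocabulary disclosure parameters
#'
#' Controls the two filters that reduce a corpus-wide term set to the
#' minimum informative vocabulary: the baseline promiscuity cut-off and
#' the per-gene optimized informativeness cut-off `t + k/n`.
#'
#' @param t minimum threshold of the optimized cut-off (default 0.15).
#' @param k constant of the optimized cut-off (default 1.5).
#' @param baseline_cutoff maximum baseline frequency a term may have
#'   before it is considered promiscuous (default 0.05, i.e. five percent).
#' @param min_genes minimum number of genes in which a term must exceed its
#'   optimized cut-off to count as informative rather than gene-specific
#'   (default 2).
#' @return an object of class `cutoff_params`.
#' @export
cutoff_params <- function(t = 0.15, k = 1.5, baseline_cutoff = 0.05,
                          min_genes = 2L) {
  stopifnot(t >= 0, k >= 0, baseline_cutoff > 0, baseline_cutoff < 1,
            min_genes >= 1)
  structure(list(t = t, k = k, baseline_cutoff = baseline_cutoff,
                 min_genes = as.integer(min_genes)),
            class = "cutoff_params")
}

#' Per-gene optimized frequency cut-off
#'
#' `t + k/n`, where `n` is the gene's abstract count. The cut-off loosens
#' for genes with few abstracts (where presence fractions are coarse and
#' noisy) and tends to `t` as `n` grows, compensating for differences in
#' corpus size across genes.
#'
#' @param n abstract count(s), each at least 1.
#' @param params a [cutoff_params()].
#' @return numeric vector of thresholds, strictly decreasing in `n`.
#' @examples
#' optimized_cutoff(c(5, 50), cutoff_params())  # 0.45, 0.18
#' @export
optimized_cutoff <- function(n, params = cutoff_params()) {
  stopifnot(inherits(params, "cutoff_params"))
  if (any(n < 1)) stop("abstract count n must be >= 1")
  params$t + params$k / n
}

#' Disclose the minimum informative vocabulary
#'
#' A stemmed term enters the vocabulary iff
#' (a) its baseline frequency is at most `baseline_cutoff` (terms above it
#' are promiscuous: common in generic gene literature), and
#' (b) in at least `min_genes` genes its frequency exceeds the baseline
#' frequency by more than that gene's optimized cut-off `t + k/n`
#' (terms failing this everywhere are uninformative; terms passing it in
#' fewer than `min_genes` genes are gene-specific and useless for
#' generalizing to a category).
#'
#' @param vectors list of `tf_vector` (each carries its abstract count `n`).
#' @param baseline a [baseline_profile()].
#' @param params a [cutoff_params()].
#' @return an object of class `vocabulary`: list with `terms`
#'   (lexicographically sorted unique stems) and `provenance` (the
#'   parameters and corpus identifiers used).
#' @export
disclose_vocabulary <- function(vectors, baseline,
                                params = cutoff_params()) {
  stopifnot(length(vectors) > 0L, inherits(baseline, "baseline_profile"),
            inherits(params, "cutoff_params"))
  candidates <- sort(unique(unlist(lapply(vectors,
                                          function(v) names(v$freqs)),
                                   use.names = FALSE)))
  if (length(candidates) == 0L) {
    return(.vocabulary(character(0), vectors, params))
  }
  b <- baseline_freq(baseline, candidates)
  support <- integer(length(candidates))
  names(support) <- candidates
  for (v in vectors) {
    cut <- optimized_cutoff(v$n, params)
    terms <- names(v$freqs)
    excess <- v$freqs - b[terms]
    hit <- terms[excess > cut]
    support[hit] <- support[hit] + 1L
  }
  keep <- b <= params$baseline_cutoff & support >= params$min_genes
  .vocabulary(candidates[keep], vectors, params)
}

.vocabulary <- function(terms, vectors, params) {
  structure(
    list(terms = terms,
         provenance = list(
           params = unclass(params),
           n_genes = length(vectors),
           genes_hash = hash_object(sort(vapply(vectors, `[[`,
                                                character(1),
                                                "gene_name"))))),
    class = "vocabulary"
  )
}

#' @export
print.vocabulary <- function(x, ...) {
  cat(sprintf("<vocabulary> %d informative stemmed terms\n",
              length(x$terms)))
  invisible(x)
}

#' Project term-frequency vectors onto a vocabulary
#'
#' `project()` aligns one vector to the vocabulary's fixed term order:
#' vocabulary terms absent from the vector become 0, vector terms outside
#' the vocabulary are dropped. `project_matrix()` stacks a list of vectors
#' into a dense genes-by-terms matrix.
#'
#' @param vector a `tf_vector`.
#' @param vocab a `vocabulary`.
#' @return `project()`: named numeric row in vocabulary order;
#'   `project_matrix()`: numeric matrix with gene rownames, term colnames,
#'   and a `vocab_hash` attribute identifying the vocabulary.
#' @export
project <- function(vector, vocab) {
  stopifnot(inherits(vector, "tf_vector"), inherits(vocab, "vocabulary"))
  row <- vector$freqs[vocab$terms]
  row[is.na(row)] <- 0
  names(row) <- vocab$terms
  row
}

#' @rdname project
#' @param vectors list of `tf_vector`.
#' @export
project_matrix <- function(vectors, vocab) {
  stopifnot(inherits(vocab, "vocabulary"))
  mat <- do.call(rbind, lapply(vectors, project, vocab = vocab))
  rownames(mat) <- vapply(vectors, `[[`, character(1), "gene_name")
  attr(mat, "vocab_hash") <- vocabulary_hash(vocab)
  mat
}

#' Hash of a vocabulary's term list
#'
#' Used to assert at prediction time that rows were projected on the same
#' vocabulary the model was trained on.
#'
#' @param vocab a `vocabulary` or a character vector of terms.
#' @return md5 hex string.
#' @export
vocabulary_hash <- function(vocab) {
  terms <- if (inherits(vocab, "vocabulary")) vocab$terms else vocab
  hash_object(terms)
}

# md5 of a serialized object, via a temp file (no in-memory md5 in base R)
hash_object <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  con <- file(tf, "wb")
  serialize(x, con, version = 2L)
  close(con)
  unname(tools::md5sum(tf))
}

#' Read and write vocabulary files
#'
#' One term per line, preceded by `#`-comment header lines recording the
#' disclosure parameters and the hash of the gene set that produced it.
#'
#' @param vocab a `vocabulary`.
#' @param path file path.
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "vocabulary"))
  p <- vocab$provenance$params
  header <- c(
    sprintf("# t=%g k=%g baseline_cutoff=%g min_genes=%d",
            p$t, p$k, p$baseline_cutoff, p$min_genes),
    sprintf("# n_genes=%d genes_hash=%s",
            vocab$provenance$n_genes, vocab$provenance$genes_hash))
  writeLines(c(header, vocab$terms), path)
  invisible(path)
}

#' @rdname write_vocabulary
#' @return `read_vocabulary()`: a `vocabulary` (provenance parsed from the
#'   header when present).
#' @export
read_vocabulary <- function(path) {
  lines <- readLines(path, warn = FALSE)
  headers <- grep("^#", lines, value = TRUE)
  terms <- lines[!grepl("^#", lines) & nzchar(lines)]
  prov <- list(params = NULL, n_genes = NA_integer_, genes_hash = NA_character_)
  kv <- regmatches(headers, gregexpr("[a-z_]+=[^ ]+", headers))
  kv <- unlist(kv, use.names = FALSE)
  if (length(kv) > 0L) {
    vals <- sub("^[a-z_]+=", "", kv)
    names(vals) <- sub("=.*$", "", kv)
    if (all(c("t", "k", "baseline_cutoff", "min_genes") %in% names(vals))) {
      prov$params <- list(t = as.numeric(vals[["t"]]),
                          k = as.numeric(vals[["k"]]),
                          baseline_cutoff = as.numeric(vals[["baseline_cutoff"]]),
                          min_genes = as.integer(vals[["min_genes"]]))
    }
    if ("n_genes" %in% names(vals)) prov$n_genes <- as.integer(vals[["n_genes"]])
    if ("genes_hash" %in% names(vals)) prov$genes_hash <- vals[["genes_hash"]]
  }
  structure(list(terms = terms, provenance = prov), class = "vocabulary")
}

#' Write a dense genes-by-terms frequency matrix as TSV
#'
#' First column `gene`, remaining columns the vocabulary terms in order;
#' absent terms are explicit zeros.
#'
#' @param mat matrix from [project_matrix()].
#' @param path output TSV path.
#' @export
write_tf_matrix <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
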