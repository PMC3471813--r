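# Independent brute-force oracles used to cross-check the implementation.
# These deliberately recompute everything with the most literal possible
# loops, sharing no code with the package internals.

# vocabulary disclosure: double loop over candidate terms and genes
oracle_vocabulary <- function(vectors, baseline, params) {
  terms <- sort(unique(unlist(lapply(vectors, function(v) names(v$freqs)))))
  keep <- character(0)
  for (w in terms) {
    b <- if (w %in% names(baseline$freqs)) baseline$freqs[[w]] else 0
    if (b > params$baseline_cutoff) next
    support <- 0L
    for (v in vectors) {
      f <- if (w %in% names(v$freqs)) v$freqs[[w]] else 0
      if (f - b > params$t + params$k / v$n) support <- support + 1L
    }
    if (support >= params$min_genes) keep <- c(keep, w)
  }
  keep
}

# precision/recall at each threshold by direct enumeration
oracle_pr <- function(correct, conf, thresholds) {
  n_total <- length(correct)
  do.call(rbind, lapply(thresholds, function(th) {
    assigned <- which(conf >= th)
    nc <- sum(correct[assigned])
    data.frame(
      threshold = th,
      precision = if (length(assigned) == 0) NA_real_ else nc / length(assigned),
      recall = nc / n_total,
      n_assigned = length(assigned))
  }))
}

# connected components of the graph {r >= r_min}; agrees with
# average-linkage clustering when blocks are well separated
oracle_components <- function(rows, r_min) {
  r <- stats::cor(t(rows))
  n <- nrow(rows)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (r[i, j] >= r_min && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# textbook paired t-test
oracle_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  list(statistic = t, p_value = 2 * stats::pt(-abs(t), n - 1))
}

# two partitions describe the same clustering?
same_partition <- function(p1, p2) {
  length(p1) == length(p2) &&
    all(outer(p1, p1, "==") == outer(p2, p2, "=="))
}

# build a tf_vector directly (bypassing text processing) for toy cases
tfv <- function(gene, n, ...) {
  freqs <- c(...)
  structure(list(gene_name = gene, freqs = freqs[order(names(freqs))],
                 n = n),
            class = "tf_vector")
}

bprof <- function(n_abstracts, ...) {
  freqs <- c(...)
  structure(list(freqs = freqs, n_abstracts = n_abstracts),
            class = "baseline_profile")
}
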