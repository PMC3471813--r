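#' Collapse near-duplicate literature profiles
#'
#' Orthologous genes sharing a name, and homonym survivors, can carry
#' almost identical abstract corpora and hence almost identical
#' term-frequency rows; left in place they would inflate apparent training
#' redundancy. Rows are clustered by agglomerative hierarchical clustering
#' with distance `1 - Pearson r` and average linkage, the dendrogram is cut
#' at `1 - r_min` (so genes correlated at `>= r_min` fall in one cluster),
#' and one representative per cluster is drawn uniformly at random under
#' the given seed.
#'
#' Rows with zero variance have undefined Pearson correlation; they are
#' quarantined as their own singleton clusters with a warning.
#'
#' @param rows dense numeric matrix (genes x terms) with gene rownames,
#'   e.g. from [project_matrix()].
#' @param r_min correlation threshold at or above which genes are merged
#'   (default 0.99).
#' @param seed integer seed for the representative draw.
#' @return an object of class `cluster_assignment`: list with `cluster`
#'   (named integer vector gene -> cluster id), `representatives`
#'   (character, one gene per cluster), `r_min`, `seed`.
#' @export
reduce_redundancy <- function(rows, r_min = 0.99, seed = 1L) {
  stopifnot(is.matrix(rows), nrow(rows) >= 1L, r_min > 0, r_min <= 1)
  if (is.null(rownames(rows))) {
    rownames(rows) <- paste0("gene", seq_len(nrow(rows)))
  }
  genes <- rownames(rows)
  vars <- apply(rows, 1L, stats::var)
  degenerate <- vars == 0 | is.na(vars)
  if (any(degenerate)) {
    warning(sprintf(
      "%d zero-variance row(s) quarantined as singleton clusters: %s",
      sum(degenerate), paste(genes[degenerate], collapse = ", ")))
  }
  ok <- genes[!degenerate]
  cluster <- integer(length(genes))
  names(cluster) <- genes

  if (length(ok) == 1L) {
    cluster[ok] <- 1L
  } else if (length(ok) > 1L) {
    r <- stats::cor(t(rows[ok, , drop = FALSE]))
    d <- stats::as.dist(1 - r)
    hc <- stats::hclust(d, method = "average")
    cluster[ok] <- stats::cutree(hc, h = 1 - r_min)
  }
  # quarantined rows become singletons after the clustered ids
  next_id <- if (length(ok) > 0L) max(cluster[ok]) else 0L
  for (g in genes[degenerate]) {
    next_id <- next_id + 1L
    cluster[g] <- next_id
  }

  set.seed(seed)
  reps <- vapply(sort(unique(cluster)), function(k) {
    members <- sort(genes[cluster == k])
    if (length(members) == 1L) members else sample(members, 1L)
  }, character(1))

  structure(list(cluster = cluster, representatives = unname(reps),
                 r_min = r_min, seed = as.integer(seed)),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf(
    "<cluster_assignment> %d genes -> %d clusters (r_min=%g, seed=%d)\n",
    length(x$cluster), length(x$representatives), x$r_min, x$seed))
  invisible(x)
}

#' Write a cluster assignment as TSV
#'
#' Columns: `gene`, `cluster_id`, `is_representative`.
#'
#' @param assignment a `cluster_assignment`.
#' @param path output path.
#' @export
write_cluster_assignment <- function(assignment, path) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  df <- data.frame(
    gene = names(assignment$cluster),
    cluster_id = unname(assignment$cluster),
    is_representative = names(assignment$cluster) %in%
      assignment$representatives,
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
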