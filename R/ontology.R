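#' Functional-category ontology
#'
#' A two-level ontology in the style of the JCVI Comprehensive Microbial
#' Resource: top-level functional categories, each holding subcategories.
#' Classification is at category level only; subcategories exist for
#' rearrangement bookkeeping.
#'
#' @param x a data.frame with columns `category` and `subcategory`
#'   (one row per pair), or a named list mapping category to a character
#'   vector of subcategories.
#' @return an object of class `gl_ontology` with fields `categories`
#'   (character) and `subcategories` (named list).
#' @export
ontology <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("category", "subcategory") %in% names(x)))
    subs <- split(as.character(x$subcategory), as.character(x$category))
    subs <- subs[unique(as.character(x$category))]
  } else if (is.list(x)) {
    subs <- lapply(x, as.character)
  } else {
    stop("x must be a data.frame or a named list")
  }
  if (is.null(names(subs)) || anyDuplicated(names(subs))) {
    stop("category names must be present and unique")
  }
  for (cat in names(subs)) {
    if (anyDuplicated(subs[[cat]])) {
      stop(sprintf("duplicate subcategory under category '%s'", cat))
    }
  }
  structure(list(categories = names(subs), subcategories = subs),
            class = "gl_ontology")
}

#' @export
print.gl_ontology <- function(x, ...) {
  cat(sprintf("<ontology> %d categories, %d subcategories\n",
              length(x$categories),
              sum(lengths(x$subcategories))))
  invisible(x)
}

#' Read and write ontologies as TSV
#'
#' Tab-separated with header, columns `category` and `subcategory`.
#'
#' @param path file path.
#' @export
read_ontology <- function(path) {
  ontology(utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character"))
}

#' @rdname read_ontology
#' @param ont a `gl_ontology`.
#' @export
write_ontology <- function(ont, path) {
  stopifnot(inherits(ont, "gl_ontology"))
  df <- data.frame(
    category = rep(ont$categories, lengths(ont$subcategories)),
    subcategory = unlist(ont$subcategories, use.names = FALSE),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Ontology rearrangement plan
#'
#' Describes how a source ontology is adjusted before training: whole
#' categories to drop (e.g. one too underrepresented to train on),
#' individual subcategories to drop (e.g. noisy "Other" bins), and
#' subcategories to merge into a new artificial category that collects
#' mutually confusable subcategories from different parents. No
#' subcategory is ever moved between established categories, so the
#' source hierarchy is not violated.
#'
#' @param drop_categories character vector of category names to drop.
#' @param drop_subcategories data.frame with columns `category`,
#'   `subcategory` to drop.
#' @param merge_into_mix data.frame with columns `category`,
#'   `subcategory` to move under `mix_name`.
#' @param mix_name name of the artificial category
#'   (default "Mix category").
#' @return an object of class `rearrangement_plan`.
#' @export
rearrangement_plan <- function(drop_categories = character(0),
                               drop_subcategories = NULL,
                               merge_into_mix = NULL,
                               mix_name = "Mix category") {
  empty <- data.frame(category = character(0), subcategory = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(drop_subcategories)) drop_subcategories <- empty
  if (is.null(merge_into_mix)) merge_into_mix <- empty
  plan <- structure(
    list(drop_categories = as.character(drop_categories),
         drop_subcategories = drop_subcategories,
         merge_into_mix = merge_into_mix,
         mix_name = mix_name),
    class = "rearrangement_plan")
  keys <- c(plan$drop_categories,
            paste(drop_subcategories$category, drop_subcategories$subcategory,
                  sep = "\t"),
            paste(merge_into_mix$category, merge_into_mix$subcategory,
                  sep = "\t"))
  if (anyDuplicated(keys)) stop("an item appears twice in the plan")
  plan
}

#' Read and write rearrangement plans as JSON
#'
#' @param path file path.
#' @export
read_plan <- function(path) {
  p <- jsonlite::fromJSON(path)
  as_pairs <- function(x) {
    if (is.null(x) || length(x) == 0L) return(NULL)
    data.frame(category = x$category, subcategory = x$subcategory,
               stringsAsFactors = FALSE)
  }
  rearrangement_plan(
    drop_categories = if (is.null(p$drop_categories)) character(0)
                      else p$drop_categories,
    drop_subcategories = as_pairs(p$drop_subcategories),
    merge_into_mix = as_pairs(p$merge_into_mix),
    mix_name = if (is.null(p$mix_name)) "Mix category" else p$mix_name)
}

#' @rdname read_plan
#' @param plan a `rearrangement_plan`.
#' @export
write_plan <- function(plan, path) {
  stopifnot(inherits(plan, "rearrangement_plan"))
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

.check_plan <- function(ont, plan) {
  unknown_cat <- setdiff(plan$drop_categories, ont$categories)
  if (length(unknown_cat) > 0L) {
    stop(sprintf("plan references unknown category: %s",
                 paste(unknown_cat, collapse = ", ")))
  }
  check_pairs <- function(pairs, what) {
    for (i in seq_len(nrow(pairs))) {
      cat <- pairs$category[i]; sub <- pairs$subcategory[i]
      if (!cat %in% ont$categories) {
        stop(sprintf("plan %s references unknown category: %s", what, cat))
      }
      if (!sub %in% ont$subcategories[[cat]]) {
        stop(sprintf("plan %s references unknown subcategory: %s / %s",
                     what, cat, sub))
      }
    }
  }
  check_pairs(plan$drop_subcategories, "drop")
  check_pairs(plan$merge_into_mix, "merge")
  invisible(TRUE)
}

#' Apply a rearrangement plan to an ontology
#'
#' Dropped categories and subcategories are removed; merged subcategories
#' are moved under the plan's mix category; every surviving non-mix
#' subcategory keeps its original parent.
#'
#' @param ont source `gl_ontology`.
#' @param plan a `rearrangement_plan`; every referenced item must exist in
#'   `ont`.
#' @return the rearranged `gl_ontology`.
#' @export
rearrange <- function(ont, plan) {
  stopifnot(inherits(ont, "gl_ontology"),
            inherits(plan, "rearrangement_plan"))
  .check_plan(ont, plan)
  subs <- ont$subcategories
  subs <- subs[setdiff(names(subs), plan$drop_categories)]
  drop_one <- function(subs, pairs) {
    for (i in seq_len(nrow(pairs))) {
      cat <- pairs$category[i]
      if (!cat %in% names(subs)) next
      subs[[cat]] <- setdiff(subs[[cat]], pairs$subcategory[i])
    }
    subs
  }
  subs <- drop_one(subs, plan$drop_subcategories)
  merged <- character(0)
  for (i in seq_len(nrow(plan$merge_into_mix))) {
    cat <- plan$merge_into_mix$category[i]
    sub <- plan$merge_into_mix$subcategory[i]
    if (cat %in% names(subs)) {
      subs[[cat]] <- setdiff(subs[[cat]], sub)
      merged <- c(merged, sub)
    }
  }
  if (length(merged) > 0L) subs[[plan$mix_name]] <- merged
  subs <- subs[lengths(subs) > 0L | names(subs) == plan$mix_name]
  ontology(subs)
}

#' Relabel a gene table under a rearrangement plan
#'
#' Genes in dropped categories or dropped subcategories are removed (and
#' counted); genes in merged subcategories are relabeled to the mix
#' category; all other genes keep their labels. Subcategory-level plan
#' items require a `subcategory` column in the gene table.
#'
#' @param genes data.frame with columns `gene`, `category`, optionally
#'   `subcategory`; every label must resolve in `source`.
#' @param source the source `gl_ontology`.
#' @param plan a `rearrangement_plan`.
#' @return list with `genes` (relabeled table) and `removed` (named
#'   integer vector: `dropped_category`, `dropped_subcategory`).
#' @export
relabel_genes <- function(genes, source, plan) {
  stopifnot(is.data.frame(genes),
            all(c("gene", "category") %in% names(genes)),
            inherits(source, "gl_ontology"),
            inherits(plan, "rearrangement_plan"))
  .check_plan(source, plan)
  bad <- setdiff(unique(genes$category), source$categories)
  if (length(bad) > 0L) {
    offenders <- genes$gene[genes$category %in% bad]
    stop(sprintf("unresolvable category label(s) %s for gene(s): %s",
                 paste(bad, collapse = ", "),
                 paste(offenders, collapse = ", ")))
  }
  has_sub <- "subcategory" %in% names(genes)
  needs_sub <- nrow(plan$drop_subcategories) > 0L ||
    nrow(plan$merge_into_mix) > 0L
  if (needs_sub && !has_sub) {
    stop("plan acts on subcategories but gene table has no 'subcategory' column")
  }
  key <- function(df) paste(df$category, df$subcategory, sep = "\t")

  drop_cat <- genes$category %in% plan$drop_categories
  drop_sub <- if (has_sub) {
    key(genes) %in% key(plan$drop_subcategories)
  } else rep(FALSE, nrow(genes))
  out <- genes[!(drop_cat | drop_sub), , drop = FALSE]
  if (has_sub && nrow(plan$merge_into_mix) > 0L) {
    hit <- key(out) %in% key(plan$merge_into_mix)
    out$category[hit] <- plan$mix_name
  }
  rownames(out) <- NULL
  list(genes = out,
       removed = c(dropped_category = sum(drop_cat),
                   dropped_subcategory = sum(drop_sub & !drop_cat)))
}

#' Default shipped ontology and rearrangement plan
#'
#' `default_ontology()` loads the curated category/subcategory table
#' shipped with the package: the sixteen trainable JCVI-CMR-style
#' categories plus "Signal transduction", with the subcategories the
#' default plan acts on. `default_plan()` loads the matching plan:
#' drop "Signal transduction" (too few single-category genes to train on),
#' drop the "Other" subcategories of "Cell envelope" and "Central
#' intermediary metabolism" (frequently misclassified), and merge the four
#' polysaccharide-biosynthesis-related subcategories into the Mix category.
#'
#' @return a `gl_ontology` / `rearrangement_plan`.
#' @export
default_ontology <- function() {
  read_ontology(system.file("extdata", "jcvi_cmr_ontology.tsv",
                            package = "genelit", mustWork = TRUE))
}

#' @rdname default_ontology
#' @export
default_plan <- function() {
  read_plan(system.file("extdata", "default_rearrangement_plan.json",
                        package = "genelit", mustWork = TRUE))
}
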