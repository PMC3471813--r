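#' Corpus acquisition configuration
#'
#' Eligibility and retrieval thresholds for per-gene abstract corpora:
#' a gene needs at least `min_abstracts` abstracts to be profiled, and at
#' most the `max_abstracts` most recent ones are kept.
#'
#' @param min_abstracts minimum abstracts for a gene to be eligible
#'   (default 5).
#' @param max_abstracts maximum abstracts retained per gene (default 50).
#' @param case_insensitive whether gene-name matching ignores case
#'   (default TRUE).
#' @return an object of class `corpus_config`.
#' @export
corpus_config <- function(min_abstracts = 5L, max_abstracts = 50L,
                          case_insensitive = TRUE) {
  min_abstracts <- as.integer(min_abstracts)
  max_abstracts <- as.integer(max_abstracts)
  if (min_abstracts < 1L || min_abstracts > max_abstracts) {
    stop("need 1 <= min_abstracts <= max_abstracts")
  }
  structure(list(min_abstracts = min_abstracts,
                 max_abstracts = max_abstracts,
                 case_insensitive = isTRUE(case_insensitive)),
            class = "corpus_config")
}

#' A gene's abstract corpus
#'
#' @param gene_name canonical gene name.
#' @param abstracts data.frame with columns `pmid` (unique, non-empty
#'   character), `date` (Date), `text` (non-empty character).
#' @return an object of class `gene_corpus` with fields `gene_name`,
#'   `abstracts`, `n`.
#' @export
gene_corpus <- function(gene_name, abstracts) {
  stopifnot(is.character(gene_name), length(gene_name) == 1L,
            nzchar(gene_name), is.data.frame(abstracts))
  need <- c("pmid", "date", "text")
  if (!all(need %in% names(abstracts))) {
    stop("abstracts must have columns pmid, date, text")
  }
  abstracts$pmid <- as.character(abstracts$pmid)
  abstracts$date <- as.Date(abstracts$date)
  abstracts$text <- as.character(abstracts$text)
  if (anyDuplicated(abstracts$pmid)) stop("duplicate pmid in corpus")
  if (any(!nzchar(abstracts$pmid))) stop("empty pmid in corpus")
  if (any(!nzchar(abstracts$text))) stop("empty abstract text in corpus")
  rownames(abstracts) <- NULL
  structure(list(gene_name = gene_name,
                 abstracts = abstracts[, need],
                 n = nrow(abstracts)),
            class = "gene_corpus")
}

#' @export
print.gene_corpus <- function(x, ...) {
  cat(sprintf("<gene_corpus> '%s': %d abstracts\n", x$gene_name, x$n))
  invisible(x)
}

#' Marker for a gene with too little literature
#'
#' @param gene_name gene name.
#' @param count number of abstracts found (below the eligibility minimum).
#' @return an object of class `ineligible_gene`.
#' @export
ineligible_gene <- function(gene_name, count) {
  structure(list(gene_name = gene_name, count = as.integer(count)),
            class = "ineligible_gene")
}

#' @rdname ineligible_gene
#' @param x object to test.
#' @export
is_ineligible <- function(x) inherits(x, "ineligible_gene")

#' Offline abstract provider backed by a fixture table
#'
#' Wraps a data.frame (or JSON-lines corpus file) with columns
#' `gene`, `pmid`, `date`, `text` as an abstract source for
#' [fetch_abstracts()]. Matching on gene name is exact (optionally
#' case-insensitive), which keeps fixture retrieval deterministic;
#' approximate matching is a property of the live PubMed engine only.
#'
#' @param store data.frame with columns `gene`, `pmid`, `date`, `text`,
#'   or the path of a JSON-lines corpus file in that record format.
#' @return an object of class `abstract_provider`.
#' @export
offline_provider <- function(store) {
  if (is.character(store) && length(store) == 1L) {
    store <- .read_corpus_records(store)
  }
  stopifnot(is.data.frame(store),
            all(c("gene", "pmid", "date", "text") %in% names(store)))
  store$date <- as.Date(store$date)
  force(store)
  structure(
    list(
      kind = "offline",
      get = function(gene_name, case_insensitive = TRUE) {
        hit <- if (case_insensitive) {
          tolower(store$gene) == tolower(gene_name)
        } else {
          store$gene == gene_name
        }
        store[hit, c("pmid", "date", "text"), drop = FALSE]
      }
    ),
    class = "abstract_provider"
  )
}

#' Live PubMed abstract provider (NCBI E-utilities)
#'
#' Queries esearch/efetch over HTTPS. Requires a contact email (NCBI usage
#' policy) and rate-limits requests. Transport failures signal a condition
#' of class `genelit_transport_error`, distinct from gene ineligibility, so
#' callers can retry. Needs the `xml2` package and network access; the rest
#' of the pipeline is fully testable offline through [offline_provider()].
#'
#' @param email contact email sent with every request (mandatory).
#' @param api_key optional NCBI API key.
#' @param query_template `sprintf` template applied to the gene name to
#'   build the PubMed query; default queries the raw name with no field
#'   qualifier.
#' @param delay seconds to sleep between requests (default 0.4).
#' @return an object of class `abstract_provider`.
#' @export
entrez_provider <- function(email, api_key = NULL, query_template = "%s",
                            delay = 0.4) {
  if (missing(email) || !is.character(email) || !nzchar(email)) {
    stop("entrez_provider() requires a contact email")
  }
  if (!requireNamespace("xml2", quietly = TRUE)) {
    stop("entrez_provider() requires the xml2 package")
  }
  base <- "https://eutils.ncbi.nlm.nih.gov/entrez/eutils"
  fetch_xml <- function(url) {
    Sys.sleep(delay)
    tryCatch(xml2::read_xml(url), error = function(e) {
      stop(structure(
        class = c("genelit_transport_error", "error", "condition"),
        list(message = paste0("E-utilities request failed: ",
                              conditionMessage(e)),
             call = NULL)))
    })
  }
  structure(
    list(
      kind = "entrez",
      get = function(gene_name, case_insensitive = TRUE) {
        query <- utils::URLencode(sprintf(query_template, gene_name),
                                  reserved = TRUE)
        key <- if (is.null(api_key)) "" else paste0("&api_key=", api_key)
        ids_doc <- fetch_xml(sprintf(
          "%s/esearch.fcgi?db=pubmed&term=%s&retmax=10000&email=%s%s",
          base, query, utils::URLencode(email, reserved = TRUE), key))
        ids <- xml2::xml_text(xml2::xml_find_all(ids_doc, "//IdList/Id"))
        if (length(ids) == 0L) {
          return(data.frame(pmid = character(0), date = as.Date(character(0)),
                            text = character(0)))
        }
        art <- fetch_xml(sprintf(
          "%s/efetch.fcgi?db=pubmed&id=%s&retmode=xml&email=%s%s",
          base, paste(ids, collapse = ","),
          utils::URLencode(email, reserved = TRUE), key))
        nodes <- xml2::xml_find_all(art, "//PubmedArticle")
        recs <- lapply(nodes, function(nd) {
          pmid <- xml2::xml_text(xml2::xml_find_first(nd, ".//PMID"))
          title <- xml2::xml_text(xml2::xml_find_first(nd, ".//ArticleTitle"))
          abst <- paste(xml2::xml_text(
            xml2::xml_find_all(nd, ".//Abstract/AbstractText")),
            collapse = " ")
          yr <- xml2::xml_text(xml2::xml_find_first(
            nd, ".//PubDate/Year | .//PubDate/MedlineDate"))
          yr <- sub("^([0-9]{4}).*", "\\1", yr)
          if (!grepl("^[0-9]{4}$", yr)) yr <- "1900"
          data.frame(pmid = pmid,
                     date = as.Date(paste0(yr, "-01-01")),
                     text = trimws(paste(title, abst)),
                     stringsAsFactors = FALSE)
        })
        out <- do.call(rbind, recs)
        out[nzchar(out$text) & nzchar(out$pmid), , drop = FALSE]
      }
    ),
    class = "abstract_provider"
  )
}

#' Fetch a gene's abstract corpus
#'
#' Retrieves all abstracts matching the gene name from the provider, and if
#' at least `min_abstracts` are found keeps the `max_abstracts` most recent
#' ones (publication date descending, ties broken by descending PMID).
#' Otherwise returns an ineligibility marker carrying the observed count.
#'
#' @param gene_name non-empty gene name.
#' @param config a [corpus_config()].
#' @param source an `abstract_provider` ([offline_provider()] or
#'   [entrez_provider()]).
#' @return a `gene_corpus`, or an `ineligible_gene` marker.
#' @export
fetch_abstracts <- function(gene_name, config = corpus_config(), source) {
  if (!is.character(gene_name) || length(gene_name) != 1L ||
      !nzchar(gene_name)) {
    stop("gene_name must be a non-empty string")
  }
  stopifnot(inherits(config, "corpus_config"),
            inherits(source, "abstract_provider"))
  hits <- source$get(gene_name, case_insensitive = config$case_insensitive)
  if (nrow(hits) < config$min_abstracts) {
    return(ineligible_gene(gene_name, nrow(hits)))
  }
  pm_num <- suppressWarnings(as.numeric(hits$pmid))
  pm_key <- if (anyNA(pm_num)) xtfrm(hits$pmid) else pm_num
  ord <- order(as.Date(hits$date), pm_key, decreasing = TRUE)
  keep <- hits[ord[seq_len(min(nrow(hits), config$max_abstracts))], ,
               drop = FALSE]
  gene_corpus(gene_name, keep)
}

#' Fetch corpora for a vector of gene names
#'
#' @param genes character vector of gene names (empty names yield
#'   ineligibility markers with count 0 rather than errors).
#' @inheritParams fetch_abstracts
#' @return named list of `gene_corpus` / `ineligible_gene`, one per gene.
#' @export
fetch_corpora <- function(genes, config = corpus_config(), source) {
  out <- lapply(genes, function(g) {
    if (!nzchar(g)) return(ineligible_gene(g, 0L))
    fetch_abstracts(g, config, source)
  })
  names(out) <- genes
  out
}

#' Filter a labeled gene table against corpus eligibility
#'
#' Retains genes that (a) have a non-empty name and (b) have an eligible
#' corpus, and reports how many genes each step removed.
#'
#' @param genes data.frame with at least a `gene` column (typically also
#'   `category`).
#' @param corpora named list mapping gene name to `gene_corpus` or
#'   `ineligible_gene` (genes absent from the map count as ineligible).
#' @return list with `genes` (the filtered table) and `removed`
#'   (named integer vector: `unnamed`, `too_few_abstracts`).
#' @export
filter_gene_table <- function(genes, corpora) {
  stopifnot(is.data.frame(genes), "gene" %in% names(genes))
  named <- !is.na(genes$gene) & nzchar(genes$gene)
  n_unnamed <- sum(!named)
  kept <- genes[named, , drop = FALSE]
  eligible <- vapply(kept$gene, function(g) {
    inherits(corpora[[g]], "gene_corpus")
  }, logical(1))
  n_too_few <- sum(!eligible)
  out <- kept[eligible, , drop = FALSE]
  rownames(out) <- NULL
  list(genes = out,
       removed = c(unnamed = n_unnamed, too_few_abstracts = n_too_few))
}

# parse JSON-lines {gene, pmid, date, text} records into a flat data.frame
.read_corpus_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines_keep <- which(nzchar(trimws(lines)))
  recs <- lapply(lines_keep, function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) {
      stop(sprintf("malformed corpus record at line %d of %s: %s",
                   i, path, conditionMessage(e)), call. = FALSE)
    })
    need <- c("gene", "pmid", "date", "text")
    miss <- setdiff(need, names(rec))
    if (length(miss) > 0L) {
      stop(sprintf("corpus record at line %d of %s missing field(s): %s",
                   i, path, paste(miss, collapse = ", ")), call. = FALSE)
    }
    data.frame(gene = as.character(rec$gene), pmid = as.character(rec$pmid),
               date = as.character(rec$date), text = as.character(rec$text),
               stringsAsFactors = FALSE)
  })
  if (length(recs) == 0L) {
    return(data.frame(gene = character(0), pmid = character(0),
                      date = character(0), text = character(0)))
  }
  out <- do.call(rbind, recs)
  out$date <- as.Date(out$date)
  out
}

#' Read and write gene corpora as JSON-lines
#'
#' The on-disk corpus format is JSON-lines with one record per abstract:
#' `{"gene": ..., "pmid": ..., "date": "YYYY-MM-DD", "text": ...}`.
#' `write_corpus_file()` followed by `read_corpus_file()` reproduces gene
#' names, PMIDs, dates, and texts exactly.
#'
#' @param path file path.
#' @return `read_corpus_file()`: a named list of `gene_corpus`, one per
#'   gene, in first-appearance order.
#' @export
read_corpus_file <- function(path) {
  recs <- .read_corpus_records(path)
  if (nrow(recs) == 0L) return(structure(list(), names = character(0)))
  genes <- unique(recs$gene)
  out <- lapply(genes, function(g) {
    gene_corpus(g, recs[recs$gene == g, c("pmid", "date", "text")])
  })
  names(out) <- genes
  out
}

#' @rdname read_corpus_file
#' @param corpora named list of `gene_corpus` (ineligible markers are
#'   skipped).
#' @export
write_corpus_file <- function(corpora, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cp in corpora) {
    if (!inherits(cp, "gene_corpus")) next
    for (i in seq_len(cp$n)) {
      writeLines(jsonlite::toJSON(
        list(gene = cp$gene_name,
             pmid = cp$abstracts$pmid[i],
             date = format(cp$abstracts$date[i]),
             text = cp$abstracts$text[i]),
        auto_unbox = TRUE), con)
    }
  }
  invisible(path)
}

#' Read and write labeled gene tables
#'
#' TSV with header; columns `gene`, `category`, and optionally
#' `subcategory`.
#'
#' @param path file path.
#' @return a data.frame.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!"gene" %in% names(df)) stop("gene table must have a 'gene' column")
  df
}

#' @rdname read_gene_table
#' @param genes data.frame to write.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
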