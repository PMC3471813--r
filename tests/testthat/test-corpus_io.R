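test_that("fetch keeps the most recent abstracts up to the maximum", {
  src <- offline_provider(fixture_store())
  cp <- fetch_abstracts("recA", corpus_config(5, 50), src)
  expect_s3_class(cp, "gene_corpus")
  expect_equal(cp$n, 50)
  # newest first; the two abstracts sharing the newest date are ordered by
  # descending pmid
  expect_true(all(diff(as.numeric(cp$abstracts$date)) <= 0))
  newest <- cp$abstracts[cp$abstracts$date == max(cp$abstracts$date), ]
  expect_identical(newest$pmid, c("1060", "1059"))
  # the 10 oldest of the 60 are the ones cut
  all_recs <- fixture_store()
  dropped <- setdiff(all_recs$pmid[all_recs$gene == "recA"],
                     cp$abstracts$pmid)
  expect_length(dropped, 10)
  expect_identical(sort(dropped), sort(as.character(1000 + 1:10)))
})

test_that("eligibility boundary is inclusive at the minimum", {
  src <- offline_provider(fixture_store())
  too_few <- fetch_abstracts("orfX", corpus_config(5, 50), src)
  expect_true(is_ineligible(too_few))
  expect_equal(too_few$count, 4)
  exactly5 <- fetch_abstracts("lexA", corpus_config(5, 50), src)
  expect_s3_class(exactly5, "gene_corpus")
  expect_equal(exactly5$n, 5)
})

test_that("gene-name matching is case insensitive by default", {
  src <- offline_provider(fixture_store())
  expect_equal(fetch_abstracts("RECA", corpus_config(), src)$n, 50)
  expect_true(is_ineligible(
    fetch_abstracts("RECA", corpus_config(case_insensitive = FALSE), src)))
})

test_that("fetch respects min/max bounds for arbitrary configs", {
  src <- offline_provider(fixture_store())
  for (mx in c(1, 5, 20, 60, 100)) {
    cfg <- corpus_config(1, mx)
    cp <- fetch_abstracts("recA", cfg, src)
    expect_lte(cp$n, mx)
  }
  expect_error(corpus_config(0, 50))
  expect_error(corpus_config(10, 5))
  expect_error(fetch_abstracts("", corpus_config(), src), "non-empty")
})

test_that("fetch is deterministic for a fixed fixture store", {
  src <- offline_provider(fixture_store())
  a <- fetch_abstracts("recA", corpus_config(), src)
  b <- fetch_abstracts("recA", corpus_config(), src)
  expect_identical(a, b)
})

test_that("gene table filtering counts removals by cause", {
  genes <- data.frame(
    gene = c("g1", "g2", "", NA, "g5", "g6", "g7", "g8", "g9", "g10"),
    category = paste0("c", 1:10), stringsAsFactors = FALSE)
  mk <- function(g) gene_corpus(g, data.frame(
    pmid = as.character(1:5), date = as.Date("2020-01-01") + 1:5,
    text = paste("text", 1:5)))
  corpora <- c(
    stats::setNames(lapply(c("g1", "g2", "g5", "g6", "g7"), mk),
                    c("g1", "g2", "g5", "g6", "g7")),
    list(g8 = ineligible_gene("g8", 2), g9 = ineligible_gene("g9", 0),
         g10 = ineligible_gene("g10", 4)))
  res <- filter_gene_table(genes, corpora)
  expect_equal(nrow(res$genes), 5)
  expect_equal(res$removed, c(unnamed = 2, too_few_abstracts = 3))

  all_ok <- filter_gene_table(genes[1:2, ], corpora)
  expect_identical(all_ok$genes$gene, c("g1", "g2"))
  empty <- filter_gene_table(genes[0, ], corpora)
  expect_equal(nrow(empty$genes), 0)
  expect_equal(unname(empty$removed), c(0, 0))
})

test_that("corpus files round-trip through JSON-lines", {
  src <- offline_provider(fixture_store())
  corpora <- fetch_corpora(c("recA", "lexA", "orfX"), corpus_config(), src)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus_file(corpora, path)
  back <- read_corpus_file(path)
  expect_identical(names(back), c("recA", "lexA"))  # ineligible skipped
  for (g in names(back)) {
    expect_identical(back[[g]]$abstracts, corpora[[g]]$abstracts)
    expect_identical(back[[g]]$n, corpora[[g]]$n)
  }
})

test_that("malformed corpus records fail with the line number", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  ok <- '{"gene":"x","pmid":"1","date":"2020-01-01","text":"t"}'
  writeLines(c(ok, '{"gene":"x","date":"2020-01-02","text":"t"}'), path)
  expect_error(read_corpus_file(path), "line 2.*pmid")
  writeLines(c(ok, "{not json"), path)
  expect_error(read_corpus_file(path), "line 2")
})

test_that("an empty corpus file yields an empty map", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(character(0), path)
  expect_length(read_corpus_file(path), 0)
})

test_that("corpus invariants are enforced by the constructor", {
  df <- data.frame(pmid = c("1", "1"), date = as.Date("2020-01-01") + 0:1,
                   text = c("a", "b"))
  expect_error(gene_corpus("g", df), "duplicate pmid")
  df2 <- data.frame(pmid = c("1", "2"), date = as.Date("2020-01-01") + 0:1,
                    text = c("a", ""))
  expect_error(gene_corpus("g", df2), "empty abstract text")
})
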