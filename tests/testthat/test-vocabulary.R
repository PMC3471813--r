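test_that("optimized cutoff follows t + k/n and decreases with n", {
  p <- cutoff_params()
  expect_equal(optimized_cutoff(50, p), 0.18)
  expect_equal(optimized_cutoff(5, p), 0.45)
  expect_equal(optimized_cutoff(1e9, p), 0.15, tolerance = 1e-6)
  expect_true(all(diff(optimized_cutoff(1:100, p)) < 0))
  expect_error(optimized_cutoff(0, p))
})

# three genes with n = 5, 10, 50 (cutoffs 0.45, 0.30, 0.18) and six
# hand-chosen terms; expected set frozen from the brute-force oracle
test_that("disclosure applies the promiscuity and support rules exactly", {
  g1 <- tfv("g1", 5, promisc = 1.0, strong = 0.6, border = 0.5,
            lonely = 0.8, everywhere = 1.0)
  g2 <- tfv("g2", 10, promisc = 1.0, strong = 0.4, border = 0.2,
            weak = 0.25, everywhere = 1.0)
  g3 <- tfv("g3", 50, promisc = 1.0, strong = 0.1, border = 0.3,
            weak = 0.15, everywhere = 1.0)
  bl <- bprof(100, promisc = 0.30, border = 0.04, everywhere = 0.06)
  params <- cutoff_params()
  got <- disclose_vocabulary(list(g1, g2, g3), bl, params)
  # promisc: baseline 0.30 > 0.05 -> out, despite freq 1 everywhere
  # strong:  excess 0.6>0.45 (g1), 0.4>0.30 (g2) -> support 2 -> in
  # border:  excess 0.46>0.45 (g1), 0.16<0.30, 0.26>0.18 (g3) -> in
  # lonely:  support 1 < min_genes -> out
  # weak:    0.25<0.30, 0.15<0.18 -> support 0 -> out
  # everywhere: baseline 0.06 > 0.05 -> out
  expect_identical(got$terms, c("border", "strong"))
  expect_identical(got$terms,
                   oracle_vocabulary(list(g1, g2, g3), bl, params))
  # gene-specific terms become usable at min_genes = 1
  lax <- disclose_vocabulary(list(g1, g2, g3), bl,
                             cutoff_params(min_genes = 1))
  expect_true("lonely" %in% lax$terms)
  expect_false("promisc" %in% lax$terms)
})

test_that("disclosure matches the brute-force oracle on random instances", {
  make_instance <- function(n_genes, n_terms, seed) {
    set.seed(seed)
    terms <- paste0("t", sprintf("%04d", seq_len(n_terms)))
    vectors <- lapply(seq_len(n_genes), function(i) {
      n <- sample(5:50, 1)
      k <- sample.int(n_terms, sample(5:min(60, n_terms), 1))
      tf <- sample.int(n, length(k), replace = TRUE) / n
      structure(list(gene_name = paste0("g", i),
                     freqs = stats::setNames(tf, terms[k])[order(terms[k])],
                     n = n), class = "tf_vector")
    })
    base_idx <- sample.int(n_terms, n_terms %/% 2)
    bl <- bprof(200, stats::setNames(stats::runif(length(base_idx), 0, 0.2),
                                     terms[base_idx]))
    list(vectors = vectors, baseline = bl)
  }
  for (seed in 1:3) {
    inst <- make_instance(30, 120, seed)
    params <- cutoff_params()
    expect_identical(
      disclose_vocabulary(inst$vectors, inst$baseline, params)$terms,
      oracle_vocabulary(inst$vectors, inst$baseline, params))
  }
})

test_that("both filters are anti-monotone in their parameters", {
  set.seed(42)
  terms <- paste0("w", 1:50)
  vectors <- lapply(1:15, function(i) {
    n <- sample(5:50, 1)
    k <- sample.int(50, 20)
    tfv(paste0("g", i), n,
        stats::setNames(sample.int(n, 20, replace = TRUE) / n, terms[k]))
  })
  bl <- bprof(100, stats::setNames(stats::runif(25, 0, 0.15), terms[1:25]))
  base <- disclose_vocabulary(vectors, bl, cutoff_params())$terms
  tighter_bc <- disclose_vocabulary(vectors, bl,
                                    cutoff_params(baseline_cutoff = 0.02))$terms
  more_support <- disclose_vocabulary(vectors, bl,
                                      cutoff_params(min_genes = 4))$terms
  expect_true(all(tighter_bc %in% base))
  expect_true(all(more_support %in% base))
  # every vocabulary term is re-attestable above its cutoff in >= min_genes
  for (w in base) {
    support <- sum(vapply(vectors, function(v) {
      f <- if (w %in% names(v$freqs)) v$freqs[[w]] else 0
      b <- if (w %in% names(bl$freqs)) bl$freqs[[w]] else 0
      f - b > optimized_cutoff(v$n, cutoff_params())
    }, logical(1)))
    expect_gte(support, 2)
  }
})

test_that("projection aligns rows to the vocabulary order", {
  vocab <- structure(list(terms = c("alpha", "beta", "gamma"),
                          provenance = NULL), class = "vocabulary")
  v_disjoint <- tfv("g1", 10, other = 0.5)
  expect_equal(unname(project(v_disjoint, vocab)), c(0, 0, 0))
  v_subset <- tfv("g2", 10, beta = 0.3, alpha = 0.7)
  expect_equal(project(v_subset, vocab),
               c(alpha = 0.7, beta = 0.3, gamma = 0))
  # random pair vs per-term lookup oracle
  set.seed(9)
  terms <- sample(letters, 10)
  vocab2 <- structure(list(terms = sort(terms[1:6]), provenance = NULL),
                      class = "vocabulary")
  v <- tfv("g3", 20, stats::setNames(stats::runif(5, 0.05, 1), terms[4:8]))
  row <- project(v, vocab2)
  for (w in vocab2$terms) {
    expect_equal(unname(row[w]),
                 if (w %in% names(v$freqs)) v$freqs[[w]] else 0)
  }
})

test_that("projected matrices carry gene rows and a vocabulary hash", {
  vocab <- structure(list(terms = c("aa", "bb"), provenance = NULL),
                     class = "vocabulary")
  mat <- project_matrix(list(tfv("g1", 5, aa = 0.4), tfv("g2", 5, bb = 1)),
                        vocab)
  expect_identical(rownames(mat), c("g1", "g2"))
  expect_identical(colnames(mat), c("aa", "bb"))
  expect_identical(attr(mat, "vocab_hash"), vocabulary_hash(vocab))
})

test_that("vocabulary files round-trip terms and provenance", {
  g1 <- tfv("g1", 5, alpha = 0.9, beta = 0.8)
  g2 <- tfv("g2", 10, alpha = 0.8, beta = 0.7)
  vocab <- disclose_vocabulary(list(g1, g2), bprof(50, zz = 0.5),
                               cutoff_params())
  path <- withr::local_tempfile(fileext = ".txt")
  write_vocabulary(vocab, path)
  back <- read_vocabulary(path)
  expect_identical(back$terms, vocab$terms)
  expect_equal(back$provenance$params$t, 0.15)
  expect_equal(back$provenance$params$min_genes, 2L)
  expect_identical(back$provenance$genes_hash, vocab$provenance$genes_hash)
})
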