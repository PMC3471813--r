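toy_ontology <- function() {
  ontology(list(A = c("a1", "a2"), B = c("b1")))
}

test_that("rearrangement merges, drops, and preserves the hierarchy", {
  plan <- rearrangement_plan(
    merge_into_mix = data.frame(category = c("A", "B"),
                                subcategory = c("a2", "b1")),
    mix_name = "Mix")
  out <- rearrange(toy_ontology(), plan)
  expect_setequal(out$categories, c("A", "Mix"))
  expect_identical(out$subcategories$A, "a1")
  expect_setequal(out$subcategories$Mix, c("a2", "b1"))

  expect_identical(rearrange(toy_ontology(), rearrangement_plan()),
                   toy_ontology())

  dropA <- rearrange(toy_ontology(),
                     rearrangement_plan(drop_categories = "A"))
  expect_identical(dropA$categories, "B")
})

test_that("plans referencing unknown items fail naming the offender", {
  expect_error(rearrange(toy_ontology(),
                         rearrangement_plan(drop_categories = "Z")), "Z")
  bad <- rearrangement_plan(
    merge_into_mix = data.frame(category = "A", subcategory = "zz"))
  expect_error(rearrange(toy_ontology(), bad), "zz")
  expect_error(
    rearrangement_plan(drop_categories = c("A", "A")), "twice")
})

test_that("gene relabeling follows the plan and reports removals", {
  genes <- data.frame(
    gene = c("x1", "x2", "x3", "x4"),
    category = c("A", "A", "B", "A"),
    subcategory = c("a1", "a2", "b1", "a1"),
    stringsAsFactors = FALSE)
  plan <- rearrangement_plan(
    merge_into_mix = data.frame(category = "A", subcategory = "a2"),
    mix_name = "Mix category")
  res <- relabel_genes(genes, toy_ontology(), plan)
  expect_identical(res$genes$category, c("A", "Mix category", "B", "A"))
  expect_equal(unname(res$removed), c(0, 0))

  res2 <- relabel_genes(genes, toy_ontology(),
                        rearrangement_plan(drop_categories = "A"))
  expect_identical(res2$genes$gene, "x3")
  expect_equal(res2$removed[["dropped_category"]], 3)

  genes_bad <- within(genes, category[1] <- "Unknown cat")
  expect_error(relabel_genes(genes_bad, toy_ontology(), plan), "x1")
})

test_that("category counts obey the rearrangement identity", {
  # |after| = |before| - |dropped| + 1 when the plan merges something
  ont <- ontology(list(A = c("a1", "a2"), B = c("b1", "b2"),
                       C = c("c1"), D = c("d1")))
  plan <- rearrangement_plan(
    drop_categories = c("C", "D"),
    merge_into_mix = data.frame(category = "B", subcategory = "b2"))
  out <- rearrange(ont, plan)
  expect_equal(length(out$categories), length(ont$categories) - 2 + 1)
})

test_that("the shipped default plan yields the 16-category ontology", {
  ont <- default_ontology()
  plan <- default_plan()
  out <- rearrange(ont, plan)
  expect_equal(length(out$categories), 16)
  expect_true("Mix category" %in% out$categories)
  expect_false("Signal transduction" %in% out$categories)
  expect_setequal(out$subcategories[["Mix category"]],
                  c("Biosynthesis and degradation of surface polysaccharides and lipopolysaccharides",
                    "Biosynthesis of murein sacculus and peptidoglycan",
                    "Biosynthesis and degradation of polysaccharides",
                    "Sugar-nucleotide biosynthesis and conversions"))
  # every surviving non-mix subcategory keeps its original parent
  for (cat in setdiff(out$categories, "Mix category")) {
    expect_true(all(out$subcategories[[cat]] %in%
                      ont$subcategories[[cat]]))
  }
})

test_that("ontologies and plans round-trip through their file formats", {
  ont <- toy_ontology()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ontology(ont, path)
  expect_identical(read_ontology(path), ont)

  plan <- rearrangement_plan(
    drop_categories = "B",
    merge_into_mix = data.frame(category = "A", subcategory = "a2"),
    mix_name = "Mix")
  ppath <- withr::local_tempfile(fileext = ".json")
  write_plan(plan, ppath)
  back <- read_plan(ppath)
  expect_identical(back$drop_categories, plan$drop_categories)
  expect_identical(back$merge_into_mix, plan$merge_into_mix)
  expect_identical(back$mix_name, plan$mix_name)
})
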