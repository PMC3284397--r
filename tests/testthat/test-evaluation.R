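# A small tree-consistent taxonomy: two genera in one phylum plus one
# genus in another, species 1:1 with strain.
eval_taxonomy <- function() {
  taxonomy_table(data.frame(
    taxon_id = c("a1", "a2", "b1", "c1"),
    strain = c("a1", "a2", "b1", "c1"),
    species = c("sp_a1", "sp_a2", "sp_b1", "sp_c1"),
    genus = c("gA", "gA", "gB", "gC"),
    family = c("fA", "fA", "fB", "fC"),
    order = c("oAB", "oAB", "oAB", "oC"),
    class = c("cAB", "cAB", "cAB", "cC"),
    phylum = c("p1", "p1", "p1", "p2"),
    superkingdom = rep("V", 4)))
}

pred_df <- function(ids, taxa) {
  data.frame(read_id = ids, best_taxon = taxa, stringsAsFactors = FALSE)
}

truth_df <- function(ids, taxa) {
  data.frame(read_id = ids, source_taxon = taxa, stringsAsFactors = FALSE)
}

test_that("rank_accuracy is exact on hand-counted cases", {
  tax <- eval_taxonomy()
  ids <- sprintf("r%02d", 1:4)
  perfect <- rank_accuracy(pred_df(ids, rep("a1", 4)),
                           truth_df(ids, rep("a1", 4)), tax)
  expect_true(all(perfect$accuracy == 1))
  expect_true(all(perfect$n_evaluable == 4L))

  # 10 reads: 7 exact, 2 same-genus different strain, 1 different phylum
  ids <- sprintf("r%02d", 1:10)
  truth <- truth_df(ids, rep("a1", 10))
  preds <- pred_df(ids, c(rep("a1", 7), "a2", "a2", "c1"))
  rep <- rank_accuracy(preds, truth, tax,
                       ranks = c("strain", "genus", "phylum"))
  expect_equal(rep$accuracy[rep$rank == "strain"], 0.7)
  expect_equal(rep$accuracy[rep$rank == "genus"], 0.9)
  expect_equal(rep$accuracy[rep$rank == "phylum"], 0.9)
  expect_true(all(rep$n_evaluable + rep$n_indeterminate == 10L))
})

test_that("UNKNOWN ranks and unclassified reads shrink the denominator", {
  tax <- taxonomy_table(data.frame(
    taxon_id = c("k1", "k2"), strain = c("k1", "k2"),
    species = c("s1", "s2"), genus = c("g1", "g1"),
    family = c("f1", "f1"), order = c("o1", ""),  # k2 order unknown
    class = c("c1", "c1"), phylum = c("p1", "p1"),
    superkingdom = c("V", "V")))
  ids <- sprintf("r%02d", 1:10)
  truth <- truth_df(ids, c(rep("k2", 3), rep("k1", 7)))
  preds <- pred_df(ids, rep("k1", 10))
  rep <- rank_accuracy(preds, truth, tax, ranks = "order")
  expect_equal(rep$n_evaluable, 7L)
  expect_equal(rep$n_indeterminate, 3L)

  # unclassified predictions are indeterminate, never wrong
  preds$best_taxon[1:2] <- NA
  rep2 <- rank_accuracy(preds, truth, tax, ranks = "phylum")
  expect_equal(rep2$n_evaluable, 8L)
  expect_equal(rep2$accuracy, 1)
})

test_that("rank_accuracy rejects predictions without truth rows", {
  tax <- eval_taxonomy()
  expect_error(
    rank_accuracy(pred_df("rX", "a1"), truth_df("rY", "a1"), tax),
    "absent from truth")
})

test_that("per-organism averaging weighs organisms equally", {
  tax <- eval_taxonomy()
  # a1: 8 reads all correct; b1: 2 reads, one correct
  ids <- sprintf("r%02d", 1:10)
  truth <- truth_df(ids, c(rep("a1", 8), rep("b1", 2)))
  preds <- pred_df(ids, c(rep("a1", 8), "b1", "a1"))
  rep <- rank_accuracy(preds, truth, tax, ranks = "strain")
  expect_equal(rep$accuracy, 0.9)                 # pooled
  expect_equal(rep$accuracy_per_organism, 0.75)   # mean(1, 0.5)
})

test_that("predominant_match_breakdown applies the strict 40% rule", {
  ids <- sprintf("r%03d", 1:100)
  truth <- truth_df(ids, rep("org1", 100))
  # 45 reads to X, the rest scattered
  preds <- pred_df(ids, c(rep("X", 45), rep(sprintf("y%02d", 1:55), 1)))
  row <- predominant_match_breakdown(preds, truth)
  expect_equal(row$predominant_match, "X")
  expect_equal(row$fraction, 0.45)
  expect_true(row$confident)

  self <- predominant_match_breakdown(pred_df(ids, rep("org1", 100)), truth)
  expect_equal(self$fraction, 1.0)
  expect_true(self$confident)

  # uniform spread over 5 taxa: modal fraction 0.20 is not > 0.40
  spread <- pred_df(ids, rep(sprintf("t%d", 1:5), each = 20))
  row3 <- predominant_match_breakdown(spread, truth)
  expect_equal(row3$fraction, 0.20)
  expect_false(row3$confident)
  expect_equal(row3$predominant_match, "t1")  # lexicographic tie-break

  # exactly at the threshold is not confident (strict inequality)
  at40 <- pred_df(ids, c(rep("X", 40), rep(sprintf("z%02d", 1:60), 1)))
  expect_false(predominant_match_breakdown(at40, truth)$confident)
})

test_that("compare_assignments measures per-rank agreement", {
  tax <- eval_taxonomy()
  ids <- sprintf("r%d", 1:4)
  a <- pred_df(ids, c("a1", "a1", "a2", "b1"))
  self <- compare_assignments(a, a, tax)
  expect_true(all(self$match == 1))
  expect_true(all(abs(self$match + self$mismatch + self$indeterminate - 1)
                  < 1e-12))

  # one of four reads differs at species but shares the genus
  b <- pred_df(ids, c("a1", "a2", "a2", "b1"))
  ab <- compare_assignments(a, b, tax, ranks = c("species", "genus"))
  expect_equal(ab$match[ab$rank == "species"], 0.75)
  expect_equal(ab$match[ab$rank == "genus"], 1.0)

  # symmetry
  ba <- compare_assignments(b, a, tax, ranks = c("species", "genus"))
  expect_equal(ab$match, ba$match)
  expect_equal(ab$mismatch, ba$mismatch)

  expect_error(compare_assignments(a, pred_df("zz", "a1"), tax),
               "share no read ids")
})

test_that("UNKNOWN labels and unclassified reads are indeterminate agreement", {
  tax <- taxonomy_table(data.frame(
    taxon_id = c("u", "v"), strain = c("u", "v"),
    species = c("su", "sv"), genus = c("g", "g"),
    family = c("f", "f"), order = c("o", "o"), class = c("c", "c"),
    phylum = c("", "pv"), superkingdom = c("V", "V")))
  ids <- sprintf("r%d", 1:4)
  a <- pred_df(ids, c("u", "v", "v", NA))
  b <- pred_df(ids, c("v", "v", "v", "v"))
  cmp <- compare_assignments(a, b, tax, ranks = "phylum")
  # r1: u vs v -> indeterminate (u phylum unknown); r4: NA -> indeterminate
  expect_equal(cmp$indeterminate, 0.5)
  expect_equal(cmp$match, 0.5)
})
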