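# Marker-based completeness/duplication scoring, the draft-quality rule,
# contaminant flagging and bin refinement.

toy_assignment <- function(bins) {
  tibble::tibble(
    scaffold_id = unlist(bins, use.names = FALSE),
    bin = rep(names(bins), lengths(bins)))
}

test_that("completeness arithmetic matches the stated rule", {
  asg <- toy_assignment(list(bin_001 = c("s1", "s2")))
  mk <- tibble::tibble(scaffold_id = rep(c("s1", "s2"), c(25, 15)),
                       marker_id = marker_set("bacteria")[1:40])
  q <- assess_bins(asg, mk, domain = "bacteria")
  expect_equal(q$completeness, 40 / 51)
  expect_equal(q$duplicated_marker_count, 0L)
  expect_true(q$draft_quality)
})

test_that("a bin with no markers has completeness zero and fails draft quality", {
  asg <- toy_assignment(list(bin_001 = "s1"))
  mk <- tibble::tibble(scaffold_id = character(), marker_id = character())
  q <- assess_bins(asg, mk, domain = "archaea")
  expect_equal(q$completeness, 0)
  expect_false(q$draft_quality)
})

test_that("the draft-quality boundary sits exactly at 70% completeness", {
  # 51 * 0.7 = 35.7: 35 markers miss draft quality, 36 reach it
  asg <- toy_assignment(list(bin_001 = "s1"))
  q35 <- assess_bins(asg, tibble::tibble(
    scaffold_id = "s1", marker_id = marker_set("bacteria")[1:35]),
    domain = "bacteria")
  q36 <- assess_bins(asg, tibble::tibble(
    scaffold_id = "s1", marker_id = marker_set("bacteria")[1:36]),
    domain = "bacteria")
  expect_false(q35$draft_quality)
  expect_lt(q35$completeness, 0.70)
  expect_true(q36$draft_quality)
  expect_gte(q36$completeness, 0.70)
})

test_that("excess duplication vetoes draft quality despite high completeness", {
  asg <- toy_assignment(list(bin_001 = "s1"))
  ids <- marker_set("bacteria")[1:39]           # completeness 39/51 ~ 0.76
  dup <- marker_set("bacteria")[1:6]            # 6/51 > 0.10 duplicated
  q <- assess_bins(asg, tibble::tibble(
    scaffold_id = "s1", marker_id = c(ids, dup)), domain = "bacteria")
  expect_gte(q$completeness, 0.70)
  expect_equal(q$duplicated_marker_count, 6L)
  expect_false(q$draft_quality)
})

test_that("domain auto-detection keeps the higher-completeness set", {
  asg <- toy_assignment(list(bin_001 = "s1"))
  mk <- tibble::tibble(scaffold_id = "s1",
                       marker_id = marker_set("archaea")[1:30])
  q <- assess_bins(asg, mk)
  expect_equal(q$domain, "archaea")
  expect_equal(q$completeness, 30 / 38)
  expect_error(assess_bins(asg, mk, domain = "eukarya"), "unknown domain")
  expect_error(
    assess_bins(asg, tibble::tibble(scaffold_id = "s1",
                                    marker_id = "not_a_marker")),
    "not_a_marker")
})

test_that("a perfectly recovered synthetic genome scores completeness 1", {
  com <- small_community(n_genomes = 2, seed = 31)
  truth <- com$truth$scaffold_genome
  asg <- tibble::tibble(scaffold_id = truth$scaffold_id,
                        bin = truth$genome_id)
  q <- assess_bins(asg, com$markers)
  expect_equal(q$completeness, c(1, 1))
  expect_equal(q$duplicated_marker_count, c(0L, 0L))
  expect_identical(
    q$domain[order(q$bin)],
    com$design$genomes$domain[order(com$design$genomes$genome_id)])

  # splitting a bin partitions its markers: completeness sums to 1
  g1 <- truth$scaffold_id[truth$genome_id == "G_001"]
  half <- seq_len(ceiling(length(g1) / 2))
  split_asg <- tibble::tibble(
    scaffold_id = g1,
    bin = ifelse(seq_along(g1) %in% half, "half_a", "half_b"))
  dom <- com$design$genomes$domain[com$design$genomes$genome_id == "G_001"]
  qs <- assess_bins(split_asg, com$markers, domain = dom)
  expect_equal(sum(qs$completeness), 1)
})

test_that("merging two genomes' bins produces duplicated markers", {
  com <- small_community(n_genomes = 2, seed = 32, overrides = list(
    domain = "bacteria"))
  merged <- tibble::tibble(
    scaffold_id = com$truth$scaffold_genome$scaffold_id, bin = "merged")
  q <- assess_bins(merged, com$markers, domain = "bacteria")
  expect_equal(q$completeness, 1)
  expect_equal(q$duplicated_marker_count, 51L)
  expect_false(q$draft_quality)
})

test_that("homogeneous bins yield no contaminant flags (zero-MAD skip)", {
  asg <- toy_assignment(list(b = paste0("s", 1:5)))
  sc <- tibble::tibble(scaffold_id = paste0("s", 1:5), gc = 0.5)
  cov <- normalize_coverage(
    tibble::tibble(scaffold_id = paste0("s", 1:5), s1 = 4, s2 = 4))
  taxa <- tibble::tibble(scaffold_id = paste0("s", 1:5), taxon = "PhylumA")
  flags <- flag_contaminants(asg, sc, cov, taxa)
  expect_equal(nrow(flags), 0)
})

test_that("a strongly displaced GC value is flagged with reason gc", {
  # oracle: direct median/MAD computation
  gc <- c(0.50, 0.51, 0.49, 0.50, 0.505, 0.80)
  stopifnot(abs(0.80 - median(gc)) > 3.5 * stats::mad(gc))
  asg <- toy_assignment(list(b = paste0("s", 1:6)))
  sc <- tibble::tibble(scaffold_id = paste0("s", 1:6), gc = gc)
  cov <- normalize_coverage(tibble::tibble(
    scaffold_id = paste0("s", 1:6), s1 = c(4, 4.1, 3.9, 4, 4.05, 4)))
  flags <- flag_contaminants(asg, sc, cov)
  expect_equal(flags$scaffold_id, "s6")
  expect_match(flags$reasons, "gc")
})

test_that("a minority taxon vote against a strict majority is flagged", {
  asg <- toy_assignment(list(b = paste0("s", 1:6)))
  sc <- tibble::tibble(scaffold_id = paste0("s", 1:6), gc = 0.5)
  cov <- normalize_coverage(tibble::tibble(
    scaffold_id = paste0("s", 1:6), s1 = 4))
  taxa <- tibble::tibble(scaffold_id = paste0("s", 1:6),
                         taxon = c(rep("PhylumA", 4), "PhylumB", NA))
  flags <- flag_contaminants(asg, sc, cov, taxa)
  expect_equal(flags$scaffold_id, "s5")
  expect_equal(flags$reasons, "taxonomy")

  # a 50/50 split is not a strict majority: no taxonomy flags
  taxa2 <- tibble::tibble(scaffold_id = paste0("s", 1:6),
                          taxon = rep(c("PhylumA", "PhylumB"), each = 3))
  expect_equal(nrow(flag_contaminants(asg, sc, cov, taxa2)), 0)
})

test_that("tiny bins are never flagged and member order does not matter", {
  asg3 <- toy_assignment(list(b = paste0("s", 1:3)))
  sc <- tibble::tibble(scaffold_id = paste0("s", 1:3), gc = c(0.5, 0.5, 0.9))
  cov <- normalize_coverage(tibble::tibble(
    scaffold_id = paste0("s", 1:3), s1 = c(4, 4, 400)))
  expect_equal(nrow(flag_contaminants(asg3, sc, cov)), 0)

  gc <- c(0.50, 0.51, 0.49, 0.50, 0.505, 0.80)
  asg <- toy_assignment(list(b = paste0("s", 1:6)))
  sc6 <- tibble::tibble(scaffold_id = paste0("s", 1:6), gc = gc)
  cov6 <- normalize_coverage(tibble::tibble(
    scaffold_id = paste0("s", 1:6), s1 = 4))
  f1 <- flag_contaminants(asg, sc6, cov6)
  perm <- c(4, 2, 6, 1, 5, 3)
  f2 <- flag_contaminants(asg[perm, ], sc6[perm, ], cov6)
  expect_identical(dplyr::arrange(f1, scaffold_id),
                   dplyr::arrange(f2, scaffold_id))
})

test_that("refinement moves exactly the flagged scaffolds to UNBINNED", {
  asg <- toy_assignment(list(bin_a = paste0("s", 1:6),
                             bin_b = paste0("t", 1:4)))
  expect_identical(refine_bins(asg, tibble::tibble(scaffold_id = character())),
                   asg)
  flags <- tibble::tibble(scaffold_id = c("s1", "s3", "s5"))
  ref <- refine_bins(asg, flags)
  expect_equal(sum(ref$bin == "bin_a"), 3)
  expect_equal(sum(ref$bin == "bin_b"), 4)
  expect_true(all(ref$bin[ref$scaffold_id %in% flags$scaffold_id] == "UNBINNED"))
  expect_setequal(ref$scaffold_id, asg$scaffold_id)
})

test_that("reassessment after refinement drops markers on removed scaffolds", {
  com <- small_community(n_genomes = 1, seed = 33, overrides = list(
    domain = "bacteria"))
  truth <- com$truth$scaffold_genome
  asg <- tibble::tibble(scaffold_id = truth$scaffold_id, bin = "G_001")
  drop <- truth$scaffold_id[1]
  ref <- refine_bins(asg, tibble::tibble(scaffold_id = drop))
  q <- assess_bins(ref, com$markers, domain = "bacteria")
  # consistency oracle: recompute expected completeness from annotations
  kept_markers <- unique(
    com$markers$marker_id[com$markers$scaffold_id != drop])
  expect_equal(q$completeness, length(kept_markers) / 51)
})
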