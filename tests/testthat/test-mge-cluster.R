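test_that("PLA is 1 for identical sequences and contained fragments", {
  withr::local_seed(301)
  a <- rnd_dna(3000)
  expect_equal(pairwise_pla(a, a), 1)
  half <- substring(a, 1, 1500)
  expect_equal(pairwise_pla(a, half), 1)          # shorter-denominator rule
  expect_equal(pairwise_pla(half, a), 1)          # symmetric
  expect_lt(pairwise_pla(a, half, denominator = "longer"), 0.6)
  # reverse-complemented copy still aligns fully
  expect_equal(pairwise_pla(a, rc_chr(a)), 1)
})

test_that("PLA of unrelated random sequences is near zero", {
  withr::local_seed(307)
  for (i in 1:5) {
    a <- rnd_dna(10000); b <- rnd_dna(10000)
    expect_lt(pairwise_pla(a, b), 0.05)
  }
})

test_that("PLA matches planted shared-block coverage", {
  withr::local_seed(311)
  for (i in 1:5) {
    a <- rnd_dna(5000)
    frac <- sample(c(0.2, 0.4, 0.6), 1)
    blk_len <- round(5000 * frac)
    blk <- substring(a, 1001, 1000 + blk_len)
    # b: the shared block flanked by unrelated sequence, same total length
    b <- paste0(rnd_dna(2000), blk, rnd_dna(3000 - blk_len))
    expect_equal(pairwise_pla(a, b), frac, tolerance = 0.02)
    # with a few substitutions in the block the footprint barely changes
    b_mut <- paste0(rnd_dna(2000), mutate_seq(blk, 0.01),
                    rnd_dna(3000 - blk_len))
    expect_equal(pairwise_pla(a, b_mut), frac, tolerance = 0.05)
  }
})

test_that("PLA matrix is symmetric with unit diagonal", {
  withr::local_seed(313)
  el <- data.frame(element_id = sprintf("e%d", 1:4),
                   sequence = replicate(4, rnd_dna(1500)))
  el$sequence[2] <- el$sequence[1]
  m <- pla_matrix(el)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 4))
  expect_equal(m["e1", "e2"], 1)
})

test_that("average linkage follows forced merge orders and tie rules", {
  d <- matrix(c(0, 0.1, 0.8,
                0.1, 0, 0.8,
                0.8, 0.8, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- average_linkage(d)
  expect_equal(hc$height, c(0.1, 0.8))
  expect_equal(sort(hc$merge[1, ]), c(-2L, -1L))

  # all-equal distances: a single chain at that height, smallest ids first
  deq <- matrix(0.5, 4, 4); diag(deq) <- 0
  dimnames(deq) <- list(letters[1:4], letters[1:4])
  hc2 <- average_linkage(deq)
  expect_equal(hc2$height, rep(0.5, 3))
  expect_equal(sort(hc2$merge[1, ]), c(-2L, -1L))  # ties: smallest members

  # asymmetric input is rejected
  bad <- d; bad[1, 2] <- 0.2
  expect_error(average_linkage(bad), "asymmetric")
})

test_that("merge heights agree with hclust average linkage", {
  withr::local_seed(317)
  for (n in c(6, 9, 12, 15)) {
    x <- matrix(stats::rnorm(n * 3), n)
    rownames(x) <- sprintf("e%02d", seq_len(n))
    d <- as.matrix(stats::dist(x))   # tie-free with probability 1
    hc <- average_linkage(d)
    ref <- stats::hclust(stats::as.dist(d), method = "average")
    expect_equal(hc$height, ref$height, tolerance = 1e-10)
    # cluster memberships at several heights agree up to relabelling
    for (h in stats::quantile(hc$height, c(0.25, 0.75))) {
      a <- stats::cutree(hc, h = h)
      b <- stats::cutree(ref, h = h)
      tab <- table(a, b) > 0
      expect_true(all(rowSums(tab) == 1) && all(colSums(tab) == 1))
    }
  }
})

test_that("Newick export follows the ultrametric convention, round-trips", {
  d <- matrix(c(0, 0.2, 0.2, 0), 2, 2, dimnames = list(c("A", "B"),
                                                       c("A", "B")))
  hc <- average_linkage(d)
  expect_equal(to_newick(hc), "(A:0.1,B:0.1);")
  expect_equal(to_newick(NULL, labels = "A"), "A;")

  withr::local_seed(331)
  x <- matrix(stats::rnorm(40), 20)
  rownames(x) <- sprintf("t%02d", 1:20)
  hc2 <- average_linkage(as.matrix(stats::dist(x)))
  tr <- ape::read.tree(text = to_newick(hc2))
  expect_equal(sort(tr$tip.label), sort(hc2$labels))
  # leaf depths reconstruct half the root merge height (ultrametric)
  depths <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)]
  expect_equal(unname(depths), rep(max(hc2$height) / 2, 20),
               tolerance = 1e-8)
})

test_that("dereplication collapses duplicates and keeps singletons apart", {
  withr::local_seed(337)
  s <- rnd_dna(2000)
  el <- data.frame(element_id = c("a", "b", "c"), sequence = c(s, s, s))
  dr <- dereplicate(el)
  expect_equal(length(dr$representatives), 1L)
  expect_equal(length(unique(dr$clusters$cluster_id)), 1L)

  el2 <- data.frame(element_id = c("a", "b"),
                    sequence = c(rnd_dna(2000), rnd_dna(2000)))
  dr2 <- dereplicate(el2)
  expect_equal(length(dr2$representatives), 2L)

  # representative is the longest member, ties to smallest id
  el3 <- data.frame(element_id = c("zz", "aa"),
                    sequence = c(substring(s, 1, 1000), s))
  dr3 <- dereplicate(el3)
  expect_equal(dr3$representatives, "aa")
})

test_that("dereplication recovers planted near-duplicate groups exactly", {
  withr::local_seed(347)
  el <- make_derep_groups(n_groups = 5L, per_group = 4L, len = 1500L)
  dr <- dereplicate(el, threshold = 0.95)
  expect_equal(length(dr$representatives), 5L)
  expect_equal(length(unique(paste(el$group, dr$clusters$cluster_id))), 5L)
})

test_that("dereplication is threshold-monotone", {
  withr::local_seed(349)
  el <- make_derep_groups(n_groups = 3L, per_group = 3L, len = 1200L,
                          mut_rate = 0.03)
  lo <- dereplicate(el, threshold = 0.8)
  hi <- dereplicate(el, threshold = 0.98)
  # clusters at the higher threshold refine those at the lower one
  for (cl in unique(hi$clusters$cluster_id)) {
    members <- hi$clusters$element_id[hi$clusters$cluster_id == cl]
    lo_ids <- lo$clusters$cluster_id[lo$clusters$element_id %in% members]
    expect_equal(length(unique(lo_ids)), 1L)
  }
})

test_that("predictions co-clustering with reference MGEs are flagged", {
  withr::local_seed(353)
  plasmid <- rnd_dna(4000)
  pro <- data.frame(
    element_id = c("pred1", "pred2"),
    sequence = c(substring(plasmid, 501, 3500), rnd_dna(3000)))
  refs <- data.frame(element_id = "plasA", sequence = plasmid,
                     category = "plasmid")
  fl <- cocluster_with_references(pro, refs, threshold = 0.95)
  expect_true(fl$coclusters_with_mge[fl$element_id == "pred1"])
  expect_false(fl$coclusters_with_mge[fl$element_id == "pred2"])
  # no references: nothing flagged
  none <- cocluster_with_references(pro, NULL)
  expect_false(any(none$coclusters_with_mge))
})
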