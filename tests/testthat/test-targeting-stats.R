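test_that("backbone coordinates subtract merged prophage lengths", {
  withr::local_seed(61)
  g <- make_genome(rnd_dna(1000))
  # scaled version of the 1 Mb / two 10 kb prophage arithmetic
  pro <- data.frame(genome_id = "g1", contig_id = "c1",
                    start = c(100L, 500L), end = c(200L, 600L),
                    label = c("p1", "p2"))
  bb <- backbone_coordinates(g, pro)
  expect_equal(bb$backbone_length, 800L)
  expect_equal(nrow(bb$segments), 3L)
  expect_equal(bb$segments$offset, c(0L, 100L, 400L))  # excised coordinates

  # no prophages: whole genome
  bb2 <- backbone_coordinates(g, pro[0, ])
  expect_equal(bb2$backbone_length, 1000L)

  # abutting prophages excise one block
  pro3 <- data.frame(genome_id = "g1", contig_id = "c1",
                     start = c(0L, 100L), end = c(100L, 200L),
                     label = c("p1", "p2"))
  bb3 <- backbone_coordinates(g, pro3)
  expect_equal(bb3$backbone_length, 800L)
  expect_equal(nrow(bb3$segments), 1L)

  # full coverage flags zero backbone
  pro4 <- data.frame(genome_id = "g1", contig_id = "c1",
                     start = 0L, end = 1000L, label = "p1")
  expect_true(backbone_coordinates(g, pro4)$zero_backbone)
})

test_that("bin counts tile regions with the partial-bin rule", {
  expect_equal(bin_counts(c(100L, 1100L, 1200L), 3500L),
               c(1L, 2L, 0L, 0L))                     # 1000/1000/1000/500
  expect_equal(bin_counts(integer(0), 4200L), rep(0L, 5))
  # trailing 50 bp < min_partial merges into the previous bin
  expect_equal(length(bin_counts(integer(0), 3050L)), 3L)
  expect_equal(bin_counts(c(3040L), 3050L), c(0L, 0L, 1L))
  # region shorter than one bin stays a single bin
  expect_equal(bin_counts(c(10L), 60L), 1L)
})

test_that("bin counts conserve match totals on random instances", {
  withr::local_seed(67)
  for (i in 1:100) {
    L <- sample(500:20000, 1)
    n <- stats::rpois(1, 10)
    starts <- sample.int(L, n, replace = TRUE) - 1L
    expect_equal(sum(bin_counts(starts, L)), n)
  }
})

test_that("Mann-Whitney worked example and degenerate cases", {
  r <- mann_whitney_one_sided(c(3, 2, 4), c(0, 0, 0, 0, 0, 1))
  expect_equal(unname(r$U), 18)   # all 18 pairwise comparisons favour x
  expect_lt(r$p, 0.05)

  same <- mann_whitney_one_sided(c(1, 1), c(1, 1))
  expect_equal(same$U, 2)         # n1*n2/2
  expect_gte(same$p, 0.5)

  expect_true(is.na(mann_whitney_one_sided(numeric(0), c(1, 2))$p))
})

test_that("exact branch equals exhaustive permutation enumeration", {
  withr::local_seed(71)
  for (n1 in 2:5) {
    for (n2 in 2:5) {
      x <- sample(1:100, n1)  # tie-free
      y <- sample(setdiff(1:100, x), n2)
      got <- mann_whitney_one_sided(x, y)
      oracle <- mwu_enum_oracle(x, y)
      expect_equal(unname(got$U), oracle$U)
      expect_equal(got$p, oracle$p, tolerance = 1e-12)
    }
  }
})

test_that("U is monotone in added prophage-compartment matches", {
  withr::local_seed(73)
  y <- stats::rpois(50, 0.3)
  x <- stats::rpois(10, 0.3)
  u0 <- mann_whitney_one_sided(x, y)$U
  for (i in 1:5) {
    j <- sample(10, 1)
    x[j] <- x[j] + 1L
    u1 <- mann_whitney_one_sided(x, y)$U
    expect_gte(u1, u0)
    u0 <- u1
  }
})

test_that("Holm-Sidak closed form, monotonicity and edge cases", {
  hs <- holm_sidak(c(0.01, 0.2, 0.04))
  expect_equal(hs$p_adjusted,
               c(1 - 0.99^3, 0.2, 1 - 0.96^2), tolerance = 1e-12)
  expect_equal(hs$reject, c(TRUE, FALSE, FALSE))

  expect_equal(holm_sidak(0.03)$p_adjusted, 0.03)   # m = 1: identity
  expect_equal(holm_sidak(rep(1, 4))$p_adjusted, rep(1, 4))
  expect_false(any(holm_sidak(rep(1, 4))$reject))
  expect_error(holm_sidak(c(0.5, 1.2)), "\\[0, 1\\]")

  withr::local_seed(79)
  for (i in 1:20) {
    p <- stats::runif(sample(2:12, 1))
    adj <- holm_sidak(p)$p_adjusted
    expect_true(all(adj >= p))                       # never below raw
    expect_true(all(diff(adj[order(p)]) >= -1e-15))  # monotone in sorted order
    # rejections are a prefix of the sorted p-values
    rej <- holm_sidak(p, alpha = 0.2)$reject
    ord <- order(p)
    expect_true(all(diff(rej[ord]) <= 0))
  }
})

test_that("prophage scoring reproduces the density arithmetic", {
  withr::local_seed(83)
  # 5 prophage matches / 10 kb prophage vs 49 backbone matches / 980 kb
  g_1mb <- make_genome(strrep("A", 990000))
  pro <- data.frame(genome_id = "g1", contig_id = "c1",
                    start = 0L, end = 10000L, label = "p1")
  m <- data.frame(
    spacer_id = sprintf("s%d", 1:54), donor_species = "B",
    target_genome_id = "g1", target_species = "A", contig_id = "c1",
    start = c(sample.int(10000, 5) - 1L, 10000L + sample.int(980000, 49)),
    strand = "+",
    compartment = rep(c("prophage", "backbone"), c(5, 49)),
    prophage_id = rep(c("p1", NA), c(5, 49)))
  m$end <- m$start + 30L
  res <- score_prophages(m, pro, list(g_1mb))
  expect_equal(res$prophage_density, 0.5)
  expect_equal(res$backbone_density, 0.05)
  expect_equal(res$ratio, 10)
  expect_equal(res$backbone_length_bp, 980000L)
})

test_that("zero matches yield zero densities and nothing significant", {
  g <- make_genome(strrep("A", 50000))
  pro <- data.frame(genome_id = "g1", contig_id = "c1",
                    start = 1000L, end = 6000L, label = "p1")
  m <- simulate_classified_matches(50000, pro, backbone_rate_per_kb = 0)
  res <- score_prophages(m, pro, list(g))
  expect_equal(res$prophage_density, 0)
  expect_true(is.na(res$ratio))
  expect_true(is.na(res$p_raw))       # no data, untestable
  expect_false(res$significant)
})

test_that("density identity and ratio sentinel hold on simulated runs", {
  withr::local_seed(89)
  g <- make_genome(strrep("A", 200000))
  pro <- data.frame(genome_id = "g1", contig_id = "c1",
                    start = c(10000L, 100000L), end = c(30000L, 120000L),
                    label = c("p1", "p2"))
  for (i in 1:10) {
    m <- simulate_classified_matches(200000, pro, backbone_rate_per_kb = 0.2,
                                     prophage_multiplier = c(5, 1))
    res <- score_prophages(m, pro, list(g))
    ok <- !is.na(res$ratio) & is.finite(res$ratio)
    expect_equal(res$ratio[ok],
                 (res$prophage_density / res$backbone_density)[ok])
    inf <- res$backbone_density == 0 & res$prophage_density > 0
    expect_true(all(is.infinite(res$ratio[inf])))
    # per-bin sums equal compartment counts (conservation)
    bb <- backbone_coordinates(g, pro)
    bm <- m[m$compartment == "backbone", ]
    expect_equal(sum(backbone_bins(bm, bb)), nrow(bm))
  }
})
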