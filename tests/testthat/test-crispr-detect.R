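test_that("planted repeats are found at their positions on both strands", {
  rep_seq <- "GATTACAGATTACAGATTACAGAT"  # 24 bp, not self-complementary
  withr::local_seed(2)
  g_seq <- rnd_dna(200)
  substr(g_seq, 11, 34) <- rep_seq
  substr(g_seq, 65, 88) <- rc_chr(rep_seq)
  g <- make_genome(g_seq)
  reps <- data.frame(repeat_id = "r1", sequence = rep_seq)
  occ <- find_repeat_occurrences(g, reps, max_mismatches = 0L)
  expect_equal(occ$start, c(10L, 64L))
  expect_equal(occ$strand, c("+", "-"))
})

test_that("no occurrences when nothing is within the mismatch budget", {
  g <- make_genome(strrep("A", 500))
  reps <- data.frame(repeat_id = "r1", sequence = strrep("C", 24))
  occ <- find_repeat_occurrences(g, reps, max_mismatches = 2L)
  expect_equal(nrow(occ), 0L)
  # repeat longer than contig: skipped silently
  tiny <- make_genome("ACGT")
  expect_equal(nrow(find_repeat_occurrences(tiny, reps, 2L)), 0L)
})

test_that("repeat occurrence search equals the naive Hamming-scan oracle", {
  withr::local_seed(31)
  for (rep_i in 1:6) {
    g_seq <- rnd_dna(8000)
    reps <- data.frame(repeat_id = sprintf("r%d", 1:3),
                       sequence = replicate(3, rnd_dna(30)))
    # plant noisy copies so the scan has something to find
    for (k in 1:4) {
      p <- sample(1:7900, 1)
      copy <- mutate_seq(reps$sequence[sample(3, 1)], 0.05)
      if (stats::runif(1) < 0.5) copy <- rc_chr(copy)
      substr(g_seq, p, p + 29) <- copy
    }
    g <- make_genome(g_seq)
    occ <- find_repeat_occurrences(g, reps, max_mismatches = 2L)
    for (j in 1:3) {
      oracle <- naive_hamming_scan(reps$sequence[j], g_seq, 2L)
      got <- occ[occ$repeat_id == reps$repeat_id[j], c("start", "strand")]
      rownames(got) <- NULL
      expect_equal(got, oracle)
    }
  }
})

test_that("arrays are called from repeat runs with in-range gaps", {
  occ <- data.frame(genome_id = "g1", contig_id = "c1",
                    start = c(10L, 64L, 118L), strand = "+",
                    repeat_id = "r1")
  rep_seq <- strrep("ACGT", 6)  # 24 bp, gaps of 30
  withr::local_seed(4)
  g_seq <- rnd_dna(200)
  for (s in occ$start) substr(g_seq, s + 1, s + 24) <- rep_seq
  g <- make_genome(g_seq)
  reps <- data.frame(repeat_id = "r1", sequence = rep_seq)
  res <- call_arrays(occ, reps, g, min_repeats = 3L,
                     spacer_len_range = c(20L, 50L))
  expect_equal(nrow(res$arrays), 1L)
  expect_equal(res$arrays$start, 10L)
  expect_equal(res$arrays$end, 118L + 24L)
  expect_equal(res$spacers$start, c(34L, 88L))
  expect_equal(res$spacers$end, c(64L, 118L))
  expect_equal(res$spacers$sequence,
               c(substring(g_seq, 35, 64), substring(g_seq, 89, 118)))

  # two repeats only: below min_repeats
  res2 <- call_arrays(occ[1:2, ], reps, g, min_repeats = 3L)
  expect_equal(nrow(res2$arrays), 0L)

  # a 500 bp gap splits the run; each piece must reach min_repeats alone
  occ3 <- data.frame(genome_id = "g1", contig_id = "c1",
                     start = c(10L, 64L, 118L, 642L, 696L), strand = "+",
                     repeat_id = "r1")
  g_seq3 <- rnd_dna(1000)
  for (s in occ3$start) substr(g_seq3, s + 1, s + 24) <- rep_seq
  res3 <- call_arrays(occ3, reps, make_genome(g_seq3), min_repeats = 3L)
  expect_equal(nrow(res3$arrays), 1L)   # only the first run of 3 survives
  expect_equal(res3$arrays$n_repeats, 3L)
})

test_that("array regions rebuild byte-for-byte from repeat plus spacers", {
  cm <- generate_community(community_config(
    n_species = 2L, genomes_per_species = 1L, genome_length_bp = 40000L,
    prophages_per_genome = 0L, arrays_per_genome = 2L,
    repeats_per_array = 6L, prophage_target_rate = 0,
    backbone_target_rate = 0, rng_seed = 17L))
  det <- detect_crispr(cm$genomes, cm$repeats, max_mismatches = 2L)
  expect_equal(nrow(det$arrays), nrow(cm$truth$arrays))
  for (i in seq_len(nrow(det$arrays))) {
    a <- det$arrays[i, ]
    rep_seq <- cm$repeats$sequence[cm$repeats$repeat_id == a$repeat_id]
    sp <- det$spacers[det$spacers$array_id == a$array_id, ]
    sp <- sp[order(sp$position_index), ]
    rebuilt <- paste0(paste0(rep_seq, sp$sequence, collapse = ""), rep_seq)
    region <- substring(cm$genomes[[a$genome_id]]$contigs[[a$contig_id]],
                        a$start + 1L, a$end)
    if (a$strand == "-") region <- rc_chr(region)
    expect_identical(rebuilt, region)
  }
})

test_that("minus-strand arrays extract spacers in array orientation", {
  withr::local_seed(9)
  rep_seq <- "GATTACAGATTACAGATTACAGAT"  # 24bp, not palindromic
  sp1 <- rnd_dna(30); sp2 <- rnd_dna(30)
  arr_fwd <- paste0(rep_seq, sp1, rep_seq, sp2, rep_seq)
  g_seq <- paste0(rnd_dna(100), rc_chr(arr_fwd), rnd_dna(100))
  g <- make_genome(g_seq)
  reps <- data.frame(repeat_id = "r1", sequence = rep_seq)
  occ <- find_repeat_occurrences(g, reps, 0L)
  expect_true(all(occ$strand == "-"))
  res <- call_arrays(occ, reps, g, min_repeats = 3L)
  expect_equal(nrow(res$arrays), 1L)
  expect_equal(res$spacers$sequence[order(res$spacers$position_index)],
               c(sp1, sp2))
})

test_that("consensus repeats are the most common per species, ties kept", {
  arrays <- data.frame(species = c(rep("A", 6), "B"),
                       repeat_id = c(rep("r1", 5), "r2", "r3"))
  reps <- data.frame(repeat_id = c("r1", "r2", "r3"),
                     sequence = c("AAAA", "CCCC", "GGGG"))
  cons <- consensus_repeat(arrays, reps)
  expect_equal(cons$repeat_id[cons$species == "A"], "r1")
  expect_equal(cons$repeat_id[cons$species == "B"], "r3")

  tie <- data.frame(species = "A", repeat_id = c("r1", "r1", "r2", "r2"))
  cons2 <- consensus_repeat(tie, reps)
  expect_setequal(cons2$repeat_id, c("r1", "r2"))
  expect_equal(nrow(consensus_repeat(arrays[0, ], reps)), 0L)
})

test_that("spacer deduplication canonicalises and conserves provenance", {
  sp <- data.frame(
    spacer_id = c("a1:s0", "a2:s0", "a3:s0"),
    sequence = c("GATTACAGATTACAGATTACA",
                 "GATTACAGATTACAGATTACA",
                 rc_chr("GATTACAGATTACAGATTACA")),
    source_genome_id = c("g1", "g2", "g3"),
    source_species = c("A", "A", "B"),
    array_id = c("a1", "a2", "a3"),
    position_index = 0L, contig_id = "c1", start = 0L, end = 20L)
  dd <- dedupe_spacers(sp)
  expect_equal(nrow(dd$spacers), 1L)
  expect_equal(dd$spacers$n_carriers, 3L)
  expect_equal(nrow(dd$provenance), 3L)  # provenance multiset conserved

  dd2 <- dedupe_spacers(sp, canonicalize = FALSE)
  expect_equal(nrow(dd2$spacers), 2L)

  empty <- dedupe_spacers(sp[0, ])
  expect_equal(nrow(empty$spacers), 0L)

  shared <- shared_spacers_across_species(dd)
  expect_equal(shared$spacer_id, dd$spacers$spacer_id)
  expect_equal(shared$species, "A,B")
})

test_that("cross-species shared spacers are reported exactly", {
  # hand-built community where 3 spacer sequences recur in both species
  withr::local_seed(23)
  rep_a <- rnd_dna(32); rep_b <- rnd_dna(32)
  shared_seqs <- replicate(3, rnd_dna(30))
  own_a <- replicate(2, rnd_dna(30)); own_b <- replicate(2, rnd_dna(30))
  build <- function(rep_seq, spacers) {
    paste0(paste0(rep_seq, spacers, collapse = ""), rep_seq)
  }
  gA <- make_genome(paste0(rnd_dna(300),
                           build(rep_a, c(shared_seqs, own_a)),
                           rnd_dna(300)), id = "gA", sp = "A")
  gB <- make_genome(paste0(rnd_dna(300),
                           build(rep_b, c(own_b, shared_seqs)),
                           rnd_dna(300)), id = "gB", sp = "B")
  reps <- data.frame(repeat_id = c("rA", "rB"),
                     sequence = c(rep_a, rep_b))
  det <- detect_crispr(list(gA, gB), reps)
  dd <- dedupe_spacers(det$spacers)
  shared <- shared_spacers_across_species(dd)
  expect_equal(nrow(shared), 3L)
  seqs <- dd$spacers$sequence[match(shared$spacer_id, dd$spacers$spacer_id)]
  expect_setequal(canonical_seq(seqs), canonical_seq(shared_seqs))
})
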