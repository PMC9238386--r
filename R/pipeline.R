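#' Run the full CRISPR targeting pipeline
#'
#' Chains the pipeline stages on a set of genomes: repeat-seeded CRISPR
#' detection, spacer deduplication, exact spacer matching, array-match
#' removal, prophage/backbone classification, and per-prophage targeting
#' statistics.
#'
#' @param genomes List of `genome_record` objects.
#' @param prophages Prophage interval data.frame (`genome_id`, `contig_id`,
#'   `start`, `end`, `label`).
#' @param repeats Repeat seed data.frame (`repeat_id`, `species`,
#'   `sequence`).
#' @param max_mismatches Repeat-match Hamming tolerance (default 2).
#' @param min_repeats Minimum repeats per array (default 3).
#' @param spacer_len_range Admissible spacer lengths (default `c(20, 50)`).
#' @param canonicalize Collapse reverse-complement spacers (default TRUE).
#' @param alpha Significance level (default 0.05).
#' @param bin_size Bin width in bp (default 1000).
#' @param alternative Mann-Whitney alternative (default `"greater"`).
#' @return List with elements `arrays`, `spacers`, `dedupe`, `raw_matches`,
#'   `matches` (surviving, classified), `removed_array_matches`, `results`
#'   (from [score_prophages()]), and `summary`
#'   ([targeting_summary()]).
#' @export
run_targeting_pipeline <- function(genomes, prophages, repeats,
                                   max_mismatches = 2L, min_repeats = 3L,
                                   spacer_len_range = c(20L, 50L),
                                   canonicalize = TRUE, alpha = 0.05,
                                   bin_size = 1000L,
                                   alternative = "greater") {
  genomes <- as_genome_list(genomes)
  det <- detect_crispr(genomes, repeats, max_mismatches, min_repeats,
                       spacer_len_range)
  dd <- dedupe_spacers(det$spacers, canonicalize)
  donors <- donor_spacers(dd)
  raw <- match_spacers(donors, genomes)
  filt <- filter_array_matches(raw, det$arrays)
  classified <- classify_matches(filt$matches, prophages)
  results <- if (nrow(prophages) > 0L) {
    score_prophages(classified, prophages, genomes, alpha, bin_size,
                    alternative = alternative)
  } else NULL
  list(arrays = det$arrays, spacers = det$spacers, dedupe = dd,
       raw_matches = raw, matches = classified,
       removed_array_matches = filt$removed, results = results,
       summary = targeting_summary(classified))
}
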