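#!/usr/bin/env Rscript
# Match every unique spacer against every genome (zero mismatches, full
# length, both strands), remove CRISPR-array self-matches, classify the
# survivors as prophage or backbone, and verify recovery of the planted
# protospacers. Reads results/community/ and results/crispr/, writes
# results/matches/.

suppressMessages(library(crisptarget))

dir.create("results/matches", recursive = TRUE, showWarnings = FALSE)
species <- utils::read.table("results/community/species.tsv", header = TRUE,
                             sep = "\t")
genomes <- lapply(seq_len(nrow(species)), function(i) {
  read_genome_fasta(file.path("results/community",
                              paste0(species$genome_id[i], ".fasta")),
                    genome_id = species$genome_id[i],
                    species = species$species[i])
})
prophages <- read_intervals("results/community/prophages.tsv", genomes)
arrays <- utils::read.table("results/crispr/arrays.tsv", header = TRUE,
                            sep = "\t")
uniq <- utils::read.table("results/crispr/spacers.tsv", header = TRUE,
                          sep = "\t")
prov <- utils::read.table("results/crispr/spacer_provenance.tsv",
                          header = TRUE, sep = "\t")
donors <- donor_spacers(list(spacers = uniq, provenance = prov))

raw <- match_spacers(donors, genomes)
filt <- filter_array_matches(raw, arrays)
classified <- classify_matches(filt$matches, prophages)

utils::write.table(classified, "results/matches/matches.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(targeting_summary(classified),
                   "results/matches/summary.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat(sprintf("raw matches: %d; removed in arrays: %d; surviving: %d\n",
            nrow(raw), filt$n_removed, nrow(classified)))
cat(sprintf("by compartment: %d prophage / %d backbone\n",
            sum(classified$compartment == "prophage"),
            sum(classified$compartment == "backbone")))

truth <- utils::read.table("results/community/protospacers.tsv",
                           header = TRUE, sep = "\t")
truth_sp <- utils::read.table("results/community/spacers.tsv",
                              header = TRUE, sep = "\t")
key_t <- paste(canonical_seq(truth_sp$sequence[
                 match(truth$spacer_id, truth_sp$spacer_id)]),
               truth$target_genome_id, truth$contig_id, truth$start)
key_m <- paste(canonical_seq(uniq$sequence[
                 match(classified$spacer_id, uniq$spacer_id)]),
               classified$target_genome_id, classified$contig_id,
               classified$start)
cat(sprintf("planted protospacer recovery: %.3f (%d planted)\n",
            mean(key_t %in% key_m), nrow(truth)))
cat("wrote results/matches/\n")
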