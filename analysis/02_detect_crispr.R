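#!/usr/bin/env Rscript
# Detect CRISPR arrays in the simulated community by seeding with the
# species repeat sequences, extract spacers, deduplicate them, and report
# per-species consensus repeats and any spacers shared across species.
# Reads results/community/, writes results/crispr/.

suppressMessages(library(crisptarget))

dir.create("results/crispr", recursive = TRUE, showWarnings = FALSE)
species <- utils::read.table("results/community/species.tsv", header = TRUE,
                             sep = "\t")
genomes <- lapply(seq_len(nrow(species)), function(i) {
  read_genome_fasta(file.path("results/community",
                              paste0(species$genome_id[i], ".fasta")),
                    genome_id = species$genome_id[i],
                    species = species$species[i])
})
repeats <- utils::read.table("results/community/repeats.tsv", header = TRUE,
                             sep = "\t")

det <- detect_crispr(genomes, repeats, max_mismatches = 2L,
                     min_repeats = 3L, spacer_len_range = c(20L, 50L))
dd <- dedupe_spacers(det$spacers)
cons <- consensus_repeat(det$arrays, repeats)
shared <- shared_spacers_across_species(dd)

write_intervals(det$arrays, "results/crispr/arrays.tsv")
utils::write.table(dd$spacers, "results/crispr/spacers.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(dd$provenance, "results/crispr/spacer_provenance.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(cons, "results/crispr/consensus_repeats.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(shared, "results/crispr/shared_spacers.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat(sprintf("found %d arrays carrying %d spacers (%d unique)\n",
            nrow(det$arrays), nrow(det$spacers), nrow(dd$spacers)))
cat(sprintf("%d spacer(s) shared across species\n", nrow(shared)))
cat("wrote results/crispr/\n")
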