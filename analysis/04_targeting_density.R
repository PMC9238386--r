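#!/usr/bin/env Rscript
# Score every prophage: targeting density versus its genome's backbone,
# per-kb-bin Mann-Whitney U tests and Holm-Sidak correction across all
# prophages in the run. Reads results/community/ and results/matches/,
# writes results/targeting/targeting_results.tsv.

suppressMessages(library(crisptarget))

dir.create("results/targeting", recursive = TRUE, showWarnings = FALSE)
species <- utils::read.table("results/community/species.tsv", header = TRUE,
                             sep = "\t")
genomes <- lapply(seq_len(nrow(species)), function(i) {
  read_genome_fasta(file.path("results/community",
                              paste0(species$genome_id[i], ".fasta")),
                    genome_id = species$genome_id[i],
                    species = species$species[i])
})
prophages <- read_intervals("results/community/prophages.tsv", genomes)
matches <- utils::read.table("results/matches/matches.tsv", header = TRUE,
                             sep = "\t")

res <- score_prophages(matches, prophages, genomes, alpha = 0.05,
                       bin_size = 1000L)
utils::write.table(res, "results/targeting/targeting_results.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

n_sig <- sum(res$significant, na.rm = TRUE)
cat(sprintf("prophages tested: %d; significantly targeted: %d\n",
            nrow(res), n_sig))
fin <- res$ratio[is.finite(res$ratio)]
if (length(fin)) {
  cat(sprintf("density ratio (prophage/backbone): median %.1f, range %.1f-%.1f\n",
              stats::median(fin), min(fin), max(fin)))
}
cat(sprintf("%d prophage(s) had zero backbone matches (ratio = Inf)\n",
            sum(is.infinite(res$ratio))))
cat("wrote results/targeting/targeting_results.tsv\n")
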