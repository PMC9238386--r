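#!/usr/bin/env Rscript
# Dereplicate the prophage sequences at 95% length aligned, cluster them
# with a synthetic plasmid reference by percent-length-aligned distance
# (average linkage), export the dendrogram in Newick format, and flag
# predictions that co-cluster with the plasmid. Reads results/community/,
# writes results/clusters/.

suppressMessages(library(crisptarget))

dir.create("results/clusters", recursive = TRUE, showWarnings = FALSE)
species <- utils::read.table("results/community/species.tsv", header = TRUE,
                             sep = "\t")
genomes <- lapply(seq_len(nrow(species)), function(i) {
  read_genome_fasta(file.path("results/community",
                              paste0(species$genome_id[i], ".fasta")),
                    genome_id = species$genome_id[i],
                    species = species$species[i])
})
names(genomes) <- species$genome_id
prophages <- read_intervals("results/community/prophages.tsv", genomes)

# prophage sequences straight from the genomes; add a redundant copy and a
# synthetic plasmid-derived prediction so dereplication and co-clustering
# have something to find
elements <- data.frame(
  element_id = prophages$label,
  sequence = vapply(seq_len(nrow(prophages)), function(i) {
    substring(genomes[[prophages$genome_id[i]]]$contigs[[
      prophages$contig_id[i]]], prophages$start[i] + 1L, prophages$end[i])
  }, character(1)))
set.seed(7)
dup <- elements[1, ]
dup$element_id <- paste0(dup$element_id, ":dup")
plasmid <- paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE),
                 collapse = "")
plasmid_pred <- data.frame(element_id = "pred:plasmid_fragment",
                           sequence = substring(plasmid, 2001, 16000))
elements <- rbind(elements, dup, plasmid_pred)

dr <- dereplicate(elements, threshold = 0.95)
utils::write.table(dr$clusters, "results/clusters/clusters.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
writeLines(to_newick(dr$tree), "results/clusters/dendrogram.nwk")

reps <- elements[elements$element_id %in% dr$representatives, ]
refs <- data.frame(element_id = "plasmid_A", sequence = plasmid,
                   category = "plasmid")
flags <- cocluster_with_references(reps, refs, threshold = 0.95)
utils::write.table(flags, "results/clusters/cocluster_flags.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat(sprintf("%d elements -> %d representatives at PLA >= 0.95\n",
            nrow(elements), length(dr$representatives)))
cat(sprintf("flagged as plasmid-like: %s\n",
            paste(flags$element_id[flags$coclusters_with_mge],
                  collapse = ", ")))
cat("wrote results/clusters/\n")
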