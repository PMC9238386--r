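#!/usr/bin/env Rscript
# Generate the synthetic multi-species community the downstream analyses
# run on: four species, two 0.2 Mb genomes each, two planted prophages and
# one CRISPR array per genome, protospacers planted into prophages (5 per
# prophage per donor species) and backbones (2 per Mb per donor species).
# Writes genomes (FASTA) and ground-truth tables (TSV) under
# results/community/.

suppressMessages(library(crisptarget))

seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 42L
cfg <- community_config(rng_seed = seed)
cm <- generate_community(cfg)
write_community(cm, "results/community")

cat(sprintf("community: %d genomes from %d species, %s bp each\n",
            length(cm$genomes), cfg$n_species,
            format(cfg$genome_length_bp, big.mark = ",")))
cat(sprintf("planted: %d prophages, %d arrays (%d spacers), %d protospacers\n",
            nrow(cm$truth$prophages), nrow(cm$truth$arrays),
            nrow(cm$truth$spacers), nrow(cm$truth$protospacers)))
cat(sprintf("protospacers by compartment: %d prophage / %d backbone\n",
            sum(cm$truth$protospacers$compartment == "prophage"),
            sum(cm$truth$protospacers$compartment == "backbone")))
cat("wrote results/community/\n")
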