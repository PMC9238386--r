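#!/usr/bin/env Rscript
# Build the directed interspecies CRISPR targeting network and infer
# additional host species for significantly targeted, non-plasmid-like
# prophages. Reads results/matches/, results/targeting/ and
# results/clusters/, writes results/network/.

suppressMessages(library(crisptarget))

dir.create("results/network", recursive = TRUE, showWarnings = FALSE)
matches <- utils::read.table("results/matches/matches.tsv", header = TRUE,
                             sep = "\t")
res <- utils::read.table("results/targeting/targeting_results.tsv",
                         header = TRUE, sep = "\t")
flags <- utils::read.table("results/clusters/cocluster_flags.tsv",
                           header = TRUE, sep = "\t")

eligible <- eligible_prophages(res, flags)
meta <- data.frame(prophage_id = res$prophage_id,
                   native_species = res$species)
hi <- infer_hosts(eligible, matches, meta)
utils::write.table(hi$hosts, "results/network/hosts.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(hi$support, "results/network/host_support.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

prov <- utils::read.table("results/crispr/spacer_provenance.tsv",
                          header = TRUE, sep = "\t")
per <- unique(prov[, c("spacer_id", "source_species")])
totals <- vapply(split(per$spacer_id, per$source_species),
                 function(x) length(unique(x)), integer(1))
nw <- build_species_network(matches, eligible, spacer_totals = totals)
export_network(nw, "results/network/network.graphml",
               "results/network/network_edges.tsv")

cat(sprintf("eligible prophages: %d of %d tested\n", length(eligible),
            nrow(res)))
multi <- sum(hi$hosts$n_additional_hosts > 0)
cat(sprintf("prophages with >=1 additional inferred host species: %d\n",
            multi))
cat(sprintf("network: %d species nodes, %d directed edges\n",
            nrow(nw$nodes), nrow(nw$edges)))
cat("wrote results/network/\n")
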