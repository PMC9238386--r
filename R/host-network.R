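#' Prophages eligible for host inference
#'
#' Predicted prophages enter host inference only if their targeting density
#' is significantly higher than their backbone's and they do not cluster
#' with plasmids or genetic islands; known phages bypass both gates.
#'
#' @param results Targeting results from [score_prophages()].
#' @param cocluster_flags Data.frame from [cocluster_with_references()]
#'   (`element_id`, `coclusters_with_mge`), or `NULL` (nothing flagged).
#' @param known_phage_ids Character vector of prophage ids that are known
#'   phages (always eligible).
#' @return Character vector of eligible prophage ids.
#' @export
eligible_prophages <- function(results, cocluster_flags = NULL,
                               known_phage_ids = character(0)) {
  flagged <- if (is.null(cocluster_flags)) character(0) else
    cocluster_flags$element_id[cocluster_flags$coclusters_with_mge]
  sig <- results$prophage_id[!is.na(results$significant) & results$significant]
  pred <- setdiff(sig, flagged)
  union(intersect(known_phage_ids, results$prophage_id), pred)
}

#' Infer host species of prophages from CRISPR targeting
#'
#' Any species encoding at least one spacer that matches a prophage is
#' inferred to be a host of that prophage, in addition to the native
#' species (the species of the genome carrying it). Species supported by
#' more than one distinct spacer are marked `multi_spacer_support`.
#'
#' @param prophage_ids Eligible prophage ids ([eligible_prophages()]).
#' @param matches Classified match data.frame with `compartment`,
#'   `prophage_id`, `donor_species`, `spacer_id`.
#' @param prophage_meta Data.frame `prophage_id`, `native_species` (e.g.
#'   built from the prophage table and genome species).
#' @return List with `hosts` (one row per prophage: `prophage_id`,
#'   `native_species`, `additional_hosts` comma-joined) and `support` (one
#'   row per prophage x donor species: distinct `n_spacers`,
#'   `multi_spacer_support`, `is_native`).
#' @export
infer_hosts <- function(prophage_ids, matches, prophage_meta) {
  pm <- matches[matches$compartment == "prophage" &
                matches$prophage_id %in% prophage_ids, , drop = FALSE]
  support <- list(); hosts <- list()
  for (pid in prophage_ids) {
    native <- prophage_meta$native_species[prophage_meta$prophage_id == pid]
    if (length(native) != 1L) stop("no native species for prophage ", pid)
    mm <- pm[pm$prophage_id == pid, , drop = FALSE]
    per <- unique(mm[, c("donor_species", "spacer_id")])
    n_sp <- if (nrow(per)) table(per$donor_species) else
      table(character(0))
    add <- setdiff(names(n_sp), native)
    hosts[[pid]] <- data.frame(
      prophage_id = pid, native_species = native,
      additional_hosts = paste(sort(add), collapse = ","),
      n_additional_hosts = length(add), stringsAsFactors = FALSE)
    if (length(n_sp)) {
      support[[pid]] <- data.frame(
        prophage_id = pid, donor_species = names(n_sp),
        n_spacers = as.integer(n_sp),
        multi_spacer_support = as.integer(n_sp) > 1L,
        is_native = names(n_sp) == native, stringsAsFactors = FALSE)
    }
  }
  empty_sup <- data.frame(prophage_id = character(0),
                          donor_species = character(0),
                          n_spacers = integer(0),
                          multi_spacer_support = logical(0),
                          is_native = logical(0), stringsAsFactors = FALSE)
  list(hosts = if (length(hosts)) do.call(rbind, c(hosts, make.row.names = FALSE))
       else data.frame(prophage_id = character(0), native_species = character(0),
                       additional_hosts = character(0),
                       n_additional_hosts = integer(0)),
       support = if (length(support))
         do.call(rbind, c(support, make.row.names = FALSE)) else empty_sup)
}

#' Directed interspecies CRISPR targeting network
#'
#' One directed edge per (donor species, target species) pair with at least
#' one surviving spacer match. Counts are of distinct spacers: prophage
#' counts are restricted to eligible prophages, backbone counts use all
#' backbone matches. Self-loops (a species targeting itself) are retained.
#'
#' @param matches Classified match data.frame.
#' @param prophage_ids Eligible prophage ids for the prophage-count side.
#' @param spacer_totals Optional named vector: total distinct spacers
#'   encoded per species (node attribute); computed from `matches` donors
#'   if omitted (then only donor species appear as nodes).
#' @return List with `edges` (data.frame `donor_species`, `target_species`,
#'   `prophage_spacer_count`, `backbone_spacer_count`, `prophage_fraction`)
#'   and `nodes` (data.frame `species`, `total_spacers`).
#' @export
build_species_network <- function(matches, prophage_ids,
                                  spacer_totals = NULL) {
  keep <- matches$compartment == "backbone" |
    (matches$compartment == "prophage" & matches$prophage_id %in% prophage_ids)
  mm <- matches[keep, , drop = FALSE]
  edges <- data.frame(donor_species = character(0),
                      target_species = character(0),
                      prophage_spacer_count = integer(0),
                      backbone_spacer_count = integer(0),
                      prophage_fraction = numeric(0), stringsAsFactors = FALSE)
  if (nrow(mm) > 0L) {
    key <- paste(mm$donor_species, mm$target_species, sep = "\r")
    rows <- lapply(unique(key), function(k) {
      sub <- mm[key == k, , drop = FALSE]
      np <- length(unique(sub$spacer_id[sub$compartment == "prophage"]))
      nb <- length(unique(sub$spacer_id[sub$compartment == "backbone"]))
      data.frame(donor_species = sub$donor_species[1L],
                 target_species = sub$target_species[1L],
                 prophage_spacer_count = np, backbone_spacer_count = nb,
                 prophage_fraction = if (np + nb > 0L) np / (np + nb)
                 else NA_real_, stringsAsFactors = FALSE)
    })
    edges <- do.call(rbind, rows)
    edges <- edges[order(edges$donor_species, edges$target_species), ]
    rownames(edges) <- NULL
  }
  if (is.null(spacer_totals)) {
    per <- unique(matches[, c("donor_species", "spacer_id")])
    spacer_totals <- vapply(split(per$spacer_id, per$donor_species),
                            function(x) length(unique(x)), integer(1))
  }
  species <- sort(unique(c(names(spacer_totals), edges$donor_species,
                           edges$target_species)))
  nodes <- data.frame(species = species,
                      total_spacers = as.integer(
                        ifelse(species %in% names(spacer_totals),
                               spacer_totals[species], 0L)),
                      stringsAsFactors = FALSE)
  list(edges = edges, nodes = nodes)
}

#' Export a species network as GraphML and a TSV edge list
#'
#' @param network Output of [build_species_network()].
#' @param graphml_path Path for the GraphML file (`NULL` to skip).
#' @param tsv_path Path for the edge-list TSV (`NULL` to skip).
#' @param drop_self_loops Drop donor == target edges from the export
#'   (default `FALSE`).
#' @return The igraph object, invisibly.
#' @export
export_network <- function(network, graphml_path = NULL, tsv_path = NULL,
                           drop_self_loops = FALSE) {
  edges <- network$edges
  if (drop_self_loops) {
    edges <- edges[edges$donor_species != edges$target_species, , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(
    edges, directed = TRUE, vertices = network$nodes)
  if (!is.null(graphml_path)) {
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  if (!is.null(tsv_path)) {
    out <- edges
    names(out) <- c("donor", "target", "prophage_spacers", "backbone_spacers",
                    "prophage_fraction")
    utils::write.table(out, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(g)
}
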