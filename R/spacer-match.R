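#' Find exact full-length spacer matches in genomes
#'
#' Reports every zero-mismatch, full-length occurrence of each spacer on
#' either strand of each contig. A spacer occurring k times yields k
#' matches; a palindromic spacer matching the same locus on both strands is
#' reported once (on the plus strand). Spacers or genomic windows containing
#' `N` can never satisfy the zero-mismatch rule and therefore never match.
#'
#' @param spacers Data.frame with at least `spacer_id` and `sequence`
#'   columns, and optionally `donor_species` (or `source_species`, used as
#'   donor). A spacer id listed with several donor species yields one match
#'   record per donor species per locus.
#' @param genomes List of `genome_record` objects (or a single record).
#' @return Data.frame with columns `spacer_id`, `donor_species`,
#'   `target_genome_id`, `target_species`, `contig_id`, `start`, `end`,
#'   `strand`. Coordinates are 0-based half-open on the forward strand.
#' @export
match_spacers <- function(spacers, genomes) {
  genomes <- as_genome_list(genomes)
  if (is.null(spacers$donor_species)) {
    spacers$donor_species <-
      if (!is.null(spacers$source_species)) spacers$source_species else NA_character_
  }
  stopifnot(!is.null(spacers$spacer_id), !is.null(spacers$sequence))
  if (any(grepl("N", spacers$sequence, fixed = TRUE))) {
    stop("spacer sequences must be N-free")
  }
  uniq <- unique(spacers[, c("spacer_id", "sequence")])
  if (anyDuplicated(uniq$spacer_id)) {
    stop("a spacer_id maps to more than one sequence")
  }
  donors <- unique(spacers[, c("spacer_id", "donor_species")])

  hits <- list()
  widths <- nchar(uniq$sequence)
  for (g in genomes) {
    for (ctg in names(g$contigs)) {
      subject <- Biostrings::DNAString(g$contigs[[ctg]])
      rsubject <- Biostrings::reverseComplement(subject)
      n <- length(subject)
      # Aho-Corasick multi-pattern search per spacer width, both strands
      for (w in unique(widths)) {
        if (w > n) next
        idx <- which(widths == w)
        pd <- Biostrings::PDict(Biostrings::DNAStringSet(uniq$sequence[idx]))
        mi_f <- Biostrings::matchPDict(pd, subject)
        mi_r <- Biostrings::matchPDict(pd, rsubject)
        for (k in seq_along(idx)) {
          fwd <- Biostrings::start(mi_f[[k]]) - 1L
          rev <- n - Biostrings::end(mi_r[[k]])          # back to + coords
          if (length(fwd) == 0L && length(rev) == 0L) next
          loci <- data.frame(
            start = c(fwd, rev),
            strand = rep(c("+", "-"), c(length(fwd), length(rev))),
            stringsAsFactors = FALSE)
          # palindromic spacers hit the same locus on both strands: keep "+"
          loci <- loci[order(loci$start, loci$strand), ]
          loci <- loci[!duplicated(loci$start), ]
          hits[[length(hits) + 1L]] <- data.frame(
            spacer_id = uniq$spacer_id[idx[k]],
            target_genome_id = g$genome_id,
            target_species = g$species,
            contig_id = ctg,
            start = loci$start,
            end = loci$start + w,
            strand = loci$strand,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  cols <- c("spacer_id", "donor_species", "target_genome_id", "target_species",
            "contig_id", "start", "end", "strand")
  if (length(hits) == 0L) {
    out <- data.frame(spacer_id = character(0), donor_species = character(0),
                      target_genome_id = character(0),
                      target_species = character(0), contig_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
    return(out[cols])
  }
  out <- do.call(rbind, hits)
  out <- merge(out, donors, by = "spacer_id")
  out <- out[order(out$target_genome_id, out$contig_id, out$start,
                   out$spacer_id, out$donor_species), cols]
  rownames(out) <- NULL
  out
}

#' Remove matches that fall in CRISPR arrays
#'
#' A match overlapping any array interval by at least one base is removed;
#' this drops array self-matches (a spacer hitting its own locus) and hits
#' to homologous arrays in other genomes, mirroring the exclusion of
#' array loci from protospacer counting.
#'
#' @param matches Match data.frame from [match_spacers()].
#' @param arrays Interval data.frame with `genome_id`, `contig_id`, `start`,
#'   `end` (array coordinates). `NULL` or empty leaves matches unchanged.
#' @return List with `matches` (surviving), `removed` (dropped rows) and
#'   `n_removed`.
#' @export
filter_array_matches <- function(matches, arrays = NULL) {
  if (is.null(arrays) || nrow(arrays) == 0L || nrow(matches) == 0L) {
    return(list(matches = matches,
                removed = matches[0, , drop = FALSE], n_removed = 0L))
  }
  in_array <- overlaps_any(matches, arrays)
  list(matches = matches[!in_array, , drop = FALSE],
       removed = matches[in_array, , drop = FALSE],
       n_removed = sum(in_array))
}

# logical vector: does each match overlap >=1 bp of any interval
# on the same genome and contig? (half-open coordinates)
overlaps_any <- function(matches, intervals) {
  res <- logical(nrow(matches))
  key_m <- paste(matches$target_genome_id, matches$contig_id)
  gid <- if (!is.null(intervals$genome_id)) intervals$genome_id else
    intervals$target_genome_id
  key_i <- paste(gid, intervals$contig_id)
  for (k in unique(key_m)) {
    iv <- intervals[key_i == k, , drop = FALSE]
    if (nrow(iv) == 0L) next
    sel <- which(key_m == k)
    for (j in sel) {
      res[j] <- any(matches$start[j] < iv$end & matches$end[j] > iv$start)
    }
  }
  res
}

#' Classify matches as prophage or backbone
#'
#' A match overlapping any prophage interval by at least one base is
#' assigned to the prophage compartment; when several prophages overlap the
#' match, the one containing the match start wins (then the first by
#' coordinate). All other matches are backbone.
#'
#' @param matches Match data.frame (post [filter_array_matches()]).
#' @param prophages Interval data.frame with `genome_id`, `contig_id`,
#'   `start`, `end`, `label` (the prophage id).
#' @return `matches` with added columns `compartment`
#'   (`"prophage"`/`"backbone"`) and `prophage_id` (NA for backbone).
#' @export
classify_matches <- function(matches, prophages) {
  matches$compartment <- rep("backbone", nrow(matches))
  matches$prophage_id <- rep(NA_character_, nrow(matches))
  if (nrow(matches) == 0L || is.null(prophages) || nrow(prophages) == 0L) {
    return(matches)
  }
  prophages <- prophages[order(prophages$genome_id, prophages$contig_id,
                               prophages$start), , drop = FALSE]
  key_m <- paste(matches$target_genome_id, matches$contig_id)
  key_p <- paste(prophages$genome_id, prophages$contig_id)
  for (k in unique(key_m)) {
    pp <- prophages[key_p == k, , drop = FALSE]
    if (nrow(pp) == 0L) next
    for (j in which(key_m == k)) {
      ov <- which(matches$start[j] < pp$end & matches$end[j] > pp$start)
      if (length(ov) == 0L) next
      contains <- ov[matches$start[j] >= pp$start[ov] &
                     matches$start[j] < pp$end[ov]]
      pick <- if (length(contains) > 0L) contains[1L] else ov[1L]
      matches$compartment[j] <- "prophage"
      matches$prophage_id[j] <- pp$label[pick]
    }
  }
  matches
}

#' Summarise targeting counts per donor species and target genome
#'
#' @param matches Classified match data.frame from [classify_matches()].
#' @return Data.frame with columns `donor_species`, `target_genome_id`,
#'   `prophage_matches`, `backbone_matches`. The two count columns partition
#'   the surviving matches.
#' @export
targeting_summary <- function(matches) {
  if (nrow(matches) == 0L) {
    return(data.frame(donor_species = character(0),
                      target_genome_id = character(0),
                      prophage_matches = integer(0),
                      backbone_matches = integer(0)))
  }
  stopifnot("compartment" %in% names(matches))
  tab <- table(donor = matches$donor_species,
               genome = matches$target_genome_id,
               comp = factor(matches$compartment,
                             levels = c("prophage", "backbone")))
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  wide <- stats::reshape(df, idvar = c("donor", "genome"),
                         timevar = "comp", direction = "wide")
  out <- data.frame(donor_species = wide$donor,
                    target_genome_id = wide$genome,
                    prophage_matches = as.integer(wide$Freq.prophage),
                    backbone_matches = as.integer(wide$Freq.backbone),
                    stringsAsFactors = FALSE)
  out <- out[out$prophage_matches + out$backbone_matches > 0L, , drop = FALSE]
  out <- out[order(out$donor_species, out$target_genome_id), ]
  rownames(out) <- NULL
  out
}
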