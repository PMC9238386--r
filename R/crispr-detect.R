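#' Find occurrences of CRISPR repeat seeds in a genome
#'
#' Scans both strands of every contig for windows within a Hamming distance
#' (no indels) of each repeat seed. Every qualifying window is reported
#' exactly once; a window matching on both strands is reported on the plus
#' strand. Repeats longer than a contig skip that contig silently.
#'
#' @param genome A `genome_record`.
#' @param repeats Data.frame with columns `repeat_id`, `sequence` (and
#'   optionally `species`).
#' @param max_mismatches Maximum Hamming distance (default 2).
#' @return Data.frame `genome_id`, `contig_id`, `start` (0-based), `strand`,
#'   `repeat_id`, sorted by contig then start.
#' @export
find_repeat_occurrences <- function(genome, repeats, max_mismatches = 2L) {
  stopifnot(inherits(genome, "genome_record"), nrow(repeats) >= 1L,
            max_mismatches >= 0L)
  occ <- list()
  for (ctg in names(genome$contigs)) {
    subject <- Biostrings::DNAString(genome$contigs[[ctg]])
    for (i in seq_len(nrow(repeats))) {
      rseq <- repeats$sequence[i]
      if (nchar(rseq) > length(subject)) next
      fwd <- Biostrings::start(Biostrings::matchPattern(
        rseq, subject, max.mismatch = max_mismatches,
        with.indels = FALSE, fixed = TRUE))
      rev <- Biostrings::start(Biostrings::matchPattern(
        revcomp(rseq), subject, max.mismatch = max_mismatches,
        with.indels = FALSE, fixed = TRUE))
      if (length(fwd) == 0L && length(rev) == 0L) next
      d <- data.frame(start = c(fwd, rev) - 1L,
                      strand = rep(c("+", "-"), c(length(fwd), length(rev))),
                      stringsAsFactors = FALSE)
      d <- d[order(d$start, d$strand), ]
      d <- d[!duplicated(d$start), ]  # both-strand window reported once
      occ[[length(occ) + 1L]] <- data.frame(
        genome_id = genome$genome_id, contig_id = ctg, start = d$start,
        strand = d$strand, repeat_id = repeats$repeat_id[i],
        stringsAsFactors = FALSE)
    }
  }
  if (length(occ) == 0L) {
    return(data.frame(genome_id = character(0), contig_id = character(0),
                      start = integer(0), strand = character(0),
                      repeat_id = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, occ)
  out <- out[order(out$contig_id, out$start, out$repeat_id), ]
  rownames(out) <- NULL
  out
}

#' Call CRISPR arrays from repeat occurrences and extract spacers
#'
#' Maximal runs of occurrences of the same repeat, on the same contig and
#' strand, in which every gap between consecutive repeats lies within the
#' spacer length range, are called as arrays; runs shorter than
#' `min_repeats` are discarded. Spacers are the genomic gap sequences
#' between consecutive repeats, reported in array orientation (reverse
#' complemented, and ordered 5' to 3' along the repeat strand, for
#' minus-strand arrays).
#'
#' @param occurrences Output of [find_repeat_occurrences()], sorted.
#' @param repeats Repeat seed data.frame (`repeat_id`, `sequence`).
#' @param genome The `genome_record` the occurrences came from.
#' @param min_repeats Minimum repeats per array (default 3).
#' @param spacer_len_range Length-2 vector `(lo, hi)` of admissible gap
#'   lengths in bp (default `c(20, 50)`).
#' @return List with `arrays` (one row per array: `array_id`, `genome_id`,
#'   `species`, `contig_id`, `start`, `end`, `strand`, `repeat_id`,
#'   `n_repeats`, `repeat_starts` comma-joined) and `spacers` (one row per
#'   spacer: `spacer_id`, `sequence`, `source_genome_id`, `source_species`,
#'   `array_id`, `position_index`, `contig_id`, `start`, `end`).
#' @export
call_arrays <- function(occurrences, repeats, genome, min_repeats = 3L,
                        spacer_len_range = c(20L, 50L)) {
  stopifnot(min_repeats >= 2L, length(spacer_len_range) == 2L)
  lo <- spacer_len_range[1L]; hi <- spacer_len_range[2L]
  rep_len <- stats::setNames(nchar(repeats$sequence), repeats$repeat_id)
  arrays <- list(); spacers <- list()
  if (nrow(occurrences) > 0L) {
    grp <- split(occurrences,
                 list(occurrences$contig_id, occurrences$repeat_id,
                      occurrences$strand), drop = TRUE)
    for (p in grp) {
      p <- p[order(p$start), ]
      L <- rep_len[[p$repeat_id[1L]]]
      gaps <- diff(p$start) - L
      run_id <- cumsum(c(0L, as.integer(gaps < lo | gaps > hi)))
      for (r in split(seq_len(nrow(p)), run_id)) {
        if (length(r) < min_repeats) next
        q <- p[r, ]
        a_start <- q$start[1L]; a_end <- q$start[nrow(q)] + L
        array_id <- sprintf("%s:%s:%d", genome$genome_id, q$contig_id[1L],
                            a_start)
        arrays[[length(arrays) + 1L]] <- data.frame(
          array_id = array_id, genome_id = genome$genome_id,
          species = genome$species, contig_id = q$contig_id[1L],
          start = a_start, end = a_end, strand = q$strand[1L],
          repeat_id = q$repeat_id[1L], n_repeats = nrow(q),
          repeat_starts = paste(q$start, collapse = ","),
          stringsAsFactors = FALSE)
        sp_start <- q$start[-nrow(q)] + L
        sp_end <- q$start[-1L]
        seqs <- substring(genome$contigs[[q$contig_id[1L]]],
                          sp_start + 1L, sp_end)
        idx <- seq_along(seqs) - 1L
        if (q$strand[1L] == "-") {
          seqs <- rev(revcomp(seqs))
          sp_start <- rev(sp_start); sp_end <- rev(sp_end)
        }
        spacers[[length(spacers) + 1L]] <- data.frame(
          spacer_id = sprintf("%s:s%d", array_id, idx),
          sequence = seqs, source_genome_id = genome$genome_id,
          source_species = genome$species, array_id = array_id,
          position_index = idx, contig_id = q$contig_id[1L],
          start = sp_start, end = sp_end, stringsAsFactors = FALSE)
      }
    }
  }
  empty_arr <- data.frame(array_id = character(0), genome_id = character(0),
                          species = character(0), contig_id = character(0),
                          start = integer(0), end = integer(0),
                          strand = character(0), repeat_id = character(0),
                          n_repeats = integer(0), repeat_starts = character(0),
                          stringsAsFactors = FALSE)
  empty_sp <- data.frame(spacer_id = character(0), sequence = character(0),
                         source_genome_id = character(0),
                         source_species = character(0), array_id = character(0),
                         position_index = integer(0), contig_id = character(0),
                         start = integer(0), end = integer(0),
                         stringsAsFactors = FALSE)
  list(arrays = if (length(arrays)) do.call(rbind, arrays) else empty_arr,
       spacers = if (length(spacers)) do.call(rbind, spacers) else empty_sp)
}

#' Detect CRISPR arrays across a set of genomes
#'
#' Convenience wrapper: runs [find_repeat_occurrences()] and [call_arrays()]
#' on every genome and concatenates the results.
#'
#' @inheritParams find_repeat_occurrences
#' @inheritParams call_arrays
#' @param genomes List of `genome_record` objects.
#' @return List with `arrays` and `spacers` data.frames (see
#'   [call_arrays()]).
#' @export
detect_crispr <- function(genomes, repeats, max_mismatches = 2L,
                          min_repeats = 3L, spacer_len_range = c(20L, 50L)) {
  genomes <- as_genome_list(genomes)
  res <- lapply(genomes, function(g) {
    occ <- find_repeat_occurrences(g, repeats, max_mismatches)
    call_arrays(occ, repeats, g, min_repeats, spacer_len_range)
  })
  list(arrays = do.call(rbind, c(lapply(res, `[[`, "arrays"),
                                 make.row.names = FALSE)),
       spacers = do.call(rbind, c(lapply(res, `[[`, "spacers"),
                                  make.row.names = FALSE)))
}

#' Consensus repeat(s) per species
#'
#' For each species, returns the repeat seed(s) whose arrays are most
#' numerous; ties return all tied sequences.
#'
#' @param arrays Array data.frame from [call_arrays()] / [detect_crispr()]
#'   (columns `species`, `repeat_id`).
#' @param repeats Repeat seed data.frame (`repeat_id`, `sequence`).
#' @return Data.frame `species`, `repeat_id`, `sequence`, `n_arrays`.
#' @export
consensus_repeat <- function(arrays, repeats) {
  if (nrow(arrays) == 0L) {
    return(data.frame(species = character(0), repeat_id = character(0),
                      sequence = character(0), n_arrays = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- list()
  for (sp in unique(arrays$species)) {
    tab <- table(arrays$repeat_id[arrays$species == sp])
    win <- names(tab)[tab == max(tab)]
    out[[sp]] <- data.frame(
      species = sp, repeat_id = win,
      sequence = repeats$sequence[match(win, repeats$repeat_id)],
      n_arrays = as.integer(tab[win]), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Deduplicate spacers to unique sequences with provenance
#'
#' Collapses spacers to one record per distinct sequence. By default two
#' spacers are the same if their canonical forms (lexicographic minimum of
#' sequence and reverse complement) agree, since array orientation is
#' arbitrary; set `canonicalize = FALSE` to treat strands as distinct.
#'
#' @param spacers Spacer data.frame from [call_arrays()].
#' @param canonicalize Collapse reverse complements (default `TRUE`).
#' @return List with `spacers` (`spacer_id`, `sequence`, `n_carriers`) and
#'   `provenance` (`spacer_id`, `source_genome_id`, `source_species`,
#'   `array_id`, `member_spacer_id`), where `spacer_id` is the unique-spacer
#'   id `u<k>` in order of first appearance.
#' @export
dedupe_spacers <- function(spacers, canonicalize = TRUE) {
  if (nrow(spacers) == 0L) {
    return(list(
      spacers = data.frame(spacer_id = character(0), sequence = character(0),
                           n_carriers = integer(0), stringsAsFactors = FALSE),
      provenance = data.frame(spacer_id = character(0),
                              source_genome_id = character(0),
                              source_species = character(0),
                              array_id = character(0),
                              member_spacer_id = character(0),
                              stringsAsFactors = FALSE)))
  }
  key <- if (canonicalize) canonical_seq(spacers$sequence) else spacers$sequence
  first <- !duplicated(key)
  uid <- sprintf("u%04d", seq_len(sum(first)))[match(key, key[first])]
  # representative sequence: the first-seen form
  uniq <- data.frame(spacer_id = uid[first], sequence = spacers$sequence[first],
                     n_carriers = as.integer(table(uid)[uid[first]]),
                     stringsAsFactors = FALSE)
  prov <- data.frame(spacer_id = uid,
                     source_genome_id = spacers$source_genome_id,
                     source_species = spacers$source_species,
                     array_id = spacers$array_id,
                     member_spacer_id = spacers$spacer_id,
                     stringsAsFactors = FALSE)
  list(spacers = uniq, provenance = prov)
}

#' Donor-expanded spacer table for matching
#'
#' One row per unique spacer per donor species carrying it; a spacer shared
#' by two species contributes matches under both donors.
#'
#' @param dedupe Output of [dedupe_spacers()].
#' @return Data.frame `spacer_id`, `sequence`, `donor_species`.
#' @export
donor_spacers <- function(dedupe) {
  d <- unique(dedupe$provenance[, c("spacer_id", "source_species")])
  out <- merge(dedupe$spacers[, c("spacer_id", "sequence")], d,
               by = "spacer_id")
  names(out)[names(out) == "source_species"] <- "donor_species"
  out[order(out$spacer_id, out$donor_species), ]
}

#' Spacers shared across species
#'
#' @param dedupe Output of [dedupe_spacers()].
#' @return Data.frame `spacer_id`, `n_species`, `species` (comma-joined) for
#'   unique spacers carried by genomes of two or more species.
#' @export
shared_spacers_across_species <- function(dedupe) {
  prov <- unique(dedupe$provenance[, c("spacer_id", "source_species")])
  n <- tapply(prov$source_species, prov$spacer_id,
              function(x) length(unique(x)))
  ids <- names(n)[n >= 2L]
  if (length(ids) == 0L) {
    return(data.frame(spacer_id = character(0), n_species = integer(0),
                      species = character(0), stringsAsFactors = FALSE))
  }
  sp <- vapply(ids, function(i) {
    paste(sort(unique(prov$source_species[prov$spacer_id == i])),
          collapse = ",")
  }, character(1))
  out <- data.frame(spacer_id = ids, n_species = as.integer(n[ids]),
                    species = sp, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Bootstrap repeat seeds from exact tandem k-mers
#'
#' Tallies exact k-mers that recur on one contig with consecutive gaps
#' inside the spacer length range at least `min_repeats` times. Intended
#' only to bootstrap repeat seeds on synthetic genomes; it is not a de novo
#' CRISPR detector.
#'
#' @param genome A `genome_record`.
#' @param repeat_length k-mer length to tally (default 32).
#' @param min_repeats Minimum tandem occurrences (default 3).
#' @param spacer_len_range Admissible gap range in bp (default `c(20, 50)`).
#' @return Data.frame `repeat_id`, `species`, `sequence`.
#' @export
bootstrap_repeat_seeds <- function(genome, repeat_length = 32L,
                                   min_repeats = 3L,
                                   spacer_len_range = c(20L, 50L)) {
  lo <- spacer_len_range[1L]; hi <- spacer_len_range[2L]
  found <- character(0)
  for (ctg in names(genome$contigs)) {
    s <- genome$contigs[[ctg]]
    n <- nchar(s)
    if (n < repeat_length) next
    kmers <- substring(s, 1:(n - repeat_length + 1L), repeat_length:n)
    pos <- split(seq_along(kmers), kmers)
    pos <- pos[lengths(pos) >= min_repeats]
    for (km in names(pos)) {
      gaps <- diff(pos[[km]]) - repeat_length
      runs <- rle(gaps >= lo & gaps <= hi)
      if (any(runs$values & runs$lengths >= (min_repeats - 1L))) {
        found <- c(found, km)
      }
    }
  }
  found <- unique(found)
  data.frame(repeat_id = sprintf("%s:rep%d", genome$genome_id,
                                 seq_along(found)),
             species = genome$species, sequence = found,
             stringsAsFactors = FALSE)
}
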