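#' Configuration for a synthetic bacterial community
#'
#' Defines the study conditions a synthetic community is generated under:
#' how many species and genomes, genome and prophage sizes, CRISPR array
#' geometry, and the expected rates at which protospacers are planted into
#' prophages and genome backbones per donor species.
#'
#' Defaults emulate small multi-species communities of commensal bacteria:
#' a handful of species with 0.2 Mb single-contig genomes, two prophages of
#' 15-30 kb each, one CRISPR array of ten 32 bp repeats separated by 30 bp
#' spacers, prophages targeted at an expected 5 protospacers per prophage
#' per donor species and backbones at 2 protospacers per Mb per donor
#' species.
#'
#' @param n_species Number of species.
#' @param genomes_per_species Genomes per species.
#' @param genome_length_bp Genome (single contig) length in bp.
#' @param prophages_per_genome Prophages planted per genome.
#' @param prophage_length_bp Length-1 or length-2 (range, sampled uniformly)
#'   prophage length in bp.
#' @param arrays_per_genome CRISPR arrays planted per genome.
#' @param repeats_per_array Repeats per array; at least 3.
#' @param repeat_length_bp Repeat length in bp (default 32).
#' @param spacer_length_bp Spacer length in bp (default 30).
#' @param prophage_target_rate Expected planted protospacers per prophage
#'   per donor species (Poisson mean).
#' @param backbone_target_rate Expected planted protospacers per Mb of
#'   backbone per donor species (Poisson mean scale).
#' @param rng_seed Integer seed; generation is deterministic given the seed.
#' @return A validated list of class `community_config`.
#' @export
community_config <- function(n_species = 4L, genomes_per_species = 2L,
                             genome_length_bp = 200000L,
                             prophages_per_genome = 2L,
                             prophage_length_bp = c(15000L, 30000L),
                             arrays_per_genome = 1L, repeats_per_array = 10L,
                             repeat_length_bp = 32L, spacer_length_bp = 30L,
                             prophage_target_rate = 5,
                             backbone_target_rate = 2,
                             rng_seed = 1L) {
  cfg <- list(n_species = as.integer(n_species),
              genomes_per_species = as.integer(genomes_per_species),
              genome_length_bp = as.integer(genome_length_bp),
              prophages_per_genome = as.integer(prophages_per_genome),
              prophage_length_bp = as.integer(prophage_length_bp),
              arrays_per_genome = as.integer(arrays_per_genome),
              repeats_per_array = as.integer(repeats_per_array),
              repeat_length_bp = as.integer(repeat_length_bp),
              spacer_length_bp = as.integer(spacer_length_bp),
              prophage_target_rate = prophage_target_rate,
              backbone_target_rate = backbone_target_rate,
              rng_seed = as.integer(rng_seed))
  counts <- cfg[c("n_species", "genomes_per_species", "genome_length_bp",
                  "prophages_per_genome", "arrays_per_genome",
                  "repeats_per_array", "repeat_length_bp",
                  "spacer_length_bp")]
  if (any(unlist(counts) < 0L)) stop("all counts must be >= 0")
  if (cfg$prophage_target_rate < 0 || cfg$backbone_target_rate < 0) {
    stop("rates must be >= 0")
  }
  if (cfg$arrays_per_genome > 0L && cfg$repeats_per_array < 3L) {
    stop("repeats_per_array must be >= 3 (minimum array size)")
  }
  if (!length(cfg$prophage_length_bp) %in% c(1L, 2L)) {
    stop("prophage_length_bp must be a length or a (lo, hi) range")
  }
  arr_len <- array_span(cfg)
  planted <- cfg$prophages_per_genome * max(cfg$prophage_length_bp) +
    cfg$arrays_per_genome * arr_len
  if (cfg$genome_length_bp <= planted) {
    stop("genome_length_bp must exceed the total length of planted elements (",
         planted, " bp)")
  }
  structure(cfg, class = "community_config")
}

array_span <- function(cfg) {
  cfg$repeats_per_array * cfg$repeat_length_bp +
    max(cfg$repeats_per_array - 1L, 0L) * cfg$spacer_length_bp
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# sample a non-overlapping placement of `len` bp inside `within`
# (a data.frame of half-open intervals), avoiding `occupied`;
# rejection-sampled with a retry cap
place_element <- function(len, within, occupied, retries = 1000L) {
  room <- within[within$end - within$start >= len, , drop = FALSE]
  if (nrow(room) == 0L) return(NULL)
  w <- (room$end - room$start) - len + 1L
  for (t in seq_len(retries)) {
    i <- sample.int(nrow(room), 1L, prob = w)
    s <- room$start[i] + sample.int(w[i], 1L) - 1L
    e <- s + len
    if (nrow(occupied) == 0L || !any(s < occupied$end & e > occupied$start)) {
      return(c(s, e))
    }
  }
  NA_integer_
}

#' Plant protospacers into a genome's compartments
#'
#' Plants exact copies (or reverse complements, strand chosen uniformly) of
#' donor spacers into a genome. The number of copies is Poisson: mean
#' `prophage_rate` per prophage interval, and `backbone_rate` per Mb of
#' backbone (genome length minus prophage lengths). Placements never
#' overlap arrays, prophage/backbone boundaries, or one another;
#' compartments too short for a spacer are skipped with a warning.
#'
#' Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param genome A `genome_record` (single or multi contig).
#' @param spacers Data.frame with `spacer_id`, `sequence`, and
#'   (optionally) `donor_species` columns: the donor pool.
#' @param prophages Prophage interval data.frame for this genome (may have
#'   zero rows).
#' @param arrays Array interval data.frame for this genome (may be `NULL`).
#' @param prophage_rate Expected copies per prophage.
#' @param backbone_rate Expected copies per Mb of backbone.
#' @param occupied Optional data.frame of already-occupied intervals
#'   (`contig_id`, `start`, `end`) to avoid, e.g. previously planted copies.
#' @return List with `genome` (modified record) and `planted`, a data.frame
#'   `spacer_id`, `donor_species`, `target_genome_id`, `target_species`,
#'   `contig_id`, `start`, `end`, `strand`, `compartment`, `prophage_id`.
#' @export
plant_protospacers <- function(genome, spacers, prophages, arrays = NULL,
                               prophage_rate = 0, backbone_rate = 0,
                               occupied = NULL) {
  stopifnot(inherits(genome, "genome_record"))
  empty <- data.frame(spacer_id = character(0), donor_species = character(0),
                      target_genome_id = character(0),
                      target_species = character(0), contig_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), compartment = character(0),
                      prophage_id = character(0), stringsAsFactors = FALSE)
  if (nrow(spacers) == 0L) return(list(genome = genome, planted = empty))
  if (any(nchar(spacers$sequence) == 0L)) stop("spacer sequences must be non-empty")
  if (is.null(spacers$donor_species)) spacers$donor_species <- NA_character_
  blocked <- rbind(
    if (!is.null(arrays) && nrow(arrays)) arrays[, c("contig_id", "start", "end")],
    if (!is.null(occupied) && nrow(occupied)) occupied[, c("contig_id", "start", "end")])
  if (is.null(blocked)) {
    blocked <- data.frame(contig_id = character(0), start = integer(0),
                          end = integer(0), stringsAsFactors = FALSE)
  }
  lens <- contig_lengths(genome)
  planted <- list()

  plant_one <- function(row_i, within_ctg, compartment, prophage_id) {
    sq <- spacers$sequence[row_i]
    len <- nchar(sq)
    pos <- place_element(len, within_ctg$iv,
                         blocked[blocked$contig_id == within_ctg$ctg, ,
                                 drop = FALSE])
    if (is.null(pos)) {
      warning("compartment shorter than spacer in ", genome$genome_id,
              "; skipping a planted copy")
      return(invisible(FALSE))
    }
    if (anyNA(pos)) {
      stop("could not place a protospacer in genome ", genome$genome_id,
           " after bounded retries")
    }
    strand <- sample(c("+", "-"), 1L)
    ins <- if (strand == "+") sq else revcomp(sq)
    s <- genome$contigs[[within_ctg$ctg]]
    substr(s, pos[1L] + 1L, pos[2L]) <- ins
    genome$contigs[[within_ctg$ctg]] <<- s
    blocked <<- rbind(blocked, data.frame(contig_id = within_ctg$ctg,
                                          start = pos[1L], end = pos[2L],
                                          stringsAsFactors = FALSE))
    planted[[length(planted) + 1L]] <<- data.frame(
      spacer_id = spacers$spacer_id[row_i],
      donor_species = spacers$donor_species[row_i],
      target_genome_id = genome$genome_id, target_species = genome$species,
      contig_id = within_ctg$ctg, start = pos[1L], end = pos[2L],
      strand = strand, compartment = compartment, prophage_id = prophage_id,
      stringsAsFactors = FALSE)
    invisible(TRUE)
  }

  # prophage compartment
  if (!is.null(prophages) && nrow(prophages) > 0L && prophage_rate > 0) {
    for (i in seq_len(nrow(prophages))) {
      n <- stats::rpois(1L, prophage_rate)
      for (k in seq_len(n)) {
        ri <- sample.int(nrow(spacers), 1L)
        plant_one(ri, list(ctg = prophages$contig_id[i],
                           iv = prophages[i, c("start", "end")]),
                  "prophage", prophages$label[i])
      }
    }
  }
  # backbone compartment: per-contig complements of merged prophages
  if (backbone_rate > 0) {
    merged <- if (!is.null(prophages) && nrow(prophages) > 0L) {
      merge_intervals(cbind(genome_id = genome$genome_id, prophages))
    } else NULL
    bb_len <- 0L
    bb <- list()
    for (ctg in names(lens)) {
      pv <- if (is.null(merged)) NULL else
        merged[merged$contig_id == ctg, , drop = FALSE]
      cuts <- if (is.null(pv) || nrow(pv) == 0L) {
        data.frame(start = 0L, end = lens[[ctg]])
      } else {
        data.frame(start = c(0L, pv$end), end = c(pv$start, lens[[ctg]]))
      }
      cuts <- cuts[cuts$end > cuts$start, , drop = FALSE]
      bb[[ctg]] <- cuts
      bb_len <- bb_len + sum(cuts$end - cuts$start)
    }
    n <- stats::rpois(1L, backbone_rate * bb_len / 1e6)
    ctg_w <- vapply(bb, function(x) sum(x$end - x$start), numeric(1))
    for (k in seq_len(n)) {
      ri <- sample.int(nrow(spacers), 1L)
      ctg <- sample(names(bb), 1L, prob = ctg_w)
      plant_one(ri, list(ctg = ctg, iv = bb[[ctg]]), "backbone",
                NA_character_)
    }
  }
  planted <- if (length(planted)) do.call(rbind, planted) else empty
  list(genome = genome, planted = planted)
}

#' Generate a synthetic multi-species community with ground truth
#'
#' Builds genomes of i.i.d. uniform random sequence, plants non-overlapping
#' prophage intervals and repeat-spacer CRISPR arrays (one species-specific
#' repeat per species), then plants protospacers: for each genome, spacers
#' drawn from the arrays of every *other* genome's species are copied into
#' prophages (Poisson mean `prophage_target_rate` per prophage per donor
#' species) and into the backbone (Poisson mean `backbone_target_rate` per
#' Mb per donor species). Byte-identical output for a fixed seed.
#'
#' @param config A [community_config()].
#' @param prophage_rate_matrix Optional species-by-species matrix (rows =
#'   donor species, columns = target species) of prophage planting rates
#'   overriding the scalar `prophage_target_rate`.
#' @return List with `genomes` (named list of `genome_record`), `repeats`
#'   (seed table), and `truth`: data.frames `prophages`, `arrays`,
#'   `spacers`, `protospacers` (all 0-based half-open).
#' @export
generate_community <- function(config, prophage_rate_matrix = NULL) {
  stopifnot(inherits(config, "community_config"))
  set.seed(config$rng_seed)
  species <- sprintf("sp%02d", seq_len(config$n_species))
  if (!is.null(prophage_rate_matrix)) {
    stopifnot(all(dim(prophage_rate_matrix) == config$n_species))
    dimnames(prophage_rate_matrix) <- list(species, species)
  }
  rep_len <- config$repeat_length_bp
  repeats <- data.frame(repeat_id = paste0(species, ":rep"),
                        species = species,
                        sequence = vapply(species, function(s) random_dna(rep_len),
                                          character(1)),
                        stringsAsFactors = FALSE)
  genomes <- list()
  truth_pro <- list(); truth_arr <- list(); truth_sp <- list()

  # pass 1: genomes with prophages and arrays
  for (sp in species) {
    for (gi in seq_len(config$genomes_per_species)) {
      gid <- sprintf("%s_g%d", sp, gi)
      ctg <- "c1"
      seq <- random_dna(config$genome_length_bp)
      occupied <- data.frame(contig_id = character(0), start = integer(0),
                             end = integer(0), stringsAsFactors = FALSE)
      whole <- data.frame(start = 0L, end = config$genome_length_bp)
      # prophages
      for (pi in seq_len(config$prophages_per_genome)) {
        plen <- if (length(config$prophage_length_bp) == 2L) {
          sample(config$prophage_length_bp[1L]:config$prophage_length_bp[2L], 1L)
        } else config$prophage_length_bp
        pos <- place_element(plen, whole,
                             occupied[occupied$contig_id == ctg, , drop = FALSE])
        if (is.null(pos) || anyNA(pos)) {
          stop("could not place prophage in genome ", gid)
        }
        pid <- sprintf("%s:pro%d", gid, pi)
        occupied <- rbind(occupied, data.frame(contig_id = ctg,
                                               start = pos[1L], end = pos[2L]))
        truth_pro[[length(truth_pro) + 1L]] <- data.frame(
          genome_id = gid, contig_id = ctg, start = pos[1L], end = pos[2L],
          label = pid, stringsAsFactors = FALSE)
      }
      # arrays
      rseq <- repeats$sequence[repeats$species == sp]
      for (ai in seq_len(config$arrays_per_genome)) {
        alen <- array_span(config)
        pos <- place_element(alen, whole,
                             occupied[occupied$contig_id == ctg, , drop = FALSE])
        if (is.null(pos) || anyNA(pos)) {
          stop("could not place CRISPR array in genome ", gid)
        }
        aid <- sprintf("%s:%s:%d", gid, ctg, pos[1L])
        sps <- vapply(seq_len(config$repeats_per_array - 1L),
                      function(i) random_dna(config$spacer_length_bp),
                      character(1))
        body <- paste0(paste0(rseq, sps, collapse = ""), rseq)
        stopifnot(nchar(body) == alen)
        substr(seq, pos[1L] + 1L, pos[2L]) <- body
        occupied <- rbind(occupied, data.frame(contig_id = ctg,
                                               start = pos[1L], end = pos[2L]))
        rep_starts <- pos[1L] + (seq_len(config$repeats_per_array) - 1L) *
          (rep_len + config$spacer_length_bp)
        truth_arr[[length(truth_arr) + 1L]] <- data.frame(
          array_id = aid, genome_id = gid, species = sp, contig_id = ctg,
          start = pos[1L], end = pos[2L], strand = "+",
          repeat_id = repeats$repeat_id[repeats$species == sp],
          n_repeats = config$repeats_per_array,
          repeat_starts = paste(rep_starts, collapse = ","),
          stringsAsFactors = FALSE)
        sp_starts <- rep_starts[-length(rep_starts)] + rep_len
        truth_sp[[length(truth_sp) + 1L]] <- data.frame(
          spacer_id = sprintf("%s:s%d", aid, seq_along(sps) - 1L),
          sequence = sps, source_genome_id = gid, source_species = sp,
          array_id = aid, position_index = seq_along(sps) - 1L,
          contig_id = ctg, start = sp_starts,
          end = sp_starts + config$spacer_length_bp, stringsAsFactors = FALSE)
      }
      genomes[[gid]] <- genome_record(gid, sp, stats::setNames(seq, ctg))
    }
  }
  bind <- function(x, proto) if (length(x)) do.call(rbind, x) else proto
  prophages <- bind(truth_pro, data.frame(genome_id = character(0),
                                          contig_id = character(0),
                                          start = integer(0), end = integer(0),
                                          label = character(0)))
  arrays <- bind(truth_arr, NULL)
  spacer_tab <- bind(truth_sp, data.frame(
    spacer_id = character(0), sequence = character(0),
    source_genome_id = character(0), source_species = character(0),
    array_id = character(0), position_index = integer(0),
    contig_id = character(0), start = integer(0), end = integer(0)))

  # pass 2: plant protospacers donor species by donor species
  protospacers <- list()
  for (gid in names(genomes)) {
    g <- genomes[[gid]]
    g_pro <- prophages[prophages$genome_id == gid, , drop = FALSE]
    g_arr <- if (!is.null(arrays)) arrays[arrays$genome_id == gid, , drop = FALSE] else NULL
    occupied <- data.frame(contig_id = character(0), start = integer(0),
                           end = integer(0), stringsAsFactors = FALSE)
    for (d in species) {
      pool <- spacer_tab[spacer_tab$source_species == d &
                         spacer_tab$source_genome_id != gid, , drop = FALSE]
      if (nrow(pool) == 0L) next
      pool <- data.frame(spacer_id = pool$spacer_id, sequence = pool$sequence,
                         donor_species = d, stringsAsFactors = FALSE)
      p_rate <- if (!is.null(prophage_rate_matrix)) {
        prophage_rate_matrix[d, g$species]
      } else config$prophage_target_rate
      res <- plant_protospacers(g, pool, g_pro, g_arr,
                                prophage_rate = p_rate,
                                backbone_rate = config$backbone_target_rate,
                                occupied = occupied)
      g <- res$genome
      if (nrow(res$planted) > 0L) {
        occupied <- rbind(occupied,
                          res$planted[, c("contig_id", "start", "end")])
        protospacers[[length(protospacers) + 1L]] <- res$planted
      }
    }
    genomes[[gid]] <- g
  }
  protospacers <- bind(protospacers, data.frame(
    spacer_id = character(0), donor_species = character(0),
    target_genome_id = character(0), target_species = character(0),
    contig_id = character(0), start = integer(0), end = integer(0),
    strand = character(0), compartment = character(0),
    prophage_id = character(0)))
  list(genomes = genomes, repeats = repeats,
       truth = list(prophages = prophages, arrays = arrays,
                    spacers = spacer_tab, protospacers = protospacers),
       config = config)
}

#' Write a community to disk
#'
#' One FASTA per genome plus ground-truth TSV tables (`prophages.tsv`,
#' `arrays.tsv`, `spacers.tsv`, `protospacers.tsv`), a species table and a
#' flat key-value config file, all 0-based half-open.
#'
#' @param community Output of [generate_community()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_community <- function(community, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in community$genomes) {
    write_genome_fasta(g, file.path(dir, paste0(g$genome_id, ".fasta")))
  }
  sp <- data.frame(genome_id = names(community$genomes),
                   species = vapply(community$genomes, `[[`, character(1),
                                    "species"))
  utils::write.table(sp, file.path(dir, "species.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (nm in names(community$truth)) {
    utils::write.table(community$truth[[nm]],
                       file.path(dir, paste0(nm, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  utils::write.table(community$repeats, file.path(dir, "repeats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- community$config
  writeLines(paste0(names(cfg), ": ",
                    vapply(cfg, function(x) paste(x, collapse = ","),
                           character(1))),
             file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Simulate a classified match table at given targeting densities
#'
#' Draws spacer-match positions directly (skipping sequence generation):
#' Poisson counts per compartment at the given per-kb densities, positions
#' uniform within the compartment. With `prophage_multiplier = 1` for every
#' prophage this is uniform placement over the whole genome (a null
#' community with arbitrary prophage annotations); a multiplier of 10
#' plants a prophage at ten times the backbone targeting density.
#'
#' Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param genome_length Genome (single contig) length in bp.
#' @param prophages Prophage interval data.frame (`contig_id`, `start`,
#'   `end`, `label`; `genome_id` optional).
#' @param backbone_rate_per_kb Expected matches per kb of backbone.
#' @param prophage_multiplier Scalar or per-prophage vector: prophage
#'   density relative to the backbone density.
#' @param genome_id,contig_id Ids used in the output (defaults `g1`/`c1`).
#' @param donor_species Donor species label for all simulated matches.
#' @return A classified match data.frame compatible with
#'   [score_prophages()].
#' @export
simulate_classified_matches <- function(genome_length, prophages,
                                        backbone_rate_per_kb,
                                        prophage_multiplier = 1,
                                        genome_id = "g1", contig_id = "c1",
                                        donor_species = "spX") {
  stopifnot(nrow(prophages) >= 0L)
  if (length(prophage_multiplier) == 1L) {
    prophage_multiplier <- rep(prophage_multiplier, nrow(prophages))
  }
  stopifnot(length(prophage_multiplier) == nrow(prophages))
  pro_len <- sum(prophages$end - prophages$start)
  bb_len <- genome_length - pro_len
  rows <- list()
  add <- function(starts, compartment, prophage_id) {
    if (length(starts) == 0L) return(invisible(NULL))
    rows[[length(rows) + 1L]] <<- data.frame(
      spacer_id = NA_character_, donor_species = donor_species,
      target_genome_id = genome_id, target_species = donor_species,
      contig_id = contig_id, start = as.integer(starts),
      end = as.integer(starts) + 1L, strand = "+",
      compartment = compartment, prophage_id = prophage_id,
      stringsAsFactors = FALSE)
    invisible(NULL)
  }
  for (i in seq_len(nrow(prophages))) {
    lam <- backbone_rate_per_kb * prophage_multiplier[i] *
      (prophages$end[i] - prophages$start[i]) / 1000
    n <- stats::rpois(1L, lam)
    add(prophages$start[i] +
          sample.int(prophages$end[i] - prophages$start[i], n,
                     replace = TRUE) - 1L,
        "prophage", prophages$label[i])
  }
  # backbone: uniform over the complement of the prophage intervals
  segs <- if (nrow(prophages) > 0L) {
    m <- prophages[order(prophages$start), , drop = FALSE]
    data.frame(start = c(0L, m$end), end = c(m$start, genome_length))
  } else data.frame(start = 0L, end = genome_length)
  segs <- segs[segs$end > segs$start, , drop = FALSE]
  n <- stats::rpois(1L, backbone_rate_per_kb * bb_len / 1000)
  if (n > 0L) {
    off <- sample.int(bb_len, n, replace = TRUE) - 1L
    cum <- cumsum(segs$end - segs$start)
    si <- findInterval(off, c(0L, cum[-length(cum)] ), rightmost.closed = FALSE)
    pos <- segs$start[si] + (off - c(0L, cum)[si])
    add(pos, "backbone", NA_character_)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(spacer_id = character(0), donor_species = character(0),
               target_genome_id = character(0), target_species = character(0),
               contig_id = character(0), start = integer(0), end = integer(0),
               strand = character(0), compartment = character(0),
               prophage_id = character(0), stringsAsFactors = FALSE)
  out$spacer_id <- sprintf("sim%05d", seq_len(nrow(out)))
  out
}
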