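#' Construct a genome record
#'
#' A genome record is the unit every pipeline stage operates on: a named,
#' species-tagged, ordered set of contig sequences. Sequences are stored
#' uppercase over the alphabet `{A, C, G, T, N}`; all coordinates used by the
#' package are 0-based half-open on these contigs.
#'
#' @param genome_id Single string identifying the genome.
#' @param species Single string; the species tag used for donor/target
#'   attribution downstream.
#' @param contigs Named character vector of DNA sequences. Names are contig
#'   ids and must be unique; sequences are uppercased on construction.
#' @return An object of class `genome_record`: a list with elements
#'   `genome_id`, `species` and `contigs`.
#' @examples
#' g <- genome_record("g1", "sp1", c(c1 = "acgtACGT"))
#' g$contigs[["c1"]]  # "ACGTACGT"
#' @export
genome_record <- function(genome_id, species, contigs) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L,
            is.character(species), length(species) == 1L,
            is.character(contigs), length(contigs) >= 1L)
  ids <- names(contigs)
  if (is.null(ids) || anyNA(ids) || any(ids == "")) {
    stop("all contigs must be named")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate contig id: ", ids[duplicated(ids)][1L])
  }
  contigs <- toupper(contigs)
  if (any(nchar(contigs) == 0L)) {
    stop("empty sequence for contig: ", ids[nchar(contigs) == 0L][1L])
  }
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad)) {
    stop("non-ACGTN characters in contig: ", ids[bad][1L])
  }
  structure(list(genome_id = genome_id, species = species, contigs = contigs),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s (%s): %d contig(s), %s bp total\n",
              x$genome_id, x$species, length(x$contigs),
              format(sum(nchar(x$contigs)), big.mark = ",")))
  invisible(x)
}

#' Contig lengths of a genome record
#'
#' @param genome A `genome_record`.
#' @return Named integer vector of contig lengths.
#' @export
contig_lengths <- function(genome) {
  stopifnot(inherits(genome, "genome_record"))
  vapply(genome$contigs, nchar, integer(1))
}

#' Read a genome from a FASTA file
#'
#' Lowercase input is uppercased; record order is preserved. Round-tripping
#' through [write_genome_fasta()] preserves sequence content and order.
#'
#' @param path Path to a FASTA file.
#' @param genome_id Genome id; defaults to the file name without extension.
#' @param species Species tag (default `"unknown"`).
#' @return A `genome_record`.
#' @export
read_genome_fasta <- function(path, genome_id = NULL, species = "unknown") {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("not FASTA-formatted: ", path,
                                           " (", conditionMessage(e), ")"))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  # header up to first whitespace is the contig id
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate contig id in ", path, ": ", ids[duplicated(ids)][1L])
  }
  seqs <- as.character(set)
  names(seqs) <- ids
  if (is.null(genome_id)) {
    genome_id <- sub("\\.(fa|fasta|fna)$", "", basename(path))
  }
  genome_record(genome_id, species, seqs)
}

#' Write a genome record to FASTA
#'
#' @param genome A `genome_record`.
#' @param path Output path.
#' @param width Line width for wrapping (default 80).
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 80L) {
  stopifnot(inherits(genome, "genome_record"))
  set <- Biostrings::DNAStringSet(genome$contigs)
  names(set) <- names(genome$contigs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Reverse complement of DNA strings
#'
#' Vectorised over `x`; `N` complements to `N`.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Canonical form of a DNA sequence
#'
#' The lexicographic minimum of a sequence and its reverse complement; used
#' to treat a spacer and its reverse complement as the same sequence when
#' array orientation is arbitrary.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of canonical sequences.
#' @export
canonical_seq <- function(x) {
  if (length(x) == 0L) return(character(0))
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}
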