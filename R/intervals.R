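#' Read an interval table (BED-like TSV)
#'
#' Expects tab-separated columns `genome_id`, `contig_id`, `start`, `end`,
#' `label` with a header row. Coordinates are 0-based half-open. Every
#' interval is validated against the contig lengths of the supplied genomes;
#' overlapping intervals are permitted and preserved.
#'
#' @param path Path to the TSV file.
#' @param genomes A list of `genome_record` objects (any names), or a single
#'   `genome_record`.
#' @return A data.frame with columns `genome_id`, `contig_id`, `start`,
#'   `end`, `label`.
#' @export
read_intervals <- function(path, genomes) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character",
                                         "integer", "integer", "character"),
                          stringsAsFactors = FALSE)
  need <- c("genome_id", "contig_id", "start", "end", "label")
  if (!all(need %in% names(df))) {
    stop("interval table must have columns: ", paste(need, collapse = ", "))
  }
  validate_intervals(df[need], genomes, source = path)
}

#' Validate intervals against contig lengths
#'
#' @param df Interval data.frame (`genome_id`, `contig_id`, `start`, `end`,
#'   plus any extra columns).
#' @param genomes List of `genome_record` objects or a single record.
#' @param source Label used in error messages (default "intervals").
#' @return `df`, unchanged, if all intervals are valid.
#' @export
validate_intervals <- function(df, genomes, source = "intervals") {
  genomes <- as_genome_list(genomes)
  lens <- lapply(genomes, contig_lengths)
  names(lens) <- vapply(genomes, `[[`, character(1), "genome_id")
  for (i in seq_len(nrow(df))) {
    g <- df$genome_id[i]; ctg <- df$contig_id[i]
    if (is.null(lens[[g]]) || !(ctg %in% names(lens[[g]]))) {
      stop(source, " line ", i, ": unknown genome/contig ", g, "/", ctg)
    }
    L <- lens[[g]][[ctg]]
    if (df$start[i] < 0L || df$start[i] >= df$end[i] || df$end[i] > L) {
      stop(source, " line ", i, ": invalid interval [", df$start[i], ",",
           df$end[i], ") on contig ", ctg, " of length ", L)
    }
  }
  df
}

as_genome_list <- function(genomes) {
  if (inherits(genomes, "genome_record")) genomes <- list(genomes)
  stopifnot(all(vapply(genomes, inherits, logical(1), "genome_record")))
  names(genomes) <- vapply(genomes, `[[`, character(1), "genome_id")
  genomes
}

#' Merge intervals into a disjoint sorted set
#'
#' Overlapping or abutting intervals (half-open: `[0,100)` and `[100,200)`
#' abut) on the same genome and contig are merged; the union of covered
#' bases is preserved. Idempotent. Labels of merged members are collapsed
#' with `","` (unique, in order of appearance).
#'
#' @param df Interval data.frame with columns `genome_id`, `contig_id`,
#'   `start`, `end` and optionally `label`.
#' @return A data.frame of pairwise-disjoint intervals sorted by genome,
#'   contig and start.
#' @export
merge_intervals <- function(df) {
  cols <- c("genome_id", "contig_id", "start", "end", "label")
  if (is.null(df$label)) df$label <- ""
  if (nrow(df) == 0L) return(df[cols])
  pieces <- split(df, list(df$genome_id, df$contig_id), drop = TRUE)
  out <- lapply(pieces, function(p) {
    ir <- IRanges::IRanges(start = p$start + 1L, end = p$end)  # 1-based closed
    red <- IRanges::reduce(ir)
    ov <- IRanges::findOverlaps(ir, red)
    labs <- vapply(seq_along(red), function(j) {
      members <- S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == j]
      paste(unique(p$label[members]), collapse = ",")
    }, character(1))
    data.frame(genome_id = p$genome_id[1L], contig_id = p$contig_id[1L],
               start = IRanges::start(red) - 1L, end = IRanges::end(red),
               label = labs, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$genome_id, out$contig_id, out$start), cols]
  rownames(out) <- NULL
  out
}

#' Write an interval table as BED-like TSV
#'
#' @param df Interval data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
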