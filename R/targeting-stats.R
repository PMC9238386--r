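#' Backbone coordinates of a genome
#'
#' The backbone is the genome minus all (merged) prophage intervals. Array
#' intervals remain part of the backbone: only prophage lengths are
#' subtracted from the genome length, while array matches are removed
#' upstream — the density definition is deliberately asymmetric in this
#' way.
#'
#' @param genome A `genome_record`.
#' @param prophages Prophage interval data.frame for this genome (zero rows
#'   allowed).
#' @return List with `segments` (data.frame `contig_id`, `start`, `end`,
#'   `offset` — the excised coordinate of each segment start, restarting at
#'   0 on every contig), `backbone_length` (total bp) and `zero_backbone`
#'   flag (prophages cover the whole genome).
#' @export
backbone_coordinates <- function(genome, prophages) {
  stopifnot(inherits(genome, "genome_record"))
  lens <- contig_lengths(genome)
  merged <- if (!is.null(prophages) && nrow(prophages) > 0L) {
    merge_intervals(prophages)
  } else NULL
  segs <- list()
  for (ctg in names(lens)) {
    pv <- if (is.null(merged)) NULL else
      merged[merged$contig_id == ctg & merged$genome_id %in% genome$genome_id, ,
             drop = FALSE]
    cuts <- if (is.null(pv) || nrow(pv) == 0L) {
      data.frame(start = 0L, end = lens[[ctg]])
    } else {
      data.frame(start = c(0L, pv$end), end = c(pv$start, lens[[ctg]]))
    }
    cuts <- cuts[cuts$end > cuts$start, , drop = FALSE]
    if (nrow(cuts) == 0L) next
    cuts$contig_id <- ctg
    cuts$offset <- cumsum(c(0L, (cuts$end - cuts$start)[-nrow(cuts)]))
    segs[[ctg]] <- cuts[, c("contig_id", "start", "end", "offset")]
  }
  if (length(segs) == 0L) {
    return(list(segments = data.frame(contig_id = character(0),
                                      start = integer(0), end = integer(0),
                                      offset = integer(0)),
                backbone_length = 0L, zero_backbone = TRUE))
  }
  segments <- do.call(rbind, c(segs, make.row.names = FALSE))
  list(segments = segments,
       backbone_length = sum(segments$end - segments$start),
       zero_backbone = FALSE)
}

#' Per-bin match counts over a linear region
#'
#' Tiles `[0, region_length)` into bins of `bin_size` bp left to right and
#' counts match start positions per bin. A final partial bin is kept as its
#' own datapoint when at least `min_partial` bp, otherwise merged into the
#' previous bin (a region shorter than one bin is always a single bin).
#'
#' @param starts Integer vector of 0-based match start positions within the
#'   region.
#' @param region_length Region length in bp.
#' @param bin_size Bin width in bp (default 1000).
#' @param min_partial Minimum size of a trailing partial bin (default 100).
#' @return Integer vector of counts, one per bin; `sum(counts)` equals
#'   `length(starts)`.
#' @export
bin_counts <- function(starts, region_length, bin_size = 1000L,
                       min_partial = 100L) {
  stopifnot(bin_size > 0L, region_length > 0L,
            all(starts >= 0L & starts < region_length))
  n_full <- region_length %/% bin_size
  rem <- region_length %% bin_size
  n_bins <- if (rem == 0L) n_full
            else if (rem >= min_partial || n_full == 0L) n_full + 1L
            else n_full
  idx <- pmin(starts %/% bin_size, n_bins - 1L)  # merged tail folds into last bin
  tabulate(idx + 1L, nbins = n_bins)
}

#' Bin vector for the backbone of a genome
#'
#' Maps backbone matches to excised-and-concatenated coordinates and bins
#' them per contig; bins never span contig junctions (the tiling restarts at
#' each contig).
#'
#' @param matches Classified match data.frame rows with
#'   `compartment == "backbone"` for one genome.
#' @param backbone Output of [backbone_coordinates()] for that genome.
#' @inheritParams bin_counts
#' @return Integer vector of per-bin counts across all contigs.
#' @export
backbone_bins <- function(matches, backbone, bin_size = 1000L,
                          min_partial = 100L) {
  segs <- backbone$segments
  if (nrow(segs) == 0L) return(integer(0))
  out <- integer(0)
  for (ctg in unique(segs$contig_id)) {
    sv <- segs[segs$contig_id == ctg, , drop = FALSE]
    clen <- sum(sv$end - sv$start)
    mm <- matches[matches$contig_id == ctg, , drop = FALSE]
    pos <- integer(0)
    if (nrow(mm) > 0L) {
      for (j in seq_len(nrow(mm))) {
        i <- which(mm$start[j] >= sv$start & mm$start[j] < sv$end)
        if (length(i) != 1L) {
          stop("backbone match start outside backbone segments")
        }
        pos <- c(pos, sv$offset[i] + (mm$start[j] - sv$start[i]))
      }
    }
    out <- c(out, bin_counts(pos, clen, bin_size, min_partial))
  }
  out
}

#' One-sided Mann-Whitney U test for per-kb bin counts
#'
#' Tests whether the first sample (prophage bins) is stochastically greater
#' than the second (backbone bins). U is computed with midrank tie
#' handling. The p-value branch depends on the data:
#' tie-free samples with the smaller side at most 8 use the exact null
#' distribution; tied samples with few distinct values (the typical shape
#' of sparse per-kb count bins) use the exact conditional permutation
#' distribution of U given the pooled value multiset, enumerated over
#' value-count compositions of the smaller sample; everything else falls
#' back to the tie-corrected normal approximation with continuity
#' correction. The exact tie branch exists because the asymptotic tail is
#' anticonservative for very sparse counts, which would inflate the
#' family-wise error rate downstream. Two identical constant samples give
#' `U = n1*n2/2`, `p = 1`.
#'
#' @param x Numeric vector (prophage bins).
#' @param y Numeric vector (backbone bins).
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param max_enum Enumeration budget for the exact tie branch: maximum
#'   size of the composition grid (default 2e5).
#' @return List with `U` and `p`; both `NA` if either vector is empty.
#' @export
mann_whitney_one_sided <- function(x, y, alternative = "greater",
                                   max_enum = 2e5) {
  if (length(x) == 0L || length(y) == 0L) return(list(U = NA_real_, p = NA_real_))
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (all(pooled == pooled[1L])) {
    return(list(U = n1 * n2 / 2, p = 1))
  }
  has_ties <- anyDuplicated(pooled) > 0L
  if (!has_ties && min(n1, n2) <= 8L) {
    wt <- stats::wilcox.test(x, y, alternative = alternative, exact = TRUE)
    return(list(U = U, p = wt$p.value))
  }
  if (has_ties) {
    p <- mwu_exact_conditional(x, y, U, alternative, max_enum)
    if (!is.na(p)) return(list(U = U, p = p))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative,
                                            exact = FALSE, correct = TRUE))
  list(U = U, p = wt$p.value)
}

# exact conditional Mann-Whitney p-value for tied data: the permutation
# distribution of U given the pooled multiset depends only on how many
# observations of each distinct value fall in the smaller group, so it is
# enumerated exactly over those compositions (multivariate hypergeometric
# weights). Returns NA when the composition grid exceeds max_enum.
mwu_exact_conditional <- function(x, y, U_obs, alternative, max_enum) {
  n1 <- length(x); n2 <- length(y)
  vals <- sort(unique(c(x, y)))
  k <- length(vals)
  t_v <- as.vector(table(factor(c(x, y), levels = vals)))
  # enumerate over the smaller group; U for the other side mirrors
  swap <- n2 < n1
  n_small <- if (swap) n2 else n1
  caps <- pmin(t_v, n_small)
  if (prod(caps + 1) > max_enum) return(NA_real_)
  grid <- as.matrix(expand.grid(lapply(caps, function(m) 0:m)))
  grid <- grid[rowSums(grid) == n_small, , drop = FALSE]
  # log multivariate hypergeometric weight of each composition
  logw <- -lchoose(n1 + n2, n_small)
  for (j in seq_len(k)) logw <- logw + lchoose(t_v[j], grid[, j])
  # U(small side) from value counts: sum_vw a_v (t_w - a_w) ([v>w]+.5[v==w])
  gt <- outer(vals, vals, ">") + 0.5 * outer(vals, vals, "==")
  other <- sweep(-grid, 2, t_v, "+")         # counts in the larger group
  u_small <- rowSums((grid %*% gt) * other)
  u_grid <- if (swap) n1 * n2 - u_small else u_small
  w <- exp(logw)
  eps <- 1e-9
  p_ge <- sum(w[u_grid >= U_obs - eps])
  if (alternative == "greater") return(min(1, p_ge))
  p_le <- sum(w[u_grid <= U_obs + eps])
  min(1, 2 * min(p_ge, p_le))
}

#' Holm-Sidak step-down multiple-testing correction
#'
#' Sorts raw p-values ascending, sets adjusted
#' `p_(i) = 1 - (1 - p_(i))^(m - i + 1)`, enforces monotone non-decreasing
#' adjusted values by running maximum, and restores input order. `NA`
#' p-values are passed through as `NA` and do not count towards `m`.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]` (NAs allowed).
#' @param alpha Rejection level (default 0.05).
#' @return List with `p_adjusted` and logical `reject`
#'   (`p_adjusted <= alpha`; `NA` stays `NA`).
#' @export
holm_sidak <- function(p, alpha = 0.05) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  adj <- rep(NA_real_, length(p))
  m <- sum(ok)
  if (m > 0L) {
    pv <- p[ok]
    ord <- order(pv)
    a <- 1 - (1 - pv[ord])^(m - seq_len(m) + 1L)
    a <- cummax(a)
    tmp <- adj[ok]; tmp[ord] <- a; adj[ok] <- tmp
  }
  list(p_adjusted = adj, reject = !is.na(adj) & adj <= alpha)
}

#' Score prophages: densities, per-kb Mann-Whitney tests, Holm-Sidak
#'
#' For every prophage, computes the targeting density (matches per kb of
#' prophage), the backbone density of its genome (backbone matches per kb
#' of genome-minus-all-prophages), their ratio, and a per-kb-bin
#' Mann-Whitney U test of prophage versus backbone bins. Raw p-values are
#' Holm-Sidak adjusted across all prophages tested in the run; a prophage
#' is significant when its adjusted p-value is at most `alpha`. Genomes
#' with no surviving matches at all yield `p = NA`.
#'
#' @param matches Classified match data.frame ([classify_matches()]).
#' @param prophages Prophage interval data.frame (`genome_id`, `contig_id`,
#'   `start`, `end`, `label`).
#' @param genomes List of `genome_record` objects.
#' @param alpha Significance level after adjustment (default 0.05).
#' @param bin_size Bin width in bp (default 1000).
#' @param min_partial Minimum trailing partial bin (default 100 bp).
#' @param alternative Mann-Whitney alternative (default `"greater"`).
#' @return Data.frame, one row per prophage: ids, coordinates, lengths,
#'   counts, densities (per kb), `ratio` (`Inf` when only the backbone
#'   density is zero, `NA` when both are), `u_statistic`, `p_raw`,
#'   `p_adjusted`, `significant`.
#' @export
score_prophages <- function(matches, prophages, genomes, alpha = 0.05,
                            bin_size = 1000L, min_partial = 100L,
                            alternative = "greater") {
  genomes <- as_genome_list(genomes)
  stopifnot(nrow(prophages) >= 1L)
  rows <- vector("list", nrow(prophages))
  for (i in seq_len(nrow(prophages))) {
    pid <- prophages$label[i]; gid <- prophages$genome_id[i]
    g <- genomes[[gid]]
    if (is.null(g)) stop("no genome record for ", gid)
    g_pro <- prophages[prophages$genome_id == gid, , drop = FALSE]
    bb <- backbone_coordinates(g, g_pro)
    pro_len <- prophages$end[i] - prophages$start[i]
    gm <- matches[matches$target_genome_id == gid, , drop = FALSE]
    pm <- gm[gm$compartment == "prophage" & !is.na(gm$prophage_id) &
             gm$prophage_id == pid, , drop = FALSE]
    bm <- gm[gm$compartment == "backbone", , drop = FALSE]
    pro_density <- nrow(pm) / (pro_len / 1000)
    bb_density <- if (bb$backbone_length > 0L) {
      nrow(bm) / (bb$backbone_length / 1000)
    } else NA_real_
    ratio <- if (is.na(bb_density)) NA_real_
      else if (bb_density == 0 && pro_density > 0) Inf
      else if (bb_density == 0) NA_real_
      else pro_density / bb_density
    if (nrow(gm) == 0L || bb$backbone_length == 0L) {
      mw <- list(U = NA_real_, p = NA_real_)
    } else {
      pbins <- bin_counts(pm$start - prophages$start[i], pro_len,
                          bin_size, min_partial)
      bbins <- backbone_bins(bm, bb, bin_size, min_partial)
      mw <- mann_whitney_one_sided(pbins, bbins, alternative)
    }
    rows[[i]] <- data.frame(
      prophage_id = pid, genome_id = gid, species = g$species,
      contig_id = prophages$contig_id[i], start = prophages$start[i],
      end = prophages$end[i], prophage_length_bp = pro_len,
      prophage_matches = nrow(pm), prophage_density = pro_density,
      backbone_length_bp = bb$backbone_length, backbone_matches = nrow(bm),
      backbone_density = bb_density, ratio = ratio,
      u_statistic = mw$U, p_raw = mw$p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  hs <- holm_sidak(out$p_raw, alpha)
  out$p_adjusted <- hs$p_adjusted
  out$significant <- hs$reject
  rownames(out) <- NULL
  out
}
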