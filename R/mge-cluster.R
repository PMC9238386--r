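# k-mer start-position index of a sequence (1-based starts)
kmer_index <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(list())
  km <- substring(seq, 1:(n - k + 1L), k:n)
  split(seq_along(km), km)
}

# ungapped X-drop extension of an aligned block; returns extension length
# going outward position by position (match +1, mismatch -2)
extend_xdrop <- function(a_chars, b_chars, a_from, b_from, step, xdrop = 20L) {
  best <- 0L; best_len <- 0L; score <- 0L; len <- 0L
  i <- a_from; j <- b_from
  na <- length(a_chars); nb <- length(b_chars)
  while (i >= 1L && j >= 1L && i <= na && j <= nb) {
    score <- score + if (a_chars[i] == b_chars[j]) 1L else -2L
    len <- len + 1L
    if (score > best) { best <- score; best_len <- len }
    if (best - score > xdrop) break
    i <- i + step; j <- j + step
  }
  best_len
}

# high-identity ungapped segments between a and one orientation of b:
# exact k-mer seeds on shared diagonals, merged when the uncovered gap is
# at most max_gap, extended outward with X-drop, kept at >= min_identity
ungapped_segments <- function(a, b, k = 21L, max_gap = 50L, xdrop = 20L,
                              min_identity = 0.9) {
  idx_a <- kmer_index(a, k); idx_b <- kmer_index(b, k)
  shared <- intersect(names(idx_a), names(idx_b))
  if (length(shared) == 0L) {
    return(data.frame(a_start = integer(0), a_end = integer(0),
                      b_start = integer(0), b_end = integer(0)))
  }
  seeds_i <- integer(0); seeds_j <- integer(0)
  for (km in shared) {
    pa <- idx_a[[km]]; pb <- idx_b[[km]]
    seeds_i <- c(seeds_i, rep(pa, each = length(pb)))
    seeds_j <- c(seeds_j, rep(pb, times = length(pa)))
  }
  a_chars <- strsplit(a, "")[[1L]]
  b_chars <- strsplit(b, "")[[1L]]
  segs <- list()
  for (d in unique(seeds_i - seeds_j)) {
    ii <- sort(seeds_i[seeds_i - seeds_j == d])
    gap_break <- c(FALSE, ii[-1L] - (ii[-length(ii)] + k) > max_gap)
    for (run in split(ii, cumsum(gap_break))) {
      a1 <- run[1L]; a2 <- run[length(run)] + k - 1L  # 1-based closed
      b1 <- a1 - d; b2 <- a2 - d
      left <- extend_xdrop(a_chars, b_chars, a1 - 1L, b1 - 1L, -1L, xdrop)
      right <- extend_xdrop(a_chars, b_chars, a2 + 1L, b2 + 1L, +1L, xdrop)
      a1 <- a1 - left; b1 <- b1 - left
      a2 <- a2 + right; b2 <- b2 + right
      ident <- mean(a_chars[a1:a2] == b_chars[b1:b2])
      if (ident >= min_identity) {
        segs[[length(segs) + 1L]] <- c(a1, a2, b1, b2)
      }
    }
  }
  if (length(segs) == 0L) {
    return(data.frame(a_start = integer(0), a_end = integer(0),
                      b_start = integer(0), b_end = integer(0)))
  }
  m <- do.call(rbind, segs)
  # 0-based half-open
  data.frame(a_start = m[, 1L] - 1L, a_end = m[, 2L],
             b_start = m[, 3L] - 1L, b_end = m[, 4L])
}

covered_bases <- function(starts, ends, len) {
  if (length(starts) == 0L) return(0L)
  ir <- IRanges::reduce(IRanges::IRanges(start = starts + 1L, end = ends))
  sum(pmin(IRanges::end(ir), len) - pmax(IRanges::start(ir), 1L) + 1L)
}

#' Percent length aligned between two sequences
#'
#' Finds high-identity ungapped local alignment segments between `a` and
#' `b` (both orientations of `b`): exact k-mer seeds chained on shared
#' diagonals, greedy ungapped X-drop extension, minimum segment identity
#' filter. Segment footprints are merged on each sequence and PLA is the
#' fraction of the denominator sequence covered. With the default
#' `denominator = "shorter"`, containment of a fragment in a full-length
#' element gives PLA 1 — redundancy in the dereplication sense.
#'
#' @param a,b DNA sequence strings.
#' @param k Seed k-mer length (default 21).
#' @param max_gap Maximum uncovered gap (bp) bridged when chaining seeds on
#'   one diagonal (default 50).
#' @param xdrop X-drop threshold for ungapped extension (default 20;
#'   match +1, mismatch -2).
#' @param min_identity Minimum identity of a kept segment (default 0.9).
#' @param denominator `"shorter"` (default), `"longer"`, or `"query"`
#'   (= `a`): which sequence's length divides its covered bases.
#' @return PLA fraction in `[0, 1]`.
#' @export
pairwise_pla <- function(a, b, k = 21L, max_gap = 50L, xdrop = 20L,
                         min_identity = 0.9,
                         denominator = c("shorter", "longer", "query")) {
  denominator <- match.arg(denominator)
  la <- nchar(a); lb <- nchar(b)
  fwd <- ungapped_segments(a, b, k, max_gap, xdrop, min_identity)
  rc <- ungapped_segments(a, revcomp(b), k, max_gap, xdrop, min_identity)
  a_starts <- c(fwd$a_start, rc$a_start)
  a_ends <- c(fwd$a_end, rc$a_end)
  b_starts <- c(fwd$b_start, lb - rc$b_end)
  b_ends <- c(fwd$b_end, lb - rc$b_start)
  cov_a <- covered_bases(a_starts, a_ends, la)
  cov_b <- covered_bases(b_starts, b_ends, lb)
  val <- switch(denominator,
    shorter = if (la <= lb) cov_a / la else cov_b / lb,
    longer = if (la >= lb) cov_a / la else cov_b / lb,
    query = cov_a / la)
  min(max(val, 0), 1)
}

#' All-by-all PLA matrix
#'
#' @param elements Data.frame with `element_id` and `sequence` columns, or
#'   a named character vector of sequences.
#' @inheritParams pairwise_pla
#' @return Symmetric matrix of PLA fractions with unit diagonal; the
#'   clustering distance is `1 - pla`.
#' @export
pla_matrix <- function(elements, k = 21L, max_gap = 50L, xdrop = 20L,
                       min_identity = 0.9,
                       denominator = c("shorter", "longer", "query")) {
  denominator <- match.arg(denominator)
  if (is.character(elements)) {
    elements <- data.frame(element_id = names(elements), sequence = elements,
                           stringsAsFactors = FALSE)
  }
  ids <- elements$element_id
  stopifnot(!anyDuplicated(ids))
  n <- length(ids)
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  if (n >= 2L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        v <- pairwise_pla(elements$sequence[i], elements$sequence[j], k,
                          max_gap, xdrop, min_identity, denominator)
        m[i, j] <- v; m[j, i] <- v
      }
    }
  }
  m
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Agglomerates on a distance matrix with the unweighted average linkage
#' update; merge heights are non-decreasing. Tied merges are resolved
#' deterministically in favour of the pair whose clusters contain the
#' smallest original member indices.
#'
#' @param d Symmetric distance matrix (e.g. `1 - pla_matrix(...)`) with
#'   dimnames, or a `dist` object.
#' @param tol Symmetry tolerance (default 1e-9).
#' @return An object of class `hclust` (merge, height, labels, order,
#'   method = "average").
#' @export
average_linkage <- function(d, tol = 1e-9) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d), nrow(d) >= 2L)
  if (max(abs(d - t(d))) > tol) stop("distance matrix is asymmetric")
  n <- nrow(d)
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  active <- seq_len(n)
  node_of <- -seq_len(n)       # hclust convention: negative = leaf
  sizes <- rep(1L, n)
  minleaf <- seq_len(n)        # smallest original index per cluster
  D <- d
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (s in seq_len(n - 1L)) {
    best <- NULL
    for (ai in seq_along(active)[-length(active)]) {
      for (aj in (ai + 1L):length(active)) {
        i <- active[ai]; j <- active[aj]
        dij <- D[i, j]
        key <- c(dij, sort(c(minleaf[i], minleaf[j])))
        if (is.null(best) || lex_less(key, best$key)) {
          best <- list(i = i, j = j, key = key)
        }
      }
    }
    i <- best$i; j <- best$j
    height[s] <- D[i, j]
    merge[s, ] <- c(node_of[i], node_of[j])  # i precedes j in original order
    # average-linkage update into slot i
    for (o in active) {
      if (o == i || o == j) next
      D[i, o] <- (sizes[i] * D[i, o] + sizes[j] * D[j, o]) /
        (sizes[i] + sizes[j])
      D[o, i] <- D[i, o]
    }
    sizes[i] <- sizes[i] + sizes[j]
    minleaf[i] <- min(minleaf[i], minleaf[j])
    node_of[i] <- s
    active <- active[active != j]
  }
  hc <- list(merge = merge, height = height,
             order = dendrogram_order(merge, n), labels = labels,
             method = "average", call = match.call(),
             dist.method = "1 - PLA")
  class(hc) <- "hclust"
  hc
}

lex_less <- function(a, b) {
  for (t in seq_along(a)) {
    if (a[t] < b[t]) return(TRUE)
    if (a[t] > b[t]) return(FALSE)
  }
  FALSE
}

dendrogram_order <- function(merge, n) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1L]), walk(merge[node, 2L]))
  }
  walk(n - 1L)
}

#' Cut a dendrogram into clusters at a distance threshold
#'
#' Clusters are the connected groups after applying every merge with height
#' at most `h`.
#'
#' @param hc An `hclust` object.
#' @param h Cut height (distance).
#' @return Named integer membership vector (element_id -> cluster id).
#' @export
cut_clusters <- function(hc, h) {
  stats::cutree(hc, h = h)
}

#' Dereplicate sequences at a PLA threshold
#'
#' Computes the all-by-all PLA matrix, performs average-linkage clustering
#' on `1 - PLA`, cuts at distance `1 - threshold`, and picks one
#' representative per cluster: the longest member, ties broken by
#' lexicographically smallest id.
#'
#' @param elements Data.frame with `element_id`, `sequence` (extra columns
#'   carried through), or a named character vector.
#' @param threshold PLA dereplication threshold (default 0.95).
#' @inheritParams pairwise_pla
#' @return List with `clusters` (data.frame `element_id`, `cluster_id`,
#'   `representative`), `representatives` (character ids), `tree`
#'   (`hclust`, `NULL` for a single element) and `pla` (the matrix).
#' @export
dereplicate <- function(elements, threshold = 0.95, k = 21L, max_gap = 50L,
                        xdrop = 20L, min_identity = 0.9,
                        denominator = c("shorter", "longer", "query")) {
  denominator <- match.arg(denominator)
  if (is.character(elements)) {
    elements <- data.frame(element_id = names(elements), sequence = elements,
                           stringsAsFactors = FALSE)
  }
  n <- nrow(elements)
  stopifnot(n >= 1L)
  if (n == 1L) {
    return(list(clusters = data.frame(element_id = elements$element_id,
                                      cluster_id = 1L, representative = TRUE,
                                      stringsAsFactors = FALSE),
                representatives = elements$element_id, tree = NULL,
                pla = matrix(1, 1, 1,
                             dimnames = list(elements$element_id,
                                             elements$element_id))))
  }
  pla <- pla_matrix(elements, k, max_gap, xdrop, min_identity, denominator)
  hc <- average_linkage(1 - pla)
  mem <- cut_clusters(hc, 1 - threshold)
  lens <- nchar(elements$sequence)
  reps <- vapply(split(seq_len(n), mem), function(ix) {
    ix <- ix[order(-lens[ix], elements$element_id[ix])]
    elements$element_id[ix[1L]]
  }, character(1))
  clusters <- data.frame(element_id = elements$element_id,
                         cluster_id = as.integer(mem),
                         representative = elements$element_id %in% reps,
                         stringsAsFactors = FALSE)
  list(clusters = clusters, representatives = unname(reps), tree = hc,
       pla = pla)
}

#' Export a dendrogram as a Newick string
#'
#' Ultrametric convention: a node at merge height `h` places its children
#' at height `h / 2` from the leaves, so two leaves merged at 0.2 give
#' `"(A:0.1,B:0.1);"`. A single leaf gives `"A;"`.
#'
#' @param hc An `hclust` object, or `NULL` with `labels` of length 1.
#' @param labels Optional single label for the degenerate one-leaf case.
#' @return Newick string (with trailing `";"`).
#' @export
to_newick <- function(hc, labels = NULL) {
  if (is.null(hc)) {
    stopifnot(length(labels) == 1L)
    return(paste0(labels, ";"))
  }
  stopifnot(inherits(hc, "hclust"))
  node_height <- function(node) {
    if (node < 0) 0 else hc$height[node] / 2
  }
  walk <- function(node, parent_h) {
    if (node < 0) {
      sprintf("%s:%s", hc$labels[-node], format(parent_h, digits = 10))
    } else {
      h <- node_height(node)
      sprintf("(%s,%s):%s", walk(hc$merge[node, 1L], h),
              walk(hc$merge[node, 2L], h),
              format(parent_h - h, digits = 10))
    }
  }
  root <- nrow(hc$merge)
  h <- node_height(root)
  paste0("(", walk(hc$merge[root, 1L], h), ",",
         walk(hc$merge[root, 2L], h), ");")
}

#' Flag prophage predictions that cluster with non-phage MGEs
#'
#' Clusters dereplicated prophage predictions together with reference
#' mobile elements (plasmids, genetic islands) at the PLA threshold and
#' flags every prediction sharing a cut cluster with a reference of
#' category `plasmid` or `genetic_island`. Flagged predictions are excluded
#' from host inference downstream.
#'
#' @param prophages Data.frame `element_id`, `sequence` (category implied
#'   `predicted_prophage`).
#' @param references Data.frame `element_id`, `sequence`, `category`
#'   (`plasmid` / `genetic_island`); `NULL` or empty flags nothing.
#' @param threshold PLA cut threshold (default 0.95).
#' @inheritParams pairwise_pla
#' @return Data.frame `element_id`, `cluster_id`, `coclusters_with_mge`
#'   (one row per prophage prediction).
#' @export
cocluster_with_references <- function(prophages, references = NULL,
                                      threshold = 0.95, k = 21L,
                                      max_gap = 50L, xdrop = 20L,
                                      min_identity = 0.9,
                                      denominator = c("shorter", "longer",
                                                      "query")) {
  denominator <- match.arg(denominator)
  if (is.null(references) || nrow(references) == 0L) {
    return(data.frame(element_id = prophages$element_id,
                      cluster_id = seq_len(nrow(prophages)),
                      coclusters_with_mge = FALSE, stringsAsFactors = FALSE))
  }
  stopifnot(all(references$category %in% c("plasmid", "genetic_island",
                                           "known_phage")))
  all_el <- rbind(
    data.frame(element_id = prophages$element_id,
               sequence = prophages$sequence,
               category = "predicted_prophage", stringsAsFactors = FALSE),
    references[, c("element_id", "sequence", "category")])
  dr <- dereplicate(all_el, threshold, k, max_gap, xdrop, min_identity,
                    denominator)
  mem <- dr$clusters
  bad_clusters <- unique(mem$cluster_id[
    all_el$category %in% c("plasmid", "genetic_island")])
  pro <- mem[all_el$category == "predicted_prophage", , drop = FALSE]
  data.frame(element_id = pro$element_id, cluster_id = pro$cluster_id,
             coclusters_with_mge = pro$cluster_id %in% bad_clusters,
             stringsAsFactors = FALSE)
}
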