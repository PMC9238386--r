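# Independent brute-force oracles and small fixture builders.
# These deliberately avoid the code paths they check.

rnd_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc_chr <- function(x) chartr("ACGT", "TGCA", vapply(x, function(s) {
  paste(rev(strsplit(s, "")[[1]]), collapse = "")
}, character(1), USE.NAMES = FALSE))

make_genome <- function(seq, id = "g1", sp = "spA", ctg = "c1") {
  genome_record(id, sp, stats::setNames(seq, ctg))
}

# naive windowed zero-mismatch scan over both strands (vectorised substring
# comparison); palindromic loci reported once on "+"
naive_exact_scan <- function(spacers, genome) {
  out <- list()
  for (ctg in names(genome$contigs)) {
    s <- genome$contigs[[ctg]]
    n <- nchar(s)
    for (L in unique(nchar(spacers))) {
      if (L > n) next
      win <- substring(s, 1:(n - L + 1L), L:n)
      for (id in names(spacers)[nchar(spacers) == L]) {
        sq <- spacers[[id]]
        fw <- which(win == sq)
        rv <- which(win == rc_chr(sq))
        st <- sort(unique(c(fw, rv)))
        if (length(st) == 0L) next
        out[[length(out) + 1L]] <- data.frame(
          spacer_id = id, contig_id = ctg, start = st - 1L,
          strand = as.character(ifelse(st %in% fw, "+", "-")),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(spacer_id = character(0), contig_id = character(0),
                      start = integer(0), strand = character(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$contig_id, res$start, res$spacer_id), ]
}

# naive sliding-window Hamming scan over both strands
naive_hamming_scan <- function(rep_seq, seq, max_mm) {
  s <- strsplit(seq, "")[[1L]]
  scan_one <- function(pat) {
    p <- strsplit(pat, "")[[1L]]
    L <- length(p); n <- length(s)
    if (L > n) return(integer(0))
    mism <- integer(n - L + 1L)
    for (j in seq_len(L)) {
      mism <- mism + (s[j:(n - L + j)] != p[j])
    }
    which(mism <= max_mm)
  }
  fw <- scan_one(rep_seq)
  rv <- scan_one(rc_chr(rep_seq))
  st <- sort(unique(c(fw, rv)))
  data.frame(start = st - 1L,
             strand = as.character(ifelse(st %in% fw, "+", "-")),
             stringsAsFactors = FALSE)
}

# exhaustive permutation enumeration of the one-sided Mann-Whitney test
mwu_enum_oracle <- function(x, y) {
  u_of <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  pooled <- c(x, y)
  n1 <- length(x)
  u_obs <- u_of(x, y)
  ix <- utils::combn(length(pooled), n1)
  us <- apply(ix, 2, function(i) u_of(pooled[i], pooled[-i]))
  list(U = u_obs, p = mean(us >= u_obs - 1e-12))
}

# mutate a sequence with substitutions at the given per-base rate
mutate_seq <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1L]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

# ten groups of near-duplicate sequences for dereplication checks
make_derep_groups <- function(n_groups = 10L, per_group = 5L,
                              len = 2000L, mut_rate = 0.01) {
  masters <- replicate(n_groups, rnd_dna(len))
  el <- list()
  for (g in seq_len(n_groups)) {
    for (m in seq_len(per_group)) {
      el[[length(el) + 1L]] <- data.frame(
        element_id = sprintf("grp%02d_m%d", g, m),
        sequence = if (m == 1L) masters[g] else mutate_seq(masters[g], mut_rate),
        group = g, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, el)
}
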