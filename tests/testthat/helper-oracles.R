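# Independent reference implementations used as oracles.  These are
# deliberately naive (substring scans, explicit enumeration) and share
# no code with the package internals they check.

# brute-force 0-based cut positions: compare every substring to the motif
oracle_cuts <- function(seq, motif, cut_offset) {
  L <- nchar(seq)
  m <- nchar(motif)
  if (L < m) return(integer(0))
  starts <- which(substring(seq, 1:(L - m + 1), m:L) == motif)
  sort((starts - 1L) + cut_offset)
}

# fragments implied by brute-force cuts (0-based half-open, no empties)
oracle_fragments <- function(seq, motif, cut_offset) {
  L <- nchar(seq)
  cuts <- oracle_cuts(seq, motif, cut_offset)
  bounds <- unique(c(0L, cuts[cuts > 0L & cuts < L], L))
  data.frame(start = bounds[-length(bounds)], end = bounds[-1L])
}

# textbook BH step-up, written from the definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  sorted <- p[o] * n / seq_len(n)
  for (k in seq_len(n)) adj[k] <- min(sorted[k:n], 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# reverse complement without Biostrings
oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# exhaustive allele scoring: enumerate every motif-length window
# overlapping the SNP on both strands, score from first principles
oracle_allele_best <- function(counts, pseudocount, background, context,
                               snp_offset, base) {
  probs <- apply(counts, 2, function(col)
    (col + pseudocount / 4) / (sum(col) + pseudocount))
  rownames(probs) <- c("A", "C", "G", "T")
  L <- ncol(probs)
  seq <- context
  substr(seq, snp_offset + 1, snp_offset + 1) <- base
  best <- -Inf
  for (o in (snp_offset - L + 1):snp_offset) {
    for (w in c(substr(seq, o + 1, o + L),
                oracle_revcomp(substr(seq, o + 1, o + L)))) {
      b <- strsplit(w, "")[[1]]
      if (any(!b %in% c("A", "C", "G", "T"))) next
      s <- 0
      for (j in seq_len(L))
        s <- s + log2(probs[b[j], j] / background[match(b[j],
                                                        c("A","C","G","T"))])
      best <- max(best, s)
    }
  }
  best
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
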