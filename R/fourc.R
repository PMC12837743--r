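#' Demultiplex paired 4C reads on the reading primer and trim it
#'
#' A read pair is kept iff exactly one mate begins with the bait's
#' reading primer (Hamming distance over the primer length
#' `<= max_mismatch`; the match is anchored at the read start).  Pairs
#' where neither or both mates match are discarded and counted.  For each
#' kept pair two capture sequences are emitted: the primer-bearing mate
#' with the primer prefix removed (`side = "bait"`, carrying bait-side
#' sequence up to the ligation junction) and the untouched partner mate
#' (`side = "partner"`, carrying the captured fragment).
#'
#' @param pairs data.frame with columns `pair_id`, `read1`, `read2`.
#' @param bait a [bait_spec()].
#' @param max_mismatch maximum primer mismatches tolerated (default 0).
#' @return list with `captures` (data.frame `pair_id`, `sequence`,
#'   `origin` — which mate carried the primer —, `side`) and `stats`
#'   (named counts: `n_pairs`, `n_kept`, `n_no_primer`, `n_both_primer`).
#' @export
demultiplex_and_trim <- function(pairs, bait, max_mismatch = 0L) {
  stopifnot(is.data.frame(pairs),
            all(c("pair_id", "read1", "read2") %in% names(pairs)))
  primer <- bait$reading_primer
  stop_if(any(nchar(pairs$read1) == 0L) || any(nchar(pairs$read2) == 0L),
          "empty read in pair input")
  m1 <- hamming_prefix(pairs$read1, primer) <= max_mismatch
  m2 <- hamming_prefix(pairs$read2, primer) <= max_mismatch
  m1[is.na(m1)] <- FALSE
  m2[is.na(m2)] <- FALSE
  keep <- xor(m1, m2)
  origin <- ifelse(m1, "read1", "read2")[keep]
  primer_mate <- ifelse(m1, pairs$read1, pairs$read2)[keep]
  partner_mate <- ifelse(m1, pairs$read2, pairs$read1)[keep]
  captures <- data.frame(
    pair_id = rep(pairs$pair_id[keep], 2L),
    sequence = c(substr(primer_mate, nchar(primer) + 1L,
                        nchar(primer_mate)),
                 partner_mate),
    origin = rep(origin, 2L),
    side = rep(c("bait", "partner"), each = sum(keep)),
    stringsAsFactors = FALSE)
  captures <- captures[nchar(captures$sequence) > 0L, , drop = FALSE]
  rownames(captures) <- NULL
  list(captures = captures,
       stats = c(n_pairs = nrow(pairs), n_kept = sum(keep),
                 n_no_primer = sum(!m1 & !m2),
                 n_both_primer = sum(m1 & m2)))
}

# 0-based cut positions of several enzymes in a vector of sequences;
# returns a list of integer vectors.  Overlap-aware via fixed-string
# scanning of each motif at every offset.
cut_positions_multi <- function(seqs, enzymes) {
  cuts <- vector("list", length(seqs))
  cuts[] <- list(integer(0))
  for (e in enzymes) {
    hits <- gregexpr(paste0("(?=", e$motif, ")"), seqs, perl = TRUE)
    for (i in seq_along(seqs)) {
      p <- hits[[i]]
      if (p[1] != -1L)
        cuts[[i]] <- c(cuts[[i]], as.integer(p) - 1L + e$cut_offset)
    }
  }
  lapply(cuts, function(x) sort(unique(x)))
}

#' Digest capture sequences in silico
#'
#' Splits each sequence at every enzyme cut position (same cut rule as
#' [digest_genome()], overlapping occurrences included) and drops
#' sub-sequences shorter than `min_len`.
#'
#' @param seqs character vector of DNA sequences.
#' @param enzymes a single [enzyme_spec()] or a list of them.
#' @param min_len minimum retained sub-sequence length (default 1).
#' @return a list (one element per input sequence) of character vectors
#'   of retained sub-sequences, in left-to-right order.
#' @examples
#' digest_read("TTGATCAA", enzyme("DpnII"), min_len = 2)
#' @export
digest_read <- function(seqs, enzymes, min_len = 1L) {
  stop_if(min_len < 1L, "min_len must be >= 1")
  if (inherits(enzymes, "enzyme_spec")) enzymes <- list(enzymes)
  cuts <- cut_positions_multi(seqs, enzymes)
  lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    L <- nchar(s)
    bounds <- unique(c(0L, cuts[[i]][cuts[[i]] > 0L & cuts[[i]] < L], L))
    out <- substring(s, bounds[-length(bounds)] + 1L, bounds[-1L])
    out[nchar(out) >= min_len]
  })
}

#' Place sequences by exact, genome-unique matching
#'
#' A toy-scale aligner for the simulated genome: a sequence is placed iff
#' it occurs exactly once in the reference considering both strands (the
#' reverse complement is searched too).  Ambiguous (two or more
#' occurrences) and absent sequences are discarded and counted.  Real
#' data aligned externally enters via [load_placements_sam()] instead.
#'
#' @param seqs character vector of DNA sequences (may repeat; placement
#'   is computed once per distinct sequence).
#' @param refs a reference set.
#' @param min_len sequences shorter than this seed length are dropped
#'   before matching (default 20).
#' @return list with `placements` (data.frame `seq` index into `seqs`,
#'   `chrom`, `start` 0-based leftmost base, `width`, `strand`) and
#'   `stats` (`n_input`, `n_placed`, `n_ambiguous`, `n_unplaced`,
#'   `n_too_short`).
#' @export
place_sequences <- function(seqs, refs, min_len = 20L) {
  refs <- reference_set(refs)
  ok <- nchar(seqs) >= min_len
  uni <- unique(seqs[ok])
  hit <- place_unique_sequences(uni, refs)
  idx <- match(seqs, uni)           # NA for too-short
  placed <- which(ok & !is.na(hit$chrom[idx]))
  placements <- data.frame(
    seq = placed,
    chrom = hit$chrom[idx[placed]],
    start = hit$start[idx[placed]],
    width = nchar(seqs[placed]),
    strand = hit$strand[idx[placed]],
    stringsAsFactors = FALSE)
  n_amb <- sum(hit$n_occ[idx[which(ok)]] > 1L)
  n_unp <- sum(hit$n_occ[idx[which(ok)]] == 0L)
  list(placements = placements,
       stats = c(n_input = length(seqs), n_placed = length(placed),
                 n_ambiguous = n_amb, n_unplaced = n_unp,
                 n_too_short = sum(!ok)))
}

# Exact matching of distinct sequences against both strands of the
# reference.  A single variable-width PDict (trusted-band prefix of the
# shortest pattern) per strand keeps this fast at library scale.
# Returns per-sequence occurrence count and, for unique hits, the
# forward-coordinate leftmost 0-based start and strand.
place_unique_sequences <- function(uni, refs) {
  n <- length(uni)
  n_occ <- integer(n)
  chrom <- rep(NA_character_, n)
  start <- rep(NA_integer_, n)
  strand <- rep(NA_character_, n)
  if (n == 0L)
    return(list(n_occ = n_occ, chrom = chrom, start = start, strand = strand))
  clean <- grepl("^[ACGT]+$", uni)     # ambiguity codes can never place
  ii <- which(clean)
  if (length(ii) > 0L) {
    pats <- Biostrings::DNAStringSet(uni[ii])
    tb <- min(Biostrings::width(pats))
    pd_f <- Biostrings::PDict(pats, tb.start = 1L, tb.width = tb)
    pd_r <- Biostrings::PDict(Biostrings::reverseComplement(pats),
                              tb.start = 1L, tb.width = tb)
    for (ch in names(refs)) {
      subject <- refs[[ch]]
      for (sd in c("+", "-")) {
        pd <- if (sd == "+") pd_f else pd_r
        m <- Biostrings::matchPDict(pd, subject)
        cnt <- S4Vectors::elementNROWS(m)
        for (k in which(cnt > 0L)) {
          i <- ii[k]
          n_occ[i] <- n_occ[i] + cnt[k]
          if (n_occ[i] == 1L && cnt[k] == 1L) {
            s1 <- BiocGenerics::start(m[[k]])   # 1-based on forward coords
            chrom[i] <- ch
            start[i] <- s1 - 1L
            strand[i] <- sd
          }
        }
      }
    }
  }
  amb <- n_occ != 1L
  chrom[amb] <- NA_character_
  start[amb] <- NA_integer_
  strand[amb] <- NA_character_
  list(n_occ = n_occ, chrom = chrom, start = start, strand = strand)
}

#' Load read placements from a SAM file
#'
#' Ingestion route for real data aligned externally.  Keeps primary,
#' mapped records with MAPQ at or above `min_mapq`; converts SAM 1-based
#' leftmost positions to the package's 0-based convention and derives the
#' reference-space width from the CIGAR string.
#'
#' @param path path to a SAM file (with header).
#' @param refs reference set the alignments must refer to.
#' @param min_mapq minimum mapping quality retained (default 1).
#' @return data.frame with columns `chrom`, `start`, `width`, `strand`.
#' @export
load_placements_sam <- function(path, refs, min_mapq = 1L) {
  refs <- reference_set(refs)
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  res <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      what = c("rname", "pos", "strand", "mapq", "cigar", "flag")))[[1]]
  flag <- res$flag
  keep <- !is.na(res$pos) &
    bitwAnd(flag, 0x4) == 0L &          # mapped
    bitwAnd(flag, 0x100) == 0L &        # not secondary
    bitwAnd(flag, 0x800) == 0L          # not supplementary
  mapq <- res$mapq
  mapq[is.na(mapq)] <- 255L
  keep <- keep & mapq >= min_mapq
  rname <- as.character(res$rname[keep])
  stop_if(!all(rname %in% names(refs)),
          "SAM reference name not in reference set: ",
          paste(unique(setdiff(rname, names(refs))), collapse = ", "))
  data.frame(chrom = rname,
             start = res$pos[keep] - 1L,
             width = cigar_ref_width(res$cigar[keep]),
             strand = as.character(res$strand[keep]),
             stringsAsFactors = FALSE)
}

# reference-consumed width of CIGAR strings (M, D, N, =, X ops)
cigar_ref_width <- function(cigar) {
  vapply(regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar)), function(ops) {
    n <- as.integer(sub("[A-Z=]$", "", ops))
    op <- sub("^\\d+", "", ops)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, 0L)
}

#' Per-fragment read coverage in RPM
#'
#' Assigns each placement to the restriction fragment containing its
#' 5'-most aligned base (the leftmost base on `+`, the rightmost on `-`;
#' fragment boundaries follow the half-open rule) and converts counts to
#' reads per million over the total assigned placements.
#'
#' @param placements data.frame with `chrom`, `start`, `width`, `strand`
#'   (from [place_sequences()] or [load_placements_sam()]).
#' @param fragmap a `fragment_map`.
#' @param replicate_id label stored on the result.
#' @return a `fragment_coverage`: data.frame `fragment_id`, `count`,
#'   `rpm` (covered fragments only), with `replicate_id` and
#'   `total_assigned` attributes.
#' @export
coverage_per_fragment <- function(placements, fragmap, replicate_id = "rep1") {
  stop_if(!all(placements$chrom %in% fragmap$chrom),
          "placement chromosome missing from fragment map")
  pos5 <- ifelse(placements$strand == "-",
                 placements$start + placements$width - 1L,
                 placements$start)
  fid <- integer(nrow(placements))
  for (ch in unique(placements$chrom)) {
    sub <- fragmap[fragmap$chrom == ch, ]
    sel <- placements$chrom == ch
    fid[sel] <- sub$fragment_id[findInterval(pos5[sel], sub$start)]
  }
  stop_if(length(fid) == 0L, "no placements assigned; RPM undefined")
  tab <- table(fid)
  total <- sum(tab)
  cov <- data.frame(fragment_id = as.integer(names(tab)),
                    count = as.integer(tab),
                    rpm = as.numeric(tab) / total * 1e6)
  cov <- cov[order(cov$fragment_id), ]
  rownames(cov) <- NULL
  structure(cov, replicate_id = replicate_id, total_assigned = total,
            class = c("fragment_coverage", "data.frame"))
}

#' Call reproducible bait interactions from replicate coverages
#'
#' A fragment is called iff its RPM exceeds `rpm_threshold` in every
#' replicate and it is neither the bait fragment nor within the bait's
#' exclusion radius (in fragments, same chromosome).  Calls are flagged
#' cis/trans relative to the bait chromosome; cis calls carry the signed
#' distance from the fragment midpoint to the SNP.
#'
#' @param covs list of >= 2 `fragment_coverage` objects over the same
#'   fragment map.
#' @param bait a [bait_spec()].
#' @param fragmap the `fragment_map` the coverages were computed on.
#' @param rpm_threshold per-replicate RPM threshold (default 50, strict
#'   `>`).
#' @return data.frame with columns `fragment_id`, `chrom`, `start`,
#'   `end`, one `rpm_rep<i>` column per replicate, `is_cis`,
#'   `distance_to_bait` (NA for trans), ordered by `fragment_id`.
#' @export
call_interactions <- function(covs, bait, fragmap, rpm_threshold = 50) {
  stop_if(length(covs) < 2L, "need >= 2 replicates")
  ids <- fragmap$fragment_id
  rpm <- vapply(covs, function(cv) {
    stop_if(!all(cv$fragment_id %in% ids),
            "coverage refers to fragments absent from the fragment map")
    v <- numeric(length(ids))
    v[match(cv$fragment_id, ids)] <- cv$rpm
    v
  }, numeric(length(ids)))
  pass <- rowSums(rpm > rpm_threshold) == length(covs)
  excl <- fragmap$chrom == bait$chrom &
    abs(ids - bait$bait_fragment_id) <= bait$exclusion_radius_fragments
  sel <- which(pass & !excl)
  calls <- data.frame(fragment_id = ids[sel],
                      chrom = fragmap$chrom[sel],
                      start = fragmap$start[sel],
                      end = fragmap$end[sel],
                      stringsAsFactors = FALSE)
  rpmcols <- as.data.frame(rpm[sel, , drop = FALSE])
  names(rpmcols) <- paste0("rpm_rep", seq_along(covs))
  calls <- cbind(calls, rpmcols)
  calls$is_cis <- calls$chrom == bait$chrom
  calls$distance_to_bait <-
    ifelse(calls$is_cis,
           (calls$start + calls$end) / 2 - bait$position, NA_real_)
  rownames(calls) <- NULL
  calls
}

#' Summarize an interaction call set into cis/trans counts
#'
#' @param calls call table from [call_interactions()] (or any data.frame
#'   with a logical `is_cis` column).
#' @return list with `n_total`, `n_cis`, `n_trans`, `pct_cis`,
#'   `pct_trans` (percentages rounded to 2 decimals).
#' @examples
#' summarize_cis_trans(data.frame(is_cis = rep(c(TRUE, FALSE), c(416, 138))))
#' @export
summarize_cis_trans <- function(calls) {
  stop_if(nrow(calls) == 0L, "empty call set")
  n_cis <- sum(calls$is_cis)
  n_total <- nrow(calls)
  list(n_total = n_total, n_cis = n_cis, n_trans = n_total - n_cis,
       pct_cis = round(100 * n_cis / n_total, 2),
       pct_trans = round(100 * (n_total - n_cis) / n_total, 2))
}

#' Export coverage and calls as genome-browser tracks
#'
#' Writes per-fragment RPM as bedGraph and the call set as BED (name =
#' fragment_id, score = minimum replicate RPM capped at 1000).
#'
#' @param cov a `fragment_coverage`.
#' @param calls call table from [call_interactions()].
#' @param fragmap the `fragment_map`.
#' @param bedgraph_path,bed_path output paths.
#' @return invisibly, the two paths.
#' @export
export_tracks <- function(cov, calls, fragmap, bedgraph_path, bed_path) {
  i <- match(cov$fragment_id, fragmap$fragment_id)
  bg <- data.frame(chrom = fragmap$chrom[i], start = fragmap$start[i],
                   end = fragmap$end[i],
                   score = format(cov$rpm, digits = 15, scientific = FALSE,
                                  trim = TRUE))
  con <- file(bedgraph_path, "w")
  writeLines("track type=bedGraph name=fragment_rpm", con)
  utils::write.table(bg, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  rpmcols <- grep("^rpm_rep", names(calls), value = TRUE)
  con <- file(bed_path, "w")
  writeLines("# baitlink interaction calls (score = min replicate RPM, capped at 1000)",
             con)
  if (nrow(calls) > 0L) {
    minrpm <- do.call(pmin, calls[rpmcols])
    bed <- data.frame(chrom = calls$chrom, start = calls$start,
                      end = calls$end, name = calls$fragment_id,
                      score = pmin(round(minrpm), 1000L))
    utils::write.table(bed, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  close(con)
  invisible(c(bedgraph = bedgraph_path, bed = bed_path))
}

#' Run the full viewpoint 4C pipeline on one replicate's FASTQ pair
#'
#' Convenience wrapper: demultiplex on the reading primer, digest the
#' capture sequences in silico with both cutters, place them by exact
#' unique matching, and compute per-fragment RPM coverage.
#'
#' @param fastq1,fastq2 paths to the mate FASTQ files.
#' @param refs reference set.
#' @param fragmap fragment map (first cutter).
#' @param bait a [bait_spec()].
#' @param enzymes list of [enzyme_spec()]s used for read-level digestion
#'   (default DpnII + CviQI).
#' @param max_mismatch primer mismatches tolerated (default 0).
#' @param min_len minimum placed sub-sequence length (default 20).
#' @param replicate_id label for the coverage object.
#' @return a `fragment_coverage` (stats from each stage in
#'   `attr(, "pipeline_stats")`).
#' @export
run_4c_replicate <- function(fastq1, fastq2, refs, fragmap, bait,
                             enzymes = list(enzyme("DpnII"), enzyme("CviQI")),
                             max_mismatch = 0L, min_len = 20L,
                             replicate_id = "rep1") {
  r1 <- Biostrings::readDNAStringSet(fastq1, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(fastq2, format = "fastq")
  stop_if(length(r1) != length(r2), "mate FASTQ files differ in length")
  pairs <- data.frame(pair_id = sub("\\s.*$", "", names(r1)),
                      read1 = as.character(r1), read2 = as.character(r2),
                      stringsAsFactors = FALSE)
  dm <- demultiplex_and_trim(pairs, bait, max_mismatch)
  # digest distinct capture sequences once, then expand
  uni <- unique(dm$captures$sequence)
  dig <- digest_read(uni, enzymes, min_len = 1L)
  pieces <- unlist(dig[match(dm$captures$sequence, uni)], use.names = FALSE)
  pl <- place_sequences(pieces, refs, min_len = min_len)
  cov <- coverage_per_fragment(pl$placements, fragmap, replicate_id)
  attr(cov, "pipeline_stats") <- list(demultiplex = dm$stats,
                                      placement = pl$stats)
  cov
}
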