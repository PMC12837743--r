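#' Construct a position weight matrix model
#'
#' Wraps a 4 x L count matrix (rows A, C, G, T) with a pseudocount and a
#' background distribution.  Column probabilities are computed as
#' `(count + pseudocount/4) / (colsum + pseudocount)` — the pseudocount
#' is split equally across the four bases.
#'
#' @param counts numeric 4 x L matrix of non-negative counts; rows in
#'   A, C, G, T order (rownames set accordingly if absent).
#' @param name model name.
#' @param pseudocount total pseudocount per column (default 0.8).
#' @param background length-4 base background probabilities summing to 1
#'   (default uniform).
#' @return an object of class `pwm_model`.
#' @export
pwm_model <- function(counts, name = "pwm",
                      pseudocount = 0.8, background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  stop_if(nrow(counts) != 4L, "counts must have 4 rows (A, C, G, T)")
  stop_if(ncol(counts) < 4L, "motif length must be >= 4")
  stop_if(any(counts < 0), "negative counts")
  stop_if(pseudocount <= 0, "pseudocount must be > 0")
  stop_if(length(background) != 4L || abs(sum(background) - 1) > 1e-9,
          "background must be 4 probabilities summing to 1")
  rownames(counts) <- c("A", "C", "G", "T")
  background <- stats::setNames(as.numeric(background), c("A", "C", "G", "T"))
  structure(list(name = name, counts = counts, pseudocount = pseudocount,
                 background = background),
            class = "pwm_model")
}

#' @export
print.pwm_model <- function(x, ...) {
  p <- pwm_probabilities(x)
  consensus <- paste(rownames(p)[apply(p, 2, which.max)], collapse = "")
  cat(sprintf("<pwm_model> %s  length %d  consensus %s\n",
              x$name, ncol(p), consensus))
  invisible(x)
}

#' @rdname pwm_model
#' @param pwm a `pwm_model`.
#' @return `pwm_probabilities()` returns the 4 x L probability matrix
#'   (columns sum to 1).
#' @export
pwm_probabilities <- function(pwm) {
  cs <- colSums(pwm$counts)
  sweep(pwm$counts + pwm$pseudocount / 4, 2, cs + pwm$pseudocount, "/")
}

#' Load a JASPAR PFM file
#'
#' Parses the JASPAR position-frequency-matrix text format: a header
#' line `>ID name` followed by four base rows, either bracketed
#' (`A [ 1 2 3 ]`) or plain whitespace-separated counts.
#'
#' @param path path to a `.pfm`/`.jaspar` file (first matrix is read).
#' @inheritParams pwm_model
#' @return a `pwm_model`.
#' @export
load_jaspar_pfm <- function(path, pseudocount = 0.8,
                            background = rep(0.25, 4)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  header <- grepl("^>", lines)
  name <- if (any(header)) sub("^>\\s*", "", lines[which(header)[1]]) else "pwm"
  rows <- lines[!header][1:4]
  stop_if(anyNA(rows), "expected 4 matrix rows")
  parse_row <- function(r) {
    r <- sub("^\\s*[ACGTacgt]?\\s*\\[?", "", r)
    r <- sub("\\]\\s*$", "", r)
    vals <- suppressWarnings(as.numeric(strsplit(trimws(r), "\\s+")[[1]]))
    stop_if(anyNA(vals), "non-numeric count in PFM row: ", r)
    vals
  }
  counts <- lapply(rows, parse_row)
  stop_if(length(unique(lengths(counts))) != 1L,
          "PFM rows have unequal lengths")
  counts <- do.call(rbind, counts)
  pwm_model(counts, name = name, pseudocount = pseudocount,
            background = background)
}

# log2-odds score of one L-mer (character scalar) under the PWM; NA if
# the window contains a base outside A/C/G/T.
score_window <- function(window, probs, background) {
  b <- strsplit(window, "", fixed = TRUE)[[1]]
  i <- match(b, rownames(probs))
  if (anyNA(i)) return(NA_real_)
  sum(log2(probs[cbind(i, seq_along(i))] / background[i]))
}

#' Score both alleles of a SNP against a PWM
#'
#' For each allele the SNP base is substituted into the context, every
#' motif-length window overlapping the SNP is scored on both strands as
#' the sum of per-position log2(p/background) (bits), and the maximum is
#' taken.  Windows containing N are skipped; an error is raised if every
#' window is skipped.
#'
#' @param pwm a `pwm_model`.
#' @param context DNA string around the SNP; every motif-length window
#'   overlapping the SNP must fit inside it.
#' @param snp_offset 0-based offset of the SNP within `context`.
#' @param ref_base,alt_base the two alleles; `substr(context,
#'   snp_offset+1, snp_offset+1)` must equal `ref_base`.
#' @return list with `snp_id`-less report fields: `allele_ref`,
#'   `allele_alt`, `best_score_ref`, `best_score_alt`,
#'   `best_window_ref`, `best_window_alt` (each a list `offset` 0-based,
#'   `strand`), and `delta = best_score_alt - best_score_ref`.
#' @export
score_alleles <- function(pwm, context, snp_offset, ref_base, alt_base) {
  context <- toupper(context)
  snp_offset <- as.integer(snp_offset)
  probs <- pwm_probabilities(pwm)
  L <- ncol(probs)
  n <- nchar(context)
  stop_if(snp_offset < 0 || snp_offset >= n, "SNP offset outside context")
  stop_if(snp_offset < L - 1L || snp_offset + L > n,
          "context too short: every ", L,
          "-bp window overlapping the SNP must fit")
  stop_if(substr(context, snp_offset + 1L, snp_offset + 1L) != toupper(ref_base),
          "context base at snp_offset does not equal ref_base")
  best_for <- function(base) {
    seq <- context
    substr(seq, snp_offset + 1L, snp_offset + 1L) <- toupper(base)
    offsets <- (snp_offset - L + 1L):snp_offset
    best <- -Inf; best_at <- NULL
    for (o in offsets) {
      w <- substr(seq, o + 1L, o + L)
      for (sd in c("+", "-")) {
        s <- score_window(if (sd == "+") w else revcomp(w), probs,
                          pwm$background)
        if (!is.na(s) && s > best) {
          best <- s
          best_at <- list(offset = o, strand = sd)
        }
      }
    }
    stop_if(is.null(best_at), "all windows overlapping the SNP contain N")
    list(score = best, window = best_at)
  }
  r <- best_for(ref_base)
  a <- best_for(alt_base)
  list(allele_ref = toupper(ref_base), allele_alt = toupper(alt_base),
       best_score_ref = r$score, best_score_alt = a$score,
       best_window_ref = r$window, best_window_alt = a$window,
       delta = a$score - r$score)
}

#' ChIP-qPCR fold enrichment between two conditions
#'
#' Percent-input arithmetic: for each condition,
#' `percent_input = 100 * 2^((ct_input - log2(input_dilution_factor)) - ct_ip)`,
#' and the fold enrichment is the target condition's percent input over
#' the control's.
#'
#' @param ct_ip_target,ct_input_target IP and input Ct for the target
#'   condition (e.g. risk allele).
#' @param ct_ip_ctrl,ct_input_ctrl IP and input Ct for the control
#'   condition (e.g. non-risk allele).
#' @param input_dilution_factor fold dilution of the input aliquot
#'   relative to the IP (> 0).
#' @return fold enrichment (target / control).
#' @export
chip_fold_enrichment <- function(ct_ip_target, ct_input_target,
                                 ct_ip_ctrl, ct_input_ctrl,
                                 input_dilution_factor = 100) {
  stop_if(input_dilution_factor <= 0, "input dilution factor must be > 0")
  stop_if(any(c(ct_ip_target, ct_input_target, ct_ip_ctrl,
                ct_input_ctrl) <= 0), "Ct values must be > 0")
  pct <- function(ct_input, ct_ip)
    100 * 2^((ct_input - log2(input_dilution_factor)) - ct_ip)
  pct(ct_input_target, ct_ip_target) / pct(ct_input_ctrl, ct_ip_ctrl)
}

#' Does a SNP fall inside any of a set of intervals?
#'
#' Half-open overlap test (`start <= pos < end`), e.g. a SNP against
#' H3K27ac peak intervals.
#'
#' @param chrom,pos SNP chromosome and 0-based position.
#' @param intervals data.frame with `chrom`, `start`, `end` and
#'   optionally `name` (BED-like, 0-based half-open).
#' @return list with `overlaps` (logical) and `interval_ids` (names, or
#'   row indices if unnamed, of the containing intervals).
#' @export
snp_in_intervals <- function(chrom, pos, intervals) {
  hit <- intervals$chrom == chrom &
    intervals$start <= pos & pos < intervals$end
  ids <- if ("name" %in% names(intervals)) intervals$name[hit] else which(hit)
  list(overlaps = any(hit), interval_ids = ids)
}
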