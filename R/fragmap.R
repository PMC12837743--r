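#' Build a validated reference set
#'
#' A reference set is the in-memory genome the whole pipeline works
#' against: a named [Biostrings::DNAStringSet] with unique chromosome
#' names, non-empty uppercase sequences and an A/C/G/T/N alphabet.
#'
#' @param seqs named character vector of DNA sequences, or a
#'   [Biostrings::DNAStringSet]. Lowercase input is uppercased.
#' @return a `DNAStringSet` with one entry per chromosome.
#' @examples
#' refs <- reference_set(c(chr1 = "aagatctt", chr2 = "GTACGTAC"))
#' names(refs)
#' @export
reference_set <- function(seqs) {
  if (is.character(seqs)) {
    stop_if(is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""),
            "all sequences must be named")
    seqs <- Biostrings::DNAStringSet(toupper(seqs))
  } else if (methods::is(seqs, "DNAStringSet")) {
    seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  } else {
    stop("seqs must be a named character vector or a DNAStringSet",
         call. = FALSE)
  }
  stop_if(length(seqs) == 0L, "reference set is empty")
  stop_if(anyDuplicated(names(seqs)) > 0L, "chromosome names must be unique")
  stop_if(any(Biostrings::width(seqs) == 0L), "empty reference sequence")
  check_dna(as.character(seqs), "reference sequence")
  seqs
}

#' Read a reference set from FASTA
#'
#' @param path path to a (multi-record) FASTA file; case-insensitive.
#' @return a `DNAStringSet` (see [reference_set()]).
#' @export
read_fasta_refs <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  # keep only the first whitespace-delimited token of each FASTA header
  names(x) <- sub("\\s.*$", "", names(x))
  reference_set(x)
}

#' Restriction enzyme specification
#'
#' Describes a restriction enzyme by its recognition motif and the cut
#' offset (bp from the motif start at which the enzyme cleaves).  The two
#' enzymes used by the double-digest 4C protocol ship as built-ins with
#' their true chemistry: DpnII cuts ^GATC (offset 0) and CviQI cuts G^TAC
#' (offset 1).
#'
#' @param name enzyme name.
#' @param motif recognition motif, A/C/G/T only, length >= 4.
#' @param cut_offset integer offset of the cut from the motif start,
#'   `0 <= cut_offset <= nchar(motif)`.
#' @return an object of class `enzyme_spec`.
#' @examples
#' enzyme("DpnII")
#' enzyme_spec("MboI", "GATC", 0)
#' @export
enzyme_spec <- function(name, motif, cut_offset) {
  motif <- toupper(motif)
  stop_if(nchar(motif) < 4L, "recognition motif must be >= 4 bp")
  check_dna(motif, "recognition motif", allow_n = FALSE)
  cut_offset <- as.integer(cut_offset)
  stop_if(cut_offset < 0L || cut_offset > nchar(motif),
          "cut_offset must lie within [0, motif length]")
  structure(list(name = name, motif = motif, cut_offset = cut_offset),
            class = "enzyme_spec")
}

#' @export
print.enzyme_spec <- function(x, ...) {
  cut <- paste0(substr(x$motif, 1, x$cut_offset), "^",
                substr(x$motif, x$cut_offset + 1, nchar(x$motif)))
  cat(sprintf("<enzyme_spec> %s  %s\n", x$name, cut))
  invisible(x)
}

.builtin_enzymes <- list(
  DpnII = list(motif = "GATC", cut_offset = 0L),
  CviQI = list(motif = "GTAC", cut_offset = 1L)
)

#' @rdname enzyme_spec
#' @export
enzyme <- function(name) {
  e <- .builtin_enzymes[[name]]
  stop_if(is.null(e), "unknown built-in enzyme: ", name,
          " (known: ", paste(names(.builtin_enzymes), collapse = ", "), ")")
  enzyme_spec(name, e$motif, e$cut_offset)
}

# 0-based cut positions of `enzyme` in one sequence (character scalar).
# Overlapping motif occurrences each produce a cut; N never matches.
cut_positions <- function(seq, enzyme) {
  m <- Biostrings::matchPattern(enzyme$motif, Biostrings::DNAString(seq))
  sort(unique(BiocGenerics::start(m) - 1L + enzyme$cut_offset))
}

#' Digest a reference set into a restriction-fragment map
#'
#' Cuts every chromosome at each exact occurrence of the enzyme's
#' recognition motif (offset by the enzyme's cut position; overlapping
#' occurrences all cut; N never matches) and returns the ordered
#' fragments tiling each chromosome.  Coordinates are 0-based, half-open
#' (BED convention); zero-length fragments (a cut at position 0 or at the
#' chromosome end) are dropped.
#'
#' @param refs a reference set (see [reference_set()]).
#' @param enzyme an [enzyme_spec()].
#' @return a `fragment_map`: a data.frame with columns `chrom`, `start`,
#'   `end`, `fragment_id` (integer ids assigned in genome order), with the
#'   chromosome lengths in `attr(, "seqlengths")`.
#' @examples
#' refs <- reference_set(c(c1 = "AAGATCTT"))
#' digest_genome(refs, enzyme("DpnII"))
#' @export
digest_genome <- function(refs, enzyme) {
  refs <- reference_set(refs)
  stopifnot(inherits(enzyme, "enzyme_spec"))
  lens <- stats::setNames(Biostrings::width(refs), names(refs))
  pieces <- lapply(names(refs), function(chrom) {
    L <- lens[[chrom]]
    cuts <- cut_positions(as.character(refs[[chrom]]), enzyme)
    bounds <- unique(c(0L, cuts[cuts > 0L & cuts < L], L))
    data.frame(chrom = chrom,
               start = bounds[-length(bounds)],
               end = bounds[-1L],
               stringsAsFactors = FALSE)
  })
  fm <- do.call(rbind, pieces)
  fm$fragment_id <- seq_len(nrow(fm))
  new_fragment_map(fm, lens)
}

new_fragment_map <- function(df, seqlengths) {
  rownames(df) <- NULL
  structure(df[, c("chrom", "start", "end", "fragment_id")],
            seqlengths = seqlengths,
            class = c("fragment_map", "data.frame"))
}

validate_fragment_map <- function(fm) {
  stop_if(any(fm$start >= fm$end), "fragment with start >= end")
  lens <- attr(fm, "seqlengths")
  for (chrom in unique(fm$chrom)) {
    sub <- fm[fm$chrom == chrom, ]
    stop_if(sub$start[1] != 0L, "fragments on ", chrom, " do not start at 0")
    stop_if(any(sub$start[-1] != sub$end[-nrow(sub)]),
            "fragments on ", chrom, " do not abut")
    if (!is.null(lens))
      stop_if(sub$end[nrow(sub)] != lens[[chrom]],
              "fragments on ", chrom, " do not reach the chromosome end")
  }
  invisible(fm)
}

#' Locate the restriction fragment containing a position
#'
#' @param fragmap a `fragment_map` from [digest_genome()].
#' @param chrom chromosome name.
#' @param position 0-based position; must satisfy
#'   `0 <= position < chromosome length`.
#' @return the `fragment_id` of the unique fragment with
#'   `start <= position < end`.
#' @export
locate_bait <- function(fragmap, chrom, position) {
  sub <- fragmap[fragmap$chrom == chrom, ]
  stop_if(nrow(sub) == 0L, "chromosome not in fragment map: ", chrom)
  stop_if(position < 0 || position >= sub$end[nrow(sub)],
          "position ", position, " outside [0, ", sub$end[nrow(sub)],
          ") on ", chrom)
  i <- findInterval(position, sub$start)
  sub$fragment_id[i]
}

#' Bait (viewpoint) specification
#'
#' Fixes the 4C viewpoint: the SNP position, the reading primer whose
#' presence at a read's start identifies captures, and the resolved bait
#' fragment plus an exclusion radius (in fragments) around it that is
#' never reported as an interaction (self-ligation / undigested signal).
#'
#' @param chrom,position chromosome and 0-based bp of the SNP/viewpoint.
#' @param reading_primer bait-anchored primer sequence, length >= 10.
#' @param fragmap fragment map used to resolve the bait fragment.
#' @param exclusion_radius_fragments fragments on each side of the bait
#'   fragment excluded from interaction calling (default 2).
#' @return an object of class `bait_spec`.
#' @export
bait_spec <- function(chrom, position, reading_primer, fragmap,
                      exclusion_radius_fragments = 2L) {
  reading_primer <- toupper(reading_primer)
  stop_if(nchar(reading_primer) < 10L, "reading primer must be >= 10 bp")
  check_dna(reading_primer, "reading primer", allow_n = FALSE)
  id <- locate_bait(fragmap, chrom, position)
  structure(list(chrom = chrom, position = as.integer(position),
                 reading_primer = reading_primer,
                 bait_fragment_id = id,
                 exclusion_radius_fragments =
                   as.integer(exclusion_radius_fragments)),
            class = "bait_spec")
}

#' @export
print.bait_spec <- function(x, ...) {
  cat(sprintf("<bait_spec> %s:%d  fragment %d  primer %s  exclusion +/-%d\n",
              x$chrom, x$position, x$bait_fragment_id, x$reading_primer,
              x$exclusion_radius_fragments))
  invisible(x)
}

#' Write / read a fragment map as BED
#'
#' BED columns: chrom, start, end, fragment_id.  `read_fragment_map()`
#' re-sorts unsorted rows (with a warning), validates that fragments tile
#' each chromosome, and reports malformed lines by line number.
#'
#' @param fragmap a `fragment_map`.
#' @param path file path.
#' @return `read_fragment_map()` returns a `fragment_map`;
#'   `write_fragment_map()` returns `path` invisibly.
#' @export
write_fragment_map <- function(fragmap, path) {
  utils::write.table(as.data.frame(fragmap), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_fragment_map
#' @export
read_fragment_map <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  n <- lengths(fields)
  stop_if(any(n < 4L),
          "malformed BED line ", lineno[which(n < 4L)[1]],
          ": fewer than 4 fields")
  df <- data.frame(
    chrom = vapply(fields, `[`, "", 1L),
    start = suppressWarnings(as.integer(vapply(fields, `[`, "", 2L))),
    end = suppressWarnings(as.integer(vapply(fields, `[`, "", 3L))),
    fragment_id = suppressWarnings(as.integer(vapply(fields, `[`, "", 4L))),
    stringsAsFactors = FALSE)
  bad <- which(is.na(df$start) | is.na(df$end) | is.na(df$fragment_id))
  stop_if(length(bad) > 0L,
          "malformed BED line ", lineno[bad[1]], ": non-numeric field")
  bad <- which(df$start >= df$end)
  stop_if(length(bad) > 0L,
          "malformed BED line ", lineno[bad[1]], ": start >= end")
  ord <- order(match(df$chrom, unique(df$chrom)), df$start)
  if (is.unsorted(ord)) {
    warning("fragment map rows were unsorted; re-sorting", call. = FALSE)
    df <- df[ord, ]
  }
  lens <- vapply(split(df$end, df$chrom), max, 0L)[unique(df$chrom)]
  validate_fragment_map(new_fragment_map(df, lens))
}

# fragment map as GRanges (internal; used for overlap queries)
fragmap_granges <- function(fragmap) {
  GenomicRanges::GRanges(
    seqnames = fragmap$chrom,
    ranges = IRanges::IRanges(start = fragmap$start + 1L, end = fragmap$end),
    fragment_id = fragmap$fragment_id)
}
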