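#' Read / write a differential-expression table
#'
#' TSV with header columns `gene_id`, `chrom`, `start`, `end`, `strand`,
#' `log2fc`, `pvalue`, `padj`.  Coordinates are 0-based half-open, like
#' everything else in the package.
#'
#' @param path file path.
#' @param de a DE data.frame.
#' @return `read_de_table()` returns the validated data.frame.
#' @export
read_de_table <- function(path) {
  de <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "strand",
            "log2fc", "pvalue", "padj")
  stop_if(!all(need %in% names(de)),
          "DE table missing columns: ",
          paste(setdiff(need, names(de)), collapse = ", "))
  validate_de(de)
  de
}

#' @rdname read_de_table
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_de <- function(de) {
  stop_if(any(de$start >= de$end), "DE record with start >= end")
  stop_if(any(de$pvalue < 0 | de$pvalue > 1), "pvalue outside [0, 1]")
  stop_if(any(de$padj < 0 | de$padj > 1), "padj outside [0, 1]")
  invisible(de)
}

#' Threshold a DE table into a gene set
#'
#' Returns the genes passing a direction-specific fold-change cut and an
#' adjusted-p cut, both strict: down-regulated means
#' `log2fc < -fc_cut & padj < padj_cut`, up-regulated
#' `log2fc > fc_cut & padj < padj_cut`.
#'
#' @param de DE data.frame (see [read_de_table()]).
#' @param direction `"down"` or `"up"`.
#' @param fc_cut fold-change magnitude on the log2 scale (default 1.3).
#' @param padj_cut adjusted-p threshold (default 0.05).
#' @return character vector of `gene_id`s.
#' @export
filter_de <- function(de, direction = c("down", "up"),
                      fc_cut = 1.3, padj_cut = 0.05) {
  direction <- match.arg(direction)
  stop_if(fc_cut < 0, "fc_cut is a magnitude and must be >= 0")
  validate_de(de)
  pass <- de$padj < padj_cut &
    if (direction == "down") de$log2fc < -fc_cut else de$log2fc > fc_cut
  de$gene_id[pass]
}

#' Assign interaction calls to genes by windowed overlap
#'
#' A call supports a gene iff the call interval overlaps
#' `[gene$start - window, gene$end + window)` on the gene's chromosome.
#'
#' @param calls call table from [call_interactions()].
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`.
#' @param window bp added on each side of the gene body (default 50000).
#' @return named list mapping `gene_id` to the integer row indices of its
#'   supporting calls (genes without support are absent).
#' @export
assign_calls_to_genes <- function(calls, genes, window = 50000L) {
  stop_if(window < 0L, "window must be >= 0")
  if (nrow(calls) == 0L || nrow(genes) == 0L)
    return(stats::setNames(list(), character(0)))
  gr_genes <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(start = pmax(genes$start - window, 0L) + 1L,
                     end = genes$end + window))
  gr_calls <- GenomicRanges::GRanges(
    calls$chrom, IRanges::IRanges(start = calls$start + 1L, end = calls$end))
  # disjoint chromosome sets are a legitimate "no support" answer, not
  # a user error worth a GenomicRanges warning
  ov <- suppressWarnings(GenomicRanges::findOverlaps(gr_genes, gr_calls))
  sp <- split(S4Vectors::subjectHits(ov),
              genes$gene_id[S4Vectors::queryHits(ov)])
  lapply(sp, unname)
}

#' Nominate enhancer target genes by the two-step filter
#'
#' A gene is nominated iff (1) it is significantly down-regulated on
#' enhancer loss (`log2fc < -fc_cut`, `padj < padj_cut`, strict) and
#' (2) at least one interaction call within `window` bp of the gene body
#' has minimum-across-replicates RPM above `rpm_cut` (strict).  Trans
#' contacts nominate exactly like cis contacts.
#'
#' @param de DE data.frame.
#' @param calls call table from [call_interactions()] (per-replicate
#'   `rpm_rep*` columns required).
#' @param fc_cut,padj_cut DE thresholds (defaults 1.3, 0.05).
#' @param rpm_cut per-call minimum-replicate RPM threshold (default 50).
#' @param window gene-assignment window in bp (default 50000).
#' @return data.frame of candidates sorted by `best_min_rpm` descending
#'   (ties by `gene_id`): `gene_id`, `n_supporting`,
#'   `supporting_fragment_ids` (comma-joined), `best_min_rpm`,
#'   `distance_class` (cis/trans of the best call), `distance_to_bait`.
#' @export
nominate_targets <- function(de, calls, fc_cut = 1.3, padj_cut = 0.05,
                             rpm_cut = 50, window = 50000L) {
  down <- filter_de(de, "down", fc_cut, padj_cut)
  rpmcols <- grep("^rpm_rep", names(calls), value = TRUE)
  stop_if(length(rpmcols) == 0L, "calls carry no per-replicate rpm columns")
  minrpm <- if (nrow(calls)) do.call(pmin, calls[rpmcols]) else numeric(0)
  strong <- calls[minrpm > rpm_cut, , drop = FALSE]
  strong_min <- minrpm[minrpm > rpm_cut]
  genes <- de[de$gene_id %in% down, , drop = FALSE]
  support <- assign_calls_to_genes(strong, genes, window)
  if (length(support) == 0L)
    return(data.frame(gene_id = character(0), n_supporting = integer(0),
                      supporting_fragment_ids = character(0),
                      best_min_rpm = numeric(0),
                      distance_class = character(0),
                      distance_to_bait = numeric(0)))
  rows <- lapply(names(support), function(g) {
    idx <- support[[g]]
    best <- idx[which.max(strong_min[idx])]
    data.frame(
      gene_id = g, n_supporting = length(idx),
      supporting_fragment_ids = paste(strong$fragment_id[idx],
                                      collapse = ","),
      best_min_rpm = max(strong_min[idx]),
      distance_class = if (isTRUE(strong$is_cis[best])) "cis" else "trans",
      distance_to_bait = strong$distance_to_bait[best],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$best_min_rpm, out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Overlap two thresholded DE gene sets
#'
#' Each set is defined by [filter_de()] semantics over its own DE table
#' (a padj-only set is expressed with `fc_cut = 0`).  Tables with
#' different gene universes intersect over shared ids, with a warning.
#'
#' @param de_a,de_b DE data.frames.
#' @param spec_a,spec_b lists with elements `direction`, `fc_cut`,
#'   `padj_cut`.
#' @return list with `n_a`, `n_b`, `n_overlap`, `members` (sorted
#'   character vector of shared gene ids).
#' @export
overlap_gene_sets <- function(de_a, spec_a, de_b, spec_b) {
  if (!setequal(de_a$gene_id, de_b$gene_id))
    warning("gene universes differ; intersecting over shared ids",
            call. = FALSE)
  a <- filter_de(de_a, spec_a$direction, spec_a$fc_cut, spec_a$padj_cut)
  b <- filter_de(de_b, spec_b$direction, spec_b$fc_cut, spec_b$padj_cut)
  members <- sort(intersect(a, b))
  list(n_a = length(a), n_b = length(b), n_overlap = length(members),
       members = members)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (delegates to
#' [stats::p.adjust()] with `method = "BH"`), with input validation.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of adjusted p-values, same order as the input.
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03))
#' @export
benjamini_hochberg <- function(pvalues) {
  stop_if(length(pvalues) == 0L, "empty p-value vector")
  stop_if(anyNA(pvalues) || any(pvalues < 0 | pvalues > 1),
          "p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}
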