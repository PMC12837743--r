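#' Fit a qPCR standard curve and derive amplification efficiency
#'
#' Ordinary least squares of Ct on log10(template dilution) over a
#' genomic-DNA dilution series.  The amplification efficiency is derived
#' from the slope as `E = 10^(-1/slope) - 1` (E = 1 means perfect
#' per-cycle doubling).  A primer pair passes QC iff its efficiency lies
#' in `[qc_lo, qc_hi]` (inclusive; defaults 90-110%).
#'
#' @param dilutions positive template amounts (at least 3 distinct).
#' @param cts observed Ct values, same length as `dilutions`.
#' @param qc_lo,qc_hi inclusive efficiency QC bounds (defaults 0.90,
#'   1.10, as fractions).
#' @param primer_pair_id optional label stored on the result.
#' @return an object of class `standard_curve`: list with `slope`,
#'   `intercept`, `r_squared`, `efficiency`, `pass`, `primer_pair_id`.
#' @examples
#' fit_standard_curve(c(1, 0.1, 0.01), 10 - log2(c(1, 0.1, 0.01)))
#' @export
fit_standard_curve <- function(dilutions, cts, qc_lo = 0.90, qc_hi = 1.10,
                               primer_pair_id = NA_character_) {
  stop_if(length(dilutions) != length(cts),
          "dilutions and cts differ in length")
  stop_if(any(dilutions <= 0), "dilutions must be positive")
  stop_if(length(unique(dilutions)) < 3L,
          "need at least 3 distinct dilutions")
  x <- log10(dilutions)
  fit <- stats::lm(cts ~ x)
  slope <- unname(stats::coef(fit)[2])
  stop_if(!is.finite(slope) || slope >= 0,
          "non-amplifying curve (slope >= 0)")
  efficiency <- 10^(-1 / slope) - 1
  # R^2 computed directly (summary.lm warns on exactly collinear input)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((cts - mean(cts))^2)
  structure(list(primer_pair_id = primer_pair_id,
                 slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 efficiency = efficiency,
                 pass = efficiency >= qc_lo && efficiency <= qc_hi),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> %s  slope %.4f  E %.1f%%  R2 %.4f  QC %s\n",
    x$primer_pair_id %||% "?", x$slope, 100 * x$efficiency, x$r_squared,
    if (x$pass) "pass" else "FAIL"))
  invisible(x)
}

#' Efficiency-corrected relative quantity
#'
#' `RQ = (1 + E)^(-Ct)`: the template abundance implied by a Ct value
#' under the primer pair's measured amplification efficiency.
#'
#' @param ct Ct value(s), cycles.
#' @param efficiency amplification efficiency E as a fraction (> 0).
#' @return numeric relative quantities.
#' @examples
#' relative_quantity(10, 1)   # 2^-10
#' @export
relative_quantity <- function(ct, efficiency) {
  stop_if(any(efficiency <= 0), "efficiency must be > 0")
  (1 + efficiency)^(-ct)
}

#' Normalize relative quantities to the anchor self-ligation product
#'
#' @param rq named numeric vector of per-region RQ values.
#' @param anchor_region_id name of the anchor region within `rq`.
#' @return named numeric vector of interaction frequencies (the anchor
#'   maps to 1).
#' @export
normalize_to_anchor <- function(rq, anchor_region_id) {
  stop_if(!anchor_region_id %in% names(rq),
          "anchor region missing: ", anchor_region_id)
  a <- rq[[anchor_region_id]]
  stop_if(a == 0, "anchor RQ is zero")
  rq / a
}

#' Summarize interaction frequencies across biological replicates
#'
#' @param values data.frame with columns `region_id`, `value` (one row
#'   per region x biological replicate), or a named list of numeric
#'   vectors.
#' @return data.frame `region_id`, `mean`, `sem` (sd with n-1
#'   denominator over sqrt(n); NA when n = 1), `n`.
#' @export
summarize_replicates <- function(values) {
  if (is.list(values) && !is.data.frame(values))
    values <- data.frame(
      region_id = rep(names(values), lengths(values)),
      value = unlist(values, use.names = FALSE))
  sp <- split(values$value, values$region_id)
  out <- data.frame(
    region_id = names(sp),
    mean = vapply(sp, mean, 0),
    sem = vapply(sp, function(v)
      if (length(v) < 2L) NA_real_ else stats::sd(v) / sqrt(length(v)), 0),
    n = lengths(sp),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Promoter versus flank interaction-frequency ratios
#'
#' Ratios of the promoter's mean interaction frequency to each adjacent
#' flank, with first-order (delta-method) SEM propagation:
#' `sem(p/f) = (p/f) * sqrt((sem_p/p)^2 + (sem_f/f)^2)`.
#'
#' @param freqs data.frame from [summarize_replicates()].
#' @param promoter,upstream,downstream region ids within `freqs`.
#' @return data.frame with one row per comparison: `comparison`,
#'   `ratio`, `sem`.
#' @export
compare_promoter_flank <- function(freqs, promoter, upstream, downstream) {
  get <- function(id) {
    row <- freqs[freqs$region_id == id, ]
    stop_if(nrow(row) != 1L, "region missing or duplicated: ", id)
    row
  }
  p <- get(promoter)
  ratio_to <- function(flank) {
    f <- get(flank)
    stop_if(f$mean == 0, "zero flank mean: ", flank)
    r <- p$mean / f$mean
    data.frame(
      comparison = paste0(promoter, "/", flank),
      ratio = r,
      sem = r * sqrt((p$sem / p$mean)^2 + (f$sem / f$mean)^2),
      stringsAsFactors = FALSE)
  }
  out <- rbind(ratio_to(upstream), ratio_to(downstream))
  rownames(out) <- NULL
  out
}

#' Read a Ct table
#'
#' TSV with header `primer_pair_id`, `sample_id`, `replicate`,
#' `dilution` (NA for sample rows, numeric for standard-curve rows),
#' `ct`.
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
read_ct_table <- function(path) {
  ct <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("primer_pair_id", "sample_id", "replicate", "dilution", "ct")
  stop_if(!all(need %in% names(ct)),
          "Ct table missing columns: ",
          paste(setdiff(need, names(ct)), collapse = ", "))
  stop_if(any(ct$ct <= 0), "Ct values must be > 0")
  ct
}

#' Fit standard curves for every primer pair in a Ct table
#'
#' Uses the dilution-series rows (`dilution` non-NA) of each primer pair.
#'
#' @param ct_table data.frame from [read_ct_table()].
#' @inheritParams fit_standard_curve
#' @return named list of `standard_curve` objects.
#' @export
fit_curves_from_table <- function(ct_table, qc_lo = 0.90, qc_hi = 1.10) {
  std <- ct_table[!is.na(ct_table$dilution), ]
  sp <- split(std, std$primer_pair_id)
  lapply(sp, function(d)
    fit_standard_curve(d$dilution, d$ct, qc_lo, qc_hi,
                       primer_pair_id = d$primer_pair_id[1]))
}

#' Quantify 3C interaction frequencies from a Ct table
#'
#' For each biological replicate: technical-replicate Ct values are
#' arithmetically averaged per region, converted to RQ with each
#' region's primer efficiency, and normalized to the anchor region
#' within that replicate; normalized frequencies are then summarized
#' across replicates.  Primer pairs failing efficiency QC are dropped
#' (with a warning).
#'
#' @param ct_table data.frame from [read_ct_table()] (sample rows have
#'   `dilution = NA`; `sample_id` is the region, `replicate` the
#'   biological replicate; repeated rows per (region, replicate) are
#'   technical replicates).
#' @param curves named list of `standard_curve`s, one per
#'   `primer_pair_id` (see [fit_curves_from_table()]).
#' @param anchor_region_id the anchor (self-ligation) region id.
#' @param region_primer named character: region id -> primer_pair_id.
#' @return list with `frequencies` (per region x replicate normalized
#'   values) and `summary` (from [summarize_replicates()]).
#' @export
quantify_3c <- function(ct_table, curves, anchor_region_id, region_primer) {
  smp <- ct_table[is.na(ct_table$dilution), ]
  stop_if(nrow(smp) == 0L, "no sample rows in Ct table")
  failed <- names(curves)[!vapply(curves, `[[`, TRUE, "pass")]
  if (length(failed) > 0L) {
    warning("dropping primer pairs failing efficiency QC: ",
            paste(failed, collapse = ", "), call. = FALSE)
    drop_regions <- names(region_primer)[region_primer %in% failed]
    stop_if(anchor_region_id %in% drop_regions,
            "anchor primer pair failed efficiency QC")
    smp <- smp[!smp$sample_id %in% drop_regions, ]
  }
  eff <- vapply(curves, `[[`, 0, "efficiency")
  rows <- list()
  for (rep_id in sort(unique(smp$replicate))) {
    d <- smp[smp$replicate == rep_id, ]
    ct_mean <- tapply(d$ct, d$sample_id, mean)      # technical reps -> mean Ct
    regions <- names(ct_mean)
    primer <- region_primer[regions]
    stop_if(anyNA(primer), "region without a primer pair mapping")
    rq <- stats::setNames(
      relative_quantity(as.numeric(ct_mean), eff[primer]), regions)
    norm <- normalize_to_anchor(rq, anchor_region_id)
    rows[[length(rows) + 1L]] <- data.frame(
      region_id = regions, replicate = rep_id, value = as.numeric(norm),
      stringsAsFactors = FALSE)
  }
  freqs <- do.call(rbind, rows)
  rownames(freqs) <- NULL
  list(frequencies = freqs,
       summary = summarize_replicates(freqs[, c("region_id", "value")]))
}
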