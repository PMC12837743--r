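# Seeded simulators producing every input the pipeline consumes, with a
# ground-truth manifest for recovery tests.  All generators are pure
# functions of (parameters, seed): no hidden global state survives.

# deterministic small integer offset from a replicate label, so one
# scenario seed yields distinct but reproducible per-replicate streams
replicate_seed <- function(seed, replicate_id) {
  (as.integer(seed) + sum(utf8ToInt(as.character(replicate_id)))) %% 2147483647L
}

#' Simulate a multi-chromosome toy genome
#'
#' Uniform random A/C/G/T sequence in which chance occurrences of the
#' first cutter's GATC motif are mutated away and a GATC site is
#' injected every `motif_spacing` bp, so the first-cutter fragment map
#' is dense and of predictable size (about `length / motif_spacing`
#' fragments per chromosome).  Second-cutter GTAC sites are left where
#' they fall, so read-level digestion stays non-trivial.
#'
#' @param seed integer RNG seed.
#' @param chrom_lengths named integer vector of chromosome lengths
#'   (>= 10 kb each).
#' @param motif_spacing injected GATC spacing in bp (default 400).
#' @param fasta_path optional path; when given the genome is also
#'   written as FASTA.
#' @return a reference set (`DNAStringSet`).
#' @export
make_genome <- function(seed, chrom_lengths = c(chr1 = 1000000L,
                                                chr2 = 500000L),
                        motif_spacing = 400L, fasta_path = NULL) {
  stop_if(any(chrom_lengths < 10000L), "chromosome lengths must be >= 10 kb")
  set.seed(as.integer(seed))
  seqs <- vapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    b <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    # mutate away chance GATC occurrences (A -> C; loop in case a
    # replacement spawns a new overlapping site)
    repeat {
      s <- paste(b, collapse = "")
      hits <- gregexpr("(?=GATC)", s, perl = TRUE)[[1]]
      if (hits[1] == -1L) break
      b[as.integer(hits) + 1L] <- "C"
    }
    inj <- seq(motif_spacing, L - 4L, by = motif_spacing)
    b[inj + 1L] <- "G"; b[inj + 2L] <- "A"
    b[inj + 3L] <- "T"; b[inj + 4L] <- "C"
    paste(b, collapse = "")
  }, "")
  refs <- reference_set(seqs)
  if (!is.null(fasta_path))
    Biostrings::writeXStringSet(refs, fasta_path)
  refs
}

#' Bait contact profile over a fragment map
#'
#' Sampling distribution for the partner fragment of each simulated 4C
#' ligation: planted peak fragments get absolute weights, cis background
#' decays with genomic distance as `(1 + |d|/d0)^(-alpha)`, and trans
#' fragments share a flat floor `trans_eps`.  The bait fragment gets
#' probability zero; weights are normalized over all other fragments.
#'
#' @param fragmap a `fragment_map`.
#' @param bait a [bait_spec()].
#' @param peaks data.frame with `fragment_id`, `weight` (absolute
#'   sampling weights on the background scale).
#' @param alpha cis decay exponent (default 3).
#' @param d0 cis decay scale in bp (default 2000).
#' @param trans_eps per-fragment trans background weight (default 2e-5).
#' @return object of class `contact_profile` with the per-fragment
#'   probability vector in `$prob` (aligned to `fragmap$fragment_id`).
#' @export
contact_profile <- function(fragmap, bait, peaks = NULL,
                            alpha = 3, d0 = 2000, trans_eps = 2e-5) {
  stop_if(alpha <= 0, "alpha must be > 0")
  stop_if(trans_eps < 0, "trans_eps must be >= 0")
  mid <- (fragmap$start + fragmap$end) / 2
  w <- ifelse(fragmap$chrom == bait$chrom,
              (1 + abs(mid - bait$position) / d0)^(-alpha),
              trans_eps)
  if (!is.null(peaks) && nrow(peaks) > 0L) {
    stop_if(any(peaks$weight <= 0), "peak weights must be > 0")
    i <- match(peaks$fragment_id, fragmap$fragment_id)
    stop_if(anyNA(i), "peak references a fragment absent from the map")
    w[i] <- peaks$weight
  }
  w[fragmap$fragment_id == bait$bait_fragment_id] <- 0
  structure(list(bait_fragment_id = bait$bait_fragment_id,
                 peaks = peaks, alpha = alpha, d0 = d0,
                 trans_eps = trans_eps,
                 fragment_id = fragmap$fragment_id,
                 prob = w / sum(w)),
            class = "contact_profile")
}

#' Simulate one replicate's paired-end 4C library
#'
#' Each read pair is drawn i.i.d.: the partner fragment is sampled from
#' the contact profile; the primer-bearing mate is the reading primer
#' followed by bait-side sequence up to the first-cutter site; the other
#' mate is a prefix of the partner fragment.  Which physical mate
#' carries the primer is randomized per pair.  Reads are error-free with
#' constant base qualities.
#'
#' @param refs reference set.
#' @param fragmap first-cutter `fragment_map`.
#' @param bait a [bait_spec()].
#' @param profile a [contact_profile()].
#' @param n_pairs number of read pairs (>= 1).
#' @param seed,replicate_id the RNG stream is a pure function of both.
#' @param fastq1,fastq2 output FASTQ paths.
#' @param read_len sequencer read length (default 150).
#' @return invisibly, a data.frame of the true partner `fragment_id` per
#'   pair (`pair_id`, `fragment_id`).
#' @export
simulate_4c_library <- function(refs, fragmap, bait, profile, n_pairs,
                                seed, replicate_id, fastq1, fastq2,
                                read_len = 150L) {
  stop_if(n_pairs < 1L, "n_pairs must be >= 1")
  set.seed(replicate_seed(seed, replicate_id))
  refs <- reference_set(refs)
  baitrow <- fragmap[fragmap$fragment_id == bait$bait_fragment_id, ]
  primer <- bait$reading_primer
  bait_side_full <- substring(as.character(refs[[bait$chrom]]),
                              bait$position + nchar(primer) + 1L,
                              baitrow$end)
  read_primer_mate <- paste0(
    primer, substr(bait_side_full, 1L, read_len - nchar(primer)))

  partner <- sample(fragmap$fragment_id, n_pairs, replace = TRUE,
                    prob = profile$prob)
  i <- match(partner, fragmap$fragment_id)
  partner_mate <- character(n_pairs)
  for (ch in unique(fragmap$chrom[i])) {
    sel <- which(fragmap$chrom[i] == ch)
    st <- fragmap$start[i[sel]]
    en <- pmin(st + read_len, fragmap$end[i[sel]])
    partner_mate[sel] <- substring(as.character(refs[[ch]]), st + 1L, en)
  }
  swap <- sample(c(TRUE, FALSE), n_pairs, replace = TRUE)
  read1 <- ifelse(swap, partner_mate, read_primer_mate)
  read2 <- ifelse(swap, read_primer_mate, partner_mate)
  ids <- sprintf("%s_pair%07d", replicate_id, seq_len(n_pairs))
  write_fastq <- function(seqs, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    qual <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  }
  write_fastq(read1, fastq1)
  write_fastq(read2, fastq2)
  invisible(data.frame(pair_id = ids, fragment_id = partner,
                       stringsAsFactors = FALSE))
}

#' Simulate a differential-expression table with planted targets
#'
#' Null genes get `log2fc ~ Normal(0, null_sd)` and `p ~ Uniform(0, 1)`;
#' planted target genes get `log2fc ~ Normal(target_mean, target_sd)`
#' rejection-sampled below `-fc_guarantee` and `p ~ Uniform(0, 1e-5)`,
#' so they always pass the default down-regulation filter.  Target gene
#' bodies coincide with their planted peak fragments; null gene bodies
#' are placed to avoid them.  Adjusted p-values come from
#' [benjamini_hochberg()].
#'
#' @param fragmap the `fragment_map` the peaks live on.
#' @param target_fragments integer `fragment_id`s of the planted peaks;
#'   one target gene is planted on each.
#' @param n_genes total gene count (default 200).
#' @param seed RNG seed.
#' @param null_sd,target_mean,target_sd log2FC distribution parameters
#'   (defaults 0.2, -2.0, 0.3).
#' @param fc_guarantee targets are resampled until `log2fc < -fc_guarantee`
#'   (default 1.3).
#' @param gene_width width of null gene bodies in bp (default 2000).
#' @return list with `de` (DE data.frame) and `truth` (character vector
#'   of planted target gene ids).
#' @export
simulate_de_table <- function(fragmap, target_fragments = integer(0),
                              n_genes = 200L, seed = 1L,
                              null_sd = 0.2, target_mean = -2.0,
                              target_sd = 0.3, fc_guarantee = 1.3,
                              gene_width = 2000L) {
  n_targets <- length(target_fragments)
  stop_if(n_targets > n_genes, "more targets than genes")
  set.seed(as.integer(seed))
  lens <- attr(fragmap, "seqlengths")
  ti <- match(target_fragments, fragmap$fragment_id)
  stop_if(anyNA(ti), "target fragment absent from the map")
  rows <- list()
  if (n_targets > 0L) {
    l2fc <- stats::rnorm(n_targets, target_mean, target_sd)
    while (any(bad <- l2fc >= -fc_guarantee))     # rejection-sampling guarantee
      l2fc[bad] <- stats::rnorm(sum(bad), target_mean, target_sd)
    rows$targets <- data.frame(
      gene_id = sprintf("TARGET%02d", seq_len(n_targets)),
      chrom = fragmap$chrom[ti],
      start = fragmap$start[ti], end = fragmap$end[ti],
      strand = sample(c("+", "-"), n_targets, replace = TRUE),
      log2fc = l2fc,
      pvalue = stats::runif(n_targets, 0, 1e-5),
      stringsAsFactors = FALSE)
  }
  n_null <- n_genes - n_targets
  if (n_null > 0L) {
    chroms <- sample(names(lens), n_null, replace = TRUE,
                     prob = as.numeric(lens))
    start <- vapply(chroms, function(ch)
      sample.int(lens[[ch]] - gene_width, 1L) - 1L, 0L)
    # reject null genes falling on a planted peak fragment
    if (n_targets > 0L) {
      repeat {
        clash <- rep(FALSE, n_null)
        for (k in seq_len(n_targets)) {
          clash <- clash | (chroms == fragmap$chrom[ti[k]] &
                              start < fragmap$end[ti[k]] &
                              start + gene_width > fragmap$start[ti[k]])
        }
        if (!any(clash)) break
        chroms[clash] <- sample(names(lens), sum(clash), replace = TRUE,
                                prob = as.numeric(lens))
        start[clash] <- vapply(chroms[clash], function(ch)
          sample.int(lens[[ch]] - gene_width, 1L) - 1L, 0L)
      }
    }
    rows$null <- data.frame(
      gene_id = sprintf("GENE%04d", seq_len(n_null)),
      chrom = chroms, start = start, end = start + gene_width,
      strand = sample(c("+", "-"), n_null, replace = TRUE),
      log2fc = stats::rnorm(n_null, 0, null_sd),
      pvalue = stats::runif(n_null),
      stringsAsFactors = FALSE)
  }
  de <- do.call(rbind, rows)
  rownames(de) <- NULL
  de$padj <- benjamini_hochberg(de$pvalue)
  list(de = de,
       truth = if (n_targets > 0L) rows$targets$gene_id else character(0))
}

#' Simulate a 3C-qPCR Ct table from known primer efficiencies
#'
#' `Ct = intercept - log(template) / log(1 + E) + Normal(0, noise_sd^2)`,
#' for both the genomic-DNA dilution series of each primer pair (rows
#' with `dilution` set) and the 3C sample regions (rows with
#' `dilution = NA`).
#'
#' @param curves data.frame with `primer_pair_id`, `efficiency`,
#'   `intercept` (true values).
#' @param samples data.frame with `region_id`, `primer_pair_id`,
#'   `replicate`, `template` (relative template amount per biological
#'   replicate); technical replicates are generated per row.
#' @param dilutions dilution series (default `10^(0:-4)`).
#' @param n_dilution_reps technical replicates per dilution (default 3).
#' @param n_tech_reps technical replicates per sample row (default 3).
#' @param noise_sd Ct noise standard deviation in cycles (default 0.1).
#' @param seed RNG seed.
#' @return data.frame with columns `primer_pair_id`, `sample_id`,
#'   `replicate`, `dilution`, `ct` (see [read_ct_table()]).
#' @export
simulate_ct_table <- function(curves, samples = NULL,
                              dilutions = 10^(0:-4), n_dilution_reps = 3L,
                              n_tech_reps = 3L, noise_sd = 0.1, seed = 1L) {
  stop_if(any(curves$efficiency <= 0), "true efficiencies must be > 0")
  stop_if(any(dilutions <= 0), "dilutions must be > 0")
  set.seed(as.integer(seed))
  true_ct <- function(E, intercept, template)
    intercept - log(template) / log(1 + E)
  out <- list()
  for (k in seq_len(nrow(curves))) {
    cv <- curves[k, ]
    dil <- rep(dilutions, each = n_dilution_reps)
    out[[length(out) + 1L]] <- data.frame(
      primer_pair_id = cv$primer_pair_id, sample_id = "standard",
      replicate = rep(seq_len(n_dilution_reps), length(dilutions)),
      dilution = dil,
      ct = true_ct(cv$efficiency, cv$intercept, dil) +
        stats::rnorm(length(dil), 0, noise_sd),
      stringsAsFactors = FALSE)
  }
  if (!is.null(samples) && nrow(samples) > 0L) {
    ci <- match(samples$primer_pair_id, curves$primer_pair_id)
    stop_if(anyNA(ci), "sample references an unknown primer pair")
    stop_if(any(samples$template <= 0), "template amounts must be > 0")
    for (k in seq_len(nrow(samples))) {
      s <- samples[k, ]
      out[[length(out) + 1L]] <- data.frame(
        primer_pair_id = s$primer_pair_id, sample_id = s$region_id,
        replicate = s$replicate, dilution = NA_real_,
        ct = true_ct(curves$efficiency[ci[k]], curves$intercept[ci[k]],
                     s$template) + stats::rnorm(n_tech_reps, 0, noise_sd),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  tab
}

# synthetic SOX-family-like PFM whose consensus AACAAT is completed by
# the scenario's alt allele; written to disk as a JASPAR-format file
sox_like_pfm_counts <- function() {
  rbind(A = c(94,  95,  2, 90, 93,  1),
        C = c( 2,   1, 94,  4,  2,  2),
        G = c( 2,   2,  2,  3,  3,  2),
        T = c( 2,   2,  2,  3,  2, 95))
}

write_jaspar_pfm <- function(counts, path, id = "SYN0001",
                             name = "SOXlike_synthetic") {
  con <- file(path, "w")
  writeLines(sprintf(">%s %s", id, name), con)
  for (b in c("A", "C", "G", "T"))
    writeLines(sprintf("%s [ %s ]", b,
                       paste(counts[b, ], collapse = " ")), con)
  close(con)
  invisible(path)
}

#' Generate the default synthetic study scenario
#'
#' Writes every input the pipeline consumes into `dir`, with known
#' ground truth: a two-chromosome genome (1 Mb + 0.5 Mb, first-cutter
#' sites every ~400 bp), a bait near 300 kb on chr1 whose SNP sits
#' inside a synthetic SOX-like motif (reference allele breaks the
#' consensus, alternative allele completes it), three planted contact
#' peaks (cis at bait +50 kb and +400 kb, trans on chr2), two replicate
#' paired-end FASTQ libraries, a 200-gene DE table with one
#' down-regulated target per peak, and a 4-primer-pair Ct table (true
#' efficiencies 0.95, 1.00, 1.05 and 0.85 — the last must fail the
#' 90-110% QC) covering an anchor, a promoter and its flanks.
#'
#' @param dir output directory (created if needed).
#' @param seed scenario seed (default 42).
#' @param n_pairs read pairs per replicate (default 1e5).
#' @param peak_weight absolute contact-profile weight of each planted
#'   peak (default 0.01; roughly 175x the cis background at 50 kb).
#' @return list (also written to `manifest.yaml`): file paths, bait
#'   parameters and the ground truth (`peak_fragment_ids`,
#'   `target_genes`, `true_efficiencies`, `motif_delta_sign`).
#' @export
make_scenario <- function(dir, seed = 42L, n_pairs = 100000L,
                          peak_weight = 0.01) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(dir, f)
  chrom_lengths <- c(chr1 = 1000000L, chr2 = 500000L)
  refs <- make_genome(seed, chrom_lengths, motif_spacing = 400L)

  # resolve a bait fragment near 300 kb wide enough for primer + remainder
  fm0 <- digest_genome(refs, enzyme("DpnII"))
  id0 <- locate_bait(fm0, "chr1", 300000L)
  row <- which(fm0$fragment_id == id0)
  while (fm0$end[row] - fm0$start[row] < 120L) row <- row + 1L
  snp_pos <- fm0$start[row] + 30L

  # embed the motif context at the SNP: reference allele G breaks the
  # AACAAT consensus, alt allele A completes it; guard the following
  # base so no new GATC site is created
  g <- as.character(refs[["chr1"]])
  substr(g, snp_pos - 2L, snp_pos + 3L) <- "AACGAT"
  if (substr(g, snp_pos + 4L, snp_pos + 4L) == "C")
    substr(g, snp_pos + 4L, snp_pos + 4L) <- "A"
  refs <- reference_set(stats::setNames(
    c(g, as.character(refs[["chr2"]])), names(chrom_lengths)))
  Biostrings::writeXStringSet(refs, pth("genome.fasta"))

  fragmap <- digest_genome(refs, enzyme("DpnII"))
  write_fragment_map(fragmap, pth("fragments.bed"))
  primer <- substring(as.character(refs[["chr1"]]), snp_pos + 1L,
                      snp_pos + 20L)
  bait <- bait_spec("chr1", snp_pos, primer, fragmap)

  peak_ids <- c(locate_bait(fragmap, "chr1", snp_pos + 50000L),
                locate_bait(fragmap, "chr1", snp_pos + 400000L),
                locate_bait(fragmap, "chr2", 250000L))
  peaks <- data.frame(fragment_id = peak_ids, weight = peak_weight)
  profile <- contact_profile(fragmap, bait, peaks)
  for (r in c("rep1", "rep2"))
    simulate_4c_library(refs, fragmap, bait, profile, n_pairs, seed, r,
                        pth(sprintf("%s_R1.fastq", r)),
                        pth(sprintf("%s_R2.fastq", r)))

  sim_de <- simulate_de_table(fragmap, target_fragments = peak_ids,
                              n_genes = 200L, seed = seed)
  write_de_table(sim_de$de, pth("de_table.tsv"))

  # intercepts tied so one template scale underlies every primer pair
  # (all standard curves come from the same genomic-DNA library):
  # Ct(t=1) * log(1+E) is constant, hence RQ = const * template
  eff <- c(0.95, 1.00, 1.05, 0.85)
  curves <- data.frame(
    primer_pair_id = c("P1", "P2", "P3", "P4"),
    efficiency = eff,
    intercept = 20 * log(2) / log(1 + eff),
    stringsAsFactors = FALSE)
  regions <- data.frame(region_id = c("anchor", "promoter", "upstream",
                                      "downstream", "far_region"),
                        primer_pair_id = c("P1", "P2", "P3", "P2", "P4"),
                        template = c(0.02, 0.01, 0.005, 0.005, 0.002),
                        stringsAsFactors = FALSE)
  samples <- do.call(rbind, lapply(1:3, function(r)
    transform(regions, replicate = r)))
  ct_tab <- simulate_ct_table(curves, samples, seed = seed)
  utils::write.table(ct_tab, pth("ct_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  write_jaspar_pfm(sox_like_pfm_counts(), pth("sox_like_synthetic.pfm"))
  context <- substring(as.character(refs[["chr1"]]), snp_pos - 6L,
                       snp_pos + 9L)   # 16 bp, SNP at 0-based offset 7

  manifest <- list(
    name = "default", seed = as.integer(seed), n_pairs = as.integer(n_pairs),
    files = list(genome = pth("genome.fasta"),
                 fragment_map = pth("fragments.bed"),
                 fastq = list(rep1 = c(pth("rep1_R1.fastq"), pth("rep1_R2.fastq")),
                              rep2 = c(pth("rep2_R1.fastq"), pth("rep2_R2.fastq"))),
                 de_table = pth("de_table.tsv"),
                 ct_table = pth("ct_table.tsv"),
                 pfm = pth("sox_like_synthetic.pfm")),
    bait = list(chrom = "chr1", position = snp_pos, reading_primer = primer,
                bait_fragment_id = bait$bait_fragment_id),
    snp = list(context = context, offset = 7L, ref = "G", alt = "A"),
    region_primer = stats::setNames(regions$primer_pair_id,
                                    regions$region_id),
    truth = list(peak_fragment_ids = peak_ids,
                 target_genes = sim_de$truth,
                 true_efficiencies = stats::setNames(curves$efficiency,
                                                     curves$primer_pair_id),
                 qc_should_fail = "P4",
                 true_region_templates = stats::setNames(regions$template,
                                                         regions$region_id),
                 motif_delta_sign = 1L))
  yaml::write_yaml(manifest, pth("manifest.yaml"))
  invisible(manifest)
}
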