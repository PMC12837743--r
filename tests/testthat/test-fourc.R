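# small shared fixture: one chromosome, a bait fragment, a reading primer
make_tiny_bait <- function() {
  # c1: frag1 [0,12) then GATC fragments; primer = first 10 bases
  refs <- reference_set(c(
    c1 = "ACGTACGTGGTTGATCAAAACCCCGGGGTTTTGATCTTTTAAAACCCCGGGG",
    c2 = "TTTTCCCCAAAAGGGGTACTTTTCCCCAAAAGGGG"))
  fm <- digest_genome(refs, enzyme("DpnII"))
  bait <- bait_spec("c1", 2, "ACGTACGTGG", fm,
                    exclusion_radius_fragments = 0L)
  list(refs = refs, fm = fm, bait = bait)
}

test_that("demultiplexing keeps pairs with exactly one anchored primer match", {
  fx <- make_tiny_bait()
  bait <- fx$bait   # primer ACGTACGTGG
  pairs <- data.frame(
    pair_id = c("exact", "internal", "both", "neither", "mate2"),
    read1 = c("ACGTACGTGGTTTT", "GGACGTACGTGGTT", "ACGTACGTGGAAAA",
              "CCCCCCCCCCCCCC", "TTTTTTTTTTTTTT"),
    read2 = c("CCCCAAAATTTT", "CCCCAAAATTTT", "ACGTACGTGGTTTT",
              "GGGGGGGGGGGG", "ACGTACGTGGCCCC"))
  out <- demultiplex_and_trim(pairs, bait, max_mismatch = 0)
  kept <- out$captures
  expect_setequal(unique(kept$pair_id), c("exact", "mate2"))
  expect_identical(kept$sequence[kept$pair_id == "exact" &
                                   kept$side == "bait"], "TTTT")
  expect_identical(kept$sequence[kept$pair_id == "exact" &
                                   kept$side == "partner"], "CCCCAAAATTTT")
  expect_identical(kept$origin[kept$pair_id == "mate2"][1], "read2")
  expect_identical(kept$sequence[kept$pair_id == "mate2" &
                                   kept$side == "bait"], "CCCC")
  expect_identical(out$stats[["n_kept"]], 2L)
  expect_identical(out$stats[["n_no_primer"]], 2L)
  expect_identical(out$stats[["n_both_primer"]], 1L)
})

test_that("primer matching tolerates Hamming mismatches up to the budget", {
  fx <- make_tiny_bait()
  one_off <- data.frame(pair_id = "p", read1 = "ACGAACGTGGTTTT",
                        read2 = "CCCCAAAATTTT")
  expect_identical(demultiplex_and_trim(one_off, fx$bait, 0)$stats[["n_kept"]], 0L)
  out <- demultiplex_and_trim(one_off, fx$bait, 1)
  expect_identical(out$stats[["n_kept"]], 1L)
  expect_identical(out$captures$sequence[out$captures$side == "bait"], "TTTT")
  # oracle: count mismatches over the primer length by hand
  mm <- sum(strsplit("ACGAACGTGG", "")[[1]] !=
              strsplit(fx$bait$reading_primer, "")[[1]])
  expect_identical(mm, 1L)
})

test_that("in-silico read digestion matches brute-force cut enumeration", {
  expect_identical(digest_read("TTGATCAA", enzyme("DpnII"), 2)[[1]],
                   c("TT", "GATCAA"))
  expect_identical(digest_read("TTTT", enzyme("DpnII"), 2)[[1]], "TTTT")
  expect_identical(digest_read("TGATCA", enzyme("DpnII"), 3)[[1]], "GATCA")
  set.seed(5)
  enzymes <- list(enzyme("DpnII"), enzyme("CviQI"))
  for (i in 1:200) {
    s <- random_dna(sample(5:300, 1))
    got <- digest_read(s, enzymes, 1)[[1]]
    cuts <- sort(unique(c(oracle_cuts(s, "GATC", 0), oracle_cuts(s, "GTAC", 1))))
    bounds <- unique(c(0L, cuts[cuts > 0 & cuts < nchar(s)], nchar(s)))
    expect_identical(got, substring(s, bounds[-length(bounds)] + 1,
                                    bounds[-1]))
  }
})

test_that("placement requires exact genome-unique occurrence over both strands", {
  fx <- make_tiny_bait()
  seqs <- c(unique = "TTGATCAAAACCCCGGGGTT",        # c1 once, forward
            ambiguous = "TTTTCCCCAAAAGGGG",         # c2 twice
            minus = oracle_revcomp("TTTTGATCTTTTAAAACCCCG"),
            absent = paste(rep("ACGTT", 5), collapse = ""))
  out <- place_sequences(seqs, fx$refs, min_len = 10)
  pl <- out$placements
  expect_identical(nrow(pl), 2L)
  expect_identical(pl$chrom[pl$seq == 1], "c1")
  expect_identical(pl$strand[pl$seq == 1], "+")
  expect_identical(pl$start[pl$seq == 1],
                   as.integer(regexpr(seqs[["unique"]],
                     as.character(fx$refs[["c1"]]), fixed = TRUE)) - 1L)
  expect_identical(pl$strand[pl$seq == 3], "-")
  expect_identical(pl$start[pl$seq == 3],
                   as.integer(regexpr("TTTTGATCTTTTAAAACCCCG",
                     as.character(fx$refs[["c1"]]), fixed = TRUE)) - 1L)
  expect_identical(out$stats[["n_ambiguous"]], 1L)
  expect_identical(out$stats[["n_unplaced"]], 1L)
})

test_that("SAM ingestion keeps primary mapped records above the MAPQ floor", {
  fx <- make_tiny_bait()
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:c1\tLN:%d", nchar(as.character(fx$refs[["c1"]]))),
    sprintf("@SQ\tSN:c2\tLN:%d", nchar(as.character(fx$refs[["c2"]]))),
    "r1\t0\tc1\t13\t60\t8M\t*\t0\t0\tGATCAAAA\tIIIIIIII",
    "r2\t16\tc1\t5\t60\t6M\t*\t0\t0\tACGTGG\tIIIIII",
    "r3\t4\t*\t0\t0\t*\t*\t0\t0\tACGTACGT\tIIIIIIII",   # unmapped
    "r4\t0\tc2\t1\t0\t8M\t*\t0\t0\tTTTTCCCC\tIIIIIIII"  # MAPQ 0
  ), sam)
  pl <- load_placements_sam(sam, fx$refs, min_mapq = 1)
  expect_identical(nrow(pl), 2L)
  expect_identical(pl$start, c(12L, 4L))    # SAM 1-based -> 0-based
  expect_identical(pl$strand, c("+", "-"))
  expect_identical(pl$width, c(8L, 6L))
})

test_that("coverage assigns the 5'-most base, scales to RPM, and conserves mass", {
  fx <- make_tiny_bait()
  # counts f1:5, f2:15 -> rpm 250000 / 750000
  pl <- data.frame(chrom = "c1",
                   start = c(rep(0L, 5), rep(13L, 15)),
                   width = 4L, strand = "+")
  cov <- coverage_per_fragment(pl, fx$fm)
  expect_equal(cov$rpm, c(250000, 750000))
  expect_equal(sum(cov$rpm), 1e6)

  single <- coverage_per_fragment(
    data.frame(chrom = "c1", start = 0L, width = 4L, strand = "+"), fx$fm)
  expect_equal(single$rpm, 1e6)

  # boundary base b belongs to the fragment that starts at b
  b <- fx$fm$start[2]
  cb <- coverage_per_fragment(
    data.frame(chrom = "c1", start = b, width = 4L, strand = "+"), fx$fm)
  expect_identical(cb$fragment_id, fx$fm$fragment_id[2])
  # a minus-strand placement is assigned by its rightmost (5') base
  cm <- coverage_per_fragment(
    data.frame(chrom = "c1", start = b - 2L, width = 3L, strand = "-"), fx$fm)
  expect_identical(cm$fragment_id, fx$fm$fragment_id[2])

  expect_error(coverage_per_fragment(pl[0, ], fx$fm), "RPM undefined")
})

test_that("interaction calls demand the threshold in every replicate and exclude the bait", {
  fx <- make_tiny_bait()
  fm <- fx$fm
  mkcov <- function(rpmize) {
    counts <- rpmize(fm)
    pl <- data.frame(chrom = rep(fm$chrom, counts),
                     start = rep(fm$start, counts), width = 2L,
                     strand = "+")
    coverage_per_fragment(pl, fm)
  }
  # rpm per fragment proportional to counts; thresholds scale with totals
  cov1 <- mkcov(function(fm) c(10, 60, 10, 20))
  cov2 <- mkcov(function(fm) c(10, 70, 5, 15))
  bait <- bait_spec("c1", 2, "ACGTACGTGG", fm,
                    exclusion_radius_fragments = 0L)
  calls <- call_interactions(list(cov1, cov2), bait, fm,
                             rpm_threshold = 150000)
  expect_true(all(calls$fragment_id != bait$bait_fragment_id))
  expect_identical(calls$fragment_id, 2L)   # passes in both replicates
  expect_true(calls$is_cis[1])
  expect_equal(calls$distance_to_bait[1],
               (fm$start[2] + fm$end[2]) / 2 - 2)

  # reproducibility: a fragment above threshold in one replicate only is out
  cov3 <- mkcov(function(fm) c(80, 5, 10, 5))
  expect_false(2L %in% call_interactions(list(cov1, cov3), bait, fm,
                                         150000)$fragment_id)

  # exclusion radius removes bait-adjacent fragments however strong
  bait2 <- bait_spec("c1", 2, "ACGTACGTGG", fm,
                     exclusion_radius_fragments = 2L)
  calls2 <- call_interactions(list(cov1, cov2), bait2, fm, 1)
  expect_true(all(abs(calls2$fragment_id - bait2$bait_fragment_id) > 2 |
                    calls2$chrom != "c1"))
})

test_that("cis/trans summary reproduces the worked split and simple arithmetic", {
  s <- summarize_cis_trans(
    data.frame(is_cis = rep(c(TRUE, FALSE), c(416, 138))))
  expect_identical(s$n_total, 554L)
  expect_identical(s$n_cis, 416L)
  expect_identical(s$n_trans, 138L)
  expect_identical(s$pct_cis, 75.09)
  expect_identical(s$pct_trans, 24.91)

  s2 <- summarize_cis_trans(data.frame(is_cis = rep(TRUE, 10)))
  expect_identical(c(s2$pct_cis, s2$pct_trans), c(100, 0))
  s3 <- summarize_cis_trans(data.frame(is_cis = c(TRUE, FALSE, FALSE)))
  expect_identical(c(s3$pct_cis, s3$pct_trans), c(33.33, 66.67))
  expect_error(summarize_cis_trans(data.frame(is_cis = logical(0))), "empty")
})

test_that("raising the RPM threshold never adds calls (monotonicity)", {
  fx <- make_tiny_bait()
  set.seed(21)
  mk <- function() {
    counts <- sample(0:40, nrow(fx$fm), replace = TRUE)
    pl <- data.frame(chrom = rep(fx$fm$chrom, counts),
                     start = rep(fx$fm$start, counts), width = 2L,
                     strand = "+")
    coverage_per_fragment(pl, fx$fm)
  }
  bait <- fx$bait
  for (i in 1:20) {
    covs <- list(mk(), mk())
    thr <- sort(runif(3, 0, 4e5))
    sets <- lapply(thr, function(t)
      call_interactions(covs, bait, fx$fm, t)$fragment_id)
    expect_true(all(sets[[2]] %in% sets[[1]]))
    expect_true(all(sets[[3]] %in% sets[[2]]))
  }
})

test_that("exported tracks round-trip RPM values and call scores", {
  fx <- make_tiny_bait()
  pl <- data.frame(chrom = "c1", start = c(rep(0L, 3), rep(13L, 17)),
                   width = 4L, strand = "+")
  cov <- coverage_per_fragment(pl, fx$fm)
  calls <- call_interactions(list(cov, cov), fx$bait, fx$fm,
                             rpm_threshold = 1e5)
  bg <- withr::local_tempfile(fileext = ".bedGraph")
  bed <- withr::local_tempfile(fileext = ".bed")
  export_tracks(cov, calls, fx$fm, bg, bed)
  # independent reader for the bedGraph
  gr <- rtracklayer::import(bg, format = "bedGraph")
  expect_equal(gr$score, cov$rpm, tolerance = 1e-6)
  expect_identical(BiocGenerics::start(gr) - 1L,
                   fx$fm$start[match(cov$fragment_id, fx$fm$fragment_id)])
  bed_df <- utils::read.delim(bed, header = FALSE, comment.char = "#")
  expect_identical(bed_df$V4, calls$fragment_id)
  expect_true(all(bed_df$V5 <= 1000))

  # empty call set still writes a commented BED
  export_tracks(cov, calls[0, ], fx$fm, bg, bed)
  expect_match(readLines(bed)[1], "^#")
  expect_identical(length(readLines(bed)), 1L)
})

test_that("the replicate pipeline is deterministic end to end", {
  dir <- withr::local_tempdir()
  refs <- make_genome(9, c(chrA = 20000L, chrB = 12000L))
  fm <- digest_genome(refs, enzyme("DpnII"))
  id <- locate_bait(fm, "chrA", 10000)
  row <- which(fm$fragment_id == id)
  pos <- fm$start[row] + 30L
  primer <- substring(as.character(refs[["chrA"]]), pos + 1, pos + 20)
  bait <- bait_spec("chrA", pos, primer, fm)
  prof <- contact_profile(fm, bait)
  f1 <- file.path(dir, "R1.fastq"); f2 <- file.path(dir, "R2.fastq")
  simulate_4c_library(refs, fm, bait, prof, 2000, 9, "rep1", f1, f2)
  cov_a <- run_4c_replicate(f1, f2, refs, fm, bait)
  cov_b <- run_4c_replicate(f1, f2, refs, fm, bait)
  expect_identical(as.data.frame(cov_a), as.data.frame(cov_b))
  expect_equal(sum(cov_a$rpm), 1e6, tolerance = 1e-9)
})
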