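# Base counting at panel loci from SAM alignments, the non-maternal allele
# summary, and the gold-standard fraction.

q40 <- function(n) strrep("I", n)

test_that("a manual three-read pileup is reproduced exactly", {
  panel <- make_panel("1", 10000L, "A", "G")
  reads <- data.frame(
    qname = c("r1", "r2", "r3"), flag = 0L, chrom = "chr1",
    pos = c(9981L, 9990L, 9975L), mapq = 60L, cigar = "50M",
    seq = c(strrep("A", 50), strrep("A", 50),
            paste0(strrep("C", 25), "G", strrep("C", 24))),
    qual = q40(50))
  # r3 places its 26th base (G) on 10000 = 9975 + 25
  sam <- write_test_sam(reads)
  counts <- count_alleles(sam, panel)
  expect_equal(counts$n_maternal, 2L)
  expect_equal(counts$n_nonmaternal, 1L)
  expect_equal(counts$n_other, 1L) # G is the array alt allele
})

test_that("N bases, low-quality bases and deletions are discarded, not counted", {
  panel <- make_panel("1", 1000L, "A", "G")
  reads <- data.frame(
    qname = c("n1", "q1", "d1", "ok"), flag = 0L, chrom = "chr1",
    pos = c(991L, 991L, 981L, 991L), mapq = 60L,
    cigar = c("20M", "20M", "10M15D10M", "20M"),
    seq = c(paste0(strrep("A", 9), "N", strrep("A", 10)),
            strrep("A", 20), strrep("A", 20), strrep("A", 20)),
    qual = c(q40(20),
             paste0(strrep("I", 9), "#", strrep("I", 10)), # base 10 at Q2
             q40(20), q40(20)))
  counts <- count_alleles(write_test_sam(reads), panel)
  # d1 spans 981-990 (M), deletes 991-1005, so the locus is under a deletion
  expect_equal(counts$n_maternal, 1L)
  expect_equal(counts$n_nonmaternal, 0L)
  expect_equal(counts$n_discarded, 3L)
})

test_that("duplicate, secondary, supplementary and low-MAPQ records are excluded", {
  panel <- make_panel("1", 1000L, "A", "G")
  reads <- data.frame(
    qname = c("a", "b", "c", "d", "e"),
    flag = c(0L, 1024L, 256L, 2048L, 0L),
    chrom = "chr1", pos = 991L,
    mapq = c(60L, 60L, 60L, 60L, 5L), cigar = "20M",
    seq = strrep("G", 20), qual = q40(20))
  counts <- count_alleles(write_test_sam(reads), panel)
  expect_equal(counts$n_nonmaternal, 1L) # only read "a" survives
  counts_nodedup <- count_alleles(write_test_sam(reads), panel, dedup = FALSE)
  expect_equal(counts_nodedup$n_nonmaternal, 2L) # duplicate now counted
})

test_that("overlapping mates of one template contribute a single base", {
  panel <- make_panel("1", 1000L, "A", "G")
  # same qname covering the locus twice with different bases; the
  # higher-quality base (G at Q40) must win over A at Q25
  reads <- data.frame(
    qname = "frag1", flag = c(99L, 147L), chrom = "chr1",
    pos = c(991L, 995L), mapq = 60L, cigar = "20M",
    seq = c(paste0(strrep("T", 9), "A", strrep("T", 10)),
            paste0(strrep("T", 5), "G", strrep("T", 14))),
    qual = c(paste0(strrep("I", 9), ":", strrep("I", 10)), q40(20)))
  counts <- count_alleles(write_test_sam(reads), panel)
  expect_equal(counts$n_maternal + counts$n_nonmaternal, 1L)
  expect_equal(counts$n_nonmaternal, 1L)
})

test_that("soft clips and insertions shift the query offset correctly", {
  panel <- make_panel("1", 1000L, "A", "G")
  reads <- data.frame(
    qname = c("sc", "ins"), flag = 0L, chrom = "chr1",
    pos = c(996L, 991L), mapq = 60L,
    cigar = c("5S15M", "5M3I12M"),
    # sc: aligned part starts at 996, locus at offset 5 of the M block,
    # query index 5 (clip) + 5 = 10
    seq = c(paste0(strrep("T", 9), "G", strrep("T", 10)),
            # ins: 5M covers 991-995, 3I, 12M covers 996-1007;
            # locus 1000 = query 5 + 3 + 5 = 13
            paste0(strrep("T", 12), "A", strrep("T", 7))),
    qual = q40(20))
  counts <- count_alleles(write_test_sam(reads), panel)
  expect_equal(counts$n_maternal, 1L)
  expect_equal(counts$n_nonmaternal, 1L)
})

test_that("counting matches an independent naive pileup on a random 50-read fixture", {
  set.seed(7)
  panel <- make_panel(
    chrom = rep("1", 5), pos = c(1000L, 1040L, 2000L, 3000L, 5000L),
    ref = c("A", "C", "G", "T", "A"), alt = c("G", "T", "A", "C", "C"),
    maternal = c("A", "T", "G", "T", "C"))
  n <- 50
  reads <- data.frame(
    qname = sprintf("r%02d", seq_len(n)), flag = 0L, chrom = "chr1",
    pos = sample(c(960:1050, 1960:2010, 2960:4990), n, replace = TRUE),
    mapq = sample(c(0L, 30L, 60L), n, replace = TRUE), cigar = "50M",
    seq = replicate(n, paste(sample(c("A", "C", "G", "T", "N"), 50,
      replace = TRUE, prob = c(.3, .3, .2, .15, .05)), collapse = "")),
    qual = replicate(n, paste(intToUtf8(33L + sample(5:40, 50, replace = TRUE),
      multiple = TRUE), collapse = "")))
  oracle <- naive_pileup(reads, panel)
  counts <- count_alleles(write_test_sam(reads), panel)
  expect_equal(counts$pos, oracle$pos)
  expect_equal(counts$n_maternal, oracle$n_maternal)
  expect_equal(counts$n_nonmaternal, oracle$n_nonmaternal)
  expect_equal(counts$n_other, oracle$n_other)
  expect_equal(counts$n_discarded, oracle$n_discarded)
  # shuffling the alignment order changes nothing
  shuffled <- reads[sample.int(n), ]
  counts2 <- count_alleles(write_test_sam(shuffled), panel)
  expect_equal(counts2, counts)
})

test_that("X is invariant under chromosome renaming and panel re-sorting", {
  set.seed(8)
  panel <- make_panel(rep("1", 3), c(1000L, 2000L, 3000L), "A", "G")
  reads <- data.frame(
    qname = sprintf("r%d", 1:30), flag = 0L, chrom = "chr1",
    pos = rep(c(981L, 1991L, 2981L), 10), mapq = 60L, cigar = "50M",
    seq = replicate(30, paste(sample(c("A", "G"), 50, replace = TRUE,
      prob = c(.9, .1)), collapse = "")),
    qual = q40(50))
  x1 <- summarize_nonmaternal(count_alleles(write_test_sam(reads), panel))$X
  # same alignments without the chr prefix, panel rows reversed
  reads2 <- reads
  reads2$chrom <- "1"
  sam2 <- write_test_sam(reads2, chrom_lens = c("1" = 1000000L))
  panel2 <- panel[rev(seq_len(nrow(panel))), ]
  panel2 <- read_panel(write_panel(panel2, tempfile(fileext = ".tsv")))
  x2 <- summarize_nonmaternal(count_alleles(sam2, panel2))$X
  expect_equal(x1, x2)
})

test_that("the non-maternal summary is plain pooled arithmetic", {
  counts <- data.frame(chrom = "1", pos = 1:4,
    maternal_allele = "A",
    n_maternal = c(5000L, 2000L, 1965L, 1000L),
    n_nonmaternal = c(10L, 5L, 0L, 20L),
    n_other = 0L, n_discarded = 0L)
  s <- summarize_nonmaternal(counts)
  expect_equal(s$total_bases, 10000)
  expect_equal(s$X, 0.35) # 35 / 10000 in percent
  expect_equal(s$n_loci_covered, 4)
  # all-maternal boundary
  counts$n_nonmaternal <- 0L
  expect_equal(summarize_nonmaternal(counts)$X, 0)
  # no counted bases is an error
  counts$n_maternal <- 0L
  expect_error(summarize_nonmaternal(counts), "no counted bases")
})

test_that("the gold-standard fraction follows F = 2p/(p+q) x 100", {
  fetal <- data.frame(chrom = "1", pos = c(100L, 200L), ref = "A", alt = "G",
    genotype = c("AB", "AB"), alt_freq = NA_real_)
  class(fetal) <- c("ff_genotypes", "data.frame")
  counts <- data.frame(chrom = "1", pos = c(100L, 200L), ref = "A", alt = "G",
    maternal_allele = "A",
    n_maternal = c(50L, 40L), n_nonmaternal = c(7L, 5L),
    n_other = c(6L, 4L), n_discarded = 0L)
  res <- compute_actual_fraction(counts, fetal)
  expect_equal(res$p, 10)
  expect_equal(res$q, 90)
  expect_equal(res$F, 20) # 2*10/100*100; neither-allele bases ignored
  # p = 0 boundary
  counts$n_other <- 0L
  expect_equal(compute_actual_fraction(counts, fetal)$F, 0)
  # p + q = 0 is an error
  counts$n_maternal <- 0L
  expect_error(compute_actual_fraction(counts, fetal), "p \\+ q = 0")
  # loci where the fetus is homozygous are not informative
  fetal$genotype <- c("AA", "AA")
  counts$n_maternal <- c(50L, 40L)
  expect_error(compute_actual_fraction(counts, fetal), "p \\+ q = 0")
})

test_that("restricting to a random half of informative loci moves F only within sampling noise", {
  cfg <- sim_config(n_loci = 40000, coverage = 10, f_true_pct = 12,
                    mode = "site_level", seed = 99)
  s <- simulate_sample(cfg)
  full <- compute_actual_fraction(s)
  inf_idx <- which(s$fetal_genotypes$genotype == "AB")
  set.seed(1)
  for (rep in 1:3) {
    half <- sort(sample(inf_idx, length(inf_idx) %/% 2))
    res <- compute_actual_fraction(s$counts[half, ], s$fetal_genotypes)
    # binomial sampling SD of F on the half-panel
    r <- res$p / (res$p + res$q)
    sd_f <- 200 * sqrt(r * (1 - r) / (res$p + res$q))
    expect_lt(abs(res$F - full$F), 4 * sd_f)
  }
})
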