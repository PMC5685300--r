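# Allele counting at panel loci from plasma alignments (SAM/BAM) or
# pre-tabulated pileup tables, the non-maternal allele fraction X, and the
# gold-standard fetal fraction from known fetal genotypes.

#' Count maternal and non-maternal bases at panel loci
#'
#' Walks every primary, mapped, non-duplicate alignment and extracts the base
#' it places on each panel locus. A base counts as maternal when it equals
#' the maternal allele and as non-maternal when it is any other A/C/G/T base;
#' `N` bases, bases below the base-quality threshold, and deletions/reference
#' skips spanning the locus go to `n_discarded`. Bases equal to the locus's
#' other array allele (alt for maternal-ref loci, ref for maternal-alt loci)
#' are additionally tracked in `n_other`, which is what the gold-standard
#' fraction needs.
#'
#' Each aligned segment contributes at most one base per locus, and when both
#' mates of a pair cover the same locus only the higher-quality base is
#' counted, so one template molecule is never counted twice.
#'
#' @param alignments path to a SAM or BAM file. SAM input is converted on the
#'   fly via [Rsamtools::asBam()].
#' @param panel an `ff_panel` from [select_homozygous()] or [read_panel()].
#' @param min_base_quality minimum Phred base quality for a base to be
#'   counted (default 20).
#' @param min_mapq minimum mapping quality (default 20).
#' @param dedup drop duplicate-flagged (0x400) records (default `TRUE`).
#'   Secondary (0x100), supplementary (0x800) and unmapped records are always
#'   dropped.
#' @return a data frame of class `ff_counts` with columns `chrom`, `pos`,
#'   `ref`, `alt`, `maternal_allele`, `n_maternal`, `n_nonmaternal`,
#'   `n_other`, `n_discarded`; one row per panel locus overlapped by at least
#'   one inspected base.
#' @export
count_alleles <- function(alignments, panel, min_base_quality = 20,
                          min_mapq = 20, dedup = TRUE) {
  if (!file.exists(alignments)) stopf("alignment file not found: %s", alignments)
  if (nrow(panel) == 0) stopf("panel is empty; nothing to count")
  bam <- alignments
  if (grepl("\\.sam$", alignments, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(alignments, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE,
    isDuplicate = if (dedup) FALSE else NA)
  param <- Rsamtools::ScanBamParam(
    flag = flag, mapqFilter = min_mapq,
    what = c("qname", "rname", "pos", "cigar", "seq", "qual"))
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  if (length(rec$pos) == 0) stopf("no usable alignments in %s", alignments)

  calls <- .pileup_calls(rec, panel)
  if (nrow(calls) == 0) {
    stopf("no alignments overlap the panel; fetal fraction estimation is impossible")
  }
  # one base per template per locus: keep the best-quality call of each
  # (locus, read name) pair, preferring real bases over discarded ones
  qual_key <- ifelse(is.na(calls$qual), -1L, calls$qual)
  ord <- order(calls$chrom, calls$pos, calls$qname, -qual_key)
  calls <- calls[ord, , drop = FALSE]
  dup <- duplicated(paste(calls$chrom, calls$pos, calls$qname))
  calls <- calls[!dup, , drop = FALSE]

  discarded <- is.na(calls$base) | calls$base == "N" | calls$qual < min_base_quality
  .aggregate_calls(calls, discarded, panel)
}

# Extract per-(read, locus) base calls by walking CIGAR strings.
.pileup_calls <- function(rec, panel) {
  chrom_read <- normalize_chrom(as.character(rec$rname))
  seqs <- as.character(rec$seq)
  quals <- as.character(rec$qual)
  by_chrom <- split(seq_len(nrow(panel)), panel$chrom)
  out_chrom <- character(0); out_pos <- integer(0); out_qname <- character(0)
  out_base <- character(0); out_qual <- integer(0)
  n <- length(rec$pos)
  for (i in seq_len(n)) {
    chrom <- chrom_read[i]
    idx <- by_chrom[[chrom]]
    if (is.null(idx)) next
    loci <- panel$pos[idx]
    res <- .walk_cigar(rec$cigar[i], rec$pos[i], seqs[i], quals[i], loci)
    if (length(res$pos) == 0) next
    out_chrom <- c(out_chrom, rep(chrom, length(res$pos)))
    out_pos <- c(out_pos, res$pos)
    out_qname <- c(out_qname, rep(rec$qname[i], length(res$pos)))
    out_base <- c(out_base, res$base)
    out_qual <- c(out_qual, res$qual)
  }
  data.frame(chrom = out_chrom, pos = out_pos, qname = out_qname,
             base = out_base, qual = out_qual, stringsAsFactors = FALSE)
}

# Returns the base and Phred quality each alignment places on every panel
# locus it spans; deletions/refskips yield base NA. `loci` must be sorted.
.walk_cigar <- function(cigar, start, seq, qual, loci) {
  ops_len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  ref_cur <- start
  q_cur <- 1L
  pos_out <- integer(0); base_out <- character(0); qual_out <- integer(0)
  for (k in seq_along(ops)) {
    L <- ops_len[k]
    op <- ops[k]
    if (op %in% c("M", "=", "X")) {
      lo <- findInterval(ref_cur - 1L, loci) + 1L
      hi <- findInterval(ref_cur + L - 1L, loci)
      if (hi >= lo) {
        for (j in lo:hi) {
          off <- loci[j] - ref_cur
          qi <- q_cur + off
          pos_out <- c(pos_out, loci[j])
          base_out <- c(base_out, substr(seq, qi, qi))
          qual_out <- c(qual_out, utf8ToInt(substr(qual, qi, qi)) - 33L)
        }
      }
      ref_cur <- ref_cur + L
      q_cur <- q_cur + L
    } else if (op %in% c("D", "N")) {
      lo <- findInterval(ref_cur - 1L, loci) + 1L
      hi <- findInterval(ref_cur + L - 1L, loci)
      if (hi >= lo) {
        for (j in lo:hi) {
          pos_out <- c(pos_out, loci[j])
          base_out <- c(base_out, NA_character_)
          qual_out <- c(qual_out, NA_integer_)
        }
      }
      ref_cur <- ref_cur + L
    } else if (op %in% c("I", "S")) {
      q_cur <- q_cur + L
    }
    # H and P consume neither reference nor query
  }
  list(pos = pos_out, base = base_out, qual = qual_out)
}

.aggregate_calls <- function(calls, discarded, panel) {
  key <- paste(calls$chrom, calls$pos)
  pkey <- paste(panel$chrom, panel$pos)
  pidx <- match(key, pkey)
  maternal <- panel$maternal_allele[pidx]
  other <- ifelse(maternal == panel$ref[pidx], panel$alt[pidx], panel$ref[pidx])
  is_mat <- !discarded & calls$base == maternal
  is_other <- !discarded & calls$base == other
  is_nonmat <- !discarded & calls$base != maternal & calls$base %in% .base_set
  discarded2 <- discarded | (!is_mat & !is_nonmat)

  agg <- function(v) tapply(as.integer(v), key, sum)
  n_mat <- agg(is_mat)
  loci_keys <- names(n_mat)
  li <- match(loci_keys, pkey)
  out <- data.frame(
    chrom = panel$chrom[li], pos = panel$pos[li],
    ref = panel$ref[li], alt = panel$alt[li],
    maternal_allele = panel$maternal_allele[li],
    n_maternal = as.integer(n_mat),
    n_nonmaternal = as.integer(agg(is_nonmat)),
    n_other = as.integer(agg(is_other)),
    n_discarded = as.integer(agg(discarded2)),
    stringsAsFactors = FALSE)
  out <- out[order_loci(out), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ff_counts", "data.frame")
  out
}

#' Read and write per-locus allele-count tables
#'
#' The pileup TSV dialect has a header and columns `chrom`, `pos`,
#' `maternal_allele`, `n_maternal`, `n_nonmaternal`, with optional `ref`,
#' `alt`, `n_other` and `n_discarded`.
#'
#' @param path file path.
#' @param counts an `ff_counts` data frame.
#' @return `read_pileup_tsv` returns an `ff_counts` data frame;
#'   `write_counts` returns `path` invisibly.
#' @export
read_pileup_tsv <- function(path) {
  if (!file.exists(path)) stopf("pileup file not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "maternal_allele", "n_maternal", "n_nonmaternal")
  if (!all(need %in% names(df))) {
    stopf("pileup file lacks required columns: %s",
          paste(setdiff(need, names(df)), collapse = ", "))
  }
  df$chrom <- normalize_chrom(as.character(df$chrom))
  df$pos <- as.integer(df$pos)
  if (is.null(df$n_other)) df$n_other <- NA_integer_
  if (is.null(df$n_discarded)) df$n_discarded <- 0L
  df <- df[order_loci(df), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("ff_counts", "data.frame")
  df
}

#' @rdname read_pileup_tsv
#' @export
write_counts <- function(counts, path) {
  write.table(as.data.frame(counts), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Aggregate allele counts into the non-maternal allele fraction X
#'
#' Pools counts over all loci and reports
#' `X = 100 * nonmaternal_bases / total_bases`, the percentage of counted
#' bases that differ from the maternal allele. `X` is the raw signal the
#' calibration model converts to a fetal DNA fraction.
#'
#' @param x an `ff_counts` data frame or an [simulate_sample()] result.
#' @param ... unused.
#' @return a list of class `ff_summary` with `total_bases`,
#'   `nonmaternal_bases`, `X` (percent) and `n_loci_covered` (`NA` when the
#'   input is aggregate-only).
#' @export
summarize_nonmaternal <- function(x, ...) UseMethod("summarize_nonmaternal")

#' @export
summarize_nonmaternal.data.frame <- function(x, ...) {
  total <- sum(x$n_maternal) + sum(x$n_nonmaternal)
  if (total == 0) stopf("no counted bases; cannot compute the non-maternal fraction")
  nonmat <- sum(x$n_nonmaternal)
  .new_summary(total, nonmat, sum(x$n_maternal + x$n_nonmaternal >= 1))
}

.new_summary <- function(total, nonmat, n_loci_covered) {
  structure(list(
    total_bases = total, nonmaternal_bases = nonmat,
    X = 100 * nonmat / total, n_loci_covered = n_loci_covered),
    class = "ff_summary")
}

#' @exportS3Method print ff_summary
print.ff_summary <- function(x, ...) {
  cat(sprintf("Non-maternal allele summary\n  bases counted: %s\n  non-maternal:  %s\n  X = %.4f%%\n",
      format(x$total_bases, big.mark = ","),
      format(x$nonmaternal_bases, big.mark = ","), x$X))
  invisible(x)
}

#' Write a non-maternal allele summary as JSON
#'
#' @param summary an `ff_summary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Gold-standard fetal fraction from known fetal genotypes
#'
#' At informative loci -- maternal homozygous and fetal heterozygous for the
#' same ref/alt pair -- the fetal-specific allele is the one the mother does
#' not carry. With `p` the number of bases carrying the fetal-specific allele
#' and `q` the number carrying the shared maternal allele, the actual fetal
#' DNA fraction is
#' \deqn{F = \frac{2p}{p+q} \times 100.}
#' The factor 2 reflects that only half of fetal molecules at a heterozygous
#' locus carry the fetal-specific allele. Bases matching neither array allele
#' are ignored.
#'
#' @param x an `ff_counts` data frame (with the `n_other` column populated)
#'   or a `site_level` [simulate_sample()] result.
#' @param fetal_genotypes an `ff_genotypes` data frame of fetal genotypes
#'   (required for counts input).
#' @param ... unused.
#' @return a list of class `ff_actual` with `p`, `q`, `F` (percent) and
#'   `n_informative`.
#' @export
compute_actual_fraction <- function(x, ...) UseMethod("compute_actual_fraction")

#' @export
compute_actual_fraction.data.frame <- function(x, fetal_genotypes, ...) {
  if (missing(fetal_genotypes)) stopf("fetal genotypes are required for counts input")
  if (any(is.na(x$n_other))) {
    stopf("counts lack the n_other column; per-allele counts are required")
  }
  fg <- fetal_genotypes[fetal_genotypes$genotype == "AB", , drop = FALSE]
  key_c <- paste(x$chrom, x$pos)
  key_f <- paste(normalize_chrom(fg$chrom), fg$pos)
  m <- match(key_c, key_f)
  keep <- !is.na(m)
  if ("ref" %in% names(x)) {
    # guard against ref/alt disagreements between the two genotype sources
    keep <- keep & x$ref == fg$ref[m] & x$alt == fg$alt[m]
  }
  inf <- x[keep, , drop = FALSE]
  p <- sum(inf$n_other)
  q <- sum(inf$n_maternal)
  if (p + q == 0) stopf("no informative bases (p + q = 0); cannot compute the actual fraction")
  structure(list(p = p, q = q, F = 200 * p / (p + q),
                 n_informative = nrow(inf)), class = "ff_actual")
}

#' @exportS3Method print ff_actual
print.ff_actual <- function(x, ...) {
  cat(sprintf("Gold-standard fetal fraction: F = %.3f%% (p = %s, q = %s, %d informative loci)\n",
      x$F, format(x$p, big.mark = ","), format(x$q, big.mark = ","),
      x$n_informative))
  invisible(x)
}
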