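# Fixture builders and independent oracles shared across test files.
# Everything is generated in code; no binary fixtures are stored.

# Build an ff_panel through the public API from parallel vectors.
make_panel <- function(chrom, pos, ref, alt, maternal = ref) {
  geno <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
    genotype = ifelse(maternal == ref, "AA", "BB"),
    alt_freq = NA_real_, stringsAsFactors = FALSE)
  class(geno) <- c("ff_genotypes", "data.frame")
  select_homozygous(geno, include_sex_chroms = TRUE)
}

# Write a SAM file from a record data frame
# (qname, flag, chrom, pos, mapq, cigar, seq, qual).
write_test_sam <- function(records, path = tempfile(fileext = ".sam"),
                           chrom_lens = c(chr1 = 1000000L, chr2 = 1000000L)) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lens), chrom_lens))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
    records$qname, records$flag, records$chrom, records$pos,
    records$mapq, records$cigar, records$seq, records$qual)
  writeLines(c(header, body), path)
  path
}

# Independent per-base pileup oracle for reads with simple "<n>M" CIGARs.
# Reimplements the counting rules naively: flag/MAPQ filters, per-base
# quality, one base per (locus, read name) keeping the highest quality.
naive_pileup <- function(records, panel, min_bq = 20, min_mapq = 20) {
  calls <- list()
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (bitwAnd(r$flag, 0x4 + 0x100 + 0x400 + 0x800) != 0) next
    if (r$mapq < min_mapq) next
    stopifnot(grepl("^[0-9]+M$", r$cigar))
    len <- nchar(r$seq)
    for (j in seq_len(nrow(panel))) {
      if (sub("^chr", "", r$chrom) != panel$chrom[j]) next
      off <- panel$pos[j] - r$pos + 1L
      if (off >= 1 && off <= len) {
        calls[[length(calls) + 1L]] <- data.frame(
          j = j, qname = r$qname, base = substr(r$seq, off, off),
          q = utf8ToInt(substr(r$qual, off, off)) - 33L)
      }
    }
  }
  out <- data.frame(chrom = panel$chrom, pos = panel$pos,
    n_maternal = 0L, n_nonmaternal = 0L, n_other = 0L, n_discarded = 0L)
  if (length(calls) == 0) return(out[0, ])
  calls <- do.call(rbind, calls)
  calls <- calls[order(calls$j, calls$qname, -calls$q), ]
  calls <- calls[!duplicated(paste(calls$j, calls$qname)), ]
  for (k in seq_len(nrow(calls))) {
    j <- calls$j[k]
    maternal <- panel$maternal_allele[j]
    other <- ifelse(maternal == panel$ref[j], panel$alt[j], panel$ref[j])
    b <- calls$base[k]
    if (b == "N" || calls$q[k] < min_bq || !(b %in% c("A", "C", "G", "T"))) {
      out$n_discarded[j] <- out$n_discarded[j] + 1L
    } else if (b == maternal) {
      out$n_maternal[j] <- out$n_maternal[j] + 1L
    } else {
      out$n_nonmaternal[j] <- out$n_nonmaternal[j] + 1L
      if (b == other) out$n_other[j] <- out$n_other[j] + 1L
    }
  }
  out[rowSums(out[, 3:6]) > 0, ]
}

# Quantile oracle: linear interpolation between order statistics,
# hand-rolled (matches the "type 7" definition by construction).
interp_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

# Minimal VCF writer kept independent of the package's internals.
write_test_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    lines), path)
  path
}
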