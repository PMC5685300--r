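# Genotype and SNP-panel I/O: reading maternal (or fetal) genotypes from VCF
# or TSV, deriving the maternal-homozygous panel, and panel round-tripping.

#' Read genotypes from a VCF or TSV file
#'
#' Parses biallelic SNV genotypes into a data frame with one row per usable
#' record. Multi-allelic sites, indels and otherwise malformed records are
#' skipped (their number is reported as a message and stored in the
#' `n_skipped` attribute). The TSV dialect is
#' `chrom  pos  ref  alt  genotype  [alt_freq]`, with or without a header
#' line; genotypes are `AA`, `AB`, `BB` (A = ref, B = alt) or `missing`.
#' In VCF input the first sample's `GT` field is used, with `0/0 -> AA`,
#' `0/1 -> AB`, `1/1 -> BB`, and `./.` -> `missing`.
#'
#' Chromosome names are normalized by stripping any `chr` prefix, and
#' positions are 1-based as in VCF.
#'
#' @param path path to the genotype file.
#' @param format `"auto"` (by file extension), `"vcf"` or `"tsv"`.
#' @return a data frame of class `ff_genotypes` with columns `chrom`, `pos`,
#'   `ref`, `alt`, `genotype`, `alt_freq`, and attribute `n_skipped`.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("genotype file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  gt <- switch(format,
    vcf = .read_genotypes_vcf(path),
    tsv = .read_genotypes_tsv(path))
  gt
}

.new_genotypes <- function(df, n_skipped) {
  df$chrom <- normalize_chrom(df$chrom)
  df$pos <- as.integer(df$pos)
  df <- df[order_loci(df), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "n_skipped") <- n_skipped
  class(df) <- c("ff_genotypes", "data.frame")
  if (n_skipped > 0) {
    message(sprintf("skipped %d record(s) (multi-allelic, indel or malformed)", n_skipped))
  }
  df
}

.read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) return(.new_genotypes(
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), genotype = character(), alt_freq = numeric()), 0L))
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")[, 1]
  ok <- !is.na(fix$ALT) & fix$ALT != "." &
    !grepl(",", fix$ALT, fixed = TRUE) &
    nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    fix$REF %in% .base_set & fix$ALT %in% .base_set
  n_skipped <- sum(!ok)
  fix <- fix[ok, , drop = FALSE]
  gt_raw <- gt_raw[ok]
  geno <- .parse_gt(gt_raw)
  af <- rep(NA_real_, nrow(fix))
  if (!is.null(fix$INFO)) {
    m <- regmatches(fix$INFO, regexpr("(?:^|;)AF=([0-9.eE+-]+)", fix$INFO))
    has_af <- grepl("(?:^|;)AF=", fix$INFO)
    af[has_af] <- suppressWarnings(as.numeric(sub("^;?AF=", "", m)))
  }
  .new_genotypes(data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
    genotype = geno, alt_freq = af, stringsAsFactors = FALSE), n_skipped)
}

.parse_gt <- function(gt) {
  gt <- sub(":.*$", "", gt)
  gt <- gsub("|", "/", gt, fixed = TRUE)
  out <- rep("missing", length(gt))
  out[gt %in% c("0/0")] <- "AA"
  out[gt %in% c("0/1", "1/0")] <- "AB"
  out[gt %in% c("1/1")] <- "BB"
  out
}

.read_genotypes_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) > 0 && grepl("^chrom\\b", lines[1], ignore.case = TRUE)) {
    lines <- lines[-1]
  }
  if (length(lines) == 0) {
    return(.new_genotypes(data.frame(
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), genotype = character(), alt_freq = numeric()), 0L))
  }
  fields <- strsplit(lines, "[\t ]+")
  n_skipped <- 0L
  rows <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    ok <- length(f) >= 5 &&
      !is.na(suppressWarnings(as.integer(f[2]))) &&
      nchar(f[3]) == 1 && nchar(f[4]) == 1 &&
      f[3] %in% .base_set && f[4] %in% .base_set && f[3] != f[4]
    geno <- if (ok) .normalize_geno_label(f[5]) else NA_character_
    if (!ok || is.na(geno)) {
      n_skipped <- n_skipped + 1L
      next
    }
    af <- if (length(f) >= 6) suppressWarnings(as.numeric(f[6])) else NA_real_
    rows[[i]] <- data.frame(chrom = f[1], pos = as.integer(f[2]), ref = f[3],
      alt = f[4], genotype = geno, alt_freq = af, stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), genotype = character(), alt_freq = numeric())
  if (n_skipped > 0) warnf("skipped %d malformed genotype line(s)", n_skipped)
  .new_genotypes(df, n_skipped)
}

.normalize_geno_label <- function(x) {
  x <- toupper(x)
  if (x %in% c("AA", "AB", "BB")) return(x)
  if (x %in% c("BA")) return("AB")
  if (x %in% c("MISSING", "NN", "./.", ".")) return("missing")
  NA_character_
}

#' Derive the maternal-homozygous SNP panel from genotypes
#'
#' Keeps exactly the homozygous records (`AA`, `BB`) and records which allele
#' the mother carries: the reference allele for `AA`, the alternative allele
#' for `BB`. Heterozygous and missing genotypes are dropped. Sex chromosomes
#' are excluded by default because chromosome-Y alignments confound the
#' non-maternal signal for male fetuses.
#'
#' @param genotypes an `ff_genotypes` data frame from [read_genotypes()].
#' @param include_sex_chroms keep X/Y loci (default `FALSE`).
#' @return a data frame of class `ff_panel` with columns `chrom`, `pos`,
#'   `ref`, `alt`, `maternal_allele`, `alt_freq`, sorted by (chrom, pos) and
#'   unique by locus. Attributes `n_het`, `n_missing` and `n_sex_excluded`
#'   record what was dropped.
#' @export
select_homozygous <- function(genotypes, include_sex_chroms = FALSE) {
  stopifnot(is.data.frame(genotypes))
  n_het <- sum(genotypes$genotype == "AB")
  n_missing <- sum(genotypes$genotype == "missing")
  hom <- genotypes[genotypes$genotype %in% c("AA", "BB"), , drop = FALSE]
  n_sex <- 0L
  if (!include_sex_chroms) {
    sex <- is_sex_chrom(hom$chrom)
    n_sex <- sum(sex)
    hom <- hom[!sex, , drop = FALSE]
  }
  panel <- data.frame(
    chrom = hom$chrom, pos = hom$pos, ref = hom$ref, alt = hom$alt,
    maternal_allele = ifelse(hom$genotype == "AA", hom$ref, hom$alt),
    alt_freq = hom$alt_freq, stringsAsFactors = FALSE)
  panel <- .as_panel(panel)
  attr(panel, "n_het") <- n_het
  attr(panel, "n_missing") <- n_missing
  attr(panel, "n_sex_excluded") <- n_sex
  if (nrow(panel) == 0) warnf("no homozygous loci: the panel is empty")
  panel
}

.as_panel <- function(df) {
  df$chrom <- normalize_chrom(df$chrom)
  df$pos <- as.integer(df$pos)
  df <- df[order_loci(df), , drop = FALSE]
  key <- paste(df$chrom, df$pos)
  if (anyDuplicated(key)) {
    warnf("dropping %d duplicate panel locus/loci", sum(duplicated(key)))
    df <- df[!duplicated(key), , drop = FALSE]
  }
  bad <- df$maternal_allele != df$ref & df$maternal_allele != df$alt
  if (any(bad)) stopf("%d panel row(s) have maternal_allele outside {ref, alt}", sum(bad))
  rownames(df) <- NULL
  class(df) <- c("ff_panel", "data.frame")
  df
}

#' Write and read a maternal-homozygous panel as TSV
#'
#' The panel format is a header line followed by
#' `chrom  pos  ref  alt  maternal_allele  alt_freq` rows, sorted by
#' (chrom, pos). `read_panel(write_panel(p))` is the identity.
#'
#' @param panel an `ff_panel`.
#' @param path output (or input) file path.
#' @return `write_panel` returns `path` invisibly; `read_panel` returns an
#'   `ff_panel`.
#' @export
write_panel <- function(panel, path) {
  panel <- .as_panel(as.data.frame(panel))
  write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stopf("panel file not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "maternal_allele")
  if (!all(need %in% names(df))) {
    stopf("panel file lacks required columns: %s",
          paste(setdiff(need, names(df)), collapse = ", "))
  }
  if (is.null(df$alt_freq)) df$alt_freq <- NA_real_
  df$alt_freq <- as.numeric(df$alt_freq)
  df$chrom <- as.character(df$chrom)
  df$ref <- as.character(df$ref)
  df$alt <- as.character(df$alt)
  df$maternal_allele <- as.character(df$maternal_allele)
  .as_panel(df)
}

#' Export panel coordinates as BED
#'
#' BED uses 0-based half-open intervals, so a SNP at 1-based position `pos`
#' becomes the interval `[pos - 1, pos)`.
#'
#' @param panel an `ff_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
panel_to_bed <- function(panel, path) {
  bed <- data.frame(chrom = panel$chrom, start = panel$pos - 1L, end = panel$pos,
    name = paste0(panel$ref, "/", panel$alt))
  write.table(bed, path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(path)
}
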