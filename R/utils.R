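# Shared helpers: chromosome-name handling, coverage arithmetic, seeds.

# Reference constants used to convert between read-pair counts and fold
# coverage: human genome ~3.1 Gb, 2 x 50 bp paired-end reads = 100 bp/pair,
# so 1 million pairs ~ 0.032-fold coverage.
.GENOME_LENGTH <- 3.1e9
.BASES_PER_PAIR <- 100

#' Convert read-pair counts to fold coverage and back
#'
#' Coverage is total sequenced bases divided by the genome length (3.1 Gb),
#' with one read pair contributing 100 bases (2 x 50 bp).
#'
#' @param n_pairs number of read pairs.
#' @param coverage fold coverage of the genome.
#' @return a numeric scalar/vector.
#' @examples
#' pairs_to_coverage(1e6) # ~0.032
#' @export
pairs_to_coverage <- function(n_pairs) n_pairs * .BASES_PER_PAIR / .GENOME_LENGTH

#' @rdname pairs_to_coverage
#' @export
coverage_to_pairs <- function(coverage) coverage * .GENOME_LENGTH / .BASES_PER_PAIR

# Strip any "chr" prefix so panels and alignments match regardless of
# reference naming style.
normalize_chrom <- function(x) sub("^chr", "", as.character(x), ignore.case = TRUE)

# Sort key giving the conventional karyotype order 1..22, X, Y, MT, then
# anything else alphabetically.
chrom_rank <- function(chrom) {
  n <- suppressWarnings(as.integer(chrom))
  rank <- ifelse(!is.na(n), n,
    ifelse(chrom == "X", 23L,
      ifelse(chrom == "Y", 24L,
        ifelse(chrom %in% c("M", "MT"), 25L, 26L))))
  rank
}

order_loci <- function(df) order(chrom_rank(df$chrom), df$chrom, df$pos)

is_sex_chrom <- function(chrom) chrom %in% c("X", "Y")

# One reproducible sub-seed per unit of work, derived from a master seed.
# Values stay within the 32-bit integer range R requires.
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}

.base_set <- c("A", "C", "G", "T")

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Provenance sidecar written next to CLI artifacts: inputs, parameters, seed
# and package version, enough to re-run the command.
write_provenance <- function(path, subcommand, params) {
  prov <- list(
    artifact = basename(path),
    subcommand = subcommand,
    parameters = params,
    package = "plasmaFF",
    version = as.character(utils::packageVersion("plasmaFF"))
  )
  jsonlite::write_json(prov, paste0(path, ".provenance.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(prov)
}
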