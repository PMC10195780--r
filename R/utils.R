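# Internal helpers: chromosome naming, seeding, validation.

AUTOSOME_PATTERN <- "^chr[0-9]+$"

#' Normalize chromosome names to the "chr" prefix dialect
#'
#' Peak files in the wild use either "chr1" or "1". All internal processing
#' uses the "chr" prefix; names are normalized once on read.
#'
#' @param chrom character vector of chromosome names.
#' @return character vector with a "chr" prefix on every name.
#' @examples
#' normalize_chrom(c("1", "chr2", "X"))
#' @export
normalize_chrom <- function(chrom) {
  chrom <- as.character(chrom)
  miss <- !startsWith(chrom, "chr")
  chrom[miss] <- paste0("chr", chrom[miss])
  chrom
}

#' Test whether chromosome names are autosomal
#'
#' @param chrom character vector of (normalized) chromosome names.
#' @return logical vector, TRUE for chr1..chr22 style names.
#' @export
is_autosome <- function(chrom) {
  grepl(AUTOSOME_PATTERN, normalize_chrom(chrom))
}

# Deterministic derivation of stage/run seeds from one master seed.
# run/stage offsets are XORed in so distinct purposes get distinct streams
# while staying reproducible and below 2^31.
derive_seed <- function(seed, offset) {
  seed <- as.integer(seed)
  stopifnot(!is.na(seed), offset >= 0)
  bitwAnd(bitwXor(seed, as.integer(offset)), .Machine$integer.max)
}

# Evaluate `expr` under a temporary RNG state.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

abort_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
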