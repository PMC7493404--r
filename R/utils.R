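# Internal helpers shared across modules: variant-key normalization,
# per-stage seed derivation, and table validation.

VARIANT_COLS <- c(
  "subject_id", "sample_id", "sample_type", "chrom", "pos", "ref", "alt",
  "depth", "alt_count", "af", "gene", "cds_change", "is_hotspot",
  "is_synonymous"
)

KEY_COLS <- c("chrom", "pos", "ref", "alt")

#' Normalize variant allele representation
#'
#' Reduces each (pos, ref, alt) to its minimal representation by trimming
#' shared trailing bases, then shared leading bases (advancing `pos`), so
#' that the same indel called in tissue and plasma yields an identical key.
#' At least one base is always retained on each allele. Left-alignment
#' against a reference genome is out of scope; trimming alone guarantees key
#' equality for calls emitted from the same caller dialect.
#'
#' @param x A data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @return `x` with `pos`, `ref`, `alt` minimized; other columns untouched.
#' @export
#' @examples
#' normalize_variants(tibble::tibble(
#'   chrom = "chr7", pos = 100L, ref = "CTT", alt = "CT"
#' ))
normalize_variants <- function(x) {
  stopifnot(all(KEY_COLS %in% names(x)))
  if (nrow(x) == 0) return(x)
  trimmed <- pmap(list(x$pos, x$ref, x$alt), function(pos, ref, alt) {
    r <- strsplit(ref, "", fixed = TRUE)[[1]]
    a <- strsplit(alt, "", fixed = TRUE)[[1]]
    while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]
      a <- a[-length(a)]
    }
    while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
      r <- r[-1]
      a <- a[-1]
      pos <- pos + 1L
    }
    list(pos = as.integer(pos), ref = paste(r, collapse = ""),
         alt = paste(a, collapse = ""))
  })
  x$pos <- map_int(trimmed, "pos")
  x$ref <- map_chr(trimmed, "ref")
  x$alt <- map_chr(trimmed, "alt")
  x
}

variant_key <- function(x) {
  paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
}

#' Derive a reproducible per-stage seed from a master seed
#'
#' Each pipeline stage draws its RNG seed deterministically from the master
#' seed and a stage label, so stages can be rerun in isolation with
#' bit-identical results. The scheme is
#' `(master * 7919 + hash(label)) mod (2^31 - 1)`.
#'
#' @param master Integer master seed.
#' @param stage Character stage label.
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 7919 + h) %% (2^31 - 1) + 1)
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

#' Validate a variant table
#'
#' Checks the invariants every downstream stage relies on: `alt_count <=
#' depth`, `af` consistent with `alt_count / depth` to within rounding,
#' `pos >= 1`, `ref != alt`, `af` in `[0, 1]`, and alleles drawn from
#' A/C/G/T (multi-base strings encode indels in minimal representation).
#'
#' @param x A data frame of variant calls.
#' @param context Label used in error messages (e.g. a file path).
#' @return `x` invisibly, as a tibble, if valid; otherwise an error naming
#'   the first offending row.
#' @export
validate_variant_table <- function(x, context = "variant table") {
  x <- as_tibble(x)
  missing_cols <- setdiff(VARIANT_COLS, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s: missing columns: %s", context,
                  paste(missing_cols, collapse = ", ")))
  }
  fail <- function(rows, what) {
    abort(sprintf("%s: row %d: %s", context, rows[1], what))
  }
  if (nrow(x) == 0) return(invisible(x))
  bad <- which(!x$sample_type %in% c("tissue", "plasma"))
  if (length(bad)) fail(bad, "sample_type must be 'tissue' or 'plasma'")
  bad <- which(x$pos < 1)
  if (length(bad)) fail(bad, "pos must be >= 1")
  bad <- which(x$ref == x$alt)
  if (length(bad)) fail(bad, "ref and alt must differ")
  bad <- which(!grepl("^[ACGT]+$", x$ref) | !grepl("^[ACGT]+$", x$alt))
  if (length(bad)) fail(bad, "alleles must be strings over A/C/G/T")
  bad <- which(x$depth < 0 | x$alt_count < 0)
  if (length(bad)) fail(bad, "depth and alt_count must be non-negative")
  bad <- which(x$alt_count > x$depth)
  if (length(bad)) fail(bad, "alt_count exceeds depth")
  bad <- which(x$af < 0 | x$af > 1 | is.na(x$af))
  if (length(bad)) fail(bad, "af must lie in [0, 1]")
  with_counts <- which(x$depth > 0)
  bad <- with_counts[abs(x$af[with_counts] -
                           x$alt_count[with_counts] / x$depth[with_counts]) > 5e-3]
  if (length(bad)) fail(bad, "af inconsistent with alt_count / depth")
  invisible(x)
}
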