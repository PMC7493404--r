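# Reading and writing the tabular interchange formats: the variant-call TSV
# dialect, VCF v4.2, and the sample manifest. All coordinates are held
# 1-based, fully closed (VCF convention) in memory.

manifest_cols <- c("subject_id", "sample_id", "sample_type", "collection_day",
                   "input_mass_ng")

#' Read a variant-call table
#'
#' Reads per-sample variant calls from either the package's TSV dialect or a
#' VCF v4.2 file, normalizes indel representation, validates invariants, and
#' returns one row per called alteration. Row order is preserved.
#'
#' The TSV dialect has exactly the columns documented in
#' [write_variant_table()]: `subject_id, sample_id, sample_type, chrom, pos,
#' ref, alt, depth, alt_count, af, gene, cds_change, is_hotspot,
#' is_synonymous`. For VCF input, sample identity is not encoded in the
#' format, so `subject_id`, `sample_id` and `sample_type` must be supplied;
#' allele frequency and depth are taken from the FORMAT fields of the first
#' genotype column when present (keys `af_key`/`dp_key`), else from INFO.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @param subject_id,sample_id,sample_type Sample identity for VCF input
#'   (ignored for TSV, which carries its own columns).
#' @param af_key,dp_key FORMAT/INFO keys holding allele frequency and
#'   de-duplicated depth in VCF input.
#' @return A tibble of validated variant calls.
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf"),
                               subject_id = NA_character_,
                               sample_id = NA_character_,
                               sample_type = NA_character_,
                               af_key = "AF", dp_key = "DP") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  x <- switch(dialect,
    tsv = read_variant_tsv(path),
    vcf = read_variant_vcf(path, subject_id, sample_id, sample_type,
                           af_key, dp_key)
  )
  x <- normalize_variants(x)
  validate_variant_table(x, context = path)
  x
}

read_variant_tsv <- function(path) {
  x <- readr::read_tsv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      sample_id = readr::col_character(),
      sample_type = readr::col_character(),
      chrom = readr::col_character(),
      pos = readr::col_integer(),
      ref = readr::col_character(),
      alt = readr::col_character(),
      depth = readr::col_integer(),
      alt_count = readr::col_integer(),
      af = readr::col_double(),
      gene = readr::col_character(),
      cds_change = readr::col_character(),
      is_hotspot = readr::col_logical(),
      is_synonymous = readr::col_logical()
    )
  )
  probs <- readr::problems(x)
  if (nrow(probs) > 0) {
    abort(sprintf("%s: parse error at line %d: expected %s, got %s",
                  path, probs$row[1] + 1L, probs$expected[1], probs$actual[1]))
  }
  x$gene[is.na(x$gene)] <- ""
  x$cds_change[is.na(x$cds_change)] <- ""
  x
}

read_variant_vcf <- function(path, subject_id, sample_id, sample_type,
                             af_key, dp_key) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  n <- nrow(fix)
  if (n == 0) return(empty_variant_table())
  has_gt <- ncol(v@gt) >= 2
  get_field <- function(key) {
    val <- rep(NA_character_, n)
    if (has_gt) {
      gt <- tryCatch(
        vcfR::extract.gt(v, element = key, as.numeric = FALSE),
        error = function(e) NULL
      )
      if (!is.null(gt)) val <- gt[, 1]
    }
    miss <- is.na(val)
    if (any(miss)) {
      info <- vcfR::extract.info(v, element = key)
      if (!is.null(info)) val[miss] <- info[miss]
    }
    val
  }
  af_raw <- get_field(af_key)
  dp_raw <- get_field(dp_key)
  rows <- map(seq_len(n), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    afs <- suppressWarnings(
      as.numeric(strsplit(af_raw[i] %||% NA_character_, ",")[[1]])
    )
    if (length(afs) < length(alts)) afs <- rep(afs[1], length(alts))
    depth <- suppressWarnings(as.integer(dp_raw[i]))
    tibble(
      chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
      ref = fix$REF[i], alt = alts,
      depth = depth %||% NA_integer_,
      af = afs[seq_along(alts)]
    )
  })
  x <- list_rbind(rows)
  x$alt_count <- as.integer(round(x$af * x$depth))
  tibble(
    subject_id = subject_id, sample_id = sample_id, sample_type = sample_type,
    chrom = x$chrom, pos = x$pos, ref = x$ref, alt = x$alt,
    depth = x$depth, alt_count = x$alt_count, af = x$af,
    gene = "", cds_change = "", is_hotspot = FALSE, is_synonymous = FALSE
  )
}

empty_variant_table <- function() {
  tibble(
    subject_id = character(), sample_id = character(),
    sample_type = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), depth = integer(),
    alt_count = integer(), af = double(), gene = character(),
    cds_change = character(), is_hotspot = logical(),
    is_synonymous = logical()
  )
}

#' Write a variant table in the package's TSV dialect
#'
#' Columns, in order: `subject_id, sample_id, sample_type, chrom, pos, ref,
#' alt, depth, alt_count, af, gene, cds_change, is_hotspot, is_synonymous`.
#' Allele frequencies are written with enough digits to round-trip.
#'
#' @param x A validated variant table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(x, path) {
  validate_variant_table(x)
  out <- as_tibble(x)[, VARIANT_COLS]
  out$af <- format(out$af, digits = 15, scientific = FALSE, trim = TRUE)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a sample manifest
#'
#' The manifest carries one row per sequenced sample: `subject_id,
#' sample_id, sample_type, collection_day` (integer days from histological
#' diagnosis), `input_mass_ng` (DNA input mass), and optionally
#' `plasma_volume_ml` and `treatment_start_day`. Rows are returned sorted
#' stably by subject then collection day.
#'
#' @param path Path to the manifest TSV.
#' @return A tibble of sample records.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(manifest_cols, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s: missing columns: %s", path,
                  paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(x$sample_id)) {
    abort(sprintf("%s: duplicate sample_id: %s", path,
                  x$sample_id[duplicated(x$sample_id)][1]))
  }
  if (any(x$collection_day < 0)) {
    abort(sprintf("%s: negative collection_day for sample %s", path,
                  x$sample_id[x$collection_day < 0][1]))
  }
  if (any(x$input_mass_ng <= 0)) {
    abort(sprintf("%s: input_mass_ng must be positive", path))
  }
  x$collection_day <- as.integer(x$collection_day)
  arrange(as_tibble(x), .data$subject_id, .data$collection_day)
}

#' Write a sample manifest
#'
#' @param x A manifest tibble (see [read_manifest()] for columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}
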