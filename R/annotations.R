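# Population / somatic database annotations, the repetitive-region mask and
# the hotspot whitelist, bundled into one queryable object.

#' Construct an annotation bundle
#'
#' @param pop_af Tibble with columns `chrom, pos, ref, alt, db, af`: per
#'   population database (ExAC, dbSNP, 1000G roles) allele frequency.
#' @param somatic_evidence Tibble with `chrom, pos, ref, alt, count`:
#'   somatic-evidence observation counts (COSMIC/TCGA roles).
#' @param mask A [GenomicRanges::GRanges] of repetitive regions (1-based,
#'   closed), or `NULL` for an empty mask.
#' @param hotspots Tibble with `chrom, pos, ref, alt`: the whitelist of
#'   well-known hotspot mutations.
#' @return An object of class `ctdna_annotations`.
#' @export
annotations <- function(pop_af = NULL, somatic_evidence = NULL,
                        mask = NULL, hotspots = NULL) {
  pop_af <- as_tibble(pop_af %||% tibble(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), db = character(), af = double()
  ))
  somatic_evidence <- as_tibble(somatic_evidence %||% tibble(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), count = integer()
  ))
  hotspots <- as_tibble(hotspots %||% tibble(
    chrom = character(), pos = integer(), ref = character(),
    alt = character()
  ))
  if (nrow(pop_af) && (any(pop_af$af < 0) || any(pop_af$af > 1))) {
    abort("population allele frequencies must lie in [0, 1]")
  }
  if (is.null(mask)) {
    mask <- GenomicRanges::GRanges()
  }
  mask <- GenomicRanges::reduce(mask)
  structure(
    list(pop_af = pop_af, somatic_evidence = somatic_evidence,
         mask = mask, hotspots = hotspots),
    class = "ctdna_annotations"
  )
}

#' @export
print.ctdna_annotations <- function(x, ...) {
  cat("<ctdna_annotations>\n")
  cat("  pop_af entries:          ", nrow(x$pop_af), "\n")
  cat("  somatic_evidence entries:", nrow(x$somatic_evidence), "\n")
  cat("  mask intervals:          ", length(x$mask), "\n")
  cat("  hotspot entries:         ", nrow(x$hotspots), "\n")
  invisible(x)
}

#' Load annotation tables from disk
#'
#' Population and somatic tables are TSVs with columns `chrom, pos, ref,
#' alt, af` (population) or `chrom, pos, ref, alt, count` (somatic); the
#' database name of each population table is taken from the names of
#' `pop_paths` (falling back to the file stem). The repetitive-region mask
#' is a standard BED file (0-based half-open); it is converted to 1-based
#' closed coordinates on read, so BED line `chr17 100 200` masks positions
#' 101..200. The hotspot list is a TSV with `chrom, pos, ref, alt`.
#'
#' @param pop_paths Named character vector of population-table paths.
#' @param somatic_paths Character vector of somatic-evidence table paths.
#' @param mask_bed Path to the repetitive-region BED, or `NULL`.
#' @param hotspot_path Path to the hotspot TSV, or `NULL`.
#' @return A `ctdna_annotations` object.
#' @export
load_annotations <- function(pop_paths = character(),
                             somatic_paths = character(),
                             mask_bed = NULL, hotspot_path = NULL) {
  for (p in c(pop_paths, somatic_paths, mask_bed, hotspot_path)) {
    if (!file.exists(p)) abort(sprintf("annotation file not found: %s", p))
  }
  db_names <- names(pop_paths) %||% rep("", length(pop_paths))
  if (length(pop_paths)) {
    stem <- sub("\\.[^.]*$", "", basename(pop_paths))
    db_names[!nzchar(db_names)] <- stem[!nzchar(db_names)]
  }
  pop_af <- list_rbind(map2(pop_paths, db_names, function(p, db) {
    x <- readr::read_tsv(p, show_col_types = FALSE, progress = FALSE)
    mutate(x, db = db, pos = as.integer(.data$pos))
  }))
  somatic <- list_rbind(map(somatic_paths, function(p) {
    x <- readr::read_tsv(p, show_col_types = FALSE, progress = FALSE)
    mutate(x, pos = as.integer(.data$pos), count = as.integer(.data$count))
  }))
  mask <- NULL
  if (!is.null(mask_bed)) {
    # rtracklayer converts BED's 0-based half-open intervals to 1-based
    # closed GRanges; malformed overlaps are merged by reduce() in the
    # constructor rather than rejected.
    mask <- tryCatch(rtracklayer::import(mask_bed, format = "BED"),
                     error = function(e) {
                       if (length(readLines(mask_bed)) == 0) {
                         GenomicRanges::GRanges()
                       } else {
                         abort(sprintf("failed to parse BED %s: %s",
                                       mask_bed, conditionMessage(e)))
                       }
                     })
  }
  hotspots <- NULL
  if (!is.null(hotspot_path)) {
    hotspots <- readr::read_tsv(hotspot_path, show_col_types = FALSE,
                                progress = FALSE)
    hotspots$pos <- as.integer(hotspots$pos)
  }
  annotations(pop_af = if (length(pop_paths)) pop_af else NULL,
              somatic_evidence = if (length(somatic_paths)) somatic else NULL,
              mask = mask, hotspots = hotspots)
}

#' Test positions for repetitive-region mask membership
#'
#' @param ann A `ctdna_annotations` object.
#' @param chrom,pos Parallel vectors of chromosome and 1-based position.
#' @return Logical vector: `TRUE` where the position falls in a masked
#'   interval.
#' @export
is_masked <- function(ann, chrom, pos) {
  stopifnot(is(ann, "ctdna_annotations"))
  if (length(ann$mask) == 0 || length(pos) == 0) {
    return(rep(FALSE, length(pos)))
  }
  query <- GenomicRanges::GRanges(
    seqnames = chrom, ranges = IRanges::IRanges(start = pos, width = 1)
  )
  # queries on chromosomes absent from the mask are legitimately unmasked
  suppressWarnings(GenomicRanges::countOverlaps(query, ann$mask) > 0)
}

# Max population AF across databases for each variant key; absent keys -> 0.
max_pop_af_lookup <- function(ann, keys) {
  if (nrow(ann$pop_af) == 0 || nrow(keys) == 0) {
    return(tibble(keys, max_pop_af = rep(0, nrow(keys)),
                  n_dbs_present = rep(0L, nrow(keys))))
  }
  agg <- ann$pop_af |>
    group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    summarise(max_pop_af = max(.data$af),
              n_dbs_present = dplyr::n_distinct(.data$db), .groups = "drop")
  out <- left_join(keys, agg, by = KEY_COLS)
  out$max_pop_af[is.na(out$max_pop_af)] <- 0
  out$n_dbs_present[is.na(out$n_dbs_present)] <- 0L
  out
}

# AF in one named database role (e.g. "ExAC"); absent keys -> 0.
db_af_lookup <- function(ann, keys, db) {
  sub <- filter(ann$pop_af, .data$db == .env$db)
  if (nrow(sub) == 0 || nrow(keys) == 0) {
    return(rep(0, nrow(keys)))
  }
  sub <- sub |>
    group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    summarise(af = max(.data$af), .groups = "drop")
  out <- left_join(keys, sub, by = KEY_COLS)
  ifelse(is.na(out$af), 0, out$af)
}

somatic_evidence_lookup <- function(ann, keys) {
  if (nrow(ann$somatic_evidence) == 0 || nrow(keys) == 0) {
    return(rep(0L, nrow(keys)))
  }
  agg <- ann$somatic_evidence |>
    group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    summarise(count = sum(.data$count), .groups = "drop")
  out <- left_join(keys, agg, by = KEY_COLS)
  ifelse(is.na(out$count), 0L, out$count)
}

in_hotspot_list <- function(ann, keys) {
  if (nrow(ann$hotspots) == 0 || nrow(keys) == 0) {
    return(rep(FALSE, nrow(keys)))
  }
  hk <- paste(ann$hotspots$chrom, ann$hotspots$pos, ann$hotspots$ref,
              ann$hotspots$alt, sep = ":")
  variant_key(keys) %in% hk
}
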