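# Post-call filtering of FFPE tumor-tissue variant calls down to the
# high-confidence somatic set that seeds each subject's tracking set.

FFPE_CRITERIA <- c("repetitive_region", "predicted_germline",
                   "pop_af_ge_1pct", "af_below_threshold")

#' Apply the four FFPE tumor-tissue post-call filters
#'
#' A tissue variant passes only if it (1) lies outside the repetitive-region
#' mask, (2) is classified putative-somatic by the germline model, (3) has
#' ExAC population frequency below 1%, and (4) has allele frequency
#' strictly above 5% — relaxed to strictly above 3% for hotspot-whitelist
#' variants. All four criteria are evaluated for every variant (no
#' short-circuiting), so `failed_criteria` is complete.
#'
#' @param variants Tissue variant table (rows with `sample_type` other than
#'   `"tissue"` are rejected).
#' @param annotations A `ctdna_annotations` bundle.
#' @param model A trained `germline_model`.
#' @param af_min,af_min_hotspot Strict lower AF thresholds for non-hotspot
#'   and hotspot variants.
#' @param exac_max Strict upper bound on the ExAC-role population frequency.
#' @param exac_db Name of the database playing the ExAC role in the
#'   annotation bundle.
#' @return The variant table with `passed` (logical) and `failed_criteria`
#'   (list column of character vectors, empty iff passed) appended.
#' @export
apply_ffpe_filters <- function(variants, annotations, model,
                               af_min = 0.05, af_min_hotspot = 0.03,
                               exac_max = 0.01, exac_db = "ExAC") {
  variants <- as_tibble(variants)
  if (nrow(variants) == 0) {
    return(mutate(variants, passed = logical(), failed_criteria = list()))
  }
  if (any(variants$sample_type != "tissue")) {
    abort("apply_ffpe_filters() expects tissue variants only")
  }
  classified <- classify_germline(variants, model, annotations)
  keys <- select(variants, dplyr::all_of(KEY_COLS))
  hotspot <- variants$is_hotspot | in_hotspot_list(annotations, keys)
  fail <- cbind(
    repetitive_region = is_masked(annotations, variants$chrom, variants$pos),
    predicted_germline = classified$germline_class == "predicted_germline",
    pop_af_ge_1pct = db_af_lookup(annotations, keys, exac_db) >= exac_max,
    af_below_threshold = !(variants$af > af_min |
                             (hotspot & variants$af > af_min_hotspot))
  )
  mutate(
    variants,
    passed = rowSums(fail) == 0,
    failed_criteria = map(seq_len(nrow(fail)),
                          function(i) FFPE_CRITERIA[fail[i, ]])
  )
}

#' Build a subject's tracking set from filter outcomes
#'
#' The tracking set is the deduplicated key set of tissue variants that
#' passed all four FFPE filters in the subject's baseline tissue sample;
#' these are the variants whose mean plasma allele frequency the Monte
#' Carlo detector tests against background. Synonymous variants are kept by
#' default (both synonymous and non-synonymous somatic variants are
#' tracked).
#'
#' @param outcomes Output of [apply_ffpe_filters()] for one subject's
#'   baseline tissue sample.
#' @param subject_id Subject identifier; defaults to the (single) value in
#'   `outcomes`.
#' @param include_synonymous Keep synonymous variants? Default `TRUE`.
#' @return A `tracking_set` tibble with columns `subject_id, chrom, pos,
#'   ref, alt`; [tracking_n()] gives its size. An empty set (n = 0) is
#'   legal; detection is then indeterminate.
#' @export
build_tracking_set <- function(outcomes, subject_id = NULL,
                               include_synonymous = TRUE) {
  outcomes <- as_tibble(outcomes)
  if (is.null(subject_id)) {
    subject_id <- if (nrow(outcomes)) unique(outcomes$subject_id)[1] else NA_character_
  }
  kept <- filter(outcomes, .data$passed)
  if (!include_synonymous) kept <- filter(kept, !.data$is_synonymous)
  out <- kept |>
    select(dplyr::all_of(KEY_COLS)) |>
    distinct() |>
    mutate(subject_id = subject_id, .before = 1)
  class(out) <- c("tracking_set", class(out))
  out
}

#' Number of tracked variants in a tracking set
#'
#' @param tracking A `tracking_set`.
#' @return Integer count of tracked variant keys.
#' @export
tracking_n <- function(tracking) nrow(tracking)

#' Flatten filter outcomes for TSV output
#'
#' Collapses the `failed_criteria` list column to a comma-separated string
#' so outcomes can be written with [readr::write_tsv()].
#'
#' @param outcomes Output of [apply_ffpe_filters()].
#' @return The same tibble with `failed_criteria` as character.
#' @export
flatten_filter_outcomes <- function(outcomes) {
  mutate(as_tibble(outcomes),
         failed_criteria = map_chr(.data$failed_criteria, paste,
                                   collapse = ","))
}
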