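# Shared fixtures: a hand-weighted germline model with known decision
# geometry, a small annotation bundle, and a variant-row builder.

make_variants <- function(n = 1, subject_id = "S1", sample_id = "S1_P1",
                          sample_type = "plasma", chrom = "chr1",
                          pos = seq(1001L, by = 1000L, length.out = n),
                          ref = "A", alt = "T", depth = 1000L,
                          af = 0.02, gene = "", cds_change = "",
                          is_hotspot = FALSE, is_synonymous = FALSE) {
  alt_count <- as.integer(round(af * depth))
  tibble::tibble(
    subject_id = subject_id, sample_id = sample_id,
    sample_type = sample_type, chrom = chrom, pos = as.integer(pos),
    ref = ref, alt = alt, depth = as.integer(depth),
    alt_count = alt_count, af = alt_count / depth, gene = gene,
    cds_change = cds_change, is_hotspot = is_hotspot,
    is_synonymous = is_synonymous
  )
}

# Logistic germline model with fixed, interpretable weights:
# eta = -1 + 30 * max_pop_af - 10 * af_distance_to_het.
# Germline iff eta >= 0: driven by database presence and closeness to 0.5.
toy_germline_model <- function() {
  w <- c("(Intercept)" = -1, max_pop_af = 30, n_dbs_present = 0,
         somatic_evidence_count = 0, observed_af = 0,
         af_distance_to_het = -10, af_distance_to_hom = 0)
  structure(list(weights = w, threshold = 0.5, seed = 1L, n_train = 0L,
                 training_accuracy = NA_real_),
            class = "germline_model")
}

toy_annotations <- function(pop_af = NULL, somatic_evidence = NULL,
                            mask_df = NULL, hotspots = NULL) {
  mask <- NULL
  if (!is.null(mask_df)) {
    mask <- GenomicRanges::GRanges(
      seqnames = mask_df$chrom,
      ranges = IRanges::IRanges(start = mask_df$start, end = mask_df$end)
    )
  }
  annotations(pop_af = pop_af, somatic_evidence = somatic_evidence,
              mask = mask, hotspots = hotspots)
}

# The four FFPE post-call criteria, exercised over every failure
# combination with the hand-weighted toy model:
#   repetitive_region  <- position inside the mask
#   predicted_germline <- dbSNP 0.40 (drives the logistic score germline)
#   pop_af_ge_1pct     <- ExAC 0.02
#   af_below_threshold <- af 0.04 instead of 0.20 (non-hotspot)
boundary_fixture <- function() {
  combos <- expand.grid(masked = c(FALSE, TRUE), germ = c(FALSE, TRUE),
                        exac = c(FALSE, TRUE), lowaf = c(FALSE, TRUE))
  pos <- seq(10001L, by = 1000L, length.out = nrow(combos))
  v <- make_variants(n = nrow(combos), sample_type = "tissue", pos = pos,
                     af = ifelse(combos$lowaf, 0.04, 0.20))
  pop <- dplyr::bind_rows(
    tibble::tibble(chrom = "chr1", pos = pos[combos$germ], ref = "A",
                   alt = "T", db = "dbSNP", af = 0.40),
    tibble::tibble(chrom = "chr1", pos = pos[combos$exac], ref = "A",
                   alt = "T", db = "ExAC", af = 0.02)
  )
  mask_df <- data.frame(chrom = "chr1", start = pos[combos$masked],
                        end = pos[combos$masked])
  ann <- toy_annotations(pop_af = pop, mask_df = mask_df)
  list(variants = v, ann = ann, combos = combos)
}

small_sim_config <- function(...) {
  args <- utils::modifyList(
    list(n_subjects = 10, panel_positions = 600, seed = 20260925),
    list(...)
  )
  do.call(cohort_sim_config, args)
}
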