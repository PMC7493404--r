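# Ground-truth-labelled synthetic cohort generator. Emulates the study's
# data shape: a 71-subject advanced-NSCLC cohort with baseline FFPE tumor
# tissue and 2-18 longitudinal plasma draws per subject on a targeted panel,
# overdispersed background sequencing error, germline variants shared
# between tissue and plasma, tumor-fraction trajectories tied to treatment
# response, and progression-free survival linked to ctDNA-bearing status.

POP_DBS <- c("ExAC", "dbSNP", "1000G")
GENE_POOL <- c("TP53", "KRAS", "KEAP1", "BRAF", "STK11", "ERBB2", "EGFR",
               "NPAP1", "LRRTM4", "CSMD3", "MET", "ALK", "ROS1", "PIK3CA",
               "PTEN", "NF1", "RB1", "SMARCA4", "ARID1A", "ATM")

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the study conditions: 71 subjects, 2-18 plasma samples
#' per subject with median 6, mean de-duplicated depth 2779 (plasma) and
#' 1116 (tissue), a mean of six somatic variants per tissue sample, tissue
#' allele frequencies spanning 3.29-86.82%, a mean background error rate of
#' 1e-4 with beta-binomial overdispersion, and a true hazard ratio of 2.3
#' for ctDNA-bearing versus ctDNA-free subjects with a ctDNA-free median
#' PFS of 271 days (8.9 months).
#'
#' @param n_subjects Number of subjects.
#' @param samples_per_subject Integer pair: min and max plasma samples per
#'   subject.
#' @param samples_nb_mu,samples_nb_size Negative-binomial parameters for the
#'   number of plasma samples beyond the minimum (truncated at the maximum);
#'   defaults give a median of about 6 samples.
#' @param panel_positions Number of assayed panel positions.
#' @param mean_error Mean per-position background error rate (alternate
#'   allele fraction).
#' @param error_concentration Beta concentration (shape1 + shape2) of the
#'   per-position error-rate distribution; smaller values give more
#'   overdispersion.
#' @param depth_plasma,depth_tissue Mean de-duplicated depths.
#' @param depth_cv Lognormal coefficient of variation of per-sample depth.
#' @param n_somatic_lambda Poisson mean of somatic variants per subject
#'   beyond the first (count = 1 + Poisson, so mean 6 at the default 5).
#' @param germline_per_subject Expected germline variants per subject.
#' @param germline_hom_prob Probability a germline variant is homozygous
#'   (allele frequency near 1 rather than 0.5).
#' @param germline_db_miss_rate Fraction of germline variants absent from
#'   every population database.
#' @param somatic_db_rate Fraction of somatic variants present in a
#'   population database at very low frequency.
#' @param tissue_af_range,tissue_af_shape Range and Beta shape of tissue
#'   somatic allele frequencies.
#' @param clonal_shape Beta shape of per-variant clonal fractions shared by
#'   tissue and plasma.
#' @param tf_baseline_meanlog,tf_baseline_sdlog Lognormal parameters of the
#'   baseline tumor fraction.
#' @param decline_per_cycle,growth_per_cycle Multiplicative tumor-fraction
#'   change per treatment cycle during response and after resistance onset.
#' @param cycle_days Treatment cycle length in days.
#' @param clearance_prob Probability a subject's ctDNA clears completely at
#'   treatment start (the ctDNA-negative stratum).
#' @param regrow_floor Tumor fraction from which regrowth restarts after
#'   clearance.
#' @param radiographic_delay_range Days by which resistance onset precedes
#'   radiographic progression (uniform range).
#' @param treatment_start_day Day therapy begins (diagnosis is day 0).
#' @param imaging_interval_days Days between CT assessments.
#' @param hazard_ratio_true True hazard ratio for ctDNA-bearing status at
#'   the first post-treatment draw.
#' @param median_pfs_negative_days Median PFS of the ctDNA-free stratum.
#' @param censor_day_range Uniform range of administrative censoring days.
#' @param hotspot_fraction Fraction of panel sites designated hotspot sites.
#' @param snp_site_fraction Fraction of panel sites that are polymorphism
#'   (SNP) sites from which germline variants are drawn; disjoint from
#'   hotspot sites.
#' @param somatic_hotspot_prob Probability a somatic variant falls on a
#'   hotspot site.
#' @param synonymous_prob Probability a somatic variant is synonymous.
#' @param mask_fraction Fraction of panel sites inside the repetitive mask.
#' @param seed Master seed; all stages derive their seeds from it.
#' @return A validated list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_subjects = 71,
                              samples_per_subject = c(2L, 18L),
                              samples_nb_mu = 4.4, samples_nb_size = 2.5,
                              panel_positions = 2000,
                              mean_error = 1e-4,
                              error_concentration = 1000,
                              depth_plasma = 2779, depth_tissue = 1116,
                              depth_cv = 0.1,
                              n_somatic_lambda = 5,
                              germline_per_subject = 15,
                              germline_hom_prob = 0.12,
                              germline_db_miss_rate = 0.08,
                              somatic_db_rate = 0.05,
                              tissue_af_range = c(0.0329, 0.8682),
                              tissue_af_shape = c(1.2, 4.8),
                              clonal_shape = c(5, 1.5),
                              tf_baseline_meanlog = log(0.02),
                              tf_baseline_sdlog = 0.7,
                              decline_per_cycle = 0.65,
                              growth_per_cycle = 1.5,
                              cycle_days = 21,
                              clearance_prob = 0.35,
                              regrow_floor = 0.005,
                              radiographic_delay_range = c(60, 120),
                              treatment_start_day = 7,
                              imaging_interval_days = 42,
                              hazard_ratio_true = 2.3,
                              median_pfs_negative_days = 271,
                              censor_day_range = c(60, 500),
                              hotspot_fraction = 0.02,
                              snp_site_fraction = 0.25,
                              somatic_hotspot_prob = 0.15,
                              synonymous_prob = 0.25,
                              mask_fraction = 0.05,
                              seed = 20200915) {
  cfg <- as.list(environment())
  probs <- c(cfg$germline_hom_prob, cfg$germline_db_miss_rate,
             cfg$somatic_db_rate, cfg$clearance_prob,
             cfg$somatic_hotspot_prob, cfg$synonymous_prob,
             cfg$hotspot_fraction, cfg$snp_site_fraction, cfg$mask_fraction)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (cfg$hazard_ratio_true <= 0) abort("hazard_ratio_true must be positive")
  for (rng in list(cfg$samples_per_subject, cfg$tissue_af_range,
                   cfg$radiographic_delay_range, cfg$censor_day_range)) {
    if (length(rng) != 2 || rng[1] > rng[2]) abort("ranges must be ordered pairs")
  }
  if (cfg$mean_error <= 0 || cfg$mean_error >= 1) {
    abort("mean_error must lie in (0, 1)")
  }
  structure(cfg, class = "cohort_sim_config")
}

error_beta_shapes <- function(config) {
  a <- config$mean_error * config$error_concentration
  b <- (1 - config$mean_error) * config$error_concentration
  c(a, b)
}

#' Draw zero-truncated background-alteration allele frequencies
#'
#' Background alterations are positions with at least one alternate read,
#' mostly sequencing error. Per position the error rate is Beta-distributed
#' (mean `mean_error`, concentration `error_concentration`) and the
#' alternate-read count is binomial in `depth`; counts of zero are not
#' alterations and are discarded, so the returned allele frequencies follow
#' the zero-truncated beta-binomial divided by depth.
#'
#' @param n Number of alteration AFs to draw.
#' @param config A [cohort_sim_config()].
#' @param depth Per-position de-duplicated depth.
#' @return Numeric vector of length `n` with values in (0, 1].
#' @export
sample_background_af <- function(n, config, depth = config$depth_plasma) {
  shapes <- error_beta_shapes(config)
  # P(count >= 1) under the beta-binomial mixture, for batch sizing.
  p_emit <- max(1e-6, 1 - exp(lbeta(shapes[1], depth + shapes[2]) -
                                lbeta(shapes[1], shapes[2])))
  out <- numeric(0)
  while (length(out) < n) {
    m <- min(ceiling((n - length(out)) / p_emit * 1.2) + 100, 5e6)
    e <- rbeta(m, shapes[1], shapes[2])
    k <- rbinom(m, depth, e)
    out <- c(out, k[k > 0] / depth)
  }
  out[seq_len(n)]
}

# Exact pmf of the beta-binomial background count model, P(K = k) for
# k = 0..depth. Used by tests as the enumeration oracle for truncated means.
background_count_pmf <- function(config, depth) {
  shapes <- error_beta_shapes(config)
  k <- 0:depth
  exp(lchoose(depth, k) + lbeta(k + shapes[1], depth - k + shapes[2]) -
        lbeta(shapes[1], shapes[2]))
}

#' Simulate background allele alterations at panel positions
#'
#' @param config A [cohort_sim_config()].
#' @param n_positions Number of panel positions to simulate.
#' @param depth Per-position depth.
#' @param seed Optional seed for a deterministic draw.
#' @return A variant-table tibble with one row per position showing at least
#'   one alternate read; positions with zero alternate reads are omitted.
#' @export
simulate_background <- function(config, n_positions, depth, seed = NULL) {
  stopifnot(depth > 0)
  with_seed_if(seed, {
    shapes <- error_beta_shapes(config)
    e <- rbeta(n_positions, shapes[1], shapes[2])
    k <- rbinom(n_positions, depth, e)
    keep <- which(k > 0)
    ref <- sample(c("A", "C", "G", "T"), n_positions, replace = TRUE)
    alt <- vapply(ref[keep], function(r) {
      sample(setdiff(c("A", "C", "G", "T"), r), 1)
    }, character(1), USE.NAMES = FALSE)
    tibble(
      subject_id = "BG", sample_id = "BG", sample_type = "plasma",
      chrom = "chr1", pos = keep * 1000L, ref = ref[keep], alt = alt,
      depth = as.integer(depth), alt_count = as.integer(k[keep]),
      af = k[keep] / depth, gene = "", cds_change = "",
      is_hotspot = FALSE, is_synonymous = FALSE
    )
  })
}

# Fixed assay panel shared by the whole cohort: site coordinates, alleles,
# gene labels, hotspot designation and the repetitive mask.
simulate_panel <- function(config) {
  with_seed_if(derive_seed(config$seed, "panel"), {
    p <- config$panel_positions
    chroms <- paste0("chr", c(1, 2, 3, 17))
    chrom <- rep(chroms, length.out = 4)[
      rep(seq_along(chroms), each = ceiling(p / 4))][seq_len(p)]
    pos <- integer(p)
    for (cc in chroms) {
      idx <- which(chrom == cc)
      pos[idx] <- sort(sample.int(2e7, length(idx))) + 10000L
    }
    ref <- sample(c("A", "C", "G", "T"), p, replace = TRUE)
    alt <- vapply(ref, function(r) {
      sample(setdiff(c("A", "C", "G", "T"), r), 1)
    }, character(1), USE.NAMES = FALSE)
    gene <- sample(GENE_POOL, p, replace = TRUE,
                   prob = seq(2, 1, length.out = length(GENE_POOL)))
    is_hotspot_site <- runif(p) < config$hotspot_fraction
    masked <- runif(p) < config$mask_fraction
    # fixed polymorphism sites: common germline variation lives at a stable
    # subset of panel positions, disjoint from hotspot (somatic) sites
    is_snp_site <- !is_hotspot_site & runif(p) < config$snp_site_fraction
    tibble(chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
           is_hotspot_site = is_hotspot_site, is_snp_site = is_snp_site,
           masked = masked)
  })
}

panel_mask_granges <- function(panel) {
  masked <- panel[panel$masked, ]
  if (nrow(masked) == 0) return(GenomicRanges::GRanges())
  GenomicRanges::reduce(GenomicRanges::GRanges(
    seqnames = masked$chrom,
    ranges = IRanges::IRanges(start = masked$pos, width = 1)
  ))
}

# Piecewise-exponential tumor-fraction trajectory: decline on therapy
# (or immediate clearance), regrowth from resistance onset day r_day.
tumor_fraction_at <- function(day, tf0, cleared, r_day, config) {
  t0 <- config$treatment_start_day
  cyc <- config$cycle_days
  tf <- ifelse(day <= t0, tf0,
               if (cleared) 0 else tf0 * config$decline_per_cycle^((day - t0) / cyc))
  if (!is.na(r_day) && day > r_day) {
    base <- if (cleared) {
      config$regrow_floor
    } else {
      max(tf0 * config$decline_per_cycle^((r_day - t0) / cyc),
          config$regrow_floor)
    }
    tf <- base * config$growth_per_cycle^((day - r_day) / cyc)
  }
  min(tf, 0.9)
}

rand_depth <- function(mean_depth, cv) {
  max(50L, as.integer(round(mean_depth * exp(rnorm(1, 0, cv)))))
}

#' Simulate one subject's tissue, plasma and clinical data
#'
#' Draws the subject's somatic and germline variants, a tumor-fraction
#' trajectory tied to response arm, longitudinal plasma samples with
#' binomial sampling noise plus beta-binomial background error, RECIST
#' assessment days, and a PFS outcome whose hazard is multiplied by
#' `hazard_ratio_true` when the first post-treatment draw is ctDNA-bearing.
#'
#' @param config A [cohort_sim_config()].
#' @param subject_id Subject identifier.
#' @param panel Optional pre-built panel (from the cohort generator); built
#'   from the config seed when omitted.
#' @param seed Seed for this subject's draws.
#' @return A list with elements `tissue`, `plasma` (variant tables),
#'   `manifest`, `recist`, `germline_truth`, `somatic_truth`,
#'   `sample_truth`, `subject_truth`.
#' @export
simulate_subject <- function(config, subject_id = "S001", panel = NULL,
                             seed = derive_seed(config$seed, subject_id)) {
  if (is.null(panel)) panel <- simulate_panel(config)
  with_seed_if(seed, simulate_subject_impl(config, subject_id, panel))
}

simulate_subject_impl <- function(config, subject_id, panel) {
  p <- nrow(panel)
  bases <- c("A", "C", "G", "T")
  shapes <- error_beta_shapes(config)

  ## --- survival + trajectory scaffolding -------------------------------
  cleared <- runif(1) < config$clearance_prob
  tf0 <- min(exp(rnorm(1, config$tf_baseline_meanlog, config$tf_baseline_sdlog)),
             0.5)
  bearing_first <- !cleared
  rate0 <- log(2) / config$median_pfs_negative_days
  rate <- rate0 * ifelse(bearing_first, config$hazard_ratio_true, 1)
  t_event <- rexp(1, rate)
  c_cens <- runif(1, config$censor_day_range[1], config$censor_day_range[2])
  event <- t_event <= c_cens
  time_days <- max(1L, as.integer(round(min(t_event, c_cens))))
  r_day <- NA_real_
  if (event) {
    delay <- runif(1, config$radiographic_delay_range[1],
                   config$radiographic_delay_range[2])
    r_day <- max(config$treatment_start_day + 14, time_days - delay)
  }
  arm <- if (event) "progressor" else "responder"

  ## --- variant content -------------------------------------------------
  n_som <- 1L + rpois(1, config$n_somatic_lambda)
  n_germ <- max(1L, rpois(1, config$germline_per_subject))
  hot_sites <- which(panel$is_hotspot_site)
  open_sites <- which(!panel$is_hotspot_site & !panel$is_snp_site &
                        !panel$masked)
  som_hot <- runif(n_som) < config$somatic_hotspot_prob
  som_idx <- integer(n_som)
  som_idx[som_hot] <- sample(hot_sites, sum(som_hot))
  som_idx[!som_hot] <- sample(open_sites, sum(!som_hot))
  # germline polymorphisms live at the panel's SNP sites, never on the
  # curated somatic hotspot list
  germ_idx <- sample(which(panel$is_snp_site), n_germ)

  lo <- config$tissue_af_range[1] + 0.002
  hi <- config$tissue_af_range[2] - 0.002
  tissue_af <- lo + (hi - lo) * rbeta(n_som, config$tissue_af_shape[1],
                                      config$tissue_af_shape[2])
  clonal <- rbeta(n_som, config$clonal_shape[1], config$clonal_shape[2])
  synonymous <- runif(n_som) < config$synonymous_prob
  germ_hom <- runif(n_germ) < config$germline_hom_prob
  germ_af <- ifelse(germ_hom, pmin(rnorm(n_germ, 0.97, 0.01), 1),
                    pmin(pmax(rnorm(n_germ, 0.5, 0.02), 0.05), 0.95))

  site_row <- function(idx) panel[idx, , drop = FALSE]
  cds <- function(site) paste0("c.", site$pos %% 10000, site$ref, ">", site$alt)

  ## --- sampling schedule ----------------------------------------------
  extra <- min(rnbinom(1, size = config$samples_nb_size,
                       mu = config$samples_nb_mu),
               config$samples_per_subject[2] - config$samples_per_subject[1])
  n_samp <- config$samples_per_subject[1] + extra
  gaps <- round(runif(n_samp - 1, 18, 25))
  days <- as.integer(c(0, cumsum(gaps)))
  keep <- days <= time_days + 30
  keep[seq_len(min(2, n_samp))] <- TRUE
  days <- days[keep]
  n_samp <- length(days)

  ## --- tissue sample ---------------------------------------------------
  tissue_depth <- rand_depth(config$depth_tissue, config$depth_cv)
  tissue_mass <- min(max(exp(rnorm(1, log(50), 0.5)), 9), 200)
  som_sites <- site_row(som_idx)
  tissue_alt <- pmax(1L, as.integer(round(tissue_af * tissue_depth)))
  germ_sites <- site_row(germ_idx)
  germ_alt_t <- rbinom(n_germ, tissue_depth, germ_af)

  mk_rows <- function(sample_id, sample_type, sites, depth, alt_count,
                      is_syn, gene = sites$gene) {
    tibble(
      subject_id = subject_id, sample_id = sample_id,
      sample_type = sample_type, chrom = sites$chrom, pos = sites$pos,
      ref = sites$ref, alt = sites$alt, depth = as.integer(depth),
      alt_count = as.integer(alt_count), af = alt_count / depth,
      gene = gene, cds_change = cds(sites),
      is_hotspot = sites$is_hotspot_site, is_synonymous = is_syn
    )
  }

  bg_rows <- function(sample_id, sample_type, depth, exclude_idx) {
    idx <- setdiff(seq_len(p), exclude_idx)
    e <- rbeta(length(idx), shapes[1], shapes[2])
    k <- rbinom(length(idx), depth, e)
    hit <- idx[k > 0]
    if (length(hit) == 0) return(empty_variant_table())
    mk_rows(sample_id, sample_type, site_row(hit), depth,
            k[k > 0], FALSE)
  }

  tissue_sample_id <- paste0(subject_id, "_T0")
  tissue <- bind_rows(
    mk_rows(tissue_sample_id, "tissue", som_sites, tissue_depth, tissue_alt,
            synonymous),
    mk_rows(tissue_sample_id, "tissue", germ_sites, tissue_depth,
            germ_alt_t, FALSE),
    bg_rows(tissue_sample_id, "tissue", tissue_depth, c(som_idx, germ_idx))
  ) |> filter(.data$alt_count > 0)

  ## --- plasma samples --------------------------------------------------
  plasma_list <- vector("list", n_samp)
  sample_truth <- vector("list", n_samp)
  manifest <- vector("list", n_samp + 1)
  manifest[[1]] <- tibble(
    subject_id = subject_id, sample_id = tissue_sample_id,
    sample_type = "tissue", collection_day = 0L,
    input_mass_ng = round(tissue_mass, 1), plasma_volume_ml = NA_real_,
    treatment_start_day = as.integer(config$treatment_start_day)
  )
  for (i in seq_len(n_samp)) {
    d <- days[i]
    sid <- sprintf("%s_P%02d", subject_id, i)
    depth_i <- rand_depth(config$depth_plasma, config$depth_cv)
    mass_i <- min(max(exp(rnorm(1, log(20), 0.35)), 10), 50)
    tf_d <- tumor_fraction_at(d, tf0, cleared, r_day, config)
    som_p <- pmin(0.5 * clonal * tf_d, 0.95)
    som_alt <- rbinom(n_som, depth_i, som_p)
    germ_alt <- rbinom(n_germ, depth_i, germ_af)
    plasma_list[[i]] <- bind_rows(
      mk_rows(sid, "plasma", som_sites, depth_i, som_alt, synonymous),
      mk_rows(sid, "plasma", germ_sites, depth_i, germ_alt, FALSE),
      bg_rows(sid, "plasma", depth_i, c(som_idx, germ_idx))
    ) |> filter(.data$alt_count > 0)
    sample_truth[[i]] <- tibble(
      subject_id = subject_id, sample_id = sid, collection_day = d,
      true_tumor_fraction = tf_d
    )
    manifest[[i + 1]] <- tibble(
      subject_id = subject_id, sample_id = sid, sample_type = "plasma",
      collection_day = d, input_mass_ng = round(mass_i, 1),
      plasma_volume_ml = 4, treatment_start_day =
        as.integer(config$treatment_start_day)
    )
  }

  ## --- RECIST schedule -------------------------------------------------
  imaging_days <- seq(0L, time_days, by = config$imaging_interval_days)
  imaging_days <- unique(sort(c(imaging_days[imaging_days < time_days],
                                time_days)))
  response <- vapply(imaging_days, function(d) {
    if (d == time_days && event) return("PD")
    if (d == 0) return("SD")
    tf_d <- tumor_fraction_at(d, tf0, cleared, r_day, config)
    if (tf_d < tf0 * 0.7) "PR" else "SD"
  }, character(1))
  recist <- tibble(subject_id = subject_id, day = imaging_days,
                   response = response)

  list(
    tissue = tissue,
    plasma = list_rbind(plasma_list),
    manifest = list_rbind(manifest),
    recist = recist,
    germline_truth = mutate(select(germ_sites, dplyr::all_of(KEY_COLS)),
                            subject_id = subject_id, label = "germline",
                            true_af = germ_af),
    somatic_truth = mutate(select(som_sites, dplyr::all_of(KEY_COLS)),
                           subject_id = subject_id, label = "somatic",
                           tissue_af = tissue_af, clonal_fraction = clonal),
    sample_truth = list_rbind(sample_truth),
    subject_truth = tibble(
      subject_id = subject_id, arm = arm, cleared = cleared,
      baseline_tumor_fraction = tf0, bearing_first = bearing_first,
      mp_true_day = r_day, pfs_time = time_days, pfs_event = event,
      last_imaging_day = max(imaging_days),
      # clinical covariates for the adjustment-factor screen; drawn with
      # the cohort's marginal frequencies, independent of outcome
      age = round(rnorm(1, 62.5, 10)),
      sex = sample(c("male", "female"), 1, prob = c(0.63, 0.37)),
      ecog = sample(c("0", "1_or_2"), 1, prob = c(0.31, 0.69)),
      smoking = sample(c("current", "quit", "never"), 1,
                       prob = c(0.59, 0.26, 0.15)),
      stage = sample(c("IV", "IIIB", "IIIA"), 1,
                     prob = c(0.831, 0.113, 0.056))
    )
  )
}

# Cohort-level annotation tables derived from ground truth: germline
# variants carry population AFs (unless db-missed), a small fraction of
# somatic variants appear at trace population frequency, hotspot sites
# carry somatic-evidence counts.
build_cohort_annotations <- function(config, panel, germline_truth,
                                     somatic_truth) {
  with_seed_if(derive_seed(config$seed, "annotations"), {
    germ <- distinct(germline_truth, .data$chrom, .data$pos, .data$ref,
                     .data$alt)
    pop_rows <- list()
    if (nrow(germ) > 0) {
      missed <- runif(nrow(germ)) < config$germline_db_miss_rate
      present <- germ[!missed, , drop = FALSE]
      if (nrow(present) > 0) {
        base_af <- runif(nrow(present), 0.01, 0.5)
        n_dbs <- sample(1:3, nrow(present), replace = TRUE,
                        prob = c(0.2, 0.3, 0.5))
        pop_rows <- pmap(list(seq_len(nrow(present)), base_af, n_dbs),
                         function(i, afv, nd) {
          dbs <- sample(POP_DBS, nd)
          tibble(chrom = present$chrom[i], pos = present$pos[i],
                 ref = present$ref[i], alt = present$alt[i], db = dbs,
                 af = pmin(pmax(afv * exp(rnorm(nd, 0, 0.1)), 1e-4), 0.99))
        })
      }
    }
    som <- distinct(somatic_truth, .data$chrom, .data$pos, .data$ref,
                    .data$alt)
    som_in_db <- som[runif(nrow(som)) < config$somatic_db_rate, , drop = FALSE]
    if (nrow(som_in_db) > 0) {
      pop_rows <- c(pop_rows, list(tibble(
        chrom = som_in_db$chrom, pos = som_in_db$pos, ref = som_in_db$ref,
        alt = som_in_db$alt, db = sample(POP_DBS, nrow(som_in_db),
                                         replace = TRUE),
        af = runif(nrow(som_in_db), 1e-5, 5e-3)
      )))
    }
    pop_af <- if (length(pop_rows)) list_rbind(pop_rows) else NULL

    hot <- panel[panel$is_hotspot_site, , drop = FALSE]
    ev_rows <- list()
    if (nrow(hot) > 0) {
      ev_rows <- c(ev_rows, list(tibble(
        chrom = hot$chrom, pos = hot$pos, ref = hot$ref, alt = hot$alt,
        count = as.integer(5 + rpois(nrow(hot), 50))
      )))
    }
    if (nrow(som) > 0) {
      seen <- som[runif(nrow(som)) < 0.3, , drop = FALSE]
      if (nrow(seen) > 0) {
        ev_rows <- c(ev_rows, list(tibble(
          chrom = seen$chrom, pos = seen$pos, ref = seen$ref,
          alt = seen$alt, count = as.integer(1 + rpois(nrow(seen), 3))
        )))
      }
    }
    somatic_ev <- if (length(ev_rows)) list_rbind(ev_rows) else NULL
    hotspots <- select(hot, dplyr::all_of(KEY_COLS))

    annotations(pop_af = pop_af, somatic_evidence = somatic_ev,
                mask = panel_mask_granges(panel), hotspots = hotspots)
  })
}

#' Simulate a complete labelled cohort
#'
#' Generates the full bundle the pipeline consumes: tissue and plasma
#' variant tables, sample manifest, annotation tables (population AFs,
#' somatic evidence, repetitive mask, hotspot whitelist), RECIST schedules,
#' and ground-truth labels. Identical `(config, seed)` give a bit-identical
#' bundle. When `dir` is given the bundle is also written to disk in the
#' package's TSV/BED dialects and can be re-read with [read_cohort()].
#'
#' @param config A [cohort_sim_config()].
#' @param dir Optional output directory.
#' @param overwrite Overwrite a non-empty `dir`? Default `FALSE`.
#' @return A list of class `ctdna_cohort` with elements `variants`,
#'   `manifest`, `recist`, `annotations`, `panel`, `ground_truth` (list of
#'   `variant_labels`, `sample_truth`, `subject_truth`) and `config`.
#' @export
simulate_cohort <- function(config = cohort_sim_config(), dir = NULL,
                            overwrite = FALSE) {
  panel <- simulate_panel(config)
  ids <- sprintf("S%03d", seq_len(config$n_subjects))
  subjects <- map(ids, function(id) {
    simulate_subject(config, subject_id = id, panel = panel)
  })
  empty_truth <- tibble(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        subject_id = character(), label = character())
  pull_bind <- function(field, empty = tibble()) {
    out <- list_rbind(map(subjects, field))
    if (is.null(out) || nrow(out) == 0) empty else out
  }
  germline_truth <- pull_bind("germline_truth", empty_truth)
  somatic_truth <- pull_bind("somatic_truth", empty_truth)
  ann <- build_cohort_annotations(config, panel, germline_truth,
                                  somatic_truth)
  variant_labels <- bind_rows(
    select(germline_truth, "subject_id", dplyr::all_of(KEY_COLS), "label"),
    select(somatic_truth, "subject_id", dplyr::all_of(KEY_COLS), "label")
  )
  empty_manifest <- tibble(subject_id = character(), sample_id = character(),
                           sample_type = character(),
                           collection_day = integer(),
                           input_mass_ng = double(),
                           plasma_volume_ml = double(),
                           treatment_start_day = integer())
  cohort <- structure(list(
    variants = bind_rows(empty_variant_table(), pull_bind("tissue"),
                         pull_bind("plasma")),
    manifest = pull_bind("manifest", empty_manifest),
    recist = pull_bind("recist", tibble(subject_id = character(),
                                        day = integer(),
                                        response = character())),
    annotations = ann,
    panel = panel,
    ground_truth = list(
      variant_labels = variant_labels,
      sample_truth = pull_bind("sample_truth"),
      subject_truth = pull_bind("subject_truth")
    ),
    config = config
  ), class = "ctdna_cohort")
  if (!is.null(dir)) write_cohort(cohort, dir, overwrite = overwrite)
  cohort
}

#' @export
print.ctdna_cohort <- function(x, ...) {
  cat("<ctdna_cohort>", x$config$n_subjects, "subjects,",
      nrow(x$manifest), "samples,", nrow(x$variants), "variant rows\n")
  invisible(x)
}

#' Write a simulated cohort bundle to disk
#'
#' @param cohort A `ctdna_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @param overwrite Overwrite a non-empty directory?
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite) {
    abort(sprintf("output directory %s is not empty (use overwrite = TRUE)",
                  dir))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_variant_table(cohort$variants, file.path(dir, "variants.tsv"))
  write_manifest(cohort$manifest, file.path(dir, "manifest.tsv"))
  readr::write_tsv(cohort$recist, file.path(dir, "recist.tsv"),
                   progress = FALSE)
  ann <- cohort$annotations
  for (db in unique(ann$pop_af$db)) {
    readr::write_tsv(select(filter(ann$pop_af, .data$db == .env$db),
                            -"db"),
                     file.path(dir, paste0("pop_", db, ".tsv")),
                     progress = FALSE)
  }
  readr::write_tsv(ann$somatic_evidence,
                   file.path(dir, "somatic_evidence.tsv"), progress = FALSE)
  readr::write_tsv(ann$hotspots, file.path(dir, "hotspots.tsv"),
                   progress = FALSE)
  mask <- ann$mask
  bed <- if (length(mask) == 0) {
    tibble(chrom = character(), start = integer(), end = integer())
  } else {
    tibble(chrom = as.character(GenomicRanges::seqnames(mask)),
           start = GenomicRanges::start(mask) - 1L,
           end = GenomicRanges::end(mask))
  }
  readr::write_tsv(bed, file.path(dir, "mask.bed"), col_names = FALSE,
                   progress = FALSE)
  gt <- cohort$ground_truth
  readr::write_tsv(gt$variant_labels,
                   file.path(dir, "ground_truth_variants.tsv"),
                   progress = FALSE)
  readr::write_tsv(gt$sample_truth,
                   file.path(dir, "ground_truth_samples.tsv"),
                   progress = FALSE)
  readr::write_tsv(gt$subject_truth,
                   file.path(dir, "ground_truth_subjects.tsv"),
                   progress = FALSE)
  yaml::write_yaml(unclass(cohort$config), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a cohort bundle written by [write_cohort()]
#'
#' @param dir Directory containing the bundle.
#' @return A `ctdna_cohort` list (without the panel, which is not part of
#'   the on-disk interchange).
#' @export
read_cohort <- function(dir) {
  pop_files <- list.files(dir, pattern = "^pop_.*\\.tsv$", full.names = TRUE)
  names(pop_files) <- sub("^pop_(.*)\\.tsv$", "\\1", basename(pop_files))
  ann <- load_annotations(
    pop_paths = pop_files,
    somatic_paths = file.path(dir, "somatic_evidence.tsv"),
    mask_bed = file.path(dir, "mask.bed"),
    hotspot_path = file.path(dir, "hotspots.tsv")
  )
  read_gt <- function(f) {
    readr::read_tsv(file.path(dir, f), show_col_types = FALSE,
                    progress = FALSE)
  }
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  structure(list(
    variants = read_variant_table(file.path(dir, "variants.tsv"), "tsv"),
    manifest = read_manifest(file.path(dir, "manifest.tsv")),
    recist = read_gt("recist.tsv"),
    annotations = ann,
    panel = NULL,
    ground_truth = list(
      variant_labels = read_gt("ground_truth_variants.tsv"),
      sample_truth = read_gt("ground_truth_samples.tsv"),
      subject_truth = read_gt("ground_truth_subjects.tsv")
    ),
    config = do.call(cohort_sim_config, cfg[names(cfg) %in%
                                              names(formals(cohort_sim_config))])
  ), class = "ctdna_cohort")
}

#' Simulate survival records directly from the cohort's survival model
#'
#' A fast path that draws only the survival component of the generator:
#' ctDNA-bearing status at the first post-treatment draw (Bernoulli with
#' probability `1 - clearance_prob`), an exponential PFS time whose hazard
#' is multiplied by `hazard_ratio_true` for bearing subjects, and uniform
#' administrative censoring. Used for Cox/log-rank calibration and coverage
#' experiments where the sequencing layer is irrelevant.
#'
#' @param config A [cohort_sim_config()].
#' @param seed Seed.
#' @return A tibble with `subject_id`, `time_days`, `event`, `group`
#'   (`ctDNA_positive` / `ctDNA_negative`).
#' @export
simulate_survival_records <- function(config = cohort_sim_config(),
                                      seed = config$seed) {
  with_seed_if(seed, {
    n <- config$n_subjects
    bearing <- runif(n) >= config$clearance_prob
    rate0 <- log(2) / config$median_pfs_negative_days
    t_event <- rexp(n, rate0 * ifelse(bearing, config$hazard_ratio_true, 1))
    c_cens <- runif(n, config$censor_day_range[1], config$censor_day_range[2])
    tibble(
      subject_id = sprintf("S%03d", seq_len(n)),
      time_days = pmax(1L, as.integer(round(pmin(t_event, c_cens)))),
      event = t_event <= c_cens,
      group = ifelse(bearing, "ctDNA_positive", "ctDNA_negative")
    )
  })
}
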