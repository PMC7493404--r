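# End-to-end orchestration: one config, per-stage derived seeds, and a
# results bundle covering filtering, tracking, detection, monitoring and
# survival. Rerunning with the same config and cohort is bit-identical.

#' Pipeline configuration
#'
#' Collects the analysis parameters: the FFPE filter thresholds (AF > 5%,
#' or > 3% for hotspot variants; ExAC population frequency < 1%), the Monte
#' Carlo detection settings (10,000 iterations, positivity at empirical
#' p < 0.01), the molecular-progression rule (2 consecutive strict
#' increases, any-variant), the mGE conversion constant (3.3 pg per haploid
#' genome), and a master seed from which every stage derives its own seed
#' via [derive_seed()].
#'
#' @param af_min,af_min_hotspot,exac_max FFPE filter thresholds.
#' @param iterations,alpha Monte Carlo detection settings.
#' @param k_increases,mp_rule Molecular-progression settings.
#' @param haploid_genome_mass_ng mGE conversion constant.
#' @param include_synonymous Keep synonymous variants in tracking sets?
#' @param germline_threshold Decision threshold of the germline classifier.
#' @param train_subjects Subjects in the internally simulated training
#'   cohort used when no germline model is supplied.
#' @param seed Master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(af_min = 0.05, af_min_hotspot = 0.03,
                            exac_max = 0.01, iterations = 10000,
                            alpha = 0.01, k_increases = 2,
                            mp_rule = "any_variant",
                            haploid_genome_mass_ng = 0.0033,
                            include_synonymous = TRUE,
                            germline_threshold = 0.5,
                            train_subjects = 15, seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$alpha <= 0 || cfg$alpha >= 1) abort("alpha must lie in (0, 1)")
  for (th in c(cfg$af_min, cfg$af_min_hotspot, cfg$exac_max)) {
    if (th <= 0 || th >= 1) abort("filter thresholds must lie in (0, 1)")
  }
  if (cfg$iterations < 1) abort("iterations must be >= 1")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  do.call(pipeline_config, vals[names(vals) %in% known])
}

# Label the cohort's variant rows from ground truth and fit the classifier.
train_model_from_cohort <- function(cohort, config) {
  labels <- cohort$ground_truth$variant_labels
  labelled <- dplyr::inner_join(
    cohort$variants, labels, by = c("subject_id", KEY_COLS)
  )
  feats <- germline_features(labelled, cohort$annotations)
  train_germline_model(feats, labelled$label,
                       threshold = config$germline_threshold,
                       seed = derive_seed(config$seed, "germline-train"))
}

#' Run the full monitoring pipeline on a cohort
#'
#' Stages: (1) germline model — supplied, or trained on a separate
#' internally simulated training cohort; (2) FFPE filters + tracking set
#' per subject with baseline tissue; (3) Monte Carlo ctDNA detection on
#' every plasma sample; (4) total-ctDNA quantification and
#' molecular-progression / lead-time calling per subject; (5) PFS records,
#' Kaplan-Meier curves, log-rank test and univariate Cox models with ctDNA
#' status from the first and the last post-treatment sample, plus the
#' clinical adjustment-factor Cox screen when covariates are present.
#'
#' @param cohort A `ctdna_cohort` (from [simulate_cohort()] or
#'   [read_cohort()]).
#' @param config A [pipeline_config()].
#' @param model Optional pre-trained `germline_model`; when `NULL` one is
#'   trained on a fresh synthetic training cohort derived from the master
#'   seed.
#' @param out_dir Optional directory for TSV outputs.
#' @return A list of class `ctdna_pipeline_result`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), model = NULL,
                         out_dir = NULL) {
  stopifnot(is(cohort, "ctdna_cohort"))
  ann <- cohort$annotations

  if (is.null(model)) {
    train_cfg <- cohort$config
    train_cfg$n_subjects <- config$train_subjects
    train_cfg$seed <- derive_seed(config$seed, "train-cohort")
    train_cohort <- simulate_cohort(train_cfg)
    model <- train_model_from_cohort(train_cohort, config)
  }

  tissue <- filter(cohort$variants, .data$sample_type == "tissue")
  plasma <- filter(cohort$variants, .data$sample_type == "plasma")

  ## FFPE filtering and tracking sets, one per subject with tissue
  outcomes <- apply_ffpe_filters(
    tissue, ann, model,
    af_min = config$af_min, af_min_hotspot = config$af_min_hotspot,
    exac_max = config$exac_max
  )
  tracking_sets <- outcomes |>
    split(outcomes$subject_id) |>
    map(build_tracking_set,
        include_synonymous = config$include_synonymous)

  ## Detection per plasma sample. The observed mean is read from the full
  ## alteration table, but the background null is drawn from the
  ## germline-filtered table so heterozygous/homozygous germline
  ## alterations never contaminate the sequencing-error null.
  plasma_somatic <- classify_germline(plasma, model, ann) |>
    filter(.data$germline_class == "putative_somatic")
  plasma_by_sample <- split(plasma, plasma$sample_id)
  somatic_by_sample <- split(plasma_somatic, plasma_somatic$sample_id)
  detections <- imap(plasma_by_sample, function(pv, sid) {
    subj <- pv$subject_id[1]
    tracking <- tracking_sets[[subj]]
    if (is.null(tracking)) {
      return(tibble(sample_id = sid, observed_mean_af = NA_real_,
                    empirical_p = NA_real_,
                    iterations = as.integer(config$iterations),
                    n_used = 0L, call = "indeterminate",
                    seed = NA_integer_))
    }
    detect_ctdna(pv, tracking, alpha = config$alpha,
                 iterations = config$iterations,
                 seed = derive_seed(config$seed, paste0("detect:", sid)),
                 sample_id = sid,
                 background_variants = somatic_by_sample[[sid]] %||%
                   empty_variant_table())
  }) |> list_rbind()
  detections <- left_join(detections,
                          select(cohort$manifest, "sample_id", "subject_id",
                                 "collection_day"),
                          by = "sample_id")

  ## Monitoring: trajectories, total ctDNA, molecular progression
  monitor <- monitor_subjects(cohort, tracking_sets, config)

  ## Survival
  surv <- survival_stage(cohort, detections)

  result <- structure(list(
    model = model, filter_outcomes = outcomes,
    tracking_sets = tracking_sets, detections = detections,
    monitor = monitor$calls, levels = monitor$levels,
    survival = surv, config = config
  ), class = "ctdna_pipeline_result")

  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

# Per-subject trajectory of tracked-variant AFs, total ctDNA per sample,
# molecular-progression call and lead time against the first PD event.
monitor_subjects <- function(cohort, tracking_sets, config) {
  manifest <- filter(cohort$manifest, .data$sample_type == "plasma")
  plasma <- filter(cohort$variants, .data$sample_type == "plasma")
  calls <- list()
  levels <- list()
  for (subj in names(tracking_sets)) {
    tracking <- tracking_sets[[subj]]
    man_s <- arrange(filter(manifest, .data$subject_id == subj),
                     .data$collection_day)
    if (nrow(man_s) < 2 || tracking_n(tracking) == 0) next
    pv <- filter(plasma, .data$subject_id == subj)
    traj <- man_s |>
      select("sample_id", day = "collection_day") |>
      dplyr::cross_join(mutate(as_tibble(tracking)[, KEY_COLS],
                               variant = variant_key(tracking))) |>
      left_join(select(pv, "sample_id", dplyr::all_of(KEY_COLS), "af"),
                by = c("sample_id", KEY_COLS)) |>
      mutate(af = ifelse(is.na(.data$af), 0, .data$af))
    levels[[subj]] <- traj |>
      group_by(.data$sample_id, .data$day) |>
      summarise(sum_af = sum(.data$af), .groups = "drop") |>
      left_join(select(man_s, "sample_id", "input_mass_ng"),
                by = "sample_id") |>
      mutate(subject_id = subj,
             total_ctdna_mge = map2(.data$sum_af, .data$input_mass_ng,
                                    function(s, m) {
                                      s * m / config$haploid_genome_mass_ng
                                    }) |> unlist())
    mp <- detect_molecular_progression(
      select(traj, "day", "variant", "af"),
      k_increases = config$k_increases, rule = config$mp_rule
    )
    recist_s <- filter(cohort$recist, .data$subject_id == subj)
    pd_day <- if (any(recist_s$response == "PD")) {
      min(recist_s$day[recist_s$response == "PD"])
    } else {
      NA_integer_
    }
    calls[[subj]] <- tibble(
      subject_id = subj, mp_called = mp$called, mp_day = mp$call_day,
      pd_day = pd_day,
      lead_time_days = if (!is.na(pd_day)) lead_time(mp, pd_day) else NA_real_
    )
  }
  list(calls = list_rbind(calls), levels = list_rbind(levels))
}

survival_stage <- function(cohort, detections) {
  subjects <- distinct(cohort$manifest, .data$subject_id)
  records <- list_rbind(map(subjects$subject_id, function(subj) {
    recist_s <- filter(cohort$recist, .data$subject_id == subj)
    if (nrow(recist_s) == 0) return(NULL)
    tl <- subject_timeline(subj, recist = select(recist_s, "day", "response"))
    compute_pfs(tl)
  }))
  covariate_cols <- intersect(c("age", "sex", "ecog", "smoking", "stage"),
                              names(cohort$ground_truth$subject_truth))
  if (length(covariate_cols)) {
    records <- left_join(
      records,
      select(cohort$ground_truth$subject_truth, "subject_id",
             dplyr::all_of(covariate_cols)),
      by = "subject_id"
    )
  }
  per_status <- function(which) {
    grp <- ctdna_status_groups(detections, cohort$manifest, which = which)
    rec <- left_join(records, select(grp, "subject_id", "group"),
                     by = "subject_id")
    usable <- filter(rec, !is.na(.data$group))
    res <- list(records = rec)
    if (length(unique(usable$group)) == 2 && sum(usable$event) > 0) {
      res$km <- km_estimate(usable, group = "group")
      res$logrank <- logrank_test(usable)
      res$cox <- cox_univariate(usable, "group",
                                reference = "ctDNA_negative")
    }
    res
  }
  screen <- NULL
  if (length(covariate_cols) && sum(records$event) > 0) {
    screen <- list_rbind(map(covariate_cols, function(cv) {
      tryCatch(cox_univariate(records, cv), error = function(e) NULL)
    }))
  }
  list(first = per_status("first"), last = per_status("last"),
       factor_screen = screen)
}

#' @export
print.ctdna_pipeline_result <- function(x, ...) {
  cat("<ctdna_pipeline_result>\n")
  cat("  tracking sets:", length(x$tracking_sets), "subjects\n")
  cat("  detections:   ", nrow(x$detections), "plasma samples (",
      sum(x$detections$call == "positive"), "positive )\n")
  if (!is.null(x$survival$first$cox)) {
    cox <- x$survival$first$cox
    cat(sprintf("  Cox HR (first post-treatment status): %.2f (%.2f-%.2f)\n",
                cox$hr[1], cox$conf_low[1], cox$conf_high[1]))
  }
  invisible(x)
}

write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(flatten_filter_outcomes(result$filter_outcomes),
                   file.path(out_dir, "filter_outcomes.tsv"),
                   progress = FALSE)
  readr::write_tsv(list_rbind(map(result$tracking_sets, as_tibble)),
                   file.path(out_dir, "tracking_sets.tsv"), progress = FALSE)
  readr::write_tsv(result$detections, file.path(out_dir, "detections.tsv"),
                   progress = FALSE)
  if (!is.null(result$monitor)) {
    readr::write_tsv(result$monitor,
                     file.path(out_dir, "molecular_progression.tsv"),
                     progress = FALSE)
  }
  if (!is.null(result$levels)) {
    readr::write_tsv(result$levels, file.path(out_dir, "ctdna_levels.tsv"),
                     progress = FALSE)
  }
  for (which in c("first", "last")) {
    sv <- result$survival[[which]]
    if (!is.null(sv$cox)) {
      readr::write_tsv(sv$cox,
                       file.path(out_dir, paste0("cox_", which, ".tsv")),
                       progress = FALSE)
      readr::write_tsv(tidy(sv$km),
                       file.path(out_dir, paste0("km_", which, ".tsv")),
                       progress = FALSE)
      readr::write_tsv(sv$logrank,
                       file.path(out_dir, paste0("logrank_", which, ".tsv")),
                       progress = FALSE)
    }
  }
  if (!is.null(result$survival$factor_screen)) {
    readr::write_tsv(result$survival$factor_screen,
                     file.path(out_dir, "cox_factor_screen.tsv"),
                     progress = FALSE)
  }
  write_germline_model(result$model,
                       file.path(out_dir, "germline_model.txt"))
  yaml::write_yaml(unclass(result$config),
                   file.path(out_dir, "pipeline_config.yaml"))
  invisible(out_dir)
}
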