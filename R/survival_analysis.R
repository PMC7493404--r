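# Progression-free survival: PFS computation from subject timelines,
# Kaplan-Meier estimation, two-group log-rank testing, and univariate Cox
# models for ctDNA status and clinical adjustment-factor screens. Model
# fitting is delegated to the survival package (Efron tie handling);
# medians and the stratification variable follow the conventions below.

#' Compute progression-free survival for one subject
#'
#' PFS runs from histological diagnosis (day 0) to the first RECIST PD
#' event or death of any cause, whichever comes first (`event = TRUE`);
#' subjects with neither are censored at the last imaging assessment.
#'
#' @param timeline A [subject_timeline()].
#' @return A one-row tibble: `subject_id, time_days, event`.
#' @export
compute_pfs <- function(timeline) {
  stopifnot(is(timeline, "subject_timeline"))
  pd <- first_pd_day(timeline)
  death <- timeline$death_day
  if (is.na(pd) && is.na(death) && is.na(timeline$last_imaging_day)) {
    abort(sprintf("subject %s: no imaging assessment and no death date",
                  timeline$subject_id))
  }
  if (!is.na(pd) || !is.na(death)) {
    t <- min(c(pd, death), na.rm = TRUE)
    tibble(subject_id = timeline$subject_id, time_days = as.integer(t),
           event = TRUE)
  } else {
    tibble(subject_id = timeline$subject_id,
           time_days = as.integer(timeline$last_imaging_day), event = FALSE)
  }
}

#' Assign ctDNA status groups from detection results
#'
#' The stratification variable of the survival analysis: each subject's
#' ctDNA status (`ctDNA_positive` / `ctDNA_negative`) is taken from either
#' the first or the last available post-treatment plasma sample, where
#' post-treatment means `collection_day > treatment_start_day`.
#' Indeterminate detections are skipped when choosing the sample; subjects
#' with no determinate post-treatment sample get `NA`.
#'
#' @param detections Tibble of per-sample detection results (from
#'   [detect_ctdna()]), with a `sample_id` column.
#' @param manifest Sample manifest with `subject_id, sample_id,
#'   collection_day, treatment_start_day`.
#' @param which `"first"` (default) or `"last"` post-treatment sample.
#' @return Tibble `subject_id, group, status_sample_id`.
#' @export
ctdna_status_groups <- function(detections, manifest,
                                which = c("first", "last")) {
  which <- match.arg(which)
  joined <- manifest |>
    filter(.data$sample_type == "plasma",
           .data$collection_day > .data$treatment_start_day) |>
    dplyr::inner_join(select(as_tibble(detections), "sample_id", "call"),
                      by = "sample_id") |>
    filter(.data$call != "indeterminate") |>
    arrange(.data$subject_id, .data$collection_day)
  picked <- joined |>
    group_by(.data$subject_id) |>
    slice(if (which == "first") 1 else n()) |>
    ungroup()
  all_subjects <- distinct(manifest, .data$subject_id)
  out <- left_join(all_subjects,
                   select(picked, "subject_id", "call", "sample_id"),
                   by = "subject_id")
  tibble(subject_id = out$subject_id,
         group = if_else(is.na(out$call), NA_character_,
                         if_else(out$call == "positive", "ctDNA_positive",
                                 "ctDNA_negative")),
         status_sample_id = out$sample_id)
}

#' Kaplan-Meier estimate of progression-free survival
#'
#' Product-limit estimator, optionally stratified by a grouping column.
#' The median is the smallest time at which the survival curve reaches
#' 0.5 or below; it is `NA` when the curve never does.
#'
#' @param records Tibble with `time_days` (> 0), `event` (logical), and
#'   optionally the grouping column.
#' @param group Name of the grouping column, or `NULL` for a single curve.
#' @return A `km_fit` object with [tidy()], [glance()] and [autoplot()]
#'   methods.
#' @export
km_estimate <- function(records, group = NULL) {
  records <- as_tibble(records)
  if (nrow(records) == 0) abort("km_estimate() needs at least one record")
  if (any(records$time_days <= 0)) abort("time_days must be positive")
  if (!is.null(group)) {
    records$.group <- as.character(records[[group]])
    records <- filter(records, !is.na(.data$.group))
    fit <- survival::survfit(
      survival::Surv(time_days, event) ~ .group, data = records
    )
  } else {
    records$.group <- "all"
    fit <- survival::survfit(
      survival::Surv(time_days, event) ~ 1, data = records
    )
  }
  structure(list(fit = fit, records = records, group = group),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat("<km_fit>\n")
  print(glance(x))
  invisible(x)
}

#' @export
tidy.km_fit <- function(x, ...) {
  s <- summary(x$fit, censored = TRUE)
  grp <- if (is.null(s$strata)) {
    rep("all", length(s$time))
  } else {
    sub("^.*=", "", as.character(s$strata))
  }
  tibble(group = grp, time = s$time, n_risk = s$n.risk,
         n_event = s$n.event, n_censor = s$n.censor, survival = s$surv,
         std_error = s$std.err)
}

km_median <- function(times, surv) {
  hit <- which(surv <= 0.5)
  if (length(hit) == 0) NA_real_ else min(times[hit])
}

#' @export
glance.km_fit <- function(x, ...) {
  tidy(x) |>
    group_by(.data$group) |>
    summarise(n = NA_integer_, n_events = sum(.data$n_event),
              median_survival = km_median(.data$time, .data$survival),
              .groups = "drop") |>
    mutate(n = map_int(.data$group, function(g) {
      sum(x$records$.group == g)
    }))
}

#' Two-group log-rank test
#'
#' Standard log-rank test with hypergeometric (tie-corrected) variance,
#' symmetric in group order. When neither group contributes any event the
#' statistic is 0 and p = 1 by convention (with a warning).
#'
#' @param records Tibble with `time_days`, `event`, and the grouping
#'   column (exactly two levels).
#' @param group Name of the grouping column (default `"group"`).
#' @return A one-row tibble: `statistic, df, p_value, n_<level>` counts.
#' @export
logrank_test <- function(records, group = "group") {
  records <- as_tibble(records)
  records$.group <- as.character(records[[group]])
  records <- filter(records, !is.na(.data$.group))
  levels <- sort(unique(records$.group))
  if (length(levels) != 2) {
    abort("logrank_test() requires exactly two non-empty groups")
  }
  if (sum(records$event) == 0) {
    warn("no events in either group; log-rank p-value set to 1")
    return(tibble(statistic = 0, df = 1L, p_value = 1))
  }
  sd <- survival::survdiff(
    survival::Surv(time_days, event) ~ .group, data = records
  )
  tibble(statistic = sd$chisq, df = 1L,
         p_value = pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards model
#'
#' Fits an unadjusted Cox model for a single covariate with Efron tie
#' handling; hazard ratios carry Wald 95% confidence intervals on the
#' log-HR scale. Categorical covariates with more than two levels report
#' one HR per non-reference level plus a single global likelihood-ratio
#' p-value. Non-convergence or monotone likelihood (complete separation)
#' is flagged in the result, never returned as silent numbers.
#'
#' @param records Tibble with `time_days`, `event`, and the covariate
#'   column.
#' @param covariate Name of the covariate column.
#' @param reference Optional reference level for categorical covariates.
#' @return A tibble with one row per estimated term: `covariate, level,
#'   hr, conf_low, conf_high, p_value, global_p, flagged`.
#' @export
cox_univariate <- function(records, covariate = "group", reference = NULL) {
  records <- as_tibble(records)
  x <- records[[covariate]]
  records <- records[!is.na(x), ]
  x <- x[!is.na(x)]
  if (length(unique(x)) < 2) {
    abort(sprintf("covariate '%s' must have at least 2 observed levels",
                  covariate))
  }
  if (sum(records$event) == 0) {
    abort("cox_univariate() needs at least one event")
  }
  categorical <- is.character(x) || is.factor(x) || is.logical(x)
  if (categorical) {
    x <- factor(as.character(x))
    if (!is.null(reference)) x <- stats::relevel(x, ref = reference)
  }
  records$.x <- x
  flagged <- FALSE
  withCallingHandlers(
    fit <- survival::coxph(survival::Surv(time_days, event) ~ .x,
                           data = records, ties = "efron"),
    warning = function(w) {
      flagged <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  if (any(abs(coef(fit)) > 10, na.rm = TRUE)) flagged <- TRUE
  s <- summary(fit)
  terms <- rownames(s$coefficients)
  lvl <- if (categorical) sub("^\\.x", "", terms) else covariate
  global_p <- as.numeric(1 - pchisq(2 * diff(fit$loglik),
                                    df = length(coef(fit))))
  tibble(
    covariate = covariate,
    level = lvl,
    reference = if (categorical) levels(x)[1] else NA_character_,
    hr = unname(s$coefficients[, "exp(coef)"]),
    conf_low = unname(s$conf.int[, "lower .95"]),
    conf_high = unname(s$conf.int[, "upper .95"]),
    p_value = unname(s$coefficients[, "Pr(>|z|)"]),
    global_p = global_p,
    flagged = flagged
  )
}
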