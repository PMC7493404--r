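# Longitudinal monitoring: total ctDNA quantification in mutated genome
# equivalents, molecular-progression calling from allele-frequency
# trajectories, and lead time against radiographic progression.

#' Total ctDNA level in mutated genome equivalents (mGE)
#'
#' Sums the allele frequencies of the variants detected in a plasma sample
#' and scales by the number of haploid genome equivalents in the cfDNA
#' input: `mGE = sum(af) * input_mass_ng / haploid_genome_mass_ng`. One
#' haploid human genome weighs about 3.3 pg (0.0033 ng), so 33 ng of input
#' is 10,000 genome equivalents and a single variant at 10% AF in that
#' input is 1000 mGE. The level is additive over variants and linear in
#' input mass; a sample with no detected variants has level 0.
#'
#' @param af Numeric vector of detected-variant allele frequencies (may be
#'   empty).
#' @param input_mass_ng Total cfDNA input mass in nanograms (> 0).
#' @param haploid_genome_mass_ng Mass of one haploid genome in ng.
#' @return Total ctDNA level in mGE.
#' @export
total_ctdna_level <- function(af, input_mass_ng,
                              haploid_genome_mass_ng = 0.0033) {
  if (length(input_mass_ng) != 1 || is.na(input_mass_ng) ||
        input_mass_ng <= 0) {
    abort("input_mass_ng must be a single positive number")
  }
  sum(af) * input_mass_ng / haploid_genome_mass_ng
}

#' Build a subject timeline
#'
#' Bundles one subject's ordered plasma samples (with per-variant allele
#' frequencies and detection results where available) and clinical anchor
#' dates. Diagnosis is day 0 by convention.
#'
#' @param subject_id Subject identifier.
#' @param samples Tibble with at least `sample_id` and `collection_day`,
#'   ordered or orderable by day; optional columns `total_ctdna`, `call`.
#' @param trajectory Tibble of per-variant AFs by day: columns `day`,
#'   `variant`, `af` (absent tracked variants recorded as `af = 0`).
#' @param recist Tibble of RECIST assessments: columns `day`, `response`
#'   (one of CR/PR/SD/PD).
#' @param death_day Day of death, or `NA`.
#' @param last_imaging_day Day of the last imaging assessment; defaults to
#'   the latest RECIST day.
#' @param treatment_start_day Day first-line treatment began, or `NA`.
#' @return A `subject_timeline` object.
#' @export
subject_timeline <- function(subject_id, samples = NULL, trajectory = NULL,
                             recist = NULL, death_day = NA_integer_,
                             last_imaging_day = NULL,
                             treatment_start_day = NA_integer_) {
  samples <- as_tibble(samples %||% tibble(sample_id = character(),
                                           collection_day = integer()))
  samples <- arrange(samples, .data$collection_day)
  recist <- as_tibble(recist %||% tibble(day = integer(),
                                         response = character()))
  recist <- arrange(recist, .data$day)
  if (is.null(last_imaging_day)) {
    last_imaging_day <- if (nrow(recist)) max(recist$day) else NA_integer_
  }
  structure(
    list(subject_id = subject_id, samples = samples,
         trajectory = as_tibble(trajectory %||%
                                  tibble(day = integer(), variant = character(),
                                         af = double())),
         recist = recist, death_day = death_day,
         last_imaging_day = last_imaging_day,
         treatment_start_day = treatment_start_day),
    class = "subject_timeline"
  )
}

#' @export
print.subject_timeline <- function(x, ...) {
  cat("<subject_timeline>", x$subject_id, "-", nrow(x$samples), "samples,",
      nrow(x$recist), "RECIST assessments\n")
  invisible(x)
}

first_pd_day <- function(timeline) {
  pd <- filter(timeline$recist, .data$response == "PD")
  if (nrow(pd) == 0) NA_integer_ else min(pd$day)
}

# Earliest index ending a run of k strict increases whose starting value is
# at least the baseline (first-sample) value; NA when no such run exists.
run_call_index <- function(af, k) {
  m <- length(af)
  if (m < k + 1) return(NA_integer_)
  inc <- diff(af) > 0
  for (end in (k + 1):m) {
    start <- end - k
    if (all(inc[start:(end - 1)]) && af[start] >= af[1]) {
      return(end)
    }
  }
  NA_integer_
}

#' Call molecular progression from allele-frequency trajectories
#'
#' Molecular progression is a run of `k_increases` consecutive strict
#' increases in mutation allele frequency starting from baseline: under the
#' default `any_variant` rule the call lands on the earliest sample day at
#' which some tracked variant completes such a run, where the run's
#' starting value must be at least the variant's baseline (first-sample)
#' value; ties break the run. The `mean_af` rule applies the same test to
#' the per-day mean allele frequency across variants. With fewer than
#' `k_increases + 1` samples no call is possible.
#'
#' @param trajectory Tibble with columns `day`, `variant`, `af`: each
#'   tracked variant's allele frequency at each sampled day (0 when not
#'   observed). May also be a `subject_timeline`, whose `trajectory` is
#'   used.
#' @param k_increases Required number of consecutive strict increases
#'   (default 2).
#' @param rule `"any_variant"` (default) or `"mean_af"`.
#' @return A `molecular_progression` list: `called`, `call_day`,
#'   `supporting` (tibble of the variants whose runs support the call, with
#'   their AF series).
#' @export
detect_molecular_progression <- function(trajectory, k_increases = 2,
                                         rule = c("any_variant", "mean_af")) {
  rule <- match.arg(rule)
  if (is(trajectory, "subject_timeline")) trajectory <- trajectory$trajectory
  trajectory <- arrange(as_tibble(trajectory), .data$variant, .data$day)
  days <- sort(unique(trajectory$day))
  if (length(days) < 2) {
    abort("molecular-progression calling needs at least 2 samples")
  }
  if (rule == "mean_af") {
    series <- trajectory |>
      group_by(.data$day) |>
      summarise(af = mean(.data$af), .groups = "drop") |>
      arrange(.data$day)
    idx <- run_call_index(series$af, k_increases)
    called <- !is.na(idx)
    return(structure(list(
      called = called,
      call_day = if (called) series$day[idx] else NA_integer_,
      rule = rule, k_increases = k_increases,
      supporting = if (called) {
        tibble(variant = "mean_af", days = list(series$day),
               afs = list(series$af))
      } else {
        tibble(variant = character(), days = list(), afs = list())
      }
    ), class = "molecular_progression"))
  }
  per_variant <- trajectory |>
    tidyr::complete(variant = unique(trajectory$variant), day = days,
                    fill = list(af = 0)) |>
    arrange(.data$variant, .data$day) |>
    group_by(.data$variant) |>
    summarise(idx = run_call_index(.data$af, k_increases),
              days = list(.data$day), afs = list(.data$af),
              .groups = "drop") |>
    mutate(call_day = map2(.data$idx, .data$days,
                           function(i, d) if (is.na(i)) NA_integer_ else d[i]) |>
             unlist())
  hits <- filter(per_variant, !is.na(.data$call_day))
  called <- nrow(hits) > 0
  call_day <- if (called) min(hits$call_day) else NA_integer_
  structure(list(
    called = called, call_day = call_day, rule = rule,
    k_increases = k_increases,
    supporting = if (called) {
      select(filter(hits, .data$call_day == .env$call_day),
             "variant", "days", "afs")
    } else {
      tibble(variant = character(), days = list(), afs = list())
    }
  ), class = "molecular_progression")
}

#' @export
print.molecular_progression <- function(x, ...) {
  if (x$called) {
    cat("<molecular_progression> called at day", x$call_day, "(rule:",
        x$rule, ", k =", x$k_increases, ")\n")
  } else {
    cat("<molecular_progression> not called\n")
  }
  invisible(x)
}

#' @export
tidy.molecular_progression <- function(x, ...) {
  tibble(called = x$called, call_day = x$call_day, rule = x$rule,
         k_increases = x$k_increases,
         n_supporting = nrow(x$supporting))
}

#' Lead time of the molecular-progression call over radiographic progression
#'
#' Days from the molecular-progression call day to the first radiographic
#' PD day; negative when radiology preceded the molecular call (reported,
#' not clamped); `NA` when either side is missing.
#'
#' @param mp A `molecular_progression` call.
#' @param timeline A `subject_timeline` (its first PD event is used), or a
#'   single PD day.
#' @return Lead time in days, or `NA_real_`.
#' @export
lead_time <- function(mp, timeline) {
  pd_day <- if (is(timeline, "subject_timeline")) {
    first_pd_day(timeline)
  } else {
    timeline
  }
  if (!isTRUE(mp$called) || is.na(pd_day)) return(NA_real_)
  as.numeric(pd_day) - as.numeric(mp$call_day)
}
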