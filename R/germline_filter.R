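# Germline/somatic classification without a matched normal: a logistic
# score over database annotations and observed allele frequency, with a
# hard hotspot-whitelist override. A transparent, auditable stand-in for
# proprietary classifiers trained on matched-normal truth sets.

GERMLINE_FEATURES <- c("max_pop_af", "n_dbs_present",
                       "somatic_evidence_count", "observed_af",
                       "af_distance_to_het", "af_distance_to_hom")

#' Compute germline-classification features for each variant
#'
#' Features per variant: the maximum population allele frequency across
#' databases (`max_pop_af`, 0 when absent everywhere), the number of
#' databases carrying the variant, the pooled somatic-evidence count, the
#' observed allele frequency, and its distances to the canonical
#' heterozygous (0.5) and homozygous (1.0) germline frequencies, plus the
#' hotspot-whitelist flag. Absent database entries yield zeros, never
#' missing values.
#'
#' @param variants A variant table.
#' @param annotations A `ctdna_annotations` bundle.
#' @return A tibble: the variant keys plus feature columns.
#' @export
germline_features <- function(variants, annotations) {
  keys <- select(as_tibble(variants), dplyr::all_of(KEY_COLS))
  pop <- max_pop_af_lookup(annotations, keys)
  tibble(
    keys,
    max_pop_af = pop$max_pop_af,
    n_dbs_present = pop$n_dbs_present,
    somatic_evidence_count = somatic_evidence_lookup(annotations, keys),
    observed_af = variants$af,
    af_distance_to_het = abs(variants$af - 0.5),
    af_distance_to_hom = abs(variants$af - 1.0),
    is_hotspot = variants$is_hotspot | in_hotspot_list(annotations, keys)
  )
}

#' Train the germline/somatic logistic classifier
#'
#' Fits a logistic regression of the germline label on the feature set of
#' [germline_features()] (the hotspot flag is excluded: whitelisted
#' variants are exempted by a hard rule at classification time, not scored).
#' To guarantee that growing population frequency can only push a variant
#' toward the germline class, the `max_pop_af` coefficient is constrained
#' to be non-negative on the germline side (clamped at 0 if the fit comes
#' out negative, which does not occur on realistic training data).
#'
#' @param features Feature tibble from [germline_features()].
#' @param labels Character/factor vector: `"germline"` or `"somatic"`, one
#'   per feature row.
#' @param threshold Posterior-probability decision threshold in (0, 1).
#' @param seed Recorded in the model metadata (the fit itself is
#'   deterministic).
#' @return A `germline_model` object with [tidy()] and [glance()] methods.
#' @export
train_germline_model <- function(features, labels, threshold = 0.5,
                                 seed = 1L) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) {
    abort("training data must contain both germline and somatic labels")
  }
  if (threshold <= 0 || threshold >= 1) abort("threshold must lie in (0, 1)")
  df <- as_tibble(features)[, GERMLINE_FEATURES]
  df$y <- as.integer(labels == "germline")
  fit <- suppressWarnings(
    glm(y ~ ., data = df, family = binomial(), control = list(maxit = 50))
  )
  w <- coef(fit)
  w[is.na(w)] <- 0
  if (w["max_pop_af"] < 0) w["max_pop_af"] <- 0  # monotonicity constraint
  eta <- as.matrix(df[, GERMLINE_FEATURES]) %*% w[GERMLINE_FEATURES] +
    w["(Intercept)"]
  acc <- mean((plogis(eta) >= threshold) == (df$y == 1))
  structure(
    list(weights = w, threshold = threshold, seed = as.integer(seed),
         n_train = nrow(df), training_accuracy = acc),
    class = "germline_model"
  )
}

#' @export
print.germline_model <- function(x, ...) {
  cat("<germline_model> logistic score on", length(x$weights) - 1,
      "features;", "threshold", x$threshold, "\n")
  cat("  trained on", x$n_train, "variants, training accuracy",
      round(x$training_accuracy, 4), "\n")
  invisible(x)
}

#' @export
tidy.germline_model <- function(x, ...) {
  tibble(term = names(x$weights), estimate = unname(x$weights))
}

#' @export
glance.germline_model <- function(x, ...) {
  tibble(n_train = x$n_train, threshold = x$threshold,
         training_accuracy = x$training_accuracy, seed = x$seed)
}

germline_score <- function(model, features) {
  w <- model$weights
  eta <- as.matrix(as_tibble(features)[, GERMLINE_FEATURES]) %*%
    w[GERMLINE_FEATURES] + w["(Intercept)"]
  plogis(drop(eta))
}

#' Classify variants as predicted-germline or putative-somatic
#'
#' Hotspot-whitelist variants are ruled putative-somatic before scoring
#' (so a well-known cancer mutation at allele frequency near 0.5 is never
#' discarded as germline); all other variants are scored by the logistic
#' model and called germline when the posterior probability reaches the
#' model threshold. There is no allele-frequency cut-off: low-frequency
#' variants are classified from database evidence and AF jointly.
#'
#' @param variants A variant table.
#' @param model A `germline_model`.
#' @param annotations A `ctdna_annotations` bundle.
#' @return The variant table with `p_germline` and `germline_class`
#'   (`"predicted_germline"` / `"putative_somatic"`) columns appended; the
#'   two classes partition the input.
#' @export
classify_germline <- function(variants, model, annotations) {
  stopifnot(is(model, "germline_model"))
  variants <- as_tibble(variants)
  if (nrow(variants) == 0) {
    return(mutate(variants, p_germline = double(),
                  germline_class = character()))
  }
  feats <- germline_features(variants, annotations)
  p <- germline_score(model, feats)
  cls <- if_else(feats$is_hotspot, "putative_somatic",
                 if_else(p >= model$threshold, "predicted_germline",
                         "putative_somatic"))
  mutate(variants, p_germline = p, germline_class = cls)
}

#' Write a germline model to a flat text file
#'
#' Format: one `term<TAB>weight` line per coefficient at full precision,
#' then `threshold`, `seed`, `n_train`, `training_accuracy` rows. A model
#' read back with [read_germline_model()] reproduces the original
#' bit-for-bit.
#'
#' @param model A `germline_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_germline_model <- function(model, path) {
  num <- function(x) sprintf("%.17g", x)
  lines <- c(
    paste0("#plasmatrace germline_model v1"),
    paste(names(model$weights), vapply(model$weights, num, character(1)),
          sep = "\t"),
    paste("threshold", num(model$threshold), sep = "\t"),
    paste("seed", model$seed, sep = "\t"),
    paste("n_train", model$n_train, sep = "\t"),
    paste("training_accuracy", num(model$training_accuracy), sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a germline model written by [write_germline_model()]
#'
#' @param path Path to the model file.
#' @return A `germline_model`.
#' @export
read_germline_model <- function(path) {
  if (!file.exists(path)) abort(sprintf("model file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  key <- vapply(parts, `[[`, character(1), 1)
  val <- vapply(parts, `[[`, character(1), 2)
  meta <- c("threshold", "seed", "n_train", "training_accuracy")
  w <- as.numeric(val[!key %in% meta])
  names(w) <- key[!key %in% meta]
  structure(
    list(weights = w,
         threshold = as.numeric(val[key == "threshold"]),
         seed = as.integer(val[key == "seed"]),
         n_train = as.integer(val[key == "n_train"]),
         training_accuracy = as.numeric(val[key == "training_accuracy"])),
    class = "germline_model"
  )
}
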