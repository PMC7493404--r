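test_that("features default to zero for database-absent variants", {
  ann <- toy_annotations()
  v <- make_variants(af = 0.02)
  f <- germline_features(v, ann)
  expect_equal(f$max_pop_af, 0)
  expect_equal(f$n_dbs_present, 0L)
  expect_equal(f$somatic_evidence_count, 0L)
  expect_equal(f$observed_af, 0.02)
  expect_false(anyNA(f))
})

test_that("feature arithmetic matches the definitions", {
  v <- make_variants(chrom = "chr2", pos = 500L, af = 0.49)
  ann <- toy_annotations(pop_af = tibble::tibble(
    chrom = "chr2", pos = 500L, ref = "A", alt = "T", db = "ExAC",
    af = 0.30
  ))
  f <- germline_features(v, ann)
  expect_equal(f$max_pop_af, 0.30)
  expect_equal(f$n_dbs_present, 1L)
  expect_equal(f$af_distance_to_het, 0.01)
  expect_equal(f$af_distance_to_hom, 0.51)
})

test_that("whitelist membership is visible in the feature vector", {
  v <- make_variants(chrom = "chr7", pos = 140453136L, ref = "A",
                     alt = "T", af = 0.45)
  ann <- toy_annotations(hotspots = tibble::tibble(
    chrom = "chr7", pos = 140453136L, ref = "A", alt = "T"
  ))
  f <- germline_features(v, ann)
  expect_true(f$is_hotspot)
})

make_training_features <- function(n_per_class, seed = 1) {
  withr::with_seed(seed, {
    germ <- tibble::tibble(
      max_pop_af = runif(n_per_class, 0.05, 0.5),
      n_dbs_present = sample(1:3, n_per_class, TRUE),
      somatic_evidence_count = 0L,
      observed_af = rnorm(n_per_class, 0.5, 0.03),
      af_distance_to_het = NA_real_, af_distance_to_hom = NA_real_,
      is_hotspot = FALSE
    )
    som <- tibble::tibble(
      max_pop_af = 0,
      n_dbs_present = 0L,
      somatic_evidence_count = rpois(n_per_class, 2),
      observed_af = runif(n_per_class, 0.005, 0.3),
      af_distance_to_het = NA_real_, af_distance_to_hom = NA_real_,
      is_hotspot = FALSE
    )
    out <- dplyr::bind_rows(germ, som)
    out$af_distance_to_het <- abs(out$observed_af - 0.5)
    out$af_distance_to_hom <- abs(out$observed_af - 1.0)
    list(features = out,
         labels = rep(c("germline", "somatic"), each = n_per_class))
  })
}

test_that("a separable training set is fit perfectly and deterministically", {
  tr <- make_training_features(60)
  m1 <- train_germline_model(tr$features, tr$labels)
  m2 <- train_germline_model(tr$features, tr$labels)
  expect_equal(m1$training_accuracy, 1.0)
  expect_identical(m1$weights, m2$weights)
  expect_error(train_germline_model(tr$features,
                                    rep("somatic", nrow(tr$features))),
               "both germline and somatic")
})

test_that("shuffled labels give chance-level held-out accuracy", {
  # Permutation null: with labels destroyed, held-out accuracy is binomial
  # around 0.5.
  tr <- make_training_features(300, seed = 7)
  perm <- withr::with_seed(13, sample(tr$labels))
  idx <- rep(c(TRUE, FALSE), length.out = nrow(tr$features))
  model <- train_germline_model(tr$features[idx, ], perm[idx])
  p <- plasmatrace:::germline_score(model, tr$features[!idx, ])
  acc <- mean((p >= 0.5) == (perm[!idx] == "germline"))
  n_test <- sum(!idx)
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / n_test))
})

test_that("classification follows database evidence, not an AF cut-off", {
  model <- toy_germline_model()
  ann <- toy_annotations(
    pop_af = tibble::tibble(chrom = "chr1", pos = 2001L, ref = "A",
                            alt = "T", db = "ExAC", af = 0.40),
    hotspots = tibble::tibble(chrom = "chr1", pos = 3001L, ref = "A",
                              alt = "T")
  )
  v <- make_variants(n = 3, pos = c(1001L, 2001L, 3001L),
                     af = c(0.25, 0.50, 0.52))
  out <- classify_germline(v, model, ann)
  # low-AF variant with no database support: somatic despite af < 30%
  expect_equal(out$germline_class[1], "putative_somatic")
  # canonical germline: ExAC 0.40 at af 0.50
  expect_equal(out$germline_class[2], "predicted_germline")
  # hotspot whitelist override at af 0.52
  expect_equal(out$germline_class[3], "putative_somatic")
  # partition is exhaustive and exclusive
  expect_setequal(unique(out$germline_class),
                  c("putative_somatic", "predicted_germline"))
})

test_that("increasing population AF never flips germline to somatic", {
  tr <- make_training_features(150, seed = 3)
  model <- train_germline_model(tr$features, tr$labels)
  expect_gte(model$weights["max_pop_af"], 0)
  base <- tibble::tibble(
    max_pop_af = 0, n_dbs_present = 1L, somatic_evidence_count = 1L,
    observed_af = 0.4, af_distance_to_het = 0.1, af_distance_to_hom = 0.6,
    is_hotspot = FALSE
  )
  grid <- seq(0, 0.5, by = 0.01)
  p <- vapply(grid, function(g) {
    f <- base
    f$max_pop_af <- g
    plasmatrace:::germline_score(model, f)
  }, numeric(1))
  expect_true(all(diff(p) >= -1e-12))
})

test_that("model serialization round-trips bit-equal", {
  tr <- make_training_features(40, seed = 9)
  model <- train_germline_model(tr$features, tr$labels, seed = 42)
  path <- withr::local_tempfile(fileext = ".txt")
  write_germline_model(model, path)
  back <- read_germline_model(path)
  expect_identical(back$weights, model$weights)
  expect_identical(back$threshold, model$threshold)
  expect_identical(back$seed, model$seed)
  expect_identical(back$n_train, model$n_train)
  expect_identical(back$training_accuracy, model$training_accuracy)
})

test_that("tidy() and glance() expose coefficients and metadata", {
  tr <- make_training_features(40)
  model <- train_germline_model(tr$features, tr$labels)
  td <- tidy(model)
  expect_true(all(c("(Intercept)", "max_pop_af") %in% td$term))
  gl <- glance(model)
  expect_equal(gl$n_train, 80L)
})

test_that("held-out cohorts are labelled concordantly with ground truth", {
  cfg_a <- small_sim_config(n_subjects = 8, seed = 101)
  cfg_b <- small_sim_config(n_subjects = 8, seed = 202)
  train <- simulate_cohort(cfg_a)
  test <- simulate_cohort(cfg_b)
  fit_on <- function(co) {
    labelled <- dplyr::inner_join(
      co$variants, co$ground_truth$variant_labels,
      by = c("subject_id", "chrom", "pos", "ref", "alt")
    )
    list(feats = germline_features(labelled, co$annotations),
         labels = labelled$label, variants = labelled)
  }
  tr <- fit_on(train)
  te <- fit_on(test)
  model <- train_germline_model(tr$feats, tr$labels)
  out <- classify_germline(te$variants, model, test$annotations)
  predicted <- ifelse(out$germline_class == "predicted_germline",
                      "germline", "somatic")
  concordance <- mean(predicted == te$labels)
  expect_gte(concordance, 0.85)
})
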