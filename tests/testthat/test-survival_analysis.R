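recist_tbl <- function(days, responses) {
  tibble::tibble(day = as.integer(days), response = responses)
}

test_that("PFS runs to the first PD, death, or censoring at last imaging", {
  pd <- subject_timeline("S1", recist = recist_tbl(c(0, 80, 159),
                                                   c("SD", "SD", "PD")))
  expect_equal(compute_pfs(pd), tibble::tibble(subject_id = "S1",
                                               time_days = 159L,
                                               event = TRUE))
  cens <- subject_timeline("S2", recist = recist_tbl(c(0, 100, 200),
                                                     c("SD", "PR", "SD")))
  out <- compute_pfs(cens)
  expect_equal(out$time_days, 200L)
  expect_false(out$event)

  died <- subject_timeline("S3", recist = recist_tbl(c(0, 80, 159),
                                                     c("SD", "SD", "PD")),
                           death_day = 120L)
  out3 <- compute_pfs(died)
  expect_equal(out3$time_days, 120L)
  expect_true(out3$event)

  bare <- subject_timeline("S4")
  expect_error(compute_pfs(bare), "no imaging")
})

test_that("KM with no censoring equals the empirical survivor function", {
  withr::local_seed(14)
  for (rep in 1:3) {
    n <- sample(5:40, 1)
    times <- sample.int(500, n)        # distinct event times
    rec <- tibble::tibble(time_days = times, event = TRUE)
    km <- km_estimate(rec)
    d <- tidy(km)
    emp <- vapply(d$time, function(t) mean(times > t), numeric(1))
    expect_equal(d$survival, emp)
    # median: smallest t with S(t) <= 0.5
    expect_equal(glance(km)$median_survival,
                 min(d$time[d$survival <= 0.5]))
  }
})

test_that("KM handles the degenerate censoring patterns", {
  all_cens <- tibble::tibble(time_days = c(10L, 20L, 30L), event = FALSE)
  km <- km_estimate(all_cens)
  expect_true(all(tidy(km)$survival == 1))
  expect_true(is.na(glance(km)$median_survival))

  single <- km_estimate(tibble::tibble(time_days = 42L, event = TRUE))
  d <- tidy(single)
  expect_equal(d$survival[d$time == 42], 0)
  expect_error(km_estimate(tibble::tibble(time_days = integer(),
                                          event = logical())),
               "at least one")
  expect_error(km_estimate(tibble::tibble(time_days = 0L, event = TRUE)),
               "positive")
})

test_that("KM curves are bounded, non-increasing, and start at 1", {
  withr::local_seed(15)
  rec <- tibble::tibble(time_days = sample.int(300, 60, replace = TRUE),
                        event = runif(60) < 0.7,
                        group = sample(c("A", "B"), 60, TRUE))
  km <- km_estimate(rec, group = "group")
  d <- tidy(km)
  for (g in c("A", "B")) {
    s <- d$survival[d$group == g]
    expect_true(all(s >= 0 & s <= 1))
    expect_true(all(diff(s) <= 1e-12))
  }
})

test_that("log-rank is zero for identical groups and matches hand computation", {
  base <- tibble::tibble(time_days = c(10L, 20L, 30L, 40L),
                         event = c(TRUE, TRUE, FALSE, TRUE))
  rec <- dplyr::bind_rows(dplyr::mutate(base, group = "A"),
                          dplyr::mutate(base, group = "B"))
  out <- logrank_test(rec)
  expect_equal(out$statistic, 0, tolerance = 1e-12)
  expect_equal(out$p_value, 1)

  # small worked instance: accumulate O-E and V over event times by hand
  rec2 <- tibble::tibble(
    time_days = c(5L, 8L, 12L, 20L, 25L, 30L),
    event = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    group = c("A", "A", "B", "A", "B", "B")
  )
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(rec2$time_days[rec2$event]))) {
    at_risk <- rec2$time_days >= t
    d_t <- sum(rec2$event & rec2$time_days == t)
    n_t <- sum(at_risk)
    n_a <- sum(at_risk & rec2$group == "A")
    d_a <- sum(rec2$event & rec2$time_days == t & rec2$group == "A")
    e_a <- d_t * n_a / n_t
    o_minus_e <- o_minus_e + (d_a - e_a)
    if (n_t > 1) {
      v <- v + d_t * (n_a / n_t) * (1 - n_a / n_t) * (n_t - d_t) / (n_t - 1)
    }
  }
  expected_chisq <- o_minus_e^2 / v
  out2 <- logrank_test(rec2)
  expect_equal(out2$statistic, expected_chisq, tolerance = 1e-8)
  # symmetric in group order
  rec2_flipped <- dplyr::mutate(rec2,
                                group = ifelse(group == "A", "B", "A"))
  expect_equal(logrank_test(rec2_flipped)$statistic, out2$statistic,
               tolerance = 1e-12)
})

test_that("log-rank with zero events warns and returns p = 1", {
  rec <- tibble::tibble(time_days = c(10L, 20L), event = FALSE,
                        group = c("A", "B"))
  expect_warning(out <- logrank_test(rec), "no events")
  expect_equal(out$p_value, 1)
})

test_that("log-rank type-I error is nominal under equal hazards", {
  withr::local_seed(26)
  reps <- 500
  rejections <- vapply(seq_len(reps), function(i) {
    ta <- rexp(30, 1 / 200)
    tb <- rexp(30, 1 / 200)
    cens <- runif(60, 50, 600)
    rec <- tibble::tibble(
      time_days = pmax(1L, as.integer(round(pmin(c(ta, tb), cens)))),
      event = c(ta, tb) <= cens,
      group = rep(c("A", "B"), each = 30)
    )
    logrank_test(rec)$p_value < 0.05
  }, logical(1))
  rate <- mean(rejections)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("Cox estimates invert under label swap and reject bad input", {
  rec <- simulate_survival_records(cohort_sim_config(n_subjects = 120),
                                   seed = 3)
  fit <- cox_univariate(rec, "group", reference = "ctDNA_negative")
  swapped <- dplyr::mutate(rec, group = ifelse(group == "ctDNA_positive",
                                               "ctDNA_negative",
                                               "ctDNA_positive"))
  fit2 <- cox_univariate(swapped, "group", reference = "ctDNA_negative")
  expect_equal(fit$hr, 1 / fit2$hr, tolerance = 1e-8)

  const <- dplyr::mutate(rec, group = "same")
  expect_error(cox_univariate(const, "group"), "2 observed levels")
  no_event <- dplyr::mutate(rec, event = FALSE)
  expect_error(cox_univariate(no_event, "group"), "event")
})

test_that("a single cohort's Cox HR lands near the generator truth", {
  cfg <- cohort_sim_config(n_subjects = 600)
  rec <- simulate_survival_records(cfg, seed = 11)
  fit <- cox_univariate(rec, "group", reference = "ctDNA_negative")
  expect_equal(fit$level, "ctDNA_positive")
  expect_gt(fit$conf_high, cfg$hazard_ratio_true * 0.9)
  expect_lt(fit$conf_low, cfg$hazard_ratio_true * 1.1)
  expect_false(fit$flagged)
})

test_that("multi-level covariates report per-level HRs and a global p", {
  withr::local_seed(5)
  rec <- simulate_survival_records(cohort_sim_config(n_subjects = 150),
                                   seed = 9)
  rec$smoking <- sample(c("current", "quit", "never"), 150, TRUE,
                        prob = c(0.6, 0.25, 0.15))
  fit <- cox_univariate(rec, "smoking", reference = "quit")
  expect_equal(nrow(fit), 2)
  expect_setequal(fit$level, c("current", "never"))
  expect_equal(unique(fit$reference), "quit")
  expect_length(unique(fit$global_p), 1)
  expect_true(all(fit$global_p >= 0 & fit$global_p <= 1))
})

test_that("complete separation is flagged, not silently reported", {
  rec <- tibble::tibble(
    time_days = c(5L, 6L, 7L, 100L, 110L, 120L),
    event = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    group = rep(c("bad", "good"), each = 3)
  )
  fit <- cox_univariate(rec, "group")
  expect_true(fit$flagged)
})

test_that("ctDNA status groups pick the right post-treatment sample", {
  manifest <- tibble::tibble(
    subject_id = "S1",
    sample_id = c("S1_P1", "S1_P2", "S1_P3", "S1_P4"),
    sample_type = "plasma",
    collection_day = c(0L, 21L, 42L, 63L),
    input_mass_ng = 20, treatment_start_day = 7L
  )
  detections <- tibble::tibble(
    sample_id = manifest$sample_id,
    call = c("positive", "indeterminate", "negative", "positive")
  )
  first <- ctdna_status_groups(detections, manifest, which = "first")
  expect_equal(first$group, "ctDNA_negative")   # P2 indeterminate skipped
  expect_equal(first$status_sample_id, "S1_P3")
  last <- ctdna_status_groups(detections, manifest, which = "last")
  expect_equal(last$group, "ctDNA_positive")
  expect_equal(last$status_sample_id, "S1_P4")
})
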