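# ctDNA presence testing: the mean allele frequency of a subject's tracked
# variants in a plasma sample is compared against a Monte Carlo null built
# from that sample's own background allele alterations.

#' Extract a plasma sample's background allele alterations
#'
#' The background is every observed alteration in the sample whose key is
#' not in the tracking set; tracked keys never leak into the null.
#'
#' @param plasma_variants One plasma sample's full alteration table
#'   (including sub-threshold alterations when available).
#' @param tracking The subject's `tracking_set`.
#' @return A tibble of background alterations (`chrom, pos, ref, alt, af`).
#' @export
extract_background <- function(plasma_variants, tracking) {
  plasma_variants <- as_tibble(plasma_variants)
  bg <- anti_join(plasma_variants, as_tibble(tracking), by = KEY_COLS)
  select(bg, dplyr::all_of(KEY_COLS), "af")
}

#' Mean allele frequency of tracked variants in a plasma sample
#'
#' All `n` tracked keys enter the mean; a tracked variant not observed in
#' the sample contributes allele frequency 0 rather than shrinking `n`, so
#' `n` stays fixed at the tracking-set size.
#'
#' @param plasma_variants One plasma sample's alteration table.
#' @param tracking The subject's `tracking_set`.
#' @return A one-row tibble with `mean_af` (`NA` when the tracking set is
#'   empty) and `n_used`.
#' @export
observed_mean_af <- function(plasma_variants, tracking) {
  n <- tracking_n(tracking)
  if (n == 0) return(tibble(mean_af = NA_real_, n_used = 0L))
  joined <- left_join(as_tibble(tracking)[, KEY_COLS],
                      select(as_tibble(plasma_variants),
                             dplyr::all_of(KEY_COLS), "af"),
                      by = KEY_COLS)
  af <- ifelse(is.na(joined$af), 0, joined$af)
  tibble(mean_af = mean(af), n_used = n)
}

# Sample `iterations` subsets of n distinct indices from N, as an n x
# iterations matrix. Vectorized rejection: draw with replacement, re-draw
# columns containing duplicates. Falls back to per-column sampling when n
# is a large fraction of N (rejection would thrash).
sample_index_matrix <- function(N, n, iterations) {
  if (n == 1) {
    return(matrix(sample.int(N, iterations, replace = TRUE), nrow = 1))
  }
  if (n / N > 0.5) {
    return(vapply(seq_len(iterations), function(i) sample.int(N, n),
                  integer(n)))
  }
  idx <- matrix(sample.int(N, n * iterations, replace = TRUE), nrow = n)
  repeat {
    srt <- matrix(idx[order(col(idx), idx)], nrow = n)
    bad <- colSums(srt[-1L, , drop = FALSE] ==
                     srt[-n, , drop = FALSE]) > 0
    nb <- sum(bad)
    if (nb == 0L) break
    idx[, bad] <- sample.int(N, n * nb, replace = TRUE)
  }
  idx
}

#' Monte Carlo empirical p-value for ctDNA presence
#'
#' Each iteration randomly picks `n` distinct background allele alterations
#' and records their mean allele frequency; the empirical p-value is the
#' add-one-smoothed tail fraction `(1 + #\{iteration mean >= observed
#' mean\}) / (iterations + 1)`, so p is never exactly 0 and ties count
#' toward the tail (conservative).
#'
#' @param mean_obs Observed mean allele frequency of the tracked variants.
#' @param background_af Numeric vector of background alteration AFs.
#' @param n Number of tracked variants (subset size per iteration).
#' @param iterations Monte Carlo iterations (default 10000).
#' @param seed Optional seed for a deterministic p-value.
#' @param replace Fall back to sampling with replacement when the
#'   background is smaller than `n`? Off by default (returns `NA`,
#'   signalling an indeterminate call).
#' @return The empirical p-value in `[1/(iterations+1), 1]`, or `NA_real_`
#'   when the background is too small and `replace = FALSE`.
#' @export
monte_carlo_pvalue <- function(mean_obs, background_af, n,
                               iterations = 10000, seed = NULL,
                               replace = FALSE) {
  if (n < 1) abort("n must be >= 1")
  if (iterations < 1) abort("iterations must be >= 1")
  N <- length(background_af)
  if (N < n && !replace) return(NA_real_)
  if (N == 0) return(NA_real_)
  with_seed_if(seed, {
    idx <- if (replace && N < n) {
      matrix(sample.int(N, n * iterations, replace = TRUE), nrow = n)
    } else {
      sample_index_matrix(N, n, iterations)
    }
    means <- colMeans(matrix(background_af[idx], nrow = n))
    (1 + sum(means >= mean_obs)) / (iterations + 1)
  })
}

#' Exact empirical p-value by exhaustive subset enumeration
#'
#' Enumerates every size-`n` subset of the background and applies the same
#' add-one smoothing as [monte_carlo_pvalue()], giving the exact value the
#' Monte Carlo estimate converges to. Intended as a test oracle for small
#' instances.
#'
#' @inheritParams monte_carlo_pvalue
#' @param max_combinations Refuse instances with more subsets than this.
#' @return The exact smoothed tail fraction.
#' @export
exhaustive_pvalue <- function(mean_obs, background_af, n,
                              max_combinations = 1e6) {
  N <- length(background_af)
  if (n < 1 || N < n) abort("need 1 <= n <= length(background_af)")
  if (choose(N, n) > max_combinations) {
    abort(sprintf("C(%d, %d) exceeds max_combinations", N, n))
  }
  means <- combn(N, n, FUN = function(i) mean(background_af[i]))
  (1 + sum(means >= mean_obs)) / (length(means) + 1)
}

#' Turn an empirical p-value into a ctDNA presence call
#'
#' @param empirical_p Empirical p-value (may be `NA`).
#' @param n_used Number of tracked variants used.
#' @param alpha Significance threshold; a sample is called positive iff
#'   `p < alpha` (strict), default 0.01.
#' @return `"positive"`, `"negative"`, or `"indeterminate"` (empty tracking
#'   set or background too small — never coerced to a definite call).
#' @export
classify_sample <- function(empirical_p, n_used, alpha = 0.01) {
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1)")
  if_else(n_used == 0 | is.na(empirical_p), "indeterminate",
          if_else(empirical_p < alpha, "positive", "negative"))
}

#' Run the full ctDNA presence test on one plasma sample
#'
#' Computes the observed mean tracked allele frequency, extracts the
#' sample's background alterations, runs the Monte Carlo test, and applies
#' the positivity threshold.
#'
#' @param plasma_variants One plasma sample's alteration table.
#' @param tracking The subject's `tracking_set`.
#' @param alpha Positivity threshold on the empirical p-value.
#' @param iterations Monte Carlo iterations.
#' @param seed Seed for the Monte Carlo draw.
#' @param sample_id Sample label for the result row; defaults to the value
#'   in `plasma_variants`.
#' @param background_variants Alteration table from which the background
#'   null is drawn; defaults to `plasma_variants`. Pass the
#'   germline-filtered table here so that germline alterations (allele
#'   frequency near 0.5) do not contaminate the sequencing-error null.
#' @return A one-row tibble: `sample_id, observed_mean_af, empirical_p,
#'   iterations, n_used, call, seed`.
#' @export
detect_ctdna <- function(plasma_variants, tracking, alpha = 0.01,
                         iterations = 10000, seed = 1L,
                         sample_id = NULL, background_variants = NULL) {
  plasma_variants <- as_tibble(plasma_variants)
  if (is.null(sample_id)) {
    sample_id <- if (nrow(plasma_variants)) {
      unique(plasma_variants$sample_id)[1]
    } else {
      NA_character_
    }
  }
  obs <- observed_mean_af(plasma_variants, tracking)
  p <- NA_real_
  if (obs$n_used > 0) {
    bg <- extract_background(background_variants %||% plasma_variants,
                             tracking)
    p <- monte_carlo_pvalue(obs$mean_af, bg$af, obs$n_used,
                            iterations = iterations, seed = seed)
  }
  tibble(
    sample_id = sample_id,
    observed_mean_af = obs$mean_af,
    empirical_p = p,
    iterations = as.integer(iterations),
    n_used = obs$n_used,
    call = classify_sample(p, obs$n_used, alpha),
    seed = as.integer(seed)
  )
}
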