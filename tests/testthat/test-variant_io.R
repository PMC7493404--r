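test_that("an empty variant table round-trips to an empty tibble", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(plasmatrace:::empty_variant_table(), path)
  out <- read_variant_table(path, "tsv")
  expect_equal(nrow(out), 0)
  expect_named(out, plasmatrace:::VARIANT_COLS)
})

test_that("a TSV row carrying a TP53 CDS change reads back intact", {
  x <- make_variants(sample_type = "plasma", chrom = "chr17",
                     pos = 7675000L, ref = "T", alt = "G", depth = 2000L,
                     af = 0.030, gene = "TP53", cds_change = "c.712T>G")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(x, path)
  out <- read_variant_table(path, "tsv")
  expect_equal(out$af, 0.030)
  expect_equal(out$gene, "TP53")
  expect_equal(out$cds_change, "c.712T>G")
})

test_that("invariant violations are rejected with the offending row", {
  x <- make_variants(n = 2)
  x$alt_count[2] <- 10L
  x$depth[2] <- 5L
  expect_error(validate_variant_table(x), "row 2.*alt_count exceeds depth")
  y <- make_variants()
  y$af <- 1.5
  expect_error(validate_variant_table(y), "af")
  z <- make_variants(ref = "A", alt = "A")
  expect_error(validate_variant_table(z), "ref and alt")
  w <- make_variants(pos = 0L)
  expect_error(validate_variant_table(w), "pos")
})

test_that("write/read round-trip preserves every field", {
  withr::local_seed(11)
  for (rep in 1:3) {
    n <- sample(3:25, 1)
    depth <- sample(500:3000, n, replace = TRUE)
    alt_count <- pmax(1L, rbinom(n, depth, runif(n, 0.001, 0.6)))
    x <- tibble::tibble(
      subject_id = sample(c("S1", "S2"), n, TRUE),
      sample_id = paste0("smp", seq_len(n)),
      sample_type = sample(c("tissue", "plasma"), n, TRUE),
      chrom = sample(paste0("chr", 1:5), n, TRUE),
      pos = sample.int(1e7, n),
      ref = sample(c("A", "C", "G", "T"), n, TRUE),
      alt = NA_character_, depth = depth, alt_count = alt_count,
      af = alt_count / depth,
      gene = sample(c("TP53", "KRAS", ""), n, TRUE),
      cds_change = "", is_hotspot = runif(n) < 0.2,
      is_synonymous = runif(n) < 0.3
    )
    x$alt <- vapply(x$ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                    "", USE.NAMES = FALSE)
    path <- withr::local_tempfile(fileext = ".tsv")
    write_variant_table(x, path)
    out <- read_variant_table(path, "tsv")
    expect_equal(out[setdiff(names(out), "af")],
                 x[setdiff(names(x), "af")])
    expect_equal(out$af, x$af, tolerance = 1e-6)
  }
})

test_that("indel keys are reduced to minimal representation", {
  x <- tibble::tibble(chrom = c("chr1", "chr1", "chr2"),
                      pos = c(100L, 200L, 300L),
                      ref = c("CTT", "ACGT", "A"),
                      alt = c("CT", "AGGT", "T"))
  out <- normalize_variants(x)
  # CTT>CT: trailing T trimmed, anchor base kept -> CT>C at 100
  # ACGT>AGGT: shared suffix GT and prefix A trimmed -> C>G at 201
  expect_equal(out$pos, c(100L, 201L, 300L))
  expect_equal(out$ref, c("CT", "C", "A"))
  expect_equal(out$alt, c("C", "G", "T"))
})

test_that("VCF input is parsed with 1-based coordinates and FORMAT AF", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Allele freq\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "chr17\t7675000\t.\tT\tG\t.\tPASS\tDP=2000\tAF:DP\t0.03:2000",
    "chr1\t12345\t.\tG\tA\t.\tPASS\tDP=1500\tAF:DP\t0.10:1500"
  )
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  out <- read_variant_table(path, "vcf", subject_id = "S1",
                            sample_id = "S1_P1", sample_type = "plasma")
  expect_equal(out$pos, c(7675000L, 12345L))
  expect_equal(out$af, c(0.03, 0.10))
  expect_equal(out$alt_count, c(60L, 150L))
})

test_that("manifests sort per subject by collection day and validate", {
  man <- tibble::tibble(
    subject_id = "S1",
    sample_id = paste0("S1_P", 6:1),
    sample_type = "plasma",
    collection_day = c(110L, 90L, 70L, 45L, 20L, 0L),
    input_mass_ng = 20
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_manifest(man, path)
  out <- read_manifest(path)
  expect_equal(nrow(out), 6)
  expect_true(all(diff(out$collection_day) >= 0))

  dup <- man
  dup$sample_id <- "same"
  write_manifest(dup, path)
  expect_error(read_manifest(path), "duplicate sample_id")

  neg <- man
  neg$collection_day[1] <- -3L
  write_manifest(neg, path)
  expect_error(read_manifest(path), "negative collection_day")
})

test_that("a single tissue manifest row reads as one tissue record", {
  man <- tibble::tibble(subject_id = "S1", sample_id = "S1_T0",
                        sample_type = "tissue", collection_day = 0L,
                        input_mass_ng = 50)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_manifest(man, path)
  out <- read_manifest(path)
  expect_equal(nrow(out), 1)
  expect_equal(out$sample_type, "tissue")
})

test_that("BED masks convert to 1-based closed coordinates", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr17\t100\t200", path)
  ann <- load_annotations(mask_bed = path)
  expect_false(is_masked(ann, "chr17", 100))
  expect_true(is_masked(ann, "chr17", 101))
  expect_true(is_masked(ann, "chr17", 200))
  expect_false(is_masked(ann, "chr17", 201))
  expect_false(is_masked(ann, "chr16", 150))
})

test_that("an empty BED masks nothing", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(0), path)
  ann <- load_annotations(mask_bed = path)
  expect_false(any(is_masked(ann, rep("chr1", 5), c(1, 10, 100, 1e6, 2e7))))
})

test_that("mask membership matches a brute-force interval scan", {
  withr::local_seed(5)
  for (rep in 1:5) {
    n_iv <- sample(1:6, 1)
    start0 <- sort(sample.int(500, n_iv))      # BED 0-based starts
    end0 <- start0 + sample.int(40, n_iv)      # half-open ends
    path <- withr::local_tempfile(fileext = ".bed")
    writeLines(sprintf("chr9\t%d\t%d", start0, end0), path)
    ann <- load_annotations(mask_bed = path)
    pos <- 1:600
    brute <- vapply(pos, function(p) {
      any(start0 < p & p <= end0)  # 1-based p masked iff s < p <= e
    }, logical(1))
    expect_equal(is_masked(ann, rep("chr9", length(pos)), pos), brute)
  }
})

test_that("population tables answer point queries", {
  pop <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(chrom = "chr1", pos = 5000L, ref = "A",
                                  alt = "G", af = 0.02), pop)
  ann <- load_annotations(pop_paths = c(ExAC = pop))
  keys <- tibble::tibble(chrom = "chr1", pos = 5000L, ref = "A", alt = "G")
  expect_equal(plasmatrace:::db_af_lookup(ann, keys, "ExAC"), 0.02)
  absent <- tibble::tibble(chrom = "chr1", pos = 1L, ref = "A", alt = "G")
  expect_equal(plasmatrace:::db_af_lookup(ann, absent, "ExAC"), 0)
  expect_error(load_annotations(pop_paths = "/nonexistent.tsv"),
               "not found")
})
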