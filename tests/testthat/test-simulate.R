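test_that("generation is reproducible under a fixed seed", {
  specs <- dplyr::bind_rows(
    gene_class_spec("germline_maternal", 10),
    gene_class_spec("housekeeping", 30, 1, 50)
  )
  d1 <- generate_dataset(specs, seed = 4L)
  d2 <- generate_dataset(specs, seed = 4L)
  expect_identical(d1$counts$counts, d2$counts$counts)
  expect_identical(d1$lengths, d2$lengths)
  d3 <- generate_dataset(specs, seed = 5L)
  expect_false(identical(d1$counts$counts, d3$counts$counts))
})

test_that("zero genes yield an empty matrix and truth table", {
  ds <- generate_dataset(gene_class_spec("housekeeping", 0))
  expect_equal(nrow(ds$counts$counts), 0)
  expect_equal(nrow(ds$truth), 0)
  expect_equal(nrow(truth_expected_summary(ds$truth)), 0)
})

test_that("counts are unbiased for the class means (Poisson limit, CLT bound)", {
  specs <- gene_class_spec("housekeeping", 1000, 50, 50, offtarget_rpkm = 0)
  ds <- generate_dataset(specs, bcv = 0, seed = 6L,
                         length_range = c(2000, 2000))
  n <- default_library_sizes()
  m <- as.matrix(ds$counts$counts[, -1])
  for (j in c(1, 6, 9)) {
    mu <- 50 * 2000 * n[[j]] / 1e9
    se <- sqrt(mu / nrow(m))
    expect_lt(abs(mean(m[, j]) - mu), 3 * se)
  }
})

test_that("NB noise at bcv 0.4 shows the assumed mean-variance relation", {
  specs <- gene_class_spec("housekeeping", 2000, 80, 80, offtarget_rpkm = 0)
  ds <- generate_dataset(specs, bcv = 0.4, seed = 7L,
                         length_range = c(2000, 2000))
  n <- default_library_sizes()
  x <- as.matrix(ds$counts$counts[, -1])[, 1]
  mu <- 80 * 2000 * n[[1]] / 1e9
  v_expected <- mu + 0.16 * mu^2
  # NB fourth moments make the sample variance noisy: allow 15% relative
  expect_lt(abs(var(x) / v_expected - 1), 0.15)
  expect_lt(abs(mean(x) - mu), 4 * sqrt(v_expected / length(x)))
})

test_that("planted truth implies the expected analytic screen outcome", {
  specs <- dplyr::bind_rows(
    gene_class_spec("germline_maternal", 5, 500, 500, offtarget_rpkm = 0),
    gene_class_spec("follicle_cell", 3, 300, 300),
    gene_class_spec("housekeeping", 20, 50, 50, offtarget_rpkm = 0),
    gene_class_spec("silent", 2)
  )
  ds <- generate_dataset(specs, seed = 8L)
  exp <- truth_expected_summary(ds$truth)
  by_class <- split(exp, exp$class_name)
  expect_true(all(by_class$germline_maternal$expected_strict))
  expect_true(all(by_class$germline_maternal$expected_germline_call))
  # ovary 500 RPKM over four zero off-targets: ratio 500 / 0.1
  expect_true(all(by_class$germline_maternal$expected_ratio))
  expect_true(all(by_class$follicle_cell$expected_follicle_flag))
  expect_false(any(by_class$follicle_cell$expected_germline_call))
  expect_false(any(by_class$housekeeping$expected_strict))
  expect_false(any(by_class$silent$expected_strict))
})

test_that("generator refuses incomplete library-size maps", {
  n <- default_library_sizes()[-1]
  expect_error(generate_dataset(gene_class_spec("housekeeping", 5),
                                lib_sizes = n),
               class = "ovascreen_config_error")
})

test_that("dataset files round-trip through the core readers", {
  specs <- gene_class_spec("germline_maternal", 5)
  ds <- generate_dataset(specs, seed = 10L)
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir)
  cm <- read_counts(paths[["counts"]], paths[["samples"]])
  expect_equal(cm$counts, ds$counts$counts)
  len <- read_gene_lengths(paths[["lengths"]])
  expect_equal(len, ds$lengths)
})
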