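test_that("nb_pmf degenerates to Poisson, normalizes, and matches the NB closed form", {
  expect_equal(nb_pmf(0, mean = 1, phi = 0), exp(-1))
  expect_equal(sum(nb_pmf(0:500, mean = 5, phi = 0.16)), 1, tolerance = 1e-9)
  # frozen from independent log-gamma evaluation of the NB mass with
  # size 1/phi = 6.25, mean 2
  expect_equal(nb_pmf(2, mean = 2, phi = 0.16), 0.234829715766,
               tolerance = 1e-10)
  expect_error(nb_pmf(-1, 1, 0.1), class = "ovascreen_domain_error")
})

test_that("conditional exact test handles conventions and frozen oracle values", {
  # balanced observation at the conditional mode: every partition counts
  expect_equal(conditional_exact_test(5, 5, 1e6, 1e6, 0.4), 1)
  # no information
  expect_equal(conditional_exact_test(0, 0, 1e6, 1e6, 0.4), 1)
  # frozen from exhaustive 13-term conditional enumeration
  expect_equal(conditional_exact_test(12, 0, 1e6, 1e6, 0.4),
               0.00856415881868, tolerance = 1e-9)
  expect_error(conditional_exact_test(-1, 2, 1e6, 1e6, 0.4),
               class = "ovascreen_domain_error")
})

test_that("exact test is symmetric under swapping the two libraries", {
  cases <- expand.grid(y1 = c(0, 3, 17), y2 = c(1, 8, 25))
  for (i in seq_len(nrow(cases))) {
    expect_equal(
      conditional_exact_test(cases$y1[i], cases$y2[i], 1e6, 3e6, 0.4),
      conditional_exact_test(cases$y2[i], cases$y1[i], 3e6, 1e6, 0.4)
    )
  }
})

test_that("bcv = 0 reduces to the conditional binomial test", {
  frac <- 2e6 / (2e6 + 6e6)
  for (s in c(1, 9, 30)) {
    pr <- dbinom(0:s, s, frac)
    for (y1 in 0:s) {
      expected <- min(1, sum(pr[pr <= pr[y1 + 1] * (1 + 1e-10)]))
      expect_equal(conditional_exact_test(y1, s - y1, 2e6, 6e6, 0),
                   expected, tolerance = 1e-10)
    }
  }
})

test_that("bh_fdr reproduces hand-computed step-up adjustments", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(0.37), 0.37)
  # monotone: adjustment preserves p-value ordering
  set.seed(42)
  p <- runif(200)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_error(bh_fdr(c(0.1, 1.2)), class = "ovascreen_domain_error")
})

test_that("run_contrast: null identity, extremal gene, and finite logfc", {
  sheet <- full_sheet()
  set.seed(3)
  base <- as.integer(rpois(1000, 20))
  counts <- data.frame(gene_id = sprintf("g%04d", 1:1000))
  for (s in sheet$sample_id) counts[[s]] <- base
  cm <- as_count_matrix(counts, sheet)
  ct <- run_contrast(cm, "larvae")
  # identical columns carry no evidence for any gene
  expect_true(all(ct$p_value == 1))
  expect_true(all(ct$fdr == 1))
  expect_true(all(is.finite(ct$logfc)))
  expect_true(all(ct$fdr >= ct$p_value))

  counts$S9[1] <- 1000L  # ovary_1_2 column
  counts$S5[1] <- 0L     # larvae column
  cm2 <- as_count_matrix(counts, sheet)
  ct2 <- run_contrast(cm2, "larvae")
  expect_equal(which.min(ct2$fdr), 1L)
  expect_gt(ct2$logfc[1], 0)
  expect_error(run_contrast(cm2, "embryo_0_1", ovary_role = "ovary_1_2"),
               NA)
})

test_that("exact test agrees with edgeR's exact test at equal library sizes", {
  skip_if_not_installed("edgeR")
  set.seed(7)
  mu <- exp(runif(400, log(5), log(500)))
  y <- matrix(rnbinom(800, size = 1 / 0.16, mu = rep(mu, each = 2)),
              ncol = 2, byrow = TRUE)
  d <- edgeR::DGEList(counts = y, group = c(1, 2),
                      lib.size = c(1e6, 1e6), norm.factors = c(1, 1))
  et <- edgeR::exactTest(d, dispersion = 0.16)
  ours <- conditional_exact_test(y[, 1], y[, 2], 1e6, 1e6, 0.4)
  expect_equal(ours, et$table$PValue, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("TMM effective sizes differ from raw totals under asymmetric counts", {
  skip_if_not_installed("edgeR")
  fx <- default_screen_fixture()
  raw <- library_sizes(fx$ds$counts)
  tmm <- tmm_library_sizes(fx$ds$counts)
  expect_equal(names(tmm), names(raw))
  expect_true(all(tmm > 0))
  expect_false(all(tmm == raw))
})
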