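test_that("ovary ratio substitutes zeros and respects the strict threshold", {
  profs <- rbind(
    g1 = profile_row(ovary_1_2 = 738),                        # others 0
    g2 = profile_row(ovary_1_2 = 10, larvae = 0.1, pupae = 0.1,
                     male_1_5 = 0.1, carcass_24pbm = 0.1),
    g3 = profile_row()                                        # all zero
  )
  em <- em_from_profiles(profs)
  r <- ovary_ratio(em, screen_config())
  expect_equal(r$ovary_ratio[r$gene_id == "g1"], 738 / 0.1)
  # ratio exactly 100 does not pass the strict ">" filter
  expect_equal(r$ovary_ratio[r$gene_id == "g2"], 100)
  expect_equal(r$ovary_ratio[r$gene_id == "g3"], 1)
  scr <- screen_from_rpkm(em, contrasts = NULL) |> suppressMessages()
  expect_true(scr$genes$passes_ratio[scr$genes$gene_id == "g1"])
  expect_false(scr$genes$passes_ratio[scr$genes$gene_id == "g2"])
})

test_that("follicle-cell flag fires below the embryo threshold, boundary excluded", {
  profs <- rbind(
    flagged = profile_row(ovary_1_2 = 500, embryo_0_1 = 0),
    deposited = profile_row(ovary_1_2 = 500, embryo_0_1 = 200),
    boundary = profile_row(ovary_1_2 = 500, embryo_0_1 = 1)
  )
  f <- follicle_cell_flag(em_from_profiles(profs), screen_config())
  expect_true(f$follicle_flag[f$gene_id == "flagged"])
  expect_false(f$follicle_flag[f$gene_id == "deposited"])
  expect_false(f$follicle_flag[f$gene_id == "boundary"])
})

test_that("zygotic flag reports the first rising embryo interval", {
  profs <- rbind(
    early = profile_row(embryo_0_1 = 5, embryo_2_4 = 20, embryo_4_8 = 18,
                        embryo_8_12 = 15),
    maternal = profile_row(embryo_0_1 = 40, embryo_2_4 = 20,
                           embryo_4_8 = 10, embryo_8_12 = 5),
    fromzero = profile_row(embryo_0_1 = 0, embryo_2_4 = 1),
    late = profile_row(embryo_0_1 = 40, embryo_2_4 = 20, embryo_4_8 = 50,
                       embryo_8_12 = 40)
  )
  z <- zygotic_flag(em_from_profiles(profs), screen_config())
  zi <- function(g) z$zygotic_interval[z$gene_id == g]
  expect_true(z$zygotic_flag[z$gene_id == "early"])
  expect_equal(zi("early"), "embryo_0_1:embryo_2_4")
  expect_false(z$zygotic_flag[z$gene_id == "maternal"])
  # zero predecessor substituted by the pseudocount: 1 > 2 * 0.1
  expect_true(z$zygotic_flag[z$gene_id == "fromzero"])
  expect_equal(zi("late"), "embryo_2_4:embryo_4_8")
})

test_that("blood-meal classes partition the PBM/previtellogenic fold change", {
  profs <- rbind(
    same = profile_row(ovary_1_2 = 10, ovary_24pbm = 10),
    up = profile_row(ovary_1_2 = 10, ovary_24pbm = 100),
    down = profile_row(ovary_1_2 = 100, ovary_24pbm = 10)
  )
  b <- bloodmeal_class(em_from_profiles(profs), screen_config())
  expect_equal(b$bloodmeal_class[match(c("same", "up", "down"), b$gene_id)],
               c("same", "up", "down"))
})

test_that("mean profile averages gene rows and ignores gene order", {
  p <- profile_row(ovary_1_2 = 10, larvae = 2)
  q <- profile_row(ovary_1_2 = 30, larvae = 0)
  em <- em_from_profiles(rbind(a = p, b = q))
  single <- mean_profile(em, "a")
  expect_equal(single$mean_rpkm, unname(p[as.character(single$role)]))
  both <- mean_profile(em, c("a", "b"))
  swapped <- mean_profile(em, c("b", "a"))
  expect_equal(both, swapped)
  expect_equal(both$mean_rpkm[both$role == "ovary_1_2"], 20)
  expect_error(mean_profile(em, character()),
               class = "ovascreen_domain_error")
})

test_that("intersection requires the cutoff in every contrast, boundary included", {
  mk <- function(fdr, logfc = 1) {
    tibble::tibble(gene_id = c("g1", "g2"), count_ovary = 1L,
                   count_other = 0L, logfc = logfc, p_value = fdr, fdr = fdr)
  }
  # g1 significant everywhere (at exactly alpha in one contrast), g2 misses
  # the cutoff in the fourth contrast only
  cts <- list(mk(c(0.001, 0.0005)), mk(c(0.0002, 0.0002)),
              mk(c(0.0001, 0.0009)), mk(c(0.0004, 0.002)))
  expect_equal(intersect_contrasts(cts, 0.001), "g1")
  # direction requirement: ovary-down in one contrast excludes the gene
  cts_dir <- cts
  cts_dir[[2]]$logfc <- c(-1, 1)
  expect_equal(intersect_contrasts(cts_dir, 0.001), character(0))
  expect_equal(intersect_contrasts(cts_dir, 0.001, require_ovary_up = FALSE),
               "g1")
  cts_bad <- cts
  cts_bad[[3]]$gene_id <- c("g1", "gX")
  expect_error(intersect_contrasts(cts_bad, 0.001),
               class = "ovascreen_config_error")
})

test_that("an all-null matrix yields empty strict and relaxed sets", {
  sheet <- full_sheet()
  counts <- data.frame(gene_id = sprintf("g%03d", 1:50))
  for (s in sheet$sample_id) counts[[s]] <- 5L
  cm <- as_count_matrix(counts, sheet)
  scr <- run_screen(cm, data.frame(gene_id = counts$gene_id,
                                   length_nt = 1000L))
  expect_equal(scr$summary$n_fdr_strict, 0)
  expect_equal(scr$summary$n_fdr_relaxed, 0)
  expect_equal(scr$summary$n_germline, 0)
})

test_that("screen output is deterministic and strict set nests in relaxed set", {
  specs <- dplyr::bind_rows(
    gene_class_spec("germline_maternal", 20),
    gene_class_spec("housekeeping", 200, 1, 100, offtarget_rpkm = 0)
  )
  ds <- generate_dataset(specs, seed = 9L)
  s1 <- run_screen(ds$counts, ds$lengths)
  s2 <- run_screen(ds$counts, ds$lengths)
  expect_identical(s1$genes, s2$genes)
  expect_true(all(s1$genes$in_fdr_relaxed[s1$genes$in_fdr_strict]))
  expect_true(all(s1$genes$in_fdr_strict[s1$genes$germline_call]))
  # tidy/glance expose the per-gene table and the headline counts
  expect_identical(tidy(s1), s1$genes)
  expect_equal(glance(s1)$n_germline, s1$summary$n_germline)
})

test_that("the ratio statistic ignores samples outside the five involved", {
  p <- profile_row(ovary_1_2 = 50, larvae = 1, pupae = 2, male_1_5 = 0,
                   carcass_24pbm = 1, embryo_0_1 = 40)
  q <- p
  q[c("embryo_2_4", "female_1_5", "ovary_24pbm")] <- c(999, 999, 999)
  em <- em_from_profiles(rbind(a = p, b = q))
  r <- ovary_ratio(em, screen_config())
  expect_equal(r$ovary_ratio[1], r$ovary_ratio[2])
})

test_that("autoplot returns a profile bar chart for a nonempty screen", {
  fx <- default_screen_fixture()
  pl <- ggplot2::ggplot_build(autoplot(fx$scr))
  expect_equal(nrow(pl$data[[1]]), 11)
})
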