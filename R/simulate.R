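#' Gene-class specification for the synthetic generator
#'
#' Each planted class emulates an expression archetype seen across the
#' eleven-sample design:
#' \describe{
#'   \item{germline_maternal}{high in both ovary samples, deposited into
#'     the embryo (0-1 hr at the ovary base level) and decaying maternally
#'     across the embryo time course; near-silent in larvae, pupae, males
#'     and the PBM carcass; the whole-female sample carries an ovary
#'     contribution.}
#'   \item{follicle_cell}{ovary-high but absent from all embryo samples
#'     (somatic follicle-cell transcripts are not deposited).}
#'   \item{maternal_zygotic}{maternal profile plus a fresh zygotic rise at
#'     `zygotic_onset`.}
#'   \item{zygotic_only}{silent outside the embryos; expressed from
#'     `zygotic_onset` onward.}
#'   \item{housekeeping}{uniform across all eleven samples.}
#'   \item{silent}{zero everywhere.}
#' }
#' Per-gene expression levels are drawn log-uniformly over
#' `[base_rpkm_min, base_rpkm_max]`.
#'
#' @param class_name One of the six class names above.
#' @param n_genes Number of genes of the class.
#' @param base_rpkm_min,base_rpkm_max Range for the log-uniform ovary (or
#'   peak) expression level, RPKM.
#' @param decay_per_embryo_step Multiplicative survival of maternal
#'   transcript per embryo interval, in (0, 1].
#' @param zygotic_onset Embryo role at which zygotic expression starts
#'   (classes with a zygotic component), else `NA`.
#' @param offtarget_rpkm Leakage RPKM in larvae/pupae/male/carcass.
#' @return One-row tibble; bind rows to build a class table.
#' @export
gene_class_spec <- function(class_name, n_genes,
                            base_rpkm_min = 50, base_rpkm_max = 2000,
                            decay_per_embryo_step = 0.5,
                            zygotic_onset = NA_character_,
                            offtarget_rpkm = 0.2) {
  classes <- c("germline_maternal", "follicle_cell", "maternal_zygotic",
               "zygotic_only", "housekeeping", "silent")
  if (!class_name %in% classes) {
    abort(paste0("unknown gene class: ", class_name),
          class = "ovascreen_config_error")
  }
  stopifnot(n_genes >= 0, base_rpkm_min > 0, base_rpkm_max >= base_rpkm_min,
            decay_per_embryo_step > 0, decay_per_embryo_step <= 1,
            offtarget_rpkm >= 0)
  if (!is.na(zygotic_onset) && !zygotic_onset %in% embryo_roles()) {
    abort("zygotic_onset must be an embryo role",
          class = "ovascreen_config_error")
  }
  tibble::tibble(
    class_name = class_name, n_genes = as.integer(n_genes),
    base_rpkm_min = base_rpkm_min, base_rpkm_max = base_rpkm_max,
    decay_per_embryo_step = decay_per_embryo_step,
    zygotic_onset = zygotic_onset, offtarget_rpkm = offtarget_rpkm
  )
}

#' Default planted-class table of the synthetic study
#'
#' 5,000 genes: 200 germline-maternal, 20 follicle-cell, 30
#' maternal-plus-zygotic, 50 zygotic-only, 4,500 housekeeping and 200
#' silent — a germline fraction of the same order as a real transcriptome
#' screen, with enough housekeeping genes to exercise FDR control.
#'
#' @return Tibble of class specs (see [gene_class_spec()]).
#' @export
default_gene_classes <- function() {
  dplyr::bind_rows(
    gene_class_spec("germline_maternal", 200, 50, 2000),
    gene_class_spec("follicle_cell", 20, 50, 500),
    gene_class_spec("maternal_zygotic", 30, 50, 500,
                    zygotic_onset = "embryo_2_4"),
    gene_class_spec("zygotic_only", 50, 20, 200,
                    zygotic_onset = "embryo_2_4", offtarget_rpkm = 0),
    gene_class_spec("housekeeping", 4500, 1, 100, offtarget_rpkm = 0),
    gene_class_spec("silent", 200, 1, 1, offtarget_rpkm = 0)
  )
}

#' Default per-sample library sizes (mapped reads)
#'
#' One library per role, totals spread over 5-20 million mapped reads to
#' emulate unequal sequencing depth across the eleven samples.
#'
#' @return Named numeric vector, one entry per canonical role.
#' @export
default_library_sizes <- function() {
  setNames(
    c(8e6, 1.2e7, 9e6, 1.1e7, 2e7, 1.5e7, 7e6, 1.3e7, 1e7, 1.6e7, 5e6),
    sample_roles()
  )
}

# true per-sample RPKM profile for one gene, given its class row and draws
class_profile <- function(row, base, bm_factor) {
  prof <- setNames(numeric(11), sample_roles())
  er <- embryo_roles()
  d <- row$decay_per_embryo_step
  switch(row$class_name,
    germline_maternal = {
      prof["ovary_1_2"] <- base
      prof["ovary_24pbm"] <- base * bm_factor
      prof[er] <- base * d^(0:3)
      prof[c("larvae", "pupae", "male_1_5", "carcass_24pbm")] <-
        row$offtarget_rpkm
      prof["female_1_5"] <- row$offtarget_rpkm + 0.3 * base
    },
    follicle_cell = {
      prof["ovary_1_2"] <- base
      prof["ovary_24pbm"] <- base * bm_factor
      prof[er] <- 0
      prof[c("larvae", "pupae", "male_1_5", "carcass_24pbm")] <-
        row$offtarget_rpkm
      prof["female_1_5"] <- row$offtarget_rpkm + 0.3 * base
    },
    maternal_zygotic = {
      prof["ovary_1_2"] <- base
      prof["ovary_24pbm"] <- base * bm_factor
      prof[er] <- base * d^(0:3)
      onset <- match(row$zygotic_onset, er)
      # zygotic burst: 4x the decayed maternal level from onset onward
      prof[er[onset:4]] <- pmax(prof[er[onset:4]],
                                4 * base * d^(onset - 2))
      prof[c("larvae", "pupae", "male_1_5", "carcass_24pbm")] <-
        row$offtarget_rpkm
      prof["female_1_5"] <- row$offtarget_rpkm + 0.3 * base
    },
    zygotic_only = {
      onset <- match(row$zygotic_onset, er)
      prof[er[onset:4]] <- base
    },
    housekeeping = {
      prof[] <- base
    },
    silent = {
      prof[] <- 0
    }
  )
  prof
}

#' Generate a synthetic eleven-sample dataset with planted gene classes
#'
#' Draws, per gene and sample, a count from a negative binomial with mean
#' `mu = rpkm * L * N / 1e9` (the inverse of the RPKM formula) and the same
#' common dispersion the exact test assumes, `bcv^2` — a deliberately
#' well-specified noise model so that recovery failures indicate pipeline
#' defects rather than model mismatch. Gene lengths are uniform integers in
#' `length_range`. `misspecify_sd` adds log-normal gene-wise jitter to the
#' dispersion for robustness exploration.
#'
#' @param specs Class table, e.g. [default_gene_classes()].
#' @param lib_sizes Named per-role library sizes covering all 11 roles;
#'   default [default_library_sizes()].
#' @param bcv Biological coefficient of variation of the NB noise.
#' @param seed Integer seed; identical inputs and seed reproduce the
#'   dataset exactly.
#' @param length_range Gene-length range in nt, default 500-5000.
#' @param misspecify_sd Standard deviation of gene-wise `log(phi)` jitter
#'   (0 = well-specified, the default).
#' @return List with `counts` (a `count_matrix`; sample ids equal roles),
#'   `lengths` (gene-length tibble) and `truth` (tibble: `gene_id`,
#'   `class_name`, one `rpkm_<role>` column per sample with the true mean
#'   RPKM).
#' @export
generate_dataset <- function(specs, lib_sizes = default_library_sizes(),
                             bcv = 0.4, seed = 1L,
                             length_range = c(500, 5000),
                             misspecify_sd = 0) {
  specs <- tibble::as_tibble(specs)
  miss <- setdiff(sample_roles(), names(lib_sizes))
  if (length(miss) > 0) {
    abort(paste0("lib_sizes missing role(s): ", paste(miss, collapse = ", ")),
          class = "ovascreen_config_error")
  }
  if (any(lib_sizes <= 0)) {
    abort("library sizes must be positive", class = "ovascreen_config_error")
  }
  lib_sizes <- lib_sizes[sample_roles()]
  n_total <- sum(specs$n_genes)
  roles <- sample_roles()
  samples <- tibble::tibble(sample_id = roles, role = roles)

  if (n_total == 0) {
    counts <- tibble::as_tibble(
      c(list(gene_id = character()),
        setNames(rep(list(integer()), 11), roles))
    )
    return(list(
      counts = as_count_matrix(counts, samples),
      lengths = tibble::tibble(gene_id = character(), length_nt = integer()),
      truth = tibble::tibble(gene_id = character(), class_name = character())
    ))
  }

  withr::with_seed(as.integer(seed), {
    gene_id <- sprintf("SYN%05d", seq_len(n_total))
    L <- length_range[1] - 1L +
      sample.int(length_range[2] - length_range[1] + 1, n_total,
                 replace = TRUE)
    profiles <- matrix(0, n_total, 11, dimnames = list(gene_id, roles))
    class_name <- character(n_total)
    i <- 0L
    for (r in seq_len(nrow(specs))) {
      row <- specs[r, ]
      if (row$n_genes == 0) next
      base <- exp(runif(row$n_genes, log(row$base_rpkm_min),
                        log(row$base_rpkm_max)))
      if (row$class_name == "silent") base <- rep(0, row$n_genes)
      # blood-meal response factor: mixes up/down/same across ovary genes
      bm <- exp(runif(row$n_genes, log(0.25), log(4)))
      for (g in seq_len(row$n_genes)) {
        i <- i + 1L
        profiles[i, ] <- class_profile(row, base[g], bm[g])
        class_name[i] <- row$class_name
      }
    }
    mu <- profiles * L / 1e9
    mu <- sweep(mu, 2, lib_sizes, "*")
    phi <- bcv^2
    if (misspecify_sd > 0) {
      phi <- phi * exp(stats::rnorm(n_total, 0, misspecify_sd))
    } else {
      phi <- rep(phi, n_total)
    }
    counts_m <- matrix(0L, n_total, 11, dimnames = dimnames(mu))
    for (j in seq_len(11)) {
      pos <- mu[, j] > 0
      if (!any(pos)) next
      counts_m[pos, j] <- if (bcv == 0) {
        rpois(sum(pos), mu[pos, j])
      } else {
        rnbinom(sum(pos), size = 1 / phi[pos], mu = mu[pos, j])
      }
    }
  })

  counts <- tibble::as_tibble(counts_m)
  counts <- tibble::add_column(counts, gene_id = gene_id, .before = 1)
  truth <- tibble::as_tibble(profiles)
  names(truth) <- paste0("rpkm_", roles)
  truth <- tibble::add_column(truth, gene_id = gene_id,
                              class_name = class_name, .before = 1)
  list(
    counts = as_count_matrix(counts, samples),
    lengths = tibble::tibble(gene_id = gene_id, length_nt = as.integer(L)),
    truth = truth
  )
}

#' Expected screen outcome from the planted truth
#'
#' Noise-free recovery baseline: the pipeline is evaluated on the *expected*
#' counts (`round(mu)`) implied by each gene's true mean RPKM profile,
#' with the ratio and refinement stages applied to the true RPKM values
#' directly. No sampling is involved, so the result states which planted
#' genes *should* pass each stage under the given configuration.
#'
#' @param truth Truth tibble from [generate_dataset()].
#' @param cfg A [screen_config()].
#' @param lib_sizes Named per-role library sizes (must match the ones used
#'   for generation); default [default_library_sizes()].
#' @param length_nt Representative gene length used to convert true RPKM to
#'   expected counts; defaults to the midpoint of the generator's default
#'   length range.
#' @return Tibble `gene_id`, `class_name`, `expected_strict`,
#'   `expected_ratio`, `expected_follicle_flag`, `expected_zygotic_flag`,
#'   `expected_germline_call`.
#' @export
truth_expected_summary <- function(truth, cfg = screen_config(),
                                   lib_sizes = default_library_sizes(),
                                   length_nt = 2750) {
  stopifnot(all(c("gene_id", "class_name") %in% names(truth)))
  roles <- sample_roles()
  if (nrow(truth) == 0) {
    return(tibble::tibble(
      gene_id = character(), class_name = character(),
      expected_strict = logical(), expected_ratio = logical(),
      expected_follicle_flag = logical(), expected_zygotic_flag = logical(),
      expected_germline_call = logical()
    ))
  }
  prof <- as.matrix(truth[, paste0("rpkm_", roles)])
  colnames(prof) <- roles
  rownames(prof) <- truth$gene_id
  lib_sizes <- lib_sizes[roles]
  mu <- round(sweep(prof * length_nt / 1e9, 2, lib_sizes, "*"))

  # expected exact-test outcome on noise-free counts, per contrast
  rl <- screen_roles()
  ov <- mu[, rl$ovary]
  n_ov <- lib_sizes[[rl$ovary]]
  sig <- matrix(FALSE, nrow(prof), length(rl$contrasts))
  for (k in seq_along(rl$contrasts)) {
    ot <- mu[, rl$contrasts[k]]
    p <- conditional_exact_test(ov, ot, n_ov, lib_sizes[[rl$contrasts[k]]],
                                bcv = cfg$bcv)
    up <- ov / n_ov > ot / lib_sizes[[rl$contrasts[k]]]
    sig[, k] <- bh_fdr(p) <= cfg$fdr_strict &
      (!cfg$require_ovary_up | up)
  }
  expected_strict <- rowSums(sig) == length(rl$contrasts)

  off <- prof[, rl$contrasts, drop = FALSE]
  off_sub <- sub_zero(off, cfg$pseudocount)
  ratio <- sub_zero(prof[, rl$ovary], cfg$pseudocount) / rowMeans(off_sub)
  foll <- prof[, "embryo_0_1"] < cfg$embryo_min_rpkm
  er <- embryo_roles()
  zyg <- rep(FALSE, nrow(prof))
  for (k in seq_len(3)) {
    zyg <- zyg | prof[, er[k + 1]] >
      cfg$zygotic_fold * sub_zero(prof[, er[k]], cfg$pseudocount)
  }
  tibble::tibble(
    gene_id = truth$gene_id,
    class_name = truth$class_name,
    expected_strict = unname(expected_strict),
    expected_ratio = unname(ratio > cfg$fold_threshold),
    expected_follicle_flag = unname(foll),
    expected_zygotic_flag = unname(zyg),
    expected_germline_call = unname(expected_strict & !foll)
  )
}

#' Write a generated dataset to TSV files
#'
#' Emits exactly the formats [read_counts()] and [read_gene_lengths()]
#' consume: `counts.tsv`, `samples.tsv`, `lengths.tsv`, `truth.tsv`.
#'
#' @param dataset Result of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the file paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    samples = file.path(dir, "samples.tsv"),
    lengths = file.path(dir, "lengths.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  readr::write_tsv(dataset$counts$counts, paths["counts"], progress = FALSE)
  readr::write_tsv(dataset$counts$samples, paths["samples"], progress = FALSE)
  readr::write_tsv(dataset$lengths, paths["lengths"], progress = FALSE)
  readr::write_tsv(dataset$truth, paths["truth"], progress = FALSE)
  invisible(paths)
}
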