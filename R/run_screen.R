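#' Run the full germline-specificity screen
#'
#' Executes the whole pipeline on a raw count matrix: RPKM normalization,
#' the four replicate-free exact-test contrasts of the previtellogenic
#' ovary against larvae, pupae, males and the 24 hr PBM carcass, the
#' all-contrast FDR intersection at the strict and relaxed levels, the
#' pseudocount fold-ratio statistic, the follicle-cell and zygotic
#' refinement flags, and the blood-meal response class. The final germline
#' call keeps strict-set genes that are not follicle-flagged; zygotic-
#' flagged genes are annotated but retained.
#'
#' @param cm A `count_matrix` with at least the ovary, the four contrast
#'   roles, and `embryo_0_1` (all eleven roles for the full annotation set).
#' @param lengths Gene-length tibble (see [read_gene_lengths()]).
#' @param cfg A [screen_config()].
#' @param libsizes Optional library sizes for the exact test (e.g.
#'   [tmm_library_sizes()]); RPKM always uses raw column totals.
#' @return An object of class `germline_screen`: list with `genes` (the
#'   per-gene tibble, see [write_screen_table()] for its columns),
#'   `contrasts` (list of per-contrast tibbles), `summary` (headline
#'   counts), `profile` (mean RPKM profile of the final gene set, `NULL`
#'   when empty), and `config`.
#' @export
run_screen <- function(cm, lengths, cfg = screen_config(), libsizes = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  validate_sample_sheet(cm$samples, require_screen_roles = TRUE)
  if (!"embryo_0_1" %in% cm$samples$role) {
    abort("screen requires the embryo_0_1 role for the follicle-cell flag",
          class = "ovascreen_config_error")
  }
  em <- rpkm(cm, lengths)
  contrasts <- lapply(screen_roles()$contrasts, function(role) {
    run_contrast(cm, role, cfg, libsizes = libsizes)
  })
  names(contrasts) <- screen_roles()$contrasts
  screen_assemble(em, contrasts, cfg)
}

#' Screen from a precomputed RPKM matrix
#'
#' Runs the ratio and refinement stages on an already-normalized RPKM table
#' (for example a deposited supplementary matrix) without recomputing from
#' raw counts. When `contrasts` is `NULL` the FDR stages are skipped and
#' the FDR columns are absent; supply contrast tibbles (from
#' [run_contrast()] on the matching raw counts) to restore them.
#'
#' @param em An `expression_matrix` (see [read_rpkm_matrix()]).
#' @param cfg A [screen_config()].
#' @param contrasts Optional named list of contrast tibbles.
#' @return A `germline_screen` object; without contrasts, `in_fdr_*` and
#'   `germline_call` are `NA` and the summary reports only ratio counts.
#' @export
screen_from_rpkm <- function(em, cfg = screen_config(), contrasts = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  if (is.null(contrasts)) {
    inform("no contrasts supplied: differential-expression stages skipped")
  }
  screen_assemble(em, contrasts, cfg)
}

screen_assemble <- function(em, contrasts, cfg) {
  ratio <- ovary_ratio(em, cfg)
  foll <- follicle_cell_flag(em, cfg)
  zyg <- zygotic_flag(em, cfg)
  roles_present <- em$samples$role
  bm <- if (all(c("ovary_1_2", "ovary_24pbm") %in% roles_present)) {
    bloodmeal_class(em, cfg)
  } else {
    tibble::tibble(gene_id = ratio$gene_id, bloodmeal_class = NA_character_)
  }
  genes <- ratio |>
    dplyr::left_join(foll, by = "gene_id") |>
    dplyr::left_join(zyg, by = "gene_id") |>
    dplyr::left_join(bm, by = "gene_id") |>
    dplyr::mutate(passes_ratio = .data$ovary_ratio > cfg$fold_threshold)

  if (!is.null(contrasts)) {
    strict <- intersect_contrasts(contrasts, cfg$fdr_strict,
                                  cfg$require_ovary_up)
    relaxed <- intersect_contrasts(contrasts, cfg$fdr_relaxed,
                                   cfg$require_ovary_up)
    genes <- genes |>
      dplyr::mutate(
        in_fdr_strict = .data$gene_id %in% strict,
        in_fdr_relaxed = .data$gene_id %in% relaxed,
        germline_call = .data$in_fdr_strict & !.data$follicle_flag
      )
    for (nm in names(contrasts)) {
      ct <- contrasts[[nm]]
      add <- ct[, c("gene_id", "logfc", "p_value", "fdr")]
      names(add)[-1] <- paste0(c("logfc_", "p_", "fdr_"), nm)
      genes <- dplyr::left_join(genes, add, by = "gene_id")
    }
  } else {
    genes <- genes |>
      dplyr::mutate(in_fdr_strict = NA, in_fdr_relaxed = NA,
                    germline_call = NA)
  }

  genes <- genes |>
    dplyr::select(
      "gene_id", "in_fdr_strict", "in_fdr_relaxed", "ovary_ratio",
      "passes_ratio", "follicle_flag", "zygotic_flag", "zygotic_interval",
      "bloodmeal_class", "max_offtarget_rpkm", "germline_call",
      dplyr::everything()
    )

  have_fdr <- !is.null(contrasts)
  n_strict <- if (have_fdr) sum(genes$in_fdr_strict) else NA_integer_
  final_set <- if (have_fdr) genes$gene_id[genes$germline_call] else character()
  strict_max <- if (have_fdr && n_strict > 0) {
    genes$max_offtarget_rpkm[genes$in_fdr_strict]
  } else {
    numeric()
  }
  summary <- list(
    n_fdr_strict = n_strict,
    n_fdr_relaxed = if (have_fdr) sum(genes$in_fdr_relaxed) else NA_integer_,
    n_ratio = sum(genes$passes_ratio),
    n_ratio_in_strict = if (have_fdr) {
      sum(genes$passes_ratio & genes$in_fdr_strict)
    } else {
      NA_integer_
    },
    n_germline = if (have_fdr) length(final_set) else NA_integer_,
    # share of strict-set genes whose worst off-target sample stays low
    frac_offtarget_lt_11 = if (length(strict_max) > 0) {
      mean(strict_max < 11)
    } else {
      NA_real_
    },
    frac_offtarget_lt_5 = if (length(strict_max) > 0) {
      mean(strict_max < 5)
    } else {
      NA_real_
    }
  )
  profile <- if (length(final_set) > 0) mean_profile(em, final_set) else NULL

  structure(
    list(genes = genes, contrasts = contrasts, summary = summary,
         profile = profile, config = cfg, expression = em),
    class = "germline_screen"
  )
}

#' @export
print.germline_screen <- function(x, ...) {
  s <- x$summary
  cat("Germline-specificity screen\n")
  cat(sprintf("  genes tested:            %d\n", nrow(x$genes)))
  if (!is.na(s$n_fdr_strict)) {
    cat(sprintf("  strict FDR set (<= %g):  %d\n",
                x$config$fdr_strict, s$n_fdr_strict))
    cat(sprintf("  relaxed FDR set (<= %g): %d\n",
                x$config$fdr_relaxed, s$n_fdr_relaxed))
  }
  cat(sprintf("  ratio > %g:              %d\n",
              x$config$fold_threshold, s$n_ratio))
  if (!is.na(s$n_fdr_strict)) {
    cat(sprintf("  ratio set in strict set: %d\n", s$n_ratio_in_strict))
    cat(sprintf("  final germline calls:    %d\n", s$n_germline))
  }
  invisible(x)
}

#' @rdname run_screen
#' @param x A `germline_screen`.
#' @param ... Unused.
#' @method tidy germline_screen
#' @export
tidy.germline_screen <- function(x, ...) {
  x$genes
}

#' @rdname run_screen
#' @method glance germline_screen
#' @export
glance.germline_screen <- function(x, ...) {
  tibble::as_tibble(x$summary)
}

#' Plot the mean expression profile of the screened gene set
#'
#' Bar plot of the mean RPKM per sample (canonical role order) over the
#' final germline gene set, the standard way these screens display their
#' hit lists.
#'
#' @param object A `germline_screen` with a nonempty final set.
#' @param log_scale Use a log10 y axis (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot germline_screen
#' @export
autoplot.germline_screen <- function(object, log_scale = TRUE, ...) {
  if (is.null(object$profile)) {
    abort("screen has no final gene set to plot",
          class = "ovascreen_domain_error")
  }
  p <- ggplot2::ggplot(object$profile,
                       ggplot2::aes(x = .data$role, y = .data$mean_rpkm)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::labs(x = NULL, y = "mean RPKM",
                  title = "Mean expression profile of germline calls") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (log_scale) p <- p + ggplot2::scale_y_log10()
  p
}

#' Write the summary of a screen as JSON
#'
#' @param screen A `germline_screen`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screen_summary <- function(screen, path) {
  s <- screen$summary
  s$config <- unclass(screen$config)
  jsonlite::write_json(s, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
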