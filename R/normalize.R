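#' Per-sample library sizes
#'
#' The library size of a sample is the total number of reads mapped to the
#' transcriptome, i.e. the column sum of the count matrix. This is the `N`
#' of the RPKM formula and the conditioning total of the exact test.
#'
#' @param cm A `count_matrix` from [read_counts()] / [as_count_matrix()].
#' @return Named numeric vector of positive totals, one per sample.
#' @export
library_sizes <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  n <- colSums(count_mat(cm))
  if (any(n == 0)) {
    abort(paste0("sample(s) with zero total counts: ",
                 paste(names(n)[n == 0], collapse = ", ")),
          class = "ovascreen_degenerate_error")
  }
  n
}

#' RPKM normalization
#'
#' Reads per kilobase of transcript per million mapped reads:
#' \deqn{RPKM_{gs} = 10^9 \, c_{gs} / (N_s L_g)}
#' with \eqn{c_{gs}} the mapped reads of gene \eqn{g} in sample \eqn{s},
#' \eqn{N_s} the sample's library size and \eqn{L_g} the transcript length
#' in nucleotides. No pseudocount is applied here; zeros stay zero, and the
#' pseudocount substitution happens only inside ratio statistics.
#'
#' @param cm A `count_matrix`.
#' @param lengths Tibble from [read_gene_lengths()]; every gene in `cm`
#'   must be present.
#' @param libsizes Optional named library sizes; defaults to
#'   [library_sizes()] of `cm`.
#' @return A list of class `expression_matrix` with elements `rpkm` (tibble:
#'   `gene_id` + one column per sample) and `samples` (the sample sheet).
#' @export
#' @examples
#' sheet <- data.frame(sample_id = c("a", "b"),
#'                     role = c("ovary_1_2", "larvae"))
#' cm <- as_count_matrix(
#'   data.frame(gene_id = "g1", a = 1000L, b = 10L), sheet)
#' len <- data.frame(gene_id = "g1", length_nt = 1000L)
#' rpkm(cm, len, libsizes = c(a = 1e7, b = 1e7))
rpkm <- function(cm, lengths, libsizes = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  lengths <- validate_gene_lengths(lengths)
  if (is.null(libsizes)) libsizes <- library_sizes(cm)
  m <- count_mat(cm)
  libsizes <- libsizes[colnames(m)]
  if (anyNA(libsizes) || any(libsizes <= 0)) {
    abort("library sizes must be positive and cover every sample",
          class = "ovascreen_config_error")
  }
  idx <- match(rownames(m), lengths$gene_id)
  if (anyNA(idx)) {
    abort(paste0("no length for gene(s): ",
                 paste(utils::head(rownames(m)[is.na(idx)], 5),
                       collapse = ", ")),
          class = "ovascreen_lookup_error")
  }
  L <- lengths$length_nt[idx]
  vals <- 1e9 * sweep(m / L, 2, libsizes, "/")
  out <- tibble::as_tibble(vals)
  out <- tibble::add_column(out, gene_id = rownames(m), .before = 1)
  structure(list(rpkm = out, samples = cm$samples),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix (RPKM): %d genes x %d samples\n",
              nrow(x$rpkm), nrow(x$samples)))
  invisible(x)
}

# RPKM values as a base matrix with role column names
rpkm_by_role <- function(em) {
  m <- as.matrix(em$rpkm[, -1, drop = FALSE])
  rownames(m) <- em$rpkm$gene_id
  colnames(m) <- em$samples$role[match(colnames(m), em$samples$sample_id)]
  m
}
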