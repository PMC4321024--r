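#' Read a gene-by-sample count matrix
#'
#' The count file is a TSV whose first column holds gene identifiers and
#' whose remaining columns hold the mapped-read counts of one library each
#' (the eleven-sample design has one library per sample). The sample sheet
#' maps every count column to a canonical role; columns may appear in any
#' order, and downstream results do not depend on that order.
#'
#' @param path Path to the count TSV (header row of sample ids, first column
#'   gene ids).
#' @param sample_sheet Path to a two-column TSV (`sample_id`, `role`) or a
#'   data frame with those columns.
#' @param require_screen_roles Passed to [validate_sample_sheet()]; set
#'   `TRUE` when the matrix is destined for [run_screen()].
#' @return A list of class `count_matrix` with elements `counts` (tibble:
#'   `gene_id` plus one integer column per sample, ordered as in the sheet)
#'   and `samples` (the validated sample sheet).
#' @export
read_counts <- function(path, sample_sheet, require_screen_roles = FALSE) {
  samples <- if (is.data.frame(sample_sheet)) {
    sample_sheet
  } else {
    readr::read_tsv(sample_sheet, col_types = readr::cols(.default = "c"),
                    progress = FALSE)
  }
  samples <- validate_sample_sheet(samples, require_screen_roles)
  raw <- readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(), .default = "d"), progress = FALSE)
  names(raw)[1] <- "gene_id"
  raw$gene_id <- as.character(raw$gene_id)
  missing <- setdiff(samples$sample_id, names(raw))
  if (length(missing) > 0) {
    abort(paste0("count matrix lacks column(s) named in sample sheet: ",
                 paste(missing, collapse = ", ")),
          class = "ovascreen_format_error")
  }
  counts <- raw[, c("gene_id", samples$sample_id)]
  as_count_matrix(counts, samples)
}

#' Assemble a count matrix from in-memory tables
#'
#' @param counts Data frame with a `gene_id` column and one column of
#'   non-negative integer counts per sample.
#' @param samples Sample sheet data frame (`sample_id`, `role`).
#' @return A `count_matrix` object; see [read_counts()].
#' @export
as_count_matrix <- function(counts, samples) {
  samples <- validate_sample_sheet(samples)
  counts <- tibble::as_tibble(counts)
  if (names(counts)[1] != "gene_id") {
    abort("first column of counts must be 'gene_id'",
          class = "ovascreen_format_error")
  }
  if (anyDuplicated(counts$gene_id)) {
    abort("duplicate gene_id in count matrix",
          class = "ovascreen_format_error")
  }
  missing <- setdiff(samples$sample_id, names(counts))
  if (length(missing) > 0) {
    abort(paste0("counts lack sample column(s): ",
                 paste(missing, collapse = ", ")),
          class = "ovascreen_format_error")
  }
  counts <- counts[, c("gene_id", samples$sample_id)]
  m <- as.matrix(counts[, -1, drop = FALSE])
  if (anyNA(m) || any(m < 0) || any(m != floor(m))) {
    abort("counts must be non-negative integers",
          class = "ovascreen_format_error")
  }
  counts[, -1] <- lapply(counts[, -1, drop = FALSE], as.integer)
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), nrow(x$samples)))
  cat("roles:", paste(x$samples$role, collapse = ", "), "\n")
  invisible(x)
}

# count columns as a base matrix, gene ids as rownames
count_mat <- function(cm) {
  m <- as.matrix(cm$counts[, -1, drop = FALSE])
  rownames(m) <- cm$counts$gene_id
  storage.mode(m) <- "double"
  m
}

#' Read gene (transcript) lengths
#'
#' Accepts either a two-column TSV (`gene_id`, `length_nt`) or a GFF3 file,
#' from which the length of each gene is the sum of its exon widths (GFF3
#' coordinates are 1-based inclusive, so an exon from 1 to 100 contributes
#' 100 nt). The GFF3 path requires the rtracklayer package.
#'
#' @param path Path to the TSV or GFF3 (`.gff`/`.gff3`) file.
#' @return Tibble with columns `gene_id`, `length_nt`.
#' @export
read_gene_lengths <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    return(gff_gene_lengths(path))
  }
  first <- readLines(path, n = 1)
  has_header <- grepl("length_nt", first, fixed = TRUE)
  len <- readr::read_tsv(
    path,
    col_names = if (has_header) TRUE else c("gene_id", "length_nt"),
    col_types = "cd", progress = FALSE
  )
  names(len)[1:2] <- c("gene_id", "length_nt")
  len$length_nt <- as.numeric(len$length_nt)
  validate_gene_lengths(len)
}

validate_gene_lengths <- function(len) {
  len <- tibble::as_tibble(len)[, c("gene_id", "length_nt")]
  if (anyNA(len$length_nt) || any(len$length_nt < 1) ||
      any(len$length_nt != floor(len$length_nt))) {
    abort("gene lengths must be positive integers (nt)",
          class = "ovascreen_format_error")
  }
  if (anyDuplicated(len$gene_id)) {
    abort("duplicate gene_id in length table",
          class = "ovascreen_format_error")
  }
  len$length_nt <- as.integer(len$length_nt)
  len
}

gff_gene_lengths <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("reading GFF3 lengths requires the rtracklayer package",
          class = "ovascreen_config_error")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0) {
    abort("GFF3 contains no exon features", class = "ovascreen_format_error")
  }
  parent <- as.character(S4Vectors::unstrsplit(ex$Parent, ","))
  parent <- sub("^transcript:", "", parent)
  w <- tapply(BiocGenerics::width(ex), parent, sum)
  validate_gene_lengths(tibble::tibble(
    gene_id = names(w), length_nt = as.numeric(w)
  ))
}

#' Write / read a screen result table
#'
#' The per-gene screen table is written as TSV with a fixed, documented
#' column order so that re-reading reproduces the table exactly:
#' `gene_id`, `in_fdr_strict`, `in_fdr_relaxed`, `ovary_ratio`,
#' `passes_ratio`, `follicle_flag`, `zygotic_flag`, `zygotic_interval`,
#' `bloodmeal_class`, `max_offtarget_rpkm`, `germline_call`, followed by the
#' per-contrast `logfc_*`, `p_*`, `fdr_*` columns.
#'
#' @param result Per-gene screen tibble (see [run_screen()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_screen_table <- function(result, path) {
  readr::write_tsv(result, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_screen_table
#' @export
read_screen_table <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      gene_id = "c", zygotic_interval = "c", bloodmeal_class = "c",
      in_fdr_strict = "l", in_fdr_relaxed = "l", passes_ratio = "l",
      follicle_flag = "l", zygotic_flag = "l", germline_call = "l",
      .default = "d"
    ),
    progress = FALSE
  )
}

#' Write / read an RPKM matrix TSV
#'
#' Layout matches the count matrix: first column `gene_id`, one column per
#' sample. A precomputed RPKM table in this layout (for example the one a
#' study deposits as supplementary data) can be ingested with
#' [read_rpkm_matrix()] and fed to [screen_from_rpkm()] in place of
#' recomputation from raw counts.
#'
#' @param rpkm An `expression_matrix` from [rpkm()].
#' @param path TSV path.
#' @return `path` invisibly, or an `expression_matrix` for the reader.
#' @export
write_rpkm_matrix <- function(rpkm, path) {
  readr::write_tsv(rpkm$rpkm, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_rpkm_matrix
#' @param sample_sheet Sample sheet path or data frame (as in
#'   [read_counts()]).
#' @export
read_rpkm_matrix <- function(path, sample_sheet) {
  samples <- if (is.data.frame(sample_sheet)) {
    sample_sheet
  } else {
    readr::read_tsv(sample_sheet, col_types = readr::cols(.default = "c"),
                    progress = FALSE)
  }
  samples <- validate_sample_sheet(samples)
  raw <- readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(), .default = "d"), progress = FALSE)
  names(raw)[1] <- "gene_id"
  raw$gene_id <- as.character(raw$gene_id)
  missing <- setdiff(samples$sample_id, names(raw))
  if (length(missing) > 0) {
    abort(paste0("RPKM matrix lacks column(s): ",
                 paste(missing, collapse = ", ")),
          class = "ovascreen_format_error")
  }
  vals <- raw[, c("gene_id", samples$sample_id)]
  m <- as.matrix(vals[, -1, drop = FALSE])
  if (anyNA(m) || any(m < 0)) {
    abort("RPKM values must be non-negative", class = "ovascreen_format_error")
  }
  structure(list(rpkm = vals, samples = samples), class = "expression_matrix")
}
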