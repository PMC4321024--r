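#' Three-taxon Venn partition of ortholog-group membership
#'
#' Given a boolean ortholog-membership table (one row per gene and taxon:
#' does the gene belong to an ortholog group with a member in that taxon?),
#' assigns each screened gene to exactly one of the eight regions of a
#' three-set Venn diagram. Genes absent from the table for a taxon count as
#' lacking an ortholog there; genes entirely absent fall outside all three
#' sets, with a warning.
#'
#' @param table Data frame with columns `gene_id`, `taxon`,
#'   `has_ortholog_group` (logical); `(gene_id, taxon)` pairs unique.
#' @param genes Character vector of gene ids to partition.
#' @param taxa Exactly three distinct taxon labels present in `table`.
#' @return Object of class `venn_partition`: tibble with one row per region
#'   (`region` such as `"A&B"`, `membership` logical columns named by
#'   taxon, `count`), plus attributes `n_genes`, `n_any` (genes in at least
#'   one taxon) and `n_all` (genes in all three).
#' @export
venn_partition <- function(table, genes, taxa) {
  table <- tibble::as_tibble(table)
  need <- c("gene_id", "taxon", "has_ortholog_group")
  miss <- setdiff(need, names(table))
  if (length(miss) > 0) {
    abort(paste0("ortholog table lacks column(s): ",
                 paste(miss, collapse = ", ")),
          class = "ovascreen_format_error")
  }
  if (length(taxa) != 3 || anyDuplicated(taxa)) {
    abort("exactly three distinct taxa required",
          class = "ovascreen_config_error")
  }
  unknown <- setdiff(taxa, unique(table$taxon))
  if (length(unknown) > 0) {
    abort(paste0("taxa absent from ortholog table: ",
                 paste(unknown, collapse = ", ")),
          class = "ovascreen_config_error")
  }
  if (anyDuplicated(table[, c("gene_id", "taxon")])) {
    abort("duplicate (gene_id, taxon) rows", class = "ovascreen_format_error")
  }
  off_table <- setdiff(genes, table$gene_id)
  if (length(off_table) > 0) {
    warn(paste0(length(off_table),
                " gene(s) absent from the ortholog table count as outside",
                " all sets"))
  }
  # gene x taxon membership, absent rows default FALSE
  member <- vapply(taxa, function(tx) {
    sub <- table[table$taxon == tx, ]
    hit <- sub$has_ortholog_group[match(genes, sub$gene_id)]
    ifelse(is.na(hit), FALSE, hit)
  }, logical(length(genes)))
  if (length(genes) == 1) member <- matrix(member, nrow = 1,
                                           dimnames = list(NULL, taxa))
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), 3))
  names(patterns) <- taxa
  counts <- integer(nrow(patterns))
  if (length(genes) > 0) {
    key <- member %*% c(1L, 2L, 4L)
    tab <- tabulate(key + 1, nbins = 8)
    counts <- tab[as.matrix(patterns) %*% c(1L, 2L, 4L) + 1]
  }
  region <- apply(patterns, 1, function(p) {
    inn <- taxa[as.logical(p)]
    if (length(inn) == 0) "outside" else paste(inn, collapse = "&")
  })
  out <- tibble::as_tibble(patterns)
  out <- tibble::add_column(out, region = region, .before = 1)
  out$count <- as.integer(counts)
  attr(out, "n_genes") <- length(genes)
  attr(out, "n_any") <- if (length(genes) > 0) sum(rowSums(member) > 0) else 0L
  attr(out, "n_all") <- if (length(genes) > 0) sum(rowSums(member) == 3) else 0L
  class(out) <- c("venn_partition", class(out))
  out
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("Three-set ortholog Venn partition\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-30s %d\n", x$region[i], x$count[i]))
  }
  cat(sprintf("  genes with >=1 taxon: %d; in all three: %d (of %d)\n",
              attr(x, "n_any"), attr(x, "n_all"), attr(x, "n_genes")))
  invisible(x)
}
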