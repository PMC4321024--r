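#' Intersect significant genes across contrasts
#'
#' A gene enters the set for a given FDR level only if it meets the cutoff
#' (`fdr <= alpha`, boundary included) in *every* contrast, and — unless
#' direction is disabled — is ovary-up (`logfc > 0`) in every contrast.
#'
#' @param contrasts List of contrast tibbles from [run_contrast()], all over
#'   the identical gene universe.
#' @param alpha FDR cutoff.
#' @param require_ovary_up Require positive log fold change in all
#'   contrasts.
#' @return Character vector of gene ids (in input gene order).
#' @export
intersect_contrasts <- function(contrasts, alpha, require_ovary_up = TRUE) {
  stopifnot(length(contrasts) >= 1)
  ids <- contrasts[[1]]$gene_id
  for (ct in contrasts[-1]) {
    if (!identical(ct$gene_id, ids)) {
      abort("contrasts cover different gene universes",
            class = "ovascreen_config_error")
    }
  }
  keep <- rep(TRUE, length(ids))
  for (ct in contrasts) {
    ok <- ct$fdr <= alpha
    if (require_ovary_up) ok <- ok & ct$logfc > 0
    keep <- keep & ok
  }
  ids[keep]
}

# substitute zeros by the pseudocount (substitution, not addition)
sub_zero <- function(x, pseudocount) {
  x[x == 0] <- pseudocount
  x
}

#' Ovary-to-soma expression ratio
#'
#' Per gene, the previtellogenic-ovary RPKM divided by the mean RPKM of the
#' four off-target samples (larvae, pupae, male, 24 hr PBM carcass). Every
#' zero among the five values involved is substituted by the pseudocount
#' before forming the ratio, so a gene silent everywhere scores exactly 1.
#'
#' @param em An `expression_matrix` from [rpkm()].
#' @param cfg A [screen_config()].
#' @return Tibble `gene_id`, `ovary_ratio`, `max_offtarget_rpkm`.
#' @export
ovary_ratio <- function(em, cfg = screen_config()) {
  m <- rpkm_by_role(em)
  roles <- screen_roles()
  need <- c(roles$ovary, roles$contrasts)
  miss <- setdiff(need, colnames(m))
  if (length(miss) > 0) {
    abort(paste0("missing role(s) for ovary_ratio: ",
                 paste(miss, collapse = ", ")),
          class = "ovascreen_config_error")
  }
  ov <- sub_zero(m[, roles$ovary], cfg$pseudocount)
  off <- m[, roles$contrasts, drop = FALSE]
  off_sub <- sub_zero(off, cfg$pseudocount)
  tibble::tibble(
    gene_id = rownames(m),
    ovary_ratio = unname(ov / rowMeans(off_sub)),
    max_offtarget_rpkm = unname(apply(off, 1, max))
  )
}

#' Follicle-cell flag
#'
#' Transcripts made by the somatic follicle cells of the ovary are not
#' deposited into the oocyte, so an ovary-specific gene with essentially no
#' signal in the 0-1 hr embryo is likely follicle-cell derived rather than
#' germline. Flag: embryo_0_1 RPKM strictly below `embryo_min_rpkm`.
#'
#' @param em An `expression_matrix` containing the `embryo_0_1` role.
#' @param cfg A [screen_config()].
#' @return Tibble `gene_id`, `follicle_flag`.
#' @export
follicle_cell_flag <- function(em, cfg = screen_config()) {
  m <- rpkm_by_role(em)
  if (!"embryo_0_1" %in% colnames(m)) {
    abort("embryo_0_1 role required for the follicle-cell flag",
          class = "ovascreen_config_error")
  }
  tibble::tibble(
    gene_id = rownames(m),
    follicle_flag = unname(m[, "embryo_0_1"] < cfg$embryo_min_rpkm)
  )
}

#' Zygotic-expression flag
#'
#' A purely maternal transcript decays monotonically across the embryo time
#' course; a rise between consecutive embryo samples indicates transcription
#' from the embryo's own genome. A gene is flagged when the RPKM at any
#' later embryo point exceeds `zygotic_fold` times the RPKM at the
#' immediately preceding point (zero predecessors substituted by the
#' pseudocount); the first offending interval is reported. Flagged genes are
#' annotated, never removed from the candidate list.
#'
#' @param em An `expression_matrix` with all four embryo roles.
#' @param cfg A [screen_config()].
#' @return Tibble `gene_id`, `zygotic_flag`, `zygotic_interval` (`NA` when
#'   unflagged).
#' @export
zygotic_flag <- function(em, cfg = screen_config()) {
  m <- rpkm_by_role(em)
  er <- embryo_roles()
  miss <- setdiff(er, colnames(m))
  if (length(miss) > 0) {
    abort(paste0("missing embryo role(s): ", paste(miss, collapse = ", ")),
          class = "ovascreen_config_error")
  }
  flag <- rep(FALSE, nrow(m))
  interval <- rep(NA_character_, nrow(m))
  for (k in seq_len(length(er) - 1)) {
    prev <- sub_zero(m[, er[k]], cfg$pseudocount)
    nxt <- m[, er[k + 1]]
    hit <- !flag & nxt > cfg$zygotic_fold * prev
    interval[hit] <- paste0(er[k], ":", er[k + 1])
    flag <- flag | hit
  }
  tibble::tibble(gene_id = rownames(m), zygotic_flag = unname(flag),
                 zygotic_interval = unname(interval))
}

#' Blood-meal response class
#'
#' Compares ovary expression 24 hr post blood meal to the previtellogenic
#' ovary (zeros substituted by the pseudocount): `up` when the PBM/previt
#' ratio exceeds `bloodmeal_fold`, `down` when below its reciprocal,
#' otherwise `same`.
#'
#' @param em An `expression_matrix` with both ovary roles.
#' @param cfg A [screen_config()].
#' @return Tibble `gene_id`, `bloodmeal_class`.
#' @export
bloodmeal_class <- function(em, cfg = screen_config()) {
  m <- rpkm_by_role(em)
  miss <- setdiff(c("ovary_1_2", "ovary_24pbm"), colnames(m))
  if (length(miss) > 0) {
    abort(paste0("missing ovary role(s): ", paste(miss, collapse = ", ")),
          class = "ovascreen_config_error")
  }
  previt <- sub_zero(m[, "ovary_1_2"], cfg$pseudocount)
  pbm <- sub_zero(m[, "ovary_24pbm"], cfg$pseudocount)
  r <- pbm / previt
  tibble::tibble(
    gene_id = rownames(m),
    bloodmeal_class = unname(dplyr::case_when(
      r > cfg$bloodmeal_fold ~ "up",
      r < 1 / cfg$bloodmeal_fold ~ "down",
      TRUE ~ "same"
    ))
  )
}

#' Mean expression profile of a gene set
#'
#' Arithmetic mean RPKM per sample over a gene set, in the canonical
#' 11-role display order (restricted to the roles present).
#'
#' @param em An `expression_matrix`.
#' @param genes Non-empty character vector of gene ids.
#' @return Tibble `role`, `mean_rpkm`, ordered canonically.
#' @export
mean_profile <- function(em, genes) {
  if (length(genes) == 0) {
    abort("empty gene set", class = "ovascreen_domain_error")
  }
  m <- rpkm_by_role(em)
  miss <- setdiff(genes, rownames(m))
  if (length(miss) > 0) {
    abort(paste0("unknown gene(s): ", paste(utils::head(miss, 5),
                                            collapse = ", ")),
          class = "ovascreen_lookup_error")
  }
  sub <- m[genes, , drop = FALSE]
  mu <- colMeans(sub)
  ord <- intersect(sample_roles(), names(mu))
  tibble::tibble(role = factor(ord, levels = sample_roles()),
                 mean_rpkm = unname(mu[ord]))
}
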