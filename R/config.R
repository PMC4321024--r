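#' Screen configuration
#'
#' Collects every tunable threshold of the germline-specificity screen.
#'
#' @param fdr_strict Strict BH-FDR cutoff for the high-confidence gene set.
#' @param fdr_relaxed Relaxed BH-FDR cutoff for the extended set; must be at
#'   least `fdr_strict`.
#' @param bcv Biological coefficient of variation assumed for the
#'   replicate-free negative-binomial exact test; the NB dispersion is
#'   `bcv^2`. With single libraries per condition the dispersion cannot be
#'   estimated and must be asserted; 0.4 is a conventional value for
#'   biological replicates of non-model organisms.
#' @param pseudocount Value substituted for zero RPKM entries wherever an
#'   expression ratio is formed (substitution, not an additive offset).
#' @param fold_threshold Ovary-to-soma RPKM ratio above which a gene passes
#'   the fold filter (strict `>`).
#' @param embryo_min_rpkm RPKM in the 0-1 hr embryo below which an
#'   ovary-specific gene is flagged as likely follicle-cell derived (no
#'   maternal deposition).
#' @param zygotic_fold Fold increase between consecutive embryo time points
#'   that flags zygotic (embryo-genome) expression.
#' @param bloodmeal_fold Fold change between 24 hr PBM and previtellogenic
#'   ovary RPKM separating the up / same / down blood-meal classes.
#' @param require_ovary_up If `TRUE` (default) the FDR intersection keeps
#'   only genes up-regulated in the ovary in every contrast, not merely
#'   differentially expressed.
#' @param seed Integer seed recorded in run manifests.
#' @return A `screen_config` list.
#' @export
#' @examples
#' screen_config(fdr_strict = 0.001)
screen_config <- function(fdr_strict = 0.001,
                          fdr_relaxed = 0.01,
                          bcv = 0.4,
                          pseudocount = 0.1,
                          fold_threshold = 100,
                          embryo_min_rpkm = 1.0,
                          zygotic_fold = 2.0,
                          bloodmeal_fold = 2.0,
                          require_ovary_up = TRUE,
                          seed = 1L) {
  stopifnot(is.numeric(fdr_strict), is.numeric(fdr_relaxed))
  if (!(fdr_strict > 0 && fdr_strict <= fdr_relaxed && fdr_relaxed < 1)) {
    abort("need 0 < fdr_strict <= fdr_relaxed < 1",
          class = "ovascreen_config_error")
  }
  if (bcv < 0) abort("bcv must be >= 0", class = "ovascreen_config_error")
  if (pseudocount <= 0) {
    abort("pseudocount must be > 0", class = "ovascreen_config_error")
  }
  if (fold_threshold <= 0) {
    abort("fold_threshold must be > 0", class = "ovascreen_config_error")
  }
  if (embryo_min_rpkm < 0) {
    abort("embryo_min_rpkm must be >= 0", class = "ovascreen_config_error")
  }
  if (zygotic_fold <= 0 || bloodmeal_fold <= 0) {
    abort("fold parameters must be > 0", class = "ovascreen_config_error")
  }
  structure(
    list(
      fdr_strict = fdr_strict, fdr_relaxed = fdr_relaxed, bcv = bcv,
      pseudocount = pseudocount, fold_threshold = fold_threshold,
      embryo_min_rpkm = embryo_min_rpkm, zygotic_fold = zygotic_fold,
      bloodmeal_fold = bloodmeal_fold, require_ovary_up = require_ovary_up,
      seed = as.integer(seed)
    ),
    class = "screen_config"
  )
}

#' @export
print.screen_config <- function(x, ...) {
  cat("Germline screen configuration\n")
  for (nm in setdiff(names(x), "seed")) {
    cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  }
  cat(sprintf("  %-18s %d\n", "seed", x$seed))
  invisible(x)
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Keys mirror the
#' arguments of [screen_config()]; unknown keys are an error.
#'
#' @param path Path to the configuration file.
#' @return A `screen_config`.
#' @export
read_screen_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) {
    abort(paste0("malformed config line: '", lines[bad][1], "'"),
          class = "ovascreen_config_error")
  }
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- vapply(kv, `[[`, "", 2L)
  allowed <- names(formals(screen_config))
  unknown <- setdiff(keys, allowed)
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
          class = "ovascreen_config_error")
  }
  args <- lapply(seq_along(keys), function(i) {
    if (keys[i] == "require_ovary_up") as.logical(vals[i]) else as.numeric(vals[i])
  })
  names(args) <- keys
  do.call(screen_config, args)
}
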