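#' Negative-binomial probability mass
#'
#' NB mass parameterized by mean and dispersion `phi`, with variance
#' `mean + phi * mean^2`. `phi = 0` degenerates to the Poisson mass. This is
#' the noise model assumed throughout: with one library per condition the
#' dispersion cannot be estimated, so it is asserted as the square of a
#' biological coefficient of variation (BCV).
#'
#' @param y Non-negative integer count(s).
#' @param mean Positive mean.
#' @param phi Non-negative dispersion (`BCV^2`).
#' @param log Return log-probability.
#' @return Probability mass (or its log), vectorized over `y`.
#' @export
#' @examples
#' nb_pmf(0, mean = 1, phi = 0)   # exp(-1)
#' nb_pmf(2, mean = 2, phi = 0.16)
nb_pmf <- function(y, mean, phi, log = FALSE) {
  if (any(y < 0) || any(y != floor(y))) {
    abort("y must be a non-negative integer", class = "ovascreen_domain_error")
  }
  stopifnot(all(mean > 0), phi >= 0)
  if (phi == 0) {
    dpois(y, lambda = mean, log = log)
  } else {
    dnbinom(y, size = 1 / phi, mu = mean, log = log)
  }
}

nb_log_pmf <- function(y, mean, phi) {
  if (phi == 0) dpois(y, mean, log = TRUE) else dnbinom(y, size = 1 / phi, mu = mean, log = TRUE)
}

#' Replicate-free conditional exact test for two NB counts
#'
#' Two-sided exact test of differential abundance between two single
#' libraries. With observed counts `y1`, `y2` and library sizes `n1`, `n2`,
#' the common relative abundance under the null is estimated as
#' `p = (y1 + y2) / (n1 + n2)`, the two counts are modelled as NB with means
#' `p * n1` and `p * n2` and common dispersion `bcv^2`, and the p-value is
#' the sum of the conditional probabilities `P(Y1 = y | Y1 + Y2 = s)` over
#' every partition `y` of `s` whose conditional probability does not exceed
#' that of the observed partition (ties included; capped at 1). `s = 0`
#' returns 1 by convention (a gene observed in neither library carries no
#' information). With `bcv = 0` the conditional distribution is exactly
#' binomial(`s`, `n1/(n1+n2)`).
#'
#' Enumeration is exact over all `s + 1` partitions; for `s` above one
#' million the sum is restricted to a wide window around the conditional
#' mode (the excluded tail mass is far below double precision) and a message
#' is emitted.
#'
#' @param y1,y2 Observed counts (scalars or equal-length vectors).
#' @param n1,n2 Library sizes of the two samples.
#' @param bcv Biological coefficient of variation; dispersion is `bcv^2`.
#' @return P-value(s) in `[0, 1]`.
#' @export
#' @examples
#' conditional_exact_test(12, 0, 1e6, 1e6, bcv = 0.4)
conditional_exact_test <- function(y1, y2, n1, n2, bcv = 0.4) {
  stopifnot(length(y1) == length(y2), n1 > 0, n2 > 0, bcv >= 0)
  if (any(y1 < 0) || any(y2 < 0)) {
    abort("counts must be non-negative", class = "ovascreen_domain_error")
  }
  phi <- bcv^2
  s <- y1 + y2
  frac1 <- n1 / (n1 + n2)
  vapply(seq_along(y1), function(i) {
    si <- s[i]
    if (si == 0) return(1)
    mu1 <- si * frac1
    mu2 <- si - mu1
    if (si > 1e6) {
      inform(sprintf(
        "conditional_exact_test: s = %d > 1e6, windowed enumeration around the conditional mode",
        si))
      sd <- sqrt(si * frac1 * (1 - frac1) * (1 + phi * max(mu1, mu2)))
      lo <- max(0, floor(si * frac1 - 40 * sd))
      hi <- min(si, ceiling(si * frac1 + 40 * sd))
      y <- lo:hi
      if (y1[i] < lo || y1[i] > hi) {
        # observed partition is far outside the window: essentially all
        # conditional mass exceeds it, p ~ excluded tail mass ~ 0
        return(0)
      }
    } else {
      y <- 0:si
    }
    lp <- nb_log_pmf(y, mu1, phi) + nb_log_pmf(si - y, mu2, phi)
    lp <- lp - max(lp)
    pr <- exp(lp)
    pr <- pr / sum(pr)
    # ties included; tolerance keeps mathematically exact ties together when
    # the two pmf evaluations differ in the last ulp
    sel <- pr <= pr[match(y1[i], y)] * (1 + 1e-10)
    if (all(sel)) 1 else min(1, sum(pr[sel]))
  }, numeric(1))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: with `m` p-values sorted ascending,
#' `q_(i) = min_{j >= i} min(1, p_(j) * m / j)`, returned in input order.
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @return Adjusted values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0) || any(p_values > 1)) {
    abort("p-values must lie in [0, 1]", class = "ovascreen_domain_error")
  }
  p.adjust(p_values, method = "BH")
}

#' TMM effective library sizes
#'
#' Trimmed-mean-of-M-values scaling factors (30% trim on log-ratios, 5% on
#' average log-intensity) multiplied into the raw column totals, for use as
#' an optional alternative conditioning total in [run_contrast()].
#'
#' @param cm A `count_matrix`.
#' @return Named numeric vector of effective library sizes.
#' @export
tmm_library_sizes <- function(cm) {
  if (!requireNamespace("edgeR", quietly = TRUE)) {
    abort("TMM effective library sizes require the edgeR package",
          class = "ovascreen_config_error")
  }
  m <- count_mat(cm)
  f <- edgeR::calcNormFactors(m, method = "TMM")
  colSums(m) * f
}

#' Run one ovary-versus-other exact-test contrast
#'
#' Applies [conditional_exact_test()] gene-wise to the ovary column and one
#' off-target column, with BH-FDR across all genes of the contrast. The
#' log2 fold change is `log2` of the ratio of relative abundances with a
#' `(count + 0.5) / (N + 1)` guard so it stays finite for zero counts; its
#' sign is positive when the ovary relative abundance is the higher one.
#' Only the sign feeds the screen; the magnitude is reported for inspection.
#'
#' @param cm A `count_matrix` containing both roles.
#' @param other_role The off-target role to contrast against the ovary.
#' @param cfg A [screen_config()] (supplies `bcv`).
#' @param ovary_role Ovary role, default `"ovary_1_2"`.
#' @param libsizes Optional named library sizes (e.g. from
#'   [tmm_library_sizes()]); defaults to raw column totals.
#' @return Tibble with columns `gene_id`, `count_ovary`, `count_other`,
#'   `logfc`, `p_value`, `fdr`; attribute `contrast` names the comparison.
#' @export
run_contrast <- function(cm, other_role, cfg = screen_config(),
                         ovary_role = "ovary_1_2", libsizes = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  s_ov <- role_sample(cm$samples, ovary_role)
  s_ot <- role_sample(cm$samples, other_role)
  if (is.null(libsizes)) libsizes <- library_sizes(cm)
  m <- count_mat(cm)
  y1 <- m[, s_ov]
  y2 <- m[, s_ot]
  n1 <- libsizes[[s_ov]]
  n2 <- libsizes[[s_ot]]
  p <- conditional_exact_test(y1, y2, n1, n2, bcv = cfg$bcv)
  logfc <- log2(((y1 + 0.5) / (n1 + 1)) / ((y2 + 0.5) / (n2 + 1)))
  out <- tibble::tibble(
    gene_id = rownames(m),
    count_ovary = as.integer(y1),
    count_other = as.integer(y2),
    logfc = logfc,
    p_value = p,
    fdr = bh_fdr(p)
  )
  attr(out, "contrast") <- paste0(ovary_role, "_vs_", other_role)
  out
}
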