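#' Poisson concentration estimate from droplet counts
#'
#' In droplet digital PCR the template is partitioned into ~15,000-20,000
#' droplets; each droplet is read positive or negative after end-point
#' amplification. Under random partitioning the copies per droplet are
#' Poisson, so the mean copies per droplet is recovered from the negative
#' fraction: `lambda = -log(1 - positives / total)`. Concentration ratios
#' between assays are formed directly from lambda values (the droplet
#' volume cancels).
#'
#' @param positives Count of positive droplets (vectorized).
#' @param total_droplets Total accepted droplets.
#' @return Mean copies per droplet, `lambda >= 0`.
#' @export
#' @examples
#' ddpcr_lambda(5000, 15000)  # -log(2/3)
ddpcr_lambda <- function(positives, total_droplets) {
  if (any(total_droplets <= 0)) {
    abort("total_droplets must be positive", class = "ovascreen_domain_error")
  }
  if (any(positives < 0) || any(positives > total_droplets)) {
    abort("need 0 <= positives <= total_droplets",
          class = "ovascreen_domain_error")
  }
  if (any(positives == total_droplets)) {
    abort("all droplets positive: assay saturated, concentration not estimable",
          class = "ovascreen_saturation_error")
  }
  -log(1 - positives / total_droplets)
}

#' Per-individual target/reference concentration ratios from a wells table
#'
#' @param wells Data frame with columns `sample_id`, `assay` (`"target"` or
#'   `"reference"`), `positives`, `total_droplets`, `group`
#'   (`"transgenic"` or `"nontransgenic"`). One target and one reference
#'   well per individual.
#' @return Tibble `sample_id`, `group`, `ratio` (target lambda / reference
#'   lambda).
#' @export
ddpcr_ratios <- function(wells) {
  wells <- tibble::as_tibble(wells)
  need <- c("sample_id", "assay", "positives", "total_droplets", "group")
  miss <- setdiff(need, names(wells))
  if (length(miss) > 0) {
    abort(paste0("wells table lacks column(s): ", paste(miss, collapse = ", ")),
          class = "ovascreen_format_error")
  }
  bad <- setdiff(unique(wells$assay), c("target", "reference"))
  if (length(bad) > 0) {
    abort(paste0("unknown assay label(s): ", paste(bad, collapse = ", ")),
          class = "ovascreen_format_error")
  }
  wells$lambda <- ddpcr_lambda(wells$positives, wells$total_droplets)
  wide <- wells |>
    dplyr::select("sample_id", "group", "assay", "lambda") |>
    tidyr::pivot_wider(names_from = "assay", values_from = "lambda")
  if (anyNA(wide$target) || anyNA(wide$reference)) {
    abort("every individual needs one target and one reference well",
          class = "ovascreen_format_error")
  }
  if (any(wide$reference == 0)) {
    abort("reference assay with zero positives: ratio undefined",
          class = "ovascreen_degenerate_error")
  }
  wide |>
    dplyr::mutate(ratio = .data$target / .data$reference) |>
    dplyr::select("sample_id", "group", "ratio")
}

#' Knockdown percentage with a Welch test
#'
#' Knockdown of a target transcript in a transgenic line is summarized as
#' `100 * (1 - mean(transgenic ratios) / mean(control ratios))`, where each
#' individual contributes one target/reference concentration ratio (ratios
#' are averaged per group, not formed from group means). Significance is a
#' two-sided Welch unequal-variance t test on the per-individual ratios;
#' with 4-8 individuals per group this is the conventional robust choice.
#' Degenerate inputs where both groups are constant return p = 1 when the
#' constants agree and p = 0 otherwise.
#'
#' @param transgenic,control Numeric vectors of per-individual ratios.
#' @return Tibble with `knockdown_percent`, `p_value`, `mean_transgenic`,
#'   `mean_control`, `n_transgenic`, `n_control`.
#' @export
#' @examples
#' knockdown_percent(c(0.27, 0.27), c(1, 1))
knockdown_percent <- function(transgenic, control) {
  if (length(transgenic) == 0 || length(control) == 0) {
    abort("both groups must be nonempty", class = "ovascreen_domain_error")
  }
  m_t <- mean(transgenic)
  m_c <- mean(control)
  if (m_c == 0) {
    abort("control group mean is zero: knockdown undefined",
          class = "ovascreen_degenerate_error")
  }
  p <- tryCatch(
    t.test(transgenic, control)$p.value,
    error = function(e) if (isTRUE(all.equal(m_t, m_c))) 1 else 0
  )
  tibble::tibble(
    knockdown_percent = 100 * (1 - m_t / m_c),
    p_value = p,
    mean_transgenic = m_t,
    mean_control = m_c,
    n_transgenic = length(transgenic),
    n_control = length(control)
  )
}

#' Knockdown summary straight from a ddPCR wells table
#'
#' Convenience wrapper: [ddpcr_ratios()] then [knockdown_percent()] of the
#' transgenic group against the nontransgenic group.
#'
#' @inheritParams ddpcr_ratios
#' @return Tibble as in [knockdown_percent()].
#' @export
ddpcr_knockdown <- function(wells) {
  r <- ddpcr_ratios(wells)
  groups <- unique(r$group)
  miss <- setdiff(c("transgenic", "nontransgenic"), groups)
  if (length(miss) > 0) {
    abort(paste0("wells table lacks group(s): ", paste(miss, collapse = ", ")),
          class = "ovascreen_config_error")
  }
  knockdown_percent(r$ratio[r$group == "transgenic"],
                    r$ratio[r$group == "nontransgenic"])
}

#' Delta-delta-Ct relative quantification
#'
#' Standard ddCt: per sample `dCt = ct_target - ct_reference`; against the
#' single flagged calibrator `ddCt = dCt - dCt_calibrator`; the relative
#' quantity is `RQ = 2^(-ddCt)`, so the calibrator's RQ is exactly 1.
#'
#' @param measurements Data frame with columns `sample_id`, `ct_target`,
#'   `ct_reference`, `is_calibrator` (exactly one `TRUE`).
#' @return Tibble `sample_id`, `dct`, `ddct`, `rq`.
#' @export
#' @examples
#' ddct_fold_change(data.frame(
#'   sample_id = c("cal", "s1"), ct_target = c(20, 23),
#'   ct_reference = c(18, 20), is_calibrator = c(TRUE, FALSE)))
ddct_fold_change <- function(measurements) {
  m <- tibble::as_tibble(measurements)
  need <- c("sample_id", "ct_target", "ct_reference", "is_calibrator")
  miss <- setdiff(need, names(m))
  if (length(miss) > 0) {
    abort(paste0("Ct table lacks column(s): ", paste(miss, collapse = ", ")),
          class = "ovascreen_format_error")
  }
  if (anyNA(m$ct_target) || anyNA(m$ct_reference) ||
      any(!is.finite(m$ct_target)) || any(!is.finite(m$ct_reference))) {
    abort("Ct values must be finite", class = "ovascreen_format_error")
  }
  if (sum(m$is_calibrator) != 1) {
    abort("exactly one calibrator required", class = "ovascreen_config_error")
  }
  m$dct <- m$ct_target - m$ct_reference
  m$ddct <- m$dct - m$dct[m$is_calibrator]
  m$rq <- 2^(-m$ddct)
  m[, c("sample_id", "dct", "ddct", "rq")]
}
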