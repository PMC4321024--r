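# Shared fixture builders and the independent exact-test oracle.

# sample sheet with all 11 roles, sample ids distinct from role names
full_sheet <- function() {
  data.frame(
    sample_id = paste0("S", seq_len(11)),
    role = sample_roles()
  )
}

# small deterministic count matrix over all 11 roles
tiny_cm <- function(n_genes = 3, value = 10L) {
  sheet <- full_sheet()
  counts <- data.frame(gene_id = paste0("g", seq_len(n_genes)))
  for (s in sheet$sample_id) counts[[s]] <- rep(value, n_genes)
  as_count_matrix(counts, sheet)
}

tiny_lengths <- function(cm, length_nt = 1000L) {
  data.frame(gene_id = cm$counts$gene_id, length_nt = length_nt)
}

# expression matrix with prescribed per-role RPKM rows
em_from_profiles <- function(profiles) {
  sheet <- full_sheet()
  vals <- as.data.frame(profiles)
  names(vals) <- sheet$sample_id[match(colnames(profiles), sheet$role)]
  vals <- cbind(gene_id = rownames(profiles), vals)
  structure(list(rpkm = tibble::as_tibble(vals), samples = sheet),
            class = "expression_matrix")
}

profile_row <- function(...) {
  vals <- list(...)
  prof <- setNames(numeric(11), sample_roles())
  prof[names(vals)] <- unlist(vals)
  prof
}

# Independent brute-force oracle for the conditional exact test: direct
# log-gamma evaluation of the NB mass, exhaustive enumeration of the s + 1
# partitions, two-sided by summing conditional probabilities <= observed.
oracle_cond_p <- function(y1, y2, n1, n2, bcv) {
  s <- y1 + y2
  if (s == 0) return(1)
  phi <- bcv^2
  mu1 <- s * n1 / (n1 + n2)
  mu2 <- s * n2 / (n1 + n2)
  lg <- function(y, mu) {
    if (phi == 0) {
      -mu + y * log(mu) - lgamma(y + 1)
    } else {
      r <- 1 / phi
      pp <- r / (r + mu)
      lgamma(y + r) - lgamma(r) - lgamma(y + 1) + r * log(pp) +
        y * log1p(-pp)
    }
  }
  lw <- vapply(0:s, function(y) lg(y, mu1) + lg(s - y, mu2), numeric(1))
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  min(1, sum(w[w <= w[y1 + 1] * (1 + 1e-10)]))
}

# default synthetic dataset + screen, computed once and reused by the
# acceptance-level tests (generation and screening are deterministic)
default_screen_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- generate_dataset(default_gene_classes(), seed = 1L)
      scr <- run_screen(ds$counts, ds$lengths, screen_config())
      cache <<- list(ds = ds, scr = scr)
    }
    cache
  }
})
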