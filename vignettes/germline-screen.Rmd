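---
title: "Screening for germline-specific genes without replicates: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for germline-specific genes without replicates: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovascreen)
```

# The problem

Mosquito gene-drive and reproductive-biology work needs genes whose
expression is confined to the early (previtellogenic) female germline:
their promoters can drive maternal cargo into the oocyte, and their
transcripts are candidate maternal-effect targets. A practical screen for
such genes profiles a panel of developmental stages, sexes and dissections
by RNA-seq — here the eleven-sample design of four embryo windows, larvae,
pupae, adult males, adult females, 1–2 day previtellogenic ovaries, 24 hr
post-blood-meal (PBM) ovaries and the 24 hr PBM carcass — and asks which
genes are expressed in the previtellogenic ovary but not in samples that
lack female germline tissue.

The statistical difficulty is that such panels are typically sequenced with
**one library per sample**. Nothing can be replicated, so every inferential
step must be honest about what a single library can and cannot support.

# The exact test and its assumptions

Counts for a gene in two libraries are modelled as negative binomial with
variance $\mu + \phi\mu^2$. With no replicates $\phi$ cannot be estimated;
it is *asserted* via a biological coefficient of variation,
$\phi = \mathrm{BCV}^2$, with BCV = 0.4 as the default — a deliberately
conservative value of the order seen between true biological replicates in
non-model insects. Setting BCV lower (e.g. 0.1) treats almost all
between-sample variation as signal and inflates the candidate list; the
results should be read as conditional on the asserted BCV.

For observed counts $(y_1, y_2)$ with library sizes $(N_1, N_2)$ the null
relative abundance is $\hat p = (y_1+y_2)/(N_1+N_2)$ and the two counts are
$\mathrm{NB}(\hat p N_1, \phi)$ and $\mathrm{NB}(\hat p N_2, \phi)$. The
test conditions on the total $s = y_1 + y_2$ and sums the conditional
probabilities of every partition of $s$ that is no more probable than the
observed one (the usual two-sided exact-test convention, ties included).
Unequal depths are handled by conditioning with unequal NB means rather
than by quantile-adjusting the counts to a common library size as edgeR
does; the two approaches agree to machine precision when depths are equal
(this is checked against edgeR in the test suite) and are asymptotically
equivalent otherwise, while the direct conditioning is fully specified and
brute-forceable. Trimmed-mean-of-M-values (TMM) effective library sizes are
available behind `tmm_library_sizes()` for users who want edgeR's default
normalization in the conditioning totals; raw column sums are the default.

At $\mathrm{BCV} = 0$ the conditional law is exactly
$\mathrm{Binomial}(s, N_1/(N_1+N_2))$, which the tests verify, and a gene
with $s = 0$ carries no information ($p = 1$ by convention).

Numerical choices: partition probabilities are computed in log space and
normalized against the per-gene maximum, so no intermediate underflows;
tie comparison uses a relative tolerance of $10^{-10}$ because partitions
that are *mathematically* exactly tied (e.g. binomial ties at rational
success probabilities) can differ in the last floating-point ulp between
evaluation orders; when every partition qualifies the p-value is set to 1
exactly. Enumeration is exact over all $s+1$ partitions up to
$s = 10^6$; beyond that a wide window around the conditional mode is used
(excluded mass far below double precision) and a message is emitted —
never reached at the library sizes this design produces.

# The screen

Four contrasts compare the previtellogenic ovary to larvae, pupae, adult
males and the PBM carcass. Embryos are excluded because maternally
deposited germline transcripts would make germline genes look
"expressed" there; whole females are excluded because they contain the
ovary; the PBM ovary is excluded so that genes need not be exclusive to
the previtellogenic window. Benjamini–Hochberg adjustment is applied per
contrast, and a gene enters the strict (FDR ≤ 0.001) or relaxed (≤ 0.01)
set only if it meets the cutoff in **all four** contrasts. Boundary genes
(FDR exactly at the cutoff) are included. The intersection additionally
requires ovary-*up* direction (`logfc > 0`) in every contrast: a gene
called "differentially expressed" because it is *depleted* in the ovary is
not a germline candidate. This direction requirement can be disabled
(`require_ovary_up = FALSE`) for users who want the pure two-sided
intersection. The log fold change itself carries a
$(y + 0.5)/(N + 1)$ guard to stay finite at zero counts; only its sign is
ever used for screening.

The fold-ratio filter works on RPKM ($10^9 c / (N L)$, $L$ the summed-exon
transcript length in nt, no rounding). Zeros among the five values entering
the ratio are **substituted** by a pseudocount of 0.1 RPKM — substitution,
not addition, which matters for small nonzero values: a gene at 0.05 RPKM
keeps 0.05, it does not become 0.15. Ratios strictly above 100 pass. The
pseudocount is applied only inside ratio statistics, never at
normalization time, so the RPKM matrix itself has zeros exactly where
counts are zero.

Two refinements use the embryo time course:

* **Follicle-cell flag** — somatic follicle cells express genes in the
  ovary without depositing transcripts into the oocyte, so an
  ovary-specific gene with no 0–1 hr embryo signal is suspect. "No
  signal" needs a number; the default is RPKM < 1.0, a conventional
  detection floor for bulk RNA-seq, exposed as `embryo_min_rpkm` and
  recorded in the run summary. Flagged genes are removed from the final
  germline call.
* **Zygotic flag** — a purely maternal transcript decays monotonically
  across the embryo course; a rise of more than `zygotic_fold` (default
  2.0) between consecutive embryo points, with zero predecessors
  substituted by the pseudocount, marks zygotic (embryo-genome)
  expression. A fold rule replaces visual inspection to make the call
  testable and reproducible. Flagged genes are annotated with the first
  rising interval but **retained** — zygotic expression on top of a
  maternal profile does not disqualify a germline gene, and removing them
  would be arbitrary.

Genes are also classed `up`/`down`/`same` across the blood meal by the
PBM/previtellogenic RPKM fold (threshold 2.0, zeros substituted); this is
annotation only. The summary additionally reports what fraction of the
strict set keeps its worst off-target sample below 11 and 5 RPKM — the
maximum-over-samples reading, stated as such.

Testes and any other unsampled tissue are invisible to this design; the
final list is a first approximation to germline specificity, not a proof.

# The synthetic study

`generate_dataset()` draws counts from exactly the noise model the test
assumes: true per-sample RPKM profiles per planted class, converted to
expected counts $\mu = \mathrm{RPKM}\cdot L\cdot N/10^9$ and sampled
$\mathrm{NB}(\mu, \mathrm{BCV}^2)$. This is intentional: with a
well-specified generator, recovery failures indicate pipeline defects, not
model mismatch. A `misspecify_sd` option adds gene-wise log-normal
dispersion jitter for robustness exploration.

Default conditions (the study design the tests run under): 5,000 genes —
200 germline-maternal, 20 follicle-cell, 30 maternal+zygotic, 50
zygotic-only, 4,500 housekeeping, 200 silent; one library per role with
totals spread over 5–20 million reads; gene lengths uniform over
500–5,000 nt; ovary expression log-uniform 50–2,000 RPKM for germline
genes (the range spanned by validated ovary markers in real screens),
1–100 RPKM for housekeeping; maternal decay 0.5 per embryo step; off-target
leakage 0.2 RPKM for ovary classes; a log-uniform 0.25–4× blood-meal factor
mixes the up/down/same classes. The whole-female profile adds 0.3× the
ovary level to background, mirroring why that sample is excluded from
contrasts.

What the generator does *not* emulate: positional/GC bias, isoforms,
gene-wise dispersion structure, correlated genes, and count-generation
artifacts upstream of the matrix. Passing recovery tests therefore
demonstrates the pipeline's correctness under its own assumptions, not
performance on any particular real dataset.

`truth_expected_summary()` provides the analytic recovery baseline: it
evaluates the pipeline on the noise-free expected counts (rounded $\mu$)
and the true RPKM profiles, with no sampling, stating which planted genes
*should* pass each stage.

# Quantification modules

ddPCR concentration uses the Poisson estimator
$\lambda = -\ln(1 - \text{positives}/\text{total})$; saturated wells
(all positive) are an error, not infinity. Knockdown is
$100(1 - \bar r_{tg}/\bar r_{ctrl})$ over per-individual target/reference
$\lambda$-ratios — ratios are averaged per group, not formed from group
means, matching how per-individual measurements are reported; the
ratio-of-means alternative is a one-line change on the returned ratios.
The significance test is Welch's unequal-variance t test, a robust
conventional choice at 4–8 individuals per group; it is computed on the
returned per-individual ratios and can be swapped freely. Degenerate
constant groups return p = 1 (equal) or 0 (unequal) rather than erroring.

ΔΔCt follows the instrument convention: $\Delta Ct = Ct_{target} -
Ct_{ref}$ per sample, $\Delta\Delta Ct$ against the single flagged
calibrator, $RQ = 2^{-\Delta\Delta Ct}$, so the calibrator is exactly 1.
No amplification-efficiency correction is attempted.

The ortholog Venn partition consumes a user-supplied boolean membership
table (gene × taxon) for exactly three taxa; ortholog inference itself
depends on external database versions and is upstream. Genes absent from
the table count as outside all sets, with a warning.

# Problem sizes and verification

The test suite verifies the exact test against an independent brute-force
enumeration (direct log-gamma evaluation of the NB mass) for every
partition of every total up to 40 under two depth configurations and BCV ∈
{0, 0.4}, at tolerance $10^{-10}$; against the conditional binomial closed
form at BCV = 0; and against edgeR's exact test at equal depths. Null
calibration uses 5,000 simulated null genes at $\phi = 0.16$ (the rate of
$p < 0.05$ stays below nominal — discrete exact tests are conservative).
End-to-end recovery runs the full screen once on the default 5,000-gene
dataset; the same run backs the acceptance script. These sizes keep the
entire suite under a couple of minutes on a laptop core while leaving the
planted classes large enough for stable rate estimates.

# Known limitations

* All conclusions are conditional on the asserted BCV; there is no
  data-driven dispersion here by construction.
* RPKM with column-sum library sizes inherits composition effects between
  very different tissues; the TMM option mitigates this only inside the
  exact test's conditioning totals.
* The follicle-cell flag needs the 0–1 hr embryo sample and a detection
  threshold; both are design choices, and a gene maternally deposited
  below 1 RPKM would be wrongly flagged.
* Zygotic expression masked by abundant maternal transcript (no net rise)
  goes undetected, as it must in this design.
* The screen cannot see tissues that were not sampled.
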