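# ovascreen

Screens bulk RNA-seq data for **previtellogenic female germline-specific
genes** in mosquitoes (and comparable eleven-sample designs), and quantifies
transcript knockdown from droplet digital PCR and qPCR data. The package is
aimed at vector-biology groups hunting maternal germline promoters and
maternal-effect targets — for example as components of *Medea*-style gene
drive cassettes — from a single-replicate developmental RNA-seq panel.

## The design and the statistics

The expected input is one library for each of eleven samples: four embryo
time windows (0–1, 2–4, 4–8, 8–12 hr), larvae, pupae, adult males, adult
females, previtellogenic (1–2 day) ovaries, ovaries 24 hr post blood meal
(PBM), and the 24 hr PBM carcass with ovaries removed.

**Replicate-free exact test.** With one library per condition the NB
dispersion cannot be estimated, so it is asserted through a biological
coefficient of variation: φ = BCV², default BCV = 0.4. For a gene with
counts (y₁, y₂) in two libraries of sizes (N₁, N₂), the null relative
abundance is p̂ = (y₁+y₂)/(N₁+N₂), the counts are modelled as
NB(p̂N₁, φ) and NB(p̂N₂, φ), and the two-sided p-value sums the
conditional probabilities P(Y₁ = y | Y₁+Y₂ = s) over all partitions no more
probable than the observed one. The previtellogenic ovary is contrasted
against larvae, pupae, males, and the PBM carcass; embryos are excluded
(maternal deposition would mask specificity) and whole females are excluded
(they contain the ovary). Genes that are ovary-up with Benjamini–Hochberg
FDR ≤ 0.001 (strict) or ≤ 0.01 (relaxed) in **all four** contrasts form the
candidate sets.

**RPKM and the fold-ratio filter.** RPKM(g,s) = 10⁹·c/(N·L) with L the
summed-exon transcript length. A complementary filter computes
ovary RPKM / mean(four off-target RPKM), substituting 0.1 for any zero
among the five values, and keeps ratios > 100.

**Refinements.** Ovary-specific genes with essentially no 0–1 hr embryo
signal (RPKM < 1 by default) are flagged as likely follicle-cell derived
(somatic, not deposited) and removed from the final call; genes whose
embryo profile *rises* ≥ 2-fold between consecutive time points are
annotated as zygotically expressed but retained; each gene is classed
up/down/same across the blood meal.

**Quantification.** ddPCR concentrations come from the Poisson estimator
λ = −ln(1 − positives/total); knockdown is 100·(1 − mean ratio of
transgenic individuals / mean ratio of controls) with a Welch test. qPCR
uses standard ΔΔCt with RQ = 2^(−ΔΔCt). A three-taxon Venn partition
summarizes ortholog-group membership of the final gene set.

A synthetic generator (`generate_dataset()`) plants six gene classes
(germline-maternal, follicle-cell, maternal+zygotic, zygotic-only,
housekeeping, silent) under exactly this design, with a truth table for
end-to-end recovery testing.

## Worked example

```r
library(ovascreen)

ds  <- generate_dataset(default_gene_classes(), seed = 1)
scr <- run_screen(ds$counts, ds$lengths, screen_config())
scr
#> Germline-specificity screen
#>   genes tested:            5000
#>   strict FDR set (<= 0.001):  247
#>   relaxed FDR set (<= 0.01): 250
#>   ratio > 100:              234
#>   ratio set in strict set: 233
#>   final germline calls:    227
```

Of 5,000 synthetic genes, 250 were planted as ovary-expressed
(200 germline-maternal + 20 follicle-cell + 30 maternal-zygotic): 247 reach
the strict FDR set, 234 pass the >100-fold ratio filter, and the follicle
flag removes the 20 somatic genes, leaving 227 germline calls. Per-gene
detail and headline counts are tidyverse-friendly:

```r
head(tidy(scr)[tidy(scr)$germline_call,
               c("gene_id", "ovary_ratio", "bloodmeal_class", "fdr_larvae")], 3)
#>   gene_id  ovary_ratio bloodmeal_class fdr_larvae
#> 1 SYN00001       2508. down              5.07e-15
#> 2 SYN00002       5892. same              2.97e-17
#> 3 SYN00003        935.  same              1.37e-13
glance(scr)       # one-row summary
autoplot(scr)     # mean RPKM profile of the final set
```

Knockdown from per-individual ddPCR target/reference ratios:

```r
knockdown_percent(
  transgenic = c(0.16, 0.21, 0.18, 0.15, 0.20, 0.17),
  control    = c(0.62, 0.70, 0.55, 0.66, 0.71, 0.60))
#>   knockdown_percent  p_value ...
#> 1              72.1  1.39e-6
```

i.e. target mRNA reduced by 72% in the transgenic line (Welch p ≈ 1.4e-6).

A command-line front-end with `simulate`, `screen`, `quantify-ddpcr`,
`quantify-ddct` and `venn` subcommands lives at
`inst/cli/ovascreen.R`; every run writes a manifest (config snapshot, input
digests, seed) for reproducibility. Precomputed RPKM matrices in the
genes-by-samples TSV layout can be ingested directly with
`read_rpkm_matrix()` + `screen_from_rpkm()` when raw counts are not at
hand.

## Scope

Read mapping and count generation are upstream (counts are the interface);
GO annotation, ortholog inference, and transgenesis wet-lab protocols are
out of scope. See the methods vignette (`vignettes/germline-screen.Rmd`)
for the model assumptions, parameter defaults, and known limitations.
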