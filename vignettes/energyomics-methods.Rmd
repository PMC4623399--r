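---
title: "Statistical methods behind energyomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind energyomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(energyomics)
library(dplyr)
```

`energyomics` implements the statistical layer of a tri-omic comparison
between a high-ATP overexpression (OE) plant line and wild type (WT):
RNA-seq of two unreplicated libraries across the nuclear, mitochondrial and
chloroplast genomes; iTRAQ proteomics quantified as four replicate OE/WT
ratios per protein; and GC–MS metabolite, ATP/ADP/NADP(H) and qPCR panels
measured in replicate at three timepoints (0, 1 and 8 h after
illumination). This vignette explains each model, its assumptions, the
tunable parameters, and the numerical and design decisions — in the spirit
of the methods vignettes of DESeq2 or limma.

## RPKM quantification across three genomes

Transcript abundance is reported in RPKM,

$$\mathrm{RPKM} = \frac{10^9\,C}{N\,L},$$

with $C$ the reads on the gene, $N$ the library's total mappable reads and
$L$ the gene length in bp. Two choices are explicit because conventions
vary:

* **$N$ is the library's own total**, not a pooled total across libraries,
  and it may exceed the column sum of the count table (reads mapping
  outside the annotated gene set still count toward $N$). If no totals are
  supplied, `compute_rpkm()` falls back to column sums with a warning.
* **Rows are whatever the input is keyed by.** With transcript-level ids
  the tallies of `summarize_gene_types()` are transcript-level (a genome
  with alternative splicing has more transcripts than genes); collapsing to
  gene level is the caller's join.

Expression detection (`detect_expressed()`) uses an explicit threshold —
at least `min_count` reads in at least one library, default 1 — because
"detected" is a reporting convention, not a model quantity.

## The exact two-library Poisson test

With a single library per genotype there are no biological replicates, so
the test works from the Poisson model alone: reads of gene $A$ in each
library are Poisson, and conditional on the count $x$ in library 1 the
count $y$ in library 2 follows a distribution free of the unknown rate:

$$p(y \mid x) = \left(\frac{N_2}{N_1}\right)^{\!y}
\frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}},$$

the negative-binomial law with size $x+1$ and success probability
$1/(1+N_2/N_1)$. The two-sided p-value doubles the smaller tail: with
$S=\sum_{i=0}^{y} p(i\mid x)$ it is $2S$ when $S\le 0.5$ and otherwise
$2\sum_{i=y}^{\infty} p(i\mid x)$, clamped to $(0,1]$.

Numerical choices:

* **Log-space evaluation.** Factorials overflow beyond $x+y\approx 170$;
  terms are accumulated as cumulative sums of
  $\log p(i{+}1)/p(i) = \log\frac{r(x+i+1)}{(i+1)(1+r)}$ from a log-gamma
  starting point.
* **The smaller tail is always summed directly**, never computed as
  $1-S$: a p-value of $10^{-60}$ keeps full relative precision instead of
  collapsing into cancellation noise.
* **Upper-tail truncation is decay-aware.** Beyond the conditional mode,
  successive terms shrink at least geometrically by $r/(1+r)$; the series
  is run $\lceil 47/\log(1+1/r)\rceil$ terms past
  $\max(y,\mu+12\sigma)$, where the discarded mass is below $10^{-20}$ of
  the total.
* **Tail convention.** The upper branch *includes* the observed $y$
  (`upper_tail_includes_y = TRUE`), the proper discrete two-sided
  convention; it is slightly conservative. The variant excluding $y$ is
  exposed as a flag; it is exactly symmetric under swapping
  $(x,N_1)\leftrightarrow(y,N_2)$ — the doubled tails are complementary
  by the negative-binomial/binomial duality — whereas the conservative
  default differs from the swapped value by the observed point mass only.

Fold change is the ratio of library-size-normalized counts
$(y/N_2)/(x/N_1)$ (gene length cancels, so this equals the RPKM ratio),
with sentinels so extinction events stay callable: a gene with reads in
only one library gets fold change $0$ or $\infty$ and passes the filter —
a transcript whose expression collapses to zero in the OE line is the
clearest differential signal there is, not a missing value. Genes with
zero counts in **both** libraries are undetected: they are excluded from
testing and from the multiple-testing family rather than given $p=1$.

Calls combine Benjamini–Hochberg FDR ($q \le 0.001$) with a fold-change
filter ($>2$ genome-wide; organellar contrasts are conventionally rerun at
$>1.5$, and every 2-fold call is necessarily a 1.5-fold call). BH is used
for "the FDR method" because it is the standard step-up referent; it is
`stats::p.adjust` behind a validating wrapper.

The test assumes Poisson counts — no biological variance beyond sampling.
That is exactly what the synthetic generator produces by default, so
passing calibration tests here says the implementation is correct, *not*
that the Poisson model is adequate for biological replicates; with
overdispersed data the test is anti-conservative, which is why replicated
designs use negative-binomial GLMs instead (out of scope here). An
overdispersion knob (Gamma-mixed Poisson) exists in the generator for
robustness studies, default off.

## Tiered protein t-tests

iTRAQ quantification gives each protein four replicate OE/WT ratios (two
biological × two technical, treated as four independent replicates — the
same simplification the $n=4$, df$=3$ test itself makes). Identification
first requires an unused ProtScore $\ge 1.3$ and $\ge 2$ peptides at 95 %
confidence, both bounds inclusive.

Rather than testing against a no-change null of 1, each protein is tested
against three assumed fold-change tiers $\mu_0 \in \{1.2, 1.33, 1.5\}$
with a one-tailed one-sample t-test,

$$t = \frac{\bar{x}-\mu_0}{s/\sqrt{n}}, \qquad n = 4,\ \mathrm{df} = 3,$$

on the **arithmetic mean of raw ratios** (as the formula states; a
log-scale analysis would use the geometric mean and is left to the caller
via the ratio columns). A protein is `up` at a tier when
$\bar x > \mu_0$ and the upper-tail $p < 0.05$. Decisions made where the
convention was open:

* **Suppression null.** Down-regulation is tested against
  $\mu_0' = 1/\mu_0$ with the lower tail (reciprocal on the ratio scale,
  symmetric on the log scale): $0.833 = 1/1.2$ mirrors "1.2-fold change"
  for suppression. The alternative — lower tail against $\mu_0$ itself —
  is available as `down = "lower_tail"`.
* **No multiple-testing correction across proteins**: each protein is
  judged at raw $p<0.05$ per tier, the convention for tiered iTRAQ
  screens. Tallies of "significant" proteins must be read accordingly.
* **Zero-variance records are degenerate**: $t$ and $p$ are `NA`, the
  protein is never significant, and a message is logged.

Tier calls nest on the up side: for a protein whose mean clears the
highest tier, $p$ increases with $\mu_0$, so significance at 1.5× implies
it at 1.33× and 1.2×.

## Assay normalization and testing

* **GC–MS**: `value = peak_height / ribitol_height / fresh_weight` — the
  internal-standard (ribitol) response and the extracted fresh weight
  (about 50 mg) both divide out, giving a relative response per gram fresh
  weight. `relative_to_reference_group()` then divides by the WT 0 h mean
  per metabolite, so the reference group averages exactly 1 and the whole
  chain is invariant to rescaling all peak heights.
* **Energy panel**: ATP/ADP, ATP+ADP, NADPH/NADP⁺, NADP⁺+NADPH and
  ATP/NADPH are computed **per replicate, then summarized** as mean ± SD —
  preserving replicate-level variance — rather than as ratios of means
  (available via `ratio_of_means = TRUE`; the source convention is
  ambiguous and with $n=3$ the two differ). A zero-denominator replicate
  loses only that replicate's ratio.
* **Two-sample contrasts** default to Welch's unequal-variance t-test;
  referenced software defaults vary, so the pooled Student test is one
  argument away and with $n=3$ per group both are worth reporting.
  Stars follow `*` $p<0.05$, `**` $p<0.01$.
* **qPCR**: $\Delta Ct = Ct_{target} - Ct_{reference}$ per replicate
  (the reference gene playing the Actin-2 internal-control role),
  $\Delta\Delta Ct$ is the difference of group means, fold change
  $2^{-\Delta\Delta Ct}$; significance is a two-tailed **paired** t-test
  on per-replicate $\Delta Ct$, paired by replicate index (unequal group
  sizes are an error, not a silent drop). "Normalizing to the maximum
  level" is applied after the $2^{-\Delta Ct}$ transformation, per common
  practice; the largest group mean maps to 1.

## Category enrichment

PageMan-style enrichment runs two tests per functional bin against the
complement of the bin within the tested universe:

* **Fisher's exact test** (one-sided, upper tail) on the 2×2 table of
  DE × membership — overrepresentation of calls;
* **Wilcoxon rank-sum** (two-sided) on log2 fold changes — a shift of the
  whole category, significant or not gene-by-gene.

The exact rank-sum null is enumerated for bins of ≤ 10 members with
tie-free data; larger bins (or ties) use the normal approximation with tie
and continuity correction. A category is flagged at raw $P<0.01$ on either
test — no correction across categories by default, matching the raw-cutoff
convention; `adjust = "BH"` corrects each test family instead. Features
mapped to several bins count once per bin; mapped features missing from
the universe are dropped with a warning. The bin ontology is user data
(a two-column feature→bin table); `gen_category_map()` ships a synthetic
balanced ontology for testing, not a curated one.

## The synthetic experiment

`sim_config()` fixes the simulated study design; defaults mirror the
emulated experiment:

| parameter | default | meaning |
|---|---|---|
| `n_genes_by_compartment` | 23250 / 126 / 96 | nuclear / mito / chloroplast genes |
| `library_sizes` | 10⁷, 10⁷ | mappable reads per library (typical bulk RNA-seq depth; the emulated study reports totals only as "clean reads") |
| `gene_length_range` | 300–3000 bp | uniform; spans typical transcripts and exercises the $L$ term |
| `rpkm_log_mean`, `rpkm_log_sd` | 2, 1.5 | lognormal RPKM; median ≈ 7 RPKM, total expected reads just under the library size |
| `frac_de`, `log2_effects` | 0.1, ±2 | spike-in fraction and true effects |
| `n_proteins`, noise sd | 2611, 0.1 | candidate proteins; natural-log replicate sd |
| `frac_low_confidence` | 0.16 | fraction failing identification (≈ 2611 → 2195 kept) |
| `metabolite_cv`, `n_reps` | 0.15, 3 | replicate CV; triplicates |
| `qpcr_ct_noise_sd` | 0.1 Ct | additive well noise |

Counts are generated by inverting the RPKM equation into Poisson rates
$\lambda_{g,\ell} = N_\ell L_g \mathrm{RPKM}_g/10^9$, with
$2^{\delta_g}$ applied to the OE library for spiked genes — exactly the
model the exact test assumes, which is what makes the generator a
ground-truth instrument for calibration and power rather than a biological
simulator. What it deliberately does **not** model: biological replicate
variance, multi-mapping between homologous nuclear/organellar copies,
rRNA carryover, iTRAQ reporter-ion compression, GC–MS peak-picking
artifacts. Passing tests therefore validate the statistics, not the
upstream measurement process.

Each generator draws from its own RNG stream (`seed` plus a fixed
offset), so adding or reordering generators never perturbs the others,
and `floor(frac · n)` features — the first in a shuffled order — carry
effects cycled from the configured list. The energy-panel group means are
invented plausible values (nmol/g FW) with the OE line richer in ATP and
ATP/NADPH at every timepoint; they are synthetic stand-ins, not
measurements.

## Problem sizes and verification

The shipped tests and the acceptance script verify, among others: exact
agreement of the test with R's negative-binomial CDF over the full
$(x,y)\in[0,200]^2$ grid at three library ratios (max relative error
$\sim 10^{-12}$); pmf normalization to $10^{-12}$; null calibration on
20,000 simulated null genes with rates spanning 1–10⁴ (the discrete test
is conservative: $\hat P(p\le0.05)\approx 0.04$); realized FDR on a
10,000-gene experiment with 10 % of genes spiked 4-fold (zero to a few
false discoveries among ~850); ≥ 90 % recovery of true 2-fold proteins at
the 1.5× tier with ≤ 5 % null calls; byte-identical pipeline re-runs. The
simulation sizes were chosen so each Monte-Carlo bound (3 standard errors)
is decisive while the whole suite stays interactive.

## Known limitations

* The exact test's validity is conditional on the Poisson model; it has
  no defense against biological overdispersion.
* Arithmetic-mean ratio testing is scale-asymmetric (a 2× and a 0.5×
  protein are not mirror images in $t$); the reciprocal suppression null
  restores symmetry at the call level but not in the statistic.
* With $n=3$ replicates, Welch degrees of freedom can drop near 2 and
  both t-variants have little power; stars on assay panels are
  descriptive, not confirmatory.
* Enrichment treats bins as flat labels; the hierarchy in `a.b.c` names
  is not used for nested testing.
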