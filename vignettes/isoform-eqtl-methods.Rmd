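---
title: "Methods: isoform deconvolution, cis-eQTL mapping and regulatory prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isoform deconvolution, cis-eQTL mapping and regulatory prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette records the models behind `isoqtl`, the assumptions they make,
the tunable parameters, and the design choices taken where more than one
reasonable option existed.

## 1. Quantification by disjoint-region deconvolution

### Model

Transcript isoforms of one gene often share exons, so no single counting
region identifies each isoform. `isoqtl` works from *signature regions*: for
each isoform, the most 3′ exon (largest end on `+`, smallest start on `-`)
that is not carried by all isoforms of the gene, preferring exons unique to
exactly one isoform. "Carried" is decided by exon-level identity (identical
start and end): a 200-nt exon that is a prefix of another isoform's 280-nt
exon counts as two distinct candidate regions, and their overlap is resolved
downstream rather than during selection. A single-isoform gene contributes
its entire exon set.

The union of signature intervals is partitioned at every interval boundary
into *disjoint regions* — maximal segments with constant isoform membership.
Under a uniform per-base coverage model the expected count of region $j$ is

$$E[c_j] \;=\; L_j \sum_{i \in M_j} d_i,$$

where $L_j$ is the region length in nt, $M_j$ its member set, and $d_i$ the
per-base read density of isoform $i$ in that sample. Densities are recovered
per sample by non-negative least squares on the incidence matrix
$A_{ji} = L_j\,[i \in M_j]$ (densities are physically non-negative, hence
the constraint rather than a plain solve). The *deconvolved count* of
isoform $i$ is $d_i S_i$, where $S_i = \sum_{j: i \in M_j} L_j$ is its
signature length. For exactly determined systems this definition conserves
reads: summed deconvolved counts equal summed region counts within each
connected block of overlapping regions. RPKM is
$d_i S_i / (S_i/10^3) / (\mathrm{lib}/10^6)$ with `lib` the per-sample total
mapped reads.

### Assumptions and numerical choices

* **Uniform coverage within signature regions.** The length-proportional
  incidence matrix is exactly the uniform-coverage likelihood; 3′ bias, GC
  bias and positional effects are not modeled.
* **Counting modes.** A read overlapping $k>1$ disjoint regions is split
  $1/k$ to each (`fractional`, default); `any` duplicates it, `strict`
  drops it. Fractional counting preserves totals.
* **Degeneracy.** If two isoforms belong to exactly the same regions the
  incidence matrix is rank deficient and `deconvolve()` refuses, naming the
  confounded isoforms. An unconstrained solution more negative than
  $-10^{-8}$ triggers a warning before clamping; this threshold separates
  numerical noise from genuine model misfit.
* **Real-valued counts.** Deconvolved counts are not rounded; downstream
  log-CPM adds a prior count, so non-integer values are unproblematic.

## 2. cis-eQTL mapping

Expression features (deconvolved isoform counts, optionally gene-level sums
of them, and all background genes) are normalized with TMM (trimmed mean of
M-values; 30% trim on log-ratios, 5% on average intensity, reference = the
sample whose upper quartile is closest to the mean upper quartile, factors
scaled to geometric mean 1 — delegated to edgeR) and transformed to
$\log_2\!\big((c + 0.5)/(\mathrm{lib}\cdot f + 1)\cdot 10^6\big)$. Library
size is an explicit argument rather than always the column sum: mapped reads
outside the modeled features belong to it, and the scaled-pair identity
(factors $\{1/\sqrt2, \sqrt2\}$ when one sample doubles another at equal
library size) only holds with the mapped totals supplied.

Precision weights follow the voom recipe (per-feature linear fits on
log-CPM, lowess trend of $\sqrt{\text{residual sd}}$ against mean log-count
with span 0.5, predicted $\mathrm{sd}^{-4}$ as weights; limma's
implementation). Two guards are added: with fewer than 10 features the
mean-variance trend is meaningless and unit weights are used with a warning,
and predicted standard deviations are floored at $10^{-4}$ (weights capped
at $10^{16}$) so constant features cannot produce infinite weights.

The association model per feature and variant is weighted least squares of
log-CPM on intercept, alt-allele dosage in $[0,2]$ and covariates; the
dosage coefficient (log2 expression change per alt allele) is tested
two-sided with $n-p$ degrees of freedom, and p-values are BH-adjusted within
each feature family. Variant filters follow the stated conventions exactly:
cis window of 500 kb around the locus span with *inclusive* boundaries,
*strict* inequalities for minor allele frequency (> 0.05) and imputation
quality (> 0.8).

**Surrogate variables.** Hidden expression confounders are absorbed by the
top-$k$ principal components of the expression matrix after regressing out
known covariates (`residual_pcs`, deterministic sign convention, unit-norm
scores). This plays the role of surrogate-variable estimation but is
deterministic and directly testable. One practical rule matters: compute the
components on genes *outside* the cis locus under test. A strong cis effect
concentrated on a handful of features is itself a leading variance
direction, and a component that captures it will absorb the dosage effect
(we observed recovered betas shrinking from 0.5 to below 0.1 when locus
features were included at $k=5$). The default $k$ is left to the analyst;
simulations here use $k = 5$ for 200 background genes. Whether age joins sex
as a known covariate is configurable; both modes are supported.

## 3. LD proxies and regulatory candidates

Pairwise LD uses the haplotype-frequency definition
$r^2 = D^2/(p_A q_A p_B q_B)$ with $D = p_{AB} - p_A p_B$ when phased 0/1
haplotypes are available, and the squared Pearson correlation of dosages
otherwise; under Hardy–Weinberg equilibrium the two agree, which is asserted
by simulation. Proxy search keeps variants within ±200 kb of the index whose
r² exceeds the threshold in **every** panel (min over panels) — the
strictest reading of "high LD in all groups"; the index is always included.
The threshold comparison defaults to strict (`> 0.8`) with `>=` available,
since both conventions appear in common usage.

Positional classification assigns one label per SNV with priority
CDS > 3′ UTR > intronic > intergenic. Within the CDS the reference and
alternate codons are translated (strand-aware complement, standard genetic
code); a mismatch between the supplied CDS sequence and the VCF reference
allele is an error, not a silent reinterpretation. Exonic positions of
non-coding isoforms and 5′ UTRs fall into the `intronic` bucket — the label
means "inside the gene body without coding consequence" in this scheme.

Regulatory scoring is deliberately transparent: one point for DNase1
hypersensitivity, one for any enhancer/promoter histone mark (H3K4me1,
H3K4me3, H3K9ac), one for an intergenic position between the two target
genes; stable sort by score then position. It reproduces the logic by which
a single intergenic, DNase-accessible, mark-covered variant stands out of an
LD block, and is not intended as a general-purpose functional score.

## 4. Coexpression and gene-set enrichment

Coexpression is Pearson correlation on (optionally covariate-residualized)
log-CPM with the $t$-approximation p-value and BH adjustment; zero-variance
genes are dropped with a warning and the target excluded from its own list.
Enrichment uses the classic weighted Kolmogorov–Smirnov running sum: genes
ranked by a signed score (the correlation, by default), hits incremented by
$|s|^p / \sum_{hits} |s|^p$ (default $p = 1$; $p = 0$ gives the unweighted
statistic), misses decremented by $1/(N - N_h)$, ES = maximum deviation.
Where two positions deviate equally (within $10^{-9}$) the earlier rank
defines the ES — without an explicit tie rule, accumulation order makes the
sign of the result platform-dependent. Significance comes from gene-label
permutations (random same-size sets), comparing |ES| among permuted ES of
the same sign; NES divides by the mean same-sign |permuted ES|. Sample
permutation is unavailable in preranked mode by construction. Genes at
unadjusted p < 0.001 are exportable as the coexpression list
(`coexpression_hits`), threshold configurable.

## 5. The synthetic study

The generator emulates the structure the pipeline targets, with known truth
at every stage:

* **Locus.** Gene A: one isoform, two exons, minus strand (signature length
  1000 nt). Gene B, plus strand: a four-exon full-length coding isoform, a
  two-exon short coding isoform from a second TSS, and two lncRNAs from a
  third TSS whose first exons are 200/280-nt prefixes (alternative splice
  donor) joined to a last exon shared by all four isoforms. CDS intervals
  are multiples of three with planted codons so that specific variants are
  missense (G2S, P707L, S833Y) or synonymous (L900L) when classified.
* **Genotypes.** An index SNP at MAF 0.3; 10 proxies created by copying the
  index haplotype and flipping alleles with probability
  $f = (1-\sqrt{r^2_\mathrm{target}})/2$ (expected $r^2 \approx (1-2f)^2$
  at matched MAF; target 0.95); 10 independent decoys, two of them beyond
  the proxy window and one each below the MAF and quality filters. One
  analysis cohort (n = 200 diploid) and five reference panels (n = 100
  each) are drawn independently. This allele-flipping construction gives the
  pairwise LD needed to test proxy logic but no realistic haplotype
  structure, recombination gradient or population differentiation.
* **Expression.** Per sample, isoform density
  $d_i = b_i \cdot 2^{\beta_i g + \gamma_i Z + \varepsilon}$ with $g$ the
  index dosage, $Z$ a standard-normal latent factor (loading $-\gamma$ on
  gene A, $+\gamma$ on gene B isoforms, $\gamma = 0.15$ — the substrate for
  the inverse coexpression of the two genes), and
  $\varepsilon \sim N(0, 0.2^2)$ log2-normal noise. Default effects
  $\beta$: −0.5 (gene A), −0.3 (full-length coding), +0.3 (short coding),
  +0.5 (both lncRNAs) — the opposite-direction architecture, with baseline
  expression highest for the first lncRNA. 200 background genes carry no
  genotype effect; two 20-gene blocks load $\pm\gamma$ on the latent factor
  and seed the toy gene sets.
* **Reads.** Coverage is parameterized as mean depth (reads covering a
  base); read-start density is depth / read length (default 100× / 100 nt).
  Fragment counts per exon are Poisson with mean density × length, placed
  uniformly, and fragments are truncated at disjoint-region boundaries so
  that expected region counts equal density × region length exactly.
  Without truncation, fragment-length edge effects around regions shorter
  than a fragment (the 80-nt lncRNA tail) bias the deconvolution by tens of
  percent; real libraries do have such edge effects, which is a known gap
  between the simulation and real data. Boundary-spanning reads and the
  fractional counting rule are exercised by dedicated unit tests instead.
* **Determinism.** All draws derive from one master seed through a
  scrambling seed-derivation function; identical configurations give
  byte-identical output files. The scrambling is not cosmetic: deriving
  nearby Mersenne-Twister seeds for the genotype and expression streams
  produced measurably correlated streams and an inflated type-I error
  (9% at some seeds) until the derivation was hardened.

What passing on this generator does **not** establish: robustness to
coverage biases, junction reads, paired-end fragments, population structure
or relatedness, imputation dosage uncertainty (dosages are hard calls), or
the behaviour of surrogate-variable estimation on real confounding.

## 6. Problem sizes used by the test-suite and acceptance script

Simulated checks run at the study conditions: n = 200 samples, 100×
coverage, MAF 0.3, effects ±0.3/±0.5 log2 units, five panels of 100
individuals. Replicate counts are chosen for stable verdicts at reasonable
runtime: 100 replicates for effect-sign recovery, 500 (tests) / 300
(acceptance script) for type-I calibration, 1000 random instances for the
deconvolution and enrichment-score oracles, and a reduced 12-sample
configuration for byte-identity checks of every emitter.

## 7. Known limitations

* Signature selection assumes each isoform is distinguishable by at least
  one exon not shared by all isoforms; loci whose isoforms differ only by
  internal junction use need junction-aware methods out of scope here.
* Gene-level eQTLs are computed on summed isoform counts. Summing averages
  out counting noise, so the gene-level test statistic is *not* bounded by
  the strongest isoform statistic; it is bounded below by the weakest in
  practice and sign-dominated by the most abundant responsive isoforms.
* The prioritization score is a three-component integer; it does not weigh
  evidence sources or model tissue specificity beyond the input table.
* Permutation p-values are gene-label permutations; they ignore inter-gene
  correlation and are anti-conservative on strongly correlated sets.
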