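---
title: "Measuring and testing allele-specific expression with alleleflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and testing allele-specific expression with alleleflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alleleflow)
```

## The problem

A diploid individual heterozygous at a SNP carries a built-in controlled
experiment: both alleles of the surrounding gene share one nucleus, one
trans environment, and one library preparation, so a consistent departure of
their expression ratio from 50:50 — *allelic imbalance* — is evidence of
cis-acting regulatory variation. Measuring this in droplet single-nucleus
RNA-seq is harder than in bulk: each molecule is identified by a cell
barcode (CBC) and a unique molecular identifier (UMI), most reads never
touch a heterozygous site, duplicate reads of one molecule can disagree, and
alignment to the reference genome favors reference alleles (reference bias).

`alleleflow` implements the full path from tagged alignments and phased
genotypes to calibrated imbalance statistics, and pairs every stage with a
synthetic-data generator so the whole pipeline can be validated against
known truth.

## From reads to allele-resolved UMI counts

The counting model works on one alignment record per read (secondary and
supplementary records are dropped; multiplicity is judged from the `NH`
tag):

1. **Filters.** Reads with `NH > 1` (multimappers) and reads failing the
   WASP remapping filter (`vW` tag other than 1) are excluded. A read the
   filter never evaluated — no variant overlapped it — passes, but is
   necessarily unphased. This keeps UMI totals honest without letting
   reference-biased reads vote.
2. **Per-read haplotype call.** Each covered heterozygous SNP contributes a
   vote for haplotype 1 or 2 (or `NEITHER` for a third allele, which carries
   no information). A read is assigned to the majority haplotype only when
   it holds strictly more than 95% of the informative votes; at 19/20 votes
   (exactly 95%) the read is discarded as conflicted. Votes at unphased
   SNPs are excluded from this combination, because combining across SNPs
   is exactly what phase provides.
3. **UMI collapse.** Reads are grouped per (CBC, feature, UMI). If reads of
   one molecule assign both haplotypes, the UMI is *ambiguous*: it is
   reported, but never enters a test, since we cannot know which allele the
   molecule came from. Unassigned reads do not dilute an informative
   call — a UMI with one HAP1 read and three uninformative reads is a HAP1
   UMI. Only molecules with no informative read are *unphased*.

A read listing several features (overlapping genes, or a peak set)
contributes to each: the overlap is genuinely ambiguous and downstream
tests are per-feature, so per-feature contribution is the conservative
choice.

SNP-direct counting (`count_snp_level()`) repeats the same collapse per
(CBC, SNP, UMI) with each read voting only at the SNPs it covers, and
translates haplotype votes to reference/alternative alleles through each
SNP's own phase. It wastes the reads that miss variants, but it is the only
valid mode when genotypes are unphased — including genotypes called from
expression itself (`call_het_from_pileups()`, which keeps sites with depth
strictly above 10 and an alternative-allele fraction strictly inside
(0.1, 0.9)).

## Long reads and isoforms

Long reads need no aligner-side variant annotation: for each het SNP inside
the read's aligned segments, the query base at that reference position is
compared to the two alleles directly (`genotype_overlap_alleles()`). A SNP
under a small deletion is covered-but-absent and votes `NEITHER`; a SNP
under an intron skip (`N`) is simply not covered. Only an aligned query
base is evidence.

Isoform assignment builds one interval model per transcript (its exon
blocks) plus one *unspliced* model per gene spanning the whole gene body —
the pre-mRNA hypothesis. For each read (best alignment only; reads whose
maximum alignment score is tied are discarded), aligned blocks within 10 bp
are merged, candidate isoforms are trimmed to the read's genomic span, and
the overlap is the intersected length between trimmed exon blocks and read
blocks. A candidate survives only if the overlap reaches 95% of **both**
the trimmed-isoform length and the read length. The largest surviving
overlap wins unless another survivor comes within 10 bp, in which case the
read is unassignable.

The both-denominators rule is a deliberate design choice where the
lax alternative ("95% of either") was also defensible on wording: under
the lax rule the unspliced model, which always contains a spliced read's
blocks, reaches 100% of the read denominator for every read, survives, ties
the true isoform's overlap exactly, and the 10-bp margin then discards
every spliced read. The strict rule is the only reading under which a read
generated exactly from a transcript's exons is assigned to that transcript,
so it is the default; `require_both = FALSE` restores the lax variant.

## Cohort assembly

Gene-level counts are haplotype-labelled, and haplotype numbering is
arbitrary across individuals. To compare individuals at a query SNP, each
heterozygous sample's counts are *oriented*: the haplotype carrying the
SNP's reference allele becomes "ref" (phase `0|1` keeps hap1 as ref, `1|0`
swaps). Samples not heterozygous — or heterozygous but unphased — at the
query SNP are excluded, since they carry no (orientable) signal there. When
a gene holds several candidate SNPs, each SNP/gene pair is tested
separately. Ambiguous and unphased UMIs never enter the oriented columns.

Pseudobulking sums cell-level counts within (individual, cell type) before
modelling. The default cohort filter keeps features with more than 10
phased UMIs in more than 5 samples (both strict), the conventional
minimum for a stable beta-binomial fit.

## The statistical model

Oriented counts are modelled as beta-binomial with mean `mu` on the logit
scale and intra-class correlation `rho`:

$$k_i \sim \mathrm{BetaBinomial}(n_i,\ \mu_i,\ \rho), \qquad
  \mathrm{logit}(\mu_i) = x_i^\top \beta,$$

with beta shape parameters $a = \mu(1-\rho)/\rho$ and
$b = (1-\mu)(1-\rho)/\rho$; $\rho \to 0$ recovers the binomial. The
intercept-only model tests H0: `logit(ref fraction) = 0` (50:50). Fitting
is maximum likelihood on transformed parameters ($\beta$ free, $\rho$
through a logit link) with BFGS; p-values are Wald, from the observed
information. When $\hat\rho$ sits on its boundary the information matrix is
singular in that direction, so standard errors fall back to the
$\beta$-block (profile) information; degenerate data with every count on
one allele are flagged as boundary fits with `NA` p-values rather than
fitted. Effect sizes are reported on the logit scale of the reference
fraction; swapping ref/alt labels negates every effect and preserves every
p-value, a symmetry the test suite asserts.

Variants of the test:

* **Quasi-binomial** (`fit_quasibinom()`): binomial GLM estimates with
  Pearson-dispersion-scaled standard errors and t-reference p-values.
* **Mixed model** (`fit_betabinom_mixed()`): cell-level rows with a
  Gaussian random intercept per individual ($\sigma_b$), integrated out by
  a Laplace approximation — all per-sample inner modes are found
  simultaneously by a damped, vectorized Newton iteration, and the outer
  optimization warm-starts them. On simulated data the fit agrees with
  glmmTMB's beta-binomial family to ~4 decimal places (asserted in the test
  suite), while the implementation stays independent of it.
* **Permutation** (`permutation_pvalue()`): each of 1000 (default)
  permutations independently swaps $k_i \leftrightarrow n_i - k_i$ per
  individual with probability 1/2 and refits; the statistic is the
  intercept Wald z and the p-value uses the add-one estimator, so the
  smallest achievable value is $1/(n_{\mathrm{perm}}+1)$. Non-convergent
  permutation fits are redrawn up to a cap, then skipped and counted.
* **Differential imbalance**: the design gains a condition indicator
  (`~ condition`) and the condition coefficient is reported — a nonzero
  value means the allelic ratio differs between, say, cases and controls.
* **Peak vs gene**: two rows per sample (peak; gene minus peak) with a peak
  indicator. The comparison is standard; the specific statistic is this
  package's construction and the result is labelled `peak_vs_gene_bb`.

Multiple testing uses Benjamini–Hochberg within each stratum (cell type) by
default; `NA` p-values are propagated and excluded from the number of
tests.

### Calibration

`fpr_calibration()` measures the empirical false positive rate: each
replicate swaps ref/alt per (individual, feature) with probability 1/2 —
destroying any true imbalance while preserving depths and overdispersion —
runs the chosen test on every feature, and records the fraction with
p < 0.05. On the package's calibration design (200 features × 30
individuals, $\rho = 0.1$, depth ~100, true ratios mixed over
[0.3, 0.7]) the pseudobulk beta-binomial test's median fraction lands just
above 5%, i.e. approximately nominal: the swap construction produces a
symmetric two-point mixture rather than an exact beta-binomial, and the
Wald test with estimated $\rho$ at 30 samples is slightly anti-conservative.
The permutation test is calibrated by construction and is the conservative
choice when the ~1000-fold refitting cost is acceptable.

## The synthetic-data generators

`simulate_genotypes()` draws SNP sites shared across individuals on a toy
chromosome (1 Mb by default), each site heterozygous per individual with a
configurable rate and phase uniform over `0|1`/`1|0`; the VCF text it emits
round-trips through `load_genotypes()`. `simulate_annotation()` lays out
non-overlapping genes (alternating strands, 2–4 exons per transcript) with
an overlap switch for multi-feature reads. `simulate_tagged_reads()` draws,
per UMI, a gene, a haplotype from the gene's true reference fraction, and a
geometric number of reads (mean 1.5, echoing the roughly one-read-per-UMI
regime of non-selected libraries; a constant-count mode exists for
deterministic tests); reads are contiguous gene-body fragments whose bases
at covered SNPs carry the haplotype's allele, flipped to a random other
base at a configurable per-SNP error rate. Both short-read records
(pre-annotated votes, SAM text with `CB`/`UB`/`GN`/`NH`/`vW`/`vA`/`vG`
tags) and long-read records (query sequences for genotype lookup) are
emitted, with a per-UMI truth table. `simulate_betabinom_counts()`
implements the statistical model itself, including the random intercept and
a condition shift.

What the generators do *not* emulate — and hence what passing tests cannot
show about real data: reference bias (the WASP filter is consumed as a tag,
never simulated as biased alignment), barcode errors and doublets,
platform-specific error profiles (errors are uniform substitutions),
fragment-length and 3'-positional bias, and spliced short reads. Tests
passing here validate the bookkeeping and the statistics, not an aligner.

## Numerical choices and problem sizes

Internal coordinates are 0-based half-open everywhere; VCF (1-based) and
GTF (1-based closed) are converted at parse time. All thresholds follow
their stated wording: strict `>` for the 95% majority, `DP > 10`,
`0.1 < AD/DP < 0.9`, the `> 10 UMIs in > 5 samples` filter, and the
strictly-less-than-10-bp isoform margin; the bait-design coverage threshold
is `>= 10` ("at least"). SNP flank regions include the SNP base (width
261 bp for a 130-bp flank), and `<= 10 bp` gaps fuse read blocks. Tie-broken
cases resolve conservatively: a 50:50 vote split is unassigned, an exact
overlap tie is unassignable.

The test suite's simulation sizes are chosen to keep the full run in a few
minutes while leaving comfortable statistical margins: oracle equivalence
on >1500 simulated reads and 500 random isoform instances; Wald coverage
and mixed-model $\sigma_b$ recovery over 100 replicates each (200
individuals × depth 100, and 40 individuals × 50 cells respectively);
permutation uniformity over 200 features with 99 permutations each (p-value
granularity 0.01 is negligible against the Kolmogorov–Smirnov critical
value at n = 200); and the 100-replicate calibration harness at the design
above.

## Known limitations

* The mixed model assumes a single random intercept; random slopes and
  additional covariance structure are out of scope.
* Beta-binomial overdispersion is shared across observations of a feature;
  per-cell-type dispersion requires stratified runs.
* The peak-vs-gene statistic treats peak and rest-of-gene rows as
  conditionally independent given the indicator, ignoring their shared
  molecule pool; at typical depths the effect is negligible, but a peak
  containing most of a gene's counts leaves little information in the rest.
* Isoform assignment is winner-takes-all; reads compatible with several
  isoforms (within the 10-bp margin) are dropped rather than fractionally
  assigned.
* Orientation requires phased genotypes at the query SNP; unphased
  individuals are analyzable only SNP-directly.
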