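---
title: "Methods: sweep scans and blooming-time association in bloomsweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sweep scans and blooming-time association in bloomsweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

*Prunus mume* cultivars from different Chinese provinces bloom weeks apart,
and blooming time tracks the local chilling regime. Given whole-genome
resequencing data for a small panel of accessions stratified into early-,
mid- and late-blooming groups, two complementary questions arise:

1. Which genomic regions show the signature of selection associated with the
   blooming contrast — strongly reduced diversity in one group together with
   elevated differentiation between groups?
2. Which individual SNPs associate with the ordinal blooming phenotype once
   relatedness among accessions is accounted for?

`bloomsweep` implements the full analysis path from a multi-sample VCF,
a GFF3 annotation and a sample-to-group table to candidate sweep regions,
gene lists, LD-decay summaries and a kinship-corrected association table.
Because the motivating panel is small (19 accessions: 6 early, 5 mid,
8 late), every stage is also exercised against a built-in genotype simulator
with analytically known structure, so the statistical behaviour of the
pipeline can be verified without any external download.

## Data model and conventions

Genotypes are stored as alternate-allele dosages (0/1/2, `NA` for missing)
for biallelic SNPs only; multiallelic and non-SNP records are dropped at
ingestion, and half-calls such as `./1` are treated as missing — the
conservative reading when the upstream caller's behaviour is unknown. All
internal coordinates are 1-based inclusive; conversion to BED's 0-based
half-open convention happens only in the BED writer. Positions are strictly
increasing within a chromosome, which the window scan exploits via
cumulative sums.

## Per-individual diversity

For one diploid sample, with `n_sites` genotyped SNPs of which
`n_polymorphic` are heterozygous:

- observed heterozygosity `Hetobs = n_polymorphic / n_sites`,
- per-individual nucleotide diversity `pi = Hetobs / 2` (two haplotypes),
- inbreeding coefficient `F_IS = 1 − Hobs/Hexp`.

The `F_IS` convention deserves a note. Within a single diploid, every
polymorphic site is by definition heterozygous (`Hobs = 1`) and the
within-individual allele frequency at such a site is 0.5, so
`Hexp = 2 × 0.5 × 0.5 = 0.5` and `F_IS = 1 − 1/0.5 = −1` for every sample
that carries at least one heterozygous site. A fully homozygous sample has
no polymorphic site and the coefficient is undefined (reported `NA`). This
is the convention under which published per-accession tables report a
constant −1 column, and the package reproduces it exactly.

## The window scan

Statistics are computed in 50-kb windows sliding in 10-kb steps (both
configurable); the k-th window is `[10000(k−1)+1, 10000(k−1)+50000]`,
truncated at the chromosome end. Within a window:

- **Nucleotide diversity** per group:
  `pi = sum_sites [n/(n−1)] · 2·p·(1−p) / span`, where `n` is the
  non-missing allele count at the site and `p` the alternate-allele
  frequency. This equals the mean pairwise per-bp difference over
  haplotypes, which the test suite verifies by brute-force enumeration. The
  denominator is the full window span in bp, not the callable-site count:
  the input VCF carries variant sites only, so a callable-site denominator
  is not observable here, and the span matches how published region
  coordinates tile the 10-kb grid.
- **Watterson's theta** over the pooled contrast samples:
  `theta_W = S / a_{n−1} / span`, `a_{n−1} = sum_{i<n} 1/i`, with
  `n = 2 ×` (number of contrast samples). It is reported alongside pi; the
  log2 ratio below uses pi, the quantity the contrast is about.
- **F_ST** between the two groups: Weir–Cockerham (1984) variance
  components `a` (between populations), `b` (between individuals within
  populations) and `c` (within individuals), aggregated as a ratio of sums
  `sum(a) / sum(a+b+c)` over the window's sites. Slightly negative
  estimates are reported as computed. A Hudson-style estimator
  (ratio-of-sums of the Bhatia et al. 2013 per-site components) is
  available behind `estimator = "hudson"`; Weir–Cockerham is the default
  because it is the field's standard choice for windowed scans.
- **log2 pi-ratio**, oriented high-group over low-group (late over early):
  a sweep in the early/low group collapses its pi and produces a large
  positive value. `pi_low = 0` with `pi_high > 0` maps to `+Inf`, which is
  always in the right tail; a window with both diversities zero is
  unusable.

Sites missing in more than half of a group's samples are excluded from that
group's statistics (configurable); F_ST and the window's SNP count use sites
passing the rule in both groups. Windows with fewer than `min_snps = 10`
usable segregating sites are flagged unusable — with ~100 SNPs expected per
50-kb window at typical densities this only removes windows where a pi
ratio would be numerically meaningless.

### Thresholds and regions

Both scan statistics are thresholded at the empirical 5% right tail of the
usable windows, using the deterministic nearest-rank order statistic at
rank `ceiling(0.95·n)`; a window is significant only if **both** F_ST and
the log2 ratio strictly exceed their cuts. Using the joint (AND) criterion
means the expected significant fraction lies between ~0.25% (independent
tails) and 5% (perfectly dependent tails).

Overlapping or book-ended significant windows are merged into maximal runs;
each region records its absorbed window count and, given an annotation, the
genes whose closed intervals intersect it. A `min_length` post-filter is
exposed but defaults to 0: published region tables from this kind of scan
contain no region shorter than 100 kb even though a lone significant window
spans only 50 kb, which suggests an unstated minimum-length or
minimum-window filter upstream; rather than guess its value the package
calls every merged run and lets the user set the filter explicitly.

Sweep genes are then grouped into 1-Mb genome bins by gene midpoint, runs
of adjacent non-empty bins are merged into segments, and segments with no
more than five genes are discarded. The surviving gene sets are exactly
what an ontology-enrichment step would consume (enrichment itself is out of
scope — it needs an external GO database). The merge-adjacent-bins reading
resolves an ambiguity in how such segment rules are usually stated; the
bin width and gene-count threshold are both arguments.

## LD decay

With unphased genotypes, r² is the squared Pearson correlation of dosage
vectors over samples non-missing at both sites (composite LD). This is
deliberate: haplotype-EM r² assumes phase information the panel does not
have. All intra-chromosomal pairs within `max_dist = 500 kb` are pooled
into 10-kb distance bins (both configurable — no standard values exist for
this panel size, and the defaults cover the distances over which tree-crop
LD is typically examined). The half-decay distance is the smallest
distance, linearly interpolated between adjacent bin midpoints, at which
the mean-r² curve falls to half its maximum bin mean; it is `NA` when that
level is never reached, e.g. for unlinked data where the curve sits flat at
the `1/(n−1)` sampling floor. For large inputs pairs can be subsampled with
a fixed seed, which reproduces the curve to within Monte-Carlo noise.

## Association

SNPs and samples are filtered in a fixed, reported order: samples with call
rate < 80% are dropped first; then SNPs with missing rate > 10%, minor
allele frequency < 5% (with 19 accessions this removes exactly the
singletons and nothing else at the boundary: MAF ≥ 5% of 38 alleles means
minor-allele count ≥ 2), and Hardy–Weinberg exact-test p < 0.001. The HWE
test is the conditional exact test with the two-sided probability-mass
criterion and no mid-p correction, verified against full enumeration. Note
the direction: the conventional filter *excludes* HWE-violating SNPs. A
`literal_hwe` flag inverts the retention rule (keeping only p ≤ 0.001) for
comparability with pipelines that describe their filter with that wording,
but the default follows the convention.

The phenotype is the ordinal blooming code early = 0, mid = 1, late = 2 —
a deliberate choice where group-dummy coding would be an alternative; the
ordinal coding uses the natural ordering of the trait and yields one effect
per SNP.

The mixed model `y = mu + x·beta + u + e`, `cov(u) = sigma_g²·K`, uses the
standardized genomic kinship
`K = (1/m) sum_s (g_s − 2p_s)(g_s − 2p_s)' / (2p_s(1−p_s))` with per-site
mean imputation of missing dosages. K is eigendecomposed once; the variance
ratio `delta = sigma_e²/sigma_g²` is estimated by REML on the null model
over a 61-point log-spaced grid (`10^-5..10^5`) followed by local
refinement with `optimize()`; each SNP is then tested by generalized least
squares with the null variance components held fixed. This is the
EMMAX-style approximation — the same family of speedup FaST-LMM uses — and
it is exact when the SNP effect is small relative to the polygenic
background. Wald p-values use a t reference with n − 2 degrees of freedom,
so with `K = I` the results coincide with ordinary least squares to
numerical precision (a property the tests assert at 1e-8).

**Small-sample caveat.** At n = 19 the far tail of the Wald t reference is
not trustworthy: the permutation distribution of the test statistic is
discrete and the kinship correction consumes information the t reference
does not account for. Calibration checks (fraction of null p-values below
alpha; zero BH discoveries at FDR 0.01 on null phenotypes) are therefore
run at n ≈ 100 simulated samples, where the reference is accurate; results
on 19-accession panels should be read as hypothesis-generating, which is
also how such panels are used in practice.

Multiple testing uses the hand-implemented Benjamini–Hochberg step-up
(`q_(i) = min_{j≥i} p_(j)·m/j`), cross-checked against `stats::p.adjust`,
with discoveries declared at q ≤ 0.01. Significant SNPs are assigned to
every gene whose body extended by 2 kb on both sides (strand-agnostic)
contains the SNP.

## The genotype simulator

The simulator provides data with *known* population-genetic structure:

- Per site, an ancestral frequency `p ~ U(0.05, 0.95)`; early- and
  late-group frequencies drawn independently from
  `Beta(p(1−F)/F, (1−p)(1−F)/F)` — the Balding–Nichols model, mean `p`,
  variance `F·p(1−p)` — so the expected Weir–Cockerham F_ST between the
  groups is approximately `F`. Genotypes are `Binomial(2, p_g)`.
- The mid group's frequency is the equal-weight average of the two extreme
  groups' frequencies, mirroring its intermediate role; it is used by the
  association stage only, never by the scan contrast.
- Inside a sweep interval the swept group's frequency is replaced, with
  probability `intensity` per site, by a fixed allele (1 with probability
  `p`), collapsing that group's diversity and inflating local F_ST.
- An optional causal SNP adds `effect × dosage + N(0, noise_sd)` to the
  ordinal phenotype.

Defaults are fixed at the study design the pipeline targets: 6/5/8 samples
per group, F = 0.1 (the upper range of between-region differentiation in a
crop panel), one SNP per 500 bp, two 5-Mb chromosomes. The chromosome count
and length are desk-scale choices that still give ~1,000 windows per scan —
enough for a stable 5% empirical tail — and the acceptance analyses state
the sizes they use.

What the simulator does **not** emulate, and what that means for the tests:
there is no recombination map and sites are independent, so there is no LD
block structure (LD tests therefore check the *null* sampling floor and
determinism, not realistic decay shapes); the site-frequency spectrum is
uniform rather than neutral-coalescent, so pi/theta_W comparisons use an
explicit neutral-SFS construction (allele counts drawn proportional to
1/k) instead of the Balding–Nichols generator; there is no sequencing-error
or missingness model (tests add missingness explicitly where it matters);
and there is no demography. Passing tests demonstrate the estimators and
decision rules are correct on data satisfying their assumptions — they do
not certify behaviour on real resequencing data with LD, call-rate
artefacts and admixture.

## Numerical choices

- Empirical-tail cuts are nearest-rank order statistics: deterministic, no
  interpolation, and exactly reproducible across platforms.
- `+Inf` log2 ratios sort above any finite cut, so fully swept windows are
  always significant when their F_ST also clears its cut; thresholds
  themselves are computed from finite values only.
- HWE tie handling: probabilities equal to the observed one (within a
  1e-12 relative tolerance, guarding against floating-point
  representation) are included in the p-value, matching the enumeration
  oracle to 1e-12.
- Eigenvalues of K are floored at zero before forming GLS weights; a
  non-finite weight aborts with a diagnostic rather than returning garbage.
- Region merging treats book-ended windows (end + 1 = start) as one run,
  consistent with closed-interval semantics everywhere else; gene/region
  and SNP/gene overlap are closed-interval intersections, so a gene
  starting exactly one base past a region end is *not* assigned.
- Report files are written with fixed formatting (6 decimals for
  frequencies, no quoting) so byte-identical reruns are a testable
  contract.

## Known limitations

- The scan contrast uses exactly two groups; the mid group is never part
  of the diversity quantiles (a deliberate reading of how a three-group
  panel is used in a two-tail contrast).
- The association stage supports an intercept and one SNP at a time; no
  additional covariates.
- Watterson's theta uses the nominal haplotype count of the contrast
  samples rather than a per-site count under missingness; with the
  default missingness rule the difference is bounded by the 50% site
  exclusion threshold and vanishes on complete data.
- The LD stage reports composite dosage r² only; haplotype-based
  statistics (D', EM r², iHS, XP-EHH) are out of scope.
- Gene-set enrichment is out of scope; the segment reports are its
  prepared input.
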