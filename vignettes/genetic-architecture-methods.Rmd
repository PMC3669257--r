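---
title: "Methods: mixed-model GWAS and genetic-architecture statistics for inbred panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixed-model GWAS and genetic-architecture statistics for inbred panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`seqgwas` implements the analysis chain used in sequence-based association
studies of selfed (inbred) plant panels — for example a *Medicago
truncatula* diversity panel phenotyped for developmental and
nodulation traits in a greenhouse block design. This vignette explains the
statistical machinery, the assumptions behind each stage, and the design
choices that were genuinely open.

## Data model

Accessions are inbred lines, so genotypes are haploid-coded: 0 (reference
allele), 1 (alternate), or missing. Homozygous-diploid VCF calls
(`0/0`, `1/1`) are accepted and collapsed; a heterozygous call is treated
as a data error rather than silently dropped, because the inbred coding is
a contract every downstream stage relies on. Minor allele frequency (MAF)
is always computed over called genotypes only and lies in [0, 0.5].
Variants enter the association analysis when scored in at least 100
accessions with MAF at least 0.02 (both bounds inclusive; the MAF bound is
taken as inclusive where source descriptions vary between "at least" and
"greater than"). Missing genotypes are never imputed at the data layer;
each analysis stage decides its own handling and documents it.

## Phenotypes: block adjustment and variance partition

Phenotyping follows a randomized complete block design: one replicate of
each accession in each of (by default) 8 greenhouse blocks. All
association analyses use least-squares means per accession from the
additive fixed-effects model `value = accession + block` (no interaction —
with one replicate per cell it is inestimable), with a sum-to-zero
constraint on blocks so the LS mean of an accession is its prediction
averaged over blocks. Unbalanced data (germination failures, lost pots)
are handled by the normal equations of the observed design.

Flowering time is scored on up to 9 discrete dates; the encoder maps dates
to ranks 1–9 in chronological order and assigns never-flowered plants a
10th category, after which the score is treated as continuous with no
transformation.

The among-accession variance proportion is estimated by removing block
effects (same fit as above) and then applying one-way random-effects
method-of-moments on the block-adjusted values:
`sigma2_within = MS_within`, `sigma2_among = max(0, (MS_among −
MS_within)/n0)` with `n0` the standard unbalanced replicate coefficient.
Method-of-moments was chosen over REML here deliberately: it is
deterministic, closed-form, and checkable against a hand-computed oracle,
and the quantity is descriptive. Block effects are removed *before*
partitioning (the alternative order is defensible; this one is documented
and fixed). The estimate is truncated at zero and is invariant to affine
transforms of the trait.

## Kinship and the expedited mixed model

Relatedness is estimated as allele-sharing identity-in-state (IBS): the
proportion of sampled SNPs at which two accessions carry the same allele,
over pairwise-complete calls, using up to 5,000 randomly sampled SNPs per
chromosome. The estimator is bounded in [0, 1] with unit diagonal and is
deliberately simple and swappable. Pairwise-complete denominators can
make the raw matrix slightly indefinite, so it is bent when needed:
negative eigenvalues are clipped and the unit diagonal restored by
congruence rescaling. With complete data the estimate is returned
untouched.

The association model is the standard single-variant mixed model
\[ y = \mu + x\beta + g + e,\qquad g \sim N(0, \sigma^2_g K),\quad
   e \sim N(0, \sigma^2_e I), \]
fitted in the expedited (EMMAX/P3D) fashion: the variance components are
estimated once by REML under the null model (no SNP) and then held fixed
for every variant, reducing each test to generalized least squares under
\(V = \sigma^2_g K + \sigma^2_e I\). Numerical recipe: spectral
decomposition of \(K\) (and of the intercept-projected \(SKS\) for the
restricted likelihood), followed by a one-dimensional bounded search for
\(\log\delta \in [-10, 10]\), \(\delta = \sigma^2_e/\sigma^2_g\),
convergence tolerance 1e-8. With \(K = I\) the two components are not
separately identifiable — only their sum is — and every test reduces
exactly to ordinary least squares; this degeneracy is intentional and
tested.

Per variant, missing genotypes are mean-imputed to the variant's allele
frequency *for the scan only* (this keeps one global rotation; `n_used`
reports the true call count). The test statistic is t with n − 2 degrees
of freedom (equivalent to the 1-df F test). Each per-variant quantity is
computed from fixed precision-matrix products with one fixed-shape
matrix–vector product per variant, so scanning any subset of variants (an
*in silico* platform, say) reproduces the full scan bit for bit.

Diagnostics follow standard practice: quantile–quantile data against the
uniform expectation i/(m+1) and the genomic-control inflation factor
\(\lambda_{GC}\) (median association chi-square over the null median).
No structure covariates beyond \(K\) enter the model; a utility reports
the variance captured by leading kinship principal components, but PCs
are descriptive only.

## Candidates and architecture statistics

Because genome-wide multiple-testing correction is problematic at millions
of dependent tests, candidate sets are simply the top 50 or top 200
variants by p-value, with ties broken by ascending (chromosome, position)
so lists are deterministic and order-invariant. A Bonferroni adjustment
(`min(1, p·m)` with the test count `m` explicit) is available for
assessing individual top hits.

Architecture statistics on a candidate set:

* **LD structure** — pairwise \(r^2\) (squared Pearson correlation of call
  vectors over pairwise-complete accessions, invariant to allele
  recoding; pairs with fewer than 10 complete observations are flagged
  undefined), summarized as the proportion of candidates whose maximum
  \(r^2\) with any other candidate is below 0.8 and below 0.3.
* **MAF spectrum** — counts in the bins [0.02, 0.05), [0.05, 0.10),
  [0.10, 0.5] (left-closed; a MAF below 0.02 is a filter violation and an
  error), plus a permutation test comparing candidate mean MAF with the
  genome-wide mean and a one-way fixed-effects F test across traits'
  candidate MAF lists.
* **MAF–effect coupling** — Pearson correlation of MAF with effect size.
  Effect size is |beta|, the predicted phenotypic difference between the
  two variants of a 0/1 genotype; the signed-beta correlation is also
  reported for transparency. Negative coupling (rare alleles, larger
  effects) is the signature expected under mutation–selection balance.
* **Gene tagging** — a SNP inside a gene interval tags that gene;
  intergenic SNPs tag the nearest gene on the same chromosome (distance to
  the closest interval boundary, zero inside; equidistant ties resolve to
  the smaller start coordinate and are flagged). Gene intervals stand in
  for coding regions — the synthetic annotation carries no exon structure,
  a documented simplification. Hits within 10 kb of named genes are
  reported pair-by-pair, inclusive at the boundary.
* **Expression-specificity enrichment** — a gene is nodule/root-specific
  iff expressed in nodule and/or root and in no other assayed tissue;
  enrichment of specific genes among candidate-tagged genes is the exact
  upper-tail hypergeometric probability.

## Variance explained and the winner's curse

The top 50 candidates enter a multiple linear regression on accession
means, each SNP as a categorical predictor with levels {0, 1, missing} —
missingness as an explicit third state rather than imputed. The full
model is simplified by backwards stepwise AIC, removing at each step the
SNP (both of its indicator columns together) whose removal lowers AIC
most, until no removal lowers AIC. The implementation works on a
prebuilt numeric design with grouped drops — the classical
backwards-`stepAIC` algorithm, verified in the test suite to reproduce
`MASS::stepAIC` decisions exactly — because the permutation null below
reruns the selection hundreds of times and formula-interface refits would
dominate the runtime. Rank-deficient designs are handled by pivoted QR
(collinear candidates dropped and recorded); when the full model would
not be estimable the candidate list is pre-pruned from the bottom of the
p-value ranking, and the pruning is recorded.

Selecting predictors by their association with the phenotype and then
evaluating them on the same data inflates r² — the winner's curse, or
Beavis effect. The correction reruns the *entire* pipeline (scan,
candidate selection, stepwise regression) on R = 20 datasets in which the
phenotype vector is permuted over accessions after block adjustment,
leaving genotypes intact. R defaults to 20 and is configurable. These
permutations are approximate null expectations: to the extent the kinship
matrix enters the model, the data are not fully exchangeable. Assuming
the variance that true causal SNPs could explain is uniformly distributed
between the null mean r² and one, the adjusted proportion is
\[(r^2_{emp} - \bar r^2_{null}) / (1 - \bar r^2_{null}),\]
which may legitimately be negative. Under a *global* null — phenotype
fully independent of genotype — the adjusted value is centered on zero;
with a polygenic background the empirical r² genuinely exceeds the
permutation null (the permutation destroys the kinship–phenotype
covariance), so a positive adjusted r² there is signal, not bias. Each
null replicate also records the candidate MAF-bin profile and MAF–effect
correlations (top 50 and top 200), so empirical spectra can be compared
against selection-only expectations: on causal simulations the empirical
candidate spectrum shifts toward common alleles relative to the
randomized one.

## The in silico reduced-representation experiment

To quantify what a SNP-array study would have seen, platforms are designed
from a small discovery panel (default 26 deeply sequenced accessions):
panel MAF is computed on panel accessions only; SNPs with panel MAF
*strictly* above 0.10 are eligible; one eligible SNP is drawn uniformly
from each 1-kb window containing any; and filler SNPs are drawn uniformly
without replacement from the remaining *eligible* SNPs up to the target
size (the canonical design: 250,000 total over 224,339 windows, hence
25,661 fillers; when no target is given the same ~11.4% filler ratio is
applied to the simulated genome). Requiring fillers to pass the panel
filter is a documented choice — a design could equally draw them from all
SNPs — and is switchable by passing `panel_maf_min = 0`. If eligible SNPs
run out the platform is truncated with a warning, mirroring real designs
where fewer SNPs meet criteria than slots exist.

The platform scan applies the identical model and filters to the platform
subset, so shared SNPs carry identical statistics. Overlap is scored as
the number of top-20/top-50 platform candidates within 1 kb and 20 kb
(inclusive) of the nearest top-200 sequence candidate on the same
chromosome, aggregated min/mean/max over (by default 100) platform
replicates. The MAF-bias report bins, on the standard MAF bins: all
assayed SNPs, sequence candidates, platform candidates, and the sequence
candidates *tagged* by a platform (within 1 kb of any top-50 platform
candidate). Ascertainment from a small panel with a frequency floor
depletes the tagged set of rare variants — the central caution about
reduced-representation GWAS.

## The synthetic-data generator

The generator produces data with the statistical structure the analysis
assumes, plus ground truth for parameter-recovery tests:

* **LD blocks** — each chromosome is cut into blocks (default 3,000 bp,
  the typical LD scale in a selfing species); each block carries a pool of
  founder haplotypes (default 24) and each accession picks one founder per
  block, so founder-sharing accessions are identical within a block.
  Founder mosaics were chosen over a coalescent backend to keep exact
  control of block boundaries; a coalescent generator could sit behind the
  same contract.
* **Population structure** — founders have "home" subpopulations whose
  usage weight is boosted by `subpop_divergence` (default 0.5, giving the
  pronounced structure of a broad natural collection; at 1 subpopulations
  have nearly private founder pools). Admixture weights set subpopulation
  sizes.
* **MAF spectrum** — ancestral alternate-allele frequencies are drawn from
  Beta(shape, 10); the fixed second parameter suppresses the common tail
  so that the single shape knob controls the rare-allele skew. The default
  shape 0.12 was calibrated once so the post-filter spectrum has mean MAF
  near 0.09 at panel defaults, the genome-wide value typical of deep
  resequencing of a selfing species. Monomorphic sites are retained and
  removed by the variant filter, mirroring the real pipeline order.
* **Phenotypes** — replicate values are causal + polygenic + block +
  residual. Heritabilities are defined at the accession-mean level:
  `h2_causal` and `h2_polygenic` are the variance fractions of
  block-adjusted means given the configured replicate number, enforced
  exactly in-sample by rescaling; the replicate-level residual variance is
  `n_blocks * (1 - h2_causal - h2_polygenic)`. Effect magnitudes scale as
  \([p(1-p)]^{-\alpha}\) with random signs, so the MAF–effect correlation
  is tunable; causal variants are drawn from a configurable realized-MAF
  interval. The polygenic value is drawn with covariance proportional to
  the IBS kinship of the complete (pre-missingness) genotypes, which is
  recorded in the ground truth as the "true" kinship.
* **Missingness** — independent per call (default rate 0.2, matching a
  panel whose median variant is scored in ~80% of lines).
* **Annotation and expression** — genes tile chromosomes with gaps; a
  configurable fraction is nodule/root-specific.

What the generator does **not** emulate: sequencing reads and read-level
genotype error (calls are correct or missing, never wrong), recombination
within blocks, allele-frequency/missingness correlation, genotype–
environment interaction, and non-Gaussian trait distributions. Passing
tests therefore demonstrate correctness of the statistical machinery
under the stated model, not robustness to artifacts real data may carry.

## Numerical choices and degenerate inputs

* REML search on log delta in [−10, 10], tolerance 1e-8; eigenvalues
  clipped at zero after symmetrization; a kinship matrix with eigenvalues
  below −1e-6 (relative) is rejected.
* Variants monomorphic after imputation get NA statistics and are
  excluded from candidate selection.
* AIC is the Gaussian profile form `n log(RSS/n) + 2 edf` (the `stepAIC`
  convention); removals must improve AIC by more than 1e-8 to continue.
* Ties in p-values, equidistant genes, and window draws all have
  deterministic, documented resolutions, and every stochastic routine
  takes an explicit seed (the pipeline derives per-stage seeds from one
  master seed by stable hashing).

## Problem sizes

The test suite and pipeline examples run at desk scale, chosen so the
whole suite completes in a few minutes while leaving every statistical
property measurable: panels of 50–226 accessions, 4,000–20,000 simulated
variants (roughly 1,000–5,000 after filtering), 20-seed replication for
property tests, 20 permutation replicates for the null distribution, and
5–100 platform replicates for the array experiment. The defaults of the
generator itself (226 accessions, 8 chromosomes, 8 blocks, 26-accession
discovery panel, 5,000 kinship SNPs per chromosome, top-50/200
candidates, R = 20, 100 platforms) are the conditions of the emulated
study design.

## Known limitations

* The IBS kinship of a structured inbred panel has a compressed
  eigenvalue spectrum (high baseline allele sharing), so the REML
  variance ratio is weakly identified on some datasets; the scan is
  robust to this (it conditions on the fitted ratio), but interpreting
  `sigma2_g` in isolation is discouraged.
* P3D fixes variance components at their null estimates; for variants of
  very large effect this slightly misestimates standard errors relative
  to exact per-variant REML (full EMMA), a standard trade-off.
* The permutation null is approximate under kinship (non-exchangeability,
  flagged above and in the function documentation).
* Gene tagging treats whole gene intervals as coding regions; exon-level
  annotation is out of scope.
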