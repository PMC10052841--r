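---
title: "Methods: evaluating a forensic DIP panel with dipkit"
author: "dipkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating a forensic DIP panel with dipkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dipkit)
```

# Scope and data model

dipkit evaluates multiplex panels of biallelic deletion/insertion
polymorphisms (DIPs) for forensic use. Every statistic operates on
insertion dosage — the count (0, 1, 2) of insertion alleles an individual
carries at a locus — held in a `DipGenotypes` container
(`SummarizedExperiment` with a loci × samples `dosage` assay, a
`marker_class` per locus and population/continent/sex per sample). Only
`autosomal_dip` loci enter statistics; Y-chromosomal DIPs and the sex
locus are carried as metadata. Deletion frequencies are never stored:
they are `1 - pIns` by definition, which keeps every module consistent
under the I/D relabelling invariance that several tests assert.

Missing calls (`N/N`) are excluded locus-wise per computation (pairwise
deletion). They are never imputed, with one deliberate exception: PCA and
the classifiers need complete feature matrices, so dosages are mean-imputed
per locus there — the convention of genotype-PCA practice, and neutral in
the sense that an imputed sample sits at the centroid of the locus.

# Forensic parameters

Per locus with insertion frequency $p$, $q = 1-p$, diploid count $n$,
observed heterozygosity $h$, $H = 1-h$:

* $He = 2pq \cdot 2n/(2n-1)$ — the unbiased (small-sample corrected)
  expected heterozygosity. The correction matters at forensic sample
  sizes: at $p = 0.7146$, $n = 233$ the corrected value is 0.4088 where
  the uncorrected one is 0.4079.
* $PIC = 1 - (p^2+q^2) - 2p^2q^2$, maximal at $3/8$ for $p = 1/2$.
* $MP = \sum_g (c_g/n)^2$ over the three **observed** genotype
  frequencies, $PD = 1 - MP$. Observed rather than Hardy–Weinberg
  expected frequencies are used deliberately: that is what the standard
  forensic tooling (STRAF) reports, and the identity $PD = 1 - MP$ is then
  exact by construction.
* $PE = h^2(1 - 2hH^2)$ (trio exclusion), $TPI = 1/(2H)$; both depend
  only on observed heterozygosity. $h = 1$ makes TPI infinite and is
  flagged rather than silently propagated.

Cumulative indices multiply across loci. Because $CMP$ for a 57-locus
panel is $\sim 10^{-24}$, $CPD = 1 - CMP$ is indistinguishable from 1 in
double precision; the report path therefore carries $\log_{10} CMP$ and
renders the long decimal expansion of $CPD$ by digit-string subtraction
from the mantissa/exponent form ($10^D - s$ as a digit string). This
yields ~14 correct significant mantissa digits, ample for the 4–5 digits
such reports print, without an arbitrary-precision dependency.

# Hardy–Weinberg and linkage disequilibrium screening

The HWE test is the exact conditional test for biallelic markers: given
the minor-allele count, all admissible heterozygote counts (same parity)
are enumerated and the two-sided p-value sums the probabilities of all
outcomes no more likely than the observed one (probability-ordering
convention; stated explicitly because tail conventions differ between
implementations). This replaces the Markov-chain exact test of
Arlequin-style software: for biallelic loci, full enumeration is cheap and
deterministic, and the tail definition coincides. Monomorphic loci return
p = 1 by convention. A suite asserts agreement with an independent
factorial-enumeration oracle on every genotype configuration with
$n \le 50$, and conservatism (rejection rate at or below nominal) on data
simulated under equilibrium at $n = 233$.

The LD test estimates the four two-locus haplotype frequencies by EM —
the double heterozygote is the only ambiguous class; convergence
tolerance $10^{-8}$, at most 1000 iterations, allele-frequency margins
preserved exactly — and tests independence with
$G = 2(\ln L_{hap} - \ln L_{indep})$. Significance defaults to a
permutation test (one locus's genotypes permuted; the observed statistic
counted into the reference set, so $p \ge 1/(B+1)$), with the asymptotic
$\chi^2_1$ p-value always reported; the full-panel screen defaults to the
asymptotic p for speed across $\binom{57}{2} = 1596$ pairs. Bonferroni
thresholds are plain $\alpha/m$: $3.1328\times10^{-5}$ at
$\alpha = 0.05$ for 1596 pairwise tests, $8.77\times10^{-4}$ for 57
per-locus tests.

# Full-sibling likelihood ratios

The LR of "full siblings" versus "unrelated" at one locus uses the IBD
decomposition with $\kappa = (1/4, 1/2, 1/4)$ and Hardy–Weinberg genotype
probabilities; the one-IBD transition $T_1$ draws the shared allele
uniformly from the first individual's genotype and the companion allele
from the population. Loci are combined by summing $\log_{10}$ LRs,
justified by the panel's LD screen. Calibration is asserted analytically:
$E[LR \mid unrelated] = 1$ per locus to $10^{-12}$ over a grid of
frequencies.

The simulator is mechanistic rather than a κ-mixture shortcut: two
parents are drawn from HWE and each child receives one uniformly chosen
allele from each parent, independently per locus. The (0.25, 0.5, 0.25)
IBD pattern then *emerges* from Mendelian segregation — a property test
tracks labelled parental alleles and recovers κ within Monte-Carlo error —
and the same machinery generalises to other relationships.

The power study simulates `nPairs` (default 1000, the scale typical of
such validations) pairs per hypothesis and classifies with the
**inclusive** rule $LR \ge limit$ at limits 1, 10, 100, 1000, 10000. The
inclusive choice is made visible by a degenerate test: a panel with no
informative locus puts every pair at LR = 1, so accuracy and
false-positive rate are both 100% at limit 1. Accuracy and false-positive
curves are non-increasing in the limit by construction.

Because the genotype data such studies run on are typically not
releasable, `syntheticPanelFreqs()` provides a deterministic 57-locus
insertion-frequency profile: power-law spaced between 0.3283 and 0.7146
with the exponent solved (by `uniroot`) so the mean is 0.5045 — the
minimum, maximum and mean characteristic of these panels in East Asian
populations. On this profile the 1000-pair study lands near 98% sibling
accuracy at $LR \ge 1$ with a false-positive ratio near 2%.

# Population distances, informativeness and AMOVA

* **FST**: Weir–Cockerham (1984) variance components $a, b, c$ per locus
  from allele frequencies, sample sizes and observed heterozygosities;
  multi-locus $\theta = \sum a / \sum(a+b+c)$. The estimator is fixed to
  W&C so numbers are *comparable* (not identical) to AMOVA-based pairwise
  FSTs of other software. Negative estimates are retained in reports —
  they are legitimate near zero differentiation — and floored at zero
  (with a `clamped` flag) only for geometry-consuming stages.
* **DA**: $1 - \frac{1}{L}\sum_l(\sqrt{p_x p_y} + \sqrt{q_x q_y})$.
* **Informativeness for assignment** $I_n$: natural-log form with the
  unweighted across-population mean and $0\ln 0 = 0$; bounded by
  $\ln K$ and zero iff all populations share frequencies.
* **AMOVA** is computed on allele copies (each diploid contributes two
  insertion indicators), locus by locus, with the standard unequal-size
  expected-mean-square coefficients, in a two-level (among/within
  populations) or three-level (groups / populations in groups / within)
  design; variance components are summed over loci. The within-individual
  level is collapsed into the within-population term, matching the
  granularity these panel reports use. A consistency test checks
  two-level $\Phi_{ST} \approx$ pairwise $\theta$ to 0.01.

# Ordination and trees

Individual-level PCA features are centred, unscaled dosages; population
level uses frequencies (centring only — scaling would distort the
frequency geometry). Component signs are fixed by forcing the first
nonzero loading entry non-negative, so output is deterministic. MDS is
classical Torgerson scaling written directly on the eigendecomposition of
the double-centred squared-distance matrix; when fewer than the requested
dimensions have positive eigenvalues the remaining columns are
zero-padded with a warning. (The originating workflow's SPSS MDS variant
is unknowable; classical scaling is the canonical choice for metric
distance matrices and recovers planted configurations exactly, which the
suite asserts to $10^{-9}$ Procrustes residual.) NJ trees delegate to
`ape::nj` — standard Saitou–Nei agglomeration with a deterministic
internal tie-break — with negative branch lengths floored at zero per
mainstream tree-software convention and flagged.

# Biogeographic-origin classification

The contribution here is the evaluation protocol, not the learners: a
stratified holdout split (default 75/25 — consistent with the ~25%
holdout sizes such reports imply — under a fixed seed), library-default
hyperparameters for `randomForest`, `xgboost`
(`multi:softmax`, 50 rounds, single thread), `e1071::svm` and
`rpart`, and scoring by a predicted × truth confusion matrix with exact
Clopper–Pearson binomial CI on the accuracy (beta-quantile form; verified
against `binom.test` to $10^{-9}$). A single split rather than
cross-validation mirrors the reporting format being emulated; the split,
seed and sizes are recorded in the result. Chance-level behaviour under
permuted labels and near-perfect separability at continental
$F_{ST} = 0.15$ are asserted as sanity property tests, and a
five-class-style scenario with one admixed class (frequencies midway
between two others) checks that the admixed class absorbs the off-diagonal
mass — the qualitative reason accuracy drops when intermediate continents
enter the task.

# The synthetic-data generator

`makeDataset()` draws a hierarchical Balding–Nichols world: ancestral
insertion frequencies uniform on [0.3, 0.72] (the range these panels are
designed for — markers pre-selected for high polymorphism), continental
frequencies Beta-distributed around them at the continental divergence
$F$, population frequencies around those at the within-continent
divergence, and genotypes drawn under HWE within populations. Frequencies
are truncated to $[10^{-4}, 1-10^{-4}]$ so LR engines stay defined. The
defaults (34 populations: 13 East Asian, 7 African, 5 European, 5 South
Asian, 4 American; 142 diploid samples each) mirror a worldwide reference
collection of ~4800 individuals.

Calibration note: under this hierarchy, pairwise W&C $\theta$ between
populations from continents with divergences $F_1, F_2$ estimates
approximately $(F_1+F_2)/2$ plus the within-continent term (verified by
simulation in the test suite). The default divergences (Africa 0.30,
Europe 0.17, East Asia 0.05, America 0.09, South Asia 0.06; 0.009 within
continents) are chosen so that the synthetic pairwise-$\theta$ magnitudes
against an East Asian target population land near 0.18 (Africa), 0.11
(Europe), 0.07 (America), 0.06 (South Asia) and 0.01 (within East Asia) —
the magnitudes reported for worldwide DIP panels.

What the generator deliberately does **not** emulate: linkage (loci are
independent by construction — so passing LD screens on synthetic data
validates the test's null behaviour, not its power on real linked
markers), admixture and migration (every population is an independent
Balding–Nichols draw; real American and South Asian populations are
admixed, which is why their classifier behaviour on real data is harder
than the synthetic analogue), mutation, genotyping error and null
alleles. Passing tests on synthetic data therefore demonstrate estimator
correctness under the stated model, not robustness to those real-data
features.

# Numerical choices and degenerate inputs

* Products over loci always accumulate in log space (CMP, CPE via
  `log1p`, kinship LRs) to avoid underflow at 57 loci.
* Monomorphic loci: HWE p = 1; LD short-circuits with D = 0, p = 1 and a
  flag; LR engines exclude fixed loci with a warning; frequency tables
  flag them.
* EM for haplotype frequencies never decreases the likelihood (asserted)
  and stops at $10^{-8}$ or 1000 iterations.
* PHYLIP export truncates labels to 10 characters and refuses silent
  collisions unless `relaxedNames = TRUE`.
* All simulation entry points take an explicit integer seed; pipeline
  outputs are pure functions of (input, config, seed), and the manifest
  records seed, parameters, input hash and package versions.

# Problem sizes in the shipped suites

The test and acceptance suites run at desk scale by design: 1000 pairs
per hypothesis for kinship power (matching the scale of the emulated
study), 80–100 loci × 4–5 populations × ≤100 samples for FST/AMOVA
recovery, 10⁵-pair frozen oracle references computed once for the
balanced-panel kinship check, and full HWE oracle enumeration for all
genotype configurations up to n = 50. These sizes keep Monte-Carlo error
well inside the 3-standard-error bands the assertions use.

# Known limitations

* Only biallelic loci; no multi-allelic exact tests or haplotype phasing
  beyond the two-locus EM.
* Kinship module covers full-sibling vs unrelated only (no parent–child,
  mutation models, or linked-locus LRs).
* AMOVA assumes the allele-copy (haplotypic) distance; other molecular
  distance choices would shift percentages slightly.
* The classifiers use library defaults on purpose; no hyperparameter
  search or calibration analysis is attempted.
* Pairwise FST/DA values on synthetic data are comparability anchors for
  magnitude, not replications of any specific published matrix.
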