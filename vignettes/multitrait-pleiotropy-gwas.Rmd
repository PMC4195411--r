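---
title: "Multi-trait GWAS with GRAMMAR residuals, trait principal components and multivariate Bayes factors"
author: "pleioscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-trait GWAS with GRAMMAR residuals, trait principal components and multivariate Bayes factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`pleioscan` implements a complete two-step mixed-model association workflow
for several correlated quantitative traits measured on related individuals
— the situation of livestock mapping populations such as the QTL-MAS 2012
workshop benchmark (five 100-Mb chromosomes of equally spaced SNPs, three
traits with heritabilities around 0.55–0.66 and genetic correlations from
+0.84 to −0.43, and a handful of large pleiotropic QTL).  This vignette
describes the models, the tunable parameters, the synthetic-data generator
used for testing, the numerical choices, and the limitations a user should
know about.

## The polygenic animal model and GRAMMAR

Each scan phenotype (a trait or a principal-component score) is first
fitted with the intercept-only animal model

$$ y_i = \mu + a_i + e_i, \qquad
   a \sim N(0,\, A\,\sigma^2_a), \quad e \sim N(0,\, I\,\sigma^2_e), $$

where $A$ is the genomic relationship matrix.  `compute_kinship()`
estimates it as the SNP-averaged standardized allele sharing

$$ G_{ij} = \frac{1}{n}\sum_{k}
   \frac{(g_{ik}-p_k)(g_{jk}-p_k)}{p_k(1-p_k)}, $$

with the genotype on the allelic scale $g \in \{0, 0.5, 1\}$ (half the
allele count) and $p_k$ the sample allele frequency.  On this scale $G$
estimates kinship coefficients: the diagonal averages about 0.5 and full
sibs about 0.25.  The formula is invariant to which allele is called the
reference, so the major-allele convention is a labelling choice, not a
numerical one.  The familiar 0/1/2 coding with denominator $2p(1-p)$
(`coding = "vanraden"`) is exactly twice this matrix.  Because the two
codings differ only by scale, all model fitting routines first rescale the
matrix to mean diagonal 1 (`kinship_eigen()`); $\sigma^2_a$ is then on the
phenotypic-variance scale and $h^2 = \sigma^2_a/(\sigma^2_a+\sigma^2_e)$
has its usual meaning under either coding.

`fit_univariate_reml()` maximises the restricted likelihood through the
spectral decomposition of $A$: in the eigenbasis the covariance is
diagonal, the intercept and total variance profile out analytically, and
REML reduces to a one-dimensional search in $h^2$ (Brent search on
$[10^{-6}, 1-10^{-6}]$, tolerance $10^{-8}$; estimates within $10^{-4}$ of
an endpoint are flagged as boundary cases).  The decomposition is computed
once and reused across traits, principal components and permutation
replicates — this is what makes desk-scale permutation work affordable.
Standard errors come from the observed information at the optimum by
central differences; they are reported for orientation only and are not a
quantity the original variance-component software would reproduce exactly.

The second step regresses the mixed-model residuals

$$ y^*_i = y_i - (\hat\mu + \hat a_i)
         = \hat\sigma^2_e\, V^{-1}(y - \hat\mu) , \qquad
   V = \hat\sigma^2_a A + \hat\sigma^2_e I, $$

on each SNP's allele dose ($y^* = \mu^* + k\,g + e^*$), reporting the
per-dose effect, its standard error, the one-degree-of-freedom chi-square
$(k/\mathrm{se})^2$ and its nominal p-value.  The GLS identity above is
also the closed form the test suite checks the residuals against.  Since
the intercept is fitted by GLS, residuals are exactly zero-mean.

**Conservativeness.**  GRAMMAR residuals are *deflated* along genotype
directions: the BLUP removes not only family means but also part of any
SNP effect, because the tested SNPs themselves build $A$.  On polygenic
null data the scan's mean chi-square therefore falls below 1 (asserted in
the test suite), and genome-wide rejection rates fall below the nominal
level — the classical GRAMMAR behaviour.  Users who need exact per-SNP
tests should treat the scan as a screening step, as the original two-step
design intends.  See "Permutation significance" below for the practical
consequence.

## Bivariate REML for genetic correlations

Genetic and phenotypic correlations come from pairwise bivariate fits
(`fit_bivariate_reml()`), with additive covariance
$\Sigma_a \otimes A$ and residual covariance $\Sigma_e \otimes I$.  A
simultaneous three-trait fit would add cost without changing any quantity
used downstream (every reported number is a pairwise function), so the
three trait pairs are fitted independently.  In the eigenbasis of $A$ the
likelihood factorises over eigenvalues into 2x2 problems, making one
evaluation $O(n)$.  The two covariance matrices are parameterised by their
log-Cholesky factors, which enforces positive definiteness; optimisation
is Nelder-Mead from univariate-fit starting values (with two shrunken
restarts) followed by a BFGS polish, and a finite-difference gradient
check guards against silent non-convergence.  Phenotypes are standardised
internally, so the optimiser is indifferent to the wildly different trait
scales, and results are mapped back.  Estimates with $|r| > 0.999$ are
flagged as degenerate (boundary) fits.

`refit_with_snp_covariates()` re-runs the same fit with candidate SNP
doses as fixed effects, the standard way to ask how much of a genetic
correlation the identified loci explain.  Collinear covariate columns are
dropped with a warning; monomorphic ones likewise.

## Principal components as scan phenotypes

`trait_pca()` decomposes the *correlation* matrix of the traits — the
covariance matrix would be meaningless here because the traits differ in
scale by orders of magnitude.  Eigenvector signs are fixed by making each
component's largest-magnitude loading positive, so output is reproducible
across platforms.  Scores are z-scored traits projected on the
eigenvectors; their sample variances equal the eigenvalues and they are
mutually uncorrelated, identities the tests assert.  Components explaining
less than `min_share` (default 1%) of total variance are dropped by
`select_pcs()`; the default mirrors the practice of discarding a trailing
component with negligible variance, and the threshold is configurable
because the original analysis gave no number.  PCA is computed on the raw
phenotypes and the retained scores are then treated exactly like traits
(REML, residuals, scan); this follows the stated order of operations in
the workflow the package reproduces.

## Permutation significance and QTL regions

Genome-wide significance for each scan is empirical: residuals are
permuted across individuals (genotypes untouched, preserving LD and
marker structure), the full scan is re-run, and the maximum chi-square of
each of $B$ permutations (default 1000) forms the null.  The adjusted
p-value of an observed statistic $s$ is $(1 + \#\{\max \ge s\})/(B+1)$,
and the reported threshold is the statistic above which the adjusted
p-value is at most $\alpha$.  Each scan gets its own null, from an
independent, named substream of the master seed, so scans reproduce in
any order.  `B\alpha < 1` is rejected as undefined.

Because the procedure's null assumes exchangeable residuals, it is exact
for uncorrelated individuals (the suite verifies ~5% rejection on iid
residuals) but *conservative* for GRAMMAR residuals on a strongly related
population: the deflation described above pushes the genome-wide type-I
rate below the nominal 5% under the generator's default family structure.
This is a property of the two-step design, not of the permutation
machinery, and matches the original study's own caution that its
multiple-testing correction "might be too conservative" — we document it
rather than re-scale the statistics (genomic-control-style corrections
are out of scope).

Significant SNPs are merged into QTL regions by single-linkage chaining:
two hits on the same chromosome join one region when at most
`merge_distance` apart (default 10 Mb, with positions compared at 1e-6 Mb
tolerance).  Chaining at <=10 Mb is the reading of "a 10-Mb interval
around the significant SNPs" that reproduces the published count of ten
trait-level regions from the published hit coordinates (shipped in
`inst/extdata/` and returned by `reported_grammar_hits()`); the reported
interval is the member span widened by half the merge distance on each
side, clipped to the chromosome.

## The conjugate multivariate model and Bayes factors

For the joint test of all traits at one SNP, the three GRAMMAR residual
vectors are z-scored (`scale_residuals()`, denominator $n-1$) and modelled
as

$$ Y = C\,\beta^\top + E, \qquad
   E_i \sim N_q(0, \Sigma), \quad
   \beta \mid \Sigma \sim N(M, V\,\Sigma), \quad
   \Sigma \sim \mathrm{IW}(c, Q), $$

with $C$ the mean-centered dose (no intercept: the residuals are already
zero-mean; a model with explicit intercept is available by passing an
extra design column).  The coefficient prior is read as a matrix-normal
with *scalar* row covariance $V$ — the only reading of the prior that
stays conjugate — and the inverse-Wishart uses the standard
degrees-of-freedom parameterisation (density
$\propto |\Sigma|^{-(c+q+1)/2} e^{-\mathrm{tr}(Q\Sigma^{-1})/2}$,
requiring $c > q-1$).  Defaults are the conventional snptest-style choices
$c = 6$, $Q = 4 I_q$, $M = 0$, $V = 0.02$.

The marginal likelihood is the closed-form matrix-variate-t integral,

$$ p(Y) = \pi^{-nq/2}\,
   \frac{\Gamma_q((c+n)/2)}{\Gamma_q(c/2)}\,
   \frac{|Q|^{c/2}}{|S_n|^{(c+n)/2}}
   \left(\frac{|\Omega_n|}{|\Omega_0|}\right)^{q/2}, $$

evaluated via log-determinants and log-gamma functions
(`log_marginal_likelihood()`), and the Bayes factor compares the dose
model against the no-association null on the log10 scale — the scale on
which the published per-SNP values (3.8 to 10.3) are plausible.  The test
suite pins the formula against three independent oracles: brute-force
Monte-Carlo integration over prior draws on small fixtures, the scalar
normal-inverse-gamma closed form at $q = 1$, and the analytic $V \to 0$
limit in which the Bayes factor is exactly 1.  The whole-genome scan
(`mv_scan()`) uses the rank-one determinant-lemma form of the same
expression, so it is a few matrix products and provably identical to the
per-SNP route.

Classification thresholds (log10 BF >= 3 suggestive, >= 5 significant)
are package conventions in the spirit of the usual evidence grades; the
original figures drew such lines without printing numbers, so both are
mandatory configuration with documented defaults.

One behaviour worth understanding: with strongly correlated traits the
multivariate Bayes factor measures the effect vector in the
$\Sigma^{-1}$ metric.  When the trait correlation matrix is nearly
singular (as the emulated dataset's is: its determinant is about 0.01),
effect patterns pointing *along* the small-eigenvalue direction are
enormously amplified, and a single-trait effect can outrank an equally
powered pleiotropic one whose pattern lies in the bulk of the correlation
structure.  The classical "pleiotropy accumulates evidence across traits"
intuition — a pleiotropic locus beating an equally powered single-trait
locus — holds cleanly when residuals are approximately independent, and
that is the regime in which the package's pleiotropy-sensitivity test
operates (identity correlation matrices, heritabilities at their
defaults).

## The synthetic-data generator

No genotype data were deposited with the original study, so the package
ships a generator (`sim_config()`, `simulate_genotypes()`,
`simulate_phenotypes()`) whose *defaults are the study conditions*:

* **Map**: 5 chromosomes x 100 Mb, SNPs on an equal-spacing grid (2000
  per chromosome at full scale — the 0.05-Mb grid visible in the
  published coordinates; reduced sizes just coarsen the grid).
* **Population**: a founder pool of 80 haplotypes with reference-allele
  frequencies uniform on (0.05, 0.95); base-generation haplotypes are
  segment *mosaics* of the pool (mean segment 5 Mb), which creates local
  LD that decays on that scale while keeping the genotype space full
  rank; then 3 generations of random mating with recombination at
  1 cM/Mb (one expected crossover per 100-Mb chromosome per meiosis)
  build the family structure GRAMMAR exists to correct for.  The
  pedigree is recorded as an attribute.  A pool of `2n` haplotypes with
  zero generations yields an effectively unrelated sample.  The original
  population was pedigreed livestock of undisclosed size; n = 3000 at
  full scale and n = 1000 at test scale are package conventions, not
  facts about the source data.
* **Traits**: three phenotypes with heritabilities (0.56, 0.55, 0.66),
  genetic correlations (+0.84, −0.43, +0.11) and phenotypic correlations
  (+0.82, −0.44, +0.14).  Phenotypes are assembled on a standardized
  scale as QTL effects + polygenic values + residuals, then shifted and
  scaled per trait (defaults give the traits different orders of
  magnitude, as in the source data, which is why correlation-based PCA
  matters).
* **QTL**: seven loci on chromosomes 1–4 (none on 5) at the published
  peak positions, with per-allele effects of 0.13–0.27 phenotypic SD —
  sized from the published chi-square magnitudes (the largest statistic,
  about 57 at the original sample size, implies roughly 2% of variance
  explained; the others less), so each locus explains about 0.5–2% of
  phenotypic variance.

Two structural choices deserve explanation.  First, the polygenic draw
has between-individual covariance proportional to the *realized*
relationship matrix (rescaled to mean diagonal 1) rather than to a
pedigree expectation: the REML model is then exactly true for the
simulated data, which is what a parameter-recovery test should test.
Second, the polygenic covariance matrix is set to the *target total
genetic covariance minus the realized QTL covariance*, and the residual
covariance to the target phenotypic covariance minus the total genetic
covariance.  This makes realized heritabilities and both correlation
matrices match the configuration in expectation *including* the QTL
contribution — the alternative (imposing correlations on the polygenic
part only) lets large QTL drag the realized correlations off target.  A
configuration whose QTL variance exceeds the target genetic variance is
rejected as unreachable.

The published variance-component table is, as printed, *slightly
inconsistent*: the phenotypic-minus-genetic covariance gap has a smallest
eigenvalue of about −0.016 (both printed correlation matrices are nearly
singular).  The generator therefore clips residual-covariance eigenvalues
at a small positive floor; this moves realized phenotypic correlations by
roughly 0.01–0.02, well inside every tolerance used.

What the generator does **not** emulate: the undisclosed pedigree design
of the workshop data (litter structure, selection), sex or other fixed
effects, missing genotypes, genotyping error, and any MAF–effect-size
coupling.  Passing tests therefore demonstrate correctness of the
*methods* under a clean polygenic architecture, not robustness to every
property of real livestock data.

## Numerical choices

* Positions are carried in Mb end to end; base pairs exist only at the
  PED/MAP boundary (x 1e6).  Position equality uses a 1e-6 Mb tolerance.
* Relationship matrices are repaired to near-PSD by clipping eigenvalues
  at 1e-8 before factorisation; a warning is emitted when the clip is
  material.
* A kinship matrix numerically proportional to the identity is rejected
  (variance components would be unidentifiable).
* Degenerate regressions: a SNP monomorphic in the sample yields an NA
  record excluded from max statistics; a zero slope with zero residual
  variance is chi-square 0, a nonzero slope with zero residual variance
  is infinite.
* The QC report attributes a SNP failing both filters to the MAF rule
  (first-rule-wins), keeping the accounting identity exact; the HWE test
  is the 1-df Pearson chi-square, stated in the report so users know
  which test was applied.
* All randomness descends from one master seed through named substreams
  (`simulation`, one per scan's permutations), so stages rerun in any
  order reproduce byte-identically.

## Problem sizes used by the test suite

The suite favours a few deep, parameterised checks over many shallow
ones.  Simulation-backed checks run at: parameter recovery, n = 1000
with 2000 SNPs over 10 seeds; permutation calibration, 200 null
replicates at n = 200 with 2000 SNPs and B = 200; pleiotropy ranking,
10 seeds at n = 800; Monte-Carlo oracle fixtures, 1e6 draws at
n <= 8, q <= 3.  These sizes are the package's chosen desk scale; the
full-scale defaults (n = 3000, 10000 SNPs, B = 1000) run the same code
paths unchanged.

## Known limitations

* Exact per-SNP mixed-model tests (EMMAX/GEMMA-style), leave-one-
  chromosome-out kinship and genomic-control corrections are out of
  scope; the GRAMMAR scan is deliberately two-step and conservative.
* Univariate and pairwise-bivariate REML only: no repeated records,
  maternal effects, or arbitrary fixed-effect formulas (SNP covariates
  are the one supported fixed-effect extension).
* The Bayes-factor model is closed-form conjugate by design; there is no
  MCMC fallback, no missing-phenotype handling, and no imputation-dosage
  support.
* Individual-level QC (call rate, heterozygosity) is not implemented;
  the generator emits complete data and the readers mean-impute missing
  doses only for kinship.
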