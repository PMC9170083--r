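---
title: "Models and methods in hlaase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in hlaase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlaase)
```

# The generative model

Every analysis in this package is exercised against a
variance-components model of allelic HLA class I expression. For one
allele copy in one sample and condition,

$$\ln(\mathrm{tpm}) = \mu_{\ell} + \alpha_a + g_i + h_k +
  \underbrace{\left[\lambda_{\ell} + s_a\right]}_{\text{stimulated only}} +
  \sum_v \beta_v d_{iv} + \varepsilon$$

with $\mu_\ell$ the locus mean, $\alpha_a \sim N(0, \sigma_A^2)$ a fixed
effect of the allele *name* shared by all carriers (allele lineages have
characteristic expression), $g_i \sim N(0, \sigma_G^2)$ a factor shared
by both alleles of an individual (coordinated biallelic expression),
$h_k \sim N(0, \sigma_H^2)$ a founder-haplotype factor,
$\lambda_\ell$ the per-locus stimulation shift with per-allele deviation
$s_a \sim N(0, \sigma_S^2)$, $\beta_v d_{iv}$ planted cis-variant
effects, and $\varepsilon \sim N(0, \sigma_E^2)$ fresh per record and
condition.

All effects are on the **natural-log** scale. This makes the
allelic-balance statistic analytically tractable: within a heterozygous
individual, $\mu$, $g$ and the stimulation shift cancel, the
log-difference between the two alleles is
$d \sim N(0, 2(\sigma_A^2 + \sigma_E^2))$ (plus $2\sigma_S^2$ under
stimulation, and haplotype/eQTL terms where they differ between the two
haplotypes), and

$$\mathrm{ASE} = \frac{1}{1 + e^{|d|}}, \qquad
  \mathrm{median(ASE)} = \frac{1}{1 + \exp\!\big(0.6745\,
  \sqrt{2(\sigma_A^2 + \sigma_E^2)}\big)}$$

since the median of a half-normal is $0.6745\sigma$. The calibrations
used throughout follow from inverting this closed form:
$(\sigma_A, \sigma_E) = (0.10, 0.08)$ gives a median ASE of 0.4695,
$(0.23, 0.10)$ gives 0.4405, and $(0.06, 0.035)$ gives 0.4834. The test
suite verifies the simulated medians against this closed form at
100,000 heterozygous draws within ±0.005.

## Draw order and reproducibility

A single seeded stream drives each cohort, in a fixed documented order:
haplotype/allele assignment, per-allele effects (lexicographic allele
name order), per-haplotype effects, per-individual factors,
stimulation-specific allele terms. Measurement residuals are drawn at
expression time from a stream seeded by the cohort seed plus a fixed
per-condition offset, so conditions share $\alpha$, $g$ and $h$ (the
paired design) while residuals are independent, and any condition can
be re-simulated without disturbing the others.

Allele effects are shared per allele name by default; homozygotes
receive the same $\alpha$ twice with independent residuals. A
`"fresh"` mode draws an independent effect per carried copy instead —
with 15-ish alleles the shared mode realizes only a handful of distinct
$\alpha$ values, so large-sample closed-form checks use the fresh mode
where effect differences are i.i.d. normal.

## What the generator does and does not emulate

It reproduces: two alleles per individual per locus, fixed allele-level
expression, individual-level coordination, founder-haplotype structure
with marker LD arising purely from haplotype sharing (including coding
variants defined as markers carried exactly by the haplotypes bearing a
given allele), a multiplicative stimulation response, and planted
regulatory variants. It does **not** emulate read-level noise,
HLA-typing error, four-field allele resolution, recombination within
haplotypes, cell-composition effects, or individual-level variation in
the stimulation response (only allele-level deviation via $\sigma_S$ is
exposed; whether real cohorts vary by individual is not established).
Passing tests therefore demonstrate correctness of the statistics under
this structure, not robustness to artefacts absent from it.

## Default study shape

`demo_run_config()` fixes the simulated study at 63 individuals, three
expressed loci (a DRB1 column rides along in haplotype labels but has
no expression records), 15 alleles per locus on 30 founder haplotypes
(the most frequent at 12%, so its carriers can be grouped), 56
individuals with a stimulated condition, $\sigma_A = 0.10$,
$\sigma_G = 0.40$, $\sigma_H = 0.15$, $\sigma_E = 0.08$, stimulation
shifts $\ln(2.5), \ln(2.04), \ln(2.11)$ for A/B/C with
$\sigma_S = 0.10$ and reduced stimulated dispersion
$(\sigma_A, \sigma_E) = (0.06, 0.035)$, locus means 866/1870/1238 tpm
(entered as $\ln(\text{mean}) - \sigma^2_{tot}/2$, the lognormal
correction), one planted HLA-C regulatory variant ($\beta = 0.35$ per
dosage), 1000 permutations and a 5% FDR.

# The ASE statistic and its permutation null

`compute_ase()` is the lower-expressed allele's share of the pair
total. Homozygous individuals are **excluded** by default: their two
records carry the same allele name, so the ratio measures copies, not
alleles; a flag includes them as min-copy over total since the
convention used in published cohorts is not always stated.

The null of interest is "no within-individual coordination, given the
observed allele-level expression". `permute_within_alleles()` shuffles
the tpm values uniformly among all carrier slots of each allele name —
for the whole cohort simultaneously, independently per allele,
singleton carriers mapping to themselves — which exactly preserves
every per-allele tpm multiset (and hence allele means) while breaking
the pairing within individuals. `permutation_test_median_ase()` repeats
this `R` times, recomputes each locus' median ASE, and reports the
one-sided empirical p-value $(b+1)/(R+1)$ where ties (replicate medians
equal to the observed) count against rejection. Under the generative
model the permutation injects the shared-factor variance
$2\sigma_G^2$ into the allele-pair log-differences, which is why a
coordinated cohort ($\sigma_G = 0.40$) with an observed median near
0.47 faces a null median near 0.40 and yields the floor p-value at
$R = 1000$. With $\sigma_G = 0$ records are exchangeable within allele,
the test is exact, and the suite verifies a 5% ± 2% rejection rate at
$\alpha = 0.05$ over 400 seeded cohorts.

The paired comparison between conditions is the Wilcoxon
**signed-rank** test on per-individual ASE differences (a rank-sum test
cannot be paired, so that is the coherent reading of a "paired
Wilcoxon" analysis); zero differences are dropped, following Wilcoxon's
original treatment, and an all-zero difference vector returns p = 1.
Allele-pair correlations use Spearman's rank correlation with the
asymptotic t approximation, pairing each individual's
(lower-expressed, higher-expressed) alleles — a deterministic ordering,
since published scatter plots do not fix one.

# Expression summaries

Locus summaries are plain means and sample SDs over allele records.
Fold variation is the ratio of the highest to the lowest per-allele
central value (mean or median across carriers), with single-carrier
alleles flagged as low support rather than dropped. Stimulation fold
change is the **mean of per-record ratios**, not the ratio of means —
it matches per-allele reporting and, for lognormal residuals,
$E[\mathrm{stim}/\mathrm{unstim}] = e^{\lambda}e^{\sigma_E^2}$, which
the suite checks within 3%.

# Haplotype assignment and co-expression

`assign_haplotypes()` decomposes unphased genotypes against a reference
table greedily: one compatible reference haplotype is assigned with its
complement derived from the remaining alleles; when several are
compatible, a genotype explained *exactly* by one unordered pair of
reference haplotypes is resolved to that pair, and anything else stays
unresolved (a state, not an error). Expression is attributed to a
haplotype by allele name, so loci where an individual is homozygous are
skipped as ambiguous.

Inter-locus regressions are ordinary least squares of one locus' allele
tpm on another's, restricted to the alleles on the named haplotype;
the reported spread is the residual standard error
$\sqrt{RSS/(n-2)}$. `shared_vs_second_contrast()` computes, on the same
individuals (carriers of exactly one copy of the common haplotype),
that residual SE once with the shared haplotype's alleles and once with
each individual's second haplotype's alleles: a nonzero $\sigma_H$ (or
allele-effect variance on the heterogeneous second haplotypes) widens
only the latter. Both regression orientations are reported by the
pipeline since the choice of regressor per locus pair is a display
convention.

# The cis-eQTL stage

Variant QC applies, in a fixed logged order, MAF ≥ 1% (computed on
non-missing calls), missingness ≤ 2.5%, and a 1-df chi-square HWE test
at p ≥ 1e-5; filtering is idempotent. The chi-square test agrees with
exact enumeration within 2-fold where its approximation is valid (all
expected genotype counts ≥ 5, p not extreme); outside that regime a
chi-square can be badly anticonservative, which is the usual argument
for exact tests at rare-variant sites — the threshold here (1e-5)
mainly removes gross genotyping artefacts, where either test suffices.

Phenotypes are inverse-normal transformed via
$\Phi^{-1}((\mathrm{rank} - 0.5)/n)$ (average ranks for ties), then
residualized on covariates (intercept always included; rank deficiency
is an error, not a silent drop). PC covariates are prcomp scores of the
column-centered matrix, standardized. Missing dosages are mean-imputed
per variant inside the scan only — the stored matrix keeps its `NA`s.

The scan is a per-variant simple regression over the fully closed
window $[\mathrm{TSS} - 10^6, \mathrm{TSS} + 10^6]$ (1-based
coordinates; distance signs follow the strand, negative = upstream).
The best variant minimizes nominal p with ties broken by distance to
the TSS, then id. Gene-level significance permutes the phenotype $R$
times and takes each replicate's minimum nominal p as the null
statistic; the empirical p gets the add-one correction, and a
Beta$(a,b)$ fit to the null minima (method-of-moments start, bounded
L-BFGS-B maximum likelihood, minima clamped to
$[10^{-12}, 1 - 10^{-12}]$, moments fallback on non-convergence —
recorded in the result) smooths p-values below the $1/(R+1)$
resolution. A degenerate null (all minima identical) is an error.
FDR control is Benjamini–Hochberg on the beta-approximated gene
p-values — assumption-light where the permutation machinery's
alternative (Storey) requires a well-behaved p-value histogram; the
selection function is self-contained so a Storey variant can be swapped
in.

The genotype×stimulation interaction is fitted with fixed
per-individual intercepts. For a balanced two-condition paired design
this is exact and reduces to regressing the within-individual
difference (stim − unstim) on dosage: that slope is the interaction
effect, and with condition coded ±1/2 the stratified per-condition
slopes satisfy `slope = main ± interaction/2` identically (the suite
asserts both identities at 1e-12). This is a deliberate fixed-effects
realization of a mixed model — for this design the interaction point
estimate coincides, and no random-effects machinery is needed.
Genotype constant across individuals is an error (inestimable).

$\pi_1 = 1 - \hat\pi_0$ with
$\hat\pi_0 = \#\{p > \lambda\}/((1-\lambda)m)$ at a single
$\lambda = 0.5$, clipped to $[0,1]$; a grid-average flag
($\lambda = 0.2, \dots, 0.8$) is available, but the single-λ estimator
is kept as default for transparency since the exact published
configuration of the spline estimator is not stated. Recovery tests
plant non-null fractions $\{0.2, 0.34, 0.5\}$ at $m = 10{,}000$ with
alternative p-values drawn from Beta(0.02, 1) — a small-p distribution
whose mass above $\lambda$ (≈1.4%) keeps the estimator's bias well
inside the ±0.05 check.

LD is the squared Pearson correlation of dosage vectors on jointly
non-missing samples, verified against the population identity
$r^2 = D^2/(p_1 q_1 p_2 q_2)$ on exhaustively paired founder pools.
The expression-PC count is chosen by rerunning the full scan per
candidate k and keeping the k with the most FDR-significant genes,
smallest k on ties.

# Problem sizes and numerical tolerances in the checks

The test suite runs at desk scale by design: permutation calibration
uses 400 seeded 63-individual cohorts at $R = 199$ (the empirical
p-value is exactly uniform on its support, so $\alpha = 0.05$ is
attainable at that resolution); closed-form ASE checks use $10^5$
draws (±0.005); the planted-variant variance-explained check averages
10 cohorts of $n = 2000$ (a single draw has Monte Carlo SE ≈ 0.016,
wider than the ±0.02 band being verified); scan-uniformity uses 500
independent variants at $n = 300$ (KS p > 0.01); oracle-equivalence
checks run at 1e-10 (OLS) and 1e-12 (Spearman, LD identity). The
full demo pipeline (63 individuals, $R = 1000$) completes in seconds.

# Known limitations

- Haplotype assignment is combinatorial, not statistical: no EM
  frequency estimation, no phasing; ambiguous genotypes stay
  unresolved rather than being probabilistically resolved.
- The eQTL stage is single-signal per gene: no conditional or
  forward-selection analysis for independent signals, no trans scans,
  and no imputation.
- The beta approximation targets the null minimum-p distribution of a
  single gene's cis window; with very few polymorphic variants it adds
  little over the empirical p-value.
- Four-field allele nomenclature, read-level simulation and
  cell-surface (flow cytometry) analyses are out of scope; an external
  MFI table can only be correlated against, not modeled.
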