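# hlaase

Allelic expression balance and cis-eQTL analysis for HLA class I.

Each individual carries two alleles at every HLA class I locus (HLA-A,
-B, -C), and RNA-seq with allele-aware quantification yields one tpm
value per allele, sample and culture condition. Two questions drive the
analyses in this package:

1. **Is biallelic expression coordinated within individuals?** The
   allele-specific expression statistic for one individual at one locus
   is
   `ASE = tpm_low / (tpm_low + tpm_high)` — the lower-expressed
   allele's share, in (0, 0.5], with 0.5 perfect balance. Because
   allele lineages have characteristic expression levels, balance must
   be judged against an *allele-constrained* null: tpm values are
   shuffled among the carriers of each allele name (every individual
   keeps its typing), the per-locus median ASE is recomputed `R` times,
   and the one-sided empirical p-value is `(b + 1)/(R + 1)`.
2. **Do non-coding cis variants regulate expression?** A compact eQTL
   stage covers variant QC (MAF ≥ 1%, missingness ≤ 2.5%, HWE
   p ≥ 1e-5), rank-based inverse normal transformation, PC covariates,
   a ±1 Mb cis window scan, gene-level significance by phenotype
   permutation with a Beta-distribution approximation of the null
   minimum p, Benjamini–Hochberg selection, genotype×stimulation
   interaction tests on paired samples, Storey π1 replication
   estimates, and LD r² to the coding variants that define alleles.

The package also analyses cytokine-stimulation fold changes and
haplotype-level co-expression (inter-locus regressions restricted to
alleles carried on a shared haplotype), and it ships a
variance-components lognormal simulator:

```
ln(tpm) = mu_locus + alpha_allele + g_individual + h_haplotype
          + [stim shift + s_allele] + beta_v * dosage_v + epsilon
```

whose components (fixed per-allele effects, a shared per-individual
factor, per-haplotype effects, planted cis variants riding on founder
haplotypes) reproduce the statistical structure the analyses assume, so
every stage is testable without donor data.

## Worked example

```r
library(hlaase)

cfg    <- demo_run_config(seed = 1)        # 63 individuals, 3 loci, 30 founder haplotypes
cohort <- sample_cohort(cfg$generator)
expr   <- simulate_expression(cohort, "unstim")

locus_summary(expr, "unstim")
#>   locus  mean_tpm    sd_tpm   n
#> 1     A  873.5169  481.7954 126
#> 2     B 1812.5137  946.4295 126
#> 3     C 1753.3327 1097.3747 126

permutation_test_median_ase(expr, R = 1000, seed = 1)
#> Allele-constrained permutation test of median ASE (R = 1000, condition: unstim)
#>  locus  n observed_median_ase null_median empirical_p
#>      A 56              0.4427      0.3891    0.000999
#>      B 53              0.4593      0.3939    0.000999
#>      C 47              0.4619      0.3752    0.000999
```

The locus means track the configured targets (HLA-B highest). At every
locus the observed median ASE sits near 0.5 — coordinated biallelic
expression — while the allele-constrained null concentrates around
0.38–0.40, so no replicate reaches the observed balance and the
empirical p-value is at its floor, 1/1001. The shared individual factor
also shows up as a strong correlation between each individual's two
allele tpm values:

```r
spearman_allele_pairs(expr, "A", "unstim")
#> $rho     0.9322625
#> $p.value 1.656575e-25
#> $n       56
```

The full pipeline (simulate → summaries → ASE permutation test →
haplotype regressions → eQTL scan) runs from one configuration:

```r
run_pipeline(demo_run_config(seed = 1), "demo_out")
```

or from a shell: `Rscript inst/cli/hlaase.R --demo --out demo_out`.
Outputs are TSV/JSON/VCF files plus a manifest with md5 hashes;
rerunning with the same seed reproduces the hashes.

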