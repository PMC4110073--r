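# truncscore

Sequence-based annotation and pathogenicity scoring of protein-truncating
variants (stop-gains and frameshifts), for researchers triaging
loss-of-function calls in exome/genome cohorts or benchmarking variant
prioritization methods.

Truncating variants are not interchangeable: a premature stop that removes
95% of a protein, destroys an InterPro domain, hits an exon shared by every
isoform (including the APPRIS principal isoform), and sits more than 50 nt
upstream of the last exon–exon junction — the canonical trigger for
nonsense-mediated decay (NMD) — is a different object from one trimming a
few residues off one alternative isoform's tail. truncscore computes
exactly these six sequence features per variant, strand-aware, across all
isoforms of the assigned gene, and combines them in a naïve Bayes posterior
probability of pathogenicity:

$$
P(c=1 \mid y) = \frac{p_1 \prod_{k=1}^{K} L_k(y_k \mid 1)}
  {p_1 \prod_k L_k(y_k \mid 1) + (1-p_1) \prod_k L_k(y_k \mid 0)}
$$

with normal likelihoods (class means $\mu_1,\mu_0$, pooled intra-class
variance $\nu_k = E[(x_{ik}-\mu_{c_i,k})^2]$) for the continuous features
and Bernoulli likelihoods for the binary ones. Rankings are provably
invariant to the prior $p_1$. Around the score sit the standard evaluation
tools: pooled 75/25 subsampling ROC curves, a column-shuffle randomization
control, product combination with gene-level scores (including the logistic
map of a negated intolerance score), rank percentiles, an exact
Hardy–Weinberg filter, logistic MAF-trend regression with a heterogeneity
test, and carrier expression z-scores that check NMD predictions against
RNA-seq. A seeded generator fabricates every input (GTF, VCF, domain /
principal-isoform / score tables, expression matrix) with ground truth
attached, so the whole pipeline runs and is tested fully offline.

## Worked example

```r
library(truncscore)

fx  <- simulate_fixture(fixture_config(seed = 7), tempdir())
ann <- annotate_files(fx$paths[["genes.gtf"]], fx$paths[["variants.vcf"]],
                      domains_path   = fx$paths[["domains.tsv"]],
                      principal_path = fx$paths[["principal.tsv"]])
ann[1:3, c("variant_id", "gene_id", "fraction_affected_max",
           "domain_truncation_max", "ratio_isoforms_affected",
           "principal_truncated", "nmd_target")]
#>   variant_id gene_id fraction_affected_max domain_truncation_max
#> 1      V0001     G17                 0.977                     1
#> 2      V0002     G01                 0.350                     0
#> 3      V0003     G08                 0.967                    NA
#>   ratio_isoforms_affected principal_truncated nmd_target
#> 1                   1.000                TRUE       TRUE
#> 2                   1.000                TRUE       TRUE
#> 3                   0.667                TRUE       TRUE
```

V0001 truncates 97.7% of the protein, loses a domain completely, affects
every isoform and is predicted to trigger NMD — a pathogenic-looking
profile; V0003's `NA` domain truncation marks a gene without domain
annotation, imputed to 0 at classification time. Train and evaluate:

```r
lab <- as.integer(fx$truth$class[match(ann$variant_id,
                                       fx$truth$variant_id)] == "pathogenic")
X   <- impute_features(ann)[, names(truncation_features())]

roc <- roc_subsample(X, lab, iters = 500, seed = 42,
                     kinds = truncation_features())
roc
#> <roc_result> AUC = 0.8996 (12344 positives, 12656 negatives, 500 subsampling iterations)

randomization_test(X, lab, iters = 500, seed = 42,
                   kinds = truncation_features())$auc
#> [1] 0.483
```

The pooled held-out AUC of 0.90 is the classifier separating the planted
pathogenic-like from benign-like variants; shuffling each feature column
before every fit collapses it to chance (0.48), confirming the evaluation
loop leaks no labels. The expression check recovers the planted NMD effect:

```r
z  <- zscore_by_gene(fx$expression)
cz <- carrier_zscores(data.frame(variant_id = fx$truth$variant_id,
                                 gene_id = fx$truth$gene_id),
                      fx$variants, z)
nmd <- fx$truth$nmd_target[match(cz$variant_id, fx$truth$variant_id)]
median(cz$z[nmd]); median(cz$z[!nmd])
#> [1] -1.05
#> [1] -0.03
compare_groups(cz$z[nmd], cz$z[!nmd], "less")
#> [1] 1.4e-19
```

Carriers of predicted NMD targets express the affected gene about one
standard deviation below the cohort; NMD escapes sit at the cohort mean.

A command-line interface wraps the same functions
(`inst/cli/truncscore.R`): `simulate`, `annotate` (with the
`esp_frameshift_plus1` coordinate dialect for ESP-style tables), `train`,
`score`, `evaluate`.

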