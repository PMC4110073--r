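---
title: "Scoring protein-truncating variants from transcript structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring protein-truncating variants from transcript structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(truncscore)
```

Stop-gains and frameshifts are routinely collapsed into a single
"loss-of-function" category, yet their consequences range from complete
functional knockout to the benign trimming of a few terminal residues of one
minor isoform. truncscore scores each truncating variant from *where* it
falls in the transcript structure of its gene, producing a per-variant
posterior probability of pathogenicity and the population-genetics and
expression analyses needed to evaluate such a score.

## The sequence features

Every variant is mapped, strand-aware, from its genomic coordinate to a
spliced CDS coordinate on each isoform of its gene (`genomic_to_cds()`).
Both variant classes are modeled as truncating the protein from the codon
containing the variant position onward; for frameshifts that position is the
base of the insertion/deletion event (ESP-style tables report the base
before it, hence the `esp_frameshift_plus1` reader dialect). No downstream
scan for a new stop codon is attempted — no nucleotide sequence is modeled,
and the positional features are deliberately identical for the two classes.

Six features summarize a variant across the isoforms of its gene:

| feature | kind | definition |
|---|---|---|
| `fraction_affected_max` | continuous | max over affected isoforms of (residues at/after the truncation codon) / protein length |
| `domain_truncation_max` | continuous | max over domains and affected isoforms of the fraction of domain residues lost |
| `n_isoforms` | continuous | number of annotated isoforms of the gene |
| `ratio_isoforms_affected` | continuous | fraction of isoforms whose CDS contains the position |
| `principal_truncated` | binary | the principal (APPRIS-like) isoform is affected |
| `nmd_target` | binary | the premature stop is predicted to trigger nonsense-mediated decay |

"Affected" fractions are reported as fractions of protein residues rather
than absolute residue counts because relative truncation is what separates
the classes; absolute lengths are recoverable from the transcript models.

A position is *constitutively spliced* when every isoform contains it; the
flag is kept alongside the classifier features for analyses of alternative
splicing, as is the stricter all/some/none summary of NMD status across
isoforms.

### The NMD rule and its boundary

A transcript position is in the NMD-target region when it lies **more than
50 nucleotides upstream of the 3'-most exon–exon junction**. The
inequality is strict: a distance of exactly 50 escapes. Only coding exons
are modeled, so the junction used is the last CDS-segment junction; for
annotations that include UTR exons the reader accepts a per-transcript
`junction_cds` override (the junction may then lie beyond the coding
length, e.g. in the 3' UTR), which is the honest way to handle final exons
that begin inside the CDS. Single-segment transcripts have no junction and
always escape.

For the classifier, a variant counts as an NMD target when **at least one
affected isoform** is predicted to be degraded. The aggregation over
isoforms is a genuine design choice — one could equally require all
isoforms — so the stricter variant is exposed as the `nmd_all_isoforms`
flag rather than silently discarded.

### Conventions and degenerate inputs

* Intervals are stored 0-based half-open internally; GTF/VCF coordinates
  are converted exactly once at the reader boundary.
* The CDS includes the natural stop codon (CCDS convention), so a CDS of
  $3(L+1)$ nt encodes $L$ residues.
* A variant falling in the natural stop codon of some isoform clamps to the
  last residue for the fraction feature (with a logged warning) but removes
  nothing of any domain ending earlier.
* Genes missing from the principal-isoform table fall back to the
  longest-CDS isoform, ties broken by lexicographically smallest transcript
  id (deterministic), and the row is flagged `missing_principal`.
* Genes with no domain annotation yield `NA` domain truncation, imputed to
  0 by `impute_features()` immediately before classification — the only
  two kinds of missingness the model accepts are these two.
* A variant coding in no isoform of its assigned gene is kept but flagged
  `non_coding_all_isoforms` and excluded from feature computation; a
  variant overlapping several genes is annotated once per gene with the
  multiplicity recorded.

## The classifier

Let $y$ be the $K$-dimensional feature row of a new variant. With training
matrix $X_{N \times K}$ and labels $c \in \{0,1\}^N$ (1 = pathogenic), the
posterior probability of pathogenicity is

$$
P(c = 1 \mid y) \;=\;
\frac{p_1 \prod_k L_k(y_k \mid \text{class } 1)}
     {p_1 \prod_k L_k(y_k \mid 1) + (1 - p_1) \prod_k L_k(y_k \mid 0)},
$$

with normal likelihoods for the four continuous features and Bernoulli
likelihoods for the two binary ones (naïve Bayes factorization). Fitting is
pure maximum likelihood: class-specific means $\mu_1, \mu_0$, and a single
**pooled** intra-class variance per feature,
$\nu_k = \tfrac1N \sum_i (x_{ik} - \mu_{c_i,k})^2$ — a plain mean with
divisor $N$, matching the estimator's definition as an expectation rather
than an unbiased variant. Two guards that the model family itself does not
specify:

* a variance floor of $10^{-9}$ (squared feature units) prevents degenerate
  normal likelihoods on separable training sets;
* Bernoulli rates use Laplace smoothing $\theta = (s + 1)/(n + 2)$ so no
  rate is ever exactly 0 or 1.

The prior $p_1$ defaults to the empirical class fraction. The *ranking* of
variants is provably invariant to $p_1$ (the posterior is a monotone map of
the class likelihood ratio), so benchmark orderings, rank percentiles and
AUCs do not depend on it; the property is verified as a test. Posteriors
are evaluated in log space and agree with the direct product formula to
$10^{-10}$ wherever the latter does not underflow.

Features were not transformed before fitting; the fit operates on raw
values, and any per-feature transform can be applied upstream of `nb_fit()`
by the caller.

## Evaluation machinery

**Subsampling ROC.** `roc_subsample()` repeats: draw a random 75% training
split, fit, score the held-out 25%; all validation (score, label) pairs are
**pooled across iterations** and one ROC/AUC is computed on the pool (not
an average of per-iteration curves). Splits are unstratified, with redraws
when a class goes missing from training (counted and reported); a
stratified option exists. AUC is the Mann–Whitney estimator — wins plus
half-credit for ties over all positive–negative pairs — and the stored
curve's trapezoidal area equals it exactly. The reference iteration count
is 10,000; the test suite uses 30–500 iterations, which on fixture-sized
data already brings the Monte-Carlo error well below the assertion
tolerances.

**Randomization control.** `randomization_test()` permutes each feature
column independently before every iteration, destroying feature–label
coupling while preserving marginals; a sound pipeline returns AUC ≈ 0.5.

**Joint scores.** A gene-level probability (either a precomputed gene score
or the logistic of a negated intolerance score, `rvis_to_prob()`) is
combined with the sequence posterior by plain product — the joint
probability under conditional independence. `rank_percentile()` reports,
per variant, the percentage of variants scoring strictly more pathogenic
(0 = top of the ranking; ties share a percentile).

**Hardy–Weinberg filter.** `hwe_exact_test()` is the exact conditional
test: given the observed allele counts, every possible heterozygote count
is enumerated, and the p-value sums configurations as-or-less probable than
the observed one. "Fisher's exact" is ambiguous for the three genotype
cells; the as-or-less-probable two-sided rule is the standard resolution
and is validated against a full-enumeration oracle. Variants with
$p < 0.05$ are filtered as likely genotyping artifacts.

**Allele-frequency trends.** `maf_trend()` regresses feature presence on
$\log \mathrm{MAF}$ per variant class with `stats::glm()` (IRLS, tolerance
$10^{-10}$), refusing fits that show signs of perfect separation;
`heterogeneity_test()` compares two slopes from disjoint variant sets with
a zero-covariance z-test.

## Carrier expression z-scores

Expression is standardized per gene across samples using the **population**
standard deviation (divisor $n$; the convention is stated because either
choice is defensible, and it is what makes a full-cohort carrier set give
exactly z = 0). A variant's expression impact is the mean z of its gene
over carrier samples. Predicted NMD targets should show lower carrier z
than NMD escapes; groups are compared with a one-sided Wilcoxon rank-sum
test (exact for small tie-free groups, normal approximation with tie
correction otherwise), and `score_expression_quintiles()` relates score
rank percentiles to equal-count bins of carrier z.

Genotype counts describe the full genotyped cohort while the `carriers`
list names carriers within the (smaller) expression panel; the carrier list
must be a subset of the cohort carriers, and singleton status is decided on
cohort counts when they exist.

## The synthetic fixture generator

`simulate_fixture()` produces every input the pipeline consumes — GTF,
VCF with sample genotypes, domain/principal/score tables, an expression
matrix — together with a ground-truth feature table computed from the
generator's own exon bookkeeping, independent of the coordinate code it is
used to test. One seed drives all stages through deterministically derived
sub-seeds, and regeneration is byte-identical; the bundle under
`inst/extdata/golden/` is the default configuration at seed 7.

What it emulates, and the defaults chosen as a realistic desk-scale study:

* 20 genes on both strands across the autosomes, 1–4 isoforms each (the
  first isoform carries every exon), 1–6 coding exons of 12–50 codons —
  always including one single-exon and one single-isoform gene for edge
  coverage; 60% of transcripts carry 1–2 InterPro-like domains; 15% of
  genes are absent from the principal table.
* 100 pathogenic-like variants: rare (MAF $10^{-4}$–$10^{-3}$,
  log-uniform), placed 5'-biased (Beta(1.2, 3.5) relative position) on the
  principal isoform — the placement that loads domains, NMD-target regions
  and the principal flag. 100 benign-like variants: common (MAF 0.01–0.33),
  3'-biased (Beta(3.5, 1.2)) on a random isoform, diverted onto an
  alternatively spliced exon half of the time one exists.
* Genotype counts for a cohort of 3,000 individuals derived from the drawn
  MAF under Hardy–Weinberg proportions (so the generated data pass the HWE
  filter); expression for 50 samples from per-gene log-normal baselines
  with log-scale noise (sd 0.25), carriers of NMD-target variants reduced
  multiplicatively by 50%.
* `generate_feature_matrix()` bypasses transcripts entirely and samples
  classifier rows straight from the Gaussian/Bernoulli class models —
  the right substrate for parameter-recovery tests and for estimating the
  Bayes-optimal AUC ceiling with the true parameters.

What it does **not** emulate — and therefore what passing tests do not
show about real data: realistic exon/intron length distributions and
genome sequence, linkage between variants, population structure in allele
frequencies, tissue-dependent isoform usage, partial NMD efficiency, and
annotation error in transcript models. The generator exists to verify the
machinery exactly, not to claim field performance; headline numbers on
real cohorts require the corresponding external datasets.

## Problem sizes and tolerances used by the test suite

Deterministic identities are asserted exactly or at $10^{-10}$–$10^{-12}$;
stochastic checks fix their seeds and use sizes chosen so the assertion
tolerance sits several standard errors from the expected value: parameter
recovery at $N = 10{,}000$ rows, chance-level controls at $n = 400$ with
200 iterations (AUC $0.5 \pm 0.05$), held-out AUC within $0.02$ of the
Bayes ceiling, directional expression and joint-score properties over 100
seeded replicates with a 95-replicate pass requirement.

## Known limitations

* Frameshifts truncate from the indel codon; a real frameshift translates
  a short novel peptide before the next stop, which can move the effective
  NMD position slightly 3'.
* Stop-codon read-through and tissue-specific isoform weighting are out of
  scope.
* With CDS-only transcript models the NMD junction ignores UTR-only exons
  unless a `junction_cds` override is supplied.
* The classifier treats `n_isoforms` and `ratio_isoforms_affected` as
  normal despite their discreteness/boundedness — the model family is a
  deliberate simplification whose ranking quality, not calibration, is the
  target.
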