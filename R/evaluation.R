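#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' `(wins + 0.5 * ties) / (n_pos * n_neg)` over all positive-negative pairs,
#' computed via midranks.
#'
#' @param scores Numeric scores (higher = more pathogenic).
#' @param labels Binary labels (1/TRUE = positive).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels)) stop("scores/labels contain NA")
  n1 <- as.numeric(sum(labels)); n0 <- as.numeric(sum(!labels))
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute an AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve with thresholds at distinct scores
#'
#' Step curve from (0,0) to (1,1); tied scores are grouped into single
#' threshold points, so the trapezoidal area of the curve equals the
#' Mann-Whitney [auc()] exactly (ties receive half credit as diagonal
#' segments).
#'
#' @inheritParams auc
#' @return List of class `roc_result`: `fpr`, `tpr`, `auc`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  grp_end <- which(!duplicated(s, fromLast = TRUE))  # last index of each tie group
  tp <- cumsum(l)[grp_end]; fp <- cumsum(!l)[grp_end]
  res <- list(fpr = c(0, fp / n0), tpr = c(0, tp / n1),
              auc = auc(scores, labels), n_pos = n1, n_neg = n0)
  class(res) <- "roc_result"
  res
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d positives, %d negatives%s)\n",
              x$auc, x$n_pos, x$n_neg,
              if (!is.null(x$iterations))
                paste0(", ", x$iterations, " subsampling iterations") else ""))
  invisible(x)
}

#' Repeated-subsampling ROC of the naive Bayes classifier
#'
#' In each iteration the rows are split at random into a training fraction
#' (default 75%) and a validation remainder; the classifier is fitted on the
#' training rows and the validation rows are scored. Validation (score,
#' label) pairs are pooled across all iterations and a single ROC/AUC is
#' computed on the pool, minimizing Monte-Carlo error. Splits leaving a class
#' empty in training are redrawn (counted in `redraws`).
#'
#' @param X Feature data frame/matrix (see [nb_fit()]).
#' @param labels Binary labels.
#' @param train_frac Fraction of rows used for training per iteration.
#' @param iters Number of subsampling iterations.
#' @param seed Integer seed; mandatory for reproducibility.
#' @param stratified Draw the split within each class instead of over all
#'   rows.
#' @param prior,kinds,variance_floor,smoothing Passed to [nb_fit()].
#' @return `roc_result` with additional elements `iterations`, `seed`,
#'   `redraws`.
#' @export
roc_subsample <- function(X, labels, train_frac = 0.75, iters = 10000L,
                          seed, stratified = FALSE, prior = "empirical",
                          kinds = NULL, variance_floor = 1e-9, smoothing = 1) {
  stopifnot(iters >= 1L, train_frac > 0, train_frac < 1)
  X <- as.data.frame(X)
  labels <- as.integer(as.logical(labels))
  n <- nrow(X)
  set.seed(as.integer(seed))
  pooled_s <- vector("list", iters)
  pooled_l <- vector("list", iters)
  redraws <- 0L
  for (it in seq_len(iters)) {
    repeat {
      tr <- draw_split(labels, train_frac, stratified)
      if (length(unique(labels[tr])) == 2L && length(tr) < n) break
      redraws <- redraws + 1L
      if (redraws > 1000L * iters)
        stop("cannot draw a training split containing both classes")
    }
    fit <- nb_fit(X[tr, , drop = FALSE], labels[tr], prior = prior,
                  kinds = kinds, variance_floor = variance_floor,
                  smoothing = smoothing)
    va <- setdiff(seq_len(n), tr)
    pooled_s[[it]] <- nb_posterior(fit, X[va, , drop = FALSE])
    pooled_l[[it]] <- labels[va]
  }
  res <- roc_curve(unlist(pooled_s), unlist(pooled_l))
  res$iterations <- iters
  res$seed <- as.integer(seed)
  res$redraws <- redraws
  res
}

draw_split <- function(labels, train_frac, stratified) {
  n <- length(labels)
  if (!stratified) {
    sort(sample.int(n, size = round(train_frac * n)))
  } else {
    unlist(lapply(split(seq_len(n), labels), function(ix)
      sample(ix, size = round(train_frac * length(ix)))))
  }
}

#' Column-shuffle randomization test of the subsampling ROC
#'
#' Negative control for [roc_subsample()]: in every iteration each feature
#' column is independently permuted across rows before the split and fit,
#' destroying any feature-label coupling while preserving the marginal
#' feature distributions. The pooled AUC should be near 0.5 for an unbiased
#' evaluation pipeline.
#'
#' @inheritParams roc_subsample
#' @return `roc_result` as in [roc_subsample()].
#' @export
randomization_test <- function(X, labels, train_frac = 0.75, iters = 10000L,
                               seed, stratified = FALSE, prior = "empirical",
                               kinds = NULL, variance_floor = 1e-9,
                               smoothing = 1) {
  stopifnot(iters >= 1L)
  X <- as.data.frame(X)
  labels <- as.integer(as.logical(labels))
  n <- nrow(X)
  set.seed(as.integer(seed))
  pooled_s <- vector("list", iters)
  pooled_l <- vector("list", iters)
  redraws <- 0L
  for (it in seq_len(iters)) {
    Xp <- as.data.frame(lapply(X, function(col) col[sample.int(n)]))
    repeat {
      tr <- draw_split(labels, train_frac, stratified)
      if (length(unique(labels[tr])) == 2L && length(tr) < n) break
      redraws <- redraws + 1L
      if (redraws > 1000L * iters) stop("cannot draw a two-class split")
    }
    fit <- nb_fit(Xp[tr, , drop = FALSE], labels[tr], prior = prior,
                  kinds = kinds, variance_floor = variance_floor,
                  smoothing = smoothing)
    va <- setdiff(seq_len(n), tr)
    pooled_s[[it]] <- nb_posterior(fit, Xp[va, , drop = FALSE])
    pooled_l[[it]] <- labels[va]
  }
  res <- roc_curve(unlist(pooled_s), unlist(pooled_l))
  res$iterations <- iters
  res$seed <- as.integer(seed)
  res$redraws <- redraws
  res
}

#' Joint sequence-and-gene score
#'
#' Product of the sequence-based posterior and a gene-based probability —
#' the joint probability of a pathogenic variant in a pathogenicity-relevant
#' gene under conditional independence of the two scores.
#'
#' @param sb,gb Probabilities in `[0, 1]` (vectorized).
#' @return Elementwise product.
#' @export
joint_score <- function(sb, gb) {
  if (any(sb < 0 | sb > 1, na.rm = TRUE) || any(gb < 0 | gb > 1, na.rm = TRUE))
    stop("joint_score expects probabilities in [0, 1]")
  sb * gb
}

#' Map a raw RVIS value to a pathogenicity probability
#'
#' The logistic function of the negated score: intolerant genes (negative
#' RVIS) map above 0.5.
#'
#' @param rvis Numeric vector of raw RVIS values.
#' @return `1 / (1 + exp(rvis))`.
#' @export
rvis_to_prob <- function(rvis) 1 / (1 + exp(rvis))

#' Rank percentiles of pathogenicity scores
#'
#' The percentage of all scored variants with a strictly more pathogenic
#' score: 0 marks the most pathogenic variant, values near 100 the least.
#' Tied scores share a percentile.
#'
#' @param scores Numeric scores.
#' @param higher_is_pathogenic Direction of pathogenicity (default `TRUE`).
#' @return Percentiles in `[0, 100)`.
#' @export
rank_percentile <- function(scores, higher_is_pathogenic = TRUE) {
  if (length(scores) == 0L) stop("need at least one score")
  s <- if (higher_is_pathogenic) scores else -scores
  n <- length(s)
  100 * (n - rank(s, ties.method = "max")) / n
}

#' Assemble a per-variant score table
#'
#' Joins sequence-based scores with optional gene-based scores, forms the
#' joint product score where both components exist, and attaches rank
#' percentiles per score column (computed over the non-missing values of
#' that column).
#'
#' @param seq_scores Data frame from [score_variants()] (needs `variant_id`,
#'   `gene_id`, `score_seq`).
#' @param gene_scores Optional data frame from [read_gene_scores()]; a
#'   `rvis` column is converted with [rvis_to_prob()] when no `gene_score`
#'   probability is present.
#' @param labels Optional named logical/integer vector (by `variant_id`).
#' @return Data frame with scores, `score_joint` and `rank_pct_*` columns.
#' @export
build_score_table <- function(seq_scores, gene_scores = NULL, labels = NULL) {
  out <- seq_scores
  if (!is.null(gene_scores)) {
    gb <- if ("gene_score" %in% names(gene_scores)) gene_scores$gene_score
          else if ("rvis" %in% names(gene_scores)) rvis_to_prob(gene_scores$rvis)
          else stop("gene_scores needs a 'gene_score' or 'rvis' column")
    out$score_gene <- gb[match(out$gene_id, gene_scores$gene_id)]
    both <- !is.na(out$score_gene)
    out$score_joint <- NA_real_
    out$score_joint[both] <- joint_score(out$score_seq[both],
                                         out$score_gene[both])
  }
  for (cl in intersect(c("score_seq", "score_gene", "score_joint"),
                       names(out))) {
    pc <- rep(NA_real_, nrow(out))
    ok <- !is.na(out[[cl]])
    if (any(ok)) pc[ok] <- rank_percentile(out[[cl]][ok])
    out[[paste0("rank_pct_", sub("^score_", "", cl))]] <- pc
  }
  if (!is.null(labels))
    out$label <- as.logical(labels[out$variant_id])
  out
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test: given the observed allele counts, the probability
#' of each possible heterozygote count is computed under Hardy-Weinberg
#' proportions, and the p-value sums the probabilities of all configurations
#' as or less probable than the observed one (two-sided,
#' "as-or-less-probable" rule).
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts (scalars, nonnegative).
#' @return Exact p-value in `(0, 1]`.
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  cnt <- c(n_hom_ref, n_het, n_hom_alt)
  if (anyNA(cnt) || any(cnt < 0)) stop("genotype counts must be nonnegative")
  d <- hwe_het_distribution(n_hom_ref, n_het, n_hom_alt)
  p_obs <- d$prob[d$het == n_het]
  sum(d$prob[d$prob <= p_obs * (1 + 1e-9)])
}

# conditional distribution of the heterozygote count given allele counts:
# all genotype configurations with the observed minor-allele count, with
# probabilities proportional to n! / (nAA! nAa! naa!) * 2^nAa
hwe_het_distribution <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  if (n < 1L) stop("need at least one genotyped individual")
  n_alt <- n_het + 2L * n_hom_alt
  n_minor <- min(n_alt, 2L * n - n_alt)
  het <- seq.int(n_minor %% 2L, n_minor, by = 2L)
  hom_minor <- (n_minor - het) %/% 2L
  hom_major <- n - het - hom_minor
  logw <- lgamma(n + 1) - lgamma(hom_major + 1) - lgamma(het + 1) -
    lgamma(hom_minor + 1) + het * log(2)
  w <- exp(logw - max(logw))
  data.frame(het = het, prob = w / sum(w))
}

#' Filter variants deviating from Hardy-Weinberg equilibrium
#'
#' Removes variants whose exact HWE p-value falls below `alpha` — in exome
#' cohorts these are typically technical artifacts showing an excess of rare
#' homozygous calls. Variants without genotype counts are kept untouched.
#'
#' @param variants Data frame from [read_variants()].
#' @param alpha Significance threshold (default 0.05).
#' @return The kept rows, with attribute `"removed"` listing filtered
#'   variant ids and their p-values.
#' @export
filter_hwe <- function(variants, alpha = 0.05) {
  has_gc <- !is.na(variants$n_hom_ref) & !is.na(variants$n_het) &
    !is.na(variants$n_hom_alt)
  p <- rep(NA_real_, nrow(variants))
  p[has_gc] <- vapply(which(has_gc), function(i)
    hwe_exact_test(variants$n_hom_ref[i], variants$n_het[i],
                   variants$n_hom_alt[i]), numeric(1))
  drop <- has_gc & p < alpha
  out <- variants[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- data.frame(variant_id = variants$variant_id[drop],
                                     p_hwe = p[drop],
                                     stringsAsFactors = FALSE)
  out
}

#' Allele-frequency trend of a sequence feature
#'
#' For each variant class, logistic regression (IRLS via [stats::glm()],
#' convergence tolerance 1e-10) of feature presence on `log(MAF)`. The slope
#' describes how the probability of carrying the feature changes with allele
#' frequency — e.g. depletion of domain-losing positions among common
#' truncating variants.
#'
#' @param present Logical vector: feature observed for each variant.
#' @param maf Minor allele frequencies (> 0).
#' @param vclass Variant class per variant.
#' @return Data frame with one row per class: `vclass`, `beta` (slope on
#'   log MAF), `se`, `n`.
#' @export
maf_trend <- function(present, maf, vclass) {
  stopifnot(length(present) == length(maf), length(maf) == length(vclass))
  if (any(maf <= 0)) stop("MAF must be positive to take logarithms")
  res <- lapply(split(seq_along(maf), vclass), function(ix) {
    y <- as.integer(present[ix])
    if (length(unique(y)) < 2L)
      stop("feature is constant within class '", vclass[ix[1]],
           "'; no trend estimable")
    if (length(unique(maf[ix])) < 2L)
      stop("need at least two distinct MAF values in class '",
           vclass[ix[1]], "'")
    fit <- stats::glm(y ~ log(maf[ix]), family = stats::binomial(),
                      control = stats::glm.control(epsilon = 1e-10,
                                                   maxit = 100))
    cf <- summary(fit)$coefficients
    if (!fit$converged || abs(cf[2, 1]) > 20)
      stop("logistic fit did not converge for class '", vclass[ix[1]],
           "' (likely perfect separation); pool MAF bins or add variants")
    data.frame(vclass = vclass[ix[1]], beta = cf[2, 1], se = cf[2, 2],
               n = length(ix), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Heterogeneity test between two trend slopes
#'
#' Z-test for equality of two regression coefficients estimated on disjoint
#' variant sets (zero covariance): `z = (bA - bB) / sqrt(seA^2 + seB^2)`,
#' two-sided normal p-value.
#'
#' @param beta_a,se_a,beta_b,se_b Slopes and standard errors.
#' @return List with `z` and `p`.
#' @export
heterogeneity_test <- function(beta_a, se_a, beta_b, se_b) {
  z <- (beta_a - beta_b) / sqrt(se_a^2 + se_b^2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Spearman correlation with bootstrap confidence interval
#'
#' Spearman rank correlation of two paired score vectors with a percentile
#' bootstrap CI over paired resampling.
#'
#' @param a,b Numeric vectors of equal length (at least 3).
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @param conf Confidence level.
#' @return List with `rho`, `ci` (length 2), `n`, `n_boot`.
#' @export
correlate_scores <- function(a, b, n_boot = 10000L, seed, conf = 0.95) {
  stopifnot(length(a) == length(b))
  if (length(a) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined for a constant score vector")
  rho <- stats::cor(a, b, method = "spearman")
  set.seed(as.integer(seed))
  n <- length(a)
  boot <- vapply(seq_len(n_boot), function(i) {
    ix <- sample.int(n, replace = TRUE)
    suppressWarnings(stats::cor(a[ix], b[ix], method = "spearman"))
  }, numeric(1))
  alpha <- (1 - conf) / 2
  list(rho = rho,
       ci = unname(stats::quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE)),
       n = n, n_boot = n_boot)
}
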