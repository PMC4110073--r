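test_that("Mann-Whitney AUC handles separation, ties and mixed cases", {
  expect_equal(auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(auc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_equal(auc(c(0.9, 0.3, 0.5, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_error(auc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("AUC agrees with pairwise enumeration and pROC on random instances", {
  set.seed(61)
  for (rep in 1:100) {
    n <- sample(6:24, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forced ties
    labels <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    expect_equal(auc(scores, labels), oracle_auc(scores, labels))
  }
  skip_if_not_installed("pROC")
  set.seed(62)
  for (rep in 1:10) {
    scores <- stats::rnorm(60)
    labels <- c(1, 0, sample(0:1, 58, replace = TRUE))
    expect_equal(auc(scores, labels),
                 as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                direction = "<",
                                                quiet = TRUE))))
  }
})

test_that("AUC invariances: monotone transforms, label flips, curve area", {
  set.seed(67)
  scores <- stats::rnorm(80)
  labels <- sample(0:1, 80, replace = TRUE, prob = c(0.6, 0.4))
  a <- auc(scores, labels)
  expect_equal(auc(exp(scores), labels), a)         # strictly monotone map
  expect_equal(auc(scores, 1 - labels), 1 - a)
  r <- roc_curve(scores, labels)
  trap <- sum(diff(r$fpr) * (utils::head(r$tpr, -1) + utils::tail(r$tpr, -1)) / 2)
  expect_equal(trap, a, tolerance = 1e-12)
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
  expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
  expect_equal(c(r$fpr[length(r$fpr)], r$tpr[length(r$tpr)]), c(1, 1))
})

test_that("subsampling ROC is deterministic under a seed and separates planted classes", {
  sep <- default_class_model()
  sep$mu0[] <- sep$mu1 - 10 * sqrt(sep$nu)   # 10 sigma apart
  fm <- generate_feature_matrix(60, 60, sep, seed = 71)
  r1 <- roc_subsample(fm$X, fm$labels, iters = 50, seed = 9)
  expect_equal(r1$auc, 1)
  r2 <- roc_subsample(fm$X, fm$labels, iters = 50, seed = 9)
  expect_identical(r1, r2)
  r3 <- roc_subsample(fm$X, fm$labels, iters = 1, seed = 10)
  r4 <- roc_subsample(fm$X, fm$labels, iters = 1, seed = 10)
  expect_identical(r3, r4)
})

test_that("permuted labels and column shuffling drive the pooled AUC to chance", {
  fm <- generate_feature_matrix(200, 200, seed = 73)
  set.seed(74)
  null_labels <- sample(fm$labels)
  rn <- roc_subsample(fm$X, null_labels, iters = 100, seed = 75)
  expect_lt(abs(rn$auc - 0.5), 0.05)
  rs <- randomization_test(fm$X, fm$labels, iters = 100, seed = 76)
  expect_lt(abs(rs$auc - 0.5), 0.05)
  rs2 <- randomization_test(fm$X, fm$labels, iters = 100, seed = 76)
  expect_identical(rs, rs2)
})

test_that("joint scores and the RVIS logistic map obey their closed forms", {
  expect_equal(joint_score(1, 0.7), 0.7)
  expect_equal(joint_score(c(0.5, 0.2), c(0.4, 0.9)), c(0.2, 0.18))
  expect_error(joint_score(1.2, 0.5), "probabilities")
  expect_equal(rvis_to_prob(0), 0.5)
  expect_equal(rvis_to_prob(-log(3)), 0.75)
  expect_gt(rvis_to_prob(-2), rvis_to_prob(2))  # intolerant genes score higher
})

test_that("rank percentiles count strictly more pathogenic scores", {
  expect_equal(rank_percentile(c(0.9, 0.5, 0.1)), c(0, 100 / 3, 200 / 3))
  expect_equal(rank_percentile(rep(0.4, 5)), rep(0, 5))
  expect_equal(rank_percentile(0.7), 0)
  expect_equal(rank_percentile(c(1, 3, 2), higher_is_pathogenic = FALSE),
               c(0, 200 / 3, 100 / 3))
  # invariance: percentiles of posteriors coincide across priors
  fm <- generate_feature_matrix(40, 40, seed = 79)
  m <- nb_fit(fm$X, fm$labels)
  expect_equal(rank_percentile(nb_posterior(m, fm$X, prior = 0.1)),
               rank_percentile(nb_posterior(m, fm$X, prior = 0.9)))
})

test_that("the exact HWE test matches full enumeration and sums to one", {
  expect_equal(hwe_exact_test(1, 1, 0), 1)
  expect_equal(hwe_exact_test(2, 0, 0), 1)
  o <- oracle_hwe(5, 0, 5)
  expect_equal(hwe_exact_test(5, 0, 5), o$p_value)
  set.seed(83)
  for (rep in 1:40) {
    n <- sample(2:50, 1)
    nA <- sample(0:n, 1); nH <- sample(0:(n - nA), 1)
    o <- oracle_hwe(n - nA - nH, nH, nA)
    expect_equal(o$total, 1, tolerance = 1e-12)
    expect_equal(hwe_exact_test(n - nA - nH, nH, nA), o$p_value,
                 tolerance = 1e-12)
  }
  expect_error(hwe_exact_test(-1, 2, 0), "nonnegative")
})

test_that("HWE filtering removes excess-homozygote artifacts only", {
  v <- data.frame(variant_id = c("ok", "bad", "nogc"),
                  chrom = "1", pos = 1:3, ref = "A", alt = "T",
                  vclass = "stop_gain",
                  maf = c(0.01, 0.01, 0.01),
                  n_hom_ref = c(980L, 980L, NA), n_het = c(20L, 0L, NA),
                  n_hom_alt = c(0L, 10L, NA), dataset = "d",
                  stringsAsFactors = FALSE)
  v$carriers <- list(character(), character(), character())
  kept <- filter_hwe(v)
  expect_identical(kept$variant_id, c("ok", "nogc"))
  expect_equal(attr(kept, "removed")$variant_id, "bad")
  expect_lt(attr(kept, "removed")$p_hwe, 0.05)
})

test_that("MAF-trend slopes and the heterogeneity z-test behave under the null", {
  set.seed(89)
  n <- 600
  maf <- 10^stats::runif(2 * n, -4, -0.5)
  vclass <- rep(c("stop_gain", "synonymous"), each = n)
  present <- stats::rbinom(2 * n, 1, 0.4) == 1   # independent of MAF
  tr <- maf_trend(present, maf, vclass)
  expect_equal(sort(tr$vclass), c("stop_gain", "synonymous"))
  het <- heterogeneity_test(tr$beta[1], tr$se[1], tr$beta[2], tr$se[2])
  expect_lt(abs(het$z), 3)
  expect_equal(heterogeneity_test(0.4, 0.1, 0.4, 0.2)$z, 0)
  expect_equal(heterogeneity_test(0.4, 0.1, 0.4, 0.2)$p, 1)
  expect_equal(heterogeneity_test(1.3, 0.3, 1.0, 0.4)$z, 0.6)
  # a feature planted to depend on MAF gives a detectable slope
  p <- stats::plogis(1.2 * log(maf[1:n]) + 4)
  dep <- stats::rbinom(n, 1, p) == 1
  tr2 <- maf_trend(c(dep, present[(n + 1):(2 * n)]), maf, vclass)
  b <- tr2[tr2$vclass == "stop_gain", ]
  expect_gt(b$beta, 0.8)
  het2 <- heterogeneity_test(b$beta, b$se, tr2$beta[2], tr2$se[2])
  expect_lt(het2$p, 1e-6)
  expect_error(maf_trend(rep(TRUE, 10), rep(0.1, 10), rep("a", 10)),
               "constant")
})

test_that("Spearman correlation with bootstrap CI covers the planted value", {
  a <- seq_len(50)
  expect_equal(correlate_scores(a, a, n_boot = 200, seed = 1)$rho, 1)
  expect_equal(correlate_scores(a, -a, n_boot = 200, seed = 1)$rho, -1)
  set.seed(97)
  x <- stats::runif(600); y <- stats::runif(600)
  cs <- correlate_scores(x, y, n_boot = 500, seed = 2)
  expect_lt(abs(cs$rho), 0.1)
  expect_true(cs$ci[1] < 0 && cs$ci[2] > 0)
  expect_error(correlate_scores(rep(1, 10), stats::runif(10),
                                n_boot = 10, seed = 1), "constant")
})

test_that("score tables join gene scores, joint products and percentiles", {
  seqs <- data.frame(variant_id = c("V1", "V2", "V3"),
                     gene_id = c("G1", "G2", "G3"),
                     score_seq = c(0.9, 0.5, 0.2), stringsAsFactors = FALSE)
  gs <- data.frame(gene_id = c("G1", "G2"), gene_score = c(0.8, 0.1),
                   stringsAsFactors = FALSE)
  st <- build_score_table(seqs, gs,
                          labels = c(V1 = TRUE, V2 = FALSE, V3 = FALSE))
  expect_equal(st$score_joint, c(0.72, 0.05, NA))
  expect_equal(st$rank_pct_seq, c(0, 100 / 3, 200 / 3))
  expect_equal(st$rank_pct_joint, c(0, 50, NA))  # over non-missing rows only
  expect_identical(st$label, c(TRUE, FALSE, FALSE))
})
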