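# Independent brute-force oracles used to validate the fast implementations.

# pairwise-enumeration AUC: (wins + 0.5 ties) / (n1 * n0) by double loop
oracle_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# exact HWE by direct enumeration of genotype configurations with the
# observed allele counts, using the closed-form conditional probability
#   P(het) = n! nA! na! 2^het / (nAA! het! naa! (2n)!)
oracle_hwe <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  n_alt <- n_het + 2 * n_hom_alt
  n_minor <- min(n_alt, 2 * n - n_alt)
  n_major <- 2 * n - n_minor
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  logp <- vapply(hets, function(h) {
    hom_minor <- (n_minor - h) / 2
    hom_major <- n - h - hom_minor
    lfactorial(n) + lfactorial(n_minor) + lfactorial(n_major) +
      h * log(2) - lfactorial(hom_major) - lfactorial(h) -
      lfactorial(hom_minor) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp)
  obs <- p[hets == n_het]
  list(p_value = sum(p[p <= obs * (1 + 1e-9)]), total = sum(p))
}

# direct-product naive Bayes posterior (no log space)
oracle_posterior_direct <- function(model, y, prior = NULL) {
  p1 <- if (is.null(prior)) model$p1 else prior
  lik <- function(mu, th) {
    L <- 1
    for (k in model$feature_names) {
      v <- as.numeric(y[[k]])
      L <- L * if (model$kinds[[k]] == "continuous")
        stats::dnorm(v, mu[[k]], sqrt(model$nu[[k]]))
      else th[[k]]^v * (1 - th[[k]])^(1 - v)
    }
    L
  }
  l1 <- lik(model$mu1, model$theta1)
  l0 <- lik(model$mu0, model$theta0)
  p1 * l1 / (p1 * l1 + (1 - p1) * l0)
}

# per-residue marking oracle for truncation features: mark every residue at
# or downstream of the truncation codon and count
oracle_fraction_affected <- function(codon, plen) {
  marked <- seq_len(plen) >= min(codon, plen)
  sum(marked) / plen
}

oracle_domain_fraction <- function(codon, start_aa, end_aa, plen) {
  resid <- seq(start_aa, end_aa)
  sum(resid >= codon) / length(resid)
}

# random single-transcript model for coordinate property tests
random_transcript <- function(id = "T1", n_seg = sample(1:6, 1),
                              strand = sample(c("+", "-"), 1)) {
  codons <- sample(2:30, n_seg, replace = TRUE)
  gaps <- sample(20:200, n_seg, replace = TRUE)
  start <- sample(1000:100000, 1)
  starts <- integer(n_seg); ends <- integer(n_seg)
  for (k in seq_len(n_seg)) {
    starts[k] <- start
    ends[k] <- start + 3 * codons[k] - 1
    start <- ends[k] + gaps[k]
  }
  transcript_model(id, "G1", "1", strand, starts, ends)
}

# tiny deterministic two-isoform gene used across feature tests:
# T1 (principal candidate) has exons A(101-160, 20 codons) B(301-420, 40
# codons) C(501-560, 20 codons); T2 skips B. Plus strand.
toy_gene <- function(principal = "T1") {
  t1 <- transcript_model("T1", "G1", "1", "+",
                         starts = c(101, 301, 501), ends = c(160, 420, 560))
  t2 <- transcript_model("T2", "G1", "1", "+",
                         starts = c(101, 501), ends = c(160, 560))
  gene_model("G1", list(t1, t2), principal_transcript_id = principal)
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
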