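#' Default per-class generative model for classifier features
#'
#' Class-conditional Gaussian/Bernoulli parameters used by
#' [generate_feature_matrix()] to sample feature rows directly from the model
#' family the classifier assumes. Defaults place the pathogenic class at
#' larger truncated fractions, heavier domain loss, higher principal-isoform
#' and NMD-target rates, with overlapping but distinguishable distributions.
#'
#' @return List with `mu1`, `mu0`, `nu` (named over the continuous features)
#'   and `theta1`, `theta0` (named over the binary features).
#' @export
default_class_model <- function() {
  list(
    mu1 = c(fraction_affected_max = 0.75, domain_truncation_max = 0.55,
            n_isoforms = 2.4, ratio_isoforms_affected = 0.85),
    mu0 = c(fraction_affected_max = 0.30, domain_truncation_max = 0.12,
            n_isoforms = 2.4, ratio_isoforms_affected = 0.55),
    nu = c(fraction_affected_max = 0.04, domain_truncation_max = 0.08,
           n_isoforms = 1.2, ratio_isoforms_affected = 0.07),
    theta1 = c(principal_truncated = 0.95, nmd_target = 0.80),
    theta0 = c(principal_truncated = 0.55, nmd_target = 0.35))
}

#' Configuration for the synthetic fixture generator
#'
#' One seed drives all stages (sub-seeds are derived deterministically per
#' stage, so stages can be regenerated independently). Defaults produce the
#' small bundle used throughout the test suite: 20 multi-isoform genes, 100
#' variants per class, a 3000-individual genotyped cohort and 50
#' expression-profiled samples.
#'
#' @param seed Master integer seed.
#' @param n_genes Number of genes.
#' @param isoform_range,exons_range Min/max isoforms per gene and coding
#'   exons per gene.
#' @param exon_codon_range Min/max exon length in codons (so CDS lengths are
#'   always divisible by 3).
#' @param intron_range Min/max intron length in nucleotides.
#' @param domain_density Probability that a transcript carries domain
#'   annotation.
#' @param principal_missing_rate Fraction of genes absent from the
#'   principal-isoform table (exercising the longest-isoform imputation).
#' @param n_variants_per_class Pathogenic-like and benign-like variant
#'   counts.
#' @param cohort_size Genotyped individuals behind the genotype counts.
#' @param n_samples Expression-profiled samples.
#' @param pathogenic_maf_range,benign_maf_range Per-class MAF ranges
#'   (log-uniform draws): rare for pathogenic-like, common for benign-like.
#' @param pathogenic_beta,benign_beta Beta-distribution shapes for the
#'   relative position of the truncation along the protein (pathogenic-like
#'   5'-biased, benign-like 3'-biased).
#' @param alt_exon_pref Probability that a benign-like variant is forced
#'   onto an alternatively spliced exon when its isoform has one.
#' @param nmd_effect_size Multiplicative expression reduction applied to
#'   carriers of NMD-target variants, in (0, 1].
#' @param expr_noise_sd Log-scale expression noise.
#' @param baseline_log_mean,baseline_log_sd Log-normal per-gene baseline.
#' @param class_feature_model See [default_class_model()].
#' @param nmd_window NMD distance threshold in nucleotides.
#' @return List of class `fixture_config`.
#' @export
fixture_config <- function(seed = 7L, n_genes = 20L,
                           isoform_range = c(1L, 4L),
                           exons_range = c(1L, 6L),
                           exon_codon_range = c(12L, 50L),
                           intron_range = c(60L, 300L),
                           domain_density = 0.6,
                           principal_missing_rate = 0.15,
                           n_variants_per_class = 100L,
                           cohort_size = 3000L,
                           n_samples = 50L,
                           pathogenic_maf_range = c(1e-4, 1e-3),
                           benign_maf_range = c(0.01, 0.33),
                           pathogenic_beta = c(1.2, 3.5),
                           benign_beta = c(3.5, 1.2),
                           alt_exon_pref = 0.5,
                           nmd_effect_size = 0.5,
                           expr_noise_sd = 0.25,
                           baseline_log_mean = 3,
                           baseline_log_sd = 1,
                           class_feature_model = default_class_model(),
                           nmd_window = 50L) {
  cfg <- as.list(environment())
  if (n_genes < 2L) stop("need at least 2 genes (edge-case coverage)")
  if (exon_codon_range[1] < 1L)
    stop("infeasible config: exon length below one codon")
  if (nmd_effect_size <= 0 || nmd_effect_size > 1)
    stop("nmd_effect_size must lie in (0, 1]")
  if (n_variants_per_class < 1L || n_samples < 2L || cohort_size < 2L)
    stop("counts must be positive (n_samples >= 2)")
  class(cfg) <- "fixture_config"
  cfg
}

stage_seed <- function(seed, stage)
  as.integer((as.integer(seed) %% 2000000L) * 1000L + stage)

#' Generate gene models, domains and principal-isoform truth
#'
#' Builds multi-isoform genes with shared and isoform-specific coding exons
#' on both strands. Gene 1 is always single-isoform and gene 2 single-exon
#' (edge coverage); the first isoform of every gene contains all exons. CDS
#' lengths are divisible by 3 by construction.
#'
#' @param cfg A [fixture_config()].
#' @return List: `genes` (named [gene_model()] list with principal ids set),
#'   `domains`, `principal` (data frames), and `layout` (internal slot
#'   bookkeeping consumed by [generate_variants()] for ground truth).
#' @export
generate_gene_models <- function(cfg) {
  set.seed(stage_seed(cfg$seed, 1L))
  layout <- vector("list", cfg$n_genes)
  dom_rows <- list()
  pri_rows <- list()
  for (i in seq_len(cfg$n_genes)) {
    gid <- sprintf("G%02d", i)
    chrom <- as.character(((i - 1L) %% 22L) + 1L)
    strand <- sample(c("+", "-"), 1L)
    n_slots <- if (i == 2L) 1L else
      sample(seq(cfg$exons_range[1], cfg$exons_range[2]), 1L)
    codons <- sample(seq(cfg$exon_codon_range[1], cfg$exon_codon_range[2]),
                     n_slots, replace = TRUE)
    gaps <- sample(seq(cfg$intron_range[1], cfg$intron_range[2]),
                   n_slots, replace = TRUE)
    gstart <- integer(n_slots); gend <- integer(n_slots)
    cur <- 10000L + 500000L * ((i - 1L) %/% 22L)
    for (k in seq_len(n_slots)) {
      gstart[k] <- cur
      gend[k] <- cur + 3L * codons[k] - 1L
      cur <- gend[k] + gaps[k]
    }
    n_iso <- if (i <= 2L) 1L else
      sample(seq(cfg$isoform_range[1], cfg$isoform_range[2]), 1L)
    iso_slots <- list(seq_len(n_slots))  # isoform 1 carries every exon
    if (n_iso > 1L) {
      for (k in 2:n_iso) {
        for (try in 1:5) {
          keep <- which(stats::runif(n_slots) < 0.7)
          if (length(keep) == 0L) keep <- sample.int(n_slots, 1L)
          if (!any(vapply(iso_slots, identical, logical(1), y = keep))) break
        }
        iso_slots[[k]] <- keep
      }
    }
    tids <- sprintf("%s.T%d", gid, seq_len(n_iso))
    principal_id <- sample(tids, 1L)
    principal_known <- stats::runif(1) >= cfg$principal_missing_rate
    layout[[i]] <- list(gene_id = gid, chrom = chrom, strand = strand,
                        gstart = gstart, gend = gend, codons = codons,
                        iso_slots = stats::setNames(iso_slots, tids),
                        principal_id = principal_id,
                        principal_known = principal_known)
    if (principal_known)
      pri_rows[[length(pri_rows) + 1L]] <-
        data.frame(gene_id = gid, transcript_id = principal_id,
                   stringsAsFactors = FALSE)
    for (k in seq_len(n_iso)) {
      plen <- sum(codons[iso_slots[[k]]]) - 1L
      if (stats::runif(1) < cfg$domain_density && plen > 12L) {
        for (dk in seq_len(sample(1:2, 1L))) {
          dlen <- sample(10:40, 1L)
          if (plen - dlen < 1L) next
          dstart <- sample.int(plen - dlen, 1L)
          dom_rows[[length(dom_rows) + 1L]] <- data.frame(
            transcript_id = tids[k],
            domain_id = sprintf("%s_D%d", tids[k], dk),
            start_aa = dstart, end_aa = dstart + dlen - 1L,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  domains <- if (length(dom_rows)) do.call(rbind, dom_rows) else
    data.frame(transcript_id = character(), domain_id = character(),
               start_aa = integer(), end_aa = integer())
  principal <- if (length(pri_rows)) do.call(rbind, pri_rows) else
    data.frame(gene_id = character(), transcript_id = character())

  genes <- lapply(layout, function(gl) {
    txs <- lapply(names(gl$iso_slots), function(tid) {
      sl <- sort(gl$iso_slots[[tid]])
      transcript_model(tid, gl$gene_id, gl$chrom, gl$strand,
                       starts = gl$gstart[sl], ends = gl$gend[sl])
    })
    gene_model(gl$gene_id, txs,
               principal_transcript_id =
                 if (gl$principal_known) gl$principal_id else NA_character_)
  })
  names(genes) <- vapply(layout, function(gl) gl$gene_id, character(1))
  names(layout) <- names(genes)
  list(genes = genes, domains = domains, principal = principal,
       layout = layout)
}

# ---- ground-truth arithmetic on the generator's own slot bookkeeping ------
# (independent of the transcript_model interval code it is used to test)

# transcription-order slot indices of one isoform
iso_trans_order <- function(gl, tid) {
  sl <- sort(gl$iso_slots[[tid]])
  if (gl$strand == "+") sl else rev(sl)
}

# spliced CDS coordinate of a genomic position on one isoform, or NA
layout_cds <- function(gl, tid, pos) {
  hit <- which(gl$gstart <= pos & pos <= gl$gend)
  if (length(hit) != 1L || !(hit %in% gl$iso_slots[[tid]]))
    return(NA_integer_)
  ts <- iso_trans_order(gl, tid)
  k <- which(ts == hit)
  prec <- if (k > 1L) sum(3L * gl$codons[ts[seq_len(k - 1L)]]) else 0L
  off <- if (gl$strand == "+") pos - gl$gstart[hit] else gl$gend[hit] - pos
  as.integer(prec + off + 1L)
}

layout_plen <- function(gl, tid) sum(gl$codons[gl$iso_slots[[tid]]]) - 1L

layout_junction <- function(gl, tid) {
  ts <- iso_trans_order(gl, tid)
  if (length(ts) == 1L) return(NA_integer_)
  3L * sum(gl$codons[ts]) - 3L * gl$codons[ts[length(ts)]]
}

# effective principal isoform id, replicating the longest-CDS fallback
layout_principal <- function(gl) {
  if (gl$principal_known) return(gl$principal_id)
  lens <- vapply(gl$iso_slots, function(sl) sum(gl$codons[sl]), integer(1))
  sort(names(lens)[lens == max(lens)])[1L]
}

# full feature-vector ground truth for a genomic position in one gene
layout_truth <- function(gl, pos, domains, nmd_window) {
  tids <- names(gl$iso_slots)
  frac_max <- -Inf; dom_max <- NA_real_; any_dom <- FALSE
  nmd_any <- FALSE; nmd_all <- TRUE; n_aff <- 0L
  for (tid in tids) {
    cds <- layout_cds(gl, tid, pos)
    if (is.na(cds)) next
    n_aff <- n_aff + 1L
    plen <- layout_plen(gl, tid)
    codon <- as.integer(ceiling(cds / 3))
    frac_max <- max(frac_max, (plen - min(codon, plen) + 1) / plen)
    d <- domains[domains$transcript_id == tid, , drop = FALSE]
    if (nrow(d)) {
      any_dom <- TRUE
      lost <- pmax(0L, d$end_aa - pmax(d$start_aa, codon) + 1L)
      dom_max <- max(dom_max, lost / (d$end_aa - d$start_aa + 1L),
                     na.rm = TRUE)
    }
    j <- layout_junction(gl, tid)
    nt <- !is.na(j) && (j - cds) > nmd_window
    nmd_any <- nmd_any || nt
    nmd_all <- nmd_all && nt
  }
  pr_id <- layout_principal(gl)
  list(fraction_affected_max = frac_max,
       domain_truncation_max = if (any_dom) dom_max else NA_real_,
       n_isoforms = length(tids),
       ratio_isoforms_affected = n_aff / length(tids),
       principal_truncated = !is.na(layout_cds(gl, pr_id, pos)),
       nmd_target = nmd_any,
       missing_domain = !any_dom,
       missing_principal = !gl$principal_known,
       constitutive_position = n_aff == length(tids),
       nmd_all_isoforms = if (nmd_all) "all" else if (nmd_any) "some" else "none")
}

#' Generate class-conditional truncating variants with ground truth
#'
#' Pathogenic-like variants are placed 5'-biased on the principal isoform
#' (Beta-distributed relative position); benign-like variants are placed
#' 3'-biased on a random isoform, preferring alternatively spliced exons
#' when available. MAFs are drawn log-uniformly per class (rare vs common),
#' genotype counts are derived for the full cohort under Hardy-Weinberg
#' proportions, and carriers among the expression samples are a subset of
#' the cohort carriers. The returned truth table records every feature value
#' computed from the generator's own slot bookkeeping.
#'
#' @param cfg A [fixture_config()].
#' @param gm Result of [generate_gene_models()].
#' @return List: `variants` (data frame as from [read_variants()]), `truth`
#'   (feature ground truth with a `class` column), `samples` (expression
#'   sample ids).
#' @export
generate_variants <- function(cfg, gm) {
  set.seed(stage_seed(cfg$seed, 2L))
  samples <- sprintf("S%02d", seq_len(cfg$n_samples))
  lay <- gm$layout
  n_per <- cfg$n_variants_per_class
  vrows <- list(); trows <- list()
  vi <- 0L
  for (cls in c("pathogenic", "benign")) {
    maf_rng <- if (cls == "pathogenic") cfg$pathogenic_maf_range else
      cfg$benign_maf_range
    shp <- if (cls == "pathogenic") cfg$pathogenic_beta else cfg$benign_beta
    for (r in seq_len(n_per)) {
      vi <- vi + 1L
      gl <- lay[[sample.int(length(lay), 1L)]]
      tid <- if (cls == "pathogenic") layout_principal(gl) else
        sample(names(gl$iso_slots), 1L)
      ts <- iso_trans_order(gl, tid)
      plen <- layout_plen(gl, tid)
      cumc <- cumsum(gl$codons[ts])
      # benign-like: prefer an alternatively spliced exon when one exists
      codon <- NA_integer_
      if (cls == "benign" && stats::runif(1) < cfg$alt_exon_pref) {
        shared_by_all <- Reduce(intersect, gl$iso_slots)
        alt_k <- which(!(ts %in% shared_by_all))
        if (length(alt_k)) {
          k <- if (length(alt_k) == 1L) alt_k else sample(alt_k, 1L)
          lo <- if (k > 1L) cumc[k - 1L] + 1L else 1L
          hi <- min(cumc[k], plen)
          if (lo <= hi) codon <- sample(seq(lo, hi), 1L)
        }
      }
      if (is.na(codon))
        codon <- max(1L, min(plen,
                             as.integer(ceiling(stats::rbeta(1, shp[1], shp[2]) * plen))))
      cds_nt <- 3L * (codon - 1L) + 1L + sample(0:2, 1L)
      # genomic position via the slot layout
      k <- findInterval(cds_nt - 1L, c(0L, 3L * cumc[-length(cumc)]))
      slot <- ts[k]
      off <- cds_nt - (if (k > 1L) 3L * cumc[k - 1L] else 0L) - 1L
      pos <- if (gl$strand == "+") gl$gstart[slot] + off else gl$gend[slot] - off
      vclass <- if (vi %% 2L == 1L) "stop_gain" else "frameshift"
      maf_draw <- 10^stats::runif(1, log10(maf_rng[1]), log10(maf_rng[2]))
      nalt <- max(1L, round(2 * cfg$cohort_size * maf_draw))
      hom_alt <- min(nalt %/% 2L, round(cfg$cohort_size * maf_draw^2))
      het <- nalt - 2L * hom_alt
      hom_ref <- cfg$cohort_size - het - hom_alt
      maf <- nalt / (2 * cfg$cohort_size)
      n_car <- min(het + hom_alt,
                   max(1L, stats::rbinom(1, cfg$n_samples, min(0.5, 2 * maf))))
      carriers <- sort(sample(samples, n_car))
      bases <- c("A", "C", "G", "T")
      refb <- sample(bases, 1L)
      if (vclass == "stop_gain") {
        ref <- refb; alt <- sample(setdiff(bases, refb), 1L)
      } else if (stats::runif(1) < 0.5) {
        ref <- refb; alt <- paste0(refb, sample(bases, 1L))
      } else {
        ref <- paste0(refb, sample(bases, 1L)); alt <- refb
      }
      vid <- sprintf("V%04d", vi)
      vrows[[vi]] <- data.frame(
        variant_id = vid, chrom = gl$chrom, pos = pos, ref = ref, alt = alt,
        vclass = vclass, maf = maf, n_hom_ref = hom_ref, n_het = het,
        n_hom_alt = hom_alt, dataset = "sim", stringsAsFactors = FALSE)
      vrows[[vi]]$carriers <- list(carriers)
      tr <- layout_truth(gl, pos, gm$domains, cfg$nmd_window)
      trows[[vi]] <- cbind(
        data.frame(variant_id = vid, gene_id = gl$gene_id, class = cls,
                   stringsAsFactors = FALSE),
        as.data.frame(tr, stringsAsFactors = FALSE))
    }
  }
  variants <- do.call(rbind, vrows)
  truth <- do.call(rbind, trows)
  rownames(variants) <- rownames(truth) <- NULL
  list(variants = variants, truth = truth, samples = samples)
}

#' Generate an expression matrix with NMD-coupled carrier reduction
#'
#' Per-gene log-normal baselines with log-scale noise; the expression of a
#' gene in samples carrying one of its NMD-target variants (per the truth
#' table) is multiplied by `1 - nmd_effect_size`. Carriers of NMD-escape
#' variants are untouched, giving the planted direction that carrier
#' z-scores should recover.
#'
#' @param cfg A [fixture_config()].
#' @param gm Result of [generate_gene_models()].
#' @param vr Result of [generate_variants()].
#' @return Numeric genes-by-samples matrix.
#' @export
generate_expression <- function(cfg, gm, vr) {
  set.seed(stage_seed(cfg$seed, 3L))
  genes <- names(gm$genes)
  baseline <- exp(stats::rnorm(length(genes), cfg$baseline_log_mean,
                               cfg$baseline_log_sd))
  m <- baseline * exp(matrix(stats::rnorm(length(genes) * cfg$n_samples,
                                          0, cfg$expr_noise_sd),
                             nrow = length(genes)))
  dimnames(m) <- list(genes, vr$samples)
  nmd_rows <- which(vr$truth$nmd_target)
  for (i in nmd_rows) {
    vid <- vr$truth$variant_id[i]
    gid <- vr$truth$gene_id[i]
    cs <- vr$variants$carriers[[match(vid, vr$variants$variant_id)]]
    m[gid, cs] <- m[gid, cs] * (1 - cfg$nmd_effect_size)
  }
  m
}

#' Sample classifier feature rows directly from a class model
#'
#' Bypasses transcripts entirely: continuous features are drawn from the
#' class Gaussians (common variance), binary features from the class
#' Bernoullis — the generative family the classifier assumes. Used for
#' parameter-recovery and Bayes-optimal-AUC checks.
#'
#' @param n1,n0 Rows per class (pathogenic, benign).
#' @param model Class model as from [default_class_model()].
#' @param seed Integer seed.
#' @return List: `X` (data frame; binary features logical), `labels`.
#' @export
generate_feature_matrix <- function(n1, n0, model = default_class_model(),
                                    seed) {
  set.seed(as.integer(seed))
  draw <- function(n, mu, theta) {
    cont <- as.data.frame(lapply(names(mu), function(k)
      stats::rnorm(n, mu[[k]], sqrt(model$nu[[k]]))))
    names(cont) <- names(mu)
    bin <- as.data.frame(lapply(names(theta), function(k)
      stats::rbinom(n, 1L, theta[[k]]) == 1L))
    names(bin) <- names(theta)
    cbind(cont, bin)
  }
  X <- rbind(draw(n1, model$mu1, model$theta1),
             draw(n0, model$mu0, model$theta0))
  list(X = X, labels = c(rep(1L, n1), rep(0L, n0)))
}

#' Monte-Carlo estimate of the Bayes-optimal AUC of a class model
#'
#' Scores a large sample from the model with the true generating parameters
#' (the Bayes-optimal classifier for that model) and returns the resulting
#' AUC — the ceiling any fitted classifier can approach.
#'
#' @param model Class model as from [default_class_model()].
#' @param n_mc Rows per class.
#' @param seed Integer seed.
#' @return AUC estimate.
#' @export
bayes_optimal_auc <- function(model, n_mc = 100000L, seed) {
  fm <- generate_feature_matrix(n_mc, n_mc, model, seed = seed)
  params <- structure(list(
    feature_names = c(names(model$mu1), names(model$theta1)),
    kinds = c(stats::setNames(rep("continuous", length(model$mu1)),
                              names(model$mu1)),
              stats::setNames(rep("binary", length(model$theta1)),
                              names(model$theta1))),
    mu1 = model$mu1, mu0 = model$mu0, nu = model$nu,
    theta1 = model$theta1, theta0 = model$theta0,
    p1 = 0.5, n1 = NA_integer_, n0 = NA_integer_,
    variance_floor = 0, smoothing = 0), class = "nb_classifier")
  auc(nb_posterior(params, fm$X), fm$labels)
}
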