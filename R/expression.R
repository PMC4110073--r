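#' Read an expression matrix (genes x samples TSV)
#'
#' First column `gene_id`, remaining columns one per sample; values are
#' nonnegative normalized abundances (e.g. RPKM or factor-normalized RPKM).
#'
#' @param path Path to the TSV.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene_id" %in% names(d))
    stop("expression TSV ", path, " missing column(s): gene_id")
  m <- as.matrix(d[, setdiff(names(d), "gene_id"), drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- d$gene_id
  if (anyNA(m)) stop("expression matrix contains missing cells")
  if (ncol(m) < 2L) stop("expression matrix needs at least 2 samples")
  m
}

#' Standardize an expression matrix per gene
#'
#' Z-scores each gene across samples: `z = (x - mean) / sd`, with the
#' population standard deviation (divisor n). Zero-variance genes cannot be
#' standardized and are dropped; their ids are attached as attribute
#' `"dropped"`.
#'
#' @param em Numeric genes-by-samples matrix.
#' @return Standardized matrix (per-gene mean 0, sd 1).
#' @export
zscore_by_gene <- function(em) {
  if (ncol(em) < 2L) stop("need at least 2 samples to standardize")
  mu <- rowMeans(em)
  sd_pop <- sqrt(rowMeans((em - mu)^2))
  keep <- sd_pop > 0
  z <- (em[keep, , drop = FALSE] - mu[keep]) / sd_pop[keep]
  attr(z, "dropped") <- rownames(em)[!keep]
  z
}

#' Average carrier expression z-score of a variant
#'
#' The mean standardized expression of the variant's gene over the samples
#' carrying the variant — the impact measure used to check that predicted
#' NMD targets are indeed expressed lower in carriers.
#'
#' @param zm Standardized matrix from [zscore_by_gene()].
#' @param gene_id Gene to evaluate.
#' @param carriers Character vector of carrier sample ids (nonempty, all
#'   present in `zm`).
#' @return Mean z-score (scalar).
#' @export
variant_expression_z <- function(zm, gene_id, carriers) {
  if (length(carriers) == 0L) stop("carrier list is empty")
  if (!gene_id %in% rownames(zm))
    stop("gene ", gene_id, " absent from expression matrix ",
         "(possibly dropped for zero variance)")
  missing <- setdiff(carriers, colnames(zm))
  if (length(missing))
    stop("carrier sample(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  mean(zm[gene_id, carriers])
}

#' Carrier z-scores for a table of annotated variants
#'
#' One z per (variant, gene) row with a nonempty carrier list whose gene
#' survives standardization.
#'
#' @param features Annotated variants (needs `variant_id`, `gene_id`).
#' @param variants Variant table carrying the `carriers` list-column.
#' @param zm Standardized matrix from [zscore_by_gene()].
#' @return Data frame `variant_id`, `gene_id`, `n_carriers`, `z`.
#' @export
carrier_zscores <- function(features, variants, zm) {
  car <- variants$carriers[match(features$variant_id, variants$variant_id)]
  rows <- lapply(seq_len(nrow(features)), function(i) {
    cs <- car[[i]]
    if (is.null(cs) || length(cs) == 0L) return(NULL)
    if (!features$gene_id[i] %in% rownames(zm)) return(NULL)
    data.frame(variant_id = features$variant_id[i],
               gene_id = features$gene_id[i],
               n_carriers = length(cs),
               z = variant_expression_z(zm, features$gene_id[i], cs),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(variant_id = character(), gene_id = character(),
                      n_carriers = integer(), z = numeric())
  rownames(out) <- NULL
  out
}

#' One-sided rank-sum comparison of two z-score groups
#'
#' Wilcoxon rank-sum test; exact for small tie-free samples, normal
#' approximation with tie correction otherwise.
#'
#' @param z_a,z_b Numeric vectors (nonempty).
#' @param alternative `"less"` (`z_a` shifted below `z_b`), `"greater"`, or
#'   `"two.sided"`.
#' @param exact_limit Largest group size for which the exact distribution is
#'   used (tie-free data only).
#' @return P-value.
#' @export
compare_groups <- function(z_a, z_b,
                           alternative = c("less", "greater", "two.sided"),
                           exact_limit = 50L) {
  alternative <- match.arg(alternative)
  if (length(z_a) == 0L || length(z_b) == 0L)
    stop("both groups must be nonempty")
  ties <- anyDuplicated(c(z_a, z_b)) > 0L
  exact <- !ties && length(z_a) <= exact_limit && length(z_b) <= exact_limit
  stats::wilcox.test(z_a, z_b, alternative = alternative,
                     exact = exact, correct = TRUE)$p.value
}

#' Score distribution across quintiles of carrier expression z-scores
#'
#' Bins the z values into five equal-count quantile bins ordered by
#' increasing z (quintile 1 = strongest expression decrease) and summarizes
#' the score rank percentiles within each bin, alongside the Spearman
#' correlation between z and rank percentile.
#'
#' @param rank_pct Score rank percentiles (0 = most pathogenic).
#' @param z Carrier expression z-scores, same length.
#' @param n_bins Number of quantile bins (default 5).
#' @return List with `bins` (per-bin n, median z, median/quartile rank
#'   percentile) and `rho`, `p` from [stats::cor.test()].
#' @export
score_expression_quintiles <- function(rank_pct, z, n_bins = 5L) {
  stopifnot(length(rank_pct) == length(z))
  n <- length(z)
  if (n < n_bins) stop("need at least ", n_bins, " observations")
  bin <- ceiling(n_bins * rank(z, ties.method = "first") / n)
  bins <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    ix <- bin == b
    data.frame(quintile = b, n = sum(ix),
               z_median = stats::median(z[ix]),
               rank_pct_median = stats::median(rank_pct[ix]),
               rank_pct_q1 = unname(stats::quantile(rank_pct[ix], 0.25)),
               rank_pct_q3 = unname(stats::quantile(rank_pct[ix], 0.75)))
  }))
  ct <- suppressWarnings(stats::cor.test(z, rank_pct, method = "spearman"))
  list(bins = bins, rho = unname(ct$estimate), p = ct$p.value)
}
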