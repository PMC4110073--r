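#' Annotate a variant file against transcript models on disk
#'
#' File-level wrapper chaining the readers and [annotate_variants()]: loads
#' transcripts (GTF or internal TSV), variants (VCF or TSV, with dialect
#' handling), optional domain and principal-isoform tables, and computes the
#' sequence feature vector per (variant, gene) pair.
#'
#' @param transcripts_path GTF or internal transcript TSV.
#' @param variants_path VCF or variant TSV.
#' @param domains_path,principal_path Optional TSV tables.
#' @param dialect Variant coordinate dialect, see [read_variants()].
#' @param autosomes_only Passed to [read_transcripts()].
#' @param nmd_window NMD distance threshold in nucleotides.
#' @param out Optional output TSV path (written with [write_features()]).
#' @return Annotated feature data frame.
#' @export
annotate_files <- function(transcripts_path, variants_path,
                           domains_path = NULL, principal_path = NULL,
                           dialect = "generic", autosomes_only = FALSE,
                           nmd_window = 50L, out = NULL) {
  genes <- read_transcripts(transcripts_path, autosomes_only = autosomes_only)
  if (!is.null(principal_path))
    genes <- set_principal(genes, read_principal(principal_path, genes))
  domains <- if (!is.null(domains_path)) read_domains(domains_path, genes)
             else NULL
  variants <- read_variants(variants_path, dialect = dialect)
  features <- annotate_variants(variants, genes, domains,
                                nmd_window = nmd_window)
  if (!is.null(out)) write_features(features, out)
  features
}

#' Train the classifier from annotated-feature and label files
#'
#' @param features_path TSV from [annotate_files()]/[write_features()].
#' @param labels_path TSV with columns `variant_id`, `label` (1 =
#'   pathogenic).
#' @param prior,variance_floor,smoothing Passed to [nb_fit()].
#' @param out Optional JSON model path (written with [write_classifier()]).
#' @return An `nb_classifier` object.
#' @export
train_files <- function(features_path, labels_path, prior = "empirical",
                        variance_floor = 1e-9, smoothing = 1, out = NULL) {
  features <- impute_features(read_features(features_path))
  lab <- utils::read.delim(labels_path, stringsAsFactors = FALSE)
  if (!all(c("variant_id", "label") %in% names(lab)))
    stop("label TSV needs columns variant_id, label")
  y <- lab$label[match(features$variant_id, lab$variant_id)]
  if (anyNA(y)) stop("label missing for some annotated variants")
  keep <- names(truncation_features())
  model <- nb_fit(features[, keep], y, prior = prior,
                  kinds = truncation_features(),
                  variance_floor = variance_floor, smoothing = smoothing)
  if (!is.null(out)) write_classifier(model, out)
  model
}

#' Score annotated variants from files
#'
#' @param features_path TSV from [annotate_files()].
#' @param model_path JSON model from [write_classifier()].
#' @param gene_scores_path Optional gene-score TSV ([read_gene_scores()]).
#' @param out Optional output TSV path.
#' @return Score table from [build_score_table()].
#' @export
score_files <- function(features_path, model_path, gene_scores_path = NULL,
                        out = NULL) {
  features <- read_features(features_path)
  model <- read_classifier(model_path)
  seq_scores <- score_variants(features, model)
  gene_scores <- if (!is.null(gene_scores_path))
    read_gene_scores(gene_scores_path) else NULL
  tab <- build_score_table(seq_scores, gene_scores)
  if (!is.null(out)) write_features(tab, out)
  tab
}

#' Subsampling ROC evaluation from files
#'
#' @param features_path TSV from [annotate_files()].
#' @param labels_path TSV with `variant_id`, `label`.
#' @param iters,seed,train_frac Passed to [roc_subsample()].
#' @param randomized Run the column-shuffle [randomization_test()] instead.
#' @param out_prefix Optional path prefix: writes `<prefix>_roc.tsv` (the
#'   pooled curve) and `<prefix>_summary.json`.
#' @return `roc_result`.
#' @export
evaluate_files <- function(features_path, labels_path, iters = 10000L, seed,
                           train_frac = 0.75, randomized = FALSE,
                           out_prefix = NULL) {
  features <- impute_features(read_features(features_path))
  lab <- utils::read.delim(labels_path, stringsAsFactors = FALSE)
  y <- lab$label[match(features$variant_id, lab$variant_id)]
  if (anyNA(y)) stop("label missing for some annotated variants")
  X <- features[, names(truncation_features())]
  fun <- if (randomized) randomization_test else roc_subsample
  res <- fun(X, y, train_frac = train_frac, iters = iters, seed = seed,
             kinds = truncation_features())
  if (!is.null(out_prefix)) {
    utils::write.table(data.frame(fpr = res$fpr, tpr = res$tpr),
                       paste0(out_prefix, "_roc.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(auc = res$auc, n_pos = res$n_pos, n_neg = res$n_neg,
           iterations = res$iterations, seed = res$seed,
           redraws = res$redraws),
      paste0(out_prefix, "_summary.json"), auto_unbox = TRUE, digits = NA)
  }
  res
}
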