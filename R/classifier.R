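#' Canonical classifier feature set
#'
#' The six sequence features used for pathogenicity scoring, with their
#' likelihood kinds: the four quantitative features (maximum fraction of
#' protein truncated, maximum domain truncation, number of isoforms, ratio of
#' isoforms affected) carry normal likelihoods; the two indicator features
#' (principal-isoform truncation, NMD-target status) carry Bernoulli
#' likelihoods.
#'
#' @return Named character vector mapping feature name to `"continuous"` or
#'   `"binary"`.
#' @export
truncation_features <- function() {
  c(fraction_affected_max = "continuous",
    domain_truncation_max = "continuous",
    n_isoforms = "continuous",
    ratio_isoforms_affected = "continuous",
    principal_truncated = "binary",
    nmd_target = "binary")
}

#' Impute classifier inputs for missing annotation
#'
#' The only two kinds of missingness the model accepts, each with its fixed
#' imputation: a gene without any domain annotation scores 0 domain
#' truncation, and a gene without a principal-isoform designation uses the
#' longest-CDS isoform (already substituted, and flagged, by
#' [principal_truncated()] at feature-computation time). Any other missing
#' feature value is an error.
#'
#' @param features Data frame of annotated variants
#'   (from [annotate_variants()]) or any data frame containing the classifier
#'   feature columns plus the `missing_domain` flag.
#' @return The data frame with `domain_truncation_max` filled in.
#' @export
impute_features <- function(features) {
  cols <- names(truncation_features())
  miss <- setdiff(cols, names(features))
  if (length(miss))
    stop("feature column(s) missing from input: ", paste(miss, collapse = ", "))
  fill <- is.na(features$domain_truncation_max)
  if (any(fill & !isTRUE_vec(features$missing_domain)))
    stop("domain_truncation_max is NA for rows not flagged missing_domain")
  features$domain_truncation_max[fill] <- 0
  for (cl in cols) {
    if (anyNA(features[[cl]]))
      stop("unsupported missingness in feature '", cl,
           "'; only domain truncation and principal isoform may be imputed")
  }
  features
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else !is.na(x) & x

#' Fit the naive Bayes pathogenicity classifier
#'
#' Maximum-likelihood fit of a naive Bayes model with class-specific means
#' and a single pooled (common intra-class) variance per continuous feature:
#' `nu_k = mean over all rows of (x_ik - mu_{c_i,k})^2` (divisor N, plain
#' MLE). Binary features get class-specific Bernoulli rates with Laplace
#' smoothing. The prior probability of pathogenicity defaults to the
#' empirical class fraction; because ranking is prior-invariant it can be
#' overridden freely.
#'
#' @param X Data frame or matrix of features (rows = variants). Logical
#'   columns are treated as binary, numeric columns as continuous, unless
#'   `kinds` overrides.
#' @param labels Binary vector (1/TRUE = pathogenic, 0/FALSE = benign).
#' @param prior `"empirical"` or a number in (0, 1).
#' @param kinds Optional named character vector (`"continuous"`/`"binary"`)
#'   per feature.
#' @param variance_floor Lower bound applied to each pooled variance, in
#'   squared feature units; guards against degenerate likelihoods on
#'   separable training sets.
#' @param smoothing Laplace pseudocount for Bernoulli rates:
#'   `theta = (s + a) / (n + 2a)`.
#' @return Object of class `nb_classifier` with elements `feature_names`,
#'   `kinds`, `mu1`, `mu0`, `nu`, `theta1`, `theta0`, `p1`, `n1`, `n0`.
#' @export
nb_fit <- function(X, labels, prior = "empirical", kinds = NULL,
                   variance_floor = 1e-9, smoothing = 1) {
  X <- as.data.frame(X)
  labels <- as.integer(as.logical(labels))
  if (anyNA(labels) || length(labels) != nrow(X))
    stop("labels must be a binary vector matching nrow(X)")
  if (length(unique(labels)) < 2L)
    stop("both classes must be present in the training labels")
  if (min(table(labels)) < 2L)
    stop("need at least 2 training rows per class")
  if (is.null(kinds))
    kinds <- vapply(X, function(col)
      if (is.logical(col)) "binary" else "continuous", character(1))
  kinds <- kinds[names(X)]
  if (anyNA(kinds) || !all(kinds %in% c("continuous", "binary")))
    stop("kinds must map every feature to 'continuous' or 'binary'")
  Xm <- as.matrix(as.data.frame(lapply(X, as.numeric)))
  if (anyNA(Xm)) stop("training matrix contains missing values; impute first")

  cont <- names(kinds)[kinds == "continuous"]
  bin <- names(kinds)[kinds == "binary"]
  i1 <- labels == 1L; i0 <- !i1
  n1 <- sum(i1); n0 <- sum(i0)

  mu1 <- colMeans(Xm[i1, cont, drop = FALSE])
  mu0 <- colMeans(Xm[i0, cont, drop = FALSE])
  dev <- Xm[, cont, drop = FALSE]
  dev[i1, ] <- sweep(dev[i1, , drop = FALSE], 2L, mu1)
  dev[i0, ] <- sweep(dev[i0, , drop = FALSE], 2L, mu0)
  nu <- colMeans(dev^2)
  floored <- nu < variance_floor
  if (any(floored)) {
    warning("zero/near-zero pooled variance floored for feature(s): ",
            paste(cont[floored], collapse = ", "))
    nu[floored] <- variance_floor
  }

  if (length(bin)) {
    bv <- Xm[, bin, drop = FALSE]
    if (!all(bv %in% c(0, 1)))
      stop("binary feature(s) contain values other than 0/1")
    theta1 <- (colSums(bv[i1, , drop = FALSE]) + smoothing) / (n1 + 2 * smoothing)
    theta0 <- (colSums(bv[i0, , drop = FALSE]) + smoothing) / (n0 + 2 * smoothing)
  } else {
    theta1 <- theta0 <- numeric(0)
  }

  p1 <- if (identical(prior, "empirical")) n1 / (n1 + n0) else as.numeric(prior)
  if (is.na(p1) || p1 <= 0 || p1 >= 1)
    stop("prior must be 'empirical' or a number strictly inside (0, 1)")

  structure(list(feature_names = names(kinds), kinds = kinds,
                 mu1 = mu1, mu0 = mu0, nu = nu,
                 theta1 = theta1, theta0 = theta0,
                 p1 = p1, n1 = n1, n0 = n0,
                 variance_floor = variance_floor, smoothing = smoothing),
            class = "nb_classifier")
}

#' @export
print.nb_classifier <- function(x, ...) {
  cat(sprintf("<nb_classifier> %d features (%d continuous, %d binary), prior p1 = %.4g\n",
              length(x$feature_names), sum(x$kinds == "continuous"),
              sum(x$kinds == "binary"), x$p1))
  cat(sprintf("  trained on %d pathogenic / %d benign rows\n", x$n1, x$n0))
  invisible(x)
}

#' Posterior probability of pathogenicity
#'
#' `p1 L1(y) / (p1 L1(y) + p0 L0(y))` where each class likelihood factorizes
#' over the K features (naive Bayes): normal densities with class mean and
#' pooled variance for continuous features, Bernoulli masses for binary
#' features. Evaluated in log space for numerical stability.
#'
#' @param model An [nb_fit()] object.
#' @param Y Data frame or matrix of complete (post-imputation) feature rows
#'   in any column order containing the model's features.
#' @param prior Optional prior override in (0, 1); defaults to the trained
#'   prior. Rankings are invariant to this choice.
#' @return Numeric vector of posterior probabilities in `[0, 1]`.
#' @export
nb_posterior <- function(model, Y, prior = NULL) {
  Y <- as.data.frame(Y)
  miss <- setdiff(model$feature_names, names(Y))
  if (length(miss))
    stop("feature row lacks column(s): ", paste(miss, collapse = ", "))
  Ym <- as.matrix(as.data.frame(lapply(Y[model$feature_names], as.numeric)))
  if (anyNA(Ym)) stop("feature rows contain missing values; impute first")
  p1 <- if (is.null(prior)) model$p1 else as.numeric(prior)
  if (p1 <= 0 || p1 >= 1) stop("prior must lie strictly inside (0, 1)")
  llr <- nb_loglik(model, Ym, class = 1L) - nb_loglik(model, Ym, class = 0L)
  1 / (1 + exp(-(llr + log(p1) - log(1 - p1))))
}

# log-likelihood of rows under one class's factorized model
nb_loglik <- function(model, Ym, class) {
  cont <- model$feature_names[model$kinds == "continuous"]
  bin <- model$feature_names[model$kinds == "binary"]
  mu <- if (class == 1L) model$mu1 else model$mu0
  th <- if (class == 1L) model$theta1 else model$theta0
  ll <- numeric(nrow(Ym))
  if (length(cont)) {
    yc <- Ym[, cont, drop = FALSE]
    ll <- ll + rowSums(
      -0.5 * log(2 * pi * rep(model$nu, each = nrow(yc))) -
        sweep(yc, 2L, mu)^2 / (2 * rep(model$nu, each = nrow(yc))))
  }
  if (length(bin)) {
    yb <- Ym[, bin, drop = FALSE]
    ll <- ll + rowSums(sweep(yb, 2L, log(th), `*`) +
                       sweep(1 - yb, 2L, log(1 - th), `*`))
  }
  ll
}

#' Score a table of annotated variants
#'
#' Imputes, evaluates the posterior for every row, and returns a score-table
#' fragment preserving input order.
#'
#' @param features Data frame from [annotate_variants()] (or any frame with
#'   the classifier columns plus `variant_id`).
#' @param model An [nb_fit()] object.
#' @param prior Optional prior override.
#' @return Data frame with `variant_id`, `gene_id` (if present) and
#'   `score_seq`.
#' @export
score_variants <- function(features, model, prior = NULL) {
  if (nrow(features) == 0L)
    return(data.frame(variant_id = character(), score_seq = numeric(),
                      stringsAsFactors = FALSE))
  features <- impute_features(features)
  out <- data.frame(variant_id = features$variant_id,
                    stringsAsFactors = FALSE)
  if ("gene_id" %in% names(features)) out$gene_id <- features$gene_id
  out$score_seq <- nb_posterior(model, features, prior = prior)
  out
}

#' Persist a fitted classifier as JSON
#'
#' Plain-text model document: feature names and kinds, all parameters, and
#' the training-set dimensions.
#'
#' @param model An [nb_fit()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classifier <- function(model, path) {
  doc <- list(format = "truncscore-nb", version = 1L,
              feature_names = model$feature_names,
              kinds = as.list(model$kinds),
              mu1 = as.list(model$mu1), mu0 = as.list(model$mu0),
              nu = as.list(model$nu),
              theta1 = as.list(model$theta1), theta0 = as.list(model$theta0),
              p1 = model$p1, n1 = model$n1, n0 = model$n0,
              variance_floor = model$variance_floor,
              smoothing = model$smoothing)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a classifier written by [write_classifier()]
#'
#' @param path Path to the JSON document.
#' @return An `nb_classifier` object.
#' @export
read_classifier <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "truncscore-nb"))
    stop(path, " is not a truncscore classifier document")
  unl <- function(x) unlist(x)
  structure(list(
    feature_names = unl(doc$feature_names),
    kinds = unl(doc$kinds),
    mu1 = unl(doc$mu1), mu0 = unl(doc$mu0), nu = unl(doc$nu),
    theta1 = if (length(doc$theta1)) unl(doc$theta1) else numeric(0),
    theta0 = if (length(doc$theta0)) unl(doc$theta0) else numeric(0),
    p1 = doc$p1, n1 = doc$n1, n0 = doc$n0,
    variance_floor = doc$variance_floor, smoothing = doc$smoothing),
    class = "nb_classifier")
}
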