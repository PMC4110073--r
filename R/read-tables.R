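#' Read a protein-domain table
#'
#' Tab-separated columns `transcript_id`, `domain_id`, `start_aa`, `end_aa`
#' (1-based inclusive protein coordinates, InterPro-supermatch style). When
#' `genes` is supplied, domains ending beyond the protein length of the named
#' transcript raise an error, and domains on unknown transcripts are dropped
#' with a warning.
#'
#' @param path Path to the TSV.
#' @param genes Optional named list of [gene_model()] objects for validation.
#' @return Data frame of domain annotations.
#' @export
read_domains <- function(path, genes = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "domain_id", "start_aa", "end_aa")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("domain TSV ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  d$start_aa <- as.integer(d$start_aa); d$end_aa <- as.integer(d$end_aa)
  if (any(is.na(d$start_aa)) || any(is.na(d$end_aa)) ||
      any(d$start_aa < 1L) || any(d$end_aa < d$start_aa))
    stop("malformed domain bounds in ", path,
         " (need 1 <= start_aa <= end_aa)")
  if (!is.null(genes)) {
    tx <- transcript_index(genes)
    known <- d$transcript_id %in% names(tx)
    if (any(!known)) {
      warning("dropping domains on unknown transcripts: ",
              paste(unique(d$transcript_id[!known]), collapse = ", "))
      d <- d[known, , drop = FALSE]
    }
    plen <- vapply(tx[d$transcript_id], function(t) t$protein_length_aa,
                   integer(1))
    if (any(d$end_aa > plen))
      stop("domain(s) extend beyond protein length: ",
           paste(d$domain_id[d$end_aa > plen], collapse = ", "))
  }
  rownames(d) <- NULL
  d
}

#' Read a gene-based score table
#'
#' Tab-separated with a `gene_id` column plus any of `gene_score` (a
#' probability of pathogenicity, e.g. the conservation/network gene-level
#' probability) and `rvis` (raw residual variation intolerance score, any
#' real). Duplicate gene ids keep the last row, with a warning. Probability
#' columns outside `[0, 1]` are an error; raw RVIS is unconstrained and can
#' be mapped to a probability with [rvis_to_prob()].
#'
#' @param path Path to the TSV.
#' @return Data frame keyed by `gene_id`.
#' @export
read_gene_scores <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(d))
    stop("gene-score TSV ", path, " missing column(s): gene_id")
  if (anyDuplicated(d$gene_id)) {
    warning("duplicate gene ids in ", path, "; keeping last occurrence")
    d <- d[!duplicated(d$gene_id, fromLast = TRUE), , drop = FALSE]
  }
  if ("gene_score" %in% names(d)) {
    d$gene_score <- as.numeric(d$gene_score)
    bad <- !is.na(d$gene_score) & (d$gene_score < 0 | d$gene_score > 1)
    if (any(bad))
      stop("gene_score outside [0,1] for: ",
           paste(d$gene_id[bad], collapse = ", "))
  }
  if ("rvis" %in% names(d)) d$rvis <- as.numeric(d$rvis)
  rownames(d) <- NULL
  d
}

#' Read a principal-isoform table
#'
#' Tab-separated columns `gene_id`, `transcript_id` (APPRIS-like principal
#' designation). Duplicate genes keep the last row with a warning. When
#' `genes` is supplied, entries naming an unknown gene or a transcript not
#' belonging to that gene are dropped with a warning.
#'
#' @param path Path to the TSV.
#' @param genes Optional named list of [gene_model()] objects to validate
#'   against.
#' @return Data frame with columns `gene_id`, `transcript_id`.
#' @export
read_principal <- function(path, genes = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("gene_id", "transcript_id"), names(d))
  if (length(miss))
    stop("principal TSV ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(d$gene_id)) {
    warning("duplicate gene ids in ", path, "; keeping last occurrence")
    d <- d[!duplicated(d$gene_id, fromLast = TRUE), , drop = FALSE]
  }
  if (!is.null(genes)) {
    ok <- vapply(seq_len(nrow(d)), function(i) {
      g <- genes[[d$gene_id[i]]]
      !is.null(g) && d$transcript_id[i] %in% names(g$transcripts)
    }, logical(1))
    if (any(!ok)) {
      warning("dropping principal entries with unknown gene/transcript: ",
              paste(d$gene_id[!ok], collapse = ", "))
      d <- d[ok, , drop = FALSE]
    }
  }
  rownames(d) <- NULL
  d
}

# flat transcript_id -> transcript_model lookup over a gene list
transcript_index <- function(genes) {
  tx <- unlist(lapply(genes, function(g) g$transcripts), recursive = FALSE)
  names(tx) <- vapply(tx, function(t) t$transcript_id, character(1))
  tx
}
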