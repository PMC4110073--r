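#' Truncation point of a variant on one isoform
#'
#' The 1-based codon index containing the variant position on the given
#' isoform, or `NA` when the position is non-coding for that isoform. Both
#' stop-gains and frameshifts are modeled as truncating from this codon
#' onward: every residue from the truncation codon to the protein end counts
#' as affected. For frameshifts the position is the (dialect-adjusted) base
#' of the insertion/deletion event.
#'
#' @param pos Genomic position (1-based) of the variant.
#' @param t A [transcript_model()].
#' @return Codon index, or `NA`.
#' @export
truncation_point <- function(pos, t) {
  cds <- genomic_to_cds(t, pos)
  codon_of(cds)
}

#' Fraction of the protein at or downstream of the truncation codon
#'
#' `(protein_length_aa - codon + 1) / protein_length_aa`, the "length of
#' transcript affected" on one isoform expressed as a fraction of residues.
#' A truncation codon inside the natural stop codon (one past the last
#' residue) clamps to the last residue with a warning rather than erroring.
#'
#' @param codon 1-based truncation codon index (not `NA`).
#' @param t A [transcript_model()].
#' @return Fraction in `(0, 1]`.
#' @export
fraction_affected <- function(codon, t) {
  plen <- t$protein_length_aa
  if (is.na(codon)) stop("truncation codon is NA; variant not coding in ",
                         t$transcript_id)
  if (codon > plen) {
    warning("variant in natural stop codon of ", t$transcript_id,
            "; clamping to last residue")
    codon <- plen
  }
  (plen - codon + 1) / plen
}

#' Domain truncation on one isoform
#'
#' For every domain annotated on the transcript, the fraction of its residues
#' at or downstream of the truncation codon; the maximum over domains is the
#' classifier feature. A variant strictly upstream of a domain start loses
#' that domain completely (`fraction = 1`).
#'
#' @param codon 1-based truncation codon index.
#' @param t A [transcript_model()].
#' @param domains Data frame from [read_domains()] (any subset; rows are
#'   filtered to `t$transcript_id`).
#' @return List with `max_fraction` (`NA` when the transcript has no domain
#'   annotation — imputed to 0 by the classifier), `any_complete_loss`, and
#'   `n_domains`.
#' @export
domain_truncation <- function(codon, t, domains) {
  d <- domains[domains$transcript_id == t$transcript_id, , drop = FALSE]
  if (nrow(d) == 0L)
    return(list(max_fraction = NA_real_, any_complete_loss = FALSE,
                n_domains = 0L))
  if (any(d$end_aa > t$protein_length_aa))
    stop("domain outside protein bounds on ", t$transcript_id)
  lost <- pmax(0L, d$end_aa - pmax(d$start_aa, codon) + 1L)
  frac <- lost / (d$end_aa - d$start_aa + 1L)
  list(max_fraction = max(frac),
       any_complete_loss = any(codon <= d$start_aa),
       n_domains = nrow(d))
}

#' Isoform usage of a variant position within a gene
#'
#' Counts how many isoforms of the gene are affected (the position is coding
#' for them). A position affecting every isoform is constitutively spliced;
#' one affecting a strict subset is alternatively spliced.
#'
#' @param pos Genomic position (1-based).
#' @param g A [gene_model()].
#' @return List with `n_isoforms`, `n_affected`, `ratio` and
#'   `constitutive_position`.
#' @export
isoform_summary <- function(pos, g) {
  aff <- vapply(g$transcripts, function(t) !is.na(genomic_to_cds(t, pos)),
                logical(1))
  n <- length(aff); na <- sum(aff)
  if (na == 0L)
    stop("variant at ", g$chrom, ":", pos, " is non-coding in all isoforms of ",
         g$gene_id)
  list(n_isoforms = n, n_affected = na, ratio = na / n,
       constitutive_position = na == n)
}

#' Does a variant truncate the principal isoform?
#'
#' Uses the annotated principal transcript when present; otherwise the
#' longest-CDS isoform substitutes (deterministic lexicographic tie-break)
#' and `missing_principal` is `TRUE` — the imputation applied ahead of
#' classification.
#'
#' @param pos Genomic position (1-based).
#' @param g A [gene_model()].
#' @return List with `principal_truncated`, `missing_principal`,
#'   `principal_id`.
#' @export
principal_truncated <- function(pos, g) {
  pr <- principal_transcript(g)
  list(principal_truncated = !is.na(genomic_to_cds(pr$transcript, pos)),
       missing_principal = pr$missing_principal,
       principal_id = pr$transcript$transcript_id)
}

#' Is a position in the NMD-target region of one isoform?
#'
#' The NMD-target region comprises positions more than 50 nucleotides
#' upstream of the transcript's 3'-most exon-exon junction ("more than" is
#' strict: a distance of exactly 50 escapes). The distance is measured from
#' the variant's first affected CDS nucleotide. Transcripts without a
#' junction (single coding segment, no override) escape NMD.
#'
#' @param pos Genomic position (1-based).
#' @param t A [transcript_model()].
#' @param nmd_window Distance threshold in nucleotides (default 50).
#' @return `TRUE`/`FALSE`, or `NA` when the position is non-coding in `t`.
#' @export
nmd_target <- function(pos, t, nmd_window = 50L) {
  cds <- genomic_to_cds(t, pos)
  if (is.na(cds)) return(NA)
  j <- last_junction_cds(t)
  if (is.na(j)) return(FALSE)
  (j - cds) > nmd_window
}

#' NMD prediction aggregated over the affected isoforms of a gene
#'
#' @param pos Genomic position (1-based).
#' @param g A [gene_model()].
#' @param nmd_window Distance threshold in nucleotides.
#' @return `"all"`, `"some"` or `"none"`: whether the position is in the
#'   NMD-target region of every, at least one, or no affected isoform.
#' @export
nmd_isoform_scope <- function(pos, g, nmd_window = 50L) {
  nmd <- vapply(g$transcripts, function(t) nmd_target(pos, t, nmd_window),
                logical(1))
  nmd <- nmd[!is.na(nmd)]
  if (length(nmd) == 0L)
    stop("variant non-coding in all isoforms of ", g$gene_id)
  if (all(nmd)) "all" else if (any(nmd)) "some" else "none"
}

#' Sequence feature vector of one variant
#'
#' Computes the classifier's six sequence features for a variant against all
#' isoforms of its gene: maximum fraction of protein truncated and maximum
#' domain truncation over affected isoforms, number of isoforms and ratio
#' affected, principal-isoform truncation, and NMD-target status (true when
#' at least one affected isoform is predicted to be degraded). Analysis-only
#' flags record missingness, constitutive splicing and the stricter
#' all/some/none NMD scope.
#'
#' @param pos Genomic position (1-based, dialect-adjusted for frameshifts).
#' @param g A [gene_model()].
#' @param domains Data frame from [read_domains()], or `NULL` (no domain
#'   annotation anywhere; `domain_truncation_max` is then `NA` and flagged
#'   missing).
#' @param nmd_window NMD distance threshold in nucleotides.
#' @return Named list: `fraction_affected_max`, `domain_truncation_max`,
#'   `n_isoforms`, `ratio_isoforms_affected`, `principal_truncated`,
#'   `nmd_target`, and flags `missing_domain`, `missing_principal`,
#'   `constitutive_position`, `nmd_all_isoforms`, `any_complete_domain_loss`.
#' @export
compute_feature_vector <- function(pos, g, domains = NULL, nmd_window = 50L) {
  if (is.null(domains))
    domains <- data.frame(transcript_id = character(), domain_id = character(),
                          start_aa = integer(), end_aa = integer())
  iso <- isoform_summary(pos, g)
  frac_max <- -Inf
  dom_max <- NA_real_
  any_loss <- FALSE
  any_dom <- FALSE
  nmd_any <- FALSE
  nmd_all <- TRUE
  for (t in g$transcripts) {
    codon <- truncation_point(pos, t)
    if (is.na(codon)) next
    frac_max <- max(frac_max, fraction_affected(codon, t))
    dt <- domain_truncation(codon, t, domains)
    if (dt$n_domains > 0L) {
      any_dom <- TRUE
      dom_max <- max(dom_max, dt$max_fraction, na.rm = TRUE)
      any_loss <- any_loss || dt$any_complete_loss
    }
    nt <- nmd_target(pos, t, nmd_window)
    nmd_any <- nmd_any || nt
    nmd_all <- nmd_all && nt
  }
  pr <- principal_truncated(pos, g)
  list(fraction_affected_max = frac_max,
       domain_truncation_max = if (any_dom) dom_max else NA_real_,
       n_isoforms = iso$n_isoforms,
       ratio_isoforms_affected = iso$ratio,
       principal_truncated = pr$principal_truncated,
       nmd_target = nmd_any,
       missing_domain = !any_dom,
       missing_principal = pr$missing_principal,
       constitutive_position = iso$constitutive_position,
       nmd_all_isoforms = if (nmd_all) "all" else if (nmd_any) "some" else "none",
       any_complete_domain_loss = any_loss)
}

#' Annotate a variant table with sequence features
#'
#' Assigns each variant to the gene model(s) whose genomic span contains its
#' position (a variant overlapping several genes yields one row per gene,
#' with the multiplicity recorded), then computes the feature vector per
#' (variant, gene) pair. Variants whose position is coding in no isoform of
#' the assigned gene are retained with `NA` features and flagged
#' `non_coding_all_isoforms`; variants overlapping no gene are dropped and
#' listed in the `"unassigned"` attribute.
#'
#' @param variants Data frame from [read_variants()].
#' @param genes Named list of [gene_model()] objects.
#' @param domains Optional data frame from [read_domains()].
#' @param nmd_window NMD distance threshold in nucleotides.
#' @return Data frame: variant columns, `gene_id`, `n_genes_overlapped`, the
#'   feature columns of [compute_feature_vector()] and the flags.
#' @export
annotate_variants <- function(variants, genes, domains = NULL,
                              nmd_window = 50L) {
  spans <- t(vapply(genes, gene_span, c(start = 0L, end = 0L)))
  chroms <- vapply(genes, function(g) g$chrom, character(1))
  rows <- list()
  unassigned <- character()
  for (i in seq_len(nrow(variants))) {
    hit <- which(chroms == variants$chrom[i] &
                 spans[, "start"] <= variants$pos[i] &
                 variants$pos[i] <= spans[, "end"])
    if (length(hit) == 0L) {
      unassigned <- c(unassigned, variants$variant_id[i])
      next
    }
    for (h in hit) {
      g <- genes[[h]]
      fv <- tryCatch(compute_feature_vector(variants$pos[i], g, domains,
                                            nmd_window),
                     error = function(e) NULL)
      base <- data.frame(
        variant_id = variants$variant_id[i],
        gene_id = g$gene_id,
        vclass = variants$vclass[i],
        maf = variants$maf[i],
        n_genes_overlapped = length(hit),
        stringsAsFactors = FALSE)
      if (is.null(fv)) {
        base$fraction_affected_max <- NA_real_
        base$domain_truncation_max <- NA_real_
        base$n_isoforms <- length(g$transcripts)
        base$ratio_isoforms_affected <- NA_real_
        base$principal_truncated <- NA
        base$nmd_target <- NA
        base$missing_domain <- NA
        base$missing_principal <- NA
        base$constitutive_position <- NA
        base$nmd_all_isoforms <- NA_character_
        base$any_complete_domain_loss <- NA
        base$non_coding_all_isoforms <- TRUE
      } else {
        for (nm in names(fv)) base[[nm]] <- fv[[nm]]
        base$non_coding_all_isoforms <- FALSE
      }
      rows[[length(rows) + 1L]] <- base
    }
  }
  if (length(rows) == 0L) stop("no variant overlapped any gene model")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "unassigned") <- unassigned
  out
}
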