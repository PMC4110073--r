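#' Construct a transcript model from CDS intervals
#'
#' A transcript model holds the coding (CDS) intervals of one isoform, the
#' coordinate substrate for every sequence feature in the package. Intervals
#' are supplied 1-based inclusive (GTF/CCDS convention) and stored internally
#' 0-based half-open; conversion happens only here, so all downstream interval
#' arithmetic is off-by-one free.
#'
#' The CDS is taken to include the natural stop codon (CCDS convention), so
#' the protein length is `coding_length_nt / 3 - 1` residues.
#'
#' @param transcript_id,gene_id Character identifiers.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param starts,ends Integer vectors of CDS interval starts/ends, 1-based
#'   inclusive, in genomic order.
#' @param junction_cds Optional override for the spliced-CDS coordinate of the
#'   transcript's last exon-exon junction, for users whose annotation includes
#'   UTR exons (the junction may then lie beyond the coding length). `NA`
#'   (default) means "use the last CDS-segment junction".
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand,
                             starts, ends, junction_cds = NA_integer_) {
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L,
            is.character(gene_id), length(gene_id) == 1L,
            length(chrom) == 1L, length(strand) == 1L)
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-' for transcript ", transcript_id)
  starts <- as.integer(starts); ends <- as.integer(ends)
  if (length(starts) == 0L || length(starts) != length(ends))
    stop("starts/ends must be nonempty and of equal length (", transcript_id, ")")
  if (any(is.na(starts)) || any(is.na(ends)) || any(starts > ends))
    stop("malformed CDS interval in transcript ", transcript_id)
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  if (length(starts) > 1L && any(starts[-1L] <= ends[-length(ends)]))
    stop("overlapping CDS intervals in transcript ", transcript_id)
  cds <- cbind(start = starts - 1L, end = ends)  # 0-based half-open
  len <- sum(cds[, "end"] - cds[, "start"])
  if (len %% 3L != 0L)
    stop("CDS length ", len, " not divisible by 3 in transcript ", transcript_id)
  if (len < 6L)
    stop("CDS shorter than two codons in transcript ", transcript_id)
  structure(
    list(transcript_id = transcript_id,
         gene_id = gene_id,
         chrom = as.character(chrom),
         strand = strand,
         cds = cds,
         coding_length_nt = as.integer(len),
         protein_length_aa = as.integer(len %/% 3L - 1L),
         junction_cds = as.integer(junction_cds)),
    class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%s strand %s\n",
              x$transcript_id, x$gene_id, x$chrom,
              paste0(x$cds[1, 1] + 1L, "-", x$cds[nrow(x$cds), 2]), x$strand))
  cat(sprintf("  %d CDS segment(s), %d nt coding, %d aa protein\n",
              nrow(x$cds), x$coding_length_nt, x$protein_length_aa))
  invisible(x)
}

#' Construct a gene model from transcript models
#'
#' @param gene_id Gene identifier; all transcripts must carry it.
#' @param transcripts List of [transcript_model()] objects (at least one),
#'   all on the same chromosome.
#' @param principal_transcript_id Optional identifier of the principal isoform
#'   (APPRIS-like designation); must name a member transcript.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, transcripts, principal_transcript_id = NA_character_) {
  stopifnot(is.list(transcripts), length(transcripts) >= 1L)
  ids <- vapply(transcripts, function(t) t$transcript_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate transcript ids in gene ", gene_id)
  if (!all(vapply(transcripts, function(t) t$gene_id, character(1)) == gene_id))
    stop("transcripts disagree on gene_id for gene ", gene_id)
  chroms <- unique(vapply(transcripts, function(t) t$chrom, character(1)))
  if (length(chroms) != 1L)
    stop("transcripts of gene ", gene_id, " span multiple chromosomes")
  if (!is.na(principal_transcript_id) && !principal_transcript_id %in% ids)
    stop("principal transcript ", principal_transcript_id,
         " is not a member of gene ", gene_id)
  names(transcripts) <- ids
  structure(
    list(gene_id = gene_id, chrom = chroms, transcripts = transcripts,
         principal_transcript_id = principal_transcript_id),
    class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s on %s: %d isoform(s)%s\n", x$gene_id, x$chrom,
              length(x$transcripts),
              if (is.na(x$principal_transcript_id)) ""
              else paste0(", principal ", x$principal_transcript_id)))
  invisible(x)
}

#' Map genomic positions to spliced CDS coordinates
#'
#' Returns the 1-based offset of a genomic position within the spliced CDS of
#' a transcript, counted 5' to 3' in transcription order (so on the minus
#' strand the 3'-most genomic base of the CDS is position 1). Positions
#' outside every CDS interval map to `NA` — a valid "not coding in this
#' isoform" answer, not an error.
#'
#' @param t A [transcript_model()].
#' @param gpos Integer vector of genomic positions, 1-based.
#' @return Integer vector of CDS positions in `1..coding_length_nt`, `NA`
#'   where `gpos` is non-coding for this isoform.
#' @seealso [cds_to_genomic()] for the inverse.
#' @export
genomic_to_cds <- function(t, gpos) {
  g0 <- as.integer(gpos) - 1L
  s <- t$cds[, "start"]; e <- t$cds[, "end"]
  lens <- e - s
  idx <- findInterval(g0, s)
  inside <- idx >= 1L & g0 < e[pmax(idx, 1L)]
  out <- rep(NA_integer_, length(g0))
  if (any(inside)) {
    i <- idx[inside]
    if (t$strand == "+") {
      prior <- c(0L, cumsum(lens))[i]
      out[inside] <- prior + (g0[inside] - s[i]) + 1L
    } else {
      after <- sum(lens) - cumsum(lens)[i]
      out[inside] <- after + (e[i] - 1L - g0[inside]) + 1L
    }
  }
  out
}

#' Map spliced CDS coordinates back to genomic positions
#'
#' Inverse of [genomic_to_cds()]: position 1 is the first coding base in
#' transcription order.
#'
#' @param t A [transcript_model()].
#' @param cds_nt Integer vector of 1-based spliced CDS positions.
#' @return Integer vector of 1-based genomic positions.
#' @export
cds_to_genomic <- function(t, cds_nt) {
  cds_nt <- as.integer(cds_nt)
  if (any(is.na(cds_nt)) || any(cds_nt < 1L) || any(cds_nt > t$coding_length_nt))
    stop("cds_nt out of range 1..", t$coding_length_nt,
         " for transcript ", t$transcript_id)
  s <- t$cds[, "start"]; e <- t$cds[, "end"]
  lens <- e - s
  if (t$strand == "+") {
    cum <- cumsum(lens)
    i <- findInterval(cds_nt - 1L, c(0L, cum[-length(cum)]))
    unname(s[i] + (cds_nt - c(0L, cum)[i] - 1L) + 1L)
  } else {
    rl <- rev(lens)                       # transcription order
    cum <- cumsum(rl)
    i <- findInterval(cds_nt - 1L, c(0L, cum[-length(cum)]))
    gi <- length(lens) - i + 1L           # genomic index of that segment
    unname(e[gi] - (cds_nt - c(0L, cum)[i] - 1L))
  }
}

#' CDS coordinate of the last exon-exon junction
#'
#' The spliced-CDS position (1-based, transcription order) of the last
#' nucleotide of the penultimate CDS segment — the 3'-most exon-exon junction
#' as seen by the nonsense-mediated decay rule when only coding exons are
#' modeled. Transcripts carrying a `junction_cds` override (annotations with
#' UTR exons) return that value instead, and may return a junction for a
#' single-segment CDS.
#'
#' @param t A [transcript_model()].
#' @return Integer CDS coordinate, or `NA` for single-segment transcripts
#'   without an override (such transcripts escape NMD).
#' @export
last_junction_cds <- function(t) {
  if (!is.na(t$junction_cds)) return(t$junction_cds)
  n <- nrow(t$cds)
  if (n == 1L) return(NA_integer_)
  lens <- t$cds[, "end"] - t$cds[, "start"]
  last_len <- if (t$strand == "+") lens[n] else lens[1L]
  as.integer(t$coding_length_nt - last_len)
}

#' Codon index of a CDS nucleotide position
#'
#' @param cds_nt Integer vector of 1-based spliced CDS positions.
#' @return 1-based codon indices, `ceiling(cds_nt / 3)`.
#' @export
codon_of <- function(cds_nt) as.integer(ceiling(cds_nt / 3))

# genomic span of a gene (min start, max end over all transcript CDS), used
# for variant-to-gene assignment
gene_span <- function(g) {
  m <- do.call(rbind, lapply(g$transcripts, function(t) t$cds))
  c(start = min(m[, "start"]) + 1L, end = max(m[, "end"]))
}

#' Principal isoform of a gene, with longest-CDS fallback
#'
#' When no principal transcript is annotated, the isoform with the longest
#' CDS substitutes (ties broken deterministically by lexicographically
#' smallest transcript id) and the result is flagged as imputed.
#'
#' @param g A [gene_model()].
#' @return List with `transcript` (a [transcript_model()]) and
#'   `missing_principal` (logical: `TRUE` when the fallback was used).
#' @export
principal_transcript <- function(g) {
  if (!is.na(g$principal_transcript_id)) {
    return(list(transcript = g$transcripts[[g$principal_transcript_id]],
                missing_principal = FALSE))
  }
  lens <- vapply(g$transcripts, function(t) t$coding_length_nt, integer(1))
  ids <- names(g$transcripts)
  cand <- sort(ids[lens == max(lens)])
  list(transcript = g$transcripts[[cand[1L]]], missing_principal = TRUE)
}
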