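#' Read gene models from a GTF file or internal transcript TSV
#'
#' GTF files are parsed with rtracklayer; only `CDS` features are used, and
#' records must carry `gene_id` and `transcript_id` attributes. The internal
#' TSV format (written by [write_transcripts()]) stores one row per transcript
#' with comma-separated 1-based inclusive CDS interval bounds and round-trips
#' gene models exactly.
#'
#' Transcripts violating the model invariants (CDS length not divisible by 3,
#' overlapping intervals, fewer than two codons) are excluded, not fatal; the
#' exclusions are attached as attribute `"exclusions"` (a data frame of
#' transcript id and reason).
#'
#' @param path Path to a `.gtf`/`.gff` file or the internal TSV.
#' @param format `"auto"` (by extension), `"gtf"` or `"tsv"`.
#' @param autosomes_only Keep only chromosomes named `1..22` (optionally
#'   `chr`-prefixed), the conservative core set used for human coding
#'   analyses.
#' @return Named list of [gene_model()] objects, with attribute
#'   `"exclusions"`.
#' @export
read_transcripts <- function(path, format = c("auto", "gtf", "tsv"),
                             autosomes_only = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gtf", "gff", "gff3")) "gtf" else "tsv"
  }
  tx_rows <- if (format == "gtf") gtf_transcript_rows(path) else tsv_transcript_rows(path)

  if (autosomes_only) {
    auto <- c(as.character(1:22), paste0("chr", 1:22))
    tx_rows <- tx_rows[vapply(tx_rows, function(r) r$chrom %in% auto, logical(1))]
  }

  excl <- list()
  txs <- list()
  for (r in tx_rows) {
    t <- tryCatch(
      transcript_model(r$transcript_id, r$gene_id, r$chrom, r$strand,
                       r$starts, r$ends, junction_cds = r$junction_cds),
      error = function(e) conditionMessage(e))
    if (is.character(t)) {
      excl[[length(excl) + 1L]] <- data.frame(
        transcript_id = r$transcript_id, reason = t,
        stringsAsFactors = FALSE)
    } else {
      txs[[length(txs) + 1L]] <- t
    }
  }
  if (length(txs) == 0L)
    stop("no valid transcripts in ", path)

  gene_ids <- vapply(txs, function(t) t$gene_id, character(1))
  genes <- lapply(split(txs, gene_ids), function(tt)
    gene_model(tt[[1L]]$gene_id, tt))
  # principal flags from the TSV format
  principal <- unlist(lapply(tx_rows, function(r)
    if (isTRUE(r$is_principal)) stats::setNames(r$transcript_id, r$gene_id)))
  if (length(principal)) {
    for (gid in names(principal)) {
      if (gid %in% names(genes) &&
          principal[[gid]] %in% names(genes[[gid]]$transcripts))
        genes[[gid]]$principal_transcript_id <- principal[[gid]]
    }
  }
  genes <- genes[order(names(genes))]
  attr(genes, "exclusions") <-
    if (length(excl)) do.call(rbind, excl)
    else data.frame(transcript_id = character(), reason = character(),
                    stringsAsFactors = FALSE)
  genes
}

gtf_transcript_rows <- function(path) {
  gr <- tryCatch(rtracklayer::import(path),
                 error = function(e) stop("failed to parse ", path, ": ",
                                          conditionMessage(e)))
  df <- as.data.frame(gr)
  if (!all(c("type", "gene_id", "transcript_id") %in% names(df)))
    stop("GTF ", path, " lacks type/gene_id/transcript_id attributes")
  df <- df[df$type == "CDS", , drop = FALSE]
  if (nrow(df) == 0L) stop("no valid transcripts: no CDS records in ", path)
  rows <- split(df, df$transcript_id)
  lapply(rows, function(d) list(
    transcript_id = as.character(d$transcript_id[1L]),
    gene_id = as.character(d$gene_id[1L]),
    chrom = as.character(d$seqnames[1L]),
    strand = as.character(d$strand[1L]),
    starts = d$start, ends = d$end,
    junction_cds = NA_integer_, is_principal = FALSE))
}

tsv_transcript_rows <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("gene_id", "transcript_id", "chrom", "strand",
            "cds_starts", "cds_ends")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("transcript TSV ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  lapply(seq_len(nrow(d)), function(i) {
    starts <- as.integer(strsplit(d$cds_starts[i], ",", fixed = TRUE)[[1L]])
    ends <- as.integer(strsplit(d$cds_ends[i], ",", fixed = TRUE)[[1L]])
    if (any(is.na(starts)) || any(is.na(ends)))
      stop("unparseable CDS bounds at line ", i + 1L, " of ", path)
    list(transcript_id = d$transcript_id[i], gene_id = d$gene_id[i],
         chrom = d$chrom[i], strand = d$strand[i],
         starts = starts, ends = ends,
         junction_cds = if ("junction_cds" %in% names(d))
           suppressWarnings(as.integer(d$junction_cds[i])) else NA_integer_,
         is_principal = if ("is_principal" %in% names(d))
           d$is_principal[i] %in% c("1", "TRUE") else FALSE)
  })
}

#' Write gene models to the internal transcript TSV
#'
#' One row per transcript; CDS interval bounds are written 1-based inclusive
#' and comma-separated. [read_transcripts()] on the output reconstructs the
#' models exactly, including principal-isoform designations and junction
#' overrides.
#'
#' @param genes Named list of [gene_model()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcripts <- function(genes, path) {
  rows <- lapply(genes, function(g) {
    do.call(rbind, lapply(g$transcripts, function(t) data.frame(
      gene_id = g$gene_id,
      transcript_id = t$transcript_id,
      chrom = t$chrom,
      strand = t$strand,
      cds_starts = paste(t$cds[, "start"] + 1L, collapse = ","),
      cds_ends = paste(t$cds[, "end"], collapse = ","),
      junction_cds = t$junction_cds,
      is_principal = as.integer(identical(t$transcript_id,
                                          g$principal_transcript_id)),
      stringsAsFactors = FALSE)))
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Attach principal-isoform designations to gene models
#'
#' Entries naming a gene absent from `genes`, or a transcript absent from the
#' gene's isoform list, are dropped with a warning (typical when an
#' APPRIS-like table is newer than the transcript set).
#'
#' @param genes Named list of [gene_model()] objects.
#' @param principal_map Named character vector or two-column data frame
#'   (`gene_id`, `transcript_id`).
#' @return The gene list with `principal_transcript_id` set where valid.
#' @export
set_principal <- function(genes, principal_map) {
  if (is.data.frame(principal_map))
    principal_map <- stats::setNames(principal_map$transcript_id,
                                     principal_map$gene_id)
  dropped <- character()
  for (gid in names(principal_map)) {
    tid <- principal_map[[gid]]
    if (!gid %in% names(genes) || !tid %in% names(genes[[gid]]$transcripts)) {
      dropped <- c(dropped, gid)
      next
    }
    genes[[gid]]$principal_transcript_id <- tid
  }
  if (length(dropped))
    warning("dropped principal-isoform entries with unknown gene/transcript: ",
            paste(dropped, collapse = ", "))
  genes
}
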