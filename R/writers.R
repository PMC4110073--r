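# deterministic full-precision numeric formatting for fixture files
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (v == round(v) && abs(v) < 1e15) return(sprintf("%.0f", v))
    sprintf("%.17g", v)
  }, character(1))
  out
}

#' Write gene models as a GTF file
#'
#' One `CDS` feature line per coding interval, with `gene_id` and
#' `transcript_id` attributes; readable by rtracklayer and by
#' [read_transcripts()]. Output order is deterministic (genes and
#' transcripts sorted by id).
#'
#' @param genes Named list of [gene_model()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  lines <- character()
  for (gid in sort(names(genes))) {
    g <- genes[[gid]]
    for (tid in sort(names(g$transcripts))) {
      t <- g$transcripts[[tid]]
      for (r in seq_len(nrow(t$cds))) {
        lines <- c(lines, sprintf(
          "%s\ttruncscore\tCDS\t%d\t%d\t.\t%s\t0\tgene_id \"%s\"; transcript_id \"%s\";",
          t$chrom, t$cds[r, "start"] + 1L, t$cds[r, "end"], t$strand,
          g$gene_id, t$transcript_id))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a variant table as a VCF file
#'
#' VCF v4.2 with INFO keys `VCLASS`, `MAF`, `GTC` (cohort genotype counts)
#' and `DATASET`; when `samples` is given, a `GT` column per sample encodes
#' carriers (heterozygous) among the expression panel.
#'
#' @param variants Variant data frame (see [read_variants()] for columns).
#' @param path Output path.
#' @param samples Optional character vector of sample ids.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, samples = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=VCLASS,Number=1,Type=String,Description=\"Variant class\">",
           "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Minor allele frequency\">",
           "##INFO=<ID=GTC,Number=3,Type=Integer,Description=\"Cohort genotype counts: hom-ref,het,hom-alt\">",
           "##INFO=<ID=DATASET,Number=1,Type=String,Description=\"Source dataset\">")
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (!is.null(samples)) cols <- c(cols, "FORMAT", samples)
  body <- vapply(seq_len(nrow(variants)), function(i) {
    info <- sprintf("VCLASS=%s;MAF=%s;GTC=%d,%d,%d;DATASET=%s",
                    variants$vclass[i], fmt_num(variants$maf[i]),
                    variants$n_hom_ref[i], variants$n_het[i],
                    variants$n_hom_alt[i], variants$dataset[i])
    fields <- c(variants$chrom[i], variants$pos[i], variants$variant_id[i],
                variants$ref[i], variants$alt[i], ".", "PASS", info)
    if (!is.null(samples)) {
      gt <- ifelse(samples %in% variants$carriers[[i]], "0/1", "0/0")
      fields <- c(fields, "GT", gt)
    }
    paste(fields, collapse = "\t")
  }, character(1))
  writeLines(c(hdr, paste(cols, collapse = "\t"), body), path)
  invisible(path)
}

#' Write a variant table as the package's TSV dialect
#'
#' @param variants Variant data frame with a `carriers` list-column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants_tsv <- function(variants, path) {
  out <- variants
  out$maf <- fmt_num(out$maf)
  out$carriers <- vapply(out$carriers, paste, character(1), collapse = ",")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an expression matrix as TSV
#'
#' @param em Genes-by-samples numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(em, path) {
  d <- data.frame(gene_id = rownames(em),
                  apply(em, 2L, fmt_num),
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an annotated feature (or truth) table as TSV
#'
#' Fractions are written at full precision so that a read-back compares
#' exactly against recomputed values.
#'
#' @param features Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  out <- features
  for (cl in names(out))
    if (is.double(out[[cl]])) out[[cl]] <- fmt_num(out[[cl]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an annotated feature (or truth) table written by [write_features()]
#'
#' @param path Path to the TSV.
#' @return Data frame.
#' @export
read_features <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Generate the complete synthetic fixture bundle on disk
#'
#' Runs all generator stages under one seed and writes every input the
#' pipeline consumes: `genes.gtf`, `transcripts.tsv`, `domains.tsv`,
#' `principal.tsv`, `variants.vcf`, `variants.tsv`, `labels.tsv`,
#' `truth_features.tsv`, `expression.tsv`. Re-running with the same
#' configuration reproduces every file byte for byte.
#'
#' @param cfg A [fixture_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory objects (`genes`, `domains`,
#'   `principal`, `variants`, `truth`, `expression`, `samples`) and `paths`.
#' @export
simulate_fixture <- function(cfg = fixture_config(), dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gm <- generate_gene_models(cfg)
  vr <- generate_variants(cfg, gm)
  em <- generate_expression(cfg, gm, vr)
  p <- function(f) file.path(dir, f)
  write_gtf(gm$genes, p("genes.gtf"))
  write_transcripts(gm$genes, p("transcripts.tsv"))
  utils::write.table(gm$domains, p("domains.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(gm$principal, p("principal.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_vcf(vr$variants, p("variants.vcf"), samples = vr$samples)
  write_variants_tsv(vr$variants, p("variants.tsv"))
  labels <- data.frame(variant_id = vr$truth$variant_id,
                       label = as.integer(vr$truth$class == "pathogenic"),
                       class = vr$truth$class, stringsAsFactors = FALSE)
  utils::write.table(labels, p("labels.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_features(vr$truth, p("truth_features.tsv"))
  write_expression(em, p("expression.tsv"))
  invisible(list(genes = gm$genes, domains = gm$domains,
                 principal = gm$principal, layout = gm$layout,
                 variants = vr$variants, truth = vr$truth,
                 samples = vr$samples, expression = em,
                 paths = vapply(c("genes.gtf", "transcripts.tsv",
                                  "domains.tsv", "principal.tsv",
                                  "variants.vcf", "variants.tsv",
                                  "labels.tsv", "truth_features.tsv",
                                  "expression.tsv"), p, character(1))))
}
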