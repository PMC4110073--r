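VARIANT_CLASSES <- c("stop_gain", "frameshift", "synonymous", "missense")

#' Read variants from a VCF or TSV file
#'
#' Variants are returned as a data frame with one row per (variant, alt
#' allele): `variant_id`, `chrom`, `pos` (1-based), `ref`, `alt`, `vclass`
#' (`stop_gain`, `frameshift`, `synonymous`, `missense`), `maf`, genotype
#' counts `n_hom_ref`/`n_het`/`n_hom_alt` (full genotyped cohort), a
#' `carriers` list-column (carrier sample ids among expression-profiled
#' samples, a subset of cohort carriers) and `dataset`. Multi-allelic VCF rows
#' are split into one record per alt allele.
#'
#' The `esp_frameshift_plus1` dialect adds one base to the genomic coordinate
#' of frameshift records, matching how indel positions are reported in
#' ESP-style tables relative to the actual insertion/deletion event; all other
#' classes are untouched.
#'
#' Records with malformed fields (MAF outside `[0, 0.5]`, genotype counts
#' inconsistent with the stated MAF, carrier lists larger than the cohort
#' carrier count, unknown variant class) are rejected, not fatal; rejections
#' are attached as attribute `"exclusions"`.
#'
#' VCF input uses INFO keys `VCLASS`, `MAF`, `GTC` (hom-ref,het,hom-alt) and
#' `DATASET`; when sample genotype columns are present, carriers are the
#' samples whose genotype contains the alt allele.
#'
#' @param path Path to a `.vcf` or TSV file.
#' @param dialect `"generic"` or `"esp_frameshift_plus1"`.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @return Data frame of variants with attribute `"exclusions"`.
#' @export
read_variants <- function(path, dialect = c("generic", "esp_frameshift_plus1"),
                          format = c("auto", "vcf", "tsv")) {
  dialect <- match.arg(dialect)
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- if (ext == "vcf") "vcf" else "tsv"
  }
  v <- if (format == "vcf") parse_vcf_variants(path) else parse_tsv_variants(path)

  keep <- rep(TRUE, nrow(v))
  reason <- rep(NA_character_, nrow(v))
  bad_class <- !v$vclass %in% VARIANT_CLASSES
  reason[bad_class & keep] <- paste0("unknown variant class '",
                                     v$vclass[bad_class & keep], "'")
  keep[bad_class] <- FALSE

  bad_maf <- is.na(v$maf) | v$maf < 0 | v$maf > 0.5
  reason[bad_maf & keep] <- "malformed MAF (must be in [0, 0.5])"
  keep[bad_maf] <- FALSE

  has_gc <- !is.na(v$n_hom_ref) & !is.na(v$n_het) & !is.na(v$n_hom_alt)
  if (any(has_gc)) {
    neg <- has_gc & (v$n_hom_ref < 0 | v$n_het < 0 | v$n_hom_alt < 0)
    reason[neg & keep] <- "negative genotype count"
    keep[neg] <- FALSE
    n_ind <- v$n_hom_ref + v$n_het + v$n_hom_alt
    af <- (v$n_het + 2 * v$n_hom_alt) / (2 * n_ind)
    minor <- pmin(af, 1 - af)
    tol <- pmax(1e-6, 1 / (4 * n_ind))
    bad_gc <- has_gc & !neg & !is.na(v$maf) & abs(minor - v$maf) > tol
    reason[bad_gc & keep] <- "MAF inconsistent with genotype counts"
    keep[bad_gc] <- FALSE
    n_car <- lengths(v$carriers)
    over <- has_gc & n_car > (v$n_het + v$n_hom_alt)
    reason[over & keep] <- "more listed carriers than cohort carriers"
    keep[over] <- FALSE
  }

  excl <- data.frame(variant_id = v$variant_id[!keep],
                     reason = reason[!keep], stringsAsFactors = FALSE)
  v <- v[keep, , drop = FALSE]
  if (dialect == "esp_frameshift_plus1") {
    fs <- v$vclass == "frameshift"
    v$pos[fs] <- v$pos[fs] + 1L
  }
  rownames(v) <- NULL
  attr(v, "exclusions") <- excl
  v
}

parse_tsv_variants <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("variant_id", "chrom", "pos", "ref", "alt", "vclass", "maf")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("variant TSV ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  n <- nrow(d)
  opt_int <- function(col) if (col %in% names(d))
    suppressWarnings(as.integer(d[[col]])) else rep(NA_integer_, n)
  carriers <- if ("carriers" %in% names(d)) {
    lapply(d$carriers, function(s)
      if (is.na(s) || !nzchar(s)) character() else
        strsplit(s, ",", fixed = TRUE)[[1L]])
  } else rep(list(character()), n)
  out <- data.frame(
    variant_id = as.character(d$variant_id),
    chrom = as.character(d$chrom),
    pos = suppressWarnings(as.integer(d$pos)),
    ref = as.character(d$ref), alt = as.character(d$alt),
    vclass = as.character(d$vclass),
    maf = suppressWarnings(as.numeric(d$maf)),
    n_hom_ref = opt_int("n_hom_ref"), n_het = opt_int("n_het"),
    n_hom_alt = opt_int("n_hom_alt"),
    dataset = if ("dataset" %in% names(d)) as.character(d$dataset)
              else NA_character_,
    stringsAsFactors = FALSE)
  out$carriers <- carriers
  split_multiallelic(out)
}

parse_vcf_variants <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  n <- nrow(fix)
  info_get <- function(key) {
    m <- regmatches(fix[, "INFO"],
                    regexpr(paste0("(^|;)", key, "=[^;]*"), fix[, "INFO"]))
    val <- rep(NA_character_, n)
    hit <- grepl(paste0(key, "="), fix[, "INFO"], fixed = TRUE)
    val[hit] <- sub(paste0(".*", key, "="), "", m)
    val
  }
  gtc <- info_get("GTC")
  gtc_mat <- t(vapply(gtc, function(s) {
    if (is.na(s)) return(rep(NA_integer_, 3L))
    as.integer(strsplit(s, ",", fixed = TRUE)[[1L]])[1:3]
  }, integer(3)))
  carriers <- rep(list(character()), n)
  het <- hom <- rep(NA_integer_, n)
  if (!is.null(vcf@gt) && ncol(vcf@gt) > 1L) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    samples <- colnames(gt)
    alleles <- lapply(seq_len(n), function(i)
      lapply(strsplit(gt[i, ], "[/|]"), function(a) suppressWarnings(as.integer(a))))
    for (i in seq_len(n)) {
      dose <- vapply(alleles[[i]], function(a) sum(a > 0, na.rm = TRUE),
                     integer(1))
      carriers[[i]] <- samples[dose > 0]
      het[i] <- sum(dose == 1L); hom[i] <- sum(dose >= 2L)
    }
    if (all(is.na(gtc_mat))) {
      nref <- length(samples) - het - hom
      gtc_mat <- cbind(nref, het, hom)
    }
  }
  out <- data.frame(
    variant_id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                        paste0(fix[, "CHROM"], ":", fix[, "POS"]), fix[, "ID"]),
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    vclass = info_get("VCLASS"),
    maf = suppressWarnings(as.numeric(info_get("MAF"))),
    n_hom_ref = gtc_mat[, 1L], n_het = gtc_mat[, 2L],
    n_hom_alt = gtc_mat[, 3L],
    dataset = info_get("DATASET"),
    stringsAsFactors = FALSE)
  out$carriers <- carriers
  split_multiallelic(out)
}

# one record per alt allele; vclass/maf recycled across alleles of a site
split_multiallelic <- function(v) {
  nalt <- lengths(strsplit(v$alt, ",", fixed = TRUE))
  if (all(nalt == 1L)) return(v)
  idx <- rep(seq_len(nrow(v)), nalt)
  out <- v[idx, , drop = FALSE]
  alt_split <- strsplit(v$alt, ",", fixed = TRUE)
  vc_split <- strsplit(v$vclass, ",", fixed = TRUE)
  k <- unlist(lapply(nalt, seq_len))
  out$alt <- unlist(alt_split)
  out$vclass <- unlist(mapply(function(vc, m)
    rep_len(vc, m), vc_split, nalt, SIMPLIFY = FALSE))
  multi <- nalt[idx] > 1L
  out$variant_id[multi] <- paste0(out$variant_id[multi], "_", k[multi])
  rownames(out) <- NULL
  out
}

#' Is a variant a singleton?
#'
#' A singleton is a variant observed in exactly one individual. Cohort
#' genotype counts are authoritative when present (one heterozygote, no
#' homozygotes for the minor allele); otherwise the carrier list is used.
#'
#' @param v Variant data frame from [read_variants()].
#' @return Logical vector.
#' @export
is_singleton <- function(v) {
  has_gc <- !is.na(v$n_het) & !is.na(v$n_hom_alt)
  n_car <- ifelse(has_gc, v$n_het + v$n_hom_alt, lengths(v$carriers))
  n_car == 1L
}
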