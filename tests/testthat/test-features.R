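# toy_gene(): T1 = exons 101-160, 301-420, 501-560 (80 codons, 79 aa,
# junction at CDS 180); T2 skips the middle exon (40 codons, 39 aa,
# junction at CDS 60). Plus strand.

test_that("truncation point and fraction affected follow the codon arithmetic", {
  g <- toy_gene()
  t1 <- g$transcripts$T1
  expect_equal(truncation_point(101, t1), 1L)
  expect_equal(truncation_point(103, t1), 1L)   # third base, same codon
  # cds 121 -> codon 41
  expect_equal(truncation_point(cds_to_genomic(t1, 121), t1), 41L)
  expect_true(is.na(truncation_point(301, g$transcripts$T2)))

  # 100-aa protein analogue: codon 41 of T1's 79 aa
  expect_equal(fraction_affected(41, t1), (79 - 41 + 1) / 79)
  expect_equal(fraction_affected(1, t1), 1)
  expect_equal(fraction_affected(79, t1), 1 / 79)
  # variant in the natural stop codon clamps with a warning
  expect_warning(fr <- fraction_affected(80, t1), "stop codon")
  expect_equal(fr, 1 / 79)
})

test_that("domain truncation fractions and complete-loss flags are exact", {
  g <- toy_gene()
  t1 <- g$transcripts$T1
  dom <- data.frame(transcript_id = "T1", domain_id = "D1",
                    start_aa = 50L, end_aa = 79L)
  d60 <- domain_truncation(60L, t1, dom)
  expect_equal(d60$max_fraction, 20 / 30)
  expect_false(d60$any_complete_loss)
  expect_equal(domain_truncation(80L, t1, dom)$max_fraction, 0)
  d10 <- domain_truncation(10L, t1, dom)
  expect_equal(d10$max_fraction, 1)
  expect_true(d10$any_complete_loss)
  # complete loss iff fraction 1
  for (codon in c(1L, 25L, 50L, 51L, 70L, 79L)) {
    d <- domain_truncation(codon, t1, dom)
    expect_identical(d$max_fraction == 1, d$any_complete_loss)
  }
  # no annotation -> NA fraction, flagged for imputation downstream
  expect_true(is.na(domain_truncation(10L, g$transcripts$T2, dom)$max_fraction))
})

test_that("isoform summary distinguishes constitutive from alternative positions", {
  g <- toy_gene()
  alt <- isoform_summary(301, g)     # middle exon, T1 only
  expect_equal(alt$ratio, 0.5)
  expect_false(alt$constitutive_position)
  con <- isoform_summary(101, g)     # first exon, shared
  expect_equal(con$ratio, 1)
  expect_true(con$constitutive_position)
  expect_error(isoform_summary(99999, g), "non-coding in all isoforms")
  single <- gene_model("G9", list(
    transcript_model("T9", "G9", "1", "+", 101, 160)))
  expect_equal(isoform_summary(120, single)$ratio, 1)
})

test_that("principal truncation uses annotation or the longest-CDS fallback", {
  g <- toy_gene("T2")
  expect_false(principal_truncated(301, g)$principal_truncated)  # T2 skips it
  expect_true(principal_truncated(101, g)$principal_truncated)
  gna <- toy_gene(NA_character_)
  pr <- principal_truncated(301, gna)   # falls back to T1 (longest)
  expect_true(pr$principal_truncated)
  expect_true(pr$missing_principal)
  expect_equal(pr$principal_id, "T1")
})

test_that("the NMD 50-nt rule is strict at the boundary", {
  g <- toy_gene()
  t1 <- g$transcripts$T1               # junction at CDS 180
  expect_true(nmd_target(cds_to_genomic(t1, 129), t1))   # distance 51
  expect_false(nmd_target(cds_to_genomic(t1, 130), t1))  # distance 50
  single <- transcript_model("T9", "G9", "1", "+", 101, 160)
  expect_false(nmd_target(120, single))                  # no junction
  expect_true(is.na(nmd_target(301, g$transcripts$T2)))  # not coding in T2
  # junction override shifts the boundary
  ov <- transcript_model("T8", "G9", "1", "+", 101, 160, junction_cds = 75L)
  expect_true(nmd_target(101 + 23, ov))   # cds 24, distance 51
  expect_false(nmd_target(101 + 24, ov))  # cds 25, distance 50
})

test_that("NMD scope over isoforms classifies all/some/none", {
  g <- toy_gene()
  expect_equal(nmd_isoform_scope(101, g), "all")
  expect_equal(nmd_isoform_scope(115, g), "some")  # T2 distance 45
  expect_equal(nmd_isoform_scope(501, g), "none")  # final exon in both
})

test_that("feature vectors on a degenerate gene and monotonic shifts", {
  single <- gene_model("G9", list(
    transcript_model("T9", "G9", "1", "+", 101, 400)))  # 100 codons, 99 aa
  fv <- compute_feature_vector(101, single)
  expect_equal(fv$fraction_affected_max, 1)
  expect_true(is.na(fv$domain_truncation_max))
  expect_true(fv$missing_domain)
  expect_equal(fv$n_isoforms, 1L)
  expect_equal(fv$ratio_isoforms_affected, 1)
  expect_true(fv$principal_truncated)
  expect_false(fv$nmd_target)
  expect_equal(fv$nmd_all_isoforms, "none")
  # last codon: minimal fraction, everything else unchanged
  fv2 <- compute_feature_vector(101 + 3 * 98, single)
  expect_equal(fv2$fraction_affected_max, 1 / 99)
  expect_equal(fv2[-1], fv[-1])
})

test_that("moving a variant 3' never increases truncation features nor flips NMD on", {
  set.seed(31)
  for (rep in 1:20) {
    t <- random_transcript(n_seg = sample(2:5, 1))
    plen <- t$protein_length_aa
    dlen <- min(20L, plen - 2L)
    dom <- data.frame(transcript_id = "T1", domain_id = "D1",
                      start_aa = sample.int(plen - dlen, 1),
                      end_aa = 0L)
    dom$end_aa <- dom$start_aa + dlen
    cds_seq <- seq(1L, 3L * plen, by = 7L)
    prev_f <- Inf; prev_d <- Inf; prev_nmd <- TRUE
    for (cds in cds_seq) {
      pos <- cds_to_genomic(t, cds)
      codon <- truncation_point(pos, t)
      f <- fraction_affected(codon, t)
      d <- domain_truncation(codon, t, dom)$max_fraction
      nmd <- nmd_target(pos, t)
      expect_lte(f, prev_f)
      expect_lte(d, prev_d)
      expect_false(!prev_nmd && nmd)
      prev_f <- f; prev_d <- d; prev_nmd <- nmd
    }
  }
})

test_that("features agree with per-residue brute-force marking on fixture variants", {
  fx_gm <- generate_gene_models(fixture_config(seed = 23))
  fx <- generate_variants(fixture_config(seed = 23), fx_gm)
  tx <- unlist(lapply(fx_gm$genes, function(g) g$transcripts),
               recursive = FALSE)
  names(tx) <- vapply(tx, function(t) t$transcript_id, character(1))
  checked <- 0L
  for (i in seq_len(nrow(fx$variants))) {
    gid <- fx$truth$gene_id[i]
    g <- fx_gm$genes[[gid]]
    for (t in g$transcripts) {
      codon <- truncation_point(fx$variants$pos[i], t)
      if (is.na(codon)) next
      expect_equal(fraction_affected(codon, t),
                   oracle_fraction_affected(codon, t$protein_length_aa))
      dom <- fx_gm$domains[fx_gm$domains$transcript_id == t$transcript_id, ]
      if (nrow(dom)) {
        expected <- max(vapply(seq_len(nrow(dom)), function(r)
          oracle_domain_fraction(codon, dom$start_aa[r], dom$end_aa[r],
                                 t$protein_length_aa), numeric(1)))
        expect_equal(domain_truncation(codon, t, dom)$max_fraction, expected)
      }
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 200L)
})

test_that("annotation flags variants that are coding in no isoform of their gene", {
  g <- toy_gene()
  v <- data.frame(variant_id = c("V1", "V2"), chrom = "1",
                  pos = c(301L, 200L),  # 200 is intronic for both isoforms
                  ref = "A", alt = "T", vclass = "stop_gain", maf = 0.01,
                  n_hom_ref = NA_integer_, n_het = NA_integer_,
                  n_hom_alt = NA_integer_, dataset = "d",
                  stringsAsFactors = FALSE)
  v$carriers <- list(character(), character())
  ann <- annotate_variants(v, list(G1 = g))
  expect_identical(ann$non_coding_all_isoforms, c(FALSE, TRUE))
  expect_true(is.na(ann$fraction_affected_max[2]))
})
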