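test_that("fixture generation is deterministic: identical bytes per seed", {
  d1 <- tempfile("fxa"); d2 <- tempfile("fxb")
  cfg <- fixture_config(seed = 127, n_genes = 8, n_variants_per_class = 20,
                        n_samples = 10)
  simulate_fixture(cfg, d1)
  simulate_fixture(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # a different seed changes the content
  simulate_fixture(fixture_config(seed = 128, n_genes = 8,
                                  n_variants_per_class = 20,
                                  n_samples = 10), d2)
  expect_false(identical(readLines(file.path(d1, "variants.tsv")),
                         readLines(file.path(d2, "variants.tsv"))))
})

test_that("the checked-in golden bundle is exactly regenerable", {
  golden <- system.file("extdata", "golden", package = "truncscore")
  skip_if(golden == "", "golden fixture not installed")
  d <- tempfile("gold")
  simulate_fixture(fixture_config(), d)
  files <- list.files(golden)
  expect_setequal(files, list.files(d))
  for (f in files)
    expect_identical(readLines(file.path(d, f)),
                     readLines(file.path(golden, f)), label = f)
})

test_that("generated artifacts pass every reader's validation with zero exclusions", {
  fx <- simulate_fixture(fixture_config(seed = 131), tempfile("fx"))
  genes <- read_transcripts(fx$paths[["genes.gtf"]])
  expect_equal(nrow(attr(genes, "exclusions")), 0L)
  expect_length(genes, 20L)
  v <- read_variants(fx$paths[["variants.vcf"]])
  expect_equal(nrow(attr(v, "exclusions")), 0L)
  expect_silent(read_domains(fx$paths[["domains.tsv"]], genes))
  expect_silent(read_principal(fx$paths[["principal.tsv"]], genes))
  expect_silent(read_expression(fx$paths[["expression.tsv"]]))
  # edge coverage: at least one single-isoform and one single-exon gene
  n_iso <- vapply(genes, function(g) length(g$transcripts), integer(1))
  expect_true(any(n_iso == 1L))
  n_seg <- unlist(lapply(genes, function(g)
    vapply(g$transcripts, function(t) nrow(t$cds), integer(1))))
  expect_true(any(n_seg == 1L))
  # HWE-consistent genotype counts survive the filter
  kept <- filter_hwe(v)
  expect_equal(nrow(attr(kept, "removed")), 0L)
})

test_that("annotation reproduces the generator's truth table exactly", {
  fx <- simulate_fixture(fixture_config(seed = 137), tempfile("fx"))
  # a variant placed on one isoform may fall in another isoform's natural
  # stop codon; the engine clamps it to the last residue with a warning
  ann <- suppressWarnings(
    annotate_files(fx$paths[["genes.gtf"]], fx$paths[["variants.tsv"]],
                   domains_path = fx$paths[["domains.tsv"]],
                   principal_path = fx$paths[["principal.tsv"]]))
  expect_equal(nrow(ann), nrow(fx$truth))
  m <- match(fx$truth$variant_id, ann$variant_id)
  expect_identical(ann$gene_id[m], fx$truth$gene_id)
  for (cl in c("fraction_affected_max", "domain_truncation_max",
               "ratio_isoforms_affected")) {
    expect_equal(ann[[cl]][m], fx$truth[[cl]], tolerance = 1e-12, label = cl)
  }
  for (cl in c("n_isoforms", "principal_truncated", "nmd_target",
               "missing_domain", "missing_principal",
               "constitutive_position", "nmd_all_isoforms")) {
    expect_identical(unname(unlist(ann[[cl]][m])), fx$truth[[cl]], label = cl)
  }
  # class separation in the intended directions
  path <- fx$truth$class == "pathogenic"
  expect_gt(mean(fx$truth$fraction_affected_max[path]),
            mean(fx$truth$fraction_affected_max[!path]))
  expect_gt(mean(fx$truth$nmd_target[path]), mean(fx$truth$nmd_target[!path]))
})

test_that("degenerate configurations propagate to the truth table", {
  # single-exon single-isoform genes: every position constitutive, no
  # exon-exon junction anywhere, so nothing can be an NMD target
  cfg <- fixture_config(seed = 139, n_genes = 6, n_variants_per_class = 15,
                        n_samples = 8,
                        isoform_range = c(1L, 1L), exons_range = c(1L, 1L),
                        benign_beta = c(60, 1),   # essentially last codons
                        alt_exon_pref = 0)
  gm <- generate_gene_models(cfg)
  vr <- generate_variants(cfg, gm)
  expect_true(all(!vr$truth$nmd_target))
  expect_true(all(vr$truth$nmd_all_isoforms == "none"))
  expect_true(all(vr$truth$constitutive_position))
  expect_true(all(vr$truth$ratio_isoforms_affected == 1))
  ben <- vr$truth[vr$truth$class == "benign", ]
  expect_true(all(ben$fraction_affected_max <= 0.3))
})

test_that("direct feature sampling matches the requested class models", {
  ident <- default_class_model()
  ident$mu0 <- ident$mu1
  ident$theta0 <- ident$theta1
  fm <- generate_feature_matrix(300, 300, ident, seed = 149)
  m <- nb_fit(fm$X, fm$labels)
  post <- nb_posterior(m, fm$X)
  expect_lt(abs(auc(post, fm$labels) - 0.5), 0.08)
  expect_lt(max(abs(post - 0.5)), 0.45)  # posteriors hover near the prior
  # infeasible configurations error out
  expect_error(fixture_config(exon_codon_range = c(0L, 5L)), "infeasible")
  expect_error(fixture_config(nmd_effect_size = 0), "nmd_effect_size")
})

test_that("planted expression effect matches its closed form when noise vanishes", {
  cfg <- fixture_config(seed = 151, n_genes = 6, n_variants_per_class = 10,
                        n_samples = 20, expr_noise_sd = 1e-6,
                        nmd_effect_size = 0.5)
  gm <- generate_gene_models(cfg)
  vr <- generate_variants(cfg, gm)
  em <- generate_expression(cfg, gm, vr)
  # with vanishing noise, a sample's value on gene g is the baseline times
  # (1 - e)^dose, dose = number of g's NMD variants the sample carries;
  # the carrier z-scores follow from standardizing that vector analytically
  nmd_ids <- vr$truth$variant_id[vr$truth$nmd_target]
  expect_gt(length(nmd_ids), 0L)
  z <- zscore_by_gene(em)
  for (gid in unique(vr$truth$gene_id[vr$truth$nmd_target])) {
    vids <- intersect(nmd_ids,
                      vr$truth$variant_id[vr$truth$gene_id == gid])
    samples <- colnames(em)
    dose <- rep(0L, length(samples))
    names(dose) <- samples
    for (vid in vids) {
      cs <- vr$variants$carriers[[match(vid, vr$variants$variant_id)]]
      dose[cs] <- dose[cs] + 1L
    }
    val <- (1 - cfg$nmd_effect_size)^dose
    zexp <- (val - mean(val)) / sqrt(mean((val - mean(val))^2))
    for (vid in vids) {
      cs <- vr$variants$carriers[[match(vid, vr$variants$variant_id)]]
      expect_equal(variant_expression_z(z, gid, cs), mean(zexp[cs]),
                   tolerance = 1e-3)
    }
  }
})
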