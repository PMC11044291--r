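# helpers to build small hand-specified inputs ------------------------------

mk_ld <- function(ids, R) {
  dimnames(R) <- list(ids, ids)
  structure(list(variants = tibble::tibble(variant_id = ids),
                 correlation = R),
            class = "ld_reference")
}

mk_weights <- function(ids, w, feature_id = "f1") {
  out <- tibble::tibble(
    feature_id = feature_id, gene_symbol = "G1", qtl_type = "eQTL",
    tissue_label = "brain_cortex", dataset_tag = "sim_eQTL",
    model_tag = "top1", cv_r2 = NA_real_,
    weights = list(tibble::tibble(variant_id = ids, weight = w)))
  class(out) <- c("weight_models", class(out))
  out
}

mk_qtl <- function(df) {
  defaults <- tibble::tibble(
    feature_id = character(), gene_symbol = character(),
    qtl_type = character(), tissue_label = character(),
    dataset_tag = character(), variant_id = character(),
    chromosome = character(), position = integer(),
    effect_allele = character(), other_allele = character(),
    beta_zx = numeric(), se_zx = numeric(), p_zx = numeric(), n = numeric())
  out <- dplyr::bind_rows(defaults, df)
  out$gene_symbol[is.na(out$gene_symbol)] <- "G1"
  out$qtl_type[is.na(out$qtl_type)] <- "eQTL"
  out$tissue_label[is.na(out$tissue_label)] <- "brain_cortex"
  out$dataset_tag[is.na(out$dataset_tag)] <- "sim_eQTL"
  class(out) <- c("qtl_sumstats", class(out))
  out
}

test_that("weight training: forced top1, near-perfect ridge, null cv_r2", {
  g <- simulate_genotypes(1500, 20, block_size = 10, within_block_r = 0.7,
                          seed = 51)
  # single causal, tiny noise: ridge with CV must predict almost perfectly
  ml <- simulate_molecular_layers(
    g, layers = list(eQTL = list(n_features = 3, n_causal = 1,
                                 effect_values = 1, noise_sd = 0.05)),
    cis_window_bp = 1e5, seed = 51)
  wr <- train_weights(g, ml, model = "ridge", cv_folds = 5,
                      ridge_lambda = 0.01, seed = 51)
  expect_true(all(wr$cv_r2 > 0.95))

  # pure-noise features: cv_r2 distribution centred near zero
  ml0 <- simulate_molecular_layers(
    g, layers = list(eQTL = list(n_features = 40, n_causal = 1,
                                 effect_sd = 0, noise_sd = 1)),
    cis_window_bp = 1e5, seed = 52)
  w0 <- train_weights(g, ml0, model = "ridge", cv_folds = 5, seed = 52)
  expect_lt(mean(w0$cv_r2), 0.02)

  # a feature with one cis variant forces top1 weight 1 on it
  ml1 <- simulate_molecular_layers(
    g, layers = list(eQTL = list(n_features = 1, n_causal = 1,
                                 effect_values = 1, noise_sd = 0.5)),
    cis_window_bp = 1, seed = 53)  # window so narrow only the anchor is cis
  expect_equal(lengths(ml1$features$cis_idx), 1L, ignore_attr = TRUE)
  w1 <- train_weights(g, ml1, model = "top1", cv_folds = 0, seed = 53)
  expect_equal(w1$weights[[1]]$weight, 1)
  expect_equal(w1$weights[[1]]$variant_id,
               g$variants$variant_id[ml1$features$cis_idx[[1]]])
})

test_that("weighted association reproduces hand-computed quadratic forms", {
  gwas <- mk_gwas(tibble::tibble(
    variant_id = c("v1", "v2"), chromosome = "1", position = c(1L, 2L),
    effect_allele = "A", other_allele = "G", z = c(1, 1), n = 100))
  # single variant, weight 1, R = (1): z_stat equals the GWAS z
  r1 <- twas_association(mk_weights("v1", 1), gwas, mk_ld("v1", diag(1)))
  expect_equal(r1$z_stat, 1)
  expect_equal(r1$tool, "FUSION")
  expect_equal(r1$p_value, 2 * pnorm(-1))

  # two independent variants, weights (1,1), z = (1,1): 2 / sqrt(2)
  ld2 <- mk_ld(c("v1", "v2"), diag(2))
  r2 <- twas_association(mk_weights(c("v1", "v2"), c(1, 1)), gwas, ld2)
  expect_equal(r2$z_stat, 2 / sqrt(2), tolerance = 1e-12)

  # antisymmetry in w and invariance to positive rescaling
  rneg <- twas_association(mk_weights(c("v1", "v2"), c(-1, -1)), gwas, ld2)
  expect_equal(rneg$z_stat, -r2$z_stat)
  expect_equal(rneg$p_value, r2$p_value)
  rsc <- twas_association(mk_weights(c("v1", "v2"), c(7, 7)), gwas, ld2)
  expect_equal(rsc$z_stat, r2$z_stat, tolerance = 1e-12)

  # weighted variant absent from the GWAS is an error naming it
  expect_error(
    twas_association(mk_weights("v9", 1), gwas, mk_ld("v9", diag(1))),
    "v9", class = "multixwas_data_error")
})

test_that("SMR reproduces the Wald-ratio chi-square algebra", {
  mk_pair <- function(z_zy, z_zx) {
    # unit-se coding: beta = z for both studies
    gwas <- mk_gwas(tibble::tibble(
      variant_id = "v1", chromosome = "1", position = 1L,
      effect_allele = "A", other_allele = "G",
      z = z_zy, beta = z_zy, se = 1, n = 1000))
    qtl <- mk_qtl(tibble::tibble(
      feature_id = "f1", variant_id = "v1", chromosome = "1", position = 1L,
      effect_allele = "A", other_allele = "G",
      beta_zx = z_zx, se_zx = 1, p_zx = 2 * pnorm(-abs(z_zx)), n = 500))
    smr_test(qtl, gwas, instrument_p_threshold = 1e-4)
  }
  # z_zy = z_zx = z implies z_smr^2 = z^2 / 2
  r <- mk_pair(6, 6)
  expect_equal(r$z_stat^2, 36 / 2, tolerance = 1e-12)
  # z_zy = 4, z_zx = 8 implies z_smr^2 = 16 * 64 / 80 = 12.8
  r2 <- mk_pair(4, 8)
  expect_equal(r2$z_stat^2, 12.8, tolerance = 1e-12)
  expect_equal(r2$p_value, pchisq(12.8, 1, lower.tail = FALSE))
  expect_equal(r2$b_xy_hat, 4 / 8)
  expect_equal(r2$tool, "SMR")

  # feature without a genome-wide-significant instrument is skipped
  gwas <- mk_gwas(tibble::tibble(
    variant_id = "v1", chromosome = "1", position = 1L,
    effect_allele = "A", other_allele = "G", z = 2, beta = 2, se = 1,
    n = 1000))
  qtl_weak <- mk_qtl(tibble::tibble(
    feature_id = "f1", variant_id = "v1", chromosome = "1", position = 1L,
    effect_allele = "A", other_allele = "G",
    beta_zx = 1, se_zx = 1, p_zx = 0.3, n = 500))
  r3 <- smr_test(qtl_weak, gwas, instrument_p_threshold = 5e-8)
  expect_equal(nrow(r3), 0)
  expect_equal(attr(r3, "skipped")$reason, "no instrument")
})

test_that("SMR p depends on the studies only through their z-scores", {
  # metamorphic: rescaling beta and se together preserves z, hence p
  base_gwas <- function(se_scale) mk_gwas(tibble::tibble(
    variant_id = "v1", chromosome = "1", position = 1L,
    effect_allele = "A", other_allele = "G",
    z = 3, beta = 3 * se_scale, se = se_scale, n = 1000))
  qtl <- function(se_scale) mk_qtl(tibble::tibble(
    feature_id = "f1", variant_id = "v1", chromosome = "1", position = 1L,
    effect_allele = "A", other_allele = "G",
    beta_zx = 7 * se_scale, se_zx = se_scale,
    p_zx = 2 * pnorm(-7), n = 500))
  p_at <- function(s) smr_test(qtl(s), base_gwas(s),
                               instrument_p_threshold = 1e-4)$p_value
  expect_equal(p_at(1), p_at(0.13), tolerance = 1e-12)
  expect_equal(p_at(1), p_at(5), tolerance = 1e-12)
})

test_that("HEIDI retains shared-causal features and needs enough SNPs", {
  # independent single-causal replicates: one feature per cohort, so the
  # only trait signal in the block flows through the shared causal variant
  n <- 2000
  reps <- 30
  p_heidi <- rep(NA_real_, reps)
  for (r in seq_len(reps)) {
    g <- simulate_genotypes(n, 20, block_size = 20, within_block_r = 0.9,
                            seed = 600 + r, maf_range = c(0.15, 0.5))
    ml <- simulate_molecular_layers(
      g, layers = list(eQTL = list(n_features = 1, n_causal = 1,
                                   effect_values = 0.7, noise_sd = 1)),
      cis_window_bp = 5e5, seed = 600 + r)
    tr <- simulate_trait(g, ml, mediated_frac = 1, bxy_values = 0.3,
                         n_direct = 0, noise_sd = 1, seed = 600 + r)
    gwas <- scan_gwas(g, tr$trait)
    qtl <- scan_cis_qtl(g, ml)
    hd <- heidi_test(qtl, gwas, ld_reference(g), n_draws = 2000,
                     seed = 600 + r)
    p_heidi[r] <- hd$p_heidi
  }
  ok <- p_heidi[!is.na(p_heidi)]
  expect_gt(length(ok), 15)
  expect_gte(mean(ok > 0.05), 0.8)

  # fewer than min_snps eligible SNPs: missing p, flagged
  g <- simulate_genotypes(500, 20, block_size = 20, within_block_r = 0.9,
                          seed = 699)
  ml <- simulate_molecular_layers(
    g, layers = list(eQTL = list(n_features = 1, n_causal = 1,
                                 effect_values = 0.7, noise_sd = 1)),
    cis_window_bp = 5e5, seed = 699)
  qtl <- scan_cis_qtl(g, ml)
  gwas <- scan_gwas(g, rnorm(500))
  qtl1 <- qtl %>% dplyr::slice_min(p_zx, n = 2)
  h1 <- heidi_test(qtl1, gwas, ld_reference(g), seed = 699)
  expect_true(is.na(h1$p_heidi))
  expect_match(h1$heidi_note, "not evaluable")
})

test_that("HEIDI rejects a linkage scenario with two distinct causal variants", {
  n <- 4000
  g <- simulate_genotypes(n, 20, block_size = 20, within_block_r = 0.9,
                          seed = 62, maf_range = c(0.2, 0.5))
  reps <- 25
  p_heidi <- numeric(reps)
  for (r in seq_len(reps)) {
    set.seed(1000 + r)
    a <- 5L; b <- 12L  # molecular causal vs distinct trait causal, in LD
    expr <- g$dosage[, a] * 0.8 + rnorm(n)
    trait <- g$dosage[, b] * 0.25 + rnorm(n)
    ml <- simulate_molecular_layers(
      g, layers = list(eQTL = list(n_features = 1, n_causal = 1,
                                   effect_values = 0, noise_sd = 1)),
      cis_window_bp = 5e5, seed = 1000 + r)
    ml$features$phenotype[[1]] <- expr
    ml$features$cis_idx[[1]] <- 1:20
    gwas <- scan_gwas(g, trait)
    qtl <- scan_cis_qtl(g, ml)
    hd <- heidi_test(qtl, gwas, ld_reference(g), n_draws = 2000,
                     seed = 1000 + r)
    p_heidi[r] <- hd$p_heidi
  }
  expect_lt(median(p_heidi, na.rm = TRUE), 0.05)
})

test_that("Bonferroni families and HEIDI retention gate significance", {
  res <- dplyr::bind_rows(lapply(1:20, function(i) {
    tibble::tibble(
      gene_symbol = paste0("G", i), feature_id = paste0("f", i),
      qtl_type = "eQTL", tissue_label = "brain", tissue_group = "brain",
      dataset_tag = "d1", tool = "FUSION", gwas_dataset = "SCZ_sim",
      z_stat = 1, b_xy_hat = NA_real_,
      p_value = c(0.002, 0.003, rep(0.5, 18))[i],
      p_heidi = NA_real_, n_snps_heidi = NA_integer_,
      passes_correction = NA)
  }))
  out <- bonferroni_filter(res, alpha = 0.05)
  expect_true(out$passes_correction[out$p_value == 0.002])   # < 0.0025
  expect_false(out$passes_correction[out$p_value == 0.003])  # > 0.0025

  # an SMR hit with tiny p but failed HEIDI is not retained
  smr_row <- res[1, ] %>%
    dplyr::mutate(tool = "SMR", p_value = 1e-10, p_heidi = 0.01)
  out2 <- bonferroni_filter(dplyr::bind_rows(res[-1, ], smr_row),
                            alpha = 0.05)
  expect_false(out2$passes_correction[out2$tool == "SMR"])
  smr_ok <- smr_row %>% dplyr::mutate(p_heidi = 0.5)
  out3 <- bonferroni_filter(dplyr::bind_rows(res[-1, ], smr_ok),
                            alpha = 0.05)
  expect_true(out3$passes_correction[out3$tool == "SMR"])

  expect_error(bonferroni_filter(res, alpha = 2),
               class = "multixwas_config_error")
})

test_that("features with every instrument inside the MHC vanish after exclusion", {
  gwas <- mk_gwas(tibble::tibble(
    variant_id = c("m1", "m2", "o1"), chromosome = "6",
    position = c(29000000L, 30000000L, 40000000L),
    effect_allele = "A", other_allele = "G",
    z = c(6, 6, 6), beta = c(6, 6, 6), se = 1, n = 1000))
  qtl <- mk_qtl(tibble::tibble(
    feature_id = c("fmhc", "fmhc", "fout"),
    variant_id = c("m1", "m2", "o1"), chromosome = "6",
    position = c(29000000L, 30000000L, 40000000L),
    effect_allele = "A", other_allele = "G",
    beta_zx = 0.5, se_zx = 0.05, p_zx = 1e-20, n = 500))
  res <- smr_test(qtl, exclude_region(gwas), instrument_p_threshold = 5e-8)
  expect_equal(res$feature_id, "fout")
})
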