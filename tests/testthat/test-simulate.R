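test_that("genotype simulation is deterministic and respects MAF bounds", {
  g1 <- simulate_genotypes(300, 40, block_size = 8, seed = 11)
  g2 <- simulate_genotypes(300, 40, block_size = 8, seed = 11)
  g3 <- simulate_genotypes(300, 40, block_size = 8, seed = 12)
  expect_identical(g1$dosage, g2$dosage)
  expect_false(identical(g1$dosage, g3$dosage))
  expect_true(all(g1$dosage %in% 0:2))

  g <- simulate_genotypes(2000, 100, block_size = 10, within_block_r = 0.9,
                          maf_range = c(0.1, 0.4), seed = 5)
  emp_maf <- colMeans(g$dosage) / 2
  emp_maf <- pmin(emp_maf, 1 - emp_maf)
  # empirical MAF within the target range up to binomial sampling error
  expect_true(all(emp_maf > 0.1 - 4 * sqrt(0.1 * 0.9 / 4000)))
  expect_true(all(emp_maf < 0.4 + 4 * sqrt(0.4 * 0.6 / 4000)))

  expect_error(simulate_genotypes(100, 10, maf_range = c(0, 0)),
               class = "multixwas_config_error")
  expect_error(simulate_genotypes(100, 5, block_size = 10),
               class = "multixwas_config_error")
})

test_that("within_block_r = 0 and block_size = 1 give independent variants", {
  g <- simulate_genotypes(2000, 40, block_size = 8, within_block_r = 0,
                          seed = 3)
  R <- cor(g$dosage)
  off <- abs(R[upper.tri(R)])
  expect_lt(mean(off), 3 / sqrt(2000))

  g1 <- simulate_genotypes(1500, 30, block_size = 1, within_block_r = 0.9,
                           seed = 4)
  R1 <- cor(g1$dosage)
  expect_lt(mean(abs(R1[upper.tri(R1)])), 3 / sqrt(1500))
})

test_that("LD blocks carry the declared decaying correlation", {
  g <- simulate_genotypes(4000, 40, block_size = 20, within_block_r = 0.9,
                          seed = 9, maf_range = c(0.3, 0.5))
  R <- cor(g$dosage)
  # adjacent within-block pairs correlate strongly; across blocks ~ 0
  adj <- mapply(function(i) R[i, i + 1], c(1:5, 21:25))
  expect_true(all(adj > 0.5))
  expect_lt(mean(abs(R[1:20, 21:40])), 0.06)
})

test_that("molecular layers honour sharing, fixed effects and exchangeability", {
  g <- tiny_geno
  # noise-free single-causal feature reproduces its dosage column exactly
  ml <- simulate_molecular_layers(
    g, layers = list(eQTL = list(n_features = 3, n_causal = 1,
                                 effect_values = 1, noise_sd = 0)),
    cis_window_bp = 5e4, seed = 2)
  f <- ml$features
  for (i in 1:3) {
    expect_equal(f$phenotype[[i]], as.numeric(g$dosage[, f$causal_idx[[i]]]))
  }

  # share_frac = 1: every sQTL feature reuses an eQTL gene symbol
  ml2 <- simulate_molecular_layers(
    g, layers = list(eQTL = list(n_features = 5, n_causal = 1,
                                 effect_sd = 0.4, noise_sd = 1),
                     sQTL = list(n_features = 5, n_causal = 1,
                                 effect_sd = 0.4, noise_sd = 1,
                                 share_frac = 1)),
    cis_window_bp = 5e4, seed = 2)
  esym <- ml2$features$gene_symbol[ml2$features$qtl_type == "eQTL"]
  ssym <- ml2$features$gene_symbol[ml2$features$qtl_type == "sQTL"]
  expect_true(all(ssym %in% esym))
  shared <- ml2$features[ml2$features$qtl_type == "sQTL", ]
  expect_true(all(!is.na(shared$shared_from)))

  # the same generator drives every layer: only labels differ by layer_type
  spec1 <- list(pQTL = list(n_features = 4, n_causal = 1, effect_sd = 0.4,
                            noise_sd = 1))
  spec2 <- list(mQTL = list(n_features = 4, n_causal = 1, effect_sd = 0.4,
                            noise_sd = 1))
  a <- simulate_molecular_layers(g, spec1, cis_window_bp = 5e4, seed = 7)
  b <- simulate_molecular_layers(g, spec2, cis_window_bp = 5e4, seed = 7)
  expect_identical(a$features$phenotype, b$features$phenotype)
  expect_identical(a$features$causal_idx, b$features$causal_idx)

  expect_error(simulate_molecular_layers(
    g, layers = list(eQTL = list(n_features = 2, share_frac = 2,
                                 effect_sd = 1, noise_sd = 1))),
    class = "multixwas_config_error")
  expect_error(simulate_molecular_layers(
    g, layers = list(xQTL = list(n_features = 2))),
    class = "multixwas_config_error")
})

test_that("null molecular layer yields uniform cis-QTL p-values", {
  g <- simulate_genotypes(500, 80, block_size = 8, within_block_r = 0.5,
                          seed = 21)
  ml <- simulate_molecular_layers(
    g, layers = list(mQTL = list(n_features = 300, n_causal = 1,
                                 effect_sd = 0, noise_sd = 1)),
    cis_window_bp = 2e4, seed = 21)
  qtl <- scan_cis_qtl(g, ml)
  # one p per feature (the first cis SNP) to dodge within-window correlation
  p1 <- qtl %>% dplyr::group_by(feature_id) %>% dplyr::slice(1) %>%
    dplyr::pull(p_zx)
  ks <- suppressWarnings(stats::ks.test(p1, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("trait simulation recovers the mediated effect and nulls cleanly", {
  g <- simulate_genotypes(3000, 20, block_size = 20, within_block_r = 0.8,
                          seed = 31)
  ml <- simulate_molecular_layers(
    g, layers = list(eQTL = list(n_features = 1, n_causal = 1,
                                 effect_values = 0.6, noise_sd = 1)),
    cis_window_bp = 5e5, seed = 31)
  tr <- simulate_trait(g, ml, mediated_frac = 1, bxy_values = 0.3,
                       n_direct = 0, noise_sd = 1, seed = 31)
  expect_equal(tr$truth$mediated$b_xy_true, 0.3)
  fit <- stats::lm(tr$trait ~ ml$features$phenotype[[1]])
  expect_lt(abs(unname(stats::coef(fit)[2]) - 0.3), 0.05)

  # all-zero mediated effects and no direct effects: trait independent
  tr0 <- simulate_trait(g, ml, mediated_frac = 1, bxy_values = 0,
                        n_direct = 0, noise_sd = 1, seed = 32)
  sc <- scan_gwas(g, tr0$trait)
  expect_gt(min(sc$p), 1e-4 / 20)  # no strong association expected

  # determinism
  tr2 <- simulate_trait(g, ml, mediated_frac = 1, bxy_values = 0.3,
                        n_direct = 0, noise_sd = 1, seed = 31)
  expect_identical(tr$trait, tr2$trait)

  expect_error(simulate_trait(g, ml, mediated_frac = 0, n_direct = 0,
                              noise_sd = 0),
               class = "multixwas_config_error")
})

test_that("GWAS scan matches exact relations and stays calibrated", {
  g <- tiny_geno
  y <- 2 * g$dosage[, 7]
  sc <- scan_gwas(g, y)
  expect_lt(sc$p[7], 1e-200)
  expect_equal(sc$beta[7], 2, tolerance = 1e-9)
  # internal consistency: z = beta / se everywhere
  expect_equal(sc$z, sc$beta / sc$se, tolerance = 1e-6)

  set.seed(99)
  sc0 <- scan_gwas(g, sample(y))  # permuted trait: null p-values
  ks <- suppressWarnings(stats::ks.test(sc0$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("cis scan finds causal variants and respects the window", {
  g <- simulate_genotypes(800, 100, block_size = 10, within_block_r = 0.6,
                          seed = 13)
  ml <- simulate_molecular_layers(
    g, layers = list(eQTL = list(n_features = 50, n_causal = 1,
                                 effect_values = 1, noise_sd = 0.3)),
    cis_window_bp = 4e4, seed = 13)
  qtl <- scan_cis_qtl(g, ml)
  top <- qtl %>% dplyr::group_by(feature_id) %>%
    dplyr::slice_min(p_zx, n = 1, with_ties = FALSE) %>% dplyr::ungroup()
  causal_id <- g$variants$variant_id[unlist(ml$features$causal_idx)]
  hit <- mean(top$variant_id == causal_id[match(top$feature_id,
                                                ml$features$feature_id)])
  expect_gte(hit, 0.9)  # near-noiseless: top SNP is the causal one

  # no record outside the declared cis window
  pos <- g$variants$position[match(qtl$variant_id, g$variants$variant_id)]
  anchor <- ml$features$anchor_pos[match(qtl$feature_id,
                                         ml$features$feature_id)]
  expect_true(all(abs(pos - anchor) <= 4e4))
})
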