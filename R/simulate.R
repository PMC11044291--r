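#' Simulate LD-blocked genotypes
#'
#' Draws hard-call dosages for `n_individuals` at `n_variants` biallelic
#' variants arranged in contiguous LD blocks. Within a block, haplotypes are
#' generated by thresholding a latent Gaussian with AR(1) correlation
#' `within_block_r^|i-j|`; two independent haplotypes are summed, so every
#' variant is in Hardy-Weinberg equilibrium at its drawn MAF and blocks are
#' independent in expectation.
#'
#' @param n_individuals,n_variants Cohort and panel sizes.
#' @param block_size Number of variants per LD block (last block may be
#'   shorter).
#' @param within_block_r Latent AR(1) correlation parameter in `[0, 1)`;
#'   0 gives mutually independent variants.
#' @param maf_range Interval in `(0, 0.5]` from which per-variant minor
#'   allele frequencies are drawn uniformly.
#' @param seed Integer seed.
#' @param bp_spacing Base-pair distance between adjacent variants.
#' @param chromosome Chromosome label for the whole panel.
#' @return An object of class `genotype_matrix`: a list with `dosage`
#'   (n x m matrix of 0/1/2), `variants` (tibble with ids, coordinates,
#'   alleles and target MAF) and `ld_blocks` (block index per variant).
#' @export
simulate_genotypes <- function(n_individuals, n_variants, block_size = 20L,
                               within_block_r = 0.9,
                               maf_range = c(0.05, 0.5), seed = 1L,
                               bp_spacing = 5000L, chromosome = "1") {
  stopifnot(n_individuals >= 2, n_variants >= 1, block_size >= 1,
            within_block_r >= 0, within_block_r < 1)
  if (n_variants < block_size) {
    abort("`n_variants` must be at least `block_size`",
          class = "multixwas_config_error")
  }
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    abort("`maf_range` must satisfy 0 < low <= high <= 0.5",
          class = "multixwas_config_error")
  }
  set.seed(derive_seed(seed, "genotypes"))
  maf <- runif(n_variants, maf_range[1], maf_range[2])
  blocks <- rep(seq_len(ceiling(n_variants / block_size)),
                each = block_size)[seq_len(n_variants)]
  dosage <- matrix(0L, n_individuals, n_variants)
  for (b in unique(blocks)) {
    idx <- which(blocks == b)
    k <- length(idx)
    thr <- qnorm(maf[idx])
    if (within_block_r > 0 && k > 1) {
      L <- chol(within_block_r^abs(outer(seq_len(k), seq_len(k), `-`)))
      draw_hap <- function() {
        z <- matrix(rnorm(n_individuals * k), n_individuals, k) %*% L
        sweep(z, 2, thr, `<`)
      }
    } else {
      draw_hap <- function() {
        z <- matrix(rnorm(n_individuals * k), n_individuals, k)
        sweep(z, 2, thr, `<`)
      }
    }
    dosage[, idx] <- draw_hap() + draw_hap()
  }
  storage.mode(dosage) <- "integer"
  # non-ambiguous allele pairs only, so harmonization is lossless by default
  pairs <- matrix(c("A", "G", "G", "A", "C", "T", "T", "C",
                    "A", "C", "C", "A", "G", "T", "T", "G"),
                  ncol = 2, byrow = TRUE)
  pick <- sample.int(nrow(pairs), n_variants, replace = TRUE)
  variants <- tibble(
    variant_id = sprintf("snp%05d", seq_len(n_variants)),
    chromosome = as.character(chromosome),
    position = as.integer(seq_len(n_variants)) * as.integer(bp_spacing),
    effect_allele = pairs[pick, 1],
    other_allele = pairs[pick, 2],
    maf = maf
  )
  colnames(dosage) <- variants$variant_id
  structure(list(dosage = dosage, variants = variants, ld_blocks = blocks),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d variants in %d LD blocks\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$ld_blocks))))
  invisible(x)
}

#' Empirical LD reference from simulated genotypes
#'
#' Computes the pairwise dosage correlation matrix used as the LD reference
#' for weighted association and HEIDI. Zero-variance variants get zero
#' correlation with everything (unit diagonal is kept).
#'
#' @param geno A `genotype_matrix`.
#' @return An object of class `ld_reference`: list with the variant tibble
#'   and the symmetric correlation matrix (dimnames = variant ids).
#' @export
ld_reference <- function(geno) {
  R <- suppressWarnings(cor(geno$dosage))
  R[!is.finite(R)] <- 0
  diag(R) <- 1
  R <- (R + t(R)) / 2
  dimnames(R) <- list(geno$variants$variant_id, geno$variants$variant_id)
  structure(list(variants = geno$variants, correlation = R),
            class = "ld_reference")
}

#' @export
print.ld_reference <- function(x, ...) {
  cat(sprintf("<ld_reference> %d variants\n", nrow(x$correlation)))
  invisible(x)
}

#' Simulate molecular phenotype layers
#'
#' Generates features (genes, splicing events, proteins, CpGs, m6A peaks)
#' for a subset of the five QTL layers. Every layer runs through the same
#' code path: a feature gets an anchor variant, a cis window, a set of
#' causal cis variants with Gaussian effects, and a phenotype
#' `dosage %*% beta + noise`. A stated fraction of features in non-donor
#' layers reuses a donor-layer (eQTL, when present) feature's causal
#' variants and gene symbol — the cross-layer sharing that makes cross-QTL
#' replication and MMRP enumeration non-trivial downstream. m6A features
#' are assigned a host gene symbol directly, like every other layer.
#'
#' @param geno A `genotype_matrix`.
#' @param layers Named list keyed by QTL type; each entry a list with
#'   `n_features`, `n_causal`, `effect_sd`, `noise_sd`, `share_frac` and
#'   optional `tissue_label`, `dataset_tag`, `effect_values` (fixed causal
#'   effects overriding the Gaussian draw).
#' @param cis_window_bp Half-width of the cis window around the anchor.
#' @param seed Integer seed.
#' @return An object of class `molecular_layers`: list with `features`
#'   (tibble, one row per feature, list columns for cis/causal indices,
#'   effects and the phenotype vector) and `truth` (tibble of causal
#'   assignments and sharing provenance).
#' @export
simulate_molecular_layers <- function(geno, layers, cis_window_bp = 5e5,
                                      seed = 1L) {
  bad <- setdiff(names(layers), QTL_TYPES)
  if (length(bad) > 0) {
    abort(sprintf("unknown layer type(s): %s", paste(bad, collapse = ", ")),
          class = "multixwas_config_error")
  }
  for (ly in names(layers)) {
    sf <- layers[[ly]]$share_frac %||% 0
    if (sf < 0 || sf > 1) {
      abort(sprintf("share_frac for %s must be in [0, 1]", ly),
            class = "multixwas_config_error")
    }
  }
  set.seed(derive_seed(seed, "molecular_layers"))
  v <- geno$variants
  n <- nrow(geno$dosage)
  donor_layer <- if ("eQTL" %in% names(layers)) "eQTL" else names(layers)[1]
  layer_order <- c(donor_layer, setdiff(names(layers), donor_layer))
  gene_counter <- 0L
  rows <- list()
  for (ly in layer_order) {
    sp <- layers[[ly]]
    nf <- sp$n_features
    n_causal <- sp$n_causal %||% 1L
    share_frac <- if (ly == donor_layer) 0 else sp$share_frac %||% 0
    n_share <- round(share_frac * nf)
    share_flags <- rep(c(TRUE, FALSE), c(n_share, nf - n_share))
    donors <- if (n_share > 0) {
      pool <- which(map_chr(rows, "qtl_type") == donor_layer)
      sample(pool, n_share, replace = n_share > length(pool))
    } else integer(0)
    di <- 0L
    for (i in seq_len(nf)) {
      if (share_flags[i]) {
        di <- di + 1L
        src <- rows[[donors[di]]]
        anchor <- src$anchor_idx
        gene_symbol <- src$gene_symbol
        cis_idx <- src$cis_idx
        causal_idx <- src$causal_idx
        shared_from <- src$feature_id
      } else {
        anchor <- sample.int(nrow(v), 1)
        gene_counter <- gene_counter + 1L
        gene_symbol <- sprintf("GENE%04d", gene_counter)
        cis_idx <- which(v$chromosome == v$chromosome[anchor] &
                           abs(v$position - v$position[anchor]) <= cis_window_bp)
        causal_idx <- sort(sample(cis_idx, min(n_causal, length(cis_idx))))
        shared_from <- NA_character_
      }
      beta <- if (!is.null(sp$effect_values)) {
        rep_len(sp$effect_values, length(causal_idx))
      } else {
        rnorm(length(causal_idx), 0, sp$effect_sd)
      }
      phen <- as.vector(geno$dosage[, causal_idx, drop = FALSE] %*% beta) +
        rnorm(n, 0, sp$noise_sd)
      rows[[length(rows) + 1L]] <- list(
        feature_id = sprintf("%s_f%03d", tolower(ly), i),
        gene_symbol = gene_symbol, qtl_type = ly,
        tissue_label = sp$tissue_label %||% "brain_cortex",
        dataset_tag = sp$dataset_tag %||% paste0("sim_", ly),
        chromosome = v$chromosome[anchor],
        anchor_idx = anchor,
        anchor_pos = v$position[anchor],
        gene_start = max(1L, v$position[anchor] - 10000L),
        gene_end = v$position[anchor] + 10000L,
        cis_idx = cis_idx, causal_idx = causal_idx, causal_beta = beta,
        phenotype = phen, shared_from = shared_from)
    }
  }
  features <- tibble(
    feature_id = map_chr(rows, "feature_id"),
    gene_symbol = map_chr(rows, "gene_symbol"),
    qtl_type = map_chr(rows, "qtl_type"),
    tissue_label = map_chr(rows, "tissue_label"),
    dataset_tag = map_chr(rows, "dataset_tag"),
    chromosome = map_chr(rows, "chromosome"),
    anchor_idx = map_int(rows, "anchor_idx"),
    anchor_pos = map_int(rows, "anchor_pos"),
    gene_start = map_int(rows, "gene_start"),
    gene_end = map_int(rows, "gene_end"),
    cis_idx = map(rows, "cis_idx"),
    causal_idx = map(rows, "causal_idx"),
    causal_beta = map(rows, "causal_beta"),
    phenotype = map(rows, "phenotype"),
    shared_from = map_chr(rows, "shared_from")
  )
  truth <- features %>%
    select("feature_id", "gene_symbol", "qtl_type", "causal_idx",
           "causal_beta", "shared_from")
  structure(list(features = features, truth = truth),
            class = "molecular_layers")
}

#' @export
print.molecular_layers <- function(x, ...) {
  tab <- table(x$features$qtl_type)
  cat("<molecular_layers>",
      paste(sprintf("%s:%d", names(tab), as.integer(tab)), collapse = " "),
      "\n")
  invisible(x)
}

#' Gene annotation table for simulated features
#'
#' One row per distinct gene symbol, with gene-body coordinates taken from
#' the feature anchors (1-based, closed). Aliases are empty for synthetic
#' genes.
#'
#' @param layers A `molecular_layers` object.
#' @return Annotation tibble compatible with [min_p_in_window()].
#' @export
gene_annotation <- function(layers) {
  layers$features %>%
    group_by(.data$gene_symbol) %>%
    summarise(chromosome = first(.data$chromosome),
              start = min(.data$gene_start),
              end = max(.data$gene_end), .groups = "drop") %>%
    mutate(aliases = map(.data$gene_symbol, function(...) character(0))) %>%
    select(canonical_symbol = "gene_symbol", "aliases", "chromosome",
           "start", "end")
}

#' Simulate a trait with mediated and direct genetic effects
#'
#' The trait is the sum of mediated molecular effects (a fraction of
#' features each contributes `b_xy * phenotype`), sparse direct variant
#' effects, and Gaussian noise — the causal structure summary-based
#' Mendelian randomization is designed to recover. Case-control disorders
#' are emulated on this quantitative liability scale, since all downstream
#' statistics consume z / beta / se only.
#'
#' @param geno A `genotype_matrix`.
#' @param layers A `molecular_layers` object.
#' @param mediated_frac Fraction of features (across all layers) with a
#'   nonzero effect on the trait.
#' @param bxy_sd Standard deviation of the Gaussian mediated effects.
#' @param bxy_values Optional fixed mediated effect(s), recycled across the
#'   mediated features (overrides `bxy_sd`).
#' @param n_direct Number of variants with direct (non-mediated) effects.
#' @param direct_sd Standard deviation of direct effects.
#' @param noise_sd Residual standard deviation.
#' @param seed Integer seed.
#' @return A list with `trait` (numeric vector) and `truth` (list with
#'   `mediated` and `direct` tibbles recording every nonzero effect).
#' @export
simulate_trait <- function(geno, layers, mediated_frac = 0.25, bxy_sd = 0.25,
                           bxy_values = NULL, n_direct = 10L,
                           direct_sd = 0.12, noise_sd = 1, seed = 1L) {
  if (nrow(layers$features) == 0) {
    abort("`layers` has no features", class = "multixwas_config_error")
  }
  fixed_zero <- !is.null(bxy_values) && all(bxy_values == 0)
  if ((mediated_frac == 0 || (bxy_sd == 0 && is.null(bxy_values)) || fixed_zero) &&
      (n_direct == 0 || direct_sd == 0) && noise_sd == 0) {
    abort("all trait variance components are zero",
          class = "multixwas_config_error")
  }
  set.seed(derive_seed(seed, "trait"))
  n <- nrow(geno$dosage)
  nf <- nrow(layers$features)
  n_med <- round(mediated_frac * nf)
  med_idx <- if (n_med > 0) sort(sample.int(nf, n_med)) else integer(0)
  b_xy <- if (!is.null(bxy_values)) rep_len(bxy_values, n_med)
          else rnorm(n_med, 0, bxy_sd)
  trait <- rnorm(n, 0, noise_sd)
  for (k in seq_along(med_idx)) {
    trait <- trait + b_xy[k] * layers$features$phenotype[[med_idx[k]]]
  }
  if (n_direct > 0 && direct_sd > 0) {
    didx <- sort(sample.int(ncol(geno$dosage), n_direct))
    deff <- rnorm(n_direct, 0, direct_sd)
    trait <- trait + as.vector(geno$dosage[, didx, drop = FALSE] %*% deff)
  } else {
    didx <- integer(0)
    deff <- numeric(0)
  }
  truth <- list(
    mediated = tibble(feature_id = layers$features$feature_id[med_idx],
                      gene_symbol = layers$features$gene_symbol[med_idx],
                      qtl_type = layers$features$qtl_type[med_idx],
                      b_xy_true = b_xy),
    direct = tibble(variant_id = geno$variants$variant_id[didx],
                    variant_idx = didx, effect = deff)
  )
  list(trait = trait, truth = truth)
}
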