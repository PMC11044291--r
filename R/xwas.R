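#' Train per-feature variant weights for summary-based imputation
#'
#' Implements the two weight models used by the FUSION-style stage:
#' `top1` places unit weight on the cis variant with the smallest marginal
#' p-value; `ridge` fits a penalized multivariate regression on
#' standardized dosages, `w = (X'X/n + lambda I)^-1 X'y/n`. Predictive
#' accuracy (`cv_r2`) is the k-fold cross-validated squared correlation
#' between predicted and observed molecular phenotype; with
#' `model = "best"` the model with the higher `cv_r2` is kept.
#'
#' @param geno A `genotype_matrix`.
#' @param layers A `molecular_layers` object (or its `features` tibble).
#' @param model `"top1"`, `"ridge"`, or `"best"`.
#' @param cv_folds Number of cross-validation folds (>= 2); use 0 to skip
#'   cross-validation (`cv_r2` is then `NA`; not allowed with `"best"`).
#' @param ridge_lambda Ridge penalty on the correlation scale.
#' @param seed Integer seed (fold assignment).
#' @return A `weight_models` tibble: one row per feature with `model_tag`,
#'   `cv_r2` and a `weights` list column of `(variant_id, weight)` tibbles.
#' @export
train_weights <- function(geno, layers, model = c("top1", "ridge", "best"),
                          cv_folds = 5L, ridge_lambda = 0.1, seed = 1L) {
  model <- match.arg(model)
  stopifnot(ridge_lambda > 0)
  if (model == "best" && cv_folds < 2) {
    abort("`model = \"best\"` requires `cv_folds` >= 2",
          class = "multixwas_config_error")
  }
  features <- if (inherits(layers, "molecular_layers")) layers$features else layers
  set.seed(derive_seed(seed, "train_weights"))
  n <- nrow(geno$dosage)
  folds <- if (cv_folds >= 2) sample(rep_len(seq_len(cv_folds), n)) else NULL

  fit_one <- function(X, y, kind) {
    # returns weights on standardized-dosage scale
    if (kind == "top1") {
      sc <- marginal_scan(X, y)
      j <- which.min(sc$p)
      w <- rep(0, ncol(X))
      w[j] <- 1
      w
    } else {
      sdx <- apply(X, 2, stats::sd)
      Xs <- sweep(sweep(X, 2, colMeans(X)), 2, pmax(sdx, 1e-12), "/")
      S <- crossprod(Xs) / nrow(Xs)
      s <- as.vector(crossprod(Xs, y - mean(y))) / nrow(Xs)
      as.vector(solve(S + diag(ridge_lambda, ncol(X)), s))
    }
  }
  predict_w <- function(X, w) {
    sdx <- apply(X, 2, stats::sd)
    Xs <- sweep(sweep(X, 2, colMeans(X)), 2, pmax(sdx, 1e-12), "/")
    as.vector(Xs %*% w)
  }
  cv_r2_of <- function(X, y, kind) {
    if (is.null(folds)) return(NA_real_)
    pred <- rep(NA_real_, n)
    for (f in seq_len(cv_folds)) {
      tr <- folds != f
      w <- fit_one(X[tr, , drop = FALSE], y[tr], kind)
      pred[!tr] <- predict_w(X[!tr, , drop = FALSE], w)
    }
    if (stats::sd(pred) == 0) return(0)
    cor(pred, y)^2
  }

  out <- vector("list", nrow(features))
  for (i in seq_len(nrow(features))) {
    cis <- features$cis_idx[[i]]
    X <- geno$dosage[, cis, drop = FALSE]
    if (all(apply(X, 2, stats::sd) == 0)) {
      abort(sprintf("feature %s has only zero-variance cis variants",
                    features$feature_id[i]),
            class = "multixwas_data_error")
    }
    y <- features$phenotype[[i]]
    kinds <- if (model == "best") c("top1", "ridge") else model
    r2 <- vapply(kinds, function(k) cv_r2_of(X, y, k), numeric(1))
    kind <- if (model == "best") kinds[which.max(r2)] else model
    w <- fit_one(X, y, kind)
    nz <- which(w != 0)
    out[[i]] <- tibble(
      feature_id = features$feature_id[i],
      gene_symbol = features$gene_symbol[i],
      qtl_type = features$qtl_type[i],
      tissue_label = features$tissue_label[i],
      dataset_tag = features$dataset_tag[i],
      model_tag = kind,
      cv_r2 = if (model == "best") max(r2) else r2[[1]],
      weights = list(tibble(variant_id = geno$variants$variant_id[cis[nz]],
                            weight = w[nz]))
    )
  }
  res <- bind_rows(out)
  class(res) <- c("weight_models", class(res))
  res
}

# Shared constructor for per-feature association rows.
new_xwas_row <- function(meta, tool, gwas_dataset, z_stat, p_value,
                         b_xy_hat = NA_real_, p_heidi = NA_real_,
                         n_snps_heidi = NA_integer_,
                         brain_keywords = DEFAULT_BRAIN_KEYWORDS) {
  tibble(
    gene_symbol = meta$gene_symbol, feature_id = meta$feature_id,
    qtl_type = meta$qtl_type, tissue_label = meta$tissue_label,
    tissue_group = tissue_group(meta$tissue_label, brain_keywords),
    dataset_tag = meta$dataset_tag, tool = tool,
    gwas_dataset = gwas_dataset, z_stat = z_stat, b_xy_hat = b_xy_hat,
    p_value = p_value, p_heidi = p_heidi, n_snps_heidi = n_snps_heidi,
    passes_correction = NA
  )
}

#' FUSION-style weighted association
#'
#' Imputes the molecular-phenotype association z-score from GWAS summary
#' statistics: `z_stat = w'z / sqrt(w' R w)` with `w` the feature's variant
#' weights, `z` the GWAS z-scores over the weighted variants and `R` the LD
#' reference correlation. When the quadratic form is non-positive or `R` is
#' not positive semi-definite, the ridge-regularized
#' `R_reg = (1 - lambda) R + lambda I` is substituted.
#'
#' @param weights A `weight_models` tibble from [train_weights()].
#' @param gwas A `gwas_sumstats` tibble (harmonized to the LD reference).
#' @param ld An `ld_reference`.
#' @param regularize_lambda Shrinkage intensity for `R_reg` (default 0.1).
#' @param gwas_dataset GWAS dataset label; defaults to the trait id carried
#'   by `gwas`.
#' @param brain_keywords Passed to [tissue_group()].
#' @return An `xwas_results` tibble, one row per feature, `tool = "FUSION"`.
#' @export
twas_association <- function(weights, gwas, ld, regularize_lambda = 0.1,
                             gwas_dataset = NULL,
                             brain_keywords = DEFAULT_BRAIN_KEYWORDS) {
  gwas_dataset <- gwas_dataset %||% attr(gwas, "trait_id") %||% "trait"
  zmap <- setNames(gwas$z, gwas$variant_id)
  R <- ld$correlation
  out <- vector("list", nrow(weights))
  for (i in seq_len(nrow(weights))) {
    wt <- weights$weights[[i]]
    ids <- wt$variant_id
    missing_ids <- setdiff(ids, intersect(names(zmap), rownames(R)))
    if (length(missing_ids) > 0) {
      abort(sprintf("feature %s: weighted variant(s) absent from GWAS/LD: %s",
                    weights$feature_id[i], paste(missing_ids, collapse = ", ")),
            class = "multixwas_data_error")
    }
    w <- wt$weight
    z <- unname(zmap[ids])
    Rsub <- R[ids, ids, drop = FALSE]
    qf <- drop(crossprod(w, Rsub %*% w))
    psd <- is.finite(qf) && qf > 0 &&
      !inherits(try(chol(Rsub), silent = TRUE), "try-error")
    if (!psd) {
      Rsub <- (1 - regularize_lambda) * Rsub +
        diag(regularize_lambda, length(ids))
      qf <- drop(crossprod(w, Rsub %*% w))
    }
    if (!is.finite(qf) || qf <= 0) {
      abort(sprintf("feature %s: non-positive imputation variance",
                    weights$feature_id[i]),
            class = "multixwas_data_error")
    }
    zs <- sum(w * z) / sqrt(qf)
    out[[i]] <- new_xwas_row(weights[i, ], "FUSION", gwas_dataset,
                             z_stat = zs, p_value = z_to_p(zs),
                             brain_keywords = brain_keywords)
  }
  res <- bind_rows(out)
  class(res) <- c("xwas_results", class(res))
  res
}

#' Summary-data-based Mendelian randomization (SMR)
#'
#' For each feature, uses the most significant cis-QTL variant as the
#' instrument and estimates the effect of the molecular phenotype on the
#' trait as the Wald ratio `b_xy = b_zy / b_zx`. The test statistic is
#' `z_smr^2 = z_zy^2 z_zx^2 / (z_zy^2 + z_zx^2)`, referred to chi-square
#' with 1 df. Features whose best cis-QTL does not reach
#' `instrument_p_threshold` are skipped (reported in the `"skipped"`
#' attribute).
#'
#' @param qtl A `qtl_sumstats` tibble (any number of features).
#' @param gwas A `gwas_sumstats` tibble.
#' @param instrument_p_threshold Instrument significance threshold
#'   (default 5e-8).
#' @param gwas_dataset GWAS dataset label; defaults to the trait id of
#'   `gwas`.
#' @param brain_keywords Passed to [tissue_group()].
#' @return An `xwas_results` tibble, one row per testable feature,
#'   `tool = "SMR"`, with `b_xy_hat` and the instrument id in
#'   `instrument_id`.
#' @export
smr_test <- function(qtl, gwas, instrument_p_threshold = 5e-8,
                     gwas_dataset = NULL,
                     brain_keywords = DEFAULT_BRAIN_KEYWORDS) {
  gwas_dataset <- gwas_dataset %||% attr(gwas, "trait_id") %||% "trait"
  g <- tibble(variant_id = gwas$variant_id,
              b_zy = if (all(is.na(gwas$beta))) gwas$z else gwas$beta,
              se_zy = if (all(is.na(gwas$se))) 1 else gwas$se,
              z_zy = gwas$z)
  top <- qtl %>%
    inner_join(g, by = "variant_id") %>%
    group_by(.data$feature_id) %>%
    slice_min(.data$p_zx, n = 1, with_ties = FALSE) %>%
    ungroup()
  skipped <- top %>%
    filter(.data$p_zx >= instrument_p_threshold) %>%
    mutate(reason = "no instrument") %>%
    select("feature_id", "reason")
  top <- top %>% filter(.data$p_zx < instrument_p_threshold)
  if (any(top$beta_zx == 0)) {
    abort(sprintf("zero instrument effect (undefined Wald ratio) for: %s",
                  paste(top$feature_id[top$beta_zx == 0], collapse = ", ")),
          class = "multixwas_data_error")
  }
  z_zx <- top$beta_zx / top$se_zx
  z_smr2 <- (top$z_zy^2 * z_zx^2) / (top$z_zy^2 + z_zx^2)
  b_xy <- top$b_zy / top$beta_zx
  res <- new_xwas_row(top, "SMR", gwas_dataset,
                      z_stat = sign(b_xy) * sqrt(z_smr2),
                      p_value = pchisq(z_smr2, df = 1, lower.tail = FALSE),
                      b_xy_hat = b_xy, brain_keywords = brain_keywords)
  res$instrument_id <- top$variant_id
  if (nrow(res) > 0) {
    class(res) <- c("xwas_results", class(res))
  }
  attr(res, "skipped") <- skipped
  res
}

#' HEIDI heterogeneity test
#'
#' Tests whether the SMR signal at a feature is consistent with a single
#' shared causal variant (heterogeneity absent) or reflects linkage of
#' distinct causal variants. For each selected non-instrument cis SNP `i`,
#' `d_i = b_xy(i) - b_xy(top)`; under the single-causal-variant null the
#' `d` vector is asymptotically multivariate normal with a covariance
#' obtained by the delta method from the LD correlations and per-SNP
#' standard errors. The p-value of the observed `sum((d_i / se(d_i))^2)` is
#' evaluated by Monte-Carlo sampling of that null (seeded; default 10,000
#' draws). SNP selection mirrors the conventional defaults: cis SNPs with
#' `p_zx` below `p_zx_threshold`, LD-pruned at `r^2 > r2_prune_high`,
#' excluded below `r^2 < r2_min` with the instrument, 3-20 SNPs.
#'
#' @param qtl A `qtl_sumstats` tibble.
#' @param gwas A `gwas_sumstats` tibble.
#' @param ld An `ld_reference` covering the cis variants.
#' @param min_snps,max_snps Bounds on the number of SNPs used.
#' @param r2_prune_high Pairwise LD pruning threshold.
#' @param r2_min Minimum LD with the instrument for a SNP to be eligible.
#' @param p_zx_threshold cis-QTL significance required for eligibility.
#' @param n_draws Monte-Carlo draws from the null.
#' @param seed Integer seed.
#' @return A tibble with `feature_id`, `p_heidi`, `n_snps_heidi`,
#'   `heidi_note` (`NA` p with a note when fewer than `min_snps` SNPs are
#'   eligible).
#' @export
heidi_test <- function(qtl, gwas, ld, min_snps = 3L, max_snps = 20L,
                       r2_prune_high = 0.9, r2_min = 0.05,
                       p_zx_threshold = 1.57e-3, n_draws = 10000L,
                       seed = 1L) {
  g <- tibble(variant_id = gwas$variant_id,
              b_zy = if (all(is.na(gwas$beta))) gwas$z else gwas$beta,
              se_zy = if (all(is.na(gwas$se))) 1 else gwas$se)
  R <- ld$correlation
  feats <- unique(qtl$feature_id)
  out <- vector("list", length(feats))
  for (k in seq_along(feats)) {
    fid <- feats[k]
    dat <- qtl[qtl$feature_id == fid, , drop = FALSE] %>%
      inner_join(g, by = "variant_id") %>%
      filter(.data$variant_id %in% rownames(R))
    res <- list(feature_id = fid, p_heidi = NA_real_,
                n_snps_heidi = NA_integer_, heidi_note = NA_character_)
    if (nrow(dat) == 0) {
      res$heidi_note <- "HEIDI not evaluable (no LD-covered SNPs)"
      out[[k]] <- res
      next
    }
    t_i <- which.min(dat$p_zx)
    elig <- which(dat$p_zx < p_zx_threshold)
    elig <- union(t_i, elig)
    r_top <- R[dat$variant_id[elig], dat$variant_id[t_i]]
    elig <- elig[elig == t_i | r_top^2 >= r2_min]
    # greedy LD prune, most significant first, instrument always kept
    ord <- elig[order(dat$p_zx[elig])]
    kept <- integer(0)
    for (cand in ord) {
      if (length(kept) == 0 ||
          all(R[dat$variant_id[cand], dat$variant_id[kept]]^2 <= r2_prune_high)) {
        kept <- c(kept, cand)
      } else if (cand == t_i) {
        kept <- c(kept, cand)  # instrument is never pruned away
      }
    }
    if (length(kept) > max_snps) {
      keep_others <- setdiff(kept, t_i)
      keep_others <- keep_others[order(dat$p_zx[keep_others])][seq_len(max_snps - 1L)]
      kept <- c(t_i, keep_others)
    }
    if (length(kept) < min_snps) {
      res$heidi_note <- sprintf("HEIDI not evaluable (%d < %d SNPs)",
                                length(kept), min_snps)
      out[[k]] <- res
      next
    }
    kept <- c(t_i, setdiff(kept, t_i))
    d0 <- dat[kept, , drop = FALSE]
    Rk <- R[d0$variant_id, d0$variant_id, drop = FALSE]
    bzx <- d0$beta_zx; sezx <- d0$se_zx
    bzy <- d0$b_zy; sezy <- d0$se_zy
    # delta-method covariance of the per-SNP Wald ratios (GWAS and QTL
    # cohorts independent, so the two terms add)
    C <- Rk * outer(sezy, sezy) / outer(bzx, bzx) +
      Rk * outer(sezx, sezx) * outer(bzy, bzy) / outer(bzx^2, bzx^2)
    bxy <- bzy / bzx
    m <- length(kept) - 1L
    d <- bxy[-1] - bxy[1]
    V <- C[-1, -1, drop = FALSE] -
      matrix(C[-1, 1], m, m) - matrix(C[-1, 1], m, m, byrow = TRUE) + C[1, 1]
    vd <- pmax(diag(V), 1e-12)
    t_obs <- sum(d^2 / vd)
    eg <- eigen((V + t(V)) / 2, symmetric = TRUE)
    lam <- pmax(eg$values, 0)
    set.seed(derive_seed(seed, paste0("heidi_", fid)))
    Z <- matrix(rnorm(n_draws * m), n_draws, m)
    draws <- Z %*% (t(eg$vectors) * sqrt(lam))
    t_null <- rowSums(sweep(draws^2, 2, vd, "/"))
    res$p_heidi <- (1 + sum(t_null >= t_obs)) / (n_draws + 1)
    res$n_snps_heidi <- length(kept)
    out[[k]] <- res
  }
  tibble(feature_id = map_chr(out, "feature_id"),
         p_heidi = map_dbl(out, "p_heidi"),
         n_snps_heidi = map_int(out, "n_snps_heidi"),
         heidi_note = map_chr(out, "heidi_note"))
}

#' Bonferroni correction and HEIDI retention filter
#'
#' Sets `passes_correction` within each testing family (by default one
#' GWAS dataset x one QTL dataset x one tool): a result passes when
#' `p_value < alpha / m` with `m` the family size. SMR results with an
#' evaluable HEIDI p additionally require `p_heidi` above the retention
#' threshold — associations explained by linkage rather than a shared
#' causal variant are discarded.
#'
#' @param results An `xwas_results` tibble.
#' @param alpha Family-wise error target in (0, 1).
#' @param heidi_retain_threshold Minimum HEIDI p for SMR retention.
#' @param family_key Character vector of grouping columns defining the
#'   Bonferroni family.
#' @return `results` with `passes_correction` and `m_family` filled in.
#' @export
bonferroni_filter <- function(results, alpha = 0.05,
                              heidi_retain_threshold = 0.05,
                              family_key = c("gwas_dataset", "dataset_tag",
                                             "tool")) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single value in (0, 1)",
          class = "multixwas_config_error")
  }
  if (nrow(results) == 0) {
    abort("`results` is empty", class = "multixwas_config_error")
  }
  out <- results %>%
    group_by(across(all_of(family_key))) %>%
    mutate(m_family = n(),
           passes_correction = .data$p_value < alpha / .data$m_family) %>%
    ungroup() %>%
    mutate(passes_correction = .data$passes_correction &
             (.data$tool != "SMR" | is.na(.data$p_heidi) |
                .data$p_heidi > heidi_retain_threshold))
  class(out) <- unique(c("xwas_results", class(out)))
  out
}
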