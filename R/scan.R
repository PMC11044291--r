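# Vectorised simple-regression scan: y on each column of X separately.
# Returns beta, se, z, p per column; zero-variance columns give NA.
marginal_scan <- function(X, y) {
  n <- nrow(X)
  xc <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  sxx <- colSums(xc^2)
  syy <- sum(yc^2)
  beta <- se <- rep(NA_real_, ncol(X))
  ok <- sxx > 0
  if (any(ok)) {
    sxy <- as.vector(crossprod(xc[, ok, drop = FALSE], yc))
    b <- sxy / sxx[ok]
    # floor the residual SS so a perfect fit yields a huge finite z while
    # z = beta / se stays exact
    sse <- pmax(syy - b^2 * sxx[ok], syy * 1e-16, 1e-300)
    s2 <- sse / (n - 2)
    beta[ok] <- b
    se[ok] <- sqrt(s2 / sxx[ok])
  }
  z <- beta / se
  list(beta = beta, se = se, z = z, p = z_to_p(z), n = n, ok = ok)
}

#' Genome-wide association scan on a simulated cohort
#'
#' Per-variant simple linear regression of the trait on dosage, reporting
#' beta, se, the Wald z and its two-sided Gaussian p — the summary
#' statistics a published GWAS would provide. Zero-variance variants are
#' skipped with a warning.
#'
#' @param geno A `genotype_matrix`.
#' @param trait Numeric trait vector, one value per individual.
#' @param trait_id Label stored on the result.
#' @return A `gwas_sumstats` tibble.
#' @export
scan_gwas <- function(geno, trait, trait_id = "trait") {
  stopifnot(length(trait) == nrow(geno$dosage))
  sc <- marginal_scan(geno$dosage, trait)
  if (any(!sc$ok)) {
    warn(sprintf("skipping %d zero-variance variant(s)", sum(!sc$ok)))
  }
  out <- geno$variants %>%
    mutate(z = sc$z, beta = sc$beta, se = sc$se, p = sc$p, n = sc$n) %>%
    filter(!is.na(.data$z)) %>%
    select("variant_id", "chromosome", "position", "effect_allele",
           "other_allele", "z", "beta", "se", "p", "n")
  new_gwas_sumstats(out, trait_id = trait_id)
}

#' Nominal-pass cis-QTL scan
#'
#' For every feature of every layer, regresses the molecular phenotype on
#' each cis variant separately (marginal regression within the cis window;
#' no permutation pass) and returns the long per-feature, per-variant
#' summary statistics used by the SMR/HEIDI and weight-training stages.
#'
#' @param geno A `genotype_matrix`.
#' @param layers A `molecular_layers` object (or its `features` tibble).
#' @return A `qtl_sumstats` tibble: one row per feature x cis variant.
#' @export
scan_cis_qtl <- function(geno, layers) {
  features <- if (inherits(layers, "molecular_layers")) layers$features else layers
  keep <- lengths(features$cis_idx) > 0
  if (any(!keep)) {
    warn(sprintf("skipping %d feature(s) with no cis variants", sum(!keep)))
    features <- features[keep, , drop = FALSE]
  }
  n <- nrow(geno$dosage)
  nf <- nrow(features)
  X <- geno$dosage
  xc <- sweep(X, 2, colMeans(X))
  sxx <- colSums(xc^2)
  Y <- matrix(unlist(features$phenotype), nrow = n, ncol = nf)
  Yc <- sweep(Y, 2, colMeans(Y))
  syy <- colSums(Yc^2)
  SXY <- crossprod(xc, Yc)              # m x nf
  rows <- unlist(features$cis_idx)
  reps <- lengths(features$cis_idx)
  cols <- rep(seq_len(nf), reps)
  pick <- cbind(rows, cols)
  beta <- unname(SXY[pick] / sxx[rows])
  sse <- pmax(syy[cols] - beta^2 * sxx[rows], syy[cols] * 1e-16, 1e-300)
  se <- unname(sqrt(sse / (n - 2) / sxx[rows]))
  z <- beta / se
  v <- geno$variants
  out <- tibble(
    feature_id = rep(features$feature_id, reps),
    gene_symbol = rep(features$gene_symbol, reps),
    qtl_type = rep(features$qtl_type, reps),
    tissue_label = rep(features$tissue_label, reps),
    dataset_tag = rep(features$dataset_tag, reps),
    variant_id = v$variant_id[rows],
    chromosome = v$chromosome[rows],
    position = v$position[rows],
    effect_allele = v$effect_allele[rows],
    other_allele = v$other_allele[rows],
    beta_zx = beta, se_zx = se, p_zx = z_to_p(z), n = n
  )
  bad <- !is.finite(out$beta_zx) | !is.finite(out$se_zx) | out$se_zx <= 0
  out <- out[!bad, , drop = FALSE]
  class(out) <- c("qtl_sumstats", class(out))
  out
}
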