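#' Extended MHC region
#'
#' The extended major histocompatibility complex interval on chromosome 6,
#' conventionally excluded from summary-based association because its
#' long-range, complex LD produces spurious weighted associations.
#' Coordinates are 1-based and fully closed.
#'
#' @return A list with `chromosome`, `start`, `end`.
#' @export
mhc_region <- function() {
  list(chromosome = "6", start = 28477797L, end = 33448354L)
}

#' Analysis configuration
#'
#' Bundles every tunable threshold of the pipeline together with the
#' synthetic-cohort parameters, validates them, and carries the master seed
#' from which every stage derives its own substream.
#'
#' @param seed Master integer seed for all randomness.
#' @param mhc_region Region excluded from GWAS variants before association,
#'   as a list `(chromosome, start, end)`; 1-based closed interval.
#' @param bonferroni_alpha Family-wise error target for the Bonferroni
#'   correction applied within each GWAS dataset x QTL dataset x tool family.
#' @param heidi_retain_threshold SMR associations are retained only when the
#'   HEIDI heterogeneity p-value exceeds this (default 0.05).
#' @param novelty_threshold Genome-wide significance level; a reliable gene
#'   is novel when the minimum GWAS p in its window is strictly above it.
#' @param reliable_min_count Minimum number of distinct evidence lines for a
#'   gene to be called reliable (default 2).
#' @param window_bp Half-width in bp of the novelty window added on each
#'   side of the gene body (default 1 Mb).
#' @param brain_keywords Substrings marking a tissue label as brain-derived.
#' @param instrument_p_threshold Minimum cis-QTL significance for a variant
#'   to serve as the SMR instrument (default 5e-8).
#' @param heidi Named list of HEIDI selection parameters: `min_snps`,
#'   `max_snps`, `r2_prune_high`, `r2_min`, `p_zx_threshold`, `n_draws`.
#' @param sim Named list of synthetic-cohort parameters; see
#'   [default_sim_spec()].
#' @param disorder Label for the simulated disorder.
#' @param gwas_dataset Label for the simulated GWAS dataset.
#' @param weight_model Weight-training model for the FUSION-style stage:
#'   `"top1"`, `"ridge"`, or `"best"`.
#' @return An object of class `xwas_config`.
#' @export
xwas_config <- function(seed = 1L,
                        mhc_region = multixwas::mhc_region(),
                        bonferroni_alpha = 0.05,
                        heidi_retain_threshold = 0.05,
                        novelty_threshold = 5e-8,
                        reliable_min_count = 2L,
                        window_bp = 1e6,
                        brain_keywords = DEFAULT_BRAIN_KEYWORDS,
                        instrument_p_threshold = 5e-8,
                        heidi = list(),
                        sim = list(),
                        disorder = "SCZ",
                        gwas_dataset = "SCZ_sim",
                        weight_model = c("top1", "ridge", "best")) {
  weight_model <- match.arg(weight_model)
  for (nm in c("bonferroni_alpha", "heidi_retain_threshold", "novelty_threshold")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v <= 0 || v >= 1) {
      abort(sprintf("`%s` must be a single value in (0, 1), got %s", nm,
                    paste(v, collapse = ",")),
            class = "multixwas_config_error")
    }
  }
  if (!is.numeric(window_bp) || window_bp <= 0) {
    abort("`window_bp` must be > 0", class = "multixwas_config_error")
  }
  if (!is.numeric(reliable_min_count) || reliable_min_count < 1) {
    abort("`reliable_min_count` must be >= 1", class = "multixwas_config_error")
  }
  stopifnot(is.list(mhc_region),
            all(c("chromosome", "start", "end") %in% names(mhc_region)),
            mhc_region$start <= mhc_region$end)
  heidi_defaults <- list(min_snps = 3L, max_snps = 20L, r2_prune_high = 0.9,
                         r2_min = 0.05, p_zx_threshold = 1.57e-3,
                         n_draws = 10000L)
  heidi <- utils::modifyList(heidi_defaults, heidi)
  sim <- utils::modifyList(default_sim_spec(), sim)
  structure(
    list(seed = as.integer(seed), mhc_region = mhc_region,
         bonferroni_alpha = bonferroni_alpha,
         heidi_retain_threshold = heidi_retain_threshold,
         novelty_threshold = novelty_threshold,
         reliable_min_count = as.integer(reliable_min_count),
         window_bp = window_bp, brain_keywords = brain_keywords,
         instrument_p_threshold = instrument_p_threshold,
         heidi = heidi, sim = sim, disorder = disorder,
         gwas_dataset = gwas_dataset, weight_model = weight_model),
    class = "xwas_config")
}

#' Default synthetic-cohort specification
#'
#' The cohort the pipeline simulates by default: 2,000 individuals typed at
#' 600 variants in 30 LD blocks of 20 (AR(1) within-block correlation 0.9,
#' MAF 0.05-0.5, 5 kb spacing), five molecular layers with one causal cis
#' variant per feature, 40% of non-eQTL features sharing their causal
#' variants and gene symbol with an eQTL feature, and a trait receiving
#' mediated effects from a quarter of the features plus a handful of direct
#' variant effects.
#'
#' @return A named list of simulator parameters.
#' @export
default_sim_spec <- function() {
  list(
    n_individuals = 2000L,
    n_variants = 600L,
    block_size = 20L,
    within_block_r = 0.9,
    maf_range = c(0.05, 0.5),
    bp_spacing = 5000L,
    chromosome = "1",
    cis_window_bp = 5e5,
    layers = list(
      eQTL  = list(n_features = 60L, n_causal = 1L, effect_sd = 0.35,
                   noise_sd = 1, share_frac = 0,   tissue_label = "brain_cortex"),
      sQTL  = list(n_features = 40L, n_causal = 1L, effect_sd = 0.35,
                   noise_sd = 1, share_frac = 0.4, tissue_label = "brain_cortex"),
      pQTL  = list(n_features = 30L, n_causal = 1L, effect_sd = 0.35,
                   noise_sd = 1, share_frac = 0.4, tissue_label = "brain_dlpfc"),
      mQTL  = list(n_features = 30L, n_causal = 1L, effect_sd = 0.35,
                   noise_sd = 1, share_frac = 0.4, tissue_label = "blood"),
      m6AQTL = list(n_features = 20L, n_causal = 1L, effect_sd = 0.35,
                    noise_sd = 1, share_frac = 0.4, tissue_label = "brain_cortex")
    ),
    trait = list(mediated_frac = 0.25, bxy_sd = 0.25, bxy_values = NULL,
                 n_direct = 10L, direct_sd = 0.12, noise_sd = 1)
  )
}

#' @export
print.xwas_config <- function(x, ...) {
  cat("<xwas_config>\n")
  cat("  seed:", x$seed, " disorder:", x$disorder,
      " gwas_dataset:", x$gwas_dataset, "\n")
  cat(sprintf("  MHC excluded: chr%s:%d-%d\n", x$mhc_region$chromosome,
              x$mhc_region$start, x$mhc_region$end))
  cat(sprintf("  alpha %.3g | HEIDI retain > %.3g | novelty > %.3g | min lines %d | window %s bp\n",
              x$bonferroni_alpha, x$heidi_retain_threshold,
              x$novelty_threshold, x$reliable_min_count,
              format(x$window_bp, big.mark = ",")))
  cat(sprintf("  cohort: n=%d, m=%d variants, %d layers\n",
              x$sim$n_individuals, x$sim$n_variants, length(x$sim$layers)))
  invisible(x)
}
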