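# Small shared fixtures, rebuilt in code at load time (kept cheap).

tiny_geno <- simulate_genotypes(400, 60, block_size = 10, within_block_r = 0.8,
                                maf_range = c(0.1, 0.5), seed = 42)

tiny_layers <- simulate_molecular_layers(
  tiny_geno,
  layers = list(eQTL = list(n_features = 6, n_causal = 1, effect_sd = 0.6,
                            noise_sd = 1),
                sQTL = list(n_features = 4, n_causal = 1, effect_sd = 0.6,
                            noise_sd = 1, share_frac = 0.5)),
  cis_window_bp = 5e4, seed = 42)

# A hand-written GWAS table used by harmonization / evidence tests.
mk_gwas <- function(df, trait_id = "SCZ_sim") {
  defaults <- tibble::tibble(
    variant_id = character(), chromosome = character(), position = integer(),
    effect_allele = character(), other_allele = character(),
    z = numeric(), beta = numeric(), se = numeric(), p = numeric(),
    n = numeric())
  out <- dplyr::bind_rows(defaults, df)
  if (all(is.na(out$p))) out$p <- 2 * pnorm(-abs(out$z))
  attr(out, "trait_id") <- trait_id
  class(out) <- c("gwas_sumstats", class(out))
  out
}

# Minimal evidence-line tibble in the five-field dictionary form.
mk_lines <- function(...) {
  df <- tibble::tribble(...)
  build_evidence_lines(df, source_group = "CG")
}
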