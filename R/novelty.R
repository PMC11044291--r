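#' Minimum GWAS p-value in a window around each gene
#'
#' For every gene, forms the window `[start - window_bp, end + window_bp]`
#' (1-based closed on both edges, clamped at 1) on the gene's chromosome
#' and records the minimum GWAS p-value and the number of SNPs inside.
#' The window is anchored to the gene body, so strand is irrelevant.
#' Overlap is computed with GenomicRanges; genes on chromosomes absent
#' from the GWAS, or with an empty window, get a missing `min_p` and are
#' reported, never silently dropped.
#'
#' @param genes Annotation tibble with `canonical_symbol` (or
#'   `gene_symbol`), `chromosome`, `start`, `end`.
#' @param gwas A `gwas_sumstats` tibble.
#' @param window_bp Half-width added on each side of the gene body
#'   (default 1 Mb).
#' @return A `novelty_calls` tibble: `gene_symbol`, `chromosome`,
#'   `window_start`, `window_end`, `n_snps_in_window`, `min_p`, `note`.
#' @export
min_p_in_window <- function(genes, gwas, window_bp = 1e6) {
  if ("canonical_symbol" %in% names(genes)) {
    genes <- rename(genes, gene_symbol = "canonical_symbol")
  }
  assert_columns(genes, c("gene_symbol", "chromosome", "start", "end"),
                 "gene annotation")
  out <- genes %>%
    mutate(window_start = pmax(1, .data$start - window_bp),
           window_end = .data$end + window_bp,
           n_snps_in_window = 0L, min_p = NA_real_, note = NA_character_)
  on_chr <- out$chromosome %in% unique(gwas$chromosome)
  out$note[!on_chr] <- "chromosome absent from GWAS"
  if (any(on_chr) && nrow(gwas) > 0) {
    snp_gr <- GenomicRanges::GRanges(
      seqnames = gwas$chromosome,
      ranges = IRanges::IRanges(start = gwas$position, width = 1L))
    win_gr <- GenomicRanges::GRanges(
      seqnames = out$chromosome[on_chr],
      ranges = IRanges::IRanges(start = out$window_start[on_chr],
                                end = out$window_end[on_chr]))
    hits <- GenomicRanges::findOverlaps(win_gr, snp_gr)
    if (length(hits) > 0) {
      hi <- tibble(gene = S4Vectors::queryHits(hits),
                   p = gwas$p[S4Vectors::subjectHits(hits)]) %>%
        group_by(.data$gene) %>%
        summarise(n = n(), mp = min(.data$p), .groups = "drop")
      rows <- which(on_chr)[hi$gene]
      out$n_snps_in_window[rows] <- hi$n
      out$min_p[rows] <- hi$mp
    }
  }
  out$note[on_chr & out$n_snps_in_window == 0] <- "no SNPs in window"
  out <- out %>%
    select("gene_symbol", "chromosome", "window_start", "window_end",
           "n_snps_in_window", "min_p", "note")
  class(out) <- c("novelty_calls", class(out))
  out
}

#' Classify genes as novel against the original GWAS
#'
#' A reliable gene is novel when the minimum GWAS p-value among SNPs in
#' its window is strictly greater than the genome-wide significance
#' threshold — i.e. the locus carried no significant signal in the
#' original GWAS. Genes without an evaluable window minimum stay
#' unclassifiable (`is_novel` missing).
#'
#' @param calls A `novelty_calls` tibble from [min_p_in_window()].
#' @param threshold Genome-wide significance level (default 5e-8); the
#'   comparison is strict (`min_p > threshold`), so a gene at exactly the
#'   threshold is non-novel.
#' @return `calls` with an `is_novel` logical column added.
#' @export
classify_novel <- function(calls, threshold = 5e-8) {
  stopifnot(threshold > 0, threshold < 1)
  out <- calls %>% mutate(is_novel = .data$min_p > threshold)
  class(out) <- unique(c("novelty_calls", class(out)))
  out
}
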