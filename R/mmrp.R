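#' Pairwise replication matrix between gene sets
#'
#' For a collection of labelled gene sets (QTL types or disorders),
#' computes the symmetric pairwise overlap counts and the directed
#' replication ratios: entry `(A, B)` is `|A intersect B| / |A|` — the
#' size of one set is the denominator, the overlap the numerator, so the
#' matrix is generally asymmetric. An empty set yields missing ratios
#' rather than a division error.
#'
#' @param sets Named list of character vectors (gene symbols), at least
#'   two labels.
#' @return An object of class `replication_matrix`: list with `labels`,
#'   `sizes`, `counts` (symmetric integer matrix) and `ratios` (directed).
#' @export
replication_matrix <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2, !is.null(names(sets)))
  sets <- lapply(sets, function(s) unique(as.character(s)))
  k <- length(sets)
  labels <- names(sets)
  counts <- matrix(0L, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      counts[i, j] <- length(intersect(sets[[i]], sets[[j]]))
    }
  }
  sizes <- lengths(sets)
  ratios <- counts / sizes                 # row i divided by |set i|
  ratios[sizes == 0, ] <- NA_real_
  structure(list(labels = labels, sizes = sizes, counts = counts,
                 ratios = ratios),
            class = "replication_matrix")
}

#' @export
print.replication_matrix <- function(x, ...) {
  cat("<replication_matrix>", length(x$labels), "sets\n")
  print(round(x$ratios, 3))
  invisible(x)
}

#' Tidy a replication matrix into long form
#'
#' @param x A `replication_matrix`.
#' @param ... Unused.
#' @return A tibble with `from`, `to`, `size_from`, `overlap`, `ratio`.
#' @method tidy replication_matrix
#' @export
tidy.replication_matrix <- function(x, ...) {
  k <- length(x$labels)
  tibble(
    from = rep(x$labels, each = k),
    to = rep(x$labels, k),
    size_from = rep(unname(x$sizes), each = k),
    overlap = as.integer(t(x$counts)[seq_len(k * k)]),
    ratio = as.numeric(t(x$ratios)[seq_len(k * k)])
  )
}

#' Compare replication times of novel vs non-novel genes
#'
#' Joins per-gene support counts with novelty calls and contrasts the
#' number of supporting evidence lines ("replication times") between novel
#' and non-novel genes: group medians plus a two-sided Wilcoxon rank-sum
#' test (normal approximation with tie correction). The test is flagged
#' degenerate (missing p) when either group has fewer than two genes or
#' all counts are tied.
#'
#' @param counts A `support_counts` tibble.
#' @param novelty A classified `novelty_calls` tibble (with `is_novel`).
#' @return A one-row-per-disorder tibble with `median_novel`,
#'   `median_non_novel`, `n_novel`, `n_non_novel`, `test_p`, `note`.
#' @export
compare_replication_times <- function(counts, novelty) {
  dat <- counts %>%
    inner_join(novelty %>% select("gene_symbol", "is_novel"),
               by = "gene_symbol") %>%
    filter(!is.na(.data$is_novel))
  if (nrow(dat) == 0) {
    abort("no genes shared between `counts` and `novelty`",
          class = "multixwas_data_error")
  }
  dat %>%
    group_by(.data$disorder) %>%
    summarise(
      median_novel = median(.data$n_support[.data$is_novel]),
      median_non_novel = median(.data$n_support[!.data$is_novel]),
      n_novel = sum(.data$is_novel),
      n_non_novel = sum(!.data$is_novel),
      test_p = {
        x <- .data$n_support[.data$is_novel]
        y <- .data$n_support[!.data$is_novel]
        if (length(x) < 2 || length(y) < 2 ||
            length(unique(c(x, y))) == 1) NA_real_
        else suppressWarnings(
          wilcox.test(x, y, alternative = "two.sided", exact = FALSE,
                      correct = TRUE)$p.value)
      },
      note = {
        x <- .data$n_support[.data$is_novel]
        y <- .data$n_support[!.data$is_novel]
        if (length(x) == 0 || length(y) == 0) "a group is empty"
        else if (length(x) < 2 || length(y) < 2) "test degenerate (group of 1)"
        else if (length(unique(c(x, y))) == 1) "test degenerate (all tied)"
        else NA_character_
      },
      .groups = "drop")
}

#' Per-gene QTL-type profiles
#'
#' For each disorder and gene, the set of distinct QTL types across the
#' gene's evidence lines — the molecular layers through which the gene was
#' mapped. Profiles are computed independently per disorder.
#'
#' @param lines An `evidence_lines` tibble.
#' @param disorder Optional disorder filter.
#' @return A tibble with `disorder`, `gene_symbol`, `qtl_types` (sorted
#'   list column), `profile` (canonical `+`-joined string), `n_qtl_types`.
#' @export
gene_qtl_profiles <- function(lines, disorder = NULL) {
  if (!is.null(disorder)) {
    lines <- filter(lines, .data$disorder %in% !!disorder)
  }
  lines %>%
    distinct(.data$disorder, .data$gene_symbol, .data$qtl_type) %>%
    group_by(.data$disorder, .data$gene_symbol) %>%
    summarise(
      qtl_types = list(intersect(QTL_TYPES, .data$qtl_type)),
      .groups = "drop") %>%
    mutate(profile = map_chr(.data$qtl_types, paste, collapse = "+"),
           n_qtl_types = lengths(.data$qtl_types))
}

#' Enumerate multiple molecular regulation patterns (MMRP)
#'
#' A gene mapped by two or more QTL types belongs to exactly one pattern —
#' the full set of QTL types in its profile — so per-disorder pattern gene
#' counts partition the multi-QTL genes. Patterns record whether they
#' contain eQTL and are sorted by pattern size then gene count
#' (descending).
#'
#' @param profiles Output of [gene_qtl_profiles()].
#' @param restrict_to Optional gene set (e.g. novel reliable genes)
#'   applied before enumeration.
#' @return An `mmrp_patterns` tibble: `disorder`, `profile`, `qtl_set`
#'   (list), `contains_eqtl`, `n_genes`, `genes` (sorted list column).
#' @export
enumerate_mmrp <- function(profiles, restrict_to = NULL) {
  if (!is.null(restrict_to)) {
    profiles <- filter(profiles, .data$gene_symbol %in% restrict_to)
  }
  multi <- filter(profiles, .data$n_qtl_types >= 2)
  if (nrow(multi) == 0) {
    out <- tibble(disorder = character(0), profile = character(0),
                  qtl_set = list(), contains_eqtl = logical(0),
                  n_genes = integer(0), genes = list(),
                  pattern_size = integer(0))
    class(out) <- c("mmrp_patterns", class(out))
    return(out)
  }
  out <- multi %>%
    group_by(.data$disorder, .data$profile) %>%
    summarise(qtl_set = list(.data$qtl_types[[1]]),
              contains_eqtl = "eQTL" %in% .data$qtl_types[[1]],
              n_genes = n(),
              genes = list(sort(.data$gene_symbol)),
              .groups = "drop") %>%
    mutate(pattern_size = lengths(.data$qtl_set)) %>%
    arrange(.data$disorder, .data$pattern_size, dplyr::desc(.data$n_genes),
            .data$profile)
  class(out) <- c("mmrp_patterns", class(out))
  out
}
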