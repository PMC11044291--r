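#' Read the gene-symbol alias table
#'
#' Loads the static alias-to-canonical mapping shipped with the package
#' (a small synthetic subset of HGNC-style alias pairs) or a user table
#' with columns `ALIAS`, `CANONICAL`.
#'
#' @param path Path to a tab-separated alias table; defaults to the
#'   packaged fixture.
#' @return A tibble with `alias` and `canonical` columns.
#' @export
read_alias_table <- function(path = system.file("extdata", "gene_aliases.tsv",
                                                package = "multixwas")) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(raw, c("ALIAS", "CANONICAL"), "alias table")
  tibble(alias = as.character(raw$ALIAS),
         canonical = as.character(raw$CANONICAL))
}

# Fold case and hyphen/underscore variants for fuzzy symbol matching.
fold_symbol <- function(x) gsub("[-_]", "", toupper(x))

#' Normalize gene symbols through an alias table
#'
#' Maps each raw symbol to its canonical form by exact alias lookup, then
#' by case-insensitive lookup with hyphen/underscore variants folded.
#' Unmapped symbols pass through verbatim and are listed in the attached
#' report — unmapped is a report, never an error.
#'
#' @param raw Character vector of gene symbols.
#' @param alias_table Tibble with `alias`, `canonical` columns
#'   (see [read_alias_table()]).
#' @return A tibble with `raw`, `canonical`, `mapped`; attribute
#'   `"unmapped"` holds the distinct symbols that passed through.
#' @export
normalize_symbols <- function(raw, alias_table = read_alias_table()) {
  exact <- setNames(alias_table$canonical, alias_table$alias)
  folded <- setNames(alias_table$canonical, fold_symbol(alias_table$alias))
  canon <- unname(exact[raw])
  still <- is.na(canon)
  canon[still] <- unname(folded[fold_symbol(raw[still])])
  mapped <- !is.na(canon)
  canon[!mapped] <- raw[!mapped]
  out <- tibble(raw = raw, canonical = canon, mapped = mapped)
  attr(out, "unmapped") <- unique(raw[!mapped])
  out
}

#' Build evidence lines in dictionary form
#'
#' Converts association results or curated table rows into the five-field
#' evidence dictionary 'GWAS dataset - xQTL type - tissue - tool - gene'.
#' Tissue labels are collapsed to brain / non-brain first, gene symbols are
#' normalized when an alias table is supplied, and exact-duplicate lines
#' collapse to one: a line only counts again if any of the five key fields
#' changes. Note the QTL *dataset* is deliberately not part of the key —
#' two different eQTL panels with the same tissue group and tool contribute
#' a single line.
#'
#' @param df Tibble with `gwas_dataset`, `qtl_type`, `tool`, `gene_symbol`
#'   and either `tissue_group` or `tissue_label`; an optional `disorder`
#'   column (derived from the `gwas_dataset` prefix before the first
#'   underscore when absent).
#' @param source_group `"CG"` (curated literature results) or `"SG"`
#'   (supplementary reanalyses).
#' @param brain_keywords Passed to [tissue_group()] when collapsing labels.
#' @param alias_table Optional alias table for symbol normalization.
#' @return An `evidence_lines` tibble: one row per distinct line with
#'   columns `disorder`, `gwas_dataset`, `qtl_type`, `tissue_group`,
#'   `tool`, `gene_symbol`, `source_group`.
#' @export
build_evidence_lines <- function(df, source_group = c("SG", "CG"),
                                 brain_keywords = DEFAULT_BRAIN_KEYWORDS,
                                 alias_table = NULL) {
  source_group <- match.arg(source_group)
  assert_columns(df, c("gwas_dataset", "qtl_type", "tool", "gene_symbol"),
                 "evidence input")
  if (!"tissue_group" %in% names(df)) {
    assert_columns(df, "tissue_label", "evidence input")
    df$tissue_group <- tissue_group(df$tissue_label, brain_keywords)
  }
  key <- c("gwas_dataset", "qtl_type", "tissue_group", "tool", "gene_symbol")
  bad <- which(!complete.cases(df[key]) |
                 rowSums(df[key] == "" | is.na(df[key])) > 0)
  if (length(bad) > 0) {
    abort(sprintf("evidence row(s) with missing key field(s): %s",
                  paste(bad, collapse = ", ")),
          class = "multixwas_data_error")
  }
  if (!is.null(alias_table)) {
    df$gene_symbol <- normalize_symbols(df$gene_symbol, alias_table)$canonical
  }
  if (!"disorder" %in% names(df)) {
    df$disorder <- sub("_.*$", "", df$gwas_dataset)
  }
  out <- df %>%
    mutate(source_group = source_group) %>%
    distinct(.data$disorder, .data$gwas_dataset, .data$qtl_type,
             .data$tissue_group, .data$tool, .data$gene_symbol,
             .data$source_group)
  class(out) <- c("evidence_lines", class(out))
  out
}

#' Count supporting evidence lines per gene
#'
#' Per disorder and gene, counts the distinct evidence lines supporting
#' the gene. In pooled mode (the default) CG and SG lines are pooled
#' before deduplication on the five-field key, so a CG line and an SG line
#' with identical key fields count once; in per-source mode counts are
#' reported separately for CG and SG.
#'
#' @param lines An `evidence_lines` tibble (CG, SG, or both).
#' @param pool_sources Pool CG and SG before counting (default `TRUE`).
#' @return A `support_counts` tibble: `disorder`, `gene_symbol`,
#'   `source_group` (`"pooled"` or CG/SG), `n_support`, and an `evidence`
#'   list column with the contributing line keys.
#' @export
count_support <- function(lines, pool_sources = TRUE) {
  key_str <- function(d) {
    paste(d$gwas_dataset, d$qtl_type, d$tissue_group, d$tool, sep = "—")
  }
  if (pool_sources) {
    dd <- lines %>%
      distinct(.data$disorder, .data$gwas_dataset, .data$qtl_type,
               .data$tissue_group, .data$tool, .data$gene_symbol) %>%
      mutate(source_group = "pooled")
  } else {
    dd <- lines %>%
      distinct(.data$disorder, .data$gwas_dataset, .data$qtl_type,
               .data$tissue_group, .data$tool, .data$gene_symbol,
               .data$source_group)
  }
  out <- dd %>%
    mutate(line_key = key_str(dd)) %>%
    group_by(.data$disorder, .data$gene_symbol, .data$source_group) %>%
    summarise(n_support = n(), evidence = list(sort(.data$line_key)),
              .groups = "drop") %>%
    arrange(.data$disorder, dplyr::desc(.data$n_support), .data$gene_symbol)
  class(out) <- c("support_counts", class(out))
  out
}

#' Call reliable genes
#'
#' A gene is reliable when supported by at least `min_count` distinct
#' evidence lines (default 2 — replicated at least twice).
#'
#' @param counts A `support_counts` tibble.
#' @param min_count Minimum number of distinct lines (>= 1).
#' @return The rows of `counts` reaching the threshold.
#' @export
reliable_genes <- function(counts, min_count = 2L) {
  stopifnot(min_count >= 1)
  counts %>% filter(.data$n_support >= min_count)
}

#' Reliable-gene summary across source groupings
#'
#' Per disorder, computes total and reliable gene counts for CG lines
#' alone, SG lines alone, the CG+SG pooled counting mode (lines pooled
#' before deduplication and thresholding) and the union of the two
#' per-source reliable sets — the two readings of a combined "Total" row.
#'
#' @param lines An `evidence_lines` tibble containing CG and/or SG rows.
#' @param min_count Reliable-gene threshold (default 2).
#' @return A tibble with `disorder`, `group` (CG / SG / pooled / union),
#'   `n_genes`, `n_reliable` and a `reliable` list column of gene symbols.
#' @export
reliable_gene_summary <- function(lines, min_count = 2L) {
  per_group <- function(sub, label) {
    if (nrow(sub) == 0) return(NULL)
    cnt <- count_support(sub, pool_sources = TRUE)
    rel <- reliable_genes(cnt, min_count)
    cnt %>%
      group_by(.data$disorder) %>%
      summarise(n_genes = n_distinct(.data$gene_symbol), .groups = "drop") %>%
      left_join(rel %>%
                  group_by(.data$disorder) %>%
                  summarise(n_reliable = n_distinct(.data$gene_symbol),
                            reliable = list(sort(unique(.data$gene_symbol))),
                            .groups = "drop"),
                by = "disorder") %>%
      mutate(group = label,
             n_reliable = ifelse(is.na(.data$n_reliable), 0L, .data$n_reliable),
             reliable = map(.data$reliable, function(g) g %||% character(0)))
  }
  cg <- per_group(filter(lines, .data$source_group == "CG"), "CG")
  sg <- per_group(filter(lines, .data$source_group == "SG"), "SG")
  pooled <- per_group(lines, "pooled")
  uni <- NULL
  if (!is.null(cg) && !is.null(sg)) {
    uni <- bind_rows(cg, sg) %>%
      tidyr::unnest_longer("reliable", values_to = "gene",
                           keep_empty = FALSE) %>%
      group_by(.data$disorder) %>%
      summarise(n_genes = NA_integer_,
                n_reliable = n_distinct(.data$gene),
                reliable = list(sort(unique(.data$gene))),
                .groups = "drop") %>%
      mutate(group = "union")
  }
  bind_rows(cg, sg, pooled, uni) %>%
    select("disorder", "group", "n_genes", "n_reliable", "reliable") %>%
    arrange(.data$disorder, .data$group)
}
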