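#' Read GWAS summary statistics
#'
#' Reads a tab-separated GWAS summary-statistics table into the canonical
#' layout used throughout the package: one row per variant with columns
#' `variant_id`, `chromosome`, `position`, `effect_allele`, `other_allele`,
#' `z`, `beta`, `se`, `p`, `n`. Dialects are accommodated through
#' `column_map`; `z` is computed as `beta / se` when absent, and `p` from
#' `z` when absent. Rows failing validation (non-positive position, equal
#' alleles, p outside (0, 1]) are dropped with a warning naming their line
#' numbers.
#'
#' @param path Path to a tab-separated file with a header.
#' @param column_map Named character vector mapping canonical names
#'   (`SNP, CHR, BP, A1, A2, Z, BETA, SE, P, N`) to the file's column names.
#' @param trait_id Optional trait label stored as the `trait_id` attribute.
#' @return A tibble of class `gwas_sumstats`.
#' @export
read_gwas_sumstats <- function(path, column_map = NULL, trait_id = NULL) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  canon <- c(SNP = "SNP", CHR = "CHR", BP = "BP", A1 = "A1", A2 = "A2",
             Z = "Z", BETA = "BETA", SE = "SE", P = "P", N = "N")
  if (!is.null(column_map)) canon[names(column_map)] <- unname(column_map)
  need <- c("SNP", "CHR", "BP", "A1", "A2")
  miss <- need[!canon[need] %in% names(raw)]
  if (length(miss) > 0) {
    abort(sprintf("GWAS file %s lacks required column(s): %s", path,
                  paste(canon[miss], collapse = ", ")),
          class = "multixwas_config_error")
  }
  has <- function(k) canon[[k]] %in% names(raw)
  if (!has("Z") && !(has("BETA") && has("SE"))) {
    abort("GWAS file must provide Z or both BETA and SE",
          class = "multixwas_config_error")
  }
  col <- function(k, default = NA) {
    if (has(k)) raw[[canon[[k]]]] else rep(default, nrow(raw))
  }
  out <- tibble(
    variant_id = as.character(col("SNP")),
    chromosome = sub("^chr", "", as.character(col("CHR"))),
    position = as.integer(col("BP")),
    effect_allele = toupper(as.character(col("A1"))),
    other_allele = toupper(as.character(col("A2"))),
    z = as.numeric(col("Z", NA_real_)),
    beta = as.numeric(col("BETA", NA_real_)),
    se = as.numeric(col("SE", NA_real_)),
    p = as.numeric(col("P", NA_real_)),
    n = as.numeric(col("N", NA_real_))
  )
  out$z <- ifelse(is.na(out$z) & !is.na(out$beta) & !is.na(out$se),
                  out$beta / out$se, out$z)
  out$p <- ifelse(is.na(out$p), z_to_p(out$z), out$p)
  dup <- out$variant_id[duplicated(out$variant_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicated variant_id in %s: %s", path,
                  paste(unique(dup), collapse = ", ")),
          class = "multixwas_data_error")
  }
  bad <- which(is.na(out$position) | out$position < 1 |
                 out$effect_allele == out$other_allele |
                 is.na(out$z) | is.na(out$p) | out$p <= 0 | out$p > 1)
  if (length(bad) > 0) {
    warn(sprintf("dropping %d invalid row(s) at line(s): %s",
                 length(bad), paste(bad + 1L, collapse = ", ")))
    out <- out[-bad, , drop = FALSE]
  }
  new_gwas_sumstats(out, trait_id = trait_id %||% "trait")
}

new_gwas_sumstats <- function(df, trait_id = "trait") {
  out <- as_tibble(df)
  class(out) <- c("gwas_sumstats", class(out))
  attr(out, "trait_id") <- trait_id
  out
}

#' Write GWAS summary statistics to TSV
#'
#' @param x A `gwas_sumstats` tibble.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_gwas_sumstats <- function(x, path) {
  out <- tibble(SNP = x$variant_id, CHR = x$chromosome, BP = x$position,
                A1 = x$effect_allele, A2 = x$other_allele, Z = x$z,
                BETA = x$beta, SE = x$se, P = x$p, N = x$n)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(x)
}

#' Read cis-QTL summary statistics
#'
#' Long-format table: one row per molecular feature x cis variant, with
#' per-variant effect (`beta_zx`), standard error and p-value for the
#' feature's molecular phenotype.
#'
#' @param path Tab-separated file with columns `FEATURE, GENE, QTL_TYPE,
#'   TISSUE, DATASET, SNP, CHR, BP, A1, A2, BETA, SE, P` (and optional `N`).
#' @param column_map Optional canonical-to-file column name mapping.
#' @return A tibble of class `qtl_sumstats`.
#' @export
read_qtl_sumstats <- function(path, column_map = NULL) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  canon <- c(FEATURE = "FEATURE", GENE = "GENE", QTL_TYPE = "QTL_TYPE",
             TISSUE = "TISSUE", DATASET = "DATASET", SNP = "SNP", CHR = "CHR",
             BP = "BP", A1 = "A1", A2 = "A2", BETA = "BETA", SE = "SE",
             P = "P", N = "N")
  if (!is.null(column_map)) canon[names(column_map)] <- unname(column_map)
  need <- setdiff(names(canon), "N")
  miss <- need[!canon[need] %in% names(raw)]
  if (length(miss) > 0) {
    abort(sprintf("QTL file %s lacks required column(s): %s", path,
                  paste(canon[miss], collapse = ", ")),
          class = "multixwas_config_error")
  }
  qt <- as.character(raw[[canon[["QTL_TYPE"]]]])
  bad_qt <- setdiff(unique(qt), QTL_TYPES)
  if (length(bad_qt) > 0) {
    abort(sprintf("unknown QTL type(s) in %s: %s", path,
                  paste(bad_qt, collapse = ", ")),
          class = "multixwas_data_error")
  }
  out <- tibble(
    feature_id = as.character(raw[[canon[["FEATURE"]]]]),
    gene_symbol = as.character(raw[[canon[["GENE"]]]]),
    qtl_type = qt,
    tissue_label = as.character(raw[[canon[["TISSUE"]]]]),
    dataset_tag = as.character(raw[[canon[["DATASET"]]]]),
    variant_id = as.character(raw[[canon[["SNP"]]]]),
    chromosome = sub("^chr", "", as.character(raw[[canon[["CHR"]]]])),
    position = as.integer(raw[[canon[["BP"]]]]),
    effect_allele = toupper(as.character(raw[[canon[["A1"]]]])),
    other_allele = toupper(as.character(raw[[canon[["A2"]]]])),
    beta_zx = as.numeric(raw[[canon[["BETA"]]]]),
    se_zx = as.numeric(raw[[canon[["SE"]]]]),
    p_zx = as.numeric(raw[[canon[["P"]]]]),
    n = if (canon[["N"]] %in% names(raw)) as.numeric(raw[[canon[["N"]]]]) else NA_real_
  )
  class(out) <- c("qtl_sumstats", class(out))
  out
}

#' Write cis-QTL summary statistics to TSV
#'
#' @param x A `qtl_sumstats` tibble.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_qtl_sumstats <- function(x, path) {
  out <- tibble(FEATURE = x$feature_id, GENE = x$gene_symbol,
                QTL_TYPE = x$qtl_type, TISSUE = x$tissue_label,
                DATASET = x$dataset_tag, SNP = x$variant_id,
                CHR = x$chromosome, BP = x$position, A1 = x$effect_allele,
                A2 = x$other_allele, BETA = x$beta_zx, SE = x$se_zx,
                P = x$p_zx, N = x$n)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(x)
}

#' Read a BED-like gene annotation table
#'
#' Columns `CHR, START, END, SYMBOL, ALIASES` (aliases semicolon-joined,
#' may be empty). Following BED convention `START` is 0-based half-open on
#' disk and is converted to the package's 1-based closed convention on read.
#'
#' @param path Tab-separated file with a header.
#' @return A tibble with `canonical_symbol`, `aliases` (list column),
#'   `chromosome`, `start`, `end` (1-based, closed).
#' @export
read_gene_annotation <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(raw, c("CHR", "START", "END", "SYMBOL"), "gene annotation")
  al <- if ("ALIASES" %in% names(raw)) as.character(raw$ALIASES) else ""
  al[is.na(al)] <- ""
  out <- tibble(
    canonical_symbol = as.character(raw$SYMBOL),
    aliases = lapply(strsplit(al, ";", fixed = TRUE),
                     function(x) x[nzchar(x)]),
    chromosome = sub("^chr", "", as.character(raw$CHR)),
    start = as.integer(raw$START) + 1L,
    end = as.integer(raw$END)
  )
  stopifnot(all(nzchar(out$canonical_symbol)), all(out$start <= out$end))
  out
}

#' Write a gene annotation table in BED-like form
#'
#' Converts the package's 1-based closed `start` back to BED's 0-based
#' convention on write.
#'
#' @param x Annotation tibble as returned by [read_gene_annotation()].
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_gene_annotation <- function(x, path) {
  out <- tibble(CHR = x$chromosome, START = x$start - 1L, END = x$end,
                SYMBOL = x$canonical_symbol,
                ALIASES = map_chr(x$aliases, paste, collapse = ";"))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(x)
}

#' Read a curated evidence table
#'
#' One row per evidence line in the dictionary form
#' GWAS dataset - xQTL type - tissue - tool - gene, plus the source group
#' (CG for curated literature results, SG for supplementary reanalyses).
#'
#' @param path Tab-separated file with columns `GWAS_DATASET, QTL_TYPE,
#'   TISSUE, TOOL, GENE, SOURCE`.
#' @return A tibble with the raw fields renamed to package conventions.
#' @export
read_evidence_table <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(raw, c("GWAS_DATASET", "QTL_TYPE", "TISSUE", "TOOL",
                        "GENE", "SOURCE"), "evidence table")
  tibble(
    gwas_dataset = as.character(raw$GWAS_DATASET),
    qtl_type = as.character(raw$QTL_TYPE),
    tissue_label = as.character(raw$TISSUE),
    tool = as.character(raw$TOOL),
    gene_symbol = as.character(raw$GENE),
    source_group = as.character(raw$SOURCE)
  )
}

#' Write an evidence-line table to TSV
#'
#' @param x Evidence tibble with the five key fields plus `source_group`.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_evidence_table <- function(x, path) {
  tissue <- if ("tissue_group" %in% names(x)) x$tissue_group else x$tissue_label
  out <- tibble(GWAS_DATASET = x$gwas_dataset, QTL_TYPE = x$qtl_type,
                TISSUE = tissue, TOOL = x$tool, GENE = x$gene_symbol,
                SOURCE = x$source_group)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(x)
}

#' Harmonize GWAS summary statistics to a variant reference
#'
#' Matches variants to the reference by id, flips the sign of `z` (and
#' `beta`) where effect/other alleles are swapped relative to the reference,
#' drops strand-ambiguous variants (A/T, C/G), and drops variants whose
#' alleles cannot be reconciled or that are absent from the reference.
#' Harmonization never changes `|z|` — only sign or presence.
#'
#' @param gwas A `gwas_sumstats` tibble.
#' @param reference A tibble of reference variants with `variant_id`,
#'   `effect_allele`, `other_allele` (e.g. a simulated cohort's variant
#'   table or an LD reference's variant list).
#' @return The harmonized `gwas_sumstats`; attribute `"harmonization"`
#'   holds a one-row report tibble with counts kept / flipped / dropped.
#' @export
harmonize_to_reference <- function(gwas, reference) {
  assert_columns(reference, c("variant_id", "effect_allele", "other_allele"),
                 "reference")
  ref <- reference %>%
    select("variant_id", ref_a1 = "effect_allele", ref_a2 = "other_allele")
  m <- gwas %>% inner_join(ref, by = "variant_id")
  n_unmatched <- nrow(gwas) - nrow(m)
  ambiguous <- is_ambiguous_pair(m$effect_allele, m$other_allele)
  same <- m$effect_allele == m$ref_a1 & m$other_allele == m$ref_a2
  swapped <- m$effect_allele == m$ref_a2 & m$other_allele == m$ref_a1
  n_ambiguous <- sum(ambiguous)
  keep_same <- !ambiguous & same
  keep_flip <- !ambiguous & swapped
  n_mismatch <- sum(!ambiguous & !same & !swapped)
  out <- m[keep_same | keep_flip, , drop = FALSE]
  flip <- keep_flip[keep_same | keep_flip]
  out$z[flip] <- -out$z[flip]
  out$beta[flip] <- -out$beta[flip]
  a1 <- out$effect_allele[flip]
  out$effect_allele[flip] <- out$other_allele[flip]
  out$other_allele[flip] <- a1
  out$ref_a1 <- out$ref_a2 <- NULL
  if (nrow(out) == 0) {
    abort("no variants survive harmonization (empty overlap with reference)",
          class = "multixwas_data_error")
  }
  report <- tibble(n_input = nrow(gwas), n_kept = nrow(out),
                   n_flipped = sum(flip), n_ambiguous_dropped = n_ambiguous,
                   n_mismatch_dropped = n_mismatch,
                   n_unmatched_dropped = n_unmatched)
  res <- new_gwas_sumstats(out, trait_id = attr(gwas, "trait_id") %||% "trait")
  attr(res, "harmonization") <- report
  res
}

#' Remove variants inside a genomic region
#'
#' Drops every row whose `chromosome` matches the region and whose
#' `position` lies in the closed interval `[start, end]`; all other rows
#' pass through untouched. Used with the default region to excise the
#' extended MHC before association.
#'
#' @param records Any tibble with `chromosome` and `position` columns
#'   (GWAS or QTL summary statistics, variant tables).
#' @param region A list `(chromosome, start, end)`, 1-based closed;
#'   defaults to [mhc_region()].
#' @return The filtered collection, same class as the input.
#' @export
exclude_region <- function(records, region = mhc_region()) {
  assert_columns(records, c("chromosome", "position"), "records")
  stopifnot(region$start <= region$end)
  chrom <- sub("^chr", "", as.character(region$chromosome))
  drop <- records$chromosome == chrom &
    records$position >= region$start & records$position <= region$end
  records[!drop, , drop = FALSE]
}
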