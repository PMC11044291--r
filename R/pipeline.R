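#' Run the full xWAS integration pipeline
#'
#' Orchestrates simulate -> xwas -> curate -> novelty -> metrics -> mmrp
#' from one validated configuration. Every stage draws its randomness from
#' a named substream of the master seed, so re-running with the same
#' config and seed reproduces identical outputs. Each stage logs its
#' record counts and active thresholds via [message()].
#'
#' @param config An [xwas_config()].
#' @param curated_evidence Optional curated evidence table (path to a TSV
#'   readable by [read_evidence_table()], or an equivalent tibble)
#'   contributing CG/SG lines alongside the pipeline's own results.
#' @param stages Ordered subset of
#'   `c("simulate", "xwas", "curate", "novelty", "metrics", "mmrp")`.
#'   Later stages require their prerequisites either scheduled earlier or
#'   supplied through `inputs`.
#' @param inputs Named list of pre-computed stage inputs (e.g. `gwas`,
#'   `qtl`, `ld`, `annotation`, `lines`) allowing partial runs without the
#'   simulator.
#' @return An object of class `xwas_pipeline` holding every intermediate
#'   and final table plus a run manifest.
#' @export
run_pipeline <- function(config, curated_evidence = NULL,
                         stages = c("simulate", "xwas", "curate", "novelty",
                                    "metrics", "mmrp"),
                         inputs = list()) {
  stopifnot(inherits(config, "xwas_config"))
  all_stages <- c("simulate", "xwas", "curate", "novelty", "metrics", "mmrp")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  started <- Sys.time()
  x <- inputs
  x$config <- config
  counts <- list()
  need <- function(what, stage) {
    if (is.null(x[[what]])) {
      abort(sprintf("stage '%s' requires '%s' (schedule an earlier stage or pass it via `inputs`)",
                    stage, what),
            class = "multixwas_orchestration_error")
    }
    x[[what]]
  }

  if ("simulate" %in% stages) {
    sm <- config$sim
    x$geno <- simulate_genotypes(sm$n_individuals, sm$n_variants,
                                 block_size = sm$block_size,
                                 within_block_r = sm$within_block_r,
                                 maf_range = sm$maf_range, seed = config$seed,
                                 bp_spacing = sm$bp_spacing,
                                 chromosome = sm$chromosome)
    x$layers <- simulate_molecular_layers(x$geno, sm$layers,
                                          cis_window_bp = sm$cis_window_bp,
                                          seed = config$seed)
    tr <- simulate_trait(x$geno, x$layers,
                         mediated_frac = sm$trait$mediated_frac,
                         bxy_sd = sm$trait$bxy_sd,
                         bxy_values = sm$trait$bxy_values,
                         n_direct = sm$trait$n_direct,
                         direct_sd = sm$trait$direct_sd,
                         noise_sd = sm$trait$noise_sd, seed = config$seed)
    x$trait <- tr$trait
    x$truth <- tr$truth
    x$gwas <- exclude_region(scan_gwas(x$geno, x$trait,
                                       trait_id = config$gwas_dataset),
                             config$mhc_region)
    x$qtl <- scan_cis_qtl(x$geno, x$layers)
    x$ld <- ld_reference(x$geno)
    x$annotation <- gene_annotation(x$layers)
    counts$simulate <- c(variants = nrow(x$gwas),
                         features = nrow(x$layers$features),
                         qtl_rows = nrow(x$qtl))
    message(sprintf("[simulate] %d individuals, %d GWAS variants (MHC excluded), %d features",
                    config$sim$n_individuals, nrow(x$gwas),
                    nrow(x$layers$features)))
  }

  if ("xwas" %in% stages) {
    geno <- need("geno", "xwas"); qtl <- need("qtl", "xwas")
    gwas <- need("gwas", "xwas"); ld <- need("ld", "xwas")
    layers <- need("layers", "xwas")
    cvf <- if (config$weight_model == "top1") 0L else 5L
    x$weights <- train_weights(geno, layers, model = config$weight_model,
                               cv_folds = cvf, seed = config$seed)
    fusion <- twas_association(x$weights, gwas, ld,
                               gwas_dataset = config$gwas_dataset,
                               brain_keywords = config$brain_keywords)
    smr <- smr_test(qtl, gwas,
                    instrument_p_threshold = config$instrument_p_threshold,
                    gwas_dataset = config$gwas_dataset,
                    brain_keywords = config$brain_keywords)
    if (nrow(smr) > 0) {
      hq <- qtl %>% semi_join(smr, by = "feature_id")
      hd <- heidi_test(hq, gwas, ld,
                       min_snps = config$heidi$min_snps,
                       max_snps = config$heidi$max_snps,
                       r2_prune_high = config$heidi$r2_prune_high,
                       r2_min = config$heidi$r2_min,
                       p_zx_threshold = config$heidi$p_zx_threshold,
                       n_draws = config$heidi$n_draws, seed = config$seed)
      smr <- smr %>%
        select(-"p_heidi", -"n_snps_heidi") %>%
        left_join(hd, by = "feature_id")
    }
    res <- bind_rows(fusion, smr)
    x$results <- bonferroni_filter(res, alpha = config$bonferroni_alpha,
                                   heidi_retain_threshold = config$heidi_retain_threshold)
    counts$xwas <- c(results = nrow(x$results),
                     significant = sum(x$results$passes_correction))
    message(sprintf("[xwas] %d association rows (%d FUSION, %d SMR), %d pass Bonferroni %.2g + HEIDI > %.2g",
                    nrow(x$results), nrow(fusion), nrow(smr),
                    sum(x$results$passes_correction), config$bonferroni_alpha,
                    config$heidi_retain_threshold))
  }

  if ("curate" %in% stages) {
    lines <- x$lines
    if (is.null(lines) && !is.null(x$results)) {
      sig <- x$results %>%
        filter(.data$passes_correction) %>%
        mutate(disorder = config$disorder)
      lines <- if (nrow(sig) > 0) {
        build_evidence_lines(sig, "SG",
                             brain_keywords = config$brain_keywords)
      } else NULL
    }
    if (is.null(lines) && is.null(curated_evidence) && is.null(x$results)) {
      need("results", "curate")
    }
    if (!is.null(curated_evidence)) {
      tbl <- if (is.character(curated_evidence)) {
        read_evidence_table(curated_evidence)
      } else curated_evidence
      cg <- bind_rows(lapply(unique(tbl$source_group), function(sg) {
        build_evidence_lines(tbl[tbl$source_group == sg, , drop = FALSE],
                             sg, brain_keywords = config$brain_keywords)
      }))
      lines <- bind_rows(lines, cg)
    }
    if (is.null(lines) || nrow(lines) == 0) {
      abort("stage 'curate' produced no evidence lines",
            class = "multixwas_orchestration_error")
    }
    x$lines <- distinct(lines)
    x$counts <- count_support(x$lines, pool_sources = TRUE)
    x$reliable <- reliable_genes(x$counts, config$reliable_min_count)
    x$reliable_summary <- reliable_gene_summary(x$lines,
                                                config$reliable_min_count)
    counts$curate <- c(lines = nrow(x$lines), genes = nrow(x$counts),
                       reliable = nrow(x$reliable))
    message(sprintf("[curate] %d evidence lines, %d genes, %d reliable (>= %d lines)",
                    nrow(x$lines), nrow(x$counts), nrow(x$reliable),
                    config$reliable_min_count))
  }

  if ("novelty" %in% stages) {
    gwas <- need("gwas", "novelty")
    ann <- need("annotation", "novelty")
    rel <- need("reliable", "novelty")
    rel_genes <- unique(rel$gene_symbol)
    known <- ann %>% filter(.data$canonical_symbol %in% rel_genes)
    calls <- min_p_in_window(known, gwas, window_bp = config$window_bp) %>%
      classify_novel(threshold = config$novelty_threshold)
    unknown <- setdiff(rel_genes, known$canonical_symbol)
    if (length(unknown) > 0) {
      calls <- bind_rows(calls, tibble(
        gene_symbol = unknown, chromosome = NA_character_,
        window_start = NA_real_, window_end = NA_real_,
        n_snps_in_window = 0L, min_p = NA_real_,
        note = "no coordinates", is_novel = NA))
    }
    x$novelty <- calls
    counts$novelty <- c(classified = sum(!is.na(calls$is_novel)),
                        novel = sum(calls$is_novel, na.rm = TRUE))
    message(sprintf("[novelty] %d reliable genes, %d classifiable, %d novel (min p > %.2g in +/- %s bp)",
                    length(rel_genes), sum(!is.na(calls$is_novel)),
                    sum(calls$is_novel, na.rm = TRUE),
                    config$novelty_threshold,
                    format(config$window_bp, scientific = FALSE)))
  }

  if ("metrics" %in% stages) {
    lines <- need("lines", "metrics")
    x$metrics <- list()
    by_qtl <- split(lines$gene_symbol, lines$qtl_type)
    if (length(by_qtl) >= 2) {
      x$metrics$qtl_replication <- replication_matrix(by_qtl)
    }
    if (!is.null(x$reliable)) {
      rl <- lines %>% semi_join(x$reliable, by = "gene_symbol")
      by_qtl_rel <- split(rl$gene_symbol, rl$qtl_type)
      if (length(by_qtl_rel) >= 2) {
        x$metrics$qtl_replication_reliable <- replication_matrix(by_qtl_rel)
      }
    }
    by_dis <- split(lines$gene_symbol, lines$disorder)
    if (length(by_dis) >= 2) {
      x$metrics$disorder_replication <- replication_matrix(by_dis)
    }
    if (!is.null(x$novelty) && !is.null(x$counts)) {
      x$metrics$replication_times <- tryCatch(
        compare_replication_times(x$counts, x$novelty),
        error = function(e) NULL)
    }
    counts$metrics <- c(matrices = sum(!map_lgl(x$metrics, is.null)))
    message(sprintf("[metrics] %d replication summaries", counts$metrics))
  }

  if ("mmrp" %in% stages) {
    lines <- need("lines", "mmrp")
    x$profiles <- gene_qtl_profiles(lines)
    x$mmrp <- enumerate_mmrp(x$profiles)
    if (!is.null(x$novelty) && !is.null(x$reliable)) {
      novel_rel <- intersect(
        x$reliable$gene_symbol,
        x$novelty$gene_symbol[which(x$novelty$is_novel)])
      x$mmrp_novel <- enumerate_mmrp(x$profiles, restrict_to = novel_rel)
    }
    counts$mmrp <- c(patterns = nrow(x$mmrp),
                     genes = sum(x$mmrp$n_genes))
    message(sprintf("[mmrp] %d patterns over %d multi-QTL genes",
                    nrow(x$mmrp), sum(x$mmrp$n_genes)))
  }

  x$manifest <- list(
    seed = config$seed,
    stages = stages,
    config = config,
    counts = counts,
    version = as.character(packageVersion("multixwas")),
    started = started, finished = Sys.time())
  structure(x, class = "xwas_pipeline")
}

#' @export
print.xwas_pipeline <- function(x, ...) {
  cat("<xwas_pipeline> seed", x$manifest$seed, "| stages:",
      paste(x$manifest$stages, collapse = " -> "), "\n")
  for (st in names(x$manifest$counts)) {
    cnt <- x$manifest$counts[[st]]
    cat(sprintf("  %-8s %s\n", st,
                paste(sprintf("%s=%s", names(cnt), cnt), collapse = " ")))
  }
  invisible(x)
}

#' Tidy the pipeline into a per-gene table
#'
#' @param x An `xwas_pipeline`.
#' @param ... Unused.
#' @return A tibble, one row per disorder x gene: support count,
#'   reliability, novelty call and QTL profile.
#' @method tidy xwas_pipeline
#' @export
tidy.xwas_pipeline <- function(x, ...) {
  out <- x$counts %>%
    mutate(reliable = .data$n_support >= x$config$reliable_min_count) %>%
    select("disorder", "gene_symbol", "n_support", "reliable")
  if (!is.null(x$novelty)) {
    out <- out %>%
      left_join(x$novelty %>% select("gene_symbol", "min_p", "is_novel"),
                by = "gene_symbol")
  }
  if (!is.null(x$profiles)) {
    out <- out %>%
      left_join(x$profiles %>%
                  select("disorder", "gene_symbol", "profile", "n_qtl_types"),
                by = c("disorder", "gene_symbol"))
  }
  out
}

#' One-row pipeline summary
#'
#' @param x An `xwas_pipeline`.
#' @param ... Unused.
#' @return A one-row tibble of headline counts.
#' @method glance xwas_pipeline
#' @export
glance.xwas_pipeline <- function(x, ...) {
  tibble(
    seed = x$manifest$seed,
    n_features = if (!is.null(x$layers)) nrow(x$layers$features) else NA_integer_,
    n_results = if (!is.null(x$results)) nrow(x$results) else NA_integer_,
    n_significant = if (!is.null(x$results)) sum(x$results$passes_correction) else NA_integer_,
    n_genes = if (!is.null(x$counts)) nrow(x$counts) else NA_integer_,
    n_reliable = if (!is.null(x$reliable)) nrow(x$reliable) else NA_integer_,
    n_novel = if (!is.null(x$novelty)) sum(x$novelty$is_novel, na.rm = TRUE) else NA_integer_,
    n_mmrp = if (!is.null(x$mmrp)) nrow(x$mmrp) else NA_integer_
  )
}

#' Write the pipeline's output tables to TSV
#'
#' Emits the machine-readable outputs of a run (association results,
#' evidence lines, support counts, reliable genes, novelty calls,
#' replication ratios, MMRP patterns) as deterministic TSV files — two
#' runs with the same config and seed produce byte-identical files.
#'
#' @param x An `xwas_pipeline`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_pipeline_tables <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  wr <- function(df, name) {
    p <- file.path(dir, paste0(name, ".tsv"))
    readr::write_tsv(df, p, progress = FALSE)
    paths[[name]] <<- p
  }
  if (!is.null(x$results)) {
    wr(x$results %>% select(-dplyr::any_of("heidi_note")), "xwas_results")
  }
  if (!is.null(x$lines)) wr(x$lines, "evidence_lines")
  if (!is.null(x$counts)) {
    wr(x$counts %>%
         mutate(evidence = map_chr(.data$evidence, paste, collapse = ";")),
       "support_counts")
  }
  if (!is.null(x$reliable)) {
    wr(x$reliable %>%
         mutate(evidence = map_chr(.data$evidence, paste, collapse = ";")),
       "reliable_genes")
  }
  if (!is.null(x$novelty)) wr(x$novelty, "novelty_calls")
  if (!is.null(x$metrics$qtl_replication)) {
    wr(tidy(x$metrics$qtl_replication), "qtl_replication")
  }
  if (!is.null(x$mmrp)) {
    wr(x$mmrp %>%
         mutate(qtl_set = map_chr(.data$qtl_set, paste, collapse = "+"),
                genes = map_chr(.data$genes, paste, collapse = ";")),
       "mmrp_patterns")
  }
  invisible(unlist(paths))
}

#' Render a plain-text run report
#'
#' Summarises a pipeline run in the layout of a per-disorder overview
#' table (total genes, reliable genes, novel reliable genes), followed by
#' the replication-ratio matrices and the MMRP summary. All values come
#' from synthetic cohorts, and the report says so in its banner. Sections
#' whose stage did not run are marked "not run". The report is a pure
#' function of the stored outputs, so regenerating it from the same object
#' reproduces it exactly.
#'
#' @param x An `xwas_pipeline`.
#' @param quiet Suppress printing to the console.
#' @return The report, a character vector of lines, invisibly.
#' @export
render_report <- function(x, quiet = FALSE) {
  stopifnot(inherits(x, "xwas_pipeline"))
  ln <- c("================ xWAS integration run report ================",
          "  (all values computed on SYNTHETIC cohorts)",
          sprintf("  seed %d | package v%s", x$manifest$seed,
                  x$manifest$version),
          "")
  cfg <- x$config
  ln <- c(ln, sprintf("thresholds: Bonferroni alpha %.3g | HEIDI retain > %.3g | novelty > %.3g | reliable >= %d lines | window %s bp",
                      cfg$bonferroni_alpha, cfg$heidi_retain_threshold,
                      cfg$novelty_threshold, cfg$reliable_min_count,
                      format(cfg$window_bp, scientific = FALSE)), "")
  if (!is.null(x$counts)) {
    per_dis <- x$counts %>%
      group_by(.data$disorder) %>%
      summarise(total = n_distinct(.data$gene_symbol), .groups = "drop")
    rel <- if (!is.null(x$reliable)) {
      x$reliable %>% group_by(.data$disorder) %>%
        summarise(reliable = n_distinct(.data$gene_symbol), .groups = "drop")
    } else NULL
    nov <- if (!is.null(x$novelty) && !is.null(x$reliable)) {
      x$reliable %>%
        inner_join(x$novelty %>% filter(.data$is_novel %in% TRUE) %>%
                     select("gene_symbol"), by = "gene_symbol") %>%
        group_by(.data$disorder) %>%
        summarise(novel = n_distinct(.data$gene_symbol), .groups = "drop")
    } else NULL
    tab <- per_dis
    if (!is.null(rel)) tab <- left_join(tab, rel, by = "disorder")
    if (!is.null(nov)) tab <- left_join(tab, nov, by = "disorder")
    tab <- tab %>%
      mutate(across(dplyr::any_of(c("reliable", "novel")),
                    ~ ifelse(is.na(.x), 0L, .x)))
    ln <- c(ln, "Per-disorder gene overview (total / reliable / novel):")
    for (i in seq_len(nrow(tab))) {
      ln <- c(ln, sprintf("  %-8s total %4d | reliable %4s | novel %4s",
                          tab$disorder[i], tab$total[i],
                          if ("reliable" %in% names(tab)) tab$reliable[i] %||% 0 else "-",
                          if ("novel" %in% names(tab)) tab$novel[i] %||% 0 else "-"))
    }
  } else {
    ln <- c(ln, "Gene overview: not run")
  }
  ln <- c(ln, "")
  if (!is.null(x$metrics$qtl_replication)) {
    ln <- c(ln, "Cross-QTL replication ratios (row set = denominator):",
            utils::capture.output(print(round(x$metrics$qtl_replication$ratios, 3))))
  } else {
    ln <- c(ln, "Replication metrics: not run")
  }
  ln <- c(ln, "")
  if (!is.null(x$metrics$replication_times)) {
    rt <- x$metrics$replication_times
    for (i in seq_len(nrow(rt))) {
      ln <- c(ln, sprintf("Replication times (%s): median novel %.1f vs non-novel %.1f (rank-sum p = %s)",
                          rt$disorder[i], rt$median_novel[i],
                          rt$median_non_novel[i],
                          format(rt$test_p[i], digits = 3)))
    }
    ln <- c(ln, "")
  }
  if (!is.null(x$mmrp)) {
    ln <- c(ln, sprintf("MMRP: %d pattern(s) over %d multi-QTL gene(s)",
                        nrow(x$mmrp), sum(x$mmrp$n_genes)))
    for (i in seq_len(nrow(x$mmrp))) {
      ln <- c(ln, sprintf("  %-8s %-28s %3d gene(s)%s", x$mmrp$disorder[i],
                          x$mmrp$profile[i], x$mmrp$n_genes[i],
                          if (x$mmrp$contains_eqtl[i]) "" else "  [no eQTL]"))
    }
  } else {
    ln <- c(ln, "MMRP: not run")
  }
  ln <- c(ln, "=============================================================")
  if (!quiet) cat(ln, sep = "\n")
  invisible(ln)
}
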