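#' Derive a named random substream seed
#'
#' All randomness in the package flows from one integer seed; each stage
#' derives its own substream seed from the master seed and a stage name, so
#' stages are independently reproducible and reordering stages does not
#' change their draws.
#'
#' @param seed Master integer seed.
#' @param stream Character stage name.
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stream))
  u <- utf8ToInt(stream)
  h <- sum(u * seq_along(u)) %% 999983
  as.integer((abs(as.numeric(seed)) %% 1e6 * 1009 + h * 31 + 17) %% 2147483629)
}

#' Collapse tissue labels to the brain / non-brain dichotomy
#'
#' @param tissue_label Character vector of free-text tissue labels.
#' @param brain_keywords Keywords (matched case-insensitively as substrings)
#'   marking a label as brain-derived.
#' @return Factor-like character vector with values `"brain"` / `"non-brain"`.
#' @export
tissue_group <- function(tissue_label, brain_keywords = DEFAULT_BRAIN_KEYWORDS) {
  lab <- tolower(as.character(tissue_label))
  hit <- Reduce(`|`, lapply(brain_keywords, function(k) grepl(k, lab, fixed = TRUE)),
                accumulate = FALSE)
  ifelse(hit, "brain", "non-brain")
}

# Strand-ambiguous allele pair (A/T or C/G): indistinguishable between
# strands, dropped during harmonization.
is_ambiguous_pair <- function(a1, a2) {
  p <- paste0(toupper(a1), toupper(a2))
  p %in% c("AT", "TA", "CG", "GC")
}

flip_allele <- function(a) {
  chartr("ACGT", "TGCA", toupper(a))
}

# Internal: two-sided normal p from z, kept on log-safe scale.
z_to_p <- function(z) 2 * pnorm(-abs(z))

assert_columns <- function(df, cols, what = "input") {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(miss, collapse = ", ")),
          class = "multixwas_config_error")
  }
  invisible(df)
}
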