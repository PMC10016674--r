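## Gene-set over-representation analysis and between-analysis comparison.
##
## Enrichment of a candidate gene list against term gene-sets (GO molecular
## function, Reactome, CORUM, KEGG style) is tested with the upper-tail
## hypergeometric p-value, the same statistic that underlies standard
## over-representation tools. Multiple testing is corrected per source with
## Benjamini-Hochberg (default) or Bonferroni.

#' Read term gene-sets from a GMT file
#'
#' One term per line: `term_id <TAB> term_name <TAB> gene1 <TAB> gene2 ...`.
#' The source tag is taken from the prefix of the term id (text before the
#' first `:`) when it is one of GO_MF / REAC / CORUM / KEGG, else `"custom"`.
#'
#' @param path Path to a GMT file.
#' @return Tibble with columns `term_id`, `term_name`, `source_tag`, `genes`
#'   (list of character vectors).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) {
    cs_abort("GMT lines need id, name and at least one gene.",
             "cosegscan_format_error")
  }
  term_id <- vapply(parts, `[`, character(1), 1L)
  if (anyDuplicated(term_id)) {
    cs_abort("Duplicate term ids in GMT file.", "cosegscan_format_error")
  }
  prefix <- sub(":.*$", "", term_id)
  tibble(
    term_id = term_id,
    term_name = vapply(parts, `[`, character(1), 2L),
    source_tag = ifelse(prefix %in% c("GO_MF", "REAC", "CORUM", "KEGG"),
                        prefix, "custom"),
    genes = lapply(parts, function(p) unique(p[-(1:2)]))
  )
}

#' Write term gene-sets to a GMT file
#'
#' @param terms Term tibble as returned by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(terms, path) {
  lines <- vapply(seq_len(nrow(terms)), function(i) {
    paste(c(terms$term_id[i], terms$term_name[i], terms$genes[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' For each term, tests whether the query gene list overlaps the term's gene
#' set more than expected by chance within the gene universe:
#' `p = P(X >= k)` for `X ~ Hypergeom(N = |universe|, K = |term ∩ universe|,
#' n = |query|)`, where `k` is the observed overlap.
#'
#' @param query Character vector of candidate gene symbols.
#' @param terms Term tibble ([read_gmt()]).
#' @param universe Gene universe; defaults to all genes annotated to any term
#'   (the annotated-gene convention). Query genes outside the universe are
#'   dropped with a message.
#' @return Tibble sorted by `p_raw`: `term_id`, `term_name`, `source_tag`,
#'   `term_size`, `query_size`, `overlap_size`, `query_overlap` (list),
#'   `p_raw`.
#' @export
hypergeometric_enrichment <- function(query, terms, universe = NULL) {
  if (is.null(universe)) universe <- unique(unlist(terms$genes))
  universe <- unique(universe)
  if (length(universe) == 0L) {
    cs_abort("Empty gene universe.", "cosegscan_input_error")
  }
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    cs_inform(length(outside), " query gene(s) not in the universe dropped: ",
              paste(head(outside, 5), collapse = ", "),
              if (length(outside) > 5) ", ..." else "")
    query <- intersect(query, universe)
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(seq_len(nrow(terms)), function(i) {
    term_genes <- intersect(terms$genes[[i]], universe)
    K <- length(term_genes)
    overlap <- intersect(query, term_genes)
    k <- length(overlap)
    p <- if (k == 0L) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(term_id = terms$term_id[i], term_name = terms$term_name[i],
           source_tag = terms$source_tag[i], term_size = K, query_size = n,
           overlap_size = k, query_overlap = list(sort(overlap)), p_raw = p)
  })
  dplyr::bind_rows(rows) |> dplyr::arrange(.data$p_raw, .data$term_id)
}

#' Adjust enrichment p-values for multiple testing
#'
#' Benjamini-Hochberg step-up (default) or Bonferroni scaling, applied within
#' each source database separately (each source's term family is corrected on
#' its own).
#'
#' @param rows Enrichment tibble from [hypergeometric_enrichment()].
#' @param method `"bh"` or `"bonferroni"`.
#' @return The input with a `p_adj` column added.
#' @export
adjust_pvalues <- function(rows, method = c("bh", "bonferroni")) {
  method <- match.arg(method)
  if (nrow(rows) == 0L) {
    cs_abort("No rows to adjust.", "cosegscan_input_error")
  }
  rows |>
    dplyr::group_by(.data$source_tag) |>
    dplyr::mutate(p_adj = p.adjust(.data$p_raw,
                                   method = if (method == "bh") "BH" else "bonferroni")) |>
    dplyr::ungroup()
}

#' Terms significant in two analyses
#'
#' Reports the terms with raw p-value below `alpha` in both enrichment
#' results, with the number of distinct query genes each analysis contributed
#' to the term.
#'
#' @param rows_a,rows_b Enrichment tibbles for the two analyses.
#' @param alpha Raw p-value threshold (default 0.01).
#' @return Tibble with `term_id`, `term_name`, `source_tag`, `count_a`,
#'   `count_b`, `p_raw_a`, `p_raw_b`.
#' @export
common_terms <- function(rows_a, rows_b, alpha = 0.01) {
  sig_a <- rows_a[rows_a$p_raw < alpha, , drop = FALSE]
  sig_b <- rows_b[rows_b$p_raw < alpha, , drop = FALSE]
  joined <- dplyr::inner_join(
    dplyr::select(sig_a, "term_id", "term_name", "source_tag",
                  count_a = "overlap_size", p_raw_a = "p_raw"),
    dplyr::select(sig_b, "term_id", count_b = "overlap_size", p_raw_b = "p_raw"),
    by = "term_id"
  )
  dplyr::arrange(joined, .data$term_id)
}

#' One-sided two-sample proportion test with continuity correction
#'
#' Tests whether the second proportion exceeds the first
#' (`H1: k_b/n_b > k_a/n_a`) using the pooled z statistic with Yates
#' continuity correction `cc = 0.5 * (1/n_a + 1/n_b)`:
#' `z = (p_b - p_a - cc) / sqrt(p(1 - p)(1/n_a + 1/n_b))` with `p` the pooled
#' proportion, and the p-value from the standard normal upper tail. A
#' degenerate pooled proportion (0 or 1) returns 1.
#'
#' @param k_a,n_a Successes and trials in the first sample.
#' @param k_b,n_b Successes and trials in the second sample.
#' @return Numeric vector of one-sided p-values.
#' @export
proportion_increase_test <- function(k_a, n_a, k_b, n_b) {
  n <- max(length(k_a), length(n_a), length(k_b), length(n_b))
  k_a <- rep_len(k_a, n); n_a <- rep_len(n_a, n)
  k_b <- rep_len(k_b, n); n_b <- rep_len(n_b, n)
  if (any(n_a <= 0 | n_b <= 0) || any(k_a > n_a | k_b > n_b) ||
      any(c(k_a, k_b) < 0)) {
    cs_abort("Need 0 <= k <= n and n > 0 on both sides.",
             "cosegscan_input_error")
  }
  p_a <- k_a / n_a
  p_b <- k_b / n_b
  pooled <- (k_a + k_b) / (n_a + n_b)
  cc <- 0.5 * (1 / n_a + 1 / n_b)
  se <- sqrt(pooled * (1 - pooled) * (1 / n_a + 1 / n_b))
  z <- (p_b - p_a - cc) / se
  out <- ifelse(pooled <= 0 | pooled >= 1, 1, pnorm(z, lower.tail = FALSE))
  as.numeric(out)
}
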