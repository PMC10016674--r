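## Descriptive cohort and variant summaries, and gene-list cross-referencing
## against external (e.g. transcriptomic) gene lists.

#' Summarize a family cohort
#'
#' Participant counts, sex and bilateral-disease percentages (rounded to the
#' nearest integer), and the median and range of age at diagnosis (or first
#' surgery where diagnosis age is unavailable). Participants without a
#' recorded age are excluded from the median and range (logged).
#'
#' @param cohort Family cohort tibble ([read_family_table()]).
#' @return One-row tibble: `n_participants`, `n_families`, `n_female`,
#'   `pct_female`, `n_bilateral`, `pct_bilateral`, `median_age`, `age_min`,
#'   `age_max`.
#' @export
summarize_cohort <- function(cohort) {
  if (nrow(cohort) == 0L) {
    cs_abort("Cohort is empty.", "cosegscan_input_error")
  }
  ages <- cohort$age
  if (anyNA(ages)) {
    cs_inform(sum(is.na(ages)), " participant(s) without recorded age excluded from the median.")
    ages <- ages[!is.na(ages)]
  }
  n <- nrow(cohort)
  tibble(
    n_participants = n,
    n_families = dplyr::n_distinct(cohort$family_id),
    n_female = sum(cohort$sex == "female", na.rm = TRUE),
    pct_female = as.integer(round_half_up(100 * sum(cohort$sex == "female", na.rm = TRUE) / n)),
    n_bilateral = sum(cohort$bilateral, na.rm = TRUE),
    pct_bilateral = as.integer(round_half_up(100 * sum(cohort$bilateral, na.rm = TRUE) / n)),
    median_age = median(ages),
    age_min = min(ages),
    age_max = max(ages)
  )
}

#' Summarize a set of prioritized variants
#'
#' Censoring-aware allele-frequency summaries and conservation counts for a
#' table of candidate variants: the gnomAD popmax median and IQR, the TOPMed
#' median (possibly censored), the number of variants with conservation
#' strictly above `conservation_threshold`, and the maximum population
#' frequency as a percentage (from the largest uncensored gnomAD popmax
#' frequency; when every frequency is censored, the largest bound is reported
#' and flagged as a bound).
#'
#' @param variants A variant tibble.
#' @param conservation_threshold Strict lower bound for "highly conserved"
#'   (default 0.9).
#' @return One-row tibble: `n_variants`, `n_genes`, `median_gnomad_af`,
#'   `median_gnomad_censored`, `iqr_gnomad_af`, `iqr_gnomad_is_bound`,
#'   `median_topmed_af`, `median_topmed_censored`, `n_conserved_high`,
#'   `max_af_percent`, `max_af_is_bound`.
#' @export
summarize_variants <- function(variants, conservation_threshold = 0.9) {
  if (nrow(variants) == 0L) {
    cs_abort("No variants to summarize.", "cosegscan_input_error")
  }
  med_g <- censored_median(variants$gnomad_popmax_af, variants$gnomad_popmax_censored)
  iqr_g <- censored_iqr(variants$gnomad_popmax_af, variants$gnomad_popmax_censored)
  med_t <- censored_median(variants$topmed_af, variants$topmed_censored)
  unc <- !isTRUE_v(variants$gnomad_popmax_censored) & !is.na(variants$gnomad_popmax_af)
  if (any(unc)) {
    max_af <- max(variants$gnomad_popmax_af[unc])
    max_bound <- FALSE
  } else {
    max_af <- max(variants$gnomad_popmax_af, na.rm = TRUE)
    max_bound <- TRUE
    cs_inform("All frequencies censored; maximum reported as an upper bound.")
  }
  tibble(
    n_variants = nrow(variants),
    n_genes = dplyr::n_distinct(variants$gene[!is.na(variants$gene)]),
    median_gnomad_af = med_g$value, median_gnomad_censored = med_g$censored,
    iqr_gnomad_af = iqr_g$iqr, iqr_gnomad_is_bound = iqr_g$is_bound,
    median_topmed_af = med_t$value, median_topmed_censored = med_t$censored,
    n_conserved_high = sum(variants$phastcons7 > conservation_threshold, na.rm = TRUE),
    max_af_percent = 100 * max_af,
    max_af_is_bound = max_bound
  )
}

#' Cross-reference candidate genes against external gene lists
#'
#' Intersects a candidate gene set with each named external list (e.g. genes
#' down-regulated in published expression studies) and with all lists jointly.
#'
#' @param candidates Character vector of candidate gene symbols.
#' @param external_lists Named list of character vectors.
#' @return List with `per_list` (named list of intersections with each
#'   external list) and `all` (genes present in the candidates and every
#'   external list).
#' @export
crossref_gene_lists <- function(candidates, external_lists) {
  candidates <- unique(candidates)
  per_list <- lapply(external_lists, function(l) sort(intersect(candidates, l)))
  all_int <- Reduce(intersect, external_lists, accumulate = FALSE)
  list(per_list = per_list, all = sort(intersect(candidates, all_int)))
}
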