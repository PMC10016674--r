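## Gene-based collapsing mutation-burden test against public controls.
##
## Qualifying variants (the cascade survivors) are collapsed per gene.
## Case carriers are counted directly from genotypes: a sample carries the
## gene under the dominant model with >= 1 qualifying allele and under the
## recessive model with >= 2 qualifying alleles (a homozygote counts two; two
## heterozygous sites in the same gene count two — an unphased putative
## compound heterozygote). Control carriers are *expected* counts derived
## from public aggregate allele frequencies under site independence and
## Hardy-Weinberg, rounded to integers for the exact test.

#' Control site depth QC
#'
#' A control site is usable when a sufficient fraction of control samples had
#' read depth above the depth cutoff at that position (the fraction is
#' supplied precomputed in `depth_pass_fraction`). The threshold is
#' inclusive: exactly `min_depth_fraction` passes.
#'
#' @param controls Tibble of control site records with a
#'   `depth_pass_fraction` column.
#' @param min_depth_fraction Required fraction (default 0.90).
#' @return Logical vector, `TRUE` for sites passing QC.
#' @export
site_qc <- function(controls, min_depth_fraction = 0.90) {
  controls$depth_pass_fraction >= min_depth_fraction
}

#' Case carrier counts per gene
#'
#' @param case_variants Qualifying variant tibble for the whole case cohort,
#'   with `sample_id`, `gene` and `genotype` columns.
#' @return Tibble with one row per gene: `gene`, `n_case_carriers_dom`
#'   (samples with >= 1 qualifying allele), `n_case_carriers_rec` (samples
#'   with >= 2 qualifying alleles), `variant_count` (distinct qualifying
#'   variants in the gene across the cohort).
#' @export
case_carrier_counts <- function(case_variants) {
  if (nrow(case_variants) == 0L) {
    return(tibble(gene = character(), n_case_carriers_dom = integer(),
                  n_case_carriers_rec = integer(), variant_count = integer()))
  }
  case_variants |>
    dplyr::mutate(alleles = ifelse(.data$genotype == "hom_alt", 2L, 1L)) |>
    dplyr::group_by(.data$gene, .data$sample_id) |>
    dplyr::summarise(alleles = sum(.data$alleles),
                     n_var = dplyr::n_distinct(variant_key(.data$chrom, .data$pos,
                                                           .data$ref, .data$alt)),
                     .groups = "drop_last") |>
    dplyr::summarise(
      n_case_carriers_dom = sum(.data$alleles >= 1L),
      n_case_carriers_rec = sum(.data$alleles >= 2L),
      variant_count = sum(.data$n_var),
      .groups = "drop"
    )
}

#' Expected control carrier counts per gene
#'
#' Collapses per-site control allele frequencies into expected carrier counts
#' under site independence: dominant
#' `round(n_controls * (1 - prod(1 - af_i)))`; recessive
#' `round(n_controls * (sum af_i)^2)`, capped at `n_controls` (a
#' Hardy-Weinberg approximation for homozygous or compound-heterozygous
#' genotypes). Sites with `control_an = 0` are skipped (logged).
#'
#' @param controls Tibble of QC-passed control site records with `gene`,
#'   `control_ac`, `control_an` columns.
#' @param n_controls Control cohort size (number of individuals).
#' @return Tibble with `gene`, `n_control_carriers_dom`,
#'   `n_control_carriers_rec`.
#' @export
control_carrier_counts <- function(controls, n_controls) {
  zero_an <- controls$control_an == 0
  if (any(zero_an)) {
    cs_inform(sum(zero_an), " control site(s) with AN = 0 skipped.")
    controls <- controls[!zero_an, , drop = FALSE]
  }
  if (nrow(controls) == 0L) {
    return(tibble(gene = character(), n_control_carriers_dom = integer(),
                  n_control_carriers_rec = integer()))
  }
  controls |>
    dplyr::mutate(af = .data$control_ac / .data$control_an) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_control_carriers_dom =
        as.integer(round_half_up(n_controls * (1 - prod(1 - .data$af)))),
      n_control_carriers_rec =
        as.integer(pmin(n_controls, round_half_up(n_controls * sum(.data$af)^2))),
      .groups = "drop"
    )
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value for the table `[[a, b], [c, d]]` (cases:
#' carrier/non-carrier; controls: carrier/non-carrier): the sum of
#' hypergeometric probabilities, over all tables with the observed margins,
#' that do not exceed the observed table's probability (with relative
#' numerical slack 1e-7, the standard convention). Vectorized over tables.
#' A table with an all-zero margin returns 1.
#'
#' @param a,b,c,d Nonnegative integer vectors (recycled to common length).
#' @return Numeric vector of p-values in (0, 1].
#' @examples
#' fisher_two_sided(2, 0, 0, 2)  # 1/3
#' @export
fisher_two_sided <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  if (any(c(a, b, c, d) < 0) || anyNA(c(a, b, c, d))) {
    cs_abort("Table counts must be nonnegative.", "cosegscan_input_error")
  }
  vapply(seq_len(n), function(i) {
    m <- a[i] + c[i]          # first-column margin (carriers)
    nn <- b[i] + d[i]         # second-column margin
    k <- a[i] + b[i]          # first-row margin (cases)
    ## a degenerate (zero) margin admits a single table and yields p = 1
    ## through the same formula, so no special-casing is needed
    support <- max(0, k - nn):min(k, m)
    probs <- dhyper(support, m, nn, k)
    p_obs <- dhyper(a[i], m, nn, k)
    min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Gene-based burden table
#'
#' Runs the dominant and recessive collapsing burden test for every gene with
#' at least one qualifying case variant: case carrier counts from genotypes,
#' expected control carrier counts from QC-passed control allele frequencies,
#' and two-sided exact p-values for each model. A Bonferroni-adjusted column
#' is included alongside the raw p-values.
#'
#' @param case_variants Qualifying case variant tibble (`sample_id`, `gene`,
#'   `genotype`, coordinates).
#' @param n_cases Number of case individuals.
#' @param controls Control site tibble (`gene`, `control_ac`, `control_an`,
#'   `depth_pass_fraction`).
#' @param n_controls Number of control individuals.
#' @param min_depth_fraction Control site QC threshold (default 0.90).
#' @return A tibble of class `coseg_burden`, one row per gene, sorted by
#'   `p_dom` (ties broken by gene symbol).
#' @export
burden_table <- function(case_variants, n_cases, controls, n_controls,
                         min_depth_fraction = 0.90) {
  if (nrow(case_variants) == 0L) {
    out <- tibble(gene = character(), n_case_carriers_dom = integer(),
                  n_case_carriers_rec = integer(), variant_count = integer(),
                  n_control_carriers_dom = integer(),
                  n_control_carriers_rec = integer(),
                  n_cases = integer(), n_controls = integer(),
                  p_dom = numeric(), p_rec = numeric(),
                  p_dom_bonferroni = numeric(), p_rec_bonferroni = numeric())
    class(out) <- c("coseg_burden", class(out))
    return(out)
  }
  ctl <- controls[site_qc(controls, min_depth_fraction), , drop = FALSE]
  cases <- case_carrier_counts(case_variants)
  ctl_counts <- control_carrier_counts(ctl, n_controls)
  out <- dplyr::left_join(cases, ctl_counts, by = "gene") |>
    dplyr::mutate(
      n_control_carriers_dom = .data$n_control_carriers_dom %|na|% 0L,
      n_control_carriers_rec = .data$n_control_carriers_rec %|na|% 0L,
      n_cases = as.integer(n_cases),
      n_controls = as.integer(n_controls),
      p_dom = fisher_two_sided(.data$n_case_carriers_dom,
                               n_cases - .data$n_case_carriers_dom,
                               .data$n_control_carriers_dom,
                               n_controls - .data$n_control_carriers_dom),
      p_rec = fisher_two_sided(.data$n_case_carriers_rec,
                               n_cases - .data$n_case_carriers_rec,
                               .data$n_control_carriers_rec,
                               n_controls - .data$n_control_carriers_rec),
      p_dom_bonferroni = pmin(1, .data$p_dom * dplyr::n()),
      p_rec_bonferroni = pmin(1, .data$p_rec * dplyr::n())
    ) |>
    dplyr::arrange(.data$p_dom, .data$gene)
  class(out) <- c("coseg_burden", class(out))
  out
}
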