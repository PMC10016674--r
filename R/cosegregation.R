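## Within-family co-segregation and cross-family gene overlap.
##
## A co-segregating variant is one carried by every sequenced affected member
## of a family. Members are intersected sequentially (fold-left) in the order
## given by the family table; SNVs match exactly and indels by reciprocal
## fractional overlap against the running representative, which is always the
## first-listed member's variant. Cross-family overlap is at gene level:
## families can (and in practice do) carry different alleles of the same gene.

#' Variants shared by all members of a family
#'
#' Sequentially intersects the members' variant sets. The returned rows carry
#' the first-listed member's annotations (deterministic provenance).
#'
#' @param member_callsets List (length >= 2) of variant tibbles, one per
#'   affected member, in family-table order.
#' @param min_indel_frac Reciprocal overlap fraction for indel identity.
#' @return The shared variant tibble, with attribute `n_members`.
#' @export
shared_within_family <- function(member_callsets, min_indel_frac = 0.10) {
  if (!is.list(member_callsets) || length(member_callsets) < 2L) {
    cs_abort("shared_within_family needs >= 2 member callsets.",
             "cosegscan_input_error")
  }
  shared <- member_callsets[[1]]
  for (m in member_callsets[-1]) {
    shared_snv <- shared[shared$vclass == "snv", , drop = FALSE]
    m_snv <- m[m$vclass == "snv", , drop = FALSE]
    keep_snv <- variant_key(shared_snv$chrom, shared_snv$pos,
                            shared_snv$ref, shared_snv$alt) %in%
      variant_key(m_snv$chrom, m_snv$pos, m_snv$ref, m_snv$alt)
    shared_ind <- shared[shared$vclass != "snv", , drop = FALSE]
    m_ind <- m[m$vclass != "snv", , drop = FALSE]
    pairs <- indel_matches(shared_ind, m_ind, min_indel_frac)
    keep_ind <- seq_len(nrow(shared_ind)) %in% pairs$ia
    shared <- dplyr::bind_rows(shared_snv[keep_snv, , drop = FALSE],
                               shared_ind[keep_ind, , drop = FALSE])
  }
  shared <- shared[order(shared$chrom, shared$pos, shared$ref, shared$alt), ,
                   drop = FALSE]
  attr(shared, "n_members") <- length(member_callsets)
  shared
}

#' Shared variant sets for every family in a cohort
#'
#' @param callsets A variant tibble covering all samples (e.g. per-sample
#'   consensus sets bound together), with a `sample_id` column.
#' @param families Family cohort tibble ([read_family_table()]); member order
#'   within each family follows the table's row order.
#' @param min_indel_frac Reciprocal overlap fraction for indel identity.
#' @return A variant tibble with a `family_id` column, containing each
#'   family's shared set (first-listed member's annotations).
#' @export
family_shared_sets <- function(callsets, families, min_indel_frac = 0.10) {
  validate_family_cohort(families)
  fam_ids <- unique(families$family_id)
  out <- lapply(fam_ids, function(f) {
    members <- families$sample_id[families$family_id == f]
    sets <- lapply(members, function(s) {
      callsets[callsets$sample_id %in% s, , drop = FALSE]
    })
    shared <- shared_within_family(sets, min_indel_frac)
    if (nrow(shared) > 0L) shared$family_id <- f
    shared
  })
  dplyr::bind_rows(out)
}

#' Genes with qualifying variants in two or more families
#'
#' Groups surviving co-segregating variants by gene symbol and reports genes
#' whose variants occur in at least `min_families` distinct families. The
#' overlap is at locus/gene level: the per-family alleles need not be
#' identical.
#'
#' @param family_variants A variant tibble with `family_id` and `gene`
#'   columns (e.g. the cascade survivors of each family's shared set).
#' @param min_families Minimum number of distinct families (default 2).
#' @return Tibble sorted by gene symbol, with columns `gene`, `n_families`,
#'   `families` (list of family ids) and `variants` (list of the qualifying
#'   variant rows).
#' @export
genes_in_multiple_families <- function(family_variants, min_families = 2L) {
  no_gene <- is.na(family_variants$gene)
  if (any(no_gene)) {
    cs_inform(sum(no_gene), " variant(s) without a gene symbol skipped.")
    family_variants <- family_variants[!no_gene, , drop = FALSE]
  }
  if (nrow(family_variants) == 0L) {
    return(tibble(gene = character(), n_families = integer(),
                  families = list(), variants = list()))
  }
  out <- family_variants |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_families = dplyr::n_distinct(.data$family_id),
      families = list(sort(unique(.data$family_id))),
      variants = list(dplyr::pick(dplyr::everything())),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_families >= min_families) |>
    dplyr::arrange(.data$gene)
  out
}
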