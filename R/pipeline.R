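## End-to-end convenience wrapper: hard filter -> dual-caller consensus ->
## within-family intersection -> filtering cascade -> multi-family genes.

#' Run the full family prioritization pipeline
#'
#' For each sample, both callers' callsets are hard-filtered and intersected
#' into a consensus set; each family's members are then sequentially
#' intersected; the filtering cascade is applied to the family-shared
#' variants; and genes qualifying in `min_families` or more families are
#' reported. The per-variant cascade predicates commute with the family
#' intersection, so applying the cascade after the intersection (as here)
#' selects the same variants while keeping the ledger on the co-segregating
#' set.
#'
#' @param callsets Tibble of all calls with `sample_id` and `caller_tag`
#'   (exactly two tags per sample).
#' @param families Family cohort tibble.
#' @param min_qual,min_depth Hard-filter thresholds.
#' @param min_indel_frac Reciprocal overlap fraction for indel identity.
#' @param af_max,pc_min,conservation_missing,benign_rule Cascade parameters,
#'   see [apply_cascade()].
#' @param min_families Multi-family gene threshold.
#' @return List with `consensus` (per-sample consensus calls),
#'   `family_shared` (per-family shared variants), `cascade`
#'   (`coseg_cascade` over the shared variants) and `multi_family_genes`.
#' @export
run_family_pipeline <- function(callsets, families,
                                min_qual = 30, min_depth = 10,
                                min_indel_frac = 0.10,
                                af_max = 0.01, pc_min = 0.1,
                                conservation_missing = "pass",
                                benign_rule = "both",
                                min_families = 2L) {
  validate_family_cohort(families)
  tags <- unique(callsets$caller_tag)
  if (length(tags) != 2L) {
    cs_abort("Expected exactly two caller tags.", "cosegscan_input_error")
  }
  consensus <- dplyr::bind_rows(lapply(unique(callsets$sample_id), function(s) {
    a <- hard_filter(callsets[callsets$sample_id == s &
                                callsets$caller_tag == tags[1], , drop = FALSE],
                     min_qual, min_depth)
    b <- hard_filter(callsets[callsets$sample_id == s &
                                callsets$caller_tag == tags[2], , drop = FALSE],
                     min_qual, min_depth)
    intersect_callsets(a, b, min_indel_frac)
  }))
  shared <- family_shared_sets(consensus, families, min_indel_frac)
  cascade <- apply_cascade(shared, af_max = af_max, pc_min = pc_min,
                           conservation_missing = conservation_missing,
                           benign_rule = benign_rule)
  genes <- genes_in_multiple_families(cascade$surviving, min_families)
  list(consensus = consensus, family_shared = shared,
       cascade = cascade, multi_family_genes = genes)
}
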