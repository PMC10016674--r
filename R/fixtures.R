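## Packaged worked-example data.

#' Packaged participant table
#'
#' The 21-participant, ten-family cohort table from the motivating familial
#' cholesteatoma exome study (ages at diagnosis, or first surgery where
#' flagged; bilateral disease; sex; relationship to the index case).
#'
#' @return A family cohort tibble.
#' @export
participants_fixture <- function() {
  read_family_table(system.file("extdata", "cholesteatoma_participants.tsv",
                                package = "cosegscan", mustWork = TRUE))
}

#' Packaged multi-family candidate variant table
#'
#' The thirteen co-segregating candidate variants (in six genes hit in two or
#' more families) from the motivating study, with their published population
#' allele frequencies (censored `"<0.001"` entries kept censored),
#' SIFT/PolyPhen labels and conservation scores. Genomic coordinates are
#' synthetic anchors — the published table identifies variants by rsID and
#' HGVS notation only — and carry no analytic meaning beyond gene-level
#' identity.
#'
#' @return A variant tibble with a `family_id` column.
#' @export
candidate_variants_fixture <- function() {
  read_variant_table(system.file("extdata", "multifamily_candidate_variants.tsv",
                                 package = "cosegscan", mustWork = TRUE))
}
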