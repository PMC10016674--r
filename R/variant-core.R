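## Core variant types and tabular readers/writers.
##
## Variants live in plain tibbles with a fixed column vocabulary so every
## stage of the pipeline composes with dplyr verbs. A "callset" is a variant
## tibble carrying, in addition, sample_id / caller_tag / genotype / depth.

## canonical annotation columns for a variant tibble
cs_variant_cols <- c(
  "chrom", "pos", "ref", "alt", "vclass", "qual", "gene", "rsid",
  "gnomad_popmax_af", "gnomad_popmax_censored",
  "topmed_af", "topmed_censored", "nfe_af", "nfe_censored",
  "phastcons7", "consequence", "impact_tier", "sift_label", "polyphen_label"
)

#' Classify a variant by its alleles
#'
#' The class is a pure function of the REF/ALT pair: `snv` for single-base
#' substitutions; `insertion` when ALT is longer and REF is its prefix;
#' `deletion` when REF is longer and ALT is its prefix; `complex` otherwise.
#'
#' @param ref,alt Character vectors of alleles over the alphabet `ACGTN`.
#' @return Character vector over `{snv, insertion, deletion, complex}`.
#' @examples
#' classify_variant("A", "G")     # snv
#' classify_variant("A", "ATT")   # insertion
#' classify_variant("ATTT", "A")  # deletion
#' classify_variant("AT", "GC")   # complex
#' @export
classify_variant <- function(ref, alt) {
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  ok <- nzchar(ref) & nzchar(alt) &
    grepl("^[ACGTN]+$", ref) & grepl("^[ACGTN]+$", alt)
  if (!all(ok)) {
    bad <- paste0(ref[!ok], ">", alt[!ok])
    cs_abort(
      paste0("Alleles must be nonempty strings over {A,C,G,T,N}: ",
             paste(unique(bad), collapse = ", ")),
      "cosegscan_format_error"
    )
  }
  lr <- nchar(ref)
  la <- nchar(alt)
  dplyr::case_when(
    lr == 1L & la == 1L ~ "snv",
    la > lr & startsWith(alt, ref) ~ "insertion",
    lr > la & startsWith(ref, alt) ~ "deletion",
    TRUE ~ "complex"
  )
}

#' Build a variant tibble
#'
#' Light constructor used by tests and the synthetic-cohort generator; fills
#' every canonical annotation column, derives `vclass` from the alleles and
#' validates the basic invariants (positive positions, frequencies and
#' conservation scores in [0, 1], no symbolic alleles).
#'
#' @param chrom,pos,ref,alt Required identity fields (`pos` is the 1-based
#'   VCF position).
#' @param ... Any of the annotation columns: `qual`, `gene`, `rsid`,
#'   `gnomad_popmax_af`, `gnomad_popmax_censored`, `topmed_af`,
#'   `topmed_censored`, `nfe_af`, `nfe_censored`, `phastcons7`,
#'   `consequence`, `impact_tier`, `sift_label`, `polyphen_label`, and the
#'   callset columns `sample_id`, `caller_tag`, `genotype`, `depth`.
#' @return A variant tibble.
#' @export
variant_tibble <- function(chrom, pos, ref, alt, ...) {
  out <- tibble(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = toupper(as.character(ref)), alt = toupper(as.character(alt)), ...
  )
  out$vclass <- classify_variant(out$ref, out$alt)
  for (col in setdiff(cs_variant_cols, names(out))) {
    out[[col]] <- switch(
      col,
      qual = NA_real_, phastcons7 = NA_real_,
      gnomad_popmax_af = NA_real_, topmed_af = NA_real_, nfe_af = NA_real_,
      gnomad_popmax_censored = NA, topmed_censored = NA, nfe_censored = NA,
      NA_character_
    )
  }
  ## frequencies supplied as plain numbers are uncensored unless flagged
  for (stem in c("gnomad_popmax", "topmed", "nfe")) {
    vcol <- paste0(stem, "_af"); ccol <- paste0(stem, "_censored")
    out[[ccol]][!is.na(out[[vcol]]) & is.na(out[[ccol]])] <- FALSE
  }
  validate_variants(out)
  out[union(intersect(cs_variant_cols, names(out)), names(out))]
}

#' Validate a variant tibble's invariants
#'
#' @param variants A variant tibble.
#' @return The input, invisibly, after checking positions, allele alphabets,
#'   `vclass` consistency, and the [0, 1] range of frequency/conservation
#'   annotations.
#' @export
validate_variants <- function(variants) {
  stopifnot(is.data.frame(variants))
  need <- c("chrom", "pos", "ref", "alt")
  missing <- setdiff(need, names(variants))
  if (length(missing)) {
    cs_abort(paste0("Missing variant columns: ", paste(missing, collapse = ", ")),
             "cosegscan_format_error")
  }
  if (nrow(variants) == 0L) return(invisible(variants))
  if (any(variants$pos < 1L)) {
    cs_abort("Positions must be >= 1.", "cosegscan_format_error")
  }
  vc <- classify_variant(variants$ref, variants$alt)
  if (!is.null(variants$vclass) && !all(is.na(variants$vclass)) &&
      any(variants$vclass != vc, na.rm = TRUE)) {
    cs_abort("`vclass` inconsistent with (ref, alt).", "cosegscan_format_error")
  }
  for (col in c("gnomad_popmax_af", "topmed_af", "nfe_af", "phastcons7")) {
    if (col %in% names(variants)) {
      x <- variants[[col]]
      if (any(x < 0 | x > 1, na.rm = TRUE)) {
        cs_abort(paste0("`", col, "` must lie in [0, 1]."), "cosegscan_format_error")
      }
    }
  }
  if ("genotype" %in% names(variants)) {
    bad <- setdiff(unique(variants$genotype), c("het", "hom_alt", NA))
    if (length(bad)) {
      cs_abort(paste0("Unknown genotype value(s): ", paste(bad, collapse = ", ")),
               "cosegscan_format_error")
    }
  }
  invisible(variants)
}

#' Read a family / phenotype table
#'
#' Tab-separated, headered table with columns `family_id`, `sample_id`,
#' `age`, `age_is_surgery_proxy`, `bilateral`, `sex`, `relationship`
#' (mirroring the study's participant table). Validates that every sample
#' appears once and that each family has at least two sequenced members.
#'
#' @param path Path to a TSV file.
#' @return A tibble, one row per participant.
#' @export
read_family_table <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  need <- c("family_id", "sample_id", "age", "bilateral", "sex")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    cs_abort(paste0("Family table lacks column(s): ", paste(missing, collapse = ", ")),
             "cosegscan_format_error")
  }
  out <- tibble(
    family_id = raw$family_id,
    sample_id = raw$sample_id,
    age = suppressWarnings(as.numeric(raw$age)),
    age_is_surgery_proxy =
      if ("age_is_surgery_proxy" %in% names(raw)) parse_yn(raw$age_is_surgery_proxy) else NA,
    bilateral = parse_yn(raw$bilateral),
    sex = tolower(raw$sex),
    relationship = if ("relationship" %in% names(raw)) raw$relationship else NA_character_
  )
  validate_family_cohort(out)
  out
}

parse_yn <- function(x) {
  x <- tolower(as.character(x))
  out <- dplyr::case_when(
    x %in% c("y", "yes", "true", "1") ~ TRUE,
    x %in% c("n", "no", "false", "0") ~ FALSE,
    TRUE ~ NA
  )
  out
}

#' Validate a family cohort table
#'
#' @param cohort Tibble with `family_id` and `sample_id` columns.
#' @return The input, invisibly.
#' @export
validate_family_cohort <- function(cohort) {
  if (anyDuplicated(cohort$sample_id)) {
    cs_abort("Duplicate sample_id in family table.", "cosegscan_format_error")
  }
  sizes <- table(cohort$family_id)
  if (any(sizes < 2L)) {
    small <- names(sizes)[sizes < 2L]
    cs_abort(paste0("Every family needs >= 2 members; offending: ",
                    paste(small, collapse = ", ")),
             "cosegscan_format_error")
  }
  bad_sex <- setdiff(unique(cohort$sex), c("female", "male", NA))
  if (length(bad_sex)) {
    cs_abort(paste0("Unknown sex value(s): ", paste(bad_sex, collapse = ", ")),
             "cosegscan_format_error")
  }
  invisible(cohort)
}

#' Write a family table
#'
#' @param cohort A family cohort tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_family_table <- function(cohort, path) {
  out <- cohort
  out$bilateral <- ifelse(out$bilateral, "Y", "N")
  if ("age_is_surgery_proxy" %in% names(out)) {
    out$age_is_surgery_proxy <- ifelse(isTRUE_v(out$age_is_surgery_proxy), "Y", "N")
  }
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write a variant table
#'
#' Tab-separated export of a variant tibble. Censored frequencies are encoded
#' with the `"<bound"` convention so the table round-trips through
#' [read_variant_table()] exactly.
#'
#' @param variants A variant tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  out <- variants
  for (stem in c("gnomad_popmax", "topmed", "nfe")) {
    vcol <- paste0(stem, "_af"); ccol <- paste0(stem, "_censored")
    if (vcol %in% names(out)) {
      out[[vcol]] <- format_censored(out[[vcol]],
                                     out[[ccol]] %||% rep(FALSE, nrow(out)))
      out[[ccol]] <- NULL
    }
  }
  readr::write_tsv(out, path, na = ".")
  invisible(path)
}

#' Read a variant table written by [write_variant_table()]
#'
#' @param path Path to a TSV file.
#' @return A variant tibble.
#' @export
read_variant_table <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, na = ".",
                         col_types = readr::cols(.default = readr::col_character()))
  out <- raw
  out$pos <- as.integer(raw$pos)
  for (col in c("qual", "phastcons7")) {
    if (col %in% names(out)) out[[col]] <- as.numeric(raw[[col]])
  }
  if ("depth" %in% names(out)) out$depth <- as.integer(raw$depth)
  for (stem in c("gnomad_popmax", "topmed", "nfe")) {
    vcol <- paste0(stem, "_af")
    if (vcol %in% names(out)) {
      parsed <- parse_censored(raw[[vcol]])
      out[[vcol]] <- parsed$value
      out[[paste0(stem, "_censored")]] <- parsed$censored
    }
  }
  out <- as_tibble(out)
  if (!"vclass" %in% names(out)) out$vclass <- classify_variant(out$ref, out$alt)
  validate_variants(out)
  out[union(intersect(c(cs_variant_cols, "sample_id", "caller_tag", "genotype", "depth"),
                      names(out)), names(out))]
}
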