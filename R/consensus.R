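## Dual-caller consensus.
##
## High-confidence variants are those detected by both callers for a sample.
## SNVs match on exact (chrom, pos, ref, alt) identity; indels (and complex
## variants) match when their genomic intervals reciprocally overlap by more
## than a configurable fraction (default 10%, strict inequality), mirroring a
## bedtools-style fractional overlap rule made symmetric.

#' Hard-filter a callset on call quality and depth
#'
#' @param callset A callset tibble with `qual` and `depth` columns.
#' @param min_qual Minimum caller quality score (default 30).
#' @param min_depth Minimum read depth (default 10).
#' @return The retained rows. Variants with absent quality or depth fail the
#'   filter; the number removed is reported via a message.
#' @export
hard_filter <- function(callset, min_qual = 30, min_depth = 10) {
  keep <- isTRUE_v(callset$qual >= min_qual) & isTRUE_v(callset$depth >= min_depth)
  n_absent <- sum(is.na(callset$qual) | is.na(callset$depth))
  if (n_absent > 0L) {
    cs_inform(n_absent, " variant(s) with absent qual/depth failed the hard filter.")
  }
  callset[keep, , drop = FALSE]
}

#' Exact SNV identity
#'
#' @param a,b One-row variant tibbles (or lists) with `chrom`, `pos`, `ref`,
#'   `alt`, both of class `snv`.
#' @return `TRUE` iff the two SNVs share (chrom, pos, ref, alt).
#' @export
snv_identical <- function(a, b) {
  if (!identical(a$vclass, "snv") || !identical(b$vclass, "snv")) {
    cs_abort("snv_identical is defined for SNVs only.", "cosegscan_contract_error")
  }
  identical(a$chrom, b$chrom) && identical(as.integer(a$pos), as.integer(b$pos)) &&
    identical(a$ref, b$ref) && identical(a$alt, b$alt)
}

#' Genomic interval of an indel or complex variant
#'
#' Converts the 1-based VCF representation to 0-based half-open coordinates:
#' a deletion or complex variant spans `[pos - 1, pos - 1 + nchar(ref))`; an
#' insertion is anchored to the single base before the inserted sequence,
#' `[pos - 1, pos)`.
#'
#' @param variants A variant tibble with no SNV rows.
#' @return Tibble with columns `start` and `end` (0-based half-open).
#' @export
indel_interval <- function(variants) {
  if (any(variants$vclass == "snv")) {
    cs_abort("indel_interval is defined for non-SNV variants only.",
             "cosegscan_contract_error")
  }
  start <- variants$pos - 1L
  end <- ifelse(variants$vclass == "insertion",
                start + 1L, start + nchar(variants$ref))
  tibble(start = as.integer(start), end = as.integer(end))
}

#' Fractional-overlap indel identity
#'
#' Two indels on the same chromosome are identical when their intervals
#' overlap by strictly more than `min_frac` of *both* interval lengths
#' (reciprocal rule; a fraction of exactly `min_frac` does not match).
#'
#' @param a,b One-row variant tibbles, both non-SNV, same chromosome.
#' @param min_frac Required overlap fraction, in (0, 1] (default 0.10).
#' @return Logical flag.
#' @export
indel_identical <- function(a, b, min_frac = 0.10) {
  check_min_frac(min_frac)
  if (!identical(a$chrom, b$chrom)) {
    cs_abort("indel_identical requires variants on the same chromosome.",
             "cosegscan_contract_error")
  }
  ia <- indel_interval(as_tibble(a))
  ib <- indel_interval(as_tibble(b))
  ov <- overlap_len(ia$start, ia$end, ib$start, ib$end)
  ov / (ia$end - ia$start) > min_frac && ov / (ib$end - ib$start) > min_frac
}

check_min_frac <- function(min_frac) {
  if (!is.numeric(min_frac) || length(min_frac) != 1L ||
      min_frac <= 0 || min_frac > 1) {
    cs_abort("`min_frac` must lie in (0, 1].", "cosegscan_config_error")
  }
}

overlap_len <- function(s1, e1, s2, e2) pmax(0L, pmin(e1, e2) - pmax(s1, s2))

## All reciprocal-overlap matches between two non-SNV variant tables.
## Returns a tibble of index pairs (ia, ib) with the overlap length.
indel_matches <- function(a, b, min_frac) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(tibble(ia = integer(), ib = integer(), ov = integer()))
  }
  iva <- indel_interval(a)
  ivb <- indel_interval(b)
  da <- tibble(ia = seq_len(nrow(a)), chrom = a$chrom,
               sa = iva$start, ea = iva$end)
  db <- tibble(ib = seq_len(nrow(b)), chrom = b$chrom,
               sb = ivb$start, eb = ivb$end)
  pairs <- dplyr::inner_join(da, db, by = "chrom", relationship = "many-to-many")
  pairs$ov <- overlap_len(pairs$sa, pairs$ea, pairs$sb, pairs$eb)
  keep <- pairs$ov / (pairs$ea - pairs$sa) > min_frac &
    pairs$ov / (pairs$eb - pairs$sb) > min_frac
  pairs[keep, c("ia", "ib", "ov")]
}

## For each a-indel pick its best partner in b: maximum overlap, ties broken
## by the leftmost partner interval, then by (pos, ref, alt).
best_indel_partner <- function(a, b, min_frac) {
  m <- indel_matches(a, b, min_frac)
  if (nrow(m) == 0L) return(m[, c("ia", "ib")])
  ivb <- indel_interval(b)
  m$start_b <- ivb$start[m$ib]
  m$pos_b <- b$pos[m$ib]
  m$ref_b <- b$ref[m$ib]
  m$alt_b <- b$alt[m$ib]
  m <- m[order(m$ia, -m$ov, m$start_b, m$pos_b, m$ref_b, m$alt_b), ]
  m <- m[!duplicated(m$ia), ]
  m[, c("ia", "ib")]
}

#' Intersect two callsets of the same sample
#'
#' Retains every variant of `a` that has an identical partner in `b`: exact
#' identity for SNVs, reciprocal fractional overlap for indels and complex
#' variants (greedy maximum-overlap match, ties to the leftmost partner).
#' Annotations and genotype are taken from `a`; the matched partner's
#' coordinates are recorded in `match_pos` / `match_ref` / `match_alt`.
#'
#' @param a,b Callset tibbles for the same sample.
#' @param min_indel_frac Reciprocal overlap fraction for indel identity.
#' @return The consensus callset: retained rows of `a` plus provenance
#'   columns.
#' @export
intersect_callsets <- function(a, b, min_indel_frac = 0.10) {
  check_min_frac(min_indel_frac)
  sa <- unique(a$sample_id); sb <- unique(b$sample_id)
  if (length(sa) == 1L && length(sb) == 1L && !identical(sa, sb)) {
    cs_abort(paste0("Sample mismatch: ", sa, " vs ", sb), "cosegscan_input_error")
  }
  a_snv <- a[a$vclass == "snv", , drop = FALSE]
  b_snv <- b[b$vclass == "snv", , drop = FALSE]
  snv_keep <- variant_key(a_snv$chrom, a_snv$pos, a_snv$ref, a_snv$alt) %in%
    variant_key(b_snv$chrom, b_snv$pos, b_snv$ref, b_snv$alt)
  out_snv <- a_snv[snv_keep, , drop = FALSE]
  if (nrow(out_snv)) {
    out_snv$match_pos <- out_snv$pos
    out_snv$match_ref <- out_snv$ref
    out_snv$match_alt <- out_snv$alt
  }
  a_ind <- a[a$vclass != "snv", , drop = FALSE]
  b_ind <- b[b$vclass != "snv", , drop = FALSE]
  pairs <- best_indel_partner(a_ind, b_ind, min_indel_frac)
  out_ind <- a_ind[pairs$ia, , drop = FALSE]
  if (nrow(out_ind)) {
    out_ind$match_pos <- b_ind$pos[pairs$ib]
    out_ind$match_ref <- b_ind$ref[pairs$ib]
    out_ind$match_alt <- b_ind$alt[pairs$ib]
  }
  out <- dplyr::bind_rows(out_snv, out_ind)
  out <- out[order(out$chrom, out$pos, out$ref, out$alt), , drop = FALSE]
  out
}
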