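## The rare / conserved / impactful / deleterious filtering cascade.
##
## Applied after consensus calling. Every stage is a pure per-variant
## predicate, so the cascade is order-independent within a stage and
## idempotent. A per-stage ledger records input, removed and output counts.

#' Rarity filter
#'
#' A variant is rare when its gnomAD popmax and TOPMed allele frequencies are
#' both strictly below `af_max` (a frequency of exactly `af_max` is removed,
#' matching the "removed at >= 1% in either database" convention). Censored
#' annotations (`"<bound"`) resolve via [censored_lt()]; a censored bound
#' above the threshold is indeterminate and raises an error naming the
#' variant. Absent annotations pass (logged).
#'
#' @param variants A variant tibble.
#' @param af_max Frequency threshold (default 0.01).
#' @return Logical vector, `TRUE` for rare.
#' @export
is_rare <- function(variants, af_max = 0.01) {
  lab <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  g <- censored_lt(variants$gnomad_popmax_af, variants$gnomad_popmax_censored,
                   af_max, label = lab)
  t <- censored_lt(variants$topmed_af, variants$topmed_censored,
                   af_max, label = lab)
  n_absent <- sum(is.na(g) & is.na(t))
  if (n_absent > 0L) {
    cs_inform(n_absent, " variant(s) lack both frequency annotations; passing rarity filter.")
  }
  (g %|na|% TRUE) & (t %|na|% TRUE)
}

#' Conservation filter
#'
#' Retains variants whose PhastCons 7-way score strictly exceeds `pc_min`.
#' Indels frequently lack conservation scores; absent scores pass or fail per
#' `missing` (default pass, logged).
#'
#' @param variants A variant tibble.
#' @param pc_min Conservation threshold (default 0.1, strict `>`).
#' @param missing `"pass"` or `"fail"` for absent scores.
#' @return Logical vector.
#' @export
is_conserved <- function(variants, pc_min = 0.1, missing = c("pass", "fail")) {
  missing <- match.arg(missing)
  n_absent <- sum(is.na(variants$phastcons7))
  if (n_absent > 0L) {
    cs_inform(n_absent, " variant(s) lack a conservation score; treated as ",
              if (missing == "pass") "passing." else "failing.")
  }
  (variants$phastcons7 > pc_min) %|na|% (missing == "pass")
}

#' Consequence-to-impact lookup table
#'
#' Mapping from consequence terms to impact tiers, used when a variant
#' carries only a consequence annotation. The table approximates the
#' impactful-consequence lists used by annotation tools (stop/frameshift/
#' splice-disrupting = high; missense and in-frame protein changes =
#' moderate; synonymous and non-coding classes = low/modifier) and can be
#' replaced wholesale via the `impact_map` argument of [is_impactful()].
#'
#' @return Tibble with columns `consequence` and `impact_tier`.
#' @export
default_impact_map <- function() {
  tibble(
    consequence = c(
      "stop_gained", "frameshift", "splice_acceptor", "splice_donor",
      "start_lost", "stop_lost", "transcript_ablation",
      "missense", "inframe_insertion", "inframe_deletion", "inframe_indel",
      "protein_altering",
      "synonymous", "splice_region", "stop_retained", "start_retained",
      "incomplete_terminal_codon",
      "intron", "intronic", "5_prime_utr", "3_prime_utr", "utr",
      "upstream", "downstream", "upstream_gene", "downstream_gene",
      "intergenic", "non_coding_transcript_exon"
    ),
    impact_tier = c(
      rep("high", 7), rep("moderate", 5), rep("low", 5), rep("modifier", 11)
    )
  )
}

normalize_consequence <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("[ -]", "_", x)
  sub("_variant$", "", x)
}

#' Impact filter
#'
#' Retains variants whose impact tier is `high` or `moderate`. When only a
#' consequence term is present it is mapped through `impact_map`; an unknown
#' term is an error listing the term.
#'
#' @param variants A variant tibble.
#' @param impact_map Consequence-to-tier table, see [default_impact_map()].
#' @return Logical vector.
#' @export
is_impactful <- function(variants, impact_map = default_impact_map()) {
  tier <- if ("impact_tier" %in% names(variants)) {
    tolower(variants$impact_tier)
  } else {
    rep(NA_character_, nrow(variants))
  }
  need_map <- is.na(tier) & !is.na(variants$consequence)
  if (any(need_map)) {
    csq <- normalize_consequence(variants$consequence[need_map])
    idx <- match(csq, impact_map$consequence)
    if (anyNA(idx)) {
      cs_abort(paste0("Unknown consequence term(s): ",
                      paste(unique(csq[is.na(idx)]), collapse = ", ")),
               "cosegscan_format_error")
    }
    tier[need_map] <- impact_map$impact_tier[idx]
  }
  if (any(is.na(tier))) {
    cs_abort("Variant(s) lack both impact tier and consequence annotation.",
             "cosegscan_format_error")
  }
  tier %in% c("high", "moderate")
}

#' Missense benign/tolerated exclusion
#'
#' Decides whether a missense variant is excluded on the basis of its SIFT
#' and PolyPhen labels. Under the default rule (`benign_rule = "both"`) a
#' variant is excluded only when SIFT says tolerated *and* PolyPhen says
#' benign; a single damaging call from either tool retains it. The
#' alternative `"either"` rule (excluded when either tool is
#' benign/tolerated) is provided for comparison and is deliberately stricter.
#'
#' @param variants A variant tibble whose rows are all missense.
#' @param benign_rule `"both"` (default) or `"either"`.
#' @return Logical vector, `TRUE` for excluded.
#' @export
missense_excluded <- function(variants, benign_rule = c("both", "either")) {
  benign_rule <- match.arg(benign_rule)
  csq <- normalize_consequence(variants$consequence)
  if (any(csq != "missense", na.rm = TRUE) || anyNA(csq)) {
    cs_abort("missense_excluded is defined for missense variants only.",
             "cosegscan_contract_error")
  }
  tol <- isTRUE_v(tolower(variants$sift_label) == "tolerated")
  ben <- isTRUE_v(tolower(variants$polyphen_label) == "benign")
  if (benign_rule == "both") tol & ben else tol | ben
}

#' Apply the full filtering cascade
#'
#' Stages, in order: rarity (`is_rare`), conservation (`is_conserved`),
#' impact (`is_impactful`), and missense benign/tolerated exclusion
#' (`missense_excluded`, applied to missense rows only). Returns the
#' surviving variants together with a telescoping per-stage count ledger.
#'
#' @param variants A variant tibble (typically the consensus set).
#' @param af_max Rarity threshold.
#' @param pc_min Conservation threshold.
#' @param conservation_missing `"pass"` or `"fail"` for absent scores.
#' @param benign_rule Missense exclusion rule, see [missense_excluded()].
#' @param impact_map Consequence-to-tier table.
#' @return An object of class `coseg_cascade`: a list with `surviving` (the
#'   retained variant tibble) and `ledger` (tibble with `stage`, `n_in`,
#'   `n_removed`, `n_out`).
#' @export
apply_cascade <- function(variants, af_max = 0.01, pc_min = 0.1,
                          conservation_missing = c("pass", "fail"),
                          benign_rule = c("both", "either"),
                          impact_map = default_impact_map()) {
  conservation_missing <- match.arg(conservation_missing)
  benign_rule <- match.arg(benign_rule)
  stages <- list(
    rare = function(v) is_rare(v, af_max),
    conserved = function(v) is_conserved(v, pc_min, conservation_missing),
    impactful = function(v) is_impactful(v, impact_map),
    not_benign_missense = function(v) {
      out <- rep(TRUE, nrow(v))
      ms <- !is.na(v$consequence) & normalize_consequence(v$consequence) == "missense"
      if (any(ms)) {
        out[ms] <- !missense_excluded(v[ms, , drop = FALSE], benign_rule)
      }
      out
    }
  )
  current <- variants
  ledger <- vector("list", length(stages))
  for (s in seq_along(stages)) {
    n_in <- nrow(current)
    keep <- if (n_in == 0L) logical(0) else stages[[s]](current)
    current <- current[keep, , drop = FALSE]
    ledger[[s]] <- tibble(stage = names(stages)[s], n_in = n_in,
                          n_removed = n_in - nrow(current), n_out = nrow(current))
  }
  structure(
    list(surviving = current, ledger = dplyr::bind_rows(ledger)),
    class = "coseg_cascade"
  )
}

#' @export
print.coseg_cascade <- function(x, ...) {
  cat("<coseg_cascade>\n")
  cat(sprintf("  %d variant(s) in, %d surviving\n",
              x$ledger$n_in[1], x$ledger$n_out[nrow(x$ledger)]))
  print(x$ledger)
  invisible(x)
}
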