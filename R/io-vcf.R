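## VCF input/output for per-sample, per-caller callsets.
##
## The expected dialect is VCF v4.2 with annotations as INFO keys (default
## names below) and FORMAT fields GT and DP for the single sample column.
## Multi-allelic records are decomposed into one variant per ALT allele
## before anything else happens; per-allele INFO values may be comma-lists.

#' Default INFO key names
#'
#' @return Named list mapping annotation slots to INFO keys: `gene` = GENE,
#'   `gnomad_popmax` = GPMAX, `topmed` = TOPMED, `nfe` = NFE,
#'   `phastcons7` = PC7, `consequence` = CSQ, `impact` = IMPACT,
#'   `sift` = SIFT, `polyphen` = PPH, `rsid` = RSID.
#' @export
default_info_keys <- function() {
  list(gene = "GENE", gnomad_popmax = "GPMAX", topmed = "TOPMED",
       nfe = "NFE", phastcons7 = "PC7", consequence = "CSQ",
       impact = "IMPACT", sift = "SIFT", polyphen = "PPH", rsid = "RSID")
}

normalize_chrom <- function(chrom, style = c("keep", "strip", "add")) {
  style <- match.arg(style)
  switch(style,
    keep = chrom,
    strip = sub("^chr", "", chrom),
    add = ifelse(startsWith(chrom, "chr"), chrom, paste0("chr", chrom))
  )
}

#' Read one caller's VCF into a callset tibble
#'
#' Parses a single-sample VCF, decomposes multi-allelic records into
#' biallelic variants, extracts the annotation INFO keys (censored
#' frequencies in the `"<bound"` convention are kept censored), and keeps
#' only carrier genotypes (het / hom_alt).
#'
#' @param path Path to a VCF file.
#' @param sample_id Sample identifier; defaults to the VCF sample column name.
#' @param caller_tag Which caller produced the file (e.g. `"callerA"`).
#' @param info_keys Named list of INFO key names, see [default_info_keys()].
#' @param on_missing What to do with a record lacking an annotation key:
#'   `"absent"` (default) treats the annotation as missing; `"reject"` drops
#'   the record (logged).
#' @param chrom_style `"keep"`, `"strip"` or `"add"` the `"chr"` prefix.
#' @return A callset tibble (variant columns plus `sample_id`, `caller_tag`,
#'   `genotype`, `depth`).
#' @export
read_callset <- function(path, sample_id = NULL, caller_tag = "callerA",
                         info_keys = default_info_keys(),
                         on_missing = c("absent", "reject"),
                         chrom_style = c("keep", "strip", "add")) {
  on_missing <- match.arg(on_missing)
  chrom_style <- match.arg(chrom_style)
  body_lines <- sum(!startsWith(readLines(path, warn = FALSE), "#"))
  if (body_lines == 0L) {
    return(empty_callset(sample_id %||% NA_character_, caller_tag))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (is.null(sample_id)) sample_id <- colnames(vcf@gt)[2]
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")[, 1]
  dp_raw <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)[, 1])

  info_of <- function(key) {
    val <- tryCatch(vcfR::extract.info(vcf, element = key),
                    error = function(e) rep(NA_character_, nrow(fix)))
    if (is.null(val)) rep(NA_character_, nrow(fix)) else as.character(val)
  }
  info <- lapply(info_keys, info_of)

  rows <- vector("list", nrow(fix))
  n_rejected <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    if (on_missing == "reject" &&
        any(vapply(info, function(v) is.na(v[i]), logical(1)))) {
      n_rejected <- n_rejected + 1L
      next
    }
    alleles <- strsplit(gt_raw[i], "[/|]")[[1]]
    per_alt <- function(v, j) {
      if (is.na(v[i])) return(NA_character_)
      parts <- strsplit(v[i], ",", fixed = TRUE)[[1]]
      if (length(parts) >= j) parts[j] else parts[1]
    }
    sub_rows <- lapply(seq_along(alts), function(j) {
      n_alt <- sum(alleles == as.character(j))
      if (n_alt == 0L) return(NULL)
      gp <- parse_censored(per_alt(info$gnomad_popmax, j))
      tm <- parse_censored(per_alt(info$topmed, j))
      nf <- parse_censored(per_alt(info$nfe, j))
      tibble(
        chrom = normalize_chrom(fix$CHROM[i], chrom_style),
        pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[j],
        qual = suppressWarnings(as.numeric(fix$QUAL[i])),
        gene = per_alt(info$gene, j),
        rsid = per_alt(info$rsid, j) %|na|% na_if_dot(fix$ID[i]),
        gnomad_popmax_af = gp$value, gnomad_popmax_censored = gp$censored,
        topmed_af = tm$value, topmed_censored = tm$censored,
        nfe_af = nf$value, nfe_censored = nf$censored,
        phastcons7 = suppressWarnings(as.numeric(per_alt(info$phastcons7, j))),
        consequence = per_alt(info$consequence, j),
        impact_tier = per_alt(info$impact, j),
        sift_label = per_alt(info$sift, j),
        polyphen_label = per_alt(info$polyphen, j),
        genotype = if (n_alt >= 2L) "hom_alt" else "het",
        depth = as.integer(dp_raw[i])
      )
    })
    rows[[i]] <- dplyr::bind_rows(sub_rows)
  }
  if (n_rejected > 0L) {
    cs_inform(n_rejected, " record(s) rejected for missing annotation keys.")
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) return(empty_callset(sample_id, caller_tag))
  out$vclass <- classify_variant(out$ref, out$alt)
  out$sample_id <- sample_id
  out$caller_tag <- caller_tag
  key <- variant_key(out$chrom, out$pos, out$ref, out$alt)
  if (anyDuplicated(key)) {
    cs_abort("Duplicate (chrom, pos, ref, alt) within one callset.",
             "cosegscan_format_error")
  }
  validate_variants(out)
  out[c("sample_id", "caller_tag", cs_variant_cols, "genotype", "depth")]
}

`%|na|%` <- function(x, y) ifelse(is.na(x), y, x)

na_if_dot <- function(x) ifelse(x %in% c(".", ""), NA_character_, x)

empty_callset <- function(sample_id, caller_tag) {
  out <- variant_tibble(character(), integer(), character(), character())
  out$sample_id <- character()
  out$caller_tag <- character()
  out$genotype <- character()
  out$depth <- integer()
  out[c("sample_id", "caller_tag", cs_variant_cols, "genotype", "depth")]
}

#' Write a callset tibble as a VCF file
#'
#' Emits a minimal single-sample VCF v4.2 in the package's annotation dialect
#' (one biallelic record per variant, annotations as INFO keys, GT:DP FORMAT).
#' Censored frequencies render as `"<bound"`.
#'
#' @param callset A callset tibble (one sample, one caller).
#' @param path Output path.
#' @param info_keys Named list of INFO key names, see [default_info_keys()].
#' @return `path`, invisibly.
#' @export
write_callset_vcf <- function(callset, path, info_keys = default_info_keys()) {
  sample_id <- unique(callset$sample_id)
  if (length(sample_id) > 1L) {
    cs_abort("write_callset_vcf expects a single sample.", "cosegscan_input_error")
  }
  if (length(sample_id) == 0L) sample_id <- "SAMPLE"
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf('##INFO=<ID=%s,Number=1,Type=String,Description="%s">',
            unlist(info_keys),
            c("Gene symbol", "gnomAD popmax AF (may be censored '<x')",
              "TOPMed AF (may be censored '<x')", "gnomAD NFE AF (may be censored '<x')",
              "PhastCons 7-way conservation score", "Consequence term",
              "Impact tier", "SIFT label", "PolyPhen label", "dbSNP identifier")[
                match(names(info_keys), names(default_info_keys()))]),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample_id)
  )
  fmt_num <- function(x) ifelse(is.na(x), NA_character_,
                                format(x, trim = TRUE, scientific = FALSE, digits = 15))
  info_field <- function(i) {
    kv <- c(
      GENE = callset$gene[i],
      GPMAX = format_censored(callset$gnomad_popmax_af[i],
                              callset$gnomad_popmax_censored[i]),
      TOPMED = format_censored(callset$topmed_af[i], callset$topmed_censored[i]),
      NFE = format_censored(callset$nfe_af[i], callset$nfe_censored[i]),
      PC7 = fmt_num(callset$phastcons7[i]),
      CSQ = callset$consequence[i],
      IMPACT = callset$impact_tier[i],
      SIFT = callset$sift_label[i],
      PPH = callset$polyphen_label[i],
      RSID = callset$rsid[i]
    )
    names(kv) <- unlist(info_keys)[match(names(kv), unlist(default_info_keys()))]
    kv <- kv[!is.na(kv) & kv != "."]
    if (length(kv) == 0L) return(".")
    paste(paste0(names(kv), "=", kv), collapse = ";")
  }
  ord <- order(callset$chrom, callset$pos, callset$ref, callset$alt)
  callset <- callset[ord, , drop = FALSE]
  body <- vapply(seq_len(nrow(callset)), function(i) {
    gt <- if (identical(callset$genotype[i], "hom_alt")) "1/1" else "0/1"
    paste(
      callset$chrom[i], callset$pos[i],
      callset$rsid[i] %|na|% ".",
      callset$ref[i], callset$alt[i],
      fmt_num(callset$qual[i]) %|na|% ".",
      "PASS", info_field(i), "GT:DP",
      paste0(gt, ":", callset$depth[i] %|na|% "."),
      sep = "\t"
    )
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
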