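## Synthetic multi-family cohort generator.
##
## Produces a fully specified cohort — two callsets per sample with controlled
## discordance, planted co-segregating deleterious variants, background
## variants that each violate exactly one pipeline criterion, control allele
## counts, and term gene-sets — together with a machine-readable truth table,
## so every pipeline stage can be tested end to end without restricted data.

#' Synthetic cohort configuration
#'
#' Defaults emulate the motivating study design: ten multiply affected
#' families (nine pairs and one trio, 21 exomes), six genes planted with
#' co-segregating deleterious variants in two or more families (different
#' alleles per family, as observed in practice), a handful of single-family
#' planted genes, and background variation engineered to exercise every
#' pipeline stage. Allele frequencies are drawn from rare/common beta
#' mixtures so the 1% rarity threshold bisects the distribution, and
#' frequencies below `censor_threshold` are reported censored (`"<bound"`),
#' emulating public-database annotation dialects.
#'
#' @param n_families Number of families.
#' @param members_per_family Integer vector (length `n_families`) of affected
#'   members per family; each must be >= 2.
#' @param n_genes Total genes in the synthetic exome.
#' @param n_background_variants Background variants spread over the cohort.
#' @param n_planted_genes_multifamily Genes planted in >= 2 families (the
#'   first planted gene gets three families, the rest two).
#' @param n_planted_genes_single Genes planted in exactly one family.
#' @param n_planted_per_family Planted variants per designated (gene, family)
#'   pair.
#' @param caller_discordance_rate Fraction of background variants private to
#'   one caller.
#' @param indel_fraction Fraction of planted variants that are indels.
#' @param censor_threshold Frequencies below this are reported censored.
#' @param rare_beta,common_beta Beta parameters for rare and common allele
#'   frequencies.
#' @param control_n Control cohort size (individuals).
#' @param seed Integer seed; the seed fully determines the output.
#' @return A validated config list of class `coseg_sim_config`.
#' @export
cohort_config <- function(n_families = 10L,
                          members_per_family = c(2L, 2L, 3L, 2L, 2L, 2L, 2L, 2L, 2L, 2L),
                          n_genes = 80L,
                          n_background_variants = 350L,
                          n_planted_genes_multifamily = 6L,
                          n_planted_genes_single = 4L,
                          n_planted_per_family = 1L,
                          caller_discordance_rate = 0.15,
                          indel_fraction = 0.12,
                          censor_threshold = 0.001,
                          rare_beta = c(0.4, 400),
                          common_beta = c(5, 20),
                          control_n = 5000L,
                          seed = 1L) {
  cfg <- list(
    n_families = as.integer(n_families),
    members_per_family = as.integer(members_per_family),
    n_genes = as.integer(n_genes),
    n_background_variants = as.integer(n_background_variants),
    n_planted_genes_multifamily = as.integer(n_planted_genes_multifamily),
    n_planted_genes_single = as.integer(n_planted_genes_single),
    n_planted_per_family = as.integer(n_planted_per_family),
    caller_discordance_rate = caller_discordance_rate,
    indel_fraction = indel_fraction,
    censor_threshold = censor_threshold,
    rare_beta = rare_beta,
    common_beta = common_beta,
    control_n = as.integer(control_n),
    seed = as.integer(seed)
  )
  if (length(cfg$members_per_family) != cfg$n_families) {
    cs_abort("members_per_family must have one entry per family.",
             "cosegscan_config_error")
  }
  if (any(cfg$members_per_family < 2L)) {
    cs_abort("Every family needs >= 2 members.", "cosegscan_config_error")
  }
  for (r in c("caller_discordance_rate", "indel_fraction", "censor_threshold")) {
    if (cfg[[r]] < 0 || cfg[[r]] > 1) {
      cs_abort(paste0("`", r, "` must lie in [0, 1]."), "cosegscan_config_error")
    }
  }
  n_planted <- cfg$n_planted_genes_multifamily + cfg$n_planted_genes_single
  if (n_planted > cfg$n_genes) {
    cs_abort("More planted genes than genes.", "cosegscan_config_error")
  }
  if (cfg$n_planted_genes_multifamily > 0 && cfg$n_families < 2L) {
    cs_abort("Multi-family planting needs >= 2 families.", "cosegscan_config_error")
  }
  structure(cfg, class = "coseg_sim_config")
}

sim_gene_table <- function(n_genes) {
  i <- seq_len(n_genes)
  tibble(
    gene = sprintf("GENE%03d", i),
    chrom = paste0("chr", ((i - 1L) %% 22L) + 1L),
    start = 1e6L + ((i - 1L) %/% 22L) * 1000000L
  )
}

sim_families <- function(cfg) {
  fam <- rep(as.character(seq_len(cfg$n_families)), cfg$members_per_family)
  member_idx <- unlist(lapply(cfg$members_per_family, seq_len))
  tibble(
    family_id = fam,
    sample_id = paste0(fam, letters[member_idx]),
    age = sample(1:65, length(fam), replace = TRUE),
    age_is_surgery_proxy = runif(length(fam)) < 0.2,
    bilateral = runif(length(fam)) < 0.3,
    sex = sample(c("female", "male"), length(fam), replace = TRUE),
    relationship = ifelse(member_idx == 1L, "index", "relative")
  )
}

## one synthetic variant record (annotations only, no sample columns)
sim_variant <- function(gene_row, offset, cfg, kind = c("planted", "background")) {
  kind <- match.arg(kind)
  pos <- gene_row$start + offset
  is_indel <- runif(1) < cfg$indel_fraction
  bases <- c("A", "C", "G", "T")
  if (is_indel) {
    ref <- paste(sample(bases, 4, replace = TRUE), collapse = "")
    alt <- substr(ref, 1, 1)
    consequence <- "stop_gained"
    sift <- NA_character_; pph <- NA_character_
  } else {
    ra <- sample(bases, 2)
    ref <- ra[1]; alt <- ra[2]
    consequence <- "missense"
    damaging <- list(c("deleterious", "probably_damaging"),
                     c("tolerated", "probably_damaging"),
                     c("deleterious", "benign"),
                     c("deleterious", "possibly_damaging"))
    dd <- damaging[[sample.int(4, 1)]]
    sift <- dd[1]; pph <- dd[2]
  }
  af <- function() min(rbeta(1, cfg$rare_beta[1], cfg$rare_beta[2]), 0.009)
  cens <- function(v) {
    if (v < cfg$censor_threshold) c(cfg$censor_threshold, TRUE) else c(v, FALSE)
  }
  g <- cens(af()); t <- cens(af()); nf <- cens(af())
  variant_tibble(
    chrom = gene_row$chrom, pos = pos, ref = ref, alt = alt,
    gene = gene_row$gene,
    rsid = sprintf("rs%s%07d", sub("^chr", "", gene_row$chrom), pos %% 1e7),
    gnomad_popmax_af = g[1], gnomad_popmax_censored = as.logical(g[2]),
    topmed_af = t[1], topmed_censored = as.logical(t[2]),
    nfe_af = nf[1], nfe_censored = as.logical(nf[2]),
    phastcons7 = runif(1, 0.3, 1),
    consequence = consequence,
    sift_label = sift, polyphen_label = pph
  )
}

#' Generate a synthetic multi-family cohort
#'
#' See [cohort_config()] for what the generator emulates. Planted variants
#' are present in both callers for every member of their designated families
#' and pass every filter; each background variant violates exactly one
#' pipeline criterion (common frequency, low conservation, low impact,
#' benign/tolerated missense, caller-private, member-private, or failing the
#' quality hard filter), so each stage removes known variants.
#'
#' @param config A `coseg_sim_config` from [cohort_config()].
#' @return List with elements `callsets` (tibble of all per-sample,
#'   per-caller variant calls), `families`, `controls`, `terms`, `truth`
#'   (one row per distinct variant with its expected fate), and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "coseg_sim_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  genes <- sim_gene_table(cfg$n_genes)
  families <- sim_families(cfg)
  fam_ids <- unique(families$family_id)

  n_mf <- cfg$n_planted_genes_multifamily
  n_sf <- cfg$n_planted_genes_single
  planted_mf <- genes$gene[seq_len(n_mf)]
  planted_sf <- genes$gene[n_mf + seq_len(n_sf)]
  bg_pool <- genes$gene[-seq_len(n_mf + n_sf)]
  if (length(bg_pool) == 0L) bg_pool <- genes$gene

  offset_counter <- new.env(parent = emptyenv())
  next_offset <- function(gene) {
    k <- (get0(gene, offset_counter) %||% 0L) + 1L
    assign(gene, k, offset_counter)
    k * 50L
  }

  variants <- list()   # annotation records
  placements <- list() # key -> samples & callers carrying it
  truth <- list()

  plant <- function(gene, fams, category) {
    for (f in fams) {
      for (dup in seq_len(cfg$n_planted_per_family)) {
        g_row <- genes[genes$gene == gene, ]
        v <- sim_variant(g_row, next_offset(gene), cfg)
        key <- variant_key(v$chrom, v$pos, v$ref, v$alt)
        members <- families$sample_id[families$family_id == f]
        variants[[key]] <<- v
        placements[[key]] <<- tibble(
          sample_id = rep(members, each = 2L),
          caller_tag = rep(c("callerA", "callerB"), length(members)),
          genotype = if (runif(1) < 0.1) "hom_alt" else "het"
        )
        truth[[key]] <<- tibble(
          key = key, gene = gene, families = list(f), category = category,
          expected_stage_removed = "none", expected_to_survive = TRUE
        )
      }
    }
  }

  for (i in seq_along(planted_mf)) {
    n_fam <- if (i == 1L) min(3L, cfg$n_families) else 2L
    plant(planted_mf[i], sample(fam_ids, n_fam), "planted_multifamily")
  }
  for (g in planted_sf) {
    plant(g, sample(fam_ids, 1L), "planted_single")
  }

  ## background: caller-private fraction per config, the rest cycle through
  ## the remaining single-violation categories
  n_bg <- cfg$n_background_variants
  n_private <- floor(cfg$caller_discordance_rate * n_bg)
  other <- c("common_af", "low_conservation", "low_impact",
             "benign_missense", "member_private", "hard_filter_fail")
  categories <- c(rep("caller_private", n_private),
                  rep_len(other, max(0L, n_bg - n_private)))
  stage_of <- c(
    common_af = "rare", low_conservation = "conserved",
    low_impact = "impactful", benign_missense = "not_benign_missense",
    caller_private = "consensus", member_private = "family",
    hard_filter_fail = "hard_filter"
  )
  for (cat in categories) {
    gene <- sample(bg_pool, 1L)
    g_row <- genes[genes$gene == gene, ]
    v <- sim_variant(g_row, next_offset(gene), cfg)
    ## make the variant pass everything, then break exactly one criterion
    v$consequence <- "missense"
    v$sift_label <- "deleterious"; v$polyphen_label <- "probably_damaging"
    v$vclass <- classify_variant(v$ref, v$alt)
    if (v$vclass != "snv") { # keep background single-violation logic simple
      v$ref <- "A"; v$alt <- "G"; v$vclass <- "snv"
    }
    if (cat == "common_af") {
      v$gnomad_popmax_af <- runif(1, 0.02, 0.4)
      v$gnomad_popmax_censored <- FALSE
      v$topmed_af <- runif(1, 0.02, 0.4)
      v$topmed_censored <- FALSE
    } else if (cat == "low_conservation") {
      v$phastcons7 <- runif(1, 0, 0.099)
    } else if (cat == "low_impact") {
      v$consequence <- "synonymous"
      v$sift_label <- NA_character_; v$polyphen_label <- NA_character_
    } else if (cat == "benign_missense") {
      v$sift_label <- "tolerated"; v$polyphen_label <- "benign"
    }
    f <- sample(fam_ids, 1L)
    members <- families$sample_id[families$family_id == f]
    if (cat == "member_private") members <- members[1]
    callers <- if (cat == "caller_private") "callerA" else c("callerA", "callerB")
    key <- variant_key(v$chrom, v$pos, v$ref, v$alt)
    variants[[key]] <- v
    placements[[key]] <- tibble(
      sample_id = rep(members, each = length(callers)),
      caller_tag = rep(callers, length(members)),
      genotype = if (runif(1) < 0.1) "hom_alt" else "het"
    )
    truth[[key]] <- tibble(
      key = key, gene = gene, families = list(f), category = cat,
      expected_stage_removed = unname(stage_of[cat]), expected_to_survive = FALSE
    )
  }

  ## assemble per-sample, per-caller callsets
  keys <- names(variants)
  callsets <- dplyr::bind_rows(lapply(keys, function(key) {
    v <- variants[[key]]
    pl <- placements[[key]]
    low_q <- identical(truth[[key]]$category, "hard_filter_fail")
    out <- v[rep(1L, nrow(pl)), , drop = FALSE]
    out$sample_id <- pl$sample_id
    out$caller_tag <- pl$caller_tag
    out$genotype <- pl$genotype
    out$qual <- if (low_q) runif(1, 1, 20) else runif(1, 60, 900)
    out$depth <- if (low_q) 3L else 20L + rpois(nrow(pl), 20)
    out
  }))
  callsets <- callsets[order(callsets$sample_id, callsets$caller_tag,
                             callsets$chrom, callsets$pos, callsets$ref,
                             callsets$alt), , drop = FALSE]

  ## control allele counts: tiny frequencies for planted genes (strong case
  ## excess), ordinary rare frequencies elsewhere; some sites fail depth QC
  an <- 2L * cfg$control_n
  planted_all <- c(planted_mf, planted_sf)
  ctl_af <- ifelse(genes$gene %in% planted_all, 1e-4, runif(cfg$n_genes, 1e-4, 5e-3))
  controls <- tibble(
    chrom = genes$chrom, pos = genes$start + 1L, ref = "A", alt = "G",
    gene = genes$gene,
    control_ac = pmax(1L, as.integer(round_half_up(ctl_af * an))),
    control_an = an,
    depth_pass_fraction = ifelse(runif(cfg$n_genes) < 0.1,
                                 runif(cfg$n_genes, 0.5, 0.89),
                                 runif(cfg$n_genes, 0.9, 1))
  )

  ## term gene-sets: one term carrying all multi-family planted genes plus
  ## random terms over the rest of the exome
  sources <- c("GO_MF", "REAC", "CORUM", "KEGG")
  n_terms <- 15L
  terms <- dplyr::bind_rows(
    tibble(term_id = "GO_MF:PLANTED", term_name = "planted deleterious module",
           source_tag = "GO_MF",
           genes = list(unique(c(planted_mf,
                                 sample(bg_pool, min(6L, length(bg_pool))))))),
    dplyr::bind_rows(lapply(seq_len(n_terms - 1L), function(i) {
      src <- sample(sources, 1L)
      tibble(term_id = sprintf("%s:T%03d", src, i),
             term_name = sprintf("synthetic term %d", i),
             source_tag = src,
             genes = list(sort(sample(genes$gene,
                                      sample(5:15, 1L)))))
    }))
  )

  list(
    callsets = callsets,
    families = families,
    controls = controls,
    terms = terms,
    truth = dplyr::bind_rows(truth),
    config = cfg
  )
}

#' Write a synthetic cohort to disk
#'
#' Emits one VCF per sample and caller, the family table, the control allele
#' count table, the term gene-sets (GMT) and the truth table (JSON).
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  split_cols <- interaction(cohort$callsets$sample_id, cohort$callsets$caller_tag,
                            drop = TRUE)
  for (piece in split(cohort$callsets, split_cols)) {
    f <- sprintf("%s_%s.vcf", unique(piece$sample_id), unique(piece$caller_tag))
    write_callset_vcf(piece, file.path(dir, f))
  }
  write_family_table(cohort$families, file.path(dir, "families.tsv"))
  readr::write_tsv(cohort$controls, file.path(dir, "controls.tsv"))
  write_gmt(cohort$terms, file.path(dir, "terms.gmt"))
  truth <- cohort$truth
  truth$families <- lapply(truth$families, as.character)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = FALSE)
  invisible(dir)
}

#' Generate a null cohort for burden-test calibration
#'
#' For every gene the case carriers are drawn binomially at exactly the
#' control carrier probability (single collapsed site per gene), so the
#' burden test's dominant p-values should be uniform-to-conservative.
#'
#' @param n_genes Number of genes (default 1000).
#' @param n_cases Case cohort size (default 21).
#' @param n_controls Control cohort size (default 5000).
#' @param seed Integer seed.
#' @return List with `cases` (tibble: `gene`, `n_case_carriers_dom`,
#'   `n_case_carriers_rec`), `controls` (control site tibble), `n_cases`,
#'   `n_controls`.
#' @export
generate_null_burden <- function(n_genes = 1000L, n_cases = 21L,
                                 n_controls = 5000L, seed = 1L) {
  n_genes <- as.integer(n_genes)
  with_seed(seed, {
    if (n_genes == 0L) {
      list(
        cases = tibble(gene = character(), n_case_carriers_dom = integer(),
                       n_case_carriers_rec = integer()),
        controls = tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          gene = character(), control_ac = integer(),
                          control_an = integer(),
                          depth_pass_fraction = numeric()),
        n_cases = as.integer(n_cases), n_controls = as.integer(n_controls)
      )
    } else {
      gene <- sprintf("NULLGENE%04d", seq_len(n_genes))
      an <- 2L * as.integer(n_controls)
      af <- runif(n_genes, 5e-4, 0.02)
      ac <- pmax(1L, as.integer(round_half_up(af * an)))
      af_eff <- ac / an
      q_dom <- af_eff               # single-site collapsed carrier probability
      q_rec <- pmin(1, af_eff^2)
      list(
        cases = tibble(
          gene = gene,
          n_case_carriers_dom = rbinom(n_genes, n_cases, q_dom),
          n_case_carriers_rec = rbinom(n_genes, n_cases, q_rec)
        ),
        controls = tibble(
          chrom = "chr1", pos = seq_len(n_genes) * 100L, ref = "A", alt = "G",
          gene = gene, control_ac = ac, control_an = an,
          depth_pass_fraction = 1
        ),
        n_cases = as.integer(n_cases), n_controls = as.integer(n_controls)
      )
    }
  })
}

#' Burden p-values for a (null) cohort of precomputed carrier counts
#'
#' Combines expected control carrier counts with the supplied case carrier
#' counts and computes dominant/recessive two-sided exact p-values; used to
#' check the burden test's type-I error on null cohorts.
#'
#' @param nb Output of [generate_null_burden()].
#' @return Tibble with `gene`, `p_dom`, `p_rec`.
#' @export
null_burden_pvalues <- function(nb) {
  ctl <- control_carrier_counts(nb$controls, nb$n_controls)
  dat <- dplyr::inner_join(nb$cases, ctl, by = "gene")
  tibble(
    gene = dat$gene,
    p_dom = fisher_two_sided(dat$n_case_carriers_dom,
                             nb$n_cases - dat$n_case_carriers_dom,
                             dat$n_control_carriers_dom,
                             nb$n_controls - dat$n_control_carriers_dom),
    p_rec = fisher_two_sided(dat$n_case_carriers_rec,
                             nb$n_cases - dat$n_case_carriers_rec,
                             dat$n_control_carriers_rec,
                             nb$n_controls - dat$n_control_carriers_rec)
  )
}
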