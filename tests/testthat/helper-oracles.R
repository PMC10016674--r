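# Builders and independent oracles used across the suite.

# a variant row that passes every cascade filter unless overridden
mk_variant <- function(chrom = "chr1", pos = 100L, ref = "A", alt = "G", ...) {
  args <- list(...)
  defaults <- list(
    qual = 100, gene = "GENEX", gnomad_popmax_af = 0.001,
    gnomad_popmax_censored = FALSE, topmed_af = 0.001, topmed_censored = FALSE,
    phastcons7 = 0.95, consequence = "missense",
    sift_label = "deleterious", polyphen_label = "probably_damaging"
  )
  for (nm in names(defaults)) if (is.null(args[[nm]])) args[[nm]] <- defaults[[nm]]
  do.call(variant_tibble, c(list(chrom = chrom, pos = pos, ref = ref, alt = alt), args))
}

mk_callset <- function(variants, sample_id = "s1", caller_tag = "callerA",
                       genotype = "het", depth = 40L) {
  variants$sample_id <- sample_id
  variants$caller_tag <- caller_tag
  if (!"genotype" %in% names(variants) || all(is.na(variants$genotype))) {
    variants$genotype <- genotype
  }
  if (!"depth" %in% names(variants) || all(is.na(variants$depth))) {
    variants$depth <- depth
  }
  variants
}

# random callset with a mix of SNVs and indels; no duplicate keys
random_callset <- function(n, sample_id = "s1", caller_tag = "callerA",
                           chroms = c("chr1", "chr2")) {
  pos <- sample(1:500, n, replace = TRUE)
  kind <- sample(c("snv", "del", "ins"), n, replace = TRUE, prob = c(0.6, 0.25, 0.15))
  bases <- c("A", "C", "G", "T")
  ref <- character(n); alt <- character(n)
  for (i in seq_len(n)) {
    if (kind[i] == "snv") {
      ra <- sample(bases, 2); ref[i] <- ra[1]; alt[i] <- ra[2]
    } else if (kind[i] == "del") {
      len <- sample(2:8, 1)
      ref[i] <- paste0("A", strrep("T", len - 1)); alt[i] <- "A"
    } else {
      len <- sample(2:5, 1)
      alt[i] <- paste0("A", strrep("G", len - 1)); ref[i] <- "A"
    }
  }
  v <- mk_variant(chrom = sample(chroms, n, replace = TRUE),
                  pos = pos, ref = ref, alt = alt)
  v <- v[!duplicated(variant_key(v$chrom, v$pos, v$ref, v$alt)), , drop = FALSE]
  mk_callset(v, sample_id = sample_id, caller_tag = caller_tag)
}

# brute-force all-pairs consensus oracle: keys of `a` with any identical
# partner in `b` (exact for SNVs, reciprocal fractional overlap otherwise)
oracle_consensus_keys <- function(a, b, min_frac = 0.10) {
  iv <- function(v) {
    s <- v$pos - 1
    e <- ifelse(v$vclass == "insertion", s + 1, s + nchar(v$ref))
    cbind(s, e)
  }
  keys <- character(0)
  for (i in seq_len(nrow(a))) {
    va <- a[i, ]
    hit <- FALSE
    for (j in seq_len(nrow(b))) {
      vb <- b[j, ]
      if (va$vclass == "snv") {
        if (vb$vclass == "snv" && va$chrom == vb$chrom && va$pos == vb$pos &&
            va$ref == vb$ref && va$alt == vb$alt) hit <- TRUE
      } else if (vb$vclass != "snv" && va$chrom == vb$chrom) {
        ia <- iv(va); ib <- iv(vb)
        ov <- max(0, min(ia[2], ib[2]) - max(ia[1], ib[1]))
        if (ov / (ia[2] - ia[1]) > min_frac && ov / (ib[2] - ib[1]) > min_frac) {
          hit <- TRUE
        }
      }
      if (hit) break
    }
    if (hit) keys <- c(keys, variant_key(va$chrom, va$pos, va$ref, va$alt))
  }
  sort(keys)
}

# enumeration oracle for the two-sided exact test, built from binomial
# coefficients directly (independent of dhyper)
oracle_fisher <- function(a, b, c, d) {
  m <- a + c; nn <- b + d; k <- a + b
  support <- max(0, k - nn):min(k, m)
  prob <- choose(m, support) * choose(nn, k - support) / choose(m + nn, k)
  p_obs <- choose(m, a) * choose(nn, k - a) / choose(m + nn, k)
  min(1, sum(prob[prob <= p_obs * (1 + 1e-7)]))
}

# enumeration oracle for the hypergeometric upper tail P(X >= k)
oracle_hyper_tail <- function(N, K, n, k) {
  xs <- k:min(K, n)
  if (length(xs) == 0 || k > min(K, n)) return(0)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}
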