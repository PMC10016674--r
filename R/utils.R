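## Internal helpers shared across modules.

#' Canonical variant key
#'
#' A variant is identified throughout the package by the 4-tuple
#' (chrom, pos, ref, alt). This helper builds the string key used for exact
#' (SNV) identity and for truth-table bookkeeping.
#'
#' @param chrom,pos,ref,alt Vectors of equal length.
#' @return Character vector of keys, e.g. `"chr1:100:A:G"`.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

cs_inform <- function(...) inform(paste0(...))

cs_abort <- function(msg, class) {
  abort(msg, class = c(class, "cosegscan_error"))
}

## deterministic RNG scope: run `expr` under `seed` and restore the caller's
## RNG state afterwards, so generators never perturb user code.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    cs_abort("`seed` must be a single integer.", "cosegscan_config_error")
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

## round half away from zero, the convention used when converting expected
## control carrier counts to integer cells for the exact test
round_half_up <- function(x) floor(x + 0.5)
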