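## broom-style tidiers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a filtering-cascade result
#'
#' @param x A `coseg_cascade` object.
#' @param ... Unused.
#' @return The per-stage ledger tibble (`stage`, `n_in`, `n_removed`,
#'   `n_out`).
#' @method tidy coseg_cascade
#' @export
tidy.coseg_cascade <- function(x, ...) x$ledger

#' One-row summary of a filtering-cascade result
#'
#' @param x A `coseg_cascade` object.
#' @param ... Unused.
#' @return One-row tibble with `n_input`, `n_surviving`, `n_removed`,
#'   `n_stages`.
#' @method glance coseg_cascade
#' @export
glance.coseg_cascade <- function(x, ...) {
  tibble(
    n_input = x$ledger$n_in[1],
    n_surviving = x$ledger$n_out[nrow(x$ledger)],
    n_removed = x$ledger$n_in[1] - x$ledger$n_out[nrow(x$ledger)],
    n_stages = nrow(x$ledger)
  )
}

#' One-row summary of a burden table
#'
#' @param x A `coseg_burden` tibble.
#' @param alpha Significance threshold for the reported significant-gene
#'   counts (default 0.05, unadjusted).
#' @param ... Unused.
#' @return One-row tibble with gene counts and significant-gene counts under
#'   the dominant and recessive models.
#' @method glance coseg_burden
#' @export
glance.coseg_burden <- function(x, alpha = 0.05, ...) {
  tibble(
    n_genes = nrow(x),
    n_sig_dom = sum(x$p_dom < alpha),
    n_sig_rec = sum(x$p_rec < alpha),
    n_sig_dom_bonferroni = sum(x$p_dom_bonferroni < alpha),
    n_sig_rec_bonferroni = sum(x$p_rec_bonferroni < alpha)
  )
}
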