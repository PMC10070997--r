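#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a tumor-specificity screen
#'
#' One row per gene: the minimum fold change over included healthy tissues,
#' the tissue attaining it, the worst adjusted p, the biotype, and the pass
#' flag (the per-gene table behind the min-FC volcano).
#'
#' @param x A `taa_screen` from [screen_specificity()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy taa_screen
#' @export
tidy.taa_screen <- function(x, ...) {
  x$specificity
}

#' One-row summary of a tumor-specificity screen
#'
#' @param x A `taa_screen` from [screen_specificity()].
#' @param ... Unused.
#' @return A one-row tibble: genes tested, healthy tissues compared, tissues
#'   excluded, candidate count, and the thresholds applied.
#' @method glance taa_screen
#' @export
glance.taa_screen <- function(x, ...) {
  tibble(
    n_genes = nrow(x$specificity),
    n_tissues = x$specificity$n_tissues_compared[1],
    n_excluded_tissues = length(x$params$excluded_tissues),
    n_pass = sum(x$specificity$passes),
    fc_threshold = x$params$fc_threshold,
    alpha = x$params$alpha,
    expression_min = x$params$expression_min
  )
}
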