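#' Relative expression against a three-gene housekeeping reference
#'
#' For each sample, the reference Ct is the arithmetic mean of the three
#' housekeeping Cts (equivalently, the geometric mean of their expression
#' levels), set at 100%. A target's relative expression is then
#' `100 * efficiency^(reference_ct - target_ct)`: a target one cycle later
#' than the reference sits at 50% under perfect doubling.
#'
#' @param ct Long Ct tibble with columns `sample_id`, `gene`, `ct`.
#' @param targets Target genes to report (default: every non-housekeeping
#'   gene in the table).
#' @param hkg Exactly three housekeeping gene names (default GUSB, VPS29,
#'   PSMB4).
#' @param efficiency Amplification efficiency per cycle (default 2, perfect
#'   doubling).
#' @return A tibble with columns `sample_id`, `gene`,
#'   `relative_expression_percent`.
#' @examples
#' ct <- tibble::tibble(
#'   sample_id = "s1",
#'   gene = c("GUSB", "VPS29", "PSMB4", "PRAME"),
#'   ct = c(20, 21, 22, 26.5)
#' )
#' relative_expression(ct) # 100 * 2^(21 - 26.5) ~ 2.21%
#' @export
relative_expression <- function(ct, targets = NULL,
                                hkg = c("GUSB", "VPS29", "PSMB4"),
                                efficiency = 2) {
  if (length(hkg) != 3) abort("exactly three housekeeping genes are required")
  if (efficiency <= 1) abort("amplification efficiency must exceed 1")
  if (any(!is.finite(ct$ct))) abort("Ct values must be finite")
  targets <- targets %||% setdiff(unique(ct$gene), hkg)
  if (length(targets) == 0) abort("no target genes to report")

  refs <- ct |>
    filter(.data$gene %in% hkg) |>
    group_by(.data$sample_id) |>
    summarise(
      n_hkg = dplyr::n_distinct(.data$gene),
      reference_ct = mean(.data$ct),
      .groups = "drop"
    )
  incomplete <- refs$sample_id[refs$n_hkg < 3]
  all_missing <- setdiff(unique(ct$sample_id), refs$sample_id)
  if (length(incomplete) || length(all_missing)) {
    bad <- c(incomplete, all_missing)[1]
    miss <- setdiff(hkg, ct$gene[ct$sample_id == bad])
    abort(paste0(
      "sample ", bad, " is missing housekeeping measurement(s): ",
      paste(miss, collapse = ", ")
    ))
  }

  ct |>
    filter(.data$gene %in% targets) |>
    left_join(refs[, c("sample_id", "reference_ct")], by = "sample_id") |>
    transmute(
      .data$sample_id,
      .data$gene,
      relative_expression_percent =
        100 * efficiency^(.data$reference_ct - .data$ct)
    ) |>
    arrange(.data$sample_id, .data$gene)
}
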