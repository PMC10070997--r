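#' Merge multi-source count tables into one atlas
#'
#' Restricts all tables to their common gene universe (in the first table's
#' gene order), concatenates samples, and applies the per-source subsampling
#' caps within each (source, tissue) group by seeded uniform sampling without
#' replacement. Defaults mirror the pooled-atlas construction convention:
#' tumor cohorts capped at 30 samples, bulk-healthy at 20, protein-atlas
#' uncapped.
#'
#' @param atlases A list of [count_atlas()] objects (a single atlas is
#'   accepted and re-capped).
#' @param caps Named numeric vector of per-source caps; `Inf` disables a cap.
#' @param seed Integer seed for the subsampling draw.
#' @return A merged, capped [count_atlas()].
#' @export
assemble_atlas <- function(atlases, caps = SOURCE_CAPS, seed = 1) {
  if (inherits(atlases, "count_atlas")) atlases <- list(atlases)
  stopifnot(length(atlases) >= 1)
  gene_sets <- map(atlases, function(a) rownames(a$counts))
  shared <- Reduce(intersect, gene_sets)
  if (length(shared) == 0) abort("empty gene intersection across tables")
  shared <- gene_sets[[1]][gene_sets[[1]] %in% shared]

  all_samples <- unlist(map(atlases, function(a) a$samples$sample_id))
  if (anyDuplicated(all_samples)) {
    abort("duplicate sample ids across tables")
  }

  counts <- do.call(cbind, map(atlases, function(a) {
    a$counts[shared, , drop = FALSE]
  }))
  samples <- bind_rows(map(atlases, function(a) a$samples))
  genes <- atlases[[1]]$genes[match(shared, atlases[[1]]$genes$gene_id), ]

  keep <- withr::with_seed(seed, {
    samples |>
      mutate(.idx = dplyr::row_number()) |>
      group_by(.data$source, .data$tissue) |>
      group_map(function(g, key) {
        cap <- caps[[key$source]] %||% Inf
        if (nrow(g) > cap) g$.idx[sort(sample.int(nrow(g), cap))] else g$.idx
      }) |>
      unlist() |>
      sort()
  })

  count_atlas(
    counts[, keep, drop = FALSE],
    samples[keep, , drop = FALSE],
    genes
  )
}

#' Relative-log-expression (median-of-ratios) size factors
#'
#' The per-gene reference is the geometric mean of counts across samples,
#' using only genes with nonzero counts in every sample (the geometric mean is
#' undefined otherwise); each sample's factor is the median over those genes
#' of count/reference. Factors are left unrescaled: downstream counts-per-
#' million are invariant to a global rescale.
#'
#' @param x A [count_atlas()] or a counts matrix with dimnames.
#' @return A tibble with columns `sample_id`, `size_factor`, carrying the
#'   per-gene reference log-means in attribute `reference_log_means`.
#' @examples
#' m <- matrix(c(2, 4, 8, 4, 8, 16), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("A", "B")))
#' compute_size_factors(m) # (1/sqrt(2), sqrt(2))
#' @export
compute_size_factors <- function(x) {
  counts <- if (inherits(x, "count_atlas")) x$counts else as.matrix(x)
  usable <- rowSums(counts == 0) == 0
  if (!any(usable)) {
    abort("degenerate matrix: no gene has nonzero counts in every sample")
  }
  ref_log <- rowMeans(log(counts[usable, , drop = FALSE]))
  ratios <- counts[usable, , drop = FALSE] / exp(ref_log)
  factors <- apply(ratios, 2, median)
  out <- tibble(sample_id = colnames(counts), size_factor = unname(factors))
  attr(out, "reference_log_means") <-
    setNames(ref_log, rownames(counts)[usable])
  out
}

#' Log2 counts-per-million on effective library sizes
#'
#' Effective library size is the raw column sum times the sample's size
#' factor; each value is `log2((count + prior_count) / effective_lib * 1e6)`.
#' The prior count keeps zeros finite.
#'
#' @param x A [count_atlas()] or counts matrix.
#' @param factors Size-factor tibble from [compute_size_factors()]; computed
#'   from `x` when omitted.
#' @param prior_count Non-negative pseudo-count added before the log.
#' @return A real matrix of log2 CPM values, same dimnames as the counts.
#' @export
normalize_cpm <- function(x, factors = NULL, prior_count = 0.5) {
  counts <- if (inherits(x, "count_atlas")) x$counts else as.matrix(x)
  if (prior_count < 0) abort("prior_count must be >= 0")
  factors <- factors %||% compute_size_factors(counts)
  f <- factors$size_factor[match(colnames(counts), factors$sample_id)]
  if (anyNA(f)) abort("size factors must cover every sample")
  eff_lib <- colSums(counts) * f
  if (any(eff_lib <= 0)) abort("zero effective library size")
  log2(sweep(counts + prior_count, 2, eff_lib, `/`) * 1e6)
}

#' Filter genes by evidence of expression in the tumor cohort
#'
#' Retains genes whose mean count over the tumor samples is at or above the
#' threshold, preserving gene order. The threshold applies to raw counts by
#' default ("read counts"); set `use_normalized = TRUE` to apply it to
#' size-factor-normalized counts instead.
#'
#' @param atlas A [count_atlas()].
#' @param threshold Minimum mean count (default 100).
#' @param use_normalized Apply the threshold to normalized counts.
#' @param factors Size factors, required when `use_normalized = TRUE`
#'   (computed on the fly when omitted).
#' @return The filtered [count_atlas()].
#' @export
filter_expressed <- function(atlas, threshold = 100, use_normalized = FALSE,
                             factors = NULL) {
  tumor <- atlas$samples$is_tumor
  if (!any(tumor)) abort("atlas contains no tumor samples")
  m <- atlas$counts[, tumor, drop = FALSE]
  if (use_normalized) {
    factors <- factors %||% compute_size_factors(atlas)
    f <- factors$size_factor[match(colnames(m), factors$sample_id)]
    m <- sweep(m, 2, f, `/`)
  }
  subset_atlas(atlas, genes = which(rowMeans(m) >= threshold))
}
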