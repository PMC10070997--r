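#' Moment-based negative-binomial dispersion estimation
#'
#' Per-gene method-of-moments estimate of the NB dispersion \eqn{\phi}
#' (variance \eqn{\mu + \phi\mu^2}) from within-group residual variance on
#' the size-factor-normalized scale, floored at zero, then shrunk toward a
#' common (trimmed-mean) estimate:
#' `phi_tagwise = (1 - w) * phi_gene + w * phi_common`.
#'
#' For a group with \eqn{n_g} samples the expected residual sum of squares of
#' the normalized counts is
#' \eqn{(1 - 1/n_g)\,\lambda \sum_j 1/s_j + (n_g - 1)\,\phi\,\lambda^2};
#' solving for \eqn{\phi} across all groups with \eqn{n_g \ge 2} gives the
#' per-gene estimate.
#'
#' @param atlas A [count_atlas()].
#' @param factors Size factors (computed from the atlas when omitted).
#' @param shrink_weight Weight `w` in `[0, 1]` on the common estimate.
#' @param trim Trim fraction for the common (trimmed-mean) estimate.
#' @return A tibble with columns `gene_id`, `phi_gene`, `phi_tagwise`, with
#'   the common estimate and weight in attributes `common` / `shrink_weight`.
#' @export
estimate_dispersions <- function(atlas, factors = NULL, shrink_weight = 0.3,
                                 trim = 0.25) {
  stopifnot(shrink_weight >= 0, shrink_weight <= 1)
  factors <- factors %||% compute_size_factors(atlas)
  counts <- atlas$counts
  s <- factors$size_factor[match(colnames(counts), factors$sample_id)]
  groups <- atlas$samples$tissue
  group_sizes <- table(groups)
  usable_groups <- names(group_sizes)[group_sizes >= 2]
  if (length(usable_groups) == 0) {
    warn("all tissue groups are singletons; returning common dispersion 0")
    out <- tibble(
      gene_id = rownames(counts),
      phi_gene = 0,
      phi_tagwise = 0
    )
    attr(out, "common") <- 0
    attr(out, "shrink_weight") <- shrink_weight
    return(out)
  }

  z <- sweep(counts, 2, s, `/`)
  ss <- numeric(nrow(counts))
  poisson_part <- numeric(nrow(counts))
  quad_part <- numeric(nrow(counts))
  for (g in usable_groups) {
    idx <- which(groups == g)
    n_g <- length(idx)
    zg <- z[, idx, drop = FALSE]
    lam <- rowMeans(zg)
    ss <- ss + rowSums((zg - lam)^2)
    poisson_part <- poisson_part + (1 - 1 / n_g) * lam * sum(1 / s[idx])
    quad_part <- quad_part + (n_g - 1) * lam^2
  }
  phi_gene <- ifelse(quad_part > 0, pmax((ss - poisson_part) / quad_part, 0), 0)
  informative <- quad_part > 0
  common <- if (any(informative)) {
    mean(phi_gene[informative], trim = trim)
  } else {
    0
  }
  out <- tibble(
    gene_id = rownames(counts),
    phi_gene = unname(phi_gene),
    phi_tagwise = unname((1 - shrink_weight) * phi_gene +
                           shrink_weight * common)
  )
  attr(out, "common") <- common
  attr(out, "shrink_weight") <- shrink_weight
  out
}

# Vectorized NB mean MLE with per-sample exposure s and per-gene dispersion
# phi: solves sum_j (y_ij - s_j * lam_i) / (1 + phi_i * s_j * lam_i) = 0 by
# damped Newton iteration (exact at phi = 0, where the solution is the
# exposure-weighted mean).
nb_mean_mle <- function(y, s, phi, max_iter = 100, tol = 1e-12) {
  y <- as.matrix(y)
  smat <- matrix(s, nrow(y), length(s), byrow = TRUE)
  lam <- pmax(rowSums(y) / sum(s), 1e-12)
  for (i in seq_len(max_iter)) {
    d <- 1 + (phi * lam) * smat
    score <- rowSums((y - lam * smat) / d)
    info <- rowSums(smat * (1 + phi * y) / d^2)
    step <- score / info
    lam_new <- lam + step
    lam_new <- ifelse(lam_new > 0, lam_new, lam / 10)
    done <- max(abs(lam_new - lam)) <= tol * (1 + max(lam))
    lam <- lam_new
    if (done) break
  }
  lam
}

nb_loglik <- function(y, s, phi, lam) {
  y <- as.matrix(y)
  mu <- pmax(lam, 1e-12) * matrix(s, nrow(y), length(s), byrow = TRUE)
  ll <- matrix(NA_real_, nrow(y), ncol(y))
  pos <- phi > 0
  if (any(pos)) {
    ll[pos, ] <- dnbinom(
      y[pos, , drop = FALSE],
      size = 1 / phi[pos],
      mu = mu[pos, , drop = FALSE],
      log = TRUE
    )
  }
  if (any(!pos)) {
    ll[!pos, ] <- dpois(
      y[!pos, , drop = FALSE],
      lambda = mu[!pos, , drop = FALSE],
      log = TRUE
    )
  }
  rowSums(ll)
}

#' Likelihood-ratio contrast of the tumor cohort against one healthy tissue
#'
#' Per gene, tests equality of the NB means of the two groups (library-size
#' factors as exposures, dispersion fixed at the tagwise estimate) with a
#' likelihood-ratio statistic referred to \eqn{\chi^2_1}. The reported fold
#' change is the ratio of normalized group means with a pseudo-count:
#' `log2((mean_tumor + prior) / (mean_tissue + prior))`.
#'
#' @param atlas A [count_atlas()].
#' @param factors Size factors covering both sample sets.
#' @param dispersions Tibble from [estimate_dispersions()] (or a numeric
#'   vector of per-gene dispersions in gene order).
#' @param tumor_samples,tissue_samples Disjoint, nonempty character vectors of
#'   sample ids.
#' @param prior_count Pseudo-count used in the fold-change ratio.
#' @return A tibble with columns `gene_id`, `log2_fold_change`, `statistic`,
#'   `p_value`.
#' @export
test_contrast <- function(atlas, factors, dispersions, tumor_samples,
                          tissue_samples, prior_count = 0.5) {
  if (length(tumor_samples) == 0 || length(tissue_samples) == 0) {
    abort("both sample sets must be nonempty")
  }
  if (length(intersect(tumor_samples, tissue_samples)) > 0) {
    abort("tumor and tissue sample sets overlap")
  }
  counts <- atlas$counts
  missing <- setdiff(c(tumor_samples, tissue_samples), colnames(counts))
  if (length(missing)) {
    abort(paste0("samples not in atlas: ", paste(missing, collapse = ", ")))
  }
  phi <- if (is.numeric(dispersions)) {
    dispersions
  } else {
    dispersions$phi_tagwise[match(rownames(counts), dispersions$gene_id)]
  }
  s_all <- factors$size_factor[match(colnames(counts), factors$sample_id)]
  names(s_all) <- colnames(counts)

  y1 <- counts[, tumor_samples, drop = FALSE]
  y2 <- counts[, tissue_samples, drop = FALSE]
  s1 <- s_all[tumor_samples]
  s2 <- s_all[tissue_samples]

  lam1 <- nb_mean_mle(y1, s1, phi)
  lam2 <- nb_mean_mle(y2, s2, phi)
  lam0 <- nb_mean_mle(cbind(y1, y2), c(s1, s2), phi)

  ll_alt <- nb_loglik(y1, s1, phi, lam1) + nb_loglik(y2, s2, phi, lam2)
  ll_null <- nb_loglik(cbind(y1, y2), c(s1, s2), phi, lam0)
  statistic <- pmax(2 * (ll_alt - ll_null), 0)

  m1 <- rowMeans(sweep(y1, 2, s1, `/`))
  m2 <- rowMeans(sweep(y2, 2, s2, `/`))

  tibble(
    gene_id = rownames(counts),
    log2_fold_change = unname(log2((m1 + prior_count) / (m2 + prior_count))),
    statistic = unname(statistic),
    p_value = unname(pchisq(statistic, df = 1, lower.tail = FALSE))
  )
}

#' Contrast the tumor cohort against every healthy tissue
#'
#' Runs [test_contrast()] for each non-tumor tissue in the atlas and adjusts
#' p-values with [adjust_fdr()] within each tissue contrast (across genes).
#'
#' @inheritParams test_contrast
#' @param tissues Healthy tissues to test (default: all non-tumor tissues).
#' @return A long tibble with columns `gene_id`, `tissue`,
#'   `log2_fold_change`, `statistic`, `p_value`, `adjusted_p`.
#' @export
test_contrasts <- function(atlas, factors = NULL, dispersions = NULL,
                           tissues = NULL, prior_count = 0.5) {
  factors <- factors %||% compute_size_factors(atlas)
  dispersions <- dispersions %||% estimate_dispersions(atlas, factors)
  tumor <- tumor_sample_ids(atlas)
  if (length(tumor) == 0) abort("atlas contains no tumor samples")
  healthy <- unique(atlas$samples$tissue[!atlas$samples$is_tumor])
  tissues <- tissues %||% healthy
  map(tissues, function(t) {
    ids <- atlas$samples$sample_id[atlas$samples$tissue == t &
                                     !atlas$samples$is_tumor]
    test_contrast(atlas, factors, dispersions, tumor, ids, prior_count) |>
      mutate(tissue = t, .after = "gene_id")
  }) |>
    list_rbind() |>
    group_by(.data$tissue) |>
    mutate(adjusted_p = adjust_fdr(.data$p_value)) |>
    ungroup()
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (monotone after sorting, `>=` raw).
#' @export
adjust_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Aggregate per-tissue contrasts into tumor-specificity records
#'
#' Per gene, over the included healthy tissues (reproductive and other-tumor
#' tissues are the conventional exclusions): the minimum tumor-over-tissue
#' fold change (signed, so any healthy tissue expressed at or above the tumor
#' drives min FC to 1 or below), the tissue attaining it, and the worst
#' (maximum) adjusted p. A gene passes when
#' `min_fold_change >= fc_threshold` and `worst_adjusted_p <= alpha`
#' (both boundaries inclusive) and, when the biotype filter is on, its
#' biotype is `protein_coding`.
#'
#' @param contrasts Tibble from [test_contrasts()].
#' @param gene_annotation Tibble with `gene_id`, `biotype`.
#' @param excluded_tissues Tissues left out of the aggregation.
#' @param fc_threshold Minimum fold change required (default 20).
#' @param alpha FDR level (default 0.05).
#' @param biotype_filter Require `protein_coding` biotype for a pass.
#' @return A tibble with one row per gene: `gene_id`, `min_fold_change`,
#'   `min_log2_fold_change`, `worst_adjusted_p`, `limiting_tissue`,
#'   `n_tissues_compared`, `biotype`, `passes`.
#' @export
aggregate_specificity <- function(contrasts, gene_annotation,
                                  excluded_tissues = character(),
                                  fc_threshold = 20, alpha = 0.05,
                                  biotype_filter = TRUE) {
  included <- setdiff(unique(contrasts$tissue), excluded_tissues)
  if (length(included) == 0) abort("no tissues left after exclusions")
  kept <- contrasts[contrasts$tissue %in% included, ]

  complete <- kept |>
    count(.data$gene_id) |>
    filter(.data$n < length(included))
  if (nrow(complete) > 0) {
    g <- complete$gene_id[1]
    miss <- setdiff(included, kept$tissue[kept$gene_id == g])
    abort(paste0(
      "missing contrast for gene ", g, " in tissue ",
      paste(miss, collapse = ", ")
    ))
  }

  out <- kept |>
    group_by(.data$gene_id) |>
    summarise(
      min_log2_fold_change = min(.data$log2_fold_change),
      limiting_tissue = .data$tissue[which.min(.data$log2_fold_change)],
      worst_adjusted_p = max(.data$adjusted_p),
      n_tissues_compared = dplyr::n(),
      .groups = "drop"
    ) |>
    mutate(
      min_fold_change = 2^.data$min_log2_fold_change,
      .before = "min_log2_fold_change"
    ) |>
    left_join(
      gene_annotation[, c("gene_id", "biotype")],
      by = "gene_id"
    ) |>
    mutate(
      passes = .data$min_fold_change >= fc_threshold &
        .data$worst_adjusted_p <= alpha &
        (!biotype_filter | .data$biotype == "protein_coding")
    )
  out[match(intersect(unique(contrasts$gene_id), out$gene_id), out$gene_id), ]
}

#' Run the full tumor-specificity screen on an atlas
#'
#' Convenience wrapper chaining size factors, the minimum-expression filter,
#' dispersion estimation, per-tissue likelihood-ratio contrasts, FDR
#' adjustment and min-fold-change aggregation. Reproductive tissues are
#' excluded from the aggregation by default (taken from the sample
#' annotation).
#'
#' @param atlas A [count_atlas()].
#' @param expression_min Minimum tumor-cohort mean raw count (default 100).
#' @param fc_threshold,alpha Pass thresholds (defaults 20 and 0.05).
#' @param excluded_tissues Tissues excluded from aggregation; defaults to the
#'   reproductive tissues flagged in the sample annotation.
#' @param prior_count Pseudo-count for fold changes and log-CPM.
#' @param shrink_weight Dispersion shrinkage weight.
#' @param biotype_filter Require `protein_coding` biotype for a pass.
#' @return A `taa_screen` object; see [tidy.taa_screen()],
#'   [glance.taa_screen()] and [autoplot.taa_screen()].
#' @examples
#' cfg <- sim_config(
#'   seed = 1,
#'   panel = default_tissue_panel(n_bulk = 5, n_protein_atlas = 2),
#'   n_genes = 150, library_size_cv = 0.2,
#'   planted = planted_genes("PRAME_like", fold_change = 200,
#'                           tumor_mean = 2000)
#' )
#' screen <- simulate_counts(cfg) |> screen_specificity()
#' tidy(screen) |> dplyr::filter(passes)
#' @export
screen_specificity <- function(atlas, expression_min = 100,
                               fc_threshold = 20, alpha = 0.05,
                               excluded_tissues = NULL,
                               prior_count = 0.5, shrink_weight = 0.3,
                               biotype_filter = TRUE) {
  factors <- compute_size_factors(atlas)
  filtered <- filter_expressed(atlas, threshold = expression_min)
  if (nrow(filtered$counts) == 0) abort("no genes pass the expression filter")
  dispersions <- estimate_dispersions(
    filtered, factors,
    shrink_weight = shrink_weight
  )
  contrasts <- test_contrasts(
    filtered, factors, dispersions,
    prior_count = prior_count
  )
  excluded_tissues <- excluded_tissues %||%
    unique(atlas$samples$tissue[atlas$samples$is_reproductive])
  specificity <- aggregate_specificity(
    contrasts, filtered$genes,
    excluded_tissues = excluded_tissues,
    fc_threshold = fc_threshold, alpha = alpha,
    biotype_filter = biotype_filter
  )
  structure(
    list(
      specificity = specificity,
      contrasts = contrasts,
      dispersions = dispersions,
      size_factors = factors,
      atlas = filtered,
      params = list(
        expression_min = expression_min,
        fc_threshold = fc_threshold,
        alpha = alpha,
        excluded_tissues = excluded_tissues,
        prior_count = prior_count,
        shrink_weight = shrink_weight,
        biotype_filter = biotype_filter
      )
    ),
    class = "taa_screen"
  )
}

#' @export
print.taa_screen <- function(x, ...) {
  cat(
    "<taa_screen> ", nrow(x$specificity), " genes x ",
    x$specificity$n_tissues_compared[1], " healthy tissues; ",
    sum(x$specificity$passes), " candidate gene(s) at min FC >= ",
    x$params$fc_threshold, ", FDR <= ", x$params$alpha, "\n",
    sep = ""
  )
  invisible(x)
}

#' Per-group expression summaries with fold-change reference lines
#'
#' Five-number box summaries (min, Q1, median, Q3, max) of log2 CPM per gene
#' and tissue group, with two reference lines per gene: the reference group's
#' median and that median minus `log2(fc_threshold)` (the "20-times-lower"
#' line when `fc_threshold = 20`).
#'
#' @param cpm Log2 CPM matrix from [normalize_cpm()].
#' @param groups Character vector of group labels aligned to the matrix
#'   columns (or a sample annotation tibble, whose `tissue` column is used).
#' @param reference_group Group providing the reference median (the tumor).
#' @param genes Genes to summarise (default: all rows).
#' @param fc_threshold Fold change marked by the lower reference line.
#' @return A tibble with columns `gene_id`, `group`, `n`, `min`, `q1`,
#'   `median`, `q3`, `max`, `ref_median`, `ref_lower`.
#' @export
summarize_expression <- function(cpm, groups, reference_group, genes = NULL,
                                 fc_threshold = 20) {
  if (is.data.frame(groups)) groups <- groups$tissue
  if (length(groups) != ncol(cpm)) {
    abort("groups must align with the matrix columns")
  }
  if (!reference_group %in% groups) {
    abort(paste0("unknown reference group: ", reference_group))
  }
  genes <- genes %||% rownames(cpm)
  missing <- setdiff(genes, rownames(cpm))
  if (length(missing)) {
    abort(paste0("genes not in matrix: ", paste(missing, collapse = ", ")))
  }
  grid <- tidyr::expand_grid(gene_id = genes, group = unique(groups))
  out <- grid |>
    mutate(stats = map2(.data$gene_id, .data$group, function(g, grp) {
      v <- cpm[g, groups == grp]
      q <- unname(quantile(v, c(0, 0.25, 0.5, 0.75, 1)))
      tibble(
        n = length(v), min = q[1], q1 = q[2], median = q[3],
        q3 = q[4], max = q[5]
      )
    })) |>
    tidyr::unnest("stats")
  ref <- out |>
    filter(.data$group == reference_group) |>
    transmute(
      .data$gene_id,
      ref_median = .data$median,
      ref_lower = .data$median - log2(fc_threshold)
    )
  left_join(out, ref, by = "gene_id")
}
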