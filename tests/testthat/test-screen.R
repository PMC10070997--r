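unit_factors <- function(ids) {
  tibble::tibble(sample_id = ids, size_factor = 1)
}

flat_atlas <- function(counts, tissue, is_tumor) {
  count_atlas(
    counts,
    tibble::tibble(
      sample_id = colnames(counts),
      source = ifelse(is_tumor, "tumor-atlas", "bulk-healthy"),
      tissue = tissue,
      is_tumor = is_tumor,
      is_reproductive = FALSE
    ),
    tibble::tibble(gene_id = rownames(counts), biotype = "protein_coding")
  )
}

test_that("dispersion estimation recovers the generating dispersion", {
  panel <- default_tissue_panel(n_bulk = 5, n_protein_atlas = 0)

  pois <- simulate_counts(sim_config(
    seed = 31, panel = panel, n_genes = 2000, dispersion = 0,
    library_size_cv = 0.2,
    baseline_log_mean_range = c(log(50), log(500))
  ))
  d0 <- estimate_dispersions(pois)
  expect_lte(median(d0$phi_tagwise), 0.01)

  nb <- simulate_counts(sim_config(
    seed = 32, panel = panel, n_genes = 2000, dispersion = 0.1,
    library_size_cv = 0.2,
    baseline_log_mean_range = c(log(50), log(500))
  ))
  d1 <- estimate_dispersions(nb)
  expect_gte(median(d1$phi_tagwise), 0.05)
  expect_lte(median(d1$phi_tagwise), 0.2)

  # constant counts within every group: zero residual variance, phi = 0
  const <- matrix(rep(c(10, 20, 30), each = 4), 3, byrow = TRUE,
                  dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  a <- flat_atlas(const, tissue = rep(c("t1", "t2"), each = 2),
                  is_tumor = rep(c(TRUE, FALSE), each = 2))
  expect_equal(
    estimate_dispersions(a, unit_factors(colnames(const)))$phi_gene,
    rep(0, 3)
  )

  # all-singleton groups degrade gracefully
  single <- flat_atlas(const[, 1:2], tissue = c("t1", "t2"),
                       is_tumor = c(TRUE, FALSE))
  expect_warning(
    ds <- estimate_dispersions(single, unit_factors(colnames(const)[1:2])),
    "singleton"
  )
  expect_equal(attr(ds, "common"), 0)
})

test_that("the likelihood-ratio contrast behaves at the MLE and in arithmetic", {
  # identical data on both sides of the split: statistic 0, p = 1
  block <- matrix(rpois(20, 50), 5,
                  dimnames = list(paste0("g", 1:5), paste0("a", 1:4)))
  twin <- cbind(block, block)
  colnames(twin) <- paste0("s", 1:8)
  atlas <- flat_atlas(twin, tissue = rep(c("tum", "h1"), each = 4),
                      is_tumor = rep(c(TRUE, FALSE), each = 4))
  res <- test_contrast(
    atlas, unit_factors(colnames(twin)), rep(0.1, 5),
    tumor_samples = paste0("s", 1:4), tissue_samples = paste0("s", 5:8)
  )
  expect_equal(res$statistic, rep(0, 5), tolerance = 1e-8)
  expect_equal(res$p_value, rep(1, 5), tolerance = 1e-8)

  # normalized tumor mean 400 vs tissue mean 20 at prior 0: FC exactly 20
  m <- matrix(c(rep(400, 3), rep(20, 3)), 1, byrow = TRUE,
              dimnames = list("g1", paste0("s", 1:6)))
  a2 <- flat_atlas(m, tissue = rep(c("tum", "h1"), each = 3),
                   is_tumor = rep(c(TRUE, FALSE), each = 3))
  r2 <- test_contrast(
    a2, unit_factors(colnames(m)), 0.1,
    tumor_samples = paste0("s", 1:3), tissue_samples = paste0("s", 4:6),
    prior_count = 0
  )
  expect_equal(r2$log2_fold_change, log2(20), tolerance = 1e-12)

  expect_error(
    test_contrast(a2, unit_factors(colnames(m)), 0.1,
                  paste0("s", 1:3), paste0("s", 3:6)),
    "overlap"
  )
})

test_that("LRT p-values match a brute-force likelihood-maximization oracle", {
  panel <- tissue_panel(
    tissue = c("tum", "h1"), source = c("protein-atlas", "protein-atlas"),
    n_available = c(5, 5), is_tumor = c(TRUE, FALSE)
  )
  atlas <- simulate_counts(sim_config(
    seed = 77, panel = panel, n_genes = 200, dispersion = 0.1,
    library_size_cv = 0.25
  ))
  f <- compute_size_factors(atlas)
  phi <- rep(0.1, 200)
  res <- test_contrast(
    atlas, f, phi,
    tumor_samples = atlas$samples$sample_id[atlas$samples$is_tumor],
    tissue_samples = atlas$samples$sample_id[!atlas$samples$is_tumor]
  )
  s <- f$size_factor
  tum <- atlas$samples$is_tumor
  oracle <- vapply(seq_len(200), function(i) {
    bf_nb_lrt(
      atlas$counts[i, tum], atlas$counts[i, !tum],
      s[tum], s[!tum], 0.1
    )
  }, numeric(1))
  expect_lt(max(abs(res$p_value - oracle)), 1e-4)

  # Poisson limit: phi = 0 equals the Poisson LRT
  res0 <- test_contrast(
    atlas, f, rep(0, 200),
    tumor_samples = atlas$samples$sample_id[tum],
    tissue_samples = atlas$samples$sample_id[!tum]
  )
  oracle0 <- vapply(seq_len(200), function(i) {
    bf_nb_lrt(
      atlas$counts[i, tum], atlas$counts[i, !tum],
      s[tum], s[!tum], 0
    )
  }, numeric(1))
  expect_lt(max(abs(res0$p_value - oracle0)), 1e-4)
})

test_that("BH adjustment matches the textbook step-up", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(adjust_fdr(0.42), 0.42)
  set.seed(55)
  p <- runif(1000)^2
  expect_equal(adjust_fdr(p), bf_bh(p))
  expect_true(all(adjust_fdr(p) >= p))
  expect_error(adjust_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("specificity aggregation takes the min FC over included tissues", {
  contrasts <- tidyr::expand_grid(
    gene_id = "g1",
    tissue = c("brain", "endometrium", "skin")
  ) |>
    dplyr::mutate(
      log2_fold_change = log2(c(25, 19, 30)),
      statistic = 50,
      p_value = 1e-6,
      adjusted_p = 1e-5
    )
  ann <- tibble::tibble(gene_id = "g1", biotype = "protein_coding")

  all_in <- aggregate_specificity(contrasts, ann)
  expect_equal(all_in$min_fold_change, 19, tolerance = 1e-12)
  expect_equal(all_in$limiting_tissue, "endometrium")
  expect_false(all_in$passes)

  # excluding the limiting reproductive tissue flips the verdict
  excl <- aggregate_specificity(contrasts, ann,
                                excluded_tissues = "endometrium")
  expect_equal(excl$min_fold_change, 25, tolerance = 1e-12)
  expect_true(excl$passes)

  # single included tissue: min FC is that contrast's FC
  solo <- aggregate_specificity(
    contrasts, ann,
    excluded_tissues = c("endometrium", "skin")
  )
  expect_equal(solo$min_fold_change, 25, tolerance = 1e-12)
  expect_equal(solo$n_tissues_compared, 1L)

  # a gene missing one included tissue's contrast is reported by name
  two_genes <- dplyr::bind_rows(
    contrasts,
    dplyr::mutate(contrasts, gene_id = "g2")
  )
  ann2 <- tibble::tibble(gene_id = c("g1", "g2"), biotype = "protein_coding")
  expect_error(
    aggregate_specificity(two_genes[-2, ], ann2),
    "g1.*endometrium"
  )
})

test_that("pass rule is inclusive at both thresholds and biotype-aware", {
  mk <- function(fc, padj, biotype) {
    contrasts <- tibble::tibble(
      gene_id = "g", tissue = "t1",
      log2_fold_change = log2(fc), statistic = 1,
      p_value = padj, adjusted_p = padj
    )
    aggregate_specificity(
      contrasts,
      tibble::tibble(gene_id = "g", biotype = biotype)
    )$passes
  }
  expect_true(mk(20, 0.05, "protein_coding"))    # both boundaries inclusive
  expect_false(mk(19.999, 0.05, "protein_coding"))
  expect_false(mk(20, 0.0501, "protein_coding"))
  expect_false(mk(20, 0.05, "pseudogene"))       # biotype filter

  # 9 passing genes of which 6 non-protein-coding: 3 final candidates
  contrasts <- tidyr::expand_grid(
    gene_id = sprintf("g%02d", 1:9), tissue = c("t1", "t2")
  ) |>
    dplyr::mutate(
      log2_fold_change = log2(40), statistic = 60,
      p_value = 1e-8, adjusted_p = 1e-7
    )
  ann <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:9),
    biotype = c(
      rep("protein_coding", 3),
      c("pseudogene", "pseudogene", "pseudogene", "miRNA", "antisense",
        "lncRNA")
    )
  )
  spec <- aggregate_specificity(contrasts, ann)
  expect_equal(sum(spec$passes), 3)
  expect_equal(
    sum(aggregate_specificity(contrasts, ann, biotype_filter = FALSE)$passes),
    9
  )
})

test_that("min FC never increases when a healthy tissue is added", {
  set.seed(91)
  base <- tidyr::expand_grid(
    gene_id = sprintf("g%02d", 1:20),
    tissue = sprintf("t%02d", 1:8)
  ) |>
    dplyr::mutate(
      log2_fold_change = rnorm(dplyr::n(), 4, 2),
      statistic = 1, p_value = runif(dplyr::n()),
      adjusted_p = pmin(p_value * 2, 1)
    )
  ann <- tibble::tibble(gene_id = sprintf("g%02d", 1:20),
                        biotype = "protein_coding")
  for (k in 2:7) {
    smaller <- aggregate_specificity(
      base[base$tissue %in% sprintf("t%02d", 1:k), ], ann
    )
    larger <- aggregate_specificity(
      base[base$tissue %in% sprintf("t%02d", 1:(k + 1)), ], ann
    )
    expect_true(all(
      larger$min_fold_change <= smaller$min_fold_change + 1e-12
    ))
  }
})

test_that("expression summaries give five-number boxes with reference lines", {
  cpm <- matrix(
    c(10, 3, 4, 5, 6, 7, 10, 2, 2, 2, 2, 2), 2, byrow = TRUE,
    dimnames = list(c("gA", "gB"), paste0("s", 1:6))
  )
  groups <- c("tum", rep("h1", 5))
  sm <- summarize_expression(cpm, groups, reference_group = "tum")

  solo <- sm[sm$gene_id == "gA" & sm$group == "tum", ]
  expect_equal(unlist(solo[, c("min", "q1", "median", "q3", "max")]),
               setNames(rep(10, 5), c("min", "q1", "median", "q3", "max")))
  expect_equal(unique(sm$ref_lower[sm$gene_id == "gA"]), 10 - log2(20))

  h1 <- sm[sm$gene_id == "gA" & sm$group == "h1", ]
  v <- c(3, 4, 5, 6, 7)
  expect_equal(unlist(h1[, c("min", "q1", "median", "q3", "max")]),
               setNames(bf_quantile7(v, c(0, 0.25, 0.5, 0.75, 1)),
                        c("min", "q1", "median", "q3", "max")))

  set.seed(17)
  r <- matrix(rnorm(40), 2, dimnames = list(c("gA", "gB"), paste0("x", 1:20)))
  g <- rep(c("tum", "h1"), 10)
  sr <- summarize_expression(r, g, reference_group = "tum")
  for (grp in c("tum", "h1")) {
    row <- sr[sr$gene_id == "gB" & sr$group == grp, ]
    expect_equal(
      unlist(row[, c("min", "q1", "median", "q3", "max")]),
      setNames(bf_quantile7(r["gB", g == grp], c(0, 0.25, 0.5, 0.75, 1)),
               c("min", "q1", "median", "q3", "max"))
    )
  }

  expect_error(summarize_expression(cpm, groups, "nope"), "unknown")
})
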