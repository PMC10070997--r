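#' Construct a count atlas container
#'
#' Light container pairing a genes-by-samples integer count matrix with its
#' sample and gene annotation tables. All analysis functions accept and return
#' this shape; annotations are tibbles so results chain with the pipe.
#'
#' @param counts Non-negative integer matrix, genes in rows, samples in
#'   columns, with row and column names.
#' @param samples Tibble with columns `sample_id`, `source`, `tissue`,
#'   `is_tumor`, `is_reproductive`, one row per matrix column (same order).
#' @param genes Tibble with columns `gene_id`, `biotype`, one row per matrix
#'   row (same order).
#' @return A `count_atlas` object.
#' @export
count_atlas <- function(counts, samples, genes) {
  counts <- as.matrix(counts)
  # a zero-row/zero-column matrix cannot hold non-NULL dimnames in R
  rn <- rownames(counts) %||% character(0)
  cn <- colnames(counts) %||% character(0)
  if (length(rn) != nrow(counts) || length(cn) != ncol(counts)) {
    abort("count matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rn)) abort("duplicate gene ids")
  if (anyDuplicated(cn)) abort("duplicate sample ids")
  if (any(counts < 0)) abort("counts must be non-negative")
  samples <- as_tibble(samples)
  genes <- as_tibble(genes)
  if (!identical(cn, as.character(samples$sample_id %||% character(0)))) {
    abort("sample annotation must match count matrix columns (same order)")
  }
  if (!identical(rn, as.character(genes$gene_id %||% character(0)))) {
    abort("gene annotation must match count matrix rows (same order)")
  }
  structure(
    list(counts = counts, samples = samples, genes = genes),
    class = "count_atlas"
  )
}

#' @export
print.count_atlas <- function(x, ...) {
  cat(
    "<count_atlas> ", nrow(x$counts), " genes x ", ncol(x$counts),
    " samples across ", length(unique(x$samples$tissue)), " tissues (",
    sum(x$samples$is_tumor), " tumor samples)\n",
    sep = ""
  )
  invisible(x)
}

#' @export
dim.count_atlas <- function(x) dim(x$counts)

# Subset an atlas by gene and/or sample index, keeping annotations in step.
subset_atlas <- function(atlas, genes = NULL, samples = NULL) {
  gi <- genes %||% seq_len(nrow(atlas$counts))
  si <- samples %||% seq_len(ncol(atlas$counts))
  count_atlas(
    atlas$counts[gi, si, drop = FALSE],
    atlas$samples[si, , drop = FALSE],
    atlas$genes[gi, , drop = FALSE]
  )
}

tumor_sample_ids <- function(atlas) {
  atlas$samples$sample_id[atlas$samples$is_tumor]
}

#' Simulate a multi-source tumor/healthy count atlas
#'
#' Draws a genes-by-samples raw count matrix with the statistical structure
#' the screen assumes: negative-binomial counts (variance
#' \eqn{\mu + \phi\mu^2}), log-normal per-sample library-size factors, group
#' sizes following the per-source subsampling caps (30 for the tumor cohort,
#' 20 for bulk-healthy tissues, all samples for protein-atlas tissues), and
#' optional planted genes whose expected tumor/healthy mean ratio equals their
#' specified fold change in every healthy tissue.
#'
#' @param config A [sim_config()] object.
#' @return A [count_atlas()] with planted genes listed after background genes.
#' @examples
#' atlas <- simulate_counts(sim_config(
#'   seed = 7,
#'   panel = default_tissue_panel(n_bulk = 4, n_protein_atlas = 2),
#'   n_genes = 50
#' ))
#' atlas
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  panel <- config$panel
  n_planted <- if (is.null(config$planted)) 0L else nrow(config$planted)
  n_genes <- config$n_genes + n_planted
  if (n_genes == 0L) abort("configuration yields zero genes")

  withr::with_seed(config$seed, {
    n_per_tissue <- pmin(panel$n_available, SOURCE_CAPS[panel$source])
    samples <- tibble(
      sample_id = unlist(map2(panel$tissue, n_per_tissue, function(t, n) {
        paste0(t, "_s", sprintf("%02d", seq_len(n)))
      })),
      source = rep(panel$source, n_per_tissue),
      tissue = rep(panel$tissue, n_per_tissue),
      is_tumor = rep(panel$is_tumor, n_per_tissue),
      is_reproductive = rep(panel$is_reproductive, n_per_tissue)
    )
    n_samples <- nrow(samples)
    if (n_samples == 0L) abort("configuration yields zero samples")

    # Background genes share one mean across all tissues (nulls); planted
    # genes get tumor_mean in the tumor cohort and tumor_mean / fold_change in
    # every healthy tissue.
    bg_ids <- if (config$n_genes > 0) {
      paste0("gene", sprintf("%05d", seq_len(config$n_genes)))
    } else {
      character(0)
    }
    bg_mu <- exp(runif(
      config$n_genes,
      config$baseline_log_mean_range[1],
      config$baseline_log_mean_range[2]
    ))
    mu <- matrix(bg_mu, nrow = config$n_genes, ncol = n_samples)
    gene_ids <- bg_ids
    biotypes <- rep(config$background_biotype, config$n_genes)
    if (n_planted > 0) {
      planted_mu <- outer(
        config$planted$tumor_mean,
        as.numeric(samples$is_tumor),
        function(m, t) m
      )
      healthy <- !samples$is_tumor
      planted_mu[, healthy] <- config$planted$tumor_mean /
        config$planted$fold_change
      mu <- rbind(mu, planted_mu)
      gene_ids <- c(gene_ids, config$planted$gene_id)
      biotypes <- c(biotypes, config$planted$biotype)
    }

    # Library-size factors: log-normal with mean 1 and the configured CV.
    size <- if (config$library_size_cv > 0) {
      sdlog <- sqrt(log(1 + config$library_size_cv^2))
      rlnorm(n_samples, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else {
      rep(1, n_samples)
    }

    mu <- sweep(mu, 2, size, `*`)
    counts <- if (config$dispersion > 0) {
      matrix(
        rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
        nrow = n_genes
      )
    } else {
      matrix(rpois(length(mu), lambda = mu), nrow = n_genes)
    }
    dimnames(counts) <- list(gene_ids, samples$sample_id)

    count_atlas(
      counts,
      samples,
      tibble(gene_id = gene_ids, biotype = biotypes)
    )
  })
}

#' Generate a toy proteome with target isoforms and family off-targets
#'
#' Target isoforms share the core region verbatim and each append their own
#' unique C-terminal region. Family members are derived from the canonical
#' target (isoform 1) by substituting `round(length * (1 - identity/100))`
#' aligned positions with a different residue, yielding near-homologs with a
#' known Hamming distance for the uniqueness filter; sequence beyond the
#' aligned prefix is drawn at random.
#'
#' @param spec A [proteome_spec()] object.
#' @return A tibble with columns `protein_id`, `gene`, `isoform` (NA for
#'   family members), `role` (`"target"`, `"target_isoform"` or
#'   `"family_offtarget"`) and `sequence`.
#' @export
simulate_proteome <- function(spec) {
  stopifnot(inherits(spec, "proteome_spec"))
  withr::with_seed(spec$seed, {
    rand_aa <- function(n) {
      paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")
    }
    core <- rand_aa(spec$shared_core_length)
    uniq_len <- rep_len(spec$unique_region_lengths, spec$n_isoforms)
    iso_seq <- map_chr(seq_len(spec$n_isoforms), function(i) {
      paste0(core, if (uniq_len[i] > 0) rand_aa(uniq_len[i]) else "")
    })
    target <- tibble(
      protein_id = paste0(spec$target_gene, "-iso", seq_len(spec$n_isoforms)),
      gene = spec$target_gene,
      isoform = seq_len(spec$n_isoforms),
      role = c("target", rep("target_isoform", spec$n_isoforms - 1)),
      sequence = iso_seq
    )
    fam <- spec$family_members
    family <- if (!is.null(fam) && nrow(fam) > 0) {
      canonical <- strsplit(iso_seq[1], "")[[1]]
      tibble(
        protein_id = fam$name,
        gene = fam$name,
        isoform = NA_integer_,
        role = "family_offtarget",
        sequence = pmap(
          list(fam$identity, fam$length),
          function(identity, len) {
            aligned <- min(len, length(canonical))
            seq_chars <- canonical[seq_len(aligned)]
            n_sub <- round(aligned * (1 - identity / 100))
            if (n_sub > 0) {
              pos <- sample.int(aligned, n_sub)
              seq_chars[pos] <- map_chr(seq_chars[pos], function(a) {
                sample(setdiff(AA_ALPHABET, a), 1)
              })
            }
            extra <- len - aligned
            paste0(
              paste(seq_chars, collapse = ""),
              if (extra > 0) rand_aa(extra) else ""
            )
          }
        ) |> unlist()
      )
    } else {
      NULL
    }
    bind_rows(target, family)
  })
}

#' Simulate a peptide-spectrum-match table over a proteome
#'
#' Draws class I-length peptides as exact substrings of the target/isoform
#' sequences, with configured fractions of sub-threshold identification scores
#' and out-of-band ppm mass errors, and attaches each originating sample's HLA
#' typing (the fields of a search-engine export).
#'
#' @param spec A [psm_spec()] object.
#' @param proteome A proteome tibble from [simulate_proteome()].
#' @return A tibble with columns `sample_id`, `peptide`, `protein_id`,
#'   `best_ion_score`, `ppm_error`, `hla_typing`.
#' @export
simulate_psms <- function(spec, proteome) {
  stopifnot(inherits(spec, "psm_spec"))
  targets <- proteome[proteome$role %in% c("target", "target_isoform"), ]
  if (nrow(targets) == 0) abort("proteome contains no target sequences")
  withr::with_seed(spec$seed, {
    n <- spec$n_psms
    pick <- sample.int(nrow(targets), n, replace = TRUE)
    len <- sample(
      seq(spec$peptide_lengths[1], spec$peptide_lengths[2]), n,
      replace = TRUE
    )
    seqs <- targets$sequence[pick]
    start <- map_int(seq_len(n), function(i) {
      sample.int(nchar(seqs[i]) - len[i] + 1L, 1L)
    })
    peptide <- substr(seqs, start, start + len - 1L)

    # Exactly round(frac * n) PSMs in each low-quality stratum.
    n_low <- round(spec$frac_below_score * n)
    score <- runif(n, spec$score_range[1], spec$score_range[2])
    low_idx <- sample.int(n, n_low)
    score[low_idx] <- runif(
      n_low, spec$low_score_range[1], spec$low_score_range[2]
    )
    n_out <- round(spec$frac_ppm_out * n)
    ppm <- runif(n, -spec$ppm_max, spec$ppm_max)
    out_idx <- sample.int(n, n_out)
    ppm[out_idx] <- sample(c(-1, 1), n_out, replace = TRUE) *
      runif(n_out, spec$ppm_max * 1.05, spec$ppm_max * 2)

    samp <- spec$samples[sample.int(nrow(spec$samples), n, replace = TRUE), ]
    tibble(
      sample_id = samp$sample_id,
      peptide = peptide,
      protein_id = targets$protein_id[pick],
      best_ion_score = score,
      ppm_error = ppm,
      hla_typing = samp$hla_typing
    )
  })
}

#' Simulate a qPCR Ct table
#'
#' Inverts the relative-expression definition: each target gene's Ct is placed
#' `log(relative_percent/100, base = efficiency)` cycles below the mean
#' housekeeping Ct, then optional Gaussian cycle noise is added to every
#' measurement (housekeeping and target alike).
#'
#' @param spec A [qpcr_spec()] object.
#' @return A long tibble with columns `sample_id`, `gene`, `ct`.
#' @export
simulate_qpcr <- function(spec) {
  stopifnot(inherits(spec, "qpcr_spec"))
  withr::with_seed(spec$seed, {
    ref_ct <- mean(spec$hkg_ct)
    target_ct <- ref_ct - log(spec$targets$relative_percent / 100,
                              base = spec$efficiency)
    per_sample <- tibble(
      gene = c(spec$hkg, spec$targets$gene),
      ct = c(spec$hkg_ct, target_ct)
    )
    out <- tidyr::crossing(sample_id = spec$samples, per_sample)
    if (spec$noise_sd > 0) {
      out$ct <- out$ct + rnorm(nrow(out), sd = spec$noise_sd)
    }
    arrange(out, .data$sample_id, .data$gene)
  })
}
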