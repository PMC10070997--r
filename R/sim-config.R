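#' Describe a tissue panel for atlas simulation
#'
#' Builds the tissue panel table consumed by [sim_config()]. Each row is one
#' tissue cohort with its data source, the number of samples available before
#' subsampling, and flags marking the tumor cohort and reproductive tissues
#' (the latter are conventionally excluded from the specificity aggregation
#' because expression in the reproductive compartment is tolerated for
#' gynaecological tumor targets).
#'
#' @param tissue Character vector of tissue names (unique).
#' @param source Data source per tissue: one of `"tumor-atlas"` (TCGA-like,
#'   subsampled to 30), `"bulk-healthy"` (GTEx-like, subsampled to 20) or
#'   `"protein-atlas"` (HPA-like, all samples kept).
#' @param n_available Samples available per tissue before the source cap.
#' @param is_tumor Logical; exactly one tissue must be the tumor cohort.
#' @param is_reproductive Logical; reproductive-organ tissues.
#' @return A tibble with one row per tissue.
#' @examples
#' tissue_panel(
#'   tissue = c("ovarian_tumor", "lung", "testis"),
#'   source = c("tumor-atlas", "bulk-healthy", "protein-atlas"),
#'   n_available = c(60, 35, 4),
#'   is_tumor = c(TRUE, FALSE, FALSE),
#'   is_reproductive = c(FALSE, FALSE, TRUE)
#' )
#' @export
tissue_panel <- function(tissue, source, n_available,
                         is_tumor = FALSE, is_reproductive = FALSE) {
  panel <- tibble(
    tissue = as.character(tissue),
    source = as.character(source),
    n_available = as.integer(n_available),
    is_tumor = as.logical(is_tumor),
    is_reproductive = as.logical(is_reproductive)
  )
  validate_tissue_panel(panel)
}

validate_tissue_panel <- function(panel) {
  if (!all(panel$source %in% names(SOURCE_CAPS))) {
    abort(paste0(
      "tissue sources must be one of: ",
      paste(names(SOURCE_CAPS), collapse = ", ")
    ))
  }
  if (anyDuplicated(panel$tissue)) abort("duplicate tissue names in panel")
  if (any(panel$n_available < 1L)) abort("every tissue needs n_available >= 1")
  if (sum(panel$is_tumor) != 1L) {
    abort("the panel must contain exactly one tumor tissue")
  }
  panel
}

#' Default tumor/healthy tissue panel
#'
#' A panel emulating the structure of a pooled TCGA/GTEx/HPA screen at desk
#' scale: one tumor cohort plus `n_bulk` GTEx-like healthy tissues (capped at
#' 20 samples each) and `n_protein_atlas` HPA-like tissues contributing 3-5
#' samples each. One bulk tissue (`testis`) and one protein-atlas tissue
#' (`ovary`) are flagged reproductive so the exclusion rule is exercised by
#' default.
#'
#' @param n_bulk Number of bulk-healthy tissues.
#' @param n_protein_atlas Number of protein-atlas tissues.
#' @param tumor_tissue Name of the tumor cohort.
#' @return A tissue panel tibble (see [tissue_panel()]).
#' @export
default_tissue_panel <- function(n_bulk = 24, n_protein_atlas = 6,
                                 tumor_tissue = "ovarian_tumor") {
  stopifnot(n_bulk >= 1)
  bulk_names <- c(
    "testis",
    paste0("bulk_tissue_", sprintf("%02d", seq_len(max(0, n_bulk - 1))))
  )[seq_len(n_bulk)]
  pa_names <- if (n_protein_atlas > 0) {
    c("ovary", paste0("pa_tissue_", sprintf(
      "%02d", seq_len(max(0, n_protein_atlas - 1))
    )))[seq_len(n_protein_atlas)]
  } else {
    character(0)
  }
  tissue_panel(
    tissue = c(tumor_tissue, bulk_names, pa_names),
    source = c(
      "tumor-atlas",
      rep("bulk-healthy", n_bulk),
      rep("protein-atlas", n_protein_atlas)
    ),
    n_available = c(
      60L,
      rep(40L, n_bulk),
      if (n_protein_atlas > 0) {
        rep_len(c(4L, 3L, 5L), n_protein_atlas)
      } else {
        integer(0)
      }
    ),
    is_tumor = c(TRUE, rep(FALSE, n_bulk + n_protein_atlas)),
    is_reproductive = c(
      FALSE,
      bulk_names == "testis",
      if (n_protein_atlas > 0) pa_names == "ovary" else logical(0)
    )
  )
}

#' Describe genes planted with a known tumor/healthy fold change
#'
#' @param gene_id Gene identifiers.
#' @param fold_change True expected-count ratio of the tumor cohort over every
#'   healthy tissue (> 0).
#' @param tumor_mean Expected raw count in the tumor cohort at unit library
#'   size (> 0).
#' @param biotype Gene biotype annotation; only `"protein_coding"` genes
#'   survive the downstream biotype filter.
#' @return A tibble with one row per planted gene.
#' @export
planted_genes <- function(gene_id, fold_change, tumor_mean,
                          biotype = "protein_coding") {
  out <- tibble(
    gene_id = as.character(gene_id),
    fold_change = as.numeric(fold_change),
    tumor_mean = as.numeric(tumor_mean),
    biotype = as.character(biotype)
  )
  if (any(out$fold_change <= 0)) abort("planted fold_change must be > 0")
  if (any(out$tumor_mean <= 0)) abort("planted tumor_mean must be > 0")
  if (anyDuplicated(out$gene_id)) abort("duplicate planted gene ids")
  out
}

#' Configure a synthetic atlas simulation
#'
#' Bundles everything [simulate_counts()] needs: the tissue panel, the number
#' of background (null) genes, the negative-binomial noise model and any
#' planted tumor-specific genes. With the seed fixed the generated artifacts
#' are byte-identical across runs.
#'
#' Counts are drawn NB with variance \eqn{\mu + \phi \mu^2}; `dispersion = 0`
#' gives the Poisson limit. Per-sample library-size factors are log-normal
#' with coefficient of variation `library_size_cv`, the multiplicative depth
#' variation that median-of-ratios normalization is designed to remove.
#'
#' @param seed Integer seed driving all randomness.
#' @param panel Tissue panel tibble, see [tissue_panel()].
#' @param n_genes Number of background genes (planted genes are added on top).
#' @param baseline_log_mean_range Range (natural log of expected counts) from
#'   which background gene means are drawn uniformly.
#' @param dispersion NB dispersion \eqn{\phi \ge 0}.
#' @param library_size_cv Coefficient of variation of per-sample depth factors.
#' @param planted Optional tibble from [planted_genes()].
#' @param background_biotype Biotype assigned to background genes.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       panel = default_tissue_panel(),
                       n_genes = 2000,
                       baseline_log_mean_range = c(log(5), log(500)),
                       dispersion = 0.1,
                       library_size_cv = 0.3,
                       planted = NULL,
                       background_biotype = "protein_coding") {
  validate_tissue_panel(panel)
  if (n_genes < 1 && is.null(planted)) abort("simulation needs at least one gene")
  if (dispersion < 0) abort("dispersion must be >= 0")
  if (library_size_cv < 0) abort("library_size_cv must be >= 0")
  if (length(baseline_log_mean_range) != 2 ||
      diff(baseline_log_mean_range) < 0) {
    abort("baseline_log_mean_range must be an increasing pair")
  }
  structure(
    list(
      seed = as.integer(seed),
      panel = panel,
      n_genes = as.integer(n_genes),
      baseline_log_mean_range = as.numeric(baseline_log_mean_range),
      dispersion = as.numeric(dispersion),
      library_size_cv = as.numeric(library_size_cv),
      planted = planted,
      background_biotype = background_biotype
    ),
    class = "sim_config"
  )
}

#' Configure a toy proteome fixture
#'
#' Describes a target gene with several isoforms sharing a verbatim core
#' region (each isoform appending its own unique region), plus near-homologous
#' family members generated by per-site substitution of the canonical target
#' at rate `1 - identity/100`. The family members are the off-target universe
#' for the peptide uniqueness scan.
#'
#' @param target_gene Target gene name.
#' @param n_isoforms Number of target isoforms (>= 1).
#' @param shared_core_length Length of the shared core region.
#' @param unique_region_lengths Lengths of the per-isoform unique regions,
#'   recycled to `n_isoforms`.
#' @param family_members Tibble with columns `name`, `identity` (percent, in
#'   `[0, 100)`) and `length`.
#' @param seed Integer seed.
#' @return A `proteome_spec` list.
#' @export
proteome_spec <- function(target_gene = "CTCFL",
                          n_isoforms = 3,
                          shared_core_length = 200,
                          unique_region_lengths = 30,
                          family_members = tibble(
                            name = "CTCF",
                            identity = 70,
                            length = 230
                          ),
                          seed = 1) {
  if (n_isoforms < 1) abort("need at least one isoform")
  if (shared_core_length < 8) abort("shared core must be at least 8 residues")
  if (!is.null(family_members) && nrow(family_members) > 0) {
    if (any(family_members$identity < 0 | family_members$identity > 100)) {
      abort("family member identity must lie in [0, 100]")
    }
    if (any(family_members$identity == 100 &
            family_members$name != target_gene)) {
      abort(paste(
        "a family member at 100% identity with a distinct name makes",
        "peptide uniqueness undecidable"
      ))
    }
  }
  structure(
    list(
      target_gene = target_gene,
      n_isoforms = as.integer(n_isoforms),
      shared_core_length = as.integer(shared_core_length),
      unique_region_lengths = as.integer(unique_region_lengths),
      family_members = family_members,
      seed = as.integer(seed)
    ),
    class = "proteome_spec"
  )
}

#' Configure a synthetic peptide-spectrum-match table
#'
#' @param n_psms Number of PSM rows.
#' @param samples Tibble with `sample_id` and `hla_typing` (semicolon-joined
#'   four-digit HLA class I allele names).
#' @param frac_below_score Fraction of PSMs drawn below the identification
#'   score threshold.
#' @param frac_ppm_out Fraction of PSMs with |ppm error| beyond `ppm_max`.
#' @param score_threshold Score boundary separating the two score strata.
#' @param score_range Range for confident scores (at or above the threshold).
#' @param low_score_range Range for sub-threshold scores.
#' @param ppm_max Mass-accuracy bound (ppm) separating the two ppm strata.
#' @param peptide_lengths Range of peptide lengths to draw (class I ligands).
#' @param seed Integer seed.
#' @return A `psm_spec` list.
#' @export
psm_spec <- function(n_psms = 100,
                     samples = tibble(
                       sample_id = c("OVCA-1", "OVCA-2"),
                       hla_typing = c(
                         "A*02:01;A*01:01;B*07:02;B*08:01",
                         "A*02:01;A*24:02;B*35:01;B*40:01"
                       )
                     ),
                     frac_below_score = 0.2,
                     frac_ppm_out = 0.1,
                     score_threshold = 20,
                     score_range = c(20, 80),
                     low_score_range = c(5, 19.5),
                     ppm_max = 10,
                     peptide_lengths = c(8, 12),
                     seed = 1) {
  if (n_psms < 1) abort("n_psms must be >= 1")
  if (frac_below_score < 0 || frac_below_score > 1 ||
      frac_ppm_out < 0 || frac_ppm_out > 1) {
    abort("fractions must lie in [0, 1]")
  }
  structure(
    list(
      n_psms = as.integer(n_psms),
      samples = samples,
      frac_below_score = frac_below_score,
      frac_ppm_out = frac_ppm_out,
      score_threshold = score_threshold,
      score_range = score_range,
      low_score_range = low_score_range,
      ppm_max = ppm_max,
      peptide_lengths = as.integer(peptide_lengths),
      seed = as.integer(seed)
    ),
    class = "psm_spec"
  )
}

#' Configure a synthetic qPCR Ct table
#'
#' Target Ct values are derived by inverting the relative-expression
#' definition: a target at `relative_percent` of the housekeeping reference
#' sits `log(percent/100, base = efficiency)` cycles from the mean
#' housekeeping Ct.
#'
#' @param samples Character vector of sample ids.
#' @param hkg Names of the three housekeeping genes.
#' @param hkg_ct Base Ct of each housekeeping gene (recycled across samples).
#' @param targets Tibble with `gene` and `relative_percent`.
#' @param noise_sd Gaussian Ct noise (cycles) added to every measurement.
#' @param efficiency Amplification efficiency (2 = perfect doubling).
#' @param seed Integer seed.
#' @return A `qpcr_spec` list.
#' @export
qpcr_spec <- function(samples = c("OVCA-1", "OVCA-2"),
                      hkg = c("GUSB", "VPS29", "PSMB4"),
                      hkg_ct = c(20, 21, 22),
                      targets = tibble(
                        gene = c("PRAME", "CTCFL"),
                        relative_percent = c(40, 3.2)
                      ),
                      noise_sd = 0,
                      efficiency = 2,
                      seed = 1) {
  if (length(hkg) != 3) abort("exactly three housekeeping genes are required")
  if (length(hkg_ct) != 3) abort("hkg_ct must give one Ct per housekeeping gene")
  if (efficiency <= 1) abort("amplification efficiency must exceed 1")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  structure(
    list(
      samples = as.character(samples),
      hkg = as.character(hkg),
      hkg_ct = as.numeric(hkg_ct),
      targets = targets,
      noise_sd = noise_sd,
      efficiency = efficiency,
      seed = as.integer(seed)
    ),
    class = "qpcr_spec"
  )
}
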