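#' Configure an end-to-end discovery run
#'
#' Validates thresholds up front and bundles the inputs for [run_pipeline()].
#' Inputs are supplied either as in-memory objects (an atlas, PSM/Ct tibbles,
#' a proteome tibble) or as a [sim_config()] to be generated at run time.
#'
#' @param atlas A [count_atlas()], or `NULL` to simulate from `sim`.
#' @param sim A [sim_config()] used when `atlas` is `NULL`.
#' @param psms Optional PSM tibble for the triage stage.
#' @param proteome Optional proteome tibble (required with `psms`).
#' @param allele_freq Optional allele-frequency tibble (required with `psms`).
#' @param predictor Binding predictor; defaults to
#'   [stub_binding_predictor()].
#' @param ct Optional long Ct tibble for the qPCR stage.
#' @param outdir Output directory for reports and the manifest.
#' @param fc_threshold,alpha,expression_min,score_min,ppm_max,rank_max,freq_min,mismatch_margin
#'   Stage thresholds (defaults 20, 0.05, 100, 20, 10, 2.0, 1.0, 2).
#' @param prior_count Pseudo-count for fold changes and log-CPM.
#' @param shrink_weight Dispersion shrinkage weight.
#' @param excluded_tissues Tissues excluded from aggregation (default: the
#'   atlas's reproductive tissues).
#' @param soft_score Keep-and-flag sub-threshold identification scores.
#' @param seed Integer seed (subsampling and any simulation).
#' @return A validated `run_config` list.
#' @export
run_config <- function(atlas = NULL, sim = NULL, psms = NULL, proteome = NULL,
                       allele_freq = NULL, predictor = NULL, ct = NULL,
                       outdir = tempfile("taa_run_"),
                       fc_threshold = 20, alpha = 0.05, expression_min = 100,
                       score_min = 20, ppm_max = 10, rank_max = 2.0,
                       freq_min = 1.0, mismatch_margin = 2,
                       prior_count = 0.5, shrink_weight = 0.3,
                       excluded_tissues = NULL, soft_score = TRUE,
                       seed = 1) {
  thresholds <- c(
    fc_threshold = fc_threshold, alpha = alpha,
    expression_min = expression_min, score_min = score_min,
    ppm_max = ppm_max, rank_max = rank_max, freq_min = freq_min,
    mismatch_margin = mismatch_margin
  )
  bad <- names(thresholds)[thresholds <= 0]
  if (length(bad)) {
    abort(paste0(
      "thresholds must be positive; offending: ", paste(bad, collapse = ", ")
    ))
  }
  if (alpha > 1) abort("alpha must lie in (0, 1]")
  if (is.null(atlas) && is.null(sim)) {
    abort("provide either an atlas or a sim_config")
  }
  if (!is.null(psms) && (is.null(proteome) || is.null(allele_freq))) {
    abort("the triage stage needs a proteome and an allele-frequency table")
  }
  structure(
    list(
      atlas = atlas, sim = sim, psms = psms, proteome = proteome,
      allele_freq = allele_freq,
      predictor = predictor %||% stub_binding_predictor(),
      ct = ct, outdir = outdir,
      fc_threshold = fc_threshold, alpha = alpha,
      expression_min = expression_min, score_min = score_min,
      ppm_max = ppm_max, rank_max = rank_max, freq_min = freq_min,
      mismatch_margin = mismatch_margin, prior_count = prior_count,
      shrink_weight = shrink_weight, excluded_tissues = excluded_tissues,
      soft_score = soft_score, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Run the discovery pipeline end to end
#'
#' Executes assemble/simulate, normalization, the expression filter, the
#' per-tissue likelihood-ratio screen and min-FC aggregation, then optionally
#' the immunopeptidome triage and the qPCR stage, writing every report via
#' [write_reports()] and a manifest listing each output with its MD5 content
#' hash. Thresholds and record-level rejections are logged to stderr.
#'
#' @param config A [run_config()].
#' @return The manifest tibble (`file`, `md5`), invisibly also written as
#'   `manifest.tsv`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  atlas <- config$atlas %||% simulate_counts(config$sim)
  message(
    "[taascreen] atlas: ", nrow(atlas$counts), " genes x ",
    ncol(atlas$counts), " samples"
  )
  message(
    "[taascreen] thresholds: FC >= ", config$fc_threshold,
    ", FDR <= ", config$alpha,
    ", tumor mean count >= ", config$expression_min
  )
  screen <- screen_specificity(
    atlas,
    expression_min = config$expression_min,
    fc_threshold = config$fc_threshold,
    alpha = config$alpha,
    excluded_tissues = config$excluded_tissues,
    prior_count = config$prior_count,
    shrink_weight = config$shrink_weight
  )
  message(
    "[taascreen] screen: ", nrow(screen$specificity), " genes tested, ",
    sum(screen$specificity$passes), " candidate(s)"
  )

  triage <- NULL
  if (!is.null(config$psms)) {
    triage <- triage_ligandome(
      config$psms, config$proteome, config$predictor, config$allele_freq,
      score_min = config$score_min, ppm_max = config$ppm_max,
      soft_score = config$soft_score, rank_max = config$rank_max,
      freq_min = config$freq_min, mismatch_margin = config$mismatch_margin
    )
    for (i in seq_len(nrow(triage$rejections))) {
      message(
        "[taascreen] PSM rejected (", triage$rejections$reason[i], "): ",
        triage$rejections$peptide[i], " in ",
        triage$rejections$sample_id[i]
      )
    }
    message(
      "[taascreen] triage: ", nrow(triage$candidates),
      " candidate peptide-HLA pair(s)"
    )
  }

  qpcr <- NULL
  if (!is.null(config$ct)) {
    qpcr <- relative_expression(config$ct)
    message("[taascreen] qPCR: ", nrow(qpcr), " relative-expression value(s)")
  }

  files <- write_reports(
    screen,
    outdir = config$outdir,
    triage = triage,
    qpcr = qpcr
  )
  manifest <- tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files))
  )
  readr::write_tsv(manifest, file.path(config$outdir, "manifest.tsv"))
  message(
    "[taascreen] wrote ", nrow(manifest), " report file(s) to ",
    config$outdir, " in ",
    sprintf("%.1fs", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  )
  invisible(manifest)
}

#' Write the screen, triage and qPCR reports
#'
#' Emits tab-delimited, header-rowed tables: the min-FC volcano table, the
#' per-tissue contrast table, size factors, box summaries with the
#' fold-change reference lines for candidate genes, the candidate gene list,
#' and (when present) the candidate peptide table and qPCR percentages.
#' Empty results yield headers-only files.
#'
#' @param screen A `taa_screen` from [screen_specificity()].
#' @param outdir Output directory (created if needed).
#' @param triage Optional result of [triage_ligandome()].
#' @param qpcr Optional result of [relative_expression()].
#' @return Character vector of written file paths, invisibly.
#' @export
write_reports <- function(screen, outdir, triage = NULL, qpcr = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) abort(paste0("cannot create directory ", outdir))
  paths <- character(0)
  emit <- function(tbl, name) {
    p <- file.path(outdir, name)
    readr::write_tsv(tbl, p)
    paths <<- c(paths, p)
  }

  emit(
    screen$specificity[, c(
      "gene_id", "min_fold_change", "min_log2_fold_change",
      "worst_adjusted_p", "limiting_tissue", "biotype", "passes"
    )],
    "specificity_volcano.tsv"
  )
  emit(screen$contrasts, "contrasts.tsv")
  emit(
    screen$size_factors[, c("sample_id", "size_factor")],
    "size_factors.tsv"
  )

  candidates <- screen$specificity[screen$specificity$passes, ]
  emit(candidates, "candidate_genes.tsv")

  box <- if (nrow(candidates) > 0) {
    cpm <- normalize_cpm(
      screen$atlas, screen$size_factors,
      prior_count = screen$params$prior_count
    )
    tumor_tissue <- unique(
      screen$atlas$samples$tissue[screen$atlas$samples$is_tumor]
    )
    summarize_expression(
      cpm, screen$atlas$samples$tissue, tumor_tissue,
      genes = candidates$gene_id,
      fc_threshold = screen$params$fc_threshold
    )
  } else {
    tibble(
      gene_id = character(), group = character(), n = integer(),
      min = numeric(), q1 = numeric(), median = numeric(), q3 = numeric(),
      max = numeric(), ref_median = numeric(), ref_lower = numeric()
    )
  }
  emit(box, "expression_summary.tsv")

  if (!is.null(triage)) {
    emit(triage$candidates, "peptide_candidates.tsv")
    emit(triage$rejections, "psm_rejections.tsv")
  }
  if (!is.null(qpcr)) emit(qpcr, "qpcr_relative_expression.tsv")

  invisible(paths)
}
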