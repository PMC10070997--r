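#' Filter peptide-spectrum matches on score and mass accuracy
#'
#' Retains PSMs with `|ppm_error| <= ppm_max` and, in strict mode,
#' `best_ion_score >= score_min`. The score rule is soft by default: a
#' sub-threshold score is kept but flagged (`below_score_threshold`), since a
#' confidently fragmenting peptide can be worth pursuing despite a weak best
#' ion score. A rejection log states which rule fired for every dropped PSM.
#'
#' @param psms PSM tibble (see [read_psm_table()] for the columns).
#' @param score_min Identification score threshold (default 20).
#' @param ppm_max Mass-accuracy bound in ppm (default 10, boundary inclusive).
#' @param soft_score Flag rather than drop sub-threshold scores.
#' @return A list with `retained` (tibble, plus the
#'   `below_score_threshold` flag) and `rejections` (tibble with `row`,
#'   `sample_id`, `peptide`, `reason`).
#' @examples
#' psms <- tibble::tibble(
#'   sample_id = "s1", peptide = c("QLLALLPSL", "KLHGILVEA"),
#'   protein_id = "PRAME-iso1", best_ion_score = c(37, 12),
#'   ppm_error = c(3, 2), hla_typing = "A*02:01;B*07:02"
#' )
#' filter_psms(psms)$retained
#' filter_psms(psms, soft_score = FALSE)$rejections
#' @export
filter_psms <- function(psms, score_min = 20, ppm_max = 10,
                        soft_score = TRUE) {
  psms <- validate_psms(psms)
  ppm_ok <- abs(psms$ppm_error) <= ppm_max
  score_ok <- psms$best_ion_score >= score_min
  keep <- ppm_ok & (score_ok | soft_score)
  reason <- dplyr::case_when(
    !ppm_ok & !score_ok ~ "ppm_error and best_ion_score",
    !ppm_ok ~ "ppm_error",
    !score_ok ~ "best_ion_score",
    .default = NA_character_
  )
  retained <- psms[keep, ] |>
    mutate(below_score_threshold = !score_ok[keep])
  rejections <- tibble(
    row = which(!keep),
    sample_id = psms$sample_id[!keep],
    peptide = psms$peptide[!keep],
    reason = reason[!keep]
  )
  list(retained = retained, rejections = rejections)
}

#' Build a substring/mismatch index over a proteome
#'
#' Splits a proteome into target sequences (the target gene and its isoforms)
#' and family off-targets, ready for exact-occurrence lookups and
#' minimum-Hamming window scans.
#'
#' @param proteome Proteome tibble (see [simulate_proteome()] /
#'   [read_proteome_fasta()]).
#' @return A `proteome_index` object.
#' @export
proteome_index <- function(proteome) {
  targets <- proteome[proteome$role %in% c("target", "target_isoform"), ]
  offtargets <- proteome[proteome$role == "family_offtarget", ]
  if (nrow(targets) == 0) abort("proteome holds no target sequences")
  structure(
    list(
      targets = targets,
      offtargets = offtargets,
      target_set = Biostrings::AAStringSet(
        setNames(targets$sequence, targets$protein_id)
      ),
      offtarget_set = Biostrings::AAStringSet(
        setNames(offtargets$sequence, offtargets$protein_id)
      )
    ),
    class = "proteome_index"
  )
}

#' @export
print.proteome_index <- function(x, ...) {
  cat(
    "<proteome_index> ", nrow(x$targets), " target sequence(s), ",
    nrow(x$offtargets), " family off-target(s)\n",
    sep = ""
  )
  invisible(x)
}

# Minimum Hamming distance between a peptide and every equal-length window of
# one subject sequence (Inf when the subject is shorter than the peptide).
min_hamming_to_sequence <- function(peptide, subject) {
  k <- nchar(peptide)
  n <- nchar(subject)
  if (n < k) return(Inf)
  d <- Biostrings::neditStartingAt(
    Biostrings::AAString(peptide),
    Biostrings::AAString(subject),
    starting.at = seq_len(n - k + 1),
    with.indels = FALSE
  )
  min(d)
}

#' Peptide uniqueness against family off-targets
#'
#' Scans every equal-length window of every family off-target sequence and
#' reports the minimum Hamming distance. A peptide is unique to the target
#' when that distance is at least `mismatch_margin` (an exact off-target
#' substring has distance 0 and is never unique); the margin operationalizes
#' "no major sequence overlap" so that single-substitution near-matches to
#' ubiquitously expressed homologs are also excluded.
#'
#' @param peptides Character vector of peptides; each must occur in at least
#'   one target/isoform sequence.
#' @param index A [proteome_index()].
#' @param mismatch_margin Minimum Hamming distance required (default 2).
#' @return A tibble with columns `peptide`, `unique_to_target`,
#'   `min_mismatch_to_offtarget` (Inf when there are no off-targets) and
#'   `closest_offtarget` (NA when none attains the minimum).
#' @export
check_uniqueness <- function(peptides, index, mismatch_margin = 2) {
  stopifnot(inherits(index, "proteome_index"))
  map(unique(peptides), function(pep) {
    in_target <- any(map_int(index$targets$sequence, function(s) {
      as.integer(grepl(pep, s, fixed = TRUE))
    }) == 1L)
    if (!in_target) {
      abort(paste0(
        "peptide ", pep, " does not occur in any target sequence"
      ))
    }
    if (nrow(index$offtargets) == 0) {
      return(tibble(
        peptide = pep,
        unique_to_target = TRUE,
        min_mismatch_to_offtarget = Inf,
        closest_offtarget = NA_character_
      ))
    }
    d <- map_dbl(index$offtargets$sequence, function(s) {
      min_hamming_to_sequence(pep, s)
    })
    tibble(
      peptide = pep,
      unique_to_target = min(d) >= mismatch_margin,
      min_mismatch_to_offtarget = min(d),
      closest_offtarget = if (is.finite(min(d))) {
        index$offtargets$protein_id[which.min(d)]
      } else {
        NA_character_
      }
    )
  }) |>
    list_rbind()
}

#' Deterministic stub binding predictor
#'
#' A pluggable stand-in for an MHC class I binding predictor: maps
#' (peptide, allele) to a rank percentile in `(0, 100]` by a deterministic
#' arithmetic hash. It carries no biology; it exists so the triage chain is
#' testable without an external predictor. Supply your own
#' `function(peptide, allele) -> rank` (lower = stronger predicted binding)
#' for real use, or [fixed_binding_predictor()] to pin ranks in tests.
#'
#' @return A predictor `function(peptide, allele)`.
#' @export
stub_binding_predictor <- function() {
  function(peptide, allele) {
    map2(peptide, allele, function(p, a) {
      codes <- utf8ToInt(paste0(p, "|", a))
      h <- 0
      for (c in codes) h <- (h * 31 + c) %% 999983
      (h %% 10000) / 100 + 0.01
    }) |> unlist()
  }
}

#' Binding predictor with pinned ranks
#'
#' @param ranks Tibble with columns `peptide`, `allele`, `rank`.
#' @param default Rank returned for pairs not in the table.
#' @return A predictor `function(peptide, allele)`.
#' @export
fixed_binding_predictor <- function(ranks, default = 100) {
  function(peptide, allele) {
    key <- paste(peptide, allele)
    i <- match(key, paste(ranks$peptide, ranks$allele))
    ifelse(is.na(i), default, ranks$rank[i])
  }
}

#' Assign HLA alleles to a peptide
#'
#' An allele is assigned when (i) the predictor's rank percentile is at most
#' `rank_max`, (ii) the allele occurs in the HLA typing of at least one
#' sample in which the peptide was observed, and (iii) its population
#' frequency is at least `freq_min` percent (restricting candidates to common
#' alleles). A peptide may receive several alleles; each becomes its own
#' candidate row downstream.
#'
#' @param peptide One peptide.
#' @param sample_hla Character vector of semicolon-joined typings (one per
#'   observing sample), or a list of allele character vectors.
#' @param predictor A `function(peptide, allele) -> rank` (see
#'   [stub_binding_predictor()]).
#' @param allele_freq Tibble with `allele`, `frequency_percent`; must cover
#'   every allele encountered.
#' @param rank_max Maximum predicted rank percentile (default 2.0, the
#'   conventional weak-binder cutoff).
#' @param freq_min Minimum population allele frequency in percent (default 1).
#' @return A tibble with columns `peptide`, `hla_allele`, `predicted_rank`.
#' @export
assign_hla <- function(peptide, sample_hla, predictor, allele_freq,
                       rank_max = 2.0, freq_min = 1.0) {
  stopifnot(length(peptide) == 1)
  alleles <- unique(unlist(
    if (is.list(sample_hla)) sample_hla else strsplit(sample_hla, ";")
  ))
  missing <- setdiff(alleles, allele_freq$allele)
  if (length(missing)) {
    abort(paste0(
      "allele(s) missing from the frequency table: ",
      paste(missing, collapse = ", ")
    ))
  }
  freq <- allele_freq$frequency_percent[match(alleles, allele_freq$allele)]
  rank <- predictor(rep(peptide, length(alleles)), alleles)
  hit <- rank <= rank_max & freq >= freq_min
  tibble(
    peptide = peptide,
    hla_allele = alleles[hit],
    predicted_rank = rank[hit]
  ) |>
    arrange(.data$hla_allele)
}

#' Isoform coverage of a peptide
#'
#' Counts how many target isoform sequences contain the peptide as an exact
#' substring. A peptide confined to one variant's unique region covers only
#' that variant; a shared-core peptide covers them all.
#'
#' @param peptides Character vector of peptides.
#' @param index A [proteome_index()].
#' @return A tibble with columns `peptide`, `n_containing`, `n_isoforms`.
#' @export
annotate_isoform_coverage <- function(peptides, index) {
  stopifnot(inherits(index, "proteome_index"))
  n_iso <- nrow(index$targets)
  if (n_iso == 0) abort("index holds no target isoforms")
  tibble(
    peptide = unique(peptides),
    n_containing = map_int(unique(peptides), function(pep) {
      sum(map_int(index$targets$sequence, function(s) {
        as.integer(grepl(pep, s, fixed = TRUE))
      }))
    }),
    n_isoforms = n_iso
  )
}

#' Build the vetted candidate peptide-HLA table
#'
#' Collapses retained PSMs into one row per (peptide, HLA allele):
#' `source_samples` is the sorted distinct set of observing samples,
#' `best_score_seen` their maximum identification score, joined with the
#' uniqueness, isoform-coverage and binding-rank annotations. Wet-lab
#' validation flags (synthetic-spectrum comparison, pMHC-monomer refolding)
#' default to `FALSE`; that evidence is supplied externally. Literature-only
#' peptides (identified elsewhere, not in the mass-spectrometry input) are
#' appended with empty sources.
#'
#' @param psms Retained PSM tibble; must carry a `gene` column and either an
#'   `hla_allele` column (pre-assigned restriction) or be joined with
#'   `assignments`.
#' @param assignments Optional tibble `peptide`, `hla_allele`,
#'   `predicted_rank` from [assign_hla()].
#' @param uniqueness Optional tibble from [check_uniqueness()].
#' @param coverage Optional tibble from [annotate_isoform_coverage()].
#' @param literature Optional tibble with `gene`, `peptide`, `hla_allele` (and
#'   optionally `best_ion_score`) for peptides included on published evidence.
#' @return A tibble with one row per (peptide, hla_allele), sorted by gene,
#'   allele, peptide.
#' @export
build_candidate_table <- function(psms, assignments = NULL, uniqueness = NULL,
                                  coverage = NULL, literature = NULL) {
  if (!is.null(assignments)) {
    psms <- inner_join(
      psms[, setdiff(names(psms), "hla_allele")],
      assignments,
      by = "peptide",
      relationship = "many-to-many"
    )
  }
  if (nrow(psms) > 0 && !"hla_allele" %in% names(psms)) {
    abort("PSMs need an hla_allele column or an assignments table")
  }
  rows <- if (nrow(psms) > 0) {
    psms |>
      group_by(.data$gene, .data$peptide, .data$hla_allele) |>
      summarise(
        source_samples = paste(sort(unique(.data$sample_id)), collapse = ";"),
        n_sources = dplyr::n_distinct(.data$sample_id),
        best_score_seen = max(.data$best_ion_score),
        predicted_rank = if ("predicted_rank" %in% names(psms)) {
          .data$predicted_rank[1]
        } else {
          NA_real_
        },
        .groups = "drop"
      ) |>
      mutate(literature_only = FALSE)
  } else {
    tibble(
      gene = character(), peptide = character(), hla_allele = character(),
      source_samples = character(), n_sources = integer(),
      best_score_seen = numeric(), predicted_rank = numeric(),
      literature_only = logical()
    )
  }
  if (!is.null(literature) && nrow(literature) > 0) {
    lit <- literature |>
      transmute(
        .data$gene, .data$peptide, .data$hla_allele,
        source_samples = "",
        n_sources = 0L,
        best_score_seen = if ("best_ion_score" %in% names(literature)) {
          as.numeric(.data$best_ion_score)
        } else {
          NA_real_
        },
        predicted_rank = NA_real_,
        literature_only = TRUE
      )
    rows <- bind_rows(rows, lit)
  }
  if (!is.null(uniqueness)) {
    rows <- left_join(
      rows,
      uniqueness[, c(
        "peptide", "unique_to_target", "min_mismatch_to_offtarget"
      )],
      by = "peptide"
    )
  } else {
    rows$unique_to_target <- NA
    rows$min_mismatch_to_offtarget <- NA_real_
  }
  if (!is.null(coverage)) {
    rows <- left_join(
      rows,
      coverage[, c("peptide", "n_containing", "n_isoforms")],
      by = "peptide"
    )
  } else {
    rows$n_containing <- NA_integer_
    rows$n_isoforms <- NA_integer_
  }
  rows |>
    mutate(
      validated_by_synthetic_spectrum = FALSE,
      monomer_refold_stable = FALSE
    ) |>
    arrange(.data$gene, .data$hla_allele, .data$peptide)
}

#' Full ligandome triage chain
#'
#' Chains [filter_psms()], [check_uniqueness()], [assign_hla()],
#' [annotate_isoform_coverage()] and [build_candidate_table()] over a PSM
#' table and a role-annotated proteome. Peptides that fail the uniqueness
#' margin are dropped from the candidate table (they remain visible in the
#' returned `uniqueness` component).
#'
#' @inheritParams filter_psms
#' @param proteome Proteome tibble.
#' @param predictor Binding predictor function.
#' @param allele_freq Allele-frequency tibble.
#' @param rank_max,freq_min,mismatch_margin Triage thresholds (defaults 2.0,
#'   1.0, 2).
#' @return A list with `candidates`, `uniqueness`, `coverage`, `rejections`.
#' @export
triage_ligandome <- function(psms, proteome, predictor, allele_freq,
                             score_min = 20, ppm_max = 10, soft_score = TRUE,
                             rank_max = 2.0, freq_min = 1.0,
                             mismatch_margin = 2) {
  filt <- filter_psms(psms, score_min, ppm_max, soft_score)
  retained <- filt$retained
  index <- proteome_index(proteome)
  gene_of <- setNames(index$targets$gene, index$targets$protein_id)
  retained$gene <- unname(gene_of[retained$protein_id])
  if (nrow(retained) == 0) {
    return(list(
      candidates = build_candidate_table(
        mutate(retained, gene = character(0))
      ),
      uniqueness = NULL, coverage = NULL, rejections = filt$rejections
    ))
  }
  uniq <- check_uniqueness(retained$peptide, index, mismatch_margin)
  coverage <- annotate_isoform_coverage(retained$peptide, index)
  assignments <- retained |>
    group_by(.data$peptide) |>
    summarise(typings = list(unique(.data$hla_typing)), .groups = "drop") |>
    pmap(function(peptide, typings) {
      assign_hla(
        peptide, typings, predictor, allele_freq,
        rank_max = rank_max, freq_min = freq_min
      )
    }) |>
    list_rbind()
  keep_peptides <- uniq$peptide[uniq$unique_to_target]
  candidates <- build_candidate_table(
    retained[retained$peptide %in% keep_peptides, ],
    assignments = assignments,
    uniqueness = uniq,
    coverage = coverage
  )
  list(
    candidates = candidates,
    uniqueness = uniq,
    coverage = coverage,
    rejections = filt$rejections
  )
}

#' The packaged ovarian-cancer peptide panel
#'
#' Loads the packaged panel of 17 published HLA class I peptides derived from
#' the ovarian-cancer target genes PRAME, CTCFL and CLDN6: for each peptide
#' its HLA restriction, the samples/cell lines it was eluted from, and the
#' best ion score. One peptide (LYVDSLFFL in A*24:02) was included on
#' literature evidence rather than identified by mass spectrometry and
#' carries no source or score.
#'
#' @return A tibble with columns `gene`, `peptide`, `hla_allele`, `sources`,
#'   `best_ion_score`, `literature_only`.
#' @examples
#' panel <- ovca_peptide_panel()
#' nrow(panel) # 17
#' @export
ovca_peptide_panel <- function() {
  readr::read_tsv(
    taa_extdata("ovca_peptides.tsv"),
    show_col_types = FALSE
  ) |>
    mutate(
      sources = dplyr::coalesce(.data$sources, ""),
      literature_only = .data$sources == ""
    )
}

#' Replay a published peptide panel through the candidate-table builder
#'
#' Expands each panel row into per-source PSM-shaped records (plus the
#' literature-only rows) and rebuilds the candidate table, verifying that the
#' builder reproduces the published row structure.
#'
#' @param panel Tibble as returned by [ovca_peptide_panel()].
#' @return The rebuilt candidate tibble (one row per peptide-HLA pair).
#' @export
replay_peptide_panel <- function(panel = ovca_peptide_panel()) {
  observed <- panel[!panel$literature_only, ]
  psms <- observed |>
    mutate(sample_id = strsplit(.data$sources, ";")) |>
    tidyr::unnest("sample_id") |>
    transmute(
      .data$sample_id,
      .data$gene,
      .data$peptide,
      .data$hla_allele,
      best_ion_score = .data$best_ion_score
    )
  build_candidate_table(
    psms,
    literature = panel[panel$literature_only, ]
  )
}
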