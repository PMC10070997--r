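#' Read and write pipeline artifacts
#'
#' Delimited-text round-trips for every artifact the pipeline consumes or
#' emits: counts (genes x samples TSV with a header row of sample ids), sample
#' and gene annotations (TSV), size factors (TSV), PSM tables (CSV with
#' semicolon-joined HLA typings), Ct tables (long TSV) and proteomes (FASTA
#' with role-annotated headers).
#'
#' @param atlas A [count_atlas()].
#' @param dir Directory to write the three atlas files into.
#' @return `write_count_atlas()` returns the written paths invisibly;
#'   `read_count_atlas()` returns a [count_atlas()].
#' @name atlas_io
NULL

#' @rdname atlas_io
#' @export
write_count_atlas <- function(atlas, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("counts.tsv", "samples.tsv", "genes.tsv"))
  counts_tbl <- as_tibble(atlas$counts, rownames = "gene_id")
  readr::write_tsv(counts_tbl, paths[1])
  readr::write_tsv(atlas$samples, paths[2])
  readr::write_tsv(atlas$genes, paths[3])
  invisible(paths)
}

#' @rdname atlas_io
#' @export
read_count_atlas <- function(dir) {
  counts_tbl <- readr::read_tsv(
    file.path(dir, "counts.tsv"),
    show_col_types = FALSE
  )
  counts <- as.matrix(counts_tbl[, -1])
  storage.mode(counts) <- "integer"
  rownames(counts) <- counts_tbl$gene_id
  samples <- readr::read_tsv(
    file.path(dir, "samples.tsv"),
    show_col_types = FALSE
  )
  genes <- readr::read_tsv(file.path(dir, "genes.tsv"), show_col_types = FALSE)
  count_atlas(counts, samples, genes)
}

#' Write a proteome tibble as role-annotated FASTA
#'
#' Headers carry machine-parseable key=value fields:
#' `>PROT_ID gene=G isoform=I role=R`.
#'
#' @param proteome Tibble from [simulate_proteome()].
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
write_proteome_fasta <- function(proteome, path) {
  seqs <- Biostrings::AAStringSet(proteome$sequence)
  names(seqs) <- sprintf(
    "%s gene=%s isoform=%s role=%s",
    proteome$protein_id, proteome$gene,
    ifelse(is.na(proteome$isoform), "NA", proteome$isoform),
    proteome$role
  )
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a role-annotated proteome FASTA
#'
#' @param path FASTA path written by [write_proteome_fasta()] (or any FASTA
#'   whose headers carry `gene=`, `isoform=` and `role=` fields).
#' @return A proteome tibble (see [simulate_proteome()]).
#' @export
read_proteome_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  headers <- names(seqs)
  field <- function(key) {
    m <- regmatches(headers, regexpr(paste0(key, "=[^ ]+"), headers))
    sub(paste0(key, "="), "", m)
  }
  iso <- field("isoform")
  tibble(
    protein_id = sub(" .*", "", headers),
    gene = field("gene"),
    isoform = suppressWarnings(as.integer(iso)),
    role = field("role"),
    sequence = unname(as.character(seqs))
  )
}

#' Read and write PSM tables
#'
#' Comma-delimited with columns `sample_id`, `peptide`, `protein_id`,
#' `best_ion_score`, `ppm_error`, `hla_typing` (semicolon-joined alleles).
#' Peptides are validated at parse time: standard residues only, class I
#' lengths 8-15.
#'
#' @param psms PSM tibble.
#' @param path File path.
#' @return `read_psm_table()` returns a validated tibble.
#' @name psm_io
NULL

#' @rdname psm_io
#' @export
write_psm_table <- function(psms, path) {
  readr::write_csv(psms, path)
  invisible(path)
}

#' @rdname psm_io
#' @export
read_psm_table <- function(path) {
  psms <- readr::read_csv(path, show_col_types = FALSE)
  validate_psms(psms)
}

validate_psms <- function(psms) {
  bad <- !grepl(PEPTIDE_REGEX, psms$peptide)
  if (any(bad)) {
    abort(paste0(
      "malformed peptide sequence in PSM record(s): ",
      paste(unique(psms$peptide[bad]), collapse = ", ")
    ))
  }
  n <- nchar(psms$peptide)
  if (any(n < 8 | n > 15)) {
    off <- unique(psms$peptide[n < 8 | n > 15])
    abort(paste0(
      "peptides outside the HLA class I length range 8-15: ",
      paste(off, collapse = ", ")
    ))
  }
  alleles <- unique(unlist(strsplit(psms$hla_typing, ";")))
  bad_allele <- alleles[!grepl(HLA_ALLELE_REGEX, alleles)]
  if (length(bad_allele)) {
    abort(paste0(
      "HLA allele names not in locus*group:protein form: ",
      paste(bad_allele, collapse = ", ")
    ))
  }
  as_tibble(psms)
}

#' @rdname atlas_io
#' @param factors Size-factor tibble from [compute_size_factors()].
#' @param path File path.
#' @export
write_size_factors <- function(factors, path) {
  readr::write_tsv(factors[, c("sample_id", "size_factor")], path)
  invisible(path)
}

#' Read a long-format Ct table
#'
#' Tab-delimited with columns `sample_id`, `gene`, `ct`.
#'
#' @param ct Ct tibble.
#' @param path File path.
#' @return `read_ct_table()` returns a tibble.
#' @name ct_io
NULL

#' @rdname ct_io
#' @export
write_ct_table <- function(ct, path) {
  readr::write_tsv(ct, path)
  invisible(path)
}

#' @rdname ct_io
#' @export
read_ct_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Read an HLA allele population-frequency table
#'
#' Tab-delimited with columns `allele`, `frequency_percent`. A synthetic
#' illustrative table covering the alleles of the packaged peptide panel ships
#' with the package (see [taa_extdata()]).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_allele_frequencies <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Locate packaged example data
#'
#' @param file File name under the package's `extdata/`; with no argument,
#'   lists the available files.
#' @return A file path (or a vector of file names).
#' @export
taa_extdata <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "taascreen")))
  }
  path <- system.file("extdata", file, package = "taascreen")
  if (path == "") abort(paste0("no packaged file called ", file))
  path
}
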