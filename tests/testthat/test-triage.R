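test_that("PSM filtering applies the score and mass-accuracy rules", {
  psms <- tibble::tibble(
    sample_id = paste0("s", 1:4),
    peptide = c("QLLALLPSL", "KLHGILVEA", "SPSVSQLSVL", "YEDIHGTLHL"),
    protein_id = "P1",
    best_ion_score = c(37, 12, 65, 42),
    ppm_error = c(3, 2, 10.0, 10.0001),
    hla_typing = "A*02:01;B*07:02"
  )
  soft <- filter_psms(psms)
  expect_equal(soft$retained$peptide,
               c("QLLALLPSL", "KLHGILVEA", "SPSVSQLSVL"))
  expect_equal(soft$retained$below_score_threshold, c(FALSE, TRUE, FALSE))
  expect_equal(soft$rejections$reason, "ppm_error")  # 10.0001 ppm out

  strict <- filter_psms(psms, soft_score = FALSE)
  expect_equal(strict$retained$peptide, c("QLLALLPSL", "SPSVSQLSVL"))
  expect_true("best_ion_score" %in% strict$rejections$reason)

  bad <- psms
  bad$peptide[1] <- "QLLAXLPSL"
  expect_error(filter_psms(bad), "QLLAXLPSL")
  short <- psms
  short$peptide[2] <- "KLHGILV"
  expect_error(filter_psms(short), "length")
})

test_that("uniqueness scanning finds the minimum off-target Hamming distance", {
  core <- paste(rep("ACDEFGHIKLMNPQRSTVWY", 3), collapse = "")
  pep <- substr(core, 11, 19)  # MNPQRSTVW
  # off-target 1 embeds the peptide verbatim; off-target 2 carries a window
  # differing at exactly 4 positions (M->W, Q->A, T->C, W->H)
  offt2 <- paste0("AAAA", "WNPARSCVH", "CCCC")
  proteome <- tibble::tibble(
    protein_id = c("T-iso1", "OFF1", "OFF2"),
    gene = c("T", "OFF1", "OFF2"),
    isoform = c(1L, NA, NA),
    role = c("target", "family_offtarget", "family_offtarget"),
    sequence = c(core, paste0("GGG", pep, "GGG"), offt2)
  )
  idx <- proteome_index(proteome)

  res <- check_uniqueness(pep, idx, mismatch_margin = 2)
  expect_false(res$unique_to_target)          # verbatim substring of OFF1
  expect_equal(res$min_mismatch_to_offtarget, 0)
  expect_equal(res$closest_offtarget, "OFF1")

  idx2 <- proteome_index(proteome[c(1, 3), ])
  res2 <- check_uniqueness(pep, idx2, mismatch_margin = 2)
  expect_equal(res2$min_mismatch_to_offtarget, 4)
  expect_true(res2$unique_to_target)
  expect_equal(res2$min_mismatch_to_offtarget,
               bf_min_hamming(pep, offt2))

  expect_error(check_uniqueness("WWWWWWWW", idx), "does not occur")
})

test_that("uniqueness matches the brute-force window scan on a seeded fixture", {
  pr <- toy_proteome(seed = 23)
  idx <- proteome_index(pr)
  target_seq <- pr$sequence[pr$role == "target"]
  off_seqs <- pr$sequence[pr$role == "family_offtarget"]
  set.seed(8)
  for (k in c(8, 9, 11, 15)) {
    start <- sample.int(nchar(target_seq) - k + 1, 1)
    pep <- substr(target_seq, start, start + k - 1)
    got <- check_uniqueness(pep, idx)
    expect_equal(got$min_mismatch_to_offtarget,
                 bf_min_hamming(pep, off_seqs))
  }

  # anti-monotonicity: adding off-target sequences never raises the minimum
  peps <- vapply(c(1, 30, 60), function(st) {
    substr(target_seq, st, st + 8)
  }, character(1))
  idx_small <- proteome_index(pr[pr$role != "family_offtarget" |
                                   pr$protein_id == "CTCF", ])
  d_small <- check_uniqueness(peps, idx_small)
  d_full <- check_uniqueness(peps, idx)
  expect_true(all(
    d_full$min_mismatch_to_offtarget <= d_small$min_mismatch_to_offtarget
  ))
  expect_true(all(d_full$unique_to_target <= d_small$unique_to_target))
})

test_that("HLA assignment requires binding, typing match and common allele", {
  freq <- tibble::tibble(
    allele = c("A*02:01", "B*07:02", "B*35:01", "B*73:01"),
    frequency_percent = c(27, 12, 6.6, 0.5)
  )
  pred <- fixed_binding_predictor(tibble::tibble(
    peptide = rep("MPMQDIKMIL", 4),
    allele = c("A*02:01", "B*07:02", "B*35:01", "B*73:01"),
    rank = c(0.2, 0.5, 1.5, 0.1)
  ))

  # strong predicted binder to an allele absent from every observing sample
  got <- assign_hla(
    "MPMQDIKMIL", c("B*07:02;B*35:01", "B*07:02;B*73:01"), pred, freq
  )
  expect_false("A*02:01" %in% got$hla_allele)
  # one peptide, two assigned alleles -> two candidate rows downstream
  expect_equal(got$hla_allele, c("B*07:02", "B*35:01"))
  # the 0.5%-frequency allele is never assigned at freq_min 1% despite rank
  expect_false("B*73:01" %in% got$hla_allele)

  expect_error(
    assign_hla("MPMQDIKMIL", "C*07:01", pred, freq),
    "missing from the frequency table"
  )

  # the bundled stub predictor is deterministic with ranks in (0, 100]
  stub <- stub_binding_predictor()
  r1 <- stub(c("QLLALLPSL", "QLLALLPSL"), c("A*02:01", "B*07:02"))
  expect_identical(r1, stub(c("QLLALLPSL", "QLLALLPSL"),
                            c("A*02:01", "B*07:02")))
  expect_true(all(r1 > 0 & r1 <= 100))
  expect_false(r1[1] == r1[2])
})

test_that("isoform coverage counts exact-substring containment", {
  pr <- toy_proteome()
  idx <- proteome_index(pr)
  isoforms <- pr$sequence[pr$role %in% c("target", "target_isoform")]
  core_pep <- substr(isoforms[1], 40, 48)
  uniq_pep <- substr(isoforms[3], 121 + 5, 121 + 13)  # variant 3 unique tail

  cov <- annotate_isoform_coverage(c(core_pep, uniq_pep), idx)
  expect_equal(cov$n_containing, c(3L, 1L))
  expect_equal(cov$n_isoforms, c(3L, 3L))

  # brute-force substring count agrees for arbitrary windows
  set.seed(4)
  for (st in sample(10:100, 5)) {
    pep <- substr(isoforms[2], st, st + 8)
    expect_equal(
      annotate_isoform_coverage(pep, idx)$n_containing,
      sum(vapply(isoforms, grepl, TRUE, pattern = pep, fixed = TRUE))
    )
  }
})

test_that("the candidate builder reproduces the packaged peptide panel", {
  rebuilt <- replay_peptide_panel()
  expect_equal(nrow(rebuilt), 17)
  expect_equal(sum(rebuilt$source_samples != ""), 16)
  expect_equal(sum(rebuilt$literature_only), 1)
  expect_equal(sum(rebuilt$gene == "PRAME"), 9)

  # one peptide listed under two alleles keeps two rows
  mpm <- rebuilt[rebuilt$peptide == "MPMQDIKMIL", ]
  expect_equal(sort(mpm$hla_allele), c("B*07:02", "B*35:01"))

  # the sub-threshold score the panel retained is present
  expect_true(any(rebuilt$peptide == "KLHGILVEA" &
                    rebuilt$best_score_seen == 12))

  # empty input gives an empty, well-formed table
  empty <- build_candidate_table(
    tibble::tibble(
      gene = character(), peptide = character(), hla_allele = character(),
      sample_id = character(), best_ion_score = numeric()
    )
  )
  expect_equal(nrow(empty), 0)
  expect_true(all(c("gene", "peptide", "hla_allele", "source_samples") %in%
                    names(empty)))
})

test_that("the full triage chain composes and stays order-invariant", {
  pr <- toy_proteome(seed = 37)
  psms <- simulate_psms(
    psm_spec(n_psms = 120, frac_below_score = 0.15, frac_ppm_out = 0.1,
             seed = 13),
    pr
  )
  freq <- toy_allele_freq()
  pred <- function(peptide, allele) {
    ifelse(substr(allele, 1, 1) == "A", 0.5, 5)  # A alleles bind, B/C do not
  }
  tri <- triage_ligandome(psms, pr, pred, freq)

  expect_true(all(tri$candidates$unique_to_target))
  expect_true(all(tri$candidates$n_sources >= 1 |
                    tri$candidates$literature_only))
  expect_true(all(substr(tri$candidates$hla_allele, 1, 1) == "A"))
  expect_equal(
    nrow(dplyr::distinct(tri$candidates, peptide, hla_allele)),
    nrow(tri$candidates)
  )

  # score/ppm filtering commutes with uniqueness checking
  filt_first <- filter_psms(psms)$retained
  uniq_after <- check_uniqueness(unique(filt_first$peptide),
                                 proteome_index(pr))
  uniq_all <- check_uniqueness(unique(psms$peptide), proteome_index(pr))
  keep_a <- sort(intersect(
    filt_first$peptide, uniq_after$peptide[uniq_after$unique_to_target]
  ))
  keep_b <- sort(intersect(
    filter_psms(psms)$retained$peptide,
    uniq_all$peptide[uniq_all$unique_to_target]
  ))
  expect_identical(keep_a, keep_b)
})
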