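# Independent brute-force reference implementations used to check the
# package's computations on small seeded instances. These deliberately share
# no code with the implementation: plain loops, optimize()-based likelihood
# maximization, and textbook formulas.

bf_size_factors <- function(counts) {
  usable <- apply(counts, 1, function(r) all(r > 0))
  ref <- apply(counts[usable, , drop = FALSE], 1, function(r) {
    exp(mean(log(r)))
  })
  vapply(seq_len(ncol(counts)), function(j) {
    stats::median(counts[usable, j] / ref)
  }, numeric(1))
}

bf_log2_cpm <- function(counts, factors, prior) {
  out <- counts * NA_real_
  for (j in seq_len(ncol(counts))) {
    eff <- sum(counts[, j]) * factors[j]
    for (i in seq_len(nrow(counts))) {
      out[i, j] <- log2((counts[i, j] + prior) / eff * 1e6)
    }
  }
  out
}

bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running_min <- 1
  for (k in rev(seq_len(m))) {
    running_min <- min(running_min, p[o[k]] * m / k)
    adj[o[k]] <- running_min
  }
  adj
}

# Textbook type-7 sample quantile by linear interpolation of sorted values.
bf_quantile7 <- function(x, probs) {
  s <- sort(x)
  n <- length(s)
  vapply(probs, function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }, numeric(1))
}

bf_min_hamming <- function(peptide, sequences) {
  pep <- strsplit(peptide, "")[[1]]
  k <- length(pep)
  best <- Inf
  for (s in sequences) {
    chars <- strsplit(s, "")[[1]]
    n <- length(chars)
    if (n < k) next
    for (start in seq_len(n - k + 1)) {
      d <- sum(chars[start:(start + k - 1)] != pep)
      best <- min(best, d)
    }
  }
  best
}

# Grid-search/optimize NB likelihood maximization for the two-group
# likelihood-ratio test at fixed dispersion, one gene at a time.
bf_nb_lrt <- function(y1, y2, s1, s2, phi) {
  ll <- function(y, s, lam) {
    if (phi > 0) {
      sum(stats::dnbinom(y, size = 1 / phi, mu = pmax(lam, 1e-12) * s,
                         log = TRUE))
    } else {
      sum(stats::dpois(y, lambda = pmax(lam, 1e-12) * s, log = TRUE))
    }
  }
  fit <- function(y, s) {
    upper <- max(1, 4 * sum(y) / sum(s))
    grid <- seq(0, upper, length.out = 200)
    coarse <- grid[which.max(vapply(grid, function(l) ll(y, s, l), 1))]
    lo <- max(0, coarse - upper / 100)
    hi <- coarse + upper / 100
    opt <- stats::optimize(function(l) ll(y, s, l),
                           lower = lo, upper = hi,
                           maximum = TRUE, tol = 1e-12)
    opt$objective
  }
  stat <- max(0, 2 * (fit(y1, s1) + fit(y2, s2) -
                        fit(c(y1, y2), c(s1, s2))))
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

# Shared small fixtures -------------------------------------------------------

toy_proteome <- function(seed = 11) {
  simulate_proteome(proteome_spec(
    target_gene = "CTCFL", n_isoforms = 3, shared_core_length = 120,
    unique_region_lengths = c(20, 25, 30),
    family_members = tibble::tibble(
      name = c("CTCF", "CLDN9"),
      identity = c(75, 88),
      length = c(140, 130)
    ),
    seed = seed
  ))
}

toy_allele_freq <- function() {
  read_allele_frequencies(taa_extdata("hla_frequencies_synthetic.tsv"))
}

small_screen_config <- function(seed = 1, planted = NULL, n_genes = 120) {
  sim_config(
    seed = seed,
    panel = default_tissue_panel(n_bulk = 5, n_protein_atlas = 2),
    n_genes = n_genes,
    library_size_cv = 0.2,
    planted = planted
  )
}
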