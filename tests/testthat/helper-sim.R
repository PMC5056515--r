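# Shared fixtures and independent oracles for the test suite.

# A small, quick collection used across tests.
small_config <- function(seed = 7, ...) {
  defaults <- list(n_founders = 6, n_genotypes = 24, n_chromosomes = 3,
                   n_transcripts = 120, prob_polymorphic = 0.5,
                   mean_snps_per_transcript = 4, n_clusters = 3, n_traits = 4,
                   seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# Build a genotype matrix from a bare dosage matrix.
toy_geno <- function(dosage, pos = NULL, chrom = NULL) {
  S <- ncol(dosage)
  sites <- data.frame(site_id = sprintf("s%03d", seq_len(S)),
                      ref = "A", var = "G", stringsAsFactors = FALSE)
  if (!is.null(pos)) sites$pos <- pos
  if (!is.null(chrom)) sites$chrom <- rep_len(chrom, S)
  genotype_matrix(dosage, sites)
}

# One allele-depth record.
depth_rec <- function(sample, site, ref_n, var_n, qual = 30,
                      ref = "A", var = "G") {
  data.frame(sample = sample, site_id = site, ref_allele = ref,
             var_allele = var, ref_count = ref_n, var_count = var_n,
             mean_var_quality = qual, stringsAsFactors = FALSE)
}

# Brute-force nucleotide diversity: expand every sample into its two
# allele copies and average the mismatch indicator over all pairs of
# copies, per site; returns the sum over sites (pi * L). Independent of
# the frequency-based formula in the package.
brute_force_pi_total <- function(dosage) {
  total <- 0
  for (s in seq_len(ncol(dosage))) {
    d <- dosage[, s]
    d <- d[!is.na(d)]
    copies <- unlist(lapply(d, function(x) c(rep(1, x), rep(0, 2 - x))))
    n <- length(copies)
    if (n < 2) next
    diffs <- 0
    for (i in seq_len(n - 1)) {
      diffs <- diffs + sum(copies[i] != copies[(i + 1):n])
    }
    total <- total + diffs / choose(n, 2)
  }
  total
}

# Brute-force Gabriel block finder: classify every eligible pair with
# dprime_ci, enumerate ALL contiguous spans, keep those passing the
# strong-fraction rule within the span cap, then accept greedily by bp
# length (ties: leftmost). Mirrors the documented rule, not the package's
# windowed implementation.
brute_force_blocks <- function(g, max_block_kb = 2000,
                               min_strong_fraction = 0.95, min_maf = 0.05) {
  maf <- pmin(colMeans(g$dosage, na.rm = TRUE) / 2,
              1 - colMeans(g$dosage, na.rm = TRUE) / 2)
  keep <- which(!is.na(g$sites$chrom) & !is.na(g$sites$pos) & maf >= min_maf)
  out <- list()
  for (ch in unique(g$sites$chrom[keep])) {
    idx <- keep[g$sites$chrom[keep] == ch]
    idx <- idx[order(g$sites$pos[idx])]
    m <- length(idx)
    if (m < 2) next
    pos <- g$sites$pos[idx]
    class_of <- matrix(0L, m, m)
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        if (pos[j] - pos[i] > max_block_kb * 1000) next
        ci <- tryCatch(dprime_ci(g$dosage[, idx[i]], g$dosage[, idx[j]]),
                       error = function(e) NULL)
        if (is.null(ci)) next
        if (ci$ci_low > 0.7 && ci$ci_high >= 0.98) class_of[i, j] <- 1L
        else if (ci$ci_high < 0.9) class_of[i, j] <- -1L
      }
    }
    cand <- NULL
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        if (pos[j] - pos[i] > max_block_kb * 1000) next
        cls <- class_of[i:j, i:j][upper.tri(diag(j - i + 1))]
        strong <- sum(cls == 1L); recomb <- sum(cls == -1L)
        if (strong + recomb >= 1 && strong / (strong + recomb) > min_strong_fraction)
          cand <- rbind(cand, data.frame(i = i, j = j, span = pos[j] - pos[i]))
      }
    }
    if (is.null(cand)) next
    cand <- cand[order(-cand$span, cand$i), , drop = FALSE]
    taken <- rep(FALSE, m)
    for (r in seq_len(nrow(cand))) {
      rng <- cand$i[r]:cand$j[r]
      if (any(taken[rng])) next
      taken[rng] <- TRUE
      out[[length(out) + 1]] <- data.frame(chrom = ch, start = pos[cand$i[r]],
                                           end = pos[cand$j[r]],
                                           n_snps = length(rng))
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_snps = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

# Sample an unphased genotype matrix for two loci from known phased
# haplotype frequencies (f_rr, f_rv, f_vr, f_vv); returns dosage columns.
sample_two_locus <- function(n, f) {
  haps <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), ncol = 2, byrow = TRUE)
  pick <- sample.int(4, 2 * n, replace = TRUE, prob = f)
  h <- haps[pick, , drop = FALSE]
  a <- h[seq(1, 2 * n, 2), ] + h[seq(2, 2 * n, 2), ]
  list(da = a[, 1], db = a[, 2])
}
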