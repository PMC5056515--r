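test_that("synteny projection follows the strand-aware offset rule", {
  dose <- matrix(1L, 2, 3)
  sites <- data.frame(site_id = c("a", "b", "c"),
                      transcript_id = c("t1", "t2", "t3"),
                      offset = c(5L, 10L, 7L), ref = "A", var = "G",
                      stringsAsFactors = FALSE)
  g <- genotype_matrix(dose, sites, samples = c("s1", "s2"))
  anchors <- data.frame(transcript_id = c("t1", "t2"),
                        chrom = c("Chr01", "Chr02"), start = c(1000L, 500L),
                        strand = c("+", "-"), transcript_length = c(100L, 100L),
                        stringsAsFactors = FALSE)
  gp <- project_snps(g, anchors)
  expect_equal(gp$sites$pos[1], 1004)          # 1000 + 5 - 1
  expect_equal(gp$sites$pos[2], 500 + 100 - 10)
  expect_true(is.na(gp$sites$pos[3]))          # unanchored stays unplaced
  expect_equal(attr(gp, "placed_fraction"), 2 / 3)
  # minus strand without a transcript length: anchored at start with warning
  anchors$transcript_length <- NULL
  expect_warning(gp2 <- project_snps(g, anchors), "transcript length unknown")
  expect_equal(gp2$sites$pos[2], 500)
  # anchors with unknown chromosome are rejected with a warning
  anchors2 <- data.frame(transcript_id = "t1", chrom = NA_character_,
                         start = 1L, strand = "+", stringsAsFactors = FALSE)
  expect_warning(project_snps(g, anchors2), "rejected")
})

test_that("identical genotype columns are in perfect LD", {
  set.seed(1)
  x <- as.integer(rbinom(40, 2, 0.5))
  g <- toy_geno(cbind(x, x))
  ld <- pairwise_r2(g, matrix(c(1, 2), ncol = 2))
  expect_equal(ld$r2, 1, tolerance = 1e-9)
  expect_equal(ld$dprime, 1, tolerance = 1e-9)
})

test_that("EM haplotype frequencies match phased truth on large samples", {
  set.seed(2)
  freqs <- list(c(0.4, 0.1, 0.1, 0.4), c(0.25, 0.25, 0.25, 0.25),
                c(0.55, 0.05, 0.15, 0.25))
  for (f in freqs) {
    tl <- sample_two_locus(10000, f)
    g <- toy_geno(cbind(tl$da, tl$db))
    ld <- pairwise_r2(g, matrix(c(1, 2), ncol = 2))
    est <- as.numeric(ld[1, c("f_rr", "f_rv", "f_vr", "f_vv")])
    expect_lt(max(abs(est - f)), 0.01)
  }
})

test_that("EM r2 equals the phased allele-copy correlation without double heterozygotes", {
  # without double heterozygotes every individual's haplotypes are directly
  # observable, so the EM answer must equal the squared Pearson correlation
  # of allelic states across the 2n observed haplotypes, exactly
  da <- as.integer(c(0, 0, 1, 1, 2, 2, 0, 2, 1, 0))
  db <- as.integer(c(0, 1, 0, 2, 2, 2, 0, 1, 0, 0))
  stopifnot(sum(da == 1 & db == 1) == 0)
  # haplotype phasing is unambiguous when at most one locus is heterozygous
  expand <- function(d) if (d == 1L) c(1L, 0L) else rep(d %/% 2L, 2)
  hap_a <- unlist(lapply(da, expand))
  hap_b <- unlist(lapply(db, expand))
  g <- toy_geno(cbind(da, db))
  ld <- pairwise_r2(g, matrix(c(1, 2), ncol = 2))
  expect_equal(ld$r2, cor(hap_a, hap_b)^2, tolerance = 1e-9)
})

test_that("independent loci show null-scale r2, not 0.5", {
  set.seed(4)
  n <- 52
  r2 <- replicate(300, {
    tl <- sample_two_locus(n, c(0.36, 0.24, 0.24, 0.16))  # independent: D = 0
    g <- toy_geno(cbind(tl$da, tl$db))
    out <- pairwise_r2(g, matrix(c(1, 2), ncol = 2))
    if (nrow(out)) out$r2 else NA_real_
  })
  m <- mean(r2, na.rm = TRUE)
  expect_lt(m, 0.1)          # near 1/n scale
  expect_gt(m, 0.001)
})

test_that("D' confidence intervals separate strong LD from recombination", {
  set.seed(6)
  # perfect LD, decent sample: strong-LD call
  tl <- sample_two_locus(60, c(0.5, 0, 0, 0.5))
  ci <- dprime_ci(tl$da, tl$db)
  expect_gt(ci$ci_low, 0.7)
  expect_gte(ci$ci_high, 0.98)
  # independent loci, large sample: strong recombination evidence
  tl0 <- sample_two_locus(400, c(0.25, 0.25, 0.25, 0.25))
  ci0 <- dprime_ci(tl0$da, tl0$db)
  expect_lt(ci0$ci_high, 0.9)
  # tiny sample with only double heterozygotes: wide, uninformative interval
  ci4 <- dprime_ci(rep(1L, 4), rep(1L, 4))
  expect_lt(ci4$ci_low, 0.7)
  expect_gte(ci4$ci_high, 0.98)
})

test_that("background LD is high for duplicated chromosomes and seed-stable", {
  set.seed(9)
  S <- 30
  # every site on both chromosomes carries the same genotype vector, so
  # all inter-chromosome pairs are in perfect LD
  x <- as.integer(rbinom(40, 2, 0.5))
  dup <- matrix(rep(x, 2 * S), nrow = 40)
  g <- toy_geno(dup, pos = rep(seq_len(S) * 1000L, 2),
                chrom = rep(c("Chr01", "Chr02"), each = S))
  thr <- background_ld(g, n_pairs = 2000, seed = 5)
  expect_gt(thr, 0.99)
  thr2 <- background_ld(g, n_pairs = 2000, seed = 5)
  expect_identical(as.numeric(thr), as.numeric(thr2))
})

test_that("background LD is near the null scale for unrelated samples", {
  set.seed(10)
  n <- 80; S <- 60
  dose <- matrix(as.integer(rbinom(n * S, 2, 0.5)), n, S)
  g <- toy_geno(dose, pos = rep(seq_len(S / 2) * 1000L, 2),
                chrom = rep(c("Chr01", "Chr02"), each = S / 2))
  thr <- background_ld(g, n_pairs = 800, seed = 3)
  expect_lt(thr, 0.2)
})

test_that("LD decay table and decay distances behave at the edges", {
  pairs <- data.frame(r2 = c(0.8, 0.7, 0.3, 0.25, 0.05, 0.04),
                      dist_bp = c(1000, 2000, 7000, 8000, 14000, 16000))
  dec <- ld_decay(pairs, bin_width_kb = 5, thresholds = c(0.1, 0.3, 0.9))
  expect_equal(nrow(dec$table), 4)
  expect_equal(unname(dec$decay_kb[["r2<0.1"]]), 12.5)   # third bin midpoint
  expect_equal(unname(dec$decay_kb[["r2<0.3"]]), 7.5)
  # threshold above every bin mean: first bin midpoint
  expect_equal(unname(dec$decay_kb[["r2<0.9"]]), 2.5)
  single <- ld_decay(data.frame(r2 = 0.5, dist_bp = 100), bin_width_kb = 5)
  expect_equal(nrow(single$table), 1)
})

test_that("LD decays faster under more recombination", {
  decay_for <- function(gens, seed) {
    cfg <- small_config(seed = seed, n_transcripts = 150,
                        generations = gens, n_genotypes = 40,
                        chromosome_length_bp = 2e6, cluster_fst = 0,
                        n_clusters = 2, n_founders = 4)
    sim <- simulate_collection(cfg, reads = FALSE)
    g <- sim$truth$true_genotypes
    keep <- which(pmin(colMeans(g$dosage) / 2, 1 - colMeans(g$dosage) / 2) > 0.05)
    g <- g[, keep]
    pr <- snpgem:::within_chromosome_pairs(g, max_dist_bp = 2e6, max_pairs = 4000,
                                           seed = 1)
    ld <- pairwise_r2(g, pr)
    mean(ld$r2[ld$dist_bp > 5e5], na.rm = TRUE) -
      mean(ld$r2[ld$dist_bp < 1e5], na.rm = TRUE)
  }
  # long-range LD (relative to short-range) shrinks with more meioses
  few <- decay_for(1, 41)
  many <- decay_for(6, 41)
  expect_lt(many, few + 0.05)
})

test_that("haplotype blocks recover a planted perfect-LD cluster", {
  set.seed(11)
  n <- 40
  x <- as.integer(rbinom(n, 2, 0.5))
  indep <- function() as.integer(rbinom(n, 2, 0.5))
  dose <- cbind(indep(), x, x, x, x, x, indep())
  pos <- c(1000L, 50000L, 60000L, 70000L, 80000L, 90000L, 200000L)
  g <- toy_geno(dose, pos = pos, chrom = "Chr01")
  bl <- haplotype_blocks(g)
  expect_equal(nrow(bl), 1)
  expect_equal(bl$start, 50000)
  expect_equal(bl$end, 90000)
  expect_equal(bl$n_snps, 5)
})

test_that("independent loci yield no blocks; over-cap spans are rejected", {
  set.seed(12)
  n <- 100
  dose <- matrix(as.integer(rbinom(n * 10, 2, 0.5)), n, 10)
  g <- toy_geno(dose, pos = seq_len(10) * 10000L, chrom = "Chr01")
  expect_equal(nrow(haplotype_blocks(g)), 0)
  # perfect pair 2,500 kb apart exceeds the 2,000 kb cap
  x <- as.integer(rbinom(n, 2, 0.5))
  g2 <- toy_geno(cbind(x, x), pos = c(1L, 2500001L), chrom = "Chr01")
  expect_equal(nrow(haplotype_blocks(g2)), 0)
})

test_that("windowed block finder matches exhaustive enumeration", {
  set.seed(13)
  for (rep in 1:3) {
    n <- 30
    S <- 12
    base <- as.integer(rbinom(n, 2, 0.5))
    dose <- sapply(seq_len(S), function(s) {
      if (runif(1) < 0.5) {
        d <- base
        flip <- sample(n, 2)
        d[flip] <- sample(0:2, 2, TRUE)
        as.integer(d)
      } else as.integer(rbinom(n, 2, runif(1, 0.2, 0.8)))
    })
    pos <- sort(sample.int(3e6, S))
    g <- toy_geno(dose, pos = pos, chrom = "Chr01")
    got <- haplotype_blocks(g)
    want <- brute_force_blocks(g)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$n_snps, want$n_snps)
    }
  }
})

test_that("accepted blocks re-audit cleanly and never overlap", {
  set.seed(14)
  n <- 35
  x <- as.integer(rbinom(n, 2, 0.4))
  y <- as.integer(rbinom(n, 2, 0.6))
  dose <- cbind(x, x, x, y, y, y,
                as.integer(rbinom(n, 2, 0.5)))
  pos <- c(1e4, 2e4, 3e4, 2e5, 2.1e5, 2.2e5, 5e5)
  g <- toy_geno(dose, pos = as.integer(pos), chrom = "Chr01")
  bl <- haplotype_blocks(g)
  expect_gte(nrow(bl), 1)
  if (nrow(bl) > 1) {
    for (r in 2:nrow(bl)) expect_gt(bl$start[r], bl$end[r - 1])
  }
  # every reported block passes the strong-fraction rule when re-checked
  for (r in seq_len(nrow(bl))) {
    ids <- strsplit(bl$site_ids[r], ",")[[1]]
    idx <- match(ids, g$sites$site_id)
    cmb <- combn(idx, 2)
    cls <- apply(cmb, 2, function(pr) {
      ci <- dprime_ci(g$dosage[, pr[1]], g$dosage[, pr[2]])
      if (ci$ci_low > 0.7 && ci$ci_high >= 0.98) 1L
      else if (ci$ci_high < 0.9) -1L else 0L
    })
    strong <- sum(cls == 1); recomb <- sum(cls == -1)
    expect_gt(strong / (strong + recomb), 0.95)
  }
})
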