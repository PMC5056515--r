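test_that("config validation rejects impossible collections", {
  expect_error(sim_config(n_clusters = 30, n_genotypes = 24, n_founders = 40),
               "n_clusters")
  expect_error(sim_config(heritability = 1.5), "heritability")
  expect_error(sim_config(selfing_rate = -0.1), "probability")
  expect_error(sim_config(n_chromosomes = 0), "positive count")
})

test_that("simulation is deterministic given the seed", {
  a <- simulate_collection(small_config(seed = 11))
  b <- simulate_collection(small_config(seed = 11))
  expect_identical(a$truth$true_genotypes$dosage, b$truth$true_genotypes$dosage)
  expect_identical(a$depths, b$depths)
  expect_identical(a$expression, b$expression)
  expect_identical(a$phenotypes, b$phenotypes)
  c <- simulate_collection(small_config(seed = 12))
  expect_false(identical(a$depths, c$depths))
})

test_that("offspring dosages are Mendelian-consistent with stored parents", {
  sim <- simulate_collection(small_config(seed = 3), reads = FALSE)
  ped <- sim$truth$pedigree
  dose <- sim$truth$true_genotypes$dosage
  kids <- ped$child[!is.na(ped$mother)]
  for (kid in kids) {
    dm <- dose[ped$mother[match(kid, ped$child)], ]
    df <- dose[ped$father[match(kid, ped$child)], ]
    dk <- dose[kid, ]
    lo <- (dm == 2) + (df == 2)
    hi <- (dm > 0) + (df > 0)
    expect_true(all(dk >= lo & dk <= hi),
                info = paste("Mendelian violation for", kid))
  }
})

test_that("realized read depth tracks the configured mean", {
  sim <- simulate_collection(small_config(seed = 5, prob_polymorphic = 1))
  depth <- sim$depths$ref_count + sim$depths$var_count
  expect_gt(length(depth), 10000)
  expect_lt(abs(mean(depth) - 30) / 30, 0.05)
})

test_that("error-free saturating depth reproduces the true genotypes", {
  cfg <- small_config(seed = 9, seq_error_rate = 0, mean_depth = 200,
                      depth_dispersion = 0)
  sim <- simulate_collection(cfg)
  called <- call_genotypes(sim$depths, discover_variants(sim$depths))
  truth <- sim$truth$true_genotypes
  shared <- intersect(called$sites$site_id, truth$sites$site_id)
  expect_equal(called$dosage[, shared],
               truth$dosage[rownames(called$dosage), shared])
})

test_that("founder allele frequencies follow the configured Beta spectrum", {
  cfg <- sim_config(n_founders = 200, n_genotypes = 200, n_chromosomes = 2,
                    n_transcripts = 1700, prob_polymorphic = 1,
                    mean_snps_per_transcript = 6, founder_maf_beta = c(0.5, 0.5),
                    cluster_fst = 0, n_clusters = 2, generations = 1,
                    n_traits = 1, seed = 21)
  sim <- simulate_collection(cfg, reads = FALSE)
  p <- colMeans(sim$truth$true_genotypes$dosage) / 2
  folded <- pmin(p, 1 - p)
  # folded CDF of Beta(0.5, 0.5): F(x) + 1 - F(1-x) on [0, 0.5]
  grid <- seq(0.001, 0.5, by = 0.001)
  theor <- pbeta(grid, 0.5, 0.5) + 1 - pbeta(1 - grid, 0.5, 0.5)
  emp <- ecdf(folded)(grid)
  expect_gt(length(p), 9000)
  expect_lt(max(abs(emp - theor)), 0.05)
})

test_that("null traits are uncorrelated with genotype", {
  cfg <- small_config(seed = 13, heritability = 0, n_trait_snps = 0)
  sim <- simulate_collection(cfg, reads = FALSE)
  dose <- sim$truth$true_genotypes$dosage
  poly <- which(apply(dose, 2, sd) > 0)
  y <- sim$phenotypes[[1]]
  r <- vapply(poly, function(s) abs(cor(y, dose[, s])), numeric(1))
  # |r| bounded by ~3/sqrt(n) for the bulk of null sites
  expect_lt(median(r), 3 / sqrt(nrow(dose)))
  expect_lt(mean(r > 4 / sqrt(nrow(dose))), 0.1)
})

test_that("replicates reproduce calls at saturating depth and degrade at low depth", {
  cfg <- small_config(seed = 15, seq_error_rate = 0, mean_depth = 300,
                      depth_dispersion = 0)
  sim <- simulate_collection(cfg, reads = FALSE)
  reps <- make_replicates(sim$truth, c("G001", "G005"), cfg, n_reps = 3)
  expect_setequal(unique(reps$replicate_group), c("G001", "G005"))
  g <- call_genotypes(reps, discover_variants(reps))
  groups <- setNames(reps$replicate_group[match(rownames(g$dosage), reps$sample)],
                     rownames(g$dosage))
  rr <- replicate_reproducibility(g, groups)
  expect_equal(rr$overall, 100)

  # shallow noisy replicates: reproducibility below 100 but well above 50
  overall <- vapply(1:6, function(s) {
    cfg2 <- small_config(seed = 15, seq_error_rate = 0.01, mean_depth = 20)
    reps2 <- make_replicates(sim$truth, "G001", cfg2, n_reps = 4,
                             seed = 100 + s)
    g2 <- call_genotypes(reps2, discover_variants(reps2))
    grp <- setNames(rep("G001", nrow(g2$dosage)), rownames(g2$dosage))
    replicate_reproducibility(g2, grp)$overall
  }, numeric(1))
  expect_true(all(overall < 100))
  expect_true(all(overall > 50))
})

test_that("replicate edge cases: empty request and unknown ids", {
  sim <- simulate_collection(small_config(seed = 2), reads = FALSE)
  empty <- make_replicates(sim$truth, character(0), sim$truth$config)
  expect_equal(nrow(empty), 0)
  expect_error(make_replicates(sim$truth, "nope", sim$truth$config), "unknown")
})
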