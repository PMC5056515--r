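test_that("GRM has unit-scale diagonal and flags duplicates", {
  set.seed(51)
  S <- 2000; n <- 40
  p <- runif(S, 0.1, 0.9)
  dose <- t(replicate(n, rbinom(S, 2, p)))
  dose <- rbind(dose, dup = dose[1, ])
  rownames(dose) <- c(sprintf("g%02d", 1:n), "dup")
  K <- grm(toy_geno(dose))
  expect_lt(abs(mean(diag(K)[1:n]) - 1), 0.05)      # HWE diagonal ~ 1
  expect_lt(abs(K["g01", "dup"] - K["g01", "g01"]), 1e-9)
  expect_lt(max(abs(K[2:n, 2:n][upper.tri(K[2:n, 2:n])])), 6 / sqrt(S))
  expect_error(grm(toy_geno(matrix(0L, 4, 5))), "polymorphic")
})

test_that("REML with identity kinship matches ordinary least squares", {
  set.seed(52)
  n <- 60
  y <- rnorm(n, 5, 2)
  vc <- reml_fit(y, diag(n))
  # only the total variance is identified; it must equal the OLS residual MS
  expect_equal(vc$sigma_g2 + vc$sigma_e2, sum((y - mean(y))^2) / (n - 1),
               tolerance = 1e-6)
})

test_that("REML recovers simulated heritability and maximizes the likelihood", {
  hats <- vapply(1:3, function(s) {
    set.seed(200 + s)
    n <- 200; S <- 500
    blocks <- rep(1:5, each = n / 5)
    p0 <- runif(S, 0.2, 0.8)
    dose <- matrix(0L, n, S)
    for (b in 1:5) {
      pb <- pmin(pmax(p0 + rnorm(S, 0, 0.15), 0.02), 0.98)
      idx <- which(blocks == b)
      dose[idx, ] <- t(replicate(length(idx), rbinom(S, 2, pb)))
    }
    rownames(dose) <- sprintf("i%03d", 1:n)
    g <- toy_geno(dose)
    K <- grm(g)
    u <- rnorm(S)
    z <- scale(dose); z[is.na(z)] <- 0
    gval <- as.numeric(z %*% u); gval <- gval / sd(gval)
    y <- gval + rnorm(n)            # h2 = 0.5
    reml_fit(y, K)$h2
  }, numeric(1))
  expect_true(all(hats > 0.3 & hats < 0.7))

  # returned ratio is a local maximum of the profile REML likelihood
  set.seed(204)
  n <- 80
  K <- grm(toy_geno(matrix(as.integer(rbinom(n * 300, 2, 0.5)), n, 300)))
  K <- K + diag(1e-6, n)
  y <- rnorm(n) + as.numeric(chol(K + diag(0.01, n)) %*% rnorm(n)) * 0.5
  vc <- reml_fit(y, K)
  ll <- function(delta) {
    # evaluate the profile REML likelihood at a perturbed ratio
    X <- matrix(1, n, 1)
    S <- diag(n) - X %*% solve(crossprod(X), t(X))
    ev <- eigen(S %*% (K + diag(n)) %*% S, symmetric = TRUE)
    xi <- ev$values[seq_len(n - 1)] - 1
    eta <- crossprod(ev$vectors[, seq_len(n - 1)], y)[, 1]
    nq <- n - 1
    0.5 * (nq * (log(nq / (2 * pi)) - 1 - log(sum(eta^2 / (xi + delta)))) -
             sum(log(xi + delta)))
  }
  expect_gte(vc$reml_loglik + 1e-6, ll(vc$delta * 1.01))
  expect_gte(vc$reml_loglik + 1e-6, ll(vc$delta * 0.99))
  expect_error(reml_fit(rep(1, 10), diag(10)), "zero variance")
})

test_that("mixed-model scan reduces to simple regression when K = I", {
  set.seed(53)
  n <- 50; S <- 40
  dose <- matrix(as.integer(rbinom(n * S, 2, 0.4)), n, S,
                 dimnames = list(sprintf("i%02d", 1:n), NULL))
  g <- toy_geno(dose)
  y <- setNames(rnorm(n) + 0.8 * dose[, 1], rownames(dose))
  res <- snp_scan(g, y, K = diag(n))
  for (s in c(1, 5, 20)) {
    fit <- summary(lm(y ~ dose[, s]))$coefficients
    row <- res[res$site_id == g$sites$site_id[s], ]
    expect_equal(row$beta, fit[2, 1], tolerance = 1e-6)
    expect_equal(row$se, fit[2, 2], tolerance = 1e-6)
    expect_equal(row$p_value, fit[2, 4], tolerance = 1e-6)
  }
})

test_that("scan handles missing dosages by dropping samples per SNP", {
  set.seed(54)
  n <- 40
  dose <- matrix(as.integer(rbinom(n * 10, 2, 0.5)), n, 10,
                 dimnames = list(sprintf("i%02d", 1:n), NULL))
  dose[1:5, 3] <- NA
  g <- toy_geno(dose)
  y <- setNames(rnorm(n), rownames(dose))
  res <- snp_scan(g, y, K = diag(n))
  row <- res[res$site_id == g$sites$site_id[3], ]
  expect_equal(row$n, n - 5)
  keep <- !is.na(dose[, 3])
  fit <- summary(lm(y[keep] ~ dose[keep, 3]))$coefficients
  expect_equal(row$beta, fit[2, 1], tolerance = 1e-6)
  expect_equal(row$p_value, fit[2, 4], tolerance = 1e-6)
})

test_that("planted effects report beta near truth; effect is per variant copy", {
  set.seed(55)
  n <- 150; S <- 60
  dose <- matrix(as.integer(rbinom(n * S, 2, 0.5)), n, S,
                 dimnames = list(sprintf("i%03d", 1:n), NULL))
  g <- toy_geno(dose)
  beta_true <- 1.2
  y <- setNames(beta_true * dose[, 7] + rnorm(n), rownames(dose))
  res <- snp_scan(g, y, K = diag(n))
  row <- res[res$site_id == g$sites$site_id[7], ]
  expect_lt(abs(row$beta - beta_true), 2 * row$se)
  expect_true(row$significant)
  expect_equal(row$effective_allele, "G")
  expect_equal(row$effective_freq, mean(dose[, 7]) / 2)
})

test_that("null p-values are uniform under the identity model", {
  set.seed(56)
  n <- 80; S <- 400
  dose <- matrix(as.integer(rbinom(n * S, 2, 0.5)), n, S,
                 dimnames = list(sprintf("i%03d", 1:n), NULL))
  g <- toy_geno(dose)
  y <- setNames(rnorm(n), rownames(dose))
  res <- snp_scan(g, y, K = diag(n))
  ks <- suppressWarnings(ks.test(res$p_value, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("QQ diagnostics report calibrated and inflated lambda", {
  p <- seq(1e-6, 1, length.out = 10001)
  qq <- qq_diagnostics(p)
  expect_equal(qq$lambda, 1, tolerance = 0.01)
  qq2 <- qq_diagnostics(p / 2)
  expect_gt(qq2$lambda, 1)
  expect_error(qq_diagnostics(numeric(0)), "no p-values")
  expect_error(qq_diagnostics(c(0.5, 0)), "0, 1")
})

test_that("favorable alleles follow effect sign and improvement direction", {
  dose <- matrix(c(2L, 1L, 0L, 0L), 4, 1,
                 dimnames = list(c("hi1", "het1", "lo1", "lo2"), NULL))
  g <- toy_geno(dose)
  res <- data.frame(site_id = "s001", effective_allele = "G", other_allele = "A",
                    beta = 3, p_value = 1e-6, significant = TRUE,
                    stringsAsFactors = FALSE)
  fav <- favorable_alleles(res, g, directions = c(yield = "higher"),
                           trait = "yield")
  expect_equal(fav$beneficial_allele, "G")
  expect_equal(fav$homozygous_carriers, "hi1")
  expect_equal(fav$heterozygous_carriers, "het1")
  # negative effect on a higher-is-better trait favors the other allele
  res$beta <- -3
  fav2 <- favorable_alleles(res, g, directions = c(yield = "higher"),
                            trait = "yield")
  expect_equal(fav2$beneficial_allele, "A")
  expect_equal(fav2$homozygous_carriers, "lo1,lo2")
  expect_error(favorable_alleles(res, g, directions = c(other = 1),
                                 trait = "yield"), "direction")
})
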