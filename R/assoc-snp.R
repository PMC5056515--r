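#' Genomic relationship matrix
#'
#' GCTA-style GRM: with dosage `x_ij` at site `i` for sample `j` and
#' variant frequency `p_i`, `A_jk = (1/M) sum_i (x_ij - 2 p_i)(x_ik - 2
#' p_i) / (2 p_i (1 - p_i))` over the `M` polymorphic sites. Missing
#' dosages are imputed to `2 p_i`; monomorphic sites are excluded.
#'
#' @param g a [genotype_matrix()].
#' @return Symmetric samples x samples matrix of class `kinship_matrix`.
#' @export
grm <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  p <- site_variant_freq(g)
  keep <- !is.na(p) & p > 0 & p < 1
  if (!any(keep)) stop("no polymorphic sites: cannot build a GRM")
  x <- g$dosage[, keep, drop = FALSE]
  p <- p[keep]
  z <- sweep(x, 2, 2 * p)
  z[is.na(z)] <- 0
  z <- sweep(z, 2, sqrt(2 * p * (1 - p)), `/`)
  K <- tcrossprod(z) / ncol(z)
  class(K) <- c("kinship_matrix", class(K))
  K
}

#' Single-random-effect REML variance components (EMMA-style)
#'
#' Fits `y = X b + g + e` with `g ~ N(0, sigma_g^2 K)` and `e ~ N(0,
#' sigma_e^2 I)` by restricted maximum likelihood, using a one-time
#' eigendecomposition of the projected kinship and a 1-D optimization of
#' the variance ratio `delta = sigma_e^2 / sigma_g^2` on the exact profile
#' REML likelihood. Deterministic.
#'
#' @param y numeric trait vector (complete for included samples).
#' @param K kinship matrix (positive semidefinite up to a small jitter).
#' @param X optional covariate matrix (an intercept is always added).
#' @param jitter diagonal jitter tolerated to restore PSD-ness.
#' @return List of class `variance_components`: `sigma_g2`, `sigma_e2`,
#'   `h2`, `delta`, `reml_loglik`.
#' @export
reml_fit <- function(y, K, X = NULL, jitter = 1e-6) {
  n <- length(y)
  if (sd(y) == 0) stop("trait has zero variance")
  X <- cbind(`(Intercept)` = rep(1, n), X)
  q <- ncol(X)
  K <- as.matrix(K)
  stopifnot(nrow(K) == n)
  evK <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(evK) < -jitter * max(abs(evK)) - 1e-8)
    stop("kinship matrix is not positive semidefinite beyond jitter tolerance")
  # project out fixed effects, then eigendecompose S (K + I) S as in EMMA
  S <- diag(n) - X %*% solve(crossprod(X), t(X))
  ev <- eigen(S %*% (K + diag(n)) %*% S, symmetric = TRUE)
  xi <- ev$values[seq_len(n - q)] - 1
  xi <- pmax(xi, -1 + 1e-9)
  eta <- crossprod(ev$vectors[, seq_len(n - q), drop = FALSE], y)[, 1]
  nq <- n - q
  ll <- function(log_delta) {
    delta <- exp(log_delta)
    0.5 * (nq * (log(nq / (2 * pi)) - 1 - log(sum(eta^2 / (xi + delta)))) -
             sum(log(xi + delta)))
  }
  grid <- seq(-10, 10, length.out = 81)
  vals <- vapply(grid, ll, numeric(1))
  best <- which.max(vals)
  lo <- grid[max(1, best - 1)]; hi <- grid[min(length(grid), best + 1)]
  opt <- stats::optimize(ll, c(lo, hi), maximum = TRUE, tol = 1e-8)
  delta <- exp(opt$maximum)
  sigma_g2 <- sum(eta^2 / (xi + delta)) / nq
  sigma_e2 <- delta * sigma_g2
  structure(list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
                 h2 = sigma_g2 / (sigma_g2 + sigma_e2), delta = delta,
                 reml_loglik = opt$objective),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("sigma_g2 = %.4g  sigma_e2 = %.4g  h2 = %.3f  (REML logLik %.3f)\n",
              x$sigma_g2, x$sigma_e2, x$h2, x$reml_loglik))
  invisible(x)
}

#' Kinship-corrected mixed-model SNP association scan
#'
#' Variance components are estimated once per trait under the null model
#' and held fixed across SNPs (the EMMA-X / GCTA-MLMA approximation); each
#' SNP is then tested by generalized least squares with covariance
#' `sigma_g^2 K + sigma_e^2 I` and a Wald t-test on its dosage
#' coefficient. Effects are reported per copy of the counted (effective =
#' variant) allele. Samples missing the tested SNP are dropped for that
#' SNP; samples missing the trait are dropped throughout.
#'
#' @param g a [genotype_matrix()].
#' @param y named trait vector (names = sample ids) or unnamed vector
#'   aligned with `g`.
#' @param K kinship matrix from [grm()]; defaults to computing it from `g`.
#' @param n_pcs number of principal-component covariates (0, 6 or 10 are
#'   the conventional choices; any nonnegative count is accepted).
#' @param alpha significance rule on the raw p-value (default 1e-4,
#'   unadjusted); the returned table flags `significant = p < alpha` and
#'   also carries a Benjamini-Hochberg FDR column for transparency.
#' @return data.frame of class `assoc_result` with one row per testable
#'   SNP: ids, alleles, effective-allele frequency, `beta`, `se`,
#'   `t_value`, `p_value`, `fdr`, `significant`, `n`.
#' @export
snp_scan <- function(g, y, K = grm(g), n_pcs = 0, alpha = 1e-4) {
  stopifnot(inherits(g, "geno_matrix"))
  if (!is.null(names(y))) y <- y[sample_ids(g)]
  ok <- !is.na(y)
  if (sum(ok) < 5) stop("too few samples with trait values")
  g2 <- g[which(ok), ]
  y <- as.numeric(y[ok])
  K <- as.matrix(K)[ok, ok]
  X0 <- matrix(1, length(y), 1)
  if (n_pcs > 0) {
    pcs <- snp_pca(g2, n_components = n_pcs)$scores
    X0 <- cbind(X0, pcs)
  }
  vc <- reml_fit(y, K, X = if (ncol(X0) > 1) X0[, -1, drop = FALSE] else NULL)
  evV <- eigen(vc$sigma_g2 * K + vc$sigma_e2 * diag(length(y)), symmetric = TRUE)
  W <- sweep(t(evV$vectors), 1, sqrt(pmax(evV$values, 1e-12)), `/`)
  yt <- as.numeric(W %*% y)
  Xt <- W %*% X0
  qrX <- qr(Xt)
  ry <- qr.resid(qrX, yt)
  n <- length(y); q <- ncol(X0)

  dose <- g2$dosage
  p <- site_variant_freq(g2)
  complete <- colSums(is.na(dose)) == 0
  testable <- !is.na(p) & p > 0 & p < 1
  beta <- se <- tval <- pval <- rep(NA_real_, ncol(dose))
  nn <- colSums(!is.na(dose))

  # fast path: SNPs without missing calls share the transformation
  fast <- which(complete & testable)
  if (length(fast) > 0) {
    Xs <- W %*% dose[, fast, drop = FALSE]
    rx <- qr.resid(qrX, Xs)
    sxx <- colSums(rx^2)
    b <- colSums(rx * ry) / sxx
    rss <- sum(ry^2) - b^2 * sxx
    df <- n - q - 1
    s2 <- rss / df
    se_f <- sqrt(s2 / sxx)
    beta[fast] <- b; se[fast] <- se_f
    tval[fast] <- b / se_f
    pval[fast] <- 2 * stats::pt(-abs(tval[fast]), df)
  }
  # slow path: refit with the sample subset per SNP
  slow <- which(!complete & testable)
  for (s in slow) {
    use <- !is.na(dose[, s])
    if (sum(use) < q + 3) next
    x <- dose[use, s]
    if (sd(x) == 0) next
    Vi <- vc$sigma_g2 * K[use, use] + vc$sigma_e2 * diag(sum(use))
    Wl <- solve(chol(Vi))
    yl <- crossprod(Wl, y[use])
    Xl <- crossprod(Wl, cbind(X0[use, , drop = FALSE], x))
    fit <- stats::lm.fit(Xl, yl)
    cf <- fit$coefficients[q + 1]
    df <- sum(use) - q - 1
    s2 <- sum(fit$residuals^2) / df
    XtX_inv <- chol2inv(fit$qr$qr[seq_len(q + 1), seq_len(q + 1), drop = FALSE])
    se_s <- sqrt(s2 * XtX_inv[q + 1, q + 1])
    beta[s] <- cf; se[s] <- se_s
    tval[s] <- cf / se_s
    pval[s] <- 2 * stats::pt(-abs(tval[s]), df)
  }

  res <- data.frame(
    site_id = g2$sites$site_id,
    transcript_id = g2$sites$transcript_id,
    offset = g2$sites$offset,
    chrom = g2$sites$chrom, pos = g2$sites$pos,
    effective_allele = g2$sites$var, other_allele = g2$sites$ref,
    effective_freq = p,
    beta = beta, se = se, t_value = tval, p_value = pval,
    n = nn, stringsAsFactors = FALSE
  )
  res <- res[!is.na(res$p_value), , drop = FALSE]
  res$fdr <- stats::p.adjust(res$p_value, "BH")
  res$significant <- res$p_value < alpha
  attr(res, "variance_components") <- vc
  class(res) <- c("assoc_result", class(res))
  res
}

#' QQ diagnostics and genomic inflation
#'
#' @param p_values vector of p-values in (0, 1].
#' @return List with `qq` (data.frame of expected and observed -log10
#'   quantiles) and `lambda`, the genomic inflation factor
#'   `median(qchisq(1 - p, 1)) / 0.4549`.
#' @export
qq_diagnostics <- function(p_values) {
  p <- p_values[!is.na(p_values)]
  if (length(p) == 0) stop("no p-values supplied")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  m <- length(p)
  obs <- sort(p)
  expd <- (seq_len(m) - 0.5) / m
  lambda <- stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1, lower.tail = FALSE)
  list(qq = data.frame(expected = -log10(expd), observed = -log10(obs)),
       lambda = lambda)
}

#' Report carriers of favorable alleles
#'
#' For each significant association, the beneficial allele is the effective
#' allele when the effect sign matches the declared improvement direction
#' of the trait, and the other allele otherwise. Genotypes homozygous or
#' heterozygous for the beneficial allele are listed as candidate parents.
#'
#' @param results an `assoc_result` table with a `trait` column (or a
#'   single-trait table plus `trait` argument).
#' @param g the [genotype_matrix()] the scan ran on.
#' @param directions named vector per trait: `"higher"`/`1` when larger
#'   trait values are better, `"lower"`/`-1` otherwise.
#' @param trait trait id used when `results` lacks a `trait` column.
#' @return data.frame with one row per significant SNP: trait, site,
#'   beneficial allele and comma-separated homozygous / heterozygous
#'   carriers.
#' @export
favorable_alleles <- function(results, g, directions, trait = NULL) {
  if (is.null(results$trait)) {
    if (is.null(trait)) stop("results lack a trait column; supply `trait`")
    results$trait <- trait
  }
  sig <- results[results$significant, , drop = FALSE]
  dirn <- function(x) {
    if (is.character(x)) c(higher = 1, lower = -1)[[x]] else sign(x)
  }
  out <- lapply(seq_len(nrow(sig)), function(r) {
    row <- sig[r, ]
    if (!row$trait %in% names(directions))
      stop("no improvement direction declared for trait '", row$trait, "'")
    want <- dirn(directions[[row$trait]])
    beneficial_is_effective <- sign(row$beta) == want
    ben <- if (beneficial_is_effective) row$effective_allele else row$other_allele
    d <- g$dosage[, row$site_id]
    hom_code <- if (beneficial_is_effective) 2L else 0L
    hom <- names(d)[!is.na(d) & d == hom_code]
    het <- names(d)[!is.na(d) & d == 1L]
    data.frame(trait = row$trait, site_id = row$site_id,
               beneficial_allele = ben, beta = row$beta, p_value = row$p_value,
               homozygous_carriers = paste(hom, collapse = ","),
               heterozygous_carriers = paste(het, collapse = ","),
               stringsAsFactors = FALSE)
  })
  if (length(out) == 0) {
    return(data.frame(trait = character(), site_id = character(),
                      beneficial_allele = character(), beta = numeric(),
                      p_value = numeric(), homozygous_carriers = character(),
                      heterozygous_carriers = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
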