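#' Nucleotide diversity, Watterson's theta and Tajima's D
#'
#' Per segregating site with `n` non-missing allele copies and variant
#' frequency `p`, the unbiased per-site diversity is
#' `pi_site = n/(n-1) * 2p(1-p)`. `pi` is the mean of `pi_site` over all
#' assayed sites, `theta = S / (a1 * L)` with `S` the segregating-site
#' count, `L` the assayed-site count and `a1 = sum(1/i, i = 1..n-1)`, and
#' Tajima's D uses the standard constants (Tajima 1989) with `n` taken as
#' the total allele-copy count of the matrix. The denominator is the
#' assayed SNP-site count, not a transcriptome length, so values are on the
#' per-variant-site scale.
#'
#' @param g a [genotype_matrix()].
#' @return An object of class `diversity_stats`: list with `pi`, `theta`,
#'   `S`, `tajimas_d` (`NA` when `S` = 0), `n_samples`, `L` and the total
#'   pairwise-difference sum `pi_total` (= pi * L).
#' @export
diversity <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  if (n_samples(g) < 2) stop("diversity needs at least 2 samples")
  L <- n_sites(g)
  nn <- 2 * colSums(!is.na(g$dosage))
  p <- site_variant_freq(g)
  seg <- !is.na(p) & p > 0 & p < 1 & nn >= 2
  pi_site <- ifelse(seg, nn / (nn - 1) * 2 * p * (1 - p), 0)
  pi_total <- sum(pi_site)
  S <- sum(seg)
  n <- 2 * n_samples(g)
  a1 <- sum(1 / seq_len(n - 1))
  theta <- S / (a1 * L)
  D <- NA_real_
  if (S > 0) {
    a2 <- sum(1 / seq_len(n - 1)^2)
    b1 <- (n + 1) / (3 * (n - 1))
    b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1
    c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    e1 <- c1 / a1
    e2 <- c2 / (a1^2 + a2)
    D <- (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  }
  structure(list(pi = pi_total / L, theta = theta, S = S, tajimas_d = D,
                 n_samples = n_samples(g), L = L, pi_total = pi_total),
            class = "diversity_stats")
}

#' @export
print.diversity_stats <- function(x, ...) {
  cat(sprintf("pi = %.4f  theta = %.4f  S = %d  Tajima's D = %s  (n = %d, L = %d)\n",
              x$pi, x$theta, x$S,
              ifelse(is.na(x$tajimas_d), "NA", sprintf("%.3f", x$tajimas_d)),
              x$n_samples, x$L))
  invisible(x)
}

#' Method-of-moments inbreeding coefficients
#'
#' PLINK `--het` style estimator: for each sample, over its non-missing
#' sites, `F = (observed_hom - expected_hom) / (n_nonmissing -
#' expected_hom)` where the expected homozygous-site count under
#' Hardy-Weinberg is `sum over sites of 1 - 2p(1-p) * n/(n-1)`, with `p`
#' the sample-wide variant frequency at the site and `n` its non-missing
#' allele-copy count. Sites with fewer than 2 allele copies are skipped.
#'
#' On a complete-data matrix this F is an affine function of the sample's
#' heterozygous-site count, so its correlation with heterozygosity is
#' exactly -1.
#'
#' @param g a [genotype_matrix()].
#' @return data.frame with columns `sample`, `observed_hom`,
#'   `expected_hom`, `n_nonmissing`, `F`.
#' @export
inbreeding_f <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  p <- site_variant_freq(g)
  nn <- 2 * colSums(!is.na(g$dosage))
  usable <- !is.na(p) & nn >= 2
  e_hom_site <- ifelse(usable, 1 - 2 * p * (1 - p) * nn / (nn - 1), NA_real_)
  obs <- exp_h <- nonmiss <- numeric(n_samples(g))
  for (i in seq_len(n_samples(g))) {
    d <- g$dosage[i, ]
    sel <- !is.na(d) & usable
    obs[i] <- sum(d[sel] != 1L)
    exp_h[i] <- sum(e_hom_site[sel])
    nonmiss[i] <- sum(sel)
  }
  data.frame(sample = sample_ids(g), observed_hom = obs,
             expected_hom = exp_h, n_nonmissing = nonmiss,
             F = (obs - exp_h) / (nonmiss - exp_h),
             stringsAsFactors = FALSE)
}

#' Identity-by-state distance matrix
#'
#' For each pair over mutually non-missing sites, IBS is the fraction of
#' shared allele copies, `(2 * IBS2 + IBS1) / (2 * sites)` where IBS2 sites
#' have identical dosage and IBS1 sites differ by one. The distance is
#' `1 - IBS`; the diagonal is 0. Pairs with no overlapping sites get `NA`
#' with a warning.
#'
#' @param g a [genotype_matrix()].
#' @return Symmetric numeric matrix of 1-IBS distances.
#' @export
ibs_distance <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  N <- n_samples(g)
  if (N < 2) stop("need at least 2 samples")
  D <- matrix(0, N, N, dimnames = list(sample_ids(g), sample_ids(g)))
  any_na <- FALSE
  for (i in seq_len(N - 1)) {
    di <- g$dosage[i, ]
    for (j in (i + 1):N) {
      dj <- g$dosage[j, ]
      ok <- !is.na(di) & !is.na(dj)
      if (!any(ok)) {
        D[i, j] <- D[j, i] <- NA_real_
        any_na <- TRUE
      } else {
        D[i, j] <- D[j, i] <- mean(abs(di[ok] - dj[ok])) / 2
      }
    }
  }
  if (any_na) warning("some sample pairs share no genotyped sites")
  D
}

#' Method-of-moments IBD estimates for all sample pairs
#'
#' PLINK `--genome` style estimator assuming a homogeneous population: the
#' observed proportions of IBS states 0/1/2 across sites are equated with
#' their expectations under IBD states 0/1/2 given the sample allele
#' frequencies, and solved sequentially for Z0, Z1, Z2. Negative estimates
#' are clipped to zero and the triple renormalized; `PI_HAT = Z2 + Z1/2`.
#'
#' @param g a [genotype_matrix()].
#' @param min_maf sites below this minor allele frequency are ignored
#'   (uninformative for IBD); default 0.01.
#' @return data.frame with columns `id1`, `id2`, `Z0`, `Z1`, `Z2`,
#'   `PI_HAT`, `n_sites`.
#' @export
ibd_estimates <- function(g, min_maf = 0.01) {
  stopifnot(inherits(g, "geno_matrix"))
  p <- site_variant_freq(g)
  keep <- !is.na(p) & pmin(p, 1 - p) > min_maf
  if (!any(keep)) stop("no polymorphic sites: IBD estimation impossible")
  d <- g$dosage[, keep, drop = FALSE]
  p <- p[keep]
  q <- 1 - p
  # per-site IBS-state probabilities conditional on IBD state
  e0_ibd0 <- 2 * p^2 * q^2
  e1_ibd0 <- 4 * p^3 * q + 4 * p * q^3
  e1_ibd1 <- 2 * p^2 * q + 2 * p * q^2
  N <- nrow(d)
  out <- vector("list", N * (N - 1) / 2)
  k <- 0
  for (i in seq_len(N - 1)) {
    di <- d[i, ]
    for (j in (i + 1):N) {
      dj <- d[j, ]
      ok <- !is.na(di) & !is.na(dj)
      diff <- abs(di[ok] - dj[ok])
      m <- sum(ok)
      o0 <- mean(diff == 2)
      o1 <- mean(diff == 1)
      E00 <- mean(e0_ibd0[ok]); E10 <- mean(e1_ibd0[ok]); E11 <- mean(e1_ibd1[ok])
      z0 <- o0 / E00
      z1 <- (o1 - z0 * E10) / E11
      z2 <- 1 - z0 - z1
      z <- pmax(c(z0, z1, z2), 0)
      z <- pmin(z, 1)
      z <- z / sum(z)
      k <- k + 1
      out[[k]] <- data.frame(id1 = rownames(d)[i], id2 = rownames(d)[j],
                             Z0 = z[1], Z1 = z[2], Z2 = z[3],
                             PI_HAT = z[3] + z[2] / 2, n_sites = m,
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Classify pairwise relationships from IBD Z-probabilities
#'
#' Default boxes: parent-child when `Z1 >= 0.7` and `Z0 <= 0.2`; half-sib
#' when both `Z0` and `Z1` fall in [0.35, 0.65]; otherwise
#' unrelated/other.
#'
#' @param est output of [ibd_estimates()].
#' @param thresholds list overriding any of `pc_z1`, `pc_z0`, `hs_lo`,
#'   `hs_hi`.
#' @return `est` with an added `relationship` column.
#' @export
classify_relationships <- function(est, thresholds = list()) {
  th <- utils::modifyList(list(pc_z1 = 0.7, pc_z0 = 0.2,
                               hs_lo = 0.35, hs_hi = 0.65), thresholds)
  lab <- rep("unrelated/other", nrow(est))
  hs <- est$Z1 >= th$hs_lo & est$Z1 <= th$hs_hi &
    est$Z0 >= th$hs_lo & est$Z0 <= th$hs_hi
  pc <- est$Z1 >= th$pc_z1 & est$Z0 <= th$pc_z0
  lab[hs] <- "half-sib"
  lab[pc] <- "parent-child"
  est$relationship <- lab
  est
}

#' Correlations between inbreeding coefficients and traits
#'
#' Pearson correlation and two-sided t-test p-value of each trait against
#' per-sample F, over genotypes with both values.
#'
#' @param f output of [inbreeding_f()].
#' @param traits data.frame of per-genotype trait values (row names or a
#'   `genotype` column identify the genotypes).
#' @return data.frame with `trait`, `r`, `p_value`, `n`; zero-variance or
#'   undersized traits give `NA` with a warning.
#' @export
f_trait_correlations <- function(f, traits) {
  if (!is.null(traits$genotype)) {
    rownames(traits) <- traits$genotype
    traits$genotype <- NULL
  }
  shared <- intersect(f$sample, rownames(traits))
  if (length(shared) < 3) stop("need at least 3 genotypes shared with the trait table")
  fv <- f$F[match(shared, f$sample)]
  out <- lapply(names(traits), function(tr) {
    y <- traits[shared, tr]
    ok <- !is.na(y) & !is.na(fv)
    if (sum(ok) < 3 || sd(y[ok]) == 0 || sd(fv[ok]) == 0) {
      warning("trait '", tr, "' has too few values or zero variance")
      return(data.frame(trait = tr, r = NA_real_, p_value = NA_real_,
                        n = sum(ok), stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(fv[ok], y[ok])
    data.frame(trait = tr, r = unname(ct$estimate), p_value = ct$p.value,
               n = sum(ok), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
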