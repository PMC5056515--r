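#' Define gene expression markers (GEMs)
#'
#' A transcript qualifies as a GEM when its normalized expression value is
#' at least `min_value` in at least one genotype (the threshold is
#' inclusive).
#'
#' @param e transcripts x genotypes nonnegative expression matrix.
#' @param min_value expression floor (default 2, FPKM-like units).
#' @return Character vector of qualifying transcript ids.
#' @export
filter_expressed <- function(e, min_value = 2) {
  e <- as.matrix(e)
  if (nrow(e) == 0) stop("expression matrix is empty")
  rownames(e)[apply(e, 1, max, na.rm = TRUE) >= min_value]
}

#' Per-GEM simple linear regression on a trait
#'
#' For each transcript, fits `expression = a + b * trait` over the
#' genotypes with both values and reports the slope, its standard error,
#' `t = b / se`, the two-sided p-value on `n - 2` degrees of freedom and
#' the adjusted r-squared. Expression is deliberately the dependent
#' variable, matching how expression-marker tables are conventionally
#' reported.
#'
#' @param e expression matrix restricted to the GEMs of interest.
#' @param trait named numeric vector of per-genotype trait values.
#' @return data.frame with one row per transcript: `transcript_id`,
#'   `estimate`, `se`, `t_value`, `p_value`, `adj_r2`, `n`. Transcripts
#'   with zero expression variance get `NA` statistics and are flagged in
#'   `degenerate`.
#' @export
gem_regression <- function(e, trait) {
  e <- as.matrix(e)
  if (!is.null(names(trait))) {
    shared <- intersect(colnames(e), names(trait))
    e <- e[, shared, drop = FALSE]
    trait <- trait[shared]
  }
  ok <- !is.na(trait)
  e <- e[, ok, drop = FALSE]
  x <- as.numeric(trait[ok])
  n <- length(x)
  if (n < 3) stop("need at least 3 genotypes with both expression and trait values")
  if (sd(x) == 0) stop("trait has zero variance")
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  ec <- e - rowMeans(e)
  b <- as.numeric(ec %*% xc) / sxx
  syy <- rowSums(ec^2)
  rss <- pmax(syy - b^2 * sxx, 0)
  df <- n - 2
  s2 <- rss / df
  se <- sqrt(s2 / sxx)
  tval <- b / se
  pval <- 2 * stats::pt(-abs(tval), df)
  adj_r2 <- 1 - s2 / (syy / (n - 1))
  degenerate <- syy == 0
  out <- data.frame(transcript_id = rownames(e), estimate = b, se = se,
                    t_value = tval, p_value = pval, adj_r2 = adj_r2,
                    n = n, degenerate = degenerate, stringsAsFactors = FALSE)
  out[degenerate, c("se", "t_value", "p_value", "adj_r2")] <- NA_real_
  rownames(out) <- NULL
  out
}

#' Bonferroni-corrected per-test threshold
#'
#' @param n_tests number of tests in the family (>= 1).
#' @param alpha family-wise error rate (default 0.05).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (length(n_tests) != 1 || is.na(n_tests) || n_tests < 1)
    stop("n_tests must be a positive count")
  alpha / n_tests
}

#' Linearity screen for a Bonferroni-passing GEM-trait association
#'
#' Automated stand-in for the visual inspection of regression assumptions:
#' the association fails when either (a) removing the single
#' highest-leverage genotype raises the p-value above the Bonferroni
#' threshold, or (b) a quadratic term added to the model is significant at
#' `quad_alpha`. Residual-vs-fitted and scatter coordinates are returned
#' for plotting.
#'
#' @param expr expression values of the transcript (named by genotype).
#' @param trait trait values (named by genotype).
#' @param bonferroni_p the per-test threshold the association must survive.
#' @param quad_alpha significance level of the quadratic-term check.
#' @return List with `pass` (`TRUE`/`FALSE`, or `NA` when fewer than 5
#'   genotypes remain after leverage removal), `fail_leverage`,
#'   `fail_quadratic`, `p_without_top_leverage`, `p_quadratic` and
#'   `diagnostics` (data.frame of trait, expression, fitted, residual,
#'   leverage).
#' @export
linearity_screen <- function(expr, trait, bonferroni_p, quad_alpha = 0.01) {
  if (!is.null(names(trait)) && !is.null(names(expr))) {
    shared <- intersect(names(expr), names(trait))
    expr <- expr[shared]; trait <- trait[shared]
  }
  ok <- !is.na(expr) & !is.na(trait)
  expr <- as.numeric(expr[ok]); trait <- as.numeric(trait[ok])
  fit <- stats::lm(expr ~ trait)
  lev <- stats::hatvalues(fit)
  diagnostics <- data.frame(trait = trait, expression = expr,
                            fitted = stats::fitted(fit),
                            residual = stats::residuals(fit), leverage = lev)
  if (length(expr) - 1 < 5) {
    return(list(pass = NA, fail_leverage = NA, fail_quadratic = NA,
                p_without_top_leverage = NA_real_, p_quadratic = NA_real_,
                diagnostics = diagnostics))
  }
  drop <- which.max(lev)
  fit_drop <- stats::lm(expr[-drop] ~ trait[-drop])
  p_drop <- stats::coef(summary(fit_drop))[2, 4]
  fail_a <- p_drop > bonferroni_p
  p_quad <- NA_real_
  fail_b <- FALSE
  if (length(unique(trait)) > 2) {
    fit_q <- stats::lm(expr ~ trait + I(trait^2))
    cf <- stats::coef(summary(fit_q))
    if (nrow(cf) == 3) {
      p_quad <- cf[3, 4]
      fail_b <- p_quad < quad_alpha
    }
  }
  list(pass = !fail_a && !fail_b, fail_leverage = fail_a,
       fail_quadratic = fail_b, p_without_top_leverage = p_drop,
       p_quadratic = p_quad, diagnostics = diagnostics)
}

#' GEM-trait association scan
#'
#' Runs [gem_regression()] for every GEM x trait combination, applies the
#' Bonferroni threshold per trait family (the family size is the number of
#' GEMs), then subjects Bonferroni-passing associations to the
#' [linearity_screen()].
#'
#' @param e full expression matrix (transcripts x genotypes).
#' @param traits data.frame of per-genotype trait values (rows named by
#'   genotype, one column per trait).
#' @param alpha family-wise error rate (default 0.05).
#' @param min_value GEM expression floor passed to [filter_expressed()].
#' @param quad_alpha quadratic-term level of the linearity screen.
#' @return List with `results` (all regressions, all traits, with
#'   `passed_bonferroni` and `passed_linearity` flags), `passing` (the
#'   final table), `threshold` (per-test Bonferroni threshold) and
#'   `n_gems`.
#' @export
gem_scan <- function(e, traits, alpha = 0.05, min_value = 2, quad_alpha = 0.01) {
  e <- as.matrix(e)
  gems <- filter_expressed(e, min_value)
  if (length(gems) == 0) stop("no transcript passes the expression filter")
  eg <- e[gems, , drop = FALSE]
  thr <- bonferroni_threshold(length(gems), alpha)
  out <- list()
  for (tr in colnames(traits)) {
    y <- stats::setNames(traits[[tr]], rownames(traits))
    if (all(is.na(y))) {
      warning("trait '", tr, "' has no values; skipped")
      next
    }
    res <- gem_regression(eg, y)
    res$trait <- tr
    res$passed_bonferroni <- !is.na(res$p_value) & res$p_value < thr
    res$passed_linearity <- NA
    for (i in which(res$passed_bonferroni)) {
      scr <- linearity_screen(eg[res$transcript_id[i], ], y, thr, quad_alpha)
      res$passed_linearity[i] <- scr$pass
    }
    out[[tr]] <- res
  }
  if (length(out) == 0) stop("no usable trait columns")
  results <- do.call(rbind, out)
  rownames(results) <- NULL
  passing <- results[results$passed_bonferroni &
                       !is.na(results$passed_linearity) & results$passed_linearity, ,
                     drop = FALSE]
  list(results = results, passing = passing, threshold = thr,
       n_gems = length(gems))
}
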