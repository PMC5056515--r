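#' Discover variant sites from allele read depths
#'
#' A site is retained when at least one sample provides all three pieces of
#' base evidence: at least `min_var_reads` reads calling the variant allele,
#' a variant read fraction of at least `min_vaf` in that sample, and a mean
#' variant base quality of at least `min_qual`.
#'
#' @param depths allele depth table: data.frame with columns `sample`,
#'   `site_id`, `ref_allele`, `var_allele`, `ref_count`, `var_count`,
#'   `mean_var_quality` (extra columns are carried along and ignored).
#' @param min_var_reads,min_vaf,min_qual the three base criteria.
#' @return Character vector of retained site ids (in first-appearance order).
#' @export
discover_variants <- function(depths, min_var_reads = 2, min_vaf = 0.20,
                              min_qual = 10) {
  check_depth_table(depths)
  if (nrow(depths) == 0) stop("allele depth table is empty")
  total <- depths$ref_count + depths$var_count
  vaf <- ifelse(total > 0, depths$var_count / total, 0)
  pass <- depths$var_count >= min_var_reads & vaf >= min_vaf &
    depths$mean_var_quality >= min_qual
  unique(depths$site_id[pass])
}

check_depth_table <- function(depths) {
  req <- c("sample", "site_id", "ref_allele", "var_allele",
           "ref_count", "var_count", "mean_var_quality")
  miss <- setdiff(req, names(depths))
  if (length(miss) > 0) {
    stop("allele depth table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (any(depths$ref_count < 0 | depths$var_count < 0, na.rm = TRUE)) {
    stop("read counts must be nonnegative")
  }
  invisible(TRUE)
}

#' Call per-sample genotypes at discovered sites
#'
#' Dosage is called from the variant read fraction f = var/(ref+var):
#' total depth below `min_depth` gives a missing call; otherwise f <
#' `min_vaf` is homozygous reference (0), `min_vaf` <= f <= `het_max` is
#' heterozygous (1) and f > `het_max` is homozygous variant (2). A sample
#' that meets the depth rule with f >= `min_vaf` but a mean variant base
#' quality below `min_qual` is set to missing rather than trusted.
#'
#' @inheritParams discover_variants
#' @param sites site ids to call, normally the output of
#'   [discover_variants()].
#' @param min_depth minimum total read depth for a call.
#' @param het_max upper variant-fraction bound of the heterozygous band;
#'   above it the call is homozygous variant.
#' @return A [genotype_matrix()] (samples x sites). Site metadata
#'   (transcript id, offset, alleles) is taken from the depth table when the
#'   optional `transcript_id`/`offset` columns are present.
#' @export
call_genotypes <- function(depths, sites = discover_variants(depths),
                           min_depth = 5, min_vaf = 0.20, het_max = 0.80,
                           min_qual = 10) {
  check_depth_table(depths)
  keep <- depths$site_id %in% sites
  d <- depths[keep, , drop = FALSE]
  samples <- unique(depths$sample)
  site_ids <- unique(d$site_id)
  si <- match(d$sample, samples)
  ti <- match(d$site_id, site_ids)

  dp <- matrix(NA_real_, length(samples), length(site_ids))
  vc <- qv <- dp
  idx <- cbind(si, ti)
  dp[idx] <- d$ref_count + d$var_count
  vc[idx] <- d$var_count
  qv[idx] <- d$mean_var_quality

  f <- vc / dp
  dose <- matrix(NA_integer_, length(samples), length(site_ids))
  called <- !is.na(dp) & dp >= min_depth
  dose[called & f < min_vaf] <- 0L
  dose[called & f >= min_vaf & f <= het_max] <- 1L
  dose[called & f > het_max] <- 2L
  low_q <- called & f >= min_vaf & qv < min_qual
  dose[low_q] <- NA_integer_

  first <- d[!duplicated(d$site_id), , drop = FALSE]
  first <- first[match(site_ids, first$site_id), , drop = FALSE]
  meta <- data.frame(
    site_id = site_ids,
    transcript_id = if (!is.null(first$transcript_id)) first$transcript_id else NA_character_,
    offset = if (!is.null(first$offset)) first$offset else NA_integer_,
    ref = first$ref_allele, var = first$var_allele,
    stringsAsFactors = FALSE
  )
  genotype_matrix(dose, meta, samples = samples)
}

#' Filter sites on minor allele frequency and missingness
#'
#' Retains sites whose minor allele frequency (over non-missing allele
#' copies) exceeds `min_maf` and whose missing fraction is below
#' `max_missing`. Site order is preserved.
#'
#' @param g a [genotype_matrix()].
#' @param min_maf exclusive MAF floor (default 0.001, i.e. 0.1 percent).
#' @param max_missing exclusive missing-fraction ceiling (default 0.10).
#' @return The filtered `geno_matrix`; empty (with a warning) if no site
#'   survives.
#' @export
filter_sites <- function(g, min_maf = 0.001, max_missing = 0.10) {
  stopifnot(inherits(g, "geno_matrix"))
  if (n_sites(g) == 0) stop("genotype matrix has no sites")
  maf <- site_maf(g)
  miss <- site_missing_fraction(g)
  keep <- !is.na(maf) & maf > min_maf & miss < max_missing
  if (!any(keep)) warning("all sites removed by MAF/missingness filter")
  g[, which(keep)]
}

#' Per-site and per-sample genotype summaries
#'
#' @param g a [genotype_matrix()].
#' @return A list with `sites` (site id, major/minor allele frequency,
#'   missing fraction, heterozygous-sample fraction) and `samples` (sample
#'   id, number of called SNPs, missing fraction, heterozygous-site
#'   fraction; the latter is `NA` for an all-missing sample).
#' @export
site_and_sample_summaries <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  if (n_sites(g) == 0) stop("genotype matrix has no sites")
  p <- site_variant_freq(g)
  sites <- data.frame(
    site_id = g$sites$site_id,
    major_freq = pmax(p, 1 - p),
    minor_freq = pmin(p, 1 - p),
    missing_fraction = site_missing_fraction(g),
    het_fraction = site_het_fraction(g),
    stringsAsFactors = FALSE
  )
  called <- rowSums(!is.na(g$dosage))
  hets <- rowSums(g$dosage == 1L, na.rm = TRUE)
  samples <- data.frame(
    sample = sample_ids(g),
    n_called = called,
    missing_fraction = 1 - called / n_sites(g),
    het_fraction = ifelse(called > 0, hets / called, NA_real_),
    stringsAsFactors = FALSE
  )
  list(sites = sites, samples = samples)
}

#' Replicate reproducibility of genotype calls
#'
#' For every within-group sample pair and site at which both calls are
#' non-missing, a pair scores 1 when the dosage codes are identical and 0
#' otherwise. Per-site reproducibility is the unweighted mean over pairs;
#' the overall figure is the mean over sites with at least one scored pair.
#' Also reports the sites that are perfectly reproducible in every group
#' (the basis of a "reproducible in all controls" marker subset).
#'
#' @param g a [genotype_matrix()] containing the replicate samples.
#' @param groups named character/factor vector mapping sample id to
#'   replicate group (e.g. the genotype the replicates derive from).
#' @return List with `per_site` (data.frame: site_id, reproducibility,
#'   n_pairs), `overall` (percent), and `sites_reproducible_all_groups`
#'   (character vector of site ids).
#' @export
replicate_reproducibility <- function(g, groups) {
  stopifnot(inherits(g, "geno_matrix"))
  groups <- groups[sample_ids(g)]
  if (anyNA(groups)) stop("every sample needs a replicate-group label")
  tab <- table(groups)
  small <- names(tab)[tab < 2]
  if (length(small) > 0) {
    warning("excluding replicate group(s) of size 1: ",
            paste(small, collapse = ", "))
  }
  use_groups <- names(tab)[tab >= 2]
  if (length(use_groups) == 0) stop("no replicate group has >= 2 samples")

  S <- n_sites(g)
  agree <- pairs <- numeric(S)
  all_ok <- matrix(TRUE, length(use_groups), S)
  for (gi in seq_along(use_groups)) {
    members <- which(groups == use_groups[gi])
    cmb <- utils::combn(members, 2)
    for (k in seq_len(ncol(cmb))) {
      a <- g$dosage[cmb[1, k], ]
      b <- g$dosage[cmb[2, k], ]
      ok <- !is.na(a) & !is.na(b)
      eq <- ok & a == b
      agree <- agree + eq
      pairs <- pairs + ok
      all_ok[gi, ] <- all_ok[gi, ] & (!ok | eq)
    }
  }
  per_site <- data.frame(
    site_id = g$sites$site_id,
    reproducibility = ifelse(pairs > 0, 100 * agree / pairs, NA_real_),
    n_pairs = pairs,
    stringsAsFactors = FALSE
  )
  scored <- !is.na(per_site$reproducibility)
  list(
    per_site = per_site,
    overall = mean(per_site$reproducibility[scored]),
    sites_reproducible_all_groups =
      g$sites$site_id[colSums(!all_ok) == 0 & pairs > 0]
  )
}
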