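#' Genotype matrix container
#'
#' The central object of the pipeline: a samples x sites matrix of diploid
#' dosage codes (0 = homozygous reference, 1 = heterozygous, 2 = homozygous
#' variant, `NA` = missing) together with per-site metadata (source
#' transcript, 1-based offset within the transcript, reference/variant
#' alleles, and -- once synteny projection has run -- a chromosome and
#' 1-based genomic position on the proxy genome).
#'
#' @param dosage integer matrix, samples in rows and sites in columns;
#'   values must be 0, 1, 2 or `NA`.
#' @param sites data.frame with one row per site. Required columns:
#'   `site_id`, `ref`, `var`. Optional: `transcript_id`, `offset`,
#'   `chrom`, `pos` (filled with `NA` when absent).
#' @param samples character vector of sample ids; defaults to the row names
#'   of `dosage`.
#'
#' @return An object of class `geno_matrix`: a list with elements `dosage`
#'   (named integer matrix) and `sites` (data.frame).
#' @export
genotype_matrix <- function(dosage, sites, samples = rownames(dosage)) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(samples)) {
    samples <- sprintf("sample%03d", seq_len(nrow(dosage)))
  }
  stopifnot(is.data.frame(sites), nrow(sites) == ncol(dosage))
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  for (col in c("site_id", "ref", "var")) {
    if (is.null(sites[[col]])) stop("sites is missing required column '", col, "'")
  }
  if (anyDuplicated(sites$site_id)) stop("site ids must be unique")
  if (anyDuplicated(samples)) stop("sample ids must be unique")
  bad <- !(dosage %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("dosage codes must be 0, 1, 2 or NA")
  if (is.null(sites$transcript_id)) sites$transcript_id <- NA_character_
  if (is.null(sites$offset)) sites$offset <- NA_integer_
  if (is.null(sites$chrom)) sites$chrom <- NA_character_
  if (is.null(sites$pos)) sites$pos <- NA_integer_
  if (any(!is.na(sites$pos) & sites$pos < 1)) stop("projected positions must be positive")
  rownames(dosage) <- samples
  colnames(dosage) <- sites$site_id
  rownames(sites) <- NULL
  structure(list(dosage = dosage, sites = sites), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d samples x %d sites\n",
              nrow(x$dosage), ncol(x$dosage)))
  placed <- sum(!is.na(x$sites$pos))
  cat(sprintf("  placed sites: %d (%.1f%%)  missing calls: %.2f%%\n",
              placed, 100 * placed / max(1L, ncol(x$dosage)),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix
#'
#' `i` selects samples, `j` selects sites (either may be indices, logicals
#' or names).
#' @param x a `geno_matrix`.
#' @param i,j sample / site selectors.
#' @param ... ignored.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosage))
  if (missing(j)) j <- seq_len(ncol(x$dosage))
  if (is.character(j)) j <- match(j, x$sites$site_id)
  genotype_matrix(x$dosage[i, j, drop = FALSE], x$sites[j, , drop = FALSE])
}

#' @rdname genotype_matrix
#' @param g a `geno_matrix`.
#' @export
n_samples <- function(g) nrow(g$dosage)

#' @rdname genotype_matrix
#' @export
n_sites <- function(g) ncol(g$dosage)

#' @rdname genotype_matrix
#' @export
sample_ids <- function(g) rownames(g$dosage)

# Variant-allele frequency per site over non-missing allele copies.
# Returns NA for sites with fewer than one non-missing call.
site_variant_freq <- function(g) {
  nn <- colSums(!is.na(g$dosage))
  cnt <- colSums(g$dosage, na.rm = TRUE)
  ifelse(nn > 0, cnt / (2 * nn), NA_real_)
}

# Minor allele frequency per site (folded variant frequency).
site_maf <- function(g) {
  p <- site_variant_freq(g)
  pmin(p, 1 - p)
}

site_missing_fraction <- function(g) colMeans(is.na(g$dosage))

site_het_fraction <- function(g) {
  nn <- colSums(!is.na(g$dosage))
  ifelse(nn > 0, colSums(g$dosage == 1L, na.rm = TRUE) / nn, NA_real_)
}
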