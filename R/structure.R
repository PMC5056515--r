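#' Ward clustering of a 1-IBS distance matrix
#'
#' Agglomerative hierarchical clustering of the pairwise 1-IBS distances
#' with Ward's linkage (the classical `ward.D` criterion, matching the
#' historical default of R's `hclust` on a precomputed distance matrix),
#' cut into `k` clusters.
#'
#' @param dist_matrix symmetric distance matrix with zero diagonal, e.g.
#'   from [ibs_distance()].
#' @param k number of clusters to cut to.
#' @param method linkage criterion passed to [stats::hclust()].
#' @return An object of class `cluster_result`: list with `method`,
#'   `assignments` (named integer vector), `hclust` (merge history) and `k`.
#' @export
snp_ward_clustering <- function(dist_matrix, k, method = "ward.D") {
  dist_matrix <- as.matrix(dist_matrix)
  n <- nrow(dist_matrix)
  if (k > n) stop("k exceeds the number of samples")
  if (any(abs(diag(dist_matrix)) > 1e-12)) stop("distance matrix diagonal must be zero")
  if (max(abs(dist_matrix - t(dist_matrix)), na.rm = TRUE) > 1e-8)
    stop("distance matrix must be symmetric")
  hc <- stats::hclust(stats::as.dist(dist_matrix), method = method)
  structure(list(method = paste0("ibs-ward(", method, ")"),
                 assignments = stats::cutree(hc, k = k),
                 hclust = hc, k = k),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %s, k = %d\n", x$method, x$k))
  print(table(cluster = x$assignments))
  invisible(x)
}

#' Principal component analysis of standardized dosages
#'
#' Dosages are centered at `2p` and scaled by `sqrt(2p(1-p))` per site
#' (the standardization underlying the genomic relationship matrix);
#' missing dosages are imputed to the site mean. The sample coordinates are
#' `U * sqrt(lambda)` from the eigendecomposition of the GRM, so the inner
#' product matrix of the retained coordinates reconstructs the (truncated)
#' GRM.
#'
#' @param g a [genotype_matrix()].
#' @param n_components number of components to return.
#' @return List of class `pca_result` with `scores` (samples x components),
#'   `eigenvalues` and `explained_variance` (nonincreasing fractions).
#' @export
snp_pca <- function(g, n_components = 10) {
  K <- grm(g)
  ev <- eigen(K, symmetric = TRUE)
  pos <- ev$values > 1e-10 * max(ev$values)
  n_components <- min(n_components, sum(pos))
  lam <- ev$values[seq_len(n_components)]
  scores <- ev$vectors[, seq_len(n_components), drop = FALSE] %*%
    diag(sqrt(lam), n_components)
  dimnames(scores) <- list(rownames(K), paste0("PC", seq_len(n_components)))
  structure(list(scores = scores, eigenvalues = lam,
                 explained_variance = lam / sum(ev$values[ev$values > 0])),
            class = "pca_result")
}

#' Ward clustering of gene expression markers
#'
#' Expression values are transformed to `log2(x + 1)`, transcripts ranked
#' by variance across genotypes, the `top_n` most variable retained, and
#' genotype profiles clustered on Euclidean distance with Ward's linkage.
#' The same machinery orders expression heat maps.
#'
#' @param e transcripts x genotypes nonnegative expression matrix.
#' @param top_n number of most-variable transcripts to use (default 1000).
#' @param k number of clusters to cut to.
#' @param method linkage criterion.
#' @return A `cluster_result` (see [snp_ward_clustering()]); also carries
#'   `transcripts_used`.
#' @export
gem_clustering <- function(e, top_n = 1000, k, method = "ward.D") {
  e <- as.matrix(e)
  if (k > ncol(e)) stop("k exceeds the number of genotypes")
  lx <- log2(e + 1)
  v <- apply(lx, 1, stats::var)
  if (top_n > nrow(lx)) {
    warning("top_n exceeds available transcripts; using all ", nrow(lx))
    top_n <- nrow(lx)
  }
  ord <- order(v, decreasing = TRUE)[seq_len(top_n)]
  d <- stats::dist(t(lx[ord, , drop = FALSE]))
  hc <- stats::hclust(d, method = method)
  res <- structure(list(method = paste0("gem-ward(", method, ")"),
                        assignments = stats::cutree(hc, k = k),
                        hclust = hc, k = k,
                        transcripts_used = rownames(lx)[ord]),
                   class = "cluster_result")
  res
}

#' Concordance of a clustering with pedigree or reference labels
#'
#' Counts how many known first-degree pairs (parent-child from the
#' pedigree records, plus half-sibs sharing a recorded parent) land in the
#' same cluster, and emits the confusion-style contingency table. When full
#' reference labels are supplied the adjusted Rand index is computed as
#' well.
#'
#' @param clusters a `cluster_result` or a named cluster-assignment vector.
#' @param pedigree data.frame with columns `child`, `mother`, `father`
#'   (either may be `NA`); optional.
#' @param reference named vector of reference labels; optional.
#' @return List with `pairs` (data.frame of known pairs and whether they
#'   were co-clustered), `concordance` (fraction co-clustered),
#'   `confusion` (cluster x cluster table of known pairs) and `ari`
#'   (`NA` without reference labels).
#' @export
cluster_concordance <- function(clusters, pedigree = NULL, reference = NULL) {
  assign <- if (inherits(clusters, "cluster_result")) clusters$assignments else clusters
  ari <- NA_real_
  if (!is.null(reference)) {
    shared <- intersect(names(assign), names(reference))
    if (length(shared) > 0) ari <- adjusted_rand_index(assign[shared], reference[shared])
  }
  pairs <- NULL
  concord <- NA_real_
  confusion <- NULL
  if (!is.null(pedigree)) {
    rel <- pedigree_pairs(pedigree)
    rel <- rel[rel$id1 %in% names(assign) & rel$id2 %in% names(assign), , drop = FALSE]
    if (nrow(rel) == 0) {
      warning("no pedigree pairs overlap the clustered samples")
      confusion <- table(factor(integer(0)), factor(integer(0)))
    } else {
      rel$cluster1 <- assign[rel$id1]
      rel$cluster2 <- assign[rel$id2]
      rel$co_clustered <- rel$cluster1 == rel$cluster2
      concord <- mean(rel$co_clustered)
      confusion <- table(cluster1 = rel$cluster1, cluster2 = rel$cluster2)
      pairs <- rel
    }
  }
  list(pairs = pairs, concordance = concord, confusion = confusion, ari = ari)
}

# Known first-degree pairs implied by pedigree records: parent-child edges
# and half-sib pairs sharing a recorded parent.
pedigree_pairs <- function(pedigree) {
  pc <- rbind(
    data.frame(id1 = pedigree$child, id2 = pedigree$mother,
               relationship = "parent-child", stringsAsFactors = FALSE),
    data.frame(id1 = pedigree$child, id2 = pedigree$father,
               relationship = "parent-child", stringsAsFactors = FALSE)
  )
  pc <- pc[!is.na(pc$id2) & pc$id1 != pc$id2, , drop = FALSE]
  sib <- list()
  for (parent_col in c("mother", "father")) {
    par <- pedigree[[parent_col]]
    for (p in unique(par[!is.na(par)])) {
      kids <- pedigree$child[!is.na(par) & par == p]
      if (length(kids) >= 2) {
        cmb <- utils::combn(sort(kids), 2)
        sib[[length(sib) + 1]] <- data.frame(id1 = cmb[1, ], id2 = cmb[2, ],
                                             relationship = "half-sib",
                                             stringsAsFactors = FALSE)
      }
    }
  }
  out <- rbind(pc, if (length(sib)) do.call(rbind, sib))
  key <- apply(cbind(pmin(out$id1, out$id2), pmax(out$id1, out$id2)), 1, paste,
               collapse = "|")
  out[!duplicated(key), , drop = FALSE]
}
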