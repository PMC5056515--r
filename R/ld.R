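#' Project transcript SNPs onto a proxy genome
#'
#' Assigns a provisional chromosome and 1-based position to every SNP whose
#' source transcript has a synteny anchor: for a `+` strand anchor the
#' position is `start + offset - 1`; for a `-` strand anchor with a known
#' transcript length it is `start + transcript_length - offset`. Minus
#' strand anchors without a transcript length place the SNP at the anchor
#' start with a warning. SNPs on unanchored transcripts stay unplaced and
#' are excluded from positional analyses only.
#'
#' @param g a [genotype_matrix()] whose sites carry `transcript_id` and
#'   `offset`.
#' @param anchors data.frame with columns `transcript_id`, `chrom`,
#'   `start`, `strand` and optionally `transcript_length`.
#' @return `g` with `chrom`/`pos` filled for placed sites; the attribute
#'   `placed_fraction` reports the placed share.
#' @export
project_snps <- function(g, anchors) {
  stopifnot(inherits(g, "geno_matrix"))
  bad <- is.na(anchors$chrom) | is.na(anchors$start)
  if (any(bad)) {
    warning(sum(bad), " anchor record(s) with unknown chromosome/start rejected")
    anchors <- anchors[!bad, , drop = FALSE]
  }
  if (anyDuplicated(anchors$transcript_id))
    stop("anchors must have one best placement per transcript")
  m <- match(g$sites$transcript_id, anchors$transcript_id)
  placed <- !is.na(m) & !is.na(g$sites$offset)
  strand <- anchors$strand[m]
  start <- anchors$start[m]
  txlen <- if (!is.null(anchors$transcript_length)) anchors$transcript_length[m] else
    rep(NA_real_, length(m))
  pos <- rep(NA_integer_, length(m))
  plus <- placed & strand == "+"
  minus <- placed & strand == "-"
  pos[plus] <- as.integer(start[plus] + g$sites$offset[plus] - 1L)
  known <- minus & !is.na(txlen)
  pos[known] <- as.integer(start[known] + txlen[known] - g$sites$offset[known])
  flagged <- minus & is.na(txlen)
  if (any(flagged)) {
    warning(sum(flagged), " minus-strand SNP(s) placed at anchor start ",
            "(transcript length unknown)")
    pos[flagged] <- as.integer(start[flagged])
  }
  g$sites$chrom <- ifelse(placed, anchors$chrom[m], NA_character_)
  g$sites$pos <- pos
  attr(g, "placed_fraction") <- mean(placed)
  g
}

# 3x3 unphased two-locus genotype counts for one site pair, as a length-9
# vector ordered n00,n01,n02,n10,n11,n12,n20,n21,n22 (first index = dosage
# at locus A).
pair_genotype_counts <- function(da, db) {
  ok <- !is.na(da) & !is.na(db)
  tabulate(1L + 3L * da[ok] + db[ok], nbins = 9L)
}

# EM estimation of two-locus haplotype frequencies from unphased diploid
# genotype counts, vectorized across pairs. `counts` is a matrix with 9
# columns in pair_genotype_counts() order. Returns haplotype frequencies
# (f_rr, f_rv, f_vr, f_vv), allele frequencies, D, D', r2 and the double
# heterozygote phase weight.
em_haplotype_freqs <- function(counts, tol = 1e-10, max_iter = 1000) {
  counts <- matrix(counts, ncol = 9)
  n <- rowSums(counts)
  n2 <- 2 * n
  pA <- (counts[, 4] + counts[, 5] + counts[, 6] +
           2 * (counts[, 7] + counts[, 8] + counts[, 9])) / n2
  pB <- (counts[, 2] + counts[, 5] + counts[, 8] +
           2 * (counts[, 3] + counts[, 6] + counts[, 9])) / n2
  # fixed haplotype contributions (everything but the double heterozygote)
  base_rr <- 2 * counts[, 1] + counts[, 2] + counts[, 4]
  base_rv <- 2 * counts[, 3] + counts[, 2] + counts[, 6]
  base_vr <- 2 * counts[, 7] + counts[, 4] + counts[, 8]
  base_vv <- 2 * counts[, 9] + counts[, 8] + counts[, 6]
  ndh <- counts[, 5]
  frr <- (1 - pA) * (1 - pB); frv <- (1 - pA) * pB
  fvr <- pA * (1 - pB); fvv <- pA * pB
  for (iter in seq_len(max_iter)) {
    cis <- frr * fvv
    trans <- frv * fvr
    alpha <- ifelse(cis + trans > 0, cis / (cis + trans), 0.5)
    new_rr <- (base_rr + ndh * alpha) / n2
    new_rv <- (base_rv + ndh * (1 - alpha)) / n2
    new_vr <- (base_vr + ndh * (1 - alpha)) / n2
    new_vv <- (base_vv + ndh * alpha) / n2
    delta <- pmax(abs(new_rr - frr), abs(new_rv - frv),
                  abs(new_vr - fvr), abs(new_vv - fvv))
    frr <- new_rr; frv <- new_rv; fvr <- new_vr; fvv <- new_vv
    if (max(delta) < tol) break
  }
  D <- fvv - pA * pB
  denom <- pA * (1 - pA) * pB * (1 - pB)
  r2 <- ifelse(denom > 0, D^2 / denom, NA_real_)
  dmax <- ifelse(D >= 0,
                 pmin(pA * (1 - pB), (1 - pA) * pB),
                 pmin(pA * pB, (1 - pA) * (1 - pB)))
  dprime <- ifelse(dmax > 0, abs(D) / dmax, NA_real_)
  list(freqs = cbind(f_rr = frr, f_rv = frv, f_vr = fvr, f_vv = fvv),
       pA = pA, pB = pB, D = D, r2 = r2, dprime = pmin(dprime, 1), n = n)
}

#' Pairwise linkage disequilibrium (r-squared and D-prime)
#'
#' Two-locus haplotype frequencies are estimated by EM over the unphased
#' diploid genotypes (resolving the double-heterozygote phase ambiguity
#' iteratively), from which `D`, `D'` and `r2 = D^2 / (pA qA pB qB)` follow.
#'
#' @param g a [genotype_matrix()].
#' @param pairs two-column matrix of site indices or site ids; defaults to
#'   all site pairs (quadratic -- supply `pairs` for large matrices).
#' @return data.frame with `site_a`, `site_b`, `r2`, `dprime`, `D`, the
#'   four haplotype frequencies, `n` (samples used), `dist_bp` (`NA` for
#'   unplaced or inter-chromosome pairs) and `inter_chrom`.
#'   Pairs with a monomorphic member are skipped.
#' @export
pairwise_r2 <- function(g, pairs = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  if (is.null(pairs)) {
    if (n_sites(g) > 2000)
      stop("refusing all-pairs LD on > 2000 sites; supply `pairs`")
    pairs <- t(utils::combn(n_sites(g), 2))
  }
  if (is.character(pairs)) pairs <- matrix(match(pairs, g$sites$site_id), ncol = 2)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  counts <- t(apply(pairs, 1, function(pr) {
    pair_genotype_counts(g$dosage[, pr[1]], g$dosage[, pr[2]])
  }))
  em <- em_haplotype_freqs(counts)
  poly <- em$pA > 0 & em$pA < 1 & em$pB > 0 & em$pB < 1 & em$n > 0
  sa <- g$sites[pairs[, 1], ]
  sb <- g$sites[pairs[, 2], ]
  same_chrom <- !is.na(sa$chrom) & !is.na(sb$chrom) & sa$chrom == sb$chrom
  out <- data.frame(
    site_a = sa$site_id, site_b = sb$site_id,
    r2 = em$r2, dprime = em$dprime, D = em$D,
    em$freqs, n = em$n,
    dist_bp = ifelse(same_chrom, abs(sb$pos - sa$pos), NA_integer_),
    inter_chrom = !is.na(sa$chrom) & !is.na(sb$chrom) & sa$chrom != sb$chrom,
    stringsAsFactors = FALSE
  )
  out[poly, , drop = FALSE]
}

# Likelihood-grid D' confidence intervals for a batch of pairs
# (Gabriel/Haploview convention). `counts` is a 9-column matrix; allele
# frequencies are fixed at their MLEs, |D'| is scanned on a grid, the
# normalized likelihood is treated as a posterior-like weight, and
# ci_low / ci_high are the (1-ci_mass)/2 and 1-(1-ci_mass)/2 cut points.
dprime_ci_batch <- function(counts, grid_step = 0.001, ci_mass = 0.90) {
  counts <- matrix(counts, ncol = 9)
  np <- nrow(counts)
  em <- em_haplotype_freqs(counts)
  grid <- seq(0, 1, by = grid_step)
  ng <- length(grid)
  pA <- em$pA; pB <- em$pB
  sgn <- ifelse(em$D >= 0, 1, -1)
  dmax <- ifelse(sgn > 0,
                 pmin(pA * (1 - pB), (1 - pA) * pB),
                 pmin(pA * pB, (1 - pA) * (1 - pB)))
  ok <- pA > 0 & pA < 1 & pB > 0 & pB < 1 & dmax > 0
  lo <- hi <- rep(NA_real_, np)
  if (!any(ok)) {
    return(data.frame(dprime = em$dprime, ci_low = lo, ci_high = hi))
  }
  idx <- which(ok)
  alpha <- (1 - ci_mass) / 2
  for (chunk in split(idx, ceiling(seq_along(idx) / 512))) {
    Dg <- outer(grid, sgn[chunk] * dmax[chunk])          # ng x nc
    fvv <- sweep(Dg, 2, pA[chunk] * pB[chunk], `+`)
    fvr <- sweep(-Dg, 2, pA[chunk] * (1 - pB[chunk]), `+`)
    frv <- sweep(-Dg, 2, (1 - pA[chunk]) * pB[chunk], `+`)
    frr <- sweep(Dg, 2, (1 - pA[chunk]) * (1 - pB[chunk]), `+`)
    eps <- 1e-12
    fvv <- pmax(fvv, eps); fvr <- pmax(fvr, eps)
    frv <- pmax(frv, eps); frr <- pmax(frr, eps)
    cn <- t(counts[chunk, , drop = FALSE])               # 9 x nc
    ll <- log(frr^2) * rep(cn[1, ], each = ng) +
      log(2 * frr * frv) * rep(cn[2, ], each = ng) +
      log(frv^2) * rep(cn[3, ], each = ng) +
      log(2 * frr * fvr) * rep(cn[4, ], each = ng) +
      log(2 * (frr * fvv + frv * fvr)) * rep(cn[5, ], each = ng) +
      log(2 * frv * fvv) * rep(cn[6, ], each = ng) +
      log(fvr^2) * rep(cn[7, ], each = ng) +
      log(2 * fvr * fvv) * rep(cn[8, ], each = ng) +
      log(fvv^2) * rep(cn[9, ], each = ng)
    ll <- sweep(ll, 2, apply(ll, 2, max))
    w <- exp(ll)
    cum <- apply(w, 2, cumsum)
    cum <- sweep(cum, 2, cum[ng, ], `/`)
    below <- rbind(0, cum[-ng, , drop = FALSE])          # mass strictly below
    for (ci in seq_along(chunk)) {
      i <- chunk[ci]
      lo[i] <- grid[max(which(below[, ci] <= alpha))]
      hi[i] <- grid[min(which(cum[, ci] >= 1 - alpha))]
    }
  }
  data.frame(dprime = em$dprime, ci_low = lo, ci_high = hi)
}

#' D-prime with a likelihood-based confidence interval for one site pair
#'
#' @param da,db dosage vectors (0/1/2/NA) of the two sites.
#' @param grid_step grid resolution on |D'|.
#' @param ci_mass central mass of the interval (default 0.90).
#' @return List with `dprime`, `ci_low`, `ci_high`.
#' @export
dprime_ci <- function(da, db, grid_step = 0.001, ci_mass = 0.90) {
  cnt <- pair_genotype_counts(da, db)
  res <- dprime_ci_batch(matrix(cnt, nrow = 1), grid_step, ci_mass)
  if (is.na(res$ci_low[1])) stop("degenerate allele frequencies: D' undefined")
  list(dprime = res$dprime[1], ci_low = res$ci_low[1], ci_high = res$ci_high[1])
}

#' Background LD from inter-chromosome marker pairs
#'
#' Subsamples pairs of placed SNPs on different chromosomes, computes r2
#' for each, and returns the 90th percentile -- the background level
#' against which within-chromosome decay is judged.
#'
#' @param g a placed [genotype_matrix()] (see [project_snps()]).
#' @param n_pairs maximum number of inter-chromosome pairs to use.
#' @param seed seed for the subsampling.
#' @param probs quantile to report (default 0.90).
#' @return The r2 threshold (numeric scalar), with attribute `n_pairs`.
#' @export
background_ld <- function(g, n_pairs = 1e5, seed = 1, probs = 0.90) {
  placed <- which(!is.na(g$sites$chrom) & !is.na(g$sites$pos))
  chroms <- g$sites$chrom[placed]
  if (length(unique(chroms)) < 2) stop("need placed SNPs on >= 2 chromosomes")
  maf <- site_maf(g)[placed]
  use <- placed[!is.na(maf) & maf > 0]
  chroms <- g$sites$chrom[use]
  set.seed(seed)
  n_draw <- min(n_pairs * 2, 4e6)
  a <- use[sample.int(length(use), n_draw, replace = TRUE)]
  b <- use[sample.int(length(use), n_draw, replace = TRUE)]
  keep <- g$sites$chrom[a] != g$sites$chrom[b]
  pairs <- unique(cbind(pmin(a[keep], b[keep]), pmax(a[keep], b[keep])))
  if (nrow(pairs) > n_pairs) pairs <- pairs[seq_len(n_pairs), , drop = FALSE]
  if (nrow(pairs) < 100) {
    warning("fewer than 100 inter-chromosome pairs available (", nrow(pairs), ")")
  }
  ld <- pairwise_r2(g, pairs)
  thr <- unname(stats::quantile(ld$r2, probs, na.rm = TRUE))
  attr(thr, "n_pairs") <- nrow(ld)
  thr
}

#' LD decay with distance
#'
#' Bins within-chromosome pairs by physical distance and reports the mean
#' and median r2 per bin, genome-wide and per chromosome. The decay
#' distance at a threshold is the midpoint of the first bin whose mean r2
#' falls below the threshold and stays below it in every larger bin.
#'
#' @param pairs output of [pairwise_r2()] restricted to placed pairs, or
#'   any data.frame with `r2` and `dist_bp` (and optionally a chromosome
#'   column `chrom`).
#' @param bin_width_kb distance bin width, kb.
#' @param thresholds r2 thresholds at which to report decay distances;
#'   typically `c(0.1, 0.2)` plus the [background_ld()] value.
#' @return List with `table` (per-bin summaries) and `decay_kb` (named
#'   vector of decay distances in kb; `NA` when the mean never drops below
#'   the threshold).
#' @export
ld_decay <- function(pairs, bin_width_kb = 5, thresholds = c(0.1, 0.2)) {
  d <- pairs[!is.na(pairs$dist_bp) & !is.na(pairs$r2), , drop = FALSE]
  if (nrow(d) == 0) stop("no positioned pairs supplied")
  kb <- d$dist_bp / 1000
  bin <- floor(kb / bin_width_kb)
  agg <- function(sel, label) {
    b <- sort(unique(bin[sel]))
    data.frame(
      scope = label,
      bin_start_kb = b * bin_width_kb,
      bin_mid_kb = (b + 0.5) * bin_width_kb,
      n_pairs = as.integer(table(factor(bin[sel], levels = b))),
      mean_r2 = tapply(d$r2[sel], factor(bin[sel], levels = b), mean),
      median_r2 = tapply(d$r2[sel], factor(bin[sel], levels = b), stats::median),
      stringsAsFactors = FALSE
    )
  }
  tab <- agg(rep(TRUE, nrow(d)), "genome")
  if (!is.null(d$chrom)) {
    for (ch in sort(unique(d$chrom[!is.na(d$chrom)]))) {
      tab <- rbind(tab, agg(!is.na(d$chrom) & d$chrom == ch, ch))
    }
  }
  rownames(tab) <- NULL
  gw <- tab[tab$scope == "genome", ]
  decay <- vapply(thresholds, function(thr) {
    beneath <- gw$mean_r2 < thr
    stays <- rev(cumprod(rev(beneath))) == 1   # below here and ever after
    if (!any(stays)) return(NA_real_)
    gw$bin_mid_kb[which(stays)[1]]
  }, numeric(1))
  names(decay) <- sprintf("r2<%g", thresholds)
  list(table = tab, decay_kb = decay)
}

#' Gabriel-style haplotype blocks
#'
#' Within each chromosome, every placed SNP pair closer than the window is
#' classified from its D' confidence interval as strong LD (`ci_low >
#' strong_low` and `ci_high >= strong_high`), strong recombination
#' (`ci_high < recomb_high`) or uninformative. A contiguous span of SNPs is
#' a candidate block when its strong-LD pairs exceed `min_strong_fraction`
#' of its informative pairs; candidates are ranked by bp length and
#' accepted greedily if they do not overlap an accepted block. Blocks are
#' capped at `max_block_kb`.
#'
#' @param g a placed [genotype_matrix()].
#' @param max_block_kb maximum block span, kb (default 2000 = 2 Mb, also
#'   the pair-classification window).
#' @param min_strong_fraction strong-LD share required (default 0.95).
#' @param min_maf block-eligible SNPs must exceed this MAF (default 0.05).
#' @param strong_low,strong_high,recomb_high CI bounds of the Gabriel rule.
#' @return data.frame with `chrom`, `start`, `end`, `n_snps`, `span_kb`,
#'   `site_ids` (comma separated); zero rows when no block is found.
#' @export
haplotype_blocks <- function(g, max_block_kb = 2000, min_strong_fraction = 0.95,
                             min_maf = 0.05, strong_low = 0.7,
                             strong_high = 0.98, recomb_high = 0.9) {
  stopifnot(inherits(g, "geno_matrix"))
  maf <- site_maf(g)
  eligible <- which(!is.na(g$sites$chrom) & !is.na(g$sites$pos) &
                      !is.na(maf) & maf >= min_maf)
  out <- list()
  window_bp <- max_block_kb * 1000
  for (ch in unique(g$sites$chrom[eligible])) {
    idx <- eligible[g$sites$chrom[eligible] == ch]
    idx <- idx[order(g$sites$pos[idx])]
    m <- length(idx)
    if (m < 2) next
    pos <- g$sites$pos[idx]
    # classify all pairs within the window
    pa <- pb <- integer(0)
    for (j in 2:m) {
      ks <- which(pos[j] - pos[seq_len(j - 1)] <= window_bp)
      pa <- c(pa, ks); pb <- c(pb, rep(j, length(ks)))
    }
    if (length(pa) == 0) next
    counts <- t(vapply(seq_along(pa), function(t) {
      pair_genotype_counts(g$dosage[, idx[pa[t]]], g$dosage[, idx[pb[t]]])
    }, numeric(9)))
    ci <- dprime_ci_batch(counts)
    cls <- integer(length(pa))                 # 0 uninformative
    cls[!is.na(ci$ci_low) & ci$ci_low > strong_low &
          ci$ci_high >= strong_high] <- 1L     # strong LD
    cls[!is.na(ci$ci_high) & ci$ci_high < recomb_high] <- -1L
    cand <- enumerate_block_candidates(pos, pa, pb, cls, window_bp,
                                       min_strong_fraction)
    if (nrow(cand) == 0) next
    cand <- cand[order(-cand$span_bp, cand$i), , drop = FALSE]
    taken <- rep(FALSE, m)
    for (r in seq_len(nrow(cand))) {
      rng <- cand$i[r]:cand$j[r]
      if (any(taken[rng])) next
      taken[rng] <- TRUE
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = pos[cand$i[r]], end = pos[cand$j[r]],
        n_snps = length(rng), span_kb = cand$span_bp[r] / 1000,
        site_ids = paste(g$sites$site_id[idx[rng]], collapse = ","),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      n_snps = integer(), span_kb = numeric(),
                      site_ids = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

# Enumerate candidate spans [i..j] whose strong-LD pairs exceed the
# required fraction of informative pairs. Pair classes are given as
# parallel vectors (pa, pb, cls); spans wider than window_bp are skipped.
enumerate_block_candidates <- function(pos, pa, pb, cls, window_bp,
                                       min_strong_fraction) {
  m <- length(pos)
  # per right-end j: classes of pairs (k, j), as suffix sums over k
  by_j <- split(seq_along(pb), pb)
  suffix <- vector("list", m)
  for (j_chr in names(by_j)) {
    j <- as.integer(j_chr)
    sel <- by_j[[j_chr]]
    ks <- pa[sel]
    o <- order(ks)
    ks <- ks[o]; cl <- cls[sel][o]
    s_strong <- rev(cumsum(rev(cl == 1L)))
    s_recomb <- rev(cumsum(rev(cl == -1L)))
    suffix[[j]] <- list(kmin = ks[1], ks = ks,
                        strong = s_strong, recomb = s_recomb)
  }
  res_i <- res_j <- integer(0); res_span <- numeric(0)
  for (i in seq_len(m - 1)) {
    strong <- recomb <- 0
    j <- i
    while (j < m && pos[j + 1] - pos[i] <= window_bp) {
      j <- j + 1
      sfx <- suffix[[j]]
      if (!is.null(sfx)) {
        t <- findInterval(i - 1, sfx$ks) + 1   # first k >= i
        if (t <= length(sfx$ks)) {
          strong <- strong + sfx$strong[t]
          recomb <- recomb + sfx$recomb[t]
        }
      }
      info <- strong + recomb
      if (info >= 1 && strong / info > min_strong_fraction && strong >= 1) {
        res_i <- c(res_i, i); res_j <- c(res_j, j)
        res_span <- c(res_span, pos[j] - pos[i])
      }
    }
  }
  data.frame(i = res_i, j = res_j, span_bp = res_span)
}
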