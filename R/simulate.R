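#' Configuration for the synthetic breeding-collection simulator
#'
#' Describes a diploid, highly heterozygous, open-pollinated collection in
#' the style of a small tuber-crop breeding program: a handful of founder
#' genotypes partitioned into genotypic clusters, a few generations of open
#' pollination in which only the maternal parent is certain (the recorded
#' "likely paternal parents" form the candidate-father list), RNA-seq style
#' allele-specific read counts with sequencing error, structured gene
#' expression, and quantitative traits with planted SNP effects, a polygenic
#' background and trait-linked transcripts.
#'
#' Defaults mirror the collection the pipeline targets: 52 genotypes, 11
#' chromosomes, 6 genotypic clusters, ~20 traits, roughly one in five
#' transcripts polymorphic, high founder heterozygosity (Beta(0.5, 0.5)
#' allele frequencies), and ~81 percent of transcripts anchored to the proxy
#' genome.
#'
#' @param n_founders number of founder genotypes (partitioned across clusters).
#' @param n_genotypes total collection size, founders included.
#' @param n_chromosomes chromosomes of the proxy genome.
#' @param chromosome_length_bp length of every chromosome, bp.
#' @param n_transcripts number of transcripts tiled on the genome.
#' @param transcript_length_bp transcript length, bp (uniform).
#' @param prob_polymorphic probability a transcript carries any SNPs.
#' @param mean_snps_per_transcript mean SNPs in a polymorphic transcript
#'   (shifted Poisson, minimum 1).
#' @param founder_maf_beta shape parameters (alpha, beta) of the ancestral
#'   allele-frequency distribution.
#' @param cluster_fst Balding-Nichols style divergence of per-cluster allele
#'   frequencies around the ancestral frequency; 0 disables divergence.
#' @param generations number of open-pollination waves after the founders.
#' @param selfing_rate probability an offspring is produced by selfing.
#' @param n_candidate_fathers number of recorded likely paternal parents.
#' @param mean_depth mean sequencing depth per sample x site.
#' @param depth_dispersion negative-binomial dispersion of depth (0 = Poisson).
#' @param seq_error_rate probability a read reports the wrong allele.
#' @param base_quality_mean,base_quality_sd phred-scale distribution of the
#'   mean variant base quality.
#' @param n_clusters number of genotypic clusters.
#' @param n_traits number of phenotypic traits.
#' @param n_trait_snps causal SNPs planted per trait.
#' @param snp_effect_sizes effect sizes (trait units per variant-allele copy),
#'   recycled across the planted SNPs of a trait.
#' @param heritability fraction of trait variance that is genetic, in [0, 1].
#' @param n_trait_gems transcripts whose expression is linearly linked to a
#'   trait, per trait.
#' @param gem_slope slope of expression on trait for trait-linked transcripts.
#' @param gem_noise_sd residual SD of trait-linked expression.
#' @param expr_mean_log2,expr_sd_log2 baseline transcript abundance on the
#'   log2 scale.
#' @param expr_cluster_sd SD of cluster-specific log2 expression shifts.
#' @param expr_resid_sd residual log2 expression noise.
#' @param prop_cluster_transcripts fraction of transcripts carrying
#'   cluster-specific shifts.
#' @param anchored_fraction fraction of transcripts with a proxy-genome anchor.
#' @param seed integer seed; all simulator randomness flows from it.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 12, n_genotypes = 52, n_chromosomes = 11,
                       chromosome_length_bp = 5e7, n_transcripts = 2000,
                       transcript_length_bp = 1200,
                       prob_polymorphic = 0.2, mean_snps_per_transcript = 6,
                       founder_maf_beta = c(0.5, 0.5), cluster_fst = 0.15,
                       generations = 3, selfing_rate = 0.05,
                       n_candidate_fathers = 3,
                       mean_depth = 30, depth_dispersion = 0.3,
                       seq_error_rate = 0.01,
                       base_quality_mean = 30, base_quality_sd = 2,
                       n_clusters = 6,
                       n_traits = 20, n_trait_snps = 2,
                       snp_effect_sizes = c(1, 0.6),
                       heritability = 0.5,
                       n_trait_gems = 2, gem_slope = 5, gem_noise_sd = 1,
                       expr_mean_log2 = 3, expr_sd_log2 = 1.5,
                       expr_cluster_sd = 1, expr_resid_sd = 0.5,
                       prop_cluster_transcripts = 0.2,
                       anchored_fraction = 0.81,
                       seed = 1) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  probs <- c("prob_polymorphic", "selfing_rate", "seq_error_rate",
             "anchored_fraction", "prop_cluster_transcripts", "heritability")
  for (p in probs) {
    if (!is.numeric(cfg[[p]]) || cfg[[p]] < 0 || cfg[[p]] > 1)
      stop("invalid config: '", p, "' must be a probability in [0, 1]")
  }
  counts <- c("n_founders", "n_genotypes", "n_chromosomes", "n_transcripts",
              "transcript_length_bp", "chromosome_length_bp", "n_clusters",
              "n_traits", "generations")
  for (p in counts) {
    if (!is.numeric(cfg[[p]]) || cfg[[p]] < 1)
      stop("invalid config: '", p, "' must be a positive count")
  }
  if (cfg$n_clusters > cfg$n_genotypes)
    stop("invalid config: n_clusters exceeds n_genotypes")
  if (cfg$n_clusters > cfg$n_founders)
    stop("invalid config: n_clusters exceeds n_founders")
  if (cfg$n_founders > cfg$n_genotypes)
    stop("invalid config: n_founders exceeds n_genotypes")
  if (cfg$cluster_fst < 0 || cfg$cluster_fst >= 1)
    stop("invalid config: cluster_fst must be in [0, 1)")
  if (cfg$mean_depth <= 0 || cfg$depth_dispersion < 0)
    stop("invalid config: depth parameters out of range")
  if (any(cfg$founder_maf_beta <= 0) || length(cfg$founder_maf_beta) != 2)
    stop("invalid config: founder_maf_beta must be two positive shapes")
  invisible(TRUE)
}

# Lay transcripts on chromosomes and place SNPs inside them.
# Returns a site table with true proxy-genome coordinates for every SNP.
build_site_map <- function(cfg) {
  tx <- data.frame(
    transcript_id = sprintf("TR%05d", seq_len(cfg$n_transcripts)),
    chrom = sprintf("Chr%02d", sample.int(cfg$n_chromosomes, cfg$n_transcripts,
                                          replace = TRUE)),
    start = sample.int(max(1, cfg$chromosome_length_bp - cfg$transcript_length_bp),
                       cfg$n_transcripts, replace = TRUE),
    strand = sample(c("+", "-"), cfg$n_transcripts, replace = TRUE),
    length = cfg$transcript_length_bp,
    stringsAsFactors = FALSE
  )
  poly <- runif(cfg$n_transcripts) < cfg$prob_polymorphic
  nsnp <- integer(cfg$n_transcripts)
  nsnp[poly] <- 1L + rpois(sum(poly), max(0, cfg$mean_snps_per_transcript - 1))
  idx <- rep(seq_len(cfg$n_transcripts), nsnp)
  offset <- unlist(lapply(nsnp[nsnp > 0L], function(k) {
    sort(sample.int(cfg$transcript_length_bp, min(k, cfg$transcript_length_bp)))
  }))
  sites <- data.frame(
    transcript_id = tx$transcript_id[idx],
    chrom = tx$chrom[idx],
    strand = tx$strand[idx],
    offset = offset,
    stringsAsFactors = FALSE
  )
  tx_start <- tx$start[idx]
  sites$pos <- ifelse(sites$strand == "+",
                      tx_start + sites$offset - 1L,
                      tx_start + cfg$transcript_length_bp - sites$offset)
  sites$site_id <- sprintf("S_%06d", seq_len(nrow(sites)))
  alle <- t(vapply(seq_len(nrow(sites)),
                   function(i) sample(c("A", "C", "G", "T"), 2),
                   character(2)))
  sites$ref <- alle[, 1]
  sites$var <- alle[, 2]
  list(transcripts = tx, sites = sites)
}

# One gamete from a phased parent: Poisson(1) crossovers per chromosome,
# uniform breakpoints, random starting haplotype.
make_gamete <- function(hap1, hap2, chrom_of, pos, chrom_len) {
  gam <- integer(length(hap1))
  for (ch in unique(chrom_of)) {
    sel <- which(chrom_of == ch)
    k <- rpois(1, 1)
    start <- sample.int(2, 1)
    if (k == 0) {
      phase <- rep(start, length(sel))
    } else {
      bp <- sort(runif(k, 0, chrom_len))
      seg <- findInterval(pos[sel], bp)
      phase <- 1 + (start - 1 + seg) %% 2
    }
    gam[sel] <- ifelse(phase == 1, hap1[sel], hap2[sel])
  }
  gam
}

#' Simulate an open-pollinated breeding collection
#'
#' Generates founders with Beta-distributed allele frequencies (optionally
#' diverged per cluster), produces offspring by open pollination (mother
#' drawn from the cluster, father drawn uniformly from the recorded
#' candidate fathers), and emits allele-specific read counts, a normalized
#' expression matrix and a phenotype table, all tied to a known truth.
#'
#' @param config a [sim_config()].
#' @param reads if `FALSE`, skip the (comparatively expensive) read-count
#'   table; `$depths` is then `NULL`.
#'
#' @return A list with elements `truth` (class `sim_truth`: pedigree,
#'   phased haplotypes, true genotype matrix, causal SNPs/GEMs, cluster
#'   assignment, anchor table, config), `depths` (allele depth table),
#'   `expression` (transcripts x genotypes FPKM-like matrix) and
#'   `phenotypes` (genotypes x traits data.frame of LS-mean style values).
#' @export
simulate_collection <- function(config = sim_config(), reads = TRUE) {
  cfg <- config
  validate_sim_config(cfg)
  set.seed(cfg$seed)

  map <- build_site_map(cfg)
  sites <- map$sites
  S <- nrow(sites)
  if (S == 0) stop("no polymorphic transcripts simulated; raise prob_polymorphic")

  p0 <- pmin(pmax(rbeta(S, cfg$founder_maf_beta[1], cfg$founder_maf_beta[2]),
                  1e-3), 1 - 1e-3)
  cluster_freq <- matrix(p0, nrow = cfg$n_clusters, ncol = S, byrow = TRUE)
  if (cfg$cluster_fst > 0) {
    f <- cfg$cluster_fst
    for (cl in seq_len(cfg$n_clusters)) {
      cluster_freq[cl, ] <- rbeta(S, p0 * (1 - f) / f, (1 - p0) * (1 - f) / f)
    }
  }

  ids <- sprintf("G%03d", seq_len(cfg$n_genotypes))
  hap1 <- matrix(0L, cfg$n_genotypes, S, dimnames = list(ids, sites$site_id))
  hap2 <- hap1
  cluster_of <- integer(cfg$n_genotypes)
  founder_cluster <- sort(rep_len(seq_len(cfg$n_clusters), cfg$n_founders))
  for (i in seq_len(cfg$n_founders)) {
    cl <- founder_cluster[i]
    hap1[i, ] <- rbinom(S, 1, cluster_freq[cl, ])
    hap2[i, ] <- rbinom(S, 1, cluster_freq[cl, ])
    cluster_of[i] <- cl
  }

  pedigree <- data.frame(
    child = ids, mother = NA_character_, father = NA_character_,
    candidate_fathers = NA_character_, generation = 0L,
    stringsAsFactors = FALSE
  )

  n_off <- cfg$n_genotypes - cfg$n_founders
  if (n_off > 0) {
    wave <- sort(rep_len(seq_len(cfg$generations), n_off))
    chrom_of <- sites$chrom
    pos <- sites$pos
    for (o in seq_len(n_off)) {
      i <- cfg$n_founders + o
      cl <- sample.int(cfg$n_clusters, 1)
      # parents must already exist: founders plus offspring of earlier waves
      avail <- which(cluster_of[seq_len(i - 1)] == cl &
                       pedigree$generation[seq_len(i - 1)] < wave[o])
      if (length(avail) == 0) avail <- which(cluster_of[seq_len(i - 1)] == cl)
      mother <- avail[sample.int(length(avail), 1)]
      others <- setdiff(avail, mother)
      cand <- if (length(others) > 0) {
        others[sample.int(length(others), min(cfg$n_candidate_fathers, length(others)))]
      } else mother
      father <- if (runif(1) < cfg$selfing_rate || length(others) == 0) {
        mother
      } else cand[sample.int(length(cand), 1)]
      hap1[i, ] <- make_gamete(hap1[mother, ], hap2[mother, ], chrom_of, pos,
                               cfg$chromosome_length_bp)
      hap2[i, ] <- make_gamete(hap1[father, ], hap2[father, ], chrom_of, pos,
                               cfg$chromosome_length_bp)
      cluster_of[i] <- cl
      pedigree$mother[i] <- ids[mother]
      pedigree$father[i] <- ids[father]
      pedigree$candidate_fathers[i] <- paste(unique(ids[sort(c(cand, father))]),
                                             collapse = ",")
      pedigree$generation[i] <- wave[o]
    }
  }

  dosage <- hap1 + hap2
  true_g <- genotype_matrix(
    dosage,
    data.frame(site_id = sites$site_id, transcript_id = sites$transcript_id,
               offset = sites$offset, ref = sites$ref, var = sites$var,
               chrom = sites$chrom, pos = sites$pos, stringsAsFactors = FALSE),
    samples = ids
  )

  # ---- phenotypes -----------------------------------------------------
  traits <- sprintf("trait%02d", seq_len(cfg$n_traits))
  pheno <- matrix(NA_real_, cfg$n_genotypes, cfg$n_traits,
                  dimnames = list(ids, traits))
  causal_snps <- list()
  poly_sites <- which(site_maf(true_g) > 0)
  for (tt in seq_len(cfg$n_traits)) {
    mu <- rnorm(1, 10, 3)
    g_snp <- rep(0, cfg$n_genotypes)
    if (cfg$n_trait_snps > 0 && length(poly_sites) > 0) {
      picks <- poly_sites[sample.int(length(poly_sites),
                                     min(cfg$n_trait_snps, length(poly_sites)))]
      eff <- rep_len(cfg$snp_effect_sizes, length(picks))
      for (k in seq_along(picks)) {
        g_snp <- g_snp + eff[k] * (dosage[, picks[k]] - mean(dosage[, picks[k]]))
      }
      causal_snps[[tt]] <- data.frame(trait = traits[tt],
                                      site_id = sites$site_id[picks],
                                      effect = eff, stringsAsFactors = FALSE)
    }
    g_poly <- rep(0, cfg$n_genotypes)
    if (length(poly_sites) > 1) {
      bg <- poly_sites[sample.int(length(poly_sites),
                                  min(200, length(poly_sites)))]
      u <- rnorm(length(bg))
      raw <- scale(dosage[, bg, drop = FALSE]) %*% u
      raw[is.na(raw)] <- 0
      if (sd(raw) > 0) {
        target_sd <- if (sd(g_snp) > 0) sd(g_snp) else 1
        g_poly <- as.numeric(raw) / sd(raw) * target_sd
      }
    }
    g <- g_snp + g_poly
    if (cfg$heritability == 0 || sd(g) == 0) {
      pheno[, tt] <- mu + rnorm(cfg$n_genotypes)
    } else if (cfg$heritability == 1) {
      pheno[, tt] <- mu + g
    } else {
      sigma_e <- sd(g) * sqrt((1 - cfg$heritability) / cfg$heritability)
      pheno[, tt] <- mu + g + rnorm(cfg$n_genotypes, 0, sigma_e)
    }
  }
  causal_snps <- if (length(causal_snps)) do.call(rbind, causal_snps) else
    data.frame(trait = character(), site_id = character(), effect = numeric())

  # ---- expression -----------------------------------------------------
  tx <- map$transcripts
  mu_t <- rnorm(cfg$n_transcripts, cfg$expr_mean_log2, cfg$expr_sd_log2)
  log2x <- matrix(rnorm(cfg$n_transcripts * cfg$n_genotypes, 0, cfg$expr_resid_sd),
                  cfg$n_transcripts, cfg$n_genotypes) + mu_t
  n_cl_tx <- round(cfg$prop_cluster_transcripts * cfg$n_transcripts)
  cl_tx <- sample.int(cfg$n_transcripts, n_cl_tx)
  if (n_cl_tx > 0) {
    shifts <- matrix(rnorm(n_cl_tx * cfg$n_clusters, 0, cfg$expr_cluster_sd),
                     n_cl_tx, cfg$n_clusters)
    log2x[cl_tx, ] <- log2x[cl_tx, ] + shifts[, cluster_of]
  }
  expr <- 2^log2x
  expr[expr < 0.5] <- 0

  causal_gems <- list()
  free_tx <- setdiff(seq_len(cfg$n_transcripts), cl_tx)
  for (tt in seq_len(cfg$n_traits)) {
    if (cfg$n_trait_gems == 0 || length(free_tx) == 0) break
    picks <- free_tx[sample.int(length(free_tx),
                                min(cfg$n_trait_gems, length(free_tx)))]
    free_tx <- setdiff(free_tx, picks)
    for (tr in picks) {
      intercept <- 20
      expr[tr, ] <- pmax(0, intercept + cfg$gem_slope * (pheno[, tt] - mean(pheno[, tt])) +
                           rnorm(cfg$n_genotypes, 0, cfg$gem_noise_sd))
    }
    causal_gems[[tt]] <- data.frame(trait = traits[tt],
                                    transcript_id = tx$transcript_id[picks],
                                    slope = cfg$gem_slope, stringsAsFactors = FALSE)
  }
  causal_gems <- if (length(causal_gems)) do.call(rbind, causal_gems) else
    data.frame(trait = character(), transcript_id = character(), slope = numeric())
  dimnames(expr) <- list(tx$transcript_id, ids)

  # ---- anchors --------------------------------------------------------
  n_anch <- round(cfg$anchored_fraction * cfg$n_transcripts)
  anch_idx <- sort(sample.int(cfg$n_transcripts, n_anch))
  anchors <- data.frame(
    transcript_id = tx$transcript_id[anch_idx], chrom = tx$chrom[anch_idx],
    start = tx$start[anch_idx], strand = tx$strand[anch_idx],
    transcript_length = tx$length[anch_idx], stringsAsFactors = FALSE
  )

  truth <- structure(list(
    pedigree = pedigree,
    true_genotypes = true_g,
    haplotypes = list(hap1 = hap1, hap2 = hap2),
    causal_snps = causal_snps,
    causal_gems = causal_gems,
    cluster_assignment = stats::setNames(cluster_of, ids),
    anchor_table = anchors,
    transcripts = tx,
    config = cfg
  ), class = "sim_truth")

  depths <- NULL
  if (reads) {
    depths <- sample_allele_depths(dosage, true_g$sites, cfg,
                                   seed = derive_seed(cfg$seed, 1L))
  }

  list(truth = truth,
       depths = depths,
       expression = expr,
       phenotypes = as.data.frame(pheno))
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %d genotypes, %d SNPs, %d clusters, seed %d\n",
              nrow(x$true_genotypes$dosage), ncol(x$true_genotypes$dosage),
              x$config$n_clusters, x$config$seed))
  invisible(x)
}

# Draw an allele-depth table for the given dosage matrix under the
# configured depth / error / base-quality model.
sample_allele_depths <- function(dosage, sites, cfg, seed = NULL,
                                 replicate_group = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ns <- nrow(dosage); S <- ncol(dosage)
  n <- ns * S
  depth <- if (cfg$depth_dispersion > 0) {
    rnbinom(n, size = 1 / cfg$depth_dispersion, mu = cfg$mean_depth)
  } else {
    rpois(n, cfg$mean_depth)
  }
  f <- as.vector(dosage) / 2
  fe <- f * (1 - cfg$seq_error_rate) + (1 - f) * cfg$seq_error_rate
  var_count <- rbinom(n, depth, fe)
  qual <- round(pmax(1, rnorm(n, cfg$base_quality_mean, cfg$base_quality_sd)), 1)
  out <- data.frame(
    sample = rep(rownames(dosage), times = S),
    site_id = rep(sites$site_id, each = ns),
    transcript_id = rep(sites$transcript_id, each = ns),
    offset = rep(sites$offset, each = ns),
    ref_allele = rep(sites$ref, each = ns),
    var_allele = rep(sites$var, each = ns),
    ref_count = depth - var_count,
    var_count = var_count,
    mean_var_quality = qual,
    stringsAsFactors = FALSE
  )
  if (!is.null(replicate_group)) {
    out$replicate_group <- rep(replicate_group, times = S)
  }
  out
}

#' Biological replicate read counts for chosen genotypes
#'
#' Resamples independent read counts (new depth, error and base-quality
#' draws) for the same underlying genotypes, emulating biological replicates
#' grown from independent seed tubers. Samples are named
#' `<id>_rep<k>` and tagged with a `replicate_group` column equal to the
#' genotype id.
#'
#' @param truth a `sim_truth`.
#' @param ids genotype ids to replicate.
#' @param config a [sim_config()]; depth/error parameters are read from it.
#' @param n_reps replicates per genotype (default 4, the usual control design).
#' @param seed seed for the resampling draws.
#' @return An allele depth table (data.frame) with a `replicate_group` column.
#' @export
make_replicates <- function(truth, ids, config = truth$config, n_reps = 4,
                            seed = derive_seed(config$seed, 2L)) {
  stopifnot(inherits(truth, "sim_truth"))
  if (length(ids) == 0 || n_reps == 0) {
    out <- sample_allele_depths(truth$true_genotypes$dosage[0, , drop = FALSE],
                                truth$true_genotypes$sites, config,
                                replicate_group = character(0))
    return(out)
  }
  missing_ids <- setdiff(ids, rownames(truth$true_genotypes$dosage))
  if (length(missing_ids) > 0) {
    stop("unknown genotype id(s): ", paste(missing_ids, collapse = ", "))
  }
  dose <- truth$true_genotypes$dosage[rep(ids, each = n_reps), , drop = FALSE]
  rownames(dose) <- paste0(rep(ids, each = n_reps), "_rep",
                           rep(seq_len(n_reps), times = length(ids)))
  sample_allele_depths(dose, truth$true_genotypes$sites, config, seed = seed,
                       replicate_group = rep(ids, each = n_reps))
}
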