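#' Run the whole characterization pipeline on a simulated collection
#'
#' Chains the stages end to end -- simulate, call and filter SNPs,
#' diversity and relatedness, population structure (SNP Ward, PCA, GEM
#' Ward), synteny projection with LD decay and haplotype blocks,
#' mixed-model SNP association and GEM association -- writing each stage's
#' tables to `out_dir` stamped with the package version, a config hash and
#' the seed. Stages can be toggled off; later stages fall back to
#' whatever inputs earlier stages produced.
#'
#' @param config a [sim_config()]; its seed drives all randomness.
#' @param out_dir output directory (created if needed); `NULL` skips all
#'   file output.
#' @param stages named logical vector toggling `diversity`, `relatedness`,
#'   `structure`, `ld`, `blocks`, `assoc_snp`, `assoc_gem`.
#' @param k number of clusters for the structure stage (defaults to the
#'   simulated cluster count).
#' @param assoc_traits trait ids to scan with the mixed model (defaults to
#'   the first two traits, to keep the default run light).
#' @return Invisibly, a list with every stage's in-memory results plus a
#'   `log` data.frame of per-stage record counts (the filter-cascade
#'   audit trail).
#' @export
run_pipeline <- function(config = sim_config(),
                         out_dir = NULL,
                         stages = c(diversity = TRUE, relatedness = TRUE,
                                    structure = TRUE, ld = TRUE, blocks = TRUE,
                                    assoc_snp = TRUE, assoc_gem = TRUE),
                         k = config$n_clusters,
                         assoc_traits = NULL) {
  on <- function(name) {
    if (name %in% names(stages)) isTRUE(stages[[name]]) else TRUE
  }
  stamp <- config_stamp(config, config$seed)
  emit <- function(x, name) {
    if (!is.null(out_dir)) write_tsv(x, file.path(out_dir, name), stamp = stamp)
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  log <- list()
  note <- function(stage, what, n) {
    log[[length(log) + 1]] <<- data.frame(stage = stage, metric = what, n = n,
                                          stringsAsFactors = FALSE)
  }

  sim <- simulate_collection(config)
  note("simulate", "genotypes", config$n_genotypes)
  note("simulate", "true_snps", n_sites(sim$truth$true_genotypes))

  discovered <- discover_variants(sim$depths)
  note("call_snps", "discovered_sites", length(discovered))
  called <- call_genotypes(sim$depths, discovered)
  filtered <- filter_sites(called)
  note("call_snps", "filtered_sites", n_sites(filtered))
  summaries <- site_and_sample_summaries(filtered)
  if (!is.null(out_dir)) {
    write_vcf(filtered, file.path(out_dir, "genotypes.vcf"))
    write_config(config, file.path(out_dir, "config.json"))
  }
  emit(summaries$sites, "site_summary.tsv")
  emit(summaries$samples, "sample_summary.tsv")

  results <- list(truth = sim$truth, genotypes = filtered,
                  summaries = summaries)

  if (on("diversity")) {
    div <- diversity(filtered)
    f <- inbreeding_f(filtered)
    fcor <- f_trait_correlations(f, sim$phenotypes)
    results$diversity <- div
    results$inbreeding <- f
    results$f_trait <- fcor
    emit(data.frame(pi = div$pi, theta = div$theta, S = div$S,
                    tajimas_d = div$tajimas_d), "diversity.tsv")
    emit(f, "inbreeding.tsv")
    emit(fcor, "f_trait_correlations.tsv")
    note("diversity", "segregating_sites", div$S)
  }

  dist <- NULL
  if (on("relatedness") || on("structure")) {
    dist <- ibs_distance(filtered)
  }
  if (on("relatedness")) {
    ibd <- classify_relationships(ibd_estimates(filtered))
    results$ibd <- ibd
    emit(ibd, "ibd_pairs.tsv")
    emit(as.data.frame(dist), "ibs_distance.tsv")
    note("relatedness", "pairs", nrow(ibd))
  }

  if (on("structure")) {
    snp_cl <- snp_ward_clustering(dist, k = k)
    pca <- snp_pca(filtered, n_components = min(10, n_samples(filtered) - 1))
    gem_cl <- gem_clustering(sim$expression, top_n = min(1000, nrow(sim$expression)),
                             k = k)
    results$snp_clusters <- snp_cl
    results$pca <- pca
    results$gem_clusters <- gem_cl
    results$concordance <- list(
      snp = cluster_concordance(snp_cl, sim$truth$pedigree,
                                sim$truth$cluster_assignment),
      gem = cluster_concordance(gem_cl, sim$truth$pedigree,
                                sim$truth$cluster_assignment)
    )
    emit(data.frame(sample = names(snp_cl$assignments),
                    snp_cluster = snp_cl$assignments,
                    gem_cluster = gem_cl$assignments[names(snp_cl$assignments)]),
         "clusters.tsv")
    emit(as.data.frame(pca$scores), "pca_scores.tsv")
    note("structure", "clusters", k)
  }

  placed <- NULL
  if (on("ld") || on("blocks")) {
    placed <- project_snps(filtered, sim$truth$anchor_table)
    note("ld", "placed_sites", sum(!is.na(placed$sites$pos)))
  }
  if (on("ld")) {
    bg <- background_ld(placed, n_pairs = 2e4, seed = derive_seed(config$seed, 3L))
    pr <- within_chromosome_pairs(placed, max_dist_bp = 2e6, max_pairs = 5e4,
                                  seed = derive_seed(config$seed, 4L))
    ld <- pairwise_r2(placed, pr)
    ld$chrom <- placed$sites$chrom[match(ld$site_a, placed$sites$site_id)]
    decay <- ld_decay(ld, bin_width_kb = 50,
                      thresholds = c(0.1, 0.2, background = as.numeric(bg)))
    results$background_ld <- bg
    results$ld_pairs <- ld
    results$ld_decay <- decay
    emit(ld[, c("site_a", "site_b", "r2", "dprime", "dist_bp")], "ld_pairs.tsv")
    emit(decay$table, "ld_decay.tsv")
    note("ld", "within_chrom_pairs", nrow(ld))
  }
  if (on("blocks")) {
    blocks <- haplotype_blocks(placed)
    results$blocks <- blocks
    emit(blocks, "haplotype_blocks.tsv")
    note("blocks", "haplotype_blocks", nrow(blocks))
  }

  if (on("assoc_snp")) {
    K <- grm(filtered)
    traits <- assoc_traits %||% utils::head(colnames(sim$phenotypes), 2)
    scans <- lapply(traits, function(tr) {
      y <- stats::setNames(sim$phenotypes[[tr]], rownames(sim$phenotypes))
      res <- snp_scan(filtered, y, K = K)
      res$trait <- tr
      res
    })
    scan_tab <- do.call(rbind, scans)
    results$kinship <- K
    results$snp_assoc <- scan_tab
    results$qq <- qq_diagnostics(scan_tab$p_value)
    emit(scan_tab, "snp_associations.tsv")
    note("assoc_snp", "tests", nrow(scan_tab))
  }

  if (on("assoc_gem")) {
    gems <- gem_scan(sim$expression, sim$phenotypes)
    results$gem_assoc <- gems
    emit(gems$results, "gem_associations.tsv")
    emit(gems$passing, "gem_associations_passing.tsv")
    note("assoc_gem", "passing", nrow(gems$passing))
  }

  results$log <- do.call(rbind, log)
  emit(results$log, "pipeline_log.tsv")
  invisible(results)
}

# Within-chromosome site-index pairs up to a distance cap, subsampled to
# max_pairs with a fixed seed when necessary.
within_chromosome_pairs <- function(g, max_dist_bp = 2e6, max_pairs = 5e4,
                                    seed = 1) {
  placed <- which(!is.na(g$sites$chrom) & !is.na(g$sites$pos))
  pa <- pb <- integer(0)
  for (ch in unique(g$sites$chrom[placed])) {
    idx <- placed[g$sites$chrom[placed] == ch]
    idx <- idx[order(g$sites$pos[idx])]
    pos <- g$sites$pos[idx]
    for (j in seq_along(idx)[-1]) {
      ks <- which(pos[j] - pos[seq_len(j - 1)] <= max_dist_bp)
      pa <- c(pa, idx[ks]); pb <- c(pb, rep(idx[j], length(ks)))
    }
  }
  pairs <- cbind(pa, pb)
  if (nrow(pairs) > max_pairs) {
    set.seed(seed)
    pairs <- pairs[sample.int(nrow(pairs), max_pairs), , drop = FALSE]
  }
  pairs
}
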