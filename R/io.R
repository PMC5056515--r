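# File formats. TSV is the interchange format for tables; genotypes travel
# as VCF v4.2 with GT calls and the source transcript carried in INFO.

#' Write a genotype matrix as VCF v4.2
#'
#' Sites are written in transcript space: CHROM is the source transcript id
#' (or `"."`), POS the 1-based offset within it. Projected proxy-genome
#' coordinates, when present, travel in the INFO fields `PCHR`/`PPOS`
#' alongside `TID` (transcript) and `OFF` (offset), so the matrix
#' round-trips losslessly. Genotypes are unphased GT calls with `./.` for
#' missing.
#'
#' @param g a [genotype_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "geno_matrix"))
  s <- g$sites
  info <- paste0(
    "TID=", ifelse(is.na(s$transcript_id), ".", s$transcript_id),
    ";OFF=", ifelse(is.na(s$offset), ".", s$offset),
    ifelse(is.na(s$chrom), "", paste0(";PCHR=", s$chrom)),
    ifelse(is.na(s$pos), "", paste0(";PPOS=", s$pos))
  )
  gt <- matrix(c("0/0", "0/1", "1/1")[g$dosage + 1L], nrow = nrow(g$dosage))
  gt[is.na(g$dosage)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=snpgem-%s", as.character(utils::packageVersion("snpgem"))),
    "##INFO=<ID=TID,Number=1,Type=String,Description=\"Source transcript id\">",
    "##INFO=<ID=OFF,Number=1,Type=Integer,Description=\"1-based offset within transcript\">",
    "##INFO=<ID=PCHR,Number=1,Type=String,Description=\"Projected chromosome\">",
    "##INFO=<ID=PPOS,Number=1,Type=Integer,Description=\"Projected 1-based position\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids(g)), collapse = "\t")
  )
  body <- paste(
    ifelse(is.na(s$transcript_id), ".", s$transcript_id),
    ifelse(is.na(s$offset), 1L, s$offset),
    s$site_id, s$ref, s$var, ".", "PASS", info, "GT",
    apply(t(gt), 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a genotype matrix from VCF
#'
#' Parses with `VariantAnnotation::readVcf`. Only biallelic SNP records are
#' kept; multi-allelic records are skipped with a warning. Missing GT
#' (`./.`) becomes a missing dosage.
#'
#' @param path VCF file (as produced by [write_vcf()] or any VCF v4.2 with
#'   GT calls).
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_vcf requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  alt <- VariantAnnotation::alt(vcf)
  multi <- S4Vectors::elementNROWS(alt) != 1
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped")
    vcf <- vcf[!multi]
    alt <- alt[!multi]
  }
  gt <- VariantAnnotation::geno(vcf)$GT
  dose <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt),
                 dimnames = list(colnames(gt), rownames(gt)))
  map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
           "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L)
  dose[] <- map[t(gt)]
  info <- VariantAnnotation::info(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  unpack <- function(x) {
    if (is.null(x)) return(rep(NA, nrow(vcf)))
    x <- as.vector(x)
    x[x %in% "."] <- NA
    x
  }
  sites <- data.frame(
    site_id = names(rr),
    transcript_id = as.character(unpack(info$TID)),
    offset = as.integer(unpack(info$OFF)),
    ref = as.character(VariantAnnotation::ref(vcf)),
    var = as.character(unlist(alt)),
    chrom = as.character(unpack(info$PCHR)),
    pos = as.integer(unpack(info$PPOS)),
    stringsAsFactors = FALSE
  )
  genotype_matrix(dose, sites)
}

#' Write / read a TSV table
#'
#' Thin wrappers over `data.table::fwrite` / `fread` with an optional
#' comment header naming the package version and a config fingerprint, so
#' that every emitted table is traceable to the run that produced it.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @param stamp optional character vector of `# key: value` comment lines.
#' @return `path` (write) / data.frame (read), invisibly for the writer.
#' @export
write_tsv <- function(x, path, stamp = NULL) {
  if (!is.null(stamp)) {
    writeLines(paste0("# ", stamp), path)
    data.table::fwrite(x, path, sep = "\t", append = TRUE, col.names = TRUE)
  } else {
    data.table::fwrite(x, path, sep = "\t")
  }
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "# ")]
  as.data.frame(data.table::fread(text = lines, sep = "\t", header = TRUE))
}

#' Serialize / restore a run configuration
#'
#' Configurations round-trip losslessly through JSON.
#'
#' @param config a [sim_config()] or plain list of stage parameters.
#' @param path JSON file path.
#' @return For the reader, the restored configuration.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (all(c("n_founders", "mean_depth", "seed") %in% names(cfg))) {
    cfg <- do.call(sim_config, cfg)
  }
  cfg
}

config_stamp <- function(config, seed) {
  json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  c(sprintf("snpgem %s", as.character(utils::packageVersion("snpgem"))),
    sprintf("config_hash: %s", fnv1a_hash(as.character(json))),
    sprintf("seed: %s", seed))
}
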