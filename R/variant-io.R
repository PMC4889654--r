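#' Read a VCF into a genotype matrix
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) into a [genotype_matrix()].
#' Genotypes are converted to ALT-allele dosages; any genotype containing a
#' missing allele (including half-calls such as `0/.`) becomes `NA`. Per-
#' genotype `DP` is captured when present. Multi-allelic records and indels
#' are retained but flagged (`sites$biallelic_snp == FALSE`) so that
#' [filter_sites()] can remove them. Contig lengths are taken from
#' `##contig` header lines when available.
#'
#' @param path path to an (uncompressed or bgzipped) VCF file.
#' @return a `genotype_matrix`.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  head_lines <- readLines(path, n = 500L, warn = FALSE)
  hdr <- grep("^#CHROM\t", head_lines)
  if (!length(hdr)) {
    # maybe the header is deeper; do a cheap full scan of '#' lines
    con <- file(path, "r"); on.exit(close(con))
    ln <- 0L; found <- FALSE
    repeat {
      l <- readLines(con, n = 1L, warn = FALSE); ln <- ln + 1L
      if (!length(l)) break
      if (grepl("^#CHROM\t", l)) { found <- TRUE; break }
      if (!grepl("^#", l)) break
    }
    if (!found)
      stop("malformed VCF (no #CHROM header found by line ", ln, "): ", path)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  dp <- NULL
  if (ncol(vcf@gt) >= 1L &&
      any(grepl("(^|:)DP(:|$)", unique(vcf@gt[, "FORMAT"]))))
    dp <- suppressWarnings(
      vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))

  ref <- fix$REF; alt <- fix$ALT
  single_base <- function(x) !is.na(x) & nchar(x) == 1L &
    toupper(x) %in% c("A", "C", "G", "T")
  biallelic <- single_base(ref) & single_base(alt) & !grepl(",", alt)

  # dosage lookup over the (few) distinct genotype strings
  dosage_of <- function(g) {
    if (is.na(g) || g == ".") return(NA_integer_)
    al <- strsplit(g, "[/|]", perl = TRUE)[[1L]]
    if (any(al == ".")) return(NA_integer_)
    sum(al != "0")
  }
  u <- unique(as.vector(gt_raw))
  map <- vapply(u, dosage_of, integer(1))
  geno <- matrix(map[match(as.vector(gt_raw), u)],
                 nrow = nrow(gt_raw), ncol = ncol(gt_raw))
  # vcfR returns variants x samples; we want samples x sites
  geno <- t(geno)
  if (!is.null(dp)) dp <- t(dp)

  sites <- data.frame(contig = fix$CHROM, pos = as.numeric(fix$POS),
                      ref = ref, alt = alt, biallelic_snp = biallelic,
                      stringsAsFactors = FALSE)
  contig_lengths <- NULL
  meta <- vcf@meta
  ctg <- grep("^##contig=", meta, value = TRUE)
  if (length(ctg)) {
    ids <- sub('.*ID=([^,>]+).*', '\\1', ctg)
    lens <- suppressWarnings(as.numeric(sub('.*length=([0-9]+).*', '\\1', ctg)))
    if (!all(is.na(lens))) contig_lengths <- stats::setNames(lens, ids)
  }
  genotype_matrix(geno, sites, colnames(gt_raw), depth = dp,
                  contig_lengths = contig_lengths)
}

#' Write a genotype matrix to a VCF file
#'
#' Emits a minimal VCF 4.2 with `GT` (and `DP` when depth is present) per
#' genotype, missing dosages as `./.`, and `##contig` lines carrying contig
#' lengths when known. Output is deterministic: identical input produces a
#' byte-identical file.
#'
#' @param gm a `genotype_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot open for writing: ", path)
  on.exit(close(con))
  lines <- c("##fileformat=VCFv4.2",
             "##source=ldscreen")
  ctgs <- unique(gm$sites$contig)
  for (ctg in ctgs) {
    len <- gm$contig_lengths[ctg]
    lines <- c(lines, if (!is.null(gm$contig_lengths) && !is.na(len))
      sprintf("##contig=<ID=%s,length=%d>", ctg, as.integer(len))
      else sprintf("##contig=<ID=%s>", ctg))
  }
  lines <- c(lines,
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  has_dp <- !is.null(gm$depth)
  if (has_dp)
    lines <- c(lines,
      '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read Depth">')
  lines <- c(lines, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                            "FILTER", "INFO", "FORMAT", gm$sample_ids),
                          collapse = "\t"))
  writeLines(lines, con)

  gt_str <- c("0/0", "0/1", "1/1")
  S <- n_sites(gm)
  for (j in seq_len(S)) {
    d <- gm$geno[, j]
    g <- ifelse(is.na(d), "./.", gt_str[d + 1L])
    if (has_dp) {
      dp <- gm$depth[, j]
      g <- paste0(g, ":", ifelse(is.na(dp), ".", as.character(dp)))
    }
    writeLines(paste(c(gm$sites$contig[j], format(gm$sites$pos[j], scientific = FALSE),
                       ".", gm$sites$ref[j], gm$sites$alt[j], ".", "PASS", ".",
                       if (has_dp) "GT:DP" else "GT", g),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Filtering thresholds for the SNP cleaning cascade
#'
#' Defaults reproduce a standard ddRAD cleaning recipe: per-genotype depth
#' must exceed 7 reads (`DP > 7`, strict), a site must be called in at least
#' 80% of samples and have under 30% missing data, minor allele frequency
#' must exceed 0.05 (strict), and only biallelic SNPs are kept.
#'
#' @param min_genotype_depth genotypes with depth `<=` this are masked.
#' @param max_site_missing_frac sites with missing fraction `>=` this are
#'   dropped.
#' @param min_site_call_rate sites called in fewer than this fraction of
#'   samples are dropped.
#' @param min_sample_call_rate samples called at fewer than this fraction of
#'   sites are dropped.
#' @param maf_min sites with minor allele frequency `<=` this are dropped.
#' @param biallelic_only drop indels and multi-allelic records.
#' @return a `filter_config` list.
#' @export
filter_config <- function(min_genotype_depth = 7,
                          max_site_missing_frac = 0.30,
                          min_site_call_rate = 0.80,
                          min_sample_call_rate = 0.80,
                          maf_min = 0.05,
                          biallelic_only = TRUE) {
  fr <- c(max_site_missing_frac, min_site_call_rate,
          min_sample_call_rate, maf_min)
  if (any(fr < 0) || any(fr > 1)) stop("fractions must lie in [0, 1]")
  structure(list(min_genotype_depth = min_genotype_depth,
                 max_site_missing_frac = max_site_missing_frac,
                 min_site_call_rate = min_site_call_rate,
                 min_sample_call_rate = min_sample_call_rate,
                 maf_min = maf_min,
                 biallelic_only = isTRUE(biallelic_only)),
            class = "filter_config")
}

#' Mask genotypes with insufficient read depth
#'
#' Sets genotypes with depth `<= min_genotype_depth` to missing (a depth-8
#' genotype is kept, depth-7 is masked). Non-masked dosages are never
#' altered; genotypes with missing depth are masked conservatively.
#'
#' @param gm a `genotype_matrix` with depth information.
#' @param min_genotype_depth strict lower bound on depth (default 7).
#' @return the masked `genotype_matrix`.
#' @export
mask_low_depth <- function(gm, min_genotype_depth = 7) {
  if (is.null(gm$depth))
    stop("genotype matrix carries no depth field; cannot apply depth mask")
  low <- is.na(gm$depth) | gm$depth <= min_genotype_depth
  gm$geno[low] <- NA_integer_
  gm
}

#' Filter sites on biallelic status, call rate, missingness and MAF
#'
#' Drops (in site order, which is preserved): non-biallelic/indel records
#' when `cfg$biallelic_only`; sites with call rate `< min_site_call_rate` or
#' missing fraction `>= max_site_missing_frac`; and sites with MAF
#' `<= maf_min` computed over non-missing calls. Applying the filter twice
#' gives the same result as applying it once.
#'
#' @param gm a `genotype_matrix`.
#' @param cfg a [filter_config()].
#' @return the filtered `genotype_matrix` (empty, with a warning, if no site
#'   survives).
#' @export
filter_sites <- function(gm, cfg = filter_config()) {
  if (n_sites(gm) == 0L) return(gm)
  ss <- site_summary(gm)
  keep <- rep(TRUE, n_sites(gm))
  if (cfg$biallelic_only) keep <- keep & gm$sites$biallelic_snp
  keep <- keep & ss$call_rate >= cfg$min_site_call_rate
  keep <- keep & ss$missing_frac < cfg$max_site_missing_frac
  keep <- keep & !is.na(ss$maf) & ss$maf > cfg$maf_min
  if (!any(keep)) warning("all sites removed by site filters")
  gm_subset(gm, sites = keep)
}

#' Remove low-call-rate samples, then re-drop dead sites
#'
#' Samples genotyped at fewer than `min_sample_call_rate` of sites are
#' removed ("at least 80%" keeps a sample at exactly 0.80). Sites that were
#' polymorphic only in the removed samples — i.e. are monomorphic or fully
#' missing in the survivors — are then dropped as well.
#'
#' @param gm a `genotype_matrix`.
#' @param min_sample_call_rate inclusive lower bound (default 0.80).
#' @return the filtered `genotype_matrix`.
#' @export
filter_samples <- function(gm, min_sample_call_rate = 0.80) {
  keep <- sample_call_rate(gm) >= min_sample_call_rate
  out <- gm_subset(gm, samples = keep)
  if (all(keep)) return(out)
  ss <- site_summary(out)
  poly <- !is.na(ss$maf) & ss$maf > 0
  gm_subset(out, sites = poly)
}

#' Run the full SNP filtering cascade
#'
#' Order: depth mask (when depth is present) -> site filters -> sample
#' filter -> re-drop sites left monomorphic. The order matters; this is the
#' sequence in which the thresholds are conventionally applied to ddRAD
#' genotype data.
#'
#' @param gm a `genotype_matrix`.
#' @param cfg a [filter_config()].
#' @param verbose print a per-stage summary.
#' @return the filtered `genotype_matrix`, with an attribute `"filter_log"`
#'   (data frame of per-stage sample/site counts).
#' @export
filter_cascade <- function(gm, cfg = filter_config(), verbose = FALSE) {
  log <- data.frame(stage = "input", n_samples = n_samples(gm),
                    n_sites = n_sites(gm))
  if (!is.null(gm$depth) && !is.null(cfg$min_genotype_depth)) {
    gm <- mask_low_depth(gm, cfg$min_genotype_depth)
    log <- rbind(log, data.frame(stage = "depth_mask",
                                 n_samples = n_samples(gm),
                                 n_sites = n_sites(gm)))
  }
  gm <- filter_sites(gm, cfg)
  log <- rbind(log, data.frame(stage = "site_filters",
                               n_samples = n_samples(gm),
                               n_sites = n_sites(gm)))
  gm <- filter_samples(gm, cfg$min_sample_call_rate)
  log <- rbind(log, data.frame(stage = "sample_filter",
                               n_samples = n_samples(gm),
                               n_sites = n_sites(gm)))
  if (verbose) print(log)
  attr(gm, "filter_log") <- log
  gm
}
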