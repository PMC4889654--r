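#' Genotype matrix container
#'
#' Holds biallelic SNP genotypes as allele dosages (count of ALT alleles,
#' 0/1/2, `NA` = missing) for a set of samples at a set of sites, together
#' with site coordinates and, optionally, per-genotype read depth and contig
#' lengths. This is the object every filtering and statistics function in
#' the package operates on.
#'
#' @param geno integer matrix, samples x sites, values in `{0,1,2,NA}`.
#' @param sites data frame with columns `contig`, `pos` (1-based bp),
#'   `ref`, `alt`, and logical `biallelic_snp`. Positions must be strictly
#'   increasing within each contig.
#' @param sample_ids character vector, one per row of `geno`.
#' @param depth optional integer matrix of read depths, same shape as `geno`.
#' @param contig_lengths optional named numeric vector of contig lengths (bp).
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, sites, sample_ids, depth = NULL,
                            contig_lengths = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  stopifnot(is.data.frame(sites),
            all(c("contig", "pos") %in% names(sites)),
            nrow(sites) == ncol(geno),
            length(sample_ids) == nrow(geno))
  if (is.null(sites$ref)) sites$ref <- "A"
  if (is.null(sites$alt)) sites$alt <- "T"
  if (is.null(sites$biallelic_snp)) sites$biallelic_snp <- TRUE
  sites$contig <- as.character(sites$contig)
  bad <- geno[!is.na(geno)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("dosages must lie in {0, 1, 2, NA}")
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    stopifnot(all(dim(depth) == dim(geno)))
  }
  # enforce coordinate order within contigs
  ord <- order(match(sites$contig, unique(sites$contig)), sites$pos)
  if (any(ord != seq_len(nrow(sites)))) {
    sites <- sites[ord, , drop = FALSE]
    geno <- geno[, ord, drop = FALSE]
    if (!is.null(depth)) depth <- depth[, ord, drop = FALSE]
  }
  for (ctg in unique(sites$contig)) {
    p <- sites$pos[sites$contig == ctg]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within contig ", ctg)
    if (any(p < 1)) stop("positions are 1-based and must be >= 1")
  }
  rownames(sites) <- NULL
  dimnames(geno) <- list(sample_ids, NULL)
  structure(list(sample_ids = as.character(sample_ids), sites = sites,
                 geno = geno, depth = depth,
                 contig_lengths = contig_lengths),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", n_samples(x), "samples x", n_sites(x), "sites on",
      length(unique(x$sites$contig)), "contig(s);",
      if (is.null(x$depth)) "no depth" else "with depth", "\n")
  mr <- mean(is.na(x$geno))
  cat(sprintf("  missing genotypes: %.2f%%\n", 100 * mr))
  invisible(x)
}

#' Number of samples / sites in a genotype matrix
#' @param gm a `genotype_matrix`.
#' @return integer count.
#' @export
n_samples <- function(gm) nrow(gm$geno)

#' @rdname n_samples
#' @export
n_sites <- function(gm) ncol(gm$geno)

#' Subset a genotype matrix by samples and/or sites
#'
#' @param gm a `genotype_matrix`.
#' @param samples logical/integer index over samples (default: all).
#' @param sites logical/integer index over sites (default: all).
#' @return the subsetted `genotype_matrix`; site order is preserved.
#' @export
gm_subset <- function(gm, samples = NULL, sites = NULL) {
  if (is.null(samples)) samples <- seq_len(n_samples(gm))
  if (is.null(sites)) sites <- seq_len(n_sites(gm))
  genotype_matrix(gm$geno[samples, sites, drop = FALSE],
                  gm$sites[sites, , drop = FALSE],
                  gm$sample_ids[samples],
                  depth = if (!is.null(gm$depth))
                    gm$depth[samples, sites, drop = FALSE],
                  contig_lengths = gm$contig_lengths)
}

#' Per-site summaries: call rate, missing fraction, minor allele frequency
#'
#' MAF is computed over non-missing genotypes only; a site with no calls has
#' `NA` frequency.
#'
#' @param gm a `genotype_matrix`.
#' @return data frame with `contig`, `pos`, `n_called`, `call_rate`,
#'   `missing_frac`, `alt_freq`, `maf`.
#' @export
site_summary <- function(gm) {
  called <- !is.na(gm$geno)
  n_called <- colSums(called)
  alt <- colSums(gm$geno, na.rm = TRUE)
  p <- ifelse(n_called > 0, alt / (2 * n_called), NA_real_)
  data.frame(contig = gm$sites$contig, pos = gm$sites$pos,
             n_called = n_called,
             call_rate = n_called / n_samples(gm),
             missing_frac = 1 - n_called / n_samples(gm),
             alt_freq = p,
             maf = pmin(p, 1 - p))
}

#' Per-sample call rates
#' @param gm a `genotype_matrix`.
#' @return named numeric vector of the fraction of sites called per sample.
#' @export
sample_call_rate <- function(gm) {
  r <- rowMeans(!is.na(gm$geno))
  names(r) <- gm$sample_ids
  r
}
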