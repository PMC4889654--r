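#' Read a population map
#'
#' Two-column TSV (sample_id, population) with an optional third phenotype
#' column (e.g. infected/uninfected). No header.
#'
#' @param path path to the TSV file.
#' @return data frame with `sample`, `population` and, when present,
#'   `phenotype`.
#' @export
read_popmap <- function(path) {
  pm <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(pm) < 2) stop("population map needs at least two columns")
  names(pm)[1:2] <- c("sample", "population")
  if (ncol(pm) >= 3) names(pm)[3] <- "phenotype"
  pm
}

pop_vector <- function(gm, popmap) {
  i <- match(gm$sample_ids, popmap$sample)
  if (anyNA(i))
    stop("samples missing from population map: ",
         paste(gm$sample_ids[is.na(i)], collapse = ", "))
  popmap$population[i]
}

#' Observed heterozygosity per individual and per population
#'
#' Per individual: the fraction of non-missing genotypes that are
#' heterozygous. Per population: the mean over its member individuals.
#' Individuals with zero non-missing calls are reported as `NA`.
#'
#' @param gm a `genotype_matrix`.
#' @param popmap optional population map (see [read_popmap()]).
#' @return list with `individual` (named numeric) and, when `popmap` is
#'   given, `population` (named numeric).
#' @export
observed_heterozygosity <- function(gm, popmap = NULL) {
  het <- rowSums(gm$geno == 1L, na.rm = TRUE)
  ncall <- rowSums(!is.na(gm$geno))
  ho <- ifelse(ncall > 0, het / ncall, NA_real_)
  names(ho) <- gm$sample_ids
  out <- list(individual = ho)
  if (!is.null(popmap)) {
    pop <- pop_vector(gm, popmap)
    out$population <- tapply(ho, pop, mean, na.rm = TRUE)
  }
  out
}

# windows are half-open [start, start + w); index floor((pos - 1) / w)
window_frame <- function(gm, window_bp) {
  if (window_bp < 1) stop("window_bp must be >= 1")
  ctgs <- unique(gm$sites$contig)
  lens <- gm$contig_lengths
  if (is.null(lens)) {
    lens <- tapply(gm$sites$pos, gm$sites$contig, max)
    lens <- lens[ctgs]
  } else lens <- lens[ctgs]
  do.call(rbind, lapply(ctgs, function(ctg) {
    L <- lens[[ctg]]
    n_win <- ceiling(L / window_bp)
    start <- (seq_len(n_win) - 1) * window_bp + 1
    data.frame(contig = ctg, start = start,
               end = pmin(start + window_bp - 1, L))
  }))
}

site_window_index <- function(gm, wins, window_bp) {
  key_w <- paste(wins$contig, (wins$start - 1) %/% window_bp)
  key_s <- paste(gm$sites$contig, (gm$sites$pos - 1) %/% window_bp)
  match(key_s, key_w)
}

#' Windowed nucleotide diversity (pi)
#'
#' Per non-overlapping window, pi is the sum over SNPs of the unbiased
#' per-site heterozygosity `2 p (1-p) n / (n-1)` (with `n` the number of
#' non-missing alleles at the site), divided by the window length in bp.
#' Invariant sites contribute zero, so windows without SNPs have pi = 0.
#'
#' @param gm a `genotype_matrix`.
#' @param window_bp window width in bp (default 5000, the usual choice for
#'   whole-genome diversity scans; reduced-representation data are often
#'   summarized at 1000 bp).
#' @return data frame of windows (`contig`, `start`, `end`, `n_snps`,
#'   `value`, `defined`) with attribute `"genome_average"` = total diversity
#'   over total length.
#' @export
nucleotide_diversity <- function(gm, window_bp = 5000) {
  wins <- window_frame(gm, window_bp)
  wi <- site_window_index(gm, wins, window_bp)
  called <- !is.na(gm$geno)
  n_al <- 2 * colSums(called)
  j <- colSums(gm$geno, na.rm = TRUE)
  pi_site <- ifelse(n_al > 1, 2 * (j / n_al) * (1 - j / n_al) *
                      n_al / (n_al - 1), 0)
  segregating <- !is.na(pi_site) & pi_site > 0
  wins$n_snps <- as.vector(table(factor(wi, levels = seq_len(nrow(wins)))))
  sums <- tapply(pi_site, factor(wi, levels = seq_len(nrow(wins))), sum)
  sums[is.na(sums)] <- 0
  len <- wins$end - wins$start + 1
  wins$value <- as.numeric(sums) / len
  wins$defined <- TRUE
  attr(wins, "genome_average") <- sum(as.numeric(sums)) / sum(len)
  rownames(wins) <- NULL
  wins
}

tajima_constants <- function(n) {
  # n = number of sequences (alleles)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Windowed Tajima's D
#'
#' D per non-overlapping window from the 1989 formulas: the constants are
#' computed from the number of sequences (2 x samples, assuming random
#' union of gametes on unphased genotypes), the pairwise-diversity estimator
#' sums per-site `j (n_i - j) / choose(n_i, 2)` over segregating sites using
#' each site's own non-missing allele count, and the Watterson estimator is
#' `S / a1`. Windows with no segregating sites are `defined = FALSE`.
#'
#' Two averages are attached: `"average_all"` counts undefined windows as
#' zero ("regardless of whether they contain SNPs"), `"average_snp"`
#' averages only over windows containing at least one SNP.
#'
#' @param gm a `genotype_matrix` with at least 2 samples (4 sequences).
#' @param window_bp window width in bp (default 1000).
#' @return data frame of windows with `value` = D and `defined`, plus
#'   attributes `"average_all"` and `"average_snp"`.
#' @export
tajimas_d <- function(gm, window_bp = 1000) {
  n_seq <- 2 * n_samples(gm)
  if (n_seq < 4) stop("Tajima's D needs at least 4 sequences")
  k <- tajima_constants(n_seq)
  wins <- window_frame(gm, window_bp)
  wi <- site_window_index(gm, wins, window_bp)

  called <- !is.na(gm$geno)
  n_al <- 2 * colSums(called)
  j <- colSums(gm$geno, na.rm = TRUE)
  seg <- n_al > 1 & j > 0 & j < n_al
  pi_site <- ifelse(seg, j * (n_al - j) / choose(n_al, 2), 0)

  f <- factor(wi, levels = seq_len(nrow(wins)))
  S <- as.vector(tapply(seg, f, sum)); S[is.na(S)] <- 0
  th_pi <- as.vector(tapply(pi_site, f, sum)); th_pi[is.na(th_pi)] <- 0
  wins$n_snps <- S
  th_w <- S / k$a1
  vr <- k$e1 * S + k$e2 * S * (S - 1)
  d <- ifelse(S > 0 & vr > 0, (th_pi - th_w) / sqrt(vr), NA_real_)
  wins$value <- d
  wins$defined <- !is.na(d)
  attr(wins, "average_all") <- mean(ifelse(is.na(d), 0, d))
  attr(wins, "average_snp") <- if (any(wins$defined))
    mean(d[wins$defined]) else NA_real_
  rownames(wins) <- NULL
  wins
}

#' Exact Hardy-Weinberg test from genotype counts
#'
#' Exact p-value by enumerating all heterozygote counts compatible with the
#' observed allele counts (same parity) and summing the probabilities of
#' configurations no more likely than the observed one. Monomorphic sites
#' have p = 1.
#'
#' @param n_aa,n_ab,n_bb genotype counts (hom-ref, het, hom-alt).
#' @return exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  na_ <- 2 * n_aa + n_ab       # allele A count
  nb_ <- 2 * n - na_
  m <- min(na_, nb_)
  if (m == 0) return(1)
  ks <- seq(m %% 2, m, by = 2)  # possible het counts, same parity
  logp <- vapply(ks, function(k) {
    aa <- (na_ - k) / 2; bb <- (nb_ - k) / 2
    lfactorial(n) - lfactorial(aa) - lfactorial(k) - lfactorial(bb) +
      k * log(2) + lfactorial(na_) + lfactorial(nb_) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- p[match(n_ab, ks)]
  sum(p[p <= obs * (1 + 1e-12)])
}

#' Per-site exact HWE tests with multiple-testing correction
#'
#' @param gm a `genotype_matrix`.
#' @param level significance level for the adjusted flags (default 0.05).
#' @return data frame with `contig`, `pos`, genotype counts, `p`,
#'   Bonferroni- and Benjamini-Hochberg-adjusted p-values and flags
#'   (`sig_bonf`, `sig_bh`, deviation at `p_adj <= level`).
#' @export
hwe_exact <- function(gm, level = 0.05) {
  n_aa <- colSums(gm$geno == 0L, na.rm = TRUE)
  n_ab <- colSums(gm$geno == 1L, na.rm = TRUE)
  n_bb <- colSums(gm$geno == 2L, na.rm = TRUE)
  p <- vapply(seq_len(n_sites(gm)), function(j)
    hwe_exact_test(n_aa[j], n_ab[j], n_bb[j]), numeric(1))
  p_bonf <- stats::p.adjust(p, method = "bonferroni")
  p_bh <- stats::p.adjust(p, method = "BH")
  data.frame(contig = gm$sites$contig, pos = gm$sites$pos,
             n_aa = n_aa, n_ab = n_ab, n_bb = n_bb, p = p,
             p_bonf = p_bonf, p_bh = p_bh,
             sig_bonf = p_bonf <= level, sig_bh = p_bh <= level)
}

#' Weir-Cockerham Fst variance components and estimates
#'
#' Per-site variance components `a` (among populations), `b` (among
#' individuals within populations) and `c` (within individuals) for unequal
#' sample sizes, from per-population allele frequencies and observed
#' heterozygote frequencies. Two genome-wide estimates are returned: the
#' mean of per-site ratios `a / (a + b + c)` over sites with a positive
#' denominator, and the "weighted" ratio-of-sums `sum(a) / sum(a + b + c)`,
#' which corrects for sample size.
#'
#' Sites where any analyzed population has no calls are excluded from the
#' components.
#'
#' @param gm a `genotype_matrix`.
#' @param popmap population map (see [read_popmap()]).
#' @param pops optional subset of population labels to analyze (default:
#'   all; at least two required).
#' @return list with `per_site` (data frame of `a`, `b`, `c`, `fst`),
#'   `mean_fst` and `weighted_fst`.
#' @export
wc_fst <- function(gm, popmap, pops = NULL) {
  pop <- pop_vector(gm, popmap)
  if (is.null(pops)) pops <- sort(unique(pop))
  if (length(pops) < 2) stop("Fst needs at least two populations")
  keep <- pop %in% pops
  gm <- gm_subset(gm, samples = keep)
  pop <- pop[keep]
  r <- length(pops)

  nmat <- hmat <- pmat <- matrix(0, nrow = r, ncol = n_sites(gm))
  for (k in seq_len(r)) {
    g <- gm$geno[pop == pops[k], , drop = FALSE]
    nk <- colSums(!is.na(g))
    if (all(nk == 0))
      stop("population ", pops[k], " has no calls at any site")
    nmat[k, ] <- nk
    pmat[k, ] <- ifelse(nk > 0, colSums(g, na.rm = TRUE) / (2 * nk), NA)
    hmat[k, ] <- ifelse(nk > 0, colSums(g == 1L, na.rm = TRUE) / nk, NA)
  }
  ok <- colSums(nmat > 0) == r
  a <- b <- cc <- rep(NA_real_, n_sites(gm))
  if (any(ok)) {
    nm <- nmat[, ok, drop = FALSE]; pm <- pmat[, ok, drop = FALSE]
    hm <- hmat[, ok, drop = FALSE]
    nbar <- colMeans(nm)
    nsum <- colSums(nm)
    nc <- (nsum - colSums(nm^2) / nsum) / (r - 1)
    pbar <- colSums(nm * pm) / nsum
    s2 <- colSums(nm * sweep(pm, 2, pbar)^2) / ((r - 1) * nbar)
    hbar <- colSums(nm * hm) / nsum
    pq <- pbar * (1 - pbar)
    a_ok <- nbar / nc *
      (s2 - (pq - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b_ok <- nbar / (nbar - 1) *
      (pq - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    c_ok <- hbar / 2
    a[ok] <- a_ok; b[ok] <- b_ok; cc[ok] <- c_ok
  }
  denom <- a + b + cc
  fst_site <- ifelse(!is.na(denom) & denom > 0, a / denom, NA_real_)
  use <- !is.na(denom) & denom > 0
  list(per_site = data.frame(contig = gm$sites$contig, pos = gm$sites$pos,
                             a = a, b = b, c = cc, fst = fst_site),
       mean_fst = mean(fst_site[use]),
       weighted_fst = sum(a[use]) / sum(denom[use]))
}

#' Pairwise Fst matrix across populations
#'
#' Square matrix with the mean-of-ratios estimate above the diagonal and
#' the weighted (ratio-of-sums) estimate below it, zero on the diagonal.
#'
#' @param gm a `genotype_matrix`.
#' @param popmap population map.
#' @param pops populations to include (default: all, sorted).
#' @return numeric matrix with population labels as dimnames.
#' @export
pairwise_fst_matrix <- function(gm, popmap, pops = NULL) {
  pop <- pop_vector(gm, popmap)
  if (is.null(pops)) pops <- sort(unique(pop))
  m <- matrix(0, length(pops), length(pops),
              dimnames = list(pops, pops))
  for (i in seq_along(pops)) for (j in seq_along(pops)) if (i < j) {
    f <- wc_fst(gm, popmap, pops = c(pops[i], pops[j]))
    m[i, j] <- f$mean_fst
    m[j, i] <- f$weighted_fst
  }
  m
}

#' SNP density in non-overlapping windows
#'
#' Counts SNPs per window over each contig's full length (zero-count
#' windows included) and summarizes.
#'
#' @param gm a `genotype_matrix`.
#' @param window_bp window width in bp (default 10000).
#' @return data frame of windows with `n_snps`, with attribute `"summary"`
#'   (mean, median, max per window).
#' @export
snp_density <- function(gm, window_bp = 10000) {
  wins <- window_frame(gm, window_bp)
  wi <- site_window_index(gm, wins, window_bp)
  wins$n_snps <- as.vector(table(factor(wi, levels = seq_len(nrow(wins)))))
  attr(wins, "summary") <- c(mean = mean(wins$n_snps),
                             median = stats::median(wins$n_snps),
                             max = max(wins$n_snps))
  rownames(wins) <- NULL
  wins
}
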