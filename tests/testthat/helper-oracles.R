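# Independent brute-force oracles used to validate the package's
# estimators, plus small fixture builders. Every oracle recomputes its
# quantity by a different route than the implementation under test.

# r^2 from the 3x3 dosage contingency table: accumulate moments from the
# table counts rather than from the vectors themselves.
oracle_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  tab <- table(factor(x, 0:2), factor(y, 0:2))
  n <- sum(tab)
  sx <- sy <- sxx <- syy <- sxy <- 0
  for (i in 0:2) for (j in 0:2) {
    c_ij <- tab[i + 1, j + 1]
    sx <- sx + c_ij * i; sy <- sy + c_ij * j
    sxx <- sxx + c_ij * i^2; syy <- syy + c_ij * j^2
    sxy <- sxy + c_ij * i * j
  }
  cov <- sxy / n - (sx / n) * (sy / n)
  vx <- sxx / n - (sx / n)^2
  vy <- syy / n - (sy / n)^2
  cov^2 / (vx * vy)
}

# Tajima's D from a haplotype (sequence) matrix, by direct transcription of
# the 1989 formulas with the pairwise-difference estimator enumerated over
# all sequence pairs.
oracle_tajima_d <- function(haps) {
  n <- nrow(haps)
  seg <- apply(haps, 2, function(col) length(unique(col)) > 1)
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  prs <- utils::combn(n, 2)
  diffs <- apply(prs, 2, function(ij)
    sum(haps[ij[1], ] != haps[ij[2], ]))
  theta_pi <- mean(diffs)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (theta_pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# windowed pi from a haplotype matrix: mean pairwise difference count over
# all sequence pairs, with the site-wise n/(n-1) correction folded in by the
# enumeration itself, divided by window length.
oracle_pi <- function(haps, window_len) {
  n <- nrow(haps)
  prs <- utils::combn(n, 2)
  diffs <- apply(prs, 2, function(ij)
    sum(haps[ij[1], ] != haps[ij[2], ]))
  mean(diffs) / window_len
}

# exact HWE p-value by full enumeration with factorial arithmetic
oracle_hwe <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na_ <- 2 * n_aa + n_ab
  nb_ <- 2 * n - na_
  m <- min(na_, nb_)
  if (m == 0) return(1)
  ks <- seq(m %% 2, m, by = 2)
  probs <- sapply(ks, function(k) {
    aa <- (na_ - k) / 2; bb <- (nb_ - k) / 2
    factorial(n) / (factorial(aa) * factorial(k) * factorial(bb)) * 2^k
  })
  probs <- probs / sum(probs)
  obs <- probs[ks == n_ab]
  sum(probs[probs <= obs * (1 + 1e-12)])
}

# Benjamini-Hochberg step-up by hand: adjusted p_i = min over j >= i of
# p_(j) * m / j, capped at 1, mapped back to input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  adj_sorted <- pmin(adj_sorted, 1)
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# build a genotype_matrix from a dosage matrix with minimal ceremony
make_gm <- function(geno, pos = NULL, contig = "ctgA", depth = NULL,
                    contig_lengths = NULL) {
  geno <- as.matrix(geno)
  if (is.null(pos)) pos <- seq_len(ncol(geno)) * 100
  genotype_matrix(geno,
                  data.frame(contig = contig, pos = pos,
                             ref = "A", alt = "T", biallelic_snp = TRUE),
                  sprintf("s%02d", seq_len(nrow(geno))),
                  depth = depth, contig_lengths = contig_lengths)
}

# 10-sample, 20-site fixture for the filter cascade with a hand-enumerated
# truth set under the default thresholds (DP > 7, call rate >= 0.80,
# missing < 0.30, MAF > 0.05, biallelic only). Site roles (1-based):
#   1  clean polymorphic              -> kept
#   2  monomorphic (MAF 0)            -> dropped (MAF)
#   3  MAF exactly 0.05               -> dropped (MAF > 0.05 is strict)
#   4  MAF 0.10                       -> kept
#   5  3/10 genotypes missing         -> dropped (call rate 0.7, missing 0.3)
#   6  2/10 missing (call rate 0.80)  -> kept (boundary inclusive)
#   7  all depth 7 at a clean site    -> dropped (depth mask empties it)
#   8  one depth-7 cell               -> kept (call rate 0.8 after masking)
#   9  indel record                   -> dropped (not a biallelic SNP)
#  10  multi-allelic record           -> dropped (not a biallelic SNP)
# 11-19 clean polymorphic (het counts 2..10) -> kept
#  20  ALT carried only by sample 10  -> passes site filters, then
#      re-dropped when sample 10 is removed (polymorphic only there)
# Sample 10 is missing at sites 1, 4, 8 and 11-19, so after site filtering
# its call rate is 2/14 < 0.8 and it is removed.
make_filter_fixture <- function() {
  n <- 10
  geno <- matrix(0L, nrow = n, ncol = 20)
  depth <- matrix(50L, nrow = n, ncol = 20)
  geno[, 1] <- c(0, 1, 1, 2, 0, 1, 0, 0, 1, 0)
  geno[, 2] <- 0L                                   # monomorphic
  geno[, 3] <- c(1, rep(0, 9))                      # MAF = 1/20 = 0.05
  geno[, 4] <- c(1, 1, rep(0, 8))                   # MAF 0.10
  geno[, 5] <- c(NA, NA, NA, 1, 1, 0, 0, 1, 0, 0)   # 30% missing
  geno[, 6] <- c(NA, NA, 1, 1, 0, 0, 1, 0, 1, 0)    # call rate exactly 0.8
  geno[, 7] <- c(0, 1, 1, 0, 1, 0, 1, 0, 1, 0)
  depth[, 7] <- 7L                                  # DP > 7 masks all
  geno[, 8] <- c(0, 1, 1, 0, 1, 0, 1, 0, 1, 0)
  depth[1, 8] <- 7L                                 # one cell masked
  geno[, 9] <- c(0, 1, 1, 0, 0, 1, 0, 1, 0, 1)      # indel record
  geno[, 10] <- c(0, 1, 1, 0, 0, 1, 0, 1, 0, 1)     # multi-allelic record
  for (j in 11:19) {
    k <- j - 9  # 2..10 heterozygotes
    geno[, j] <- c(rep(1L, k), rep(0L, n - k))
  }
  geno[, 20] <- c(rep(0L, 9), 2L)                   # MAF 2/20 = 0.10
  geno[10, c(1, 4, 8, 11:19)] <- NA                 # sparse sample
  sites <- data.frame(contig = "ctgA", pos = seq_len(20) * 10,
                      ref = "A", alt = "T", biallelic_snp = TRUE)
  sites$ref[9] <- "AT"    # indel
  sites$alt[10] <- "T,G"  # multi-allelic
  sites$biallelic_snp[c(9, 10)] <- FALSE
  gm <- genotype_matrix(geno, sites, sprintf("s%02d", 1:n), depth = depth)
  list(gm = gm,
       surviving_pos = c(1, 4, 6, 8, 11:19) * 10,
       surviving_samples = sprintf("s%02d", 1:9))
}
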