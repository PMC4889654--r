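#' Symmetric shrink of r-squared values into the open unit interval
#'
#' The Beta distribution lives on the open interval (0, 1), but empirical
#' `r^2` values hit both endpoints exactly. The transform
#' `((x - 0.5) * theta) + 0.5` shrinks the values symmetrically about 0.5 so
#' that every scaled value lies strictly inside (0, 1) while preserving
#' order; 0.5 is its fixed point. With the default `theta = 0.999`, 0 maps
#' to 0.0005 and 1 to 0.9995. [unscale_r2()] inverts it exactly.
#'
#' @param x numeric values in `[0, 1]`.
#' @param theta shrink factor strictly in (0, 1), default 0.999.
#' @return scaled values in (0, 1).
#' @export
scale_r2 <- function(x, theta = 0.999) {
  if (!(theta > 0 && theta < 1)) stop("theta must lie strictly in (0, 1)")
  if (any(x < 0 | x > 1, na.rm = TRUE))
    stop("r^2 values must lie in [0, 1]")
  ((x - 0.5) * theta) + 0.5
}

#' @rdname scale_r2
#' @param y scaled values.
#' @export
unscale_r2 <- function(y, theta = 0.999) {
  if (!(theta > 0 && theta < 1)) stop("theta must lie strictly in (0, 1)")
  (y - 0.5) / theta + 0.5
}

#' Fit a Beta distribution to scaled r-squared values
#'
#' Maximum-likelihood shapes (via \pkg{fitdistrplus}) initialized at the
#' method-of-moments estimate `a = m (m (1 - m) / v - 1)`,
#' `b = (1 - m) (m (1 - m) / v - 1)`. If the optimization fails the moments
#' estimate is returned with `converged = FALSE`.
#'
#' @param x values strictly in (0, 1).
#' @param min_n minimum number of values (default 10; the MLE is unstable
#'   below that).
#' @return list with `shape_a`, `shape_b`, `n`, `method` ("mle" or
#'   "moments"), `converged`.
#' @export
fit_beta <- function(x, min_n = 10) {
  x <- x[!is.na(x)]
  if (length(x) < min_n)
    stop("need at least ", min_n, " values to fit a Beta distribution")
  if (any(x <= 0 | x >= 1))
    stop("values must lie strictly in (0, 1); scale them first")
  m <- mean(x); v <- stats::var(x)
  if (v < 1e-12) {
    # essentially constant bin: a sharply concentrated Beta at the mean
    conc <- 1e6
    return(list(shape_a = m * conc, shape_b = (1 - m) * conc,
                n = length(x), method = "moments", converged = FALSE))
  }
  common <- m * (1 - m) / v - 1
  a0 <- max(m * common, 1e-3)
  b0 <- max((1 - m) * common, 1e-3)
  fit <- try(suppressWarnings(
    fitdistrplus::fitdist(x, "beta",
                          start = list(shape1 = a0, shape2 = b0))),
    silent = TRUE)
  if (!inherits(fit, "try-error") &&
      all(is.finite(fit$estimate)) && all(fit$estimate > 0)) {
    return(list(shape_a = unname(fit$estimate["shape1"]),
                shape_b = unname(fit$estimate["shape2"]),
                n = length(x), method = "mle", converged = TRUE))
  }
  list(shape_a = a0, shape_b = b0, n = length(x), method = "moments",
       converged = FALSE)
}

# merge bins with fewer than min_n pairs into the next non-empty bin upward
# (a trailing small group merges downward); returns a group id per pair
merge_small_bins <- function(binset, min_n) {
  bb <- binset$bins[binset$bins$count > 0, , drop = FALSE]
  grp <- integer(nrow(bb))
  g <- 1L; acc <- 0L
  for (i in seq_len(nrow(bb))) {
    grp[i] <- g
    acc <- acc + bb$count[i]
    if (acc >= min_n && i < nrow(bb)) { g <- g + 1L; acc <- 0L }
  }
  if (acc > 0L && acc < min_n && g > 1L)
    grp[grp == g] <- g - 1L
  data.frame(bin = bb$bin, group = grp)
}

#' Per-bin Beta fits for distance-binned LD values
#'
#' Scales each pair's `r^2` (see [scale_r2()]) and fits a Beta distribution
#' to every distance bin. Bins with fewer than `min_n` pairs are merged with
#' the next bin upward before fitting; the merged ranges are recorded.
#'
#' @param binset an `ld_bins` object from [bin_by_distance()].
#' @param theta shrink factor for [scale_r2()].
#' @param min_n minimum pairs per fitted bin (default 10).
#' @return list with `fits` (data frame: `group`, `lo`, `hi`, `n`,
#'   `shape_a`, `shape_b`, `method`, `converged`), `pair_group` (group id
#'   per row of `binset$pairs`), `theta`.
#' @export
fit_bin_betas <- function(binset, theta = 0.999, min_n = 10) {
  stopifnot(inherits(binset, "ld_bins"))
  map <- merge_small_bins(binset, min_n)
  pair_group <- map$group[match(binset$pairs$bin, map$bin)]
  scaled <- scale_r2(binset$pairs$r2, theta)
  fits <- do.call(rbind, lapply(sort(unique(map$group)), function(g) {
    sel <- which(pair_group == g)
    ft <- fit_beta(scaled[sel], min_n = min(min_n, length(sel)))
    bins_g <- map$bin[map$group == g]
    data.frame(group = g, lo = min(bins_g) * binset$width,
               hi = (max(bins_g) + 1) * binset$width,
               n = ft$n, shape_a = ft$shape_a, shape_b = ft$shape_b,
               method = ft$method, converged = ft$converged)
  }))
  list(fits = fits, pair_group = pair_group, theta = theta)
}

#' Upper-tail probabilities for binned SNP pairs under their bin's Beta fit
#'
#' For each pair, `p_raw = 1 - CDF(scaled r^2)` under the Beta distribution
#' fitted to the pair's own (possibly merged) distance bin: the probability
#' of observing a more extreme LD value in that bin.
#'
#' @param binset an `ld_bins` object.
#' @param bin_fits result of [fit_bin_betas()] for the same `binset`.
#' @return the pair table with `group`, `scaled_r2` and `p_raw` columns.
#' @export
pair_probabilities <- function(binset, bin_fits) {
  pairs <- binset$pairs
  pairs$group <- bin_fits$pair_group
  pairs$scaled_r2 <- scale_r2(pairs$r2, bin_fits$theta)
  i <- match(pairs$group, bin_fits$fits$group)
  pairs$p_raw <- 1 - stats::pbeta(pairs$scaled_r2,
                                  bin_fits$fits$shape_a[i],
                                  bin_fits$fits$shape_b[i])
  pairs
}

#' Flag LD-outlier pairs after false-discovery-rate correction
#'
#' Benjamini-Hochberg correction of the raw upper-tail probabilities,
#' applied either globally across all retained pairs (default; the
#' genome-wide flagged count is then a single FDR statement) or within each
#' bin group. Pairs with `p_adj <= alpha` are flagged.
#'
#' @param probs pair table from [pair_probabilities()].
#' @param alpha FDR level (default 0.01).
#' @param scope `"global"` or `"bin"`.
#' @return the pair table with `p_adj` and logical `flagged`, plus
#'   attribute `"summary"` (flagged count, total, fraction).
#' @export
flag_outliers <- function(probs, alpha = 0.01,
                          scope = c("global", "bin")) {
  scope <- match.arg(scope)
  if (scope == "global") {
    probs$p_adj <- stats::p.adjust(probs$p_raw, method = "BH")
  } else {
    probs$p_adj <- stats::ave(probs$p_raw, probs$group,
                              FUN = function(p) stats::p.adjust(p, "BH"))
  }
  probs$flagged <- probs$p_adj <= alpha
  attr(probs, "summary") <- c(flagged = sum(probs$flagged),
                              total = nrow(probs),
                              fraction = mean(probs$flagged))
  probs
}

#' Full LD-outlier scan on a pair table
#'
#' Convenience wrapper: [bin_by_distance()] -> [fit_bin_betas()] ->
#' [pair_probabilities()] -> [flag_outliers()].
#'
#' @param pairs pair table from [pairwise_r2()].
#' @param width distance-bin width in bp (default 50).
#' @param theta shrink factor (default 0.999).
#' @param alpha FDR level (default 0.01).
#' @param min_bin_n minimum pairs per fitted bin (default 10).
#' @param scope BH scope, `"global"` (default) or `"bin"`.
#' @return list with `pairs` (flagged pair table), `fits` (per-bin Beta
#'   fits) and `summary`.
#' @export
ld_outlier_scan <- function(pairs, width = 50, theta = 0.999, alpha = 0.01,
                            min_bin_n = 10, scope = "global") {
  binset <- bin_by_distance(pairs, width = width)
  bf <- fit_bin_betas(binset, theta = theta, min_n = min_bin_n)
  probs <- pair_probabilities(binset, bf)
  flagged <- flag_outliers(probs, alpha = alpha, scope = scope)
  list(pairs = flagged, fits = bf$fits, summary = attr(flagged, "summary"))
}
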