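#' Configuration for the synthetic ddRAD panel generator
#'
#' The simulator produces multi-population diploid SNP panels whose linkage
#' disequilibrium decays with physical distance at an analytically known
#' rate. Haplotypes follow a copying chain on latent uniforms: the latent
#' value at a site is copied from the previous site with probability
#' `retention_per_bp^d` (`d` = inter-site distance in bp) and redrawn
#' otherwise; the allele is the indicator that the latent value falls below
#' the site's population allele frequency. Marginal allele frequencies are
#' therefore exact, and for two sites at distance `d` with frequency 0.5 the
#' expected `r^2` is `retention_per_bp^(2d)`, giving a true half-decay
#' distance of `log(2) / (2 * log(1 / retention_per_bp))` bp.
#' Population allele frequencies are drawn around a shared ancestral
#' frequency by the Balding-Nichols construction so that the expected
#' Weir-Cockerham Fst over many sites is `fst_target`.
#'
#' Defaults mirror a small multi-population ddRAD study of tsetse flies:
#' three analyzable populations of 16 flies, ~40x depth, 5% missing calls.
#'
#' @param n_populations number of populations.
#' @param n_samples_per_pop diploid samples per population.
#' @param n_contigs number of contigs (assembly scaffolds).
#' @param contig_length contig length in bp.
#' @param snp_spacing mean inter-SNP distance in bp.
#' @param retention_per_bp per-bp allele-identity retention of the copying
#'   chain, strictly in (0, 1).
#' @param fst_target Weir-Cockerham-scale differentiation in `[0, 1)`.
#' @param missing_rate per-genotype missingness probability.
#' @param depth_mean mean of the Poisson read-depth model.
#' @param maf_floor ancestral frequencies are drawn uniformly on
#'   `[maf_floor, 1 - maf_floor]`.
#' @param n_spiked_pairs number of planted near-`r^2`-1 SNP pairs.
#' @param n_spiked_diff_sites number of planted sites with extreme
#'   between-population frequency differences.
#' @param seed integer RNG seed; the same seed and config give
#'   byte-identical outputs.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_populations = 3,
                       n_samples_per_pop = 16,
                       n_contigs = 20,
                       contig_length = 10000,
                       snp_spacing = 50,
                       retention_per_bp = 0.999,
                       fst_target = 0.2,
                       missing_rate = 0.05,
                       depth_mean = 40,
                       maf_floor = 0.05,
                       n_spiked_pairs = 3,
                       n_spiked_diff_sites = 3,
                       seed = 1) {
  if (!(retention_per_bp > 0 && retention_per_bp < 1))
    stop("retention_per_bp must lie strictly in (0, 1)")
  if (!(fst_target >= 0 && fst_target < 1))
    stop("fst_target must lie in [0, 1)")
  counts <- c(n_populations, n_samples_per_pop, n_contigs,
              n_spiked_pairs, n_spiked_diff_sites)
  if (any(counts < 0)) stop("counts must be >= 0")
  if (n_populations < 1 || n_samples_per_pop < 1)
    stop("need at least one population with at least one sample")
  if (n_contigs < 1 || contig_length < 1)
    stop("need at least one contig of positive length")
  if (missing_rate < 0 || missing_rate > 1)
    stop("missing_rate must lie in [0, 1]")
  if (maf_floor < 0 || maf_floor >= 0.5)
    stop("maf_floor must lie in [0, 0.5)")
  if (snp_spacing < 1) stop("snp_spacing must be >= 1 bp")
  structure(list(n_populations = n_populations,
                 n_samples_per_pop = n_samples_per_pop,
                 n_contigs = n_contigs, contig_length = contig_length,
                 snp_spacing = snp_spacing,
                 retention_per_bp = retention_per_bp,
                 fst_target = fst_target, missing_rate = missing_rate,
                 depth_mean = depth_mean, maf_floor = maf_floor,
                 n_spiked_pairs = n_spiked_pairs,
                 n_spiked_diff_sites = n_spiked_diff_sites,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' True LD half-decay distance of a copying-chain configuration
#' @param retention_per_bp per-bp retention probability in (0, 1).
#' @return distance (bp) at which expected `r^2` halves.
#' @export
true_half_decay <- function(retention_per_bp)
  log(2) / (2 * log(1 / retention_per_bp))

#' Draw per-population allele frequencies by the Balding-Nichols model
#'
#' Each population's frequency at a site is Beta-distributed with mean equal
#' to the ancestral frequency `p` and variance `fst * p * (1 - p)`
#' (shapes `p(1-F)/F` and `(1-p)(1-F)/F`). With `fst_target = 0` all
#' populations share the ancestral frequencies.
#'
#' @param ancestral numeric vector of ancestral frequencies in (0, 1).
#' @param cfg a [sim_config()].
#' @return matrix of `n_populations` rows x `length(ancestral)` columns.
#' @export
apply_structure <- function(ancestral, cfg) {
  K <- cfg$n_populations
  F <- cfg$fst_target
  if (F == 0)
    return(matrix(rep(ancestral, each = K), nrow = K))
  lam <- (1 - F) / F
  freq <- matrix(0, nrow = K, ncol = length(ancestral))
  for (k in seq_len(K))
    freq[k, ] <- stats::rbeta(length(ancestral),
                              ancestral * lam, (1 - ancestral) * lam)
  freq
}

#' Simulate a structured haplotype panel with known LD decay
#'
#' Generates SNP positions, ancestral and Balding-Nichols population
#' frequencies, haplotypes by the copying chain described in
#' [sim_config()], diploid genotypes with Poisson read depths and random
#' missingness, planted high-LD site pairs, planted high-differentiation
#' sites, and a mock per-SNP selection-scan (alpha) table in which the
#' planted sites carry the top ranks.
#'
#' Spiked pairs duplicate one site's alleles at a second site on the same
#' contig with 1% independent flips, yielding `r^2` near 1 without
#' degeneracy. Low-depth genotypes are *not* masked here: the depth filter
#' downstream is expected to remove them.
#'
#' @param cfg a [sim_config()].
#' @return a `sim_panel`: list with `cfg`, `sites`, `contig_lengths`,
#'   `sample_ids`, `pop` (population label per sample), `phenotype`,
#'   `haplotypes` (2N x S 0/1 matrix), `geno` (N x S dosages with `NA` at
#'   simulated missing calls), `depth` (N x S), `freq_pop`
#'   (populations x sites), `freq_anc`, `spiked_pairs`, `spiked_diff`,
#'   `alpha_table`, `genes` (planted gene track with known offsets).
#' @export
simulate_haplotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  K <- cfg$n_populations
  Nk <- cfg$n_samples_per_pop
  N <- K * Nk
  H <- 2L * N

  # site coordinates: geometric-ish spacing with the requested mean
  contigs <- sprintf("contig%03d", seq_len(cfg$n_contigs))
  pos_list <- lapply(contigs, function(ctg) {
    n_max <- ceiling(cfg$contig_length / cfg$snp_spacing * 3) + 10
    gaps <- 1 + stats::rgeom(n_max, prob = min(1, 1 / cfg$snp_spacing))
    p <- cumsum(gaps)
    p[p <= cfg$contig_length]
  })
  if (sum(lengths(pos_list)) == 0L)
    stop("degenerate configuration: no SNP sites generated")
  sites <- data.frame(
    contig = rep(contigs, lengths(pos_list)),
    pos = unlist(pos_list))
  S <- nrow(sites)

  freq_anc <- stats::runif(S, cfg$maf_floor, 1 - cfg$maf_floor)
  freq_pop <- apply_structure(freq_anc, cfg)
  # avoid exactly-fixed population frequencies (keeps downstream r^2 defined)
  freq_pop <- pmin(pmax(freq_pop, 1e-4), 1 - 1e-4)

  pop_names <- paste0("pop", LETTERS[seq_len(K)])
  pop_of_hap <- rep(seq_len(K), each = 2L * Nk)

  haps <- matrix(0L, nrow = H, ncol = S)
  for (ci in seq_along(contigs)) {
    idx <- which(sites$contig == contigs[ci])
    pos <- sites$pos[idx]
    u <- stats::runif(H)
    haps[, idx[1L]] <- as.integer(u < freq_pop[pop_of_hap, idx[1L]])
    if (length(idx) > 1L) {
      for (j in 2L:length(idx)) {
        d <- pos[j] - pos[j - 1L]
        copy <- stats::runif(H) < cfg$retention_per_bp^d
        u_new <- stats::runif(H)
        u <- ifelse(copy, u, u_new)
        haps[, idx[j]] <- as.integer(u < freq_pop[pop_of_hap, idx[j]])
      }
    }
  }

  # planted near-r^2-1 pairs: copy site A's alleles onto a partner site ~2 kb
  # downstream with 1% independent flips
  spiked_pairs <- data.frame(contig = character(0), pos_a = numeric(0),
                             pos_b = numeric(0), idx_a = integer(0),
                             idx_b = integer(0))
  if (cfg$n_spiked_pairs > 0L) {
    target_gap <- min(2000, floor(cfg$contig_length / 3))
    eligible <- contigs[lengths(pos_list) >= 4L]
    for (k in seq_len(cfg$n_spiked_pairs)) {
      if (!length(eligible)) break
      ctg <- eligible[1L + (k - 1L) %% length(eligible)]
      idx <- which(sites$contig == ctg)
      a <- idx[which.min(abs(sites$pos[idx] - (500 + 137 * k)))]
      bs <- idx[sites$pos[idx] > sites$pos[a]]
      if (!length(bs)) next
      b <- bs[which.min(abs(sites$pos[bs] - (sites$pos[a] + target_gap)))]
      if (b == a) next
      flip <- stats::runif(H) < 0.01
      haps[, b] <- ifelse(flip, 1L - haps[, a], haps[, a])
      freq_pop[, b] <- freq_pop[, a]
      spiked_pairs <- rbind(spiked_pairs, data.frame(
        contig = ctg, pos_a = sites$pos[a], pos_b = sites$pos[b],
        idx_a = a, idx_b = b))
    }
  }

  # planted extreme-differentiation sites (alternating 0.05 / 0.95 per pop)
  spiked_diff <- data.frame(contig = character(0), pos = numeric(0),
                            idx = integer(0))
  if (cfg$n_spiked_diff_sites > 0L && K >= 1L) {
    used <- c(spiked_pairs$idx_a, spiked_pairs$idx_b)
    cand <- setdiff(seq_len(S), used)
    pick <- cand[round(seq(1, length(cand),
                           length.out = min(cfg$n_spiked_diff_sites,
                                            length(cand))))]
    for (j in pick) {
      pk <- ifelse(seq_len(K) %% 2L == 1L, 0.95, 0.05)
      freq_pop[, j] <- pk
      haps[, j] <- as.integer(stats::runif(H) < pk[pop_of_hap])
      spiked_diff <- rbind(spiked_diff, data.frame(
        contig = sites$contig[j], pos = sites$pos[j], idx = j))
    }
  }

  # diploid genotypes, depth, missingness
  geno <- haps[seq(1, H, by = 2L), , drop = FALSE] +
    haps[seq(2, H, by = 2L), , drop = FALSE]
  storage.mode(geno) <- "integer"
  depth <- matrix(stats::rpois(N * S, cfg$depth_mean), nrow = N)
  if (cfg$missing_rate > 0) {
    miss <- matrix(stats::runif(N * S) < cfg$missing_rate, nrow = N)
    geno[miss] <- NA_integer_
  }

  sample_ids <- sprintf("%s_%02d", rep(pop_names, each = Nk),
                        rep(seq_len(Nk), K))
  phenotype <- rep_len(c("infected", "uninfected"), N)

  # mock selection-scan table: planted sites carry the top alpha ranks
  alpha <- stats::rnorm(S, 0, 0.5)
  qval <- stats::runif(S, 0.2, 1)
  spiked_idx <- unique(c(spiked_pairs$idx_a, spiked_pairs$idx_b,
                         spiked_diff$idx))
  if (length(spiked_idx)) {
    alpha[spiked_idx] <- max(3, max(alpha) + 1) +
      0.1 * seq_along(spiked_idx)
    qval[spiked_idx] <- 1e-4
  }
  fst_site <- if (K >= 2)
    apply(freq_pop, 2, function(p) stats::var(p) /
            max(mean(p) * (1 - mean(p)), 1e-9)) else rep(0, S)
  alpha_table <- data.frame(prob = round(stats::runif(S), 4),
                            log10_PO = round(stats::rnorm(S), 4),
                            qval = signif(qval, 4),
                            alpha = round(alpha, 4),
                            fst = signif(pmin(fst_site, 1), 4))

  # planted gene track: one gene near each spiked "anchor" site, at offsets
  # cycling through 0 (SNP inside gene), 500, and exactly 1000 bp, plus one
  # background gene per contig
  anchors <- data.frame(contig = c(spiked_pairs$contig, spiked_diff$contig),
                        pos = c(spiked_pairs$pos_a, spiked_diff$pos))
  offsets <- c(0, 500, 1000)
  genes <- NULL
  if (nrow(anchors)) {
    off <- offsets[1 + (seq_len(nrow(anchors)) - 1) %% length(offsets)]
    start <- ifelse(off == 0, pmax(1, anchors$pos - 200), anchors$pos + off)
    end <- pmin(start + 400, cfg$contig_length)
    genes <- data.frame(contig = anchors$contig, start = start, end = end,
                        strand = "+",
                        gene_id = sprintf("GENE%04d", seq_len(nrow(anchors))),
                        anchor_pos = anchors$pos, offset = off)
  }
  bg <- data.frame(contig = contigs,
                   start = pmin(101, cfg$contig_length),
                   end = pmin(600, cfg$contig_length),
                   strand = "-",
                   gene_id = sprintf("BGGENE%03d", seq_len(cfg$n_contigs)),
                   anchor_pos = NA_real_, offset = NA_real_)
  genes <- rbind(genes, bg)

  structure(list(cfg = cfg, sites = sites,
                 contig_lengths = stats::setNames(
                   rep(cfg$contig_length, cfg$n_contigs), contigs),
                 sample_ids = sample_ids,
                 pop = rep(pop_names, each = Nk),
                 phenotype = phenotype,
                 haplotypes = haps, geno = geno, depth = depth,
                 freq_anc = freq_anc, freq_pop = freq_pop,
                 spiked_pairs = spiked_pairs, spiked_diff = spiked_diff,
                 alpha_table = alpha_table, genes = genes),
            class = "sim_panel")
}

#' @export
print.sim_panel <- function(x, ...) {
  cat("sim_panel:", length(x$sample_ids), "samples in",
      x$cfg$n_populations, "population(s),", nrow(x$sites), "sites on",
      x$cfg$n_contigs, "contig(s)\n")
  cat(sprintf("  retention/bp %.5f -> true half-decay %.0f bp; Fst target %.2f\n",
              x$cfg$retention_per_bp, true_half_decay(x$cfg$retention_per_bp),
              x$cfg$fst_target))
  invisible(x)
}

#' Convert a simulated panel to a genotype matrix
#' @param panel a `sim_panel`.
#' @return a [genotype_matrix()] with depth and contig lengths.
#' @export
panel_to_gm <- function(panel) {
  genotype_matrix(panel$geno,
                  data.frame(contig = panel$sites$contig,
                             pos = panel$sites$pos,
                             ref = "A", alt = "T", biallelic_snp = TRUE),
                  panel$sample_ids, depth = panel$depth,
                  contig_lengths = panel$contig_lengths)
}

#' Write simulator fixtures to disk
#'
#' Emits, into `out_dir`: `sim.vcf` (GT:DP, missing as `./.`),
#' `genes.gff3` (gene features, 1-based inclusive), `popmap.tsv`
#' (sample, population, phenotype), `alpha_table.txt` (whitespace-delimited
#' mock selection-scan output with `alpha`, `fst`, `qval` columns in SNP
#' order), and `truth.tsv` (machine-readable ground truth: planted pairs and
#' sites, gene offsets, and model parameters). Writing is deterministic.
#'
#' @param panel a `sim_panel`.
#' @param out_dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
emit_fixtures <- function(panel, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok) stop("cannot create output directory: ", out_dir)
  paths <- c(vcf = file.path(out_dir, "sim.vcf"),
             gff = file.path(out_dir, "genes.gff3"),
             popmap = file.path(out_dir, "popmap.tsv"),
             alpha = file.path(out_dir, "alpha_table.txt"),
             truth = file.path(out_dir, "truth.tsv"))

  write_vcf(panel_to_gm(panel), paths[["vcf"]])

  gff <- c("##gff-version 3",
           sprintf("##sequence-region %s 1 %d", names(panel$contig_lengths),
                   as.integer(panel$contig_lengths)),
           sprintf("%s\tldscreen_sim\tgene\t%d\t%d\t.\t%s\t.\tID=gene:%s;Name=%s",
                   panel$genes$contig, as.integer(panel$genes$start),
                   as.integer(panel$genes$end), panel$genes$strand,
                   panel$genes$gene_id, panel$genes$gene_id))
  writeLines(gff, paths[["gff"]])

  utils::write.table(data.frame(sample = panel$sample_ids,
                                population = panel$pop,
                                phenotype = panel$phenotype),
                     paths[["popmap"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  at <- panel$alpha_table
  lines <- c(paste(c("", names(at)), collapse = " "),
             paste(seq_len(nrow(at)), at$prob, at$log10_PO, at$qval,
                   at$alpha, at$fst, sep = " "))
  writeLines(lines, paths[["alpha"]])

  cfg <- panel$cfg
  tr <- rbind(
    data.frame(kind = "spiked_pair", contig = panel$spiked_pairs$contig,
               pos = panel$spiked_pairs$pos_a,
               pos_b = panel$spiked_pairs$pos_b, id = "", value = NA_real_),
    data.frame(kind = "spiked_diff", contig = panel$spiked_diff$contig,
               pos = panel$spiked_diff$pos, pos_b = NA_real_, id = "",
               value = NA_real_),
    data.frame(kind = "gene",
               contig = panel$genes$contig[!is.na(panel$genes$offset)],
               pos = panel$genes$anchor_pos[!is.na(panel$genes$offset)],
               pos_b = NA_real_,
               id = panel$genes$gene_id[!is.na(panel$genes$offset)],
               value = panel$genes$offset[!is.na(panel$genes$offset)]),
    data.frame(kind = "param", contig = "", pos = NA_real_, pos_b = NA_real_,
               id = c("retention_per_bp", "true_half_decay_bp",
                      "fst_target", "seed", "n_sites"),
               value = c(cfg$retention_per_bp,
                         true_half_decay(cfg$retention_per_bp),
                         cfg$fst_target, cfg$seed, nrow(panel$sites))))
  utils::write.table(tr, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
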