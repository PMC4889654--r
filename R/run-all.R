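#' Configuration for a full pipeline run
#'
#' Aggregates every module's thresholds with the standard defaults: depth
#' mask at DP > 7, under 30% missing per site, 80% call rates, MAF > 0.05,
#' 50-bp LD bins, shrink factor 0.999, FDR 0.01 on the LD-outlier flags,
#' top 10% alpha, 1000-bp gene window and 1000-bp Tajima windows.
#'
#' @param vcf input VCF path.
#' @param out_dir output directory.
#' @param popmap optional population-map path.
#' @param gff optional GFF3 path (required for the selection screen).
#' @param alpha_table optional selection-scan table path (required for the
#'   selection screen).
#' @param min_dp,max_missing,min_call_rate,min_sample_call_rate,maf filter
#'   thresholds, see [filter_config()].
#' @param bin_width LD distance-bin width in bp.
#' @param span loess span for the decay fit (number or "aicc").
#' @param theta shrink factor for the Beta outlier test.
#' @param alpha_level FDR level for flagging LD outliers.
#' @param top_fraction top alpha fraction for the selection screen.
#' @param gene_window gene search window in bp.
#' @param tajima_window,pi_window,density_window window widths in bp.
#' @param min_pop_samples minimum samples for per-population LD curves.
#' @param min_pair_obs minimum complete observations per SNP pair.
#' @param comparison label for the selection-screen report.
#' @param seed integer seed recorded with the run (the pipeline itself is
#'   deterministic).
#' @return a `run_config` list.
#' @export
run_config <- function(vcf, out_dir, popmap = NULL, gff = NULL,
                       alpha_table = NULL,
                       min_dp = 7, max_missing = 0.30, min_call_rate = 0.80,
                       min_sample_call_rate = 0.80, maf = 0.05,
                       bin_width = 50, span = "aicc", theta = 0.999,
                       alpha_level = 0.01, top_fraction = 0.10,
                       gene_window = 1000, tajima_window = 1000,
                       pi_window = 5000, density_window = 10000,
                       min_pop_samples = 5, min_pair_obs = 5,
                       comparison = "all_samples", seed = 1) {
  structure(as.list(environment()), class = "run_config")
}

write_tsv <- function(d, path, params = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("# ldscreen ",
                    as.character(utils::packageVersion("ldscreen")),
                    if (!is.null(params)) paste0(" | ", params) else ""),
             con)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes filter -> stats -> ld-decay -> ld-outliers -> selection-screen
#' in order, writing every result as a headered TSV under
#' `config$out_dir`. Any stage failure aborts with the stage name and
#' cause. The serialized configuration is written alongside the outputs,
#' and two runs with the same inputs and configuration produce
#' byte-identical output trees.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the filtered matrix, statistics, decay
#'   curves, LD-outlier scan and selection report (where applicable), plus
#'   `files`, the paths written.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(config$out_dir, x)
  files <- character(0)

  cfgdf <- data.frame(
    key = c("vcf", "popmap", "gff", "alpha_table", "min_dp", "max_missing",
            "min_call_rate", "min_sample_call_rate", "maf", "bin_width",
            "span", "theta", "alpha_level", "top_fraction", "gene_window",
            "tajima_window", "pi_window", "density_window",
            "min_pop_samples", "min_pair_obs", "comparison", "seed"),
    value = as.character(c(config$vcf, config$popmap %||% "",
                           config$gff %||% "", config$alpha_table %||% "",
                           config$min_dp, config$max_missing,
                           config$min_call_rate, config$min_sample_call_rate,
                           config$maf, config$bin_width, config$span,
                           config$theta, config$alpha_level,
                           config$top_fraction, config$gene_window,
                           config$tajima_window, config$pi_window,
                           config$density_window, config$min_pop_samples,
                           config$min_pair_obs, config$comparison,
                           config$seed)))
  files <- c(files, write_tsv(cfgdf, fp("run_config.tsv")))

  # --- filter ---------------------------------------------------------
  raw_sites <- NULL
  gm <- stage("filter", {
    g <- read_vcf(config$vcf)
    raw_sites <- g$sites
    fc <- filter_config(min_genotype_depth = config$min_dp,
                        max_site_missing_frac = config$max_missing,
                        min_site_call_rate = config$min_call_rate,
                        min_sample_call_rate = config$min_sample_call_rate,
                        maf_min = config$maf)
    filter_cascade(g, fc)
  })
  stage("filter", {
    write_vcf(gm, fp("filtered.vcf"))
    files <- c(files, fp("filtered.vcf"),
               write_tsv(attr(gm, "filter_log"), fp("filter_log.tsv")))
  })

  popmap <- NULL
  if (!is.null(config$popmap)) popmap <- read_popmap(config$popmap)

  # --- stats ----------------------------------------------------------
  stats_out <- stage("stats", {
    ho <- observed_heterozygosity(gm, popmap)
    pi <- nucleotide_diversity(gm, config$pi_window)
    td <- tajimas_d(gm, config$tajima_window)
    hw <- hwe_exact(gm)
    dens <- snp_density(gm, config$density_window)
    fstm <- NULL
    if (!is.null(popmap) && length(unique(pop_vector(gm, popmap))) >= 2)
      fstm <- pairwise_fst_matrix(gm, popmap)
    list(ho = ho, pi = pi, td = td, hw = hw, dens = dens, fstm = fstm)
  })
  stage("stats", {
    files <- c(files,
      write_tsv(data.frame(sample = names(stats_out$ho$individual),
                           ho = stats_out$ho$individual),
                fp("heterozygosity.tsv")),
      write_tsv(stats_out$pi, fp("pi_windows.tsv"),
                sprintf("window=%d genome_average=%.6g", config$pi_window,
                        attr(stats_out$pi, "genome_average"))),
      write_tsv(stats_out$td, fp("tajimas_d_windows.tsv"),
                sprintf("window=%d average_all=%.6g average_snp=%.6g",
                        config$tajima_window,
                        attr(stats_out$td, "average_all"),
                        attr(stats_out$td, "average_snp"))),
      write_tsv(stats_out$hw, fp("hwe.tsv")),
      write_tsv(stats_out$dens, fp("snp_density.tsv")))
    if (!is.null(stats_out$fstm)) {
      m <- as.data.frame(stats_out$fstm)
      m <- cbind(population = rownames(stats_out$fstm), m)
      files <- c(files, write_tsv(m, fp("fst_matrix.tsv"),
        "mean Fst above diagonal, weighted Fst below"))
    }
  })

  # --- ld-decay -------------------------------------------------------
  ld <- stage("ld-decay", {
    pairs <- pairwise_r2(gm, min_obs = config$min_pair_obs)
    binset <- bin_by_distance(pairs, width = config$bin_width)
    curve <- fit_decay(binset, span = config$span)
    percurves <- NULL
    if (!is.null(popmap))
      percurves <- suppressWarnings(
        per_population_decay(gm, popmap, min_samples = config$min_pop_samples,
                             width = config$bin_width, span = config$span,
                             min_obs = config$min_pair_obs))
    list(pairs = pairs, binset = binset, curve = curve,
         percurves = percurves)
  })
  stage("ld-decay", {
    files <- c(files,
      write_tsv(ld$pairs, fp("ld_pairs.tsv")),
      write_tsv(ld$binset$bins, fp("ld_bins.tsv"),
                sprintf("width=%d", config$bin_width)))
    summ <- data.frame(population = "ALL",
                       n_samples = n_samples(gm),
                       r2_max = ld$curve$r2_max, d_half = ld$curve$d_half)
    if (!is.null(ld$percurves) && !is.null(attr(ld$percurves, "summary")))
      summ <- rbind(summ, attr(ld$percurves, "summary"))
    summ$span <- config$span
    files <- c(files, write_tsv(summ, fp("decay_summary.tsv")))
  })

  # --- ld-outliers ----------------------------------------------------
  scan <- stage("ld-outliers", {
    bf <- fit_bin_betas(ld$binset, theta = config$theta)
    probs <- pair_probabilities(ld$binset, bf)
    flagged <- flag_outliers(probs, alpha = config$alpha_level)
    list(pairs = flagged, fits = bf$fits,
         summary = attr(flagged, "summary"))
  })
  stage("ld-outliers", {
    files <- c(files,
      write_tsv(scan$fits, fp("beta_fits.tsv"),
                sprintf("theta=%g", config$theta)),
      write_tsv(scan$pairs, fp("ld_outliers.tsv"),
                sprintf("alpha=%g flagged=%d total=%d", config$alpha_level,
                        scan$summary[["flagged"]], scan$summary[["total"]])))
  })

  # --- selection-screen -----------------------------------------------
  report <- NULL
  if (!is.null(config$alpha_table)) {
    report <- stage("selection-screen", {
      if (is.null(config$gff))
        stop("selection screen requested but no GFF provided")
      # the external scan reports loci in input-VCF row order; map against
      # the raw site list, then keep the SNPs that survived filtering
      alpha <- read_alpha_table(config$alpha_table, raw_sites)
      keep <- paste0(alpha$contig, ":", alpha$pos) %in%
        paste0(gm$sites$contig, ":", gm$sites$pos)
      alpha <- alpha[keep, , drop = FALSE]
      genes <- read_gff_genes(config$gff)
      selection_screen(alpha, scan$pairs, genes,
                       fraction = config$top_fraction,
                       window = config$gene_window,
                       comparison = config$comparison)
    })
    stage("selection-screen", {
      files <- c(files, write_tsv(report, fp("selection_report.tsv"),
        sprintf("top=%g window=%d", config$top_fraction,
                config$gene_window)))
    })
  }

  invisible(list(gm = gm, stats = stats_out, ld = ld, scan = scan,
                 report = report, files = files))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
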