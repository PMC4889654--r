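#' Read a per-SNP selection-scan (alpha) table
#'
#' Parses the whitespace-delimited per-locus output of a Bayesian Fst
#' outlier scan (BayeScan `_fst.txt` dialect: header row with columns
#' including `alpha`, and usually `fst` and `qval`; loci reported by row
#' order). Rows are mapped to SNPs by order against the supplied site list;
#' a row-count mismatch is a hard error, never a silent reindex.
#'
#' @param path path to the table.
#' @param sites data frame with `contig` and `pos` in SNP order (e.g.
#'   `gm$sites`).
#' @return data frame with `contig`, `pos`, `alpha` and any of `fst`,
#'   `qval` present in the file.
#' @export
read_alpha_table <- function(path, sites) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (!"alpha" %in% names(tab))
    stop("alpha table has no 'alpha' column: ", path)
  if (nrow(tab) != nrow(sites))
    stop("alpha table has ", nrow(tab), " rows but the site list has ",
         nrow(sites), "; row order cannot be matched")
  out <- data.frame(contig = sites$contig, pos = sites$pos,
                    alpha = tab$alpha)
  for (col in c("fst", "qval")) if (col %in% names(tab)) out[[col]] <- tab[[col]]
  out
}

#' Top-ranked SNPs by alpha
#'
#' SNPs with alpha at or above the `(1 - fraction)` quantile. Ties at the
#' boundary are all included, so the set may exceed `fraction * m` loci.
#'
#' @param records alpha records from [read_alpha_table()].
#' @param fraction top fraction in (0, 1], default 0.10.
#' @param use_abs rank on `|alpha|` instead of signed alpha.
#' @return the subset of `records` in the top fraction, with a
#'   `percentile` column (rank percentile of alpha).
#' @export
top_alpha <- function(records, fraction = 0.10, use_abs = FALSE) {
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must lie in (0, 1]")
  v <- if (use_abs) abs(records$alpha) else records$alpha
  cutoff <- stats::quantile(v, 1 - fraction, names = FALSE)
  keep <- v >= cutoff
  out <- records[keep, , drop = FALSE]
  out$percentile <- 100 * rank(v)[keep] / length(v)
  rownames(out) <- NULL
  out
}

#' Intersect top-ranked SNPs with LD-flagged pairs
#'
#' Retains top SNPs that are a member of at least one flagged pair, each
#' annotated with its best partner (the flagged pair with the smallest
#' adjusted probability). Both members of a flagged pair are eligible.
#'
#' @param top_snps output of [top_alpha()].
#' @param flagged_pairs pair table from [flag_outliers()] /
#'   [ld_outlier_scan()]; only rows with `flagged == TRUE` are used.
#' @return candidate data frame: top-SNP columns plus `partner_pos` and
#'   `p_adj`.
#' @export
intersect_ld <- function(top_snps, flagged_pairs) {
  fp <- flagged_pairs
  if ("flagged" %in% names(fp)) fp <- fp[fp$flagged, , drop = FALSE]
  empty <- cbind(top_snps[0, , drop = FALSE],
                 data.frame(partner_pos = numeric(0), p_adj = numeric(0)))
  if (!nrow(fp) || !nrow(top_snps)) return(empty)
  long <- rbind(
    data.frame(key = paste0(fp$contig, ":", fp$pos_a),
               partner_pos = fp$pos_b, p_adj = fp$p_adj),
    data.frame(key = paste0(fp$contig, ":", fp$pos_b),
               partner_pos = fp$pos_a, p_adj = fp$p_adj))
  long <- long[order(long$p_adj), , drop = FALSE]
  best <- long[!duplicated(long$key), , drop = FALSE]
  key <- paste0(top_snps$contig, ":", top_snps$pos)
  i <- match(key, best$key)
  hit <- !is.na(i)
  out <- top_snps[hit, , drop = FALSE]
  out$partner_pos <- best$partner_pos[i[hit]]
  out$p_adj <- best$p_adj[i[hit]]
  rownames(out) <- NULL
  out
}

#' Read gene features from a GFF3 file
#'
#' @param path GFF3 path (1-based inclusive intervals).
#' @param feature feature type to keep (default `"gene"`).
#' @return data frame with `contig`, `start`, `end`, `strand`, `gene_id`.
#' @export
read_gff_genes <- function(path, feature = "gene") {
  g <- ape::read.gff(path)
  g <- g[g$type == feature, , drop = FALSE]
  id <- sub(".*ID=(?:gene:)?([^;]+).*", "\\1", g$attributes, perl = TRUE)
  data.frame(contig = as.character(g$seqid), start = g$start, end = g$end,
             strand = as.character(g$strand), gene_id = id,
             stringsAsFactors = FALSE)
}

#' Genes within a window of candidate SNPs
#'
#' A gene is reported iff the minimum distance between the SNP position and
#' the gene interval is at most `window` bp (inclusive at exactly
#' `window`). A SNP inside the gene has distance 0; otherwise the distance
#' is the signed gap in bp, positive when the gene starts downstream of the
#' SNP and negative when it ends upstream. Strand never affects the
#' distance.
#'
#' @param snps data frame with `contig` and `pos`.
#' @param genes gene table from [read_gff_genes()].
#' @param window maximum gap in bp (default 1000; must be >= 0).
#' @return data frame with `contig`, `pos`, `gene_id`, `distance`,
#'   `strand`; zero rows if nothing is in range.
#' @export
genes_near <- function(snps, genes, window = 1000) {
  if (window < 0) stop("window must be >= 0")
  missing_ctg <- setdiff(unique(snps$contig), unique(genes$contig))
  if (length(missing_ctg))
    warning("no gene annotations on contig(s): ",
            paste(missing_ctg, collapse = ", "))
  out <- NULL
  for (i in seq_len(nrow(snps))) {
    g <- genes[genes$contig == snps$contig[i], , drop = FALSE]
    if (!nrow(g)) next
    pos <- snps$pos[i]
    dist <- ifelse(pos < g$start, g$start - pos,
                   ifelse(pos > g$end, g$end - pos, 0))
    hit <- abs(dist) <= window
    if (any(hit))
      out <- rbind(out, data.frame(contig = snps$contig[i], pos = pos,
                                   gene_id = g$gene_id[hit],
                                   distance = dist[hit],
                                   strand = g$strand[hit]))
  }
  if (is.null(out))
    out <- data.frame(contig = character(0), pos = numeric(0),
                      gene_id = character(0), distance = numeric(0),
                      strand = character(0))
  rownames(out) <- NULL
  out
}

#' SNPs shared between candidate sets from different comparisons
#'
#' @param candidate_sets named list (>= 2 entries) of data frames with
#'   `contig` and `pos`.
#' @return data frame keyed by `contig:pos` with `n_comparisons` and the
#'   comma-separated comparison labels, restricted to SNPs present in at
#'   least two sets.
#' @export
shared_outliers <- function(candidate_sets) {
  if (length(candidate_sets) < 2)
    stop("need at least two labeled candidate sets")
  if (is.null(names(candidate_sets)) || any(!nzchar(names(candidate_sets))))
    stop("candidate sets must be named by comparison")
  keys <- lapply(candidate_sets, function(d)
    unique(paste0(d$contig, ":", d$pos)))
  all_keys <- unique(unlist(keys))
  inset <- vapply(keys, function(k) all_keys %in% k,
                  logical(length(all_keys)))
  inset <- matrix(inset, nrow = length(all_keys))
  n <- rowSums(inset)
  sel <- n >= 2
  labs <- apply(inset[sel, , drop = FALSE], 1, function(r)
    paste(names(candidate_sets)[r], collapse = ","))
  parts <- strsplit(all_keys[sel], ":", fixed = TRUE)
  data.frame(contig = vapply(parts, `[`, "", 1),
             pos = as.numeric(vapply(parts, `[`, "", 2)),
             n_comparisons = n[sel], comparisons = labs,
             stringsAsFactors = FALSE)
}

#' Selection screen: alpha rank x LD filter x gene proximity
#'
#' Intersects the top-alpha SNPs with LD-flagged pairs and annotates each
#' candidate with genes within `window` bp.
#'
#' @param alpha_records from [read_alpha_table()].
#' @param flagged_pairs from [flag_outliers()] / [ld_outlier_scan()].
#' @param genes from [read_gff_genes()] (or `NULL` to skip gene lookup).
#' @param fraction top alpha fraction (default 0.10).
#' @param window gene search window in bp (default 1000).
#' @param comparison label recorded on every row (required).
#' @param use_abs rank on absolute alpha.
#' @return candidate report: one row per candidate x nearby gene (gene
#'   fields `NA` when no gene is in range), columns `contig`, `pos`,
#'   `alpha`, `percentile`, `partner_pos`, `p_adj`, `gene_id`, `distance`,
#'   `comparison`.
#' @export
selection_screen <- function(alpha_records, flagged_pairs, genes = NULL,
                             fraction = 0.10, window = 1000,
                             comparison, use_abs = FALSE) {
  if (missing(comparison) || !nzchar(comparison))
    stop("a comparison label is required")
  top <- top_alpha(alpha_records, fraction = fraction, use_abs = use_abs)
  cand <- intersect_ld(top, flagged_pairs)
  if (!nrow(cand)) {
    return(data.frame(contig = character(0), pos = numeric(0),
                      alpha = numeric(0), percentile = numeric(0),
                      partner_pos = numeric(0), p_adj = numeric(0),
                      gene_id = character(0), distance = numeric(0),
                      comparison = character(0)))
  }
  if (!is.null(genes)) {
    hits <- genes_near(cand, genes, window = window)
    key_c <- paste0(cand$contig, ":", cand$pos)
    key_h <- paste0(hits$contig, ":", hits$pos)
    rows <- lapply(seq_len(nrow(cand)), function(i) {
      h <- hits[key_h == key_c[i], , drop = FALSE]
      if (!nrow(h))
        h <- data.frame(gene_id = NA_character_, distance = NA_real_)
      data.frame(contig = cand$contig[i], pos = cand$pos[i],
                 alpha = cand$alpha[i], percentile = cand$percentile[i],
                 partner_pos = cand$partner_pos[i], p_adj = cand$p_adj[i],
                 gene_id = h$gene_id, distance = h$distance)
    })
    out <- do.call(rbind, rows)
  } else {
    out <- data.frame(contig = cand$contig, pos = cand$pos,
                      alpha = cand$alpha, percentile = cand$percentile,
                      partner_pos = cand$partner_pos, p_adj = cand$p_adj,
                      gene_id = NA_character_, distance = NA_real_)
  }
  out$comparison <- comparison
  rownames(out) <- NULL
  out
}
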