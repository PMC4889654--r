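mock_alpha_file <- function(path, alphas) {
  lines <- c(" prob log10_PO qval alpha fst",
             paste(seq_along(alphas), 0.5, 0.1, 0.2, alphas, 0.1))
  writeLines(lines, path)
  path
}

test_that("alpha tables parse by row order and fail loudly on mismatch", {
  f <- withr::local_tempfile()
  mock_alpha_file(f, round(seq(-1, 1, length.out = 10), 3))
  sites <- data.frame(contig = "c1", pos = 1:10 * 100)
  rec <- read_alpha_table(f, sites)
  expect_equal(nrow(rec), 10)
  expect_equal(rec$alpha[1], -1)
  expect_equal(rec$pos, sites$pos)
  expect_error(read_alpha_table(f, sites[1:9, ]), "row order")
  f2 <- withr::local_tempfile()
  writeLines(c(" prob qval beta", paste(1:3, 0.5, 0.1, 0.2)), f2)
  expect_error(read_alpha_table(f2, sites[1:3, ]), "alpha")
})

test_that("top-alpha selection keeps the right fraction and all boundary ties", {
  rec <- data.frame(contig = "c1", pos = 1:100, alpha = sample(1:100))
  expect_equal(nrow(top_alpha(rec, 1)), 100)
  top10 <- top_alpha(rec, 0.10)
  expect_equal(sort(top10$alpha), 91:100)
  # ties straddling the cutoff are all included
  rec_t <- data.frame(contig = "c1", pos = 1:10,
                      alpha = c(rep(5, 4), rep(1, 6)))
  expect_equal(nrow(top_alpha(rec_t, 0.10)), 4)
  expect_error(top_alpha(rec, 0), "fraction")
  # absolute-value ranking option
  rec_n <- data.frame(contig = "c1", pos = 1:4, alpha = c(-9, 3, 1, 0))
  expect_equal(top_alpha(rec_n, 0.25, use_abs = TRUE)$alpha, -9)
})

test_that("LD intersection keeps only ranked SNPs inside flagged pairs", {
  top <- data.frame(contig = "c1", pos = c(100, 500, 900),
                    alpha = c(3, 2.5, 2), percentile = c(99, 98, 97))
  fp <- data.frame(contig = "c1", pos_a = c(100, 300), pos_b = c(2100, 500),
                   p_adj = c(0.001, 0.005), flagged = c(TRUE, TRUE))
  cand <- intersect_ld(top, fp)
  expect_equal(cand$pos, c(100, 500))
  expect_equal(cand$partner_pos, c(2100, 300))
  expect_equal(cand$p_adj, c(0.001, 0.005))
  # SNP 900 has no flagged pair -> excluded; empty flag set -> no candidates
  expect_false(900 %in% cand$pos)
  fp$flagged <- FALSE
  expect_equal(nrow(intersect_ld(top, fp)), 0)
  # candidates are a subset of the ranked set and of flagged-pair members
  expect_true(all(cand$pos %in% top$pos))
  expect_true(all(cand$pos %in% c(fp$pos_a, fp$pos_b)))
})

test_that("gene proximity is inclusive at the window edge and unsigned by strand", {
  genes <- data.frame(contig = "c1",
                      start = c(400, 2001, 2000, 5000),
                      end = c(600, 3000, 3000, 6000),
                      strand = c("+", "-", "+", "-"),
                      gene_id = c("gIn", "gFar", "gEdge", "gWay"))
  snps <- data.frame(contig = "c1", pos = c(500, 1000))
  hits <- genes_near(snps, genes, window = 1000)
  # SNP inside a gene -> distance 0
  expect_equal(hits$distance[hits$pos == 500 & hits$gene_id == "gIn"], 0)
  h1000 <- hits[hits$pos == 1000, ]
  # gap of exactly 1000 bp is included; 1001 is not
  expect_true("gEdge" %in% h1000$gene_id)
  expect_false("gFar" %in% h1000$gene_id)
  expect_equal(h1000$distance[h1000$gene_id == "gEdge"], 1000)
  # upstream gene -> negative signed distance
  up <- genes_near(data.frame(contig = "c1", pos = 700), genes, 1000)
  expect_equal(up$distance[up$gene_id == "gIn"], -100)
  # strand never affects distances
  genes_flip <- genes
  genes_flip$strand <- "-"
  expect_equal(genes_near(snps, genes_flip, 1000)$distance, hits$distance)
  # widening the window never loses a hit
  wide <- genes_near(snps, genes, window = 5000)
  expect_true(all(paste(hits$pos, hits$gene_id) %in%
                  paste(wide$pos, wide$gene_id)))
  # unannotated contig warns and returns no hits
  expect_warning(none <- genes_near(data.frame(contig = "cX", pos = 5),
                                    genes, 1000), "cX")
  expect_equal(nrow(none), 0)
  expect_error(genes_near(snps, genes, window = -1), ">= 0")
})

test_that("GFF3 gene features round-trip through the generator's track", {
  cfg <- sim_config(n_contigs = 4, contig_length = 5000, seed = 19)
  pan <- simulate_haplotypes(cfg)
  d <- withr::local_tempdir()
  paths <- emit_fixtures(pan, d)
  genes <- read_gff_genes(paths[["gff"]])
  expect_equal(nrow(genes), nrow(pan$genes))
  expect_equal(sort(genes$gene_id), sort(pan$genes$gene_id))
  i <- match(pan$genes$gene_id, genes$gene_id)
  expect_equal(genes$start[i], pan$genes$start)
  expect_equal(genes$end[i], pan$genes$end)
})

test_that("shared outliers are exactly the multi-comparison intersection", {
  a <- data.frame(contig = "c1", pos = c(100, 200, 300))
  b <- data.frame(contig = "c1", pos = c(200, 300, 400))
  c_ <- data.frame(contig = "c2", pos = c(999))
  sh <- shared_outliers(list(ab = a, cd = b, ef = c_))
  expect_equal(sort(sh$pos), c(200, 300))
  expect_equal(sh$n_comparisons, c(2, 2))
  # disjoint -> empty; identical -> everything
  expect_equal(nrow(shared_outliers(list(x = a, y = c_))), 0)
  sh_all <- shared_outliers(list(x = a, y = a))
  expect_equal(sort(sh_all$pos), c(100, 200, 300))
  expect_error(shared_outliers(list(a)), "two")
  expect_error(shared_outliers(list(a, b)), "named")
})

test_that("the screen report satisfies its defining invariants", {
  rec <- data.frame(contig = "c1", pos = seq(100, 2000, by = 100),
                    alpha = c(5, 4, rep(0, 18)))
  fp <- data.frame(contig = "c1", pos_a = c(100, 300), pos_b = c(1500, 800),
                   p_adj = c(1e-4, 1e-3), flagged = TRUE)
  genes <- data.frame(contig = "c1", start = 140, end = 240, strand = "+",
                      gene_id = "g1")
  rep1 <- selection_screen(rec, fp, genes, fraction = 0.10,
                           comparison = "cmp1")
  # pos 100 is ranked and flagged; pos 200 (alpha 4) is ranked but not in
  # any flagged pair -> excluded
  expect_equal(rep1$pos, 100)
  expect_equal(rep1$gene_id, "g1")
  expect_equal(rep1$distance, 40)
  expect_equal(rep1$comparison, "cmp1")
  expect_error(selection_screen(rec, fp, genes, comparison = ""),
               "label")
})
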