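toy_features <- function() {
  tibble::tibble(
    chrom = "A01",
    start = c(10000L, 30000L, 10100L, 50000L),
    end = c(12000L, 32000L, 10550L, 50400L),
    strand = c("+", "-", "+", "+"),
    feature_id = c("g_plus", "g_minus", "te1", "te2"),
    kind = c("PCG", "PCG", "TE", "TE"),
    te_family = c(NA, NA, "Copia", "Gypsy"),
    exons = list(tibble::tibble(start = c(10000L, 11000L),
                                end = c(10500L, 12000L)),
                 tibble::tibble(start = 30000L, end = 32000L),
                 NULL, NULL))
}

test_that("annotate_dmrs applies promoter > exon > intron > intergenic", {
  feats <- toy_features()
  dmrs <- tibble::tibble(
    chrom = "A01",
    start = c(10100L, 10700L, 9000L, 32100L, 29000L, 70000L),
    end = c(10200L, 10800L, 9100L, 32200L, 29100L, 70100L),
    context = "CHH")
  ann <- annotate_dmrs(dmrs, feats)
  # inside an exon and a TE: category exon, TE flagged independently
  expect_equal(ann$gene_category[1], "exon")
  expect_true(ann$te_overlap[1])
  expect_equal(ann$te_length_class[1], "short")
  # inside the gene body but between exons: intron
  expect_equal(ann$gene_category[2], "intron")
  # within 2 kb upstream of the plus-strand TSS: promoter
  expect_equal(ann$gene_category[3], "promoter")
  # upstream of a minus-strand gene means beyond its end coordinate
  expect_equal(ann$gene_category[4], "promoter")
  # 1 bp past the minus-strand gene's 3' end is NOT its promoter
  expect_equal(ann$gene_category[5], "intergenic")
  expect_equal(ann$gene_category[6], "intergenic")
  expect_false(ann$te_overlap[6])
  pct <- attr(ann, "percentages")
  expect_equal(sum(pct$percent), 100)
})

test_that("promoter_methylation windows are strand-aware", {
  feats <- toy_features()[1:2, ]
  # one covered cytosine in each true promoter, one in each false flank
  sites <- tibble::tibble(
    chrom = "A01", pos = c(9000L, 12500L, 33000L, 29500L),
    strand = "+", context = "CHH",
    count_m = c(8L, 4L, 6L, 2L), count_u = c(2L, 6L, 4L, 8L))
  m <- methylome(sites)
  pm <- promoter_methylation(m, feats)
  expect_equal(pm$level[pm$gene_id == "g_plus"], 0.8)   # [8000,10000) only
  expect_equal(pm$level[pm$gene_id == "g_minus"], 0.6)  # [32000,34000) only
  # promoter with zero covered cytosines is undefined and counted
  far <- dplyr::mutate(feats[1, ], start = 90000L, end = 92000L,
                       feature_id = "g_far")
  pm2 <- promoter_methylation(m, dplyr::bind_rows(feats, far))
  expect_true(is.na(pm2$level[pm2$gene_id == "g_far"]))
  expect_equal(attr(pm2, "n_undefined"), 1L)
})

test_that("methylation-expression correlation reports r and signed r-squared", {
  pl <- tibble::tibble(gene_id = paste0("g", 1:10),
                       level = seq(0.05, 0.5, by = 0.05))
  expr <- tibble::tibble(gene_id = pl$gene_id,
                         fpkm_R0 = 2^(8 - 10 * pl$level) - 1)
  res <- methylation_expression_correlation(pl, expr)
  expect_equal(res$pearson_r, -1, tolerance = 1e-12)
  expect_equal(res$signed_r_squared, -1, tolerance = 1e-12)
  expect_equal(res$n, 10L)
  expect_equal(tidy(res)$estimate, res$pearson_r)
  # degenerate variance is flagged
  flat <- dplyr::mutate(pl, level = 0.2)
  expect_warning(res0 <- methylation_expression_correlation(flat, expr),
                 "Degenerate")
  expect_true(is.na(res0$pearson_r))
  expect_warning(methylation_expression_correlation(pl[1:2, ], expr),
                 "Fewer than 3")
})

test_that("DMR vs non-DMR coupling contrast behaves on shared and empty sets", {
  pl <- tibble::tibble(gene_id = paste0("g", 1:20),
                       level = runif(20, 0, 0.5))
  expr <- tibble::tibble(gene_id = pl$gene_id,
                         fpkm_R0 = 2^(6 - 8 * pl$level) - 1)
  both <- compare_dmr_vs_nondmr_correlation(pl, expr, pl$gene_id[1:10])
  expect_equal(both$group, c("dmr", "non_dmr"))
  expect_equal(both$n, c(10L, 10L))
  one_sided <- compare_dmr_vs_nondmr_correlation(pl, expr, character(0))
  expect_equal(one_sided$n[one_sided$group == "dmr"], 0L)
  expect_true(is.na(one_sided$pearson_r[one_sided$group == "dmr"]))
})

test_that("k-means recovers well-separated trajectories deterministically", {
  skip_if_not_installed("mclust")
  withr::with_seed(31, {
    k <- 4L
    centers <- matrix(rnorm(k * 5, sd = 4), k, 5)
    truth <- rep(seq_len(k), each = 50)
    mat <- centers[truth, ] + rnorm(length(truth) * 5, sd = 0.3)
    expr <- tibble::as_tibble(as.data.frame(2^mat))
    names(expr) <- paste0("fpkm_s", 1:5)
    expr$gene_id <- paste0("g", seq_along(truth))
  })
  cl1 <- cluster_expression(expr, k = k, seed = 99L)
  cl2 <- cluster_expression(expr, k = k, seed = 99L)
  expect_identical(cl1$cluster, cl2$cluster)
  ari <- mclust::adjustedRandIndex(cl1$cluster, truth)
  expect_gte(ari, 0.9)
  # objective: multi-start solution no worse than the data's total SS
  expect_lte(attr(cl1, "tot_withinss"), attr(cl1, "totss"))
  # duplicated gene rows land in the same cluster
  dup <- dplyr::bind_rows(expr[1, ], expr[1, ])
  dup$gene_id <- c("d1", "d2")
  cld <- cluster_expression(dplyr::bind_rows(expr, dup), k = k, seed = 99L)
  expect_equal(cld$cluster[cld$gene_id == "d1"],
               cld$cluster[cld$gene_id == "d2"])
  expect_error(cluster_expression(expr[1:3, ], k = 10L), "exceeds")
})

test_that("deg_filter applies the published thresholds inclusively", {
  tab <- tibble::tibble(gene_id = paste0("g", 1:4),
                        p_value = c(0.01, 0.2, 0.01, 0.04),
                        log2_ratio = c(2.5, 5, -2, 1.9))
  degs <- deg_filter(tab)
  expect_equal(degs$gene_id, c("g1", "g3"))
  expect_equal(degs$direction, c("up", "down"))
  expect_error(deg_filter(dplyr::select(tab, -log2_ratio)), "log2_ratio")
})

test_that("siRNA-overlap gene groups differ when methylation is planted", {
  withr::with_seed(41, {
    n <- 120L
    genes <- tibble::tibble(chrom = "A01",
                            start = seq(0L, by = 3000L, length.out = n),
                            end = start + 2000L, strand = "+",
                            feature_id = paste0("g", seq_len(n)), kind = "PCG")
    overlapping <- seq_len(n) <= n / 2
    loci <- tibble::tibble(chrom = "A01",
                           start = genes$start[overlapping] + 500L,
                           end = genes$start[overlapping] + 524L)
    lvl <- ifelse(overlapping, 0.35, 0.15)
    sites <- tibble::tibble(chrom = "A01",
                            pos = as.integer(genes$start + 1000L), strand = "+",
                            context = "CHH",
                            count_m = rbinom(n, 60, lvl))
    sites$count_u <- 60L - sites$count_m
    m <- methylome(sites)
  })
  res <- genes_by_sirna_overlap(genes, loci, m, contexts = "CHH")
  expect_equal(res$n_overlap, 60L)
  expect_lt(res$p_value, 1e-10)
  # identical level distributions: no signal
  withr::with_seed(42, {
    sites0 <- dplyr::mutate(tibble::as_tibble(m),
                            count_m = rbinom(n, 60, 0.2),
                            count_u = 60L - count_m)
  })
  res0 <- genes_by_sirna_overlap(genes, loci, methylome(sites0),
                                 contexts = "CHH")
  expect_gt(res0$p_value, 0.01)
  assign <- attr(res, "genes")
  expect_equal(sum(assign$overlaps_sirna), 60L)
})

test_that("te_balance_test is the 50:50 goodness-of-fit chi-squared", {
  even <- te_balance_test(10, 10)
  expect_equal(even$statistic, 0)
  expect_equal(even$p_value, 1)
  extreme <- te_balance_test(20, 0)
  expect_equal(extreme$statistic, 20)
  expect_equal(extreme$p_value, pchisq(20, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_lt(abs(extreme$p_value - 7.7e-6), 1e-7)
  # symmetry
  expect_equal(te_balance_test(123, 77)$p_value,
               te_balance_test(77, 123)$p_value)
  expect_error(te_balance_test(0, 0), "not both zero")
  expect_equal(glance(extreme)$df, 1L)
})
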