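test_that("fixed seed gives identical synthetic datasets", {
  cfg <- tiny_config(seed = 42L)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$genome$sequences, s2$genome$sequences)
  expect_identical(as.data.frame(s1$genome$features[1:7]),
                   as.data.frame(s2$genome$features[1:7]))
  expect_identical(as.data.frame(s1$samples$WT), as.data.frame(s2$samples$WT))
  expect_identical(as.data.frame(s1$sirna_loci), as.data.frame(s2$sirna_loci))
  expect_identical(as.data.frame(s1$expression), as.data.frame(s2$expression))
})

test_that("generated genomes respect configuration", {
  sim <- tiny_sim()
  feats <- sim$genome$features
  expect_setequal(unique(feats$chrom), c("A01", "D01"))
  expect_true(all(substr(names(sim$genome$chrom_lengths), 1, 1) %in% c("A", "D")))
  # features non-overlapping within each kind
  for (k in c("PCG", "TE", "TEG")) {
    f <- dplyr::arrange(dplyr::filter(feats, kind == k), chrom, start)
    by_chrom <- split(f, f$chrom)
    for (fc in by_chrom) {
      if (nrow(fc) > 1) expect_true(all(fc$start[-1] >= fc$end[-nrow(fc)]))
    }
  }
  # exons nested within their gene
  genes <- dplyr::filter(feats, kind != "TE")
  ok <- purrr::pmap_lgl(list(genes$exons, genes$start, genes$end),
                        function(e, s, en) all(e$start >= s & e$end <= en))
  expect_true(all(ok))
  # no long TEs when the long class has weight zero
  cfg0 <- tiny_config(te_class_weights = c(short = 0.5, medium = 0.5, long = 0))
  g0 <- generate_genome(cfg0)
  tes <- dplyr::filter(g0$features, kind == "TE")
  expect_true(all(tes$end - tes$start <= 4000))
  # capacity overflow is rejected
  expect_error(generate_genome(sim_config(chroms = c(A01 = 20000L),
                                          n_genes = 20L)), "capacity")
})

test_that("true methylomes track context means, islands and planted DMRs", {
  # zero-variance config: every site exactly at its context mean
  cfg0 <- sim_config(seed = 3L, chroms = c(A01 = 30000L), n_genes = 0L,
                     n_tes = 0L, n_tegs = 0L, level_concentration = Inf,
                     promoter_chh = NULL, n_dmrs = c(CG = 0L, CHG = 0L, CHH = 0L))
  g0 <- generate_genome(cfg0)
  t0 <- generate_methylome(g0, cfg0)
  for (ctx in c("CG", "CHG", "CHH")) {
    lv <- t0$sites$level_WT[t0$sites$context == ctx]
    expect_true(all(lv == cfg0$context_means[[ctx]]))
  }
  # law of large numbers: CHH mean 0.08 within 0.01 over >= 1e4 sites, no DMRs
  cfg1 <- sim_config(seed = 4L, chroms = c(A01 = 100000L), n_genes = 0L,
                     n_tes = 0L, n_tegs = 0L, promoter_chh = NULL,
                     n_dmrs = c(CG = 0L, CHG = 0L, CHH = 0L))
  t1 <- generate_methylome(generate_genome(cfg1), cfg1, contexts = "CHH")
  expect_gt(nrow(t1$sites), 1e4)
  expect_lt(abs(mean(t1$sites$level_WT) - 0.08), 0.01)
  # planted CHH DMRs shift the designated sample by ~ the planned delta
  sim <- tiny_sim()
  chh <- dplyr::filter(sim$truth$dmrs, context == "CHH")
  expect_true(all(abs(chh$realized_delta - chh$delta) < 0.05))
  expect_true(all(sim$truth$dmrs$n_sites >= sim$config$dmr_min_sites))
  # truth and planted table agree when recomputed from site levels
  d1 <- chh[1, ]
  in_bin <- sim$truth$sites$chrom == d1$chrom &
    sim$truth$sites$pos - 1 >= d1$start & sim$truth$sites$pos - 1 < d1$end &
    sim$truth$sites$context == "CHH"
  expect_equal(mean(sim$truth$sites$level_R0[in_bin]) -
                 mean(sim$truth$sites$level_WT[in_bin]),
               d1$realized_delta, tolerance = 1e-12)
})

test_that("bisulfite counts follow the m + (1-m)r observation model", {
  cfg <- sim_config(seed = 5L, chroms = c(A01 = 200000L), n_genes = 0L,
                    n_tes = 0L, n_tegs = 0L, level_concentration = Inf,
                    promoter_chh = NULL, n_dmrs = c(CG = 0L, CHG = 0L, CHH = 0L),
                    context_means = c(CG = 0, CHG = 1, CHH = 0.5))
  truth <- generate_methylome(generate_genome(cfg), cfg)
  obs <- simulate_bisulfite_counts(truth, "WT", cfg)
  lv <- methylation_level(obs, context)
  # m = 0: observed level ~ r; m = 1: ~ 1; m = 0.5: ~ 0.5 + 0.5 * 0.006
  expect_lt(abs(lv$level[lv$context == "CG"] - 0.006), 0.001)
  expect_gt(lv$level[lv$context == "CHG"], 0.999)
  expect_lt(abs(lv$level[lv$context == "CHH"] - 0.503), 0.002)
})

test_that("siRNA loci honour the CHH-hyper coupling", {
  cfg1 <- tiny_config(seed = 9L, sirna_coupling = 1)
  sim1 <- simulate_dataset(cfg1)
  expect_true(all(sim1$sirna_loci$in_chh_hyper))
  hyper <- dplyr::filter(sim1$truth$dmrs, context == "CHH", delta > 0)
  ov <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(sim1$sirna_loci$chrom,
                           IRanges::IRanges(sim1$sirna_loci$start + 1,
                                            sim1$sirna_loci$end)),
    GenomicRanges::GRanges(hyper$chrom,
                           IRanges::IRanges(hyper$start + 1, hyper$end)))
  expect_equal(length(unique(S4Vectors::queryHits(ov))), nrow(sim1$sirna_loci))
  # binomial sampling of the coupling fraction
  cfg2 <- tiny_config(seed = 10L, sirna_coupling = 0.5, n_sirna_loci = 1000L)
  sim2 <- simulate_dataset(cfg2)
  n_in <- sum(sim2$sirna_loci$in_chh_hyper)
  expect_true(abs(n_in - 500) < 50)
})

test_that("expression is linear in true promoter CHH level", {
  cfg <- tiny_config(seed = 12L,
                     expression = list(slope = -4, noise_sd = 0, intercept = 6,
                                       coupled = "all"))
  sim <- simulate_dataset(cfg)
  x <- attr(sim$expression, "truth")$promoter_chh$R0
  y <- log2(sim$expression$fpkm_R0 + 1)
  expect_equal(unname(cor(x, y)), -1, tolerance = 1e-9)
  fit <- lm(y ~ x)
  expect_equal(unname(coef(fit)[2]), -4, tolerance = 1e-9)
  # slope 0: no correlation beyond noise
  cfg0 <- tiny_config(seed = 13L,
                      expression = list(slope = 0, noise_sd = 0.5,
                                        intercept = 6, coupled = "all"))
  sim0 <- simulate_dataset(cfg0)
  x0 <- attr(sim0$expression, "truth")$promoter_chh$R0
  y0 <- log2(sim0$expression$fpkm_R0 + 1)
  expect_lt(abs(cor(x0, y0)), 0.5)  # 22 genes, pure noise
})
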