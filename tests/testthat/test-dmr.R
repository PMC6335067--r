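test_that("bin_genome tiles correctly and conserves counts", {
  m <- make_methylome(pos = c(100, 101, 250), count_m = c(2, 3, 4),
                      count_u = c(8, 7, 6), chrom_lengths = c(A01 = 300L))
  bins <- bin_genome(m, "CHH")
  # 1-based pos 100 is the last base of bin [0, 100)
  expect_equal(bins$start[1], 0)
  expect_equal(bins$count_m[1], 2)
  expect_equal(bins$start, c(0, 100, 200))
  expect_equal(sum(bins$count_m) + sum(bins$count_u),
               sum(m$count_m) + sum(m$count_u))
  # informative requires >= 4 reads
  m2 <- make_methylome(pos = c(10, 20), count_m = c(1, 2),
                       count_u = c(2, 2))
  expect_equal(bin_genome(m2, "CHH")$informative, 1L)
  # complete tiling surfaces empty bins with zero counts
  full <- bin_genome(m, "CHH", complete = TRUE)
  expect_equal(nrow(full), 3L)
  empty <- bin_genome(make_methylome(pos = 5, count_m = 1, count_u = 1,
                                     chrom_lengths = c(A01 = 300L)),
                      "CHH", complete = TRUE)
  expect_equal(empty$count_m[empty$start == 200], 0L)
  expect_equal(empty$informative[empty$start == 200], 0L)
})

test_that("fisher_bin_test matches enumeration, symmetry and conventions", {
  expect_equal(fisher_bin_test(5, 5, 5, 5), 1)
  expect_equal(fisher_bin_test(5, 5, 0, 10), fisher_oracle_vec(5, 5, 0, 10),
               tolerance = 1e-12)
  expect_lt(abs(fisher_bin_test(5, 5, 0, 10) - 0.0325), 5e-4)
  expect_equal(fisher_bin_test(5, 5, 0, 10), fisher_bin_test(0, 10, 5, 5))
  # degenerate margins carry no information
  expect_equal(fisher_bin_test(0, 0, 0, 0), 1)
  expect_equal(fisher_bin_test(0, 0, 3, 7), 1)
  expect_equal(fisher_bin_test(5, 0, 7, 0), 1)
  expect_error(fisher_bin_test(-1, 2, 3, 4), "non-negative")
  # exhaustive agreement with the enumeration oracle for small margins
  small <- expand.grid(ma = 0:6, ua = 0:6, mb = 0:6, ub = 0:6)
  p_impl <- fisher_bin_test(small$ma, small$ua, small$mb, small$ub)
  p_orac <- fisher_oracle_vec(small$ma, small$ua, small$mb, small$ub)
  expect_equal(p_impl, p_orac, tolerance = 1e-10)
  # cross-check against the reference library implementation
  withr::with_seed(21, {
    for (i in 1:50) {
      tab <- matrix(rpois(4, 8), 2, byrow = TRUE)
      expect_equal(fisher_bin_test(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                   stats::fisher.test(tab)$p.value, tolerance = 1e-7)
    }
  })
})

test_that("bh_adjust reproduces the step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  withr::with_seed(22, {
    for (i in 1:10) {
      p <- runif(sample(3:40, 1))
      expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
    }
  })
})

test_that("call_dmrs enforces the informative filter and null identity", {
  sim <- tiny_sim()
  # a sample against itself: every 2x2 table is symmetric, zero DMRs
  d_null <- call_dmrs(sim$samples$WT, sim$samples$WT, "CHH")
  expect_equal(nrow(d_null), 0L)
  expect_gt(attr(d_null, "n_tested"), 0L)
  # a bin with 9 informative cytosines in one sample is never tested
  pos_a <- seq(10L, 100L, by = 10L)         # 10 informative sites
  a <- make_methylome(pos = pos_a, count_m = 5, count_u = 5)
  b <- make_methylome(pos = pos_a[1:9], count_m = 9, count_u = 1)
  d <- call_dmrs(a, b, "CHH")
  expect_equal(attr(d, "n_tested"), 0L)
  expect_equal(nrow(d), 0L)
  # with 10 informative in each, the bin is tested
  b2 <- make_methylome(pos = pos_a, count_m = 9, count_u = 1)
  d2 <- call_dmrs(a, b2, "CHH", keep_all = TRUE)
  expect_equal(attr(d2, "n_tested"), 1L)
})

test_that("planted DMRs are recovered with the right direction", {
  sim <- tiny_sim()
  for (ctx in c("CG", "CHG", "CHH")) {
    planted <- dplyr::filter(sim$truth$dmrs, context == ctx)
    called <- call_dmrs(sim$samples$WT, sim$samples$R0, ctx)
    hits <- dplyr::inner_join(planted, tibble::as_tibble(called),
                              by = c("chrom", "start"))
    expect_gte(nrow(hits), nrow(planted) - 1)
    expect_true(all(sign(hits$delta.y) == sign(hits$delta.x)))
    expect_true(all(hits$direction == ifelse(hits$delta.x > 0,
                                             "hyper", "hypo")))
  }
})

test_that("call_dmcs applies caller discordance and context deltas", {
  # CG site 5/5 vs 0/6: delta 1.0 >= 0.7 and statuses differ
  a <- make_methylome(pos = c(10, 20, 30), count_m = c(5, 9, 5),
                      count_u = c(0, 21, 0), context = "CG")
  b <- make_methylome(pos = c(10, 20, 40), count_m = c(0, 13, 9),
                      count_u = c(6, 37, 1), context = "CG")
  dmcs <- call_dmcs(a, b)
  expect_equal(dmcs$pos, 10L)
  expect_equal(dmcs$delta, -1)
  # CHH levels 0.30 vs 0.26: below the 0.1 delta, not a DMC
  a2 <- make_methylome(pos = 10, count_m = 30, count_u = 70)
  b2 <- make_methylome(pos = 10, count_m = 26, count_u = 74)
  expect_equal(nrow(call_dmcs(a2, b2)), 0L)
  # position covered in only one sample is excluded (pos 30/40 above)
  expect_false(any(c(30L, 40L) %in% dmcs$pos))
  # the per-site Fisher variant also flags the clear case
  dmcs_f <- call_dmcs(a, b, method = "fisher")
  expect_true(10L %in% dmcs_f$pos)
})

test_that("compare_dmr_sets partitions overlap classes", {
  mk <- function(starts, ctx = "CHH") {
    tibble::tibble(chrom = "A01", start = starts, end = starts + 100L,
                   context = ctx)
  }
  disjoint <- compare_dmr_sets(list(a = mk(0), b = mk(1000)))
  expect_true(all(disjoint$overlap_class == "unique"))
  same <- compare_dmr_sets(list(a = mk(c(0, 200)), b = mk(c(0, 200))))
  expect_true(all(same$overlap_class == "common"))
  # one shared bin between sets of sizes 3 and 4
  mix <- compare_dmr_sets(list(a = mk(c(0, 200, 400)),
                               b = mk(c(0, 1000, 2000, 3000))))
  smry <- attr(mix, "summary")
  expect_equal(smry$n[smry$set == "a" & smry$overlap_class == "common"], 1L)
  expect_equal(smry$n[smry$set == "a" & smry$overlap_class == "unique"], 2L)
  expect_equal(smry$n[smry$set == "b" & smry$overlap_class == "unique"], 3L)
  # overlap requires matching context
  cross <- compare_dmr_sets(list(a = mk(0), b = mk(0, ctx = "CG")))
  expect_true(all(cross$overlap_class == "unique"))
})
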