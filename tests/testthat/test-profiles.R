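# A uniform methylome: every covered cytosine 3/7, so every defined level
# is exactly 0.3 wherever pooled.
uniform_methylome <- function(len = 20000L, chrom = "A01", by = 7L) {
  pos <- seq(3L, len - 2L, by = by)
  make_methylome(pos = pos, count_m = 3L, count_u = 7L, chrom = chrom,
                 strand = rep(c("+", "-"), length.out = length(pos)),
                 chrom_lengths = setNames(len, chrom))
}

test_that("metagene profiles are flat on uniform methylomes", {
  m <- uniform_methylome()
  feats <- tibble::tibble(chrom = "A01", start = c(5000L, 12000L),
                          end = c(8000L, 14000L), strand = c("+", "-"))
  pr <- metagene_profile(m, feats, "CHH")
  expect_equal(nrow(pr), 300L)
  expect_equal(unique(pr$segment), c("upstream", "body", "downstream"))
  defined <- !is.na(pr$level)
  expect_gt(sum(defined), 250)
  expect_true(all(pr$level[defined] == 0.3))
})

test_that("profiles are strand-correct: mirrored genomes give identical bins", {
  sim <- tiny_sim()
  genes <- dplyr::filter(sim$genome$features, kind == "PCG", chrom == "A01")
  len <- sim$config$chroms[["A01"]]
  s <- tibble::as_tibble(sim$samples$WT) |> dplyr::filter(chrom == "A01")
  pr <- metagene_profile(methylome(s, chrom_lengths = c(A01 = len)),
                         genes, "CHH")
  # mirror every coordinate and flip every strand
  s_m <- dplyr::mutate(s, pos = len - pos + 1L,
                       strand = ifelse(strand == "+", "-", "+"))
  genes_m <- dplyr::mutate(genes, start0 = len - end, end = len - start,
                           start = start0,
                           strand = ifelse(strand == "+", "-", "+")) |>
    dplyr::select(-start0)
  pr_m <- metagene_profile(methylome(s_m, chrom_lengths = c(A01 = len)),
                           genes_m, "CHH")
  expect_equal(pr_m$level, pr$level)
  expect_equal(pr_m$count_total, pr$count_total)
})

test_that("single minus-strand feature equals its plus-strand mirror layout", {
  m <- uniform_methylome(by = 13L)
  minus <- tibble::tibble(chrom = "A01", start = 9000L, end = 11000L,
                          strand = "-")
  pr <- metagene_profile(m, minus, "CHH", flank = 1000L, nbins = 10L)
  expect_equal(nrow(pr), 30L)
  expect_true(all(pr$level[!is.na(pr$level)] == 0.3))
})

test_that("rddm_profile peaks at CHH-hyper loci and truncates at edges", {
  sim <- tiny_sim()
  rd <- rddm_profile(sim$samples$R0, sim$sirna_loci)
  body <- mean(rd$level[rd$segment == "body"], na.rm = TRUE)
  flank_ends <- mean(rd$level[rd$bin %in% c(1:10, 291:300)], na.rm = TRUE)
  expect_gt(body, flank_ends + 0.1)
  # locus at the chromosome start: flank bins beyond the edge stay undefined
  edge <- tibble::tibble(chrom = "A01", start = 0L, end = 100L)
  m <- uniform_methylome()
  pr <- rddm_profile(m, edge, flank = 5000L, nbins = 100L)
  expect_true(all(is.na(pr$level[pr$bin <= 95])))
})

test_that("window tracks pool correctly and keep partial windows", {
  m <- uniform_methylome(len = 25000L)
  tr <- window_track(m, window = 10000, step = 5000, contexts = "CHH")
  expect_true(all(tr$level_CHH == 0.3))
  expect_true(any(tr$partial))
  # degenerate single window equals the genome-wide level
  tr1 <- window_track(m, window = 25000, step = 25000, contexts = "CHH")
  expect_equal(nrow(tr1), 1L)
  expect_equal(tr1$level_CHH, weighted_level(m))
  # read-weighted mean over a tiling recovers the genome-wide level exactly
  sim <- tiny_sim()
  wt <- sim$samples$WT
  tr2 <- window_track(wt, window = 10000, step = 10000, contexts = "CHH")
  chh <- dplyr::filter(tibble::as_tibble(wt), context == "CHH")
  reads <- region_level(wt, tr2[c("chrom", "start", "end")], "CHH")
  expect_equal(sum(reads$level * reads$n_reads, na.rm = TRUE) / sum(reads$n_reads),
               weighted_level(chh), tolerance = 1e-12)
  expect_error(window_track(m, window = 100, step = 200), "step")
})

test_that("TE length classes follow the strict thresholds", {
  tes <- tibble::tibble(chrom = "A01", start = 0L,
                        end = c(400L, 4000L, 5000L, 500L))
  cls <- classify_te_lengths(tes)
  per_te <- attr(cls, "classes")
  expect_equal(per_te$te_length_class, c("short", "medium", "long", "medium"))
  expect_equal(sum(cls$fraction), 1)
  expect_error(classify_te_lengths(tibble::tibble(chrom = "A01", start = 5L,
                                                  end = 5L)), "Zero-length")
})

test_that("subgenome summaries group by chromosome prefix", {
  sim <- tiny_sim()
  loci_a_only <- dplyr::filter(sim$sirna_loci, chrom == "A01")
  s <- subgenome_summary(sim$samples$WT, loci = loci_a_only)
  expect_equal(s$n_sirna_loci[s$subgenome == "D"], 0L)
  expect_gt(s$n_sirna_loci[s$subgenome == "A"], 0L)
  # symmetric simulated genome: A and D levels agree within sampling error
  expect_lt(abs(s$level_CG[1] - s$level_CG[2]), 0.02)
  weird <- make_methylome(pos = c(5, 10), count_m = 1, count_u = 1,
                          chrom = "chrUn")
  expect_warning(s2 <- subgenome_summary(weird), "unassigned")
  expect_equal(s2$subgenome, "unassigned")
})

test_that("siRNA length fractions sum to one and flag empty input", {
  expect_equal(sirna_length_fractions(rep(24L, 5))$fraction, 1)
  half <- sirna_length_fractions(c(rep(21L, 10), rep(24L, 10)))
  expect_equal(half$fraction, c(0.5, 0.5))
  empty <- sirna_length_fractions(integer(0))
  expect_true(attr(empty, "empty"))
  expect_error(sirna_length_fractions(c(24L, 0L)), "positive")
})

test_that("length-methylation correlation recovers planted relations", {
  # levels constructed as an exact linear function of length
  lens <- seq(100L, 2000L, by = 100L)
  feats <- tibble::tibble(chrom = "A01", start = cumsum(c(0L, head(lens, -1) + 50L)),
                          end = start + lens)
  depth <- 100L
  sites <- tibble::tibble(chrom = "A01", pos = as.integer(feats$start + 5L),
                          strand = "+", context = "CHH",
                          count_m = as.integer(round(depth * lens / 4000)),
                          count_u = as.integer(depth - round(depth * lens / 4000)))
  m <- methylome(sites)
  r <- length_methylation_correlation(feats, m, contexts = "CHH")
  expect_gt(r$pearson_r, 0.99)
  # fewer than 3 usable features is flagged undefined
  expect_warning(
    r0 <- length_methylation_correlation(feats[1:2, ], m, contexts = "CHH"),
    "Fewer than 3")
  expect_true(is.na(r0$pearson_r))
})

test_that("constitutive siRNA loci are separated from specific ones", {
  sim <- tiny_sim()
  loci <- sim$sirna_loci[1:20, ]
  same <- classify_constitutive_loci(loci, loci, sim$samples$R0)
  expect_equal(same$n_loci[same$class == "constitutive"], 40L)
  expect_equal(sum(same$n_loci[same$class != "constitutive"]), 0L)
  disjoint <- classify_constitutive_loci(loci[1:10, ],
                                         dplyr::mutate(loci[11:20, ]),
                                         sim$samples$R0)
  expect_equal(disjoint$n_loci[disjoint$class == "constitutive"], 0L)
  # loci planted in CHH-hyper DMRs are hypermethylated relative to background
  hyper_loci <- dplyr::filter(sim$sirna_loci, in_chh_hyper)
  bg_loci <- dplyr::filter(sim$sirna_loci, !in_chh_hyper)
  cls <- classify_constitutive_loci(hyper_loci, bg_loci, sim$samples$R0)
  expect_gt(cls$level[cls$class == "specific_a"],
            cls$level[cls$class == "specific_b"] + 0.1)
})
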