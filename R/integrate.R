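#' Annotate DMRs with genomic categories
#'
#' Each DMR gets exactly one gene-centric category by >= 1 bp overlap with
#' precedence promoter > exon > intron > intergenic (promoters are the
#' strand-aware 2-kb windows upstream of gene TSSs; introns are gene-body
#' positions not covered by an exon). TE overlap is flagged independently,
#' with the length class of the overlapped TE, since TE percentages are
#' reported separately from the gene-centric split.
#'
#' @param dmrs A [call_dmrs()] result (or any interval tibble).
#' @param features Feature tibble containing PCG/TEG genes (with exons) and
#'   TEs.
#' @param promoter_len Promoter span upstream of the TSS (2000 bp).
#' @param te_short_max,te_long_min TE length-class boundaries.
#' @return `dmrs` plus `gene_category`, `te_overlap`, `te_length_class`;
#'   category percentages (summing to 100 over the four gene-centric
#'   categories) attached as attribute `percentages`, the TE-overlap
#'   percentage as attribute `te_percent`.
#' @export
annotate_dmrs <- function(dmrs, features, promoter_len = 2000L,
                          te_short_max = 500L, te_long_min = 4000L) {
  dmrs <- as_tibble(dmrs)
  feats <- as_tibble(features)
  genes <- filter(feats, .data$kind %in% c("PCG", "TEG"))
  tes <- filter(feats, .data$kind == "TE")
  n <- nrow(dmrs)
  hit_any <- function(iv) {
    out <- rep(FALSE, n)
    if (nrow(iv) && n) {
      hit <- findOverlaps(regions_granges(dmrs), regions_granges(iv),
                          minoverlap = 1L)
      out[unique(queryHits(hit))] <- TRUE
    }
    out
  }
  proms <- if (nrow(genes)) promoter_intervals(genes, promoter_len) else genes[0, ]
  exons <- if (nrow(genes)) {
    purrr::map2(genes$exons, seq_len(nrow(genes)), function(e, i) {
      if (is.null(e) || !nrow(e)) return(NULL)
      tibble(chrom = genes$chrom[i], start = e$start, end = e$end)
    }) |> bind_rows()
  } else tibble(chrom = character(0), start = integer(0), end = integer(0))
  in_prom <- hit_any(proms)
  in_exon <- hit_any(exons)
  in_gene <- hit_any(genes)
  dmrs$gene_category <- case_when(
    in_prom ~ "promoter",
    in_exon ~ "exon",
    in_gene ~ "intron",
    TRUE ~ "intergenic")
  dmrs$te_overlap <- hit_any(tes)
  dmrs$te_length_class <- NA_character_
  if (nrow(tes) && any(dmrs$te_overlap)) {
    hit <- findOverlaps(regions_granges(dmrs), regions_granges(tes),
                        minoverlap = 1L)
    ov <- interval_overlap(dmrs$chrom[queryHits(hit)],
                           dmrs$start[queryHits(hit)], dmrs$end[queryHits(hit)],
                           tes$chrom[subjectHits(hit)],
                           tes$start[subjectHits(hit)], tes$end[subjectHits(hit)])
    best <- tibble(q = queryHits(hit), s = subjectHits(hit), ov = ov) |>
      group_by(.data$q) |>
      slice_max(.data$ov, n = 1, with_ties = FALSE) |>
      ungroup()
    te_len <- tes$end[best$s] - tes$start[best$s]
    dmrs$te_length_class[best$q] <- ifelse(te_len < te_short_max, "short",
                                           ifelse(te_len > te_long_min, "long",
                                                  "medium"))
  }
  pct <- tibble(gene_category = c("promoter", "exon", "intron", "intergenic")) |>
    left_join(count(dmrs, .data$gene_category), by = "gene_category") |>
    mutate(n = coalesce(.data$n, 0L),
           percent = if (nrow(dmrs)) 100 * .data$n / nrow(dmrs) else NA_real_)
  structure(dmrs, percentages = pct,
            te_percent = if (n) 100 * mean(dmrs$te_overlap) else NA_real_,
            class = class(tibble()))
}

#' Per-gene promoter methylation level
#'
#' Pools one context's counts over the strand-aware 2-kb window upstream of
#' each gene's TSS. Promoters with zero covered cytosines get `NA` levels
#' and are counted in the `n_undefined` attribute.
#'
#' @param sample A [methylome()].
#' @param genes Gene tibble (needs `chrom`, `start`, `end`, `strand`,
#'   `feature_id`).
#' @param context Context to pool.
#' @param promoter_len Promoter span (2000 bp).
#' @return Tibble: `gene_id`, `n_sites`, `n_reads`, `level`.
#' @export
promoter_methylation <- function(sample, genes, context = "CHH",
                                 promoter_len = 2000L) {
  genes <- as_tibble(genes)
  proms <- promoter_intervals(genes, promoter_len)
  lv <- region_level(sample, proms[c("chrom", "start", "end")], context = context)
  out <- tibble(gene_id = proms$feature_id, n_sites = lv$n_sites,
                n_reads = lv$n_reads, level = lv$level)
  structure(out, n_undefined = sum(is.na(out$level)), class = class(tibble()))
}

#' Correlation of promoter methylation with expression
#'
#' Pearson correlation between per-gene promoter methylation level and
#' `log2(FPKM + 1)`. Alongside plain `r`, the signed coefficient of
#' determination `sign(r) * r^2` is reported, matching the signed-R-squared
#' convention used in methylome-expression figures.
#'
#' @param promoter_levels A [promoter_methylation()] result (or tibble with
#'   `gene_id`, `level`).
#' @param expression Expression tibble with `gene_id` and FPKM columns.
#' @param fpkm_col Which FPKM column to use; defaults to the first column
#'   matching `^fpkm_`.
#' @return A one-row `meth_expr_cor` tibble: `pearson_r`,
#'   `signed_r_squared`, `n`, `fpkm_col`.
#' @export
methylation_expression_correlation <- function(promoter_levels, expression,
                                               fpkm_col = NULL) {
  expression <- as_tibble(expression)
  fpkm_col <- fpkm_col %||% grep("^fpkm_", names(expression), value = TRUE)[1]
  if (is.na(fpkm_col) || !fpkm_col %in% names(expression)) {
    abort("No FPKM column found in `expression`.")
  }
  dat <- inner_join(as_tibble(promoter_levels), expression, by = "gene_id") |>
    filter(!is.na(.data$level), !is.na(.data[[fpkm_col]]))
  out <- tibble(pearson_r = NA_real_, signed_r_squared = NA_real_,
                n = nrow(dat), fpkm_col = fpkm_col)
  if (nrow(dat) < 3) {
    warn("Fewer than 3 genes with defined promoter level and expression.")
  } else {
    x <- dat$level
    y <- log2(dat[[fpkm_col]] + 1)
    if (sd(x) == 0 || sd(y) == 0) {
      warn("Degenerate variance; correlation undefined.")
    } else {
      r <- cor(x, y)
      out$pearson_r <- r
      out$signed_r_squared <- sign(r) * r^2
    }
  }
  structure(out, class = c("meth_expr_cor", class(tibble())))
}

#' Contrast methylation-expression coupling in DMR vs non-DMR genes
#'
#' Runs [methylation_expression_correlation()] separately for genes whose
#' promoters overlap DMRs and for the remaining genes, reporting both with
#' group sizes. An empty group yields an `NA` row.
#'
#' @param promoter_levels A [promoter_methylation()] result.
#' @param expression Expression tibble.
#' @param dmr_gene_ids Character vector of DMR-overlapped gene ids.
#' @param fpkm_col Forwarded to the correlation.
#' @return Two-row tibble with `group` (`dmr` / `non_dmr`) plus the
#'   correlation columns.
#' @export
compare_dmr_vs_nondmr_correlation <- function(promoter_levels, expression,
                                              dmr_gene_ids, fpkm_col = NULL) {
  pl <- as_tibble(promoter_levels)
  groups <- list(dmr = filter(pl, .data$gene_id %in% dmr_gene_ids),
                 non_dmr = filter(pl, !.data$gene_id %in% dmr_gene_ids))
  purrr::map2(groups, names(groups), function(g, nm) {
    if (!nrow(g)) {
      return(tibble(group = nm, pearson_r = NA_real_,
                    signed_r_squared = NA_real_, n = 0L,
                    fpkm_col = NA_character_))
    }
    res <- suppressWarnings(
      methylation_expression_correlation(g, expression, fpkm_col))
    mutate(res, group = nm) |> relocate("group")
  }) |> bind_rows()
}

#' Cluster gene expression trajectories with k-means
#'
#' Standardises each gene's expression across stages (z-score; flat genes
#' become all-zero profiles), then runs Lloyd k-means with `nstart` random
#' restarts under a fixed seed, keeping the solution with the lowest
#' within-cluster sum of squares. Clusters are relabelled by descending
#' first-stage centroid mean (roman numerals I..X at k = 10) so output is
#' stable across runs.
#'
#' @param expression Expression tibble with `gene_id` and the stage
#'   columns.
#' @param stage_cols Character vector of stage column names (defaults to
#'   every `fpkm_*` column, log2(x+1)-transformed).
#' @param k Number of clusters (10).
#' @param seed RNG seed controlling the restarts.
#' @param nstart Random restarts (10).
#' @param log_transform Apply `log2(x + 1)` to the stage columns first.
#' @return An `expr_clusters` tibble (`gene_id`, `cluster`); centroids,
#'   within-cluster SS and settings attached as attributes.
#' @export
cluster_expression <- function(expression, stage_cols = NULL, k = 10L,
                               seed = 1L, nstart = 10L, log_transform = TRUE) {
  expression <- as_tibble(expression)
  stage_cols <- stage_cols %||% grep("^fpkm_", names(expression), value = TRUE)
  if (length(stage_cols) < 2) abort("Need at least two stage columns.")
  if (nrow(expression) < k) abort("k exceeds the number of genes.")
  mat <- as.matrix(expression[stage_cols])
  if (log_transform) mat <- log2(mat + 1)
  mu <- rowMeans(mat)
  sdv <- apply(mat, 1, sd)
  z <- (mat - mu) / ifelse(sdv > 0, sdv, 1)
  n_distinct_profiles <- nrow(unique(z))
  if (n_distinct_profiles < k) {
    warn(paste0("Only ", n_distinct_profiles, " distinct standardized ",
                "profiles; reducing k from ", k, "."))
    k <- n_distinct_profiles
  }
  fit <- with_seed(as.integer(seed), {
    suppressWarnings(kmeans(z, centers = k, nstart = nstart, iter.max = 100L,
                            algorithm = "Lloyd"))
  })
  ord <- order(fit$centers[, 1], decreasing = TRUE)
  relabel <- match(seq_len(k), ord)
  labels <- as.character(as.roman(seq_len(k)))
  out <- tibble(gene_id = expression$gene_id,
                cluster = labels[relabel[fit$cluster]])
  centers <- fit$centers[ord, , drop = FALSE]
  rownames(centers) <- labels
  structure(out, centers = centers,
            withinss = fit$withinss[ord], tot_withinss = fit$tot.withinss,
            totss = fit$totss, k = k, seed = seed, stage_cols = stage_cols,
            class = c("expr_clusters", class(tibble())))
}

#' Filter differentially expressed genes
#'
#' Pure filter on a differential-test table: keep genes with
#' `p_value < p` and `|log2_ratio| >= min_abs_log2fc` (boundary inclusive);
#' the ratio sign gives the direction.
#'
#' @param expression Tibble with `p_value` and `log2_ratio`.
#' @param p P-value threshold (0.05).
#' @param min_abs_log2fc Minimum absolute log2 ratio (2).
#' @return The DEG rows plus a `direction` (`up`/`down`) column.
#' @export
deg_filter <- function(expression, p = 0.05, min_abs_log2fc = 2) {
  expression <- as_tibble(expression)
  for (col in c("p_value", "log2_ratio")) {
    if (!col %in% names(expression)) {
      abort(paste0("Expression table is missing required column \"", col, "\""))
    }
  }
  expression |>
    filter(.data$p_value < p, abs(.data$log2_ratio) >= min_abs_log2fc) |>
    mutate(direction = ifelse(.data$log2_ratio > 0, "up", "down"))
}

#' Compare methylation of genes with and without 24-nt siRNA overlap
#'
#' Splits genes by >= 1 bp gene-body overlap with any 24-nt siRNA locus and
#' compares the per-gene body methylation levels of the two groups with a
#' two-sided Wilcoxon rank-sum test per context (exact for small samples
#' without ties, normal approximation with tie correction otherwise, as
#' implemented by [stats::wilcox.test()]).
#'
#' @param genes Gene tibble.
#' @param loci siRNA locus tibble.
#' @param sample A [methylome()].
#' @param contexts Contexts to compare.
#' @return Tibble per context: group sizes, median levels, `p_value`
#'   (`NA` with empty groups); per-gene assignments attached as attribute
#'   `genes`.
#' @export
genes_by_sirna_overlap <- function(genes, loci, sample,
                                   contexts = c("CG", "CHG", "CHH")) {
  genes <- as_tibble(genes)
  loci <- as_tibble(loci)
  if (!nrow(genes) || !nrow(loci)) abort("`genes` and `loci` must be non-empty.")
  ov <- rep(FALSE, nrow(genes))
  hit <- findOverlaps(regions_granges(genes), regions_granges(loci),
                      minoverlap = 1L)
  ov[unique(queryHits(hit))] <- TRUE
  assign <- tibble(gene_id = genes$feature_id, overlaps_sirna = ov)
  res <- purrr::map(contexts, function(ctx) {
    lv <- region_level(sample, genes[c("chrom", "start", "end")], context = ctx)
    ok <- !is.na(lv$level)
    x <- lv$level[ok & ov]
    y <- lv$level[ok & !ov]
    p <- if (length(x) && length(y)) {
      suppressWarnings(wilcox.test(x, y, alternative = "two.sided")$p.value)
    } else NA_real_
    tibble(context = ctx, n_overlap = length(x), n_no_overlap = length(y),
           median_overlap = if (length(x)) median(x) else NA_real_,
           median_no_overlap = if (length(y)) median(y) else NA_real_,
           p_value = p)
  }) |> bind_rows()
  structure(res, genes = assign, class = class(tibble()))
}

#' Chi-squared balance test for up- vs down-regulated TEs
#'
#' One-degree-of-freedom goodness-of-fit test of the observed up/down
#' counts against an equal 50:50 split, without continuity correction.
#' Symmetric in its arguments.
#'
#' @param n_up,n_down Counts of up- and down-regulated elements.
#' @return A one-row `te_balance` tibble: `n_up`, `n_down`, `statistic`,
#'   `df`, `p_value`.
#' @examples
#' te_balance_test(5031, 4651)  # the zebularine TE imbalance
#' @export
te_balance_test <- function(n_up, n_down) {
  if (length(n_up) != 1 || length(n_down) != 1 ||
      is.na(n_up) || is.na(n_down) || n_up < 0 || n_down < 0 ||
      (n_up + n_down) == 0) {
    abort("`n_up` and `n_down` must be non-negative counts, not both zero.")
  }
  fit <- suppressWarnings(chisq.test(c(n_up, n_down), p = c(0.5, 0.5)))
  structure(tibble(n_up = n_up, n_down = n_down,
                   statistic = unname(fit$statistic), df = 1L,
                   p_value = unname(fit$p.value)),
            class = c("te_balance", class(tibble())))
}
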