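#' Pool cytosine counts into genome bins
#'
#' Tiles each chromosome with non-overlapping `bin_size`-bp bins
#' (0-based half-open; a 1-based position `p` falls in bin
#' `floor((p-1)/bin_size)`), pools the read counts of one context's sites
#' per bin and counts the informative cytosines — sites of the context
#' covered by more than 3 reads (i.e. at least `informative_min_reads`).
#'
#' @param sample A [methylome()].
#' @param context Context to bin.
#' @param bin_size Bin width in bp (default 100).
#' @param informative_min_reads Coverage floor for an informative cytosine
#'   (default 4, the published "covered by >3 reads").
#' @param complete If `TRUE` and chromosome lengths are known, emit every
#'   bin of the tiling, including empty ones with zero counts.
#' @return Tibble: `chrom`, `start`, `end`, `count_m`, `count_u`,
#'   `n_sites`, `informative`.
#' @export
bin_genome <- function(sample, context, bin_size = 100L,
                       informative_min_reads = 4L, complete = FALSE) {
  ctx <- context
  sites <- as_tibble(validate_sites(sample)) |> filter(.data$context == ctx)
  bins <- sites |>
    mutate(start = ((.data$pos - 1L) %/% bin_size) * bin_size) |>
    group_by(.data$chrom, .data$start) |>
    summarise(n_sites = n(),
              informative = sum(.data$count_m + .data$count_u >=
                                  informative_min_reads),
              count_m = sum(.data$count_m),
              count_u = sum(.data$count_u),
              .groups = "drop") |>
    relocate("count_m", "count_u", .after = "start")
  if (complete) {
    cl <- chrom_lengths(sample)
    if (is.null(cl)) abort("`complete = TRUE` needs chromosome lengths.")
    tiling <- bind_rows(purrr::map2(names(cl), cl, function(ch, len) {
      tibble(chrom = ch,
             start = seq(0L, len - 1L, by = bin_size))
    }))
    bins <- left_join(tiling, bins, by = c("chrom", "start")) |>
      mutate(across(c("count_m", "count_u", "n_sites", "informative"),
                    ~ coalesce(.x, 0L)))
  }
  bins |>
    mutate(end = .data$start + bin_size) |>
    relocate("chrom", "start", "end") |>
    arrange(.data$chrom, .data$start)
}

#' Two-sided Fisher's exact test for a pooled 2x2 count table
#'
#' Tests the table `[[m_a, u_a], [m_b, u_b]]` by summing the hypergeometric
#' probabilities of all tables (with the same margins) no more probable
#' than the observed one. A table with an all-zero margin carries no
#' information and returns p = 1 by convention. Vectorised over bins.
#'
#' @param m_a,u_a Methylated/unmethylated pooled counts in sample A.
#' @param m_b,u_b Same for sample B.
#' @return Two-sided p-value(s).
#' @examples
#' fisher_bin_test(5, 5, 5, 5)   # 1
#' fisher_bin_test(5, 5, 0, 10)  # ~0.0325
#' @export
fisher_bin_test <- function(m_a, u_a, m_b, u_b) {
  args <- vctrs_recycle(m_a, u_a, m_b, u_b)
  m_a <- args[[1]]; u_a <- args[[2]]; m_b <- args[[3]]; u_b <- args[[4]]
  if (any(c(m_a, u_a, m_b, u_b) < 0)) abort("Counts must be non-negative.")
  vapply(seq_along(m_a), function(i) {
    fisher_one(m_a[i], u_a[i], m_b[i], u_b[i])
  }, numeric(1))
}

fisher_one <- function(ma, ua, mb, ub) {
  n1 <- ma + ua
  n2 <- mb + ub
  m <- ma + mb
  if (n1 == 0 || n2 == 0 || m == 0 || (ua + ub) == 0) return(1)
  lo <- max(0, m - n2)
  hi <- min(n1, m)
  d <- dhyper(lo:hi, n1, n2, m)
  # relative tolerance guards against ties broken by floating-point noise
  min(1, sum(d[d <= d[ma - lo + 1] * (1 + 1e-7)]))
}

vctrs_recycle <- function(...) {
  xs <- list(...)
  n <- max(lengths(xs))
  lapply(xs, function(x) {
    if (length(x) == n) x else rep_len(x, n)
  })
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} p_(j) * m / j`, capped at
#' 1 and order-preserving.
#'
#' @param p_values Vector of p-values in `[0, 1]`.
#' @return q-values, parallel to the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p_values, method = "BH")
}

#' Call differentially methylated regions between two samples
#'
#' The genome is tiled in `bin_size`-bp bins; only bins holding at least
#' `min_informative` informative cytosines of the context *in each sample*
#' are tested (the stricter, symmetric reading of the informative filter).
#' Each tested bin gets a two-sided Fisher's exact p on the pooled counts,
#' q-values are Benjamini-Hochberg-adjusted across all tested bins of this
#' context/comparison, and bins with `q < fdr` are reported as DMRs —
#' single significant bins, never merged. `delta = level_b - level_a`;
#' direction `hyper` means the second sample is higher. No minimum delta is
#' imposed; `delta` is reported for post-filtering.
#'
#' @param sample_a,sample_b Two [methylome()]s on the same genome.
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param bin_size Bin width (100 bp).
#' @param min_informative Informative-cytosine floor per sample (10).
#' @param informative_min_reads Reads needed for a cytosine to be
#'   informative (4).
#' @param fdr BH FDR threshold (0.05).
#' @param keep_all Return all tested bins (with a `significant` flag)
#'   instead of significant bins only.
#' @return A `dmr_set` tibble (`chrom`, `start`, `end`, `context`,
#'   `m_a`, `u_a`, `m_b`, `u_b`, `level_a`, `level_b`, `delta`, `p_value`,
#'   `q_value`, `direction`), with attributes `n_tested`, `comparison`,
#'   `fdr`.
#' @export
call_dmrs <- function(sample_a, sample_b, context, bin_size = 100L,
                      min_informative = 10L, informative_min_reads = 4L,
                      fdr = 0.05, keep_all = FALSE) {
  bins_a <- bin_genome(sample_a, context, bin_size, informative_min_reads)
  bins_b <- bin_genome(sample_b, context, bin_size, informative_min_reads)
  tested <- inner_join(bins_a, bins_b, by = c("chrom", "start", "end"),
                       suffix = c("_a", "_b")) |>
    filter(.data$informative_a >= min_informative,
           .data$informative_b >= min_informative)
  comparison <- c(sample_name(sample_a), sample_name(sample_b))
  if (!nrow(tested)) {
    inform(paste0("No testable ", context, " bins for ",
                  paste(comparison, collapse = " vs "), "."))
    out <- tibble(chrom = character(0), start = integer(0), end = integer(0),
                  context = character(0), m_a = integer(0), u_a = integer(0),
                  m_b = integer(0), u_b = integer(0),
                  level_a = numeric(0), level_b = numeric(0),
                  delta = numeric(0), p_value = numeric(0),
                  q_value = numeric(0), direction = character(0))
    return(structure(out, n_tested = 0L, comparison = comparison, fdr = fdr,
                     class = c("dmr_set", class(tibble()))))
  }
  out <- tested |>
    transmute(.data$chrom, .data$start, .data$end, context = context,
              m_a = .data$count_m_a, u_a = .data$count_u_a,
              m_b = .data$count_m_b, u_b = .data$count_u_b,
              level_a = .data$m_a / (.data$m_a + .data$u_a),
              level_b = .data$m_b / (.data$m_b + .data$u_b),
              delta = .data$level_b - .data$level_a) |>
    mutate(p_value = fisher_bin_test(.data$m_a, .data$u_a,
                                     .data$m_b, .data$u_b),
           q_value = bh_adjust(.data$p_value),
           direction = ifelse(.data$delta > 0, "hyper", "hypo"),
           significant = .data$q_value < fdr)
  n_tested <- nrow(out)
  if (!keep_all) out <- filter(out, .data$significant) |> select(-"significant")
  structure(out, n_tested = n_tested, comparison = comparison, fdr = fdr,
            class = c("dmr_set", class(tibble())))
}

#' Call differentially methylated cytosines between two samples
#'
#' At every position covered by at least `min_coverage` reads in both
#' samples, a DMC requires (default `method = "status"`) that the two
#' binomial call statuses disagree — methylated in exactly one sample —
#' and that the absolute level difference reaches the context-specific
#' threshold (CG 0.7, CHG 0.5, CHH 0.1). `method = "fisher"` instead
#' requires a BH-adjusted per-site Fisher's exact q < 0.05 together with
#' the same delta rule.
#'
#' @param sample_a,sample_b Two [methylome()]s.
#' @param dmc_delta Named per-context absolute level thresholds.
#' @param min_coverage Per-sample coverage floor (3).
#' @param method `"status"` (discordant binomial calls) or `"fisher"`.
#' @param p_threshold,ratio_threshold Caller thresholds for `"status"`.
#' @param fdr FDR threshold for `"fisher"`.
#' @return Tibble of DMCs with both samples' counts, levels, statuses and
#'   `delta` (B minus A).
#' @export
call_dmcs <- function(sample_a, sample_b,
                      dmc_delta = c(CG = 0.7, CHG = 0.5, CHH = 0.1),
                      min_coverage = 3L, method = c("status", "fisher"),
                      p_threshold = 1e-5, ratio_threshold = 0.25, fdr = 0.05) {
  method <- match.arg(method)
  a <- as_tibble(validate_sites(sample_a))
  b <- as_tibble(validate_sites(sample_b))
  shared <- inner_join(a, b, by = c("chrom", "pos", "strand", "context"),
                       suffix = c("_a", "_b")) |>
    mutate(n_a = .data$count_m_a + .data$count_u_a,
           n_b = .data$count_m_b + .data$count_u_b) |>
    filter(.data$n_a >= min_coverage, .data$n_b >= min_coverage) |>
    mutate(level_a = .data$count_m_a / .data$n_a,
           level_b = .data$count_m_b / .data$n_b,
           delta = .data$level_b - .data$level_a)
  if (!nrow(shared)) return(shared)
  thr <- unname(dmc_delta[shared$context])
  if (method == "status") {
    r_a <- nonconversion_rate(sample_a)
    r_b <- nonconversion_rate(sample_b)
    meth_a <- site_pvalue(shared$count_m_a, shared$n_a, r_a) < p_threshold &
      shared$level_a > ratio_threshold
    meth_b <- site_pvalue(shared$count_m_b, shared$n_b, r_b) < p_threshold &
      shared$level_b > ratio_threshold
    shared$status_a <- ifelse(meth_a, "methylated", "unmethylated")
    shared$status_b <- ifelse(meth_b, "methylated", "unmethylated")
    keep <- xor(meth_a, meth_b) & abs(shared$delta) >= thr
  } else {
    p <- fisher_bin_test(shared$count_m_a, shared$count_u_a,
                         shared$count_m_b, shared$count_u_b)
    shared$p_value <- p
    shared$q_value <- bh_adjust(p)
    keep <- shared$q_value < fdr & abs(shared$delta) >= thr
  }
  shared[keep, , drop = FALSE] |>
    select(-any_of(c("triplet_a", "triplet_b")))
}

#' Compare DMR sets by interval overlap
#'
#' Assigns every DMR an overlap class across two or more named sets:
#' `common` when a same-context DMR overlapping by at least 1 bp exists in
#' every other set, `unique` when in no other set, `partial` otherwise.
#'
#' @param sets Named list of DMR tibbles (at least 2).
#' @return Tibble of all DMRs with `set`, `n_sets_hit` and `overlap_class`;
#'   per-set class counts attached as attribute `summary`.
#' @export
compare_dmr_sets <- function(sets) {
  if (length(sets) < 2) abort("Need at least two DMR sets.")
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- paste0("set", seq_along(sets))
  }
  k <- length(sets)
  all_dmrs <- purrr::map(sets, ~ as_tibble(.x)[c("chrom", "start", "end", "context")]) |>
    bind_rows(.id = "set")
  hit_count <- function(q, s) {
    if (!nrow(q)) return(integer(0))
    if (!nrow(s)) return(rep(0L, nrow(q)))
    ov <- findOverlaps(regions_granges(q), regions_granges(s), minoverlap = 1L)
    same_ctx <- q$context[queryHits(ov)] == s$context[subjectHits(ov)]
    as.integer(tabulate(queryHits(ov)[same_ctx], nbins = nrow(q)) > 0)
  }
  res <- purrr::map(names(sets), function(nm) {
    q <- filter(all_dmrs, .data$set == nm)
    hits <- rep(1L, nrow(q))  # counts its own set
    for (other in setdiff(names(sets), nm)) {
      hits <- hits + hit_count(q, filter(all_dmrs, .data$set == other))
    }
    mutate(q, n_sets_hit = hits,
           overlap_class = case_when(hits == k ~ "common",
                                     hits == 1L ~ "unique",
                                     TRUE ~ "partial"))
  }) |> bind_rows()
  structure(res, summary = count(res, .data$set, .data$overlap_class),
            class = class(tibble()))
}
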