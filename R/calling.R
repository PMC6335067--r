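#' One-sided binomial p-value for a cytosine site
#'
#' Probability of observing `count_m` or more unconverted reads out of `n`
#' if the cytosine were truly unmethylated and every unconverted read were
#' bisulfite non-conversion error: the exact upper tail
#' `P(X >= count_m)` for `X ~ Binomial(n, r)`.
#'
#' @param count_m Methylated (unconverted) read count(s).
#' @param n Total read count(s); recycled against `count_m`.
#' @param r Non-conversion rate in `[0, 1)`.
#' @return p-value(s) in `[0, 1]`; `count_m = 0` gives exactly 1.
#' @examples
#' site_pvalue(3, 3, 0.006)   # 0.006^3
#' site_pvalue(3, 12, 0.006)  # ~4.5e-5
#' @export
site_pvalue <- function(count_m, n, r = 0.006) {
  if (any(is.na(count_m)) || any(is.na(n)) || any(count_m < 0) || any(n < 0)) {
    abort("Counts must be non-negative.")
  }
  if (any(count_m > n)) abort("`count_m` cannot exceed `n`.")
  if (length(r) != 1 || r < 0 || r >= 1) abort("`r` must be a single rate in [0, 1).")
  pbinom(count_m - 1, n, r, lower.tail = FALSE)
}

#' Smallest significant methylated count at a given depth
#'
#' For each depth `n`, the smallest `count_m` whose binomial tail p-value
#' falls below `alpha`, or `NA` when no count up to `n` is significant.
#' Useful as a lookup table for what the caller can detect at a given
#' coverage.
#'
#' @param n Depth(s).
#' @param r Non-conversion rate.
#' @param alpha Significance threshold (the caller uses 1e-5).
#' @return Integer vector parallel to `n`.
#' @examples
#' min_methylated_count(c(3, 10), 0.006, 1e-5)  # 3, 4
#' @export
min_methylated_count <- function(n, r = 0.006, alpha = 1e-5) {
  if (any(n < 1)) abort("`n` must be >= 1.")
  vapply(n, function(ni) {
    p <- site_pvalue(0:ni, ni, r)
    hit <- which(p < alpha)
    if (length(hit)) as.integer(hit[1] - 1L) else NA_integer_
  }, integer(1))
}

#' Call methylated cytosines in a sample
#'
#' Every site receives exactly one status: `uncallable` below the coverage
#' floor (fewer than `min_coverage` reads); otherwise `methylated` when the
#' one-sided binomial p-value against the non-conversion rate is below
#' `p_threshold` *and* the methylated ratio exceeds `ratio_threshold`
#' (strict), else `unmethylated`. No multiple-testing correction is applied
#' to per-site calls; the fixed threshold is the published operating point.
#'
#' @param sample A [methylome()] (its stored non-conversion rate is used
#'   unless `r` is given).
#' @param min_coverage Coverage floor, inclusive (default 3 reads).
#' @param p_threshold Binomial p threshold (default 1e-5).
#' @param ratio_threshold Methylated-ratio threshold, strict (default 0.25).
#' @param r Optional non-conversion rate override.
#' @return The site tibble plus `n` (coverage), `ratio`, `p_value`,
#'   `status`; carries class `meth_calls` and the sample attributes.
#' @export
call_sites <- function(sample, min_coverage = 3L, p_threshold = 1e-5,
                       ratio_threshold = 0.25, r = NULL) {
  sites <- validate_sites(sample)
  r <- r %||% nonconversion_rate(sample)
  n <- sites$count_m + sites$count_u
  p <- rep(NA_real_, length(n))
  callable <- n >= min_coverage
  p[callable] <- site_pvalue(sites$count_m[callable], n[callable], r)
  ratio <- ifelse(n > 0, sites$count_m / n, NA_real_)
  status <- rep("uncallable", length(n))
  status[callable] <- ifelse(
    p[callable] < p_threshold & ratio[callable] > ratio_threshold,
    "methylated", "unmethylated")
  out <- sites
  out$n <- n
  out$ratio <- ratio
  out$p_value <- p
  out$status <- status
  structure(out, class = c("meth_calls", class(tibble())),
            sample_name = sample_name(sample),
            nonconversion_rate = r,
            chrom_lengths = chrom_lengths(sample))
}

#' Methylome composition by context
#'
#' Counts and relative content of methylated cytosines in the CG, CHG and
#' CHH contexts, plus per-context totals of callable sites. Fractions are
#' taken among methylated sites and sum to 1; an all-unmethylated sample is
#' flagged via the `empty` attribute and `NA` fractions.
#'
#' @param calls A [call_sites()] result.
#' @return A tibble with one row per context: `n_callable`, `n_methylated`,
#'   `pct_of_callable`, `fraction_of_mc`.
#' @export
methylome_composition <- function(calls) {
  stopifnot(all(c("context", "status") %in% names(calls)))
  out <- as_tibble(calls) |>
    filter(.data$status != "uncallable") |>
    count(.data$context, methylated = .data$status == "methylated") |>
    group_by(.data$context) |>
    summarise(n_callable = sum(.data$n),
              n_methylated = sum(.data$n[.data$methylated]),
              .groups = "drop") |>
    right_join(tibble(context = c("CG", "CHG", "CHH")), by = "context") |>
    mutate(n_callable = coalesce(.data$n_callable, 0L),
           n_methylated = coalesce(.data$n_methylated, 0L),
           pct_of_callable = ifelse(.data$n_callable > 0,
                                    100 * .data$n_methylated / .data$n_callable,
                                    NA_real_))
  total_mc <- sum(out$n_methylated)
  out$fraction_of_mc <- if (total_mc > 0) out$n_methylated / total_mc else NA_real_
  structure(arrange(out, .data$context), empty = total_mc == 0,
            class = class(tibble()))
}

#' Classify methylated sites as constitutive, varied or unique
#'
#' Across k call sets, a position methylated in at least one sample is
#' labelled `constitutive` when methylated in all k samples, `unique` when
#' methylated in exactly one, and `varied` otherwise. Positions are matched
#' exactly on `(chrom, pos, strand, context)`.
#'
#' @param callsets A named list of two or more [call_sites()] results.
#' @return A tibble of methylated positions with `n_samples_methylated` and
#'   `sharing_class`; per-class counts are attached as attribute `summary`.
#' @export
classify_sharing <- function(callsets) {
  if (length(callsets) < 2) abort("Need at least two call sets.")
  if (is.null(names(callsets)) || any(names(callsets) == "")) {
    names(callsets) <- paste0("sample", seq_along(callsets))
  }
  k <- length(callsets)
  meth <- purrr::map(callsets, function(cs) {
    as_tibble(cs) |>
      filter(.data$status == "methylated") |>
      select("chrom", "pos", "strand", "context")
  }) |> bind_rows(.id = "sample")
  out <- meth |>
    count(.data$chrom, .data$pos, .data$strand, .data$context,
          name = "n_samples_methylated") |>
    mutate(sharing_class = case_when(
      .data$n_samples_methylated == k ~ "constitutive",
      .data$n_samples_methylated == 1L ~ "unique",
      TRUE ~ "varied"))
  structure(out,
            summary = count(out, .data$context, .data$sharing_class),
            class = class(tibble()))
}
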