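#' Construct a methylome sample
#'
#' A methylome is a tibble of cytosine sites plus the sample's bisulfite
#' non-conversion rate and (optionally) the chromosome lengths, carried as
#' attributes. Sites use report coordinates: `pos` is the 1-based genomic
#' position of the cytosine, on its own strand. `count_m` is the number of
#' reads in which the cytosine stayed unconverted (methylated evidence);
#' `count_u` the number converted to T.
#'
#' Sites are validated (non-negative counts, known strand and context),
#' de-duplication on `(chrom, pos, strand)` is enforced, and rows are sorted
#' by `(chrom, pos)`.
#'
#' @param sites Data frame with columns `chrom`, `pos`, `strand` (`"+"`/`"-"`),
#'   `context` (`"CG"`, `"CHG"`, `"CHH"`), `count_m`, `count_u`, and
#'   optionally `triplet`.
#' @param name Sample label (e.g. `"WT"`, `"R0"`, `"NEC"`).
#' @param nonconversion_rate Probability that an unmethylated cytosine escapes
#'   bisulfite conversion; must lie in `[0, 1)`. Typically estimated from an
#'   unmethylated lambda spike-in (0.006 here).
#' @param chrom_lengths Optional named integer vector of chromosome lengths,
#'   required by tiling operations such as [window_track()].
#'
#' @return A tibble with class `methylome`.
#' @seealso [read_cytosine_report()], [call_sites()]
#' @examples
#' sites <- tibble::tibble(
#'   chrom = "A01", pos = c(5L, 9L), strand = "+",
#'   context = c("CG", "CHH"), count_m = c(8L, 1L), count_u = c(2L, 20L)
#' )
#' methylome(sites, name = "demo")
#' @export
methylome <- function(sites, name = "sample", nonconversion_rate = 0.006,
                      chrom_lengths = NULL) {
  sites <- validate_sites(sites)
  if (!is.numeric(nonconversion_rate) || length(nonconversion_rate) != 1 ||
      is.na(nonconversion_rate) || nonconversion_rate < 0 || nonconversion_rate >= 1) {
    abort("`nonconversion_rate` must be a single number in [0, 1).")
  }
  if (!is.null(chrom_lengths)) {
    if (is.null(names(chrom_lengths)) || any(chrom_lengths <= 0)) {
      abort("`chrom_lengths` must be a named vector of positive lengths.")
    }
  }
  sites <- arrange(sites, .data$chrom, .data$pos, .data$strand) |>
    relocate("chrom", "pos", "strand", "count_m", "count_u", "context")
  dup <- duplicated(sites[c("chrom", "pos", "strand")])
  if (any(dup)) {
    abort(paste0("Duplicated (chrom, pos, strand) site(s), e.g. ",
                 sites$chrom[dup][1], ":", sites$pos[dup][1]))
  }
  structure(sites,
            class = c("methylome", class(tibble())),
            sample_name = name,
            nonconversion_rate = nonconversion_rate,
            chrom_lengths = chrom_lengths)
}

validate_sites <- function(sites) {
  sites <- as_tibble(sites)
  need <- c("chrom", "pos", "strand", "context", "count_m", "count_u")
  miss <- setdiff(need, names(sites))
  if (length(miss)) {
    abort(paste0("Site table is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(sites)) {
    if (any(is.na(sites$pos)) || any(sites$pos < 1)) {
      abort("Site positions must be 1-based integers >= 1.")
    }
    if (any(is.na(sites$count_m)) || any(is.na(sites$count_u)) ||
        any(sites$count_m < 0) || any(sites$count_u < 0)) {
      abort("Read counts must be non-negative.")
    }
    if (!all(sites$strand %in% c("+", "-"))) {
      abort("Site strand must be '+' or '-'.")
    }
    if (!all(sites$context %in% c("CG", "CHG", "CHH"))) {
      bad <- unique(sites$context[!sites$context %in% c("CG", "CHG", "CHH")])
      abort(paste0("Unknown context token(s): ", paste(bad, collapse = ", ")))
    }
  }
  sites
}

#' @export
print.methylome <- function(x, ...) {
  cat("<methylome> sample:", sample_name(x),
      " non-conversion:", format(nonconversion_rate(x)), "\n")
  NextMethod()
}

#' Methylome accessors
#'
#' @param x A [methylome()].
#' @return The sample label, non-conversion rate, or named chromosome-length
#'   vector stored on the object.
#' @export
sample_name <- function(x) attr(x, "sample_name") %||% "sample"

#' @rdname sample_name
#' @export
nonconversion_rate <- function(x) attr(x, "nonconversion_rate") %||% 0.006

#' @rdname sample_name
#' @export
chrom_lengths <- function(x) attr(x, "chrom_lengths")

#' Weighted (pooled-count) methylation level
#'
#' The methylation level of a set of cytosine sites, computed by pooling read
#' counts: sum of methylated reads over sum of all reads. Pooling weights
#' every read equally and is therefore robust to uneven per-site coverage;
#' the unweighted mean of per-site ratios is available via
#' [methylation_level()] with `method = "mean"`.
#'
#' @param sites Data frame with `count_m` and `count_u` columns (e.g. a
#'   [methylome()] or any filtered subset of one).
#' @return A single number in `[0, 1]`, or `NA_real_` when the set carries no
#'   reads (the undefined case).
#' @examples
#' weighted_level(tibble::tibble(count_m = c(3, 2), count_u = c(1, 2))) # 5/8
#' @export
weighted_level <- function(sites) {
  if (!all(c("count_m", "count_u") %in% names(sites))) {
    abort("`sites` must have count_m and count_u columns.")
  }
  m <- sites$count_m
  u <- sites$count_u
  if (any(m < 0, na.rm = TRUE) || any(u < 0, na.rm = TRUE)) {
    abort("Read counts must be non-negative.")
  }
  tot <- sum(m) + sum(u)
  if (!length(m) || tot == 0) return(NA_real_)
  sum(m) / tot
}

#' Methylation level summaries by group
#'
#' Tidy wrapper around the level computation: returns one row per group with
#' the pooled (`"weighted"`, default) or mean-of-ratios (`"mean"`) level and
#' the supporting read totals.
#'
#' @param sites A site table ([methylome()] or tibble).
#' @param ... Grouping columns passed to [dplyr::group_by()], e.g. `context`.
#' @param method `"weighted"` pools counts; `"mean"` averages per-site ratios
#'   over covered sites.
#' @return A tibble with the grouping columns plus `n_sites`, `n_reads`,
#'   `level`.
#' @examples
#' sites <- tibble::tibble(
#'   chrom = "A01", pos = 1:4, strand = "+",
#'   context = c("CG", "CG", "CHH", "CHH"),
#'   count_m = c(3L, 2L, 0L, 1L), count_u = c(1L, 2L, 5L, 9L)
#' )
#' methylation_level(sites, context)
#' @export
methylation_level <- function(sites, ..., method = c("weighted", "mean")) {
  method <- match.arg(method)
  sites <- as_tibble(sites)
  grouped <- group_by(sites, ...)
  if (method == "weighted") {
    summarise(grouped,
              n_sites = n(),
              n_reads = sum(.data$count_m + .data$count_u),
              level = ifelse(.data$n_reads > 0,
                             sum(.data$count_m) / .data$n_reads, NA_real_),
              .groups = "drop")
  } else {
    summarise(grouped,
              n_sites = n(),
              n_reads = sum(.data$count_m + .data$count_u),
              level = {
                n <- .data$count_m + .data$count_u
                ok <- n > 0
                if (any(ok)) mean(.data$count_m[ok] / n[ok]) else NA_real_
              },
              .groups = "drop")
  }
}

#' Assign the sequence context of a cytosine
#'
#' Plant cytosine methylation is classified by the two bases following the
#' cytosine on its own strand: CG (second base G), CHG (third base G, second
#' base not G) and the asymmetric CHH (neither), with H = A, T or C.
#'
#' @param triplet Character vector of 3-base strings starting with `C`, read
#'   on the cytosine's strand.
#' @return Character vector of `"CG"`, `"CHG"` or `"CHH"`.
#' @examples
#' assign_context(c("CGT", "CAG", "CAT"))
#' @export
assign_context <- function(triplet) {
  if (!length(triplet)) return(character(0))
  if (any(is.na(triplet)) || any(nchar(triplet) != 3L)) {
    abort("Context triplets must be 3-base strings.")
  }
  if (any(!grepl("^C[ACGT][ACGT]$", triplet))) {
    bad <- triplet[!grepl("^C[ACGT][ACGT]$", triplet)]
    abort(paste0("Invalid triplet(s) (must start with C, bases in ACGT): ",
                 paste(head(unique(bad), 3), collapse = ", ")))
  }
  b2 <- substr(triplet, 2, 2)
  b3 <- substr(triplet, 3, 3)
  ifelse(b2 == "G", "CG", ifelse(b3 == "G", "CHG", "CHH"))
}

#' Overlap length of genomic intervals
#'
#' Intervals follow the internal 0-based half-open convention `[start, end)`.
#' Vectorised with the usual recycling; intervals on different chromosomes
#' overlap by 0.
#'
#' @param a_chrom,a_start,a_end First interval(s).
#' @param b_chrom,b_start,b_end Second interval(s).
#' @return Integer-valued vector of overlap lengths in bp.
#' @examples
#' interval_overlap("A01", 0, 100, "A01", 50, 150)  # 50
#' interval_overlap("A01", 0, 100, "A01", 100, 200) # 0 (half-open)
#' @export
interval_overlap <- function(a_chrom, a_start, a_end, b_chrom, b_start, b_end) {
  ov <- pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start))
  ov[a_chrom != b_chrom] <- 0
  ov
}

# GRanges helpers (internal): sites are single-base, regions are 0-based
# half-open and converted to the 1-based closed IRanges convention.
sites_granges <- function(sites) {
  GRanges(sites$chrom, IRanges(sites$pos, width = 1L))
}

regions_granges <- function(regions) {
  if (nrow(regions) && any(regions$start < 0 | regions$end <= regions$start)) {
    abort("Regions must satisfy 0 <= start < end.")
  }
  GRanges(regions$chrom, IRanges(regions$start + 1L, regions$end))
}
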