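#' Pooled methylation level over arbitrary regions
#'
#' For each region, pools the read counts of one context's cytosines whose
#' position falls inside the region and returns the weighted level
#' (`NA` when the region carries no reads). The work-horse behind promoter,
#' gene-body, TE and siRNA-locus levels.
#'
#' @param sample A [methylome()].
#' @param regions Tibble with `chrom`, 0-based half-open `start`/`end`.
#' @param context Context to pool.
#' @param method `"weighted"` pools counts; `"mean"` averages per-site
#'   ratios.
#' @return `regions` plus `n_sites`, `n_reads`, `level`.
#' @export
region_level <- function(sample, regions, context = "CHH",
                         method = c("weighted", "mean")) {
  method <- match.arg(method)
  ctx <- context
  regions <- as_tibble(regions)
  sites <- as_tibble(validate_sites(sample)) |> filter(.data$context == ctx)
  n_sites <- integer(nrow(regions))
  msum <- usum <- rsum <- covered <- numeric(nrow(regions))
  if (nrow(sites) && nrow(regions)) {
    hit <- findOverlaps(sites_granges(sites), regions_granges(regions))
    qi <- queryHits(hit); si <- subjectHits(hit)
    if (length(qi)) {
      n <- sites$count_m[qi] + sites$count_u[qi]
      agg <- rowsum(cbind(sites$count_m[qi], sites$count_u[qi],
                          ifelse(n > 0, sites$count_m[qi] / pmax(n, 1), NA),
                          as.numeric(n > 0)), si, na.rm = TRUE)
      got <- as.integer(rownames(agg))
      msum[got] <- agg[, 1]
      usum[got] <- agg[, 2]
      rsum[got] <- agg[, 3]
      covered[got] <- agg[, 4]
      n_sites[got] <- tabulate(si, nbins = nrow(regions))[got]
    }
  }
  regions$n_sites <- n_sites
  regions$n_reads <- msum + usum
  regions$level <- if (method == "weighted") {
    ifelse(regions$n_reads > 0, msum / regions$n_reads, NA_real_)
  } else {
    ifelse(covered > 0, rsum / covered, NA_real_)
  }
  regions
}

#' Metagene methylation profile
#'
#' Aggregates one context's methylation over aligned features: each
#' feature's body is rescaled to `nbins` fractional bins and each 2-kb
#' flank is cut into `nbins` fixed-width bins (20 bp at the defaults), so
#' flank distances stay interpretable (e.g. the CHH island sits in the
#' upstream-proximal bins). Minus-strand features are reversed so bin 1 is
#' always the 5'-most upstream bin and bin `3*nbins` the 3'-most
#' downstream. Per-bin levels pool read counts across all features
#' (coverage-weighted); bins with zero reads are `NA`. Flank bins running
#' past a chromosome end simply receive no sites.
#'
#' @param sample A [methylome()].
#' @param features Feature tibble (needs `chrom`, `start`, `end`,
#'   `strand`); strandless intervals are treated as plus.
#' @param context Context to profile.
#' @param flank Flank width in bp (2000 for metagene, 5000 for RdDM loci).
#' @param nbins Bins per segment (100).
#' @param method `"weighted"` (pooled counts) or `"mean"` (per-site ratios
#'   averaged within bins).
#' @return A `meta_profile` tibble: `bin` (1..3*nbins), `segment`
#'   (upstream/body/downstream), `context`, `count_m`, `count_total`,
#'   `level`; attributes `flank`, `nbins`, `n_features`.
#' @export
metagene_profile <- function(sample, features, context = "CHH", flank = 2000L,
                             nbins = 100L, method = c("weighted", "mean")) {
  method <- match.arg(method)
  ctx <- context
  feats <- as_tibble(features)
  if (!nrow(feats)) abort("`features` is empty.")
  if (any(feats$end - feats$start < 1)) abort("Features must span at least 1 bp.")
  if (!"strand" %in% names(feats)) feats$strand <- "+"
  sites <- as_tibble(validate_sites(sample)) |> filter(.data$context == ctx)
  ext <- tibble(chrom = feats$chrom,
                start = pmax(feats$start - flank, 0L),
                end = feats$end + flank)
  hit <- findOverlaps(sites_granges(sites), regions_granges(ext))
  qi <- queryHits(hit); si <- subjectHits(hit)
  p0 <- sites$pos[qi] - 1L
  fs <- feats$start[si]; fe <- feats$end[si]
  minus <- feats$strand[si] == "-"
  w <- flank / nbins
  bin <- integer(length(qi))
  up <- ifelse(minus, p0 >= fe, p0 < fs)
  down <- ifelse(minus, p0 < fs, p0 >= fe)
  body <- !up & !down
  # upstream flank: distance from the flank's outer (5') edge
  d_up <- ifelse(minus, fe + flank - 1L - p0, p0 - (fs - flank))
  bin[up] <- pmin(pmax(floor(d_up[up] / w), 0), nbins - 1) + 1L
  # body: fraction of the transcription unit, 5' to 3'
  frac <- ifelse(minus, (fe - 1L - p0) / (fe - fs), (p0 - fs) / (fe - fs))
  bin[body] <- nbins + pmin(pmax(floor(frac[body] * nbins), 0), nbins - 1) + 1L
  # downstream flank: distance past the 3' end
  d_dn <- ifelse(minus, fs - 1L - p0, p0 - fe)
  bin[down] <- 2L * nbins + pmin(pmax(floor(d_dn[down] / w), 0), nbins - 1) + 1L

  n <- sites$count_m[qi] + sites$count_u[qi]
  prof <- tibble(bin = bin, count_m = sites$count_m[qi], count_total = n,
                 ratio = ifelse(n > 0, sites$count_m[qi] / pmax(n, 1), NA_real_)) |>
    group_by(.data$bin) |>
    summarise(count_m = sum(.data$count_m),
              count_total = sum(.data$count_total),
              mean_ratio = mean(.data$ratio, na.rm = TRUE),
              .groups = "drop")
  out <- tibble(bin = seq_len(3L * nbins),
                segment = rep(c("upstream", "body", "downstream"), each = nbins),
                context = ctx) |>
    left_join(prof, by = "bin") |>
    mutate(count_m = coalesce(.data$count_m, 0L),
           count_total = coalesce(.data$count_total, 0L),
           level = if (method == "weighted") {
             ifelse(.data$count_total > 0, .data$count_m / .data$count_total,
                    NA_real_)
           } else {
             ifelse(is.finite(.data$mean_ratio), .data$mean_ratio, NA_real_)
           }) |>
    select(-"mean_ratio")
  structure(out, flank = flank, nbins = nbins, n_features = nrow(feats),
            sample_name = sample_name(sample),
            class = c("meta_profile", class(tibble())))
}

#' RdDM-locus methylation profile
#'
#' [metagene_profile()] specialised to 24-nt siRNA loci: locus bodies with
#' 5-kb flanks. Strandless loci are profiled on the plus strand.
#'
#' @inheritParams metagene_profile
#' @param loci siRNA locus tibble (`chrom`, `start`, `end`).
#' @export
rddm_profile <- function(sample, loci, context = "CHH", flank = 5000L,
                         nbins = 100L, method = c("weighted", "mean")) {
  loci <- as_tibble(loci)
  if (!nrow(loci)) abort("`loci` is empty.")
  loci$strand <- "+"
  metagene_profile(sample, loci, context = context, flank = flank,
                   nbins = nbins, method = method)
}

#' Constitutive versus sample-specific siRNA loci
#'
#' Splits two siRNA locus sets into loci shared by both samples
#' (overlapping by at least 1 bp: `constitutive`) and sample-specific loci,
#' and reports the pooled CHH (or other context) methylation level over
#' each class's intervals.
#'
#' @param loci_a,loci_b Locus tibbles for the two samples.
#' @param sample A [methylome()] supplying the methylation.
#' @param context Context to pool (default CHH).
#' @return Tibble: `class` (constitutive / specific_a / specific_b),
#'   `n_loci`, `total_bp`, `n_reads`, `level`.
#' @export
classify_constitutive_loci <- function(loci_a, loci_b, sample, context = "CHH") {
  a <- as_tibble(loci_a); b <- as_tibble(loci_b)
  ov_ab <- rep(FALSE, nrow(a)); ov_ba <- rep(FALSE, nrow(b))
  if (nrow(a) && nrow(b)) {
    hit <- findOverlaps(regions_granges(a), regions_granges(b), minoverlap = 1L)
    ov_ab[unique(queryHits(hit))] <- TRUE
    ov_ba[unique(subjectHits(hit))] <- TRUE
  }
  classes <- list(
    constitutive = bind_rows(a[ov_ab, c("chrom", "start", "end")],
                             b[ov_ba, c("chrom", "start", "end")]),
    specific_a = a[!ov_ab, c("chrom", "start", "end")],
    specific_b = b[!ov_ba, c("chrom", "start", "end")])
  purrr::map2(classes, names(classes), function(iv, cl) {
    if (!nrow(iv)) {
      return(tibble(class = cl, n_loci = 0L, total_bp = 0L,
                    n_reads = 0, level = NA_real_))
    }
    lv <- region_level(sample, iv, context = context)
    tibble(class = cl, n_loci = nrow(iv),
           total_bp = sum(iv$end - iv$start),
           n_reads = sum(lv$n_reads),
           level = if (sum(lv$n_reads) > 0) {
             sum(lv$level * lv$n_reads, na.rm = TRUE) / sum(lv$n_reads)
           } else NA_real_)
  }) |> bind_rows()
}

#' Sliding-window methylation track
#'
#' Pools one or more contexts' levels in windows of `window` bp advanced by
#' `step` bp along each chromosome (1-Mb windows sliding 200 kb for
#' chromosome overviews; 100-kb sliding 1 kb for fine tracks). A cytosine
#' contributes to every window containing it. The last, possibly partial,
#' window on each chromosome is kept and flagged. Optional siRNA-locus and
#' feature densities (count overlapping / window length) can be attached.
#'
#' @param sample A [methylome()] with known chromosome lengths (or pass
#'   `chrom_lengths`).
#' @param window,step Window width and slide in bp; `step <= window`.
#' @param contexts Contexts to report (wide `level_<ctx>` columns).
#' @param loci Optional siRNA locus tibble for `sirna_density`.
#' @param features Optional feature tibble for `feature_density`.
#' @param chrom_lengths Optional override of the sample's chromosome
#'   lengths.
#' @return A `window_track` tibble: `chrom`, `start`, `end`, `partial`,
#'   one `level_*` column per context, and the optional densities.
#' @export
window_track <- function(sample, window = 1e6, step = 2e5,
                         contexts = c("CG", "CHG", "CHH"),
                         loci = NULL, features = NULL, chrom_lengths = NULL) {
  if (step < 1 || step > window) abort("Need 1 <= step <= window.")
  cl <- chrom_lengths %||% chrom_lengths(sample)
  if (is.null(cl)) abort("Chromosome lengths are required for window tracks.")
  wins <- bind_rows(purrr::map2(names(cl), cl, function(ch, len) {
    starts <- seq(0, max(len - 1, 0), by = step)
    starts <- starts[starts < len]
    tibble(chrom = ch, start = as.integer(starts),
           end = as.integer(pmin(starts + window, len)))
  })) |>
    mutate(partial = (.data$end - .data$start) < window)
  for (ctx in contexts) {
    lv <- region_level(sample, wins[c("chrom", "start", "end")], context = ctx)
    wins[[paste0("level_", ctx)]] <- lv$level
  }
  if (!is.null(loci)) {
    hit <- findOverlaps(regions_granges(as_tibble(loci)), regions_granges(wins))
    wins$sirna_density <- tabulate(subjectHits(hit), nbins = nrow(wins)) /
      (wins$end - wins$start)
  }
  if (!is.null(features)) {
    hit <- findOverlaps(regions_granges(as_tibble(features)), regions_granges(wins))
    wins$feature_density <- tabulate(subjectHits(hit), nbins = nrow(wins)) /
      (wins$end - wins$start)
  }
  structure(wins, window = window, step = step,
            class = c("window_track", class(tibble())))
}

#' Transposable-element length classes
#'
#' Partitions TEs into short (< `short_max` bp), long (> `long_min` bp,
#' strict) and medium (everything between, inclusive of both boundaries)
#' classes, and optionally attaches per-class pooled methylation levels per
#' context.
#'
#' @param tes TE tibble (`chrom`, `start`, `end`).
#' @param sample Optional [methylome()] for per-class levels.
#' @param short_max,long_min Class boundaries (500 and 4000 bp).
#' @param contexts Contexts for the per-class levels.
#' @return Tibble with one row per class: `n`, `fraction`, and optional
#'   `level_<ctx>` columns; per-TE assignments attached as attribute
#'   `classes`.
#' @export
classify_te_lengths <- function(tes, sample = NULL, short_max = 500L,
                                long_min = 4000L,
                                contexts = c("CG", "CHG", "CHH")) {
  tes <- as_tibble(tes)
  if (!nrow(tes)) abort("`tes` is empty.")
  len <- tes$end - tes$start
  if (any(len <= 0)) abort("Zero-length TE encountered.")
  tes$length <- len
  tes$te_length_class <- ifelse(len < short_max, "short",
                                ifelse(len > long_min, "long", "medium"))
  out <- tibble(te_length_class = c("short", "medium", "long")) |>
    left_join(count(tes, .data$te_length_class), by = "te_length_class") |>
    mutate(n = coalesce(.data$n, 0L), fraction = .data$n / nrow(tes))
  if (!is.null(sample)) {
    for (ctx in contexts) {
      lv <- purrr::map_dbl(out$te_length_class, function(cl) {
        iv <- filter(tes, .data$te_length_class == cl)
        if (!nrow(iv)) return(NA_real_)
        weighted_level(semi_join_sites(sample, iv, ctx))
      })
      out[[paste0("level_", ctx)]] <- lv
    }
  }
  structure(out, classes = tes, class = class(tibble()))
}

# Sites of one context falling inside any of the given regions.
semi_join_sites <- function(sample, regions, context) {
  ctx <- context
  sites <- as_tibble(validate_sites(sample)) |> filter(.data$context == ctx)
  if (!nrow(sites) || !nrow(regions)) return(sites[0, ])
  hit <- findOverlaps(sites_granges(sites), regions_granges(as_tibble(regions)))
  sites[unique(queryHits(hit)), ]
}

#' Per-subgenome methylation and siRNA summary
#'
#' Groups chromosomes by the leading letter of their name (the A/D
#' subgenome convention of allotetraploid cotton); anything else lands in
#' an `unassigned` group with a warning. Reports pooled levels per context
#' and, optionally, 24-nt siRNA locus counts per subgenome.
#'
#' @param sample A [methylome()].
#' @param loci Optional siRNA locus tibble.
#' @param contexts Contexts to summarise.
#' @return Tibble: `subgenome`, `level_<ctx>` columns, `n_sirna_loci`
#'   (when `loci` given).
#' @export
subgenome_summary <- function(sample, loci = NULL,
                              contexts = c("CG", "CHG", "CHH")) {
  sites <- as_tibble(validate_sites(sample))
  sub_of <- function(chrom) {
    first <- toupper(substr(chrom, 1, 1))
    ifelse(first %in% c("A", "D"), first, "unassigned")
  }
  sites$subgenome <- sub_of(sites$chrom)
  if (any(sites$subgenome == "unassigned")) {
    warn("Chromosome(s) without A/D prefix grouped as 'unassigned'.")
  }
  out <- distinct(sites["subgenome"]) |> arrange(.data$subgenome)
  for (ctx in contexts) {
    lv <- sites |>
      filter(.data$context == ctx) |>
      group_by(.data$subgenome) |>
      summarise(level = ifelse(sum(.data$count_m + .data$count_u) > 0,
                               sum(.data$count_m) /
                                 sum(.data$count_m + .data$count_u), NA_real_),
                .groups = "drop")
    out <- left_join(out, lv, by = "subgenome")
    names(out)[names(out) == "level"] <- paste0("level_", ctx)
  }
  if (!is.null(loci)) {
    loci <- as_tibble(loci)
    loci$subgenome <- sub_of(loci$chrom)
    out <- left_join(out, count(loci, .data$subgenome, name = "n_sirna_loci"),
                     by = "subgenome") |>
      mutate(n_sirna_loci = coalesce(.data$n_sirna_loci, 0L))
  }
  out
}

#' Fractions of small RNAs by length
#'
#' @param lengths Integer vector of small-RNA lengths (nt), or a data frame
#'   with a `length` column.
#' @return Tibble `length`, `n`, `fraction` (fractions sum to 1); an empty
#'   input yields an empty tibble flagged with attribute `empty`.
#' @export
sirna_length_fractions <- function(lengths) {
  if (is.data.frame(lengths)) lengths <- lengths$length
  if (!length(lengths)) {
    return(structure(tibble(length = integer(0), n = integer(0),
                            fraction = numeric(0)), empty = TRUE,
                     class = class(tibble())))
  }
  if (any(lengths <= 0)) abort("Lengths must be positive.")
  tibble(length = lengths) |>
    count(.data$length) |>
    mutate(fraction = .data$n / sum(.data$n))
}

#' Correlation of feature length with body methylation
#'
#' Pearson correlation between feature length and the pooled body
#' methylation level, per context. Features with undefined levels are
#' excluded and counted; fewer than 3 usable features yields `NA` with a
#' warning.
#'
#' @param features Feature tibble.
#' @param sample A [methylome()].
#' @param contexts Contexts to correlate.
#' @return Tibble: `context`, `pearson_r`, `n_used`, `n_excluded`.
#' @export
length_methylation_correlation <- function(features, sample,
                                           contexts = c("CG", "CHG", "CHH")) {
  feats <- as_tibble(features)
  purrr::map(contexts, function(ctx) {
    lv <- region_level(sample, feats[c("chrom", "start", "end")], context = ctx)
    ok <- !is.na(lv$level)
    if (sum(ok) < 3) {
      warn(paste0("Fewer than 3 ", ctx, " features with defined levels."))
      return(tibble(context = ctx, pearson_r = NA_real_,
                    n_used = sum(ok), n_excluded = sum(!ok)))
    }
    len <- (feats$end - feats$start)[ok]
    tibble(context = ctx,
           pearson_r = if (sd(len) > 0 && sd(lv$level[ok]) > 0) {
             cor(len, lv$level[ok])
           } else NA_real_,
           n_used = sum(ok), n_excluded = sum(!ok))
  }) |> bind_rows()
}
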