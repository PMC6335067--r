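#' Configuration for the synthetic methylome generator
#'
#' Defines the study conditions the generator emulates: a miniature
#' two-subgenome genome (chromosome names carry A/D prefixes), annotated
#' protein-coding genes (PCGs) with exons, transposable elements (TEs) in
#' three length classes and TE-related genes (TEGs); context-stratified
#' methylation (CG high, CHG intermediate, CHH low); CHH islands upstream of
#' transcription start sites; planted context-specific DMRs; bisulfite read
#' counts with non-conversion error; 24-nt siRNA loci co-located with
#' CHH-hypermethylated regions; and gene expression negatively coupled to
#' promoter CHH methylation.
#'
#' Defaults: two 500-kb chromosomes (A01, D01), two samples (WT, R0),
#' per-site true levels Beta-distributed around context means
#' CG 0.75 / CHG 0.45 / CHH 0.08 (concentration 10; `Inf` gives
#' zero-variance levels exactly at the mean), Poisson(30) coverage,
#' non-conversion rate 0.006, a 500-bp CHH island adding 0.15 immediately
#' upstream of each TSS, 20 planted DMRs per context in the second sample
#' (CG -0.8, CHG +0.5, CHH +0.4, each bin holding at least 15 cytosines of
#' its context), 300 24-nt siRNA loci of which a fraction `sirna_coupling`
#' (0.8) falls inside CHH-hypermethylated DMR bins, and log2(FPKM+1)
#' expression with slope -4 on the true promoter CHH level and Gaussian
#' noise sd 0.5. Per-gene promoter CHH baselines are drawn
#' Beta(mean 0.25, concentration 2) so promoter methylation varies between
#' genes; without that between-gene variance the expression coupling would
#' be unidentifiable.
#'
#' @param seed Master seed; every output stream derives its own sub-seed
#'   from it, so regenerating one output does not perturb the others.
#' @param chroms Named vector of chromosome lengths (bp); names should carry
#'   the subgenome prefix letter.
#' @param samples Two or more sample labels; planted DMRs shift the sample
#'   named in the plan (by default the second).
#' @param n_genes,n_tes,n_tegs Feature counts per chromosome.
#' @param te_class_weights Sampling weights for short (<0.5 kb), medium and
#'   long (>4 kb) TEs.
#' @param context_means Named true mean levels for CG, CHG, CHH.
#' @param level_concentration Beta concentration of per-site true levels;
#'   `Inf` for zero variance.
#' @param chh_island List with `width` (bp upstream of the TSS) and `height`
#'   (added CHH level); set `height = 0` to disable.
#' @param promoter_chh `NULL`, or a list with `mean` and `concentration` for
#'   the per-gene Beta draw of the promoter CHH baseline (2-kb upstream).
#' @param mean_depth Mean per-site coverage.
#' @param overdispersion `NULL` for Poisson coverage, or a negative-binomial
#'   size parameter for over-dispersed coverage.
#' @param nonconversion_rate Probability an unmethylated C reads as C.
#' @param dmr_plan `NULL` to plan DMRs automatically from `n_dmrs`,
#'   `dmr_deltas` and `dmr_min_sites`, or a tibble with columns
#'   `chrom`, `start`, `end`, `context`, `delta`, `sample`.
#' @param n_dmrs,dmr_deltas Named per-context counts and signed level shifts
#'   for automatic DMR planning.
#' @param dmr_min_sites Minimum cytosines of the planted context per DMR bin.
#' @param n_sirna_loci,sirna_coupling Number of 24-nt siRNA loci and the
#'   probability each one is placed inside a CHH-hypermethylated DMR.
#' @param expression List with `slope` (on true promoter CHH level),
#'   `noise_sd`, `intercept` (log2(FPKM+1) scale) and `coupled` (`"all"` or a
#'   character vector of coupled gene ids; uncoupled genes get slope 0).
#'
#' @return A list with class `sim_config`.
#' @seealso [simulate_dataset()], [generate_genome()]
#' @export
sim_config <- function(seed = 1L,
                       chroms = c(A01 = 500000L, D01 = 500000L),
                       samples = c("WT", "R0"),
                       n_genes = 30L, n_tes = 60L, n_tegs = 8L,
                       te_class_weights = c(short = 0.54, medium = 0.45, long = 0.01),
                       context_means = c(CG = 0.75, CHG = 0.45, CHH = 0.08),
                       level_concentration = 10,
                       chh_island = list(width = 500L, height = 0.15),
                       promoter_chh = list(mean = 0.25, concentration = 2),
                       mean_depth = 30,
                       overdispersion = NULL,
                       nonconversion_rate = 0.006,
                       dmr_plan = NULL,
                       n_dmrs = c(CG = 20L, CHG = 20L, CHH = 20L),
                       dmr_deltas = c(CG = -0.8, CHG = 0.5, CHH = 0.4),
                       dmr_min_sites = 15L,
                       n_sirna_loci = 300L,
                       sirna_coupling = 0.8,
                       expression = list(slope = -4, noise_sd = 0.5,
                                         intercept = 6, coupled = "all")) {
  stopifnot(
    length(seed) == 1, !is.na(seed),
    length(chroms) >= 1, all(chroms > 0), !is.null(names(chroms)),
    length(samples) >= 2, !anyDuplicated(samples),
    all(context_means >= 0 & context_means <= 1),
    identical(sort(names(context_means)), c("CG", "CHG", "CHH")),
    level_concentration > 0,
    chh_island$width >= 0, chh_island$height >= 0, chh_island$height <= 1,
    mean_depth > 0,
    nonconversion_rate >= 0, nonconversion_rate < 1,
    sirna_coupling >= 0, sirna_coupling <= 1,
    is.numeric(expression$slope), expression$noise_sd >= 0
  )
  if (!is.null(promoter_chh)) {
    stopifnot(promoter_chh$mean > 0, promoter_chh$mean < 1,
              promoter_chh$concentration > 0)
  }
  if (is.null(dmr_plan)) {
    stopifnot(identical(sort(names(n_dmrs)), c("CG", "CHG", "CHH")),
              identical(sort(names(dmr_deltas)), c("CG", "CHG", "CHH")),
              all(abs(dmr_deltas) <= 1))
  }
  structure(
    list(seed = as.integer(seed), chroms = chroms, samples = samples,
         n_genes = n_genes, n_tes = n_tes, n_tegs = n_tegs,
         te_class_weights = te_class_weights,
         context_means = context_means,
         level_concentration = level_concentration,
         chh_island = chh_island, promoter_chh = promoter_chh,
         mean_depth = mean_depth, overdispersion = overdispersion,
         nonconversion_rate = nonconversion_rate,
         dmr_plan = dmr_plan, n_dmrs = n_dmrs, dmr_deltas = dmr_deltas,
         dmr_min_sites = dmr_min_sites,
         n_sirna_loci = n_sirna_loci, sirna_coupling = sirna_coupling,
         expression = expression),
    class = c("sim_config", "list"))
}

# Derive a reproducible sub-seed (< 2^31) for one output stream.
stream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647L)
}

#' Generate a miniature annotated genome
#'
#' Draws uniform-random chromosome sequences and places protein-coding genes
#' (with exons), TEs spanning the three length classes and TE-related genes,
#' all mutually non-overlapping. Feature capacity is checked against
#' chromosome length before placement.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_genome` with `chrom_lengths`, `sequences`
#'   (named character vector) and `features` (tibble with 0-based half-open
#'   `start`/`end`, `strand`, `feature_id`, `kind` in PCG/TE/TEG,
#'   `te_family`, and an `exons` list-column for gene kinds).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(stream_seed(config$seed, 1L), {
    seqs <- vapply(config$chroms, function(len) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    }, character(1))
    feats <- purrr::map(names(config$chroms), function(chrom) {
      place_features_one_chrom(chrom, config$chroms[[chrom]], config)
    })
    features <- bind_rows(feats)
  })
  structure(list(chrom_lengths = config$chroms, sequences = seqs,
                 features = features),
            class = "sim_genome")
}

place_features_one_chrom <- function(chrom, len, config) {
  w <- config$te_class_weights / sum(config$te_class_weights)
  te_class <- sample(names(w), config$n_tes, replace = TRUE, prob = w)
  te_len <- vapply(te_class, function(cl) {
    switch(cl,
           short  = round(runif(1, 100, 499)),
           medium = round(runif(1, 500, 3999)),
           long   = round(runif(1, 4001, 8000)))
  }, numeric(1))
  gene_len <- round(runif(config$n_genes, 1000, 4000))
  teg_len <- round(runif(config$n_tegs, 800, 3000))
  lens <- c(gene_len, teg_len, te_len)
  kinds <- c(rep("PCG", config$n_genes), rep("TEG", config$n_tegs),
             rep("TE", config$n_tes))
  if (sum(lens) * 1.6 > len) {
    abort(paste0("Requested features exceed chromosome capacity on ", chrom))
  }
  # greedy random placement, rejecting overlaps with already-placed features
  starts <- integer(length(lens))
  occ_s <- integer(0); occ_e <- integer(0)
  for (i in seq_along(lens)) {
    ok <- FALSE
    for (try in 1:500) {
      s <- floor(runif(1, 0, len - lens[i]))
      e <- s + lens[i]
      if (!any(s < occ_e & e > occ_s)) { ok <- TRUE; break }
    }
    if (!ok) abort(paste0("Could not place features on ", chrom,
                          "; reduce counts or lengths."))
    starts[i] <- s
    occ_s <- c(occ_s, s); occ_e <- c(occ_e, e)
  }
  strand <- sample(c("+", "-"), length(lens), replace = TRUE)
  strand[kinds == "TE"] <- sample(c("+", "-"), sum(kinds == "TE"), replace = TRUE)
  family <- rep(NA_character_, length(lens))
  family[kinds == "TE"] <- sample(c("Gypsy", "Copia", "LINE", "hAT", "Mutator"),
                                  sum(kinds == "TE"), replace = TRUE)
  ids <- character(length(lens))
  ids[kinds == "PCG"] <- sprintf("%s_G%04d", chrom, seq_len(config$n_genes))
  ids[kinds == "TEG"] <- sprintf("%s_TEG%03d", chrom, seq_len(config$n_tegs))
  ids[kinds == "TE"] <- sprintf("%s_TE%04d", chrom, seq_len(config$n_tes))
  exons <- purrr::pmap(list(starts, starts + lens, kinds), function(s, e, k) {
    if (k == "TE") return(NULL)
    make_exons(s, e)
  })
  tibble(chrom = chrom, start = starts, end = starts + as.integer(lens),
         strand = strand, feature_id = ids, kind = kinds,
         te_family = family, exons = exons) |>
    arrange(.data$start)
}

# Split a gene body into alternating exon/intron segments (first and last
# segments are exonic).
make_exons <- function(s, e) {
  n_ex <- sample(1:4, 1)
  if (n_ex == 1 || (e - s) < 2 * (2 * n_ex - 1)) return(tibble(start = s, end = e))
  cuts <- sort(sample(seq(s + 1L, e - 1L), 2 * n_ex - 2))
  bounds <- c(s, cuts, e)
  seg_s <- bounds[-length(bounds)]
  seg_e <- bounds[-1]
  keep <- seq_along(seg_s) %% 2 == 1
  tibble(start = as.integer(seg_s[keep]), end = as.integer(seg_e[keep]))
}

#' Extract cytosine positions and contexts from a simulated genome
#'
#' Scans both strands for cytosines (C on plus, G on minus) and assigns the
#' CG/CHG/CHH context from the 3-base triplet on the cytosine's strand.
#' Cytosines too close to a chromosome end to carry a full triplet are
#' skipped.
#'
#' @param genome A [generate_genome()] result.
#' @param contexts Optional subset of contexts to keep (saves memory when
#'   only one context is analysed).
#' @return A tibble with `chrom`, `pos` (1-based), `strand`, `context`,
#'   `triplet`.
#' @export
extract_cytosines <- function(genome, contexts = NULL) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- purrr::map(names(genome$sequences), function(chrom) {
    bases <- strsplit(genome$sequences[[chrom]], "", fixed = TRUE)[[1]]
    len <- length(bases)
    # plus strand: C with two following bases
    cp <- which(bases == "C")
    cp <- cp[cp <= len - 2L]
    trip_p <- paste0(bases[cp], bases[cp + 1L], bases[cp + 2L])
    # minus strand: G with two preceding bases; triplet read 5'->3' on minus
    gp <- which(bases == "G")
    gp <- gp[gp >= 3L]
    trip_m <- paste0(comp[bases[gp]], comp[bases[gp - 1L]], comp[bases[gp - 2L]])
    tibble(chrom = chrom,
           pos = c(cp, gp),
           strand = rep(c("+", "-"), c(length(cp), length(gp))),
           triplet = c(trip_p, trip_m))
  })
  sites <- bind_rows(out)
  sites$context <- assign_context(sites$triplet)
  if (!is.null(contexts)) sites <- filter(sites, .data$context %in% contexts)
  arrange(sites, .data$chrom, .data$pos, .data$strand)
}

#' Simulate true per-site methylation levels with planted DMRs
#'
#' Draws a shared baseline level per cytosine (Beta around the context mean,
#' with CHH-island and promoter elevation near gene TSSs), then applies the
#' planted DMR deltas to the designated sample only. Levels pushed outside
#' `[0, 1]` are clamped and flagged in the truth table, and the realised
#' per-bin deltas are recorded in the returned DMR table.
#'
#' @param genome A [generate_genome()] result.
#' @param config A [sim_config()].
#' @param contexts Optional context subset forwarded to
#'   [extract_cytosines()].
#' @return A list of class `sim_methylome`: `sites` (cytosine table with one
#'   `level_<sample>` column per sample and a `clamped` flag) and `dmrs`
#'   (planted DMR table with planned and realised deltas).
#' @export
generate_methylome <- function(genome, config, contexts = NULL) {
  stopifnot(inherits(genome, "sim_genome"), inherits(config, "sim_config"))
  sites <- extract_cytosines(genome, contexts = contexts)
  with_seed(stream_seed(config$seed, 2L), {
    mu <- unname(config$context_means[sites$context])

    genes <- filter(genome$features, .data$kind %in% c("PCG", "TEG"))
    if (nrow(genes)) {
      proms <- promoter_intervals(genes, promoter_len = 2000L)
      if (!is.null(config$promoter_chh)) {
        pc <- config$promoter_chh
        mu_gene <- rbeta(nrow(genes), pc$mean * pc$concentration,
                         (1 - pc$mean) * pc$concentration)
        hit <- findOverlaps(sites_granges(sites), regions_granges(proms))
        idx <- queryHits(hit)[sites$context[queryHits(hit)] == "CHH"]
        gidx <- subjectHits(hit)[sites$context[queryHits(hit)] == "CHH"]
        mu[idx] <- mu_gene[gidx]
      }
      isl <- config$chh_island
      if (isl$height > 0 && isl$width > 0) {
        prox <- proms
        up_plus <- prox$strand != "-"
        prox$start[up_plus] <- pmax(prox$end[up_plus] - isl$width, prox$start[up_plus])
        prox$end[!up_plus] <- pmin(prox$start[!up_plus] + isl$width, prox$end[!up_plus])
        hit <- findOverlaps(sites_granges(sites), regions_granges(prox))
        idx <- unique(queryHits(hit)[sites$context[queryHits(hit)] == "CHH"])
        mu[idx] <- mu[idx] + isl$height
      }
    }
    kap <- config$level_concentration
    base <- if (is.infinite(kap)) {
      pmin(pmax(mu, 0), 1)
    } else {
      # Beta parameters need means strictly inside (0, 1)
      mu_b <- pmin(pmax(mu, 1e-3), 1 - 1e-3)
      rbeta(length(mu), mu_b * kap, (1 - mu_b) * kap)
    }

    plan <- config$dmr_plan %||% plan_dmrs(sites, config)
    levels <- matrix(base, nrow = length(base), ncol = length(config$samples),
                     dimnames = list(NULL, config$samples))
    clamped <- logical(length(base))
    if (nrow(plan)) {
      hit <- findOverlaps(sites_granges(sites), regions_granges(plan))
      qi <- queryHits(hit); si <- subjectHits(hit)
      keep <- sites$context[qi] == plan$context[si]
      qi <- qi[keep]; si <- si[keep]
      for (s in unique(plan$sample)) {
        in_s <- plan$sample[si] == s
        shifted <- levels[qi[in_s], s] + plan$delta[si[in_s]]
        clamped[qi[in_s]] <- clamped[qi[in_s]] | shifted < 0 | shifted > 1
        levels[qi[in_s], s] <- pmin(pmax(shifted, 0), 1)
      }
      # realised per-bin mean level per sample and realised delta
      ref <- config$samples[1]
      plan$realized_delta <- vapply(seq_len(nrow(plan)), function(j) {
        sel <- qi[si == j]
        if (!length(sel)) return(NA_real_)
        mean(levels[sel, plan$sample[j]]) - mean(levels[sel, ref])
      }, numeric(1))
      plan$n_sites <- as.integer(tabulate(si, nbins = nrow(plan)))
    }
  })
  for (s in config$samples) sites[[paste0("level_", s)]] <- levels[, s]
  sites$clamped <- clamped
  structure(list(sites = sites, dmrs = plan), class = "sim_methylome")
}

# Pick non-overlapping 100-bp bins dense enough in each context to host the
# planted DMRs; guarantees every planted DMR meets the informative-cytosine
# precondition of the DMR caller.
plan_dmrs <- function(sites, config) {
  bin_size <- 100L
  chosen <- tibble(chrom = character(0), start = integer(0), end = integer(0),
                   context = character(0), delta = numeric(0),
                   sample = character(0))
  target <- config$samples[2]
  counts <- sites |>
    mutate(bin = ((.data$pos - 1L) %/% bin_size) * bin_size) |>
    count(.data$chrom, .data$bin, .data$context)
  for (ctx in c("CG", "CHG", "CHH")) {
    n_want <- config$n_dmrs[[ctx]]
    if (is.null(n_want) || n_want == 0) next
    cand <- filter(counts, .data$context == ctx, .data$n >= config$dmr_min_sites)
    cand <- anti_join(cand, chosen |> mutate(bin = .data$start),
                      by = c("chrom", "bin"))
    if (nrow(cand) < n_want) {
      abort(paste0("Only ", nrow(cand), " candidate bins with >= ",
                   config$dmr_min_sites, " ", ctx,
                   " cytosines; cannot plant ", n_want, " DMRs."))
    }
    pick <- cand[sample.int(nrow(cand), n_want), ]
    chosen <- bind_rows(chosen,
                        tibble(chrom = pick$chrom, start = pick$bin,
                               end = pick$bin + bin_size, context = ctx,
                               delta = unname(config$dmr_deltas[[ctx]]),
                               sample = target))
  }
  arrange(chosen, .data$chrom, .data$start)
}

#' Simulate bisulfite read counts for one sample
#'
#' Per site, coverage is drawn from the configured model (Poisson by
#' default) and the methylated-read count from
#' `Binomial(n, m + (1 - m) * r)`, where `m` is the true level and `r` the
#' non-conversion rate: non-conversion adds false methylation signal to
#' unmethylated cytosines but methylated cytosines are never falsely
#' converted, matching the unmethylated-lambda calibration model.
#'
#' @param truth A `sim_methylome` (or its `sites` tibble).
#' @param sample_name Which `level_<sample>` column to observe.
#' @param config A [sim_config()].
#' @return A [methylome()] for the sample (zero-coverage sites retained).
#' @export
simulate_bisulfite_counts <- function(truth, sample_name, config) {
  sites <- if (inherits(truth, "sim_methylome")) truth$sites else as_tibble(truth)
  lev_col <- paste0("level_", sample_name)
  if (!lev_col %in% names(sites)) {
    abort(paste0("No true levels for sample '", sample_name, "'."))
  }
  m <- sites[[lev_col]]
  stopifnot(all(m >= 0 & m <= 1))
  k <- match(sample_name, config$samples)
  with_seed(stream_seed(config$seed, 10L + k), {
    n <- if (is.null(config$overdispersion)) {
      rpois(length(m), config$mean_depth)
    } else {
      rnbinom(length(m), mu = config$mean_depth, size = config$overdispersion)
    }
    r <- config$nonconversion_rate
    cm <- rbinom(length(m), n, m + (1 - m) * r)
  })
  methylome(
    tibble(chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
           context = sites$context,
           count_m = as.integer(cm), count_u = as.integer(n - cm),
           triplet = if ("triplet" %in% names(sites)) sites$triplet else NA_character_),
    name = sample_name,
    nonconversion_rate = config$nonconversion_rate,
    chrom_lengths = config$chroms)
}

#' Simulate 24-nt siRNA loci
#'
#' Places merged 24-nt siRNA alignment loci so that a fraction
#' `sirna_coupling` of them falls inside CHH-hypermethylated planted DMR
#' bins (RdDM-like co-location) and the rest uniformly elsewhere.
#'
#' @param truth A `sim_methylome` (its planted DMR table supplies the
#'   CHH-hyper regions).
#' @param genome A [generate_genome()] result.
#' @param config A [sim_config()].
#' @return A BED-like tibble: `chrom`, `start`, `end` (0-based half-open),
#'   `locus_id`, `abundance`, `strand` (`"."`), `in_chh_hyper`.
#' @export
simulate_sirna_loci <- function(truth, genome, config) {
  hyper <- filter(truth$dmrs, .data$context == "CHH", .data$delta > 0)
  n <- config$n_sirna_loci
  lens <- c(24L, 48L, 72L, 96L)
  with_seed(stream_seed(config$seed, 3L), {
    inside <- if (nrow(hyper)) runif(n) < config$sirna_coupling else rep(FALSE, n)
    len <- sample(lens, n, replace = TRUE)
    chrom <- character(n); start <- integer(n)
    for (i in seq_len(n)) {
      if (inside[i]) {
        j <- sample.int(nrow(hyper), 1)
        w <- hyper$end[j] - hyper$start[j]
        li <- min(len[i], w)
        len[i] <- li
        chrom[i] <- hyper$chrom[j]
        start[i] <- hyper$start[j] + floor(runif(1, 0, w - li + 1))
      } else {
        repeat {
          ch <- sample(names(config$chroms), 1)
          s <- floor(runif(1, 0, config$chroms[[ch]] - len[i]))
          if (!nrow(hyper) ||
              !any(hyper$chrom == ch & s < hyper$end & (s + len[i]) > hyper$start)) {
            chrom[i] <- ch; start[i] <- s; break
          }
        }
      }
    }
    abundance <- rpois(n, 20) + 1L
  })
  tibble(chrom = chrom, start = start, end = start + len,
         locus_id = sprintf("sirna%04d", seq_len(n)),
         abundance = abundance, strand = ".", in_chh_hyper = inside) |>
    arrange(.data$chrom, .data$start)
}

#' Simulate an expression table coupled to promoter CHH methylation
#'
#' For each gene and sample, `log2(FPKM + 1)` is linear in the true promoter
#' (2-kb upstream) CHH methylation level plus Gaussian noise. A two-sample
#' log2 ratio and a synthetic p-value (normal test on the known noise sd)
#' are attached so the differential-expression filter can be exercised; the
#' p-values are simulation conveniences, not a re-implementation of an
#' RNA-Seq differential test.
#'
#' @param truth A `sim_methylome`.
#' @param genome A [generate_genome()] result.
#' @param config A [sim_config()]; `config$expression$coupled` may restrict
#'   the slope to a subset of gene ids.
#' @return A tibble: `gene_id`, one `fpkm_<sample>` column per sample,
#'   `log2_ratio` (second vs first sample), `p_value`; the true promoter
#'   levels used are attached as attribute `truth`.
#' @export
simulate_expression <- function(truth, genome, config) {
  genes <- filter(genome$features, .data$kind %in% c("PCG", "TEG"))
  if (!nrow(genes)) abort("Genome has no genes to express.")
  proms <- promoter_intervals(genes, promoter_len = 2000L)
  sites <- filter(truth$sites, .data$context == "CHH")
  hit <- findOverlaps(sites_granges(sites), regions_granges(proms))
  ex <- config$expression
  coupled <- if (identical(ex$coupled, "all")) genes$feature_id else ex$coupled
  slope_g <- ifelse(genes$feature_id %in% coupled, ex$slope, 0)
  y <- list(); x <- list()
  with_seed(stream_seed(config$seed, 4L), {
    for (s in config$samples) {
      lv <- sites[[paste0("level_", s)]]
      xs <- rep(NA_real_, nrow(genes))
      agg <- rowsum(lv[queryHits(hit)], subjectHits(hit))
      cnt <- tabulate(subjectHits(hit), nbins = nrow(genes))
      got <- as.integer(rownames(agg))
      xs[got] <- agg[, 1] / cnt[got]
      xs[is.na(xs)] <- 0  # promoter with no CHH cytosine: treated as level 0
      x[[s]] <- xs
      y[[s]] <- ex$intercept + slope_g * xs + rnorm(nrow(genes), 0, ex$noise_sd)
    }
  })
  s1 <- config$samples[1]; s2 <- config$samples[2]
  out <- tibble(gene_id = genes$feature_id)
  for (s in config$samples) out[[paste0("fpkm_", s)]] <- pmax(2^y[[s]] - 1, 0)
  out$log2_ratio <- y[[s2]] - y[[s1]]
  if (ex$noise_sd > 0) {
    z <- out$log2_ratio / (sqrt(2) * ex$noise_sd)
    out$p_value <- 2 * pnorm(-abs(z))
  } else {
    out$p_value <- ifelse(out$log2_ratio != 0, 0, 1)
  }
  attr(out, "truth") <- list(promoter_chh = x, slope = ex$slope,
                             noise_sd = ex$noise_sd, coupled = coupled)
  out
}

#' Simulate a complete study
#'
#' Chains genome, methylome truth, per-sample bisulfite counts, siRNA loci
#' and the expression table under one master seed (one derived stream per
#' output). Fixed seed implies byte-identical outputs.
#'
#' @param config A [sim_config()].
#' @param contexts Optional context subset for the methylome (memory saver).
#' @return A list of class `sim_dataset`: `config`, `genome`, `truth`
#'   (`sim_methylome`), `samples` (named list of [methylome()]s),
#'   `sirna_loci`, `expression`.
#' @export
simulate_dataset <- function(config = sim_config(), contexts = NULL) {
  genome <- generate_genome(config)
  truth <- generate_methylome(genome, config, contexts = contexts)
  samples <- lapply(config$samples, function(s) {
    simulate_bisulfite_counts(truth, s, config)
  })
  names(samples) <- config$samples
  sirna <- simulate_sirna_loci(truth, genome, config)
  expr <- simulate_expression(truth, genome, config)
  structure(list(config = config, genome = genome, truth = truth,
                 samples = samples, sirna_loci = sirna, expression = expr),
            class = "sim_dataset")
}

# Strand-aware promoter windows: [TSS - len, TSS) on the gene's strand,
# 0-based half-open, truncated at position 0.
promoter_intervals <- function(genes, promoter_len = 2000L) {
  plus <- genes$strand != "-"
  start <- ifelse(plus, pmax(genes$start - promoter_len, 0L), genes$end)
  end <- ifelse(plus, genes$start, genes$end + promoter_len)
  tibble(chrom = genes$chrom, start = as.integer(start), end = as.integer(end),
         strand = genes$strand, feature_id = genes$feature_id) |>
    filter(.data$end > .data$start)
}
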