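#' Run the whole simulate-call-DMR-profile-integrate pipeline
#'
#' Chains every stage of the analysis on a synthetic study and writes all
#' inputs, intermediates and results as plain-text tables under `outdir`:
#' cytosine reports, GFF3/BED annotations, per-sample calls and
#' composition, DMRs and DMCs per context, metagene/RdDM profiles, window
#' tracks, DMR annotation, promoter methylation, expression correlation,
#' k-means clusters, DEGs, siRNA gene groups, TE length classes and a
#' scalar summary. All randomness derives from `config$seed` (one stream
#' per output), so a fixed seed gives byte-identical files across runs.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if missing).
#' @param params A [meth_params()] bundle of analysis thresholds.
#' @return Invisibly, a list with the in-memory results and the written
#'   file paths.
#' @export
run_pipeline <- function(config = sim_config(), outdir, params = meth_params()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  path <- function(...) file.path(outdir, paste0(...))
  sim <- simulate_dataset(config)
  s1 <- config$samples[1]; s2 <- config$samples[2]
  files <- character(0)
  keep <- function(p) { files <<- c(files, p); p }

  # inputs as they would arrive from upstream tools
  for (s in config$samples) {
    write_cytosine_report(sim$samples[[s]], keep(path("report_", s, ".tsv")))
  }
  write_features_gff3(sim$genome$features, keep(path("genes.gff3")))
  write_bed(filter(sim$genome$features, .data$kind == "TE"),
            keep(path("tes.bed")))
  write_bed(sim$sirna_loci, keep(path("sirna_loci.bed")))
  write_expression(sim$expression, keep(path("expression.tsv")))
  readr::write_tsv(sim$truth$dmrs, keep(path("truth_dmrs.tsv")), progress = FALSE)

  # methylcytosine calling
  calls <- lapply(sim$samples, function(sm) {
    call_sites(sm, min_coverage = params$min_coverage_call,
               p_threshold = params$call_p_threshold,
               ratio_threshold = params$call_ratio_threshold)
  })
  comp <- bind_rows(lapply(calls, methylome_composition), .id = "sample")
  readr::write_tsv(comp, keep(path("composition.tsv")), progress = FALSE)
  sharing <- classify_sharing(calls)
  readr::write_tsv(attr(sharing, "summary"), keep(path("sharing_summary.tsv")),
                   progress = FALSE)

  # differential methylation
  dmr_sets <- list()
  for (ctx in c("CG", "CHG", "CHH")) {
    dmrs <- call_dmrs(sim$samples[[s1]], sim$samples[[s2]], context = ctx,
                      bin_size = params$dmr_bin_size,
                      min_informative = params$dmr_min_informative,
                      informative_min_reads = params$informative_min_reads,
                      fdr = params$dmr_fdr)
    dmr_sets[[ctx]] <- dmrs
    write_dmrs(dmrs, keep(path("dmrs_", ctx, ".tsv")))
  }
  dmcs <- call_dmcs(sim$samples[[s1]], sim$samples[[s2]],
                    dmc_delta = params$dmc_delta,
                    min_coverage = params$min_coverage_call)
  readr::write_tsv(dmcs, keep(path("dmcs.tsv")), progress = FALSE)

  # profiles
  genes <- filter(sim$genome$features, .data$kind == "PCG")
  tes <- filter(sim$genome$features, .data$kind == "TE")
  profs <- list()
  for (ctx in c("CG", "CHG", "CHH")) {
    for (kind in c("PCG", "TE", "TEG")) {
      fx <- filter(sim$genome$features, .data$kind == !!kind)
      if (!nrow(fx)) next
      pr <- metagene_profile(sim$samples[[s2]], fx, context = ctx,
                             flank = params$metagene_flank,
                             nbins = params$metagene_nbins)
      profs[[paste(ctx, kind)]] <- mutate(as_tibble(pr), kind = kind)
    }
  }
  readr::write_tsv(bind_rows(profs), keep(path("metagene_profiles.tsv")),
                   progress = FALSE)
  rddm <- rddm_profile(sim$samples[[s2]], sim$sirna_loci,
                       flank = params$rddm_flank, nbins = params$metagene_nbins)
  readr::write_tsv(as_tibble(rddm), keep(path("rddm_profile.tsv")),
                   progress = FALSE)
  track <- window_track(sim$samples[[s2]],
                        window = min(params$fine_window, min(config$chroms)),
                        step = max(params$fine_step,
                                   min(params$fine_window, min(config$chroms)) %/% 100),
                        loci = sim$sirna_loci, features = tes)
  readr::write_tsv(as_tibble(track), keep(path("window_track.tsv")),
                   progress = FALSE)
  te_classes <- classify_te_lengths(tes, sample = sim$samples[[s2]],
                                    short_max = params$te_short_max,
                                    long_min = params$te_long_min)
  readr::write_tsv(te_classes, keep(path("te_length_classes.tsv")),
                   progress = FALSE)
  subg <- subgenome_summary(sim$samples[[s2]], loci = sim$sirna_loci)
  readr::write_tsv(subg, keep(path("subgenome_summary.tsv")), progress = FALSE)

  # integration
  all_genes <- filter(sim$genome$features, .data$kind %in% c("PCG", "TEG"))
  ann <- annotate_dmrs(dmr_sets$CHH, sim$genome$features,
                       promoter_len = params$promoter_len,
                       te_short_max = params$te_short_max,
                       te_long_min = params$te_long_min)
  readr::write_tsv(ann, keep(path("dmr_annotation.tsv")), progress = FALSE)
  prom <- promoter_methylation(sim$samples[[s2]], all_genes,
                               promoter_len = params$promoter_len)
  readr::write_tsv(prom, keep(path("promoter_methylation.tsv")),
                   progress = FALSE)
  corr <- methylation_expression_correlation(prom, sim$expression,
                                             fpkm_col = paste0("fpkm_", s2))
  readr::write_tsv(corr, keep(path("expression_correlation.tsv")),
                   progress = FALSE)
  clusters <- cluster_expression(sim$expression,
                                 k = min(params$kmeans_k,
                                         nrow(sim$expression) %/% 2),
                                 seed = config$seed)
  readr::write_tsv(clusters, keep(path("expression_clusters.tsv")),
                   progress = FALSE)
  degs <- deg_filter(sim$expression, p = params$deg_p,
                     min_abs_log2fc = params$deg_min_abs_log2fc)
  readr::write_tsv(degs, keep(path("degs.tsv")), progress = FALSE)
  sirna_groups <- genes_by_sirna_overlap(all_genes, sim$sirna_loci,
                                         sim$samples[[s2]])
  readr::write_tsv(sirna_groups, keep(path("sirna_gene_groups.tsv")),
                   progress = FALSE)

  summary <- tibble(
    quantity = c("seed", "n_sites", "n_dmrs_CG", "n_dmrs_CHG", "n_dmrs_CHH",
                 "n_dmcs", "n_degs", "pearson_r", "signed_r_squared"),
    value = c(config$seed, nrow(sim$samples[[s1]]),
              nrow(dmr_sets$CG), nrow(dmr_sets$CHG), nrow(dmr_sets$CHH),
              nrow(dmcs), nrow(degs), corr$pearson_r, corr$signed_r_squared))
  readr::write_tsv(summary, keep(path("summary.tsv")), progress = FALSE)

  invisible(list(sim = sim, calls = calls, composition = comp,
                 sharing = sharing, dmrs = dmr_sets, dmcs = dmcs,
                 rddm = rddm, track = track, te_classes = te_classes,
                 subgenome = subg, annotation = ann, promoters = prom,
                 correlation = corr, clusters = clusters, degs = degs,
                 sirna_groups = sirna_groups, summary = summary,
                 files = files))
}
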