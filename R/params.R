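#' Analysis parameter defaults
#'
#' One bundle holding every threshold used across the pipeline, so a whole
#' analysis can be re-run under modified settings by editing a single list.
#' Individual functions expose the same values as arguments; `meth_params()`
#' is what [run_pipeline()] consumes.
#'
#' The defaults are the published operating points of the method:
#' methylcytosines require at least 3 reads, a one-sided binomial
#' P < 1e-5 against the non-conversion rate and a methylated ratio > 25%;
#' DMRs are 100-bp bins with at least 10 informative cytosines (covered by
#' more than 3 reads, i.e. >= 4) in each sample, Fisher's exact test and
#' Benjamini-Hochberg FDR < 0.05; DMCs need a context-specific absolute
#' level difference (CG 0.7, CHG 0.5, CHH 0.1); promoters and metagene
#' flanks span 2 kb (100 intervals per segment), RdDM-locus flanks 5 kb;
#' TEs are short below 0.5 kb and long above 4 kb; expression work uses 10
#' k-means clusters and the DEG filter P < 0.05 with |log2 ratio| >= 2.
#'
#' @param ... Named overrides for any default listed above.
#'
#' @return A named list of parameters with class `meth_params`.
#' @examples
#' meth_params(dmr_fdr = 0.01)$dmr_fdr
#' @export
meth_params <- function(...) {
  p <- list(
    min_coverage_call    = 3L,
    call_p_threshold     = 1e-5,
    call_ratio_threshold = 0.25,
    nonconversion_rate   = 0.006,
    dmr_bin_size         = 100L,
    dmr_min_informative  = 10L,
    informative_min_reads = 4L,
    dmr_fdr              = 0.05,
    dmc_delta            = c(CG = 0.7, CHG = 0.5, CHH = 0.1),
    promoter_len         = 2000L,
    metagene_flank       = 2000L,
    metagene_nbins       = 100L,
    rddm_flank           = 5000L,
    te_short_max         = 500L,
    te_long_min          = 4000L,
    kmeans_k             = 10L,
    deg_p                = 0.05,
    deg_min_abs_log2fc   = 2,
    circos_window        = 1e6,
    circos_step          = 2e5,
    fine_window          = 1e5,
    fine_step            = 1e3,
    sirna_len            = 24L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) {
      abort(paste0("Unknown parameter(s): ", paste(bad, collapse = ", ")))
    }
    p[names(dots)] <- dots
  }
  stopifnot(
    all(vapply(p[c("min_coverage_call", "dmr_bin_size", "dmr_min_informative",
                   "informative_min_reads", "promoter_len", "metagene_flank",
                   "metagene_nbins", "rddm_flank", "te_short_max",
                   "te_long_min", "kmeans_k", "sirna_len")],
               function(x) x > 0, logical(1))),
    identical(sort(names(p$dmc_delta)), c("CG", "CHG", "CHH")),
    all(p$dmc_delta > 0)
  )
  structure(p, class = c("meth_params", "list"))
}
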