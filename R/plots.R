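#' Plot a metagene / RdDM methylation profile
#'
#' Line plot of the per-bin pooled level over the upstream flank, scaled
#' body and downstream flank, with segment boundaries marked.
#'
#' @param object A `meta_profile` from [metagene_profile()] or
#'   [rddm_profile()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.meta_profile <- function(object, ...) {
  nbins <- attr(object, "nbins") %||% (nrow(object) %/% 3)
  ggplot(as_tibble(object), aes(x = .data$bin, y = .data$level)) +
    geom_line(na.rm = TRUE) +
    geom_vline(xintercept = c(nbins, 2 * nbins) + 0.5, linetype = "dashed",
               colour = "grey50") +
    labs(x = "bin (upstream | body | downstream)",
         y = paste0(object$context[1], " methylation level"),
         title = paste0("Methylation profile (", attr(object, "n_features"),
                        " features, ", attr(object, "flank"), "-bp flanks)")) +
    theme_minimal()
}

#' Plot a DMR set as delta against significance
#'
#' @param object A `dmr_set` from [call_dmrs()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.dmr_set <- function(object, ...) {
  cmp <- attr(object, "comparison") %||% c("A", "B")
  ggplot(as_tibble(object),
         aes(x = .data$delta, y = -log10(pmax(.data$q_value, 1e-300)),
             colour = .data$direction)) +
    geom_point(alpha = 0.6, na.rm = TRUE) +
    labs(x = paste0("level difference (", cmp[2], " - ", cmp[1], ")"),
         y = "-log10 q", colour = NULL,
         title = paste0(object$context[1], "-DMRs (", nrow(object),
                        " of ", attr(object, "n_tested"), " tested bins)")) +
    theme_minimal()
}

#' Plot standardized expression trajectories per k-means cluster
#'
#' @param object An `expr_clusters` from [cluster_expression()].
#' @param ... Ignored.
#' @return A ggplot of the cluster centroids across stages.
#' @export
autoplot.expr_clusters <- function(object, ...) {
  centers <- attr(object, "centers")
  dat <- as_tibble(centers, rownames = "cluster") |>
    pivot_longer(-"cluster", names_to = "stage", values_to = "z")
  dat$stage <- factor(dat$stage, levels = colnames(centers))
  ggplot(dat, aes(x = .data$stage, y = .data$z, group = .data$cluster)) +
    geom_line() +
    geom_point() +
    facet_wrap(~ .data$cluster) +
    labs(x = NULL, y = "standardized expression",
         title = paste0("k-means expression clusters (k = ",
                        attr(object, "k"), ")")) +
    theme_minimal()
}

#' Plot methylome composition by context
#'
#' Bar chart of the relative content of methylcytosines per context.
#'
#' @param composition A [methylome_composition()] result.
#' @return A ggplot.
#' @export
plot_composition <- function(composition) {
  ggplot(as_tibble(composition),
         aes(x = .data$context, y = .data$fraction_of_mc)) +
    geom_col() +
    labs(x = NULL, y = "fraction of methylcytosines") +
    theme_minimal()
}

#' Plot a sliding-window methylation track
#'
#' @param track A [window_track()] result.
#' @param context Context to draw.
#' @return A ggplot faceted by chromosome.
#' @export
plot_window_track <- function(track, context = "CHH") {
  col <- paste0("level_", context)
  if (!col %in% names(track)) abort(paste0("Track has no column ", col))
  ggplot(as_tibble(track),
         aes(x = (.data$start + .data$end) / 2, y = .data[[col]])) +
    geom_line(na.rm = TRUE) +
    facet_wrap(~ .data$chrom, ncol = 1, scales = "free_x") +
    labs(x = "position (bp)", y = paste0(context, " level")) +
    theme_minimal()
}
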