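#' Broom-style tidiers for methylbin result objects
#'
#' `tidy()` returns the per-observation or per-term table of a result;
#' `glance()` a one-row summary.
#'
#' @param x A `meth_expr_cor`, `te_balance`, `expr_clusters` or `dmr_set`
#'   object.
#' @param ... Ignored.
#' @return A tibble.
#' @name methylbin-tidiers
NULL

#' @rdname methylbin-tidiers
#' @export
tidy.meth_expr_cor <- function(x, ...) {
  tibble(term = "promoter_methylation",
         estimate = x$pearson_r,
         signed_r_squared = x$signed_r_squared,
         n = x$n)
}

#' @rdname methylbin-tidiers
#' @export
glance.meth_expr_cor <- function(x, ...) {
  tibble(pearson_r = x$pearson_r, signed_r_squared = x$signed_r_squared,
         n = x$n, fpkm_col = x$fpkm_col)
}

#' @rdname methylbin-tidiers
#' @export
tidy.te_balance <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p_value)
}

#' @rdname methylbin-tidiers
#' @export
glance.te_balance <- function(x, ...) {
  tibble(n_up = x$n_up, n_down = x$n_down, statistic = x$statistic,
         df = x$df, p.value = x$p_value)
}

#' @rdname methylbin-tidiers
#' @export
tidy.expr_clusters <- function(x, ...) {
  as_tibble(x)
}

#' @rdname methylbin-tidiers
#' @export
glance.expr_clusters <- function(x, ...) {
  tibble(k = attr(x, "k"), n_genes = nrow(x),
         tot_withinss = attr(x, "tot_withinss"), totss = attr(x, "totss"),
         seed = attr(x, "seed"))
}

#' @rdname methylbin-tidiers
#' @export
glance.dmr_set <- function(x, ...) {
  tibble(context = if (nrow(x)) x$context[1] else NA_character_,
         n_dmrs = nrow(x), n_tested = attr(x, "n_tested"),
         n_hyper = sum(x$direction == "hyper"),
         n_hypo = sum(x$direction == "hypo"),
         fdr = attr(x, "fdr"),
         comparison = paste(attr(x, "comparison"), collapse = "_vs_"))
}
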