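# Independent reference implementations used to validate the package's
# statistics, written from first principles (log-binomial-coefficient
# arithmetic, quadratic-time step-up) so they share no code path with the
# implementations they check.

# Upper binomial tail P(X >= m), X ~ Binomial(n, r), by explicit summation.
binom_tail_oracle <- function(m, n, r) {
  if (m <= 0) return(1)
  if (r == 0) return(0)
  k <- m:n
  sum(exp(lchoose(n, k) + k * log(r) + (n - k) * log1p(-r)))
}

# Two-sided Fisher p for [[ma, ua], [mb, ub]] by full enumeration of the
# hypergeometric support, vectorised over tables.
fisher_oracle_vec <- function(ma, ua, mb, ub) {
  n1 <- ma + ua; n2 <- mb + ub; m <- ma + mb
  lo <- pmax(0L, m - n2); hi <- pmin(n1, m)
  cnt <- hi - lo + 1L
  tid <- rep(seq_along(ma), cnt)
  k <- sequence(cnt, from = lo, by = 1L)
  logp <- lchoose(n1[tid], k) + lchoose(n2[tid], m[tid] - k) -
    lchoose(n1[tid] + n2[tid], m[tid])
  log_obs <- lchoose(n1, ma) + lchoose(n2, mb) - lchoose(n1 + n2, m)
  keep <- logp <= log_obs[tid] + log1p(1e-7)
  out <- numeric(length(ma))
  agg <- rowsum(exp(logp[keep]), tid[keep])
  out[as.integer(rownames(agg))] <- agg[, 1]
  pmin(out, 1)
}

# Quadratic-time Benjamini-Hochberg step-up.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (j in seq_len(m)) {
    cand <- vapply(j:m, function(l) p[o[l]] * m / l, numeric(1))
    q_sorted[j] <- min(1, min(cand))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Build a methylome from compact per-site vectors.
make_methylome <- function(pos, count_m, count_u, context = "CHH",
                           chrom = "A01", strand = "+", name = "s",
                           r = 0.006, chrom_lengths = NULL) {
  methylome(tibble::tibble(chrom = chrom, pos = as.integer(pos),
                           strand = strand, context = context,
                           count_m = as.integer(count_m),
                           count_u = as.integer(count_u)),
            name = name, nonconversion_rate = r,
            chrom_lengths = chrom_lengths)
}

# Small simulation shared by several module tests.
tiny_config <- function(seed = 7L, ...) {
  defaults <- list(seed = seed, chroms = c(A01 = 100000L, D01 = 100000L),
                   n_genes = 8L, n_tes = 15L, n_tegs = 3L,
                   n_dmrs = c(CG = 4L, CHG = 4L, CHH = 6L),
                   dmr_min_sites = 12L, n_sirna_loci = 50L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

tiny_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_dataset(tiny_config())
    cache
  }
})
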