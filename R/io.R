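#' Read a per-cytosine bisulfite report
#'
#' Reads the tab-separated cytosine-report dialect produced by standard
#' bisulfite callers: `chrom`, `pos` (1-based), `strand`, `count_m`,
#' `count_u`, `context`, `triplet`, no header by default. Gzip files are
#' handled transparently by extension. Validation is strict: malformed
#' lines, non-positive positions, negative counts, unknown strand or
#' context tokens, and duplicated `(chrom, pos, strand)` addresses are all
#' rejected with the offending line number rather than coerced.
#'
#' @param path Report file (`.tsv` or `.tsv.gz`).
#' @param name Sample label; defaults to the file stem.
#' @param nonconversion_rate Sample non-conversion rate, stored on the
#'   returned object.
#' @param chrom_lengths Optional named chromosome lengths.
#' @param header Set `TRUE` for files carrying a header line.
#' @return A [methylome()].
#' @export
read_cytosine_report <- function(path, name = NULL, nonconversion_rate = 0.006,
                                 chrom_lengths = NULL, header = FALSE) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  cn <- c("chrom", "pos", "strand", "count_m", "count_u", "context", "triplet")
  tab <- readr::read_tsv(path,
                         col_names = if (header) TRUE else cn,
                         col_types = cols(
                           chrom = col_character(), pos = col_double(),
                           strand = col_character(),
                           count_m = col_double(), count_u = col_double(),
                           context = col_character(), triplet = col_character()),
                         progress = FALSE, show_col_types = FALSE)
  if (header) {
    miss <- setdiff(cn[1:6], names(tab))
    if (length(miss)) abort(paste0("Report missing column(s): ",
                                   paste(miss, collapse = ", ")))
  }
  probs <- readr::problems(tab)
  line0 <- if (header) 1L else 0L
  if (nrow(probs)) {
    abort(paste0("Malformed report line ", probs$row[1] + line0, " in ", path))
  }
  bad_line <- function(i) abort(paste0("Invalid record at line ", i + line0,
                                       " of ", path))
  chk <- function(ok) { if (any(!ok)) bad_line(which(!ok)[1]) }
  chk(!is.na(tab$pos) & tab$pos >= 1 & tab$pos == floor(tab$pos))
  chk(!is.na(tab$count_m) & tab$count_m >= 0)
  chk(!is.na(tab$count_u) & tab$count_u >= 0)
  chk(tab$strand %in% c("+", "-"))
  chk(tab$context %in% c("CG", "CHG", "CHH"))
  dup <- duplicated(tab[c("chrom", "pos", "strand")])
  if (any(dup)) {
    abort(paste0("Duplicate site at line ", which(dup)[1] + line0, " of ", path))
  }
  tab$pos <- as.integer(tab$pos)
  tab$count_m <- as.integer(tab$count_m)
  tab$count_u <- as.integer(tab$count_u)
  methylome(tab,
            name = name %||% sub("\\.(tsv|txt)(\\.gz)?$", "", basename(path)),
            nonconversion_rate = nonconversion_rate,
            chrom_lengths = chrom_lengths)
}

#' Write a per-cytosine bisulfite report
#'
#' Inverse of [read_cytosine_report()]: tab-separated, headerless by
#' default, gzip by extension. Sites lacking a `triplet` column are written
#' with `"."` in that field.
#'
#' @param sample A [methylome()] or compatible site table.
#' @param path Output path.
#' @param header Write a header line (off by default, matching common
#'   tooling).
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(sample, path, header = FALSE) {
  sites <- validate_sites(sample)
  trip <- if ("triplet" %in% names(sites)) sites$triplet else rep(".", nrow(sites))
  trip[is.na(trip)] <- "."
  out <- tibble(chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
                count_m = sites$count_m, count_u = sites$count_u,
                context = sites$context, triplet = trip)
  readr::write_tsv(out, path, col_names = header, progress = FALSE)
  invisible(path)
}

#' Read gene/TE annotations from GFF3 or BED
#'
#' GFF3 (1-based inclusive) and BED (0-based half-open) records are both
#' mapped to the internal 0-based half-open convention. From GFF3, `gene`
#' records become features (kind from their `kind` attribute, defaulting to
#' PCG) and `exon` records are attached to their parent by ID; an exon
#' whose span falls outside its parent is dropped with a warning. From
#' BED6, every record becomes a TE feature, with the name field parsed as
#' `id` or `id:family`.
#'
#' @param path A `.gff3`/`.gff` or `.bed` file.
#' @return A feature tibble (`chrom`, 0-based `start`/`end`, `strand`,
#'   `feature_id`, `kind`, `te_family`, `exons` list-column).
#' @export
read_features <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path)
    nm <- mcols(gr)$name %||% sprintf("TE%05d", seq_along(gr))
    parts <- strsplit(nm, ":", fixed = TRUE)
    return(tibble(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = ifelse(as.character(GenomicRanges::strand(gr)) %in% c("+", "-"),
                      as.character(GenomicRanges::strand(gr)), "+"),
      feature_id = vapply(parts, `[`, character(1), 1),
      kind = "TE",
      te_family = vapply(parts, function(x) if (length(x) > 1) x[2] else NA_character_,
                         character(1)),
      exons = vector("list", length(gr))))
  }
  gr <- rtracklayer::import(path)
  md <- mcols(gr)
  is_gene <- md$type %in% c("gene", "transposable_element_gene")
  genes <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr))[is_gene],
    start = GenomicRanges::start(gr)[is_gene] - 1L,
    end = GenomicRanges::end(gr)[is_gene],
    strand = ifelse(as.character(GenomicRanges::strand(gr))[is_gene] == "-", "-", "+"),
    feature_id = as.character(md$ID[is_gene]),
    kind = if ("kind" %in% names(md)) {
      k <- as.character(md$kind[is_gene]); k[is.na(k)] <- "PCG"; k
    } else rep("PCG", sum(is_gene)),
    te_family = NA_character_)
  is_ex <- md$type == "exon"
  parent <- as.character(vapply(md$Parent[is_ex], function(p) {
    if (length(p)) p[1] else NA_character_
  }, character(1)))
  ex <- tibble(chrom = as.character(GenomicRanges::seqnames(gr))[is_ex],
               start = GenomicRanges::start(gr)[is_ex] - 1L,
               end = GenomicRanges::end(gr)[is_ex],
               parent = parent)
  orphan <- !ex$parent %in% genes$feature_id
  if (any(orphan)) {
    warn(paste0(sum(orphan), " exon(s) with unknown parent skipped in ", path))
    ex <- ex[!orphan, ]
  }
  pi <- match(ex$parent, genes$feature_id)
  outside <- ex$start < genes$start[pi] | ex$end > genes$end[pi] |
    ex$chrom != genes$chrom[pi]
  if (any(outside)) {
    warn(paste0(sum(outside), " exon(s) outside their parent span skipped in ",
                path))
    ex <- ex[!outside, ]
  }
  genes$exons <- lapply(genes$feature_id, function(id) {
    sub <- ex[ex$parent == id, c("start", "end")]
    if (nrow(sub)) arrange(sub, .data$start) else NULL
  })
  genes
}

#' Write gene features to GFF3 / intervals to BED6
#'
#' `write_features_gff3()` emits `gene` records (with a `kind` attribute)
#' and `exon` children; `write_bed()` emits BED6, encoding a TE family as
#' `id:family` in the name column. Internal 0-based half-open coordinates
#' are converted to each format's native dialect.
#'
#' @param features Feature tibble (gene kinds for GFF3).
#' @param intervals Interval tibble with `chrom`, `start`, `end` and
#'   optionally `feature_id`/`locus_id`, `te_family`, `abundance`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features_gff3 <- function(features, path) {
  genes <- filter(as_tibble(features), .data$kind %in% c("PCG", "TEG"))
  gr_g <- GRanges(genes$chrom, IRanges(genes$start + 1L, genes$end),
                  strand = genes$strand)
  mcols(gr_g)$type <- "gene"
  mcols(gr_g)$ID <- genes$feature_id
  mcols(gr_g)$kind <- genes$kind
  ex <- purrr::map2(genes$exons, seq_len(nrow(genes)), function(e, i) {
    if (is.null(e) || !nrow(e)) return(NULL)
    tibble(chrom = genes$chrom[i], start = e$start, end = e$end,
           strand = genes$strand[i], parent = genes$feature_id[i])
  }) |> bind_rows()
  gr_all <- gr_g
  if (nrow(ex)) {
    gr_e <- GRanges(ex$chrom, IRanges(ex$start + 1L, ex$end), strand = ex$strand)
    mcols(gr_e)$type <- "exon"
    mcols(gr_e)$ID <- NA_character_
    mcols(gr_e)$kind <- NA_character_
    mcols(gr_e)$Parent <- ex$parent
    mcols(gr_g)$Parent <- NA_character_
    gr_all <- c(gr_g, gr_e)
  }
  rtracklayer::export(gr_all, path, format = "gff3")
  invisible(path)
}

col_or <- function(x, nm, default = NULL) {
  if (nm %in% names(x)) x[[nm]] else default
}

#' @rdname write_features_gff3
#' @export
write_bed <- function(intervals, path) {
  x <- as_tibble(intervals)
  id <- col_or(x, "feature_id") %||% col_or(x, "locus_id") %||%
    sprintf("iv%05d", seq_len(nrow(x)))
  fam <- col_or(x, "te_family", rep(NA_character_, nrow(x)))
  nm <- ifelse(is.na(fam), id, paste0(id, ":", fam))
  strand <- col_or(x, "strand", rep(".", nrow(x)))
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GRanges(x$chrom, IRanges(x$start + 1L, x$end), strand = strand)
  mcols(gr)$name <- nm
  mcols(gr)$score <- as.numeric(col_or(x, "abundance", rep(0, nrow(x))))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read 24-nt siRNA loci (or any intervals) from BED
#'
#' @param path BED file.
#' @return Tibble with `chrom`, 0-based `start`/`end`, `locus_id`,
#'   `abundance`, `strand`.
#' @export
read_sirna_loci <- function(path) {
  gr <- rtracklayer::import(path)
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1L,
         end = GenomicRanges::end(gr),
         locus_id = as.character(mcols(gr)$name %||% sprintf("locus%05d", seq_along(gr))),
         abundance = as.numeric(mcols(gr)$score %||% rep(NA_real_, length(gr))),
         strand = {
           s <- as.character(GenomicRanges::strand(gr)); s[s == "*"] <- "."; s
         })
}

dmr_columns <- c("chrom", "start", "end", "context", "level_a", "level_b",
                 "delta", "p_value", "q_value", "direction")

#' Read/write DMR tables
#'
#' DMRs travel as a BED-like TSV with a header: `chrom`, `start`, `end`
#' (0-based half-open bin), `context`, `level_a`, `level_b`, `delta`,
#' `p_value`, `q_value`, `direction`. Writing then reading is an exact
#' inverse; an empty DMR set round-trips as a header-only file.
#'
#' @param dmrs A DMR tibble from [call_dmrs()].
#' @param path File path.
#' @return `write_dmrs()` returns `path` invisibly; `read_dmrs()` the tibble.
#' @export
write_dmrs <- function(dmrs, path) {
  miss <- setdiff(dmr_columns, names(dmrs))
  if (length(miss)) abort(paste0("DMR table missing column(s): ",
                                 paste(miss, collapse = ", ")))
  readr::write_tsv(as_tibble(dmrs)[, union(dmr_columns, names(dmrs))], path,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_dmrs
#' @export
read_dmrs <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = cols(chrom = col_character(),
                                          context = col_character(),
                                          direction = col_character()))
  miss <- setdiff(dmr_columns, names(tab))
  if (length(miss)) abort(paste0("DMR file missing column(s): ",
                                 paste(miss, collapse = ", ")))
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  tab
}

#' Read a gene expression table
#'
#' Requires `gene_id`, `p_value`, `log2_ratio` and at least one
#' `fpkm_<sample>` column; missing requirements are rejected by name.
#'
#' @param path TSV file.
#' @return The expression tibble.
#' @export
read_expression <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("gene_id", "p_value", "log2_ratio")) {
    if (!col %in% names(tab)) {
      abort(paste0("Expression table is missing required column \"", col, "\""))
    }
  }
  if (!any(grepl("^fpkm_", names(tab)))) {
    abort("Expression table is missing required column \"fpkm_<sample>\"")
  }
  tab
}

#' @rdname read_expression
#' @param expression Expression tibble to write.
#' @export
write_expression <- function(expression, path) {
  readr::write_tsv(as_tibble(expression), path, progress = FALSE)
  invisible(path)
}
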