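#' Reads per kilobase of feature per million mapped reads
#'
#' `rpkm = 1e9 * count / (library_size * length_bp)`: read counts normalized
#' by sequencing depth and feature length. Vectorized over `count` and
#' `length_bp`.
#'
#' @param count Non-negative read count(s).
#' @param length_bp Feature length(s) in nucleotides, > 0.
#' @param library_size Total mapped reads in the library, > 0.
#' @return RPKM value(s).
#' @export
rpkm <- function(count, length_bp, library_size) {
  if (any(library_size <= 0)) stop("library_size must be positive")
  if (any(length_bp <= 0)) stop("length_bp must be positive")
  if (any(count < 0)) stop("counts must be non-negative")
  1e9 * count / (library_size * length_bp)
}

#' Per-ORF expression table with RPKM and median-relativized expression
#'
#' Computes RPKM for every ORF and relativizes each ORF's RPKM by the median
#' RPKM of its genome (all predicted ORFs of the genome enter the median,
#' including zero-count ones; an even ORF count uses the mean of the two
#' middle values). A relative expression of 1 marks median expression within
#' the genome. Genomes whose median RPKM is 0 (at least half the ORFs
#' unexpressed) get `rel_expr = NA` with a warning — zeros are never imputed.
#'
#' @param ct A `count_table`.
#' @param orfs An [orf_table].
#' @return data.frame of class `expression_table` with columns `orf_id`,
#'   `bin_id`, `library_id`, `count`, `length_bp`, `rpkm`, `rel_expr`;
#'   attribute `"medians"` holds per-genome median RPKM.
#' @export
expression_table <- function(ct, orfs) {
  stopifnot(inherits(ct, "count_table"))
  fc <- ct$feature_counts
  len <- stats::setNames(orfs$length_bp, orfs$orf_id)[fc$orf_id]
  if (any(is.na(len))) stop("count table contains ORFs absent from the ORF table")
  df <- data.frame(orf_id = fc$orf_id, bin_id = fc$bin_id,
                   library_id = ct$library_id,
                   count = fc$count, length_bp = unname(len),
                   stringsAsFactors = FALSE)
  df$rpkm <- rpkm(df$count, df$length_bp, ct$library_size)
  df <- relative_expression(df)
  class(df) <- c("expression_table", "data.frame")
  df
}

#' Relativize per-ORF RPKM by the genome median
#'
#' @param df data.frame with `orf_id`, `bin_id`, `rpkm`.
#' @return Same data.frame with `rel_expr` added and a `"medians"` attribute
#'   (`bin_id`, `median_rpkm`, `n_orfs`, `undefined`).
#' @export
relative_expression <- function(df) {
  stopifnot(all(c("orf_id", "bin_id", "rpkm") %in% names(df)))
  med <- vapply(split(df$rpkm, df$bin_id), stats::median, numeric(1))
  medians <- data.frame(bin_id = names(med), median_rpkm = unname(med),
                        n_orfs = as.integer(table(df$bin_id)[names(med)]),
                        undefined = unname(med) == 0,
                        stringsAsFactors = FALSE)
  if (any(medians$undefined)) {
    warning("genome median RPKM is 0 for: ",
            paste(medians$bin_id[medians$undefined], collapse = ", "),
            "; relative expression undefined (NA) there")
  }
  m <- med[df$bin_id]
  df$rel_expr <- ifelse(m > 0, df$rpkm / m, NA_real_)
  attr(df, "medians") <- medians
  df
}

#' Per-genome median RPKM of an expression table
#' @param expr An [expression_table].
#' @return data.frame `bin_id`, `median_rpkm`, `n_orfs`, `undefined`.
#' @export
genome_medians <- function(expr) {
  attr(expr, "medians")
}

#' Community abundance/expression profile from genome-level read densities
#'
#' For each genome, the length-normalized read density is the total number of
#' reads mapped to the genome divided by the genome length (read count /
#' genome size); fractions are densities normalized over the included bins.
#' Computed independently per library, so a DNA library yields relative
#' abundance and an mRNA library yields relative gene expression.
#'
#' @param count_tables A `count_table` or list of them (e.g. DNA and RNA).
#' @param gs A [genome_set].
#' @param include Bins to include; default all binned genomes.
#' @param include_unbinned Include the `"unbinned"` pool as a pseudo-bin.
#' @return data.frame of class `community_profile`: `bin_id`, `library_id`,
#'   `read_count`, `read_density` (reads/bp), `fraction`.
#' @export
community_profile <- function(count_tables, gs, include = NULL,
                              include_unbinned = FALSE) {
  if (inherits(count_tables, "count_table")) count_tables <- list(count_tables)
  if (is.null(include)) {
    include <- gs$bins$bin_id
    if (include_unbinned) include <- c(include, "unbinned")
  }
  include <- setdiff(include, if (!include_unbinned) "unbinned" else character(0))
  if (!length(include)) stop("empty bin include list")
  glen <- stats::setNames(gs$bins$total_length_bp, gs$bins$bin_id)
  if (include_unbinned && !"unbinned" %in% names(glen)) {
    stop("include_unbinned requires unbinned contigs in the genome set")
  }
  out <- do.call(rbind, lapply(count_tables, function(ct) {
    cnt <- stats::setNames(ct$genome_counts$count, ct$genome_counts$bin_id)
    cnt <- ifelse(is.na(cnt[include]), 0, cnt[include])
    dens <- unname(cnt / glen[include])
    data.frame(bin_id = include, library_id = ct$library_id,
               read_count = as.integer(cnt),
               read_density = dens,
               fraction = dens / sum(dens),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("community_profile", "data.frame")
  out
}

#' Most highly expressed ORFs of a genome relative to its median
#'
#' Stable sort by relative expression, descending; ties broken by lexical
#' `orf_id`. Reproduces the screen for genes maintained tens of fold above
#' median expression (e.g. hydrazine synthase / hydrazine dehydrogenase in
#' an anammox genome).
#'
#' @param expr An [expression_table].
#' @param bin_id Genome to rank.
#' @param k Number of ORFs to return; larger than the genome returns all.
#' @return data.frame subset of `expr`, ranked.
#' @export
top_expressed <- function(expr, bin_id, k = 10) {
  sub <- expr[expr$bin_id == bin_id, , drop = FALSE]
  if (!nrow(sub)) stop("no ORFs for bin ", bin_id)
  ord <- order(-sub$rel_expr, sub$orf_id)
  out <- sub[ord, , drop = FALSE][seq_len(min(k, nrow(sub))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an expression table as TSV
#' @param expr An [expression_table].
#' @param path Output path.
#' @export
write_expression_table <- function(expr, path) {
  cols <- c("orf_id", "bin_id", "library_id", "count", "length_bp", "rpkm", "rel_expr")
  write_tsv(as.data.frame(expr)[, cols], path)
}
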