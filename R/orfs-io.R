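#' Build an ORF table from parsed coordinates
#'
#' Internal coordinates are 0-based half-open (`start0`, `end0`); GFF3 I/O
#' converts at the boundary. `length_bp` is the GFF length (end - start + 1).
#'
#' @param df data.frame with `orf_id`, `contig_id`, `start0`, `end0`,
#'   `strand` ("+"/"-"), optional `product`.
#' @param min_length_bp ORFs shorter than this are dropped with a warning
#'   (gene callers in this pipeline emit nothing under 60 nt).
#' @return data.frame of class `orf_table`, sorted by (contig, start).
#' @export
orf_table <- function(df, min_length_bp = 60) {
  stopifnot(all(c("orf_id", "contig_id", "start0", "end0", "strand") %in% names(df)))
  df <- data.frame(orf_id = as.character(df$orf_id),
                   contig_id = as.character(df$contig_id),
                   start0 = as.numeric(df$start0),
                   end0 = as.numeric(df$end0),
                   strand = as.character(df$strand),
                   product = if ("product" %in% names(df)) as.character(df$product) else "",
                   stringsAsFactors = FALSE)
  if (any(df$end0 <= df$start0)) stop("ORF with end <= start")
  if (!all(df$strand %in% c("+", "-"))) stop("ORF strand must be '+' or '-'")
  if (anyDuplicated(df$orf_id)) stop("duplicate orf_id")
  df$length_bp <- df$end0 - df$start0
  short <- df$length_bp < min_length_bp
  if (any(short)) {
    warning(sprintf("excluding %d ORF(s) shorter than %d nt: %s",
                    sum(short), min_length_bp,
                    paste(utils::head(df$orf_id[short], 5), collapse = ", ")))
    df <- df[!short, , drop = FALSE]
  }
  df <- df[order(df$contig_id, df$start0, df$orf_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("orf_table", "data.frame")
  df
}

#' Read ORF coordinates from a GFF3 file
#'
#' CDS features with an `ID` attribute (the locus tag) are read; 1-based
#' inclusive GFF coordinates become 0-based half-open internally. CDS
#' shorter than `min_length_bp` (default 60 nt) are excluded with a warning;
#' a CDS on a contig not present in `genome_set` is a hard error.
#'
#' @param path GFF3 file.
#' @param genome_set Optional [genome_set] used to validate contig ids.
#' @param min_length_bp Minimum CDS nucleotide length retained.
#' @return An [orf_table].
#' @export
read_gff3 <- function(path, genome_set = NULL, min_length_bp = 60) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == "CDS"]
  if (!length(gr)) stop("no CDS features in ", path)
  ids <- as.character(gr$ID)
  if (any(is.na(ids) | ids == "")) stop("CDS feature without ID attribute in ", path)
  product <- if (!is.null(gr$product)) as.character(gr$product) else ""
  product[is.na(product)] <- ""
  df <- data.frame(orf_id = ids,
                   contig_id = as.character(GenomicRanges::seqnames(gr)),
                   start0 = GenomicRanges::start(gr) - 1,
                   end0 = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   product = product,
                   stringsAsFactors = FALSE)
  if (!all(df$strand %in% c("+", "-"))) stop("CDS with undefined strand in ", path)
  if (!is.null(genome_set)) {
    unknown <- setdiff(df$contig_id, genome_set$contigs$contig_id)
    if (length(unknown)) {
      stop("CDS on contig(s) absent from the genome set: ",
           paste(unknown, collapse = ", "))
    }
  }
  orf_table(df, min_length_bp = min_length_bp)
}

#' Write an ORF table as canonical GFF3
#'
#' Emits one CDS line per ORF with `ID` and `product` attributes, converting
#' internal 0-based half-open coordinates back to GFF3 1-based inclusive.
#' @param orfs An [orf_table].
#' @param path Output path.
#' @param source Value for the GFF source column.
#' @export
write_gff3 <- function(orfs, path, source = "granuletx") {
  stopifnot(inherits(orfs, "orf_table"))
  orfs <- orfs[order(orfs$contig_id, orfs$start0, orfs$orf_id), , drop = FALSE]
  attrs <- sprintf("ID=%s", orfs$orf_id)
  has_prod <- !is.na(orfs$product) & orfs$product != ""
  attrs[has_prod] <- paste0(attrs[has_prod], ";product=",
                            gsub("[;=\t\n]", " ", orfs$product[has_prod]))
  lines <- sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                   orfs$contig_id, source,
                   as.integer(orfs$start0 + 1), as.integer(orfs$end0),
                   orfs$strand, attrs)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
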