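# SAM text subset reader. Scope: single-end records (libraries are merged
# upstream), plain-text SAM with @SQ header lines, CIGAR ops MIDNSHP=X.
# Identity is computed as 1 - NM / aligned_read_length, where
# aligned_read_length counts M/I/=/X bases (soft-clipped bases excluded);
# this definition is the reader's contract, stated here rather than guessed
# from any particular mapper's reporting.

parse_cigar <- function(cigar, pos0) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))
  n <- length(cigar)
  blocks <- vector("list", n)
  read_len <- numeric(n)
  ref_span <- numeric(n)
  for (i in seq_len(n)) {
    op <- substring(ops[[i]], nchar(ops[[i]]), nchar(ops[[i]]))
    len <- as.numeric(substring(ops[[i]], 1, nchar(ops[[i]]) - 1))
    read_len[i] <- sum(len[op %in% c("M", "I", "=", "X")])
    consumes_ref <- op %in% c("M", "D", "N", "=", "X")
    ref_span[i] <- sum(len[consumes_ref])
    # aligned blocks: maximal runs of reference-consuming match ops,
    # split at D (deletion) and N (skip)
    p <- pos0[i]
    bs <- be <- numeric(0)
    open <- FALSE
    for (j in seq_along(op)) {
      if (op[j] %in% c("M", "=", "X")) {
        if (!open) {
          bs <- c(bs, p); be <- c(be, p + len[j]); open <- TRUE
        } else {
          be[length(be)] <- be[length(be)] + len[j]
        }
        p <- p + len[j]
      } else if (op[j] %in% c("D", "N")) {
        p <- p + len[j]
        open <- FALSE
      }
      # I, S, H, P consume no reference
    }
    blocks[[i]] <- cbind(start0 = bs, end0 = be)
  }
  list(blocks = blocks, read_len = read_len, ref_span = ref_span)
}

sam_tag <- function(fields, tag) {
  # fields: character vector of optional columns for one record
  hit <- fields[startsWith(fields, paste0(tag, ":"))]
  if (!length(hit)) return(NA_character_)
  sub("^[A-Za-z0-9]{2}:[AifZHB]:", "", hit[1])
}

#' Read single-end alignments from a SAM text file
#'
#' Parses mapped records, derives aligned blocks from the CIGAR string, and
#' filters on alignment identity. Identity is `1 - NM / aligned_read_length`
#' (M/I/=/X bases); records without an NM tag are dropped with a warning by
#' default. Unmapped and identity-filtered records are counted, not returned.
#'
#' @param path SAM file.
#' @param min_identity Minimum alignment identity retained (default 0.95, the
#'   species-level mapping threshold the pipeline assumes upstream).
#' @param on_missing_identity `"drop"` (default) or `"accept"` records with
#'   no NM tag.
#' @return An `alignment_set`: list with `records` (data.frame: `read_id`,
#'   `contig_id`, `start0`, `end0` footprint, `strand`, `identity`,
#'   `n_best_hits`, list-column `blocks`) and `totals`
#'   (`n_unmapped`, `n_filtered_identity`, `n_missing_identity`, `n_records`).
#' @export
read_sam <- function(path, min_identity = 0.95,
                     on_missing_identity = c("drop", "accept")) {
  on_missing_identity <- match.arg(on_missing_identity)
  stopifnot(min_identity >= 0, min_identity <= 1)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  sq <- hdr[startsWith(hdr, "@SQ")]
  contigs_in_header <- sub("^SN:", "",
                           vapply(strsplit(sq, "\t"),
                                  function(f) f[startsWith(f, "SN:")][1],
                                  character(1)))
  if (!length(body)) {
    return(structure(list(
      records = empty_alignment_records(),
      totals = list(n_unmapped = 0L, n_filtered_identity = 0L,
                    n_missing_identity = 0L, n_records = 0L)),
      class = "alignment_set"))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  flag <- vapply(fields, function(f) as.integer(f[2]), integer(1))
  rname <- vapply(fields, function(f) f[3], character(1))
  unmapped <- bitwAnd(flag, 4L) > 0L | rname == "*"
  n_unmapped <- sum(unmapped)
  fields <- fields[!unmapped]
  flag <- flag[!unmapped]
  rname <- rname[!unmapped]
  unknown <- setdiff(unique(rname), contigs_in_header)
  if (length(unknown)) {
    stop("SAM record(s) reference contig(s) absent from the header: ",
         paste(unknown, collapse = ", "))
  }
  qname <- vapply(fields, function(f) f[1], character(1))
  pos0 <- vapply(fields, function(f) as.numeric(f[4]), numeric(1)) - 1
  cigar <- vapply(fields, function(f) f[6], character(1))
  opt <- lapply(fields, function(f) if (length(f) > 11) f[12:length(f)] else character(0))
  nm <- suppressWarnings(as.numeric(vapply(opt, sam_tag, character(1), tag = "NM")))
  nh <- suppressWarnings(as.integer(vapply(opt, sam_tag, character(1), tag = "NH")))
  nh[is.na(nh)] <- 1L
  cig <- parse_cigar(cigar, pos0)
  identity <- 1 - nm / cig$read_len

  missing_id <- is.na(identity)
  n_missing <- sum(missing_id)
  if (n_missing && on_missing_identity == "drop") {
    warning(sprintf("dropping %d record(s) with no computable identity (no NM tag)",
                    n_missing))
    keep0 <- !missing_id
  } else {
    if (n_missing) identity[missing_id] <- 1 # accepted as-is
    keep0 <- rep(TRUE, length(identity))
  }
  low <- keep0 & identity < min_identity
  keep <- keep0 & !low
  records <- data.frame(read_id = qname[keep],
                        contig_id = rname[keep],
                        start0 = pos0[keep],
                        end0 = pos0[keep] + cig$ref_span[keep],
                        strand = ifelse(bitwAnd(flag[keep], 16L) > 0L, "-", "+"),
                        identity = identity[keep],
                        n_best_hits = nh[keep],
                        stringsAsFactors = FALSE)
  records$blocks <- cig$blocks[keep]
  structure(list(records = records,
                 totals = list(n_unmapped = as.integer(n_unmapped),
                               n_filtered_identity = as.integer(sum(low)),
                               n_missing_identity = as.integer(n_missing),
                               n_records = nrow(records))),
            class = "alignment_set")
}

empty_alignment_records <- function() {
  df <- data.frame(read_id = character(0), contig_id = character(0),
                   start0 = numeric(0), end0 = numeric(0),
                   strand = character(0), identity = numeric(0),
                   n_best_hits = integer(0), stringsAsFactors = FALSE)
  df$blocks <- list()
  df
}

#' @export
print.alignment_set <- function(x, ...) {
  cat(sprintf("alignment_set: %d record(s) kept (%d unmapped, %d identity-filtered, %d no-identity)\n",
              x$totals$n_records, x$totals$n_unmapped,
              x$totals$n_filtered_identity, x$totals$n_missing_identity))
  invisible(x)
}

#' Write single-end perfect-CIGAR records as SAM text
#'
#' Used by the simulator; every record is a single `<len>M` block with an
#' explicit `NM` tag.
#' @param reads data.frame with `read_id`, `contig_id`, `start0`, `length`,
#'   `strand`, and optional `nm` (edit distance, default 0).
#' @param contigs data.frame with `contig_id`, `length_bp` for the header.
#' @param path Output path.
#' @export
write_sam <- function(reads, contigs, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", contigs$contig_id,
                   as.integer(contigs$length_bp)))
  if (!nrow(reads)) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  nm <- if ("nm" %in% names(reads)) reads$nm else 0L
  lines <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*\tNM:i:%d",
                   reads$read_id,
                   ifelse(reads$strand == "-", 16L, 0L),
                   reads$contig_id,
                   as.integer(reads$start0 + 1),
                   as.integer(reads$length),
                   as.integer(nm))
  writeLines(c(hdr, lines), path)
  invisible(path)
}
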