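#' Construct a genome set from contig and bin tables
#'
#' A genome set holds the binning of assembled contigs into MAGs: a contig
#' table (`contig_id`, `bin_id`, `length_bp`) and a derived bin table
#' (`bin_id`, `taxonomy`, `total_length_bp`, `n_contigs`). Contigs not
#' assigned to any MAG carry the reserved bin id `"unbinned"`.
#'
#' @param contigs data.frame with columns `contig_id`, `bin_id`, `length_bp`.
#' @param taxonomy Optional data.frame with columns `bin_id`, `taxonomy`.
#' @return An object of class `genome_set`.
#' @export
genome_set <- function(contigs, taxonomy = NULL) {
  stopifnot(all(c("contig_id", "bin_id", "length_bp") %in% names(contigs)))
  contigs <- data.frame(contig_id = as.character(contigs$contig_id),
                        bin_id = as.character(contigs$bin_id),
                        length_bp = as.numeric(contigs$length_bp),
                        stringsAsFactors = FALSE)
  dup <- contigs$contig_id[duplicated(contigs$contig_id)]
  if (length(dup)) {
    stop("contig assigned to more than one bin: ", paste(unique(dup), collapse = ", "))
  }
  if (any(contigs$length_bp <= 0)) stop("contig lengths must be positive")
  contigs <- contigs[order(contigs$bin_id, contigs$contig_id), , drop = FALSE]
  rownames(contigs) <- NULL
  bins <- stats::aggregate(length_bp ~ bin_id, data = contigs, FUN = sum)
  names(bins)[2] <- "total_length_bp"
  bins$n_contigs <- as.integer(table(contigs$bin_id)[bins$bin_id])
  bins$taxonomy <- ""
  if (!is.null(taxonomy)) {
    idx <- match(bins$bin_id, taxonomy$bin_id)
    bins$taxonomy <- ifelse(is.na(idx), "", as.character(taxonomy$taxonomy)[idx])
  }
  bins <- bins[order(bins$bin_id), c("bin_id", "taxonomy", "total_length_bp", "n_contigs")]
  rownames(bins) <- NULL
  structure(list(bins = bins, contigs = contigs), class = "genome_set")
}

#' @export
print.genome_set <- function(x, ...) {
  cat(sprintf("genome_set: %d bin(s), %d contig(s), %.2f Mb total\n",
              nrow(x$bins), nrow(x$contigs), sum(x$contigs$length_bp) / 1e6))
  print(utils::head(x$bins, 20))
  invisible(x)
}

#' Read binned genomes from FASTA plus a contig-to-bin assignment table
#'
#' Contig lengths come from the FASTA; the assignment TSV (columns
#' `contig_id`, `bin_id`, optional `taxonomy` per bin) maps each contig to a
#' MAG or to the `"unbinned"` pool. Contigs present in the FASTA but absent
#' from the table are placed in `"unbinned"`.
#'
#' @param fasta_paths Character vector of FASTA files with contig sequences.
#' @param bin_table Path to the assignment TSV, or an equivalent data.frame.
#' @return A [genome_set].
#' @export
read_genome_bins <- function(fasta_paths, bin_table) {
  seqs <- Biostrings::readDNAStringSet(fasta_paths)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) stop("duplicate contig ids in FASTA input")
  tab <- if (is.character(bin_table) && length(bin_table) == 1L) {
    read_tsv(bin_table, required = c("contig_id", "bin_id"))
  } else {
    bin_table
  }
  missing <- setdiff(tab$contig_id, names(seqs))
  if (length(missing)) {
    stop("contig(s) in bin table missing from FASTA: ", paste(missing, collapse = ", "))
  }
  bin_of <- stats::setNames(as.character(tab$bin_id), tab$contig_id)
  contigs <- data.frame(contig_id = names(seqs),
                        bin_id = unname(ifelse(is.na(bin_of[names(seqs)]),
                                               "unbinned", bin_of[names(seqs)])),
                        length_bp = Biostrings::width(seqs),
                        stringsAsFactors = FALSE)
  taxonomy <- NULL
  if ("taxonomy" %in% names(tab)) {
    taxonomy <- unique(tab[, c("bin_id", "taxonomy")])
  }
  gs <- genome_set(contigs, taxonomy)
  attr(gs, "sequences") <- seqs
  gs
}

#' Write a contig-to-bin assignment table
#'
#' Canonical TSV (sorted by bin then contig) so that read/write round-trips
#' are byte-stable.
#' @param gs A [genome_set].
#' @param path Output TSV path.
#' @export
write_bin_assignment <- function(gs, path) {
  stopifnot(inherits(gs, "genome_set"))
  tab <- gs$contigs[, c("contig_id", "bin_id", "length_bp")]
  tax <- stats::setNames(gs$bins$taxonomy, gs$bins$bin_id)
  tab$taxonomy <- unname(tax[tab$bin_id])
  write_tsv(tab, path)
}

#' Read a bin assignment table written by [write_bin_assignment]
#' @param path TSV path (columns `contig_id`, `bin_id`, `length_bp`, optional `taxonomy`).
#' @return A [genome_set].
#' @export
read_bin_assignment <- function(path) {
  tab <- read_tsv(path, required = c("contig_id", "bin_id", "length_bp"))
  taxonomy <- if ("taxonomy" %in% names(tab)) unique(tab[, c("bin_id", "taxonomy")])
  genome_set(tab, taxonomy)
}
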