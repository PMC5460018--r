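# In-code fixtures shared across the suite.

# Quick ORF layout on one or more contigs; lengths >= 60 so the table passes
# the gene-caller minimum.
tiny_orfs <- function(starts, ends, strands = "+", contig = "ctg1",
                      ids = sprintf("orf%02d", seq_along(starts))) {
  orf_table(data.frame(orf_id = ids, contig_id = contig,
                       start0 = starts, end0 = ends,
                       strand = rep_len(strands, length(starts)),
                       stringsAsFactors = FALSE))
}

# Single alignment record in the internal representation.
tiny_record <- function(start0, end0, strand = "+", contig = "ctg1",
                        blocks = NULL) {
  if (is.null(blocks)) blocks <- cbind(start0 = start0, end0 = end0)
  list(contig_id = contig, start0 = start0, end0 = end0, strand = strand,
       blocks = blocks)
}

# Two-contig, two-bin genome set used across IO/counting tests.
tiny_genome_set <- function() {
  genome_set(data.frame(contig_id = c("ctg1", "ctg2"),
                        bin_id = c("A", "B"),
                        length_bp = c(10000, 5000),
                        stringsAsFactors = FALSE))
}

# Random read/ORF-layout instance for oracle-equivalence checks: overlapping
# and boundary-touching ORFs, both strands, one- or two-block reads, all
# strandedness modes and both gap policies.
random_instance <- function() {
  n_orfs <- sample(2:6, 1)
  starts <- sample(0:400, n_orfs, replace = TRUE)
  lens <- sample(60:200, n_orfs, replace = TRUE)
  orfs <- data.frame(orf_id = sprintf("o%d", seq_len(n_orfs)),
                     contig_id = "c",
                     start0 = starts, end0 = starts + lens,
                     strand = sample(c("+", "-"), n_orfs, replace = TRUE),
                     stringsAsFactors = FALSE)
  rstart <- sample(0:550, 1)
  rlen <- sample(20:120, 1)
  if (stats::runif(1) < 0.3) {
    # read with an internal deletion: two blocks, merged footprint
    b1 <- max(5, floor(rlen / 2))
    gap <- sample(1:15, 1)
    blocks <- cbind(start0 = c(rstart, rstart + b1 + gap),
                    end0 = c(rstart + b1, rstart + rlen + gap))
    rend <- rstart + rlen + gap
  } else {
    blocks <- cbind(start0 = rstart, end0 = rstart + rlen)
    rend <- rstart + rlen
  }
  list(orfs = orfs,
       record = tiny_record(rstart, rend, strand = sample(c("+", "-"), 1),
                            contig = "c", blocks = blocks),
       stranded = sample(c("yes", "no", "reverse"), 1),
       gap_policy = sample(c("covered", "per_block"), 1))
}

# Expression-table surrogate from chosen RPKM values (counts mirror RPKMs so
# zero RPKM means zero counts).
expr_from_rpkm <- function(orf_id, bin_id, rpkm) {
  df <- data.frame(orf_id = orf_id, bin_id = bin_id, rpkm = rpkm,
                   count = rpkm, stringsAsFactors = FALSE)
  relative_expression(df)
}

# Small community written to disk; shared by IO/pipeline tests.
write_small_community <- function(dir, seed = 7, n_genomes = 3,
                                  sizes = c(60000, 90000, 120000),
                                  dna_depth = 20000, rna_depth = 20000, ...) {
  spec <- community_spec(n_genomes, total_length_bp = sizes,
                         orfs_per_mb = 600, n_contigs = 2)
  simulate_community(dir, spec = spec, seed = seed,
                     dna_depth = dna_depth, rna_depth = rna_depth, ...)
}
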