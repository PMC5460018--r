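test_that("genome sets enforce the contig partition and sum lengths", {
  gs <- genome_set(data.frame(contig_id = c("c1", "c2"), bin_id = "A",
                              length_bp = c(1000, 500)))
  expect_equal(gs$bins$total_length_bp, 1500)
  expect_equal(gs$bins$n_contigs, 2L)

  expect_error(
    genome_set(data.frame(contig_id = c("c1", "c1"), bin_id = c("A", "B"),
                          length_bp = c(1000, 500))),
    "more than one bin")
})

test_that("FASTA + assignment reading validates contigs and pools the unbinned", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fasta")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(
    c(c1 = strrep("ACGT", 250), c2 = strrep("ACGT", 125),
      c3 = strrep("ACGT", 100))), fa)
  tab <- data.frame(contig_id = c("c1", "c2"), bin_id = "A")
  gs <- read_genome_bins(fa, tab)
  expect_equal(sort(gs$bins$bin_id), c("A", "unbinned"))
  expect_equal(gs$bins$total_length_bp[gs$bins$bin_id == "A"], 1500)
  expect_equal(gs$contigs$bin_id[gs$contigs$contig_id == "c3"], "unbinned")

  expect_error(
    read_genome_bins(fa, data.frame(contig_id = "c9", bin_id = "A")),
    "c9")
})

test_that("a many-bin assignment table round-trips identically", {
  # 17-bin layout with taxonomy labels, like a MAG statistics table
  contigs <- do.call(rbind, lapply(1:17, function(i) {
    data.frame(contig_id = sprintf("b%02d_c%d", i, 1:3),
               bin_id = sprintf("MAG%02d", i),
               length_bp = 1000 * i + (1:3))
  }))
  tax <- data.frame(bin_id = sprintf("MAG%02d", 1:17),
                    taxonomy = sprintf("Bacteria; Phylum%02d", 1:17))
  gs <- genome_set(contigs, tax)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_bin_assignment(gs, p1)
  gs2 <- read_bin_assignment(p1)
  write_bin_assignment(gs2, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(gs$bins, gs2$bins)
  expect_identical(gs$contigs, gs2$contigs)
})

test_that("GFF3 coordinates convert to 0-based half-open and back losslessly", {
  dir <- withr::local_tempdir()
  gff <- file.path(dir, "x.gff3")
  writeLines(c("##gff-version 3",
               "ctg1\tsrc\tCDS\t11\t70\t.\t+\t0\tID=orfA;product=peptidase",
               "ctg1\tsrc\tCDS\t100\t399\t.\t-\t0\tID=orfB"), gff)
  orfs <- read_gff3(gff)
  expect_equal(orfs$start0[orfs$orf_id == "orfA"], 10)
  expect_equal(orfs$end0[orfs$orf_id == "orfA"], 70)
  expect_equal(orfs$length_bp[orfs$orf_id == "orfA"], 60)
  expect_equal(orfs$product[orfs$orf_id == "orfA"], "peptidase")

  out <- file.path(dir, "y.gff3")
  write_gff3(orfs, out)
  orfs2 <- read_gff3(out)
  expect_equal(orfs2$start0, orfs$start0)
  expect_equal(orfs2$end0, orfs$end0)
  expect_equal(orfs2$strand, orfs$strand)
  # write is canonical: a second round trip is byte-identical
  out2 <- file.path(dir, "z.gff3")
  write_gff3(orfs2, out2)
  expect_identical(readLines(out), readLines(out2))
})

test_that("sub-minimum CDS are excluded with a warning; overlaps are kept", {
  dir <- withr::local_tempdir()
  gff <- file.path(dir, "x.gff3")
  writeLines(c("##gff-version 3",
               "ctg1\tsrc\tCDS\t1\t59\t.\t+\t0\tID=short",     # 59 nt
               "ctg1\tsrc\tCDS\t1\t60\t.\t+\t0\tID=exact60",   # boundary case
               "ctg1\tsrc\tCDS\t30\t120\t.\t+\t0\tID=overlap"), gff)
  expect_warning(orfs <- read_gff3(gff), "shorter than 60")
  expect_setequal(orfs$orf_id, c("exact60", "overlap"))

  gs <- tiny_genome_set()
  writeLines(c("##gff-version 3",
               "nowhere\tsrc\tCDS\t1\t600\t.\t+\t0\tID=lost"), gff)
  expect_error(read_gff3(gff, gs), "nowhere")
})

test_that("SAM reading derives blocks, footprints and identity from the record", {
  dir <- withr::local_tempdir()
  sam <- file.path(dir, "x.sam")
  writeLines(c("@HD\tVN:1.6",
               "@SQ\tSN:ctg1\tLN:10000",
               # perfect 100M at pos 1 (0-based 0)
               "r1\t0\tctg1\t1\t60\t100M\t*\t0\t0\t*\t*\tNM:i:0",
               # 50M10D50M: two blocks, one footprint spanning the deletion
               "r2\t16\tctg1\t201\t60\t50M10D50M\t*\t0\t0\t*\t*\tNM:i:0",
               # identity 0.93 < 0.95: filtered
               "r3\t0\tctg1\t1\t60\t100M\t*\t0\t0\t*\t*\tNM:i:7",
               # unmapped
               "r4\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*"), sam)
  aln <- read_sam(sam, min_identity = 0.95)
  expect_equal(aln$totals$n_records, 2L)
  expect_equal(aln$totals$n_filtered_identity, 1L)
  expect_equal(aln$totals$n_unmapped, 1L)

  r1 <- aln$records[aln$records$read_id == "r1", ]
  expect_equal(r1$start0, 0)
  expect_equal(r1$end0, 100)
  expect_equal(unname(r1$blocks[[1]][, "start0"]), 0)

  r2 <- aln$records[aln$records$read_id == "r2", ]
  expect_equal(r2$strand, "-")
  expect_equal(r2$end0 - r2$start0, 110)  # deletion consumes reference
  expect_equal(nrow(r2$blocks[[1]]), 2)
  expect_equal(unname(r2$blocks[[1]][2, "start0"]), 200 + 60)
})

test_that("SAM reading rejects unknown contigs and handles missing identity", {
  dir <- withr::local_tempdir()
  sam <- file.path(dir, "x.sam")
  writeLines(c("@SQ\tSN:ctg1\tLN:10000",
               "r1\t0\tghost\t1\t60\t50M\t*\t0\t0\t*\t*\tNM:i:0"), sam)
  expect_error(read_sam(sam), "ghost")

  writeLines(c("@SQ\tSN:ctg1\tLN:10000",
               "r1\t0\tctg1\t1\t60\t50M\t*\t0\t0\t*\t*"), sam)
  expect_warning(aln <- read_sam(sam), "no computable identity")
  expect_equal(aln$totals$n_records, 0L)
  aln2 <- suppressWarnings(read_sam(sam, on_missing_identity = "accept"))
  expect_equal(aln2$totals$n_records, 1L)
})

test_that("pathway, annotation and cost tables enforce their invariants", {
  defs <- pathway_definitions(data.frame(
    pathway_id = "anammox", reaction_id = "hzs", is_key = TRUE,
    group_kind = "complex", members = "hzsA,hzsB,hzsC"))
  expect_length(defs$members[[1]], 3)
  expect_true(defs$is_key[1])

  expect_error(pathway_definitions(data.frame(
    pathway_id = "empty", reaction_id = "", is_key = FALSE,
    group_kind = "single", members = "")), "empty")

  expect_error(cost_table(data.frame(amino_acid = AA_THREE_LETTER,
                                     cost_rank = c(2:20, 21))),
               "permutation")
  ct <- cost_table(data.frame(amino_acid = AA_THREE_LETTER, cost_rank = 1:20))
  expect_equal(nrow(ct), 20)

  expect_warning(
    ann <- annotation_table(data.frame(orf_id = "o1", namespace = "peptidase",
                                       family_code = "S08", location = "moon")),
    "unknown location")
  expect_equal(ann$location, "unknown")
})

test_that("pathway definitions round-trip through TSV", {
  defs <- pathway_definitions(data.frame(
    pathway_id = c("p1", "p1", "p1"),
    reaction_id = c("r1", "r1", "r2"),
    is_key = c(TRUE, TRUE, FALSE),
    group_kind = c("complex", "single", "none"),
    members = c("a,b", "c", "")))
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_pathway_definitions(defs, p1)
  defs2 <- read_pathway_definitions(p1)
  write_pathway_definitions(defs2, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(defs$members, defs2$members)
})
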