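test_that("intersection-strict assignment handles the canonical cases", {
  orfs <- tiny_orfs(starts = c(100, 150, 500), ends = c(300, 400, 700),
                    strands = c("+", "+", "-"))

  # fully inside a lone ORF, matching strand
  expect_equal(assign_read(tiny_record(550, 650, "-"), orfs)$status, "assigned")
  expect_equal(assign_read(tiny_record(550, 650, "-"), orfs)$orf_id, "orf03")

  # 10 terminal bases outside the ORF: strict demands every position covered
  expect_equal(assign_read(tiny_record(90, 190, "+"), orfs)$status, "no_feature")

  # fully inside the overlap of two same-strand ORFs
  expect_equal(assign_read(tiny_record(200, 280, "+"), orfs)$status, "ambiguous")

  # opposite strand under stranded = yes
  expect_equal(assign_read(tiny_record(550, 650, "+"), orfs, stranded = "yes")$status,
               "no_feature")
  # same read accepted when strand is ignored
  expect_equal(assign_read(tiny_record(550, 650, "+"), orfs, stranded = "no")$status,
               "assigned")
  # and under reverse-stranded protocols
  expect_equal(assign_read(tiny_record(550, 650, "+"), orfs, stranded = "reverse")$status,
               "assigned")
})

test_that("deletion-spanned positions follow the gap policy", {
  orfs <- tiny_orfs(starts = 100, ends = 300)
  # two blocks inside the ORF: assigned under both policies
  rec <- tiny_record(120, 250, blocks = cbind(start0 = c(120, 200),
                                              end0 = c(170, 250)))
  expect_equal(assign_read(rec, orfs, gap_policy = "covered")$status, "assigned")
  expect_equal(assign_read(rec, orfs, gap_policy = "per_block")$status, "assigned")

  # footprint pokes out but each block is inside a different context:
  # second block beyond the ORF end
  rec2 <- tiny_record(250, 340, blocks = cbind(start0 = c(250, 310),
                                               end0 = c(290, 340)))
  expect_equal(assign_read(rec2, orfs, gap_policy = "covered")$status, "no_feature")
  expect_equal(assign_read(rec2, orfs, gap_policy = "per_block")$status, "no_feature")
})

test_that("index-based assignment agrees with the per-base oracle", {
  set.seed(4031)
  n_checked <- 0
  for (i in 1:1500) {
    inst <- random_instance()
    a <- assign_read(inst$record, inst$orfs, stranded = inst$stranded,
                     gap_policy = inst$gap_policy)
    b <- brute_force_assign(inst$record, inst$orfs, stranded = inst$stranded,
                            gap_policy = inst$gap_policy)
    expect_identical(a$status, b$status)
    expect_identical(a$orf_id, b$orf_id)
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 1500)
})

test_that("strictly assigned reads always overlap a feature under any-overlap", {
  # monotone strictness: intersection-strict assignment implies the
  # any-overlap feature set is non-empty and contains the assigned ORF;
  # the converse fails for partially overlapping reads
  set.seed(911)
  converse_failures <- 0
  for (i in 1:400) {
    inst <- random_instance()
    a <- assign_read(inst$record, inst$orfs, stranded = inst$stranded,
                     gap_policy = inst$gap_policy)
    o <- inst$orfs
    union_set <- o$orf_id[o$start0 < inst$record$end0 &
                            o$end0 > inst$record$start0 &
                            granuletx:::strand_compatible(inst$record$strand,
                                                          o$strand, inst$stranded)]
    if (a$status == "assigned") {
      expect_true(a$orf_id %in% union_set)
    } else if (a$status == "no_feature" && length(union_set) > 0) {
      converse_failures <- converse_failures + 1
    }
  }
  expect_gt(converse_failures, 0)
})

test_that("counting partitions records into disjoint categories", {
  gs <- tiny_genome_set()
  orfs <- tiny_orfs(starts = c(100, 150, 500), ends = c(300, 400, 700),
                    strands = c("+", "+", "-"))
  dir <- withr::local_tempdir()
  sam <- file.path(dir, "x.sam")
  reads <- data.frame(
    read_id = sprintf("r%d", 1:6),
    contig_id = c("ctg1", "ctg1", "ctg1", "ctg1", "ctg2", "ctg2"),
    start0 = c(550, 90, 200, 550, 100, 200),
    length = c(100, 100, 80, 100, 50, 50),
    strand = c("-", "+", "+", "+", "+", "+"))
  write_sam(reads, gs$contigs, sam)
  ct <- count_library(read_sam(sam), gs, orfs, stranded = "yes")

  tot <- ct$totals
  expect_equal(tot$n_assigned + tot$n_no_feature + tot$n_ambiguous, 6L)
  expect_equal(tot$n_assigned, sum(ct$feature_counts$count))
  expect_equal(tot$n_assigned, 1L)   # only r1
  expect_equal(tot$n_ambiguous, 1L)  # r3 in the overlap
  # genome counts tally every mapped read, coding or not
  expect_equal(ct$genome_counts$count[ct$genome_counts$bin_id == "A"], 4L)
  expect_equal(ct$genome_counts$count[ct$genome_counts$bin_id == "B"], 2L)
})

test_that("an empty record stream yields an all-zero table", {
  gs <- tiny_genome_set()
  orfs <- tiny_orfs(starts = 100, ends = 300)
  dir <- withr::local_tempdir()
  sam <- file.path(dir, "empty.sam")
  write_sam(data.frame(), gs$contigs, sam)
  ct <- count_library(read_sam(sam), gs, orfs)
  expect_equal(sum(ct$feature_counts$count), 0L)
  expect_equal(sum(ct$genome_counts$count), 0L)
  expect_equal(ct$totals$n_assigned, 0L)
})

test_that("intergenic reads count toward the genome but not any feature", {
  gs <- tiny_genome_set()
  orfs <- tiny_orfs(starts = 100, ends = 300)
  dir <- withr::local_tempdir()
  sam <- file.path(dir, "x.sam")
  write_sam(data.frame(read_id = sprintf("r%d", 1:10), contig_id = "ctg1",
                       start0 = 5000 + (1:10), length = 50, strand = "+"),
            gs$contigs, sam)
  ct <- count_library(read_sam(sam), gs, orfs)
  expect_equal(ct$genome_counts$count[ct$genome_counts$bin_id == "A"], 10L)
  expect_equal(ct$totals$n_no_feature, 10L)
  expect_equal(sum(ct$feature_counts$count), 0L)
})

test_that("multi-mapper records collapse to one location deterministically", {
  gs <- tiny_genome_set()
  orfs <- tiny_orfs(starts = c(100, 600), ends = c(400, 900))
  dir <- withr::local_tempdir()
  sam <- file.path(dir, "x.sam")
  # same read reported at two candidate locations
  write_sam(data.frame(read_id = c("r1", "r1", "r2"), contig_id = "ctg1",
                       start0 = c(150, 650, 200), length = 50, strand = "+"),
            gs$contigs, sam)
  ct1 <- count_library(read_sam(sam), gs, orfs, seed = 5)
  ct2 <- count_library(read_sam(sam), gs, orfs, seed = 5)
  expect_identical(ct1$feature_counts, ct2$feature_counts)
  expect_equal(sum(ct1$feature_counts$count), 2L)  # one location per read
  expect_equal(ct1$library_size, 2L)
})
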