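test_that("enzyme aggregation: min over complex subunits, max over isozymes", {
  lookup <- c(hzsA = 3, hzsB = 8, hzsC = 2, soloA = 5, soloB = 9,
              cplx1 = 2, cplx2 = 6, iso = 4, zeroed = 0, other = 7)

  expect_equal(enzyme_group_rpkm(c("hzsA", "hzsB", "hzsC"), "complex", lookup)$rpkm, 2)
  expect_equal(enzyme_group_rpkm("soloA", "single", lookup)$rpkm, 5)

  z <- enzyme_group_rpkm(c("zeroed", "other"), "complex", lookup)
  expect_equal(z$rpkm, 0)
  expect_true(z$zero_subunit)

  expect_equal(reaction_rpkm(list(list(members = "soloA", kind = "single"),
                                  list(members = "soloB", kind = "single")),
                             lookup)$rpkm, 9)
  expect_equal(reaction_rpkm(list(list(members = "soloA", kind = "single")),
                             lookup)$rpkm, 5)
  # composed min-then-max: complex bottoms out at 2, the single isozyme at 4
  expect_equal(reaction_rpkm(list(list(members = c("cplx1", "cplx2"), kind = "complex"),
                                  list(members = "iso", kind = "single")),
                             lookup)$rpkm, 4)

  expect_error(enzyme_group_rpkm("ghost", "single", lookup), "unresolvable")
})

make_call_fixture <- function(rpkms = c(a1 = 9, a2 = 2, a3 = 4, a4 = 5,
                                        pad1 = 4, pad2 = 4, pad3 = 4)) {
  expr <- expr_from_rpkm(names(rpkms), "G", unname(rpkms))
  defs <- pathway_definitions(data.frame(
    pathway_id = "pwy",
    reaction_id = c("r1", "r2", "r3", "r4"),
    is_key = c(TRUE, FALSE, FALSE, FALSE),
    group_kind = "single",
    members = c("a1", "a2", "a3", "a4")))
  list(expr = expr, defs = defs)
}

test_that("pathway expression is the mean over assigned reactions", {
  fx <- make_call_fixture()
  call <- pathway_call(fx$defs, "pwy", "G", fx$expr, threshold = 0.75)
  expect_equal(call$pathway_rpkm, mean(c(9, 2, 4, 5)))
  expect_true(call$present)
  expect_equal(call$completeness, 1)
  # relativized by the genome ORF median (4)
  expect_equal(call$rel_pathway_expr, 5 / 4)
})

test_that("a missing key reaction blocks presence regardless of completeness", {
  fx <- make_call_fixture()
  # drop the key reaction's gene from the genome: a1 absent from expression
  expr <- expr_from_rpkm(c("a2", "a3", "a4", "pad1", "pad2", "pad3"), "G",
                         c(2, 4, 5, 4, 4, 4))
  call <- pathway_call(fx$defs, "pwy", "G", expr, threshold = 0.75)
  expect_equal(call$completeness, 0.75)
  expect_false(call$key_ok)
  expect_false(call$present)

  # pathway with no assigned reactions
  expr_none <- expr_from_rpkm(c("x1", "x2"), "G", c(1, 2))
  call0 <- pathway_call(fx$defs, "pwy", "G", expr_none)
  expect_false(call0$present)
  expect_true(is.na(call0$pathway_rpkm))
})

test_that("unassigned reactions can be zero-filled by flag", {
  fx <- make_call_fixture()
  expr <- expr_from_rpkm(c("a1", "a2", "a3", "pad1"), "G", c(9, 2, 4, 4))
  excl <- pathway_call(fx$defs, "pwy", "G", expr, unassigned = "exclude")
  zero <- pathway_call(fx$defs, "pwy", "G", expr, unassigned = "zero")
  expect_equal(excl$pathway_rpkm, mean(c(9, 2, 4)))
  expect_equal(zero$pathway_rpkm, sum(c(9, 2, 4)) / 4)
})

test_that("simulated truth classes are recovered through definitions on disk", {
  spec <- community_spec(4, total_length_bp = 50000, orfs_per_mb = 2000,
                         n_contigs = 1)
  sim <- simulate_genomes(spec, seed = 31, sequences = FALSE)
  pw <- simulate_pathways(sim, n_pathways = 12, seed = 37)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pathway_definitions(pw$definitions, path)
  defs <- read_pathway_definitions(path)

  counts <- data.frame(orf_id = sim$orfs$orf_id, count = 5L)
  ct <- count_table_from_counts(counts, sim$genomes, sim$orfs, library_id = "rna")
  expr <- expression_table(ct, sim$orfs)
  calls <- pathway_calls(defs, expr, threshold = 0.75)
  m <- merge(calls, pw$truth, by = c("bin_id", "pathway_id"))
  expect_equal(nrow(m), nrow(pw$truth))
  expect_identical(m$present.x, m$present.y)
  expect_equal(m$completeness.x, m$completeness.y)
  # complete and missing-key classes recover at any threshold <= 1
  for (thr in c(0.25, 0.5, 1)) {
    calls_t <- pathway_calls(defs, expr, threshold = thr)
    mt <- merge(calls_t, pw$truth, by = c("bin_id", "pathway_id"))
    expect_true(all(mt$present.x[mt$class == "complete"]))
    expect_true(all(!mt$present.x[mt$class %in% c("partial_key", "absent")]))
  }
})

test_that("pathway expression is monotone in any member gene's RPKM", {
  set.seed(53)
  fx <- make_call_fixture()
  base_rpkm <- c(a1 = 9, a2 = 2, a3 = 4, a4 = 5, pad1 = 4, pad2 = 4, pad3 = 4)
  base <- pathway_call(fx$defs, "pwy", "G",
                       expr_from_rpkm(names(base_rpkm), "G", unname(base_rpkm)))
  for (g in c("a1", "a2", "a3", "a4")) {
    for (bump in c(0.5, 3, 20)) {
      r <- base_rpkm
      r[g] <- r[g] + bump
      call <- pathway_call(fx$defs, "pwy", "G",
                           expr_from_rpkm(names(r), "G", unname(r)))
      expect_gte(call$pathway_rpkm, base$pathway_rpkm)
    }
  }
})

test_that("denitrification steps follow complex/isozyme rules and flag silent subunits", {
  ann <- annotation_table(data.frame(
    orf_id = c("narG", "narH", "narI", "nirK1", "nirS1", "nosZ1"),
    namespace = "marker",
    family_code = c("narGHIJ", "narGHIJ", "narGHIJ", "nirK", "nirS", "nosZ"),
    location = "cytoplasmic"))
  expr <- expr_from_rpkm(c("narG", "narH", "narI", "nirK1", "nirS1", "nosZ1", "pad"),
                         "G", c(10, 12, 0, 4, 6, 3, 5))
  dm <- denitrification_profile(ann, expr)

  nar <- dm[dm$step == "NO3->NO2", ]
  expect_true(nar$present)
  expect_true(nar$zero_subunit_flag)       # narI silent while the step is encoded
  expect_equal(nar$step_rpkm, 0)           # min over subunits
  expect_true(is.na(nar$log2_step_rpkm))   # log2 undefined at 0, no pseudocount

  no2no <- dm[dm$step == "NO2->NO", ]
  expect_equal(no2no$step_rpkm, 6)         # max over nirK/nirS isozymes
  expect_equal(no2no$log2_step_rpkm, log2(6))
  expect_false(no2no$zero_subunit_flag)

  expect_false(dm$present[dm$step == "NO->N2O"])
  expect_true(dm$present[dm$step == "N2O->N2"])
})

test_that("a genome with only nosZ shows only the final reduction step", {
  ann <- annotation_table(data.frame(orf_id = "z1", namespace = "marker",
                                     family_code = "nosZ",
                                     location = "cytoplasmic"))
  expr <- expr_from_rpkm(c("z1", "pad1", "pad2"), "G", c(8, 4, 4))
  dm <- denitrification_profile(ann, expr)
  expect_equal(dm$step[dm$present], "N2O->N2")
  expect_equal(dm$step_rpkm[dm$present], 8)
})
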