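# Synthetic anammox-like communities with known ground truth. The generator
# emulates the statistical structure the estimators assume: a handful of
# MAGs of differing lengths carrying non-overlapping ORFs, Dirichlet
# community composition, log-normal within-genome transcript levels, and
# Poisson read counts proportional to abundance x length x expression, with
# a configurable intergenic/noise read fraction. Reads are fixed-length and
# error-free so intersection-strict counting can recover counts exactly.

#' Default genome specification for a simulated community
#'
#' Five genomes spanning 0.5-4 Mb (the size range typical of granule MAGs),
#' with ORF numbers close to one per kilobase.
#' @param n_genomes Number of genomes.
#' @param total_length_bp Genome sizes (recycled).
#' @param orfs_per_mb ORF density.
#' @param n_contigs Contigs per genome (recycled).
#' @return data.frame with `bin_id`, `n_contigs`, `total_length_bp`, `n_orfs`.
#' @export
community_spec <- function(n_genomes = 5,
                           total_length_bp = round(seq(0.5e6, 4e6,
                                                       length.out = n_genomes)),
                           orfs_per_mb = 900,
                           n_contigs = 3) {
  data.frame(bin_id = sprintf("BIN%d", seq_len(n_genomes)),
             n_contigs = rep_len(n_contigs, n_genomes),
             total_length_bp = rep_len(total_length_bp, n_genomes),
             n_orfs = pmax(1L, round(rep_len(total_length_bp, n_genomes) / 1e6 * orfs_per_mb)),
             stringsAsFactors = FALSE)
}

#' Simulate binned genomes with non-overlapping ORFs
#'
#' ORF lengths are drawn as `3 x max(20, ceiling(Gamma(shape 2, scale 150)))`
#' codons (minimum 60 nt); ORFs are placed uniformly at random without
#' overlap, strands Bernoulli(1/2). Each genome draws from its own seed
#' substream, so regenerating one genome never disturbs another.
#'
#' @param spec Genome specification as from [community_spec]. `n_orfs = 0`
#'   yields a valid genome with no ORFs.
#' @param seed Master seed.
#' @param sequences Generate random DNA contig sequences (needed only when a
#'   FASTA is to be emitted).
#' @param max_tries Placement attempts per ORF before declaring the packing
#'   infeasible.
#' @return list with `genomes` ([genome_set]), `orfs` ([orf_table]),
#'   `sequences` (DNAStringSet or NULL), `spec`, `seed`.
#' @export
simulate_genomes <- function(spec, seed = 1L, sequences = TRUE, max_tries = 500L) {
  stopifnot(all(c("bin_id", "n_contigs", "total_length_bp", "n_orfs") %in% names(spec)))
  seeds <- split_seed(seed, nrow(spec))
  contig_rows <- list()
  orf_rows <- list()
  seq_list <- character(0)
  for (g in seq_len(nrow(spec))) {
    bin <- spec$bin_id[g]
    res <- with_seed(seeds[g], {
      nct <- spec$n_contigs[g]
      total <- spec$total_length_bp[g]
      props <- if (nct == 1) 1 else stats::rgamma(nct, shape = 5)
      clen <- floor(total * props / sum(props))
      clen[1] <- clen[1] + (total - sum(clen))
      if (any(clen <= 0)) stop("degenerate contig length for ", bin)
      ctg_ids <- sprintf("%s_c%d", bin, seq_len(nct))

      n_orfs <- spec$n_orfs[g]
      orfs <- NULL
      if (n_orfs > 0) {
        len <- 3 * pmax(20, ceiling(stats::rgamma(n_orfs, shape = 2, scale = 150) / 3))
        if (sum(len) > 0.95 * total) {
          stop(sprintf("infeasible ORF packing for %s: %d ORFs totalling %d bp in %d bp",
                       bin, n_orfs, sum(len), total))
        }
        host <- sample(seq_len(nct), n_orfs, replace = TRUE, prob = clen)
        starts <- numeric(n_orfs)
        placed <- lapply(seq_len(nct), function(i) matrix(numeric(0), ncol = 2))
        for (i in order(-len)) {
          ci <- host[i]
          L <- clen[ci]
          if (len[i] > L) ci <- host[i] <- which.max(clen)
          ok <- FALSE
          for (t in seq_len(max_tries)) {
            s <- floor(stats::runif(1, 0, clen[host[i]] - len[i] + 1))
            p <- placed[[host[i]]]
            if (!nrow(p) || all(s + len[i] <= p[, 1] | s >= p[, 2])) {
              placed[[host[i]]] <- rbind(p, c(s, s + len[i]))
              starts[i] <- s
              ok <- TRUE
              break
            }
          }
          if (!ok) {
            stop(sprintf("infeasible ORF packing for %s after %d tries", bin, max_tries))
          }
        }
        orfs <- data.frame(orf_id = sprintf("%s_%04d", bin, seq_len(n_orfs)),
                           contig_id = ctg_ids[host],
                           start0 = starts, end0 = starts + len,
                           strand = sample(c("+", "-"), n_orfs, replace = TRUE),
                           product = "hypothetical protein",
                           stringsAsFactors = FALSE)
      }
      seqs <- if (sequences) {
        vapply(clen, function(L) {
          paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
        }, character(1))
      } else NULL
      list(contigs = data.frame(contig_id = ctg_ids, bin_id = bin,
                                length_bp = clen, stringsAsFactors = FALSE),
           orfs = orfs, seqs = seqs, ctg_ids = ctg_ids)
    })
    contig_rows[[g]] <- res$contigs
    orf_rows[[g]] <- res$orfs
    if (!is.null(res$seqs)) {
      seq_list <- c(seq_list, stats::setNames(res$seqs, res$ctg_ids))
    }
  }
  orfs_df <- do.call(rbind, orf_rows[!vapply(orf_rows, is.null, logical(1))])
  if (is.null(orfs_df)) {
    orfs_df <- data.frame(orf_id = character(0), contig_id = character(0),
                          start0 = numeric(0), end0 = numeric(0),
                          strand = character(0), product = character(0),
                          stringsAsFactors = FALSE)
    orfs_df$length_bp <- numeric(0)
    class(orfs_df) <- c("orf_table", "data.frame")
  } else {
    orfs_df <- orf_table(orfs_df)
  }
  list(genomes = genome_set(do.call(rbind, contig_rows)),
       orfs = orfs_df,
       sequences = if (length(seq_list)) Biostrings::DNAStringSet(seq_list) else NULL,
       spec = spec, seed = seed)
}

#' Draw a community composition from a symmetric Dirichlet
#'
#' @param n_genomes Number of genomes.
#' @param concentration Dirichlet concentration (> 0); large values approach
#'   the uniform composition.
#' @param seed Seed.
#' @return Numeric simplex vector of length `n_genomes` (sums to 1).
#' @export
simulate_composition <- function(n_genomes, concentration = 1, seed = 1L) {
  stopifnot(concentration > 0, n_genomes >= 1)
  with_seed(seed, {
    x <- stats::rgamma(n_genomes, shape = concentration)
    while (sum(x) == 0) x <- stats::rgamma(n_genomes, shape = concentration)
    x / sum(x)
  })
}

#' Draw per-ORF relative transcript concentrations (log-normal)
#' @param orfs An [orf_table].
#' @param meanlog,sdlog Log-normal parameters (defaults 0 and 1).
#' @param seed Seed.
#' @return Named positive vector over `orfs$orf_id`.
#' @export
simulate_expression <- function(orfs, meanlog = 0, sdlog = 1, seed = 1L) {
  with_seed(seed, stats::setNames(stats::rlnorm(nrow(orfs), meanlog, sdlog),
                                  orfs$orf_id))
}

#' Bundle simulated genomes, composition and expression into a ground truth
#'
#' @param sim Output of [simulate_genomes].
#' @param abundance Simplex vector over genomes (sums to 1 within 1e-12).
#' @param expression Named positive vector over ORFs.
#' @param noise_fraction Fraction of RNA reads placed on intergenic sequence.
#' @param dna_depth,rna_depth Expected total reads per library.
#' @return list of class `community_truth`.
#' @export
community_truth <- function(sim, abundance, expression,
                            noise_fraction = 0.05,
                            dna_depth = 2e6, rna_depth = 1e6) {
  bins <- sim$genomes$bins$bin_id
  stopifnot(length(abundance) == length(bins))
  if (abs(sum(abundance) - 1) > 1e-12) stop("abundance must sum to 1")
  if (is.null(names(abundance))) names(abundance) <- bins
  if (nrow(sim$orfs)) {
    stopifnot(all(sim$orfs$orf_id %in% names(expression)))
    if (any(expression < 0)) stop("expression values must be non-negative")
  }
  stopifnot(noise_fraction >= 0, noise_fraction < 1)
  structure(list(genomes = sim$genomes, orfs = sim$orfs,
                 sequences = sim$sequences,
                 abundance = abundance, expression = expression,
                 noise_fraction = noise_fraction,
                 dna_depth = dna_depth, rna_depth = rna_depth),
            class = "community_truth")
}

# Partition every contig into ORF and intergenic regions.
region_table <- function(orfs, contigs) {
  rows <- lapply(seq_len(nrow(contigs)), function(i) {
    ctg <- contigs$contig_id[i]
    L <- contigs$length_bp[i]
    o <- orfs[orfs$contig_id == ctg, , drop = FALSE]
    o <- o[order(o$start0), , drop = FALSE]
    breaks_s <- c(o$start0, L)
    breaks_e <- c(0, o$end0)
    inter <- data.frame(contig_id = ctg, start0 = breaks_e, end0 = breaks_s,
                        type = "intergenic", orf_id = NA_character_,
                        strand = NA_character_, stringsAsFactors = FALSE)
    inter <- inter[inter$end0 > inter$start0, , drop = FALSE]
    orf <- if (nrow(o)) {
      data.frame(contig_id = ctg, start0 = o$start0, end0 = o$end0,
                 type = "orf", orf_id = o$orf_id, strand = o$strand,
                 stringsAsFactors = FALSE)
    }
    rbind(orf, inter)
  })
  out <- do.call(rbind, rows)
  out$length_bp <- out$end0 - out$start0
  out <- out[order(out$contig_id, out$start0), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate read counts (and optionally a SAM file) for one library
#'
#' DNA library: expected reads on any region are proportional to
#' `abundance(bin) x region length` (uniform coverage within a genome).
#' RNA library: expected reads on ORF i are proportional to
#' `abundance(bin) x length(i) x expression(i)`, scaled so ORF reads total
#' `(1 - noise_fraction) x depth`; a `noise_fraction` of reads falls on
#' intergenic sequence proportional to `abundance x length`. All counts are
#' Poisson draws. When `sam_path` is given, every counted read becomes a
#' perfect-identity single-block 125 bp record placed fully inside its
#' source region, so intersection-strict counting recovers the counts
#' exactly.
#'
#' @param truth A [community_truth].
#' @param library `"dna"` or `"rna"`.
#' @param seed Seed for this library's draws.
#' @param sam_path Optional SAM output path.
#' @param read_length Read length (bp); reads in regions shorter than this
#'   are shortened to the region.
#' @return list with `orf_counts` (orf_id, bin_id, count), `genome_counts`
#'   (bin_id, count: all reads on the genome, coding or not), `region_counts`,
#'   `n_noise_reads`, `library_id`, `sam_path`.
#' @export
simulate_counts <- function(truth, library = c("dna", "rna"), seed = 1L,
                            sam_path = NULL, read_length = 125) {
  library <- match.arg(library)
  stopifnot(inherits(truth, "community_truth"))
  contigs <- truth$genomes$contigs
  bin_of <- stats::setNames(contigs$bin_id, contigs$contig_id)
  reg <- region_table(truth$orfs, contigs)
  reg$bin_id <- unname(bin_of[reg$contig_id])
  ab <- truth$abundance[reg$bin_id]
  depth <- if (library == "dna") truth$dna_depth else truth$rna_depth

  if (library == "dna") {
    w <- ab * reg$length_bp
    lambda <- depth * w / sum(w)
  } else {
    is_orf <- reg$type == "orf"
    if (!any(is_orf)) stop("rna library requires at least one ORF")
    ex <- truth$expression[reg$orf_id[is_orf]]
    if (all(ex == 0)) stop("rna library with all expression zero")
    w_sig <- ab[is_orf] * reg$length_bp[is_orf] * ex
    lambda <- numeric(nrow(reg))
    lambda[is_orf] <- (1 - truth$noise_fraction) * depth * w_sig / sum(w_sig)
    if (truth$noise_fraction > 0) {
      w_noise <- ab[!is_orf] * reg$length_bp[!is_orf]
      if (!length(w_noise) || sum(w_noise) == 0) {
        stop("noise_fraction > 0 but no intergenic sequence to place noise on")
      }
      lambda[!is_orf] <- truth$noise_fraction * depth * w_noise / sum(w_noise)
    }
  }

  res <- with_seed(seed, {
    counts <- stats::rpois(length(lambda), lambda)
    reads <- NULL
    if (!is.null(sam_path)) {
      idx <- rep(seq_len(nrow(reg)), counts)
      rlen <- pmin(read_length, reg$length_bp[idx])
      starts <- reg$start0[idx] +
        floor(stats::runif(length(idx)) * (reg$length_bp[idx] - rlen + 1))
      strand <- ifelse(library == "rna" & reg$type[idx] == "orf",
                       reg$strand[idx],
                       sample(c("+", "-"), length(idx), replace = TRUE))
      reads <- data.frame(read_id = sprintf("%s_r%07d", library, seq_along(idx)),
                          contig_id = reg$contig_id[idx],
                          start0 = starts, length = rlen, strand = strand,
                          stringsAsFactors = FALSE)
    }
    list(counts = counts, reads = reads)
  })
  reg$count <- res$counts
  if (!is.null(sam_path)) write_sam(res$reads, contigs, sam_path)

  orf_reg <- reg[reg$type == "orf", , drop = FALSE]
  orf_counts <- data.frame(orf_id = orf_reg$orf_id, bin_id = orf_reg$bin_id,
                           count = orf_reg$count, stringsAsFactors = FALSE)
  gc <- stats::aggregate(count ~ bin_id, data = reg, FUN = sum)
  gc <- gc[order(gc$bin_id), ]
  rownames(gc) <- NULL
  list(orf_counts = orf_counts[order(orf_counts$orf_id), , drop = FALSE],
       genome_counts = gc,
       region_counts = reg,
       n_noise_reads = sum(reg$count[reg$type == "intergenic"]),
       library_id = library,
       sam_path = sam_path)
}

#' Simulate pathway definitions with per-genome presence ground truth
#'
#' Each pathway carries 2-8 reactions, roughly 30% flagged as key (always at
#' least one key and one non-key). Per genome, each pathway is materialized
#' in one of four classes: `complete` (all reactions held), `partial_nonkey`
#' (one or more non-key reactions missing), `partial_key` (a key reaction
#' missing), `absent` (no genes). Enzyme groups are singles or 2-3-subunit
#' complexes drawn from the genome's ORFs. The recorded `present` truth is
#' derived from the materialized content by the presence rule itself:
#' all key reactions held AND completeness >= `threshold`.
#'
#' @param sim Output of [simulate_genomes] (or any list with `genomes` and
#'   `orfs`).
#' @param n_pathways Number of pathways.
#' @param seed Seed.
#' @param threshold Completeness threshold used to record the `present` truth.
#' @param pathway_ids Optional explicit pathway ids (length `n_pathways`).
#' @return list with `definitions` ([pathway_definitions]) and `truth`
#'   (data.frame: bin_id, pathway_id, class, n_reactions, n_held,
#'   completeness, key_ok, present).
#' @export
simulate_pathways <- function(sim, n_pathways = 8, seed = 1L, threshold = 0.75,
                              pathway_ids = NULL) {
  genomes <- sim$genomes
  orfs <- sim$orfs
  if (is.null(pathway_ids)) pathway_ids <- sprintf("PWY%03d", seq_len(n_pathways))
  stopifnot(length(pathway_ids) == n_pathways)
  classes <- c("complete", "partial_nonkey", "partial_key", "absent")
  with_seed(seed, {
    def_rows <- list()
    truth_rows <- list()
    for (p in seq_len(n_pathways)) {
      n_rx <- sample(2:8, 1)
      n_key <- max(1, min(n_rx - 1, stats::rbinom(1, n_rx, 0.3)))
      is_key <- seq_len(n_rx) %in% sample(n_rx, n_key)
      rx_ids <- sprintf("%s_rx%d", pathway_ids[p], seq_len(n_rx))
      # declaration rows fix the pathway's full reaction list regardless of
      # which genomes carry genes for each reaction
      for (r in seq_len(n_rx)) {
        def_rows[[length(def_rows) + 1]] <-
          data.frame(pathway_id = pathway_ids[p], name = pathway_ids[p],
                     reaction_id = rx_ids[r], is_key = is_key[r],
                     group_kind = "none", members = "",
                     stringsAsFactors = FALSE)
      }
      for (b in genomes$bins$bin_id) {
        full_pool <- orfs$orf_id[orfs$contig_id %in%
                                   genomes$contigs$contig_id[genomes$contigs$bin_id == b]]
        pool <- full_pool
        cls <- sample(classes, 1)
        held <- switch(cls,
          complete = rep(TRUE, n_rx),
          partial_nonkey = {
            h <- rep(TRUE, n_rx)
            nk <- which(!is_key)
            h[sample(nk, sample(length(nk), 1))] <- FALSE
            h
          },
          partial_key = {
            h <- rep(TRUE, n_rx)
            k <- which(is_key)
            h[if (length(k) == 1) k else sample(k, 1)] <- FALSE
            h
          },
          absent = rep(FALSE, n_rx))
        for (r in which(held)) {
          n_groups <- sample(1:2, 1)
          for (gidx in seq_len(n_groups)) {
            kind <- sample(c("single", "complex"), 1, prob = c(0.7, 0.3))
            k <- if (kind == "single") 1 else sample(2:3, 1)
            # member ORFs are unique within a pathway while the genome's pool
            # lasts; small genomes fall back to reuse across reactions
            if (length(pool) < k) pool <- full_pool
            if (length(full_pool) < k) {
              stop("genome ", b, " has too few ORFs for pathway simulation")
            }
            members <- sample(pool, k)
            pool <- setdiff(pool, members)
            def_rows[[length(def_rows) + 1]] <-
              data.frame(pathway_id = pathway_ids[p], name = pathway_ids[p],
                         reaction_id = rx_ids[r], is_key = is_key[r],
                         group_kind = kind,
                         members = paste(members, collapse = ","),
                         stringsAsFactors = FALSE)
          }
        }
        completeness <- sum(held) / n_rx
        key_ok <- all(held[is_key])
        truth_rows[[length(truth_rows) + 1]] <-
          data.frame(bin_id = b, pathway_id = pathway_ids[p], class = cls,
                     n_reactions = n_rx, n_held = sum(held),
                     completeness = completeness, key_ok = key_ok,
                     present = key_ok && completeness >= threshold,
                     stringsAsFactors = FALSE)
      }
    }
    defs <- pathway_definitions(do.call(rbind, def_rows))
    truth <- do.call(rbind, truth_rows)
    rownames(truth) <- NULL
    list(definitions = defs, truth = truth)
  })
}

#' Generate a full synthetic community and write it in pipeline input formats
#'
#' Emits FASTA, GFF3, contig-bin assignment, DNA/RNA SAM files, pathway
#' definitions, a functional-annotation table, and ground-truth TSVs
#' (`truth_abundance.tsv`, `truth_expression.tsv`, `truth_counts.tsv`,
#' `truth_pathways.tsv`) into `outdir`.
#'
#' @param outdir Output directory (created if needed).
#' @param spec Genome specification (default [community_spec]).
#' @param seed Master seed governing all draws via [split_seed] substreams.
#' @param concentration Dirichlet concentration for the composition.
#' @param meanlog,sdlog Log-normal expression parameters.
#' @param noise_fraction Intergenic read fraction for the RNA library.
#' @param dna_depth,rna_depth Expected library sizes.
#' @param n_pathways Generic pathways to simulate (amino-acid biosynthesis /
#'   degradation pathways for all 20 amino acids are added on top).
#' @param emit_sam Write SAM files (otherwise only truth count tables).
#' @param read_length Simulated read length.
#' @return Invisible list with the truth objects and a named vector of file
#'   paths.
#' @export
simulate_community <- function(outdir, spec = community_spec(), seed = 1L,
                               concentration = 1, meanlog = 0, sdlog = 1,
                               noise_fraction = 0.05,
                               dna_depth = 2e6, rna_depth = 1e6,
                               n_pathways = 8, emit_sam = TRUE,
                               read_length = 125) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seeds <- split_seed(seed, 7)
  sim <- simulate_genomes(spec, seed = seeds[1], sequences = emit_sam)
  abundance <- stats::setNames(
    simulate_composition(nrow(spec), concentration, seed = seeds[2]),
    sim$genomes$bins$bin_id)
  expression <- simulate_expression(sim$orfs, meanlog, sdlog, seed = seeds[3])
  truth <- community_truth(sim, abundance, expression, noise_fraction,
                           dna_depth, rna_depth)

  paths <- c(fasta = file.path(outdir, "community.fasta"),
             gff = file.path(outdir, "orfs.gff3"),
             bins = file.path(outdir, "bins.tsv"),
             sam_dna = file.path(outdir, "dna.sam"),
             sam_rna = file.path(outdir, "rna.sam"),
             pathways = file.path(outdir, "pathways.tsv"),
             annotations = file.path(outdir, "annotations.tsv"),
             truth_abundance = file.path(outdir, "truth_abundance.tsv"),
             truth_expression = file.path(outdir, "truth_expression.tsv"),
             truth_counts = file.path(outdir, "truth_counts.tsv"),
             truth_pathways = file.path(outdir, "truth_pathways.tsv"))

  if (emit_sam) {
    Biostrings::writeXStringSet(truth$sequences, paths["fasta"], width = 80)
  }
  write_gff3(sim$orfs, paths["gff"])
  write_bin_assignment(sim$genomes, paths["bins"])

  dna <- simulate_counts(truth, "dna", seed = seeds[4],
                         sam_path = if (emit_sam) paths[["sam_dna"]],
                         read_length = read_length)
  rna <- simulate_counts(truth, "rna", seed = seeds[5],
                         sam_path = if (emit_sam) paths[["sam_rna"]],
                         read_length = read_length)

  # pathways: generic + amino-acid biosynthesis/degradation for the 20
  aa <- AA_THREE_LETTER
  pw_ids <- c(sprintf("PWY%03d", seq_len(n_pathways)),
              paste0("biosyn_", aa), paste0("degrad_", aa))
  pw <- simulate_pathways(sim, n_pathways = length(pw_ids), seed = seeds[6],
                          pathway_ids = pw_ids)
  ann <- simulate_annotations(sim, seed = seeds[7])

  write_pathway_definitions(pw$definitions, paths["pathways"])
  write_annotation_table(ann, paths["annotations"])
  write_tsv(data.frame(bin_id = names(abundance),
                       abundance = unname(abundance)), paths["truth_abundance"])
  write_tsv(data.frame(orf_id = names(expression),
                       expression = unname(expression)), paths["truth_expression"])
  tc <- merge(stats::setNames(dna$orf_counts, c("orf_id", "bin_id", "count_dna")),
              stats::setNames(rna$orf_counts[, c("orf_id", "count")],
                              c("orf_id", "count_rna")), by = "orf_id")
  write_tsv(tc[order(tc$orf_id), ], paths["truth_counts"])
  write_tsv(pw$truth, paths["truth_pathways"])

  invisible(list(truth = truth, dna = dna, rna = rna, pathways = pw,
                 annotations = ann, paths = paths, seed = seed))
}

#' Simulate a functional-annotation table over a community's ORFs
#'
#' Assigns a subset of each genome's ORFs to peptidase / glycoside-hydrolase
#' / transporter families with random subcellular locations, and gives every
#' genome a random subset of denitrification marker systems.
#' @param sim Output of [simulate_genomes].
#' @param seed Seed.
#' @param fraction Fraction of ORFs annotated per family namespace.
#' @return An `annotation_table`.
#' @export
simulate_annotations <- function(sim, seed = 1L, fraction = 0.05) {
  fams <- list(peptidase = c("S08", "M23", "C25", "S01"),
               glycoside_hydrolase = c("GH13", "GH23", "GH3"),
               transporter = c("3.A.1", "2.A.3", "1.B.14"))
  markers <- c("narGHIJ", "napABCGH", "nirK", "nirS", "nrfHA",
               "norBC", "norZ", "nosZ")
  marker_subunits <- c(narGHIJ = 4, napABCGH = 5, nirK = 1, nirS = 1,
                       nrfHA = 2, norBC = 2, norZ = 1, nosZ = 1)
  with_seed(seed, {
    rows <- list()
    for (b in sim$genomes$bins$bin_id) {
      pool <- sim$orfs$orf_id[sim$orfs$contig_id %in%
                                sim$genomes$contigs$contig_id[sim$genomes$contigs$bin_id == b]]
      for (ns in names(fams)) {
        n <- max(1, round(fraction * length(pool)))
        if (!length(pool)) next
        picked <- sample(pool, min(n, length(pool)))
        rows[[length(rows) + 1]] <-
          data.frame(orf_id = picked, namespace = ns,
                     family_code = sample(fams[[ns]], length(picked), replace = TRUE),
                     location = sample(LOCATION_LEVELS, length(picked), replace = TRUE),
                     stringsAsFactors = FALSE)
      }
      sys <- sample(markers, sample(2:5, 1))
      for (m in sys) {
        k <- marker_subunits[[m]]
        if (length(pool) < k) next
        picked <- sample(pool, k)
        pool <- setdiff(pool, picked)
        rows[[length(rows) + 1]] <-
          data.frame(orf_id = picked, namespace = "marker", family_code = m,
                     location = "cytoplasmic", stringsAsFactors = FALSE)
      }
    }
    annotation_table(do.call(rbind, rows))
  })
}

#' Three-letter codes of the 20 proteinogenic amino acids
#' @export
AA_THREE_LETTER <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly",
                     "His", "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser",
                     "Thr", "Trp", "Tyr", "Val")
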