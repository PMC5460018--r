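#' Build and validate a pipeline configuration
#'
#' @param fasta,gff,bins,sam_dna,sam_rna,pathways,annotations,cost Input
#'   paths. `cost` defaults to the packaged biosynthetic-cost rank table.
#' @param outdir Output directory.
#' @param min_identity Minimum alignment identity (default 0.95).
#' @param stranded_rna,stranded_dna Strandedness per library (`"yes"` for
#'   strand-specific RNA-Seq; strand is meaningless for DNA, default `"no"`).
#' @param library_size_mode RPKM denominator mode (see [count_library]).
#' @param completeness_threshold Pathway completeness threshold.
#' @param include_unbinned Include the unbinned pool in community fractions.
#' @param n_perm Permutations for the cost association.
#' @param seed Pipeline seed.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(fasta, gff, bins, sam_dna, sam_rna,
                            pathways, annotations,
                            cost = system.file("extdata", "aa_cost_ranks.tsv",
                                               package = "granuletx"),
                            outdir = "granuletx_out",
                            min_identity = 0.95,
                            stranded_rna = "yes", stranded_dna = "no",
                            library_size_mode = "mapped",
                            completeness_threshold = 0.75,
                            include_unbinned = FALSE,
                            n_perm = 10000, seed = 1L) {
  cfg <- list(fasta = fasta, gff = gff, bins = bins, sam_dna = sam_dna,
              sam_rna = sam_rna, pathways = pathways,
              annotations = annotations, cost = cost, outdir = outdir,
              min_identity = min_identity, stranded_rna = stranded_rna,
              stranded_dna = stranded_dna,
              library_size_mode = library_size_mode,
              completeness_threshold = completeness_threshold,
              include_unbinned = include_unbinned,
              n_perm = n_perm, seed = seed)
  validate_config(cfg)
}

#' @rdname pipeline_config
#' @param path YAML configuration file mirroring the [pipeline_config]
#'   arguments.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

validate_config <- function(cfg) {
  if (!is.numeric(cfg$min_identity) || cfg$min_identity < 0 || cfg$min_identity > 1) {
    stop("config error: min_identity must be in [0, 1]")
  }
  if (cfg$completeness_threshold <= 0 || cfg$completeness_threshold > 1) {
    stop("config error: completeness_threshold must be in (0, 1]")
  }
  for (f in c("fasta", "gff", "bins", "sam_dna", "sam_rna", "pathways",
              "annotations", "cost")) {
    for (p in cfg[[f]]) {
      if (!file.exists(p)) stop("config error: missing input file (", f, "): ", p)
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full pipeline: count, express, profile
#'
#' Executes counting (both libraries), expression, community profile,
#' pathway calls, denitrification matrix, amino-acid matrix and
#' functional-family profile, writing tidy TSVs plus a JSON manifest with
#' input checksums, configuration, seed and versions. Identical
#' configuration and inputs yield byte-identical outputs.
#'
#' @param cfg A [pipeline_config].
#' @return Invisible list of in-memory results and the manifest.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  gs <- stage("read_inputs", read_genome_bins(cfg$fasta, cfg$bins))
  orfs <- stage("read_inputs", read_gff3(cfg$gff, gs))
  defs <- stage("read_inputs", read_pathway_definitions(cfg$pathways))
  ann <- stage("read_inputs", read_annotation_table(cfg$annotations))
  cost <- stage("read_inputs", read_cost_table(cfg$cost))

  seeds <- split_seed(cfg$seed, 3)
  ct_dna <- stage("count_dna", {
    aln <- read_sam(cfg$sam_dna, min_identity = cfg$min_identity)
    count_library(aln, gs, orfs, stranded = cfg$stranded_dna,
                  library_size_mode = cfg$library_size_mode,
                  library_id = "dna", seed = seeds[1])
  })
  ct_rna <- stage("count_rna", {
    aln <- read_sam(cfg$sam_rna, min_identity = cfg$min_identity)
    count_library(aln, gs, orfs, stranded = cfg$stranded_rna,
                  library_size_mode = cfg$library_size_mode,
                  library_id = "rna", seed = seeds[2])
  })
  expr <- stage("expression", expression_table(ct_rna, orfs))
  comm <- stage("community", community_profile(list(ct_dna, ct_rna), gs,
                                               include_unbinned = cfg$include_unbinned))
  calls <- stage("pathways", pathway_calls(defs, expr,
                                           threshold = cfg$completeness_threshold))
  denitro <- stage("denitrification", denitrification_profile(ann, expr))
  aa_map <- amino_acid_pathway_map(unique(defs$pathway_id))
  aa <- if (nrow(aa_map)) {
    stage("amino_acids", amino_acid_matrix(calls, cost, aa_map = aa_map,
                                           n_perm = cfg$n_perm, seed = seeds[3]))
  }
  fams <- stage("families", functional_family_profile(ann, expr))

  out <- function(name) file.path(cfg$outdir, name)
  write_count_table(ct_dna, out("counts_dna.tsv"))
  write_count_table(ct_rna, out("counts_rna.tsv"))
  write_expression_table(expr, out("expr.tsv"))
  write_tsv(as.data.frame(comm), out("community.tsv"))
  write_tsv(as.data.frame(calls), out("pathway_calls.tsv"))
  write_tsv(denitro, out("denitrification.tsv"))
  if (!is.null(aa)) {
    write_tsv(aa$matrix, out("amino_acids.tsv"))
    write_tsv(aa$cost_association, out("aa_cost_association.tsv"))
  }
  write_tsv(fams, out("families.tsv"))

  outputs <- list.files(cfg$outdir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(
    package = "granuletx",
    version = as.character(utils::packageVersion("granuletx")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    config = unclass(cfg),
    inputs = as.list(tools::md5sum(unlist(cfg[c("fasta", "gff", "bins", "sam_dna",
                                                "sam_rna", "pathways",
                                                "annotations", "cost")]))),
    outputs = as.list(tools::md5sum(outputs)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(genome_set = gs, orfs = orfs,
                 counts = list(dna = ct_dna, rna = ct_rna),
                 expression = expr, community = comm, pathway_calls = calls,
                 denitrification = denitro, amino_acids = aa,
                 families = fams, manifest = manifest))
}

#' Summarize a pipeline run as a compact report
#'
#' Per-bin abundance and expression fractions, the top expressed ORFs per
#' genome, and pathway-presence counts — the community-level quantities a
#' results narrative reports.
#'
#' @param bundle Result of [run_pipeline].
#' @param top_k Top ORFs per genome to include.
#' @param json_path Optional path; when given, the summary is also written
#'   as JSON.
#' @return list summary (invisibly returns it after optional writing).
#' @export
summarize_community <- function(bundle, top_k = 5, json_path = NULL) {
  comm <- bundle$community
  bins <- unique(comm$bin_id)
  per_bin <- lapply(bins, function(b) {
    list(bin_id = b,
         abundance_pct = 100 * comm$fraction[comm$bin_id == b & comm$library_id == "dna"],
         expression_pct = 100 * comm$fraction[comm$bin_id == b & comm$library_id == "rna"],
         n_pathways_present = if (!is.null(bundle$pathway_calls)) {
           sum(bundle$pathway_calls$present[bundle$pathway_calls$bin_id == b])
         } else 0L,
         top_expressed = {
           te <- top_expressed(bundle$expression, b, k = top_k)
           lapply(seq_len(nrow(te)), function(i) {
             list(orf_id = te$orf_id[i], rel_expr = te$rel_expr[i])
           })
         })
  })
  summary <- list(n_bins = length(bins),
                  library_sizes = list(dna = bundle$counts$dna$library_size,
                                       rna = bundle$counts$rna$library_size),
                  bins = per_bin)
  if (!is.null(json_path)) {
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  invisible(summary)
}
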