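# Plain-TSV inputs standing in for database-derived annotation products
# (MetaCyc-style pathway definitions, MEROPS/CAZy/TCDB family assignments,
# subcellular locations, amino-acid cost ranks). Keeping these as versioned
# TSVs decouples the pipeline from any database release format.

LOCATION_LEVELS <- c("extracellular", "outer_membrane", "periplasm",
                     "cytoplasmic", "inner_membrane", "unknown")
FAMILY_NAMESPACES <- c("peptidase", "glycoside_hydrolase", "transporter", "marker")

#' Construct pathway definitions from an enzyme-group table
#'
#' One row per enzyme group. Alternative groups within a reaction are
#' isozymes; the members of a `complex` group are the subunits of one
#' multi-subunit enzyme (e.g. hydrazine synthase hzsABC).
#'
#' @param df data.frame with columns `pathway_id`, `reaction_id`, `is_key`
#'   (logical or "true"/"false"), `group_kind` ("single"/"complex", or
#'   "none" for a reaction-declaration row with no enzyme group — it fixes
#'   the pathway's reaction list and key flags even when no profiled genome
#'   carries genes for the reaction), `members` (comma-separated ORF ids,
#'   empty for "none" rows), optional `name`.
#' @return data.frame of class `pathway_definitions` with list-column
#'   `members`.
#' @export
pathway_definitions <- function(df) {
  req <- c("pathway_id", "reaction_id", "is_key", "group_kind", "members")
  stopifnot(all(req %in% names(df)))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$pathway_id <- as.character(df$pathway_id)
  df$reaction_id <- as.character(df$reaction_id)
  if (!is.logical(df$is_key)) df$is_key <- tolower(as.character(df$is_key)) %in% c("true", "t", "1", "yes")
  if (!all(df$group_kind %in% c("single", "complex", "none"))) {
    stop("group_kind must be 'single', 'complex' or 'none'")
  }
  if (is.character(df$members)) {
    df$members <- strsplit(df$members, ",", fixed = TRUE)
  }
  df$members <- lapply(df$members, function(m) trimws(m[nzchar(trimws(m))]))
  n_members <- vapply(df$members, length, integer(1))
  if (any(df$group_kind == "none" & n_members > 0)) {
    stop("reaction-declaration rows (group_kind 'none') must have no members")
  }
  bad <- !nzchar(df$reaction_id) |
    (df$group_kind != "none" & n_members == 0)
  if (any(bad)) {
    stop("pathway with empty reaction or enzyme group: ",
         paste(unique(df$pathway_id[bad]), collapse = ", "))
  }
  single_multi <- df$group_kind == "single" & vapply(df$members, length, integer(1)) > 1
  if (any(single_multi)) stop("'single' enzyme group with more than one member")
  if (!"name" %in% names(df)) df$name <- df$pathway_id
  # per-pathway key flags must be consistent per reaction
  key_chk <- unique(df[, c("pathway_id", "reaction_id", "is_key")])
  if (anyDuplicated(key_chk[, c("pathway_id", "reaction_id")])) {
    stop("inconsistent is_key flag within a reaction")
  }
  df <- df[order(df$pathway_id, df$reaction_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("pathway_definitions", "data.frame")
  df
}

#' Read pathway definitions from TSV
#' @param path TSV with columns `pathway_id`, `name` (optional),
#'   `reaction_id`, `is_key`, `group_kind`, `members` (comma-separated).
#' @return A [pathway_definitions] table.
#' @export
read_pathway_definitions <- function(path) {
  pathway_definitions(read_tsv(path, required = c("pathway_id", "reaction_id",
                                                  "is_key", "group_kind", "members")))
}

#' Write pathway definitions as canonical TSV
#' @param defs A [pathway_definitions] table.
#' @param path Output path.
#' @export
write_pathway_definitions <- function(defs, path) {
  out <- data.frame(pathway_id = defs$pathway_id,
                    name = defs$name,
                    reaction_id = defs$reaction_id,
                    is_key = ifelse(defs$is_key, "true", "false"),
                    group_kind = defs$group_kind,
                    members = vapply(defs$members, paste, character(1), collapse = ","),
                    stringsAsFactors = FALSE)
  write_tsv(out, path)
}

#' Read a functional-annotation table
#'
#' Maps ORFs to family codes (peptidase / glycoside hydrolase / transporter /
#' marker namespaces) and predicted subcellular locations. Unknown location
#' labels are mapped to `"unknown"` with a warning.
#'
#' @param path TSV with columns `orf_id`, `namespace`, `family_code`,
#'   `location`.
#' @return data.frame of class `annotation_table`.
#' @export
read_annotation_table <- function(path) {
  df <- read_tsv(path, required = c("orf_id", "namespace", "family_code", "location"))
  annotation_table(df)
}

#' @rdname read_annotation_table
#' @param df In-memory equivalent of the TSV.
#' @export
annotation_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!all(df$namespace %in% FAMILY_NAMESPACES)) {
    stop("unknown annotation namespace(s): ",
         paste(setdiff(unique(df$namespace), FAMILY_NAMESPACES), collapse = ", "))
  }
  bad_loc <- !(df$location %in% LOCATION_LEVELS)
  if (any(bad_loc)) {
    warning(sprintf("mapping %d unknown location label(s) to 'unknown': %s",
                    sum(bad_loc),
                    paste(unique(df$location[bad_loc]), collapse = ", ")))
    df$location[bad_loc] <- "unknown"
  }
  df <- df[order(df$orf_id, df$namespace, df$family_code), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("annotation_table", "data.frame")
  df
}

#' Write an annotation table as canonical TSV
#' @param ann An `annotation_table`.
#' @param path Output path.
#' @export
write_annotation_table <- function(ann, path) {
  write_tsv(as.data.frame(ann)[, c("orf_id", "namespace", "family_code", "location")], path)
}

#' Read an amino-acid biosynthetic-cost rank table
#'
#' Ranks order the 20 proteinogenic amino acids by biosynthetic cost
#' (1 = most costly). The table is configuration, not a built-in constant,
#' so alternative cost scales can be supplied.
#'
#' @param path TSV with columns `amino_acid` (3-letter code) and `cost_rank`.
#' @return data.frame of class `cost_table`; ranks validated as a
#'   permutation of 1..20.
#' @export
read_cost_table <- function(path) {
  cost_table(read_tsv(path, required = c("amino_acid", "cost_rank")))
}

#' @rdname read_cost_table
#' @param df In-memory equivalent of the TSV.
#' @export
cost_table <- function(df) {
  df <- data.frame(amino_acid = as.character(df$amino_acid),
                   cost_rank = as.integer(df$cost_rank),
                   stringsAsFactors = FALSE)
  if (nrow(df) != 20 || !setequal(df$cost_rank, 1:20)) {
    stop("cost table ranks must be a permutation of 1..20 over 20 amino acids")
  }
  if (anyDuplicated(df$amino_acid)) stop("duplicate amino acid in cost table")
  df <- df[order(df$cost_rank), ]
  rownames(df) <- NULL
  class(df) <- c("cost_table", "data.frame")
  df
}

#' Write a cost table as canonical TSV
#' @param ct A `cost_table`.
#' @param path Output path.
#' @export
write_cost_table <- function(ct, path) {
  write_tsv(as.data.frame(ct)[, c("amino_acid", "cost_rank")], path)
}
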