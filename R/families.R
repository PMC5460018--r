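#' Functional-family inventory with expression, stratified by location
#'
#' For each (genome, namespace, family code, subcellular location): the
#' number of member ORFs and their mean relative expression — the quantities
#' behind peptidase/transporter bubble plots (count as size, expression as
#' intensity). Families with no members in a genome yield no row.
#'
#' @param annotations An `annotation_table`.
#' @param expr An [expression_table].
#' @param namespaces Namespaces to include (default: peptidase,
#'   glycoside_hydrolase, transporter).
#' @return data.frame: `bin_id`, `namespace`, `family_code`, `location`,
#'   `n_orfs`, `mean_rel_expr`, `mean_rpkm`.
#' @export
functional_family_profile <- function(annotations, expr,
                                      namespaces = c("peptidase",
                                                     "glycoside_hydrolase",
                                                     "transporter")) {
  ann <- annotations[annotations$namespace %in% namespaces, , drop = FALSE]
  joined <- merge(ann, as.data.frame(expr)[, c("orf_id", "bin_id", "rpkm", "rel_expr")],
                  by = "orf_id")
  if (!nrow(joined)) {
    return(data.frame(bin_id = character(0), namespace = character(0),
                      family_code = character(0), location = character(0),
                      n_orfs = integer(0), mean_rel_expr = numeric(0),
                      mean_rpkm = numeric(0), stringsAsFactors = FALSE))
  }
  key <- interaction(joined$bin_id, joined$namespace, joined$family_code,
                     joined$location, drop = TRUE, sep = "\r")
  agg <- do.call(rbind, lapply(split(joined, key), function(g) {
    data.frame(bin_id = g$bin_id[1], namespace = g$namespace[1],
               family_code = g$family_code[1], location = g$location[1],
               n_orfs = nrow(g),
               mean_rel_expr = mean(g$rel_expr),
               mean_rpkm = mean(g$rpkm),
               stringsAsFactors = FALSE)
  }))
  agg <- agg[order(agg$bin_id, agg$namespace, agg$family_code, agg$location), ]
  rownames(agg) <- NULL
  agg
}
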