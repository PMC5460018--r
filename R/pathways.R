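# Pathway-level expression with the enzyme aggregation rules: within a
# multi-subunit complex the LOWEST expressed subunit sets the group's value
# (a complex runs no faster than its scarcest subunit, e.g. hydrazine
# synthase hzsABC); between isozymes / multi-copy genes the HIGHEST
# expressed gene is selected; a pathway's expression is the arithmetic mean
# over its reactions. Presence requires all key reactions plus a
# completeness threshold over the reconstructed pathway.

#' Expression of one enzyme group
#'
#' @param members Character vector of ORF ids (a single gene, or the
#'   subunits of one complex).
#' @param kind `"single"` or `"complex"`.
#' @param rpkm_lookup Named numeric vector of per-ORF RPKM.
#' @return list with `rpkm` (min over subunits for a complex, the member's
#'   value for a single) and `zero_subunit` (TRUE when a complex has a
#'   zero-RPKM subunit).
#' @export
enzyme_group_rpkm <- function(members, kind = c("single", "complex"), rpkm_lookup) {
  kind <- match.arg(kind)
  vals <- rpkm_lookup[members]
  if (any(is.na(vals))) stop("unresolvable enzyme-group member(s): ",
                             paste(members[is.na(vals)], collapse = ", "))
  if (kind == "single") {
    list(rpkm = unname(vals[1]), zero_subunit = FALSE)
  } else {
    list(rpkm = min(vals), zero_subunit = any(vals == 0))
  }
}

#' Expression of one reaction: maximum over its isozyme groups
#'
#' @param groups list of lists, each with `members` and `kind`.
#' @param rpkm_lookup Named per-ORF RPKM vector.
#' @return list with `rpkm` (max over group values) and `zero_subunit`
#'   (whether the selected aggregation saw a zero-RPKM complex subunit in
#'   any group).
#' @export
reaction_rpkm <- function(groups, rpkm_lookup) {
  if (!length(groups)) stop("reaction with no enzyme groups")
  vals <- lapply(groups, function(g) enzyme_group_rpkm(g$members, g$kind, rpkm_lookup))
  list(rpkm = max(vapply(vals, `[[`, numeric(1), "rpkm")),
       zero_subunit = any(vapply(vals, `[[`, logical(1), "zero_subunit")))
}

# Resolve a definitions table against one genome's expression rows:
# keep groups whose members all belong to the genome's ORF set.
resolve_groups <- function(defs, orf_ids) {
  ok <- defs$group_kind != "none" &
    vapply(defs$members, function(m) all(m %in% orf_ids), logical(1))
  defs[ok, , drop = FALSE]
}

#' Call one pathway in one genome
#'
#' A reaction is assigned when at least one of its enzyme groups fully
#' resolves to the genome's ORFs. `completeness` is the assigned fraction of
#' reactions; `present` requires every key reaction assigned and
#' completeness at or above `threshold`. `pathway_rpkm` is the mean of
#' reaction values over assigned reactions (reactions with no genes carry no
#' value and are excluded from the mean by default; `unassigned = "zero"`
#' zero-fills them instead). `rel_pathway_expr` relativizes by the genome's
#' median ORF RPKM, so 1 marks median expression.
#'
#' @param defs A [pathway_definitions] table (one pathway's rows, or a full
#'   table from which `pathway_id` is selected).
#' @param pathway_id Pathway to call.
#' @param bin_id Genome to profile.
#' @param expr An [expression_table].
#' @param threshold Completeness threshold in (0, 1], default 0.75.
#' @param unassigned `"exclude"` (default) or `"zero"`.
#' @return One-row data.frame of class `pathway_call`.
#' @export
pathway_call <- function(defs, pathway_id, bin_id, expr, threshold = 0.75,
                         unassigned = c("exclude", "zero")) {
  unassigned <- match.arg(unassigned)
  stopifnot(threshold > 0, threshold <= 1)
  pd <- defs[defs$pathway_id == pathway_id, , drop = FALSE]
  if (!nrow(pd)) stop("unknown pathway: ", pathway_id)
  erows <- expr[expr$bin_id == bin_id, , drop = FALSE]
  rpkm_lookup <- stats::setNames(erows$rpkm, erows$orf_id)
  med <- genome_medians(expr)
  med_rpkm <- med$median_rpkm[med$bin_id == bin_id]

  reactions <- unique(pd[, c("reaction_id", "is_key")])
  res <- resolve_groups(pd, erows$orf_id)
  assigned_rx <- unique(res$reaction_id)
  rx_vals <- vapply(assigned_rx, function(r) {
    g <- res[res$reaction_id == r, , drop = FALSE]
    groups <- lapply(seq_len(nrow(g)), function(i) {
      list(members = g$members[[i]], kind = g$group_kind[i])
    })
    reaction_rpkm(groups, rpkm_lookup)$rpkm
  }, numeric(1))

  n_rx <- nrow(reactions)
  completeness <- length(assigned_rx) / n_rx
  key_ok <- all(reactions$reaction_id[reactions$is_key] %in% assigned_rx)
  present <- key_ok && completeness >= threshold && length(assigned_rx) > 0
  pathway_rpkm <- if (!length(assigned_rx)) {
    NA_real_
  } else if (unassigned == "exclude") {
    mean(rx_vals)
  } else {
    sum(rx_vals) / n_rx
  }
  out <- data.frame(bin_id = bin_id, pathway_id = pathway_id,
                    present = present, completeness = completeness,
                    key_ok = key_ok,
                    n_reactions = n_rx, n_assigned = length(assigned_rx),
                    pathway_rpkm = pathway_rpkm,
                    rel_pathway_expr = if (length(med_rpkm) && med_rpkm > 0) {
                      pathway_rpkm / med_rpkm
                    } else NA_real_,
                    stringsAsFactors = FALSE)
  class(out) <- c("pathway_call", "data.frame")
  out
}

#' Call every pathway in every genome
#'
#' @param defs A [pathway_definitions] table.
#' @param expr An [expression_table].
#' @param bins Genomes to profile (default: all bins in `expr` except
#'   `"unbinned"`).
#' @inheritParams pathway_call
#' @return data.frame of stacked [pathway_call] rows.
#' @export
pathway_calls <- function(defs, expr, bins = NULL, threshold = 0.75,
                          unassigned = c("exclude", "zero")) {
  unassigned <- match.arg(unassigned)
  if (is.null(bins)) bins <- setdiff(sort(unique(expr$bin_id)), "unbinned")
  out <- do.call(rbind, lapply(bins, function(b) {
    do.call(rbind, lapply(unique(defs$pathway_id), function(p) {
      pathway_call(defs, p, b, expr, threshold = threshold, unassigned = unassigned)
    }))
  }))
  rownames(out) <- NULL
  out
}

# Denitrification step definitions: each step is reducible by one or more
# alternative enzyme systems (isozymes -> max); multi-subunit systems
# aggregate by min over subunits. ORFs sharing a complex-system marker code
# within a genome are treated as that complex's subunits; multiple copies of
# a single-gene marker are multi-copy genes (max).
DENITRIFICATION_STEPS <- list(
  "NO3->NO2" = list(nar = list(code = "narGHIJ", kind = "complex"),
                    nap = list(code = "napABCGH", kind = "complex")),
  "NO2->NH4" = list(nrf = list(code = "nrfHA", kind = "complex")),
  "NO2->NO" = list(nirK = list(code = "nirK", kind = "single"),
                   nirS = list(code = "nirS", kind = "single")),
  "NO->N2O" = list(norBC = list(code = "norBC", kind = "complex"),
                   norZ = list(code = "norZ", kind = "single")),
  "N2O->N2" = list(nos = list(code = "nosZ", kind = "single")))

#' Denitrification step presence/expression matrix
#'
#' For each genome and each reduction step (NO3->NO2, NO2->NH4, NO2->NO,
#' NO->N2O, N2O->N2), reports presence (any marker system annotated),
#' step RPKM under the complex-min / isozyme-max rules, its log2 (NA at 0),
#' and a `zero_subunit_flag` raised when a present complex has a subunit
#' with zero counts — the step is encoded but one subunit shows no
#' detectable expression (e.g. an unexpressed narI membrane anchor).
#'
#' @param annotations An `annotation_table`; marker rows use namespace
#'   `"marker"` and codes narGHIJ, napABCGH, nirK, nirS, nrfHA, norBC, norZ,
#'   nosZ.
#' @param expr An [expression_table].
#' @param bins Genomes to profile (default all in `expr` except unbinned).
#' @return data.frame of class `denitrification_matrix`: `bin_id`, `step`,
#'   `present`, `step_rpkm`, `log2_step_rpkm`, `zero_subunit_flag`.
#' @export
denitrification_profile <- function(annotations, expr, bins = NULL) {
  if (is.null(bins)) bins <- setdiff(sort(unique(expr$bin_id)), "unbinned")
  mk <- annotations[annotations$namespace == "marker", , drop = FALSE]
  rows <- list()
  for (b in bins) {
    erows <- expr[expr$bin_id == b, , drop = FALSE]
    rpkm_lookup <- stats::setNames(erows$rpkm, erows$orf_id)
    count_lookup <- stats::setNames(erows$count, erows$orf_id)
    for (step in names(DENITRIFICATION_STEPS)) {
      systems <- DENITRIFICATION_STEPS[[step]]
      sys_rpkm <- numeric(0)
      zero_flag <- FALSE
      for (sys in systems) {
        members <- mk$orf_id[mk$family_code == sys$code & mk$orf_id %in% erows$orf_id]
        if (!length(members)) next
        if (sys$kind == "complex") {
          sys_rpkm <- c(sys_rpkm, min(rpkm_lookup[members]))
          if (any(count_lookup[members] == 0)) zero_flag <- TRUE
        } else {
          sys_rpkm <- c(sys_rpkm, max(rpkm_lookup[members]))
        }
      }
      present <- length(sys_rpkm) > 0
      step_rpkm <- if (present) max(sys_rpkm) else NA_real_
      rows[[length(rows) + 1]] <-
        data.frame(bin_id = b, step = step, present = present,
                   step_rpkm = step_rpkm,
                   log2_step_rpkm = if (present && step_rpkm > 0) {
                     log2(step_rpkm)
                   } else NA_real_,
                   zero_subunit_flag = present && zero_flag,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("denitrification_matrix", "data.frame")
  out
}
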