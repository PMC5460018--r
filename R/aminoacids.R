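# Amino-acid biosynthesis/degradation profiles and biosynthetic-cost
# association. Auxotrophy for an amino acid is inferred from the absence of
# its biosynthesis pathway; the cost association asks whether the amino
# acids a genome can degrade are biased toward the costly end of the
# biosynthetic cost ranking (rank 1 = most costly).

#' Map pathway ids to amino acids and directions
#'
#' Default convention: `biosyn_<Aaa>` and `degrad_<Aaa>` with 3-letter
#' amino-acid codes. Supply an explicit map for other naming schemes.
#' @param pathway_ids Character vector.
#' @return data.frame `pathway_id`, `amino_acid`, `direction`
#'   (`biosynthesis`/`degradation`); non-matching ids are dropped.
#' @export
amino_acid_pathway_map <- function(pathway_ids) {
  m <- regmatches(pathway_ids, regexec("^(biosyn|degrad)_([A-Za-z]{3})$", pathway_ids))
  keep <- vapply(m, length, integer(1)) == 3
  data.frame(pathway_id = pathway_ids[keep],
             amino_acid = vapply(m[keep], `[`, character(1), 3),
             direction = ifelse(vapply(m[keep], `[`, character(1), 2) == "biosyn",
                                "biosynthesis", "degradation"),
             stringsAsFactors = FALSE)
}

#' Per-genome amino-acid biosynthesis/degradation matrix with cost ranking
#'
#' For each genome, a 20 x 2 table of relative pathway expression
#' (NA = pathway absent) for amino-acid biosynthesis and degradation,
#' auxotrophy calls (biosynthesis pathway absent), and a cost-association
#' statistic: a two-sided permutation test on the sum of biosynthetic cost
#' ranks of the amino acids the genome degrades, against random assignments
#' of the 20 ranks.
#'
#' @param calls Output of [pathway_calls] (needs `bin_id`, `pathway_id`,
#'   `present`, `rel_pathway_expr`).
#' @param cost A `cost_table` (ranks a permutation of 1..20, 1 most costly).
#' @param aa_map Optional explicit pathway-to-amino-acid map (see
#'   [amino_acid_pathway_map]).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Seed for the permutation draws.
#' @return list with `matrix` (bin_id, amino_acid, cost_rank, biosynthesis,
#'   degradation, biosyn_present, degrad_present, auxotroph) and
#'   `cost_association` (bin_id, n_degraded, rank_sum, expected_rank_sum,
#'   p_value).
#' @export
amino_acid_matrix <- function(calls, cost, aa_map = NULL, n_perm = 10000,
                              seed = 1L) {
  stopifnot(inherits(cost, "cost_table"))
  if (is.null(aa_map)) aa_map <- amino_acid_pathway_map(unique(calls$pathway_id))
  if (!nrow(aa_map)) stop("no amino-acid pathways found in the calls")
  missing_aa <- setdiff(aa_map$amino_acid, cost$amino_acid)
  if (length(missing_aa)) {
    stop("amino acid(s) missing from cost table: ", paste(missing_aa, collapse = ", "))
  }
  cc <- merge(calls, aa_map, by = "pathway_id")
  rank_of <- stats::setNames(cost$cost_rank, cost$amino_acid)

  bins <- sort(unique(cc$bin_id))
  mat <- do.call(rbind, lapply(bins, function(b) {
    sub <- cc[cc$bin_id == b, , drop = FALSE]
    out <- data.frame(bin_id = b, amino_acid = cost$amino_acid,
                      cost_rank = cost$cost_rank,
                      biosynthesis = NA_real_, degradation = NA_real_,
                      biosyn_present = FALSE, degrad_present = FALSE,
                      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(sub))) {
      j <- match(sub$amino_acid[i], out$amino_acid)
      if (sub$direction[i] == "biosynthesis") {
        out$biosyn_present[j] <- sub$present[i]
        if (sub$present[i]) out$biosynthesis[j] <- sub$rel_pathway_expr[i]
      } else {
        out$degrad_present[j] <- sub$present[i]
        if (sub$present[i]) out$degradation[j] <- sub$rel_pathway_expr[i]
      }
    }
    out$auxotroph <- !out$biosyn_present
    out
  }))
  rownames(mat) <- NULL

  seeds <- split_seed(seed, length(bins))
  assoc <- do.call(rbind, lapply(seq_along(bins), function(i) {
    b <- bins[i]
    sub <- mat[mat$bin_id == b, , drop = FALSE]
    degraded <- sub$degrad_present
    m <- sum(degraded)
    if (m == 0 || m == 20) {
      return(data.frame(bin_id = b, n_degraded = m,
                        rank_sum = sum(sub$cost_rank[degraded]),
                        expected_rank_sum = m * mean(1:20),
                        p_value = NA_real_, stringsAsFactors = FALSE))
    }
    obs <- sum(sub$cost_rank[degraded])
    mu <- m * mean(1:20)
    perm <- with_seed(seeds[i], {
      vapply(seq_len(n_perm), function(k) sum(sample(1:20, m)), numeric(1))
    })
    p <- (1 + sum(abs(perm - mu) >= abs(obs - mu))) / (n_perm + 1)
    data.frame(bin_id = b, n_degraded = m, rank_sum = obs,
               expected_rank_sum = mu, p_value = p, stringsAsFactors = FALSE)
  }))
  rownames(assoc) <- NULL
  list(matrix = mat, cost_association = assoc)
}
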