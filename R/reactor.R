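#' Total-nitrogen removal efficiency between two reactor sampling points
#'
#' Total nitrogen at a sampling point is the sum of ammonia, nitrite and
#' nitrate nitrogen (mgN/l); the removal efficiency across a stage is
#' `1 - TN(to) / TN(from)`, reported as a percentage. Used on steady-state
#' process performance tables from partial-nitritation/anammox reactors.
#'
#' @param performance data.frame with columns `stage`, `ammonia_mgN_l`,
#'   `nitrite_mgN_l`, `nitrate_mgN_l` (as read from a process TSV; see
#'   `system.file("extdata", "reactor_performance.tsv", package =
#'   "granuletx")`).
#' @param from,to Stage labels of the influent and effluent of the stage.
#' @return list with `tn_in`, `tn_out` (mgN/l) and `removal_pct`.
#' @export
nitrogen_removal <- function(performance, from = "PN-effluent",
                             to = "Anammox-effluent") {
  req <- c("stage", "ammonia_mgN_l", "nitrite_mgN_l", "nitrate_mgN_l")
  stopifnot(all(req %in% names(performance)))
  tn <- function(stage) {
    row <- performance[performance$stage == stage, , drop = FALSE]
    if (nrow(row) != 1) stop("stage not found (or duplicated): ", stage)
    row$ammonia_mgN_l + row$nitrite_mgN_l + row$nitrate_mgN_l
  }
  tn_in <- tn(from)
  tn_out <- tn(to)
  list(tn_in = tn_in, tn_out = tn_out,
       removal_pct = 100 * (1 - tn_out / tn_in))
}
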