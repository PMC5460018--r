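#' Derive reproducible substream seeds from one master seed
#'
#' All randomness in the package flows from a single integer seed. Substreams
#' (per genome, per library, per stage) get their own seeds through a fixed
#' linear-congruential split so that regenerating one component does not
#' disturb the draws of another.
#'
#' @param seed Master integer seed.
#' @param n Number of substream seeds to derive.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
split_seed <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1)
  m <- 2147483647 # 2^31 - 1, Mersenne prime modulus
  s <- (abs(as.double(seed)) %% m)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- (s * 48271 + 11) %% m
    out[i] <- s
  }
  as.integer(out %% (m - 2) + 1)
}

#' Run an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so library code never perturbs the
#' caller's RNG state.
#' @param seed Integer seed (NULL = leave RNG untouched).
#' @param expr Expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Canonical TSV writers/readers: UTF-8, tab-delimited, header row, no quoting,
# no row names. Canonical form makes write(read(x)) byte-stable.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path, required = NULL) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  if (!is.null(required)) {
    missing <- setdiff(required, names(df))
    if (length(missing)) {
      stop(sprintf("%s: missing required column(s): %s",
                   basename(path), paste(missing, collapse = ", ")))
    }
  }
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
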