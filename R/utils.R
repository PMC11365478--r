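#' Evaluate an expression without advancing the global RNG stream
#'
#' Saves `.Random.seed`, evaluates `expr` (which may consume random numbers),
#' then restores the saved state. Used so that experiment probes (branch
#' populations, snapshots) never perturb the random trajectory of the
#' evolutionary run they observe.
#'
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_preserved_seed <- function(expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)  # initialize the RNG state
  saved <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", saved, envir = globalenv()))
  expr
}

# TSV writer that round-trips doubles exactly (%.17g), '.' decimal, UTF-8.
write_tsv_precise <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  fmt_col <- function(x) {
    if (is.double(x)) sprintf("%.17g", x)
    else as.character(x)
  }
  out <- vapply(df, fmt_col, character(nrow(df)))
  if (nrow(df) == 1L) out <- matrix(out, nrow = 1L)
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df) > 0L) apply(out, 1L, paste, collapse = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Locate mean-fitness plateaus in a trajectory
#'
#' A plateau is a maximal stretch of at least `min_length` consecutive values
#' whose total range does not exceed `tolerance` (drift-sized noise). Used to
#' check that trajectories rest on the discrete fitness ladder.
#'
#' @param x numeric trajectory (e.g. per-generation mean fitness).
#' @param min_length minimum plateau length in generations.
#' @param tolerance maximum max-minus-min range within a plateau.
#' @return `data.frame` with columns `start`, `end` (1-based indices into `x`)
#'   and `level` (the plateau median); zero rows when none is found.
#' @export
detect_plateaus <- function(x, min_length = 200L, tolerance = 0.015) {
  n <- length(x)
  out <- list()
  i <- 1L
  while (i <= n - min_length + 1L) {
    j <- i
    lo <- x[i]; hi <- x[i]
    while (j < n) {
      nl <- min(lo, x[j + 1L]); nh <- max(hi, x[j + 1L])
      if (nh - nl > tolerance) break
      j <- j + 1L; lo <- nl; hi <- nh
    }
    if (j - i + 1L >= min_length) {
      out[[length(out) + 1L]] <-
        data.frame(start = i, end = j, level = stats::median(x[i:j]))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(0), end = integer(0), level = numeric(0)))
  do.call(rbind, out)
}
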