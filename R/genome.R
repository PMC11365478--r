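#' Construct a regulatory genome
#'
#' A genome holds, for each of `n` genes, one *cis* and one *trans* regulatory
#' region. A region is a binary vector of length `L`: positions `1..L-1` are
#' strength bits and position `L` is the type bit. On the cis side the type bit
#' gates whether the gene accepts any regulation at all; on the trans side it
#' sets the sign of the regulation the gene exerts (1 = activation,
#' 0 = repression).
#'
#' Bit position 1 of the documentation convention is column 1 of the matrices
#' (leftmost character in the serialized format); the type bit is column `L`.
#'
#' @param cis integer matrix (`n` x `L`) of 0/1 values, row `i` = cis region of
#'   gene `i`.
#' @param trans integer matrix (`n` x `L`) of 0/1 values, row `j` = trans
#'   region of gene `j`.
#' @return An object of class `grn_genome` with elements `cis`, `trans`, `n`,
#'   `L`.
#' @seealso [init_genome()], [build_interaction_matrix()]
#' @export
grn_genome <- function(cis, trans) {
  cis <- as_bit_matrix(cis, "cis")
  trans <- as_bit_matrix(trans, "trans")
  if (!identical(dim(cis), dim(trans)))
    stop("'cis' and 'trans' must have identical dimensions", call. = FALSE)
  if (ncol(cis) < 2L)
    stop("region length L must be at least 2", call. = FALSE)
  if (nrow(cis) < 1L)
    stop("a genome needs at least one gene", call. = FALSE)
  structure(list(cis = cis, trans = trans, n = nrow(cis), L = ncol(cis)),
            class = "grn_genome")
}

as_bit_matrix <- function(x, what) {
  if (!is.matrix(x)) stop("'", what, "' must be a matrix", call. = FALSE)
  storage.mode(x) <- "integer"
  if (anyNA(x) || !all(x == 0L | x == 1L))
    stop("'", what, "' must contain only 0/1 values", call. = FALSE)
  x
}

#' Build a founder genome
#'
#' Founders carry closed cis regions (type bit 0, so no gene accepts any
#' regulation and the interaction matrix is all zero) and activator trans
#' regions (type bit 1). Strength bits are filled according to `strength`:
#' `"random"` draws i.i.d. uniform bits, `"zeros"`/`"ones"` set them all.
#'
#' @param n gene count.
#' @param L region length (>= 2).
#' @param strength strength-bit initialization policy.
#' @return A [grn_genome()] object.
#' @export
init_genome <- function(n = 10L, L = 30L,
                        strength = c("random", "zeros", "ones")) {
  strength <- match.arg(strength)
  s <- switch(strength,
              random = matrix(as.integer(stats::runif(n * (L - 1L)) < 0.5), n, L - 1L),
              zeros  = matrix(0L, n, L - 1L),
              ones   = matrix(1L, n, L - 1L))
  cis <- cbind(s, rep(0L, n))
  trans_s <- switch(strength,
                    random = matrix(as.integer(stats::runif(n * (L - 1L)) < 0.5), n, L - 1L),
                    zeros  = matrix(0L, n, L - 1L),
                    ones   = matrix(1L, n, L - 1L))
  trans <- cbind(trans_s, rep(1L, n))
  grn_genome(cis, trans)
}

#' @export
print.grn_genome <- function(x, ...) {
  cat("<grn_genome> ", x$n, " genes, regions of length ", x$L, "\n", sep = "")
  cat("  cis type bits accepting regulation: ", sum(x$cis[, x$L]), "/", x$n,
      "; activator trans regions: ", sum(x$trans[, x$L]), "/", x$n, "\n",
      sep = "")
  invisible(x)
}

#' Signed interaction strength between a cis and a trans region
#'
#' Returns 0 when the cis type bit is 0 (the gene accepts no regulation).
#' Otherwise the magnitude is the number of strength-bit positions set in both
#' regions, divided by `L`, and the sign follows the trans type bit
#' (1 = activation, 0 = repression). The maximum attainable magnitude is
#' therefore `(L-1)/L`.
#'
#' @param cis,trans binary vectors of equal length `L >= 2`.
#' @return A single number in `[-(L-1)/L, (L-1)/L]`.
#' @export
region_interaction <- function(cis, trans) {
  cis <- as_bits(cis, "cis")
  trans <- as_bits(trans, "trans")
  if (length(cis) != length(trans))
    stop("'cis' and 'trans' must have the same length", call. = FALSE)
  if (length(cis) < 2L)
    stop("region length L must be at least 2", call. = FALSE)
  interaction_cpp(cis, trans)
}

as_bits <- function(x, what) {
  x <- as.integer(x)
  if (anyNA(x) || !all(x == 0L | x == 1L))
    stop("'", what, "' must contain only 0/1 values", call. = FALSE)
  x
}

#' Interaction matrix of a genome
#'
#' Entry `(i, j)` is the effect of gene `j`'s trans region on gene `i`'s cis
#' region, so row `i` collects everything regulating gene `i`. The diagonal
#' (self-regulation) is computed by the same rule.
#'
#' @param genome a [grn_genome()].
#' @return A numeric `n` x `n` matrix with entries in `[-1, 1]`.
#' @export
build_interaction_matrix <- function(genome) {
  stopifnot(inherits(genome, "grn_genome"))
  build_matrix_cpp(genome$cis, genome$trans)
}

#' Incrementally refresh an interaction matrix after a single-region mutation
#'
#' After the genome has been mutated in the region `(gene_index, region)`, only
#' one row (cis mutation) or one column (trans mutation) of the matrix can have
#' changed; this recomputes exactly that slice and leaves every other entry
#' untouched.
#'
#' @param matrix interaction matrix consistent with the genome *before* the
#'   mutation.
#' @param genome the already-mutated [grn_genome()].
#' @param gene_index 1-based gene index of the mutated region.
#' @param region `"cis"` or `"trans"`.
#' @return The refreshed matrix, consistent with `genome`.
#' @export
refresh_after_mutation <- function(matrix, genome, gene_index,
                                   region = c("cis", "trans")) {
  stopifnot(inherits(genome, "grn_genome"))
  region <- match.arg(region)
  gene_index <- as.integer(gene_index)
  if (is.na(gene_index) || gene_index < 1L || gene_index > genome$n)
    stop("'gene_index' out of range 1..", genome$n, call. = FALSE)
  if (!is.matrix(matrix) || nrow(matrix) != genome$n || ncol(matrix) != genome$n)
    stop("'matrix' must be an n x n interaction matrix", call. = FALSE)
  refresh_cpp(matrix, genome$cis, genome$trans, gene_index - 1L,
              if (region == "cis") 0L else 1L)
}

#' Serialize genomes to a plain-text format
#'
#' One gene per line: `gene_index<TAB>cis_bits<TAB>trans_bits`, bits written
#' with position 1 leftmost and the type bit rightmost, preceded by a header
#' line `#genes=n L=L`. Several genomes in one file are separated by
#' `#individual k` lines.
#'
#' @param genomes a [grn_genome()] or a list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genomes <- function(genomes, path) {
  if (inherits(genomes, "grn_genome")) genomes <- list(genomes)
  g1 <- genomes[[1L]]
  lines <- c(sprintf("#genes=%d L=%d", g1$n, g1$L))
  for (k in seq_along(genomes)) {
    g <- genomes[[k]]
    if (g$n != g1$n || g$L != g1$L)
      stop("all genomes in one file must share n and L", call. = FALSE)
    if (length(genomes) > 1L) lines <- c(lines, sprintf("#individual %d", k))
    lines <- c(lines, sprintf("%d\t%s\t%s", seq_len(g$n),
                              apply(g$cis, 1L, paste, collapse = ""),
                              apply(g$trans, 1L, paste, collapse = "")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read genomes written by [write_genomes()]
#'
#' @param path input file path.
#' @return A list of [grn_genome()] objects (length one for single-genome
#'   files).
#' @export
read_genomes <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1L]
  m <- regmatches(hdr, regexec("^#genes=(\\d+) L=(\\d+)$", hdr))[[1L]]
  if (length(m) != 3L) stop("malformed genome file header: ", hdr, call. = FALSE)
  n <- as.integer(m[2L]); L <- as.integer(m[3L])
  body <- lines[-1L]
  blocks <- split(body[!startsWith(body, "#")],
                  cumsum(startsWith(body, "#"))[!startsWith(body, "#")])
  parse_block <- function(bl) {
    parts <- strsplit(bl, "\t", fixed = TRUE)
    cis <- t(vapply(parts, function(p) bits_of(p[2L], L), integer(L)))
    trans <- t(vapply(parts, function(p) bits_of(p[3L], L), integer(L)))
    if (nrow(cis) != n) stop("genome block has wrong gene count", call. = FALSE)
    grn_genome(cis, trans)
  }
  unname(lapply(blocks, parse_block))
}

bits_of <- function(s, L) {
  v <- as.integer(strsplit(s, "", fixed = TRUE)[[1L]])
  if (length(v) != L || anyNA(v) || !all(v %in% 0:1))
    stop("malformed bit string in genome file", call. = FALSE)
  v
}

#' Edge list of the nonzero interactions
#'
#' @param matrix interaction matrix.
#' @return `data.frame` with columns `source_gene` (the regulator `j`),
#'   `target_gene` (the regulated gene `i`) and `weight`.
#' @export
matrix_edgelist <- function(matrix) {
  idx <- which(matrix != 0, arr.ind = TRUE)
  data.frame(source_gene = as.integer(idx[, 2L]),
             target_gene = as.integer(idx[, 1L]),
             weight = matrix[idx])
}

#' Write the nonzero interactions as a TSV edge list
#'
#' @param matrix interaction matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(matrix, path) {
  write_tsv_precise(matrix_edgelist(matrix), path)
  invisible(path)
}
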