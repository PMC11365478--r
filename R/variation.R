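#' Draw mutation events for one offspring genome
#'
#' The number of events is Poisson(`mu`); each event picks one of the `2n`
#' regulatory regions uniformly and, within it, hits the type bit (position
#' `L`) with the region kind's type-bit probability, otherwise a uniform
#' strength bit in `1..L-1`. By default cis mutations fall uniformly over the
#' whole region (type-bit chance `1/L`), while trans type-bit hits are held
#' to 1%: flipping a trans type bit turns an activator into a repressor (or
#' back) for every gene it regulates, the kind of wholesale rewiring that is
#' biologically rare compared with nudging one interaction's strength.
#'
#' @param n gene count.
#' @param L region length.
#' @param mu expected number of mutations per genome per generation (>= 0).
#' @param type_bit_prob type-bit hit probability as `c(cis, trans)`; a single
#'   value applies to both region kinds.
#' @return `data.frame` with columns `gene_index`, `region` (`"cis"` or
#'   `"trans"`) and `bit_position` (1-based; `L` is the type bit). Zero rows
#'   when no mutation occurs.
#' @export
draw_mutations <- function(n, L, mu, type_bit_prob = c(1 / L, 0.01)) {
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu < 0)
    stop("'mu' must be a single non-negative number", call. = FALSE)
  type_bit_prob <- rep_len(as.numeric(type_bit_prob), 2L)
  k <- stats::rpois(1L, mu)
  if (k == 0L)
    return(data.frame(gene_index = integer(0), region = character(0),
                      bit_position = integer(0)))
  reg <- sample.int(2L * n, k, replace = TRUE)
  is_cis <- reg <= n
  pos <- ifelse(stats::runif(k) < ifelse(is_cis, type_bit_prob[1L],
                                         type_bit_prob[2L]),
                L, sample.int(L - 1L, k, replace = TRUE))
  data.frame(gene_index = ((reg - 1L) %% n) + 1L,
             region = ifelse(is_cis, "cis", "trans"),
             bit_position = as.integer(pos))
}

#' Apply mutation events to a genome, refreshing the matrix incrementally
#'
#' Each event flips the named bit; after a cis flip only the affected row of
#' the interaction matrix is recomputed, after a trans flip only the affected
#' column.
#'
#' @param genome a [grn_genome()].
#' @param matrix interaction matrix consistent with `genome`.
#' @param events `data.frame` as produced by [draw_mutations()].
#' @return List with the mutated `genome` and the refreshed `matrix`.
#' @export
apply_mutations <- function(genome, matrix, events) {
  stopifnot(inherits(genome, "grn_genome"))
  if (nrow(events) == 0L) return(list(genome = genome, matrix = matrix))
  if (any(events$gene_index < 1L | events$gene_index > genome$n))
    stop("'gene_index' out of range", call. = FALSE)
  if (any(events$bit_position < 1L | events$bit_position > genome$L))
    stop("'bit_position' out of range", call. = FALSE)
  if (!all(events$region %in% c("cis", "trans")))
    stop("'region' must be \"cis\" or \"trans\"", call. = FALSE)
  for (e in seq_len(nrow(events))) {
    g <- events$gene_index[e]
    p <- events$bit_position[e]
    if (events$region[e] == "cis") {
      genome$cis[g, p] <- 1L - genome$cis[g, p]
    } else {
      genome$trans[g, p] <- 1L - genome$trans[g, p]
    }
    matrix <- refresh_after_mutation(matrix, genome, g, events$region[e])
  }
  list(genome = genome, matrix = matrix)
}

#' Recombine two genomes by cis-region swapping
#'
#' The child takes every trans region from `parent1`; each cis region comes
#' from `parent2` with probability 1/2 (independently per gene), otherwise
#' from `parent1`. Because swapped-in cis regions meet a new set of trans
#' regions, the child's interaction matrix is rebuilt from its own regions
#' rather than copied from either parent.
#'
#' @param parent1,parent2 [grn_genome()] objects sharing `n` and `L`.
#' @param cis_from optional integer vector of 1/2 per gene overriding the
#'   random per-gene choice (used for deterministic tests).
#' @return List with the child `genome` and its rebuilt `matrix`.
#' @export
recombine_wagner <- function(parent1, parent2, cis_from = NULL) {
  check_parents(parent1, parent2)
  n <- parent1$n
  if (is.null(cis_from)) {
    cis_from <- ifelse(stats::runif(n) < 0.5, 2L, 1L)
  } else {
    cis_from <- as.integer(cis_from)
    if (length(cis_from) != n || !all(cis_from %in% 1:2))
      stop("'cis_from' must be a length-n vector of 1/2", call. = FALSE)
  }
  cis <- parent1$cis
  cis[cis_from == 2L, ] <- parent2$cis[cis_from == 2L, , drop = FALSE]
  child <- grn_genome(cis, parent1$trans)
  list(genome = child, matrix = build_interaction_matrix(child))
}

#' Recombine two genomes at a single gene breakpoint
#'
#' A breakpoint `j` is drawn uniformly from `{1, ..., n-1}`; genes `1..j`
#' inherit both regions from `parent1` and genes `j+1..n` both regions from
#' `parent2`, so the child always mixes the two parents. Interactions across
#' the breakpoint involve regions from different parents, hence the matrix is
#' rebuilt from the child's regions.
#'
#' @inheritParams recombine_wagner
#' @param breakpoint optional fixed breakpoint in `1..n-1` (for tests).
#' @return List with the child `genome`, its rebuilt `matrix`, and the
#'   `breakpoint` used.
#' @export
recombine_breakpoint <- function(parent1, parent2, breakpoint = NULL) {
  check_parents(parent1, parent2)
  n <- parent1$n
  if (n < 2L) stop("breakpoint recombination needs n >= 2", call. = FALSE)
  if (is.null(breakpoint)) {
    breakpoint <- sample.int(n - 1L, 1L)
  } else {
    breakpoint <- as.integer(breakpoint)
    if (is.na(breakpoint) || breakpoint < 1L || breakpoint > n - 1L)
      stop("'breakpoint' must lie in 1..n-1", call. = FALSE)
  }
  take1 <- seq_len(n) <= breakpoint
  cis <- parent1$cis; trans <- parent1$trans
  cis[!take1, ] <- parent2$cis[!take1, , drop = FALSE]
  trans[!take1, ] <- parent2$trans[!take1, , drop = FALSE]
  child <- grn_genome(cis, trans)
  list(genome = child, matrix = build_interaction_matrix(child),
       breakpoint = breakpoint)
}

check_parents <- function(parent1, parent2) {
  stopifnot(inherits(parent1, "grn_genome"), inherits(parent2, "grn_genome"))
  if (parent1$n != parent2$n || parent1$L != parent2$L)
    stop("parents must share n and L", call. = FALSE)
  invisible(TRUE)
}
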