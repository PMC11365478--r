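#' Specify a fitness optimum
#'
#' The optimum is a vector over `{0, 1, NA}`; `NA` marks a neutrally evolving
#' ("free") gene whose state never enters the fitness distance. An all-`NA`
#' target is allowed and makes every viable individual equally fit (pure
#' drift).
#'
#' @param target vector of 0, 1 and `NA` values, one per gene.
#' @param sigma2 selection-strength denominator (> 0); larger values flatten
#'   the fitness function.
#' @return An object of class `grn_optimum`.
#' @export
optimum_spec <- function(target, sigma2 = 5) {
  if (length(target) < 1L) stop("'target' must have at least one gene", call. = FALSE)
  tn <- suppressWarnings(as.integer(target))
  if (any(!is.na(tn) & !(tn %in% 0:1)))
    stop("'target' entries must be 0, 1 or NA", call. = FALSE)
  if (!is.numeric(sigma2) || length(sigma2) != 1L || !is.finite(sigma2) || sigma2 <= 0)
    stop("'sigma2' must be a single positive number", call. = FALSE)
  structure(list(target = tn, sigma2 = as.numeric(sigma2)),
            class = "grn_optimum")
}

target_codes <- function(optimum) {
  t <- optimum$target
  t[is.na(t)] <- -1L
  t
}

#' One synchronous update of the expression vector
#'
#' Gene `i` receives the input `sum_j M[i,j] * E[j]` over the currently
#' expressed genes; its new state is 1 when the input is strictly positive and
#' 0 otherwise (zero or net-repressive input silences the gene). Genes whose
#' cis type bit is 0 have an all-zero matrix row and are therefore permanently
#' silent.
#'
#' @param matrix interaction matrix (`n` x `n`).
#' @param state binary expression vector of length `n`.
#' @return The updated binary vector.
#' @export
step_expression <- function(matrix, state) {
  state <- as_bits(state, "state")
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix))
    stop("'matrix' must be square", call. = FALSE)
  if (length(state) != nrow(matrix))
    stop("'state' length must match the matrix dimension", call. = FALSE)
  step_cpp(matrix, state)
}

#' Iterate expression dynamics to an equilibrium
#'
#' Repeatedly applies [step_expression()], recording every visited state, until
#' some state is revisited. A revisit with period 1 is a fixed point; period
#' `k >= 2` is a cycle (one full period of states is returned, in order); if no
#' state repeats within `step_cap` steps the individual is non-viable.
#'
#' @param matrix interaction matrix.
#' @param initial initial binary expression vector.
#' @param step_cap maximum number of update steps (default 10000).
#' @return An object of class `grn_maturation`: list with `outcome`
#'   (`"fixed_point"`, `"cycle"` or `"non_viable"`), `final_state` (fixed
#'   points only), `cycle_states` (`k` x `n` matrix, cycles only), `period`
#'   and `steps`.
#' @export
mature <- function(matrix, initial, step_cap = 10000L) {
  initial <- as_bits(initial, "initial")
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix))
    stop("'matrix' must be square", call. = FALSE)
  if (length(initial) != nrow(matrix))
    stop("'initial' length must match the matrix dimension", call. = FALSE)
  step_cap <- as.integer(step_cap)
  if (is.na(step_cap) || step_cap < 1L)
    stop("'step_cap' must be a positive integer", call. = FALSE)
  r <- mature_cpp(matrix, initial, step_cap)
  outcome <- c("fixed_point", "cycle", "non_viable")[r$outcome]
  structure(list(outcome = outcome,
                 final_state = if (outcome == "fixed_point") r$final else NULL,
                 cycle_states = if (outcome == "cycle") r$cycle else NULL,
                 period = if (outcome == "non_viable") NA_integer_ else r$period,
                 steps = r$steps),
            class = "grn_maturation")
}

#' @export
print.grn_maturation <- function(x, ...) {
  cat("<grn_maturation> outcome:", x$outcome)
  if (x$outcome == "fixed_point")
    cat(" at (", paste(x$final_state, collapse = ""), ")", sep = "")
  if (x$outcome == "cycle") cat(", period", x$period)
  cat(", after", x$steps, "steps\n")
  invisible(x)
}

#' Fitness of an expression vector
#'
#' `exp(-d / sigma2)` where `d` is the Euclidean distance between the
#' expression vector and the optimum over the non-free genes; for binary
#' vectors `d` is the square root of the number of mismatched selected genes.
#' Equals 1 exactly when all selected genes match.
#'
#' @param expression binary vector.
#' @param optimum an [optimum_spec()].
#' @return A number in `(0, 1]`.
#' @export
expression_fitness <- function(expression, optimum) {
  stopifnot(inherits(optimum, "grn_optimum"))
  expression <- as_bits(expression, "expression")
  if (length(expression) != length(optimum$target))
    stop("'expression' and optimum target lengths differ", call. = FALSE)
  sel <- !is.na(optimum$target)
  d <- sqrt(sum(expression[sel] != optimum$target[sel]))
  exp(-d / optimum$sigma2)
}

#' Mature an individual and score its fitness
#'
#' Fixed points are scored by [expression_fitness()] of the equilibrium state;
#' cycles by the minimum fitness over one full period (the transient before
#' the cycle does not contribute); non-viable individuals get fitness 0.
#'
#' @inheritParams mature
#' @param optimum an [optimum_spec()].
#' @return A number in `[0, 1]`.
#' @export
evaluate_individual <- function(matrix, initial, optimum, step_cap = 10000L) {
  stopifnot(inherits(optimum, "grn_optimum"))
  initial <- as_bits(initial, "initial")
  if (length(initial) != nrow(matrix) || length(optimum$target) != nrow(matrix))
    stop("dimension mismatch between matrix, initial state and optimum",
         call. = FALSE)
  evaluate_cpp(matrix, initial, target_codes(optimum), optimum$sigma2,
               as.integer(step_cap))
}

#' The discrete set of attainable fixed-point fitness values
#'
#' With binary expression and a Euclidean distance, fitness can only take the
#' values `exp(-sqrt(k)/sigma2)` for `k = 0..n_selected` mismatches, which is
#' why population mean-fitness trajectories plateau at these levels.
#'
#' @param n_selected number of genes under selection.
#' @param sigma2 selection-strength denominator.
#' @return Numeric vector of length `n_selected + 1`, decreasing in `k`.
#' @export
fitness_ladder <- function(n_selected = 10L, sigma2 = 5) {
  exp(-sqrt(0:n_selected) / sigma2)
}
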