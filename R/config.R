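#' Simulation configuration
#'
#' Collects and validates every parameter of a forward run. The defaults are
#' the standard study conditions: 100 haploid individuals, 10 genes with
#' 30-bit regions, mutation rate 0.005 per genome per generation, selection
#' denominator `sigma2 = 5`, an all-ones optimum, and 15000 generations.
#' Expression at birth is the constant all-ones vector; founder matrices are
#' all zero, so every founder matures to the all-zero expression state.
#'
#' @param N population size (haploid individuals).
#' @param n gene count.
#' @param L region length in bits.
#' @param mu expected mutations per genome per generation.
#' @param sigma2 selection-strength denominator of the fitness function.
#' @param optimum target expression vector over `{0, 1, NA}`; `NA` marks a
#'   neutrally evolving gene (see [optimum_spec()]).
#' @param generations number of generations to evolve (generation 0 is the
#'   initialized population and is always recorded).
#' @param step_cap maturation step cap.
#' @param initial_expression binary expression vector at birth (the constant
#'   vector every newborn starts maturation from; all-ones by default, since
#'   an all-zero start is absorbing under the expression dynamics).
#' @param recombination_model `"none"`, `"wagner"` (cis swapping) or `"r1r2"`
#'   (single breakpoint).
#' @param recombination_prob probability that an offspring has two parents;
#'   defaults to 0.5 when a recombination model is enabled, 0 otherwise.
#' @param init_strength_bits strength-bit initialization policy for founders.
#' @param type_bit_prob probability that a mutation event hits the type bit,
#'   as `c(cis, trans)` (a single value applies to both regions). The default
#'   places cis mutations uniformly over the whole region (type-bit chance
#'   `1/L`) while trans type-bit hits are rare (1%), reflecting that flipping
#'   a trans type bit rewires the sign of every interaction the gene exerts.
#' @param genotype_identity what counts as "the same genotype" for the
#'   distinct-genotype statistics: the full genome bit string (`"genome"`),
#'   the raw interaction matrix (`"matrix"`), or the sign-discretized matrix
#'   (`"matrix_sign"`); see [genotype_keys()].
#' @param on_zero_fitness policy when every individual has fitness 0:
#'   `"error"` aborts with a diagnostic, `"uniform"` falls back to uniform
#'   parent choice (pure drift).
#' @param seed optional integer seed; [run_simulation()] calls `set.seed()`
#'   with it so runs are bit-reproducible.
#' @return An object of class `grn_config` (a validated list).
#' @export
sim_config <- function(N = 100L, n = 10L, L = 30L, mu = 0.005, sigma2 = 5,
                       optimum = rep(1L, n), generations = 15000L,
                       step_cap = 10000L,
                       initial_expression = rep(1L, n),
                       recombination_model = c("none", "wagner", "r1r2"),
                       recombination_prob = NULL,
                       init_strength_bits = c("random", "zeros", "ones"),
                       type_bit_prob = c(1 / L, 0.01),
                       genotype_identity = c("genome", "matrix",
                                             "matrix_sign"),
                       on_zero_fitness = c("error", "uniform"),
                       seed = NULL) {
  recombination_model <- match.arg(recombination_model)
  init_strength_bits <- match.arg(init_strength_bits)
  genotype_identity <- match.arg(genotype_identity)
  on_zero_fitness <- match.arg(on_zero_fitness)

  chk_int <- function(x, key, min) {
    x <- as.integer(x)
    if (length(x) != 1L || is.na(x) || x < min)
      stop("'", key, "' must be a single integer >= ", min, call. = FALSE)
    x
  }
  N <- chk_int(N, "N", 1L)
  n <- chk_int(n, "n", 1L)
  L <- chk_int(L, "L", 2L)
  generations <- chk_int(generations, "generations", 0L)
  step_cap <- chk_int(step_cap, "step_cap", 1L)
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu < 0)
    stop("'mu' must be a single non-negative number", call. = FALSE)
  if (!is.numeric(type_bit_prob) || !length(type_bit_prob) %in% 1:2 ||
      anyNA(type_bit_prob) || any(type_bit_prob < 0) || any(type_bit_prob > 1))
    stop("'type_bit_prob' must be one or two probabilities in [0, 1]",
         call. = FALSE)
  type_bit_prob <- rep_len(as.numeric(type_bit_prob), 2L)
  names(type_bit_prob) <- c("cis", "trans")
  opt <- optimum_spec(optimum, sigma2)
  if (length(opt$target) != n)
    stop("'optimum' must have one entry per gene (n = ", n, ")", call. = FALSE)
  initial_expression <- as_bits(initial_expression, "initial_expression")
  if (length(initial_expression) != n)
    stop("'initial_expression' must have length n", call. = FALSE)
  if (is.null(recombination_prob))
    recombination_prob <- if (recombination_model == "none") 0 else 0.5
  if (!is.numeric(recombination_prob) || recombination_prob < 0 ||
      recombination_prob > 1)
    stop("'recombination_prob' must lie in [0, 1]", call. = FALSE)
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (is.na(seed)) stop("'seed' must be an integer", call. = FALSE)
  }

  structure(list(N = N, n = n, L = L, mu = as.numeric(mu), sigma2 = opt$sigma2,
                 optimum = opt, generations = generations, step_cap = step_cap,
                 initial_expression = initial_expression,
                 recombination_model = recombination_model,
                 recombination_prob = as.numeric(recombination_prob),
                 init_strength_bits = init_strength_bits,
                 type_bit_prob = type_bit_prob,
                 genotype_identity = genotype_identity,
                 on_zero_fitness = on_zero_fitness,
                 seed = seed),
            class = "grn_config")
}

#' @export
print.grn_config <- function(x, ...) {
  cat("<grn_config>\n")
  cat(sprintf("  N=%d individuals, n=%d genes, L=%d bits, %d generations\n",
              x$N, x$n, x$L, x$generations))
  cat(sprintf("  mu=%g, type_bit_prob=(cis %g, trans %g), sigma2=%g, step_cap=%d\n",
              x$mu, x$type_bit_prob[1L], x$type_bit_prob[2L], x$sigma2,
              x$step_cap))
  tg <- x$optimum$target
  cat("  optimum:", paste(ifelse(is.na(tg), "N", tg), collapse = ""),
      sprintf("(%d selected, %d neutral)\n", sum(!is.na(tg)), sum(is.na(tg))))
  cat(sprintf("  recombination: %s (prob %g); founders: %s strength bits\n",
              x$recombination_model, x$recombination_prob,
              x$init_strength_bits))
  if (!is.null(x$seed)) cat("  seed:", x$seed, "\n")
  invisible(x)
}

recomb_code <- function(model) {
  switch(model, none = 0L, wagner = 1L, r1r2 = 2L)
}

zero_code <- function(policy) if (policy == "error") 0L else 1L
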