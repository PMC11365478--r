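#' Initialize a founder population
#'
#' Every founder has closed cis regions (type bit 0: no gene accepts
#' regulation, so all interaction matrices are zero) and activator trans
#' regions (type bit 1); strength bits follow `config$init_strength_bits`,
#' drawn independently per individual for `"random"`. Each founder is matured
#' and scored; because the founder matrices are all zero, every founder
#' matures to the all-zero expression vector regardless of the birth state.
#'
#' @param config a [sim_config()].
#' @return An object of class `grn_population`: arrays `cis` and `trans`
#'   (`n x L x N` bits), `M` (`n x n x N`), `expression` (`n x N`), vectors
#'   `fitness`, `outcome` (1 fixed point / 2 cycle / 3 non-viable), `steps`,
#'   `period`, plus `n`, `L`, `N`.
#' @export
initialize_population <- function(config) {
  stopifnot(inherits(config, "grn_config"))
  n <- config$n; L <- config$L; N <- config$N
  fill <- function(type_bit) {
    a <- array(0L, c(n, L, N))
    a[, seq_len(L - 1L), ] <- switch(
      config$init_strength_bits,
      random = as.integer(stats::runif(n * (L - 1L) * N) < 0.5),
      zeros  = 0L,
      ones   = 1L)
    a[, L, ] <- type_bit
    a
  }
  cis <- fill(0L)
  trans <- fill(1L)
  M <- build_pop_matrices_cpp(cis, trans, n, L, N)
  dim(M) <- c(n, n, N)
  mt <- mature_pop_cpp(M, n, N, config$initial_expression, config$step_cap,
                       target_codes(config$optimum), config$sigma2)
  structure(list(cis = cis, trans = trans, M = M,
                 expression = mt$expression, fitness = mt$fitness,
                 outcome = mt$outcome, steps = mt$steps, period = mt$period,
                 n = n, L = L, N = N),
            class = "grn_population")
}

#' @export
print.grn_population <- function(x, ...) {
  cat(sprintf("<grn_population> %d individuals, %d genes (L=%d)\n",
              x$N, x$n, x$L))
  cat(sprintf("  fitness: mean %.4f, max %.4f; viable %d/%d\n",
              mean(x$fitness), max(x$fitness), sum(x$outcome != 3L), x$N))
  invisible(x)
}

#' Extract one individual's genome from a population
#'
#' @param population a `grn_population`.
#' @param k individual index in `1..N`.
#' @return A [grn_genome()].
#' @export
population_genome <- function(population, k) {
  stopifnot(inherits(population, "grn_population"))
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > population$N)
    stop("'k' out of range 1..", population$N, call. = FALSE)
  grn_genome(population$cis[, , k], population$trans[, , k])
}

#' Fitness-proportional parent choice
#'
#' Draws `count` parent indices i.i.d. with probability proportional to
#' fitness; zero-fitness individuals are never chosen. When every fitness is
#' zero the behaviour follows `on_zero`: abort with a diagnostic (default) or
#' fall back to uniform choice (pure drift).
#'
#' @param fitness numeric vector of non-negative fitness values.
#' @param count number of parents to draw.
#' @param on_zero `"error"` or `"uniform"`.
#' @return Integer vector of parent indices.
#' @export
select_parents <- function(fitness, count, on_zero = c("error", "uniform")) {
  on_zero <- match.arg(on_zero)
  if (any(fitness < 0) || anyNA(fitness))
    stop("'fitness' must be non-negative", call. = FALSE)
  if (!any(fitness > 0)) {
    if (on_zero == "error")
      stop("all individuals have zero fitness; no parent can be selected",
           call. = FALSE)
    return(sample.int(length(fitness), count, replace = TRUE))
  }
  sample.int(length(fitness), count, replace = TRUE, prob = fitness)
}

#' Produce the next (non-overlapping) generation
#'
#' Each of the `N` offspring draws one parent fitness-proportionally; with
#' probability `recombination_prob` (and an enabled model) a second parent is
#' drawn and the genomes recombine; Poisson(`mu`) bit-flip mutations are then
#' applied with incremental matrix refresh; finally the offspring is matured
#' and scored. The population size never changes.
#'
#' @param population a `grn_population`.
#' @param config the [sim_config()] governing the run.
#' @return The offspring `grn_population`.
#' @export
next_generation <- function(population, config) {
  stopifnot(inherits(population, "grn_population"),
            inherits(config, "grn_config"))
  n <- population$n; L <- population$L; N <- population$N
  r <- next_generation_cpp(population$cis, population$trans, population$M,
                           population$fitness, n, L, N,
                           config$mu, config$type_bit_prob[1L],
                           config$type_bit_prob[2L],
                           target_codes(config$optimum), config$sigma2,
                           config$initial_expression, config$step_cap,
                           recomb_code(config$recombination_model),
                           config$recombination_prob,
                           zero_code(config$on_zero_fitness))
  dim(r$cis) <- c(n, L, N); dim(r$trans) <- c(n, L, N); dim(r$M) <- c(n, n, N)
  structure(list(cis = r$cis, trans = r$trans, M = r$M,
                 expression = r$expression, fitness = r$fitness,
                 outcome = r$outcome, steps = r$steps, period = r$period,
                 n = n, L = L, N = N),
            class = "grn_population")
}

#' Genotype identity keys of a population
#'
#' Three notions of "the same genotype": the full `2nL`-bit genome string
#' (`"genome"`), the raw interaction matrix (`"matrix"` — mutations in
#' regions whose interactions are gated off are invisible, so this counts
#' regulatory phenotypes of the genotype), or the sign-discretized matrix
#' (`"matrix_sign"`, coarser still: only topology changes count).
#'
#' @param population a `grn_population`.
#' @param identity identity notion, see above.
#' @return Character vector of length `N`.
#' @export
genotype_keys <- function(population, identity = c("genome", "matrix",
                                                   "matrix_sign")) {
  identity <- match.arg(identity)
  if (identity == "genome")
    return(genome_keys_cpp(population$cis, population$trans,
                           population$n, population$L, population$N))
  v <- if (identity == "matrix") {
    # entries are (signed popcount)/L: scale back to exact integers
    matrix(as.integer(round(population$M * population$L)),
           ncol = population$N)
  } else {
    matrix(as.integer(sign(population$M)) + 1L, ncol = population$N)
  }
  apply(v, 2L, paste, collapse = ",")
}

# Shared Wright-Fisher orchestration used by both the regulatory model and the
# regulation-free baseline: the two differ only in step_fn (the genotype ->
# offspring map) and in how statistics are read off the state.
run_engine <- function(state, n_gen, step_fn, record_fn,
                       stop_fn = NULL, probe_fn = NULL, probe_at = integer(0)) {
  record_fn(state, 0L)
  if (!is.null(probe_fn) && 0L %in% probe_at) probe_fn(state, 0L)
  last <- 0L
  if (n_gen > 0L) {
    for (g in seq_len(n_gen)) {
      state <- step_fn(state)
      record_fn(state, g)
      if (!is.null(probe_fn) && g %in% probe_at) probe_fn(state, g)
      last <- g
      if (!is.null(stop_fn) && stop_fn(state, g)) break
    }
  }
  list(state = state, last = last)
}

#' Run a forward simulation
#'
#' Evolves a founder population for `config$generations` generations and
#' records per-generation statistics: mean and maximum fitness, the number of
#' viable individuals, the number of distinct genotypes in the generation, the
#' cumulative number of distinct genotypes seen since generation 0, and (when
#' the optimum mixes selected and neutral genes) the mean number of
#' sign-matrix interactions crossing the selected/neutral partition.
#'
#' Optional robustness probes: every `robustness_interval` generations the
#' population is cloned, the clone receives `branch_mutations` extra mutations
#' per individual, both copies are matured, and the expression and topology
#' identities between them are recorded. Probes run inside
#' [with_preserved_seed()], so they never alter the trajectory.
#'
#' @param config a [sim_config()].
#' @param robustness_interval probe spacing in generations (`NULL` = no
#'   probes; generation 0 is always probed when enabled).
#' @param branch_mutations mutations injected per branch individual.
#' @param stop_when optional early stop: `"individual_optimum"` stops once any
#'   individual reaches fitness 1, `"population_optimum"` once every
#'   individual does (mean fitness 1).
#' @param snapshot_every write the whole population to a genome text file
#'   every this many generations (`NULL` = never).
#' @param snapshot_dir directory for snapshot files (`gen000000.txt`, ...);
#'   created if needed.
#' @param track_genotypes maintain the distinct-genotype statistics? Skipping
#'   them (`FALSE`) leaves `n_distinct`/`cum_distinct` as `NA` and saves the
#'   bookkeeping in long scans that only need fitness trajectories.
#' @param keep_population keep the final population in the result?
#' @return An object of class `grn_sim`: `stats` (one row per recorded
#'   generation), `robustness` (probe records or `NULL`), `population`,
#'   `config`, `model`.
#' @export
run_simulation <- function(config, robustness_interval = NULL,
                           branch_mutations = 15L,
                           stop_when = c("none", "population_optimum",
                                         "individual_optimum"),
                           snapshot_every = NULL, snapshot_dir = NULL,
                           track_genotypes = TRUE, keep_population = TRUE) {
  stopifnot(inherits(config, "grn_config"))
  stop_when <- match.arg(stop_when)
  if (!is.null(snapshot_every)) {
    snapshot_every <- as.integer(snapshot_every)
    if (is.na(snapshot_every) || snapshot_every < 1L)
      stop("'snapshot_every' must be a positive integer", call. = FALSE)
    if (is.null(snapshot_dir))
      stop("'snapshot_dir' is required when snapshots are enabled",
           call. = FALSE)
    dir.create(snapshot_dir, recursive = TRUE, showWarnings = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)

  pop <- initialize_population(config)
  ng <- config$generations
  sz <- ng + 1L
  gen_v <- integer(sz); meanf <- numeric(sz); maxf <- numeric(sz)
  viable <- integer(sz)
  ndist <- rep(NA_integer_, sz); cdist <- rep(NA_integer_, sz)
  crossv <- rep(NA_real_, sz)

  seen <- new.env(hash = TRUE, parent = emptyenv())
  cum <- 0L
  mask <- is.na(config$optimum$target)
  track_cross <- any(mask) && any(!mask)
  crossmat <- if (track_cross) outer(mask, !mask, `&`) | outer(!mask, mask, `&`)

  record <- function(state, g) {
    i <- g + 1L
    gen_v[i] <<- g
    meanf[i] <<- mean(state$fitness)
    maxf[i] <<- max(state$fitness)
    viable[i] <<- sum(state$outcome != 3L)
    if (track_genotypes) {
      keys <- genotype_keys(state, config$genotype_identity)
      uk <- unique(keys)
      ndist[i] <<- length(uk)
      for (k in uk) {
        if (!exists(k, envir = seen, inherits = FALSE)) {
          assign(k, TRUE, envir = seen)
          cum <<- cum + 1L
        }
      }
      cdist[i] <<- cum
    }
    if (track_cross) {
      nz <- matrix(state$M != 0, nrow = config$n * config$n)
      crossv[i] <<- mean(colSums(nz & as.vector(crossmat)))
    }
    if (!is.null(snapshot_every) && g %% snapshot_every == 0L) {
      genomes <- lapply(seq_len(state$N),
                        function(k) population_genome(state, k))
      write_genomes(genomes,
                    file.path(snapshot_dir, sprintf("gen%06d.txt", g)))
    }
  }

  probes <- list()
  probe_fn <- NULL
  if (!is.null(robustness_interval)) {
    interval <- as.integer(robustness_interval)
    if (is.na(interval) || interval < 1L)
      stop("'robustness_interval' must be a positive integer", call. = FALSE)
    probe_at <- seq(0L, ng, by = interval)
    probe_fn <- function(state, g) {
      rec <- with_preserved_seed(
        branch_and_probe(state, branch_mutations, config))
      rec$generation <- g
      probes[[length(probes) + 1L]] <<- rec
    }
  } else {
    probe_at <- integer(0)
  }

  stop_fn <- switch(stop_when,
                    none = NULL,
                    population_optimum = function(state, g)
                      mean(state$fitness) == 1,
                    individual_optimum = function(state, g)
                      max(state$fitness) == 1)

  res <- run_engine(pop, ng, function(state) next_generation(state, config),
                    record, stop_fn, probe_fn, probe_at)
  keep <- seq_len(res$last + 1L)
  stats <- data.frame(generation = gen_v[keep], mean_fitness = meanf[keep],
                      max_fitness = maxf[keep], n_viable = viable[keep],
                      n_distinct = ndist[keep], cum_distinct = cdist[keep],
                      cross_partition = crossv[keep])
  rob <- if (length(probes) > 0L)
    do.call(rbind, lapply(probes, as.data.frame)) else NULL
  structure(list(stats = stats,
                 robustness = rob,
                 population = if (keep_population) res$state else NULL,
                 config = config, model = "grn"),
            class = "grn_sim")
}

#' @export
print.grn_sim <- function(x, ...) {
  st <- x$stats
  cat(sprintf("<grn_sim> %s model, %d generations recorded\n",
              x$model, nrow(st) - 1L))
  cat(sprintf("  final mean fitness %.4f (max %.4f); %d distinct genotypes seen\n",
              st$mean_fitness[nrow(st)], st$max_fitness[nrow(st)],
              st$cum_distinct[nrow(st)]))
  if (!is.null(x$robustness))
    cat(sprintf("  %d robustness probes recorded\n", nrow(x$robustness)))
  invisible(x)
}

#' @export
summary.grn_sim <- function(object, ...) {
  st <- object$stats
  lad <- fitness_ladder(sum(!is.na(object$config$optimum$target)),
                        object$config$sigma2)
  pl <- detect_plateaus(st$mean_fitness)
  out <- list(generations = nrow(st) - 1L,
              final_mean_fitness = st$mean_fitness[nrow(st)],
              final_max_fitness = st$max_fitness[nrow(st)],
              cum_distinct = st$cum_distinct[nrow(st)],
              time_to_optimum_individual = time_to_optimum(st, "individual"),
              time_to_optimum_population = time_to_optimum(st, "population"),
              plateaus = pl, ladder = lad)
  class(out) <- "summary.grn_sim"
  out
}

#' @export
print.summary.grn_sim <- function(x, ...) {
  cat(sprintf("Simulation of %d generations\n", x$generations))
  cat(sprintf("  final mean fitness: %.4f; final max fitness: %.4f\n",
              x$final_mean_fitness, x$final_max_fitness))
  cat(sprintf("  cumulative distinct genotypes: %d\n", x$cum_distinct))
  cat(sprintf("  first individual at optimum: %s; whole population: %s\n",
              format(x$time_to_optimum_individual),
              format(x$time_to_optimum_population)))
  if (nrow(x$plateaus) > 0L) {
    cat("  mean-fitness plateaus (level ~ nearest ladder value):\n")
    for (i in seq_len(nrow(x$plateaus))) {
      lv <- x$plateaus$level[i]
      cat(sprintf("    generations %d-%d at %.4f (ladder %.4f)\n",
                  x$plateaus$start[i] - 1L, x$plateaus$end[i] - 1L, lv,
                  x$ladder[which.min(abs(x$ladder - lv))]))
    }
  }
  invisible(x)
}

#' Plot the mean-fitness trajectory of a run
#'
#' Draws mean fitness per generation with the discrete fitness ladder
#' (`exp(-sqrt(k)/sigma2)`) as dotted horizontal guides.
#'
#' @param x a `grn_sim`.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.grn_sim <- function(x, ...) {
  st <- x$stats
  graphics::plot(st$generation, st$mean_fitness, type = "l",
                 xlab = "generation", ylab = "mean fitness",
                 ylim = c(0, 1), ...)
  lad <- fitness_ladder(sum(!is.na(x$config$optimum$target)), x$config$sigma2)
  graphics::abline(h = lad, lty = 3, col = "grey60")
  invisible(x)
}
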