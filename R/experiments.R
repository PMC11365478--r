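#' Discretize an interaction matrix to its sign pattern
#'
#' Positive entries become 1, negative entries -1, zeros stay 0. Idempotent.
#' The sign pattern is the "topology" used by the robustness probes.
#'
#' @param matrix interaction matrix (or array of them).
#' @return Matrix/array of the same shape over `{-1, 0, 1}`.
#' @export
discretize_matrix <- function(matrix) {
  sign(matrix)
}

#' Clone a population, mutate the clone, and measure robustness
#'
#' Deep-copies every individual into a "branch", injects exactly
#' `branch_mutations` uniformly placed bit flips per branch individual (same
#' placement law as the mutation model), matures both copies, and measures per
#' individual (i) the fraction of matching genes in the binary post-maturation
#' expression vectors and (ii) the fraction of matching entries in the
#' discretized interaction matrices. The core population is untouched.
#'
#' @param population a `grn_population`.
#' @param branch_mutations number of mutations per branch individual.
#' @param config the governing [sim_config()].
#' @param raw_topology also compare raw (undiscretized) matrix entries?
#' @return A one-row list/record with `expression_robustness`,
#'   `topology_robustness`, `branch_mutation_count` (and
#'   `topology_robustness_raw` when requested), each a mean over individuals.
#' @export
branch_and_probe <- function(population, branch_mutations = 15L, config,
                             raw_topology = FALSE) {
  stopifnot(inherits(population, "grn_population"),
            inherits(config, "grn_config"))
  m <- as.integer(branch_mutations)
  if (is.na(m) || m < 0L)
    stop("'branch_mutations' must be a non-negative integer", call. = FALSE)
  br <- probe_branch_cpp(population$cis, population$trans, population$M,
                         population$n, population$L, population$N,
                         m, config$type_bit_prob[1L], config$type_bit_prob[2L],
                         config$initial_expression, config$step_cap,
                         target_codes(config$optimum), config$sigma2)
  rec <- list(
    expression_robustness = mean(population$expression == br$expression),
    topology_robustness = mean(sign(population$M) == sign(br$M)),
    branch_mutation_count = m)
  if (raw_topology)
    rec$topology_robustness_raw <- mean(population$M == br$M)
  rec
}

#' Count sign-matrix interactions crossing the selected/neutral partition
#'
#' Counts the nonzero entries `(i, j)` of the discretized matrix for which
#' exactly one of genes `i`, `j` is neutral; both directions (neutral
#' regulates selected, selected regulates neutral) count separately.
#'
#' @param matrix interaction matrix.
#' @param neutral_mask logical (or 0/1) vector, `TRUE`/1 marking neutral
#'   genes; must contain at least one neutral and one selected gene.
#' @return Integer count.
#' @export
cross_partition_interactions <- function(matrix, neutral_mask) {
  neutral <- as.logical(neutral_mask)
  if (anyNA(neutral) || length(neutral) != nrow(matrix))
    stop("'neutral_mask' must be a 0/1 or logical vector of length n",
         call. = FALSE)
  if (all(neutral) || !any(neutral))
    stop("'neutral_mask' must mark at least one neutral and one selected gene",
         call. = FALSE)
  cross <- outer(neutral, !neutral, `&`) | outer(!neutral, neutral, `&`)
  sum(sign(matrix) != 0 & cross)
}

#' First generation at which the optimum is reached
#'
#' `level = "individual"`: the first recorded generation whose maximum fitness
#' equals 1 (some individual matches the optimum on every selected gene).
#' `level = "population"`: the first generation whose mean fitness equals 1
#' (every individual does), the measure used by the mutational-buffering
#' comparison, where what matters is whether the optimal genotype can be
#' transmitted intact.
#'
#' @param stats per-generation statistics (`stats` element of a run).
#' @param level `"individual"` or `"population"`.
#' @return The generation index, or `NA` when the optimum is never reached.
#' @export
time_to_optimum <- function(stats, level = c("individual", "population")) {
  level <- match.arg(level)
  hit <- if (level == "individual") stats$max_fitness == 1
         else stats$mean_fitness == 1
  i <- which(hit)
  if (length(i) == 0L) NA_integer_ else stats$generation[i[1L]]
}

#' Run the regulation-free baseline model
#'
#' Identical Wright-Fisher orchestration (fitness-proportional parents,
#' non-overlapping generations, Poisson(`mu`) mutations per genome), but the
#' genotype is the expression vector itself: a mutation flips a gene's on/off
#' state directly and there is no maturation, so every mutation is immediately
#' phenotypic. Used as the unbuffered contrast for the regulatory model.
#'
#' @param config a [sim_config()] (`L`, recombination and maturation settings
#'   are ignored). Founders start at the phenotype a founder network matures
#'   to — the all-zero expression state — so both models begin the same
#'   distance from the optimum.
#' @param stop_when optional early stop as in [run_simulation()].
#' @param track_genotypes maintain distinct-genotype statistics?
#' @return A `grn_sim` with `model = "grnless"` (the `cross_partition` column
#'   is `NA`; every individual is viable by construction).
#' @export
run_grnless <- function(config, stop_when = c("none", "population_optimum",
                                              "individual_optimum"),
                        track_genotypes = TRUE) {
  stopifnot(inherits(config, "grn_config"))
  stop_when <- match.arg(stop_when)
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n; N <- config$N
  codes <- target_codes(config$optimum)
  sel <- codes >= 0L
  fit_of_states <- function(states) {
    d <- sqrt(colSums(states[sel, , drop = FALSE] != codes[sel]))
    exp(-d / config$sigma2)
  }
  founder <- mature(matrix(0, n, n), config$initial_expression,
                    config$step_cap)$final_state
  states <- matrix(founder, nrow = n, ncol = N)
  state <- list(states = states, fitness = fit_of_states(states))

  ng <- config$generations
  sz <- ng + 1L
  gen_v <- integer(sz); meanf <- numeric(sz); maxf <- numeric(sz)
  ndist <- rep(NA_integer_, sz); cdist <- rep(NA_integer_, sz)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  cum <- 0L
  record <- function(st, g) {
    i <- g + 1L
    gen_v[i] <<- g
    meanf[i] <<- mean(st$fitness)
    maxf[i] <<- max(st$fitness)
    if (track_genotypes) {
      keys <- unique(apply(st$states, 2L, paste, collapse = ""))
      ndist[i] <<- length(keys)
      for (k in keys) {
        if (!exists(k, envir = seen, inherits = FALSE)) {
          assign(k, TRUE, envir = seen)
          cum <<- cum + 1L
        }
      }
      cdist[i] <<- cum
    }
  }
  step_fn <- function(st) {
    r <- grnless_generation_cpp(st$states, st$fitness, config$mu, codes,
                                config$sigma2,
                                zero_code(config$on_zero_fitness))
    list(states = r$states, fitness = r$fitness)
  }
  stop_fn <- switch(stop_when,
                    none = NULL,
                    population_optimum = function(st, g) mean(st$fitness) == 1,
                    individual_optimum = function(st, g) max(st$fitness) == 1)
  res <- run_engine(state, ng, step_fn, record, stop_fn)
  keep <- seq_len(res$last + 1L)
  stats <- data.frame(generation = gen_v[keep], mean_fitness = meanf[keep],
                      max_fitness = maxf[keep], n_viable = rep(N, length(keep)),
                      n_distinct = ndist[keep], cum_distinct = cdist[keep],
                      cross_partition = rep(NA_real_, length(keep)))
  structure(list(stats = stats, robustness = NULL, population = res$state,
                 config = config, model = "grnless"),
            class = "grn_sim")
}

#' Run a robustness experiment
#'
#' Convenience wrapper: [run_simulation()] with periodic branch probes.
#'
#' @param config a [sim_config()].
#' @param interval probe spacing in generations.
#' @param branch_mutations mutations injected per branch individual.
#' @return The `grn_sim`, whose `robustness` element is a `data.frame` of
#'   probe records.
#' @export
run_robustness <- function(config, interval = 500L, branch_mutations = 15L) {
  run_simulation(config, robustness_interval = interval,
                 branch_mutations = branch_mutations)
}

#' Classify robustness probes into trajectory phases
#'
#' Phases are read off the mean-fitness trajectory: `"initial"` before the
#' first fitness improvement, `"ascent"` while fitness climbs, and
#' `"plateau"` from the generation at which the run's maximum mean fitness is
#' first attained. "Improvement" and "attained" are resolved at half the
#' smallest gap of the discrete fitness ladder, the finest change a genuine
#' step can produce (drift noise in mean fitness is an order of magnitude
#' smaller, so this separates steps from noise in both directions).
#'
#' @param sim a `grn_sim` with robustness probes.
#' @return The probe `data.frame` with an added `phase` factor.
#' @export
robustness_phases <- function(sim) {
  stopifnot(inherits(sim, "grn_sim"))
  if (is.null(sim$robustness))
    stop("this run recorded no robustness probes", call. = FALSE)
  st <- sim$stats
  lad <- fitness_ladder(sum(!is.na(sim$config$optimum$target)),
                        sim$config$sigma2)
  tol <- min(abs(diff(lad))) / 2
  first_rise <- which(st$mean_fitness > st$mean_fitness[1L] + tol)
  rise_gen <- if (length(first_rise) == 0L) Inf else st$generation[first_rise[1L]]
  peak <- which(st$mean_fitness >= max(st$mean_fitness) - tol)
  peak_gen <- st$generation[peak[1L]]
  rb <- sim$robustness
  rb$phase <- factor(ifelse(rb$generation < rise_gen, "initial",
                     ifelse(rb$generation < peak_gen, "ascent", "plateau")),
                     levels = c("initial", "ascent", "plateau"))
  rb
}

#' Compare times to the optimum across mutation rates and models
#'
#' For each mutation rate and each replicate, runs both the regulatory model
#' and the regulation-free baseline from the same founder conditions and
#' records the first generation at which the whole population sits at the
#' optimum (`NA` when the cap is hit first).
#'
#' @param mu_values mutation rates to scan.
#' @param replicates replicates per rate and model.
#' @param config a [sim_config()] template; its `generations` acts as the cap
#'   and its `mu` is overridden by `mu_values`.
#' @param models which models to run.
#' @param level optimum attainment measure passed to [time_to_optimum()].
#' @param seed base seed; replicate `r` of rate index `i` uses
#'   `seed + 1000*i + r` for each model (offset by 500 for the baseline).
#' @return `data.frame` with columns `model`, `mu`, `replicate`,
#'   `time_to_optimum`, `cap`.
#' @export
run_buffering <- function(mu_values, replicates = 20L, config,
                          models = c("grn", "grnless"),
                          level = "population", seed = 1L) {
  stopifnot(inherits(config, "grn_config"))
  models <- match.arg(models, c("grn", "grnless"), several.ok = TRUE)
  stopw <- if (level == "population") "population_optimum" else
    "individual_optimum"
  out <- list()
  for (i in seq_along(mu_values)) {
    for (r in seq_len(replicates)) {
      for (mod in models) {
        cfg <- config
        cfg$mu <- mu_values[i]
        cfg$seed <- as.integer(seed + 1000L * i + r +
                                 if (mod == "grnless") 500L else 0L)
        sim <- if (mod == "grn")
          run_simulation(cfg, stop_when = stopw, track_genotypes = FALSE,
                         keep_population = FALSE)
        else run_grnless(cfg, stop_when = stopw, track_genotypes = FALSE)
        out[[length(out) + 1L]] <-
          data.frame(model = mod, mu = mu_values[i], replicate = r,
                     time_to_optimum = time_to_optimum(sim$stats, level),
                     cap = config$generations)
      }
    }
  }
  do.call(rbind, out)
}
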