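test_that("founder populations match the stated generation-0 conditions", {
  set.seed(41)
  cfg <- sim_config(N = 30L, seed = NULL)
  pop <- initialize_population(cfg)
  expect_identical(pop$N, 30L)
  # cis gates closed, trans regions all activators
  expect_true(all(pop$cis[, cfg$L, ] == 0L))
  expect_true(all(pop$trans[, cfg$L, ] == 1L))
  # all matrices zero, all matured expression vectors zero
  expect_true(all(pop$M == 0))
  expect_true(all(pop$expression == 0L))
  # every founder sits at the 10-mismatch fitness level
  expect_true(all(pop$fitness == exp(-sqrt(10) / 5)))
  # N = 1 population is legal
  expect_identical(initialize_population(sim_config(N = 1L))$N, 1L)
  # zeros/ones strength policies are honoured
  p0 <- initialize_population(sim_config(N = 2L, init_strength_bits = "zeros"))
  expect_true(all(p0$cis[, -cfg$L, ] == 0L))
  p1 <- initialize_population(sim_config(N = 2L, init_strength_bits = "ones"))
  expect_true(all(p1$trans[, -cfg$L, ] == 1L))
})

test_that("select_parents is fitness-proportional and honours the zero policy", {
  set.seed(42)
  expect_true(all(select_parents(c(1, 0), 200L) == 1L))
  draws <- select_parents(c(0.2, 0.6, 0.2), 20000L)
  expect_gt(stats::chisq.test(tabulate(draws, 3L),
                              p = c(0.2, 0.6, 0.2))$p.value, 0.001)
  draws <- select_parents(rep(2, 4L), 20000L)
  expect_gt(stats::chisq.test(tabulate(draws, 4L))$p.value, 0.001)
  expect_error(select_parents(c(0, 0), 5L), "zero fitness")
  u <- select_parents(c(0, 0, 0), 1000L, on_zero = "uniform")
  expect_gt(stats::chisq.test(tabulate(u, 3L))$p.value, 0.001)
})

test_that("next_generation copies faithfully when variation is switched off", {
  set.seed(43)
  cfg <- sim_config(N = 15L, mu = 0)
  pop <- initialize_population(cfg)
  # founders share fitness; with mu=0 and no recombination the offspring are
  # exact copies of (some) founders, each satisfying the rebuild oracle
  nxt <- next_generation(pop, cfg)
  expect_identical(nxt$N, 15L)
  k1 <- genotype_keys(pop)
  k2 <- genotype_keys(nxt)
  expect_true(all(k2 %in% k1))
  for (k in c(1L, 8L, 15L)) {
    g <- population_genome(nxt, k)
    expect_identical(nxt$M[, , k], build_interaction_matrix(g))
  }
})

test_that("evolved individuals always satisfy the matrix rebuild oracle", {
  cfg <- sim_config(N = 12L, n = 6L, L = 10L, mu = 1, generations = 40L,
                    recombination_model = "r1r2", seed = 44L)
  sim <- run_simulation(cfg)
  pop <- sim$population
  for (k in seq_len(pop$N)) {
    g <- population_genome(pop, k)
    expect_identical(pop$M[, , k], build_interaction_matrix(g))
    expect_identical(pop$M[, , k], oracle_build(g))
  }
})

test_that("runs are bit-reproducible from the seed", {
  cfg <- sim_config(N = 20L, generations = 60L, mu = 0.5,
                    recombination_model = "wagner", seed = 45L)
  s1 <- run_simulation(cfg)
  s2 <- run_simulation(cfg)
  expect_identical(s1$stats, s2$stats)
  expect_identical(s1$population$cis, s2$population$cis)
  expect_identical(s1$population$fitness, s2$population$fitness)
})

test_that("per-generation statistics have the documented shape and invariants", {
  cfg <- sim_config(N = 10L, generations = 0L, seed = 46L)
  s0 <- run_simulation(cfg)
  expect_identical(nrow(s0$stats), 1L)          # generation 0 only
  expect_identical(s0$stats$generation, 0L)

  cfg <- sim_config(N = 25L, generations = 120L, mu = 0.3, seed = 47L)
  sim <- run_simulation(cfg)
  st <- sim$stats
  expect_identical(nrow(st), 121L)
  expect_identical(st$generation, 0:120)
  expect_true(all(diff(st$cum_distinct) >= 0L))  # cumulative count never drops
  expect_true(all(st$n_distinct <= 25L))
  expect_true(all(st$n_viable == 25L))           # n = 10 < 13: always viable
  expect_true(all(st$max_fitness >= st$mean_fitness))
  # no neutral genes configured: cross-partition column stays NA
  expect_true(all(is.na(st$cross_partition)))
})

test_that("cross-partition statistics appear when the optimum mixes genes", {
  cfg <- sim_config(N = 10L, generations = 15L, mu = 1,
                    optimum = c(rep(1L, 5L), rep(NA, 5L)), seed = 48L)
  sim <- run_simulation(cfg)
  expect_true(all(!is.na(sim$stats$cross_partition)))
  # the recorded value equals the per-individual count average
  pop <- sim$population
  mask <- is.na(cfg$optimum$target)
  manual <- mean(vapply(seq_len(pop$N), function(k)
    cross_partition_interactions(pop$M[, , k], mask), numeric(1)))
  expect_identical(sim$stats$cross_partition[nrow(sim$stats)], manual)
})

test_that("genotype identity can be the genome string or the sign matrix", {
  cfg <- sim_config(N = 8L, generations = 10L, mu = 1, seed = 49L)
  sim <- run_simulation(cfg)
  pop <- sim$population
  kg <- genotype_keys(pop, "genome")
  km <- genotype_keys(pop, "matrix")
  expect_identical(length(kg), 8L)
  expect_identical(nchar(kg[1L]), 2L * 10L * 30L)
  # identical genomes imply identical sign matrices, never the reverse
  expect_true(length(unique(km)) <= length(unique(kg)))
})

test_that("the shared orchestration honours probes, stopping and recording", {
  calls <- integer(0)
  probes <- integer(0)
  res <- grnevolve:::run_engine(
    state = 0L, n_gen = 10L,
    step_fn = function(s) s + 1L,
    record_fn = function(s, g) calls <<- c(calls, g),
    stop_fn = function(s, g) s >= 4L,
    probe_fn = function(s, g) probes <<- c(probes, g),
    probe_at = c(0L, 2L, 4L, 6L))
  expect_identical(res$state, 4L)
  expect_identical(res$last, 4L)
  expect_identical(calls, 0:4)
  expect_identical(probes, c(0L, 2L, 4L))
})
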