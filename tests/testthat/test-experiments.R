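test_that("discretize_matrix is the element-wise sign and is idempotent", {
  expect_identical(discretize_matrix(matrix(0, 3L, 3L)), matrix(0, 3L, 3L))
  M <- matrix(c(0.3, 0, -0.1, 0.9), 2L, 2L)
  expect_identical(discretize_matrix(M), matrix(c(1, 0, -1, 1), 2L, 2L))
  expect_identical(discretize_matrix(discretize_matrix(M)),
                   discretize_matrix(M))
})

test_that("cross_partition_interactions counts directed boundary edges", {
  expect_identical(cross_partition_interactions(matrix(0, 4L, 4L),
                                                c(1, 1, 0, 0)), 0L)
  M <- matrix(c(0, -0.2, 0.5, 0), 2L, 2L)   # M[1,2]=0.5, M[2,1]=-0.2
  expect_identical(cross_partition_interactions(M, c(TRUE, FALSE)), 2L)
  # within-partition edges are not counted
  M3 <- diag(3) * 0.4                        # self-loops never cross
  expect_identical(cross_partition_interactions(M3, c(TRUE, FALSE, FALSE)), 0L)
  expect_error(cross_partition_interactions(M, c(FALSE, FALSE)), "at least one")
  expect_error(cross_partition_interactions(M, c(TRUE, TRUE)), "at least one")
})

test_that("branch probes measure identity and never touch the core", {
  cfg <- sim_config(N = 12L, n = 6L, L = 12L, mu = 1, generations = 30L,
                    optimum = rep(1L, 6L), seed = 51L)
  sim <- run_simulation(cfg)
  pop <- sim$population
  before <- list(cis = pop$cis, trans = pop$trans, M = pop$M,
                 expr = pop$expression)
  set.seed(52)
  # zero injected mutations: clones are identical, both identities are 1
  r0 <- branch_and_probe(pop, 0L, cfg)
  expect_identical(r0$expression_robustness, 1)
  expect_identical(r0$topology_robustness, 1)
  r <- branch_and_probe(pop, 15L, cfg, raw_topology = TRUE)
  expect_true(r$expression_robustness >= 0 && r$expression_robustness <= 1)
  expect_true(r$topology_robustness >= 0 && r$topology_robustness <= 1)
  expect_true(r$topology_robustness_raw <= r$topology_robustness)
  # core population is bit-identical after probing
  expect_identical(pop$cis, before$cis)
  expect_identical(pop$trans, before$trans)
  expect_identical(pop$M, before$M)
  expect_identical(pop$expression, before$expr)
})

test_that("founder populations are almost perfectly expression-robust", {
  set.seed(53)
  cfg <- sim_config(N = 40L)
  pop <- initialize_population(cfg)
  r <- branch_and_probe(pop, 15L, cfg)
  # closed cis gates mean most of the 15 flips cannot reach the phenotype
  expect_gt(r$expression_robustness, 0.95)
})

test_that("probing inside a run leaves the trajectory unchanged", {
  cfg <- sim_config(N = 15L, generations = 80L, mu = 0.5, seed = 54L)
  plain <- run_simulation(cfg)
  probed <- run_simulation(cfg, robustness_interval = 10L)
  expect_identical(plain$stats, probed$stats)
  expect_identical(plain$population$cis, probed$population$cis)
  expect_identical(nrow(probed$robustness), 9L)   # generations 0,10,...,80
})

test_that("time_to_optimum reads the first attainment off a stats stream", {
  st <- data.frame(generation = 0:3, max_fitness = c(1, 1, 1, 1),
                   mean_fitness = c(0.9, 0.95, 1, 1))
  expect_identical(time_to_optimum(st, "individual"), 0L)
  expect_identical(time_to_optimum(st, "population"), 2L)
  st2 <- data.frame(generation = 0:40,
                    max_fitness = c(rep(0.8, 37L), rep(1, 4L)),
                    mean_fitness = rep(0.5, 41L))
  expect_identical(time_to_optimum(st2, "individual"), 37L)
  expect_identical(time_to_optimum(st2, "population"), NA_integer_)
})

test_that("the regulation-free baseline freezes without mutation", {
  cfg <- sim_config(N = 10L, n = 4L, mu = 0, generations = 25L,
                    optimum = rep(1L, 4L), initial_expression = rep(0L, 4L),
                    seed = 55L)
  sim <- run_grnless(cfg)
  expect_identical(sim$model, "grnless")
  st <- sim$stats
  expect_true(all(st$mean_fitness == st$mean_fitness[1L]))
  expect_true(all(st$n_distinct == 1L))
  expect_identical(st$cum_distinct[nrow(st)], 1L)
})

test_that("baseline hitting times match the exact Markov-chain oracle", {
  # N = 2 individuals, n = 2 genes, optimum (1,1) one-or-two flips away:
  # the population chain over unordered pairs of non-optimal states is small
  # enough to solve exactly for the expected first generation in which some
  # individual hits the optimum.
  mu <- 0.6; sigma2 <- 5
  q <- (1 - exp(-mu)) / 2          # per-gene flip probability (Poisson parity)
  states <- list(c(0L, 0L), c(0L, 1L), c(1L, 0L))
  fit <- vapply(states, function(s) exp(-sqrt(sum(s != c(1L, 1L))) / sigma2),
                numeric(1))
  trans_to <- function(s, t) prod(ifelse(s == t, 1 - q, q))
  hit_state <- c(1L, 1L)
  pairs <- list(c(1L, 1L), c(1L, 2L), c(1L, 3L), c(2L, 2L), c(2L, 3L), c(3L, 3L))
  np <- length(pairs)
  Q <- matrix(0, np, np)
  for (pi in seq_len(np)) {
    a <- pairs[[pi]][1L]; b <- pairs[[pi]][2L]
    w <- c(fit[a], fit[b]); w <- w / sum(w)
    child <- function(t) w[1L] * trans_to(states[[a]], t) +
      w[2L] * trans_to(states[[b]], t)
    d_hit <- child(hit_state)
    d <- vapply(states, child, numeric(1))     # density over non-hit states
    for (pj in seq_len(np)) {
      x <- pairs[[pj]][1L]; y <- pairs[[pj]][2L]
      Q[pi, pj] <- if (x == y) d[x] * d[y] else 2 * d[x] * d[y]
    }
  }
  expected_T <- solve(diag(np) - Q, rep(1, np))[1L]  # start: both (0,0)

  cfg <- sim_config(N = 2L, n = 2L, mu = mu, sigma2 = sigma2,
                    optimum = c(1L, 1L), initial_expression = c(0L, 0L),
                    generations = 400L)
  set.seed(56)
  times <- vapply(1:1200, function(i) {
    cfg$seed <- 56000L + i
    time_to_optimum(run_grnless(cfg, stop_when = "individual_optimum")$stats,
                    "individual")
  }, integer(1))
  expect_true(all(!is.na(times)))
  se <- stats::sd(times) / sqrt(length(times))
  expect_lt(abs(mean(times) - expected_T), 4 * se + 0.05 * expected_T)
})

test_that("robustness identities are exchange-symmetric in core and branch", {
  cfg <- sim_config(N = 8L, n = 5L, L = 10L, mu = 2, generations = 15L,
                    optimum = rep(1L, 5L), seed = 57L)
  sim <- run_simulation(cfg)
  pop <- sim$population
  set.seed(58)
  br <- grnevolve:::probe_branch_cpp(pop$cis, pop$trans, pop$M,
                                     pop$n, pop$L, pop$N, 10L,
                                     cfg$type_bit_prob[1L],
                                     cfg$type_bit_prob[2L],
                                     cfg$initial_expression,
                                     cfg$step_cap,
                                     grnevolve:::target_codes(cfg$optimum),
                                     cfg$sigma2)
  # identity is a symmetric function of the two populations
  expect_identical(mean(pop$expression == br$expression),
                   mean(br$expression == pop$expression))
  expect_identical(mean(sign(pop$M) == sign(br$M)),
                   mean(sign(br$M) == sign(pop$M)))
})
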