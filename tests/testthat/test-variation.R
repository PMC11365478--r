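test_that("draw_mutations has Poisson counts and the stated placement laws", {
  expect_error(draw_mutations(10L, 30L, -1), "non-negative")
  set.seed(31)
  # mu = 0: always empty
  for (i in 1:20) expect_identical(nrow(draw_mutations(10L, 30L, 0)), 0L)
  # mean event count ~ mu
  counts <- replicate(4000, nrow(draw_mutations(10L, 30L, 0.5)))
  expect_lt(abs(mean(counts) - 0.5), 4 * sqrt(0.5 / 4000))
  # pooled events: regions and genes uniform; trans type-bit hits at 1%;
  # cis positions uniform over the whole region (type bit = 1/L)
  ev <- do.call(rbind, replicate(400, draw_mutations(5L, 30L, 20), simplify = FALSE))
  expect_gt(stats::chisq.test(table(ev$region))$p.value, 0.001)
  expect_gt(stats::chisq.test(table(factor(ev$gene_index, levels = 1:5)))$p.value,
            0.001)
  tr <- ev[ev$region == "trans", ]
  expect_gt(stats::binom.test(sum(tr$bit_position == 30L), nrow(tr),
                              0.01)$p.value, 0.001)
  strength <- tr$bit_position[tr$bit_position < 30L]
  expect_gt(stats::chisq.test(table(factor(strength, levels = 1:29)))$p.value,
            0.001)
  ci <- ev[ev$region == "cis", ]
  expect_gt(stats::chisq.test(table(factor(ci$bit_position,
                                           levels = 1:30)))$p.value, 0.001)
  # a shared override applies to both region kinds
  ev2 <- do.call(rbind, replicate(200, draw_mutations(5L, 30L, 20, 0.5),
                                  simplify = FALSE))
  expect_gt(stats::binom.test(sum(ev2$bit_position == 30L), nrow(ev2),
                              0.5)$p.value, 0.001)
})

test_that("apply_mutations flips bits and keeps the matrix consistent", {
  set.seed(32)
  g <- rand_genome(6L, 10L)
  M <- build_interaction_matrix(g)
  ev <- data.frame(gene_index = c(2L, 5L, 2L),
                   region = c("cis", "trans", "cis"),
                   bit_position = c(3L, 10L, 3L))
  r <- apply_mutations(g, M, ev)
  expect_identical(r$matrix, build_interaction_matrix(r$genome))
  # events 1 and 3 cancel; only the trans type-bit flip of gene 5 remains
  expect_identical(r$genome$cis, g$cis)
  expect_identical(sum(r$genome$trans != g$trans), 1L)
  expect_identical(r$genome$trans[5L, 10L], 1L - g$trans[5L, 10L])
  # Hamming distance equals the number of distinct flipped bits
  ev2 <- data.frame(gene_index = 1:4, region = rep(c("cis", "trans"), 2L),
                    bit_position = c(1L, 2L, 3L, 4L))
  r2 <- apply_mutations(g, M, ev2)
  expect_identical(sum(r2$genome$cis != g$cis) + sum(r2$genome$trans != g$trans),
                   4L)
  # empty event list: untouched
  r3 <- apply_mutations(g, M, draw_mutations(6L, 10L, 0))
  expect_identical(r3$genome, g)
  expect_identical(r3$matrix, M)
  expect_error(apply_mutations(g, M, data.frame(gene_index = 9L,
                                                region = "cis",
                                                bit_position = 1L)),
               "out of range")
})

test_that("cis-swap recombination takes trans from one parent, cis per gene", {
  set.seed(33)
  p1 <- rand_genome(8L, 12L)
  p2 <- rand_genome(8L, 12L)
  # identical parents: point mass on that genome
  same <- recombine_wagner(p1, p1)
  expect_identical(same$genome, p1)
  expect_identical(same$matrix, build_interaction_matrix(p1))
  # degenerate coin: child equals parent1
  expect_identical(recombine_wagner(p1, p2, cis_from = rep(1L, 8L))$genome, p1)
  # mixed coin: trans from p1, chosen cis rows from p2, matrix rebuilt
  pick <- c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L)
  r <- recombine_wagner(p1, p2, cis_from = pick)
  expect_identical(r$genome$trans, p1$trans)
  expect_identical(r$genome$cis[pick == 2L, ], p2$cis[pick == 2L, ])
  expect_identical(r$genome$cis[pick == 1L, ], p1$cis[pick == 1L, ])
  expect_identical(r$matrix, oracle_build(r$genome))
  # random coins still satisfy the rebuild oracle
  for (i in 1:10) {
    r <- recombine_wagner(p1, p2)
    expect_identical(r$matrix, build_interaction_matrix(r$genome))
  }
})

test_that("breakpoint recombination splits the gene list and mixes parents", {
  set.seed(34)
  n <- 10L
  p1 <- rand_genome(n, 8L)
  p2 <- rand_genome(n, 8L)
  r <- recombine_breakpoint(p1, p2, breakpoint = 4L)
  expect_identical(r$genome$cis[1:4, ], p1$cis[1:4, ])
  expect_identical(r$genome$trans[1:4, ], p1$trans[1:4, ])
  expect_identical(r$genome$cis[5:10, ], p2$cis[5:10, ])
  expect_identical(r$genome$trans[5:10, ], p2$trans[5:10, ])
  expect_identical(r$matrix, oracle_build(r$genome))
  # j never 0 or n: both parents always contribute
  for (i in 1:50) {
    j <- recombine_breakpoint(p1, p2)$breakpoint
    expect_true(j >= 1L && j <= n - 1L)
  }
  expect_error(recombine_breakpoint(rand_genome(1L, 8L), rand_genome(1L, 8L)),
               "n >= 2")
  expect_error(recombine_breakpoint(p1, rand_genome(n, 6L)), "share")
  # identical parents: child identical regardless of j
  for (j in c(1L, 5L, 9L))
    expect_identical(recombine_breakpoint(p1, p1, breakpoint = j)$genome, p1)
})

test_that("long random mutation/recombination chains keep the matrix exact", {
  set.seed(35)
  g <- rand_genome(7L, 12L)
  M <- build_interaction_matrix(g)
  pool <- replicate(5, rand_genome(7L, 12L), simplify = FALSE)
  for (i in 1:400) {
    if (stats::runif(1) < 0.8) {
      ev <- draw_mutations(7L, 12L, 2)
      r <- apply_mutations(g, M, ev)
    } else if (stats::runif(1) < 0.5) {
      r <- recombine_wagner(g, pool[[sample.int(5L, 1L)]])
    } else {
      r <- recombine_breakpoint(g, pool[[sample.int(5L, 1L)]])
    }
    g <- r$genome; M <- r$matrix
  }
  expect_identical(M, build_interaction_matrix(g))
  expect_identical(M, oracle_build(g))
})
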