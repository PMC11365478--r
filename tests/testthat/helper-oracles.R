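# Brute-force reference implementations, kept deliberately naive and separate
# from the package internals: plain R loops, trajectory stored in full and
# scanned with match().

# Signed interaction computed straight from the verbal rule.
oracle_interaction <- function(cis, trans) {
  L <- length(cis)
  if (cis[L] == 0) return(0)
  pc <- sum(cis[-L] == 1 & trans[-L] == 1)
  if (trans[L] == 1) pc / L else -pc / L
}

oracle_build <- function(genome) {
  n <- genome$n
  M <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      M[i, j] <- oracle_interaction(genome$cis[i, ], genome$trans[j, ])
  M
}

# One expression update: expressed iff summed input from expressed genes is
# strictly positive.  Accumulation order matches the engine (j ascending,
# plain double adds) so results are bit-identical.
oracle_step <- function(M, s) {
  n <- length(s)
  out <- integer(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) if (s[j] == 1L) acc <- acc + M[i, j]
    out[i] <- if (acc > 0) 1L else 0L
  }
  out
}

oracle_mature <- function(M, init, cap = 10000L) {
  keys <- paste(init, collapse = "")
  traj <- list(init)
  cur <- init
  for (t in seq_len(cap)) {
    cur <- oracle_step(M, cur)
    k <- paste(cur, collapse = "")
    hit <- match(k, keys)
    if (!is.na(hit)) {
      t0 <- hit - 1L
      per <- t - t0
      if (per == 1L)
        return(list(outcome = "fixed_point", final = cur, period = 1L,
                    steps = t, cycle = NULL))
      cyc <- do.call(rbind, traj[(t0 + 1L):(t0 + per)])
      return(list(outcome = "cycle", final = NULL, period = per,
                  steps = t, cycle = cyc))
    }
    keys <- c(keys, k)
    traj[[t + 1L]] <- cur
  }
  list(outcome = "non_viable", final = NULL, period = NA_integer_,
       steps = cap, cycle = NULL)
}

oracle_fitness <- function(expr, target, sigma2) {
  sel <- !is.na(target)
  exp(-sqrt(sum(expr[sel] != target[sel])) / sigma2)
}

rand_region <- function(L) as.integer(stats::runif(L) < 0.5)

rand_genome <- function(n, L) {
  grn_genome(matrix(as.integer(stats::runif(n * L) < 0.5), n, L),
             matrix(as.integer(stats::runif(n * L) < 0.5), n, L))
}

# Random interaction-like matrix: entries on the k/L grid with random signs
# and some structural zeros.
rand_matrix <- function(n, L = 30L, p_zero = 0.3) {
  v <- sample(0:(L - 1L), n * n, replace = TRUE) / L
  v[stats::runif(n * n) < p_zero] <- 0
  s <- sample(c(-1, 1), n * n, replace = TRUE)
  matrix(v * s, n, n)
}

all_states <- function(n) {
  g <- as.matrix(expand.grid(rep(list(0:1), n)))
  storage.mode(g) <- "integer"
  g
}
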