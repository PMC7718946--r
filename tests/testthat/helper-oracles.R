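# Independent oracles used to validate the analytical code paths. These are
# deliberately written as naive step-by-step computations, structurally
# different from the package implementations they check.

# Running-sum enrichment score by explicit walk: maintains P_hit and P_miss
# separately and records the deviation after every gene.
oracle_es <- function(scores_desc, is_hit, p = 0) {
  n <- length(scores_desc)
  nh <- sum(is_hit)
  w <- abs(scores_desc)^p
  wsum <- sum(w[is_hit])
  p_hit <- p_miss <- 0
  hi <- lo <- 0
  for (i in seq_len(n)) {
    if (is_hit[i]) p_hit <- p_hit + w[i] / wsum
    else p_miss <- p_miss + 1 / (n - nh)
    dev <- p_hit - p_miss
    if (dev > hi) hi <- dev
    if (dev < lo) lo <- dev
  }
  # same documented tie-break as the package: positive extreme wins a tie
  # (within float tolerance, so summation order cannot flip the sign)
  if (abs(hi) >= abs(lo) - 1e-12) hi else lo
}

# Two-sided Fisher p by brute-force enumeration of all tables with the
# observed margins, probabilities from factorials directly.
oracle_fisher <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  log_tab_prob <- function(x) {
    # P(table) with margins fixed, cell (1,1) = x
    (lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(c2) -
       lfactorial(n) - lfactorial(x) - lfactorial(r1 - x) -
       lfactorial(c1 - x) - lfactorial(r2 - c1 + x))
  }
  xs <- max(0, c1 - r2):min(r1, c1)
  lp <- vapply(xs, log_tab_prob, numeric(1))
  lp_obs <- lp[xs == a]
  sum(exp(lp[lp <= lp_obs + 1e-12]))
}

# tiny expression matrix with two planted groups, for classifier tests
make_toy_matrix <- function(n_genes = 20, n_high = 3, n_low = 5,
                            effect = 3, seed = 1) {
  withr::with_seed(seed, {
    n <- n_high + n_low
    x <- matrix(rnorm(n_genes * n), n_genes, n,
                dimnames = list(sprintf("g%02d", 1:n_genes),
                                sprintf("s%02d", 1:n)))
    x[, 1:n_high] <- x[, 1:n_high] + effect
    expression_matrix(x)
  })
}
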