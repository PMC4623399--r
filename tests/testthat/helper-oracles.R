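# Independent reference implementations used as oracles. Each follows a
# different code path from the package: the conditional-test oracle goes
# through R's negative-binomial CDF, the BH oracle is the literal step-up
# definition, and the rank-sum / hypergeometric oracles are full
# enumerations.

# Two-sided conditional-test p-value via stats::pnbinom: the conditional
# law of y given x is NB(size = x + 1, prob = 1/(1 + N2/N1)).
ac_oracle <- function(x, y, ratio) {
  pr <- 1 / (1 + ratio)
  lower <- pnbinom(y, size = x + 1, prob = pr)
  upper <- pnbinom(y - 1, size = x + 1, prob = pr, lower.tail = FALSE)
  p <- if (lower <= 0.5) 2 * lower else 2 * upper
  min(p, 1)
}

# Brute-force Benjamini-Hochberg step-up: q_(i) = min_{j>=i} p_(j) * m / j.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- vapply(seq_len(m), function(i) {
    min(p[ord][seq(i, m)] * m / seq(i, m))
  }, numeric(1))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# Exact two-sided rank-sum p by full enumeration of member subsets,
# mirroring the tie-free exact convention (doubled smaller tail, capped).
wilcox_enum_oracle <- function(v_in, v_out) {
  values <- c(v_in, v_out)
  n <- length(values); n_in <- length(v_in)
  r <- rank(values)
  w_obs <- sum(r[seq_len(n_in)]) - n_in * (n_in + 1) / 2
  combos <- utils::combn(n, n_in)
  w_all <- apply(combos, 2, function(idx) {
    sum(r[idx]) - n_in * (n_in + 1) / 2
  })
  mu <- n_in * (n - n_in) / 2
  p1 <- if (w_obs > mu) mean(w_all >= w_obs) else mean(w_all <= w_obs)
  min(2 * p1, 1)
}

# Upper-tail hypergeometric by direct binomial-coefficient summation.
hyper_oracle <- function(de_in, n_in, n_de, n_universe) {
  k <- seq(de_in, min(n_in, n_de))
  sum(choose(n_de, k) * choose(n_universe - n_de, n_in - k)) /
    choose(n_universe, n_in)
}

small_config <- function(seed = 1, ...) {
  sim_config(seed = seed,
             n_genes_by_compartment = c(nuclear = 600, mitochondrial = 60,
                                        chloroplast = 40),
             library_sizes = c(wt = 5e5, oe = 5e5),
             n_proteins = 200, ...)
}
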