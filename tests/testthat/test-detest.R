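test_that("conditional pmf matches hand-computed values and closed forms", {
  expect_equal(ac_pmf_conditional(0, 0, ratio = 1), 0.5)
  expect_equal(ac_pmf_conditional(1, 1, ratio = 1), 0.25)
  expect_equal(ac_pmf_conditional(2, 0, ratio = 1), 0.125)
  # geometric law at x = 0: p(i|0) = r^i / (1+r)^(i+1)
  r <- 2.5
  i <- 0:20
  expect_equal(ac_pmf_conditional(0, i, r), r^i / (1 + r)^(i + 1))
  expect_error(ac_pmf_conditional(1, 1, ratio = 0),
               class = "energyomics_domain_error")
})

test_that("conditional pmf agrees with the negative-binomial law and sums to one", {
  for (r in c(0.5, 1, 2)) {
    for (x in c(0, 3, 17, 50)) {
      i <- 0:400
      expect_equal(ac_pmf_conditional(x, i, r),
                   dnbinom(i, size = x + 1, prob = 1 / (1 + r)),
                   tolerance = 1e-12)
      k <- 0:ceiling(50 * (x + 1) * max(r, 1))
      expect_lt(abs(sum(ac_pmf_conditional(x, k, r)) - 1), 1e-12)
    }
  }
})

test_that("two-sided p-value: closed forms, symmetry, and clamping", {
  expect_equal(ac_two_sided_p(0, 0, 1e7, 1e7), 1)
  expect_equal(ac_two_sided_p(0, 10, 1e7, 1e7), 2^-9)
  # equal normalized counts are never evidence of change
  for (x in c(0, 1, 7, 40, 100)) {
    expect_equal(ac_two_sided_p(x, x, 3e6, 3e6), 1)
  }
  # swapping libraries and counts leaves p unchanged: exact for the
  # exclusive-upper-tail variant (the doubled tails are complementary under
  # the swap); the conservative default differs only by the observed point
  # mass, so both variants bracket each other
  set.seed(42)
  for (k in 1:50) {
    x <- sample(0:300, 1); y <- sample(0:300, 1)
    n1 <- sample(c(1e6, 2e6, 4e6), 1); n2 <- sample(c(1e6, 2e6, 4e6), 1)
    expect_equal(ac_two_sided_p(x, y, n1, n2,
                                upper_tail_includes_y = FALSE),
                 ac_two_sided_p(y, x, n2, n1,
                                upper_tail_includes_y = FALSE),
                 tolerance = 1e-12)
    p_cons <- ac_two_sided_p(x, y, n1, n2)
    p_swap <- ac_two_sided_p(y, x, n2, n1,
                             upper_tail_includes_y = FALSE)
    expect_gte(p_cons, p_swap * (1 - 1e-12))
  }
  expect_error(ac_two_sided_p(1, 1, 0, 1e6),
               class = "energyomics_domain_error")
  expect_error(ac_two_sided_p(-1, 1, 1e6, 1e6),
               class = "energyomics_domain_error")
})

test_that("two-sided p-value matches the negative-binomial CDF oracle", {
  set.seed(7)
  for (k in 1:400) {
    x <- sample(0:200, 1); y <- sample(0:200, 1)
    r <- sample(c(0.5, 1, 2), 1)
    p_pkg <- ac_two_sided_p(x, y, 1e6, 1e6 * r)
    p_ora <- ac_oracle(x, y, r)
    expect_equal(p_pkg, p_ora, tolerance = 1e-10,
                 label = sprintf("p(x=%d, y=%d, r=%g)", x, y, r))
  }
})

test_that("moving y away from the conditional median never lowers significance", {
  for (r in c(0.5, 1, 2)) {
    for (x in c(0, 5, 30)) {
      y <- 0:80
      p <- ac_two_sided_p(x, y, 1e6, 1e6 * r)
      med <- qnbinom(0.5, size = x + 1, prob = 1 / (1 + r))
      below <- y <= med
      # p non-decreasing toward the median from the left, non-increasing after
      expect_true(all(diff(p[below]) >= -1e-12))
      expect_true(all(diff(p[!below]) <= 1e-12))
    }
  }
})

test_that("upper-tail branch variants differ exactly by the observed-point mass", {
  x <- 20; y <- 45; r <- 1
  p_incl <- ac_two_sided_p(x, y, 1e6, 1e6)
  p_excl <- ac_two_sided_p(x, y, 1e6, 1e6, upper_tail_includes_y = FALSE)
  expect_equal(p_incl - p_excl, 2 * ac_pmf_conditional(x, y, r),
               tolerance = 1e-12)
  expect_gt(p_incl, p_excl)
})

test_that("BH q-values match examples and the brute-force step-up oracle", {
  expect_equal(bh_fdr(rep(0.03, 7)), rep(0.03, 7))
  expect_equal(bh_fdr(c(0.001, 0.01, 0.02, 0.8)),
               c(0.004, 0.02, 0.02666667, 0.8), tolerance = 1e-6)
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 0)), class = "energyomics_domain_error")
  expect_error(bh_fdr(c(0.5, 1.2)), class = "energyomics_domain_error")
  set.seed(11)
  for (k in 1:25) {
    p <- runif(sample(1:200, 1))
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("fold change is the normalized ratio with extinction sentinels", {
  expect_equal(fold_change(100, 100, 1e7, 1e7), 1)
  expect_equal(fold_change(100, 400, 1e7, 1e7), 4)
  expect_equal(fold_change(100, 100, 1e7, 2e7), 0.5)
  expect_identical(fold_change(0, 5, 1e7, 1e7), Inf)
  expect_identical(fold_change(5, 0, 1e7, 1e7), 0)
  expect_identical(fold_change(0, 0, 1e7, 1e7), 1)
})

test_that("a gene extinguished in one library is unambiguously differential", {
  # WT count like the ATP6-2 scenario: high in one library, zero in the other
  p <- ac_two_sided_p(1300, 0, 1e7, 1e7)
  expect_lt(p, 1e-10)
  expect_equal(fold_change(1300, 0, 1e7, 1e7), 0)
})

test_that("call_de_table applies FDR and fold-change thresholds jointly", {
  counts <- tibble::tibble(
    gene_id = c("null1", "null2", "spike", "dead", "small"),
    wt = c(100L, 250L, 50L, 0L, 0L),
    oe = c(98L, 260L, 800L, 0L, 1L)
  )
  de <- call_de_table(counts, n1 = 1e7, n2 = 1e7)
  expect_s3_class(de, "de_results")
  expect_equal(attr(de, "n_undetected"), 1L)
  expect_false("dead" %in% de$gene_id)
  expect_equal(de$call[de$gene_id == "spike"], "up")
  expect_equal(de$call[de$gene_id %in% c("null1", "null2", "small")],
               rep("ns", 3))
  # identical counts everywhere: nothing can be called
  nullc <- tibble::tibble(gene_id = paste0("g", 1:20),
                          wt = rep(50L, 20), oe = rep(50L, 20))
  expect_true(all(call_de_table(nullc, 1e6, 1e6)$call == "ns"))
})

test_that("1.5-fold calls are a superset of 2-fold calls", {
  sim <- gen_counts(small_config(seed = 3))
  de2 <- call_de_table(sim$counts, 5e5, 5e5, fc_threshold = 2)
  de15 <- call_de_table(sim$counts, 5e5, 5e5, fc_threshold = 1.5)
  called2 <- de2$gene_id[de2$call != "ns"]
  called15 <- de15$gene_id[de15$call != "ns"]
  expect_gt(length(called2), 0)
  expect_true(all(called2 %in% called15))
})

test_that("tidy and glance summarize a DE contrast", {
  sim <- gen_counts(small_config(seed = 5))
  de <- call_de_table(sim$counts, 5e5, 5e5)
  g <- glance(de)
  expect_equal(g$n_tested, nrow(de))
  expect_equal(g$n_up, sum(de$call == "up"))
  expect_false(inherits(tidy(de), "de_results"))
})
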