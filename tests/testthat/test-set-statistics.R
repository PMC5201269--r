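test_that("hypergeometric upper tail reproduces hand cases and edge cases", {
  # k at or below the feasible minimum: the tail covers everything
  expect_identical(hypergeom_upper_tail(0, 5, 3, 10)$p_value, 1)
  expect_identical(hypergeom_upper_tail(3, 5, 8, 10)$p_value, 1)  # k_min = 3
  # single-table point mass: k = n = K = N
  expect_equal(hypergeom_upper_tail(2, 2, 2, 2)$p_value, 1)
  # A = B identity overlap gives the minimal tail for those margins
  p_id <- hypergeom_upper_tail(4, 4, 4, 8)$p_value
  expect_equal(p_id, 1 / choose(8, 4))
  # pmf sums to 1 over the feasible range
  for (tb in list(c(6, 4, 10), c(5, 5, 7), c(2, 9, 11))) {
    n <- tb[1]; K <- tb[2]; N <- tb[3]
    ks <- max(0, n + K - N):min(n, K)
    pmf <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
    expect_equal(sum(pmf), 1, tolerance = 1e-12)
    # survival at each k equals the pmf partial sum
    for (k in ks)
      expect_equal(hypergeom_upper_tail(k, n, K, N)$p_value,
                   sum(pmf[ks >= k]), tolerance = 1e-12)
  }
})

test_that("upper tail is non-increasing in k and validates its domain", {
  ps <- vapply(0:12, function(k)
    hypergeom_upper_tail(k, 12, 30, 60)$p_value, numeric(1))
  expect_true(all(diff(ps) <= 1e-15))
  expect_error(hypergeom_upper_tail(5, 4, 10, 20), "overlap k")
  expect_error(hypergeom_upper_tail(2, 10, 30, 20), "universe")
  expect_error(hypergeom_upper_tail(-1, 4, 10, 20), "non-negative")
  expect_error(hypergeom_upper_tail(0, 9, 9, 10), "feasible minimum")
})

test_that("fisher_overlap builds the table and matches enumeration on random sets", {
  universe <- paste0("e", 1:10)
  set.seed(42)
  for (i in 1:25) {
    a <- sample(universe, sample(1:9, 1))
    b <- sample(universe, sample(1:9, 1))
    fo <- fisher_overlap(a, b, universe)
    expect_equal(fo$table$k, length(intersect(a, b)))
    expect_equal(sum(fo$table$cells), 10)
    expect_equal(fo$test$p_value,
                 oracle_hyper_tail(fo$table$k, fo$table$n, fo$table$K, 10),
                 tolerance = 1e-12)
  }
  expect_error(fisher_overlap(c("e1", "zz"), "e2", universe), "universe")
})

test_that("mann_whitney exact route equals the pair-counting oracle", {
  cases <- list(
    list(x = c(1, 2, 3), y = c(10, 11, 12)),     # extreme split
    list(x = c(1, 5, 3), y = c(2, 4, 6, 8)),
    list(x = c(1, 1, 2, 2), y = c(2, 2, 3, 3, 1)),  # heavy ties
    list(x = c(0.5, 0.1), y = c(0.2, 0.9, 0.7)))
  for (cs in cases) {
    res <- mann_whitney(cs$x, cs$y)
    expect_match(res$method, "exact")
    expect_equal(res$p_value, oracle_mw_p(cs$x, cs$y), tolerance = 1e-12)
  }
  # the documented minimal-p case: 2 * 3!3!/6! = 0.1
  expect_equal(mann_whitney(c(1, 2, 3), c(10, 11, 12))$p_value, 0.1)
  # tie-free exact route agrees with the reference implementation
  set.seed(7)
  x <- rnorm(5); y <- rnorm(6)
  expect_equal(mann_whitney(x, y)$p_value,
               stats::wilcox.test(x, y, exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("mann_whitney approximation and degenerate inputs behave", {
  expect_warning(res <- mann_whitney(c(2, 2, 2), c(2, 2)), "tied")
  expect_identical(res$p_value, 1)
  # identical multisets: U at its null mean, p = 1
  res2 <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res2$statistic, 4.5)
  expect_equal(res2$p_value, 1)
  # approximation within 0.02 of exact for small samples with ties
  x <- c(1, 2, 2, 5); y <- c(2, 3, 4, 4, 6)
  expect_lt(abs(mann_whitney(x, y, exact_limit = 0L)$p_value -
                mann_whitney(x, y)$p_value), 0.02)
  expect_error(mann_whitney(1, c(2, 3)), "at least 2")
})

test_that("venn_counts covers regions exactly and sums to the universe", {
  u <- letters[1:20]
  vc <- venn_counts(list(A = letters[1:8], B = letters[5:12]), u)
  expect_equal(sum(vc$count), 20)
  expect_equal(vc$count[vc$A & vc$B], 4)
  # 3 random sets: region sums reproduce per-set sizes (direct membership)
  set.seed(11)
  sets <- lapply(1:3, function(i) sample(u, sample(3:15, 1)))
  names(sets) <- c("A", "B", "C")
  vc3 <- venn_counts(sets, u)
  expect_equal(sum(vc3$count), 20)
  for (nm in names(sets))
    expect_equal(sum(vc3$count[vc3[[nm]]]), length(sets[[nm]]))
  # disjoint sets: all intersection regions 0
  vd <- venn_counts(list(A = letters[1:3], B = letters[4:6]), u)
  expect_equal(vd$count[vd$A & vd$B], 0)
  expect_error(venn_counts(list(letters[1:2], letters[3:4]), u), "named")
})
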