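test_that("Mann-Whitney exact mode matches symmetry and enumeration cases", {
  a <- c(1, 2, 3)
  same <- mann_whitney_u(a, a)
  expect_equal(same$p_value, 1)
  expect_match(same$method, "exact")

  sep <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$p_value, 0.1, tolerance = 1e-12)  # 2/20 assignments
  expect_equal(unname(sep$statistic), 0)
})

test_that("Mann-Whitney exact p equals the brute-force oracle", {
  set.seed(14)
  for (rep in 1:5) {
    a <- rnorm(8); b <- rnorm(8)
    got <- mann_whitney_u(a, b)
    expect_match(got$method, "exact")
    expect_equal(got$p_value, oracle_mw_exact(a, b), tolerance = 1e-12)
  }
  # tied data, small enough to enumerate
  a <- c(1, 2, 2, 3); b <- c(2, 3, 3, 4)
  got <- mann_whitney_u(a, b)
  expect_identical(got$method, "exact enumeration")
  expect_equal(got$p_value, oracle_mw_exact(a, b), tolerance = 1e-12)
})

test_that("exact recurrence agrees with the reference exact distribution", {
  set.seed(15)
  a <- rnorm(20); b <- rnorm(20)   # C(40,20) too large to enumerate
  got <- mann_whitney_u(a, b)
  expect_identical(got$method, "exact recurrence")
  ref <- stats::wilcox.test(a, b, exact = TRUE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("normal approximation matches the reference tie-corrected form", {
  set.seed(16)
  a <- sample(1:10, 30, replace = TRUE)
  b <- sample(3:12, 25, replace = TRUE)
  got <- mann_whitney_u(a, b, exact = FALSE)
  expect_identical(got$method, "normal approximation")
  ref <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  got_nc <- mann_whitney_u(a, b, exact = FALSE, correct = FALSE)
  ref_nc <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = FALSE))
  expect_equal(got_nc$p_value, ref_nc$p.value, tolerance = 1e-10)
  expect_error(mann_whitney_u(numeric(0), 1:3), "nonempty")
})

test_that("Kruskal-Wallis H matches the rank-formula oracle and reference", {
  flat <- kruskal_wallis(list(a = c(2, 2), b = c(2, 2), c = c(2, 2)))
  expect_equal(unname(flat$statistic), 0)
  expect_equal(flat$p_value, 1)

  gr <- list(a = c(1, 2), b = c(3, 4), c = c(5, 6))
  got <- kruskal_wallis(gr)
  expect_equal(unname(got$statistic), oracle_kw_h(gr), tolerance = 1e-12)

  set.seed(17)
  gr <- list(a = rnorm(12), b = rnorm(15, 0.5), c = sample(1:5, 9, TRUE))
  got <- kruskal_wallis(gr)
  ref <- stats::kruskal.test(unlist(gr), rep(1:3, lengths(gr)))
  expect_equal(unname(got$statistic), unname(ref$statistic), tolerance = 1e-10)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(unname(got$statistic), oracle_kw_h(gr), tolerance = 1e-12)
  expect_error(kruskal_wallis(list(1:3)), ">= 2 groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "empty")
})

test_that("Dunn's z matches direct mean-rank arithmetic", {
  gr <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  got <- dunns_procedure(gr)
  for (k in seq_len(nrow(got$comparisons))) {
    cc <- got$comparisons[k, ]
    expect_equal(cc$z,
                 unname(oracle_dunn_z(gr, match(cc$group1, names(gr)),
                                      match(cc$group2, names(gr)))),
                 tolerance = 1e-12)
  }
  expect_true(all(got$comparisons$p_adjusted >= got$comparisons$p_value))

  # identical pair within the family: adjusted p capped at 1
  gr2 <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(10, 11, 12))
  got2 <- dunns_procedure(gr2)
  ab <- got2$comparisons[got2$comparisons$group1 == "a" &
                           got2$comparisons$group2 == "b", ]
  expect_equal(ab$p_adjusted, 1)
  expect_error(dunns_procedure(gr2, comparisons = cbind("a", "nope")),
               "unknown group")
})

test_that("Dunn's two-group z tracks the Mann-Whitney normal approximation", {
  set.seed(18)
  a <- rnorm(20); b <- rnorm(20, 0.8)
  d <- dunns_procedure(list(a = a, b = b), adjustment = "none")
  mw <- mann_whitney_u(a, b, exact = FALSE, correct = FALSE)
  expect_lt(abs(d$comparisons$p_value - mw$p_value) /
              max(mw$p_value, 1e-12), 0.1)
})

test_that("all three tests are invariant under monotone transforms", {
  set.seed(19)
  a <- rlnorm(12); b <- rlnorm(10, 0.3); c_ <- rlnorm(14, -0.2)
  f <- function(v) exp(v) + v^3   # strictly increasing on positives
  expect_equal(mann_whitney_u(a, b)$p_value,
               mann_whitney_u(f(a), f(b))$p_value, tolerance = 1e-12)
  expect_equal(unname(kruskal_wallis(list(a, b, c_))$statistic),
               unname(kruskal_wallis(list(f(a), f(b), f(c_)))$statistic),
               tolerance = 1e-12)
  expect_equal(dunns_procedure(list(a, b, c_))$comparisons$z,
               dunns_procedure(list(f(a), f(b), f(c_)))$comparisons$z,
               tolerance = 1e-12)
})
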