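make_table <- function(raw_green, raw_red, experiment = 1L, group = "g") {
  data.frame(animal = paste0("a", seq_along(raw_green)),
             experiment = experiment, group = group,
             cell = paste0("c", seq_along(raw_green)),
             raw_green = raw_green, raw_red = raw_red,
             stringsAsFactors = FALSE)
}

test_that("per-experiment normalization divides by the channel mean", {
  tab <- normalize_per_experiment(make_table(c(2, 4), c(3, 3)))
  expect_equal(tab$x, c(2 / 3, 4 / 3))
  expect_equal(tab$y, c(1, 1))

  tab <- normalize_per_experiment(make_table(rep(7, 5), rep(7, 5)))
  expect_equal(tab$x, rep(1, 5))

  # experiments are normalized independently of each other
  tab <- normalize_per_experiment(
    make_table(c(1, 3, 10, 30), c(1, 3, 10, 30),
               experiment = c(1L, 1L, 2L, 2L)))
  expect_equal(tab$x, c(0.5, 1.5, 0.5, 1.5))

  # post-condition: every per-experiment per-channel mean is 1
  coh <- simulate_cohort(genotype_preset("met-2-null-like"), 10, 3, seed = 4)
  nn <- normalize_per_experiment(coh)
  for (e in 1:3) {
    expect_equal(mean(nn$x[nn$experiment == e]), 1, tolerance = 1e-12)
    expect_equal(mean(nn$y[nn$experiment == e]), 1, tolerance = 1e-12)
  }

  expect_error(normalize_per_experiment(make_table(c(0, 0), c(1, 2))),
               "nonpositive channel mean")
  expect_error(normalize_per_experiment(make_table(1, 1)[, -2]),
               "experiment")
})

test_that("intrinsic noise reproduces direct substitution", {
  expect_equal(intrinsic_noise(1, 1, 1, 1), 0)
  expect_equal(intrinsic_noise(2, 0, 1, 1), 2)
  expect_equal(intrinsic_noise(1.2, 0.8, 1, 1), 0.08, tolerance = 1e-15)
  expect_error(intrinsic_noise(1, 1, 0, 1), "positive")
  expect_error(intrinsic_noise(1, 1, 1, -2), "positive")
})

test_that("intrinsic noise is channel-symmetric and quadratic in scale", {
  set.seed(99)
  x <- rlnorm(1000); y <- rlnorm(1000)
  mx <- mean(x); my <- mean(y)
  expect_equal(intrinsic_noise(x, y, mx, my), intrinsic_noise(y, x, my, mx),
               tolerance = 1e-15)
  for (c_ in c(0.5, 2, 10)) {
    expect_equal(intrinsic_noise(c_ * x, c_ * y, c_ * mx, c_ * my),
                 intrinsic_noise(x, y, mx, my), tolerance = 1e-12)
  }
  expect_true(all(intrinsic_noise(x, y, mx, my) >= 0))
  expect_equal(intrinsic_noise(x, x, mx, mx), rep(0, 1000))
})

test_that("group_noise matches a naive two-pass reference", {
  set.seed(5)
  for (rep in 1:4) {
    n <- sample(50:500, 1)
    tab <- data.frame(
      animal = paste0("a", seq_len(n)),
      experiment = sample(1:3, n, replace = TRUE),
      group = sample(c("g1", "g2"), n, replace = TRUE),
      cell = paste0("c", seq_len(n)),
      x = rlnorm(n), y = rlnorm(n),
      stringsAsFactors = FALSE
    )
    for (pol in c("group_experiment", "group")) {
      got <- group_noise(tab, means = pol)
      expect_equal(got$eta, oracle_group_noise(tab, pol), tolerance = 1e-12)
      expect_identical(attr(got, "mean_policy"), pol)
    }
  }
})

test_that("group_noise is invariant to row order and collapses on unit means", {
  set.seed(6)
  n <- 120
  tab <- data.frame(animal = "a", experiment = rep(1:3, 40),
                    group = "g", cell = paste0("c", 1:n),
                    x = rlnorm(n), y = rlnorm(n), stringsAsFactors = FALSE)
  g1 <- group_noise(tab)
  g2 <- group_noise(tab[sample(n), ])
  expect_equal(sort(g1$eta), sort(g2$eta), tolerance = 1e-12)

  # unit means: eta reduces to (x - y)^2 / 2
  tab2 <- tab
  tab2$x <- tab2$x / ave(tab2$x, tab2$experiment)
  tab2$y <- tab2$y / ave(tab2$y, tab2$experiment)
  gg <- group_noise(tab2)
  expect_equal(gg$eta, (tab2$x - tab2$y)^2 / 2, tolerance = 1e-12)
  expect_error(group_noise(tab[0, ]), "empty")
})

test_that("allele R2 behaves at its limits and across both routes", {
  set.seed(7)
  x <- rlnorm(200)
  expect_equal(allele_r2(x, x), 1, tolerance = 1e-12)
  expect_equal(allele_r2(x, 3 * x + 1), 1, tolerance = 1e-12)

  xi <- rlnorm(10000); yi <- rlnorm(10000)
  expect_lt(allele_r2(xi, yi), 0.01)

  y <- 0.7 * x + rnorm(200, 0, 0.2)
  expect_equal(allele_r2(x, y, "pearson"), allele_r2(x, y, "regression"),
               tolerance = 1e-12)
  # invariance under positive affine rescaling of either channel
  expect_equal(allele_r2(2.3 * x + 0.4, y), allele_r2(x, y), tolerance = 1e-12)
  expect_equal(allele_r2(x, 0.1 * y + 7), allele_r2(x, y), tolerance = 1e-12)

  expect_error(allele_r2(1:2, 1:2), "at least 3")
  expect_error(allele_r2(rep(1, 5), 1:5), "zero variance")
})

test_that("boxplot summary matches the sorted-rank interpolation oracle", {
  expect_equal(unname(boxplot_summary(5)[-1]), rep(5, 7))
  expect_equal(boxplot_summary(1:100)[["median"]], 50.5)
  set.seed(8)
  v <- rnorm(137)
  bs <- boxplot_summary(v)
  probs <- c(median = .5, p5 = .05, p10 = .1, p25 = .25,
             p75 = .75, p90 = .9, p95 = .95)
  for (nm in names(probs)) {
    expect_equal(bs[[nm]], oracle_percentile(v, probs[[nm]]), tolerance = 1e-12)
  }
  expect_true(all(diff(bs[c("p5", "p10", "p25", "median", "p75", "p90", "p95")]) >= 0))
})

test_that("median noise rises and R2 falls with the silencing probability", {
  qs <- c(0, 0.05, 0.1, 0.2, 0.4)
  med <- r2 <- numeric(length(qs))
  for (i in seq_along(qs)) {
    par <- genotype_params("q", p_init = c(qs[i], 0, 0, 0, 0, 0))
    coh <- simulate_cohort(par, n_animals = 100, n_experiments = 1,
                           seed = 100 + i, n_cells = 20, batch_sd = 0)
    nn <- group_noise(normalize_per_experiment(coh))
    med[i] <- median(nn$eta)
    r2[i] <- allele_r2(nn$x, nn$y)
  }
  expect_true(all(diff(med) >= 0))
  expect_true(all(diff(r2) <= 0))
})

test_that("summarize_groups reports pooled percentiles and bias scores", {
  coh <- rbind(simulate_cohort(genotype_preset("wild-type"), 10, 3, seed = 31),
               simulate_cohort(genotype_preset("met-2-null-like"), 10, 3, seed = 32))
  nn <- group_noise(normalize_per_experiment(coh))
  gs <- summarize_groups(nn)
  expect_setequal(gs$group, c("wild-type", "met-2-null-like"))
  expect_equal(gs$n, c(210, 210))
  wt <- gs[gs$group == "wild-type", ]
  mut <- gs[gs$group == "met-2-null-like", ]
  expect_gt(wt$r2, mut$r2)
  expect_lt(wt$median_eta, mut$median_eta)
})
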