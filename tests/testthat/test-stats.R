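test_that("regression matches the closed-form normal equations", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2.1, 3.9, 6.2, 7.8, 10.1)
  ## frozen from the hand computation via the normal equations
  r <- regressionR2(x, y)
  expect_equal(r$slope, 1.99, tolerance = 1e-12)
  expect_equal(r$intercept, 0.05, tolerance = 1e-10)
  expect_equal(r$r2, 0.997305328900977, tolerance = 1e-12)
  expect_equal(r$p, 5.9415391117554e-05, tolerance = 1e-8)

  exact <- suppressWarnings(regressionR2(x, 2 * x))
  expect_equal(exact$r2, 1)
  expect_equal(exact$slope, 2)

  set.seed(2)
  indep <- regressionR2(rnorm(500), rnorm(500))
  expect_lt(indep$r2, 0.05)
  expect_error(regressionR2(rep(1, 5), 1:5), "zero variance")
})

test_that("normality gate selects transforms in the stated order", {
  set.seed(20)
  gauss <- lapply(1:3, function(i) rnorm(30))
  expect_identical(normalityGate(gauss)$transform, "none")

  lnorm <- lapply(1:3, function(i) exp(rnorm(40, sd = 1.2)))
  expect_identical(normalityGate(lnorm)$transform, "log")

  with_zero <- list(c(rnorm(20)^2, 0), rnorm(21)^2 + 0.1, rnorm(21)^2 + 0.1)
  g <- normalityGate(with_zero)
  expect_true(any(grepl("log transform skipped", g$notes)))
})

test_that("one-way ANOVA with Tukey HSD behaves on known structure", {
  same <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(1, 2, 3, 4))
  r <- anovaTukey(same)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)

  ## two groups: F equals the pooled-variance t-statistic squared
  set.seed(4)
  g1 <- rnorm(12); g2 <- rnorm(15, 1)
  r2 <- anovaTukey(list(g1 = g1, g2 = g2))
  tt <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(r2$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(r2$p, tt$p.value, tolerance = 1e-10)
  expect_identical(nrow(r2$posthoc), 1L)

  ## a 3-sd shifted group is detected essentially always
  set.seed(8)
  hits <- 0L
  for (i in 1:200) {
    gs <- list(rnorm(20), rnorm(20), rnorm(20, 3))
    if (anovaTukey(gs)$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.99)
})

test_that("Kruskal-Wallis + Dunn matches the tie-corrected hand example", {
  ## two groups of ordinal scores with heavy ties; frozen hand values
  r <- kruskalDunn(list(A = c(1, 1, 2), B = c(2, 3, 3)), adjust = "none")
  expect_equal(r$statistic, 10 / 3, tolerance = 1e-10)
  expect_equal(r$posthoc$z, -1.8257418583506, tolerance = 1e-10)
  expect_equal(r$posthoc$p, 0.0678891548618, tolerance = 1e-10)
  expect_equal(r$posthoc$pAdj, r$posthoc$p)

  same <- list(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5))
  expect_equal(kruskalDunn(same)$p, 1, tolerance = 1e-10)
  expect_error(kruskalDunn(list(a = c(2, 2), b = c(2, 2))), "identical")

  ## Dunn p-values are invariant under group relabeling
  set.seed(6)
  gs <- list(x = sample(1:3, 15, TRUE), y = sample(1:3, 15, TRUE),
             z = sample(1:3, 15, TRUE))
  r1 <- kruskalDunn(gs)
  r2 <- kruskalDunn(gs[c("z", "x", "y")])
  expect_equal(sort(r1$posthoc$pAdj), sort(r2$posthoc$pAdj))
})
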