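test_that("a noiseless line is fit exactly", {
  d <- data.frame(x = 1:10, y = 2 * (1:10) + 1)
  # lm warns that a perfect fit makes the summary unreliable; the point
  # estimates are still exact, which is what this checks
  f <- suppressWarnings(fit_ols(d, "y", "x"))
  expect_equal(f$coefficients$estimate, c(1, 2), tolerance = 1e-12)
  expect_equal(f$r_squared, 1)
  expect_equal(f$error_df, 8)
})

test_that("OLS matches the normal-equations oracle on random designs", {
  set.seed(71)
  for (k in 1:20) {
    n <- 20; p <- 3
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    d <- data.frame(y = y, X)
    f <- fit_ols(d, "y", paste0("X", 1:p))
    expect_equal(f$coefficients$estimate, ne_ols(X, y), tolerance = 1e-8)
  }
})

test_that("rank-deficient designs fail loudly naming the collinear column", {
  d <- data.frame(y = rnorm(10), a = rnorm(10))
  d$b <- 2 * d$a
  expect_error(fit_ols(d, "y", c("a", "b")), "collinear.*b")
  d2 <- data.frame(y = rnorm(3), a = rnorm(3), b = rnorm(3), c = rnorm(3))
  expect_error(fit_ols(d2, "y", c("a", "b", "c")), "more observations")
})

test_that("individual and total sections coincide in degenerate designs", {
  set.seed(73)
  d <- data.frame(x = rnorm(30))
  d$y <- 1 + 0.5 * d$x + rnorm(30, 0, 0.2)
  rep1 <- individual_and_total(d, "y", "x")
  expect_equal(rep1$individual_coef, rep1$total_coef)
  expect_equal(rep1$individual_r2, attr(rep1, "total_r2"))

  # orthogonal predictors: joint fit reproduces the individual coefficients
  x1 <- rep(c(-1, 1), each = 16)
  x2 <- rep(c(-1, 1), times = 16)
  stopifnot(sum(x1 * x2) == 0)
  d2 <- data.frame(x1 = x1, x2 = x2)
  d2$y <- 2 + 0.7 * x1 - 0.3 * x2 + rnorm(32, 0, 0.1)
  rep2 <- individual_and_total(d2, "y", c("x1", "x2"))
  expect_equal(rep2$individual_coef, rep2$total_coef, tolerance = 1e-8)
})

test_that("the joint model's R2 dominates every individual R2", {
  set.seed(79)
  for (k in 1:5) {
    n <- 60
    d <- data.frame(a = rnorm(n), b = rnorm(n), c = rbinom(n, 1, 0.4))
    d$y <- 1 + 0.3 * d$a - 0.2 * d$b + 0.5 * d$c + rnorm(n)
    r <- individual_and_total(d, "y", c("a", "b", "c"))
    expect_gte(attr(r, "total_r2"), max(r$individual_r2))
  }
})

test_that("downsampling balances groups deterministically under a seed", {
  s <- c(1, 2, 3, 4, 5, 1, 2, 3)
  g <- c(rep("A", 5), rep("B", 3))
  d1 <- downsample_equal(s, g, seed = 9)
  expect_equal(as.vector(table(d1$group)), c(3L, 3L))
  d2 <- downsample_equal(s, g, seed = 9)
  expect_identical(d1, d2)
  d3 <- downsample_equal(s, g, seed = 10)
  expect_false(identical(d1$score, d3$score) &&
                 identical(attr(d1, "seed"), attr(d3, "seed")))
  # already balanced input passes through complete
  d4 <- downsample_equal(c(1, 2, 3, 4), c("A", "A", "B", "B"), seed = 1)
  expect_equal(sort(d4$score), c(1, 2, 3, 4))
})

test_that("eta-squared matches hand computation and degenerate cases", {
  a <- anova_eta2(c(1, 2, 3, 4), c("g1", "g1", "g2", "g2"))
  expect_equal(a$eta_squared, 0.8)
  b <- anova_eta2(c(1, 3, 1, 3), c("g1", "g1", "g2", "g2"))
  expect_equal(b$eta_squared, 0)
  expect_error(anova_eta2(rep(2, 6), rep(c("a", "b"), 3)), "zero total variance")
  expect_error(anova_eta2(c(1, 2, 3), c("a", "a", "b")), "at least two")
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(83)
  x <- rnorm(12, 0); y <- rnorm(15, 0.8)
  a <- anova_eta2(c(x, y), rep(c("x", "y"), c(12, 15)))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(a$f_statistic, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(a$p_value, tt$p.value, tolerance = 1e-9)
})

test_that("Tukey HSD matches a studentized-range computation", {
  # small balanced three-group layout
  sc <- c(4, 5, 6, 5, 7, 8, 9, 8, 2, 3, 4, 3)
  gr <- rep(c("g1", "g2", "g3"), each = 4)
  a <- anova_eta2(sc, gr)
  n <- 4; k <- 3; df <- length(sc) - k
  mse <- sum(unlist(lapply(split(sc, gr), function(v) sum((v - mean(v))^2)))) / df
  means <- tapply(sc, gr, mean)
  pairs <- combn(names(means), 2)
  for (j in seq_len(ncol(pairs))) {
    q <- abs(means[pairs[2, j]] - means[pairs[1, j]]) / sqrt(mse / n)
    p_manual <- unname(ptukey(q, nmeans = k, df = df, lower.tail = FALSE))
    cmp <- paste(pairs[2, j], pairs[1, j], sep = "-")
    expect_equal(a$tukey$p_adj[a$tukey$comparison == cmp], p_manual,
                 tolerance = 1e-3)
  }
})

test_that("percent agreement counts exact and within-one bands", {
  a <- interrater_agreement(c(1, 2, 5), c(1, 2, 5))
  expect_equal(c(a$pct_exact, a$pct_within_one, a$pct_approx), c(100, 0, 100))
  b <- interrater_agreement(c(1, 3), c(2, 5))
  expect_equal(c(b$pct_exact, b$pct_within_one, b$pct_approx), c(0, 50, 50))
  set.seed(89)
  r1 <- sample(1:5, 100, TRUE); r2 <- sample(1:5, 100, TRUE)
  g <- interrater_agreement(r1, r2)
  expect_equal(g$pct_approx, g$pct_exact + g$pct_within_one)
  expect_error(interrater_agreement(1:3, 1:4), "length")
})

test_that("the host ANOVA wrapper is deterministic given its seed", {
  set.seed(97)
  ev <- data.frame(host1 = rep(c(1, 0, 0, 0), c(40, 30, 20, 10)),
                   host2 = rep(c(0, 1, 0, 0), c(40, 30, 20, 10)),
                   host3 = rep(c(0, 0, 1, 0), c(40, 30, 20, 10)),
                   score_r1 = pmin(pmax(round(rnorm(100, 3 +
                     rep(c(0.8, 0, -0.3, 0), c(40, 30, 20, 10)), 1)), 1), 5))
  a1 <- host_anova(ev, seed = 7)
  a2 <- host_anova(ev, seed = 7)
  expect_identical(a1$eta_squared, a2$eta_squared)
  expect_identical(a1$tukey, a2$tukey)
  expect_equal(a1$group_ns, rep(10L, 4))
  a3 <- host_anova(ev, hosts = 1:3, seed = 7)
  expect_equal(a3$group_ns, rep(20L, 3))
})
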