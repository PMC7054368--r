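test_that("rank-inverse-normal transform reproduces Blom scores", {
  # oracle: Phi^-1((r - 0.375)/(3 - 0.75 + 1)) for ranks 3, 1, 2
  got <- rankInverseNormal(c(3.1, 1.2, 2.0), offset = 0.375)
  expect_equal(got, qnorm((c(3, 1, 2) - 0.375) / 3.25), tolerance = 1e-12)
  expect_equal(round(got, 3), c(0.869, -0.869, 0.000))
})

test_that("rank-inverse-normal scores are anti-symmetric, monotone, tie-aware", {
  x <- c(5, 1, 3, 9, 7)
  z <- rankInverseNormal(x)
  expect_equal(sum(z), 0, tolerance = 1e-12)     # Blom anti-symmetry
  expect_equal(order(z), order(x))               # order-preserving
  expect_true(all(diff(rankInverseNormal(sort(x))) > 0))
  # ties get average ranks, hence identical scores
  zt <- rankInverseNormal(c(2, 2, 5, 7))
  expect_equal(zt[1], zt[2])
  # missing in, missing out; others unaffected by the NA
  xm <- c(3.1, NA, 1.2, 2.0)
  zm <- rankInverseNormal(xm)
  expect_true(is.na(zm[2]))
  expect_equal(zm[-2], rankInverseNormal(c(3.1, 1.2, 2.0)))
})

test_that("rank-inverse-normal respects strata and rejects degenerate ones", {
  x <- c(1, 5, 3, 10, 2, 8)
  g <- c("f", "f", "f", "m", "m", "m")
  z <- rankInverseNormal(x, g)
  expect_equal(z[g == "f"], rankInverseNormal(x[g == "f"]))
  expect_equal(z[g == "m"], rankInverseNormal(x[g == "m"]))
  expect_error(rankInverseNormal(c(1, 2, 3), c("a", "a", "b")),
               "stratum 'b'")
  expect_error(rankInverseNormal(c(4, 4, 4)), "constant")
})

test_that("stratified scores approximate a standard normal for n >= 50", {
  set.seed(42)
  for (n in c(50, 200)) {
    x <- rexp(n)  # skewed input
    z <- rankInverseNormal(x)
    expect_lt(abs(mean(z)), 0.02)
    expect_true(sd(z) > 0.9 && sd(z) < 1.1)
  }
})

test_that("residualisation matches the normal equations and is orthogonal", {
  set.seed(1)
  n <- 6
  tab <- data.frame(x = c(0.2, 1.1, 1.9, 3.2, 3.8, 5.1))
  tab$y <- 2 * tab$x + c(0.3, -0.2, 0.1, -0.4, 0.25, -0.05)
  r <- residualize(tab, "y", "x")$y
  # hand normal-equations solve
  X <- cbind(1, tab$x)
  beta <- solve(t(X) %*% X, t(X) %*% tab$y)
  expect_equal(r, as.numeric(tab$y - X %*% beta), tolerance = 1e-10)
  expect_lt(abs(sum(r * tab$x)), 1e-8 * n)
  expect_lt(abs(sum(r)), 1e-8 * n)
})

test_that("residualisation is idempotent and handles factors/collinearity", {
  set.seed(7)
  tab <- data.frame(age = rnorm(60, 60, 6),
                    centre = sample(c("A", "B", "C"), 60, TRUE),
                    y = rnorm(60))
  r1 <- residualize(tab, "y", c("age", "centre"))$y
  tab$r1 <- r1
  r2 <- residualize(tab, "r1", c("age", "centre"))$r1
  expect_equal(r1, r2, tolerance = 1e-10)
  # residuals orthogonal to every design column
  X <- model.matrix(~ age + centre, tab)
  expect_lt(max(abs(crossprod(X, r1))), 1e-8 * nrow(tab))
  # duplicated covariate column is dropped with a message, not an error
  tab$age2 <- tab$age
  expect_message(r3 <- residualize(tab, "y", c("age", "age2", "centre"))$y,
                 "collinear")
  expect_equal(r3, r1, tolerance = 1e-10)
  # centred target orthogonal to the covariate passes through unchanged
  tab2 <- data.frame(z = c(-1, 1, -1, 1), w = c(1, 1, -1, -1))
  expect_equal(residualize(tab2, "z", "w")$z, tab2$z, tolerance = 1e-12)
  expect_error(residualize(data.frame(z = c(1, 2), w = c(1, -1)), "z", "w"),
               "complete rows")
})

test_that("pairwise correlations have exact diagonal and flag constants", {
  set.seed(3)
  tab <- data.frame(a = rnorm(10))
  tab$b <- -tab$a
  tab$c <- rnorm(10)
  r <- pairwiseCorrelations(tab)
  expect_equal(unname(diag(r)), c(1, 1, 1))
  expect_equal(r, t(r))
  expect_equal(r["a", "b"], -1)
  # 4-row textbook Pearson oracle
  x <- c(1, 2, 4, 7); y <- c(2, 1, 5, 9)
  rxy <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pairwiseCorrelations(data.frame(x, y))["x", "y"], rxy,
               tolerance = 1e-12)
  expect_true(is.na(
    pairwiseCorrelations(data.frame(k = rep(1, 5), z = rnorm(5)))["k", "z"]))
})

test_that("covariance input uses N-1, listwise deletion, and demands PD", {
  tab <- data.frame(a = c(1, 2, 4, 7), b = c(2, 1, 5, 9),
                    c = c(0.5, 1, -1, 2))
  ci <- covarianceInput(tab)
  # hand computation with N - 1 denominator
  hand <- function(x, y) sum((x - mean(x)) * (y - mean(y))) / 3
  expect_equal(sampleCov(ci)["a", "b"], hand(tab$a, tab$b), tolerance = 1e-12)
  expect_equal(sampleCov(ci)["a", "a"], hand(tab$a, tab$a), tolerance = 1e-12)
  expect_identical(sampleCov(ci), t(sampleCov(ci)))
  expect_equal(sampleSize(ci), 4L)
  tab2 <- rbind(tab, data.frame(a = 3, b = NA, c = 1))
  expect_equal(sampleSize(covarianceInput(tab2)), 4L)  # listwise deletion
  expect_error(covarianceInput(tab[1:3, ]), "complete cases")
  sing <- data.frame(x = c(1, 2, 3, 4, 5))
  sing$y <- 2 * sing$x
  expect_error(covarianceInput(sing), "eigenvalue")
})

test_that("covariance of iid standard normals approaches the identity", {
  for (seed in 1:5) {
    set.seed(seed)
    N <- 2000
    d <- as.data.frame(matrix(rnorm(N * 4), N, 4))
    S <- sampleCov(covarianceInput(d))
    expect_lt(max(abs(S[upper.tri(S)])), 4 / sqrt(N))
  }
})

test_that("full preprocessing leaves centred unit-scale scores", {
  cohort <- generateCohort(syntheticCohortSpec(cohort = 2, n = 400,
                                               seed = 5))
  an <- preprocessCohort(cohort, c("FG", "PG", "IS", "LF"),
                         strata = c("sex", "treatment"))
  for (v in names(an)) {
    expect_lt(abs(mean(an[[v]], na.rm = TRUE)), 0.05)
    s <- sd(an[[v]], na.rm = TRUE)
    expect_true(s > 0.9 && s < 1.1)
  }
})
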