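test_that("implied covariance matches hand expansions", {
  nodes <- c("x", "m", "y")
  B <- matrix(0, 3, 3, dimnames = list(nodes, nodes))
  # B = 0 reduces to Psi
  expect_equal(impliedCovarianceFrom(B, c(2, 3, 4)), diag(c(2, 3, 4)),
               ignore_attr = TRUE)
  # chain x -> m -> y with unit disturbances: hand expansion
  b1 <- 0.5; b2 <- 0.4
  B["m", "x"] <- b1; B["y", "m"] <- b2
  Sig <- impliedCovarianceFrom(B, c(1, 1, 1))
  expect_equal(Sig["x", "m"], b1, tolerance = 1e-12)
  expect_equal(Sig["m", "m"], b1^2 + 1, tolerance = 1e-12)
  expect_equal(Sig["x", "y"], b1 * b2, tolerance = 1e-12)
  expect_equal(Sig["m", "y"], b2 * (b1^2 + 1), tolerance = 1e-12)
  expect_equal(Sig["y", "y"], b2^2 * (b1^2 + 1) + 1, tolerance = 1e-12)
  expect_equal(Sig, t(Sig))
})

test_that("cyclic implied covariance equals the truncated Neumann expansion", {
  # 2-node feedback a <-> b, b1*b2 = 0.2: (I-B)^-1 = sum_k B^k, so
  # Sigma = (sum B^k) Psi (sum B^k)^T; truncate at k = 60
  B <- matrix(c(0, 0.4, 0.5, 0), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  psi <- c(1, 1.3)
  An <- matrix(0, 2, 2); Bk <- diag(2)
  for (k in 0:60) { An <- An + Bk; Bk <- Bk %*% B }
  oracle <- An %*% diag(psi) %*% t(An)
  expect_equal(impliedCovarianceFrom(B, psi), oracle,
               tolerance = 1e-8, ignore_attr = TRUE)
  # degenerate feedback b1*b2 = 1 is singular
  Bs <- matrix(c(0, 2, 0.5, 0), 2, 2)
  expect_error(impliedCovarianceFrom(Bs, c(1, 1)), "singular")
})

test_that("ML discrepancy has its strict minimum at Sigma = S", {
  S1 <- matrix(2, 1, 1); Sig1 <- matrix(1, 1, 1)
  expect_equal(mlDiscrepancy(S1, Sig1), 1 - log(2), tolerance = 1e-12)
  S <- randomPDMatrix(4, seed = 1)
  expect_equal(mlDiscrepancy(S, S), 0, tolerance = 1e-12)
  for (seed in 1:100) {
    set.seed(seed)
    P <- matrix(rnorm(16, sd = 0.1), 4, 4)
    Sig <- S + crossprod(P) + diag(4) * 0.01
    expect_gt(mlDiscrepancy(S, Sig), 0)
  }
  expect_error(mlDiscrepancy(S, diag(c(1, 1, 1, -1))), "Sigma")
  expect_error(mlDiscrepancy(diag(c(1, 0, 1, 1)), S), "S is not")
})

test_that("saturated recursive models reproduce S exactly (chi-square 0)", {
  for (seed in 1:5) {
    S <- randomPDMatrix(3, seed = seed)
    # full lower-triangular DAG: v1 -> v2 -> v3, v1 -> v3 (just-identified)
    ed <- data.frame(label = c("a", "b", "c"),
                     from = c("v1", "v1", "v2"),
                     to = c("v2", "v3", "v3"))
    fit <- fitModel(pathModel(ed), asCovInput(S, 200), se = FALSE)
    expect_equal(modelDF(fit), 0)
    expect_lt(chisq(fit), 1e-8)
    expect_equal(impliedCovariance(fit), S, tolerance = 1e-7,
                 ignore_attr = TRUE)
  }
})

test_that("single-edge fit equals the moment ratio S_xy/S_xx", {
  S <- matrix(c(2, 0.8, 0.8, 1.5), 2, 2,
              dimnames = list(c("x", "y"), c("x", "y")))
  m <- pathModel(data.frame(label = "b", from = "x", to = "y"))
  fit <- fitModel(m, asCovInput(S, 100))
  expect_equal(coefTable(fit)$estimate, 0.8 / 2, tolerance = 1e-8)
  expect_equal(unname(fit@psi["x"]), 2, tolerance = 1e-10)  # fixed-x
})

test_that("standardized solution matches the closed-form chain and is scale-free", {
  # chain with b1 = 0.5, b2 = 0.4 fitted to its own implied covariance
  nodes <- c("x", "m", "y")
  B <- matrix(0, 3, 3, dimnames = list(nodes, nodes))
  B["m", "x"] <- 0.5; B["y", "m"] <- 0.4
  Sig <- impliedCovarianceFrom(B, c(1, 1, 1))
  fit <- fitModel(chainModel(), asCovInput(Sig, 500))
  std <- standardizedSolution(fit)
  expect_equal(std$std[std$label == "b2"],
               0.4 * sqrt(1.25) / sqrt(0.4^2 * 1.25 + 1), tolerance = 1e-6)
  # rescale one observed variable by 10: standardized solution unchanged
  D <- diag(c(1, 10, 1)); dimnames(D) <- dimnames(Sig)
  Sig2 <- D %*% Sig %*% D; dimnames(Sig2) <- dimnames(Sig)
  fit2 <- fitModel(chainModel(), asCovInput(Sig2, 500))
  expect_equal(standardizedSolution(fit2)$std, std$std, tolerance = 1e-6)
  # variance-1 input: standardized equals raw
  R <- cov2cor(Sig); dimnames(R) <- dimnames(Sig)
  fit3 <- fitModel(chainModel(), asCovInput(R, 500))
  expect_equal(standardizedSolution(fit3)$std, coefTable(fit3)$estimate,
               tolerance = 1e-8)
})

test_that("recursive ML estimates equal equation-wise least squares", {
  for (seed in 1:10) {
    p <- sample(3:4, 1)
    m <- randomRecursiveModel(p, seed = seed)
    S <- randomPDMatrix(p, seed = seed + 500)
    fit <- fitModel(m, asCovInput(S, 300), se = FALSE)
    oracle <- olsOnMoments(m, S)
    expect_equal(setNames(coefTable(fit)$estimate, coefTable(fit)$label),
                 oracle, tolerance = 1e-6)
  }
})

test_that("Wald machinery: ACOV is symmetric PSD, SEs positive, z consistent", {
  d <- simulateStructuralSystem(
    coefficientMatrix(builtinModel("TC"),
                      setNames(referenceEstimates("TC", 1)$beta,
                               referenceEstimates("TC", 1)$label)),
    n = 900, seed = 21)
  fit <- fitModel(builtinModel("TC"), covarianceInput(d))
  expect_true(fit@converged)
  AC <- paramCov(fit)
  expect_equal(AC, t(AC), tolerance = 1e-10)
  ev <- eigen(AC, symmetric = TRUE, only.values = TRUE)$values
  expect_true(min(ev) > -1e-10 * max(ev))
  cf <- coefTable(fit)
  expect_true(all(cf$se > 0))
  expect_equal(cf$z, cf$estimate / cf$se, tolerance = 1e-12)
  expect_equal(cf$p, 2 * pnorm(-abs(cf$z)), tolerance = 1e-12)
  # chi-square scaling switch: N vs N-1
  fitN <- fitModel(builtinModel("TC"), covarianceInput(d), chisqScale = "N")
  expect_equal(chisq(fitN) / chisq(fit), 900 / 899, tolerance = 1e-6)
})

test_that("fitting demands the model variables and nonnegative df", {
  S <- randomPDMatrix(2, seed = 3)
  m <- chainModel()  # needs x, m, y
  expect_error(fitModel(m, asCovInput(S, 100)), "lacks model variable")
  # saturated + extra edge: negative df
  ed <- data.frame(label = c("a", "b", "c", "d"),
                   from = c("v1", "v1", "v2", "v2"),
                   to = c("v2", "v3", "v3", "v1"))
  S3 <- randomPDMatrix(3, seed = 4)
  expect_error(fitModel(pathModel(ed), asCovInput(S3, 100)),
               "negative degrees of freedom")
})
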