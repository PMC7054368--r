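test_that("unit-variance disturbances solve the diagonal condition exactly", {
  m <- builtinModel("TC-PA")
  truth <- setNames(referenceEstimates("TC-PA", 1)$beta,
                    referenceEstimates("TC-PA", 1)$label)
  B <- coefficientMatrix(m, truth)
  psi <- unitVarianceDisturbances(B)
  expect_true(all(psi > 0))
  Sig <- impliedCovarianceFrom(B, psi)
  expect_equal(unname(diag(Sig)), rep(1, 9), tolerance = 1e-12)
  # generating B is then its own standardized solution
  ed <- edgeTable(m)
  std <- B[cbind(ed$to, ed$from)] * sqrt(diag(Sig))[ed$from] /
    sqrt(diag(Sig))[ed$to]
  expect_equal(unname(std), unname(truth[ed$label]), tolerance = 1e-12)
})

test_that("structural simulation matches implied moments", {
  # B = 0: sample covariance approaches Psi
  nodes <- c("a", "b")
  B0 <- matrix(0, 2, 2, dimnames = list(nodes, nodes))
  d0 <- simulateStructuralSystem(B0, psi = c(2, 0.5), n = 10000, seed = 1)
  S0 <- cov(d0)
  expect_lt(abs(S0[1, 1] - 2), 3 * 2 * sqrt(2 / 9999))
  expect_lt(abs(S0[2, 2] - 0.5), 3 * 0.5 * sqrt(2 / 9999))
  expect_lt(abs(S0[1, 2]), 3 * sqrt(1 / 9999))
  # chain b1 = 0.5, b2 = 0.4: cov(x, y) -> 0.2
  nodes <- c("x", "m", "y")
  B <- matrix(0, 3, 3, dimnames = list(nodes, nodes))
  B["m", "x"] <- 0.5; B["y", "m"] <- 0.4
  d <- simulateStructuralSystem(B, psi = c(1, 1, 1), n = 100000, seed = 2)
  # MC SE of a covariance of roughly unit-variance normals ~ sqrt(1.1/n)
  expect_lt(abs(cov(d$x, d$y) - 0.2), 3 * sqrt(1.1 / 100000))
  # singular feedback loop errors
  Bs <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a","b"), c("a","b")))
  expect_error(simulateStructuralSystem(Bs, psi = c(1, 1), n = 10), "singular")
})

test_that("cohort generation is seed-deterministic and calibrated", {
  spec <- syntheticCohortSpec(cohort = 1, model = "TC-PA", n = 10000,
                              seed = 99)
  c1 <- generateCohort(spec)
  c2 <- generateCohort(spec)
  expect_identical(c1, c2)
  # marginal calibration to the cohort-1 targets
  expect_equal(mean(c1$FG), 5.8, tolerance = 0.02 * 5.8)
  expect_equal(sd(c1$FG), 0.5, tolerance = 0.02 * 0.5)
  expect_equal(mean(c1$IS), 374, tolerance = 0.02 * 374)
  expect_equal(sd(c1$LF), 4.7, tolerance = 0.02 * 4.7)
  expect_equal(mean(c1$age), 60.6, tolerance = 1)
  expect_equal(mean(c1$sex == "male"), 0.83, tolerance = 0.03)
  expect_true(all(c1$treatment == "lifestyle"))  # cohort 1 untreated
  c2spec <- syntheticCohortSpec(cohort = 2, n = 2000, seed = 100)
  cc2 <- generateCohort(c2spec)
  expect_equal(mean(cc2$FG), 7.0, tolerance = 0.02 * 7)
  expect_true(all(c("lifestyle", "metformin+lifestyle") %in% cc2$treatment))
  # implausibly small cohorts are rejected up front
  expect_error(syntheticCohortSpec(cohort = 1, n = 10), ">= 50")
})

test_that("confounder effects shift raw correlations and wash out in residuals", {
  # age effect +0.3 SD/SD on LF only: raw cor(LF, age) ~ 0.3/sqrt(1.09),
  # residualisation then removes it
  spec <- syntheticCohortSpec(
    cohort = 1, n = 20000, seed = 7,
    confounderEffects = list(age = c(LF = 0.3), energy = 0,
                             carbohydrate = 0, fat = 0, protein = 0,
                             centre = rep(0, 4), sex = 0))
  spec$effects$age[setdiff(names(spec$effects$age), "LF")] <- 0
  cohort <- generateCohort(spec)
  expect_equal(cor(cohort$LF, cohort$age), 0.3 / sqrt(1.09),
               tolerance = 0.025)
  an <- preprocessCohort(cohort, c("LF", "IS", "FG"), strata = NULL,
                         covariates = c("age"))
  expect_lt(abs(cor(an$LF, cohort$age)), 0.02)
})

test_that("no-confounding cohorts keep node correlations through preprocessing", {
  spec <- syntheticCohortSpec(
    cohort = 1, n = 5000, seed = 31,
    confounderEffects = list(age = 0, energy = 0, carbohydrate = 0,
                             fat = 0, protein = 0, centre = rep(0, 4),
                             sex = 0))
  cohort <- generateCohort(spec)
  vars <- nodeNames(builtinModel("TC-PA"))
  an <- preprocessCohort(cohort, vars)
  rRaw <- pairwiseCorrelations(cohort[, vars])
  rAn <- pairwiseCorrelations(an)
  expect_lt(max(abs(rRaw - rAn)), 0.02)
})

test_that("pipeline closure: generated cohorts return the generating model", {
  truth <- referenceEstimates("TC-PA", 1)
  cohort <- generateCohort(syntheticCohortSpec(cohort = 1, n = 100000,
                                               seed = 55))
  an <- preprocessCohort(cohort, nodeNames(builtinModel("TC-PA")))
  fit <- fitModel(builtinModel("TC-PA"), covarianceInput(an), se = FALSE)
  err <- abs(coefTable(fit)$std - truth$beta)
  expect_lt(mean(err), 0.02)
  expect_true(all(sign(coefTable(fit)$std) == sign(truth$beta)))
  # and at study scale, averaged over seeds
  errs <- vapply(1:10, function(s) {
    co <- generateCohort(syntheticCohortSpec(cohort = 1, n = 725, seed = s))
    a <- preprocessCohort(co, nodeNames(builtinModel("TC-PA")))
    f <- fitModel(builtinModel("TC-PA"), covarianceInput(a), se = FALSE)
    mean(abs(coefTable(f)$std - truth$beta))
  }, numeric(1))
  expect_lt(mean(errs), 0.08)
})
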