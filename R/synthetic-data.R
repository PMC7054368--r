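#' Disturbance variances giving unit implied variances
#'
#' For a coefficient matrix B, finds the diagonal \eqn{\Psi} such that every
#' implied variance is 1: with \eqn{A = (I-B)^{-1}}, the condition
#' \eqn{diag(A \Psi A^T) = 1} is linear in \eqn{\psi}
#' (\eqn{\sum_k A_{ik}^2 \psi_k = 1}) and is solved exactly. This makes
#' standardized coefficients directly usable as generating values: data
#' simulated with (B, psi) then have unit-variance nodes, so the generating
#' B is its own standardized solution.
#'
#' @param B square coefficient matrix
#' @return named vector of disturbance variances (all positive, or an error
#'   when no positive solution exists for this B)
#' @export
unitVarianceDisturbances <- function(B) {
  p <- nrow(B)
  ImB <- diag(p) - B
  if (rcond(ImB) < 1e-12)
    stop("structural system is singular: (I - B) is not invertible")
  A <- solve(ImB)
  psi <- solve(A^2, rep(1, p))
  if (any(psi <= 0))
    stop("no positive disturbance variances give unit implied variances ",
         "for this coefficient matrix")
  setNames(as.numeric(psi), rownames(B))
}

#' Simulate a linear structural system
#'
#' Draws independent normal disturbances \eqn{\zeta \sim N(0, \Psi)} and
#' solves \eqn{y = (I - B)^{-1} \zeta} row-wise, so the population
#' covariance of the output equals the implied covariance
#' \eqn{(I-B)^{-1} \Psi (I-B)^{-T}}. Works for cyclic systems.
#'
#' @param B square coefficient matrix with node dimnames
#' @param psi disturbance variances; \code{NULL} (default) solves for the
#'   unit-implied-variance diagonal via [unitVarianceDisturbances()]
#' @param n number of rows to draw
#' @param seed optional RNG seed (caller's RNG state is preserved)
#' @return data.frame of node scores, one column per node
#' @export
simulateStructuralSystem <- function(B, psi = NULL, n, seed = NULL) {
  stopifnot(is.matrix(B), nrow(B) == ncol(B), n >= 1)
  p <- nrow(B)
  if (is.null(psi)) psi <- unitVarianceDisturbances(B)
  stopifnot(length(psi) == p, all(psi > 0))
  ImB <- diag(p) - B
  if (rcond(ImB) < 1e-12)
    stop("structural system is singular: (I - B) is not invertible")
  A <- solve(ImB)
  draw <- function() matrix(rnorm(n * p), n, p) %*%
    (diag(sqrt(psi), p) %*% t(A))
  y <- if (is.null(seed)) draw() else .seededDraw(seed, draw)
  colnames(y) <- colnames(B)
  as.data.frame(y)
}

#' Specification of a synthetic cohort
#'
#' Bundles everything [generateCohort()] needs: the generating coefficient
#' matrix (defaulting to the reference standardized estimates for the
#' chosen cohort and model), stratum composition, confounder effect sizes
#' (in SD-per-SD units on the node scores), and the marginal mean/SD
#' calibration targets for the raw scales.
#'
#' Default confounder effects are deliberately modest and uniform -- age
#' 0.10, each dietary variable 0.05 SD per SD on every node, 4 study-centre
#' offsets (0, 0.15, -0.15, 0.10 SD), a 0.2 SD sex offset, and for cohort 2
#' a metformin-group offset of -0.3 SD on FG and -0.2 SD on PG -- so that
#' the preprocessing stage has real work to do while the structural signal
#' dominates.
#'
#' @param cohort 1 (no diabetes/prediabetes) or 2 (diabetes)
#' @param model \code{"TC"} or \code{"TC-PA"}
#' @param n cohort size; defaults to the reference complete-case size
#'   (920/725/435/361 by cohort and model)
#' @param edgeCoefficients named (by edge label) or edge-ordered vector of
#'   generating coefficients; defaults to [referenceEstimates()]
#' @param confounderEffects named list overriding any of \code{age},
#'   \code{energy}, \code{carbohydrate}, \code{fat}, \code{protein}
#'   (scalar or per-node vector), \code{centre} (vector of per-level SD
#'   offsets), \code{sex} (scalar or per-node), \code{treatment}
#'   (named per-node vector)
#' @param seed RNG seed for [generateCohort()]
#' @return list of class \code{"syntheticCohortSpec"}
#' @export
syntheticCohortSpec <- function(cohort = 1, model = "TC-PA", n = NULL,
                                edgeCoefficients = NULL,
                                confounderEffects = list(), seed = 1L) {
  stopifnot(cohort %in% c(1, 2))
  pm <- builtinModel(model)
  chars <- referenceCharacteristics(cohort, model)
  if (is.null(n)) n <- chars$n
  if (n < 50) stop("n must be >= 50 for a plausible cohort")
  if (is.null(edgeCoefficients))
    edgeCoefficients <- setNames(referenceEstimates(model, cohort)$beta,
                                 referenceEstimates(model, cohort)$label)
  B <- coefficientMatrix(pm, edgeCoefficients)
  nodes <- nodeNames(pm)
  eff <- list(
    age = setNames(rep(0.10, length(nodes)), nodes),
    energy = setNames(rep(0.05, length(nodes)), nodes),
    carbohydrate = setNames(rep(0.05, length(nodes)), nodes),
    fat = setNames(rep(0.05, length(nodes)), nodes),
    protein = setNames(rep(0.05, length(nodes)), nodes),
    centre = c(0, 0.15, -0.15, 0.10),
    sex = setNames(rep(0.2, length(nodes)), nodes),
    treatment = setNames(rep(0, length(nodes)), nodes)
  )
  if (cohort == 2) eff$treatment[c("FG", "PG")] <- c(-0.3, -0.2)
  for (nm in names(confounderEffects)) {
    v <- confounderEffects[[nm]]
    if (nm == "centre") {
      eff$centre <- v
    } else if (length(v) == 1L && is.null(names(v))) {
      eff[[nm]][] <- v
    } else {
      eff[[nm]][names(v)] <- v
    }
  }
  structure(list(cohort = cohort, model = model, n = as.integer(n),
                 B = B, psi = unitVarianceDisturbances(B),
                 effects = eff, characteristics = chars,
                 seed = as.integer(seed)),
            class = "syntheticCohortSpec")
}

# Dietary intake scales used for the simulated covariates (means/SDs chosen
# as typical adult intakes; only their correlation structure matters to the
# analysis, which works on residuals).
.dietScales <- data.frame(
  var = c("energy", "carbohydrate", "fat", "protein"),
  mean = c(9000, 230, 85, 90),
  sd = c(2200, 70, 30, 25),
  unit = c("kJ/day", "g/day", "g/day", "g/day"),
  stringsAsFactors = FALSE
)

#' Attach confounders and raw scales to simulated node scores
#'
#' Draws age, sex, study centre (4 levels), treatment group (cohort 2) and
#' dietary intakes (energy plus macronutrients, correlated ~0.7 with
#' energy), adds the specified linear confounder contributions to each
#' node score, and rescales every node to its target marginal mean/SD so
#' the emitted table looks like measured data. Confounders are drawn
#' independently of the structural disturbances; confounding enters only
#' through the additive effects in the spec.
#'
#' @param scores data.frame of node scores from [simulateStructuralSystem()]
#' @param spec a [syntheticCohortSpec()]
#' @return participant data.frame: id, cohort, sex, age, centre, treatment,
#'   diet variables, and one raw-scale column per model node
#' @export
attachConfounders <- function(scores, spec) {
  stopifnot(inherits(spec, "syntheticCohortSpec"))
  n <- nrow(scores)
  nodes <- colnames(scores)
  chars <- spec$characteristics
  if (!all(is.finite(chars$vars$mean)) || !all(is.finite(chars$vars$sd)))
    stop("calibration targets must be finite")
  eff <- spec$effects

  ageZ <- rnorm(n)
  energyZ <- rnorm(n)
  mixDiet <- function() 0.7 * energyZ + sqrt(1 - 0.49) * rnorm(n)
  carbZ <- mixDiet(); fatZ <- mixDiet(); protZ <- mixDiet()
  sex <- sample(c("male", "female"), n, replace = TRUE,
                prob = c(chars$maleFraction, 1 - chars$maleFraction))
  centre <- factor(sample(paste0("C", seq_along(eff$centre)), n,
                          replace = TRUE))
  treatment <- if (spec$cohort == 2)
    sample(c("lifestyle", "metformin+lifestyle"), n, replace = TRUE)
  else rep("lifestyle", n)

  out <- data.frame(
    id = seq_len(n), cohort = spec$cohort, sex = sex,
    age = chars$age[1] + chars$age[2] * ageZ, centre = centre,
    treatment = treatment,
    energy = .dietScales$mean[1] + .dietScales$sd[1] * energyZ,
    carbohydrate = .dietScales$mean[2] + .dietScales$sd[2] * carbZ,
    fat = .dietScales$mean[3] + .dietScales$sd[3] * fatZ,
    protein = .dietScales$mean[4] + .dietScales$sd[4] * protZ,
    stringsAsFactors = FALSE
  )
  tgt <- chars$vars
  for (v in nodes) {
    z <- scores[[v]] +
      eff$age[v] * ageZ + eff$energy[v] * energyZ +
      eff$carbohydrate[v] * carbZ + eff$fat[v] * fatZ +
      eff$protein[v] * protZ +
      eff$centre[as.integer(centre)] +
      eff$sex[v] * (sex == "male") +
      eff$treatment[v] * (treatment == "metformin+lifestyle")
    m <- tgt$mean[tgt$node == v]; s <- tgt$sd[tgt$node == v]
    if (!length(m)) stop("no calibration target for node ", v)
    out[[v]] <- m + s * (z - mean(z)) / sd(z)
  }
  out
}

#' Generate a synthetic participant cohort
#'
#' Composition of [simulateStructuralSystem()] and [attachConfounders()]:
#' node scores follow the linear structural system of the chosen model with
#' the spec's generating coefficients (implied variances 1), confounder and
#' stratum effects are layered on top, and every node is put on its
#' measured scale. Deterministic given the spec's seed.
#'
#' @param spec a [syntheticCohortSpec()], or arguments forwarded to it
#' @param ... forwarded to [syntheticCohortSpec()] when \code{spec} is not
#'   already one
#' @return participant data.frame (see [attachConfounders()])
#' @examples
#' cohort <- generateCohort(syntheticCohortSpec(cohort = 1, n = 200,
#'                                              seed = 42))
#' head(cohort)
#' @export
generateCohort <- function(spec = syntheticCohortSpec(...), ...) {
  stopifnot(inherits(spec, "syntheticCohortSpec"))
  q <- freeParamCount(builtinModel(spec$model))
  if (spec$n <= q)
    warning("n = ", spec$n, " does not exceed the free parameter count (",
            q, ") of the ", spec$model, " model")
  .seededDraw(spec$seed, function() {
    scores <- simulateStructuralSystem(spec$B, spec$psi, spec$n)
    attachConfounders(scores, spec)
  })
}
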