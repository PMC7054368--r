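# Free-parameter layout shared by the objective, gradient and fit driver.
# theta = [edge coefficients (edge-table order), free disturbance variances
# (node order)]; fixed exogenous variances live in psiBase.
.paramLayout <- function(model, S) {
  nodes <- model@nodes
  p <- length(nodes)
  ed <- model@edges
  bRow <- match(ed$to, nodes) - 1L
  bCol <- match(ed$from, nodes) - 1L
  freePsiNodes <- if (model@fixedExogenous)
    setdiff(nodes, model@exogenous) else nodes
  psiIdx <- match(freePsiNodes, nodes) - 1L
  psiBase <- rep(0, p)
  if (model@fixedExogenous && length(model@exogenous))
    psiBase[match(model@exogenous, nodes)] <-
      diag(S)[match(model@exogenous, nodes)]
  list(p = p, nodes = nodes, bRow = bRow, bCol = bCol, psiIdx = psiIdx,
       psiBase = psiBase, nB = nrow(ed),
       paramNames = c(ed$label, paste0("psi_", freePsiNodes)))
}

#' Implied covariance of a linear structural system
#'
#' \eqn{\Sigma = (I - B)^{-1} \Psi (I - B)^{-T}} for a coefficient matrix B
#' (entry \code{[target, source]} per edge, zero elsewhere) and diagonal
#' disturbance covariance \eqn{\Psi}. Valid for cyclic (non-recursive)
#' systems whenever \eqn{I - B} is invertible.
#'
#' @param B square numeric matrix of path coefficients
#' @param psi vector of disturbance variances (diagonal of \eqn{\Psi})
#' @return symmetric implied covariance matrix
#' @examples
#' B <- matrix(0, 3, 3, dimnames = rep(list(c("x", "m", "y")), 2))
#' B["m", "x"] <- 0.5; B["y", "m"] <- 0.4
#' impliedCovarianceFrom(B, c(1, 1, 1))
#' @export
impliedCovarianceFrom <- function(B, psi) {
  stopifnot(is.matrix(B), nrow(B) == ncol(B), length(psi) == nrow(B))
  ImB <- diag(nrow(B)) - B
  if (abs(det(ImB)) < 1e-12 || !is.finite(rcond(ImB)) || rcond(ImB) < 1e-12)
    stop("structural system is singular: (I - B) is not invertible")
  A <- solve(ImB)
  Sigma <- A %*% diag(psi, nrow(B)) %*% t(A)
  Sigma <- (Sigma + t(Sigma)) / 2
  dimnames(Sigma) <- dimnames(B)
  Sigma
}

#' @rdname impliedCovariance
#' @export
setMethod("impliedCovariance", "SemFit", function(object) object@Sigma)

#' Maximum-likelihood discrepancy between two covariance matrices
#'
#' \eqn{F_{ML} = \ln|\Sigma| - \ln|S| + tr(S\Sigma^{-1}) - p}, the fitting
#' function minimised in ML covariance-structure estimation. Nonnegative,
#' and zero exactly when \eqn{\Sigma = S}.
#'
#' @param S sample covariance (positive definite)
#' @param Sigma implied covariance (positive definite, same order)
#' @return nonnegative scalar
#' @export
mlDiscrepancy <- function(S, Sigma) {
  stopifnot(is.matrix(S), is.matrix(Sigma), all(dim(S) == dim(Sigma)))
  p <- nrow(S)
  evS <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(evS) <= 0) stop("sample covariance S is not positive definite")
  cS <- chol(S)
  cSig <- tryCatch(chol(Sigma), error = function(e)
    stop("implied covariance Sigma is not positive definite"))
  logdetS <- 2 * sum(log(diag(cS)))
  logdetSig <- 2 * sum(log(diag(cSig)))
  logdetSig - logdetS + sum(diag(solve(Sigma, S))) - p
}

# Central-difference Hessian of F_ML from the analytic gradient.
.fmlHessian <- function(theta, S, lay, step = 1e-5) {
  q <- length(theta)
  H <- matrix(0, q, q)
  for (j in seq_len(q)) {
    h <- step * max(1, abs(theta[j]))
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    gp <- .semFmlGradCpp(tp, S, lay$bRow, lay$bCol, lay$psiIdx, lay$psiBase)
    gm <- .semFmlGradCpp(tm, S, lay$bRow, lay$bCol, lay$psiIdx, lay$psiBase)
    H[, j] <- (gp - gm) / (2 * h)
  }
  (H + t(H)) / 2
}

#' Fit a path model by maximum likelihood
#'
#' Minimises the ML discrepancy \eqn{F_{ML}(S, \Sigma(\theta))} over the
#' free path coefficients and disturbance variances by quasi-Newton
#' (L-BFGS-B with analytic gradient, disturbance variances bounded below),
#' followed by Newton polishing to drive the gradient norm down. Start
#' values are zero coefficients and half the sample variances; on
#' non-convergence up to \code{maxRestarts} seeded jittered restarts are
#' attempted. Standard errors come from the numerically differentiated
#' Hessian of \eqn{F_{ML}}: \eqn{ACOV = (2/(N-1)) H^{-1}},
#' \eqn{SE = \sqrt{diag(ACOV)}}, with two-sided normal Wald p-values
#' (no multiple-testing adjustment). The chi-square statistic is
#' \eqn{(N-1) F_{ML}} by default (\code{chisqScale = "N"} switches to
#' \eqn{N F_{ML}} for sensitivity checks).
#'
#' @param model a [PathModel-class]; cyclic systems are supported
#' @param data a [CovarianceInput-class] whose variables include every
#'   model node (matched by name, reordered as needed)
#' @param se compute the Hessian-based covariance and standard errors
#'   (disable for bulk refits such as the randomised null)
#' @param maxRestarts jittered restarts on non-convergence
#' @param restartSeed seed for the jitter stream
#' @param lowerPsi lower bound for disturbance variances
#' @param hessStep relative central-difference step
#' @param chisqScale \code{"N-1"} (Wishart likelihood, default) or \code{"N"}
#' @param control extra entries for [stats::optim()]'s control list
#' @return a [SemFit-class]
#' @examples
#' m <- builtinModel("TC")
#' truth <- referenceEstimates("TC", 1)
#' sim <- simulateStructuralSystem(coefficientMatrix(m, truth$beta),
#'                                 n = 500, seed = 7)
#' fit <- fitModel(m, covarianceInput(sim))
#' fit
#' @export
fitModel <- function(model, data, se = TRUE, maxRestarts = 10,
                     restartSeed = 1L, lowerPsi = 1e-6, hessStep = 1e-5,
                     chisqScale = c("N-1", "N"), control = list()) {
  stopifnot(is(model, "PathModel"), is(data, "CovarianceInput"))
  chisqScale <- match.arg(chisqScale)
  nodes <- model@nodes
  Sfull <- data@S
  missingVars <- setdiff(nodes, colnames(Sfull))
  if (length(missingVars))
    stop("covariance input lacks model variable(s): ",
         paste(missingVars, collapse = ", "))
  S <- Sfull[nodes, nodes]
  N <- data@N
  lay <- .paramLayout(model, S)
  df <- modelDF(model, p = lay$p)
  if (df < 0) stop("model has negative degrees of freedom (df = ", df, ")")
  logdetS <- 2 * sum(log(diag(chol(S))))

  fn <- function(th) .semFmlCpp(th, S, lay$bRow, lay$bCol, lay$psiIdx,
                                lay$psiBase, logdetS)
  gr <- function(th) .semFmlGradCpp(th, S, lay$bRow, lay$bCol, lay$psiIdx,
                                    lay$psiBase)
  nB <- lay$nB
  nPsi <- length(lay$psiIdx)
  lower <- c(rep(-Inf, nB), rep(lowerPsi, nPsi))
  start0 <- c(rep(0, nB), 0.5 * diag(S)[lay$psiIdx + 1L])
  ctrl <- utils::modifyList(
    list(maxit = 2000L, factr = 1e2, pgtol = 1e-12), control)

  best <- NULL
  evals <- 0L
  restarts <- 0L
  for (attempt in 0:maxRestarts) {
    start <- start0
    if (attempt > 0) {
      jit <- .seededDraw(restartSeed + attempt, function()
        c(runif(nB, -0.3, 0.3), runif(nPsi, 0.5, 1.5)))
      start <- c(start0[seq_len(nB)] + jit[seq_len(nB)],
                 pmax(lowerPsi * 10, start0[nB + seq_len(nPsi)] *
                        jit[nB + seq_len(nPsi)]))
      restarts <- attempt
    }
    opt <- tryCatch(
      optim(start, fn, gr, method = "L-BFGS-B", lower = lower, control = ctrl),
      error = function(e) NULL)
    if (is.null(opt)) next
    evals <- evals + opt$counts[1]
    # Newton polish: FD Hessian of the analytic gradient, projected steps
    th <- opt$par
    f <- fn(th)
    for (it in 1:25) {
      g <- gr(th)
      atBound <- th <= lower + 1e-12
      g[atBound & g > 0] <- 0  # active lower bounds
      if (max(abs(g)) < 1e-10) break
      H <- .fmlHessian(th, S, lay, step = hessStep)
      stepv <- tryCatch(solve(H, g), error = function(e) g)
      if (!all(is.finite(stepv))) stepv <- g
      ok <- FALSE
      for (sc in 2^-(0:12)) {
        cand <- pmax(lower, th - sc * stepv)
        fc <- fn(cand)
        if (is.finite(fc) && fc <= f + 1e-14) {
          th <- cand; f <- fc; ok <- TRUE; break
        }
      }
      evals <- evals + it
      if (!ok) break
    }
    g <- gr(th)
    g[th <= lower + 1e-12 & g > 0] <- 0
    gn <- max(abs(g))
    cand <- list(theta = th, fml = f, gradNorm = gn,
                 converged = is.finite(f) && f < 1e9 && gn < 1e-6)
    if (is.null(best) || cand$fml < best$fml) best <- cand
    if (best$converged) break
  }
  if (is.null(best))
    stop("optimisation failed on every start")
  if (!best$converged && best$fml >= 1e9)
    stop("model did not converge after ", maxRestarts,
         " restarts (best F_ML = ", format(best$fml), ")")

  th <- best$theta
  Sigma <- .semImpliedCpp(th, lay$p, lay$bRow, lay$bCol, lay$psiIdx,
                          lay$psiBase)
  dimnames(Sigma) <- dimnames(S)
  fml <- best$fml
  scaleN <- if (chisqScale == "N-1") N - 1 else N
  chisqVal <- max(0, scaleN * fml)

  psi <- lay$psiBase
  psi[lay$psiIdx + 1L] <- th[nB + seq_len(nPsi)]
  names(psi) <- nodes
  heywood <- any(th[nB + seq_len(nPsi)] <= lowerPsi * 1.0001)
  if (heywood)
    warning("Heywood case: a disturbance variance sits at its lower bound")

  q <- length(th)
  acov <- matrix(NA_real_, q, q)
  seVec <- rep(NA_real_, q)
  if (se) {
    H <- .fmlHessian(th, S, lay, step = hessStep)
    Hinv <- tryCatch(solve(H), error = function(e) {
      warning("Hessian singular; using pseudo-inverse for ACOV")
      MASS::ginv(H)
    })
    acov <- (2 / scaleN) * (Hinv + t(Hinv)) / 2
    dv <- diag(acov)
    seVec <- ifelse(dv > 0, sqrt(dv), NA_real_)
  }
  dimnames(acov) <- list(lay$paramNames, lay$paramNames)
  names(th) <- lay$paramNames

  sdImp <- sqrt(diag(Sigma))
  ed <- model@edges
  est <- th[seq_len(nB)]
  seE <- seVec[seq_len(nB)]
  z <- est / seE
  coefs <- data.frame(
    label = ed$label, from = ed$from, to = ed$to,
    estimate = unname(est), se = unname(seE), z = unname(z),
    p = unname(2 * pnorm(-abs(z))),
    std = unname(est * sdImp[ed$from] / sdImp[ed$to]),
    stringsAsFactors = FALSE
  )

  new("SemFit", model = model, input = data, coefficients = coefs,
      psi = psi, theta = th, acov = acov, Sigma = Sigma, fml = fml,
      chisq = chisqVal, df = as.numeric(df), converged = best$converged,
      gradNorm = best$gradNorm, iterations = as.numeric(evals),
      restarts = as.numeric(restarts), heywood = heywood)
}

# Run `draw()` under a temporary seed, restoring the caller's RNG state.
.seededDraw <- function(seed, draw) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  draw()
}

#' @rdname chisq
#' @export
setMethod("chisq", "SemFit", function(object) object@chisq)

#' @rdname modelDF
#' @export
setMethod("modelDF", "SemFit", function(object, ...) object@df)

#' @rdname coefTable
#' @export
setMethod("coefTable", "SemFit", function(object) object@coefficients)

#' @rdname paramCov
#' @export
setMethod("paramCov", "SemFit", function(object) object@acov)

#' @rdname standardizedSolution
#' @export
setMethod("standardizedSolution", "SemFit", function(object) {
  if (!object@converged) stop("fit did not converge; no standardized solution")
  if (any(diag(object@Sigma) <= 0))
    stop("zero implied variance; standardized solution undefined")
  object@coefficients[, c("label", "from", "to", "std")]
})

setMethod("show", "SemFit", function(object) {
  cat(sprintf(
    "SemFit: %d free parameters, N = %d\n  chi-square = %.3f on %d df (F_ML = %.5f)%s\n",
    length(object@theta), as.integer(object@input@N), object@chisq,
    as.integer(object@df), object@fml,
    if (object@converged) "" else "  [NOT CONVERGED]"))
  cf <- object@coefficients
  cat(sprintf("  %-6s %-3s -> %-3s %9s %8s %8s\n",
              "edge", "", "", "std beta", "SE", "p"))
  for (i in seq_len(nrow(cf)))
    cat(sprintf("  %-6s %-3s -> %-3s %9.3f %8.3f %8.3g\n",
                cf$label[i], cf$from[i], cf$to[i], cf$std[i], cf$se[i],
                cf$p[i]))
  invisible(object)
})

#' Coefficient matrix from a path model and per-edge values
#'
#' Builds the square B matrix (entry \code{[target, source]}) in the model's
#' node order from a vector of edge coefficients given in edge-table order
#' or named by edge label.
#'
#' @param model a [PathModel-class]
#' @param values numeric vector of edge coefficients
#' @return square matrix with node dimnames
#' @export
coefficientMatrix <- function(model, values) {
  ed <- model@edges
  if (!is.null(names(values))) values <- values[ed$label]
  stopifnot(length(values) == nrow(ed), !anyNA(values))
  p <- length(model@nodes)
  B <- matrix(0, p, p, dimnames = list(model@nodes, model@nodes))
  B[cbind(ed$to, ed$from)] <- values
  B
}

#' Export a fitted model as an effect-estimate table
#'
#' Writes the per-edge table in the conventional layout (outcome node,
#' parent node, edge label, standardized beta, SE, p).
#'
#' @param fit a [SemFit-class]
#' @param file optional CSV path
#' @return the data.frame, invisibly when \code{file} is given
#' @export
edgeEstimateTable <- function(fit, file = NULL) {
  cf <- coefTable(fit)
  out <- data.frame(outcome = cf$to, parent = cf$from, edge = cf$label,
                    beta = cf$std, se = cf$se, p = cf$p,
                    stringsAsFactors = FALSE)
  if (!is.null(file)) {
    write.csv(out, file, row.names = FALSE)
    return(invisible(out))
  }
  out
}
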