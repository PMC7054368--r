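#' Manifest-variable path model
#'
#' An S4 container for a directed path model over observed (manifest)
#' variables: named nodes, labelled directed edges, and the disturbance
#' convention. Directed cycles are permitted (the twin-cycle system contains
#' the feedback loop IS -> FI -> LF -> IS), so validity does not require
#' acyclicity; invertibility of (I - B) is checked at fit time instead.
#'
#' @slot nodes character vector of unique node names.
#' @slot exogenous character vector naming nodes with no inbound edges whose
#'   variance is an input to the system (e.g. \code{PA} in the TC-PA model).
#' @slot edges data.frame with columns \code{label}, \code{from}, \code{to};
#'   one row per directed edge \code{from -> to}.
#' @slot fixedExogenous logical; if \code{TRUE} (the fixed-x convention,
#'   the default) exogenous variances are fixed to their sample values
#'   rather than estimated.
#'
#' @seealso [builtinModel()], [parseModelSpec()], [pathModel()]
#' @export
setClass("PathModel",
  representation(
    nodes = "character",
    exogenous = "character",
    edges = "data.frame",
    fixedExogenous = "logical"
  )
)

setValidity("PathModel", function(object) {
  msg <- character()
  nd <- object@nodes
  ed <- object@edges
  if (anyDuplicated(nd)) msg <- c(msg, "node names must be unique")
  if (!all(c("label", "from", "to") %in% names(ed)))
    msg <- c(msg, "edges must have columns 'label', 'from', 'to'")
  else {
    unknown <- setdiff(unique(c(ed$from, ed$to)), nd)
    if (length(unknown))
      msg <- c(msg, paste0("edge references unknown node(s): ",
                           paste(unknown, collapse = ", ")))
    if (anyDuplicated(paste(ed$from, ed$to, sep = "->")))
      msg <- c(msg, "duplicate edge (same source and target declared twice)")
    if (anyDuplicated(ed$label)) msg <- c(msg, "edge labels must be unique")
    if (!all(object@exogenous %in% nd))
      msg <- c(msg, "exogenous nodes must be model nodes")
    bad_ex <- intersect(object@exogenous, ed$to)
    if (length(bad_ex))
      msg <- c(msg, paste0("exogenous node(s) are edge targets: ",
                           paste(bad_ex, collapse = ", ")))
    endo <- setdiff(nd, object@exogenous)
    orphan <- setdiff(endo, ed$to)
    if (length(orphan))
      msg <- c(msg, paste0("endogenous node(s) with no inbound edge: ",
                           paste(orphan, collapse = ", ")))
  }
  if (length(object@fixedExogenous) != 1L)
    msg <- c(msg, "fixedExogenous must be a single logical")
  if (length(msg)) msg else TRUE
})

#' Sample covariance input for model fitting
#'
#' Wraps a sample covariance matrix (denominator N - 1), the number of
#' complete cases it was computed from, and the variable order. Validity
#' requires symmetry and positive definiteness; the smallest eigenvalue is
#' reported when the check fails.
#'
#' @slot S symmetric positive-definite covariance matrix with dimnames.
#' @slot N number of complete cases used.
#'
#' @seealso [covarianceInput()]
#' @export
setClass("CovarianceInput",
  representation(S = "matrix", N = "numeric")
)

setValidity("CovarianceInput", function(object) {
  S <- object@S
  msg <- character()
  if (is.null(rownames(S)) || is.null(colnames(S)))
    msg <- c(msg, "S must have row and column names")
  if (!isTRUE(all.equal(S, t(S), tolerance = 1e-10, check.attributes = FALSE)))
    msg <- c(msg, "S must be symmetric")
  else {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      msg <- c(msg, sprintf(
        "S is not positive definite (smallest eigenvalue %.3e)", min(ev)))
  }
  if (length(object@N) != 1L || object@N < 2)
    msg <- c(msg, "N must be a single value >= 2")
  if (length(msg)) msg else TRUE
})

#' Fitted path model
#'
#' Result of maximum-likelihood estimation of a [PathModel-class] from a
#' [CovarianceInput-class]: free-parameter estimates, standard errors from
#' the numerically differentiated Hessian of the ML discrepancy, Wald tests,
#' the implied covariance, chi-square fit statistic, and the standardized
#' solution. Use the accessors ([coefTable()], [chisq()], [modelDF()],
#' [impliedCovariance()], [paramCov()]) rather than slots.
#'
#' @slot model the fitted [PathModel-class].
#' @slot input the [CovarianceInput-class] the model was fitted to.
#' @slot coefficients data.frame, one row per edge: \code{label},
#'   \code{from}, \code{to}, \code{estimate}, \code{se}, \code{z}, \code{p},
#'   \code{std} (standardized estimate).
#' @slot psi named numeric vector of disturbance/exogenous variances
#'   (fixed exogenous variances included, flagged via the model).
#' @slot theta free-parameter vector at the optimum (edges, then free psi).
#' @slot acov parameter covariance matrix, \eqn{(2/(N-1)) H^{-1}}.
#' @slot Sigma implied covariance at the optimum.
#' @slot fml ML discrepancy value at the optimum.
#' @slot chisq model chi-square, \eqn{(N-1) F_{ML}}.
#' @slot df model degrees of freedom.
#' @slot converged logical convergence flag.
#' @slot gradNorm max-norm of the gradient at the optimum.
#' @slot iterations objective evaluation count reported by the optimiser.
#' @slot restarts number of jittered restarts consumed.
#' @slot heywood TRUE when a disturbance variance sits at its lower bound.
#'
#' @export
setClass("SemFit",
  representation(
    model = "PathModel",
    input = "CovarianceInput",
    coefficients = "data.frame",
    psi = "numeric",
    theta = "numeric",
    acov = "matrix",
    Sigma = "matrix",
    fml = "numeric",
    chisq = "numeric",
    df = "numeric",
    converged = "logical",
    gradNorm = "numeric",
    iterations = "numeric",
    restarts = "numeric",
    heywood = "logical"
  )
)

#' Variable-randomised null distribution of model fit
#'
#' Chi-square values obtained by refitting the same model structure after
#' randomly reassigning the observed variables to its nodes, together with
#' the empirical p-value of the observed fit and a one-sample t test of
#' whether the null mean exceeds the observed chi-square.
#'
#' @slot chisq chi-square values of the converged null fits.
#' @slot attempted number of permutations attempted.
#' @slot convergedN number of null fits that converged (and were kept).
#' @slot seed RNG seed used.
#' @slot observed observed model chi-square.
#' @slot empiricalP add-one empirical p,
#'   \eqn{(1 + \#\{\chi^2_{null} \le \chi^2_{obs}\})/(n + 1)}.
#' @slot tStat one-sample t statistic (null mean vs observed).
#' @slot tP one-sided p-value (alternative: null mean greater).
#' @slot nullMean mean of the null chi-square values.
#'
#' @seealso [randomizedNullDistribution()], [summarizeNull()]
#' @export
setClass("NullDistribution",
  representation(
    chisq = "numeric",
    attempted = "numeric",
    convergedN = "numeric",
    seed = "numeric",
    observed = "numeric",
    empiricalP = "numeric",
    tStat = "numeric",
    tP = "numeric",
    nullMean = "numeric"
  )
)

#' Coefficient-product (indirect) pathway effect
#'
#' A single mediated pathway: the ordered nodes traversed, the product of
#' the fitted standardized edge coefficients along it, a delta-method
#' standard error from the joint parameter covariance of the path's edges,
#' and the Baron-Kenny eligibility status (every edge on the path must be
#' individually significant).
#'
#' @slot path ordered node names from source to sink.
#' @slot labels edge labels traversed.
#' @slot estimate product of standardized edge coefficients.
#' @slot se delta-method standard error.
#' @slot z Wald z.
#' @slot p two-sided normal p-value.
#' @slot eligible logical; TRUE when every edge on the path is significant.
#' @slot failingEdge label of the first non-significant edge (length 0 when
#'   eligible).
#'
#' @seealso [indirectEffect()], [eligiblePathways()], [mediationTable()]
#' @export
setClass("MediationEffect",
  representation(
    path = "character",
    labels = "character",
    estimate = "numeric",
    se = "numeric",
    z = "numeric",
    p = "numeric",
    eligible = "logical",
    failingEdge = "character"
  )
)
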