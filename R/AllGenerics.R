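#' @rdname PathModel-class
#' @param object,x a \code{PathModel}, \code{SemFit} or related object
#' @export
setGeneric("nodeNames", function(object) standardGeneric("nodeNames"))

#' @rdname PathModel-class
#' @export
setGeneric("edgeTable", function(object) standardGeneric("edgeTable"))

#' @rdname PathModel-class
#' @export
setGeneric("exogenousNodes", function(object) standardGeneric("exogenousNodes"))

#' Model degrees of freedom
#'
#' Degrees of freedom of a path model fitted to a p-variable covariance
#' matrix: \eqn{p(p+1)/2} non-redundant sample moments minus the free
#' parameters (edges plus free disturbance variances) minus, under the
#' fixed-x convention, one exactly reproduced moment per fixed exogenous
#' variance.
#'
#' @param object a [PathModel-class] or [SemFit-class]
#' @param ... for a \code{PathModel}, \code{p =} the number of observed
#'   variables (defaults to the number of nodes)
#' @return integer degrees of freedom
#' @export
setGeneric("modelDF", function(object, ...) standardGeneric("modelDF"))

#' @rdname modelDF
#' @export
setGeneric("freeParamCount", function(object, ...) standardGeneric("freeParamCount"))

#' Model chi-square statistic
#' @param object a [SemFit-class]
#' @return \eqn{(N-1) F_{ML}} at the optimum
#' @export
setGeneric("chisq", function(object) standardGeneric("chisq"))

#' Edge coefficient table of a fitted model
#' @param object a [SemFit-class]
#' @return data.frame with columns label, from, to, estimate, se, z, p, std
#' @export
setGeneric("coefTable", function(object) standardGeneric("coefTable"))

#' Parameter covariance matrix of a fitted model
#' @param object a [SemFit-class]
#' @return the asymptotic covariance of the free parameters
#' @export
setGeneric("paramCov", function(object) standardGeneric("paramCov"))

#' Model-implied covariance matrix
#'
#' For a fitted model, \eqn{\Sigma(\hat\theta) = (I-B)^{-1}\Psi(I-B)^{-T}}
#' evaluated at the estimates; also available directly from a coefficient
#' matrix and disturbance variances via the function form.
#'
#' @param object a [SemFit-class] (method form), or see
#'   [impliedCovarianceFrom()] for the (B, psi) form
#' @export
setGeneric("impliedCovariance", function(object) standardGeneric("impliedCovariance"))

#' Standardized solution of a fitted model
#'
#' Standardized coefficient of edge e: raw estimate times the ratio of
#' implied standard deviations, \eqn{\hat\beta_e \,\hat\sigma_{source} /
#' \hat\sigma_{target}}, with \eqn{\hat\sigma} from the diagonal of the
#' implied covariance. Invariant to rescaling any observed variable by a
#' positive constant.
#'
#' @param object a converged [SemFit-class]
#' @return data.frame label, from, to, std
#' @export
setGeneric("standardizedSolution", function(object) standardGeneric("standardizedSolution"))
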