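#' Independence (baseline) model fit
#'
#' The null model against which CFI and TLI are computed: all covariances
#' zero, variances free, so \eqn{\Sigma_B = diag(S)} and
#' \eqn{\chi^2_B = (N-1) F_{ML}(S, diag(S))} on \eqn{df_B = p(p-1)/2}.
#'
#' @param data a [CovarianceInput-class]
#' @return list with \code{chisq} and \code{df}
#' @export
baselineModelFit <- function(data) {
  stopifnot(is(data, "CovarianceInput"))
  S <- data@S
  p <- ncol(S)
  if (p < 2) stop("baseline model needs at least 2 variables")
  f <- mlDiscrepancy(S, diag(diag(S), p))
  list(chisq = (data@N - 1) * f, df = p * (p - 1) / 2)
}

#' Relative and absolute fit indices
#'
#' CFI and TLI against the independence baseline, and RMSEA:
#' \deqn{CFI = 1 - \frac{\max(\chi^2_M - df_M, 0)}
#'                     {\max(\chi^2_B - df_B,\; \chi^2_M - df_M,\; 0)}}
#' \deqn{TLI = \frac{\chi^2_B/df_B - \chi^2_M/df_M}{\chi^2_B/df_B - 1}}
#' \deqn{RMSEA = \sqrt{\max(\chi^2_M - df_M, 0) / (df_M (N-1))}}
#' These are reported alongside the chi-square but the package's formal fit
#' test is the variable-randomised null ([randomizedNullDistribution()]);
#' index cut-offs are sensitive to df, model complexity and sample size.
#'
#' @param fit a [SemFit-class] with positive degrees of freedom
#' @param baseline optional list(chisq, df); computed from the fit's own
#'   covariance input when omitted
#' @return list: cfi, tli, rmsea, baselineChisq, baselineDF
#' @export
computeFitIndices <- function(fit, baseline = NULL) {
  stopifnot(is(fit, "SemFit"))
  if (fit@df <= 0)
    stop("fit indices undefined for saturated models (df = 0)")
  if (is.null(baseline)) baseline <- baselineModelFit(fit@input)
  chiM <- fit@chisq; dfM <- fit@df
  chiB <- baseline$chisq; dfB <- baseline$df
  N <- fit@input@N
  num <- max(chiM - dfM, 0)
  den <- max(chiB - dfB, chiM - dfM, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  tli <- ((chiB / dfB) - (chiM / dfM)) / ((chiB / dfB) - 1)
  rmsea <- sqrt(max(chiM - dfM, 0) / (dfM * (N - 1)))
  list(cfi = cfi, tli = tli, rmsea = rmsea,
       baselineChisq = chiB, baselineDF = dfB)
}
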