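#' Stratified rank-based inverse normal transformation
#'
#' Within each stratum, values are replaced by normal quantiles of their
#' offset-adjusted ranks: \eqn{\Phi^{-1}((r - c)/(n - 2c + 1))} with average
#' ranks for ties and the Blom offset \eqn{c = 3/8} by default. The result
#' has mean approximately 0 and SD approximately 1 within each stratum and
#' is monotone in the source variable. Missing inputs map to missing
#' outputs; they do not contribute to ranks.
#'
#' @param values numeric vector
#' @param strata optional factor/vector of stratum labels (e.g. sex, or
#'   sex x treatment group); \code{NULL} for a single stratum
#' @param offset rank offset \eqn{c \in [0, 0.5]}; 3/8 is the Blom
#'   convention
#' @return numeric vector of normal scores, same length and order
#' @examples
#' rankInverseNormal(c(3.1, 1.2, 2.0))
#' @export
rankInverseNormal <- function(values, strata = NULL, offset = 0.375) {
  stopifnot(is.numeric(values), offset >= 0, offset <= 0.5)
  if (is.null(strata)) strata <- rep("all", length(values))
  if (length(strata) != length(values))
    stop("strata must match values in length")
  out <- rep(NA_real_, length(values))
  for (s in unique(strata[!is.na(strata)])) {
    idx <- which(strata == s & !is.na(values))
    n <- length(idx)
    if (n < 2)
      stop("stratum '", s, "' has fewer than 2 non-missing values")
    v <- values[idx]
    if (max(v) == min(v))
      stop("stratum '", s, "' is constant; rank-normal scores undefined")
    r <- rank(v, ties.method = "average")
    out[idx] <- qnorm((r - offset) / (n - 2 * offset + 1))
  }
  out
}

#' Two-step residual regression
#'
#' First step of the confounder-adjustment procedure: for each target
#' variable (already rank-normal transformed), extract residuals from an
#' ordinary least-squares general linear model on the covariates (age,
#' study centre, total energy intake and macronutrient intakes in the
#' canonical analysis). The residuals are then used downstream as outcome
#' and predictor variables. Categorical covariates are dummy-coded against
#' their first level; collinear design columns are dropped with a message
#' before fitting, and a design that remains rank-deficient is an error.
#'
#' @param table data.frame of participants
#' @param targets character vector of target column names (numeric)
#' @param covariates character vector of covariate column names; factors and
#'   character columns are treated as categorical
#' @return data.frame of residuals, one column per target, same row count
#'   as \code{table} (rows with any missing target/covariate get NA)
#' @export
residualize <- function(table, targets, covariates) {
  stopifnot(all(targets %in% names(table)), all(covariates %in% names(table)))
  covs <- table[, covariates, drop = FALSE]
  for (nm in names(covs))
    if (is.character(covs[[nm]]) || is.logical(covs[[nm]]))
      covs[[nm]] <- factor(covs[[nm]])
  ok <- complete.cases(covs)
  X <- model.matrix(~ ., data = covs[ok, , drop = FALSE])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[-qrX$pivot[seq_len(qrX$rank)]]
    message("dropping collinear design column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(X)
    if (qrX$rank < ncol(X))
      stop("design matrix rank-deficient after dropping: ",
           paste(dropped, collapse = ", "))
  }
  if (sum(ok) <= ncol(X))
    stop("too few complete rows (", sum(ok), ") for ", ncol(X),
         " design columns")
  res <- as.data.frame(
    setNames(replicate(length(targets), rep(NA_real_, nrow(table)),
                       simplify = FALSE), targets))
  for (tg in targets) {
    y <- table[[tg]]
    use <- ok & !is.na(y)
    Xi <- model.matrix(~ ., data = covs[use, , drop = FALSE])
    Xi <- Xi[, colnames(X), drop = FALSE]
    fit <- lm.fit(Xi, y[use])
    res[[tg]][use] <- fit$residuals
  }
  res
}

#' Pairwise Pearson correlation matrix
#'
#' Pearson correlations on pairwise-complete rows, as plotted in the
#' exploratory correlation matrix that precedes model fitting. A constant
#' column yields \code{NA} (undefined), never 0.
#'
#' @param table data.frame of numeric columns
#' @return symmetric correlation matrix with unit diagonal
#' @export
pairwiseCorrelations <- function(table) {
  m <- as.matrix(table)
  stopifnot(is.numeric(m))
  r <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  diag(r) <- ifelse(apply(m, 2, function(x) {
    x <- x[!is.na(x)]
    length(x) >= 2 && max(x) > min(x)
  }), 1, NA_real_)
  r[!is.finite(r)] <- NA_real_
  diag(r)[!is.na(diag(r))] <- 1
  r
}

#' Build the covariance input for model fitting
#'
#' Listwise deletion across the named variables, then the sample covariance
#' with denominator N - 1. The number of complete cases actually used is
#' recorded; positive definiteness is enforced (the smallest eigenvalue is
#' reported on failure).
#'
#' @param table data.frame containing the model variables
#' @param variables ordered character vector of column names (the node
#'   order of the model to be fitted)
#' @return a [CovarianceInput-class]
#' @export
covarianceInput <- function(table, variables = colnames(table)) {
  stopifnot(all(variables %in% names(table)))
  d <- table[, variables, drop = FALSE]
  d <- d[complete.cases(d), , drop = FALSE]
  N <- nrow(d)
  p <- length(variables)
  if (N < p + 1)
    stop("need at least p + 1 = ", p + 1, " complete cases; have ", N)
  S <- cov(as.matrix(d))  # denominator N - 1
  S <- (S + t(S)) / 2
  new("CovarianceInput", S = S, N = N)
}

#' @rdname CovarianceInput-class
#' @param object a \code{CovarianceInput}
#' @export
setGeneric("sampleCov", function(object) standardGeneric("sampleCov"))

#' @rdname CovarianceInput-class
#' @export
setGeneric("sampleSize", function(object) standardGeneric("sampleSize"))

#' @rdname CovarianceInput-class
#' @export
setMethod("sampleCov", "CovarianceInput", function(object) object@S)

#' @rdname CovarianceInput-class
#' @export
setMethod("sampleSize", "CovarianceInput", function(object) object@N)

setMethod("show", "CovarianceInput", function(object) {
  cat(sprintf("CovarianceInput: %d variables, N = %d complete cases\n",
              ncol(object@S), object@N))
  cat("  variables:", paste(colnames(object@S), collapse = ", "), "\n")
  invisible(object)
})

#' Preprocess a participant table into analysis-ready scores
#'
#' The full preprocessing contract: each model variable is rank-inverse-
#' normal transformed within strata (sex; or sex x treatment group), then
#' residualised on the covariates by [residualize()]. Residuals are not
#' re-standardised; the standardized SEM solution handles scale.
#'
#' @param table participant data.frame
#' @param variables model variable column names
#' @param strata character vector of stratification column names (e.g.
#'   \code{c("sex")} or \code{c("sex", "treatment")}); \code{NULL} for none
#' @param covariates covariate column names for residualisation
#' @param offset rank offset for [rankInverseNormal()]
#' @return data.frame of residualised normal scores, one column per variable
#' @export
preprocessCohort <- function(table, variables, strata = "sex",
                             covariates = c("age", "centre", "energy",
                                            "carbohydrate", "fat", "protein"),
                             offset = 0.375) {
  stratLab <- if (is.null(strata)) NULL else
    interaction(table[, strata, drop = FALSE], drop = TRUE)
  tr <- table
  for (v in variables)
    tr[[v]] <- rankInverseNormal(table[[v]], stratLab, offset = offset)
  residualize(tr, variables, covariates)
}
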