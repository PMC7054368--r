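#' Partition candidate pathways by Baron-Kenny eligibility
#'
#' A pathway is tested only when a statistically significant direct
#' association is observed for every edge along it (two-sided Wald
#' \code{p < alpha} on the individual, non-mediated edge estimates).
#' Ineligible paths carry the label of the first failing edge.
#'
#' @param fit a [SemFit-class]
#' @param paths list of paths as returned by [enumerateDirectedPaths()]
#' @param alpha per-edge significance level (default 0.05, two-sided,
#'   unadjusted)
#' @return list with elements \code{eligible} (list of paths) and
#'   \code{ineligible} (list of \code{list(path, failingEdge)})
#' @export
eligiblePathways <- function(fit, paths, alpha = 0.05) {
  stopifnot(is(fit, "SemFit"))
  cf <- coefTable(fit)
  elig <- list(); inelig <- list()
  for (pp in paths) {
    labs <- .pathEdgeLabels(fit@model, pp)
    idx <- match(labs, cf$label)
    if (anyNA(idx))
      stop("path references edge(s) absent from the fitted model: ",
           paste(labs[is.na(idx)], collapse = ", "))
    fail <- which(!(cf$p[idx] < alpha))
    if (length(fail)) {
      inelig[[length(inelig) + 1L]] <-
        list(path = pp, failingEdge = labs[fail[1]])
    } else {
      elig[[length(elig) + 1L]] <- pp
    }
  }
  list(eligible = elig, ineligible = inelig)
}

# Resolve a path (list(nodes, labels) or plain node vector) to edge labels.
.pathEdgeLabels <- function(model, path) {
  nodes <- if (is.list(path)) path$nodes else path
  if (length(nodes) < 2) stop("a path needs at least 2 nodes")
  labs <- character(length(nodes) - 1)
  for (i in seq_along(labs)) {
    labs[i] <- .edgeLabel(model, nodes[i], nodes[i + 1])
    if (is.na(labs[i]))
      stop("no edge ", nodes[i], " -> ", nodes[i + 1], " in the model")
  }
  labs
}

#' Coefficient-product (indirect) effect along a pathway
#'
#' The indirect effect of the path's source on its sink is the product of
#' the fitted standardized coefficients of the traversed edges. Its
#' standard error is obtained by the multivariate delta method using the
#' joint parameter covariance of those edges: with gradient
#' \eqn{g_i = \prod_{j \ne i} \beta_j}, \eqn{Var = g^T ACOV_{path} g}. The
#' Sobel independence approximation (dropping the covariance terms) is
#' available for comparison. Wald z and a two-sided normal p complete the
#' summary.
#'
#' @param fit a converged [SemFit-class] with standard errors
#' @param path a path from [enumerateDirectedPaths()], or a character vector
#'   of node names
#' @param alpha eligibility level passed to the Baron-Kenny screen
#' @param force compute the effect even for an ineligible path
#' @param method \code{"delta"} (joint covariance, default) or
#'   \code{"sobel"}
#' @return a [MediationEffect-class]
#' @export
indirectEffect <- function(fit, path, alpha = 0.05, force = FALSE,
                           method = c("delta", "sobel")) {
  stopifnot(is(fit, "SemFit"))
  method <- match.arg(method)
  if (!fit@converged || anyNA(diag(fit@acov)))
    stop("indirect effects need a converged fit with parameter covariance")
  nodes <- if (is.list(path)) path$nodes else path
  labs <- .pathEdgeLabels(fit@model, path)
  cf <- coefTable(fit)
  idx <- match(labs, cf$label)

  part <- eligiblePathways(fit, list(list(nodes = nodes)), alpha = alpha)
  eligible <- length(part$eligible) == 1L
  failing <- if (eligible) character(0) else part$ineligible[[1]]$failingEdge
  if (!eligible && !force)
    stop("path ", paste(nodes, collapse = "->"),
         " is ineligible (failing edge: ", failing,
         "); use force = TRUE to compute anyway")

  beta <- cf$std[idx]
  est <- prod(beta)
  # gradient of the product w.r.t. each coefficient
  g <- vapply(seq_along(beta), function(i) prod(beta[-i]), numeric(1))
  AC <- fit@acov[labs, labs, drop = FALSE]
  if (method == "sobel") AC <- diag(diag(AC), length(labs))
  v <- drop(t(g) %*% AC %*% g)
  seV <- if (v >= 0) sqrt(v) else NA_real_
  z <- est / seV
  new("MediationEffect", path = nodes, labels = labs, estimate = est,
      se = seV, z = z, p = 2 * pnorm(-abs(z)), eligible = eligible,
      failingEdge = failing)
}

setMethod("show", "MediationEffect", function(object) {
  cat(sprintf("MediationEffect: %s\n  beta = %.4f, SE = %.4f, z = %.2f, p = %.3g%s\n",
              paste(object@path, collapse = " -> "), object@estimate,
              object@se, object@z, object@p,
              if (object@eligible) "" else
                paste0("  [ineligible: ", object@failingEdge, "]")))
  invisible(object)
})

#' Pathway (mediation) effect table
#'
#' Enumerates all simple directed paths from \code{source} to each sink,
#' applies the Baron-Kenny eligibility screen, and computes the
#' coefficient-product effect with delta-method SE for the eligible ones.
#' The default arguments reproduce the canonical analysis: physical
#' activity's indirect effects on fasting and 2 h glucose.
#'
#' @param fit a converged [SemFit-class]
#' @param source source node (default \code{"PA"})
#' @param sinks sink nodes (default \code{c("FG", "PG")})
#' @param alpha eligibility level
#' @param maxLength maximum nodes per path
#' @param includeDirect include the length-2 "path" that is just the direct
#'   edge (default FALSE: mediated paths only must pass through >= 1
#'   intermediate node)
#' @return data.frame: outcome, path, beta, se, z, p, eligible, failingEdge
#' @export
mediationTable <- function(fit, source = "PA", sinks = c("FG", "PG"),
                           alpha = 0.05, maxLength = Inf,
                           includeDirect = FALSE) {
  rows <- list()
  for (sink in sinks) {
    paths <- enumerateDirectedPaths(fit@model, source, sink, maxLength)
    if (!includeDirect)
      paths <- Filter(function(p) length(p$nodes) > 2, paths)
    for (pp in paths) {
      part <- eligiblePathways(fit, list(pp), alpha = alpha)
      if (length(part$eligible)) {
        me <- indirectEffect(fit, pp, alpha = alpha)
        rows[[length(rows) + 1L]] <- data.frame(
          outcome = sink, path = paste(pp$nodes, collapse = "->"),
          beta = me@estimate, se = me@se, z = me@z, p = me@p,
          eligible = TRUE, failingEdge = NA_character_,
          stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          outcome = sink, path = paste(pp$nodes, collapse = "->"),
          beta = NA_real_, se = NA_real_, z = NA_real_, p = NA_real_,
          eligible = FALSE,
          failingEdge = part$ineligible[[1]]$failingEdge,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(outcome = character(), path = character(),
                      beta = numeric(), se = numeric(), z = numeric(),
                      p = numeric(), eligible = logical(),
                      failingEdge = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
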