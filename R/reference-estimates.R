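#' Reference standardized edge estimates for the twin-cycle models
#'
#' Curated standardized path coefficients (beta), standard errors and
#' p-values for the TC and TC-PA models as estimated in two multicentre
#' European cohorts: cohort 1, adults without diabetes at varying risk of
#' glycaemic deterioration (n = 920 for TC, 725 for TC-PA complete cases);
#' cohort 2, adults with recently diagnosed type 2 diabetes (n = 435 / 361).
#' These serve two purposes: default generating coefficients for
#' [generateCohort()], and inputs for worked examples such as checking that
#' reported pathway (mediation) effects equal the product of their edge
#' coefficients.
#'
#' p-values reported as "< 0.001" are stored as 1e-4; the one coefficient
#' reported only as "< 0.01" (gs1, cohort 2, TC model) is stored as 0.005.
#' Values are printed to two decimals, so derived products carry rounding
#' of that order.
#'
#' @param model \code{"TC"} or \code{"TC-PA"}
#' @param cohort 1 (no diabetes/prediabetes) or 2 (diabetes)
#' @return data.frame: label, from, to, beta, se, p
#' @examples
#' referenceEstimates("TC-PA", cohort = 1)
#' @export
referenceEstimates <- function(model = c("TC-PA", "TC"), cohort = 1) {
  key <- toupper(gsub("[^A-Za-z]", "", model[1]))
  stopifnot(cohort %in% c(1, 2))
  if (key == "TC") {
    ed <- .tcEdges()
    if (cohort == 1) {
      beta <- c(is1 = -0.23, lf1 = 0.41, fi1 = -0.06, fi2 = -0.70,
                fg1 = -0.67, fg2 = -0.26, tg1 = -0.31, tg2 = 0.22,
                pf1 = 0.14, gs1 = -0.05, gs2 = -0.21, pg1 = -0.58,
                pg2 = -0.17)
      se <- c(is1 = 0.04, lf1 = 0.04, fi1 = 0.03, fi2 = 0.03, fg1 = 0.03,
              fg2 = 0.03, tg1 = 0.03, tg2 = 0.03, pf1 = 0.03, gs1 = 0.04,
              gs2 = 0.03, pg1 = 0.03, pg2 = 0.03)
      p <- c(is1 = 1e-4, lf1 = 1e-4, fi1 = 0.05, fi2 = 1e-4, fg1 = 1e-4,
             fg2 = 1e-4, tg1 = 1e-4, tg2 = 1e-4, pf1 = 1e-4, gs1 = 0.185,
             gs2 = 1e-4, pg1 = 1e-4, pg2 = 1e-4)
    } else {
      beta <- c(is1 = -0.11, lf1 = 0.44, fi1 = -0.25, fi2 = -0.70,
                fg1 = -0.73, fg2 = -0.31, tg1 = -0.34, tg2 = 0.13,
                pf1 = 0.01, gs1 = 0.005, gs2 = 0.02, pg1 = -0.67,
                pg2 = -0.38)
      se <- c(is1 = 0.06, lf1 = 0.05, fi1 = 0.06, fi2 = 0.06, fg1 = 0.03,
              fg2 = 0.03, tg1 = 0.05, tg2 = 0.05, pf1 = 0.05, gs1 = 0.05,
              gs2 = 0.05, pg1 = 0.03, pg2 = 0.03)
      p <- c(is1 = 0.09, lf1 = 1e-4, fi1 = 1e-4, fi2 = 1e-4, fg1 = 1e-4,
             fg2 = 1e-4, tg1 = 1e-4, tg2 = 0.006, pf1 = 0.886, gs1 = 0.967,
             gs2 = 0.63, pg1 = 1e-4, pg2 = 1e-4)
    }
  } else if (key == "TCPA") {
    ed <- .tcpaEdges()
    if (cohort == 1) {
      beta <- c(is1 = -0.20, lf1 = 0.41, fi1 = -0.04, fi2 = -0.64,
                fg1 = -0.70, fg2 = -0.26, tg1 = -0.26, tg2 = 0.22,
                pf1 = 0.14, gs1 = -0.05, gs2 = -0.18, pg1 = -0.56,
                pg2 = -0.17, is2 = 0.30, lf2 = -0.04, fi3 = -0.12,
                fg3 = 0.11, tg3 = -0.13, pf2 = -0.06, gs3 = -0.05,
                pg3 = -0.04)
      se <- c(is1 = 0.04, lf1 = 0.04, fi1 = 0.03, fi2 = 0.04, fg1 = 0.03,
              fg2 = 0.03, tg1 = 0.04, tg2 = 0.04, pf1 = 0.03, gs1 = 0.05,
              gs2 = 0.04, pg1 = 0.03, pg2 = 0.03, is2 = 0.04, lf2 = 0.04,
              fi3 = 0.03, fg3 = 0.03, tg3 = 0.04, pf2 = 0.03, gs3 = 0.04,
              pg3 = 0.03)
      p <- c(is1 = 1e-4, lf1 = 1e-4, fi1 = 0.265, fi2 = 1e-4, fg1 = 1e-4,
             fg2 = 1e-4, tg1 = 1e-4, tg2 = 1e-4, pf1 = 1e-4, gs1 = 0.314,
             gs2 = 1e-4, pg1 = 1e-4, pg2 = 1e-4, is2 = 1e-4, lf2 = 0.234,
             fi3 = 1e-4, fg3 = 0.001, tg3 = 1e-4, pf2 = 0.067, gs3 = 0.212,
             pg3 = 0.194)
    } else {
      beta <- c(is1 = -0.12, lf1 = 0.44, fi1 = -0.23, fi2 = -0.64,
                fg1 = -0.73, fg2 = -0.28, tg1 = -0.30, tg2 = 0.16,
                pf1 = -0.01, gs1 = 0.01, gs2 = 0.02, pg1 = -0.67,
                pg2 = -0.39, is2 = 0.21, lf2 = -0.04, fi3 = -0.16,
                fg3 = 0.06, tg3 = -0.13, pf2 = -0.01, gs3 = -0.12,
                pg3 = -0.05)
      se <- c(is1 = 0.07, lf1 = 0.05, fi1 = 0.07, fi2 = 0.07, fg1 = 0.03,
              fg2 = 0.03, tg1 = 0.05, tg2 = 0.05, pf1 = 0.05, gs1 = 0.05,
              gs2 = 0.05, pg1 = 0.03, pg2 = 0.03, is2 = 0.05, lf2 = 0.05,
              fi3 = 0.05, fg3 = 0.03, tg3 = 0.05, pf2 = 0.06, gs3 = 0.06,
              pg3 = 0.04)
      p <- c(is1 = 0.065, lf1 = 1e-4, fi1 = 1e-4, fi2 = 1e-4, fg1 = 1e-4,
             fg2 = 1e-4, tg1 = 1e-4, tg2 = 0.002, pf1 = 0.819, gs1 = 0.835,
             gs2 = 0.696, pg1 = 1e-4, pg2 = 1e-4, is2 = 1e-4, lf2 = 0.447,
             fi3 = 0.001, fg3 = 0.061, tg3 = 0.012, pf2 = 0.809, gs3 = 0.032,
             pg3 = 0.162)
    }
  } else stop("unknown model '", model[1], "'")
  data.frame(ed, beta = unname(beta[ed$label]), se = unname(se[ed$label]),
             p = unname(p[ed$label]), stringsAsFactors = FALSE)
}

#' Reference pathway (mediation) effect estimates
#'
#' The reported indirect effects of physical activity on fasting (FG) and
#' 2 h (PG) glucose through the twin-cycle variables in the TC-PA model, on
#' the standardized scale, per cohort. Pathways were only reported where
#' every direct edge along them was individually significant at
#' \code{alpha = 0.05}, which is why each cohort carries a different subset.
#'
#' @param cohort 1 or 2
#' @return data.frame: outcome, path (arrow-joined node names), beta, se, p
#' @export
referencePathwayEstimates <- function(cohort = 1) {
  stopifnot(cohort %in% c(1, 2))
  if (cohort == 1) {
    data.frame(
      outcome = c("FG", "PG", "FG", "PG", "FG", "PG"),
      path = c("PA->IS->FG", "PA->IS->PG", "PA->IS->GS->FG",
               "PA->IS->GS->PG", "PA->FI->LF->IS->FG",
               "PA->FI->LF->IS->PG"),
      beta = c(-0.212, -0.171, 0.015, 0.009, -0.007, -0.006),
      se = c(0.026, 0.022, 0.004, 0.003, 0.002, 0.002),
      p = c(1e-4, 1e-4, 1e-4, 0.001, 0.002, 0.002),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      outcome = c("FG", "PG", "FG", "PG"),
      path = c("PA->IS->FG", "PA->IS->PG", "PA->GS->FG", "PA->GS->PG"),
      beta = c(-0.153, -0.140, 0.033, 0.045),
      se = c(0.039, 0.036, 0.016, 0.022),
      p = c(1e-4, 1e-4, 0.037, 0.04),
      stringsAsFactors = FALSE
    )
  }
}

#' Reference cohort characteristics (marginal means and SDs)
#'
#' Marginal mean (SD) of each model variable in the complete-case subsets of
#' the two cohorts, used by the synthetic generator to put node scores back
#' on their measured scales. Physical activity intensity (mean high-pass
#' filtered vector magnitude, milli-g) was not tabulated with the other
#' characteristics; the generator uses mean 30, SD 10 mg, typical of
#' wrist-worn accelerometry in adults of this age.
#'
#' @param cohort 1 or 2
#' @param model \code{"TC"} or \code{"TC-PA"} complete-case subset
#' @return list with \code{n}, \code{maleFraction}, \code{age} (mean, sd)
#'   and \code{vars}, a data.frame of node, mean, sd, unit
#' @export
referenceCharacteristics <- function(cohort = 1, model = "TC-PA") {
  key <- toupper(gsub("[^A-Za-z]", "", model))
  stopifnot(cohort %in% c(1, 2), key %in% c("TC", "TCPA"))
  node <- c("FG", "PG", "TG", "FI", "GS", "IS", "LF", "PF", "PA")
  unit <- c("mmol/l", "mmol/l", "mmol/l", "pmol/min/m2",
            "pmol/min/m2 per mmol/l", "ml/min/m2", "%", "%", "mg")
  if (cohort == 1 && key == "TC") {
    n <- 920; male <- 0.83; age <- c(60.6, 6.3)
    mean_ <- c(5.8, 6.0, 1.4, 105, 107, 374, 5.0, 13.5, 30)
    sd_ <- c(0.5, 1.7, 0.6, 40, 50, 56, 4.7, 9.0, 10)
  } else if (cohort == 1) {
    n <- 725; male <- 0.83; age <- c(60.6, 6.3)
    mean_ <- c(5.8, 6.0, 1.4, 106, 107, 374, 5.0, 13.6, 30)
    sd_ <- c(0.5, 1.7, 0.7, 41, 50, 56, 4.7, 9.1, 10)
  } else if (key == "TC") {
    n <- 435; male <- 0.57; age <- c(61.5, 8.3)
    mean_ <- c(7.0, 8.6, 1.5, 134, 85, 302, 8.6, 11.2, 30)
    sd_ <- c(1.5, 2.9, 0.9, 49, 54, 71, 7.2, 7.2, 10)
  } else {
    n <- 361; male <- 0.60; age <- c(61.7, 8.4)
    mean_ <- c(7.0, 8.5, 1.5, 136, 89, 302, 8.9, 11.7, 30)
    sd_ <- c(1.4, 2.8, 0.9, 50, 56, 70, 7.4, 6.9, 10)
  }
  list(n = n, maleFraction = male, age = age,
       vars = data.frame(node = node, mean = mean_, sd = sd_, unit = unit,
                         stringsAsFactors = FALSE))
}
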