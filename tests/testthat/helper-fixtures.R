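# Shared fixtures: small models and random inputs built in code.

chainModel <- function() {
  pathModel(data.frame(label = c("b1", "b2"),
                       from = c("x", "m"),
                       to = c("m", "y")))
}

# Random correlation-like PD matrix via a random factor loading structure.
randomPDMatrix <- function(p, seed) {
  set.seed(seed)
  L <- matrix(rnorm(p * p), p, p)
  S <- crossprod(L) / p + diag(p) * 0.5
  dimnames(S) <- list(paste0("v", seq_len(p)), paste0("v", seq_len(p)))
  S
}

# Random recursive (acyclic) model on p nodes: edges only i -> j for i < j,
# each non-root node guaranteed at least one parent.
randomRecursiveModel <- function(p, seed, prob = 0.6) {
  set.seed(seed)
  from <- character(); to <- character()
  for (j in 2:p) {
    parents <- which(runif(j - 1) < prob)
    if (!length(parents)) parents <- sample.int(j - 1, 1)
    from <- c(from, paste0("v", parents))
    to <- c(to, rep(paste0("v", j), length(parents)))
  }
  ed <- data.frame(label = paste0("e", seq_along(from)), from = from,
                   to = to, stringsAsFactors = FALSE)
  pathModel(ed, nodes = paste0("v", seq_len(p)), fixedExogenous = TRUE)
}

# Equation-wise least squares on moments: the independent oracle for ML
# estimation in recursive models with uncorrelated disturbances.
olsOnMoments <- function(model, S) {
  ed <- edgeTable(model)
  est <- setNames(numeric(nrow(ed)), ed$label)
  for (v in unique(ed$to)) {
    pa <- ed$from[ed$to == v]
    b <- solve(S[pa, pa, drop = FALSE], S[pa, v])
    est[ed$label[ed$to == v]] <- b
  }
  est
}

# Covariance input straight from a matrix (bypasses the data path).
asCovInput <- function(S, N) {
  methods::new("CovarianceInput", S = S, N = N)
}

# A SemFit assembled from the reference (published-scale) TC-PA estimates:
# coefficient table and a diagonal parameter covariance from the reported
# SEs. Implied covariance is set to the identity so standardized and raw
# coefficients coincide, mirroring the standardized reporting scale.
referenceFit <- function(cohort = 1) {
  m <- builtinModel("TC-PA")
  est <- referenceEstimates("TC-PA", cohort)
  p <- length(nodeNames(m))
  Sigma <- diag(p)
  dimnames(Sigma) <- list(nodeNames(m), nodeNames(m))
  psiN <- setdiff(nodeNames(m), "PA")
  nm <- c(est$label, paste0("psi_", psiN))
  acov <- diag(c(est$se^2, rep(1e-4, length(psiN))))
  dimnames(acov) <- list(nm, nm)
  theta <- setNames(c(est$beta, rep(0.5, length(psiN))), nm)
  cf <- data.frame(label = est$label, from = est$from, to = est$to,
                   estimate = est$beta, se = est$se, z = est$beta / est$se,
                   p = est$p, std = est$beta, stringsAsFactors = FALSE)
  methods::new("SemFit", model = m, input = asCovInput(Sigma, 725),
               coefficients = cf,
               psi = setNames(rep(1, p), nodeNames(m)), theta = theta,
               acov = acov, Sigma = Sigma, fml = 0.1, chisq = 72.4,
               df = 15, converged = TRUE, gradNorm = 0, iterations = 1,
               restarts = 0, heywood = FALSE)
}
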