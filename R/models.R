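# ---------------------------------------------------------------------------
# Gaussian likelihood machinery for trait evolution on a phylogeny.
#
# Every model here (BM, BMS, EB, OU1, OUM, OUMV, OUMA, OUMVA) is a Gaussian
# process whose per-branch transition is known in closed form, so the tip
# distribution has an explicit mean vector and covariance matrix. Both are
# assembled by one numerically stable preorder recursion:
#
#   B(node)   = integral of alpha from the root to the node (along its path)
#   Vn(child) = e^{-2 a dt} Vn(parent) + sigma2 * (1 - e^{-2 a dt}) / (2 a)
#   Cov(i,j)  = exp(2 B(mrca) - B(i) - B(j)) * Vn(mrca)
#
# with a, sigma2 the (regime-dependent) parameters of each branch; every
# exponent is <= 0, so nothing overflows even for very large alpha. The tip
# expectation is a convex combination of the root state and the regime optima
# with exponentially discounted residence weights (the Hansen construction);
# the weights of each tip sum to one.
# ---------------------------------------------------------------------------

MODEL_NAMES <- c("BM", "BMS", "EB", "OU1", "OUM", "OUMV", "OUMA", "OUMVA")

# one-off per-tree structure reused across likelihood evaluations
treePrecompute <- function(tree) {
  n <- length(tree$tip.label)
  ne <- nrow(tree$edge)
  preord <- reorderEdgesPreorder(tree)
  depths <- nodeDepths(tree)
  # root->tip edge paths
  edgeToChild <- integer(n + tree$Nnode)
  edgeToChild[tree$edge[, 2]] <- seq_len(ne)
  parentOf <- integer(n + tree$Nnode)
  parentOf[tree$edge[, 2]] <- tree$edge[, 1]
  root <- n + 1L
  tipPaths <- vector("list", n)
  for (i in seq_len(n)) {
    path <- integer()
    node <- i
    while (node != root) {
      path <- c(path, edgeToChild[node])
      node <- parentOf[node]
    }
    tipPaths[[i]] <- path  # tip -> root order
  }
  mrcaMat <- ape::mrca(tree)
  diag(mrcaMat) <- seq_len(n)
  list(tree = tree, n = n, ne = ne, preord = preord, depths = depths,
       edgeParent = tree$edge[, 1], edgeChild = tree$edge[, 2],
       edgeLen = tree$edge.length, root = root, tipPaths = tipPaths,
       mrcaMat = mrcaMat, tipLabels = tree$tip.label)
}

# expm1(a*dt)/a with a -> 0 limit; used for positive-exponent integrals
posExpIntegral <- function(a, dt) {
  ifelse(abs(a * dt) < 1e-12, dt, expm1(a * dt) / a)
}

# Mean design and covariance for arbitrary per-edge alpha/sigma2.
# alphaEdge, sigma2Edge: per-edge vectors; catEdge: per-edge category used to
# group the theta design columns; ebR non-zero selects the early-burst
# time-varying rate (alpha must then be zero).
# Returns list(W = n x ncat theta design, w0 = root weight, V = n x n).
meanCovStructure <- function(pre, alphaEdge, sigma2Edge, catEdge,
                             ebR = 0) {
  n <- pre$n
  nNodes <- n + pre$tree$Nnode
  B <- numeric(nNodes)
  Vn <- numeric(nNodes)
  for (e in pre$preord) {
    p <- pre$edgeParent[e]; ch <- pre$edgeChild[e]
    dt <- pre$edgeLen[e]; a <- alphaEdge[e]
    B[ch] <- B[p] + a * dt
    if (ebR != 0) {
      inc <- sigma2Edge[e] * exp(ebR * pre$depths[p]) * posExpIntegral(ebR, dt)
    } else {
      inc <- sigma2Edge[e] * expIntegral(2 * a, dt)
    }
    Vn[ch] <- exp(-2 * a * dt) * Vn[p] + inc
  }
  Btips <- B[seq_len(n)]
  m <- pre$mrcaMat
  V <- exp(2 * B[m] - outer(Btips, Btips, "+")) * Vn[m]
  cats <- sort(unique(catEdge))
  W <- matrix(0, n, length(cats), dimnames = list(pre$tipLabels, cats))
  w0 <- numeric(n)
  for (i in seq_len(n)) {
    A <- 0
    for (e in pre$tipPaths[[i]]) {   # tip -> root
      Ap <- A + alphaEdge[e] * pre$edgeLen[e]
      W[i, catEdge[e]] <- W[i, catEdge[e]] + (exp(-A) - exp(-Ap))
      A <- Ap
    }
    w0[i] <- exp(-A)
  }
  list(W = W, w0 = w0, V = V)
}

# whitened GLS under covariance V (or V = sigma2 * V0 when scale = TRUE)
glsFit <- function(V0, X, y, scale = TRUE) {
  L <- tryCatch(chol(V0), error = function(e) NULL)
  if (is.null(L)) return(NULL)
  ty <- backsolve(L, y, transpose = TRUE)
  tX <- backsolve(L, X, transpose = TRUE)
  XtX <- crossprod(tX)
  XtXinv <- tryCatch(chol2inv(chol(XtX)), error = function(e) NULL)
  if (is.null(XtXinv)) return(NULL)
  beta <- drop(XtXinv %*% crossprod(tX, ty))
  names(beta) <- colnames(X)
  resid <- ty - drop(tX %*% beta)
  Q <- sum(resid^2)
  logdet <- 2 * sum(log(diag(L)))
  nobs <- length(y)
  if (scale) {
    s2 <- Q / nobs
    if (s2 <= 0) s2 <- .Machine$double.xmin
    ll <- -0.5 * (nobs * log(2 * pi) + nobs * log(s2) + logdet + nobs)
    covBeta <- s2 * XtXinv
  } else {
    s2 <- NA_real_
    ll <- -0.5 * (nobs * log(2 * pi) + logdet + Q)
    covBeta <- XtXinv
  }
  list(beta = beta, covBeta = covBeta, Q = Q, logdet = logdet,
       logLik = ll, sigma2hat = s2)
}

# per-edge parameter expansion from named per-regime values
expandEdgeParam <- function(value, catEdge) {
  if (length(value) == 1L && is.null(names(value)))
    return(rep(unname(value), length(catEdge)))
  out <- unname(value[catEdge])
  if (anyNA(out)) stop("parameter missing for some regime")
  out
}

# categories per edge (regime of an edge = regime of its child node)
edgeCategories <- function(pre, scheme) {
  if (is.null(scheme)) return(rep("1", pre$ne))
  cat <- schemeNodeCategories(scheme, pre$tree)
  cat[pre$edgeChild]
}

#' Exact log-likelihood of a trait-evolution model
#'
#' Evaluates the Gaussian log-likelihood of tip data under BM, BMS, EB, OU1
#' or a multi-optimum Ornstein-Uhlenbeck (Hansen) model at the supplied
#' parameter values. Each tip's expectation under an OU model is a convex
#' combination of the root state and the regime optima, weighted by
#' exponentially discounted residence times along its root path; covariances
#' follow the shared-time/patristic-separation closed form generalised to
#' per-regime parameters.
#'
#' @param model One of `"BM"`, `"BMS"`, `"EB"`, `"OU1"`, `"OUM"`, `"OUMV"`,
#'   `"OUMA"`, `"OUMVA"`.
#' @param tree A valid [ape::phylo]; OU variants require an ultrametric tree.
#' @param traits A [traitTable] covering all tips (or a named numeric vector).
#' @param scheme A painted [regimeScheme]; required for BMS and multi-regime
#'   OU models.
#' @param params List with elements among `sigma2` (scalar or named per
#'   regime), `alpha` (scalar or named; must be > 0 for OU models), `theta`
#'   (named per regime, or scalar for OU1), `z0` (root state; used by
#'   BM/BMS/EB and by `rootMode = "estimated"`), `r` (EB decay, <= 0).
#' @param rootMode `"stationary"` (root state equals the optimum of the root
#'   regime; default) or `"estimated"` (`params$z0` is the root state).
#' @param log Model the log of the trait values.
#' @return The log-likelihood (a single number).
#' @export
ouLoglik <- function(model, tree, traits, scheme = NULL, params,
                     rootMode = c("stationary", "estimated"), log = FALSE) {
  model <- match.arg(model, MODEL_NAMES)
  rootMode <- match.arg(rootMode)
  y <- if (inherits(traits, "traitTable")) traitVector(tree, traits, log)
       else traits[tree$tip.label]
  if (anyNA(y)) stop("tips without trait data")
  if (any(!is.finite(unlist(params)))) stop("non-finite parameters")
  pre <- treePrecompute(tree)
  needScheme <- model %in% c("BMS", "OUM", "OUMV", "OUMA", "OUMVA")
  if (needScheme && is.null(scheme)) stop(model, " requires a regime scheme")
  isOU <- model %in% c("OU1", "OUM", "OUMV", "OUMA", "OUMVA")
  if (isOU) {
    if (any(unlist(params$alpha) <= 0))
      stop("alpha must be > 0 for OU models; use BM for alpha = 0")
    if (!checkUltrametric(tree)$ultrametric)
      stop("OU models require an ultrametric (dated) tree")
    if (is.null(params$theta)) stop("OU models require theta")
  }
  catEdge <- edgeCategories(pre, if (needScheme || isOU) scheme else NULL)
  alphaEdge <- if (isOU) expandEdgeParam(params$alpha, catEdge)
               else rep(0, pre$ne)
  sigma2Edge <- expandEdgeParam(params$sigma2, catEdge)
  if (any(sigma2Edge < 0)) stop("sigma2 must be >= 0")
  st <- meanCovStructure(pre, alphaEdge, sigma2Edge, catEdge,
                         ebR = if (model == "EB") params$r else 0)
  if (isOU) {
    theta <- params$theta
    if (length(theta) == 1L && is.null(names(theta)))
      theta <- stats::setNames(rep(theta, ncol(st$W)), colnames(st$W))
    mu <- drop(st$W %*% theta[colnames(st$W)])
    if (rootMode == "stationary") {
      rootCat <- if (is.null(scheme)) colnames(st$W)[1] else
        schemeNodeCategories(scheme, tree)[pre$root]
      mu <- mu + st$w0 * theta[rootCat]
    } else {
      if (is.null(params$z0)) stop("rootMode='estimated' requires z0")
      mu <- mu + st$w0 * params$z0
    }
  } else {
    if (is.null(params$z0)) stop(model, " requires a root state z0")
    mu <- rep(params$z0, pre$n)
  }
  L <- tryCatch(chol(st$V), error = function(e) NULL)
  if (is.null(L))
    stop("singular model covariance (zero-length terminal branches?)")
  r <- backsolve(L, y - mu, transpose = TRUE)
  -0.5 * (pre$n * log(2 * pi) + 2 * sum(log(diag(L))) + sum(r^2))
}

# implicit one-regime scheme used by OU1 without an explicit scheme
singleRegimeScheme <- function(tree) {
  n <- length(tree$tip.label)
  regimeScheme("three_cat",
               stats::setNames(rep("M", n), tree$tip.label),
               nodes = stats::setNames(rep("M", tree$Nnode),
                                       as.character((n + 1L):(n + tree$Nnode))),
               categories = c("S", "M", "L"))
}

# number of free parameters per model (stationary-root convention)
modelParamCount <- function(model, nRegimes, rootMode = "stationary") {
  k <- switch(model,
    BM = 2, BMS = nRegimes + 1, EB = 3, OU1 = 3,
    OUM = 2 + nRegimes, OUMV = 1 + 2 * nRegimes,
    OUMA = 1 + 2 * nRegimes, OUMVA = 3 * nRegimes)
  if (rootMode == "estimated" && model %in% c("OU1", "OUM", "OUMV", "OUMA",
                                              "OUMVA")) k <- k + 1
  k
}

#' Fit a trait-evolution model by maximum likelihood
#'
#' Fits BM, BMS, EB, OU1 or a multi-optimum (Hansen) OU variant by bounded
#' multi-start local optimisation. Nuisance structure is profiled wherever
#' the model allows it: optima/root are always generalised-least-squares
#' estimates given the covariance shape, and a single sigma^2 is profiled as
#' a scale parameter (BM, EB, OU1, OUM, OUMA). Remaining free parameters are
#' optimised over Latin-hypercube restarts within bounds. Optimum standard
#' errors come from the conditional GLS covariance at the optimum.
#'
#' @inheritParams ouLoglik
#' @param restarts Number of multi-start points for models with a
#'   multi-dimensional free parameter (default 10).
#' @param seed Seed controlling the restart points (fits are deterministic
#'   given the seed).
#' @param bounds List with elements `alpha`, `sigma2`, `r` giving
#'   `c(lower, upper)` search bounds.
#' @return A `modelFit` object: estimates, log-likelihood, parameter count,
#'   AICc and optimiser diagnostics.
#' @export
fitModel <- function(model, tree, traits, scheme = NULL, log = FALSE,
                     rootMode = c("stationary", "estimated"), restarts = 10,
                     seed = 1,
                     bounds = list(alpha = c(1e-6, 100),
                                   sigma2 = c(1e-8, 1e6),
                                   r = c(-10, 0))) {
  model <- match.arg(model, MODEL_NAMES)
  rootMode <- match.arg(rootMode)
  validatePhylogeny(tree)
  y <- traitVector(tree, traits, log)
  n <- length(y)
  pre <- treePrecompute(tree)
  needScheme <- model %in% c("BMS", "OUM", "OUMV", "OUMA", "OUMVA")
  if (needScheme && is.null(scheme)) stop(model, " requires a regime scheme")
  isOU <- model %in% c("OU1", "OUM", "OUMV", "OUMA", "OUMVA")
  if (isOU && !checkUltrametric(tree)$ultrametric)
    stop("OU models require an ultrametric (dated) tree")
  schemeUsed <- if (needScheme) scheme else if (isOU)
    singleRegimeScheme(tree) else scheme
  catEdge <- edgeCategories(pre, if (needScheme || isOU) schemeUsed else NULL)
  cats <- sort(unique(catEdge))
  m <- length(cats)
  rootCat <- if (needScheme || isOU)
    schemeNodeCategories(schemeUsed, tree)[pre$root] else NULL
  k <- modelParamCount(model, m, rootMode)
  fp <- dataFingerprint(tree, y)

  degenerate <- stats::sd(y) < .Machine$double.eps^0.5
  if (degenerate) {
    fit <- list(model = model, n = n, k = k, logLik = NA_real_,
                AICc = NA_real_, sigma2 = bounds$sigma2[1], alpha = NULL,
                theta = NULL, thetaSE = NULL, z0 = y[1], r = NULL,
                scheme = schemeUsed$id, rootMode = rootMode,
                logTransform = log, fingerprint = fp,
                diagnostics = list(convergence = FALSE, degenerate = TRUE,
                                   boundary = TRUE, restarts = 0))
    class(fit) <- "modelFit"
    return(fit)
  }

  # design for the mean given a per-edge alpha configuration
  designFor <- function(st) {
    if (!isOU) return(matrix(1, n, 1, dimnames = list(NULL, "z0")))
    X <- st$W
    if (rootMode == "stationary") {
      X[, rootCat] <- X[, rootCat] + st$w0
      X
    } else cbind(X, z0 = st$w0)
  }

  # profile log-likelihood evaluators -------------------------------------
  evalScale <- function(alphaByCat, ebR = 0) {
    alphaEdge <- expandEdgeParam(alphaByCat, catEdge)
    st <- meanCovStructure(pre, alphaEdge, rep(1, pre$ne), catEdge, ebR = ebR)
    g <- glsFit(st$V, designFor(st), y, scale = TRUE)
    if (is.null(g)) return(NULL)
    c(g, list(st = st))
  }
  evalAbs <- function(alphaByCat, sigma2ByCat) {
    alphaEdge <- expandEdgeParam(alphaByCat, catEdge)
    sigma2Edge <- expandEdgeParam(sigma2ByCat, catEdge)
    st <- meanCovStructure(pre, alphaEdge, sigma2Edge, catEdge)
    g <- glsFit(st$V, designFor(st), y, scale = FALSE)
    if (is.null(g)) return(NULL)
    c(g, list(st = st))
  }

  diag0 <- list(convergence = TRUE, degenerate = FALSE, boundary = FALSE,
                restarts = 0)
  est <- NULL

  if (model == "BM") {
    g <- evalScale(0)
    est <- list(logLik = g$logLik, sigma2 = g$sigma2hat, z0 = unname(g$beta),
                z0SE = sqrt(diag(as.matrix(g$covBeta))), diagnostics = diag0)
  } else if (model == "EB") {
    prof <- function(r) {
      g <- evalScale(0, ebR = r)
      if (is.null(g)) -Inf else g$logLik
    }
    opt <- gridOptimize(prof, bounds$r, nGrid = 15)
    g <- evalScale(0, ebR = opt$par)
    bdry <- min(abs(opt$par - bounds$r)) < 1e-6 * diff(range(bounds$r))
    est <- list(logLik = g$logLik, sigma2 = g$sigma2hat, r = opt$par,
                z0 = unname(g$beta),
                diagnostics = modifyList(diag0, list(boundary = bdry)))
  } else if (model %in% c("OU1", "OUM")) {
    la <- log(bounds$alpha)
    prof <- function(l) {
      g <- evalScale(exp(l))
      if (is.null(g)) -Inf else g$logLik
    }
    opt <- gridOptimize(prof, la, nGrid = 20)
    alphaHat <- exp(opt$par)
    g <- evalScale(alphaHat)
    theta <- g$beta
    se <- sqrt(diag(as.matrix(g$covBeta)))
    bdry <- min(abs(opt$par - la)) < 1e-6 * diff(range(la))
    est <- list(logLik = g$logLik, sigma2 = g$sigma2hat, alpha = alphaHat,
                theta = thetaVec(theta, se, rootMode),
                thetaSE = thetaSEVec(theta, se, rootMode),
                z0 = if (rootMode == "estimated") unname(theta["z0"]) else NULL,
                diagnostics = modifyList(diag0, list(boundary = bdry)))
  } else {
    # multi-dimensional free parameter: BMS, OUMV, OUMA, OUMVA
    spec <- multiParSpec(model, m, cats, bounds)
    objective <- function(p) {
      pars <- spec$unpack(p)
      g <- if (spec$scale) evalScale(pars$alpha) else
        evalAbs(pars$alpha, pars$sigma2)
      if (is.null(g) || !is.finite(g$logLik)) 1e10 else -g$logLik
    }
    set.seed(deriveSeed(seed, paste0("fit-", model)))
    nPar <- length(spec$lower)
    starts <- spec$lower + lhs::randomLHS(max(restarts, 2), nPar) *
      rep(spec$upper - spec$lower, each = max(restarts, 2))
    best <- NULL
    conv <- FALSE
    for (s in seq_len(nrow(starts))) {
      o <- tryCatch(
        stats::optim(starts[s, ], objective, method = "L-BFGS-B",
                     lower = spec$lower, upper = spec$upper,
                     control = list(maxit = 500)),
        error = function(e) NULL)
      if (is.null(o)) next
      if (is.null(best) || o$value < best$value) best <- o
      if (o$convergence == 0) conv <- TRUE
    }
    if (is.null(best)) stop("optimizer failed from every restart")
    pars <- spec$unpack(best$par)
    g <- if (spec$scale) evalScale(pars$alpha) else
      evalAbs(pars$alpha, pars$sigma2)
    theta <- g$beta
    se <- sqrt(diag(as.matrix(g$covBeta)))
    atB <- any(abs(best$par - spec$lower) < 1e-6) ||
      any(abs(best$par - spec$upper) < 1e-6)
    sigma2Out <- if (spec$scale) g$sigma2hat else pars$sigma2
    # rates at the lower bound are reported as zero with a boundary flag
    if (!spec$scale) {
      low <- abs(base::log(sigma2Out) - base::log(bounds$sigma2[1])) < 1e-6
      if (any(low)) { sigma2Out[low] <- 0; atB <- TRUE }
    }
    est <- list(logLik = g$logLik, sigma2 = sigma2Out,
                alpha = if (model %in% c("OUMA", "OUMVA")) pars$alpha
                        else if (model == "OUMV") unname(pars$alpha[1]) else NULL,
                theta = if (isOU) thetaVec(theta, se, rootMode) else NULL,
                thetaSE = if (isOU) thetaSEVec(theta, se, rootMode) else NULL,
                z0 = if (!isOU) unname(theta) else
                  if (rootMode == "estimated") unname(theta["z0"]) else NULL,
                diagnostics = modifyList(diag0,
                  list(convergence = conv, boundary = atB,
                       restarts = nrow(starts))))
  }

  fit <- list(model = model, n = n, k = k, logLik = est$logLik,
              AICc = if (n > k + 1) aicc(est$logLik, k, n) else NA_real_,
              sigma2 = est$sigma2, alpha = est$alpha, theta = est$theta,
              thetaSE = est$thetaSE, z0 = est$z0, r = est$r,
              scheme = if (is.null(scheme)) NULL else scheme$id,
              rootMode = rootMode, logTransform = log, fingerprint = fp,
              diagnostics = est$diagnostics)
  class(fit) <- "modelFit"
  fit
}

thetaVec <- function(beta, se, rootMode) {
  b <- beta[setdiff(names(beta), "z0")]
  b
}
thetaSEVec <- function(beta, se, rootMode) {
  names(se) <- names(beta)
  se[setdiff(names(beta), "z0")]
}

# free-parameter layout for the multi-start models (log scale throughout)
multiParSpec <- function(model, m, cats, bounds) {
  ls2 <- log(bounds$sigma2); la <- log(bounds$alpha)
  named <- function(v) stats::setNames(v, cats)
  switch(model,
    BMS = list(scale = FALSE,
               lower = rep(ls2[1], m), upper = rep(ls2[2], m),
               unpack = function(p) list(alpha = 0,
                                         sigma2 = named(exp(p)))),
    OUMV = list(scale = FALSE,
                lower = c(la[1], rep(ls2[1], m)),
                upper = c(la[2], rep(ls2[2], m)),
                unpack = function(p) list(alpha = exp(p[1]),
                                          sigma2 = named(exp(p[-1])))),
    OUMA = list(scale = TRUE,
                lower = rep(la[1], m), upper = rep(la[2], m),
                unpack = function(p) list(alpha = named(exp(p)),
                                          sigma2 = 1)),
    OUMVA = list(scale = FALSE,
                 lower = c(rep(la[1], m), rep(ls2[1], m)),
                 upper = c(rep(la[2], m), rep(ls2[2], m)),
                 unpack = function(p) list(alpha = named(exp(p[seq_len(m)])),
                                           sigma2 = named(exp(p[-seq_len(m)])))))
}

# deterministic 1-D optimisation: coarse grid then local refinement around
# the best bracket (OU profile likelihoods can be multimodal in alpha)
gridOptimize <- function(f, bounds, nGrid = 20) {
  xs <- seq(bounds[1], bounds[2], length.out = nGrid)
  vals <- vapply(xs, f, 0)
  i <- which.max(vals)
  lo <- xs[max(1, i - 1)]; hi <- xs[min(nGrid, i + 1)]
  o <- stats::optimize(f, c(lo, hi), maximum = TRUE,
                       tol = .Machine$double.eps^0.4)
  if (o$objective >= vals[i]) list(par = o$maximum, value = o$objective)
  else list(par = xs[i], value = vals[i])
}

#' @export
print.modelFit <- function(x, ...) {
  cat("Model fit:", x$model,
      if (!is.null(x$scheme)) paste0("(scheme ", x$scheme, ")"), "\n")
  cat(sprintf("  logLik %.4f  k %d  n %d  AICc %.4f\n",
              x$logLik, x$k, x$n, x$AICc))
  if (!is.null(x$sigma2))
    cat("  sigma2:", paste(formatC(x$sigma2, digits = 4), collapse = ", "), "\n")
  if (!is.null(x$alpha))
    cat("  alpha: ", paste(formatC(x$alpha, digits = 4), collapse = ", "), "\n")
  if (!is.null(x$theta)) {
    th <- paste0(names(x$theta), " = ", formatC(x$theta, digits = 4),
                 " (", formatC(x$thetaSE, digits = 3), ")")
    cat("  theta: ", paste(th, collapse = ", "), "\n")
  }
  if (!is.null(x$z0)) cat("  z0:    ", formatC(x$z0, digits = 4), "\n")
  if (!is.null(x$r)) cat("  EB r:  ", formatC(x$r, digits = 4), "\n")
  d <- x$diagnostics
  if (d$degenerate) cat("  [degenerate input: constant trait]\n")
  if (d$boundary) cat("  [a parameter sits at a search bound]\n")
  if (!d$convergence) cat("  [optimizer did not report convergence]\n")
  invisible(x)
}

#' Compare fitted models with AICc and Akaike weights
#'
#' @param fits Either a list of `modelFit` objects fitted to identical data,
#'   or a data.frame with columns `model`, `logLik`, `k` (printed values may
#'   be compared this way).
#' @param n Number of tips; required for the data.frame form.
#' @return A `modelComparison` data.frame with `model`, `logLik`, `k`,
#'   `AICc`, `dAICc` and `weight` (weights sum to one).
#' @export
compareFits <- function(fits, n = NULL) {
  if (is.data.frame(fits)) {
    if (is.null(n)) stop("n is required when comparing printed values")
    tab <- data.frame(model = fits$model, logLik = fits$logLik, k = fits$k,
                      AICc = aicc(fits$logLik, fits$k, n))
    attr(tab, "fits") <- NULL
  } else {
    stopifnot(all(vapply(fits, inherits, TRUE, "modelFit")))
    fps <- vapply(fits, function(f) f$fingerprint, "")
    if (length(unique(fps)) != 1L)
      stop("fits were not produced on identical data")
    tab <- data.frame(model = vapply(fits, function(f) f$model, ""),
                      logLik = vapply(fits, function(f) f$logLik, 0),
                      k = vapply(fits, function(f) as.numeric(f$k), 0),
                      AICc = vapply(fits, function(f) f$AICc, 0))
    attr(tab, "fits") <- fits
  }
  tab$dAICc <- tab$AICc - min(tab$AICc)
  w <- exp(-tab$dAICc / 2)
  tab$weight <- w / sum(w)
  class(tab) <- c("modelComparison", "data.frame")
  tab
}

#' @export
print.modelComparison <- function(x, ...) {
  cat(formatComparison(x), sep = "\n")
  invisible(x)
}

#' Format a model comparison as a publication-style text block
#'
#' Rows: log_L, AICc, sigma^2, alpha and one optimum row per category.
#'
#' @param cmp A `modelComparison`.
#' @return Character vector of lines.
#' @export
formatComparison <- function(cmp) {
  fits <- attr(cmp, "fits")
  header <- paste(c(sprintf("%-12s", ""), sprintf("%12s", cmp$model)),
                  collapse = "")
  rows <- list(
    log_L = sprintf("%12.2f", cmp$logLik),
    AICc = sprintf("%12.2f", cmp$AICc),
    weight = sprintf("%12.3f", cmp$weight))
  if (!is.null(fits)) {
    fmt <- function(get) vapply(fits, function(f) {
      v <- get(f)
      if (is.null(v) || all(is.na(v))) sprintf("%12s", "")
      else sprintf("%12s", paste(formatC(v, format = "f", digits = 2),
                                 collapse = ","))
    }, "")
    rows$sigma2 <- fmt(function(f) f$sigma2)
    rows$alpha <- fmt(function(f) f$alpha)
    allCats <- unique(unlist(lapply(fits, function(f) names(f$theta))))
    for (cc in allCats) {
      rows[[paste0("theta_", cc)]] <- vapply(fits, function(f) {
        if (is.null(f$theta) || !cc %in% names(f$theta))
          return(sprintf("%12s", ""))
        sprintf("%12s", sprintf("%.1f (%.1f)", f$theta[cc], f$thetaSE[cc]))
      }, "")
    }
    rows$z0 <- fmt(function(f) f$z0)
  }
  c(header, vapply(names(rows), function(r)
    paste(c(sprintf("%-12s", r), rows[[r]]), collapse = ""), ""))
}

#' @rdname formatComparison
#' @param file CSV path.
#' @export
writeComparison <- function(cmp, file) {
  utils::write.csv(as.data.frame(cmp), file, row.names = FALSE)
  txt <- sub("\\.csv$", ".txt", file)
  if (txt == file) txt <- paste0(file, ".txt")
  writeLines(formatComparison(cmp), txt)
  invisible(file)
}

#' Random-regime (OU3r) null distribution
#'
#' Refits the multi-optimum OU model under `nReps` randomized regime schemes
#' and records each AICc, quantifying how much of the observed fit is
#' explained by the regime hypothesis rather than by the extra parameters.
#'
#' @param tree Working tree.
#' @param traits A [traitTable].
#' @param scheme A painted three-category [regimeScheme] (the observed
#'   hypothesis).
#' @param nReps Number of randomized replicates.
#' @param seed Master seed (per-replicate seeds are derived from it).
#' @param mode Randomization mode, `"permute"` (default) or `"uniform"`.
#' @param log Model log trait values.
#' @return A `regimeNull` object: `observedAICc`, `aiccDist`, `exceedance`
#'   (replicates with AICc <= observed) and per-replicate failures.
#' @export
randomRegimeNull <- function(tree, traits, scheme, nReps, seed = 1,
                             mode = c("permute", "uniform"), log = FALSE) {
  mode <- match.arg(mode)
  if ("I" %in% scheme$categories)
    stop("the randomized null is defined for three-category schemes")
  obs <- fitModel("OUM", tree, traits, scheme, log = log, seed = seed)
  dist <- rep(NA_real_, nReps)
  failures <- character()
  for (i in seq_len(nReps)) {
    rs <- randomizeRegimes(scheme, mode, seed = deriveSeed(seed, i))
    f <- tryCatch(fitModel("OUM", tree, traits, rs, log = log,
                           seed = deriveSeed(seed, i + 10^6)),
                  error = function(e) e)
    if (inherits(f, "error")) {
      failures <- c(failures, paste0("rep ", i, ": ", conditionMessage(f)))
    } else dist[i] <- f$AICc
  }
  out <- list(observedAICc = obs$AICc, aiccDist = dist,
              exceedance = sum(dist <= obs$AICc, na.rm = TRUE),
              nReps = nReps, mode = mode, seed = seed, failures = failures,
              observedFit = obs)
  class(out) <- "regimeNull"
  out
}

#' @export
print.regimeNull <- function(x, ...) {
  ok <- sum(!is.na(x$aiccDist))
  cat("Random-regime null (", x$mode, "): observed AICc ",
      sprintf("%.2f", x$observedAICc), "\n", sep = "")
  if (ok) cat(sprintf("  null AICc range [%.2f, %.2f] over %d replicates\n",
                      min(x$aiccDist, na.rm = TRUE),
                      max(x$aiccDist, na.rm = TRUE), ok))
  cat("  replicates at or below observed:", x$exceedance, "/", ok, "\n")
  if (length(x$failures)) cat("  failures:", length(x$failures), "\n")
  invisible(x)
}
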