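# ---------------------------------------------------------------------------
# Phylogenetic signal statistics. All three work on the BM covariance of the
# tree and profile sigma^2 and the root state out of the Gaussian likelihood,
# which makes every statistic invariant to affine transforms of the trait.
# ---------------------------------------------------------------------------

#' Pagel's lambda
#'
#' Maximum-likelihood lambda by profiling the BM likelihood on the
#' lambda-transformed covariance (off-diagonal entries multiplied by lambda).
#' The admissible upper bound `lambdaMax` is the largest lambda keeping the
#' transformed covariance positive definite. Likelihood-ratio tests against
#' lambda = 0 (no signal) and lambda = 1 (BM) are both reported.
#'
#' @param tree A valid [ape::phylo] with >= 4 tips.
#' @param traits A [traitTable] or named numeric vector.
#' @param log Analyse log trait values.
#' @return A list of class `signalLambda`: `lambda`, `lambdaMax`, `logLik`
#'   at 0 / at the optimum / at 1, `p0` (LR test vs 0) and `p1` (vs 1).
#' @export
pagelLambda <- function(tree, traits, log = FALSE) {
  y0 <- signalInput(tree, traits, log)
  # standardize so the profile (and hence lambda-hat) is exactly invariant
  # to affine transforms of the trait; log-likelihoods are mapped back
  sc <- stats::sd(y0)
  y <- (y0 - mean(y0)) / sc
  llShift <- -length(y) * base::log(sc)
  V <- bmCovariance(tree)
  D <- diag(diag(V))
  # positive definiteness bound: V(l) = D + l (V - D)
  Dh <- diag(1 / sqrt(diag(V)))
  E <- Dh %*% (V - D) %*% Dh
  ev <- eigen((E + t(E)) / 2, symmetric = TRUE, only.values = TRUE)$values
  lambdaMax <- if (min(ev) >= -1e-12) Inf else -1 / min(ev)
  upper <- min(lambdaMax * (1 - 1e-8), 10)
  prof <- function(l) {
    g <- glsFit(l * V + (1 - l) * D, matrix(1, length(y)), y, scale = TRUE)
    if (is.null(g)) -Inf else g$logLik
  }
  opt <- gridOptimize(prof, c(0, upper), nGrid = 25)
  ll0 <- prof(0); ll1 <- if (upper >= 1) prof(1) else NA_real_
  lam <- max(opt$par, 0)
  llhat <- max(opt$value, ll0, ll1, na.rm = TRUE)
  if (ll0 >= llhat) { lam <- 0; llhat <- ll0 }
  ll0 <- ll0 + llShift; llhat <- llhat + llShift; ll1 <- ll1 + llShift
  structure(list(lambda = lam, lambdaMax = lambdaMax,
                 logLik0 = ll0, logLik = llhat, logLik1 = ll1,
                 p0 = stats::pchisq(2 * (llhat - ll0), 1, lower.tail = FALSE),
                 p1 = if (is.na(ll1)) NA_real_ else
                   stats::pchisq(2 * (llhat - ll1), 1, lower.tail = FALSE)),
            class = "signalLambda")
}

#' Blomberg's K with a randomization test
#'
#' K is the ratio of the observed mean-squared tip deviation from the
#' phylogenetically corrected mean over the GLS mean-squared error, divided
#' by its Brownian-motion expectation on the same tree; K = 1 matches BM.
#' The p-value shuffles tip labels and compares the variance of
#' phylogenetically independent contrasts: a lower observed contrast
#' variance than the permutations indicates signal. The add-one convention
#' keeps the p-value strictly positive.
#'
#' @inheritParams pagelLambda
#' @param nPerm Number of permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @return A list of class `signalK`: `K`, `p`, `nPerm`, `seed`,
#'   `contrastVar` (observed PIC variance).
#' @export
blombergK <- function(tree, traits, nPerm = 999, seed = 1, log = FALSE) {
  y <- signalInput(tree, traits, log, minTips = 3)
  n <- length(y)
  V <- bmCovariance(tree)
  Vinv <- solve(V)
  one <- rep(1, n)
  denom <- drop(one %*% Vinv %*% one)
  ahat <- drop(one %*% Vinv %*% y) / denom
  dev <- y - ahat
  mse0 <- sum(dev^2) / (n - 1)
  mse <- drop(dev %*% Vinv %*% dev) / (n - 1)
  expected <- (sum(diag(V)) - n / denom) / (n - 1)
  K <- (mse0 / mse) / expected
  btree <- if (ape::is.binary(tree)) tree else ape::multi2di(tree,
                                                             random = FALSE)
  picVar <- function(v) stats::var(ape::pic(v[btree$tip.label], btree))
  obs <- picVar(y)
  set.seed(seed)
  perm <- replicate(nPerm, {
    z <- y
    names(z) <- sample(names(y))
    picVar(z)
  })
  # low contrast variance = strong signal; equivalently the test statistic
  # -var(contrasts) is extreme when >= the observed value
  p <- (1 + sum(perm <= obs)) / (1 + nPerm)
  structure(list(K = K, p = p, nPerm = nPerm, seed = seed,
                 contrastVar = obs),
            class = "signalK")
}

#' Pagel's delta
#'
#' Maximum-likelihood delta by profiling the BM likelihood on the node-depth
#' power transform: every covariance entry t becomes `T * (t / T)^delta`
#' (total depth preserved). delta > 1 concentrates disparity late in the
#' tree (within clades); a likelihood-ratio test against delta = 1 is
#' reported. The search range defaults to the customary [0.01, 3]; an
#' estimate at a bound is flagged.
#'
#' @inheritParams pagelLambda
#' @param bounds Search interval for delta.
#' @return A list of class `signalDelta`: `delta`, `logLik`, `logLik1`,
#'   `p1`, `atBound`.
#' @export
pagelDelta <- function(tree, traits, bounds = c(0.01, 3), log = FALSE) {
  y0 <- signalInput(tree, traits, log)
  if (!checkUltrametric(tree)$ultrametric)
    stop("Pagel's delta requires an ultrametric tree")
  sc <- stats::sd(y0)
  y <- (y0 - mean(y0)) / sc   # exact affine invariance of the profile
  llShift <- -length(y) * base::log(sc)
  V <- bmCovariance(tree)
  Tdepth <- max(diag(V))
  prof <- function(d) {
    Vd <- Tdepth * (V / Tdepth)^d
    g <- glsFit(Vd, matrix(1, length(y)), y, scale = TRUE)
    if (is.null(g)) -Inf else g$logLik
  }
  opt <- gridOptimize(prof, bounds, nGrid = 25)
  ll1 <- prof(1)
  dhat <- opt$par; llhat <- opt$value
  if (ll1 > llhat) { dhat <- 1; llhat <- ll1 }
  atBound <- min(abs(dhat - bounds)) < 1e-4 * diff(bounds)
  ll1 <- ll1 + llShift; llhat <- llhat + llShift
  structure(list(delta = dhat, logLik = llhat, logLik1 = ll1,
                 p1 = stats::pchisq(2 * (llhat - ll1), 1, lower.tail = FALSE),
                 atBound = atBound, bounds = bounds),
            class = "signalDelta")
}

signalInput <- function(tree, traits, log, minTips = 4) {
  validatePhylogeny(tree)
  if (length(tree$tip.label) < minTips)
    stop("signal statistics need >= ", minTips, " tips")
  y <- if (inherits(traits, "traitTable")) traitVector(tree, traits, log)
       else {
         v <- traits[tree$tip.label]
         if (log) base::log(v) else v
       }
  if (anyNA(y)) stop("tips without trait data")
  if (stats::sd(y) < .Machine$double.eps^0.5) stop("constant trait")
  y
}

#' @export
print.signalLambda <- function(x, ...) {
  cat(sprintf("Pagel's lambda = %.4f (admissible max %.4f)\n", x$lambda,
              x$lambdaMax))
  cat(sprintf("  logLik: %.4f at 0, %.4f at MLE, %s at 1\n", x$logLik0,
              x$logLik, ifelse(is.na(x$logLik1), "NA",
                               sprintf("%.4f", x$logLik1))))
  cat(sprintf("  LR p (vs 0) = %.4g; LR p (vs 1) = %.4g\n", x$p0, x$p1))
  invisible(x)
}

#' @export
print.signalK <- function(x, ...) {
  cat(sprintf("Blomberg's K = %.4f (p = %.4g, %d permutations)\n",
              x$K, x$p, x$nPerm))
  invisible(x)
}

#' @export
print.signalDelta <- function(x, ...) {
  cat(sprintf("Pagel's delta = %.4f (LR p vs 1 = %.4g)%s\n", x$delta, x$p1,
              if (x$atBound) " [at search bound]" else ""))
  invisible(x)
}

#' One-call phylogenetic signal report
#'
#' @inheritParams blombergK
#' @return List with `lambda`, `K`, `delta` results.
#' @export
phyloSignalReport <- function(tree, traits, nPerm = 999, seed = 1,
                              log = FALSE) {
  list(lambda = pagelLambda(tree, traits, log = log),
       K = blombergK(tree, traits, nPerm = nPerm, seed = seed, log = log),
       delta = pagelDelta(tree, traits, log = log))
}
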