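# ---------------------------------------------------------------------------
# Disparity through time. At each branching event the relative disparity of
# the lineages then alive (average squared pairwise difference within each
# subclade, normalised by the whole-tree value) is averaged; the curve is
# compared with a null envelope simulated under Brownian motion and the
# morphological disparity index (MDI) is the signed area between the
# observed curve and the null median.
# ---------------------------------------------------------------------------

# per-edge clade disparity for a matrix of trait columns (tips x nsim);
# metric "avg.sq" = mean squared pairwise difference, "variance" = clade var
cladeDisparity <- function(M, Y, metric) {
  m <- rowSums(M)
  S <- M %*% Y
  SS <- M %*% (Y * Y)
  if (metric == "avg.sq") {
    denom <- m * (m - 1)
    out <- sweep(2 * (m * SS - S * S), 1,
                 ifelse(denom > 0, denom, 1), "/")
  } else {
    out <- sweep(SS - sweep(S * S, 1, pmax(m, 1), "/"), 1,
                 pmax(m - 1, 1), "/")
  }
  out[m < 2, ] <- 0
  out
}

dttStructure <- function(tree) {
  depths <- nodeDepths(tree)
  n <- length(tree$tip.label)
  Tdepth <- max(depths[seq_len(n)])
  internal <- sort(unique(depths[(n + 1L):(n + tree$Nnode)]))
  grid <- internal  # includes the root at 0
  pDepth <- depths[tree$edge[, 1]]
  cDepth <- depths[tree$edge[, 2]]
  crossing <- lapply(grid, function(t) which(pDepth <= t & cDepth > t))
  M <- edgeTipIncidence(tree)
  list(grid = grid, relTime = grid / Tdepth, crossing = crossing, M = M,
       Tdepth = Tdepth, n = n)
}

# observed/simulated curves: rows = grid points, cols = trait columns;
# the point at relative time 0 is the whole tree, i.e. exactly 1
dttCurves <- function(st, Y, metric) {
  total <- drop(cladeDisparity(matrix(TRUE, 1, st$n), Y, metric))
  D <- cladeDisparity(st$M, Y, metric)
  out <- matrix(NA_real_, length(st$grid), ncol(Y))
  for (g in seq_along(st$grid)) {
    idx <- st$crossing[[g]]
    rel <- if (length(idx) == 1L) D[idx, , drop = FALSE] else
      colMeans(D[idx, , drop = FALSE])
    out[g, ] <- drop(rel) / total
  }
  out[1, ] <- 1  # time zero: total-tree normalisation
  out
}

trapezoidArea <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Disparity through time with a Brownian-motion null and the MDI
#'
#' Computes the observed relative-disparity curve on the grid of internal
#' node times, a null envelope from `nSim` BM simulations at the ML BM rate,
#' and the morphological disparity index: the signed area between the
#' observed curve and the null median over relative time (curves are closed
#' with zero disparity at the present). Positive MDI means disparity
#' concentrated later than the BM expectation. One-sided p-values are
#' reported for both tails (`pPositive` is the conventional one for a
#' positive MDI), with the add-one convention.
#'
#' @param tree An ultrametric [ape::phylo] with >= 4 tips.
#' @param traits A [traitTable] or named numeric vector.
#' @param nSim Number of BM null simulations (default 1000).
#' @param seed Integer seed.
#' @param metric `"avg.sq"` (default) or `"variance"`.
#' @param log Analyse log trait values.
#' @return A `dttResult`: `relTime`, `observed`, `nullMedian`, `nullLo`,
#'   `nullHi` (2.5/97.5 percent), `MDI`, `pPositive`, `pNegative`, `nSim`,
#'   `seed`, `degenerate`.
#' @export
dtt <- function(tree, traits, nSim = 1000, seed = 1,
                metric = c("avg.sq", "variance"), log = FALSE) {
  metric <- match.arg(metric)
  validatePhylogeny(tree)
  if (length(tree$tip.label) < 4) stop("dtt needs >= 4 tips")
  if (!checkUltrametric(tree)$ultrametric)
    stop("dtt requires an ultrametric tree")
  y <- if (inherits(traits, "traitTable")) traitVector(tree, traits, log)
       else {
         v <- traits[tree$tip.label]
         if (log) base::log(v) else v
       }
  st <- dttStructure(tree)
  if (stats::sd(y) < .Machine$double.eps^0.5) {
    res <- list(relTime = st$relTime, observed = rep(0, length(st$relTime)),
                nullMedian = NULL, nullLo = NULL, nullHi = NULL,
                MDI = NA_real_, pPositive = NA_real_, pNegative = NA_real_,
                nSim = nSim, seed = seed, metric = metric, degenerate = TRUE)
    class(res) <- "dttResult"
    return(res)
  }
  obs <- drop(dttCurves(st, matrix(y, ncol = 1), metric))
  V <- bmCovariance(tree)
  g <- glsFit(V, matrix(1, st$n), y, scale = TRUE)
  set.seed(seed)
  L <- t(chol(V))
  Y <- drop(g$beta) + sqrt(g$sigma2hat) * (L %*%
    matrix(stats::rnorm(st$n * nSim), st$n, nSim))
  null <- dttCurves(st, Y, metric)
  med <- apply(null, 1, stats::median)
  lo <- apply(null, 1, stats::quantile, 0.025)
  hi <- apply(null, 1, stats::quantile, 0.975)
  tGrid <- c(st$relTime, 1)
  area <- function(curve) trapezoidArea(tGrid, c(curve - med, 0))
  MDI <- area(obs)
  nullAreas <- apply(null, 2, area)
  pPos <- (1 + sum(nullAreas >= MDI)) / (1 + nSim)
  pNeg <- (1 + sum(nullAreas <= MDI)) / (1 + nSim)
  res <- list(relTime = st$relTime, observed = obs, nullMedian = med,
              nullLo = lo, nullHi = hi, MDI = MDI, pPositive = pPos,
              pNegative = pNeg, nSim = nSim, seed = seed, metric = metric,
              degenerate = FALSE)
  class(res) <- "dttResult"
  res
}

#' @export
print.dttResult <- function(x, ...) {
  if (x$degenerate) {
    cat("DTT: degenerate (constant trait); MDI undefined\n")
    return(invisible(x))
  }
  cat(sprintf("DTT over %d grid points, %d BM null simulations\n",
              length(x$relTime), x$nSim))
  cat(sprintf("  MDI = %.4f (p positive-tail = %.4g, negative-tail = %.4g)\n",
              x$MDI, x$pPositive, x$pNegative))
  invisible(x)
}

#' @rdname dtt
#' @param x A `dttResult`.
#' @param file CSV path (grid, observed, null quantiles); a JSON summary is
#'   written alongside as `<file>.json`.
#' @export
writeDtt <- function(x, file) {
  utils::write.csv(data.frame(relTime = x$relTime, observed = x$observed,
                              nullMedian = x$nullMedian, nullLo = x$nullLo,
                              nullHi = x$nullHi),
                   file, row.names = FALSE)
  jsonlite::write_json(list(MDI = x$MDI, pPositive = x$pPositive,
                            pNegative = x$pNegative, nSim = x$nSim,
                            seed = x$seed, metric = x$metric),
                       paste0(file, ".json"), auto_unbox = TRUE, digits = 10)
  invisible(file)
}

#' Intraspecific coefficients of variation per taxon and island
#'
#' @param specimens Data.frame with columns `taxon`, `value`, `island`
#'   (per-specimen trait records), e.g. the `"specimens"` attribute of a
#'   [traitTable].
#' @param minN Minimum group size; smaller groups are reported with `NA`
#'   (missing, not zero).
#' @return Data.frame with `taxon`, `island`, `n`, `mean`, `sd`, `cv`
#'   (sample sd over mean).
#' @export
populationCV <- function(specimens, minN = 2) {
  stopifnot(all(c("taxon", "value", "island") %in% names(specimens)))
  groups <- split(specimens,
                  interaction(specimens$taxon, specimens$island, drop = TRUE))
  rows <- lapply(groups, function(d) {
    n <- nrow(d)
    m <- mean(d$value)
    s <- if (n >= minN) stats::sd(d$value) else NA_real_
    data.frame(taxon = d$taxon[1], island = d$island[1], n = n,
               mean = m, sd = s, cv = s / m)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$taxon, out$island), ]
}
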