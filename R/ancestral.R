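# edge x node incidence over ALL nodes (tips and internals): entry (e, v) is
# true when edge e lies on the root-to-v path; crossprod with branch lengths
# gives shared root-to-MRCA depths for any node pair
edgeNodeIncidence <- function(tree) {
  n <- length(tree$tip.label)
  nn <- tree$Nnode
  ne <- nrow(tree$edge)
  key <- paste(tree$edge[, 1], tree$edge[, 2])
  post <- ape::reorder.phylo(tree, "postorder")
  M <- matrix(FALSE, ne, n + nn)
  below <- lapply(seq_len(n + nn), function(i) i)
  for (e in seq_len(ne)) {
    p <- post$edge[e, 1]; ch <- post$edge[e, 2]
    orig <- match(paste(p, ch), key)
    M[orig, below[[ch]]] <- TRUE
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  M
}

#' Ancestral state reconstruction under Brownian motion
#'
#' Generalised-least-squares estimates of the trait at every internal node,
#' with 95 percent intervals from the conditional Gaussian variance. The
#' root is the GLS phylogenetic mean; other nodes are its best linear
#' unbiased predictors given the tips. The BM rate is estimated by REML
#' (mean squared standardized independent contrast, divisor n - 1; the
#' default, matching the usual comparative-methods practice) or ML
#' (GLS quadratic form, divisor n). ML and REML share the same point
#' estimates; only interval widths differ through the rate.
#'
#' @param tree A valid [ape::phylo] with >= 3 tips.
#' @param traits A [traitTable] or named numeric vector.
#' @param method `"REML"` (default) or `"ML"`.
#' @param log Reconstruct on the log scale.
#' @param level Interval coverage (default 0.95).
#' @return An `ancestralResult`: data.frame `nodes` (node id, estimate, lo,
#'   hi, isTip), `sigma2`, `method`, `degenerate` flag. Tip rows carry the
#'   observed values with zero-width intervals.
#' @export
ancestralBM <- function(tree, traits, method = c("REML", "ML"), log = FALSE,
                        level = 0.95) {
  method <- match.arg(method)
  validatePhylogeny(tree)
  if (length(tree$tip.label) < 3) stop("need >= 3 tips")
  y <- if (inherits(traits, "traitTable")) traitVector(tree, traits, log)
       else {
         v <- traits[tree$tip.label]
         if (log) base::log(v) else v
       }
  n <- length(y); nn <- tree$Nnode
  M <- edgeNodeIncidence(tree)
  S <- crossprod(M * sqrt(tree$edge.length))  # shared depths, all node pairs
  V <- S[seq_len(n), seq_len(n)]
  Vinv <- solve(V)
  one <- rep(1, n)
  denom <- drop(one %*% Vinv %*% one)
  ahat <- drop(one %*% Vinv %*% y) / denom
  dev <- y - ahat
  degenerate <- stats::sd(y) < .Machine$double.eps^0.5
  sigma2 <- if (degenerate) 0 else if (method == "ML") {
    drop(dev %*% Vinv %*% dev) / n
  } else {
    btree <- if (ape::is.binary(tree)) tree else
      ape::multi2di(tree, random = FALSE)
    contrasts <- ape::pic(y[btree$tip.label], btree)
    sum(contrasts^2) / (n - 1)
  }
  idx <- (n + 1L):(n + nn)
  est <- numeric(nn); varc <- numeric(nn)
  for (j in seq_len(nn)) {
    k <- idx[j]
    ck <- S[k, seq_len(n)]
    w <- drop(Vinv %*% ck)
    est[j] <- ahat + sum(w * dev)
    varc[j] <- S[k, k] - sum(ck * w) + (1 - sum(w))^2 / denom
  }
  # t quantile with the rate's residual df: the rate is estimated, and the
  # plug-in normal interval would undercover at these sample sizes
  z <- stats::qt(1 - (1 - level) / 2, df = n - 1)
  half <- z * sqrt(pmax(sigma2 * varc, 0))
  nodes <- data.frame(
    node = c(seq_len(n), idx),
    label = c(tree$tip.label, rep(NA_character_, nn)),
    estimate = c(unname(y), est),
    lo = c(unname(y), est - half),
    hi = c(unname(y), est + half),
    isTip = c(rep(TRUE, n), rep(FALSE, nn)))
  structure(list(nodes = nodes, sigma2 = sigma2, method = method,
                 level = level, degenerate = degenerate,
                 logTransform = log, rootEstimate = est[1]),
            class = "ancestralResult")
}

#' @export
print.ancestralResult <- function(x, ...) {
  cat(sprintf("BM ancestral reconstruction (%s, sigma2 = %.4g)%s\n",
              x$method, x$sigma2,
              if (x$degenerate) " [degenerate: constant trait]" else ""))
  cat(sprintf("  root estimate %.4f [%.4f, %.4f]\n",
              x$nodes$estimate[!x$nodes$isTip][1],
              x$nodes$lo[!x$nodes$isTip][1],
              x$nodes$hi[!x$nodes$isTip][1]))
  invisible(x)
}

#' Write an ancestral reconstruction
#'
#' CSV of `node, estimate, lo, hi` plus an annotated Newick whose internal
#' node labels carry the estimates.
#'
#' @param x An `ancestralResult`.
#' @param tree The tree used for the reconstruction.
#' @param file CSV path; the Newick goes to `<file>.nwk`.
#' @export
writeAncestral <- function(x, tree, file) {
  utils::write.csv(x$nodes, file, row.names = FALSE)
  tr <- tree
  tr$node.label <- sprintf("%.4f", x$nodes$estimate[!x$nodes$isTip])
  writeNewickTree(tr, paste0(file, ".nwk"))
  invisible(file)
}

#' Per-category size-change accounting against reconstructed ancestors
#'
#' For every tip, the percent change of its observed value relative to the
#' reconstructed state of its direct parent node
#' (`(tip - parent) / parent * 100`), aggregated by regime category: mean
#' percent change, number of decreasing taxa and number with changes larger
#' than the reporting threshold (5 percent by default).
#'
#' @param tree Working tree.
#' @param traits A [traitTable] or named numeric vector.
#' @param scheme A [regimeScheme] covering the tree's tips.
#' @param ancestral An `ancestralResult` for the same tree/trait pair, or
#'   `NULL` to compute one (REML).
#' @param threshold Reporting threshold in percent (default 5).
#' @param log Compute changes on the log scale.
#' @return A `categoryChange` list: `perTip` data.frame (taxon, category,
#'   value, parentEstimate, pctChange) and `summary` data.frame per category
#'   (n, meanChange, nDecreasing, nLargeChange).
#' @export
categoryChangeSummary <- function(tree, traits, scheme, ancestral = NULL,
                                  threshold = 5, log = FALSE) {
  validatePhylogeny(tree)
  if (is.null(ancestral)) ancestral <- ancestralBM(tree, traits, log = log)
  y <- if (inherits(traits, "traitTable")) traitVector(tree, traits, log)
       else traits[tree$tip.label]
  n <- length(y)
  parentOf <- integer(n + tree$Nnode)
  parentOf[tree$edge[, 2]] <- tree$edge[, 1]
  estimates <- ancestral$nodes$estimate[match(parentOf[seq_len(n)],
                                              ancestral$nodes$node)]
  pct <- (unname(y) - estimates) / estimates * 100
  cat <- scheme$tips[tree$tip.label]
  if (anyNA(cat)) stop("scheme does not cover all tips")
  perTip <- data.frame(taxon = tree$tip.label, category = unname(cat),
                       value = unname(y), parentEstimate = estimates,
                       pctChange = pct)
  agg <- lapply(split(perTip, perTip$category), function(d) {
    data.frame(category = d$category[1], n = nrow(d),
               meanChange = mean(d$pctChange),
               nDecreasing = sum(d$pctChange < 0),
               nLargeChange = sum(abs(d$pctChange) > threshold))
  })
  summary <- do.call(rbind, agg)
  rownames(summary) <- NULL
  structure(list(perTip = perTip, summary = summary, threshold = threshold),
            class = "categoryChange")
}

#' @export
print.categoryChange <- function(x, ...) {
  cat("Per-category size change vs reconstructed direct ancestor\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
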