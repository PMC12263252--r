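# Independent oracles used across the suite. The likelihood oracle rebuilds
# the mean vector and covariance matrix of every model by explicit per-tip
# path enumeration and adaptive numerical integration -- a completely
# different route from the package's stable preorder recursion.

# per-tip root-to-tip path segments: data.frame(t0, t1, cat)
oraclePathSegments <- function(tree, tip) {
  n <- length(tree$tip.label)
  depth <- islandOU:::nodeDepths(tree)
  parentOf <- integer(n + tree$Nnode)
  parentOf[tree$edge[, 2]] <- tree$edge[, 1]
  root <- n + 1L
  nodes <- integer()
  v <- tip
  while (v != root) {
    nodes <- c(v, nodes)
    v <- parentOf[v]
  }
  data.frame(t0 = depth[c(root, utils::head(nodes, -1))],
             t1 = depth[nodes], node = nodes)
}

# piecewise-constant per-branch parameters along a path
oraclePathParams <- function(tree, tip, catNode, alphaByCat, sigma2ByCat,
                             thetaByCat, ebR = 0) {
  seg <- oraclePathSegments(tree, tip)
  cat <- catNode[seg$node]
  pick <- function(p, cc) if (length(p) == 1L && is.null(names(p)))
    rep(unname(p), length(cc)) else unname(p[cc])
  seg$alpha <- pick(alphaByCat, cat)
  seg$sigma2 <- pick(sigma2ByCat, cat)
  seg$theta <- if (is.null(thetaByCat)) rep(0, nrow(seg)) else
    pick(thetaByCat, cat)
  seg$ebR <- ebR
  seg
}

oracleAlphaAt <- function(u, seg) {
  i <- findInterval(u, seg$t0, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), nrow(seg))
  seg$alpha[i]
}
oracleSigma2At <- function(u, seg) {
  i <- findInterval(u, seg$t0, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), nrow(seg))
  s <- seg$sigma2[i]
  if (seg$ebR[1] != 0) s <- s * exp(seg$ebR[1] * u)
  s
}
oracleThetaAt <- function(u, seg) {
  i <- findInterval(u, seg$t0, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), nrow(seg))
  seg$theta[i]
}

# A(u) = integral of alpha from u to the tip time; alpha is piecewise
# constant along the path so the integral is an exact overlap sum
oracleA <- function(u, seg) {
  vapply(u, function(uu) {
    sum(seg$alpha * pmax(0, seg$t1 - pmax(seg$t0, uu)))
  }, 0)
}

# dense mean vector and covariance by path enumeration + quadrature
oracleMeanCov <- function(tree, catNode, alphaByCat, sigma2ByCat,
                          thetaByCat = NULL, z0 = 0, ebR = 0,
                          rootTheta = NULL) {
  n <- length(tree$tip.label)
  segs <- lapply(seq_len(n), function(i)
    oraclePathParams(tree, i, catNode, alphaByCat, sigma2ByCat, thetaByCat,
                     ebR))
  depth <- islandOU:::nodeDepths(tree)
  mu <- vapply(seq_len(n), function(i) {
    seg <- segs[[i]]
    Ttip <- seg$t1[nrow(seg)]
    base <- z0 * exp(-oracleA(0, seg))
    pull <- 0
    for (r in seq_len(nrow(seg))) {  # integrate segment by segment
      if (seg$alpha[r] == 0) next
      pull <- pull + stats::integrate(function(u)
        oracleAlphaAt(u, seg) * oracleThetaAt(u, seg) *
          exp(-oracleA(u, seg)),
        seg$t0[r], seg$t1[r], rel.tol = 1e-12, abs.tol = 1e-13,
        subdivisions = 400L)$value
    }
    base + pull
  }, 0)
  mrca <- ape::mrca(tree)
  diag(mrca) <- seq_len(n)
  V <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(i)) {
    sij <- depth[mrca[i, j]]
    segI <- segs[[i]]; segJ <- segs[[j]]
    if (sij <= 0) { V[i, j] <- V[j, i] <- 0; next }
    f <- function(u) oracleSigma2At(u, segI) *
      exp(-(oracleA(u, segI) + oracleA(u, segJ)))
    # integrate piecewise over the shared path's breakpoints
    brk <- sort(unique(c(0, segI$t0, segI$t1, segJ$t0, segJ$t1)))
    brk <- brk[brk <= sij + 1e-12]
    if (max(brk) < sij) brk <- c(brk, sij)
    tot <- 0
    for (r in seq_len(length(brk) - 1))
      tot <- tot + stats::integrate(f, brk[r], brk[r + 1],
                                    rel.tol = 1e-12, abs.tol = 1e-13,
                                    subdivisions = 400L)$value
    V[i, j] <- V[j, i] <- tot
  }
  dimnames(V) <- list(tree$tip.label, tree$tip.label)
  names(mu) <- tree$tip.label
  list(mu = mu, V = V)
}

oracleLoglik <- function(y, mu, V) {
  n <- length(y)
  -0.5 * (n * log(2 * pi) +
            as.numeric(determinant(V, logarithm = TRUE)$modulus) +
            drop(t(y - mu) %*% solve(V) %*% (y - mu)))
}

# random ultrametric tree with named tips and a random painted scheme
randomTestTree <- function(nTips, seed) {
  set.seed(seed)
  tree <- ape::rcoal(nTips)
  tree$tip.label <- paste0("t", seq_len(nTips))
  tree
}

randomTestScheme <- function(tree, seed, categories = c("S", "M", "L")) {
  set.seed(seed)
  n <- length(tree$tip.label)
  tips <- sample(categories, n, replace = TRUE)
  # guarantee every category appears
  tips[seq_along(categories)] <- categories
  sch <- regimeScheme("three_cat", stats::setNames(tips, tree$tip.label),
                      categories = categories)
  paintInternalNodes(tree, sch, sample(categories, 1))
}

# convenience: named vector -> traitTable-free fit input
asTraitVec <- function(x) x
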