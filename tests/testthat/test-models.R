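threeTip <- function() {
  list(tree = readNewickTree("((A:1,B:1):1,C:2);"),
       traits = traitTable(c("A", "B", "C"), c(2, 4, 3)))
}

test_that("BM log-likelihood matches the dense multivariate-normal value", {
  w <- threeTip()
  ll <- ouLoglik("BM", w$tree, w$traits, params = list(sigma2 = 1, z0 = 3))
  V <- matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3, 3)
  expect_equal(ll, oracleLoglik(c(2, 4, 3), rep(3, 3), V), tolerance = 1e-10)
  expect_equal(ll, -4.6526954, tolerance = 1e-6)
})

test_that("OU1 covariance entries equal the shared-time closed form", {
  w <- threeTip()
  a <- log(2)
  ll <- ouLoglik("OU1", w$tree, w$traits,
                 params = list(sigma2 = 1, alpha = a, theta = 3))
  cav <- function(s, d) 1 / (2 * a) * exp(-a * d) * (1 - exp(-2 * a * s))
  V <- matrix(c(cav(2, 0), cav(1, 2), 0,
                cav(1, 2), cav(2, 0), 0,
                0, 0, cav(2, 0)), 3, 3)
  expect_equal(ll, oracleLoglik(c(2, 4, 3), rep(3, 3), V), tolerance = 1e-10)
  # stationary-root mean: every tip expectation is exactly theta
  expect_equal(cav(1, 2), 0.13525266, tolerance = 1e-7)
  expect_equal(cav(2, 0), 0.67626332, tolerance = 1e-7)
})

test_that("OU collapses to BM in the small-alpha limit; alpha = 0 is refused", {
  w <- threeTip()
  llbm <- ouLoglik("BM", w$tree, w$traits, params = list(sigma2 = 1, z0 = 3))
  llou <- ouLoglik("OU1", w$tree, w$traits,
                   params = list(sigma2 = 1, alpha = 1e-8, theta = 3))
  expect_lt(abs(llou - llbm), 1e-5)
  expect_error(ouLoglik("OU1", w$tree, w$traits,
                        params = list(sigma2 = 1, alpha = 0, theta = 3)),
               "alpha")
  expect_error(ouLoglik("OU1", readNewickTree("((A:1,B:2):1,C:2);"),
                        stats::setNames(c(1, 2, 3), c("A", "B", "C")),
                        params = list(sigma2 = 1, alpha = 1, theta = 0)),
               "ultrametric")
})

test_that("Hansen weights (residence + root) sum to one for every tip", {
  tree <- randomTestTree(8, 3)
  sch <- randomTestScheme(tree, 4)
  pre <- islandOU:::treePrecompute(tree)
  catEdge <- islandOU:::edgeCategories(pre, sch)
  for (a in c(0.1, 1, 17)) {
    st <- islandOU:::meanCovStructure(pre, rep(a, pre$ne), rep(1, pre$ne),
                                      catEdge)
    expect_equal(unname(rowSums(st$W) + st$w0), rep(1, 8), tolerance = 1e-12)
  }
})

test_that("every model's likelihood agrees with the path-enumeration oracle", {
  # one representative case per model family here; the acceptance suite
  # sweeps 20 random trees
  set.seed(77)
  tree <- randomTestTree(7, 10)
  sch <- randomTestScheme(tree, 11)
  catNode <- islandOU:::schemeNodeCategories(sch, tree)
  y <- stats::setNames(rnorm(7, 50, 5), tree$tip.label)
  theta <- c(S = 47, M = 60, L = 85)
  rootCat <- catNode[8]

  cases <- list(
    list(model = "BM", params = list(sigma2 = 2.5, z0 = 55),
         a = 0, s = 2.5, th = NULL),
    list(model = "BMS",
         params = list(sigma2 = c(S = 1, M = 4, L = 9), z0 = 55),
         a = 0, s = c(S = 1, M = 4, L = 9), th = NULL),
    list(model = "OUM",
         params = list(sigma2 = 3, alpha = 0.8, theta = theta),
         a = 0.8, s = 3, th = theta),
    list(model = "OUMV",
         params = list(sigma2 = c(S = 2, M = 5, L = 1), alpha = 1.2,
                       theta = theta),
         a = 1.2, s = c(S = 2, M = 5, L = 1), th = theta),
    list(model = "OUMA",
         params = list(sigma2 = 2, alpha = c(S = 0.4, M = 1.5, L = 3),
                       theta = theta),
         a = c(S = 0.4, M = 1.5, L = 3), s = 2, th = theta),
    list(model = "OUMVA",
         params = list(sigma2 = c(S = 2, M = 5, L = 1),
                       alpha = c(S = 0.4, M = 1.5, L = 3), theta = theta),
         a = c(S = 0.4, M = 1.5, L = 3), s = c(S = 2, M = 5, L = 1),
         th = theta))
  for (cs in cases) {
    ll <- ouLoglik(cs$model, tree, y, scheme = sch, params = cs$params)
    z0 <- if (is.null(cs$th)) cs$params$z0 else unname(cs$th[rootCat])
    orc <- oracleMeanCov(tree, catNode, cs$a, cs$s, cs$th, z0 = z0)
    expect_equal(ll, oracleLoglik(y, orc$mu, orc$V), tolerance = 1e-9,
                 label = cs$model)
  }
  # EB against its oracle (time-decaying rate, no regimes)
  llEB <- ouLoglik("EB", tree, y, params = list(sigma2 = 2, r = -0.6,
                                                z0 = 55))
  catOne <- rep("1", 7 + tree$Nnode)
  orc <- oracleMeanCov(tree, catOne, 0, 2, NULL, z0 = 55, ebR = -0.6)
  expect_equal(llEB, oracleLoglik(y, orc$mu, orc$V), tolerance = 1e-9)
})

test_that("BM fit recovers the closed-form GLS estimates", {
  w <- threeTip()
  f <- fitModel("BM", w$tree, w$traits)
  expect_equal(unname(f$z0), 3, tolerance = 1e-9)
  expect_equal(unname(f$sigma2), 2 / 3, tolerance = 1e-9)  # ML divisor n
  expect_equal(f$k, 2)
})

test_that("constant traits are flagged degenerate, not silently fitted", {
  tr <- simulateYule(8, crownAge = 5, seed = 1)
  tt <- traitTable(tr$tip.label, rep(55, 8))
  f <- fitModel("BM", tr, tt)
  expect_true(f$diagnostics$degenerate)
  expect_true(f$diagnostics$boundary)
})

test_that("maximized likelihoods are monotone over nested model families", {
  sc <- synthesizeInputs(seed = 31)
  sch3 <- regimeScheme("three_cat",
                       stats::setNames(ifelse(sc$scheme$tips == "I", "M",
                                              sc$scheme$tips),
                                       names(sc$scheme$tips)))
  sch3 <- paintInternalNodes(sc$tree, sch3, "M")
  fBM <- fitModel("BM", sc$tree, sc$traits)
  fOU1 <- fitModel("OU1", sc$tree, sc$traits)
  fOUM <- fitModel("OUM", sc$tree, sc$traits, sch3)
  fOUMV <- fitModel("OUMV", sc$tree, sc$traits, sch3, seed = 2)
  expect_gte(fOU1$logLik, fBM$logLik - 1e-4)
  expect_gte(fOUM$logLik, fOU1$logLik - 1e-4)
  expect_gte(fOUMV$logLik, fOUM$logLik - 1e-4)
})

test_that("AICc, delta and weights follow the finite-sample formula", {
  expect_equal(aicc(-181.13, 6, 56), 375.9743, tolerance = 1e-4)
  expect_error(aicc(-10, 5, 6), "undefined")
  cmp <- compareFits(data.frame(model = c("m1", "m2"),
                                logLik = c(-100, -100), k = c(3, 3)), n = 30)
  expect_equal(cmp$weight, c(0.5, 0.5))
  expect_equal(sum(cmp$weight), 1)
  # order invariance
  tab <- data.frame(model = c("a", "b", "c"), logLik = c(-90, -95, -100),
                    k = c(3, 4, 2))
  w1 <- compareFits(tab, n = 40)
  w2 <- compareFits(tab[3:1, ], n = 40)
  expect_equal(w1$weight, rev(w2$weight))
  expect_equal(sum(w1$weight), 1)
})

test_that("fits on different data refuse to be compared", {
  tr <- simulateYule(10, crownAge = 5, seed = 6)
  t1 <- traitTable(tr$tip.label, stats::runif(10, 40, 80))
  t2 <- traitTable(tr$tip.label, stats::runif(10, 40, 80))
  f1 <- fitModel("BM", tr, t1)
  f2 <- fitModel("BM", tr, t2)
  expect_error(compareFits(list(f1, f2)), "identical data")
  cmp <- compareFits(list(f1, fitModel("EB", tr, t1, seed = 2)))
  expect_s3_class(cmp, "modelComparison")
})

test_that("the log-transform flag transforms data, never the tree", {
  sc <- synthesizeInputs(seed = 13)
  fRaw <- fitModel("OUM", sc$tree, sc$traits, sc$scheme)
  fLog <- fitModel("OUM", sc$tree, sc$traits, sc$scheme, log = TRUE)
  # a silent double-transform would reproduce the raw fit
  expect_false(isTRUE(all.equal(fRaw$logLik, fLog$logLik)))
  expect_false(isTRUE(all.equal(unname(fRaw$theta), unname(fLog$theta),
                                tolerance = 1e-3)))
})

test_that("theta standard errors reflect the conditional GLS covariance", {
  sc <- synthesizeInputs(seed = 17)
  f <- fitModel("OUM", sc$tree, sc$traits, sc$scheme)
  expect_true(all(f$thetaSE > 0))
  expect_length(f$thetaSE, 4)
  # the abundant categories should be estimated more precisely than a
  # category would be from a fraction of the data: sanity bound on scale
  expect_true(all(f$thetaSE < 30))
})

test_that("random-regime null: planted structure beats its randomizations", {
  sc <- synthesizeInputs(list(theta = c(S = 47.5, M = 65.1, L = 93.4)),
                         seed = 23)
  nul <- randomRegimeNull(sc$tree, sc$traits, sc$scheme, nReps = 25,
                          seed = 5)
  expect_equal(nul$exceedance, 0)
  expect_length(nul$aiccDist, 25)
  # zero replicates: observed only
  n0 <- randomRegimeNull(sc$tree, sc$traits, sc$scheme, nReps = 0, seed = 5)
  expect_length(n0$aiccDist, 0)
  expect_false(is.na(n0$observedAICc))
})

test_that("random-regime null is calibrated under neutral (BM) data", {
  # with BM traits the 'observed' scheme is no better than a random one:
  # its normalized rank among randomizations should not hug zero
  sc <- synthesizeInputs(list(model = "BM", sigma2 = 33.9, z0 = 55.6,
                              theta = c(S = 0, M = 0, L = 0), alpha = 0),
                         seed = 41)
  ranks <- vapply(1:8, function(i) {
    sc2 <- synthesizeInputs(list(model = "BM", sigma2 = 33.9, z0 = 55.6,
                                 theta = c(S = 0, M = 0, L = 0), alpha = 0),
                            seed = 100 + i)
    nul <- randomRegimeNull(sc2$tree, sc2$traits, sc2$scheme, nReps = 19,
                            seed = i)
    (nul$exceedance + 1) / 21
  }, 0)
  expect_gt(mean(ranks), 0.15)
  expect_lt(mean(ranks), 0.85)
})
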