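test_that("Yule trees hit the target crown age exactly and are reproducible", {
  tr <- simulateYule(56, crownAge = 8.7, seed = 11)
  expect_equal(length(tr$tip.label), 56L)
  d <- islandOU:::nodeDepths(tr)[1:56]
  expect_true(all(abs(d - 8.7) < 1e-9))
  expect_identical(writeNewickTree(simulateYule(56, crownAge = 8.7, seed = 3)),
                   writeNewickTree(simulateYule(56, crownAge = 8.7, seed = 3)))
  expect_error(simulateYule(2, crownAge = 5), "nTips")
  expect_error(simulateYule(10, birthRate = -1), "birthRate")
})

test_that("forward Yule lineage growth matches the closed-form expectation", {
  # crown-conditioned pure birth: E[N(T)] = 2 * exp(b * T)
  b <- 0.4; T <- 3
  counts <- vapply(seq_len(500), function(i)
    length(simulateYule(birthRate = b, crownAge = T, seed = 9000 + i,
                        condition = "age")$tip.label), 0L)
  expected <- 2 * exp(b * T)
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("OU transitions with alpha = 0 reduce exactly to BM", {
  tr <- simulateYule(12, crownAge = 5, seed = 2)
  cfgOU <- simulationConfig("OU", sigma2 = 3, alpha = 0, z0 = 10)
  cfgBM <- simulationConfig("BM", sigma2 = 3, z0 = 10)
  expect_identical(simulateTrait(tr, cfgOU, seed = 5)$tipStates,
                   simulateTrait(tr, cfgBM, seed = 5)$tipStates)
})

test_that("strong pull drives every tip into its regime's stationary band", {
  tr <- simulateYule(30, crownAge = 8.7, seed = 4)
  theta <- c(S = 47.5, M = 65.1, L = 93.4)
  set.seed(8)
  sch <- regimeScheme("three_cat",
                      stats::setNames(sample(names(theta), 30, replace = TRUE),
                                      tr$tip.label))
  sch <- paintInternalNodes(tr, sch, "M")
  # stationary sd = sqrt(sigma2 / (2 alpha)) = sqrt(52 / 1e5) ~ 0.023
  cfg <- simulationConfig("OU", sigma2 = 52, alpha = 50000, theta = theta,
                          z0 = 65.1)
  sim <- simulateTrait(tr, cfg, regimes = sch, seed = 6)
  expect_true(all(abs(sim$tipStates - theta[sch$tips[names(sim$tipStates)]])
                  < 0.1))
})

test_that("BM tip covariance across replicates matches the tree covariance", {
  tr <- readNewickTree("((A:1,B:1):1,C:2);")
  cfg <- simulationConfig("BM", sigma2 = 1, z0 = 0)
  X <- vapply(seq_len(20000),
              function(i) simulateTrait(tr, cfg, seed = i)$tipStates,
              numeric(3))
  Vhat <- tcrossprod(X - rowMeans(X)) / (ncol(X) - 1)
  Vtrue <- bmCovariance(tr)[rownames(X), rownames(X)]
  # element-wise Monte-Carlo s.e. of a covariance entry ~ sqrt((v_ii v_jj +
  # v_ij^2) / n)
  se <- sqrt((outer(diag(Vtrue), diag(Vtrue)) + Vtrue^2) / ncol(X))
  expect_true(all(abs(Vhat - Vtrue) < 3 * se))
})

test_that("EB branch variance follows the decaying-rate integral", {
  # single branch of length 2 from the root: Var = s0^2 (e^{2r} - 1)/r... on
  # a 3-tip tree compare replicate variance of the deepest tip with the
  # closed form  sigma0^2 * (exp(r*T) - 1) / r
  tr <- readNewickTree("((A:1,B:1):1,C:2);")
  r <- -0.5
  cfg <- simulationConfig("EB", sigma2 = 2, r = r, z0 = 0)
  X <- vapply(seq_len(4000),
              function(i) simulateTrait(tr, cfg, seed = 40000 + i)$tipStates,
              numeric(3))
  vC <- stats::var(X["C", ])
  expected <- 2 * (exp(r * 2) - 1) / r
  se <- expected * sqrt(2 / (ncol(X) - 1))
  expect_lt(abs(vC - expected), 3 * se)
})

test_that("displaced communities respect the size gap; random ones match the
           subset-enumeration expectation", {
  sizes <- stats::setNames(c(40, 47, 55, 63, 71, 79, 87, 95),
                           paste0("sp", 1:8))
  occ <- simulateIslandCommunities(sizes, nAreas = 6, speciesPerArea = 3,
                                   structure = "displaced", minGap = 8,
                                   seed = 3)
  for (a in split(occ$taxon, occ$area)) {
    gaps <- abs(diff(sort(sizes[a])))
    expect_true(all(gaps >= 8))
  }
  # brute-force enumeration oracle over all 3-subsets of the pool
  pool <- stats::setNames(c(40, 43, 50, 58, 61, 70, 82, 90), paste0("q", 1:8))
  subsets <- utils::combn(names(pool), 3)
  hasClose <- apply(subsets, 2, function(s) any(diff(sort(pool[s])) < 8))
  pTrue <- mean(hasClose)
  hits <- vapply(seq_len(1000), function(i) {
    o <- simulateIslandCommunities(pool, nAreas = 1, speciesPerArea = 3,
                                   structure = "random", seed = 7000 + i)
    any(diff(sort(pool[o$taxon])) < 8)
  }, TRUE)
  se <- sqrt(pTrue * (1 - pTrue) / 1000)
  expect_lt(abs(mean(hits) - pTrue), 3 * se)
  # infeasible gap errors; single isolated taxon works
  expect_error(simulateIslandCommunities(pool, 1, 5, "displaced",
                                         minGap = 30, seed = 1),
               "infeasible")
  one <- simulateIslandCommunities(pool, 1, 1, "random", seed = 1)
  expect_equal(nrow(one), 1L)
})

test_that("generators are bit-reproducible and seed streams are independent", {
  tr <- simulateYule(10, crownAge = 5, seed = 1)
  cfg <- simulationConfig("BM", sigma2 = 1, z0 = 0)
  expect_identical(simulateTrait(tr, cfg, seed = 9)$tipStates,
                   simulateTrait(tr, cfg, seed = 9)$tipStates)
  expect_false(identical(deriveSeed(1, "yule"), deriveSeed(1, "trait")))
  expect_identical(deriveSeed(5, "x"), deriveSeed(5, "x"))
  expect_true(deriveSeed(123456789, "anything") < 2^31)
})

test_that("the simulation-to-reconstruction chain recovers the true root", {
  # end-to-end calibration: BM simulation, then BM ancestral reconstruction;
  # the true root must fall inside +/- 3 posterior sd nearly always
  tr <- simulateYule(56, crownAge = 8.7, seed = 21)
  cfg <- simulationConfig("BM", sigma2 = 4, z0 = 50)
  ok <- vapply(seq_len(300), function(i) {
    sim <- simulateTrait(tr, cfg, seed = 100 + i)
    anc <- ancestralBM(tr, sim$tipStates, method = "REML")
    root <- anc$nodes[!anc$nodes$isTip, ][1, ]
    sdRoot <- (root$hi - root$estimate) / stats::qt(0.975, 55)
    abs(root$estimate - 50) <= 3 * sdRoot
  }, TRUE)
  expect_gte(mean(ok), 0.99)
})
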