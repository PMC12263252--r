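threeSpeciesWorld <- function() {
  # one island of three species: rank order decides S/M/L
  traits <- traitTable(c("a", "b", "c"), c(49.3, 59.0, 70.6))
  occ <- occupancyTable(rep("isl", 3), "island", c("a", "b", "c"))
  list(traits = traits, occ = occ)
}

test_that("three sympatric species are ranked small/medium/large", {
  w <- threeSpeciesWorld()
  sch <- assignCategories(w$occ, w$traits, "three_cat")
  expect_equal(unname(sch$tips[c("a", "b", "c")]), c("S", "M", "L"))
})

test_that("two same-band species split into adjacent bands above the gap", {
  # global sympatric range 35-70: both 49 and 52 fall in the middle band;
  # their 3 mm difference exceeds 5% of the range (1.75 mm), so the smaller
  # one is pushed down a band
  traits <- traitTable(c("lo", "x", "y", "hi"), c(35, 49, 52, 70))
  occ <- occupancyTable(c("i1", "i1", "i2", "i2"), "island",
                        c("lo", "hi", "x", "y"))
  sch <- assignCategories(occ, traits, "three_cat")
  expect_equal(unname(sch$tips["x"]), "S")
  expect_equal(unname(sch$tips["y"]), "M")
  expect_false(sch$tips["x"] == sch$tips["y"])
})

test_that("widespread taxa take their modal category; ties need a policy", {
  traits <- traitTable(c("w", paste0("s", 1:4), paste0("l", 1:5)),
                       c(60, rep(40, 4), rep(80, 5)))
  # w is mid-sized in four areas (with a small partner) and bottom in one
  areas <- c("a1", "a1", "a2", "a2", "a3", "a3", "a4", "a4", "a5", "a5")
  taxa <- c("w", "s1", "w", "s2", "w", "s3", "w", "s4", "w", "l1")
  occ <- occupancyTable(c(areas, "a6", "a6", "a6", "a6"), "island",
                        c(taxa, "l2", "l3", "l4", "l5"))
  sch <- assignCategories(occ, traits, "three_cat")
  expect_equal(unname(sch$tips["w"]), "M")

  # tie: gap-splits label t 'S' next to a bigger partner and 'M' next to a
  # smaller one (all three share the global middle band)
  t2 <- traitTable(c("t", "u", "v", "lo", "hi"), c(60, 65, 55, 25, 95))
  o2 <- occupancyTable(c("a0", "a0", "x", "x", "y", "y"), "island",
                       c("lo", "hi", "t", "u", "t", "v"))
  expect_error(assignCategories(o2, t2, "three_cat"), "tie")
  s2 <- assignCategories(o2, t2, "three_cat", tieBreak = "prefer_middle")
  expect_equal(unname(s2$tips["t"]), "M")
})

test_that("isolated taxa go to M (three_cat) or their own I (four_cat)", {
  traits <- traitTable(c("iso", "a", "b", "c"), c(57.2, 49.3, 59.0, 70.6))
  occ <- occupancyTable(c("lonely", "isl", "isl", "isl"), "island",
                        c("iso", "a", "b", "c"))
  s3 <- assignCategories(occ, traits, "three_cat")
  s4 <- assignCategories(occ, traits, "four_cat")
  expect_equal(unname(s3$tips["iso"]), "M")
  expect_equal(unname(s4$tips["iso"]), "I")
  expect_false("I" %in% s3$tips)
  expect_true("I" %in% s4$categories)
})

test_that("context-only taxa shape labels but receive no tip mapping", {
  # extinct 'ghost' is the largest on the island: the extant pair is pushed
  # into lower categories even though ghost itself gets no mapping
  traits <- traitTable(c("ghost", "a", "b"), c(85, 50, 65))
  occ <- occupancyTable(rep("isl", 3), "island", c("ghost", "a", "b"))
  sch <- assignCategories(occ, traits, "three_cat", contextOnly = "ghost")
  expect_false("ghost" %in% names(sch$tips))
  expect_equal(unname(sch$tips[c("a", "b")]), c("S", "M"))
})

test_that("assignment is invariant to input row order", {
  w <- threeSpeciesWorld()
  sch1 <- assignCategories(w$occ, w$traits, "three_cat")
  occR <- w$occ[c(3, 1, 2), ]
  class(occR) <- class(w$occ)
  sch2 <- assignCategories(occR, w$traits, "three_cat")
  expect_identical(sch1$tips[sort(names(sch1$tips))],
                   sch2$tips[sort(names(sch2$tips))])
})

test_that("errors: taxa without areas, occupancy without traits", {
  traits <- traitTable(c("a", "b"), c(50, 60))
  occ <- occupancyTable("isl", "island", "a")
  expect_error(assignCategories(occ, traits, "three_cat"), "no area")
})

test_that("planted displaced tiers are recovered exactly", {
  # three clear tiers; every area holds one taxon per tier
  set.seed(1)
  sizes <- stats::setNames(c(stats::runif(6, 45, 50), stats::runif(6, 63, 68),
                             stats::runif(6, 90, 95)),
                           paste0("sp", 1:18))
  tier <- rep(c("S", "M", "L"), each = 6)
  names(tier) <- names(sizes)
  occ <- simulateIslandCommunities(sizes, nAreas = 10, speciesPerArea = 3,
                                   structure = "displaced", minGap = 10,
                                   seed = 5)
  traits <- traitTable(names(sizes), sizes)
  occAll <- occ[occ$taxon %in% occ$taxon, ]
  sch <- assignCategories(occ, traits[traits$taxon %in% occ$taxon, ],
                          "three_cat")
  expect_identical(unname(sch$tips), unname(tier[names(sch$tips)]))
})

test_that("internal-node painting covers every node and validates category", {
  tr <- simulateYule(8, crownAge = 5, seed = 2)
  tips <- stats::setNames(rep(c("S", "M"), 4), tr$tip.label)
  sch <- regimeScheme("three_cat", tips)
  pM <- paintInternalNodes(tr, sch)
  expect_equal(unname(unique(pM$nodes)), "M")
  expect_length(pM$nodes, tr$Nnode)
  pL <- paintInternalNodes(tr, sch, "L")
  expect_equal(unname(unique(pL$nodes)), "L")
  expect_error(paintInternalNodes(tr, sch, "I"), "not valid")
  expect_error(paintInternalNodes(tr, regimeScheme("three_cat",
    tips[-1]), "M"), "does not cover")
})

test_that("randomization preserves counts (permute) or is uniform", {
  tr <- simulateYule(30, crownAge = 5, seed = 3)
  set.seed(4)
  tips <- stats::setNames(sample(c("S", "M", "L"), 30, replace = TRUE),
                          tr$tip.label)
  sch <- paintInternalNodes(tr, regimeScheme("three_cat", tips))
  rp <- randomizeRegimes(sch, "permute", seed = 9)
  expect_identical(sort(unname(rp$tips)), sort(unname(sch$tips)))
  expect_identical(rp$nodes, sch$nodes)
  expect_identical(randomizeRegimes(sch, "permute", seed = 9)$tips, rp$tips)
  # uniform: aggregate frequencies over many draws ~ 1/3 each
  draws <- unlist(lapply(1:100, function(i)
    randomizeRegimes(sch, "uniform", seed = i)$tips))
  freq <- table(draws) / length(draws)
  se <- sqrt((1 / 3) * (2 / 3) / length(draws))
  expect_true(all(abs(freq - 1 / 3) < 3 * se))
  # I is never randomized
  s4 <- regimeScheme("four_cat", stats::setNames(rep("I", 30), tr$tip.label),
                     categories = c("S", "M", "L", "I"))
  expect_error(randomizeRegimes(s4, "permute", 1), "three-category")
})

test_that("schemes round-trip through CSV + JSON sidecar", {
  tr <- simulateYule(6, crownAge = 5, seed = 5)
  tips <- stats::setNames(rep(c("S", "L"), 3), tr$tip.label)
  sch <- paintInternalNodes(tr, regimeScheme("three_cat", tips), "M")
  f <- tempfile(fileext = ".csv")
  writeRegimeScheme(sch, f)
  back <- readRegimeScheme(f)
  expect_identical(back$tips[names(sch$tips)], sch$tips)
  expect_identical(back$nodes[names(sch$nodes)], sch$nodes)
  expect_identical(back$id, sch$id)
})
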