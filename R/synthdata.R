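#' Simulation configuration for trait evolution
#'
#' Bundles the parameters of the generating process: model (BM, EB or OU),
#' stochastic intensity sigma^2 (trait-units^2/Myr, optionally per regime),
#' pull strength alpha (1/Myr, optionally per regime), per-regime optima theta
#' (trait units), early-burst decay r (1/Myr, <= 0) and root state z0.
#'
#' @param model One of `"BM"`, `"EB"`, `"OU"`.
#' @param sigma2 Positive scalar or named per-regime vector.
#' @param alpha Non-negative scalar or named per-regime vector (OU only).
#' @param theta Named per-regime vector of optima (OU only); a scalar is
#'   recycled to a single regime named `"1"`.
#' @param r Early-burst decay rate, `<= 0` (EB only).
#' @param z0 Root state.
#' @return A list of class `simulationConfig`.
#' @export
simulationConfig <- function(model = c("BM", "EB", "OU"), sigma2 = 1,
                             alpha = 0, theta = NULL, r = 0, z0 = 0) {
  model <- match.arg(model)
  if (any(sigma2 <= 0)) stop("sigma2 must be > 0")
  if (any(alpha < 0)) stop("alpha must be >= 0")
  if (r > 0) stop("EB decay rate must be <= 0")
  if (model == "OU" && any(alpha > 0) && is.null(theta))
    stop("OU with alpha > 0 requires theta")
  if (!is.null(theta) && is.null(names(theta)) && length(theta) == 1L)
    names(theta) <- "1"
  structure(list(model = model, sigma2 = sigma2, alpha = alpha,
                 theta = theta, r = r, z0 = z0),
            class = "simulationConfig")
}

#' Simulate a Yule (pure-birth) tree
#'
#' Topology and branching times come from a constant-rate pure-birth process
#' conditioned on the number of tips ([ape::rphylo] with zero death rate).
#' When `crownAge` is given the tree is rescaled so every root-to-tip depth
#' equals it exactly, emulating a dated chronogram.
#'
#' @param nTips Number of tips (>= 3); ignored under `condition = "age"`.
#' @param birthRate Speciation rate (1/Myr); default 1 when only `crownAge`
#'   is given (the rescaling removes the rate's effect on depth).
#' @param crownAge Target crown age (Myr), or `NULL` to keep raw depths.
#'   Under `condition = "age"` this is the simulated duration.
#' @param seed Integer seed; the same seed always yields the same tree.
#' @param condition `"tips"` (default; the process is conditioned on
#'   `nTips`, depths optionally rescaled to `crownAge`) or `"age"` (forward
#'   simulation from two crown lineages for `crownAge` Myr, tip number
#'   random with expectation `2 * exp(birthRate * crownAge)`).
#' @return An ultrametric, bifurcating [ape::phylo] with tips `t1..tn`.
#' @export
simulateYule <- function(nTips = NULL, birthRate = NULL, crownAge = NULL,
                         seed = 1, condition = c("tips", "age")) {
  condition <- match.arg(condition)
  if (condition == "age") {
    if (is.null(birthRate) || is.null(crownAge))
      stop("condition = 'age' needs birthRate and crownAge")
    if (birthRate <= 0 || crownAge <= 0) stop("invalid rates")
    set.seed(seed)
    grow <- function(t0) {
      w <- stats::rexp(1, birthRate)
      if (t0 + w >= crownAge)
        return(sprintf(":%.10f", crownAge - t0))
      left <- grow(t0 + w)
      right <- grow(t0 + w)
      sprintf("(%s,%s):%.10f", left, right, w)
    }
    nwk <- sprintf("(%s,%s);", grow(0), grow(0))
    tree <- ape::read.tree(text = nwk)
    tree$tip.label <- paste0("t", seq_along(tree$tip.label))
    validatePhylogeny(tree)
    return(tree)
  }
  if (is.null(nTips) || nTips < 3) stop("nTips must be >= 3")
  if (is.null(birthRate)) {
    if (is.null(crownAge)) stop("give birthRate or crownAge")
    birthRate <- 1
  }
  if (birthRate <= 0) stop("birthRate must be > 0")
  set.seed(seed)
  tree <- ape::rphylo(nTips, birth = birthRate, death = 0)
  if (!is.null(crownAge)) {
    if (crownAge <= 0) stop("crownAge must be > 0")
    depth <- max(nodeDepths(tree)[seq_len(nTips)])
    tree$edge.length <- tree$edge.length * (crownAge / depth)
  }
  validatePhylogeny(tree)
  tree
}

#' Simulate trait evolution along a tree
#'
#' Values are drawn by exact per-branch Gaussian transitions (no Euler
#' discretisation): under BM the child is `Normal(parent, sigma2 * t)`; under
#' EB the branch variance is `sigma2 * (exp(r*t1) - exp(r*t0)) / r` (time
#' measured from the root); under OU the child is
#' `Normal(parent * exp(-a*t) + theta * (1 - exp(-a*t)),
#'         sigma2 * (1 - exp(-2*a*t)) / (2*a))`
#' with the `a -> 0` limit handled analytically. The regime of a branch is
#' the regime of its child node.
#'
#' @param tree A valid [ape::phylo].
#' @param config A [simulationConfig].
#' @param regimes A [regimeScheme] mapping tips and internal nodes to
#'   categories, or `NULL` for a single regime.
#' @param seed Integer seed.
#' @return List with `traits` (a [traitTable] of tip values), `tipStates`
#'   (named numeric) and `nodeStates` (numeric indexed by internal node id).
#' @export
simulateTrait <- function(tree, config, regimes = NULL, seed = 1) {
  stopifnot(inherits(config, "simulationConfig"))
  validatePhylogeny(tree)
  n <- length(tree$tip.label)
  nn <- tree$Nnode
  multi <- length(config$sigma2) > 1L || length(config$alpha) > 1L ||
    length(config$theta) > 1L
  if (multi && is.null(regimes))
    stop("regimes required when parameters differ among >1 regime")
  branchCat <- rep("1", nrow(tree$edge))
  if (!is.null(regimes)) {
    cat <- schemeNodeCategories(regimes, tree)
    branchCat <- cat[tree$edge[, 2]]
    missing <- setdiff(unique(branchCat), names(paramPerRegime(config)))
    if (length(missing))
      stop("regime categories not covered by config: ",
           paste(missing, collapse = ", "))
  }
  pr <- paramPerRegime(config)
  depth <- nodeDepths(tree)
  set.seed(seed)
  x <- numeric(n + nn)
  root <- n + 1L
  x[root] <- config$z0
  ord <- reorderEdgesPreorder(tree)
  for (e in ord) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    t <- tree$edge.length[e]
    par <- pr[[branchCat[e]]]
    if (config$model == "BM") {
      m <- x[p]; v <- par$sigma2 * t
    } else if (config$model == "EB") {
      m <- x[p]
      v <- par$sigma2 * expIntegral(-config$r, t) * exp(config$r * depth[p])
    } else {  # OU
      a <- par$alpha
      if (a == 0) {
        m <- x[p]; v <- par$sigma2 * t
      } else {
        w <- exp(-a * t)
        m <- x[p] * w + par$theta * (1 - w)
        v <- par$sigma2 * (1 - exp(-2 * a * t)) / (2 * a)
      }
    }
    x[ch] <- stats::rnorm(1, m, sqrt(max(v, 0)))
  }
  tip <- x[seq_len(n)]
  names(tip) <- tree$tip.label
  # built directly: simulated values may legitimately be <= 0 (e.g. z0 = 0),
  # so the positive-mean invariant of measured CBL tables does not apply
  traits <- data.frame(taxon = tree$tip.label, mean = unname(tip),
                       n = 1L, sd = NA_real_, stringsAsFactors = FALSE)
  class(traits) <- c("traitTable", "data.frame")
  list(traits = traits, tipStates = tip, nodeStates = x[(n + 1L):(n + nn)])
}

# per-regime parameter lists from a simulationConfig
paramPerRegime <- function(config) {
  regs <- unique(c(names(config$sigma2), names(config$alpha),
                   names(config$theta)))
  if (length(regs) == 0) regs <- "1"
  out <- lapply(regs, function(r) {
    list(sigma2 = pickParam(config$sigma2, r),
         alpha = pickParam(config$alpha, r),
         theta = if (is.null(config$theta)) 0 else pickParam(config$theta, r))
  })
  names(out) <- regs
  out
}

pickParam <- function(p, r) {
  if (length(p) == 1L && is.null(names(p))) return(unname(p))
  if (r %in% names(p)) return(unname(p[r]))
  if (length(p) == 1L) return(unname(p))
  stop("no parameter value for regime ", r)
}

#' Simulate island communities with planted size structure
#'
#' Builds an occupancy table of `nAreas` areas each holding up to
#' `speciesPerArea` taxa. With `structure = "displaced"` co-occurring taxa are
#' chosen so that every pairwise size difference is at least `minGap` mm
#' (character displacement planted by construction); with
#' `structure = "random"` co-occupants are drawn without regard to size.
#' Taxa never placed in any multi-species area remain available as isolated
#' singletons.
#'
#' @param sizes Named numeric vector of taxon sizes (mm).
#' @param nAreas Number of areas to create.
#' @param speciesPerArea Target taxa per area (1..5).
#' @param structure `"displaced"` or `"random"`.
#' @param minGap Minimum pairwise size separation (mm) under `"displaced"`.
#' @param seed Integer seed.
#' @param isolateLeftovers Give every taxon not placed in any community its
#'   own single-species area (an isolated island), so the occupancy table
#'   covers the whole taxon pool.
#' @return An [occupancyTable] with areas `area1..areaN` (kind `"island"`),
#'   plus `solo1..soloK` when `isolateLeftovers` is set.
#' @export
simulateIslandCommunities <- function(sizes, nAreas, speciesPerArea = 3,
                                      structure = c("displaced", "random"),
                                      minGap = 8, seed = 1,
                                      isolateLeftovers = FALSE) {
  structure <- match.arg(structure)
  if (speciesPerArea < 1 || speciesPerArea > 5)
    stop("speciesPerArea must be in 1..5")
  if (length(sizes) < speciesPerArea)
    stop("not enough taxa to fill an area")
  if (is.null(names(sizes))) stop("sizes must be named by taxon")
  set.seed(seed)
  area <- character(); taxon <- character()
  for (i in seq_len(nAreas)) {
    if (structure == "random") {
      pick <- sample(names(sizes), speciesPerArea)
    } else {
      pick <- sampleDisplaced(sizes, speciesPerArea, minGap)
      if (is.null(pick))
        stop("infeasible size gap: no set of ", speciesPerArea,
             " taxa separated by >= ", minGap, " mm")
    }
    area <- c(area, rep(paste0("area", i), length(pick)))
    taxon <- c(taxon, pick)
  }
  if (isolateLeftovers) {
    left <- setdiff(names(sizes), taxon)
    if (length(left)) {
      area <- c(area, paste0("solo", seq_along(left)))
      taxon <- c(taxon, left)
    }
  }
  occupancyTable(area, "island", taxon)
}

# random maximal search for a size-separated community
sampleDisplaced <- function(sizes, k, gap) {
  for (try in seq_len(200)) {
    ord <- sample(names(sizes))
    pick <- character()
    for (tx in ord) {
      if (all(abs(sizes[tx] - sizes[pick]) >= gap)) pick <- c(pick, tx)
      if (length(pick) == k) return(pick)
    }
  }
  NULL
}

#' @rdname simulationConfig
#' @param file YAML path mirroring the `simulationConfig` fields.
#' @export
readSimulationConfig <- function(file) {
  y <- yaml::read_yaml(file)
  do.call(simulationConfig, y[intersect(names(y),
    c("model", "sigma2", "alpha", "theta", "r", "z0"))])
}
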