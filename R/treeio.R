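#' Read and validate a Newick phylogeny
#'
#' Wraps [ape::read.tree()] with the validation this package's likelihoods
#' assume: a single root, unique non-empty tip labels, branch lengths on every
#' edge and no negative lengths. Square-bracket comments are stripped and
#' quoted labels are accepted (BEAST / IQ-TREE interoperability); node support
#' values stored as node labels are ignored.
#'
#' @param text Newick string, or `NULL` when `file` is given.
#' @param file Path to a Newick file.
#' @param resolvePolytomies Replace multifurcations by bifurcations with
#'   zero-length internal branches, resolving children in input order.
#' @param defaultBranchLength Value substituted for missing branch lengths;
#'   when `NULL` (default) missing lengths are an error.
#' @return A validated [ape::phylo] object (edge lengths in Myr by convention).
#' @export
readNewickTree <- function(text = NULL, file = NULL, resolvePolytomies = FALSE,
                           defaultBranchLength = NULL) {
  if (is.null(text) && is.null(file)) stop("supply 'text' or 'file'")
  if (is.null(text)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  text <- gsub("\\[[^]]*\\]", "", text)  # strip comments
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("malformed Newick string: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("malformed Newick string")
  if (inherits(tree, "multiPhylo")) tree <- tree[[1L]]
  if (is.null(tree$edge.length)) {
    if (is.null(defaultBranchLength))
      stop("tree has no branch lengths and no default is configured")
    tree$edge.length <- rep(defaultBranchLength, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    if (is.null(defaultBranchLength))
      stop("missing branch lengths and no default is configured")
    tree$edge.length[is.na(tree$edge.length)] <- defaultBranchLength
  }
  tree$tip.label <- normalizeTaxon(gsub("^'|'$", "", tree$tip.label))
  # a rooted binary tree has exactly nTip - 1 internal nodes; ape::is.binary
  # would let a trifurcating root pass as "binary unrooted"
  if (resolvePolytomies && tree$Nnode < length(tree$tip.label) - 1L) {
    tree <- ape::multi2di(tree, random = FALSE)
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  validatePhylogeny(tree)
  tree
}

#' Validate the structural invariants of a phylogeny
#'
#' @param tree A [ape::phylo] object.
#' @return The tree, invisibly; errors describe the violated invariant.
#' @export
validatePhylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  n <- length(tree$tip.label)
  if (n < 2) stop("tree needs at least two tips")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  if (any(!nzchar(tree$tip.label))) stop("empty tip labels")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  # exactly one root: one node absent from the child column
  children <- tree$edge[, 2]
  parents <- tree$edge[, 1]
  roots <- setdiff(parents, children)
  if (length(roots) != 1L) stop("tree must have exactly one root")
  if (anyDuplicated(children)) stop("a node has more than one parent")
  d <- nodeDepths(tree)
  if (any(d[seq_len(n)] <= 0)) stop("zero root-to-tip depth")
  invisible(tree)
}

#' Write a tree as Newick
#'
#' @param tree A [ape::phylo] object.
#' @param file Optional path; when `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when written to file).
#' @export
writeNewickTree <- function(tree, file = NULL) {
  s <- ape::write.tree(tree)
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

# depth (distance from root) of every node, tips first then internal nodes
nodeDepths <- function(tree) {
  n <- length(tree$tip.label)
  nn <- tree$Nnode
  depth <- numeric(n + nn)
  root <- n + 1L
  # edges in preorder so parents are visited before children
  ord <- reorderEdgesPreorder(tree)
  for (e in ord) {
    p <- tree$edge[e, 1]
    c <- tree$edge[e, 2]
    depth[c] <- depth[p] + tree$edge.length[e]
  }
  depth
}

reorderEdgesPreorder <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  # postorder visits children before parents; reverse gives a valid preorder,
  # but we must map back to the original edge row indices
  ord <- rev(seq_len(nrow(tr$edge)))
  key <- paste(tr$edge[, 1], tr$edge[, 2])
  orig <- match(key[ord], paste(tree$edge[, 1], tree$edge[, 2]))
  orig
}

# edge x tip incidence: row e true for tips descended from the child of e
edgeTipIncidence <- function(tree) {
  n <- length(tree$tip.label)
  ne <- nrow(tree$edge)
  post <- ape::reorder.phylo(tree, "postorder")
  key <- paste(tree$edge[, 1], tree$edge[, 2])
  M <- matrix(FALSE, ne, n)
  below <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) below[[i]] <- i
  for (e in seq_len(ne)) {
    p <- post$edge[e, 1]; ch <- post$edge[e, 2]
    orig <- match(paste(p, ch), key)
    M[orig, below[[ch]]] <- TRUE
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  M
}

#' Brownian-motion covariance of a phylogeny
#'
#' Entry (i, j) is the shared root-to-MRCA path length of tips i and j; the
#' diagonal holds root-to-tip depths. This is the Gram matrix underlying every
#' Gaussian likelihood in the package.
#'
#' @param tree A valid [ape::phylo] object.
#' @return A symmetric positive semi-definite tips-by-tips matrix (Myr),
#'   dimnames the tip labels.
#' @export
bmCovariance <- function(tree) {
  validatePhylogeny(tree)
  M <- edgeTipIncidence(tree)
  V <- crossprod(M * sqrt(tree$edge.length))
  dimnames(V) <- list(tree$tip.label, tree$tip.label)
  V
}

#' Test whether a tree is ultrametric
#'
#' @param tree A valid [ape::phylo] object.
#' @param relTol Relative tolerance on the depth spread (fraction of the
#'   maximum root-to-tip depth).
#' @return List with `ultrametric` (flag), `spread` (max minus min depth, Myr)
#'   and `maxDepth`.
#' @export
checkUltrametric <- function(tree, relTol = 1e-6) {
  validatePhylogeny(tree)
  d <- nodeDepths(tree)[seq_along(tree$tip.label)]
  spread <- max(d) - min(d)
  list(ultrametric = spread <= relTol * max(d), spread = spread,
       maxDepth = max(d))
}

#' Construct or read a trait table
#'
#' A trait table stores one row per taxon: mean condylobasal length (CBL, mm),
#' specimen count and optional standard deviation, with optional per-specimen
#' records (value + island) attached as the `"specimens"` attribute. When
#' specimen records exist for a taxon the stored mean must equal their
#' arithmetic mean.
#'
#' @param taxon Character vector of taxon names (unique after whitespace
#'   normalisation).
#' @param mean Mean trait values (mm, positive).
#' @param n Specimen counts (integer >= 1; default 1).
#' @param sd Optional per-taxon standard deviations (mm).
#' @param specimens Optional data.frame with columns `taxon`, `value`,
#'   `island`.
#' @return A `data.frame` of class `traitTable` with columns `taxon`, `mean`,
#'   `n`, `sd`.
#' @export
traitTable <- function(taxon, mean, n = 1L, sd = NA_real_, specimens = NULL) {
  taxon <- normalizeTaxon(taxon)
  tab <- data.frame(taxon = taxon, mean = as.numeric(mean),
                    n = as.integer(n), sd = as.numeric(sd),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(tab$taxon)) stop("duplicate taxon names in trait table")
  if (any(!is.finite(tab$mean)) || any(tab$mean <= 0))
    stop("trait means must be positive")
  if (any(tab$n < 1L)) stop("specimen counts must be >= 1")
  if (!is.null(specimens)) {
    specimens$taxon <- normalizeTaxon(specimens$taxon)
    for (tx in unique(specimens$taxon)) {
      if (!tx %in% tab$taxon) stop("specimen rows for unknown taxon: ", tx)
      m <- mean(specimens$value[specimens$taxon == tx])
      if (abs(m - tab$mean[tab$taxon == tx]) > 1e-9)
        stop("stored mean for ", tx, " differs from mean of specimen rows")
    }
    attr(tab, "specimens") <- specimens
  }
  class(tab) <- c("traitTable", "data.frame")
  tab
}

#' @rdname traitTable
#' @param file CSV path with header `taxon, mean_cbl_mm, n, sd_mm`.
#' @param specimenFile Optional CSV path with header `taxon, cbl_mm, island`.
#' @export
readTraitTable <- function(file, specimenFile = NULL) {
  raw <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("taxon", "mean_cbl_mm")
  if (!all(need %in% names(raw)))
    stop("trait CSV needs columns: taxon, mean_cbl_mm[, n, sd_mm]")
  spec <- NULL
  if (!is.null(specimenFile)) {
    s <- utils::read.csv(specimenFile, stringsAsFactors = FALSE)
    if (!all(c("taxon", "cbl_mm", "island") %in% names(s)))
      stop("specimen CSV needs columns: taxon, cbl_mm, island")
    spec <- data.frame(taxon = s$taxon, value = s$cbl_mm, island = s$island,
                       stringsAsFactors = FALSE)
  }
  traitTable(raw$taxon, raw$mean_cbl_mm,
             n = if ("n" %in% names(raw)) raw$n else 1L,
             sd = if ("sd_mm" %in% names(raw)) raw$sd_mm else NA_real_,
             specimens = spec)
}

#' @rdname traitTable
#' @param x A `traitTable`.
#' @export
writeTraitTable <- function(x, file) {
  utils::write.csv(data.frame(taxon = x$taxon, mean_cbl_mm = x$mean,
                              n = x$n, sd_mm = x$sd),
                   file, row.names = FALSE)
  invisible(file)
}

#' Construct or read an occupancy table
#'
#' Long-format table of which taxa are present in which area (island,
#' archipelago or continental area). Every taxon must appear in at least one
#' area.
#'
#' @param area,areaKind,taxon Parallel vectors; `areaKind` one of
#'   `"island"`, `"archipelago"`, `"continent"`.
#' @return A `data.frame` of class `occupancyTable`.
#' @export
occupancyTable <- function(area, areaKind, taxon) {
  kind <- match.arg(areaKind, c("island", "archipelago", "continent"),
                    several.ok = TRUE)
  tab <- data.frame(area = as.character(area),
                    area_kind = rep_len(kind, length(area)),
                    taxon = normalizeTaxon(taxon), stringsAsFactors = FALSE)
  if (any(!nzchar(tab$area))) stop("empty area names")
  if (nrow(tab) == 0) stop("occupancy table is empty")
  class(tab) <- c("occupancyTable", "data.frame")
  tab
}

#' @rdname occupancyTable
#' @param file CSV path with header `area, area_kind, taxon`.
#' @export
readOccupancyTable <- function(file) {
  raw <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("area", "area_kind", "taxon") %in% names(raw)))
    stop("occupancy CSV needs columns: area, area_kind, taxon")
  occupancyTable(raw$area, raw$area_kind, raw$taxon)
}

#' @rdname occupancyTable
#' @param x An `occupancyTable`.
#' @export
writeOccupancyTable <- function(x, file) {
  utils::write.csv(as.data.frame(x), file, row.names = FALSE)
  invisible(file)
}

#' Align a tree, trait table and occupancy table into a consistent triple
#'
#' The tree is pruned to taxa with trait data. Taxa that have traits (and
#' possibly occupancy) but no tip in the tree — recently extinct or
#' unsequenced species — are retained and flagged `"context-only"`: they
#' participate in sympatry-based category assignment but never enter a
#' likelihood. Every drop and flag is listed in the report.
#'
#' @param tree A [ape::phylo] object.
#' @param traits A [traitTable].
#' @param occupancy Optional [occupancyTable].
#' @return List with `tree`, `traits`, `occupancy`, `contextOnly` (taxon
#'   names) and `report` (character vector of actions).
#' @export
alignData <- function(tree, traits, occupancy = NULL) {
  validatePhylogeny(tree)
  report <- character()
  common <- intersect(tree$tip.label, traits$taxon)
  if (length(common) == 0)
    stop("no overlap between tree tips and trait taxa")
  dropTips <- setdiff(tree$tip.label, common)
  if (length(dropTips)) {
    tree <- ape::drop.tip(tree, dropTips)
    report <- c(report, paste0("dropped tip without trait data: ", dropTips))
  }
  contextOnly <- setdiff(traits$taxon, tree$tip.label)
  if (length(contextOnly))
    report <- c(report,
                paste0("flagged context-only (trait but no tip): ", contextOnly))
  if (!is.null(occupancy)) {
    unknown <- setdiff(occupancy$taxon, traits$taxon)
    if (length(unknown)) {
      occupancy <- occupancy[!occupancy$taxon %in% unknown, , drop = FALSE]
      report <- c(report, paste0("dropped occupancy row without trait data: ",
                                 unknown))
    }
  }
  list(tree = tree, traits = traits, occupancy = occupancy,
       contextOnly = contextOnly, report = report)
}

# named trait vector ordered like the tree's tips
traitVector <- function(tree, traits, log = FALSE) {
  idx <- match(tree$tip.label, traits$taxon)
  if (anyNA(idx)) stop("tips without trait data: ",
                       paste(tree$tip.label[is.na(idx)], collapse = ", "))
  y <- traits$mean[idx]
  names(y) <- tree$tip.label
  if (log) y <- base::log(y)
  y
}
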