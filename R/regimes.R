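#' Selective-regime schemes
#'
#' A regime scheme maps every tip (and, after painting, every internal node)
#' of the working tree to a size category: `"S"`, `"M"`, `"L"` and — under the
#' four-category scheme — `"I"` for taxa never sympatric with another
#' pteropodine. The scheme is the hypothesis handed to the multi-optimum
#' (Hansen) Ornstein-Uhlenbeck model: one optimum per category.
#'
#' @param id Scheme identifier: `"three_cat"`, `"four_cat"` or `"random"`.
#' @param tips Named character vector, taxon -> category.
#' @param nodes Named character vector, internal node id -> category (empty
#'   until [paintInternalNodes()] is applied).
#' @param categories Category levels of the scheme.
#' @param seed Seed recorded for randomized schemes.
#' @param provenance Per-taxon notes on which areas/rules produced the label.
#' @return An object of class `regimeScheme`.
#' @export
regimeScheme <- function(id, tips, nodes = character(),
                         categories = c("S", "M", "L"), seed = NULL,
                         provenance = NULL) {
  if (!id %in% c("three_cat", "four_cat", "random"))
    stop("unknown scheme id: ", id)
  if (id == "three_cat" && "I" %in% tips)
    stop("three_cat scheme must not contain category 'I'")
  if (any(!tips %in% categories))
    stop("tip category outside scheme categories")
  if (length(nodes) && any(!nodes %in% categories))
    stop("node category outside scheme categories")
  if (id == "random" && is.null(seed))
    stop("random schemes must record their seed")
  structure(list(id = id, tips = tips, nodes = nodes,
                 categories = categories, seed = seed,
                 provenance = provenance),
            class = "regimeScheme")
}

#' @export
print.regimeScheme <- function(x, ...) {
  cat("Regime scheme '", x$id, "': ", length(x$tips), " tips in categories {",
      paste(x$categories, collapse = ", "), "}\n", sep = "")
  print(table(factor(x$tips, levels = x$categories)))
  if (length(x$nodes))
    cat("internal nodes painted:",
        paste(unique(x$nodes), collapse = ", "), "\n")
  invisible(x)
}

# categories for all nodes (tips then internals) of `tree`, as a character
# vector indexed by node id; errors if the scheme does not cover the tree
schemeNodeCategories <- function(scheme, tree) {
  n <- length(tree$tip.label)
  tipCat <- scheme$tips[tree$tip.label]
  if (anyNA(tipCat))
    stop("tips without regime assignment: ",
         paste(tree$tip.label[is.na(tipCat)], collapse = ", "))
  if (length(scheme$nodes) == 0)
    stop("internal nodes not painted; call paintInternalNodes() first")
  nodeIds <- as.character((n + 1L):(n + tree$Nnode))
  nodeCat <- scheme$nodes[nodeIds]
  if (anyNA(nodeCat))
    stop("internal nodes without regime assignment")
  unname(c(tipCat, nodeCat))
}

#' Assign size categories from sympatry and relative size
#'
#' Reproduces the sympatry-based categorisation: in every area the
#' co-occurring species are labelled by relative size, and each taxon's
#' global category is the one it falls into most commonly across its areas.
#' Taxa that are alone in every area they occupy go to `"M"` under the
#' three-category scheme or to their own `"I"` category under the
#' four-category scheme.
#'
#' Per-area rules: three sympatric species are ranked small/medium/large
#' directly; areas with two or four-plus species are labelled by membership
#' in global tercile bands spanning the size range of all sympatric taxa,
#' with a minimum-gap rule splitting two same-band species into adjacent
#' bands when their difference exceeds `minGapFrac` of the global range.
#'
#' @param occupancy An [occupancyTable].
#' @param traits A [traitTable] holding every occurring taxon (including
#'   context-only taxa such as recently extinct species).
#' @param scheme `"three_cat"` or `"four_cat"`.
#' @param minGapFrac Minimum-gap threshold for two-species areas, as a
#'   fraction of the global sympatric size range (default 0.05).
#' @param tieBreak `"error"` (default) or `"prefer_middle"` for taxa whose
#'   modal category is tied.
#' @param contextOnly Taxa that inform per-area labels but receive no tip
#'   mapping (absent from the working tree).
#' @return A [regimeScheme] with tip assignments and per-taxon provenance.
#' @export
assignCategories <- function(occupancy, traits,
                             scheme = c("three_cat", "four_cat"),
                             minGapFrac = 0.05,
                             tieBreak = c("error", "prefer_middle"),
                             contextOnly = character()) {
  scheme <- match.arg(scheme)
  tieBreak <- match.arg(tieBreak)
  sizes <- stats::setNames(traits$mean, traits$taxon)
  noArea <- setdiff(traits$taxon, occupancy$taxon)
  if (length(noArea))
    stop("taxa with no area in the occupancy table: ",
         paste(noArea, collapse = ", "))
  unknown <- setdiff(occupancy$taxon, names(sizes))
  if (length(unknown))
    stop("occupancy taxa without trait data: ", paste(unknown, collapse = ", "))

  byArea <- split(occupancy$taxon, occupancy$area)
  richness <- vapply(byArea, length, 1L)
  sympatric <- unique(unlist(byArea[richness > 1]))
  isolated <- setdiff(unique(occupancy$taxon), sympatric)

  labels <- list()    # per-taxon vector of per-area labels
  notes <- list()
  if (length(sympatric)) {
    lo <- min(sizes[sympatric]); hi <- max(sizes[sympatric])
    rng <- hi - lo
    band <- function(x) {
      if (rng == 0) return(rep("M", length(x)))
      f <- (x - lo) / rng
      ifelse(f < 1 / 3, "S", ifelse(f < 2 / 3, "M", "L"))
    }
    for (a in names(byArea)[richness > 1]) {
      taxa <- byArea[[a]]
      sz <- sizes[taxa]
      k <- length(taxa)
      if (k == 3) {
        lab <- c("S", "M", "L")[rank(sz, ties.method = "first")]
        rule <- "rank-of-three"
      } else if (k == 2) {
        lab <- band(sz)
        rule <- "two-species-bands"
        if (lab[1] == lab[2]) {
          if (abs(sz[1] - sz[2]) >= minGapFrac * rng) {
            # same band but clearly separated: split into adjacent bands
            loIdx <- which.min(sz); hiIdx <- which.max(sz)
            if (lab[1] == "S") lab[hiIdx] <- "M"
            else if (lab[1] == "L") lab[loIdx] <- "M"
            else lab[loIdx] <- "S"
            rule <- "two-species-gap-split"
          }
        }
      } else {
        lab <- band(sz)
        rule <- "multi-species-bands"
      }
      for (i in seq_along(taxa)) {
        tx <- taxa[i]
        labels[[tx]] <- c(labels[[tx]], lab[i])
        notes[[tx]] <- c(notes[[tx]], paste0(a, ":", lab[i], " (", rule, ")"))
      }
    }
  }

  global <- character()
  for (tx in unique(occupancy$taxon)) {
    if (tx %in% isolated) {
      global[tx] <- if (scheme == "four_cat") "I" else "M"
      notes[[tx]] <- c(notes[[tx]], "isolated in every area")
      next
    }
    tab <- table(labels[[tx]])
    best <- names(tab)[tab == max(tab)]
    if (length(best) > 1L) {
      if (tieBreak == "error")
        stop("tie in modal category for '", tx, "' (",
             paste(best, collapse = " vs "),
             "); set tieBreak = 'prefer_middle' or supply a curated scheme")
      best <- if ("M" %in% best) "M" else {
        # tie not involving M: fall back to the taxon's own band position
        f <- (sizes[tx] - min(sizes[sympatric])) /
          max(diff(range(sizes[sympatric])), .Machine$double.eps)
        c("S", "M", "L")[findInterval(f, c(1 / 3, 2 / 3)) + 1L]
      }
      notes[[tx]] <- c(notes[[tx]], paste0("tie resolved to ", best))
    }
    global[tx] <- best[1]
  }

  cats <- if (scheme == "four_cat") c("S", "M", "L", "I") else c("S", "M", "L")
  tips <- global[setdiff(names(global), contextOnly)]
  regimeScheme(scheme, tips = tips, categories = cats,
               provenance = lapply(notes, paste, collapse = "; "))
}

#' Paint all internal nodes of a tree with one category
#'
#' The Hansen-model machinery needs a category on every branch; branch regime
#' is the regime of the branch's child node, so internal nodes must carry
#' categories. The default paints every internal node `"M"`; model fits are
#' typically repeated under `"S"`, `"M"` and `"L"` paintings as a sensitivity
#' sweep.
#'
#' @param tree Working tree whose tips the scheme must cover.
#' @param scheme A [regimeScheme].
#' @param category Single category for all internal nodes (default `"M"`).
#' @return The scheme with its `nodes` mapping filled in.
#' @export
paintInternalNodes <- function(tree, scheme, category = "M") {
  stopifnot(inherits(scheme, "regimeScheme"))
  if (!category %in% scheme$categories)
    stop("category '", category, "' not valid for scheme '", scheme$id, "'")
  missing <- setdiff(tree$tip.label, names(scheme$tips))
  if (length(missing))
    stop("scheme does not cover tips: ", paste(missing, collapse = ", "))
  n <- length(tree$tip.label)
  ids <- as.character((n + 1L):(n + tree$Nnode))
  scheme$nodes <- stats::setNames(rep(category, length(ids)), ids)
  scheme
}

#' Randomize tip categories (the OU3r null)
#'
#' `"permute"` shuffles the observed tip labels among taxa, preserving
#' category counts (the stricter null); `"uniform"` draws each tip's category
#' independently and uniformly from the scheme's categories. Internal-node
#' painting is left unchanged and the seed is recorded.
#'
#' @param scheme A three-category [regimeScheme].
#' @param mode `"permute"` (default) or `"uniform"`.
#' @param seed Integer seed.
#' @return A new [regimeScheme] with `id = "random"`.
#' @export
randomizeRegimes <- function(scheme, mode = c("permute", "uniform"), seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(scheme, "regimeScheme"))
  if ("I" %in% scheme$tips || "I" %in% scheme$categories)
    stop("only three-category schemes are randomized ('I' never randomized)")
  set.seed(seed)
  tips <- scheme$tips
  newCats <- if (mode == "permute") sample(unname(tips)) else
    sample(c("S", "M", "L"), length(tips), replace = TRUE)
  regimeScheme("random", stats::setNames(newCats, names(tips)),
               nodes = scheme$nodes, categories = scheme$categories,
               seed = seed)
}

#' Write / read a regime scheme
#'
#' The tip mapping goes to CSV (`taxon, category, provenance`); scheme id,
#' node painting, category levels and seed go to a JSON sidecar, so
#' hand-curated schemes can be supplied wherever a scheme is accepted.
#'
#' @param scheme A [regimeScheme].
#' @param file CSV path; the sidecar is `<file>.json`.
#' @export
writeRegimeScheme <- function(scheme, file) {
  prov <- vapply(names(scheme$tips), function(tx) {
    p <- scheme$provenance[[tx]]
    if (is.null(p)) "" else as.character(p)
  }, "")
  utils::write.csv(data.frame(taxon = names(scheme$tips),
                              category = unname(scheme$tips),
                              provenance = prov),
                   file, row.names = FALSE)
  side <- list(id = scheme$id, categories = scheme$categories,
               nodes = as.list(scheme$nodes))
  if (!is.null(scheme$seed)) side$seed <- scheme$seed
  jsonlite::write_json(side, paste0(file, ".json"), auto_unbox = TRUE)
  invisible(file)
}

#' @rdname writeRegimeScheme
#' @export
readRegimeScheme <- function(file) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  nodes <- unlist(side$nodes)
  if (is.null(nodes)) nodes <- character()
  regimeScheme(side$id, stats::setNames(tab$category, tab$taxon),
               nodes = nodes, categories = side$categories,
               seed = side$seed,
               provenance = stats::setNames(as.list(tab$provenance),
                                            tab$taxon))
}
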