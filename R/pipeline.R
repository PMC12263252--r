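# ---------------------------------------------------------------------------
# Configuration-driven end-to-end runs: align -> regimes -> signal -> model
# fits (with internal-node painting sweep) -> AICc comparison -> random-
# regime null -> ancestral states + per-category change -> DTT -> CV.
# ---------------------------------------------------------------------------

#' Build and validate an analysis configuration
#'
#' @param ... Configuration fields: `tree`/`traits`/`specimens`/`occupancy`
#'   (paths or objects), or `synthetic` (a list understood by
#'   [synthesizeInputs()]); `scope` (`NULL`, `"genus_only"` or
#'   `"frugivores"`, matched against the optional `scope` column of the
#'   trait CSV); `schemes` (subset of `"three_cat"`, `"four_cat"`);
#'   `paintings` (internal-node categories to sweep, default `"M"`);
#'   `models` (default BM, BMS, EB, OU1, OUM); `logTransform`; `nPerm`,
#'   `nSim`, `nReps`; `seed` (mandatory); `outputDir`.
#' @param file Optional YAML file whose fields are merged (explicit
#'   arguments win).
#' @return A validated list of class `analysisConfig`.
#' @export
analysisConfig <- function(..., file = NULL) {
  cfg <- list(...)
  if (!is.null(file)) {
    y <- yaml::read_yaml(file)
    for (nm in setdiff(names(y), names(cfg))) cfg[[nm]] <- y[[nm]]
  }
  defaults <- list(scope = NULL, schemes = c("three_cat", "four_cat"),
                   paintings = "M", tieBreak = "error",
                   models = c("BM", "BMS", "EB", "OU1", "OUM"),
                   logTransform = FALSE, nPerm = 999, nSim = 1000,
                   nReps = 100, outputDir = tempfile("islandOU-run-"))
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (is.null(cfg$seed)) stop("config error: a master seed is mandatory")
  if (is.null(cfg$synthetic) && is.null(cfg$tree))
    stop("config error: supply either input paths or a synthetic block")
  for (p in c("tree", "traits", "specimens", "occupancy")) {
    v <- cfg[[p]]
    if (is.character(v) && !file.exists(v))
      stop("config error: path for '", p, "' does not exist: ", v)
  }
  bad <- setdiff(cfg$models, MODEL_NAMES)
  if (length(bad)) stop("config error: unknown models ",
                        paste(bad, collapse = ", "))
  class(cfg) <- "analysisConfig"
  cfg
}

#' Generate a complete synthetic input set
#'
#' Emulates the study conditions: a Yule chronogram, a planted regime
#' scheme, traits evolved under a regime-dependent OU (or BM/EB) process and
#' island communities with displaced size structure. Defaults mirror the
#' empirical setting: 56 tips, 8.7 Myr crown age, four optima at
#' (93.4, 65.1, 47.5, 54.4) mm with alpha 0.60 /Myr and sigma^2 52 mm^2/Myr.
#'
#' @param spec List with optional elements `nTips`, `crownAge`, `model`,
#'   `sigma2`, `alpha`, `theta` (named per category), `r`, `z0`,
#'   `categories`, `painting`, `nAreas`, `speciesPerArea`, `minGap`.
#' @param seed Master seed.
#' @return List with `tree`, `traits`, `occupancy`, `scheme` (the true,
#'   painted scheme) and `trueStates`.
#' @export
synthesizeInputs <- function(spec = list(), seed = 1) {
  d <- list(nTips = 56, crownAge = 8.7, model = "OU", sigma2 = 52,
            alpha = 0.60,
            theta = c(L = 93.4, M = 65.1, S = 47.5, I = 54.4),
            r = 0, z0 = 65.1, painting = "M", nAreas = 12,
            speciesPerArea = 3, minGap = 8)
  for (nm in names(spec)) d[[nm]] <- spec[[nm]]
  tree <- simulateYule(d$nTips, crownAge = d$crownAge,
                       seed = deriveSeed(seed, "yule"))
  cats <- names(d$theta)
  if (is.null(cats)) cats <- "M"
  schemeId <- if ("I" %in% cats) "four_cat" else "three_cat"
  set.seed(deriveSeed(seed, "regimes"))
  tipCats <- sample(cats, d$nTips, replace = TRUE)
  scheme <- regimeScheme(schemeId,
                         stats::setNames(tipCats, tree$tip.label),
                         categories = if (schemeId == "four_cat")
                           c("S", "M", "L", "I") else c("S", "M", "L"))
  scheme <- paintInternalNodes(tree, scheme, d$painting)
  cfg <- simulationConfig(model = d$model, sigma2 = d$sigma2,
                          alpha = d$alpha, theta = d$theta, r = d$r,
                          z0 = d$z0)
  sim <- simulateTrait(tree, cfg, regimes = scheme,
                       seed = deriveSeed(seed, "trait"))
  occupancy <- tryCatch(
    simulateIslandCommunities(sim$tipStates, d$nAreas, d$speciesPerArea,
                              structure = "displaced", minGap = d$minGap,
                              seed = deriveSeed(seed, "areas"),
                              isolateLeftovers = TRUE),
    error = function(e) NULL)
  list(tree = tree, traits = sim$traits, occupancy = occupancy,
       scheme = scheme, trueStates = sim)
}

loadInputs <- function(cfg) {
  if (!is.null(cfg$synthetic))
    return(synthesizeInputs(cfg$synthetic, seed = cfg$seed))
  tree <- if (is.character(cfg$tree)) readNewickTree(file = cfg$tree)
          else cfg$tree
  traits <- if (is.character(cfg$traits))
    readTraitTable(cfg$traits, specimenFile = cfg$specimens) else cfg$traits
  if (!is.null(cfg$scope)) {
    sc <- attr(traits, "scope")
    if (is.null(sc)) stop("scope filtering requested but the trait table ",
                          "has no scope column")
    keep <- vapply(sc[traits$taxon], function(s)
      cfg$scope %in% strsplit(s, ";")[[1]], TRUE)
    traits <- traits[keep, , drop = FALSE]
    class(traits) <- c("traitTable", "data.frame")
  }
  occupancy <- if (is.character(cfg$occupancy))
    readOccupancyTable(cfg$occupancy) else cfg$occupancy
  list(tree = tree, traits = traits, occupancy = occupancy, scheme = NULL)
}

#' Run the full analysis pipeline
#'
#' Executes every stage the configuration requests and writes a report
#' bundle (JSON per stage, CSV tables, a publication-style comparison block
#' and a run log) under the configured output directory. Inputs are never
#' mutated; re-running with `resume = TRUE` skips stages whose outputs
#' already exist for the same configuration.
#'
#' @param config An [analysisConfig] (or list coerced through it).
#' @param resume Skip stages with existing outputs from the same config.
#' @return A list with every stage's result (`inputs`, `align`, `schemes`,
#'   `signal`, `fits`, `comparison`, `null`, `ancestral`, `change`, `dtt`,
#'   `cv`, `errors`).
#' @export
runAnalysis <- function(config, resume = FALSE) {
  if (!inherits(config, "analysisConfig"))
    config <- do.call(analysisConfig, config)
  out <- config$outputDir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  cfgHash <- configHash(config)
  logFile <- file.path(out, "run.log")
  logLine <- function(...) cat(format(Sys.time(), "%H:%M:%S"), ...,
                               "\n", file = logFile, append = TRUE)
  cat("islandOU run, seed ", config$seed, ", config hash ", cfgHash, "\n",
      "R ", as.character(getRversion()), ", ape ",
      as.character(utils::packageVersion("ape")), "\n",
      sep = "", file = logFile)
  bundle <- list(errors = character())
  fail <- function(stage, e) {
    msg <- paste0("stage '", stage, "' failed: ", conditionMessage(e))
    logLine(msg)
    bundle$errors <<- c(bundle$errors, msg)
    NULL
  }
  saveStage <- function(name, obj) {
    path <- file.path(out, paste0(name, ".json"))
    jsonlite::write_json(list(config_hash = cfgHash, result = obj), path,
                         auto_unbox = TRUE, digits = 10, force = TRUE,
                         pretty = TRUE)
  }
  stageDone <- function(name) {
    path <- file.path(out, paste0(name, ".json"))
    if (!resume || !file.exists(path)) return(FALSE)
    ok <- tryCatch(jsonlite::read_json(path)$config_hash == cfgHash,
                   error = function(e) FALSE)
    isTRUE(ok)
  }

  # inputs -----------------------------------------------------------------
  inputs <- tryCatch(loadInputs(config), error = function(e) fail("inputs", e))
  if (is.null(inputs)) return(invisible(bundle))
  al <- tryCatch(alignData(inputs$tree, inputs$traits, inputs$occupancy),
                 error = function(e) fail("align", e))
  if (is.null(al)) return(invisible(bundle))
  bundle$inputs <- inputs
  bundle$align <- al
  logLine("aligned: ", length(al$tree$tip.label), " tips, ",
          length(al$contextOnly), " context-only taxa")
  saveStage("align", list(tips = al$tree$tip.label,
                          contextOnly = al$contextOnly, report = al$report))

  # regime schemes ----------------------------------------------------------
  schemes <- list()
  if (!is.null(inputs$scheme)) {
    schemes[[inputs$scheme$id]] <- inputs$scheme
  } else if (!is.null(al$occupancy)) {
    for (sid in config$schemes) {
      s <- tryCatch(
        assignCategories(al$occupancy, al$traits, sid,
                         tieBreak = config$tieBreak,
                         contextOnly = al$contextOnly),
        error = function(e) fail(paste0("regimes-", sid), e))
      if (!is.null(s)) schemes[[sid]] <- s
    }
  }
  bundle$schemes <- schemes
  for (sid in names(schemes))
    writeRegimeScheme(schemes[[sid]],
                      file.path(out, paste0("scheme-", sid, ".csv")))

  tree <- al$tree; traits <- al$traits
  lg <- isTRUE(config$logTransform)

  # signal ------------------------------------------------------------------
  if (!stageDone("signal")) {
    sig <- tryCatch(
      phyloSignalReport(tree, traits, nPerm = config$nPerm,
                        seed = deriveSeed(config$seed, "signal"), log = lg),
      error = function(e) fail("signal", e))
    if (!is.null(sig)) {
      bundle$signal <- sig
      saveStage("signal", list(
        lambda = sig$lambda$lambda, lambda_p0 = sig$lambda$p0,
        K = sig$K$K, K_p = sig$K$p, delta = sig$delta$delta,
        delta_p1 = sig$delta$p1))
      logLine(sprintf("signal: lambda %.3f K %.3f delta %.3f",
                      sig$lambda$lambda, sig$K$K, sig$delta$delta))
    }
  }

  # model fits with painting sweep -------------------------------------------
  fits <- list()
  for (model in config$models) {
    needsScheme <- model %in% c("BMS", "OUM", "OUMV", "OUMA", "OUMVA")
    if (!needsScheme) {
      f <- tryCatch(
        fitModel(model, tree, traits, log = lg,
                 seed = deriveSeed(config$seed, paste0("fit-", model))),
        error = function(e) fail(paste0("fit-", model), e))
      if (!is.null(f)) fits[[model]] <- f
      next
    }
    for (sid in names(schemes)) {
      for (p in config$paintings) {
        sch <- tryCatch(paintInternalNodes(tree, schemes[[sid]], p),
                        error = function(e) NULL)
        if (is.null(sch)) next
        tag <- paste0(model, "-", sid, "-", p)
        f <- tryCatch(
          fitModel(model, tree, traits, sch, log = lg,
                   seed = deriveSeed(config$seed, paste0("fit-", tag))),
          error = function(e) fail(paste0("fit-", tag), e))
        if (!is.null(f)) fits[[tag]] <- f
      }
    }
  }
  bundle$fits <- fits
  if (length(fits) >= 2) {
    cmp <- tryCatch(compareFits(unname(fits)),
                    error = function(e) fail("compare", e))
    if (!is.null(cmp)) {
      cmp$fit <- names(fits)
      bundle$comparison <- cmp
      writeComparison(cmp, file.path(out, "comparison.csv"))
      saveStage("comparison", as.data.frame(cmp))
      logLine("best fit by AICc: ", names(fits)[which.min(cmp$AICc)])
    }
  }
  jsonlite::write_json(lapply(fits, unclass),
                       file.path(out, "fits.json"),
                       auto_unbox = TRUE, digits = 10, force = TRUE,
                       pretty = TRUE)

  # random-regime null --------------------------------------------------------
  if ("three_cat" %in% names(schemes) && config$nReps > 0 &&
      !stageDone("null")) {
    sch <- tryCatch(paintInternalNodes(tree, schemes$three_cat, "M"),
                    error = function(e) NULL)
    nul <- if (is.null(sch)) NULL else tryCatch(
      randomRegimeNull(tree, traits, sch, nReps = config$nReps,
                       seed = deriveSeed(config$seed, "null"), log = lg),
      error = function(e) fail("null", e))
    if (!is.null(nul)) {
      bundle$null <- nul
      saveStage("null", list(observedAICc = nul$observedAICc,
                             exceedance = nul$exceedance,
                             nReps = nul$nReps,
                             aiccDist = nul$aiccDist))
    }
  }

  # ancestral states + per-category change -----------------------------------
  anc <- tryCatch(ancestralBM(tree, traits, log = lg),
                  error = function(e) fail("ancestral", e))
  if (!is.null(anc)) {
    bundle$ancestral <- anc
    writeAncestral(anc, tree, file.path(out, "ancestral.csv"))
    best <- if ("four_cat" %in% names(schemes)) "four_cat"
            else names(schemes)[1]
    if (!is.null(best) && length(schemes)) {
      chg <- tryCatch(
        categoryChangeSummary(tree, traits, schemes[[best]], anc, log = lg),
        error = function(e) fail("change", e))
      if (!is.null(chg)) {
        bundle$change <- chg
        saveStage("change", chg$summary)
      }
    }
  }

  # disparity through time + intraspecific CV --------------------------------
  if (!stageDone("dtt")) {
    dd <- tryCatch(
      dtt(tree, traits, nSim = config$nSim,
          seed = deriveSeed(config$seed, "dtt"), log = lg),
      error = function(e) fail("dtt", e))
    if (!is.null(dd)) {
      bundle$dtt <- dd
      writeDtt(dd, file.path(out, "dtt.csv"))
      saveStage("dtt", list(MDI = dd$MDI, pPositive = dd$pPositive,
                            pNegative = dd$pNegative))
    }
  }
  spec <- attr(traits, "specimens")
  if (!is.null(spec)) {
    cv <- tryCatch(populationCV(spec), error = function(e) fail("cv", e))
    if (!is.null(cv)) {
      bundle$cv <- cv
      utils::write.csv(cv, file.path(out, "population-cv.csv"),
                       row.names = FALSE)
    }
  }
  logLine("run complete; errors: ", length(bundle$errors))
  invisible(bundle)
}

# order-independent hash of the configuration (djb2 over the YAML dump)
configHash <- function(cfg) {
  x <- cfg[setdiff(names(unclass(cfg)), "outputDir")]
  s <- yaml::as.yaml(x[order(names(x))])
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}
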