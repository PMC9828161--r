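#' Resolve a run configuration
#'
#' Accepts a YAML file path or a list and fills in defaults. Fields:
#' \code{seed}, \code{out_dir}, \code{n_species}, \code{visual_system}
#' (YAML path; default the packaged blackbird system), \code{thresholds},
#' \code{score_channel}, \code{score_threshold}, \code{overlap_threshold},
#' \code{strict_overlap}, \code{models}, \code{chains}, \code{iter},
#' \code{kfold_k}, and input paths \code{spectra}, \code{tree},
#' \code{traits}, \code{grid} (defaulting to the bundle files under
#' \code{out_dir}).
#'
#' @param config YAML path or list.
#' @return a completed configuration list.
#' @export
readRunConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    seed = 1, out_dir = "dichromatism_run", n_species = 77,
    visual_system = NULL, thresholds = c(1, 2, 3),
    score_channel = "combined", score_threshold = 2,
    overlap_threshold = 30, strict_overlap = TRUE,
    models = c("sympatry", "timing", "spacing", "null"),
    chains = 4, iter = 2000, kfold_k = 16, max_leapfrog = 32)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  for (nm in c("spectra", "tree", "traits", "grid", "scores"))
    if (is.null(config[[nm]]))
      config[[nm]] <- file.path(config$out_dir, switch(nm,
        spectra = "spectra.csv", tree = "tree.nwk", traits = "traits.csv",
        grid = "grid.csv", scores = "scores.csv"))
  config
}

.loadVisualSystem <- function(config) {
  if (is.null(config$visual_system)) blackbirdVisualSystem()
  else readVisualSystem(config$visual_system)
}

## append one stage record to out_dir/manifest.json
.updateManifest <- function(config, stage, files, warnings, elapsed) {
  path <- file.path(config$out_dir, "manifest.json")
  manifest <- if (file.exists(path))
    jsonlite::read_json(path, simplifyVector = FALSE) else
    list(package_version = as.character(packageVersion("dichromatR")),
         config_hash = .configHash(config), seed = config$seed,
         stages = list())
  sums <- as.list(tools::md5sum(files[file.exists(files)]))
  manifest$stages[[stage]] <- list(
    files = sums, wall_clock_s = round(elapsed, 3),
    warnings = as.list(warnings))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

.configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config[order(names(config))],
                              auto_unbox = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Condition signalled when a fit fails to converge
#' @param message condition message
#' @param call call
#' @return a condition object of class \code{dichromatR_nonconvergence}
#' @keywords internal
nonConvergenceError <- function(message, call = sys.call(-1)) {
  structure(class = c("dichromatR_nonconvergence", "error", "condition"),
            list(message = message, call = call))
}

#' Run one pipeline stage
#'
#' Stages communicate only via files under \code{config$out_dir}:
#' \describe{
#'   \item{simulate}{write a synthetic study bundle.}
#'   \item{jnd}{spectra -> specimen means -> patch JND summaries
#'     (\code{patch_contrasts.csv}).}
#'   \item{score}{patch summaries -> species scores
#'     (\code{species_scores.csv}) and monomorphic proportions
#'     (\code{monomorphic.csv}).}
#'   \item{sympatry}{traits + grid -> predictor table
#'     (\code{predictors.csv}) and pairwise overlaps
#'     (\code{overlaps.csv}).}
#'   \item{fit}{fit the configured models for the configured
#'     response; write \code{fit_<model>.csv} summaries. A non-converged
#'     fit raises a \code{dichromatR_nonconvergence} error and writes no
#'     summary.}
#'   \item{kfold}{K-fold ELPD per model and the comparison table
#'     (\code{model_comparison.csv}).}
#'   \item{report}{assemble the final predictor and comparison tables
#'     (\code{table_predictors.csv}, \code{table_comparison.csv}).}
#' }
#' Every stage appends to \code{manifest.json} (config hash, package
#' version, file checksums, wall clock, warnings).
#'
#' @param config list or YAML path (see [readRunConfig()]).
#' @param stage one of \code{"simulate"}, \code{"jnd"}, \code{"score"},
#'   \code{"sympatry"}, \code{"fit"}, \code{"kfold"}, \code{"report"}.
#' @return invisibly, the paths written by the stage.
#' @export
runStage <- function(config, stage = c("simulate", "jnd", "score",
                                       "sympatry", "fit", "kfold",
                                       "report")) {
  stage <- match.arg(stage)
  config <- readRunConfig(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings <- character()
  t0 <- proc.time()[["elapsed"]]
  out <- withCallingHandlers(
    .runStageImpl(config, stage),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  .updateManifest(config, stage, out, warnings,
                  proc.time()[["elapsed"]] - t0)
  for (w in warnings) warning(w, call. = FALSE)
  invisible(out)
}

.requireFiles <- function(...) {
  paths <- c(...)
  miss <- paths[!file.exists(paths)]
  if (length(miss))
    stop("missing input file(s) for this stage: ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible(paths)
}

.runStageImpl <- function(config, stage) {
  od <- config$out_dir
  switch(stage,
    simulate = {
      bundle <- simulateStudy(simulationConfig(nSpecies = config$n_species),
                              seed = config$seed,
                              vs = .loadVisualSystem(config))
      writeBundle(bundle, od)
    },
    jnd = {
      .requireFiles(config$spectra)
      vs <- .loadVisualSystem(config)
      spectra <- readSpectra(config$spectra)
      spectra <- resampleSpectra(spectra, wavelengths(vs))
      means <- averageReplicates(spectra)
      pc <- patchContrasts(means, vs)
      path <- file.path(od, "patch_contrasts.csv")
      write.csv(pc, path, row.names = FALSE)
      path
    },
    score = {
      pcPath <- .requireFiles(file.path(od, "patch_contrasts.csv"))
      pc <- read.csv(pcPath)
      scores <- scoreSpecies(pc, thresholds = config$thresholds)
      mono <- do.call(rbind, lapply(split(scores,
                        scores[c("channel", "threshold")], drop = TRUE),
        function(d) data.frame(channel = d$channel[1L],
                               threshold = d$threshold[1L],
                               proportionMonomorphic = mean(d$k == 0))))
      p1 <- file.path(od, "species_scores.csv")
      p2 <- file.path(od, "monomorphic.csv")
      write.csv(scores, p1, row.names = FALSE)
      write.csv(mono, p2, row.names = FALSE)
      c(p1, p2)
    },
    sympatry = {
      .requireFiles(config$traits, config$grid)
      grid <- readRangeGrid(config$grid)
      traits <- read.csv(config$traits)
      traits <- traits[c("species", "migration", "breedingSeasonMonths",
                         "landmass")]
      pred <- buildTraitTable(traits, grid,
                              overlapThreshold = config$overlap_threshold,
                              strict = config$strict_overlap)
      p1 <- file.path(od, "predictors.csv")
      p2 <- file.path(od, "overlaps.csv")
      write.csv(pred, p1, row.names = FALSE)
      write.csv(overlapTable(grid), p2, row.names = FALSE)
      c(p1, p2)
    },
    fit = {
      .requireFiles(file.path(od, "predictors.csv"),
                    file.path(od, "species_scores.csv"), config$tree)
      pred <- read.csv(file.path(od, "predictors.csv"))
      scores <- read.csv(file.path(od, "species_scores.csv"))
      scores <- scores[scores$channel == config$score_channel &
                       scores$threshold == config$score_threshold, ]
      k <- setNames(scores$k, scores$species)[pred$species]
      tree <- ape::read.tree(config$tree)
      C <- phyloCorrelation(tree, pred$species)
      paths <- character()
      for (m in config$models) {
        fit <- fitDichromatismModel(k, designMatrix(pred, m), C,
                                    chains = config$chains,
                                    iter = config$iter,
                                    maxLeapfrog = config$max_leapfrog,
                                    seed = config$seed, label = m)
        if (!fit@converged)
          stop(nonConvergenceError(sprintf(
            "model '%s' did not converge (max Rhat = %.3f); summaries withheld",
            m, max(fit@rhat))))
        s <- summarizePosterior(fit)
        tab <- s$predictors
        tab$model <- m
        tab$lambdaMedian <- if (is.null(s$lambda)) NA else s$lambda[["median"]]
        tab$lambdaLower <- if (is.null(s$lambda)) NA else s$lambda[["lower"]]
        tab$lambdaUpper <- if (is.null(s$lambda)) NA else s$lambda[["upper"]]
        tab$maxRhat <- s$maxRhat
        p <- file.path(od, sprintf("fit_%s.csv", m))
        write.csv(tab, p, row.names = FALSE)
        paths <- c(paths, p)
      }
      paths
    },
    kfold = {
      .requireFiles(file.path(od, "predictors.csv"),
                    file.path(od, "species_scores.csv"), config$tree)
      pred <- read.csv(file.path(od, "predictors.csv"))
      scores <- read.csv(file.path(od, "species_scores.csv"))
      scores <- scores[scores$channel == config$score_channel &
                       scores$threshold == config$score_threshold, ]
      k <- setNames(scores$k, scores$species)[pred$species]
      tree <- ape::read.tree(config$tree)
      C <- phyloCorrelation(tree, pred$species)
      results <- lapply(config$models, function(m)
        kfoldElpd(k, designMatrix(pred, m), C, K = config$kfold_k,
                  seed = config$seed, label = m,
                  chains = max(2, config$chains %/% 2),
                  iter = max(500, config$iter %/% 2),
                  maxLeapfrog = config$max_leapfrog))
      names(results) <- config$models
      cmp <- elpdCompare(results)
      p <- file.path(od, "model_comparison.csv")
      write.csv(cmp, p, row.names = FALSE)
      p
    },
    report = {
      fitPaths <- file.path(od, sprintf("fit_%s.csv", config$models))
      .requireFiles(fitPaths, file.path(od, "model_comparison.csv"))
      writeTables(
        predictors = do.call(rbind, lapply(fitPaths, read.csv)),
        comparison = read.csv(file.path(od, "model_comparison.csv")),
        dir = od)
    })
}

#' Write the final report tables
#'
#' Emits a model-comparison table (delta-ELPD and k-fold IC, each with
#' standard errors, best model at 0) and a predictor table (odds ratio,
#' 90\% HDI, pd, phylogenetic signal lambda) with rows whose pd is at or
#' above 0.90 flagged as reliable.
#'
#' @param predictors stacked per-model predictor summaries (as written by
#'   the fit stage).
#' @param comparison an [elpdCompare()] table (or its CSV re-read).
#' @param dir output directory.
#' @return invisibly, the two paths written.
#' @export
writeTables <- function(predictors, comparison, dir = ".") {
  predictors$reliable <- predictors$pd >= 0.90
  p1 <- file.path(dir, "table_predictors.csv")
  p2 <- file.path(dir, "table_comparison.csv")
  write.csv(predictors, p1, row.names = FALSE)
  write.csv(comparison, p2, row.names = FALSE)
  invisible(c(p1, p2))
}

#' Run several pipeline stages in order
#'
#' @param config list or YAML path (see [readRunConfig()]).
#' @param stages stages to run, in order.
#' @return invisibly, the configuration used.
#' @export
runPipeline <- function(config, stages = c("simulate", "jnd", "score",
                                           "sympatry", "fit", "kfold",
                                           "report")) {
  config <- readRunConfig(config)
  for (s in stages) {
    message("[dichromatR] stage: ", s)
    runStage(config, s)
  }
  invisible(config)
}
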