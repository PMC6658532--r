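# Config-driven pipeline runner: wires the analysis stages into reproducible
# runs with a content-hash manifest. The YAML run configuration names inputs,
# simulation parameters, thresholds and seeds; every stochastic stage
# receives an explicit seed and reruns are byte-identical.

#' Read a run configuration
#'
#' @param path YAML file with nested keys per stage (see [runPipeline()]).
#' @return the configuration list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  yaml::read_yaml(path)
}

writeManifest <- function(outDir) {
  files <- setdiff(list.files(outDir, recursive = TRUE), "manifest.csv")
  md5 <- as.character(tools::md5sum(file.path(outDir, files)))
  utils::write.csv(data.frame(file = files, md5 = md5),
                   file.path(outDir, "manifest.csv"), row.names = FALSE,
                   quote = FALSE)
}

#' Run a pipeline stage
#'
#' Drives the package's stages from a run configuration (a YAML file path or
#' an equivalent named list). Outputs are delimited tables under
#' `config$outputDir`, re-created deterministically from the configured
#' seeds, plus a `manifest.csv` listing every output file with its MD5
#' content hash. The configuration used is echoed verbatim to
#' `config.yaml` in the output directory.
#'
#' Commands:
#' \describe{
#'   \item{simulate}{generate a cluster field (`config$simulate`: a
#'     [clusterSimConfig()] argument list) and write `localizations.csv` and
#'     `truth.csv`.}
#'   \item{track}{link `localizations.csv` into `tracks.csv`
#'     (`config$tracking`: maxDisp, minLength).}
#'   \item{msd}{MSD curve and D1/D2 estimates from `tracks.csv`
#'     (`config$diffusion`: maxLag, msd1Fixed).}
#'   \item{coloc}{NCG and median distance between two localization tables
#'     (`config$coloc`: green, red, roles fixed as green = territory).}
#'   \item{junctions}{junction mask from a reference table plus track
#'     classification and excursions (`config$junctions`).}
#'   \item{clusters}{Voronoi + particle-analysis segmentation of
#'     `localizations.csv` (`config$clustering`: iterations, minPixels,
#'     seed).}
#'   \item{report}{aggregate per-ROI `coloc.csv` tables into condition-level
#'     medians (medians, not means, are the headline aggregate).}
#' }
#'
#' @param config YAML path or named list; must contain `outputDir`.
#' @param command one of the stage names above.
#' @return invisibly, a named list of the stage's main results.
#' @export
runPipeline <- function(config, command = c("simulate", "track", "msd",
                                            "coloc", "junctions", "clusters",
                                            "report")) {
  command <- match.arg(command)
  if (is.character(config)) config <- readRunConfig(config)
  if (is.null(config$outputDir)) stop("config$outputDir is required")
  outDir <- config$outputDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(config, file.path(outDir, "config.yaml"))
  locPath <- file.path(outDir, "localizations.csv")
  trkPath <- file.path(outDir, "tracks.csv")
  res <- switch(
    command,
    simulate = {
      sc <- config$simulate
      cfg <- clusterSimConfig(
        nClusters = sc$nClusters %||% 17,
        roi = Rect(0, 0, sc$roiWidth %||% 4000, sc$roiHeight %||% 4000),
        discDiameter = sc$discDiameter %||% 200,
        locsPerCluster = sc$locsPerCluster %||% 32,
        sigmaLoc = sc$sigmaLoc %||% 70,
        backgroundPixelFraction = sc$backgroundPixelFraction %||% 0.007,
        pixelSize = sc$pixelSize %||% 10,
        seed = sc$seed)
      sim <- simulateClusterField(cfg)
      writeLocalizations(sim$table, locPath)
      utils::write.csv(data.frame(cluster = sim$truth),
                       file.path(outDir, "truth.csv"), row.names = FALSE)
      utils::write.csv(sim$centers, file.path(outDir, "centers.csv"),
                       row.names = FALSE)
      list(table = sim$table)
    },
    track = {
      tc <- config$tracking
      tab <- readLocalizations(locPath)
      trk <- linkTracks(tab, maxDisp = tc$maxDisp %||% 480,
                        minLength = tc$minLength %||% 3)
      writeTracks(trk, trkPath)
      list(tracks = trk)
    },
    msd = {
      dc <- config$diffusion
      trk <- readTracks(trkPath)
      curve <- computeMSD(trk, maxLag = dc$maxLag %||% 10)
      utils::write.csv(msdData(curve), file.path(outDir, "msd.csv"),
                       row.names = FALSE)
      md <- msdData(curve)
      d1 <- if (!is.null(dc$msd1Fixed))
        diffusionCoef(estimateD1(md$msd[1], dc$msd1Fixed,
                                 frameInterval(trk))) else NA_real_
      d2 <- if (nrow(md) >= 2)
        diffusionCoef(estimateD2(md$msd[1], md$msd[2], frameInterval(trk)))
        else NA_real_
      utils::write.csv(data.frame(D1 = d1, D2 = d2),
                       file.path(outDir, "diffusion.csv"), row.names = FALSE)
      list(curve = curve, D1 = d1, D2 = d2)
    },
    coloc = {
      cc <- config$coloc
      green <- readLocalizations(cc$green, channel = "green")
      red <- readLocalizations(cc$red, channel = "red",
                               roi = roi(green))
      gMap <- binarize(renderASH(green, pixelSize = cc$pixelSize %||% 10))
      rMap <- binarize(renderASH(red, pixelSize = cc$pixelSize %||% 10))
      ncg <- computeNCG(gMap, rMap, roiId = cc$roiId %||% "")
      md <- medianDistanceToTerritory(gMap, rMap)
      out <- data.frame(roi = ncg@roiId, ncg = ncg@ncg,
                        medianDistanceNm = md@medianDistance,
                        colocalized = ncg@colocalizedPixels,
                        green = ncg@greenPixels, red = ncg@redPixels,
                        total = ncg@totalPixels)
      utils::write.csv(out, file.path(outDir, "coloc.csv"), row.names = FALSE)
      list(ncg = ncg, medianDistance = md)
    },
    junctions = {
      jc <- config$junctions
      stim <- readLocalizations(jc$reference, channel = "green")
      trk <- readTracks(trkPath)
      mask <- buildJunctionMask(stim)
      classes <- classifyTracks(trk, mask)
      exc <- maxExcursion(trk, classes)
      utils::write.csv(classes, file.path(outDir, "classes.csv"),
                       row.names = FALSE)
      utils::write.csv(exc, file.path(outDir, "excursions.csv"),
                       row.names = FALSE)
      list(mask = mask, classes = classes, excursions = exc)
    },
    clusters = {
      kc <- config$clustering
      tab <- readLocalizations(locPath)
      field <- voronoiField(tab)
      thr <- mcDensityThreshold(field, iterations = kc$iterations %||% 100,
                                seed = kc$seed)
      vor <- if (is.finite(thr$threshold))
        segmentClusters(field, thr$threshold,
                        minPixels = kc$minPixels %||% 10)
      else emptyClusterSet(roi(tab), 10, "voronoi_watershed", list())
      part <- particleAnalysis(binarize(renderASH(tab, shifts = 1)),
                               table = tab,
                               minPixels = kc$minPixels %||% 10)
      utils::write.csv(clusterData(vor),
                       file.path(outDir, "clusters_voronoi.csv"),
                       row.names = FALSE)
      utils::write.csv(clusterData(part),
                       file.path(outDir, "clusters_particle.csv"),
                       row.names = FALSE)
      summ <- rbind(cbind(method = "voronoi_watershed", clusterSummary(vor)),
                    cbind(method = "particle_analysis", clusterSummary(part)))
      utils::write.csv(summ, file.path(outDir, "cluster_summary.csv"),
                       row.names = FALSE)
      list(voronoi = vor, particle = part, summary = summ,
           threshold = thr)
    },
    report = {
      rc <- config$report
      tabs <- lapply(rc$inputs, utils::read.csv)
      all <- do.call(rbind, tabs)
      agg <- data.frame(
        nRois = nrow(all),
        medianNcg = stats::median(all$ncg),
        medianDistanceNm = stats::median(all$medianDistanceNm))
      utils::write.csv(agg, file.path(outDir, "report.csv"),
                       row.names = FALSE)
      list(report = agg)
    })
  writeManifest(outDir)
  invisible(res)
}
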