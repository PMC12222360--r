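#' Default run configuration
#'
#' All analysis constants in one place, each appearing exactly once:
#' site grid 8000 m, base replicate 2000 m, collinearity |r| 0.70,
#' critical VIF 3, AICc support width 2, isopleth level 0.95,
#' available:used ratio 4, significance level 0.05, 1000 bootstrap
#' replicates, 10 km quartic kernel radius, subadult boundary 4 years,
#' minimum 60 days of positional data, Apr-Oct season.
#'
#' @param ... overrides of any default (logged in the manifest).
#' @return named list of configuration values.
#' @export
runConfig <- function(...) {
  cfg <- list(
    seed = 1,
    gridSize = 8000, replicateLength = 2000, maxReplicateLength = 20000,
    corThreshold = 0.70, vifThreshold = 3, deltaAicc = 2,
    isoLevel = 0.95, ratio = 4, alpha = 0.05, nBoot = 1000,
    kernelRadius = 10000, subadultAge = 4, minDays = 60,
    seasonStartMonth = 4, seasonEndMonth = 10,
    maxSpeed = 10000, residencyWindow = 14, residencyMult = 10,
    householdSize = 3.7,
    ## synthetic-run sizes
    landNrow = 60, landNcol = 60, cellsize = 1000,
    nSettlements = 20, nWaterholes = 40, nPerClass = 2)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  attr(cfg, "overridden") <- names(over)
  cfg
}

.manifest <- function(outdir, stage, cfg, files) {
  files <- files[file.exists(file.path(outdir, files))]
  man <- list(stage = stage,
              config = cfg[order(names(cfg))],
              files = as.list(tools::md5sum(file.path(outdir, files))))
  names(man$files) <- files
  writeLines(jsonlite::toJSON(man, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(outdir, paste0("manifest_", stage, ".json")))
}

#' Run one pipeline stage on a synthetic study
#'
#' Orchestrates \code{simulate} (landscape + prey survey + telemetry),
#' \code{occupancy} (detection histories, replicate-length selection,
#' multi-model inference, abundance surface), \code{homerange}
#' (preprocessing + utilization distributions), \code{rsf} (design, VIF
#' pruning, GLMM, term deletion, per-class maps) and \code{report}
#' (summary tables); \code{"all"} runs the full chain.  Every stage is
#' deterministic given the configuration seed and writes a manifest of
#' output hashes.
#'
#' @param stage stage name.
#' @param config a [runConfig()].
#' @param outdir output directory (created if needed).
#' @return invisible list of the stage's in-memory outputs.
#' @export
runStage <- function(stage = c("all", "simulate", "occupancy", "homerange",
                               "rsf", "report"),
                     config = runConfig(), outdir = tempfile("habsel_run")) {
  stage <- match.arg(stage)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (stage == "all") {
    for (s in c("simulate", "occupancy", "homerange", "rsf", "report"))
      out <- runStage(s, config, outdir)
    return(invisible(out))
  }
  switch(stage,
         simulate = .stageSimulate(config, outdir),
         occupancy = .stageOccupancy(config, outdir),
         homerange = .stageHomerange(config, outdir),
         rsf = .stageRsf(config, outdir),
         report = .stageReport(config, outdir))
}

.needFile <- function(outdir, f) {
  p <- file.path(outdir, f)
  if (!file.exists(p)) stop("missing upstream artifact: ", f)
  p
}

.stageSimulate <- function(cfg, outdir) {
  lc <- landscapeConfig(nrow = cfg$landNrow, ncol = cfg$landNcol,
                        cellsize = cfg$cellsize, seed = cfg$seed,
                        nSettlements = cfg$nSettlements,
                        nWaterholes = cfg$nWaterholes)
  land <- generateLandscape(lc)
  stack <- deriveFeatureLayers(land$stack, land$settlements,
                               land$waterholes, land$river,
                               radius = cfg$kernelRadius,
                               householdSize = cfg$householdSize)
  for (nm in names(stack@layers))
    writeAsciiGrid(rasterGrid(stack@layers[[nm]], stack@grid),
                   file.path(outdir, paste0(nm, ".asc")))
  writeGeoJSON(land$settlements[, 1:2, drop = FALSE],
               file.path(outdir, "settlements.geojson"), "points",
               properties = data.frame(
                 households = land$settlements[, "households"]))
  writeGeoJSON(land$waterholes, file.path(outdir, "waterholes.geojson"),
               "points")
  if (!is.null(land$river))
    writeGeoJSON(list(land$river), file.path(outdir, "river.geojson"),
                 "lines")
  ## prey: one species driven by NDVI on the standardized scale
  std <- standardizeLayers(stack)
  truth <- preyTruth("impala", a0 = 0.2, a = c(ndvi = 0.8), r = 0.3)
  lam <- simulatePreySurface(std, truth)
  roads <- makeRoadNetwork(stack@grid, cfg$gridSize)
  survey <- simulateTrackSurvey(lam, roads, siteSize = cfg$gridSize,
                                replicateLength = cfg$replicateLength,
                                truth = truth,
                                seed = childSeed(cfg$seed, 2))
  write.csv(survey$records, file.path(outdir, "survey_records.csv"),
            row.names = FALSE)
  write.csv(survey$sites, file.path(outdir, "survey_sites.csv"),
            row.names = FALSE)
  ## telemetry: class-specific selection with a sign-flipped
  ## precipitation response for subadult males
  tt <- telemetryTruth(list(
    "adult female" = c(precipitation = 0.6, ndvi = -0.5),
    "subadult female" = c(precipitation = 0.6, ndvi = -0.5),
    "adult male" = c(precipitation = 0.6, ndvi = -0.5),
    "subadult male" = c(precipitation = -0.7, ndvi = -0.5)),
    kernelSd = 5000, year = 2013)
  tel <- simulateTelemetry(std, tt, nPerClass = cfg$nPerClass,
                           seed = childSeed(cfg$seed, 3))
  write.csv(tel$fixes, file.path(outdir, "telemetry_fixes.csv"),
            row.names = FALSE)
  writeKeyValue(list(
    prey_species = truth$species, prey_a0 = truth$a0,
    prey_a_ndvi = truth$a[["ndvi"]], prey_r = truth$r,
    telemetry_kernel_sd = tt$kernelSd,
    beta_precip_ref = 0.6, beta_precip_subadult_male = -0.7,
    beta_ndvi = -0.5, seed = cfg$seed),
    file.path(outdir, "truth.txt"))
  write.csv(std@standardization, file.path(outdir, "standardization.csv"),
            row.names = FALSE)
  .manifest(outdir, "simulate", cfg,
            c(paste0(names(stack@layers), ".asc"), "survey_records.csv",
              "survey_sites.csv", "telemetry_fixes.csv", "truth.txt",
              "standardization.csv"))
  invisible(list(stack = stack, survey = survey, telemetry = tel))
}

.readStack <- function(outdir, layers) {
  mats <- list(); g <- NULL
  for (nm in layers) {
    r <- readAsciiGrid(.needFile(outdir, paste0(nm, ".asc")))
    mats[[nm]] <- r@values; g <- r@grid
  }
  covariateStack(mats, g)
}

.stageOccupancy <- function(cfg, outdir) {
  records <- read.csv(.needFile(outdir, "survey_records.csv"))
  sites <- read.csv(.needFile(outdir, "survey_sites.csv"))
  stack <- .readStack(outdir, c("precipitation", "ndvi", "canopy",
                                "dist_water", "dist_settlement"))
  std <- standardizeLayers(stack)
  covs <- extractValues(std, sites[, c("x", "y")])
  covs$site <- sites$site
  dh <- buildDetectionHistories(records, covs,
                                replicateLength = cfg$replicateLength)
  sel <- selectReplicateLength(dh, maxLength = cfg$maxReplicateLength,
                               deltaAicc = cfg$deltaAicc, seed = cfg$seed)
  dhSel <- aggregateReplicates(dh, sel$chosen / cfg$replicateLength)
  ms <- modelSelection(dhSel, c("precipitation", "ndvi", "canopy"),
                       alpha = cfg$alpha, corThreshold = cfg$corThreshold,
                       deltaAicc = cfg$deltaAicc, seed = cfg$seed)
  lam <- predictAbundance(ms$averaged, std)
  writeAsciiGrid(lam, file.path(outdir, "prey_lambda.asc"))
  write.csv(ms$ranking, file.path(outdir, "occupancy_ranking.csv"),
            row.names = FALSE)
  write.csv(ms$averaged, file.path(outdir, "occupancy_averaged.csv"),
            row.names = FALSE)
  write.csv(sel$trace, file.path(outdir, "replicate_length_trace.csv"),
            row.names = FALSE)
  .manifest(outdir, "occupancy", cfg,
            c("prey_lambda.asc", "occupancy_ranking.csv",
              "occupancy_averaged.csv", "replicate_length_trace.csv"))
  invisible(list(selection = sel, models = ms, lambda = lam))
}

.stageHomerange <- function(cfg, outdir) {
  fixes <- read.csv(.needFile(outdir, "telemetry_fixes.csv"))
  clean <- preprocessTelemetry(fixes, maxSpeed = cfg$maxSpeed,
                               residencyWindow = cfg$residencyWindow,
                               residencyMult = cfg$residencyMult,
                               seasonMonths =
                                 cfg$seasonStartMonth:cfg$seasonEndMonth)
  write.csv(clean, file.path(outdir, "telemetry_clean.csv"),
            row.names = FALSE)
  uds <- homeRanges(clean, minDays = cfg$minDays, level = cfg$isoLevel,
                    subadultAge = cfg$subadultAge)
  polys <- list(); props <- list()
  for (key in names(uds)) {
    u <- uds[[key]]
    for (p in seq_along(u@isoPolygons)) {
      polys[[length(polys) + 1L]] <- u@isoPolygons[[p]]
      props[[length(props) + 1L]] <- data.frame(
        rangeSeason = key, class = u@demographicClass, part = p)
    }
  }
  if (length(polys))
    writeGeoJSON(polys, file.path(outdir, "homeranges.geojson"), "polygons",
                 properties = do.call(rbind, props))
  .manifest(outdir, "homerange", cfg,
            c("telemetry_clean.csv", "homeranges.geojson"))
  invisible(list(clean = clean, uds = uds))
}

.stageRsf <- function(cfg, outdir) {
  hr <- .stageHomerange(cfg, outdir)  # UDs are cheap to rebuild; keeps
                                      # the stage re-runnable in isolation
  stack <- .readStack(outdir, c("precipitation", "ndvi"))
  design <- buildDesign(hr$uds, hr$clean, stack,
                        covariates = c("precipitation", "ndvi"),
                        ratio = cfg$ratio, seed = childSeed(cfg$seed, 7))
  vp <- vifPrune(design@data[design@covariates],
                 threshold = cfg$vifThreshold)
  lrt <- lrtTermDeletion(design, covariates = vp$retained,
                         classInteractions = vp$retained,
                         randomTerms = "(1 | individual)",
                         alpha = cfg$alpha)
  write.csv(designData(design), file.path(outdir, "rsf_design.csv"),
            row.names = FALSE)
  write.csv(lrt$table, file.path(outdir, "rsf_lrt.csv"), row.names = FALSE)
  fx <- fixedEffects(lrt$final)
  orTab <- cbind(fx, oddsRatios(fx$beta, fx$se))
  write.csv(orTab, file.path(outdir, "rsf_fixed_effects.csv"),
            row.names = FALSE)
  r2 <- r2Nakagawa(lrt$final, design)
  writeKeyValue(list(aic = lrt$final@aic, r2_marginal = r2[["marginal"]],
                     r2_conditional = r2[["conditional"]]),
                file.path(outdir, "rsf_stats.txt"))
  for (cls in demographicClasses()) {
    mp <- predictRsfMap(lrt$final, stack, cls, design)
    tag <- gsub(" ", "_", cls)
    writeAsciiGrid(mp$scaled,
                   file.path(outdir, sprintf("rsf_map_%s.asc", tag)))
  }
  .manifest(outdir, "rsf", cfg,
            c("rsf_design.csv", "rsf_lrt.csv", "rsf_fixed_effects.csv",
              "rsf_stats.txt",
              sprintf("rsf_map_%s.asc",
                      gsub(" ", "_", demographicClasses()))))
  invisible(list(design = design, vif = vp, lrt = lrt))
}

.stageReport <- function(cfg, outdir) {
  fx <- read.csv(.needFile(outdir, "rsf_fixed_effects.csv"))
  lrtTab <- read.csv(.needFile(outdir, "rsf_lrt.csv"))
  stats <- readKeyValue(.needFile(outdir, "rsf_stats.txt"))
  tab <- data.frame(term = fx$term, beta = round(fx$beta, 2),
                    se = round(fx$se, 2), z = round(fx$z, 2),
                    p_z = signif(fx$p, 2), or_ci = fx$formatted)
  m <- match(tab$term, lrtTab$term)
  tab$df <- lrtTab$df[m]
  tab$chisq <- round(lrtTab$chisq[m], 2)
  tab$p_chisq <- signif(lrtTab$p[m], 2)
  write.csv(tab, file.path(outdir, "report_fixed_effects.csv"),
            row.names = FALSE)
  footer <- sprintf("AIC %.1f | Marginal R^2 %.2f | Conditional R^2 %.2f",
                    stats$aic, stats$r2_marginal, stats$r2_conditional)
  writeLines(c(utils::capture.output(print(tab, row.names = FALSE)), footer),
             file.path(outdir, "report.txt"))
  .manifest(outdir, "report", cfg,
            c("report_fixed_effects.csv", "report.txt"))
  invisible(list(table = tab, footer = footer))
}
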