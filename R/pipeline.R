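## End-to-end workflows over synthetic (or user-supplied) data, plus run
## configuration. Every output file carries the config hash and seed in a
## leading comment line so a run is identifiable and reruns with the same
## config and seed are byte-identical.

## Stage seeds derive from the base seed; double-precision arithmetic with
## a final modulus keeps every derived seed inside the 32-bit integer range.
.deriveSeed <- function(seed, offset)
  as.integer((as.numeric(seed) * 1000 + offset) %% 2147483647)

#' Default run configuration
#'
#' Nested list of all tunables for the three workflows. Values mirror the
#' package's study conditions: flow-cell stacks of 40 x 128 x 128 voxels
#' at (0.5, 0.2, 0.2) um with ~2000 biomass voxels per layer and a 5%/30%
#' bottom/top step in plasmid loss; beads of radius 150 um at (2, 1, 1) um
#' voxels with a log-linear aggregate size model; FACS mixtures with
#' populations 8 log-sd apart. Thresholding follows the per-experiment
#' convention: Yen (green) and Moments (red) for flow cells without
#' smoothing, Otsu for both bead channels after 3x3x3 median smoothing.
#'
#' @return a `RunConfig` list.
#' @export
defaultRunConfig <- function() {
  list(
    flowcell = list(
      nLayers = 40L, ny = 128L, nx = 128L, biomassPerLayer = 2000,
      lossBottom = 0.05, lossTop = 0.30,
      voxelSize = c(dz = 0.5, dy = 0.2, dx = 0.2),
      methodGreen = "yen", methodRed = "moments", smooth = FALSE,
      span = 0.75, nImages = 2L, nReplicates = 3L,
      plasmids = c("conjugative", "conjugation_deficient")),
    bead = list(
      radiusUm = 150, nAggregates = 50L, nBeads = 3L,
      interceptCarrier = 2.8, interceptFree = 3.1, slope = 0.8,
      sigmaLog10 = 0.15, freeFraction = 0.2,
      voxelSize = c(dz = 2, dy = 1, dx = 1),
      minVolume = 50, exclusionFactor = 1.1, smooth = TRUE,
      method = "otsu"),
    facs = list(
      nControlEvents = 5000L, nEvents = 5000L, days = 4L,
      generationsPerDay = 10, lambdaWT = 0.004, lambdaMRB1 = 0.0015,
      sCost = 0.05, nBioReps = 4L, nTechReps = 3L,
      plasmids = c("conjugative", "conjugation_deficient"),
      competitionGenerations = 10))
}

#' Validate a run configuration
#'
#' Checks numeric parameters against their documented ranges; called by
#' [runPipeline()] before any computation.
#'
#' @param config a `RunConfig` list.
#' @return invisibly `TRUE`; errors describe the offending key.
#' @export
validateRunConfig <- function(config) {
  chk <- function(ok, key) if (!isTRUE(ok))
    stop(sprintf("invalid config: %s", key), call. = FALSE)
  fc <- config$flowcell
  chk(fc$nLayers >= 2, "flowcell.nLayers >= 2")
  chk(fc$lossBottom >= 0 && fc$lossBottom <= 1, "flowcell.lossBottom in [0,1]")
  chk(fc$lossTop >= 0 && fc$lossTop <= 1, "flowcell.lossTop in [0,1]")
  chk(all(fc$voxelSize > 0), "flowcell.voxelSize > 0")
  chk(fc$span > 0 && fc$span <= 1, "flowcell.span in (0,1]")
  chk(fc$methodGreen %in% c("otsu", "yen", "moments"), "flowcell.methodGreen")
  chk(fc$methodRed %in% c("otsu", "yen", "moments"), "flowcell.methodRed")
  bd <- config$bead
  chk(bd$radiusUm > 0, "bead.radiusUm > 0")
  chk(bd$minVolume >= 0, "bead.minVolume >= 0")
  chk(bd$exclusionFactor >= 1, "bead.exclusionFactor >= 1")
  chk(bd$freeFraction >= 0 && bd$freeFraction <= 1, "bead.freeFraction in [0,1]")
  fx <- config$facs
  chk(fx$days >= 1, "facs.days >= 1")
  chk(fx$lambdaWT >= 0 && fx$lambdaWT <= 1, "facs.lambdaWT in [0,1]")
  chk(fx$lambdaMRB1 >= 0 && fx$lambdaMRB1 <= 1, "facs.lambdaMRB1 in [0,1]")
  invisible(TRUE)
}

#' Read a run configuration from YAML
#'
#' Missing keys fall back to [defaultRunConfig()]; the config round-trips
#' through YAML losslessly.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return a `RunConfig` list.
#' @export
readRunConfig <- function(path = NULL) {
  config <- defaultRunConfig()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (section in names(user)) {
      for (key in names(user[[section]])) {
        v <- user[[section]][[key]]
        if (key %in% c("voxelSize") && is.list(v)) v <- unlist(v)
        config[[section]][[key]] <- v
      }
    }
  }
  validateRunConfig(config)
  config
}

#' Hash a run configuration
#'
#' 32-bit FNV-1a hash of the YAML serialization, used to stamp output
#' files so a report is traceable to its exact configuration.
#'
#' @param config a `RunConfig` list.
#' @return an 8-character hex string.
#' @export
configHash <- function(config) {
  bytes <- utf8ToInt(yaml::as.yaml(config))
  ## polynomial rolling hash over the serialized bytes, kept in double
  ## precision below 2^31 so the arithmetic is exact
  h <- 7
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

.writeStamped <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# plasmidQuant config %s seed %d", hash, seed), con)
  write.csv(df, con, row.names = FALSE)
}

.runFlowcell <- function(config, seed, outDir, hash, writePlots) {
  fc <- config$flowcell
  mid <- fc$nLayers / 2
  strata <- list(); profiles <- list(); curves <- list()
  counter <- 0L
  for (pl in fc$plasmids) {
    for (rep in seq_len(fc$nReplicates)) {
      imgProfiles <- list()
      for (im in seq_len(fc$nImages)) {
        counter <- counter + 1L
        tr <- flowcellTruth(
          nLayers = fc$nLayers, ny = fc$ny, nx = fc$nx,
          lossProfile = function(z) ifelse(z <= mid, fc$lossBottom, fc$lossTop),
          biomassProfile = function(z) rep(fc$biomassPerLayer, length(z)),
          voxelSize = fc$voxelSize, seed = .deriveSeed(seed, counter))
        sim <- simulateFlowcellStack(tr)
        fm <- segmentChannel(sim$image, "green", fc$methodGreen, smooth = fc$smooth)
        cm <- segmentChannel(sim$image, "red", fc$methodRed, smooth = fc$smooth)
        prof <- recenterZ(layerProfile(fm, cm))
        imgProfiles[[im]] <- prof
        st <- splitTopBottom(prof)
        st$plasmid <- pl; st$replicate <- rep; st$image <- im
        strata[[length(strata) + 1L]] <- st
      }
      avg <- lossProportion(averageReplicates(imgProfiles))
      avg$plasmid <- pl; avg$replicate <- rep
      profiles[[length(profiles) + 1L]] <- avg
      cv <- weightedLoess(avg$zCorrected, avg$pLoss, avg$biomass,
                          span = fc$span)
      cv$plasmid <- pl; cv$replicate <- rep
      curves[[length(curves) + 1L]] <- cv
    }
  }
  strata <- do.call(rbind, strata)
  profiles <- do.call(rbind, profiles)
  curves <- do.call(rbind, curves)
  anova <- compareStrata(strata)
  .writeStamped(profiles, file.path(outDir, "flowcell_profiles.csv"), hash, seed)
  .writeStamped(curves, file.path(outDir, "flowcell_loess.csv"), hash, seed)
  .writeStamped(strata, file.path(outDir, "flowcell_strata.csv"), hash, seed)
  .writeStamped(anova, file.path(outDir, "flowcell_anova.csv"), hash, seed)
  if (writePlots) {
    p <- plotLossCurve(profiles, curves)
    ggplot2::ggsave(file.path(outDir, "flowcell_loss_profile.pdf"), p,
                    width = 7, height = 5)
  }
  topP <- sum(strata$nFree[strata$stratum == "top"]) /
    sum(strata$biomass[strata$stratum == "top"])
  bottomP <- sum(strata$nFree[strata$stratum == "bottom"]) /
    sum(strata$biomass[strata$stratum == "bottom"])
  list(topLossProportion = topP, bottomLossProportion = bottomP,
       pStratum = anova$p[anova$term == "stratum"],
       pPlasmid = anova$p[anova$term == "plasmid"])
}

.runBead <- function(config, seed, outDir, hash, writePlots) {
  bd <- config$bead
  tables <- list()
  for (b in seq_len(bd$nBeads)) {
    tr <- beadTruth(radiusUm = bd$radiusUm, nAggregates = bd$nAggregates,
                    interceptCarrier = bd$interceptCarrier,
                    interceptFree = bd$interceptFree, slope = bd$slope,
                    sigmaLog10 = bd$sigmaLog10,
                    freeFraction = bd$freeFraction,
                    voxelSize = bd$voxelSize, seed = .deriveSeed(seed, b))
    sim <- simulateBeadStack(tr, beadId = sprintf("bead%d", b))
    fm <- segmentChannel(sim$image, "green", bd$method, smooth = bd$smooth)
    cm <- segmentChannel(sim$image, "red", bd$method, smooth = bd$smooth)
    ctr <- beadCenter(fm, cm, bd$voxelSize)
    tab <- detectAggregates(fm, cm, bd$voxelSize, ctr,
                            beadId = sprintf("bead%d", b))
    tables[[b]] <- tab
  }
  table <- do.call(rbind, tables)
  table <- filterAggregates(table, minVolume = bd$minVolume,
                            exclusionFactor = bd$exclusionFactor)
  table <- normalizeDistances(table)
  ratios <- lossRatio(table)
  reg <- sizeDistanceRegression(table)
  lmmFit <- sizeByStatusLMM(table)
  perBead <- ratios$perBead
  models <- data.frame(
    quantity = c("sizeDistanceSlope", "sizeDistanceIntercept",
                 "statusEffectLog10", "statusEffectSE", "statusEffectP",
                 "pooledLossRatio"),
    value = c(reg$slope, reg$intercept, lmmFit$estimate, lmmFit$se,
              lmmFit$p, ratios$pooled))
  .writeStamped(table, file.path(outDir, "bead_aggregates.csv"), hash, seed)
  .writeStamped(perBead, file.path(outDir, "bead_perbead.csv"), hash, seed)
  .writeStamped(models, file.path(outDir, "bead_models.csv"), hash, seed)
  if (writePlots) {
    ggplot2::ggsave(file.path(outDir, "bead_size_distance.pdf"),
                    plotSizeDistance(table, reg$band), width = 7, height = 5)
    ggplot2::ggsave(file.path(outDir, "bead_loss_ratio.pdf"),
                    plotLossRatioBox(perBead), width = 4, height = 5)
  }
  list(pooledLossRatio = ratios$pooled, slope = reg$slope,
       statusEffect = lmmFit$estimate, statusP = lmmFit$p)
}

.runFacs <- function(config, seed, outDir, hash, writePlots) {
  fx <- config$facs
  ## gates from pure-population controls
  gates <- buildGates(
    simulateFacsEvents(facsTruth(nEvents = fx$nControlEvents,
                                 freeFraction = 0, debrisFraction = 0,
                                 seed = .deriveSeed(seed, 1L))),
    simulateFacsEvents(facsTruth(nEvents = fx$nControlEvents,
                                 freeFraction = 1, debrisFraction = 0,
                                 seed = .deriveSeed(seed, 2L))))
  rows <- list(); counter <- 10L
  for (pl in fx$plasmids) {
    for (strain in c("WT", "MRB1")) {
      lambda <- if (strain == "WT") fx$lambdaWT else fx$lambdaMRB1
      for (br in seq_len(fx$nBioReps)) {
        tr <- trajectoryTruth(lambdaSeg = lambda, sCost = fx$sCost,
                              generationsPerDay = fx$generationsPerDay,
                              days = fx$days, f0 = 0)
        traj <- simulateLossTimecourse(tr, samplingN = 10000L,
                                       seed = .deriveSeed(seed, counter),
                                       strain = strain, plasmid = pl,
                                       bioRep = br)
        counter <- counter + 1L
        for (d in traj$day) {
          for (tk in seq_len(fx$nTechReps)) {
            counter <- counter + 1L
            ev <- simulateFacsEvents(
              facsTruth(nEvents = fx$nEvents,
                        freeFraction = traj$expectedFraction[traj$day == d],
                        seed = .deriveSeed(seed, counter)),
              strain = strain, plasmid = pl, day = d, bioRep = br,
              techRep = tk)
            lf <- lossFraction(ev, gates)
            rows[[length(rows) + 1L]] <- data.frame(
              strain = strain, plasmid = pl, day = d, bioRep = br,
              techRep = tk, fraction = lf$fraction,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  fractions <- do.call(rbind, rows)
  traj <- aggregateTrajectory(fractions)
  trends <- do.call(rbind, lapply(fx$plasmids, function(pl) {
    tc <- compareTrends(traj$replicates[traj$replicates$plasmid == pl, ])
    data.frame(plasmid = pl, interaction = tc$interaction, se = tc$se,
               t = tc$t, df = tc$df, p = tc$p, stringsAsFactors = FALSE)
  }))
  ## competition assay: equal start, cost-driven divergence over G generations
  set.seed(.deriveSeed(seed, 5L))
  G <- fx$competitionGenerations
  n0 <- 1e5
  nFree0 <- rpois(1, n0); nCar0 <- rpois(1, n0)
  nFree1 <- rpois(1, nFree0 * (2 * (1 + fx$sCost))^G)
  nCar1 <- rpois(1, nCar0 * 2^G)
  fitness <- relativeFitness(nFree0, nFree1, nCar0, nCar1)
  .writeStamped(traj$replicates, file.path(outDir, "facs_trajectory.csv"),
                hash, seed)
  .writeStamped(traj$summary, file.path(outDir, "facs_trajectory_summary.csv"),
                hash, seed)
  .writeStamped(trends, file.path(outDir, "facs_trends.csv"), hash, seed)
  .writeStamped(data.frame(w = fitness$w, t(fitness$counts)),
                file.path(outDir, "facs_fitness.csv"), hash, seed)
  if (writePlots)
    ggplot2::ggsave(file.path(outDir, "facs_trajectory.pdf"),
                    plotTrajectory(traj$summary), width = 7, height = 5)
  list(trendP = setNames(trends$p, trends$plasmid),
       relativeFitness = fitness$w,
       finalLoss = traj$summary$mean[traj$summary$day == fx$days &
                                       traj$summary$strain == "WT" &
                                       traj$summary$plasmid == fx$plasmids[1]])
}

#' Run an end-to-end analysis workflow
#'
#' Executes the flow-cell, bead or FACS workflow (or all three) on
#' synthetic data generated under the configured study conditions, writing
#' CSV report tables, optional figures and a machine-readable JSON summary
#' to `outDir`. Every output names the config hash and seed; a rerun with
#' identical config and seed is byte-identical (figures excluded - PDF
#' embeds timestamps).
#'
#' @param experiment `"flowcell"`, `"bead"`, `"facs"` or `"all"`.
#' @param config a `RunConfig` list (default [defaultRunConfig()]).
#' @param seed integer base seed; all stage seeds derive from it.
#' @param outDir output directory (created if missing).
#' @param writePlots also write PDF figures.
#' @return invisibly, the summary list (also written as `summary.json`).
#' @export
runPipeline <- function(experiment = c("all", "flowcell", "bead", "facs"),
                        config = defaultRunConfig(), seed = 1L,
                        outDir = tempfile("plasmidquant"),
                        writePlots = FALSE) {
  experiment <- match.arg(experiment)
  validateRunConfig(config)
  seed <- as.integer(seed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hash <- configHash(config)
  summary <- list(configHash = hash, seed = seed)
  if (experiment %in% c("all", "flowcell"))
    summary$flowcell <- .runFlowcell(config, seed, outDir, hash, writePlots)
  if (experiment %in% c("all", "bead"))
    summary$bead <- .runBead(config, seed, outDir, hash, writePlots)
  if (experiment %in% c("all", "facs"))
    summary$facs <- .runFacs(config, seed, outDir, hash, writePlots)
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(summary)
}
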