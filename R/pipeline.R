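# End-to-end orchestration: synthetic cohort -> features -> screening ->
# thermal protocol sweep, with CSV/JSON artifacts, advisory figures and a
# reproducibility manifest. All randomness flows from the config seeds.

#' Default run configuration
#'
#' @param outDir output directory.
#' @param seed master seed; every stochastic stage derives its own seed
#'   from it.
#' @param nDM,nNonDM cohort sizes (default mirrors an 11 + 11 patient
#'   repository).
#' @param alpha t-test retention threshold.
#' @param nBoot bootstrap resamples for AUC intervals.
#' @param stages character subset of
#'   `c("synth", "features", "screen", "simulate")`.
#' @param intensities,duties,durations thermal protocol grid (W/cm^2,
#'   fraction, minutes).
#' @param gridSpacing bioheat grid spacing, cm.
#' @param makePlots write advisory PNG figures.
#' @return list of class `"RunConfig"`.
#' @export
runConfig <- function(outDir = "pancus-run", seed = 1,
                      nDM = 11, nNonDM = 11, alpha = 0.05, nBoot = 2000,
                      stages = c("synth", "features", "screen", "simulate"),
                      intensities = c(1, 5, 10),
                      duties = c(0.10, 0.25, 0.50, 0.75, 1.00),
                      durations = c(1, 3, 5),
                      gridSpacing = 0.05,
                      makePlots = TRUE) {
  structure(list(outDir = outDir, seed = as.integer(seed), nDM = nDM,
                 nNonDM = nNonDM, alpha = alpha, nBoot = nBoot,
                 stages = stages, intensities = intensities, duties = duties,
                 durations = durations, gridSpacing = gridSpacing,
                 makePlots = makePlots),
            class = "RunConfig")
}

#' Read/write a run configuration as YAML (lossless round trip)
#' @param path YAML file.
#' @export
readRunConfig <- function(path) {
  obj <- yaml::read_yaml(path)
  do.call(runConfig, obj)
}

#' @rdname readRunConfig
#' @param config a [runConfig()].
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Thermal safety sweep over a protocol grid
#'
#' One bioheat simulation per (intensity, duty, duration) cell; per-cell
#' peak pancreatic temperature and CEM43 with safety verdicts. Cell
#' failures are recorded and the sweep continues.
#'
#' @param stack a [TissueStack-class].
#' @param transducer a [TransducerSpec-class].
#' @param intensities W/cm^2.
#' @param duties duty factors.
#' @param durations minutes.
#' @param grid a [bioheatGrid()].
#' @param dutyAvoid advisory flag threshold on the duty factor.
#' @return data.frame with one row per cell: `intensity`, `duty`,
#'   `duration`, `peak_T`, `peak_panc_T`, `peak_panc_cem43`,
#'   `peak_cem43`, `pass`, `avoid_flag`, `error`.
#' @export
protocolSweep <- function(stack, transducer,
                          intensities = c(1, 5, 10),
                          duties = c(0.10, 0.25, 0.50, 0.75, 1.00),
                          durations = c(1, 3, 5),
                          grid = bioheatGrid(), dutyAvoid = 0.75) {
  cells <- expand.grid(intensity = intensities, duty = duties,
                       duration = durations, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    ce <- cells[i, ]
    out <- data.frame(intensity = ce$intensity, duty = ce$duty,
                      duration = ce$duration, peak_T = NA_real_,
                      peak_panc_T = NA_real_, peak_panc_cem43 = NA_real_,
                      peak_cem43 = NA_real_, pass = NA,
                      avoid_flag = ce$duty >= dutyAvoid, error = "",
                      stringsAsFactors = FALSE)
    res <- tryCatch({
      pr <- methods::new("SonicationProtocol", intensity = ce$intensity,
                         dutyFactor = ce$duty, duration = ce$duration,
                         pulsePeriod = 1)
      fld <- solveBioheat(stack, transducer, pr, grid = grid)
      dose <- thermalDose(fld)
      rep <- safetyReport(dose, fld, stack, protocol = pr)
      out$peak_T <- peakTemperature(fld)
      out$peak_panc_T <- peakTemperature(fld, "pancreas")
      out$peak_panc_cem43 <- peakDose(dose, "pancreas")
      out$peak_cem43 <- peakDose(dose)
      out$pass <- rep$pass
      out
    }, error = function(e) { out$error <- conditionMessage(e); out })
    res
  })
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' Stages: `synth` (seeded phantom cohort written as PNGs + metadata),
#' `features` (per-phantom feature table CSV), `screen` (t-test gate,
#' Spearman/MI, range-adjusted mean-difference ranking, AUC table with
#' stratified bootstrap CIs, depth summaries; CSV + JSON), `simulate`
#' (protocol sweep safety matrix on the default stack CSV). Advisory
#' figures (class boxplots, ranked bars, ROC overlay, heating curves) are
#' written as PNGs; the numeric CSV/JSON artifacts are the tested
#' surface. A JSON manifest records seeds, package version and a config
#' hash; identical configs give byte-identical CSV outputs.
#'
#' @param config a [runConfig()].
#' @return invisibly, a list with the in-memory artifacts and the
#'   manifest. Stage errors mark the bundle incomplete rather than
#'   aborting the run.
#' @export
runPipeline <- function(config = runConfig()) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list()
  errors <- list()
  manifest <- list(package = "pancus",
                   version = as.character(utils::packageVersion("pancus")),
                   seed = config$seed,
                   config_hash = rlang::hash(
                     unclass(config)[setdiff(names(config), "outDir")]),
                   stages_run = character())

  if ("synth" %in% config$stages) {
    res <- tryCatch({
      cs <- cohortSpec(config$nDM, config$nNonDM,
                       masterSeed = deriveSeed(config$seed, 1L))
      cohort <- generateCohort(cs)
      writeCohort(cohort, file.path(config$outDir, "cohort"))
      cohort
    }, error = function(e) e)
    if (inherits(res, "error")) errors$synth <- conditionMessage(res)
    else { artifacts$cohort <- res
           manifest$stages_run <- c(manifest$stages_run, "synth") }
  }

  if ("features" %in% config$stages && !is.null(artifacts$cohort)) {
    res <- tryCatch({
      ft <- cohortFeatureTable(artifacts$cohort)
      writeFeatureCSV(ft, file.path(config$outDir, "features.csv"))
      ft
    }, error = function(e) e)
    if (inherits(res, "error")) errors$features <- conditionMessage(res)
    else { artifacts$features <- res
           manifest$stages_run <- c(manifest$stages_run, "features") }
  }

  if ("screen" %in% config$stages && !is.null(artifacts$features)) {
    res <- tryCatch({
      ft <- artifacts$features
      sc <- screenFeatures(ft, alpha = config$alpha)
      utils::write.csv(sc, file.path(config$outDir, "screening.csv"),
                       row.names = FALSE)
      rk <- absMeanDiffRanking(ft, excludeArea = TRUE)
      utils::write.csv(rk, file.path(config$outDir, "ranking.csv"),
                       row.names = FALSE)
      au <- aucTable(ft, features = sc$feature[sc$retained],
                     nBoot = config$nBoot, seed = deriveSeed(config$seed, 2L))
      utils::write.csv(au, file.path(config$outDir, "auc.csv"),
                       row.names = FALSE)
      depths <- data.frame(
        patient = ft$id, image = ft$id, region = "whole",
        depth_cm = ft$centroid_y)
      dp <- depthProfile(depths)
      jsonlite::write_json(
        list(screening = sc, auc = au,
             depth_progression = dp$progression,
             region_visibility = dp$visibility),
        file.path(config$outDir, "screening.json"),
        dataframe = "rows", auto_unbox = TRUE, digits = NA)
      list(screening = sc, ranking = rk, auc = au, depth = dp)
    }, error = function(e) e)
    if (inherits(res, "error")) errors$screen <- conditionMessage(res)
    else { artifacts$screen <- res
           manifest$stages_run <- c(manifest$stages_run, "screen") }
  }

  if ("simulate" %in% config$stages) {
    res <- tryCatch({
      stack <- defaultTissueStack()
      td <- methods::new("TransducerSpec")
      sw <- protocolSweep(stack, td,
                          intensities = config$intensities,
                          duties = config$duties,
                          durations = config$durations,
                          grid = bioheatGrid(dr = config$gridSpacing,
                                             dz = config$gridSpacing))
      utils::write.csv(sw, file.path(config$outDir, "safety_matrix.csv"),
                       row.names = FALSE)
      sw
    }, error = function(e) e)
    if (inherits(res, "error")) errors$simulate <- conditionMessage(res)
    else { artifacts$sweep <- res
           manifest$stages_run <- c(manifest$stages_run, "simulate") }
  }

  if (config$makePlots) {
    tryCatch(pipelineFigures(artifacts, config), error = function(e) NULL)
  }

  manifest$complete <- length(errors) == 0
  manifest$errors <- errors
  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(artifacts, list(manifest = manifest)))
}

#' Advisory figures for a pipeline run (PNG)
#' @noRd
pipelineFigures <- function(artifacts, config) {
  out <- config$outDir
  if (!is.null(artifacts$features) && !is.null(artifacts$screen)) {
    sc <- artifacts$screen$screening
    ft <- artifacts$features
    top <- utils::head(sc$feature[order(sc$p_value)], 6)
    grDevices::png(file.path(out, "fig_boxplots.png"), 900, 600)
    graphics::par(mfrow = c(2, 3))
    for (f in top)
      graphics::boxplot(ft[[f]] ~ ft$dm_status, main = f, xlab = "", ylab = f)
    grDevices::dev.off()

    rk <- artifacts$screen$ranking
    grDevices::png(file.path(out, "fig_ranked_diff.png"), 800, 500)
    graphics::par(mar = c(5, 12, 2, 1))
    graphics::barplot(rev(rk$score), names.arg = rev(rk$feature), horiz = TRUE,
                      las = 1, xlab = "range-adjusted |mean difference|")
    grDevices::dev.off()

    grDevices::png(file.path(out, "fig_mi.png"), 800, 500)
    graphics::par(mar = c(5, 12, 2, 1))
    o <- order(sc$mi_score)
    graphics::barplot(sc$mi_score[o], names.arg = sc$feature[o], horiz = TRUE,
                      las = 1, xlab = "mutual information (nats)")
    grDevices::dev.off()

    au <- artifacts$screen$auc
    if (nrow(au)) {
      top5 <- utils::head(au$feature[order(-au$auc)], 5)
      grDevices::png(file.path(out, "fig_roc.png"), 600, 600)
      graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 2, col = "gray",
                     xlab = "false positive rate", ylab = "true positive rate")
      cols <- seq_along(top5) + 1
      for (i in seq_along(top5)) {
        r <- univariateLogisticAuc(ft[[top5[i]]], ft$dm_status,
                                   nBoot = 10, seed = 1)$roc
        graphics::lines(r$fpr, r$tpr, col = cols[i])
      }
      graphics::legend("bottomright", legend = top5, col = cols, lty = 1, cex = 0.8)
      grDevices::dev.off()
    }
  }
  if (!is.null(artifacts$sweep)) {
    sw <- artifacts$sweep
    grDevices::png(file.path(out, "fig_sweep.png"), 800, 500)
    graphics::plot(sw$duty, sw$peak_panc_T, pch = 19,
                   col = ifelse(isTRUE(sw$pass), "darkgreen", "firebrick"),
                   xlab = "duty factor", ylab = "peak pancreatic T (C)")
    graphics::abline(h = 40, lty = 2)
    grDevices::dev.off()
  }
  invisible(NULL)
}
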