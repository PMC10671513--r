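## Pipeline orchestration: one call runs simulate -> summarize ->
## {heritability, classify, forecast, correlate} in dependency order,
## writes CSV outputs plus the fully resolved config for provenance, and
## returns a manifest. One root seed is fanned out to per-stage substreams.

.CONFIG_KEYS <- list(
  top = c("seed", "out_dir", "input", "simulate", "heritability",
          "classify", "forecast", "correlate"),
  input = c("path", "dialect"),
  simulate = c("lineNames", "micePerCell", "schedule", "baselineAsymptote",
               "baselineRate", "baselineMidpoint", "sigmaLine", "sigmaGxL",
               "genotypeMain", "sexEffect", "femalePlateauWeek",
               "plateauFactor", "maleDeclineWeek", "declineLine",
               "declinePerVisit", "sigmaIndividual", "sigmaMeasurement"),
  heritability = c("toWeeks", "fromWeek"),
  classify = c("models", "folds", "repeats", "standardize"),
  forecast = c("lastWeeks", "folds"),
  correlate = c("lines", "heatmaps"))

.checkKeys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    ccwStop("ccweight_invalid_config", "unknown config key(s) in %s: %s",
            where, paste(unknown, collapse = ", "))
}

.resolveConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config))
    ccwStop("ccweight_invalid_config", "config must be a list or YAML path")
  .checkKeys(config, .CONFIG_KEYS$top, "top level")
  for (blk in c("input", "simulate", "heritability", "classify",
                "forecast", "correlate"))
    if (!is.null(config[[blk]]))
      .checkKeys(config[[blk]], .CONFIG_KEYS[[blk]], blk)
  defaults <- list(
    seed = 1L, out_dir = tempfile("ccweight_run_"),
    input = NULL, simulate = list(),
    heritability = list(toWeeks = c(16, 32, 40, 48), fromWeek = 6),
    classify = list(models = .MODEL_NAMES, folds = 4L, repeats = 3L,
                    standardize = FALSE),
    forecast = list(lastWeeks = NULL, folds = 5L),
    correlate = list(lines = NULL, heatmaps = FALSE))
  cfg <- utils::modifyList(defaults, config)
  for (blk in c("heritability", "classify", "forecast", "correlate"))
    cfg[[blk]] <- utils::modifyList(defaults[[blk]],
                                    as.list(cfg[[blk]]))
  cfg
}

.stage <- function(manifest, name, file, t0) {
  message(sprintf("[%s] wrote %s (%.2fs)", name, file,
                  as.numeric(Sys.time()) - t0))
  rbind(manifest, data.frame(stage = name, file = file,
                             stringsAsFactors = FALSE))
}

#' Run the full analysis pipeline
#'
#' Stages run in dependency order: obtain a cohort (read `input`, or
#' simulate one when no input is given), then cohort summary, heritability
#' table, genotype-classification benchmark, chained-forecast table and
#' correlation matrices. Every stage writes CSV into `out_dir`; the fully
#' resolved configuration is written alongside for provenance. Unknown
#' config keys are rejected before any stage runs, and outputs are
#' deterministic for a fixed `seed`.
#'
#' @param config A named list, or the path to a YAML file, with optional
#'   keys `seed`, `out_dir`, `input` (`path`, `dialect`), `simulate`
#'   ([TrajectorySimParam()] fields), `heritability` (`toWeeks`,
#'   `fromWeek`), `classify` (`models`, `folds`, `repeats`, `standardize`),
#'   `forecast` (`lastWeeks`, `folds`), `correlate` (`lines`, `heatmaps`).
#' @return Manifest data.frame (`stage`, `file`), invisibly.
#' @export
#' @examples
#' \donttest{
#' m <- runPipeline(list(seed = 7,
#'                       simulate = list(micePerCell = 5L,
#'                                       lineNames = c("IL72", "IL188"))))
#' m$stage
#' }
runPipeline <- function(config = list()) {
  cfg <- .resolveConfig(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))],
                   file.path(cfg$out_dir, "config_resolved.yaml"))
  manifest <- data.frame(stage = character(0), file = character(0))
  t0 <- as.numeric(Sys.time())

  ## cohort: read or simulate
  if (!is.null(cfg$input)) {
    cohort <- readCohort(cfg$input$path,
                         dialect = cfg$input$dialect %||% "wide")
    message(sprintf("[input] read %d mice from %s (seed %d)",
                    ncol(cohort), cfg$input$path, cfg$seed))
  } else {
    param <- do.call(TrajectorySimParam,
                     c(cfg$simulate,
                       list(seed = childSeed(cfg$seed, "simulate"))))
    cohort <- simulateCohort(param)
    message(sprintf("[simulate] %d mice, %d lines (seed %d)",
                    ncol(cohort), length(param@lineNames), cfg$seed))
  }
  cohortCsv <- file.path(cfg$out_dir, "cohort.csv")
  writeCohort(cohort, cohortCsv, dialect = "wide")
  manifest <- .stage(manifest, "cohort", cohortCsv, t0)

  ## summary
  t0 <- as.numeric(Sys.time())
  counts <- summarizeCounts(cohort)
  countsCsv <- file.path(cfg$out_dir, "counts.csv")
  utils::write.csv(counts$cells, countsCsv, row.names = FALSE)
  manifest <- .stage(manifest, "summarize", countsCsv, t0)

  ## heritability
  t0 <- as.numeric(Sys.time())
  h2 <- heritabilityTable(cohort, toWeeks = cfg$heritability$toWeeks,
                          fromWeek = cfg$heritability$fromWeek)
  h2Csv <- file.path(cfg$out_dir, "heritability.csv")
  utils::write.csv(h2, h2Csv, row.names = FALSE)
  manifest <- .stage(manifest, "heritability", h2Csv, t0)

  ## genotype classification benchmark
  t0 <- as.numeric(Sys.time())
  auc <- benchmarkCohort(cohort, models = cfg$classify$models,
                         folds = cfg$classify$folds,
                         repeats = cfg$classify$repeats,
                         seed = childSeed(cfg$seed, "classify"),
                         standardize = cfg$classify$standardize)
  aucCsv <- file.path(cfg$out_dir, "auc.csv")
  utils::write.csv(auc, aucCsv, row.names = FALSE)
  manifest <- .stage(manifest, "classify", aucCsv, t0)

  ## chained forecast
  t0 <- as.numeric(Sys.time())
  lastWeeks <- cfg$forecast$lastWeeks %||%
    schedule(cohort)[schedule(cohort) <= 24]
  r2 <- forecastTable(cohort, lastWeeks = lastWeeks,
                      folds = cfg$forecast$folds,
                      seed = childSeed(cfg$seed, "forecast"))
  r2Csv <- file.path(cfg$out_dir, "r2.csv")
  utils::write.csv(r2, r2Csv, row.names = FALSE)
  manifest <- .stage(manifest, "forecast", r2Csv, t0)

  ## correlation matrices (long CSV; optional heatmaps)
  t0 <- as.numeric(Sys.time())
  lines <- cfg$correlate$lines %||% sort(unique(mouseLine(cohort)))
  corrRows <- list()
  for (ln in lines) for (sx in c("F", "M")) for (gt in c(0L, 1L)) {
    cm <- tryCatch(correlationMatrix(cohort, ln, sx, gt),
                   ccweight_not_estimable = function(e) NULL)
    if (is.null(cm)) next
    idx <- which(upper.tri(cm$r, diag = TRUE), arr.ind = TRUE)
    corrRows[[length(corrRows) + 1L]] <- data.frame(
      line = ln, sex = sx, genotype = gt,
      week1 = cm$weeks[idx[, 1]], week2 = cm$weeks[idx[, 2]],
      r = cm$r[idx], n = cm$n[idx], stringsAsFactors = FALSE)
    if (isTRUE(cfg$correlate$heatmaps))
      exportCorrelationHeatmap(cm, file.path(
        cfg$out_dir, sprintf("heatmap_%s_%s_g%d.png", ln, sx, gt)))
  }
  corrCsv <- file.path(cfg$out_dir, "correlations.csv")
  utils::write.csv(do.call(rbind, corrRows), corrCsv, row.names = FALSE)
  manifest <- .stage(manifest, "correlate", corrCsv, t0)

  utils::write.csv(manifest, file.path(cfg$out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
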