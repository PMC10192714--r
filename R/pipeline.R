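## Workflow orchestration: seed derivation, batch execution of
## synthesize -> quantify -> classify -> simulate/fit, manifest with
## content hashes for reproducibility checks.

#' Derive a per-task seed from the global seed
#'
#' Deterministic seed derivation so that batch items are reproducible and
#' independent of execution order: an FNV-1a hash of
#' \code{"<globalSeed>/<stage>/<index>"} folded into the positive 31-bit
#' integer range.
#'
#' @param globalSeed integer global seed.
#' @param stage stage name.
#' @param index item index within the stage.
#' @return a positive integer seed.
#' @export
deriveSeed <- function(globalSeed, stage, index = 1L) {
  s <- paste(globalSeed, stage, index, sep = "/")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h %% (2^31 - 2)) + 1L
}

.KNOWN_STAGES <- c("synth", "quantify", "classify", "fcs")

#' Construct a workflow configuration
#'
#' @param workflow workflow name (free text, recorded in the manifest).
#' @param stages character vector of stages to execute, in order; any of
#'   \code{"synth"}, \code{"quantify"}, \code{"classify"}, \code{"fcs"}.
#' @param seed global seed; all stage randomness derives from it via
#'   [deriveSeed()].
#' @param outDir output directory (created if missing).
#' @param nScenesPerPhase scenes per phase for the synth stage.
#' @param nTraces traces for the fcs stage.
#' @param sceneCfg a [sceneConfig()].
#' @param ruleCfg a [pcnaRuleConfig()].
#' @param simCfg a [SimConfig-class] template (its seed is overridden per
#'   trace).
#' @param nSegments segments for the ACF error bars in the fcs stage.
#' @param logLevel \code{"info"} or \code{"quiet"}.
#' @return a list of class \code{"runConfig"}.
#' @export
runConfig <- function(workflow = "demo",
                      stages = c("synth", "quantify", "classify", "fcs"),
                      seed = 1L, outDir = tempfile("nucleodyn_run_"),
                      nScenesPerPhase = 10L, nTraces = 5L,
                      sceneCfg = sceneConfig(), ruleCfg = pcnaRuleConfig(),
                      simCfg = simConfig(), nSegments = 8L,
                      logLevel = c("info", "quiet")) {
  bad <- setdiff(stages, .KNOWN_STAGES)
  if (length(bad))
    stop("schema error: unknown stage name(s): ", paste(bad, collapse = ", "))
  if (any(c("quantify", "classify") %in% stages) && !"synth" %in% stages)
    stop("schema error: quantify/classify stages require the synth stage")
  cfg <- list(workflow = workflow, stages = stages,
              seed = as.integer(seed), outDir = outDir,
              nScenesPerPhase = as.integer(nScenesPerPhase),
              nTraces = as.integer(nTraces), sceneCfg = sceneCfg,
              ruleCfg = ruleCfg, simCfg = simCfg,
              nSegments = as.integer(nSegments),
              logLevel = match.arg(logLevel))
  class(cfg) <- "runConfig"
  cfg
}

.wlog <- function(cfg, ...) {
  if (cfg$logLevel == "info") message("[nucleodyn] ", ...)
}

#' Execute a workflow
#'
#' Runs the configured stages in order, writing every output below
#' \code{cfg$outDir}, and returns (and writes) a manifest listing each
#' output file with its MD5 content hash. Re-running with an identical
#' configuration reproduces identical hashes: all randomness flows from
#' the global seed through [deriveSeed()].
#'
#' @param cfg a [runConfig()].
#' @return the manifest, invisibly (also written to
#'   \code{<outDir>/manifest.json}).
#' @export
runWorkflow <- function(cfg) {
  stopifnot(inherits(cfg, "runConfig"))
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  .wlog(cfg, "nucleodyn ", as.character(utils::packageVersion("nucleodyn")),
        " workflow '", cfg$workflow, "', seed ", cfg$seed,
        ", stages: ", paste(cfg$stages, collapse = " -> "))
  .wlog(cfg, "resolved config: ", paste(utils::capture.output(
    utils::str(cfg[c("nScenesPerPhase", "nTraces", "nSegments")])),
    collapse = " "))
  files <- character(0)
  scenes <- NULL

  if ("synth" %in% cfg$stages) {
    phases <- c("G", "ES", "MS", "LS")
    scenes <- list()
    for (ph in phases) {
      for (i in seq_len(cfg$nScenesPerPhase)) {
        sc <- renderPCNA(ph, cfg$sceneCfg,
                         seed = deriveSeed(cfg$seed, paste0("synth_", ph), i))
        scenes[[paste0(ph, "_", i)]] <- sc
        files <- c(files, writeScene(
          sc, file.path(cfg$outDir, sprintf("scene_%s_%03d", ph, i))))
      }
    }
    .wlog(cfg, "synth: ", length(scenes), " scenes")
  }

  if ("quantify" %in% cfg$stages) {
    resPx <- cfg$ruleCfg$resolutionUm / cfg$ruleCfg$pixelUm
    met <- do.call(rbind, lapply(names(scenes), function(nm) {
      sc <- scenes[[nm]]
      rep <- detectFoci(sc@image, sc@nucleusMask, sc@nucleoliMask, resPx)
      data.frame(cell_id = nm, cv = rep@cv, n_foci = rep@nFoci,
                 i_r_foci = rep@iRFoci)
    }))
    mpath <- file.path(cfg$outDir, "metrics.csv")
    utils::write.csv(met, mpath, row.names = FALSE, quote = FALSE)
    files <- c(files, mpath)
    .wlog(cfg, "quantify: metrics.csv (", nrow(met), " cells)")
  }

  if ("classify" %in% cfg$stages) {
    calls <- do.call(rbind, lapply(names(scenes), function(nm) {
      sc <- scenes[[nm]]
      ft <- extractPCNAFeatures(sc@image, sc@nucleusMask, sc@nucleoliMask,
                                cfg$ruleCfg)
      pc <- classifyPhase(ft, cfg$ruleCfg)
      data.frame(cell_id = nm, label = pc@label, rule_fired = pc@ruleFired,
                 n_foci = ft@nFoci,
                 frac_peripheral = ft@fracPeripheral,
                 frac_perinucleolar = ft@fracPerinucleolar)
    }))
    cpath <- file.path(cfg$outDir, "calls.csv")
    utils::write.csv(calls, cpath, row.names = FALSE, quote = FALSE)
    files <- c(files, cpath)
    .wlog(cfg, "classify: calls.csv")
  }

  if ("fcs" %in% cfg$stages) {
    for (i in seq_len(cfg$nTraces)) {
      sc <- cfg$simCfg
      sc@seed <- deriveSeed(cfg$seed, "fcs", i)
      out <- simulateTrace(sc)
      crv <- segmentACF(out@trace, cfg$nSegments)
      fit <- fitACF(crv, orderedTimes = TRUE,
                    seed = deriveSeed(cfg$seed, "fcs_fit", i))
      apath <- file.path(cfg$outDir, sprintf("acf_%03d.csv", i))
      fpath <- file.path(cfg$outDir, sprintf("fit_%03d.json", i))
      writeACFCsv(crv, apath)
      writeFitResultJson(fit, fpath)
      files <- c(files, apath, fpath)
    }
    .wlog(cfg, "fcs: ", cfg$nTraces, " traces fitted")
  }

  manifest <- list(
    package = "nucleodyn",
    version = as.character(utils::packageVersion("nucleodyn")),
    workflow = cfg$workflow, seed = cfg$seed,
    stages = cfg$stages,
    outputs = lapply(unname(files), function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    }))
  jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
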