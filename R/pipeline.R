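#' Run the evaluation pipeline end-to-end
#'
#' Orchestrates the stages `simulate` (or loading an existing dataset),
#' `qc`, `relmat`, `fit`, `validate`, `gwas` and `ld`, writing every table
#' plus a JSON-lines log and a manifest (seed, parameter digest) into the
#' output directory. Each stage's randomness is derived from the master
#' seed per stage name, so a rerun with the same configuration reproduces
#' the bundle.
#'
#' @param config named list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{stages}{character subset of
#'       `c("simulate","qc","relmat","fit","validate","gwas","ld")`; the
#'       stage graph is honoured regardless of order.}
#'     \item{params}{[simParams()] overrides (list) for the simulate
#'       stage.}
#'     \item{datasetDir}{existing dataset directory (alternative to
#'       simulate).}
#'     \item{trait}{trait to evaluate (default `"harvestWeight"`).}
#'     \item{vc}{variance components list, or `"reml"` to estimate them.}
#'     \item{validation}{list: `strategies`, `k`, `replicates`.}
#'     \item{gwas}{list: `nIter`.}
#'     \item{outdir}{output directory.}
#'     \item{seed}{master seed.}
#'   }
#' @return invisible list of stage results.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  allStages <- c("simulate", "qc", "relmat", "fit", "validate", "gwas", "ld")
  stages <- config$stages %||% allStages
  bad <- setdiff(stages, allStages)
  if (length(bad) > 0)
    stop("undefined stage name(s): ", paste(bad, collapse = ", "))
  outdir <- config$outdir %||% stop("config$outdir is required")
  seed <- config$seed %||% 1
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  logPath <- file.path(outdir, "pipeline_log.jsonl")
  if (file.exists(logPath)) unlink(logPath)
  logStage <- function(stage, ...) {
    rec <- list(stage = stage, ...)
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
        sep = "", file = logPath, append = TRUE)
  }
  timed <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    logStage(stage, wallSeconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }

  results <- list()
  ## data
  if ("simulate" %in% stages) {
    params <- do.call(simParams, config$params %||% list())
    sim <- timed("simulate", simulateDataset(params, seed = seed))
    writeDataset(sim, file.path(outdir, "dataset"))
  } else if (!is.null(config$datasetDir)) {
    sim <- timed("load", readDataset(config$datasetDir))
  } else {
    stop("either the simulate stage or config$datasetDir is required")
  }
  results$dataset <- sim
  ped <- sim@ped
  geno <- sim@geno
  pheno <- sim@pheno
  trait <- config$trait %||% "harvestWeight"
  spec <- defaultModelSpecs()[[trait]] %||%
    stop("no model spec for trait: ", trait)

  if ("qc" %in% stages) {
    qc <- timed("qc", snpQc(geno))
    geno <- qc$geno
    writeQcReport(qc$report, file.path(outdir, "qc_report.csv"))
    results$qc <- qc$report
  }
  rel <- NULL
  if (any(c("relmat", "fit", "validate", "gwas") %in% stages)) {
    rel <- timed("relmat", buildRelationships(ped, geno))
  }
  vc <- config$vc
  if (is.null(vc) && !is.null(sim@truth$vc)) vc <- sim@truth$vc[[trait]]
  design <- buildDesign(pheno, spec, ped)
  if (identical(vc, "reml")) {
    est <- timed("reml", emReml(design, rel$Ainv))
    vc <- list(sigma2_u = est$sigma2_u, sigma2_p = est$sigma2_p,
               sigma2_e = est$sigma2_e)
    results$reml <- est
  }
  if (is.null(vc)) stop("variance components unavailable: set config$vc")

  if ("fit" %in% stages) {
    fits <- timed("fit", list(
      BLUP = solveMME(design, rel$Ainv, vc, method = "BLUP"),
      ssGBLUP = solveMME(design, rel$Hinv, vc, method = "ssGBLUP")))
    for (m in names(fits))
      writeSolutions(fits[[m]], ped,
                     file.path(outdir, paste0("solutions_", m, ".csv")))
    results$fits <- fits
    logStage("fit", corBlupSsgblup = stats::cor(ebv(fits$BLUP),
                                                ebv(fits$ssGBLUP)))
  }
  if ("validate" %in% stages) {
    v <- config$validation %||% list()
    res <- timed("validate", runValidation(
      ped, geno, pheno, spec, vc, rel = rel,
      strategies = v$strategies %||% c(1, 2),
      k = v$k %||% 5, replicates = v$replicates %||% 5,
      seed = deriveSeed(seed, "validate")))
    utils::write.csv(res, file.path(outdir, "validation.csv"),
                     row.names = FALSE)
    utils::write.csv(summarizeValidation(res),
                     file.path(outdir, "validation_summary.csv"),
                     row.names = FALSE)
    results$validation <- res
  }
  if ("gwas" %in% stages) {
    gw <- config$gwas %||% list()
    scan <- timed("gwas", wssgblup(ped, geno, pheno, spec, vc,
                                   nIter = gw$nIter %||% 5,
                                   seed = deriveSeed(seed, "gwas")))
    it <- scan$iterations[[scan$selected]]
    win <- windowVariances(it$effects, alleleFrequencies(geno),
                           snpMap(geno))
    utils::write.csv(win, file.path(outdir, "gwas_windows.csv"),
                     row.names = FALSE)
    utils::write.csv(manhattanTable(win),
                     file.path(outdir, "manhattan.csv"), row.names = FALSE)
    results$gwas <- scan
    logStage("gwas", selectedIteration = scan$selected,
             topWindowPct = max(win$pctVariance))
  }
  if ("ld" %in% stages) {
    ldRes <- timed("ld", {
      rec <- adjacentR2(geno)
      list(records = rec, mean = meanR2(rec), ne = neFromLd(geno))
    })
    utils::write.csv(ldRes$records, file.path(outdir, "ld_pairs.csv"),
                     row.names = FALSE)
    utils::write.csv(ldRes$ne$byChrom, file.path(outdir, "ld_by_chrom.csv"),
                     row.names = FALSE)
    results$ld <- ldRes
    logStage("ld", genomeMeanR2 = ldRes$mean$genome, NeLd = ldRes$ne$Ne)
  }
  jsonlite::write_json(
    list(seed = seed, stages = stages,
         params = if (!is.null(results$dataset)) results$dataset@params),
    file.path(outdir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(results)
}
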