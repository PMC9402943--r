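# End-to-end replay pipeline: simulate (or load) -> filter -> fit clock ->
# score -> subtype -> survival -> associations -> optional frozen-weight
# validation replay. One global seed; per-stage seeds are derived by
# hashing the stage name, so adding a stage never perturbs the draws of
# earlier stages.

# FNV-1a 32-bit hash, multiplication split into 16-bit halves so every
# intermediate stays exactly representable in a double
xor32 <- function(a, b) {
  bitwXor(a %% 65536, b %% 65536) +
    bitwXor(a %/% 65536, b %/% 65536) * 65536
}

fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- xor32(h, b)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  h
}

#' Derive a stage-specific seed from the pipeline seed
#'
#' Keyed scheme: the stage name is hashed (FNV-1a) and combined with the
#' global seed modulo 2^31 - 1, so each stage has its own reproducible
#' stream and inserting a new stage leaves the others' draws unchanged.
#'
#' @param seed global integer seed.
#' @param stage stage name.
#' @return integer seed in \[0, 2^31 - 1).
#' @export
stageSeed <- function(seed, stage) {
  as.integer((as.numeric(seed) + fnv1a(stage)) %% 2147483647)
}

defaultPipelineConfig <- function() {
  list(
    seed = 1L,
    simulate = list(),
    filters = c("survival_unknown", "survival_lt_30d"),
    clock = list(threshold = 0.5, normalization = "minmax01",
                 calibration_mode = "cohort_constant"),
    survival = list(max_years = 6, prognostic_screen = TRUE, alpha = 0.05),
    association = list(stemness_method = "pearson"),
    validation = NULL
  )
}

mergeConfig <- function(base, user) {
  for (k in names(user)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(user[[k]]))
      mergeConfig(base[[k]], user[[k]]) else user[[k]]
  }
  base
}

loadCohortStage <- function(cfg, seed) {
  if (!is.null(cfg$inputs)) {
    inp <- cfg$inputs
    if (is.null(inp$expression) || is.null(inp$clinical))
      stop("config inputs must name 'expression' and 'clinical' paths")
    for (p in c(inp$expression, inp$clinical, inp$stemness, inp$gene_panel))
      if (!file.exists(p)) stop("input path does not exist: ", p)
    panel <- if (!is.null(inp$gene_panel)) readLines(inp$gene_panel) else NULL
    expr <- readExpression(inp$expression, geneSubset = panel)
    clin <- readClinical(inp$clinical,
                         timeUnit = if (is.null(inp$time_unit)) "days"
                                    else inp$time_unit)
    stem <- if (!is.null(inp$stemness)) readStemness(inp$stemness) else NULL
    InflammCohort(expr, clin, stemness = stem)
  } else {
    sim <- cfg$simulate
    sim$seed <- seed
    generateCohort(do.call(simConfig, sim))
  }
}

#' Run the full inflammatory-clock pipeline
#'
#' Executes the stages in study order — cohort acquisition (synthetic by
#' default, or the three input tables), inclusion filtering, age-gene
#' screening and clock fitting, iAge scoring, median-split subtyping,
#' Kaplan-Meier / log-rank comparison of the subtypes, the univariate Cox
#' prognostic screen, stemness correlations, the annual conditional
#' survival table, and (when a `validation` block is present) frozen-weight
#' replay scoring of a second cohort. Every intermediate result is written
#' to `outDir` as plain text, and a JSON run manifest records the config
#' hash, per-stage sizes and timings. Two runs with the same config and
#' seed produce identical numeric outputs.
#'
#' @param config a configuration list, or the path of a YAML file holding
#'   one. Recognized top-level keys: `seed`, `simulate` (arguments of
#'   [simConfig()]) or `inputs` (paths `expression`, `clinical`,
#'   `stemness`, `gene_panel`, plus `time_unit`), `filters`, `clock`
#'   (`threshold`, `normalization`, `calibration_mode`), `survival`
#'   (`max_years`, `prognostic_screen`, `alpha`), `association`
#'   (`stemness_method`), `validation` (same shape as `simulate`/`inputs`).
#'   Unspecified keys fall back to defaults.
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with the manifest and the in-memory stage
#'   results (`cohort`, `filter_report`, `model`, `iage`, `subtypes`,
#'   `logrank`, `prognostic`, `stemness`, `conditional`, `validation`).
#' @export
runPipeline <- function(config = list(), outDir = tempfile("inflammrun")) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file does not exist: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- mergeConfig(defaultPipelineConfig(), config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("inflammclock")),
    config_hash = {
      h <- fnv1a(paste(deparse(cfg), collapse = ""))
      sprintf("%04x%04x", h %/% 65536, h %% 65536)
    },
    seed = cfg$seed,
    stages = list(),
    warnings = character(0)
  )
  results <- list()
  current <- "init"
  tick <- function(name, n) {
    manifest$stages[[name]] <<- list(n = n, seconds = round(
      as.numeric(proc.time()[3]) - t0, 3))
    t0 <<- as.numeric(proc.time()[3])
  }
  t0 <- as.numeric(proc.time()[3])

  runStages <- function() {
    current <<- "cohort"
    cohort <- loadCohortStage(cfg, stageSeed(cfg$seed, "simulate"))
    results$cohort <<- cohort
    tick("cohort", ncol(cohort))

    current <<- "filter"
    report <- applyInclusionFilters(clinicalData(cohort), cfg$filters)
    filterReportJSON(report, file.path(outDir, "filter_report.json"))
    cohort <- retainSamples(cohort, report)
    results$filter_report <<- report
    tick("filter", report@nRetained)

    current <<- "clock"
    model <- fitIAgeClock(cohort,
                          threshold = cfg$clock$threshold,
                          normalization = cfg$clock$normalization,
                          calibrationMode = cfg$clock$calibration_mode)
    writeIAgeModel(model, file.path(outDir, "model.json"))
    iage <- scoreCohort(model, cohort)
    subtypes <- classifyByMedian(iage)
    iage$subtype <- subtypes$subtype
    utils::write.table(iage, file.path(outDir, "iage.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    results$model <<- model
    results$iage <<- iage
    results$subtypes <<- subtypes
    tick("clock", sum(model@weights$selected))

    current <<- "survival"
    cl <- clinicalData(cohort)
    known <- cl$survival_known
    yrs <- cl$survival_time_days[known] / 365.25
    ev <- cl$event[known]
    grp <- subtypes$subtype[known]
    lr <- logrankTest(yrs, ev, grp)
    jsonlite::write_json(lr, file.path(outDir, "logrank.json"),
                         auto_unbox = TRUE, digits = NA)
    for (g in levels(grp)) {
      km <- kmEstimate(yrs[grp == g], ev[grp == g])
      utils::write.table(
        data.frame(time = km@time, n_risk = km@nRisk, n_event = km@nEvent,
                   survival = km@surv, se = km@se),
        file.path(outDir, paste0("km_", g, ".tsv")), sep = "\t",
        quote = FALSE, row.names = FALSE)
    }
    kmAll <- kmEstimate(yrs, ev)
    condTab <- annualSurvivalTable(kmAll, cfg$survival$max_years)
    utils::write.table(condTab$probabilities,
                       file.path(outDir, "conditional_survival.tsv"),
                       sep = "\t", quote = FALSE, row.names = TRUE,
                       col.names = NA)
    results$logrank <<- lr
    results$conditional <<- condTab
    if (isTRUE(cfg$survival$prognostic_screen)) {
      prog <- screenPrognosticGenes(cohort, alpha = cfg$survival$alpha)
      utils::write.table(prog, file.path(outDir, "prognostic_genes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      results$prognostic <<- prog
    }
    tick("survival", sum(known))

    current <<- "association"
    if (!is.null(stemnessData(cohort))) {
      stemCor <- correlateStemness(iage, cohort,
                                   method = cfg$association$stemness_method)
      utils::write.table(stemCor, file.path(outDir, "stemness_correlations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      results$stemness <<- stemCor
    }
    tick("association", 8L)

    if (!is.null(cfg$validation)) {
      current <<- "validation"
      vcfg <- cfg
      vcfg$inputs <- cfg$validation$inputs
      vcfg$simulate <- cfg$validation$simulate
      if (is.null(vcfg$inputs) && is.null(vcfg$simulate))
        stop("validation block needs 'inputs' or 'simulate'")
      vcohort <- loadCohortStage(vcfg, stageSeed(cfg$seed, "validation"))
      vrules <- if (is.null(cfg$validation$filters))
        c("recurrent_or_multiple", "survival_unknown") else
        cfg$validation$filters
      vreport <- applyInclusionFilters(clinicalData(vcohort), vrules)
      vcohort <- retainSamples(vcohort, vreport)
      viage <- scoreCohort(model, vcohort)      # frozen replay
      vsub <- classifyByMedian(viage)
      viage$subtype <- vsub$subtype
      utils::write.table(viage, file.path(outDir, "validation_iage.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      filterReportJSON(vreport,
                       file.path(outDir, "validation_filter_report.json"))
      results$validation <<- list(report = vreport, iage = viage,
                                  subtypes = vsub, cohort = vcohort)
      tick("validation", vreport@nRetained)
    }
  }

  ok <- tryCatch({
    withCallingHandlers(runStages(), warning = function(w) {
      manifest$warnings <<- c(manifest$warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
    TRUE
  }, error = function(e) {
    manifest$failed_stage <<- current
    manifest$error <<- conditionMessage(e)
    FALSE
  })
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!ok)
    stop("pipeline failed at stage '", current, "': ", manifest$error)
  invisible(c(list(manifest = manifest, out_dir = outDir), results))
}
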