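# Orchestrates the full analysis from a single validated config:
# synthetic or file inputs -> paired-sample QC -> CV seed-gene filter ->
# network/modules -> module-trait -> PPI hub screen -> clinical/survival
# -> enrichment. Every stage persists its artifact and is echoed in a
# machine-readable run report.

.pipelineDefaults <- function() {
  list(
    seed = 1L,
    outdir = NULL,
    synth = list(),           # simulationConfig overrides; NULL = file input
    input = list(expression = NULL, samples = NULL, ppi = NULL,
                 clinical = NULL, geneSets = NULL),
    qc = list(tumorGroups = 2L, normalGroups = 3L, tol = 0.15),
    cv = list(cutoff = NULL, topN = NULL, topFraction = 0.8,
              scale = "linear"),
    network = list(power = 6L, minModuleSize = 30L, mergeHeight = 0.25,
                   edgeThreshold = 0.1, sign = "unsigned",
                   scaleFreeTarget = 0.85, staticQuantile = 0.99,
                   gapSensitivity = 0.1),
    moduleSelect = list(n = 3L, direction = "abs"),
    hub = list(proportionThreshold = 0.10, alpha = 0.05,
               adjust = "bonferroni"),
    clinical = list(covariates = c("age_class", "sex", "tnm",
                                   "tumor_size", "afp")),
    enrichment = list(nPerm = 1000L, weight = 1, metric = "s2n",
                      ssgseaAlpha = 0.25)
  )
}

#' Validate a pipeline configuration
#'
#' Accepts a named list or a path to a JSON file; unknown keys and
#' out-of-range values are rejected with the offending field named;
#' missing keys are filled with the canonical defaults (power 6,
#' minimum module size 30, merge height 0.25, edge threshold 0.1,
#' proportion threshold 0.10, alpha 0.05).
#'
#' @param config named list or JSON file path (NULL = all defaults).
#' @return validated config list of class \code{"PipelineConfig"}.
#' @export
validateConfig <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config)) config <- list()
  if (inherits(config, "PipelineConfig")) config <- unclass(config)
  defaults <- .pipelineDefaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  merged <- defaults
  for (k in names(config)) {
    if (is.list(defaults[[k]]) && k != "synth") {
      sub <- config[[k]]
      bad <- setdiff(names(sub), names(defaults[[k]]))
      if (length(bad))
        stop("unknown config key(s) under '", k, "': ",
             paste(bad, collapse = ", "))
      merged[[k]][names(sub)] <- sub
    } else {
      merged[[k]] <- config[[k]]
    }
  }
  # range checks mirror the stage constructors, so failures name fields
  nw <- merged$network
  if (nw$power < 1 || nw$power != round(nw$power))
    stop("network.power must be an integer >= 1")
  do.call(networkConfig, nw)  # full validation
  if (!is.null(merged$synth) && length(merged$synth))
    do.call(simulationConfig, c(merged$synth,
                                list(seed = merged$seed)))
  hb <- merged$hub
  if (hb$proportionThreshold < 0 || hb$proportionThreshold > 1)
    stop("hub.proportionThreshold must lie in [0, 1]")
  if (hb$alpha <= 0 || hb$alpha >= 1)
    stop("hub.alpha must lie in (0, 1)")
  if (!hb$adjust %in% c("bonferroni", "bh"))
    stop("hub.adjust must be 'bonferroni' or 'bh'")
  if (merged$enrichment$nPerm < 100)
    stop("enrichment.nPerm must be >= 100")
  merged$seed <- as.integer(merged$seed)
  structure(merged, class = "PipelineConfig")
}

#' Serialize a validated config to JSON
#'
#' \code{validateConfig(dumpConfig(x))} revalidates to an identical
#' object.
#'
#' @param config a \code{"PipelineConfig"}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
dumpConfig <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: data (synthetic generation or file input), qc,
#' cv_filter, network, module_trait, hub_screen, clinical, enrichment.
#' Each stage writes its artifact TSV under \code{outdir}; a failure
#' aborts with the stage name; stages without inputs (e.g. no clinical
#' table) are marked "skipped". Fully deterministic given the seed.
#'
#' @param config a \code{\link{validateConfig}} result (or anything it
#'   accepts).
#' @return invisible list: \code{report} (per-stage status, counts,
#'   timings, parameters, seed, version) plus the main in-memory
#'   artifacts.
#' @export
runPipeline <- function(config = NULL) {
  config <- validateConfig(config)
  outdir <- config$outdir
  if (is.null(outdir))
    stop("config$outdir is required")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(version = as.character(packageVersion("hepanet")),
                 seed = config$seed, stages = list())
  artifacts <- list()
  stamp <- function(stage, status, counts = list(), t0 = NULL) {
    report$stages[[stage]] <<- c(
      list(status = status,
           seconds = if (is.null(t0)) NA_real_ else
             round(as.numeric(Sys.time()) - t0, 3)),
      counts)
  }
  runStage <- function(stage, fn) {
    t0 <- as.numeric(Sys.time())
    tryCatch(fn(t0), error = function(e)
      stop("pipeline stage '", stage, "' failed: ",
           conditionMessage(e), call. = FALSE))
  }

  useSynth <- is.null(config$input$expression)

  # ---- stage: data ----
  runStage("data", function(t0) {
    if (useSynth) {
      simCfg <- do.call(simulationConfig,
                        c(config$synth, list(seed = config$seed)))
      ex <- simulateExpression(simCfg)
      pp <- simulatePPI(simCfg, ex$truth)
      clin <- simulateClinicalTable(n = simCfg$nSubjects,
                                    survivalSpec = simCfg$survival,
                                    seed = config$seed + 4L)
      sets <- syntheticImmuneSets(rownames(ex$se),
                                  seed = config$seed + 5L)
      artifacts$se <<- ex$se
      artifacts$truth <<- ex$truth
      artifacts$ppi <<- pp$ppi
      artifacts$plantedHubs <<- pp$hubs
      artifacts$clinical <<- clin
      artifacts$geneSets <<- sets
    } else {
      cd <- if (!is.null(config$input$samples))
        read.delim(config$input$samples, stringsAsFactors = FALSE)
      else NULL
      artifacts$se <<- readExpressionMatrix(config$input$expression,
                                            colData = cd)
      artifacts$ppi <<- if (!is.null(config$input$ppi))
        readPPIEdges(config$input$ppi) else NULL
      artifacts$clinical <<- if (!is.null(config$input$clinical))
        readClinical(config$input$clinical) else NULL
      artifacts$geneSets <<- if (!is.null(config$input$geneSets))
        readGeneSets(config$input$geneSets) else NULL
    }
    stamp("data", "completed",
          list(genes = nrow(artifacts$se),
               samples = ncol(artifacts$se)), t0)
  })
  se <- artifacts$se

  # ---- stage: qc ----
  hasPairs <- all(c("subject_id", "tissue") %in%
                  colnames(SummarizedExperiment::colData(se)))
  if (hasPairs) {
    runStage("qc", function(t0) {
      qc <- selectConsistentPairs(se,
        tumorGroups = config$qc$tumorGroups,
        normalGroups = config$qc$normalGroups, tol = config$qc$tol)
      artifacts$qc <<- qc
      artifacts$se <<- applyFilters(se, qc = qc)
      write.table(droppedSamples(qc), file.path(outdir, "qc_dropped.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      stamp("qc", "completed",
            list(subjectsRetained = length(retainedSubjects(qc)),
                 samplesRetained = length(retainedSamples(qc)),
                 samplesDropped = nrow(droppedSamples(qc))), t0)
    })
    se <- artifacts$se
  } else stamp("qc", "skipped")

  # ---- stage: cv_filter ----
  runStage("cv_filter", function(t0) {
    cvc <- config$cv
    gf <- if (!is.null(cvc$topN))
      cvFilter(se, topN = cvc$topN, scale = cvc$scale)
    else if (!is.null(cvc$cutoff))
      cvFilter(se, cutoff = cvc$cutoff, scale = cvc$scale)
    else
      cvFilter(se, topN = max(10L, round(cvc$topFraction * nrow(se))),
               scale = cvc$scale)
    artifacts$geneFilter <<- gf
    artifacts$se <<- applyFilters(se, geneFilter = gf)
    writeResultTable(
      data.frame(gene = names(geneCV(gf)), cv = geneCV(gf),
                 retained = names(geneCV(gf)) %in% retainedGenes(gf)),
      file.path(outdir, "cv_filter.tsv"))
    stamp("cv_filter", "completed",
          list(genesIn = nrow(se), genesOut = length(retainedGenes(gf))),
          t0)
  })
  se <- artifacts$se

  # ---- stage: network ----
  runStage("network", function(t0) {
    ncfg <- do.call(networkConfig, config$network)
    net <- buildCoexpressionNetwork(se, ncfg)
    artifacts$network <<- net
    mods <- moduleLabels(net)
    writeResultTable(data.frame(gene = names(mods), module = mods),
                     file.path(outdir, "modules.tsv"))
    me <- eigengenes(net)
    if (nrow(me))
      writeResultTable(data.frame(module = rownames(me),
                                  as.data.frame(me),
                                  check.names = FALSE),
                       file.path(outdir, "eigengenes.tsv"))
    stamp("network", "completed",
          list(genes = length(net@genes),
               modules = length(setdiff(unique(mods), "grey")),
               greyGenes = sum(mods == "grey")), t0)
  })
  net <- artifacts$network

  # ---- stage: module_trait ----
  runStage("module_trait", function(t0) {
    trait <- SummarizedExperiment::colData(se)$trait
    if (is.null(trait) || nrow(eigengenes(net)) == 0L) {
      stamp("module_trait", "skipped")
      return(invisible(NULL))
    }
    mt <- moduleTraitCorrelation(eigengenes(net), as.numeric(trait))
    artifacts$moduleTrait <<- mt
    writeResultTable(mt, file.path(outdir, "module_trait.tsv"))
    nSel <- min(config$moduleSelect$n, nrow(mt))
    sel <- if (config$moduleSelect$direction == "positive")
      head(mt$module[order(-mt$r)], nSel)
    else head(mt$module, nSel)
    artifacts$selectedModules <<- sel
    mods <- moduleLabels(net)
    edges <- exportEdges(tomMatrix(net), mods,
                         threshold = config$network$edgeThreshold,
                         selectedModules = sel)
    writeResultTable(edges, file.path(outdir, "edges.tsv"))
    stamp("module_trait", "completed",
          list(modulesSelected = length(sel), edges = nrow(edges)), t0)
  })

  # ---- stage: hub_screen ----
  if (!is.null(artifacts$ppi) && !is.null(artifacts$selectedModules)) {
    runStage("hub_screen", function(t0) {
      mods <- moduleLabels(net)
      coexprGenes <- names(mods)[mods %in% artifacts$selectedModules]
      hs <- screenHubs(artifacts$ppi, coexprGenes,
                       proportionThreshold =
                         config$hub$proportionThreshold,
                       alpha = config$hub$alpha,
                       adjust = config$hub$adjust)
      artifacts$hubScreen <<- hs
      writeResultTable(hubTable(hs), file.path(outdir, "hub_table.tsv"))
      stamp("hub_screen", "completed",
            list(coexprGenes = length(coexprGenes),
                 covered = hs@coverage$nCovered,
                 hubs = length(hubGenes(hs))), t0)
    })
  } else stamp("hub_screen", "skipped")

  # ---- stage: clinical ----
  clin <- artifacts$clinical
  if (!is.null(clin) && nrow(clin) > 0L) {
    runStage("clinical", function(t0) {
      cvs <- intersect(config$clinical$covariates, colnames(clin))
      counts <- list()
      if ("expr_class" %in% colnames(clin) && length(cvs)) {
        assoc <- clinicalAssociationTable(clin, clin$expr_class, cvs)
        writeResultTable(assoc, file.path(outdir, "clinical_assoc.tsv"))
        counts$covariatesTested <- length(cvs)
      }
      if (all(c("time", "event") %in% colnames(clin))) {
        km <- kmEstimate(clin)
        writeResultTable(km, file.path(outdir, "km.tsv"))
        if ("expr_class" %in% colnames(clin)) {
          lr <- logrankTest(clin, clin$expr_class)
          df <- clin
          df$expr_high <- as.integer(df$expr_class == "high")
          cx <- coxFit(df, c("expr_high", cvs), mode = "univariate")
          artifacts$cox <<- cx
          writeResultTable(cx, file.path(outdir, "cox.tsv"))
          counts$logrank_p <- lr$p
        }
      }
      artifacts$clinicalCounts <<- counts
      stamp("clinical", "completed", counts, t0)
    })
  } else stamp("clinical", "skipped")

  # ---- stage: enrichment ----
  if (!is.null(artifacts$geneSets)) {
    runStage("enrichment", function(t0) {
      trait <- SummarizedExperiment::colData(se)$trait
      counts <- list()
      if (!is.null(trait) && length(unique(trait)) == 2L) {
        gs <- gseaPermutation(se, ifelse(trait == 1, "tumor", "normal"),
                              artifacts$geneSets,
                              nPerm = config$enrichment$nPerm,
                              weight = config$enrichment$weight,
                              metric = config$enrichment$metric,
                              seed = config$seed + 7L,
                              positiveGroup = "tumor")
        artifacts$gsea <<- gs
        writeResultTable(gs, file.path(outdir, "gsea.tsv"))
        counts$gseaSets <- nrow(gs)
      }
      ss <- ssgseaScores(se, artifacts$geneSets,
                         alpha = config$enrichment$ssgseaAlpha)
      artifacts$ssgsea <<- ss
      writeResultTable(
        data.frame(cell_type = rownames(ss$scores),
                   as.data.frame(ss$scores), check.names = FALSE),
        file.path(outdir, "ssgsea.tsv"))
      hubs <- if (!is.null(artifacts$hubScreen))
        hubGenes(artifacts$hubScreen) else character(0)
      if (length(hubs)) {
        gv <- SummarizedExperiment::assay(se, "exprs")[hubs[1L], ]
        ic <- immuneCorrelation(ss$scores, gv)
        artifacts$immuneCorrelation <<- ic
        writeResultTable(ic, file.path(outdir, "immune_corr.tsv"))
        counts$immuneCellTypes <- nrow(ic)
      }
      stamp("enrichment", "completed", counts, t0)
    })
  } else stamp("enrichment", "skipped")

  report$stages <- report$stages
  jsonlite::write_json(report, file.path(outdir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(list(report = report), artifacts))
}
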