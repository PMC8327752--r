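# Synthetic-data generator: block-correlated expression with planted
# modules tied to a binary tumor/normal trait, a scale-free PPI graph
# with planted co-expression-enriched hubs, exponential survival with
# expression-dependent hazards, and 2x2-structured clinical covariates.
# All generators are pure functions of (config, seed): substreams are
# derived as seed + fixed small offsets.

#' Build a simulation configuration
#'
#' Defaults describe the emulated study: 54 subject pairs (tumor +
#' adjacent normal), three planted co-expression modules of 50 genes at
#' within-module correlation 0.9 whose latent eigengene is shifted by the
#' tumor trait, 100 unstructured background genes, a preferential-
#' attachment PPI graph (2000 nodes, so the co-expression genes cover
#' ~7.5% of it, near the coverage rate of the emulated human network)
#' with four planted hubs whose neighborhoods are co-expression-enriched
#' at rate 0.4, exponential survival with hazard
#' ratio 1.921 for the high-expression class, and clinical covariates
#' with the marginal frequencies of a 90-patient tissue-microarray
#' cohort.
#'
#' @param nSubjects number of subjects; each contributes one tumor and
#'   one normal sample.
#' @param nGenes total genes (module genes + background).
#' @param modules list of lists with elements \code{size}, \code{rho}
#'   (within-module correlation in (0,1)) and \code{d} (trait shift of
#'   the latent eigengene, in latent SD units).
#' @param noiseSd idiosyncratic noise SD multiplier.
#' @param baseline mean of the per-gene baseline, giving
#'   log2-microarray-like values.
#' @param baselineSd SD of the per-gene baseline. Gene-level baselines
#'   shared across samples are what give real expression data its high
#'   sample-sample correlations; without them correlation-based sample
#'   QC has nothing to measure.
#' @param ppi list: \code{nNodes}, \code{attach} (edges per arriving
#'   node), \code{nHubs}, \code{hubCoexprRate}, \code{minHubDegree}.
#' @param survival list: \code{baselineHazard} (events/month),
#'   \code{betaSurv} (log hazard ratio per covariate unit),
#'   \code{censoringRate} in [0, 1).
#' @param seed integer master seed.
#' @return validated list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(nSubjects = 54L,
                             nGenes = 250L,
                             modules = list(
                               list(size = 50L, rho = 0.9, d = 2),
                               list(size = 50L, rho = 0.9, d = 2),
                               list(size = 50L, rho = 0.9, d = 2)),
                             noiseSd = 1,
                             baseline = 8,
                             baselineSd = 2,
                             ppi = list(nNodes = 2000L, attach = 3L,
                                        nHubs = 4L, hubCoexprRate = 0.4,
                                        minHubDegree = 30L),
                             survival = list(baselineHazard = 0.05,
                                             betaSurv = log(1.921),
                                             censoringRate = 0.3),
                             seed = 1L) {
  cfg <- list(nSubjects = as.integer(nSubjects),
              nGenes = as.integer(nGenes), modules = modules,
              noiseSd = noiseSd, baseline = baseline,
              baselineSd = baselineSd, ppi = ppi,
              survival = survival, seed = as.integer(seed))
  sizes <- vapply(modules, function(m) as.integer(m$size), integer(1))
  rhos <- vapply(modules, function(m) m$rho, numeric(1))
  if (sum(sizes) > cfg$nGenes)
    stop("infeasible config: module sizes exceed gene count")
  if (any(rhos <= 0 | rhos >= 1))
    stop("within-module correlation rho must lie in (0, 1)")
  if (cfg$survival$censoringRate < 0 || cfg$survival$censoringRate >= 1)
    stop("censoring rate must lie in [0, 1)")
  if (cfg$survival$baselineHazard <= 0)
    stop("baseline hazard must be positive")
  if (cfg$nSubjects < 1L) stop("need at least one subject")
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Simulate paired tumor/normal expression with planted modules
#'
#' Latent-factor model: module \eqn{m} has one latent eigengene per
#' sample, \eqn{e = N(0,1) + d \cdot trait}; each member gene is
#' \eqn{x = \sqrt{\rho}\, e + noiseSd\sqrt{1-\rho}\, \epsilon + b_g}
#' with a per-gene baseline \eqn{b_g \sim N(baseline, baselineSd^2)}, so
#' with \code{noiseSd = 1} the within-module gene-gene correlation is
#' \eqn{\rho}. Background genes are i.i.d. noise around their baseline.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list with \code{se} (SummarizedExperiment; colData has
#'   \code{subject_id}, \code{tissue}, \code{trait}) and \code{truth}
#'   (list: \code{moduleLabels} named per gene with "background" for
#'   unstructured genes, \code{eigengenes} latent module x sample matrix).
#' @export
simulateExpression <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 1L)
  nS <- config$nSubjects
  subj <- sprintf("S%03d", seq_len(nS))
  sampleIds <- c(paste0(subj, "_T"), paste0(subj, "_N"))
  tissue <- rep(c("tumor", "normal"), each = nS)
  trait <- as.integer(tissue == "tumor")
  n <- 2L * nS

  sizes <- vapply(config$modules, function(m) as.integer(m$size),
                  integer(1))
  nMod <- length(sizes)
  geneIds <- sprintf("G%04d", seq_len(config$nGenes))
  labels <- rep("background", config$nGenes)
  idx <- 0L
  latent <- matrix(0, nrow = nMod, ncol = n,
                   dimnames = list(paste0("M", seq_len(nMod)), sampleIds))
  mat <- matrix(0, nrow = config$nGenes, ncol = n,
                dimnames = list(geneIds, sampleIds))
  for (m in seq_len(nMod)) {
    spec <- config$modules[[m]]
    e <- rnorm(n) + spec$d * trait
    latent[m, ] <- e
    rows <- idx + seq_len(sizes[m])
    eps <- matrix(rnorm(sizes[m] * n), nrow = sizes[m])
    mat[rows, ] <- sqrt(spec$rho) * matrix(e, nrow = sizes[m],
                                           ncol = n, byrow = TRUE) +
      config$noiseSd * sqrt(1 - spec$rho) * eps
    labels[rows] <- paste0("M", m)
    idx <- idx + sizes[m]
  }
  nBg <- config$nGenes - idx
  if (nBg > 0L)
    mat[idx + seq_len(nBg), ] <- config$noiseSd *
      matrix(rnorm(nBg * n), nrow = nBg)
  geneBaseline <- rnorm(config$nGenes, config$baseline,
                        config$baselineSd)
  mat <- mat + geneBaseline
  names(labels) <- geneIds

  cd <- S4Vectors::DataFrame(
    sample_id = sampleIds, subject_id = rep(subj, 2L),
    tissue = tissue, trait = trait, row.names = sampleIds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = mat), colData = cd)
  list(se = se,
       truth = list(moduleLabels = labels, eigengenes = latent))
}

#' Simulate a scale-free PPI graph with planted co-expression hubs
#'
#' A preferential-attachment (Barabasi-Albert) graph over a node universe
#' containing every simulated gene (padded with extra background symbols
#' if \code{ppi$nNodes > nGenes}). Planted hub genes are drawn from the
#' module genes; each hub's neighborhood is redrawn so that every
#' neighbor is a module (co-expressed) gene independently with
#' probability \code{hubCoexprRate}. Non-hub neighborhoods inherit the
#' attachment wiring, which is blind to module membership, so their
#' co-expressed-neighbor fraction sits at the background rate.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param truth the \code{truth} element from
#'   \code{\link{simulateExpression}}.
#' @return list with \code{ppi} (a \code{\link{PPINetwork}}) and
#'   \code{hubs} (character vector of planted hub genes).
#' @export
simulatePPI <- function(config, truth) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 2L)
  p <- config$ppi
  moduleGenes <- names(truth$moduleLabels)[
    truth$moduleLabels != "background"]
  if (p$nHubs > length(moduleGenes))
    stop("hub count exceeds module genes")
  genes <- names(truth$moduleLabels)
  nNodes <- as.integer(p$nNodes)
  universe <- if (nNodes <= length(genes)) sample(genes, nNodes)
              else c(genes, sprintf("PPIBG%05d",
                                    seq_len(nNodes - length(genes))))
  universe <- sample(universe)  # scatter module genes over degree ranks

  g <- igraph::sample_pa(nNodes, power = 1, m = p$attach,
                         directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  from <- universe[el[, 1L]]
  to <- universe[el[, 2L]]

  hubs <- sample(moduleGenes, p$nHubs)
  keep <- !(from %in% hubs | to %in% hubs)
  from <- from[keep]; to <- to[keep]
  bgPool <- setdiff(universe, c(moduleGenes, hubs))
  deg <- table(c(el[, 1L], el[, 2L]))
  for (h in hubs) {
    d0 <- deg[as.character(match(h, universe))]
    k <- max(p$minHubDegree, if (is.na(d0)) 0L else as.integer(d0))
    isCo <- rbinom(k, 1L, p$hubCoexprRate) == 1L
    nbCo <- sample(setdiff(moduleGenes, h), sum(isCo))
    nbBg <- sample(bgPool, sum(!isCo))
    from <- c(from, rep(h, k))
    to <- c(to, c(nbCo, nbBg))
  }
  list(ppi = makePPINetwork(from, to, nodes = universe), hubs = hubs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate exponential survival with expression-dependent hazard
#'
#' Event times are exponential with subject hazard
#' \eqn{h_0 \exp(\beta x)}; censoring times are uniform on \eqn{(0, u)}
#' with \eqn{u} solved numerically so the expected censoring fraction
#' matches \code{censoringRate} (0 disables censoring entirely).
#'
#' @param x numeric covariate vector, one value per patient.
#' @param survivalSpec list with \code{baselineHazard}, \code{betaSurv},
#'   \code{censoringRate}.
#' @param seed integer seed.
#' @return data.frame: \code{time} (months), \code{event} (0/1),
#'   \code{x}.
#' @export
simulateSurvival <- function(x, survivalSpec, seed = 1L) {
  h0 <- survivalSpec$baselineHazard
  if (!is.numeric(h0) || h0 <= 0) stop("baseline hazard must be positive")
  beta <- survivalSpec$betaSurv
  cr <- survivalSpec$censoringRate
  set.seed(seed)
  lam <- h0 * exp(beta * x)
  tt <- rexp(length(x), rate = lam)
  if (cr > 0) {
    censFrac <- function(u) mean((1 - exp(-lam * u)) / (lam * u)) - cr
    u <- uniroot(censFrac, lower = 1e-8, upper = 1e8, tol = 1e-10)$root
    cc <- runif(length(x), 0, u)
    event <- as.integer(tt <= cc)
    time <- pmin(tt, cc)
  } else {
    event <- rep(1L, length(x))
    time <- tt
  }
  data.frame(time = time, event = event, x = x)
}

#' Simulate a clinicopathological table with 2x2-structured covariates
#'
#' Patients get a binary expression class (low/high); each categorical
#' covariate is drawn with a prescribed marginal frequency and a
#' prescribed odds ratio linking its second level to the high-expression
#' class. Defaults follow the marginal structure of a 90-patient cohort
#' (57 low / 33 high; AFP and TNM associated with expression, odds
#' ratios 3.0 and 2.5; age, sex and tumor size unassociated).
#'
#' @param n number of patients.
#' @param classProbs named numeric: probability of \code{low} and
#'   \code{high} expression class (sums to 1).
#' @param associationSpec named list per covariate:
#'   \code{levels} (length 2), \code{marginal} (probability of level 2),
#'   \code{or} (odds ratio of level 2 for high vs low class).
#' @param survivalSpec optional; when given, \code{time}/\code{event}
#'   columns are added with hazard multiplied by \code{exp(betaSurv)}
#'   for the high class.
#' @param seed integer seed.
#' @return data.frame with \code{patient_id}, \code{expr_class},
#'   covariate columns and optional survival columns.
#' @export
simulateClinicalTable <- function(n = 90L,
                                  classProbs = c(low = 57 / 90,
                                                 high = 33 / 90),
                                  associationSpec = defaultClinicalSpec(),
                                  survivalSpec = NULL,
                                  seed = 1L) {
  if (abs(sum(classProbs) - 1) > 1e-8)
    stop("class probabilities must sum to 1")
  for (cv in names(associationSpec)) {
    sp <- associationSpec[[cv]]
    if (sp$marginal < 0 || sp$marginal > 1)
      stop("invalid marginal probability for ", cv)
    if (sp$or <= 0) stop("odds ratio must be positive for ", cv)
  }
  set.seed(seed)
  cls <- sample(c("low", "high"), n, replace = TRUE,
                prob = classProbs[c("low", "high")])
  out <- data.frame(patient_id = sprintf("P%03d", seq_len(n)),
                    expr_class = cls, stringsAsFactors = FALSE)
  pHigh <- classProbs[["high"]]
  for (cv in names(associationSpec)) {
    sp <- associationSpec[[cv]]
    # solve P(level2 | low) so the marginal and the odds ratio both hold
    f <- function(p0) {
      p1 <- sp$or * p0 / (1 - p0 + sp$or * p0)
      pHigh * p1 + (1 - pHigh) * p0 - sp$marginal
    }
    p0 <- if (abs(sp$or - 1) < 1e-12) sp$marginal
          else uniroot(f, c(1e-9, 1 - 1e-9), tol = 1e-12)$root
    p1 <- sp$or * p0 / (1 - p0 + sp$or * p0)
    pr <- ifelse(cls == "high", p1, p0)
    out[[cv]] <- ifelse(runif(n) < pr, sp$levels[2L], sp$levels[1L])
  }
  if (!is.null(survivalSpec)) {
    surv <- simulateSurvival(as.numeric(cls == "high"), survivalSpec,
                             seed = seed + 10L)
    out$time <- surv$time
    out$event <- surv$event
  }
  out
}

#' Default clinical covariate association spec
#'
#' Marginal frequencies and expression-class odds ratios emulating the
#' 90-patient cohort structure: AFP > 300 and TNM II-IV enriched in the
#' high-expression class, the rest unassociated.
#'
#' @return named list usable as \code{associationSpec}.
#' @export
defaultClinicalSpec <- function() {
  list(
    age_class = list(levels = c("<=50", ">50"), marginal = 50 / 90, or = 1),
    sex = list(levels = c("female", "male"), marginal = 80 / 90, or = 1),
    tnm = list(levels = c("I", "II-IV"), marginal = 27 / 90, or = 2.5),
    tumor_size = list(levels = c("<=3cm", ">3cm"), marginal = 54 / 90,
                      or = 1),
    afp = list(levels = c("<=300", ">300"), marginal = 42 / 90, or = 3.0)
  )
}

#' Generate synthetic immune-cell marker gene sets
#'
#' Disjoint marker sets drawn from a gene universe, for testing ssGSEA
#' immune-infiltration scoring without shipping third-party marker lists.
#' All sets are labelled synthetic.
#'
#' @param genes gene universe to draw from.
#' @param cellTypes character vector of set names.
#' @param size markers per set.
#' @param seed integer seed.
#' @return a \code{\link{GeneSetCollection}}.
#' @export
syntheticImmuneSets <- function(genes,
                                cellTypes = c(
                                  "aDC", "B_cells", "CD8_T_cells",
                                  "Cytotoxic_cells", "DC", "Eosinophils",
                                  "Macrophages", "Mast_cells",
                                  "Neutrophils", "NK_CD56bright",
                                  "NK_cells", "Tcm", "Th17", "Tregs"),
                                size = 10L, seed = 1L) {
  size <- min(size, length(genes) %/% length(cellTypes))
  if (size < 3L)
    stop("gene universe too small for the requested marker sets")
  set.seed(seed)
  pool <- sample(genes, length(cellTypes) * size)
  members <- split(pool, rep(seq_along(cellTypes), each = size))
  new("GeneSetCollection", setNames = cellTypes,
      descriptions = rep("synthetic marker set", length(cellTypes)),
      members = unname(lapply(members, as.character)))
}

#' Write a complete synthetic dataset directory
#'
#' Emits the TSV/GMT/CSV dialects the readers consume, plus a
#' ground-truth JSON (planted module labels, hubs, survival beta).
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param dir output directory (created if missing).
#' @return invisible list of the generated objects.
#' @export
writeSyntheticDataset <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ex <- simulateExpression(config)
  writeExpressionMatrix(ex$se, file.path(dir, "expression.tsv"))
  write.table(as.data.frame(SummarizedExperiment::colData(ex$se)),
              file.path(dir, "samples.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  pp <- simulatePPI(config, ex$truth)
  edges <- ppiEdges(pp$ppi)
  write.table(edges, file.path(dir, "ppi.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  clin <- simulateClinicalTable(n = config$nSubjects,
                                survivalSpec = config$survival,
                                seed = config$seed + 4L)
  utils::write.csv(clin, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  sets <- syntheticImmuneSets(rownames(ex$se), seed = config$seed + 5L)
  writeGeneSets(sets, file.path(dir, "immune_sets.gmt"))
  truth <- list(moduleLabels = as.list(ex$truth$moduleLabels),
                hubs = pp$hubs,
                betaSurv = config$survival$betaSurv,
                seed = config$seed)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(expression = ex, ppi = pp, clinical = clin,
                 immuneSets = sets))
}
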