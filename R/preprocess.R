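# Sample-correlation quality control with paired-sample retention, and
# coefficient-of-variation seed-gene selection.

#' Sample-sample Pearson correlation matrix
#'
#' @param se SummarizedExperiment (assay "exprs") or numeric matrix,
#'   genes in rows.
#' @param byTissue when TRUE, compute one matrix per tissue class of the
#'   colData \code{tissue} column and return a named list.
#' @return symmetric correlation matrix with unit diagonal, or a named
#'   list of them.
#' @export
sampleCorrelationMatrix <- function(se, byTissue = FALSE) {
  mat <- exprOf(se)
  if (ncol(mat) < 2L) stop("need at least 2 samples")
  sds <- apply(mat, 2L, sd)
  if (any(sds == 0))
    stop("zero-variance sample(s): ",
         paste(colnames(mat)[sds == 0], collapse = ", "))
  if (!byTissue) return(cor(mat))
  tissue <- as.character(SummarizedExperiment::colData(se)$tissue)
  lapply(split(colnames(mat), tissue),
         function(ids) cor(mat[, ids, drop = FALSE]))
}

# internal: pull the expression matrix out of whatever was passed
exprOf <- function(se) {
  if (is(se, "SummarizedExperiment"))
    SummarizedExperiment::assay(se, "exprs")
  else as.matrix(se)
}

#' Paired-sample correlation quality control
#'
#' Within each tissue class, samples are clustered by average-linkage on
#' 1 - Pearson correlation and cut into a configurable number of groups
#' (defaults: 2 tumor, 3 normal). Clusters whose mean intra-cluster
#' correlation falls within \code{tol} of the best cluster are all kept
#' (so homogeneous data loses nothing and the procedure is idempotent);
#' otherwise only the best cluster survives, ties broken toward the
#' larger cluster. A subject is retained only when its tumor AND normal
#' samples both survive.
#'
#' @param se SummarizedExperiment whose colData has \code{subject_id}
#'   and \code{tissue} (\code{"tumor"}/\code{"normal"}).
#' @param tumorGroups,normalGroups number of clusters to cut per tissue.
#' @param tol keep any cluster whose mean intra-cluster correlation is
#'   within this distance of the best cluster's; genuine outlier
#'   clusters sit far below this margin while arbitrary splits of
#'   homogeneous data sit within it.
#' @return a \code{\link{QCReport}}.
#' @export
selectConsistentPairs <- function(se, tumorGroups = 2L, normalGroups = 3L,
                                  tol = 0.15) {
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  if (!all(c("subject_id", "tissue") %in% colnames(cd)))
    stop("colData must provide subject_id and tissue")
  corrs <- sampleCorrelationMatrix(se, byTissue = TRUE)
  kGroups <- list(tumor = tumorGroups, normal = normalGroups)
  clusters <- list()
  keptByTissue <- list()
  dropped <- data.frame(sample_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  for (tis in names(corrs)) {
    cm <- corrs[[tis]]
    k <- min(kGroups[[tis]] %||% 2L, ncol(cm))
    cl <- if (k <= 1L || ncol(cm) < 3L) {
      setNames(rep(1L, ncol(cm)), colnames(cm))
    } else {
      hc <- hclust(as.dist(1 - cm), method = "average")
      cutree(hc, k = k)
    }
    clusters[[tis]] <- cl
    # singleton clusters are scored by their correlation to the rest of
    # the tissue class (a singleton is never "perfectly consistent")
    meanCor <- vapply(split(names(cl), cl), function(ids) {
      if (length(ids) == ncol(cm)) return(1)
      if (length(ids) == 1L)
        return(mean(cm[ids, setdiff(colnames(cm), ids)]))
      sub <- cm[ids, ids]
      mean(sub[upper.tri(sub)])
    }, numeric(1))
    sizes <- table(cl)[names(meanCor)]
    best <- max(meanCor)
    keepCl <- names(meanCor)[meanCor >= best - tol]
    if (length(keepCl) < length(meanCor) && length(keepCl) > 1L) {
      # distinct near-ties beyond numerical noise: largest wins
      exact <- names(meanCor)[abs(meanCor - best) < 1e-12]
      if (length(exact) > 1L)
        keepCl <- exact[which.max(sizes[exact])]
    }
    kept <- names(cl)[as.character(cl) %in% keepCl]
    keptByTissue[[tis]] <- kept
    for (s in setdiff(names(cl), kept))
      dropped <- rbind(dropped, data.frame(
        sample_id = s, reason = sprintf("low-correlation %s cluster", tis),
        stringsAsFactors = FALSE))
  }
  rownames(cd) <- cd$sample_id %||% rownames(cd)
  keptAll <- unlist(keptByTissue, use.names = FALSE)
  subjOf <- setNames(as.character(cd$subject_id), rownames(cd))
  tisOf <- setNames(as.character(cd$tissue), rownames(cd))
  subjKept <- split(tisOf[keptAll], subjOf[keptAll])
  complete <- names(subjKept)[vapply(subjKept, function(x)
    all(c("tumor", "normal") %in% x), logical(1))]
  if (!length(complete))
    stop("no subject survives paired-sample QC")
  finalSamples <- rownames(cd)[subjOf[rownames(cd)] %in% complete &
                               rownames(cd) %in% keptAll]
  for (s in setdiff(keptAll, finalSamples))
    dropped <- rbind(dropped, data.frame(
      sample_id = s, reason = "paired sample failed QC",
      stringsAsFactors = FALSE))
  new("QCReport", correlation = corrs, clusters = clusters,
      retainedSamples = sort(finalSamples),
      retainedSubjects = sort(complete), dropped = dropped)
}

#' Coefficient-of-variation seed-gene filter
#'
#' CV = sd / |mean| per gene across retained samples. By default the CV
#' is computed on the linear scale obtained by exponentiating the
#' (assumed log2) input, where cutoffs of the magnitude used for
#' microarray seed-gene selection are achievable; set
#' \code{scale = "asis"} to use the provided values directly. Genes with
#' zero mean have undefined CV and are excluded with a log entry.
#'
#' @param se SummarizedExperiment or matrix, genes in rows.
#' @param cutoff retain genes with CV strictly greater than this.
#' @param topN alternatively retain the top-N genes by CV (overrides
#'   \code{cutoff} when non-NULL); ties broken by gene id for
#'   determinism.
#' @param scale \code{"linear"} (2^x before CV) or \code{"asis"}.
#' @return a \code{\link{GeneFilterResult}}.
#' @export
cvFilter <- function(se, cutoff = 3.6, topN = NULL, scale = c("linear",
                                                              "asis")) {
  scale <- match.arg(scale)
  mat <- exprOf(se)
  vals <- if (scale == "linear") 2^mat else mat
  mu <- rowMeans(vals)
  sds <- apply(vals, 1L, sd)
  cv <- ifelse(mu == 0, NA_real_, sds / abs(mu))
  names(cv) <- rownames(mat)
  nExcl <- sum(is.na(cv))
  excluded <- data.frame(gene = names(cv)[is.na(cv)],
                         reason = rep("zero mean: CV undefined", nExcl),
                         stringsAsFactors = FALSE)
  defined <- cv[!is.na(cv)]
  if (!is.null(topN)) {
    topN <- as.integer(topN)
    ord <- order(-defined, names(defined))
    retained <- names(defined)[ord][seq_len(min(topN, length(defined)))]
    res <- new("GeneFilterResult", cv = cv, cutoff = NA_real_,
               topN = topN, retained = sort(retained),
               excluded = excluded)
  } else {
    retained <- names(defined)[defined > cutoff]
    res <- new("GeneFilterResult", cv = cv, cutoff = cutoff,
               topN = NA_integer_, retained = sort(retained),
               excluded = excluded)
  }
  res
}

#' Subset an expression SummarizedExperiment by QC and gene filter
#'
#' @param se SummarizedExperiment.
#' @param qc optional \code{\link{QCReport}}.
#' @param geneFilter optional \code{\link{GeneFilterResult}}.
#' @return the filtered SummarizedExperiment.
#' @export
applyFilters <- function(se, qc = NULL, geneFilter = NULL) {
  if (!is.null(qc))
    se <- se[, retainedSamples(qc)]
  if (!is.null(geneFilter))
    se <- se[intersect(rownames(se), retainedGenes(geneFilter)), ]
  se
}
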