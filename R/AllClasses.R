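#' @import methods
#' @importFrom stats cor sd median quantile phyper pchisq pt p.adjust
#'   hclust cutree as.dist rnorm rexp runif rbinom uniroot setNames
#'   cor.test ks.test aggregate complete.cases var coef lm residuals
#' @importFrom utils read.delim write.table packageVersion head
NULL

#' PPINetwork: an undirected protein-protein interaction graph
#'
#' Holds a deduplicated, self-loop-free undirected interaction graph over
#' gene symbols, with an optional per-edge confidence score in [0, 1]
#' (HIPPIE-style). Edge orientation is canonicalized so that
#' \code{from <= to} lexicographically; duplicate edges are collapsed on
#' construction.
#'
#' @slot nodes character vector of unique gene symbols.
#' @slot edges data.frame with columns \code{from}, \code{to} and optional
#'   \code{score}; each unordered pair appears once.
#' @slot nSelfLoopsRemoved integer, self-loops dropped at read time.
#' @slot nDuplicatesRemoved integer, duplicate edges collapsed at read time.
#' @exportClass PPINetwork
setClass("PPINetwork",
  representation(
    nodes = "character",
    edges = "data.frame",
    nSelfLoopsRemoved = "integer",
    nDuplicatesRemoved = "integer"
  )
)

setValidity("PPINetwork", function(object) {
  msg <- character(0)
  if (anyDuplicated(object@nodes))
    msg <- c(msg, "duplicate node symbols")
  e <- object@edges
  if (!all(c("from", "to") %in% colnames(e)))
    msg <- c(msg, "edges must have 'from' and 'to' columns")
  else {
    if (any(e$from == e$to))
      msg <- c(msg, "self-loops present in edges")
    if (!all(c(e$from, e$to) %in% object@nodes))
      msg <- c(msg, "edge endpoint not in nodes")
    key <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate undirected edges")
    if ("score" %in% colnames(e) &&
        any(e$score < 0 | e$score > 1, na.rm = TRUE))
      msg <- c(msg, "edge scores outside [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' QCReport: result of paired-sample correlation quality control
#'
#' @slot correlation named list of per-tissue sample-sample Pearson
#'   correlation matrices.
#' @slot clusters named list of per-tissue integer cluster assignments.
#' @slot retainedSamples character, sample ids surviving QC (complete pairs).
#' @slot retainedSubjects character, subjects whose tumor and normal samples
#'   both survived.
#' @slot dropped data.frame with columns \code{sample_id}, \code{reason}.
#' @exportClass QCReport
setClass("QCReport",
  representation(
    correlation = "list",
    clusters = "list",
    retainedSamples = "character",
    retainedSubjects = "character",
    dropped = "data.frame"
  )
)

setValidity("QCReport", function(object) {
  for (m in object@correlation) {
    if (!isSymmetric(unname(m), tol = 1e-8))
      return("correlation matrix not symmetric")
    if (any(abs(diag(m) - 1) > 1e-8))
      return("correlation matrix diagonal not 1")
  }
  TRUE
})

#' GeneFilterResult: coefficient-of-variation seed-gene selection
#'
#' @slot cv named numeric vector of per-gene CV values (NA where undefined).
#' @slot cutoff numeric CV cutoff actually applied (NA in top-N mode).
#' @slot topN integer top-N actually applied (NA in cutoff mode).
#' @slot retained character vector of retained gene ids.
#' @slot excluded data.frame of genes excluded for undefined CV.
#' @exportClass GeneFilterResult
setClass("GeneFilterResult",
  representation(
    cv = "numeric",
    cutoff = "numeric",
    topN = "integer",
    retained = "character",
    excluded = "data.frame"
  )
)

#' CoexpressionNetwork: weighted co-expression network state
#'
#' Container assembled by \code{\link{buildCoexpressionNetwork}}: the
#' soft-thresholded adjacency, the topological overlap matrix, the
#' average-linkage dendrogram, module labels (WGCNA-style colors, "grey"
#' for unassigned), eigengenes and per-module variance explained.
#'
#' @slot genes character, genes in network order.
#' @slot adjacency gene x gene matrix in [0,1], zero diagonal.
#' @slot tom gene x gene topological overlap matrix in [0,1], unit diagonal.
#' @slot dendrogram hclust object over 1 - TOM.
#' @slot modules named character vector gene -> module color ("grey" =
#'   unassigned).
#' @slot eigengenes module x sample matrix, each row unit Euclidean norm.
#' @slot varianceExplained named numeric per module.
#' @slot config list of network parameters used.
#' @exportClass CoexpressionNetwork
setClass("CoexpressionNetwork",
  representation(
    genes = "character",
    adjacency = "matrix",
    tom = "matrix",
    dendrogram = "ANY",
    modules = "character",
    eigengenes = "matrix",
    varianceExplained = "numeric",
    config = "list"
  )
)

setValidity("CoexpressionNetwork", function(object) {
  a <- object@adjacency
  w <- object@tom
  if (length(a) && (any(a < -1e-12) || any(a > 1 + 1e-12)))
    return("adjacency entries outside [0, 1]")
  if (length(w) && (any(w < -1e-12) || any(w > 1 + 1e-12)))
    return("TOM entries outside [0, 1]")
  if (length(object@modules) &&
      !identical(names(object@modules), object@genes))
    return("module labels not aligned to genes")
  TRUE
})

#' GeneSetCollection: named gene sets parsed from a GMT file
#'
#' @slot setNames character vector of unique set names.
#' @slot descriptions character vector aligned to setNames.
#' @slot members list of character vectors (unique symbols, length >= 1).
#' @exportClass GeneSetCollection
setClass("GeneSetCollection",
  representation(
    setNames = "character",
    descriptions = "character",
    members = "list"
  )
)

setValidity("GeneSetCollection", function(object) {
  if (anyDuplicated(object@setNames))
    return("duplicate gene set names")
  if (length(object@members) != length(object@setNames) ||
      length(object@descriptions) != length(object@setNames))
    return("slots not aligned")
  if (any(vapply(object@members, function(m)
        length(m) < 1L || anyDuplicated(m) > 0L, logical(1))))
    return("each set needs >= 1 unique member")
  TRUE
})

#' HubScreenResult: ranked PPI-neighborhood enrichment table
#'
#' One row per covered, degree >= 1 co-expression gene: co-expressed
#' neighbor count \code{c}, other-neighbor count \code{o}, the proportion
#' c/(c+o), the one-sided hypergeometric (Fisher) p-value and its
#' multiplicity-adjusted value, plus the screening verdict.
#'
#' @slot table data.frame sorted by adjusted p.
#' @slot hubs character, genes passing proportion and adjusted-p thresholds.
#' @slot params list: proportion threshold, alpha, adjust method, m.
#' @slot coverage list of coverage statistics (see \code{\link{mapToPPI}}).
#' @exportClass HubScreenResult
setClass("HubScreenResult",
  representation(
    table = "data.frame",
    hubs = "character",
    params = "list",
    coverage = "list"
  )
)

setMethod("show", "PPINetwork", function(object) {
  cat("PPINetwork:", length(object@nodes), "nodes,",
      nrow(object@edges), "undirected edges\n")
  cat("  removed at read:", object@nSelfLoopsRemoved, "self-loops,",
      object@nDuplicatesRemoved, "duplicate edges\n")
  if ("score" %in% colnames(object@edges))
    cat("  confidence scores present\n")
})

setMethod("show", "QCReport", function(object) {
  cat("QCReport:", length(object@retainedSubjects), "subject pairs retained,",
      nrow(object@dropped), "samples dropped\n")
})

setMethod("show", "GeneFilterResult", function(object) {
  mode <- if (is.na(object@cutoff)) sprintf("top-%d", object@topN)
          else sprintf("CV > %g", object@cutoff)
  cat("GeneFilterResult (", mode, "): ", length(object@retained), " of ",
      length(object@cv), " genes retained\n", sep = "")
})

setMethod("show", "CoexpressionNetwork", function(object) {
  tab <- table(object@modules)
  nm <- sum(names(tab) != "grey")
  cat("CoexpressionNetwork:", length(object@genes), "genes,",
      nm, "modules (beta =", object@config$power, ")\n")
  if (length(tab)) {
    ord <- order(-tab)
    cat("  sizes:", paste(sprintf("%s=%d", names(tab)[ord], tab[ord]),
                          collapse = " "), "\n")
  }
})

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection:", length(object@setNames), "sets, sizes",
      paste(range(vapply(object@members, length, integer(1))),
            collapse = "-"), "\n")
})

setMethod("show", "HubScreenResult", function(object) {
  cat("HubScreenResult:", nrow(object@table), "genes screened,",
      length(object@hubs), "hubs (proportion >=",
      object@params$proportionThreshold, ", adjusted p <",
      object@params$alpha, ")\n")
  if (length(object@hubs))
    cat("  hubs:", paste(object@hubs, collapse = ", "), "\n")
})

# ---- accessors ----

#' @describeIn PPINetwork-accessors node symbols
#' @export
ppiNodes <- function(x) x@nodes

#' Accessors for PPINetwork, CoexpressionNetwork and friends
#'
#' Small accessor family; slots are implementation detail.
#'
#' @param x the object.
#' @name PPINetwork-accessors
#' @aliases ppiNodes ppiEdges ppiDegree
NULL

#' @describeIn PPINetwork-accessors edge table (from, to, optional score)
#' @export
ppiEdges <- function(x) x@edges

#' @describeIn PPINetwork-accessors named integer degree vector over all nodes
#' @export
ppiDegree <- function(x) {
  d <- setNames(integer(length(x@nodes)), x@nodes)
  t1 <- table(x@edges$from)
  t2 <- table(x@edges$to)
  d[names(t1)] <- d[names(t1)] + as.integer(t1)
  d[names(t2)] <- d[names(t2)] + as.integer(t2)
  d
}

#' Neighbor list of a PPI network
#'
#' @param x a \code{PPINetwork}.
#' @return named list: node -> character vector of neighbors.
#' @export
ppiNeighborList <- function(x) {
  nb <- c(split(x@edges$to, x@edges$from), split(x@edges$from, x@edges$to))
  nb <- lapply(split(unlist(nb, use.names = FALSE),
                     rep(names(nb), lengths(nb))), unique)
  out <- setNames(vector("list", length(x@nodes)), x@nodes)
  out[names(nb)] <- nb
  out[vapply(out, is.null, logical(1))] <- list(character(0))
  out
}

#' @describeIn CoexpressionNetwork-accessors module label per gene
#' @export
moduleLabels <- function(x) x@modules

#' Accessors for CoexpressionNetwork
#' @param x a \code{CoexpressionNetwork}.
#' @name CoexpressionNetwork-accessors
#' @aliases moduleLabels eigengenes tomMatrix adjacencyOf
NULL

#' @describeIn CoexpressionNetwork-accessors module x sample eigengene matrix
#' @export
eigengenes <- function(x) x@eigengenes

#' @describeIn CoexpressionNetwork-accessors topological overlap matrix
#' @export
tomMatrix <- function(x) x@tom

#' @describeIn CoexpressionNetwork-accessors adjacency matrix
#' @export
adjacencyOf <- function(x) x@adjacency

#' @describeIn HubScreenResult-accessors full ranked screening table
#' @export
hubTable <- function(x) x@table

#' Accessors for HubScreenResult
#' @param x a \code{HubScreenResult}.
#' @name HubScreenResult-accessors
#' @aliases hubTable hubGenes
NULL

#' @describeIn HubScreenResult-accessors genes passing both screens
#' @export
hubGenes <- function(x) x@hubs

#' @describeIn GeneSetCollection-accessors member list, named by set
#' @export
geneSetMembers <- function(x) setNames(x@members, x@setNames)

#' Accessors for GeneSetCollection
#' @param x a \code{GeneSetCollection}.
#' @name GeneSetCollection-accessors
#' @aliases geneSetMembers geneSetNames
NULL

#' @describeIn GeneSetCollection-accessors set names
#' @export
geneSetNames <- function(x) x@setNames

#' @describeIn QCReport-accessors retained sample ids
#' @export
retainedSamples <- function(x) x@retainedSamples

#' Accessors for QCReport
#' @param x a \code{QCReport}.
#' @name QCReport-accessors
#' @aliases retainedSamples retainedSubjects droppedSamples
NULL

#' @describeIn QCReport-accessors retained subject ids (complete pairs)
#' @export
retainedSubjects <- function(x) x@retainedSubjects

#' @describeIn QCReport-accessors drop log with reasons
#' @export
droppedSamples <- function(x) x@dropped

#' @describeIn GeneFilterResult-accessors retained gene ids
#' @export
retainedGenes <- function(x) x@retained

#' Accessors for GeneFilterResult
#' @param x a \code{GeneFilterResult}.
#' @name GeneFilterResult-accessors
#' @aliases retainedGenes geneCV
NULL

#' @describeIn GeneFilterResult-accessors per-gene CV values
#' @export
geneCV <- function(x) x@cv
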