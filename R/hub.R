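# PPI-neighborhood hub screening: map co-expression genes onto the PPI
# network, count co-expressed neighbors per gene, one-sided
# hypergeometric (Fisher exact) enrichment against the network
# background, multiplicity adjustment, and threshold screening.

#' Coverage statistics of a gene list on a PPI network
#'
#' @param coexprGenes character vector of co-expression genes.
#' @param ppi a \code{\link{PPINetwork}}.
#' @return list: \code{nNodes}, \code{nEdges}, \code{meanDegree}
#'   (2E/V), \code{covered} (genes present in the network),
#'   \code{nCovered}, \code{meanCoexprNeighbors} (mean co-expressed
#'   neighbor count among covered genes).
#' @export
mapToPPI <- function(coexprGenes, ppi) {
  if (!length(coexprGenes)) stop("empty co-expression gene list")
  covered <- intersect(coexprGenes, ppiNodes(ppi))
  if (!length(covered))
    stop("no co-expression gene is covered by the PPI network")
  nb <- ppiNeighborList(ppi)
  coSet <- unique(coexprGenes)
  meanCo <- mean(vapply(covered, function(g)
    sum(nb[[g]] %in% coSet), numeric(1)))
  list(nNodes = length(ppiNodes(ppi)), nEdges = nrow(ppiEdges(ppi)),
       meanDegree = 2 * nrow(ppiEdges(ppi)) / length(ppiNodes(ppi)),
       covered = sort(covered), nCovered = length(covered),
       meanCoexprNeighbors = meanCo)
}

#' Co-expressed / other neighbor counts for one gene
#'
#' @param gene focal gene symbol (must be a network node).
#' @param ppi a \code{\link{PPINetwork}}.
#' @param coexprSet character vector of co-expression genes.
#' @return integer vector \code{c(c = ..., o = ...)}: neighbors inside
#'   and outside the co-expression set; the focal gene itself is never
#'   counted.
#' @export
neighborhoodOverlap <- function(gene, ppi, coexprSet) {
  if (!gene %in% ppiNodes(ppi))
    stop("gene absent from PPI network: ", gene)
  e <- ppiEdges(ppi)
  nb <- unique(c(e$to[e$from == gene], e$from[e$to == gene]))
  nb <- setdiff(nb, gene)
  cc <- sum(nb %in% coexprSet)
  c(c = cc, o = length(nb) - cc)
}

#' One-sided neighborhood enrichment p-value
#'
#' Upper-tail hypergeometric probability \eqn{P(X \ge c)} for drawing
#' \eqn{n = c + o} neighbors from a network of \eqn{N} genes of which
#' \eqn{M} are co-expression genes; equivalent to a one-sided Fisher
#' exact test on the table [[c, o], [M - c, N - M - o]].
#'
#' @param c co-expressed neighbor count.
#' @param o other neighbor count.
#' @param M co-expression genes present in the network.
#' @param N total network genes.
#' @return the one-sided p-value.
#' @export
fisherEnrichment <- function(c, o, M, N) {
  if (any(c(c, o, M, N) < 0) || c > M || c + o > N || M > N)
    stop("inconsistent counts for fisherEnrichment")
  phyper(c - 1, M, N - M, c + o, lower.tail = FALSE)
}

#' Multiplicity adjustment with an explicit test count
#'
#' \code{"bonferroni"}: min(1, m * p). \code{"bh"}: Benjamini-Hochberg
#' step-up computed as if \code{m} tests had been performed (the
#' missing ones at p = 1). The default m downstream is the number of
#' co-expression genes covered by the PPI network.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param method \code{"bonferroni"} or \code{"bh"}.
#' @param m total number of tests (>= length(p)).
#' @return adjusted p-values in input order.
#' @export
adjustPValues <- function(p, method = c("bonferroni", "bh"),
                          m = length(p)) {
  method <- match.arg(method)
  if (m < length(p)) stop("m must be at least the number of p-values")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  switch(method,
         bonferroni = pmin(1, m * p),
         bh = p.adjust(p, method = "BH", n = m))
}

#' Screen PPI hubs by neighborhood co-expression enrichment
#'
#' Builds one candidate row per covered, degree >= 1 co-expression gene
#' (c, o, proportion = c/(c+o), one-sided Fisher p, adjusted p) and
#' screens for hubs: proportion >= \code{proportionThreshold} AND
#' adjusted p < \code{alpha}. Degree-0 covered genes are excluded from
#' testing; in \code{"bonferroni"} (fidelity) mode m stays the full
#' covered count, in \code{"bh"} mode m is the number of tested genes.
#'
#' @param ppi a \code{\link{PPINetwork}}.
#' @param coexprGenes character vector of co-expression genes.
#' @param proportionThreshold minimum co-expressed neighbor proportion.
#' @param alpha adjusted-p significance cutoff.
#' @param adjust \code{"bonferroni"} (default, reproduces the
#'   published-table arithmetic with m = covered genes) or \code{"bh"}.
#' @return a \code{\link{HubScreenResult}}; the table is sorted by
#'   adjusted then raw p.
#' @export
screenHubs <- function(ppi, coexprGenes, proportionThreshold = 0.10,
                       alpha = 0.05,
                       adjust = c("bonferroni", "bh")) {
  adjust <- match.arg(adjust)
  cov <- mapToPPI(coexprGenes, ppi)
  coSet <- unique(coexprGenes)
  N <- cov$nNodes
  M <- cov$nCovered
  nb <- ppiNeighborList(ppi)
  counts <- t(vapply(cov$covered, function(g) {
    v <- setdiff(nb[[g]], g)
    cc <- sum(v %in% coSet)
    c(cc, length(v) - cc)
  }, numeric(2)))
  keep <- rowSums(counts) >= 1
  tested <- cov$covered[keep]
  counts <- counts[keep, , drop = FALSE]
  tab <- data.frame(
    gene = tested,
    n_coexpr_neighbors = as.integer(counts[, 1L]),
    n_other_neighbors = as.integer(counts[, 2L]),
    n_coexpr_genes = M,
    n_network_genes = N,
    proportion = counts[, 1L] / rowSums(counts),
    stringsAsFactors = FALSE)
  tab$fisher_p <- mapply(fisherEnrichment, tab$n_coexpr_neighbors,
                         tab$n_other_neighbors,
                         MoreArgs = list(M = M, N = N))
  mEff <- if (adjust == "bonferroni") M else nrow(tab)
  tab$adjusted_p <- adjustPValues(tab$fisher_p, method = adjust,
                                  m = mEff)
  tab <- screenCandidates(tab, proportionThreshold, alpha)
  new("HubScreenResult", table = tab, hubs = tab$gene[tab$is_hub],
      params = list(proportionThreshold = proportionThreshold,
                    alpha = alpha, adjust = adjust, m = mEff,
                    note = paste("adjustment labelled FDR upstream;",
                                 "bonferroni m*p reproduces the",
                                 "published arithmetic")),
      coverage = cov)
}

#' Apply the hub screening rule to a candidate table
#'
#' Hubs are genes with \code{proportion >= proportionThreshold} AND
#' \code{adjusted_p < alpha}; the table is returned sorted by adjusted
#' then raw p with an \code{is_hub} verdict column. The verdict is
#' invariant to the input row order.
#'
#' @param candidates data.frame with at least \code{gene},
#'   \code{proportion}, \code{fisher_p}, \code{adjusted_p}.
#' @param proportionThreshold minimum co-expressed neighbor proportion.
#' @param alpha adjusted-p cutoff.
#' @return the sorted candidate table with \code{is_hub}.
#' @export
screenCandidates <- function(candidates, proportionThreshold = 0.10,
                             alpha = 0.05) {
  need <- c("gene", "proportion", "fisher_p", "adjusted_p")
  if (!all(need %in% colnames(candidates)))
    stop("candidate table lacks columns: ",
         paste(setdiff(need, colnames(candidates)), collapse = ", "))
  tab <- candidates
  tab$is_hub <- tab$proportion >= proportionThreshold &
    tab$adjusted_p < alpha
  ord <- order(tab$adjusted_p, tab$fisher_p, tab$gene)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Assemble a published-style hub table from explicit counts
#'
#' Utility for worked examples: given per-gene (c, o) counts and the
#' (M, N) background, produce the eight-column screening table
#' (gene, c, o, M, N, proportion, fisher p, adjusted p).
#'
#' @param genes character vector.
#' @param c,o integer vectors of co-expressed / other neighbor counts.
#' @param M,N background counts.
#' @param adjust adjustment method, see \code{\link{adjustPValues}}.
#' @param m total test count for the adjustment (default M).
#' @return data.frame in published column order.
#' @export
hubTableFromCounts <- function(genes, c, o, M, N,
                               adjust = "bonferroni", m = M) {
  p <- mapply(fisherEnrichment, c, o, MoreArgs = list(M = M, N = N))
  data.frame(gene = genes,
             n_coexpr_neighbors = as.integer(c),
             n_other_neighbors = as.integer(o),
             n_coexpr_genes = as.integer(M),
             n_network_genes = as.integer(N),
             proportion = c / (c + o),
             fisher_p = p,
             adjusted_p = adjustPValues(p, method = adjust, m = m),
             stringsAsFactors = FALSE)
}
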