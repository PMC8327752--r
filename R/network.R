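# Weighted co-expression network construction from scratch:
# soft-threshold diagnostics, adjacency, topological overlap, average-
# linkage clustering, deterministic module detection, eigengenes,
# module merging, module-trait statistics, thresholded edge export.

# size-ranked module color sequence (WGCNA convention)
.moduleColorSequence <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black",
  "pink", "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue")

#' Network construction parameters
#'
#' Defaults follow the canonical WGCNA choices: soft power 6 (unsigned),
#' minimum module size 30, eigengene merge height 0.25, edge export
#' threshold 0.1, scale-free fit target R^2 0.85.
#'
#' @param power soft-threshold exponent beta (integer >= 1).
#' @param minModuleSize smallest allowed module.
#' @param mergeHeight eigengene dissimilarity below which modules merge.
#' @param edgeThreshold minimum weight for exported edges.
#' @param sign \code{"unsigned"} (|cor|^beta) or \code{"signed"}
#'   (((1+cor)/2)^beta).
#' @param scaleFreeTarget target signed R^2 for power recommendation.
#' @param staticQuantile quantile of merge heights for the static cut.
#' @param gapSensitivity height gap above which a branch counts as a
#'   separate cohesive module.
#' @return validated list of class \code{"NetworkConfig"}.
#' @export
networkConfig <- function(power = 6L, minModuleSize = 30L,
                          mergeHeight = 0.25, edgeThreshold = 0.1,
                          sign = c("unsigned", "signed"),
                          scaleFreeTarget = 0.85,
                          staticQuantile = 0.99, gapSensitivity = 0.1) {
  sign <- match.arg(sign)
  if (power < 1 || power != round(power))
    stop("power must be an integer >= 1")
  for (nm in c("mergeHeight", "edgeThreshold", "scaleFreeTarget",
               "staticQuantile", "gapSensitivity")) {
    v <- get(nm)
    if (!is.numeric(v) || v <= 0 || v >= 1)
      stop(nm, " must lie in (0, 1)")
  }
  structure(list(power = as.integer(power),
                 minModuleSize = as.integer(minModuleSize),
                 mergeHeight = mergeHeight,
                 edgeThreshold = edgeThreshold, sign = sign,
                 scaleFreeTarget = scaleFreeTarget,
                 staticQuantile = staticQuantile,
                 gapSensitivity = gapSensitivity),
            class = "NetworkConfig")
}

#' Soft-threshold diagnostics and power recommendation
#'
#' For each candidate power: soft-threshold the correlation matrix,
#' compute the connectivity k_i, bin log10(k) into equal-width bins and
#' regress log10(mean bin frequency) on log10(mean bin k). The signed
#' scale-free fit is -sign(slope) * R^2, positive for the decreasing
#' degree distribution of a scale-free network. The recommended power is
#' the smallest reaching the target, else the power of maximal fit.
#'
#' @param se SummarizedExperiment or matrix, genes in rows.
#' @param powers candidate integer powers (>= 3 of them).
#' @param config a \code{\link{networkConfig}} (sign mode and target).
#' @param nBins histogram bins for the fit.
#' @return list: \code{table} (data.frame power, signedR2, slope,
#'   meanConnectivity), \code{recommended}.
#' @export
pickSoftThreshold <- function(se, powers = c(1:10, 12L, 14L, 16L),
                              config = networkConfig(), nBins = 10L) {
  if (length(powers) < 3L) stop("need at least 3 candidate powers")
  mat <- exprOf(se)
  if (nrow(mat) < 10L) stop("need at least 10 genes")
  cc <- cor(t(mat))
  sim <- if (config$sign == "unsigned") abs(cc) else (1 + cc) / 2
  diag(sim) <- 0
  rows <- lapply(sort(unique(as.integer(powers))), function(b) {
    k <- rowSums(sim^b)
    fit <- scaleFreeFit(k, nBins = nBins)
    data.frame(power = b, signedR2 = fit$signedR2, slope = fit$slope,
               meanConnectivity = mean(k))
  })
  tab <- do.call(rbind, rows)
  ok <- which(tab$signedR2 >= config$scaleFreeTarget)
  rec <- if (length(ok)) tab$power[ok[1L]]
         else tab$power[which.max(tab$signedR2)]
  list(table = tab, recommended = rec)
}

# internal: scale-free topology fit index from a connectivity vector
scaleFreeFit <- function(k, nBins = 10L) {
  k <- k[k > 0]
  if (!length(k)) stop("all connectivities are zero")
  lk <- log10(k)
  brk <- seq(min(lk), max(lk), length.out = nBins + 1L)
  brk[1L] <- brk[1L] - 1e-9
  bin <- cut(lk, brk, labels = FALSE)
  freq <- tabulate(bin, nbins = nBins) / length(lk)
  mk <- vapply(seq_len(nBins), function(b)
    if (any(bin == b)) mean(k[bin == b]) else NA_real_, numeric(1))
  use <- freq > 0 & !is.na(mk)
  if (sum(use) < 3L) return(list(signedR2 = 0, slope = 0))
  fit <- stats::lm(log10(freq[use]) ~ log10(mk[use]))
  r2 <- summary(fit)$r.squared
  slope <- unname(coef(fit)[2L])
  list(signedR2 = -sign(slope) * r2, slope = slope)
}

#' Soft-thresholded adjacency matrix
#'
#' Unsigned: \eqn{a_{ij} = |cor(x_i, x_j)|^\beta}; signed:
#' \eqn{a_{ij} = ((1 + cor)/2)^\beta}. Diagonal forced to zero.
#'
#' @param se SummarizedExperiment or matrix, genes in rows.
#' @param config a \code{\link{networkConfig}}.
#' @return gene x gene adjacency matrix.
#' @export
adjacencyMatrix <- function(se, config = networkConfig()) {
  mat <- exprOf(se)
  sds <- apply(mat, 1L, sd)
  if (any(sds == 0))
    stop("zero-variance gene(s) present: ",
         paste(head(rownames(mat)[sds == 0], 5L), collapse = ", "))
  cc <- cor(t(mat))
  a <- if (config$sign == "unsigned") abs(cc)^config$power
       else ((1 + cc) / 2)^config$power
  diag(a) <- 0
  a
}

#' Topological overlap matrix
#'
#' \eqn{\omega_{ij} = (l_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 - a_{ij})}
#' for \eqn{i \ne j}, with \eqn{l_{ij} = \sum_u a_{iu} a_{uj}} and
#' \eqn{k_i = \sum_u a_{iu}}; \eqn{\omega_{ii} = 1}.
#'
#' @param adj symmetric adjacency matrix in [0, 1] with zero diagonal.
#' @return TOM matrix with unit diagonal.
#' @export
tomSimilarity <- function(adj) {
  if (!isSymmetric(unname(adj), tol = 1e-10))
    stop("adjacency must be symmetric")
  if (any(adj < -1e-12) || any(adj > 1 + 1e-12))
    stop("adjacency entries must lie in [0, 1]")
  a <- adj
  diag(a) <- 0
  l <- a %*% a
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  w <- (l + a) / denom
  diag(w) <- 1
  dimnames(w) <- dimnames(adj)
  w
}

#' Average-linkage clustering of genes on 1 - TOM
#'
#' @param tom TOM matrix.
#' @return an \code{hclust} object.
#' @export
clusterGenes <- function(tom) {
  if (nrow(tom) < 2L) stop("need at least 2 genes")
  hclust(as.dist(1 - tom), method = "average")
}

#' Deterministic two-phase module detection
#'
#' Phase 1 cuts the dendrogram statically at the
#' \code{staticQuantile} of merge heights. Phase 2 walks each resulting
#' branch: a branch is accepted as a module when it hangs below its
#' parent merge by more than \code{gapSensitivity}; a large branch
#' (>= 2x minimum size) whose internal top gap also exceeds the
#' sensitivity is re-cut recursively into its children; branches that
#' are neither cohesive nor large enough are descended into, and
#' anything falling below the minimum size ends up "grey". Surviving
#' modules are named by size rank along the conventional color
#' sequence.
#'
#' @param hc \code{hclust} from \code{\link{clusterGenes}}.
#' @param config a \code{\link{networkConfig}}.
#' @return named character vector gene -> module color.
#' @export
cutModules <- function(hc, config = networkConfig()) {
  labels <- hc$labels
  n <- length(labels)
  minSize <- config$minModuleSize
  out <- setNames(rep("grey", n), labels)
  if (n < minSize) return(out)

  merge <- hc$merge
  height <- hc$height
  # leaves under each internal node
  leavesOf <- vector("list", nrow(merge))
  for (i in seq_len(nrow(merge))) {
    kids <- merge[i, ]
    leavesOf[[i]] <- unlist(lapply(kids, function(kk)
      if (kk < 0) -kk else leavesOf[[kk]]))
  }
  nodeHeight <- function(k) if (k < 0) 0 else height[k]
  nodeSize <- function(k) if (k < 0) 1L else length(leavesOf[[k]])

  clusters <- list()
  accept <- function(k, parentH) {
    if (nodeSize(k) < minSize) return(invisible(NULL))
    h <- nodeHeight(k)
    gap <- parentH - h
    if (k > 0) {
      kids <- merge[k, ]
      internalGap <- h - max(vapply(kids, nodeHeight, numeric(1)))
      sizes <- vapply(kids, nodeSize, integer(1))
      if (nodeSize(k) >= 2L * minSize &&
          internalGap > config$gapSensitivity &&
          all(sizes >= minSize)) {
        accept(kids[1L], h); accept(kids[2L], h)
        return(invisible(NULL))
      }
    }
    if (gap > config$gapSensitivity) {
      clusters[[length(clusters) + 1L]] <<-
        if (k < 0) -k else leavesOf[[k]]
    } else if (k > 0) {
      kids <- merge[k, ]
      accept(kids[1L], h); accept(kids[2L], h)
    }
    invisible(NULL)
  }

  h0 <- quantile(height, config$staticQuantile, names = FALSE)
  # branches hanging below the static cut, with their parent merges
  isBelow <- height <= h0
  for (i in seq_len(nrow(merge))) {
    if (isBelow[i]) next
    for (kk in merge[i, ])
      if (kk < 0 || isBelow[kk]) accept(kk, height[i])
  }
  if (all(isBelow)) accept(nrow(merge), max(height) + 1)

  if (length(clusters)) {
    ord <- order(-lengths(clusters),
                 vapply(clusters, min, numeric(1)))
    clusters <- clusters[ord]
    for (i in seq_along(clusters)) {
      colr <- if (i <= length(.moduleColorSequence))
        .moduleColorSequence[i] else sprintf("module%d", i)
      out[clusters[[i]]] <- colr
    }
  }
  out
}

#' Module eigengenes
#'
#' The eigengene of a module is the first right singular vector of its
#' gene-standardized submatrix: one value per sample, unit Euclidean
#' norm, sign-aligned so its correlation with the module's mean
#' standardized expression profile is non-negative (first-coordinate-
#' positive fallback when that correlation is undefined).
#'
#' @param se SummarizedExperiment or matrix, genes in rows.
#' @param modules named character vector gene -> module ("grey"
#'   ignored).
#' @return list: \code{eigengenes} (module x sample matrix),
#'   \code{varianceExplained} (named numeric).
#' @export
moduleEigengenes <- function(se, modules) {
  mat <- exprOf(se)
  mods <- setdiff(unique(modules), "grey")
  if (!length(mods)) stop("no non-grey modules")
  me <- matrix(0, nrow = length(mods), ncol = ncol(mat),
               dimnames = list(mods, colnames(mat)))
  ve <- setNames(numeric(length(mods)), mods)
  for (m in mods) {
    genes <- names(modules)[modules == m]
    x <- mat[genes, , drop = FALSE]
    x <- t(scale(t(x)))
    x[!is.finite(x)] <- 0  # constant gene contributes nothing
    sv <- svd(x, nu = 0, nv = 1)
    v <- sv$v[, 1L]
    ve[m] <- sv$d[1L]^2 / sum(sv$d^2)
    ref <- colMeans(x)
    al <- if (sd(ref) > 0) suppressWarnings(cor(v, ref)) else NA_real_
    if (!is.na(al) && al < 0) v <- -v
    else if (is.na(al) && v[which(v != 0)[1L]] < 0) v <- -v
    me[m, ] <- v
  }
  list(eigengenes = me, varianceExplained = ve)
}

#' Merge close modules by eigengene similarity
#'
#' Average-linkage clustering of 1 - cor(ME) among module eigengenes;
#' groups joined below \code{mergeHeight} are merged (the merged module
#' keeps the largest member's label), eigengenes are recomputed, and the
#' procedure iterates to a fixed point. Final labels are re-ranked by
#' size along the color sequence.
#'
#' @param se SummarizedExperiment or matrix, genes in rows.
#' @param modules named character vector gene -> module.
#' @param config a \code{\link{networkConfig}}.
#' @return list: \code{modules}, \code{eigengenes},
#'   \code{varianceExplained}, \code{nMergeRounds}.
#' @export
mergeModules <- function(se, modules, config = networkConfig()) {
  rounds <- 0L
  repeat {
    mods <- setdiff(unique(modules), "grey")
    if (length(mods) < 2L) break
    eg <- moduleEigengenes(se, modules)
    d <- 1 - cor(t(eg$eigengenes))
    hc <- hclust(as.dist(d), method = "average")
    grp <- cutree(hc, h = config$mergeHeight)
    if (max(table(grp)) == 1L) break
    rounds <- rounds + 1L
    for (g in unique(grp)) {
      members <- names(grp)[grp == g]
      if (length(members) < 2L) next
      sizes <- vapply(members, function(m) sum(modules == m), integer(1))
      keep <- members[which.max(sizes)]
      modules[modules %in% members] <- keep
    }
  }
  # deterministic size-ranked renaming
  mods <- setdiff(unique(modules), "grey")
  if (length(mods)) {
    sizes <- vapply(mods, function(m) sum(modules == m), integer(1))
    first <- vapply(mods, function(m) which(modules == m)[1L], integer(1))
    ord <- mods[order(-sizes, first)]
    newName <- setNames(ifelse(seq_along(ord) <=
                                 length(.moduleColorSequence),
                               .moduleColorSequence[seq_along(ord)],
                               sprintf("module%d", seq_along(ord))), ord)
    modules[modules != "grey"] <- newName[modules[modules != "grey"]]
  }
  eg <- if (length(mods)) moduleEigengenes(se, modules)
        else list(eigengenes = matrix(0, 0, ncol(exprOf(se))),
                  varianceExplained = numeric(0))
  list(modules = modules, eigengenes = eg$eigengenes,
       varianceExplained = eg$varianceExplained, nMergeRounds = rounds)
}

#' Module-trait correlation table
#'
#' Pearson correlation between each module eigengene and the trait with
#' the two-sided t-distribution p-value
#' (\eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}}, n - 2 df), sorted by |r|.
#'
#' @param me module x sample eigengene matrix.
#' @param trait numeric trait vector aligned to samples.
#' @return data.frame: module, r, p, n.
#' @export
moduleTraitCorrelation <- function(me, trait) {
  if (ncol(me) != length(trait))
    stop("trait vector not aligned to samples")
  if (sd(trait) == 0) stop("constant trait")
  n <- length(trait)
  r <- apply(me, 1L, function(v) cor(v, trait))
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  out <- data.frame(module = rownames(me), r = r, p = p, n = n,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-abs(out$r), out$module), , drop = FALSE]
}

#' Export thresholded co-expression edges
#'
#' Undirected edges (gene_i, gene_j, weight) with weight strictly above
#' the threshold, restricted to genes in the selected modules; each pair
#' emitted once, in deterministic (gene1, gene2) order.
#'
#' @param weights symmetric weight matrix (TOM by default upstream).
#' @param modules named character vector gene -> module.
#' @param threshold minimum edge weight.
#' @param selectedModules modules to keep (default: all non-grey).
#' @return data.frame: gene1, gene2, weight.
#' @export
exportEdges <- function(weights, modules,
                        threshold = 0.1,
                        selectedModules = NULL) {
  if (is.null(selectedModules))
    selectedModules <- setdiff(unique(modules), "grey")
  genes <- names(modules)[modules %in% selectedModules]
  genes <- intersect(rownames(weights), genes)
  w <- weights[genes, genes, drop = FALSE]
  idx <- which(upper.tri(w) & w > threshold, arr.ind = TRUE)
  out <- data.frame(gene1 = genes[idx[, 1L]], gene2 = genes[idx[, 2L]],
                    weight = w[idx], stringsAsFactors = FALSE)
  out[order(out$gene1, out$gene2), , drop = FALSE]
}

#' Build the full co-expression network
#'
#' Convenience wrapper: adjacency -> TOM -> average-linkage dendrogram
#' -> module detection -> eigengenes -> module merging. Genes with zero
#' variance are dropped (and counted in the config echo) before
#' correlation.
#'
#' @param se SummarizedExperiment or matrix, genes in rows.
#' @param config a \code{\link{networkConfig}}.
#' @return a \code{\link{CoexpressionNetwork}}.
#' @export
buildCoexpressionNetwork <- function(se, config = networkConfig()) {
  mat <- exprOf(se)
  sds <- apply(mat, 1L, sd)
  nZero <- sum(sds == 0)
  if (nZero > 0L) {
    message(nZero, " zero-variance gene(s) dropped before correlation")
    mat <- mat[sds > 0, , drop = FALSE]
  }
  adj <- adjacencyMatrix(mat, config)
  tom <- tomSimilarity(adj)
  hc <- clusterGenes(tom)
  modules <- cutModules(hc, config)
  if (any(modules != "grey")) {
    mg <- mergeModules(mat, modules, config)
    modules <- mg$modules
    me <- mg$eigengenes
    ve <- mg$varianceExplained
  } else {
    me <- matrix(0, 0, ncol(mat),
                 dimnames = list(NULL, colnames(mat)))
    ve <- numeric(0)
  }
  cfg <- unclass(config)
  cfg$nZeroVarianceDropped <- nZero
  new("CoexpressionNetwork", genes = rownames(mat), adjacency = adj,
      tom = tom, dendrogram = hc, modules = modules, eigengenes = me,
      varianceExplained = ve, config = cfg)
}
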