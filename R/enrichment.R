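# Gene set enrichment: two-class GSEA with permutation significance,
# single-sample GSEA (ssGSEA) scoring, and immune-infiltration
# correlation / survival-association summaries. Hand-rolled running-sum
# statistics (no GSEA implementation ships with the environment).

#' Rank genes by a two-class differential metric
#'
#' Signal-to-noise: (mu1 - mu2) / (s1 + s2) with each group SD floored
#' at 0.2 |mu| of that group (and a small absolute floor), the
#' conventional GSEA variance stabilization. Also available: Welch-less
#' pooled t statistic and plain log2 fold change (difference of means on
#' log2 data).
#'
#' @param se SummarizedExperiment or matrix, genes in rows.
#' @param groups two-level vector aligned to samples.
#' @param metric \code{"s2n"}, \code{"t"}, or \code{"log2fc"}.
#' @param positiveGroup the group whose up-regulation gives positive
#'   metric values (default: the first value encountered in
#'   \code{groups}); the metric is positiveGroup - other.
#' @return data.frame (gene, metric) in descending metric order; ties
#'   broken by gene id.
#' @export
rankGenes <- function(se, groups, metric = c("s2n", "t", "log2fc"),
                      positiveGroup = NULL) {
  metric <- match.arg(metric)
  mat <- exprOf(se)
  g <- as.character(groups)
  if (length(unique(g)) != 2L) stop("exactly two groups required")
  if (any(table(g) < 3L)) stop("each group needs at least 3 samples")
  if (is.null(positiveGroup)) positiveGroup <- g[1L]
  if (!positiveGroup %in% g) stop("positiveGroup not present in groups")
  x1 <- mat[, g == positiveGroup, drop = FALSE]
  x2 <- mat[, g != positiveGroup, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  s1 <- apply(x1, 1L, sd); s2 <- apply(x2, 1L, sd)
  val <- switch(metric,
    s2n = {
      s1 <- pmax(s1, 0.2 * abs(m1), 1e-8)
      s2 <- pmax(s2, 0.2 * abs(m2), 1e-8)
      (m1 - m2) / (s1 + s2)
    },
    t = {
      n1 <- ncol(x1); n2 <- ncol(x2)
      sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
      sp <- pmax(sp, 1e-8)
      (m1 - m2) / (sp * sqrt(1 / n1 + 1 / n2))
    },
    log2fc = m1 - m2)
  out <- data.frame(gene = rownames(mat), metric = unname(val),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$metric, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walking the ranked list, hits increment the running sum by
#' |metric|^w normalized by the in-set total, misses decrement by
#' 1/(n - m); the ES is the signed maximum deviation. When the set
#' covers the whole list (no misses) the miss ECDF falls back to the
#' uniform i/n so the running sum still returns to zero.
#'
#' @param ranked data.frame from \code{\link{rankGenes}} or a named
#'   numeric vector in descending order.
#' @param geneSet character vector of member symbols.
#' @param weight exponent w on |metric| (0 gives the classical
#'   unweighted KS statistic).
#' @return list: \code{es}, \code{position} (index of the extremum),
#'   \code{leadingEdge}, \code{runningSum}.
#' @export
gseaES <- function(ranked, geneSet, weight = 1) {
  if (is.data.frame(ranked)) {
    genes <- ranked$gene
    metric <- ranked$metric
  } else {
    genes <- names(ranked)
    metric <- as.numeric(ranked)
  }
  n <- length(genes)
  hit <- genes %in% geneSet
  m <- sum(hit)
  if (m == 0L) stop("no overlap between gene set and ranked list")
  w <- abs(metric)^weight
  w[hit][w[hit] == 0] <- 0  # zero-weight hits contribute nothing
  denomHit <- sum(w[hit])
  incHit <- if (denomHit > 0) w * hit / denomHit else hit / m
  incMiss <- if (n > m) (!hit) / (n - m) else rep(1 / n, n)
  running <- cumsum(incHit) - cumsum(incMiss)
  pos <- which.max(abs(running))
  es <- running[pos]
  leading <- if (es >= 0) genes[seq_len(pos)][hit[seq_len(pos)]]
             else genes[pos:n][hit[pos:n]]
  list(es = es, position = pos, leadingEdge = leading,
       runningSum = running)
}

#' GSEA with permutation significance
#'
#' Phenotype-label permutation null (gene-set permutation fallback with
#' a logged warning when a group has fewer than 7 samples). NES is
#' ES / mean(|null ES| of the same sign); the nominal p is the fraction
#' of same-sign null ES at least as extreme (add-one corrected so
#' p is in (0, 1]); q is Benjamini-Hochberg across sets.
#'
#' @param se SummarizedExperiment or matrix.
#' @param groups two-level vector aligned to samples.
#' @param gsc a \code{\link{GeneSetCollection}}.
#' @param nPerm number of permutations (>= 100).
#' @param weight ES weight exponent.
#' @param metric ranking metric, see \code{\link{rankGenes}}.
#' @param positiveGroup see \code{\link{rankGenes}}; held fixed across
#'   permutations.
#' @param seed integer seed; results are deterministic given it.
#' @return data.frame: set, size, es, nes, p, q, leading_edge.
#' @export
gseaPermutation <- function(se, groups, gsc, nPerm = 1000L,
                            weight = 1, metric = "s2n", seed = 1L,
                            positiveGroup = NULL) {
  if (nPerm < 100L) stop("nPerm must be at least 100")
  mat <- exprOf(se)
  g <- as.character(groups)
  if (is.null(positiveGroup)) positiveGroup <- g[1L]
  sets <- geneSetMembers(gsc)
  obsRank <- rankGenes(mat, g, metric, positiveGroup = positiveGroup)
  obs <- lapply(sets, function(s) gseaES(obsRank, s, weight))
  esObs <- vapply(obs, `[[`, numeric(1), "es")

  set.seed(seed)
  phenotype <- min(table(g)) >= 7L
  if (!phenotype)
    warning("fewer than 7 samples per group: ",
            "falling back to gene-set permutation")
  nullES <- matrix(NA_real_, nrow = nPerm, ncol = length(sets))
  if (phenotype) {
    for (b in seq_len(nPerm)) {
      gp <- sample(g)
      rk <- rankGenes(mat, gp, metric, positiveGroup = positiveGroup)
      nullES[b, ] <- vapply(sets, function(s)
        gseaES(rk, s, weight)$es, numeric(1))
    }
  } else {
    sizes <- vapply(sets, function(s)
      sum(obsRank$gene %in% s), integer(1))
    for (b in seq_len(nPerm)) {
      nullES[b, ] <- vapply(sizes, function(k)
        gseaES(obsRank, sample(obsRank$gene, k), weight)$es,
        numeric(1))
    }
  }

  p <- nes <- numeric(length(sets))
  for (j in seq_along(sets)) {
    nv <- nullES[, j]
    same <- if (esObs[j] >= 0) nv[nv >= 0] else nv[nv < 0]
    if (!length(same)) {
      p[j] <- 1 / (nPerm + 1)
      nes[j] <- NA_real_
    } else {
      p[j] <- (sum(abs(same) >= abs(esObs[j])) + 1) /
        (length(same) + 1)
      nes[j] <- esObs[j] / mean(abs(same))
    }
  }
  out <- data.frame(
    set = names(sets),
    size = vapply(sets, function(s) sum(obsRank$gene %in% s),
                  integer(1)),
    es = esObs, nes = nes, p = p,
    q = p.adjust(p, method = "BH"),
    leading_edge = vapply(obs, function(o)
      paste(o$leadingEdge, collapse = ","), character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p, -abs(out$nes)), , drop = FALSE]
}

#' Single-sample GSEA scores
#'
#' Per sample, genes are ranked by expression; the score is the
#' integrated difference between the rank-weighted (rank^alpha) ECDF of
#' in-set genes and the unweighted ECDF of out-of-set genes. Raw scores
#' are rank-based and hence invariant to any strictly monotone
#' transformation of a sample's expression values. Final scores are
#' normalized by the global score range (standard min-max convention).
#'
#' @param se SummarizedExperiment or matrix.
#' @param gsc a \code{\link{GeneSetCollection}}.
#' @param alpha rank weighting exponent (default 0.25).
#' @param normalize divide by the global score range.
#' @return list: \code{scores} (set x sample, normalized if requested),
#'   \code{raw}, \code{flagged} (sets with < 2 genes present; sets with
#'   no genes present score NA).
#' @export
ssgseaScores <- function(se, gsc, alpha = 0.25, normalize = TRUE) {
  mat <- exprOf(se)
  sets <- geneSetMembers(gsc)
  n <- nrow(mat)
  present <- lapply(sets, function(s) intersect(s, rownames(mat)))
  flagged <- names(sets)[lengths(present) < 2L]
  raw <- matrix(NA_real_, nrow = length(sets), ncol = ncol(mat),
                dimnames = list(names(sets), colnames(mat)))
  for (j in seq_len(ncol(mat))) {
    r <- rank(mat[, j], ties.method = "average")
    ord <- order(-r, rownames(mat))  # walk from highest expression
    rOrd <- r[ord]
    gOrd <- rownames(mat)[ord]
    for (i in seq_along(sets)) {
      mem <- present[[i]]
      if (!length(mem)) next
      hit <- gOrd %in% mem
      m <- sum(hit)
      wts <- rOrd^alpha * hit
      cdfIn <- cumsum(wts) / sum(wts)
      cdfOut <- if (n > m) cumsum(!hit) / (n - m)
                else seq_len(n) / n
      raw[i, j] <- sum(cdfIn - cdfOut)
    }
  }
  scores <- raw
  if (normalize) {
    rng <- range(raw, na.rm = TRUE)
    if (diff(rng) > 0) scores <- raw / diff(rng)
  }
  list(scores = scores, raw = raw, flagged = flagged)
}

#' Spearman correlation of immune scores with a gene's expression
#'
#' @param scores cell-type x sample score matrix.
#' @param geneValues numeric vector aligned to samples.
#' @return data.frame (cell_type, rho, p) sorted by rho, p from the
#'   asymptotic t approximation.
#' @export
immuneCorrelation <- function(scores, geneValues) {
  if (ncol(scores) != length(geneValues))
    stop("samples not aligned")
  rows <- lapply(rownames(scores), function(ct) {
    v <- scores[ct, ]
    if (sd(v) == 0) stop("constant score vector for ", ct)
    ct2 <- suppressWarnings(
      cor.test(v, geneValues, method = "spearman", exact = FALSE))
    data.frame(cell_type = ct, rho = unname(ct2$estimate),
               p = ct2$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$rho), , drop = FALSE]
}

#' Survival association of immune-infiltration scores
#'
#' Each cell-type score is dichotomized at its median (high vs low
#' infiltration); per cell type the two-group log-rank p and the
#' univariate Cox hazard ratio of the high group are reported,
#' heatmap-ready.
#'
#' @param scores cell-type x sample score matrix.
#' @param records survival data.frame (\code{time}, \code{event})
#'   aligned to samples.
#' @return data.frame: cell_type, HR, ci_low, ci_high, cox_p,
#'   logrank_p.
#' @export
immuneSurvivalAssociation <- function(scores, records) {
  checkSurvivalRecords(records)
  if (ncol(scores) != nrow(records)) stop("samples not aligned")
  if (nrow(records) == 0L) stop("empty survival record set")
  rows <- lapply(rownames(scores), function(ct) {
    grp <- dichotomizeExpression(scores[ct, ], rule = "median")
    if (length(unique(grp)) < 2L)
      stop("degenerate dichotomization for ", ct)
    df <- cbind(records, high = as.integer(grp == "high"))
    cx <- coxFit(df, "high", mode = "univariate")
    lr <- logrankTest(records, grp)
    data.frame(cell_type = ct, HR = cx$HR, ci_low = cx$ci_low,
               ci_high = cx$ci_high, cox_p = cx$p,
               logrank_p = lr$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
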