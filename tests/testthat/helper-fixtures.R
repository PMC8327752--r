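# Fixture builders shared across test files. Everything is generated in
# code; nothing binary ships with the package.

# write a small expression TSV and return its path
writeExprFixture <- function(mat, path = tempfile(fileext = ".tsv"),
                             geneIds = rownames(mat)) {
  df <- data.frame(gene = geneIds, mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# write a PPI edge TSV (no header) and return its path
writePPIFixture <- function(from, to, score = NULL,
                            path = tempfile(fileext = ".tsv")) {
  df <- data.frame(from = from, to = to, stringsAsFactors = FALSE)
  if (!is.null(score)) df$score <- score
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  path
}

# a small paired tumor/normal SummarizedExperiment from a plain matrix
pairedSE <- function(mat, nSubjects) {
  subj <- sprintf("S%03d", seq_len(nSubjects))
  ids <- c(paste0(subj, "_T"), paste0(subj, "_N"))
  stopifnot(ncol(mat) == 2 * nSubjects)
  colnames(mat) <- ids
  cd <- S4Vectors::DataFrame(
    sample_id = ids, subject_id = rep(subj, 2),
    tissue = rep(c("tumor", "normal"), each = nSubjects),
    trait = rep(c(1L, 0L), each = nSubjects), row.names = ids)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = mat), colData = cd)
}

# plant aberrant (low-correlation) subjects into a simulated experiment:
# their samples keep only 20% of the gene-baseline structure, share an
# aberrant profile, and carry heavy extra noise
plantOutlierSubjects <- function(se, subjects, seed = 99,
                                 tissues = c("_T", "_N")) {
  m <- SummarizedExperiment::assay(se, "exprs")
  set.seed(seed)
  bg <- rowMeans(m)
  delta <- rnorm(nrow(m))
  for (s in subjects)
    for (suf in tissues)
      m[, paste0(s, suf)] <- 8 + 0.2 * (bg - 8) + delta +
        rnorm(nrow(m), sd = 2)
  SummarizedExperiment::assay(se, "exprs") <- m
  se
}

# adjusted Rand index between two label vectors (contingency form)
adjustedRandIndex <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sumij <- sum(choose(tab, 2))
  sumi <- sum(choose(rowSums(tab), 2))
  sumj <- sum(choose(colSums(tab), 2))
  expected <- sumi * sumj / choose(n, 2)
  maxidx <- (sumi + sumj) / 2
  if (maxidx == expected) return(1)
  (sumij - expected) / (maxidx - expected)
}

# brute-force average-linkage agglomeration: returns sorted merge heights
bruteAverageLinkHeights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters))
      for (j in seq_len(i - 1L)) {
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        if (dd < bestd) { bestd <- dd; best <- c(j, i) }
      }
    heights <- c(heights, bestd)
    clusters[[best[1L]]] <- c(clusters[[best[1L]]],
                              clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  sort(heights)
}

# brute-force TOM by triple loop
bruteTOM <- function(a) {
  n <- nrow(a)
  w <- matrix(0, n, n)
  k <- rowSums(a)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { w[i, j] <- 1; next }
    l <- 0
    for (u in seq_len(n)) l <- l + a[i, u] * a[u, j]
    w[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  w
}

# random symmetric adjacency in [0,1] with zero diagonal
randomAdjacency <- function(n) {
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  a
}
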