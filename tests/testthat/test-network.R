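# exact-correlation fixture with Pareto-distributed soft loadings on one
# latent factor: connectivity is power-law by construction
scaleFreeExpression <- function(n = 150, ns = 160, w0 = 0.02,
                                seed = 13) {
  set.seed(seed)
  w <- w0 / (1 - ((1:n) - 0.5) / n * (1 - w0))
  p <- w^(1 / 3)
  C <- sqrt(p) %o% sqrt(p); diag(C) <- 1
  A <- t(chol(C))
  Z <- scale(matrix(rnorm(ns * n), ns, n), scale = FALSE)
  Q <- qr.Q(qr(Z))
  X <- A %*% t(Q) * sqrt(ns - 1)
  dimnames(X) <- list(sprintf("G%03d", 1:n), sprintf("S%03d", 1:ns))
  X
}

test_that("soft-threshold diagnostics: scale-free fit and monotonicity", {
  X <- scaleFreeExpression()
  st <- pickSoftThreshold(X, powers = c(2, 4, 6, 8, 10))
  expect_gte(max(st$table$signedR2), 0.8)
  expect_true(st$recommended %in% st$table$power)
  expect_gte(st$table$signedR2[st$table$power == st$recommended], 0.85)

  # i.i.d. noise: mean connectivity strictly decreasing in beta
  set.seed(3)
  noise <- matrix(rnorm(100 * 30), 100,
                  dimnames = list(sprintf("G%03d", 1:100), NULL))
  stN <- pickSoftThreshold(noise, powers = c(1, 2, 4, 6, 8))
  expect_true(all(diff(stN$table$meanConnectivity) < 0))

  # candidate order does not matter
  st2 <- pickSoftThreshold(X, powers = c(10, 6, 2, 8, 4))
  expect_equal(st$table, st2$table)
  expect_error(pickSoftThreshold(X, powers = c(2, 6)), "at least 3")
})

test_that("adjacency matches |cor|^beta exactly", {
  # engineered correlation of exactly 0.5
  set.seed(2)
  x <- rnorm(30)
  e <- residuals(lm(rnorm(30) ~ x))
  y <- 0.5 * as.vector(scale(x)) + sqrt(0.75) * as.vector(scale(e))
  m <- rbind(g1 = x, g2 = y, g3 = 2 * x + 1)
  a <- adjacencyMatrix(m, networkConfig(power = 6))
  expect_equal(a["g1", "g2"], 0.5^6, tolerance = 1e-12)
  expect_equal(a["g1", "g3"], 1, tolerance = 1e-12)   # perfect correlation
  expect_equal(unname(diag(a)), rep(0, 3))

  # oracle equivalence on a random 20-gene matrix
  set.seed(5)
  m2 <- matrix(rnorm(20 * 12), 20,
               dimnames = list(sprintf("G%02d", 1:20), NULL))
  a2 <- adjacencyMatrix(m2, networkConfig(power = 6))
  cc <- cor(t(m2)); expectA <- abs(cc)^6; diag(expectA) <- 0
  expect_equal(a2, expectA, tolerance = 1e-12)

  # signed mode
  aS <- adjacencyMatrix(m2, networkConfig(power = 6, sign = "signed"))
  expectS <- ((1 + cc) / 2)^6; diag(expectS) <- 0
  expect_equal(aS, expectS, tolerance = 1e-12)

  m3 <- rbind(m2, flat = rep(1, 12))
  expect_error(adjacencyMatrix(m3, networkConfig()), "zero-variance")
})

test_that("TOM: degenerate cases and brute-force oracle equivalence", {
  # isolated genes
  a0 <- matrix(0, 3, 3)
  w0 <- tomSimilarity(a0)
  expect_equal(w0[upper.tri(w0)], rep(0, 3))
  expect_equal(unname(diag(w0)), rep(1, 3))

  # full clique: identical neighborhoods with a = 1
  a1 <- matrix(1, 3, 3); diag(a1) <- 0
  w1 <- tomSimilarity(a1)
  expect_equal(w1[1, 2], 1, tolerance = 1e-12)

  # brute-force triple-loop oracle on random instances
  set.seed(8)
  for (rep in 1:5) {
    a <- randomAdjacency(15)
    expect_equal(unname(tomSimilarity(a)), bruteTOM(a),
                 tolerance = 1e-12)
  }
})

test_that("average-linkage dendrogram matches a brute-force oracle", {
  # a gene pair with unit similarity merges first, at height zero
  w0 <- matrix(0.3, 4, 4); diag(w0) <- 1
  w0[1, 2] <- w0[2, 1] <- 1
  w0[3, 4] <- w0[4, 3] <- 0.9
  dimnames(w0) <- list(paste0("G", 1:4), paste0("G", 1:4))
  hc <- clusterGenes(w0)
  expect_equal(hc$height[1], 0, tolerance = 1e-12)

  # 6-gene toy dissimilarity: merge heights equal hand agglomeration
  set.seed(21)
  w <- matrix(runif(36, 0.2, 0.9), 6); w <- (w + t(w)) / 2; diag(w) <- 1
  dimnames(w) <- list(paste0("G", 1:6), paste0("G", 1:6))
  hc2 <- clusterGenes(w)
  expect_equal(sort(hc2$height), bruteAverageLinkHeights(1 - w),
               tolerance = 1e-12)

  # permuting gene order: identical tree up to relabeling
  set.seed(22)
  tom3 <- tomSimilarity(randomAdjacency(12))
  dimnames(tom3) <- list(sprintf("G%02d", 1:12), sprintf("G%02d", 1:12))
  perm <- sample(12)
  hcA <- clusterGenes(tom3)
  hcB <- clusterGenes(tom3[perm, perm])
  expect_equal(sort(hcA$height), sort(hcB$height), tolerance = 1e-12)
  for (k in 2:4) {
    pa <- cutree(hcA, k)[sprintf("G%02d", 1:12)]
    pb <- cutree(hcB, k)[sprintf("G%02d", 1:12)]
    expect_equal(adjustedRandIndex(pa, pb), 1)
  }
})

test_that("module detection recovers planted modules and rejects noise", {
  ex <- simulateExpression(simulationConfig(seed = 4L))
  net <- buildCoexpressionNetwork(
    SummarizedExperiment::assay(ex$se), networkConfig())
  mods <- moduleLabels(net)
  found <- setdiff(unique(mods), "grey")
  expect_equal(length(found), 3L)
  truth <- ex$truth$moduleLabels[names(mods)]
  expect_gte(adjustedRandIndex(mods, truth), 0.9)
  # non-grey modules respect the minimum size
  expect_true(all(table(mods[mods != "grey"]) >= 30))

  # pure noise: nothing passes
  set.seed(9)
  noise <- matrix(rnorm(200 * 40), 200,
                  dimnames = list(sprintf("G%03d", 1:200),
                                  sprintf("S%02d", 1:40)))
  netN <- buildCoexpressionNetwork(noise, networkConfig())
  expect_equal(length(setdiff(unique(moduleLabels(netN)), "grey")), 0L)

  # planted module below the minimum size goes grey
  exS <- simulateExpression(simulationConfig(
    nSubjects = 25L, nGenes = 60L,
    modules = list(list(size = 10L, rho = 0.9, d = 0)), seed = 2L))
  netS <- buildCoexpressionNetwork(
    SummarizedExperiment::assay(exS$se),
    networkConfig(minModuleSize = 30L))
  expect_true(all(moduleLabels(netS) == "grey"))
})

test_that("module labels are permutation-equivariant and deterministic", {
  ex <- simulateExpression(simulationConfig(
    nSubjects = 30L, nGenes = 150L,
    modules = list(list(size = 40L, rho = 0.9, d = 1),
                   list(size = 40L, rho = 0.9, d = 1)), seed = 14L))
  m <- SummarizedExperiment::assay(ex$se)
  net1 <- buildCoexpressionNetwork(m, networkConfig())
  net2 <- buildCoexpressionNetwork(m, networkConfig())
  expect_identical(moduleLabels(net1), moduleLabels(net2))

  set.seed(1); perm <- sample(nrow(m))
  net3 <- buildCoexpressionNetwork(m[perm, ], networkConfig())
  l1 <- moduleLabels(net1)[rownames(m)]
  l3 <- moduleLabels(net3)[rownames(m)]
  expect_equal(adjustedRandIndex(l1, l3), 1)
})

test_that("module eigengenes: degenerate modules and SVD oracle", {
  # identical genes: variance explained 1, ME proportional to profile
  prof <- rnorm(12)
  m <- rbind(g1 = prof, g2 = prof, g3 = prof)
  colnames(m) <- sprintf("S%02d", 1:12)
  mods <- setNames(rep("turquoise", 3), rownames(m))
  eg <- moduleEigengenes(m, mods)
  expect_equal(unname(eg$varianceExplained), 1, tolerance = 1e-12)
  expect_equal(abs(cor(eg$eigengenes["turquoise", ], prof)), 1,
               tolerance = 1e-12)
  expect_equal(sum(eg$eigengenes^2), 1, tolerance = 1e-12)
  # sign rule: positively aligned with the module mean profile
  expect_gt(cor(eg$eigengenes["turquoise", ], prof), 0)

  # two perfectly anti-correlated genes still explain all variance
  m2 <- rbind(up = prof, down = -prof)
  colnames(m2) <- colnames(m)
  eg2 <- moduleEigengenes(m2, setNames(rep("blue", 2), rownames(m2)))
  expect_equal(unname(eg2$varianceExplained), 1, tolerance = 1e-12)

  # random module: matches covariance eigendecomposition
  set.seed(17)
  m3 <- matrix(rnorm(8 * 15), 8,
               dimnames = list(paste0("G", 1:8), paste0("S", 1:15)))
  eg3 <- moduleEigengenes(m3, setNames(rep("brown", 8), rownames(m3)))
  xs <- t(scale(t(m3)))
  ev <- eigen(crossprod(xs), symmetric = TRUE)
  expect_equal(abs(cor(eg3$eigengenes["brown", ], ev$vectors[, 1])), 1,
               tolerance = 1e-10)
  expect_equal(unname(eg3$varianceExplained),
               ev$values[1] / sum(ev$values), tolerance = 1e-10)

  # single-gene module: standardized profile
  eg4 <- moduleEigengenes(m3, setNames(c("red", rep("grey", 7)),
                                       rownames(m3)))
  expect_equal(abs(cor(eg4$eigengenes["red", ], m3[1, ])), 1,
               tolerance = 1e-12)
})

test_that("module merging joins shared-factor modules and is idempotent", {
  # two 'modules' driven by one latent factor
  set.seed(30)
  n <- 40; f <- rnorm(n)
  mk <- function(sz) t(sapply(seq_len(sz), function(i)
    sqrt(0.9) * f + sqrt(0.1) * rnorm(n)))
  m <- rbind(mk(35), mk(35))
  rownames(m) <- sprintf("G%03d", 1:70); colnames(m) <- paste0("S", 1:n)
  mods <- setNames(rep(c("turquoise", "blue"), each = 35), rownames(m))
  mg <- mergeModules(m, mods, networkConfig())
  expect_equal(length(setdiff(unique(mg$modules), "grey")), 1L)

  # orthogonal factors stay separate
  f2 <- residuals(lm(rnorm(n) ~ f))
  m2 <- rbind(mk(35),
              t(sapply(1:35, function(i)
                sqrt(0.9) * f2 + sqrt(0.1) * rnorm(n))))
  rownames(m2) <- rownames(m); colnames(m2) <- colnames(m)
  mg2 <- mergeModules(m2, mods, networkConfig())
  expect_equal(length(setdiff(unique(mg2$modules), "grey")), 2L)

  # fixed point: a second call changes nothing
  mg3 <- mergeModules(m2, mg2$modules, networkConfig())
  expect_identical(mg2$modules, mg3$modules)
  expect_equal(mg3$nMergeRounds, 0L)
})

test_that("module-trait correlation: exact formula and null calibration", {
  # eigengene equal to the trait
  me <- matrix(rep(c(0, 1), each = 10) / sqrt(20), nrow = 1,
               dimnames = list("turquoise", NULL))
  trait <- rep(c(0, 1), each = 10)
  mt <- moduleTraitCorrelation(me, trait)
  expect_equal(mt$r, 1, tolerance = 1e-12)
  expect_lt(mt$p, 1e-12)

  # hand-sized n = 6 against the textbook formula
  me2 <- matrix(c(0.1, -0.3, 0.25, 0.4, -0.2, 0.05), nrow = 1,
                dimnames = list("blue", NULL))
  tr2 <- c(1, 0, 1, 1, 0, 0)
  mt2 <- moduleTraitCorrelation(me2, tr2)
  r <- cor(me2[1, ], tr2)
  tt <- r * sqrt(4) / sqrt(1 - r^2)
  expect_equal(mt2$r, r, tolerance = 1e-12)
  expect_equal(mt2$p, 2 * pt(-abs(tt), 4), tolerance = 1e-12)

  # null calibration at the paired-cohort size
  set.seed(55)
  trait54 <- rep(c(0, 1), 54)
  hits <- sum(vapply(1:100, function(i) {
    meN <- matrix(rnorm(108), 1, dimnames = list("m", NULL))
    moduleTraitCorrelation(meN, trait54)$p > 0.05
  }, logical(1)))
  expect_gte(hits, 95)

  expect_error(moduleTraitCorrelation(me, rep(1, 20)), "constant")
})

test_that("edge export respects threshold, module restriction, density", {
  set.seed(60)
  w <- randomAdjacency(6); diag(w) <- 1
  dimnames(w) <- list(paste0("G", 1:6), paste0("G", 1:6))
  mods <- setNames(c(rep("turquoise", 4), rep("grey", 2)),
                   rownames(w))
  expect_equal(nrow(exportEdges(w, mods, threshold = 1)), 0L)
  e0 <- exportEdges(w, mods, threshold = 0)
  expect_equal(nrow(e0), 6L)  # complete graph on the 4 module genes
  expect_true(all(e0$gene1 < e0$gene2))

  # planted-module network: within-module denser than between at 0.1
  ex <- simulateExpression(simulationConfig(seed = 4L))
  net <- buildCoexpressionNetwork(
    SummarizedExperiment::assay(ex$se), networkConfig())
  mods2 <- moduleLabels(net)
  ee <- exportEdges(tomMatrix(net), mods2, threshold = 0.1)
  within <- sum(mods2[ee$gene1] == mods2[ee$gene2])
  modGenes <- names(mods2)[mods2 != "grey"]
  sizes <- table(mods2[modGenes])
  possWithin <- sum(sizes * (sizes - 1) / 2)
  possBetween <- choose(length(modGenes), 2) - possWithin
  expect_gt(within / possWithin,
            (nrow(ee) - within) / max(possBetween, 1))
})

test_that("raising beta never raises connectivity", {
  set.seed(61)
  m <- matrix(rnorm(50 * 20), 50,
              dimnames = list(sprintf("G%02d", 1:50), NULL))
  ks <- sapply(c(1, 2, 4, 6, 10), function(b)
    mean(rowSums(adjacencyMatrix(m, networkConfig(power = b)))))
  expect_true(all(diff(ks) < 0))
})
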