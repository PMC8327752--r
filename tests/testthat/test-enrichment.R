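test_that("gene ranking: shifted gene first, antisymmetry, formula", {
  set.seed(2)
  m <- matrix(rnorm(50 * 12), 50,
              dimnames = list(sprintf("G%02d", 1:50),
                              sprintf("S%02d", 1:12)))
  g <- rep(c("tumor", "normal"), each = 6)
  m["G07", ] <- 3 + c(rep(5, 6), rep(0, 6))  # zero within-group noise
  rk <- rankGenes(m, g, metric = "s2n")
  expect_equal(rk$gene[1], "G07")

  # swapping the positive group negates the metric, reverses the order
  rkSwap <- rankGenes(m, g, metric = "s2n", positiveGroup = "normal")
  ord <- match(rk$gene, rkSwap$gene)
  expect_equal(rkSwap$metric[ord], -rk$metric, tolerance = 1e-12)

  # per-gene hand formula with the 0.2|mu| floor
  x1 <- m[, 1:6]; x2 <- m[, 7:12]
  for (gene in c("G01", "G07", "G30")) {
    m1 <- mean(x1[gene, ]); m2 <- mean(x2[gene, ])
    s1 <- max(sd(x1[gene, ]), 0.2 * abs(m1), 1e-8)
    s2 <- max(sd(x2[gene, ]), 0.2 * abs(m2), 1e-8)
    expect_equal(rk$metric[rk$gene == gene], (m1 - m2) / (s1 + s2),
                 tolerance = 1e-12)
  }
  expect_error(rankGenes(m, rep(c("a", "b", "c"), 4)), "two groups")
  expect_error(rankGenes(m[, 1:5], c("a", "a", "b", "b", "b")),
               "at least 3")
})

test_that("enrichment score: concentration, degeneracy, brute force", {
  ranked <- data.frame(gene = sprintf("G%02d", 1:20),
                       metric = seq(2, -2, length.out = 20))
  # set = top k
  k <- 4
  es <- gseaES(ranked, sprintf("G%02d", 1:k))
  expect_gt(es$es, 0)
  expect_gte(es$es, 1 - k / 20)
  expect_equal(es$leadingEdge, sprintf("G%02d", 1:k))

  # set = entire list: running sum returns to zero and the extremum
  # equals the documented uniform-miss fallback oracle
  esAll <- gseaES(ranked, ranked$gene)
  expect_equal(esAll$runningSum[20], 0, tolerance = 1e-12)
  w <- abs(ranked$metric) / sum(abs(ranked$metric))
  devAll <- cumsum(w) - (1:20) / 20
  expect_equal(esAll$es, devAll[which.max(abs(devAll))],
               tolerance = 1e-12)

  # 5-member set against a step-by-step oracle
  set.seed(6)
  members <- sample(ranked$gene, 5)
  hit <- ranked$gene %in% members
  nr <- sum(abs(ranked$metric[hit]))
  run <- 0; best <- 0
  for (i in 1:20) {
    run <- run + if (hit[i]) abs(ranked$metric[i]) / nr else -1 / 15
    if (abs(run) > abs(best)) best <- run
  }
  es5 <- gseaES(ranked, members, weight = 1)
  expect_equal(es5$es, best, tolerance = 1e-12)

  expect_error(gseaES(ranked, c("ZZ1", "ZZ2")), "no overlap")
})

test_that("weight 0 reduces to the classical unweighted KS statistic", {
  set.seed(7)
  for (i in 1:10) {
    n <- sample(15:40, 1)
    ranked <- data.frame(gene = sprintf("g%03d", 1:n),
                         metric = sort(rnorm(n), decreasing = TRUE))
    mset <- sample(ranked$gene, sample(3:8, 1))
    hit <- ranked$gene %in% mset
    m <- sum(hit)
    dev <- cumsum(hit) / m - cumsum(!hit) / (n - m)
    classical <- dev[which.max(abs(dev))]
    expect_equal(gseaES(ranked, mset, weight = 0)$es, classical,
                 tolerance = 1e-12)
  }
})

test_that("GSEA permutation: planted signal, determinism, fallback", {
  set.seed(91)
  n <- 300; ns <- 20
  m <- matrix(rnorm(n * ns), n,
              dimnames = list(sprintf("G%03d", 1:n),
                              sprintf("S%02d", 1:ns)))
  g <- rep(c("tumor", "normal"), each = 10)
  planted <- sprintf("G%03d", 1:20)
  m[planted, g == "tumor"] <- m[planted, g == "tumor"] + 2
  sets <- c(list(planted), lapply(1:9, function(i)
    sample(rownames(m), 20)))
  gsc <- new("GeneSetCollection",
             setNames = c("planted", paste0("null", 1:9)),
             descriptions = rep("", 10), members = sets)
  res <- gseaPermutation(m, g, gsc, nPerm = 500, seed = 5)
  row <- res[res$set == "planted", ]
  expect_gt(row$nes, 0)
  expect_lt(row$q, 0.05)
  expect_true(all(abs(res$es) <= 1))

  # determinism
  res2 <- gseaPermutation(m, g, gsc, nPerm = 500, seed = 5)
  expect_identical(res, res2)

  # small groups fall back to gene-set permutation with a warning
  expect_warning(
    gseaPermutation(m[, c(1:5, 11:15)], g[c(1:5, 11:15)], gsc,
                    nPerm = 100, seed = 1),
    "gene-set permutation")
})

test_that("ssGSEA: monotonicity, rank invariance, hand oracle", {
  set.seed(12)
  m <- matrix(rnorm(30 * 4, 8), 30,
              dimnames = list(sprintf("G%02d", 1:30), paste0("S", 1:4)))
  mem <- sprintf("G%02d", 1:5)
  # members top-expressed in S1, bottom in S2
  m[mem, 1] <- 20
  m[mem, 2] <- -20
  gsc <- new("GeneSetCollection", setNames = "sig",
             descriptions = "", members = list(mem))
  sc <- ssgseaScores(m, gsc)
  expect_gt(sc$scores["sig", "S1"], sc$scores["sig", "S2"])

  # strictly monotone per-sample transformation leaves raw scores alone
  m2 <- m; m2[, 3] <- exp(m[, 3] / 4)
  sc2 <- ssgseaScores(m2, gsc, normalize = FALSE)
  sc1 <- ssgseaScores(m, gsc, normalize = FALSE)
  expect_equal(sc2$raw["sig", "S3"], sc1$raw["sig", "S3"],
               tolerance = 1e-12)

  # 10-gene, 2-sample toy against the weighted ECDF difference
  toy <- matrix(c(10:1, c(2, 9, 4, 7, 6, 5, 8, 3, 10, 1)), ncol = 2,
                dimnames = list(paste0("g", 1:10), c("A", "B")))
  gsc2 <- new("GeneSetCollection", setNames = "s",
              descriptions = "", members = list(c("g1", "g3", "g8")))
  out <- ssgseaScores(toy, gsc2, alpha = 0.25, normalize = FALSE)
  for (j in 1:2) {
    r <- rank(toy[, j])
    ord <- order(-r, rownames(toy))
    hit <- rownames(toy)[ord] %in% c("g1", "g3", "g8")
    wts <- r[ord]^0.25 * hit
    oracle <- sum(cumsum(wts) / sum(wts) - cumsum(!hit) / 7)
    expect_equal(out$raw["s", j], oracle, tolerance = 1e-12)
  }

  # absent sets are flagged and score NA
  gsc3 <- new("GeneSetCollection", setNames = c("s", "ghost"),
              descriptions = c("", ""),
              members = list(c("g1", "g3"), c("zz1", "zz2")))
  out3 <- ssgseaScores(toy, gsc3)
  expect_true("ghost" %in% out3$flagged)
  expect_true(all(is.na(out3$scores["ghost", ])))
})

test_that("immune correlation: exact cases and rank oracle", {
  set.seed(14)
  v <- rnorm(20)
  scores <- rbind(same = v, rev = -v, noise = rnorm(20))
  colnames(scores) <- paste0("S", 1:20)
  res <- immuneCorrelation(scores, v)
  expect_equal(res$rho[res$cell_type == "same"], 1)
  expect_equal(res$rho[res$cell_type == "rev"], -1)
  # rank-then-Pearson oracle
  expect_equal(res$rho[res$cell_type == "noise"],
               cor(rank(scores["noise", ]), rank(v)),
               tolerance = 1e-12)
  # sorted by rho
  expect_equal(res$cell_type[1], "same")
  expect_error(immuneCorrelation(rbind(flat = rep(1, 20)), v),
               "constant")
})

test_that("immune survival association flags protective cell types", {
  set.seed(15)
  n <- 300
  score <- rnorm(n)
  # higher infiltration halves the hazard
  d <- simulateSurvival(as.numeric(score > median(score)),
                        list(baselineHazard = 0.08,
                             betaSurv = log(0.5),
                             censoringRate = 0.2), seed = 16)
  scores <- matrix(score, nrow = 1,
                   dimnames = list("NK_cells", paste0("S", 1:n)))
  res <- immuneSurvivalAssociation(scores, d[c("time", "event")])
  expect_lt(res$HR, 1)
  expect_lt(res$cox_p, 0.05)

  # independent score: CI straddles 1 in most replicates
  cover <- vapply(1:30, function(s) {
    set.seed(700 + s)
    sc <- matrix(rnorm(120), 1, dimnames = list("ct", NULL))
    dd <- simulateSurvival(rep(0, 120),
                           list(baselineHazard = 0.08, betaSurv = 0,
                                censoringRate = 0.2), seed = 800 + s)
    r <- immuneSurvivalAssociation(sc, dd[c("time", "event")])
    r$ci_low <= 1 && 1 <= r$ci_high
  }, logical(1))
  expect_gte(mean(cover), 0.85)

  expect_error(immuneSurvivalAssociation(scores,
                                         d[0, c("time", "event")]),
               "empty|aligned")
})
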