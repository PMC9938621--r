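test_that("adjacency is the soft-powered correlation with unit diagonal", {
  withr::with_seed(1, {
    v <- matrix(rnorm(20 * 12), 20, 12,
                dimnames = list(paste0("g", 1:20), NULL))
    ds <- makeLog2Dataset(v, nPerStage = c(4, 4, 4))
    a <- buildAdjacency(ds)
    r <- cor(t(exprValues(ds)))
    expect_equal(a[2, 7], abs(r[2, 7])^6)
    expect_true(all(a >= 0 & a <= 1))
    expect_equal(unname(diag(a)), rep(1, 20))
    expect_true(isSymmetric(a))
    s <- buildAdjacency(ds, params = networkParams(sign = "signed"))
    expect_equal(s[3, 9], ((1 + r[3, 9]) / 2)^6)
  })
  # perfectly correlated pair -> adjacency 1; cor 0.5 at beta 6 -> 0.5^6
  v2 <- rbind(g1 = c(1, 2, 3, 4, 5, 6), g2 = c(2, 4, 6, 8, 10, 12))
  ds2 <- makeLog2Dataset(v2, nPerStage = c(2, 2, 2))
  expect_equal(buildAdjacency(ds2)[1, 2], 1)
  expect_equal(0.5^6, 0.015625) # the soft-power contract at cor 0.5
  v3 <- rbind(v2, g3 = rep(1, 6))
  expect_error(buildAdjacency(makeLog2Dataset(v3, nPerStage = c(2, 2, 2))),
               "zero-variance.*g3")
})

test_that("TOM matches the hand example and the triple-loop oracle", {
  a <- matrix(0.5, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(a) <- 1
  w <- tomSimilarity(a)
  expect_equal(w[1, 2], (0.25 + 0.5) / (1 + 1 - 0.5)) # = 0.5
  a0 <- diag(4)
  expect_equal(unname(tomSimilarity(a0)), diag(4)) # empty network
  withr::with_seed(5, {
    for (n in c(10, 25, 50)) {
      r <- cor(matrix(rnorm(n * 15), 15, n))
      a <- abs(r)^6
      diag(a) <- 1
      dimnames(a) <- list(paste0("g", 1:n), paste0("g", 1:n))
      w <- tomSimilarity(a)
      expect_equal(w, tomOracle(a), tolerance = 1e-12)
      expect_true(all(w >= 0 & w <= 1))
      expect_true(isSymmetric(w))
    }
  })
  bad <- matrix(c(1, 0.2, 0.5, 1), 2)
  expect_error(tomSimilarity(bad), "symmetric")
})

test_that("planted correlation blocks are recovered exactly", {
  withr::with_seed(8, {
    n <- 30
    f1 <- rnorm(n); f2 <- rnorm(n)
    block <- function(f, k, noise) {
      t(replicate(k, sqrt(0.9) * f + sqrt(0.1) * rnorm(n) * noise))
    }
    v <- rbind(block(f1, 40, 1), block(f2, 40, 1))
    rownames(v) <- paste0("g", 1:80)
    ds <- makeLog2Dataset(v, nPerStage = c(10, 10, 10))
    labels <- detectModules(tomSimilarity(buildAdjacency(ds)))
    truth <- rep(c("A", "B"), each = 40)
    expect_equal(adjustedRand(labels, truth), 1.0)
    expect_equal(length(unique(labels)), 2)
    # permutation invariance (up to labels)
    perm <- sample(80)
    dsP <- makeLog2Dataset(v[perm, ], nPerStage = c(10, 10, 10))
    labP <- detectModules(tomSimilarity(buildAdjacency(dsP)))
    expect_equal(adjustedRand(labP, truth[perm]), 1.0)
    # independent genes carry no module structure
    v0 <- matrix(rnorm(60 * n), 60, n,
                 dimnames = list(paste0("h", 1:60), NULL))
    ds0 <- makeLog2Dataset(v0, nPerStage = c(10, 10, 10))
    lab0 <- detectModules(tomSimilarity(buildAdjacency(ds0)))
    expect_true(all(lab0 == "grey"))
  })
  expect_warning(
    detectModules(diag(3), networkParams(minModuleSize = 5)), "grey"
  )
})

test_that("eigengenes summarize modules and track stage", {
  # all members rise PR -> RE -> PO in equal steps: r = +1
  ds <- makeStageMeansDataset(rep(list(c(1, 2, 3)), 5), n = 4)
  labels <- structure(rep("turquoise", 5), names = rownames(ds))
  es <- moduleEigengeneStageCor(ds, labels)
  expect_equal(unname(es$stageCor["turquoise"]), 1, tolerance = 1e-9)
  expect_equal(sum(es$eigengenes[, "turquoise"]^2), 1) # unit norm
  # negating member profiles flips eigengene and correlation sign
  dsNeg <- makeLog2Dataset(-exprValues(ds), nPerStage = c(4, 4, 4))
  esNeg <- moduleEigengeneStageCor(dsNeg, labels)
  expect_equal(esNeg$eigengenes[, 1], -es$eigengenes[, 1],
               tolerance = 1e-9)
  expect_equal(unname(esNeg$stageCor[1]), -1, tolerance = 1e-9)
  # stage-independent module: small correlation in expectation
  withr::with_seed(33, {
    ps <- vapply(1:100, function(i) {
      v <- matrix(rnorm(6 * 12), 6, 12)
      d <- makeLog2Dataset(v, nPerStage = c(4, 4, 4))
      l <- structure(rep("blue", 6), names = rownames(d))
      moduleEigengeneStageCor(d, l)$stageCorP[["blue"]]
    }, 0)
    expect_gt(mean(ps > 0.05), 0.85) # ~95% expected under the null
  })
  # singleton module falls back to the gene's standardized profile
  one <- makeLog2Dataset(matrix(1:6, 1), nPerStage = c(2, 2, 2))
  esOne <- moduleEigengeneStageCor(
    one, structure("m1", names = rownames(one))
  )
  expect_equal(abs(cor(esOne$eigengenes[, 1], 1:6)), 1, tolerance = 1e-9)
})

test_that("hubs are the intramodular connectivity maxima", {
  # star topology: center correlated with all leaves
  a <- matrix(0.1, 11, 11,
              dimnames = list(paste0("g", 1:11), paste0("g", 1:11)))
  a[1, ] <- a[, 1] <- 0.9
  diag(a) <- 1
  labels <- structure(rep("turquoise", 11), names = rownames(a))
  hk <- hubGenes(a, labels)
  expect_identical(unname(hk$hubs["turquoise"]), "g1")
  expect_true(all(hk$kWithin >= 0))
  # exact tie -> lexicographically smaller id
  b <- matrix(0.5, 4, 4, dimnames = list(c("gB", "gA", "gC", "gD"),
                                         c("gB", "gA", "gC", "gD")))
  diag(b) <- 1
  hk2 <- hubGenes(b, structure(rep("blue", 4), names = rownames(b)))
  expect_identical(unname(hk2$hubs["blue"]), "gA")
})

test_that("planted hubs are recovered from realized expression", {
  hits <- vapply(1:25, function(s) {
    # full cohort size (48 patients x 3): hub margins are calibrated to the
    # correlation-estimation noise of the study design
    cfg <- testSimConfig(seed = s, nGenes = 80, nDEG = 0, nPatients = 48)
    sim <- simulateTrainingCohort(cfg)
    modGenes <- names(sim$truth$moduleLabels)[
      sim$truth$moduleLabels != "none"
    ]
    mods <- coexpressionModules(sim$dataset, modGenes,
                                networkParams(minModuleSize = 10))
    all(sim$truth$hubIds %in% hubGenesOf(mods))
  }, NA)
  expect_gte(mean(hits), 0.95)
})

test_that("network parameters are validated", {
  expect_error(networkParams(beta = 0.5), "beta")
  expect_error(networkParams(cutHeight = 1.2), "cutHeight")
  expect_error(networkParams(minModuleSize = 1), "minModuleSize")
})
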