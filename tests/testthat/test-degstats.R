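test_that("one-way F, SS and p match hand-computed toy values", {
  # PR=(1,2), RE=(2,3), PO=(3,4): MS_stage=2, MS_error=0.5, F=4,
  # p = P(F(2,3) > 4) = (1 + 2*4/3)^(-3/2)
  ds <- makeLog2Dataset(matrix(c(1, 2, 2, 3, 3, 4), nrow = 1),
                        nPerStage = c(2, 2, 2))
  gs <- geneANOVA(ds)
  expect_equal(gs$ms_stage, 2.0)
  expect_equal(gs$ms_error, 0.5)
  expect_equal(gs$F, 4.0)
  expect_equal(gs$p_value, (1 + 8 / 3)^(-3 / 2), tolerance = 1e-12)
  expect_equal(gs$ss_stage + gs$ss_error,
               sum((c(1, 2, 2, 3, 3, 4) - 2.5)^2), tolerance = 1e-12)
})

test_that("ANOVA agrees with the aov oracle on random small layouts", {
  withr::with_seed(101, {
    for (i in 1:100) {
      reps <- sample(2:6, 3, replace = TRUE)
      stage <- rep(STAGES3, times = reps)
      y <- rnorm(length(stage), mean = sample(0:3, 1))
      ds <- makeLog2Dataset(matrix(y, 1), stage = stage)
      gs <- geneANOVA(ds)
      orc <- anovaOracle(y, stage)
      expect_equal(gs$ss_stage, orc$ss_stage, tolerance = 1e-10)
      expect_equal(gs$ss_error, orc$ss_error, tolerance = 1e-10)
      expect_equal(gs$F, orc$F, tolerance = 1e-10)
      expect_equal(gs$p_value, orc$p, tolerance = 1e-10)
    }
  })
})

test_that("two-way main-effects ANOVA matches lm with stage fitted last", {
  withr::with_seed(55, {
    stage <- rep(STAGES3, times = c(5, 7, 6))
    prot <- sample(c("natural", "HRT"), length(stage), replace = TRUE)
    y <- rnorm(length(stage)) + (prot == "HRT") * 0.8
    ds <- makeLog2Dataset(matrix(y, 1), stage = stage)
    SummarizedExperiment::colData(ds)$protocol <- prot
    gs <- geneANOVA(ds, includeTreatment = TRUE)
    a <- stats::anova(stats::lm(y ~ factor(prot) +
                                  factor(stage, levels = STAGES3)))
    expect_equal(gs$ss_stage, a["Sum Sq"][2, 1], tolerance = 1e-10)
    expect_equal(gs$ss_error, a["Sum Sq"][3, 1], tolerance = 1e-10)
    expect_equal(gs$F, a["F value"][2, 1], tolerance = 1e-10)
    expect_equal(gs$df_error, a["Df"][3, 1])
    expect_true(S4Vectors::metadata(gs)$treatment_fitted)
    # constant protocol drops the term silently
    gs1 <- geneANOVA(makeLog2Dataset(matrix(y, 1), stage = stage),
                     includeTreatment = TRUE)
    expect_false(S4Vectors::metadata(gs1)$treatment_fitted)
  })
})

test_that("degenerate genes are flagged rather than mis-tested", {
  ds <- makeLog2Dataset(rbind(rep(5, 6), c(1, 1, 2, 2, 3, 3)),
                        nPerStage = c(2, 2, 2))
  gs <- geneANOVA(ds)
  expect_identical(gs$degenerate[1], "constant")
  expect_equal(gs$p_value[1], 1)
  expect_true(all(c(gs$tukey_PR_RE[1], gs$tukey_RE_PO[1],
                    gs$tukey_PR_PO[1]) == 1))
  # zero residual, non-zero stage separation
  expect_identical(gs$degenerate[2], "zero_residual")
  expect_equal(gs$F[2], Inf)
  expect_equal(gs$p_value[2], 0)
  expect_equal(gs$tukey_PR_PO[2], 0)
})

test_that("design and metadata errors are explicit", {
  ds <- makeLog2Dataset(matrix(rnorm(5), 1), stage = c("PR", "PR", "RE",
                                                       "RE", "PO"))
  expect_error(geneANOVA(ds), "fewer than 2")
  ds2 <- makeLog2Dataset(matrix(rnorm(6), 1), nPerStage = c(2, 2, 2))
  SummarizedExperiment::colData(ds2)$stage[1] <- "unknown"
  expect_error(geneANOVA(ds2), "stage")
})

test_that("BH adjustment reproduces the hand example and the step-up oracle", {
  expect_equal(bhFDR(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bhFDR(rep(1, 5)), rep(1, 5))
  expect_equal(bhFDR(0.123), 0.123)
  withr::with_seed(77, {
    for (i in 1:20) {
      p <- runif(sample(1:200, 1))^sample(1:3, 1)
      q <- bhFDR(p)
      expect_equal(q, bhOracle(p), tolerance = 1e-15)
      expect_true(all(q >= p - 1e-15) && all(q <= 1))
      # monotone with respect to p-ordering
      o <- order(p)
      expect_true(all(diff(q[o]) >= -1e-15))
    }
  })
  expect_error(bhFDR(c(0.1, NA)), "NA")
  expect_equal(bhFDR(c(0.1, NA), naAction = "propagate")[1], 0.1)
})

test_that("pairwise log2 fold change is a difference of stage means", {
  ds <- makeStageMeansDataset(list(c(5, 7, 5), c(1, 1, 1)), n = 3)
  expect_equal(unname(pairwiseLog2FC(ds, "PR", "RE")["g1"]), 2) # 4-fold
  expect_equal(unname(pairwiseLog2FC(ds, "PR", "RE")["g2"]), 0)
  expect_equal(pairwiseLog2FC(ds, "RE", "PR"),
               -pairwiseLog2FC(ds, "PR", "RE"))
  expect_error(pairwiseLog2FC(ds, "PR", "XX"), "design error")
})

test_that("volcano classification honors both cutoffs and the boundary", {
  expect_identical(volcanoClassify(0.01, 1.5), "up")
  expect_identical(volcanoClassify(0.2, 3), "ns")
  expect_identical(volcanoClassify(0.04, -1.0), "down") # inclusive boundary
  expect_identical(volcanoClassify(0.04, 0.99), "ns")
  expect_error(volcanoClassify(0.01, 1, fcCut = 1), "fcCut")
})

test_that("Tukey pairwise p-values match ptukey and behave at extremes", {
  # equal group means: statistic 0, p ~ 1
  ds0 <- makeStageMeansDataset(list(c(2, 2, 2)), n = 5, sd = 0.5, seed = 3)
  # huge separation: all pairwise p tiny
  ds1 <- makeStageMeansDataset(list(c(0, 10, 20)), n = 5, sd = 0.1,
                               seed = 4)
  tk1 <- tukeyHSDPerGene(ds1)
  expect_true(all(tk1 < 1e-6))
  # direct agreement with the studentized-range distribution
  gs <- geneANOVA(ds0)
  q <- abs(gs$mean_PR - gs$mean_RE) / sqrt(gs$ms_error / 5)
  expect_equal(gs$tukey_PR_RE,
               stats::ptukey(q, 3, gs$df_error, lower.tail = FALSE))
  # agreement with TukeyHSD on a random unbalanced layout (Tukey-Kramer)
  withr::with_seed(9, {
    stage <- rep(STAGES3, times = c(4, 6, 5))
    y <- rnorm(15)
    ds <- makeLog2Dataset(matrix(y, 1), stage = stage)
    tk <- tukeyHSDPerGene(ds)
    ref <- stats::TukeyHSD(stats::aov(y ~ factor(stage)))[[1]][, "p adj"]
    expect_equal(sort(unname(tk[1, ])), sort(unname(ref)),
                 tolerance = 1e-8)
  })
})

test_that("Tukey p never increases when stage separation grows", {
  withr::with_seed(31, {
    stage <- rep(STAGES3, each = 5)
    y <- rnorm(15, rep(c(0.3, 0.5, 1.1), each = 5), 0.7)
    gm <- tapply(y, stage, mean)[stage] # realized group means
    prev <- NULL
    for (cc in c(1, 1.5, 2.5, 4)) {
      yc <- y + (cc - 1) * gm # scales every separation by cc, MSE fixed
      tk <- tukeyHSDPerGene(makeLog2Dataset(matrix(yc, 1), stage = stage))
      if (!is.null(prev)) expect_true(all(tk <= prev + 1e-12))
      prev <- tk
    }
  })
})

test_that("type-I error is calibrated under the simulated null", {
  cfg <- simulationConfig(nGenes = 2000, nDEG = 0, nPatients = 16,
                          moduleSizes = integer(0), seed = 17)
  p <- geneANOVA(simulateTrainingCohort(cfg)$dataset)$p_value
  expect_lt(abs(mean(p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
})
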