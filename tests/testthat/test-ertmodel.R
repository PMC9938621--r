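makeSeparableCohort <- function(nPatients = 12, nNoise = 20, nMarkers = 3,
                                sep = 6, sd = 0.4, seed = 1) {
  withr::with_seed(seed, {
    stage <- rep(STAGES3, times = nPatients)
    patient <- rep(sprintf("p%02d", seq_len(nPatients)), each = 3)
    v <- matrix(rnorm((nNoise + nMarkers) * length(stage)),
                nNoise + nMarkers, length(stage))
    for (i in seq_len(nMarkers)) {
      v[i, ] <- c(PR = 0, RE = sep, PO = 2 * sep)[stage] +
        rnorm(length(stage), 0, sd)
    }
    rownames(v) <- c(sprintf("marker%d", seq_len(nMarkers)),
                     sprintf("n%d", seq_len(nNoise)))
    makeLog2Dataset(v, stage = stage, patient = patient)
  })
}

test_that("training validates inputs and separates a separable cohort", {
  ds <- makeSeparableCohort()
  model <- trainERT(ds, rownames(ds), ntree = 200, seed = 3)
  expect_s4_class(model, "ERTModel")
  pred <- predictReceptivity(model, ds)
  expect_identical(pred$call, stageLabels(ds)) # training accuracy 1
  expect_error(trainERT(ds, c("marker1", "missing_gene")), "missing_gene")
  # a single perfectly separating marker suffices
  m1 <- trainERT(ds, "marker1", ntree = 200, seed = 3)
  expect_identical(predictReceptivity(m1, ds)$call, stageLabels(ds))
  expect_error(trainERT(ds, rownames(ds), tau = 0.2), "tau")
})

test_that("probabilities form a simplex and the threshold rule is exact", {
  prob <- rbind(c(0.70, 0.20, 0.10), c(0.55, 0.30, 0.15),
                c(0.10, 0.30, 0.60), c(1 / 3, 1 / 3, 1 / 3))
  colnames(prob) <- STAGES3
  rep1 <- fluidERT:::probsToReport(prob, 0.6, paste0("s", 1:4))
  expect_identical(rep1$call, c("PR", "NO_CALL", "PO", "NO_CALL"))
  expect_identical(rep1$woi, c("delayed", "indeterminate", "advanced",
                               "indeterminate"))
  # tau just above 1/3 calls everything (argmax >= 1/3 + eps here)
  repLow <- fluidERT:::probsToReport(prob[1:3, ], 1 / 3 + 1e-9,
                                     paste0("s", 1:3))
  expect_false(any(repLow$call == "NO_CALL"))
  # raising tau never converts NO_CALL into a call
  for (tau2 in c(0.5, 0.7, 0.9)) {
    repHi <- fluidERT:::probsToReport(prob, tau2, paste0("s", 1:4))
    expect_true(all(repHi$call[rep1$call == "NO_CALL"] == "NO_CALL" |
                      tau2 < 0.6))
  }
  expect_error(fluidERT:::probsToReport(prob / 2, 0.6, paste0("s", 1:4)))
})

test_that("real predictions satisfy the report invariants", {
  ds <- makeSeparableCohort(seed = 5)
  model <- trainERT(ds, rownames(ds), ntree = 200, seed = 5)
  pred <- predictReceptivity(model, ds,
                             failedSamples = colnames(ds)[1])
  expect_equal(rowSums(pred[-1, c("p_PR", "p_RE", "p_PO")]),
               rep(1, ncol(ds) - 1), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_identical(pred$woi[1], "detection_failed")
  expect_true(all(is.na(pred[1, c("p_PR", "p_RE", "p_PO")])))
  mism <- ReceptivityExperiment(
    2^exprValues(ds), "fpkm",
    cbind(sample_id = colnames(ds), sampleInfo(ds))
  )
  expect_error(predictReceptivity(model, mism), "log2")
})

test_that("WOI interpretation maps calls as the clinical rule dictates", {
  expect_identical(interpretWOI("RE"), "normal")
  expect_identical(interpretWOI("PR"), "delayed")
  expect_identical(interpretWOI("PO"), "advanced")
  expect_identical(interpretWOI("NO_CALL"), "indeterminate")
  expect_error(interpretWOI("XX"), "unknown call")
})

test_that("model serialization round-trips to identical predictions", {
  ds <- makeSeparableCohort(seed = 9)
  model <- trainERT(ds, rownames(ds), ntree = 200, seed = 9)
  path <- withr::local_tempfile(fileext = ".rds")
  saveRDS(model, path)
  back <- readRDS(path)
  expect_identical(predictReceptivity(back, ds),
                   predictReceptivity(model, ds))
})

test_that("cross-validation folds partition patients and score separable data", {
  ds <- makeSeparableCohort(nPatients = 15, seed = 2)
  cv <- crossValidate(ds, rownames(ds), k = 5, ntree = 200, seed = 2)
  expect_equal(unname(cv$mean["accuracy"]), 1.0)
  expect_true(all(cv$folds$accuracy >= 0) && all(cv$folds$accuracy <= 1))
  # structural patient-grouping: each patient in exactly one fold
  expect_equal(sort(names(cv$assignment)), sort(unique(patientIds(ds))))
  expect_equal(length(cv$assignment), 15)
  expect_error(crossValidate(ds, rownames(ds), k = 16), "exceeds")
  expect_error(crossValidate(ds, rownames(ds), k = 1), "k must be")
})

test_that("permuted labels drop cross-validation to chance", {
  accs <- vapply(1:20, function(s) {
    ds <- makeSeparableCohort(nPatients = 12, seed = s)
    perm <- withr::with_seed(100 + s, {
      cd <- SummarizedExperiment::colData(ds)
      cd$stage <- sample(cd$stage)
      SummarizedExperiment::colData(ds) <- cd
      ds
    })
    unname(crossValidate(perm, rownames(ds), k = 4, ntree = 150,
                         seed = s)$mean["accuracy"])
  }, 0)
  # no above-chance inflation (leakage check); grouped-fold argmax carries
  # a small negative composition bias, hence the coarse two-sided band
  expect_lt(mean(accs) - 1 / 3, 3 * sd(accs) / sqrt(20))
  expect_lt(abs(mean(accs) - 1 / 3), 0.06)
})

test_that("LDA projection separates classes and survives degeneracy", {
  ds <- makeSeparableCohort(nPatients = 12, nNoise = 5, seed = 4)
  proj <- ldaProject(ds, rownames(ds))
  # silhouette on LD1/LD2 by stage
  st <- stageLabels(ds)
  d <- as.matrix(dist(proj))
  sil <- vapply(seq_len(nrow(proj)), function(i) {
    a <- mean(d[i, st == st[i]][-which(which(st == st[i]) == i)])
    b <- min(vapply(setdiff(STAGES3, st[i]),
                    function(cl) mean(d[i, st == cl]), 0))
    (b - a) / max(a, b)
  }, 0)
  expect_gt(mean(sil), 0.5)
  # duplicated samples project identically
  dup <- makeLog2Dataset(cbind(exprValues(ds), exprValues(ds)),
                         stage = rep(st, 2),
                         patient = rep(patientIds(ds), 2))
  pd <- ldaProject(dup, rownames(dup))
  expect_equal(unname(pd[1:36, ]), unname(pd[37:72, ]), tolerance = 1e-9)
  # collinear class means (1-D structure): handled, LD2 ~ degenerate
  ds0 <- makeSeparableCohort(nNoise = 0, seed = 8)
  p0 <- ldaProject(ds0, rownames(ds0)) # collinear class means
  expect_lt(stats::var(p0[, "LD2"]) / stats::var(p0[, "LD1"]), 0.05)
  expect_error(
    ldaProject(makeLog2Dataset(matrix(rnorm(5), 1),
                               stage = c("PR", "PR", "RE", "RE", "PO")),
               "g1"),
    "fewer than 2"
  )
})
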