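## Three-class receptivity classifier: random forest on the marker panel,
## probability-threshold call rule, WOI interpretation, patient-grouped
## cross-validation, LDA projection.

#' ERTModel: the trained receptivity classifier
#'
#' Holds the fitted random forest, the ordered marker list, the fixed class
#' order PR/RE/PO and the probability threshold tau of the no-call rule: a
#' sample is called only when its maximum class probability reaches tau
#' (default 0.6), otherwise `NO_CALL`.
#'
#' @slot markers ordered marker gene ids.
#' @slot forest the fitted `randomForest` object.
#' @slot tau probability threshold in (1/3, 1].
#' @slot classLevels class order (always PR, RE, PO).
#' @slot ntree trees in the forest.
#' @slot seed RNG seed used at fit time.
#' @slot classCounts training samples per class.
#' @exportClass ERTModel
setClass("ERTModel", representation(
  markers = "character", forest = "ANY", tau = "numeric",
  classLevels = "character", ntree = "numeric", seed = "numeric",
  classCounts = "integer"
))

setValidity("ERTModel", function(object) {
  msg <- character(0)
  if (!length(object@markers)) msg <- c(msg, "markers must be non-empty")
  if (object@tau <= 1 / 3 || object@tau > 1) {
    msg <- c(msg, "tau must lie in (1/3, 1]")
  }
  if (!identical(object@classLevels, STAGES)) {
    msg <- c(msg, "classLevels must be PR, RE, PO")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ERTModel", function(object) {
  cat(sprintf(
    "ERTModel: %d markers, %d trees, tau = %.2f\n  training: %s\n",
    length(object@markers), object@ntree, object@tau,
    paste(sprintf("%s=%d", object@classLevels, object@classCounts),
          collapse = " ")
  ))
})

#' Train the receptivity classifier
#'
#' Fits a random forest (default 500 trees, sqrt features per split) on the
#' marker-panel expression against the three stage labels.
#'
#' @param x log2-scale [ReceptivityExperiment-class] with PR/RE/PO labels.
#' @param markers marker gene ids (all must be present in `x`).
#' @param tau probability threshold for the no-call rule.
#' @param ntree trees in the forest.
#' @param seed RNG seed; refitting with the same seed reproduces identical
#'   predictions.
#' @return An [ERTModel-class].
#' @export
trainERT <- function(x, markers, tau = 0.6, ntree = 500, seed = 1) {
  if (exprScale(x) != "log2") stopf("trainERT expects log2 scale")
  miss <- setdiff(markers, rownames(x))
  if (length(miss)) {
    stopf("marker gene(s) missing from matrix: %s",
          paste(head(miss, 3), collapse = ", "))
  }
  stage <- factor(stageLabels(x), levels = STAGES)
  if (anyNA(stage)) stopf("metadata error: unlabelled training sample")
  if (any(tapply(patientIds(x), stage, function(p) length(unique(p))) < 2)) {
    stopf("design error: every class needs >= 2 patients")
  }
  feat <- t(exprValues(x)[markers, , drop = FALSE])
  rf <- withSeed(seed, randomForest::randomForest(feat, stage,
                                                  ntree = ntree))
  new("ERTModel", markers = markers, forest = rf, tau = tau,
      classLevels = STAGES, ntree = ntree, seed = seed,
      classCounts = as.integer(table(stage)))
}

#' Predict receptivity with the probability-threshold call rule
#'
#' Class probabilities are the forest vote fractions; the call is the
#' argmax class when the maximum probability reaches `tau`, otherwise
#' `NO_CALL`. The window-of-implantation interpretation assumes sampling on
#' the expected receptive day (LH+7 natural / P+5 HRT): RE means a normal
#' WOI, PR a delayed WOI (not yet receptive), PO an advanced WOI, NO_CALL
#' indeterminate. Samples listed in `failedSamples` (for example, libraries
#' rejected by [qcFilter()]) are reported as `detection_failed`.
#'
#' @param model an [ERTModel-class].
#' @param x log2-scale [ReceptivityExperiment-class] containing all marker
#'   genes.
#' @param failedSamples sample ids whose libraries failed QC.
#' @return A `PredictionReport` data.frame: `sample_id`, `p_PR`, `p_RE`,
#'   `p_PO`, `call`, `woi`.
#' @export
predictReceptivity <- function(model, x, failedSamples = character(0)) {
  if (exprScale(x) != "log2") stopf("validation error: expected log2 scale")
  miss <- setdiff(model@markers, rownames(x))
  if (length(miss)) {
    stopf("marker gene(s) missing from matrix: %s",
          paste(head(miss, 3), collapse = ", "))
  }
  feat <- t(exprValues(x)[model@markers, , drop = FALSE])
  prob <- predict(model@forest, feat, type = "prob")
  prob <- prob[, STAGES, drop = FALSE]
  report <- probsToReport(prob, model@tau, colnames(x))
  failedSamples <- intersect(failedSamples, report$sample_id)
  if (length(failedSamples)) {
    i <- report$sample_id %in% failedSamples
    report$call[i] <- NA_character_
    report$woi[i] <- "detection_failed"
    report[i, c("p_PR", "p_RE", "p_PO")] <- NA_real_
  }
  report
}

probsToReport <- function(prob, tau, ids) {
  stopifnot(all(abs(rowSums(prob) - 1) < 1e-9))
  imax <- max.col(prob, ties.method = "first")
  pmax_ <- prob[cbind(seq_len(nrow(prob)), imax)]
  call <- ifelse(pmax_ >= tau, STAGES[imax], "NO_CALL")
  data.frame(
    sample_id = ids, p_PR = prob[, "PR"], p_RE = prob[, "RE"],
    p_PO = prob[, "PO"], call = call,
    woi = vapply(call, interpretWOI, ""),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Window-of-implantation interpretation of a stage call
#'
#' On the expected receptive day, a receptive endometrium (RE) is a normal
#' WOI; a still pre-receptive one (PR) a delayed WOI; an already
#' post-receptive one (PO) an advanced WOI; NO_CALL is indeterminate.
#'
#' @param call one of `"PR"`, `"RE"`, `"PO"`, `"NO_CALL"`.
#' @return `"normal"`, `"delayed"`, `"advanced"` or `"indeterminate"`.
#' @export
interpretWOI <- function(call) {
  switch(as.character(call),
    RE = "normal", PR = "delayed", PO = "advanced",
    NO_CALL = "indeterminate",
    stopf("validation error: unknown call label '%s'", call)
  )
}

#' Patient-grouped k-fold cross-validation
#'
#' Folds partition patients (all three stage-timed samples of a patient
#' stay in the same fold) unless `groupByPatient = FALSE`. Per fold, a
#' forest is trained on the remaining patients and evaluated on the
#' held-out samples by argmax prediction; accuracy plus macro one-vs-rest
#' sensitivity, specificity, PPV and NPV are reported per fold and as
#' means.
#'
#' @param x log2-scale [ReceptivityExperiment-class].
#' @param markers marker panel gene ids.
#' @param k folds (default 10).
#' @param ntree trees per fold model.
#' @param seed RNG seed (fold assignment and forests).
#' @param groupByPatient keep each patient's samples in one fold.
#' @return List of class `CVReport`: `folds` (per-fold metric data.frame),
#'   `mean` (named metric means), `assignment` (patient -> fold), `k`,
#'   `seed`.
#' @export
crossValidate <- function(x, markers, k = 10, ntree = 500, seed = 1,
                          groupByPatient = TRUE) {
  stage <- factor(stageLabels(x), levels = STAGES)
  if (anyNA(stage)) stopf("metadata error: unlabelled sample")
  units <- if (groupByPatient) patientIds(x) else colnames(x)
  uu <- unique(units)
  if (k < 2) stopf("design error: k must be >= 2")
  if (k > length(uu)) {
    stopf("design error: k = %d exceeds %d cross-validation units",
          k, length(uu))
  }
  feat <- t(exprValues(x)[markers, , drop = FALSE])
  withSeed(seed, {
    fold <- structure(
      sample(rep(seq_len(k), length.out = length(uu))), names = uu
    )
    rows <- lapply(seq_len(k), function(f) {
      test <- fold[units] == f
      rf <- randomForest::randomForest(
        feat[!test, , drop = FALSE], stage[!test], ntree = ntree
      )
      pred <- predict(rf, feat[test, , drop = FALSE])
      cbind(fold = f, confusionMetrics(stage[test], pred))
    })
    folds <- do.call(rbind, rows)
    list2 <- list(
      folds = folds,
      mean = colMeans(folds[, -1, drop = FALSE], na.rm = TRUE),
      assignment = fold, k = k, seed = seed
    )
    class(list2) <- "CVReport"
    list2
  })
}

## accuracy + macro one-vs-rest metrics for a 3-class confusion
confusionMetrics <- function(truth, pred) {
  truth <- factor(truth, levels = STAGES)
  pred <- factor(pred, levels = STAGES)
  tab <- table(truth, pred)
  n <- sum(tab)
  acc <- sum(diag(tab)) / n
  per <- vapply(STAGES, function(cl) {
    tp <- tab[cl, cl]
    fn <- sum(tab[cl, ]) - tp
    fp <- sum(tab[, cl]) - tp
    tn <- n - tp - fn - fp
    c(sens = tp / (tp + fn), spec = tn / (tn + fp),
      ppv = tp / (tp + fp), npv = tn / (tn + fn))
  }, numeric(4))
  data.frame(
    accuracy = acc,
    sensitivity = mean(per["sens", ], na.rm = TRUE),
    specificity = mean(per["spec", ], na.rm = TRUE),
    ppv = mean(per["ppv", ], na.rm = TRUE),
    npv = mean(per["npv", ], na.rm = TRUE)
  )
}

#' @export
print.CVReport <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d)\n", x$k, x$seed))
  m <- x$mean
  cat(sprintf(
    "  mean accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%, PPV %.1f%%, NPV %.1f%%\n",
    100 * m[["accuracy"]], 100 * m[["sensitivity"]],
    100 * m[["specificity"]], 100 * m[["ppv"]], 100 * m[["npv"]]
  ))
  invisible(x)
}

#' Linear discriminant projection of the marker panel
#'
#' Projects samples onto the two leading discriminant axes of the
#' marker-panel expression (visualization of class separation; the
#' classifier of record is the forest). A ridge `epsilon` is added to the
#' pooled within-class covariance when it is singular.
#'
#' @param x log2-scale [ReceptivityExperiment-class] with stage labels.
#' @param markers marker gene ids.
#' @param epsilon ridge added to the feature variances on singularity.
#' @return Numeric matrix samples x 2 (`LD1`, `LD2`; LD2 zero when only one
#'   discriminant direction exists).
#' @export
ldaProject <- function(x, markers, epsilon = 1e-8) {
  stage <- factor(stageLabels(x), levels = STAGES)
  stage <- droplevels(stage)
  if (any(table(stage) < 2)) {
    stopf("class %s has fewer than 2 samples",
          names(which(table(stage) < 2))[1])
  }
  feat <- t(exprValues(x)[markers, , drop = FALSE])
  fit <- tryCatch(
    suppressWarnings(MASS::lda(feat, stage)),
    error = function(e) {
      jit <- feat + withSeed(0, matrix(
        rnorm(length(feat), 0, sqrt(epsilon)), nrow(feat)
      ))
      suppressWarnings(MASS::lda(jit, stage))
    }
  )
  proj <- predict(fit, feat)$x
  out <- matrix(0, nrow(feat), 2,
                dimnames = list(rownames(feat), c("LD1", "LD2")))
  out[, seq_len(min(2, ncol(proj)))] <- proj[, seq_len(min(2, ncol(proj)))]
  out
}
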