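## Per-gene differential expression across the three receptivity stages:
## main-effects ANOVA with an F ratio of stage to error, BH q-values,
## pairwise log2 fold changes, volcano classification, Tukey HSD post hoc
## comparisons.

#' Per-gene ANOVA across receptivity stages
#'
#' Fits, for every gene, the main-effects decomposition
#' \eqn{Y_{gij} = \mu_g + T_{gi} + S_{gj} + \varepsilon_{gij}} on log2
#' expression, where \eqn{T} is the cycle-protocol (treatment) term and
#' \eqn{S} the three-level receptivity-stage term, and tests the stage term
#' with \eqn{F = MS_{stage}/MS_{error}}. The treatment term is fitted only
#' when requested and the protocol column is non-constant (the training
#' cohort is all natural-cycle); the stage sum of squares is then the type-II
#' (stage-last) sum of squares. Degenerate genes get `p = 1` and flag
#' `"constant"` (zero total variance) or `p = 0`, `F = Inf` and flag
#' `"zero_residual"`.
#'
#' Also returns, per gene: stage means, pairwise log2 fold changes
#' (later stage minus earlier stage for PR-RE, RE-PO, PR-PO), Tukey HSD
#' pairwise p-values (Tukey-Kramer studentized-range statistic
#' \eqn{q_{ij} = |\bar y_i - \bar y_j| / \sqrt{(MS_e/2)(1/n_i + 1/n_j)}}
#' with k = 3 groups and the ANOVA error df), BH q-values, and volcano
#' classes per comparison at the default cutoffs (p < 0.05,
#' fold change 2).
#'
#' @param x a log2-scale [ReceptivityExperiment-class]; every sample must
#'   carry a PR/RE/PO stage label with at least 2 samples per stage.
#' @param includeTreatment fit the protocol term when non-constant.
#' @return A [S4Vectors::DataFrame] (one row per gene) with columns
#'   `mean_PR/RE/PO`, `ss_stage`, `ss_treatment`, `ss_error`, `df_stage`,
#'   `df_error`, `ms_stage`, `ms_error`, `F`, `p_value`, `q_value`,
#'   `lfc_PR_RE`, `lfc_RE_PO`, `lfc_PR_PO`, `tukey_PR_RE`, `tukey_RE_PO`,
#'   `tukey_PR_PO`, `volcano_*`, `degenerate`.
#' @export
geneANOVA <- function(x, includeTreatment = FALSE) {
  if (exprScale(x) != "log2") stopf("geneANOVA expects log2 scale")
  stage <- stageLabels(x)
  if (any(!stage %in% STAGES)) {
    stopf("metadata error: unknown stage label '%s'",
          setdiff(stage, STAGES)[1])
  }
  ns <- table(factor(stage, levels = STAGES))
  if (any(ns < 2)) {
    stopf("design error: stage %s has fewer than 2 samples",
          names(ns)[ns < 2][1])
  }
  Y <- exprValues(x)
  N <- ncol(Y)
  stageF <- factor(stage, levels = STAGES)
  prot <- factor(sampleInfo(x)$protocol)
  useTreat <- includeTreatment && nlevels(droplevels(prot)) > 1

  ## residual sums of squares via projection; SS_stage is the drop in SSE
  ## when the stage term is removed from the full model (stage-last)
  sseUnder <- function(X) {
    Q <- qr.Q(qr(X))
    E <- Y - (Y %*% Q) %*% t(Q)
    rowSums(E * Y) # = rowSums(E^2) since E is a residual projection of Y
  }
  if (useTreat) {
    Xfull <- stats::model.matrix(~ stageF + prot)
    Xred <- stats::model.matrix(~prot)
  } else {
    Xfull <- stats::model.matrix(~stageF)
    Xred <- matrix(1, N, 1)
  }
  sseFull <- sseUnder(Xfull)
  sseRed <- sseUnder(Xred)
  ssStage <- pmax(sseRed - sseFull, 0)
  center <- Y - rowMeans(Y)
  ssTotal <- rowSums(center^2)
  ## type-II treatment SS (treatment-last); in a balanced or one-way design
  ## the decomposition SS_total = SS_stage + SS_treatment + SS_error is exact
  ssTreat <- if (useTreat) {
    pmax(sseUnder(stats::model.matrix(~stageF)) - sseFull, 0)
  } else {
    rep(0, nrow(Y))
  }

  dfStage <- 2L
  dfErr <- N - ncol(Xfull)
  msStage <- ssStage / dfStage
  msErr <- sseFull / dfErr

  means <- vapply(STAGES, function(s) {
    rowMeans(Y[, stageF == s, drop = FALSE])
  }, numeric(nrow(Y)))
  if (is.null(dim(means))) {
    means <- matrix(means, 1, 3, dimnames = list(rownames(Y), STAGES))
  }

  tolAbs <- 1e-12
  constant <- ssTotal <= tolAbs * pmax(1, rowMeans(Y)^2)
  zeroResid <- !constant & sseFull <= tolAbs * pmax(1, ssTotal)
  Fstat <- msStage / msErr
  p <- pf(Fstat, dfStage, dfErr, lower.tail = FALSE)
  Fstat[constant] <- 0
  p[constant] <- 1
  Fstat[zeroResid] <- Inf
  p[zeroResid] <- 0
  degenerate <- rep(NA_character_, nrow(Y))
  degenerate[constant] <- "constant"
  degenerate[zeroResid] <- "zero_residual"

  ## Tukey-Kramer pairwise p on the one-way error line
  tk <- matrix(NA_real_, nrow(Y), 3)
  colnames(tk) <- vapply(STAGE_PAIRS, paste, "", collapse = "_")
  for (j in seq_along(STAGE_PAIRS)) {
    pr <- STAGE_PAIRS[[j]]
    se <- sqrt((msErr / 2) * (1 / ns[[pr[1]]] + 1 / ns[[pr[2]]]))
    q <- abs(means[, pr[1]] - means[, pr[2]]) / se
    tk[, j] <- ptukey(q, nmeans = 3, df = dfErr, lower.tail = FALSE)
    tk[zeroResid, j] <- as.numeric(
      means[zeroResid, pr[1]] == means[zeroResid, pr[2]]
    )
  }
  tk[constant, ] <- 1

  lfc <- cbind(
    lfc_PR_RE = means[, "RE"] - means[, "PR"],
    lfc_RE_PO = means[, "PO"] - means[, "RE"],
    lfc_PR_PO = means[, "PO"] - means[, "PR"]
  )

  out <- S4Vectors::DataFrame(
    mean_PR = unname(means[, "PR"]), mean_RE = unname(means[, "RE"]),
    mean_PO = unname(means[, "PO"]),
    ss_stage = unname(ssStage), ss_treatment = unname(ssTreat),
    ss_error = unname(sseFull), df_stage = dfStage, df_error = dfErr,
    ms_stage = unname(msStage), ms_error = unname(msErr),
    F = unname(Fstat), p_value = unname(p), q_value = unname(bhFDR(p)),
    lfc_PR_RE = unname(lfc[, "lfc_PR_RE"]),
    lfc_RE_PO = unname(lfc[, "lfc_RE_PO"]),
    lfc_PR_PO = unname(lfc[, "lfc_PR_PO"]),
    tukey_PR_RE = unname(tk[, 1]), tukey_RE_PO = unname(tk[, 2]),
    tukey_PR_PO = unname(tk[, 3]),
    degenerate = degenerate, row.names = rownames(Y)
  )
  for (cmp in c("PR_RE", "RE_PO", "PR_PO")) {
    out[[paste0("volcano_", cmp)]] <- volcanoClassify(
      out$p_value, out[[paste0("lfc_", cmp)]]
    )
  }
  S4Vectors::metadata(out) <- list(
    n_per_stage = as.integer(ns), treatment_fitted = useTreat
  )
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (the q-value reported alongside
#' each per-gene ANOVA p-value).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param naAction `"error"` rejects missing p-values, `"propagate"` passes
#'   them through.
#' @return Adjusted q-values, same length and order as `p`.
#' @export
bhFDR <- function(p, naAction = c("error", "propagate")) {
  naAction <- match.arg(naAction)
  if (anyNA(p) && naAction == "error") {
    stopf("NaN/NA p-values (use naAction = 'propagate' to keep them)")
  }
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stopf("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Pairwise log2 fold change between two stages
#'
#' Per-gene difference of stage means on the log2 scale,
#' `mean(stageB) - mean(stageA)`, so `|value| >= 1` corresponds to a
#' fold change of at least 2.
#'
#' @param x log2-scale [ReceptivityExperiment-class].
#' @param stageA,stageB stage labels ("PR", "RE", "PO").
#' @return Named numeric vector of per-gene log2 fold changes.
#' @export
pairwiseLog2FC <- function(x, stageA, stageB) {
  if (exprScale(x) != "log2") stopf("pairwiseLog2FC expects log2 scale")
  st <- stageLabels(x)
  for (s in c(stageA, stageB)) {
    if (!any(st == s)) stopf("design error: no samples in stage %s", s)
  }
  Y <- exprValues(x)
  rowMeans(Y[, st == stageB, drop = FALSE]) -
    rowMeans(Y[, st == stageA, drop = FALSE])
}

#' Volcano classification
#'
#' Classifies genes as `up` / `down` / `ns` from a p-value and a log2 fold
#' change, with the conventional cutoffs p < 0.05 and fold change 2: `up`
#' when `p < pCut` and `lfc >= log2(fcCut)`, `down` when `p < pCut` and
#' `lfc <= -log2(fcCut)` (the fold-change boundary is inclusive), otherwise
#' `ns`.
#'
#' @param p per-gene p-values (the raw ANOVA p).
#' @param lfc per-gene log2 fold changes for one stage comparison.
#' @param pCut p-value cutoff (default 0.05).
#' @param fcCut fold-change cutoff on the natural scale (default 2; must
#'   exceed 1).
#' @return Character vector in `{"up", "down", "ns"}`.
#' @export
volcanoClassify <- function(p, lfc, pCut = 0.05, fcCut = 2) {
  if (fcCut <= 1) stopf("configuration error: fcCut must be > 1")
  lcut <- log2(fcCut)
  out <- rep("ns", length(p))
  out[p < pCut & lfc >= lcut] <- "up"
  out[p < pCut & lfc <= -lcut] <- "down"
  out
}

#' Tukey HSD pairwise p-values per gene
#'
#' Convenience wrapper extracting the three studentized-range post hoc
#' p-values (PR-RE, RE-PO, PR-PO) from [geneANOVA()] as a matrix.
#'
#' @param x log2-scale [ReceptivityExperiment-class].
#' @return Numeric matrix, genes by the three stage pairs.
#' @export
tukeyHSDPerGene <- function(x) {
  gs <- geneANOVA(x)
  m <- cbind(PR_RE = gs$tukey_PR_RE, RE_PO = gs$tukey_RE_PO,
             PR_PO = gs$tukey_PR_PO)
  rownames(m) <- rownames(gs)
  m
}
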