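## Marker-panel assembly: conjunctive Tukey filter, random-forest
## dual-importance ranking (mean decrease accuracy / mean decrease Gini),
## hub-gene augmentation.

#' All-pairwise Tukey filter
#'
#' Keeps genes whose Tukey HSD post hoc p-values are below `alpha` in all
#' three stage comparisons (PR-RE, RE-PO, PR-PO) — the genes that
#' distinguish every pair of receptivity stages. Degenerate genes are
#' excluded.
#'
#' @param genestats result of [geneANOVA()].
#' @param alpha per-comparison significance level (default 0.05).
#' @return Character vector of candidate gene ids.
#' @export
tukeyFilter <- function(genestats, alpha = 0.05) {
  need <- c("tukey_PR_RE", "tukey_RE_PO", "tukey_PR_PO")
  if (!all(need %in% colnames(genestats))) {
    stopf("dependency error: Tukey p-values missing from genestats")
  }
  if (alpha <= 0 || alpha > 1) stopf("alpha must lie in (0, 1]")
  ok <- genestats$tukey_PR_RE < alpha &
    genestats$tukey_RE_PO < alpha &
    genestats$tukey_PR_PO < alpha &
    is.na(genestats$degenerate)
  rownames(genestats)[which(ok)]
}

#' Random-forest dual importance ranking
#'
#' Fits a random forest of the candidate genes against the three stage
#' labels and reports both importance measures: mean decrease accuracy
#' (out-of-bag permutation importance) and mean decrease Gini (total
#' impurity decrease). Deterministic given the seed.
#'
#' @param x log2-scale [ReceptivityExperiment-class].
#' @param genes candidate gene ids.
#' @param ntree trees in the forest (default 500).
#' @param seed RNG seed.
#' @param scale report accuracy importance scaled by its standard error
#'   (the conventional display); `FALSE` gives the raw mean decrease.
#' @return data.frame `gene`, `mda`, `gini` sorted by mean decrease
#'   accuracy (descending), ties by Gini then gene id.
#' @export
rfImportanceRank <- function(x, genes, ntree = 500, seed = 1,
                             scale = TRUE) {
  stage <- factor(stageLabels(x), levels = STAGES)
  if (any(table(stage) < 2)) {
    stopf("design error: every stage needs >= 2 samples")
  }
  feat <- t(exprValues(x)[genes, , drop = FALSE])
  rf <- withSeed(seed, randomForest::randomForest(
    feat, stage, ntree = ntree, importance = TRUE
  ))
  imp <- randomForest::importance(rf, scale = scale)
  out <- data.frame(
    gene = rownames(imp),
    mda = unname(imp[, "MeanDecreaseAccuracy"]),
    gini = unname(imp[, "MeanDecreaseGini"]),
    stringsAsFactors = FALSE
  )
  out[order(-out$mda, -out$gini, out$gene), , drop = FALSE]
}

#' Assemble the marker panel
#'
#' Selects the top `panelSize` candidates honoring both forest importance
#' measures — a gene qualifies if it sits in the top `2 * panelSize` by
#' mean decrease Gini, and qualifying genes are taken in mean decrease
#' accuracy order (pure accuracy order fills any shortfall) — then appends
#' the non-grey module hub genes as additional markers. A hub already
#' selected is not double-counted (it keeps source `"tukey_rf"`).
#'
#' @param ranked importance table from [rfImportanceRank()].
#' @param hubs character vector of hub gene ids (grey-module hub excluded
#'   upstream).
#' @param panelSize target number of importance-selected markers
#'   (default 87).
#' @return data.frame `gene`, `mda`, `gini`, `source`
#'   (`"tukey_rf"`/`"hub"`), `rank`; ordered by mean decrease accuracy
#'   descending (hubs last in hub order).
#' @export
assemblePanel <- function(ranked, hubs = character(0), panelSize = 87) {
  if (panelSize < 1) stopf("panelSize must be >= 1")
  if (nrow(ranked) < panelSize) {
    warnf("only %d candidates for panelSize %d", nrow(ranked), panelSize)
    panelSize <- nrow(ranked)
  }
  giniTop <- ranked$gene[order(-ranked$gini, -ranked$mda, ranked$gene)]
  giniTop <- giniTop[seq_len(min(2 * panelSize, length(giniTop)))]
  sel <- ranked$gene[ranked$gene %in% giniTop]
  sel <- sel[seq_len(min(panelSize, length(sel)))]
  if (length(sel) < panelSize) {
    extra <- setdiff(ranked$gene, sel)
    sel <- c(sel, extra[seq_len(panelSize - length(sel))])
    sel <- ranked$gene[ranked$gene %in% sel] # restore importance order
  }
  panel <- data.frame(
    gene = sel, source = "tukey_rf", stringsAsFactors = FALSE
  )
  newHubs <- setdiff(hubs, sel)
  if (length(newHubs)) {
    panel <- rbind(panel, data.frame(gene = newHubs, source = "hub"))
  }
  idx <- match(panel$gene, ranked$gene)
  panel$mda <- ranked$mda[idx]
  panel$gini <- ranked$gini[idx]
  panel$rank <- seq_len(nrow(panel))
  panel[, c("gene", "mda", "gini", "source", "rank")]
}

#' One-call marker selection
#'
#' Tukey all-pairwise filter, forest dual-importance ranking, and panel
#' assembly with hub augmentation.
#'
#' @param x log2-scale [ReceptivityExperiment-class].
#' @param genestats result of [geneANOVA()].
#' @param modules optional [ModuleAssignment-class]; its non-grey hubs are
#'   appended to the panel.
#' @param alpha Tukey filter level.
#' @param panelSize importance-selected panel size (default 87).
#' @param ntree,seed forest settings.
#' @return The panel data.frame of [assemblePanel()].
#' @export
selectMarkers <- function(x, genestats, modules = NULL, alpha = 0.05,
                          panelSize = 87, ntree = 500, seed = 1) {
  cand <- tukeyFilter(genestats, alpha)
  if (!length(cand)) stopf("no genes pass the all-pairwise Tukey filter")
  ranked <- rfImportanceRank(x, cand, ntree = ntree, seed = seed)
  hubs <- character(0)
  if (!is.null(modules)) {
    h <- hubGenesOf(modules)
    hubs <- unname(h[setdiff(names(h), "grey")])
  }
  assemblePanel(ranked, hubs, panelSize)
}
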