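## Weighted co-expression network: soft-power adjacency, topological
## overlap, average-linkage module detection with a static tree cut, module
## eigengenes and stage correlation, and intramodular-connectivity hubs.

#' Network construction parameters
#'
#' @param beta soft-thresholding power applied to the correlation.
#' @param sign `"unsigned"` (`|r|^beta`) or `"signed"`
#'   (`((1+r)/2)^beta`).
#' @param cutHeight static tree-cut height on TOM dissimilarity `1 - omega`
#'   (see the vignette for why the default sits high on the dendrogram).
#' @param minModuleSize smallest cluster kept as a module; smaller clusters
#'   are relabelled `"grey"`.
#' @return A validated list of class `NetworkParams`.
#' @export
networkParams <- function(beta = 6, sign = c("unsigned", "signed"),
                          cutHeight = 0.9, minModuleSize = 30) {
  sign <- match.arg(sign)
  if (beta < 1) stopf("configuration error: beta must be >= 1")
  if (cutHeight <= 0 || cutHeight >= 1) {
    stopf("configuration error: cutHeight must lie in (0, 1)")
  }
  if (minModuleSize < 3) {
    stopf("configuration error: minModuleSize must be >= 3")
  }
  structure(list(beta = beta, sign = sign, cutHeight = cutHeight,
                 minModuleSize = as.integer(minModuleSize)),
            class = "NetworkParams")
}

#' ModuleAssignment: co-expression modules, eigengenes and hubs
#'
#' Result container of the co-expression step. Gene-to-module labels
#' partition the analyzed genes (unassigned genes are `"grey"`), module
#' labels are size-ranked color names; per-module unit-norm eigengenes,
#' module-stage Pearson correlations with p-values, per-gene intramodular
#' connectivity and the per-module hub gene (maximum kWithin,
#' lexicographic tie-break) are attached.
#'
#' @slot labels named character vector, gene -> module color.
#' @slot eigengenes numeric matrix, samples by modules (unit-norm columns).
#' @slot stageCor named numeric vector of module-stage correlations.
#' @slot stageCorP named numeric vector of the matching p-values.
#' @slot kWithin named numeric vector of intramodular connectivity.
#' @slot hubs named character vector, module -> hub gene id.
#' @slot params the `NetworkParams` list used.
#' @exportClass ModuleAssignment
setClass("ModuleAssignment", representation(
  labels = "character", eigengenes = "matrix", stageCor = "numeric",
  stageCorP = "numeric", kWithin = "numeric", hubs = "character",
  params = "list"
))

setValidity("ModuleAssignment", function(object) {
  msg <- character(0)
  sizes <- table(object@labels[object@labels != "grey"])
  minsz <- object@params$minModuleSize %||% 3
  if (length(sizes) && any(sizes < minsz)) {
    msg <- c(msg, "non-grey module below minModuleSize")
  }
  for (m in names(object@hubs)) {
    h <- object@hubs[[m]]
    if (!is.na(h) && !identical(unname(object@labels[h]), m)) {
      msg <- c(msg, sprintf("hub %s not a member of module %s", h, m))
    }
  }
  if (length(object@kWithin) && any(object@kWithin < -1e-12)) {
    msg <- c(msg, "negative intramodular connectivity")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ModuleAssignment", function(object) {
  sizes <- sort(table(object@labels), decreasing = TRUE)
  cat(sprintf("ModuleAssignment: %d genes, %d modules (+grey)\n",
              length(object@labels),
              sum(names(sizes) != "grey")))
  for (m in names(sizes)) {
    hub <- if (m %in% names(object@hubs)) object@hubs[[m]] else NA
    r <- if (m %in% names(object@stageCor)) {
      sprintf("%+.2f", object@stageCor[[m]])
    } else {
      "NA"
    }
    cat(sprintf("  %-10s %4d genes  hub=%s  stage r=%s\n",
                m, sizes[[m]], hub, r))
  }
})

#' @describeIn ModuleAssignment gene-to-module label vector.
#' @param x a `ModuleAssignment`.
#' @export
moduleLabels <- function(x) x@labels

#' @describeIn ModuleAssignment per-module hub gene ids.
#' @export
hubGenesOf <- function(x) x@hubs

#' @describeIn ModuleAssignment samples-by-modules eigengene matrix.
#' @export
moduleEigengenes <- function(x) x@eigengenes

#' @describeIn ModuleAssignment module-stage correlations and p-values.
#' @export
moduleStageCorOf <- function(x) {
  data.frame(module = names(x@stageCor), r = unname(x@stageCor),
             p = unname(x@stageCorP[names(x@stageCor)]))
}

#' Soft-thresholded co-expression adjacency
#'
#' Pearson-correlation adjacency `a_ij = |cor|^beta` (unsigned) or
#' `((1+cor)/2)^beta` (signed), with unit diagonal.
#'
#' @param x log2-scale [ReceptivityExperiment-class].
#' @param genes gene ids to include (default: all).
#' @param params a [networkParams()].
#' @return Symmetric adjacency matrix with entries in \[0, 1\].
#' @export
buildAdjacency <- function(x, genes = rownames(x),
                           params = networkParams()) {
  Y <- exprValues(x)[genes, , drop = FALSE]
  if (ncol(Y) < 3) stopf("need at least 3 samples")
  v <- apply(Y, 1, stats::var)
  if (any(v <= 0)) {
    stopf("zero-variance gene(s): %s",
          paste(head(genes[v <= 0], 3), collapse = ", "))
  }
  r <- cor(t(Y))
  a <- if (params$sign == "unsigned") {
    abs(r)^params$beta
  } else {
    ((1 + r) / 2)^params$beta
  }
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' \deqn{\omega_{ij} = \frac{l_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}}}
#' with \eqn{l_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}} and connectivity
#' \eqn{k_i = \sum_{u \ne i} a_{iu}}; \eqn{\omega_{ii} = 1}.
#'
#' @param a symmetric adjacency in \[0, 1\] with unit diagonal.
#' @return Symmetric TOM with entries in \[0, 1\] and unit diagonal.
#' @export
tomSimilarity <- function(a) {
  if (!isSymmetric(unname(a), tol = 1e-10)) {
    stopf("adjacency must be symmetric")
  }
  if (any(a < -1e-12) || any(a > 1 + 1e-12)) {
    stopf("adjacency entries must lie in [0, 1]")
  }
  k <- rowSums(a) - diag(a)
  ## (A^2)_ij includes u = i and u = j; subtract a_ii*a_ij + a_ij*a_jj
  d <- diag(a)
  l <- a %*% a - a * outer(d, rep(1, ncol(a))) - a * outer(rep(1, nrow(a)), d)
  kmin <- outer(k, k, pmin)
  w <- (l + a) / (kmin + 1 - a)
  diag(w) <- 1
  w[w < 0] <- 0
  w[w > 1] <- 1
  dimnames(w) <- dimnames(a)
  w
}

#' Detect co-expression modules
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity
#' `1 - omega`, cut statically at `cutHeight`; clusters smaller than
#' `minModuleSize` become `"grey"`. Module labels are size-ranked color
#' names (turquoise, blue, yellow, ...). Deterministic given its inputs and
#' invariant to gene order up to labels.
#'
#' @param tom TOM from [tomSimilarity()].
#' @param params a [networkParams()].
#' @return Named character vector gene -> module color.
#' @export
detectModules <- function(tom, params = networkParams()) {
  g <- rownames(tom)
  if (nrow(tom) < params$minModuleSize) {
    warnf("fewer genes than minModuleSize; all grey")
    return(structure(rep("grey", nrow(tom)), names = g))
  }
  hc <- hclust(as.dist(1 - tom), method = "average")
  cl <- cutree(hc, h = params$cutHeight)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= params$minModuleSize]
  labels <- rep("grey", length(cl))
  if (length(keep)) {
    keep <- keep[order(-sizes[keep], as.integer(keep))]
    cols <- moduleColorNames(length(keep))
    for (i in seq_along(keep)) labels[cl == keep[i]] <- cols[i]
  }
  structure(labels, names = g)
}

#' Module eigengenes and module-stage correlation
#'
#' The eigengene of a module is the first principal component of its
#' standardized member expression (unit norm over samples), sign-oriented so
#' that its mean correlation with the members is positive. The
#' module-stage relationship is the Pearson correlation of the eigengene
#' with the ordinal stage code PR = 1, RE = 2, PO = 3, with a
#' t-approximation p-value.
#'
#' @param x log2-scale [ReceptivityExperiment-class] with stage labels.
#' @param labels gene -> module vector from [detectModules()].
#' @return List with `eigengenes` (samples x modules, grey included),
#'   `stageCor`, `stageCorP`.
#' @export
moduleEigengeneStageCor <- function(x, labels) {
  Y <- exprValues(x)[names(labels), , drop = FALSE]
  stage <- stageLabels(x)
  code <- match(stage, STAGES) # ordinal 1/2/3
  mods <- unique(labels)
  eig <- matrix(NA_real_, ncol(Y), length(mods),
                dimnames = list(colnames(Y), mods))
  r <- p <- structure(rep(NA_real_, length(mods)), names = mods)
  for (m in mods) {
    Z <- Y[labels == m, , drop = FALSE]
    Z <- t(scale(t(Z)))
    e <- if (nrow(Z) == 1) as.numeric(Z) else svd(t(Z), nu = 1)$u[, 1]
    e <- e / sqrt(sum(e^2))
    if (mean(cor(e, t(Z))) < 0) e <- -e
    eig[, m] <- e
    if (!anyNA(code) && sd(code) > 0) {
      ct <- stats::cor.test(e, code)
      r[m] <- unname(ct$estimate)
      p[m] <- ct$p.value
    }
  }
  list(eigengenes = eig, stageCor = r, stageCorP = p)
}

#' Hub genes by intramodular connectivity
#'
#' `kWithin_i` is the summed adjacency of gene i to the other members of
#' its module; the hub is the member attaining the module maximum, ties
#' broken by the lexicographically smaller gene id. The grey (unassigned)
#' pseudo-module's hub is reported too but is excluded from marker panels
#' downstream.
#'
#' @param a adjacency over the analyzed genes.
#' @param labels gene -> module vector over the same genes.
#' @return List with `kWithin` (named per gene) and `hubs` (named per
#'   module).
#' @export
hubGenes <- function(a, labels) {
  stopifnot(identical(rownames(a), names(labels)))
  kWithin <- structure(rep(0, length(labels)), names = names(labels))
  mods <- unique(labels)
  hubs <- structure(character(length(mods)), names = mods)
  for (m in mods) {
    idx <- which(labels == m)
    if (!length(idx)) next
    sub <- a[idx, idx, drop = FALSE]
    kw <- rowSums(sub) - diag(sub)
    kWithin[idx] <- kw
    ord <- order(-kw, names(kw))
    hubs[m] <- names(kw)[ord[1]]
  }
  list(kWithin = kWithin, hubs = hubs)
}

#' Full co-expression analysis
#'
#' Runs adjacency, TOM, module detection, eigengene-stage correlation and
#' hub identification over a gene set and bundles the result.
#'
#' @param x log2-scale [ReceptivityExperiment-class].
#' @param genes genes to analyze (typically the stage-associated genes).
#' @param params a [networkParams()].
#' @return A [ModuleAssignment-class].
#' @export
coexpressionModules <- function(x, genes = rownames(x),
                                params = networkParams()) {
  a <- buildAdjacency(x, genes, params)
  w <- tomSimilarity(a)
  labels <- detectModules(w, params)
  es <- moduleEigengeneStageCor(x, labels)
  hk <- hubGenes(a, labels)
  new("ModuleAssignment", labels = labels, eigengenes = es$eigengenes,
      stageCor = es$stageCor, stageCorP = es$stageCorP,
      kWithin = hk$kWithin, hubs = hk$hubs, params = unclass(params))
}
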