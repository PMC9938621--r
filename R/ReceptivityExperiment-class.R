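#' ReceptivityExperiment: uterine-fluid expression with stage metadata
#'
#' `ReceptivityExperiment` extends
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' and is the common currency of the whole pipeline: a gene-by-sample
#' expression matrix on one of three declared scales (`"counts"`, `"fpkm"`,
#' `"log2"`) together with per-sample cohort metadata (patient id, sampling
#' day, receptivity stage, cycle protocol, pregnancy outcome) in `colData`
#' and per-gene transcript lengths (required on the counts scale) in
#' `rowData`.
#'
#' The scale tag governs validity: counts must be non-negative integers with
#' positive gene lengths attached; FPKM values must be finite and
#' non-negative; log2 values must be finite.
#'
#' @slot ... see [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class].
#'
#' @seealso [ReceptivityExperiment()] for the constructor, [fpkmNormalize()],
#'   [log2Transform()], [qcFilter()].
#' @name ReceptivityExperiment-class
#' @aliases ReceptivityExperiment-class
#' @exportClass ReceptivityExperiment
setClass("ReceptivityExperiment",
  contains = "SummarizedExperiment"
)

EXPR_SCALES <- c("counts", "fpkm", "log2")
META_COLS <- c("patient_id", "day", "stage", "protocol", "outcome")
DAY_LEVELS <- c("LH+5", "LH+7", "LH+9", "transfer-day")
STAGE_LEVELS <- c("PR", "RE", "PO", "unknown")
PROTOCOL_LEVELS <- c("natural", "HRT")
OUTCOME_LEVELS <- c("pregnant", "not_pregnant", "unknown")

validReceptivityExperiment <- function(object) {
  msg <- character(0)
  sc <- S4Vectors::metadata(object)$scale
  if (is.null(sc) || !sc %in% EXPR_SCALES) {
    msg <- c(msg, sprintf(
      "scale must be one of %s", paste(EXPR_SCALES, collapse = "/")
    ))
  }
  v <- SummarizedExperiment::assay(object, "expr")
  gid <- rownames(object)
  sid <- colnames(object)
  if (is.null(gid) || anyDuplicated(gid)) {
    msg <- c(msg, "gene ids must be present and unique")
  }
  if (is.null(sid) || anyDuplicated(sid)) {
    msg <- c(msg, "sample ids must be present and unique")
  }
  cd <- SummarizedExperiment::colData(object)
  missing_cols <- setdiff(META_COLS, colnames(cd))
  if (length(missing_cols)) {
    msg <- c(msg, paste("missing metadata columns:",
                        paste(missing_cols, collapse = ", ")))
  } else {
    bad <- list(
      day = setdiff(unique(cd$day), DAY_LEVELS),
      stage = setdiff(unique(cd$stage), STAGE_LEVELS),
      protocol = setdiff(unique(cd$protocol), PROTOCOL_LEVELS),
      outcome = setdiff(unique(cd$outcome), OUTCOME_LEVELS)
    )
    for (f in names(bad)) {
      if (length(bad[[f]])) {
        msg <- c(msg, sprintf("invalid %s label(s): %s", f,
                              paste(bad[[f]], collapse = ", ")))
      }
    }
  }
  if (length(v) && isTRUE(sc %in% EXPR_SCALES)) {
    if (sc == "counts") {
      if (any(!is.finite(v)) || any(v < 0) ||
          any(abs(v - round(v)) > 1e-8)) {
        msg <- c(msg, "counts scale requires non-negative integer values")
      }
      len <- SummarizedExperiment::rowData(object)$gene_length
      if (is.null(len) || any(!is.finite(len)) || any(len <= 0)) {
        msg <- c(msg,
          "counts scale requires positive gene_length in rowData")
      }
    } else if (sc == "fpkm") {
      if (any(!is.finite(v)) || any(v < 0)) {
        msg <- c(msg, "fpkm scale requires finite non-negative values")
      }
    } else if (any(!is.finite(v))) {
      msg <- c(msg, "log2 scale requires finite values")
    }
  }
  if (length(msg)) msg else TRUE
}

setValidity("ReceptivityExperiment", validReceptivityExperiment)

#' Construct a ReceptivityExperiment
#'
#' @param values numeric gene-by-sample matrix with rownames (gene ids) and
#'   colnames (sample ids).
#' @param scale one of `"counts"`, `"fpkm"`, `"log2"`; tags the unit of
#'   `values` and is checked by the class validity method.
#' @param sampleMeta data.frame with one row per sample, columns
#'   `sample_id`, `patient_id`, `day`, `stage`, `protocol`, `outcome`.
#'   Rows are matched to matrix columns by `sample_id` and every sample must
#'   appear on both sides.
#' @param geneLengths numeric vector of transcript lengths in bp, parallel
#'   to the rows of `values` (required when `scale = "counts"`).
#' @return A [ReceptivityExperiment-class] object.
#' @examples
#' m <- matrix(rpois(6, 50), 3, 2,
#'             dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' meta <- data.frame(sample_id = c("s1", "s2"), patient_id = c("p1", "p1"),
#'                    day = c("LH+5", "LH+7"), stage = c("PR", "RE"),
#'                    protocol = "natural", outcome = "unknown")
#' re <- ReceptivityExperiment(m, "counts", meta, geneLengths = c(1e3, 2e3, 5e2))
#' exprScale(re)
#' @export
ReceptivityExperiment <- function(values, scale, sampleMeta,
                                  geneLengths = NULL) {
  values <- as.matrix(values)
  scale <- match.arg(scale, EXPR_SCALES)
  if (!is.data.frame(sampleMeta) || !"sample_id" %in% colnames(sampleMeta)) {
    stopf("sampleMeta must be a data.frame with a sample_id column")
  }
  sid <- colnames(values)
  if (is.null(sid)) stopf("values must carry sample ids as colnames")
  extra <- setdiff(sid, sampleMeta$sample_id)
  orphan <- setdiff(sampleMeta$sample_id, sid)
  if (length(extra) || length(orphan)) {
    stopf(
      "sample ids in matrix and metadata disagree (matrix-only: %s; meta-only: %s)",
      paste(head(extra, 3), collapse = ","),
      paste(head(orphan, 3), collapse = ",")
    )
  }
  sampleMeta <- sampleMeta[match(sid, sampleMeta$sample_id), , drop = FALSE]
  for (f in setdiff(META_COLS, colnames(sampleMeta))) {
    sampleMeta[[f]] <- "unknown"
  }
  cd <- S4Vectors::DataFrame(
    sampleMeta[, META_COLS, drop = FALSE], row.names = sid
  )
  rd <- S4Vectors::DataFrame(row.names = rownames(values))
  if (!is.null(geneLengths)) {
    if (length(geneLengths) != nrow(values)) {
      stopf("geneLengths must have one entry per gene")
    }
    rd$gene_length <- as.numeric(geneLengths)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = values), colData = cd, rowData = rd,
    metadata = list(scale = scale)
  )
  new("ReceptivityExperiment", se)
}

#' @describeIn ReceptivityExperiment declared expression scale
#'   (`"counts"`, `"fpkm"` or `"log2"`).
#' @param x a `ReceptivityExperiment`.
#' @export
exprScale <- function(x) S4Vectors::metadata(x)$scale

#' @describeIn ReceptivityExperiment the gene-by-sample expression matrix.
#' @export
exprValues <- function(x) SummarizedExperiment::assay(x, "expr")

#' @describeIn ReceptivityExperiment per-sample stage labels (PR/RE/PO/unknown).
#' @export
stageLabels <- function(x) {
  as.character(SummarizedExperiment::colData(x)$stage)
}

#' @describeIn ReceptivityExperiment per-sample patient identifiers.
#' @export
patientIds <- function(x) {
  as.character(SummarizedExperiment::colData(x)$patient_id)
}

#' @describeIn ReceptivityExperiment sample metadata as a base data.frame.
#' @export
sampleInfo <- function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
}

#' @describeIn ReceptivityExperiment gene lengths in bp (or NULL).
#' @export
geneLengths <- function(x) SummarizedExperiment::rowData(x)$gene_length

setMethod("show", "ReceptivityExperiment", function(object) {
  cat(sprintf(
    "ReceptivityExperiment: %d genes x %d samples [%s scale]\n",
    nrow(object), ncol(object), exprScale(object)
  ))
  st <- table(factor(stageLabels(object), levels = STAGE_LEVELS))
  cat("  stages:", paste(sprintf("%s=%d", names(st), st), collapse = " "),
      "\n")
  cat(sprintf("  patients: %d\n", length(unique(patientIds(object)))))
})
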