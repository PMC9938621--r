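## Matrix / metadata I-O, FPKM normalization, log2 transform and library QC.

#' Read an expression dataset from TSV files
#'
#' Expression is a tab-separated gene-by-sample matrix whose first column
#' holds gene ids and whose header row holds sample ids; metadata is a
#' tab-separated table with a `sample_id` column plus the cohort fields.
#'
#' @param exprPath path to the expression TSV.
#' @param metaPath path to the sample metadata TSV.
#' @param scale declared unit of the matrix: `"counts"`, `"fpkm"` or
#'   `"log2"`.
#' @param lengthsPath optional TSV with columns `gene_id`, `length` (bp);
#'   required for the counts scale.
#' @return A [ReceptivityExperiment-class].
#' @export
readDataset <- function(exprPath, metaPath, scale, lengthsPath = NULL) {
  for (p in c(exprPath, metaPath, lengthsPath)) {
    if (!file.exists(p)) stopf("file not found: %s", p)
  }
  expr <- data.table::fread(exprPath, sep = "\t", header = TRUE,
                            data.table = FALSE)
  if (ncol(expr) < 2) stopf("%s: expected gene id column plus samples",
                            exprPath)
  gid <- as.character(expr[[1]])
  m <- as.matrix(expr[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(expr[-1], is.numeric, logical(1)))[1]
    stopf("%s: non-numeric values in column '%s'", exprPath,
          colnames(expr)[-1][bad])
  }
  storage.mode(m) <- "double"
  rownames(m) <- gid
  if (anyDuplicated(gid)) {
    stopf("%s: duplicate gene id '%s'", exprPath, gid[duplicated(gid)][1])
  }
  meta <- data.table::fread(metaPath, sep = "\t", header = TRUE,
                            data.table = FALSE, colClasses = "character")
  lens <- NULL
  if (!is.null(lengthsPath)) {
    lt <- data.table::fread(lengthsPath, sep = "\t", header = TRUE,
                            data.table = FALSE)
    idx <- match(gid, as.character(lt[[1]]))
    if (anyNA(idx)) stopf("%s: missing length for gene '%s'", lengthsPath,
                          gid[which(is.na(idx))[1]])
    lens <- as.numeric(lt[[2]])[idx]
  }
  ReceptivityExperiment(m, scale = scale, sampleMeta = meta,
                        geneLengths = lens)
}

#' Write an expression dataset to a directory
#'
#' Writes `expr.tsv` (gene-by-sample matrix, full double precision so a
#' read-back reproduces the values exactly), `meta.tsv`, and — on the counts
#' scale — `lengths.tsv`. Output is byte-deterministic for identical input.
#'
#' @param x a [ReceptivityExperiment-class].
#' @param dir output directory (created if absent).
#' @return Invisibly, the named vector of written paths.
#' @export
writeDataset <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  exprPath <- file.path(dir, "expr.tsv")
  metaPath <- file.path(dir, "meta.tsv")
  writeMatrixTSV(exprValues(x), exprPath, idCol = "gene_id")
  meta <- cbind(sample_id = colnames(x), sampleInfo(x))
  utils::write.table(meta, metaPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(expr = exprPath, meta = metaPath)
  if (exprScale(x) == "counts") {
    lenPath <- file.path(dir, "lengths.tsv")
    utils::write.table(
      data.frame(gene_id = rownames(x), length = geneLengths(x)),
      lenPath, sep = "\t", quote = FALSE, row.names = FALSE
    )
    paths <- c(paths, lengths = lenPath)
  }
  invisible(paths)
}

## %.17g round-trips doubles exactly through text
writeMatrixTSV <- function(m, path, idCol = "gene_id") {
  txt <- matrix(sprintf("%.17g", m), nrow = nrow(m))
  out <- cbind(rownames(m), txt)
  colnames(out) <- c(idCol, colnames(m))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' FPKM-normalize a count dataset
#'
#' Fragments per kilobase of transcript per million mapped fragments:
#' \deqn{FPKM_{gs} = count_{gs} \cdot 10^9 / (N_s \cdot L_g)} with library
#' size \eqn{N_s} taken as the column sum of the count matrix and \eqn{L_g}
#' the transcript length in bp.
#'
#' @param x a counts-scale [ReceptivityExperiment-class] with gene lengths.
#' @return An fpkm-scale `ReceptivityExperiment`.
#' @export
fpkmNormalize <- function(x) {
  if (exprScale(x) != "counts") stopf("fpkmNormalize expects counts scale")
  len <- geneLengths(x)
  if (is.null(len)) stopf("gene lengths are required for FPKM")
  counts <- exprValues(x)
  libsize <- colSums(counts)
  if (any(libsize <= 0)) {
    stopf("zero library size in sample(s): %s",
          paste(colnames(counts)[libsize <= 0], collapse = ", "))
  }
  f <- sweep(counts * 1e9 / len, 2, libsize, "/")
  out <- ReceptivityExperiment(f, "fpkm", cbind(sample_id = colnames(x),
                                                sampleInfo(x)))
  S4Vectors::metadata(out)$library_size <- libsize
  out
}

#' Log2-transform an FPKM dataset
#'
#' Applies `log2(FPKM + pseudocount)` cell-wise. With the default
#' pseudocount of 1, zero FPKM maps to 0 and the transform is invertible as
#' `2^y - pseudocount`.
#'
#' @param x an fpkm-scale [ReceptivityExperiment-class].
#' @param pseudocount positive offset added before the logarithm.
#' @return A log2-scale `ReceptivityExperiment`.
#' @export
log2Transform <- function(x, pseudocount = 1) {
  if (exprScale(x) != "fpkm") stopf("log2Transform expects fpkm scale")
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    stopf("pseudocount must be > 0")
  }
  v <- exprValues(x)
  if (any(v < 0)) stopf("negative FPKM values")
  out <- ReceptivityExperiment(log2(v + pseudocount), "log2",
                               cbind(sample_id = colnames(x), sampleInfo(x)))
  S4Vectors::metadata(out)$pseudocount <- pseudocount
  out
}

#' Library quality-control gate
#'
#' Flags samples with too few detected genes (expression value > 0) or too
#' few total fragments and removes them from the dataset. The gate is
#' idempotent: filtering an already filtered dataset changes nothing.
#'
#' @param x a [ReceptivityExperiment-class] (any scale; `minTotal` is only
#'   meaningful on the counts scale and is ignored otherwise).
#' @param minGenesDetected minimum number of genes with value > 0.
#' @param minTotal minimum column sum (counts scale only).
#' @return A list with `dataset` (passing samples) and `report`, a
#'   data.frame with per-sample totals, detected-gene counts, pass flag and
#'   failure reason.
#' @export
qcFilter <- function(x, minGenesDetected = 5000, minTotal = 1e5) {
  if (minGenesDetected < 0 || minTotal < 0) stopf("thresholds must be >= 0")
  v <- exprValues(x)
  detected <- colSums(v > 0)
  total <- colSums(v)
  reason <- rep(NA_character_, ncol(v))
  fail_genes <- detected < minGenesDetected
  fail_total <- exprScale(x) == "counts" & total < minTotal
  reason[fail_total] <- "total_fragments"
  reason[fail_genes] <- "genes_detected"
  pass <- !(fail_genes | fail_total)
  report <- data.frame(
    sample_id = colnames(v), total = unname(total),
    genes_detected = unname(detected), pass = unname(pass),
    reason = unname(reason), stringsAsFactors = FALSE
  )
  if (!any(pass)) stopf("empty dataset: all %d samples fail QC", ncol(v))
  list(dataset = x[, pass], report = report)
}
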