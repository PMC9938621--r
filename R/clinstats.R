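## Clinical association of WOI calls with pregnancy outcomes: exact 2x2
## inference, cohort rate summaries, and a generic hypergeometric
## over-representation test.

#' Fisher's exact test for a 2x2 table
#'
#' Exact conditional inference on a 2x2 contingency table. The two-sided
#' p-value follows the sum-of-smaller-probabilities convention: with both
#' margins fixed, it sums the hypergeometric probabilities of every table
#' whose probability does not exceed (up to a 1e-7 relative tolerance) that
#' of the observed table. The odds ratio is the sample ratio
#' \eqn{(a d)/(b c)}, reported as `Inf`, `0` or `NaN` (undefined) under the
#' corresponding zero-cell patterns with an explanatory flag.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return List: `p_value`, `odds_ratio`, `or_flag` (`"finite"`,
#'   `"infinite"`, `"zero"`, `"undefined"`).
#' @examples
#' fisherExact2x2(matrix(c(14, 0, 4, 3), 2)) # p = 35/1330
#' @export
fisherExact2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2)) stopf("expected a 2x2 table")
  if (any(tab < 0) || any(abs(tab - round(tab)) > 1e-9)) {
    stopf("validation error: cells must be non-negative integers")
  }
  tab <- round(tab)
  m <- sum(tab[1, ]) # row 1 margin
  n <- sum(tab[2, ])
  kk <- sum(tab[, 1]) # column 1 margin
  if (m + n == 0) stopf("at least one margin must be positive")
  support <- max(0, kk - n):min(kk, m)
  dens <- dhyper(support, m, n, kk)
  dobs <- dhyper(tab[1, 1], m, n, kk)
  p <- sum(dens[dens <= dobs * (1 + 1e-7)])
  p <- min(1, p)
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  or <- (a * d) / (b * c)
  flag <- if (b * c == 0 && a * d == 0) {
    "undefined"
  } else if (b * c == 0) {
    "infinite"
  } else if (a * d == 0) {
    "zero"
  } else {
    "finite"
  }
  list(p_value = p, odds_ratio = or, or_flag = flag)
}

#' Associate WOI calls with pregnancy outcomes
#'
#' Builds the normal-versus-displaced WOI outcome table from a prediction
#' report: a normal WOI is an RE call, a displaced WOI pools PR and PO
#' calls; samples with `detection_failed` or `indeterminate` status are
#' excluded from the table (and listed with reasons). Row-wise success
#' rates and the two-sided Fisher exact p are attached. Overall cohort
#' rates use the full enrolled denominator, including excluded samples.
#'
#' @param predictions a prediction report from [predictReceptivity()].
#' @param outcomes named character vector (`"pregnant"` /
#'   `"not_pregnant"`) per sample id; taken from `predictions$outcome` if
#'   present.
#' @return List of class `OutcomeTable`: `table` (2x2 counts: rows
#'   normal/displaced WOI, columns pregnant/not pregnant), `rates` (per-row
#'   success rates), `fisher` (p, odds ratio, flag), `overall_rate`
#'   (successes over all enrolled samples), `excluded` (data.frame with
#'   reasons), `n_enrolled`.
#' @export
outcomeAssociation <- function(predictions, outcomes = NULL) {
  if (is.null(outcomes)) outcomes <- structure(predictions$outcome,
                                               names = predictions$sample_id)
  analyzable <- !predictions$woi %in% c("detection_failed", "indeterminate")
  excluded <- data.frame(
    sample_id = predictions$sample_id[!analyzable],
    reason = predictions$woi[!analyzable], stringsAsFactors = FALSE
  )
  keep <- predictions[analyzable, , drop = FALSE]
  if (!nrow(keep)) stopf("no analyzable samples (all no-call or failed)")
  out <- outcomes[keep$sample_id]
  if (anyNA(out) || any(!out %in% c("pregnant", "not_pregnant"))) {
    bad <- keep$sample_id[is.na(out) |
                            !out %in% c("pregnant", "not_pregnant")][1]
    stopf("data error: missing/invalid outcome for sample %s", bad)
  }
  woiRow <- ifelse(keep$woi == "normal", "normal_WOI", "displaced_WOI")
  tab <- table(factor(woiRow, c("normal_WOI", "displaced_WOI")),
               factor(out, c("pregnant", "not_pregnant")))
  tab <- unclass(tab)
  fisher <- fisherExact2x2(tab)
  res <- list(
    table = tab,
    rates = tab[, "pregnant"] / pmax(rowSums(tab), 1),
    fisher = fisher,
    overall_rate = sum(tab[, "pregnant"]) / nrow(predictions),
    excluded = excluded,
    n_enrolled = nrow(predictions)
  )
  class(res) <- "OutcomeTable"
  res
}

#' @export
print.OutcomeTable <- function(x, ...) {
  print(x$table)
  cat(sprintf(
    "normal-WOI rate %.1f%%, displaced-WOI rate %.1f%%, overall %.1f%% (n=%d enrolled)\n",
    100 * x$rates[["normal_WOI"]], 100 * x$rates[["displaced_WOI"]],
    100 * x$overall_rate, x$n_enrolled
  ))
  cat(sprintf("Fisher exact two-sided p = %.4g, OR = %.3g (%s)\n",
              x$fisher$p_value, x$fisher$odds_ratio, x$fisher$or_flag))
  if (nrow(x$excluded)) {
    cat("excluded:", paste(sprintf("%s (%s)", x$excluded$sample_id,
                                   x$excluded$reason), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Hypergeometric over-representation analysis
#'
#' For each annotation set, tests whether the query gene list overlaps it
#' more than expected by chance given the background universe: upper-tail
#' hypergeometric p \eqn{P(X \ge k)} with `N` background genes, `K`
#' annotated, `n` in the query and `k` in the overlap; fold enrichment is
#' \eqn{(k/n)/(K/N)}; BH adjustment across sets.
#'
#' @param query character vector of query genes (subset of background).
#' @param sets named list of annotation gene sets (subsets of background).
#' @param background character vector, the gene universe.
#' @return data.frame `set`, `size`, `overlap`, `fold_enrichment`,
#'   `p_value`, `fdr`.
#' @export
hypergeometricORA <- function(query, sets, background) {
  if (!length(background)) stopf("validation error: empty background")
  background <- unique(background)
  query <- unique(query)
  if (length(setdiff(query, background))) {
    stopf("query genes missing from background")
  }
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    set <- intersect(unique(sets[[nm]]), background)
    K <- length(set)
    k <- length(intersect(query, set))
    fold <- if (k == 0 || K == 0) 0 else (k / n) / (K / N)
    p <- if (k == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, size = K, overlap = k, fold_enrichment = fold,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bhFDR(out$p_value)
  out[order(out$p_value, out$set), , drop = FALSE]
}
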