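#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats cor pf ptukey phyper dhyper rnorm runif rnbinom
#'   p.adjust hclust cutree as.dist prcomp pt sd quantile predict rbinom
#' @importFrom utils head
NULL

## canonical stage order used everywhere downstream (class order of the
## classifier, columns of probability matrices, Tukey pair naming)
STAGES <- c("PR", "RE", "PO")
STAGE_DAYS <- c(PR = "LH+5", RE = "LH+7", PO = "LH+9")
STAGE_PAIRS <- list(c("PR", "RE"), c("RE", "PO"), c("PR", "PO"))

## unit-variance centered ordinal code for PR/RE/PO under a balanced design
stageCode <- function(stage) {
  code <- c(PR = -1, RE = 0, PO = 1) * sqrt(3 / 2)
  unname(code[as.character(stage)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## evaluate `expr` under `seed` without disturbing the caller's RNG state
withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## size-ranked module label palette (largest module first, "grey" reserved
## for unassigned genes)
MODULE_COLORS <- c(
  "turquoise", "blue", "yellow", "brown", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan", "midnightblue"
)

moduleColorNames <- function(n) {
  if (n <= length(MODULE_COLORS)) return(MODULE_COLORS[seq_len(n)])
  c(MODULE_COLORS, paste0("module", seq_len(n - length(MODULE_COLORS))))
}
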