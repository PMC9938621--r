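# Shared fixtures: tiny hand-built datasets and scaled simulation configs.

STAGES3 <- c("PR", "RE", "PO")

# dataset with given per-stage sample counts and a gene x sample value matrix
makeLog2Dataset <- function(values, nPerStage = NULL, stage = NULL,
                            patient = NULL) {
  if (is.null(stage)) stage <- rep(STAGES3, times = nPerStage)
  n <- length(stage)
  if (is.null(patient)) patient <- paste0("p", seq_len(n))
  if (is.null(dim(values))) values <- matrix(values, nrow = 1)
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  }
  colnames(values) <- paste0("s", seq_len(n))
  meta <- data.frame(
    sample_id = colnames(values), patient_id = patient,
    day = c(PR = "LH+5", RE = "LH+7", PO = "LH+9")[stage],
    stage = stage, protocol = "natural", outcome = "unknown",
    stringsAsFactors = FALSE
  )
  ReceptivityExperiment(values, "log2", meta)
}

# one balanced dataset per stage-mean vector: gene g has means mu[[g]]
makeStageMeansDataset <- function(mus, n = 5, sd = 0, seed = 1) {
  withr::with_seed(seed, {
    rows <- lapply(mus, function(mu) {
      rep(mu, each = n) + rnorm(3 * n, 0, sd)
    })
    values <- do.call(rbind, rows)
    makeLog2Dataset(values, nPerStage = rep(n, 3))
  })
}

# small simulation config used across tests (fast but same structure as
# the full design)
testSimConfig <- function(seed = 1, ...) {
  args <- list(nGenes = 600, nDEG = 80, nPatients = 16,
               moduleSizes = c(40, 30), validationN = 10, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simulationConfig, args)
}

# brute-force one-way ANOVA oracle via lm/anova for a single gene
anovaOracle <- function(y, stage) {
  fit <- stats::aov(y ~ factor(stage, levels = STAGES3))
  s <- summary(fit)[[1]]
  list(ss_stage = s[1, "Sum Sq"], ss_error = s[2, "Sum Sq"],
       F = s[1, "F value"], p = s[1, "Pr(>F)"])
}

# reference BH step-up oracle, written independently of stats::p.adjust
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / (m:1)))[ro]
}

# triple-loop TOM oracle
tomOracle <- function(a) {
  n <- nrow(a)
  w <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      }
      ki <- sum(a[i, -i])
      kj <- sum(a[j, -j])
      w[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
    }
  }
  dimnames(w) <- dimnames(a)
  w
}

# adjusted Rand index between two label vectors
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}
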