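# In-code fixtures and independent oracles shared across the suite.

# GrowthExpressionSet from a bare matrix; condition/growth defaults settable.
makeGes <- function(values, conditionId = colnames(values),
                    growth = seq_len(ncol(values)),
                    alignment = NA_real_, isAle = FALSE, isMut = FALSE,
                    scaleTag = "log_tpm") {
  if (is.null(colnames(values)))
    colnames(values) <- paste0("e", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  meta <- data.frame(experiment_id = colnames(values),
                     condition_id = conditionId,
                     growth_rate = growth,
                     alignment_score = alignment,
                     is_ale = isAle,
                     is_mutant_or_ko = isMut)
  GrowthExpressionSet(values, meta, scaleTag = scaleTag)
}

# Weight table where every codon has the same weight.
flatWeightTable <- function(w = 1) {
  gc <- Biostrings::GENETIC_CODE
  sense <- sort(names(gc)[gc != "*"])
  new("CodonWeightTable", metricName = "flat",
      weights = stats::setNames(rep(w, length(sense)), sense),
      provenance = "test fixture")
}

# Weight table with given weights for given codons (rest filled with 1).
customWeightTable <- function(codons, weights) {
  wt <- flatWeightTable(1)
  w <- codonWeights(wt)
  w[codons] <- weights
  new("CodonWeightTable", metricName = "custom", weights = w,
      provenance = "test fixture")
}

# --- independent oracles (direct formulas, no shared code paths) ---

# geometric mean by direct product-then-root (safe only for short inputs)
prodRootOracle <- function(w) prod(w)^(1 / length(w))

pearsonOracle <- function(x, y) {
  dx <- x - sum(x) / length(x)
  dy <- y - sum(y) / length(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# OLS via explicit normal equations solve
normalEqOracle <- function(y, X) {
  X1 <- cbind(1, as.matrix(X))
  beta <- solve(t(X1) %*% X1, t(X1) %*% y)
  res <- y - X1 %*% beta
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - sum(res^2) / sst
  n <- length(y); p <- ncol(X1) - 1
  list(beta = as.vector(beta), r2 = r2,
       adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p - 1))
}

# Spearman rho by the classical Sum-d^2 formula (valid without ties)
spearmanOracle <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# hypergeometric upper tail by complete enumeration of query subsets
hyperEnumOracle <- function(N, K, n, k) {
  hits <- seq_len(K)
  sets <- utils::combn(N, n)
  mean(colSums(matrix(sets %in% hits, nrow = n)) >= k)
}

# BH step-up by direct definition
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  q[o] <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(q, 1)
}
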