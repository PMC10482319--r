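#' All-by-all condition R-squared matrix
#'
#' Squared Pearson correlation between every pair of expression columns over
#' all genes. Constant columns have undefined correlations; their entries are
#' `NA` and their ids are attached as `attr(x, "undefined_columns")` rather
#' than being silently zeroed. The diagonal is 1 for non-constant columns.
#'
#' @param ges a [GrowthExpressionSet-class] (or plain numeric matrix) with at
#'   least 2 columns.
#' @return Symmetric numeric matrix of R-squared values in \\[0, 1\\].
#' @export
pairwiseConditionR2 <- function(ges) {
  v <- if (is(ges, "GrowthExpressionSet")) exprValues(ges) else as.matrix(ges)
  if (ncol(v) < 2) stop("need at least 2 columns")
  const <- apply(v, 2, function(x) stats::var(x) == 0)
  r <- suppressWarnings(stats::cor(v))
  r2 <- r^2
  diag(r2)[!const] <- 1
  r2[const, ] <- NA_real_
  r2[, const] <- NA_real_
  attr(r2, "undefined_columns") <- colnames(v)[const]
  r2
}

#' Growth Correlation Index of a single gene
#'
#' The Growth Correlation Index (GCI) of a gene is the Pearson correlation
#' coefficient between its expression level and the growth rate across
#' conditions. Genes with positive GCI are upregulated during rapid growth;
#' negative GCI marks genes upregulated during slow growth. With zero
#' variance in either vector the correlation is undefined and `NA` is
#' returned (not 0, which would assert an absence of association that was
#' never measured).
#'
#' @param expr numeric vector of (log) expression over conditions.
#' @param growth numeric vector of growth rates (1/h), same length >= 3.
#' @return Pearson r in \\[-1, 1\\], or `NA` if undefined.
#' @examples
#' gci(c(1, 2, 4), c(1, 2, 3))
#' @export
gci <- function(expr, growth) {
  if (length(expr) != length(growth))
    stop("expr and growth must have equal length")
  if (length(expr) < 3) stop("GCI needs at least 3 conditions")
  if (stats::var(expr) == 0 || stats::var(growth) == 0) return(NA_real_)
  stats::cor(expr, growth)
}

#' Per-gene GCI over a whole matrix
#'
#' Vectorized [gci()] across the rows of a replicate-averaged matrix against
#' its growth rates. Genes with zero expression variance get `NA`; the count
#' of such genes is attached as `attr(x, "n_undefined")`.
#'
#' @param ges a [GrowthExpressionSet-class], one column per condition.
#' @return Named numeric vector of GCI values (NA where undefined).
#' @export
computeGci <- function(ges) {
  stopifnot(is(ges, "GrowthExpressionSet"))
  g <- unname(growthRates(ges))
  if (ncol(ges) < 3) stop("GCI needs at least 3 conditions")
  if (any(is.na(g))) stop("growth rates must be known; run filterConditions")
  out <- .rowPearson(exprValues(ges), g)
  attr(out, "n_undefined") <- sum(is.na(out))
  out
}

# Pearson r of each matrix row against vector y, NA for zero-variance rows.
.rowPearson <- function(m, y) {
  yc <- y - mean(y)
  sy <- sqrt(sum(yc^2))
  mc <- m - rowMeans(m)
  sx <- sqrt(rowSums(mc^2))
  r <- as.vector(mc %*% yc) / (sx * sy)
  r[sx == 0 | sy == 0] <- NA_real_
  stats::setNames(r, rownames(m))
}

#' Permutation null for the GCI
#'
#' For each gene independently, shuffles the pairing between expression
#' values and growth rates (a uniform random permutation) and computes one
#' permuted GCI. This gives the null distribution of GCI under no
#' association while preserving each gene's marginal expression distribution.
#' Deterministic given `seed`. With only 2 conditions any pairing is
#' perfectly linear, so permuted r is always +1 or -1; at least 3 conditions
#' are required, as for [gci()].
#'
#' @param ges a [GrowthExpressionSet-class], one column per condition.
#' @param seed integer seed.
#' @return Named numeric vector of permuted GCI values (NA where undefined).
#' @export
gciPermutationNull <- function(ges, seed) {
  stopifnot(is(ges, "GrowthExpressionSet"))
  g <- unname(growthRates(ges))
  if (ncol(ges) < 3) stop("GCI needs at least 3 conditions")
  rng <- .seedScope(seed)
  on.exit(rng$restore(), add = TRUE)
  n <- ncol(ges)
  m <- exprValues(ges)
  perm <- t(vapply(seq_len(nrow(m)), function(i) m[i, sample.int(n)],
                   numeric(n)))
  rownames(perm) <- rownames(m)
  out <- .rowPearson(perm, g)
  attr(out, "n_undefined") <- sum(is.na(out))
  out
}

#' Summarize observed GCI against its permutation null
#'
#' Reports the null mean and standard deviation and the fraction of observed
#' GCI values falling outside the null mean +/- 2 sd band. This is a
#' descriptive comparison; no significance claim is attached.
#'
#' @param observed numeric vector of observed GCI values (NA dropped).
#' @param permuted numeric vector of permuted GCI values (NA dropped).
#' @return List with `null_mean`, `null_sd`, `frac_outside_2sd`, `n_observed`,
#'   `n_null`.
#' @export
permutationNullSummary <- function(observed, permuted) {
  observed <- observed[!is.na(observed)]
  permuted <- permuted[!is.na(permuted)]
  mu <- mean(permuted); sd0 <- stats::sd(permuted)
  list(null_mean = mu, null_sd = sd0,
       frac_outside_2sd = mean(observed < mu - 2 * sd0 |
                               observed > mu + 2 * sd0),
       n_observed = length(observed), n_null = length(permuted))
}

#' Per-condition expression-to-CUB fit strength
#'
#' For each condition, the R-squared of an ordinary least-squares fit of the
#' CUB score on that condition's expression column (for a simple regression
#' this equals the squared Pearson correlation). Genes with undefined CUB are
#' excluded pairwise; a condition with fewer than 3 usable genes gets `NA`.
#'
#' @param ges a [GrowthExpressionSet-class], one column per condition.
#' @param cub named numeric vector of CUB scores; matched to `rownames(ges)`.
#' @return data.frame with columns `condition_id`, `growth_rate`,
#'   `expr_cub_r2`.
#' @export
perConditionCubFit <- function(ges, cub) {
  stopifnot(is(ges, "GrowthExpressionSet"))
  cubv <- cub[rownames(ges)]
  usable <- !is.na(cubv)
  if (sum(usable) < 3)
    stop("CUB must be defined for at least 3 genes present in the matrix")
  v <- exprValues(ges)[usable, , drop = FALSE]
  cc <- cubv[usable]
  r <- .rowPearson(t(v), cc)
  r2 <- unname(r)^2
  # a constant expression column (or constant CUB) leaves the fit undefined
  data.frame(condition_id = as.character(conditionIds(ges)),
             growth_rate = unname(growthRates(ges)),
             expr_cub_r2 = r2,
             row.names = NULL)
}

#' Spearman correlation between growth rate and fit strength
#'
#' Rank correlation (with two-sided p-value) between per-condition growth
#' rates and the expression-to-CUB R-squared from [perConditionCubFit()].
#' The p-value uses exact enumeration for n <= 9 (where the large-sample
#' approximation is invalid) and the t-approximation otherwise.
#'
#' @param fitTable data.frame with columns `growth_rate` and `expr_cub_r2`
#'   (NA rows dropped); at least 4 usable rows.
#' @return List with `rho`, `p`, `n`, `method`.
#' @export
growthVsFitCorrelation <- function(fitTable) {
  ok <- stats::complete.cases(fitTable[, c("growth_rate", "expr_cub_r2")])
  x <- fitTable$growth_rate[ok]
  y <- fitTable$expr_cub_r2[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 conditions with defined fits")
  if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0)
    stop("degenerate input: all ranks tied, Spearman correlation undefined")
  exact <- n <= 9 && !anyDuplicated(x) && !anyDuplicated(y)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = exact))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n,
       method = if (exact) "exact" else "t-approximation")
}

#' Doubling time from exponential growth rate
#'
#' `ln(2) / rate`, in hours for a rate in 1/h. A rate of 0.07 1/h corresponds
#' to a population doubling time of 9.9 h.
#'
#' @param rate positive growth rate(s), 1/h.
#' @return Doubling time(s) in hours.
#' @examples
#' doublingTime(c(0.07, 1.42))
#' @export
doublingTime <- function(rate) {
  if (any(rate <= 0)) stop("growth rate must be positive")
  log(2) / rate
}

#' Assemble the per-gene score table
#'
#' Combines mean expression (arithmetic mean of the stored log-scale values
#' across conditions), GCI, one permuted GCI per gene, and the CUB scores
#' into the table downstream models consume.
#'
#' @param ges a replicate-averaged [GrowthExpressionSet-class].
#' @param cai,tai named numeric CUB scores (either may be `NULL`).
#' @param seed integer seed for the permutation null.
#' @return A [S4Vectors::DataFrame] with columns `gene_id`, `mean_expression`,
#'   `gci`, `gci_permuted`, and `cai`/`tai` where supplied.
#' @export
buildGeneScoreTable <- function(ges, cai = NULL, tai = NULL, seed = 1L) {
  obs <- computeGci(ges)
  perm <- gciPermutationNull(ges, seed = seed)
  out <- DataFrame(gene_id = rownames(ges),
                   mean_expression = unname(rowMeans(exprValues(ges))),
                   gci = unname(obs),
                   gci_permuted = unname(perm))
  if (!is.null(cai)) out$cai <- unname(cai[rownames(ges)])
  if (!is.null(tai)) out$tai <- unname(tai[rownames(ges)])
  rownames(out) <- out$gene_id
  out
}
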