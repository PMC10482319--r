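#' Generate synthetic condition metadata
#'
#' Draws condition-level growth rates uniformly on `rateRange` (defaults to
#' the 0.07-1.42 1/h span typical of laboratory growth compendia), expands
#' each condition into replicate experiments with small rate jitter, and
#' assigns strain flags: a fraction `fracAle` of conditions are
#' adaptive-laboratory-evolution strains and a fraction `fracMutant` of the
#' remaining conditions are mutants or knock-outs. Alignment scores are drawn
#' high (85-100) with a fraction `fracLowAlign` of experiments planted below
#' the usual quality threshold of 80. Deterministic given `seed`.
#'
#' @param nCond number of conditions (>= 3).
#' @param rateRange `c(lo, hi)` growth-rate range, 1/h, `lo > 0`.
#' @param replicates integer: replicates per condition (scalar or length
#'   `nCond`).
#' @param fracAle fraction of conditions flagged ALE.
#' @param fracMutant fraction of the non-ALE conditions flagged mutant/KO.
#' @param fracLowAlign fraction of experiments given alignment scores below
#'   80.
#' @param rateJitterSd replicate-level growth-rate jitter sd, 1/h.
#' @param seed integer seed.
#' @return List with `meta` (experiment-level data.frame: `experiment_id`,
#'   `condition_id`, `growth_rate`, `alignment_score`, `is_ale`,
#'   `is_mutant_or_ko`) and `growth` (condition-level rate vector).
#' @export
genConditions <- function(nCond = 50, rateRange = c(0.07, 1.42),
                          replicates = 2L, fracAle = 0.5, fracMutant = 0.4,
                          fracLowAlign = 0, rateJitterSd = 0.02, seed = 1L) {
  stopifnot(nCond >= 3, rateRange[1] > 0, rateRange[2] > rateRange[1])
  rng <- .seedScope(seed)
  on.exit(rng$restore(), add = TRUE)
  plan <- as.integer(rep(replicates, length.out = nCond))
  mu <- stats::runif(nCond, rateRange[1], rateRange[2])
  cond <- sprintf("cond%03d", seq_len(nCond))
  ale <- rep(FALSE, nCond)
  ale[sample.int(nCond, round(fracAle * nCond))] <- TRUE
  mut <- rep(FALSE, nCond)
  nonAle <- which(!ale)
  if (length(nonAle))
    mut[sample(nonAle, round(fracMutant * length(nonAle)))] <- TRUE
  idx <- rep(seq_len(nCond), plan)
  nExp <- length(idx)
  rate <- pmax(mu[idx] + stats::rnorm(nExp, 0, rateJitterSd), 0.01)
  align <- stats::runif(nExp, 85, 100)
  if (fracLowAlign > 0) {
    low <- sample.int(nExp, max(1L, round(fracLowAlign * nExp)))
    align[low] <- stats::runif(length(low), 50, 79.9)
  }
  meta <- data.frame(
    experiment_id = paste0(cond[idx], "_r",
                           unlist(lapply(plan, seq_len))),
    condition_id = cond[idx],
    growth_rate = rate,
    alignment_score = round(align, 1),
    is_ale = ale[idx],
    is_mutant_or_ko = mut[idx])
  list(meta = meta, growth = stats::setNames(mu, cond), plan = plan)
}

#' Generate a synthetic expression matrix with planted growth coupling
#'
#' Per-gene log expression is an affine function of growth rate plus
#' Gaussian noise: `e_gc = b_g + s_g * mu_c + eps`, `eps ~ N(0, sigma^2)`,
#' evaluated at each experiment's (jittered) growth rate. Baselines are
#' `N(baselineMean, baselineSd^2)`; slopes come from a two-component normal
#' mixture with a configurable negative fraction, mirroring the left-skewed
#' growth-correlation distributions seen in real compendia where most genes
#' decrease in relative abundance during rapid growth. Optionally injects
#' duplicated condition profiles (identical expression, different reported
#' growth rates) to exercise duplicate detection.
#'
#' @param nGenes number of genes.
#' @param conditions output of [genConditions()].
#' @param baselineMean,baselineSd baseline distribution parameters
#'   (log-TPM-like units).
#' @param slopeNegFrac fraction of genes with negative-component slopes.
#' @param slopeNegMean,slopeNegSd,slopePosMean,slopePosSd slope mixture
#'   components (log-expression units per 1/h).
#' @param noiseSd Gaussian noise sd.
#' @param nDuplicatePairs number of condition pairs to duplicate.
#' @param seed integer seed.
#' @return List with `ges` (a [GrowthExpressionSet-class], experiment-level)
#'   and `truth` (a [SyntheticTruth-class]).
#' @export
genExpression <- function(nGenes = 3000, conditions,
                          baselineMean = 3, baselineSd = 1.5,
                          slopeNegFrac = 0.65,
                          slopeNegMean = -0.5, slopeNegSd = 0.3,
                          slopePosMean = 0.8, slopePosSd = 0.4,
                          noiseSd = 0.5, nDuplicatePairs = 0, seed = 1L) {
  stopifnot(noiseSd >= 0)
  rng <- .seedScope(seed)
  on.exit(rng$restore(), add = TRUE)
  meta <- conditions$meta
  nExp <- nrow(meta)
  b <- stats::rnorm(nGenes, baselineMean, baselineSd)
  isNeg <- stats::runif(nGenes) < slopeNegFrac
  s <- ifelse(isNeg, stats::rnorm(nGenes, slopeNegMean, slopeNegSd),
              stats::rnorm(nGenes, slopePosMean, slopePosSd))
  genes <- sprintf("g%05d", seq_len(nGenes))
  vals <- outer(s, meta$growth_rate) + b +
    matrix(stats::rnorm(nGenes * nExp, 0, noiseSd), nGenes, nExp)
  dimnames(vals) <- list(genes, meta$experiment_id)
  dupPairs <- matrix(character(0), 0, 2)
  if (nDuplicatePairs > 0) {
    conds <- unique(meta$condition_id)
    pick <- matrix(sample(conds, 2L * nDuplicatePairs), ncol = 2)
    for (i in seq_len(nrow(pick))) {
      from <- which(meta$condition_id == pick[i, 1])
      to <- which(meta$condition_id == pick[i, 2])
      m <- min(length(from), length(to))
      vals[, to[seq_len(m)]] <- vals[, from[seq_len(m)]]
      if (length(to) > m)   # surplus replicates would break exact duplication
        vals[, to[-seq_len(m)]] <- vals[, from[rep(1L, length(to) - m)]]
    }
    dupPairs <- pick
  }
  ges <- GrowthExpressionSet(vals, meta, scaleTag = "log_tpm")
  truth <- new("SyntheticTruth", seed = as.integer(seed),
               growthRates = unname(conditions$growth),
               baselines = stats::setNames(b, genes),
               slopes = stats::setNames(s, genes),
               noiseSd = noiseSd, biasStrengths = numeric(0),
               coupling = c(alpha_expr = NA_real_, gamma_gci = NA_real_),
               plantedTerms = list(),
               replicatePlan = conditions$plan,
               duplicatePairs = dupPairs)
  list(ges = ges, truth = truth)
}

.softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

#' Generate coding sequences whose codon bias tracks planted expression
#'
#' Samples one coding sequence per gene under a codon-choice model in which
#' each gene's bias strength is coupled to its planted expression
#' parameters: `beta_g = softplus(alphaExpr * z(b_g) + gammaGci * z(s_g))`
#' (z = z-score across genes), and within each synonymous family codon `c`
#' is drawn with probability proportional to `w(c)^beta_g`. `beta_g = 0`
#' gives uniform synonymous usage; large `beta_g` concentrates every family
#' on its preferred (weight-1) codon, driving CAI toward 1. Amino acids are
#' drawn uniformly over the 18 multi-codon families (single-codon families
#' carry no bias signal); an ATG start and TAA stop frame every sequence, so
#' lengths are divisible by 3 by construction. Deterministic given `seed`.
#'
#' @param truth a [SyntheticTruth-class] from [genExpression()].
#' @param weightTable a [CodonWeightTable-class] covering all 61 sense codons.
#' @param lengthRange inclusive range (codons, excluding start/stop) from
#'   which gene lengths are drawn uniformly.
#' @param alphaExpr,gammaGci coupling of bias strength to baseline and slope.
#' @param betaOverride optional nonnegative scalar or per-gene vector used as
#'   `beta_g` directly, bypassing the softplus coupling (e.g. 0 for exactly
#'   uniform synonymous usage).
#' @param seed integer seed.
#' @return List with `cds` (a named [Biostrings::DNAStringSet]) and `truth`
#'   (the input truth with `biasStrengths` and `coupling` filled in).
#' @export
genSequences <- function(truth, weightTable, lengthRange = c(100, 400),
                         alphaExpr = 1.0, gammaGci = 0.5,
                         betaOverride = NULL, seed = 1L) {
  stopifnot(is(truth, "SyntheticTruth"), is(weightTable, "CodonWeightTable"))
  w <- codonWeights(weightTable)
  if (length(setdiff(.SENSE_CODONS, names(w))))
    stop("weight table must cover all 61 sense codons")
  rng <- .seedScope(seed)
  on.exit(rng$restore(), add = TRUE)
  b <- plantedBaselines(truth); s <- plantedSlopes(truth)
  beta <- if (!is.null(betaOverride)) {
    stopifnot(all(betaOverride >= 0))
    rep_len(betaOverride, length(b))
  } else {
    .softplus(alphaExpr * as.vector(scale(b)) + gammaGci * as.vector(scale(s)))
  }
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[.SENSE_CODONS]
  fams <- split(.SENSE_CODONS, aa)
  fams <- fams[lengths(fams) > 1]   # multi-codon families only
  nGenes <- length(b)
  lens <- sample(seq(lengthRange[1], lengthRange[2]), nGenes, replace = TRUE)
  seqs <- vapply(seq_len(nGenes), function(i) {
    nf <- stats::rmultinom(1, lens[i], rep(1, length(fams)))[, 1]
    cods <- unlist(lapply(which(nf > 0), function(f) {
      cf <- fams[[f]]
      p <- w[cf]^beta[i]
      cf[sample.int(length(cf), nf[f], replace = TRUE, prob = p)]
    }), use.names = FALSE)
    paste0("ATG", paste(cods[sample.int(length(cods))], collapse = ""), "TAA")
  }, character(1))
  cds <- Biostrings::DNAStringSet(seqs)
  names(cds) <- names(b)
  truth@biasStrengths <- stats::setNames(beta, names(b))
  truth@coupling <- c(alpha_expr = alphaExpr, gamma_gci = gammaGci)
  methods::validObject(truth)
  list(cds = cds, truth = truth)
}

#' Generate an annotation table with terms planted among positive-slope genes
#'
#' Background terms draw members uniformly from all genes; each planted term
#' draws a fraction `enrichmentStrength` of its members from the
#' positive-slope genes (the rest uniformly), emulating functional classes
#' (e.g. translation machinery) concentrated among growth-upregulated genes.
#' Planted membership is recorded in the returned truth object.
#'
#' @param truth a [SyntheticTruth-class].
#' @param nTerms total number of terms (>= 1), including planted ones.
#' @param nPlanted number of planted (enriched) terms.
#' @param termSizeRange inclusive range of term sizes (genes per term).
#' @param enrichmentStrength fraction of a planted term's members drawn from
#'   positive-slope genes (0 = uniform null).
#' @param seed integer seed.
#' @return List with `annotations` (data.frame `gene_id`, `term_id`) and
#'   `truth` (with `plantedTerms` filled in).
#' @export
genAnnotations <- function(truth, nTerms = 40, nPlanted = 1,
                           termSizeRange = c(20, 120),
                           enrichmentStrength = 0.8, seed = 1L) {
  stopifnot(is(truth, "SyntheticTruth"), nTerms >= 1, nPlanted <= nTerms)
  rng <- .seedScope(seed)
  on.exit(rng$restore(), add = TRUE)
  genes <- names(plantedSlopes(truth))
  posGenes <- genes[plantedSlopes(truth) > 0]
  terms <- sprintf("T%04d", seq_len(nTerms))
  planted <- if (nPlanted > 0) terms[seq_len(nPlanted)] else character(0)
  rows <- lapply(seq_len(nTerms), function(t) {
    size <- min(sample(seq(termSizeRange[1], termSizeRange[2]), 1L),
                length(genes))
    if (terms[t] %in% planted && enrichmentStrength > 0 &&
        length(posGenes)) {
      nPos <- min(round(enrichmentStrength * size), length(posGenes))
      members <- c(sample(posGenes, nPos),
                   sample(setdiff(genes, posGenes),
                          min(size - nPos, length(genes) - length(posGenes))))
    } else {
      members <- sample(genes, size)
    }
    data.frame(gene_id = unique(members), term_id = terms[t])
  })
  ann <- do.call(rbind, rows)
  truth@plantedTerms <- stats::setNames(
    lapply(planted, function(p) ann$gene_id[ann$term_id == p]), planted)
  list(annotations = ann, truth = truth)
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper chaining [genConditions()], [genExpression()],
#' [genSequences()] and [genAnnotations()] with consistent sub-seeds derived
#' from one master seed, producing everything the pipeline consumes plus the
#' planted ground truth.
#'
#' @param nGenes,nCond study size (defaults 3000 genes x 50 conditions).
#' @param seed master integer seed.
#' @param weightTable [CodonWeightTable-class] used for sequence generation
#'   (default: illustrative CAI table).
#' @param nDuplicatePairs duplicated condition-profile pairs to inject.
#' @param ... passed on to [genExpression()].
#' @return List with `ges`, `cds`, `weightTable`, `annotations`, `truth`,
#'   `conditions`.
#' @export
simulateGrowthCubData <- function(nGenes = 3000, nCond = 50, seed = 1L,
                                  weightTable = makeIllustrativeWeightTable("CAI"),
                                  nDuplicatePairs = 0, ...) {
  seed <- as.integer(seed)
  conds <- genConditions(nCond = nCond, seed = seed)
  ex <- genExpression(nGenes = nGenes, conditions = conds,
                      nDuplicatePairs = nDuplicatePairs,
                      seed = seed + 1L, ...)
  sq <- genSequences(ex$truth, weightTable, seed = seed + 2L)
  an <- genAnnotations(sq$truth, seed = seed + 3L)
  list(ges = ex$ges, cds = sq$cds, weightTable = weightTable,
       annotations = an$annotations, truth = an$truth, conditions = conds)
}
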