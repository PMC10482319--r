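#' Read an expression matrix and condition metadata from TSV
#'
#' The expression TSV has `gene_id` as its first column and one column per
#' experiment; the metadata TSV has columns `experiment_id`, `condition_id`,
#' `growth_rate` and optionally `alignment_score`, `is_ale`,
#' `is_mutant_or_ko`.
#'
#' @param exprPath path to the expression TSV.
#' @param metaPath path to the condition metadata TSV.
#' @param scaleTag normalization tag recorded on the object (the log base of
#'   an external compendium's values is treated as opaque).
#' @return A [GrowthExpressionSet-class].
#' @export
readExpressionMatrix <- function(exprPath, metaPath, scaleTag = "log_tpm") {
  expr <- utils::read.delim(exprPath, check.names = FALSE,
                            stringsAsFactors = FALSE)
  if (colnames(expr)[1] != "gene_id")
    stop("expression TSV must start with a gene_id column")
  m <- as.matrix(expr[, -1, drop = FALSE])
  rownames(m) <- expr$gene_id
  meta <- utils::read.delim(metaPath, stringsAsFactors = FALSE)
  for (fl in c("is_ale", "is_mutant_or_ko"))
    if (fl %in% colnames(meta)) meta[[fl]] <- as.logical(meta[[fl]])
  GrowthExpressionSet(m, meta, scaleTag = scaleTag)
}

#' Write a GrowthExpressionSet to TSV
#'
#' @param ges a [GrowthExpressionSet-class].
#' @param exprPath,metaPath output TSV paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
writeExpressionMatrix <- function(ges, exprPath = NULL, metaPath = NULL) {
  if (!is.null(exprPath)) {
    df <- data.frame(gene_id = rownames(ges), exprValues(ges),
                     check.names = FALSE)
    utils::write.table(df, exprPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(metaPath)) {
    cd <- as.data.frame(colData(ges))
    cd <- cbind(experiment_id = rownames(cd), cd)
    utils::write.table(cd, metaPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(exprPath, metaPath))
}

#' Filter experiments on growth-rate and alignment quality
#'
#' Retains columns whose growth rate is reported and positive (growth rates
#' of zero may be stationary-phase cultures or reporting errors) and, when an
#' alignment score is present, at least `minAlignment`. Column order is
#' preserved. A per-reason removal report is stored in
#' `metadata(result)$filter_report` (reasons `missing_growth`, `zero_growth`,
#' `low_alignment`).
#'
#' @param ges a [GrowthExpressionSet-class].
#' @param minAlignment minimum acceptable alignment score (default 80).
#' @param requirePositiveGrowth drop columns with missing or non-positive
#'   growth rate (default TRUE).
#' @return The filtered [GrowthExpressionSet-class]; inspect the report with
#'   `metadata(x)$filter_report`.
#' @export
filterConditions <- function(ges, minAlignment = 80,
                             requirePositiveGrowth = TRUE) {
  stopifnot(is(ges, "GrowthExpressionSet"))
  gr <- colData(ges)$growth_rate
  al <- colData(ges)$alignment_score
  reason <- rep(NA_character_, ncol(ges))
  if (requirePositiveGrowth) {
    reason[is.na(gr)] <- "missing_growth"
    reason[is.na(reason) & gr <= 0] <- "zero_growth"
  }
  reason[is.na(reason) & !is.na(al) & al < minAlignment] <- "low_alignment"
  keep <- is.na(reason)
  if (!any(keep)) stop("all experiments removed by condition filters")
  out <- ges[, keep]
  metadata(out)$filter_report <-
    c(table(factor(reason[!keep],
                   levels = c("missing_growth", "zero_growth",
                              "low_alignment"))))
  out
}

#' Normalize raw abundances to a log fractional scale
#'
#' Transforms a nonnegative abundance matrix column-wise by
#' `a -> 6 + log(a / sum(a))` in natural log (`"six_plus_ln_frac"`, as used
#' for protein copies per cell) or log10 (`"six_plus_log10_frac"`, as used
#' for fmol/mgDW abundances). Zeros are first replaced by the smallest
#' nonzero value of the whole matrix (`zeroPolicy = "replace_with_min_nonzero"`,
#' the default; `"per_column_min_nonzero"` uses each column's own minimum;
#' `"error"` refuses). Column totals are recomputed after replacement so the
#' implied fractions sum to one.
#'
#' @param raw nonnegative numeric matrix, genes x experiments.
#' @param flavor `"six_plus_ln_frac"` or `"six_plus_log10_frac"`.
#' @param zeroPolicy see Description.
#' @return Numeric matrix of normalized values, same dimnames as `raw`.
#' @examples
#' normalizeAbundances(matrix(c(1, 1), 2, 1), "six_plus_ln_frac")
#' @export
normalizeAbundances <- function(raw,
                                flavor = c("six_plus_ln_frac",
                                           "six_plus_log10_frac"),
                                zeroPolicy = c("replace_with_min_nonzero",
                                               "per_column_min_nonzero",
                                               "error")) {
  flavor <- match.arg(flavor)
  zeroPolicy <- match.arg(zeroPolicy)
  raw <- as.matrix(raw)
  if (any(raw < 0)) stop("abundances must be nonnegative")
  if (any(colSums(raw) == 0)) stop("degenerate all-zero column(s)")
  if (any(raw == 0)) {
    if (zeroPolicy == "error")
      stop("zero entries present and zeroPolicy = 'error'")
    if (zeroPolicy == "replace_with_min_nonzero") {
      repl <- min(raw[raw > 0])
      raw[raw == 0] <- repl
    } else {
      for (j in seq_len(ncol(raw))) {
        cj <- raw[, j]
        if (any(cj == 0)) raw[cj == 0, j] <- min(cj[cj > 0])
      }
    }
  }
  frac <- sweep(raw, 2, colSums(raw), "/")
  if (flavor == "six_plus_ln_frac") 6 + log(frac) else 6 + log10(frac)
}

#' Average replicate experiments into conditions
#'
#' Collapses experiments sharing a `condition_id` into one column per
#' condition: expression values and growth rates are arithmetic means on the
#' stored (log) scale, alignment scores are averaged, and strain flags are
#' merged by logical OR. Averaging is intended to run *after* normalization.
#' Condition order follows first appearance.
#'
#' @param ges a [GrowthExpressionSet-class].
#' @return A [GrowthExpressionSet-class] with one column per condition
#'   (colnames are condition ids).
#' @export
averageReplicates <- function(ges) {
  stopifnot(is(ges, "GrowthExpressionSet"))
  cid <- as.character(colData(ges)$condition_id)
  if (any(is.na(cid) | !nzchar(cid))) stop("every column needs a condition_id")
  conds <- unique(cid)
  groups <- lapply(conds, function(cc) which(cid == cc))
  vals <- vapply(groups, function(ix)
    rowMeans(exprValues(ges)[, ix, drop = FALSE]), numeric(nrow(ges)))
  dimnames(vals) <- list(rownames(ges), conds)
  cd <- colData(ges)
  meanOrNa <- function(v) if (all(is.na(v))) NA_real_ else
    mean(v, na.rm = TRUE)
  meta <- data.frame(
    experiment_id = conds,
    condition_id = conds,
    growth_rate = vapply(groups, function(ix)
      meanOrNa(cd$growth_rate[ix]), numeric(1)),
    alignment_score = vapply(groups, function(ix)
      meanOrNa(cd$alignment_score[ix]), numeric(1)),
    is_ale = vapply(groups, function(ix) any(cd$is_ale[ix]), logical(1)),
    is_mutant_or_ko = vapply(groups, function(ix)
      any(cd$is_mutant_or_ko[ix]), logical(1)))
  out <- GrowthExpressionSet(vals, meta, scaleTag = scaleTag(ges))
  metadata(out)$replicate_plan <-
    stats::setNames(lengths(groups), conds)
  out
}

#' Detect duplicated expression profiles
#'
#' Flags pairs of columns whose all-by-all Spearman correlation reaches
#' `1 - tol` -- identical rank profiles are extremely unlikely to arise
#' experimentally and usually indicate duplicated records. Constant columns
#' (zero rank variance) have undefined correlations and are reported
#' separately, never as duplicates. Ties are handled by average ranks.
#'
#' @param ges a [GrowthExpressionSet-class] with at least 2 columns.
#' @param tol slack below exact rank agreement (default 0: rho must equal 1).
#' @return A list with `pairs` (data.frame `a`, `b`, `rho`) and
#'   `undefined` (ids of constant columns).
#' @export
detectDuplicateProfiles <- function(ges, tol = 0) {
  stopifnot(is(ges, "GrowthExpressionSet"), ncol(ges) >= 2)
  v <- exprValues(ges)
  const <- apply(v, 2, function(x) stats::var(x) == 0)
  rho <- suppressWarnings(stats::cor(v[, !const, drop = FALSE],
                                     method = "spearman"))
  # 1e-12 guard: cor() on long tied-rank vectors can return 1 - few*eps
  hit <- which(upper.tri(rho) & rho >= 1 - tol - 1e-12, arr.ind = TRUE)
  list(pairs = data.frame(a = rownames(rho)[hit[, 1]],
                          b = colnames(rho)[hit[, 2]],
                          rho = rho[hit]),
       undefined = colnames(v)[const])
}

#' Exclude duplicated expression profiles
#'
#' Default policy removes *both* members of each duplicate pair: when two
#' records share an expression profile but report different growth rates,
#' neither averaging nor keeping one is defensible. `"keep_one"` retains the
#' lexicographically first member instead.
#'
#' @param ges a [GrowthExpressionSet-class].
#' @param policy `"drop_both"` (default) or `"keep_one"`.
#' @param tol passed to [detectDuplicateProfiles()].
#' @return The [GrowthExpressionSet-class] with duplicates removed; the ids
#'   dropped are in `metadata(x)$duplicates_removed`.
#' @export
excludeDuplicateProfiles <- function(ges, policy = c("drop_both", "keep_one"),
                                     tol = 0) {
  policy <- match.arg(policy)
  dup <- detectDuplicateProfiles(ges, tol = tol)
  drop <- if (policy == "drop_both") unique(c(dup$pairs$a, dup$pairs$b))
  else unique(apply(dup$pairs[, c("a", "b"), drop = FALSE], 1,
                    function(p) sort(p)[2]))
  out <- ges[, !(colnames(ges) %in% drop)]
  metadata(out)$duplicates_removed <- drop
  out
}

#' Prune to a sparse set of maximally distinct conditions
#'
#' Iteratively removes one condition of the currently most rank-correlated
#' pair (Spearman, all-by-all) until `targetN` columns remain; which member
#' of the pair is removed is a uniform coin flip driven by `seed`, so the
#' result is deterministic given the seed. When several pairs tie at the
#' maximal correlation the lexicographically smallest pair is taken before
#' the coin flip. Correlations among surviving columns are unaffected by a
#' removal, so the all-by-all matrix is computed once and masked.
#'
#' @param ges a [GrowthExpressionSet-class].
#' @param targetN number of conditions to keep (2 <= targetN <= ncol).
#' @param seed integer seed for the removal coin flips.
#' @return The pruned [GrowthExpressionSet-class]; the removal log (iteration,
#'   pair, removed id) is in `metadata(x)$prune_log`.
#' @export
pruneToSparse <- function(ges, targetN, seed) {
  stopifnot(is(ges, "GrowthExpressionSet"),
            targetN >= 2, targetN <= ncol(ges))
  rho <- suppressWarnings(stats::cor(exprValues(ges), method = "spearman"))
  rho[is.na(rho)] <- -Inf   # constant columns: undefined, never "most correlated"
  diag(rho) <- -Inf
  alive <- stats::setNames(rep(TRUE, ncol(ges)), colnames(ges))
  log_it <- integer(); log_a <- character(); log_b <- character()
  log_rm <- character()
  rng <- .seedScope(seed)
  on.exit(rng$restore(), add = TRUE)
  it <- 0L
  while (sum(alive) > targetN) {
    it <- it + 1L
    sub <- rho[alive, alive, drop = FALSE]
    mx <- max(sub)
    cand <- which(sub == mx & upper.tri(sub), arr.ind = TRUE)
    pairs <- cbind(rownames(sub)[cand[, 1]], colnames(sub)[cand[, 2]])
    pairs <- t(apply(pairs, 1, sort))
    ord <- order(pairs[, 1], pairs[, 2])
    pick <- pairs[ord[1], ]
    removed <- pick[sample.int(2L, 1L)]
    alive[removed] <- FALSE
    log_it <- c(log_it, it); log_a <- c(log_a, pick[1])
    log_b <- c(log_b, pick[2]); log_rm <- c(log_rm, removed)
  }
  out <- ges[, alive]
  metadata(out)$prune_log <- data.frame(iteration = log_it, a = log_a,
                                        b = log_b, removed = log_rm)
  out
}

# Run code under a local RNG state so package functions never disturb the
# caller's random stream.
.seedScope <- function(seed) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  list(restore = function() {
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
}

#' Neutral condition subsets
#'
#' Builds the two "neutral" subsets used as robustness controls: `non_ale`
#' excludes adaptive-laboratory-evolution strains; `non_ale_wildtype` further
#' excludes mutants and knock-outs.
#'
#' @param ges a [GrowthExpressionSet-class] with strain flags populated.
#' @return A list of two [GrowthExpressionSet-class] objects, `non_ale` and
#'   `non_ale_wildtype`.
#' @export
neutralSubsets <- function(ges) {
  stopifnot(is(ges, "GrowthExpressionSet"))
  ale <- colData(ges)$is_ale
  mut <- colData(ges)$is_mutant_or_ko
  list(non_ale = ges[, !ale],
       non_ale_wildtype = ges[, !ale & !mut])
}

#' Drop a set of genes from the matrix
#'
#' Removes rows by gene id (e.g. a published AT-rich outlier list). Ids not
#' present in the matrix are ignored; their count is reported in
#' `metadata(x)$genes_dropped` alongside the number removed.
#'
#' @param ges a [GrowthExpressionSet-class].
#' @param geneIds character vector of gene ids to remove.
#' @return The reduced [GrowthExpressionSet-class].
#' @export
dropGeneSet <- function(ges, geneIds) {
  stopifnot(is(ges, "GrowthExpressionSet"))
  present <- geneIds[geneIds %in% rownames(ges)]
  absent <- setdiff(geneIds, present)
  if (length(absent))
    message(length(absent), " id(s) not present in the matrix were ignored")
  out <- ges[!(rownames(ges) %in% present), ]
  metadata(out)$genes_dropped <- c(removed = length(unique(present)),
                                   absent = length(absent))
  out
}
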