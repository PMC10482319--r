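#' Run the full growth/CUB analysis pipeline
#'
#' Orchestrates the stages end-to-end on in-memory objects or file paths:
#' (1) prep -- optional raw-abundance normalization, condition quality
#' filters, replicate averaging, duplicate-profile exclusion, optional
#' sparse pruning; (2) CUB scoring of the coding sequences; (3) GCI with
#' permutation null and its summary; (4) per-condition expression-CUB fits
#' and the growth-vs-fit Spearman correlation; (5) the four-model battery;
#' (6) group statistics -- GCI-sign split with over-representation analysis
#' and optional label t-tests. Every stage logs its row/column bookkeeping
#' into the returned manifest; rerunning with the same inputs and seed is
#' reproducible.
#'
#' @param expr a [GrowthExpressionSet-class], or path to an expression TSV
#'   (then `meta` must be a metadata TSV path).
#' @param meta condition metadata TSV path when `expr` is a path.
#' @param cds a [Biostrings::DNAStringSet] or FASTA/GenBank path.
#' @param weights a [CodonWeightTable-class], a named list of them, or a
#'   named character vector of TSV paths (names = metric names).
#' @param annotations optional data.frame (`gene_id`, `term_id`) or TSV path
#'   for enrichment.
#' @param labels optional data.frame (`gene_id`, `label`) or TSV path for a
#'   GCI t-test.
#' @param normalize `"none"` (values already log scale) or a flavor accepted
#'   by [normalizeAbundances()].
#' @param minAlignment alignment-score threshold (default 80).
#' @param sparseN optional target size for [pruneToSparse()].
#' @param cubMetric which metric drives the condition fits and model battery
#'   (default first weight table).
#' @param pMax,qMax,topK enrichment thresholds (defaults 0.04, 0.05, 15).
#' @param cdsFormat format for a `cds` path (default `"fasta"`).
#' @param seed integer master seed for permutation and pruning.
#' @param outDir optional directory; when given, stage outputs are written
#'   as TSV/JSON (`gene_scores.tsv`, `condition_fits.tsv`,
#'   `model_comparison.tsv`, `enrichment_pos.tsv`, `enrichment_neg.tsv`,
#'   `summary.json`, `manifest.json`).
#' @return A manifest list: `parameters`, `stages` (per-stage counts),
#'   `results` (geneScores, conditionFits, growthVsFit, nullSummary,
#'   modelFits, enrichment, labelTests).
#' @export
runPipeline <- function(expr, meta = NULL, cds, weights,
                        annotations = NULL, labels = NULL,
                        normalize = "none", minAlignment = 80,
                        sparseN = NULL, cubMetric = NULL,
                        pMax = 0.04, qMax = 0.05, topK = 15,
                        cdsFormat = "fasta", seed = 1L, outDir = NULL) {
  seed <- as.integer(seed)
  ## ---- validate & load inputs (fail before any stage runs) ----
  ges <- if (is(expr, "GrowthExpressionSet")) expr
  else readExpressionMatrix(expr, meta,
                            scaleTag = if (normalize == "none") "log_tpm"
                            else "raw")
  cdsSet <- if (is(cds, "DNAStringSet")) cds else readCds(cds, cdsFormat)
  if (is(weights, "CodonWeightTable"))
    weights <- stats::setNames(list(weights), metricName(weights))
  if (is.character(weights))
    weights <- stats::setNames(
      lapply(names(weights), function(m) loadWeightTable(weights[[m]], m)),
      names(weights))
  if (is.null(cubMetric)) cubMetric <- names(weights)[1]
  if (!cubMetric %in% names(weights))
    stop("cubMetric '", cubMetric, "' not among the weight tables")
  if (is.character(annotations) && length(annotations) == 1L)
    annotations <- utils::read.delim(annotations, stringsAsFactors = FALSE)
  if (is.character(labels) && length(labels) == 1L)
    labels <- utils::read.delim(labels, stringsAsFactors = FALSE)
  if (!is.null(sparseN) &&
      sparseN > length(unique(colData(ges)$condition_id)))
    stop("sparseN (", sparseN, ") exceeds the number of conditions")

  manifest <- list(parameters = list(
    normalize = normalize, min_alignment = minAlignment,
    sparse_n = sparseN, cub_metric = cubMetric,
    p_max = pMax, q_max = qMax, top_k = topK, seed = seed))
  stage <- list()

  ## ---- stage 1: prep (normalize -> filter -> average -> dedup -> prune) ----
  nExpIn <- ncol(ges)
  if (normalize != "none") {
    vals <- normalizeAbundances(exprValues(ges), flavor = normalize)
    cd <- as.data.frame(colData(ges))
    cd <- cbind(experiment_id = rownames(cd), cd)
    ges <- GrowthExpressionSet(vals, cd, scaleTag = normalize)
  }
  ges <- filterConditions(ges, minAlignment = minAlignment)
  filtRep <- metadata(ges)$filter_report
  avg <- averageReplicates(ges)
  nCondAvg <- ncol(avg)
  avg <- excludeDuplicateProfiles(avg)
  dupDropped <- metadata(avg)$duplicates_removed
  if (!is.null(sparseN)) {
    if (sparseN > ncol(avg))
      stop("sparseN exceeds the conditions surviving preprocessing")
    avg <- pruneToSparse(avg, targetN = sparseN, seed = seed)
  }
  stage$prep <- list(
    experiments_in = nExpIn,
    experiments_removed = sum(filtRep),
    experiments_kept = nExpIn - sum(filtRep),
    filter_report = as.list(filtRep),
    conditions_after_averaging = nCondAvg,
    duplicates_removed = length(dupDropped),
    conditions_final = ncol(avg))

  ## ---- stage 2: CUB scoring ----
  nCdsIn <- length(cdsSet)
  filt <- filterCds(cdsSet)
  scores <- lapply(weights, function(wt) cubScore(filt$kept, wt))
  stage$cub <- list(cds_in = nCdsIn,
                    cds_removed = nrow(filt$removed),
                    cds_kept = length(filt$kept),
                    removal_reasons = as.list(table(filt$removed$reason)))

  ## ---- stage 3: GCI + permutation null ----
  cai <- if ("CAI" %in% names(scores)) scores$CAI else scores[[1]]
  tai <- if ("tAI" %in% names(scores)) scores$tAI else NULL
  geneScores <- buildGeneScoreTable(avg, cai = cai, tai = tai, seed = seed)
  nullSum <- permutationNullSummary(geneScores$gci, geneScores$gci_permuted)
  stage$gci <- list(genes_in = nrow(avg),
                    genes_undefined_gci = sum(is.na(geneScores$gci)),
                    genes_defined_gci = sum(!is.na(geneScores$gci)))

  ## ---- stage 4: per-condition fits vs growth ----
  cubVec <- scores[[cubMetric]]
  fits <- perConditionCubFit(avg, cubVec)
  gvf <- growthVsFitCorrelation(fits)
  stage$condition_fits <- list(conditions = nrow(fits),
                               conditions_undefined =
                                 sum(is.na(fits$expr_cub_r2)))

  ## ---- stage 5: model battery ----
  battery <- modelBattery(
    cub = cubVec,
    meanExpr = stats::setNames(geneScores$mean_expression,
                               geneScores$gene_id),
    gciValues = stats::setNames(geneScores$gci, geneScores$gene_id))
  stage$models <- list(genes_used = battery$additive$n,
                       genes_excluded = attr(battery, "n_excluded"))

  ## ---- stage 6: group statistics / enrichment ----
  gciVec <- stats::setNames(geneScores$gci, geneScores$gene_id)
  sets <- splitByGciSign(gciVec)
  enrichment <- NULL
  if (!is.null(annotations)) {
    universe <- names(gciVec)[!is.na(gciVec)]
    enrichment <- list(
      pos = oraEnrichment(sets$pos, universe, annotations,
                          pMax = pMax, qMax = qMax, topK = topK),
      neg = oraEnrichment(sets$neg, universe, annotations,
                          pMax = pMax, qMax = qMax, topK = topK))
  }
  labelTests <- NULL
  if (!is.null(labels)) labelTests <- gciLabelTest(gciVec, labels)
  stage$groups <- list(n_pos = length(sets$pos), n_neg = length(sets$neg),
                       n_zero = attr(sets, "n_zero"),
                       n_undefined = attr(sets, "n_undefined"))

  manifest$stages <- stage
  manifest$results <- list(geneScores = geneScores, conditionFits = fits,
                           growthVsFit = gvf, nullSummary = nullSum,
                           modelFits = battery,
                           modelComparison = modelComparisonTable(battery),
                           enrichment = enrichment, labelTests = labelTests,
                           prepped = avg, cubScores = scores)
  if (!is.null(outDir)) .writePipelineOutputs(manifest, outDir)
  manifest
}

.writePipelineOutputs <- function(manifest, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  res <- manifest$results
  utils::write.table(as.data.frame(res$geneScores),
                     file.path(outDir, "gene_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$conditionFits,
                     file.path(outDir, "condition_fits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$modelComparison,
                     file.path(outDir, "model_comparison.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$enrichment)) {
    utils::write.table(res$enrichment$pos$top,
                       file.path(outDir, "enrichment_pos.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$enrichment$neg$top,
                       file.path(outDir, "enrichment_neg.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  summary <- c(res$growthVsFit[c("rho", "p", "n")], res$nullSummary,
               list(vif_additive = unname(res$modelFits$additive$vif[1])))
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  slim <- manifest[c("parameters", "stages")]
  jsonlite::write_json(slim, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(outDir)
}

#' Read a pipeline configuration file
#'
#' Reads a YAML (or JSON) run configuration whose keys mirror the arguments
#' of [runPipeline()] (`expr`, `meta`, `cds`, `weights`, `annotations`,
#' `labels`, `normalize`, `min_alignment`, `sparse_n`, `cub_metric`,
#' `p_max`, `q_max`, `top_k`, `seed`, `out_dir`).
#'
#' @param path configuration file path.
#' @return Named list of arguments for [runPipeline()].
#' @export
readRunConfig <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  else {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  }
  map <- c(min_alignment = "minAlignment", sparse_n = "sparseN",
           cub_metric = "cubMetric", p_max = "pMax", q_max = "qMax",
           top_k = "topK", out_dir = "outDir", cds_format = "cdsFormat")
  names(cfg) <- ifelse(names(cfg) %in% names(map), map[names(cfg)],
                       names(cfg))
  if (!is.null(cfg$weights)) cfg$weights <- unlist(cfg$weights)
  cfg
}
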