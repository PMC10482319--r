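#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

.SENSE_CODONS <- local({
  gc <- Biostrings::GENETIC_CODE
  sort(names(gc)[gc != "*"])
})

.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Codon weight table for a codon usage bias metric
#'
#' A `CodonWeightTable` maps sense codons to relative adaptiveness weights in
#' (0, 1], defining a codon usage bias (CUB) metric such as the Codon
#' Adaptation Index (CAI) or the tRNA Adaptation Index (tAI). A gene's score
#' under the metric is the geometric mean of the weights of its codons.
#'
#' @slot metricName single string naming the metric ("CAI", "tAI", or custom).
#' @slot weights named numeric vector, codon -> weight, each in (0, 1].
#' @slot provenance single string citing where the weights come from.
#'
#' @seealso [loadWeightTable()], [makeIllustrativeWeightTable()], [cubScore()]
#' @export
setClass("CodonWeightTable",
  slots = c(metricName = "character",
            weights = "numeric",
            provenance = "character"))

setValidity("CodonWeightTable", function(object) {
  w <- object@weights
  msg <- character()
  if (length(object@metricName) != 1L || !nzchar(object@metricName))
    msg <- c(msg, "metricName must be a single non-empty string")
  if (is.null(names(w)) || anyDuplicated(names(w)))
    msg <- c(msg, "weights must be uniquely named by codon")
  bad <- names(w)[!grepl("^[ACGT]{3}$", names(w))]
  if (length(bad))
    msg <- c(msg, paste0("malformed codon name(s): ",
                         paste(bad, collapse = ", ")))
  if (any(names(w) %in% .STOP_CODONS))
    msg <- c(msg, "stop codons must not carry weights")
  if (any(!is.finite(w)) || any(w <= 0) || any(w > 1))
    msg <- c(msg, paste0("all weights must lie in (0, 1]; a weight of 0 would",
                         " zero the geometric mean - use a small positive",
                         " pseudo-weight explicitly"))
  if (length(msg)) msg else TRUE
})

#' Expression matrix with growth-rate condition metadata
#'
#' `GrowthExpressionSet` extends
#' [SummarizedExperiment::SummarizedExperiment] for a genes x experiments
#' log-scale abundance matrix (assay `"exprs"`) whose column metadata carries
#' the condition structure the growth analysis needs: a replicate-grouping
#' `condition_id`, the reported `growth_rate` (1/h), an RNA-seq
#' `alignment_score`, and strain flags (`is_ale` for adaptive laboratory
#' evolution strains, `is_mutant_or_ko` for mutants and knock-outs).
#'
#' The normalization applied to the values is recorded in
#' `metadata(x)$scale_tag` (one of `"log_tpm"`, `"six_plus_ln_frac"`,
#' `"six_plus_log10_frac"`, `"raw"`); the log base of an external compendium's
#' "log-TPM" is treated as opaque and only tagged.
#'
#' @seealso [GrowthExpressionSet()] constructor, [filterConditions()],
#'   [averageReplicates()], [computeGci()]
#' @export
setClass("GrowthExpressionSet", contains = "SummarizedExperiment")

.REQUIRED_COLDATA <- c("condition_id", "growth_rate", "alignment_score",
                       "is_ale", "is_mutant_or_ko")

setValidity("GrowthExpressionSet", function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  miss <- setdiff(.REQUIRED_COLDATA, colnames(colData(object)))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks column(s): ",
                         paste(miss, collapse = ", ")))
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "experiment ids (colnames) must be present and unique")
  gr <- colData(object)$growth_rate
  if (!is.null(gr) && any(is.infinite(gr)))
    msg <- c(msg, "growth_rate must be finite or NA")
  if (is.null(metadata(object)$scale_tag))
    msg <- c(msg, "metadata scale_tag is required")
  if (length(msg)) msg else TRUE
})

#' Construct a GrowthExpressionSet
#'
#' @param values numeric matrix, genes x experiments, log-scale abundances;
#'   rownames are gene ids, colnames experiment ids.
#' @param meta data.frame of condition metadata with columns `experiment_id`,
#'   `condition_id`, `growth_rate`, and optionally `alignment_score`,
#'   `is_ale`, `is_mutant_or_ko` (missing optional columns are filled with
#'   `NA` / `FALSE`). Rows are matched to `colnames(values)` by
#'   `experiment_id`.
#' @param scaleTag string recording the normalization of `values`.
#'
#' @return A [GrowthExpressionSet-class] object.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("e", 1:4)))
#' meta <- data.frame(experiment_id = paste0("e", 1:4),
#'                    condition_id = c("c1", "c1", "c2", "c2"),
#'                    growth_rate = c(0.5, 0.5, 1.1, 1.1))
#' ges <- GrowthExpressionSet(m, meta)
#' growthRates(ges)
#' @export
GrowthExpressionSet <- function(values, meta,
                                scaleTag = c("log_tpm", "six_plus_ln_frac",
                                             "six_plus_log10_frac", "raw")) {
  scaleTag <- match.arg(scaleTag)
  values <- as.matrix(values)
  if (!"experiment_id" %in% colnames(meta))
    stop("meta must have an experiment_id column")
  if (!setequal(meta$experiment_id, colnames(values)) ||
      anyDuplicated(meta$experiment_id))
    stop("meta experiment_id must match colnames(values) one-to-one")
  meta <- meta[match(colnames(values), meta$experiment_id), , drop = FALSE]
  if (!"condition_id" %in% colnames(meta))
    stop("meta must have a condition_id column")
  if (!"growth_rate" %in% colnames(meta))
    stop("meta must have a growth_rate column")
  if (!"alignment_score" %in% colnames(meta)) meta$alignment_score <- NA_real_
  if (!"is_ale" %in% colnames(meta)) meta$is_ale <- FALSE
  if (!"is_mutant_or_ko" %in% colnames(meta)) meta$is_mutant_or_ko <- FALSE
  cd <- DataFrame(meta[, c("condition_id", "growth_rate", "alignment_score",
                           "is_ale", "is_mutant_or_ko")],
                  row.names = meta$experiment_id)
  se <- SummarizedExperiment(assays = list(exprs = values), colData = cd)
  metadata(se)$scale_tag <- scaleTag
  new("GrowthExpressionSet", se)
}

#' Planted ground truth of a synthetic data set
#'
#' Bookkeeping for the synthetic-data generator: the generative parameters of
#' the expression model `e_gc = b_g + s_g * mu_c + eps` (baselines `b_g`,
#' growth slopes `s_g`, noise sd), the codon-bias coupling, and the planted
#' annotation terms, so that parameter-recovery tests can compare estimates
#' against truth.
#'
#' @slot seed integer seed the data were generated from.
#' @slot growthRates condition-level growth rates (1/h).
#' @slot baselines per-gene baseline log expression `b_g`.
#' @slot slopes per-gene growth slope `s_g`.
#' @slot noiseSd Gaussian noise standard deviation, log-expression units.
#' @slot biasStrengths per-gene codon-bias exponent `beta_g >= 0` (empty until
#'   sequences are generated).
#' @slot coupling named numeric `c(alpha_expr, gamma_gci)` linking
#'   `beta_g = softplus(alpha * z(b_g) + gamma * z(s_g))`.
#' @slot plantedTerms named list, term id -> character vector of member genes.
#' @slot replicatePlan integer vector, replicates per condition.
#' @slot duplicatePairs character matrix (pairs x 2) of condition ids whose
#'   expression profiles were injected as duplicates.
#' @export
setClass("SyntheticTruth",
  slots = c(seed = "integer", growthRates = "numeric", baselines = "numeric",
            slopes = "numeric", noiseSd = "numeric",
            biasStrengths = "numeric", coupling = "numeric",
            plantedTerms = "list", replicatePlan = "integer",
            duplicatePairs = "matrix"))

setValidity("SyntheticTruth", function(object) {
  msg <- character()
  if (length(object@baselines) != length(object@slopes))
    msg <- c(msg, "baselines and slopes must have equal length")
  if (length(object@biasStrengths) &&
      length(object@biasStrengths) != length(object@slopes))
    msg <- c(msg, "biasStrengths length must match slopes")
  if (length(object@noiseSd) != 1L || object@noiseSd < 0)
    msg <- c(msg, "noiseSd must be a single value >= 0")
  if (length(object@replicatePlan) &&
      length(object@replicatePlan) != length(object@growthRates))
    msg <- c(msg, "replicatePlan length must match growthRates")
  if (length(msg)) msg else TRUE
})
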