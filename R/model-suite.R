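#' Ordinary least-squares fit with adjusted R-squared
#'
#' Fits `y ~ predictors` (optionally with all pairwise interactions) by
#' least squares and reports the quantities used for model comparison:
#' coefficients, `r2 = 1 - SSres/SStot`, `adj_r2 = 1 - (1 - r2)(n - 1)/(n -
#' p - 1)` with `p` the number of non-intercept terms, and the overall
#' F-test p-value. A rank-deficient design is an error naming the collinear
#' columns.
#'
#' @param y numeric response vector.
#' @param predictors named list or data.frame of numeric predictor vectors.
#' @param interaction include all pairwise interaction terms (default FALSE).
#' @param modelId label carried into the result.
#' @return A list of class `"cubModelFit"`: `model_id`, `coefficients`, `r2`,
#'   `adj_r2`, `p_overall`, `n`, `p_terms`, and the underlying `lm` in `fit`.
#' @examples
#' olsFit(c(1, 2, 3, 5), list(x = 1:4))
#' @export
olsFit <- function(y, predictors, interaction = FALSE, modelId = "model") {
  df <- as.data.frame(predictors)
  if (anyNA(y) || anyNA(df))
    stop("missing values must be excluded upstream (listwise, with a logged",
         " count)")
  n <- length(y)
  rhs <- paste(colnames(df), collapse = if (interaction) " * " else " + ")
  form <- stats::as.formula(paste("y ~", rhs))
  dat <- cbind(data.frame(y = y), df)
  fit <- stats::lm(form, data = dat)
  p <- fit$rank - 1L
  if (n <= p + 1L) stop("need n > number of parameters + 1")
  alias <- is.na(stats::coef(fit))
  if (any(alias))
    stop("singular design: collinear column(s) ",
         paste(names(stats::coef(fit))[alias], collapse = ", "))
  sm <- summary(fit)
  p_overall <- if (p == 0) NA_real_ else
    stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
              lower.tail = FALSE)
  structure(list(model_id = modelId,
                 coefficients = stats::coef(fit),
                 r2 = sm$r.squared,
                 adj_r2 = sm$adj.r.squared,
                 p_overall = unname(p_overall),
                 n = n, p_terms = p, fit = fit),
            class = "cubModelFit")
}

#' @export
print.cubModelFit <- function(x, ...) {
  cat("cubModelFit '", x$model_id, "': n = ", x$n, ", ", x$p_terms,
      " term(s)\n", sep = "")
  cat("  r2 = ", format(x$r2, digits = 4),
      ", adj_r2 = ", format(x$adj_r2, digits = 4),
      ", overall p = ", format(x$p_overall, digits = 3), "\n", sep = "")
  if (!is.null(x$vif))
    cat("  VIF: ", paste(names(x$vif), format(x$vif, digits = 4),
                         sep = " = ", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Variance inflation factors
#'
#' `VIF_k = 1 / (1 - R2_k)` where `R2_k` is the R-squared from regressing
#' predictor k on the remaining predictors. Values near 1 indicate no
#' collinearity; values above 5 are usually considered problematic. For two
#' predictors both VIFs equal `1 / (1 - r^2)`. Perfectly collinear
#' predictors yield `Inf`.
#'
#' @param predictors named list or data.frame of at least 2 nonconstant
#'   numeric vectors.
#' @return Named numeric vector of VIFs (>= 1, possibly `Inf`).
#' @examples
#' vifScores(data.frame(a = 1:10, b = c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9)))
#' @export
vifScores <- function(predictors) {
  df <- as.data.frame(predictors)
  if (ncol(df) < 2) stop("need at least 2 predictors")
  if (any(vapply(df, function(v) stats::var(v) == 0, logical(1))))
    stop("constant predictor(s) present")
  vapply(colnames(df), function(k) {
    fit <- stats::lm(stats::reformulate(setdiff(colnames(df), k), k),
                     data = df)
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Four-model battery predicting CUB from expression and GCI
#'
#' Fits the four linear models used to ask whether growth coupling carries
#' information about codon usage bias beyond expression level: (1) CUB ~
#' mean expression; (2) CUB ~ GCI; (3) the additive model with both; (4) the
#' additive model plus an expression x GCI interaction. Adjusted R-squared
#' is the comparison measure; the additive model additionally carries VIFs
#' for both predictors. Genes with a missing value in any of the three
#' inputs are excluded listwise so the four fits share one gene set (the
#' exclusion count is attached as `attr(x, "n_excluded")`).
#'
#' @param cub named numeric CUB response (e.g. CAI).
#' @param meanExpr named numeric mean log expression.
#' @param gciValues named numeric GCI per gene.
#' @param standardize standardize predictors before fitting (default FALSE;
#'   predictors are used on their stored scales so coefficients keep their
#'   units, but standardizing reduces nonessential collinearity in the
#'   interaction model).
#' @return Named list of four `cubModelFit` objects in fixed order
#'   `expr_only`, `gci_only`, `additive`, `interaction`.
#' @export
modelBattery <- function(cub, meanExpr, gciValues, standardize = FALSE) {
  ids <- names(cub)
  if (is.null(ids) || is.null(names(meanExpr)) || is.null(names(gciValues)))
    stop("all three vectors must be named by gene id")
  common <- Reduce(intersect, list(ids, names(meanExpr), names(gciValues)))
  y <- cub[common]; e <- meanExpr[common]; g <- gciValues[common]
  ok <- !(is.na(y) | is.na(e) | is.na(g))
  y <- y[ok]; e <- e[ok]; g <- g[ok]
  if (standardize) { e <- as.vector(scale(e)); g <- as.vector(scale(g)) }
  fits <- list(
    expr_only = olsFit(y, list(mean_expression = e), modelId = "expr_only"),
    gci_only = olsFit(y, list(gci = g), modelId = "gci_only"),
    additive = olsFit(y, list(mean_expression = e, gci = g),
                      modelId = "additive"),
    interaction = olsFit(y, list(mean_expression = e, gci = g),
                         interaction = TRUE, modelId = "interaction"))
  fits$additive$vif <- vifScores(data.frame(mean_expression = e, gci = g))
  attr(fits, "n_excluded") <- sum(!ok) + (length(cub) - length(common))
  fits
}

#' Model comparison table
#'
#' @param fits list of `cubModelFit` objects (e.g. from [modelBattery()]).
#' @return data.frame with one row per model: `model_id`, `n`, `r2`,
#'   `adj_r2`, `p_overall`.
#' @export
modelComparisonTable <- function(fits) {
  do.call(rbind, lapply(fits, function(f)
    data.frame(model_id = f$model_id, n = f$n, r2 = f$r2, adj_r2 = f$adj_r2,
               p_overall = f$p_overall, row.names = NULL)))
}

#' Linear versus quadratic fit comparison
#'
#' AIC comparison of `y ~ x` against `y ~ x + x^2`, used to check whether a
#' relationship (e.g. CUB on GCI) is best characterized as linear. The
#' quadratic is the only alternative considered.
#'
#' @param y,x numeric vectors of equal length.
#' @return List with `aic_linear`, `aic_quadratic`, `preferred` ("linear"
#'   when its AIC is lower or within 2 units, else "quadratic").
#' @export
linearVsQuadraticAIC <- function(y, x) {
  ok <- !(is.na(y) | is.na(x))
  dat <- data.frame(y = y[ok], x = x[ok])
  a1 <- stats::AIC(stats::lm(y ~ x, data = dat))
  a2 <- stats::AIC(stats::lm(y ~ x + I(x^2), data = dat))
  list(aic_linear = a1, aic_quadratic = a2,
       preferred = if (a2 < a1 - 2) "quadratic" else "linear")
}
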