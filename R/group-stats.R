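#' Two-sample Student's t-test on GCI groups
#'
#' Pooled-variance two-sided Student's t-test (df = n_a + n_b - 2) comparing
#' mean GCI between two gene classes (essential vs nonessential, core vs
#' accessory, ...). A Welch variant is available for unequal variances.
#'
#' @param a,b numeric vectors (NA dropped), each of length >= 2.
#' @param variant `"pooled"` (Student, default) or `"welch"`.
#' @return List with `t`, `df`, `p`, `mean_a`, `mean_b`, `n_a`, `n_b`.
#' @examples
#' twoSampleT(c(1, 2, 3), c(2, 3, 4))
#' @export
twoSampleT <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("both groups need at least 2 observations")
  if (variant == "pooled") {
    sp2 <- ((length(a) - 1) * stats::var(a) +
            (length(b) - 1) * stats::var(b)) / (length(a) + length(b) - 2)
    if (sp2 == 0) stop("zero pooled variance: t statistic degenerate")
  }
  ht <- stats::t.test(a, b, var.equal = (variant == "pooled"))
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
       mean_a = mean(a), mean_b = mean(b),
       n_a = length(a), n_b = length(b))
}

#' Split genes by the sign of their GCI
#'
#' Genes with GCI exactly 0 (or undefined) belong to neither set; their
#' counts are attached as attributes `n_zero` and `n_undefined`.
#'
#' @param scores a [S4Vectors::DataFrame]/data.frame with columns `gene_id`
#'   and `gci`, or a named numeric vector of GCI values.
#' @return List with `neg` and `pos` character vectors of gene ids.
#' @export
splitByGciSign <- function(scores) {
  if (is.numeric(scores)) {
    g <- scores; ids <- names(scores)
  } else {
    g <- scores$gci; ids <- scores$gene_id
  }
  if (is.null(ids)) stop("gene ids are required")
  out <- list(neg = ids[!is.na(g) & g < 0], pos = ids[!is.na(g) & g > 0])
  attr(out, "n_zero") <- sum(!is.na(g) & g == 0)
  attr(out, "n_undefined") <- sum(is.na(g))
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted p-values (q-values); input order is
#' preserved and `p <= q <= 1` elementwise.
#'
#' @param p numeric vector of p-values in \\[0, 1\\].
#' @return Numeric vector of q-values, same order as `p`.
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("all p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric over-representation analysis
#'
#' Tests each annotation term for over-representation in a query gene set
#' against a gene universe. For a term annotating `K` of the `N` universe
#' genes, with `k` of the `n` query genes annotated, the p-value is the
#' hypergeometric upper tail `P(X >= k)`; q-values are Benjamini-Hochberg
#' over all tested terms; the odds ratio is the 2x2 cross-product
#' `(k * (N - K - n + k)) / ((n - k) * (K - k))`, reported as `Inf` when a
#' zero cell makes it so (no Haldane-Anscombe correction unless
#' `haldane = TRUE`). Terms passing `p <= pMax` and `q <= qMax` are ranked
#' by odds ratio, descending, and the top `topK` returned.
#'
#' @param querySet character vector of gene ids (must be within `universe`).
#' @param universe character vector of all analyzable gene ids.
#' @param annotations data.frame with columns `gene_id`, `term_id` (an
#'   optional `term_name` is carried through); pairs outside the universe
#'   are dropped.
#' @param pMax,qMax significance filters (defaults 0.04 and 0.05).
#' @param topK number of top terms to return (default 15).
#' @param haldane apply the 0.5 continuity correction to the odds-ratio
#'   table (default FALSE: infinities are reported honestly).
#' @return List with `table` (all tested terms: `term_id`, `k_in_set`,
#'   `n_set`, `K_term`, `N_universe`, `p`, `q`, `odds_ratio`) and `top`
#'   (survivors ranked by odds ratio, at most `topK` rows).
#' @export
oraEnrichment <- function(querySet, universe, annotations,
                          pMax = 0.04, qMax = 0.05, topK = 15,
                          haldane = FALSE) {
  querySet <- unique(querySet); universe <- unique(universe)
  if (!length(querySet) || !length(universe))
    stop("query set and universe must be nonempty")
  if (!all(querySet %in% universe))
    stop("query set must be a subset of the universe")
  ann <- annotations[annotations$gene_id %in% universe, , drop = FALSE]
  ann <- unique(ann[, intersect(c("gene_id", "term_id", "term_name"),
                                colnames(ann)), drop = FALSE])
  if (!nrow(ann)) stop("no annotations overlap the universe")
  N <- length(universe); n <- length(querySet)
  terms <- split(ann$gene_id, ann$term_id)
  K <- lengths(terms)
  k <- vapply(terms, function(g) sum(g %in% querySet), integer(1))
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  q <- bhAdjust(p)
  adj <- if (haldane) 0.5 else 0
  orNum <- (k + adj) * (N - K - n + k + adj)
  orDen <- (n - k + adj) * (K - k + adj)
  or <- ifelse(orDen == 0, ifelse(orNum == 0, NaN, Inf), orNum / orDen)
  tab <- data.frame(term_id = names(terms), k_in_set = unname(k),
                    n_set = n, K_term = unname(K), N_universe = N,
                    p = unname(p), q = unname(q), odds_ratio = unname(or),
                    row.names = NULL)
  if ("term_name" %in% colnames(ann))
    tab$term_name <- ann$term_name[match(tab$term_id, ann$term_id)]
  keep <- tab$p <= pMax & tab$q <= qMax & !is.nan(tab$odds_ratio)
  top <- tab[keep, , drop = FALSE]
  top <- top[order(-top$odds_ratio, top$p, top$term_id), , drop = FALSE]
  top <- utils::head(top, topK)
  rownames(top) <- NULL
  list(table = tab, top = top)
}

#' t-tests of GCI across a gene label table
#'
#' Runs [twoSampleT()] on GCI between the two levels of each binary
#' classification (e.g. essential/nonessential, core/accessory).
#'
#' @param gciValues named numeric vector of GCI (NA excluded).
#' @param labels data.frame with columns `gene_id`, `label` (exactly two
#'   label levels among genes with defined GCI).
#' @param variant passed to [twoSampleT()].
#' @return List with the [twoSampleT()] result plus `label_a`, `label_b`.
#' @export
gciLabelTest <- function(gciValues, labels, variant = "pooled") {
  g <- gciValues[labels$gene_id]
  ok <- !is.na(g)
  lv <- sort(unique(as.character(labels$label[ok])))
  if (length(lv) != 2) stop("need exactly 2 label levels with defined GCI")
  a <- g[ok][labels$label[ok] == lv[1]]
  b <- g[ok][labels$label[ok] == lv[2]]
  res <- twoSampleT(a, b, variant = variant)
  c(res, list(label_a = lv[1], label_b = lv[2]))
}
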