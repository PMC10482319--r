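test_that("condition filters drop missing/zero growth and poor alignments", {
  m <- matrix(rnorm(30), 10, 3)
  ges <- makeGes(m, growth = c(0.5, 0, NA))
  kept <- filterConditions(ges)
  expect_identical(colnames(kept), "e1")
  rep <- S4Vectors::metadata(kept)$filter_report
  expect_identical(unname(rep[c("zero_growth", "missing_growth")]),
                   c(1L, 1L))

  ges2 <- makeGes(matrix(rnorm(20), 10, 2), growth = c(1, 1),
                  alignment = c(85, 79))
  kept2 <- filterConditions(ges2)
  expect_identical(colnames(kept2), "e1")   # 79 < 80 removed

  # 10-column fixture: 2 zero-growth, 1 low-alignment -> 7 kept
  ges3 <- makeGes(matrix(rnorm(100), 10, 10),
                  growth = c(0, 0, rep(1, 8)),
                  alignment = c(rep(95, 9), 60))
  kept3 <- filterConditions(ges3)
  expect_identical(ncol(kept3), 7L)
  expect_error(filterConditions(makeGes(matrix(1:4, 2, 2), growth = c(0, 0))),
               "all experiments removed")
})

test_that("abundance normalization matches the 6+log(a/sum a) formulas", {
  expect_equal(normalizeAbundances(matrix(c(1, 1), 2), "six_plus_ln_frac"),
               matrix(6 + log(0.5), 2), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(normalizeAbundances(matrix(c(1, 1), 2),
                                          "six_plus_log10_frac")[, 1]),
               rep(5.69897, 2), tolerance = 1e-5)
  # zeros replaced by the global min nonzero BEFORE the transform,
  # totals recomputed after replacement
  out <- normalizeAbundances(matrix(c(0, 1, 3), 3), "six_plus_log10_frac")
  expect_equal(unname(out[, 1]), c(6 + log10(0.2), 6 + log10(0.2),
                                   6 + log10(0.6)), tolerance = 1e-12)
  expect_equal(out[1, 1], 5.30103, tolerance = 1e-5)
  expect_equal(out[3, 1], 5.778151, tolerance = 1e-6)
  expect_error(normalizeAbundances(matrix(c(0, 1), 2), "six_plus_ln_frac",
                                   zeroPolicy = "error"), "zero")
  expect_error(normalizeAbundances(matrix(c(0, 0), 2), "six_plus_ln_frac"),
               "all-zero")
  # conservation: implied fractions sum to 1 per column
  set.seed(7)
  raw <- matrix(rpois(60, 20), 12, 5)
  ln <- normalizeAbundances(raw, "six_plus_ln_frac")
  expect_equal(unname(colSums(exp(ln - 6))), rep(1, 5), tolerance = 1e-12)
  l10 <- normalizeAbundances(raw, "six_plus_log10_frac")
  expect_equal(unname(colSums(10^(l10 - 6))), rep(1, 5), tolerance = 1e-12)
})

test_that("replicate averaging merges values, growth and flags per condition", {
  m <- matrix(c(2, 2, 4, 4), 2, 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  ges <- makeGes(m, conditionId = c("c1", "c1"), growth = c(0.5, 0.7))
  avg <- averageReplicates(ges)
  expect_identical(ncol(avg), 1L)
  expect_equal(unname(exprValues(avg)[, 1]), c(3, 3))
  expect_equal(unname(growthRates(avg)), 0.6)

  # idempotence on identical replicates
  m2 <- cbind(a = c(1, 2), b = c(1, 2))
  rownames(m2) <- c("g1", "g2")
  avg2 <- averageReplicates(makeGes(m2, conditionId = c("c", "c"),
                                    growth = c(1, 1)))
  expect_equal(unname(exprValues(avg2)[, 1]), c(1, 2))

  # 6 experiments in 3 conditions of 2 -> 3 columns; flags OR-merged
  m3 <- matrix(rnorm(12), 2, 6)
  ges3 <- makeGes(m3, conditionId = rep(c("c1", "c2", "c3"), each = 2),
                  growth = rep(1, 6),
                  isAle = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  avg3 <- averageReplicates(ges3)
  expect_identical(ncol(avg3), 3L)
  expect_identical(unname(isAle(avg3)), c(TRUE, FALSE, FALSE))

  # grand mean conserved under equal replicate counts
  expect_equal(mean(exprValues(avg3)), mean(m3), tolerance = 1e-12)
})

test_that("duplicate profiles are found by rank correlation and excluded", {
  m <- cbind(a = c(1, 2, 3, 5), b = c(1, 2, 3, 5), c = c(4, 1, 2, 8))
  rownames(m) <- paste0("g", 1:4)
  d <- detectDuplicateProfiles(makeGes(m, growth = 1:3))
  expect_identical(nrow(d$pairs), 1L)
  expect_identical(sort(c(d$pairs$a, d$pairs$b)), c("a", "b"))

  # monotone transform still has rho = 1
  m2 <- cbind(a = c(1, 2, 3), b = c(10, 20, 30), c = c(3, 1, 2))
  rownames(m2) <- paste0("g", 1:3)
  d2 <- detectDuplicateProfiles(makeGes(m2, growth = 1:3))
  expect_identical(sort(c(d2$pairs$a, d2$pairs$b)), c("a", "b"))

  # constant column reported separately, never as duplicate
  m3 <- cbind(a = c(1, 1, 1), b = c(1, 2, 3), c = c(2, 9, 4))
  rownames(m3) <- paste0("g", 1:3)
  d3 <- detectDuplicateProfiles(makeGes(m3, growth = 1:3))
  expect_identical(d3$undefined, "a")
  expect_identical(nrow(d3$pairs), 0L)

  # 5-column fixture with exactly one injected duplicate pair
  set.seed(11)
  m5 <- matrix(rnorm(100), 20, 5,
               dimnames = list(paste0("g", 1:20), paste0("e", 1:5)))
  m5[, 4] <- m5[, 2]
  d5 <- detectDuplicateProfiles(makeGes(m5, growth = 1:5))
  expect_identical(nrow(d5$pairs), 1L)
  expect_identical(sort(c(d5$pairs$a, d5$pairs$b)), c("e2", "e4"))

  # default policy drops both members
  ex <- excludeDuplicateProfiles(makeGes(m5, growth = 1:5))
  expect_identical(colnames(ex), c("e1", "e3", "e5"))
  ex1 <- excludeDuplicateProfiles(makeGes(m5, growth = 1:5),
                                  policy = "keep_one")
  expect_identical(colnames(ex1), c("e1", "e2", "e3", "e5"))
})

test_that("sparse pruning is seeded, deterministic, and lowers the max correlation", {
  set.seed(3)
  m <- matrix(rnorm(200), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("e", 1:10)))
  ges <- makeGes(m, growth = seq(0.1, 1, 0.1))
  # no-op when target equals current count
  same <- pruneToSparse(ges, targetN = 10, seed = 1)
  expect_identical(colnames(same), colnames(ges))
  expect_identical(nrow(S4Vectors::metadata(same)$prune_log), 0L)

  # forced removal of one member of an identical pair
  m3 <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(4, 2, 6, 1))
  rownames(m3) <- paste0("g", 1:4)
  p3 <- pruneToSparse(makeGes(m3, growth = 1:3), targetN = 2, seed = 5)
  expect_identical(ncol(p3), 2L)
  expect_true("c" %in% colnames(p3))

  # determinism under a fixed seed
  p1 <- pruneToSparse(ges, targetN = 5, seed = 99)
  p2 <- pruneToSparse(ges, targetN = 5, seed = 99)
  expect_identical(S4Vectors::metadata(p1)$prune_log,
                   S4Vectors::metadata(p2)$prune_log)
  expect_identical(colnames(p1), colnames(p2))

  # surviving max pairwise correlation never exceeds the input's global max
  rhoMax <- function(x) {
    r <- cor(exprValues(x), method = "spearman"); diag(r) <- -Inf; max(r)
  }
  for (s in 1:5)
    expect_lte(rhoMax(pruneToSparse(ges, targetN = 5, seed = s)),
               rhoMax(ges) + 1e-12)
})

test_that("neutral subsets apply the ALE and mutant/KO exclusions", {
  m <- matrix(rnorm(40), 10, 4)
  ges <- makeGes(m, growth = 1:4,
                 isAle = c(TRUE, TRUE, FALSE, FALSE),
                 isMut = c(FALSE, FALSE, TRUE, FALSE))
  ns <- neutralSubsets(ges)
  expect_identical(ncol(ns$non_ale), 2L)
  expect_identical(ncol(ns$non_ale_wildtype), 1L)
  expect_identical(colnames(ns$non_ale_wildtype), "e4")

  allF <- neutralSubsets(makeGes(m, growth = 1:4))
  expect_identical(ncol(allF$non_ale), 4L)
  expect_identical(ncol(allF$non_ale_wildtype), 4L)
})

test_that("gene-set dropping removes present ids and counts absent ones", {
  m <- matrix(rnorm(40), 10, 4,
              dimnames = list(paste0("g", 1:10), paste0("e", 1:4)))
  ges <- makeGes(m, growth = 1:4)
  expect_identical(nrow(dropGeneSet(ges, character(0))), 10L)
  out <- dropGeneSet(ges, c("g1", "g5"))
  expect_identical(nrow(out), 8L)
  expect_false(any(c("g1", "g5") %in% rownames(out)))
  expect_message(out2 <- dropGeneSet(ges, "not_a_gene"), "ignored")
  expect_identical(nrow(out2), 10L)
  expect_identical(unname(S4Vectors::metadata(out2)$genes_dropped["absent"]),
                   1L)
})

test_that("expression TSV round-trips through read/write", {
  m <- matrix(rnorm(12), 3, 4,
              dimnames = list(paste0("g", 1:3), paste0("e", 1:4)))
  ges <- makeGes(m, conditionId = c("c1", "c1", "c2", "c2"),
                 growth = c(0.5, 0.5, 1, 1), alignment = 90)
  ePath <- withr::local_tempfile(fileext = ".tsv")
  mPath <- withr::local_tempfile(fileext = ".tsv")
  writeExpressionMatrix(ges, ePath, mPath)
  back <- readExpressionMatrix(ePath, mPath)
  expect_equal(exprValues(back), exprValues(ges), tolerance = 1e-9)
  expect_identical(unname(conditionIds(back)), unname(conditionIds(ges)))
  expect_equal(unname(growthRates(back)), unname(growthRates(ges)))
})
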