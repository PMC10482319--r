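test_that("FASTA reading preserves records, canonicalizes case, fixes duplicates", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">geneA some description", "atggctTAA", ">geneB", "ATGAAATAG"),
             fa)
  cds <- readCds(fa)
  expect_length(cds, 2)
  expect_identical(names(cds), c("geneA", "geneB"))
  expect_identical(as.character(cds[["geneA"]]), "ATGGCTTAA")

  writeLines(c(">x", "ATG", ">x", "GCT", ">x", "AAA"), fa)
  expect_warning(dup <- readCds(fa), "duplicate")
  expect_identical(names(dup), c("x", "x_dup1", "x_dup2"))

  writeLines(character(0), fa)
  expect_error(readCds(fa), "no coding sequences")
  expect_error(readCds(file.path(tempdir(), "absent.fa")), "read")
})

test_that("GenBank extraction takes CDS features only, splicing strand and joins", {
  gb <- system.file("extdata", "synthetic_small.gb", package = "growthCUB")
  cds <- readCds(gb, format = "genbank")
  expect_length(cds, 3)   # the tRNA feature is skipped
  expect_identical(names(cds), c("SYN_0001", "SYN_0002", "SYN_0003"))
  expect_identical(as.character(cds[["SYN_0001"]]), "ATGGCTAAAGGCTCCTAA")
  # minus-strand feature comes back reverse-complemented
  expect_identical(as.character(cds[["SYN_0002"]]), "ATGCCCGGGTTTACCTAA")
  # join() location spliced in order
  expect_identical(as.character(cds[["SYN_0003"]]), "ATGGATCGATCTTGGTAA")
  expect_identical(S4Vectors::mcols(cds)$declared_length, rep(18L, 3))
})

test_that("CDS filters remove frame violations, length mismatches and giants", {
  mk <- function(lens) {
    s <- Biostrings::DNAStringSet(vapply(lens, function(L)
      paste(rep("A", L), collapse = ""), character(1)))
    names(s) <- paste0("g", seq_along(lens))
    s
  }
  all300 <- filterCds(mk(rep(300, 5)))
  expect_length(all300$kept, 5)
  expect_identical(nrow(all300$removed), 0L)

  div3 <- filterCds(mk(c(300, 301, 300)))
  expect_identical(div3$removed$id, "g2")
  expect_identical(div3$removed$reason, "not_multiple_of_3")

  # median computed over ALL inputs before removal: median 30, cutoff 150
  tooLong <- filterCds(mk(c(30, 30, 30, 30, 300)))
  expect_identical(tooLong$removed$id, "g5")
  expect_identical(tooLong$removed$reason, "too_long")
  expect_length(tooLong$kept, 4)

  s <- mk(c(300, 300))
  S4Vectors::mcols(s) <- S4Vectors::DataFrame(declared_length = c(300L, 299L))
  mism <- filterCds(s)
  expect_identical(mism$removed$id, "g2")
  expect_identical(mism$removed$reason, "length_mismatch")

  expect_error(filterCds(Biostrings::DNAStringSet()), "nonempty")
})

test_that("codon counting respects frame, flags, and ambiguity", {
  expect_identical(codonCounts("ATGGCT"), c(ATG = 1L, GCT = 1L))
  expect_identical(codonCounts("ATGGCTTAA", dropStop = TRUE),
                   c(ATG = 1L, GCT = 1L))
  expect_identical(codonCounts("ATGGCTTAA", dropStop = FALSE),
                   c(ATG = 1L, GCT = 1L, TAA = 1L))
  expect_identical(codonCounts("ATGNNNGCT"),
                   c(ATG = 1L, GCT = 1L, ambiguous = 1L))
  expect_identical(codonCounts("ATGGCTGCT", dropStart = TRUE),
                   c(GCT = 2L))
  # dropStop only removes an actual stop codon
  expect_identical(codonCounts("ATGGCT", dropStop = TRUE),
                   c(ATG = 1L, GCT = 1L))
  expect_error(codonCounts("ATGG"), "frame")
})

test_that("CUB score is the geometric mean of codon weights", {
  expect_equal(cubScore("ATGGCTAAA", flatWeightTable(1)),
               c(`1` = 1), ignore_attr = TRUE)
  # two codons with weights 1.0 and 0.25 -> sqrt(0.25) = 0.5
  wt <- customWeightTable(c("ATG", "GCT"), c(1, 0.25))
  expect_equal(unname(cubScore(Biostrings::DNAStringSet(c(x = "ATGGCT")), wt)),
               0.5, tolerance = 1e-12)
  # frozen 6-codon value, verified with the direct product oracle
  w6 <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
  cods <- c("GCA", "GCC", "GCG", "GCT", "AAA", "AAG")
  wt6 <- customWeightTable(cods, w6)
  s6 <- Biostrings::DNAStringSet(c(g = paste(cods, collapse = "")))
  expect_equal(unname(cubScore(s6, wt6)), 0.6265205, tolerance = 1e-6)
  expect_equal(unname(cubScore(s6, wt6)), prodRootOracle(w6),
               tolerance = 1e-12)
})

test_that("CUB scoring handles stop/start flags, ambiguity and errors", {
  wt <- customWeightTable(c("ATG", "GCT"), c(0.5, 0.25))
  ss <- Biostrings::DNAStringSet(c(a = "ATGGCTTAA"))
  expect_equal(unname(cubScore(ss, wt, dropStop = TRUE)),
               sqrt(0.5 * 0.25), tolerance = 1e-12)
  # with the stop retained there is no TAA weight -> missing-weight error
  expect_error(cubScore(ss, wt, dropStop = FALSE), "TAA")
  expect_equal(unname(cubScore(ss, wt, dropStop = TRUE, dropStart = TRUE)),
               0.25, tolerance = 1e-12)
  # ambiguous codons drop out of numerator and denominator
  amb <- Biostrings::DNAStringSet(c(a = "ATGNNNGCT"))
  expect_equal(unname(cubScore(amb, wt)), sqrt(0.5 * 0.25),
               tolerance = 1e-12)
  expect_error(cubScore(Biostrings::DNAStringSet(c(a = "TAA")), wt,
                        dropStop = TRUE), "no scorable")
  expect_error(cubScore(Biostrings::DNAStringSet(c(a = "ATGGC")), wt),
               "divisible by 3")
})

test_that("CUB score properties: length invariance, concatenation, range, oracle", {
  set.seed(42)
  gc <- Biostrings::GENETIC_CODE
  sense <- sort(names(gc)[gc != "*"])
  wt <- makeIllustrativeWeightTable("CAI")
  w <- codonWeights(wt)
  for (rep in 1:20) {
    n1 <- sample(2:10, 1); n2 <- sample(2:10, 1)
    c1 <- sample(sense, n1, replace = TRUE)
    c2 <- sample(sense, n2, replace = TRUE)
    s1 <- paste(c1, collapse = ""); s2 <- paste(c2, collapse = "")
    sc <- function(x) unname(cubScore(Biostrings::DNAStringSet(x), wt,
                                      dropStop = FALSE))
    # self-concatenation leaves the score unchanged
    expect_equal(sc(paste0(s1, s1)), sc(s1), tolerance = 1e-12)
    # concatenation = length-weighted geometric mean
    expect_equal(sc(paste0(s1, s2)),
                 (sc(s1)^n1 * sc(s2)^n2)^(1 / (n1 + n2)), tolerance = 1e-9)
    # all weights <= 1 -> score in (0, 1]
    expect_gt(sc(s1), 0); expect_lte(sc(s1), 1)
    # log-space computation matches direct product-then-root
    expect_equal(sc(s1), prodRootOracle(w[c1]), tolerance = 1e-12)
  }
})

test_that("weight table loading validates range, codons, and coverage", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gc <- Biostrings::GENETIC_CODE
  sense <- sort(names(gc)[gc != "*"])
  df <- data.frame(codon = sense, weight = seq(0.1, 1, length.out = 61))
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  wt <- loadWeightTable(tsv, "CAI")
  expect_s4_class(wt, "CodonWeightTable")
  expect_length(codonWeights(wt), 61)
  expect_identical(metricName(wt), "CAI")

  df0 <- df; df0$weight[5] <- 0
  write.table(df0, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(loadWeightTable(tsv, "CAI"), "pseudo-weight")

  dfm <- df[-10, ]
  write.table(dfm, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(wt60 <- loadWeightTable(tsv, "CAI"), df$codon[10])
  expect_length(codonWeights(wt60), 60)

  dfb <- df; dfb$codon[1] <- "AXG"
  write.table(dfb, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(loadWeightTable(tsv, "CAI"), "malformed")
})

test_that("gene score TSV round-trips", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeGeneScores(list(CAI = c(g1 = 0.5, g2 = 0.75), tAI = c(g1 = 0.4)),
                  path)
  tab <- read.delim(path)
  expect_identical(nrow(tab), 3L)
  expect_identical(sort(unique(tab$metric)), c("CAI", "tAI"))
  expect_equal(tab$value[tab$gene_id == "g2" & tab$metric == "CAI"], 0.75)
})
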