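#' Read coding sequences from FASTA or GenBank
#'
#' Reads a collection of coding sequences (CDS). For FASTA the whole file is
#' read, one record per CDS, ids taken as the first whitespace-delimited token
#' of each header. For GenBank flat files only features annotated as CDS are
#' extracted and spliced from the `ORIGIN` sequence (simple, `complement()`
#' and `join()` locations are supported); ids are taken from `/locus_tag`,
#' falling back to `/gene`.
#'
#' Sequences are upper-cased. Duplicate ids are disambiguated with a
#' deterministic `_dup<k>` suffix and a warning. For GenBank input, the
#' declared span of the feature location is kept in `mcols()$declared_length`
#' together with strand/coordinate text in `mcols()$source_meta`, so that
#' [filterCds()] can check declared against counted length.
#'
#' @param path path to the input file (FASTA may be gzipped).
#' @param format `"fasta"` or `"genbank"`.
#' @return A [Biostrings::DNAStringSet] with one element per CDS, in file
#'   order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">geneA", "atggctTAA", ">geneB", "ATGAAATAG"), fa)
#' readCds(fa)
#' @export
readCds <- function(path, format = c("fasta", "genbank")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read file: ", path)
  if (format == "fasta") {
    dss <- Biostrings::readDNAStringSet(path)
    if (length(dss) == 0L) stop("no coding sequences found in ", path)
    ids <- sub("\\s.*$", "", names(dss))
    seqs <- toupper(as.character(dss))
    meta <- DataFrame(source_meta = rep(NA_character_, length(ids)),
                      declared_length = rep(NA_integer_, length(ids)))
  } else {
    rec <- .parseGenbankCds(path)
    if (length(rec$seq) == 0L) stop("no coding sequences found in ", path)
    ids <- rec$id
    seqs <- rec$seq
    meta <- DataFrame(source_meta = rec$location,
                      declared_length = rec$declared_length)
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    warning("duplicate CDS id(s) disambiguated: ",
            paste(dup, collapse = ", "))
    ids <- .disambiguate(ids)
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  mcols(out) <- meta
  out
}

.disambiguate <- function(ids) {
  for (d in unique(ids[duplicated(ids)])) {
    at <- which(ids == d)
    ids[at[-1]] <- paste0(d, "_dup", seq_along(at[-1]))
  }
  ids
}

# Minimal GenBank flat-file CDS extractor: feature table keys start at column
# 6, qualifiers at column 22; ORIGIN blocks hold the sequence. Handles
# location forms start..end, complement(...), join(...), and <, > partial
# markers. Enough for curated bacterial-style records.
.parseGenbankCds <- function(path) {
  lines <- readLines(path, warn = FALSE)
  o <- grep("^ORIGIN", lines)
  if (!length(o)) stop("malformed GenBank file (no ORIGIN): ", path)
  seq_lines <- lines[(o[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  genome <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  f <- grep("^FEATURES", lines)
  if (!length(f)) stop("malformed GenBank file (no FEATURES): ", path)
  feat <- lines[(f[1] + 1L):(o[1] - 1L)]

  keys <- grepl("^ {5}\\S", feat)
  idx <- cumsum(keys)
  ids <- character(); locs <- character(); seqs <- character()
  decl <- integer()
  for (b in unique(idx[idx > 0])) {
    block <- feat[idx == b]
    key <- sub("^ {5}(\\S+).*$", "\\1", block[1])
    if (key != "CDS") next
    hdr <- sub("^ {5}\\S+\\s+", "", block[1])
    # location may continue onto lines before the first qualifier
    qual_at <- grep("^ {21}/", block)
    loc_end <- if (length(qual_at)) qual_at[1] - 1L else length(block)
    loc <- paste0(hdr, paste(trimws(block[seq_len(loc_end)][-1]),
                             collapse = ""))
    loc <- gsub("\\s", "", loc)
    quals <- paste(trimws(block[-seq_len(loc_end)]), collapse = " ")
    id <- .gbQualifier(quals, "locus_tag")
    if (is.na(id)) id <- .gbQualifier(quals, "gene")
    if (is.na(id)) id <- paste0("CDS_", length(ids) + 1L)
    parsed <- .gbLocation(loc)
    pieces <- vapply(seq_len(nrow(parsed$ranges)), function(i) {
      substr(genome, parsed$ranges[i, 1], parsed$ranges[i, 2])
    }, character(1))
    s <- paste(pieces, collapse = "")
    if (parsed$complement)
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    ids <- c(ids, id); locs <- c(locs, loc); seqs <- c(seqs, s)
    decl <- c(decl, sum(parsed$ranges[, 2] - parsed$ranges[, 1] + 1L))
  }
  list(id = ids, location = locs, seq = seqs, declared_length = decl)
}

.gbQualifier <- function(quals, name) {
  pat <- paste0("/", name, "=\"([^\"]+)\"")
  m <- regmatches(quals, regexec(pat, quals))[[1]]
  if (length(m) == 2L) m[2] else NA_character_
}

.gbLocation <- function(loc) {
  complement <- grepl("complement\\(", loc)
  inner <- gsub("complement\\(|join\\(|\\)|<|>", "", loc)
  parts <- strsplit(inner, ",", fixed = TRUE)[[1]]
  rng <- t(vapply(parts, function(p) {
    se <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    if (length(se) == 1L) se <- c(se, se)
    se
  }, integer(2)))
  if (complement) rng <- rng[rev(seq_len(nrow(rng))), , drop = FALSE]
  list(ranges = rng, complement = complement)
}

#' Quality-filter coding sequences
#'
#' Applies the CDS quality rules used before codon usage bias scoring: the
#' sequence length must be divisible by 3; when a declared length is present
#' (GenBank coordinates) it must agree with the counted base length; and
#' unrealistically long sequences, longer than `maxLenFactor` times the
#' median length over *all* input records (median taken before any removal),
#' are excluded.
#'
#' @param records [Biostrings::DNAStringSet] from [readCds()].
#' @param maxLenFactor positive multiple of the median length above which a
#'   CDS is considered unrealistically long (default 5).
#' @return A list with `kept` (a `DNAStringSet`) and `removed` (a
#'   [S4Vectors::DataFrame] with columns `id`, `length`, `reason`; reasons are
#'   `"not_multiple_of_3"`, `"length_mismatch"`, `"too_long"`).
#' @examples
#' s <- Biostrings::DNAStringSet(c(a = "ATGGCT", b = "ATGGC"))
#' filterCds(s)$removed
#' @export
filterCds <- function(records, maxLenFactor = 5) {
  if (length(records) == 0L) stop("records must be nonempty")
  stopifnot(maxLenFactor > 0)
  len <- Biostrings::width(records)
  med <- stats::median(len)
  decl <- if (!is.null(mcols(records)$declared_length))
    mcols(records)$declared_length else rep(NA_integer_, length(records))
  reason <- rep(NA_character_, length(records))
  reason[len %% 3L != 0L] <- "not_multiple_of_3"
  mism <- is.na(reason) & !is.na(decl) & decl != len
  reason[mism] <- "length_mismatch"
  reason[is.na(reason) & len > maxLenFactor * med] <- "too_long"
  drop <- !is.na(reason)
  list(kept = records[!drop],
       removed = DataFrame(id = names(records)[drop],
                           length = len[drop],
                           reason = reason[drop]))
}

#' Count codons of a coding sequence
#'
#' Counts successive non-overlapping triplets read 5'->3' in frame 0. Codons
#' containing ambiguous bases (N) are tallied under the `"ambiguous"` key and
#' are never scored. The terminal codon is excluded when `dropStop` is set and
#' it is a stop codon (TAA/TAG/TGA); the first codon is excluded when
#' `dropStart` is set.
#'
#' @param x a single sequence: character string, [Biostrings::DNAString], or
#'   length-1 `DNAStringSet`.
#' @param dropStop,dropStart logical flags, see Description.
#' @return Named integer vector of codon counts (only observed codons), with
#'   an `"ambiguous"` entry when N-containing codons occur.
#' @examples
#' codonCounts("ATGGCTTAA", dropStop = TRUE)
#' @export
codonCounts <- function(x, dropStop = FALSE, dropStart = FALSE) {
  s <- toupper(as.character(x))
  if (length(s) != 1L) stop("codonCounts expects a single sequence")
  n <- nchar(s)
  if (n %% 3L != 0L)
    stop("sequence length ", n, " is not divisible by 3 (frame error)")
  cod <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
  if (dropStop && length(cod) && cod[length(cod)] %in% .STOP_CODONS)
    cod <- cod[-length(cod)]
  if (dropStart && length(cod)) cod <- cod[-1L]
  amb <- grepl("[^ACGT]", cod)
  out <- table(cod[!amb])
  counts <- stats::setNames(as.integer(out), names(out))
  if (any(amb)) counts <- c(counts, ambiguous = sum(amb))
  counts
}

#' Codon usage bias score of coding sequences
#'
#' Computes the CUB score of each sequence under a [CodonWeightTable-class]:
#' the geometric mean of the weights of the scored codons,
#' `exp(mean(log w))`, evaluated in log space to avoid underflow on long
#' genes. Ambiguous (N-containing) codons are excluded from both the product
#' and the codon count. By default the terminal stop codon is dropped
#' (standard CAI/tAI tables carry no stop-codon weights) and the start codon
#' is kept.
#'
#' @param records a [Biostrings::DNAStringSet] (or single sequence accepted by
#'   [codonCounts()]); lengths must be divisible by 3 (use [filterCds()]).
#' @param table a [CodonWeightTable-class].
#' @param dropStop drop a terminal stop codon before scoring (default TRUE).
#' @param dropStart drop the first codon before scoring (default FALSE).
#' @return Named numeric vector of scores in (0, 1], one per sequence.
#' @examples
#' wt <- makeIllustrativeWeightTable("CAI")
#' cubScore(Biostrings::DNAStringSet(c(g1 = "ATGGCTGCTTAA")), wt)
#' @export
cubScore <- function(records, table, dropStop = TRUE, dropStart = FALSE) {
  stopifnot(is(table, "CodonWeightTable"))
  if (!is(records, "DNAStringSet"))
    records <- Biostrings::DNAStringSet(toupper(as.character(records)))
  if (any(Biostrings::width(records) %% 3L != 0L))
    stop("all sequence lengths must be divisible by 3 (run filterCds first)")
  counts <- Biostrings::trinucleotideFrequency(records, step = 3)
  if (dropStop) {
    last <- substring(as.character(Biostrings::subseq(
      records, start = Biostrings::width(records) - 2L)), 1L, 3L)
    hit <- last %in% .STOP_CODONS
    if (any(hit))
      counts[cbind(which(hit), match(last[hit], colnames(counts)))] <-
        counts[cbind(which(hit), match(last[hit], colnames(counts)))] - 1L
  }
  if (dropStart) {
    first <- substring(as.character(records), 1L, 3L)
    ok <- !grepl("[^ACGT]", first)
    counts[cbind(which(ok), match(first[ok], colnames(counts)))] <-
      counts[cbind(which(ok), match(first[ok], colnames(counts)))] - 1L
  }
  used <- colSums(counts) > 0L
  missing <- setdiff(colnames(counts)[used], names(codonWeights(table)))
  if (length(missing))
    stop("no weight for codon(s): ", paste(missing, collapse = ", "),
         " in table '", metricName(table), "'")
  counts <- counts[, used, drop = FALSE]
  logw <- log(codonWeights(table))[colnames(counts)]
  L <- rowSums(counts)
  if (any(L == 0L))
    stop("sequence(s) with no scorable codons: ",
         paste(names(records)[L == 0L], collapse = ", "))
  score <- exp(as.vector(counts %*% logw) / L)
  stats::setNames(score, names(records))
}

#' Load a codon weight table from TSV
#'
#' Reads a tab-separated table with columns `codon` and `weight` defining a
#' CUB metric. Weights must lie in (0, 1]; a weight of exactly 0 is rejected
#' because it would zero every geometric mean it touches (use a small positive
#' pseudo-weight explicitly if that is intended). A table covering only a
#' subset of the 61 sense codons is accepted with a warning listing the
#' missing codons.
#'
#' @param path TSV file with columns `codon`, `weight`.
#' @param metricName name of the metric the weights define (e.g. "CAI").
#' @param provenance citation string stored alongside the weights.
#' @return A [CodonWeightTable-class].
#' @export
loadWeightTable <- function(path, metricName,
                            provenance = paste0("loaded from ", path)) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("codon", "weight") %in% colnames(tab)))
    stop("weight TSV must have columns 'codon' and 'weight'")
  cod <- toupper(tab$codon)
  if (any(!grepl("^[ACGT]{3}$", cod)))
    stop("malformed codon string(s): ",
         paste(tab$codon[!grepl("^[ACGT]{3}$", cod)], collapse = ", "))
  w <- as.numeric(tab$weight)
  if (any(!is.finite(w)) || any(w <= 0) || any(w > 1))
    stop("weights must lie in (0, 1]; found ",
         paste(unique(w[!is.finite(w) | w <= 0 | w > 1]), collapse = ", "),
         ". A weight of 0 would zero the geometric mean; supply a small",
         " positive pseudo-weight explicitly if intended.")
  miss <- setdiff(.SENSE_CODONS, cod)
  if (length(miss))
    warning("weight table covers ", length(cod), "/61 sense codons; missing: ",
            paste(miss, collapse = ", "))
  new("CodonWeightTable", metricName = metricName,
      weights = stats::setNames(w, cod), provenance = provenance)
}

#' Illustrative codon weight tables
#'
#' Builds a deterministic, clearly synthetic weight table over all 61 sense
#' codons for examples and simulations: within each synonymous family the
#' codons (alphabetical) get weights `(i/k)^shape` for `i = 1..k`, so every
#' family's preferred codon has weight 1 (the classic convention, which also
#' gives single-codon families ATG and TGG weight 1). These are **not**
#' published CAI or tAI weights; real analyses should load published tables
#' with [loadWeightTable()].
#'
#' @param metricName `"CAI"` (shape 1) or `"tAI"` (shape 1.5), or any name
#'   with an explicit `shape`.
#' @param shape positive exponent controlling how steeply within-family
#'   weights fall off; default chosen by `metricName`.
#' @return A [CodonWeightTable-class] flagged as illustrative.
#' @export
makeIllustrativeWeightTable <- function(metricName = c("CAI", "tAI"),
                                        shape = NULL) {
  metricName <- metricName[1]
  if (is.null(shape)) shape <- if (identical(metricName, "tAI")) 1.5 else 1
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[.SENSE_CODONS]
  w <- unlist(lapply(split(.SENSE_CODONS, aa), function(cods) {
    k <- length(cods)
    stats::setNames((seq_len(k) / k)^shape, sort(cods))
  }), use.names = TRUE)
  names(w) <- sub("^.*\\.", "", names(w))
  new("CodonWeightTable", metricName = metricName,
      weights = w[.SENSE_CODONS],
      provenance = "illustrative synthetic weights (not published values)")
}

#' Write per-gene CUB scores as TSV
#'
#' @param scores named numeric vector from [cubScore()], or a list of such
#'   vectors named by metric.
#' @param path output TSV path (columns `gene_id`, `metric`, `value`).
#' @param metricName metric label when `scores` is a bare vector.
#' @return `path`, invisibly.
#' @export
writeGeneScores <- function(scores, path, metricName = "CUB") {
  if (!is.list(scores)) scores <- stats::setNames(list(scores), metricName)
  rows <- do.call(rbind, lapply(names(scores), function(m) {
    data.frame(gene_id = names(scores[[m]]), metric = m,
               value = unname(scores[[m]]))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
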