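#' @importFrom stats optim sd setNames t.test
#' @importFrom utils write.table head
NULL

## map a character vector of aligned sequences to the 1-based state coding;
## anything outside the alphabet (B, Z, X, U, O, ".", ...) becomes the gap.
.codeSequences <- function(sequences, alphabet) {
  q <- length(alphabet)
  lut <- setNames(seq_len(q), alphabet)
  mat <- do.call(rbind, strsplit(sequences, ""))
  codes <- matrix(lut[mat], nrow = nrow(mat))
  codes[is.na(codes)] <- 1L
  storage.mode(codes) <- "integer"
  codes
}

#' Construct a CodedAlignment from character sequences
#'
#' @param sequences equal-length aligned sequences (uppercase; gap "-").
#' @param ids sequence identifiers.
#' @param queryId identifier of the query sequence (default: first).
#' @param q alphabet size (21 for protein families; smaller for synthetic
#'   families).
#' @return a [CodedAlignment-class] object.
#' @export
codedAlignment <- function(sequences, ids = NULL, queryId = NULL, q = 21L) {
  if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
  if (is.null(queryId)) queryId <- ids[1L]
  qi <- match(queryId, ids)
  if (is.na(qi)) stop("query id '", queryId, "' not found in the alignment")
  alphabet <- alloAlphabet(q)
  sequences <- unname(toupper(sequences))
  new("CodedAlignment", sequences = sequences, ids = as.character(ids),
      queryIndex = as.integer(qi),
      codes = .codeSequences(sequences, alphabet),
      alphabet = alphabet)
}

.parseStockholm <- function(lines) {
  lines <- lines[!grepl("^\\s*$", lines)]
  rf <- NULL
  seqs <- list()
  for (ln in lines) {
    if (grepl("^#=GC\\s+RF\\s+", ln)) {
      rf <- paste0(rf, sub("^#=GC\\s+RF\\s+", "", ln))
    } else if (!grepl("^#", ln) && !grepl("^//", ln)) {
      parts <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(parts) == 2L)
        seqs[[parts[1]]] <- paste0(seqs[[parts[1]]], parts[2])
    }
  }
  list(ids = names(seqs), sequences = unlist(seqs, use.names = FALSE), rf = rf)
}

#' Read a multiple sequence alignment
#'
#' FASTA input is treated as a2m-style: lowercase and "." characters are
#' per-sequence insert states and are removed before coding. Stockholm input
#' uses the `#=GC RF` annotation to select match columns when present;
#' otherwise columns containing any lowercase/"." character are dropped.
#'
#' @param path file path.
#' @param format "fasta" or "stockholm".
#' @param queryId identifier of the query sequence (matched against the first
#'   whitespace-delimited token of each header).
#' @param q alphabet size, default 21.
#' @return a [CodedAlignment-class].
#' @export
readAlignment <- function(path, format = c("fasta", "stockholm"), queryId,
                          q = 21L) {
  format <- match.arg(format)
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    ids <- sub("\\s.*$", "", names(ss))
    raw <- as.character(ss)
    sequences <- gsub("[a-z.]", "", raw)
    if (length(unique(nchar(sequences))) != 1L)
      stop("sequences have unequal lengths after insert-state removal; ",
           "input is not a consistent a2m/FASTA alignment")
  } else {
    st <- .parseStockholm(readLines(path))
    ids <- sub("/.*$", "", st$ids)
    if (length(unique(nchar(st$sequences))) != 1L)
      stop("Stockholm block widths are inconsistent")
    chars <- do.call(rbind, strsplit(st$sequences, ""))
    keep <- if (!is.null(st$rf)) {
      !strsplit(st$rf, "")[[1]] %in% c(".", "~")
    } else {
      apply(chars, 2, function(col) !any(grepl("[a-z.]", col)))
    }
    sequences <- apply(chars[, keep, drop = FALSE], 1, paste, collapse = "")
    sequences <- chartr(".", "-", sequences)
  }
  if (!queryId %in% ids)
    stop("query id '", queryId, "' not present in ", path)
  codedAlignment(sequences, ids = ids, queryId = queryId, q = q)
}

#' Write the processed alignment as normalized FASTA
#' @param aln a [CodedAlignment-class].
#' @param path output file.
#' @export
writeAlignmentFasta <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", aln@ids, "\n", toupper(aln@sequences)), con)
  invisible(path)
}

#' Identity-based sequence reweighting
#'
#' Each sequence receives weight 1/k where k is the number of alignment rows
#' (itself included) at or above the identity threshold. The sum of weights
#' is the effective number of sequences Neff. The default threshold of 0.80
#' is the standard 80%-identity reweighting used in coevolution analysis.
#'
#' @param aln a [CodedAlignment-class].
#' @param identityThreshold identity fraction in (0, 1].
#' @param nonGapOnly if TRUE, identity is computed over columns where both
#'   sequences are non-gap; by default all columns count and gap-gap is a
#'   match.
#' @return a [SequenceWeights-class].
#' @export
computeWeights <- function(aln, identityThreshold = 0.80, nonGapOnly = FALSE) {
  stopifnot(identityThreshold > 0, identityThreshold <= 1)
  if (alnDepth(aln) < 1L) stop("empty alignment")
  w <- cpp_pair_weights(alnCodes(aln), identityThreshold, nonGapOnly)
  new("SequenceWeights", weights = as.numeric(w), neff = sum(w),
      identityThreshold = identityThreshold)
}

#' Write per-sequence weights as TSV (columns: id, weight)
#' @param aln a [CodedAlignment-class].
#' @param w matching [SequenceWeights-class].
#' @param path output file.
#' @export
writeWeightsTsv <- function(aln, w, path) {
  write.table(data.frame(id = seqIds(aln), weight = seqWeights(w)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' EmpiricalFrequencies: weighted single-site and pairwise frequencies
#'
#' @slot fi L x q single-site frequencies.
#' @slot fij L x L x q x q pairwise co-occurrence frequencies.
#' @slot pseudocount smoothing fraction mixed with the uniform distribution.
#' @export
setClass("EmpiricalFrequencies",
  representation(fi = "matrix", fij = "array", pseudocount = "numeric"))

#' Weighted empirical frequencies of an alignment
#'
#' Weighted counts are normalized by Neff and, when `pseudocount` > 0, mixed
#' with the uniform distribution: f <- (1 - pc) * f + pc / q (pairwise:
#' pc / q^2). At pseudocount 0 the pairwise marginals are consistent with
#' the single-site frequencies. The PLM fit does not use pseudocounts (it
#' regularizes via L2); this is primarily a reporting/diagnostic operation
#' and is quadratic in L and alphabet size in memory.
#'
#' @param aln a [CodedAlignment-class].
#' @param w a matching [SequenceWeights-class].
#' @param pseudocount smoothing fraction in \[0, 1).
#' @return an [EmpiricalFrequencies-class].
#' @export
computeFrequencies <- function(aln, w, pseudocount = 0) {
  stopifnot(pseudocount >= 0, pseudocount < 1)
  codes <- alnCodes(aln)
  n <- nrow(codes); L <- ncol(codes); q <- alphabetSize(aln)
  ws <- seqWeights(w)
  if (length(ws) != n) stop("weights do not match the alignment")
  ne <- sum(ws)
  ind <- lapply(seq_len(L), function(i) {
    m <- matrix(0, n, q)
    m[cbind(seq_len(n), codes[, i])] <- 1
    m
  })
  indW <- lapply(ind, function(m) m * ws)
  fi <- do.call(rbind, lapply(indW, colSums)) / ne
  fij <- array(0, dim = c(L, L, q, q))
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      fij[i, j, , ] <- crossprod(indW[[i]], ind[[j]]) / ne
    }
  }
  if (pseudocount > 0) {
    fi <- (1 - pseudocount) * fi + pseudocount / q
    fij <- (1 - pseudocount) * fij + pseudocount / (q * q)
  }
  new("EmpiricalFrequencies", fi = fi, fij = fij, pseudocount = pseudocount)
}
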