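## zero-sum gauge: subtract row and column means, add back the grand mean
.centerBlock <- function(B) {
  B - outer(rowMeans(B), rep(1, ncol(B))) -
    outer(rep(1, nrow(B)), colMeans(B)) + mean(B)
}

#' Frobenius-norm coupling strengths
#'
#' For every column pair the q x q coupling block is transformed to the
#' zero-sum gauge (row/column state means removed) and its Frobenius norm
#' taken as the coupling strength FN(i, j). By default the gap state is
#' excluded before centering so that gap-stretch artifacts cannot dominate
#' the norm; set `excludeGaps = FALSE` for the strict all-state variant.
#'
#' @param model a [PottsModel-class].
#' @param excludeGaps drop the gap state from the norm (default TRUE).
#' @return L x L symmetric matrix, zero diagonal.
#' @export
frobeniusNorms <- function(model, excludeGaps = TRUE) {
  d <- dim(model@J); L <- d[1]; q <- d[3]
  states <- if (excludeGaps && q > 2L) 2:q else 1:q
  FN <- matrix(0, L, L)
  for (i in seq_len(L - 1L)) {
    for (j in seq((i + 1L), L)) {
      Bc <- .centerBlock(model@J[i, j, states, states])
      FN[i, j] <- FN[j, i] <- sqrt(sum(Bc^2))
    }
  }
  FN
}

#' Average product correction
#'
#' Removes the shared background (phylogeny, undersampling) from a coupling
#' strength matrix: EC(i, j) = FN(i, j) - m_i * m_j / m, with m_i the mean
#' of row i over its off-diagonal entries and m the grand off-diagonal
#' mean. An all-zero input returns all zeros.
#'
#' @param FN symmetric non-negative matrix with zero diagonal.
#' @return symmetric matrix of corrected scores, zero diagonal.
#' @export
applyApc <- function(FN) {
  stopifnot(is.matrix(FN), nrow(FN) == ncol(FN))
  L <- nrow(FN)
  if (L < 2L) return(FN * 0)
  m_i <- rowSums(FN) / (L - 1)
  gm <- sum(FN) / (L * (L - 1))
  if (gm == 0) return(FN * 0)
  EC <- FN - outer(m_i, m_i) / gm
  diag(EC) <- 0
  EC
}

#' Coupling score matrices from a fitted model
#'
#' @param model a [PottsModel-class].
#' @param excludeGaps see [frobeniusNorms()].
#' @return a [CouplingScores-class] holding the raw Frobenius norms and the
#'   APC-corrected scores.
#' @export
couplingScores <- function(model, excludeGaps = TRUE) {
  FN <- frobeniusNorms(model, excludeGaps = excludeGaps)
  new("CouplingScores", FN = FN, EC = applyApc(FN))
}

#' Write couplings as a sorted TSV edge list
#'
#' Columns: i, j (1-based indices of the processed alignment), res_i, res_j
#' (query-row letters), FN, EC; one row per unordered pair, sorted by
#' descending EC.
#'
#' @param scores a [CouplingScores-class].
#' @param aln the alignment the model was fitted on.
#' @param path output file.
#' @export
writeCouplingsTsv <- function(scores, aln, path) {
  L <- nrow(scores@FN)
  qs <- strsplit(querySequence(aln), "")[[1]]
  idx <- which(upper.tri(scores@FN), arr.ind = TRUE)
  df <- data.frame(i = idx[, 1], j = idx[, 2],
                   res_i = qs[idx[, 1]], res_j = qs[idx[, 2]],
                   FN = scores@FN[idx], EC = scores@EC[idx])
  df <- df[order(-df$EC, df$i, df$j), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
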