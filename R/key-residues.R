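#' Build the residue coupling-profile matrix E
#'
#' E[i, j] is the APC-corrected coupling EC between candidate residue a_i
#' (rows: the allosteric pocket, or every residue outside the orthosteric
#' pocket in enzyme mode) and orthosteric-pocket residue b_j (columns).
#' Unmapped residues are dropped with a warning.
#'
#' @param EC L x L corrected coupling matrix.
#' @param candidateResidues ordered residue ids, disjoint from the
#'   orthosteric pocket.
#' @param orthosteric the orthosteric [Pocket-class].
#' @param map a [ResidueColumnMap-class].
#' @return N x M numeric matrix with residue ids as dimnames.
#' @export
buildProfileMatrix <- function(EC, candidateResidues, orthosteric, map) {
  candidateResidues <- as.character(candidateResidues)
  if (length(intersect(candidateResidues, residueIds(orthosteric))))
    stop("candidate residues overlap the orthosteric pocket")
  mm <- map@map
  rows <- mm[match(candidateResidues, mm$residueId), ]
  rows <- rows[!is.na(rows$column), ]
  if (nrow(rows) < length(candidateResidues))
    warning(length(candidateResidues) - nrow(rows),
            " candidate residue(s) unmapped and dropped", call. = FALSE)
  oc <- mm[match(residueIds(orthosteric), mm$residueId), ]
  oc <- oc[!is.na(oc$column), ]
  if (nrow(rows) < 2L || nrow(oc) < 2L)
    stop("need >= 2 mapped candidate residues and >= 2 mapped orthosteric ",
         "residues (have ", nrow(rows), " and ", nrow(oc), ")")
  E <- EC[rows$column, oc$column, drop = FALSE]
  dimnames(E) <- list(rows$residueId, oc$residueId)
  E
}

## p-value for comparing two profile rows; guards zero-variance degeneracies
.rowTestP <- function(x, y, test, sided) {
  if (test == "paired") {
    dd <- x - y
    if (sd(dd) == 0) return(if (mean(dd) == 0) 1 else 0)
    tt <- t.test(x, y, paired = TRUE,
                 alternative = if (sided == "two") "two.sided" else "greater")
    return(tt$p.value)
  }
  if (sd(x) == 0 && sd(y) == 0)
    return(if (isTRUE(all.equal(mean(x), mean(y))) ) 1 else 0)
  tt <- t.test(x, y, var.equal = (test == "student"),
               alternative = if (sided == "two") "two.sided" else "greater")
  tt$p.value
}

#' Pairwise t-test significance counts over coupling profiles
#'
#' Every unordered pair of rows of E is compared by a t-test on their M
#' coupling values; C[m, i] = 1 when the row means differ at level `alpha`
#' (no multiple-testing correction: d is a per-comparison count statistic,
#' not an inference). d_i = sum_m C[m, i] counts how many other candidates
#' residue i differs from. Degenerate zero-variance pairs: equal means give
#' p = 1, unequal means p = 0.
#'
#' @param E profile matrix from [buildProfileMatrix()] (M >= 2 columns).
#' @param alpha per-comparison significance level (default 0.05).
#' @param test "student" (pooled-variance, the default literal reading),
#'   "welch", or "paired" (rows share the same orthosteric-column support,
#'   so a paired design is defensible).
#' @param sided "two" (default) or "one_greater".
#' @return a [SignificanceResult-class] with C and d filled; complete it
#'   with [scoreKeyResidues()].
#' @export
pairwiseSignificance <- function(E, alpha = 0.05,
                                 test = c("student", "welch", "paired"),
                                 sided = c("two", "one_greater")) {
  test <- match.arg(test); sided <- match.arg(sided)
  if (ncol(E) < 2L) stop("E must have >= 2 orthosteric columns")
  N <- nrow(E)
  C <- matrix(0L, N, N, dimnames = list(rownames(E), rownames(E)))
  for (m in seq_len(N - 1L)) {
    for (i in seq((m + 1L), N)) {
      p <- .rowTestP(E[m, ], E[i, ], test, sided)
      if (p < alpha) {
        C[m, i] <- 1L
        if (sided == "two") C[i, m] <- 1L
      }
      if (sided == "one_greater") {
        p2 <- .rowTestP(E[i, ], E[m, ], test, sided)
        if (p2 < alpha) C[i, m] <- 1L
      }
    }
  }
  d <- colSums(C)
  ## Class= spelled out: a slot named C would otherwise partial-match it
  new(Class = "SignificanceResult", C = C, d = as.numeric(d),
      z = rep(NA_real_, N),
      mu = NA_real_, sigma = NA_real_, alpha = alpha, threshold = NA_real_,
      table = data.frame())
}

## sort key: numeric residue number when parseable, else lexicographic
.residueOrderKey <- function(ids) {
  num <- suppressWarnings(as.numeric(sub("[A-Za-z]+$", "", ids)))
  if (anyNA(num)) rank(ids) else num
}

#' Z-score significance counts and call key residues
#'
#' z_i = (d_i - mu) / sigma with the population SD over the candidate set;
#' residues with z above `threshold` are key residues (convention: 0.8 for
#' allosteric-pocket mode, 0.9 when scanning all residues outside the
#' orthosteric pocket). The full ranking is always returned so
#' near-threshold residues can be inspected. sigma = 0 yields all-zero z
#' and an empty key list with a warning.
#'
#' @param sig a [SignificanceResult-class] from [pairwiseSignificance()].
#' @param threshold key-residue Z cutoff (default 0.8).
#' @return the completed [SignificanceResult-class]; its `table` slot has
#'   residue, d, z, rank, isKey sorted by rank (descending z, ties by
#'   residue number).
#' @export
scoreKeyResidues <- function(sig, threshold = 0.8) {
  d <- sig@d
  if (length(d) < 2L) stop("need >= 2 candidate residues")
  mu <- mean(d)
  sigma <- sqrt(mean((d - mu)^2))
  if (sigma == 0) {
    warning("all significance counts identical; no residue stands out",
            call. = FALSE)
    z <- rep(0, length(d))
  } else z <- (d - mu) / sigma
  ids <- rownames(sig@C)
  if (is.null(ids)) ids <- as.character(seq_along(d))
  ord <- order(-z, .residueOrderKey(ids))
  tab <- data.frame(residue = ids, d = d, z = z, stringsAsFactors = FALSE)
  tab$rank <- integer(length(d)); tab$rank[ord] <- seq_along(d)
  tab$isKey <- sigma > 0 & tab$z > threshold
  tab <- tab[order(tab$rank), ]
  rownames(tab) <- NULL
  initialize(sig, z = z, mu = mu, sigma = sigma, threshold = threshold,
             table = tab)
}

#' Key allosteric residues from couplings, end to end
#'
#' Convenience chain: [buildProfileMatrix()] -> [pairwiseSignificance()] ->
#' [scoreKeyResidues()].
#'
#' @inheritParams buildProfileMatrix
#' @inheritParams pairwiseSignificance
#' @inheritParams scoreKeyResidues
#' @return a completed [SignificanceResult-class].
#' @export
keyResidues <- function(EC, candidateResidues, orthosteric, map,
                        alpha = 0.05, threshold = 0.8, test = "student",
                        sided = "two") {
  E <- buildProfileMatrix(EC, candidateResidues, orthosteric, map)
  sig <- pairwiseSignificance(E, alpha = alpha, test = test, sided = sided)
  scoreKeyResidues(sig, threshold = threshold)
}

#' Write the per-residue significance table as TSV
#' @param sig a completed [SignificanceResult-class].
#' @param path output file.
#' @export
writeKeyResiduesTsv <- function(sig, path) {
  write.table(sig@table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Homolog-subsampling robustness of the key-residue call
#'
#' Re-runs the fit -> couplings -> significance -> key-residue pipeline on
#' random subsamples of the alignment and reports the overlap of each
#' subsample's key set with the full-alignment reference. Requested depths
#' are expressed as multiples of the query length L (a family with ratio r
#' contributes ceiling(r * L) sequences); the query row is always retained.
#'
#' @param aln full [CodedAlignment-class].
#' @param candidateResidues,orthosteric,map as in [keyResidues()].
#' @param ratios depth ratios (sequences per residue of query length).
#' @param repeats draws per ratio (default 3).
#' @param seed RNG seed.
#' @param identityThreshold reweighting threshold (default 0.80).
#' @param minNeff subsamples whose Neff falls below this are flagged and
#'   skipped (default 10).
#' @param alpha,threshold,test,sided passed to the significance step.
#' @param lambdaH,lambdaJ,maxIter passed to [fitPlm()].
#' @param excludeGaps passed to [couplingScores()].
#' @return data.frame: ratio, rep, nSequences, neff, overlap, flagged. The
#'   reference key set is attached as attribute "referenceKeys".
#' @export
subsampleRobustness <- function(aln, candidateResidues, orthosteric, map,
                                ratios, repeats = 3L, seed = 1L,
                                identityThreshold = 0.80, minNeff = 10,
                                alpha = 0.05, threshold = 0.8,
                                test = "student", sided = "two",
                                lambdaH = 0.01, lambdaJ = NULL,
                                maxIter = 500L, excludeGaps = TRUE) {
  runKeys <- function(a) {
    w <- computeWeights(a, identityThreshold)
    if (neff(w) < minNeff) return(NULL)
    sc <- couplingScores(fitPlm(a, w, lambdaH, lambdaJ, maxIter),
                         excludeGaps = excludeGaps)
    sig <- keyResidues(ecMatrix(sc), candidateResidues, orthosteric, map,
                       alpha, threshold, test, sided)
    sig@table$residue[sig@table$isKey]
  }
  refKeys <- runKeys(aln)
  if (is.null(refKeys) || !length(refKeys))
    stop("reference run produced no key residues")
  L <- alnLength(aln); n <- alnDepth(aln); qi <- queryIndex(aln)
  set.seed(seed)
  out <- list()
  for (r in ratios) {
    for (rep_ in seq_len(repeats)) {
      nSub <- min(n, max(2L, as.integer(ceiling(r * L))))
      keep <- c(qi, sample(setdiff(seq_len(n), qi), nSub - 1L))
      sub <- codedAlignment(aln@sequences[keep], aln@ids[keep],
                            queryId = aln@ids[qi], q = alphabetSize(aln))
      w <- computeWeights(sub, identityThreshold)
      if (neff(w) < minNeff) {
        out[[length(out) + 1L]] <- data.frame(
          ratio = r, rep = rep_, nSequences = nSub, neff = neff(w),
          overlap = NA_real_, flagged = TRUE)
        next
      }
      keys <- runKeys(sub)
      ov <- if (is.null(keys)) NA_real_ else
        length(intersect(keys, refKeys)) / length(refKeys)
      out[[length(out) + 1L]] <- data.frame(
        ratio = r, rep = rep_, nSequences = nSub, neff = neff(w),
        overlap = ov, flagged = is.null(keys))
    }
  }
  res <- do.call(rbind, out)
  attr(res, "referenceKeys") <- refKeys
  res
}
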