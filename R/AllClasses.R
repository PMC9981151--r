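#' @useDynLib allosite, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

## 21-state DCA alphabet: gap first, then the 20 amino acids in the
## conventional alphabetical one-letter order.
.AA20 <- c("A","C","D","E","F","G","H","I","K","L",
           "M","N","P","Q","R","S","T","V","W","Y")

#' Residue alphabet used for Potts-model coding
#'
#' State 1 is the gap; states 2..q are amino acids. Synthetic families may
#' use a reduced alphabet (q < 21) to keep sampling and fitting fast.
#'
#' @param q alphabet size (2..21).
#' @return character vector of length `q`.
#' @export
alloAlphabet <- function(q = 21L) {
  q <- as.integer(q)
  stopifnot(q >= 2L, q <= 21L)
  c("-", .AA20)[seq_len(q)]
}

#' CodedAlignment: a numerically coded multiple sequence alignment
#'
#' Holds aligned sequences over a gap-plus-amino-acid alphabet together with
#' their integer coding (1 = gap), per-sequence identifiers and the index of
#' the query sequence. Non-standard letters (B, Z, X, U, O, ".") are coded
#' as gap.
#'
#' @slot sequences character vector of equal-length aligned sequences.
#' @slot ids per-sequence identifiers.
#' @slot queryIndex row index of the query sequence.
#' @slot codes integer matrix (sequences x columns), values in 1..q.
#' @slot alphabet the state alphabet; `alphabet[1]` is the gap.
#' @export
setClass("CodedAlignment",
  representation(sequences = "character", ids = "character",
                 queryIndex = "integer", codes = "matrix",
                 alphabet = "character"),
  validity = function(object) {
    n <- length(object@sequences)
    if (n < 1L) return("alignment has no sequences")
    if (length(unique(nchar(object@sequences))) != 1L)
      return("sequences differ in length")
    if (ncol(object@codes) < 2L) return("alignment length L must be >= 2")
    if (nrow(object@codes) != n || length(object@ids) != n)
      return("codes/ids do not match the number of sequences")
    if (object@queryIndex < 1L || object@queryIndex > n)
      return("queryIndex out of range")
    q <- length(object@alphabet)
    if (q < 2L) return("alphabet must have >= 2 states")
    rng <- range(object@codes)
    if (rng[1] < 1L || rng[2] > q)
      return("codes outside 1..q")
    TRUE
  })

#' SequenceWeights: identity-based reweighting of an alignment
#'
#' @slot weights non-negative per-sequence weights in (0, 1].
#' @slot neff effective number of sequences, `sum(weights)`.
#' @slot identityThreshold identity fraction defining the neighbourhood.
#' @export
setClass("SequenceWeights",
  representation(weights = "numeric", neff = "numeric",
                 identityThreshold = "numeric"),
  validity = function(object) {
    if (any(object@weights <= 0) || any(object@weights > 1 + 1e-12))
      return("weights must lie in (0, 1]")
    if (abs(object@neff - sum(object@weights)) > 1e-8)
      return("neff != sum(weights)")
    TRUE
  })

#' PottsModel: fields and couplings of the fitted evolutionary coupling model
#'
#' Parameters of the pairwise maximum-entropy (Potts) model
#' P(a) proportional to exp(sum_i h_i(a_i) + sum_{i<j} J_ij(a_i, a_j)),
#' estimated by per-site pseudo-likelihood maximization and symmetrized.
#'
#' @slot h L x q matrix of single-site fields.
#' @slot J L x L x q x q array of couplings; `J[i,j,,]` is the block for the
#'   column pair (i, j), with `J[i,i,,] = 0` and `J[j,i,b,a] = J[i,j,a,b]`.
#' @slot lambdaH,lambdaJ L2 regularization strengths used in the fit.
#' @slot converged per-site convergence flags from the optimizer.
#' @slot message optimizer status summary.
#' @export
setClass("PottsModel",
  representation(h = "matrix", J = "array", lambdaH = "numeric",
                 lambdaJ = "numeric", converged = "logical",
                 message = "character"),
  validity = function(object) {
    d <- dim(object@J)
    if (length(d) != 4L || d[1] != d[2] || d[3] != d[4])
      return("J must be an L x L x q x q array")
    if (nrow(object@h) != d[1] || ncol(object@h) != d[3])
      return("h dimensions do not match J")
    if (!all(is.finite(object@h)) || !all(is.finite(object@J)))
      return("non-finite parameters")
    TRUE
  })

#' CouplingScores: Frobenius-norm and APC-corrected coupling matrices
#'
#' @slot FN L x L symmetric matrix of zero-sum-gauge Frobenius norms of the
#'   coupling blocks (zero diagonal).
#' @slot EC L x L symmetric matrix of average-product-corrected scores.
#' @export
setClass("CouplingScores",
  representation(FN = "matrix", EC = "matrix"),
  validity = function(object) {
    if (!isTRUE(all.equal(object@FN, t(object@FN), tolerance = 1e-8)))
      return("FN not symmetric")
    if (any(diag(object@FN) != 0)) return("FN diagonal not zero")
    if (any(object@FN < -1e-12)) return("FN has negative entries")
    if (!identical(dim(object@FN), dim(object@EC)))
      return("FN/EC dimension mismatch")
    TRUE
  })

#' StructureModel: one protein chain plus its hetero ligands
#'
#' A light container for the heavy-atom coordinates of a single chain.
#' Residue identifiers are `paste0(resno, insert)` and keep the author's PDB
#' numbering verbatim.
#'
#' @slot chainId chain identifier.
#' @slot atoms data.frame with columns resid (3-letter), resno, insert,
#'   elety, x, y, z — protein heavy atoms only.
#' @slot ligands data.frame with columns ligname, x, y, z — hetero heavy
#'   atoms (waters excluded).
#' @export
setClass("StructureModel",
  representation(chainId = "character", atoms = "data.frame",
                 ligands = "data.frame"),
  validity = function(object) {
    need <- c("resid", "resno", "insert", "elety", "x", "y", "z")
    if (!all(need %in% names(object@atoms)))
      return("atoms must have resid/resno/insert/elety/x/y/z")
    if (!all(is.finite(as.matrix(object@atoms[, c("x","y","z")]))))
      return("non-finite coordinates")
    TRUE
  })

#' Pocket: a named set of structure residues with a role
#'
#' @slot name pocket label (e.g. "cavity_3", "orthosteric").
#' @slot residueIds residue identifiers (resno + insertion code) present in
#'   the owning StructureModel.
#' @slot role one of "orthosteric", "candidate", "allosteric_known".
#' @export
setClass("Pocket",
  representation(name = "character", residueIds = "character",
                 role = "character"),
  validity = function(object) {
    if (length(object@residueIds) < 1L) return("pocket is empty")
    if (anyDuplicated(object@residueIds)) return("duplicate residues")
    if (!object@role %in% c("orthosteric", "candidate", "allosteric_known"))
      return("unknown pocket role")
    TRUE
  })

#' ResidueColumnMap: structure residue to alignment column correspondence
#'
#' @slot map data.frame with columns residueId, column (1-based index of the
#'   processed alignment), matched (logical: identical amino acid).
#' @slot coverage fraction of structure residues mapped.
#' @export
setClass("ResidueColumnMap",
  representation(map = "data.frame", coverage = "numeric"),
  validity = function(object) {
    if (!all(c("residueId", "column") %in% names(object@map)))
      return("map must have residueId and column")
    if (anyDuplicated(object@map$residueId) || anyDuplicated(object@map$column))
      return("map is not one-to-one")
    TRUE
  })

#' SignificanceResult: t-test significance counts and key-residue calls
#'
#' @slot C N x N binary matrix; `C[m,i] = 1` when the coupling profiles of
#'   candidate residues m and i differ significantly.
#' @slot d per-residue significance counts, column sums of C.
#' @slot z per-residue Z-scores of d (population SD).
#' @slot mu,sigma normalization constants.
#' @slot alpha per-comparison significance level.
#' @slot threshold Z cutoff for the key-residue call.
#' @slot table data.frame: residue, d, z, rank, isKey — full ranking.
#' @export
setClass("SignificanceResult",
  representation(C = "matrix", d = "numeric", z = "numeric", mu = "numeric",
                 sigma = "numeric", alpha = "numeric", threshold = "numeric",
                 table = "data.frame"),
  validity = function(object) {
    n <- length(object@d)
    if (!identical(dim(object@C), c(n, n) + 0L) &&
        !identical(dim(object@C), as.integer(c(n, n))))
      return("C dimensions do not match d")
    if (any(diag(object@C) != 0)) return("C diagonal not zero")
    TRUE
  })

#' PlantedFamilySpec: parameters of a synthetic Potts family
#'
#' Defines a planted coupling architecture: every (orthosteric, allosteric)
#' column pair is coupled with a ferromagnetic block of strength
#' `couplingStrength`; pairs involving a key column are boosted by
#' `keyBoost`. Decoy columns carry no couplings and act as negative-control
#' pockets.
#'
#' @slot L,q,nSequences alignment dimensions and sampling depth.
#' @slot orthoCols,alloCols,decoyCols disjoint column index sets.
#' @slot keyCols subset of alloCols with boosted coupling.
#' @slot couplingStrength base coupling (diagonal block magnitude).
#' @slot keyBoost multiplicative boost for key columns (>= 1).
#' @slot burnIn,thinning Gibbs sampler controls (sweeps).
#' @slot fieldSd SD of the random single-site fields.
#' @export
setClass("PlantedFamilySpec",
  representation(L = "integer", q = "integer", nSequences = "integer",
                 orthoCols = "integer", alloCols = "integer",
                 decoyCols = "list", keyCols = "integer",
                 couplingStrength = "numeric", keyBoost = "numeric",
                 burnIn = "integer", thinning = "integer",
                 fieldSd = "numeric"),
  validity = function(object) {
    cols <- c(object@orthoCols, object@alloCols, unlist(object@decoyCols))
    if (any(cols < 1L) || any(cols > object@L))
      return("column sets outside 1..L")
    if (anyDuplicated(cols)) return("column sets must be disjoint")
    if (!all(object@keyCols %in% object@alloCols))
      return("keyCols must be a subset of alloCols")
    if (object@couplingStrength < 0) return("couplingStrength must be >= 0")
    if (object@keyBoost < 1) return("keyBoost must be >= 1")
    TRUE
  })
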