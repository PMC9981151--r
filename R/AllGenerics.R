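#' @rdname CodedAlignment-class
#' @param x,object an object.
#' @export
setGeneric("alnLength", function(x) standardGeneric("alnLength"))
#' @rdname CodedAlignment-class
#' @export
setGeneric("alnDepth", function(x) standardGeneric("alnDepth"))
#' @rdname CodedAlignment-class
#' @export
setGeneric("alnCodes", function(x) standardGeneric("alnCodes"))
#' @rdname CodedAlignment-class
#' @export
setGeneric("alphabetSize", function(x) standardGeneric("alphabetSize"))
#' @rdname CodedAlignment-class
#' @export
setGeneric("queryIndex", function(x) standardGeneric("queryIndex"))
#' @rdname CodedAlignment-class
#' @export
setGeneric("querySequence", function(x) standardGeneric("querySequence"))
#' @rdname CodedAlignment-class
#' @export
setGeneric("seqIds", function(x) standardGeneric("seqIds"))

#' @rdname SequenceWeights-class
#' @param x an object.
#' @export
setGeneric("seqWeights", function(x) standardGeneric("seqWeights"))
#' @rdname SequenceWeights-class
#' @export
setGeneric("neff", function(x) standardGeneric("neff"))

#' @rdname CouplingScores-class
#' @param x an object.
#' @export
setGeneric("fnMatrix", function(x) standardGeneric("fnMatrix"))
#' @rdname CouplingScores-class
#' @export
setGeneric("ecMatrix", function(x) standardGeneric("ecMatrix"))

#' @rdname Pocket-class
#' @param x an object.
#' @export
setGeneric("residueIds", function(x) standardGeneric("residueIds"))
#' @rdname Pocket-class
#' @export
setGeneric("pocketRole", function(x) standardGeneric("pocketRole"))
#' @rdname Pocket-class
#' @export
setGeneric("pocketName", function(x) standardGeneric("pocketName"))

setMethod("alnLength", "CodedAlignment", function(x) ncol(x@codes))
setMethod("alnDepth", "CodedAlignment", function(x) nrow(x@codes))
setMethod("alnCodes", "CodedAlignment", function(x) x@codes)
setMethod("alphabetSize", "CodedAlignment", function(x) length(x@alphabet))
setMethod("queryIndex", "CodedAlignment", function(x) x@queryIndex)
setMethod("querySequence", "CodedAlignment",
          function(x) x@sequences[x@queryIndex])
setMethod("seqIds", "CodedAlignment", function(x) x@ids)

setMethod("seqWeights", "SequenceWeights", function(x) x@weights)
setMethod("neff", "SequenceWeights", function(x) x@neff)

setMethod("fnMatrix", "CouplingScores", function(x) x@FN)
setMethod("ecMatrix", "CouplingScores", function(x) x@EC)

setMethod("residueIds", "Pocket", function(x) x@residueIds)
setMethod("pocketRole", "Pocket", function(x) x@role)
setMethod("pocketName", "Pocket", function(x) x@name)
setMethod("residueIds", "StructureModel",
          function(x) unique(paste0(x@atoms$resno, x@atoms$insert)))

setMethod("show", "CodedAlignment", function(object) {
  cat("CodedAlignment:", alnDepth(object), "sequences x",
      alnLength(object), "columns, q =", alphabetSize(object), "\n")
  cat("  query:", object@ids[object@queryIndex],
      sprintf("(row %d)\n", object@queryIndex))
})

setMethod("show", "SequenceWeights", function(object) {
  cat(sprintf("SequenceWeights: %d sequences, neff = %.2f (identity >= %.0f%%)\n",
              length(object@weights), object@neff,
              100 * object@identityThreshold))
})

setMethod("show", "PottsModel", function(object) {
  d <- dim(object@J)
  cat(sprintf("PottsModel: L = %d, q = %d (lambda_h = %g, lambda_J = %g)\n",
              d[1], d[3], object@lambdaH, object@lambdaJ))
  cat(sprintf("  %d/%d site fits converged\n",
              sum(object@converged), length(object@converged)))
})

setMethod("show", "CouplingScores", function(object) {
  L <- nrow(object@FN)
  off <- object@FN[upper.tri(object@FN)]
  cat(sprintf("CouplingScores: %d x %d (max FN = %.3f, mean FN = %.3f)\n",
              L, L, max(off), mean(off)))
})

setMethod("show", "StructureModel", function(object) {
  cat(sprintf("StructureModel: chain %s, %d residues, %d protein atoms",
              object@chainId, length(residueIds(object)),
              nrow(object@atoms)))
  if (nrow(object@ligands))
    cat(sprintf(", ligands: %s",
                paste(unique(object@ligands$ligname), collapse = ", ")))
  cat("\n")
})

setMethod("show", "Pocket", function(object) {
  cat(sprintf("Pocket '%s' (%s): %d residues\n", object@name, object@role,
              length(object@residueIds)))
})

setMethod("show", "ResidueColumnMap", function(object) {
  cat(sprintf("ResidueColumnMap: %d residues mapped (coverage %.1f%%)\n",
              nrow(object@map), 100 * object@coverage))
})

setMethod("show", "SignificanceResult", function(object) {
  cat(sprintf("SignificanceResult: %d candidates, alpha = %g, threshold z > %g\n",
              length(object@d), object@alpha, object@threshold))
  if (nrow(object@table))
    cat(sprintf("  key residues: %d\n", sum(object@table$isKey)))
})

setMethod("show", "PlantedFamilySpec", function(object) {
  cat(sprintf("PlantedFamilySpec: L = %d, q = %d, n = %d\n",
              object@L, object@q, object@nSequences))
  cat(sprintf("  ortho %d cols, allo %d cols (%d key), %d decoy pockets\n",
              length(object@orthoCols), length(object@alloCols),
              length(object@keyCols), length(object@decoyCols)))
})
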