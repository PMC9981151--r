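## resolve an alignment argument: path or CodedAlignment
.resolveAln <- function(alignment, queryId = NULL, format = "fasta",
                        q = 21L) {
  if (is(alignment, "CodedAlignment")) return(alignment)
  if (is.null(queryId)) stop("queryId is required when reading from file")
  readAlignment(alignment, format = format, queryId = queryId, q = q)
}

.resolveStructure <- function(structure, chain = NULL) {
  if (is(structure, "StructureModel")) return(structure)
  readStructure(structure, chain = chain)
}

.resolveOrtho <- function(structure, orthoPocket, orthoLigand, orthoCutoff) {
  if (!is.null(orthoPocket)) {
    if (is(orthoPocket, "Pocket")) return(orthoPocket)
    return(pocket("orthosteric", orthoPocket, role = "orthosteric",
                  structure = structure))
  }
  if (is.null(orthoLigand))
    stop("provide orthoPocket (residue ids) or orthoLigand (ligand name)")
  pocketFromLigand(structure, orthoLigand, cutoff = orthoCutoff,
                   name = "orthosteric", role = "orthosteric")
}

#' Predict allosteric pockets end to end
#'
#' Runs the full workflow: alignment -> 80%-identity reweighting -> PLM fit
#' -> Frobenius-norm couplings -> orthosteric pocket from its ligand (6 A)
#' or an explicit residue list -> candidate filtering (>50% overlap rule)
#' -> ECS Z-scores with the z > 0.5 allosteric call.
#'
#' @param alignment a [CodedAlignment-class] or a file path.
#' @param structure a [StructureModel-class] or a PDB/mmCIF path.
#' @param candidatePockets list of [Pocket-class] objects, or a pocket-file
#'   path (see [readPocketFile()]).
#' @param queryId,format,q alignment reading options (file input).
#' @param chain structure chain (file input).
#' @param orthoLigand ligand name defining the orthosteric pocket.
#' @param orthoPocket explicit orthosteric residue ids (overrides ligand).
#' @param orthoCutoff orthosteric proximity cutoff (default 6 A).
#' @param identityThreshold reweighting identity (default 0.80).
#' @param lambdaH,lambdaJ,maxIter PLM hyperparameters (see [fitPlm()]).
#' @param excludeGaps gap handling in the Frobenius norm.
#' @param zThreshold allosteric call threshold (default 0.5).
#' @param topKPairs optional top-k-pairs ECS variant.
#' @param model optional pre-fitted [PottsModel-class] to reuse across
#'   workflows (skips the expensive fit).
#' @param outDir when set, TSV tables and a JSON run summary are written
#'   there.
#' @return list: table (ranked pockets), scores ([CouplingScores-class]),
#'   model, weights, map, orthosteric, candidates (post filtering).
#' @export
runPredictSites <- function(alignment, structure, candidatePockets,
                            queryId = NULL, format = "fasta", q = 21L,
                            chain = NULL, orthoLigand = NULL,
                            orthoPocket = NULL, orthoCutoff = 6,
                            identityThreshold = 0.80, lambdaH = 0.01,
                            lambdaJ = NULL, maxIter = 500L,
                            excludeGaps = TRUE, zThreshold = 0.5,
                            topKPairs = NULL, model = NULL, outDir = NULL) {
  aln <- .resolveAln(alignment, queryId, format, q)
  s <- .resolveStructure(structure, chain)
  ortho <- .resolveOrtho(s, orthoPocket, orthoLigand, orthoCutoff)
  if (is.character(candidatePockets) && length(candidatePockets) == 1L)
    candidatePockets <- readPocketFile(candidatePockets, structure = s)
  cands <- filterCandidatePockets(candidatePockets, ortho)
  if (!length(cands)) stop("no candidate pockets survive filtering")
  w <- computeWeights(aln, identityThreshold)
  if (is.null(model)) model <- fitPlm(aln, w, lambdaH, lambdaJ, maxIter)
  sc <- couplingScores(model, excludeGaps = excludeGaps)
  map <- mapStructureToAlignment(s, aln)
  tab <- rankPockets(cands, ortho, fnMatrix(sc), map,
                     zThreshold = zThreshold, topKPairs = topKPairs)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    write.table(tab, file.path(outDir, "pocket_scores.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeCouplingsTsv(sc, aln, file.path(outDir, "couplings.tsv"))
    writeWeightsTsv(aln, w, file.path(outDir, "weights.tsv"))
    writeMapTsv(map, file.path(outDir, "residue_map.tsv"))
    jsonlite::write_json(
      list(workflow = "predict-sites",
           settings = list(identityThreshold = identityThreshold,
                           lambdaH = model@lambdaH, lambdaJ = model@lambdaJ,
                           orthoCutoff = orthoCutoff,
                           zThreshold = zThreshold,
                           excludeGaps = excludeGaps,
                           topKPairs = topKPairs),
           neff = neff(w), L = alnLength(aln), nSequences = alnDepth(aln),
           orthosteric = residueIds(ortho),
           table = tab),
      file.path(outDir, "run_summary.json"), auto_unbox = TRUE, digits = NA)
  }
  list(table = tab, scores = sc, model = model, weights = w, map = map,
       orthosteric = ortho, candidates = cands)
}

#' Identify key allosteric residues end to end
#'
#' Pocket mode compares the coupling profiles of the allosteric-pocket
#' residues to the orthosteric pocket (key call at z > 0.8 by convention);
#' outside mode scans every mapped residue outside the orthosteric pocket
#' (enzyme workflow, key call at z > 0.9). When no allosteric pocket is
#' supplied in pocket mode, the 8 A proximity fallback around
#' `alloLigand` is used.
#'
#' @inheritParams runPredictSites
#' @param mode "pocket" or "outside".
#' @param alloPocket allosteric [Pocket-class] or residue ids (pocket mode).
#' @param alloLigand allosteric ligand name for the 8 A fallback.
#' @param alloCutoff fallback cutoff (default 8 A).
#' @param alpha t-test significance level (default 0.05).
#' @param threshold key-residue Z cutoff; defaults to 0.8 (pocket) / 0.9
#'   (outside).
#' @param test,sided t-test variant (see [pairwiseSignificance()]).
#' @param surfaceOnly in outside mode, restrict candidates to surface
#'   residues (relative SASA >= 0.10).
#' @return list: result ([SignificanceResult-class]), table, E, scores,
#'   model, weights, map, orthosteric, candidates.
#' @export
runKeyResidues <- function(alignment, structure, mode = c("pocket", "outside"),
                           queryId = NULL, format = "fasta", q = 21L,
                           chain = NULL, orthoLigand = NULL,
                           orthoPocket = NULL, orthoCutoff = 6,
                           alloPocket = NULL, alloLigand = NULL,
                           alloCutoff = 8, identityThreshold = 0.80,
                           lambdaH = 0.01, lambdaJ = NULL, maxIter = 500L,
                           excludeGaps = TRUE, alpha = 0.05,
                           threshold = NULL, test = "student", sided = "two",
                           surfaceOnly = FALSE, model = NULL, outDir = NULL) {
  mode <- match.arg(mode)
  if (is.null(threshold)) threshold <- if (mode == "pocket") 0.8 else 0.9
  aln <- .resolveAln(alignment, queryId, format, q)
  s <- .resolveStructure(structure, chain)
  ortho <- .resolveOrtho(s, orthoPocket, orthoLigand, orthoCutoff)
  w <- computeWeights(aln, identityThreshold)
  if (is.null(model)) model <- fitPlm(aln, w, lambdaH, lambdaJ, maxIter)
  sc <- couplingScores(model, excludeGaps = excludeGaps)
  map <- mapStructureToAlignment(s, aln)
  if (mode == "pocket") {
    allo <- if (!is.null(alloPocket)) {
      if (is(alloPocket, "Pocket")) alloPocket else
        pocket("allosteric", alloPocket, role = "allosteric_known",
               structure = s)
    } else if (!is.null(alloLigand)) {
      pocketFromLigand(s, alloLigand, cutoff = alloCutoff,
                       name = "allosteric", role = "allosteric_known")
    } else stop("pocket mode needs alloPocket or alloLigand")
    candidates <- setdiff(residueIds(allo), residueIds(ortho))
  } else {
    candidates <- setdiff(map@map$residueId, residueIds(ortho))
    if (surfaceOnly)
      candidates <- intersect(candidates, surfaceResidues(s))
  }
  E <- buildProfileMatrix(ecMatrix(sc), candidates, ortho, map)
  sig <- pairwiseSignificance(E, alpha = alpha, test = test, sided = sided)
  sig <- scoreKeyResidues(sig, threshold = threshold)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeKeyResiduesTsv(sig, file.path(outDir, "key_residues.tsv"))
    write.table(sig@C, file.path(outDir, "significance_matrix.tsv"),
                sep = "\t", quote = FALSE)
    jsonlite::write_json(
      list(workflow = paste0("key-residues-", mode),
           settings = list(alpha = alpha, threshold = threshold,
                           test = test, sided = sided,
                           orthoCutoff = orthoCutoff,
                           alloCutoff = alloCutoff),
           neff = neff(w),
           keyResidues = sig@table$residue[sig@table$isKey],
           table = sig@table),
      file.path(outDir, "run_summary.json"), auto_unbox = TRUE, digits = NA)
  }
  list(result = sig, table = sig@table, E = E, scores = sc, model = model,
       weights = w, map = map, orthosteric = ortho, candidates = candidates)
}
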