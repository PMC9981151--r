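#' Specification of a planted synthetic Potts family
#'
#' Default geometry: L = 60 columns, alphabet q = 8 (gap plus seven amino
#' acid states; the reduced alphabet keeps Gibbs mixing and PLM fitting
#' fast), 2000 sequences. Columns 11-18 form the orthosteric block, 31-38
#' the allosteric block (31-33 boosted as key columns) and three decoy
#' pockets (1-8, 21-28, 41-48) carry no couplings. Every
#' orthosteric-allosteric column pair is coupled through a ferromagnetic
#' diagonal block of magnitude `couplingStrength` over the non-gap states
#' (zero-sum-gauge Frobenius norm c * sqrt(q - 2 + ...) ~ c * sqrt(6) for q
#' = 8, i.e. about 0.5 at the default c = 0.2 — the magnitude of a strong
#' contact coupling in real families); pairs involving a key column are
#' boosted `keyBoost`-fold.
#'
#' @param L,q,nSequences alignment dimensions and depth.
#' @param orthoCols,alloCols,decoyCols disjoint column sets (decoyCols is a
#'   list of integer vectors, one per decoy pocket).
#' @param keyCols subset of alloCols with boosted coupling.
#' @param couplingStrength base diagonal coupling (default 0.2).
#' @param keyBoost boost factor for key columns (default 5).
#' @param burnIn,thinning Gibbs sweeps (defaults 1000 / 10).
#' @param fieldSd SD of random single-site fields (default 0.1).
#' @return a [PlantedFamilySpec-class].
#' @export
plantedFamilySpec <- function(L = 60L, q = 8L, nSequences = 2000L,
                              orthoCols = 11:18, alloCols = 31:38,
                              decoyCols = list(1:8, 21:28, 41:48),
                              keyCols = 31:33, couplingStrength = 0.2,
                              keyBoost = 5, burnIn = 1000L, thinning = 10L,
                              fieldSd = 0.1) {
  new("PlantedFamilySpec", L = as.integer(L), q = as.integer(q),
      nSequences = as.integer(nSequences), orthoCols = as.integer(orthoCols),
      alloCols = as.integer(alloCols),
      decoyCols = lapply(decoyCols, as.integer), keyCols = as.integer(keyCols),
      couplingStrength = couplingStrength, keyBoost = keyBoost,
      burnIn = as.integer(burnIn), thinning = as.integer(thinning),
      fieldSd = fieldSd)
}

## planted edge list and coupling blocks of a spec (non-gap states only)
.plantedModel <- function(spec, seed) {
  set.seed(seed)
  L <- spec@L; q <- spec@q
  h <- matrix(stats::rnorm(L * q, sd = spec@fieldSd), L, q)
  h[, 1] <- -30 # gap state suppressed: synthetic families are gap-free
  edges <- as.matrix(expand.grid(i = spec@orthoCols, j = spec@alloCols))
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  ## edges must satisfy i < j for the sampler's block orientation
  flip <- edges[, 1] > edges[, 2]
  edges[flip, ] <- edges[flip, 2:1]
  Jblocks <- numeric(nrow(edges) * q * q)
  for (e in seq_len(nrow(edges))) {
    c_e <- spec@couplingStrength *
      if (edges[e, 1] %in% spec@keyCols || edges[e, 2] %in% spec@keyCols)
        spec@keyBoost else 1
    blk <- matrix(0, q, q)
    diag(blk)[-1] <- c_e
    Jblocks[(e - 1) * q * q + seq_len(q * q)] <- as.numeric(blk)
  }
  list(h = h, edges = edges, Jblocks = Jblocks)
}

#' Gibbs-sample a synthetic protein family with planted couplings
#'
#' Draws `nSequences` sequences from the planted Potts model of `spec` with
#' a single-chain Gibbs sampler (burn-in then thinned sweeps). Sampling is
#' deterministic under `seed`. The first sampled sequence is designated the
#' query.
#'
#' @param spec a [PlantedFamilySpec-class].
#' @param seed integer seed.
#' @return list: `aln` (a [CodedAlignment-class]), `spec`, `plantedPairs`
#'   (data.frame i, j, strength), `keyCols`.
#' @export
sampleFamily <- function(spec, seed = 1L) {
  pm <- .plantedModel(spec, seed)
  states <- cpp_gibbs_potts(pm$h, pm$edges, pm$Jblocks,
                            spec@nSequences, spec@burnIn, spec@thinning)
  alphabet <- alloAlphabet(spec@q)
  sequences <- apply(states, 1, function(row)
    paste(alphabet[row], collapse = ""))
  ids <- c("query", paste0("hom", seq_len(spec@nSequences - 1L) + 1L))
  aln <- codedAlignment(sequences, ids = ids, queryId = "query", q = spec@q)
  strength <- spec@couplingStrength *
    ifelse(pm$edges[, 1] %in% spec@keyCols | pm$edges[, 2] %in% spec@keyCols,
           spec@keyBoost, 1)
  list(aln = aln,
       spec = spec,
       plantedPairs = data.frame(i = pm$edges[, 1], j = pm$edges[, 2],
                                 strength = strength),
       keyCols = spec@keyCols)
}

#' Build a toy structure whose ligand pockets recover the planted columns
#'
#' Residues sit on an extended chain (3.8 A CA spacing along x, with a CB
#' pseudo-sidechain at y = -1.5). An "ORT" ligand atom floats 5 A above
#' each orthosteric residue, so the 6 A proximity rule selects exactly
#' `orthoCols` (neighbours are 6.28 A away); an "ALO" ligand atom floats
#' 7.5 A above each allosteric residue, so the 8 A fallback rule selects
#' exactly `alloCols`. Residue numbering equals the alignment column index
#' and residue identity follows `querySeq` when given.
#'
#' @param spec a [PlantedFamilySpec-class].
#' @param querySeq optional query sequence (length L, no gaps) giving
#'   residue identities; default all-ALA.
#' @return a [StructureModel-class] with ligands "ORT" and "ALO".
#' @export
makeToyStructure <- function(spec, querySeq = NULL) {
  L <- spec@L
  one2three <- setNames(bio3d::aa123(.AA20), .AA20)
  letters1 <- if (is.null(querySeq)) rep("A", L) else {
    s <- strsplit(querySeq, "")[[1]]
    if (length(s) != L) stop("querySeq length != L")
    ifelse(s %in% .AA20, s, "A")
  }
  x <- 3.8 * (seq_len(L) - 1)
  atoms <- data.frame(
    resid = rep(one2three[letters1], each = 2L),
    resno = rep(seq_len(L), each = 2L),
    insert = "",
    elety = rep(c("CA", "CB"), L),
    x = rep(x, each = 2L),
    y = rep(c(0, -1.5), L),
    z = 0,
    stringsAsFactors = FALSE)
  ligands <- rbind(
    data.frame(ligname = "ORT", x = x[spec@orthoCols], y = 5, z = 0),
    data.frame(ligname = "ALO", x = x[spec@alloCols], y = 7.5, z = 0))
  s <- new("StructureModel", chainId = "A", atoms = atoms, ligands = ligands)
  ## constructed guarantee: the proximity rules recover the planted pockets
  po <- pocketFromLigand(s, "ORT", 6)
  if (!setequal(residueIds(po), as.character(spec@orthoCols)))
    stop("toy geometry failed to isolate the orthosteric columns")
  s
}

#' Decoy pockets of a planted family as Pocket objects
#'
#' @param spec a [PlantedFamilySpec-class].
#' @return list of candidate [Pocket-class] objects named decoy1, decoy2, ...
#' @export
decoyPockets <- function(spec) {
  lapply(seq_along(spec@decoyCols), function(k)
    new("Pocket", name = paste0("decoy", k),
        residueIds = as.character(spec@decoyCols[[k]]), role = "candidate"))
}

#' Write a planted-family fixture to disk
#'
#' Emits FASTA (alignment), PDB (toy structure), a pocket file (orthosteric
#' + allosteric + decoys) and a ground-truth JSON (planted pairs, key
#' columns, seed).
#'
#' @param spec a [PlantedFamilySpec-class].
#' @param dir output directory (created if needed).
#' @param seed sampling seed.
#' @return invisibly, the list of written paths.
#' @export
writeFixture <- function(spec, dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fam <- sampleFamily(spec, seed)
  s <- makeToyStructure(spec, querySequence(fam$aln))
  paths <- list(
    alignment = file.path(dir, "family.fasta"),
    structure = file.path(dir, "structure.pdb"),
    pockets = file.path(dir, "pockets.txt"),
    truth = file.path(dir, "truth.json"))
  writeAlignmentFasta(fam$aln, paths$alignment)
  .writeToyPdb(s, paths$structure)
  con <- file(paths$pockets, "w")
  writeLines(c("> orthosteric orthosteric",
               paste(spec@orthoCols, collapse = " "),
               "> allosteric allosteric_known",
               paste(spec@alloCols, collapse = " "),
               unlist(lapply(seq_along(spec@decoyCols), function(k)
                 c(paste0("> decoy", k, " candidate"),
                   paste(spec@decoyCols[[k]], collapse = " "))))), con)
  close(con)
  jsonlite::write_json(
    list(seed = seed, keyCols = spec@keyCols,
         orthoCols = spec@orthoCols, alloCols = spec@alloCols,
         plantedPairs = fam$plantedPairs),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

.writeToyPdb <- function(structure, path) {
  at <- structure@atoms
  lines <- sprintf(
    "ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
    seq_len(nrow(at)), at$elety, at$resid, structure@chainId, at$resno,
    at$x, at$y, at$z)
  lg <- structure@ligands
  if (nrow(lg)) {
    lines <- c(lines, sprintf(
      "HETATM%5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      nrow(at) + seq_len(nrow(lg)), "C1", lg$ligname, structure@chainId,
      9000L + seq_len(nrow(lg)), lg$x, lg$y, lg$z))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
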