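## Tien et al. (2013) theoretical maximum accessible surface areas (A^2),
## used to normalize per-residue SASA to relative exposure.
.MAX_ASA <- c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
              GLU = 223, GLN = 225, GLY = 104, HIS = 224, ILE = 197,
              LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
              SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)

## heavy-atom van der Waals radii (A) keyed by element symbol
.VDW <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90,
          F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

.elementRadius <- function(elety) {
  el <- toupper(sub("^[0-9']*", "", elety))
  el1 <- substr(el, 1, 1)
  r <- .VDW[el]
  r[is.na(r)] <- .VDW[el1[is.na(r)]]
  r[is.na(r)] <- 1.8
  unname(r)
}

#' Read a protein chain and its ligands from a PDB/mmCIF file
#'
#' Keeps heavy atoms of the first model; for alternate conformations the
#' highest-occupancy altloc is retained. Waters are discarded. Hetero
#' groups on the selected chain become ligands, identified by their residue
#' name. Residue numbering (including insertion codes) is kept verbatim.
#'
#' @param path structure file (.pdb or .cif).
#' @param chain chain identifier; default: first protein chain.
#' @return a [StructureModel-class].
#' @export
readStructure <- function(path, chain = NULL) {
  pdb <- if (grepl("\\.cif$", path, ignore.case = TRUE))
    bio3d::read.cif(path) else bio3d::read.pdb(path)
  at <- pdb$atom
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  ## drop hydrogens and waters
  if ("elesy" %in% names(at) && any(!is.na(at$elesy)))
    at <- at[!at$elesy %in% c("H", "D"), ]
  else
    at <- at[!grepl("^[0-9]*H", trimws(at$elety)), ]
  at <- at[!at$resid %in% c("HOH", "WAT", "DOD"), ]
  prot <- at[at$type == "ATOM", ]
  if (is.null(chain)) chain <- prot$chain[1]
  prot <- prot[prot$chain == chain, ]
  if (!nrow(prot)) stop("no protein atoms on chain ", chain)
  ## highest-occupancy altloc per atom
  key <- paste(prot$resno, prot$insert, prot$elety)
  ord <- order(key, -replace(prot$o, is.na(prot$o), 1))
  prot <- prot[ord, ][!duplicated(key[ord]), ]
  prot <- prot[order(prot$resno, prot$insert), ]
  het <- at[at$type == "HETATM" & at$chain == chain, ]
  ligands <- if (nrow(het))
    data.frame(ligname = het$resid, x = het$x, y = het$y, z = het$z,
               stringsAsFactors = FALSE)
  else data.frame(ligname = character(), x = numeric(), y = numeric(),
                  z = numeric())
  new("StructureModel", chainId = chain,
      atoms = data.frame(resid = prot$resid, resno = prot$resno,
                         insert = prot$insert, elety = prot$elety,
                         x = prot$x, y = prot$y, z = prot$z,
                         stringsAsFactors = FALSE),
      ligands = ligands)
}

#' Construct a Pocket
#'
#' @param name pocket label.
#' @param residueIds residue identifiers (resno + insertion code).
#' @param role "orthosteric", "candidate" or "allosteric_known".
#' @param structure optional [StructureModel-class]; when given, membership
#'   of every residue is checked.
#' @return a [Pocket-class].
#' @export
pocket <- function(name, residueIds, role = "candidate", structure = NULL) {
  residueIds <- as.character(residueIds)
  if (!is.null(structure)) {
    missing <- setdiff(residueIds, residueIds(structure))
    if (length(missing))
      stop("pocket '", name, "': residues not in structure: ",
           paste(missing, collapse = ", "))
  }
  new("Pocket", name = name, residueIds = residueIds, role = role)
}

#' Read pocket definitions from a plain-text file
#'
#' Format: one pocket per block. A block starts with `> name [role]`;
#' subsequent lines list residues as whitespace-separated `resnum` or
#' `chain:resnum` tokens (the chain part is ignored).
#'
#' @param path file path.
#' @param structure optional [StructureModel-class] for membership checks.
#' @return list of [Pocket-class] objects.
#' @export
readPocketFile <- function(path, structure = NULL) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  pockets <- list(); cur <- NULL; curName <- NULL; curRole <- "candidate"
  flush <- function() {
    if (!is.null(curName))
      pockets[[length(pockets) + 1L]] <<-
        pocket(curName, cur, role = curRole, structure = structure)
  }
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      flush()
      parts <- strsplit(trimws(sub("^>", "", ln)), "\\s+")[[1]]
      curName <- parts[1]
      curRole <- if (length(parts) > 1L) parts[2] else "candidate"
      cur <- character()
    } else {
      toks <- strsplit(ln, "\\s+")[[1]]
      cur <- c(cur, sub("^[^:]*:", "", toks))
    }
  }
  flush()
  pockets
}

.residueMinDist <- function(structure, points) {
  at <- structure@atoms
  ids <- paste0(at$resno, at$insert)
  d2 <- outer(at$x, points[, 1], "-")^2 + outer(at$y, points[, 2], "-")^2 +
    outer(at$z, points[, 3], "-")^2
  tapply(sqrt(apply(d2, 1, min)), factor(ids, levels = unique(ids)), min)
}

#' Derive a pocket from ligand proximity
#'
#' Selects every residue with at least one heavy atom within `cutoff`
#' angstroms of any heavy atom of the named ligand. The conventional
#' cutoffs are 6 A for the orthosteric ligand and 8 A for an allosteric
#' ligand used as a fallback pocket definition.
#'
#' @param structure a [StructureModel-class].
#' @param ligandName ligand residue name (e.g. "ATP").
#' @param cutoff distance cutoff in angstroms (> 0).
#' @param name pocket label (default: the ligand name).
#' @param role pocket role (default "orthosteric").
#' @return a [Pocket-class].
#' @export
pocketFromLigand <- function(structure, ligandName, cutoff = 6,
                             name = ligandName, role = "orthosteric") {
  stopifnot(cutoff > 0)
  lig <- structure@ligands[structure@ligands$ligname == ligandName, ]
  if (!nrow(lig)) stop("ligand '", ligandName, "' not found")
  md <- .residueMinDist(structure, as.matrix(lig[, c("x", "y", "z")]))
  ids <- names(md)[md <= cutoff]
  if (!length(ids))
    stop("no residues within ", cutoff, " A of ligand ", ligandName)
  pocket(name, ids, role = role, structure = structure)
}

#' Filter candidate pockets against the orthosteric pocket
#'
#' A candidate sharing more than 50% of its residues with the orthosteric
#' pocket is excluded outright; otherwise the overlapping residues are
#' removed and the trimmed pocket kept. Candidates that become empty are
#' dropped with a message. The orthosteric pocket itself is never returned.
#'
#' @param candidates list of [Pocket-class] objects.
#' @param orthosteric the orthosteric [Pocket-class].
#' @param overlapFraction exclusion threshold (default 0.5).
#' @return list of trimmed candidate pockets, disjoint from `orthosteric`.
#' @export
filterCandidatePockets <- function(candidates, orthosteric,
                                   overlapFraction = 0.5) {
  out <- list()
  for (p in candidates) {
    if (identical(pocketName(p), pocketName(orthosteric))) next
    ov <- intersect(residueIds(p), residueIds(orthosteric))
    frac <- length(ov) / length(residueIds(p))
    if (frac > overlapFraction) {
      message("pocket '", pocketName(p), "' excluded: ",
              round(100 * frac), "% overlap with the orthosteric pocket")
      next
    }
    keep <- setdiff(residueIds(p), ov)
    if (!length(keep)) {
      message("pocket '", pocketName(p), "' dropped: empty after overlap removal")
      next
    }
    out[[length(out) + 1L]] <- new("Pocket", name = pocketName(p),
                                   residueIds = keep, role = pocketRole(p))
  }
  out
}

## evenly distributed unit-sphere points (Fibonacci lattice)
.spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  y <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - y^2))
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  cbind(r * cos(phi), y, r * sin(phi))
}

#' Shrake-Rupley solvent-accessible surface area per atom
#'
#' @param xyz N x 3 coordinate matrix.
#' @param radii per-atom van der Waals radii.
#' @param probe probe radius in angstroms (water: 1.4).
#' @param nPoints test points per atom sphere.
#' @return numeric vector of per-atom accessible areas (A^2).
#' @export
shrakeRupley <- function(xyz, radii, probe = 1.4, nPoints = 244L) {
  n <- nrow(xyz)
  stopifnot(length(radii) == n)
  sp <- .spherePoints(nPoints)
  R <- radii + probe
  area <- numeric(n)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(d < R[i] + R & seq_len(n) != i)
    pts <- sweep(sp * R[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, nPoints)
    for (j in nb) {
      occ <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2 < R[j]^2
      free <- free & !occ
      if (!any(free)) break
    }
    area[i] <- 4 * pi * R[i]^2 * sum(free) / nPoints
  }
  area
}

#' Per-residue solvent accessibility
#'
#' Shrake-Rupley SASA over the protein heavy atoms, summed per residue and
#' normalized by the residue's theoretical maximum accessible area to give
#' relative exposure. Residues with unknown names get `relSasa = NA`.
#'
#' @param structure a [StructureModel-class].
#' @param probe probe radius (default 1.4 A).
#' @param nPoints sphere test points per atom (default 244).
#' @return data.frame with residueId, resid, sasa, relSasa.
#' @export
residueSasa <- function(structure, probe = 1.4, nPoints = 244L) {
  at <- structure@atoms
  area <- shrakeRupley(as.matrix(at[, c("x", "y", "z")]),
                       .elementRadius(at$elety), probe, nPoints)
  ids <- paste0(at$resno, at$insert)
  byRes <- tapply(area, factor(ids, levels = unique(ids)), sum)
  resname <- at$resid[!duplicated(ids)]
  data.frame(residueId = names(byRes), resid = resname,
             sasa = as.numeric(byRes),
             relSasa = as.numeric(byRes) / unname(.MAX_ASA[resname]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Surface residues by relative solvent accessibility
#'
#' @param structure a [StructureModel-class].
#' @param relSasaThreshold relative-SASA cutoff (default 0.10). Residues
#'   whose relative SASA cannot be normalized (unknown residue name) are
#'   kept when their absolute SASA exceeds 10 A^2.
#' @param probe,nPoints passed to [residueSasa()].
#' @return character vector of residue ids.
#' @export
surfaceResidues <- function(structure, relSasaThreshold = 0.10, probe = 1.4,
                            nPoints = 244L) {
  rs <- residueSasa(structure, probe, nPoints)
  keep <- ifelse(is.na(rs$relSasa), rs$sasa > 10,
                 rs$relSasa >= relSasaThreshold)
  rs$residueId[keep]
}

.structureSequence <- function(structure) {
  at <- structure@atoms
  ids <- paste0(at$resno, at$insert)
  resname <- at$resid[!duplicated(ids)]
  one <- bio3d::aa321(resname)
  one[is.na(one) | one == "X"] <- "X"
  list(ids = unique(ids), seq = paste(one, collapse = ""), letters = one)
}

#' Map structure residues to alignment columns
#'
#' Globally aligns the structure-observed one-letter sequence against the
#' gapless query row of the alignment and records the residue-to-column
#' correspondence. Mismatching positions are dropped unless
#' `tolerateMismatch = TRUE` (they are then flagged in the `matched`
#' column). Coverage below 50% of structure residues aborts, since that
#' usually means the wrong chain or the wrong family alignment.
#'
#' @param structure a [StructureModel-class].
#' @param aln a [CodedAlignment-class] whose query row is the structure's
#'   protein.
#' @param tolerateMismatch keep mismatching aligned pairs (default FALSE).
#' @return a [ResidueColumnMap-class].
#' @export
mapStructureToAlignment <- function(structure, aln, tolerateMismatch = FALSE) {
  ss <- .structureSequence(structure)
  qchars <- strsplit(querySequence(aln), "")[[1]]
  nonGapCols <- which(qchars != "-")
  qseq <- paste(qchars[nonGapCols], collapse = "")
  letters <- unique(c(strsplit(ss$seq, "")[[1]], strsplit(qseq, "")[[1]]))
  subm <- matrix(-1, length(letters), length(letters),
                 dimnames = list(letters, letters))
  diag(subm) <- 2
  pa <- Biostrings::pairwiseAlignment(ss$seq, qseq, type = "global",
                                      substitutionMatrix = subm,
                                      gapOpening = 5, gapExtension = 2)
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ip <- 0L; is_ <- 0L
  rows <- list()
  for (k in seq_along(ap)) {
    if (ap[k] != "-") ip <- ip + 1L
    if (as_[k] != "-") is_ <- is_ + 1L
    if (ap[k] != "-" && as_[k] != "-") {
      same <- ap[k] == as_[k]
      if (same || tolerateMismatch)
        rows[[length(rows) + 1L]] <- data.frame(
          residueId = ss$ids[ip], column = nonGapCols[is_], matched = same,
          stringsAsFactors = FALSE)
      else
        message("unmapped mismatch: structure ", ss$ids[ip], " (", ap[k],
                ") vs column ", nonGapCols[is_], " (", as_[k], ")")
    }
  }
  map <- if (length(rows)) do.call(rbind, rows) else
    data.frame(residueId = character(), column = integer(),
               matched = logical())
  coverage <- nrow(map) / length(ss$ids)
  if (coverage < 0.5)
    stop(sprintf(paste0("only %.0f%% of structure residues mapped to the ",
                        "alignment; wrong chain or wrong family?"),
                 100 * coverage))
  new("ResidueColumnMap", map = map, coverage = coverage)
}

#' Write a residue-to-column map as TSV
#' @param map a [ResidueColumnMap-class].
#' @param path output file.
#' @export
writeMapTsv <- function(map, path) {
  write.table(map@map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## look up alignment columns for a set of residue ids; unmapped are dropped
.mapColumns <- function(residueIds, map, warn = TRUE) {
  idx <- match(as.character(residueIds), map@map$residueId)
  if (warn && anyNA(idx))
    warning(sum(is.na(idx)), " residue(s) not mapped to alignment columns",
            call. = FALSE)
  map@map$column[idx[!is.na(idx)]]
}
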