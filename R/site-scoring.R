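## sum of FN over cross pairs of two column sets, optionally top-k pairs only
.crossSum <- function(FN, colsA, colsB, topKPairs = NULL) {
  v <- as.numeric(FN[colsA, colsB, drop = FALSE])
  if (!is.null(topKPairs)) {
    k <- min(topKPairs, length(v))
    v <- sort(v, decreasing = TRUE)[seq_len(k)]
  }
  sum(v)
}

#' Evolutionary coupling strength between a pocket and the orthosteric pocket
#'
#' The ECS of a candidate pocket is the sum of the raw Frobenius-norm
#' coupling strengths FN(i, j) over every residue pair spanning the two
#' pockets. With `topKPairs` set, only the k largest cross-pair values are
#' summed (pocket-size control; k is capped at the number of available
#' pairs). The raw FN (not the APC-corrected score) is used here by design;
#' key-residue identification uses the corrected EC instead.
#'
#' @param FN L x L coupling strength matrix.
#' @param cavity candidate [Pocket-class], disjoint from the orthosteric
#'   pocket (apply [filterCandidatePockets()] upstream).
#' @param orthosteric the orthosteric [Pocket-class].
#' @param map a [ResidueColumnMap-class].
#' @param topKPairs optional count of largest cross pairs to sum.
#' @return non-negative scalar ECS.
#' @export
pocketEcs <- function(FN, cavity, orthosteric, map, topKPairs = NULL) {
  ca <- .mapColumns(residueIds(cavity), map)
  oa <- .mapColumns(residueIds(orthosteric), map)
  if (!length(ca) || !length(oa))
    stop("pocket '", pocketName(cavity),
         "': no mapped residues in cavity or orthosteric pocket")
  .crossSum(FN, ca, oa, topKPairs)
}

.zTable <- function(names, nres, ecs, zThreshold) {
  mu <- mean(ecs)
  sigma <- sqrt(mean((ecs - mu)^2)) # population SD
  z <- if (sigma > 0) (ecs - mu) / sigma else rep(0, length(ecs))
  ord <- order(-z, names)
  df <- data.frame(pocket = names, nResidues = nres, ECS = ecs, z = z,
                   stringsAsFactors = FALSE)
  df$rank <- integer(length(ecs))
  df$rank[ord] <- seq_along(ecs)
  df$predictedAllosteric <- df$z > zThreshold
  attr(df, "mu") <- mu
  attr(df, "sigma") <- sigma
  df[order(df$rank), ]
}

#' Rank candidate pockets by coupling strength to the orthosteric pocket
#'
#' Computes the ECS of every scoreable candidate, normalizes over the
#' cohort to Z-scores (population SD) and ranks by descending z (ties by
#' pocket name). Pockets with z above `zThreshold` (default 0.5) are
#' flagged as predicted allosteric. When every candidate has the same ECS
#' all z are zero and nothing is flagged; with fewer than two scoreable
#' candidates z is undefined (NA) and a warning is raised.
#'
#' @param candidates list of candidate [Pocket-class] objects (already
#'   filtered against the orthosteric pocket).
#' @param orthosteric the orthosteric [Pocket-class].
#' @param FN L x L coupling strength matrix.
#' @param map a [ResidueColumnMap-class].
#' @param zThreshold allosteric call threshold (default 0.5).
#' @param topKPairs optional top-k-pairs ECS variant.
#' @return data.frame: pocket, nResidues, ECS, z, rank, predictedAllosteric,
#'   ordered by rank; cohort mean/SD as attributes "mu"/"sigma".
#' @export
rankPockets <- function(candidates, orthosteric, FN, map, zThreshold = 0.5,
                        topKPairs = NULL) {
  ecs <- numeric(0); nm <- character(0); nres <- integer(0)
  for (p in candidates) {
    e <- tryCatch(pocketEcs(FN, p, orthosteric, map, topKPairs),
                  error = function(e) {
                    warning("pocket '", pocketName(p), "' not scoreable: ",
                            conditionMessage(e), call. = FALSE)
                    NA_real_
                  })
    if (!is.na(e)) {
      ecs <- c(ecs, e); nm <- c(nm, pocketName(p))
      nres <- c(nres, length(residueIds(p)))
    }
  }
  if (length(ecs) < 2L) {
    warning("fewer than 2 scoreable candidate pockets; z undefined",
            call. = FALSE)
    return(data.frame(pocket = nm, nResidues = nres, ECS = ecs,
                      z = NA_real_, rank = seq_along(ecs),
                      predictedAllosteric = NA))
  }
  .zTable(nm, nres, ecs, zThreshold)
}

#' Score single residues as singleton pockets
#'
#' Each residue of `residueSet` is treated as a one-residue pocket, its ECS
#' to the orthosteric pocket computed and Z-normalized over the set (the
#' exposed Ser/Thr/Tyr PTM-site analysis). Unmapped residues are excluded
#' with a warning.
#'
#' @param residueSet residue ids, disjoint from the orthosteric pocket.
#' @param orthosteric the orthosteric [Pocket-class].
#' @param FN coupling strength matrix.
#' @param map a [ResidueColumnMap-class].
#' @param zThreshold call threshold (default 0.5).
#' @return data.frame as in [rankPockets()], one row per residue.
#' @export
scoreSingleResidues <- function(residueSet, orthosteric, FN, map,
                                zThreshold = 0.5) {
  residueSet <- as.character(residueSet)
  if (length(intersect(residueSet, residueIds(orthosteric))))
    stop("residue set overlaps the orthosteric pocket")
  singles <- lapply(residueSet, function(r)
    new("Pocket", name = r, residueIds = r, role = "candidate"))
  rankPockets(singles, orthosteric, FN, map, zThreshold)
}

#' Random surface-patch control
#'
#' Tests whether the allosteric-orthosteric coupling exceeds that of two
#' size-matched random surface patches. Per repeat, two distinct surface
#' residues outside both reference pockets are drawn as centers; patch1 is
#' the |orthosteric| residues nearest (CA distance) the first center and
#' patch2 the |allosteric| residues nearest the second. Draws where the
#' patches overlap each other by more than 50% are retried. Reports the
#' mean and SD of the patch-pair ECS over the repeats next to the observed
#' allosteric ECS.
#'
#' @param structure a [StructureModel-class].
#' @param orthosteric,allosteric reference [Pocket-class] objects.
#' @param FN coupling strength matrix.
#' @param map a [ResidueColumnMap-class].
#' @param repeats number of patch draws (default 4).
#' @param seed RNG seed for reproducible draws.
#' @param relSasaThreshold surface definition (default 0.10).
#' @param maxRetries redraw budget per repeat (default 20).
#' @return list with patchEcs (per repeat), patchMean, patchSd (sample SD),
#'   alloEcs.
#' @export
randomPatchControl <- function(structure, orthosteric, allosteric, FN, map,
                               repeats = 4L, seed = 1L,
                               relSasaThreshold = 0.10, maxRetries = 20L) {
  surf <- surfaceResidues(structure, relSasaThreshold)
  excl <- union(residueIds(orthosteric), residueIds(allosteric))
  centers <- setdiff(surf, excl)
  if (length(centers) < 2L)
    stop("not enough surface residues outside the reference pockets")
  at <- structure@atoms
  ca <- at[at$elety == "CA", ]
  if (!nrow(ca)) ca <- at[!duplicated(paste0(at$resno, at$insert)), ]
  caIds <- paste0(ca$resno, ca$insert)
  caXyz <- as.matrix(ca[, c("x", "y", "z")])
  nearest <- function(center, n) {
    d <- sqrt(colSums((t(caXyz) - caXyz[match(center, caIds), ])^2))
    caIds[order(d)][seq_len(min(n, length(caIds)))]
  }
  nOrtho <- length(residueIds(orthosteric))
  nAllo <- length(residueIds(allosteric))
  set.seed(seed)
  patchEcs <- numeric(repeats)
  for (r in seq_len(repeats)) {
    ok <- FALSE
    for (try in seq_len(maxRetries)) {
      cs <- sample(centers, 2L)
      p1 <- nearest(cs[1], nOrtho)
      p2 <- nearest(cs[2], nAllo)
      if (length(intersect(p1, p2)) / min(length(p1), length(p2)) <= 0.5) {
        ok <- TRUE; break
      }
    }
    if (!ok) stop("could not draw non-overlapping patches")
    c1 <- .mapColumns(p1, map, warn = FALSE)
    c2 <- .mapColumns(p2, map, warn = FALSE)
    patchEcs[r] <- .crossSum(FN, c1, c2)
  }
  alloEcs <- pocketEcs(FN, allosteric, orthosteric, map)
  list(patchEcs = patchEcs, patchMean = mean(patchEcs),
       patchSd = sd(patchEcs), alloEcs = alloEcs)
}
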