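# shared small fixtures for the unit suite

# deterministic random alignment over the first q states (no planted signal)
randomAlignment <- function(n, L, q, seed = 1) {
  set.seed(seed)
  alpha <- alloAlphabet(q)
  seqs <- replicate(n, paste(sample(alpha[-1], L, TRUE), collapse = ""))
  codedAlignment(seqs, q = q)
}

# small planted family used across modules: fast to sample and to fit
tinySpec <- function(...) {
  args <- utils::modifyList(
    list(L = 12L, q = 4L, nSequences = 400L,
         orthoCols = 2:4, alloCols = 7:9,
         decoyCols = list(10:12), keyCols = 7L,
         couplingStrength = 0.6, keyBoost = 4,
         burnIn = 200L, thinning = 5L),
    list(...))
  do.call(plantedFamilySpec, args)
}

# toy 3-residue structure with tabulated coordinates: residue 1 has an atom
# 5.9 A from the ligand atom at the origin, residue 2 one at 6.1 A,
# residue 3 one at 7.9 A
toyThreeResidues <- function() {
  atoms <- data.frame(
    resid = c("ALA", "GLY", "SER"),
    resno = 1:3, insert = "",
    elety = "CA",
    x = c(5.9, 6.1, 7.9), y = 0, z = 0,
    stringsAsFactors = FALSE)
  lig <- data.frame(ligname = "LIG", x = 0, y = 0, z = 0)
  new("StructureModel", chainId = "A", atoms = atoms, ligands = lig)
}

# identity residue->column map over 1..L
identityMap <- function(L) {
  new("ResidueColumnMap",
      map = data.frame(residueId = as.character(seq_len(L)),
                       column = seq_len(L), matched = TRUE,
                       stringsAsFactors = FALSE),
      coverage = 1)
}

# literal Frobenius-norm oracle: explicit centering and double loop
literalBlockFn <- function(B) {
  q <- nrow(B)
  Bc <- matrix(0, q, q)
  for (k in seq_len(q)) for (l in seq_len(q))
    Bc[k, l] <- B[k, l] - mean(B[k, ]) - mean(B[, l]) + mean(B)
  s <- 0
  for (k in seq_len(q)) for (l in seq_len(q)) s <- s + Bc[k, l]^2
  sqrt(s)
}

# literal APC oracle with explicit index sums (diagonal excluded from means)
literalApc <- function(FN) {
  L <- nrow(FN)
  EC <- matrix(0, L, L)
  m <- numeric(L)
  for (i in seq_len(L)) {
    s <- 0
    for (j in seq_len(L)) if (j != i) s <- s + FN[i, j]
    m[i] <- s / (L - 1)
  }
  tot <- 0
  for (i in seq_len(L)) for (j in seq_len(L)) if (j != i) tot <- tot + FN[i, j]
  gm <- tot / (L * (L - 1))
  for (i in seq_len(L)) for (j in seq_len(L)) if (i != j)
    EC[i, j] <- FN[i, j] - m[i] * m[j] / gm
  EC
}

# random symmetric non-negative matrix with zero diagonal
randomFn <- function(L, seed = 1) {
  set.seed(seed)
  M <- matrix(abs(rnorm(L * L)), L, L)
  M <- (M + t(M)) / 2
  diag(M) <- 0
  M
}
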