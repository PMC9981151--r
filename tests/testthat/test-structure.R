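test_that("ligand-proximity pockets respect the distance cutoff", {
  s <- toyThreeResidues()
  p6 <- pocketFromLigand(s, "LIG", 6)
  expect_equal(residueIds(p6), "1")     # 5.9 in, 6.1 out
  p8 <- pocketFromLigand(s, "LIG", 8)
  expect_setequal(residueIds(p8), c("1", "2", "3"))
  expect_error(pocketFromLigand(s, "NOPE", 6), "not found")
  expect_error(pocketFromLigand(s, "LIG", 2), "no residues within")

  # monotone in cutoff, membership equals the brute-force distance check
  at <- s@atoms; lig <- s@ligands
  prev <- character(0)
  for (cut in c(3, 6, 6.5, 8, 10)) {
    p <- tryCatch(residueIds(pocketFromLigand(s, "LIG", cut)),
                  error = function(e) character(0))
    expect_true(all(prev %in% p))
    brute <- unique(at$resno[vapply(seq_len(nrow(at)), function(k)
      any(sqrt((at$x[k] - lig$x)^2 + (at$y[k] - lig$y)^2 +
                 (at$z[k] - lig$z)^2) <= cut), TRUE)])
    expect_setequal(p, as.character(brute))
    prev <- p
  }
})

test_that("candidate pockets are filtered by the >50% overlap rule", {
  ortho <- pocket("orthosteric", as.character(1:10), role = "orthosteric")
  mk <- function(ids, nm) pocket(nm, as.character(ids))
  # 6/10 overlap: excluded outright
  # 4/10 overlap: kept with the 6 non-overlapping residues
  # exactly 5/10: *not* more than 50%, kept with 5 residues
  cands <- list(mk(c(1:6, 11:14), "over"),
                mk(c(1:4, 11:16), "trim"),
                mk(c(1:5, 11:15), "edge"),
                mk(1:10, "swallowed"))
  expect_message(out <- filterCandidatePockets(cands, ortho), "excluded")
  nms <- vapply(out, pocketName, "")
  expect_setequal(nms, c("trim", "edge"))
  expect_setequal(residueIds(out[[match("trim", nms)]]), as.character(11:16))
  expect_setequal(residueIds(out[[match("edge", nms)]]), as.character(11:15))
  # outputs are disjoint from the orthosteric pocket
  for (p in out)
    expect_length(intersect(residueIds(p), residueIds(ortho)), 0)
  # the orthosteric pocket itself is never returned
  out2 <- filterCandidatePockets(c(cands, list(ortho)), ortho)
  expect_false("orthosteric" %in% vapply(out2, pocketName, ""))
})

test_that("Shrake-Rupley areas agree with closed-form sphere geometry", {
  # isolated atom: full sphere of radius r + probe
  a <- shrakeRupley(matrix(c(0, 0, 0), 1), radii = 1.7, probe = 1.4,
                    nPoints = 2000L)
  expect_equal(a, 4 * pi * 3.1^2, tolerance = 1e-6)

  # two equal spheres at distance d: lost area per sphere is the spherical
  # cap 2*pi*R*h with h = R - d/2 (analytic, since the buried cap is cut at
  # the midplane)
  R <- 1.7 + 1.4; d <- 3.0
  a2 <- shrakeRupley(matrix(c(0, 0, 0, d, 0, 0), 2, byrow = TRUE),
                     radii = c(1.7, 1.7), probe = 1.4, nPoints = 5000L)
  capA <- 2 * pi * R * (R - d / 2)
  expect_equal(a2[1], 4 * pi * R^2 - capA, tolerance = 0.02)

  # an atom enclosed by a shell of neighbours has zero accessible area
  sh <- allosite:::.spherePoints(60) * 2.5
  xyz <- rbind(c(0, 0, 0), sh)
  aN <- shrakeRupley(xyz, radii = rep(1.7, nrow(xyz)), probe = 1.4,
                     nPoints = 500L)
  expect_equal(aN[1], 0)
})

test_that("relative SASA separates exposed from buried residues", {
  # a single isolated residue is fully exposed
  one <- new("StructureModel", chainId = "A",
             atoms = data.frame(resid = "GLY", resno = 1, insert = "",
                                elety = "CA", x = 0, y = 0, z = 0),
             ligands = data.frame(ligname = character(), x = numeric(),
                                  y = numeric(), z = numeric()))
  rs <- residueSasa(one)
  expect_gt(rs$relSasa, 0.9)
  expect_equal(surfaceResidues(one), "1")

  # a residue buried under a shell is never surface
  sh <- allosite:::.spherePoints(80) * 2.5
  atoms <- data.frame(resid = c("GLY", rep("ALA", nrow(sh))),
                      resno = c(1, rep(2, nrow(sh))), insert = "",
                      elety = c("CA", paste0("C", seq_len(nrow(sh)))),
                      x = c(0, sh[, 1]), y = c(0, sh[, 2]),
                      z = c(0, sh[, 3]))
  buried <- new("StructureModel", chainId = "A", atoms = atoms,
                ligands = one@ligands)
  expect_false("1" %in% surfaceResidues(buried))
})

test_that("structure residues map onto alignment columns of the query", {
  spec <- tinySpec()
  fam <- sampleFamily(spec, seed = 4)
  s <- makeToyStructure(spec, querySequence(fam$aln))
  # identical sequences: identity map at coverage 1
  mp <- mapStructureToAlignment(s, fam$aln)
  expect_equal(mp@coverage, 1.0)
  expect_equal(mp@map$column, seq_len(spec@L))
  expect_equal(mp@map$residueId, as.character(seq_len(spec@L)))

  # two missing N-terminal residues: those columns drop out
  s2 <- s
  s2@atoms <- s2@atoms[s2@atoms$resno > 2, ]
  mp2 <- mapStructureToAlignment(s2, fam$aln)
  expect_equal(mp2@coverage, 1.0)           # all *observed* residues map
  expect_equal(nrow(mp2@map), spec@L - 2L)
  expect_false(any(c(1L, 2L) %in% mp2@map$column))

  # a point mutation is unmapped by default, mapped under tolerance
  s3 <- s
  qs <- strsplit(querySequence(fam$aln), "")[[1]]
  swap <- if (qs[5] == "A") "TRP" else "ALA"
  s3@atoms$resid[s3@atoms$resno == 5] <- swap
  expect_message(mp3 <- mapStructureToAlignment(s3, fam$aln), "mismatch")
  expect_false("5" %in% mp3@map$residueId)
  mp3t <- mapStructureToAlignment(s3, fam$aln, tolerateMismatch = TRUE)
  expect_true("5" %in% mp3t@map$residueId)
  expect_false(mp3t@map$matched[mp3t@map$residueId == "5"])
})

test_that("pocket files round-trip residue lists with roles", {
  f <- tempfile(fileext = ".txt")
  writeLines(c("> orthosteric orthosteric", "A:1 A:2 3",
               "> cav1", "10 11", "12"), f)
  ps <- readPocketFile(f)
  expect_length(ps, 2L)
  expect_equal(pocketRole(ps[[1]]), "orthosteric")
  expect_setequal(residueIds(ps[[1]]), c("1", "2", "3"))
  expect_setequal(residueIds(ps[[2]]), c("10", "11", "12"))
  expect_equal(pocketRole(ps[[2]]), "candidate")
})
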