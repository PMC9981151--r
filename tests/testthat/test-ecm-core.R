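test_that("analytic PLM gradient matches central finite differences", {
  aln <- randomAlignment(25, 5, 4, seed = 2)
  w <- computeWeights(aln, 0.8)
  q <- 4L; L <- 5L
  npar <- q + (L - 1L) * q * q
  set.seed(7)
  par <- rnorm(npar, sd = 0.4)
  an <- plmSiteObjective(aln, w, 3, par)
  eps <- 1e-5
  fd <- vapply(seq_len(npar), function(k) {
    up <- par; up[k] <- up[k] + eps
    dn <- par; dn[k] <- dn[k] - eps
    (plmSiteObjective(aln, w, 3, up)$value -
       plmSiteObjective(aln, w, 3, dn)$value) / (2 * eps)
  }, numeric(1))
  relErr <- max(abs(fd - an$gradient) / pmax(1, abs(fd)))
  expect_lt(relErr, 1e-7)
})

test_that("constant columns produce no covariation signal", {
  # identical sequences: the constant likelihood spreads uniformly over
  # fields and couplings, so FN is flat and APC removes it entirely;
  # stronger regularization pins the couplings themselves near zero
  aln <- codedAlignment(rep("ACDEF", 10), q = 6)
  w <- computeWeights(aln, 0.8)
  expect_warning(m <- fitPlm(aln, w), "neff")
  expect_lt(max(abs(m@J)), 1)
  sc <- couplingScores(m)
  off <- fnMatrix(sc)[upper.tri(fnMatrix(sc))]
  expect_lt(diff(range(off)), 1e-4)           # flat background
  expect_lt(max(abs(ecMatrix(sc))), 1e-6)     # no signal after APC
  mStrong <- suppressWarnings(fitPlm(aln, w, lambdaJ = 10))
  expect_lt(max(abs(mStrong@J)), 0.01)
})

test_that("stronger coupling regularization shrinks J toward zero", {
  fam <- sampleFamily(tinySpec(), seed = 5)
  w <- computeWeights(fam$aln)
  mSmall <- fitPlm(fam$aln, w, lambdaJ = 0.1)
  mBig <- fitPlm(fam$aln, w, lambdaJ = 1e4)
  expect_lt(max(abs(mBig@J)), 0.01)
  expect_gt(max(abs(mSmall@J)), max(abs(mBig@J)))
})

test_that("fitted couplings are symmetric with zero diagonal and finite", {
  fam <- sampleFamily(tinySpec(), seed = 1)
  m <- fitPlm(fam$aln, computeWeights(fam$aln))
  L <- alnLength(fam$aln)
  for (i in seq_len(L)) expect_equal(max(abs(m@J[i, i, , ])), 0)
  for (i in 1:3) for (j in 4:6)
    expect_equal(m@J[i, j, , ], t(m@J[j, i, , ]))
  expect_true(all(is.finite(m@J)))
})

test_that("Frobenius norms match closed forms and a literal-loop oracle", {
  L <- 4L; q <- 5L
  J <- array(0, dim = c(L, L, q, q))
  m0 <- new("PottsModel", h = matrix(0, L, q), J = J, lambdaH = 0.01,
            lambdaJ = 0.01, converged = rep(TRUE, L), message = "")
  expect_equal(frobeniusNorms(m0), matrix(0, L, L))

  # 2-state zero-sum block [[c,-c],[-c,c]] has norm 2|c|
  J2 <- array(0, dim = c(2, 2, 2, 2))
  cc <- 0.7
  blk <- matrix(c(cc, -cc, -cc, cc), 2, 2)
  J2[1, 2, , ] <- blk; J2[2, 1, , ] <- t(blk)
  m2 <- new("PottsModel", h = matrix(0, 2, 2), J = J2, lambdaH = 0,
            lambdaJ = 0, converged = c(TRUE, TRUE), message = "")
  expect_equal(frobeniusNorms(m2, excludeGaps = FALSE)[1, 2], 2 * cc)

  # random 21-state block equals the explicit centering + double-sum oracle
  set.seed(11)
  q21 <- 21L
  B <- matrix(rnorm(q21 * q21), q21, q21)
  Jr <- array(0, dim = c(2, 2, q21, q21))
  Jr[1, 2, , ] <- B; Jr[2, 1, , ] <- t(B)
  mr <- new("PottsModel", h = matrix(0, 2, q21), J = Jr, lambdaH = 0,
            lambdaJ = 0, converged = c(TRUE, TRUE), message = "")
  expect_equal(frobeniusNorms(mr, excludeGaps = FALSE)[1, 2],
               literalBlockFn(B), tolerance = 1e-12)
  # gap exclusion drops the first state row/column before centering
  expect_equal(frobeniusNorms(mr, excludeGaps = TRUE)[1, 2],
               literalBlockFn(B[-1, -1]), tolerance = 1e-12)
})

test_that("gauge shifts of a coupling block leave the Frobenius norm alone", {
  set.seed(4)
  q <- 6L
  B <- matrix(rnorm(q * q), q, q)
  shift <- B + matrix(rnorm(q), q, q, byrow = TRUE)  # add const per column
  shift <- shift + matrix(rnorm(q), q, q)            # and per row
  expect_equal(literalBlockFn(B), literalBlockFn(shift), tolerance = 1e-10)
  J <- array(0, dim = c(2, 2, q, q))
  J[1, 2, , ] <- B; J[2, 1, , ] <- t(B)
  Js <- J; Js[1, 2, , ] <- shift; Js[2, 1, , ] <- t(shift)
  mk <- function(JJ) new("PottsModel", h = matrix(0, 2, q), J = JJ,
                         lambdaH = 0, lambdaJ = 0,
                         converged = c(TRUE, TRUE), message = "")
  expect_equal(frobeniusNorms(mk(J), excludeGaps = FALSE),
               frobeniusNorms(mk(Js), excludeGaps = FALSE),
               tolerance = 1e-10)
})

test_that("APC equals the literal oracle and removes uniform background", {
  # constant off-diagonal FN is fully explained by the product background
  L <- 6L
  FNc <- matrix(0.8, L, L); diag(FNc) <- 0
  expect_equal(applyApc(FNc), matrix(0, L, L), tolerance = 1e-12)
  # all-zero FN is guarded
  expect_equal(applyApc(matrix(0, 4, 4)), matrix(0, 4, 4))
  # random symmetric matrices match the explicit-index-sum implementation
  for (seed in 1:3) {
    FN <- randomFn(6, seed)
    expect_equal(applyApc(FN), literalApc(FN), tolerance = 1e-12)
  }
})

test_that("column permutations permute FN and EC consistently", {
  fam <- sampleFamily(tinySpec(), seed = 2)
  aln <- fam$aln
  w <- computeWeights(aln)
  sc <- couplingScores(fitPlm(aln, w))
  perm <- sample(alnLength(aln))
  seqsP <- vapply(strsplit(aln@sequences, ""), function(s)
    paste(s[perm], collapse = ""), "")
  alnP <- codedAlignment(seqsP, aln@ids, queryId = "query",
                         q = alphabetSize(aln))
  scP <- couplingScores(fitPlm(alnP, computeWeights(alnP)))
  # column j of the permuted alignment is original column perm[j]; the
  # optimizer path differs slightly, hence the loose numeric tolerance
  expect_equal(fnMatrix(scP), fnMatrix(sc)[perm, perm], tolerance = 1e-2)
  expect_equal(ecMatrix(scP), ecMatrix(sc)[perm, perm], tolerance = 1e-2)
})

test_that("a planted strong pair is ranked first on exactly sampled families", {
  spec <- plantedFamilySpec(L = 6, q = 3, nSequences = 1000,
                            orthoCols = 2L, alloCols = 5L,
                            decoyCols = list(), keyCols = integer(0),
                            couplingStrength = 1.0, burnIn = 500,
                            thinning = 5)
  hits <- 0L
  for (seed in 1:5) {
    fam <- sampleFamily(spec, seed = seed)
    FN <- frobeniusNorms(fitPlm(fam$aln, computeWeights(fam$aln)))
    ut <- which(upper.tri(FN), arr.ind = TRUE)
    best <- ut[which.max(FN[ut]), ]
    if (best[1] == 2 && best[2] == 5) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})
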