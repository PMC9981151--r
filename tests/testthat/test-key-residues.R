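test_that("profile matrix gathers EC entries by residue pair", {
  L <- 8L
  EC <- randomFn(L, seed = 21)
  mp <- identityMap(L)
  ortho <- pocket("orthosteric", c("1", "2", "3"), role = "orthosteric")
  E <- buildProfileMatrix(EC, c("5", "7"), ortho, mp)
  expect_equal(dim(E), c(2L, 3L))
  expect_equal(E["5", "2"], EC[5, 2])
  expect_equal(E["7", "1"], EC[7, 1])
  expect_equal(rownames(E), c("5", "7"))
  # a candidate inside the orthosteric pocket violates the precondition
  expect_error(buildProfileMatrix(EC, c("2", "5"), ortho, mp), "overlap")
  # too few rows or columns is an input error
  expect_error(buildProfileMatrix(EC, "5", ortho, mp), ">= 2")
  # enzyme mode: all residues outside the pocket form the rows
  outside <- setdiff(as.character(1:L), residueIds(ortho))
  Eo <- buildProfileMatrix(EC, outside, ortho, mp)
  expect_equal(nrow(Eo), L - 3L)
})

test_that("pairwise t-tests fill C symmetrically and d counts columns", {
  # identical rows never differ
  E0 <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  s0 <- pairwiseSignificance(E0)
  expect_equal(as.numeric(s0@C), rep(0, 4))
  expect_equal(s0@d, c(a = 0, b = 0), ignore_attr = TRUE)

  # separated means with negligible variance are significant
  E1 <- rbind(a = c(0, 0, 0, 0), b = c(5, 5, 5, 5.0001))
  s1 <- pairwiseSignificance(E1)
  expect_equal(s1@d, c(1, 1), ignore_attr = TRUE)

  # zero-variance degeneracies: equal means p = 1, unequal p = 0
  Ez <- rbind(c(2, 2, 2), c(2, 2, 2), c(3, 3, 3))
  sz <- pairwiseSignificance(Ez)
  expect_equal(sz@d, c(1, 1, 2), ignore_attr = TRUE)

  # a 4x5 matrix against the reference t-test pair by pair
  set.seed(31)
  E <- matrix(rnorm(20, mean = rep(c(0, 0, 1, 3), 5)), 4, 5,
              dimnames = list(paste0("r", 1:4), NULL))
  for (tv in c("student", "welch", "paired")) {
    s <- pairwiseSignificance(E, test = tv)
    for (m in 1:3) for (i in (m + 1):4) {
      p <- switch(tv,
        student = t.test(E[m, ], E[i, ], var.equal = TRUE)$p.value,
        welch = t.test(E[m, ], E[i, ])$p.value,
        paired = t.test(E[m, ], E[i, ], paired = TRUE)$p.value)
      expect_equal(s@C[m, i], as.integer(p < 0.05))
      expect_equal(s@C[i, m], s@C[m, i])  # two-sided symmetry
    }
    expect_equal(s@d, colSums(s@C), ignore_attr = TRUE)
    expect_equal(sum(s@d) %% 2, 0)  # sum of counts is even
    expect_equal(diag(s@C), rep(0L, 4), ignore_attr = TRUE)
  }
})

test_that("location shifts of the whole matrix leave significance unchanged", {
  set.seed(41)
  E <- matrix(rnorm(24, mean = rep(c(0, 0.5, 2, 0), 6)), 4, 6,
              dimnames = list(paste0("r", 1:4), NULL))
  s <- scoreKeyResidues(pairwiseSignificance(E), 0.8)
  sShift <- scoreKeyResidues(pairwiseSignificance(E + 7.3), 0.8)
  expect_equal(s@C, sShift@C)
  expect_equal(s@d, sShift@d)
  expect_equal(s@z, sShift@z)
})

test_that("duplicating orthosteric columns cannot weaken significance", {
  set.seed(51)
  for (rep_ in 1:5) {
    E <- matrix(rnorm(15, mean = rep(runif(3, 0, 2), 5)), 3, 5)
    rownames(E) <- paste0("r", 1:3)
    s1 <- pairwiseSignificance(E)
    s2 <- pairwiseSignificance(cbind(E, E))
    expect_true(all(s2@C >= s1@C))
  }
})

test_that("significance-count Z-scores and key calls follow the count spread", {
  # equal counts: no spread, no keys, with a warning
  sEq <- new(Class = "SignificanceResult",
             C = matrix(0L, 3, 3, dimnames = list(letters[1:3], letters[1:3])),
             d = c(3, 3, 3), z = rep(NA_real_, 3), mu = NA_real_,
             sigma = NA_real_, alpha = 0.05, threshold = NA_real_,
             table = data.frame())
  expect_warning(rEq <- scoreKeyResidues(sEq, 0.8), "identical")
  expect_equal(rEq@z, rep(0, 3))
  expect_false(any(rEq@table$isKey))

  # d = (9,1,1,1): z1 = (9-3)/sqrt(27) = 1.732..., only residue 1 is key
  s4 <- new(Class = "SignificanceResult",
            C = matrix(0L, 4, 4, dimnames = list(1:4, 1:4)),
            d = c(9, 1, 1, 1), z = rep(NA_real_, 4), mu = NA_real_,
            sigma = NA_real_, alpha = 0.05, threshold = NA_real_,
            table = data.frame())
  r4 <- scoreKeyResidues(s4, 0.8)
  expect_equal(r4@z[1], 6 / sqrt(mean((c(9, 1, 1, 1) - 3)^2)))
  expect_equal(r4@z[1], 1.7320508, tolerance = 1e-6)
  expect_equal(r4@table$residue[r4@table$isKey], "1")
  # z normalization contracts: mean 0, population SD 1
  expect_equal(mean(r4@z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(r4@z^2)), 1, tolerance = 1e-12)

  # key count is monotone non-increasing over a threshold sweep
  set.seed(61)
  E <- matrix(rnorm(40, mean = rep(c(0, 0, 0.4, 1, 2, 0, 3, 0.1), 5)), 8, 5)
  rownames(E) <- paste0("r", 1:8)
  sig <- pairwiseSignificance(E)
  counts <- vapply(seq(0.5, 1.0, by = 0.1), function(th)
    sum(scoreKeyResidues(sig, th)@table$isKey), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("planted key columns dominate the significance ranking", {
  # allosteric rows with boosted couplings must collect the most
  # significant differences (precision at k over several families)
  spec <- tinySpec(nSequences = 500L)
  hits <- 0L; total <- 0L
  for (seed in 1:5) {
    fam <- sampleFamily(spec, seed = seed)
    sc <- couplingScores(fitPlm(fam$aln, computeWeights(fam$aln)))
    mp <- identityMap(spec@L)
    ortho <- pocket("orthosteric", as.character(spec@orthoCols),
                    role = "orthosteric")
    sig <- keyResidues(ecMatrix(sc), as.character(spec@alloCols), ortho, mp)
    k <- length(spec@keyCols)
    topK <- sig@table$residue[sig@table$rank <= k]
    hits <- hits + length(intersect(topK, as.character(spec@keyCols)))
    total <- total + k
  }
  expect_gte(hits / total, 0.8)
})

test_that("subsampling the family reproduces the reference keys", {
  # moderate base coupling so the boosted column stands out cleanly at N = 3
  spec <- tinySpec(couplingStrength = 0.3)
  fam <- sampleFamily(spec, seed = 12)
  mp <- identityMap(spec@L)
  ortho <- pocket("orthosteric", as.character(spec@orthoCols),
                  role = "orthosteric")
  full <- alnDepth(fam$aln) / alnLength(fam$aln)
  tab <- subsampleRobustness(fam$aln, as.character(spec@alloCols), ortho,
                             mp, ratios = full, repeats = 2, seed = 5)
  # the full-depth "subsample" is the alignment itself: overlap 1
  expect_equal(tab$overlap, c(1, 1))
  # determinism under a fixed seed
  tab2 <- subsampleRobustness(fam$aln, as.character(spec@alloCols), ortho,
                              mp, ratios = full, repeats = 2, seed = 5)
  expect_identical(tab, tab2)
})
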