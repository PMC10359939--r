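test_that("similarity coefficients match set-count arithmetic", {
  a <- Fingerprint(c(1L, 2L), "ECFP4")
  b <- Fingerprint(c(2L, 3L), "ECFP4")
  expect_identical(diceSimilarity(a, a), 1)
  expect_identical(diceSimilarity(a, b), 0.5)
  expect_equal(tanimotoSimilarity(Fingerprint(c(1L, 2L), "MACCS"),
                                  Fingerprint(c(2L, 3L), "MACCS")), 1 / 3)
  disjoint <- Fingerprint(c(9L, 10L), "ECFP4")
  expect_identical(diceSimilarity(a, disjoint), 0)
  expect_identical(tanimotoSimilarity(Fingerprint(1L, "MACCS"),
                                      Fingerprint(2L, "MACCS")), 0)
  # both-empty convention
  e <- Fingerprint(integer(0), "ECFP4")
  expect_identical(diceSimilarity(e, e), 1)
  # kind mismatch is an error
  expect_error(diceSimilarity(a, Fingerprint(1L, "MACCS")), "mismatch")
})

test_that("Dice dominates Tanimoto and both are symmetric on random bit sets", {
  set.seed(71)
  for (rep in 1:50) {
    x <- sort(sample(0:63, sample(1:20, 1)))
    y <- sort(sample(0:63, sample(1:20, 1)))
    fx <- Fingerprint(x, "ECFP4", 64L)
    fy <- Fingerprint(y, "ECFP4", 64L)
    d <- diceSimilarity(fx, fy)
    j <- tanimotoSimilarity(fx, fy)
    expect_gte(d, j)                      # Dice = 2J/(1+J) >= J
    expect_equal(d, 2 * j / (1 + j))
    expect_identical(d, diceSimilarity(fy, fx))
    expect_identical(j, tanimotoSimilarity(fy, fx))
    expect_identical(d == 1, setequal(x, y))
  }
})

test_that("near-duplicate removal keeps the last cluster member in input order", {
  # identical pair: first-listed compound removed
  fps <- FingerprintSet(list(ECFP4 = list(X = c(1L, 2L, 3L),
                                          Y = c(1L, 2L, 3L),
                                          Z = c(50L, 60L))))
  rep1 <- dedupeNearDuplicates(fps, cutoff = 0.99, order = c("X", "Y", "Z"))
  expect_setequal(keptIds(rep1), c("Y", "Z"))
  expect_equal(removedPairs(rep1)$removed_id, "X")
  expect_equal(removedPairs(rep1)$kept_id, "Y")
  expect_equal(removedPairs(rep1)$similarity, 1)

  # all pairwise below cutoff: nothing removed
  apart <- FingerprintSet(list(ECFP4 = list(U = 1:5, V = 10:14, W = 20:24)))
  rep2 <- dedupeNearDuplicates(apart, cutoff = 0.99)
  expect_equal(keptIds(rep2), c("U", "V", "W"))
  expect_equal(nrow(removedPairs(rep2)), 0L)

  # chain A~B (0.99), B~C (0.99) with A, C below cutoff (0.98): one
  # transitive cluster, C kept
  chain <- FingerprintSet(list(ECFP4 = list(
    A = 1:100, B = c(2:100, 200L), C = c(3:100, 200L, 201L))))
  repc <- dedupeNearDuplicates(chain, cutoff = 0.985,
                               order = c("A", "B", "C"))
  expect_equal(keptIds(repc), "C")
  expect_setequal(removedPairs(repc)$removed_id, c("A", "B"))
  expect_true(all(removedPairs(repc)$kept_id == "C"))
})

test_that("dedupe clustering agrees with a graph-components oracle", {
  skip_if_not_installed("igraph")
  set.seed(33)
  for (rep in 1:10) {
    fps <- randomFps(15, nbits = 24L, maxBits = 12L)
    cutoff <- 0.8
    ids <- compoundIds(fps)
    m <- similarityMatrix(fps, "ECFP4")
    flagged <- which(m >= cutoff - 1e-9 & upper.tri(m), arr.ind = TRUE)
    g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
    g <- igraph::add_edges(g, t(flagged))
    comp <- igraph::components(g)$membership
    expectKept <- vapply(split(seq_along(ids), comp),
                         function(idx) ids[max(idx)], character(1))
    rep_ <- dedupeNearDuplicates(fps, cutoff = cutoff)
    expect_setequal(keptIds(rep_), unname(expectKept))
    expect_equal(length(keptIds(rep_)) + nrow(removedPairs(rep_)),
                 length(ids))
  }
})

test_that("dedupe is idempotent on its own kept set", {
  set.seed(12)
  fps <- randomFps(20, nbits = 16L, maxBits = 10L)
  rep1 <- dedupeNearDuplicates(fps, cutoff = 0.7)
  keep <- keptIds(rep1)
  sub <- FingerprintSet(list(ECFP4 = fps@bits$ECFP4[keep]),
                        nbits = fps@nbits)
  rep2 <- dedupeNearDuplicates(sub, cutoff = 0.7)
  expect_equal(nrow(removedPairs(rep2)), 0L)
  expect_setequal(keptIds(rep2), keep)
})

test_that("a pair is flagged when any single fingerprint kind reaches the cutoff", {
  fps <- FingerprintSet(list(
    ECFP4 = list(A = 1:10, B = 40:60),        # dissimilar here
    MACCS = list(A = 1:20, B = 1:20)))        # identical here
  rep_ <- dedupeNearDuplicates(fps, cutoff = 0.99, order = c("A", "B"))
  expect_equal(keptIds(rep_), "B")
  expect_equal(removedPairs(rep_)$kind, "MACCS")
})

test_that("fingerprint enumeration flags bad SMILES and matches the backend", {
  skip_if_not_installed("ChemmineR")
  skip_if_not_installed("ChemmineOB")
  cpds <- data.frame(
    compound_id = c("benzene", "cyclohexane", "broken", "benzene2"),
    smiles = c("c1ccccc1", "C1CCCCC1", "C1CC", "c1ccccc1"),
    stringsAsFactors = FALSE)
  fps <- fingerprintCompounds(cpds)
  expect_equal(fps@failed, "broken")
  expect_setequal(fpKinds(fps), c("ECFP4", "ECFP6", "MACCS"))
  expect_equal(unname(fps@nbits[c("ECFP4", "MACCS")]), c(2048L, 167L))
  # determinism: identical SMILES give identical bit sets
  expect_identical(fps@bits$ECFP4$benzene, fps@bits$ECFP4$benzene2)
  # aromatic vs saturated ring differ structurally
  s <- diceSimilarity(getFingerprint(fps, "benzene", "ECFP4"),
                      getFingerprint(fps, "cyclohexane", "ECFP4"))
  expect_lt(s, 1)
  # cross-check against the backend similarity on the raw fingerprints
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(
    c(benzene = "c1ccccc1", cyclohexane = "C1CCCCC1")))
  raw <- suppressWarnings(ChemmineR::fingerprintOB(sdf, "ECFP4"))@fpma
  inter <- sum(raw[1, ] & raw[2, ])
  backendDice <- 2 * inter / (sum(raw[1, ]) + sum(raw[2, ]))
  expect_equal(s, backendDice)
  expect_error(fingerprintCompounds(data.frame(compound_id = "x",
                                               smiles = "notasmiles")),
               "unparsable")
})
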