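test_that("target-space expansion follows first-neighbor/influencer definitions", {
  edges <- data.frame(source = c("A", "B"), dest = c("B", "C"))
  ex <- expandTargetSpace("A", edges)
  expect_equal(ex$firstNeighbors, "B")
  expect_equal(ex$influencers, "C")

  # triangle: both neighbors are first neighbors, nothing is left over
  tri <- data.frame(source = c("A", "A", "B"), dest = c("B", "C", "C"))
  ex2 <- expandTargetSpace("A", tri)
  expect_setequal(ex2$firstNeighbors, c("B", "C"))
  expect_equal(ex2$influencers, character(0))

  # isolated seed
  ex3 <- expandTargetSpace("Z", edges)
  expect_equal(ex3$firstNeighbors, character(0))
  expect_equal(ex3$influencers, character(0))

  # invariant to edge order and direction
  flipped <- data.frame(source = c("C", "B"), dest = c("B", "A"))
  expect_equal(expandTargetSpace("A", flipped), ex)
})

test_that("target-space expansion agrees with a 2-hop BFS oracle on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(55)
  for (rep in 1:10) {
    n <- 30
    edges <- data.frame(source = sprintf("N%02d", sample.int(n, 60, TRUE)),
                        dest = sprintf("N%02d", sample.int(n, 60, TRUE)))
    edges <- edges[edges$source != edges$dest, ]
    seeds <- sprintf("N%02d", sample.int(n, 3))
    got <- expandTargetSpace(seeds, edges)

    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
    present <- intersect(seeds, igraph::V(g)$name)
    dist <- if (length(present) > 0)
      apply(igraph::distances(g, v = present), 2, min) else numeric(0)
    expect_setequal(got$firstNeighbors, names(dist)[dist == 1])
    expect_setequal(got$influencers, names(dist)[dist == 2])
  }
})

test_that("the representative per target is the most potent compound, any assay type", {
  bt <- BioactivityTable(data.frame(
    compound_id = c("X", "Y", "P", "Q"),
    target_id = c("T1", "T1", "T2", "T2"),
    assay_type = c("IC50", "Ki", "Ki", "IC50"),
    value_nM = c(5, 50, 10, 5)))
  sel <- libraryEntries(pickRepresentativePerTarget(bt))
  expect_equal(sel$compound_id[sel$target_id == "T1"], "X")
  # assay types are treated equally: the 5 nM IC50 beats the 10 nM Ki
  expect_equal(sel$compound_id[sel$target_id == "T2"], "Q")
  expect_false(any(sel$substituted))

  # value tie: lexicographically smaller compound id wins
  tie <- BioactivityTable(data.frame(
    compound_id = c("B", "A"), target_id = "T1",
    assay_type = c("IC50", "IC50"), value_nM = c(5, 5)))
  expect_equal(libraryEntries(pickRepresentativePerTarget(tie))$compound_id,
               "A")
})

test_that("availability substitution walks to the next most potent available compound", {
  bt <- BioactivityTable(data.frame(
    compound_id = c("A", "B", "C", "D"),
    target_id = c("T1", "T1", "T1", "T2"),
    assay_type = "IC50", value_nM = c(5, 12, 40, 7)))
  sel <- pickRepresentativePerTarget(bt)

  # representative A unavailable, runner-up B at 12 nM available
  sub <- substituteUnavailable(sel, bt, c(A = FALSE, B = TRUE, C = TRUE,
                                          D = TRUE))
  e <- libraryEntries(sub)
  expect_equal(e$compound_id[e$target_id == "T1"], "B")
  expect_equal(e$value_nM[e$target_id == "T1"], 12)
  expect_true(e$substituted[e$target_id == "T1"])
  expect_false(e$substituted[e$target_id == "T2"])

  # nothing available for T1: target becomes uncovered
  none <- substituteUnavailable(sel, bt, c(A = FALSE, B = FALSE, C = FALSE,
                                           D = TRUE))
  expect_equal(uncoveredTargets(none), "T1")
  expect_equal(libraryEntries(none)$target_id, "T2")

  # all available: identity
  all_ <- substituteUnavailable(sel, bt, c(A = TRUE, B = TRUE, C = TRUE,
                                           D = TRUE))
  expect_equal(libraryEntries(all_), libraryEntries(sel))

  # unknown availability counts as unavailable
  unk <- substituteUnavailable(sel, bt, c(B = TRUE, D = TRUE))
  expect_true(libraryEntries(unk)$substituted[1])
})

test_that("post-substitution selections are potency-optimal among available compounds", {
  set.seed(90)
  for (rep in 1:10) {
    bt <- aggregateReplicates(randomBioTable(nCompounds = 25, nTargets = 6))
    cpds <- unique(bioRecords(bt)$compound_id)
    avail <- setNames(runif(length(cpds)) < 0.6, cpds)
    sel <- substituteUnavailable(pickRepresentativePerTarget(bt), bt, avail)
    df <- bioRecords(bt)
    for (i in seq_len(nrow(libraryEntries(sel)))) {
      e <- libraryEntries(sel)[i, ]
      availVals <- df$value_nM[df$target_id == e$target_id &
                               avail[df$compound_id]]
      expect_true(avail[[e$compound_id]])
      expect_lte(e$value_nM, min(availVals))
    }
    # substitution never covers fewer targets than dropping outright
    dropped <- libraryEntries(pickRepresentativePerTarget(bt))
    keptIfDropped <- sum(avail[dropped$compound_id], na.rm = TRUE)
    expect_gte(nrow(libraryEntries(sel)), keptIfDropped)
  }
})

test_that("coverage accounting equals brute-force group-by tallies", {
  bt <- BioactivityTable(data.frame(
    compound_id = c("A", "A", "B", "B"),
    target_id = c("T1", "T2", "T2", "T3"),
    assay_type = "IC50", value_nM = c(10, 20, 5000, 30)))
  sel <- new("LibrarySelection",
             entries = data.frame(target_id = "T1", compound_id = "A",
                                  assay_type = "IC50", value_nM = 10,
                                  substituted = FALSE),
             uncoveredTargets = character(0))
  cov <- coverageSummary(sel, bt, c("T1", "T2", "T3", "T4"), 1000)
  # A is potent on T1 and T2 only -> 2 of 4 universe targets
  expect_equal(cov@nTargetsCovered, 2L)
  expect_equal(cov@coverageFraction, 0.5)
  expect_equal(unname(cov@targetsPerCompound["A"]), 2L)
  expect_equal(unname(cov@compoundsPerTarget[c("T1", "T2", "T3", "T4")]),
               c(1L, 1L, 0L, 0L))

  # empty selection
  empty <- pickRepresentativePerTarget(BioactivityTable(tinyBioDf()[0, ]))
  cov0 <- coverageSummary(empty, bt, c("T1", "T2"))
  expect_equal(cov0@coverageFraction, 0)
  expect_equal(cov0@nCompounds, 0L)

  # random tables vs group-by oracle
  set.seed(18)
  for (rep in 1:5) {
    bt2 <- aggregateReplicates(randomBioTable())
    sel2 <- pickRepresentativePerTarget(bt2)
    uni <- unique(bioRecords(bt2)$target_id)
    cov2 <- coverageSummary(sel2, bt2, uni, 1000)
    df <- bioRecords(bt2)
    df <- df[df$compound_id %in% libraryEntries(sel2)$compound_id &
             df$value_nM <= 1000, ]
    pairs <- unique(df[c("compound_id", "target_id")])
    expect_equal(cov2@nTargetsCovered,
                 length(intersect(unique(pairs$target_id), uni)))
    for (cp in names(cov2@targetsPerCompound)) {
      expect_equal(unname(cov2@targetsPerCompound[cp]),
                   sum(pairs$compound_id == cp))
    }
  }
})

test_that("the design driver chains stages with monotone shrinkage and a retention log", {
  lib <- synthBioactivity(SynthLibraryConfig(seed = 3L))
  res <- designLibrary(lib$table, FilterConfig(), fps = lib$fps,
                       availability = lib$availability,
                       targetUniverse = lib$targets$target_id)
  expect_true(all(diff(res$log$records) <= 0))
  expect_s4_class(res$selection, "LibrarySelection")
  expect_s4_class(res$coverage, "CoverageStats")
  expect_lte(abs(res$threshold - 0.7), 0.05)
  expect_true("similarity_dedupe" %in% res$log$stage)
  expect_lte(res$coverage@coverageFraction, 1)
  # every library entry exists in the filtered table
  df <- bioRecords(res$table)
  e <- libraryEntries(res$selection)
  expect_true(all(paste(e$compound_id, e$target_id) %in%
                  paste(df$compound_id, df$target_id)))
})
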