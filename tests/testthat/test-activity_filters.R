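test_that("replicate aggregation records the median per compound/target/assay", {
  bt <- BioactivityTable(data.frame(
    compound_id = "C1", target_id = "T1", assay_type = "IC50",
    value_nM = c(100, 200, 400)))
  expect_equal(bioRecords(aggregateReplicates(bt))$value_nM, 200)

  # even replicate count: midpoint median (sort-and-midpoint oracle)
  bt2 <- BioactivityTable(data.frame(
    compound_id = "C1", target_id = "T1", assay_type = "IC50",
    value_nM = c(300, 100)))
  expect_equal(bioRecords(aggregateReplicates(bt2))$value_nM, 200)

  # single record untouched; distinct assay types are distinct groups
  bt3 <- BioactivityTable(data.frame(
    compound_id = c("C1", "C1"), target_id = "T1",
    assay_type = c("IC50", "Ki"), value_nM = c(10, 30)))
  agg <- bioRecords(aggregateReplicates(bt3))
  expect_equal(nrow(agg), 2L)
  expect_equal(sort(agg$value_nM), c(10, 30))
})

test_that("potency cutoff is inclusive at the boundary", {
  bt <- BioactivityTable(data.frame(
    compound_id = c("A", "B", "C"), target_id = "T1", assay_type = "IC50",
    value_nM = c(1000, 1001, 10)))
  out <- bioRecords(applyPotencyCutoff(bt, 1000))
  expect_setequal(out$compound_id, c("A", "C"))  # 1000 kept, 1001 dropped
  empty <- BioactivityTable(tinyBioDf()[0, ])
  expect_equal(nrow(bioRecords(applyPotencyCutoff(empty, 1000))), 0L)
})

test_that("target-specific filter retains the requested percentile per target", {
  # 10 distinct potencies at percentile 80 -> 8 retained
  set.seed(4)
  bt <- BioactivityTable(data.frame(
    compound_id = sprintf("C%02d", 1:10), target_id = "T1",
    assay_type = "IC50", value_nM = sort(10^runif(10, 0, 3))))
  out <- bioRecords(targetSpecificFilter(bt, 80))
  expect_equal(nrow(out), 8L)
  expect_setequal(out$compound_id, sprintf("C%02d", 1:8))

  # degenerate targets are retained unchanged
  single <- BioactivityTable(data.frame(
    compound_id = "C1", target_id = "T1", assay_type = "Kd", value_nM = 5))
  expect_equal(nrow(bioRecords(targetSpecificFilter(single, 80))), 1L)
  flat <- BioactivityTable(data.frame(
    compound_id = c("A", "B", "C"), target_id = "T1", assay_type = "Ki",
    value_nM = 100))
  expect_equal(nrow(bioRecords(targetSpecificFilter(flat, 80))), 3L)
})

test_that("activity filters match brute-force percentile oracles on random tables", {
  set.seed(202)
  for (rep in 1:25) {
    bt <- aggregateReplicates(randomBioTable())
    df <- bioRecords(bt)

    gotT <- bioRecords(targetSpecificFilter(bt, 80))
    expect_equal(gotT, df[oracleTargetFilter(df, 80), , drop = FALSE],
                 ignore_attr = TRUE)

    gotG <- bioRecords(globalActivityFilter(bt, 95))
    expect_equal(gotG, df[oracleGlobalFilter(df, 95), , drop = FALSE],
                 ignore_attr = TRUE)
  }
})

test_that("the global filter threshold comes from the most variable target", {
  set.seed(9)
  wide <- data.frame(compound_id = sprintf("W%02d", 1:20), target_id = "T1",
                     assay_type = "IC50", value_nM = 10^rnorm(20, 2, 1.2))
  narrow <- data.frame(compound_id = sprintf("N%02d", 1:20), target_id = "T2",
                       assay_type = "IC50", value_nM = 10^rnorm(20, 3, 0.3))
  bt <- BioactivityTable(rbind(wide, narrow))
  df <- bioRecords(bt)
  keep <- oracleGlobalFilter(df, 95)
  expect_equal(bioRecords(globalActivityFilter(bt, 95)),
               df[keep, , drop = FALSE], ignore_attr = TRUE)
  # records removed from BOTH targets when they exceed tau
  removedTargets <- unique(df$target_id[!keep])
  expect_true("T1" %in% removedTargets)

  # percentile 100 keeps everything
  expect_equal(nrow(bioRecords(globalActivityFilter(bt, 100))), nrow(df))

  # all-singleton targets: warned no-op
  singles <- BioactivityTable(data.frame(
    compound_id = c("A", "B"), target_id = c("T1", "T2"),
    assay_type = "IC50", value_nM = c(10, 20)))
  expect_warning(out <- globalActivityFilter(singles, 95), "no-op")
  expect_equal(nrow(bioRecords(out)), 2L)
})

test_that("filters shrink monotonically and are stable on re-application", {
  set.seed(77)
  for (rep in 1:10) {
    bt <- randomBioTable()
    agg <- aggregateReplicates(bt)
    cut <- applyPotencyCutoff(agg, 1000)
    tsf <- targetSpecificFilter(cut, 80)
    gbf <- globalActivityFilter(tsf, 95)
    ns <- vapply(list(bt, agg, cut, tsf, gbf), length, integer(1))
    expect_true(all(diff(ns) <= 0))
    # each output is a subset of its input
    key <- function(x) do.call(paste, bioRecords(x))
    expect_true(all(key(cut) %in% key(agg)))
    expect_true(all(key(tsf) %in% key(cut)))
    expect_true(all(key(gbf) %in% key(tsf)))

    # cutoff filter is exactly idempotent; percentile filters recompute
    # their thresholds on the filtered data, so a second pass trims the
    # new tail again -- only the subset property is asserted for them
    expect_equal(bioRecords(applyPotencyCutoff(cut, 1000)), bioRecords(cut))
    expect_true(all(key(targetSpecificFilter(tsf, 80)) %in% key(tsf)))
    expect_true(all(key(globalActivityFilter(gbf, 95)) %in% key(gbf)))
  }
})

test_that("per-target retention fraction stays within 1/n of the percentile", {
  set.seed(31)
  bt <- aggregateReplicates(randomBioTable(nCompounds = 60, nRows = 600))
  out <- bioRecords(targetSpecificFilter(bt, 80))
  df <- bioRecords(bt)
  for (t in unique(df$target_id)) {
    n <- sum(df$target_id == t)
    if (length(unique(df$value_nM[df$target_id == t])) < n) next
    frac <- sum(out$target_id == t) / n
    expect_gte(frac, 0.8 - 1 / n - 1e-9)
    expect_lte(frac, 0.8 + 1 / n + 1e-9)
  }
})
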