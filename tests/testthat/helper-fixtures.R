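# Shared fixtures and independent oracles used across the suite.

# A tiny well-formed bioactivity data.frame.
tinyBioDf <- function() {
  data.frame(
    compound_id = c("C1", "C1", "C2", "C3"),
    target_id = c("EGFR", "EGFR", "EGFR", "BRAF"),
    assay_type = c("IC50", "IC50", "Ki", "EC50"),
    value_nM = c(100, 300, 50, 800),
    stringsAsFactors = FALSE)
}

# Random long-format bioactivity table: n compounds x targets with
# replicate structure, log-normal potencies.
randomBioTable <- function(nCompounds = 40, nTargets = 8, nRows = 400) {
  df <- data.frame(
    compound_id = sprintf("C%03d", sample.int(nCompounds, nRows, TRUE)),
    target_id = sprintf("T%02d", sample.int(nTargets, nRows, TRUE)),
    assay_type = sample(c("IC50", "EC50", "Ki", "Kd"), nRows, TRUE),
    value_nM = 10^rnorm(nRows, 2, 1),
    stringsAsFactors = FALSE)
  BioactivityTable(df)
}

# One-plate screen fixture with explicit counts.
onePlate <- function(treated, dmso, patient = "P1", plate = "PL1",
                     conc = 300) {
  n <- length(treated) + length(dmso)
  ScreenPlateSet(data.frame(
    plate_id = plate, patient_id = patient,
    well = sprintf("W%02d", seq_len(n)),
    role = c(rep("treated", length(treated)), rep("dmso", length(dmso))),
    compound_id = c(sprintf("C%02d", seq_along(treated)),
                    rep(NA_character_, length(dmso))),
    concentration_nM = c(rep(conc, length(treated)),
                         rep(NA_real_, length(dmso))),
    nuclei_count = c(treated, dmso), stringsAsFactors = FALSE))
}

# Linear-interpolation percentile written out longhand, independent of
# stats::quantile: the brute-force sort-and-interpolate oracle.
oraclePercentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  if (n == 1L) return(x)
  h <- (n - 1) * p / 100 + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Brute-force target-specific filter on raw log10 values (z-scoring is
# monotone, so the retained sets must coincide).
oracleTargetFilter <- function(df, percentile) {
  keep <- logical(nrow(df))
  for (t in unique(df$target_id)) {
    idx <- which(df$target_id == t)
    v <- log10(df$value_nM[idx])
    if (length(unique(v)) == 1L) {
      keep[idx] <- TRUE
    } else {
      thr <- oraclePercentile(v, percentile)
      keep[idx] <- v <= thr + 1e-9
    }
  }
  keep
}

# Brute-force global filter oracle: recompute per-target centered values
# and sds from scratch, then the reference target's percentile.
oracleGlobalFilter <- function(df, percentile) {
  centered <- numeric(nrow(df))
  sds <- c()
  for (t in unique(df$target_id)) {
    idx <- which(df$target_id == t)
    v <- log10(df$value_nM[idx])
    centered[idx] <- v - mean(v)
    if (length(v) >= 2L) sds[t] <- sd(v)
  }
  ref <- names(sds)[which.max(sds)]
  tau <- oraclePercentile(centered[df$target_id == ref], percentile)
  centered <= tau + 1e-9
}

# Random fingerprint set of a single kind (bit sets over a small space so
# overlaps are common).
randomFps <- function(n = 12, nbits = 64L, maxBits = 20L, kind = "ECFP4") {
  bits <- lapply(seq_len(n), function(i)
    sort(sample.int(nbits, sample.int(maxBits, 1L)) - 1L))
  names(bits) <- sprintf("C%02d", seq_len(n))
  FingerprintSet(setNames(list(bits), kind), nbits = setNames(nbits, kind))
}
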