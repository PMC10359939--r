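# Bioactivity filters. Every filter returns a subset of its input table
# (monotone shrinkage); all distribution work is on log10-transformed
# values with assay types pooled per target.

#' Aggregate replicate bioactivity measurements
#'
#' Collapses multiple entries for the same (compound, target, assay type)
#' to a single record holding their median value.
#'
#' @param table a \linkS4class{BioactivityTable}.
#' @return A \linkS4class{BioactivityTable} with one record per
#'   (compound, target, assay_type).
#' @examples
#' bt <- BioactivityTable(data.frame(
#'   compound_id = "C1", target_id = "T1", assay_type = "IC50",
#'   value_nM = c(100, 200, 400)))
#' bioRecords(aggregateReplicates(bt))$value_nM  # 200
#' @export
aggregateReplicates <- function(table) {
  stopifnot(is(table, "BioactivityTable"))
  df <- bioRecords(table)
  if (nrow(df) == 0L) return(table)
  key <- paste(df$compound_id, df$target_id, df$assay_type, sep = "\r")
  med <- tapply(df$value_nM, key, stats::median)
  first <- !duplicated(key)
  out <- df[first, , drop = FALSE]
  out$value_nM <- as.numeric(med[key[first]])
  rownames(out) <- NULL
  BioactivityTable(out)
}

#' Apply an absolute potency cutoff
#'
#' Retains records with \code{value_nM} at or below the cutoff (the
#' liberal multi-dose activity threshold is inclusive).
#'
#' @param table a \linkS4class{BioactivityTable}.
#' @param cutoff_nM positive cutoff in nM (default 1000).
#' @return Filtered \linkS4class{BioactivityTable}.
#' @export
applyPotencyCutoff <- function(table, cutoff_nM = 1000) {
  stopifnot(is(table, "BioactivityTable"), cutoff_nM > 0)
  df <- bioRecords(table)
  out <- df[df$value_nM <= cutoff_nM, , drop = FALSE]
  rownames(out) <- NULL
  BioactivityTable(out)
}

#' Target-specific percentile activity filter
#'
#' Per target, the pooled log10 bioactivity distribution (IC50, EC50, Ki
#' and Kd readouts together) is z-score normalized to zero mean and unit
#' variance; a threshold is placed at the requested percentile of the
#' normalized values (linear-interpolation percentile) and records
#' strictly above it -- the least potent tail -- are removed. "Within the
#' threshold" is inclusive. A target whose values have zero spread (single
#' record or all identical) is retained unchanged, since normalization is
#' degenerate there.
#'
#' Because z-scoring is monotone, the retained set per target equals the
#' set at or below the same percentile of the raw log10 values.
#'
#' @param table a \linkS4class{BioactivityTable}.
#' @param percentile retention percentile in (0, 100] (default 80).
#' @return Filtered \linkS4class{BioactivityTable}.
#' @export
targetSpecificFilter <- function(table, percentile = 80) {
  stopifnot(is(table, "BioactivityTable"))
  if (percentile <= 0 || percentile > 100)
    stop("percentile must lie in (0, 100]")
  df <- bioRecords(table)
  if (nrow(df) == 0L) return(table)
  keep <- logical(nrow(df))
  for (idx in split(seq_len(nrow(df)), df$target_id)) {
    v <- log10(df$value_nM[idx])
    s <- stats::sd(v)
    if (length(v) == 1L || !is.finite(s) || s == 0) {
      keep[idx] <- TRUE
      next
    }
    z <- (v - mean(v)) / s
    thr <- .percentile(z, percentile)
    keep[idx] <- z <= thr + .EPS
  }
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  BioactivityTable(out)
}

#' Global (target-agnostic) percentile activity filter
#'
#' All log10 bioactivities are centered to zero mean per target; the
#' target with the highest standard deviation of its centered values is
#' identified and the requested percentile of that target's centered
#' values becomes a single global threshold, applied across all targets:
#' records whose centered value exceeds it are removed. Centering puts
#' every target's profile on a common location scale so the most variable
#' target's spread bounds everyone's retained spread.
#'
#' Targets with a single record have a centered value of 0 and are kept
#' whenever the threshold is non-negative. When no target has two or more
#' records the filter is a no-op with a warning.
#'
#' @param table a \linkS4class{BioactivityTable}.
#' @param percentile retention percentile in (0, 100] (default 95).
#' @return Filtered \linkS4class{BioactivityTable}.
#' @export
globalActivityFilter <- function(table, percentile = 95) {
  stopifnot(is(table, "BioactivityTable"))
  if (percentile <= 0 || percentile > 100)
    stop("percentile must lie in (0, 100]")
  df <- bioRecords(table)
  if (nrow(df) == 0L) return(table)
  groups <- split(seq_len(nrow(df)), df$target_id)
  centered <- numeric(nrow(df))
  sds <- vapply(groups, function(idx) {
    v <- log10(df$value_nM[idx])
    centered[idx] <<- v - mean(v)
    if (length(v) >= 2L) stats::sd(v) else NA_real_
  }, numeric(1L))
  if (all(is.na(sds))) {
    warning("no target has >= 2 records; global activity filter is a no-op")
    return(table)
  }
  refTarget <- names(sds)[which.max(sds)]
  tau <- .percentile(centered[groups[[refTarget]]], percentile)
  out <- df[centered <= tau + .EPS, , drop = FALSE]
  rownames(out) <- NULL
  BioactivityTable(out)
}
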