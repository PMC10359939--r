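# Data-driven selection of the compound-similarity cutoff. The scan rests
# on the assumption that structurally similar compounds share activity
# distributions: at a good cutoff, the pairs called "similar" have small
# two-sample K-S distances between their activity value sets.

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' \eqn{D = \sup_x |F_x(t) - F_y(t)|} over the two empirical CDFs.
#' Symmetric in its arguments; ties are handled exactly.
#'
#' @param x,y non-empty numeric samples.
#' @return D in [0, 1].
#' @examples
#' ksStatistic(c(1, 2, 3), c(1, 2, 4))  # 1/3
#' @export
ksStatistic <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty")
  pts <- sort(unique(c(x, y)))
  fx <- findInterval(pts, sort(x)) / length(x)
  fy <- findInterval(pts, sort(y)) / length(y)
  max(abs(fx - fy))
}

# Default threshold score: treats the mean squared K-S distance among
# above-threshold pairs as residual error of a one-parameter model,
# AIC(t) = m * ln(SS/m + eps) + 2k with k = 1 threshold parameter.
.aicScore <- function(m, ss, k = 1L, eps = 1e-12) {
  m * log(ss / m + eps) + 2 * k
}

#' Select the compound-similarity threshold by a K-S/AIC grid scan
#'
#' For each seed, a uniform without-replacement subsample of the
#' configured fraction of compounds is drawn; all pairwise similarities
#' within the subsample are computed (Dice for ECFP kinds, Tanimoto for
#' MACCS, per \code{similarityKind} in the config). For every grid
#' threshold t the pairs at similarity >= t whose two compounds each have
#' at least 3 log10 activity values are scored by the two-sample K-S
#' statistic D between the compounds' activity value sets; with m_t such
#' pairs and SS_t the sum of squared D, the threshold score is
#' AIC(t) = m_t ln(SS_t/m_t + 1e-12) + 2. Grid points with fewer than
#' \code{minPairs} evaluated pairs are inadmissible. Each seed selects the
#' admissible threshold with the smallest AIC (ties broken towards the
#' largest threshold); the final selection is the median over seeds.
#'
#' @param fps a \linkS4class{FingerprintSet}.
#' @param activities a \linkS4class{BioactivityTable}; each compound's
#'   activity value set pools all its log10 values across targets and
#'   assay types.
#' @param config a \linkS4class{FilterConfig}.
#' @param seeds integer seeds, one subsample each (default
#'   \code{seq_len(config@nSeeds)}).
#' @param scoreFun scoring function \code{function(m, ss)} returning the
#'   per-threshold score to minimize; the AIC above by default. Pluggable
#'   so alternative information criteria can be swapped in without
#'   touching the scan.
#' @return A \linkS4class{ThresholdScanResult}.
#' @seealso \code{\link{synthBioactivity}} for a generator planting a
#'   known redundancy cutoff this scan recovers.
#' @export
selectSimilarityThreshold <- function(fps, activities, config = FilterConfig(),
                                      seeds = seq_len(config@nSeeds),
                                      scoreFun = .aicScore) {
  stopifnot(is(fps, "FingerprintSet"), is(activities, "BioactivityTable"),
            is(config, "FilterConfig"))
  kind <- config@similarityKind
  if (!(kind %in% fpKinds(fps)))
    stop(sprintf("fingerprint set does not hold kind '%s'", kind))
  grid <- thresholdGrid(config)

  df <- bioRecords(activities)
  logvals <- lapply(split(log10(df$value_nM), df$compound_id), as.numeric)
  universe <- intersect(compoundIds(fps), names(logvals))
  nRich <- sum(vapply(logvals[universe], length, integer(1L)) >= 3L)
  if (nRich < 20L)
    stop("need >= 20 compounds with fingerprints and >= 3 activity values")

  simFun <- .kindSimFun(kind)
  bits <- fps@bits[[kind]]
  nSub <- max(2L, round(config@subsampleFraction * length(universe)))

  scan <- vector("list", length(seeds))
  selectedPerSeed <- numeric(length(seeds))
  for (s in seq_along(seeds)) {
    sub <- .withSeed(seeds[s], sample(universe, nSub))
    # pair similarities and K-S distances, computed once per pair
    pairSim <- numeric(0)
    pairD <- numeric(0)
    for (i in seq_len(nSub - 1L)) {
      vi <- logvals[[sub[i]]]
      bi <- bits[[sub[i]]]
      for (j in (i + 1L):nSub) {
        sim <- simFun(bi, bits[[sub[j]]])
        if (sim < grid[1L] - .EPS) next
        vj <- logvals[[sub[j]]]
        if (length(vi) < 3L || length(vj) < 3L) next
        pairSim <- c(pairSim, sim)
        pairD <- c(pairD, ksStatistic(vi, vj))
      }
    }
    rows <- data.frame(seed = seeds[s], threshold = grid,
                       m = NA_integer_, mean_D = NA_real_, aic = NA_real_,
                       admissible = FALSE)
    for (g in seq_along(grid)) {
      sel <- pairSim >= grid[g] - .EPS
      m <- sum(sel)
      rows$m[g] <- m
      if (m > 0L) rows$mean_D[g] <- mean(pairD[sel])
      if (m >= config@minPairs) {
        rows$aic[g] <- scoreFun(m, sum(pairD[sel]^2))
        rows$admissible[g] <- TRUE
      }
    }
    if (!any(rows$admissible))
      stop("no admissible threshold for seed ", seeds[s],
           "; consider a larger subsample fraction")
    adm <- rows[rows$admissible, , drop = FALSE]
    best <- adm$threshold[adm$aic <= min(adm$aic) + .EPS]
    selectedPerSeed[s] <- max(best)  # ties resolved towards the largest t
    scan[[s]] <- rows
  }
  med <- stats::median(selectedPerSeed)
  # an even seed count can average two grid points; snap back onto the grid
  selected <- grid[which.min(abs(grid - med))]
  new("ThresholdScanResult", grid = grid, scan = do.call(rbind, scan),
      selectedPerSeed = selectedPerSeed, selected = selected)
}
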