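# Seeded synthetic-data generators. These produce inputs carrying the
# statistical structure each analysis stage assumes -- planted redundant
# compound clusters for the similarity machinery, and two-component
# survival-fraction mixtures for the screen analysis -- so the whole
# pipeline is testable without external databases. Generators are pure
# functions of (config, seed): the caller's RNG state is untouched.

#' SynthLibraryConfig: synthetic bioactivity/fingerprint generator settings
#'
#' The generator plants \code{nClusters} redundant compound clusters.
#' Cluster members share a core fingerprint bit set plus member-specific
#' unique bits, calibrated so that every within-cluster pairwise Dice
#' similarity lies just above the planted redundancy cutoff \code{sStar}
#' (within +0.035), while compounds from different clusters share no bits
#' at all. Members of a cluster draw their activities from identical
#' per-target log-normal distributions, honoring the design assumption
#' that structurally similar compounds share activity distributions.
#'
#' @slot nTargets number of protein targets.
#' @slot nCompounds number of compounds (split evenly across clusters).
#' @slot nClusters number of planted redundant clusters.
#' @slot targetsPerCompound activity records per compound (each against a
#'   distinct target of its cluster).
#' @slot log10PotencyMean,log10PotencySd per-target potency location
#'   draws, log10 nM.
#' @slot clusterShiftSd sd of the cluster-specific shift added to a
#'   target's potency location.
#' @slot activityNoiseSd replicate-level log10 noise.
#' @slot sStar planted redundancy cutoff in (0, 0.99].
#' @slot coreBits shared fingerprint bits per cluster.
#' @slot fingerprintNbits fingerprint bit-space size.
#' @slot availabilityRate Bernoulli rate of compound availability.
#' @slot seed integer seed.
#' @export
setClass("SynthLibraryConfig",
         representation(nTargets = "integer", nCompounds = "integer",
                        nClusters = "integer", targetsPerCompound = "integer",
                        log10PotencyMean = "numeric",
                        log10PotencySd = "numeric",
                        clusterShiftSd = "numeric",
                        activityNoiseSd = "numeric", sStar = "numeric",
                        coreBits = "integer", fingerprintNbits = "integer",
                        availabilityRate = "numeric", seed = "integer"))

setValidity("SynthLibraryConfig", function(object) {
  if (object@nTargets < 1L || object@nCompounds < 4L || object@nClusters < 2L)
    return("counts must be positive (>= 4 compounds, >= 2 clusters)")
  if (object@nCompounds < 2L * object@nClusters)
    return("each planted cluster needs at least 2 members")
  if (object@sStar <= 0 || object@sStar > 0.99)
    return("sStar must lie in (0, 0.99]")
  if (object@targetsPerCompound < 3L)
    return("targetsPerCompound must be >= 3 (K-S needs 3 values per compound)")
  if (object@targetsPerCompound > object@nTargets)
    return("targetsPerCompound cannot exceed nTargets")
  if (object@availabilityRate < 0 || object@availabilityRate > 1)
    return("availabilityRate must lie in [0, 1]")
  if (object@coreBits < 20L) return("coreBits must be >= 20")
  TRUE
})

#' Construct a SynthLibraryConfig
#'
#' @param nTargets,nCompounds,nClusters,targetsPerCompound see the class
#'   documentation; defaults 40, 500, 25, 4.
#' @param log10PotencyMean,log10PotencySd target potency locations in
#'   log10 nM (defaults 2 and 1: potencies centered on 100 nM).
#' @param clusterShiftSd,activityNoiseSd log10-scale spread parameters
#'   (defaults 0.5, 0.3).
#' @param sStar planted redundancy cutoff (default 0.7).
#' @param coreBits,fingerprintNbits fingerprint construction (defaults
#'   300 and 2^20).
#' @param availabilityRate compound availability rate (default 0.8).
#' @param seed integer seed (default 1).
#' @return A \linkS4class{SynthLibraryConfig}.
#' @export
SynthLibraryConfig <- function(nTargets = 40L, nCompounds = 500L,
                               nClusters = 25L, targetsPerCompound = 4L,
                               log10PotencyMean = 2, log10PotencySd = 1,
                               clusterShiftSd = 0.5, activityNoiseSd = 0.3,
                               sStar = 0.7, coreBits = 300L,
                               fingerprintNbits = 1048576L,
                               availabilityRate = 0.8, seed = 1L) {
  new("SynthLibraryConfig", nTargets = as.integer(nTargets),
      nCompounds = as.integer(nCompounds), nClusters = as.integer(nClusters),
      targetsPerCompound = as.integer(targetsPerCompound),
      log10PotencyMean = log10PotencyMean, log10PotencySd = log10PotencySd,
      clusterShiftSd = clusterShiftSd, activityNoiseSd = activityNoiseSd,
      sStar = sStar, coreBits = as.integer(coreBits),
      fingerprintNbits = as.integer(fingerprintNbits),
      availabilityRate = availabilityRate, seed = as.integer(seed))
}

#' @export
setMethod("show", "SynthLibraryConfig", function(object) {
  cat(sprintf(
    "SynthLibraryConfig: %d compounds in %d clusters, %d targets, s* = %.2f, seed %d\n",
    object@nCompounds, object@nClusters, object@nTargets, object@sStar,
    object@seed))
})

#' Generate a synthetic bioactivity library with planted redundancy
#'
#' Emits compounds, targets, a validated bioactivity table, ECFP4-style
#' fingerprints with the planted similarity structure described in
#' \linkS4class{SynthLibraryConfig}, an availability map, and the ground
#' truth (cluster assignment and planted cutoff). Fully reproducible per
#' seed. \code{\link{selectSimilarityThreshold}} run on the output
#' recovers \code{sStar}.
#'
#' @param config a \linkS4class{SynthLibraryConfig}.
#' @return list with \code{compounds} (data.frame), \code{targets}
#'   (data.frame), \code{table} (\linkS4class{BioactivityTable}),
#'   \code{fps} (\linkS4class{FingerprintSet}), \code{availability}
#'   (named logical) and \code{truth} (list: \code{cluster} named integer,
#'   \code{sStar}).
#' @examples
#' lib <- synthBioactivity(SynthLibraryConfig(nCompounds = 60L,
#'                                            nClusters = 6L, seed = 7L))
#' lib$table
#' @export
synthBioactivity <- function(config = SynthLibraryConfig()) {
  stopifnot(is(config, "SynthLibraryConfig"))
  c0 <- config@coreBits
  sLo <- config@sStar + 0.001
  sHi <- min(config@sStar + 0.035, 0.999)
  uMax <- floor(c0 * (1 / sLo - 1))
  uMin <- max(1L, ceiling(c0 * (1 / sHi - 1)))
  if (uMin > uMax)
    stop("infeasible similarity constraints: increase coreBits or lower sStar")
  bitsNeeded <- config@nClusters *
    (c0 + ceiling(config@nCompounds / config@nClusters) * uMax)
  if (bitsNeeded > config@fingerprintNbits)
    stop("infeasible similarity constraints: fingerprintNbits too small ",
         "for the requested cluster sizes")

  .withSeed(config@seed, {
    n <- config@nCompounds
    ids <- sprintf("CPD%04d", seq_len(n))
    targetIds <- sprintf("TGT%03d", seq_len(config@nTargets))
    cluster <- sort(rep_len(seq_len(config@nClusters), n))
    names(cluster) <- ids

    # fingerprints: disjoint per-cluster cores, member-specific unique bits
    fpBits <- vector("list", n)
    names(fpBits) <- ids
    nextBit <- 0L
    for (k in seq_len(config@nClusters)) {
      members <- which(cluster == k)
      core <- nextBit + seq_len(c0) - 1L
      nextBit <- nextBit + c0
      for (i in members) {
        u <- sample(uMin:uMax, 1L)
        fpBits[[i]] <- as.integer(c(core, nextBit + seq_len(u) - 1L))
        nextBit <- nextBit + u
      }
    }
    fps <- FingerprintSet(list(ECFP4 = fpBits),
                          nbits = c(ECFP4 = config@fingerprintNbits))

    # activities: cluster members share per-target generating distributions
    targetMu <- stats::rnorm(config@nTargets, config@log10PotencyMean,
                             config@log10PotencySd)
    names(targetMu) <- targetIds
    recs <- vector("list", config@nClusters)
    for (k in seq_len(config@nClusters)) {
      members <- ids[cluster == k]
      tgts <- sample(targetIds, config@targetsPerCompound)
      mu <- targetMu[tgts] + stats::rnorm(length(tgts), 0,
                                          config@clusterShiftSd)
      vals <- 10^(rep(mu, times = length(members)) +
                  stats::rnorm(length(tgts) * length(members), 0,
                               config@activityNoiseSd))
      recs[[k]] <- data.frame(
        compound_id = rep(members, each = length(tgts)),
        target_id = rep(tgts, times = length(members)),
        assay_type = sample(ASSAY_TYPES, length(tgts) * length(members),
                            replace = TRUE),
        value_nM = vals, stringsAsFactors = FALSE)
    }
    table <- BioactivityTable(do.call(rbind, recs))

    availability <- setNames(
      stats::runif(n) < config@availabilityRate, ids)
    compounds <- data.frame(compound_id = ids, smiles = NA_character_,
                            available = as.logical(availability),
                            stringsAsFactors = FALSE)
    targets <- data.frame(target_id = targetIds, is_cancer_associated = TRUE,
                          mutant_of = NA_character_, stringsAsFactors = FALSE)
    list(compounds = compounds, targets = targets, table = table, fps = fps,
         availability = availability,
         truth = list(cluster = cluster, sStar = config@sStar))
  })
}

#' SynthScreenConfig: synthetic imaging-screen generator settings
#'
#' Emulates a 384-well survival screen: DMSO-well nuclei counts are
#' Poisson around \code{dmsoCountMean}; treated-well counts are the DMSO
#' mean scaled by a survival fraction drawn from a two-component Gaussian
#' mixture -- a background centered at 1 for inactive compounds and an
#' active component for planted hits, whose location tightens mildly and
#' monotonically with dose.
#'
#' @slot nPatients,nCompounds screen dimensions.
#' @slot concentrationsNM ascending tested concentrations.
#' @slot backgroundMean,backgroundSd inactive survival-fraction component.
#' @slot activeFraction,activeMean,activeSd planted-hit component.
#' @slot nDmsoWells,nPositiveWells control wells per plate.
#' @slot dmsoCountMean Poisson mean of control nuclei counts.
#' @slot plateCapacity treated wells per plate.
#' @slot seed integer seed.
#' @export
setClass("SynthScreenConfig",
         representation(nPatients = "integer", nCompounds = "integer",
                        concentrationsNM = "numeric",
                        backgroundMean = "numeric", backgroundSd = "numeric",
                        activeFraction = "numeric", activeMean = "numeric",
                        activeSd = "numeric", nDmsoWells = "integer",
                        nPositiveWells = "integer", dmsoCountMean = "numeric",
                        plateCapacity = "integer", seed = "integer"))

setValidity("SynthScreenConfig", function(object) {
  if (object@nPatients < 1L || object@nCompounds < 20L)
    return("need >= 1 patient and >= 20 compounds (mixture fitting floor)")
  cc <- object@concentrationsNM
  if (length(cc) < 2L || any(cc <= 0) || is.unsorted(cc, strictly = TRUE))
    return("concentrationsNM must be >= 2 ascending positive values")
  if (object@activeFraction < 0 || object@activeFraction >= 1)
    return("activeFraction must lie in [0, 1)")
  if (object@dmsoCountMean <= 0) return("dmsoCountMean must be positive")
  if (object@nDmsoWells < 2L)
    return("need >= 2 DMSO wells per plate for z scores")
  TRUE
})

#' Construct a SynthScreenConfig
#'
#' Defaults mirror the pilot screen layout: 6 patients, four 10-fold
#' concentrations 3--3000 nM, a survival-fraction background of
#' N(1, 0.05), and planted hits (10\% of compounds) responding at
#' N(0.3, 0.1) across all doses.
#'
#' @param nPatients,nCompounds screen dimensions (defaults 6, 300).
#' @param concentrationsNM tested concentrations (default 3/30/300/3000).
#' @param backgroundMean,backgroundSd background component (1, 0.05).
#' @param activeFraction,activeMean,activeSd planted-hit component
#'   (0.1, 0.3, 0.1).
#' @param nDmsoWells,nPositiveWells control wells per plate (16, 8).
#' @param dmsoCountMean Poisson mean nuclei count (2000).
#' @param plateCapacity treated wells per plate (352).
#' @param seed integer seed (default 1).
#' @return A \linkS4class{SynthScreenConfig}.
#' @export
SynthScreenConfig <- function(nPatients = 6L, nCompounds = 300L,
                              concentrationsNM = c(3, 30, 300, 3000),
                              backgroundMean = 1, backgroundSd = 0.05,
                              activeFraction = 0.1, activeMean = 0.3,
                              activeSd = 0.1, nDmsoWells = 16L,
                              nPositiveWells = 8L, dmsoCountMean = 2000,
                              plateCapacity = 352L, seed = 1L) {
  new("SynthScreenConfig", nPatients = as.integer(nPatients),
      nCompounds = as.integer(nCompounds),
      concentrationsNM = as.numeric(concentrationsNM),
      backgroundMean = backgroundMean, backgroundSd = backgroundSd,
      activeFraction = activeFraction, activeMean = activeMean,
      activeSd = activeSd, nDmsoWells = as.integer(nDmsoWells),
      nPositiveWells = as.integer(nPositiveWells),
      dmsoCountMean = dmsoCountMean,
      plateCapacity = as.integer(plateCapacity), seed = as.integer(seed))
}

#' @export
setMethod("show", "SynthScreenConfig", function(object) {
  cat(sprintf(
    "SynthScreenConfig: %d patients x %d compounds at %s nM (%.0f%% active), seed %d\n",
    object@nPatients, object@nCompounds,
    paste(object@concentrationsNM, collapse = "/"),
    100 * object@activeFraction, object@seed))
})

#' Generate a synthetic imaging screen with ground-truth hit labels
#'
#' Planted hits respond with the active survival-fraction component at
#' every dose (with a mild monotone dose effect); all other compounds
#' draw from the background. Returns the plate set together with the
#' truth labels, so sensitivity and specificity of downstream hit
#' calling can be computed.
#'
#' @param config a \linkS4class{SynthScreenConfig}.
#' @return list with \code{plates} (\linkS4class{ScreenPlateSet}),
#'   \code{truth} (data.frame \code{compound_id}, \code{is_active}) and
#'   \code{config}.
#' @examples
#' scr <- synthScreen(SynthScreenConfig(nPatients = 2L, nCompounds = 50L,
#'                                      seed = 3L))
#' scr$plates
#' @export
synthScreen <- function(config = SynthScreenConfig()) {
  stopifnot(is(config, "SynthScreenConfig"))
  .withSeed(config@seed, {
    ids <- sprintf("CPD%04d", seq_len(config@nCompounds))
    patients <- sprintf("P%02d", seq_len(config@nPatients))
    nActive <- round(config@activeFraction * config@nCompounds)
    active <- sort(sample(ids, nActive))
    conc <- config@concentrationsNM
    # mild monotone dose effect on the planted hits: higher dose, lower SF
    doseScale <- seq(1.15, 0.85, length.out = length(conc))
    rows <- list()
    for (p in patients) {
      for (ci in seq_along(conc)) {
        chunks <- split(ids, ceiling(seq_along(ids) / config@plateCapacity))
        for (ch in seq_along(chunks)) {
          plate <- sprintf("%s_d%d_p%d", p, ci, ch)
          cpds <- chunks[[ch]]
          isAct <- cpds %in% active
          sf <- ifelse(
            isAct,
            stats::rnorm(length(cpds), config@activeMean * doseScale[ci],
                         config@activeSd),
            stats::rnorm(length(cpds), config@backgroundMean,
                         config@backgroundSd))
          sf <- pmax(sf, 0)
          posSf <- pmax(stats::rnorm(config@nPositiveWells, 0.05, 0.02), 0)
          nTreated <- length(cpds)
          nWells <- nTreated + config@nDmsoWells + config@nPositiveWells
          rows[[plate]] <- data.frame(
            plate_id = plate, patient_id = p,
            well = sprintf("W%03d", seq_len(nWells)),
            role = c(rep("treated", nTreated),
                     rep("dmso", config@nDmsoWells),
                     rep("positive_control", config@nPositiveWells)),
            compound_id = c(cpds, rep(NA_character_,
                                      nWells - nTreated)),
            concentration_nM = c(rep(conc[ci], nTreated),
                                 rep(NA_real_, nWells - nTreated)),
            nuclei_count = c(round(config@dmsoCountMean * sf),
                             stats::rpois(config@nDmsoWells,
                                          config@dmsoCountMean),
                             round(config@dmsoCountMean * posSf)),
            stringsAsFactors = FALSE)
        }
      }
    }
    plates <- ScreenPlateSet(do.call(rbind, rows))
    list(plates = plates,
         truth = data.frame(compound_id = ids, is_active = ids %in% active,
                            stringsAsFactors = FALSE),
         config = config)
  })
}
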