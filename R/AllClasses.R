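#' BioactivityTable: long-format compound-target potency records
#'
#' Container for multi-dose bioactivity records (IC50, EC50, Ki or Kd, in
#' nM), one row per measurement. This is the substrate every activity
#' filter operates on.
#'
#' @slot records data.frame with columns \code{compound_id},
#'   \code{target_id}, \code{assay_type} (one of IC50, EC50, Ki, Kd) and
#'   \code{value_nM} (positive).
#' @export
setClass("BioactivityTable", representation(records = "data.frame"))

setValidity("BioactivityTable", function(object) {
  df <- object@records
  req <- c("compound_id", "target_id", "assay_type", "value_nM")
  if (!all(req %in% names(df)))
    return(paste("records must have columns", paste(req, collapse = ", ")))
  if (nrow(df) == 0L) return(TRUE)
  bad <- which(!(df$assay_type %in% ASSAY_TYPES))
  if (length(bad) > 0L)
    return(sprintf("invalid assay_type at row(s) %s (must be one of %s)",
                   paste(head(bad, 5L), collapse = ", "),
                   paste(ASSAY_TYPES, collapse = ", ")))
  bad <- which(!is.finite(df$value_nM) | df$value_nM <= 0)
  if (length(bad) > 0L)
    return(sprintf("value_nM must be positive and finite; offending row(s): %s",
                   paste(head(bad, 5L), collapse = ", ")))
  if (anyNA(df$compound_id) || any(!nzchar(df$compound_id)))
    return("compound_id must be non-empty")
  if (anyNA(df$target_id) || any(!nzchar(df$target_id)))
    return("target_id must be non-empty")
  TRUE
})

#' Construct a BioactivityTable
#'
#' @param records data.frame with columns \code{compound_id},
#'   \code{target_id}, \code{assay_type}, \code{value_nM}.
#' @return A \linkS4class{BioactivityTable}.
#' @examples
#' bt <- BioactivityTable(data.frame(
#'   compound_id = "C1", target_id = "EGFR",
#'   assay_type = "IC50", value_nM = 25))
#' nrow(bioRecords(bt))
#' @export
BioactivityTable <- function(records) {
  records <- as.data.frame(records)
  rownames(records) <- NULL
  for (col in c("compound_id", "target_id", "assay_type"))
    if (col %in% names(records)) records[[col]] <- as.character(records[[col]])
  new("BioactivityTable", records = records)
}

#' @describeIn BioactivityTable accessor for the records data.frame.
#' @param x a \code{BioactivityTable}.
#' @export
bioRecords <- function(x) {
  stopifnot(is(x, "BioactivityTable"))
  x@records
}

#' @export
setMethod("show", "BioactivityTable", function(object) {
  df <- object@records
  cat(sprintf("BioactivityTable: %d records, %d compounds, %d targets\n",
              nrow(df), length(unique(df$compound_id)),
              length(unique(df$target_id))))
  if (nrow(df) > 0L) {
    cat("assay types:",
        paste(sprintf("%s=%d", names(table(df$assay_type)),
                      table(df$assay_type)), collapse = " "), "\n")
  }
})

#' @export
setMethod("length", "BioactivityTable", function(x) nrow(x@records))

#' Fingerprint: a binary molecular fingerprint as a set of set-bit indices
#'
#' @slot kind one of \code{"ECFP4"}, \code{"ECFP6"}, \code{"MACCS"}.
#' @slot bits sorted integer vector of set-bit indices (0-based).
#' @slot nbits total bit-vector length (2048 for ECFP kinds, 167 for MACCS).
#' @export
setClass("Fingerprint",
         representation(kind = "character", bits = "integer",
                        nbits = "integer"))

setValidity("Fingerprint", function(object) {
  if (length(object@kind) != 1L || !(object@kind %in% FP_KINDS))
    return(paste("kind must be one of", paste(FP_KINDS, collapse = ", ")))
  if (length(object@nbits) != 1L || object@nbits <= 0L)
    return("nbits must be a positive integer")
  b <- object@bits
  if (anyNA(b) || any(b < 0L) || any(b >= object@nbits))
    return("bit indices must lie in [0, nbits)")
  if (anyDuplicated(b)) return("bit indices must be unique")
  TRUE
})

#' Construct a Fingerprint
#'
#' @param bits integer vector of 0-based set-bit indices (may be empty).
#' @param kind fingerprint kind.
#' @param nbits bit-vector length; defaults to 2048 for ECFP kinds and
#'   167 for MACCS.
#' @return A \linkS4class{Fingerprint}.
#' @examples
#' fp <- Fingerprint(c(1L, 5L, 9L), "ECFP4")
#' @export
Fingerprint <- function(bits, kind, nbits = .fpDefaultNbits(kind)) {
  kind <- match.arg(kind, FP_KINDS)
  new("Fingerprint", kind = kind, bits = sort(unique(as.integer(bits))),
      nbits = as.integer(nbits))
}

#' @export
setMethod("show", "Fingerprint", function(object) {
  cat(sprintf("Fingerprint(%s): %d/%d bits set\n", object@kind,
              length(object@bits), object@nbits))
})

#' FingerprintSet: per-compound fingerprints, kind-major
#'
#' @slot bits named list, one element per kind held; each element is a
#'   named list (compound_id -> sorted 0-based integer bit indices).
#' @slot nbits named integer, bit-vector length per kind.
#' @slot failed character vector of compound ids flagged un-fingerprintable.
#' @export
setClass("FingerprintSet",
         representation(bits = "list", nbits = "integer",
                        failed = "character"))

setValidity("FingerprintSet", function(object) {
  kinds <- names(object@bits)
  if (length(kinds) == 0L) return("at least one fingerprint kind required")
  if (!all(kinds %in% FP_KINDS))
    return(paste("kinds must be among", paste(FP_KINDS, collapse = ", ")))
  if (!identical(sort(kinds), sort(names(object@nbits))))
    return("nbits must be named by the same kinds as bits")
  ids <- names(object@bits[[1L]])
  for (k in kinds) {
    if (!identical(sort(names(object@bits[[k]])), sort(ids)))
      return("every compound must carry all held fingerprint kinds")
  }
  if (length(intersect(ids, object@failed)) > 0L)
    return("failed compounds must not also carry fingerprints")
  TRUE
})

#' Construct a FingerprintSet
#'
#' @param bits named list of kinds; each a named list mapping compound id
#'   to an integer vector of 0-based set-bit indices.
#' @param nbits named integer vector of bit-vector lengths per kind;
#'   defaults to the standard length for each kind.
#' @param failed compound ids that could not be fingerprinted.
#' @return A \linkS4class{FingerprintSet}.
#' @examples
#' fps <- FingerprintSet(list(ECFP4 = list(A = c(0L, 1L), B = c(1L, 2L))))
#' compoundIds(fps)
#' @export
FingerprintSet <- function(bits, nbits = NULL, failed = character()) {
  bits <- lapply(bits, function(kk)
    lapply(kk, function(v) sort(unique(as.integer(v)))))
  if (is.null(nbits))
    nbits <- vapply(names(bits), .fpDefaultNbits, integer(1L))
  new("FingerprintSet", bits = bits,
      nbits = setNames(as.integer(nbits), names(bits)),
      failed = as.character(failed))
}

#' @describeIn FingerprintSet compound ids carrying fingerprints.
#' @param x a \code{FingerprintSet}.
#' @export
compoundIds <- function(x) {
  stopifnot(is(x, "FingerprintSet"))
  names(x@bits[[1L]])
}

#' @describeIn FingerprintSet fingerprint kinds held.
#' @export
fpKinds <- function(x) {
  stopifnot(is(x, "FingerprintSet"))
  names(x@bits)
}

#' @describeIn FingerprintSet extract one compound's fingerprint of a kind.
#' @param id compound id.
#' @param kind fingerprint kind.
#' @export
getFingerprint <- function(x, id, kind) {
  stopifnot(is(x, "FingerprintSet"))
  kind <- match.arg(kind, fpKinds(x))
  b <- x@bits[[kind]][[id]]
  if (is.null(b)) stop(sprintf("no %s fingerprint for compound '%s'", kind, id))
  Fingerprint(b, kind, x@nbits[[kind]])
}

#' @export
setMethod("show", "FingerprintSet", function(object) {
  cat(sprintf("FingerprintSet: %d compounds, kinds: %s",
              length(names(object@bits[[1L]])),
              paste(names(object@bits), collapse = ", ")))
  if (length(object@failed) > 0L)
    cat(sprintf(" (%d un-fingerprintable)", length(object@failed)))
  cat("\n")
})

#' DedupeReport: outcome of near-duplicate compound removal
#'
#' @slot kept compound ids retained.
#' @slot removed data.frame with columns \code{removed_id}, \code{kept_id},
#'   \code{kind}, \code{similarity}: each removed compound, the cluster
#'   member kept in its place, and the strongest similarity between them.
#' @export
setClass("DedupeReport",
         representation(kept = "character", removed = "data.frame"))

setValidity("DedupeReport", function(object) {
  if (length(intersect(object@kept, object@removed$removed_id)) > 0L)
    return("kept and removed compound sets must be disjoint")
  TRUE
})

#' @describeIn DedupeReport ids retained after deduplication.
#' @param x a \code{DedupeReport}.
#' @export
keptIds <- function(x) {
  stopifnot(is(x, "DedupeReport"))
  x@kept
}

#' @describeIn DedupeReport removal table.
#' @export
removedPairs <- function(x) {
  stopifnot(is(x, "DedupeReport"))
  x@removed
}

#' @export
setMethod("show", "DedupeReport", function(object) {
  cat(sprintf("DedupeReport: %d kept, %d removed\n",
              length(object@kept), nrow(object@removed)))
})

#' ThresholdScanResult: K-S/AIC similarity-threshold scan outcome
#'
#' @slot grid the threshold grid scanned (strictly increasing).
#' @slot scan data.frame with one row per (seed, threshold): \code{seed},
#'   \code{threshold}, \code{m} (evaluated pair count), \code{mean_D}
#'   (mean K-S statistic), \code{aic}, \code{admissible}.
#' @slot selectedPerSeed threshold chosen by each seed.
#' @slot selected final selection (median over seeds).
#' @export
setClass("ThresholdScanResult",
         representation(grid = "numeric", scan = "data.frame",
                        selectedPerSeed = "numeric", selected = "numeric"))

setValidity("ThresholdScanResult", function(object) {
  if (is.unsorted(object@grid, strictly = TRUE))
    return("grid must be strictly increasing")
  if (length(object@selected) != 1L) return("selected must be scalar")
  if (!any(abs(object@grid - object@selected) < 1e-8))
    return("selected threshold must lie on the grid")
  TRUE
})

#' @describeIn ThresholdScanResult the selected similarity threshold.
#' @param x a \code{ThresholdScanResult}.
#' @export
selectedThreshold <- function(x) {
  stopifnot(is(x, "ThresholdScanResult"))
  x@selected
}

#' @describeIn ThresholdScanResult per-(seed, threshold) scan table.
#' @export
scanTable <- function(x) {
  stopifnot(is(x, "ThresholdScanResult"))
  x@scan
}

#' @describeIn ThresholdScanResult per-seed selections.
#' @export
selectedPerSeed <- function(x) {
  stopifnot(is(x, "ThresholdScanResult"))
  x@selectedPerSeed
}

#' @export
setMethod("show", "ThresholdScanResult", function(object) {
  cat(sprintf(
    "ThresholdScanResult: selected %.2f (per seed: %s); grid [%.2f, %.2f]\n",
    object@selected, paste(sprintf("%.2f", object@selectedPerSeed),
                           collapse = ", "),
    min(object@grid), max(object@grid)))
})

#' ScreenPlateSet: raw well-level imaging-screen measurements
#'
#' @slot wells data.frame with columns \code{plate_id}, \code{patient_id},
#'   \code{well}, \code{role} (treated / dmso / positive_control),
#'   \code{compound_id}, \code{concentration_nM}, \code{nuclei_count}.
#' @export
setClass("ScreenPlateSet", representation(wells = "data.frame"))

setValidity("ScreenPlateSet", function(object) {
  df <- object@wells
  req <- c("plate_id", "patient_id", "well", "role", "compound_id",
           "concentration_nM", "nuclei_count")
  if (!all(req %in% names(df)))
    return(paste("wells must have columns", paste(req, collapse = ", ")))
  if (nrow(df) == 0L) return("plate set must contain at least one well")
  if (!all(df$role %in% WELL_ROLES))
    return(paste("role must be one of", paste(WELL_ROLES, collapse = ", ")))
  bad <- which(!is.finite(df$nuclei_count) | df$nuclei_count < 0)
  if (length(bad) > 0L)
    return(sprintf("nuclei_count must be non-negative; row(s): %s",
                   paste(head(bad, 5L), collapse = ", ")))
  noDmso <- setdiff(unique(df$plate_id), unique(df$plate_id[df$role == "dmso"]))
  if (length(noDmso) > 0L)
    return(sprintf(
      "plate(s) without DMSO wells (normalization impossible): %s",
      paste(head(noDmso, 5L), collapse = ", ")))
  trt <- df[df$role == "treated", , drop = FALSE]
  if (nrow(trt) > 0L) {
    bad <- which(is.na(trt$compound_id) | !nzchar(trt$compound_id) |
                 !is.finite(trt$concentration_nM) | trt$concentration_nM <= 0)
    if (length(bad) > 0L)
      return("treated wells must carry a compound and a positive concentration")
  }
  TRUE
})

#' Construct a ScreenPlateSet
#'
#' @param wells data.frame of wells; see the class documentation for the
#'   required columns. Role labels are canonicalized case-insensitively.
#' @return A \linkS4class{ScreenPlateSet}.
#' @export
ScreenPlateSet <- function(wells) {
  wells <- as.data.frame(wells)
  rownames(wells) <- NULL
  for (col in c("plate_id", "patient_id", "well", "role", "compound_id"))
    if (col %in% names(wells)) wells[[col]] <- as.character(wells[[col]])
  if ("role" %in% names(wells)) wells$role <- .canonRole(wells$role)
  new("ScreenPlateSet", wells = wells)
}

#' @describeIn ScreenPlateSet accessor for the well table.
#' @param x a \code{ScreenPlateSet}.
#' @export
wells <- function(x) {
  stopifnot(is(x, "ScreenPlateSet"))
  x@wells
}

#' @export
setMethod("show", "ScreenPlateSet", function(object) {
  df <- object@wells
  cat(sprintf(
    "ScreenPlateSet: %d wells on %d plates, %d patients, %d compounds\n",
    nrow(df), length(unique(df$plate_id)), length(unique(df$patient_id)),
    length(unique(df$compound_id[df$role == "treated"]))))
})

#' MixtureFit: two-component Gaussian background/active model
#'
#' Fit of the survival-fraction (or z-score) distribution for one
#' (patient, concentration) stratum. One component captures the inactive
#' background (mean near 1 for survival fractions), the other the extreme
#' responses; the hit threshold is an extreme lower quantile of the
#' background component.
#'
#' @slot patientId patient the fit belongs to (NA for ad hoc fits).
#' @slot concentrationNM concentration stratum (NA for ad hoc fits).
#' @slot weights,means,sds component parameters (length 2; weights sum 1).
#' @slot backgroundIndex index (1 or 2) of the background component.
#' @slot loglik final log-likelihood.
#' @slot loglikTrace per-iteration log-likelihood (non-decreasing).
#' @slot threshold activity threshold derived from the fit (NA until set).
#' @slot fallback TRUE when the two-component fit degenerated and a single
#'   background Gaussian was used instead.
#' @export
setClass("MixtureFit",
         representation(patientId = "character", concentrationNM = "numeric",
                        weights = "numeric", means = "numeric",
                        sds = "numeric", backgroundIndex = "integer",
                        loglik = "numeric", loglikTrace = "numeric",
                        threshold = "numeric", fallback = "logical"))

setValidity("MixtureFit", function(object) {
  if (length(object@weights) != 2L || length(object@means) != 2L ||
      length(object@sds) != 2L)
    return("weights, means, sds must each have length 2")
  if (abs(sum(object@weights) - 1) > 1e-9)
    return("component weights must sum to 1")
  if (any(object@weights < 0)) return("weights must be non-negative")
  if (any(!is.finite(object@sds) | object@sds <= 0))
    return("component sds must be positive")
  if (!(object@backgroundIndex %in% c(1L, 2L)))
    return("backgroundIndex must be 1 or 2")
  TRUE
})

#' @describeIn MixtureFit mean of the background component.
#' @param x a \code{MixtureFit}.
#' @export
backgroundMean <- function(x) {
  stopifnot(is(x, "MixtureFit"))
  x@means[x@backgroundIndex]
}

#' @describeIn MixtureFit sd of the background component.
#' @export
backgroundSd <- function(x) {
  stopifnot(is(x, "MixtureFit"))
  x@sds[x@backgroundIndex]
}

#' @describeIn MixtureFit weight of the non-background (active) component.
#' @export
activeWeight <- function(x) {
  stopifnot(is(x, "MixtureFit"))
  x@weights[3L - x@backgroundIndex]
}

#' @export
setMethod("show", "MixtureFit", function(object) {
  bg <- object@backgroundIndex
  cat(sprintf(
    "MixtureFit%s: background N(%.3f, %.3f) w=%.2f; other N(%.3f, %.3f) w=%.2f%s\n",
    if (!is.na(object@patientId))
      sprintf(" [%s @ %g nM]", object@patientId, object@concentrationNM)
    else "",
    object@means[bg], object@sds[bg], object@weights[bg],
    object@means[3L - bg], object@sds[3L - bg], object@weights[3L - bg],
    if (object@fallback) " (single-Gaussian fallback)" else ""))
})

#' LibrarySelection: one representative compound per target
#'
#' @slot entries data.frame with columns \code{target_id},
#'   \code{compound_id}, \code{assay_type}, \code{value_nM},
#'   \code{substituted}; at most one row per target.
#' @slot uncoveredTargets targets for which no (available) compound exists.
#' @export
setClass("LibrarySelection",
         representation(entries = "data.frame",
                        uncoveredTargets = "character"))

setValidity("LibrarySelection", function(object) {
  df <- object@entries
  req <- c("target_id", "compound_id", "assay_type", "value_nM", "substituted")
  if (!all(req %in% names(df)))
    return(paste("entries must have columns", paste(req, collapse = ", ")))
  if (anyDuplicated(df$target_id))
    return("at most one entry per target")
  if (length(intersect(df$target_id, object@uncoveredTargets)) > 0L)
    return("uncovered targets must not also have entries")
  TRUE
})

#' @describeIn LibrarySelection accessor for the selection table.
#' @param x a \code{LibrarySelection}.
#' @export
libraryEntries <- function(x) {
  stopifnot(is(x, "LibrarySelection"))
  x@entries
}

#' @describeIn LibrarySelection targets left without a compound.
#' @export
uncoveredTargets <- function(x) {
  stopifnot(is(x, "LibrarySelection"))
  x@uncoveredTargets
}

#' @export
setMethod("show", "LibrarySelection", function(object) {
  cat(sprintf(
    "LibrarySelection: %d targets covered by %d compounds (%d substituted, %d uncovered)\n",
    nrow(object@entries), length(unique(object@entries$compound_id)),
    sum(object@entries$substituted), length(object@uncoveredTargets)))
})

#' CoverageStats: compound/target coverage accounting for a selection
#'
#' Counts are based on records at or below the configured potency
#' threshold, so a compound "covers" a target only through a sufficiently
#' potent measured activity.
#'
#' @slot nCompounds number of distinct selected compounds.
#' @slot nTargetsCovered universe targets hit by at least one selected
#'   compound at the potency threshold.
#' @slot coverageFraction nTargetsCovered / universe size.
#' @slot targetsPerCompound named integer: potent targets per selected
#'   compound.
#' @slot compoundsPerTarget named integer: selected compounds per universe
#'   target.
#' @slot universeSize size of the target universe.
#' @export
setClass("CoverageStats",
         representation(nCompounds = "integer", nTargetsCovered = "integer",
                        coverageFraction = "numeric",
                        targetsPerCompound = "integer",
                        compoundsPerTarget = "integer",
                        universeSize = "integer"))

setValidity("CoverageStats", function(object) {
  if (object@universeSize > 0L &&
      abs(object@coverageFraction -
          object@nTargetsCovered / object@universeSize) > 1e-9)
    return("coverageFraction must equal nTargetsCovered / universe size")
  TRUE
})

#' @export
setMethod("show", "CoverageStats", function(object) {
  cat(sprintf(
    "CoverageStats: %d compounds covering %d/%d targets (%.1f%%)\n",
    object@nCompounds, object@nTargetsCovered, object@universeSize,
    100 * object@coverageFraction))
})
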