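# Imaging-screen readouts: per-plate DMSO-normalized survival fractions,
# z scores, dose-response profiles with AUC, and mixture-based strong-hit
# calling.

#' Per-well survival fractions
#'
#' SF(well) = nuclei count / mean nuclei count of the DMSO wells on the
#' same plate. By construction the DMSO wells of a plate average to
#' SF = 1.
#'
#' @param plates a \linkS4class{ScreenPlateSet}.
#' @return The well table with an \code{sf} column appended.
#' @export
survivalFraction <- function(plates) {
  stopifnot(is(plates, "ScreenPlateSet"))
  df <- wells(plates)
  dmso <- df[df$role == "dmso", , drop = FALSE]
  dmsoMean <- tapply(dmso$nuclei_count, dmso$plate_id, mean)
  zero <- names(dmsoMean)[dmsoMean <= 0]
  if (length(zero) > 0L)
    stop("DMSO mean nuclei count is zero on plate(s): ",
         paste(zero, collapse = ", "))
  df$sf <- df$nuclei_count / as.numeric(dmsoMean[df$plate_id])
  df
}

#' Per-well survival-fraction z scores
#'
#' Z(well) = (SF(well) - mean SF of the plate's DMSO wells) / sample sd
#' of the plate's DMSO SFs; the number of standard deviations a well's
#' survival fraction sits from the DMSO mean. Plates with fewer than two
#' DMSO wells or zero DMSO spread yield missing z scores with a warning.
#'
#' @param plates a \linkS4class{ScreenPlateSet}.
#' @return The well table with \code{sf} and \code{zscore} columns.
#' @export
sfZscore <- function(plates) {
  df <- survivalFraction(plates)
  dmso <- df[df$role == "dmso", , drop = FALSE]
  mu <- tapply(dmso$sf, dmso$plate_id, mean)
  sdv <- tapply(dmso$sf, dmso$plate_id, function(v)
    if (length(v) >= 2L) stats::sd(v) else NA_real_)
  bad <- names(sdv)[is.na(sdv) | sdv == 0]
  if (length(bad) > 0L)
    warning("z score undefined (DMSO sd missing or zero) on plate(s): ",
            paste(head(bad, 5L), collapse = ", "))
  sdv[!is.na(sdv) & sdv == 0] <- NA_real_
  df$zscore <- (df$sf - as.numeric(mu[df$plate_id])) /
    as.numeric(sdv[df$plate_id])
  df
}

#' Dose-response profiles from a plate set
#'
#' Averages treated-well survival fractions (and z scores when
#' computable) over replicate wells per (patient, compound,
#' concentration). Only the concentrations configured for the screen are
#' retained.
#'
#' @param plates a \linkS4class{ScreenPlateSet}.
#' @param config a \linkS4class{ScreenConfig}.
#' @return data.frame with columns \code{patient_id}, \code{compound_id},
#'   \code{concentration_nM}, \code{sf}, \code{zscore}.
#' @export
doseResponseProfiles <- function(plates, config = ScreenConfig()) {
  stopifnot(is(plates, "ScreenPlateSet"), is(config, "ScreenConfig"))
  df <- suppressWarnings(sfZscore(plates))
  df <- df[df$role == "treated" &
           df$concentration_nM %in% config@concentrationsNM, , drop = FALSE]
  if (nrow(df) == 0L) stop("no treated wells at the configured concentrations")
  key <- interaction(df$patient_id, df$compound_id, df$concentration_nM,
                     drop = TRUE)
  agg <- function(v) tapply(v, key, mean)
  sf <- agg(df$sf)
  z <- agg(df$zscore)
  first <- !duplicated(key)
  out <- data.frame(patient_id = df$patient_id[first],
                    compound_id = df$compound_id[first],
                    concentration_nM = df$concentration_nM[first],
                    sf = as.numeric(sf[as.character(key[first])]),
                    zscore = as.numeric(z[as.character(key[first])]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$patient_id, out$compound_id, out$concentration_nM), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dose-response area under the curve
#'
#' Trapezoidal area of the response over log10 concentration, normalized
#' by the log-concentration span so that a constant response c gives
#' AUC = c; the AUC therefore shares the survival-fraction scale and
#' lower values indicate higher compound activity. The unnormalized
#' trapezoid area is attached as attribute \code{"raw"}.
#'
#' @param response responses (e.g. survival fractions), one per
#'   concentration, in matching order.
#' @param concentrations_nM ascending positive concentrations (nM).
#' @return Normalized AUC (with attribute \code{raw}).
#' @examples
#' doseAUC(c(1, 1, 0, 0), c(3, 30, 300, 3000))  # 0.5
#' @export
doseAUC <- function(response, concentrations_nM) {
  if (length(response) != length(concentrations_nM) || length(response) < 2L)
    stop("response and concentrations_nM must have equal length >= 2")
  if (any(!is.finite(response)))
    stop("missing response at one or more doses")
  if (is.unsorted(concentrations_nM, strictly = TRUE) ||
      any(concentrations_nM <= 0))
    stop("concentrations must be ascending and positive")
  x <- log10(concentrations_nM)
  raw <- sum(diff(x) * (head(response, -1L) + tail(response, -1L)) / 2)
  auc <- raw / (x[length(x)] - x[1L])
  attr(auc, "raw") <- raw
  auc
}

#' Per-(patient, compound) AUC table
#'
#' @param profiles profile table from \code{\link{doseResponseProfiles}}.
#' @param config a \linkS4class{ScreenConfig}; every configured
#'   concentration must be present for each (patient, compound).
#' @return data.frame with \code{patient_id}, \code{compound_id},
#'   \code{auc}, \code{auc_raw}.
#' @export
aucTable <- function(profiles, config = ScreenConfig()) {
  stopifnot(is(config, "ScreenConfig"))
  conc <- config@concentrationsNM
  split_idx <- split(seq_len(nrow(profiles)),
                     paste(profiles$patient_id, profiles$compound_id,
                           sep = "\r"))
  rows <- lapply(split_idx, function(idx) {
    p <- profiles[idx, , drop = FALSE]
    m <- match(conc, p$concentration_nM)
    if (anyNA(m))
      stop(sprintf("missing dose(s) for %s / %s", p$patient_id[1L],
                   p$compound_id[1L]))
    a <- doseAUC(p$sf[m], conc)
    data.frame(patient_id = p$patient_id[1L], compound_id = p$compound_id[1L],
               auc = as.numeric(a), auc_raw = attr(a, "raw"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$patient_id, out$compound_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit per-(patient, concentration) background mixtures and thresholds
#'
#' Pools the configured readout of all compounds within each (patient,
#' concentration) stratum, fits the two-component background/active
#' mixture and derives the data-driven activity threshold from the
#' background component.
#'
#' @param profiles profile table from \code{\link{doseResponseProfiles}}.
#' @param config a \linkS4class{ScreenConfig}.
#' @param seed integer seed forwarded to the mixture fits.
#' @return list with \code{fits} (list of \linkS4class{MixtureFit} with
#'   thresholds set) and \code{thresholds}, a data.frame with columns
#'   \code{patient_id}, \code{concentration_nM}, \code{threshold},
#'   \code{mean_bg}, \code{sd_bg}, \code{weight_active}, \code{fallback}.
#' @export
fitScreenMixtures <- function(profiles, config = ScreenConfig(), seed = 1L) {
  stopifnot(is(config, "ScreenConfig"))
  readoutCol <- if (config@readout == "zscore") "zscore" else "sf"
  anchor <- if (config@readout == "zscore") 0 else 1
  strata <- split(seq_len(nrow(profiles)),
                  list(profiles$patient_id, profiles$concentration_nM),
                  drop = TRUE)
  fits <- list()
  rows <- list()
  for (nm in names(strata)) {
    idx <- strata[[nm]]
    vals <- profiles[[readoutCol]][idx]
    vals <- vals[is.finite(vals)]
    fit <- fitBackgroundMixture(
      vals, seed = seed, anchor = anchor,
      patientId = profiles$patient_id[idx[1L]],
      concentrationNM = profiles$concentration_nM[idx[1L]])
    fit@threshold <- activityThreshold(fit, config@hitPercentile)
    validObject(fit)
    fits[[nm]] <- fit
    rows[[nm]] <- data.frame(
      patient_id = fit@patientId, concentration_nM = fit@concentrationNM,
      threshold = fit@threshold, mean_bg = backgroundMean(fit),
      sd_bg = backgroundSd(fit), weight_active = activeWeight(fit),
      fallback = fit@fallback, stringsAsFactors = FALSE)
  }
  thresholds <- do.call(rbind, rows)
  thresholds <- thresholds[order(thresholds$patient_id,
                                 thresholds$concentration_nM), , drop = FALSE]
  rownames(thresholds) <- NULL
  list(fits = fits, thresholds = thresholds)
}

#' Classify strong hits
#'
#' A compound is a strong hit for a patient when its configured readout
#' is strictly below the (patient, concentration) activity threshold at
#' every configured concentration. The study-level hit set is the union
#' over patients; per-patient provenance is retained so stricter
#' all-patient definitions can be recovered.
#'
#' @param profiles profile table from \code{\link{doseResponseProfiles}}.
#' @param thresholds data.frame with \code{patient_id},
#'   \code{concentration_nM} and \code{threshold} (see
#'   \code{\link{fitScreenMixtures}}); a threshold must exist for every
#'   (patient, concentration) in \code{profiles}.
#' @param config a \linkS4class{ScreenConfig}.
#' @return list with \code{perDose} (one row per patient/compound/dose
#'   with its \code{below_threshold} flag), \code{calls} (one row per
#'   patient/compound with \code{is_strong_hit}) and \code{hits}, the
#'   union-over-patients character vector of strong-hit compounds.
#' @export
classifyStrongHits <- function(profiles, thresholds, config = ScreenConfig()) {
  stopifnot(is(config, "ScreenConfig"))
  .assertCols(thresholds, c("patient_id", "concentration_nM", "threshold"),
              "threshold table")
  readoutCol <- if (config@readout == "zscore") "zscore" else "sf"
  key <- paste(profiles$patient_id, profiles$concentration_nM, sep = "\r")
  tkey <- paste(thresholds$patient_id, thresholds$concentration_nM,
                sep = "\r")
  m <- match(key, tkey)
  if (anyNA(m)) {
    miss <- unique(key[is.na(m)])
    stop("missing threshold for (patient, dose): ",
         paste(gsub("\r", " @ ", head(miss, 5L)), collapse = ", "))
  }
  perDose <- profiles[c("patient_id", "compound_id", "concentration_nM")]
  perDose$readout <- profiles[[readoutCol]]
  perDose$threshold <- thresholds$threshold[m]
  perDose$below_threshold <- is.finite(perDose$readout) &
    perDose$readout < perDose$threshold
  ckey <- paste(perDose$patient_id, perDose$compound_id, sep = "\r")
  nDose <- tapply(perDose$concentration_nM, ckey,
                  function(v) length(unique(v)))
  nBelow <- tapply(perDose$below_threshold, ckey, sum)
  first <- !duplicated(ckey)
  calls <- data.frame(
    patient_id = perDose$patient_id[first],
    compound_id = perDose$compound_id[first],
    n_doses = as.integer(nDose[ckey[first]]),
    n_below = as.integer(nBelow[ckey[first]]),
    stringsAsFactors = FALSE)
  nConc <- length(config@concentrationsNM)
  calls$is_strong_hit <- calls$n_doses == nConc & calls$n_below == nConc
  calls <- calls[order(calls$patient_id, calls$compound_id), , drop = FALSE]
  rownames(calls) <- NULL
  hits <- sort(unique(calls$compound_id[calls$is_strong_hit]))
  list(perDose = perDose, calls = calls, hits = hits)
}

#' End-to-end imaging-screen analysis
#'
#' Normalizes a plate set to per-well survival fractions and z scores,
#' aggregates dose-response profiles, fits the per-(patient,
#' concentration) background mixtures, derives the data-driven activity
#' thresholds, computes dose AUCs and classifies strong hits.
#'
#' @param plates a \linkS4class{ScreenPlateSet}.
#' @param config a \linkS4class{ScreenConfig}.
#' @param seed integer seed for the mixture fits.
#' @return list with \code{profiles}, \code{fits}, \code{thresholds},
#'   \code{auc}, \code{perDose}, \code{calls} and \code{hits} (the
#'   union-over-patients strong-hit compounds).
#' @export
runScreenAnalysis <- function(plates, config = ScreenConfig(), seed = 1L) {
  profiles <- doseResponseProfiles(plates, config)
  mix <- fitScreenMixtures(profiles, config, seed)
  hits <- classifyStrongHits(profiles, mix$thresholds, config)
  list(profiles = profiles, fits = mix$fits, thresholds = mix$thresholds,
       auc = aucTable(profiles, config), perDose = hits$perDose,
       calls = hits$calls, hits = hits$hits)
}
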