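#' FilterConfig: parameters of the library-design filtering pipeline
#'
#' Defaults follow the study settings: a liberal multi-dose potency cutoff
#' of 1000 nM, an 80th-percentile target-specific activity filter, a
#' 95th-percentile global filter anchored on the most variable target, a
#' 0.99 near-duplicate similarity cutoff, and a similarity-threshold scan
#' over a 0.10--0.99 grid (step 0.01) on a 10\% compound subsample
#' repeated with three random seeds.
#'
#' @slot potencyCutoffNM potency cutoff in nM (records above are dropped).
#' @slot targetPercentile per-target retention percentile, in (0, 100].
#' @slot globalPercentile global retention percentile, in (0, 100].
#' @slot dedupeCutoff near-duplicate similarity cutoff, in (0, 1].
#' @slot subsampleFraction compound fraction used by the threshold scan.
#' @slot gridLo,gridHi,gridStep similarity-threshold grid.
#' @slot nSeeds number of random seeds for the threshold scan.
#' @slot minPairs minimum evaluated pair count for a grid point to be
#'   admissible.
#' @slot similarityKind fingerprint kind used by the threshold scan.
#' @export
setClass("FilterConfig",
         representation(potencyCutoffNM = "numeric",
                        targetPercentile = "numeric",
                        globalPercentile = "numeric",
                        dedupeCutoff = "numeric",
                        subsampleFraction = "numeric",
                        gridLo = "numeric", gridHi = "numeric",
                        gridStep = "numeric", nSeeds = "integer",
                        minPairs = "integer", similarityKind = "character"))

setValidity("FilterConfig", function(object) {
  if (object@potencyCutoffNM <= 0) return("potencyCutoffNM must be positive")
  for (p in c(object@targetPercentile, object@globalPercentile))
    if (p <= 0 || p > 100) return("percentiles must lie in (0, 100]")
  if (object@dedupeCutoff <= 0 || object@dedupeCutoff > 1)
    return("dedupeCutoff must lie in (0, 1]")
  if (object@subsampleFraction <= 0 || object@subsampleFraction > 1)
    return("subsampleFraction must lie in (0, 1]")
  if (object@gridLo >= object@gridHi) return("gridLo must be < gridHi")
  if (object@gridStep <= 0) return("gridStep must be positive")
  if (object@nSeeds < 1L) return("nSeeds must be positive")
  if (object@minPairs < 1L) return("minPairs must be positive")
  if (!(object@similarityKind %in% FP_KINDS))
    return(paste("similarityKind must be one of",
                 paste(FP_KINDS, collapse = ", ")))
  TRUE
})

#' Construct a FilterConfig
#'
#' @param potencyCutoffNM potency cutoff in nM (default 1000).
#' @param targetPercentile per-target percentile (default 80).
#' @param globalPercentile global percentile (default 95).
#' @param dedupeCutoff near-duplicate cutoff (default 0.99).
#' @param subsampleFraction threshold-scan subsample fraction (default 0.10).
#' @param gridLo,gridHi,gridStep threshold grid (defaults 0.10, 0.99, 0.01).
#' @param nSeeds scan repetitions (default 3).
#' @param minPairs admissibility floor for evaluated pairs (default 5).
#' @param similarityKind fingerprint kind for the scan (default ECFP4).
#' @return A \linkS4class{FilterConfig}.
#' @examples
#' cfg <- FilterConfig()
#' cfg
#' @export
FilterConfig <- function(potencyCutoffNM = 1000, targetPercentile = 80,
                         globalPercentile = 95, dedupeCutoff = 0.99,
                         subsampleFraction = 0.10, gridLo = 0.10,
                         gridHi = 0.99, gridStep = 0.01, nSeeds = 3L,
                         minPairs = 5L, similarityKind = "ECFP4") {
  new("FilterConfig", potencyCutoffNM = potencyCutoffNM,
      targetPercentile = targetPercentile,
      globalPercentile = globalPercentile, dedupeCutoff = dedupeCutoff,
      subsampleFraction = subsampleFraction, gridLo = gridLo,
      gridHi = gridHi, gridStep = gridStep, nSeeds = as.integer(nSeeds),
      minPairs = as.integer(minPairs),
      similarityKind = match.arg(similarityKind, FP_KINDS))
}

#' @export
setMethod("show", "FilterConfig", function(object) {
  cat(sprintf(
    paste0("FilterConfig: potency <= %g nM; target %g%%; global %g%%; ",
           "dedupe >= %.2f; scan %.0f%% subsample, grid [%.2f, %.2f] step ",
           "%.2f, %d seeds, minPairs %d, %s\n"),
    object@potencyCutoffNM, object@targetPercentile, object@globalPercentile,
    object@dedupeCutoff, 100 * object@subsampleFraction, object@gridLo,
    object@gridHi, object@gridStep, object@nSeeds, object@minPairs,
    object@similarityKind))
})

#' @describeIn FilterConfig the similarity-threshold grid implied by the
#'   config (rounded to the grid-step precision).
#' @param config a \code{FilterConfig}.
#' @export
thresholdGrid <- function(config) {
  stopifnot(is(config, "FilterConfig"))
  digits <- max(0L, ceiling(-log10(config@gridStep)))
  round(seq(config@gridLo, config@gridHi, by = config@gridStep), digits)
}

#' ScreenConfig: parameters of the imaging-screen analysis
#'
#' @slot concentrationsNM tested concentrations in nM, strictly increasing
#'   (default 3, 30, 300, 3000).
#' @slot hitPercentile background-distribution percentile used as the hit
#'   threshold. The default 0.01 is the 0.01th percentile, i.e. a
#'   lower-tail probability of 1e-4.
#' @slot readout readout thresholds and hit calls are based on:
#'   \code{"survival_fraction"} or \code{"zscore"}.
#' @export
setClass("ScreenConfig",
         representation(concentrationsNM = "numeric",
                        hitPercentile = "numeric", readout = "character"))

setValidity("ScreenConfig", function(object) {
  cc <- object@concentrationsNM
  if (length(cc) < 2L || any(cc <= 0) || is.unsorted(cc, strictly = TRUE))
    return("concentrationsNM must be >= 2 strictly increasing positive values")
  if (object@hitPercentile <= 0 || object@hitPercentile >= 100)
    return("hitPercentile must lie in (0, 100)")
  if (!(object@readout %in% c("survival_fraction", "zscore")))
    return("readout must be 'survival_fraction' or 'zscore'")
  TRUE
})

#' Construct a ScreenConfig
#'
#' @param concentrationsNM ascending tested concentrations in nM.
#' @param hitPercentile background percentile for the hit threshold
#'   (default 0.01, i.e. lower-tail probability 1e-4).
#' @param readout \code{"survival_fraction"} (default) or \code{"zscore"}.
#' @return A \linkS4class{ScreenConfig}.
#' @examples
#' ScreenConfig()
#' @export
ScreenConfig <- function(concentrationsNM = c(3, 30, 300, 3000),
                         hitPercentile = 0.01,
                         readout = c("survival_fraction", "zscore")) {
  new("ScreenConfig", concentrationsNM = as.numeric(concentrationsNM),
      hitPercentile = hitPercentile, readout = match.arg(readout))
}

#' @export
setMethod("show", "ScreenConfig", function(object) {
  cat(sprintf(
    "ScreenConfig: %s nM; hit threshold at %g percentile of background; readout %s\n",
    paste(object@concentrationsNM, collapse = "/"), object@hitPercentile,
    object@readout))
})

#' Read a FilterConfig or ScreenConfig from YAML or JSON
#'
#' Keys use snake_case matching the file contract (e.g.
#' \code{potency_cutoff_nM}, \code{hit_percentile}); unknown keys are an
#' error. Missing keys keep their defaults.
#'
#' @param path path to a .yaml/.yml or .json file.
#' @param what \code{"filter"} or \code{"screen"}.
#' @return A \linkS4class{FilterConfig} or \linkS4class{ScreenConfig}.
#' @export
readConfig <- function(path, what = c("filter", "screen")) {
  what <- match.arg(what)
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else if (ext == "json") {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("reading JSON configs requires the 'jsonlite' package")
    jsonlite::fromJSON(path)
  } else stop("config must be a .yaml, .yml or .json file")
  keymap <- if (what == "filter") {
    c(potency_cutoff_nM = "potencyCutoffNM",
      target_percentile = "targetPercentile",
      global_percentile = "globalPercentile",
      dedupe_cutoff = "dedupeCutoff",
      subsample_fraction = "subsampleFraction",
      grid_lo = "gridLo", grid_hi = "gridHi", grid_step = "gridStep",
      n_seeds = "nSeeds", min_pairs = "minPairs",
      similarity_kind = "similarityKind")
  } else {
    c(concentrations_nM = "concentrationsNM",
      hit_percentile = "hitPercentile", readout = "readout")
  }
  unknown <- setdiff(names(vals), names(keymap))
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  args <- setNames(vals, keymap[names(vals)])
  do.call(if (what == "filter") FilterConfig else ScreenConfig, args)
}
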