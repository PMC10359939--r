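# Library assembly: target-space expansion over an interaction network,
# one-representative-per-target selection, availability substitution and
# coverage accounting.

#' Expand a target space over a protein-interaction network
#'
#' First neighbors are proteins directly and physically interacting with
#' a seed (cancer-associated) target; influencers are proteins directly
#' interacting with a first neighbor. Edges are symmetrized and
#' self-loops dropped, so results do not depend on edge order or
#' direction. Seeds, first neighbors and influencers are pairwise
#' disjoint.
#'
#' @param seedTargets non-empty character vector of seed target ids.
#' @param edges data.frame with \code{source} and \code{dest} columns
#'   (see \code{\link{readEdgeTable}}).
#' @return list with character vectors \code{firstNeighbors} and
#'   \code{influencers}.
#' @examples
#' edges <- data.frame(source = c("A", "B"), dest = c("B", "C"))
#' expandTargetSpace("A", edges)  # neighbors B, influencers C
#' @export
expandTargetSpace <- function(seedTargets, edges) {
  seedTargets <- unique(as.character(seedTargets))
  if (length(seedTargets) == 0L) stop("seedTargets must be non-empty")
  .assertCols(edges, c("source", "dest"), "edge table")
  a <- as.character(edges$source)
  b <- as.character(edges$dest)
  keep <- a != b
  from <- c(a[keep], b[keep])
  to <- c(b[keep], a[keep])
  adjacency <- function(nodes) unique(to[from %in% nodes])
  firstNeighbors <- setdiff(adjacency(seedTargets), seedTargets)
  influencers <- setdiff(adjacency(firstNeighbors),
                         union(seedTargets, firstNeighbors))
  list(firstNeighbors = sort(firstNeighbors), influencers = sort(influencers))
}

# Deterministic candidate ordering: ascending potency, ties by compound id
# then assay type in enum order.
.rankCandidates <- function(df) {
  df[order(df$value_nM, df$compound_id,
           match(df$assay_type, ASSAY_TYPES)), , drop = FALSE]
}

#' Pick a single most potent compound per target
#'
#' For each target, selects the record with the lowest bioactivity value
#' across all multi-dose assay types -- IC50, EC50, Ki and Kd are treated
#' equally. Ties are broken deterministically by the lexicographically
#' smaller compound id, then by assay type in the order IC50, EC50, Ki,
#' Kd. Expects an aggregated table (one row per compound/target/assay).
#'
#' @param table a \linkS4class{BioactivityTable}.
#' @return A \linkS4class{LibrarySelection} with one entry per target and
#'   \code{substituted = FALSE} throughout.
#' @seealso \code{\link{substituteUnavailable}}, \code{\link{coverageSummary}}
#' @export
pickRepresentativePerTarget <- function(table) {
  stopifnot(is(table, "BioactivityTable"))
  df <- bioRecords(table)
  if (nrow(df) == 0L) {
    return(new("LibrarySelection",
               entries = data.frame(target_id = character(),
                                    compound_id = character(),
                                    assay_type = character(),
                                    value_nM = numeric(),
                                    substituted = logical()),
               uncoveredTargets = character()))
  }
  ranked <- .rankCandidates(df)
  first <- ranked[!duplicated(ranked$target_id), , drop = FALSE]
  entries <- data.frame(target_id = first$target_id,
                        compound_id = first$compound_id,
                        assay_type = first$assay_type,
                        value_nM = first$value_nM,
                        substituted = FALSE, stringsAsFactors = FALSE)
  entries <- entries[order(entries$target_id), , drop = FALSE]
  rownames(entries) <- NULL
  new("LibrarySelection", entries = entries, uncoveredTargets = character())
}

#' Replace unavailable representatives by the next most potent available compound
#'
#' For each selected entry whose compound is not available for sale, the
#' target's candidate compounds are walked in ascending potency order and
#' the first available one replaces the original (flagged
#' \code{substituted}). Targets with no available compound at all move to
#' the uncovered list. Compounds with unknown availability are treated as
#' unavailable (conservative for purchasability).
#'
#' @param selection a \linkS4class{LibrarySelection} derived from
#'   \code{table}.
#' @param table the aggregated \linkS4class{BioactivityTable} the
#'   selection was derived from.
#' @param availability named logical vector, compound id -> available.
#'   Missing or NA entries count as unavailable.
#' @return An updated \linkS4class{LibrarySelection}.
#' @export
substituteUnavailable <- function(selection, table, availability) {
  stopifnot(is(selection, "LibrarySelection"), is(table, "BioactivityTable"))
  entries <- libraryEntries(selection)
  if (nrow(entries) == 0L) return(selection)
  df <- bioRecords(table)
  isAvail <- function(id) {
    v <- availability[id]
    !is.na(v) & isTRUE(as.logical(v))
  }
  keep <- logical(nrow(entries))
  uncovered <- uncoveredTargets(selection)
  for (i in seq_len(nrow(entries))) {
    if (isAvail(entries$compound_id[i])) {
      keep[i] <- TRUE
      next
    }
    cand <- .rankCandidates(df[df$target_id == entries$target_id[i], ,
                               drop = FALSE])
    avail <- vapply(cand$compound_id, isAvail, logical(1L))
    if (any(avail)) {
      j <- which(avail)[1L]
      entries$compound_id[i] <- cand$compound_id[j]
      entries$assay_type[i] <- cand$assay_type[j]
      entries$value_nM[i] <- cand$value_nM[j]
      entries$substituted[i] <- TRUE
      keep[i] <- TRUE
    } else {
      uncovered <- union(uncovered, entries$target_id[i])
    }
  }
  out <- entries[keep, , drop = FALSE]
  rownames(out) <- NULL
  new("LibrarySelection", entries = out, uncoveredTargets = sort(uncovered))
}

#' Coverage accounting for a library selection
#'
#' Counts targets per compound and compounds per target from the
#' bioactivity table restricted to the selected compounds and to records
#' at or below the potency cutoff, so coverage reflects measured potent
#' activity (including off-target activity of the selected compounds),
#' not just the per-target assignments.
#'
#' @param selection a \linkS4class{LibrarySelection}.
#' @param table the \linkS4class{BioactivityTable} coverage is judged
#'   against.
#' @param targetUniverse character vector of targets coverage is measured
#'   over.
#' @param potencyCutoffNM records above this value are ignored
#'   (default 1000).
#' @return A \linkS4class{CoverageStats}.
#' @export
coverageSummary <- function(selection, table, targetUniverse,
                            potencyCutoffNM = 1000) {
  stopifnot(is(selection, "LibrarySelection"), is(table, "BioactivityTable"))
  targetUniverse <- unique(as.character(targetUniverse))
  cpds <- unique(libraryEntries(selection)$compound_id)
  df <- bioRecords(table)
  df <- df[df$compound_id %in% cpds & df$value_nM <= potencyCutoffNM, ,
           drop = FALSE]
  pairs <- unique(df[c("compound_id", "target_id")])
  tpc <- setNames(integer(length(cpds)), cpds)
  if (length(cpds) > 0L && nrow(pairs) > 0L) {
    tab <- table(pairs$compound_id)
    tpc[names(tab)] <- as.integer(tab)
  }
  cpt <- setNames(integer(length(targetUniverse)), targetUniverse)
  inUniverse <- pairs[pairs$target_id %in% targetUniverse, , drop = FALSE]
  if (nrow(inUniverse) > 0L) {
    tab <- table(inUniverse$target_id)
    cpt[names(tab)] <- as.integer(tab)
  }
  covered <- sum(cpt > 0L)
  new("CoverageStats", nCompounds = length(cpds),
      nTargetsCovered = as.integer(covered),
      coverageFraction = if (length(targetUniverse) > 0L)
        covered / length(targetUniverse) else 0,
      targetsPerCompound = tpc, compoundsPerTarget = cpt,
      universeSize = length(targetUniverse))
}

#' Run the full library-design filtering pipeline
#'
#' Chains the design stages in their canonical order: replicate
#' aggregation, the absolute potency cutoff, the target-specific
#' percentile filter, optional near-duplicate removal at a similarity
#' threshold (either supplied or selected by the K-S/AIC scan when
#' fingerprints are given), the global percentile filter, per-target
#' representative selection and availability substitution. Monotone
#' shrinkage of the record count across stages is asserted.
#'
#' @param table a \linkS4class{BioactivityTable} of raw records.
#' @param config a \linkS4class{FilterConfig}.
#' @param fps optional \linkS4class{FingerprintSet}; enables the
#'   similarity stage.
#' @param availability optional named logical vector of compound
#'   availability; enables the substitution stage.
#' @param targetUniverse targets coverage is measured over (default: all
#'   targets in \code{table}).
#' @param similarityThreshold optional fixed dedupe threshold; when NULL
#'   and \code{fps} is given, \code{\link{selectSimilarityThreshold}}
#'   chooses it.
#' @return list with the final \code{selection}
#'   (\linkS4class{LibrarySelection}), \code{coverage}
#'   (\linkS4class{CoverageStats}), the selected \code{threshold} (or NA),
#'   the filtered \code{table}, and \code{log}, a data.frame of per-stage
#'   record counts.
#' @export
designLibrary <- function(table, config = FilterConfig(), fps = NULL,
                          availability = NULL, targetUniverse = NULL,
                          similarityThreshold = NULL) {
  stopifnot(is(table, "BioactivityTable"), is(config, "FilterConfig"))
  if (is.null(targetUniverse))
    targetUniverse <- unique(bioRecords(table)$target_id)
  stages <- character()
  counts <- integer()
  note <- function(stage, tab) {
    stages <<- c(stages, stage)
    counts <<- c(counts, nrow(bioRecords(tab)))
  }
  note("input", table)
  cur <- aggregateReplicates(table)
  note("aggregate_replicates", cur)
  cur <- applyPotencyCutoff(cur, config@potencyCutoffNM)
  note("potency_cutoff", cur)
  cur <- targetSpecificFilter(cur, config@targetPercentile)
  note("target_specific_filter", cur)
  threshold <- NA_real_
  if (!is.null(fps)) {
    threshold <- if (is.null(similarityThreshold)) {
      selectedThreshold(selectSimilarityThreshold(fps, cur, config))
    } else similarityThreshold
    present <- intersect(compoundIds(fps),
                         unique(bioRecords(cur)$compound_id))
    if (length(present) > 1L) {
      sub <- FingerprintSet(
        lapply(fps@bits, function(kk) kk[present]),
        nbits = fps@nbits)
      rep <- dedupeNearDuplicates(sub, cutoff = threshold)
      df <- bioRecords(cur)
      keepRow <- !(df$compound_id %in% removedPairs(rep)$removed_id)
      cur <- BioactivityTable(df[keepRow, , drop = FALSE])
    }
    note("similarity_dedupe", cur)
  }
  cur <- globalActivityFilter(cur, config@globalPercentile)
  note("global_activity_filter", cur)
  stopifnot(!is.unsorted(rev(counts)))  # monotone shrinkage across stages
  selection <- pickRepresentativePerTarget(cur)
  if (!is.null(availability))
    selection <- substituteUnavailable(selection, cur, availability)
  coverage <- coverageSummary(selection, cur, targetUniverse,
                              config@potencyCutoffNM)
  list(selection = selection, coverage = coverage, threshold = threshold,
       table = cur,
       log = data.frame(stage = stages, records = counts,
                        stringsAsFactors = FALSE))
}
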