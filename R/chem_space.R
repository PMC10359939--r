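# Fingerprint similarity and near-duplicate removal. Similarities operate
# on abstract bit sets, so everything downstream of fingerprint
# enumeration runs without a chemistry backend.

# Internal set-count similarities on sorted integer bit vectors.
.diceBits <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na == 0L && nb == 0L) return(1)
  ni <- sum(a %in% b)
  2 * ni / (na + nb)
}

.tanimotoBits <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na == 0L && nb == 0L) return(1)
  ni <- sum(a %in% b)
  ni / (na + nb - ni)
}

.checkComparable <- function(a, b) {
  stopifnot(is(a, "Fingerprint"), is(b, "Fingerprint"))
  if (a@kind != b@kind)
    stop(sprintf("fingerprint kind mismatch: %s vs %s", a@kind, b@kind))
  if (a@nbits != b@nbits)
    stop(sprintf("fingerprint length mismatch: %d vs %d", a@nbits, b@nbits))
  invisible(TRUE)
}

#' Dice similarity between two fingerprints
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}, the coefficient used for ECFP4/6
#' fingerprints; defined as 1 when both bit sets are empty.
#'
#' @param a,b \linkS4class{Fingerprint} objects of the same kind and length.
#' @return Similarity in [0, 1].
#' @examples
#' a <- Fingerprint(c(1L, 2L), "ECFP4")
#' b <- Fingerprint(c(2L, 3L), "ECFP4")
#' diceSimilarity(a, b)  # 0.5
#' @seealso \code{\link{tanimotoSimilarity}}
#' @export
diceSimilarity <- function(a, b) {
  .checkComparable(a, b)
  .diceBits(a@bits, b@bits)
}

#' Tanimoto similarity between two fingerprints
#'
#' \eqn{|A \cap B| / |A \cup B|}, the coefficient used for MACCS keys;
#' defined as 1 when both bit sets are empty.
#'
#' @inheritParams diceSimilarity
#' @return Similarity in [0, 1].
#' @examples
#' a <- Fingerprint(c(1L, 2L), "MACCS")
#' b <- Fingerprint(c(2L, 3L), "MACCS")
#' tanimotoSimilarity(a, b)  # 1/3
#' @export
tanimotoSimilarity <- function(a, b) {
  .checkComparable(a, b)
  .tanimotoBits(a@bits, b@bits)
}

# The similarity convention per kind: Dice for circular fingerprints,
# Tanimoto for MACCS keys.
.kindSimFun <- function(kind) {
  if (kind == "MACCS") .tanimotoBits else .diceBits
}

#' Pairwise similarity matrix for a set of compounds
#'
#' Uses the kind's conventional coefficient (Dice for ECFP4/6, Tanimoto
#' for MACCS).
#'
#' @param fps a \linkS4class{FingerprintSet}.
#' @param kind fingerprint kind to use.
#' @param ids compounds to include (default: all in \code{fps}).
#' @return Symmetric numeric matrix with unit diagonal.
#' @export
similarityMatrix <- function(fps, kind = fpKinds(fps)[1L], ids = NULL) {
  stopifnot(is(fps, "FingerprintSet"))
  kind <- match.arg(kind, fpKinds(fps))
  if (is.null(ids)) ids <- compoundIds(fps)
  bits <- fps@bits[[kind]][ids]
  simFun <- .kindSimFun(kind)
  n <- length(ids)
  m <- diag(1, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      bi <- bits[[i]]
      for (j in (i + 1L):n) {
        m[i, j] <- m[j, i] <- simFun(bi, bits[[j]])
      }
    }
  }
  dimnames(m) <- list(ids, ids)
  m
}

#' Remove structurally near-duplicate compounds
#'
#' A compound pair is flagged when any held fingerprint kind reaches the
#' cutoff (Dice for ECFP4/6, Tanimoto for MACCS). Flagged pairs are
#' clustered by transitive closure; within each cluster the last compound
#' in input order is kept and all earlier members are removed, mirroring
#' the convention that of a redundant pair the first-listed compound is
#' dropped. Requiring any single kind to flag a pair is the conservative
#' pruning choice.
#'
#' @param fps a \linkS4class{FingerprintSet}.
#' @param cutoff similarity cutoff in (0, 1] (default 0.99).
#' @param order compound ids in input order; defaults to the order held in
#'   \code{fps}.
#' @return A \linkS4class{DedupeReport}. The removed table reports, per
#'   removed compound, the kind and value of its strongest similarity to
#'   the kept cluster member (which can fall below the cutoff for chained
#'   clusters).
#' @examples
#' fps <- FingerprintSet(list(ECFP4 = list(
#'   X = c(1L, 2L, 3L), Y = c(1L, 2L, 3L), Z = c(50L, 60L))))
#' rep <- dedupeNearDuplicates(fps, cutoff = 0.99)
#' keptIds(rep)  # Y kept of the X/Y duplicate pair, Z untouched
#' @export
dedupeNearDuplicates <- function(fps, cutoff = 0.99, order = compoundIds(fps)) {
  stopifnot(is(fps, "FingerprintSet"))
  if (cutoff <= 0 || cutoff > 1) stop("cutoff must lie in (0, 1]")
  ids <- order
  if (!setequal(ids, compoundIds(fps)) || anyDuplicated(ids))
    stop("'order' must be a permutation of the compound ids in 'fps'")
  n <- length(ids)
  kinds <- fpKinds(fps)
  bitsByKind <- lapply(kinds, function(k) fps@bits[[k]][ids])
  names(bitsByKind) <- kinds
  simFuns <- lapply(kinds, .kindSimFun)
  names(simFuns) <- kinds

  # union-find over flagged pairs
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  flagged <- logical(n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        hit <- FALSE
        for (k in kinds) {
          s <- simFuns[[k]](bitsByKind[[k]][[i]], bitsByKind[[k]][[j]])
          if (s >= cutoff - .EPS) { hit <- TRUE; break }
        }
        if (hit) {
          flagged[i] <- flagged[j] <- TRUE
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }

  removed <- data.frame(removed_id = character(), kept_id = character(),
                        kind = character(), similarity = numeric(),
                        stringsAsFactors = FALSE)
  keep <- rep(TRUE, n)
  if (any(flagged)) {
    roots <- vapply(seq_len(n), find, integer(1L))
    for (r in unique(roots[flagged])) {
      members <- which(roots == r)  # in input order
      keeper <- members[length(members)]
      drop <- members[-length(members)]
      keep[drop] <- FALSE
      for (d in drop) {
        best <- -Inf; bestKind <- kinds[1L]
        for (k in kinds) {
          s <- simFuns[[k]](bitsByKind[[k]][[d]], bitsByKind[[k]][[keeper]])
          if (s > best) { best <- s; bestKind <- k }
        }
        removed <- rbind(removed, data.frame(
          removed_id = ids[d], kept_id = ids[keeper], kind = bestKind,
          similarity = best, stringsAsFactors = FALSE))
      }
    }
  }
  new("DedupeReport", kept = ids[keep], removed = removed)
}

#' Enumerate molecular fingerprints from SMILES
#'
#' Computes ECFP4/ECFP6 (radius 2/3 circular fingerprints, folded to 2048
#' bits) and 167-bit MACCS key fingerprints through the
#' ChemmineR/ChemmineOB (OpenBabel) chemistry backend. The backend emits
#' 4096-bit circular fingerprints, which are OR-folded to the 2048-bit
#' community default by index modulo. Compounds whose SMILES cannot be
#' parsed are flagged un-fingerprintable rather than failing the run;
#' only an entirely unparsable input is an error.
#'
#' The rest of the package consumes abstract bit sets, so a
#' \linkS4class{FingerprintSet} built by any other means (including the
#' synthetic generator) is an equally valid input downstream.
#'
#' @param compounds data.frame with \code{compound_id} and \code{smiles}
#'   columns (see \code{\link{readCompoundTable}}, \code{\link{readSmiles}}).
#' @param kinds fingerprint kinds to compute (default all three).
#' @return A \linkS4class{FingerprintSet}; un-fingerprintable compounds
#'   are listed in its \code{failed} slot.
#' @export
fingerprintCompounds <- function(compounds, kinds = FP_KINDS) {
  .assertCols(compounds, c("compound_id", "smiles"), "compound table")
  kinds <- match.arg(kinds, FP_KINDS, several.ok = TRUE)
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE))
    stop("fingerprint enumeration requires the ChemmineR and ChemmineOB packages")
  ids <- as.character(compounds$compound_id)
  smi <- as.character(compounds$smiles)
  usable <- !is.na(smi) & nzchar(trimws(smi))

  # validity probe: OpenBabel canonicalization returns an empty string for
  # SMILES it cannot parse (it otherwise only warns and emits garbage)
  ok <- logical(length(ids))
  for (i in which(usable)) {
    can <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", paste0(smi[i], " m\n")),
      error = function(e) "")
    ok[i] <- nzchar(trimws(can))
  }
  if (!any(ok))
    stop("no compound could be fingerprinted (all SMILES unparsable)")
  failed <- ids[!ok]
  sdfset <- suppressWarnings(
    ChemmineR::smiles2sdf(setNames(smi[ok], ids[ok])))
  suppressWarnings(ChemmineR::cid(sdfset) <- ids[ok])

  bits <- list()
  for (k in kinds) {
    fpset <- suppressWarnings(ChemmineR::fingerprintOB(sdfset, k))
    mat <- fpset@fpma
    nb <- .fpDefaultNbits(k)
    bits[[k]] <- lapply(seq_len(nrow(mat)), function(i) {
      idx <- which(mat[i, ] != 0) - 1L  # 0-based backend indices
      if (k == "MACCS") {
        idx <- idx[idx < nb]          # backend pads MACCS to 256 bits
      } else {
        idx <- unique(idx %% nb)      # fold 4096 -> 2048
      }
      sort(as.integer(idx))
    })
    names(bits[[k]]) <- ids[ok]
  }
  FingerprintSet(bits, failed = failed)
}
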