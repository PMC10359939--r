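# Table input/output. All tables are long-format CSV/TSV with mandated
# header names; the delimiter is inferred from the file extension
# (.csv -> comma, anything else -> tab). Units are fixed to nM in files.

.readDelim <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L)
    stop("empty file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  fun <- if (ext == "csv") utils::read.csv else utils::read.delim
  df <- fun(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L)
    stop("table has a header but no data rows: ", path, call. = FALSE)
  df
}

.writeDelim <- function(df, path) {
  ext <- tolower(tools::file_ext(path))
  sep <- if (ext == "csv") "," else "\t"
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Map role spellings ("DMSO", "positive-control", ...) onto the canonical
# vocabulary; unknown labels pass through and are caught by validity.
.canonRole <- function(role) {
  r <- gsub("[ -]", "_", tolower(trimws(role)))
  r[r %in% c("control", "negative_control", "untreated")] <- "dmso"
  r[r %in% c("positive", "pos_control", "staurosporine")] <- "positive_control"
  r
}

#' Read a bioactivity table
#'
#' Reads a long-format CSV/TSV with header columns \code{compound_id},
#' \code{target_id}, \code{assay_type} (IC50/EC50/Ki/Kd, case-insensitive)
#' and \code{value_nM}. Rows with an unknown assay type or a non-positive
#' value are rejected with row-indexed diagnostics.
#'
#' @param path path to a .csv or .tsv/.txt file.
#' @return A \linkS4class{BioactivityTable}.
#' @seealso \code{\link{writeBioactivityTable}}
#' @export
readBioactivityTable <- function(path) {
  df <- .readDelim(path)
  .assertCols(df, c("compound_id", "target_id", "assay_type", "value_nM"),
              "bioactivity table")
  df$assay_type <- .canonAssay(df$assay_type)
  df$value_nM <- suppressWarnings(as.numeric(df$value_nM))
  bad <- which(!(df$assay_type %in% ASSAY_TYPES))
  if (length(bad) > 0L)
    stop(sprintf("unknown assay_type at data row(s) %s",
                 paste(head(bad, 10L), collapse = ", ")), call. = FALSE)
  bad <- which(!is.finite(df$value_nM) | df$value_nM <= 0)
  if (length(bad) > 0L)
    stop(sprintf("non-positive or non-numeric value_nM at data row(s) %s",
                 paste(head(bad, 10L), collapse = ", ")), call. = FALSE)
  BioactivityTable(df[c("compound_id", "target_id", "assay_type", "value_nM")])
}

.canonAssay <- function(x) {
  x <- trimws(as.character(x))
  canon <- setNames(ASSAY_TYPES, toupper(ASSAY_TYPES))
  hit <- canon[toupper(x)]
  ifelse(is.na(hit), x, hit)
}

#' Write a bioactivity table
#'
#' @param x a \linkS4class{BioactivityTable}.
#' @param path output path (.csv for comma-separated, else tab-separated).
#' @return The path, invisibly.
#' @export
writeBioactivityTable <- function(x, path) {
  stopifnot(is(x, "BioactivityTable"))
  .writeDelim(bioRecords(x), path)
}

#' Read a screening-plate table
#'
#' Reads a CSV/TSV with columns \code{plate_id}, \code{patient_id},
#' \code{well}, \code{role}, \code{compound_id}, \code{concentration_nM}
#' and \code{nuclei_count}. Role labels are canonicalized (e.g.
#' "DMSO"/"dmso", "positive-control"). Every plate must contain at least
#' one DMSO well, otherwise plate normalization is impossible.
#'
#' @param path path to the table.
#' @return A \linkS4class{ScreenPlateSet}.
#' @export
readPlateTable <- function(path) {
  df <- .readDelim(path)
  .assertCols(df, c("plate_id", "patient_id", "well", "role", "compound_id",
                    "concentration_nM", "nuclei_count"), "plate table")
  df$concentration_nM <- suppressWarnings(as.numeric(df$concentration_nM))
  df$nuclei_count <- suppressWarnings(as.numeric(df$nuclei_count))
  bad <- which(!is.finite(df$nuclei_count) | df$nuclei_count < 0 |
               df$nuclei_count != round(df$nuclei_count))
  if (length(bad) > 0L)
    stop(sprintf("nuclei_count must be a non-negative integer; row(s) %s",
                 paste(head(bad, 10L), collapse = ", ")), call. = FALSE)
  ScreenPlateSet(df)
}

#' Write a screening-plate table
#'
#' @param x a \linkS4class{ScreenPlateSet}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writePlateTable <- function(x, path) {
  stopifnot(is(x, "ScreenPlateSet"))
  .writeDelim(wells(x), path)
}

#' Read a compound annotation table
#'
#' Requires a \code{compound_id} column; recognises optional \code{smiles}
#' and \code{available} (logical or 0/1/yes/no) columns. Any further
#' columns (clinical phase, ATC class, names, CAS, ...) are kept as
#' metadata. Compounds with unknown availability are treated as
#' unavailable by the availability filter, which is the conservative
#' choice for purchasability.
#'
#' @param path path to the table.
#' @return data.frame with canonical \code{compound_id}, \code{smiles},
#'   \code{available} columns plus any metadata columns.
#' @export
readCompoundTable <- function(path) {
  df <- .readDelim(path)
  .assertCols(df, "compound_id", "compound table")
  df$compound_id <- as.character(df$compound_id)
  if (anyNA(df$compound_id) || any(!nzchar(df$compound_id)))
    stop("compound_id must be non-empty", call. = FALSE)
  if (anyDuplicated(df$compound_id))
    stop("duplicate compound_id(s): ",
         paste(head(unique(df$compound_id[duplicated(df$compound_id)]), 5L),
               collapse = ", "), call. = FALSE)
  if (!("smiles" %in% names(df))) df$smiles <- NA_character_
  df$smiles <- as.character(df$smiles)
  df$smiles[!is.na(df$smiles) & !nzchar(trimws(df$smiles))] <- NA_character_
  df$available <- if ("available" %in% names(df))
    .parseLogical(df$available) else NA
  df
}

.parseLogical <- function(x) {
  if (is.logical(x)) return(x)
  s <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(s))
  out[s %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[s %in% c("false", "f", "0", "no", "n")] <- FALSE
  out
}

#' Read a target annotation table
#'
#' Requires \code{target_id}; recognises optional
#' \code{is_cancer_associated} and \code{mutant_of} columns. A mutant
#' variant is modelled as a distinct target whose \code{mutant_of} names
#' its wild-type parent, which must itself appear in the table.
#'
#' @param path path to the table.
#' @return data.frame with \code{target_id}, \code{is_cancer_associated},
#'   \code{mutant_of} plus any annotation columns.
#' @export
readTargetTable <- function(path) {
  df <- .readDelim(path)
  .assertCols(df, "target_id", "target table")
  df$target_id <- as.character(df$target_id)
  if (anyDuplicated(df$target_id))
    stop("duplicate target_id(s)", call. = FALSE)
  if (!("is_cancer_associated" %in% names(df))) df$is_cancer_associated <- NA
  df$is_cancer_associated <- .parseLogical(df$is_cancer_associated)
  if (!("mutant_of" %in% names(df))) df$mutant_of <- NA_character_
  df$mutant_of <- as.character(df$mutant_of)
  df$mutant_of[!is.na(df$mutant_of) & !nzchar(df$mutant_of)] <- NA_character_
  bad <- !is.na(df$mutant_of) & !(df$mutant_of %in% df$target_id)
  if (any(bad))
    stop("mutant_of must name another target_id in the table; offending: ",
         paste(head(df$target_id[bad], 5L), collapse = ", "), call. = FALSE)
  df
}

#' Read a protein-interaction edge list
#'
#' Two-column (\code{source}, \code{dest}) CSV/TSV of undirected physical
#' or signalling interactions. Self-loops are dropped.
#'
#' @param path path to the table.
#' @return data.frame with \code{source} and \code{dest} columns.
#' @export
readEdgeTable <- function(path) {
  df <- .readDelim(path)
  .assertCols(df, c("source", "dest"), "edge table")
  df$source <- as.character(df$source)
  df$dest <- as.character(df$dest)
  df <- df[df$source != df$dest, c("source", "dest"), drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a SMILES file
#'
#' One molecule per line: \code{SMILES<whitespace>compound_id}. Blank
#' lines and lines starting with '#' are ignored.
#'
#' @param path path to a .smi file.
#' @return data.frame with \code{compound_id} and \code{smiles}.
#' @export
readSmiles <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("no molecules in ", path, call. = FALSE)
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- which(vapply(parts, length, integer(1L)) < 2L)
  if (length(bad) > 0L)
    stop(sprintf("lines without a compound id: %s",
                 paste(head(bad, 10L), collapse = ", ")), call. = FALSE)
  df <- data.frame(
    compound_id = vapply(parts, `[[`, character(1L), 2L),
    smiles = vapply(parts, `[[`, character(1L), 1L),
    stringsAsFactors = FALSE)
  if (anyDuplicated(df$compound_id))
    stop("duplicate compound ids in SMILES file", call. = FALSE)
  df
}
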