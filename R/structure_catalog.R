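#' Load a structure index
#'
#' Reads the local snapshot of protein-to-structure cross-references: one row
#' per `(pdb_id, protein)` with the experimental method and resolution.  The
#' snapshot replaces live database queries so that candidate selection is
#' reproducible.
#'
#' @param tsv_path TSV with header
#'   `pdb_id  method  resolution  accession  chains`, `chains`
#'   comma-separated; `resolution` may be blank only for NMR entries.
#' @return An `xl_index` data frame (`pdb_id`, `method`, `resolution`,
#'   `accession`, `chains` list-column).  Malformed rows are dropped and
#'   reported in `attr(, "rejects")`.
#' @export
load_structure_index <- function(tsv_path) {
  tab <- utils::read.delim(tsv_path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("pdb_id", "method", "resolution", "accession", "chains")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    stop("structure index missing column(s): ", paste(miss, collapse = ", "))
  }
  res <- suppressWarnings(as.numeric(tab$resolution))
  blank <- is.na(res) | tab$resolution == ""
  method <- tolower(tab$method)
  reason <- character(nrow(tab))
  reason[!method %in% c("xray", "em", "nmr")] <- "unknown method"
  reason[reason == "" & blank & method != "nmr"] <-
    "missing resolution on non-NMR entry"
  reason[reason == "" & !blank & res <= 0] <- "non-positive resolution"
  reason[reason == "" & tab$chains == ""] <- "no chains listed"
  rejects <- cbind(tab[reason != "", need, drop = FALSE],
                   reason = reason[reason != ""])
  keep <- reason == ""
  out <- data.frame(pdb_id = tab$pdb_id[keep], method = method[keep],
                    resolution = res[keep], accession = tab$accession[keep],
                    stringsAsFactors = FALSE)
  out$chains <- lapply(strsplit(tab$chains[keep], ","), trimws)
  attr(out, "rejects") <- rejects
  class(out) <- c("xl_index", "data.frame")
  out
}

#' Filter a structure index by resolution
#'
#' Keeps entries whose resolution is at least as good as (numerically at or
#' below) the cutoff.  NMR entries without a deposited resolution are always
#' kept.
#'
#' @param index An `xl_index`.
#' @param cutoff Resolution cutoff in Angstrom (default 3.5).
#' @return The filtered `xl_index`.
#' @export
filter_by_resolution <- function(index, cutoff = 3.5) {
  stopifnot(inherits(index, "xl_index"))
  keep <- (is.na(index$resolution) & index$method == "nmr") |
    (!is.na(index$resolution) & index$resolution <= cutoff)
  out <- index[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("xl_index", "data.frame")
  out
}

#' Candidate structures for one cross-link
#'
#' For an intermolecular link, the structures that contain chains for both
#' proteins (the cross-correlation of the two partners' structure lists); for
#' an intramolecular link, every structure containing the protein.  An empty
#' result is valid and feeds the "novel" class.
#'
#' @param link A single-row `xl_links` data frame (or list with `protein_a`,
#'   `protein_b`, `linkage`).
#' @param index A (typically resolution-filtered) `xl_index`.
#' @return Character vector of pdb ids, sorted, unique.
#' @export
candidates_for_link <- function(link, index) {
  stopifnot(inherits(index, "xl_index"))
  has_a <- unique(index$pdb_id[index$accession == link$protein_a])
  if (link$linkage == "intra") {
    return(sort(has_a))
  }
  has_b <- unique(index$pdb_id[index$accession == link$protein_b])
  sort(intersect(has_a, has_b))
}

#' Chain map for one structure from the index
#'
#' Collects the chain-to-accession assignments of all index rows of one
#' structure, for use as the `chain_map` of [load_ca_table()].
#'
#' @param index An `xl_index`.
#' @param pdb_id Structure id.
#' @return Named character vector, chain id -> accession.
#' @export
index_chain_map <- function(index, pdb_id) {
  stopifnot(inherits(index, "xl_index"))
  rows <- which(index$pdb_id == pdb_id)
  if (length(rows) == 0L) {
    stop("structure not in index: ", pdb_id)
  }
  cm <- character()
  for (i in rows) {
    ch <- index$chains[[i]]
    cm[ch] <- index$accession[i]
  }
  cm
}
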