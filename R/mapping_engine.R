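#' Anchor peptide around a cross-linked residue
#'
#' For an interior residue, the tripeptide with the cross-linked residue in
#' the middle; for the first or last residue of the sequence, a dipeptide with
#' the terminal position flagged so that alignment can require it to sit at
#' the corresponding chain terminus.
#'
#' @param sequence One-letter reference sequence.
#' @param pos 1-based position of the cross-linked residue.
#' @return List with `peptide`, `terminal` (`"none"`, `"N"` or `"C"`), and
#'   `center` (1-based index of the cross-linked residue within the peptide).
#' @export
make_anchor_peptide <- function(sequence, pos) {
  n <- nchar(sequence)
  if (pos < 1L || pos > n) {
    stop("position ", pos, " outside sequence of length ", n)
  }
  if (n < 2L) {
    stop("sequence too short for anchor peptide")
  }
  if (pos == 1L) {
    list(peptide = substr(sequence, 1L, 2L), terminal = "N", center = 1L)
  } else if (pos == n) {
    list(peptide = substr(sequence, n - 1L, n), terminal = "C", center = 2L)
  } else {
    list(peptide = substr(sequence, pos - 1L, pos + 1L), terminal = "none",
         center = 2L)
  }
}

# Offsets in nearest-first scan order: 0, +1, -1, ..., +w, -w.
window_offsets <- function(window) {
  if (window == 0L) return(0L)
  c(0L, as.vector(rbind(seq_len(window), -seq_len(window))))
}

#' Resolve a cross-linked residue on a structure chain
#'
#' Places the anchor peptide on the resolved sequence of one chain.  The
#' peptide is first matched at the assumed author residue number (mode
#' `direct`); on failure it is shifted through a +/- `window` residue window
#' around the assumed position, nearest offset first (mode `windowed`).
#' Anchor letters must match the consecutive letters of the resolved chain
#' sequence, so an unresolved neighbour breaks the match; terminal dipeptides
#' must in addition sit at the corresponding chain terminus.  If no offset
#' matches, or an offset admits more than one placement, the residue cannot
#' be measured unambiguously and the resolution fails (mode `failed`).
#'
#' @param anchor From [make_anchor_peptide()].
#' @param chain_seq From [chain_sequence()]: list with `seq` and `resno`.
#' @param assumed_pos Reference (UniProt) position of the cross-linked
#'   residue, taken as the assumed author number.
#' @param window Maximum |offset| scanned (default 5).
#' @return List with `mode` (`direct` / `windowed` / `terminal_dipeptide` /
#'   `failed`), `resno` (resolved author number or `NA`), `offset`
#'   (resolved - assumed, or `NA`).  `terminal_dipeptide` flags a dipeptide
#'   anchor resolved away from offset 0.
#' @export
resolve_anchor <- function(anchor, chain_seq, assumed_pos, window = 5L) {
  letters_ <- strsplit(chain_seq$seq, "")[[1]]
  resno <- chain_seq$resno
  n <- length(letters_)
  pep <- strsplit(anchor$peptide, "")[[1]]
  plen <- length(pep)
  failed <- list(mode = "failed", resno = NA_integer_, offset = NA_integer_)
  if (n < plen || anchor$peptide == "" || grepl("X", anchor$peptide,
                                                fixed = TRUE)) {
    return(failed)
  }
  match_at <- function(start) {
    start >= 1L && start + plen - 1L <= n &&
      all(letters_[start:(start + plen - 1L)] == pep)
  }
  for (off in window_offsets(as.integer(window))) {
    target <- assumed_pos + off
    idx <- which(resno == target)
    if (length(idx) == 0L) next
    if (length(idx) > 1L) {
      # duplicated author number: placement ambiguous at this offset
      return(failed)
    }
    start <- idx - anchor$center + 1L
    hit <- switch(anchor$terminal,
      none = match_at(start),
      N = idx == 1L && match_at(start),
      C = idx == n && match_at(start)
    )
    if (isTRUE(hit)) {
      mode <- if (off == 0L) {
        "direct"
      } else if (anchor$terminal == "none") {
        "windowed"
      } else {
        "terminal_dipeptide"
      }
      return(list(mode = mode, resno = resno[idx], offset = off))
    }
  }
  failed
}

#' Euclidean distance between two points
#'
#' @param p,q Numeric length-3 coordinate vectors (Angstrom).
#' @return Distance in Angstrom.
#' @export
euclidean_distance <- function(p, q) {
  sqrt(sum((p - q)^2))
}

#' Is a chain pair an asymmetric-unit artefact?
#'
#' Crystallographic asymmetric units may contain several biological copies of
#' a complex; by common deposition convention the copies are distinguished by
#' chain-label case or by the first character of two-character chain ids.
#' Distances measured between copies are artefacts and must be excluded.  A
#' pair is flagged when (a) exactly one of two single-character labels is
#' lowercase (e.g. `A` to `b` instead of `A` to `B`), or (b) both labels have
#' two characters and their first characters differ (e.g. `AA` to `BB`
#' instead of `AA` to `AB`).
#'
#' @param chain_a,chain_b Author chain identifiers.
#' @return Logical.  Symmetric in its arguments.  Labels containing
#'   non-alphabetic characters never trigger the rules (a warning is issued):
#'   the conventions are defined only on letter case.
#' @export
is_asymmetric_pair <- function(chain_a, chain_b) {
  stopifnot(nzchar(chain_a), nzchar(chain_b))
  if (!grepl("^[A-Za-z]+$", chain_a) || !grepl("^[A-Za-z]+$", chain_b)) {
    warning("non-alphabetic chain label(s): ", chain_a, ", ", chain_b,
            "; asymmetric-unit rules not applied")
    return(FALSE)
  }
  is_lower <- function(s) s == tolower(s) & s != toupper(s)
  if (nchar(chain_a) == 1L && nchar(chain_b) == 1L) {
    return(xor(is_lower(chain_a), is_lower(chain_b)))
  }
  if (nchar(chain_a) == 2L && nchar(chain_b) == 2L) {
    return(substr(chain_a, 1L, 1L) != substr(chain_b, 1L, 1L))
  }
  FALSE
}

#' Measure all C-alpha distances for one cross-link on one structure
#'
#' Resolves both cross-linked residues independently on every chain mapped to
#' their protein, then measures the C-alpha/C-alpha distance for every chain
#' combination.  Pairs matching the asymmetric-unit chain rules are flagged
#' `asymmetric`; for intramolecular links on multi-copy proteins, within-chain
#' measurements are the default and between-copy measurements are flagged
#' `cross_copy`.  Flagged measurements are retained in the record but excluded
#' from classification.
#'
#' @param link Single-row `xl_links` data frame (or equivalent list).
#' @param ca_table A `ca_table` whose `chain_map` covers the link's proteins.
#' @param window Alignment window passed to [resolve_anchor()].
#' @param sequences Optional `xl_sequences`; when supplied, anchor peptides
#'   are cut from the reference sequence (the normal case).  Without it the
#'   anchor is cut from the chain's own resolved sequence (only sensible for
#'   structures in reference numbering).
#' @return An `xl_measurements` data frame with columns `link_id`, `pdb_id`,
#'   `chain_a`, `res_a`, `chain_b`, `res_b`, `distance`, `asymmetric`,
#'   `cross_copy`, `offset_a`, `offset_b`, `mode_a`, `mode_b`.  Zero rows when
#'   an anchor fails everywhere.
#' @export
measure_crosslink <- function(link, ca_table, window = 5L, sequences = NULL) {
  stopifnot(inherits(ca_table, "ca_table"))
  cm <- attr(ca_table, "chain_map")
  chains_a <- names(cm)[cm == link$protein_a]
  chains_b <- names(cm)[cm == link$protein_b]
  empty <- empty_measurements()

  if (length(chains_a) == 0L || length(chains_b) == 0L) return(empty)

  resolve_on <- function(chain_id, protein, pos) {
    cs <- chain_sequence(ca_table, chain_id)
    seq_ref <- if (is.null(sequences)) cs$seq else sequences[[protein]]
    anchor <- make_anchor_peptide(seq_ref, pos)
    resolve_anchor(anchor, cs, pos, window = window)
  }
  res_a <- lapply(chains_a, resolve_on, protein = link$protein_a,
                  pos = link$pos_a)
  names(res_a) <- chains_a
  res_b <- lapply(chains_b, resolve_on, protein = link$protein_b,
                  pos = link$pos_b)
  names(res_b) <- chains_b

  ca_xyz <- function(chain_id, resno) {
    row <- ca_table[ca_table$chain == chain_id & ca_table$resno == resno, ]
    c(row$x[1], row$y[1], row$z[1])
  }
  rows <- list()
  for (ca in chains_a) {
    if (res_a[[ca]]$mode == "failed") next
    for (cb in chains_b) {
      if (res_b[[cb]]$mode == "failed") next
      intra <- link$linkage == "intra"
      if (intra && ca > cb) next           # count each unordered copy pair once
      if (intra && ca == cb &&
          res_a[[ca]]$resno == res_b[[cb]]$resno && link$pos_a == link$pos_b) {
        next
      }
      d <- euclidean_distance(ca_xyz(ca, res_a[[ca]]$resno),
                              ca_xyz(cb, res_b[[cb]]$resno))
      rows[[length(rows) + 1L]] <- data.frame(
        link_id = link$id, pdb_id = attr(ca_table, "pdb_id"),
        chain_a = ca, res_a = res_a[[ca]]$resno,
        chain_b = cb, res_b = res_b[[cb]]$resno,
        distance = d,
        asymmetric = if (ca == cb) FALSE else is_asymmetric_pair(ca, cb),
        cross_copy = intra && ca != cb,
        offset_a = res_a[[ca]]$offset, offset_b = res_b[[cb]]$offset,
        mode_a = res_a[[ca]]$mode, mode_b = res_b[[cb]]$mode,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  class(out) <- c("xl_measurements", "data.frame")
  out
}

empty_measurements <- function() {
  out <- data.frame(
    link_id = character(), pdb_id = character(),
    chain_a = character(), res_a = integer(),
    chain_b = character(), res_b = integer(),
    distance = numeric(), asymmetric = logical(), cross_copy = logical(),
    offset_a = integer(), offset_b = integer(),
    mode_a = character(), mode_b = character(),
    stringsAsFactors = FALSE
  )
  class(out) <- c("xl_measurements", "data.frame")
  out
}

#' Measure a whole cross-link table against a structure catalogue
#'
#' Runs [candidates_for_link()] and [measure_crosslink()] for every link; the
#' pipeline's workhorse.
#'
#' @param links An `xl_links` data frame.
#' @param index A filtered `xl_index`.
#' @param structures Named list of `ca_table` objects keyed by pdb id
#'   (candidates missing from the list are skipped).
#' @param sequences An `xl_sequences` object.
#' @param window Alignment window.
#' @return An `xl_measurements` data frame over all links and structures.
#' @export
measure_all <- function(links, index, structures, sequences, window = 5L) {
  stopifnot(inherits(links, "xl_links"))
  out <- list()
  for (i in seq_len(nrow(links))) {
    link <- links[i, ]
    for (pdb in candidates_for_link(link, index)) {
      tab <- structures[[pdb]]
      if (is.null(tab)) next
      out[[length(out) + 1L]] <-
        measure_crosslink(link, tab, window = window, sequences = sequences)
    }
  }
  if (length(out) == 0L) return(empty_measurements())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("xl_measurements", "data.frame")
  res
}

#' Write the measurement report
#'
#' @param measurements An `xl_measurements` data frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(measurements, path) {
  utils::write.table(as.data.frame(measurements), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
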