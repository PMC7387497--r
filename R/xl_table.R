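#' Read reference protein sequences from FASTA
#'
#' Loads the reference sequence database that defines the numbering frame for
#' all cross-link positions (typically UniProt sequences of the proteins in
#' the complex under study).
#'
#' @param fasta_path Path to a FASTA file of amino-acid sequences.
#'
#' @return An object of class `xl_sequences`: a named list of one-letter
#'   residue strings (names are accessions, i.e. the first whitespace-separated
#'   token of each header), with the remainder of each header kept in the
#'   `"description"` attribute.  Positions are 1-based.
#'
#' @details Lowercase residues are uppercased with a warning.  Characters
#'   outside the 20 standard amino-acid letters plus `X` are an error, as is a
#'   duplicated accession or an empty file.
#'
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">P0A7K2", "MKA"), fa)
#' seqs <- load_sequences(fa)
#' nchar(seqs$P0A7K2)
#' @export
load_sequences <- function(fasta_path) {
  if (!file.exists(fasta_path)) {
    stop("FASTA file not found: ", fasta_path)
  }
  lines <- readLines(fasta_path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) {
    stop("empty FASTA file (no records): ", fasta_path)
  }
  hdr_acc <- sub("^>(\\S*).*$", "\\1", lines[hdr])
  dup <- hdr_acc[duplicated(hdr_acc)]
  if (length(dup) > 0L) {
    stop("duplicate accession(s) in FASTA: ", paste(unique(dup), collapse = ", "))
  }
  fa <- bio3d::read.fasta(fasta_path)
  ali <- fa$ali
  if (is.null(dim(ali))) ali <- matrix(ali, nrow = 1L)
  raw <- apply(ali, 1L, function(row) paste(row[row != "-"], collapse = ""))
  acc <- fa$id
  if (any(raw != toupper(raw))) {
    low <- acc[raw != toupper(raw)]
    warning("lowercase residues uppercased for: ", paste(low, collapse = ", "))
    raw <- toupper(raw)
  }
  bad <- !grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"), raw)
  if (any(bad)) {
    stop("non-standard residue letters in: ", paste(acc[bad], collapse = ", "))
  }
  desc <- sub("^>\\S*\\s*", "", lines[hdr])
  seqs <- as.list(raw)
  names(seqs) <- acc
  attr(seqs, "description") <- stats::setNames(desc, acc)
  class(seqs) <- "xl_sequences"
  seqs
}

# 20 standard residues + X for unmapped non-standard residues
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X"
)

#' Parse a cross-link table
#'
#' Reads a tab-separated cross-link table (one row per residue pair) and
#' validates each row against the loaded reference sequences.  Rows whose
#' accession is unknown or whose position exceeds the sequence length are
#' rejected, not fatal; the rejected rows are attached as a report.
#'
#' @param table_path TSV with header
#'   `id  protein_a  pos_a  protein_b  pos_b  linkage`; `linkage`
#'   (`intra`/`inter`) may be omitted and is then derived from protein
#'   identity.
#' @param sequences An `xl_sequences` object from [load_sequences()].
#'
#' @return An `xl_links` data frame with columns `id`, `protein_a`, `pos_a`,
#'   `site_a`, `protein_b`, `pos_b`, `site_b`, `linkage`, `multiplicity`.
#'   Each pair is stored in canonical order (lexicographic on
#'   `(accession, pos)`), so a swapped duplicate row denotes the same link.
#'   Rejected rows are in `attr(, "rejects")` with a `reason` column.
#' @seealso [collapse_redundant()], [validate_chemistry()]
#' @export
parse_crosslinks <- function(table_path, sequences) {
  stopifnot(inherits(sequences, "xl_sequences"))
  tab <- utils::read.delim(table_path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("id", "protein_a", "pos_a", "protein_b", "pos_b")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    stop("cross-link table missing column(s): ", paste(miss, collapse = ", "))
  }
  tab$pos_a <- suppressWarnings(as.integer(tab$pos_a))
  tab$pos_b <- suppressWarnings(as.integer(tab$pos_b))

  reason <- character(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    if (is.na(r$pos_a) || is.na(r$pos_b) || r$pos_a < 1L || r$pos_b < 1L) {
      reason[i] <- "position not a positive integer"
    } else if (!r$protein_a %in% names(sequences)) {
      reason[i] <- paste0("unknown accession: ", r$protein_a)
    } else if (!r$protein_b %in% names(sequences)) {
      reason[i] <- paste0("unknown accession: ", r$protein_b)
    } else if (r$pos_a > nchar(sequences[[r$protein_a]])) {
      reason[i] <- paste0("pos_a beyond sequence length of ", r$protein_a)
    } else if (r$pos_b > nchar(sequences[[r$protein_b]])) {
      reason[i] <- paste0("pos_b beyond sequence length of ", r$protein_b)
    }
  }
  rejects <- cbind(tab[reason != "", need, drop = FALSE],
                   reason = reason[reason != ""])
  ok <- tab[reason == "", , drop = FALSE]

  links <- data.frame(
    id = ok$id,
    protein_a = ok$protein_a, pos_a = ok$pos_a,
    protein_b = ok$protein_b, pos_b = ok$pos_b,
    stringsAsFactors = FALSE
  )
  # canonical order: lexicographic on (accession, pos)
  if (nrow(links) > 0L) {
    swap <- links$protein_a > links$protein_b |
      (links$protein_a == links$protein_b & links$pos_a > links$pos_b)
    links[swap, c("protein_a", "pos_a", "protein_b", "pos_b")] <-
      links[swap, c("protein_b", "pos_b", "protein_a", "pos_a")]
  }
  links$site_a <- vapply(seq_len(nrow(links)), function(i) {
    substr(sequences[[links$protein_a[i]]], links$pos_a[i], links$pos_a[i])
  }, character(1))
  links$site_b <- vapply(seq_len(nrow(links)), function(i) {
    substr(sequences[[links$protein_b[i]]], links$pos_b[i], links$pos_b[i])
  }, character(1))
  links$linkage <- ifelse(links$protein_a == links$protein_b, "intra", "inter")
  if ("linkage" %in% names(tab) && nrow(ok) > 0L) {
    given <- tolower(ok$linkage)
    bad <- !is.na(given) & given != "" & given != links$linkage
    if (any(bad)) {
      warning(sum(bad), " row(s) carried a linkage flag inconsistent with ",
              "protein identity; derived flag used")
    }
  }
  links$multiplicity <- 1L
  links <- links[, c("id", "protein_a", "pos_a", "site_a",
                     "protein_b", "pos_b", "site_b", "linkage",
                     "multiplicity")]
  attr(links, "rejects") <- rejects
  class(links) <- c("xl_links", "data.frame")
  links
}

# DSAU site specificity: one side Lys/Ser/Thr/Tyr or protein N-terminus,
# the other side Lys or N-terminus.
SITE1_RESIDUES <- c("K", "S", "T", "Y")
SITE2_RESIDUES <- "K"

#' Check cross-link sites against cross-linker chemistry
#'
#' Advisory check that each linked residue is plausible for an amine-reactive
#' cross-linker with Lys/Ser/Thr/Tyr/N-terminus specificity on one reactive
#' site and Lys/N-terminus on the other (the DSAU chemistry).  Both ways of
#' assigning the two residues to the two sites are tried; a warning is issued
#' only when neither ordering is allowed.  Position 1 always qualifies as an
#' N-terminus site.
#'
#' @param links An `xl_links` data frame.
#' @param sequences The matching `xl_sequences`.
#' @return `links` with an added logical column `chem_ok`; a single warning
#'   lists the offending link ids, but no row is rejected.
#' @export
validate_chemistry <- function(links, sequences) {
  stopifnot(inherits(links, "xl_links"))
  side_ok <- function(res, pos, allowed) pos == 1L | res %in% allowed
  ok1 <- side_ok(links$site_a, links$pos_a, SITE1_RESIDUES) &
    side_ok(links$site_b, links$pos_b, SITE2_RESIDUES)
  ok2 <- side_ok(links$site_b, links$pos_b, SITE1_RESIDUES) &
    side_ok(links$site_a, links$pos_a, SITE2_RESIDUES)
  links$chem_ok <- ok1 | ok2
  if (any(!links$chem_ok)) {
    warning("cross-link(s) outside cross-linker site specificity: ",
            paste(links$id[!links$chem_ok], collapse = ", "))
  }
  links
}

#' Collapse redundant cross-links
#'
#' Merges exact duplicates of the canonical `(protein, pos)`--`(protein, pos)`
#' pair into one non-redundant link, summing evidence multiplicities.  The
#' first id seen for a pair is retained.  Idempotent and independent of row
#' order up to the retained id.
#'
#' @param links An `xl_links` data frame (rows already in canonical pair
#'   order, as produced by [parse_crosslinks()]).
#' @return An `xl_links` data frame of non-redundant links.
#' @export
collapse_redundant <- function(links) {
  stopifnot(inherits(links, "xl_links"))
  if (nrow(links) == 0L) return(links)
  key <- paste(links$protein_a, links$pos_a, links$protein_b, links$pos_b,
               sep = "\r")
  mult <- tapply(links$multiplicity, key, sum)
  first <- !duplicated(key)
  out <- links[first, , drop = FALSE]
  out$multiplicity <- as.integer(mult[key[first]])
  rownames(out) <- NULL
  class(out) <- c("xl_links", "data.frame")
  out
}

#' Write a cross-link table
#'
#' Serializes the canonical columns of an `xl_links` object as TSV; the
#' written file parses back to the identical canonical table.
#'
#' @param links An `xl_links` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_crosslinks <- function(links, path) {
  stopifnot(inherits(links, "xl_links"))
  out <- links[, c("id", "protein_a", "pos_a", "protein_b", "pos_b", "linkage")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write sequences as FASTA
#'
#' @param sequences An `xl_sequences` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(sequences, path) {
  stopifnot(inherits(sequences, "xl_sequences"))
  desc <- attr(sequences, "description")
  lines <- unlist(lapply(names(sequences), function(acc) {
    d <- if (!is.null(desc) && !is.na(desc[acc]) && nzchar(desc[acc])) {
      paste0(" ", desc[acc])
    } else {
      ""
    }
    c(paste0(">", acc, d), sequences[[acc]])
  }))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.xl_links <- function(x, ...) {
  cat(sprintf("Cross-link table: %d link(s) (%d intra, %d inter)\n",
              nrow(x), sum(x$linkage == "intra"), sum(x$linkage == "inter")))
  rej <- attr(x, "rejects")
  if (!is.null(rej) && nrow(rej) > 0L) {
    cat(sprintf("  %d row(s) rejected at parse time\n", nrow(rej)))
  }
  print.data.frame(x, ...)
  invisible(x)
}
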