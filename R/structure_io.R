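# 3-letter -> 1-letter mapping; unmapped residues become "X" and are excluded
# from alignment anchors.
AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  MSE = "M", SEC = "U", PYL = "O"
)

aa3to1 <- function(res3) {
  out <- AA3TO1[res3]
  out[is.na(out)] <- "X"
  unname(out)
}

read_cif_atoms <- function(mmcif_path) {
  if (!file.exists(mmcif_path)) {
    stop("cannot read coordinate file: ", mmcif_path)
  }
  cif <- suppressWarnings(bio3d::read.cif(mmcif_path, rm.alt = FALSE))
  cif$atom
}

# Altloc policy: within each (chain, resno, atom name) group keep the
# highest-occupancy alternate location, ties broken alphabetically.
apply_altloc_policy <- function(atoms) {
  if (nrow(atoms) == 0L) return(atoms)
  alt <- atoms$alt
  alt[is.na(alt)] <- ""
  grp <- paste(atoms$chain, atoms$resno, atoms$elety, sep = "\r")
  occ <- atoms$o
  occ[is.na(occ)] <- 1
  ord <- order(grp, -occ, alt)
  atoms <- atoms[ord, , drop = FALSE]
  atoms[!duplicated(grp[ord]), , drop = FALSE]
}

#' Reduce a coordinate file to a C-alpha table
#'
#' Reads a structure in mmCIF format and keeps residue type, author residue
#' number, author chain identifier and the coordinates of every C-alpha atom.
#' This simplified table is the working representation for all distance
#' mapping.
#'
#' @param mmcif_path Path to an mmCIF coordinate file.
#' @param chain_map Named character vector mapping chain id to protein
#'   accession (e.g. `c(A = "P0A7K2")`).  Chains absent from the map are kept
#'   in the table but cannot be targeted by cross-links.
#' @param pdb_id Identifier recorded on the table (defaults to the file base
#'   name).
#' @param method One of `"xray"`, `"em"`, `"nmr"`.
#' @param resolution Resolution in Angstrom, or `NA` (NMR).
#'
#' @return A `ca_table`: data frame with columns `chain`, `resno`, `resid`
#'   (one-letter code), `x`, `y`, `z`, sorted by `(chain, resno)`, plus
#'   attributes `pdb_id`, `method`, `resolution`, `chain_map`.
#'
#' @details Only model 1 of multi-model (NMR-style) files is used.  Alternate
#'   locations keep the highest-occupancy copy (ties alphabetically).
#'   Residues carrying an insertion code are skipped with a warning; residues
#'   lacking a C-alpha atom are skipped silently (they are simply unresolved
#'   at the C-alpha level).  A file with no C-alpha atoms at all is an error.
#' @export
load_ca_table <- function(mmcif_path, chain_map = character(),
                          pdb_id = NULL, method = "xray", resolution = NA_real_) {
  atoms <- read_cif_atoms(mmcif_path)
  # element check keeps calcium ions (atom name CA, element Ca) out
  atoms <- atoms[atoms$elety == "CA" & atoms$elesy == "C", , drop = FALSE]
  if (nrow(atoms) == 0L) {
    stop("no C-alpha atoms in ", mmcif_path)
  }
  ins <- !is.na(atoms$insert) & atoms$insert != ""
  if (any(ins)) {
    warning(sum(ins), " residue(s) with insertion codes skipped in ",
            basename(mmcif_path))
    atoms <- atoms[!ins, , drop = FALSE]
  }
  atoms <- apply_altloc_policy(atoms)
  tab <- data.frame(
    chain = atoms$chain,
    resno = as.integer(atoms$resno),
    resid = aa3to1(atoms$resid),
    x = atoms$x, y = atoms$y, z = atoms$z,
    stringsAsFactors = FALSE
  )
  if (is.null(pdb_id)) {
    pdb_id <- sub("\\.(cif|mmcif)$", "", basename(mmcif_path))
  }
  new_ca_table(tab, pdb_id = pdb_id, method = method,
               resolution = resolution, chain_map = chain_map)
}

new_ca_table <- function(tab, pdb_id, method = "xray",
                         resolution = NA_real_, chain_map = character()) {
  stopifnot(all(c("chain", "resno", "resid", "x", "y", "z") %in% names(tab)))
  if (anyNA(tab$x) || anyNA(tab$y) || anyNA(tab$z) ||
      any(!is.finite(tab$x + tab$y + tab$z))) {
    stop("non-finite coordinates in C-alpha table")
  }
  tab <- tab[order(tab$chain, tab$resno), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab,
            pdb_id = pdb_id, method = method, resolution = resolution,
            chain_map = chain_map,
            class = c("ca_table", "data.frame"))
}

#' @export
print.ca_table <- function(x, ...) {
  res <- attr(x, "resolution")
  cat(sprintf("C-alpha table %s [%s%s]: %d residue(s), %d chain(s)\n",
              attr(x, "pdb_id"), attr(x, "method"),
              if (is.na(res)) "" else sprintf(", %.2f A", res),
              nrow(x), length(unique(x$chain))))
  invisible(x)
}

#' Extract the resolved sequence of one chain
#'
#' Returns the one-letter sequence of a chain in author-number order together
#' with the author number of every letter.  Numbering gaps (unresolved loops)
#' are not padded: consecutive letters of the string may carry non-consecutive
#' numbers.
#'
#' @param table A `ca_table`.
#' @param chain_id Chain identifier.
#' @return A list with `seq` (one-letter string), `resno` (integer vector,
#'   one per letter).
#' @export
chain_sequence <- function(table, chain_id) {
  stopifnot(inherits(table, "ca_table"))
  sel <- table$chain == chain_id
  if (!any(sel)) {
    stop("chain not present in structure: ", chain_id)
  }
  sub <- table[sel, , drop = FALSE]
  list(seq = paste(sub$resid, collapse = ""), resno = sub$resno)
}

#' Load heavy atoms from a coordinate file
#'
#' All non-hydrogen atoms of model 1, for occupancy-grid construction.
#' Waters are excluded by default.
#'
#' @param mmcif_path Path to an mmCIF file.
#' @param keep_waters Keep water molecules? Default `FALSE`.
#' @return Data frame with columns `chain`, `resno`, `element`, `x`, `y`, `z`.
#' @export
load_heavy_atoms <- function(mmcif_path, keep_waters = FALSE) {
  atoms <- read_cif_atoms(mmcif_path)
  atoms <- atoms[!(atoms$elesy %in% c("H", "D")), , drop = FALSE]
  if (!keep_waters) {
    atoms <- atoms[!(atoms$resid %in% c("HOH", "DOD", "WAT")), , drop = FALSE]
  }
  atoms <- apply_altloc_policy(atoms)
  data.frame(
    chain = atoms$chain,
    resno = as.integer(atoms$resno),
    element = atoms$elesy,
    x = atoms$x, y = atoms$y, z = atoms$z,
    stringsAsFactors = FALSE
  )
}

#' Write / read the simplified C-alpha table
#'
#' TSV serialization of a `ca_table` (`pdb_id chain resno resid x y z` plus a
#' metadata comment line); `read_ca_table()` restores an identical object.
#'
#' @param table A `ca_table`.
#' @param path Output (or input) path.
#' @return `write_ca_table()`: `path` invisibly; `read_ca_table()`: a
#'   `ca_table`.
#' @export
write_ca_table <- function(table, path) {
  stopifnot(inherits(table, "ca_table"))
  cm <- attr(table, "chain_map")
  meta <- sprintf("# pdb_id=%s method=%s resolution=%s chain_map=%s",
                  attr(table, "pdb_id"), attr(table, "method"),
                  attr(table, "resolution"),
                  paste(sprintf("%s:%s", names(cm), cm), collapse = ","))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  out <- cbind(pdb_id = attr(table, "pdb_id"), as.data.frame(table))
  utils::write.table(format(out, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ca_table
#' @export
read_ca_table <- function(path) {
  meta <- readLines(path, n = 1L)
  kv <- regmatches(meta, gregexpr("\\S+=\\S*", meta))[[1]]
  vals <- sub("^[^=]+=", "", kv)
  names(vals) <- sub("=.*$", "", kv)
  cm <- character()
  if (nzchar(vals[["chain_map"]])) {
    parts <- strsplit(strsplit(vals[["chain_map"]], ",")[[1]], ":")
    cm <- vapply(parts, `[`, character(1), 2L)
    names(cm) <- vapply(parts, `[`, character(1), 1L)
  }
  tab <- utils::read.delim(path, skip = 1L, stringsAsFactors = FALSE,
                           colClasses = c(pdb_id = "character",
                                          chain = "character",
                                          resid = "character"))
  new_ca_table(tab[, c("chain", "resno", "resid", "x", "y", "z")],
               pdb_id = vals[["pdb_id"]], method = vals[["method"]],
               resolution = suppressWarnings(as.numeric(vals[["resolution"]])),
               chain_map = cm)
}
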