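# One-letter -> three-letter codes for fixture writing (X -> UNK).
AA1TO3 <- local({
  std <- AA3TO1[1:20]
  out <- stats::setNames(names(std), std)
  out["X"] <- "UNK"
  out
})

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

random_unique_tripeptide_seq <- function(n, max_tries = 200L) {
  letters20 <- AA_ALPHABET[AA_ALPHABET != "X"]
  for (k in seq_len(max_tries)) {
    s <- sample(letters20, n, replace = TRUE)
    tri <- paste0(s[seq_len(n - 2L)], s[seq_len(n - 2L) + 1L],
                  s[seq_len(n - 2L) + 2L])
    if (!anyDuplicated(tri)) return(paste(s, collapse = ""))
  }
  stop("could not draw a tripeptide-unique sequence of length ", n)
}

#' Ideal alpha-helical C-alpha trace
#'
#' Generates a chain of C-alpha positions on an ideal alpha helix (rise 1.5
#' Angstrom per residue, 100 degrees turn per residue, helix radius 2.3
#' Angstrom), optionally rigidly transformed.  Consecutive C-alpha atoms come
#' out ~3.8 Angstrom apart, the canonical spacing.
#'
#' @param length Number of residues (>= 3).
#' @param chain_id Chain label for the records.
#' @param transform Optional rigid motion: list with `R` (3x3 rotation) and
#'   `t` (length-3 translation).
#' @param sequence Optional one-letter string of `length` residues; default
#'   all `"A"` (assembly assigns real sequences).
#' @return Data frame `chain`, `resno` (1..length), `resid`, `x`, `y`, `z`.
#' @export
make_helix_chain <- function(length, chain_id, transform = NULL,
                             sequence = NULL) {
  if (length < 3L) stop("helix chain needs length >= 3")
  i <- seq_len(length)
  theta <- (i - 1) * 100 * pi / 180
  xyz <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * (i - 1))
  if (!is.null(transform)) {
    xyz <- xyz %*% t(transform$R)
    xyz <- sweep(xyz, 2L, transform$t, "+")
  }
  resid <- if (is.null(sequence)) {
    rep("A", length)
  } else {
    stopifnot(nchar(sequence) == length)
    strsplit(sequence, "")[[1]]
  }
  data.frame(chain = chain_id, resno = i, resid = resid,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

#' Rigid transform helper
#'
#' @param angle_deg Rotation angle about `axis` (degrees).
#' @param axis Rotation axis (length 3).
#' @param translation Translation vector (Angstrom).
#' @return List with `R` and `t`, for [make_helix_chain()].
#' @export
rigid_transform <- function(angle_deg = 0, axis = c(0, 0, 1),
                            translation = c(0, 0, 0)) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  list(R = R, t = translation)
}

#' Assemble a toy multi-chain complex
#'
#' Builds a C-alpha-level complex of helical chains with known geometry plus
#' the matching reference sequences.  Each accession gets one random
#' sequence (shared by all of its chains), drawn reproducibly from `seed`.
#'
#' @param chains Data frame with columns `accession`, `chain_id`, `length`
#'   and translation columns `tx`, `ty`, `tz` (and optionally `rotz`,
#'   degrees about the z axis).  Chain ids must be unique.
#' @param seed Integer seed; the construction is deterministic given
#'   `chains` and `seed`.
#' @param pdb_id Identifier for the resulting table (default `"SYN1"`).
#' @param method,resolution Metadata for the table (defaults `"xray"`, 2.0).
#' @return List with `ca_table` (a `ca_table` whose `chain_map` maps every
#'   chain to its accession) and `sequences` (an `xl_sequences`).
#' @export
assemble_complex <- function(chains, seed = 1L, pdb_id = "SYN1",
                             method = "xray", resolution = 2.0) {
  stopifnot(all(c("accession", "chain_id", "length", "tx", "ty", "tz") %in%
                  names(chains)))
  if (anyDuplicated(chains$chain_id)) {
    stop("overlapping chain labels: ",
         paste(chains$chain_id[duplicated(chains$chain_id)], collapse = ", "))
  }
  acc <- unique(chains$accession)
  len_by_acc <- vapply(acc, function(a) {
    ls <- unique(chains$length[chains$accession == a])
    if (length(ls) > 1L) stop("inconsistent lengths for accession ", a)
    as.integer(ls)
  }, integer(1))
  # sequences are drawn with all tripeptides unique, so anchor placement on
  # the toy chains is unambiguous by construction (real proteins show little
  # local repetition; the generator makes that property exact)
  seqs <- with_seed(seed, {
    lapply(len_by_acc, function(n) random_unique_tripeptide_seq(n))
  })
  names(seqs) <- acc
  recs <- lapply(seq_len(nrow(chains)), function(i) {
    ch <- chains[i, ]
    rotz <- if ("rotz" %in% names(chains)) ch$rotz else 0
    tr <- rigid_transform(rotz, c(0, 0, 1), c(ch$tx, ch$ty, ch$tz))
    make_helix_chain(ch$length, ch$chain_id, tr,
                     sequence = seqs[[ch$accession]])
  })
  tab <- do.call(rbind, recs)
  cm <- stats::setNames(chains$accession, chains$chain_id)
  attr(seqs, "description") <- stats::setNames(rep("synthetic", length(acc)),
                                               acc)
  class(seqs) <- "xl_sequences"
  list(ca_table = new_ca_table(tab, pdb_id = pdb_id, method = method,
                               resolution = resolution, chain_map = cm),
       sequences = seqs)
}

#' Duplicate a complex as a second asymmetric-unit copy
#'
#' Appends a rigidly displaced copy of every chain, relabeled by one of the
#' deposition conventions the asymmetric-unit chain rules recognise:
#' `"lowercase"` (copy of chain `A` is `a`) or `"two_char"` (originals become
#' `A<chain>`, copies `B<chain>`).
#'
#' @param table A single-copy `ca_table`.
#' @param convention `"lowercase"` or `"two_char"`.
#' @param displacement Rigid displacement of the copy (default 100 Angstrom
#'   along x, so cross-copy distances are unambiguously artefactual).
#' @return A `ca_table` with both copies; the chain map covers both.
#' @export
duplicate_asymmetric <- function(table,
                                 convention = c("lowercase", "two_char"),
                                 displacement = c(100, 0, 0)) {
  stopifnot(inherits(table, "ca_table"))
  convention <- match.arg(convention)
  cm <- attr(table, "chain_map")
  orig <- as.data.frame(table)
  copy <- orig
  copy$x <- copy$x + displacement[1]
  copy$y <- copy$y + displacement[2]
  copy$z <- copy$z + displacement[3]
  if (convention == "lowercase") {
    if (any(orig$chain != toupper(orig$chain))) {
      stop("lowercase convention needs uppercase single-copy chain labels")
    }
    copy$chain <- tolower(copy$chain)
    cm2 <- c(cm, stats::setNames(cm, tolower(names(cm))))
  } else {
    orig$chain <- paste0("A", orig$chain)
    copy$chain <- paste0("B", copy$chain)
    cm2 <- c(stats::setNames(cm, paste0("A", names(cm))),
             stats::setNames(cm, paste0("B", names(cm))))
  }
  new_ca_table(rbind(orig, copy), pdb_id = attr(table, "pdb_id"),
               method = attr(table, "method"),
               resolution = attr(table, "resolution"), chain_map = cm2)
}

#' Sample cross-links at known distances
#'
#' Draws residue pairs from a complex so that their true C-alpha distances
#' fall inside a requested band, and records the ground truth (pair, chains,
#' true distance).  Reproducible under `seed`.
#'
#' @param table A `ca_table` (typically the single-copy complex, in
#'   reference numbering).
#' @param n Number of links.
#' @param distance_band Length-2 numeric, inclusive band in Angstrom.
#' @param seed Integer seed.
#' @param linkage `"intra"`, `"inter"` or `"both"` (default).
#' @param id_offset Links are labelled `#<id_offset+1>` onwards.
#' @return List with `links` (an `xl_links`) and `truth` (data frame
#'   `id`, `chain_a`, `res_a`, `chain_b`, `res_b`, `true_distance`).
#' @export
sample_crosslinks <- function(table, n, distance_band, seed = 1L,
                              linkage = c("both", "intra", "inter"),
                              id_offset = 0L) {
  stopifnot(inherits(table, "ca_table"), n >= 1L,
            length(distance_band) == 2L)
  linkage <- match.arg(linkage)
  cm <- attr(table, "chain_map")
  tab <- as.data.frame(table)
  # achievable range for the error message and the feasibility check
  xyz <- as.matrix(tab[, c("x", "y", "z")])
  dall <- stats::dist(xyz)
  if (distance_band[1] > max(dall) || distance_band[2] < min(dall[dall > 0])) {
    stop(sprintf("distance band [%g, %g] unsatisfiable; achievable range is [%.2f, %.2f]",
                 distance_band[1], distance_band[2],
                 min(dall[dall > 0]), max(dall)))
  }
  pick <- function() {
    i <- sample.int(nrow(tab), 1L)
    j <- sample.int(nrow(tab), 1L)
    c(i, j)
  }
  out <- list(); truth <- list()
  with_seed(seed, {
    tries <- 0L
    while (length(out) < n) {
      tries <- tries + 1L
      if (tries > 20000L * n) {
        stop(sprintf("distance band [%g, %g] unsatisfiable under linkage '%s'; achievable range is [%.2f, %.2f]",
                     distance_band[1], distance_band[2], linkage,
                     min(dall[dall > 0]), max(dall)))
      }
      ij <- pick()
      if (ij[1] == ij[2]) next
      a <- tab[ij[1], ]; b <- tab[ij[2], ]
      prot_a <- cm[[a$chain]]; prot_b <- cm[[b$chain]]
      same_prot <- identical(prot_a, prot_b)
      if (linkage == "intra" && !(same_prot && a$chain == b$chain)) next
      if (linkage == "inter" && same_prot) next
      if (linkage == "both" && same_prot && a$chain != b$chain) next
      if (same_prot && a$resno == b$resno) next
      d <- euclidean_distance(c(a$x, a$y, a$z), c(b$x, b$y, b$z))
      if (d < distance_band[1] || d > distance_band[2]) next
      out[[length(out) + 1L]] <- data.frame(
        id = sprintf("#%d", id_offset + length(out) + 1L),
        protein_a = prot_a, pos_a = a$resno, site_a = a$resid,
        protein_b = prot_b, pos_b = b$resno, site_b = b$resid,
        linkage = if (same_prot) "intra" else "inter",
        multiplicity = 1L, stringsAsFactors = FALSE
      )
      truth[[length(truth) + 1L]] <- data.frame(
        id = out[[length(out)]]$id,
        chain_a = a$chain, res_a = a$resno,
        chain_b = b$chain, res_b = b$resno,
        true_distance = d, stringsAsFactors = FALSE
      )
    }
  })
  links <- do.call(rbind, out)
  # canonical pair order
  swap <- links$protein_a > links$protein_b |
    (links$protein_a == links$protein_b & links$pos_a > links$pos_b)
  links[swap, c("protein_a", "pos_a", "site_a", "protein_b", "pos_b",
                "site_b")] <-
    links[swap, c("protein_b", "pos_b", "site_b", "protein_a", "pos_a",
                  "site_a")]
  class(links) <- c("xl_links", "data.frame")
  list(links = links, truth = do.call(rbind, truth))
}

#' Perturb the numbering of one chain
#'
#' Emulates the annotation discrepancies seen in deposited structures:
#' constant numbering shifts, a cleaved start methionine, or an unresolved
#' segment.
#'
#' @param table A `ca_table`.
#' @param chain Chain to perturb.
#' @param mode `"shift"`, `"drop_start_met"` or `"drop_segment"`.
#' @param s Shift amount (mode `"shift"`).
#' @param from,to Author-number range to delete (mode `"drop_segment"`).
#' @param policy For `"drop_start_met"`: `"renumber"` (remaining residues
#'   renumbered from 1, i.e. the whole chain shifts by -1, the common
#'   deposition style) or `"keep"` (numbering retains the gap at 1).
#' @return List with `table` (perturbed `ca_table`) and `offset` (the
#'   resolved-minus-assumed offset the aligner should recover for interior
#'   residues of this chain: `s`, `-1`, or `0`).
#' @export
perturb_numbering <- function(table, chain,
                              mode = c("shift", "drop_start_met",
                                       "drop_segment"),
                              s = 0L, from = NULL, to = NULL,
                              policy = c("renumber", "keep")) {
  stopifnot(inherits(table, "ca_table"))
  mode <- match.arg(mode)
  policy <- match.arg(policy)
  tab <- as.data.frame(table)
  sel <- tab$chain == chain
  if (!any(sel)) stop("chain not present: ", chain)
  offset <- 0L
  if (mode == "shift") {
    tab$resno[sel] <- tab$resno[sel] + as.integer(s)
    offset <- as.integer(s)
  } else if (mode == "drop_start_met") {
    first <- min(tab$resno[sel])
    drop <- sel & tab$resno == first
    tab <- tab[!drop, , drop = FALSE]
    sel <- tab$chain == chain
    if (policy == "renumber") {
      tab$resno[sel] <- tab$resno[sel] - 1L
      offset <- -1L
    }
  } else {
    stopifnot(!is.null(from), !is.null(to))
    if (from < min(tab$resno[sel]) || to > max(tab$resno[sel])) {
      stop("segment [", from, ", ", to, "] outside chain ", chain)
    }
    tab <- tab[!(sel & tab$resno >= from & tab$resno <= to), , drop = FALSE]
  }
  list(table = new_ca_table(tab, pdb_id = attr(table, "pdb_id"),
                            method = attr(table, "method"),
                            resolution = attr(table, "resolution"),
                            chain_map = attr(table, "chain_map")),
       offset = offset)
}

#' Write a minimal mmCIF fixture
#'
#' Serializes a `ca_table` (and optionally extra heavy atoms) as a minimal
#' `atom_site` loop readable by [load_ca_table()] / [load_heavy_atoms()].
#' Coordinates are written with 4 decimals, so a round trip preserves them
#' well beyond 3-decimal precision.
#'
#' @param table A `ca_table`.
#' @param path Output path.
#' @param heavy_atoms Optional data frame of additional atoms with columns
#'   `chain`, `resno`, `resname` (3-letter), `atom` (name), `element`, `x`,
#'   `y`, `z` (e.g. obstacle walls for accessibility fixtures, or waters).
#' @return `path`, invisibly.
#' @export
write_mmcif_fixture <- function(table, path, heavy_atoms = NULL) {
  stopifnot(inherits(table, "ca_table"))
  rows <- data.frame(
    chain = table$chain, resno = table$resno,
    resname = unname(AA1TO3[table$resid]),
    atom = "CA", element = "C",
    x = table$x, y = table$y, z = table$z, stringsAsFactors = FALSE
  )
  rows$resname[is.na(rows$resname)] <- "UNK"
  if (!is.null(heavy_atoms)) {
    rows <- rbind(rows, heavy_atoms[, c("chain", "resno", "resname", "atom",
                                        "element", "x", "y", "z")])
  }
  n <- nrow(rows)
  lines <- c(
    paste0("data_", attr(table, "pdb_id")),
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    sprintf("%s %d %s %s . %s %s 1 %d ? %.4f %.4f %.4f 1.00 0.00 %d %s %s %s 1",
            ifelse(rows$resname %in% names(AA3TO1), "ATOM", "HETATM"),
            seq_len(n), rows$element, rows$atom, rows$resname, rows$chain,
            rows$resno, rows$x, rows$y, rows$z, rows$resno, rows$resname,
            rows$chain, rows$atom),
    "#"
  )
  writeLines(lines, path)
  invisible(path)
}
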