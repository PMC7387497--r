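# Staged restraint means in Angstrom: ladder descends 45 -> 25 in steps of 5.
LADDER_MEANS <- c(45, 40, 35, 30, 25)

#' Staged Gaussian restraint ladder for a violated cross-link
#'
#' A violated cross-link is converted into a sequence of Gaussian distance
#' restraints whose mean is stepped down from 45 to 25 Angstrom in 5 Angstrom
#' steps (sigma 0.1 throughout), for use by a remodeling engine.  Lowering
#' the target gradually maintains the structural integrity of flexible
#' regions.  The full five-stage ladder is always emitted; the consumer stops
#' early once the remodeled distance drops below the threshold
#' (`stop_when = "remodeled distance <= threshold"` annotation).  A link
#' whose current distance already satisfies the threshold gets an empty
#' ladder.
#'
#' @param link Single-row `xl_links` data frame (or list with `id`).
#' @param residue_pair List with `chain_a`, `res_a`, `chain_b`, `res_b`: the
#'   resolved residue pair on the working structure (e.g. a row of
#'   [measure_crosslink()] output).  `NULL` entries mean the pair could not
#'   be resolved and are an error.
#' @param current_distance Measured distance on the working structure
#'   (Angstrom).
#' @param threshold Classification threshold for this link (Angstrom).
#' @param sigma Restraint standard deviation; recorded verbatim (0.1, in the
#'   units of the consuming modeling program, conventionally Angstrom).
#' @return An `xl_restraints` data frame: `link_id`, `chain_a`, `res_a`,
#'   `chain_b`, `res_b`, `stage_index`, `mean`, `sigma`, `form`
#'   (`"gaussian"`), with the early-stop contract in
#'   `attr(, "stop_when")`.
#' @export
build_ladder <- function(link, residue_pair, current_distance, threshold,
                         sigma = 0.1) {
  if (is.null(residue_pair) || anyNA(c(residue_pair$res_a,
                                       residue_pair$res_b))) {
    stop("cross-link ", link$id,
         ": residue pair not resolvable on the working structure")
  }
  means <- if (current_distance <= threshold) numeric(0) else LADDER_MEANS
  out <- data.frame(
    link_id = rep(link$id, length(means)),
    chain_a = rep(residue_pair$chain_a, length(means)),
    res_a = rep(residue_pair$res_a, length(means)),
    chain_b = rep(residue_pair$chain_b, length(means)),
    res_b = rep(residue_pair$res_b, length(means)),
    stage_index = seq_along(means),
    mean = means,
    sigma = rep(sigma, length(means)),
    form = rep("gaussian", length(means)),
    stringsAsFactors = FALSE
  )
  attr(out, "stop_when") <- "remodeled distance <= threshold"
  class(out) <- c("xl_restraints", "data.frame")
  out
}

#' Mobile/static environment for single-protein remodeling
#'
#' Remodeling moves a single target protein while the rest of the assembly is
#' kept static; to bound the computation, the static set contains only the
#' chains within `cutoff` of the target plus the cross-linked interaction
#' partners of the target.  Proximity is measured C-alpha to C-alpha (the
#' pipeline's structure model is C-alpha-level); rRNA or other non-protein
#' chains present in the table are treated identically.
#'
#' @param ca_table A `ca_table` whose `chain_map` contains the target.
#' @param target_protein Accession of the mobile protein.
#' @param cutoff Proximity cutoff in Angstrom (default 10).
#' @param links Optional `xl_links`; proteins cross-linked to the target are
#'   added to the static set regardless of distance.
#' @return An `environment_spec`: data frame `chain`, `role`
#'   (`mobile`/`static`), `reason` (`target`/`proximity`/`partner`).  Chains
#'   neither near nor linked are omitted.
#' @export
select_environment <- function(ca_table, target_protein, cutoff = 10,
                               links = NULL) {
  stopifnot(inherits(ca_table, "ca_table"))
  cm <- attr(ca_table, "chain_map")
  target_chains <- names(cm)[cm == target_protein]
  if (length(target_chains) == 0L) {
    stop("target protein not in chain map: ", target_protein)
  }
  partners <- character(0)
  if (!is.null(links)) {
    inv <- links$linkage == "inter" &
      (links$protein_a == target_protein | links$protein_b == target_protein)
    partners <- setdiff(unique(c(links$protein_a[inv], links$protein_b[inv])),
                        target_protein)
  }
  txyz <- as.matrix(ca_table[ca_table$chain %in% target_chains,
                             c("x", "y", "z")])
  other <- setdiff(unique(ca_table$chain), target_chains)
  rows <- data.frame(chain = target_chains, role = "mobile",
                     reason = "target", stringsAsFactors = FALSE)
  for (ch in other) {
    cxyz <- as.matrix(ca_table[ca_table$chain == ch, c("x", "y", "z")])
    near <- min_pairwise_distance(txyz, cxyz) <= cutoff
    partner <- !is.null(cm[ch]) && !is.na(cm[ch]) && cm[ch] %in% partners
    if (near || partner) {
      rows <- rbind(rows, data.frame(
        chain = ch, role = "static",
        reason = if (near) "proximity" else "partner",
        stringsAsFactors = FALSE
      ))
    }
  }
  rownames(rows) <- NULL
  structure(rows, cutoff = cutoff,
            class = c("environment_spec", "data.frame"))
}

min_pairwise_distance <- function(a, b) {
  # min over ||a_i - b_j||; modest sizes, direct cross term
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}

#' Export restraints and environment as TSV
#'
#' Deterministic, timestamp-free exports: identical inputs give byte-identical
#' files.
#'
#' @param stages An `xl_restraints` data frame (possibly rbind-ed over links).
#' @param env An `environment_spec`.
#' @param path Restraint TSV path; the environment is written next to it with
#'   suffix `"_environment.tsv"` unless `env_path` is given.
#' @param env_path Optional explicit environment path.
#' @return Character vector of the written paths, invisibly.
#' @export
export_restraint_table <- function(stages, env, path, env_path = NULL) {
  if (is.null(env_path)) {
    env_path <- sub("(\\.[^.]*)?$", "_environment.tsv", path)
  }
  utils::write.table(as.data.frame(stages), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(as.data.frame(env), env_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, env_path))
}
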