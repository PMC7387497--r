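#' Distance-threshold policy
#'
#' Default thresholds: 30 Angstrom for intramolecular cross-links (no
#' protein-protein interface involved) and 37.5 Angstrom for intermolecular
#' cross-links (150% of the ~25 Angstrom maximum C-alpha distance of
#' cross-linked lysines, allowing for conformational flexibility).  A distance
#' exactly at the threshold counts as satisfied by default
#' (`inclusive = TRUE`).
#'
#' @param intra,inter Thresholds in Angstrom.
#' @param inclusive Treat `distance == threshold` as satisfied?
#' @return A `threshold_policy` list.
#' @export
threshold_policy <- function(intra = 30, inter = 37.5, inclusive = TRUE) {
  stopifnot(intra > 0, inter > 0)
  structure(list(intra = intra, inter = inter, inclusive = inclusive),
            class = "threshold_policy")
}

eligible_measurements <- function(measurements) {
  measurements[!measurements$asymmetric & !measurements$cross_copy, ,
               drop = FALSE]
}

satisfied_at <- function(distance, threshold, inclusive = TRUE) {
  if (inclusive) distance <= threshold else distance < threshold
}

#' Classify one cross-link from its measurements
#'
#' A structure satisfies the link when the minimum eligible distance measured
#' within it is at or below the threshold (one compatible chain pair is enough
#' to explain the cross-link chemically).  The link is `satisfied` when every
#' structure satisfies it, `violated` when none does, `mixed` when both kinds
#' of structure exist, and `novel` when it could not be measured on any
#' structure.  Asymmetric-unit and cross-copy measurements are excluded.
#'
#' @param measurements `xl_measurements` rows of one link.
#' @param threshold Distance threshold in Angstrom.
#' @param inclusive Tie policy at the threshold (see [threshold_policy()]).
#' @return A list with `cls`, `n_measurements` (eligible count), and
#'   `per_structure` (data frame `pdb_id`, `min_distance`, `satisfied`).
#' @export
classify_crosslink <- function(measurements, threshold, inclusive = TRUE) {
  m <- eligible_measurements(measurements)
  if (nrow(m) == 0L) {
    return(list(cls = "novel", n_measurements = 0L,
                per_structure = data.frame(pdb_id = character(),
                                           min_distance = numeric(),
                                           satisfied = logical())))
  }
  mind <- tapply(m$distance, m$pdb_id, min)
  per <- data.frame(pdb_id = names(mind),
                    min_distance = as.numeric(mind),
                    stringsAsFactors = FALSE)
  per$satisfied <- satisfied_at(per$min_distance, threshold, inclusive)
  per <- per[order(per$pdb_id), , drop = FALSE]
  rownames(per) <- NULL
  cls <- if (all(per$satisfied)) {
    "satisfied"
  } else if (!any(per$satisfied)) {
    "violated"
  } else {
    "mixed"
  }
  list(cls = cls, n_measurements = nrow(m), per_structure = per)
}

#' Classify every cross-link of a table
#'
#' Applies [classify_crosslink()] per link with the threshold selected by the
#' link's intra/inter flag.
#'
#' @param measurements An `xl_measurements` data frame (all links).
#' @param links The `xl_links` table the measurements came from.
#' @param policy A [threshold_policy()].
#' @return An `xl_verdicts` data frame: `link_id`, `linkage`, `cls`,
#'   `n_measurements`, `n_structures`, `min_distance` (NA for novel);
#'   per-structure detail in `attr(, "per_structure")` (one data frame per
#'   link id).
#' @export
classify_all <- function(measurements, links, policy = threshold_policy()) {
  stopifnot(inherits(links, "xl_links"))
  per_structure <- list()
  rows <- vector("list", nrow(links))
  for (i in seq_len(nrow(links))) {
    link <- links[i, ]
    m <- measurements[measurements$link_id == link$id, , drop = FALSE]
    thr <- if (link$linkage == "intra") policy$intra else policy$inter
    v <- classify_crosslink(m, thr, policy$inclusive)
    per_structure[[link$id]] <- v$per_structure
    rows[[i]] <- data.frame(
      link_id = link$id, linkage = link$linkage, cls = v$cls,
      n_measurements = v$n_measurements,
      n_structures = nrow(v$per_structure),
      min_distance = if (nrow(v$per_structure) > 0L) {
        min(v$per_structure$min_distance)
      } else {
        NA_real_
      },
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows) == 0L) {
    data.frame(link_id = character(), linkage = character(),
               cls = character(), n_measurements = integer(),
               n_structures = integer(), min_distance = numeric(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  attr(out, "per_structure") <- per_structure
  attr(out, "policy") <- policy
  class(out) <- c("xl_verdicts", "data.frame")
  out
}

#' @export
print.xl_verdicts <- function(x, ...) {
  tab <- table(factor(x$cls, levels = c("satisfied", "mixed", "violated",
                                        "novel")))
  cat(sprintf("Cross-link verdicts for %d link(s):\n", nrow(x)))
  for (k in names(tab)) cat(sprintf("  %-9s %d\n", k, tab[[k]]))
  invisible(x)
}

#' Summary statistics of a measurement set
#'
#' Counts every eligible (link x structure x chain-pair) measurement and
#' reports the median distance, overall and split by linkage; with verdicts
#' supplied, also the class counts and the two satisfaction percentages the
#' field quotes (always-satisfied, and satisfied in at least one structure,
#' both relative to the mapped links).
#'
#' @param measurements An `xl_measurements` data frame.
#' @param links Optional `xl_links` (enables the by-linkage split).
#' @param verdicts Optional `xl_verdicts`.
#' @return An `xl_summary` list.
#' @export
summarize_distances <- function(measurements, links = NULL, verdicts = NULL) {
  m <- eligible_measurements(measurements)
  out <- list(n_measurements = nrow(m),
              median_distance = if (nrow(m)) stats::median(m$distance)
                                else NA_real_)
  if (!is.null(links)) {
    for (lk in c("intra", "inter")) {
      ids <- links$id[links$linkage == lk]
      d <- m$distance[m$link_id %in% ids]
      out[[paste0("n_", lk)]] <- length(d)
      out[[paste0("median_", lk)]] <- if (length(d)) stats::median(d)
                                      else NA_real_
    }
  }
  if (!is.null(verdicts)) {
    out$class_counts <- table(factor(verdicts$cls,
                                     levels = c("satisfied", "mixed",
                                                "violated", "novel")))
    mapped <- verdicts[verdicts$cls != "novel", , drop = FALSE]
    out$n_mapped <- nrow(mapped)
    if (nrow(mapped) > 0L) {
      out$pct_always_satisfied <- 100 * mean(mapped$cls == "satisfied")
      out$pct_satisfied_ge1 <- 100 * mean(mapped$cls %in% c("satisfied",
                                                            "mixed"))
    }
  }
  class(out) <- "xl_summary"
  out
}

#' @export
print.xl_summary <- function(x, ...) {
  cat(sprintf("Measurements: N = %d, median = %.2f A\n",
              x$n_measurements, x$median_distance))
  if (!is.null(x$median_intra)) {
    cat(sprintf("  intra: N = %d, median = %.2f A\n", x$n_intra,
                x$median_intra))
    cat(sprintf("  inter: N = %d, median = %.2f A\n", x$n_inter,
                x$median_inter))
  }
  if (!is.null(x$class_counts)) {
    cat("Classes:", paste(sprintf("%s %d", names(x$class_counts),
                                  x$class_counts), collapse = ", "), "\n")
    cat(sprintf("Satisfaction (of %d mapped): always %.1f%%, >=1 structure %.1f%%\n",
                x$n_mapped, x$pct_always_satisfied, x$pct_satisfied_ge1))
  }
  invisible(x)
}

#' Per-structure satisfaction counts and ranking
#'
#' Counts, for every structure, how many links it satisfies and violates,
#' then groups structures with identical counts and orders groups by
#' satisfied count (descending), ties by violated count (ascending).
#'
#' @param verdicts An `xl_verdicts` from [classify_all()].
#' @return Data frame `pdb_id`, `satisfied`, `violated`, `group` (group rank,
#'   1 = best), sorted by group then pdb id.
#' @export
rank_structures <- function(verdicts) {
  per <- attr(verdicts, "per_structure")
  rows <- do.call(rbind, per)
  if (is.null(rows) || nrow(rows) == 0L) {
    return(data.frame(pdb_id = character(), satisfied = integer(),
                      violated = integer(), group = integer()))
  }
  sat <- tapply(rows$satisfied, rows$pdb_id, sum)
  vio <- tapply(!rows$satisfied, rows$pdb_id, sum)
  out <- data.frame(pdb_id = names(sat), satisfied = as.integer(sat),
                    violated = as.integer(vio), stringsAsFactors = FALSE)
  out <- out[order(-out$satisfied, out$violated, out$pdb_id), , drop = FALSE]
  out$group <- cumsum(!duplicated(out[, c("satisfied", "violated")]))
  rownames(out) <- NULL
  out
}

#' Best structure by satisfied cross-links
#'
#' The structure with the highest number of satisfied links; ties resolved to
#' the lexicographically smallest pdb id.
#'
#' @param verdicts An `xl_verdicts`.
#' @return A pdb id (character scalar).
#' @export
best_structure <- function(verdicts) {
  rk <- rank_structures(verdicts)
  if (nrow(rk) == 0L) {
    stop("no structure-level verdicts available")
  }
  top <- rk[rk$satisfied == max(rk$satisfied), , drop = FALSE]
  min(top$pdb_id)
}

#' Violated-link counts over a grid of thresholds
#'
#' Reclassifies the mapped links at each threshold of the grid and counts the
#' links that are violated (satisfied in no structure).  Used to choose a
#' classification threshold: the count is non-increasing in the threshold and
#' a plateau indicates robustness of the chosen cutoff.
#'
#' @param measurements An `xl_measurements` data frame.
#' @param grid Numeric vector of thresholds (Angstrom).
#' @param inclusive Tie policy.
#' @return Data frame `threshold`, `violated_links`.
#' @export
sweep_thresholds <- function(measurements, grid, inclusive = TRUE) {
  m <- eligible_measurements(measurements)
  ids <- unique(m$link_id)
  out <- data.frame(threshold = grid, violated_links = NA_integer_)
  for (i in seq_along(grid)) {
    nv <- 0L
    for (id in ids) {
      d <- m$distance[m$link_id == id]
      if (!any(satisfied_at(d, grid[i], inclusive))) nv <- nv + 1L
    }
    out$violated_links[i] <- nv
  }
  out
}

#' Write verdicts / rankings / sweeps
#'
#' TSV exports of the classification products.
#'
#' @param x The object (`xl_verdicts` or a ranking/sweep data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
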