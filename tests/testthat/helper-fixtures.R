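# Small constructors shared across the test files.

# straight-line chain along x (3.8 A spacing) with explicit letters/numbers
line_chain <- function(letters_str, chain_id = "A", resno = NULL,
                       origin = c(0, 0, 0), step = 3.8) {
  letters_ <- strsplit(letters_str, "")[[1]]
  n <- length(letters_)
  if (is.null(resno)) resno <- seq_len(n)
  data.frame(chain = chain_id, resno = resno, resid = letters_,
             x = origin[1] + (seq_len(n) - 1) * step,
             y = origin[2], z = origin[3], stringsAsFactors = FALSE)
}

toy_ca_table <- function(..., pdb_id = "TOY", chain_map = character(),
                         method = "xray", resolution = 2.0) {
  tab <- do.call(rbind, list(...))
  xlmapr:::new_ca_table(tab, pdb_id = pdb_id, method = method,
                        resolution = resolution, chain_map = chain_map)
}

toy_links <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(id = r$id, protein_a = r$pa, pos_a = r$qa,
               site_a = if (is.null(r$sa)) "K" else r$sa,
               protein_b = r$pb, pos_b = r$qb,
               site_b = if (is.null(r$sb)) "K" else r$sb,
               linkage = if (identical(r$pa, r$pb)) "intra" else "inter",
               multiplicity = 1L, stringsAsFactors = FALSE)
  }))
  class(df) <- c("xl_links", "data.frame")
  df
}

toy_measurements <- function(link_id, pdb_id, distance,
                             asymmetric = FALSE, cross_copy = FALSE) {
  n <- max(length(link_id), length(pdb_id), length(distance))
  df <- data.frame(
    link_id = rep_len(link_id, n), pdb_id = rep_len(pdb_id, n),
    chain_a = rep_len("A", n), res_a = rep_len(1L, n),
    chain_b = rep_len("B", n), res_b = rep_len(1L, n),
    distance = rep_len(distance, n),
    asymmetric = rep_len(asymmetric, n), cross_copy = rep_len(cross_copy, n),
    offset_a = rep_len(0L, n), offset_b = rep_len(0L, n),
    mode_a = rep_len("direct", n), mode_b = rep_len("direct", n),
    stringsAsFactors = FALSE
  )
  class(df) <- c("xl_measurements", "data.frame")
  df
}

write_tsv_text <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

write_fasta_text <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}

# Floyd-Warshall shortest path over the free cells of a grid: independent
# oracle for the Dijkstra-based accessible distance (26-connectivity,
# Euclidean edge weights).
fw_grid_distance <- function(grid, start_cell, end_cell) {
  free <- which(!grid$occupied)
  nf <- length(free)
  ai <- arrayInd(free, grid$dim)
  D <- matrix(Inf, nf, nf)
  diag(D) <- 0
  for (u in seq_len(nf)) {
    for (v in seq_len(nf)) {
      dd <- abs(ai[u, ] - ai[v, ])
      if (u != v && all(dd <= 1L)) {
        D[u, v] <- grid$spacing * sqrt(sum(dd^2))
      }
    }
  }
  for (k in seq_len(nf)) {
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  }
  lin <- function(ijk) {
    (ijk[3] - 1L) * grid$dim[1] * grid$dim[2] +
      (ijk[2] - 1L) * grid$dim[1] + ijk[1]
  }
  D[match(lin(start_cell), free), match(lin(end_cell), free)]
}
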