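test_that("anchor peptides are tripeptides inside, flagged dipeptides at termini", {
  expect_identical(make_anchor_peptide("GKAVLD", 2),
                   list(peptide = "GKA", terminal = "none", center = 2L))
  expect_identical(make_anchor_peptide("GKAVLD", 1),
                   list(peptide = "GK", terminal = "N", center = 1L))
  expect_identical(make_anchor_peptide("GKAVLD", 6),
                   list(peptide = "LD", terminal = "C", center = 2L))
  expect_error(make_anchor_peptide("GKAVLD", 7), "outside")
})

test_that("anchors resolve directly on correctly numbered chains", {
  cs <- list(seq = "GKAVLD", resno = 1:6)
  r <- resolve_anchor(make_anchor_peptide("GKAVLD", 2), cs, 2)
  expect_identical(r, list(mode = "direct", resno = 2L, offset = 0L))
  # terminal dipeptides at offset 0 are also direct
  rn <- resolve_anchor(make_anchor_peptide("GKAVLD", 1), cs, 1)
  expect_identical(rn$mode, "direct")
  expect_identical(rn$resno, 1L)
})

test_that("window scan recovers any numbering shift up to +/-5 and fails beyond", {
  seq_ref <- "WGKAVLDERTYH"
  for (s in -5:5) {
    cs <- list(seq = seq_ref, resno = 1:12 + s)
    for (pos in c(1, 5, 12)) {
      r <- resolve_anchor(make_anchor_peptide(seq_ref, pos), cs, pos)
      expect_identical(r$offset, as.integer(s), label = sprintf("s=%d pos=%d", s, pos))
      expect_identical(r$resno, as.integer(pos + s))
      if (s == 0) expect_identical(r$mode, "direct")
    }
  }
  for (s in c(-7L, 6L, 9L)) {
    cs <- list(seq = seq_ref, resno = 1:12 + s)
    r <- resolve_anchor(make_anchor_peptide(seq_ref, 5), cs, 5)
    expect_identical(r$mode, "failed", label = sprintf("s=%d", s))
  }
})

test_that("unresolved neighbours and ambiguous placements fail the anchor", {
  # residue 2 unresolved: anchors centered at 2 cannot match consecutively
  cs <- list(seq = "GAVLD", resno = c(1L, 3L, 4L, 5L, 6L))
  r <- resolve_anchor(make_anchor_peptide("GKAVLD", 2), cs, 2)
  expect_identical(r$mode, "failed")
  # duplicated author number: ambiguous placement at one offset
  dup <- list(seq = "GKAGKA", resno = c(1L, 2L, 3L, 1L, 2L, 3L))
  r2 <- resolve_anchor(make_anchor_peptide("GKAVLD", 2), dup, 2)
  expect_identical(r2$mode, "failed")
  # terminal dipeptide away from the terminus does not match
  cs3 <- list(seq = "AGKAVLD", resno = 0:6)
  r3 <- resolve_anchor(make_anchor_peptide("GKAVLD", 1), cs3, 1)
  expect_identical(r3$mode, "failed")
})

test_that("euclidean distance matches the coordinate formula and its properties", {
  expect_equal(euclidean_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(euclidean_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(euclidean_distance(c(1, 2, 3), c(4, 6, 3)), 5)
  set.seed(11)
  for (k in 1:25) {
    p <- rnorm(3, sd = 20); q <- rnorm(3, sd = 20); r <- rnorm(3, sd = 20)
    expect_equal(euclidean_distance(p, q), euclidean_distance(q, p))
    expect_gte(euclidean_distance(p, r) + 1e-12,
               euclidean_distance(p, q) - euclidean_distance(q, r))
  }
})

test_that("asymmetric-unit chain rules fire on case and two-character prefixes", {
  expect_true(is_asymmetric_pair("A", "b"))
  expect_true(is_asymmetric_pair("AA", "BB"))
  expect_false(is_asymmetric_pair("AA", "AB"))
  expect_false(is_asymmetric_pair("A", "B"))
  expect_false(is_asymmetric_pair("a", "b"))
  # symmetry over random alphabetic labels
  set.seed(7)
  pool <- c("A", "b", "C", "d", "AA", "AB", "Ba", "bb", "Z", "z")
  for (k in 1:40) {
    x <- sample(pool, 1); y <- sample(pool, 1)
    expect_identical(is_asymmetric_pair(x, y), is_asymmetric_pair(y, x),
                     label = paste(x, y))
  }
  expect_warning(res <- is_asymmetric_pair("1", "A"), "non-alphabetic")
  expect_false(res)
})

test_that("measurement enumerates chain combinations with the right flags", {
  # inter link, one chain per protein
  asm <- assemble_complex(data.frame(
    accession = c("PA", "PB"), chain_id = c("A", "B"),
    length = c(12L, 12L), tx = c(0, 10), ty = 0, tz = 0), seed = 5)
  link <- toy_links(list(id = "#1", pa = "PA", qa = 5, pb = "PB", qb = 5))[1, ]
  m <- measure_crosslink(link, asm$ca_table, sequences = asm$sequences)
  expect_identical(nrow(m), 1L)
  expect_false(m$asymmetric)
  # protein B present as chains B and b: A-B kept, A-b flagged asymmetric
  dup <- duplicate_asymmetric(asm$ca_table, "lowercase")
  m2 <- measure_crosslink(link, dup, sequences = asm$sequences)
  expect_identical(nrow(m2), 4L)     # A/a x B/b
  expect_identical(sum(!m2$asymmetric), 2L)
  expect_true(all(xor(m2$chain_a == tolower(m2$chain_a),
                      m2$chain_b == tolower(m2$chain_b)) == m2$asymmetric))
})

test_that("intra links on a four-copy protein give 4 within-chain plus C(4,2) cross-copy measurements", {
  chains <- data.frame(accession = "L7", chain_id = c("P", "Q", "R", "S"),
                       length = 20L, tx = c(0, 30, 60, 90), ty = 0, tz = 0)
  asm <- assemble_complex(chains, seed = 9)
  link <- toy_links(list(id = "#1", pa = "L7", qa = 4, pb = "L7", qb = 15))[1, ]
  m <- measure_crosslink(link, asm$ca_table, sequences = asm$sequences)
  expect_identical(sum(!m$cross_copy), 4L)
  expect_identical(sum(m$cross_copy), 6L)   # one per unordered copy pair, C(4,2)
})

test_that("measured distances equal direct coordinate arithmetic on synthetic complexes", {
  asm <- assemble_complex(data.frame(
    accession = c("PA", "PB"), chain_id = c("A", "B"),
    length = c(15L, 15L), tx = c(0, 8), ty = 0, tz = 0), seed = 13)
  tab <- asm$ca_table
  got <- expected <- numeric(0)
  for (qa in c(2, 7, 14)) {
    for (qb in c(3, 9, 15)) {
      link <- toy_links(list(id = "#x", pa = "PA", qa = qa,
                             pb = "PB", qb = qb))[1, ]
      m <- measure_crosslink(link, tab, sequences = asm$sequences)
      a <- tab[tab$chain == "A" & tab$resno == qa, ]
      b <- tab[tab$chain == "B" & tab$resno == qb, ]
      got <- c(got, m$distance)
      expected <- c(expected,
                    sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2))
    }
  }
  expect_equal(got, expected, tolerance = 1e-12)
})
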