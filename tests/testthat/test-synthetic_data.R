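test_that("helix chains have canonical C-alpha spacing and rigid-motion invariance", {
  ch <- make_helix_chain(30, "A")
  expect_identical(nrow(ch), 30L)
  d <- sqrt(diff(ch$x)^2 + diff(ch$y)^2 + diff(ch$z)^2)
  expect_true(all(abs(d - 3.83) < 0.05))   # ~3.8 A consecutive spacing
  tr <- rigid_transform(angle_deg = 37, axis = c(1, 2, 3),
                        translation = c(5, -4, 11))
  ch2 <- make_helix_chain(30, "A", tr)
  d2 <- sqrt(diff(ch2$x)^2 + diff(ch2$y)^2 + diff(ch2$z)^2)
  expect_equal(d2, d, tolerance = 1e-10)
  expect_identical(nrow(make_helix_chain(3, "Z")), 3L)
  expect_error(make_helix_chain(2, "A"), "length")
})

test_that("complex assembly is deterministic under seed and rejects label clashes", {
  spec <- data.frame(accession = c("PA", "PA", "PB"),
                     chain_id = c("A", "B", "C"), length = 15L,
                     tx = c(0, 20, 40), ty = 0, tz = 0)
  a1 <- assemble_complex(spec, seed = 4)
  a2 <- assemble_complex(spec, seed = 4)
  expect_identical(as.data.frame(a1$ca_table), as.data.frame(a2$ca_table))
  expect_identical(a1$sequences$PA, a2$sequences$PA)
  expect_identical(attr(a1$ca_table, "chain_map"),
                   c(A = "PA", B = "PA", C = "PB"))
  # copies of one protein share the sequence
  expect_identical(chain_sequence(a1$ca_table, "A")$seq,
                   chain_sequence(a1$ca_table, "B")$seq)
  bad <- spec; bad$chain_id <- c("A", "A", "C")
  expect_error(assemble_complex(bad, seed = 1), "overlapping")
  a3 <- assemble_complex(spec, seed = 5)
  expect_false(identical(a1$sequences$PA, a3$sequences$PA))
})

test_that("asymmetric duplication relabels copies and keeps within-copy geometry", {
  asm <- assemble_complex(data.frame(accession = c("PA", "PB"),
                                     chain_id = c("A", "B"), length = 12L,
                                     tx = c(0, 10), ty = 0, tz = 0), seed = 2)
  dup <- duplicate_asymmetric(asm$ca_table, "lowercase",
                              displacement = c(100, 0, 0))
  expect_setequal(unique(dup$chain), c("A", "B", "a", "b"))
  expect_true(is_asymmetric_pair("A", "b"))
  # cross-copy distances exceed the displacement minus the complex size
  a1 <- dup[dup$chain == "A", ]; a2 <- dup[dup$chain == "a", ]
  cross <- sqrt(outer(a1$x, a2$x, "-")^2 + outer(a1$y, a2$y, "-")^2 +
                  outer(a1$z, a2$z, "-")^2)
  expect_true(all(cross > 60))
  # within-copy geometry unchanged
  expect_equal(a2[, c("y", "z")], a1[, c("y", "z")], ignore_attr = TRUE)
  expect_equal(a2$x - 100, a1$x, tolerance = 1e-12)
  dup2 <- duplicate_asymmetric(asm$ca_table, "two_char")
  expect_setequal(unique(dup2$chain), c("AA", "AB", "BA", "BB"))
  expect_true(is_asymmetric_pair("AA", "BB"))
  expect_false(is_asymmetric_pair("AA", "AB"))
})

test_that("cross-link sampling respects the distance band, seed, and feasibility", {
  asm <- assemble_complex(data.frame(accession = c("PA", "PB"),
                                     chain_id = c("A", "B"), length = 20L,
                                     tx = c(0, 12), ty = 0, tz = 0), seed = 8)
  s1 <- sample_crosslinks(asm$ca_table, 6, c(5, 15), seed = 101)
  expect_identical(nrow(s1$links), 6L)
  expect_true(all(s1$truth$true_distance >= 5 &
                    s1$truth$true_distance <= 15))
  s2 <- sample_crosslinks(asm$ca_table, 6, c(5, 15), seed = 101)
  expect_identical(as.data.frame(s1$links), as.data.frame(s2$links))
  expect_error(sample_crosslinks(asm$ca_table, 2, c(1000, 2000), seed = 1),
               "achievable range")
})

test_that("numbering perturbations record their ground-truth offsets", {
  asm <- assemble_complex(data.frame(accession = "PA", chain_id = "A",
                                     length = 25L, tx = 0, ty = 0, tz = 0),
                          seed = 6)
  tab <- asm$ca_table
  sh <- perturb_numbering(tab, "A", "shift", s = 3)
  expect_identical(sh$offset, 3L)
  expect_identical(sh$table$resno, tab$resno + 3L)
  met <- perturb_numbering(tab, "A", "drop_start_met", policy = "renumber")
  expect_identical(met$offset, -1L)
  expect_identical(nrow(met$table), 24L)
  expect_identical(min(met$table$resno), 1L)
  expect_identical(chain_sequence(met$table, "A")$seq,
                   substr(chain_sequence(tab, "A")$seq, 2, 25))
  keepn <- perturb_numbering(tab, "A", "drop_start_met", policy = "keep")
  expect_identical(min(keepn$table$resno), 2L)
  seg <- perturb_numbering(tab, "A", "drop_segment", from = 10, to = 20)
  expect_identical(nrow(seg$table), 25L - 11L)
  expect_false(any(seg$table$resno %in% 10:20))
  expect_error(perturb_numbering(tab, "A", "drop_segment", from = 10,
                                 to = 40), "outside")
})

test_that("mmCIF fixtures round-trip coordinates to better than 3 decimals", {
  for (k in 1:3) {
    asm <- assemble_complex(data.frame(accession = c("PA", "PB"),
                                       chain_id = c("A", "B"), length = 10L,
                                       tx = c(0, 7 + k), ty = k, tz = -k),
                            seed = 30 + k)
    tab <- asm$ca_table
    path <- tempfile(fileext = ".cif")
    write_mmcif_fixture(tab, path)
    back <- load_ca_table(path, chain_map = attr(tab, "chain_map"))
    expect_identical(back$chain, tab$chain)
    expect_identical(back$resno, tab$resno)
    expect_identical(back$resid, tab$resid)
    expect_equal(back$x, tab$x, tolerance = 5e-4)
    expect_equal(back$y, tab$y, tolerance = 5e-4)
    expect_equal(back$z, tab$z, tolerance = 5e-4)
  }
})

test_that("the full pipeline recovers ground truth on seeded fixtures", {
  b <- synthetic_benchmark(n_complexes = 6, seed = 11)
  expect_identical(b$class_agreement, 1)
  expect_lt(b$max_distance_error, 1e-3)
  expect_identical(b$offset_agreement, 1)
  # asymmetric-copy exclusion: flagged measurements never enter classification
  flagged <- b$measurements[b$measurements$asymmetric |
                              b$measurements$cross_copy, ]
  expect_gt(nrow(flagged), 0L)
  elig <- b$measurements[!b$measurements$asymmetric &
                           !b$measurements$cross_copy, ]
  per <- b$verdicts
  expect_true(all(per$n_measurements[per$cls != "novel"] > 0L))
})
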