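test_that("per-link classification covers satisfied, mixed, violated and novel", {
  thr <- 30
  sat <- classify_crosslink(toy_measurements("#1", c("S1", "S2"), c(10, 20)), thr)
  expect_identical(sat$cls, "satisfied")
  mix <- classify_crosslink(toy_measurements("#1", c("S1", "S2"), c(10, 40)), thr)
  expect_identical(mix$cls, "mixed")
  vio <- classify_crosslink(toy_measurements("#1", c("S1", "S2"), c(33, 40)), thr)
  expect_identical(vio$cls, "violated")
  nov <- classify_crosslink(toy_measurements(character(0), character(0),
                                             numeric(0)), thr)
  expect_identical(nov$cls, "novel")
  expect_identical(nov$n_measurements, 0L)
  # flagged measurements are excluded: only asymmetric ones -> novel
  fl <- classify_crosslink(toy_measurements("#1", "S1", 10, asymmetric = TRUE),
                           thr)
  expect_identical(fl$cls, "novel")
  # a structure is satisfied on its minimum eligible distance
  multi <- classify_crosslink(toy_measurements("#1", c("S1", "S1"), c(50, 12)),
                              thr)
  expect_identical(multi$cls, "satisfied")
})

test_that("every link receives exactly one class and ties at the threshold satisfy", {
  m <- rbind(toy_measurements("#1", "S1", 37.5),
             toy_measurements("#2", "S1", 37.5001))
  links <- toy_links(list(id = "#1", pa = "A", qa = 1, pb = "B", qb = 2),
                     list(id = "#2", pa = "A", qa = 3, pb = "B", qb = 4),
                     list(id = "#3", pa = "A", qa = 5, pb = "C", qb = 6))
  v <- classify_all(m, links, threshold_policy())
  expect_identical(nrow(v), 3L)
  expect_true(all(v$cls %in% c("satisfied", "violated", "mixed", "novel")))
  expect_identical(v$cls[v$link_id == "#1"], "satisfied")  # inclusive <=
  expect_identical(v$cls[v$link_id == "#2"], "violated")
  expect_identical(v$cls[v$link_id == "#3"], "novel")
  # exclusive tie policy flips the boundary case
  vx <- classify_all(m, links, threshold_policy(inclusive = FALSE))
  expect_identical(vx$cls[vx$link_id == "#1"], "violated")
})

test_that("medians and N agree with a sort-based oracle", {
  s <- summarize_distances(toy_measurements(rep("#1", 3), "S1", c(1, 2, 3)))
  expect_identical(s$n_measurements, 3L)
  expect_equal(s$median_distance, 2)
  s4 <- summarize_distances(toy_measurements(rep("#1", 4), "S1", c(1, 2, 3, 4)))
  expect_equal(s4$median_distance, 2.5)
  set.seed(31)
  d <- runif(100, 3, 80)
  sort_median <- function(v) {
    v <- sort(v); n <- length(v)
    if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
  }
  s100 <- summarize_distances(toy_measurements(rep("#1", 100), "S1", d))
  expect_equal(s100$median_distance, sort_median(d))
  # flagged measurements do not count towards N
  mflag <- rbind(toy_measurements("#1", "S1", 10),
                 toy_measurements("#1", "S1", 11, asymmetric = TRUE),
                 toy_measurements("#1", "S1", 12, cross_copy = TRUE))
  expect_identical(summarize_distances(mflag)$n_measurements, 1L)
})

test_that("structure ranking groups equal counts and best structure breaks ties lexicographically", {
  links <- toy_links(list(id = "#1", pa = "A", qa = 1, pb = "B", qb = 2),
                     list(id = "#2", pa = "A", qa = 3, pb = "B", qb = 4),
                     list(id = "#3", pa = "A", qa = 5, pb = "B", qb = 6),
                     list(id = "#4", pa = "A", qa = 7, pb = "B", qb = 8))
  m <- rbind(
    toy_measurements(c("#1", "#2", "#3", "#4"), "SB", c(10, 12, 14, 50)),
    toy_measurements(c("#1", "#2", "#3", "#4"), "SA", c(10, 12, 14, 50)),
    toy_measurements(c("#1", "#2"), "SC", c(20, 22))
  )
  v <- classify_all(m, links, threshold_policy())
  rk <- rank_structures(v)
  expect_identical(rk$group, c(1L, 1L, 2L))          # (3,1) twice, then (2,0)
  expect_identical(rk$pdb_id[1:2], c("SA", "SB"))
  expect_identical(best_structure(v), "SA")          # lexicographic tie-break
  # higher satisfied count ranks first
  expect_true(rk$satisfied[1] >= rk$satisfied[3])
  expect_identical(rank_structures(classify_all(m[0, ], links[0, ],
                                                threshold_policy()))$pdb_id,
                   character(0))
})

test_that("threshold sweep matches brute-force reclassification and is monotone", {
  # single link at 35 A: violated at 30, not at 40
  one <- toy_measurements("#1", "S1", 35)
  sw <- sweep_thresholds(one, c(30, 40))
  expect_identical(sw$violated_links, c(1L, 0L))
  # random synthetic measurement set vs brute-force oracle
  set.seed(17)
  ids <- sprintf("#%d", 1:30)
  m <- do.call(rbind, lapply(ids, function(id) {
    k <- sample(1:3, 1)
    toy_measurements(rep(id, k), sprintf("S%d", seq_len(k)),
                     runif(k, 5, 70))
  }))
  grid <- seq(10, 60, by = 5)
  sw2 <- sweep_thresholds(m, grid)
  brute <- vapply(grid, function(t) {
    sum(vapply(ids, function(id) {
      d <- m$distance[m$link_id == id]
      all(d > t)
    }, logical(1)))
  }, integer(1))
  expect_identical(sw2$violated_links, brute)
  expect_true(all(diff(sw2$violated_links) <= 0L))
})

test_that("satisfaction percentages report both framings over mapped links", {
  links <- toy_links(list(id = "#1", pa = "A", qa = 1, pb = "B", qb = 2),
                     list(id = "#2", pa = "A", qa = 3, pb = "B", qb = 4),
                     list(id = "#3", pa = "A", qa = 5, pb = "B", qb = 6),
                     list(id = "#4", pa = "A", qa = 7, pb = "C", qb = 8))
  m <- rbind(toy_measurements("#1", c("S1", "S2"), c(10, 12)),   # satisfied
             toy_measurements("#2", c("S1", "S2"), c(10, 50)),   # mixed
             toy_measurements("#3", c("S1", "S2"), c(45, 50)))   # violated
  v <- classify_all(m, links, threshold_policy())
  s <- summarize_distances(m, links, v)
  expect_identical(s$n_mapped, 3L)
  expect_equal(s$pct_always_satisfied, 100 / 3)
  expect_equal(s$pct_satisfied_ge1, 200 / 3)
})
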