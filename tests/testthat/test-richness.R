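sch37 <- make_equal_elevation_bands(1350, 5050, 100)

test_that("interpolated presence covers every intersected band", {
  expect_equal(interpolate_presence(list(elev_min = 1500, elev_max = 1720), sch37),
               2:4)
  expect_equal(interpolate_presence(list(elev_min = 2000, elev_max = 2000), sch37),
               7L)
  expect_equal(interpolate_presence(list(elev_min = 1350, elev_max = 5050), sch37),
               1:37)
  # a range ending exactly at a band's lower bound is counted there
  expect_equal(interpolate_presence(list(elev_min = 1500, elev_max = 1550), sch37),
               2:3)
  # ... but one starting at an upper bound only enters the upper band
  expect_equal(interpolate_presence(list(elev_min = 1550, elev_max = 1600), sch37),
               3L)
  expect_error(
    interpolate_presence(list(species = "alpine_x", elev_min = 1000, elev_max = 1400),
                         sch37),
    "alpine_x")
})

test_that("presence sets are contiguous runs for random ranges", {
  set.seed(7)
  for (i in 1:50) {
    r <- sort(runif(2, 1350, 5050))
    bands <- interpolate_presence(list(elev_min = r[1], elev_max = r[2]), sch37)
    expect_equal(bands, seq(min(bands), max(bands)))
    # oracle: brute-force interval intersection (closed range, half-open bands)
    hit <- which(r[2] >= sch37$lower &
                   (r[1] < sch37$upper | (seq_len(37) == 37 & r[1] <= sch37$upper)))
    expect_equal(bands, hit)
  }
})

test_that("range-size groups use inclusive 150-500 m boundaries", {
  expect_equal(as.character(range_size_group(c(0, 149.9, 150, 500, 500.1, 501))),
               c("I", "I", "II", "II", "III", "III"))
  expect_error(range_size_group(-1), "negative")
})

test_that("richness counting matches hand enumeration on a toy checklist", {
  dom <- c(0, 500)
  sch <- make_equal_elevation_bands(0, 500, 100)
  cl <- toy_checklist(
    species = c("a", "b", "c"),
    genus = c("G1", "G1", "G2"),
    family = c("F1", "F1", "F1"),
    lifeform = c("tree", "shrub", "herb"),
    elev_min = c(50, 150, 320),
    elev_max = c(250, 380, 320),
    domain = dom
  )
  rt <- richness_table(cl, sch)
  # hand enumeration: a in bands 1-3, b in 2-4, c in band 4
  expect_equal(rt$S, c(1L, 2L, 2L, 2L, 0L))
  expect_equal(rt$G, c(1L, 1L, 1L, 2L, 0L))  # congeners share band 2-3
  expect_equal(rt$F, c(1L, 1L, 1L, 1L, 0L))
  expect_equal(rt$TS, c(1L, 1L, 1L, 0L, 0L))
  expect_equal(rt$SS, c(0L, 1L, 1L, 1L, 0L))
  expect_equal(rt$HS, c(0L, 0L, 0L, 1L, 0L))
  expect_true(all(rt$G[rt$S > 1] < rt$S[rt$S > 1] | rt$G[rt$S > 1] == rt$S[rt$S > 1]))
  expect_lt(rt$G[2], rt$S[2])
})

test_that("degenerate checklists count correctly", {
  sch <- make_equal_elevation_bands(0, 500, 100)
  empty <- toy_checklist(character(), character(), character(), character(),
                         numeric(), numeric(), domain = c(0, 500))
  rt0 <- richness_table(empty, sch)
  expect_true(all(rt0[richness_variables] == 0L))
  full <- toy_checklist(c("a", "b"), c("g1", "g2"), c("f1", "f2"),
                        c("herb", "herb"), c(0, 0), c(500, 500),
                        domain = c(0, 500))
  rtf <- richness_table(full, sch)
  expect_true(all(rtf$S == 2L))
  dup <- toy_checklist(c("a", "a"), c("g1", "g1"), c("f1", "f1"),
                       c("herb", "herb"), c(0, 100), c(200, 300),
                       domain = c(0, 500))
  expect_error(richness_table(dup, sch), "conflicting ranges")
})

test_that("partition identities hold on random checklists", {
  for (seed in 1:50) {
    cl <- random_checklist(n = 60, domain = c(0, 1000), seed = seed)
    sch <- make_equal_elevation_bands(0, 1000, 100)
    rt <- richness_table(cl, sch)
    expect_equal(rt$S, rt$TS + rt$SS + rt$HS)
    expect_equal(rt$S, rt$IS + rt$IIS + rt$IIIS)
    expect_true(all(rt$S >= rt$G & rt$G >= rt$F))
  }
})

test_that("single-band subset equals brute-force enumeration", {
  cp <- checklist_params(n_species = 500, seed = 31L)
  cl <- generate_checklist(cp, c(1350, 5050))
  sub <- single_band_subset(cl, sch37)
  oracle <- vapply(seq_len(nrow(cl)), function(i) {
    length(interpolate_presence(cl[i, ], sch37)) == 1L
  }, TRUE)
  expect_equal(sub$species, cl$species[oracle])
  # every zero-range species is in the subset; any band-spanner is not
  expect_true(all(cl$species[cl$elev_min == cl$elev_max] %in% sub$species))
  expect_true(all(sub$elev_max - sub$elev_min < 100))
  # counting the subset needs no interpolation: band totals sum to subset size
  rt <- richness_table(sub, sch37)
  expect_equal(sum(rt$S), nrow(sub))
})
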