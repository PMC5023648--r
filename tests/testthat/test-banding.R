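test_that("equal-elevation banding tiles the domain", {
  sch <- make_equal_elevation_bands(1350, 5050, 100)
  expect_equal(nrow(sch), 37L)
  expect_equal(sch$lower[1], 1350)
  expect_equal(sch$upper[1], 1450)
  expect_equal(sch$lower[37], 4950)
  expect_equal(sch$upper[37], 5050)
  expect_equal(sch$upper[-37], sch$lower[-1])  # no gaps or overlaps
  expect_equal(nrow(make_equal_elevation_bands(0, 100, 100)), 1L)
  expect_error(make_equal_elevation_bands(0, 250, 100), "not divisible")
})

test_that("band areas are cell count times cell area", {
  g <- toy_grid(rep(1400L, 10), cell_area = 900, domain = c(1350, 5050))
  sch <- assign_band_areas(make_equal_elevation_bands(1350, 5050, 100), g)
  expect_equal(sch$cell_count[1], 10L)
  expect_equal(sch$area_km2[1], 0.009)
  expect_equal(sum(sch$cell_count[-1]), 0L)
  expect_error(assign_band_areas(sch, toy_grid(integer(0), domain = c(1350, 5050))),
               "empty")
})

test_that("a boundary cell goes to the half-open band that contains it", {
  g <- toy_grid(1450L, domain = c(1350, 5050))
  sch <- assign_band_areas(make_equal_elevation_bands(1350, 5050, 100), g)
  expect_equal(which(sch$cell_count == 1L), 2L)  # [1450, 1550), not [1350, 1450)
  # the domain top belongs to the closed last band
  gt <- toy_grid(5050L, domain = c(1350, 5050))
  st <- assign_band_areas(make_equal_elevation_bands(1350, 5050, 100), gt)
  expect_equal(which(st$cell_count == 1L), 37L)
})

test_that("cells outside the domain are excluded and counted", {
  g <- toy_grid(c(1400L, 1200L, 6000L), domain = c(1350, 5050))
  sch <- assign_band_areas(make_equal_elevation_bands(1350, 5050, 100), g)
  expect_equal(sum(sch$cell_count), 1L)
  expect_equal(attr(sch, "n_outside"), 2L)
})

test_that("band counts match a histogram oracle on a synthetic hump grid", {
  g <- default_mountain(seed = 13L)
  sch <- assign_band_areas(make_equal_elevation_bands(1350, 5050, 100), g)
  oracle <- as.integer(table(cut(as.vector(g$elev), seq(1350, 5050, 100),
                                 right = FALSE, include.lowest = TRUE)))
  expect_equal(sch$cell_count, oracle)
  expect_equal(sum(sch$cell_count), length(g$elev))
  # unimodal area profile with mode at the band containing the hump peak
  expect_equal(which.max(sch$cell_count), 14L)
})

test_that("equal-area banding splits cells into near-equal groups", {
  set.seed(101)
  g74 <- toy_grid(sample.int(3000, 74) + 1000L, domain = c(1000, 4001))
  ea <- make_equal_area_bands(g74, 37, seed = 1L)
  expect_true(all(ea$cell_count == 2L))
  g75 <- toy_grid(sample.int(3000, 75) + 1000L, domain = c(1000, 4001))
  ea75 <- make_equal_area_bands(g75, 37, seed = 1L)
  expect_setequal(unique(ea75$cell_count), c(2L, 3L))
  expect_equal(sum(ea75$cell_count == 3L), 1L)
  expect_error(make_equal_area_bands(g74, 100, seed = 1L), "exceeds")
})

test_that("equal-area bands conserve area and reproduce per seed", {
  g <- default_mountain(seed = 21L)
  ea1 <- make_equal_area_bands(g, 37, seed = 5L)
  ea2 <- make_equal_area_bands(g, 37, seed = 5L)
  expect_identical(ea1, ea2)
  ea3 <- make_equal_area_bands(g, 37, seed = 6L)
  expect_false(identical(ea1$lower, ea3$lower))
  expect_lte(max(ea1$cell_count) - min(ea1$cell_count), 1L)
  expect_equal(sum(ea1$cell_count), length(g$elev))
  expect_equal(sum(ea1$area_km2), length(g$elev) * g$cell_area / 1e6)
  # bands tile the domain
  expect_equal(ea1$lower[1], g$domain[1])
  expect_equal(ea1$upper[37], g$domain[2])
  expect_equal(ea1$upper[-37], ea1$lower[-1])
})

test_that("equal-area widths mirror the hypsography inversely", {
  g <- default_mountain(seed = 2L)
  ea <- make_equal_area_bands(g, 37, seed = 2L)
  ee <- assign_band_areas(make_equal_elevation_bands(1350, 5050, 100), g)
  # narrowest equal-area band sits near the hypsographic mode...
  mode_elev <- ee$mid[which.max(ee$cell_count)]
  expect_lt(abs(ea$mid[which.min(ea$width_m)] - mode_elev), 300)
  # ...and the widest is the top band, where cells are sparsest
  expect_equal(which.max(ea$width_m), 37L)
})

test_that("band climate summaries equal brute-force groupby means", {
  g <- default_mountain(seed = 17L, mat_noise_sd = 0.3, map_noise_sd = 20)
  sch <- summarize_band_climate(
    assign_band_areas(make_equal_elevation_bands(1350, 5050, 100), g), g)
  elev <- as.vector(t(g$elev))
  mat <- as.vector(t(g$mat))
  idx <- findInterval(elev, c(sch$lower, 5050), rightmost.closed = TRUE)
  for (b in c(1, 14, 25, 37)) {
    sel <- idx == b
    if (any(sel)) expect_equal(sch$mat_mean[b], mean(mat[sel]))
  }
  # constant layer: every non-empty band mean equals the constant
  g$mat[] <- 4.2
  g$map[] <- 900
  sch2 <- summarize_band_climate(sch, g)
  expect_true(all(sch2$mat_mean[!is.na(sch2$mat_mean)] == 4.2))
  g$mat <- NULL
  expect_error(summarize_band_climate(sch, g), "climate")
})
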