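test_that("sector plume kernel matches the closed form", {
  # hand evaluation: (1/(2*pi*2*10*10)) / (pi*100*45/180)
  got <- sector_plume(1, 2, 10, 10, 0, 100)
  expect_equal(got, (1 / (400 * pi)) / (pi * 100 * 45 / 180))
  expect_equal(got, 1.013e-5, tolerance = 1e-3)
  # attenuation T = 0 kills the field; linear in Q and in T
  expect_equal(sector_plume(1, 2, 10, 10, 0, 100, attenuation = 0), 0)
  expect_equal(sector_plume(2, 2, 10, 10, 0, 100), 2 * got)
  expect_equal(sector_plume(1, 2, 10, 10, 0, 100, attenuation = 3), 3 * got)
  # elevated source reduces near-ground concentration
  expect_lt(sector_plume(1, 2, 10, 10, 50, 100), got)
  expect_error(sector_plume(1, 0, 10, 10, 0, 100), "wind speed")
  expect_error(sector_plume(1, 2, 10, 10, 0, -5), "distance")
})

test_that("annual-emission wrapper applies the unit chain", {
  # ton/yr -> g/s -> mg/m^3 around the raw kernel
  q_t <- 315.36                      # = 10 g/s exactly
  expect_equal(tons_per_year_to_g_per_s(q_t), 10)
  expect_equal(sector_concentration(q_t, 2, 10, 10, 0, 100),
               1e3 * 10 * sector_plume(1, 2, 10, 10, 0, 100))
})

test_that("crosswind flux identity holds and is width-invariant", {
  set.seed(4)
  for (i in 1:20) {
    q <- runif(1, 0.1, 50); u <- runif(1, 0.5, 10)
    sy <- runif(1, 5, 200); sz <- runif(1, 5, 100)
    h <- runif(1, 0, 80); x <- runif(1, 100, 5000)
    tt <- runif(1, 0.2, 1)
    chk <- crosswind_integral_check(q, u, sy, sz, h, x, 45, tt)
    expect_equal(chk$flux, chk$rhs)
    expect_equal(chk$rhs,
                 q / (2 * pi * u * sy * sz) * exp(-h^2 / (2 * sz^2)) * tt)
    # doubling the sector width halves c but leaves the flux fixed
    chk2 <- crosswind_integral_check(q, u, sy, sz, h, x, 90, tt)
    expect_equal(chk2$concentration, chk$concentration / 2)
    expect_equal(chk2$flux, chk$flux)
  }
  # numeric quadrature of the arc-uniform profile over the arc
  chk <- crosswind_integral_check(5, 3, 40, 20, 10, 1000, 45, 1)
  quad <- integrate(function(s) rep(chk$concentration, length(s)),
                    0, chk$arc_width)
  expect_equal(quad$value, chk$flux, tolerance = 1e-8)
})

test_that("grid engine equals the brute-force per-cell oracle", {
  set.seed(9)
  rose <- manual_rose(freq = as.vector(rmultinom(1, 300, rep(1, 8))) / 300,
                      mean_speed = runif(8, 1, 6),
                      stability = sample(LETTERS[1:6], 8, replace = TRUE))
  # single elevated source on a 21x21 grid
  sf <- flat_source_field(21, 21, cells = list(
    list(row = 11, col = 11, q = 500, delta_h = 40)), elevation = 12)
  eng <- disperse(sf, rose)
  orc <- oracle_disperse(sf, rose)
  expect_equal(max(abs(eng - orc)) / max(orc), 0, tolerance = 1e-10)
  # several sources, mixed heights, elevation-dependent receptors
  g <- lapmd_grid(15, 15, 300)
  elev <- lapmd_raster(matrix(runif(225, 0, 50), 15, 15), g)
  q <- matrix(0, 15, 15); q[cbind(c(2, 8, 14), c(3, 12, 7))] <- c(50, 200, 10)
  dh <- matrix(0, 15, 15); dh[q > 0] <- c(45, 10, 0)
  sf <- source_field(lapmd_raster(q, g), lapmd_raster(dh, g), elev)
  for (conv in c("absolute", "relative")) {
    eng <- disperse(sf, rose,
                    dispersion_settings(height_convention = conv))
    orc <- oracle_disperse(sf, rose, height_convention = conv)
    expect_equal(max(abs(eng - orc)) / max(orc), 0, tolerance = 1e-10)
  }
})

test_that("superposition and linearity of the multi-source field", {
  rose <- manual_rose(freq = rep(0.125, 8), mean_speed = rep(3, 8))
  a <- flat_source_field(12, 12, cells = list(list(row = 3, col = 4, q = 80)))
  b <- flat_source_field(12, 12, cells = list(list(row = 9, col = 10, q = 40)))
  ab <- flat_source_field(12, 12, cells = list(
    list(row = 3, col = 4, q = 80), list(row = 9, col = 10, q = 40)))
  ca <- disperse(a, rose); cb <- disperse(b, rose); cab <- disperse(ab, rose)
  expect_equal(unclass(cab), unclass(ca) + unclass(cb),
               ignore_attr = TRUE)
  # zero emissions give a zero field; scaling Q scales c
  z <- flat_source_field(12, 12)
  expect_true(all(disperse(z, rose) == 0))
  a2 <- flat_source_field(12, 12, cells = list(list(row = 3, col = 4,
                                                    q = 160)))
  expect_equal(unclass(disperse(a2, rose)), 2 * unclass(ca),
               ignore_attr = TRUE)
  # scaling T scales c
  cT <- disperse(a, rose, dispersion_settings(attenuation = 0.5))
  expect_equal(unclass(cT), 0.5 * unclass(ca), ignore_attr = TRUE)
  # non-negative and finite everywhere
  expect_true(all(is.finite(cab)) && all(cab >= 0))
})

test_that("each receptor is served through exactly one sector", {
  g <- lapmd_grid(9, 9, 300)
  cc <- cell_centers(g)
  src <- c(5, 5)
  hits <- matrix(0L, 9, 9)
  for (s in 1:8) {
    freq <- rep(0, 8); freq[s] <- 1
    rose <- manual_rose(freq = freq, mean_speed = rep(3, 8))
    sf <- flat_source_field(9, 9, cells = list(
      list(row = src[1], col = src[2], q = 100)))
    conc <- disperse(sf, rose,
                     dispersion_settings(self_cell = "zero"))
    hits <- hits + (unclass(conc) > 0)
  }
  hits[src[1], src[2]] <- 1L   # self cell excluded by the zero rule
  expect_true(all(hits == 1L))
})

test_that("concentration decays along the sector centerline far downwind", {
  rose <- manual_rose(freq = c(0, 0, 0, 0, 1, 0, 0, 0),  # wind from south
                      mean_speed = rep(3, 8))
  sf <- flat_source_field(41, 21, cells = list(
    list(row = 41, col = 11, q = 100)))   # source on the south edge
  conc <- disperse(sf, rose)
  centerline <- rev(unclass(conc)[1:40, 11])  # northward from the source
  peak <- which.max(centerline)
  tail <- centerline[peak:length(centerline)]
  expect_true(all(diff(tail) <= 1e-15))
})

test_that("geometry and rose validation", {
  rose <- manual_rose(freq = rep(0.125, 8))
  g1 <- lapmd_grid(5, 5, 300); g2 <- lapmd_grid(5, 5, 200)
  sf <- source_field(lapmd_raster(matrix(1, 5, 5), g1),
                     lapmd_raster(matrix(0, 5, 5), g1),
                     lapmd_raster(matrix(0, 5, 5), g1))
  sf$elevation <- lapmd_raster(matrix(0, 5, 5), g2)
  expect_error(disperse(sf, rose), "geometry")
  badrose <- manual_rose(freq = rep(0.2, 8))
  sf2 <- flat_source_field(5, 5)
  expect_error(disperse(sf2, badrose), "sum to 1")
})
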