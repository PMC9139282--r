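# Compartment geometry and density estimation.

test_that("band area of a straight segment matches the closed form", {
  # 2000 um segment, 360 um half-width: rectangle plus two end caps
  seg <- rbind(c(0, 0), c(2000, 0))
  band <- im_band(seg, halfwidth = 360)
  expected <- 2 * 0.36 * 2.0 + pi * 0.36^2
  expect_equal(region_area(band), expected, tolerance = 0.01)
  # Monte-Carlo point-in-region integration as an independent oracle
  set.seed(5)
  bb <- c(-360, 2360, -360, 360)
  pts <- cbind(runif(40000, bb[1], bb[2]), runif(40000, bb[3], bb[4]))
  mc <- mean(region_contains(band, pts)) *
    (bb[2] - bb[1]) * (bb[4] - bb[3]) / 1e6
  expect_equal(mc, expected, tolerance = 0.03)
})

test_that("band area of a circular margin matches the annulus formula", {
  ang <- seq(0, 2 * pi, length.out = 129)[-129]
  circ <- cbind(2000 * cos(ang), 2000 * sin(ang))
  band <- im_band(circ, halfwidth = 360, closed = TRUE)
  expect_equal(region_area(band), pi * (2.36^2 - 1.64^2), tolerance = 0.01)
})

test_that("degenerate band inputs are rejected", {
  seg <- rbind(c(0, 0), c(1000, 0))
  expect_error(im_band(seg, halfwidth = 0), "halfwidth")
  expect_error(im_band(seg, halfwidth = -10), "halfwidth")
  expect_error(im_band(rbind(c(0, 0)), halfwidth = 100), "2 vertices")
})

test_that("CT of a square tumor is the inner square; small tumors error", {
  sq <- region_polygon(cbind(c(0, 4000, 4000, 0), c(0, 0, 4000, 4000)))
  band <- im_band(rbind(sq$coords, sq$coords[1, ]), halfwidth = 500)
  ct <- ct_region(sq, band)
  expect_equal(region_area(ct), 9, tolerance = 0.01)
  # covering property: band + CT at least covers the tumor polygon
  expect_gte(region_area(band) + region_area(ct), region_area(sq))
  tiny <- region_polygon(cbind(c(0, 800, 800, 0), c(0, 0, 800, 800)))
  tband <- im_band(rbind(tiny$coords, tiny$coords[1, ]), halfwidth = 500)
  expect_error(ct_region(tiny, tband), "smaller halfwidth")
})

test_that("mean_density is count over area with exact polygon areas", {
  sq <- region_polygon(cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000)))
  set.seed(11)
  pts <- cbind(runif(100, 0, 1000), runif(100, 0, 1000))
  d <- mean_density(pts, sq)
  expect_identical(d$cell_count, 100L)
  expect_equal(d$area_mm2, 1)
  expect_equal(d$density, 100)
  expect_equal(mean_density(NULL, sq)$density, 0)
  # boundary points count as inside (closed-region convention)
  expect_equal(mean_density(rbind(c(0, 0), c(1000, 500)), sq)$cell_count, 2L)
})

test_that("density estimates recover a programmed Poisson intensity", {
  # homogeneous Poisson at the reference CD3-CT intensity over 4 mm^2
  sq <- region_polygon(cbind(c(0, 2000, 2000, 0), c(0, 0, 2000, 2000)))
  set.seed(21)
  n <- rpois(1, 884 * 4)
  pts <- cbind(runif(n, 0, 2000), runif(n, 0, 2000))
  d <- mean_density(pts, sq)
  expect_lt(abs(d$density - 884), 3 * sqrt(884 / 4))
})

test_that("simulated slides are deterministic and empty at zero intensity", {
  sq <- region_polygon(cbind(c(0, 3000, 3000, 0), c(0, 0, 3000, 3000)))
  zero <- simulate_slide(sq, list(CD3 = c(CT = 0, IM = 0),
                                  CD8 = c(CT = 0, IM = 0)), seed = 1)
  expect_equal(nrow(zero$cells), 0)
  int <- list(CD3 = c(CT = 884, IM = 1409), CD8 = c(CT = 358, IM = 535))
  s1 <- simulate_slide(sq, int, seed = 99)
  s2 <- simulate_slide(sq, int, seed = 99)
  expect_identical(s1$cells, s2$cells)
  expect_error(simulate_slide(sq, list(CD3 = c(CT = -1, IM = 0))), "nonnegative")
})

test_that("simulated compartment counts match Poisson moments", {
  sq <- region_polygon(cbind(c(0, 3000, 3000, 0), c(0, 0, 3000, 3000)))
  int <- list(CD3 = c(CT = 884, IM = 1409))
  s0 <- simulate_slide(sq, int, seed = 1)
  exp_ct <- 884 * s0$ct$area_mm2
  counts <- vapply(1:25, function(i) {
    s <- simulate_slide(sq, int, seed = 300 + i)
    pts <- as.matrix(s$cells[s$cells$marker == "CD3", c("x", "y")])
    mean_density(pts, s$ct)$cell_count
  }, numeric(1))
  # mean of 25 replicates within 4 SEs of the programmed expectation
  expect_lt(abs(mean(counts) - exp_ct), 4 * sqrt(exp_ct / 25))
})

test_that("mean_density of a simulated slide recovers the intensity", {
  sq <- region_polygon(cbind(c(0, 4000, 4000, 0), c(0, 0, 4000, 4000)))
  int <- list(CD8 = c(CT = 535, IM = 535))
  s <- simulate_slide(sq, int, seed = 77)
  pts <- as.matrix(s$cells[, c("x", "y")])
  d_ct <- mean_density(pts, s$ct)
  expect_lt(abs(d_ct$density - 535), 3 * sqrt(535 / d_ct$area_mm2))
})

test_that("densities are invariant under rigid motions of the scene", {
  poly <- cbind(c(0, 2500, 3000, 1000), c(0, 500, 2500, 2000))
  set.seed(31)
  pts <- cbind(runif(400, -500, 3500), runif(400, -500, 3000))
  rot <- function(m, th, dx, dy) {
    cbind(m[, 1] * cos(th) - m[, 2] * sin(th) + dx,
          m[, 1] * sin(th) + m[, 2] * cos(th) + dy)
  }
  d0 <- mean_density(pts, region_polygon(poly))
  d1 <- mean_density(rot(pts, 0.7, 123, -456),
                     region_polygon(rot(poly, 0.7, 123, -456)))
  expect_identical(d0$cell_count, d1$cell_count)
  expect_equal(d0$area_mm2, d1$area_mm2, tolerance = 1e-9)
})

test_that("halving a region leaves the expected density unchanged", {
  # same homogeneous process measured over the full and the half window
  set.seed(41)
  n <- rpois(1, 600 * 8)  # 4 x 2 mm window
  pts <- cbind(runif(n, 0, 4000), runif(n, 0, 2000))
  full <- region_polygon(cbind(c(0, 4000, 4000, 0), c(0, 0, 2000, 2000)))
  half <- region_polygon(cbind(c(0, 2000, 2000, 0), c(0, 0, 2000, 2000)))
  d_full <- mean_density(pts, full)$density
  d_half <- mean_density(pts, half)$density
  se <- sqrt(600 / 4)  # Poisson SE over the smaller window
  expect_lt(abs(d_full - d_half), 4 * se)
})

test_that("quantify_slide reports all marker x compartment densities", {
  sq <- region_polygon(cbind(c(0, 3000, 3000, 0), c(0, 0, 3000, 3000)))
  int <- list(CD3 = c(CT = 800, IM = 1200), CD8 = c(CT = 300, IM = 500))
  q <- quantify_slide(simulate_slide(sq, int, seed = 5))
  expect_setequal(paste(q$marker, q$compartment),
                  c("CD3 CT", "CD3 IM", "CD8 CT", "CD8 IM"))
  expect_true(all(q$density == q$cell_count / q$area_mm2))
})
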