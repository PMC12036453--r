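# Meniscus anatomic alignment, region slicing, station measurement.

test_that("unperturbed meniscus aligns to identity within 0.5 degrees", {
  m <- make_meniscus(rat_men_spec("lateral", seed = 1, perturb = 0))
  fr <- align_meniscus(mesh_to_points(m), "lateral")
  ang <- acos(pmin(1, (sum(diag(fr$rotation)) - 1) / 2)) * 180 / pi
  expect_lt(ang, 0.5)
  # Kasa fit of an annular band sits slightly outside the centreline
  expect_lt(abs(fr$arc_radius - 2), 0.2)
})

test_that("a 15-degree perturbation is recovered within 1 degree", {
  m0 <- make_meniscus(rat_men_spec("lateral", seed = 5, perturb = 0))
  fr0 <- align_meniscus(mesh_to_points(m0), "lateral")
  m1 <- make_meniscus(rat_men_spec("lateral", seed = 5, perturb = 15))
  fr1 <- align_meniscus(mesh_to_points(m1), "lateral")
  # recovered frames should agree regardless of the applied perturbation
  for (ax in 1:3) {
    a0 <- sort(fr0$points[, ax])
    a1 <- sort(fr1$points[, ax])
    expect_lt(max(abs(range(a0) - range(a1))), 0.035)  # ~1 deg over 2 mm
  }
})

test_that("side flag flips the bulge axis only", {
  m <- make_meniscus(rat_men_spec("lateral", seed = 2, perturb = 0))
  pts <- mesh_to_points(m)
  lat <- align_meniscus(pts, "lateral")
  med <- align_meniscus(pts, "medial")
  expect_equal(med$rotation[1, ], -lat$rotation[1, ], tolerance = 1e-6)
  expect_equal(abs(med$rotation[3, ]), abs(lat$rotation[3, ]),
               tolerance = 1e-6)
})

test_that("degenerate clouds fail meniscus alignment", {
  withr::with_seed(4, {
    ball <- matrix(stats::rnorm(3000), ncol = 3)
  })
  expect_error(align_meniscus(ball, "medial"), "principal plane")
  expect_error(align_meniscus(matrix(stats::rnorm(30), ncol = 3), "medial"),
               ">= 100 points")
})

test_that("region slices are mirror-symmetric and 3 x increment wide", {
  m <- make_meniscus(meniscus_spec(side = "lateral", arc_radius = 2,
                                   height_field = 0.8, width_field = 1.0,
                                   vertex_spacing = 0.025, seed = 3,
                                   perturb_deg = 0))
  fr <- align_meniscus(mesh_to_points(m), "lateral")
  ant <- select_region_slices(fr, "anterior", 0.1)
  pos <- select_region_slices(fr, "posterior", 0.1)
  expect_length(ant$slices, 3L)
  expect_equal(ant$plane, "sagittal")
  # symmetric generator: anterior horn mirrors posterior through y = 0
  for (k in 1:3) {
    a <- ant$slices[[k]]
    p <- pos$slices[[k]]
    expect_equal(nrow(a), nrow(p), tolerance = 0.05 * nrow(a))
    expect_equal(range(a[, 2]), range(p[, 2]), tolerance = 0.02)
    expect_equal(sort(a[, 1]), sort(-p[, 1]), tolerance = 0.03)
  }
  cen <- select_region_slices(fr, "central", 0.1)
  expect_equal(cen$plane, "coronal")
  for (k in 1:3) {
    # constant-width wedge: central slices span the full width within 1%
    expect_lt(abs(diff(range(cen$slices[[k]][, 1])) - 1.0), 0.01)
    expect_lt(diff(range(cen$centers)) - 0.2, 1e-9)
  }
})

test_that("station heights and widths match closed forms and the oracle", {
  withr::with_seed(6, {
    g <- expand.grid(x = seq(0, 1.1, by = 0.005), y = seq(0, 0.8, by = 0.005))
  })
  hw <- slice_height_width(as.matrix(g))
  expect_equal(hw$height, 0.8, tolerance = 0.01 * 0.8)
  expect_equal(hw$width, 1.1, tolerance = 0.01 * 1.1)

  # right triangle, legs 1.0 (horizontal) x 0.5 (vertical): station extents
  # against the brute-force oracle, and the analytic tallest-station height
  tr <- expand.grid(x = seq(0, 1, by = 0.004), y = seq(0, 0.5, by = 0.004))
  tr <- as.matrix(tr[tr$y <= 0.5 * (1 - tr$x), ])
  got <- slice_height_width(tr)
  orc <- oracle_station_extents(tr)
  expect_equal(got$height, orc$height, tolerance = 1e-12)
  expect_equal(got$width, orc$width, tolerance = 1e-12)
  # closed form for the tallest station is 0.475 at the station midpoint,
  # up to one station-width effect (the station spans x in [0, 0.1])
  expect_lt(abs(got$height - 0.5 * (1 - 1 / 20)), 0.5 / 10)

  # sparse degenerate slice: one point per station -> zero extents, flagged
  sparse <- cbind(seq(0, 1, length.out = 10), seq(0, 1, length.out = 10))
  expect_warning(hw0 <- slice_height_width(sparse), "degenerate")
  expect_equal(hw0$height, 0)
  expect_error(slice_height_width(cbind(rep(0.5, 12), seq_len(12))),
               "zero extent")
})

test_that("station refinement never raises the slice maximum", {
  # a coarse station is the union of two nested fine stations, and the
  # extent of a union is at least the extent of each part, so doubling the
  # station count can only keep or lower the per-slice maximum
  withr::with_seed(8, {
    for (i in 1:10) {
      n <- sample(200:500, 1)
      s <- cbind(stats::runif(n), stats::runif(n) * 0.5)
      c10 <- slice_height_width(s, 10)
      c20 <- slice_height_width(s, 20)   # nested station boundaries
      expect_lte(c20$height, c10$height + 1e-12)
      expect_lte(c20$width, c10$width + 1e-12)
    }
  })
})

test_that("region_measure averages three slices and keeps the audit trail", {
  mk <- function(h, w) cbind(stats::runif(200) * w, stats::runif(200) * h)
  withr::with_seed(9, {
    rs <- structure(list(region = "anterior", plane = "sagittal",
                         slices = list(mk(0.2, 1), mk(0.3, 1), mk(0.4, 1)),
                         centers = 1:3, increment = 0.1),
                    class = "region_slices")
  })
  m <- region_measure(rs)
  expect_equal(dim(m$per_slice), c(3L, 2L))
  expect_equal(m$height, mean(m$per_slice[, 1]))
  expect_equal(m$width, mean(m$per_slice[, 2]))
  expect_equal(m$height, 0.3, tolerance = 0.02)
})

test_that("regional fields are recovered and mirror-consistent", {
  lat <- measure_meniscus(make_meniscus(rat_men_spec("lateral", seed = 10)),
                          increment = 0.1)
  med <- measure_meniscus(make_meniscus(rat_men_spec("medial", seed = 10)),
                          increment = 0.1)
  tru <- meniscus_truth(make_meniscus(rat_men_spec("lateral", seed = 10)))
  for (rg in c("anterior", "central", "posterior")) {
    t_h <- tru$height_mm[tru$region == rg]
    t_w <- tru$width_mm[tru$region == rg]
    expect_lt(abs(lat$height_mm[lat$region == rg] - t_h) / t_h, 0.05)
    expect_lt(abs(lat$width_mm[lat$region == rg] - t_w) / t_w, 0.05)
    expect_lt(abs(lat$width_mm[lat$region == rg] -
                  med$width_mm[med$region == rg]) /
              lat$width_mm[lat$region == rg], 0.01)
  }
})

test_that("inflating the width field inflates every recovered width", {
  base <- measure_meniscus(make_meniscus(rat_men_spec("lateral", seed = 12,
                                                      perturb = 0)),
                           increment = 0.1)
  up <- measure_meniscus(make_meniscus(rat_men_spec("lateral", seed = 12,
                                                    perturb = 0,
                                                    scale = 1.1)),
                         increment = 0.1)
  expect_true(all(up$width_mm > base$width_mm))
  expect_true(all(up$height_mm > base$height_mm))
})
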