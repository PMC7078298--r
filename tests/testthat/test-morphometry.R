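test_that("area fraction matches direct pixel proportions", {
  m <- matrix(0, 10, 10)
  m[1:10, 1] <- 255  # exactly 10% of pixels bright
  frac <- area_fraction(field_image(m, pixel_size_um = 2))
  expect_equal(as.numeric(frac), 0.10)
  expect_equal(attr(frac, "area_um2"), 10 * 4)
  # all-bright field
  expect_equal(as.numeric(area_fraction(field_image(matrix(200, 5, 5), 1))),
               1.0)
  # empty field -> 0
  expect_equal(as.numeric(area_fraction(field_image(matrix(0, 5, 5), 1))), 0)
  # random field equals the mask-sum oracle
  set.seed(4)
  r <- matrix(runif(2500, 0, 255), 50, 50)
  img <- field_image(r, pixel_size_um = 1)
  expect_equal(as.numeric(area_fraction(img)),
               sum(r / max(r) >= 0.2) / 2500)
})

test_that("area fraction is brightness invariant and monotone in threshold", {
  set.seed(5)
  r <- matrix(runif(400, 0, 200), 20, 20)
  f1 <- as.numeric(area_fraction(field_image(r, 1)))
  f2 <- as.numeric(area_fraction(field_image(2.5 * r, 1)))
  expect_equal(f1, f2)
  fr <- vapply(c(0.1, 0.2, 0.4, 0.6), function(th) {
    as.numeric(area_fraction(field_image(r, 1),
                             detection_params(threshold = th)))
  }, double(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("planted pixel fraction is recovered exactly on noise-free fields", {
  fs <- field_spec(n_cells = 15, seed = 9, field_px = 256, n_z = 1,
                   noise_sd = 0, background_level = 0)
  r <- render_field(fs)
  img <- max_project(r$stack, "iba1")
  expect_equal(as.numeric(area_fraction(img)), r$truth$area_fraction)
})

test_that("soma area follows the shoelace formula on contours", {
  square <- cbind(c(0, 0, 10, 10), c(0, 10, 10, 0))
  expect_equal(soma_area(square), 100)
  tri <- cbind(c(0, 4, 0), c(0, 0, 3))
  expect_equal(soma_area(tri), 6)
  # mask pathway: pixel count times pixel area
  mask <- matrix(FALSE, 10, 10); mask[2:5, 2:5] <- TRUE
  expect_equal(soma_area(mask, pixel_size_um = 2), 16 * 4)
  expect_error(soma_area(mask), "pixel_size_um")
  # self-intersecting bow-tie is rejected
  bowtie <- cbind(c(0, 10, 0, 10), c(0, 10, 10, 0))
  expect_error(soma_area(bowtie), "self-intersecting")
})

test_that("shoelace agrees with Pick's theorem on lattice polygons", {
  set.seed(31)
  for (i in 1:50) {
    poly <- random_lattice_polygon()
    expect_equal(polygon_area(poly), oracle_pick_area(poly))
  }
})

test_that("planted soma discs are recovered within rasterization error", {
  r <- render_single_cell(seed = 13)
  img <- max_project(r$stack, "iba1")
  truth <- r$truth$cells
  somas <- soma_areas_field(img)
  expect_length(somas, 1)
  # catalogued area is the exact rasterized pixel count
  expect_equal(somas, truth$soma_area_um2)
  # and the raster area is within tolerance of the analytic disc area
  analytic <- pi * truth$soma_radius_um^2
  expect_lt(abs(somas - analytic) / analytic, 0.10)
})

test_that("arbor area equals the brute-force hull oracle", {
  square <- cbind(c(0, 0, 10, 10), c(0, 10, 10, 0))
  expect_equal(as.numeric(arbor_area(square)), 100)
  collinear <- cbind(c(0, 5, 10), c(0, 5, 10))
  a <- arbor_area(collinear)
  expect_equal(as.numeric(a), 0)
  expect_true(attr(a, "degenerate"))
  expect_true(attr(arbor_area(cbind(c(0, 1), c(0, 1))), "degenerate"))
  set.seed(17)
  for (i in 1:200) {
    n <- sample(3:20, 1)
    pts <- cbind(runif(n, 0, 50), runif(n, 0, 50))
    expect_equal(as.numeric(arbor_area(pts)), oracle_hull_area(pts),
                 tolerance = 1e-9)
  }
  # permutation invariance
  pts <- cbind(runif(10, 0, 50), runif(10, 0, 50))
  expect_equal(as.numeric(arbor_area(pts)),
               as.numeric(arbor_area(pts[sample(10), ])))
})

test_that("hull area dominates any polygon through a subset of tips", {
  set.seed(23)
  pts <- cbind(runif(12, 0, 40), runif(12, 0, 40))
  hull <- as.numeric(arbor_area(pts))
  for (i in 1:20) {
    sub <- pts[sample(12, sample(3:8, 1)), ]
    expect_gte(hull + 1e-9, as.numeric(arbor_area(sub)))
  }
})

test_that("skeleton tips are found on canonical shapes", {
  # straight 1-px line -> 2 tips
  line <- matrix(FALSE, 15, 15)
  line[8, 3:13] <- TRUE
  tips <- extract_tips(line, pixel_size_um = 1)
  expect_equal(nrow(tips), 2)
  expect_setequal(tips$x_um, c(2, 12))
  # plus-shaped mask -> 4 tips
  plus <- matrix(FALSE, 21, 21)
  plus[11, 3:19] <- TRUE
  plus[3:19, 11] <- TRUE
  expect_equal(nrow(extract_tips(plus, pixel_size_um = 1)), 4)
  expect_error(extract_tips(matrix(FALSE, 5, 5)), "empty")
})

test_that("synthetic star cells yield exactly k tips on noise-free rasters", {
  for (seed in 1:8) {
    k <- 4 + seed %% 4
    r <- render_single_cell(seed, k = k)
    img <- max_project(r$stack, "iba1")
    mask <- apply_threshold(normalize_field(img))
    tips <- extract_tips(mask, pixel_size_um = img$pixel_size_um)
    expect_equal(nrow(tips), k)
  }
})

test_that("vertical-process puncta are counted and merged correctly", {
  blank <- field_image(matrix(0, 128, 128), pixel_size_um = 1.5)
  expect_equal(as.numeric(count_vertical_processes(blank)), 0)
  fs <- field_spec(layer = "OPL_OS", n_cells = 0, n_puncta = 15, seed = 3,
                   field_px = 256, noise_sd = 0, background_level = 0)
  pp <- render_puncta_plane(fs)
  expect_equal(as.numeric(count_vertical_processes(pp$image)), 15)
  expect_equal(nrow(pp$truth$puncta), 15)
  # two puncta closer than the merge radius count once
  m <- matrix(0, 100, 100)
  m[50:51, 50:51] <- 200
  m[50:51, 54:55] <- 200  # 4 um apart at 1 um/px, min_distance 8
  expect_equal(as.numeric(count_vertical_processes(
    field_image(m, pixel_size_um = 1))), 1)
})
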