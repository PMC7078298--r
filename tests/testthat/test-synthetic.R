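test_that("empty specs render uniform fields with empty ground truth", {
  fs <- field_spec(n_cells = 0, background_level = 5, noise_sd = 0,
                   field_px = 64, n_z = 2)
  r <- render_field(fs)
  expect_true(all(r$stack$channels$iba1 == 5))
  expect_equal(nrow(r$truth$cells), 0)
  expect_equal(r$truth$area_fraction, 0)
})

test_that("rendering is bit-identical under a fixed seed", {
  fs <- field_spec(n_cells = 20, min_spacing_um = 40, seed = 7,
                   field_px = 256, n_z = 2, intensity_mean = 60)
  r1 <- render_field(fs)
  r2 <- render_field(fs)
  expect_identical(r1$stack$channels, r2$stack$channels)
  expect_identical(r1$truth$cells, r2$truth$cells)
  # different seed -> different field
  r3 <- render_field(field_spec(n_cells = 20, min_spacing_um = 40,
                                seed = 8, field_px = 256, n_z = 2,
                                intensity_mean = 60))
  expect_false(identical(r1$stack$channels$iba1, r3$stack$channels$iba1))
})

test_that("planted somata respect the mosaic spacing and stay in the field", {
  fs <- field_spec(n_cells = 20, min_spacing_um = 40, seed = 7,
                   field_px = 256)
  r <- render_field(fs)
  cells <- r$truth$cells
  expect_equal(nrow(cells), 20)
  d <- as.matrix(dist(cbind(cells$y_um, cells$x_um)))
  expect_gte(min(d[upper.tri(d)]), 40)
  side <- sqrt(0.1502) * 1000
  expect_true(all(cells$y_um >= 0 & cells$y_um <= side))
  expect_true(all(cells$x_um >= 0 & cells$x_um <= side))
  tips <- r$truth$tips
  expect_true(all(tips$y_um >= 0 & tips$y_um <= side))
  expect_true(all(tips$x_um >= 0 & tips$x_um <= side))
})

test_that("infeasible packings error out", {
  expect_error(field_spec(n_cells = 400, min_spacing_um = 45),
               "infeasible")
})

test_that("puncta planes differ across seeds but not across identical specs", {
  base <- field_spec(layer = "OPL_OS", n_cells = 0, n_puncta = 12,
                     seed = 5, field_px = 128)
  p1 <- render_puncta_plane(base)
  p2 <- render_puncta_plane(base)
  expect_identical(p1$image$pixels, p2$image$pixels)
  other <- field_spec(layer = "OPL_OS", n_cells = 0, n_puncta = 12,
                      seed = 6, field_px = 128)
  p3 <- render_puncta_plane(other)
  expect_false(isTRUE(all.equal(p1$truth$puncta, p3$truth$puncta)))
  expect_equal(nrow(p3$truth$puncta), 12)
})

test_that("the green channel realises the configured mean intensity", {
  fs <- field_spec(n_cells = 0, intensity_mean = 51, noise_sd = 0,
                   field_px = 64, n_z = 1)
  r <- render_field(fs)
  expect_equal(r$truth$intensity_percent, 100 * 51 / 255)
  img <- max_project(r$stack, "p2ry12")
  expect_equal(as.numeric(mean_intensity_percent(img)), 20)
})

test_that("the default cohort profile encodes the expected qualitative course", {
  prof <- default_cohort_profile()
  oht <- prof$effects[prof$effects$group == "OHT", ]
  oht <- oht[order(oht$day), ]
  # plexiform count peaks at day 3-5 and day 5 exceeds day 1
  expect_true(which.max(oht$count_mult) %in% c(2, 3))
  expect_gt(oht$count_mult[3], oht$count_mult[1])
  # soma maximal at day 1; P2RY12 trough at day 3-5; VP increase monotone
  expect_equal(which.max(oht$soma_mult), 1L)
  expect_true(which.min(oht$intensity_mult) %in% c(2, 3))
  expect_true(all(diff(oht$vp_count) > 0))
  ctr <- prof$effects[prof$effects$group == "contralateral", ]
  ctr <- ctr[order(ctr$day), ]
  # contralateral: soma maximal at day 3, plexiform counts unchanged
  expect_equal(which.max(ctr$soma_mult), 2L)
  expect_true(all(ctr$count_mult == 1))
})

test_that("cohort manifests are complete, deterministic and exportable", {
  cs <- cohort_spec(n_animals = 2, days = c(1, 3), fields_per_animal = 2,
                    field_px = 64, n_z = 1, master_seed = 42)
  co <- generate_cohort(cs)
  man <- tidy(co)
  # per (group, day): 2 animals x 5 layers x 2 fields
  expect_equal(nrow(man), (2 + 2 * 2 * 2) * 5 * 2)
  expect_setequal(unique(man$group), c("naive", "OHT", "contralateral"))
  expect_equal(sum(man$group == "naive"), 2 * 5 * 2)
  co2 <- generate_cohort(cs)
  expect_identical(man, tidy(co2))
  # export writes TIFFs, ground truth and a manifest
  dir <- withr::local_tempdir()
  generate_cohort(cs, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "cohort.yaml")))
  tifs <- list.files(dir, pattern = "\\.tif$")
  expect_equal(length(tifs), nrow(man))
  js <- jsonlite::read_json(file.path(
    dir, sub("\\.tif$", ".json", man$file[man$layer == "OPL"][1])))
  expect_true(all(c("cells", "area_fraction") %in% names(js)))
})

test_that("planted OHT density rises from day 1 to day 5 in the manifest specs", {
  cs <- cohort_spec(n_animals = 2, days = c(1, 5), fields_per_animal = 1,
                    field_px = 64, n_z = 1, master_seed = 10)
  co <- generate_cohort(cs)
  man <- co$manifest
  opl <- which(man$layer == "OPL" & man$group == "OHT")
  d1 <- sapply(opl[man$day[opl] == 1], function(i) co$field_specs[[i]]$n_cells)
  d5 <- sapply(opl[man$day[opl] == 5], function(i) co$field_specs[[i]]$n_cells)
  expect_gt(mean(d5), mean(d1))
})
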