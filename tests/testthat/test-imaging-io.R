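test_that("TIFF stacks round-trip byte-identically through write/read", {
  set.seed(42)
  planes <- array(sample(0:255, 16 * 32 * 32, replace = TRUE),
                  dim = c(16, 32, 32))
  stk <- image_stack(list(iba1 = planes), pixel_size_um = 0.31)
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(stk, path)
  back <- read_stack(path, pixel_size_um = 0.31)
  expect_equal(dim(back$channels$iba1), c(16, 32, 32))
  expect_equal(back$channels$iba1, planes, ignore_attr = TRUE)
  expect_named(back$channels, "iba1")
})

test_that("two-channel stacks map channels by configured order", {
  red <- array(sample(0:255, 4 * 16 * 16, replace = TRUE), c(4, 16, 16))
  green <- array(sample(0:255, 4 * 16 * 16, replace = TRUE), c(4, 16, 16))
  stk <- image_stack(list(iba1 = red, p2ry12 = green), pixel_size_um = 0.5)
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(stk, path)
  back <- read_stack(path, pixel_size_um = 0.5,
                     channel_order = c("iba1", "p2ry12"))
  expect_equal(back$channels$iba1, red, ignore_attr = TRUE)
  expect_equal(back$channels$p2ry12, green, ignore_attr = TRUE)
  # channel-count mismatch is an error
  expect_error(read_stack(path, pixel_size_um = 0.5,
                          channel_order = c("a", "b", "c")),
               "not divisible")
})

test_that("16-bit pixel content survives a round trip", {
  planes <- array(sample(0:65535, 2 * 8 * 8, replace = TRUE), c(2, 8, 8))
  stk <- image_stack(list(iba1 = planes), pixel_size_um = 1,
                     bit_depth = 16)
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(stk, path)
  back <- read_stack(path, pixel_size_um = 1, bit_depth = 16)
  expect_equal(back$channels$iba1, planes, ignore_attr = TRUE)
})

test_that("max projection equals the per-pixel maximum oracle", {
  set.seed(7)
  a <- array(sample(0:255, 8 * 20 * 20, replace = TRUE), c(8, 20, 20))
  stk <- image_stack(list(iba1 = a), pixel_size_um = 0.76)
  proj <- max_project(stk, "iba1")
  oracle <- apply(a, c(2, 3), max)  # brute-force per-pixel max
  expect_identical(proj$pixels, oracle)
  expect_equal(proj$pixel_size_um, 0.76)
  # sparse case: single bright pixel among zero planes
  b <- array(0, c(2, 5, 5)); b[2, 3, 4] <- 200
  proj2 <- max_project(image_stack(list(iba1 = b), pixel_size_um = 1))
  expect_equal(proj2$pixels[3, 4], 200)
  expect_equal(sum(proj2$pixels), 200)
})

test_that("projection of a single plane is the identity and re-projection idempotent", {
  m <- matrix(runif(64, 0, 255), 8, 8)
  stk <- image_stack(list(iba1 = array(m, c(1, 8, 8))), pixel_size_um = 1)
  proj <- max_project(stk)
  expect_equal(proj$pixels, m)
  # re-wrap the projection as a 1-plane stack: identity again
  stk2 <- image_stack(list(iba1 = array(proj$pixels, c(1, 8, 8))),
                      pixel_size_um = 1)
  expect_equal(max_project(stk2)$pixels, proj$pixels)
})

test_that("projection commutes with monotone pixel rescaling", {
  set.seed(1)
  a <- array(sample(0:100, 4 * 10 * 10, replace = TRUE), c(4, 10, 10))
  stk <- image_stack(list(iba1 = a), pixel_size_um = 1)
  stk2 <- image_stack(list(iba1 = a * 2), pixel_size_um = 1)
  expect_equal(max_project(stk2)$pixels, 2 * max_project(stk)$pixels)
})

test_that("stack invariants are enforced", {
  expect_error(image_stack(list(iba1 = array(0, c(2, 4, 4)),
                                p2ry12 = array(0, c(2, 5, 5))),
                           pixel_size_um = 1), "share one shape")
  expect_error(image_stack(list(iba1 = array(300, c(1, 2, 2))),
                           pixel_size_um = 1, bit_depth = 8),
               "outside")
  expect_error(max_project(image_stack(list(iba1 = array(0, c(1, 2, 2))),
                                       pixel_size_um = 1), "p2ry12"),
               "not in stack")
  img <- field_image(matrix(0, 10, 20), pixel_size_um = 2)
  expect_equal(field_area_mm2(img), 10 * 20 * 4 / 1e6)
})
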