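test_that("uniform images land on the documented side of the tissue threshold", {
  expect_true(all(class_mask(threshold_tissue(flat_image(c(150, 150, 150))), "tissue")))
  expect_false(any(class_mask(threshold_tissue(flat_image(c(250, 250, 250))), "tissue")))
  ## boundary convention: exactly 205 is background (strict less-than)
  expect_false(any(class_mask(threshold_tissue(flat_image(c(205, 205, 205))), "tissue")))
})

test_that("thresholding smooths the mean-RGB image before the cutoff", {
  ## one dark pixel in a white field: smoothing dilutes it above threshold
  d <- array(255, c(32, 32, 3))
  d[16, 16, ] <- 0
  img <- calibrated_image(d, 7.03)
  expect_false(any(class_mask(threshold_tissue(img), "tissue")))
  ## a solid dark block survives smoothing
  d[8:24, 8:24, ] <- 60
  img2 <- calibrated_image(d, 7.03)
  expect_true(any(class_mask(threshold_tissue(img2), "tissue")))
})

test_that("minimum object size removes exactly the undersized blobs", {
  px <- 7.03
  m <- matrix(0, 250, 250)
  m[26:225, 26:225] <- 1 # 200x200 px ~ 1.977e6 um2
  o <- create_objects(bin_mask(m, px), 10000, 100000)
  expect_equal(nrow(o$regions), 1)
  expect_equal(o$regions$n_pixels, 40000L)
  ## polygon area within one boundary-pixel band of the pixel-count area
  pix_area <- 40000 * px^2
  band <- 4 * 200 * px^2 # perimeter x one pixel
  expect_lt(abs(o$regions$area_um2 - pix_area), band)

  small <- matrix(0, 50, 50)
  small[20:29, 20:29] <- 1 # 10x10 px ~ 4942 um2
  expect_equal(nrow(create_objects(bin_mask(small, px), 10000, 100000)$regions), 0)
  expect_equal(nrow(create_objects(bin_mask(small, px), 1000, 100000)$regions), 1)
})

test_that("minimum hole size fills exactly the undersized holes", {
  px <- 7.03
  m <- matrix(0, 150, 150)
  m[11:140, 11:140] <- 1
  m[51:90, 51:90] <- 0 # 40x40 px hole ~ 79,076 um2
  filled <- create_objects(bin_mask(m, px), 10000, 100000)
  expect_equal(filled$regions$n_pixels, 130L * 130L) # hole absorbed
  kept <- create_objects(bin_mask(m, px), 10000, 1000)
  expect_equal(kept$regions$n_pixels, 130L * 130L - 1600L) # hole preserved
})

test_that("objects are 8-connected, holes 4-connected", {
  px <- 100 # big pixels so nothing is removed
  m <- matrix(0, 8, 8)
  m[2, 2] <- 1
  m[3, 3] <- 1 # diagonal touch: one object
  o <- create_objects(bin_mask(m, px), 0, 0)
  expect_equal(nrow(o$regions), 1)
  ## a diagonal background corridor does not merge two holes 4-connectedly
  ring <- matrix(1, 9, 9)
  ring[3, 3] <- 0
  ring[4, 4] <- 0 # two diagonal holes, each 1 px
  o2 <- create_objects(bin_mask(ring, px), 0, 1.5 * px^2)
  expect_equal(o2$regions$n_pixels, 81L) # both 1-px holes filled separately
})

test_that("empty masks give empty objects, and areas are additive", {
  px <- 7.03
  empty <- create_objects(bin_mask(matrix(0, 20, 20), px), 10000, 100000)
  expect_equal(nrow(empty$regions), 0)
  expect_equal(nrow(measure_area(empty)), 0)

  two <- matrix(0, 60, 120)
  two[11:40, 11:40] <- 1
  two[11:40, 71:100] <- 1 # two identical squares
  o <- create_objects(bin_mask(two, px), 1000, 1000)
  expect_equal(nrow(o$regions), 2)
  a <- measure_area(o)
  expect_equal(a$area_um2, 2 * o$regions$area_um2[1])
})

test_that("polygon area agrees with pixel counting within the perimeter bound", {
  px <- 7.03
  withr::with_seed(7, {
    for (rep in 1:5) {
      m <- matrix(0, 60, 60)
      for (b in 1:3) {
        r0 <- sample(5:40, 1)
        c0 <- sample(5:40, 1)
        m[r0:(r0 + sample(5:15, 1)), c0:(c0 + sample(5:15, 1))] <- 1
      }
      o <- create_objects(bin_mask(m, px), 0, 0)
      npix <- sum(o$regions$n_pixels)
      perim <- sum(abs(diff(m)) > 0) + sum(abs(t(diff(t(m)))) > 0) + 100
      expect_lt(
        abs(sum(o$regions$area_um2) - npix * px^2),
        perim * px^2
      )
    }
  })
})

test_that("raising the size rules is monotone and re-creation is a fixed point", {
  px <- 7.03
  withr::with_seed(8, {
    m <- matrix(rbinom(80 * 80, 1, 0.45), 80, 80)
    m <- EBImage::dilate(m, EBImage::makeBrush(5, "disc")) # smoother blobs
    total_area <- function(min_obj, min_hole) {
      sum(create_objects(bin_mask(m, px), min_obj, min_hole)$regions$n_pixels)
    }
    sizes <- c(0, 2000, 10000, 50000)
    areas_obj <- vapply(sizes, function(s) total_area(s, 100000), numeric(1))
    expect_true(all(diff(areas_obj) <= 0)) # larger min object never adds area
    areas_hole <- vapply(sizes, function(s) total_area(1000, s), numeric(1))
    expect_true(all(diff(areas_hole) >= 0)) # larger min hole never removes area

    o <- create_objects(bin_mask(m, px), 10000, 20000)
    o2 <- create_objects(o$mask, 10000, 20000)
    expect_identical(unclass(o2$mask), unclass(o$mask))
    expect_equal(o2$regions$area_um2, o$regions$area_um2)
  })
})

test_that("objects export as GeoJSON with micrometre coordinates", {
  px <- 7.03
  m <- matrix(0, 30, 30)
  m[10:20, 12:22] <- 1
  o <- create_objects(bin_mask(m, px), 0, 0)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_geojson(o, path)
  gj <- jsonlite::read_json(path)
  expect_equal(gj$type, "FeatureCollection")
  expect_length(gj$features, 1)
  f <- gj$features[[1]]
  expect_equal(f$properties$class, "tissue")
  expect_equal(f$properties$area_um2, o$regions$area_um2[1], tolerance = 1e-9)
  xs <- vapply(f$geometry$coordinates[[1]][[1]], function(p) p[[1]], numeric(1))
  expect_true(all(xs >= 0 & xs <= 30 * px)) # coordinates are physical
})
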