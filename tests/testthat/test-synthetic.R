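test_that("generation is seeded-deterministic and partitions every pixel", {
  cfg <- small_config(seed = 11, age_group = 25)
  g1 <- generate_tissue_image(cfg)
  g2 <- generate_tissue_image(cfg)
  expect_identical(g1$image$data, g2$image$data)
  expect_identical(unclass(g1$truth), unclass(g2$truth))
  expect_true(all(unclass(g1$truth) %in% 1:5)) # exactly one class per pixel
  expect_equal(nrow(g1$artifacts), 0)
})

test_that("background pixels are bright: mean RGB above the tissue threshold", {
  for (s in 1:3) {
    g <- generate_tissue_image(small_config(seed = s, age_group = c(4, 49, 67)[s]))
    bg <- class_mask(g$truth, "background")
    mean_rgb <- (g$image$data[, , 1] + g$image$data[, , 2] + g$image$data[, , 3]) / 3
    expect_gt(min(mean_rgb[bg]), 205)
  }
})

test_that("every epithelium pixel lies within the configured band of the surface", {
  cfg <- small_config(seed = 3, age_group = 49)
  g <- generate_tissue_image(cfg)
  epi <- class_mask(g$truth, "epithelium")
  not_mucosa <- !class_mask(g$truth, "mucosa")
  d <- EBImage::distmap(matrix(as.numeric(!not_mucosa), nrow(epi), ncol(epi)))
  band_px <- cfg$epithelial_band_um / cfg$pixel_size_um
  expect_lte(max(d[epi]), band_px + 1)
})

test_that("age defaults map monotonically to morphology", {
  cfgs <- lapply(c(4, 14, 25, 49, 67), function(a) small_config(age_group = a))
  vac <- vapply(cfgs, `[[`, numeric(1), "vacuolation_fraction")
  spc <- vapply(cfgs, `[[`, numeric(1), "villus_spacing_um")
  expect_true(all(diff(vac) <= 0)) # younger -> more vacuolation
  expect_true(all(diff(spc) >= 0)) # younger -> tighter packing
})

test_that("generator rejects images too small for one villus", {
  expect_error(
    generator_config(image_size_px = c(60, 60), age_group = 49),
    "too small"
  )
  expect_error(generator_config(age_group = 12), "age_group")
  expect_error(small_config(vacuolation_fraction = 1.4), "\\[0, 1\\]")
})

test_that("artifact injection with all flags off is the identity", {
  g <- generate_tissue_image(small_config(seed = 21))
  out <- inject_artifacts(g$image, g$truth, list(), seed = 5)
  expect_identical(out$image$data, g$image$data)
  expect_identical(unclass(out$truth), unclass(g$truth))
  expect_equal(nrow(out$artifacts), 0)
})

test_that("luminal debris stains the lumen without changing tissue area", {
  g <- generate_tissue_image(small_config(seed = 22))
  out <- inject_artifacts(g$image, g$truth, list(luminal_debris = TRUE), seed = 7)
  expect_gte(nrow(out$artifacts), 1)
  expect_true(all(out$artifacts$class == "luminal_debris"))
  expect_identical(class_mask(out$truth, "tissue"), class_mask(g$truth, "tissue"))
  debris <- class_mask(out$truth, "lumen_content")
  expect_gt(sum(debris), 0)
  expect_true(all(class_mask(g$truth, "background")[debris])) # carved from lumen only
  mean_rgb <- (out$image$data[, , 1] + out$image$data[, , 2] + out$image$data[, , 3]) / 3
  expect_lt(mean(mean_rgb[debris]), 205) # stained, i.e. reads as tissue to step 1
})

test_that("edema vessels are unstained but remain tissue in the ground truth", {
  g <- generate_tissue_image(small_config(seed = 23))
  out <- inject_artifacts(g$image, g$truth, list(edema_vessels = TRUE), seed = 9)
  ves <- dplyr::filter(out$artifacts, class == "edema_vessel")
  expect_gte(nrow(ves), 1)
  ## vessel pixels: bright interior, still labelled submucosa/muscularis
  changed <- out$image$data[, , 1] != g$image$data[, , 1]
  expect_gt(sum(changed), 0)
  mean_rgb <- (out$image$data[, , 1] + out$image$data[, , 2] + out$image$data[, , 3]) / 3
  expect_gt(min(mean_rgb[changed]), 205)
  expect_true(all(class_mask(out$truth, "submucosa_muscularis")[changed]))
})

test_that("crypt abscesses carve recorded lumina out of the lamina propria", {
  g <- generate_tissue_image(small_config(seed = 24))
  out <- inject_artifacts(g$image, g$truth, list(crypt_abscesses = TRUE), seed = 13)
  abs_rec <- dplyr::filter(out$artifacts, class == "crypt_abscess")
  expect_gte(nrow(abs_rec), 1)
  expect_true(all(abs_rec$area_um2 > 0))
  ## abscess lumina are neither epithelium nor lamina propria
  lum <- class_mask(out$truth, "lumen_content")
  expect_equal(sum(lum) * g$image$pixel_size_um^2, sum(abs_rec$area_um2))
  expect_true(all(class_mask(g$truth, "lamina_propria")[lum])) # targeted compartment
})

test_that("annotation strokes are sparse, pure and reproducible", {
  g <- generate_tissue_image(small_config(seed = 31))
  ann <- sample_annotations(g$truth, c("mucosa", "submucosa_muscularis"),
    strokes_per_class = 4, stroke_radius_um = 10, seed = 17
  )
  expect_s3_class(ann, "annotation_set")
  expect_equal(nrow(ann), 8) # exactly the requested stroke count
  expect_equal(as.vector(table(ann$class)[c("mucosa", "submucosa_muscularis")]), c(4L, 4L))
  ## purity: every stroke pixel carries its class's ground-truth label
  for (k in seq_len(nrow(ann))) {
    m <- class_mask(g$truth, ann$class[k])
    expect_true(all(m[ann$pixels[[k]]]))
  }
  ## sparsity: annotated pixels are a small fraction of the image
  expect_lt(sum(ann$n_pixels), 0.05 * prod(dim(g$truth)))
  ann2 <- sample_annotations(g$truth, c("mucosa", "submucosa_muscularis"),
    strokes_per_class = 4, stroke_radius_um = 10, seed = 17
  )
  expect_identical(ann$pixels, ann2$pixels)
})

test_that("empty and infeasible annotation requests are handled", {
  g <- generate_tissue_image(small_config(seed = 32))
  empty <- sample_annotations(g$truth, c("mucosa"), strokes_per_class = 0, seed = 1)
  expect_equal(nrow(empty), 0)
  ## a brush far wider than the epithelial band cannot fit
  expect_error(
    sample_annotations(g$truth, "epithelium", 1, stroke_radius_um = 120, seed = 1),
    "too small"
  )
})

test_that("cohorts have the requested shape and are element-wise reproducible", {
  co <- small_cohort(2, seed = 51)
  expect_equal(nrow(co), 10)
  expect_equal(as.vector(table(co$age_group)), rep(2L, 5))
  co2 <- small_cohort(2, seed = 51)
  expect_identical(co$image[[7]]$data, co2$image[[7]]$data)
  expect_identical(unclass(co$truth[[3]]), unclass(co2$truth[[3]]))
  ## age effect: young sections carry more pale vacuolated epithelium than old
  pale_frac <- function(row) {
    epi <- class_mask(co$truth[[row]], "epithelium")
    r <- co$image[[row]]$data[, , 1]
    mean(r[epi] > 170) # vacuolated/goblet paint is far paler than dark epithelium
  }
  young <- mean(vapply(which(co$age_group == 4), pale_frac, numeric(1)))
  old <- mean(vapply(which(co$age_group == 67), pale_frac, numeric(1)))
  expect_gt(young, old)
})
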