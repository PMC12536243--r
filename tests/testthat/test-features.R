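test_that("every filter matches dense brute-force convolution on 32x32 input", {
  set.seed(101)
  img <- matrix(rnorm(32 * 32, 120, 30), 32, 32)
  for (sigma in c(1, 2)) {
    g <- gaussian_kernel(sigma)
    gx <- gaussian_kernel(sigma, dx = 1)
    gy <- gaussian_kernel(sigma, dy = 1)
    gxx <- gaussian_kernel(sigma, dx = 2)
    gyy <- gaussian_kernel(sigma, dy = 2)
    gxy <- gaussian_kernel(sigma, dx = 1, dy = 1)
    margin <- (nrow(g) - 1) / 2
    interior <- interior_idx(32, 32, margin)

    check <- function(fast, slow) expect_lt(max(abs(fast[interior] - slow[interior])), 1e-6)
    check(conv2_reflect(img, g), dense_conv_valid(img, g))
    ## gaussian
    check(intestseg:::feature_response(img, "gaussian", sigma), dense_conv_valid(img, g))
    ## laplacian of gaussian
    check(
      intestseg:::feature_response(img, "laplacian_of_gaussian", sigma),
      dense_conv_valid(img, gxx + gyy)
    )
    ## weighted deviation
    wd_oracle <- sqrt(pmax(0, dense_conv_valid(img^2, g) - dense_conv_valid(img, g)^2))
    check(intestseg:::feature_response(img, "weighted_deviation", sigma), wd_oracle)
    ## gradient magnitude
    gm_oracle <- sqrt(dense_conv_valid(img, gx)^2 + dense_conv_valid(img, gy)^2)
    check(intestseg:::feature_response(img, "gradient_magnitude", sigma), gm_oracle)
    ## hessian determinant
    hd_oracle <- dense_conv_valid(img, gxx) * dense_conv_valid(img, gyy) -
      dense_conv_valid(img, gxy)^2
    check(intestseg:::feature_response(img, "hessian_determinant", sigma), hd_oracle)
  }
})

test_that("structure-tensor coherence matches a brute-force computation", {
  set.seed(102)
  img <- matrix(rnorm(32 * 32, 0, 10), 32, 32)
  sigma <- 1
  g <- gaussian_kernel(sigma)
  ## double margin: gradient pass then tensor smoothing pass
  margin <- nrow(g) - 1
  interior <- interior_idx(32, 32, margin)
  ix <- dense_conv_valid(img, gaussian_kernel(sigma, dx = 1))
  iy <- dense_conv_valid(img, gaussian_kernel(sigma, dy = 1))
  jxx <- dense_conv_valid(ix^2, g)
  jyy <- dense_conv_valid(iy^2, g)
  jxy <- dense_conv_valid(ix * iy, g)
  oracle <- sqrt((jxx - jyy)^2 + 4 * jxy^2) / (jxx + jyy + 1e-12)
  fast <- intestseg:::feature_response(img, "structure_tensor_coherence", sigma)
  expect_lt(max(abs(fast[interior] - oracle[interior])), 1e-6)
})

test_that("constant images have zero derivative responses and the constant mean", {
  img <- matrix(137.5, 24, 24)
  for (sigma in c(1, 2)) {
    expect_equal(intestseg:::feature_response(img, "gaussian", sigma),
      img,
      tolerance = 1e-10
    )
    for (f in c(
      "laplacian_of_gaussian", "weighted_deviation", "gradient_magnitude",
      "hessian_determinant", "structure_tensor_coherence"
    )) {
      expect_equal(max(abs(intestseg:::feature_response(img, f, sigma))), 0,
        info = f
      )
    }
  }
})

test_that("an impulse reproduces the discrete Gaussian kernel", {
  img <- matrix(0, 21, 21)
  img[11, 11] <- 1
  resp <- intestseg:::feature_response(img, "gaussian", 1.5)
  k <- gaussian_kernel(1.5)
  r <- (nrow(k) - 1) / 2
  expect_lt(max(abs(resp[(11 - r):(11 + r), (11 - r):(11 + r)] - k)), 1e-6)
})

test_that("coherence is near 1 on a straight edge and low on isotropic noise", {
  edge <- matrix(0, 32, 32)
  edge[, 17:32] <- 100
  coh_edge <- intestseg:::feature_response(edge, "structure_tensor_coherence", 1)
  expect_gt(min(coh_edge[10:22, 16:18]), 0.95)
  set.seed(103)
  noise <- matrix(rnorm(32 * 32), 32, 32)
  coh_noise <- intestseg:::feature_response(noise, "structure_tensor_coherence", 1)
  expect_lt(mean(coh_noise), mean(coh_edge[10:22, 16:18]))
})

test_that("gradient magnitude and Hessian determinant are rotation-consistent", {
  set.seed(104)
  img <- matrix(rnorm(32 * 32, 50, 12), 32, 32)
  rot <- t(img)[, 32:1, drop = FALSE] # 90 degree rotation
  rot_of <- function(m) t(m)[, 32:1, drop = FALSE]
  for (f in c("gradient_magnitude", "hessian_determinant")) {
    a <- rot_of(intestseg:::feature_response(img, f, 1.5))
    b <- intestseg:::feature_response(rot, f, 1.5)
    expect_lt(max(abs(a - b)), 1e-6)
  }
})

test_that("weighted deviation is non-negative everywhere", {
  set.seed(105)
  for (rep in 1:5) {
    img <- matrix(rnorm(24 * 24, 100, 40), 24, 24)
    expect_gte(min(intestseg:::feature_response(img, "weighted_deviation", 1)), 0)
  }
})

test_that("presets define the documented feature-bank shapes", {
  s2 <- step2_feature_config()
  expect_setequal(s2$features, c(
    "gaussian", "laplacian_of_gaussian", "weighted_deviation", "hessian_determinant"
  ))
  expect_equal(s2$scales, c(1, 2))
  expect_equal(s2$working_resolution_um, 7.03)
  s3 <- step3_feature_config()
  expect_length(s3$features, 6)
  expect_equal(s3$scales, 1)
  expect_equal(s3$working_resolution_um, 3.51)

  img <- flat_image(c(120, 130, 140), h = 16, w = 16, px = 7.03)
  stack <- compute_feature_stack(img, s2, stain_model(cbind(H_REF, E_REF)))
  expect_equal(dim(stack$values)[3], 4 * 4 * 2) # channels x features x scales
  expect_equal(nrow(stack$info), 32)
  ## metadata order is deterministic: channel-major, then feature, then scale
  expect_equal(stack$info$channel[1:8], rep("R", 8))
  expect_equal(stack$info$scale[1:2], c(1, 2))
})

test_that("feature configs validate and round-trip through YAML", {
  expect_error(feature_config("R", "gaussian", numeric(0), 7.03), "non-empty")
  expect_error(feature_config("R", "gaussian", -1, 7.03), "positive")
  cfg <- step3_feature_config()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_feature_config(cfg, path)
  expect_equal(unclass(read_feature_config(path)), unclass(cfg))
  ## resolution mismatch and non-finite pixels are refused
  img <- flat_image(c(1, 2, 3), px = 3.51)
  expect_error(compute_feature_stack(img, step2_feature_config()), "resolution")
  expect_error(conv2_reflect(matrix(c(1, NA), 2, 2), gaussian_kernel(1)), "non-finite")
})
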