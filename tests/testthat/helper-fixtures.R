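## Shared fixtures. Small sections keep the default suite fast; geometry is
## scaled down together (shorter villi on a smaller canvas) so the layer
## topology is unchanged.

small_config <- function(seed = 1L, age_group = 49, ...) {
  generator_config(
    image_size_px = c(304, 320), age_group = age_group,
    villus_length_um = 280, villus_spacing_um = 150, villus_width_um = 100,
    seed = seed, ...
  )
}

small_cohort <- function(n_per_age_group = 1, seed = 1L, ...) {
  generate_cohort(
    n_per_age_group,
    config_overrides = list(
      image_size_px = c(304, 320), villus_length_um = 280,
      villus_spacing_um = 150, villus_width_um = 100, ...
    ),
    seed = seed
  )
}

## Dense O(n^2 k^2) convolution oracle (true convolution, interior/valid
## pixels only), independent of the FFT path under test.
dense_conv_valid <- function(img, kernel) {
  kr <- (nrow(kernel) - 1) %/% 2
  kc <- (ncol(kernel) - 1) %/% 2
  h <- nrow(img)
  w <- ncol(img)
  out <- matrix(NA_real_, h, w)
  for (i in (1 + kr):(h - kr)) {
    for (j in (1 + kc):(w - kc)) {
      acc <- 0
      for (u in -kr:kr) {
        for (v in -kc:kc) {
          acc <- acc + kernel[kr + 1 + u, kc + 1 + v] * img[i - u, j - v]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

interior_idx <- function(h, w, margin) {
  im <- matrix(FALSE, h, w)
  im[(1 + margin):(h - margin), (1 + margin):(w - margin)] <- TRUE
  im
}

## Build a noise-free two-stain image from known OD vectors and
## concentration fields (Beer-Lambert forward model).
two_stain_image <- function(vh, ve, ch, ce, pixel_size_um = 3.51) {
  n1 <- nrow(ch)
  n2 <- ncol(ch)
  od <- array(0, c(n1, n2, 3))
  for (k in 1:3) od[, , k] <- ch * vh[k] + ce * ve[k]
  calibrated_image(255 * 10^(-od), pixel_size_um)
}

unit3 <- function(v) v / sqrt(sum(v^2))
H_REF <- unit3(c(0.65, 0.70, 0.29))
E_REF <- unit3(c(0.07, 0.99, 0.11))

## A binary test mask at a given resolution.
bin_mask <- function(m, px = 7.03, class = "tissue") {
  intestseg:::binary_mask(m > 0, class, px)
}

## Uniform-colour calibrated image.
flat_image <- function(rgb, h = 32, w = 32, px = 7.03) {
  calibrated_image(array(rep(rgb, each = h * w), c(h, w, 3)), px)
}

## Cached small trained models shared across test files (built once per run).
.fixture_env <- new.env(parent = emptyenv())

fixture_models <- function() {
  if (is.null(.fixture_env$models)) {
    cohort <- small_cohort(1, seed = 401)
    ids <- cohort$sample_id[c(1, 3, 5)] # ages 4, 25, 67
    m2 <- train_step2_classifier(cohort, ids, total_annotations = 48, seed = 402)
    m3 <- train_step3_classifier(cohort, ids, total_annotations = 48, seed = 403)
    .fixture_env$models <- list(cohort = cohort, m2 = m2, m3 = m3)
  }
  .fixture_env$models
}
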