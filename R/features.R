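## Multiscale per-pixel feature bank. All filters are built from sampled
## Gaussian-derivative kernels (truncated at 4 sigma, derivative kernels
## corrected to exact zero sum) and applied with reflect padding, so constant
## images yield identically zero derivative responses and there is no
## edge-darkening bias near borders. Scales are sigmas in working-resolution
## pixels.

#' Gaussian (derivative) kernel sampled on a pixel grid
#'
#' @param sigma Standard deviation in pixels (> 0).
#' @param dx,dy Derivative order (0, 1 or 2) along columns (x) and rows (y).
#' @return Odd-sized square matrix. The smoothing kernel (`dx = dy = 0`) sums
#'   to 1; derivative kernels are mean-corrected to sum to 0.
#' @export
gaussian_kernel <- function(sigma, dx = 0, dy = 0) {
  stopifnot(sigma > 0, dx %in% 0:2, dy %in% 0:2)
  r <- max(1L, ceiling(4 * sigma))
  x <- matrix(-r:r, 2 * r + 1, 2 * r + 1, byrow = TRUE)
  y <- matrix(-r:r, 2 * r + 1, 2 * r + 1)
  g <- exp(-(x^2 + y^2) / (2 * sigma^2))
  g <- g / sum(g)
  d1 <- function(u) -u / sigma^2
  d2 <- function(u) (u^2 - sigma^2) / sigma^4
  k <- g
  if (dx == 1) k <- k * d1(x) else if (dx == 2) k <- k * d2(x)
  if (dy == 1) k <- k * d1(y) else if (dy == 2) k <- k * d2(y)
  if (dx + dy > 0) k <- k - mean(k)
  k
}

#' 2-D convolution with reflect padding
#'
#' True convolution (kernel flipped), computed by FFT on a reflect-padded
#' copy and cropped back to the input size.
#'
#' @param img Numeric matrix.
#' @param kernel Odd-sized kernel matrix.
#' @return Matrix of the input size.
#' @export
conv2_reflect <- function(img, kernel) {
  stopifnot(is.matrix(img), is.matrix(kernel))
  if (any(dim(kernel) %% 2 == 0)) abort("kernel dimensions must be odd")
  if (anyNA(img) || !all(is.finite(img))) abort("non-finite input pixels")
  pr <- (nrow(kernel) - 1) %/% 2
  pc <- (ncol(kernel) - 1) %/% 2
  ri <- reflect_index(nrow(img), pr)
  ci <- reflect_index(ncol(img), pc)
  padded <- img[ri, ci, drop = FALSE]
  out <- EBImage::filter2(padded, kernel, boundary = "circular")
  out[pr + seq_len(nrow(img)), pc + seq_len(ncol(img)), drop = FALSE]
}

## symmetric (edge-duplicating) reflection index for padding width p
reflect_index <- function(n, p) {
  if (p == 0) return(seq_len(n))
  if (p > n) abort("kernel larger than image")
  c(p:1, seq_len(n), n:(n - p + 1))
}

FEATURE_NAMES <- c(
  "gaussian", "laplacian_of_gaussian", "weighted_deviation",
  "gradient_magnitude", "structure_tensor_coherence", "hessian_determinant"
)
CHANNEL_NAMES <- c("R", "G", "B", "hematoxylin")

#' Feature-bank configuration
#'
#' @param channels Subset of `R`, `G`, `B`, `hematoxylin`.
#' @param features Subset of the six filter names (see Details).
#' @param scales Smoothing sigmas, in working-resolution pixels (> 0).
#' @param working_resolution_um Working resolution in micrometres per pixel.
#'
#' @details Per scale sigma, the filters are: `gaussian` (smoothed image),
#' `laplacian_of_gaussian`, `weighted_deviation` (Gaussian-weighted local
#' standard deviation, `sqrt(max(0, G*I^2 - (G*I)^2))`),
#' `gradient_magnitude`, `structure_tensor_coherence`
#' (`(l1 - l2) / (l1 + l2)` of the sigma-smoothed structure tensor, 0 where
#' both eigenvalues vanish) and `hessian_determinant` (determinant of the
#' Gaussian-derivative Hessian).
#' @return A `feature_config` object.
#' @export
feature_config <- function(channels, features, scales, working_resolution_um) {
  channels <- match.arg(channels, CHANNEL_NAMES, several.ok = TRUE)
  features <- match.arg(features, FEATURE_NAMES, several.ok = TRUE)
  if (length(channels) == 0 || length(features) == 0 || length(scales) == 0) {
    abort("channels, features and scales must be non-empty")
  }
  if (any(scales <= 0)) abort("scales must be strictly positive")
  structure(
    list(
      channels = channels, features = features,
      scales = as.numeric(scales),
      working_resolution_um = working_resolution_um
    ),
    class = "feature_config"
  )
}

#' Feature presets for the two classifier steps
#'
#' The mucosal-segmentation step uses Gaussian, Laplacian of Gaussian,
#' weighted deviation and Hessian determinant at sigmas 1.0 and 2.0 on a
#' 7.03 um/px working image; the epithelial step adds gradient magnitude and
#' structure-tensor coherence, all at sigma 1.0, on the native 3.51 um/px
#' image. Both use the RGB and haematoxylin channels.
#'
#' @return A [feature_config()].
#' @export
step2_feature_config <- function() {
  feature_config(
    channels = CHANNEL_NAMES,
    features = c(
      "gaussian", "laplacian_of_gaussian",
      "weighted_deviation", "hessian_determinant"
    ),
    scales = c(1, 2), working_resolution_um = 7.03
  )
}

#' @rdname step2_feature_config
#' @export
step3_feature_config <- function() {
  feature_config(
    channels = CHANNEL_NAMES, features = FEATURE_NAMES,
    scales = 1, working_resolution_um = 3.51
  )
}

#' Serialise / restore a feature config as YAML
#' @param config A [feature_config()].
#' @param path File path.
#' @return `path` (write) or a [feature_config()] (read).
#' @export
write_feature_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_feature_config
#' @export
read_feature_config <- function(path) {
  y <- yaml::read_yaml(path)
  feature_config(y$channels, y$features, y$scales, y$working_resolution_um)
}

#' Compute the per-pixel multiscale feature stack
#'
#' Extracts the configured channels from the image (the haematoxylin channel
#' through stain deconvolution with `stain_model`, estimated from the image
#' when not supplied), applies every configured filter at every scale, and
#' stacks the responses.
#'
#' @param image A [calibrated_image()] at the config's working resolution
#'   (checked to 0.5%).
#' @param config A [feature_config()].
#' @param stain_model Optional [stain_model()] for the haematoxylin channel.
#' @return A `feature_stack`: list with `values` (array `h x w x n_feature`),
#'   `info` (tibble of `channel`, `feature`, `scale` per slice, in
#'   channel-major, then feature, then scale order) and
#'   `working_resolution_um`.
#' @export
compute_feature_stack <- function(image, config, stain_model = NULL) {
  stopifnot(inherits(image, "calibrated_image"), inherits(config, "feature_config"))
  if (!same_resolution(image$pixel_size_um, config$working_resolution_um)) {
    abort(sprintf(
      "image resolution %.3f um/px does not match config working resolution %.3f um/px",
      image$pixel_size_um, config$working_resolution_um
    ))
  }
  chans <- list()
  for (ch in config$channels) {
    chans[[ch]] <- switch(ch,
      R = image$data[, , 1], G = image$data[, , 2], B = image$data[, , 3],
      hematoxylin = deconvolve(image, stain_model)$hematoxylin
    )
  }
  info <- tidyr::expand_grid(
    channel = config$channels, feature = config$features, scale = config$scales
  )
  d <- dim(image$data)
  values <- array(0, c(d[1], d[2], nrow(info)))
  for (i in seq_len(nrow(info))) {
    values[, , i] <- feature_response(
      chans[[info$channel[i]]], info$feature[i], info$scale[i]
    )
  }
  structure(
    list(values = values, info = info, working_resolution_um = image$pixel_size_um),
    class = "feature_stack"
  )
}

feature_response <- function(img, feature, sigma) {
  switch(feature,
    gaussian = conv2_reflect(img, gaussian_kernel(sigma)),
    laplacian_of_gaussian = conv2_reflect(
      img, gaussian_kernel(sigma, dx = 2) + gaussian_kernel(sigma, dy = 2)
    ),
    weighted_deviation = {
      g <- gaussian_kernel(sigma)
      m1 <- conv2_reflect(img, g)
      m2 <- conv2_reflect(img^2, g)
      sqrt(pmax(0, m2 - m1^2))
    },
    gradient_magnitude = {
      ix <- conv2_reflect(img, gaussian_kernel(sigma, dx = 1))
      iy <- conv2_reflect(img, gaussian_kernel(sigma, dy = 1))
      sqrt(ix^2 + iy^2)
    },
    hessian_determinant = {
      ixx <- conv2_reflect(img, gaussian_kernel(sigma, dx = 2))
      iyy <- conv2_reflect(img, gaussian_kernel(sigma, dy = 2))
      ixy <- conv2_reflect(img, gaussian_kernel(sigma, dx = 1, dy = 1))
      ixx * iyy - ixy^2
    },
    structure_tensor_coherence = structure_tensor_coherence(img, sigma),
    abort(sprintf("unknown feature '%s'", feature))
  )
}

## Coherence of the Gaussian structure tensor: gradients at scale sigma,
## tensor smoothed at the same sigma. (l1 - l2)/(l1 + l2 + eps) with the
## convention that near-zero tensors (constant regions) have coherence 0.
structure_tensor_coherence <- function(img, sigma, eps = 1e-12, zero_tol = 1e-8) {
  ix <- conv2_reflect(img, gaussian_kernel(sigma, dx = 1))
  iy <- conv2_reflect(img, gaussian_kernel(sigma, dy = 1))
  g <- gaussian_kernel(sigma)
  jxx <- conv2_reflect(ix^2, g)
  jyy <- conv2_reflect(iy^2, g)
  jxy <- conv2_reflect(ix * iy, g)
  tr <- jxx + jyy
  diff <- sqrt(pmax(0, (jxx - jyy)^2 + 4 * jxy^2))
  coh <- diff / (tr + eps)
  coh[tr <= zero_tol] <- 0
  coh
}

## Flatten a feature stack to an n_pixels x n_features matrix with stable
## column names (serialised with trained models).
stack_matrix <- function(stack, idx = NULL) {
  d <- dim(stack$values)
  m <- matrix(stack$values, d[1] * d[2], d[3])
  colnames(m) <- feature_column_names(stack$info)
  if (!is.null(idx)) m <- m[idx, , drop = FALSE]
  m
}

feature_column_names <- function(info) {
  sprintf("%s.%s.s%g", info$channel, info$feature, info$scale)
}
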