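## H&E stain separation. RGB intensities are converted to Beer-Lambert
## optical densities, the two dominant stain directions are estimated per
## image (the per-image colour normalisation step), and pixels are unmixed
## into haematoxylin and eosin concentration channels. Only the haematoxylin
## channel feeds the classifiers; eosin is kept for diagnostics.

## Published default H&E OD vectors (haematoxylin, eosin), used as fallback
## when an image has too little tissue to estimate from.
DEFAULT_HE_VECTORS <- {
  m <- cbind(h = c(0.65, 0.70, 0.29), e = c(0.07, 0.99, 0.11))
  sweep(m, 2, sqrt(colSums(m^2)), "/")
}

#' Convert RGB intensities to optical density
#'
#' `OD = -log10(max(I, 1) / white_point)` per channel; intensities are
#' clamped at 1 before the log so zero pixels map to a finite density (the
#' clamp is part of the contract, not an error path).
#'
#' @param image A [calibrated_image()].
#' @param white_point RGB triplet of the unstained white level, components in
#'   `(0, 255]`.
#' @return Numeric array `h x w x 3` of optical densities.
#' @export
rgb_to_od <- function(image, white_point = c(255, 255, 255)) {
  stopifnot(inherits(image, "calibrated_image"))
  if (any(white_point <= 0) || any(white_point > 255)) {
    abort("white_point components must lie in (0, 255]")
  }
  od <- image$data
  for (ch in 1:3) od[, , ch] <- -log10(pmax(od[, , ch], 1) / white_point[ch])
  od
}

#' Stain model: H&E unit vectors in optical-density space
#'
#' @param vectors 3 x 2 matrix, columns = haematoxylin and eosin OD unit
#'   vectors (non-negative components).
#' @param white_point RGB white level the model was built against.
#' @param max_od Per-stain normalisation constants (99th-percentile
#'   concentration seen at fit time; `NA` when unknown).
#' @param fallback Logical: was the published default basis substituted for a
#'   per-image estimate?
#' @return A `stain_model` object.
#' @export
stain_model <- function(vectors, white_point = c(255, 255, 255),
                        max_od = c(NA_real_, NA_real_), fallback = FALSE) {
  stopifnot(is.matrix(vectors), all(dim(vectors) == c(3, 2)))
  if (any(vectors < -1e-9)) abort("stain vectors must have non-negative components")
  nrm <- sqrt(colSums(vectors^2))
  if (any(abs(nrm - 1) > 1e-6)) abort("stain vectors must have unit norm")
  colnames(vectors) <- c("hematoxylin", "eosin")
  structure(
    list(
      vectors = vectors, white_point = white_point,
      max_od = max_od, fallback = fallback
    ),
    class = "stain_model"
  )
}

#' @export
print.stain_model <- function(x, ...) {
  cat("<stain_model>", if (x$fallback) "(fallback default basis)" else "(per-image estimate)", "\n")
  print(round(x$vectors, 4))
  invisible(x)
}

#' Estimate H&E stain vectors from an image (Macenko-style)
#'
#' Tissue pixels (mean RGB at or below `tissue_threshold`) are mapped to
#' optical density, low-density pixels are discarded, the top-2 singular
#' plane of the OD cloud is found, and the robust angular extremes (1st/99th
#' percentile) of the projected distribution are taken as the two stain
#' directions. Haematoxylin is identified as the direction with the larger
#' red-channel density (hematoxylin absorbs red/green and transmits blue).
#' Deterministic for a fixed input; pixel order is irrelevant.
#'
#' @param image A [calibrated_image()].
#' @param tissue_threshold Mean-RGB cutoff defining tissue pixels (default
#'   reuses the tissue-detection threshold, 205).
#' @param min_tissue_px Minimum tissue-pixel count below which the published
#'   default basis is returned with the `fallback` flag set.
#' @param beta Minimum OD magnitude for a pixel to enter the estimate.
#' @param white_point RGB white level.
#' @return A [stain_model()].
#' @export
estimate_stain_vectors <- function(image, tissue_threshold = 205,
                                   min_tissue_px = 200, beta = 0.10,
                                   white_point = c(255, 255, 255)) {
  stopifnot(inherits(image, "calibrated_image"))
  mean_rgb <- (image$data[, , 1] + image$data[, , 2] + image$data[, , 3]) / 3
  sel <- which(mean_rgb <= tissue_threshold)
  if (length(sel) < min_tissue_px) {
    return(stain_model(DEFAULT_HE_VECTORS, white_point, fallback = TRUE))
  }
  od <- rgb_to_od(image, white_point)
  odm <- cbind(od[, , 1][sel], od[, , 2][sel], od[, , 3][sel])
  odm <- odm[rowSums(odm^2) > beta^2, , drop = FALSE]
  if (nrow(odm) < min_tissue_px) {
    return(stain_model(DEFAULT_HE_VECTORS, white_point, fallback = TRUE))
  }
  ## top-2 right-singular plane of the OD cloud (uncentred: Beer-Lambert
  ## mixing is linear through the origin)
  sv <- svd(odm, nu = 0, nv = 2)
  basis <- sv$v # 3 x 2
  ## orient the plane so projections land in the positive quadrant-ish
  for (j in 1:2) if (sum(basis[, j]) < 0) basis[, j] <- -basis[, j]
  proj <- odm %*% basis
  phi <- atan2(proj[, 2], proj[, 1])
  qs <- stats::quantile(phi, c(0.01, 0.99), names = FALSE)
  v1 <- basis %*% c(cos(qs[1]), sin(qs[1]))
  v2 <- basis %*% c(cos(qs[2]), sin(qs[2]))
  vecs <- cbind(as.numeric(v1), as.numeric(v2))
  vecs[vecs < 0] <- 0
  vecs <- sweep(vecs, 2, sqrt(colSums(vecs^2)), "/")
  ## haematoxylin = larger red-channel density
  if (vecs[1, 1] < vecs[1, 2]) vecs <- vecs[, 2:1]
  conc <- project_concentrations(odm, vecs)
  model <- stain_model(vecs, white_point,
    max_od = apply(conc, 2, stats::quantile, 0.99, names = FALSE),
    fallback = FALSE
  )
  model
}

## Least-squares projection of OD rows onto the two stain vectors.
project_concentrations <- function(od_rows, vectors) {
  sol <- solve(crossprod(vectors), t(vectors)) # 2 x 3
  od_rows %*% t(sol)
}

#' Unmix an image into haematoxylin and eosin concentration channels
#'
#' Each pixel's optical density is projected (least squares) onto the model's
#' two stain vectors; negative concentrations are clipped to zero. Models
#' whose vectors are closer than one degree of angular separation are
#' rejected as collinear.
#'
#' @param image A [calibrated_image()].
#' @param model A [stain_model()]; estimated from the image when omitted.
#' @return List of two matrices, `hematoxylin` and `eosin`, in OD units,
#'   plus `pixel_size_um`.
#' @export
deconvolve <- function(image, model = NULL) {
  stopifnot(inherits(image, "calibrated_image"))
  model <- model %||% estimate_stain_vectors(image)
  stopifnot(inherits(model, "stain_model"))
  cosang <- sum(model$vectors[, 1] * model$vectors[, 2])
  if (cosang > cos(1 * pi / 180)) {
    abort("stain vectors are collinear (angular separation below 1 degree)")
  }
  od <- rgb_to_od(image, model$white_point)
  d <- dim(od)
  odm <- matrix(od, d[1] * d[2], 3)
  conc <- project_concentrations(odm, model$vectors)
  conc[conc < 0] <- 0
  list(
    hematoxylin = matrix(conc[, 1], d[1], d[2]),
    eosin = matrix(conc[, 2], d[1], d[2]),
    pixel_size_um = image$pixel_size_um
  )
}

#' Angular distance between two stain vectors, in degrees
#'
#' @param a,b Numeric length-3 vectors.
#' @return Angle in degrees.
#' @export
stain_angle <- function(a, b) {
  ca <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(pmin(pmax(ca, -1), 1)) * 180 / pi
}

#' Serialise / restore a stain model as YAML
#'
#' @param model A [stain_model()].
#' @param path File path.
#' @return `path` (write) or a [stain_model()] (read).
#' @export
write_stain_model <- function(model, path) {
  yaml::write_yaml(list(
    vectors = list(
      hematoxylin = as.numeric(model$vectors[, 1]),
      eosin = as.numeric(model$vectors[, 2])
    ),
    white_point = as.numeric(model$white_point),
    max_od = as.numeric(model$max_od),
    fallback = model$fallback
  ), path)
  invisible(path)
}

#' @rdname write_stain_model
#' @export
read_stain_model <- function(path) {
  y <- yaml::read_yaml(path)
  stain_model(
    cbind(y$vectors$hematoxylin, y$vectors$eosin),
    white_point = y$white_point, max_od = as.numeric(y$max_od),
    fallback = isTRUE(y$fallback)
  )
}
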