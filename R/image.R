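#' Calibrated RGB image
#'
#' A physical-resolution-aware RGB raster: an `h x w x 3` numeric array of
#' 8-bit intensities (0--255) plus the pixel edge length in micrometres.
#' Every downstream operation (thresholding, object creation, area
#' measurement, feature scales) interprets the raster through this
#' calibration.
#'
#' @param data Numeric array `h x w x 3`, values in `[0, 255]`.
#' @param pixel_size_um Physical pixel size in micrometres per pixel (> 0).
#' @return A `calibrated_image` object.
#' @export
calibrated_image <- function(data, pixel_size_um) {
  stopifnot(is.array(data), length(dim(data)) == 3, dim(data)[3] == 3)
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 || pixel_size_um <= 0) {
    abort("`pixel_size_um` must be a single positive number.")
  }
  if (anyNA(data) || !all(is.finite(data))) abort("image contains non-finite pixels")
  structure(
    list(data = data, pixel_size_um = as.numeric(pixel_size_um)),
    class = "calibrated_image"
  )
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<calibrated_image> %d x %d px @ %.3f um/px (%.2f x %.2f mm)\n",
    d[1], d[2], x$pixel_size_um,
    d[1] * x$pixel_size_um / 1000, d[2] * x$pixel_size_um / 1000
  ))
  invisible(x)
}

#' @export
dim.calibrated_image <- function(x) dim(x$data)

#' Per-pixel class raster aligned to a calibrated image
#'
#' An integer matrix whose values index into a declared class vocabulary
#' (`classes` attribute; value `k` means `classes[k]`, value 0 means
#' unclassified), carrying the same physical calibration as the image it
#' annotates.
#'
#' @param values Integer matrix of class indices (0 = unclassified).
#' @param classes Character vector: the class vocabulary.
#' @param pixel_size_um Physical pixel size in micrometres per pixel.
#' @return A `label_mask` object.
#' @export
label_mask <- function(values, classes, pixel_size_um) {
  stopifnot(is.matrix(values), is.character(classes), length(classes) >= 1)
  v <- matrix(as.integer(values), nrow(values), ncol(values))
  if (anyNA(v) || any(v < 0L) || any(v > length(classes))) {
    abort("mask values must be integers in [0, length(classes)]")
  }
  structure(v,
    classes = classes, pixel_size_um = as.numeric(pixel_size_um),
    class = c("label_mask", "matrix", "array")
  )
}

#' @export
print.label_mask <- function(x, ...) {
  cls <- attr(x, "classes")
  tab <- tabulate(x + 1L, nbins = length(cls) + 1L)
  cat(sprintf(
    "<label_mask> %d x %d px @ %.3f um/px\n", nrow(x), ncol(x),
    attr(x, "pixel_size_um")
  ))
  cat("  classes:", paste(sprintf("%s (%d px)", c("unclassified", cls), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Logical mask for one class (or a derived compartment)
#'
#' Besides the literal vocabulary entries, the derived compartments of a
#' ground-truth mask are accepted: `"tissue"` (everything except background
#' and lumen content) and `"mucosa"` (epithelium plus lamina propria).
#'
#' @param mask A [label_mask()].
#' @param class Class name, vocabulary entry or `"tissue"`/`"mucosa"`.
#' @return Logical matrix.
#' @export
class_mask <- function(mask, class) {
  cls <- attr(mask, "classes")
  m <- unclass(mask)
  if (class %in% cls) {
    return(m == match(class, cls))
  }
  if (class == "tissue") {
    drop <- match(c("background", "lumen_content"), cls)
    drop <- drop[!is.na(drop)]
    return(m != 0L & !(m %in% drop))
  }
  if (class == "mucosa") {
    keep <- match(c("epithelium", "lamina_propria"), cls)
    keep <- keep[!is.na(keep)]
    return(matrix(m %in% keep, nrow(m), ncol(m)))
  }
  abort(sprintf("unknown class '%s'; vocabulary: %s", class, paste(cls, collapse = ", ")))
}

## Build a two-class mask ("background", <class>) from a logical matrix.
binary_mask <- function(bin, class, pixel_size_um) {
  label_mask(matrix(ifelse(bin, 2L, 1L), nrow(bin), ncol(bin)),
    classes = c("background", class), pixel_size_um = pixel_size_um
  )
}

#' Downsample a calibrated image to a coarser working resolution
#'
#' Block-mean downsampling when the target/native ratio is an integer (snapped
#' within 0.5% so the printed working resolutions pair up exactly),
#' area-weighted averaging otherwise. Upsampling requests are rejected.
#'
#' @param image A [calibrated_image()].
#' @param target_um_per_px Requested pixel size, at or above the native one.
#' @return A [calibrated_image()] at the realised resolution (for a snapped
#'   integer ratio `r`, exactly `r *` the native pixel size).
#' @export
resample <- function(image, target_um_per_px) {
  stopifnot(inherits(image, "calibrated_image"))
  ratio <- target_um_per_px / image$pixel_size_um
  if (ratio < 1 - RES_TOL) abort("upsampling requested; `resample()` only downsamples")
  if (abs(ratio - 1) <= RES_TOL) return(image)
  r_int <- round(ratio)
  d <- dim(image$data)
  if (abs(ratio - r_int) <= RES_TOL * ratio && d[1] %% r_int == 0 && d[2] %% r_int == 0) {
    out <- vapply(1:3, function(ch) block_mean(image$data[, , ch], r_int),
      matrix(0, d[1] %/% r_int, d[2] %/% r_int)
    )
    return(calibrated_image(out, image$pixel_size_um * r_int))
  }
  wr <- overlap_weights(d[1], ratio)
  wc <- overlap_weights(d[2], ratio)
  out <- vapply(1:3, function(ch) wr %*% image$data[, , ch] %*% t(wc),
    matrix(0, nrow(wr), nrow(wc))
  )
  calibrated_image(out, image$pixel_size_um * ratio)
}

block_mean <- function(m, r) {
  h <- nrow(m) %/% r
  w <- ncol(m) %/% r
  ## average r x r blocks: fold rows, then columns
  m1 <- matrix(colMeans(matrix(m, nrow = r)), nrow = h)
  m2 <- matrix(colMeans(matrix(t(m1), nrow = r)), nrow = w)
  t(m2)
}

## Row-overlap weight matrix mapping n fine cells to coarse cells of width
## `ratio` fine cells (area-weighted, partial trailing cell dropped).
overlap_weights <- function(n, ratio) {
  n_out <- floor(n / ratio + 1e-9)
  w <- matrix(0, n_out, n)
  for (i in seq_len(n_out)) {
    a <- (i - 1) * ratio
    b <- i * ratio
    j0 <- floor(a) + 1
    j1 <- min(n, ceiling(b - 1e-9))
    for (j in j0:j1) {
      w[i, j] <- max(0, min(b, j) - max(a, j - 1))
    }
  }
  w / rowSums(w)
}

#' Downsample a label mask by an integer factor (block majority vote)
#'
#' Each coarse pixel takes the most frequent class among its `factor^2` fine
#' pixels; ties break toward the class listed first in the vocabulary.
#'
#' @param mask A [label_mask()].
#' @param factor Positive integer downsampling factor.
#' @return A [label_mask()] at `factor *` the input pixel size.
#' @export
resample_mask <- function(mask, factor) {
  stopifnot(inherits(mask, "label_mask"), factor >= 1, factor == round(factor))
  if (factor == 1) return(mask)
  cls <- attr(mask, "classes")
  m <- unclass(mask)
  h <- nrow(m) %/% factor
  w <- ncol(m) %/% factor
  m <- m[seq_len(h * factor), seq_len(w * factor)]
  counts <- vapply(0:length(cls), function(k) {
    block_mean((m == k) * 1, factor)
  }, matrix(0, h, w))
  ## counts: h x w x (K+1), layer 1 = unclassified; majority, ties -> earlier
  ## class (and unclassified wins ties only against nothing, i.e. listed first)
  win <- apply(counts, c(1, 2), which.max) - 1L
  label_mask(win, cls, attr(mask, "pixel_size_um") * factor)
}

#' Upsample a label mask by an integer factor (nearest neighbour)
#'
#' Used to carry a coarse-resolution restriction mask (e.g. mucosa objects at
#' the step-2 working resolution) onto the finer step-3 grid exactly.
#'
#' @param mask A [label_mask()].
#' @param factor Positive integer upsampling factor.
#' @return A [label_mask()] at `pixel_size / factor`.
#' @export
upsample_mask <- function(mask, factor) {
  stopifnot(inherits(mask, "label_mask"), factor >= 1, factor == round(factor))
  if (factor == 1) return(mask)
  m <- unclass(mask)
  out <- m[rep(seq_len(nrow(m)), each = factor), rep(seq_len(ncol(m)), each = factor)]
  label_mask(out, attr(mask, "classes"), attr(mask, "pixel_size_um") / factor)
}
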