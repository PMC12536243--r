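## Step 1 (tissue vs background by smoothed mean-RGB thresholding) and the
## object machinery shared by all steps: connected-component filtering with a
## minimum object size, hole filling with a minimum hole size, polygon
## tracing and area measurement. Objects are 8-connected, holes 4-connected
## (the standard complementary pairing); a pixel whose smoothed mean RGB is
## exactly at the threshold is background (strict less-than for tissue).

#' Threshold configuration for tissue detection
#'
#' Defaults are the published step-1 settings: mean-RGB image at a working
#' resolution of 7.03 um/px, Gaussian prefilter with smoothing sigma 2.0
#' (pixels), threshold 205 with below = tissue.
#'
#' @param working_resolution_um Working resolution, micrometres per pixel.
#' @param smoothing_sigma Gaussian prefilter sigma, in working pixels.
#' @param threshold Mean-RGB cutoff in `(0, 255)`.
#' @param below_is_tissue Logical; pixels strictly below the threshold are
#'   tissue.
#' @return A `threshold_config` object.
#' @export
threshold_config <- function(working_resolution_um = 7.03, smoothing_sigma = 2.0,
                             threshold = 205, below_is_tissue = TRUE) {
  if (threshold <= 0 || threshold >= 255) abort("threshold must lie in (0, 255)")
  if (smoothing_sigma <= 0) abort("smoothing_sigma must be positive")
  structure(
    list(
      working_resolution_um = working_resolution_um,
      smoothing_sigma = smoothing_sigma,
      threshold = threshold, below_is_tissue = below_is_tissue
    ),
    class = "threshold_config"
  )
}

#' Classify tissue vs background by thresholding smoothed mean RGB
#'
#' The mean of the three channels is smoothed with a Gaussian prefilter and
#' compared against the threshold; strictly-below means tissue. The image is
#' resampled to the configured working resolution if finer.
#'
#' @param image A [calibrated_image()].
#' @param cfg A [threshold_config()].
#' @return A binary [label_mask()] with classes `background` / `tissue`.
#' @export
threshold_tissue <- function(image, cfg = threshold_config()) {
  stopifnot(inherits(image, "calibrated_image"), inherits(cfg, "threshold_config"))
  if (image$pixel_size_um < cfg$working_resolution_um * (1 - RES_TOL)) {
    image <- resample(image, cfg$working_resolution_um)
  }
  mean_rgb <- (image$data[, , 1] + image$data[, , 2] + image$data[, , 3]) / 3
  sm <- conv2_reflect(mean_rgb, gaussian_kernel(cfg$smoothing_sigma))
  tissue <- if (cfg$below_is_tissue) sm < cfg$threshold else sm > cfg$threshold
  binary_mask(tissue, "tissue", image$pixel_size_um)
}

## 8-connected labelling built on EBImage's 4-connected bwlabel: label, then
## union labels that touch diagonally.
label_components_8 <- function(bin) {
  l4 <- EBImage::bwlabel(matrix(as.numeric(bin), nrow(bin), ncol(bin)))
  n <- max(l4)
  if (n <= 1) return(l4)
  h <- nrow(l4)
  w <- ncol(l4)
  a <- l4[-h, -w]; b <- l4[-1, -1] # down-right diagonal pairs
  c_ <- l4[-h, -1]; d <- l4[-1, -w] # down-left diagonal pairs
  pairs <- rbind(
    cbind(as.vector(a), as.vector(b)),
    cbind(as.vector(c_), as.vector(d))
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs) > 0) {
    pairs <- unique(pairs)
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- l4
  out[out > 0] <- relab[out[out > 0]]
  out
}

#' Convert a classification mask to measurable region objects
#'
#' Connected components (8-connected) of the positive class smaller than
#' `min_object_size_um2` are discarded; interior holes (4-connected
#' background components not touching the image border) smaller than
#' `min_hole_size_um2` are filled, i.e. absorbed into the region. Remaining
#' components are traced to polygons (marching squares at pixel-boundary
#' coordinates, areas by the shoelace formula).
#'
#' @param mask A [label_mask()].
#' @param min_object_size_um2,min_hole_size_um2 Size rules in um^2.
#' @param class Positive class name (defaults to the last vocabulary entry).
#' @param provenance Optional list recorded with the objects (e.g. step id).
#' @return A `region_objects` object: `regions` tibble (`region_id`, `class`,
#'   `n_pixels`, `area_um2`, `polygon` list-column of rings in um),
#'   rasterised `mask`, `pixel_size_um`, `provenance`.
#' @export
create_objects <- function(mask, min_object_size_um2, min_hole_size_um2,
                           class = NULL, provenance = list()) {
  stopifnot(inherits(mask, "label_mask"))
  px <- attr(mask, "pixel_size_um")
  px_area <- px^2
  cls <- class %||% tail(attr(mask, "classes"), 1)
  bin <- class_mask(mask, cls)
  ## 1) drop small 8-connected components
  lab <- label_components_8(bin)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    drop <- which(sizes * px_area < min_object_size_um2)
    bin[lab %in% drop] <- FALSE
  }
  ## 2) fill small interior holes (4-connected complement components that do
  ## not touch the border)
  holes <- EBImage::bwlabel(matrix(as.numeric(!bin), nrow(bin), ncol(bin)))
  if (max(holes) > 0) {
    border_labels <- unique(c(holes[1, ], holes[nrow(holes), ], holes[, 1], holes[, ncol(holes)]))
    sizes <- tabulate(holes[holes > 0], nbins = max(holes))
    fill <- setdiff(which(sizes * px_area < min_hole_size_um2), border_labels)
    bin[holes %in% fill] <- TRUE
  }
  ## 3) trace remaining components
  lab <- label_components_8(bin)
  n <- max(lab)
  regions <- purrr::map(seq_len(n), function(i) {
    comp <- lab == i
    poly <- trace_polygon(comp, px)
    tibble(
      region_id = i, class = cls, n_pixels = sum(comp),
      area_um2 = poly$area, polygon = list(poly$rings)
    )
  })
  regions <- if (n > 0) dplyr::bind_rows(regions) else {
    tibble(
      region_id = integer(), class = character(), n_pixels = integer(),
      area_um2 = numeric(), polygon = list()
    )
  }
  structure(
    list(
      regions = regions,
      mask = binary_mask(bin, cls, px),
      pixel_size_um = px,
      provenance = utils::modifyList(
        list(min_object_size_um2 = min_object_size_um2, min_hole_size_um2 = min_hole_size_um2),
        provenance
      )
    ),
    class = "region_objects"
  )
}

#' @export
print.region_objects <- function(x, ...) {
  cat(sprintf(
    "<region_objects> %d region(s) of class '%s', total %.0f um^2\n",
    nrow(x$regions), if (nrow(x$regions)) x$regions$class[1] else "-",
    sum(x$regions$area_um2)
  ))
  invisible(x)
}

## Marching-squares tracing of one component; returns rings (x,y in um) and
## the net shoelace area (outer rings positive, holes subtracted).
trace_polygon <- function(comp, px) {
  h <- nrow(comp)
  w <- ncol(comp)
  ## pad so boundary components close properly
  z <- matrix(0, h + 2, w + 2)
  z[2:(h + 1), 2:(w + 1)] <- comp * 1
  ## grid coordinates: x along columns, y along rows, pixel centres in um
  xs <- (seq_len(w + 2) - 1.5) * px
  ys <- (seq_len(h + 2) - 1.5) * px
  ib <- isoband::isobands(x = xs, y = ys, z = z, levels_low = 0.5, levels_high = Inf)[[1]]
  rings <- split(
    data.frame(x = ib$x, y = ib$y),
    ib$id
  )
  area <- sum(vapply(rings, function(r) shoelace_area(r$x, r$y), numeric(1)))
  list(rings = lapply(rings, as.matrix), area = abs(area))
}

shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

#' Total measured area per class
#'
#' Sums the traced polygon areas of a `region_objects` set; agrees with
#' pixel-count x pixel-area within one boundary-pixel band.
#'
#' @param objects A `region_objects` object (or list of them).
#' @return Tibble with `class`, `n_regions`, `n_pixels`, `area_um2`.
#' @export
measure_area <- function(objects) {
  stopifnot(inherits(objects, "region_objects"))
  if (nrow(objects$regions) == 0) {
    return(tibble(
      class = character(), n_regions = integer(),
      n_pixels = integer(), area_um2 = numeric()
    ))
  }
  dplyr::summarise(
    dplyr::group_by(objects$regions, .data$class),
    n_regions = dplyr::n(), n_pixels = sum(.data$n_pixels),
    area_um2 = sum(.data$area_um2), .groups = "drop"
  )
}

#' Export region objects as GeoJSON
#'
#' Polygon coordinates in micrometres; the class, pixel count and areas go
#' into each feature's properties. Each component's rings are written as one
#' MultiPolygon.
#'
#' @param objects A `region_objects` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(objects, path) {
  stopifnot(inherits(objects, "region_objects"))
  feats <- purrr::pmap(objects$regions, function(region_id, class, n_pixels, area_um2, polygon) {
    list(
      type = "Feature",
      geometry = list(
        type = "MultiPolygon",
        coordinates = lapply(polygon, function(ring) {
          list(lapply(seq_len(nrow(ring)), function(i) as.numeric(ring[i, c("x", "y")])))
        })
      ),
      properties = list(
        region_id = region_id, class = class,
        n_pixels = n_pixels, area_um2 = area_um2,
        unit = "um"
      )
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
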