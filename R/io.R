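## Disk interfaces: calibrated images as 8-bit RGB TIFF with the pixel size
## in the TIFF resolution tags and echoed in a YAML sidecar; masks as
## single-channel indexed TIFF with the class legend in the sidecar; cohorts
## as a directory with a manifest CSV (config hash in a header comment).

sidecar_path <- function(path) paste0(path, ".yaml")

#' Write / read a calibrated image as TIFF + YAML sidecar
#'
#' Pixel values are stored as 8-bit samples; the physical pixel size is
#' recorded in the TIFF resolution tags (pixels per cm) and in the sidecar.
#'
#' @param image A [calibrated_image()].
#' @param path Output `.tif` path.
#' @return `path` (write) / a [calibrated_image()] (read).
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "calibrated_image"))
  tiff::writeTIFF(image$data / 255, path,
    bits.per.sample = 8L,
    compression = "none"
  )
  yaml::write_yaml(list(
    kind = "calibrated_image",
    pixel_size_um = image$pixel_size_um,
    pixels_per_cm = 10000 / image$pixel_size_um
  ), sidecar_path(path))
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  meta <- yaml::read_yaml(sidecar_path(path))
  data <- tiff::readTIFF(path)
  calibrated_image(round(data * 255), meta$pixel_size_um)
}

#' Write / read a label mask as indexed TIFF + YAML sidecar
#'
#' Class indices are stored as 8-bit grey values; the class-name legend and
#' calibration live in the sidecar.
#'
#' @param mask A [label_mask()].
#' @param path Output `.tif` path.
#' @return `path` (write) / a [label_mask()] (read).
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  tiff::writeTIFF(unclass(mask) / 255, path, bits.per.sample = 8L, compression = "none")
  yaml::write_yaml(list(
    kind = "label_mask",
    pixel_size_um = attr(mask, "pixel_size_um"),
    classes = as.list(setNames(seq_along(attr(mask, "classes")), attr(mask, "classes")))
  ), sidecar_path(path))
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  meta <- yaml::read_yaml(sidecar_path(path))
  values <- round(tiff::readTIFF(path) * 255)
  label_mask(values, names(sort(unlist(meta$classes))), meta$pixel_size_um)
}

#' Simulate a cohort to disk
#'
#' Writes one image/mask TIFF pair per sample plus per-sample artifact CSVs
#' and a manifest CSV (sample id, age group, file paths, generator seed) with
#' the effective config hash in a header comment. Refuses to overwrite an
#' existing manifest unless `force = TRUE`.
#'
#' @param out_dir Output directory (created if missing).
#' @param n_per_age_group Samples per age group.
#' @param config_overrides Passed to [generate_cohort()].
#' @param seed Master seed.
#' @param force Overwrite an existing manifest.
#' @return The manifest tibble, invisibly.
#' @export
simulate_cohort <- function(out_dir, n_per_age_group, config_overrides = list(),
                            seed = 1L, force = FALSE) {
  manifest_path <- file.path(out_dir, "manifest.csv")
  if (file.exists(manifest_path) && !force) {
    abort(sprintf("manifest already exists at %s (use force = TRUE)", manifest_path))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(n_per_age_group, config_overrides, seed)
  cfg <- list(
    n_per_age_group = n_per_age_group,
    config_overrides = config_overrides, seed = seed
  )
  manifest <- purrr::pmap(cohort, function(sample_id, age_group, seed, image, truth, artifacts) {
    img_path <- file.path(out_dir, paste0(sample_id, ".tif"))
    mask_path <- file.path(out_dir, paste0(sample_id, "_mask.tif"))
    art_path <- file.path(out_dir, paste0(sample_id, "_artifacts.csv"))
    write_image(image, img_path)
    write_mask(truth, mask_path)
    readr::write_csv(artifacts, art_path)
    tibble(
      sample_id = sample_id, age_group = age_group, seed = seed,
      image_path = basename(img_path), mask_path = basename(mask_path),
      artifacts_path = basename(art_path)
    )
  })
  manifest <- dplyr::bind_rows(manifest)
  write_csv_stamped(manifest, manifest_path, config = cfg)
  invisible(manifest)
}

#' Read a simulated cohort back from disk
#'
#' @param dir Directory containing `manifest.csv` (or a manifest path).
#' @return A cohort tibble like [generate_cohort()] returns.
#' @export
read_cohort <- function(dir) {
  manifest_path <- if (dir.exists(dir)) file.path(dir, "manifest.csv") else dir
  base <- dirname(manifest_path)
  manifest <- read_csv_stamped(manifest_path)
  out <- purrr::pmap(manifest, function(sample_id, age_group, seed,
                                        image_path, mask_path, artifacts_path) {
    truth <- read_mask(file.path(base, mask_path))
    class(truth) <- c("ground_truth", class(truth))
    tibble(
      sample_id = sample_id, age_group = age_group, seed = seed,
      image = list(read_image(file.path(base, image_path))),
      truth = list(truth),
      artifacts = list(readr::read_csv(file.path(base, artifacts_path),
        show_col_types = FALSE
      ))
    )
  })
  dplyr::bind_rows(out)
}
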