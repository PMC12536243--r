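#' Derive a per-sample seed from a master seed
#'
#' Deterministic counter scheme: `(master + 7919 * counter) mod 2147483629`
#' (the modulus is a prime below 2^31, keeping seeds valid R integers). Used
#' everywhere a cohort or experiment fans one master seed out to elements, so
#' regenerating any single element reproduces it bit for bit.
#'
#' @param master_seed Integer master seed.
#' @param counter Non-negative integer index (vectorised).
#' @return Integer seed(s).
#' @export
derive_seed <- function(master_seed, counter) {
  stopifnot(is.numeric(master_seed), is.numeric(counter))
  as.integer((as.double(master_seed) + 7919 * as.double(counter)) %% 2147483629)
}

## Relative tolerance used when comparing physical pixel sizes. The two
## working resolutions in the presets (7.03 and 3.51 um/px) are not an exact
## 2x pair, so calibration comparisons are tolerant to 0.5%.
RES_TOL <- 0.005

same_resolution <- function(a, b) abs(a - b) <= RES_TOL * max(a, b)

## Short content hash for config provenance headers on exported CSVs.
config_hash <- function(x) substr(rlang::hash(x), 1, 12)

## Write a tibble as CSV with a provenance comment header.
write_csv_stamped <- function(x, path, config = NULL) {
  hash <- config_hash(config %||% x)
  readr::write_lines(sprintf("# intestseg config_hash: %s", hash), path)
  readr::write_csv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

read_csv_stamped <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}
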