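## Performance evaluation: signed relative area deviation against manual
## (here: ground-truth) areas, agreement categories on |RD|, intersection
## over union on rasters at each step's working resolution, Pearson
## correlation with interpretation labels, and age-group summary tables plus
## modified Bland-Altman exports.

#' Relative deviation of a model area from the manual area
#'
#' `RD = (A_model - A_manual) / A_manual * 100` (signed percent).
#'
#' @param a_model,a_manual Areas in consistent units; `a_manual` must be
#'   strictly positive (vectorised).
#' @return Signed percentages.
#' @export
relative_deviation <- function(a_model, a_manual) {
  if (any(a_manual <= 0)) abort("relative deviation undefined: A_manual must be > 0")
  (a_model - a_manual) / a_manual * 100
}

AGREEMENT_LEVELS <- c("very_good", "good", "fair", "poor")

#' Categorise a relative deviation into agreement levels
#'
#' Computed on `|RD|` with half-open intervals: `[0, 5)` very good,
#' `[5, 10)` good, `[10, 20)` fair, `[20, Inf)` poor (boundaries assigned
#' upward).
#'
#' @param rd Signed relative deviation(s) in percent.
#' @return Factor with levels very_good, good, fair, poor.
#' @export
agreement_category <- function(rd) {
  if (anyNA(rd)) abort("RD must be defined")
  cut(abs(rd),
    breaks = c(0, 5, 10, 20, Inf), labels = AGREEMENT_LEVELS,
    right = FALSE, include.lowest = TRUE
  )
}

#' Intersection over union of two masks
#'
#' @param mask_a,mask_b Logical matrices (or [label_mask()]s, whose positive
#'   class is taken) of identical dimensions.
#' @return IoU in `[0, 1]`. Two empty masks have no defined IoU (error).
#' @export
iou <- function(mask_a, mask_b) {
  as_bin <- function(m) {
    if (inherits(m, "label_mask")) m <- unclass(m) == length(attr(m, "classes"))
    m
  }
  a <- as_bin(mask_a)
  b <- as_bin(mask_b)
  stopifnot(all(dim(a) == dim(b)))
  u <- sum(a | b)
  if (u == 0) abort("IoU undefined: both masks are empty")
  sum(a & b) / u
}

IOU_LEVELS <- c("below_acceptable", "acceptable", "good", "near_perfect")

#' Interpret an IoU value
#'
#' Strictly-greater-than bands: `> 0.50` acceptable, `> 0.75` good, `> 0.90`
#' near-perfect; at or below 0.50 is below acceptable.
#'
#' @param value IoU value(s) in `[0, 1]`.
#' @return Factor over below_acceptable, acceptable, good, near_perfect.
#' @export
interpret_iou <- function(value) {
  if (any(value < 0 | value > 1)) abort("IoU values must lie in [0, 1]")
  cut(value,
    breaks = c(-Inf, 0.5, 0.75, 0.9, Inf), labels = IOU_LEVELS,
    right = TRUE
  )
}

PCC_LEVELS <- c("very_strong", "strong", "moderate", "weak", "negligible")

#' Pearson correlation with an interpretation label
#'
#' Product-moment correlation between manual and model areas, labelled on
#' `|r|`: `>= 0.90` very strong, `[0.70, 0.90)` strong, `[0.50, 0.70)`
#' moderate, `[0.30, 0.50)` weak, below negligible.
#'
#' @param xs,ys Numeric vectors, `n >= 3`, non-zero variance each.
#' @return One-row tibble: `r`, `n`, `interpretation`.
#' @export
pearson <- function(xs, ys) {
  if (length(xs) != length(ys)) abort("xs and ys must have equal length")
  if (length(xs) < 3) abort("Pearson correlation needs n >= 3")
  if (sd(xs) == 0 || sd(ys) == 0) abort("correlation undefined: zero variance")
  r <- cor(xs, ys)
  tibble(r = r, n = length(xs), interpretation = interpret_pcc(r))
}

interpret_pcc <- function(r) {
  cut(abs(r),
    breaks = c(-Inf, 0.3, 0.5, 0.7, 0.9, Inf),
    labels = rev(PCC_LEVELS), right = FALSE
  )
}

#' Evaluate a segmentation result against ground truth
#'
#' Builds one evaluation record per classification step: step 1 tissue, step
#' 2 mucosa, step 3 epithelium. Model and manual areas are measured the same
#' way (traced objects of the respective rasters) at each step's working
#' resolution, where the IoU is also computed; the ground truth is
#' block-majority downsampled to the coarse grid for steps 1-2.
#'
#' @param result A `segmentation_result` from [run_three_step_pipeline()].
#' @param truth The `ground_truth` [label_mask()] at the fine resolution.
#' @param sample_id,age_group,model_design Identifiers copied onto records.
#' @return Tibble (`eval_records`): `sample_id`, `age_group`, `step`,
#'   `model_design`, `target`, `a_model_um2`, `a_manual_um2`, `rd`,
#'   `category`, `iou`.
#' @export
evaluate_segmentation <- function(result, truth, sample_id = "sample",
                                  age_group = NA_integer_,
                                  model_design = "ad_hoc") {
  stopifnot(inherits(result, "segmentation_result"), inherits(truth, "label_mask"))
  factor <- round(result$coarse_pixel_size_um / result$fine_pixel_size_um)
  truth_coarse <- resample_mask(truth, factor)
  px_c <- attr(truth_coarse, "pixel_size_um")
  px_f <- attr(truth, "pixel_size_um")

  manual_area <- function(bin, px) {
    obj <- create_objects(binary_mask(bin, "manual", px), 0, 0)
    sum(obj$regions$area_um2)
  }
  crop_to <- function(bin, ref) bin[seq_len(nrow(ref)), seq_len(ncol(ref)), drop = FALSE]

  spec <- list(
    list(step = 1L, target = "tissue", model = result$masks$tissue,
         manual = class_mask(truth_coarse, "tissue"), px = px_c),
    list(step = 2L, target = "mucosa", model = result$masks$mucosa,
         manual = class_mask(truth_coarse, "mucosa"), px = px_c),
    list(step = 3L, target = "epithelium", model = result$masks$epithelium,
         manual = class_mask(truth, "epithelium"), px = px_f)
  )
  recs <- purrr::map(spec, function(s) {
    manual <- crop_to(s$manual, s$model)
    a_model <- manual_area(s$model, s$px)
    a_manual <- manual_area(manual, s$px)
    rd <- relative_deviation(a_model, a_manual)
    tibble(
      sample_id = sample_id, age_group = age_group, step = s$step,
      model_design = model_design, target = s$target,
      a_model_um2 = a_model, a_manual_um2 = a_manual,
      rd = rd, category = agreement_category(rd),
      iou = iou(s$model, manual)
    )
  })
  out <- dplyr::bind_rows(recs)
  class(out) <- c("eval_records", class(out))
  out
}

#' Summarise evaluation records per age group (plus pooled rows)
#'
#' Per (step, design, age group) and a pooled `"All"` row per (step,
#' design): mean and sd of the relative deviation, Pearson correlation
#' between manual and model areas with its interpretation, mean and sd of
#' the IoU, and agreement-category counts. Groups with fewer than three
#' records get no correlation (`NA`, labelled not computable); the pooled
#' rows are computed over the pooled records, not group averages.
#'
#' @param records An `eval_records` tibble (rows from
#'   [evaluate_segmentation()], possibly many samples/designs).
#' @return A `summary_table` tibble.
#' @export
summarize_performance <- function(records) {
  stopifnot(nrow(records) > 0)
  pooled <- dplyr::mutate(records, age_group = "All")
  both <- dplyr::bind_rows(
    dplyr::mutate(records, age_group = as.character(.data$age_group)),
    pooled
  )
  out <- dplyr::group_by(both, .data$step, .data$model_design, .data$age_group)
  out <- dplyr::summarise(out,
    target = .data$target[1],
    n = dplyr::n(),
    rd_mean = mean(.data$rd), rd_sd = sd(.data$rd),
    pcc = if (dplyr::n() >= 3 && sd(.data$a_manual_um2) > 0 && sd(.data$a_model_um2) > 0) {
      cor(.data$a_manual_um2, .data$a_model_um2)
    } else NA_real_,
    iou_mean = mean(.data$iou), iou_sd = sd(.data$iou),
    n_very_good = sum(.data$category == "very_good"),
    n_good = sum(.data$category == "good"),
    n_fair = sum(.data$category == "fair"),
    n_poor = sum(.data$category == "poor"),
    .groups = "drop"
  )
  out <- dplyr::mutate(out,
    pcc_interpretation = factor(
      ifelse(is.na(.data$pcc), "not_computable", as.character(interpret_pcc(.data$pcc))),
      levels = c(PCC_LEVELS, "not_computable")
    ),
    .after = "pcc"
  )
  out <- dplyr::arrange(out, .data$step, .data$model_design,
    .data$age_group != "All", suppressWarnings(as.numeric(.data$age_group)))
  class(out) <- c("summary_table", class(out))
  out
}

#' Modified Bland-Altman export: per-record deviation vs age
#'
#' @param records An `eval_records` tibble.
#' @return Tibble of `sample_id`, `age_group`, `step`, `model_design`, `rd`,
#'   `category` for plotting/export.
#' @export
bland_altman_data <- function(records) {
  as_tibble(records)[, c(
    "sample_id", "age_group", "step", "model_design", "rd", "category"
  )]
}

#' Modified Bland-Altman plot of relative deviation across age groups
#'
#' @param records An `eval_records` tibble.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(records) {
  dat <- bland_altman_data(records)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = factor(.data$age_group), y = .data$rd, colour = .data$model_design
  )) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.8) +
    ggplot2::facet_wrap(~step, labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = "Age group (days)", y = "Relative deviation (%)",
      colour = "Design"
    ) +
    ggplot2::theme_minimal()
}

#' Scatter of model vs manual areas per step
#'
#' @param records An `eval_records` tibble.
#' @return A ggplot object.
#' @export
plot_area_correlation <- function(records) {
  ggplot2::ggplot(records, ggplot2::aes(
    x = .data$a_manual_um2 / 1e6, y = .data$a_model_um2 / 1e6,
    colour = .data$model_design
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::facet_wrap(~step, scales = "free", labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = expression("Manual area (mm"^2 * ")"),
      y = expression("Model area (mm"^2 * ")"), colour = "Design"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot evaluation records (modified Bland-Altman)
#' @param object An `eval_records` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot eval_records
#' @export
autoplot.eval_records <- function(object, ...) plot_bland_altman(object)

#' Autoplot a summary table (IoU by age group)
#' @param object A `summary_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot summary_table
#' @export
autoplot.summary_table <- function(object, ...) {
  dat <- dplyr::filter(object, .data$age_group != "All")
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$age_group, y = .data$iou_mean,
    group = .data$model_design, colour = .data$model_design
  )) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$iou_mean - .data$iou_sd, ymax = .data$iou_mean + .data$iou_sd
    ), position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::facet_wrap(~step, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Age group (days)", y = "IoU", colour = "Design") +
    ggplot2::theme_minimal()
}
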