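## Training-set designs. Two presets reproduce the published budgets: the
## ad-hoc design (problematic slides added continuously, skewed towards the
## 49-day group) and the age-balanced design (every age group represented).
## Counts are samples per age group; totals are manual brush annotations
## (strokes) spread over samples and the two classes of each step.

DESIGN_PRESETS <- list(
  ad_hoc = list(
    step2 = list(counts = c(`4` = 2, `14` = 2, `25` = 2, `49` = 8, `67` = 1), total_annotations = 236),
    step3 = list(counts = c(`4` = 0, `14` = 1, `25` = 2, `49` = 3, `67` = 2), total_annotations = 172)
  ),
  age_balanced = list(
    step2 = list(counts = c(`4` = 2, `14` = 2, `25` = 2, `49` = 8, `67` = 1), total_annotations = 236),
    step3 = list(counts = c(`4` = 2, `14` = 2, `25` = 2, `49` = 2, `67` = 2), total_annotations = 285)
  )
)

STEP2_CLASSES <- c("mucosa", "submucosa_muscularis")
STEP3_CLASSES <- c("epithelium", "lamina_propria")

#' Training-set design presets
#'
#' @param name `"ad_hoc"` or `"age_balanced"`.
#' @return A `training_design`: per-step age-group sample counts and target
#'   annotation totals.
#' @export
training_design <- function(name = c("ad_hoc", "age_balanced")) {
  name <- match.arg(name)
  structure(c(DESIGN_PRESETS[[name]], list(name = name)), class = "training_design")
}

#' @export
print.training_design <- function(x, ...) {
  cat(sprintf("<training_design> %s\n", x$name))
  for (s in c("step2", "step3")) {
    cat(sprintf(
      "  %s: %d samples (%s), %d annotations\n", s, sum(x[[s]]$counts),
      paste(sprintf("%s d: %d", names(x[[s]]$counts), x[[s]]$counts), collapse = ", "),
      x[[s]]$total_annotations
    ))
  }
  invisible(x)
}

## Distribute `total` annotations over n_samples x n_classes as evenly as
## possible, earlier samples/first class absorbing remainders. Returns an
## n_samples x n_classes integer matrix summing exactly to `total`.
plan_annotations <- function(total, n_samples, n_classes = 2) {
  total <- as.integer(total)
  n_samples <- as.integer(n_samples)
  n_classes <- as.integer(n_classes)
  per_sample <- rep(total %/% n_samples, n_samples)
  if (total %% n_samples > 0) {
    per_sample[seq_len(total %% n_samples)] <- per_sample[seq_len(total %% n_samples)] + 1L
  }
  t(vapply(per_sample, function(k) {
    base <- rep(k %/% n_classes, n_classes)
    if (k %% n_classes > 0) base[seq_len(k %% n_classes)] <- base[seq_len(k %% n_classes)] + 1L
    base
  }, integer(n_classes)))
}

## Seeded selection of training sample ids matching per-age-group counts.
select_training_samples <- function(cohort, counts, seed) {
  ids <- withr::with_seed(seed, {
    unlist(lapply(names(counts), function(ag) {
      k <- counts[[ag]]
      if (k == 0) return(character())
      pool <- cohort$sample_id[cohort$age_group == as.integer(ag)]
      if (length(pool) < k) {
        abort(sprintf(
          "training design infeasible: need %d samples of age %s, cohort has %d",
          k, ag, length(pool)
        ))
      }
      sample(pool, k)
    }))
  })
  ids
}

## Build one training sample at a step's working resolution: resampled image,
## majority-downsampled truth, brush annotations, per-image stain model.
make_training_sample <- function(image, truth, sample_id, step, strokes_per_class,
                                 seed, stroke_radius_um = NULL) {
  stopifnot(step %in% 2:3)
  sm <- estimate_stain_vectors(image)
  if (step == 2) {
    cfg <- step2_feature_config()
    img_w <- resample(image, cfg$working_resolution_um)
    factor <- round(img_w$pixel_size_um / image$pixel_size_um)
    truth_w <- resample_mask(truth, factor)
    classes <- STEP2_CLASSES
    radius <- stroke_radius_um %||% 15
  } else {
    img_w <- image
    truth_w <- truth
    classes <- STEP3_CLASSES
    radius <- stroke_radius_um %||% 8
  }
  ann <- sample_annotations(truth_w, classes,
    strokes_per_class = setNames(strokes_per_class, classes),
    stroke_radius_um = radius, seed = seed
  )
  list(image = img_w, annotations = ann, sample_id = sample_id, stain_model = sm)
}

#' Train a step-2 (mucosal) or step-3 (epithelial) classifier on a cohort
#'
#' Selects the rows named in `sample_ids`, brushes the planned number of
#' annotation strokes per sample and class on the ground truth at the step's
#' working resolution, and fits the random forest with the step's feature
#' preset.
#'
#' @param cohort A cohort tibble from [generate_cohort()]/[read_cohort()].
#' @param sample_ids Training sample ids (rows of `cohort`).
#' @param total_annotations Total stroke budget spread over samples and the
#'   two classes.
#' @param seed Integer seed (annotation placement and forest).
#' @param rf_params Passed to [train_pixel_classifier()].
#' @return A `pixel_classifier`.
#' @export
train_step2_classifier <- function(cohort, sample_ids, total_annotations = 236,
                                   seed = 1L, rf_params = list()) {
  train_step_classifier(cohort, sample_ids, 2L, total_annotations, seed, rf_params)
}

#' @rdname train_step2_classifier
#' @export
train_step3_classifier <- function(cohort, sample_ids, total_annotations = 172,
                                   seed = 1L, rf_params = list()) {
  train_step_classifier(cohort, sample_ids, 3L, total_annotations, seed, rf_params)
}

train_step_classifier <- function(cohort, sample_ids, step, total_annotations,
                                  seed, rf_params = list()) {
  rows <- match(sample_ids, cohort$sample_id)
  if (anyNA(rows)) abort("sample_ids not all present in cohort")
  plan <- plan_annotations(total_annotations, length(rows))
  samples <- purrr::map(seq_along(rows), function(i) {
    r <- rows[i]
    make_training_sample(
      cohort$image[[r]], cohort$truth[[r]], cohort$sample_id[r],
      step = step, strokes_per_class = plan[i, ],
      seed = derive_seed(seed, 100L + i)
    )
  })
  cfg <- if (step == 2) step2_feature_config() else step3_feature_config()
  classes <- if (step == 2) STEP2_CLASSES else STEP3_CLASSES
  train_pixel_classifier(samples, cfg, classes, rf_params = rf_params, seed = seed)
}
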