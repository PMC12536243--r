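## Orchestration: segment whole cohorts, and run the paired ad-hoc vs
## age-balanced design comparison on one cohort (identical validation set,
## only the training-sample selection differs).

#' Segment and evaluate a cohort with trained classifiers
#'
#' Runs the three-step pipeline on each selected sample and evaluates every
#' step against the sample's ground truth. Fully deterministic given the
#' models (prediction involves no randomness).
#'
#' @param cohort A cohort tibble ([generate_cohort()] / [read_cohort()]).
#' @param step2_model,step3_model Trained `pixel_classifier`s.
#' @param sample_ids Subset of samples to process (default: all).
#' @param model_design Label copied onto the evaluation records.
#' @param keep_results Keep the per-sample `segmentation_result`s (memory
#'   heavy) alongside the records.
#' @return List: `records` (an `eval_records` tibble, 3 rows per sample) and
#'   `results` (named list, empty unless `keep_results`).
#' @export
segment_cohort <- function(cohort, step2_model, step3_model, sample_ids = NULL,
                           model_design = "ad_hoc", keep_results = FALSE) {
  ids <- sample_ids %||% cohort$sample_id
  rows <- match(ids, cohort$sample_id)
  if (anyNA(rows)) abort("sample_ids not all present in cohort")
  results <- list()
  records <- purrr::map(rows, function(r) {
    res <- run_three_step_pipeline(cohort$image[[r]], step2_model, step3_model)
    if (keep_results) results[[cohort$sample_id[r]]] <<- res
    evaluate_segmentation(res, cohort$truth[[r]],
      sample_id = cohort$sample_id[r], age_group = cohort$age_group[r],
      model_design = model_design
    )
  })
  records <- dplyr::bind_rows(records)
  class(records) <- c("eval_records", class(records))
  list(records = records, results = results)
}

#' Paired comparison of the ad-hoc and age-balanced training designs
#'
#' Both designs are trained on the same cohort (their own seeded
#' training-sample selections) and validated on an identical validation set;
#' only the training-sample selection differs. Outputs one summary table per
#' design plus a per-sample paired table.
#'
#' @param cohort A cohort tibble; must satisfy both designs' per-age-group
#'   sample counts.
#' @param designs Design names to run (see [training_design()]).
#' @param seed Master seed (training-sample selection, annotation placement,
#'   forests).
#' @param validation_ids Samples to validate on (default: the whole cohort,
#'   mirroring the published evaluation where the training images belong to
#'   the validation set too).
#' @param annotation_scale Multiplier on the preset annotation totals
#'   (scaled-down experiments stay proportionate).
#' @return List: `records` (both designs), `summaries` (named list of
#'   `summary_table`s), `paired` (per sample and step, RD and IoU of each
#'   design side by side), `models`, `training_ids`.
#' @export
run_design_experiment <- function(cohort, designs = c("ad_hoc", "age_balanced"),
                                  seed = 1L, validation_ids = NULL,
                                  annotation_scale = 1) {
  validation_ids <- validation_ids %||% cohort$sample_id
  out_records <- list()
  summaries <- list()
  models <- list()
  training_ids <- list()
  for (d in designs) {
    des <- training_design(d)
    dseed <- derive_seed(seed, match(d, designs))
    ids2 <- select_training_samples(cohort, des$step2$counts, derive_seed(dseed, 2L))
    ids3 <- select_training_samples(cohort, des$step3$counts, derive_seed(dseed, 3L))
    m2 <- train_step2_classifier(cohort, ids2,
      total_annotations = max(2, round(des$step2$total_annotations * annotation_scale)),
      seed = derive_seed(dseed, 20L)
    )
    m3 <- train_step3_classifier(cohort, ids3,
      total_annotations = max(2, round(des$step3$total_annotations * annotation_scale)),
      seed = derive_seed(dseed, 30L)
    )
    seg <- segment_cohort(cohort, m2, m3,
      sample_ids = validation_ids, model_design = d
    )
    out_records[[d]] <- seg$records
    summaries[[d]] <- summarize_performance(seg$records)
    models[[d]] <- list(step2 = m2, step3 = m3)
    training_ids[[d]] <- list(step2 = ids2, step3 = ids3)
  }
  records <- dplyr::bind_rows(out_records)
  class(records) <- c("eval_records", class(records))
  paired <- NULL
  if (length(designs) >= 2) {
    paired <- tidyr::pivot_wider(
      as_tibble(records)[, c("sample_id", "age_group", "step", "model_design", "rd", "iou")],
      names_from = "model_design", values_from = c("rd", "iou")
    )
  }
  list(
    records = records, summaries = summaries, paired = paired,
    models = models, training_ids = training_ids, seed = seed
  )
}
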