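## Steps 2-3: random-forest pixel classifiers trained on sparse brush
## annotations over the multiscale feature bank, applied hierarchically
## (mucosal segmentation inside the tissue objects, epithelial segmentation
## inside the mucosa objects). Training rows are the annotated pixels only --
## no background sampling -- matching brush-tool supervision.

DEFAULT_RF_PARAMS <- list(num.trees = 100, min.node.size = 1)

#' Train a random-forest pixel classifier on sparse annotations
#'
#' Features are computed per training image with the supplied
#' [feature_config()]; the training matrix holds exactly the annotated
#' pixels. The forest uses 100 trees, a per-split feature subset of
#' `sqrt(n_features)`, no depth cap and no class weighting unless overridden
#' through `rf_params`; the fit is deterministic for a fixed seed
#' (single-threaded).
#'
#' @param samples List of training samples, each a list with `image` (a
#'   [calibrated_image()] at the config's working resolution), `annotations`
#'   (an [sample_annotations()] set on the same grid) and optionally
#'   `sample_id` and `stain_model`.
#' @param config A [feature_config()].
#' @param classes Character vector (length 2 for the step presets); every
#'   class must have at least one annotated pixel across the set.
#' @param rf_params Named list merged over the defaults
#'   (`num.trees = 100`, `min.node.size = 1`).
#' @param seed Integer seed for the forest.
#' @return A `pixel_classifier`: fitted forest, feature config, class list,
#'   training manifest (per-sample, per-class stroke and pixel counts), seed
#'   and version tag.
#' @export
train_pixel_classifier <- function(samples, config, classes,
                                   rf_params = list(), seed = 1L) {
  stopifnot(inherits(config, "feature_config"), length(classes) >= 2)
  rf <- utils::modifyList(DEFAULT_RF_PARAMS, rf_params)
  rows <- list()
  labels <- list()
  manifest <- list()
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    ann <- s$annotations
    stopifnot(inherits(ann, "annotation_set"))
    extra <- setdiff(unique(ann$class), classes)
    if (length(extra) > 0) {
      abort(sprintf("annotation classes not in `classes`: %s", paste(extra, collapse = ", ")))
    }
    stack <- compute_feature_stack(s$image, config, s$stain_model)
    h <- dim(stack$values)[1]
    for (k in seq_len(nrow(ann))) {
      pix <- ann$pixels[[k]]
      idx <- pix[, 1] + (pix[, 2] - 1) * h
      rows[[length(rows) + 1]] <- stack_matrix(stack, idx)
      labels[[length(labels) + 1]] <- rep(ann$class[k], nrow(pix))
    }
    manifest[[i]] <- dplyr::mutate(
      dplyr::count(as_tibble(ann)[c("class", "n_pixels")], .data$class,
        wt = .data$n_pixels, name = "n_annotated_px"
      ),
      n_strokes = as.integer(table(ann$class)[.data$class]),
      sample_id = s$sample_id %||% sprintf("sample_%02d", i), .before = 1
    )
  }
  x <- do.call(rbind, rows)
  y <- factor(unlist(labels), levels = classes)
  missing <- classes[!classes %in% y]
  if (length(missing) > 0) {
    abort(sprintf("no annotated pixels for class(es): %s", paste(missing, collapse = ", ")))
  }
  if (length(unique(y)) < 2) abort("degenerate training set: only one class annotated")
  forest <- rlang::exec(ranger::ranger,
    x = as.data.frame(x), y = y,
    mtry = floor(sqrt(ncol(x))), probability = TRUE,
    importance = "impurity", seed = seed, num.threads = 1,
    !!!rf
  )
  structure(
    list(
      forest = forest, feature_config = config, classes = classes,
      manifest = dplyr::bind_rows(manifest), seed = as.integer(seed),
      rf_params = rf, n_train = nrow(x), version = "intestseg-1"
    ),
    class = "pixel_classifier"
  )
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf(
    "<pixel_classifier> %s | %d trees, %d training px, OOB error %.4f\n",
    paste(x$classes, collapse = " vs "),
    x$forest$num.trees, x$n_train, x$forest$prediction.error
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted pixel classifier: per-feature importance
#' @param x A `pixel_classifier`.
#' @param ... Unused.
#' @return Tibble with `term` (channel.feature.scale) and `importance`.
#' @method tidy pixel_classifier
#' @export
tidy.pixel_classifier <- function(x, ...) {
  imp <- ranger::importance(x$forest)
  tibble(term = names(imp), importance = as.numeric(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' One-row fit summary of a pixel classifier
#' @param x A `pixel_classifier`.
#' @param ... Unused.
#' @return One-row tibble: trees, mtry, training pixels, classes, OOB error.
#' @method glance pixel_classifier
#' @export
glance.pixel_classifier <- function(x, ...) {
  tibble(
    num_trees = x$forest$num.trees, mtry = x$forest$mtry,
    n_train_px = x$n_train, n_classes = length(x$classes),
    oob_error = x$forest$prediction.error, seed = x$seed
  )
}

#' Apply a trained pixel classifier inside a restriction mask
#'
#' Pixels outside `restrict_mask` are left unclassified (value 0) and never
#' carry a class; inside, each pixel takes the class with the largest share
#' of forest votes, ties breaking toward the first class in the declared
#' order.
#'
#' @param model A `pixel_classifier`.
#' @param image A [calibrated_image()] at the model's working resolution.
#' @param restrict_mask Optional logical matrix or binary [label_mask()];
#'   `NULL` classifies every pixel.
#' @param stain_model Optional [stain_model()] reused for the haematoxylin
#'   channel.
#' @param feature_config Optional config; must equal the training config if
#'   supplied (mismatch is refused with a diagnostic).
#' @return A [label_mask()] with classes `c("unclassified", model$classes)`,
#'   where unclassified pixels have value 0.
#' @export
apply_classifier <- function(model, image, restrict_mask = NULL,
                             stain_model = NULL, feature_config = NULL) {
  stopifnot(inherits(model, "pixel_classifier"), inherits(image, "calibrated_image"))
  if (!is.null(feature_config) && !identical(unclass(feature_config), unclass(model$feature_config))) {
    abort(paste(
      "feature config mismatch: the supplied config differs from the one the",
      "classifier was trained with (channels/features/scales/resolution must be identical)"
    ))
  }
  restrict <- if (is.null(restrict_mask)) {
    matrix(TRUE, dim(image$data)[1], dim(image$data)[2])
  } else if (inherits(restrict_mask, "label_mask")) {
    ## binary masks: the positive class is the last vocabulary entry
    unclass(restrict_mask) == length(attr(restrict_mask, "classes"))
  } else {
    restrict_mask
  }
  stopifnot(all(dim(restrict) == dim(image$data)[1:2]))
  out <- matrix(0L, nrow(restrict), ncol(restrict))
  idx <- which(restrict)
  if (length(idx) > 0) {
    stack <- compute_feature_stack(image, model$feature_config, stain_model)
    x <- as.data.frame(stack_matrix(stack, idx))
    votes <- stats::predict(model$forest, x, num.threads = 1)$predictions
    votes <- votes[, model$classes, drop = FALSE]
    out[idx] <- max.col(votes, ties.method = "first")
  }
  label_mask(out, model$classes, image$pixel_size_um)
}

#' Run the full three-step segmentation pipeline on one image
#'
#' Step 1 thresholds smoothed mean RGB at the coarse working resolution and
#' converts the tissue class to objects (minimum object 10,000 um^2, minimum
#' hole 100,000 um^2). Step 2 applies the mucosal classifier inside the
#' step-1 tissue objects and creates mucosa objects with the same rules.
#' Step 3 applies the epithelial classifier at the fine resolution inside
#' the mucosa objects and creates epithelium and lamina-propria objects with
#' minimum object and hole sizes of 1,000 um^2.
#'
#' @param image A [calibrated_image()] at the fine (step-3) resolution.
#' @param step2_model,step3_model Trained `pixel_classifier`s built with the
#'   step-2 / step-3 presets.
#' @param threshold_cfg A [threshold_config()].
#' @param object_params List of the per-step object rules (defaults are the
#'   published values).
#' @param stain_model Optional [stain_model()]; estimated once from the
#'   image when omitted (the per-image colour normalisation).
#' @return A `segmentation_result`: per-step `region_objects`, an `areas`
#'   tibble (step, class, area_um2), and the step masks (`tissue`, `mucosa`
#'   at the coarse grid; `mucosa_fine`, `epithelium`, `lamina_propria` at the
#'   fine grid).
#' @export
run_three_step_pipeline <- function(image, step2_model, step3_model,
                                    threshold_cfg = threshold_config(),
                                    object_params = list(
                                      step1 = c(min_object = 10000, min_hole = 100000),
                                      step2 = c(min_object = 10000, min_hole = 100000),
                                      step3 = c(min_object = 1000, min_hole = 1000)
                                    ),
                                    stain_model = NULL) {
  stopifnot(inherits(image, "calibrated_image"))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("%s failed: %s", what, conditionMessage(e)), parent = e)
    })
  }
  sm <- stain_model %||% stage("stain estimation", estimate_stain_vectors(image))

  ## --- Step 1: tissue detection at the coarse resolution
  coarse <- stage("step 1 (tissue detection)", {
    img_c <- resample(image, threshold_cfg$working_resolution_um)
    mask1 <- threshold_tissue(img_c, threshold_cfg)
    obj1 <- create_objects(mask1,
      object_params$step1[["min_object"]], object_params$step1[["min_hole"]],
      provenance = list(step = 1)
    )
    list(img = img_c, obj = obj1)
  })
  tissue_bin <- class_mask(coarse$obj$mask, "tissue")

  ## --- Step 2: mucosal segmentation inside the tissue objects
  step2 <- stage("step 2 (mucosal segmentation)", {
    pred <- apply_classifier(step2_model, coarse$img, tissue_bin, stain_model = sm)
    mucosa_bin <- class_mask(pred, step2_model$classes[1])
    obj <- create_objects(
      binary_mask(mucosa_bin, "mucosa", coarse$img$pixel_size_um),
      object_params$step2[["min_object"]], object_params$step2[["min_hole"]],
      provenance = list(step = 2)
    )
    list(pred = pred, obj = obj)
  })
  mucosa_bin <- class_mask(step2$obj$mask, "mucosa")

  ## --- Step 3: epithelial segmentation inside the mucosa objects, fine grid
  step3 <- stage("step 3 (epithelial segmentation)", {
    factor <- round(coarse$img$pixel_size_um / image$pixel_size_um)
    mucosa_fine <- upsample_mask(step2$obj$mask, factor)
    ## crop/pad to the fine image in case of trailing-pixel mismatch
    d <- dim(image$data)
    mf <- matrix(0L, d[1], d[2])
    mm <- unclass(mucosa_fine)
    mf[seq_len(min(d[1], nrow(mm))), seq_len(min(d[2], ncol(mm)))] <-
      mm[seq_len(min(d[1], nrow(mm))), seq_len(min(d[2], ncol(mm)))]
    restrict <- mf == 2L
    pred <- apply_classifier(step3_model, image, restrict, stain_model = sm)
    epi_bin <- class_mask(pred, step3_model$classes[1])
    lp_bin <- class_mask(pred, step3_model$classes[2])
    obj_epi <- create_objects(
      binary_mask(epi_bin, step3_model$classes[1], image$pixel_size_um),
      object_params$step3[["min_object"]], object_params$step3[["min_hole"]],
      provenance = list(step = 3)
    )
    obj_lp <- create_objects(
      binary_mask(lp_bin, step3_model$classes[2], image$pixel_size_um),
      object_params$step3[["min_object"]], object_params$step3[["min_hole"]],
      provenance = list(step = 3)
    )
    list(pred = pred, obj_epi = obj_epi, obj_lp = obj_lp, restrict = restrict)
  })

  areas <- dplyr::bind_rows(
    dplyr::mutate(measure_area(coarse$obj), step = 1L),
    dplyr::mutate(measure_area(step2$obj), step = 2L),
    dplyr::mutate(measure_area(step3$obj_epi), step = 3L),
    dplyr::mutate(measure_area(step3$obj_lp), step = 3L)
  )
  ## submucosa/muscularis = classified tissue that is not mucosa
  subm_bin <- class_mask(step2$pred, step2_model$classes[2])
  areas <- dplyr::bind_rows(
    areas,
    tibble(
      class = step2_model$classes[2], n_regions = NA_integer_,
      n_pixels = sum(subm_bin),
      area_um2 = sum(subm_bin) * coarse$img$pixel_size_um^2, step = 2L
    )
  )[, c("step", "class", "n_regions", "n_pixels", "area_um2")]

  structure(
    list(
      step1 = coarse$obj, step2 = step2$obj,
      step3_epithelium = step3$obj_epi, step3_lamina_propria = step3$obj_lp,
      areas = areas,
      masks = list(
        tissue = tissue_bin, mucosa = mucosa_bin,
        mucosa_fine = step3$restrict,
        epithelium = class_mask(step3$obj_epi$mask, step3_model$classes[1]),
        lamina_propria = class_mask(step3$obj_lp$mask, step3_model$classes[2])
      ),
      coarse_pixel_size_um = coarse$img$pixel_size_um,
      fine_pixel_size_um = image$pixel_size_um,
      stain_model = sm
    ),
    class = "segmentation_result"
  )
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("<segmentation_result>\n")
  print(as.data.frame(x$areas))
  invisible(x)
}
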