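## Synthetic H&E-like full-wall small-intestine sections with exact ground
## truth. The generator targets layer topology, colour and texture scale --
## not histologic realism: a white lumen on top, capsule-shaped villi with an
## epithelial rim and lamina-propria core rising from a crypt band, then
## submucosa and muscularis. Colours approximate H&E (haematoxylin-dark
## epithelium, eosin-pink stroma) and are perturbed per image so stain-vector
## estimation is non-trivial.

## Paint palette: mean 8-bit RGB per painted component. Classes are pairwise
## separable by design (channel distances well above the default pixel noise)
## except where overlap is the point: vacuolated fetal-type enterocytes are
## deliberately close to the pale submucosa so that classifiers never shown
## vacuolation misread them, and artifact paint mimics its error mode.
PALETTE <- list(
  background     = c(250, 250, 250),
  epithelium     = c(125,  95, 165),
  vacuolated     = c(195, 185, 215),
  goblet         = c(210, 195, 220),
  lamina_propria = c(225, 160, 190),
  nucleus        = c(110,  80, 140),
  submucosa      = c(220, 172, 196),
  muscularis     = c(205, 130, 160),
  debris         = c(180, 145, 165),
  vessel         = c(250, 249, 250),
  abscess        = c(160, 120, 155)
)

## Age-dependent morphology defaults. Younger animals: more vacuolated
## fetal-type enterocytes (replaced by ~3 weeks of age), tighter villus
## packing (smaller inter-villus gaps) and longer villi.
AGE_DEFAULTS <- tibble::tibble(
  age_group            = AGE_GROUPS,
  vacuolation_fraction = c(0.60, 0.35, 0.15, 0.05, 0.00),
  villus_spacing_um    = c(170, 185, 200, 215, 230),
  villus_length_um     = c(520, 490, 460, 430, 400),
  villus_width_um      = c(120, 120, 120, 120, 120)
)

#' Configuration for the synthetic section generator
#'
#' Defaults encode the study conditions the generator emulates: native
#' calibration 3.51 um/px (so the fine-resolution classification step runs
#' natively and the coarse steps downsample by 2x), five age groups with
#' monotone age-to-morphology defaults (younger: higher vacuolation fraction,
#' tighter villus packing, longer villi), and three switchable artifact
#' classes plus a goblet-cell density.
#'
#' @param image_size_px `c(height, width)` in pixels.
#' @param pixel_size_um Native calibration, micrometres per pixel.
#' @param age_group One of 4, 14, 25, 49, 67 (days).
#' @param villus_count Number of villi; default derived from the age group's
#'   packing (image width / spacing).
#' @param villus_length_um,villus_width_um Villus geometry; age defaults.
#' @param villus_spacing_um Centre-to-centre villus spacing; age default.
#' @param vacuolation_fraction Fraction of epithelial length rendered as pale
#'   fetal-type vacuolated enterocytes, in `[0, 1]`; age default.
#' @param goblet_density Goblet cells per millimetre of epithelial surface.
#' @param epithelial_band_um Epithelial rim width in micrometres.
#' @param artifact_flags Named logical list: `luminal_debris`,
#'   `edema_vessels`, `crypt_abscesses`.
#' @param color_noise_sd Per-channel Gaussian pixel noise (8-bit units).
#' @param region_variant `"jejunum"` (default), `"duodenum"` or `"ileum"`;
#'   variants only nudge villus geometry, no translatability claim attached.
#' @param seed Integer seed; generation is bit-reproducible given the config.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(image_size_px = c(384, 448),
                             pixel_size_um = 3.51,
                             age_group = 49,
                             villus_count = NULL,
                             villus_length_um = NULL,
                             villus_width_um = NULL,
                             villus_spacing_um = NULL,
                             vacuolation_fraction = NULL,
                             goblet_density = 4,
                             epithelial_band_um = 35,
                             artifact_flags = list(),
                             color_noise_sd = 8,
                             region_variant = "jejunum",
                             seed = 1L) {
  if (!age_group %in% AGE_GROUPS) {
    abort(sprintf("age_group must be one of %s", paste(AGE_GROUPS, collapse = ", ")))
  }
  def <- AGE_DEFAULTS[AGE_DEFAULTS$age_group == age_group, ]
  flags <- utils::modifyList(
    list(luminal_debris = FALSE, edema_vessels = FALSE, crypt_abscesses = FALSE),
    as.list(artifact_flags)
  )
  variant_scale <- switch(region_variant,
    jejunum = 1, duodenum = 0.9, ileum = 0.8,
    abort("region_variant must be jejunum, duodenum or ileum")
  )
  cfg <- list(
    image_size_px = as.integer(image_size_px),
    pixel_size_um = pixel_size_um,
    age_group = as.integer(age_group),
    villus_length_um = (villus_length_um %||% def$villus_length_um) * variant_scale,
    villus_width_um = villus_width_um %||% def$villus_width_um,
    villus_spacing_um = villus_spacing_um %||% def$villus_spacing_um,
    vacuolation_fraction = vacuolation_fraction %||% def$vacuolation_fraction,
    goblet_density = goblet_density,
    epithelial_band_um = epithelial_band_um,
    artifact_flags = flags,
    color_noise_sd = color_noise_sd,
    region_variant = region_variant,
    ## fixed wall-layer thicknesses (um)
    muscularis_um = 130, submucosa_um = 200, crypt_band_um = 260,
    seed = as.integer(seed)
  )
  cfg$villus_count <- as.integer(
    villus_count %||% floor(image_size_px[2] * pixel_size_um / cfg$villus_spacing_um)
  )
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  fr <- c(cfg$vacuolation_fraction)
  if (any(fr < 0 | fr > 1)) abort("fractions must lie in [0, 1]")
  pos <- c(
    cfg$pixel_size_um, cfg$villus_length_um, cfg$villus_width_um,
    cfg$villus_spacing_um, cfg$epithelial_band_um,
    cfg$muscularis_um, cfg$submucosa_um, cfg$crypt_band_um
  )
  if (any(pos <= 0)) abort("all physical dimensions must be strictly positive")
  if (cfg$goblet_density < 0 || cfg$color_noise_sd < 0) {
    abort("goblet_density and color_noise_sd must be non-negative")
  }
  h_um <- cfg$image_size_px[1] * cfg$pixel_size_um
  w_um <- cfg$image_size_px[2] * cfg$pixel_size_um
  need_h <- cfg$muscularis_um + cfg$submucosa_um + cfg$crypt_band_um +
    cfg$villus_length_um + 120 # lumen headroom + bottom margin
  if (h_um < need_h || w_um < cfg$villus_spacing_um + cfg$villus_width_um ||
    cfg$villus_count < 1) {
    abort(sprintf(
      "image too small for one villus at this scale (need >= %.0f um height, %.0f um width)",
      need_h, cfg$villus_spacing_um + cfg$villus_width_um
    ))
  }
  invisible(cfg)
}

#' Generate a calibrated synthetic section with exact ground truth
#'
#' Draws the layered wall geometry, paints it with per-image colour jitter and
#' per-pixel noise, rounds to 8-bit, and injects any artifacts switched on in
#' the config. Background pixels are clamped to stay bright (every raw
#' background pixel has mean RGB > 205, so the tissue threshold is meaningful
#' on synthetic data); the ground truth partitions every pixel into exactly
#' one of background, epithelium, lamina propria, submucosa/muscularis, lumen
#' content.
#'
#' @param config A [generator_config()].
#' @return A list: `image` ([calibrated_image()]), `truth` (a `ground_truth`
#'   [label_mask()] over the five-layer vocabulary), `artifacts` (tibble, one
#'   row per injected artifact: class, centre in um, area in um^2).
#' @export
generate_tissue_image <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  validate_generator_config(config)
  withr::with_seed(config$seed, {
    geo <- draw_geometry(config)
    img <- paint_section(geo, config)
  })
  truth <- label_mask(geo$labels, LAYER_CLASSES, config$pixel_size_um)
  class(truth) <- c("ground_truth", class(truth))
  out <- list(image = img, truth = truth, artifacts = empty_artifact_record())
  if (any(unlist(config$artifact_flags))) {
    inj <- inject_artifacts(out$image, out$truth, config$artifact_flags,
      seed = derive_seed(config$seed, 1L), color_noise_sd = config$color_noise_sd
    )
    out$image <- inj$image
    out$truth <- inj$truth
    out$artifacts <- inj$artifacts
  }
  out
}

empty_artifact_record <- function() {
  tibble(
    artifact_id = integer(), class = character(),
    x_um = numeric(), y_um = numeric(), area_um2 = numeric()
  )
}

## Geometry: build the 5-class label raster plus a finer "paint" raster that
## distinguishes texture components sharing a ground-truth class.
draw_geometry <- function(cfg) {
  h <- cfg$image_size_px[1]
  w <- cfg$image_size_px[2]
  px <- cfg$pixel_size_um
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)

  ## undulating, mutually parallel layer boundaries (amplitude kept below the
  ## submucosal clearance so injected vessels are never clipped)
  und <- 3.5 * sin(2 * pi * (seq_len(w) / w) * runif(1, 1.5, 2.5) + runif(1, 0, 2 * pi))
  und_m <- matrix(und, h, w, byrow = TRUE)
  margin_px <- round(20 / px)
  y_musc_bot <- h - margin_px + und_m
  y_musc_top <- y_musc_bot - cfg$muscularis_um / px
  y_subm_top <- y_musc_top - cfg$submucosa_um / px
  y_crypt_top <- y_subm_top - cfg$crypt_band_um / px

  labels <- matrix(1L, h, w) # background
  paint <- matrix("background", h, w)
  musc <- rows <= y_musc_bot & rows > y_musc_top
  subm <- rows <= y_musc_top & rows > y_subm_top
  crypt <- rows <= y_subm_top & rows > y_crypt_top
  labels[musc | subm] <- 4L
  labels[crypt] <- 3L
  paint[musc] <- "muscularis"
  paint[subm] <- "submucosa"
  paint[crypt] <- "lamina_propria"

  ## villi: capsules (disc-swept vertical segments) rising from the crypt band
  spacing_px <- cfg$villus_spacing_um / px
  n_villi <- cfg$villus_count
  centers <- (seq_len(n_villi) - 0.5) * (w / n_villi) +
    rnorm(n_villi, 0, spacing_px * 0.05)
  villus_id <- matrix(0L, h, w)
  for (i in seq_len(n_villi)) {
    r_px <- cfg$villus_width_um / 2 / px * runif(1, 0.9, 1.1)
    len_px <- cfg$villus_length_um / px * runif(1, 0.85, 1.05)
    cx <- min(max(centers[i], r_px + 2), w - r_px - 2)
    y_base <- y_crypt_top[1, round(cx)] + 3
    y_tip <- y_base - (len_px - r_px)
    ## distance to the vertical segment (cx, y_tip)-(cx, y_base)
    dy <- pmin(pmax(rows, y_tip), y_base) - rows
    dist2 <- (cols - cx)^2 + dy^2
    inside <- dist2 <= r_px^2 & rows <= y_base
    labels[inside & labels == 1L] <- 3L
    paint[inside & paint == "background"] <- "lamina_propria"
    villus_id[inside & villus_id == 0L] <- i
  }

  ## epithelium: mucosal pixels within the configured band of the luminal
  ## surface (distance to nearest background pixel)
  band_px <- cfg$epithelial_band_um / px
  dist_bg <- EBImage::distmap(matrix(as.numeric(labels != 1L), h, w))
  epi <- labels == 3L & dist_bg <= band_px & dist_bg > 0
  labels[epi] <- 2L
  paint[epi] <- "epithelium"

  ## vacuolated fetal-type enterocytes: whole villi are switched to the pale
  ## phenotype until the requested fraction of epithelial pixels is covered
  if (cfg$vacuolation_fraction > 0) {
    epi_per_villus <- tabulate(villus_id[epi], nbins = n_villi)
    ord <- sample.int(n_villi)
    target <- cfg$vacuolation_fraction * sum(epi)
    csum <- cumsum(epi_per_villus[ord])
    k <- sum(csum <= target)
    ## stochastic rounding on the marginal villus keeps the expected covered
    ## fraction equal to the configured one despite villus granularity
    if (k < n_villi) {
      rem <- (target - if (k > 0) csum[k] else 0) / max(1, epi_per_villus[ord][k + 1])
      if (runif(1) < rem) k <- k + 1L
    }
    if (k > 0) {
      vac <- epi & villus_id %in% ord[seq_len(k)]
      paint[vac] <- "vacuolated"
    }
  }

  ## goblet cells: small pale discs in the epithelial rim (ground truth stays
  ## epithelium); density is per mm of epithelial surface length
  if (cfg$goblet_density > 0) {
    surf_len_mm <- sum(epi) * px^2 / cfg$epithelial_band_um / 1000
    n_gob <- stats::rpois(1, cfg$goblet_density * surf_len_mm)
    if (n_gob > 0) {
      cand <- which(epi & paint == "epithelium")
      if (length(cand) > 0) {
        ctr <- sample(cand, min(n_gob, length(cand)))
        r_gob <- max(1, round(10 / px))
        for (id in ctr) {
          rc <- arrayInd(id, c(h, w))
          box_r <- pmax(1, rc[1] - r_gob):pmin(h, rc[1] + r_gob)
          box_c <- pmax(1, rc[2] - r_gob):pmin(w, rc[2] + r_gob)
          sub <- (rows[box_r, box_c] - rc[1])^2 + (cols[box_r, box_c] - rc[2])^2 <= r_gob^2
          pp <- paint[box_r, box_c]
          pp[sub & pp == "epithelium"] <- "goblet"
          paint[box_r, box_c] <- pp
        }
      }
    }
  }

  ## nuclear speckle texture in stroma
  speckle <- matrix(runif(h * w), h, w)
  paint[paint == "lamina_propria" & speckle < 0.10] <- "nucleus"
  paint[paint == "submucosa" & speckle < 0.03] <- "nucleus"

  list(
    labels = labels, paint = paint,
    bands = list(
      y_musc_top = y_musc_top, y_subm_top = y_subm_top,
      y_crypt_top = y_crypt_top, und = und_m
    )
  )
}

## Paint a geometry: class means + per-image jitter + per-pixel noise,
## muscularis banding, 8-bit rounding. Background (and any near-white paint)
## is clamped to [235, 255] so its mean RGB never drops to the threshold.
paint_section <- function(geo, cfg) {
  h <- nrow(geo$labels)
  w <- ncol(geo$labels)
  illum <- rnorm(3, 0, 4)
  img <- array(0, c(h, w, 3))
  banding <- 12 * sin(2 * pi * matrix(seq_len(h), h, w) / (28 / cfg$pixel_size_um))
  for (ch in 1:3) {
    base <- matrix(0, h, w)
    for (cl in names(PALETTE)) {
      sel <- geo$paint == cl
      if (!any(sel)) next
      mu <- PALETTE[[cl]][ch] + rnorm(1, 0, 2)
      if (!cl %in% c("background", "vessel")) mu <- mu + illum[ch]
      base[sel] <- mu
    }
    base[geo$paint == "muscularis"] <- base[geo$paint == "muscularis"] +
      banding[geo$paint == "muscularis"]
    noisy <- base + rnorm(h * w, 0, cfg$color_noise_sd)
    bright <- geo$paint %in% c("background", "vessel")
    noisy[bright] <- pmin(pmax(noisy[bright], 235), 255)
    img[, , ch] <- round(pmin(pmax(noisy, 0), 255))
  }
  calibrated_image(img, cfg$pixel_size_um)
}

#' Inject artifact classes into a generated section
#'
#' Reproduces, as controlled insertions, the error-prone structures seen on
#' real slides: stained luminal debris (labelled lumen content, i.e. not
#' tissue), dilated unstained submucosal vessels (near-white paint but still
#' submucosa/muscularis in the ground truth), and debris-filled crypt
#' abscesses (a lumen carved out of the lamina propria, ringed by
#' epithelium). Each artifact modifies pixels only inside its targeted
#' compartment.
#'
#' @param image A [calibrated_image()].
#' @param truth The aligned `ground_truth` [label_mask()].
#' @param flags Named logical list: `luminal_debris`, `edema_vessels`,
#'   `crypt_abscesses`.
#' @param seed Integer seed.
#' @param color_noise_sd Pixel noise used for artifact paint.
#' @return List: `image`, `truth`, `artifacts` (tibble with class, centre,
#'   area in um^2).
#' @export
inject_artifacts <- function(image, truth, flags, seed = 1L, color_noise_sd = 8) {
  stopifnot(inherits(image, "calibrated_image"), inherits(truth, "label_mask"))
  if (!all(dim(image$data)[1:2] == dim(truth))) abort("truth not aligned with image")
  flags <- utils::modifyList(
    list(luminal_debris = FALSE, edema_vessels = FALSE, crypt_abscesses = FALSE),
    as.list(flags)
  )
  rec <- empty_artifact_record()
  if (!any(unlist(flags))) {
    return(list(image = image, truth = truth, artifacts = rec))
  }
  px <- image$pixel_size_um
  h <- nrow(truth)
  w <- ncol(truth)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  img <- image$data
  lab <- unclass(truth)
  cls <- attr(truth, "classes")

  paint_disc <- function(sel, color) {
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[sel] <- round(pmin(pmax(
        color[ch] + rnorm(sum(sel), 0, color_noise_sd), 0
      ), 255))
      img[, , ch] <<- plane
    }
  }
  add_rec <- function(class, cx, cy, area) {
    rec <<- dplyr::bind_rows(rec, tibble(
      artifact_id = nrow(rec) + 1L, class = class,
      x_um = cx * px, y_um = cy * px, area_um2 = area
    ))
  }

  withr::with_seed(seed, {
    if (isTRUE(flags$luminal_debris)) {
      ## lumen = background pixels well above the tissue surface
      n_blob <- sample(2:4, 1)
      bg <- lab == 1L
      d_tis <- EBImage::distmap(matrix(as.numeric(bg), h, w))
      for (b in seq_len(n_blob)) {
        r_px <- 70 / px * runif(1, 0.8, 1.2)
        cand <- which(bg & d_tis > r_px * 0.6 & rows < h / 2)
        if (length(cand) == 0) next
        ctr <- arrayInd(sample(cand, 1), c(h, w))
        sel <- matrix(FALSE, h, w)
        for (k in 1:3) { # irregular blob: union of jittered discs
          oy <- rnorm(1, 0, r_px * 0.4)
          ox <- rnorm(1, 0, r_px * 0.4)
          sel <- sel | ((rows - ctr[1] - oy)^2 + (cols - ctr[2] - ox)^2 <= (r_px * runif(1, 0.6, 1))^2)
        }
        sel <- sel & bg
        if (!any(sel)) next
        paint_disc(sel, PALETTE$debris)
        lab[sel] <- match("lumen_content", cls)
        add_rec("luminal_debris", ctr[2], ctr[1], sum(sel) * px^2)
      }
    }
    if (isTRUE(flags$edema_vessels)) {
      ## one dilated unstained vessel in the submucosa; half-axes sized so the
      ## area clears the step-1 minimum hole size (1e5 um^2)
      subm_rows <- which(apply(lab == 4L, 1, any))
      a_px <- 460 / px
      b_px <- 80 / px
      ## vertical centre: middle of the submucosal band (above muscularis)
      cy <- stats::quantile(subm_rows, 0.30, names = FALSE)
      cx <- runif(1, a_px + 4, w - a_px - 4)
      sel <- ((cols - cx) / a_px)^2 + ((rows - cy) / b_px)^2 <= 1
      sel <- sel & lab == 4L
      paint_disc(sel, PALETTE$vessel)
      ## vessels are unstained tissue: clamp bright like background
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[sel] <- pmin(pmax(plane[sel], 235), 255)
        img[, , ch] <- plane
      }
      add_rec("edema_vessel", cx, cy, sum(sel) * px^2)
    }
    if (isTRUE(flags$crypt_abscesses)) {
      ## debris-filled crypt lumens in the crypt band, ringed by epithelium;
      ## ground truth: lumen_content (part of neither epithelium nor lamina
      ## propria), per the manual-annotation convention
      n_abs <- sample(2:3, 1)
      for (b in seq_len(n_abs)) {
        ## recompute the lamina-propria mask so abscesses never overlap one
        ## another (earlier injections have already relabelled their pixels)
        lp <- lab == match("lamina_propria", cls)
        d_edge <- EBImage::distmap(matrix(as.numeric(lp), h, w))
        r_px <- 50 / px * runif(1, 0.9, 1.2)
        ring_px <- 8 / px
        cand <- which(lp & d_edge > r_px + ring_px + 1 & rows > h * 0.45)
        if (length(cand) == 0) next
        ctr <- arrayInd(sample(cand, 1), c(h, w))
        d2 <- (rows - ctr[1])^2 + (cols - ctr[2])^2
        core <- d2 <= r_px^2 & lp
        ring <- d2 <= (r_px + ring_px)^2 & !core & lp
        if (!any(core)) next
        paint_disc(core, PALETTE$abscess)
        paint_disc(ring, PALETTE$epithelium)
        lab[core] <- match("lumen_content", cls)
        lab[ring] <- match("epithelium", cls)
        add_rec("crypt_abscess", ctr[2], ctr[1], sum(core) * px^2)
      }
    }
  })
  new_truth <- label_mask(lab, cls, px)
  class(new_truth) <- c("ground_truth", class(new_truth))
  list(
    image = calibrated_image(img, px),
    truth = new_truth,
    artifacts = rec
  )
}

#' Sample sparse brush-style annotations from a ground-truth mask
#'
#' Emulates interactive brush supervision: each stroke is a disc-swept random
#' walk lying entirely inside one ground-truth class region (the disc of the
#' configured radius must fit at every path point). Derived compartments
#' (`"tissue"`, `"mucosa"`) are valid class names, matching how mucosa vs
#' submucosa/muscularis examples are brushed.
#'
#' @param truth A `ground_truth` [label_mask()] at the working resolution.
#' @param classes Character vector of class names to annotate.
#' @param strokes_per_class Strokes per class: a single count or a named
#'   vector/list keyed by class.
#' @param stroke_radius_um Brush radius in micrometres.
#' @param seed Integer seed.
#' @param stroke_length_um Target swept path length in micrometres.
#' @return An `annotation_set`: tibble with one row per stroke
#'   (`stroke_id`, `class`, `n_pixels`, `pixels` list-column of (row, col)
#'   matrices), carrying the mask dimensions and calibration as attributes.
#' @export
sample_annotations <- function(truth, classes, strokes_per_class,
                               stroke_radius_um = 15, seed = 1L,
                               stroke_length_um = 160) {
  stopifnot(inherits(truth, "label_mask"))
  px <- attr(truth, "pixel_size_um")
  h <- nrow(truth)
  w <- ncol(truth)
  counts <- if (length(strokes_per_class) == 1 && is.null(names(strokes_per_class))) {
    setNames(rep(as.integer(strokes_per_class), length(classes)), classes)
  } else {
    unlist(strokes_per_class)[classes]
  }
  if (anyNA(counts)) abort("strokes_per_class must cover every requested class")
  r_px <- max(1, round(stroke_radius_um / px))
  n_steps <- max(2, round(stroke_length_um / px))
  strokes <- list()
  withr::with_seed(seed, {
    for (cl in classes) {
      n_strokes <- counts[[cl]]
      if (n_strokes == 0) next
      m <- class_mask(truth, cl)
      if (!any(m)) abort(sprintf("class '%s' not present in ground truth", cl))
      adm <- EBImage::distmap(matrix(as.numeric(m), h, w)) > r_px
      if (!any(adm)) {
        abort(sprintf(
          "class '%s' region too small for a stroke of radius %.0f um", cl, stroke_radius_um
        ))
      }
      cand <- which(adm)
      for (s in seq_len(n_strokes)) {
        start <- arrayInd(sample(cand, 1), c(h, w))
        path <- walk_admissible(adm, start, n_steps)
        pix <- sweep_disc(path, r_px, h, w)
        keep <- m[pix] # guaranteed TRUE by construction; belt and braces
        pix <- pix[keep, , drop = FALSE]
        strokes[[length(strokes) + 1]] <- tibble(
          class = cl, n_pixels = nrow(pix), pixels = list(pix)
        )
      }
    }
  })
  out <- if (length(strokes)) dplyr::bind_rows(strokes) else {
    tibble(class = character(), n_pixels = integer(), pixels = list())
  }
  out <- dplyr::mutate(out, stroke_id = dplyr::row_number(), .before = 1)
  structure(out,
    dim_px = c(h, w), pixel_size_um = px,
    class = c("annotation_set", class(out))
  )
}

## Directed random walk constrained to the admissible set (pixels where the
## brush disc fits inside the class region).
walk_admissible <- function(adm, start, n_steps) {
  h <- nrow(adm)
  w <- ncol(adm)
  theta <- runif(1, 0, 2 * pi)
  pos <- start
  path <- matrix(0L, n_steps, 2)
  path[1, ] <- pos
  n_done <- 1L
  for (s in 2:n_steps) {
    theta <- theta + rnorm(1, 0, 0.35)
    moved <- FALSE
    for (dtheta in c(0, 0.6, -0.6, 1.2, -1.2, 1.8, -1.8, 2.4, -2.4)) {
      cand <- pos + c(round(sin(theta + dtheta)), round(cos(theta + dtheta)))
      if (all(cand == pos)) next
      if (cand[1] < 1 || cand[1] > h || cand[2] < 1 || cand[2] > w) next
      if (adm[cand[1], cand[2]]) {
        pos <- cand
        theta <- theta + dtheta
        moved <- TRUE
        break
      }
    }
    if (!moved) break
    path[s, ] <- pos
    n_done <- s
  }
  path[seq_len(n_done), , drop = FALSE]
}

## Union of discs of radius r centred on the path points -> (row, col) matrix.
sweep_disc <- function(path, r, h, w) {
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  offs <- offs[offs$dr^2 + offs$dc^2 <= r^2, ]
  pts <- unique(data.frame(
    r = rep(path[, 1], each = nrow(offs)) + offs$dr,
    c = rep(path[, 2], each = nrow(offs)) + offs$dc
  ))
  pts <- pts[pts$r >= 1 & pts$r <= h & pts$c >= 1 & pts$c <= w, ]
  as.matrix(pts)
}

#' Generate a multi-age synthetic cohort
#'
#' One sample per row, `n_per_age_group` samples in each of the five age
#' groups, each generated from its own derived seed (see [derive_seed()]) so
#' the cohort is reproducible element-wise.
#'
#' @param n_per_age_group Samples per age group (>= 1).
#' @param config_overrides Named list of [generator_config()] arguments
#'   applied to every sample (age group and seed are set per sample).
#' @param seed Master seed.
#' @return Tibble: `sample_id`, `age_group`, `seed`, and list-columns
#'   `image`, `truth`, `artifacts`.
#' @export
generate_cohort <- function(n_per_age_group, config_overrides = list(), seed = 1L) {
  stopifnot(n_per_age_group >= 1)
  plan <- tidyr::expand_grid(age_group = AGE_GROUPS, rep = seq_len(n_per_age_group))
  plan <- dplyr::mutate(plan,
    sample_id = sprintf("S%03d_age%02d", dplyr::row_number(), .data$age_group),
    seed = derive_seed(seed, dplyr::row_number())
  )
  out <- purrr::pmap(plan, function(age_group, rep, sample_id, seed) {
    cfg <- rlang::exec(generator_config,
      age_group = age_group, seed = seed, !!!config_overrides
    )
    gen <- generate_tissue_image(cfg)
    tibble(
      sample_id = sample_id, age_group = age_group, seed = seed,
      image = list(gen$image), truth = list(gen$truth),
      artifacts = list(gen$artifacts)
    )
  })
  dplyr::bind_rows(out)
}
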