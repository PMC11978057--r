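# Deterministic synthetic face-image generator.  Stands in for the
# undeposited monkey recordings: procedurally composed faces (ellipse head,
# eye discs, muzzle, nostrils, brow band, band-limited fur texture) with
# identity carried by both global geometry (favours eigenfaces) and texture
# statistics (favours LBP histograms), plus nuisance variation in lighting,
# pose and sensor noise.

# parameter bounds of the identity shape space; distances for the
# separation constraint are computed on coordinates normalized by these
shape_bounds <- function() {
  list(face_a   = c(0.58, 0.72),   # head half-width, fraction of crop half-width
       face_b   = c(0.66, 0.80),   # head half-height
       eye_dx   = c(0.22, 0.34),   # eye half-spacing
       eye_y    = c(-0.32, -0.18), # eye vertical center
       eye_r    = c(0.05, 0.09),
       muzzle_w = c(0.18, 0.30),
       muzzle_h = c(0.14, 0.24),
       muzzle_y = c(0.25, 0.40),
       brow_y   = c(-0.50, -0.38),
       fur_freq = c(3, 8),         # texture cycles across the face
       fur_amp  = c(8, 20),        # texture contrast, intensity units
       base_tone = c(120, 150))    # mean facial intensity
}

#' Generate a population of identity templates
#'
#' Draws `n_identities` face templates uniformly inside the shape-parameter
#' bounds, rejection-sampling until every pair is separated by at least
#' `separation` in normalized (unit-cube) parameter space.  Same seed, same
#' population.
#'
#' @param n_identities Number of identities, >= 2.  The default 8 mirrors a
#'   small individually-housed cohort.
#' @param seed Integer seed; the population is a pure function of it.
#' @param separation Minimum pairwise Euclidean distance between templates in
#'   normalized parameter space.
#' @return A list of `identity_template` objects with fields `id`,
#'   `shape_params` and `base_texture_seed`.
#' @export
make_population <- function(n_identities = 8, seed = 1, separation = 0.25) {
  if (n_identities < 2) stopf("need at least 2 identities")
  if (separation <= 0) stopf("separation must be > 0")
  b <- shape_bounds()
  lo <- vapply(b, `[`, numeric(1), 1); hi <- vapply(b, `[`, numeric(1), 2)
  d <- length(b)
  with_seed(seed, {
    unit <- matrix(stats::runif(n_identities * d), n_identities, d)
    ok <- function(u) {
      if (nrow(u) < 2) return(TRUE)
      min(stats::dist(u)) >= separation
    }
    attempts <- 0L
    while (!ok(unit)) {
      # resample the worst offender only, keeping the rest of the draw stable
      dm <- as.matrix(stats::dist(unit)); diag(dm) <- Inf
      worst <- which.min(apply(dm, 1, min))
      unit[worst, ] <- stats::runif(d)
      attempts <- attempts + 1L
      if (attempts > 5000L)
        stopf("cannot satisfy separation %g with %d identities", separation, n_identities)
    }
    tex_seeds <- sample.int(.Machine$integer.max - 1L, n_identities)
    lapply(seq_len(n_identities), function(i) {
      p <- lo + unit[i, ] * (hi - lo)
      names(p) <- names(b)
      structure(list(id = sprintf("ID%02d", i), shape_params = p,
                     shape_unit = unit[i, ], base_texture_seed = tex_seeds[i]),
                class = "identity_template")
    })
  })
}

#' Rendering configuration for one synthetic image
#'
#' Holds the nuisance parameters of a single render.  `pose_jitter_px` and
#' `pose_jitter_deg` are maxima; the realized translation and rotation are
#' drawn uniformly within them from the render seed.
#'
#' @param lighting_gain Multiplicative intensity factor (1 = neutral).
#' @param lighting_gradient Length-2 slope `(gx, gy)` of a linear shading
#'   ramp across the crop, per normalized coordinate.
#' @param pose_jitter_px Maximum translation, pixels.
#' @param pose_jitter_deg Maximum rotation, degrees.
#' @param noise_sd Additive Gaussian sensor noise, intensity units (0-255 scale).
#' @param blur_sigma Gaussian blur standard deviation, pixels.
#' @return A `render_config` object.
#' @export
render_config <- function(lighting_gain = 1, lighting_gradient = c(0, 0),
                          pose_jitter_px = 0, pose_jitter_deg = 0,
                          noise_sd = 0, blur_sigma = 0) {
  stopifnot(lighting_gain > 0, length(lighting_gradient) == 2,
            pose_jitter_px >= 0, pose_jitter_deg >= 0,
            noise_sd >= 0, blur_sigma >= 0)
  structure(list(lighting_gain = lighting_gain,
                 lighting_gradient = as.numeric(lighting_gradient),
                 pose_jitter_px = pose_jitter_px,
                 pose_jitter_deg = pose_jitter_deg,
                 noise_sd = noise_sd, blur_sigma = blur_sigma),
            class = "render_config")
}

# smooth band-limited noise field: coarse N(0,1) grid interpolated bilinearly
# at face coordinates, so the texture is rigid with respect to the face
fur_field <- function(u, v, freq, tex_seed) {
  g <- as.integer(ceiling(freq)) + 3L
  grid <- with_seed(tex_seed, matrix(stats::rnorm(g * g), g, g))
  # map [-1.2, 1.2] -> [1, g]
  gu <- pmin(pmax((u + 1.2) / 2.4, 0), 1) * (g - 1) + 1
  gv <- pmin(pmax((v + 1.2) / 2.4, 0), 1) * (g - 1) + 1
  i0 <- pmin(floor(gv), g - 1); j0 <- pmin(floor(gu), g - 1)
  fi <- gv - i0; fj <- gu - j0
  grid[cbind(i0, j0)] * (1 - fi) * (1 - fj) +
    grid[cbind(i0 + 1, j0)] * fi * (1 - fj) +
    grid[cbind(i0, j0 + 1)] * (1 - fi) * fj +
    grid[cbind(i0 + 1, j0 + 1)] * fi * fj
}

# separable gaussian blur with edge replication
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  hw <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(-hw:hw, sd = sigma); k <- k / sum(k)
  h <- nrow(m); w <- ncol(m)
  # rows
  out <- matrix(0, h, w)
  for (j in -hw:hw) {
    idx <- pmin(pmax(seq_len(h) + j, 1L), h)
    out <- out + k[j + hw + 1L] * m[idx, , drop = FALSE]
  }
  m <- out
  out <- matrix(0, h, w)
  for (j in -hw:hw) {
    idx <- pmin(pmax(seq_len(w) + j, 1L), w)
    out <- out + k[j + hw + 1L] * m[, idx, drop = FALSE]
  }
  out
}

#' Render one synthetic face image
#'
#' Deterministic per (template, config, seed).  Composition happens in face
#' coordinates so pose jitter moves geometry and fur texture together; the
#' pipeline is compose -> blur -> additive noise -> integer quantization ->
#' lighting (gain and linear gradient) -> clip.  The lighting gain is applied
#' after quantization, so a gain >= 1 on a non-saturating render acts as a
#' strictly increasing intensity map — the transformation LBP histograms are
#' invariant to.
#'
#' @param template An `identity_template` from [make_population()].
#' @param config A [render_config()].
#' @param seed Integer seed for the per-render jitter and noise draws.
#' @param out_h,out_w Output (pre-crop) size in pixels.
#' @return An [rgb_image] (channels identical).
#' @export
render_face <- function(template, config = render_config(), seed = 1,
                        out_h = 330L, out_w = 220L) {
  stopifnot(inherits(template, "identity_template"), inherits(config, "render_config"))
  p <- template$shape_params
  draws <- with_seed(seed, stats::runif(3, -1, 1))
  tx <- draws[1] * config$pose_jitter_px / (out_w / 2)
  ty <- draws[2] * config$pose_jitter_px / (out_h / 2)
  th <- draws[3] * config$pose_jitter_deg * pi / 180

  x <- (seq_len(out_w) - (out_w + 1) / 2) / (out_w / 2)  # [-1, 1] across width
  y <- (seq_len(out_h) - (out_h + 1) / 2) / (out_h / 2)
  X <- matrix(x, out_h, out_w, byrow = TRUE)
  Y <- matrix(y, out_h, out_w)
  # inverse pose transform into face coordinates
  u <-  cos(th) * (X - tx) + sin(th) * (Y - ty)
  v <- -sin(th) * (X - tx) + cos(th) * (Y - ty)

  img <- matrix(50, out_h, out_w)                        # background
  face <- (u / p["face_a"])^2 + (v / p["face_b"])^2 <= 1
  fur <- fur_field(as.vector(u), as.vector(v), p["fur_freq"], template$base_texture_seed)
  img[face] <- p["base_tone"] + p["fur_amp"] * fur[as.vector(face)]
  # brow band
  brow <- face & abs(v - p["brow_y"]) < 0.035
  img[brow] <- img[brow] - 35
  # muzzle plate, slightly lighter
  muz <- ((u / p["muzzle_w"])^2 + ((v - p["muzzle_y"]) / p["muzzle_h"])^2) <= 1
  img[muz] <- img[muz] + 25
  # nostrils and mouth line inside the muzzle
  nos <- ((abs(u) - p["muzzle_w"] * 0.35)^2 + (v - p["muzzle_y"])^2) <= 0.015^2 * 4
  img[nos & muz] <- 45
  mouth <- muz & abs(v - (p["muzzle_y"] + p["muzzle_h"] * 0.55)) < 0.015 & abs(u) < p["muzzle_w"] * 0.7
  img[mouth] <- 60
  # eyes
  eye <- ((abs(u) - p["eye_dx"])^2 + (v - p["eye_y"])^2) <= p["eye_r"]^2
  img[eye] <- 28
  glint <- ((abs(u) - p["eye_dx"] + p["eye_r"] * 0.35)^2 +
              (v - p["eye_y"] + p["eye_r"] * 0.35)^2) <= (p["eye_r"] * 0.25)^2
  img[glint & eye] <- 180

  img <- gaussian_blur(img, config$blur_sigma)
  if (config$noise_sd > 0) {
    noise <- with_seed(seed + 1L, stats::rnorm(length(img), sd = config$noise_sd))
    img <- img + noise
  }
  img <- round_half_up(img)                              # integer sensor grid
  shade <- config$lighting_gain * (1 + config$lighting_gradient[1] * X +
                                       config$lighting_gradient[2] * Y)
  img <- clip255(round_half_up(img * shade))
  rgb_image(array(rep(img, 3L), dim = c(out_h, out_w, 3L)))
}

#' In-memory labeled synthetic face set
#'
#' Renders `images_per_id` preprocessed face crops per identity at the
#' canonical resolution, with per-image nuisance configurations drawn from
#' `config_ranges`.  This is the object [cross_validate()] and
#' [comparison_grid()] consume.
#'
#' @param population From [make_population()].
#' @param images_per_id Images per identity (default 60).
#' @param config_ranges Named list of nuisance ranges; see
#'   [default_config_ranges()].
#' @param seed Integer seed.
#' @param target_h,target_w Canonical crop resolution.
#' @return A `face_dataset`: list with `images` (list of [gray_image]),
#'   `labels` (character vector) and `configs` (per-image render settings).
#' @export
synth_dataset <- function(population, images_per_id = 60,
                          config_ranges = default_config_ranges(), seed = 1,
                          target_h = canonical_size()[1],
                          target_w = canonical_size()[2]) {
  raw <- synth_renders(population, images_per_id, config_ranges, seed)
  images <- lapply(raw$frames, function(fr)
    resize_canonical(to_grayscale(fr), target_h, target_w))
  face_dataset(images, raw$labels, configs = raw$configs)
}

# raw (integer, pre-crop) renders shared by the in-memory and on-disk paths,
# so that preprocessing a written PNG reproduces the in-memory crop exactly
synth_renders <- function(population, images_per_id, config_ranges, seed) {
  n <- length(population) * images_per_id
  seeds <- derive_seeds(seed, 2L * n)
  frames <- vector("list", n); labels <- character(n); configs <- vector("list", n)
  i <- 0L
  for (tmpl in population) {
    for (k in seq_len(images_per_id)) {
      i <- i + 1L
      cfg <- draw_config(config_ranges, seeds[2L * i - 1L])
      frames[[i]] <- render_face(tmpl, cfg, seed = seeds[2L * i])
      labels[i] <- tmpl$id
      configs[[i]] <- cfg
    }
  }
  list(frames = frames, labels = labels, configs = configs)
}

#' Default nuisance ranges of the generator
#'
#' The stated world of the synthetic benchmark: uncontrolled lighting
#' (gain 0.8-1.2 with a mild linear shading ramp), modest pose jitter from a
#' freely moving animal (up to 6 px translation, 5 degrees rotation), light
#' motion/compression blur and moderate sensor noise (sd 8 on the 0-255
#' scale).
#'
#' @return Named list of ranges consumed by [synth_dataset()].
#' @export
default_config_ranges <- function() {
  list(lighting_gain = c(0.8, 1.2),
       lighting_gradient = c(-0.15, 0.15),
       pose_jitter_px = 6,
       pose_jitter_deg = 5,
       noise_sd = 8,
       blur_sigma = c(0.5, 1.2))
}

draw_config <- function(r, seed) {
  u <- with_seed(seed, stats::runif(4))
  render_config(
    lighting_gain = r$lighting_gain[1] + u[1] * diff(r$lighting_gain),
    lighting_gradient = c(r$lighting_gradient[1] + u[2] * diff(r$lighting_gradient),
                          r$lighting_gradient[1] + u[3] * diff(r$lighting_gradient)),
    pose_jitter_px = r$pose_jitter_px,
    pose_jitter_deg = r$pose_jitter_deg,
    noise_sd = r$noise_sd,
    blur_sigma = r$blur_sigma[1] + u[4] * diff(r$blur_sigma))
}

#' Labeled face set container
#'
#' @param images List of [gray_image] crops, all at one resolution.
#' @param labels Character identity per image.
#' @param configs Optional per-image provenance.
#' @return A `face_dataset`.
#' @export
face_dataset <- function(images, labels, configs = NULL) {
  if (length(images) != length(labels)) stopf("images/labels length mismatch")
  structure(list(images = images, labels = as.character(labels), configs = configs),
            class = "face_dataset")
}

#' @export
print.face_dataset <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("<face_dataset: %d images, %d identities (%s images/id)>\n",
              length(x$images), length(tab),
              paste(range(tab), collapse = "-")))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Writes the raw face images as PNG (preprocessing to grayscale and the
#' canonical resolution is [load_dataset()]'s job, mirroring how camera
#' crops are handled), a CSV manifest (`image_path`, `identity_id`), a JSON
#' log of the per-image render configurations, and a JSON sidecar of
#' full-face ground-truth boxes for the fixture detector.
#'
#' @inheritParams synth_dataset
#' @param dir Output directory (created if missing).
#' @return Path of the manifest CSV, invisibly.
#' @export
make_dataset <- function(population, dir, images_per_id = 60,
                         config_ranges = default_config_ranges(), seed = 1) {
  raw <- synth_renders(population, images_per_id, config_ranges, seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  h <- dim(raw$frames[[1]])[1]; w <- dim(raw$frames[[1]])[2]
  paths <- character(length(raw$frames)); boxes <- vector("list", length(raw$frames))
  for (i in seq_along(raw$frames)) {
    paths[i] <- sprintf("img_%04d.png", i)
    write_image(raw$frames[[i]], file.path(dir, paths[i]))
    boxes[[i]] <- list(frame_index = i - 1L, x0 = 0L, y0 = 0L, x1 = w, y1 = h,
                       score = 1.0, identity_id = raw$labels[i])
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(data.frame(image_path = paths, identity_id = raw$labels),
                   manifest, row.names = FALSE, quote = FALSE)
  cfg <- lapply(raw$configs, unclass)
  jsonlite::write_json(cfg, file.path(dir, "render_configs.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(boxes, file.path(dir, "boxes.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Load a face dataset from a manifest
#'
#' Reads each manifest image and applies the canonical preprocessing
#' (grayscale by channel averaging, bilinear resize).
#'
#' @param manifest_path Manifest CSV path (see [read_manifest()]).
#' @param target_h,target_w Canonical resolution.
#' @return A `face_dataset`.
#' @export
load_dataset <- function(manifest_path,
                         target_h = canonical_size()[1],
                         target_w = canonical_size()[2]) {
  mf <- read_manifest(manifest_path)
  images <- lapply(mf$image_path, function(p)
    resize_canonical(to_grayscale(read_image(p)), target_h, target_w))
  face_dataset(images, mf$identity_id)
}

#' Render a multi-identity synthetic video stream
#'
#' Emulates a group-cage recording: the timeline is cut into segments of
#' roughly `segment_s` seconds, one identity visible per segment, each frame
#' a composited landscape scene containing that identity's jittered face.
#' Ground-truth boxes are returned alongside for the fixture detector.
#'
#' @param population From [make_population()].
#' @param duration_s Stream length, seconds.
#' @param fps Frame rate (default 10, the resampled pipeline rate).
#' @param segment_s Seconds per visible identity segment.
#' @param config_ranges Nuisance ranges per frame.
#' @param seed Integer seed.
#' @param scene_h,scene_w Scene (camera frame) size.
#' @return List with `stream` (a [frame_stream]), `boxes` (data.frame sidecar
#'   of ground-truth boxes) and `truth` (identity visible per frame).
#' @export
synth_video <- function(population, duration_s = 10, fps = 10, segment_s = 3,
                        config_ranges = default_config_ranges(), seed = 1,
                        scene_h = 360L, scene_w = 480L) {
  nframes <- as.integer(floor(duration_s * fps + 1e-9)) + 1L
  ts <- (seq_len(nframes) - 1L) / fps
  seg <- pmin(floor(ts / segment_s) %% length(population) + 1L, length(population))
  seeds <- derive_seeds(seed, 2L * nframes)
  face_h <- 165L; face_w <- 110L
  frames <- vector("list", nframes)
  boxes <- vector("list", nframes)
  for (i in seq_len(nframes)) {
    tmpl <- population[[seg[i]]]
    cfg <- draw_config(config_ranges, seeds[2L * i - 1L])
    crop <- render_face(tmpl, cfg, seed = seeds[2L * i],
                        out_h = face_h, out_w = face_w)
    scene <- array(40, dim = c(scene_h, scene_w, 3L))
    # slow horizontal drift of the animal across its segment
    x0 <- as.integer(60 + 40 * sin(2 * pi * ts[i] / max(duration_s, 1)) +
                       (seg[i] - 1) * 17) %% (scene_w - face_w)
    y0 <- as.integer(40 + (seg[i] * 23) %% (scene_h - face_h - 60))
    scene[y0 + seq_len(face_h), x0 + seq_len(face_w), ] <- unclass(crop)
    frames[[i]] <- rgb_image(scene)
    boxes[[i]] <- data.frame(frame_index = i - 1L, x0 = x0, y0 = y0,
                             x1 = x0 + face_w, y1 = y0 + face_h,
                             score = 1.0, identity_id = tmpl$id)
  }
  list(stream = frame_stream(frames, ts, fps),
       boxes = do.call(rbind, boxes),
       truth = vapply(population[seg], `[[`, character(1), "id"))
}
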