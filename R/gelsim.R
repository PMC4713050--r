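#' Configuration for the synthetic gel simulator
#'
#' Builds the configuration object consumed by [generate_dataset()]. The
#' defaults state the simulated world: ten 1024 x 1024 8-bit images, each
#' carrying 50 dark protein spots and 50 noise regions (plain background,
#' higher-variance patches, crack-like line artifacts), for 1000 labelled
#' regions of interest in total.
#'
#' @param images Number of gel images to simulate.
#' @param width,height Image size in pixels.
#' @param spots_per_image,noise_per_image Labelled ROIs per image and class.
#' @param background Constant light background grey level (0 = black).
#' @param noise_sd Standard deviation of the i.i.d. Gaussian pixel noise.
#' @param shading_amplitude Peak-to-trough amplitude of a smooth
#'   low-frequency shading field (grey levels); 0 disables it.
#' @param amplitude_range Range of spot depths (grey levels below
#'   background at the spot centre). `c(0, 0)` makes spots invisible,
#'   which is the no-signal null world.
#' @param sigma_range Range of spot Gaussian radii (pixels per axis).
#' @param tail_range Range of the downward streaking factor (unitless).
#' @param noise_mix Named proportions for the noise-ROI mixture over
#'   `background`, `patch` (extra-noise region) and `crack`.
#' @param n_patches,patch_sd_factor Number of additive-noise rectangles per
#'   image and their noise-sd multiplier.
#' @param n_cracks Dark line artifacts per image.
#' @param crack_depth_range,crack_width_range Crack darkness (grey levels)
#'   and width (pixels).
#' @param roi_margin Fractional dilation of the spot support that defines
#'   the ROI mask ("slightly bigger than the visible dark surface").
#' @param max_retries Placement retries per ROI before giving up.
#'
#' @return A list of class `gel_config`.
#' @export
gel_config <- function(images = 10, width = 1024, height = 1024,
                       spots_per_image = 50, noise_per_image = 50,
                       background = 220, noise_sd = 8, shading_amplitude = 5,
                       amplitude_range = c(120, 200), sigma_range = c(3, 7),
                       tail_range = c(0, 0.5),
                       noise_mix = c(background = 0.5, patch = 0.3, crack = 0.2),
                       n_patches = 6, patch_sd_factor = 2.5,
                       n_cracks = 4, crack_depth_range = c(60, 120),
                       crack_width_range = c(1, 3),
                       roi_margin = 0.2, max_retries = 1000) {
  stopifnot(images >= 0, width >= 16, height >= 16,
            spots_per_image >= 0, noise_per_image >= 0,
            background >= 0, background <= 255, noise_sd >= 0,
            all(amplitude_range >= 0), all(sigma_range > 0),
            all(tail_range >= 0), roi_margin >= 0, max_retries >= 1)
  if (is.null(names(noise_mix)) ||
      !setequal(names(noise_mix), c("background", "patch", "crack")))
    stop("`noise_mix` must be named background/patch/crack")
  if (any(noise_mix < 0) || sum(noise_mix) <= 0)
    stop("`noise_mix` proportions must be non-negative and sum > 0")
  structure(as.list(environment()), class = "gel_config")
}

#' Null (no-signal) variant of a gel configuration
#'
#' Sets spot amplitude to zero, removes cracks and extra-noise patches and
#' collapses the noise mixture to plain background, so that spot and noise
#' ROIs are drawn from one exchangeable distribution. Used for the
#' chance-level AUROC checks.
#'
#' @param config A `gel_config`.
#' @return A modified `gel_config`.
#' @export
gel_null_config <- function(config = gel_config()) {
  config$amplitude_range <- c(0, 0)
  config$n_cracks <- 0
  config$n_patches <- 0
  config$noise_mix <- c(background = 1, patch = 0, crack = 0)
  config
}

#' Deterministic integer allocation by largest remainder
#'
#' Splits `n` units over categories proportionally, flooring first and
#' assigning leftovers to the largest fractional remainders (ties broken by
#' category order).
#'
#' @param props Non-negative proportions (any positive total).
#' @param n Total count to allocate.
#' @return Integer vector summing to `n`, same names as `props`.
#' @export
allocate_largest_remainder <- function(props, n) {
  stopifnot(n >= 0, all(props >= 0), sum(props) > 0)
  exact <- props / sum(props) * n
  base <- floor(exact)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(-(exact - base), seq_along(props))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  stats::setNames(as.integer(base), names(props))
}

#' Render one spot onto a gel image
#'
#' Darkens the image by a truncated anisotropic Gaussian profile of depth
#' `amplitude`, optionally widened below the centre (`vertical_tail`) to
#' emulate streaking. Pixels are never lightened; the result is clipped to
#' \[0, 255\].
#'
#' @param image Numeric matrix of grey levels.
#' @param spot List with `center` (row, col; 1-based), `amplitude`,
#'   `sigma_row`, `sigma_col`, `vertical_tail`.
#' @return The modified image matrix.
#' @export
render_spot <- function(image, spot) {
  r0 <- spot$center[1]; c0 <- spot$center[2]
  if (r0 < 1 || r0 > nrow(image) || c0 < 1 || c0 > ncol(image))
    stop("spot center lies outside the image")
  stopifnot(spot$amplitude >= 0, spot$sigma_row > 0, spot$sigma_col > 0,
            spot$vertical_tail >= 0)
  if (spot$amplitude == 0) return(image)
  sr_dn <- spot$sigma_row * (1 + spot$vertical_tail)
  ext_r <- ceiling(4 * sr_dn); ext_c <- ceiling(4 * spot$sigma_col)
  rows <- max(1, r0 - ceiling(4 * spot$sigma_row)):min(nrow(image), r0 + ext_r)
  cols <- max(1, c0 - ext_c):min(ncol(image), c0 + ext_c)
  dr <- rows - r0
  sr <- ifelse(dr > 0, sr_dn, spot$sigma_row)
  dc <- cols - c0
  prof <- spot$amplitude *
    exp(-0.5 * (outer((dr / sr)^2, rep(1, length(dc))) +
                outer(rep(1, length(dr)), (dc / spot$sigma_col)^2)))
  prof[prof < 1e-6] <- 0  # truncation beyond ~4 sigma
  image[rows, cols] <- pmax(0, pmin(255, image[rows, cols] - prof))
  image
}

# smooth low-frequency shading field with peak-to-trough ~ amplitude
render_shading <- function(height, width, amplitude) {
  if (amplitude <= 0) return(matrix(0, height, width))
  ph <- stats::runif(4, 0, 2 * pi)
  fr <- stats::runif(2, 0.5, 1.5)
  r <- seq_len(height) / height; c <- seq_len(width) / width
  f <- outer(sin(2 * pi * fr[1] * r + ph[1]), sin(2 * pi * fr[2] * c + ph[2])) +
    0.5 * outer(cos(2 * pi * fr[2] * r + ph[3]), cos(2 * pi * fr[1] * c + ph[4]))
  amplitude / 2 * f / max(abs(f))
}

# segment rasterisation for crack artifacts; returns darkened image and the
# sampled points of each segment (for crack-ROI placement)
render_cracks <- function(image, n_cracks, depth_range, width_range) {
  pts <- list()
  if (n_cracks <= 0) return(list(image = image, points = pts))
  h <- nrow(image); w <- ncol(image)
  for (k in seq_len(n_cracks)) {
    len <- stats::runif(1, 0.2, 0.6) * min(h, w)
    ang <- stats::runif(1, 0, pi)
    r1 <- stats::runif(1, 1, h); c1 <- stats::runif(1, 1, w)
    t <- seq(0, 1, length.out = ceiling(len))
    rr <- round(r1 + t * len * sin(ang)); cc <- round(c1 + t * len * cos(ang))
    keep <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    rr <- rr[keep]; cc <- cc[keep]
    if (length(rr) < 8) next
    depth <- stats::runif(1, depth_range[1], depth_range[2])
    halfw <- (sample(seq(width_range[1], width_range[2]), 1) - 1) / 2
    for (o in seq(-ceiling(halfw), ceiling(halfw))) {
      ro <- pmin(pmax(rr + o, 1), h)
      idx <- cbind(ro, cc)
      image[idx] <- pmax(0, image[idx] - depth)
    }
    pts[[length(pts) + 1]] <- cbind(row = rr, col = cc)
  }
  list(image = image, points = pts)
}

# elliptical logical mask and its 0-based half-open bounding box, or NULL if
# the box does not fit inside the image
ellipse_roi <- function(center, radius_up, radius_dn, radius_c, h, w) {
  r0 <- center[1]; c0 <- center[2]
  top <- floor(r0 - radius_up); bot <- ceiling(r0 + radius_dn)
  lef <- floor(c0 - radius_c);  rig <- ceiling(c0 + radius_c)
  if (top < 1 || lef < 1 || bot > h || rig > w) return(NULL)
  rows <- top:bot; cols <- lef:rig
  dr <- rows - r0
  rv <- ifelse(dr > 0, radius_dn, radius_up)
  mask <- outer((dr / rv)^2, rep(1, length(cols))) +
    outer(rep(1, length(rows)), ((cols - c0) / radius_c)^2) <= 1
  list(row0 = top - 1L, col0 = lef - 1L, row1 = bot, col1 = rig, mask = mask)
}

boxes_overlap <- function(a, b) {
  a$row0 < b$row1 && b$row0 < a$row1 && a$col0 < b$col1 && b$col0 < a$col1
}

#' Sample noise ROIs on a rendered gel image
#'
#' Places `n` noise-labelled elliptical ROIs whose bounding boxes avoid
#' every spot support and each other. The mixture over plain background,
#' extra-noise patch and crack regions follows the config proportions via
#' deterministic largest-remainder allocation; each returned ROI carries a
#' `provenance` tag. ROI radii are drawn from the same size law as spot
#' ROIs so that geometry is uninformative about the class.
#'
#' @param image Gel image matrix (already carrying artifacts).
#' @param n Number of noise ROIs.
#' @param config A [gel_config()].
#' @param exclusions List of bounding boxes (spot ROIs) to avoid.
#' @param crack_points List of crack point matrices (from rendering).
#' @param patch_boxes List of patch bounding boxes.
#' @return A list of ROI records.
#' @export
sample_noise_rois <- function(image, n, config, exclusions = list(),
                              crack_points = list(), patch_boxes = list()) {
  if (n == 0) return(list())
  counts <- allocate_largest_remainder(config$noise_mix, n)
  if (counts[["crack"]] > 0 && length(crack_points) == 0)
    stop("crack noise ROIs requested but the image has no cracks")
  if (counts[["patch"]] > 0 && length(patch_boxes) == 0)
    stop("patch noise ROIs requested but the image has no noise patches")
  h <- nrow(image); w <- ncol(image)
  all_crack_pts <- do.call(rbind, crack_points)
  placed <- list()
  out <- list()
  # most constrained kinds first; plain-background ROIs must additionally
  # stay clear of patches and cracks so that their provenance is honest
  for (kind in c("crack", "patch", "background")) {
    for (i in seq_len(counts[[kind]])) {
      ok <- FALSE
      for (try in seq_len(config$max_retries)) {
        sig <- stats::runif(2, config$sigma_range[1], config$sigma_range[2])
        rad <- 2.5 * sig * (1 + config$roi_margin)
        center <- switch(kind,
          background = c(stats::runif(1, 1, h), stats::runif(1, 1, w)),
          patch = {
            pb <- patch_boxes[[sample.int(length(patch_boxes), 1)]]
            c(stats::runif(1, pb$row0 + 1, pb$row1),
              stats::runif(1, pb$col0 + 1, pb$col1))
          },
          crack = {
            cp <- crack_points[[sample.int(length(crack_points), 1)]]
            as.numeric(cp[sample.int(nrow(cp), 1), ])
          })
        roi <- ellipse_roi(center, rad[1], rad[1], rad[2], h, w)
        if (is.null(roi)) next
        clash <- any(vapply(c(exclusions, placed), boxes_overlap,
                            logical(1), b = roi))
        if (clash) next
        if (kind == "background") {
          if (any(vapply(patch_boxes, boxes_overlap, logical(1), b = roi)))
            next
          if (!is.null(all_crack_pts) &&
              any(all_crack_pts[, 1] > roi$row0 & all_crack_pts[, 1] <= roi$row1 &
                  all_crack_pts[, 2] > roi$col0 & all_crack_pts[, 2] <= roi$col1))
            next
        }
        ok <- TRUE
        break
      }
      if (!ok) stop("could not place ", n,
                    " non-overlapping noise ROIs (image too crowded)")
      roi$label <- "noise"; roi$provenance <- kind
      placed[[length(placed) + 1]] <- roi
      out[[length(out) + 1]] <- roi
    }
  }
  out[order(match(vapply(out, `[[`, character(1), "provenance"),
                  c("background", "patch", "crack")))]
}

# renders one image and its labelled ROIs; assumes the RNG is positioned
simulate_gel_image <- function(config) {
  h <- config$height; w <- config$width
  img <- matrix(config$background, h, w) +
    matrix(stats::rnorm(h * w, 0, config$noise_sd), h, w) +
    render_shading(h, w, config$shading_amplitude)

  patch_boxes <- list()
  if (config$n_patches > 0) {
    for (k in seq_len(config$n_patches)) {
      ph <- round(stats::runif(1, 0.08, 0.16) * h)
      pw <- round(stats::runif(1, 0.08, 0.16) * w)
      r0 <- sample.int(h - ph, 1); c0 <- sample.int(w - pw, 1)
      rows <- r0:(r0 + ph - 1); cols <- c0:(c0 + pw - 1)
      img[rows, cols] <- img[rows, cols] +
        matrix(stats::rnorm(ph * pw, 0,
                            config$noise_sd * (config$patch_sd_factor - 1)),
               ph, pw)
      patch_boxes[[k]] <- list(row0 = r0 - 1L, col0 = c0 - 1L,
                               row1 = r0 + ph - 1L, col1 = c0 + pw - 1L)
    }
  }
  cr <- render_cracks(img, config$n_cracks, config$crack_depth_range,
                      config$crack_width_range)
  img <- cr$image

  # spots: place non-overlapping ROI boxes, then render.  The ROI mask is
  # the visible support (profile above ~half the pixel-noise sd) dilated by
  # roi_margin; noise ROIs must additionally avoid the full 4-sigma
  # rendered support (exclusion boxes).
  vis <- max(1, config$noise_sd / 2)
  spot_rois <- list()
  spots <- list()
  exclusion <- list()
  for (k in seq_len(config$spots_per_image)) {
    ok <- FALSE
    for (try in seq_len(config$max_retries)) {
      sig <- stats::runif(2, config$sigma_range[1], config$sigma_range[2])
      amp <- stats::runif(1, config$amplitude_range[1], config$amplitude_range[2])
      tail <- stats::runif(1, config$tail_range[1], config$tail_range[2])
      center <- c(stats::runif(1, 1, h), stats::runif(1, 1, w))
      s_fac <- if (amp > vis) sqrt(2 * log(amp / vis)) else 2.5
      rad_up <- s_fac * sig[1] * (1 + config$roi_margin)
      rad_dn <- s_fac * sig[1] * (1 + tail) * (1 + config$roi_margin)
      rad_c <- s_fac * sig[2] * (1 + config$roi_margin)
      roi <- ellipse_roi(center, rad_up, rad_dn, rad_c, h, w)
      if (is.null(roi)) next
      clash <- any(vapply(spot_rois, boxes_overlap, logical(1), b = roi))
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place ", config$spots_per_image,
                  " non-overlapping spots (image too crowded)")
    roi$label <- "spot"; roi$provenance <- "spot"
    spot_rois[[k]] <- roi
    # exclusion zone = the visible rendered support (plus 1 px), the same
    # notion of support the ROI mask is required to contain
    sup_r <- s_fac * sig[1]; sup_c <- s_fac * sig[2]
    exclusion[[k]] <- list(
      row0 = max(0L, floor(center[1] - sup_r) - 1L),
      col0 = max(0L, floor(center[2] - sup_c) - 1L),
      row1 = min(h, ceiling(center[1] + sup_r * (1 + tail)) + 1L),
      col1 = min(w, ceiling(center[2] + sup_c) + 1L))
    spots[[k]] <- list(center = center, amplitude = amp,
                       sigma_row = sig[1], sigma_col = sig[2],
                       vertical_tail = tail)
  }
  for (s in spots) img <- render_spot(img, s)

  noise_rois <- sample_noise_rois(img, config$noise_per_image, config,
                                  exclusions = exclusion,
                                  crack_points = cr$points,
                                  patch_boxes = patch_boxes)
  img <- matrix(as.integer(pmax(0, pmin(255, round(img)))), h, w)
  list(image = img, rois = c(spot_rois, noise_rois))
}

#' Generate a labelled synthetic gel dataset
#'
#' Simulates `config$images` gel images and their labelled ROIs. A single
#' integer seed drives a per-image substream, so any one image is
#' reproducible independently of the rest, and the whole dataset is
#' bit-identical across runs with the same `(config, seed)`.
#'
#' @param config A [gel_config()].
#' @param seed Integer seed.
#' @return A list of class `gel_dataset` with `images` (list of integer
#'   matrices) and `rois` (a tibble: image_id, roi_id, label, provenance,
#'   0-based half-open bounding box, and a `mask` list-column of logical
#'   matrices).
#' @export
generate_dataset <- function(config = gel_config(), seed = 1L) {
  stopifnot(inherits(config, "gel_config"))
  seed <- as.integer(seed)
  images <- vector("list", config$images)
  rows <- list()
  for (img_id in seq_len(config$images)) {
    set.seed((seed + 7919L * img_id) %% .Machine$integer.max)
    sim <- simulate_gel_image(config)
    images[[img_id]] <- sim$image
    for (j in seq_along(sim$rois)) {
      roi <- sim$rois[[j]]
      rows[[length(rows) + 1]] <- tibble::tibble(
        image_id = img_id, roi_id = j, label = roi$label,
        provenance = roi$provenance,
        row0 = roi$row0, col0 = roi$col0, row1 = roi$row1, col1 = roi$col1,
        mask = list(roi$mask))
    }
  }
  rois <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(image_id = integer(), roi_id = integer(),
                   label = character(), provenance = character(),
                   row0 = integer(), col0 = integer(),
                   row1 = integer(), col1 = integer(), mask = list())
  structure(list(images = images, rois = rois, config = config, seed = seed),
            class = "gel_dataset")
}

#' Write a gel dataset to disk
#'
#' Images go out as 8-bit greyscale PNGs, ROIs as a CSV manifest with
#' 0-based half-open bounding boxes, and (optionally) one PNG mask per ROI.
#'
#' @param dataset A `gel_dataset`.
#' @param dir Output directory (created if needed).
#' @param masks Also write per-ROI mask PNGs?
#' @return `dir`, invisibly.
#' @export
write_gel_dataset <- function(dataset, dir, masks = FALSE) {
  stopifnot(inherits(dataset, "gel_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(dataset$images))
    png::writePNG(dataset$images[[i]] / 255,
                  file.path(dir, sprintf("gel_%02d.png", i)))
  manifest <- dplyr::select(dataset$rois, -"mask")
  readr::write_csv(manifest, file.path(dir, "roi_manifest.csv"))
  if (masks) {
    mdir <- file.path(dir, "masks")
    dir.create(mdir, showWarnings = FALSE)
    purrr::pwalk(list(dataset$rois$image_id, dataset$rois$roi_id,
                      dataset$rois$mask),
                 function(im, id, m)
                   png::writePNG(m * 1,
                                 file.path(mdir, sprintf("roi_%02d_%03d.png",
                                                         im, id))))
  }
  invisible(dir)
}

# pixel values of a ROI as a masked numeric matrix (NA outside the mask)
roi_pixels <- function(image, roi_row) {
  rows <- (roi_row$row0 + 1):roi_row$row1
  cols <- (roi_row$col0 + 1):roi_row$col1
  px <- image[rows, cols, drop = FALSE] * 1.0
  px[!roi_row$mask[[1]]] <- NA_real_
  px
}
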