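# Image-set container and the preprocessing stack: random oversampling,
# the seven-operator augmentation stack, and the standardizing resize.
#
# Rasters are plain base-R arrays in [0, 1]: a height x width matrix
# (grayscale) or a height x width x 3 array (RGB). EBImage stores images
# x-major (width first), so the two helpers below transpose at the
# boundary.

as_ebi <- function(img) {
  if (is.matrix(img)) {
    EBImage::Image(t(img))
  } else {
    EBImage::Image(aperm(img, c(2L, 1L, 3L)), colormode = "Color")
  }
}

from_ebi <- function(ebi) {
  d <- EBImage::imageData(ebi)
  if (length(dim(d)) == 2L) t(d) else aperm(d, c(2L, 1L, 3L))
}

clip01 <- function(img) pmin(pmax(img, 0), 1)

to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  # Rec. 709 luma
  0.2126 * img[, , 1L] + 0.7152 * img[, , 2L] + 0.0722 * img[, , 3L]
}

#' Build a labeled image set
#'
#' The tabular container every pipeline stage consumes and returns: one
#' row per image, with the raster in a list-column.
#'
#' @param images List of rasters: height x width matrices or
#'   height x width x 3 arrays, values in [0, 1].
#' @param labels Character vector, `"cancerous"` / `"non-cancerous"`.
#' @param provenance Per-image provenance tag (default `"original"`).
#' @param id Optional stable identifiers; generated from label + index
#'   when missing.
#' @return A tibble with columns `id`, `image`, `label`, `provenance`.
#' @export
image_set <- function(images, labels, provenance = "original", id = NULL) {
  stopifnot(length(images) == length(labels), length(images) > 0L)
  bad <- setdiff(unique(labels), c("cancerous", "non-cancerous"))
  if (length(bad) > 0L) {
    rlang::abort(paste0("Labels must be 'cancerous' or 'non-cancerous'; got: ",
                        paste(bad, collapse = ", ")))
  }
  if (is.null(id)) {
    id <- paste0(labels, "_", stats::ave(seq_along(labels), labels,
                                         FUN = seq_along))
  }
  tibble::tibble(id = id, image = images, label = labels,
                 provenance = rep(provenance, length.out = length(images)))
}

#' Random oversampling of the minority class
#'
#' Duplicates minority-class rows, drawn uniformly with replacement,
#' until the two class counts are equal. Originals are preserved
#' verbatim; duplicates are tagged `provenance = "oversampled"`. With the
#' study collection's counts (87 cancerous, 44 non-cancerous) this adds
#' the 43 duplicates needed to reach 87/87.
#'
#' @param data An image-set tibble with both classes present.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return The balanced tibble (originals first, duplicates appended).
#' @export
ros_oversample <- function(data, seed = NULL) {
  counts <- table(data$label)
  if (length(counts) < 2L) {
    rlang::abort("Oversampling needs both classes present.")
  }
  if (counts[1L] == counts[2L]) return(data)
  minority <- names(counts)[which.min(counts)]
  deficit <- as.integer(abs(diff(as.integer(counts))))
  pick_rows <- function() {
    idx <- which(data$label == minority)
    idx[sample.int(length(idx), deficit, replace = TRUE)]
  }
  rows <- if (is.null(seed)) pick_rows() else withr::with_seed(seed, pick_rows())
  dup <- data[rows, ]
  dup$provenance <- "oversampled"
  dup$id <- paste0(dup$id, "_ros", seq_len(nrow(dup)))
  dplyr::bind_rows(data, dup)
}

#' Augmentation configuration
#'
#' Parameters of the seven augmentation operators: rescaling by a factor
#' drawn from `resize_scales`; shear warping by an angle drawn from
#' `warp_range` (degrees); random cropping of `crop_fraction` of each
#' side (resized back); additive Gaussian noise with `noise_sd` on the
#' [0, 1] intensity scale; Gaussian blur with `blur_sigma` (pixels);
#' color jitter with the given maximum contrast/hue/saturation/
#' brightness deviations; and translation by integer offsets drawn from
#' `translate_range` (pixels).
#'
#' @param resize_scales Scale factors (default `c(0.5, 2, 3)`).
#' @param warp_range Shear angle range in degrees (default `c(40, 60)`).
#' @param crop_fraction Retained side fraction (default 0.8).
#' @param noise_sd Noise sigma (default 0.2).
#' @param blur_sigma Blur sigma in pixels (default 6).
#' @param jitter Named deviations: contrast 0.4, hue 0.1, saturation
#'   0.2, brightness 0.3.
#' @param translate_range Offset range in pixels (default `c(-50, 50)`).
#' @param operators Operators to apply, in order.
#' @return A list of class `aug_config`.
#' @export
augmentation_config <- function(resize_scales = c(0.5, 2, 3),
                                warp_range = c(40, 60),
                                crop_fraction = 0.8,
                                noise_sd = 0.2,
                                blur_sigma = 6,
                                jitter = c(contrast = 0.4, hue = 0.1,
                                           saturation = 0.2, brightness = 0.3),
                                translate_range = c(-50, 50),
                                operators = c("resize", "warp", "crop",
                                              "noise", "blur", "jitter",
                                              "translate")) {
  structure(
    list(resize_scales = resize_scales, warp_range = warp_range,
         crop_fraction = crop_fraction, noise_sd = noise_sd,
         blur_sigma = blur_sigma, jitter = jitter,
         translate_range = translate_range, operators = operators),
    class = "aug_config"
  )
}

# --- individual operators (deterministic given their arguments) -------

#' Augmentation operators
#'
#' The seven deterministic operator cores. [augment_image()] draws their
#' random arguments; they are exported so tests and callers can inject
#' exact values.
#'
#' @param img A raster (matrix or h x w x 3 array, values in [0, 1]).
#' @param scale Rescale factor.
#' @return The transformed raster, values clipped to [0, 1].
#' @name augment_ops
NULL

#' @rdname augment_ops
#' @export
aug_resize <- function(img, scale) {
  h <- max(1L, round(dim(img)[1L] * scale))
  w <- max(1L, round(dim(img)[2L] * scale))
  clip01(from_ebi(EBImage::resize(as_ebi(img), w = w, h = h)))
}

#' @rdname augment_ops
#' @param angle_deg Shear angle in degrees.
#' @export
aug_warp <- function(img, angle_deg) {
  sh <- tan(angle_deg * pi / 180)
  # horizontal shear about the vertical center, output same size:
  # x' = x + sh * (y - h/2), y' = y
  m <- matrix(c(1, sh, -sh * dim(img)[1L] / 2, 0, 1, 0), nrow = 3L)
  clip01(from_ebi(EBImage::affine(as_ebi(img), m)))
}

#' @rdname augment_ops
#' @param fraction Retained side fraction.
#' @param off_y,off_x Top-left offsets of the crop window (1-based).
#' @export
aug_crop <- function(img, fraction = 0.8, off_y = 1L, off_x = 1L) {
  h <- dim(img)[1L]; w <- dim(img)[2L]
  ch <- max(1L, floor(h * fraction)); cw <- max(1L, floor(w * fraction))
  off_y <- min(max(1L, off_y), h - ch + 1L)
  off_x <- min(max(1L, off_x), w - cw + 1L)
  cropped <- if (is.matrix(img)) {
    img[off_y:(off_y + ch - 1L), off_x:(off_x + cw - 1L)]
  } else {
    img[off_y:(off_y + ch - 1L), off_x:(off_x + cw - 1L), , drop = FALSE]
  }
  standardize_image(cropped, c(h, w))
}

#' @rdname augment_ops
#' @param sd Gaussian noise sigma on the [0, 1] scale.
#' @export
aug_noise <- function(img, sd = 0.2) {
  clip01(img + stats::rnorm(length(img), sd = sd))
}

#' @rdname augment_ops
#' @param sigma Gaussian blur sigma in pixels.
#' @export
aug_blur <- function(img, sigma = 6) {
  # gblur needs the kernel to fit inside the image; shrink sigma for
  # small rasters so the operator stays defined
  max_sigma <- (min(dim(img)[1:2]) - 1) / 8
  clip01(from_ebi(EBImage::gblur(as_ebi(img), sigma = min(sigma, max_sigma))))
}

#' @rdname augment_ops
#' @param contrast,brightness Multiplicative factors (1 = unchanged).
#' @param hue Additive hue shift in [0, 1) hue turns.
#' @param saturation Multiplicative saturation factor.
#' @export
aug_jitter <- function(img, contrast = 1, hue = 0, saturation = 1,
                       brightness = 1) {
  if (!is.matrix(img)) {
    # hue/saturation act in HSV space; grayscale degrades to
    # brightness/contrast only
    d <- dim(img)
    rgb <- matrix(aperm(img, c(3L, 1L, 2L)), nrow = 3L)
    hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
    h6 <- ((hsv[1L, ] + hue) %% 1) * 6
    s <- pmin(hsv[2L, ] * saturation, 1)
    v <- pmin(hsv[3L, ], 1)
    # numeric HSV -> RGB (avoids 8-bit color-string round trips)
    f <- function(k) {
      kk <- (k + h6) %% 6
      v - v * s * pmax(0, pmin(kk, 4 - kk, 1))
    }
    rgb2 <- rbind(f(5), f(3), f(1))
    img <- aperm(array(rgb2, c(3L, d[1L], d[2L])), c(2L, 3L, 1L))
  }
  img <- img * brightness
  mu <- mean(img)
  clip01((img - mu) * contrast + mu)
}

#' @rdname augment_ops
#' @param dy,dx Integer shifts (rows, columns); vacated pixels are
#'   zero-filled.
#' @export
aug_translate <- function(img, dy = 0L, dx = 0L) {
  h <- dim(img)[1L]; w <- dim(img)[2L]
  out <- img; out[] <- 0
  src_y <- seq_len(h) - dy; src_x <- seq_len(w) - dx
  ok_y <- src_y >= 1L & src_y <= h; ok_x <- src_x >= 1L & src_x <= w
  if (any(ok_y) && any(ok_x)) {
    if (is.matrix(img)) {
      out[which(ok_y), which(ok_x)] <- img[src_y[ok_y], src_x[ok_x]]
    } else {
      out[which(ok_y), which(ok_x), ] <- img[src_y[ok_y], src_x[ok_x], ,
                                             drop = FALSE]
    }
  }
  out
}

#' Apply the augmentation stack to one raster
#'
#' Draws each operator's random arguments from the current RNG stream
#' (seed with [set.seed()] for determinism) and returns one output per
#' enabled operator. Translation is skipped with a warning when the
#' image is smaller than the configured maximum offset.
#'
#' @param img A raster.
#' @param config An [augmentation_config()].
#' @return Named list of rasters, one per applied operator.
#' @export
augment_image <- function(img, config = augmentation_config()) {
  out <- list()
  for (op in config$operators) {
    out[[op]] <- switch(op,
      resize = aug_resize(img, sample(config$resize_scales, 1L)),
      warp = aug_warp(img, stats::runif(1, config$warp_range[1L],
                                        config$warp_range[2L])),
      crop = {
        h <- dim(img)[1L]; w <- dim(img)[2L]
        ch <- max(1L, floor(h * config$crop_fraction))
        cw <- max(1L, floor(w * config$crop_fraction))
        aug_crop(img, config$crop_fraction,
                 off_y = sample.int(h - ch + 1L, 1L),
                 off_x = sample.int(w - cw + 1L, 1L))
      },
      noise = aug_noise(img, config$noise_sd),
      blur = aug_blur(img, config$blur_sigma),
      jitter = {
        j <- config$jitter
        aug_jitter(img,
                   contrast = stats::runif(1, 1 - j[["contrast"]],
                                           1 + j[["contrast"]]),
                   hue = stats::runif(1, -j[["hue"]], j[["hue"]]),
                   saturation = stats::runif(1, 1 - j[["saturation"]],
                                             1 + j[["saturation"]]),
                   brightness = stats::runif(1, 1 - j[["brightness"]],
                                             1 + j[["brightness"]]))
      },
      translate = {
        max_off <- max(abs(config$translate_range))
        if (min(dim(img)[1:2]) <= max_off) {
          rlang::warn(sprintf(
            "translate skipped: image %dx%d smaller than max offset %d",
            dim(img)[1L], dim(img)[2L], max_off))
          NULL
        } else {
          sh <- sample(seq(config$translate_range[1L],
                           config$translate_range[2L]), 2L, replace = TRUE)
          aug_translate(img, dy = sh[1L], dx = sh[2L])
        }
      },
      rlang::abort(paste0("Unknown augmentation operator: ", op))
    )
  }
  out[!vapply(out, is.null, logical(1L))]
}

#' Augment every image in a set
#'
#' Appends the augmented variants of each row (provenance
#' `"augmented"`); typically applied to the training split only, after
#' splitting, to avoid leakage.
#'
#' @param data An image-set tibble.
#' @param config An [augmentation_config()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return The input rows followed by the augmented rows.
#' @export
augment_images <- function(data, config = augmentation_config(),
                           seed = NULL) {
  run <- function() {
    aug <- purrr::imap(data$image, function(img, i) {
      v <- augment_image(img, config)
      image_set(unname(v), rep(data$label[[i]], length(v)),
                provenance = "augmented",
                id = paste0(data$id[[i]], "_aug_", names(v)))
    })
    dplyr::bind_rows(data, dplyr::bind_rows(aug))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Standardize one raster to a target size
#'
#' @param img A raster.
#' @param size Target `c(height, width)` (positive integers).
#' @return The resized raster, values in [0, 1]. A same-size input is
#'   returned pixel-identical.
#' @export
standardize_image <- function(img, size = c(32L, 32L)) {
  if (length(size) == 1L) size <- c(size, size)
  if (any(size < 1)) rlang::abort("Target size must be positive.")
  if (all(dim(img)[1:2] == size)) return(img)
  clip01(from_ebi(EBImage::resize(as_ebi(img), w = size[2L], h = size[1L])))
}

#' Standardize every image in a set
#'
#' @param data An image-set tibble.
#' @param size Target `c(height, width)`.
#' @return The tibble with every raster resized to `size`.
#' @export
standardize_images <- function(data, size = c(32L, 32L)) {
  data$image <- purrr::map(data$image, standardize_image, size = size)
  data
}
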