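# Seeded generator of synthetic two-class fixture images, standing in for
# a real two-folder oral-image collection so every pipeline stage can be
# exercised without external data. "Cancerous" images carry a pale
# elliptical lesion with an irregular border on a textured mucosa-like
# background; "non-cancerous" images are texture only. The lesion's mean
# intensity exceeds the background by a configured margin, so the classes
# are separable by construction. Not a clinically realistic lesion
# simulator.

smooth_field <- function(size, sigma) {
  z <- matrix(stats::rnorm(size * size), size, size)
  z <- from_ebi(EBImage::gblur(as_ebi(clip01(z / 8 + 0.5)),
                               sigma = min(sigma, (size - 1) / 8)))
  z <- z - mean(z)
  s <- stats::sd(z)
  if (s > 0) z / s else z
}

synth_one <- function(size, cancerous, lesion_contrast, texture_sd,
                      noise_sd, color) {
  base <- if (color) c(0.72, 0.45, 0.47) else 0.5
  tex <- smooth_field(size, sigma = size / 8) * texture_sd
  chans <- if (color) 3L else 1L
  img <- array(0, c(size, size, chans))
  for (k in seq_len(chans)) img[, , k] <- base[k] + tex * c(1, 0.8, 0.8)[k]

  if (cancerous) {
    cy <- stats::runif(1, 0.38, 0.62) * size
    cx <- stats::runif(1, 0.38, 0.62) * size
    a <- stats::runif(1, 0.16, 0.30) * size        # semi-axes
    b <- a * stats::runif(1, 0.5, 0.95)            # eccentricity
    rot <- stats::runif(1, 0, pi)
    amp <- stats::runif(3, 0.04, 0.12)             # border irregularity
    phs <- stats::runif(3, 0, 2 * pi)
    yy <- matrix(seq_len(size), size, size) - cy
    xx <- matrix(seq_len(size), size, size, byrow = TRUE) - cx
    u <- cos(rot) * xx + sin(rot) * yy
    v <- -sin(rot) * xx + cos(rot) * yy
    rho <- sqrt((u / a)^2 + (v / b)^2)
    theta <- atan2(v, u)
    edge <- 1 + amp[1] * sin(2 * theta + phs[1]) +
      amp[2] * sin(3 * theta + phs[2]) + amp[3] * sin(5 * theta + phs[3])
    mask <- 1 / (1 + exp((rho - edge) / 0.06))     # soft irregular boundary
    for (k in seq_len(chans)) {
      # pale (leukoplakia-like) patch: lifts all channels
      img[, , k] <- img[, , k] + lesion_contrast * mask
    }
  }
  img <- img + stats::rnorm(length(img), sd = noise_sd)
  img <- clip01(img)
  if (color) img else img[, , 1L]
}

#' Generate a synthetic two-class image set
#'
#' @param n_cancerous,n_noncancerous Images per class (defaults 87 and
#'   44, the class counts of the oral lips-and-tongue image collection
#'   the pipeline targets).
#' @param size Square image side in pixels (default 64).
#' @param seed Integer seed; the output is fully reproducible.
#' @param lesion_contrast Mean intensity margin of the lesion over the
#'   background, on the [0, 1] scale (default 0.3).
#' @param texture_sd Background texture amplitude (default 0.06).
#' @param noise_sd Per-pixel Gaussian noise sigma (default 0.02).
#' @param color Generate RGB rasters? Default `TRUE`.
#' @return An image-set tibble (see [image_set()]).
#' @export
#' @examples
#' d <- synth_image_set(5, 5, size = 32, seed = 1)
#' table(d$label)
synth_image_set <- function(n_cancerous = 87L, n_noncancerous = 44L,
                            size = 64L, seed = 1L, lesion_contrast = 0.3,
                            texture_sd = 0.06, noise_sd = 0.02,
                            color = TRUE) {
  if (n_cancerous < 1L || n_noncancerous < 1L) {
    rlang::abort("Each class needs at least one image.")
  }
  withr::with_seed(seed, {
    imgs <- c(
      purrr::map(seq_len(n_cancerous), function(i) {
        synth_one(size, TRUE, lesion_contrast, texture_sd, noise_sd, color)
      }),
      purrr::map(seq_len(n_noncancerous), function(i) {
        synth_one(size, FALSE, lesion_contrast, texture_sd, noise_sd, color)
      })
    )
    labels <- c(rep("cancerous", n_cancerous),
                rep("non-cancerous", n_noncancerous))
    image_set(imgs, labels,
              id = sprintf("%s_%03d", labels,
                           c(seq_len(n_cancerous), seq_len(n_noncancerous))))
  })
}

#' Write an image set as a two-folder JPEG tree
#'
#' Mirrors the layout the loaders expect: `path/cancerous/*.jpg` and
#' `path/non-cancerous/*.jpg`, one file per row, named by `id`. JPEG
#' quality is fixed at 95 so round-trip pixel drift stays small.
#'
#' @param data An image-set tibble.
#' @param path Output directory (created if missing).
#' @param quality JPEG quality (default 95).
#' @return `path`, invisibly.
#' @export
write_image_tree <- function(data, path, quality = 95) {
  for (lab in c("cancerous", "non-cancerous")) {
    dir.create(file.path(path, lab), recursive = TRUE, showWarnings = FALSE)
  }
  if (!dir.exists(path)) rlang::abort(paste0("Cannot create ", path))
  for (i in seq_len(nrow(data))) {
    f <- file.path(path, data$label[[i]], paste0(data$id[[i]], ".jpg"))
    EBImage::writeImage(as_ebi(data$image[[i]]), f, quality = quality)
  }
  invisible(path)
}

#' Read a two-folder image tree
#'
#' Loads JPEG/PNG files from `path/cancerous` and `path/non-cancerous`
#' into an image-set tibble (provenance `"original"`), in sorted
#' filename order.
#'
#' @param path Directory containing the two class folders.
#' @return An image-set tibble.
#' @export
read_image_tree <- function(path) {
  for (lab in c("cancerous", "non-cancerous")) {
    if (!dir.exists(file.path(path, lab))) {
      rlang::abort(paste0("Missing class folder: ", file.path(path, lab)))
    }
  }
  rows <- lapply(c("cancerous", "non-cancerous"), function(lab) {
    d <- file.path(path, lab)
    files <- sort(list.files(d, pattern = "\\.(jpe?g|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L) {
      rlang::abort(paste0("Class folder is empty: ", d))
    }
    imgs <- purrr::map(files, function(f) clip01(from_ebi(EBImage::readImage(f))))
    image_set(imgs, rep(lab, length(files)),
              id = tools::file_path_sans_ext(basename(files)))
  })
  dplyr::bind_rows(rows)
}
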