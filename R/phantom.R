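# Seeded synthetic spine-phantom generator: a single curved column of
# high-intensity vertebra-like blobs on a noisy, low-contrast background,
# with an exact binary ground-truth mask.

#' Parameters of the synthetic spine-radiograph phantom
#'
#' The phantom emulates the essentials of a spinal radiograph for pipeline
#' testing: a vertical stack of rounded-rectangle "vertebral bodies" whose
#' centreline follows a lateral sinusoid `x(y) = center + A sin(2 pi y / H)`,
#' brightened above a smooth low-contrast background, Gaussian-blurred and
#' corrupted with Gaussian noise. The mask is the exact union of the bodies,
#' rendered before blur and noise.
#'
#' @param image_size square image side in pixels.
#' @param n_vertebrae number of vertebral bodies.
#' @param body_width,body_height nominal body size in pixels (each body's
#'   size is jittered by +/-10%).
#' @param gap vertical gap between consecutive bodies in pixels.
#' @param curvature_amplitude lateral sinusoidal offset amplitude in pixels.
#' @param contrast foreground-background intensity gap in `[0, 1]`.
#' @param noise_sigma Gaussian noise standard deviation (intensity units).
#' @param blur_sigma Gaussian blur standard deviation in pixels.
#' @param seed RNG seed; identical seed and parameters give bit-identical
#'   phantoms.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(image_size = 256L, n_vertebrae = 12L,
                           body_width = 48, body_height = 14, gap = 4,
                           curvature_amplitude = 20, contrast = 0.4,
                           noise_sigma = 0.05, blur_sigma = 1.0, seed = 1L) {
  p <- list(image_size = as.integer(image_size), n_vertebrae = as.integer(n_vertebrae),
            body_width = body_width, body_height = body_height, gap = gap,
            curvature_amplitude = curvature_amplitude, contrast = contrast,
            noise_sigma = noise_sigma, blur_sigma = blur_sigma, seed = as.integer(seed))
  class(p) <- "phantom_params"
  stopifnot(p$image_size >= 32L, p$n_vertebrae >= 1L, p$contrast >= 0, p$contrast <= 1,
            p$noise_sigma >= 0, p$blur_sigma >= 0)
  column_h <- p$n_vertebrae * p$body_height + (p$n_vertebrae - 1) * p$gap
  if (column_h > 0.95 * p$image_size)
    stop("invalid configuration: vertebral column does not fit the image height",
         call. = FALSE)
  if (1.1 * p$curvature_amplitude + 0.55 * p$body_width + 8 > p$image_size / 2)
    stop("invalid configuration: curvature/width overflow the image laterally",
         call. = FALSE)
  p
}

#' Generate a synthetic spine phantom
#'
#' @param p a [phantom_params()] object.
#' @return `list(image = , mask = )`: an `image_size x image_size` intensity
#'   matrix in `[0, 1]` and the binary ground-truth mask (values 0/1).
#' @export
#' @examples
#' ph <- generate_phantom(phantom_params(seed = 7))
#' mean(ph$mask)  # foreground fraction
generate_phantom <- function(p = phantom_params()) {
  stopifnot(inherits(p, "phantom_params"))
  set.seed(p$seed)
  S <- p$image_size
  b0 <- stats::runif(1, 0.20, 0.30)
  gx <- stats::runif(1, -0.10, 0.10)
  gy <- stats::runif(1, -0.10, 0.10)
  cx <- S / 2 + stats::runif(1, -8, 8)
  A <- p$curvature_amplitude * stats::runif(1, 0.8, 1.2)
  widths <- p$body_width * stats::runif(p$n_vertebrae, 0.9, 1.1)
  heights <- p$body_height * stats::runif(p$n_vertebrae, 0.9, 1.1)

  column_h <- p$n_vertebrae * p$body_height + (p$n_vertebrae - 1) * p$gap
  y0 <- (S - column_h) / 2
  mask <- matrix(0L, S, S)
  yy <- seq_len(S) - 0.5
  xx <- seq_len(S) - 0.5
  for (i in seq_len(p$n_vertebrae)) {
    cy <- y0 + (i - 0.5) * p$body_height + (i - 1) * p$gap
    cxi <- cx + A * sin(2 * pi * cy / S)
    if (cxi - widths[i] / 2 < 1 || cxi + widths[i] / 2 > S - 1)
      stop("invalid configuration: vertebra overflows the image", call. = FALSE)
    # superellipse (rounded rectangle), evaluated on the pixel grid
    u <- abs(yy - cy) / (heights[i] / 2)
    v <- abs(xx - cxi) / (widths[i] / 2)
    inside <- outer(u^4, v^4, `+`) <= 1
    mask[inside] <- 1L
  }

  bg <- b0 + gx * outer(rep(1, S), xx / S) + gy * outer(yy / S, rep(1, S))
  bg <- pmin(pmax(bg, 0.05), 0.45)
  img <- bg + p$contrast * mask
  img <- cpp_gauss_blur(img, p$blur_sigma)
  if (p$noise_sigma > 0)
    img <- img + matrix(stats::rnorm(S * S, sd = p$noise_sigma), S, S)
  img <- pmin(pmax(img, 0), 1)
  list(image = img, mask = mask)
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` image/mask PNG pairs (8-bit grayscale; masks use 0/255) with
#' per-item seeds derived from the master seed (`seed + index`), plus a
#' manifest CSV assigning items to train/validation/test splits in a 7:1:2
#' ratio.
#'
#' @param n number of phantoms (>= 10).
#' @param dir output directory (created; gains `images/`, `masks/`,
#'   `manifest.csv`).
#' @param p a [phantom_params()] template (its `seed` field is overridden
#'   per item).
#' @param seed master seed for item seeds and the split shuffle.
#' @return The manifest tibble (filename, split), invisibly.
#' @export
generate_dataset <- function(n, dir, p = phantom_params(), seed = 1L) {
  if (n < 10L) stop("invalid input: need at least 10 items", call. = FALSE)
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(file.path(dir, "images")) || !dir.exists(file.path(dir, "masks")))
    stop("I/O error: cannot create dataset directory ", dir, call. = FALSE)
  ids <- sprintf("phantom_%04d", seq_len(n))
  for (i in seq_len(n)) {
    pi <- p
    pi$seed <- as.integer(seed + i)
    g <- generate_phantom(pi)
    png::writePNG(g$image, file.path(dir, "images", paste0(ids[i], ".png")))
    png::writePNG(g$mask + 0, file.path(dir, "masks", paste0(ids[i], ".png")))
  }
  manifest <- split_dataset(ids, seed = seed)
  manifest$filename <- paste0(manifest$id, ".png")
  manifest <- manifest[, c("filename", "split")]
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
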