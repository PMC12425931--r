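# Data pipeline: PNG loading, proportional resizing with padding, horizontal
# flip augmentation, and dataset splitting.

to_gray <- function(a) {
  if (is.matrix(a)) return(a)
  d3 <- dim(a)[3L]
  if (d3 >= 3L) {
    # ITU-R BT.601 luminance
    0.299 * a[, , 1L] + 0.587 * a[, , 2L] + 0.114 * a[, , 3L]
  } else {
    a[, , 1L]  # grayscale + alpha
  }
}

#' Load an image/mask PNG pair
#'
#' The image is converted to a single channel in `[0, 1]` (RGB inputs via
#' luminance); the mask is binarized at 128 of the 8-bit range (bytes >= 128
#' map to 1).
#'
#' @param image_path,mask_path PNG file paths.
#' @return A sample: `list(image = , mask = , id = )`.
#' @export
load_pair <- function(image_path, mask_path) {
  if (!file.exists(image_path) || !file.exists(mask_path))
    stop("I/O error: missing file ", image_path, " or ", mask_path, call. = FALSE)
  img <- to_gray(png::readPNG(image_path))
  msk <- to_gray(png::readPNG(mask_path))
  if (!identical(dim(img), dim(msk)))
    stop("invalid input: image and mask sizes differ for ", basename(image_path),
         call. = FALSE)
  mask <- matrix(as.integer(msk > 0.5), nrow(msk), ncol(msk))
  list(image = img, mask = mask,
       id = sub("\\.png$", "", basename(image_path), ignore.case = TRUE))
}

#' Proportional resize with symmetric zero padding
#'
#' The longer side is scaled to `target` preserving aspect ratio (bilinear
#' for the image, nearest-neighbour for the mask), then the result is
#' zero-padded symmetrically to `target x target`.
#'
#' @param s a sample (`list(image = , mask = )`).
#' @param target output side length in pixels.
#' @return The resized sample.
#' @export
resize_proportional <- function(s, target = 256L) {
  stopifnot(target > 0)
  H <- nrow(s$image); W <- ncol(s$image)
  long <- max(H, W)
  nh <- as.integer(round(H * target / long))
  nw <- as.integer(round(W * target / long))
  img <- cpp_resize_bilinear(s$image, nh, nw)
  msk <- cpp_resize_nearest(s$mask + 0, nh, nw)
  top <- (target - nh) %/% 2L
  left <- (target - nw) %/% 2L
  out_img <- matrix(0, target, target)
  out_msk <- matrix(0L, target, target)
  out_img[top + seq_len(nh), left + seq_len(nw)] <- img
  out_msk[top + seq_len(nh), left + seq_len(nw)] <- as.integer(msk)
  s$image <- out_img
  s$mask <- out_msk
  s
}

#' Random horizontal flip (image and mask jointly)
#'
#' @param s a sample.
#' @param prob flip probability; draws from the current R RNG stream.
#' @return The (possibly flipped) sample.
#' @export
random_hflip <- function(s, prob = 0.5) {
  stopifnot(prob >= 0, prob <= 1)
  if (prob > 0 && stats::runif(1) < prob) hflip_sample(s) else s
}

#' Split ids into train/validation/test sets
#'
#' Seeded shuffle followed by contiguous assignment: validation and test get
#' `floor(n * ratio)` items each, the remainder goes to training, so 280
#' items split 7:1:2 give 196/28/56.
#'
#' @param ids character vector of item identifiers.
#' @param ratios length-3 numeric vector of train/val/test proportions.
#' @param seed shuffle seed.
#' @return A tibble (id, split) with split in train/val/test.
#' @export
#' @examples
#' table(split_dataset(sprintf("i%03d", 1:280), seed = 1)$split)
split_dataset <- function(ids, ratios = c(7, 1, 2), seed = 1L) {
  n <- length(ids)
  if (n < sum(ratios))
    stop("invalid input: fewer ids than split parts", call. = FALSE)
  set.seed(seed)
  ord <- sample(ids)
  n_val <- floor(n * ratios[2] / sum(ratios))
  n_test <- floor(n * ratios[3] / sum(ratios))
  n_train <- n - n_val - n_test
  tibble::tibble(id = ord,
                 split = rep(c("train", "val", "test"), c(n_train, n_val, n_test)))
}

#' Load a dataset directory produced by [generate_dataset()]
#'
#' @param dir dataset directory with `images/`, `masks/` and `manifest.csv`.
#' @param target optional side length for [resize_proportional()].
#' @return `list(train = , val = , test = )`, each a list of samples.
#' @export
load_segmentation_dataset <- function(dir, target = NULL) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("I/O error: no manifest.csv in ", dir, call. = FALSE)
  manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
  out <- list(train = list(), val = list(), test = list())
  for (i in seq_len(nrow(manifest))) {
    s <- load_pair(file.path(dir, "images", manifest$filename[i]),
                   file.path(dir, "masks", manifest$filename[i]))
    if (!is.null(target)) s <- resize_proportional(s, target)
    out[[manifest$split[i]]] <- c(out[[manifest$split[i]]], list(s))
  }
  out
}
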