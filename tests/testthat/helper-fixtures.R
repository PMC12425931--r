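# Shared fixtures: tiny network configs, synthetic samples, and independent
# brute-force oracles used across the suite.

tiny_cfg <- function(...) {
  network_config(encoder_widths = c(8, 16, 32, 64), ...)
}

tiny_ablation <- function(name, ...) {
  ablation_config(name, encoder_widths = c(8, 16, 32, 64), ...)
}

# a small phantom geometry for fast end-to-end tests
small_phantom_params <- function(seed = 1L, ...) {
  phantom_params(image_size = 64L, n_vertebrae = 4L, body_width = 16,
                 body_height = 6, gap = 2, curvature_amplitude = 4,
                 seed = seed, ...)
}

random_mask <- function(h, w, p = 0.5) {
  matrix(as.integer(stats::runif(h * w) < p), h, w)
}

# sample pair with a learnable structure (bright rectangle on noise)
toy_sample <- function(side = 32L, seed = 1L) {
  set.seed(seed)
  m <- matrix(0L, side, side)
  r <- sort(sample.int(side, 2))
  c <- sort(sample.int(side, 2))
  m[r[1]:r[2], c[1]:c[2]] <- 1L
  list(image = pmin(matrix(stats::runif(side * side, 0, 0.4), side, side) + 0.5 * m, 1),
       mask = m, id = sprintf("toy%02d", seed))
}

# ---- independent oracles ---------------------------------------------------

# exhaustive per-pixel confusion tally
oracle_confusion <- function(pred, gt) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && gt[i] == 1) tp <- tp + 1L
    else if (pred[i] == 1 && gt[i] == 0) fp <- fp + 1L
    else if (pred[i] == 0 && gt[i] == 0) tn <- tn + 1L
    else fn <- fn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# set-operation IoU oracle for one class label
oracle_iou <- function(pred, gt, class) {
  a <- which(pred == class)
  b <- which(gt == class)
  if (length(a) == 0 && length(b) == 0) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

# direct dense 2-D convolution ("same" zero padding) for conv oracles
oracle_conv2d <- function(img, ker) {
  k <- nrow(ker)
  p <- (k - 1) %/% 2
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- 0
    for (ki in seq_len(k)) for (kj in seq_len(k)) {
      ii <- i + ki - 1 - p; jj <- j + kj - 1 - p
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
        acc <- acc + img[ii, jj] * ker[ki, kj]
    }
    out[i, j] <- acc
  }
  out
}

# 4-connected component count (flood fill)
oracle_n_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  n <- 0L
  for (start in which(mask == 1 & lab == 0)) {
    if (lab[start] != 0L) next
    n <- n + 1L
    queue <- start
    lab[start] <- n
    H <- nrow(mask)
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- (cur - 1L) %% H + 1L
      j <- (cur - 1L) %/% H + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        ii <- i + d[1L]; jj <- j + d[2L]
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= ncol(mask)) {
          nxt <- ii + (jj - 1L) * H
          if (mask[nxt] == 1 && lab[nxt] == 0L) {
            lab[nxt] <- n
            queue <- c(queue, nxt)
          }
        }
      }
    }
  }
  n
}
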