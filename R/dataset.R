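# Dataset protocol: the 7:1:2 split performed before augmentation (so
# augmented samples can never leak across partitions), plus the crop /
# rotate / blur augmentation chain with box-consistent coordinate updates.

#' Split image ids into train / validation / test partitions
#'
#' A seeded shuffle followed by a hard cut: `floor(r_train * N)` train ids,
#' `floor(r_val * N)` validation ids, the remainder test. Splitting happens
#' before any augmentation; augmented copies inherit the partition of their
#' source image.
#'
#' @param ids character or integer vector of image ids.
#' @param ratios train/val/test proportions summing to 1 (default 7:1:2).
#' @param seed RNG seed for the shuffle.
#' @param labels optional per-id dominant class for stratified splitting.
#' @return list with train, val, test id vectors, the ratios and the seed.
#' @export
split_dataset <- function(ids, ratios = c(0.7, 0.1, 0.2), seed = 1L,
                          labels = NULL) {
  if (abs(sum(ratios) - 1) > 1e-9) stop("split ratios must sum to 1")
  if (length(ratios) != 3L) stop("need exactly three ratios (train/val/test)")
  n <- length(ids)
  n_train <- floor(ratios[1] * n)
  n_val <- floor(ratios[2] * n)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  if (is.null(labels)) {
    perm <- sample.int(n)
  } else {
    stopifnot(length(labels) == n)
    # stratified: shuffle within class, then order everything by jittered
    # within-class fractional rank so every prefix of the permutation is
    # close to class-proportional
    rnd <- stats::runif(n)
    fr <- numeric(n)
    for (cl in unique(labels)) {
      k <- which(labels == cl)
      k <- k[order(rnd[k])]
      fr[k] <- (seq_along(k) - stats::runif(length(k))) / length(k)
    }
    perm <- order(fr)
  }
  sel_train <- perm[seq_len(n_train)]
  sel_val <- perm[n_train + seq_len(n_val)]
  sel_test <- perm[-seq_len(n_train + n_val)]
  structure(list(train = ids[sel_train], val = ids[sel_val],
                 test = ids[sel_test], ratios = ratios, seed = seed),
            class = "dataset_split")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# nearest-neighbour image resize for (H, W, C) arrays
resize_nearest <- function(img, H2, W2) {
  d <- dim(img)
  ri <- pmin(pmax(round((seq_len(H2) - 0.5) * d[1] / H2 + 0.5), 1L), d[1])
  ci <- pmin(pmax(round((seq_len(W2) - 0.5) * d[2] / W2 + 0.5), 1L), d[2])
  img[ri, ci, , drop = FALSE]
}

box_blur3 <- function(img) {
  d <- dim(img)
  out <- img
  for (ch in seq_len(d[3])) {
    m <- img[, , ch]
    p <- m[c(1, seq_len(d[1]), d[1]), c(1, seq_len(d[2]), d[2])]
    acc <- matrix(0, d[1], d[2])
    for (di in 0:2) for (dj in 0:2)
      acc <- acc + p[di + seq_len(d[1]), dj + seq_len(d[2])]
    out[, , ch] <- acc / 9
  }
  out
}

# rotate image + records by k * 90 degrees counter-clockwise
rotate90_sample <- function(img, records, k) {
  k <- k %% 4L
  if (k == 0L) return(list(image = img, records = records))
  for (r in seq_len(k)) {
    d <- dim(img)
    # 90 deg CCW: new[i, j] = old[j, W + 1 - i]; for normalized centers on a
    # square image this is (cx, cy) -> (cy, 1 - cx)
    img <- aperm(img, c(2, 1, 3))[d[2]:1, , , drop = FALSE]
    if (nrow(records) > 0L) {
      ncx <- records$cy
      ncy <- 1 - records$cx
      records$cx <- ncx
      records$cy <- ncy
      tmp <- records$w
      records$w <- records$h
      records$h <- tmp
    }
  }
  list(image = img, records = records)
}

crop_sample <- function(img, records, x0, y0, cw, ch, min_visible = 0.3) {
  d <- dim(img)
  px0 <- max(1L, round(x0 * d[2]) + 1L)
  py0 <- max(1L, round(y0 * d[1]) + 1L)
  px1 <- min(d[2], round((x0 + cw) * d[2]))
  py1 <- min(d[1], round((y0 + ch) * d[1]))
  sub <- img[py0:py1, px0:px1, , drop = FALSE]
  sub <- resize_nearest(sub, d[1], d[2])
  if (nrow(records) > 0L) {
    x1 <- records$cx - records$w / 2; x2 <- records$cx + records$w / 2
    y1 <- records$cy - records$h / 2; y2 <- records$cy + records$h / 2
    nx1 <- pmin(pmax((x1 - x0) / cw, 0), 1)
    nx2 <- pmin(pmax((x2 - x0) / cw, 0), 1)
    ny1 <- pmin(pmax((y1 - y0) / ch, 0), 1)
    ny2 <- pmin(pmax((y2 - y0) / ch, 0), 1)
    vis_frac <- ((nx2 - nx1) * (ny2 - ny1) * cw * ch) /
      pmax(records$w * records$h, 1e-12)
    keep <- vis_frac >= min_visible & (nx2 - nx1) > 0 & (ny2 - ny1) > 0
    records <- records[keep, , drop = FALSE]
    if (nrow(records) > 0L) {
      records$cx <- (nx1[keep] + nx2[keep]) / 2
      records$cy <- (ny1[keep] + ny2[keep]) / 2
      records$w <- nx2[keep] - nx1[keep]
      records$h <- ny2[keep] - ny1[keep]
    }
  }
  list(image = sub, records = records)
}

#' Augment an image and its annotations
#'
#' Applies a seeded chain of random crop (box coordinates remapped, boxes
#' with less than `min_visible` of their area remaining are dropped),
#' rotation by a multiple of 90 degrees (exact box geometry), and a 3x3
#' box blur (annotations untouched). Intended for the training partition
#' only; the split is taken before augmentation.
#'
#' @param image `(H, W, 3)` array in `[0, 1]`.
#' @param records annotation data frame.
#' @param ops subset of `c("crop", "rotate", "blur")`.
#' @param seed RNG seed.
#' @param min_visible minimum remaining area fraction before a box is
#'   dropped by the crop (default 0.3).
#' @return list with `image` and `records`.
#' @export
augment_sample <- function(image, records,
                           ops = c("crop", "rotate", "blur"),
                           seed = 1L, min_visible = 0.3) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  out <- list(image = image, records = records)
  if ("crop" %in% ops) {
    s <- stats::runif(1, 0.6, 0.95)
    x0 <- stats::runif(1, 0, 1 - s)
    y0 <- stats::runif(1, 0, 1 - s)
    out <- crop_sample(out$image, out$records, x0, y0, s, s, min_visible)
  }
  if ("rotate" %in% ops) {
    k <- sample(0:3, 1)
    out <- rotate90_sample(out$image, out$records, k)
  }
  if ("blur" %in% ops && stats::runif(1) < 0.5) {
    out$image <- box_blur3(out$image)
  }
  if (nrow(out$records) > 0L) validate_records(out$records)
  out
}
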