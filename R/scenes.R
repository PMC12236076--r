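# Seeded procedural generator of weed-like scenes. The generator does not
# attempt photo-realism; it reproduces the statistical shape of the task:
# five visually distinct plant classes (parametric rosettes of elliptical
# lobes with class-specific lobe count, elongation and hue), a textured
# soil background, global illumination jitter, and single-target /
# multi-target / mutual-occlusion layouts with tight boxes.

default_class_params <- function() {
  list(
    beggartick = list(lobes = 7L, elong = 2.8, col = c(0.36, 0.55, 0.18)),
    crabgrass = list(lobes = 5L, elong = 4.5, col = c(0.30, 0.62, 0.24)),
    galinsoga_quadriradiata = list(lobes = 8L, elong = 1.6, col = c(0.18, 0.48, 0.20)),
    goosegrass = list(lobes = 6L, elong = 5.5, col = c(0.46, 0.66, 0.30)),
    tropic_ageratum_herb = list(lobes = 9L, elong = 1.3, col = c(0.24, 0.50, 0.36))
  )
}

#' Specification of a synthetic weed scene
#'
#' @param size image side in pixels (square scenes).
#' @param n_targets number of plants; `NULL` picks a scenario default.
#' @param scenario `"single"`, `"multi"` or `"occlusion"` (the last
#'   guarantees at least one overlapping pair of boxes).
#' @param seed RNG seed; the same spec and seed give a bit-identical scene.
#' @param classes class ids to draw from (default all five).
#' @param class_params per-class shape/color parameters, see
#'   [default_class_params()].
#' @export
scene_spec <- function(size = 640L, n_targets = NULL,
                       scenario = c("multi", "single", "occlusion"),
                       seed = 1L, classes = 0:4,
                       class_params = default_class_params()) {
  scenario <- match.arg(scenario)
  if (is.null(n_targets))
    n_targets <- switch(scenario, single = 1L, multi = 4L, occlusion = 3L)
  if (scenario == "single" && n_targets != 1L)
    stop("single-target scenario requires n_targets = 1")
  if (scenario == "occlusion" && n_targets < 2L)
    stop("occlusion scenario requires at least 2 targets")
  structure(list(size = as.integer(size), n_targets = as.integer(n_targets),
                 scenario = scenario, seed = as.integer(seed),
                 classes = as.integer(classes), class_params = class_params),
            class = "scene_spec")
}

soil_background <- function(size) {
  coarse <- max(4L, size %/% 16L)
  base <- c(0.36, 0.28, 0.20)
  img <- array(0, c(size, size, 3))
  noise <- array(stats::runif(coarse * coarse * 3, -0.06, 0.06), c(coarse, coarse, 3))
  noise <- box_blur3(resize_nearest(noise, size, size))
  speck <- matrix(stats::runif(size * size, -0.04, 0.04), size, size)
  for (ch in 1:3) img[, , ch] <- base[ch] + noise[, , ch] + speck
  img
}

# draw one rosette plant; returns updated image plus the tight pixel bbox
draw_plant <- function(img, cx, cy, radius, pars) {
  size <- dim(img)[1]
  ext <- ceiling(radius * 1.15)
  r0 <- max(1L, floor(cy - ext)); r1 <- min(size, ceiling(cy + ext))
  c0 <- max(1L, floor(cx - ext)); c1 <- min(size, ceiling(cx + ext))
  ys <- r0:r1; xs <- c0:c1
  dy <- outer(ys - cy, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - cx)
  mask <- matrix(FALSE, length(ys), length(xs))
  base_rot <- stats::runif(1, 0, 2 * pi)
  a <- radius * 0.52
  b <- a / pars$elong
  for (l in seq_len(pars$lobes)) {
    th <- base_rot + 2 * pi * (l - 1) / pars$lobes + stats::rnorm(1, 0, 0.08)
    u <- cos(th) * dx + sin(th) * dy
    v <- -sin(th) * dx + cos(th) * dy
    mask <- mask | (((u - radius * 0.45) / a)^2 + (v / b)^2 <= 1)
  }
  if (!any(mask)) return(NULL)
  shade <- 1 - 0.35 * sqrt(dx^2 + dy^2) / (radius * 1.15)
  gain <- stats::runif(1, 0.85, 1.15)
  for (ch in 1:3) {
    plane <- img[ys, xs, ch]
    colv <- pars$col[ch] * gain * shade +
      stats::rnorm(length(plane), 0, 0.015)
    plane[mask] <- pmin(pmax(colv[mask], 0), 1)
    img[ys, xs, ch] <- plane
  }
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  list(img = img, bbox = c(x1 = xs[cols[1]] - 1, y1 = ys[rows[1]] - 1,
                           x2 = xs[cols[2]], y2 = ys[rows[2]]))
}

#' Generate one synthetic weed scene
#'
#' @param spec a [scene_spec()].
#' @return list with `image` (`(H, W, 3)` array in `[0, 1]`) and `records`
#'   (annotation data frame with normalized center-form boxes).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  size <- spec$size
  n <- spec$n_targets
  rmin <- 0.09 * size; rmax <- 0.16 * size
  if (n * (2 * rmax)^2 > 2.5 * size^2)
    stop("generate_scene: target count exceeds packable area")
  img <- soil_background(size)
  classes <- weed_classes()
  placed <- list()
  boxes <- matrix(0, 0, 4)
  tries_budget <- 400L
  for (i in seq_len(n)) {
    radius <- stats::runif(1, rmin, rmax)
    ok <- FALSE
    for (try in seq_len(tries_budget)) {
      if (spec$scenario == "occlusion" && i == 2L) {
        # anchor the second plant on the first to guarantee overlap
        d <- (placed[[1]]$radius + radius) * stats::runif(1, 0.35, 0.55)
        th <- stats::runif(1, 0, 2 * pi)
        cx <- placed[[1]]$cx + d * cos(th)
        cy <- placed[[1]]$cy + d * sin(th)
      } else {
        cx <- stats::runif(1, radius, size - radius)
        cy <- stats::runif(1, radius, size - radius)
      }
      if (cx < radius || cx > size - radius || cy < radius || cy > size - radius)
        next
      cand <- c(cx - radius, cy - radius, cx + radius, cy + radius)
      if (nrow(boxes) > 0L && !(spec$scenario == "occlusion" && i == 2L)) {
        overlap <- max(box_iou_matrix(matrix(cand, 1), boxes))
        if (overlap > 0.08) next
      }
      ok <- TRUE
      break
    }
    if (!ok) stop("generate_scene: could not place target ", i,
                  "; target count exceeds packable area")
    cid <- sample(spec$classes, 1)
    pars <- spec$class_params[[classes[cid + 1L]]]
    res <- draw_plant(img, cx, cy, radius, pars)
    img <- res$img
    placed[[i]] <- list(cx = cx, cy = cy, radius = radius, class_id = cid,
                        bbox = res$bbox)
    boxes <- rbind(boxes, matrix(res$bbox, 1))
  }
  # global illumination jitter
  img <- pmin(pmax(img * stats::runif(1, 0.85, 1.15), 0), 1)
  bb <- do.call(rbind, lapply(placed, function(p) p$bbox))
  cid <- vapply(placed, function(p) p$class_id, numeric(1))
  records <- annotation_records(
    class_id = cid,
    cx = (bb[, 1] + bb[, 3]) / 2 / size,
    cy = (bb[, 2] + bb[, 4]) / 2 / size,
    w = (bb[, 3] - bb[, 1]) / size,
    h = (bb[, 4] - bb[, 2]) / size,
    image = sprintf("scene_%06d", spec$seed))
  list(image = img, records = records)
}

#' Generate a set of synthetic scenes
#'
#' @param n number of scenes.
#' @param scenario layout preset, see [scene_spec()]; `"mixed"` cycles
#'   through single, multi and occlusion layouts.
#' @param size image side in pixels.
#' @param seed base seed; scene i uses `seed * 1000 + i`.
#' @param dir optional directory: scenes are written as PNG plus YOLO txt.
#' @export
make_synthetic_dataset <- function(n, scenario = "mixed", size = 640L,
                                   seed = 1L, dir = NULL) {
  scens <- if (scenario == "mixed")
    rep(c("single", "multi", "occlusion"), length.out = n)
  else rep(scenario, n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sc <- generate_scene(scene_spec(size = size, scenario = scens[i],
                                    seed = seed * 1000L + i))
    sc$records$image <- sprintf("scene_%03d", i)
    sc$scenario <- scens[i]
    out[[i]] <- sc
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      png::writePNG(sc$image, file.path(dir, sprintf("scene_%03d.png", i)))
      write_yolo_txt(sc$records, file.path(dir, sprintf("scene_%03d.txt", i)))
    }
  }
  out
}
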