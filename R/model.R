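# Model assembly: configuration, the ablation-variant factory (Table of
# toggles: PGRNet backbone, AIFI-HiLo, RetC3, Focaler-WIoUv3 loss), the
# complexity accountant (trainable parameters, multiply-accumulate derived
# FLOPs at a stated input size, serialized size), and NMS-free prediction.

#' Default model configuration
#'
#' Widths that the design leaves open (PGRNet stage widths, fusion-block
#' hidden widths, encoder FFN width) carry the calibrated defaults under
#' which the builds profile to their published complexity; every entry can
#' be overridden, e.g. from a YAML config via [phrf_config_yaml()].
#' @param ... named overrides merged over the defaults (nested lists are
#'   merged recursively).
#' @export
phrf_config <- function(...) {
  cfg <- list(
    nc = 5L,
    dim = 256L,
    encoder = list(heads = 8L, ffn = 2048L),
    hilo = list(alpha = 0.5, window = 2L),
    repc3 = list(depth = 3L,
                 hidden = list(p4_td = 128L, p3 = 96L, p4_bu = 128L, p5 = 128L)),
    retc3 = list(depth = 3L, heads = 4L, gamma_min = 0.6, gamma_max = 0.98,
                 hidden = list(p4_td = 48L, p3 = 24L, p4_bu = 48L, p5 = 144L)),
    pgrnet = list(stage_widths = c(48L, 128L, 256L), stem_width = 16L,
                  width_multiple = 1),
    resnet = list(widths = c(64L, 64L, 128L, 256L, 512L)),
    decoder = list(layers = 3L, queries = 300L, heads = 8L, ffn = 1152L),
    loss = list(focaler = list(d = 0, u = 0.95),
                wiou = list(alpha = 1.9, delta = 3, momentum = 0.01),
                weights = list(cls = 1, l1 = 5, iou = 2, neg = 0.1)))
  merge_cfg(cfg, list(...))
}

merge_cfg <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_cfg(base[[nm]], over[[nm]])
    else base[[nm]] <- over[[nm]]
  }
  base
}

#' Load a configuration from YAML, merged over the defaults
#' @param path YAML file with (a subset of) the [phrf_config()] keys.
#' @export
phrf_config_yaml <- function(path) {
  do.call(phrf_config, yaml::read_yaml(path))
}

#' The ablation-variant toggle table
#'
#' Rows basic, m1..m6 and final with the four toggles (PGRNet, AIFI-HiLo,
#' RetC3, Focaler-WIoUv3); models 1-4 switch one component each, m5/m6
#' accumulate the first two/three, and the final model enables all four.
#' @export
variant_table <- function() {
  data.frame(
    variant = c("basic", "m1_pgrnet", "m2_hilo", "m3_retc3", "m4_loss",
                "m5", "m6", "final"),
    pgrnet = c(FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    hilo = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE),
    retc3 = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE),
    focaler_wiou = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
}

#' Build a model variant
#'
#' @param variant a row name of [variant_table()] (`"final"` builds the
#'   full model with all four modifications).
#' @param config a [phrf_config()].
#' @param seed seed for weight initialization.
#' @return a `phrf_model` module.
#' @export
build_variant <- function(variant = "final", config = phrf_config(),
                          seed = 0L) {
  vt <- variant_table()
  row <- vt[vt$variant == variant, ]
  if (nrow(row) != 1L) stop("unknown variant '", variant, "'; expected one of ",
                            paste(vt$variant, collapse = ", "))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  m <- ph_module_new("phrf_model")
  m$variant <- variant
  m$toggles <- as.list(row[, -1])
  m$config <- config
  m$mods$backbone <- if (row$pgrnet)
    build_pgrnet(pgrnet_spec(config$pgrnet$stage_widths,
                             config$pgrnet$stem_width,
                             config$pgrnet$width_multiple))
  else resnet18_backbone(config$resnet$widths)
  m$mods$encoder <- hybrid_encoder(m$mods$backbone$out_channels,
                                   dim = config$dim, cfg = config,
                                   use_hilo = row$hilo,
                                   fusion = if (row$retc3) "retc3" else "repc3")
  m$mods$decoder <- phrf_decoder(config$dim, config$nc,
                                 config$decoder$queries,
                                 config$decoder$layers,
                                 config$decoder$heads,
                                 config$decoder$ffn)
  m$loss_type <- if (row$focaler_wiou) "focaler_wiou" else "giou"
  m
}

#' @export
ph_fwd.phrf_model <- function(m, x, train = FALSE, ...) {
  feats <- ph_fwd(m$mods$backbone, x, train = train)
  enc <- ph_fwd(m$mods$encoder, feats, train = train)
  ph_fwd(m$mods$decoder, enc, train = train)
}

#' Profile a model build: Params, FLOPs and serialized size
#'
#' Parameters are counted in closed form (kernel-width x kernel-height x
#' C_in x C_out per convolution plus biases and normalization affine
#' terms) and cross-checked against the summed tensor sizes; FLOPs are the
#' layer-wise output-area x per-pixel-parameter products on the fused
#' inference graph, with one multiply-accumulate counted as two operations;
#' size is `params x B_params / 1024^2` megabytes with `B_params = 2`
#' (half-precision serialization).
#'
#' @param model a `phrf_model`.
#' @param input_hw input height/width (default 640 x 640).
#' @param b_params bytes per serialized weight.
#' @return a `complexity_report` list: params, gflops, size_mb, breakdown.
#' @export
profile_model <- function(model, input_hw = c(640L, 640L), b_params = 2) {
  pb <- ph_profile(model$mods$backbone, c(input_hw[1], input_hw[2], 3L))
  pe <- ph_profile(model$mods$encoder, pb$out)
  pd <- ph_profile(model$mods$decoder, pe$out)
  params <- pb$params + pe$params + pd$params
  actual <- ph_nparams(model)
  if (params != actual)
    stop("profile_model: closed-form parameter count (", params,
         ") disagrees with tensor count (", actual, ")")
  macs <- pb$macs + pe$macs + pd$macs
  structure(list(
    variant = model$variant,
    input_hw = input_hw,
    params = params,
    params_m = params / 1e6,
    macs = macs,
    flops = 2 * macs,
    gflops = 2 * macs / 1e9,
    size_mb = params * b_params / 1024^2,
    breakdown = data.frame(
      component = c("backbone", "encoder", "decoder"),
      params = c(pb$params, pe$params, pd$params),
      gflops = 2 * c(pb$macs, pe$macs, pd$macs) / 1e9)),
    class = "complexity_report")
}

#' @export
print.complexity_report <- function(x, ...) {
  cat(sprintf("%s @ %dx%d: %.2f M params, %.1f GFLOPs, %.1f MB\n",
              x$variant, x$input_hw[1], x$input_hw[2],
              x$params_m, x$gflops, x$size_mb))
  print(x$breakdown, row.names = FALSE)
  invisible(x)
}

#' Apply a module to a batched feature map
#'
#' Public entry point for running blocks on `(N, C, H, W)` arrays; the
#' batch dimension is looped, channels-last internally.
#' @param m a module; `x` an `(N, C, H, W)` array.
#' @export
ph_apply <- function(m, x, train = FALSE) {
  stopifnot(length(dim(x)) == 4L)
  n <- dim(x)[1]
  outs <- vector("list", n)
  for (i in seq_len(n)) {
    xi <- aperm(array(x[i, , , ], dim(x)[2:4]), c(2, 3, 1))
    yi <- tg_val(ph_fwd(m, xi, train = train))
    outs[[i]] <- aperm(yi, c(3, 1, 2))
  }
  d1 <- dim(outs[[1]])
  y <- array(0, c(n, d1))
  for (i in seq_len(n)) y[i, , , ] <- outs[[i]]
  y
}

#' Predict detections (NMS-free)
#'
#' Runs inference and emits one detection per query whose best class score
#' reaches the threshold: class id, confidence in `[0, 1]`, and a
#' normalized corner-form box clipped to the image, sorted by score. No
#' non-maximum suppression is applied.
#'
#' @param model a `phrf_model`.
#' @param images a single `(H, W, 3)` array or a list of them.
#' @param score_threshold minimum confidence.
#' @param batch_stats normalize with each map's own statistics instead of
#'   the stored running estimates (deterministic; appropriate after
#'   batch-of-one training, where running estimates track the most recent
#'   images rather than the set).
#' @return data frame: image, class, score, x1, y1, x2, y2 (normalized).
#' @export
predict_detections <- function(model, images, score_threshold = 0.25,
                               batch_stats = FALSE) {
  if (!is.list(images)) images <- list(images)
  mode <- if (batch_stats) "stats" else FALSE
  out <- list()
  for (i in seq_along(images)) {
    pred <- ph_fwd(model, images[[i]], train = mode)
    logits <- tg_val(pred$final$logits)
    boxes <- tg_val(pred$final$boxes)
    probs <- 1 / (1 + exp(-logits))
    cls <- max.col(probs, ties.method = "first")
    score <- probs[cbind(seq_len(nrow(probs)), cls)]
    keep <- which(score >= score_threshold)
    if (length(keep) == 0L) next
    xy <- box_cxcywh_to_xyxy(boxes[keep, , drop = FALSE])
    xy <- pmin(pmax(xy, 0), 1)
    df <- data.frame(image = i, class = cls[keep] - 1L, score = score[keep],
                     x1 = xy[, 1], y1 = xy[, 2], x2 = xy[, 3], y2 = xy[, 4])
    out[[length(out) + 1L]] <- df[order(-df$score), , drop = FALSE]
  }
  if (length(out) == 0L)
    return(data.frame(image = integer(0), class = integer(0),
                      score = numeric(0), x1 = numeric(0), y1 = numeric(0),
                      x2 = numeric(0), y2 = numeric(0)))
  do.call(rbind, out)
}
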