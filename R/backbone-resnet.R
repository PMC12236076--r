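# ResNet18 feature extractor: the baseline backbone of the r18-scale
# real-time detection transformer. Emits the stride-8/16/32 pyramid
# (p3, p4, p5) with channel widths (128, 256, 512).

ph_basic_block <- function(cin, cout, stride = 1L) {
  m <- ph_module_new("ph_basic_block")
  m$cin <- cin; m$cout <- cout; m$stride <- stride
  m$mods$c1 <- ph_conv(cin, cout, 3L, stride = stride, act = "relu")
  m$mods$c2 <- ph_conv(cout, cout, 3L, act = "identity")
  if (stride != 1L || cin != cout)
    m$mods$down <- ph_conv(cin, cout, 1L, stride = stride, pad = 0L,
                           act = "identity")
  m
}

#' @export
ph_fwd.ph_basic_block <- function(m, x, train = FALSE, ...) {
  y <- ph_fwd(m$mods$c2, ph_fwd(m$mods$c1, x, train = train), train = train)
  sk <- if (!is.null(m$mods$down)) ph_fwd(m$mods$down, x, train = train) else x
  t_relu(y + sk)
}

#' @export
ph_profile.ph_basic_block <- function(m, inshape) {
  p1 <- ph_profile(m$mods$c1, inshape)
  p2 <- ph_profile(m$mods$c2, p1$out)
  macs <- p1$macs + p2$macs
  if (!is.null(m$mods$down)) macs <- macs + ph_profile(m$mods$down, inshape)$macs
  list(out = p2$out, macs = macs, params = ph_nparams_closed(m))
}

#' ResNet18 backbone emitting the stride-8/16/32 feature pyramid
#'
#' @param widths channel plan `(stem, stage1..stage4)`.
#' @export
resnet18_backbone <- function(widths = c(64L, 64L, 128L, 256L, 512L)) {
  m <- ph_module_new("ph_resnet18")
  m$widths <- widths
  m$out_channels <- widths[3:5]
  m$mods$stem <- ph_conv(3L, widths[1], 7L, stride = 2L, pad = 3L, act = "relu")
  m$mods$pool <- ph_maxpool(3L, 2L, 1L)
  mk_stage <- function(cin, cout, stride) ph_sequential(
    ph_basic_block(cin, cout, stride), ph_basic_block(cout, cout, 1L))
  m$mods$layer1 <- mk_stage(widths[1], widths[2], 1L)
  m$mods$layer2 <- mk_stage(widths[2], widths[3], 2L)
  m$mods$layer3 <- mk_stage(widths[3], widths[4], 2L)
  m$mods$layer4 <- mk_stage(widths[4], widths[5], 2L)
  m
}

#' @export
ph_fwd.ph_resnet18 <- function(m, x, train = FALSE, ...) {
  x <- ph_fwd(m$mods$pool, ph_fwd(m$mods$stem, x, train = train))
  x <- ph_fwd(m$mods$layer1, x, train = train)
  p3 <- ph_fwd(m$mods$layer2, x, train = train)
  p4 <- ph_fwd(m$mods$layer3, p3, train = train)
  p5 <- ph_fwd(m$mods$layer4, p4, train = train)
  list(p3 = p3, p4 = p4, p5 = p5)
}

#' @export
ph_profile.ph_resnet18 <- function(m, inshape) {
  macs <- 0
  sh <- inshape
  outs <- list()
  for (nm in c("stem", "pool", "layer1", "layer2", "layer3", "layer4")) {
    pr <- ph_profile(m$mods[[nm]], sh)
    macs <- macs + pr$macs
    sh <- pr$out
    if (nm %in% c("layer2", "layer3", "layer4")) outs[[nm]] <- pr$out
  }
  list(out = list(p3 = outs$layer2, p4 = outs$layer3, p5 = outs$layer4),
       macs = macs, params = ph_nparams_closed(m))
}
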