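# PGRNet: the lightweight multi-kernel backbone. Its unit, PGRBlock, runs a
# 3x3 convolution over all C channels, a 5x5 convolution over the first
# half of that result, and a 7x7 convolution over the first quarter of the
# 5x5 result; untouched channel slices pass through unchanged (the partial
# convolution principle), the three contributions (C/4 + C/4 + C/2) are
# concatenated back to C channels, and the block closes with a residual
# add. PGRNet stacks five 3x3 convolutions (all stride 2) and four
# PGRBlocks into three stages and taps the stride-8/16/32 pyramid.

#' PGRBlock: channel-split multi-kernel residual unit
#'
#' @param channels channel count C; must be divisible by 4 so the C/2 and
#'   C/4 slices are integral.
#' @param use_norm apply batch normalization after each convolution.
#' @param act activation name.
#' @return a module; forward preserves the input shape.
#' @export
pgr_block <- function(channels, use_norm = TRUE, act = "silu") {
  if (channels %% 4L != 0L)
    stop("pgr_block: channels must be divisible by 4, got ", channels)
  m <- ph_module_new("ph_pgr_block")
  m$channels <- as.integer(channels)
  m$mods$c3 <- ph_conv(channels, channels, 3L, norm = use_norm, act = act,
                       bias = FALSE)
  m$mods$c5 <- ph_conv(channels %/% 2L, channels %/% 2L, 5L, norm = use_norm,
                       act = act, bias = FALSE)
  m$mods$c7 <- ph_conv(channels %/% 4L, channels %/% 4L, 7L, norm = use_norm,
                       act = act, bias = FALSE)
  m
}

#' @export
ph_fwd.ph_pgr_block <- function(m, x, train = FALSE, ...) {
  C <- m$channels
  d <- dim(tg_val(x))
  if (d[3] != C) stop("pgr_block: expected ", C, " channels, got ", d[3])
  y3 <- ph_fwd(m$mods$c3, x, train = train)
  half <- t_chan(y3, seq_len(C %/% 2L))            # convolved slice
  pass3 <- t_chan(y3, (C %/% 2L + 1L):C)           # untouched half
  y5 <- ph_fwd(m$mods$c5, half, train = train)
  quarter <- t_chan(y5, seq_len(C %/% 4L))
  pass5 <- t_chan(y5, (C %/% 4L + 1L):(C %/% 2L))  # untouched quarter
  y7 <- ph_fwd(m$mods$c7, quarter, train = train)
  out <- tg_concat_ch(list(y7, pass5, pass3))
  y <- out + x
  dy <- dim(tg_val(y))
  if (!all(dy == d)) stop("pgr_block: spatial dims changed (internal error)")
  y
}

#' @export
ph_profile.ph_pgr_block <- function(m, inshape) {
  C <- m$channels
  hw <- inshape[1] * inshape[2]
  macs <- hw * (9 * C^2 + 25 * (C / 2)^2 + 49 * (C / 4)^2)
  list(out = inshape, macs = macs, params = ph_nparams_closed(m))
}

#' Grouped convolution as a functional operation
#'
#' Splits the input into `groups` channel groups, convolves each with its
#' own kernels and concatenates, using `1/groups` the parameters of the
#' standard convolution.
#'
#' @param x feature map, `(N, C, H, W)` array.
#' @param out_channels output channels.
#' @param k kernel side; `groups` channel groups; `stride`, `pad` as usual.
#' @param module optionally, a prebuilt [ph_conv()] to apply.
#' @return list with `value` (`(N, C_out, H', W')` array) and `module`.
#' @export
group_conv <- function(x, out_channels, k = 3L, groups = 1L, stride = 1L,
                       pad = "same", module = NULL) {
  cin <- dim(x)[2]
  if (cin %% groups != 0L)
    stop("group_conv: input channels not divisible by groups")
  if (is.null(module))
    module <- ph_conv(cin, out_channels, k, stride = stride, pad = pad,
                      groups = groups, norm = FALSE, act = "identity",
                      bias = FALSE)
  list(value = ph_apply(module, x), module = module)
}

#' PGRNet backbone specification
#'
#' @param stage_widths pyramid channel widths `(w1, w2, w3)` at strides
#'   8/16/32; each divisible by 4.
#' @param stem_width width of the two leading stem convolutions.
#' @param width_multiple multiplier applied to all widths.
#' @param use_norm,act normalization / activation plan.
#' @export
pgrnet_spec <- function(stage_widths = c(64L, 128L, 304L), stem_width = 24L,
                        width_multiple = 1, use_norm = TRUE, act = "silu") {
  w <- as.integer(round(stage_widths * width_multiple))
  w0 <- as.integer(round(stem_width * width_multiple))
  if (any(c(w, w0) %% 4L != 0L))
    stop("pgrnet_spec: widths must be divisible by 4")
  list(stage_widths = w, stem_width = w0, use_norm = use_norm, act = act)
}

#' Build the PGRNet backbone
#'
#' Three stages over nine layers — stage 1: conv, conv, PGRBlock; stage 2:
#' conv, PGRBlock, conv; stage 3: PGRBlock, conv, PGRBlock — with exactly
#' five 3x3 convolutions (each stride 2, so the stride product is 32) and
#' four PGRBlocks. The pyramid is tapped after the PGRBlocks at strides
#' 8, 16 and 32.
#'
#' @param spec a [pgrnet_spec()].
#' @export
build_pgrnet <- function(spec = pgrnet_spec()) {
  m <- ph_module_new("ph_pgrnet")
  w <- spec$stage_widths
  w0 <- spec$stem_width
  m$out_channels <- w
  un <- spec$use_norm; ac <- spec$act
  m$mods$conv1 <- ph_conv(3L, w0, 3L, stride = 2L, norm = un, act = ac)
  m$mods$conv2 <- ph_conv(w0, w0, 3L, stride = 2L, norm = un, act = ac)
  m$mods$pgr1 <- pgr_block(w0, use_norm = un, act = ac)
  m$mods$conv3 <- ph_conv(w0, w[1], 3L, stride = 2L, norm = un, act = ac)
  m$mods$pgr2 <- pgr_block(w[1], use_norm = un, act = ac)
  m$mods$conv4 <- ph_conv(w[1], w[2], 3L, stride = 2L, norm = un, act = ac)
  m$mods$pgr3 <- pgr_block(w[2], use_norm = un, act = ac)
  m$mods$conv5 <- ph_conv(w[2], w[3], 3L, stride = 2L, norm = un, act = ac)
  m$mods$pgr4 <- pgr_block(w[3], use_norm = un, act = ac)
  m
}

pgrnet_layer_order <- c("conv1", "conv2", "pgr1", "conv3", "pgr2",
                        "conv4", "pgr3", "conv5", "pgr4")

#' @export
ph_fwd.ph_pgrnet <- function(m, x, train = FALSE, ...) {
  taps <- list()
  for (nm in pgrnet_layer_order) {
    x <- ph_fwd(m$mods[[nm]], x, train = train)
    if (nm == "pgr2") taps$p3 <- x
    if (nm == "pgr3") taps$p4 <- x
    if (nm == "pgr4") taps$p5 <- x
  }
  taps
}

#' @export
ph_profile.ph_pgrnet <- function(m, inshape) {
  macs <- 0
  sh <- inshape
  outs <- list()
  for (nm in pgrnet_layer_order) {
    pr <- ph_profile(m$mods[[nm]], sh)
    macs <- macs + pr$macs
    sh <- pr$out
    if (nm == "pgr2") outs$p3 <- sh
    if (nm == "pgr3") outs$p4 <- sh
    if (nm == "pgr4") outs$p5 <- sh
  }
  list(out = outs, macs = macs, params = ph_nparams_closed(m))
}

#' Structural audit of a backbone: 3x3 convolution and PGRBlock counts
#' @export
backbone_audit <- function(m) {
  n_conv3 <- 0L
  n_pgr <- 0L
  walk <- function(mod) {
    if (inherits(mod, "ph_pgr_block")) {
      n_pgr <<- n_pgr + 1L
      return(invisible())  # inner convs belong to the block
    }
    if (inherits(mod, "ph_conv") && mod$k == 3L) n_conv3 <<- n_conv3 + 1L
    for (s in mod$mods) walk(s)
  }
  walk(m)
  list(conv3x3 = n_conv3, pgr_blocks = n_pgr)
}
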