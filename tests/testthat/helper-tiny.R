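# shared fixtures: a reduced-width configuration for forward-pass tests
# (full-width builds are only profiled, never run numerically in tests)

tiny_config <- function(...) {
  phrf_config(
    dim = 32L,
    encoder = list(heads = 4L, ffn = 64L),
    repc3 = list(hidden = list(p4_td = 16L, p3 = 16L, p4_bu = 16L, p5 = 16L)),
    retc3 = list(heads = 2L, hidden = list(p4_td = 16L, p3 = 16L,
                                           p4_bu = 16L, p5 = 16L)),
    pgrnet = list(stage_widths = c(16L, 32L, 64L), stem_width = 8L),
    decoder = list(layers = 2L, queries = 20L, heads = 4L, ffn = 64L),
    ...)
}

# (N, C, H, W) random feature map
rand_fm <- function(n, c, h, w, seed = 1) {
  set.seed(seed)
  array(stats::rnorm(n * c * h * w), c(n, c, h, w))
}

# internal channels-last map
rand_map <- function(h, w, c, seed = 1) {
  set.seed(seed)
  array(stats::rnorm(h * w * c), c(h, w, c))
}

expect_all_finite <- function(x) expect_true(all(is.finite(unlist(x))))

# brute-force AP oracle: exhaustive integration of the P(R) staircase for a
# ranked TP/FP list, with the same precision-envelope conventions
ap_oracle <- function(tp, n_gt, grid = seq(0, 1, by = 0.01)) {
  ctp <- cumsum(tp)
  prec <- ctp / seq_along(tp)
  rec <- ctp / n_gt
  vapply(grid, function(r) {
    ok <- which(rec >= r - 1e-12)
    if (length(ok) == 0) 0 else max(prec[ok[1]:length(prec)])
  }, numeric(1)) |> mean()
}
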