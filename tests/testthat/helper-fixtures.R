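# shared in-code fixtures -------------------------------------------------

# two-level co-flow frame: `dark_cols` columns at `lo` then `hi`
two_level_frame <- function(dark_cols, width = 200, height = 50,
                            lo = 40, hi = 200) {
  f <- matrix(hi, height, width)
  if (dark_cols > 0) f[, seq_len(dark_cols)] <- lo
  f
}

# filled-channel frame: dark band of `band_px` columns centred in a bright
# frame; `extra_rows_wider` rows get one extra band column (sub-pixel mean)
band_frame <- function(band_px, width = 600, height = 50,
                       extra_rows_wider = 0, lo = 30, hi = 220) {
  f <- matrix(hi, height, width)
  start <- floor((width - band_px) / 2)
  f[, start + seq_len(band_px)] <- lo
  if (extra_rows_wider > 0) {
    f[seq_len(extra_rows_wider), start + band_px + 1] <- lo
  }
  f
}

default_scenario <- function(seed = 7, ...) {
  synthetic_scenario(seed = seed, ...)
}

analysis_config <- function(scenario, ...) {
  utils::modifyList(
    list(protocol = scenario$protocol, mu_R = scenario$fluids$mu_R),
    list(...))
}
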