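# shared fixtures built in code

# delta-F/F trace from explicit values (times 0 at frame `injury`)
make_dff <- function(values, dt = 2, injury = 1) {
  kinetic_trace((seq_along(values) - injury) * dt, values, kind = "dff",
                injury_index = injury)
}

# noise-free influx generator shortcut
quiet_influx <- function(...) {
  influx_model(noise_sd = 0, photon_scale = 0, ...)
}

# rotate a Y x X matrix by 90 degrees clockwise and transform (row, col)
# coordinates accordingly: (r, c) -> (c, n_rows + 1 - r)
rot90_mat <- function(m) t(m[nrow(m):1, , drop = FALSE])
rot90_pt <- function(p, n_rows) c(p[2], n_rows + 1 - p[1])
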