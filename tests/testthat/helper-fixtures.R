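# Shared in-code fixtures for the test suite. Everything is generated at
# test time; nothing is read from disk.

# One analytic AP train: instantaneous upstroke to `amp`, then linear
# repolarization to zero over `repol_ms`, repeated every `cl_ms`.
ramp_train <- function(n_beats = 3, cl_ms = 500, repol_ms = 200, amp = 1,
                       frame_rate = 500) {
  dt <- 1000 / frame_rate
  t <- seq(0, n_beats * cl_ms - dt, by = dt)
  tau <- t %% cl_ms
  v <- pmax(0, amp * (1 - tau / repol_ms))
  voltage_trace_set(matrix(v, ncol = 1, dimnames = list(NULL, "s1")), frame_rate)
}

# Square pulse train: amplitude 1 for `width_ms`, zero otherwise.
square_train <- function(n_beats = 3, cl_ms = 500, width_ms = 100,
                         frame_rate = 500) {
  dt <- 1000 / frame_rate
  t <- seq(0, n_beats * cl_ms - dt, by = dt)
  v <- as.numeric((t %% cl_ms) < width_ms)
  voltage_trace_set(matrix(v, ncol = 1, dimnames = list(NULL, "s1")), frame_rate)
}

# Dense matrix with named genes/cells for count fixtures.
named_counts <- function(x) {
  dimnames(x) <- list(sprintf("g%03d", seq_len(nrow(x))),
                      sprintf("c%03d", seq_len(ncol(x))))
  x
}

# Direct evaluation of the spherical-tip Hertz force (SI units) used as an
# oracle against the generator and the fitter.
hertz_oracle_nN <- function(delta_um, E_pa, R_um, nu) {
  4 * sqrt(R_um * 1e-6) / 3 * E_pa / (1 - nu^2) * (delta_um * 1e-6)^1.5 * 1e9
}
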