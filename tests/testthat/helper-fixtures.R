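# Shared fixtures, all built in code.

# simple waveform on a uniform grid
mk_wave <- function(v, site = "ascending_aorta", period = 0.5, ...) {
  velocity_waveform(site, seq(0, period, length.out = length(v)), v, ...)
}

# half-sine pulse of given amplitude over one cycle
half_sine <- function(amp, n = 101, site = "ascending_aorta", period = 0.5) {
  t <- seq(0, period, length.out = n)
  mk_wave(amp * pmax(sin(pi * t / period), 0), site = site, period = period)
}

mk_flow <- function(q, patch = "descending_aorta", period = 0.5) {
  flow_waveform(patch, seq(0, period, length.out = length(q)), q)
}

# flow waveform proportional to a raised-cosine pulse with given peak
pulse_flow <- function(peak, patch = "ascending_aorta", n = 1000,
                       period = 0.5, sf = 0.35) {
  t <- seq(0, period, length.out = n)
  q <- ifelse(t <= sf * period,
              0.5 * (1 - cos(2 * pi * t / (sf * period))), 0)
  flow_waveform(patch, t, peak * q / max(q))
}

# write a sampled-line file: position pressure velocity
write_profile_file <- function(path, position, pressure, velocity) {
  writeLines(sprintf("%.10g %.10g %.10g", position, pressure, velocity), path)
  path
}

# regular n-gon contour of circumradius r
ngon <- function(n, r = 1) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(r * cos(th), r * sin(th))
}

# open cylinder surface mesh along z in [0, L] with radius r(z)
cylinder_mesh <- function(radius_fun, L = 10, n_theta = 96, n_z = 40) {
  z <- seq(0, L, length.out = n_z + 1)
  th <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  tris <- list()
  for (k in seq_len(n_z)) {
    r1 <- radius_fun(z[k]); r2 <- radius_fun(z[k + 1])
    for (j in seq_len(n_theta)) {
      j2 <- j %% n_theta + 1
      a <- c(r1 * cos(th[j]), r1 * sin(th[j]), z[k])
      b <- c(r1 * cos(th[j2]), r1 * sin(th[j2]), z[k])
      cc <- c(r2 * cos(th[j]), r2 * sin(th[j]), z[k + 1])
      d <- c(r2 * cos(th[j2]), r2 * sin(th[j2]), z[k + 1])
      tris[[length(tris) + 1]] <- c(a, b, cc)
      tris[[length(tris) + 1]] <- c(b, d, cc)
    }
  }
  structure(list(triangles = do.call(rbind, tris)), class = "stl_mesh")
}
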