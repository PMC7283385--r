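#' Construct a single-cycle Doppler velocity waveform
#'
#' Represents one cardiac cycle of the digitized Doppler envelope velocity at
#' a named measurement site. Times must be strictly increasing and the
#' envelope magnitude non-negative; the sample span is taken to be exactly one
#' cardiac period.
#'
#' @param site one of `"ascending_aorta"`, `"innominate"`, `"lcca"`,
#'   `"lsca"`, `"coarctation"`, `"descending_aorta"`.
#' @param time numeric vector of sample times in seconds, strictly increasing,
#'   length >= 3.
#' @param velocity numeric vector of envelope velocities in m/s, same length
#'   as `time`, all >= 0.
#' @param heart_rate_bpm optional heart rate from ECG monitoring, beats/min.
#' @param phase `"pre_repair"` or `"post_repair"`.
#' @return an object of class `velocity_waveform`.
#' @examples
#' t <- seq(0, 0.5, length.out = 51)
#' w <- velocity_waveform("ascending_aorta", t, pmax(sin(2 * pi * t), 0))
#' peak_of(w)
#' @export
velocity_waveform <- function(site, time, velocity, heart_rate_bpm = NULL,
                              phase = c("pre_repair", "post_repair")) {
  site <- as_site(site)
  phase <- match.arg(phase)
  time <- as.numeric(time); velocity <- as.numeric(velocity)
  if (length(time) < 3L)
    coa_stop("a waveform needs at least 3 samples", "coaflow_invalid_parameter")
  if (length(time) != length(velocity))
    coa_stop("time and velocity lengths differ", "coaflow_invalid_parameter")
  if (anyNA(time) || anyNA(velocity))
    coa_stop("NA in waveform samples", "coaflow_invalid_parameter")
  if (any(diff(time) <= 0))
    coa_stop("times must be strictly increasing", "coaflow_invalid_parameter")
  if (any(velocity < 0))
    coa_stop("Doppler envelope velocities must be >= 0",
             "coaflow_invalid_parameter")
  if (!is.null(heart_rate_bpm)) {
    heart_rate_bpm <- as.numeric(heart_rate_bpm)
    if (length(heart_rate_bpm) != 1L || !is.finite(heart_rate_bpm) ||
        heart_rate_bpm <= 0)
      coa_stop("heart_rate_bpm must be a positive scalar",
               "coaflow_invalid_parameter")
  }
  structure(list(site = site, time = time, velocity = velocity,
                 heart_rate_bpm = heart_rate_bpm, phase = phase),
            class = "velocity_waveform")
}

#' @export
print.velocity_waveform <- function(x, ...) {
  p <- waveform_period(x)
  cat(sprintf("<velocity_waveform> site=%s phase=%s n=%d period=%.4g s peak=%.4g m/s",
              x$site, x$phase, length(x$time), p, max(x$velocity)))
  if (!is.null(x$heart_rate_bpm))
    cat(sprintf(" HR=%.4g bpm", x$heart_rate_bpm))
  cat("\n")
  invisible(x)
}

#' @export
plot.velocity_waveform <- function(x, ...) {
  plot(x$time, x$velocity, type = "l", xlab = "time [s]",
       ylab = "velocity [m/s]",
       main = sprintf("%s (%s)", x$site, x$phase), ...)
  invisible(x)
}

#' Cardiac period spanned by a waveform
#' @param w a `velocity_waveform` or `flow_waveform`
#' @return period in seconds (last minus first sample time)
#' @export
waveform_period <- function(w) {
  w$time[length(w$time)] - w$time[1L]
}

#' Smooth a velocity waveform with a centered local quadratic fit
#'
#' Each sample is replaced by the value at its own time of an order-2
#' polynomial fitted by least squares over a centered window of `window`
#' samples. Near the ends the window shrinks symmetrically, so the first and
#' last samples are returned unchanged. Fitted values are clamped at zero to
#' respect the Doppler envelope sign.
#'
#' @param w a [velocity_waveform()].
#' @param window odd integer window length in samples, default 7.
#' @return a smoothed `velocity_waveform` on the same time grid.
#' @examples
#' t <- seq(0, 0.5, length.out = 41)
#' w <- velocity_waveform("coarctation", t, pmax(3.49 * sin(2 * pi * t), 0))
#' s <- smooth_waveform(w, window = 5)
#' @export
smooth_waveform <- function(w, window = 7L) {
  stopifnot(inherits(w, "velocity_waveform"))
  n <- length(w$time)
  if (length(window) != 1L || is.na(window) || window != as.integer(window) ||
      window %% 2L == 0L || window < 1L || window > n)
    coa_stop("window must be an odd integer in [1, n_samples]",
             "coaflow_invalid_parameter")
  window <- as.integer(window)
  if (window == 1L) return(w)
  h <- (window - 1L) %/% 2L
  v <- w$velocity
  out <- numeric(n)
  for (i in seq_len(n)) {
    hi <- min(h, i - 1L, n - i)      # symmetric shrink keeps the fit centered
    idx <- (i - hi):(i + hi)
    if (length(idx) < 3L) { out[i] <- v[i]; next }
    tt <- w$time[idx] - w$time[i]
    fit <- lm.fit(cbind(1, tt, tt^2), v[idx])
    out[i] <- fit$coefficients[1L]
  }
  out <- pmax(out, 0)
  velocity_waveform(w$site, w$time, out, w$heart_rate_bpm, w$phase)
}

#' Rescale a waveform to a common cardiac period
#'
#' Linearly rescales the time axis to span `target_period` seconds starting
#' at zero, leaving velocities untouched. The default 0.5 s corresponds to a
#' heart rate of 120 beats per minute, the common reference period to which
#' traces recorded at varying heart rates are normalized before they can be
#' combined.
#'
#' @param w a [velocity_waveform()] (or [flow_waveform()]).
#' @param target_period target cardiac period in seconds, default 0.5.
#' @return a waveform with period exactly `target_period`; for velocity
#'   waveforms `heart_rate_bpm` is updated to `60 / target_period`.
#' @export
normalize_period <- function(w, target_period = 0.5) {
  if (!is.numeric(target_period) || length(target_period) != 1L ||
      target_period <= 0)
    coa_stop("target_period must be a positive scalar",
             "coaflow_invalid_parameter")
  span <- waveform_period(w)
  if (span <= 0)
    coa_stop("waveform has zero-length time span", "coaflow_degenerate_waveform")
  tt <- (w$time - w$time[1L]) * (target_period / span)
  tt[length(tt)] <- target_period   # pin the endpoint against roundoff
  if (inherits(w, "flow_waveform"))
    return(flow_waveform(w$patch, tt, w$flow))
  velocity_waveform(w$site, tt, w$velocity,
                    heart_rate_bpm = 60 / target_period, phase = w$phase)
}

#' Peak value of a waveform
#'
#' Returns the maximum sampled value and its earliest time of occurrence
#' (ties broken to the first sample, matching peak systole being the first
#' systolic event).
#'
#' @param w a [velocity_waveform()] or [flow_waveform()].
#' @return named list with `t_peak` (s) and `v_max` (m/s) for velocity
#'   waveforms, or `t_peak` and `q_max` (m^3/s) for flow waveforms.
#' @export
peak_of <- function(w) UseMethod("peak_of")

#' @export
peak_of.velocity_waveform <- function(w) {
  i <- which.max(w$velocity)      # which.max returns the first maximum
  list(t_peak = w$time[i], v_max = w$velocity[i])
}

#' @export
peak_of.flow_waveform <- function(w) {
  i <- which.max(w$flow)
  list(t_peak = w$time[i], q_max = w$flow[i])
}

#' Resample a waveform onto a uniform time grid
#'
#' Linear interpolation onto `n` equally spaced times spanning the same
#' period; the first and last samples are preserved exactly. Used to place
#' several site waveforms on a common grid before summation.
#'
#' @param w a [velocity_waveform()] or [flow_waveform()].
#' @param n number of samples, >= 3.
#' @return a waveform of the same class with `n` uniform samples.
#' @export
resample_uniform <- function(w, n = 1000L) {
  if (length(n) != 1L || is.na(n) || n < 3L)
    coa_stop("n must be >= 3", "coaflow_invalid_parameter")
  n <- as.integer(n)
  tt <- seq(w$time[1L], w$time[length(w$time)], length.out = n)
  if (inherits(w, "flow_waveform")) {
    q <- approx(w$time, w$flow, xout = tt, rule = 2)$y
    return(flow_waveform(w$patch, tt, q))
  }
  v <- approx(w$time, w$velocity, xout = tt, rule = 2)$y
  velocity_waveform(w$site, tt, v, w$heart_rate_bpm, w$phase)
}

#' Read a digitized Doppler waveform from delimited text
#'
#' Accepts comma- or whitespace-delimited two-column text (`t_s`, `v_ms`)
#' with optional metadata header lines of the form `# key: value` carrying
#' `site`, `phase` and `heart_rate_bpm`. One-cycle extraction from multi-beat
#' recordings is upstream of this reader: the file must already contain a
#' single cycle.
#'
#' @param path file path.
#' @param site,phase,heart_rate_bpm overrides for (or in lieu of) metadata in
#'   the file header.
#' @return a [velocity_waveform()].
#' @export
read_velocity_waveform <- function(path, site = NULL, phase = NULL,
                                   heart_rate_bpm = NULL) {
  if (!file.exists(path))
    coa_stop(sprintf("file not found: %s", path), "coaflow_io_error")
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^\\s*#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    m <- regmatches(ml, regexec("^\\s*#\\s*([A-Za-z_]+)\\s*[:=]\\s*(\\S+)", ml))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- m[3]
  }
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  # drop a non-numeric column-name header if present
  if (length(body) && is.na(suppressWarnings(
        as.numeric(strsplit(trimws(body[1]), "[,[:space:]]+")[[1]][1]))))
    body <- body[-1]
  parts <- strsplit(trimws(body), "[,[:space:]]+")
  if (any(lengths(parts) < 2L))
    coa_stop("each data row needs two columns: t_s, v_ms", "coaflow_io_error")
  tt <- as.numeric(vapply(parts, `[`, "", 1L))
  vv <- as.numeric(vapply(parts, `[`, "", 2L))
  site <- site %||% meta$site
  phase <- phase %||% meta$phase %||% "pre_repair"
  hr <- heart_rate_bpm %||%
    (if (!is.null(meta$heart_rate_bpm)) as.numeric(meta$heart_rate_bpm))
  if (is.null(site))
    coa_stop("site not given and not present in the file header",
             "coaflow_io_error")
  velocity_waveform(site, tt, vv, heart_rate_bpm = hr, phase = phase)
}

#' Write a Doppler waveform as delimited text
#'
#' Inverse of [read_velocity_waveform()]: metadata header lines followed by
#' two comma-separated columns at 6 significant digits, rows in time order.
#'
#' @param w a [velocity_waveform()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_velocity_waveform <- function(w, path) {
  hdr <- c(sprintf("# site: %s", w$site), sprintf("# phase: %s", w$phase))
  if (!is.null(w$heart_rate_bpm))
    hdr <- c(hdr, sprintf("# heart_rate_bpm: %s",
                          format(w$heart_rate_bpm, digits = 6)))
  rows <- sprintf("%s,%s", formatC(w$time, digits = 6, format = "g"),
                  formatC(w$velocity, digits = 6, format = "g"))
  writeLines(c(hdr, "t_s,v_ms", rows), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
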