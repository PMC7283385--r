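# Seeded generator of single-cycle Doppler-envelope waveform sets and toy
# patient datasets so every pipeline stage can be exercised without clinical
# data. The envelope family is a raised-cosine systolic pulse with an
# optional exponential diastolic tail (the clinical marker of continued flow
# through a stenosis during diastole), cyclic phase lag, and additive
# Gaussian sampling noise clamped at zero.

#' Parameters of a synthetic Doppler envelope
#'
#' @param peak_velocity systolic peak velocity in m/s.
#' @param heart_rate_bpm heart rate, default 120 (period 0.5 s).
#' @param systolic_fraction fraction of the cycle in systole, in (0, 1),
#'   default 0.35.
#' @param diastolic_tail_fraction tail amplitude at end systole as a fraction
#'   of the peak, in [0, 1), default 0.
#' @param tail_decay exponential decay time constant of the tail in seconds;
#'   default one cardiac period (a slow, stenosis-like tail).
#' @param phase_lag cyclic shift of the envelope in seconds, default 0.
#' @param noise_sd additive Gaussian noise standard deviation in m/s,
#'   default 0.
#' @param n_samples number of samples over the cycle, default 201.
#' @param seed integer RNG seed for the noise realization.
#' @return an object of class `waveform_params`.
#' @export
waveform_params <- function(peak_velocity, heart_rate_bpm = 120,
                            systolic_fraction = 0.35,
                            diastolic_tail_fraction = 0,
                            tail_decay = NULL, phase_lag = 0, noise_sd = 0,
                            n_samples = 201L, seed = 1L) {
  if (peak_velocity <= 0)
    coa_stop("peak_velocity must be positive", "coaflow_invalid_parameter")
  if (systolic_fraction <= 0 || systolic_fraction >= 1)
    coa_stop("systolic_fraction must lie in (0, 1)",
             "coaflow_invalid_parameter")
  if (diastolic_tail_fraction < 0 || diastolic_tail_fraction >= 1)
    coa_stop("diastolic_tail_fraction must lie in [0, 1)",
             "coaflow_invalid_parameter")
  if (noise_sd < 0)
    coa_stop("noise_sd must be >= 0", "coaflow_invalid_parameter")
  structure(list(peak_velocity = peak_velocity,
                 heart_rate_bpm = heart_rate_bpm,
                 systolic_fraction = systolic_fraction,
                 diastolic_tail_fraction = diastolic_tail_fraction,
                 tail_decay = tail_decay, phase_lag = phase_lag,
                 noise_sd = noise_sd, n_samples = as.integer(n_samples),
                 seed = as.integer(seed)),
            class = "waveform_params")
}

# Closed-form clean envelope at local cycle time tloc in [0, T].
envelope_value <- function(tloc, p, period) {
  t_sys <- p$systolic_fraction * period
  tau <- p$tail_decay %||% period
  v <- ifelse(tloc <= t_sys,
              p$peak_velocity * 0.5 * (1 - cos(2 * pi * tloc / t_sys)),
              p$diastolic_tail_fraction * p$peak_velocity *
                exp(-(tloc - t_sys) / tau))
  v
}

#' Generate a synthetic Doppler velocity waveform
#'
#' Samples the raised-cosine + exponential-tail envelope on a uniform grid
#' over one cardiac period, applies the cyclic phase lag, rescales so the
#' sampled maximum equals `peak_velocity` exactly, then adds the seeded
#' Gaussian noise clamped at zero. Bit-reproducible for a fixed seed.
#'
#' @param p a [waveform_params()].
#' @param site site label for the resulting waveform.
#' @param phase `"pre_repair"` or `"post_repair"`.
#' @return a [velocity_waveform()].
#' @examples
#' w <- gen_waveform(waveform_params(3.49, diastolic_tail_fraction = 0.3),
#'                   site = "coarctation")
#' peak_of(w)$v_max
#' @export
gen_waveform <- function(p, site = "ascending_aorta",
                         phase = c("pre_repair", "post_repair")) {
  stopifnot(inherits(p, "waveform_params"))
  phase <- match.arg(phase)
  period <- 60 / p$heart_rate_bpm
  tt <- seq(0, period, length.out = p$n_samples)
  tloc <- (tt - p$phase_lag) %% period
  tloc[tloc == 0 & tt >= period] <- period   # right limit at the cycle end
  v <- envelope_value(tloc, p, period)
  v <- v * (p$peak_velocity / max(v))   # sampled max is the peak exactly
  if (p$noise_sd > 0) {
    v <- v + with_seed(p$seed, rnorm(length(v), 0, p$noise_sd))
    v <- pmax(v, 0)
  }
  velocity_waveform(site, tt, v, heart_rate_bpm = p$heart_rate_bpm,
                    phase = phase)
}

# Evaluate expr under a fixed RNG state, restoring the caller's state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

# Reference Doppler magnitudes: peak velocities (m/s) and measured diameters
# (mm) per site for the pre-repair (full) and post-repair (partial) studies.
SYNTH_REFERENCE <- list(
  pre = list(
    velocity = c(ascending_aorta = 1.3, innominate = 1.11, lcca = 0.81,
                 lsca = 0.70, coarctation = 3.49, descending_aorta = 0.63),
    diameter = c(ascending_aorta = 13.00, innominate = 8.15, lcca = 4.30,
                 lsca = 5.00, coarctation = 6.00, descending_aorta = 8.29),
    tail = c(ascending_aorta = 0, innominate = 0.05, lcca = 0.05,
             lsca = 0.05, coarctation = 0.30, descending_aorta = 0.10),
    lag = c(ascending_aorta = 0, innominate = 0.015, lcca = 0.02,
            lsca = 0.02, coarctation = 0.01, descending_aorta = 0.03)),
  post = list(
    velocity = c(ascending_aorta = 1.3, innominate = 0.84,
                 coarctation = 2.38),
    diameter = c(ascending_aorta = 11.21, innominate = 6.98,
                 coarctation = 6.00),
    tail = c(ascending_aorta = 0, innominate = 0.05, coarctation = 0.10),
    lag = c(ascending_aorta = 0, innominate = 0, coarctation = 0.01)))

#' Generate a synthetic patient dataset with known ground truth
#'
#' Builds a per-site waveform set emulating a Doppler measurement campaign,
#' calibrated so that the flow-split pipeline recovers the stored
#' ground-truth factors exactly in the noise-free case:
#' \itemize{
#'   \item `"full_data"` (pre-repair): all six sites; outlet envelopes are
#'     scaled so that [conserve_mass_scale()] recovers
#'     `factors$outlet_scale`.
#'   \item `"partial_post_repair"`: only the ascending aorta, innominate and
#'     coarctation are measured; the innominate amplitude is calibrated so
#'     that [derive_case2_outlets()] solves the descending scaling to
#'     `factors$descending_inlet_scale`.
#'   \item `"hypothetical_healthy"`: only the ascending-aorta waveform (the
#'     healthy split needs no outlet data) plus branch diameters;
#'     `factors$descending_fraction` is the ground truth.
#' }
#' Noise, when requested, is added after calibration, so recovery from noisy
#' data is approximate.
#'
#' @param scenario one of `"full_data"`, `"partial_post_repair"`,
#'   `"hypothetical_healthy"`.
#' @param seed integer seed; distinct seeds give distinct noise realizations.
#' @param noise_sd Gaussian noise standard deviation in m/s, default 0.
#' @param factors ground-truth [split_factors()]; defaults to the reference
#'   split (outlet scale 0.8243, descending inlet scale 0.5101, descending
#'   fraction 0.70, branch ratios 1.09/3.72 for both carotid and subclavian).
#' @param n_samples samples per waveform, default 201.
#' @param heart_rate_bpm generator heart rate, default 120.
#' @return an object of class `synthetic_patient`: waveforms (named list),
#'   diameters (mm), ground-truth `factors`, scenario, seed, noise_sd.
#' @export
gen_patient <- function(scenario = c("full_data", "partial_post_repair",
                                     "hypothetical_healthy"),
                        seed = 1L, noise_sd = 0,
                        factors = split_factors(
                          outlet_scale = 0.8243,
                          descending_inlet_scale = 0.5101,
                          descending_fraction = 0.70,
                          branch_ratios = c(lcca = 1.09 / 3.72,
                                            lsca = 1.09 / 3.72)),
                        n_samples = 201L, heart_rate_bpm = 120) {
  scenario <- match.arg(scenario)
  ref <- if (scenario == "full_data") SYNTH_REFERENCE$pre else
    SYNTH_REFERENCE$post
  phase <- if (scenario == "full_data") "pre_repair" else "post_repair"
  sites <- if (scenario == "hypothetical_healthy") "ascending_aorta" else
    names(ref$velocity)

  params <- function(site, amp, noise = 0, idx)
    waveform_params(amp, heart_rate_bpm, systolic_fraction = 0.35,
                    diastolic_tail_fraction = ref$tail[[site]],
                    phase_lag = if (scenario == "partial_post_repair") 0 else
                      ref$lag[[site]],
                    noise_sd = noise, n_samples = n_samples,
                    seed = seed * 101L + idx)

  amps <- ref$velocity[sites]

  if (scenario == "full_data") {
    # Calibrate outlet amplitudes so the uniform mass-conservation scaling
    # of the clean flows is exactly the ground-truth outlet_scale.
    clean <- lapply(seq_along(sites), function(i)
      gen_waveform(params(sites[i], amps[[i]], 0, i), sites[i], phase))
    names(clean) <- sites
    inlet_q <- velocity_to_flow(clean$ascending_aorta,
                                circular_area(ref$diameter[["ascending_aorta"]]),
                                "parabolic_half_max")
    out_q <- lapply(OUTLET_SITES, function(s)
      velocity_to_flow(clean[[s]], circular_area(ref$diameter[[s]]),
                       "max_equals_avg"))
    c0 <- conserve_mass_scale(inlet_q, out_q)$factor
    adj <- c0 / factors$outlet_scale
    amps[OUTLET_SITES] <- amps[OUTLET_SITES] * adj
    gt_ratios <- branch_ratios_from(lapply(OUTLET_SITES, function(s)
      scale_flow(velocity_to_flow(clean[[s]],
                                  circular_area(ref$diameter[[s]])), adj)))
    gt <- split_factors(outlet_scale = factors$outlet_scale,
                        descending_inlet_scale =
                          factors$descending_inlet_scale,
                        descending_fraction = factors$descending_fraction,
                        branch_ratios = gt_ratios)
  } else if (scenario == "partial_post_repair") {
    # Calibrate the innominate amplitude so the solved descending scaling is
    # exactly the ground truth: with aligned, same-shape envelopes,
    # peak(branches) must equal (1 - s) * peak(inlet flow).
    s0 <- factors$descending_inlet_scale
    if (is.null(s0))
      coa_stop("factors must carry descending_inlet_scale",
               "coaflow_configuration_error")
    br <- factors$branch_ratios
    p_in <- 0.5 * circular_area(ref$diameter[["ascending_aorta"]]) *
      amps[["ascending_aorta"]]
    amps[["innominate"]] <-
      (1 - s0) * p_in /
      (factors$outlet_scale *
         circular_area(ref$diameter[["innominate"]]) *
         (1 + br[["lcca"]] + br[["lsca"]]))
    gt <- factors
  } else {
    gt <- factors
  }

  waveforms <- lapply(seq_along(sites), function(i)
    gen_waveform(params(sites[i], amps[[i]], noise_sd, i), sites[i], phase))
  names(waveforms) <- sites
  diameters <- if (scenario == "hypothetical_healthy")
    SYNTH_REFERENCE$pre$diameter else ref$diameter
  structure(list(scenario = scenario, seed = as.integer(seed),
                 noise_sd = noise_sd, waveforms = waveforms,
                 diameters = diameters, factors = gt),
            class = "synthetic_patient")
}

#' @export
print.synthetic_patient <- function(x, ...) {
  cat(sprintf("<synthetic_patient> scenario=%s seed=%d noise_sd=%g sites=%s\n",
              x$scenario, x$seed, x$noise_sd,
              paste(names(x$waveforms), collapse = ", ")))
  invisible(x)
}

#' Write a synthetic patient to disk
#'
#' One waveform text file per site (format of [write_velocity_waveform()])
#' plus a YAML manifest recording diameters, the ground-truth split factors,
#' scenario and seed for test harnesses.
#'
#' @param patient a [gen_patient()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_patient <- function(patient, dir) {
  stopifnot(inherits(patient, "synthetic_patient"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  for (s in names(patient$waveforms)) {
    f <- file.path(dir, paste0(s, ".csv"))
    write_velocity_waveform(patient$waveforms[[s]], f)
    files[[s]] <- basename(f)
  }
  manifest <- list(scenario = patient$scenario, seed = patient$seed,
                   noise_sd = patient$noise_sd,
                   diameters_mm = as.list(patient$diameters),
                   factors = Filter(Negate(is.null),
                                    lapply(unclass(patient$factors), function(v)
                                      if (is.null(names(v))) v else as.list(v))),
                   waveform_files = files)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
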