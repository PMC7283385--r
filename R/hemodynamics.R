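# Scalar hemodynamic formulas: simplified Bernoulli, velocity-to-flow
# conversion, pressure unit handling. SI units internally; mmHg only at
# presentation boundaries.

# Pa -> mmHg, pinned at 6 s.f. for bit-stable output.
PA_TO_MMHG <- 0.00750062

#' Blood fluid properties
#'
#' Defaults are the standard values for blood treated as an incompressible
#' Newtonian fluid: kinematic viscosity 3.78e-6 m^2/s and density
#' 1060 kg/m^3.
#'
#' @param kinematic_viscosity kinematic viscosity in m^2/s.
#' @param density density in kg/m^3.
#' @return an object of class `fluid_properties`.
#' @export
fluid_properties <- function(kinematic_viscosity = 3.78e-6, density = 1060) {
  if (!is.numeric(kinematic_viscosity) || kinematic_viscosity <= 0 ||
      !is.numeric(density) || density <= 0)
    coa_stop("fluid properties must be strictly positive",
             "coaflow_invalid_parameter")
  structure(list(kinematic_viscosity = kinematic_viscosity, density = density),
            class = "fluid_properties")
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat(sprintf("<fluid_properties> nu=%g m^2/s rho=%g kg/m^3\n",
              x$kinematic_viscosity, x$density))
  invisible(x)
}

#' Simplified-Bernoulli pressure difference
#'
#' The clinical simplified Bernoulli relation `dP = 4 v^2` converts a peak
#' Doppler velocity (m/s) directly into a pressure difference in mmHg,
#' neglecting frictional losses and the proximal velocity; the factor 4
#' absorbs the blood density and the Pa-to-mmHg conversion (the exact
#' coefficient is `0.5 * 1060 * 0.00750062 = 3.9753`, which clinical use
#' rounds to 4).
#'
#' @param v_max peak velocity in m/s, >= 0 (vectorized).
#' @return pressure difference in mmHg.
#' @examples
#' bernoulli_pressure_mmHg(3.49)  # a severe coarctation jet
#' @export
bernoulli_pressure_mmHg <- function(v_max) {
  if (!is.numeric(v_max) || any(is.na(v_max)) || any(v_max < 0))
    coa_stop("v_max must be non-negative", "coaflow_invalid_parameter")
  4 * v_max^2
}

#' Area of a circular cross section from its diameter in mm
#'
#' Echo-measured vessel diameters assume a circular cross section; this
#' converts a diameter in millimetres to an area in square metres.
#'
#' @param d diameter in mm, > 0 (vectorized).
#' @return area in m^2.
#' @export
circular_area <- function(d) {
  if (!is.numeric(d) || any(is.na(d)) || any(d <= 0))
    coa_stop("diameter must be positive", "coaflow_invalid_parameter")
  pi * (d / 2000)^2
}

#' Convert kinematic pressure to mmHg
#'
#' Incompressible-flow solvers report kinematic pressure p/rho (m^2/s^2);
#' multiplying by the density and the Pa-to-mmHg factor 0.00750062 gives
#' clinical units.
#'
#' @param p_kin kinematic pressure in m^2/s^2 (vectorized).
#' @param fluid a [fluid_properties()].
#' @return pressure in mmHg.
#' @export
kinematic_pressure_to_mmHg <- function(p_kin, fluid = fluid_properties()) {
  stopifnot(inherits(fluid, "fluid_properties"))
  p_kin * fluid$density * PA_TO_MMHG
}

#' Construct a volumetric flow waveform
#'
#' One cardiac cycle of volumetric flow rate at a named boundary patch.
#'
#' @param patch site label of the boundary patch.
#' @param time numeric sample times in s, strictly increasing, length >= 3.
#' @param flow volumetric flow rate in m^3/s, >= 0.
#' @return an object of class `flow_waveform`.
#' @export
flow_waveform <- function(patch, time, flow) {
  patch <- as_site(patch)
  time <- as.numeric(time); flow <- as.numeric(flow)
  if (length(time) < 3L || length(time) != length(flow))
    coa_stop("need >= 3 (t, Q) samples of equal length",
             "coaflow_invalid_parameter")
  if (anyNA(time) || anyNA(flow))
    coa_stop("NA in flow samples", "coaflow_invalid_parameter")
  if (any(diff(time) <= 0))
    coa_stop("times must be strictly increasing", "coaflow_invalid_parameter")
  if (any(flow < 0))
    coa_stop("flow rates must be >= 0", "coaflow_invalid_parameter")
  structure(list(patch = patch, time = time, flow = flow),
            class = "flow_waveform")
}

#' @export
print.flow_waveform <- function(x, ...) {
  cat(sprintf("<flow_waveform> patch=%s n=%d period=%.4g s peak=%.4g m^3/s\n",
              x$patch, length(x$time), waveform_period(x), max(x$flow)))
  invisible(x)
}

#' @export
plot.flow_waveform <- function(x, ...) {
  plot(x$time, x$flow * 1e5, type = "l", xlab = "time [s]",
       ylab = "Q [1e-5 m^3/s]", main = x$patch, ...)
  invisible(x)
}

#' Convert a velocity waveform to a volumetric flow waveform
#'
#' `Q(t) = A_patch * v_ave(t)`. Doppler envelopes record the maximum velocity
#' in the beam; at outlet patches the average is taken equal to that maximum
#' (`profile = "max_equals_avg"`), while at the inlet the average velocity is
#' taken as half the maximum as for a parabolic profile
#' (`profile = "parabolic_half_max"`).
#'
#' @param w a [velocity_waveform()].
#' @param area patch area in m^2, > 0.
#' @param profile velocity-profile assumption, see Details.
#' @return a [flow_waveform()] on the same time grid.
#' @export
velocity_to_flow <- function(w, area,
                             profile = c("max_equals_avg",
                                         "parabolic_half_max")) {
  stopifnot(inherits(w, "velocity_waveform"))
  profile <- match.arg(profile)
  if (!is.numeric(area) || length(area) != 1L || is.na(area) || area <= 0)
    coa_stop("area must be a positive scalar", "coaflow_invalid_parameter")
  fac <- if (profile == "parabolic_half_max") 0.5 else 1
  flow_waveform(w$site, w$time, area * fac * w$velocity)
}
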