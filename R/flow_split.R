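# Mass-consistent outlet flow derivation under the three data regimes:
# case 1 (full pre-repair dataset), case 2 (partial post-repair dataset),
# case 3 (hypothetical healthy state).

CASE_MODES <- c("full_data", "partial_post_repair", "hypothetical_healthy")

#' Flow-split factors
#'
#' Bundle of the dimensionless factors governing the outlet flow splits:
#' the uniform outlet scaling applied when a full outlet dataset violates
#' mass conservation (`outlet_scale`), the scaling of the inlet waveform
#' reused at the descending aorta when distal data are missing
#' (`descending_inlet_scale`), the descending-aorta flow fraction of the
#' hypothetical healthy split (`descending_fraction`, default 0.70), and the
#' outlet-to-innominate peak-flow ratios (`branch_ratios`).
#'
#' @param outlet_scale uniform outlet scaling, in (0, 2].
#' @param descending_inlet_scale descending-aorta inlet-waveform scaling, in
#'   (0, 2], or `NULL` when not yet solved.
#' @param descending_fraction healthy-case descending flow fraction, in (0, 1).
#' @param branch_ratios named numeric, peak-flow ratios relative to the
#'   innominate for `lcca` and `lsca`.
#' @return an object of class `split_factors`.
#' @export
split_factors <- function(outlet_scale = NULL, descending_inlet_scale = NULL,
                          descending_fraction = 0.70, branch_ratios = NULL) {
  chk <- function(x, nm) {
    if (!is.null(x) && (!is.numeric(x) || any(is.na(x)) || any(x <= 0) ||
                        any(x > 2)))
      coa_stop(sprintf("%s must lie in (0, 2]", nm),
               "coaflow_invalid_parameter")
  }
  chk(outlet_scale, "outlet_scale")
  chk(descending_inlet_scale, "descending_inlet_scale")
  chk(branch_ratios, "branch_ratios")
  if (!is.numeric(descending_fraction) || length(descending_fraction) != 1L ||
      is.na(descending_fraction) ||
      descending_fraction <= 0 || descending_fraction >= 1)
    coa_stop("descending_fraction must lie strictly in (0, 1)",
             "coaflow_invalid_parameter")
  structure(list(outlet_scale = outlet_scale,
                 descending_inlet_scale = descending_inlet_scale,
                 descending_fraction = descending_fraction,
                 branch_ratios = branch_ratios),
            class = "split_factors")
}

#' @export
print.split_factors <- function(x, ...) {
  fmt <- function(v) if (is.null(v)) "-" else paste(format(v, digits = 6),
                                                    collapse = ", ")
  cat("<split_factors>\n",
      sprintf("  outlet_scale:           %s\n", fmt(x$outlet_scale)),
      sprintf("  descending_inlet_scale: %s\n", fmt(x$descending_inlet_scale)),
      sprintf("  descending_fraction:    %s\n", fmt(x$descending_fraction)),
      sprintf("  branch_ratios:          %s\n",
              if (is.null(x$branch_ratios)) "-" else
                paste(names(x$branch_ratios),
                      format(x$branch_ratios, digits = 6),
                      sep = "=", collapse = ", ")), sep = "")
  invisible(x)
}

scale_flow <- function(w, factor) {
  flow_waveform(w$patch, w$time, w$flow * factor)
}

# Cyclic time shift of a flow waveform by dt seconds (periodic linear
# interpolation back onto the original grid).
shift_cyclic <- function(w, dt) {
  period <- waveform_period(w)
  tloc <- (w$time - w$time[1L] - dt) %% period
  # two periods of support so interpolation never extrapolates at the seam
  tt <- c(w$time - w$time[1L], w$time[-1L] - w$time[1L] + period)
  qq <- c(w$flow, w$flow[-1L])
  flow_waveform(w$patch, w$time, approx(tt, qq, xout = tloc, rule = 2)$y)
}

# Pointwise sum of flow waveforms on a common uniform grid spanning the
# shared period. All waveforms must share the same period (to 1e-6 relative).
sum_flows <- function(flows, n_grid = 1000L) {
  periods <- vapply(flows, waveform_period, 0)
  if (max(periods) - min(periods) > 1e-6 * max(periods))
    coa_stop("flow waveforms must be normalized to a common period",
             "coaflow_invalid_parameter")
  t0 <- flows[[1L]]$time[1L]
  tt <- seq(t0, t0 + periods[1L], length.out = n_grid)
  q <- rowSums(vapply(flows, function(w)
    approx(w$time, w$flow, xout = tt, rule = 2)$y, numeric(n_grid)))
  flow_waveform(flows[[1L]]$patch, tt, pmax(q, 0))
}

#' Uniformly scale outlet flows to restore mass conservation
#'
#' Doppler-derived outlet flow waveforms generally violate mass conservation
#' against the inlet. Under a rigid-wall assumption they are scaled uniformly
#' by the factor that makes the peak of the summed outlet flows match the
#' peak inlet flow.
#'
#' @param inlet inlet [flow_waveform()].
#' @param outlets list of outlet [flow_waveform()]s (>= 1), all on the same
#'   cardiac period as the inlet.
#' @param n_grid number of points of the common summation grid, default 1000;
#'   the inlet and summed-outlet peaks are both read off this grid.
#' @param align_phases if `TRUE`, first shift every outlet waveform except
#'   the descending aorta cyclically so its peak coincides with the inlet
#'   peak. An alternative adjustment strategy kept for comparison studies;
#'   off by default because uniform amplitude scaling preserves the measured
#'   phase relationships.
#' @return list with `outlets` (scaled waveforms) and `factor`.
#' @export
conserve_mass_scale <- function(inlet, outlets, n_grid = 1000L,
                                align_phases = FALSE) {
  stopifnot(inherits(inlet, "flow_waveform"))
  if (!length(outlets))
    coa_stop("need at least one outlet", "coaflow_configuration_error")
  if (isTRUE(align_phases)) {
    t_in <- inlet$time[which.max(inlet$flow)]
    outlets <- lapply(outlets, function(w) {
      if (w$patch == "descending_aorta") return(w)
      shift_cyclic(w, t_in - w$time[which.max(w$flow)])
    })
  }
  periods <- vapply(c(list(inlet), outlets), waveform_period, 0)
  if (max(periods) - min(periods) > 1e-6 * max(periods))
    coa_stop("inlet and outlets must share a common period",
             "coaflow_invalid_parameter")
  # both peaks evaluated on the same common grid so the scaled identity is
  # exact regardless of where the native samples fall
  peak_sum <- max(sum_flows(outlets, n_grid)$flow)
  if (peak_sum <= 0)
    coa_stop("summed outlet flow has zero peak", "coaflow_degenerate_input")
  factor <- max(resample_uniform(inlet, n_grid)$flow) / peak_sum
  list(outlets = lapply(outlets, scale_flow, factor = factor),
       factor = factor)
}

#' Outlet-to-innominate peak flow ratios
#'
#' Ratio of each supra-aortic branch's peak flow to the innominate peak flow,
#' used to impute missing branch flows in partial datasets.
#'
#' @param outlets list of [flow_waveform()]s including the innominate and the
#'   `lcca`/`lsca` branches.
#' @return named numeric vector of ratios for `lcca` and `lsca`.
#' @export
branch_ratios_from <- function(outlets) {
  patches <- vapply(outlets, `[[`, "", "patch")
  names(outlets) <- patches
  if (!"innominate" %in% patches)
    coa_stop("innominate waveform missing", "coaflow_configuration_error")
  p_inn <- max(outlets[["innominate"]]$flow)
  if (p_inn <= 0)
    coa_stop("innominate peak flow is zero", "coaflow_degenerate_input")
  targets <- intersect(c("lcca", "lsca"), patches)
  if (!length(targets))
    coa_stop("no lcca/lsca waveforms to ratio", "coaflow_configuration_error")
  setNames(vapply(targets, function(p) max(outlets[[p]]$flow) / p_inn, 0),
           targets)
}

#' Derive outlet flows for a partial post-repair dataset
#'
#' When only the inlet and innominate flows are measured post-repair, the
#' full outlet set is imputed: the innominate flow inherits the pre-repair
#' uniform outlet scaling; LCCA and LSCA are synthesized from the pre-repair
#' branch-to-innominate peak ratios; and the descending aorta reuses the
#' inlet waveform shape (there being little diastolic flow through the
#' repaired stenosis) scaled by a factor `s` solved so that the peak of the
#' summed outlets equals the peak inlet flow.
#'
#' @param case1_factors a [split_factors()] carrying `outlet_scale` and
#'   `branch_ratios` for `lcca` and `lsca` from the full pre-repair dataset.
#' @param inlet2 post-repair inlet [flow_waveform()].
#' @param innominate2 post-repair innominate [flow_waveform()].
#' @param descending_scale optional externally fixed `s`; when `NULL`
#'   (default) `s` is solved by bisection on (0, 2] to tolerance 1e-10.
#' @param n_grid summation grid size, default 1000.
#' @return list with `outlets` (innominate, lcca, lsca, descending_aorta) and
#'   `factors` (a [split_factors()] with `descending_inlet_scale = s`).
#' @export
derive_case2_outlets <- function(case1_factors, inlet2, innominate2,
                                 descending_scale = NULL, n_grid = 1000L) {
  stopifnot(inherits(case1_factors, "split_factors"),
            inherits(inlet2, "flow_waveform"),
            inherits(innominate2, "flow_waveform"))
  if (is.null(case1_factors$outlet_scale))
    coa_stop("case1_factors must carry outlet_scale",
             "coaflow_configuration_error")
  br <- case1_factors$branch_ratios
  if (is.null(br) || !all(c("lcca", "lsca") %in% names(br)))
    coa_stop("case1_factors must carry branch_ratios for lcca and lsca",
             "coaflow_configuration_error")
  inn <- scale_flow(innominate2, case1_factors$outlet_scale)
  lcca <- flow_waveform("lcca", inn$time, inn$flow * br[["lcca"]])
  lsca <- flow_waveform("lsca", inn$time, inn$flow * br[["lsca"]])

  peak_inlet <- max(resample_uniform(inlet2, n_grid)$flow)
  peak_with <- function(s) {
    dao <- flow_waveform("descending_aorta", inlet2$time, inlet2$flow * s)
    max(sum_flows(list(inn, lcca, lsca, dao), n_grid)$flow) - peak_inlet
  }
  if (is.null(descending_scale)) {
    lo <- 1e-12; hi <- 2
    f_lo <- peak_with(lo); f_hi <- peak_with(hi)
    if (f_lo > 0 || f_hi < 0)
      coa_stop("no descending scaling in (0, 2] balances the peak flows",
               "coaflow_degenerate_input")
    # peak of (branches + s * inlet) is continuous and nondecreasing in s
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (peak_with(mid) > 0) hi <- mid else lo <- mid
      if (hi - lo < 1e-10) break
    }
    s <- (lo + hi) / 2
  } else {
    s <- descending_scale
    if (!is.numeric(s) || length(s) != 1L || s <= 0 || s > 2)
      coa_stop("descending_scale must lie in (0, 2]",
               "coaflow_invalid_parameter")
  }
  dao <- flow_waveform("descending_aorta", inlet2$time, inlet2$flow * s)
  factors <- split_factors(outlet_scale = case1_factors$outlet_scale,
                           descending_inlet_scale = s,
                           descending_fraction =
                             case1_factors$descending_fraction,
                           branch_ratios = br)
  list(outlets = list(inn, lcca, lsca, dao), factors = factors)
}

#' Derive outlet flows for the hypothetical healthy state
#'
#' With no measured data, a fixed fraction of the inlet flow (default 70%,
#' the healthy-aorta value) is routed through the descending aorta and the
#' remainder is divided among the supra-aortic branches in proportion to
#' their patch areas. The split conserves mass pointwise by construction.
#'
#' @param inlet inlet [flow_waveform()].
#' @param patch_areas named numeric of branch patch areas (m^2) covering
#'   `innominate`, `lcca`, `lsca`; only their ratios matter.
#' @param fraction descending-aorta flow fraction, in (0, 1), default 0.70.
#' @return list of outlet [flow_waveform()]s (innominate, lcca, lsca,
#'   descending_aorta).
#' @export
derive_case3_outlets <- function(inlet, patch_areas, fraction = 0.70) {
  stopifnot(inherits(inlet, "flow_waveform"))
  if (!all(BRANCH_SITES %in% names(patch_areas)))
    coa_stop("patch_areas must name innominate, lcca and lsca",
             "coaflow_configuration_error")
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction <= 0 || fraction >= 1)
    coa_stop("fraction must lie strictly in (0, 1)",
             "coaflow_invalid_parameter")
  a <- as.numeric(patch_areas[BRANCH_SITES])
  if (any(is.na(a)) || any(a <= 0))
    coa_stop("patch areas must be positive", "coaflow_invalid_parameter")
  share <- (1 - fraction) * a / sum(a)
  out <- lapply(seq_along(BRANCH_SITES), function(i)
    flow_waveform(BRANCH_SITES[i], inlet$time, inlet$flow * share[i]))
  c(out, list(flow_waveform("descending_aorta", inlet$time,
                            inlet$flow * fraction)))
}

#' Extract steady peak-systolic boundary conditions
#'
#' Steady-state boundary values are taken at peak systole: the first time at
#' which the inlet flow is maximal. Each outlet's steady flow is its value at
#' that instant (linear interpolation); the inlet boundary value is set to
#' the sum of the outlet values so that the specification conserves mass
#' exactly.
#'
#' @param inlet inlet [flow_waveform()].
#' @param outlets list of outlet [flow_waveform()]s on the same period.
#' @param fluid a [fluid_properties()].
#' @return a [boundary_spec()].
#' @export
extract_steady_bcs <- function(inlet, outlets, fluid = fluid_properties()) {
  stopifnot(inherits(inlet, "flow_waveform"))
  if (!length(outlets))
    coa_stop("need at least one outlet", "coaflow_configuration_error")
  t_star <- inlet$time[which.max(inlet$flow)]
  vals <- vapply(outlets, function(w)
    approx(w$time, w$flow, xout = t_star, rule = 2)$y, 0)
  names(vals) <- vapply(outlets, `[[`, "", "patch")
  boundary_spec(outlet_flows = vals, fluid = fluid)
}

#' Steady boundary-condition specification
#'
#' Per-patch steady peak-systolic volumetric flow rates plus fluid
#' properties. The inlet value is defined as the sum of the outlet values
#' (the mass-conservation contract) and the constructor enforces it to 1e-9
#' relative if supplied explicitly.
#'
#' @param outlet_flows named numeric of outlet flow rates in m^3/s (names are
#'   site labels).
#' @param inlet_flow optional inlet flow; defaults to `sum(outlet_flows)`.
#' @param fluid a [fluid_properties()].
#' @return an object of class `boundary_spec`.
#' @export
boundary_spec <- function(outlet_flows, inlet_flow = NULL,
                          fluid = fluid_properties()) {
  if (!length(outlet_flows) || is.null(names(outlet_flows)) ||
      any(!nzchar(names(outlet_flows))))
    coa_stop("outlet_flows must be a named numeric vector",
             "coaflow_configuration_error")
  for (nm in names(outlet_flows)) as_site(nm)
  if (any(outlet_flows < 0))
    coa_stop("outlet flows must be >= 0", "coaflow_invalid_parameter")
  s <- sum(outlet_flows)
  if (is.null(inlet_flow)) inlet_flow <- s
  if (!is_rel_equal(inlet_flow, s))
    coa_stop("inlet flow must equal the sum of outlet flows (1e-9 relative)",
             "coaflow_conservation_error")
  stopifnot(inherits(fluid, "fluid_properties"))
  structure(list(outlet_flows = outlet_flows, inlet_flow = inlet_flow,
                 fluid = fluid),
            class = "boundary_spec")
}

#' @export
print.boundary_spec <- function(x, ...) {
  cat("<boundary_spec> steady peak-systolic volumetric flow rates\n")
  df <- data.frame(patch = c("inlet", names(x$outlet_flows)),
                   `Q_1e5_m3s` = round(c(x$inlet_flow, x$outlet_flows) * 1e5,
                                       4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Serialize a flow-split result to a report file
#'
#' Writes the per-patch steady flows (in 1e-5 m^3/s for readability, SI in
#' machine fields) and the derived split factors as YAML or JSON.
#'
#' @param spec a [boundary_spec()].
#' @param factors optional [split_factors()].
#' @param path output path; format chosen by extension (`.json` or
#'   `.yaml`/`.yml`).
#' @return `path`, invisibly.
#' @export
write_flow_report <- function(spec, factors = NULL, path) {
  stopifnot(inherits(spec, "boundary_spec"))
  rep <- list(
    units = "1e-5 m^3/s (display), m^3/s (si)",
    inlet = list(display = round(spec$inlet_flow * 1e5, 4),
                 si = spec$inlet_flow),
    outlets = lapply(as.list(spec$outlet_flows), function(q)
      list(display = round(q * 1e5, 4), si = q)),
    fluid = list(kinematic_viscosity = spec$fluid$kinematic_viscosity,
                 density = spec$fluid$density))
  if (!is.null(factors))
    rep$factors <- Filter(Negate(is.null), unclass(factors))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(rep, path)
  }
  invisible(path)
}
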