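# End-to-end orchestration: echo processing -> flow waveforms -> boundary
# spec -> OpenFOAM case, plus the grid-check runner. These functions back the
# exec/coaflow command-line entry point but are equally usable interactively.

#' Process a set of digitized Doppler waveforms
#'
#' Smooths each site waveform (centered local quadratic), normalizes all of
#' them to a common cardiac period, converts to volumetric flow waveforms
#' using the measured diameters (parabolic-profile assumption at the inlet,
#' max-equals-average at the outlets), and tabulates peak velocity and
#' simplified-Bernoulli pressure per site.
#'
#' @param waveforms named list of [velocity_waveform()]s, or a named
#'   character vector of file paths readable by [read_velocity_waveform()];
#'   names are site labels.
#' @param diameters_mm named numeric of measured vessel diameters in mm
#'   (sites without a diameter get no flow waveform).
#' @param window smoothing window (odd sample count), default 7.
#' @param target_period common cardiac period in s, default 0.5.
#' @return list with `waveforms` (processed), `flows` (named list of
#'   [flow_waveform()]s) and `report` (data frame: site, v_max_ms, t_peak_s,
#'   dp_mmHg, diameter_mm).
#' @export
process_echo <- function(waveforms, diameters_mm = NULL, window = 7L,
                         target_period = 0.5) {
  if (is.character(waveforms)) {
    paths <- waveforms
    waveforms <- lapply(seq_along(paths), function(i)
      read_velocity_waveform(paths[i], site = names(paths)[i]))
    names(waveforms) <- vapply(waveforms, `[[`, "", "site")
  }
  if (is.null(names(waveforms)))
    names(waveforms) <- vapply(waveforms, `[[`, "", "site")
  processed <- lapply(waveforms, function(w)
    normalize_period(smooth_waveform(w, window), target_period))
  peaks <- lapply(processed, peak_of)
  report <- data.frame(
    site = names(processed),
    v_max_ms = vapply(peaks, `[[`, 0, "v_max"),
    t_peak_s = vapply(peaks, `[[`, 0, "t_peak"),
    dp_mmHg = bernoulli_pressure_mmHg(vapply(peaks, `[[`, 0, "v_max")),
    diameter_mm = if (is.null(diameters_mm)) NA_real_ else
      as.numeric(diameters_mm[names(processed)]),
    row.names = NULL)
  flows <- list()
  for (s in names(processed)) {
    d <- if (s %in% names(diameters_mm)) diameters_mm[[s]] else NA_real_
    if (is.na(d) || s == "coarctation") next   # coarctation is not a patch
    prof <- if (s == "ascending_aorta") "parabolic_half_max" else
      "max_equals_avg"
    flows[[s]] <- velocity_to_flow(processed[[s]], circular_area(d), prof)
  }
  list(waveforms = processed, flows = flows, report = report)
}

#' Build steady boundary conditions and an OpenFOAM case for one regime
#'
#' Applies the flow-split regime matching the available data:
#' \describe{
#'   \item{`full_data`}{all outlet flows measured; they are scaled uniformly
#'     to conserve mass ([conserve_mass_scale()]) and the branch ratios are
#'     recorded for later imputation.}
#'   \item{`partial_post_repair`}{only inlet and innominate measured; LCCA,
#'     LSCA and the descending aorta are imputed from the full-data factors
#'     ([derive_case2_outlets()]).}
#'   \item{`hypothetical_healthy`}{no outlet data; a fixed fraction (default
#'     0.70) of the inlet flow leaves through the descending aorta and the
#'     rest splits by branch area ([derive_case3_outlets()]).}
#' }
#' Steady values are extracted at peak systole and, when `dir` is given, an
#' OpenFOAM case skeleton plus a flow report and machine-readable manifest
#' are written.
#'
#' @param processed result of [process_echo()] (needs `flows` for the sites
#'   the regime requires).
#' @param mode one of `"full_data"`, `"partial_post_repair"`,
#'   `"hypothetical_healthy"`.
#' @param case1_factors [split_factors()] from a full-data run (required for
#'   `partial_post_repair`).
#' @param patch_areas named numeric of branch patch areas in m^2 for the
#'   healthy split; defaults to circular areas from `diameters_mm`.
#' @param diameters_mm named numeric of diameters in mm (fallback source of
#'   `patch_areas`).
#' @param fraction healthy-case descending flow fraction, default 0.70.
#' @param fluid a [fluid_properties()].
#' @param dir optional output directory for the OpenFOAM case and reports.
#' @param patch_names site-to-patch mapping for case writing.
#' @param zero_pressure_outlets write the grid-study pressure variant.
#' @return list with `spec` ([boundary_spec()]), `factors`, `outlets`, and
#'   `table` (per-patch steady flows in 1e-5 m^3/s).
#' @export
build_case <- function(processed,
                       mode = c("full_data", "partial_post_repair",
                                "hypothetical_healthy"),
                       case1_factors = NULL, patch_areas = NULL,
                       diameters_mm = NULL, fraction = 0.70,
                       fluid = fluid_properties(), dir = NULL,
                       patch_names = default_patch_names(),
                       zero_pressure_outlets = FALSE) {
  mode <- match.arg(mode)
  flows <- processed$flows
  need <- function(sites) {
    miss <- setdiff(sites, names(flows))
    if (length(miss))
      coa_stop(sprintf("mode '%s' requires flow waveform(s) for: %s",
                       mode, paste(miss, collapse = ", ")),
               "coaflow_configuration_error")
  }
  need("ascending_aorta")
  inlet <- flows$ascending_aorta
  factors <- NULL
  if (mode == "full_data") {
    need(OUTLET_SITES)
    cms <- conserve_mass_scale(inlet, flows[OUTLET_SITES])
    outlets <- cms$outlets
    factors <- split_factors(outlet_scale = cms$factor,
                             branch_ratios = branch_ratios_from(outlets))
  } else if (mode == "partial_post_repair") {
    need("innominate")
    if (is.null(case1_factors))
      coa_stop("partial_post_repair requires case1_factors from a full-data run",
               "coaflow_configuration_error")
    d2 <- derive_case2_outlets(case1_factors, inlet, flows$innominate)
    outlets <- d2$outlets
    factors <- d2$factors
  } else {
    if (is.null(patch_areas)) {
      if (is.null(diameters_mm) ||
          !all(BRANCH_SITES %in% names(diameters_mm)))
        coa_stop("healthy split needs patch_areas or branch diameters_mm",
                 "coaflow_configuration_error")
      patch_areas <- setNames(circular_area(
        as.numeric(diameters_mm[BRANCH_SITES])), BRANCH_SITES)
    }
    outlets <- derive_case3_outlets(inlet, patch_areas, fraction)
    factors <- split_factors(descending_fraction = fraction)
  }
  spec <- extract_steady_bcs(inlet, outlets, fluid)
  tab <- data.frame(
    patch = c("inlet", names(spec$outlet_flows)),
    Q_1e5_m3s = c(spec$inlet_flow, unname(spec$outlet_flows)) * 1e5,
    row.names = NULL)
  if (!is.null(dir)) {
    write_openfoam_case(spec, dir, patch_names,
                        zero_pressure_outlets = zero_pressure_outlets)
    write_flow_report(spec, factors, file.path(dir, "flow_report.yaml"))
    jsonlite::write_json(
      list(mode = mode,
           factors = lapply(Filter(Negate(is.null), unclass(factors)),
                            function(v) if (length(v) > 1L) as.list(v) else
                              unname(v)),
           inlet_flow_m3s = spec$inlet_flow,
           outlet_flows_m3s = as.list(spec$outlet_flows)),
      file.path(dir, "run_manifest.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  list(spec = spec, factors = factors, outlets = outlets, table = tab)
}

#' Run a grid-independence check over sampled-line files
#'
#' @param mesh_files named list, ordered coarsest to finest; each element a
#'   character vector of sampled-line file paths (names = station labels)
#'   for that mesh.
#' @param threshold relative-difference criterion, default 0.05.
#' @param columns column mapping passed to [read_sampled_lines()].
#' @param csv optional CSV report path.
#' @return a `grid_check_report` (see [assess_grid_independence()]).
#' @export
run_grid_check <- function(mesh_files, threshold = 0.05,
                           columns = c(position = 1, pressure = 2,
                                       velocity = 3),
                           csv = NULL) {
  if (length(mesh_files) < 2L)
    coa_stop("need sampled files for at least 2 meshes",
             "coaflow_configuration_error")
  meshes <- lapply(names(mesh_files), function(m)
    read_sampled_lines(mesh_files[[m]], m, columns))
  names(meshes) <- names(mesh_files)
  report <- assess_grid_independence(meshes, threshold)
  if (!is.null(csv)) write_grid_report(report, csv)
  report
}
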