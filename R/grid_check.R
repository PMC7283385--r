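# Grid-independence assessment: compare station-averaged pressures and
# velocity profiles across mesh resolutions; the solution is declared grid
# independent when every metric changes by no more than the threshold
# (default 5%) between successive refinements.

#' Position-weighted mean pressure along a sampled line
#'
#' Trapezoidal average of the kinematic pressure over the sample line,
#' i.e. the integral of p over position divided by the line length.
#'
#' @param profile a [sampled_profile()] with at least 2 samples.
#' @return mean kinematic pressure in m^2/s^2.
#' @export
station_mean_pressure <- function(profile) {
  stopifnot(inherits(profile, "sampled_profile"))
  x <- profile$position; p <- profile$pressure
  if (length(x) < 2L)
    coa_stop("need at least 2 samples to average", "coaflow_degenerate_input")
  dx <- diff(x)
  sum(dx * (head(p, -1) + tail(p, -1)) / 2) / (x[length(x)] - x[1L])
}

#' Compare velocity profiles from two mesh resolutions
#'
#' Interpolates the coarse-mesh profile onto the fine-mesh positions over the
#' overlapping range and reports the relative L2 and max-norm differences,
#' both normalized by the fine profile.
#'
#' @param coarse,fine [sampled_profile()]s of the same station.
#' @return named list with `rel_L2` and `rel_max`.
#' @export
compare_profiles <- function(coarse, fine) {
  stopifnot(inherits(coarse, "sampled_profile"),
            inherits(fine, "sampled_profile"))
  lo <- max(min(coarse$position), min(fine$position))
  hi <- min(max(coarse$position), max(fine$position))
  if (lo >= hi)
    coa_stop("profiles have disjoint position ranges",
             "coaflow_invalid_comparison")
  keep <- fine$position >= lo & fine$position <= hi
  xf <- fine$position[keep]; vf <- fine$velocity[keep]
  vc <- approx(coarse$position, coarse$velocity, xout = xf, rule = 2)$y
  if (all(vf == 0))
    coa_stop("fine profile is identically zero; relative norm undefined",
             "coaflow_invalid_comparison")
  d <- vc - vf
  list(rel_L2 = sqrt(sum(d^2)) / sqrt(sum(vf^2)),
       rel_max = max(abs(d)) / max(abs(vf)))
}

#' Assess grid independence across mesh resolutions
#'
#' For each pair of successive meshes (in the order given, coarsest first)
#' and each shared station, computes the relative change in station-mean
#' pressure and the relative L2/max-norm velocity-profile differences. The
#' study passes when every metric is at or below the threshold.
#'
#' @param meshes named list (ordered coarsest to finest) of lists of
#'   [sampled_profile()]s, as returned by [read_sampled_lines()]; >= 2
#'   meshes sharing station labels.
#' @param threshold relative-difference criterion, default 0.05.
#' @return an object of class `grid_check_report`: a data frame of per-pair,
#'   per-station metrics with attributes `pass` and `threshold`.
#' @export
assess_grid_independence <- function(meshes, threshold = 0.05) {
  if (length(meshes) < 2L)
    coa_stop("need at least 2 meshes", "coaflow_configuration_error")
  if (is.null(names(meshes)))
    names(meshes) <- paste0("mesh", seq_along(meshes))
  by_station <- lapply(meshes, function(pf)
    setNames(pf, vapply(pf, `[[`, "", "station")))
  shared <- Reduce(intersect, lapply(by_station, names))
  if (!length(shared))
    coa_stop("meshes share no station labels", "coaflow_configuration_error")
  rows <- list()
  for (k in seq_len(length(meshes) - 1L)) {
    a <- by_station[[k]]; b <- by_station[[k + 1L]]
    for (st in shared) {
      pa <- station_mean_pressure(a[[st]])
      pb <- station_mean_pressure(b[[st]])
      dp <- abs(pa - pb) / max(abs(pb), .Machine$double.eps)
      vm <- compare_profiles(a[[st]], b[[st]])
      rows[[length(rows) + 1L]] <- data.frame(
        pair = sprintf("%s->%s", names(meshes)[k], names(meshes)[k + 1L]),
        station = st,
        mean_pressure_coarse = pa, mean_pressure_fine = pb,
        pressure_rel_diff = dp,
        velocity_rel_L2 = vm$rel_L2, velocity_rel_max = vm$rel_max)
    }
  }
  df <- do.call(rbind, rows)
  metrics <- as.matrix(df[, c("pressure_rel_diff", "velocity_rel_L2",
                              "velocity_rel_max")])
  df$pass <- apply(metrics <= threshold, 1L, all)
  structure(df, pass = all(df$pass), threshold = threshold,
            class = c("grid_check_report", "data.frame"))
}

#' @export
print.grid_check_report <- function(x, ...) {
  thr <- attr(x, "threshold")
  cat(sprintf("Grid-independence report (threshold %.3g)\n", thr))
  print.data.frame(cbind(x[, c("pair", "station")],
                         round(x[, c("pressure_rel_diff", "velocity_rel_L2",
                                     "velocity_rel_max")], 5),
                         pass = x$pass), row.names = FALSE)
  if (attr(x, "pass")) {
    cat("PASS: all stations grid independent at the threshold\n")
  } else {
    bad <- unique(x$station[!x$pass])
    cat(sprintf("FAIL at station(s): %s\n", paste(bad, collapse = ", ")))
  }
  invisible(x)
}

#' Write a grid-check report to CSV
#' @param report a `grid_check_report`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_grid_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
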