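# Cross-section metrics: area, perimeter, hydraulic diameter, coarctation
# ratio, outlet-extension length. Lengths in mm throughout this module.

#' Construct a vessel cross section
#'
#' Either an ordered closed planar contour (mm) or a direct (area, perimeter)
#' pair in mm^2 / mm.
#'
#' @param contour numeric matrix or data frame with two columns (x, y) in mm;
#'   the polygon is closed implicitly (last vertex joins the first).
#' @param area,perimeter direct metrics in mm^2 and mm, used when `contour`
#'   is `NULL`.
#' @param label free-text label (e.g. `"coarctation"`).
#' @return an object of class `cross_section` with fields `area`,
#'   `perimeter`, `label` and, when given, `contour`.
#' @export
cross_section <- function(contour = NULL, area = NULL, perimeter = NULL,
                          label = "") {
  if (!is.null(contour)) {
    m <- polygon_metrics(contour)
    return(structure(list(contour = as.matrix(contour), area = m$area,
                          perimeter = m$perimeter, label = label),
                     class = "cross_section"))
  }
  if (is.null(area) || is.null(perimeter) || area <= 0 || perimeter <= 0)
    coa_stop("need a contour or positive area and perimeter",
             "coaflow_invalid_geometry")
  structure(list(contour = NULL, area = area, perimeter = perimeter,
                 label = label), class = "cross_section")
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf("<cross_section> %s A=%.4g mm^2 P=%.4g mm D_h=%.4g mm\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              x$area, x$perimeter, hydraulic_diameter(x$area, x$perimeter)))
  invisible(x)
}

#' Area and perimeter of a closed planar contour
#'
#' Area by the shoelace formula (absolute value, so vertex orientation does
#' not matter), perimeter by summed segment lengths. The contour must be
#' simple (non-self-intersecting) with at least 3 distinct vertices.
#'
#' @param contour two-column matrix/data frame of (x, y) vertices in mm.
#' @return list with `area` (mm^2) and `perimeter` (mm).
#' @examples
#' polygon_metrics(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))  # unit square
#' @export
polygon_metrics <- function(contour) {
  p <- as.matrix(contour)
  if (!is.numeric(p) || ncol(p) != 2L || nrow(p) < 3L || anyNA(p))
    coa_stop("contour must be a numeric n x 2 matrix with n >= 3",
             "coaflow_invalid_geometry")
  # drop a duplicated closing vertex
  if (nrow(p) > 3L && all(abs(p[1L, ] - p[nrow(p), ]) < 1e-12))
    p <- p[-nrow(p), , drop = FALSE]
  if (nrow(p) < 3L)
    coa_stop("degenerate contour", "coaflow_invalid_geometry")
  x <- p[, 1L]; y <- p[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  area <- abs(sum(x * yn - xn * y)) / 2
  if (area <= 0)
    coa_stop("degenerate contour (zero area)", "coaflow_invalid_geometry")
  if (contour_self_intersects(x, y))
    coa_stop("self-intersecting contour", "coaflow_invalid_geometry")
  list(area = area, perimeter = sum(sqrt((xn - x)^2 + (yn - y)^2)))
}

# O(n^2) check that no two non-adjacent edges of the closed polygon cross.
contour_self_intersects <- function(x, y) {
  n <- length(x)
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    if (i == 1L) js <- js[js != n]   # edge n is adjacent to edge 1
    for (j in js) {
      d1 <- cross(x[i], y[i], x2[i], y2[i], x[j], y[j])
      d2 <- cross(x[i], y[i], x2[i], y2[i], x2[j], y2[j])
      d3 <- cross(x[j], y[j], x2[j], y2[j], x[i], y[i])
      d4 <- cross(x[j], y[j], x2[j], y2[j], x2[i], y2[i])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
        return(TRUE)
    }
  }
  FALSE
}

#' Hydraulic diameter of a cross section
#'
#' `D_h = 4 A / P`; equals the geometric diameter for a circle. This is the
#' diameter definition used for coarctation severity grading of non-circular
#' lumen sections.
#'
#' @param area cross-section area in mm^2, > 0.
#' @param perimeter cross-section perimeter in mm, > 0.
#' @return hydraulic diameter in mm.
#' @examples
#' hydraulic_diameter(8.08, 9.59)
#' @export
hydraulic_diameter <- function(area, perimeter) {
  if (!is.numeric(area) || !is.numeric(perimeter) || any(is.na(area)) ||
      any(is.na(perimeter)) || any(area <= 0) || any(perimeter <= 0))
    coa_stop("area and perimeter must be positive",
             "coaflow_invalid_parameter")
  4 * area / perimeter
}

#' Patch geometry with derived hydraulic diameter
#'
#' @param section a [cross_section()].
#' @return an object of class `patch_geometry` with the section and its
#'   `hydraulic_diameter` (mm).
#' @export
patch_geometry <- function(section) {
  stopifnot(inherits(section, "cross_section"))
  structure(list(section = section,
                 hydraulic_diameter = hydraulic_diameter(section$area,
                                                         section$perimeter)),
            class = "patch_geometry")
}

#' @export
print.patch_geometry <- function(x, ...) {
  cat(sprintf("<patch_geometry> %s D_h=%.4g mm\n",
              if (nzchar(x$section$label)) x$section$label else "(unlabelled)",
              x$hydraulic_diameter))
  invisible(x)
}

#' Coarctation severity ratio
#'
#' Ratio of the coarctation-site hydraulic diameter to the descending-aorta
#' hydraulic diameter at the level of the diaphragm; values well below 1
#' indicate a severe stenosis.
#'
#' @param coarct [patch_geometry()] of the (minimum) coarctation section.
#' @param dao [patch_geometry()] of the descending aorta at the diaphragm.
#' @return dimensionless ratio.
#' @export
coarctation_ratio <- function(coarct, dao) {
  stopifnot(inherits(coarct, "patch_geometry"), inherits(dao, "patch_geometry"))
  coarct$hydraulic_diameter / dao$hydraulic_diameter
}

#' Outlet extension length
#'
#' Outlet patches are extruded by a multiple (default ten) of their hydraulic
#' diameter so that recirculation regions do not intersect the outlet plane.
#'
#' @param patch a [patch_geometry()].
#' @param multiple extrusion multiple, > 0, default 10.
#' @return extension length in mm.
#' @export
extension_length <- function(patch, multiple = 10) {
  stopifnot(inherits(patch, "patch_geometry"))
  if (!is.numeric(multiple) || length(multiple) != 1L || multiple <= 0)
    coa_stop("multiple must be positive", "coaflow_invalid_parameter")
  multiple * patch$hydraulic_diameter
}

#' Read a planar contour from a delimited x,y point list (mm)
#'
#' @param path file path; comma- or whitespace-delimited, two columns, `#`
#'   comments allowed.
#' @return numeric matrix of vertices.
#' @export
read_contour <- function(path) {
  if (!file.exists(path))
    coa_stop(sprintf("file not found: %s", path), "coaflow_io_error")
  lines <- readLines(path, warn = FALSE)
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(trimws(body), "[,[:space:]]+")
  if (any(lengths(parts) < 2L))
    coa_stop("each contour row needs two columns: x, y",
             "coaflow_io_error")
  cbind(x = as.numeric(vapply(parts, `[`, "", 1L)),
        y = as.numeric(vapply(parts, `[`, "", 2L)))
}

#' Tabulate cross-section metrics
#'
#' Builds a severity table: per section the area, perimeter, hydraulic
#' diameter, and the ratio to a reference descending-aorta section.
#'
#' @param sections named list of [cross_section()]s for the coarctation
#'   region states.
#' @param dao reference descending-aorta [cross_section()].
#' @param path optional CSV output path.
#' @return data frame with one row per section plus the reference row.
#' @export
section_report <- function(sections, dao, path = NULL) {
  stopifnot(inherits(dao, "cross_section"))
  pg_dao <- patch_geometry(dao)
  rows <- lapply(names(sections), function(nm) {
    pg <- patch_geometry(sections[[nm]])
    data.frame(geometry = nm, area_mm2 = pg$section$area,
               perimeter_mm = pg$section$perimeter,
               hydraulic_diameter_mm = pg$hydraulic_diameter,
               ratio_to_dao = coarctation_ratio(pg, pg_dao))
  })
  df <- rbind(do.call(rbind, rows),
              data.frame(geometry = "descending_aorta",
                         area_mm2 = dao$area, perimeter_mm = dao$perimeter,
                         hydraulic_diameter_mm = pg_dao$hydraulic_diameter,
                         ratio_to_dao = NA_real_))
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
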