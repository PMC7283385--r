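# Minimal STL handling: reading triangle soups and cutting planar
# cross-section contours out of a tubular surface. Coordinates are taken to
# be in mm, matching the segmentation export convention.

#' Read an STL surface mesh (ASCII or binary)
#'
#' @param path file path.
#' @return an object of class `stl_mesh`: a list with `triangles`, an
#'   `n x 9` matrix of vertex coordinates (v1x v1y v1z v2x ... v3z) in mm.
#' @export
read_stl <- function(path) {
  if (!file.exists(path))
    coa_stop(sprintf("file not found: %s", path), "coaflow_io_error")
  con <- file(path, "rb")
  head_raw <- readBin(con, "raw", 80L)
  is_ascii <- grepl("^\\s*solid", rawToChar(head_raw[head_raw != as.raw(0)]))
  if (is_ascii) {
    close(con)
    # confirm: a binary file can also start with "solid"; require "facet"
    txt <- readLines(path, warn = FALSE)
    if (!any(grepl("facet", txt))) is_ascii <- FALSE else {
      nums <- regmatches(txt, regexpr(
        "vertex\\s+\\S+\\s+\\S+\\s+\\S+", txt))
      vv <- do.call(rbind, lapply(strsplit(trimws(sub("vertex", "", nums)),
                                           "\\s+"), as.numeric))
      if (is.null(vv) || nrow(vv) %% 3L != 0L)
        coa_stop("malformed ASCII STL", "coaflow_io_error")
      tri <- matrix(as.vector(t(vv)), ncol = 9L, byrow = TRUE)
      return(structure(list(triangles = tri), class = "stl_mesh"))
    }
    con <- file(path, "rb")
    readBin(con, "raw", 80L)
  }
  n_tri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  rec <- readBin(con, "raw", n_tri * 50L)
  close(con)
  if (length(rec) < n_tri * 50L)
    coa_stop("truncated binary STL", "coaflow_io_error")
  m <- matrix(rec, nrow = 50L)
  tri <- t(vapply(seq_len(n_tri), function(i)
    readBin(m[13:48, i], "numeric", 9L, size = 4L, endian = "little"),
    numeric(9L)))
  structure(list(triangles = tri), class = "stl_mesh")
}

#' Write a mesh as ASCII STL
#' @param mesh an `stl_mesh`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stl_ascii <- function(mesh, path) {
  tri <- mesh$triangles
  out <- c("solid coaflow")
  for (i in seq_len(nrow(tri))) {
    v <- tri[i, ]
    out <- c(out, "  facet normal 0 0 0", "    outer loop",
             sprintf("      vertex %.9g %.9g %.9g", v[1], v[2], v[3]),
             sprintf("      vertex %.9g %.9g %.9g", v[4], v[5], v[6]),
             sprintf("      vertex %.9g %.9g %.9g", v[7], v[8], v[9]),
             "    endloop", "  endfacet")
  }
  writeLines(c(out, "endsolid coaflow"), path)
  invisible(path)
}

#' Cut a planar cross-section contour from a surface mesh
#'
#' Intersects every triangle with the plane through `point` with normal
#' `normal`, chains the resulting segments into a closed loop, and projects
#' it onto in-plane 2D coordinates suitable for [polygon_metrics()]. When
#' the plane cuts the surface in several loops the one with the largest
#' enclosed area is returned (a tube cut yields one loop per lumen).
#'
#' @param mesh an `stl_mesh` from [read_stl()].
#' @param point numeric length-3 point on the plane (mm).
#' @param normal numeric length-3 plane normal.
#' @return two-column matrix of ordered contour vertices (mm) in plane
#'   coordinates.
#' @export
plane_cut_contour <- function(mesh, point, normal) {
  stopifnot(inherits(mesh, "stl_mesh"))
  n <- normal / sqrt(sum(normal^2))
  tri <- mesh$triangles
  d <- function(p) (p[, 1] - point[1]) * n[1] + (p[, 2] - point[2]) * n[2] +
    (p[, 3] - point[3]) * n[3]
  v1 <- tri[, 1:3, drop = FALSE]; v2 <- tri[, 4:6, drop = FALSE]
  v3 <- tri[, 7:9, drop = FALSE]
  d1 <- d(v1); d2 <- d(v2); d3 <- d(v3)
  segs <- list()
  for (i in seq_len(nrow(tri))) {
    dd <- c(d1[i], d2[i], d3[i])
    vv <- rbind(v1[i, ], v2[i, ], v3[i, ])
    pts <- list()
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      a <- dd[e[1]]; b <- dd[e[2]]
      if ((a < 0 && b >= 0) || (a >= 0 && b < 0)) {
        t <- a / (a - b)
        pts[[length(pts) + 1L]] <- vv[e[1], ] + t * (vv[e[2], ] - vv[e[1], ])
      }
    }
    if (length(pts) == 2L) segs[[length(segs) + 1L]] <- rbind(pts[[1]], pts[[2]])
  }
  if (length(segs) < 3L)
    coa_stop("plane does not cut the surface in a closed contour",
             "coaflow_invalid_geometry")
  loops <- chain_segments(segs)
  # project each loop to 2D and keep the largest-area one
  u <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- u - sum(u * n) * n; u <- u / sqrt(sum(u^2))
  w <- c(n[2] * u[3] - n[3] * u[2], n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  best <- NULL; best_area <- -Inf
  for (lp in loops) {
    if (nrow(lp) < 3L) next
    xy <- cbind(lp %*% u, lp %*% w)
    x <- xy[, 1]; y <- xy[, 2]
    a <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
    if (a > best_area) { best_area <- a; best <- xy }
  }
  if (is.null(best) || best_area <= 0)
    coa_stop("plane cut produced no usable loop", "coaflow_invalid_geometry")
  colnames(best) <- c("x", "y")
  best
}

# Greedy chaining of 3D segments into loops by endpoint matching.
chain_segments <- function(segs, tol = NULL) {
  pts <- do.call(rbind, segs)
  if (is.null(tol))
    tol <- 1e-6 * max(1, max(abs(pts)))
  used <- rep(FALSE, length(segs))
  loops <- list()
  repeat {
    i0 <- which(!used)[1L]
    if (is.na(i0)) break
    used[i0] <- TRUE
    loop <- segs[[i0]]
    repeat {
      tail_pt <- loop[nrow(loop), ]
      found <- FALSE
      for (j in which(!used)) {
        s <- segs[[j]]
        if (sum((s[1, ] - tail_pt)^2) < tol^2) {
          loop <- rbind(loop, s[2, ]); used[j] <- TRUE; found <- TRUE; break
        }
        if (sum((s[2, ] - tail_pt)^2) < tol^2) {
          loop <- rbind(loop, s[1, ]); used[j] <- TRUE; found <- TRUE; break
        }
      }
      if (!found) break
      if (sum((loop[nrow(loop), ] - loop[1, ])^2) < tol^2) {
        loop <- loop[-nrow(loop), , drop = FALSE]
        break
      }
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' Minimum hydraulic diameter over a sweep of cutting planes
#'
#' Cuts the surface at each supplied plane and reports the smallest hydraulic
#' diameter found, locating the narrowest section of a stenosed region.
#'
#' @param mesh an `stl_mesh`.
#' @param points matrix of plane points (one row per plane, mm).
#' @param normals matrix of plane normals (one row per plane).
#' @return list with `min_hydraulic_diameter` (mm), `index` of the minimizing
#'   plane, and the per-plane `diameters`.
#' @export
min_hydraulic_diameter <- function(mesh, points, normals) {
  points <- rbind(points); normals <- rbind(normals)
  stopifnot(nrow(points) == nrow(normals))
  dh <- vapply(seq_len(nrow(points)), function(i) {
    m <- polygon_metrics(plane_cut_contour(mesh, points[i, ], normals[i, ]))
    hydraulic_diameter(m$area, m$perimeter)
  }, 0)
  list(min_hydraulic_diameter = min(dh), index = which.min(dh),
       diameters = dh)
}
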