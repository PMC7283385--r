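test_that("polygon metrics match closed forms and ignore orientation", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  m <- polygon_metrics(sq)
  expect_equal(m$area, 1)
  expect_equal(m$perimeter, 4)
  # reversed vertex order: identical
  m2 <- polygon_metrics(sq[4:1, ])
  expect_equal(m2, m)
  # a 256-gon is a circle to 0.1%
  g <- ngon(256, r = 3)
  mg <- polygon_metrics(g)
  expect_equal(mg$area, pi * 9, tolerance = 1e-3)
  expect_equal(mg$perimeter, 2 * pi * 3, tolerance = 1e-3)
  # duplicated closing vertex tolerated
  expect_equal(polygon_metrics(rbind(sq, sq[1, ]))$area, 1)
  # degenerate and self-intersecting contours rejected
  expect_error(polygon_metrics(cbind(0:2, 0:2)), "degenerate|zero area")
  th <- 2 * pi * (0:4) / 5
  pentagram <- cbind(cos(th), sin(th))[c(1, 3, 5, 2, 4), ]
  expect_error(polygon_metrics(pentagram), "self-intersecting")
})

test_that("hydraulic diameters reproduce the severity-table values", {
  expect_equal(round(hydraulic_diameter(8.08, 9.59), 2), 3.37)
  expect_equal(round(hydraulic_diameter(25.91, 17.99), 2), 5.76)
  expect_equal(round(hydraulic_diameter(61.82, 27.61), 2), 8.96)
  expect_equal(round(hydraulic_diameter(48.25, 24.66), 2), 7.83)
  # circle: D_h = 2 r exactly
  r <- 4.2
  expect_equal(hydraulic_diameter(pi * r^2, 2 * pi * r), 2 * r)
  expect_error(hydraulic_diameter(-1, 2), "positive")
})

test_that("hydraulic diameter scales linearly with the contour", {
  g <- ngon(64, 2.5)
  for (k in c(0.5, 3)) {
    m1 <- polygon_metrics(g); mk <- polygon_metrics(k * g)
    expect_equal(hydraulic_diameter(mk$area, mk$perimeter),
                 k * hydraulic_diameter(m1$area, m1$perimeter))
  }
})

test_that("coarctation ratios grade severity against the descending aorta", {
  dao <- patch_geometry(cross_section(area = 48.25, perimeter = 24.66,
                                      label = "descending_aorta"))
  c1 <- patch_geometry(cross_section(area = 8.08, perimeter = 9.59))
  c3 <- patch_geometry(cross_section(area = 61.82, perimeter = 27.61))
  expect_equal(round(coarctation_ratio(c1, dao), 2), 0.43)
  expect_equal(round(coarctation_ratio(c3, dao), 2), 1.14)
  expect_equal(coarctation_ratio(dao, dao), 1)
  # invariant under uniform scaling of both sections
  k <- 2.7
  c1k <- patch_geometry(cross_section(area = k^2 * 8.08,
                                      perimeter = k * 9.59))
  daok <- patch_geometry(cross_section(area = k^2 * 48.25,
                                       perimeter = k * 24.66))
  expect_equal(coarctation_ratio(c1k, daok), coarctation_ratio(c1, dao))
})

test_that("outlet extensions are a multiple of the hydraulic diameter", {
  dao <- patch_geometry(cross_section(area = 48.25, perimeter = 24.66))
  expect_equal(extension_length(dao), 78.3, tolerance = 1e-3)
  c1 <- patch_geometry(cross_section(area = 8.08, perimeter = 9.59))
  expect_equal(extension_length(c1), 33.7, tolerance = 1e-3)
  two <- patch_geometry(cross_section(area = pi, perimeter = 2 * pi))
  expect_equal(extension_length(two, multiple = 0.5), 1)
  expect_error(extension_length(two, multiple = 0), "positive")
})

test_that("section reports tabulate metrics against the reference section", {
  dao <- cross_section(area = 48.25, perimeter = 24.66)
  secs <- list(case1 = cross_section(area = 8.08, perimeter = 9.59),
               case2 = cross_section(area = 25.91, perimeter = 17.99))
  f <- tempfile(fileext = ".csv")
  df <- section_report(secs, dao, f)
  expect_equal(round(df$hydraulic_diameter_mm, 2), c(3.37, 5.76, 7.83))
  expect_equal(round(df$ratio_to_dao[1:2], 2), c(0.43, 0.74))
  expect_true(file.exists(f))
  back <- read.csv(f)
  expect_equal(back$area_mm2, df$area_mm2)
})

test_that("contours can be read from delimited point files", {
  f <- tempfile()
  writeLines(c("# unit square, mm", "0,0", "1 0", "1,1", "0 1"), f)
  g <- read_contour(f)
  expect_equal(polygon_metrics(g)$area, 1)
})

test_that("plane cuts of a tube recover circular sections and the stenosis", {
  # straight tube of radius 5 mm: the cut is a circle, D_h = 10 mm
  tube <- cylinder_mesh(function(z) 5, L = 10)
  ct <- plane_cut_contour(tube, point = c(0, 0, 5), normal = c(0, 0, 1))
  m <- polygon_metrics(ct)
  expect_equal(hydraulic_diameter(m$area, m$perimeter), 10, tolerance = 2e-3)
  # stenosed tube: minimum D_h located at the waist
  waist <- function(z) 5 - 3 * exp(-((z - 6) / 1.5)^2)
  sten <- cylinder_mesh(waist, L = 12, n_z = 60)
  zs <- seq(1.1, 11.1, by = 0.4)   # planes between mesh rings
  res <- min_hydraulic_diameter(sten,
                                cbind(0, 0, zs),
                                matrix(rep(c(0, 0, 1), length(zs)),
                                       ncol = 3, byrow = TRUE))
  expect_equal(zs[res$index], 5.9)
  expect_equal(res$min_hydraulic_diameter, 2 * waist(5.9), tolerance = 2e-2)
  expect_error(plane_cut_contour(tube, c(0, 0, 50), c(0, 0, 1)),
               "does not cut")
})

test_that("STL files round-trip through the ASCII writer and both readers", {
  tube <- cylinder_mesh(function(z) 2, L = 4, n_theta = 24, n_z = 6)
  fa <- tempfile(fileext = ".stl")
  write_stl_ascii(tube, fa)
  back <- read_stl(fa)
  expect_equal(back$triangles, tube$triangles, tolerance = 1e-7)
  # binary STL fixture built in code
  fb <- tempfile(fileext = ".stl")
  con <- file(fb, "wb")
  writeBin(as.raw(rep(0, 80)), con)
  writeBin(nrow(tube$triangles), con, size = 4, endian = "little")
  for (i in seq_len(nrow(tube$triangles))) {
    writeBin(numeric(3), con, size = 4, endian = "little")   # normal
    writeBin(tube$triangles[i, ], con, size = 4, endian = "little")
    writeBin(as.raw(c(0, 0)), con)
  }
  close(con)
  bb <- read_stl(fb)
  expect_equal(bb$triangles, tube$triangles, tolerance = 1e-6)
})
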