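# OpenFOAM (version 6 keyword set) case-file generation and post-processing
# readback. Writers are deterministic: regenerating from the same inputs is
# byte-identical.

# Shortest decimal representation that round-trips the double exactly.
foam_num <- function(x) {
  vapply(x, function(v) {
    for (d in 1:17) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, "")
}

foam_header <- function(class, location, object) {
  c("FoamFile",
    "{",
    "    version     2.0;",
    "    format      ascii;",
    sprintf("    class       %s;", class),
    sprintf("    location    \"%s\";", location),
    sprintf("    object      %s;", object),
    "}",
    "")
}

#' Generate the velocity boundary-condition dictionary (0/U)
#'
#' Encodes the steady peak-systolic flow boundary conditions: a
#' `flowRateInletVelocity` condition carrying the inlet volumetric flow rate
#' at the inlet patch, `flowRateOutletVelocity` with each outlet's flow rate
#' at the outlet patches (positive magnitudes; the built-in condition handles
#' direction), and `noSlip` at the vessel wall.
#'
#' @param spec a [boundary_spec()] (inlet = sum of outlets is enforced by its
#'   constructor).
#' @param patch_names named character mapping site labels to OpenFOAM patch
#'   names; must cover `ascending_aorta` (the inlet) and every outlet site in
#'   `spec`.
#' @param wall_patch name of the wall patch, default `"wall"`.
#' @return character vector of dictionary lines.
#' @export
write_velocity_bcs <- function(spec, patch_names, wall_patch = "wall") {
  stopifnot(inherits(spec, "boundary_spec"))
  outlet_sites <- names(spec$outlet_flows)
  if (!length(outlet_sites))
    coa_stop("boundary spec has no outlets", "coaflow_configuration_error")
  needed <- c("ascending_aorta", outlet_sites)
  missing <- setdiff(needed, names(patch_names))
  if (length(missing))
    coa_stop(sprintf("no patch name mapped for site(s): %s",
                     paste(missing, collapse = ", ")),
             "coaflow_configuration_error")
  entry <- function(patch, type, q) {
    c(sprintf("    %s", patch),
      "    {",
      sprintf("        type            %s;", type),
      if (!is.null(q))
        sprintf("        volumetricFlowRate constant %s;", foam_num(q)),
      if (!is.null(q))
        "        value           uniform (0 0 0);",
      "    }")
  }
  lines <- c(foam_header("volVectorField", "0", "U"),
             "dimensions      [0 1 -1 0 0 0 0];",
             "",
             "internalField   uniform (0 0 0);",
             "",
             "boundaryField",
             "{",
             entry(patch_names[["ascending_aorta"]],
                   "flowRateInletVelocity", spec$inlet_flow))
  for (s in outlet_sites)
    lines <- c(lines, entry(patch_names[[s]], "flowRateOutletVelocity",
                            spec$outlet_flows[[s]]))
  c(lines, entry(wall_patch, "noSlip", NULL), "}", "")
}

#' Generate the pressure dictionary (0/p)
#'
#' Kinematic pressure field. By default every patch is `zeroGradient` and the
#' pressure level is fixed by the reference cell in `fvSolution`; with
#' `zero_pressure_outlets = TRUE` the grid-study variant is produced instead
#' (outlets `fixedValue uniform 0`).
#'
#' @inheritParams write_velocity_bcs
#' @param zero_pressure_outlets use the fixed-zero outlet-pressure variant.
#' @return character vector of dictionary lines.
#' @export
write_pressure_bcs <- function(spec, patch_names, wall_patch = "wall",
                               zero_pressure_outlets = FALSE) {
  stopifnot(inherits(spec, "boundary_spec"))
  outlet_sites <- names(spec$outlet_flows)
  entry <- function(patch, type, fixed0 = FALSE) {
    c(sprintf("    %s", patch),
      "    {",
      sprintf("        type            %s;", type),
      if (fixed0) "        value           uniform 0;",
      "    }")
  }
  otype <- if (zero_pressure_outlets) "fixedValue" else "zeroGradient"
  lines <- c(foam_header("volScalarField", "0", "p"),
             "dimensions      [0 2 -2 0 0 0 0];",
             "",
             "internalField   uniform 0;",
             "",
             "boundaryField",
             "{",
             entry(patch_names[["ascending_aorta"]], "zeroGradient"))
  for (s in outlet_sites)
    lines <- c(lines, entry(patch_names[[s]], otype,
                            fixed0 = zero_pressure_outlets))
  c(lines, entry(wall_patch, "zeroGradient"), "}", "")
}

#' Generate transport, scheme and solution dictionaries
#'
#' Newtonian transport with the blood kinematic viscosity, backward (second
#' order implicit) time scheme, a bounded second-order convective scheme
#' (`linearUpwind`), and a pressure reference (cell 0, value 0).
#'
#' @param fluid a [fluid_properties()].
#' @return named list of character vectors: `transportProperties`,
#'   `fvSchemes`, `fvSolution`.
#' @export
write_transport_and_schemes <- function(fluid = fluid_properties()) {
  stopifnot(inherits(fluid, "fluid_properties"))
  transport <- c(foam_header("dictionary", "constant", "transportProperties"),
                 "transportModel  Newtonian;",
                 "",
                 sprintf("nu              [0 2 -1 0 0 0 0] %s;",
                         foam_num(fluid$kinematic_viscosity)),
                 "")
  schemes <- c(foam_header("dictionary", "system", "fvSchemes"),
               "ddtSchemes",
               "{",
               "    default         backward;",
               "}",
               "",
               "gradSchemes",
               "{",
               "    default         Gauss linear;",
               "}",
               "",
               "divSchemes",
               "{",
               "    default         none;",
               "    div(phi,U)      Gauss linearUpwind grad(U);",
               "}",
               "",
               "laplacianSchemes",
               "{",
               "    default         Gauss linear corrected;",
               "}",
               "",
               "interpolationSchemes",
               "{",
               "    default         linear;",
               "}",
               "",
               "snGradSchemes",
               "{",
               "    default         corrected;",
               "}",
               "")
  solution <- c(foam_header("dictionary", "system", "fvSolution"),
                "solvers",
                "{",
                "    p",
                "    {",
                "        solver          GAMG;",
                "        smoother        GaussSeidel;",
                "        tolerance       1e-07;",
                "        relTol          0.01;",
                "    }",
                "",
                "    U",
                "    {",
                "        solver          smoothSolver;",
                "        smoother        symGaussSeidel;",
                "        tolerance       1e-08;",
                "        relTol          0;",
                "    }",
                "}",
                "",
                "PISO",
                "{",
                "    nCorrectors     2;",
                "    nNonOrthogonalCorrectors 1;",
                "    pRefCell        0;",
                "    pRefValue       0;",
                "}",
                "")
  list(transportProperties = transport, fvSchemes = schemes,
       fvSolution = solution)
}

#' Write a complete OpenFOAM case skeleton
#'
#' Emits `0/U`, `0/p`, `constant/transportProperties`, `system/fvSchemes`
#' and `system/fvSolution` under `dir`. Mesh generation and solver
#' invocation are left to the user.
#'
#' @inheritParams write_velocity_bcs
#' @inheritParams write_pressure_bcs
#' @param dir case directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_openfoam_case <- function(spec, dir, patch_names = default_patch_names(),
                                wall_patch = "wall",
                                zero_pressure_outlets = FALSE) {
  for (d in file.path(dir, c("0", "constant", "system")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  writeLines(write_velocity_bcs(spec, patch_names, wall_patch),
             file.path(dir, "0", "U"))
  writeLines(write_pressure_bcs(spec, patch_names, wall_patch,
                                zero_pressure_outlets),
             file.path(dir, "0", "p"))
  ts <- write_transport_and_schemes(spec$fluid)
  writeLines(ts$transportProperties,
             file.path(dir, "constant", "transportProperties"))
  writeLines(ts$fvSchemes, file.path(dir, "system", "fvSchemes"))
  writeLines(ts$fvSolution, file.path(dir, "system", "fvSolution"))
  invisible(dir)
}

#' Default site-to-patch name mapping
#' @return named character vector mapping every site to an OpenFOAM patch
#'   name.
#' @export
default_patch_names <- function() {
  c(ascending_aorta = "inlet", innominate = "innominate", lcca = "lcca",
    lsca = "lsca", descending_aorta = "descending_aorta")
}

#' Parse flow rates back out of a velocity dictionary
#'
#' Inverse of [write_velocity_bcs()]: recovers each patch's
#' `volumetricFlowRate` and its condition type.
#'
#' @param path path to a `0/U` file written by this package.
#' @return data frame with columns `patch`, `type`, `flow`.
#' @export
read_velocity_bcs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  check_foam_syntax(lines)
  patches <- character(); types <- character(); flows <- numeric()
  i <- 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (grepl("^type\\s", ln)) {
      type <- sub(";$", "", sub("^type\\s+", "", ln))
      # patch name is the token above the opening brace
      j <- i - 1L
      while (j > 0 && trimws(lines[j]) != "{") j <- j - 1L
      patch <- trimws(lines[j - 1L])
      q <- NA_real_
      if (i + 1L <= length(lines) &&
          grepl("volumetricFlowRate", lines[i + 1L]))
        q <- as.numeric(sub(";$", "", sub(
          ".*constant\\s+", "", trimws(lines[i + 1L]))))
      patches <- c(patches, patch); types <- c(types, type)
      flows <- c(flows, q)
    }
    i <- i + 1L
  }
  data.frame(patch = patches, type = types, flow = flows)
}

#' Grammar check of an OpenFOAM dictionary fragment
#'
#' Verifies balanced braces and that every non-block entry line is
#' semicolon-terminated.
#'
#' @param lines character vector of dictionary lines.
#' @return `TRUE` invisibly; otherwise an error.
#' @export
check_foam_syntax <- function(lines) {
  depth <- 0L
  for (k in seq_along(lines)) {
    ln <- trimws(lines[k])
    if (!nzchar(ln) || grepl("^//", ln) || grepl("^/\\*", ln)) next
    depth <- depth + lengths(regmatches(ln, gregexpr("\\{", ln))) -
      lengths(regmatches(ln, gregexpr("\\}", ln)))
    if (depth < 0L)
      coa_stop(sprintf("unbalanced closing brace at line %d", k),
               "coaflow_parse_error")
    if (!grepl("[{}]", ln) && grepl("\\s", ln) && !grepl(";$", ln))
      coa_stop(sprintf("unterminated entry at line %d: '%s'", k, ln),
               "coaflow_parse_error")
  }
  if (depth != 0L)
    coa_stop("unbalanced braces in dictionary", "coaflow_parse_error")
  invisible(TRUE)
}

#' Read sampled-line post-processing output
#'
#' Parses whitespace-delimited sampled-set files (one per station) with a
#' configurable column mapping, as produced by solver post-processing along
#' the assessment lines (inlet, arch, proximal/local/distal stenosis,
#' outlets). Kinematic pressure is retained; convert with
#' [kinematic_pressure_to_mmHg()] on demand.
#'
#' @param files character vector of file paths; names, when present, are the
#'   station labels (defaulting to the base file name without extension).
#' @param mesh_label label of the mesh resolution these samples belong to.
#' @param columns named integer vector giving the 1-based column indices of
#'   `position`, `pressure` and `velocity`.
#' @return list of `sampled_profile` objects.
#' @export
read_sampled_lines <- function(files, mesh_label,
                               columns = c(position = 1, pressure = 2,
                                           velocity = 3)) {
  stopifnot(all(c("position", "pressure", "velocity") %in% names(columns)))
  stations <- names(files)
  if (is.null(stations))
    stations <- sub("\\.[^.]*$", "", basename(files))
  out <- vector("list", length(files))
  for (k in seq_along(files)) {
    if (!file.exists(files[k]))
      coa_stop(sprintf("file not found: %s", files[k]), "coaflow_io_error")
    lines <- readLines(files[k], warn = FALSE)
    keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
    lineno <- which(keep)
    parts <- strsplit(trimws(lines[keep]), "\\s+")
    need <- max(columns)
    bad <- which(lengths(parts) < need)
    if (length(bad))
      coa_stop(sprintf("ragged row in %s at line %d (need %d columns)",
                       files[k], lineno[bad[1L]], need),
               "coaflow_parse_error")
    grab <- function(i) as.numeric(vapply(parts, `[`, "", columns[[i]]))
    out[[k]] <- sampled_profile(stations[k], grab("position"),
                                grab("pressure"), grab("velocity"),
                                mesh_label)
  }
  out
}

#' Construct a sampled line profile
#'
#' @param station station label.
#' @param position positions along the sample line (m).
#' @param pressure kinematic pressure (m^2/s^2).
#' @param velocity velocity magnitude (m/s).
#' @param mesh_label mesh resolution label.
#' @return an object of class `sampled_profile`. Non-monotone positions are
#'   sorted with a warning.
#' @export
sampled_profile <- function(station, position, pressure, velocity,
                            mesh_label = "") {
  if (anyNA(position) || anyNA(pressure) || anyNA(velocity))
    coa_stop("NA in sampled profile", "coaflow_parse_error")
  if (length(position) != length(pressure) ||
      length(position) != length(velocity))
    coa_stop("profile columns differ in length", "coaflow_parse_error")
  if (is.unsorted(position, strictly = TRUE)) {
    warning(sprintf("station '%s': positions not strictly increasing; sorting",
                    station))
    o <- order(position)
    position <- position[o]; pressure <- pressure[o]; velocity <- velocity[o]
    keep <- !duplicated(position)
    position <- position[keep]; pressure <- pressure[keep]
    velocity <- velocity[keep]
  }
  structure(list(station = station, position = position, pressure = pressure,
                 velocity = velocity, mesh_label = mesh_label),
            class = "sampled_profile")
}

#' @export
print.sampled_profile <- function(x, ...) {
  cat(sprintf("<sampled_profile> station=%s mesh=%s n=%d\n", x$station,
              x$mesh_label, length(x$position)))
  invisible(x)
}
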