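#' Land-use classification codes
#'
#' The eight-class land-use legend used throughout the package. Codes 1-5 are
#' ecological land (woodland, three grassland coverage levels, water); codes
#' 6-8 are non-ecological land (farmland, construction, saline-alkali and
#' other unused land). Grassland coverage ordering, needed by the
#' degradation/restoration intensities, is high (>50%) > medium (20-50%) >
#' low (5-20%).
#'
#' @return A data.frame with columns `code`, `key`, `label`, `ecological`.
#' @export
land_use_classes <- function() {
  data.frame(
    code = 1:8,
    key = c("woodland", "grass_high", "grass_medium", "grass_low",
            "water", "farmland", "construction", "saline_alkali"),
    label = c("Woodland", "High coverage grassland", "Medium coverage grassland",
              "Low coverage grassland", "Water", "Farmland",
              "Construction land", "Saline-alkali land and others"),
    ecological = c(rep(TRUE, 5), rep(FALSE, 3)),
    stringsAsFactors = FALSE
  )
}

#' Codes of the three grassland classes, ordered high to low coverage
#' @return Integer vector `c(grass_high = 2, grass_medium = 3, grass_low = 4)`.
#' @export
grassland_codes <- function() c(grass_high = 2L, grass_medium = 3L, grass_low = 4L)

#' Construct a categorical land-use grid
#'
#' A `land_use_grid` is the fundamental raster input: a rectangular integer
#' matrix of the eight class codes (NA = nodata), with square cells of known
#' size and a lower-left origin. Row 1 is the north edge of the map.
#'
#' @param codes Integer matrix of class codes (1-8) or NA.
#' @param cell_size_m Cell edge length in metres (> 0).
#' @param xll,yll Map coordinates of the lower-left corner of the grid.
#' @param year Optional year label carried through the pipeline.
#' @return An object of class `land_use_grid`.
#' @export
land_use_grid <- function(codes, cell_size_m, xll = 0, yll = 0, year = NA) {
  if (!is.matrix(codes)) stop("`codes` must be a matrix")
  if (!is.numeric(cell_size_m) || length(cell_size_m) != 1 || cell_size_m <= 0)
    stop("`cell_size_m` must be a single positive number")
  codes <- matrix(as.integer(codes), nrow = nrow(codes))
  bad <- codes[!is.na(codes) & !(codes %in% 1:8)]
  if (length(bad))
    stop("codes outside the 8-class legend: ", paste(unique(bad), collapse = ", "))
  structure(
    list(codes = codes, cell_size_m = as.numeric(cell_size_m),
         xll = as.numeric(xll), yll = as.numeric(yll), year = year),
    class = "land_use_grid"
  )
}

#' @export
print.land_use_grid <- function(x, ...) {
  cat(sprintf("<land_use_grid> %d x %d cells, %g m, origin (%g, %g), year %s\n",
              nrow(x$codes), ncol(x$codes), x$cell_size_m, x$xll, x$yll,
              as.character(x$year)))
  tab <- table(factor(x$codes, levels = 1:8, labels = land_use_classes()$key))
  print(tab)
  invisible(x)
}

#' @export
dim.land_use_grid <- function(x) dim(x$codes)

#' Area of one cell in km^2
#' @param grid A `land_use_grid`.
#' @return Scalar km^2.
#' @export
cell_area_km2 <- function(grid) (grid$cell_size_m / 1000)^2

same_geometry <- function(a, b, tol = 1e-9) {
  identical(dim(a$codes), dim(b$codes)) &&
    abs(a$cell_size_m - b$cell_size_m) < tol &&
    abs(a$xll - b$xll) < tol && abs(a$yll - b$yll) < tol
}

stop_geometry <- function(a, b) {
  if (!same_geometry(a, b))
    stop("geometry mismatch: grids differ in shape, cell size or origin",
         call. = FALSE)
  invisible(TRUE)
}

#' Whole-raster class areas in km^2
#' @param grid A `land_use_grid`.
#' @return Named numeric vector over the 8 classes.
#' @export
class_areas <- function(grid) {
  counts <- tabulate(grid$codes[!is.na(grid$codes)], nbins = 8)
  stats::setNames(counts * cell_area_km2(grid), land_use_classes()$key)
}

# ---- ESRI ASCII grid I/O ------------------------------------------------

#' Write a grid as an ESRI ASCII raster
#'
#' Standard 6-line header (ncols, nrows, xllcorner, yllcorner, cellsize,
#' NODATA_value) followed by one text row per raster row, north first.
#'
#' @param grid A `land_use_grid` (or plain numeric matrix via `values`).
#' @param path Output path.
#' @param nodata NODATA_value written for NA cells.
#' @export
write_asc <- function(grid, path, nodata = -9999L) {
  m <- grid$codes
  m[is.na(m)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(m)),
    paste("nrows", nrow(m)),
    paste("xllcorner", format(grid$xll, scientific = FALSE)),
    paste("yllcorner", format(grid$yll, scientific = FALSE)),
    paste("cellsize", format(grid$cell_size_m, scientific = FALSE)),
    paste("NODATA_value", nodata)
  ), con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write an arbitrary numeric field as an ESRI ASCII raster
#' @param values Numeric matrix (row 1 = north).
#' @param geom A `land_use_grid` supplying cell size and origin.
#' @param path Output path.
#' @param nodata NODATA_value for NA cells.
#' @export
write_field_asc <- function(values, geom, path, nodata = -9999) {
  g <- geom
  g$codes <- NULL
  m <- values
  m[is.na(m)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(m)),
    paste("nrows", nrow(m)),
    paste("xllcorner", format(g$xll, scientific = FALSE)),
    paste("yllcorner", format(g$yll, scientific = FALSE)),
    paste("cellsize", format(g$cell_size_m, scientific = FALSE)),
    paste("NODATA_value", nodata)
  ), con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a land-use raster from an ESRI ASCII grid
#'
#' Codes outside `expected_classes` are mapped to nodata with a warning
#' reporting how many cells were remapped.
#'
#' @param path Path to an `.asc` file.
#' @param expected_classes Integer vector of legal class codes.
#' @param year Optional year label to attach.
#' @param reference Optional `land_use_grid`; if supplied the file must match
#'   its geometry exactly or an error is raised.
#' @return A `land_use_grid`.
#' @export
load_raster <- function(path, expected_classes = 1:8, year = NA, reference = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr_lines <- readLines(path, n = 6)
  hdr <- list()
  for (ln in hdr_lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not an ESRI ASCII grid (missing header fields): ", path)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(path, skip = 6, quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("cell count does not match header in ", path)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA
  illegal <- !is.na(m) & !(m %in% expected_classes)
  if (any(illegal)) {
    warning(sum(illegal), " cell(s) with codes outside the expected class set ",
            "mapped to nodata")
    m[illegal] <- NA
  }
  g <- land_use_grid(m, hdr$cellsize, hdr$xllcorner, hdr$yllcorner, year = year)
  if (!is.null(reference)) stop_geometry(g, reference)
  g
}

# ---- Assessment units ---------------------------------------------------

#' Tessellate a raster into square assessment units
#'
#' Divides the raster into blocks of `unit_size_m` x `unit_size_m` (the 1 x 1
#' km basic assessment unit by default). Blocks truncated at the south/east
#' edge are kept with their true, smaller area so that no boundary landscape
#' is discarded. Block bounds are half-open in cell indices: unit (ur, uc)
#' covers rows `[(ur-1)*f+1, min(ur*f, nrow)]`.
#'
#' @param grid A `land_use_grid`.
#' @param unit_size_m Unit edge length in metres; must be a positive integer
#'   multiple of the cell size.
#' @return An `assessment_units` object: `$units` data.frame (unit, urow,
#'   ucol, cell bounds, a_k km^2, nodata_km2, centroid, quadrant) and
#'   `$areas`, an n_units x 8 matrix of per-class areas A_ki in km^2.
#' @export
tessellate <- function(grid, unit_size_m = 1000) {
  f <- unit_size_m / grid$cell_size_m
  if (unit_size_m < grid$cell_size_m)
    stop("unit size smaller than one cell")
  if (abs(f - round(f)) > 1e-9)
    stop("`unit_size_m` must be an integer multiple of the cell size")
  f <- as.integer(round(f))
  nr <- nrow(grid$codes); nc <- ncol(grid$codes)
  n_ur <- ceiling(nr / f); n_uc <- ceiling(nc / f)
  ca <- cell_area_km2(grid)

  urow_of_cell <- (seq_len(nr) - 1L) %/% f + 1L
  ucol_of_cell <- (seq_len(nc) - 1L) %/% f + 1L
  # unit id of every cell, column-major like the codes matrix
  uid <- matrix(urow_of_cell, nr, nc) + (matrix(ucol_of_cell, nr, nc, byrow = TRUE) - 1L) * n_ur

  n_units <- n_ur * n_uc
  cls <- grid$codes
  valid <- !is.na(cls)
  # per-unit class-area matrix by cross tabulation of (unit id, class code)
  areas <- matrix(0, n_units, 8, dimnames = list(NULL, land_use_classes()$key))
  if (any(valid)) {
    tab <- table(factor(uid[valid], levels = seq_len(n_units)),
                 factor(cls[valid], levels = 1:8))
    areas <- unclass(tab) * ca
    dimnames(areas) <- list(NULL, land_use_classes()$key)
  }
  cells_per_unit <- tabulate(as.vector(uid), nbins = n_units)

  ur <- rep(seq_len(n_ur), times = n_uc)
  uc <- rep(seq_len(n_uc), each = n_ur)
  row0 <- (ur - 1L) * f + 1L; row1 <- pmin(ur * f, nr)
  col0 <- (uc - 1L) * f + 1L; col1 <- pmin(uc * f, nc)
  # map-coordinate centroid of the (possibly truncated) block
  cx <- grid$xll + (col0 - 1 + col1) / 2 * grid$cell_size_m
  cy <- grid$yll + (nr - (row0 - 1 + row1) / 2) * grid$cell_size_m

  units <- data.frame(
    unit = seq_len(n_units), urow = ur, ucol = uc,
    row0 = row0, row1 = row1, col0 = col0, col1 = col1,
    a_k = cells_per_unit * ca,
    nodata_km2 = cells_per_unit * ca - rowSums(areas),
    centroid_x = cx, centroid_y = cy,
    quadrant = NA_character_,
    stringsAsFactors = FALSE
  )
  structure(
    list(units = units, areas = areas, n_urow = n_ur, n_ucol = n_uc,
         unit_size_m = unit_size_m, cell_factor = f,
         geometry = list(nrow = nr, ncol = nc, cell_size_m = grid$cell_size_m,
                         xll = grid$xll, yll = grid$yll)),
    class = "assessment_units"
  )
}

#' @export
print.assessment_units <- function(x, ...) {
  cat(sprintf("<assessment_units> %d units (%d x %d) of %g m over a %d x %d raster\n",
              nrow(x$units), x$n_urow, x$n_ucol, x$unit_size_m,
              x$geometry$nrow, x$geometry$ncol))
  invisible(x)
}

QUADRANTS <- c("N", "NE", "E", "SE", "S", "SW", "W", "NW")

#' Assign eight-quadrant azimuth sectors to assessment units
#'
#' Each unit is labelled by the 45-degree sector of the azimuth from the
#' study-area centre to the unit centroid, measured clockwise from grid
#' north. Sectors are centred on the cardinal/intercardinal directions
#' (N covers azimuths \[-22.5, 22.5)). A centroid coincident with the centre
#' is assigned N by convention.
#'
#' @param units An `assessment_units` object.
#' @param center Optional `c(x, y)`; default is the raster centre.
#' @return The `assessment_units` with `$units$quadrant` filled.
#' @export
assign_quadrants <- function(units, center = NULL) {
  g <- units$geometry
  if (is.null(center))
    center <- c(g$xll + g$ncol * g$cell_size_m / 2,
                g$yll + g$nrow * g$cell_size_m / 2)
  if (center[1] < g$xll || center[1] > g$xll + g$ncol * g$cell_size_m ||
      center[2] < g$yll || center[2] > g$yll + g$nrow * g$cell_size_m)
    stop("center lies outside the raster bounds")
  dx <- units$units$centroid_x - center[1]
  dy <- units$units$centroid_y - center[2]
  az <- (atan2(dx, dy) * 180 / pi) %% 360   # clockwise from north
  sector <- (floor((az + 22.5) / 45) %% 8) + 1
  sector[dx == 0 & dy == 0] <- 1            # coincident with centre -> N
  units$units$quadrant <- QUADRANTS[sector]
  units
}

#' Export the unit table (with per-class areas) as CSV
#' @param units An `assessment_units` object.
#' @param path Output CSV path.
#' @export
write_units_csv <- function(units, path) {
  df <- cbind(units$units, as.data.frame(units$areas))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export unit blocks as GeoJSON polygons
#'
#' Plain FeatureCollection of axis-aligned rectangles in map coordinates;
#' properties carry unit id, quadrant and total area.
#'
#' @param units An `assessment_units` object.
#' @param path Output path.
#' @export
write_units_geojson <- function(units, path) {
  g <- units$geometry
  u <- units$units
  feat <- lapply(seq_len(nrow(u)), function(i) {
    x0 <- g$xll + (u$col0[i] - 1) * g$cell_size_m
    x1 <- g$xll + u$col1[i] * g$cell_size_m
    y1 <- g$yll + (g$nrow - u$row0[i] + 1) * g$cell_size_m
    y0 <- g$yll + (g$nrow - u$row1[i]) * g$cell_size_m
    list(
      type = "Feature",
      properties = list(unit = u$unit[i], quadrant = u$quadrant[i], a_k = u$a_k[i]),
      geometry = list(
        type = "Polygon",
        coordinates = list(list(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0)))
      )
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feat),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
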