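# Land-use change accounting: transfer matrices, grassland degradation /
# restoration intensities, and patch statistics.

#' Land-use transfer matrix between two dates
#'
#' Cell-wise cross-tabulation of the two co-registered rasters, scaled by
#' cell area: entry (i, j) is the area (km^2) occupied by class i at t1 and
#' class j at t2. Cells that are nodata at either date are excluded, so the
#' row sums equal the t1 class areas and the column sums the t2 class areas
#' over the jointly valid extent (exactly, by integer cell counting).
#'
#' @param grid_t1,grid_t2 `land_use_grid` objects with identical geometry.
#' @param dt Time interval in years; defaults to the difference of the two
#'   year labels.
#' @return An 8 x 8 matrix of class `transfer_matrix` with attribute `dt`.
#' @export
transfer_matrix <- function(grid_t1, grid_t2, dt = NULL) {
  stop_geometry(grid_t1, grid_t2)
  if (is.null(dt)) {
    y1 <- suppressWarnings(as.numeric(grid_t1$year))
    y2 <- suppressWarnings(as.numeric(grid_t2$year))
    if (is.na(y1) || is.na(y2))
      stop("`dt` must be given when year labels are not numeric")
    dt <- y2 - y1
  }
  if (dt <= 0) stop("`dt` must be positive")
  keys <- land_use_classes()$key
  ok <- !is.na(grid_t1$codes) & !is.na(grid_t2$codes)
  tab <- table(factor(grid_t1$codes[ok], levels = 1:8),
               factor(grid_t2$codes[ok], levels = 1:8))
  m <- unclass(tab) * cell_area_km2(grid_t1)
  dimnames(m) <- list(from = keys, to = keys)
  structure(m, dt = dt, class = c("transfer_matrix", "matrix"))
}

#' @export
print.transfer_matrix <- function(x, ...) {
  cat(sprintf("<transfer_matrix> km^2, dt = %g yr\n", attr(x, "dt")))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Export a transfer matrix as labeled CSV
#' @param tm A `transfer_matrix`.
#' @param path Output path.
#' @export
write_transfer_csv <- function(tm, path) {
  df <- as.data.frame.matrix(unclass(tm))
  df <- cbind(from = rownames(df), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Degradation targets (lower-coverage grassland, construction, saline-alkali)
# and restoration targets (higher-coverage grassland, water, woodland) per
# grassland class, under the fixed coverage ordering
# saline-alkali < low < medium < high.
degradation_targets <- function(code) switch(as.character(code),
  "2" = c(3L, 4L, 7L, 8L), "3" = c(4L, 7L, 8L), "4" = c(7L, 8L))
restoration_targets <- function(code) switch(as.character(code),
  "2" = c(1L, 5L), "3" = c(2L, 1L, 5L), "4" = c(3L, 2L, 1L, 5L))

#' Grassland degradation and restoration intensities
#'
#' For each grassland class i, the degradation intensity K_i1 is the area
#' transferred to lower-coverage grassland, construction land or
#' saline-alkali land, divided by the class's initial area and by the time
#' interval; the restoration intensity K_i2 counts transfers to
#' higher-coverage grassland, water or woodland. Units: fraction per year.
#' Classes absent at t1 get NA intensities (undefined, not zero).
#'
#' @param tm A `transfer_matrix`.
#' @return data.frame with columns `class`, `s_it` (initial area, km^2),
#'   `k1`, `k2`.
#' @export
grassland_intensities <- function(tm) {
  stopifnot(inherits(tm, "transfer_matrix"))
  dt <- attr(tm, "dt")
  m <- unclass(tm)
  out <- lapply(grassland_codes(), function(code) {
    s_it <- sum(m[code, ])
    if (s_it <= 0) return(c(s_it = 0, k1 = NA_real_, k2 = NA_real_))
    c(s_it = s_it,
      k1 = sum(m[code, degradation_targets(code)]) / s_it / dt,
      k2 = sum(m[code, restoration_targets(code)]) / s_it / dt)
  })
  df <- as.data.frame(do.call(rbind, out))
  df <- cbind(class = names(grassland_codes()), df)
  rownames(df) <- NULL
  df
}

# Connected components of a logical mask under 4- or 8-connectivity,
# via igraph on the cell adjacency of TRUE cells.
count_patches <- function(mask, connectivity = 8) {
  idx <- which(mask)
  if (!length(idx)) return(0L)
  nr <- nrow(mask)
  id <- matrix(NA_integer_, nrow(mask), ncol(mask))
  id[idx] <- seq_along(idx)
  edges <- list()
  shifts <- list(c(1, 0), c(0, 1))
  if (connectivity == 8) shifts <- c(shifts, list(c(1, 1), c(1, -1)))
  else if (connectivity != 4) stop("connectivity must be 4 or 8")
  rc <- arrayInd(idx, dim(mask))
  for (s in shifts) {
    r2 <- rc[, 1] + s[1]; c2 <- rc[, 2] + s[2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= ncol(mask)
    ok[ok] <- !is.na(id[cbind(r2[ok], c2[ok])])
    if (any(ok))
      edges[[length(edges) + 1]] <-
        cbind(id[cbind(rc[ok, 1], rc[ok, 2])], id[cbind(r2[ok], c2[ok])])
  }
  el <- if (length(edges)) do.call(rbind, edges) else matrix(integer(), 0, 2)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, length(idx) - igraph::vcount(g))
  as.integer(igraph::components(g)$no)
}

#' Patch counts and fragmentation per land-use class
#'
#' N_i is the number of connected components of class i under the chosen
#' connectivity (default 8, the landscape-ecology convention); the
#' fragmentation index is patch density C_i = N_i / A_i (patches per km^2)
#' by default, or any user-supplied function of (N_i, A_i).
#'
#' @param grid A `land_use_grid`.
#' @param connectivity 4 or 8.
#' @param fragmentation Function `(n, a) -> C`; default patch density.
#' @return data.frame with columns `class`, `code`, `n_patches`, `area_km2`,
#'   `c_i` (NA where the class is absent).
#' @export
patch_stats <- function(grid, connectivity = 8, fragmentation = function(n, a) n / a) {
  cls <- land_use_classes()
  areas <- class_areas(grid)
  n <- vapply(cls$code, function(code)
    count_patches(!is.na(grid$codes) & grid$codes == code, connectivity),
    integer(1))
  c_i <- ifelse(areas > 0, fragmentation(n, areas), NA_real_)
  data.frame(class = cls$key, code = cls$code, n_patches = n,
             area_km2 = as.numeric(areas), c_i = as.numeric(c_i),
             stringsAsFactors = FALSE)
}
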